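#' Run the selection pipeline from a configuration
#'
#' Orchestrates the standard chain — obtain data (simulate, or read a matrix
#' and labels), preprocess (missingness filter, zero-variance filter, KNN
#' imputation, optional log2 transform and z-scaling), score with sDCFE, and
#' select top features — writing each stage's outputs plus a run manifest to
#' `out_dir`. The manifest records the package version, the full resolved
#' configuration (seeds included), per-stage row/column counts, and md5
#' checksums of every written file; it contains no wall-clock state, so a
#' rerun with an identical configuration reproduces it byte for byte. A
#' stage failure halts the run with the failing stage named; outputs of
#' completed stages are preserved.
#'
#' @param config a configuration list, or the path to a JSON file holding
#'   one. Recognized sections: `out_dir` (required), `simulate` (arguments
#'   for [simulation_config()]) or `input` (`matrix`, `labels`, optional
#'   `transpose`), `preprocess` (`max_feature_missing_rate`, `knn_k`,
#'   `log2`, `log_offset`, `scale`), `sdcfe` (arguments for
#'   [sdcfe_params()]), `select` (`fraction` or `top_k`).
#' @return the manifest list, invisibly; written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  if (is.null(config$out_dir)) stop("config field 'out_dir' is required")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(package = "sdcfe",
                   version = as.character(utils::packageVersion("sdcfe")),
                   config = config, stages = list())
  outputs <- character(0)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- data stage -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- run_stage("simulate", {
      cfg <- do.call(simulation_config, as.list(config$simulate))
      simulate_expression(cfg)
    })
    m <- sim$matrix
    y <- sim$labels
    lab_path <- file.path(out_dir, "labels.tsv")
    utils::write.table(data.frame(sample_id = rownames(m), label = as.character(y)),
                       lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
    planted_path <- file.path(out_dir, "planted_genes.txt")
    writeLines(sim$planted, planted_path)
    mat_path <- file.path(out_dir, "simulated_matrix.tsv")
    write_omics(m, mat_path)
    outputs <- c(outputs, mat_path, lab_path, planted_path)
    manifest$stages$simulate <- list(rows = nrow(m), cols = ncol(m),
                                     n_planted = length(sim$planted),
                                     seed = sim$cfg$seed,
                                     outputs = basename(c(mat_path, lab_path, planted_path)))
  } else if (!is.null(config$input)) {
    loaded <- run_stage("input", {
      if (is.null(config$input$matrix)) stop("config field 'input$matrix' is required")
      if (is.null(config$input$labels)) stop("config field 'input$labels' is required")
      m <- read_omics(config$input$matrix,
                      transpose = isTRUE(config$input$transpose))
      clin <- read_clinical(config$input$labels)
      match_clinical(m, clin, keep_labels = config$input$keep_labels)
    })
    m <- loaded$matrix
    y <- loaded$labels
    manifest$stages$input <- list(rows = nrow(m), cols = ncol(m),
                                  n_classes = nlevels(y))
  } else {
    stop("config must contain either a 'simulate' or an 'input' section")
  }

  # --- preprocess stage -----------------------------------------------------
  pp <- config$preprocess
  if (is.null(pp)) pp <- list()
  m <- run_stage("preprocess", {
    max_rate <- if (is.null(pp$max_feature_missing_rate)) 0.5 else pp$max_feature_missing_rate
    out <- filter_missing_features(m, max_rate)
    if (anyNA(out)) out <- knn_impute(out, k = if (is.null(pp$knn_k)) 5L else pp$knn_k)
    out <- drop_zero_variance(out)
    if (isTRUE(pp$log2)) {
      out <- log2_transform(out, offset = if (is.null(pp$log_offset)) 1 else pp$log_offset)
    }
    if (isTRUE(pp$scale)) out <- zscore_scale(out)$matrix
    out
  })
  manifest$stages$preprocess <- list(rows = nrow(m), cols = ncol(m))

  # --- score stage ----------------------------------------------------------
  score_tab <- run_stage("score", {
    params <- do.call(sdcfe_params, as.list(config$sdcfe))
    sdcfe_score(m, y, params)
  })
  score_path <- file.path(out_dir, "score_table.tsv")
  write_score_table(score_tab, score_path)
  outputs <- c(outputs, score_path)
  manifest$stages$score <- list(rows = nrow(score_tab),
                                outputs = basename(score_path))

  # --- select stage ---------------------------------------------------------
  sel <- config$select
  if (!is.null(sel)) {
    fs <- run_stage("select", {
      if (!is.null(sel$top_k)) select_top_k(score_tab, sel$top_k)
      else if (!is.null(sel$fraction)) select_top_fraction(score_tab, sel$fraction)
      else stop("config section 'select' needs 'fraction' or 'top_k'")
    })
    sel_path <- file.path(out_dir, "selected_features.txt")
    write_feature_set(fs, sel_path)
    outputs <- c(outputs, sel_path)
    manifest$stages$select <- list(n_selected = length(fs),
                                   outputs = basename(sel_path))
  }

  manifest$checksums <- as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                                basename(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
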