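#' Simulation configuration
#'
#' Defines the statistical structure of a synthetic expression cohort:
#' multi-class log-scale expression with a block of planted class-informative
#' genes, an optional disjoint block of genes carrying latent subtype
#' structure orthogonal to the class labels (the signal the
#' cluster-separation component is designed to detect), Gaussian noise, and
#' optional MCAR missingness. The defaults mirror the parameter-recovery
#' study conditions: 4 classes, 50 samples per class, 1000 genes, 30
#' informative genes at a 2-population-sd class shift.
#'
#' @param n_classes number of classes.
#' @param n_per_class samples per class (scalar or one value per class).
#' @param n_genes total genes.
#' @param n_informative genes carrying class signal.
#' @param effect_size class-mean shift in units of `noise_sd`.
#' @param n_subtypes number of latent subtypes (0 disables the block).
#' @param subtype_effect subtype-mean shift in units of `noise_sd`.
#' @param n_subtype_genes genes carrying subtype signal (disjoint from the
#'   informative block; default `n_informative`).
#' @param noise_sd residual standard deviation (> 0).
#' @param missing_rate MCAR cell-masking probability in `[0, 1)`.
#' @param seed integer seed; the whole draw is deterministic given it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_classes = 4L, n_per_class = 50L,
                              n_genes = 1000L, n_informative = 30L,
                              effect_size = 2, n_subtypes = 2L,
                              subtype_effect = 2,
                              n_subtype_genes = n_informative,
                              noise_sd = 1, missing_rate = 0, seed = 1L) {
  stopifnot(n_classes >= 1, n_genes >= 1, n_informative >= 0,
            n_informative + (if (n_subtypes > 0) n_subtype_genes else 0) <= n_genes,
            n_subtypes >= 0, noise_sd > 0,
            missing_rate >= 0, missing_rate < 1)
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, n_classes)
  if (length(n_per_class) != n_classes) stop("n_per_class must have one value per class")
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, n_subtypes = as.integer(n_subtypes),
                 subtype_effect = subtype_effect,
                 n_subtype_genes = as.integer(n_subtype_genes),
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate a multi-class expression cohort
#'
#' Baseline expression is drawn on the log scale as
#' `Normal(mean = 6, sd = noise_sd)` (the regime of log2-transformed
#' RNA-seq). A random block of `n_informative` genes receives a
#' class-specific mean shift of magnitude `effect_size * noise_sd`: each
#' planted gene is up-shifted in one class (a marker-gene design). When
#' `n_subtypes > 0`, a disjoint block of `n_subtype_genes` genes receives an
#' analogous shift tied to latent subtype labels drawn independently of the
#' class, producing genes that separate clusters but not classes.
#'
#' @param cfg a [simulation_config()].
#' @return list with `matrix` (samples x genes [omics_matrix()]), `labels`
#'   (class factor), `planted` (informative gene ids), `subtype_genes`
#'   (subtype-block gene ids), `subtypes` (latent subtype factor), and `cfg`.
#' @export
simulate_expression <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_sim_seed(cfg$seed, {
    n <- sum(cfg$n_per_class)
    labels <- factor(rep(sprintf("class%d", seq_len(cfg$n_classes)),
                         cfg$n_per_class))
    gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
    sample_ids <- sprintf("sample%04d", seq_len(n))

    m <- matrix(stats::rnorm(n * cfg$n_genes, mean = 6, sd = cfg$noise_sd),
                n, cfg$n_genes, dimnames = list(sample_ids, gene_ids))

    n_sub_genes <- if (cfg$n_subtypes > 0) cfg$n_subtype_genes else 0L
    special <- sample(cfg$n_genes, cfg$n_informative + n_sub_genes)
    planted <- sort(special[seq_len(cfg$n_informative)])
    subtype_genes <- sort(special[cfg$n_informative + seq_len(n_sub_genes)])

    shift <- cfg$effect_size * cfg$noise_sd
    if (cfg$n_informative > 0) {
      up_class <- sample(cfg$n_classes, cfg$n_informative, replace = TRUE)
      for (g in seq_len(cfg$n_informative)) {
        rows <- labels == levels(labels)[up_class[g]]
        m[rows, planted[g]] <- m[rows, planted[g]] + shift
      }
    }

    subtypes <- factor(rep("subtype1", n))
    if (cfg$n_subtypes > 0) {
      subtypes <- factor(sprintf("subtype%d",
                                 sample(cfg$n_subtypes, n, replace = TRUE)))
      sshift <- cfg$subtype_effect * cfg$noise_sd
      up_sub <- sample(cfg$n_subtypes, n_sub_genes, replace = TRUE)
      for (g in seq_len(n_sub_genes)) {
        rows <- subtypes == levels(subtypes)[up_sub[g]]
        m[rows, subtype_genes[g]] <- m[rows, subtype_genes[g]] + sshift
      }
    }

    out_m <- omics_matrix(m, omics_tag = "rna")
    if (cfg$missing_rate > 0) {
      out_m <- inject_missing(out_m, cfg$missing_rate,
                              seed = cfg$seed + 1000003L)
    }
    list(matrix = out_m, labels = labels, planted = gene_ids[planted],
         subtype_genes = gene_ids[subtype_genes], subtypes = subtypes,
         cfg = cfg)
  })
}

#' Simulate a paired two-omics cohort
#'
#' Generates an expression-like matrix and a methylation-like matrix over
#' cohorts whose sample-id sets partially overlap; shared samples carry
#' consistent class labels in both assays (the "patients with both assays"
#' situation that late fusion requires). Methylation values are a logistic
#' transform of latent Gaussians and therefore bounded in (0, 1).
#'
#' @param cfg_a config for the expression assay.
#' @param cfg_b config for the methylation assay; must have the same class
#'   structure as `cfg_a`.
#' @param overlap_fraction fraction in `(0, 1]` of the smaller cohort's
#'   samples that also appear in the other cohort.
#' @param seed integer seed.
#' @return list with `rna` and `meth` ([omics_matrix()]s), `labels_rna`,
#'   `labels_meth` (factors in matrix row order), and `shared_ids`.
#' @export
simulate_paired_omics <- function(cfg_a = simulation_config(),
                                  cfg_b = cfg_a, overlap_fraction = 0.5,
                                  seed = 1L) {
  if (overlap_fraction <= 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in (0, 1]")
  }
  if (cfg_a$n_classes != cfg_b$n_classes) {
    stop("the two assays must share the class structure")
  }
  with_sim_seed(seed, {
    n_a <- sum(cfg_a$n_per_class); n_b <- sum(cfg_b$n_per_class)
    n_shared <- max(1L, round(overlap_fraction * min(n_a, n_b)))
    n_total <- n_a + n_b - n_shared
    ids <- sprintf("patient%04d", seq_len(n_total))
    # cohort-level labels, then assay membership
    labels_all <- factor(sprintf("class%d",
                                 sample(cfg_a$n_classes, n_total, replace = TRUE)))
    ids_a <- ids[seq_len(n_a)]
    ids_b <- ids[c(seq_len(n_shared), n_a + seq_len(n_b - n_shared))]

    rna <- sim_assay(ids_a, labels_all[match(ids_a, ids)], cfg_a,
                     transform = identity, tag = "rna")
    meth <- sim_assay(ids_b, labels_all[match(ids_b, ids)], cfg_b,
                      transform = function(x) stats::plogis(x - 6),
                      tag = "methylation")
    list(rna = rna, meth = meth,
         labels_rna = droplevels(labels_all[match(ids_a, ids)]),
         labels_meth = droplevels(labels_all[match(ids_b, ids)]),
         shared_ids = ids[seq_len(n_shared)])
  })
}

# One assay with given sample ids/labels; class shifts on a random planted
# block, then an elementwise transform (logistic for methylation-like data).
sim_assay <- function(ids, labels, cfg, transform, tag) {
  n <- length(ids)
  gene_ids <- sprintf("%s_feat%04d", substr(tag, 1, 4), seq_len(cfg$n_genes))
  m <- matrix(stats::rnorm(n * cfg$n_genes, mean = 6, sd = cfg$noise_sd),
              n, cfg$n_genes, dimnames = list(ids, gene_ids))
  if (cfg$n_informative > 0) {
    planted <- sample(cfg$n_genes, cfg$n_informative)
    up_class <- sample(cfg$n_classes, cfg$n_informative, replace = TRUE)
    shift <- cfg$effect_size * cfg$noise_sd
    lev <- sprintf("class%d", seq_len(cfg$n_classes))
    for (g in seq_along(planted)) {
      rows <- as.character(labels) == lev[up_class[g]]
      m[rows, planted[g]] <- m[rows, planted[g]] + shift
    }
  }
  omics_matrix(transform(m), omics_tag = tag)
}

#' Mask cells completely at random
#'
#' Each cell is independently set to `NA` with probability `rate`;
#' deterministic given `seed`.
#'
#' @param m omics matrix.
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer seed.
#' @return matrix with missing cells.
#' @export
inject_missing <- function(m, rate, seed = 1L) {
  check_matrix(m)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(m)
  with_sim_seed(seed, {
    mask <- stats::runif(length(m)) < rate
    m[mask] <- NA_real_
    m
  })
}
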