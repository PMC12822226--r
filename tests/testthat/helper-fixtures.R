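# Small builders shared across the suite. All fixtures are generated in code.

mk_matrix <- function(values, n_samples = NULL, tag = "rna") {
  if (!is.matrix(values)) {
    stopifnot(!is.null(n_samples))
    values <- matrix(values, nrow = n_samples)
  }
  dimnames(values) <- list(sprintf("s%02d", seq_len(nrow(values))),
                           sprintf("g%02d", seq_len(ncol(values))))
  omics_matrix(values, omics_tag = tag)
}

# The two-class toy used throughout: one gene, A = (0, 2), B = (4, 6).
toy_two_class <- function() {
  list(m = mk_matrix(c(0, 2, 4, 6), n_samples = 4),
       y = factor(c("A", "A", "B", "B")))
}

# Independent brute-force oracle for the weighted between/within variance
# ratio (lambda = 0 case), written from the definition with explicit loops
# so it shares no code path with dcfe_scores().
fisher_ratio_oracle <- function(m, y) {
  y <- as.factor(y)
  N <- nrow(m)
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    grand <- mean(x)
    between <- 0
    within <- 0
    for (c in levels(y)) {
      xc <- x[y == c]
      w <- length(xc) / N
      between <- between + w * (mean(xc) - grand)^2
      within <- within + w * mean((xc - mean(xc))^2)
    }
    out[j] <- between / (within + 1e-12)
  }
  names(out) <- colnames(m)
  out
}

# Evidence-table row builder: gene plus named presence flags.
ev_row <- function(gene, present = character(0)) {
  cols <- c(CURATED_RESOURCES, ASSOCIATION_RESOURCES)
  row <- as.list(as.integer(cols %in% present))
  names(row) <- cols
  cbind(data.frame(gene = gene, stringsAsFactors = FALSE),
        as.data.frame(row, check.names = FALSE))
}
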