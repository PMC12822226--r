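#' Evidence resources used for biomarker tiering
#'
#' Four curated biomarker/driver databases and two cancer-association
#' resources. The tiering rule treats the categories differently: presence
#' in any curated database establishes a gene, while association-only
#' evidence marks it as emerging.
#'
#' @format Character vectors of column names.
#' @name evidence_resources
NULL

#' @rdname evidence_resources
#' @export
CURATED_RESOURCES <- c("COSMIC", "OncoKB", "CIViC", "ONGene")

#' @rdname evidence_resources
#' @export
ASSOCIATION_RESOURCES <- c("HPA", "DisGeNET")

# Validate a gene x resource binary evidence table.
check_evidence <- function(ev) {
  if (!is.data.frame(ev)) stop("evidence must be a data frame")
  gene_col <- intersect(c("gene", "gene_id"), names(ev))[1]
  if (is.na(gene_col)) stop("evidence table needs a 'gene' column")
  resources <- c(CURATED_RESOURCES, ASSOCIATION_RESOURCES)
  missing <- setdiff(resources, names(ev))
  if (length(missing)) {
    stop("evidence table missing resource column(s): ",
         paste(missing, collapse = ", "))
  }
  vals <- as.matrix(ev[, resources, drop = FALSE])
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    stop("evidence entries must all be 0 or 1")
  }
  if (anyDuplicated(ev[[gene_col]])) stop("duplicate gene ids in evidence table")
  list(gene = as.character(ev[[gene_col]]), values = vals)
}

#' Mean presence score across evidence resources
#'
#' Arithmetic mean of the six binary presence indicators per gene.
#'
#' @param ev evidence data frame with a `gene` column and binary columns
#'   `COSMIC`, `OncoKB`, `CIViC`, `ONGene`, `HPA`, `DisGeNET`.
#' @return named numeric vector of means in `[0, 1]`.
#' @export
mean_presence <- function(ev) {
  parsed <- check_evidence(ev)
  stats::setNames(rowMeans(parsed$values), parsed$gene)
}

#' Tier candidate biomarkers by database evidence
#'
#' Categorical rule, in order of precedence: presence in any curated
#' biomarker/driver database (COSMIC, OncoKB, CIViC, ONGene) makes a gene an
#' established biomarker; otherwise any presence (necessarily in the
#' association resources HPA/DisGeNET) makes it an emerging candidate;
#' absence from all six resources makes it a novel candidate. The mean
#' presence score is reported alongside (`mean = 0` iff novel).
#'
#' @param ev evidence data frame (see [mean_presence()]).
#' @return data frame with columns `gene_id`, `mean_presence`, `tier`
#'   (factor `novel` / `emerging` / `established`).
#' @export
classify_tiers <- function(ev) {
  parsed <- check_evidence(ev)
  curated_any <- rowSums(parsed$values[, CURATED_RESOURCES, drop = FALSE]) > 0
  any_presence <- rowSums(parsed$values) > 0
  tier <- ifelse(curated_any, "established",
                 ifelse(any_presence, "emerging", "novel"))
  data.frame(gene_id = parsed$gene,
             mean_presence = rowMeans(parsed$values),
             tier = factor(tier, levels = c("novel", "emerging", "established")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tier counts
#'
#' @param ev evidence data frame, or the output of [classify_tiers()].
#' @return named integer vector with counts for `novel`, `emerging`,
#'   `established` (summing to the number of genes).
#' @export
tier_summary <- function(ev) {
  tiers <- if (is.data.frame(ev) && "tier" %in% names(ev)) ev else classify_tiers(ev)
  counts <- table(factor(tiers$tier, levels = c("novel", "emerging", "established")))
  stats::setNames(as.integer(counts), names(counts))
}

#' Read an evidence table from CSV
#'
#' Expects header `gene,COSMIC,OncoKB,CIViC,ONGene,HPA,DisGeNET`.
#'
#' @param path CSV file path.
#' @return validated evidence data frame.
#' @export
read_evidence <- function(path) {
  ev <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_evidence(ev)
  ev
}
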