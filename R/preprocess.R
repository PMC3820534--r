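#' Filter RNA-seq experiments by coverage quality
#'
#' Removes experiments with fewer than `min_reads` total reads or with less
#' than `min_mapped` of reads successfully mapped. The inequalities are
#' strict removals, so experiments sitting exactly on a boundary are kept.
#'
#' @param metas data frame with columns `experiment_id`, `total_reads`,
#'   `mapped_fraction`.
#' @param min_reads minimum total read count (default 1e7).
#' @param min_mapped minimum mapped fraction in \[0,1\] (default 0.5).
#' @return Character vector of surviving experiment ids. A warning is issued
#'   if nothing survives.
#' @export
filter_experiments <- function(metas, min_reads = 1e7, min_mapped = 0.5) {
  req <- c("experiment_id", "total_reads", "mapped_fraction")
  if (!is.data.frame(metas) || !all(req %in% names(metas)))
    stop("`metas` must have columns experiment_id, total_reads, mapped_fraction")
  if (!nrow(metas)) stop("`metas` is empty")
  if (anyDuplicated(metas$experiment_id))
    stop("duplicate experiment ids in metadata")
  if (any(metas$mapped_fraction < 0 | metas$mapped_fraction > 1))
    stop("mapped_fraction must lie in [0, 1]")
  keep <- metas$total_reads >= min_reads & metas$mapped_fraction >= min_mapped
  out <- as.character(metas$experiment_id[keep])
  if (!length(out))
    warning("no experiments survive the coverage filters")
  out
}

#' Filter genes by detection frequency
#'
#' A gene is "detected" in an experiment when at least one of its isoforms
#' has FPKM > 0 there. Genes detected in less than `min_detect_fraction` of
#' the experiments are removed together with all their isoform rows; genes
#' at exactly the boundary are kept.
#'
#' @param raw an `expression_matrix` in `"fpkm"` space.
#' @param bags a `bag_map` covering every isoform row of `raw`.
#' @param min_detect_fraction minimum fraction of experiments in which a gene
#'   must be detected (default 0.5).
#' @return A list with the filtered `matrix` (class `expression_matrix`),
#'   the consistent `bags`, and `dropped_genes`.
#' @export
filter_genes <- function(raw, bags, min_detect_fraction = 0.5) {
  stopifnot(inherits(raw, "expression_matrix"), inherits(bags, "bag_map"))
  if (raw$space != "fpkm")
    stop("gene detection filtering applies to the FPKM-space matrix")
  iso <- isoform_ids(raw)
  genes <- gene_of(bags, iso)  # errors on unassigned rows, naming them
  detected <- raw$values > 0
  detected[is.na(detected)] <- FALSE
  # per gene per experiment: any isoform detected
  gene_det <- rowsum(detected + 0L, group = genes) > 0
  n_exp <- ncol(raw$values)
  frac <- rowSums(gene_det) / n_exp
  keep_genes <- rownames(gene_det)[frac >= min_detect_fraction]
  dropped <- setdiff(rownames(gene_det), keep_genes)
  if (!length(keep_genes))
    warning("no genes survive the detection filter")
  keep_iso <- iso[genes %in% keep_genes]
  list(matrix = subset_matrix(raw, isoforms = keep_iso),
       bags = subset_bags(bags, keep_genes),
       dropped_genes = dropped)
}

#' Log2-transform an FPKM matrix
#'
#' Positive FPKM values become log2(FPKM). Missing cells (`NA`) and zero
#' FPKM cells -- indistinguishable from unobserved expression in quantifier
#' output -- are floored at the `sentinel` value. Applying the transform to
#' an already-transformed matrix is rejected via the space flag, preventing
#' accidental double transforms.
#'
#' @param raw an `expression_matrix` in `"fpkm"` space.
#' @param sentinel value used for missing/zero cells (default -15).
#' @return An `expression_matrix` in `"log2"` space.
#' @export
log_transform <- function(raw, sentinel = -15) {
  stopifnot(inherits(raw, "expression_matrix"))
  if (raw$space != "fpkm")
    stop("matrix is already in log2 space; refusing to transform twice")
  v <- raw$values
  if (any(v < 0, na.rm = TRUE)) stop("negative FPKM values are not allowed")
  out <- ifelse(is.na(v) | v == 0, sentinel, log2(v))
  dimnames(out) <- dimnames(v)
  expression_matrix(out, space = "log2", sentinel = sentinel)
}
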