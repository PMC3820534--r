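#' Gene-to-isoform bag map
#'
#' In the multiple-instance view a gene is a "bag" containing its isoforms as
#' instances. A `bag_map` records the gene -> isoform partition: every isoform
#' belongs to exactly one gene and every gene has at least one isoform.
#'
#' @param gene_id,isoform_id character vectors of equal length giving
#'   (gene, isoform) pairs. Exact duplicate pairs are collapsed; an isoform
#'   mapped to two different genes is an error.
#' @return An object of class `bag_map`: a data frame with columns
#'   `gene_id` and `isoform_id`.
#' @examples
#' bags <- bag_map(c("g1", "g1", "g2"), c("g1.1", "g1.2", "g2.1"))
#' isoforms_of(bags, "g1")
#' @export
bag_map <- function(gene_id, isoform_id) {
  gene_id <- as.character(gene_id)
  isoform_id <- as.character(isoform_id)
  if (length(gene_id) != length(isoform_id))
    stop("gene_id and isoform_id must have equal length")
  if (!length(gene_id)) stop("bag map cannot be empty")
  df <- unique(data.frame(gene_id = gene_id, isoform_id = isoform_id,
                          stringsAsFactors = FALSE))
  dup <- df$isoform_id[duplicated(df$isoform_id)]
  if (length(dup))
    stop("isoform(s) mapped to more than one gene: ",
         paste(unique(utils::head(dup, 5)), collapse = ", "))
  class(df) <- c("bag_map", "data.frame")
  df
}

#' @export
print.bag_map <- function(x, ...) {
  cat(sprintf("<bag_map> %d genes, %d isoforms\n",
              length(unique(x$gene_id)), nrow(x)))
  invisible(x)
}

#' @rdname bag_map
#' @param bags a `bag_map`.
#' @export
bag_genes <- function(bags) unique(bags$gene_id)

#' @rdname bag_map
#' @export
bag_isoforms <- function(bags) bags$isoform_id

#' @rdname bag_map
#' @param gene a single gene id.
#' @export
isoforms_of <- function(bags, gene) {
  iso <- bags$isoform_id[bags$gene_id == gene]
  if (!length(iso)) stop("unknown gene id: ", gene)
  iso
}

#' @rdname bag_map
#' @param isoforms character vector of isoform ids.
#' @export
gene_of <- function(bags, isoforms) {
  lut <- stats::setNames(bags$gene_id, bags$isoform_id)
  out <- lut[isoforms]
  if (anyNA(out))
    stop("isoform(s) without a gene assignment: ",
         paste(utils::head(isoforms[is.na(out)], 5), collapse = ", "))
  unname(out)
}

#' Restrict a bag map to a set of genes
#'
#' @param bags a `bag_map`.
#' @param genes gene ids to keep.
#' @return A `bag_map` containing only the requested genes.
#' @export
subset_bags <- function(bags, genes) {
  keep <- bags$gene_id %in% genes
  if (!any(keep)) stop("no bags left after subsetting")
  bag_map(bags$gene_id[keep], bags$isoform_id[keep])
}

#' Number of isoforms per gene
#'
#' @param bags a `bag_map`.
#' @return Named integer vector, one entry per gene.
#' @export
isoform_counts <- function(bags) {
  tab <- table(bags$gene_id)
  stats::setNames(as.integer(tab), names(tab))
}
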