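#' Ontology of functional terms
#'
#' A directed acyclic graph of terms connected by `is_a` (and optionally
#' `part_of`) child -> parent edges, as used for propagating gene
#' annotations up the Gene Ontology hierarchy.
#'
#' @param term_ids character vector of unique term ids.
#' @param edges data frame with columns `child`, `parent`; both endpoints
#'   must be known terms and the edge set must be acyclic.
#' @return An object of class `ontology`.
#' @export
ontology <- function(term_ids, edges) {
  term_ids <- as.character(term_ids)
  if (anyDuplicated(term_ids)) stop("duplicate term ids")
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  }
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  unknown <- setdiff(c(edges$child, edges$parent), term_ids)
  if (length(unknown))
    stop("edge endpoint(s) not in term set: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  edges <- unique(edges[, c("child", "parent")])
  # children adjacency for descendant traversal
  children <- split(edges$child, factor(edges$parent, levels = term_ids))
  obj <- structure(list(term_ids = term_ids, edges = edges,
                        children = children),
                   class = "ontology")
  if (.has_cycle(obj)) stop("ontology edges contain a cycle")
  obj
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d edges\n",
              length(x$term_ids), nrow(x$edges)))
  invisible(x)
}

# Kahn-style check: repeatedly peel terms with no remaining children
.has_cycle <- function(ont) {
  deg <- stats::setNames(integer(length(ont$term_ids)), ont$term_ids)
  tab <- table(ont$edges$parent)
  deg[names(tab)] <- as.integer(tab)
  parents_of <- split(ont$edges$parent, ont$edges$child)
  queue <- names(deg)[deg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (p in parents_of[[t]]) {
      deg[[p]] <- deg[[p]] - 1L
      if (deg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  seen < length(ont$term_ids)
}

#' Transitive descendants of a term
#'
#' Returns the transitive closure of children of `term` (the term itself is
#' excluded), i.e. all terms whose annotations propagate up to `term`.
#'
#' @param ont an `ontology`.
#' @param term a term id present in `ont`.
#' @return Character vector of descendant term ids (possibly empty).
#' @export
descendants <- function(ont, term) {
  stopifnot(inherits(ont, "ontology"))
  if (!term %in% ont$term_ids) stop("unknown term: ", term)
  out <- character()
  frontier <- ont$children[[term]]
  while (length(frontier)) {
    new <- setdiff(frontier, out)
    out <- c(out, new)
    frontier <- unique(unlist(ont$children[new], use.names = FALSE))
  }
  sort(unique(out))
}

#' Per-term gold standard of positive and negative genes
#'
#' Holds the bag labels for one functional term: `positives` are the genes
#' annotated to the term (after propagation), `negatives` the rest of the
#' gene universe.
#'
#' @param term_id term identifier.
#' @param positives,negatives disjoint character vectors of gene ids.
#' @return An object of class `term_standard`.
#' @export
term_standard <- function(term_id, positives, negatives) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (length(intersect(positives, negatives)))
    stop("positives and negatives overlap for term ", term_id)
  structure(list(term_id = term_id, positives = positives,
                 negatives = negatives),
            class = "term_standard")
}

#' @export
print.term_standard <- function(x, ...) {
  cat(sprintf("<term_standard> %s: %d positives, %d negatives\n",
              x$term_id, length(x$positives), length(x$negatives)))
  invisible(x)
}

#' Build the gold standard for one term
#'
#' Genes annotated to `term` or to any of its descendants are positives
#' (intersected with `universe`); all other genes in the universe are
#' negatives. Annotations referencing genes outside the universe are dropped
#' silently but counted in a message.
#'
#' @param ont an `ontology`.
#' @param annotations data frame with columns `gene_id`, `term_id`.
#' @param term the term to build a standard for.
#' @param universe character vector of genes under consideration (the bag
#'   map's genes).
#' @return A `term_standard`.
#' @export
build_term_standard <- function(ont, annotations, term, universe) {
  stopifnot(is.data.frame(annotations),
            all(c("gene_id", "term_id") %in% names(annotations)))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe")
  terms <- c(term, descendants(ont, term))
  hits <- annotations[annotations$term_id %in% terms, , drop = FALSE]
  outside <- setdiff(unique(hits$gene_id), universe)
  if (length(outside))
    message(length(outside), " annotated gene(s) outside the universe dropped for ",
            term)
  pos <- intersect(universe, unique(hits$gene_id))
  term_standard(term, pos, setdiff(universe, pos))
}

#' Keep terms with a tractable number of positives
#'
#' Retains gold standards whose positive set size lies in
#' \[`min_pos`, `max_pos`\] (inclusive on both ends).
#'
#' @param standards list of `term_standard` objects.
#' @param min_pos,max_pos inclusive bounds on the positive-gene count
#'   (defaults 20 and 300).
#' @return Filtered list of `term_standard` objects.
#' @export
select_terms <- function(standards, min_pos = 20, max_pos = 300) {
  sizes <- vapply(standards, function(s) length(s$positives), integer(1))
  standards[sizes >= min_pos & sizes <= max_pos]
}

#' Group terms into size quantiles
#'
#' Sorts terms by number of positive genes (ties broken by term id for
#' determinism) and splits them into `n_groups` contiguous groups of
#' as-equal-as-possible cardinality.
#'
#' @param standards non-empty list of `term_standard` objects.
#' @param n_groups number of groups (default 5, i.e. quintiles).
#' @return A list of length `n_groups`; each element has `bounds`
#'   (min and max positive count in the group) and `standards`.
#' @export
group_terms_by_size <- function(standards, n_groups = 5) {
  n <- length(standards)
  if (!n) stop("no standards to group")
  if (n_groups > n) stop("more groups requested than terms available")
  sizes <- vapply(standards, function(s) length(s$positives), integer(1))
  ids <- vapply(standards, function(s) s$term_id, character(1))
  ord <- order(sizes, ids)
  base <- n %/% n_groups
  extra <- n %% n_groups
  counts <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  grp <- rep(seq_len(n_groups), counts)
  lapply(seq_len(n_groups), function(g) {
    idx <- ord[grp == g]
    list(bounds = range(sizes[idx]), standards = standards[idx])
  })
}
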