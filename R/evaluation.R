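#' Gene-partitioned k-fold split
#'
#' Partitions genes (not isoforms) into k disjoint, exhaustive, near-equal
#' folds, so all isoforms of a gene fall on one side of every train/test
#' split and no information leaks between them. With `stratify_positives`,
#' positive genes are dealt round-robin across folds so every fold contains
#' at least one positive whenever there are at least k positives.
#'
#' @param genes character vector of gene ids (length >= k).
#' @param k number of folds (>= 2).
#' @param seed integer seed for the shuffle.
#' @param stratify_positives optional character vector of positive gene ids.
#' @return List of k elements, each with `train` and `test` gene vectors.
#' @export
kfold_by_gene <- function(genes, k, seed, stratify_positives = NULL) {
  genes <- as.character(genes)
  if (k < 2) stop("k must be at least 2")
  if (length(genes) < k) stop("fewer genes than folds")
  set.seed(as.integer(seed))
  if (is.null(stratify_positives)) {
    shuffled <- sample(genes)
    fold <- rep_len(seq_len(k), length(genes))
  } else {
    pos <- sample(intersect(genes, stratify_positives))
    neg <- sample(setdiff(genes, stratify_positives))
    shuffled <- c(pos, neg)
    fold <- c(rep_len(seq_len(k), length(pos)),
              rep_len(seq_len(k), length(neg)))
  }
  lapply(seq_len(k), function(i) {
    list(train = shuffled[fold != i], test = shuffled[fold == i])
  })
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, counting ties as one half.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length; both classes must be present.
#' @return AUC in \[0,1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (!np || !nn) stop("both classes are required to compute an AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Average-precision convention: the mean, over positives, of the precision
#' at each positive's rank in the score-descending ordering (ties kept in
#' stable input order).
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector; at least one positive required.
#' @return AUPRC in \[0,1\]; its chance baseline equals the positive
#'   prevalence.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!sum(labels == 1)) stop("at least one positive is required")
  ord <- order(-scores)
  l <- labels[ord]
  prec <- cumsum(l) / seq_along(l)
  sum(prec[l == 1]) / sum(l)
}

#' Precision at a fixed recall
#'
#' Returns the precision of the smallest score-threshold prediction set
#' achieving recall at least `r` (the required positive count is
#' `ceiling(r * n_pos)`); all instances tied at the threshold enter the set.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector; at least one positive required.
#' @param r target recall in (0, 1\].
#' @return Precision in \[0,1\].
#' @export
precision_at_recall <- function(scores, labels, r) {
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  if (!P) stop("at least one positive is required")
  if (r <= 0 || r > 1) stop("recall target must be in (0, 1]")
  need <- ceiling(r * P)
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  cumtp <- cumsum(l)
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))  # last index of each tie group
  k <- grp_end[cumtp[grp_end] >= need][1]
  cumtp[k] / k
}

#' Metric report for one term and evaluation group
#'
#' @param gene_scores named numeric vector of gene-level scores.
#' @param standard a `term_standard`.
#' @param group_tag label of the evaluation design (e.g. "kfold", "multi",
#'   "expr-high", "homolog-safe").
#' @return One-row data frame with columns `term_id`, `group_tag`, `auc`,
#'   `auprc`, `p_at_1pct`, `p_at_10pct`, `n_pos_test`, `n_neg_test`.
#' @export
evaluate_term <- function(gene_scores, standard, group_tag = "kfold") {
  labels <- as.integer(names(gene_scores) %in% standard$positives)
  data.frame(term_id = standard$term_id,
             group_tag = group_tag,
             auc = unname(roc_auc(gene_scores, labels)),
             auprc = unname(auprc(gene_scores, labels)),
             p_at_1pct = unname(precision_at_recall(gene_scores, labels, 0.01)),
             p_at_10pct = unname(precision_at_recall(gene_scores, labels, 0.10)),
             n_pos_test = sum(labels == 1),
             n_neg_test = sum(labels == 0),
             stringsAsFactors = FALSE)
}

#' Gene-level cross-validated scores for one term
#'
#' Runs the MIL heuristic on each training fold and scores the held-out
#' genes (maximum over their isoforms), pooling held-out scores across
#' folds.
#'
#' @param matrix an `expression_matrix` in log2 space.
#' @param bags a `bag_map`.
#' @param standard a `term_standard`.
#' @param config a `mil_config`.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed (defaults to `config$seed`).
#' @return List with `gene_scores` (named, pooled over folds), `fold_id`
#'   (named, which fold held each gene out) and `fits` (per-fold
#'   `mil_fit`s).
#' @export
crossval_scores <- function(matrix, bags, standard, config = mil_config(),
                            k = 5, seed = config$seed) {
  genes <- bag_genes(bags)
  splits <- kfold_by_gene(genes, k = k, seed = seed,
                          stratify_positives = standard$positives)
  gene_scores <- numeric()
  fold_id <- integer()
  fits <- vector("list", k)
  for (i in seq_len(k)) {
    sp <- splits[[i]]
    tr_std <- term_standard(standard$term_id,
                            intersect(standard$positives, sp$train),
                            intersect(standard$negatives, sp$train))
    fits[[i]] <- run_mil(matrix, subset_bags(bags, sp$train), tr_std, config)
    te_bags <- subset_bags(bags, sp$test)
    sc <- score_instances(fits[[i]]$model,
                          subset_matrix(matrix, te_bags$isoform_id))
    gs <- aggregate_gene_scores(sc, te_bags)
    gene_scores <- c(gene_scores, gs)
    fold_id <- c(fold_id, stats::setNames(rep(i, length(gs)), names(gs)))
  }
  list(gene_scores = gene_scores, fold_id = fold_id, fits = fits)
}

#' Ratio-matched multi- vs single-isoform sub-problems
#'
#' Partitions genes by isoform count (>1 vs =1) and downsamples negatives
#' (seeded, uniform) in whichever partition has the lower positive:negative
#' ratio so that both sub-problems share the same ratio — and hence the
#' same baseline precision. A partition without positives is skipped with a
#' message.
#'
#' @param bags a `bag_map`.
#' @param standard a `term_standard`.
#' @param seed integer seed for the negative downsampling.
#' @return Named list with up to two `term_standard`s: `multi` and `single`.
#' @export
split_multi_single <- function(bags, standard, seed) {
  counts <- isoform_counts(bags)
  parts <- list(multi = names(counts)[counts > 1],
                single = names(counts)[counts == 1])
  pos <- lapply(parts, intersect, x = standard$positives)
  neg <- lapply(parts, intersect, x = standard$negatives)
  usable <- vapply(pos, length, integer(1)) > 0 &
    vapply(neg, length, integer(1)) > 0
  for (nm in names(parts)[!usable])
    message("partition '", nm, "' skipped: no positives (or no negatives)")
  if (!any(usable)) stop("neither partition has positives and negatives")
  ratios <- vapply(names(parts)[usable],
                   function(nm) length(pos[[nm]]) / length(neg[[nm]]),
                   numeric(1))
  target <- max(ratios)
  set.seed(as.integer(seed))
  out <- list()
  for (nm in names(parts)[usable]) {
    n_keep <- min(length(neg[[nm]]), round(length(pos[[nm]]) / target))
    kept_neg <- if (n_keep < length(neg[[nm]])) {
      sort(sample(neg[[nm]], n_keep))
    } else neg[[nm]]
    out[[nm]] <- term_standard(standard$term_id, pos[[nm]], kept_neg)
  }
  out
}

#' Partition genes into expression-level tertiles
#'
#' A gene's expression level is the mean of its isoforms' non-sentinel
#' log2 cells across all experiments. Genes are sorted and cut into three
#' near-equal groups; genes with only sentinel cells go to the low group.
#'
#' @param matrix an `expression_matrix` in log2 space.
#' @param bags a `bag_map`.
#' @return List with character vectors `high`, `mid`, `low`.
#' @export
partition_by_expression <- function(matrix, bags) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$space != "log2")
    stop("expression stratification expects the log2-space matrix")
  v <- subset_matrix(matrix, isoforms = bags$isoform_id)$values
  v[v == matrix$sentinel] <- NA
  gene <- gene_of(bags, rownames(v))
  expr <- tapply(rowMeans(v, na.rm = TRUE), gene, mean, na.rm = TRUE)
  expr[is.nan(expr)] <- -Inf  # sentinel-only genes sink to the low group
  ord <- names(expr)[order(-unlist(expr), names(expr))]
  n <- length(ord)
  base <- n %/% 3
  extra <- n %% 3
  sizes <- rep(base, 3) + c(rep(1L, extra), rep(0L, 3 - extra))
  grp <- rep(1:3, sizes)
  list(high = ord[grp == 1], mid = ord[grp == 2], low = ord[grp == 3])
}

#' Homolog-aware two-way gene partition
#'
#' Assigns whole homolog groups (genes without a group are singletons) to
#' the currently-smaller side, largest groups first (ties shuffled by
#' seed), so no homolog group is ever split between training and test and
#' the two sides differ by at most the largest group size.
#'
#' @param genes character vector of gene ids.
#' @param homolog_groups named character vector mapping gene id -> group id;
#'   genes absent from it form singleton groups.
#' @param seed integer seed for tie shuffling.
#' @return List with character vectors `A` and `B`.
#' @export
partition_by_homolog <- function(genes, homolog_groups = NULL, seed = 1L) {
  genes <- as.character(genes)
  grp <- stats::setNames(genes, genes)  # singleton default: own id
  if (!is.null(homolog_groups)) {
    known <- intersect(genes, names(homolog_groups))
    grp[known] <- homolog_groups[known]
  }
  members <- split(genes, grp[genes])
  sizes <- vapply(members, length, integer(1))
  set.seed(as.integer(seed))
  ord <- order(-sizes, sample.int(length(sizes)))
  A <- character()
  B <- character()
  for (i in ord) {
    if (length(A) <= length(B)) A <- c(A, members[[i]]) else B <- c(B, members[[i]])
  }
  list(A = A, B = B)
}
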