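#' Bootstrap split of genes
#'
#' Draws n genes with replacement from n (the 0.632 bootstrap); genes never
#' drawn form the out-of-bag set. Splitting is by gene so that all isoforms
#' of a gene travel together.
#'
#' @param genes character vector of at least one gene id.
#' @param seed integer seed; identical seeds give identical splits.
#' @return List with `train` (multiset of gene ids, length n) and `oob`
#'   (gene ids never drawn).
#' @export
bootstrap_split <- function(genes, seed) {
  genes <- as.character(genes)
  n <- length(genes)
  if (!n) stop("no genes to split")
  set.seed(as.integer(seed))
  train <- genes[sample.int(n, n, replace = TRUE)]
  list(train = train, oob = setdiff(genes, train))
}

# fit the Platt-style sigmoid on (score, label) pairs; returns a monotone
# score -> probability map
.fit_sigmoid <- function(scores, labels01) {
  if (length(unique(labels01)) < 2)
    stop("degenerate one-class input: cannot calibrate probabilities")
  df <- data.frame(y = labels01, s = scores)
  fit <- suppressWarnings(stats::glm(y ~ s, family = stats::binomial(), data = df))
  function(new_scores) {
    as.numeric(suppressWarnings(
      stats::predict(fit, newdata = data.frame(s = new_scores),
                     type = "response")))
  }
}

#' Calibrate decision scores to probabilities
#'
#' Fits a sigmoid (Platt-style logistic) map on the (score, label) pairs of
#' the POS/NEG instances of `final_labeling` and applies it to every score.
#' The map is monotone, so ranking by probability equals ranking by score.
#'
#' @param decision_scores named numeric vector of decision scores.
#' @param final_labeling an `instance_labeling` with both classes present;
#'   NEUTRAL instances are excluded from the fit but still receive a
#'   probability.
#' @return Named numeric vector of probabilities in \[0,1\].
#' @export
calibrate_probability <- function(decision_scores, final_labeling) {
  lab <- .lab_vec(final_labeling)
  fitted_on <- intersect(names(decision_scores), names(lab)[lab != "NEUTRAL"])
  if (!length(fitted_on)) stop("no labeled instances with scores to calibrate on")
  sig <- .fit_sigmoid(decision_scores[fitted_on],
                      as.integer(lab[fitted_on] == "POS"))
  stats::setNames(sig(decision_scores), names(decision_scores))
}

#' Fold change of a prediction over the term's background
#'
#' Each term has a different background probability for a gene to be
#' annotated to it; the fold change reports the calibrated probability
#' relative to that prior, `|positives| / universe_size`.
#'
#' @param probability numeric vector of calibrated probabilities.
#' @param standard a `term_standard` with at least one positive gene.
#' @param universe_size number of genes in the universe.
#' @return Numeric vector of non-negative fold changes.
#' @export
fold_change <- function(probability, standard, universe_size) {
  prior <- length(standard$positives) / universe_size
  if (!is.finite(prior) || prior <= 0)
    stop("zero background prior for term ", standard$term_id)
  probability / prior
}

#' Bootstrap-bagged out-of-bag isoform predictions
#'
#' Runs the MIL heuristic on `n_rounds` bootstrap resamples of the genes;
#' in each round, all out-of-bag isoforms are scored with that round's final
#' model. Each isoform's decision score is the median over the rounds in
#' which it was out-of-bag. Isoforms never out-of-bag in any round are
#' scored by one supplementary round that excludes their genes from
#' training (and are flagged in a message). Probabilities come from a
#' sigmoid calibration fitted on the full-data run's final labeling; the
#' fold change divides the probability by the term prior, and the gene
#' score is the maximum over its isoforms.
#'
#' @param matrix an `expression_matrix` in log2 space.
#' @param bags a `bag_map`.
#' @param standard a `term_standard`.
#' @param config a `mil_config`; its seed governs the bootstrap draws.
#' @param n_rounds number of bootstrap rounds (default 30).
#' @return A data frame of class `term_predictions` with columns `term_id`,
#'   `gene_id`, `isoform_id`, `decision_score`, `probability`,
#'   `fold_change`, `n_rounds_covered`, sorted lexicographically; gene-level
#'   max scores are in `attr(, "gene_scores")`.
#' @export
bagged_predict <- function(matrix, bags, standard, config = mil_config(),
                           n_rounds = 30L) {
  stopifnot(n_rounds >= 1)
  genes <- bag_genes(bags)
  iso <- bags$isoform_id
  oob_scores <- matrix(NA_real_, nrow = length(iso), ncol = n_rounds,
                       dimnames = list(iso, NULL))

  for (r in seq_len(n_rounds)) {
    seed_r <- config$seed + 7919L * r
    split <- bootstrap_split(genes, seed = seed_r)
    train_genes <- unique(split$train)
    tr_std <- term_standard(standard$term_id,
                            intersect(standard$positives, train_genes),
                            intersect(standard$negatives, train_genes))
    if (!length(tr_std$positives) || !length(tr_std$negatives)) {
      warning("round ", r, " skipped: single-class bootstrap draw")
      next
    }
    cfg <- config
    cfg$seed <- seed_r
    fit <- run_mil(matrix, subset_bags(bags, train_genes), tr_std, cfg)
    if (!length(split$oob)) next
    oob_iso <- bags$isoform_id[bags$gene_id %in% split$oob]
    sc <- score_instances(fit$model, subset_matrix(matrix, isoforms = oob_iso))
    oob_scores[oob_iso, r] <- sc
  }

  covered <- rowSums(!is.na(oob_scores))
  decision <- apply(oob_scores, 1, stats::median, na.rm = TRUE)

  never <- iso[covered == 0]
  if (length(never)) {
    message(length(never),
            " isoform(s) never out-of-bag; scored by a supplementary round")
    held_genes <- unique(gene_of(bags, never))
    rest <- setdiff(genes, held_genes)
    hs <- term_standard(standard$term_id,
                        intersect(standard$positives, rest),
                        intersect(standard$negatives, rest))
    fit <- run_mil(matrix, subset_bags(bags, rest), hs, config)
    decision[never] <- score_instances(
      fit$model, subset_matrix(matrix, isoforms = never))
  }

  # calibration map from the full-data run's final labeling and scores
  full_fit <- run_mil(matrix, bags, standard, config)
  lab <- .lab_vec(full_fit$labeling)
  labeled <- names(lab)[lab != "NEUTRAL"]
  sig <- .fit_sigmoid(full_fit$scores[labeled],
                      as.integer(lab[labeled] == "POS"))
  probability <- stats::setNames(sig(decision), iso)
  fc <- fold_change(probability, standard, universe_size = length(genes))

  out <- data.frame(term_id = standard$term_id,
                    gene_id = bags$gene_id,
                    isoform_id = iso,
                    decision_score = as.numeric(decision[iso]),
                    probability = as.numeric(probability[iso]),
                    fold_change = as.numeric(fc[iso]),
                    n_rounds_covered = as.integer(covered[iso]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$term_id, out$gene_id, out$isoform_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gene_scores") <- aggregate_gene_scores(
    stats::setNames(out$decision_score, out$isoform_id), bags)
  class(out) <- c("term_predictions", "data.frame")
  out
}
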