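#' Configuration for a multiple-instance SVM run
#'
#' Bundles the knobs of the iterative MIL heuristic. `formulation` selects
#' between the mi-SVM update (every isoform of a positive gene is relabeled
#' POS/NEG each iteration), the MI-SVM update (exactly one witness per
#' positive gene, the rest NEUTRAL and excluded from the margin), and the
#' random-witness MI-SVM baseline. `threshold_variant` (mi-SVM only) picks
#' the label cutoff computed from the negative-instance score distribution:
#' its mode, its 75th percentile, or its maximum — increasingly strict
#' choices, with `"p75"` the default.
#'
#' @param formulation one of `"mi_svm"`, `"MI_svm"`, `"MI_svm_random"`.
#' @param threshold_variant one of `"p75"`, `"mode"`, `"max"`, `"zero"`.
#'   The first three cut at the named statistic of the negative-instance
#'   score distribution; `"zero"` cuts at the decision boundary itself,
#'   i.e. the generic local-objective update in which each hidden label is
#'   set to the side of the hyperplane its instance falls on.
#' @param cost soft-margin trade-off C of the linear SVM (default 1).
#' @param max_iterations iteration cap of the heuristic (default 50).
#' @param class_weighting up-weight the minority class inversely to its
#'   frequency (default FALSE: at initialization roughly half the
#'   positive-instance labels are wrong by construction, and up-weighting
#'   that label-noisy class amplifies the noise).
#' @param seed integer seed governing any stochastic choice (random witness,
#'   cross-fitting folds).
#' @param threshold_on compute the threshold from isoforms of negative genes
#'   (`"negative_bags"`, default) or from all currently-NEG instances
#'   (`"negative_instances"`).
#' @param profile_centering center each instance's profile on its own mean
#'   over non-sentinel cells before margin fitting (default TRUE), so that
#'   discrimination rests on the co-expression pattern across experiments
#'   rather than on absolute expression level; sentinel cells are left at
#'   the sentinel.
#' @param update_scoring how instances are scored for the label update:
#'   `"crossfit"` (default) scores each instance with a model whose
#'   training folds exclude the instance's gene, removing the instance's
#'   own-label influence on its score; `"insample"` scores the training set
#'   with the model trained on it.
#' @param crossfit_folds gene-partitioned folds used by `"crossfit"`
#'   (default 3).
#' @param crossfit_iterations maximum number of label updates driven by
#'   cross-fitted scores (default 15); the update uses the running mean of
#'   the centered cross-fitted scores across iterations, which stabilizes
#'   the labeling and yields fast exact convergence. If the labeling still
#'   moves after that many updates, the remaining iterations use in-sample
#'   scores. Ignored under `"insample"`.
#' @return An object of class `mil_config`.
#' @export
mil_config <- function(formulation = c("mi_svm", "MI_svm", "MI_svm_random"),
                       threshold_variant = c("p75", "mode", "max", "zero"),
                       cost = 1,
                       max_iterations = 50L,
                       class_weighting = FALSE,
                       seed = 1L,
                       threshold_on = c("negative_bags", "negative_instances"),
                       profile_centering = TRUE,
                       update_scoring = c("crossfit", "insample"),
                       crossfit_folds = 3L,
                       crossfit_iterations = 15L) {
  formulation <- match.arg(formulation)
  threshold_variant <- match.arg(threshold_variant)
  threshold_on <- match.arg(threshold_on)
  update_scoring <- match.arg(update_scoring)
  stopifnot(cost > 0, max_iterations >= 1, crossfit_folds >= 2)
  structure(list(formulation = formulation,
                 threshold_variant = threshold_variant,
                 cost = cost,
                 max_iterations = as.integer(max_iterations),
                 class_weighting = isTRUE(class_weighting),
                 seed = as.integer(seed),
                 threshold_on = threshold_on,
                 profile_centering = isTRUE(profile_centering),
                 update_scoring = update_scoring,
                 crossfit_folds = as.integer(crossfit_folds),
                 crossfit_iterations = as.integer(crossfit_iterations)),
            class = "mil_config")
}

#' Initialize instance labels from the gene-level gold standard
#'
#' Every isoform of a positive gene starts as POS; every isoform of a
#' negative gene is NEG. No NEUTRAL labels occur at initialization.
#'
#' @param standard a `term_standard` covering all genes in `bags`.
#' @param bags a `bag_map`.
#' @return Named character vector (isoform id -> `"POS"`/`"NEG"`), class
#'   `instance_labeling`.
#' @export
initialize_labels <- function(standard, bags) {
  stopifnot(inherits(standard, "term_standard"), inherits(bags, "bag_map"))
  genes <- bag_genes(bags)
  known <- c(standard$positives, standard$negatives)
  missing <- setdiff(genes, known)
  if (length(missing))
    stop("gene(s) in bags absent from the gold standard: ",
         paste(utils::head(missing, 5), collapse = ", "))
  gene_lab <- ifelse(bags$gene_id %in% standard$positives, "POS", "NEG")
  lab <- stats::setNames(gene_lab, bags$isoform_id)
  class(lab) <- "instance_labeling"
  lab
}

# strip class for plain-vector operations
.lab_vec <- function(labeling) {
  out <- unclass(labeling)
  out
}

# center each row on its own non-sentinel mean; sentinel cells stay put.
# A per-instance transform, so it applies identically at fit and score time.
.row_center <- function(values, sentinel = NULL) {
  if (is.null(sentinel)) return(values)
  miss <- values == sentinel
  v <- values
  v[miss] <- NA
  mu <- rowMeans(v, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  out <- values - mu
  out[miss] <- sentinel
  out
}

#' Train the maximum-margin classifier on the current labeling
#'
#' Fits a linear soft-margin SVM on the POS/NEG instances of the current
#' labeling; NEUTRAL instances are excluded from fitting. With
#' `class_weighting` on, each class is weighted n/(2 * n_class).
#'
#' @param matrix an `expression_matrix` in log2 space containing all labeled
#'   isoforms as rows.
#' @param labeling an `instance_labeling` with at least one POS and one NEG.
#' @param config a `mil_config`.
#' @return An object of class `margin_model` wrapping the fitted SVM, with
#'   a deterministic real-valued decision score per feature vector.
#' @export
train_margin_classifier <- function(matrix, labeling, config = mil_config()) {
  stopifnot(inherits(matrix, "expression_matrix"))
  lab <- .lab_vec(labeling)
  keep <- names(lab)[lab != "NEUTRAL"]
  y <- lab[keep]
  if (length(unique(y)) < 2)
    stop("single-class labeling: cannot train a margin classifier")
  X <- subset_matrix(matrix, isoforms = keep)$values
  sentinel <- if (config$profile_centering) matrix$sentinel else NULL
  X <- .row_center(X, sentinel)
  # standardize columns from the training rows; the sentinel floor would
  # otherwise dominate the geometry and condition libsvm poorly
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  yf <- factor(y, levels = c("NEG", "POS"))
  cw <- NULL
  if (config$class_weighting) {
    tab <- table(yf)
    cw <- stats::setNames(length(yf) / (2 * as.numeric(tab)), names(tab))
  }
  fit <- e1071::svm(Xs, yf, kernel = "linear", cost = config$cost,
                    scale = FALSE, class.weights = cw)
  # libsvm orients decision values toward its internally-first class; the
  # column name "A/B" means positive values favor A
  dv <- attr(stats::predict(fit, Xs[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  flip <- if (identical(colnames(dv), "POS/NEG")) 1 else -1
  structure(list(fit = fit, flip = flip, features = colnames(X),
                 sentinel = sentinel,
                 center = center, scale = scale,
                 cost = config$cost, class_weighting = config$class_weighting,
                 class_weights = cw),
            class = "margin_model")
}

#' @export
print.margin_model <- function(x, ...) {
  cat(sprintf("<margin_model> linear SVM, C = %g, %d support vectors\n",
              x$cost, nrow(x$fit$SV)))
  invisible(x)
}

#' Decision scores for all isoforms
#'
#' Scores every row of `matrix` (POS, NEG and NEUTRAL instances alike) with
#' the signed distance to the separating hyperplane, oriented so that
#' higher means more positive.
#'
#' @param model a `margin_model`.
#' @param matrix an `expression_matrix` with the same experiment columns, in
#'   the same order, as the training matrix.
#' @return Named numeric vector of finite scores, one per isoform.
#' @export
score_instances <- function(model, matrix) {
  stopifnot(inherits(model, "margin_model"), inherits(matrix, "expression_matrix"))
  if (!identical(colnames(matrix$values), model$features))
    stop("experiment columns do not match the model's feature space")
  X <- .row_center(matrix$values, model$sentinel)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  dv <- attr(stats::predict(model$fit, Xs, decision.values = TRUE),
             "decision.values")
  scores <- model$flip * dv[, 1]
  stats::setNames(as.numeric(scores), rownames(matrix$values))
}

#' Extract the separating hyperplane
#'
#' Returns the weight vector and intercept of a linear `margin_model` in the
#' original (unstandardized) feature space, so that the decision score
#' equals `w . x + b` for a raw feature vector `x`. When the model was fit
#' with profile centering, `x` here is the row-centered profile (raw values
#' minus their non-sentinel row mean).
#'
#' @param model a `margin_model`.
#' @return List with `w` (named numeric, one weight per experiment) and `b`.
#' @export
decision_hyperplane <- function(model) {
  w_std <- model$flip * drop(crossprod(model$fit$coefs, model$fit$SV))
  b_std <- -model$flip * model$fit$rho
  w <- w_std / model$scale
  b <- b_std - sum(w_std * model$center / model$scale)
  list(w = stats::setNames(as.numeric(w), model$features), b = as.numeric(b))
}

#' Primal soft-margin objective of a model under a labeling
#'
#' Computes `0.5 * ||w||^2 + C * sum(weight_i * hinge_i)` in the
#' standardized feature space the SVM is solved in, with the hinge loss
#' taken over the POS/NEG instances of `labeling` (NEUTRAL excluded) and
#' `weight_i` the per-class weight used at fitting time (1 when class
#' weighting is off). Comparable across models only when they share the
#' same training rows (and hence standardization); used to compare the
#' iterative heuristic against exhaustive labeling enumeration on small
#' problems.
#'
#' @param model a `margin_model`.
#' @param matrix an `expression_matrix` containing the labeled isoforms.
#' @param labeling an `instance_labeling`.
#' @return A single non-negative number.
#' @export
svm_objective <- function(model, matrix, labeling) {
  lab <- .lab_vec(labeling)
  keep <- names(lab)[lab != "NEUTRAL"]
  w_std <- model$flip * drop(crossprod(model$fit$coefs, model$fit$SV))
  f <- score_instances(model, subset_matrix(matrix, isoforms = keep))
  y <- ifelse(lab[keep] == "POS", 1, -1)
  wts <- rep(1, length(keep))
  if (!is.null(model$class_weights))
    wts <- as.numeric(model$class_weights[lab[keep]])
  xi <- pmax(0, 1 - y * f[keep])
  0.5 * sum(w_std^2) + model$cost * sum(wts * xi)
}

#' Label-update threshold from negative-instance scores
#'
#' The mi-SVM update relabels positive-gene isoforms against a cutoff
#' derived from the score distribution of negative instances: its mode
#' (least strict), its 75th percentile, or its maximum (most strict).
#' The mode is estimated as the midpoint of the most populated histogram
#' bin under Freedman-Diaconis binning (ties go to the lower bin); the
#' percentile uses linear interpolation between order statistics.
#'
#' @param neg_scores non-empty numeric vector of negative-instance scores.
#' @param variant one of `"mode"`, `"p75"`, `"max"`.
#' @return A single numeric threshold.
#' @export
compute_threshold <- function(neg_scores, variant = c("p75", "mode", "max")) {
  variant <- match.arg(variant)
  if (!length(neg_scores)) stop("no negative scores to compute a threshold from")
  if (anyNA(neg_scores)) stop("NA in negative scores")
  switch(variant,
    max = max(neg_scores),
    p75 = unname(stats::quantile(neg_scores, 0.75, type = 7)),
    mode = {
      if (diff(range(neg_scores)) == 0) return(neg_scores[[1]])
      k <- grDevices::nclass.FD(neg_scores)
      if (!is.finite(k) || k < 1) k <- grDevices::nclass.Sturges(neg_scores)
      brk <- seq(min(neg_scores), max(neg_scores), length.out = k + 1)
      bin <- findInterval(neg_scores, brk, rightmost.closed = TRUE,
                          all.inside = TRUE)
      cnt <- tabulate(bin, nbins = k)
      mids <- (brk[-1] + brk[-(k + 1)]) / 2
      mids[which.max(cnt)]  # which.max returns the first (lower) bin on ties
    })
}

#' mi-SVM label update
#'
#' In each positive gene, isoforms scoring strictly above `threshold` become
#' POS and the rest NEG; if no isoform clears the threshold the
#' maximum-scoring isoform (ties broken by lexicographically smallest id) is
#' forced POS, preserving the at-least-one-witness constraint. All isoforms
#' of negative genes stay NEG; no NEUTRAL labels are produced.
#'
#' @param scores named numeric vector covering every isoform in `bags`.
#' @param bags a `bag_map`.
#' @param standard a `term_standard`.
#' @param threshold numeric cutoff (computed from negative-instance scores).
#' @return An `instance_labeling`.
#' @export
update_labels_mi <- function(scores, bags, standard, threshold) {
  lab <- stats::setNames(rep("NEG", nrow(bags)), bags$isoform_id)
  for (g in intersect(bag_genes(bags), standard$positives)) {
    iso <- bags$isoform_id[bags$gene_id == g]
    s <- scores[iso]
    if (anyNA(s)) stop("unscored isoform(s) in gene ", g)
    pos <- s > threshold
    if (!any(pos)) {
      best <- iso[s == max(s)]
      pos <- iso == min(best)  # lexicographic tie-break
    }
    lab[iso] <- ifelse(pos, "POS", "NEG")
  }
  class(lab) <- "instance_labeling"
  lab
}

#' MI-SVM witness update
#'
#' Selects exactly one POS witness per positive gene — the maximum-scoring
#' isoform (ties to the lexicographically smallest id), or a uniformly
#' random isoform when `random_witness` is set — and marks the gene's other
#' isoforms NEUTRAL (excluded from the margin). Negative-gene isoforms are
#' NEG.
#'
#' @param scores named numeric vector covering every isoform in `bags`.
#' @param bags a `bag_map`.
#' @param standard a `term_standard`.
#' @param random_witness pick the witness uniformly at random instead of by
#'   score (the baseline formulation).
#' @param seed integer seed used when `random_witness` is TRUE.
#' @return An `instance_labeling`.
#' @export
update_labels_MI <- function(scores, bags, standard, random_witness = FALSE,
                             seed = 1L) {
  lab <- stats::setNames(rep("NEG", nrow(bags)), bags$isoform_id)
  pos_genes <- intersect(bag_genes(bags), standard$positives)
  if (random_witness) set.seed(as.integer(seed))
  for (g in pos_genes) {
    iso <- sort(bags$isoform_id[bags$gene_id == g])
    if (random_witness) {
      witness <- iso[sample.int(length(iso), 1)]
    } else {
      s <- scores[iso]
      if (anyNA(s)) stop("unscored isoform(s) in gene ", g)
      best <- iso[s == max(s)]
      witness <- min(best)
    }
    lab[iso] <- ifelse(iso == witness, "POS", "NEUTRAL")
  }
  class(lab) <- "instance_labeling"
  lab
}

#' Convergence test for the label-update iteration
#'
#' The heuristic stops when the candidate labeling equals the most recent
#' labeling (fixed point) or any earlier labeling in the history (cycle
#' detection). Comparison is exact per-isoform label equality.
#'
#' @param history non-empty list of `instance_labeling`s, oldest first.
#' @param candidate an `instance_labeling`.
#' @return TRUE or FALSE.
#' @export
has_converged <- function(history, candidate) {
  if (!length(history)) stop("empty labeling history")
  key <- .labeling_key(candidate)
  any(vapply(history, function(h) identical(.labeling_key(h), key), logical(1)))
}

# canonical order-independent representation of a labeling
.labeling_key <- function(labeling) {
  lab <- .lab_vec(labeling)
  lab <- lab[order(names(lab))]
  paste(names(lab), lab, sep = "=", collapse = ";")
}

#' Run the iterative multiple-instance SVM heuristic
#'
#' Alternates (train margin classifier on current labels) and (relabel
#' positive-gene isoforms from the resulting scores) until the labeling
#' reaches a fixed point or revisits an earlier state, or `max_iterations`
#' passes elapse. The pass that confirms convergence counts as an
#' iteration, so a problem whose labels never move (e.g. all positive genes
#' single-isoform) takes exactly 2 iterations: train, confirm.
#'
#' With the default `update_scoring = "crossfit"`, the scores driving each
#' label update come from gene-partitioned fold models that never saw the
#' scored instance, so an instance's current (possibly wrong) label cannot
#' prop up its own score; when a fold's training side degenerates to a
#' single class the run falls back to in-sample update scoring. The
#' returned `model` and `scores` always come from a fit on the full
#' instance set under the final labeling.
#'
#' @param matrix an `expression_matrix` in log2 space containing at least
#'   the isoforms of `bags`.
#' @param bags a `bag_map`.
#' @param standard a `term_standard` with at least one positive and one
#'   negative gene present in `bags`.
#' @param config a `mil_config`.
#' @return An object of class `mil_fit`: list with `model` (the final
#'   iteration's `margin_model`), `labeling` (final `instance_labeling`,
#'   satisfying the at-least-one-witness constraint), `scores` (from the
#'   final model, all isoforms of `bags`), `iterations`, `converged`,
#'   `thresholds` (mi-SVM threshold trajectory), and `config`.
#' @export
run_mil <- function(matrix, bags, standard, config = mil_config()) {
  stopifnot(inherits(config, "mil_config"))
  genes <- bag_genes(bags)
  if (!length(intersect(genes, standard$positives)))
    stop("no positive genes in bags for term ", standard$term_id)
  if (!length(intersect(genes, standard$negatives)))
    stop("no negative genes in bags for term ", standard$term_id)
  sub <- subset_matrix(matrix, isoforms = bags$isoform_id)
  neg_bag_iso <- bags$isoform_id[bags$gene_id %in% standard$negatives]

  # gene-partitioned folds for cross-fitted update scoring; the partition
  # is rotated every iteration (seeded) so that running-mean averaging also
  # cancels fold-assignment luck
  crossfit_on <- config$update_scoring == "crossfit"
  pos_in_bags <- intersect(genes, standard$positives)
  k_folds <- min(config$crossfit_folds, length(genes))
  if (k_folds < 2) crossfit_on <- FALSE
  make_folds <- function(it) {
    kfold_by_gene(genes, k = k_folds, seed = config$seed + 131L * it,
                  stratify_positives = pos_in_bags)
  }
  folds <- NULL
  # Cross-fitted update scores. Decision values from different fold models
  # are not on a common scale, so each fold's scores are centered on that
  # fold's own threshold (computed from its held-out negative instances);
  # the label update then cuts at zero. Returns NULL when a fold's training
  # side degenerates to one class (fall back to in-sample scoring).
  update_scores <- function(labeling) {
    if (is.null(folds)) return(NULL)
    lab <- .lab_vec(labeling)
    sc <- rep(NA_real_, nrow(bags))
    names(sc) <- bags$isoform_id
    fold_thr <- numeric()
    for (f in folds) {
      tr_iso <- bags$isoform_id[bags$gene_id %in% f$train]
      tr_lab <- lab[tr_iso]
      if (length(unique(tr_lab[tr_lab != "NEUTRAL"])) < 2)
        return(NULL)
      tl <- lab[tr_iso]
      class(tl) <- "instance_labeling"
      m <- train_margin_classifier(subset_matrix(sub, tr_iso), tl, config)
      te_iso <- bags$isoform_id[bags$gene_id %in% f$test]
      fs <- score_instances(m, subset_matrix(sub, te_iso))
      if (config$formulation == "mi_svm") {
        thr_f <- if (config$threshold_variant == "zero") 0 else {
          ref_iso <- if (config$threshold_on == "negative_bags") {
            intersect(te_iso, neg_bag_iso)
          } else {
            te_iso[lab[te_iso] == "NEG"]
          }
          compute_threshold(fs[ref_iso], config$threshold_variant)
        }
        fold_thr <- c(fold_thr, thr_f)
        fs <- fs - thr_f
      }
      sc[te_iso] <- fs
    }
    list(scores = sc, threshold = mean(fold_thr))
  }

  labeling <- initialize_labels(standard, bags)
  history <- list(labeling)
  candidate <- NULL
  model <- NULL
  thresholds <- numeric()
  converged <- FALSE
  n_iter <- 0L

  mean_scores <- NULL  # running mean of centered cross-fitted scores
  n_cf <- 0L
  for (it in seq_len(config$max_iterations)) {
    n_iter <- it
    if (!is.null(candidate)) {
      if (has_converged(history, candidate)) {
        converged <- TRUE
        labeling <- candidate
        break
      }
      history[[length(history) + 1L]] <- candidate
      labeling <- candidate
    }
    if (crossfit_on && it > config$crossfit_iterations) {
      # labeling still moving: fall back to in-sample updates, restarting
      # the cycle history so that phase converges to its own fixed point
      crossfit_on <- FALSE
      history <- list(labeling)
    }
    folds <- if (crossfit_on) make_folds(it) else NULL
    cf <- update_scores(labeling)
    if (!is.null(cf)) {
      # the first update's fold models are trained on the fully imputed
      # all-positive labels, the noisiest labeling of the run; its scores
      # drive the first update but are excluded from the running mean
      if (it > 1L) {
        n_cf <- n_cf + 1L
        mean_scores <- if (is.null(mean_scores)) cf$scores else
          mean_scores + (cf$scores - mean_scores) / n_cf
        cf$scores <- mean_scores
      }
    }
    if (is.null(cf)) {
      model <- train_margin_classifier(sub, labeling, config)
      usc <- score_instances(model, sub)
      if (config$formulation == "mi_svm") {
        thr <- if (config$threshold_variant == "zero") 0 else {
          ref <- if (config$threshold_on == "negative_bags") {
            usc[neg_bag_iso]
          } else {
            usc[names(labeling)[.lab_vec(labeling) == "NEG"]]
          }
          compute_threshold(ref, config$threshold_variant)
        }
        thresholds <- c(thresholds, thr)
        candidate <- update_labels_mi(usc, bags, standard, thr)
      } else {
        candidate <- update_labels_MI(
          usc, bags, standard,
          random_witness = config$formulation == "MI_svm_random",
          seed = config$seed + it)
      }
    } else {
      model <- NULL  # full model deferred to the final fit
      if (config$formulation == "mi_svm") {
        thresholds <- c(thresholds, cf$threshold)
        candidate <- update_labels_mi(cf$scores, bags, standard, 0)
      } else {
        candidate <- update_labels_MI(
          cf$scores, bags, standard,
          random_witness = config$formulation == "MI_svm_random",
          seed = config$seed + it)
      }
    }
  }
  if (!converged) {
    warning("MIL heuristic did not converge within ", config$max_iterations,
            " iterations for term ", standard$term_id)
    labeling <- candidate
  }
  if (is.null(model))
    model <- train_margin_classifier(sub, labeling, config)
  scores <- score_instances(model, sub)
  structure(list(model = model, labeling = labeling, scores = scores,
                 iterations = n_iter, converged = converged,
                 thresholds = thresholds, config = config,
                 term_id = standard$term_id),
            class = "mil_fit")
}

#' @export
print.mil_fit <- function(x, ...) {
  cat(sprintf("<mil_fit> term %s: %s in %d iteration(s)%s\n",
              x$term_id,
              if (x$converged) "converged" else "stopped",
              x$iterations,
              if (length(x$thresholds))
                sprintf(", final threshold %.3g", utils::tail(x$thresholds, 1))
              else ""))
  invisible(x)
}

#' Aggregate isoform scores to gene scores
#'
#' The score of a gene is the maximum score over its isoforms, under the
#' assumption that a gene's function is carried out by at least one of its
#' isoforms.
#'
#' @param scores named numeric vector covering every isoform in `bags`.
#' @param bags a `bag_map`.
#' @return Named numeric vector, one score per gene.
#' @export
aggregate_gene_scores <- function(scores, bags) {
  s <- scores[bags$isoform_id]
  if (anyNA(s))
    stop("unscored isoform(s): ",
         paste(utils::head(bags$isoform_id[is.na(s)], 5), collapse = ", "))
  out <- tapply(s, bags$gene_id, max)
  stats::setNames(as.numeric(out), names(out))
}

#' Select the SVM cost parameter by inner cross-validation
#'
#' Grid-searches the soft-margin trade-off C by gene-partitioned inner
#' cross-validation on the initial (all-positive) labeling, scoring each
#' candidate by held-out gene-level AUC. Intended to be run once per term
#' before the MIL iteration.
#'
#' @param matrix an `expression_matrix` in log2 space.
#' @param bags a `bag_map`.
#' @param standard a `term_standard`.
#' @param config a `mil_config` (its cost field is ignored).
#' @param grid candidate cost values.
#' @param folds number of inner folds (default 3).
#' @return The cost value with the highest mean held-out AUC.
#' @export
tune_regularization <- function(matrix, bags, standard, config = mil_config(),
                                grid = c(0.1, 1, 10), folds = 3L) {
  genes <- bag_genes(bags)
  splits <- kfold_by_gene(genes, k = folds, seed = config$seed,
                          stratify_positives = standard$positives)
  auc_for <- function(cost) {
    cfg <- config
    cfg$cost <- cost
    mean(vapply(splits, function(sp) {
      tr_bags <- subset_bags(bags, sp$train)
      tr_std <- term_standard(standard$term_id,
                              intersect(standard$positives, sp$train),
                              intersect(standard$negatives, sp$train))
      lab <- initialize_labels(tr_std, tr_bags)
      m <- train_margin_classifier(subset_matrix(matrix, tr_bags$isoform_id),
                                   lab, cfg)
      te_bags <- subset_bags(bags, sp$test)
      sc <- score_instances(m, subset_matrix(matrix, te_bags$isoform_id))
      gs <- aggregate_gene_scores(sc, te_bags)
      lab01 <- as.integer(names(gs) %in% standard$positives)
      if (length(unique(lab01)) < 2) return(NA_real_)
      roc_auc(gs, lab01)
    }, numeric(1)), na.rm = TRUE)
  }
  perf <- vapply(grid, auc_for, numeric(1))
  grid[which.max(perf)]
}
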