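test_that("initialization marks every positive-gene isoform POS, the rest NEG", {
  bags <- bag_map(c("p1", "p1", "p1", "n1", "n2"),
                  c("p1.1", "p1.2", "p1.3", "n1.1", "n2.1"))
  std <- term_standard("t", "p1", c("n1", "n2"))
  lab <- initialize_labels(std, bags)
  expect_identical(unname(unclass(lab)[c("p1.1", "p1.2", "p1.3")]),
                   rep("POS", 3))
  expect_identical(unname(unclass(lab)[c("n1.1", "n2.1")]), rep("NEG", 2))
  expect_false(any(unclass(lab) == "NEUTRAL"))
  # degenerate all-negative standard still initializes; training refuses it
  std0 <- term_standard("t", character(0), c("p1", "n1", "n2"))
  lab0 <- initialize_labels(std0, bags)
  expect_true(all(unclass(lab0) == "NEG"))
  # gene missing from the standard is an error
  expect_error(initialize_labels(term_standard("t", "p1", "n1"), bags),
               "absent")
})

test_that("margin classifier separates separable clouds and tolerates conflicts", {
  fix <- make_separable()
  cfg <- mil_config()
  m <- train_margin_classifier(fix$matrix, fix$labeling, cfg)
  sc <- score_instances(m, fix$matrix)
  expect_gt(min(sc[fix$pos]), max(sc[fix$neg]))
  # identical points with conflicting labels: soft margin still fits
  X <- matrix(rep(c(1, 0), each = 4), 4, 2)
  mm <- make_matrix(X)
  lab <- stats::setNames(c("POS", "NEG", "POS", "NEG"), rownames(mm$values))
  class(lab) <- "instance_labeling"
  m2 <- train_margin_classifier(mm, lab, mil_config(profile_centering = FALSE))
  expect_true(all(is.finite(score_instances(m2, mm))))
  # single-class labeling refused
  lab1 <- stats::setNames(rep("POS", 4), rownames(mm$values))
  class(lab1) <- "instance_labeling"
  expect_error(train_margin_classifier(mm, lab1, cfg), "single-class")
})

test_that("scores are deterministic, order-equivariant, and finite for all labels", {
  fix <- make_separable(n_pos = 6, n_neg = 12, d = 5)
  lab <- fix$labeling
  lab[fix$pos[1]] <- "NEUTRAL"  # NEUTRAL excluded from fit but still scored
  m <- train_margin_classifier(fix$matrix, lab, mil_config())
  s1 <- score_instances(m, fix$matrix)
  s2 <- score_instances(m, fix$matrix)
  expect_identical(s1, s2)
  expect_true(all(is.finite(s1)))
  expect_true(fix$pos[1] %in% names(s1))
  perm <- sample(isoform_ids(fix$matrix))
  s3 <- score_instances(m, subset_matrix(fix$matrix, isoforms = perm))
  expect_equal(s3[perm], s1[perm])
  # column mismatch is a hard error
  swapped <- subset_matrix(fix$matrix,
                           experiments = rev(experiment_ids(fix$matrix)))
  expect_error(score_instances(m, swapped), "columns")
})

test_that("scores equal w.x + b from the exported hyperplane", {
  fix <- make_separable(n_pos = 5, n_neg = 5, d = 3, seed = 9)
  # without profile centering the map is exactly affine in the raw features
  m <- train_margin_classifier(fix$matrix, fix$labeling,
                               mil_config(profile_centering = FALSE))
  hp <- decision_hyperplane(m)
  manual <- drop(fix$matrix$values %*% hp$w) + hp$b
  expect_equal(unname(score_instances(m, fix$matrix)), unname(manual),
               tolerance = 1e-8)
  # with centering, the same identity holds on the centered profiles
  m2 <- train_margin_classifier(fix$matrix, fix$labeling, mil_config())
  hp2 <- decision_hyperplane(m2)
  ctr <- fix$matrix$values - rowMeans(fix$matrix$values)
  manual2 <- drop(ctr %*% hp2$w) + hp2$b
  expect_equal(unname(score_instances(m2, fix$matrix)), unname(manual2),
               tolerance = 1e-8)
})

test_that("decision scores agree in sign with an independent convex solver", {
  skip_if_not_installed("kernlab")
  set.seed(33)
  X <- matrix(rnorm(20 * 4), 20, 4)
  X[1:8, 1] <- X[1:8, 1] + 1.5
  # pre-standardize so both solvers face the identical problem
  X <- scale(X)
  attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  m <- make_matrix(X)
  lab <- stats::setNames(rep(c("POS", "NEG"), c(8, 12)), rownames(m$values))
  class(lab) <- "instance_labeling"
  mine <- train_margin_classifier(m, lab, mil_config(profile_centering = FALSE))
  sc <- score_instances(mine, m)
  ref <- kernlab::ksvm(X, factor(unclass(lab), levels = c("NEG", "POS")),
                       kernel = "vanilladot", C = 1, scaled = FALSE,
                       kpar = list())
  ref_sc <- kernlab::predict(ref, X, type = "decision")[, 1]
  if (cor(sc, ref_sc) < 0) ref_sc <- -ref_sc
  expect_gte(mean(sign(sc) == sign(ref_sc)), 0.95)
})

test_that("thresholds follow the three stated estimators", {
  expect_equal(compute_threshold(c(-1, 0, 2), "max"), 2)
  expect_equal(compute_threshold(c(0, 1, 2, 3), "p75"), 2.25)
  set.seed(101)
  draws <- rnorm(10000, mean = -2)
  expect_lt(abs(compute_threshold(draws, "mode") - (-2)), 0.2)
  # degenerate all-equal input has a well-defined mode
  expect_equal(compute_threshold(rep(1.5, 4), "mode"), 1.5)
  expect_error(compute_threshold(numeric(0), "max"), "no negative scores")
})

test_that("thresholds are ordered mode <= p75 <= max on unimodal samples", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(2000)
    t_mode <- compute_threshold(x, "mode")
    t_p75 <- compute_threshold(x, "p75")
    t_max <- compute_threshold(x, "max")
    expect_lte(t_mode, t_p75)
    expect_lte(t_p75, t_max)
  }
})

test_that("mi-SVM update thresholds strictly and rescues empty bags", {
  bags <- bag_map(c("p1", "p1", "p2", "p2", "n1"),
                  c("p1.a", "p1.b", "p2.a", "p2.b", "n1.a"))
  std <- term_standard("t", c("p1", "p2"), "n1")
  sc <- c(p1.a = 0.2, p1.b = -0.5, p2.a = -0.3, p2.b = -0.5, n1.a = -1)
  lab <- unclass(update_labels_mi(sc, bags, std, 0))
  expect_identical(unname(lab[c("p1.a", "p1.b")]), c("POS", "NEG"))
  # p2 has nothing above threshold: its argmax is rescued
  expect_identical(unname(lab[c("p2.a", "p2.b")]), c("POS", "NEG"))
  expect_identical(unname(lab["n1.a"]), "NEG")
  # exact threshold value is NEG (strict inequality)
  lab2 <- unclass(update_labels_mi(c(p1.a = 0, p1.b = -1, p2.a = 1,
                                     p2.b = 0, n1.a = 0), bags, std, 0))
  expect_identical(unname(lab2["p1.a"]), "POS")  # rescued argmax despite tie
  expect_identical(unname(lab2["p2.b"]), "NEG")
  # rescue tie goes to the lexicographically smallest isoform
  lab3 <- unclass(update_labels_mi(c(p1.a = -1, p1.b = -1, p2.a = 0.5,
                                     p2.b = -2, n1.a = 0), bags, std, 0))
  expect_identical(unname(lab3[c("p1.a", "p1.b")]), c("POS", "NEG"))
})

test_that("mi-SVM update equals a per-bag brute-force re-derivation", {
  set.seed(55)
  for (rep in 1:50) {
    n_genes <- sample(4:10, 1)
    iso_n <- sample(1:4, n_genes, replace = TRUE)
    gene <- rep(sprintf("g%02d", seq_len(n_genes)), iso_n)
    iso <- paste0(gene, ".", unlist(lapply(iso_n, seq_len)))
    bags <- bag_map(gene, iso)
    pos <- sample(unique(gene), sample(1:3, 1))
    std <- term_standard("t", pos, setdiff(unique(gene), pos))
    sc <- stats::setNames(round(rnorm(length(iso)), 1), iso)  # ties likely
    thr <- round(rnorm(1), 1)
    lab <- unclass(update_labels_mi(sc, bags, std, thr))
    for (g in unique(gene)) {
      members <- iso[gene == g]
      if (!g %in% pos) {
        expect_true(all(lab[members] == "NEG"))
      } else {
        manual <- ifelse(sc[members] > thr, "POS", "NEG")
        if (!any(manual == "POS")) {
          best <- members[sc[members] == max(sc[members])]
          manual[members == min(best)] <- "POS"
        }
        expect_identical(unname(lab[members]), unname(manual))
      }
    }
  }
})

test_that("MI-SVM update selects exactly one witness, others NEUTRAL", {
  bags <- bag_map(c("p1", "p1", "p1", "p2", "n1"),
                  c("p1.a", "p1.b", "p1.c", "p2.a", "n1.a"))
  std <- term_standard("t", c("p1", "p2"), "n1")
  sc <- c(p1.a = 0.9, p1.b = 0.1, p1.c = -0.2, p2.a = -5, n1.a = 0)
  lab <- unclass(update_labels_MI(sc, bags, std))
  expect_identical(unname(lab[c("p1.a", "p1.b", "p1.c")]),
                   c("POS", "NEUTRAL", "NEUTRAL"))
  expect_identical(unname(lab["p2.a"]), "POS")  # single-isoform forced witness
  expect_identical(unname(lab["n1.a"]), "NEG")
  # tie broken lexicographically
  sc2 <- c(p1.a = 1, p1.b = 1, p1.c = -1, p2.a = 0, n1.a = 0)
  expect_identical(unname(unclass(update_labels_MI(sc2, bags, std))["p1.a"]),
                   "POS")
})

test_that("random witness selection is uniform over isoforms", {
  bags <- bag_map(rep("p1", 3), c("p1.a", "p1.b", "p1.c"))
  std <- term_standard("t", "p1", character(0))
  sc <- c(p1.a = 0, p1.b = 0, p1.c = 0)
  picks <- vapply(1:10000, function(s) {
    lab <- unclass(update_labels_MI(sc, bags, std, random_witness = TRUE,
                                    seed = s))
    names(lab)[lab == "POS"]
  }, character(1))
  freqs <- table(picks) / 10000
  expect_true(all(abs(freqs - 1 / 3) < 0.02))
})

test_that("convergence detects fixed points and cycles", {
  mk <- function(...) {
    lab <- c(...)
    class(lab) <- "instance_labeling"
    lab
  }
  a <- mk(x = "POS", y = "NEG")
  b <- mk(x = "NEG", y = "POS")
  c_ <- mk(x = "POS", y = "POS")
  expect_true(has_converged(list(a), a))
  expect_true(has_converged(list(a, b, c_), c_))  # fixed point at last
  expect_true(has_converged(list(a, b, c_), a))   # revert to history[[1]]
  expect_false(has_converged(list(a, b), c_))
  # name order must not matter
  a_rev <- mk(y = "NEG", x = "POS")
  expect_true(has_converged(list(a), a_rev))
})

test_that("run_mil confirms in exactly two passes when labels cannot move", {
  # all positive genes single-isoform: no hidden variables to update
  set.seed(77)
  n_neg <- 30
  gene <- c("p1", "p2", "p3", sprintf("n%02d", 1:n_neg))
  iso <- paste0(gene, ".1")
  X <- matrix(rnorm(length(iso) * 10), length(iso), 10)
  X[1:3, 1:4] <- X[1:3, 1:4] + 3
  m <- make_matrix(X, iso = iso)
  bags <- bag_map(gene, iso)
  std <- term_standard("t", c("p1", "p2", "p3"), gene[-(1:3)])
  fit <- run_mil(m, bags, std, mil_config(seed = 1))
  expect_true(fit$converged)
  expect_identical(fit$iterations, 2L)
  expect_identical(unclass(fit$labeling)[paste0(std$positives, ".1")],
                   stats::setNames(rep("POS", 3), paste0(std$positives, ".1")))
})

test_that("run_mil converges on planted-witness data and is seed-reproducible", {
  d <- small_synth(seed = 7)
  cfg <- mil_config(seed = 7)
  fit1 <- run_mil(d$matrix, d$bags, d$standard, cfg)
  expect_true(fit1$converged)
  expect_lte(fit1$iterations, 10)
  # at-least-one-witness constraint holds in the final labeling
  lab <- unclass(fit1$labeling)
  for (g in d$standard$positives)
    expect_true(any(lab[isoforms_of(d$bags, g)] == "POS"))
  neg_iso <- d$bags$isoform_id[d$bags$gene_id %in% d$standard$negatives]
  expect_true(all(lab[neg_iso] == "NEG"))
  # identical config and seed reproduce scores and labels exactly
  fit2 <- run_mil(d$matrix, d$bags, d$standard, cfg)
  expect_identical(fit2$scores, fit1$scores)
  expect_identical(unclass(fit2$labeling), unclass(fit1$labeling))
  expect_identical(fit2$iterations, fit1$iterations)
})

test_that("MI-SVM runs keep exactly one witness per positive bag", {
  d <- small_synth(seed = 11)
  fit <- run_mil(d$matrix, d$bags, d$standard,
                 mil_config(formulation = "MI_svm", seed = 11))
  lab <- unclass(fit$labeling)
  for (g in d$standard$positives) {
    members <- isoforms_of(d$bags, g)
    expect_identical(sum(lab[members] == "POS"), 1L)
    expect_true(all(lab[members] %in% c("POS", "NEUTRAL")))
  }
})

test_that("random-witness baseline halts through cycle detection", {
  d <- small_synth(seed = 13)
  # a random witness per iteration rarely reaches a fixed point: the run
  # must still halt, through cycle detection or the iteration cap
  fit <- suppressWarnings(
    run_mil(d$matrix, d$bags, d$standard,
            mil_config(formulation = "MI_svm_random", seed = 13,
                       update_scoring = "insample")))
  expect_lte(fit$iterations, fit$config$max_iterations)
  lab <- unclass(fit$labeling)
  for (g in d$standard$positives)
    expect_identical(sum(lab[isoforms_of(d$bags, g)] == "POS"), 1L)
})

test_that("gene aggregation takes the maximum over isoforms", {
  bags <- bag_map(c("g1", "g1", "g2"), c("g1.a", "g1.b", "g2.a"))
  sc <- c(g1.a = 0.1, g1.b = 0.9, g2.a = -0.4)
  gs <- aggregate_gene_scores(sc, bags)
  expect_equal(gs[["g1"]], 0.9)
  expect_equal(gs[["g2"]], -0.4)
  expect_error(aggregate_gene_scores(sc[-1], bags), "unscored")
  # random fixture vs per-gene loop
  set.seed(88)
  gene <- rep(sprintf("g%03d", 1:100), sample(1:4, 100, replace = TRUE))
  iso <- paste0(gene, ".", ave(seq_along(gene), gene, FUN = seq_along))
  bags2 <- bag_map(gene, iso)
  sc2 <- stats::setNames(rnorm(length(iso)), iso)
  gs2 <- aggregate_gene_scores(sc2, bags2)
  for (g in sample(unique(gene), 20))
    expect_equal(gs2[[g]], max(sc2[iso[gene == g]]))
})

test_that("stricter thresholds never produce more positives", {
  # on the same scores, POS counts are ordered mode >= p75 >= max
  set.seed(99)
  n_genes <- 30
  iso_n <- sample(1:4, n_genes, replace = TRUE)
  gene <- rep(sprintf("g%02d", 1:n_genes), iso_n)
  iso <- paste0(gene, ".", unlist(lapply(iso_n, seq_len)))
  bags <- bag_map(gene, iso)
  pos <- sprintf("g%02d", 1:10)
  std <- term_standard("t", pos, setdiff(unique(gene), pos))
  sc <- stats::setNames(rnorm(length(iso)), iso)
  neg_sc <- sc[iso[!gene %in% pos]]
  counts <- vapply(c("mode", "p75", "max"), function(v) {
    lab <- unclass(update_labels_mi(sc, bags, std,
                                    compute_threshold(neg_sc, v)))
    sum(lab == "POS")
  }, numeric(1))
  expect_gte(counts[["mode"]], counts[["p75"]])
  expect_gte(counts[["p75"]], counts[["max"]])
})
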