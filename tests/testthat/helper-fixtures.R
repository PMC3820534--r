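# Fixture builders shared across the test files. Everything is generated in
# code; no fixture is read from disk unless a test writes it first.

# small expression matrix with named rows/columns
make_matrix <- function(values, iso = NULL, exps = NULL, space = "log2") {
  if (is.null(iso)) iso <- sprintf("iso%02d", seq_len(nrow(values)))
  if (is.null(exps)) exps <- sprintf("e%02d", seq_len(ncol(values)))
  dimnames(values) <- list(iso, exps)
  expression_matrix(values, space = space)
}

# well-separated two-class point cloud as an expression_matrix + labeling;
# the class shift sits on the first feature only so that it survives
# per-instance profile centering
make_separable <- function(n_pos = 10, n_neg = 10, d = 2, gap = 4, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm((n_pos + n_neg) * d), n_pos + n_neg, d)
  X[seq_len(n_pos), 1] <- X[seq_len(n_pos), 1] + gap
  m <- make_matrix(X)
  lab <- stats::setNames(rep(c("POS", "NEG"), c(n_pos, n_neg)),
                         rownames(m$values))
  class(lab) <- "instance_labeling"
  list(matrix = m, labeling = lab,
       pos = rownames(m$values)[seq_len(n_pos)],
       neg = rownames(m$values)[n_pos + seq_len(n_neg)])
}

# random tiny MIL problem for oracle-enumeration comparisons:
# <= 4 positive bags of <= 2 isoforms, <= 10 negative single-isoform genes
make_tiny_problem <- function(seed, n_features = 2, shift = 2.5) {
  set.seed(seed)
  n_pos_bags <- sample(2:4, 1)
  pos_sizes <- sample(1:2, n_pos_bags, replace = TRUE)
  n_neg <- sample(6:10, 1)
  gene <- c(rep(sprintf("pg%02d", seq_len(n_pos_bags)), pos_sizes),
            sprintf("ng%02d", seq_len(n_neg)))
  iso <- paste0(gene, ".", unlist(c(lapply(pos_sizes, seq_len),
                                    as.list(rep(1, n_neg)))))
  bags <- bag_map(gene, iso)
  pos_genes <- unique(gene[startsWith(gene, "pg")])
  # one true witness per positive bag gets a shifted signature
  X <- matrix(rnorm(length(iso) * n_features), length(iso), n_features)
  rownames(X) <- iso
  for (g in pos_genes) {
    members <- iso[gene == g]
    wit <- sample(members, 1)
    sig <- seq_len(ceiling(n_features / 2))
    X[wit, sig] <- X[wit, sig] + shift
  }
  m <- make_matrix(X, iso = iso)
  std <- term_standard("T:TINY", pos_genes, setdiff(unique(gene), pos_genes))
  list(matrix = m, bags = bags, standard = std)
}

# all admissible mi-SVM labelings of a tiny problem: every instance of a
# negative gene NEG; each positive bag any non-empty POS subset
admissible_labelings <- function(bags, standard) {
  base <- stats::setNames(rep("NEG", nrow(bags)), bags$isoform_id)
  pos_genes <- intersect(bag_genes(bags), standard$positives)
  per_bag <- lapply(pos_genes, function(g) {
    iso <- isoforms_of(bags, g)
    subsets <- list()
    for (mask in seq_len(2^length(iso) - 1)) {
      subsets[[length(subsets) + 1]] <-
        iso[bitwAnd(mask, 2^(seq_along(iso) - 1)) > 0]
    }
    subsets
  })
  combos <- expand.grid(lapply(per_bag, seq_along))
  out <- list()
  for (i in seq_len(nrow(combos))) {
    lab <- base
    for (b in seq_along(per_bag))
      lab[per_bag[[b]][[combos[i, b]]]] <- "POS"
    class(lab) <- "instance_labeling"
    out[[i]] <- lab
  }
  out
}

# small synthetic study used where the full default would be overkill
small_synth <- function(seed = 7, ...) {
  generate_term_dataset(synth_config(n_pos_genes = 15, n_neg_genes = 150,
                                     n_experiments = 40, signature_dim = 12,
                                     seed = seed, ...))
}
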