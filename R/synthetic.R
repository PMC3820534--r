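#' Configuration of the synthetic study generator
#'
#' Describes a single-term synthetic study with planted witness isoforms:
#' positive genes carry at least one "functional" isoform whose expression
#' is shifted by `effect_size` in a fixed subset of `signature_dim`
#' experiments (a co-expression signature), while non-functional isoforms
#' and all negative-gene isoforms are baseline noise. Baseline means are
#' drawn per isoform to mimic expression-level heterogeneity across genes.
#' Values live on the log2 scale, the working space of the real pipeline,
#' with missing cells at the sentinel.
#'
#' Defaults place ~2.4% of genes in the positive class (50 of 2050), the
#' prevalence regime of typical Gene Ontology terms with 20-300 positives
#' among ~19k genes scaled down; most genes are single-isoform, matching
#' annotated transcriptomes.
#'
#' @param n_pos_genes,n_neg_genes gene counts (defaults 50 and 2000).
#' @param n_experiments number of expression columns (default 120).
#' @param iso_count_probs probability over isoform counts 1..6 per gene
#'   (default mass 0.6 on single-isoform genes).
#' @param witness_fraction fraction of a positive gene's isoforms that are
#'   functional; `NULL` (default) plants exactly one witness per gene.
#' @param signature_dim number of experiments carrying the signal
#'   (default 30).
#' @param effect_size log2 shift added to functional isoforms in signature
#'   experiments (default 2).
#' @param noise_sd standard deviation of the Gaussian noise (default 1).
#' @param missing_rate fraction of cells set to the missing sentinel
#'   (default 0.05).
#' @param sentinel missing-value sentinel (default -15).
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_pos_genes = 50L, n_neg_genes = 2000L,
                         n_experiments = 120L,
                         iso_count_probs = c(0.60, 0.16, 0.10, 0.06, 0.05, 0.03),
                         witness_fraction = NULL,
                         signature_dim = 30L, effect_size = 2.0,
                         noise_sd = 1.0, missing_rate = 0.05,
                         sentinel = -15, seed = 1L) {
  stopifnot(n_pos_genes >= 1, n_neg_genes >= 1, n_experiments >= 1,
            length(iso_count_probs) >= 1, all(iso_count_probs >= 0),
            signature_dim >= 1, signature_dim <= n_experiments,
            noise_sd > 0, missing_rate >= 0, missing_rate <= 1)
  if (!is.null(witness_fraction))
    stopifnot(witness_fraction > 0, witness_fraction <= 1)
  structure(list(n_pos_genes = as.integer(n_pos_genes),
                 n_neg_genes = as.integer(n_neg_genes),
                 n_experiments = as.integer(n_experiments),
                 iso_count_probs = iso_count_probs / sum(iso_count_probs),
                 witness_fraction = witness_fraction,
                 signature_dim = as.integer(signature_dim),
                 effect_size = effect_size, noise_sd = noise_sd,
                 missing_rate = missing_rate, sentinel = sentinel,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate one synthetic term dataset with planted witnesses
#'
#' @param config a `synth_config`.
#' @return List with `matrix` (log2-space `expression_matrix`), `bags`
#'   (`bag_map`), `standard` (`term_standard`, term id `"GO:SYNTH"`),
#'   `truth` (named character: `"functional"` / `"non_functional"` per
#'   isoform) and `signature` (the signal-carrying experiment ids).
#' @export
generate_term_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_genes <- config$n_pos_genes + config$n_neg_genes
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  pos_genes <- gene_ids[seq_len(config$n_pos_genes)]
  k_choices <- seq_along(config$iso_count_probs)
  iso_n <- sample(k_choices, n_genes, replace = TRUE,
                  prob = config$iso_count_probs)
  gene_col <- rep(gene_ids, iso_n)
  iso_ids <- paste0(gene_col, ".", unlist(lapply(iso_n, seq_len)))
  bags <- bag_map(gene_col, iso_ids)

  exp_ids <- sprintf("exp%03d", seq_len(config$n_experiments))
  signature <- sort(sample(exp_ids, config$signature_dim))

  n_iso <- length(iso_ids)
  mu <- stats::rnorm(n_iso, mean = 3, sd = 2)
  values <- mu + matrix(stats::rnorm(n_iso * config$n_experiments,
                                     sd = config$noise_sd),
                        nrow = n_iso)
  dimnames(values) <- list(iso_ids, exp_ids)

  truth <- stats::setNames(rep("non_functional", n_iso), iso_ids)
  for (g in pos_genes) {
    iso <- iso_ids[gene_col == g]
    n_wit <- if (is.null(config$witness_fraction)) 1L else
      max(1L, round(config$witness_fraction * length(iso)))
    wit <- if (length(iso) == 1L) iso else sample(iso, n_wit)
    truth[wit] <- "functional"
    values[wit, signature] <- values[wit, signature, drop = FALSE] +
      config$effect_size
  }

  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n_iso * config$n_experiments) <
                     config$missing_rate,
                   nrow = n_iso)
    values[mask] <- config$sentinel
  }

  list(matrix = expression_matrix(values, space = "log2",
                                  sentinel = config$sentinel),
       bags = bags,
       standard = term_standard("GO:SYNTH", pos_genes,
                                setdiff(gene_ids, pos_genes)),
       truth = truth,
       signature = signature)
}

#' Generate a toy ontology with gene annotations
#'
#' Builds a random `is_a` tree of `n_terms` terms and annotates genes to
#' leaf-level terms with sizes straddling the 20/300 selection bounds, so
#' that after descendant propagation some terms fall below, inside and
#' above the window.
#'
#' @param n_terms number of terms (>= 2).
#' @param seed integer seed.
#' @param n_genes size of the gene pool (default 1500).
#' @return List with `ontology`, `annotations` (data frame `gene_id`,
#'   `term_id`) and `genes` (the universe).
#' @export
generate_toy_ontology <- function(n_terms, seed = 1L, n_genes = 1500L) {
  if (n_terms < 2) stop("need at least 2 terms")
  set.seed(as.integer(seed))
  terms <- sprintf("T:%04d", seq_len(n_terms))
  parent <- vapply(seq_len(n_terms - 1L) + 1L,
                   function(i) terms[sample.int(i - 1L, 1)], character(1))
  edges <- data.frame(child = terms[-1], parent = parent,
                      stringsAsFactors = FALSE)
  ont <- ontology(terms, edges)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  # direct annotation sizes drawn from a mixture so propagated sizes
  # straddle the 20 and 300 bounds
  size_pool <- function() {
    cls <- sample(c("small", "mid", "large"), 1, prob = c(0.4, 0.45, 0.15))
    switch(cls,
           small = sample(3:15, 1),
           mid = sample(25:150, 1),
           large = sample(350:500, 1))
  }
  ann <- do.call(rbind, lapply(terms, function(t) {
    n <- size_pool()
    data.frame(gene_id = sample(genes, min(n, n_genes)), term_id = t,
               stringsAsFactors = FALSE)
  }))
  list(ontology = ont, annotations = ann, genes = genes)
}
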