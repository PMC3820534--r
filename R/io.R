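#' Read an isoform expression TSV
#'
#' Expects a header row of experiment ids and a first column of isoform
#' ids; cells are numeric or the literal token `NA` (missing). Rows with a
#' deviant field count raise an error naming the line.
#'
#' @param path file path.
#' @param space `"fpkm"` (raw quantifier output, default) or `"log2"`.
#' @param sentinel sentinel for log2-space matrices (default -15).
#' @return An `expression_matrix`.
#' @export
read_expression_tsv <- function(path, space = "fpkm", sentinel = -15) {
  cf <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(cf != cf[1])
  if (length(bad))
    stop("malformed row length at line ", bad[1] + 0L, " of ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("expression TSV needs an id column and >= 1 experiment")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate isoform id(s): ", ids[duplicated(ids)][1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(vals), nrow = nrow(vals)))
  non_na <- vals != "NA" & !is.na(vals)
  if (any(is.na(storage) & non_na))
    stop("non-numeric cell in expression TSV: ",
         vals[is.na(storage) & non_na][1])
  dimnames(storage) <- list(ids, colnames(df)[-1])
  expression_matrix(storage, space = space, sentinel = sentinel)
}

#' Write an expression matrix as TSV
#'
#' Deterministic byte-for-byte: fixed column order, `NA` for missing
#' FPKM cells, LF line endings.
#'
#' @param matrix an `expression_matrix`.
#' @param path output path.
#' @export
write_expression_tsv <- function(matrix, path) {
  v <- matrix$values
  df <- data.frame(isoform_id = rownames(v),
                   format_num(v), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("isoform_id", colnames(v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

# fixed-precision numeric formatting shared by all writers (%.10g keeps
# round-trips lossless at the scales used while staying byte-deterministic)
format_num <- function(x) {
  out <- ifelse(is.na(x), NA_character_, sprintf("%.10g", x))
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Read experiment metadata TSV
#'
#' Columns: `experiment_id`, `total_reads`, `mapped_fraction`.
#'
#' @param path file path.
#' @return Data frame suitable for [filter_experiments()].
#' @export
read_experiment_meta <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  req <- c("experiment_id", "total_reads", "mapped_fraction")
  if (!all(req %in% names(df)))
    stop("metadata TSV must have columns: ", paste(req, collapse = ", "))
  df
}

#' Read a gene-to-isoform map
#'
#' Accepts either a two-column TSV (`gene_id`, `isoform_id`, with header)
#' or a GTF file, from which (gene_id, transcript_id) attribute pairs of
#' `transcript` features are extracted (via rtracklayer). Duplicate pairs
#' are collapsed; an isoform mapped to two genes is an error.
#'
#' @param path file path; a `.gtf` extension selects GTF parsing.
#' @return A `bag_map`.
#' @export
read_gene_map <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF gene maps requires the rtracklayer package")
    g <- rtracklayer::readGFF(path,
                              columns = "type",
                              tags = c("gene_id", "transcript_id"))
    g <- g[g$type == "transcript", , drop = FALSE]
    if (!nrow(g)) stop("no transcript features found in ", path)
    return(bag_map(as.character(g$gene_id), as.character(g$transcript_id)))
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("gene_id", "isoform_id") %in% names(df)))
    stop("gene map TSV must have columns gene_id, isoform_id")
  bag_map(df$gene_id, df$isoform_id)
}

#' Write a gene-to-isoform map as TSV
#'
#' @param bags a `bag_map`.
#' @param path output path.
#' @export
write_gene_map <- function(bags, path) {
  df <- as.data.frame(bags)[order(bags$gene_id, bags$isoform_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas for `id:`, `is_a:` and (optionally)
#' `relationship: part_of` lines. Obsolete terms are skipped and counted in
#' a message; edges touching them are dropped.
#'
#' @param path file path.
#' @param include_part_of also propagate `part_of` relationships
#'   (default FALSE: only `is_a` edges are used).
#' @return An `ontology`; the number of skipped obsolete terms is in
#'   `attr(, "n_obsolete")`.
#' @export
read_obo <- function(path, include_part_of = FALSE) {
  lines <- readLines(path, warn = FALSE)
  terms <- character()
  children <- character()
  parents <- character()
  cur <- NULL
  cur_parents <- character()
  obsolete <- FALSE
  n_obsolete <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    if (obsolete) {
      n_obsolete <<- n_obsolete + 1L
    } else {
      terms <<- c(terms, cur)
      if (length(cur_parents)) {
        children <<- c(children, rep(cur, length(cur_parents)))
        parents <<- c(parents, cur_parents)
      }
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      flush()
      cur <- NULL; cur_parents <- character(); obsolete <- FALSE
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush()
      cur <- NULL; in_term <- FALSE
    } else if (in_term) {
      if (grepl("^id:", ln)) {
        cur <- sub("^id:\\s*", "", ln)
      } else if (grepl("^is_a:", ln)) {
        cur_parents <- c(cur_parents,
                         sub("\\s*!.*$", "", sub("^is_a:\\s*", "", ln)))
      } else if (include_part_of && grepl("^relationship:\\s*part_of", ln)) {
        cur_parents <- c(cur_parents,
                         sub("\\s*!.*$", "",
                             sub("^relationship:\\s*part_of\\s*", "", ln)))
      } else if (grepl("^is_obsolete:\\s*true", ln)) {
        obsolete <- TRUE
      }
    }
  }
  flush()
  if (n_obsolete)
    message(n_obsolete, " obsolete term(s) skipped in ", path)
  keep <- parents %in% terms  # drop edges into obsolete/unknown parents
  ont <- ontology(terms, data.frame(child = children[keep],
                                    parent = parents[keep],
                                    stringsAsFactors = FALSE))
  attr(ont, "n_obsolete") <- n_obsolete
  ont
}

#' Write a minimal OBO 1.2 file
#'
#' @param ont an `ontology`.
#' @param path output path.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  by_child <- split(ont$edges$parent, ont$edges$child)
  for (t in sort(ont$term_ids)) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    for (p in sort(by_child[[t]])) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Read gene-term annotations (GAF 2.x or two-column TSV)
#'
#' Lines starting with `!` are skipped. Two-column files are read as
#' (gene_id, term_id) pairs; files with 15-17 columns are treated as GAF,
#' taking the DB object id (column 2) and GO id (column 5). Annotations to
#' terms absent from `ont` (e.g. obsolete) are dropped and counted in a
#' message when an ontology is supplied.
#'
#' @param path file path.
#' @param ont optional `ontology` used to drop annotations to unknown terms.
#' @return Data frame with columns `gene_id`, `term_id` (deduplicated).
#' @export
read_gaf <- function(path, ont = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (!length(lines)) stop("no annotation lines in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (all(ncols == 2)) {
    df <- data.frame(gene_id = vapply(fields, `[[`, "", 1),
                     term_id = vapply(fields, `[[`, "", 2),
                     stringsAsFactors = FALSE)
    # tolerate a header row in the two-column dialect
    if (identical(unname(unlist(df[1, ])), c("gene_id", "term_id")))
      df <- df[-1, , drop = FALSE]
  } else if (all(ncols >= 15 & ncols <= 17)) {
    df <- data.frame(gene_id = vapply(fields, `[[`, "", 2),
                     term_id = vapply(fields, `[[`, "", 5),
                     stringsAsFactors = FALSE)
  } else {
    stop("line ", which(ncols != 2 & (ncols < 15 | ncols > 17))[1],
         ": unknown column count in ", path)
  }
  df <- unique(df)
  if (!is.null(ont)) {
    drop <- !df$term_id %in% ont$term_ids
    if (any(drop))
      message(sum(drop), " annotation(s) to unknown/obsolete terms dropped")
    df <- df[!drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write isoform-level predictions as TSV
#'
#' Columns: term_id, gene_id, isoform_id, decision_score, probability,
#' fold_change. Rows are ordered lexicographically by (term, gene,
#' isoform); output is byte-deterministic.
#'
#' @param predictions a `term_predictions` data frame (or any data frame
#'   with those columns).
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("term_id", "gene_id", "isoform_id", "decision_score",
            "probability", "fold_change")
  if (!all(cols %in% names(predictions)))
    stop("predictions must have columns: ", paste(cols, collapse = ", "))
  df <- predictions[order(predictions$term_id, predictions$gene_id,
                          predictions$isoform_id), cols, drop = FALSE]
  for (cc in c("decision_score", "probability", "fold_change"))
    df[[cc]] <- format_num(df[[cc]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

#' Read back a predictions TSV
#'
#' @param path file path.
#' @return Data frame with the prediction columns typed numerically.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  for (cc in c("decision_score", "probability", "fold_change"))
    df[[cc]] <- as.numeric(df[[cc]])
  df
}

#' Write an evaluation report as TSV
#'
#' Columns: term_id, group_tag, auc, auprc, p_at_1pct, p_at_10pct,
#' n_pos_test, n_neg_test; rows ordered by (term, group).
#'
#' @param report data frame as produced by [evaluate_term()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  cols <- c("term_id", "group_tag", "auc", "auprc", "p_at_1pct",
            "p_at_10pct", "n_pos_test", "n_neg_test")
  if (!all(cols %in% names(report)))
    stop("report must have columns: ", paste(cols, collapse = ", "))
  df <- report[order(report$term_id, report$group_tag), cols, drop = FALSE]
  for (cc in c("auc", "auprc", "p_at_1pct", "p_at_10pct"))
    df[[cc]] <- format_num(df[[cc]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}
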