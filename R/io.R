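# Tab-delimited, GMT, and edge-list adapters.  Dialect is fixed: UTF-8,
# tab-separated, header row, no quoting; numeric columns are written with 6
# significant digits so re-runs are byte-comparable.

#' Write a data frame as TSV
#'
#' Fixed dialect: tab-separated, header, no quotes, no row names; numeric
#' columns rounded to 6 significant digits for byte-stable output.
#'
#' @param df Data frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV with required columns
#'
#' @param path Input file.
#' @param required Character vector of column names that must be present.
#' @return Data frame.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", fileEncoding = "UTF-8")
  if (!is.null(required)) assert_columns(df, required, path)
  df
}

#' Read a replicate score table
#'
#' Validates the screen-table schema (\code{pair_id}, \code{gene_a},
#' \code{gene_b}, \code{genotype}, \code{replicate}, \code{score}), the
#' genotype vocabulary, and score finiteness.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_score_table <- function(path) {
  df <- read_tsv(path, required = c("pair_id", "gene_a", "gene_b",
                                    "genotype", "replicate", "score"))
  bad <- which(!df$genotype %in% c("control", "A", "B", "AB"))
  if (length(bad)) {
    stop(sprintf("invalid genotype '%s' at data line %d of %s",
                 df$genotype[bad[1]], bad[1], path), call. = FALSE)
  }
  if (any(!is.finite(df$score))) {
    stop("non-finite score in ", path, call. = FALSE)
  }
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per line, tab-separated fields
#' \code{term<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path GMT file.
#' @return Named list of gene identifier vectors with a \code{description}
#'   attribute per element.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop(sprintf("malformed GMT line %d in %s (need term, description, ",
                   i, path), ">= 1 gene)", call. = FALSE)
    }
    genes <- unique(parts[-(1:2)])
    attr(genes, "description") <- parts[2]
    if (parts[1] %in% names(sets)) {
      stop(sprintf("duplicate term '%s' at GMT line %d", parts[1], i),
           call. = FALSE)
    }
    sets[[parts[1]]] <- genes
  }
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of gene vectors (optional \code{description}
#'   attributes; defaults to the term id).
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(tid) {
    desc <- attr(sets[[tid]], "description") %||% tid
    paste(c(tid, desc, sets[[tid]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a weighted edge list into an igraph graph
#'
#' TSV with header columns \code{gene1}, \code{gene2}, \code{weight}.
#' Self-loops and duplicate edges (in either orientation) are rejected with
#' their line number; weights must lie in (0, 1].
#'
#' @param path TSV edge list.
#' @return Undirected \pkg{igraph} graph with edge weights.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv(path, required = c("gene1", "gene2", "weight"))
  edge_list_to_graph(df, source = path)
}

#' @keywords internal
#' @noRd
edge_list_to_graph <- function(df, source = "edge list") {
  df <- as.data.frame(df)
  assert_columns(df, c("gene1", "gene2", "weight"), source)
  loops <- which(df$gene1 == df$gene2)
  if (length(loops)) {
    stop(sprintf("self-loop at data line %d of %s", loops[1], source),
         call. = FALSE)
  }
  key <- paste(pmin(df$gene1, df$gene2), pmax(df$gene1, df$gene2))
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate edge at data line %d of %s", dup[1], source),
         call. = FALSE)
  }
  if (any(df$weight <= 0 | df$weight > 1)) {
    bad <- which(df$weight <= 0 | df$weight > 1)[1]
    stop(sprintf("weight out of (0, 1] at data line %d of %s", bad, source),
         call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(df[, c("gene1", "gene2")],
                                     directed = FALSE)
  igraph::E(g)$weight <- df$weight
  g
}

#' Write an igraph graph as a TSV edge list
#'
#' @param graph Undirected weighted \pkg{igraph} graph.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  write_tsv(data.frame(gene1 = el[, 1], gene2 = el[, 2], weight = w), path)
}

#' Read a one-identifier-per-line gene list
#'
#' @param path Text file; blank lines ignored.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, encoding = "UTF-8"))
  x[nzchar(x)]
}
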