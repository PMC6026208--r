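#' Call differentially expressed genes from a DE table
#'
#' Applies the standard two-criterion filter: absolute log2 fold-change
#' strictly greater than \code{lfc_threshold} AND corrected FDR strictly
#' below \code{fdr_threshold}.  A gene sitting exactly on either threshold is
#' excluded.
#'
#' @param table Data frame with columns \code{gene}, \code{log2FC},
#'   \code{FDR}.
#' @param lfc_threshold Absolute log2 fold-change cut (default 1, i.e. a
#'   two-fold change).
#' @param fdr_threshold FDR cut (default 0.05).
#' @return Character vector of DE gene identifiers.
#' @examples
#' call_de_genes(data.frame(gene = c("a", "b"), log2FC = c(1.5, 0.9),
#'                          FDR = c(0.01, 0.001)))
#' @export
call_de_genes <- function(table, lfc_threshold = 1, fdr_threshold = 0.05) {
  table <- as.data.frame(table)
  assert_columns(table, c("gene", "log2FC", "FDR"), "DE table")
  if (any(table$FDR < 0 | table$FDR > 1, na.rm = TRUE)) {
    stop("FDR values must lie in [0, 1]", call. = FALSE)
  }
  keep <- abs(table$log2FC) > lfc_threshold & table$FDR < fdr_threshold
  table$gene[which(keep)]
}

#' Translate a gene set through a homolog mapping table
#'
#' Resolves a many-to-many fly-to-human homolog mapping.  The default policy
#' keeps every mapped pair; \code{"best_score"} keeps only the top-scoring
#' human homolog per fly gene (ties broken by identifier order).  Genes with
#' no mapping are dropped and counted.
#'
#' @param genes Character vector of source (fly) gene identifiers.
#' @param mapping Data frame with columns \code{fly}, \code{human},
#'   \code{score}.
#' @param policy \code{"keep_all"} or \code{"best_score"}.
#' @return List with \code{translated} (unique human identifiers),
#'   \code{n_unmapped}, and \code{unmapped} (the dropped source genes).
#' @export
map_homologs <- function(genes, mapping, policy = c("keep_all",
                                                    "best_score")) {
  policy <- match.arg(policy)
  mapping <- as.data.frame(mapping)
  assert_columns(mapping, c("fly", "human", "score"), "homolog mapping")
  if (!nrow(mapping)) stop("homolog mapping is empty", call. = FALSE)
  hit <- mapping[mapping$fly %in% genes, , drop = FALSE]
  if (policy == "best_score" && nrow(hit)) {
    hit <- hit[order(hit$fly, -hit$score, hit$human), , drop = FALSE]
    hit <- hit[!duplicated(hit$fly), , drop = FALSE]
  }
  unmapped <- setdiff(genes, mapping$fly)
  list(translated = unique(hit$human), n_unmapped = length(unmapped),
       unmapped = unmapped)
}

#' Parametric gene-set enrichment (PAGE) Z-scores
#'
#' For each gene set, averages the log2 fold-changes of its measured member
#' genes (\eqn{S_m}), and standardises against the background of all measured
#' genes: \deqn{Z = (S_m - \mu)\sqrt{m} / \delta,} where \eqn{\mu} and
#' \eqn{\delta} are the mean and sample SD of all log2 fold-changes and m the
#' number of measured member genes.  Z measures coordinated up- (positive) or
#' down-regulation (negative) of the set.  Two-sided normal p-values are
#' corrected across the retained terms by Benjamini-Hochberg; terms reaching
#' adjusted p below \code{sig_threshold} are flagged significant.  Terms with
#' at least \code{max_set_size} measured genes are excluded as too general,
#' as are terms with fewer than \code{min_set_size} measured genes.
#'
#' The \eqn{\sqrt{m}} factor is the classic parametric-enrichment convention
#' (the central-limit standardisation of a mean of m values); setting
#' \code{sqrt_m = FALSE} standardises the raw set mean instead.
#'
#' @param table DE table (\code{gene}, \code{log2FC}; an \code{FDR} column is
#'   ignored here — enrichment uses all measured genes).
#' @param sets Named list mapping term ids to gene identifier vectors (as
#'   read by [read_gmt()]).
#' @param max_set_size Terms with m >= this are dropped (default 500).
#' @param min_set_size Minimum measured member genes (default 2).
#' @param sqrt_m Include the \eqn{\sqrt{m}} factor (default TRUE).
#' @param sig_threshold Adjusted-p cut for the \code{significant} flag.
#' @return Data frame with one row per retained term: \code{term}, \code{m},
#'   \code{S_m}, \code{mu}, \code{delta}, \code{Z}, \code{p}, \code{p_adj},
#'   \code{significant}.
#' @examples
#' tab <- data.frame(gene = paste0("g", 1:4), log2FC = 1:4)
#' page_zscores(tab, list(t1 = c("g2", "g4")))
#' @export
page_zscores <- function(table, sets, max_set_size = 500L, min_set_size = 2L,
                         sqrt_m = TRUE, sig_threshold = 0.01) {
  table <- as.data.frame(table)
  assert_columns(table, c("gene", "log2FC"), "DE table")
  if (anyDuplicated(table$gene)) {
    stop("gene ids must be unique within a DE table", call. = FALSE)
  }
  lfc <- table$log2FC
  names(lfc) <- table$gene
  mu <- mean(lfc)
  delta <- stats::sd(lfc)
  if (!is.finite(delta) || delta == 0) {
    stop("degenerate expression table: zero SD of log2 fold-changes",
         call. = FALSE)
  }
  rows <- lapply(names(sets), function(tid) {
    members <- intersect(sets[[tid]], table$gene)
    m <- length(members)
    if (m < min_set_size || m >= max_set_size) return(NULL)
    s_m <- mean(lfc[members])
    z <- (s_m - mu) * (if (sqrt_m) sqrt(m) else 1) / delta
    data.frame(term = tid, m = m, S_m = s_m, mu = mu, delta = delta, Z = z)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), m = integer(0), S_m = numeric(0),
                      mu = numeric(0), delta = numeric(0), Z = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  }
  out$p <- 2 * stats::pnorm(-abs(out$Z))
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < sig_threshold
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Monotone step-up adjusted p-values, capped at 1; the output is never below
#' the input.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Permutation test for cross-model overlap of DE genes
#'
#' Given per-model DE gene sets restricted to an annotation universe (for
#' example, cell proliferation genes), counts how many universe genes are DE
#' in at least k models, and estimates an empirical p-value by resampling:
#' each permutation redraws every model's set uniformly without replacement
#' from the universe at its observed size, preserving the set sizes while
#' destroying any coordination between models.  The add-one estimator
#' \code{p = (1 + #(null >= observed)) / (n_perm + 1)} is reported, so p is
#' never zero and its minimum is \code{1/(n_perm + 1)}.
#'
#' @param de_sets List of character vectors (one per model), each a subset of
#'   \code{universe}.
#' @param universe Character vector of annotation-universe gene ids.
#' @param k_values Overlap thresholds to test (default \code{c(2, 3)}).
#' @param n_perm Number of permutations (>= 99; default 9999).
#' @param seed Integer seed for the resampling.
#' @return An object of class \code{overlap_test}: list with \code{observed}
#'   (named counts per k), \code{p} (named empirical p per k), \code{n_perm},
#'   and \code{null_quantiles}.
#' @examples
#' u <- paste0("g", 1:50)
#' sets <- replicate(4, u[1:20], simplify = FALSE)
#' overlap_permutation_test(sets, u, n_perm = 99, seed = 1)$p
#' @export
overlap_permutation_test <- function(de_sets, universe, k_values = c(2L, 3L),
                                     n_perm = 9999L, seed = 1L) {
  n_perm <- assert_count(n_perm, "n_perm", min = 99L)
  if (!length(de_sets)) stop("'de_sets' must be non-empty", call. = FALSE)
  universe <- unique(as.character(universe))
  nu <- length(universe)
  sizes <- lengths(de_sets)
  if (any(sizes > nu)) {
    stop("a DE set is larger than the universe", call. = FALSE)
  }
  extra <- setdiff(unlist(de_sets), universe)
  if (length(extra)) {
    stop("DE sets must be subsets of the universe (offending: ",
         paste(utils::head(extra, 3), collapse = ", "), ")", call. = FALSE)
  }
  k_values <- sort(unique(as.integer(k_values)))
  count_ge <- function(membership_counts) {
    vapply(k_values, function(k) sum(membership_counts >= k), integer(1))
  }
  obs_counts <- tabulate(match(unlist(de_sets), universe), nbins = nu)
  observed <- count_ge(obs_counts)
  names(observed) <- paste0("k", k_values)
  null_mat <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      counts <- tabulate(
        unlist(lapply(sizes, function(s) sample.int(nu, s))), nbins = nu)
      count_ge(counts)
    }, integer(length(k_values)))
  })
  null_mat <- matrix(null_mat, nrow = length(k_values))
  p <- vapply(seq_along(k_values), function(j) {
    (1 + sum(null_mat[j, ] >= observed[j])) / (n_perm + 1)
  }, numeric(1))
  names(p) <- names(observed)
  qs <- t(apply(null_mat, 1, stats::quantile,
                probs = c(0.025, 0.5, 0.975)))
  rownames(qs) <- names(observed)
  structure(list(observed = observed, p = p, n_perm = n_perm,
                 k_values = k_values, null_quantiles = qs,
                 universe_size = nu, set_sizes = sizes),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("<overlap_test> %d sets over a universe of %d genes, %d perms\n",
              length(x$set_sizes), x$universe_size, x$n_perm))
  for (j in seq_along(x$k_values)) {
    cat(sprintf("  DE in >= %d models: observed %d, empirical p = %.4g\n",
                x$k_values[j], x$observed[j], x$p[j]))
  }
  invisible(x)
}

#' Score-based enrichment of a gene set (one-sided t-test)
#'
#' Compares a user-supplied per-gene score between members and non-members
#' of a gene set with a one-sided Welch t-test (alternative: members
#' greater).  Provided for set-level enrichment of quantities such as
#' network connectivity; the score to compare is deliberately left to the
#' caller.
#'
#' @param scores Named numeric vector (gene -> score).
#' @param set Character vector of member gene ids.
#' @return List with \code{t}, \code{p}, \code{mean_in}, \code{mean_out},
#'   \code{n_in}, \code{n_out}.
#' @export
set_score_ttest <- function(scores, set) {
  inside <- scores[names(scores) %in% set]
  outside <- scores[!names(scores) %in% set]
  if (length(inside) < 2L || length(outside) < 2L) {
    stop("need at least 2 genes inside and outside the set", call. = FALSE)
  }
  tt <- stats::t.test(inside, outside, alternative = "greater")
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_in = mean(inside), mean_out = mean(outside),
       n_in = length(inside), n_out = length(outside))
}
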