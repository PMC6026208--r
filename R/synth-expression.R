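#' Define ground truth for a synthetic multi-model expression study
#'
#' Describes a panel of RNAi knockdown models profiled against a common
#' control: per-model differential-expression tables (gene, log2 fold-change,
#' FDR) with planted enriched gene sets, a planted ~50% knockdown of each
#' model's target gene (log2FC near -1), and a controllable fraction of
#' differentially expressed (DE) genes shared across all models.
#'
#' @param n_genes Number of measured genes.
#' @param n_models Number of knockdown models.
#' @param planted_terms List of planted enriched sets, each a list with
#'   elements \code{term} (id), \code{genes} (member identifiers, subset of
#'   the gene universe), and \code{shift} (log2FC offset added to members in
#'   every model).  Term sizes must be below 500 (larger terms are the
#'   "very general" ones the enrichment stage excludes).
#' @param knockdown_lfc log2 fold-change assigned to each model's own target
#'   gene.  The default -1.05 models the roughly 50% transcript reduction
#'   RNAi achieves while remaining past the strict |log2FC| > 1 DE cut.
#' @param null_logfc_sd SD of the null log2FC distribution.
#' @param shared_de_fraction Fraction of each model's DE genes drawn from a
#'   pool common to all models.
#' @param n_de_per_model Number of DE genes planted per model.
#' @param seed Integer seed.
#' @return An object of class \code{expression_truth}.
#' @export
expression_truth <- function(n_genes = 2000L, n_models = 6L,
                             planted_terms = list(), knockdown_lfc = -1.05,
                             null_logfc_sd = 0.5, shared_de_fraction = 0,
                             n_de_per_model = 200L, seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes", min = 10L)
  n_models <- assert_count(n_models, "n_models")
  assert_fraction(shared_de_fraction, "shared_de_fraction")
  n_de_per_model <- assert_count(n_de_per_model, "n_de_per_model", min = 0L)
  for (tm in planted_terms) {
    if (!all(c("term", "genes", "shift") %in% names(tm))) {
      stop("each planted term needs elements 'term', 'genes', 'shift'",
           call. = FALSE)
    }
    if (length(tm$genes) >= 500L) {
      stop(sprintf("planted term '%s' has %d genes; sizes must be < 500",
                   tm$term, length(tm$genes)), call. = FALSE)
    }
    if (length(tm$genes) > n_genes) {
      stop(sprintf("planted term '%s' is larger than the gene universe",
                   tm$term), call. = FALSE)
    }
  }
  structure(list(n_genes = n_genes, n_models = n_models,
                 planted_terms = planted_terms,
                 knockdown_lfc = knockdown_lfc,
                 null_logfc_sd = null_logfc_sd,
                 shared_de_fraction = shared_de_fraction,
                 n_de_per_model = n_de_per_model, seed = as.integer(seed)),
            class = "expression_truth")
}

#' Generate a synthetic multi-model differential-expression study
#'
#' Produces one DE table per knockdown model over a shared gene universe
#' \code{g0001 ... gN}.  Null genes get log2FC ~ N(0, null_logfc_sd) and an
#' FDR drawn above 0.05; planted DE genes get |log2FC| between 1.2 and 3
#' (random sign) and FDR below 0.05; planted-term members get the term's
#' shift added to their log2FC in every model (FDR lowered below 0.05 when
#' the shifted value passes the fold-change cut); each model's own target
#' gene is set to \code{knockdown_lfc} with FDR 0.01.  FDR values are
#' assigned, not fitted: DE model fitting is upstream of this pipeline, which
#' consumes its tabular output.
#'
#' @param truth An [expression_truth()].
#' @return A list with components \code{models} (named list of data frames
#'   \code{gene}, \code{log2FC}, \code{FDR}), \code{sets} (named list of
#'   planted-term gene vectors, GMT-compatible), \code{knockdown_genes}
#'   (named character vector, one target per model), and \code{truth}.
#' @examples
#' study <- generate_expression_study(expression_truth(n_genes = 500,
#'                                                     n_models = 3))
#' head(study$models[[1]])
#' @export
generate_expression_study <- function(truth) {
  if (!inherits(truth, "expression_truth")) {
    stop("'truth' must be an expression_truth", call. = FALSE)
  }
  genes <- sprintf("g%04d", seq_len(truth$n_genes))
  model_ids <- sprintf("model%02d", seq_len(truth$n_models))
  with_seed(truth$seed, {
    knockdown <- sample(genes, truth$n_models)
    names(knockdown) <- model_ids
    n_shared <- round(truth$shared_de_fraction * truth$n_de_per_model)
    shared_pool <- if (n_shared > 0) sample(genes, n_shared) else character(0)
    models <- lapply(model_ids, function(mid) {
      lfc <- rnorm(truth$n_genes, 0, truth$null_logfc_sd)
      fdr <- runif(truth$n_genes, 0.05, 1)
      names(lfc) <- names(fdr) <- genes
      n_extra <- truth$n_de_per_model - n_shared
      extra <- if (n_extra > 0) {
        sample(setdiff(genes, shared_pool), n_extra)
      } else {
        character(0)
      }
      de <- c(shared_pool, extra)
      if (length(de)) {
        lfc[de] <- sample(c(-1, 1), length(de), replace = TRUE) *
          runif(length(de), 1.2, 3)
        fdr[de] <- runif(length(de), 0, 0.049)
      }
      for (tm in truth$planted_terms) {
        lfc[tm$genes] <- lfc[tm$genes] + tm$shift
        hit <- tm$genes[abs(lfc[tm$genes]) > 1]
        fdr[hit] <- pmin(fdr[hit], runif(length(hit), 0, 0.049))
      }
      kd <- knockdown[[mid]]
      lfc[kd] <- truth$knockdown_lfc
      fdr[kd] <- 0.01
      data.frame(gene = genes, log2FC = unname(lfc), FDR = unname(fdr))
    })
    names(models) <- model_ids
    sets <- lapply(truth$planted_terms, `[[`, "genes")
    names(sets) <- vapply(truth$planted_terms, `[[`, "", "term")
    list(models = models, sets = sets, knockdown_genes = knockdown,
         truth = truth)
  })
}
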