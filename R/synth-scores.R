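#' Define a planted two-hit genetic interaction
#'
#' Describes the ground truth for one gene pair in a synthetic modifier
#' screen.  The four genotypes of the 2 x 2 knockdown design (control, A
#' one-hit, B one-hit, A+B two-hit) get cell means
#' \code{control_mean}, \code{+effect_a}, \code{+effect_b}, and
#' \code{+effect_a+effect_b+interaction_shift} respectively, so
#' \code{interaction_shift} is the planted interaction contrast
#' (mean(AB) - mean(A)) - (mean(B) - mean(control)).
#'
#' @param gene_a,gene_b Gene identifiers.
#' @param class_label One of \code{"none"}, \code{"additive"},
#'   \code{"suppressor"}, \code{"enhancer"}, \code{"full_rescue"}.
#' @param effect_a,effect_b One-hit severity shifts versus control (score
#'   units; positive = more severe).
#' @param interaction_shift Planted interaction contrast.  Must be negative
#'   for suppressors, positive for enhancers, and zero for additive/none.
#'   Ignored for \code{"full_rescue"}, where the two-hit mean is pinned at the
#'   control mean.
#' @param within_sd Within-genotype replicate SD (score units), > 0.
#' @param n_replicates Replicates per genotype, >= 2.
#' @return An object of class \code{interaction_truth}.
#' @export
interaction_truth <- function(gene_a, gene_b,
                              class_label = c("none", "additive", "suppressor",
                                              "enhancer", "full_rescue"),
                              effect_a = 0, effect_b = 0,
                              interaction_shift = 0, within_sd = 1,
                              n_replicates = 12L) {
  class_label <- match.arg(class_label)
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 2L)
  if (!is.numeric(within_sd) || within_sd <= 0) {
    stop("'within_sd' must be > 0", call. = FALSE)
  }
  ok <- switch(class_label,
               suppressor = interaction_shift < 0,
               enhancer   = interaction_shift > 0,
               additive   = interaction_shift == 0,
               none       = interaction_shift == 0,
               full_rescue = TRUE)
  if (!ok) {
    stop(sprintf("interaction_shift = %g is inconsistent with class '%s'",
                 interaction_shift, class_label), call. = FALSE)
  }
  structure(list(gene_a = as.character(gene_a), gene_b = as.character(gene_b),
                 class_label = class_label, effect_a = effect_a,
                 effect_b = effect_b, interaction_shift = interaction_shift,
                 within_sd = within_sd, n_replicates = n_replicates),
            class = "interaction_truth")
}

#' Simulate a replicate score table for planted interactions
#'
#' Emits, for each planted pair, Gaussian replicate severity scores for the
#' four genotypes of the two-hit design.  For \code{full_rescue} truths the
#' two-hit cell mean equals \code{control_mean} regardless of the one-hit
#' effects (the modifier returns the phenotype to control level).
#'
#' @param truths A list of [interaction_truth()] objects (non-empty).
#' @param control_mean Mean severity score of the control genotype.
#' @param seed Integer seed; one child stream per pair, so adding a pair never
#'   perturbs the scores of the others.
#' @return A score table: data frame with columns \code{pair_id},
#'   \code{gene_a}, \code{gene_b}, \code{genotype} (one of \code{control},
#'   \code{A}, \code{B}, \code{AB}), \code{replicate}, \code{score}.
#' @examples
#' tr <- interaction_truth("rl", "cox6AL", "suppressor", effect_a = 10,
#'                         interaction_shift = -8)
#' head(generate_score_table(list(tr), control_mean = 20, seed = 1))
#' @export
generate_score_table <- function(truths, control_mean = 20, seed = 1L) {
  if (!length(truths)) stop("'truths' must be non-empty", call. = FALSE)
  if (inherits(truths, "interaction_truth")) truths <- list(truths)
  rows <- lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    if (!inherits(tr, "interaction_truth")) {
      stop("all elements of 'truths' must be interaction_truth objects",
           call. = FALSE)
    }
    ab_mean <- if (tr$class_label == "full_rescue") {
      control_mean
    } else {
      control_mean + tr$effect_a + tr$effect_b + tr$interaction_shift
    }
    means <- c(control = control_mean,
               A = control_mean + tr$effect_a,
               B = control_mean + tr$effect_b,
               AB = ab_mean)
    n <- tr$n_replicates
    pair_id <- paste0(tr$gene_a, ":", tr$gene_b)
    scores <- with_seed(child_seed(seed, pair_id), {
      rnorm(4L * n, mean = rep(means, each = n), sd = tr$within_sd)
    })
    data.frame(pair_id = pair_id, gene_a = tr$gene_a, gene_b = tr$gene_b,
               genotype = rep(names(means), each = n),
               replicate = rep(seq_len(n), times = 4L),
               score = scores)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
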