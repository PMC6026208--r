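#' Two-way ANOVA for a one-pair two-hit design
#'
#' Decomposes replicate severity scores for the four genotypes of a two-hit
#' knockdown experiment (control, A one-hit, B one-hit, A+B two-hit) into
#' main effects of knocking down A and B and their interaction — the 2 x 2
#' factorial with one degree of freedom per effect.  Balanced designs use the
#' classical cell-mean decomposition; unbalanced designs use type-II sums of
#' squares (no a-priori ordering of the two factors).
#'
#' @param table Data frame with columns \code{genotype} (values
#'   \code{control}, \code{A}, \code{B}, \code{AB}) and \code{score}, the
#'   rows of one gene pair.  All four genotypes must be present and the
#'   residual degrees of freedom positive.
#' @return An object of class \code{anova_result}: data frame \code{effects}
#'   with one row per effect (\code{A}, \code{B}, \code{A:B}) giving
#'   \code{SS}, \code{df}, \code{F}, \code{p}; plus \code{residual_ss},
#'   \code{residual_df}, \code{balanced}, and \code{f_undefined} (TRUE when
#'   the residual variance is zero, in which case F and p are NA).
#' @examples
#' tab <- data.frame(genotype = rep(c("control", "A", "B", "AB"), each = 2),
#'                   score = c(10, 12, 20, 22, 14, 16, 24, 26))
#' two_way_anova(tab)
#' @export
two_way_anova <- function(table) {
  table <- as.data.frame(table)
  assert_columns(table, c("genotype", "score"), "score table")
  genos <- c("control", "A", "B", "AB")
  missing <- setdiff(genos, unique(table$genotype))
  if (length(missing)) {
    stop("missing genotype cell(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(table$score))) {
    stop("scores must be finite", call. = FALSE)
  }
  table <- table[table$genotype %in% genos, , drop = FALSE]
  kA <- table$genotype %in% c("A", "AB")
  kB <- table$genotype %in% c("B", "AB")
  n_cell <- table(factor(table$genotype, levels = genos))
  N <- nrow(table)
  df_res <- N - 4L
  if (df_res < 1L) {
    stop("need residual degrees of freedom: at least 5 observations over ",
         "the four genotypes (>= 2 replicates somewhere)", call. = FALSE)
  }
  balanced <- length(unique(n_cell)) == 1L
  y <- table$score
  if (balanced) {
    n <- unname(n_cell[1])
    gm <- mean(y)
    mA <- tapply(y, kA, mean)            # FALSE, TRUE margins
    mB <- tapply(y, kB, mean)
    cellm <- tapply(y, list(kA, kB), mean)
    ss_a <- 2 * n * sum((mA - gm)^2)
    ss_b <- 2 * n * sum((mB - gm)^2)
    ss_ab <- n * sum((cellm - outer(mA, rep(1, 2)) -
                        outer(rep(1, 2), mB) + gm)^2)
    fitted <- cellm[cbind(as.character(kA), as.character(kB))]
    ss_res <- sum((y - fitted)^2)
    ss <- c(A = ss_a, B = ss_b, `A:B` = ss_ab)
  } else {
    fit <- stats::lm(y ~ kA * kB)
    a2 <- car::Anova(fit, type = 2)
    ss <- c(A = a2["kA", "Sum Sq"], B = a2["kB", "Sum Sq"],
            `A:B` = a2["kA:kB", "Sum Sq"])
    ss_res <- a2["Residuals", "Sum Sq"]
  }
  f_undefined <- ss_res <= max(1e-12, 1e-10 * sum(y^2))
  ms_res <- ss_res / df_res
  fstat <- if (f_undefined) rep(NA_real_, 3) else ss / ms_res
  pval <- stats::pf(fstat, 1, df_res, lower.tail = FALSE)
  structure(list(effects = data.frame(effect = names(ss), SS = unname(ss),
                                      df = 1L, F = unname(fstat),
                                      p = unname(pval)),
                 residual_ss = ss_res, residual_df = df_res,
                 balanced = balanced, f_undefined = f_undefined),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s design, residual df = %d%s\n",
              if (x$balanced) "balanced" else "unbalanced", x$residual_df,
              if (x$f_undefined) " (zero residual variance; F undefined)"
              else ""))
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Interaction contrast of a two-hit design
#'
#' Computes the change in mean phenotype caused by adding the B knockdown in
#' each background: \code{delta1 = mean(AB) - mean(A)} (effect of B on the A
#' background) and \code{delta2 = mean(B) - mean(control)} (effect of B on
#' wild type).  Their difference is the 2 x 2 interaction contrast; it is
#' zero when the two genes act additively, negative when B suppresses the A
#' phenotype, positive when it enhances it, and symmetric under swapping the
#' roles of A and B.
#'
#' @inheritParams two_way_anova
#' @return List with \code{delta1}, \code{delta2}, \code{contrast}.
#' @export
interaction_contrast <- function(table) {
  table <- as.data.frame(table)
  assert_columns(table, c("genotype", "score"), "score table")
  genos <- c("control", "A", "B", "AB")
  missing <- setdiff(genos, unique(table$genotype))
  if (length(missing)) {
    stop("missing genotype cell(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- tapply(table$score, factor(table$genotype, levels = genos), mean)
  d1 <- unname(m["AB"] - m["A"])
  d2 <- unname(m["B"] - m["control"])
  list(delta1 = d1, delta2 = d2, contrast = d1 - d2)
}

#' Classify a two-hit genetic interaction
#'
#' Applies the decision model of a two-hit modifier screen: if the two-way
#' ANOVA interaction term is significant, the pair is a \code{suppressor}
#' (negative interaction contrast: the two-hit phenotype is less severe than
#' the additive expectation) or \code{enhancer} (positive contrast); if only
#' the B main effect is significant the genes act \code{additive}ly (B shifts
#' the phenotype equally in both backgrounds); otherwise \code{none}.
#' Suppressors are additionally flagged \code{full_rescue} when the two-hit
#' eye is statistically indistinguishable from control (Mann-Whitney,
#' p >= \code{rescue_alpha}) while the A one-hit differs from control.
#'
#' Higher score = more severe phenotype; the suppressor/enhancer directions
#' depend on this convention and flip if scores are negated.
#'
#' @inheritParams two_way_anova
#' @param alpha Significance level for the ANOVA interaction and main-effect
#'   tests (per-pair, df = 1).
#' @param rescue_alpha Significance level of the Mann-Whitney rescue checks.
#' @param alternative Alternative hypothesis for the Mann-Whitney
#'   comparisons (default two-sided).
#' @return An object of class \code{interaction_call}: list with
#'   \code{delta1}, \code{delta2}, \code{contrast}, \code{class},
#'   \code{full_rescue}, supporting p-values (\code{p_interaction},
#'   \code{p_b_main}, \code{p_ab_vs_control}, \code{p_a_vs_control}),
#'   \code{F_interaction}, and the underlying \code{anova} result.
#' @examples
#' tr <- interaction_truth("rl", "cox6AL", "suppressor", effect_a = 10,
#'                         interaction_shift = -8, within_sd = 1)
#' tab <- generate_score_table(list(tr), control_mean = 20, seed = 3)
#' classify_interaction(tab)$class
#' @export
classify_interaction <- function(table, alpha = 0.05, rescue_alpha = 0.05,
                                 alternative = "two.sided") {
  table <- as.data.frame(table)
  an <- two_way_anova(table)
  ct <- interaction_contrast(table)
  p_int <- an$effects$p[an$effects$effect == "A:B"]
  p_b <- an$effects$p[an$effects$effect == "B"]
  cls <- if (!is.na(p_int) && p_int < alpha) {
    if (ct$contrast < 0) "suppressor" else "enhancer"
  } else if (!is.na(p_b) && p_b < alpha) {
    "additive"
  } else {
    "none"
  }
  sc <- function(g) table$score[table$genotype == g]
  mw <- function(g1, g2) {
    suppressWarnings(stats::wilcox.test(sc(g1), sc(g2),
                                        alternative = alternative,
                                        exact = FALSE)$p.value)
  }
  p_ab_ctl <- mw("AB", "control")
  p_a_ctl <- mw("A", "control")
  full_rescue <- cls == "suppressor" && !is.na(p_ab_ctl) &&
    p_ab_ctl >= rescue_alpha && !is.na(p_a_ctl) && p_a_ctl < rescue_alpha
  structure(list(pair_id = if ("pair_id" %in% names(table))
                   table$pair_id[1] else NA_character_,
                 delta1 = ct$delta1, delta2 = ct$delta2,
                 contrast = ct$contrast, class = cls,
                 full_rescue = full_rescue,
                 p_interaction = p_int, p_b_main = p_b,
                 p_ab_vs_control = p_ab_ctl, p_a_vs_control = p_a_ctl,
                 F_interaction = an$effects$F[an$effects$effect == "A:B"],
                 anova = an),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf(
    "<interaction_call> %s: %s%s (contrast = %.3f, F = %.3f, p = %.3g)\n",
    x$pair_id %||% "pair", x$class,
    if (x$full_rescue) " [full rescue]" else "",
    x$contrast, x$F_interaction, x$p_interaction))
  invisible(x)
}

#' Screen many gene pairs for two-hit interactions
#'
#' Runs [classify_interaction()] over every pair in a score table, collects
#' the calls, and exports a heatmap matrix of \code{delta1} values (the
#' change in phenotype of each A-background when each B modifier is added).
#' Per-pair failures are recorded and the screen continues.
#'
#' @param score_table Data frame with columns \code{pair_id}, \code{gene_a},
#'   \code{gene_b}, \code{genotype}, \code{score} (as produced by
#'   [generate_score_table()] or [score_batch()] aggregation).
#' @param alpha,rescue_alpha,alternative Passed to [classify_interaction()].
#' @param multiple_testing \code{"none"} (default: per-pair tests, matching
#'   screens validated by independent RNAi lines) or \code{"BH"} to apply
#'   Benjamini-Hochberg across the interaction p-values before classifying.
#' @return An object of class \code{interaction_screen}: list with
#'   \code{calls} (one row per pair: class, deltas, contrast, F, p-values,
#'   full_rescue), \code{heatmap} (gene_a x gene_b matrix of delta1), and
#'   \code{failures}.
#' @export
screen_interactions <- function(score_table, alpha = 0.05,
                                rescue_alpha = 0.05,
                                multiple_testing = c("none", "BH"),
                                alternative = "two.sided") {
  multiple_testing <- match.arg(multiple_testing)
  score_table <- as.data.frame(score_table)
  assert_columns(score_table,
                 c("pair_id", "gene_a", "gene_b", "genotype", "score"),
                 "score table")
  pairs <- unique(score_table$pair_id)
  if (!length(pairs)) stop("empty pair list", call. = FALSE)
  calls <- list()
  failures <- data.frame(pair_id = character(0), reason = character(0))
  for (pid in pairs) {
    sub <- score_table[score_table$pair_id == pid, , drop = FALSE]
    res <- tryCatch(classify_interaction(sub, alpha, rescue_alpha,
                                         alternative),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(pair_id = pid,
                                   reason = conditionMessage(res)))
      next
    }
    calls[[pid]] <- data.frame(pair_id = pid, gene_a = sub$gene_a[1],
                               gene_b = sub$gene_b[1],
                               delta1 = res$delta1, delta2 = res$delta2,
                               contrast = res$contrast, class = res$class,
                               full_rescue = res$full_rescue,
                               F_interaction = res$F_interaction,
                               p_interaction = res$p_interaction,
                               p_b_main = res$p_b_main,
                               p_ab_vs_control = res$p_ab_vs_control)
  }
  calls <- do.call(rbind, calls)
  if (!is.null(calls)) rownames(calls) <- NULL
  if (!is.null(calls) && multiple_testing == "BH") {
    calls$p_interaction_adj <- bh_adjust(calls$p_interaction)
    # reclassify with the adjusted interaction p-values
    for (i in seq_len(nrow(calls))) {
      p_int <- calls$p_interaction_adj[i]
      calls$class[i] <- if (!is.na(p_int) && p_int < alpha) {
        if (calls$contrast[i] < 0) "suppressor" else "enhancer"
      } else if (!is.na(calls$p_b_main[i]) && calls$p_b_main[i] < alpha) {
        "additive"
      } else {
        "none"
      }
      if (calls$class[i] != "suppressor") calls$full_rescue[i] <- FALSE
    }
  }
  heat <- NULL
  if (!is.null(calls)) {
    ga <- sort(unique(calls$gene_a)); gb <- sort(unique(calls$gene_b))
    heat <- matrix(NA_real_, length(ga), length(gb),
                   dimnames = list(ga, gb))
    for (i in seq_len(nrow(calls))) {
      heat[calls$gene_a[i], calls$gene_b[i]] <- calls$delta1[i]
    }
  }
  structure(list(calls = calls, heatmap = heat, failures = failures,
                 alpha = alpha, multiple_testing = multiple_testing),
            class = "interaction_screen")
}

#' @export
print.interaction_screen <- function(x, ...) {
  n <- if (is.null(x$calls)) 0L else nrow(x$calls)
  cat(sprintf("<interaction_screen> %d pairs called, %d failed (alpha = %g)\n",
              n, nrow(x$failures), x$alpha))
  if (n) print(table(x$calls$class))
  invisible(x)
}
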