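test_that("a perfectly additive table has zero interaction sum of squares", {
  tab <- data.frame(genotype = rep(c("control", "A", "B", "AB"), each = 2),
                    score = c(10, 12, 20, 22, 14, 16, 24, 26))
  an <- two_way_anova(tab)
  eff <- an$effects
  expect_equal(eff$SS[eff$effect == "A:B"], 0, tolerance = 1e-12)
  expect_equal(eff$F[eff$effect == "A:B"], 0, tolerance = 1e-12)
  expect_equal(eff$p[eff$effect == "A:B"], 1)
  expect_true(an$balanced)
  expect_equal(interaction_contrast(tab)$contrast, 0)
})

test_that("ANOVA matches the least-squares decomposition oracle", {
  set.seed(21)
  for (rep in 1:50) {
    balanced <- rep %% 2 == 0
    n_cell <- if (balanced) rep(sample(2:6, 1), 4) else sample(2:6, 4,
                                                               replace = TRUE)
    tab <- random_pair_table(n_cell)
    got <- two_way_anova(tab)
    exp <- oracle_anova(tab)
    expect_equal(got$effects$F, unname(exp$F), tolerance = 1e-6)
    expect_equal(got$effects$p, unname(exp$p), tolerance = 1e-6)
    expect_equal(got$residual_ss, exp$residual_ss, tolerance = 1e-8)
  }
})

test_that("degenerate identical observations flag an undefined F", {
  tab <- data.frame(genotype = rep(c("control", "A", "B", "AB"), each = 2),
                    score = rep(5, 8))
  an <- two_way_anova(tab)
  expect_true(an$f_undefined)
  expect_true(all(an$effects$SS == 0))
  expect_true(all(is.na(an$effects$F)))
})

test_that("missing genotype cells are rejected by name", {
  tab <- data.frame(genotype = rep(c("control", "A", "B"), each = 3),
                    score = rnorm(9))
  expect_error(two_way_anova(tab), "AB")
  expect_error(interaction_contrast(tab), "AB")
})

test_that("the interaction contrast is symmetric in the two genes", {
  set.seed(5)
  tab <- random_pair_table(c(3, 4, 5, 3))
  swapped <- tab
  swapped$genotype <- c(control = "control", A = "B", B = "A",
                        AB = "AB")[tab$genotype]
  expect_equal(interaction_contrast(tab)$contrast,
               interaction_contrast(swapped)$contrast, tolerance = 1e-12)
  # stated-means example: {control 10; A 20; B 10; AB 12}
  tab2 <- data.frame(genotype = c("control", "A", "B", "AB"),
                     score = c(10, 20, 10, 12))
  ct <- interaction_contrast(tab2)
  expect_equal(ct$delta1, -8)
  expect_equal(ct$delta2, 0)
  expect_equal(ct$contrast, -8)
})

test_that("planted interaction classes are recovered", {
  mk <- function(cls, shift) {
    interaction_truth("a", "b", cls, effect_a = 9, effect_b = 6,
                      interaction_shift = shift, within_sd = 2,
                      n_replicates = 12L)
  }
  # strong planted effects, tested at alpha = 0.01 so each call is
  # essentially deterministic (per-class recovery ~99% at these settings)
  tab_sup <- generate_score_table(list(mk("suppressor", -8)), 20, seed = 1)
  expect_equal(classify_interaction(tab_sup, alpha = 0.01)$class,
               "suppressor")
  tab_enh <- generate_score_table(list(mk("enhancer", 8)), 20, seed = 2)
  expect_equal(classify_interaction(tab_enh, alpha = 0.01)$class, "enhancer")
  tab_add <- generate_score_table(list(mk("additive", 0)), 20, seed = 3)
  expect_equal(classify_interaction(tab_add, alpha = 0.01)$class, "additive")
  tab_non <- generate_score_table(list(
    interaction_truth("a", "b", "none", within_sd = 2,
                      n_replicates = 12L)), 20, seed = 4)
  expect_equal(classify_interaction(tab_non, alpha = 0.01)$class, "none")
})

test_that("full rescue is flagged when the two-hit eye returns to control", {
  tr <- interaction_truth("a", "b", "full_rescue", effect_a = 10,
                          within_sd = 1, n_replicates = 12L)
  tab <- generate_score_table(list(tr), 20, seed = 6)
  call <- classify_interaction(tab)
  expect_equal(call$class, "suppressor")
  expect_true(call$full_rescue)
  # a plain suppressor that still differs from control is not a full rescue
  tr2 <- interaction_truth("a", "b", "suppressor", effect_a = 10,
                           interaction_shift = -5, within_sd = 1,
                           n_replicates = 12L)
  call2 <- classify_interaction(generate_score_table(list(tr2), 20, seed = 7))
  expect_equal(call2$class, "suppressor")
  expect_false(call2$full_rescue)
})

test_that("classification is invariant to shift/scale and flips under negation", {
  tr <- interaction_truth("a", "b", "suppressor", effect_a = 9, effect_b = 6,
                          interaction_shift = -8, within_sd = 2,
                          n_replicates = 12L)
  tab <- generate_score_table(list(tr), 20, seed = 8)
  base <- classify_interaction(tab)
  shifted <- tab; shifted$score <- shifted$score + 100
  scaled <- tab; scaled$score <- scaled$score * 3.5
  negated <- tab; negated$score <- -negated$score
  expect_equal(classify_interaction(shifted)$class, base$class)
  expect_equal(classify_interaction(scaled)$class, base$class)
  expect_equal(classify_interaction(shifted)$p_interaction,
               base$p_interaction, tolerance = 1e-9)
  expect_equal(classify_interaction(negated)$class, "enhancer")
})

test_that("the interaction test holds its size under the additive null", {
  set.seed(31)
  n_sim <- 400
  rej <- vapply(seq_len(n_sim), function(i) {
    tab <- generate_score_table(list(
      interaction_truth("a", "b", "additive", effect_a = 9, effect_b = 6,
                        within_sd = 2, n_replicates = 6L)), 20,
      seed = 40000 + i)
    an <- two_way_anova(tab)
    an$effects$p[an$effects$effect == "A:B"] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("screening many pairs recovers classes and exports the heatmap", {
  classes <- rep(c("none", "additive", "suppressor", "enhancer"), each = 10)
  truths <- lapply(seq_along(classes), function(i) {
    interaction_truth(sprintf("A%02d", i), sprintf("B%02d", i), classes[i],
                      effect_a = 9,
                      effect_b = if (classes[i] == "none") 0 else 6,
                      interaction_shift = switch(classes[i],
                                                 suppressor = -8,
                                                 enhancer = 8, 0),
                      within_sd = 2, n_replicates = 12L)
  })
  tab <- generate_score_table(truths, 20, seed = 12)
  scr <- screen_interactions(tab)
  expect_equal(nrow(scr$calls), 40L)
  expect_gte(mean(scr$calls$class == classes), 0.9)
  expect_equal(dim(scr$heatmap), c(40L, 40L))
  expect_equal(scr$heatmap["A01", "B01"], scr$calls$delta1[1])
  # deterministic and failure-tolerant
  expect_identical(scr$calls, screen_interactions(tab)$calls)
  broken <- tab[tab$genotype != "AB" | tab$pair_id != tab$pair_id[1], ]
  scr2 <- screen_interactions(broken)
  expect_equal(nrow(scr2$failures), 1L)
  expect_equal(nrow(scr2$calls), 39L)
  expect_error(screen_interactions(tab[0, ]), "empty")
})

test_that("BH across the screen can only make interaction calls more conservative", {
  classes <- rep(c("suppressor", "none"), each = 4)
  truths <- lapply(seq_along(classes), function(i) {
    interaction_truth(sprintf("A%02d", i), sprintf("B%02d", i), classes[i],
                      effect_a = 9,
                      interaction_shift = if (classes[i] == "suppressor") -8
                                          else 0,
                      within_sd = 2, n_replicates = 12L)
  })
  tab <- generate_score_table(truths, 20, seed = 13)
  plain <- screen_interactions(tab)
  bh <- screen_interactions(tab, multiple_testing = "BH")
  expect_true(all(bh$calls$p_interaction_adj >= bh$calls$p_interaction))
  sig_plain <- plain$calls$class %in% c("suppressor", "enhancer")
  sig_bh <- bh$calls$class %in% c("suppressor", "enhancer")
  expect_true(all(!sig_bh | sig_plain))
})
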