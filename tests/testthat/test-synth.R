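test_that("noise-free lattice has exactly n_rows * n_cols centres in offset rows", {
  out <- generate_eye_image(lattice_spec(n_rows = 20, n_cols = 20,
                                         spacing = 10, seed = 1))
  expect_equal(nrow(out$centers), 400L)
  # offset geometry: row pitch spacing * sqrt(3)/2, odd rows shifted
  ys <- sort(unique(round(out$centers$y, 6)))
  expect_equal(length(ys), 20L)
  expect_equal(diff(ys), rep(10 * sqrt(3) / 2, 19), tolerance = 1e-5)
  row1 <- sort(out$centers$x[round(out$centers$y, 6) == ys[1]])
  row2 <- sort(out$centers$x[round(out$centers$y, 6) == ys[2]])
  expect_equal(row2 - row1, rep(5, 20), tolerance = 1e-9)
})

test_that("dropout is binomial and identical seeds give identical images", {
  spec <- lattice_spec(n_rows = 20, n_cols = 20, spacing = 10,
                       dropout_rate = 0.05, seed = 99)
  a <- generate_eye_image(spec)
  b <- generate_eye_image(spec)
  expect_lt(nrow(a$centers), 400L)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$centers, b$centers)
  # different seed, different draw
  c <- generate_eye_image(lattice_spec(n_rows = 20, n_cols = 20, spacing = 10,
                                       dropout_rate = 0.05, seed = 100))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("injected jitter has sample SD close to sigma per axis", {
  ideal <- generate_eye_image(lattice_spec(n_rows = 20, n_cols = 20,
                                           spacing = 10, seed = 5))$centers
  jit <- generate_eye_image(lattice_spec(n_rows = 20, n_cols = 20,
                                         spacing = 10, jitter_sigma = 3,
                                         seed = 5))$centers
  dx <- jit$x - ideal$x
  dy <- jit$y - ideal$y
  expect_lt(abs(sd(dx) - 3) / 3, 0.10)
  expect_lt(abs(sd(dy) - 3) / 3, 0.10)
})

test_that("fusion replaces pairs by midpoints and reduces the centre count", {
  spec <- lattice_spec(n_rows = 10, n_cols = 10, spacing = 10,
                       fusion_rate = 0.2, seed = 3)
  out <- generate_eye_image(spec)
  expect_lt(nrow(out$centers), 100L)
  # forced fusion of a two-site lattice: one blob at the exact midpoint
  two <- generate_eye_image(lattice_spec(n_rows = 1, n_cols = 2,
                                         spacing = 10, fusion_rate = 1,
                                         seed = 8))
  ideal <- generate_eye_image(lattice_spec(n_rows = 1, n_cols = 2,
                                           spacing = 10, seed = 8))$centers
  expect_equal(nrow(two$centers), 1L)
  expect_equal(two$centers$x, mean(ideal$x))
  expect_equal(two$centers$y, mean(ideal$y))
})

test_that("image intensities stay inside the declared [0, 1] range", {
  out <- generate_eye_image(lattice_spec(n_rows = 8, n_cols = 8, spacing = 8,
                                         ommatidium_radius = 3,
                                         background_noise_sd = 0.3, seed = 2))
  expect_gte(min(out$image$pixels), 0)
  expect_lte(max(out$image$pixels), 1)
})

test_that("lattice_spec rejects invalid geometry and rates", {
  expect_error(lattice_spec(n_rows = 0), "n_rows")
  expect_error(lattice_spec(spacing = -1), "spacing")
  expect_error(lattice_spec(dropout_rate = 1.5), "dropout_rate")
  expect_error(lattice_spec(jitter_sigma = -1), "jitter_sigma")
  expect_error(lattice_spec(spacing = 2, ommatidium_radius = 3), "spacing")
})

test_that("score table cell means follow the planted interaction model", {
  # additive: two-hit mean = control + effect_a + effect_b
  tr_add <- interaction_truth("a", "b", "additive", effect_a = 10,
                              effect_b = 5, within_sd = 0.1,
                              n_replicates = 200L)
  tab <- generate_score_table(list(tr_add), control_mean = 20, seed = 1)
  m <- tapply(tab$score, tab$genotype, mean)
  expect_equal(unname(m["AB"]), 35, tolerance = 0.1)
  # class none with zero B effect: B and two-hit cells match their background
  tr_none <- interaction_truth("c", "d", "none", effect_a = 10, effect_b = 0,
                               within_sd = 0.1, n_replicates = 200L)
  tab2 <- generate_score_table(list(tr_none), control_mean = 20, seed = 1)
  m2 <- tapply(tab2$score, tab2$genotype, mean)
  expect_equal(unname(m2["B"]), unname(m2["control"]), tolerance = 0.1)
  expect_equal(unname(m2["AB"]), unname(m2["A"]), tolerance = 0.1)
  # planted suppressor contrast concentrates near -8 at n = 12, sd = 1
  # (SE of the contrast is sd * sqrt(4/12) ~= 0.58)
  tr_sup <- interaction_truth("e", "f", "suppressor", effect_a = 10,
                              interaction_shift = -8, within_sd = 1,
                              n_replicates = 12L)
  contrasts <- vapply(1:10, function(s) {
    interaction_contrast(generate_score_table(list(tr_sup), 20,
                                              seed = s))$contrast
  }, numeric(1))
  expect_lt(abs(median(contrasts) - (-8)), 1)
  expect_gte(mean(abs(contrasts - (-8)) < 1), 0.8)
  # full rescue pins the two-hit mean at the control mean
  tr_fr <- interaction_truth("g", "h", "full_rescue", effect_a = 10,
                             within_sd = 0.1, n_replicates = 200L)
  tab4 <- generate_score_table(list(tr_fr), control_mean = 20, seed = 3)
  m4 <- tapply(tab4$score, tab4$genotype, mean)
  expect_equal(unname(m4["AB"]), unname(m4["control"]), tolerance = 0.1)
})

test_that("interaction_truth enforces class/shift consistency", {
  expect_error(interaction_truth("a", "b", "suppressor",
                                 interaction_shift = 2), "inconsistent")
  expect_error(interaction_truth("a", "b", "additive",
                                 interaction_shift = 1), "inconsistent")
  expect_error(interaction_truth("a", "b", "none", within_sd = 0),
               "within_sd")
  expect_error(interaction_truth("a", "b", "none", n_replicates = 1),
               "n_replicates")
})

test_that("expression study plants DE structure, knockdown, and shared pool", {
  genes <- sprintf("g%04d", 1:500)
  truth <- expression_truth(n_genes = 500, n_models = 3,
                            planted_terms = list(list(term = "up",
                                                      genes = genes[1:40],
                                                      shift = 2)),
                            shared_de_fraction = 0.5, n_de_per_model = 60,
                            seed = 11)
  study <- generate_expression_study(truth)
  expect_named(study$models, sprintf("model%02d", 1:3))
  # knockdown gene passes the DE filter in its own model
  for (mid in names(study$models)) {
    tabm <- study$models[[mid]]
    kd <- study$knockdown_genes[[mid]]
    expect_lt(tabm$log2FC[tabm$gene == kd], -1)
    expect_equal(tabm$FDR[tabm$gene == kd], 0.01)
    expect_true(kd %in% call_de_genes(tabm))
  }
  # planted term genes shifted upward on average
  m1 <- study$models[[1]]
  expect_gt(mean(m1$log2FC[m1$gene %in% genes[1:40]]), 1)
  # shared pool: at least the planted shared genes are DE in all models
  de <- lapply(study$models, call_de_genes)
  expect_gte(length(Reduce(intersect, de)), 30)
  # oversized planted term rejected
  expect_error(expression_truth(n_genes = 1000,
                                planted_terms = list(list(term = "x",
                                                          genes = sprintf("h%d", 1:600),
                                                          shift = 1))),
               "500")
})

test_that("generated networks are weighted, connected, and reproducible", {
  net <- generate_network(200, list(type = "erdos_renyi", p = 0.03),
                          n_seeds = 5, annotation_fraction = 0.1, seed = 4)
  expect_true(igraph::is_connected(net$graph))
  w <- igraph::E(net$graph)$weight
  expect_true(all(w > 0 & w <= 1))
  expect_length(net$seeds, 5L)
  expect_true(all(net$seeds %in% igraph::V(net$graph)$name))
  net2 <- generate_network(200, list(type = "erdos_renyi", p = 0.03),
                           n_seeds = 5, annotation_fraction = 0.1, seed = 4)
  expect_identical(igraph::as_edgelist(net$graph),
                   igraph::as_edgelist(net2$graph))
  expect_identical(net$seeds, net2$seeds)
  expect_identical(net$annotation, net2$annotation)
  expect_error(generate_network(10, n_seeds = 11), "n_seeds")
})
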