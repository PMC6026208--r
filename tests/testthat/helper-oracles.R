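# Independent oracles and small fixture builders shared across tests.

# Greedy nearest-neighbour matching of detected centres against ground truth.
# Returns recall, precision and the largest matched displacement.
match_centers <- function(truth, detected, tol) {
  nt <- nrow(truth); nd <- nrow(detected)
  if (nd == 0L) return(list(recall = 0, precision = NA_real_, max_err = NA))
  d <- sqrt(outer(truth$x, detected$x, "-")^2 +
              outer(truth$y, detected$y, "-")^2)
  matched_t <- logical(nt); matched_d <- logical(nd)
  errs <- numeric(0)
  repeat {
    d[matched_t, ] <- Inf
    d[, matched_d] <- Inf
    k <- which.min(d)
    if (!is.finite(d[k])) break
    if (d[k] > tol) break
    i <- ((k - 1) %% nt) + 1
    j <- ((k - 1) %/% nt) + 1
    matched_t[i] <- TRUE; matched_d[j] <- TRUE
    errs <- c(errs, d[k])
    d[i, ] <- Inf; d[, j] <- Inf
  }
  list(recall = sum(matched_t) / nt, precision = sum(matched_d) / nd,
       max_err = if (length(errs)) max(errs) else NA_real_)
}

# Textbook Benjamini-Hochberg step-up, written from the definition:
# p_(i) * n / i, cumulative minimum from the largest rank down, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  run_min <- 1
  for (i in n:1) {
    run_min <- min(run_min, p[o[i]] * n / i)
    adj[o[i]] <- run_min
  }
  pmin(adj, 1)
}

# Brute-force type-II ANOVA for the 2 x 2 knockdown design via residual
# sums of squares of explicitly built design matrices (independent of both
# the closed-form balanced path and car::Anova).
oracle_anova <- function(tab) {
  y <- tab$score
  A <- as.numeric(tab$genotype %in% c("A", "AB"))
  B <- as.numeric(tab$genotype %in% c("B", "AB"))
  rss <- function(X) sum(qr.resid(qr(X), y)^2)
  one <- rep(1, length(y))
  rss_full <- rss(cbind(one, A, B, A * B))
  ss <- c(A = rss(cbind(one, B)) - rss(cbind(one, A, B)),
          B = rss(cbind(one, A)) - rss(cbind(one, A, B)),
          `A:B` = rss(cbind(one, A, B)) - rss_full)
  df_res <- length(y) - 4L
  f <- ss / (rss_full / df_res)
  list(SS = ss, F = f, p = pf(f, 1, df_res, lower.tail = FALSE),
       residual_ss = rss_full, residual_df = df_res)
}

# Random score table for one pair with chosen per-cell replicate counts.
random_pair_table <- function(n_per_cell, means = c(10, 20, 14, 24), sd = 2) {
  genos <- c("control", "A", "B", "AB")
  data.frame(
    genotype = rep(genos, times = n_per_cell),
    score = rnorm(sum(n_per_cell), rep(means, times = n_per_cell), sd))
}

# Exhaustive geodesic enumeration oracle for the connector analysis, built on
# igraph's explicit all-shortest-paths listing (the implementation under test
# never enumerates paths).
oracle_connectors <- function(g, seeds) {
  nodes <- igraph::V(g)$name
  seeds <- intersect(seeds, nodes)
  conn_nodes <- character(0)
  edge_counts <- list()
  pair_geo <- list()
  np <- 0L
  for (i in seq_along(seeds)) {
    for (j in seq_along(seeds)) {
      if (j <= i) next
      np <- np + 1L
      res <- suppressWarnings(
        igraph::all_shortest_paths(g, from = seeds[i], to = seeds[j],
                                   weights = NA))$res
      pair_geo[[np]] <- data.frame(seed_a = seeds[i], seed_b = seeds[j],
                                   n_geodesics = length(res))
      for (path in res) {
        nm <- names(path)
        if (length(nm) > 2) conn_nodes <- c(conn_nodes, nm[-c(1, length(nm))])
        for (e in seq_len(length(nm) - 1)) {
          key <- paste(sort(nm[e:(e + 1)]), collapse = "|")
          edge_counts[[key]] <- (edge_counts[[key]] %||% 0) + 1
        }
      }
    }
  }
  list(connectors = sort(setdiff(unique(conn_nodes), seeds)),
       edge_counts = unlist(edge_counts),
       pairs = do.call(rbind, pair_geo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random connected G(n, p) graph with named vertices.
random_connected_graph <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.1, 1)
  g
}

# Edge criticality of a connector_result keyed "min|max" for comparison.
keyed_criticality <- function(result) {
  ec <- result$edge_criticality
  keys <- paste(pmin(ec$from, ec$to), pmax(ec$from, ec$to), sep = "|")
  counts <- ec$c_e
  names(counts) <- keys
  counts[counts > 0]
}
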