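# Connector-gene analysis: enumerate all geodesics between seed genes on a
# functional network, extract the non-seed genes lying on them, and test the
# connector set for annotation enrichment.

# Breadth-first search from one source on an adjacency list: returns geodesic
# distance (-1 if unreachable) and geodesic count per node (first phase of
# Brandes' betweenness algorithm).
#' @keywords internal
#' @noRd
bfs_counts <- function(adj, source, n) {
  dist <- rep(-1L, n)
  sigma <- numeric(n)
  dist[source] <- 0L
  sigma[source] <- 1
  queue <- integer(n)
  queue[1L] <- source
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
      if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
    }
  }
  list(dist = dist, sigma = sigma)
}

#' Connector genes on seed-pair geodesics
#'
#' Maps seed genes onto a network, computes the shortest paths between every
#' pair of mapped seeds on the (optionally weight-thresholded, then
#' unweighted) graph, and enumerates ALL geodesics per pair via breadth-first
#' predecessor counting.  Connector genes are the non-seed nodes lying on at
#' least one geodesic of at least one seed pair.  Each edge's criticality
#' c_e is the total number of (seed pair, geodesic) memberships — the
#' quantity edge thickness is drawn from in network figures.  Deterministic.
#'
#' Geodesic counts per pair are computed by dynamic programming on the BFS
#' DAG (a node v lies on an s-t geodesic iff d(s,v) + d(v,t) = d(s,t), and
#' then carries sigma_s(v) * sigma_t(v) paths), never by explicit path
#' enumeration.
#'
#' @param network An \pkg{igraph} graph with a \code{name} vertex attribute
#'   (and optionally an edge \code{weight} attribute), or an edge-list data
#'   frame with columns \code{gene1}, \code{gene2}, \code{weight}.
#' @param seeds Character vector of seed gene identifiers; at least 2 must
#'   map to the network (unmapped seeds are reported, not fatal).
#' @param weight_cutoff Optional minimum edge weight; edges below it are
#'   removed before the (unweighted) shortest-path computation.  Default
#'   keeps all edges.
#' @return An object of class \code{connector_result}: list with
#'   \code{seeds_mapped}, \code{seeds_unmapped}, \code{pairs} (per seed pair:
#'   \code{length}, \code{n_geodesics}, \code{connected}),
#'   \code{connectors}, \code{node_path_counts} (geodesics through each
#'   connector), \code{edge_criticality} (per-edge \code{c_e}), and the
#'   thresholded \code{graph}.
#' @examples
#' g <- igraph::make_graph(~ a - x, x - b)
#' connector_analysis(g, c("a", "b"))$connectors
#' @export
connector_analysis <- function(network, seeds, weight_cutoff = NULL) {
  g <- if (igraph::is_igraph(network)) network else edge_list_to_graph(network)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  if (!is.null(weight_cutoff)) {
    w <- igraph::E(g)$weight
    if (is.null(w)) stop("weight_cutoff given but network has no weights",
                         call. = FALSE)
    g <- igraph::delete_edges(g, which(w < weight_cutoff))
  }
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  seeds <- unique(as.character(seeds))
  mapped <- intersect(seeds, nodes)
  unmapped <- setdiff(seeds, nodes)
  if (length(mapped) < 2L) {
    stop("fewer than 2 seeds map to the network", call. = FALSE)
  }
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  seed_idx <- match(mapped, nodes)
  bfs <- lapply(seed_idx, function(s) bfs_counts(adj, s, n))
  names(bfs) <- mapped
  el <- igraph::as_edgelist(g, names = FALSE)
  ce <- numeric(nrow(el))
  node_counts <- numeric(n)
  on_any <- logical(n)
  pair_rows <- list()
  np <- 0L
  for (i in seq_along(mapped)) {
    for (j in seq_along(mapped)) {
      if (j <= i) next
      bs <- bfs[[i]]; bt <- bfs[[j]]
      s <- seed_idx[i]; t <- seed_idx[j]
      L <- bs$dist[t]
      np <- np + 1L
      if (L < 0L) {
        pair_rows[[np]] <- data.frame(seed_a = mapped[i], seed_b = mapped[j],
                                      length = NA_integer_, n_geodesics = 0,
                                      connected = FALSE)
        next
      }
      n_geo <- bs$sigma[t]
      pair_rows[[np]] <- data.frame(seed_a = mapped[i], seed_b = mapped[j],
                                    length = L, n_geodesics = n_geo,
                                    connected = TRUE)
      # interior nodes of the pair's geodesics
      on_path <- bs$dist >= 0L & bt$dist >= 0L & (bs$dist + bt$dist == L)
      interior <- on_path
      interior[c(s, t)] <- FALSE
      on_any <- on_any | interior
      node_counts[interior] <- node_counts[interior] +
        bs$sigma[interior] * bt$sigma[interior]
      # edges (u,v) used s->t when d_s(u) + 1 + d_t(v) = L (either direction)
      u <- el[, 1]; v <- el[, 2]
      fwd <- bs$dist[u] >= 0L & bt$dist[v] >= 0L & (bs$dist[u] + 1L + bt$dist[v] == L)
      bwd <- bs$dist[v] >= 0L & bt$dist[u] >= 0L & (bs$dist[v] + 1L + bt$dist[u] == L)
      ce[fwd] <- ce[fwd] + bs$sigma[u[fwd]] * bt$sigma[v[fwd]]
      ce[bwd] <- ce[bwd] + bs$sigma[v[bwd]] * bt$sigma[u[bwd]]
    }
  }
  pairs <- do.call(rbind, pair_rows)
  connectors <- setdiff(nodes[on_any], mapped)
  npc <- node_counts[match(connectors, nodes)]
  names(npc) <- connectors
  edge_criticality <- data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]],
                                 c_e = ce)
  structure(list(seeds_mapped = mapped, seeds_unmapped = unmapped,
                 pairs = pairs, connectors = sort(connectors),
                 node_path_counts = npc,
                 edge_criticality = edge_criticality, graph = g),
            class = "connector_result")
}

#' @export
print.connector_result <- function(x, ...) {
  cat(sprintf(paste0("<connector_result> %d/%d seeds mapped, %d connector ",
                     "genes, %d/%d seed pairs connected\n"),
              length(x$seeds_mapped),
              length(x$seeds_mapped) + length(x$seeds_unmapped),
              length(x$connectors), sum(x$pairs$connected), nrow(x$pairs)))
  invisible(x)
}

#' Annotation enrichment of connector genes
#'
#' One-sided (greater) Fisher's exact test of whether connector genes are
#' enriched for an annotation (e.g. cell proliferation / cell cycle terms)
#' relative to a background.  The background defaults to the non-seed nodes
#' of the network the connectors were drawn from — the sampling frame of the
#' connector procedure; connectors are excluded from the background margin.
#'
#' @param result A \code{connector_result} with non-empty connectors.
#' @param annotation Character vector of annotated gene identifiers.
#' @param background Optional character vector; defaults to all non-seed
#'   network nodes.
#' @return An object of class \code{enrichment_table}: list with
#'   \code{counts} (2 x 2 matrix), \code{odds_ratio} (sample odds ratio; NA
#'   with \code{or_undefined = TRUE} when a margin is empty), and \code{p}.
#' @export
enrich_connectors <- function(result, annotation, background = NULL) {
  if (!inherits(result, "connector_result")) {
    stop("'result' must be a connector_result", call. = FALSE)
  }
  conn <- result$connectors
  if (!length(conn)) {
    stop("connector set is empty; nothing to test", call. = FALSE)
  }
  if (is.null(background)) {
    background <- setdiff(igraph::V(result$graph)$name, result$seeds_mapped)
  }
  background <- setdiff(unique(as.character(background)), conn)
  annotation <- unique(as.character(annotation))
  a <- sum(conn %in% annotation)
  b <- length(conn) - a
  c_ <- sum(background %in% annotation)
  d <- length(background) - c_
  counts <- matrix(c(a, b, c_, d), nrow = 2,
                   dimnames = list(c("annotated", "not_annotated"),
                                   c("connector", "background")))
  p <- stats::fisher.test(counts, alternative = "greater")$p.value
  or_undefined <- (b == 0 && c_ == 0) || (a == 0 && d == 0) ||
    (a + c_ == 0) || (b + d == 0)
  or <- if (b * c_ > 0) (a * d) / (b * c_) else if (a * d > 0) Inf else NA_real_
  structure(list(counts = counts, odds_ratio = or,
                 or_undefined = or_undefined, p = p),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("<enrichment_table> one-sided Fisher's exact test\n")
  print(x$counts)
  cat(sprintf("  odds ratio = %s, p = %.4g\n",
              if (is.na(x$odds_ratio)) "undefined" else
                format(x$odds_ratio, digits = 4), x$p))
  invisible(x)
}

#' Random-seed control for connector enrichment
#'
#' Repeats the connector analysis and annotation enrichment for random seed
#' sets drawn from a pool (e.g. genes with neurological phenotypes), giving
#' the null distribution of enrichment against which the real seed set's
#' result is judged.
#'
#' @param network As in [connector_analysis()].
#' @param seed_pool Character vector of candidate seed genes, length >= k.
#' @param k Seeds per draw.
#' @param n_iter Number of random draws.
#' @param annotation Passed to [enrich_connectors()].
#' @param seed Integer RNG seed.
#' @param weight_cutoff Passed to [connector_analysis()].
#' @return List with \code{results} (per-iteration data frame:
#'   \code{n_connectors}, \code{odds_ratio}, \code{p}; NA rows where a draw
#'   produced no connectors), \code{p_quantiles} and \code{or_quantiles}.
#' @export
random_seed_control <- function(network, seed_pool, k, n_iter = 100L,
                                annotation = character(0), seed = 1L,
                                weight_cutoff = NULL) {
  k <- assert_count(k, "k", min = 2L)
  n_iter <- assert_count(n_iter, "n_iter")
  seed_pool <- unique(as.character(seed_pool))
  if (length(seed_pool) < k) {
    stop("'seed_pool' must contain at least k genes", call. = FALSE)
  }
  rows <- with_seed(seed, {
    lapply(seq_len(n_iter), function(it) {
      draws <- if (length(seed_pool) == k) seed_pool
               else sample(seed_pool, k)
      res <- tryCatch(connector_analysis(network, draws, weight_cutoff),
                      error = function(e) NULL)
      if (is.null(res) || !length(res$connectors)) {
        return(data.frame(iter = it, n_connectors = 0L,
                          odds_ratio = NA_real_, p = NA_real_))
      }
      enr <- enrich_connectors(res, annotation)
      data.frame(iter = it, n_connectors = length(res$connectors),
                 odds_ratio = enr$odds_ratio, p = enr$p)
    })
  })
  results <- do.call(rbind, rows)
  qs <- function(v) if (all(is.na(v))) rep(NA_real_, 3) else
    stats::quantile(v, c(0.025, 0.5, 0.975), na.rm = TRUE)
  list(results = results, p_quantiles = qs(results$p),
       or_quantiles = qs(results$odds_ratio))
}

#' Export an attributed connector graph
#'
#' Writes the analysed network as GraphML plus node/edge attribute TSVs for
#' downstream visualisation: node attributes \code{role} (seed/connector/
#' other), \code{degree}, and \code{annotated}; edge attribute \code{c_e}
#' (geodesic criticality, the quantity edge thickness is drawn from).
#'
#' @param result A \code{connector_result}.
#' @param path Output prefix; writes \code{<path>.graphml},
#'   \code{<path>_nodes.tsv}, \code{<path>_edges.tsv}.  With \code{path =
#'   NULL} nothing is written and the attributed graph is returned.
#' @param annotation Optional annotated gene set for the node flag.
#' @return The attributed \pkg{igraph} object, invisibly.
#' @export
export_graph <- function(result, path = NULL, annotation = character(0)) {
  if (!inherits(result, "connector_result")) {
    stop("'result' must be a connector_result", call. = FALSE)
  }
  g <- result$graph
  nodes <- igraph::V(g)$name
  role <- ifelse(nodes %in% result$seeds_mapped, "seed",
                 ifelse(nodes %in% result$connectors, "connector", "other"))
  igraph::V(g)$role <- role
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::V(g)$annotated <- nodes %in% annotation
  igraph::E(g)$c_e <- result$edge_criticality$c_e
  if (!is.null(path)) {
    igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
    nt <- data.frame(node = nodes, role = role,
                     degree = igraph::V(g)$degree,
                     annotated = igraph::V(g)$annotated)
    write_tsv(nt, paste0(path, "_nodes.tsv"))
    write_tsv(result$edge_criticality, paste0(path, "_edges.tsv"))
  }
  invisible(g)
}
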