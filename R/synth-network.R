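#' Generate a random weighted gene network with seeds and annotations
#'
#' Builds an undirected random graph (Erdos-Renyi or Watts-Strogatz
#' small-world), assigns edge weights uniform on (0, 1], samples a seed gene
#' list without replacement, and samples an annotation set at a stated
#' fraction of the nodes.  If the generated graph is disconnected, its giant
#' component is kept and the result is flagged.
#'
#' @param n_nodes Number of nodes requested.
#' @param edge_model A list: either \code{list(type = "erdos_renyi", p = ...)}
#'   or \code{list(type = "small_world", nei = ..., p = ...)} (ring lattice
#'   with \code{nei} neighbours each side, rewiring probability \code{p}).
#' @param n_seeds Number of seed genes to sample (must not exceed the node
#'   count of the kept component).
#' @param annotation_fraction Fraction of nodes annotated (e.g. with a cell
#'   proliferation term), sampled independently per node.
#' @param seed Integer seed.
#' @return A list with \code{graph} (an \pkg{igraph} object with \code{name}
#'   and edge \code{weight} attributes), \code{seeds}, \code{annotation}
#'   (character vectors of node names), and \code{giant_component_taken}
#'   (logical flag).
#' @examples
#' net <- generate_network(30, list(type = "erdos_renyi", p = 0.2),
#'                         n_seeds = 3, annotation_fraction = 0.2, seed = 5)
#' igraph::vcount(net$graph)
#' @export
generate_network <- function(n_nodes,
                             edge_model = list(type = "erdos_renyi", p = 0.1),
                             n_seeds = 2L, annotation_fraction = 0.1,
                             seed = 1L) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 2L)
  n_seeds <- assert_count(n_seeds, "n_seeds", min = 2L)
  assert_fraction(annotation_fraction, "annotation_fraction")
  if (n_seeds > n_nodes) {
    stop("'n_seeds' must not exceed 'n_nodes'", call. = FALSE)
  }
  type <- edge_model$type %||% "erdos_renyi"
  with_seed(seed, {
    g <- switch(type,
      erdos_renyi = igraph::sample_gnp(n_nodes, p = edge_model$p %||% 0.1),
      small_world = igraph::sample_smallworld(dim = 1, size = n_nodes,
                                              nei = edge_model$nei %||% 2L,
                                              p = edge_model$p %||% 0.05),
      stop("unknown edge model type: ", type, call. = FALSE)
    )
    g <- igraph::simplify(g)
    igraph::V(g)$name <- sprintf("n%04d", seq_len(igraph::vcount(g)))
    giant_taken <- FALSE
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      giant_taken <- TRUE
      keep <- which(comp$membership == which.max(comp$csize))
      g <- igraph::induced_subgraph(g, keep)
    }
    if (igraph::vcount(g) < n_seeds) {
      stop("giant component smaller than 'n_seeds'; increase density",
           call. = FALSE)
    }
    # weights uniform on (0, 1]
    igraph::E(g)$weight <- 1 - runif(igraph::ecount(g))
    nodes <- igraph::V(g)$name
    seeds <- sample(nodes, n_seeds)
    annotation <- nodes[runif(length(nodes)) < annotation_fraction]
    list(graph = g, seeds = seeds, annotation = annotation,
         giant_component_taken = giant_taken)
  })
}
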