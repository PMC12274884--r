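#' Construct a connectome
#'
#' Directed sparse graph over `n` cells: an edge list with optional
#' apposition counts, plus a cell class per node for subnetwork analyses.
#' Self-edges and duplicate edges are removed.
#'
#' @param n number of cells.
#' @param edges data.frame with integer columns `src`, `dst` (1-based) and
#'   optionally `appositions`.
#' @param cell_class character vector of length `n` (default all `"PC"`).
#' @param cell_ids optional original cell ids of the nodes.
#' @export
connectome <- function(n, edges, cell_class = rep("PC", n), cell_ids = NULL) {
  stopifnot(n >= 1, is.data.frame(edges))
  if (is.null(edges$appositions)) edges$appositions <- rep(1L, nrow(edges))
  keep <- edges$src != edges$dst & !duplicated(edges[, c("src", "dst")])
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) && (max(edges$src, edges$dst) > n || min(edges$src, edges$dst) < 1))
    stop("edge endpoints out of range")
  rownames(edges) <- NULL
  structure(list(n = n, edges = edges, cell_class = cell_class,
                 cell_ids = cell_ids %||% seq_len(n)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("connectome:", x$n, "cells,", nrow(x$edges), "edges (density",
      sprintf("%.4f", nrow(x$edges) / x$n^2), "n^2 convention)\n")
  invisible(x)
}

#' Graph density of a node subset
#'
#' Edges with both endpoints in the subset divided by the squared subset
#' size. Note the n^2 denominator (not n(n-1)): this follows the convention
#' used by the circuit analyses this package reproduces, so a complete
#' digraph without self-loops has density (n-1)/n, not 1.
#'
#' @param conn a [connectome()].
#' @param node_subset node indices (default: all).
#' @export
subnetwork_density <- function(conn, node_subset = seq_len(conn$n)) {
  if (!length(node_subset)) stop("empty node subset")
  e <- conn$edges
  inset <- e$src %in% node_subset & e$dst %in% node_subset
  sum(inset) / length(node_subset)^2
}

#' In-degree distribution of a node subset
#'
#' In-degrees computed within the subset (edges from subset members only).
#' @param conn a [connectome()].
#' @param node_subset node indices (default: all).
#' @return integer vector of in-degrees, one per subset node.
#' @export
in_degree_distribution <- function(conn, node_subset = seq_len(conn$n)) {
  if (!length(node_subset)) stop("empty node subset")
  e <- conn$edges
  inset <- e$src %in% node_subset & e$dst %in% node_subset
  tab <- tabulate(match(e$dst[inset], node_subset), nbins = length(node_subset))
  as.integer(tab)
}

#' Extract the subnetwork of one cell class
#'
#' @param conn a [connectome()].
#' @param cell_class class label (e.g. `"PC"`).
#' @return node indices of that class.
#' @export
class_nodes <- function(conn, cell_class) which(conn$cell_class == cell_class)

#' Randomly prune a connectome to a target density
#'
#' Keeps a uniformly random subset of exactly `floor(target_density * n^2)`
#' edges, emulating the random selection of appositions down to a
#' biologically plausible connection density (~4%).
#'
#' @param conn a [connectome()].
#' @param target_density target edge density under the n^2 convention
#'   (default 0.04).
#' @param seed integer seed.
#' @export
prune_to_density <- function(conn, target_density = 0.04, seed = 1) {
  m_target <- floor(target_density * conn$n^2)
  m <- nrow(conn$edges)
  if (m < m_target)
    stop(sprintf("current density %.4f below target %.4f",
                 m / conn$n^2, target_density))
  set.seed(seed)
  keep <- sample.int(m, m_target)
  conn$edges <- conn$edges[sort(keep), , drop = FALSE]
  rownames(conn$edges) <- NULL
  conn
}

#' Expected connection probability from synapse statistics
#'
#' With `s` synapses per neuron and `c` synapses per connection, each neuron
#' receives `s/c` connections, so a network of `n` cells has `n*s/c` edges
#' out of `n^2 - n` possible: `p = (n*s/c) / (n^2 - n)`.
#'
#' @param synapses_per_neuron total synapses on one neuron.
#' @param synapses_per_connection synapses forming one connection.
#' @param n_cells network size.
#' @return list with `probability` and `in_degree` (= s/c).
#' @export
expected_connection_probability <- function(synapses_per_neuron,
                                            synapses_per_connection,
                                            n_cells) {
  if (synapses_per_connection <= 0) stop("synapses_per_connection must be > 0")
  indeg <- synapses_per_neuron / synapses_per_connection
  list(probability = n_cells * indeg / (n_cells^2 - n_cells),
       in_degree = indeg)
}

#' Count directed simplices
#'
#' counts[k+1] is the number of directed k-simplices: ordered tuples
#' (v0, ..., vk) of distinct vertices with an edge vi -> vj for every i < j
#' (a fully connected subgraph with a single source, a single sink, and all
#' edges aligned with one linear order). counts[1] is the node count,
#' counts[2] the edge count. Exact recursive enumeration over successive
#' out-neighbourhood intersections.
#'
#' @param conn a [connectome()] (or data.frame of `src`, `dst` with attribute
#'   n).
#' @param max_dim highest dimension to count (`Inf` to run to exhaustion).
#' @return numeric vector of counts, index k+1 = dimension k.
#' @export
count_directed_simplices <- function(conn, max_dim = Inf) {
  md <- if (is.infinite(max_dim)) -1L else as.integer(max_dim)
  cpp_count_simplices(conn$n, as.integer(conn$edges$src),
                      as.integer(conn$edges$dst), md)
}

#' Directed Erdos-Renyi random graph
#'
#' Every ordered pair (i, j), i != j, is an edge independently with
#' probability `density`.
#'
#' @param n nodes.
#' @param density edge probability.
#' @param seed integer seed.
#' @export
erdos_renyi_directed <- function(n, density, seed = 1) {
  stopifnot(n >= 2, density >= 0, density <= 1)
  set.seed(seed)
  if (density == 0) {
    ed <- data.frame(src = integer(0), dst = integer(0))
  } else {
    src <- rep(seq_len(n), each = n)
    dst <- rep(seq_len(n), times = n)
    off <- src != dst
    src <- src[off]; dst <- dst[off]
    pick <- runif(length(src)) < density
    ed <- data.frame(src = src[pick], dst = dst[pick])
  }
  connectome(n, ed)
}

#' Directed Watts-Strogatz small-world graph
#'
#' Starts from a directed ring lattice in which every node has out-edges to
#' its `k` nearest neighbours (`k/2` on each side), then rewires each edge's
#' target with probability `p` to a uniformly random node (no self-edges, no
#' duplicate edges). At `p = 0` every out-degree is exactly `k`.
#'
#' @param n nodes.
#' @param k even out-degree of the initial lattice, `k < n`.
#' @param p rewiring probability (0.7 for the published null comparison).
#' @param seed integer seed.
#' @export
watts_strogatz_directed <- function(n, k, p, seed = 1) {
  if (k %% 2 != 0 || k >= n || k < 2) stop("k must be even and 2 <= k < n")
  stopifnot(p >= 0, p <= 1)
  set.seed(seed)
  src <- rep(seq_len(n), each = k)
  offs <- c(seq_len(k / 2), -seq_len(k / 2))
  dst <- as.vector(vapply(seq_len(n), function(i)
    ((i - 1 + offs) %% n) + 1L, numeric(k)))
  has_edge <- new.env(hash = TRUE)
  for (e in seq_along(src))
    assign(paste0(src[e], ".", dst[e]), TRUE, envir = has_edge)
  rewire <- runif(length(src)) < p
  for (e in which(rewire)) {
    for (att in 1:1000) {
      cand <- sample.int(n, 1)
      key <- paste0(src[e], ".", cand)
      if (cand != src[e] && !exists(key, envir = has_edge)) {
        rm(list = paste0(src[e], ".", dst[e]), envir = has_edge)
        assign(key, TRUE, envir = has_edge)
        dst[e] <- cand
        break
      }
    }
  }
  connectome(n, data.frame(src = src, dst = dst))
}

#' Write a connectome as an edge-list CSV
#' @param conn a [connectome()].
#' @param path output path.
#' @export
write_edgelist_csv <- function(conn, path) {
  write.csv(conn$edges, path, row.names = FALSE)
  invisible(path)
}

#' Read a connectome from an edge-list CSV
#' @param path CSV with columns `src`, `dst` and optionally `appositions`.
#' @param n number of nodes (default: max endpoint).
#' @export
read_edgelist_csv <- function(path, n = NULL) {
  e <- read.csv(path)
  connectome(n %||% max(e$src, e$dst), e)
}
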