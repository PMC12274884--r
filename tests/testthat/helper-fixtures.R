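# Fixtures are built in code; no data files.

# straight unbranched neurite of given length along +Y
straight_tree <- function(len = 100, n = 11, type = "basal", diameter = 0.5) {
  ys <- seq(0, len, length.out = n)
  neurite_tree(data.frame(id = seq_len(n), parent = c(-1L, seq_len(n - 1)),
                          x = 0, y = ys, z = 0, diameter = diameter), type)
}

# Y-shaped tree: trunk to path distance 50, one child ending at path
# distance 50 + c1, the other at 50 + c2 (both straight)
y_tree <- function(c1 = 50, c2 = 30, type = "basal", diameter = 0.5) {
  nodes <- data.frame(
    id = 1:5, parent = c(-1L, 1L, 2L, 3L, 3L),
    x = c(0, 0, 0, 0, c2),
    y = c(0, 25, 50, 50 + c1, 50),
    z = 0, diameter = diameter)
  neurite_tree(nodes, type)
}

# star-shaped axon: root plus k straight leaves; branch count k + 1 for k >= 2
star_axon <- function(k, leaf_len = 30) {
  ang <- 2 * pi * seq_len(k) / k
  nodes <- data.frame(
    id = seq_len(k + 1L), parent = c(-1L, rep(1L, k)),
    x = c(0, leaf_len * cos(ang)), y = c(0, leaf_len * sin(ang)),
    z = 0, diameter = 1)
  neuron_morphology(c(0, 0, 0), 1, list(neurite_tree(nodes, "axon")),
                    meta = list(cell_class = "PC"))
}

# small fast preset for property sweeps
tiny_preset <- function(bar_mean = 6, bar_sd = 2) {
  mixt <- diagram_mixture(c(0.6, 0.4),
                          matrix(c(10, 40, 30, 80), 2, 2, byrow = TRUE),
                          matrix(c(5, 10, 10, 15), 2, 2, byrow = TRUE))
  species_preset(
    name = "tiny",
    neurites = list(basal = list(mixture = mixt, bar_count = c(bar_mean, bar_sd),
                                 n_trees = 1L),
                    axon = list(mixture = mixt, bar_count = c(bar_mean, bar_sd),
                                n_trees = 1L)),
    cell_class = "PC",
    geometry = list(segment_length = 5, direction_persistence = 0.8,
                    branch_angle_spread = 0.6))
}

# exhaustive directed-simplex oracle: enumerate every ordered tuple of
# distinct vertices and test all forward edges
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

brute_simplex_counts <- function(n, edges) {
  A <- matrix(FALSE, n, n)
  if (nrow(edges)) A[cbind(edges$src, edges$dst)] <- TRUE
  counts <- n
  for (m in 2:n) {
    cnt <- 0
    subs <- utils::combn(n, m, simplify = FALSE)
    for (s in subs) for (p in all_perms(s)) {
      ok <- TRUE
      for (i in seq_len(m - 1)) {
        if (!all(A[p[i], p[(i + 1):m]])) { ok <- FALSE; break }
      }
      if (ok) cnt <- cnt + 1
    }
    if (cnt == 0) break
    counts <- c(counts, cnt)
  }
  counts
}

random_digraph_edges <- function(n, p) {
  src <- rep(seq_len(n), each = n)
  dst <- rep(seq_len(n), times = n)
  keep <- src != dst & runif(length(src)) < p
  data.frame(src = src[keep], dst = dst[keep])
}

# two single-segment cells: axon of cell 1 along x at y = 0, dendrite of
# cell 2 along z at y = gap; their minimum distance is exactly gap
two_cell_circuit <- function(gap) {
  ax <- neurite_tree(data.frame(id = 1:2, parent = c(-1L, 1L),
                                x = c(-10, 10), y = 0, z = 0, diameter = 1),
                     "axon")
  ax_far <- neurite_tree(data.frame(id = 1:2, parent = c(-1L, 1L),
                                    x = c(500, 510), y = 500, z = 500,
                                    diameter = 1), "axon")
  de <- neurite_tree(data.frame(id = 1:2, parent = c(-1L, 1L),
                                x = 0, y = gap, z = c(-10, 10), diameter = 1),
                     "basal")
  m1 <- neuron_morphology(c(0, 0, 0), 1, list(ax),
                          meta = list(cell_class = "PC"))
  m2 <- neuron_morphology(c(0, 0, 0), 1, list(de, ax_far),
                          meta = list(cell_class = "PC"))
  spec <- column_spec(side = 2000, height = 2000, n_pc = 2, n_in = 0,
                      n_columns = 1)
  circ <- build_circuit(spec, seed = 1)
  circ$cells$x <- c(0, 0); circ$cells$y <- c(0, 0); circ$cells$z <- c(0, 0)
  circ <- assign_morphologies(circ, list(PC = list(m1, m2)), jitter_sd = 0,
                              rotate = FALSE, seed = 1)
  circ$assignment$donor <- c(1L, 2L)
  circ
}

# small mixed circuit with synthetic morphologies for oracle comparisons
small_circuit <- function(n_pc = 12, n_in = 4, seed = 5, jitter_sd = 1) {
  pc <- generate_population(default_preset("mouse", "PC"), 3, seed = seed)
  inn <- generate_population(default_preset("mouse", "IN"), 2, seed = seed + 1L)
  spec <- column_spec(side = 60, height = 150, n_pc = n_pc, n_in = n_in,
                      n_columns = 1)
  circ <- build_circuit(spec, seed = seed)
  assign_morphologies(circ, list(PC = pc, IN = inn), jitter_sd = jitter_sd,
                      seed = seed)
}
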