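#' Volume of a hexagonal prism
#'
#' Regular hexagon of side `side` (um) extruded to `height` (um):
#' `(3*sqrt(3)/2) * side^2 * height`, reported in mm^3.
#'
#' @param side hexagon side length in um.
#' @param height prism height in um.
#' @export
hex_prism_volume <- function(side, height) {
  3 * sqrt(3) / 2 * side^2 * height / 1e9
}

## hexagon helpers: regular hexagon of side a centred at the origin,
## vertices at angles 0, 60, ..., 300 degrees. Inside test via the three
## edge-normal directions; apothem a*sqrt(3)/2.
hex_inside <- function(x, y, side) {
  ap <- side * sqrt(3) / 2
  ang <- c(pi / 2, pi / 2 + pi / 3, pi / 2 - pi / 3)
  ok <- rep(TRUE, length(x))
  for (a in ang) ok <- ok & (abs(x * cos(a) + y * sin(a)) <= ap + 1e-9)
  ok
}

# centres of the 6 columns tiling around a central one
hex_neighbor_centers <- function(side) {
  d <- side * sqrt(3)
  ang <- pi / 2 + (0:5) * pi / 3
  cbind(d * cos(ang), d * sin(ang))
}

#' Column specification
#'
#' @param side hexagon side length in um (476 for the full-scale columns).
#' @param height column height in um (layer thickness).
#' @param n_pc,n_in pyramidal cells and interneurons per column.
#' @param n_columns columns in the tiling (default 7: central + 6
#'   neighbours).
#' @export
column_spec <- function(side, height, n_pc, n_in, n_columns = 7) {
  stopifnot(side > 0, height > 0, n_pc >= 0, n_in >= 0,
            n_columns %in% c(1, 7))
  structure(list(side = side, height = height, n_pc = as.integer(n_pc),
                 n_in = as.integer(n_in), n_columns = as.integer(n_columns)),
            class = "column_spec")
}

#' Column specification from the species registry
#'
#' Full scale uses the registry cell counts (methods values by default,
#' `counts = "results"` for the published realized counts). A `scale`
#' below 1 shrinks the per-column counts by that factor and the hexagon side
#' by `sqrt(scale)`, preserving the volumetric cell density (heights are
#' anatomical and stay fixed), which keeps nearest-neighbour distances at
#' their full-scale values in desk-scale builds.
#'
#' @param species `"human"` or `"mouse"`.
#' @param scale count scale factor in (0, 1].
#' @param counts `"methods"` or `"results"` cell counts.
#' @export
species_column_spec <- function(species = c("human", "mouse"), scale = 1,
                                counts = c("methods", "results")) {
  species <- match.arg(species)
  counts <- match.arg(counts)
  p <- species_params(species)
  n_pc <- if (counts == "methods") p$column_n_pc else p$column_n_pc_results
  n_in <- if (counts == "methods") p$column_n_in else p$column_n_in_results
  column_spec(side = p$hex_side_length * sqrt(scale),
              height = p$layer_thickness,
              n_pc = round(n_pc * scale), n_in = round(n_in * scale))
}

#' Build a circuit: place somata in a tiling of hexagonal columns
#'
#' Somata are distributed uniformly inside each hexagonal prism (rejection
#' sampling in the bounding box); the tiling is a central column plus its 6
#' neighbours so downstream analyses can restrict to the central column and
#' avoid boundary effects. Class counts per column follow the spec.
#'
#' @param spec a [column_spec()].
#' @param seed integer seed.
#' @return object of class `circuit`: list with `cells` (data.frame: `cell_id`,
#'   `x`, `y`, `z`, `cell_class`, `column`), `spec`, `central_ids`.
#' @export
build_circuit <- function(spec, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), if (spec$n_columns == 7) hex_neighbor_centers(spec$side))
  per_col <- spec$n_pc + spec$n_in
  cells <- vector("list", nrow(centers))
  for (k in seq_len(nrow(centers))) {
    pts <- matrix(NA_real_, 0, 2)
    while (nrow(pts) < per_col) {
      need <- per_col - nrow(pts)
      cand <- cbind(runif(ceiling(need * 1.6), -spec$side, spec$side),
                    runif(ceiling(need * 1.6), -spec$side, spec$side))
      cand <- cand[hex_inside(cand[, 1], cand[, 2], spec$side), , drop = FALSE]
      pts <- rbind(pts, cand)
    }
    pts <- pts[seq_len(per_col), , drop = FALSE]
    cells[[k]] <- data.frame(
      x = pts[, 1] + centers[k, 1],
      y = pts[, 2] + centers[k, 2],
      z = runif(per_col, 0, spec$height),
      cell_class = rep(c("PC", "IN"), c(spec$n_pc, spec$n_in)),
      column = k)
  }
  cells <- do.call(rbind, cells)
  cells$cell_id <- seq_len(nrow(cells))
  cells <- cells[, c("cell_id", "x", "y", "z", "cell_class", "column")]
  structure(list(cells = cells, spec = spec,
                 central_ids = cells$cell_id[cells$column == 1L]),
            class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  cat("circuit:", nrow(x$cells), "cells in", x$spec$n_columns, "columns",
      sprintf("(side %.0f um, height %.0f um)\n", x$spec$side, x$spec$height))
  print(table(x$cells$cell_class[x$cells$column == 1]))
  invisible(x)
}

#' Assign cloned morphologies to circuit cells
#'
#' Each cell receives a donor morphology of its class (round-robin over a
#' seeded shuffle of the pool), cloned: translated so the donor soma sits at
#' the cell position, optionally rotated about the +Y axis by a uniform
#' random angle, and perturbed by zero-mean Gaussian coordinate noise of sd
#' `jitter_sd` um. Transforms are stored, not applied; segment coordinates
#' are materialized lazily by [compute_appositions()], so the assignment is
#' cheap and fully determined by the seed.
#'
#' @param circuit a [build_circuit()] result.
#' @param pool named list: `PC` and/or `IN`, each a list of
#'   [neuron_morphology()] donors.
#' @param jitter_sd clone coordinate noise sd in um (default 1).
#' @param rotate rotate clones about +Y (default TRUE).
#' @param seed integer seed.
#' @export
assign_morphologies <- function(circuit, pool, jitter_sd = 1, rotate = TRUE,
                                seed = 1) {
  cells <- circuit$cells
  for (cl in unique(cells$cell_class))
    if (!length(pool[[cl]])) stop("empty morphology pool for class ", cl)
  set.seed(seed)
  donor <- integer(nrow(cells))
  for (cl in unique(cells$cell_class)) {
    idx <- which(cells$cell_class == cl)
    sh <- sample.int(length(pool[[cl]]))
    donor[idx] <- sh[((seq_along(idx) - 1L) %% length(sh)) + 1L]
  }
  angle <- if (rotate) runif(nrow(cells), 0, 2 * pi) else rep(0, nrow(cells))
  jseed <- sample.int(.Machine$integer.max, nrow(cells))
  circuit$assignment <- data.frame(cell_id = cells$cell_id, donor = donor,
                                   angle = angle, jitter_seed = jseed)
  circuit$pool <- pool
  circuit$jitter_sd <- jitter_sd
  circuit
}

# materialize the transformed segments of one cell.
# Returns list(axon = 6-col matrix, dend = 6-col matrix) of segment endpoints.
cell_segments <- function(circuit, i) {
  cells <- circuit$cells
  asg <- circuit$assignment
  m <- circuit$pool[[cells$cell_class[i]]][[asg$donor[i]]]
  th <- asg$angle[i]
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)
  pos <- c(cells$x[i], cells$y[i], cells$z[i])
  out <- list(axon = NULL, dend = NULL)
  set.seed(asg$jitter_seed[i])
  for (tr in m$neurites) {
    nd <- tr$nodes
    p <- cbind(nd$x, nd$y, nd$z)
    p <- sweep(p, 2, m$soma_center)
    p <- p %*% t(R)
    if (circuit$jitter_sd > 0)
      p <- p + matrix(rnorm(length(p), 0, circuit$jitter_sd), ncol = 3)
    p <- sweep(p, 2, pos, `+`)
    idx <- match(nd$parent, nd$id)
    has <- which(!is.na(idx))
    segs <- cbind(p[idx[has], , drop = FALSE], p[has, , drop = FALSE])
    key <- if (tr$type == "axon") "axon" else "dend"
    out[[key]] <- rbind(out[[key]], segs)
  }
  out
}

#' Compute axo-dendritic appositions
#'
#' A directed edge i -> j is present when the axon of cell i passes within
#' `threshold` um of a dendrite of cell j (minimum 3D segment-to-segment
#' distance); the apposition count of the edge is the number of axon segments
#' of i within the threshold of any dendrite segment of j. By default both
#' sources and targets are restricted to the central column (the tiling's
#' outer columns exist to keep soma statistics free of boundary effects).
#' The spatial-hash path and the brute-force path return identical edges.
#'
#' @param circuit a circuit with assigned morphologies.
#' @param threshold apposition distance in um (default 2).
#' @param sources,targets cell ids to use as pre-/post-synaptic cells
#'   (default: central column).
#' @param brute use the all-pairs oracle path (for testing; slow).
#' @return a [connectome()] over `union(sources, targets)` cells.
#' @export
compute_appositions <- function(circuit, threshold = 2, sources = NULL,
                                targets = NULL, brute = FALSE) {
  if (is.null(circuit$assignment)) stop("assign morphologies first")
  if (is.null(sources)) sources <- circuit$central_ids
  if (is.null(targets)) targets <- circuit$central_ids
  nodes <- sort(union(sources, targets))
  seg_block <- function(ids, key) {
    mats <- lapply(ids, function(i) {
      s <- cell_segments(circuit, i)[[key]]
      if (is.null(s)) return(NULL)
      cbind(s, i)
    })
    do.call(rbind, mats)
  }
  src <- seg_block(sources, "axon")
  tgt <- seg_block(targets, "dend")
  if (is.null(src) || !nrow(src)) stop("no axon segments among source cells")
  if (is.null(tgt) || !nrow(tgt)) stop("no dendrite segments among target cells")
  ed <- cpp_appositions(src[, 1:6, drop = FALSE], as.integer(src[, 7]),
                        tgt[, 1:6, drop = FALSE], as.integer(tgt[, 7]),
                        threshold, brute)
  classes <- circuit$cells$cell_class[match(nodes, circuit$cells$cell_id)]
  connectome(n = length(nodes), edges = data.frame(
    src = match(ed$src, nodes), dst = match(ed$dst, nodes),
    appositions = ed$appositions),
    cell_class = classes, cell_ids = nodes)
}

#' Mean neighbour counts at increasing radii
#'
#' For every central-column cell, counts the other somata (any column) within
#' each radius and averages over central cells.
#'
#' @param circuit a [build_circuit()] result.
#' @param radii radii in um.
#' @return data.frame with `radius` and `mean_count`.
#' @export
neighbor_counts <- function(circuit, radii = seq(100, 1000, by = 100)) {
  cells <- circuit$cells
  cen <- circuit$central_ids
  p <- as.matrix(cells[, c("x", "y", "z")])
  pc <- p[match(cen, cells$cell_id), , drop = FALSE]
  totals <- matrix(0, length(cen), length(radii))
  chunk <- max(1L, floor(2e7 / nrow(p)))  # bound the distance-matrix size
  for (s in seq(1, nrow(pc), by = chunk)) {
    rows <- s:min(s + chunk - 1L, nrow(pc))
    d2 <- matrix(0, length(rows), nrow(p))
    for (d in 1:3) d2 <- d2 + outer(pc[rows, d], p[, d], `-`)^2
    for (k in seq_along(radii))
      totals[rows, k] <- rowSums(d2 <= radii[k]^2) - 1  # exclude self
  }
  data.frame(radius = radii, mean_count = colMeans(totals))
}

#' Build the hybrid circuit
#'
#' A human-dimensioned column (human thickness, densities and counts) whose
#' cells carry mouse dendrites uniformly scaled so each donor's total
#' dendritic length equals the human pool's mean, with human axons grafted
#' on. The hybrid isolates dendritic shape: it has human size, density and
#' axons, but mouse branching patterns.
#'
#' @param spec human-dimensioned [column_spec()].
#' @param mouse_pool,human_pool named lists (`PC`, `IN`) of donor
#'   morphologies.
#' @param jitter_sd,rotate,seed see [assign_morphologies()].
#' @return circuit with hybrid morphology pool assigned.
#' @export
build_hybrid_circuit <- function(spec, mouse_pool, human_pool, jitter_sd = 1,
                                 rotate = TRUE, seed = 1) {
  hybrid_pool <- list()
  for (cl in names(mouse_pool)) {
    target_len <- mean(vapply(human_pool[[cl]], total_dendritic_length,
                              numeric(1)))
    hp <- filter_axon_pool(human_pool[[cl]])
    if (!length(hp)) stop("no human axon donors pass the axon filter for ", cl)
    hybrid_pool[[cl]] <- lapply(seq_along(mouse_pool[[cl]]), function(i) {
      md <- mouse_pool[[cl]][[i]]
      f <- target_len / total_dendritic_length(md)
      graft_axon(scale_morphology(md, f), hp[[((i - 1L) %% length(hp)) + 1L]])
    })
  }
  circ <- build_circuit(spec, seed = seed)
  assign_morphologies(circ, hybrid_pool, jitter_sd = jitter_sd,
                      rotate = rotate, seed = seed)
}
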