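#' Construct a neurite tree
#'
#' A neurite tree is a rooted 3D tree sampled as a sequence of nodes, each with
#' a parent, a position in micrometres and a diameter. The root is the node
#' whose parent is `-1`; parents always precede their children, so the node
#' table is in topological order.
#'
#' @param nodes data.frame with columns `id`, `parent`, `x`, `y`, `z`,
#'   `diameter` (micrometres). Exactly one node must have `parent == -1`.
#' @param type neurite type, one of `"axon"`, `"basal"`, `"apical"`.
#' @return an object of class `neurite_tree`.
#' @export
neurite_tree <- function(nodes, type = c("basal", "apical", "axon")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(nodes),
            all(c("id", "parent", "x", "y", "z", "diameter") %in% names(nodes)))
  if (sum(nodes$parent == -1L) != 1L)
    stop("neurite tree must have exactly one root (parent == -1)")
  if (any(nodes$diameter < 0)) stop("negative diameter in neurite tree")
  idx <- match(nodes$parent, nodes$id)
  bad <- which(nodes$parent != -1L & (is.na(idx) | idx >= seq_len(nrow(nodes))))
  if (length(bad))
    stop("parent must precede child; offending node id ", nodes$id[bad[1]])
  structure(list(nodes = nodes, type = type), class = "neurite_tree")
}

#' Construct a neuron morphology
#'
#' @param soma_center numeric length-3, micrometres.
#' @param soma_radius soma radius in micrometres.
#' @param neurites list of [neurite_tree()] objects.
#' @param meta list of metadata: `species`, `cell_class` (`"PC"` or `"IN"`),
#'   and optionally `region`, `layer`, `subject_id`.
#' @return an object of class `neuron_morphology`.
#' @export
neuron_morphology <- function(soma_center = c(0, 0, 0), soma_radius = 5,
                              neurites = list(), meta = list()) {
  stopifnot(length(soma_center) == 3, soma_radius >= 0)
  stopifnot(all(vapply(neurites, inherits, logical(1), "neurite_tree")))
  structure(list(soma_center = as.numeric(soma_center),
                 soma_radius = as.numeric(soma_radius),
                 neurites = neurites, meta = meta),
            class = "neuron_morphology")
}

#' @export
print.neuron_morphology <- function(x, ...) {
  types <- vapply(x$neurites, `[[`, character(1), "type")
  cat("neuron_morphology:",
      if (!is.null(x$meta$species)) x$meta$species else "?",
      if (!is.null(x$meta$cell_class)) x$meta$cell_class else "?", "\n")
  cat("  neurites:", paste(sprintf("%s(%d nodes)", types,
      vapply(x$neurites, function(tr) nrow(tr$nodes), integer(1))),
      collapse = ", "), "\n")
  invisible(x)
}

## -- internal tree helpers ----------------------------------------------------

tree_children <- function(tree) {
  split(seq_len(nrow(tree$nodes)), match(tree$nodes$parent, tree$nodes$id))
}

tree_segment_lengths <- function(tree) {
  nd <- tree$nodes
  idx <- match(nd$parent, nd$id)
  has <- !is.na(idx)
  d <- sqrt((nd$x[has] - nd$x[idx[has]])^2 +
            (nd$y[has] - nd$y[idx[has]])^2 +
            (nd$z[has] - nd$z[idx[has]])^2)
  d
}

tree_total_length <- function(tree) sum(tree_segment_lengths(tree))

# out-degree of every node, in node order
tree_out_degree <- function(tree) {
  nd <- tree$nodes
  tabulate(match(nd$parent, nd$id), nbins = nrow(nd))
}

tree_n_leaves <- function(tree) sum(tree_out_degree(tree) == 0L)
tree_n_bifurcations <- function(tree) sum(tree_out_degree(tree) >= 2L)

# branches = maximal paths between consecutive bifurcations/terminations
tree_branch_count <- function(tree) tree_n_leaves(tree) + tree_n_bifurcations(tree)

# path distance from root for every node
tree_path_distance <- function(tree) {
  nd <- tree$nodes
  idx <- match(nd$parent, nd$id)
  pd <- numeric(nrow(nd))
  for (i in seq_len(nrow(nd))) {
    if (is.na(idx[i])) pd[i] <- 0 else
      pd[i] <- pd[idx[i]] + sqrt((nd$x[i] - nd$x[idx[i]])^2 +
                                 (nd$y[i] - nd$y[idx[i]])^2 +
                                 (nd$z[i] - nd$z[idx[i]])^2)
  }
  pd
}

tree_radial_distance <- function(tree, origin = NULL) {
  nd <- tree$nodes
  if (is.null(origin)) {
    r <- which(nd$parent == -1L)
    origin <- c(nd$x[r], nd$y[r], nd$z[r])
  }
  sqrt((nd$x - origin[1])^2 + (nd$y - origin[2])^2 + (nd$z - origin[3])^2)
}

morph_trees <- function(m, types) {
  Filter(function(tr) tr$type %in% types, m$neurites)
}

dendrite_types <- c("basal", "apical")

#' Total dendritic length of a morphology
#'
#' Sum of polyline lengths over basal and apical trees, in micrometres.
#' @param m a [neuron_morphology()].
#' @export
total_dendritic_length <- function(m) {
  sum(vapply(morph_trees(m, dendrite_types), tree_total_length, numeric(1)))
}

## -- morphometrics ------------------------------------------------------------

#' Morphometric summary of a neuron
#'
#' Per-neurite-type totals: cable length (polyline sum), branch count
#' (maximal paths between consecutive bifurcations/terminations), mean
#' diameter, plus the maximum radial extent over all neurites.
#'
#' @param m a [neuron_morphology()].
#' @return data.frame with one row per neurite type present plus columns
#'   `total_length`, `branch_count`, `mean_diameter`, and attribute-free
#'   column `max_radial_extent` (same value repeated; also returned as
#'   attribute `"max_radial_extent"`).
#' @export
morphometrics <- function(m) {
  types <- vapply(m$neurites, `[[`, character(1), "type")
  ext <- 0
  rows <- lapply(unique(types), function(ty) {
    trees <- m$neurites[types == ty]
    data.frame(
      neurite_type = ty,
      total_length = sum(vapply(trees, tree_total_length, numeric(1))),
      branch_count = sum(vapply(trees, tree_branch_count, numeric(1))),
      mean_diameter = mean(unlist(lapply(trees, function(tr) tr$nodes$diameter))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (tr in m$neurites)
    ext <- max(ext, max(tree_radial_distance(tr, m$soma_center)))
  out$max_radial_extent <- ext
  out
}

#' Population morphometrics
#'
#' One row per neuron and neurite type; convenience wrapper used for CSV
#' export of cohorts.
#' @param population list of [neuron_morphology()].
#' @export
population_morphometrics <- function(population) {
  do.call(rbind, lapply(seq_along(population), function(i) {
    mm <- morphometrics(population[[i]])
    mm$neuron <- i
    mm
  }))
}

#' Mean dendritic diameter profile along path distance
#'
#' Bins dendritic nodes by path distance from the root of their tree and
#' reports per-bin mean and standard deviation of node diameters over a
#' population, mirroring how dendritic thickness is compared between species.
#'
#' @param population list of [neuron_morphology()].
#' @param bin_width bin width in micrometres.
#' @return data.frame with `bin_lo`, `bin_hi`, `mean`, `sd`, `n` (samples per
#'   bin); empty bins have `n = 0` and `NA` statistics.
#' @export
diameter_profile <- function(population, bin_width = 20) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (!length(population)) stop("population must contain at least one morphology")
  pd <- numeric(0); dia <- numeric(0)
  for (m in population) for (tr in morph_trees(m, dendrite_types)) {
    pd <- c(pd, tree_path_distance(tr))
    dia <- c(dia, tr$nodes$diameter)
  }
  edges <- seq(0, max(pd) + bin_width, by = bin_width)
  bin <- findInterval(pd, edges, rightmost.closed = FALSE)
  nb <- length(edges) - 1L
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    mean = NA_real_, sd = NA_real_, n = 0L)
  for (b in seq_len(nb)) {
    v <- dia[bin == b]
    out$n[b] <- length(v)
    if (length(v)) { out$mean[b] <- mean(v); out$sd[b] <- if (length(v) > 1) sd(v) else 0 }
  }
  out
}

## -- curation -----------------------------------------------------------------

# principal direction (unit vector) of a set of points relative to origin
principal_direction <- function(pts, origin) {
  centred <- sweep(pts, 2, origin)
  v <- colMeans(centred)
  n <- sqrt(sum(v^2))
  if (n == 0) c(0, 1, 0) else v / n
}

# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) { # opposite: rotate pi about any orthogonal axis
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    v <- ax - sum(ax * a) * a; v <- v / sqrt(sum(v^2))
    K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Curate a neuron morphology
#'
#' Fixes the common reconstruction artefacts handled by the pipeline:
#' neurite roots that do not touch the soma are rigidly translated onto the
#' soma surface; zero diameters are replaced by the mean diameter of
#' same-tree neighbours within two nodes; pyramidal cells are rotated about
#' the soma so the principal direction of the apical tree aligns with +Y.
#' Idempotent. PCs without an apical tree trigger a warning and are not
#' rotated.
#'
#' @param m a [neuron_morphology()].
#' @return curated [neuron_morphology()].
#' @export
curate_morphology <- function(m) {
  for (i in seq_along(m$neurites)) {
    tr <- m$neurites[[i]]
    r <- which(tr$nodes$parent == -1L)
    root <- c(tr$nodes$x[r], tr$nodes$y[r], tr$nodes$z[r])
    off <- root - m$soma_center
    d <- sqrt(sum(off^2))
    if (d > m$soma_radius + 1e-9) {
      # translate the whole subtree so the root sits on the soma surface
      target <- m$soma_center + off / d * m$soma_radius
      shift <- target - root
      tr$nodes$x <- tr$nodes$x + shift[1]
      tr$nodes$y <- tr$nodes$y + shift[2]
      tr$nodes$z <- tr$nodes$z + shift[3]
    }
    z <- which(tr$nodes$diameter == 0)
    if (length(z)) {
      idx <- match(tr$nodes$parent, tr$nodes$id)
      for (j in z) {
        nb <- integer(0)
        if (!is.na(idx[j])) {
          nb <- c(nb, idx[j])
          if (!is.na(idx[idx[j]])) nb <- c(nb, idx[idx[j]])
        }
        k1 <- which(idx == j)
        nb <- c(nb, k1, which(idx %in% k1))
        vals <- tr$nodes$diameter[nb]
        vals <- vals[vals > 0]
        tr$nodes$diameter[j] <- if (length(vals)) mean(vals) else
          mean(tr$nodes$diameter[tr$nodes$diameter > 0])
      }
    }
    m$neurites[[i]] <- tr
  }
  if (identical(m$meta$cell_class, "PC")) {
    apicals <- morph_trees(m, "apical")
    if (!length(apicals)) {
      warning("pyramidal cell without apical tree: skipping apical alignment")
    } else {
      pts <- do.call(rbind, lapply(apicals, function(tr)
        cbind(tr$nodes$x, tr$nodes$y, tr$nodes$z)))
      dir <- principal_direction(pts, m$soma_center)
      if (abs(sum(dir * c(0, 1, 0)) - 1) > 1e-9) {
        R <- rotation_between(dir, c(0, 1, 0))
        for (i in seq_along(m$neurites)) {
          tr <- m$neurites[[i]]
          p <- t(R %*% t(sweep(cbind(tr$nodes$x, tr$nodes$y, tr$nodes$z), 2,
                               m$soma_center)))
          tr$nodes$x <- p[, 1] + m$soma_center[1]
          tr$nodes$y <- p[, 2] + m$soma_center[2]
          tr$nodes$z <- p[, 3] + m$soma_center[3]
          m$neurites[[i]] <- tr
        }
      }
    }
  }
  m
}

## -- scaling and grafting -----------------------------------------------------

#' Scale a morphology about its soma
#'
#' Coordinates are scaled by `factor` about the soma centre; diameters are
#' left untouched (thickness is analysed separately from size). Total cable
#' length scales exactly by `factor`.
#'
#' @param m a [neuron_morphology()].
#' @param factor positive scale factor.
#' @export
scale_morphology <- function(m, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("factor must be a positive scalar")
  for (i in seq_along(m$neurites)) {
    tr <- m$neurites[[i]]
    tr$nodes$x <- m$soma_center[1] + (tr$nodes$x - m$soma_center[1]) * factor
    tr$nodes$y <- m$soma_center[2] + (tr$nodes$y - m$soma_center[2]) * factor
    tr$nodes$z <- m$soma_center[3] + (tr$nodes$z - m$soma_center[3]) * factor
    m$neurites[[i]] <- tr
  }
  m
}

#' Graft an axon onto a dendrite donor
#'
#' Returns a morphology with the dendrites (and soma) of `dendrite_donor` and
#' the axon of `axon_donor`, the axon rigidly translated so its root attaches
#' at the recipient soma surface. Used to pair intact dendritic
#' reconstructions with well-reconstructed axons.
#'
#' @param dendrite_donor,axon_donor [neuron_morphology()] objects.
#' @export
graft_axon <- function(dendrite_donor, axon_donor) {
  ax <- morph_trees(axon_donor, "axon")
  if (!length(ax)) stop("axon donor has no axon tree")
  keep <- Filter(function(tr) tr$type != "axon", dendrite_donor$neurites)
  out <- dendrite_donor
  for (tr in ax) {
    r <- which(tr$nodes$parent == -1L)
    root <- c(tr$nodes$x[r], tr$nodes$y[r], tr$nodes$z[r])
    off <- root - axon_donor$soma_center
    d <- sqrt(sum(off^2))
    u <- if (d > 0) off / d else c(0, -1, 0)
    target <- out$soma_center + u * out$soma_radius
    shift <- target - root
    tr$nodes$x <- tr$nodes$x + shift[1]
    tr$nodes$y <- tr$nodes$y + shift[2]
    tr$nodes$z <- tr$nodes$z + shift[3]
    keep <- c(keep, list(tr))
  }
  out$neurites <- keep
  out
}

#' Filter an axon pool by branch count
#'
#' Keeps morphologies whose axonal branch count exceeds `min_branches`
#' (strictly more), the inclusion rule used when selecting axons good enough
#' to support realistic connectivity.
#'
#' @param pool list of [neuron_morphology()].
#' @param min_branches threshold (default 20); an axon with exactly
#'   `min_branches` branches is dropped.
#' @export
filter_axon_pool <- function(pool, min_branches = 20) {
  Filter(function(m) {
    ax <- morph_trees(m, "axon")
    length(ax) && sum(vapply(ax, tree_branch_count, numeric(1))) > min_branches
  }, pool)
}
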