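#' Construct a persistence barcode
#'
#' The topological morphology descriptor of a neurite tree: one
#' (birth, death) interval per leaf of the tree, where birth is the value of
#' the filtration function (radial or path distance from the root) at the
#' bifurcation where the leaf's component merges into an elder component, and
#' death is the filtration value at the leaf. Exactly one essential bar spans
#' from the root's value to the maximal value reached along the eldest path.
#'
#' @param bars two-column matrix or data.frame (`birth`, `death`) in
#'   micrometres.
#' @param filtration `"radial"` or `"path"`.
#' @param source_id optional identifier of the source tree/neuron.
#' @return object of class `persistence_barcode`: data.frame with columns
#'   `birth`, `death` plus attributes `filtration`, `source_id`.
#' @export
persistence_barcode <- function(bars, filtration = c("radial", "path"),
                                source_id = NULL) {
  filtration <- match.arg(filtration)
  bars <- as.data.frame(bars)
  names(bars)[1:2] <- c("birth", "death")
  if (nrow(bars) && any(bars$birth < 0 | bars$death < 0))
    stop("barcode values must be >= 0")
  structure(bars, filtration = filtration, source_id = source_id,
            class = c("persistence_barcode", "data.frame"))
}

bar_lengths <- function(pb) abs(pb$death - pb$birth)

#' Extract the persistence barcode of a neurite tree
#'
#' Implements the elder rule on the chosen filtration: each leaf starts a
#' component at its filtration value; when components meet at a bifurcation
#' the one whose leaf value is larger survives (ties broken towards the lower
#' node id) and every other child component dies, contributing a bar
#' (f(bifurcation), leaf value). The surviving component of the root gives
#' the essential bar (f(root), max value along the eldest path).
#'
#' @param tree a [neurite_tree()].
#' @param filtration `"radial"` (Euclidean distance from the root) or
#'   `"path"` (path distance along the tree).
#' @return a [persistence_barcode()] with one bar per leaf.
#' @export
extract_barcode <- function(tree, filtration = c("radial", "path")) {
  filtration <- match.arg(filtration)
  nd <- tree$nodes
  if (!nrow(nd)) stop("empty tree")
  f <- if (filtration == "path") tree_path_distance(tree) else
    tree_radial_distance(tree)
  idx <- match(nd$parent, nd$id)
  outdeg <- tabulate(idx[!is.na(idx)], nbins = nrow(nd))
  v <- f              # component value carried up from below
  births <- numeric(0); deaths <- numeric(0)
  # children grouped by parent row; process in reverse topological order
  kids <- vector("list", nrow(nd))
  for (i in seq_len(nrow(nd))) if (!is.na(idx[i]))
    kids[[idx[i]]] <- c(kids[[idx[i]]], i)
  for (i in rev(seq_len(nrow(nd)))) {
    ch <- kids[[i]]
    if (length(ch) == 0L) { v[i] <- f[i]; next }
    if (length(ch) == 1L) { v[i] <- v[ch]; next }
    # elder rule: max v survives; ties -> lower node id
    ord <- order(-v[ch], nd$id[ch])
    surv <- ch[ord[1]]
    die <- ch[ord[-1]]
    births <- c(births, rep(f[i], length(die)))
    deaths <- c(deaths, v[die])
    v[i] <- v[surv]
  }
  r <- which(nd$parent == -1L)
  births <- c(births, f[r])
  deaths <- c(deaths, v[r])
  persistence_barcode(data.frame(birth = births, death = deaths), filtration,
                      source_id = attr(tree, "source_id"))
}

#' Barcode of all dendrites of a neuron
#'
#' Pools the bars of every basal and apical tree of a morphology into one
#' barcode (the per-neuron dendritic descriptor used for population
#' comparisons).
#' @param m a [neuron_morphology()].
#' @param filtration passed to [extract_barcode()].
#' @param types neurite types to include.
#' @export
neuron_barcode <- function(m, filtration = c("radial", "path"),
                           types = c("basal", "apical")) {
  filtration <- match.arg(filtration)
  trees <- morph_trees(m, types)
  if (!length(trees)) stop("no neurites of requested type")
  bars <- do.call(rbind, lapply(trees, function(tr)
    as.data.frame(extract_barcode(tr, filtration))[, c("birth", "death")]))
  persistence_barcode(bars, filtration, source_id = m$meta$subject_id)
}

#' Topological entropy of a barcode
#'
#' Shannon entropy (natural log) of the normalized bar lengths:
#' \deqn{E = -\sum_i (l_i/L) \log(l_i/L)} with \eqn{l_i = |t_i - b_i|} and
#' \eqn{L = \sum_i l_i}. Scale-invariant: uniformly scaling the barcode does
#' not change E. Zero-length bars contribute nothing (0 log 0 = 0).
#'
#' @param pb a [persistence_barcode()].
#' @return entropy in nats, between 0 and log(number of bars).
#' @export
barcode_entropy <- function(pb) {
  l <- bar_lengths(pb)
  L <- sum(l)
  if (!nrow(pb) || L <= 0) stop("entropy undefined: no bars with positive length")
  p <- l[l > 0] / L
  -sum(p * log(p))
}

#' Scale a barcode
#'
#' Uniform scaling multiplies births and deaths by `alpha`; non-uniform
#' scaling multiplies births (bifurcations) by `alpha` and deaths (leaves) by
#' `beta`. Non-uniform scaling can push a death below its birth; such bar
#' sets are flagged via attribute `"invalid"` (TRUE) rather than repaired.
#'
#' @param pb a [persistence_barcode()].
#' @param alpha positive factor applied to births (and deaths if `beta`
#'   missing).
#' @param beta optional positive factor applied to deaths.
#' @export
scale_barcode <- function(pb, alpha, beta = NULL) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (!is.null(beta) && beta <= 0) stop("beta must be > 0")
  b2 <- pb$birth * alpha
  d2 <- pb$death * if (is.null(beta)) alpha else beta
  out <- persistence_barcode(data.frame(birth = b2, death = d2),
                             attr(pb, "filtration"), attr(pb, "source_id"))
  if (!is.null(beta)) {
    crossed <- (pb$death >= pb$birth & d2 < b2) | (pb$death <= pb$birth & d2 > b2)
    attr(out, "invalid") <- any(crossed)
  }
  out
}

## -- persistence images -------------------------------------------------------

#' Persistence image of a barcode
#'
#' Sum of isotropic Gaussian kernels centred on the (birth, death) points of
#' the diagram, sampled on a regular grid. Deterministic.
#'
#' @param pb a [persistence_barcode()] (or a list of them, whose images are
#'   summed).
#' @param bounds list with `x = c(min,max)`, `y = c(min,max)` in micrometres;
#'   defaults to the data range padded by 5%.
#' @param resolution pixels per axis (default 100).
#' @param kernel_sigma Gaussian sd in micrometres; default 1/20 of the larger
#'   axis range.
#' @param normalize if TRUE the image is divided by its sum.
#' @return object of class `persistence_image`: list with `grid` (resolution
#'   x resolution matrix, x = birth along rows, y = death along columns),
#'   `xs`, `ys`, `bounds`, `kernel_sigma`.
#' @export
persistence_image <- function(pb, bounds = NULL, resolution = 100,
                              kernel_sigma = NULL, normalize = FALSE) {
  if (resolution < 2) stop("resolution must be >= 2")
  pbs <- if (inherits(pb, "persistence_barcode")) list(pb) else pb
  pts <- do.call(rbind, lapply(pbs, function(p)
    cbind(p$birth, p$death)))
  if (is.null(bounds)) bounds <- image_bounds(pbs)
  xs <- seq(bounds$x[1], bounds$x[2], length.out = resolution)
  ys <- seq(bounds$y[1], bounds$y[2], length.out = resolution)
  if (is.null(kernel_sigma))
    kernel_sigma <- max(diff(bounds$x), diff(bounds$y)) / 20
  grid <- matrix(0, resolution, resolution)
  if (!is.null(pts) && nrow(pts)) {
    s2 <- 2 * kernel_sigma^2
    for (i in seq_len(nrow(pts))) {
      gx <- exp(-(xs - pts[i, 1])^2 / s2)
      gy <- exp(-(ys - pts[i, 2])^2 / s2)
      grid <- grid + outer(gx, gy) / (pi * s2)
    }
  }
  if (normalize && sum(grid) > 0) grid <- grid / sum(grid)
  structure(list(grid = grid, xs = xs, ys = ys, bounds = bounds,
                 kernel_sigma = kernel_sigma), class = "persistence_image")
}

#' Common image bounds for one or more barcode populations
#'
#' Union of the (birth, death) ranges padded by 5% on each side (and clamped
#' below at 0 on the birth axis when all births are non-negative).
#' @param ... barcodes, or lists of barcodes.
#' @export
image_bounds <- function(...) {
  pbs <- unlist(lapply(list(...), function(x)
    if (inherits(x, "persistence_barcode")) list(x) else x), recursive = FALSE)
  pts <- do.call(rbind, lapply(pbs, function(p) cbind(p$birth, p$death)))
  if (is.null(pts) || !nrow(pts)) return(list(x = c(0, 1), y = c(0, 1)))
  pad <- function(r) {
    w <- diff(r); if (w == 0) w <- max(abs(r), 1)
    c(r[1] - 0.05 * w, r[2] + 0.05 * w)
  }
  list(x = pad(range(pts[, 1])), y = pad(range(pts[, 2])))
}

#' Population persistence image
#'
#' The image of a population is the sum of the images of its members (all on
#' the same grid), so image linearity holds exactly.
#' @param pbs list of [persistence_barcode()].
#' @param bounds,resolution,kernel_sigma see [persistence_image()].
#' @export
population_image <- function(pbs, bounds = NULL, resolution = 100,
                             kernel_sigma = NULL) {
  persistence_image(pbs, bounds = bounds, resolution = resolution,
                    kernel_sigma = kernel_sigma)
}

#' L1 distance between two persistence images
#'
#' Sum of absolute pixel differences; both images must share the same grid.
#' @param a,b [persistence_image()] objects.
#' @export
image_distance <- function(a, b) {
  if (!isTRUE(all.equal(a$xs, b$xs)) || !isTRUE(all.equal(a$ys, b$ys)))
    stop("persistence images are on different grids")
  sum(abs(a$grid - b$grid))
}

## -- scaling optimization -----------------------------------------------------

#' Fit a scaling transform between two barcode populations
#'
#' Finds the factor(s) that scale the source population (e.g. mouse) so that
#' its population persistence image is as close as possible (L1 pixel
#' distance) to the target population's (e.g. human). Uniform mode fits a
#' single factor alpha applied to births and deaths; non-uniform mode fits
#' alpha (births) and beta (deaths) independently. The image grid is fixed to
#' the union bounds of both populations (target and source), so the objective
#' is deterministic; optimization is derivative-free (golden-section in 1D,
#' Nelder-Mead in 2D from (1, 1)).
#'
#' @param pop_source,pop_target lists of [persistence_barcode()].
#' @param mode `"uniform"` or `"nonuniform"`.
#' @param resolution image resolution (default 100).
#' @param interval search interval for alpha (and beta), default `c(0.1, 10)`.
#' @return list with `alpha`, `beta` (NA for uniform), `distance` (achieved
#'   L1 distance), `converged`.
#' @export
fit_scaling <- function(pop_source, pop_target,
                        mode = c("uniform", "nonuniform"),
                        resolution = 100, interval = c(0.1, 10)) {
  mode <- match.arg(mode)
  if (!length(pop_source) || !length(pop_target))
    stop("both populations must be non-empty")
  bounds <- image_bounds(pop_source, pop_target)
  sigma <- max(diff(bounds$x), diff(bounds$y)) / 20
  target_img <- population_image(pop_target, bounds = bounds,
                                 resolution = resolution, kernel_sigma = sigma)
  objective <- function(alpha, beta = NULL) {
    scaled <- lapply(pop_source, scale_barcode, alpha = alpha, beta = beta)
    image_distance(population_image(scaled, bounds = bounds,
                                    resolution = resolution,
                                    kernel_sigma = sigma), target_img)
  }
  # the objective can plateau once the scaled mass leaves the grid, so a
  # coarse log-spaced scan brackets the global minimum before refining
  grid_a <- exp(seq(log(interval[1]), log(interval[2]), length.out = 41))
  if (mode == "uniform") {
    vals <- vapply(grid_a, objective, numeric(1))
    k <- which.min(vals)
    lo <- grid_a[max(1, k - 1)]; hi <- grid_a[min(length(grid_a), k + 1)]
    opt <- optimize(function(a) objective(a), interval = c(lo, hi), tol = 1e-5)
    list(alpha = opt$minimum, beta = NA_real_, distance = opt$objective,
         converged = TRUE)
  } else {
    res <- optim(c(1, 1), function(p) {
      if (any(p <= 0)) return(.Machine$double.xmax)
      objective(p[1], p[2])
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-10, maxit = 500))
    if (res$convergence != 0)
      warning("scaling optimization did not converge; returning best so far")
    list(alpha = res$par[1], beta = res$par[2], distance = res$value,
         converged = res$convergence == 0)
  }
}

## -- Gaussian mixture approximation ------------------------------------------

#' Approximate pooled persistence diagrams by a Gaussian mixture
#'
#' Pools the (birth, death) points of a population of barcodes and fits a
#' maximum-likelihood Gaussian mixture with `n_centers` full-covariance
#' components (EM via the mclust package, initialized from a seeded k-means
#' partition). Degenerate clusters trigger a refit under mclust's
#' conjugate-prior covariance regularization, flagged in the result.
#'
#' @param pbs list of [persistence_barcode()] (or a single one).
#' @param n_centers number of mixture components (default 3).
#' @param seed integer seed for the (deterministic) initialization.
#' @return list with `weights` (sums to 1), `means` (n_centers x 2),
#'   `covariances` (2 x 2 x n_centers), `loglik`, `n_points`.
#' @export
fit_diagram_mixture <- function(pbs, n_centers = 3, seed = 1) {
  if (inherits(pbs, "persistence_barcode")) pbs <- list(pbs)
  pts <- do.call(rbind, lapply(pbs, function(p) cbind(p$birth, p$death)))
  if (is.null(pts) || nrow(pts) < n_centers)
    stop("need at least n_centers pooled diagram points")
  set.seed(seed)
  if (n_centers == 1L) {
    z <- matrix(1, nrow(pts), 1)
  } else {
    km <- kmeans(pts, n_centers, nstart = 10)
    z <- mclust::unmap(km$cluster, groups = seq_len(n_centers))
  }
  fit <- mclust::meVVV(data = pts, z = z)
  regularized <- FALSE
  if (is.null(fit$loglik) || is.na(fit$loglik)) {
    # degenerate cluster: refit with the conjugate-prior regularization
    fit <- mclust::meVVV(data = pts, z = z, prior = mclust::priorControl())
    regularized <- TRUE
    if (is.null(fit$loglik) || is.na(fit$loglik)) stop("mixture fit failed")
  }
  list(weights = as.numeric(fit$parameters$pro),
       means = t(fit$parameters$mean),
       covariances = fit$parameters$variance$sigma,
       loglik = fit$loglik, n_points = nrow(pts), regularized = regularized)
}

## -- complexity profile -------------------------------------------------------

#' Per-bin topological complexity of a population
#'
#' For each distance bin, reports (i) the mean over neurons of the number of
#' bars whose span intersects the bin ("bars alive"), and (ii) the entropy of
#' the bar mass restricted to the bin (each bar contributes the length of its
#' overlap with the bin, and the entropy of those normalized overlaps is
#' computed as in [barcode_entropy()]).
#'
#' @param pbs list of [persistence_barcode()].
#' @param bin_edges increasing vector of bin edges in micrometres.
#' @return data.frame with `bin_lo`, `bin_hi`, `mean_alive`, `entropy`.
#' @export
complexity_profile <- function(pbs, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) stop("bin_edges must be increasing")
  nb <- length(bin_edges) - 1L
  alive <- matrix(0, nrow = max(length(pbs), 1L), ncol = nb)
  mass <- vector("list", nb)
  for (k in seq_len(nb)) mass[[k]] <- numeric(0)
  for (i in seq_along(pbs)) {
    pb <- pbs[[i]]
    lo <- pmin(pb$birth, pb$death); hi <- pmax(pb$birth, pb$death)
    for (k in seq_len(nb)) {
      ov <- pmin(hi, bin_edges[k + 1]) - pmax(lo, bin_edges[k])
      inbin <- ov > 0
      alive[i, k] <- sum(inbin)
      if (any(inbin)) mass[[k]] <- c(mass[[k]], ov[inbin])
    }
  }
  ent <- vapply(mass, function(l) {
    L <- sum(l)
    if (L <= 0) return(0)
    p <- l / L
    -sum(p * log(p))
  }, numeric(1))
  data.frame(bin_lo = bin_edges[-length(bin_edges)], bin_hi = bin_edges[-1],
             mean_alive = if (length(pbs)) colMeans(alive) else rep(0, nb),
             entropy = ent)
}

#' Normalize a barcode to unit maximal death
#'
#' Uniform scaling by 1/max(death); used before size-free comparisons of
#' populations of different extents.
#' @param pb a [persistence_barcode()].
#' @export
normalize_barcode <- function(pb) {
  m <- max(pb$death)
  if (m <= 0) stop("cannot normalize barcode with non-positive maximal death")
  scale_barcode(pb, 1 / m)
}

#' Export a barcode as CSV (birth, death per row)
#' @param pb a [persistence_barcode()].
#' @param path output path.
#' @export
write_barcode_csv <- function(pb, path) {
  write.csv(as.data.frame(pb)[, c("birth", "death")], path, row.names = FALSE)
  invisible(path)
}
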