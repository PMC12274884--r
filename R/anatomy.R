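#' Species parameter registry
#'
#' Returns the layer 2/3 anatomical parameters for one species, read from the
#' versioned JSON registry shipped with the package: neuron density (/mm^3),
#' excitatory/inhibitory fractions, layer thickness (um), synapse volume
#' density (/mm^3), synapse linear density on dendrites (/um), synapses per
#' neuron and per connection, and the default hexagonal-column cell counts.
#'
#' @param species `"human"` or `"mouse"`.
#' @return named list of parameters.
#' @export
species_params <- function(species = c("human", "mouse")) {
  species <- match.arg(species)
  reg <- jsonlite::read_json(system.file("extdata", "species_params.json",
                                         package = "dendronet"),
                             simplifyVector = TRUE)
  c(reg[[species]], reg$shared)
}

UM3_PER_MM3 <- 1e9

#' Closed-form mean nearest-neighbour distance of a uniform point process
#'
#' For particles at number density `N_v` (per unit volume) in an unbounded
#' medium, the expected distance to the nearest neighbour is
#' `0.554 * N_v^(-1/3)`.
#'
#' @param density number density per mm^3 (set `per = "um3"` to pass per um^3).
#' @param per unit of the supplied density.
#' @return mean nearest-neighbour distance in micrometres.
#' @export
nn_distance_formula <- function(density, per = c("mm3", "um3")) {
  per <- match.arg(per)
  if (density <= 0) stop("density must be > 0")
  nv <- if (per == "mm3") density / UM3_PER_MM3 else density
  0.554 * nv^(-1 / 3)
}

#' Simulated mean nearest-neighbour distance in a bounded box
#'
#' Generates `n_instances` uniform point processes at the given density in a
#' rectangular volume and averages, over instances, the per-point mean
#' distance to the nearest other point in the same instance. No edge
#' correction is applied, so boundary effects (larger distances in thin
#' slabs) are part of the estimate, as they are in tissue slabs of finite
#' thickness.
#'
#' @param density neurons per mm^3.
#' @param box numeric length-3, box edge lengths in micrometres.
#' @param n_instances number of independent instances (default 100).
#' @param seed integer seed.
#' @return list with `mean` and `sd` (across instances) in micrometres, and
#'   `n_points` per instance.
#' @export
nn_distance_simulated <- function(density, box, n_instances = 100, seed = 1) {
  stopifnot(length(box) == 3, all(box > 0), n_instances >= 1)
  vol_mm3 <- prod(box) / UM3_PER_MM3
  n <- round(density * vol_mm3)
  if (n < 2) stop("box too small: fewer than 2 expected points")
  if (n < 10) warning("fewer than 10 expected points per instance")
  set.seed(seed)
  means <- vapply(seq_len(n_instances), function(i) {
    pts <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
    cpp_mean_nn_distance(pts)
  }, numeric(1))
  list(mean = mean(means), sd = sd(means), n_points = n)
}

#' Dendritic length density of the neuropil
#'
#' Total dendritic cable length per tissue volume, from the synapse volume
#' density and the linear density of synapses on dendrites:
#' `d_dend = S_v / d_syn`.
#'
#' @param S_v synapses per mm^3.
#' @param d_syn synapses per um of dendrite.
#' @param unit `"m_per_mm3"` (metres of cable per mm^3, the reporting unit)
#'   or `"um_per_mm3"`.
#' @export
dendrite_length_density <- function(S_v, d_syn, unit = c("m_per_mm3", "um_per_mm3")) {
  unit <- match.arg(unit)
  if (d_syn <= 0) stop("d_syn must be > 0")
  um <- S_v / d_syn
  if (unit == "m_per_mm3") um / 1e6 else um
}

#' Axonal length density of the neuropil
#'
#' `d_axon = S_v / (d_bouton * n_syn_per_bouton)`. The number of synapses per
#' bouton is experimentally inconclusive, so no species value is asserted by
#' the registry; the formula is provided for sensitivity analyses.
#'
#' @param S_v synapses per mm^3.
#' @param d_bouton boutons per um of axon.
#' @param syn_per_bouton synapses per bouton.
#' @param unit see [dendrite_length_density()].
#' @export
axon_length_density <- function(S_v, d_bouton, syn_per_bouton = 1,
                                unit = c("m_per_mm3", "um_per_mm3")) {
  unit <- match.arg(unit)
  if (d_bouton <= 0 || syn_per_bouton <= 0)
    stop("d_bouton and syn_per_bouton must be > 0")
  um <- S_v / (d_bouton * syn_per_bouton)
  if (unit == "m_per_mm3") um / 1e6 else um
}

#' Expected number of neighbours within a radius
#'
#' For a uniform distribution at `density` per mm^3, the expected number of
#' other somata within `radius` um of a cell. The unbounded form is
#' `(4/3) pi r^3 * density`. With `thickness` given, the sphere is clipped to
#' the layer slab: at a fixed `depth` below the layer top the two spherical
#' caps protruding from the slab are subtracted; with `depth = NULL` the
#' expectation is averaged over a uniformly distributed depth, which is what
#' a homogeneously populated column realizes.
#'
#' @param density neurons per mm^3.
#' @param radius radius in um (vectorized).
#' @param thickness optional slab thickness in um.
#' @param depth optional cell depth in um (only with `thickness`); `NULL`
#'   averages over a uniform depth.
#' @export
expected_neighbor_count <- function(density, radius, thickness = NULL,
                                    depth = NULL) {
  if (any(radius < 0)) stop("radius must be >= 0")
  nv <- density / UM3_PER_MM3
  if (is.null(thickness)) return(4 / 3 * pi * radius^3 * nv)
  cap <- function(r, a) { # cap beyond a plane at distance a from the centre
    h <- pmax(r - a, 0)
    pi * h^2 * (3 * r - h) / 3
  }
  vol_at <- function(r, z) 4 / 3 * pi * r^3 - cap(r, z) - cap(r, thickness - z)
  if (is.null(depth)) {
    zs <- seq(0, thickness, length.out = 401)
    vapply(radius, function(r) mean(vol_at(r, zs)) * nv, numeric(1))
  } else {
    vapply(radius, function(r) vol_at(r, depth) * nv, numeric(1))
  }
}

#' Derived anatomy table for both species
#'
#' Computes the nearest-neighbour distances (closed form and simulated, for
#' all neurons, pyramidal cells and interneurons) and the dendritic length
#' density for human and mouse from the registry parameters.
#'
#' @param n_instances point-process instances for the simulated distances.
#' @param seed integer seed.
#' @param simulate if FALSE only closed-form values are computed.
#' @return data.frame with one row per (species, population).
#' @export
anatomy_table <- function(n_instances = 100, seed = 1, simulate = TRUE) {
  rows <- list()
  for (sp in c("human", "mouse")) {
    p <- species_params(sp)
    box <- c(1000, 1000, p$layer_thickness)
    pops <- list(all = 1, PC = p$excitatory_fraction, IN = p$inhibitory_fraction)
    for (nm in names(pops)) {
      dens <- p$neuron_density * pops[[nm]]
      sim <- if (simulate)
        nn_distance_simulated(dens, box, n_instances, seed)$mean else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, population = nm, density_mm3 = dens,
        nn_formula_um = nn_distance_formula(dens),
        nn_simulated_um = sim,
        dendrite_density_m_mm3 = if (nm == "all")
          dendrite_length_density(p$synapse_volume_density,
                                  p$synapse_linear_density) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
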