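## Dendritic memory capacity: the number of distinguishable input-weight
## configurations of a dendrite, in bits. In the linear model all s = m*k
## synapses sum at the soma; in the non-linear model each of the m subunits
## (branches) applies its own non-linearity to its k synapses, which greatly
## enlarges the combination space. Binomials are evaluated in log-space
## (lchoose): the inner binomial alone can exceed 1e100, so exact integer
## arithmetic is impossible, but log-space evaluation is accurate to ~1e-12
## relative.

log2choose <- function(n, k) lchoose(n, k) / log(2)

#' Memory capacity of the linear dendrite model
#'
#' `C_L = 2 * log2( choose(s + d - 1, s) )` bits for `s` synaptic contacts
#' drawn from `d` distinct input lines (multisets of size s from d types).
#' The arrangement of synapses over branches is irrelevant in this model.
#'
#' @param s total synaptic contacts (>= 1).
#' @param d distinct input lines (>= 1).
#' @return capacity in bits.
#' @export
memory_capacity_linear <- function(s, d) {
  stopifnot(s >= 1, d >= 1)
  2 * log2choose(s + d - 1, s)
}

#' Memory capacity of the non-linear dendrite model
#'
#' `C_N = 2 * log2( choose( choose(k + d - 1, k) + m - 1, m ) )` bits for
#' `m` non-linear subunits with `k` synapses each and `d` input lines: first
#' count the input multisets available to one subunit, then the multisets of
#' subunit configurations. Reduces to the linear model at `m = 1` (with
#' `s = k`). At fixed total synapse count `s = m*k`, capacity grows with the
#' number of subunits `m` throughout the regime where each subunit keeps
#' several synapses, and falls off again as `k` approaches 1 (the symmetric
#' extreme `m = s, k = 1` equals `m = 1`).
#'
#' @param m dendritic subunits (>= 1).
#' @param k synapses per subunit (>= 1).
#' @param d distinct input lines (>= 1).
#' @return capacity in bits.
#' @export
memory_capacity_nonlinear <- function(m, k, d) {
  stopifnot(m >= 1, k >= 1, d >= 1)
  inner <- choose(k + d - 1, k)
  if (is.finite(inner) && inner < 2^53)
    return(2 * log2choose(inner + m - 1, m))
  # inner too large for a double: choose(inner + m - 1, m) ~ inner^m / m!
  linner <- lchoose(k + d - 1, k)
  2 * (m * linner - lgamma(m + 1)) / log(2)
}

#' Correlation between memory capacity and topological complexity
#'
#' Per neuron: complexity is the entropy of its dendritic persistence
#' barcode; capacity is the non-linear model's capacity with `m` = number of
#' dendritic terminal branches (computational subunits), and `k` = the
#' neuron's total dendritic length times the synapse linear density, split
#' evenly over the subunits (rounded, minimum 1). Returns the Spearman rank
#' correlation of the two series.
#'
#' @param population list of [neuron_morphology()] (>= 3).
#' @param synapse_linear_density synapses per um of dendrite.
#' @param d distinct input lines (default 10).
#' @param filtration barcode filtration (default `"path"`).
#' @return list with `correlation`, `capacity`, `complexity`, `degenerate`
#'   (TRUE when either series is constant, in which case `correlation` is
#'   NA).
#' @export
capacity_complexity_correlation <- function(population, synapse_linear_density,
                                            d = 10, filtration = "path") {
  stopifnot(length(population) >= 3)
  complexity <- numeric(length(population))
  capacity <- numeric(length(population))
  for (i in seq_along(population)) {
    m_ <- population[[i]]
    pb <- neuron_barcode(m_, filtration)
    complexity[i] <- barcode_entropy(pb)
    dends <- morph_trees(m_, dendrite_types)
    m_sub <- sum(vapply(dends, tree_n_leaves, numeric(1)))
    syn <- total_dendritic_length(m_) * synapse_linear_density
    k <- max(1L, round(syn / m_sub))
    capacity[i] <- memory_capacity_nonlinear(m_sub, k, d)
  }
  degen <- sd(complexity) == 0 || sd(capacity) == 0
  list(correlation = if (degen) NA_real_ else
         cor(capacity, complexity, method = "spearman"),
       capacity = capacity, complexity = complexity, degenerate = degen)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Wraps the two-sided two-sample KS test; the p-value is floored at the
#' machine epsilon so underflowing comparisons report the numerical accuracy
#' instead of an exact zero.
#'
#' @param sample_a,sample_b numeric vectors (>= 2 values each).
#' @return list with `statistic` and `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("both samples need at least 2 values")
  kt <- suppressWarnings(ks.test(sample_a, sample_b))
  list(statistic = unname(kt$statistic),
       p_value = max(unname(kt$p.value), .Machine$double.eps))
}

#' Within- versus between-group barcode variability
#'
#' Mean pairwise persistence-image distance among barcodes of the same group
#' versus different groups (e.g. neurons of the same versus different
#' subjects). A ratio below 1 means same-group neurons are more alike.
#' Singleton groups are dropped with a warning.
#'
#' @param barcodes list of [persistence_barcode()].
#' @param group_labels vector of group labels, one per barcode.
#' @param resolution image resolution (default 40; pairwise distances only
#'   need a coarse grid).
#' @return list with `within_mean`, `between_mean`, `ratio`.
#' @export
group_variability <- function(barcodes, group_labels, resolution = 40) {
  stopifnot(length(barcodes) == length(group_labels))
  tab <- table(group_labels)
  if (any(tab < 2)) {
    warning("dropping singleton groups: ",
            paste(names(tab)[tab < 2], collapse = ", "))
    keep <- group_labels %in% names(tab)[tab >= 2]
    barcodes <- barcodes[keep]
    group_labels <- group_labels[keep]
  }
  if (length(unique(group_labels)) < 2)
    stop("need at least two groups with >= 2 members")
  bounds <- image_bounds(barcodes)
  imgs <- lapply(barcodes, persistence_image, bounds = bounds,
                 resolution = resolution)
  nW <- 0; sW <- 0; nB <- 0; sB <- 0
  for (i in seq_along(imgs)[-length(imgs)])
    for (j in (i + 1):length(imgs)) {
      d <- image_distance(imgs[[i]], imgs[[j]])
      if (group_labels[i] == group_labels[j]) { sW <- sW + d; nW <- nW + 1 }
      else { sB <- sB + d; nB <- nB + 1 }
    }
  list(within_mean = sW / nW, between_mean = sB / nB,
       ratio = (sW / nW) / (sB / nB))
}

#' Species comparison report
#'
#' Bundles the cross-species quantities computed by the package for two
#' synthetic populations: morphometric summaries with KS p-values, barcode
#' entropies, and the capacity-complexity correlation per population.
#'
#' @param pop_a,pop_b lists of [neuron_morphology()].
#' @param labels population labels.
#' @param synapse_linear_density_a,synapse_linear_density_b synapses/um used
#'   for the capacity computation of each population.
#' @return list with `morphometrics` (data.frame with KS tests), `entropy`
#'   (per-population values + KS), `capacity_correlation`.
#' @export
species_report <- function(pop_a, pop_b, labels = c("a", "b"),
                           synapse_linear_density_a = 0.88,
                           synapse_linear_density_b = 2.15) {
  total_len <- function(pop) vapply(pop, total_dendritic_length, numeric(1))
  ent <- function(pop) vapply(pop, function(m)
    barcode_entropy(neuron_barcode(m, "path")), numeric(1))
  la <- total_len(pop_a); lb <- total_len(pop_b)
  ea <- ent(pop_a); eb <- ent(pop_b)
  ks_len <- ks_compare(la, lb)
  ks_ent <- ks_compare(ea, eb)
  list(
    morphometrics = data.frame(
      measure = "total_dendritic_length",
      mean_a = mean(la), sd_a = sd(la), mean_b = mean(lb), sd_b = sd(lb),
      ks_statistic = ks_len$statistic, p_value = ks_len$p_value),
    entropy = data.frame(
      measure = "barcode_entropy",
      mean_a = mean(ea), sd_a = sd(ea), mean_b = mean(eb), sd_b = sd(eb),
      ks_statistic = ks_ent$statistic, p_value = ks_ent$p_value),
    labels = labels,
    capacity_correlation = c(
      a = capacity_complexity_correlation(pop_a, synapse_linear_density_a)$correlation,
      b = capacity_complexity_correlation(pop_b, synapse_linear_density_b)$correlation))
}
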