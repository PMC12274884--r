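#' L1 distance between simplex-count profiles on a log scale
#'
#' Profiles are padded with zeros to a common length and compared as
#' `sum |log1p(a) - log1p(b)|`; the log scale weights the orders-of-magnitude
#' differences that distinguish the profiles instead of letting the largest
#' dimension dominate.
#'
#' @param a,b numeric vectors of simplex counts by dimension.
#' @export
simplex_profile_distance <- function(a, b) {
  n <- max(length(a), length(b))
  pad <- function(x) c(x, rep(0, n - length(x)))
  sum(abs(log1p(pad(a)) - log1p(pad(b))))
}

#' Desk-scale cross-species circuit pipeline
#'
#' Runs the whole comparison end-to-end on synthetic populations at reduced
#' cell counts: builds a human-like and a mouse-like hexagonal column (cell
#' counts scaled from the full-size specs at fixed density, so inter-somatic
#' distances match full scale), populates them with cloned synthetic
#' morphologies, computes central-column axo-dendritic appositions, prunes
#' both connectomes to the same target density, counts directed simplices of
#' the pyramidal-cell subnetworks, builds the hybrid circuit (human
#' dimensions and axons, mouse dendrites scaled to the human mean length),
#' and generates a density-matched directed Erdos-Renyi control for the
#' human-like pyramidal subnetwork.
#'
#' @param n_total approximate cells in the central column (default 750).
#' @param pool_size donor morphologies per species and class (default 6).
#' @param seed integer seed driving every random stage.
#' @param target_density pruning target (default 0.04).
#' @param max_dim simplex dimension cap (default 15).
#' @param threshold apposition distance in um (default 2).
#' @return list with per-circuit simplex profiles (`human`, `mouse`,
#'   `hybrid`, `er_control`), subnetwork statistics, and the profile
#'   distances of the hybrid to the human-like and mouse-like circuits.
#' @export
desk_pipeline <- function(n_total = 750, pool_size = 6, seed = 1,
                          target_density = 0.04, max_dim = 15, threshold = 2) {
  pools <- list(
    human = list(PC = generate_population(default_preset("human", "PC"),
                                          pool_size, seed = seed + 11L),
                 IN = generate_population(default_preset("human", "IN"),
                                          pool_size, seed = seed + 12L)),
    mouse = list(PC = generate_population(default_preset("mouse", "PC"),
                                          pool_size, seed = seed + 13L),
                 IN = generate_population(default_preset("mouse", "IN"),
                                          pool_size, seed = seed + 14L)))
  specs <- list(
    human = species_column_spec("human", scale = n_total / 15000),
    mouse = species_column_spec("mouse", scale = n_total / 17900))

  analyze <- function(circ) {
    conn <- compute_appositions(circ, threshold = threshold)
    raw_density <- subnetwork_density(conn)
    conn <- prune_to_density(conn, target_density, seed = seed)
    pc <- class_nodes(conn, "PC")
    inn <- class_nodes(conn, "IN")
    list(connectome = conn,
         raw_density = raw_density,
         pc_density = subnetwork_density(conn, pc),
         in_density = subnetwork_density(conn, inn),
         pc_in_degree = in_degree_distribution(conn, pc),
         pc_simplices = count_directed_simplices(
           subset_connectome(conn, pc), max_dim),
         in_simplices = count_directed_simplices(
           subset_connectome(conn, inn), max_dim))
  }

  circs <- list(
    human = assign_morphologies(build_circuit(specs$human, seed = seed + 1L),
                                pools$human, seed = seed + 1L),
    mouse = assign_morphologies(build_circuit(specs$mouse, seed = seed + 2L),
                                pools$mouse, seed = seed + 2L),
    hybrid = build_hybrid_circuit(specs$human, pools$mouse, pools$human,
                                  seed = seed + 3L))
  res <- lapply(circs, analyze)

  pc_h <- class_nodes(res$human$connectome, "PC")
  er <- erdos_renyi_directed(length(pc_h), res$human$pc_density,
                             seed = seed + 4L)
  er_counts <- count_directed_simplices(er, max_dim)

  list(human = res$human, mouse = res$mouse, hybrid = res$hybrid,
       er_control = list(simplices = er_counts,
                         n = length(pc_h), density = res$human$pc_density),
       hybrid_to_mouse = simplex_profile_distance(res$hybrid$pc_simplices,
                                                  res$mouse$pc_simplices),
       hybrid_to_human = simplex_profile_distance(res$hybrid$pc_simplices,
                                                  res$human$pc_simplices))
}

#' Restrict a connectome to a node subset
#'
#' Relabels the subset nodes 1..length(subset) and keeps edges internal to
#' the subset.
#' @param conn a [connectome()].
#' @param nodes node indices to keep.
#' @export
subset_connectome <- function(conn, nodes) {
  e <- conn$edges
  keep <- e$src %in% nodes & e$dst %in% nodes
  connectome(length(nodes),
             data.frame(src = match(e$src[keep], nodes),
                        dst = match(e$dst[keep], nodes),
                        appositions = e$appositions[keep]),
             cell_class = conn$cell_class[nodes],
             cell_ids = conn$cell_ids[nodes])
}
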