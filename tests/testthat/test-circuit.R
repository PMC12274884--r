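test_that("hexagonal prism volumes match the closed form", {
  expect_equal(hex_prism_volume(1, 1), 3 * sqrt(3) / 2 / 1e9)
  expect_equal(round(hex_prism_volume(476, 1070), 1), 0.6)
  expect_equal(hex_prism_volume(476, 1070), 0.6299, tolerance = 1e-3)
  expect_equal(hex_prism_volume(476, 235), 0.1384, tolerance = 1e-3)
})

test_that("circuits place the specified cell counts uniformly inside the prisms", {
  spec <- species_column_spec("human")
  expect_equal(spec$n_pc, 10500)
  expect_equal(spec$n_in, 4500)
  spec_m <- species_column_spec("mouse")
  expect_equal(spec_m$n_pc, 15200)
  expect_equal(spec_m$n_in, 2700)
  spec_r <- species_column_spec("mouse", counts = "results")
  expect_equal(spec_r$n_pc, 14377)
  expect_equal(spec_r$n_in, 2724)

  circ <- build_circuit(spec, seed = 2)
  cen <- circ$cells[circ$cells$column == 1, ]
  expect_equal(sum(cen$cell_class == "PC"), 10500)
  expect_equal(sum(cen$cell_class == "IN"), 4500)
  expect_equal(nrow(circ$cells), 7 * 15000)
  expect_true(all(dendronet:::hex_inside(cen$x, cen$y, spec$side)))
  expect_true(all(cen$z >= 0 & cen$z <= spec$height))

  # uniformity: equal-volume z-slabs hold equal counts (chi-square)
  slab <- cut(cen$z, seq(0, spec$height, length.out = 5))
  expect_gt(chisq.test(table(slab))$p.value, 0.001)
  # empirical density in a central sub-box matches the spec density within a few %
  sub <- abs(cen$x) < 150 & abs(cen$y) < 150 & cen$z > 200 & cen$z < 800
  dens_spec <- 15000 / hex_prism_volume(spec$side, spec$height)
  dens_sub <- sum(sub) / (300 * 300 * 600 / 1e9)
  expect_lt(abs(dens_sub - dens_spec) / dens_spec, 0.05)
})

test_that("morphology assignment clones donors deterministically", {
  pc <- generate_population(default_preset("mouse", "PC"), 2, seed = 3)
  spec <- column_spec(side = 80, height = 150, n_pc = 6, n_in = 0, n_columns = 1)
  circ <- build_circuit(spec, seed = 4)

  plain <- assign_morphologies(circ, list(PC = pc), jitter_sd = 0,
                               rotate = FALSE, seed = 5)
  i <- 1L
  segs <- dendronet:::cell_segments(plain, i)
  donor <- pc[[plain$assignment$donor[i]]]
  pos <- unlist(plain$cells[i, c("x", "y", "z")])
  dends <- do.call(rbind, lapply(dendronet:::morph_trees(donor, c("basal", "apical")),
    function(tr) {
      nd <- tr$nodes
      p <- sweep(cbind(nd$x, nd$y, nd$z), 2, donor$soma_center)
      idx <- match(nd$parent, nd$id); has <- which(!is.na(idx))
      cbind(p[idx[has], , drop = FALSE], p[has, , drop = FALSE])
    }))
  expect_equal(unname(segs$dend),
               unname(sweep(dends, 2, rep(pos, 2), `+`)), tolerance = 1e-9)

  a1 <- assign_morphologies(circ, list(PC = pc), seed = 7)
  a2 <- assign_morphologies(circ, list(PC = pc), seed = 7)
  expect_identical(a1$assignment, a2$assignment)

  # per-node jitter inflates cable length by about 3*sigma^2/l per segment
  # (l = 10 um sampling); check the empirical inflation sits within twice
  # that second-order bound and shrinks quadratically with sigma
  seg_len <- function(s) sum(sqrt(rowSums((s[, 4:6] - s[, 1:3])^2)))
  jit <- assign_morphologies(circ, list(PC = pc), jitter_sd = 1,
                             rotate = FALSE, seed = 8)
  L0 <- total_dendritic_length(pc[[jit$assignment$donor[1]]])
  infl1 <- (seg_len(dendronet:::cell_segments(jit, 1)$dend) - L0) / L0
  expect_gt(infl1, 0)
  expect_lt(infl1, 2 * 3 * 1^2 / 10^2)
  tiny <- assign_morphologies(circ, list(PC = pc), jitter_sd = 0.1,
                              rotate = FALSE, seed = 8)
  L0t <- total_dendritic_length(pc[[tiny$assignment$donor[1]]])
  expect_lt(abs(seg_len(dendronet:::cell_segments(tiny, 1)$dend) - L0t) / L0t,
            0.002)

  expect_error(assign_morphologies(circ, list(IN = pc), seed = 1), "PC")
})

test_that("apposition detection applies the distance threshold exactly", {
  near <- compute_appositions(two_cell_circuit(1), threshold = 2)
  expect_equal(nrow(near$edges), 1)
  expect_equal(near$edges$src, 1)
  expect_equal(near$edges$dst, 2)
  expect_equal(near$edges$appositions, 1)
  far <- compute_appositions(two_cell_circuit(3), threshold = 2)
  expect_equal(nrow(far$edges), 0)
})

test_that("the spatial index reproduces the brute-force apposition oracle", {
  circ <- small_circuit(n_pc = 12, n_in = 4, seed = 5)
  fast <- compute_appositions(circ)
  slow <- compute_appositions(circ, brute = TRUE)
  expect_identical(fast$edges, slow$edges)
  expect_gt(nrow(fast$edges), 0)
})

test_that("appositions depend only on source axons and target dendrites", {
  pc <- generate_population(default_preset("mouse", "PC"), 2, seed = 9)
  spec <- column_spec(side = 60, height = 120, n_pc = 8, n_in = 0, n_columns = 1)
  circ <- build_circuit(spec, seed = 10)
  full <- assign_morphologies(circ, list(PC = pc), jitter_sd = 0, seed = 11)
  stripped_pool <- lapply(pc, function(m) {
    m$neurites <- Filter(function(tr) tr$type == "axon", m$neurites)
    m
  })
  dend_pool <- lapply(pc, function(m) {
    m$neurites <- Filter(function(tr) tr$type != "axon", m$neurites)
    m
  })
  e_full <- compute_appositions(full)$edges
  # sources only need axons, targets only need dendrites: computing with
  # axon-only sources against dendrite-only targets is the same graph
  mixed <- full
  mixed$pool <- list(PC = lapply(seq_along(pc), function(i) {
    m <- pc[[i]]
    m$neurites <- c(Filter(function(tr) tr$type == "axon",
                           stripped_pool[[i]]$neurites),
                    Filter(function(tr) tr$type != "axon",
                           dend_pool[[i]]$neurites))
    m
  }))
  expect_identical(compute_appositions(mixed)$edges, e_full)
})

test_that("neighbour counts match the uniform-density expectation", {
  # scale 0.2 keeps the full species density; the 7-column tiling covers the
  # tested radii laterally (apothem ~184 um)
  spec_h <- species_column_spec("human", scale = 0.2)
  spec_m <- species_column_spec("mouse", scale = 0.2)
  ch <- build_circuit(spec_h, seed = 6)
  cm <- build_circuit(spec_m, seed = 6)
  radii <- c(50, 100, 150)
  nh <- neighbor_counts(ch, radii)
  nm <- neighbor_counts(cm, radii)
  expect_true(all(nm$mean_count > nh$mean_count))
  expect_true(all(diff(nh$mean_count) > 0))
  # compare against the density the spec actually realizes (the published
  # per-column counts round the registry density down slightly)
  for (item in list(list(spec_h, nh), list(spec_m, nm))) {
    spec <- item[[1]]; got <- item[[2]]
    dens <- (spec$n_pc + spec$n_in) / hex_prism_volume(spec$side, spec$height)
    expected <- expected_neighbor_count(dens, radii, thickness = spec$height)
    expect_lt(max(abs(got$mean_count - expected) / expected), 0.05)
  }
})

test_that("the hybrid circuit carries scaled mouse dendrites and human axons", {
  hp <- list(PC = generate_population(default_preset("human", "PC"), 3, seed = 13),
             IN = generate_population(default_preset("human", "IN"), 3, seed = 14))
  mp <- list(PC = generate_population(default_preset("mouse", "PC"), 3, seed = 15),
             IN = generate_population(default_preset("mouse", "IN"), 3, seed = 16))
  spec <- column_spec(side = 80, height = 300, n_pc = 10, n_in = 4, n_columns = 1)
  hyb <- build_hybrid_circuit(spec, mp, hp, seed = 17)
  expect_equal(sum(hyb$cells$cell_class == "PC"), 10)
  expect_equal(sum(hyb$cells$cell_class == "IN"), 4)
  for (cl in c("PC", "IN")) {
    target <- mean(vapply(hp[[cl]], total_dendritic_length, numeric(1)))
    lens <- vapply(hyb$pool[[cl]], total_dendritic_length, numeric(1))
    expect_true(all(abs(lens - target) / target < 0.01))
    # axon branch counts come from the human donors
    ax_counts <- vapply(hyb$pool[[cl]], function(m)
      sum(vapply(dendronet:::morph_trees(m, "axon"),
                 dendronet:::tree_branch_count, numeric(1))), numeric(1))
    expect_true(all(ax_counts > 20))
  }
})

test_that("circuits are fully determined by spec, pools and seed", {
  c1 <- small_circuit(seed = 20)
  c2 <- small_circuit(seed = 20)
  expect_identical(c1$cells, c2$cells)
  expect_identical(c1$assignment, c2$assignment)
  expect_identical(compute_appositions(c1)$edges, compute_appositions(c2)$edges)
})
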