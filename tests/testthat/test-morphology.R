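test_that("SWC files parse, collapse the soma, and round-trip", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# minimal fixture",
               "1 1 0 0 0 5 -1",
               "2 1 0 -5 0 5 1",
               "3 1 0 5 0 5 1",
               "4 2 0 0 0 0.5 1",
               "5 2 0 -30 0 0.5 4"), path)
  m <- read_swc(path)
  expect_equal(m$soma_center, c(0, 0, 0))
  expect_equal(m$soma_radius, 5)
  expect_length(m$neurites, 1)
  expect_equal(m$neurites[[1]]$type, "axon")
  expect_equal(nrow(m$neurites[[1]]$nodes), 2)
  expect_equal(morphometrics(m)$total_length, 30)

  bad <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 2 0 0 0.5 1"), bad)
  expect_error(read_swc(bad), "line 2")

  two_somata <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 1 100 0 0 5 -1"), two_somata)
  expect_error(read_swc(two_somata), "multiple somata")
})

test_that("a generated population survives the SWC round trip", {
  pop <- generate_population(tiny_preset(), 4, seed = 3)
  dir <- withr::local_tempdir()
  write_swc_population(pop, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  for (i in seq_along(pop)) {
    back <- read_swc(file.path(dir, sprintf("neuron_%04d.swc", i)))
    mm0 <- morphometrics(pop[[i]])
    mm1 <- morphometrics(back)
    expect_equal(mm1$total_length, mm0$total_length, tolerance = 1e-9)
    expect_equal(mm1$branch_count, mm0$branch_count)
    expect_equal(mm1$mean_diameter, mm0$mean_diameter, tolerance = 1e-9)
    for (k in seq_along(pop[[i]]$neurites))
      expect_equal(back$neurites[[k]]$nodes$x, pop[[i]]$neurites[[k]]$nodes$x,
                   tolerance = 1e-6)
  }
})

test_that("morphometrics measures cable length, branches and extent", {
  m <- neuron_morphology(c(0, 0, 0), 1, list(straight_tree(100)))
  mm <- morphometrics(m)
  expect_equal(mm$total_length, 100)
  expect_equal(mm$branch_count, 1)
  expect_equal(mm$max_radial_extent, 100)

  my <- neuron_morphology(c(0, 0, 0), 1, list(y_tree(50, 50)))
  mmy <- morphometrics(my)
  expect_equal(mmy$total_length, 150)
  expect_equal(mmy$branch_count, 3)

  hp <- generate_population(default_preset("human", "PC"), 4, seed = 1)
  mp <- generate_population(default_preset("mouse", "PC"), 4, seed = 2)
  expect_gt(mean(vapply(hp, total_dendritic_length, numeric(1))),
            mean(vapply(mp, total_dendritic_length, numeric(1))))
})

test_that("diameter profiles bin thickness along path distance", {
  m <- neuron_morphology(c(0, 0, 0), 1, list(straight_tree(100, diameter = 0.5)))
  dp <- diameter_profile(list(m), 20)
  pop_bins <- dp[dp$n > 0, ]
  expect_true(all(pop_bins$mean == 0.5))
  expect_true(all(pop_bins$sd == 0))

  taper <- straight_tree(100, n = 21)
  taper$nodes$diameter <- seq(1.0, 0.2, length.out = 21)
  dpt <- diameter_profile(list(neuron_morphology(c(0, 0, 0), 1, list(taper))), 25)
  means <- dpt$mean[dpt$n > 0]
  expect_true(all(diff(means) < 0))

  m4 <- neuron_morphology(c(0, 0, 0), 1, list(straight_tree(100, diameter = 0.4)))
  m6 <- neuron_morphology(c(0, 0, 0), 1, list(straight_tree(100, diameter = 0.6)))
  dp2 <- diameter_profile(list(m4, m6), 20)
  expect_true(all(abs(dp2$mean[dp2$n > 0] - 0.5) < 1e-12))

  expect_error(diameter_profile(list(m), 0), "bin_width")
})

test_that("scaling multiplies lengths exactly and leaves diameters alone", {
  m <- generate_population(tiny_preset(), 1, seed = 9)[[1]]
  expect_equal(scale_morphology(m, 1), m)
  expect_error(scale_morphology(m, 0), "positive")
  L <- total_dendritic_length(m)
  for (f in c(0.3, 2, 7.5)) {
    ms <- scale_morphology(m, f)
    expect_equal(total_dendritic_length(ms), f * L, tolerance = 1e-12)
    expect_equal(ms$neurites[[1]]$nodes$diameter, m$neurites[[1]]$nodes$diameter)
  }
  # barcode of the scaled tree equals the uniformly scaled barcode
  pb <- extract_barcode(m$neurites[[1]], "path")
  pb2 <- extract_barcode(scale_morphology(m, 2)$neurites[[1]], "path")
  expect_equal(sort(pb2$death), sort(scale_barcode(pb, 2)$death),
               tolerance = 1e-9)
  expect_equal(sort(pb2$birth), sort(scale_barcode(pb, 2)$birth),
               tolerance = 1e-9)
})

test_that("curation reattaches roots, fixes diameters, aligns apicals, and is idempotent", {
  tr <- straight_tree(100, type = "apical")
  tr$nodes$y <- tr$nodes$y + 8  # root 8 um above a 3 um soma: disconnected
  m <- neuron_morphology(c(0, 0, 0), 3, list(tr),
                         meta = list(cell_class = "PC"))
  cur <- curate_morphology(m)
  r <- cur$neurites[[1]]$nodes
  expect_equal(sqrt(r$x[1]^2 + r$y[1]^2 + r$z[1]^2), 3, tolerance = 1e-9)
  expect_equal(curate_morphology(cur), cur)

  # apical pointing -Y gets rotated to +Y
  down <- straight_tree(100, type = "apical")
  down$nodes$y <- -down$nodes$y
  md <- neuron_morphology(c(0, 0, 0), 1, list(down),
                          meta = list(cell_class = "PC"))
  mdc <- curate_morphology(md)
  expect_gt(mean(mdc$neurites[[1]]$nodes$y), 0)

  # zero diameters replaced from neighbours
  z <- straight_tree(100, n = 5, diameter = 0.6)
  z$nodes$diameter[3] <- 0
  mz <- curate_morphology(neuron_morphology(c(0, 0, 0), 1, list(z)))
  expect_equal(mz$neurites[[1]]$nodes$diameter[3], 0.6)

  # PC without apical: warning, no rotation
  mb <- neuron_morphology(c(0, 0, 0), 1, list(straight_tree(50, type = "basal")),
                          meta = list(cell_class = "PC"))
  expect_warning(curate_morphology(mb), "apical")
})

test_that("axon grafting composes dendrites and axon from different donors", {
  pop <- generate_population(tiny_preset(), 2, seed = 11)
  a <- pop[[1]]; b <- pop[[2]]
  self <- graft_axon(a, a)
  expect_equal(morphometrics(self)[, c("total_length", "branch_count")],
               morphometrics(a)[, c("total_length", "branch_count")],
               tolerance = 1e-9)
  g <- graft_axon(a, b)
  mg <- morphometrics(g)
  ma <- morphometrics(a); mb <- morphometrics(b)
  expect_equal(mg$branch_count[mg$neurite_type == "axon"],
               mb$branch_count[mb$neurite_type == "axon"])
  expect_equal(mg$total_length[mg$neurite_type == "basal"],
               ma$total_length[ma$neurite_type == "basal"])
  no_axon <- neuron_morphology(c(0, 0, 0), 1, list(straight_tree(50)))
  expect_error(graft_axon(a, no_axon), "no axon")
})

test_that("the axon pool filter keeps axons with more than min_branches branches", {
  kept <- star_axon(20)    # 21 branches
  dropped <- star_axon(19) # 20 branches
  expect_length(filter_axon_pool(list(kept, dropped)), 1)
  expect_identical(filter_axon_pool(list()), list())

  set.seed(4)
  ks <- sample(10:30, 40, replace = TRUE)
  pool <- lapply(ks, star_axon)
  expect_length(filter_axon_pool(pool), sum(ks + 1 > 20))
})

test_that("branch bookkeeping: branches = leaves + bifurcations", {
  set.seed(8)
  pre <- tiny_preset()
  for (i in 1:6) {
    pb <- sample_barcode(pre, "basal")
    tr <- synthesize_tree(pb, pre$geometry, pre$diameter_model)
    leaves <- dendronet:::tree_n_leaves(tr)
    bifs <- dendronet:::tree_n_bifurcations(tr)
    expect_equal(dendronet:::tree_branch_count(tr), leaves + bifs)
    expect_equal(nrow(pb), leaves)
  }
})
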