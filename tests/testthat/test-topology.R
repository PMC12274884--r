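test_that("barcode extraction follows the elder rule", {
  m <- straight_tree(100)
  pb <- extract_barcode(m, "path")
  expect_equal(nrow(pb), 1)
  expect_equal(pb$birth, 0)
  expect_equal(pb$death, 100)

  pby <- extract_barcode(y_tree(50, 30), "path")
  bars <- as.data.frame(pby)[order(pby$birth), c("birth", "death")]
  expect_equal(bars$birth, c(0, 50))
  expect_equal(bars$death, c(100, 80))

  expect_error(extract_barcode(
    structure(list(nodes = data.frame()[0, ], type = "basal"),
              class = "neurite_tree")), "empty")
})

test_that("topological entropy matches the closed form and is scale-invariant", {
  one <- persistence_barcode(data.frame(birth = 0, death = 42))
  expect_equal(barcode_entropy(one), 0)
  two <- persistence_barcode(data.frame(birth = c(0, 10), death = c(5, 15)))
  expect_equal(barcode_entropy(two), log(2))
  zero <- persistence_barcode(data.frame(birth = 3, death = 3))
  expect_error(barcode_entropy(zero), "undefined")

  set.seed(2)
  pre <- tiny_preset()
  for (i in 1:10) {
    pb <- sample_barcode(pre, "basal")
    e0 <- barcode_entropy(pb)
    expect_lte(e0, log(nrow(pb)) + 1e-12)
    for (a in c(0.5, 2, 10))
      expect_equal(barcode_entropy(scale_barcode(pb, a)), e0, tolerance = 1e-12)
  }
})

test_that("barcode scaling acts on births and deaths as specified", {
  pb <- persistence_barcode(data.frame(birth = 0, death = 10))
  expect_equal(scale_barcode(pb, 2)$death, 20)
  pb2 <- persistence_barcode(data.frame(birth = c(0, 50), death = c(100, 80)))
  expect_equal(as.data.frame(scale_barcode(pb2, 1, 1))[, 1:2],
               as.data.frame(pb2)[, 1:2])
  crossed <- scale_barcode(persistence_barcode(data.frame(birth = 50, death = 80)),
                           alpha = 2, beta = 1)
  expect_equal(crossed$birth, 100)
  expect_equal(crossed$death, 80)
  expect_true(attr(crossed, "invalid"))
  expect_error(scale_barcode(pb, -1), "alpha")
})

test_that("persistence images are deterministic kernels with exact linearity", {
  empty <- persistence_barcode(data.frame(birth = numeric(0), death = numeric(0)))
  img0 <- persistence_image(empty, bounds = list(x = c(0, 1), y = c(0, 1)),
                            resolution = 20)
  expect_true(all(img0$grid == 0))

  b <- list(x = c(0, 100), y = c(0, 100))
  one <- persistence_barcode(data.frame(birth = 50, death = 50))
  img1 <- persistence_image(one, bounds = b, resolution = 101)
  peak <- which(img1$grid == max(img1$grid), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(51, 51))

  set.seed(6)
  pre <- tiny_preset()
  pbs <- lapply(1:4, function(i) sample_barcode(pre, "basal"))
  bb <- image_bounds(pbs)
  pop <- population_image(pbs, bounds = bb, resolution = 40, kernel_sigma = 5)
  members <- lapply(pbs, persistence_image, bounds = bb, resolution = 40,
                    kernel_sigma = 5)
  expect_equal(pop$grid, Reduce(`+`, lapply(members, `[[`, "grid")),
               tolerance = 1e-12)

  expect_equal(image_distance(pop, pop), 0)
  expect_equal(image_distance(members[[1]], members[[2]]),
               image_distance(members[[2]], members[[1]]))
  other <- persistence_image(pbs[[1]], bounds = list(x = c(0, 1), y = c(0, 1)),
                             resolution = 40)
  expect_error(image_distance(pop, other), "grids")

  norm1 <- persistence_image(pbs[[1]], bounds = bb, normalize = TRUE)
  expect_equal(sum(norm1$grid), 1)
})

test_that("population image distance shrinks as a population morphs toward the target", {
  set.seed(12)
  pre <- tiny_preset()
  pbs <- lapply(1:6, function(i) sample_barcode(pre, "basal"))
  bb <- image_bounds(pbs, lapply(pbs, scale_barcode, alpha = 3))
  target <- population_image(pbs, bounds = bb, resolution = 50, kernel_sigma = 5)
  d <- vapply(c(3, 2, 1.5, 1.2, 1), function(a)
    image_distance(population_image(lapply(pbs, scale_barcode, alpha = a),
                                    bounds = bb, resolution = 50,
                                    kernel_sigma = 5), target), numeric(1))
  expect_true(all(diff(d) < 0))
  expect_equal(d[5], 0)
})

test_that("scaling optimization recovers planted factors", {
  set.seed(3)
  pre <- default_preset("mouse", "PC")
  pop <- lapply(1:10, function(i) sample_barcode(pre, "apical"))
  self <- fit_scaling(pop, pop, "uniform", resolution = 64)
  expect_lt(abs(self$alpha - 1), 0.01)

  uni <- fit_scaling(pop, lapply(pop, scale_barcode, alpha = 2), "uniform",
                     resolution = 64)
  expect_lt(abs(uni$alpha - 2) / 2, 0.02)

  non <- fit_scaling(pop, lapply(pop, scale_barcode, alpha = 1.5, beta = 2),
                     "nonuniform", resolution = 64)
  expect_lt(abs(non$alpha - 1.5) / 1.5, 0.05)
  expect_lt(abs(non$beta - 2) / 2, 0.05)
  expect_error(fit_scaling(list(), pop), "non-empty")
})

test_that("diagram mixtures are recovered from pooled points", {
  set.seed(9)
  true_means <- matrix(c(50, 120, 300, 600, 150, 900), 3, 2, byrow = TRUE)
  sds <- c(20, 30)
  pts <- do.call(rbind, lapply(1:3, function(k)
    cbind(abs(rnorm(1000, true_means[k, 1], sds[1])),
          abs(rnorm(1000, true_means[k, 2], sds[2])))))
  pb <- persistence_barcode(data.frame(birth = pts[, 1], death = pts[, 2]))
  fit <- fit_diagram_mixture(pb, 3, seed = 2)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # match fitted centers to truth by nearest distance; errors < 10% of spread
  for (k in 1:3) {
    errs <- sqrt(rowSums(sweep(fit$means, 2, true_means[k, ])^2))
    expect_lt(min(errs), 0.1 * max(sds) * 3)
  }
  one <- fit_diagram_mixture(pb, 1, seed = 2)
  expect_equal(as.numeric(one$means), colMeans(pts), tolerance = 1e-9)
})

test_that("complexity profiles count bars alive and bin entropy", {
  single <- persistence_barcode(data.frame(birth = 0, death = 100))
  cp <- complexity_profile(list(single), seq(0, 100, 10))
  expect_equal(cp$mean_alive, rep(1, 10))
  cp0 <- complexity_profile(list(), seq(0, 100, 10))
  expect_true(all(cp0$mean_alive == 0))
  expect_true(all(cp0$entropy == 0))

  hp <- generate_population(default_preset("human", "PC"), 5, seed = 21)
  mp <- generate_population(default_preset("mouse", "PC"), 5, seed = 22)
  edges <- seq(0, 1000, 100)
  ch <- complexity_profile(lapply(hp, neuron_barcode, "path"), edges)
  cm <- complexity_profile(lapply(mp, neuron_barcode, "path"), edges)
  mid <- edges[-length(edges)] >= 200 & edges[-1] <= 500
  expect_true(all(ch$mean_alive[mid] > cm$mean_alive[mid]))
})

test_that("barcode normalization rescales the maximal death to one", {
  pb <- persistence_barcode(data.frame(birth = c(0, 10), death = c(200, 50)))
  nb <- normalize_barcode(pb)
  expect_equal(max(nb$death), 1)
  expect_equal(barcode_entropy(nb), barcode_entropy(pb))
})
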