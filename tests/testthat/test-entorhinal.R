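test_that("grid rate peaks at a lattice vertex and is lattice-periodic", {
  pop <- make_mec_population(3, seed = 2)
  for (i in 1:3) {
    p <- pop[i, ]
    expect_equal(grid_rate(p, p$phase_x, p$phase_y), p$peak_rate,
                 tolerance = 1e-9)
    # translation by a lattice basis vector leaves the rate unchanged
    b1 <- p$spacing_cm * c(cos(p$orientation + pi / 6),
                           sin(p$orientation + pi / 6))
    x <- c(10, 35.2, 61.7); y <- c(70, 12.3, 44.4)
    expect_equal(grid_rate(p, x + b1[1], y + b1[2]), grid_rate(p, x, y),
                 tolerance = 1e-6)
  }
})

test_that("grid rate matches a direct evaluation of the three-cosine formula", {
  p <- list(spacing_cm = 42, orientation = 0.31, phase_x = 13, phase_y = 57,
            peak_rate = 20, sharpness = 1)
  probes <- cbind(x = c(5, 20.5, 40, 63.2, 79),
                  y = c(71, 3.3, 40, 18.9, 60))
  # independent oracle: literal sum of three plane-wave cosines at 60 degrees
  oracle <- apply(probes, 1, function(r) {
    g <- sum(vapply(0:2, function(k) {
      a <- p$orientation + k * pi / 3
      u <- c(cos(a), sin(a))
      cos(4 * pi / (sqrt(3) * p$spacing_cm) *
            sum(u * (r - c(p$phase_x, p$phase_y))))
    }, numeric(1)))
    p$peak_rate * (g + 1.5) / 4.5
  })
  expect_equal(grid_rate(p, probes[, "x"], probes[, "y"]), oracle,
               tolerance = 1e-10)
  # population map agrees with the pointwise evaluation
  pop <- make_mec_population(4, seed = 5)
  maps <- mec_rate_maps(pop, 80, 1)
  ctr_idx <- c(1, 300, 4000)
  for (i in c(1, 4)) {
    xs <- ((ctr_idx - 1) %% 80 + 0.5)
    ys <- ((ctr_idx - 1) %/% 80 + 0.5)
    expect_equal(maps[i, ctr_idx], grid_rate(pop[i, ], xs, ys),
                 tolerance = 1e-9)
  }
})

test_that("LEC cells switch maps sharply at their private morph degree", {
  pop <- make_lec_population(50, seed = 3)
  expect_true(all(pop$c_star > 1 & pop$c_star < 7))
  m1 <- lec_rate_maps(pop, 1)
  m7 <- lec_rate_maps(pop, 7)
  expect_equal(m1, pop$map_a)
  expect_equal(m7, pop$map_b)
  expect_error(lec_rate_maps(pop, 8), class = "hippomorph_argument_error")
  expect_error(lec_rate(pop, 10, 10, 0.5), class = "hippomorph_argument_error")
})

test_that("population morph response is approximately uniform across steps", {
  # each cell switches once at a uniform threshold, so the expected mean
  # absolute rate change is the same for every unit step along the morph axis
  pop <- make_lec_population(1500, seed = 11)
  step_change <- vapply(1:6, function(c) {
    a <- lec_rate_maps(pop, c); b <- lec_rate_maps(pop, c + 1)
    mean(abs(a - b))
  }, numeric(1))
  expect_lt(max(step_change) / min(step_change), 1.8)
  expect_gt(min(step_change), 0)
})

test_that("synaptic weights are positive, skewed and seed-stable", {
  w <- sample_feedforward_weights(1500, seed = 4)
  expect_length(w, 1500)
  expect_true(all(w > 0))
  expect_identical(w, sample_feedforward_weights(1500, seed = 4))
  big <- sample_feedforward_weights(1e5, seed = 5)
  skew <- mean((big - mean(big))^3) / sd(big)^3
  expect_gt(skew, 0)
  # different seeds: different draws, same distribution
  a <- sample_feedforward_weights(1e4, seed = 1)
  b <- sample_feedforward_weights(1e4, seed = 2)
  expect_false(identical(a, b))
  expect_gt(suppressWarnings(ks.test(a, b))$p.value, 0.01)
  expect_error(sample_feedforward_weights(0),
               class = "hippomorph_argument_error")
})

test_that("feedforward weight matrices respect the convergence counts", {
  w <- build_feedforward_weights(20, n_mec = 100, n_lec = 120, conv_mec = 30,
                                 conv_lec = 40, seed = 9)
  expect_equal(unname(Matrix::rowSums(w$w_mec > 0)), rep(30, 20))
  expect_equal(unname(Matrix::rowSums(w$w_lec > 0)), rep(40, 20))
  expect_true(all(w$w_mec@x > 0) && all(w$w_lec@x > 0))
  # top-decile selection draws identical weights for the selected pool cells
  w10 <- build_feedforward_weights(10, n_mec = 100, n_lec = 120,
                                   conv_mec = 30, conv_lec = 40, seed = 9,
                                   top_fraction = 0.5)
  expect_equal(w10$pool_size, 20)
  expect_length(w10$pool_ids, 10)
})

test_that("grid realignment keeps spacings, changes maps, is reproducible", {
  pop <- make_mec_population(100, seed = 21)
  re <- realign_grids(pop, seed = 3)
  expect_identical(re$spacing_cm, pop$spacing_cm)
  expect_identical(re, realign_grids(pop, seed = 3))
  expect_false(identical(re$orientation, pop$orientation))
  m0 <- mec_rate_maps(pop, 80, 2)
  m1 <- mec_rate_maps(re, 80, 2)
  cors <- vapply(seq_len(nrow(pop)),
                 function(i) cor(m0[i, ], m1[i, ]), numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("entorhinal input current follows the alpha-mixed normalized form", {
  # toy case: 2 MEC + 2 LEC synapses, hand-set weights and rates
  mec_maps <- rbind(c(2, 0, 4, 1), c(1, 1, 0, 3))   # 2 cells x 4 positions
  lec_pop <- structure(list(
    map_a = rbind(c(0.5, 1, 0, 0.2), c(1, 0, 0.4, 0.8)),
    map_b = rbind(c(0, 0, 1, 1), c(0.3, 0.3, 0.3, 0.3)),
    c_star = c(3, 5), box_cm = 2, res_cm = 1
  ), class = "lec_population")
  w <- structure(list(
    w_mec = Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = c(2, 1),
                                 dims = c(1, 2)),
    w_lec = Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = c(0.5, 1),
                                 dims = c(1, 2))
  ), class = "ff_weights")
  terms <- compute_ec_terms(w, mec_maps, lec_pop)
  # hand calculation: raw mec = 2*mec1 + 1*mec2 = (5,1,8,5); z_mec = 8
  expect_equal(terms$z_mec, 8)
  # raw lec (c=1, both cells on map A) = 0.5*a1 + 1*a2 = (1.25,0.5,0.4,0.9)
  expect_equal(terms$z_lec, 1.25)
  alpha <- 0.3
  m <- ec_input_map(terms, 1, alpha)
  hand <- alpha * c(5, 1, 8, 5) / 8 + (1 - alpha) * c(1.25, 0.5, 0.4, 0.9) / 1.25
  expect_equal(as.numeric(m), hand, tolerance = 1e-12)
  # alpha = 1: drive independent of the morph condition
  expect_equal(ec_input_map(terms, 1, 1), ec_input_map(terms, 6, 1))
  # linearity in alpha at fixed position/morph
  m0 <- ec_input_map(terms, 4, 0); m1 <- ec_input_map(terms, 4, 1)
  mh <- ec_input_map(terms, 4, 0.5)
  expect_equal(mh, 0.5 * m0 + 0.5 * m1, tolerance = 1e-12)
  # point evaluation matches the map (g_ff = 1)
  cur <- ec_input_current(terms, 1, 0.5, 0.5, 1, alpha, g_ff = 1)
  expect_equal(as.numeric(cur), hand[1], tolerance = 1e-12)
  # alpha = 0 with all LEC rates zero at a position gives zero current
  lec0 <- lec_pop; lec0$map_a <- 0 * lec0$map_a + c(0, 1)  # cell 1 silent
  expect_error(ec_input_current(structure(list(), class = "ec_terms"),
                                1, 0.5, 0.5, 1, 0.5),
               class = "hippomorph_state_error")
})

test_that("mean-max normalization fixes the population scale", {
  net_cfg <- tiny_config()
  mec <- make_mec_population(net_cfg$n_mec, seed = 1)
  lec <- make_lec_population(net_cfg$n_lec, seed = 2)
  w <- build_feedforward_weights(50, net_cfg$n_mec, net_cfg$n_lec, 30, 30,
                                 seed = 3)
  terms <- compute_ec_terms(w, mec_rate_maps(mec), lec)
  rmax <- apply(terms$mec_term, 1, max)
  expect_equal(mean(rmax), 1, tolerance = 1e-9)
})

test_that("with alpha = 0 and silent LEC input the current is zero", {
  mec_maps <- rbind(c(2, 0, 4, 1))
  lec_pop <- structure(list(
    map_a = rbind(c(0, 0, 0, 0)), map_b = rbind(c(0, 0, 0, 0)),
    c_star = 3, box_cm = 2, res_cm = 1
  ), class = "lec_population")
  w <- structure(list(
    w_mec = Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1)),
    w_lec = Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1))
  ), class = "ff_weights")
  terms <- compute_ec_terms(w, mec_maps, lec_pop)
  expect_equal(as.numeric(ec_input_map(terms, 2, 0)), rep(0, 4))
})
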