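test_that("rate maps are occupancy-normalized and smoothed correctly", {
  traj <- grid_trajectory(bins = 16, reps = 2)
  # no spikes: all-zero map
  empty <- compute_rate_map(NULL, traj)
  expect_true(all(empty$rate == 0, na.rm = TRUE))
  # spikes in one bin, h -> 0: single nonzero bin equal to n/occupancy
  spk <- tibble::tibble(x_cm = rep(2.5, 5), y_cm = rep(2.5, 5))
  m0 <- compute_rate_map(spk, traj, h = 0)
  occ_bin <- 2 * attr(traj, "dt_s")
  expect_equal(m0$rate[1, 1], 5 / occ_bin)
  expect_equal(sum(m0$rate > 0, na.rm = TRUE), 1)
})

test_that("smoothing matches a hand-computed kernel average on a toy grid", {
  # 2x2 grid (box 10 cm, 5 cm bins), uniform occupancy of 1 s, h = 5 cm
  occ <- matrix(1, 2, 2)
  counts <- c(4, 0, 0, 0)
  rm <- hippomorph:::rate_map_from_counts(counts, occ, box = 10, bins = 2,
                                          h = 5)
  g1 <- 1                       # same bin
  g2 <- exp(-25 / 50)           # 5 cm apart
  g3 <- exp(-50 / 50)           # diagonal, sqrt(50) cm
  hand_11 <- 4 * g1 / (g1 + 2 * g2 + g3)
  hand_12 <- 4 * g2 / (g1 + 2 * g2 + g3)
  hand_22 <- 4 * g3 / (g1 + 2 * g2 + g3)
  expect_equal(rm$rate[1, 1], hand_11, tolerance = 1e-12)
  expect_equal(rm$rate[2, 1], hand_12, tolerance = 1e-12)
  expect_equal(rm$rate[2, 2], hand_22, tolerance = 1e-12)
  # occupancy-weighted mean is preserved under uniform occupancy
  expect_equal(mean(rm$rate), mean(rm$raw), tolerance = 1e-12)
})

test_that("place-field detection applies the size and peak rules", {
  m <- matrix(0, 16, 16)
  m[5:7, 5:7] <- 5                       # 3x3 block at 5 Hz
  f <- detect_place_fields(m)
  expect_equal(nrow(f), 1)
  expect_equal(f$size, 9L)
  expect_equal(f$peak_rate, 5)
  # peak below 2 Hz: no field
  expect_equal(nrow(detect_place_fields(m * 0.3)), 0)
  # a 200-bin suprathreshold blob violates n < 128
  big <- matrix(0, 16, 16); big[1:13, 1:16] <- 3
  expect_equal(nrow(detect_place_fields(big)), 0)
  # a too-small blob violates n > 8
  small <- matrix(0, 16, 16); small[1:2, 1:2] <- 6
  expect_equal(nrow(detect_place_fields(small)), 0)
  # members must exceed 20% of the field peak
  graded <- matrix(0, 16, 16)
  graded[4:9, 4:9] <- 10
  graded[4, 4] <- 1            # below 20% of 10: excluded from the field
  f2 <- detect_place_fields(graded)
  expect_equal(f2$size, 35L)
})

test_that("PV correlation is 1 for identical sessions, ~0 for shuffled", {
  set.seed(9)
  occ <- matrix(1, 16, 16)
  counts <- matrix(rpois(30 * 256, lambda = 3), 30, 256)
  a <- session_from_counts(counts, occ)
  pv_same <- pv_correlation(a, a)
  expect_true(all(abs(pv_same$bins$r - 1) < 1e-9, na.rm = TRUE))
  expect_equal(pv_same$mean, 1, tolerance = 1e-9)
  # second session with independently shuffled cell rates: mean near 0
  shuffled <- counts[sample(30), ]
  b <- session_from_counts(shuffled, occ)
  expect_lt(abs(pv_correlation(a, b)$mean), 0.05)
})

test_that("PV correlation matches a hand-computed toy case", {
  # 3 cells x 2 visited bins with hand-set unsmoothed rates
  occ <- matrix(0, 2, 2); occ[1, 1] <- 1; occ[2, 1] <- 1
  ca <- rbind(c(10, 2, 0, 0), c(4, 6, 0, 0), c(1, 9, 0, 0))
  cb <- rbind(c(8, 1, 0, 0), c(5, 5, 0, 0), c(2, 7, 0, 0))
  a <- session_from_counts(ca, occ, box = 80, duration = 2)
  b <- session_from_counts(cb, occ, box = 80, duration = 2)
  pv <- pv_correlation(a, b, h = 0)
  expect_equal(pv$bins$r[1], cor(ca[, 1], cb[, 1]), tolerance = 1e-12)
  expect_equal(pv$bins$r[2], cor(ca[, 2], cb[, 2]), tolerance = 1e-12)
  expect_equal(pv$mean, mean(c(cor(ca[, 1], cb[, 1]), cor(ca[, 2], cb[, 2]))),
               tolerance = 1e-12)
  # cells not above 1 Hz in both sessions are excluded
  cb2 <- cb; cb2[2, ] <- 0
  pv2 <- pv_correlation(a, session_from_counts(cb2, occ, box = 80,
                                               duration = 2), h = 0)
  expect_equal(pv2$n_cells, 2)
})

test_that("PV autocorrelation at 50 cm behaves as designed", {
  # duplicated identical cells: correlation 1 at any distance
  occ <- matrix(1, 16, 16)
  base <- matrix(rpois(256, 4), 1)
  counts <- rbind(base, base + 0L, matrix(rpois(2 * 256, 4), 2))
  s <- session_from_counts(counts * 3L, occ)
  res <- pv_autocorrelation_distance(s)
  expect_gt(res$n_pairs, 0)
  # distance window excludes same-bin pairs; qualifying pairs are 50 +/- 2.5
  ctr <- hippomorph:::bin_centers(80, 16)
  d <- as.matrix(dist(ctr))
  expect_equal(res$n_pairs, sum(upper.tri(d) & abs(d - 50) <= 2.5))
  # cells with disjoint single-bin fields decorrelate at 50 cm
  dis <- matrix(0L, 20, 256)
  set.seed(2)
  for (i in 1:20) dis[i, sample(256, 3)] <- 60L
  s2 <- session_from_counts(dis, occ)
  expect_lt(abs(pv_autocorrelation_distance(s2, h = 0)$mean), 0.15)
  # no qualifying pairs: flagged empty result
  occ_small <- matrix(0, 16, 16); occ_small[1:2, 1:2] <- 1
  s3 <- session_from_counts(counts[, , drop = FALSE], occ_small)
  expect_true(is.na(pv_autocorrelation_distance(s3)$mean))
  expect_equal(pv_autocorrelation_distance(s3)$n_pairs, 0L)
})

test_that("rate overlap is min/max of mean rates with silent-map rules", {
  occ <- matrix(1, 4, 4)
  mk <- function(total) hippomorph:::rate_map_from_counts(
    rep(total / 16, 16), occ, box = 80, bins = 4, h = 5)
  expect_equal(rate_overlap(mk(32), mk(32)), 1)
  expect_equal(rate_overlap(mk(32), mk(64)), 0.5)   # 2 Hz vs 4 Hz
  expect_equal(rate_overlap(mk(0), mk(32)), 0)
  expect_true(is.na(rate_overlap(mk(0), mk(0))))
  # symmetric in its arguments
  expect_equal(rate_overlap(mk(48), mk(16)), rate_overlap(mk(16), mk(48)))
})

test_that("spatial correlation is Pearson over mutually valid bins", {
  occ <- matrix(1, 4, 4)
  set.seed(5)
  counts_a <- rpois(16, 10)
  ma <- hippomorph:::rate_map_from_counts(counts_a, occ, 80, 4, h = 0)
  expect_equal(spatial_correlation(ma, ma), 1)
  # negative-gradient complement: anticorrelated
  mb <- hippomorph:::rate_map_from_counts(max(counts_a) - counts_a, occ, 80,
                                          4, h = 0)
  expect_lt(spatial_correlation(ma, mb), 0)
  # toy 4-bin pair, hand-computed r
  occ2 <- matrix(0, 2, 2); occ2[] <- 1
  a4 <- hippomorph:::rate_map_from_counts(c(1, 2, 3, 4), occ2, 10, 2, h = 0)
  b4 <- hippomorph:::rate_map_from_counts(c(2, 2, 5, 3), occ2, 10, 2, h = 0)
  expect_equal(spatial_correlation(a4, b4), cor(c(1, 2, 3, 4), c(2, 2, 5, 3)),
               tolerance = 1e-12)
  # constant map: flagged undefined
  cst <- hippomorph:::rate_map_from_counts(rep(2, 4), occ2, 10, 2, h = 0)
  expect_true(is.na(spatial_correlation(cst, b4)))
})

test_that("the active-cell rule is strict at 0.1 Hz across conditions", {
  occ <- matrix(1, 16, 16)   # 256 s session
  silent <- matrix(0L, 3, 256)
  low <- silent; low[2, 1:26] <- 1L        # 26/256 s ~ 0.1016 Hz > 0.1
  exact <- silent
  exact[3, 1:26] <- 1L
  s1 <- session_from_counts(silent, occ, duration = 256)
  s2 <- session_from_counts(low, occ, duration = 256)
  s3 <- session_from_counts(exact, occ, duration = 260)  # exactly 0.1 Hz
  expect_equal(active_cells(s1), integer(0))
  # active in one condition only is enough
  expect_equal(active_cells(s1, s2), 2L)
  # boundary exactly 0.1 Hz is excluded (strictly "above")
  expect_equal(active_cells(s3), integer(0))
})

test_that("spatial information is zero for flat maps and high for fields", {
  occ <- matrix(1, 8, 8)
  flat <- hippomorph:::rate_map_from_counts(rep(4, 64), occ, 80, 8, h = 0)
  expect_equal(spatial_information(flat), 0, tolerance = 1e-12)
  field <- hippomorph:::rate_map_from_counts(c(rep(0, 60), rep(64, 4)), occ,
                                             80, 8, h = 0)
  expect_gt(spatial_information(field), 2)
})
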