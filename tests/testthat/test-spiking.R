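test_that("first-spike latencies match the closed-form leaky-integrator", {
  p <- neuron_params()
  # 0.9 nA: continuous-time latency -tau*ln(1 - theta/(I*R)) = 21.1 ms
  cyc <- run_gamma_cycle(0.9, inh_delay = 3.3)
  expect_equal(cyc$first_spike_time, 21.1, tolerance = 1)
  expect_length(cyc$spike_times[[1]], 1)
  # 0.6 nA: closed-form latency ~42.5 ms exceeds the 36.5 ms cycle
  cyc6 <- run_gamma_cycle(0.6, inh_delay = 3.3)
  expect_identical(cyc6$first_spike_time, Inf)
  expect_length(cyc6$spike_times[[1]], 0)
  # steady state at or below threshold (I*R <= 15 mV) never spikes
  cyc_sub <- run_gamma_cycle(0.4545, inh_delay = 3.3)
  expect_identical(cyc_sub$first_spike_time, Inf)
})

test_that("two-cell pattern completion requires recurrent collaterals", {
  # A (stored-pattern peer of B) gets strong input and fires; B is
  # subthreshold for the cycle but has a suprathreshold weight from A
  w <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 0.5, dims = c(2, 2))
  rec <- recurrent_params(w, delta = 0.05)
  without <- run_gamma_cycle(c(0.9, 0.6), inh_delay = 3.3)
  expect_length(without$spike_times[[2]], 0)
  with_rec <- run_gamma_cycle(c(0.9, 0.6), rec_params = rec, inh_delay = 3.3)
  # A fires on its feedforward drive (possibly again later, re-excited by
  # B's EPSC after its refractory period); B is recruited by A's EPSC
  expect_gte(length(with_rec$spike_times[[1]]), 1)
  expect_equal(with_rec$spike_times[[1]][1], without$spike_times[[1]][1])
  expect_gte(length(with_rec$spike_times[[2]]), 1)
  # B's spike follows A's EPSC (release lag 1 ms)
  expect_gt(with_rec$spike_times[[2]][1],
            with_rec$spike_times[[1]][1] + neuron_params()$rec_lag)
  # with delta = 1 the threshold is unreachable: output invariant to weights
  rec_off <- recurrent_params(w, delta = 1)
  inert <- run_gamma_cycle(c(0.9, 0.6), rec_params = rec_off, inh_delay = 3.3)
  expect_equal(inert$spike_times, without$spike_times)
})

test_that("cycle invariants hold: ordering, onset, refractoriness", {
  p <- neuron_params()
  set.seed(42)
  for (rep in 1:5) {
    currents <- runif(20, 0.3, 1.2)
    cyc <- run_gamma_cycle(currents, inh_delay = 3.5)
    spikes <- cyc$spike_times
    # no spikes at or after inhibition onset
    all_t <- unlist(spikes)
    if (length(all_t)) expect_true(all(all_t < cyc$inhibition_onset))
    # per-cell inter-spike intervals respect the refractory period
    for (st in spikes) {
      if (length(st) > 1) expect_true(all(diff(st) >= p$tau_spike - 1e-9))
    }
    # without recurrence, first spikes are ordered by decreasing current
    first <- vapply(spikes, function(s) if (length(s)) s[1] else Inf,
                    numeric(1))
    fired <- is.finite(first)
    if (sum(fired) > 1) {
      expect_true(all(diff(first[order(-currents)][seq_len(sum(fired))]) >=
                        -1e-9))
    }
    # oracle: simulated first-spike times are nondecreasing in the
    # closed-form continuous latency (ties allowed: cells crossing within
    # the same 1 ms Euler step share a spike time)
    lat <- suppressWarnings(-p$tau_n * log(1 - (p$v_thresh - p$v_rest) /
                                             (currents * p$r_n)))
    lat[currents * p$r_n <= 15] <- Inf
    expect_true(all(diff(first[fired][order(lat[fired])]) >= -1e-9))
  }
})

test_that("raising a cell's current never delays its first spike", {
  base <- c(0.8, 0.7, 0.65)
  cyc_a <- run_gamma_cycle(base, inh_delay = 3.3)
  cyc_b <- run_gamma_cycle(base + c(0, 0.1, 0), inh_delay = 3.3)
  t_a <- cyc_a$spike_times[[2]]
  t_b <- cyc_b$spike_times[[2]]
  expect_true(length(t_b) >= length(t_a))
  if (length(t_a) && length(t_b)) expect_lte(t_b[1], t_a[1])
})

test_that("negative currents and mismatched weights are rejected", {
  expect_error(run_gamma_cycle(c(0.5, -0.1)),
               class = "hippomorph_argument_error")
  w <- Matrix::sparseMatrix(i = 1, j = 2, x = 0.5, dims = c(2, 2))
  expect_error(run_gamma_cycle(c(0.5, 0.5, 0.5),
                               rec_params = recurrent_params(w)),
               class = "hippomorph_state_error")
})

test_that("the session fast path agrees with the reference integrator", {
  p <- neuron_params()
  set.seed(7)
  for (rep in 1:8) {
    currents <- runif(15, 0.4, 1.1)
    lt <- latency_map(matrix(currents, ncol = 1), p)
    delay <- runif(1, 2.5, 4)
    cyc <- run_gamma_cycle(currents, inh_delay = delay)
    if (!is.finite(lt$t1[1])) {
      expect_identical(cyc$first_spike_time, Inf)
      next
    }
    expect_equal(lt$t1[1], cyc$first_spike_time, tolerance = 1e-9)
    fast_who <- which(lt$lat[, 1] < lt$t1[1] + delay)
    ref_who <- which(lengths(cyc$spike_times) > 0)
    expect_equal(fast_who, ref_who)
    ref_t <- vapply(cyc$spike_times[ref_who], `[`, numeric(1), 1)
    expect_equal(unname(lt$lat[fast_who, 1]), unname(ref_t),
                 tolerance = 0.11)
  }
})

test_that("sessions are deterministic and conserve spike counts", {
  net <- tiny_network()
  traj <- generate_trajectory(20, seed = 5)
  cur <- net$ca3_current[["1"]]
  s1 <- simulate_session(traj, cur, seed = 3, region = "ca3")
  s2 <- simulate_session(traj, cur, seed = 3, region = "ca3")
  expect_identical(s1$counts, s2$counts)
  # spike-recording path produces the same counts as the fast path
  s3 <- simulate_session(traj, cur, seed = 3, region = "ca3",
                         record_spikes = TRUE)
  expect_identical(s3$counts, s1$counts)
  # rate conservation: sum over bins of rate * occupancy = total spikes
  occ <- as.vector(s1$occupancy)
  raw <- matrix(0, s1$n_cells, length(occ))
  raw[, occ > 0] <- sweep(s1$counts[, occ > 0, drop = FALSE], 2,
                          occ[occ > 0], "/")
  expect_equal(sum(raw %*% occ), sum(s1$counts), tolerance = 1e-9)
  # all-zero input produces zero spikes
  s0 <- simulate_session(traj, 0 * cur, seed = 3)
  expect_equal(sum(s0$counts), 0)
})

test_that("analytic mean rates match empirical session rates", {
  # the a-priori rate map is the truncated-normal tail probability per cycle;
  # a long session at a fixed position should converge to it
  p <- neuron_params()
  currents <- matrix(runif(12, 0.5, 1), ncol = 1)
  lam <- mean_rate_maps(cbind(currents, currents, currents, currents), p)
  traj <- grid_trajectory(bins = 2, box = 80, reps = 2000)
  s <- simulate_session(traj, cbind(currents, currents, currents, currents),
                        seed = 11)
  emp <- rowSums(s$counts) / s$duration_s
  expect_equal(emp, rowMeans(lam), tolerance = 0.12)
})

test_that("DG input to CA3 is the beta-scaled normalized presynaptic sum", {
  # toy: 2 presynaptic cells with normalized rates 0.5 and 0.25 at a position
  rates <- rbind(c(0.5, 0.1), c(0.25, 0.3))
  presyn <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = 1,
                                 dims = c(1, 2))
  dm <- dg_input_maps(rates, presyn, beta = 1, z = 1)
  expect_equal(as.numeric(dm$drive), c(0.75, 0.4))
  expect_equal(dg_input_current(rates, presyn, 1, 0.5, 0.5, beta = 1, z = 1,
                                box_cm = 2), 0.75)
  # beta = 0 silences the pathway; silent presynaptic cells contribute zero
  expect_equal(as.numeric(dg_input_maps(rates, presyn, beta = 0, z = 1)$drive),
               c(0, 0))
  expect_equal(as.numeric(dg_input_maps(0 * rates, presyn, beta = 2,
                                        z = 1)$drive), c(0, 0))
  # missing normalization constant is a state error
  expect_error(dg_input_current(rates, presyn, 1, 0.5, 0.5),
               class = "hippomorph_state_error")
  # default normalization: population mean of the per-cell spatial maximum
  dm2 <- dg_input_maps(rates, rbind(presyn, presyn), beta = 1)
  expect_equal(dm2$z, 0.75)
})

test_that("network frequency summarizes the rhythm of spiking cycles", {
  expect_equal(network_frequency(c(30, 32, 34), c(3.3, 3.3, 3.3)),
               1000 / 35.3)
  # silent cycles (first spike beyond the cycle) carry no latency
  expect_equal(network_frequency(c(30, 32, 34, 60), rep(3.3, 4)),
               1000 / 35.3)
  expect_true(is.na(network_frequency(Inf, 3.3)))
})
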