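# Core gamma-cycle machinery.
#
# The membrane equation tau dV/dt = -(V - V_rest) + R*I with constant input has
# an exact geometric-series solution under explicit Euler, so first-spike
# latencies on the model's mixed grid (1 ms steps up to the population's first
# spike, 0.1 ms steps from there to GABA release) can be computed in closed
# form. run_gamma_cycle() below is the direct step-by-step integrator used as
# the reference (and for recurrent dynamics at small scale); the closed forms
# drive the vectorized session simulator.

# Coarse-grid first-crossing step count for drive (= R*I, mV above rest).
# Returns time in ms (multiples of dt_coarse), Inf where the steady state
# stays below threshold.
euler_latency_coarse <- function(drive_mv, params) {
  theta <- params$v_thresh - params$v_rest
  a <- 1 - params$dt_coarse / params$tau_n
  out <- rep(Inf, length(drive_mv))
  ok <- drive_mv > theta
  if (any(ok)) {
    k <- ceiling(log1p(-theta / drive_mv[ok]) / log(a) - 1e-9)
    out[ok] <- k * params$dt_coarse
  }
  out
}

# Latency on the mixed grid: coarse steps to t1 (the population's first spike
# time, itself on the coarse grid), then fine steps. `drive_mv` may be a
# matrix (cells x positions) with `t1` per column.
mixed_grid_latency <- function(drive_mv, t1, params) {
  theta <- params$v_thresh - params$v_rest
  a1 <- 1 - params$dt_coarse / params$tau_n
  a2 <- 1 - params$dt_fine / params$tau_n
  drive_mv <- as.matrix(drive_mv)
  t1 <- rep_len(t1, ncol(drive_mv))
  lat <- matrix(Inf, nrow(drive_mv), ncol(drive_mv))
  fin <- is.finite(t1)
  if (!any(fin)) return(list(lat = lat, t1 = t1))
  decay1 <- a1^(t1[fin] / params$dt_coarse)
  d <- drive_mv[, fin, drop = FALSE]
  nr <- nrow(d)
  v1 <- d * rep(1 - decay1, each = nr)          # voltage above rest at t1
  sub <- d > theta
  m <- matrix(Inf, nr, ncol(d))
  m[sub] <- ceiling(log((d[sub] - theta) / (d[sub] - v1[sub])) / log(a2) - 1e-9)
  m[sub & v1 >= theta] <- 0                     # crossed on the coarse grid
  lat[, fin] <- m * params$dt_fine + rep(t1[fin], each = nr)
  list(lat = lat, t1 = t1)
}

# Latency map for a feedforward current map (cells x positions, nA).
# Chunked over columns to bound peak memory. Returns list(lat, t1).
latency_map <- function(current_map, params, chunk = 512L) {
  drive <- params$r_n
  n_pos <- ncol(current_map)
  lat <- matrix(Inf, nrow(current_map), n_pos)
  t1 <- rep(Inf, n_pos)
  for (s in seq(1, n_pos, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n_pos)
    d <- current_map[, idx, drop = FALSE] * drive
    # the coarse latency is monotone in drive, so the population first spike
    # is the coarse latency of the per-position maximum drive
    t1c <- euler_latency_coarse(apply(d, 2, max), params)
    res <- mixed_grid_latency(d, t1c, params)
    lat[, idx] <- res$lat
    t1[idx] <- t1c
  }
  list(lat = lat, t1 = t1)
}

# A-priori mean rate map (Hz): per-cycle spike probability is the probability
# that the truncated-normal inhibition delay exceeds the latency margin.
spike_prob <- function(lat, t1, params) {
  lat <- as.matrix(lat)
  x <- lat - rep(rep_len(t1, ncol(lat)), each = nrow(lat))
  trunc_norm <- pnorm(0, params$inh_delay_mean, params$inh_delay_sd,
                      lower.tail = FALSE)
  p <- pnorm(x, params$inh_delay_mean, params$inh_delay_sd,
             lower.tail = FALSE) / trunc_norm
  p[!is.finite(lat)] <- 0
  # the first spike must fall within the gamma cycle; the GABA window then
  # runs its full course even if it crosses the nominal cycle boundary
  p[, rep_len(t1, ncol(p)) > params$gamma_t] <- 0
  p
}

#' A-priori mean rate maps from a feedforward current map
#'
#' With feedforward-only dynamics and independent gamma cycles, a cell spikes
#' in a cycle exactly when its first-spike latency beats the (random)
#' inhibition onset, so its mean rate at a position is the truncated-normal
#' tail probability divided by the cycle duration. This is the "computed a
#' priori" mean rate used as the DG input to CA3.
#'
#' @param current_map Cells x positions matrix of feedforward currents (nA).
#' @param params [neuron_params()].
#' @return Cells x positions matrix of mean rates (Hz); the maximum possible
#'   rate is one spike per gamma cycle (~27.4 Hz).
#' @export
mean_rate_maps <- function(current_map, params = neuron_params()) {
  lt <- latency_map(current_map, params)
  spike_prob(lt$lat, lt$t1, params) / (params$gamma_t / 1000)
}

#' Simulate one gamma cycle of a population
#'
#' Direct Euler integration of the integrate-and-fire population for a single
#' competitive gamma cycle: 1 ms steps from rest until the first population
#' spike, then 0.1 ms steps until the onset of global feedback inhibition
#' (first spike time plus a normally distributed delay), after which no
#' further spikes occur. Spiking cells are reset to rest, receive a decaying
#' after-hyperpolarization current, and respect the absolute refractory
#' period. If `rec_params` is supplied, every spike contributes a 3 ms step
#' EPSC with a 1 ms release lag to its cluster partners; a cell whose summed
#' weighted recurrent drive (self-connection excluded) exceeds
#' `delta * incoming weight` receives the saturating feedback current.
#'
#' @param ff_currents Nonnegative per-cell feedforward currents (nA), constant
#'   within the cycle.
#' @param rec_params Optional [recurrent_params()]; its weight matrix must
#'   match `length(ff_currents)`.
#' @param params [neuron_params()].
#' @param inh_delay Inhibition delay (ms); sampled from the truncated normal
#'   if `NULL`.
#' @param seed Seed used when sampling the delay.
#' @return A list of class `hm_cycle`: `spike_times` (list per cell, ms),
#'   `first_spike_time`, `inhibition_onset` (ms; `Inf` if no cell fired).
#' @export
#' @examples
#' # a 0.9 nA cell fires at ~21 ms; a 0.6 nA cell stays silent for the cycle
#' run_gamma_cycle(c(0.9, 0.6), inh_delay = 3.3)$spike_times
run_gamma_cycle <- function(ff_currents, rec_params = NULL,
                            params = neuron_params(), inh_delay = NULL,
                            seed = 1) {
  if (any(ff_currents < 0) || anyNA(ff_currents)) {
    abort("Feedforward currents must be nonnegative.",
          class = "hippomorph_argument_error")
  }
  n <- length(ff_currents)
  if (!is.null(rec_params)) {
    if (!inherits(rec_params, "recurrent_params")) {
      abort("`rec_params` must be built with recurrent_params().",
            class = "hippomorph_state_error")
    }
    if (nrow(rec_params$w) != n) {
      abort("Recurrent weight matrix does not match the population size.",
            class = "hippomorph_state_error")
    }
  }
  theta <- params$v_thresh - params$v_rest
  drive <- params$r_n * ff_currents
  # --- coarse phase: 1 ms steps from rest to the first population spike
  a1 <- 1 - params$dt_coarse / params$tau_n
  v <- rep(0, n)                      # voltage above rest
  t1 <- Inf
  n_coarse <- floor(params$gamma_t / params$dt_coarse)
  for (k in seq_len(n_coarse)) {
    v <- a1 * v + (1 - a1) * drive
    if (any(v >= theta)) { t1 <- k * params$dt_coarse; break }
  }
  spike_times <- rep(list(numeric(0)), n)
  if (!is.finite(t1)) {
    return(structure(list(spike_times = spike_times, first_spike_time = Inf,
                          inhibition_onset = Inf), class = "hm_cycle"))
  }
  if (is.null(inh_delay)) {
    inh_delay <- withr_seed(seed, sample_inh_delay(1, params))
  }
  onset <- t1 + inh_delay
  t_end <- onset
  first <- which(v >= theta)
  for (i in first) spike_times[[i]] <- t1
  refr_until <- rep(-Inf, n); refr_until[first] <- t1 + params$tau_spike
  last_spike <- rep(NA_real_, n); last_spike[first] <- t1
  v[first] <- 0
  # EPSC event schedule (times on the fine grid)
  ep_on <- lapply(seq_len(n), function(i) numeric(0))
  active_epsc <- rep(0, n)
  events <- list()
  add_epsc <- function(j, ts) {
    events[[length(events) + 1]] <<- c(ts + params$rec_lag, j, 1)
    events[[length(events) + 1]] <<- c(ts + params$rec_lag + params$epsc_dur,
                                       j, -1)
  }
  if (!is.null(rec_params)) for (i in first) add_epsc(i, t1)
  # --- fine phase: 0.1 ms steps in the window before GABA release
  a2 <- 1 - params$dt_fine / params$tau_n
  t <- t1
  wmat <- if (!is.null(rec_params)) as.matrix(rec_params$w) else NULL
  if (!is.null(wmat)) diag(wmat) <- 0            # no autapse drive
  h <- rep(0, n)
  while (t + params$dt_fine < t_end - 1e-12) {
    t <- t + params$dt_fine
    if (!is.null(rec_params) && length(events)) {
      due <- vapply(events, function(e) e[1] <= t + 1e-12, logical(1))
      for (e in events[due]) {
        active_epsc[e[2]] <- active_epsc[e[2]] + e[3]
      }
      if (any(due)) h <- as.numeric(wmat %*% pmin(active_epsc, 1))
      events <- events[!due]
    }
    i_rec <- if (!is.null(rec_params)) {
      rec_params$i_rec_max *
        as.numeric(h > rec_params$delta * rec_params$incoming)
    } else 0
    i_ahp <- ifelse(is.na(last_spike), 0,
                    params$a_ahp * exp(-(t - last_spike) / params$tau_ahp))
    i_tot <- ff_currents + i_rec + i_ahp
    upd <- refr_until <= t
    v[upd] <- a2 * v[upd] + (1 - a2) * params$r_n * i_tot[upd]
    v[!upd] <- 0
    cross <- which(v >= theta & upd)
    for (i in cross) {
      spike_times[[i]] <- c(spike_times[[i]], t)
      v[i] <- 0
      refr_until[i] <- t + params$tau_spike
      last_spike[i] <- t
      if (!is.null(rec_params)) add_epsc(i, t)
    }
  }
  structure(list(spike_times = spike_times, first_spike_time = t1,
                 inhibition_onset = onset), class = "hm_cycle")
}

#' Operational network oscillation frequency
#'
#' The model has no explicit oscillator; the network rhythm is operationalized
#' as the reciprocal of the median cycle "active time": first-spike latency
#' plus the sampled inhibition delay.
#'
#' @param first_spike_ms First-spike latencies (ms), one per cycle; cycles
#'   whose latency exceeds the cycle duration produced no spike and carry no
#'   measurable first-spike time, so they are excluded.
#' @param delays_ms Sampled inhibition delays (ms), one per cycle.
#' @param gamma_t Gamma-cycle duration (ms) bounding measurable latencies.
#' @return Frequency in Hz.
#' @export
network_frequency <- function(first_spike_ms, delays_ms,
                              gamma_t = neuron_params()$gamma_t) {
  tot <- first_spike_ms + delays_ms
  tot <- tot[is.finite(tot) & first_spike_ms <= gamma_t]
  if (!length(tot)) return(NA_real_)
  1000 / median(tot)
}

#' @export
print.hm_cycle <- function(x, ...) {
  ns <- sum(lengths(x$spike_times))
  cat(sprintf("<hm_cycle> %d spikes, first at %.1f ms, inhibition onset %.2f ms\n",
              ns, x$first_spike_time, x$inhibition_onset))
  invisible(x)
}
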