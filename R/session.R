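#' Simulate a full foraging session of one region
#'
#' Runs one independent competitive gamma cycle per trajectory sample: the
#' feedforward current of every cell is looked up for the current position
#' (and morph condition, already folded into `current_map`), the population's
#' first-spike latency opens the cycle, a freshly sampled inhibition delay
#' closes it, and every cell whose latency beats the GABA onset fires. With
#' `rec_params`, spikes of stored-pattern cells additionally deliver lagged
#' step EPSCs that can recruit subthreshold cluster partners within the window
#' (pattern completion); the recurrent window is integrated with 0.1 ms steps.
#' Spikes are accumulated into per-cell counts on the analysis grid;
#' `record_spikes = TRUE` additionally returns a time-stamped spike table.
#'
#' @param trajectory An `hm_trajectory`; one gamma cycle is simulated per row.
#' @param current_map Cells x positions matrix of feedforward currents (nA) on
#'   the square input grid (e.g. 80x80 at 1 cm); columns follow
#'   [position_bins()] indexing.
#' @param params [neuron_params()].
#' @param seed Integer seed for the per-cycle inhibition delays.
#' @param rec_params Optional [recurrent_params()] enabling CA3 recurrence.
#' @param record_spikes Keep a tibble of individual spikes (cycle, cell, time
#'   within cycle, position)?
#' @param region Label, `"dg"` or `"ca3"`.
#' @param condition Morph condition (defaults to the trajectory's).
#' @param latency Optional precomputed `latency_map(current_map, params)` to
#'   avoid recomputation across sessions.
#' @param analysis_bins Analysis grid side (16 bins of 5 cm).
#' @return A list of class `hm_session`: `counts` (cells x analysis bins),
#'   `occupancy` (seconds), `duration_s`, `condition`, `region`, `box_cm`,
#'   `analysis_bins`, `n_cells`, `spikes` (tibble or NULL), `first_spike_ms`
#'   and `delays_ms` per cycle (for the network-frequency diagnostic).
#' @export
simulate_session <- function(trajectory, current_map,
                             params = neuron_params(), seed = 1,
                             rec_params = NULL, record_spikes = FALSE,
                             region = "dg",
                             condition = attr(trajectory, "condition"),
                             latency = NULL, analysis_bins = 16) {
  box <- attr(trajectory, "box_cm")
  dt_s <- attr(trajectory, "dt_s")
  if (is.null(current_map)) {
    if (is.null(latency) || !is.null(rec_params)) {
      abort("`current_map` may be NULL only with precomputed `latency` and no recurrence.",
            class = "hippomorph_validation_error")
    }
    n_pos <- ncol(latency$lat)
  } else {
    n_pos <- ncol(current_map)
  }
  bins_in <- as.integer(round(sqrt(n_pos)))
  if (bins_in^2 != n_pos) {
    abort("`current_map` must have a square number of position columns.",
          class = "hippomorph_validation_error")
  }
  if (!is.null(rec_params) && nrow(rec_params$w) != nrow(current_map)) {
    abort("Recurrent weights do not match the population size.",
          class = "hippomorph_validation_error")
  }
  if (is.null(latency)) latency <- latency_map(current_map, params)
  n_cells <- nrow(latency$lat)
  n_cyc <- nrow(trajectory)
  b_in <- position_bins(trajectory$x_cm, trajectory$y_cm, box, bins_in)
  b_an <- position_bins(trajectory$x_cm, trajectory$y_cm, box, analysis_bins)
  delays <- withr_seed(seed, sample_inh_delay(n_cyc, params))
  counts <- matrix(0L, n_cells, analysis_bins^2)
  t1_cycle <- latency$t1[b_in]
  spikes <- NULL

  if (is.null(rec_params) && !record_spikes) {
    # grouped fast path: cycles sharing a position bin share latencies and
    # differ only in the sampled delay
    for (b in unique(b_in)) {
      if (latency$t1[b] > params$gamma_t) next
      cyc <- which(b_in == b)
      x <- latency$lat[, b] - latency$t1[b]
      d <- sort(delays[cyc])
      cnt <- length(d) - findInterval(x, d)
      cb <- b_an[cyc[1]]
      counts[, cb] <- counts[, cb] + cnt
    }
  } else {
    mem <- if (!is.null(rec_params)) {
      prepare_recurrence(rec_params, current_map, params)
    } else NULL
    sp_cell <- list(); sp_time <- list(); sp_cyc <- list()
    for (k in seq_len(n_cyc)) {
      b <- b_in[k]
      t1 <- latency$t1[b]
      if (t1 > params$gamma_t) next
      t_end <- t1 + delays[k]
      lat_col <- latency$lat[, b]
      if (is.null(mem)) {
        who <- which(lat_col < t_end)
        times <- lat_col[who]
      } else {
        res <- recurrent_window(mem, b, t1, t_end, lat_col, params)
        who <- res$cell
        times <- res$time
      }
      if (length(who)) {
        cb <- b_an[k]
        tab <- tabulate(who, nbins = n_cells)
        counts[, cb] <- counts[, cb] + tab
        if (record_spikes) {
          sp_cell[[length(sp_cell) + 1]] <- who
          sp_time[[length(sp_time) + 1]] <- times
          sp_cyc[[length(sp_cyc) + 1]] <- rep(k, length(who))
        }
      }
    }
    if (record_spikes) {
      cyc <- unlist(sp_cyc) %||% integer(0)
      spikes <- tibble(
        cycle = cyc,
        cell = unlist(sp_cell) %||% integer(0),
        t_ms = unlist(sp_time) %||% numeric(0),
        time_s = trajectory$time_s[cyc],
        x_cm = trajectory$x_cm[cyc],
        y_cm = trajectory$y_cm[cyc]
      )
    }
  }
  structure(list(
    counts = counts,
    occupancy = occupancy_map(trajectory, analysis_bins),
    duration_s = n_cyc * dt_s,
    condition = condition, region = region, box_cm = box,
    analysis_bins = analysis_bins, n_cells = n_cells,
    spikes = spikes,
    first_spike_ms = t1_cycle, delays_ms = delays
  ), class = "hm_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Precompute the dense within-memory machinery for the recurrent window.
prepare_recurrence <- function(rec_params, current_map, params) {
  inc <- rec_params$incoming
  outg <- Matrix::colSums(rec_params$w)
  mem_idx <- which(inc > 0 | outg > 0)
  wm <- as.matrix(rec_params$w[mem_idx, mem_idx, drop = FALSE])
  diag(wm) <- 0
  list(
    idx = mem_idx,
    wm = wm,
    thr = rec_params$delta * inc[mem_idx],
    i_max = rec_params$i_rec_max,
    i_ff = current_map[mem_idx, , drop = FALSE]
  )
}

# Integrate the window between the first spike and GABA onset for the memory
# cells of one cycle; non-memory cells fire on their feedforward latency.
# Returns integer cell indices (with multiplicity) and spike times.
recurrent_window <- function(mem, b, t1, t_end, lat_col, params) {
  # feedforward-only spikes of cells outside the memory
  nonmem_who <- setdiff(which(lat_col < t_end), mem$idx)
  cells <- nonmem_who
  times <- lat_col[nonmem_who]
  m <- length(mem$idx)
  if (m == 0 || t1 >= t_end) {
    return(list(cell = cells, time = times))
  }
  # if no memory cell can fire feedforward before onset, no EPSC ever starts
  lat_mem <- lat_col[mem$idx]
  if (min(lat_mem) + params$rec_lag >= t_end) {
    who <- which(lat_mem < t_end)
    return(list(cell = c(cells, mem$idx[who]),
                time = c(times, lat_mem[who])))
  }
  theta <- params$v_thresh - params$v_rest
  a1 <- 1 - params$dt_coarse / params$tau_n
  a2 <- 1 - params$dt_fine / params$tau_n
  i_ff <- mem$i_ff[, b]
  v <- params$r_n * i_ff * (1 - a1^(t1 / params$dt_coarse))
  n_steps <- floor((t_end - t1) / params$dt_fine - 1e-9)
  # EPSC on/off events indexed by fine step
  ev_on <- vector("list", n_steps + 1L)
  ev_off <- vector("list", n_steps + 1L)
  lag_steps <- as.integer(round(params$rec_lag / params$dt_fine))
  dur_steps <- as.integer(round(params$epsc_dur / params$dt_fine))
  schedule <- function(step) {
    on <- step + lag_steps
    if (on <= n_steps) {
      off <- on + dur_steps
      list(on = on + 1L, off = if (off <= n_steps) off + 1L else NA_integer_)
    } else NULL
  }
  epsc_count <- integer(m)
  h <- numeric(m)
  refr_until <- rep(-Inf, m)
  last_spike <- rep(NA_real_, m)
  # cells crossing on the coarse grid fire at t1
  first <- which(v >= theta)
  if (length(first)) {
    for (i in first) {
      cells <- c(cells, mem$idx[i]); times <- c(times, t1)
      ev <- schedule(0L)
      if (!is.null(ev)) {
        ev_on[[ev$on]] <- c(ev_on[[ev$on]], i)
        if (!is.na(ev$off)) ev_off[[ev$off]] <- c(ev_off[[ev$off]], i)
      }
    }
    refr_until[first] <- t1 + params$tau_spike
    last_spike[first] <- t1
    v[first] <- 0
  }
  if (n_steps < 1) return(list(cell = cells, time = times))
  for (s in seq_len(n_steps)) {
    t <- t1 + s * params$dt_fine
    for (j in ev_on[[s]]) {
      epsc_count[j] <- epsc_count[j] + 1L
      if (epsc_count[j] == 1L) h <- h + mem$wm[, j]
    }
    for (j in ev_off[[s]]) {
      epsc_count[j] <- epsc_count[j] - 1L
      if (epsc_count[j] == 0L) h <- h - mem$wm[, j]
    }
    i_rec <- mem$i_max * (h > mem$thr)
    i_ahp <- ifelse(is.na(last_spike), 0,
                    params$a_ahp * exp(-(t - last_spike) / params$tau_ahp))
    i_tot <- i_ff + i_rec + i_ahp
    upd <- refr_until <= t
    v[upd] <- a2 * v[upd] + (1 - a2) * params$r_n * i_tot[upd]
    v[!upd] <- 0
    cross <- which(v >= theta & upd)
    if (length(cross)) {
      for (i in cross) {
        cells <- c(cells, mem$idx[i]); times <- c(times, t)
        ev <- schedule(s)
        if (!is.null(ev)) {
          ev_on[[ev$on]] <- c(ev_on[[ev$on]], i)
          if (!is.na(ev$off)) ev_off[[ev$off]] <- c(ev_off[[ev$off]], i)
        }
      }
      v[cross] <- 0
      refr_until[cross] <- t + params$tau_spike
      last_spike[cross] <- t
    }
  }
  list(cell = cells, time = times)
}

#' Per-cell mean firing rates of a session
#'
#' @param session An `hm_session`.
#' @return Numeric vector, spikes divided by session duration (Hz).
#' @export
session_mean_rates <- function(session) {
  rowSums(session$counts) / session$duration_s
}

#' @export
print.hm_session <- function(x, ...) {
  cat(sprintf(
    "<hm_session> %s, condition %s, %d cells, %.0f s, %d spikes (%.1f%% cells active)\n",
    x$region, as.character(x$condition), x$n_cells, x$duration_s,
    sum(x$counts), 100 * mean(session_mean_rates(x) > 0.1)))
  invisible(x)
}
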