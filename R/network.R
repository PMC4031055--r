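#' Configuration for the EC/DG/CA3 morphing model
#'
#' Collects network sizes, convergence counts, mixing and recall parameters,
#' seeds and session durations. Defaults are the desk-scale study conditions:
#' 8000 MEC + 8000 LEC cells, 8000 simulated DG granule cells (the top decile
#' by mean synaptic weight of a conceptual pool of 80,000), 2000 CA3 cells,
#' the anatomical convergence counts (DG: 1200 MEC + 1500 LEC synapses; CA3:
#' 1400 MEC + 1500 LEC; ~50 DG inputs per CA3 cell), balanced entorhinal
#' mixing (alpha = 0.5), DG-to-EC gain beta = 1, and the best-fit recall
#' threshold 1 - delta = 95%.
#'
#' @param n_mec,n_lec Entorhinal population sizes.
#' @param n_dg Simulated DG cells (after top-percentile selection).
#' @param dg_top_fraction Fraction of the conceptual DG pool simulated (0.1).
#' @param n_ca3 CA3 cells.
#' @param conv Named list of convergence counts: `dg_mec`, `dg_lec`,
#'   `ca3_mec`, `ca3_lec`, `ca3_dg`.
#' @param alpha MEC/LEC mixing factor in `[0, 1]`.
#' @param beta DG-to-EC relative gain.
#' @param delta Recurrent excitation threshold (recall threshold = 1 - delta).
#' @param l_rate Learning factor for end-of-session weight updates.
#' @param box_cm Box side (cm).
#' @param res_cm Input-map resolution (cm).
#' @param session_s Session duration for morph-comparison sessions (s).
#' @param seeds Named list of base seeds: `ec`, `weights`, `trajectory`,
#'   `delays`. Trajectory/delay seeds are offset per session so that compared
#'   sessions always use different trajectories.
#' @param params [neuron_params()].
#' @param lec_rectify_q,grid_sharpness,weight_sdlog Input-map tailoring knobs
#'   passed to [make_lec_population()], [make_mec_population()] and
#'   [build_feedforward_weights()]. The defaults are calibrated for the full
#'   desk-scale convergence; reduced-scale runs have relatively wider input
#'   spread and may prefer a smaller `lec_rectify_q`.
#' @param scale Scale factor in (0, 1] applied to all population sizes and
#'   convergence counts (desk runs use 1; tests use small values).
#' @return A list of class `hm_config`.
#' @export
morph_config <- function(n_mec = 8000, n_lec = 8000, n_dg = 8000,
                         dg_top_fraction = 0.1, n_ca3 = 2000,
                         conv = list(dg_mec = 1200, dg_lec = 1500,
                                     ca3_mec = 1400, ca3_lec = 1500,
                                     ca3_dg = 50),
                         alpha = 0.5, beta = 1, delta = 0.05, l_rate = 0,
                         box_cm = 80, res_cm = 1, session_s = 120,
                         seeds = list(ec = 101, weights = 202,
                                      trajectory = 1000, delays = 5000),
                         params = neuron_params(),
                         lec_rectify_q = 0.05, grid_sharpness = 1,
                         weight_sdlog = 0.78, scale = 1) {
  if (!is.numeric(scale) || scale <= 0 || scale > 1) {
    abort("`scale` must lie in (0, 1].", class = "hippomorph_validation_error")
  }
  if (alpha < 0 || alpha > 1 || delta < 0 || delta > 1 ||
      l_rate < 0 || l_rate > 1 || beta < 0) {
    abort("alpha, delta and l_rate must lie in [0, 1]; beta must be >= 0.",
          class = "hippomorph_validation_error")
  }
  sc <- function(x) max(2L, as.integer(round(x * scale)))
  cfg <- list(
    n_mec = sc(n_mec), n_lec = sc(n_lec), n_dg = sc(n_dg),
    dg_top_fraction = dg_top_fraction, n_ca3 = sc(n_ca3),
    conv = lapply(conv, sc),
    alpha = alpha, beta = beta, delta = delta, l_rate = l_rate,
    box_cm = box_cm, res_cm = res_cm, session_s = session_s,
    seeds = seeds, params = params, scale = scale,
    lec_rectify_q = lec_rectify_q, grid_sharpness = grid_sharpness,
    weight_sdlog = weight_sdlog
  )
  if (cfg$conv$dg_mec > cfg$n_mec || cfg$conv$ca3_mec > cfg$n_mec ||
      cfg$conv$dg_lec > cfg$n_lec || cfg$conv$ca3_lec > cfg$n_lec) {
    abort("Convergence counts cannot exceed the presynaptic population size.",
          class = "hippomorph_validation_error")
  }
  structure(cfg, class = "hm_config")
}

# Trajectory/delay seed for session slot `k` of an experiment.
session_seed <- function(config, k, which = c("trajectory", "delays")) {
  which <- match.arg(which)
  as.integer((config$seeds[[which]] + 17L * k) %% 2147483647)
}

#' Assemble the full EC/DG/CA3 network and its per-condition input maps
#'
#' Builds the entorhinal populations and synapse matrices, selects the
#' simulated DG cells (top weight decile of the conceptual pool), computes
#' the normalized entorhinal drive for DG and CA3, derives the a-priori DG
#' mean-rate maps per morph condition analytically, and folds them (with the
#' beta gain and the mean-max normalization) into per-condition CA3 current
#' maps. DG sessions listed in `dg_session_plan` are simulated during the
#' per-condition sweep so large DG latency maps never need to be retained.
#'
#' @param config An [morph_config()] object.
#' @param conditions Morph conditions for which CA3 input maps are built.
#' @param dg_session_plan Optional tibble with columns `condition`,
#'   `duration_s` and `slot` (seed slot); one DG session is simulated per
#'   row.
#' @param mec_pop Optional MEC population override (e.g. a realigned
#'   population).
#' @param keep_dg_latency Keep DG latency maps per condition (memory-heavy at
#'   desk scale; intended for small runs).
#' @return A list of class `hm_network` with the populations, weights,
#'   `ca3_current`/`ca3_latency` per condition, `dg_sessions`, and the
#'   normalization constants.
#' @export
build_network <- function(config, conditions = 1:7, dg_session_plan = NULL,
                          mec_pop = NULL, keep_dg_latency = FALSE,
                          regions = c("dg", "ca3")) {
  stopifnot(inherits(config, "hm_config"))
  if (any(conditions < 1 | conditions > 7)) {
    abort("Conditions must lie in 1..7.", class = "hippomorph_validation_error")
  }
  conditions <- sort(unique(c(1L, as.integer(conditions))))
  p <- config$params
  if (is.null(mec_pop)) {
    mec_pop <- make_mec_population(config$n_mec, config$box_cm,
                                   sharpness = config$grid_sharpness %||% 1,
                                   seed = config$seeds$ec + 1L)
  }
  lec_pop <- make_lec_population(config$n_lec, config$box_cm, config$res_cm,
                                 rectify_q = config$lec_rectify_q %||% 0.05,
                                 seed = config$seeds$ec + 2L)
  mec_maps <- mec_rate_maps(mec_pop, config$box_cm, config$res_cm)
  sdl <- config$weight_sdlog %||% 0.78
  w_dg <- build_feedforward_weights(
    config$n_dg, config$n_mec, config$n_lec,
    config$conv$dg_mec, config$conv$dg_lec,
    seed = config$seeds$weights + 1L, top_fraction = config$dg_top_fraction,
    sdlog = sdl
  )
  with_ca3 <- "ca3" %in% regions
  w_ca3 <- presyn <- NULL
  if (with_ca3) {
    w_ca3 <- build_feedforward_weights(
      config$n_ca3, config$n_mec, config$n_lec,
      config$conv$ca3_mec, config$conv$ca3_lec,
      seed = config$seeds$weights + 2L, sdlog = sdl
    )
    # presynaptic DG partners of each CA3 cell, drawn from the conceptual
    # pool; partners outside the simulated top decile stay silent
    presyn <- withr_seed(config$seeds$weights + 3L, {
      i <- integer(0); j <- integer(0)
      for (cell in seq_len(config$n_ca3)) {
        pick <- sample.int(w_dg$pool_size, config$conv$ca3_dg)
        hit <- match(pick, w_dg$pool_ids)
        hit <- hit[!is.na(hit)]
        i <- c(i, rep(cell, length(hit))); j <- c(j, hit)
      }
      Matrix::sparseMatrix(i = i, j = j, x = 1,
                           dims = c(config$n_ca3, config$n_dg))
    })
  }
  keep_ec_maps <- length(lec_pop$map_a) <= 5e7
  gff <- p$g_ff
  n_pos <- ncol(mec_maps)
  # condition-1 entorhinal drive (current, nA) per region, built term by term
  # so at most one extra full-size matrix is alive at a time; z constants are
  # the population mean-max of each raw term in the square environment
  pos_blocks0 <- split(seq_len(n_pos), ceiling(seq_len(n_pos) / 800))
  # drives are built per position block; the normalization constants need the
  # per-cell maximum over all positions, accumulated across blocks
  build_drive <- function(w, alpha) {
    mr <- w$mean_ratio %||% 1
    acc <- matrix(0, nrow(w$w_mec), n_pos)
    rmax <- rep(-Inf, nrow(w$w_mec))
    for (pb in pos_blocks0) {
      blk <- as.matrix(w$w_mec %*% mec_maps[, pb, drop = FALSE])
      rmax <- pmax(rmax, row_maxima(blk))
      acc[, pb] <- blk
      rm(blk)
    }
    z_mec <- max(mean(rmax) * mr, 1e-12)
    acc <- acc * (gff * alpha / z_mec)
    rmax <- rep(-Inf, nrow(w$w_mec))
    lecblk <- vector("list", length(pos_blocks0))
    for (k in seq_along(pos_blocks0)) {
      pb <- pos_blocks0[[k]]
      blk <- as.matrix(w$w_lec %*% lec_pop$map_a[, pb, drop = FALSE])
      rmax <- pmax(rmax, row_maxima(blk))
      lecblk[[k]] <- blk
    }
    z_lec <- max(mean(rmax) * mr, 1e-12)
    for (k in seq_along(pos_blocks0)) {
      pb <- pos_blocks0[[k]]
      acc[, pb] <- acc[, pb] + lecblk[[k]] * (gff * (1 - alpha) / z_lec)
      lecblk[k] <- list(NULL)
    }
    list(drive = acc, z_mec = z_mec, z_lec = z_lec)
  }
  dg_d <- build_drive(w_dg, config$alpha)
  drive_dg <- dg_d$drive; dg_d$drive <- NULL
  ca3_d <- NULL; drive_ca3 <- NULL
  if (with_ca3) {
    ca3_d <- build_drive(w_ca3, config$alpha)
    drive_ca3 <- ca3_d$drive; ca3_d$drive <- NULL
  }
  terms_dg <- terms_ca3 <- NULL
  if (keep_ec_maps) {
    terms_dg <- compute_ec_terms(w_dg, mec_maps, lec_pop)
    if (with_ca3) terms_ca3 <- compute_ec_terms(w_ca3, mec_maps, lec_pop)
  } else {
    terms_dg <- structure(list(z_mec = dg_d$z_mec, z_lec = dg_d$z_lec),
                          class = "ec_terms")
    if (with_ca3) {
      terms_ca3 <- structure(list(z_mec = ca3_d$z_mec, z_lec = ca3_d$z_lec),
                             class = "ec_terms")
    }
  }
  rm(mec_maps)
  lec_diff <- lec_pop$map_b - lec_pop$map_a
  c_star <- lec_pop$c_star
  lec_keep <- if (keep_ec_maps) lec_pop else {
    structure(list(map_a = NULL, map_b = NULL, c_star = c_star,
                   box_cm = lec_pop$box_cm, res_cm = lec_pop$res_cm),
              class = "lec_population")
  }
  rm(lec_pop)
  net <- list(
    config = config, mec_pop = mec_pop, lec_pop = lec_keep,
    dg_weights = w_dg, ca3_weights = w_ca3, presyn = presyn,
    terms_dg = terms_dg, terms_ca3 = terms_ca3,
    ca3_current = list(),
    dg_latency = list(), dg_sessions = list(), z_dg = NULL
  )
  pos_blocks <- split(seq_len(n_pos), ceiling(seq_len(n_pos) / 800))
  # add the switched-cell LEC increment to a running drive matrix, by
  # position block to bound the temporaries
  apply_switch <- function(drive, w_lec, sw, scale) {
    for (pb in pos_blocks) {
      drive[, pb] <- drive[, pb] +
        scale * as.matrix(w_lec[, sw, drop = FALSE] %*%
                            lec_diff[sw, pb, drop = FALSE])
    }
    drive
  }
  prev_cond <- 1
  for (cond in conditions) {
    key <- as.character(cond)
    sw <- which(c_star > prev_cond & c_star <= cond)
    if (length(sw)) {
      drive_dg <- apply_switch(drive_dg, w_dg$w_lec, sw,
                               gff * (1 - config$alpha) / dg_d$z_lec)
      if (with_ca3) {
        drive_ca3 <- apply_switch(drive_ca3, w_ca3$w_lec, sw,
                                  gff * (1 - config$alpha) / ca3_d$z_lec)
      }
    }
    prev_cond <- cond
    rows <- if (is.null(dg_session_plan)) integer(0) else {
      which(dg_session_plan$condition == cond)
    }
    dg_needed <- keep_dg_latency || length(rows) > 0
    # single pass over contiguous position blocks: population first-spike
    # time from the per-position maximum drive (the coarse latency is
    # monotone in drive), then mixed-grid latencies and a-priori rates
    lat_full <- if (dg_needed) matrix(Inf, config$n_dg, n_pos)
    d_raw <- if (with_ca3) matrix(0, config$n_ca3, n_pos)
    t1 <- rep(Inf, n_pos)
    for (pb in pos_blocks) {
      block <- drive_dg[, pb, drop = FALSE] * p$r_n
      t1b <- euler_latency_coarse(apply(block, 2, max), p)
      res <- mixed_grid_latency(block, t1b, p)
      rm(block)
      if (with_ca3) {
        lam <- spike_prob(res$lat, t1b, p) / (p$gamma_t / 1000)
        d_raw[, pb] <- as.matrix(presyn %*% lam)
        rm(lam)
      }
      if (dg_needed) lat_full[, pb] <- res$lat
      t1[pb] <- t1b
      rm(res)
    }
    if (with_ca3) {
      if (cond == 1L) net$z_dg <- max(mean(row_maxima(d_raw)), 1e-12)
      i_ca3 <- drive_ca3 + d_raw * (gff * config$beta / net$z_dg)
      rm(d_raw)
      net$ca3_current[[key]] <- i_ca3
      rm(i_ca3)
    }
    if (dg_needed) {
      lat_dg <- list(lat = lat_full, t1 = t1)
      if (keep_dg_latency) net$dg_latency[[key]] <- lat_dg
      for (r in rows) {
        traj <- generate_trajectory(
          dg_session_plan$duration_s[r], config$box_cm,
          seed = session_seed(config, dg_session_plan$slot[r], "trajectory"),
          condition = cond
        )
        net$dg_sessions[[sprintf("%d:%d", cond, dg_session_plan$slot[r])]] <-
          simulate_session(
            traj, current_map = NULL, params = p,
            seed = session_seed(config, dg_session_plan$slot[r], "delays"),
            region = "dg", condition = cond, latency = lat_dg
          )
      }
      rm(lat_dg, lat_full)
    }
    invisible(gc(FALSE))
  }
  invisible(gc(FALSE))
  structure(net, class = "hm_network")
}

#' DG input current to CA3 cells (mossy-fiber drive)
#'
#' The summed a-priori mean rates of a CA3 cell's fixed presynaptic DG
#' partners, normalized by the population mean of the per-cell spatial
#' maximum, scaled by the relative gain `beta`.
#'
#' @param dg_rate_maps DG cells x positions matrix of a-priori mean rates
#'   (Hz) for one morph condition (see [mean_rate_maps()]).
#' @param presyn Sparse CA3 x DG 0/1 assignment matrix (fixed per
#'   simulation).
#' @param beta Relative gain factor.
#' @param z Normalization constant (population mean-max of the raw summed
#'   input); computed from `dg_rate_maps` if NULL.
#' @return A list: `drive` (CA3 cells x positions, dimensionless), `z`.
#' @export
dg_input_maps <- function(dg_rate_maps, presyn, beta = 1, z = NULL) {
  raw <- as.matrix(presyn %*% dg_rate_maps)
  if (is.null(z)) z <- max(mean(row_maxima(raw)), 1e-12)
  list(drive = beta * raw / z, z = z)
}

#' @rdname dg_input_maps
#' @param cells CA3 cell indices.
#' @param x,y Position (cm).
#' @param box_cm Box side (cm).
#' @details `dg_input_current()` evaluates the drive at one position; it
#'   raises a state error if `z` is missing (the normalization must be
#'   precomputed over all positions).
#' @export
dg_input_current <- function(dg_rate_maps, presyn, cells, x, y, beta = 1,
                             z = NULL, box_cm = 80) {
  if (is.null(z)) {
    abort("Missing precomputed normalization: pass `z` from dg_input_maps().",
          class = "hippomorph_state_error")
  }
  bins <- as.integer(round(sqrt(ncol(dg_rate_maps))))
  b <- position_bins(x, y, box_cm, bins)
  raw <- as.numeric(presyn[cells, , drop = FALSE] %*% dg_rate_maps[, b])
  beta * raw / z
}

#' Simulate a CA3 session at a morph condition
#'
#' @param network An `hm_network` with CA3 maps for `condition`.
#' @param condition Morph condition.
#' @param slot Seed slot (distinct slots give distinct trajectories/delays).
#' @param memory Optional `hm_memory`; when given, recurrence is on with the
#'   config's `delta`.
#' @param duration_s Session duration (defaults to the config's).
#' @param record_spikes Keep the spike table.
#' @return An `hm_session`.
#' @export
simulate_ca3_session <- function(network, condition, slot, memory = NULL,
                                 duration_s = NULL, record_spikes = FALSE) {
  cfg <- network$config
  key <- as.character(condition)
  if (is.null(network$ca3_current[[key]])) {
    abort(sprintf("No CA3 input map for condition %s in this network.", key),
          class = "hippomorph_state_error")
  }
  dur <- duration_s %||% cfg$session_s
  traj <- generate_trajectory(dur, cfg$box_cm,
                              seed = session_seed(cfg, slot, "trajectory"),
                              condition = condition)
  rp <- if (!is.null(memory)) {
    recurrent_params(memory$w, delta = cfg$delta)
  } else NULL
  lat <- ca3_latency(network, condition)
  simulate_session(traj, network$ca3_current[[key]], params = cfg$params,
                   seed = session_seed(cfg, slot, "delays"),
                   rec_params = rp, record_spikes = record_spikes,
                   region = "ca3", condition = condition,
                   latency = lat)
}

#' CA3 latency map for a condition (computed once, cached)
#'
#' @param network An `hm_network`.
#' @param condition Morph condition with a stored CA3 current map.
#' @return A `latency_map()` list.
#' @export
ca3_latency <- function(network, condition) {
  key <- as.character(condition)
  if (is.null(network$ca3_current[[key]])) {
    abort(sprintf("No CA3 input map for condition %s in this network.", key),
          class = "hippomorph_state_error")
  }
  cache <- network$lat_cache
  if (is.null(cache[[key]])) {
    cache[[key]] <- latency_map(network$ca3_current[[key]],
                                network$config$params)
  }
  cache[[key]]
}

#' @export
print.hm_network <- function(x, ...) {
  cat(sprintf(
    "<hm_network> MEC %d + LEC %d -> DG %d (pool %d) -> CA3 %d; conditions: %s\n",
    x$config$n_mec, x$config$n_lec, x$config$n_dg, x$dg_weights$pool_size,
    x$config$n_ca3, paste(names(x$ca3_current), collapse = " ")))
  invisible(x)
}
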