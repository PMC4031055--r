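# Experiment orchestration: seven-shape morphing with and without recurrent
# collaterals, hysteresis / learning-rate protocols, grid realignment, and
# parametric search. Seed slots keep every compared session on a different
# trajectory while recurrence-on/off pairs share theirs (paired comparison).

SLOT_TRAIN_SQ <- 1L
SLOT_TRAIN_RD <- 2L
SLOT_MORPH <- 10L     # + condition
SLOT_DG <- 30L        # + condition
SLOT_SEQ <- 50L       # + step index
SLOT_REF <- 70L

# Training sessions (recurrence-free, shapes 1 and 7) and the memory matrix.
train_memory <- function(network, duration_s = NULL, k_range = NULL) {
  s1 <- simulate_ca3_session(network, 1, SLOT_TRAIN_SQ,
                             duration_s = duration_s)
  s7 <- simulate_ca3_session(network, 7, SLOT_TRAIN_RD,
                             duration_s = duration_s)
  list(memory = build_memory(s1, s7, k_range = k_range),
       session_square = s1, session_round = s7)
}

#' Run the environment-morphing experiment
#'
#' Builds the network, familiarizes it with the two extreme shapes (square,
#' condition 1; circle, condition 7) by storing their recurrence-free CA3
#' activity patterns in the recurrent weights, then simulates every requested
#' morph condition for CA3 with recurrence on and off (sharing trajectories
#' within a condition so the recurrence effect is a paired contrast) and,
#' optionally, for DG. Each condition uses a distinct trajectory.
#'
#' @param config An [morph_config()].
#' @param conditions Morph conditions to simulate (default 1:7).
#' @param dg Simulate DG sessions as well?
#' @param dg_duration_s Duration of DG sessions (defaults to the config's
#'   `session_s`).
#' @param network Optional prebuilt `hm_network` (must cover `conditions`
#'   and, for `dg = TRUE`, contain the matching DG sessions).
#' @param k_range Candidate cluster counts for the memory construction.
#' @return A list of class `hm_morph`: `ca3_on`, `ca3_off`, `dg` (session
#'   lists keyed by condition), `memory`, `training`, `network`, `config`.
#' @export
run_morphing <- function(config, conditions = 1:7, dg = TRUE,
                         dg_duration_s = NULL, network = NULL,
                         k_range = NULL) {
  conditions <- sort(unique(as.integer(conditions)))
  if (any(conditions < 1 | conditions > 7)) {
    abort("Conditions must lie in 1..7.", class = "hippomorph_validation_error")
  }
  if (is.null(network)) {
    plan <- if (dg) {
      tibble(condition = conditions,
             duration_s = dg_duration_s %||% config$session_s,
             slot = SLOT_DG + conditions)
    } else NULL
    network <- build_network(config, conditions = unique(c(conditions, 7L)),
                             dg_session_plan = plan)
  }
  tr <- train_memory(network, k_range = k_range)
  ca3_on <- list(); ca3_off <- list()
  for (cond in conditions) {
    key <- as.character(cond)
    ca3_off[[key]] <- simulate_ca3_session(network, cond, SLOT_MORPH + cond)
    ca3_on[[key]] <- simulate_ca3_session(network, cond, SLOT_MORPH + cond,
                                          memory = tr$memory)
  }
  dg_sessions <- list()
  if (dg) {
    for (cond in conditions) {
      key <- sprintf("%d:%d", cond, SLOT_DG + cond)
      if (!is.null(network$dg_sessions[[key]])) {
        dg_sessions[[as.character(cond)]] <- network$dg_sessions[[key]]
      }
    }
  }
  structure(list(
    ca3_on = ca3_on, ca3_off = ca3_off, dg = dg_sessions,
    memory = tr$memory,
    training = list(square = tr$session_square, round = tr$session_round),
    network = network, config = config
  ), class = "hm_morph")
}

#' Metric curves of a morphing experiment
#'
#' For every simulated region/recurrence setting, computes the mean PV
#' correlation, mean rate overlap and mean spatial correlation between the
#' reference condition and every other condition, plus the within-session PV
#' autocorrelation at 50 cm for the reference session. Active cells
#' (mean rate > 0.1 Hz in at least one condition of that region) are used
#' throughout.
#'
#' @param x An `hm_morph` experiment.
#' @param ref Reference condition (1).
#' @return A tibble with columns `region` ("dg", "ca3"), `recurrence`,
#'   `metric` ("pv", "overlap", "spatial", "pv_auto"), `cond`, `value`.
#' @export
morph_metrics <- function(x, ref = 1) {
  out <- list()
  if (length(x$dg)) {
    out[[length(out) + 1]] <- dplyr::mutate(
      region_metric_curve(x$dg, ref), region = "dg", recurrence = FALSE)
  }
  out[[length(out) + 1]] <- dplyr::mutate(
    region_metric_curve(x$ca3_off, ref), region = "ca3", recurrence = FALSE)
  out[[length(out) + 1]] <- dplyr::mutate(
    region_metric_curve(x$ca3_on, ref), region = "ca3", recurrence = TRUE)
  dplyr::bind_rows(out)[, c("region", "recurrence", "metric", "cond", "value")]
}

# Metric curve (vs `ref`) for one list of sessions keyed by condition.
region_metric_curve <- function(sessions, ref = 1,
                                metrics = c("pv", "overlap", "spatial",
                                            "pv_auto")) {
  keys <- names(sessions)
  act <- active_cells(sessions)
  ref_s <- sessions[[as.character(ref)]]
  rows <- list()
  for (key in keys) {
    cond <- as.numeric(key)
    s <- sessions[[key]]
    if ("pv" %in% metrics) {
      rows[[length(rows) + 1]] <- tibble(
        metric = "pv", cond = cond,
        value = pv_correlation(ref_s, s, cells = act)$mean)
    }
    if (any(c("overlap", "spatial") %in% metrics)) {
      cc <- compare_cells(ref_s, s, cells = act)
      if ("overlap" %in% metrics) {
        rows[[length(rows) + 1]] <- tibble(
          metric = "overlap", cond = cond,
          value = mean(cc$rate_overlap, na.rm = TRUE))
      }
      if ("spatial" %in% metrics) {
        rows[[length(rows) + 1]] <- tibble(
          metric = "spatial", cond = cond,
          value = mean(cc$spatial_corr, na.rm = TRUE))
      }
    }
  }
  if ("pv_auto" %in% metrics) {
    rows[[length(rows) + 1]] <- tibble(
      metric = "pv_auto", cond = NA_real_,
      value = pv_autocorrelation_distance(ref_s, cells = act)$mean)
  }
  dplyr::bind_rows(rows)
}

#' Run a morph sequence with end-of-session learning
#'
#' Simulates the given sequence of conditions in order (recurrence on),
#' updating the recurrent weights after each session by a convex combination
#' with learning factor `l_rate`. Every step uses a fresh trajectory.
#'
#' @param network An `hm_network` covering all conditions in `sequence`.
#' @param memory The starting `hm_memory` (not modified in place).
#' @param sequence Ordered condition vector, e.g. `c(1:7, 1)`.
#' @param l_rate Learning factor in `[0, 1]`.
#' @param slot_base Seed-slot offset.
#' @param k_range Candidate cluster counts for the temporary matrices.
#' @return A list: `sessions` (in sequence order, named by condition),
#'   `memory` (final), `sequence`.
#' @export
run_sequence <- function(network, memory, sequence, l_rate,
                         slot_base = SLOT_SEQ, k_range = NULL) {
  sessions <- vector("list", length(sequence))
  for (i in seq_along(sequence)) {
    s <- simulate_ca3_session(network, sequence[i], slot_base + i,
                              memory = memory)
    sessions[[i]] <- s
    memory <- update_memory(memory, s, l_rate, k_range = k_range)
  }
  names(sessions) <- as.character(sequence)
  list(sessions = sessions, memory = memory, sequence = sequence)
}

#' Hysteresis protocol: forward then reverse morphing with learning
#'
#' Runs 1 -> 7 then 7 -> 1 with end-of-session weight updates and compares
#' the rate maps of forward and reverse visits to the same condition.
#'
#' @param config An [morph_config()]; `l_rate > 0` for hysteresis to appear.
#' @param l_rate Learning factor (defaults to the config's).
#' @param network,k_range As in [run_morphing()].
#' @return A list of class `hm_hysteresis`: `forward`, `reverse` (session
#'   lists by condition), `comparison` (tibble with per-condition mean
#'   absolute rate difference and PV correlation between visits), `memory`.
#' @export
run_hysteresis <- function(config, l_rate = NULL, network = NULL,
                           k_range = NULL) {
  l_rate <- l_rate %||% config$l_rate
  if (is.null(network)) network <- build_network(config, conditions = 1:7)
  tr <- train_memory(network, k_range = k_range)
  fwd <- run_sequence(network, tr$memory, 1:7, l_rate,
                      slot_base = SLOT_SEQ, k_range = k_range)
  rev <- run_sequence(network, fwd$memory, 7:1, l_rate,
                      slot_base = SLOT_SEQ + 10L, k_range = k_range)
  comparison <- purrr::map_dfr(1:7, function(cond) {
    a <- fwd$sessions[[as.character(cond)]]
    b <- rev$sessions[[as.character(cond)]]
    act <- active_cells(a, b)
    ra <- session_mean_rates(a)[act]
    rb <- session_mean_rates(b)[act]
    tibble(condition = cond,
           mean_abs_rate_diff = mean(abs(ra - rb)),
           pv = pv_correlation(a, b, cells = act)$mean)
  })
  structure(list(forward = fwd$sessions, reverse = rev$sessions,
                 comparison = comparison, memory = rev$memory,
                 l_rate = l_rate),
            class = "hm_hysteresis")
}

#' PV correlation of repeated visits as a function of the learning rate
#'
#' For each learning rate, runs the sequence 1-2-3-4-5-6-7-1 with
#' end-of-session updates and computes the PV correlation between the two
#' visits to condition 1 (six intermediate sessions apart) and between the
#' first two sessions (conditions 1 and 2, no intermediate session). With
#' little learning the repeated visit correlates better than the smallest
#' morph; with strong learning the intermediate sessions corrupt the stored
#' pattern and the order reverses. [crossing_l_rate()] interpolates the
#' learning rate at which the two curves meet.
#'
#' @param config An [morph_config()].
#' @param l_rates Learning-rate grid (log-spaced).
#' @param network,k_range As in [run_morphing()].
#' @param memory Optional pre-built starting `hm_memory` (skips the training
#'   sessions).
#' @return A tibble of class `hm_learning_curve` with columns `l_rate`,
#'   `pv_11p`, `pv_12`.
#' @export
learning_rate_curve <- function(config,
                                l_rates = c(0.003, 0.01, 0.03, 0.1, 0.3),
                                network = NULL, k_range = NULL,
                                memory = NULL) {
  if (is.null(network)) network <- build_network(config, conditions = 1:7)
  tr <- if (is.null(memory)) train_memory(network, k_range = k_range) else {
    list(memory = memory)
  }
  seqn <- c(1:7, 1L)
  rows <- purrr::map_dfr(l_rates, function(lr) {
    run <- run_sequence(network, tr$memory, seqn, lr, k_range = k_range)
    s1 <- run$sessions[[1]]; s2 <- run$sessions[[2]]
    s1p <- run$sessions[[length(seqn)]]
    tibble(
      l_rate = lr,
      pv_11p = pv_correlation(s1, s1p, cells = active_cells(s1, s1p))$mean,
      pv_12 = pv_correlation(s1, s2, cells = active_cells(s1, s2))$mean
    )
  })
  class(rows) <- c("hm_learning_curve", class(rows))
  rows
}

#' Learning rate at which the repeated-visit and smallest-morph PV curves
#' cross
#'
#' @param curve Output of [learning_rate_curve()].
#' @return The crossing learning rate (log-linear interpolation of
#'   `pv_11p - pv_12` across its first sign change), or NA if the curves do
#'   not cross on the grid.
#' @export
crossing_l_rate <- function(curve) {
  f <- curve$pv_11p - curve$pv_12
  lx <- log10(curve$l_rate)
  s <- which(f[-length(f)] * f[-1] <= 0 & is.finite(f[-length(f)]) &
               is.finite(f[-1]))
  if (!length(s)) return(NA_real_)
  i <- s[1]
  if (f[i] == f[i + 1]) return(10^mean(lx[i + 0:1]))
  10^(lx[i] + (0 - f[i]) / (f[i + 1] - f[i]) * (lx[i + 1] - lx[i]))
}

#' Morphing with grid-cell realignment mid-sequence
#'
#' Emulates training the two extreme shapes under different grid alignments:
#' conditions below `realign_at` use the original MEC population, conditions
#' from `realign_at` on use a realigned population (same spacings, new
#' orientations and phases). The square memory is stored under the original
#' alignment and the round memory under the realigned one, so morphing past
#' `realign_at` produces an abrupt drop in the PV correlation to the
#' reference.
#'
#' @param config An [morph_config()].
#' @param realign_at First condition simulated with realigned grids.
#' @param k_range Candidate cluster counts.
#' @return A list of class `hm_realign`: `sessions` (CA3, recurrence on,
#'   keyed by condition), `pv_curve` (tibble `cond`, `pv` vs condition 1),
#'   `realign_at`, plus both networks.
#' @export
run_realignment <- function(config, realign_at = 4, k_range = NULL) {
  if (realign_at < 2 || realign_at > 7) {
    abort("`realign_at` must lie in 2..7.",
          class = "hippomorph_validation_error")
  }
  pre_conds <- 1:(realign_at - 1)
  post_conds <- realign_at:7
  net_a <- build_network(config, conditions = pre_conds)
  mec_re <- realign_grids(net_a$mec_pop, seed = config$seeds$ec + 9L,
                          box_cm = config$box_cm)
  net_b <- build_network(config, conditions = post_conds, mec_pop = mec_re)
  s1 <- simulate_ca3_session(net_a, 1, SLOT_TRAIN_SQ)
  s7 <- simulate_ca3_session(net_b, 7, SLOT_TRAIN_RD)
  memory <- build_memory(s1, s7, k_range = k_range)
  sessions <- list()
  for (cond in 1:7) {
    net <- if (cond < realign_at) net_a else net_b
    sessions[[as.character(cond)]] <-
      simulate_ca3_session(net, cond, SLOT_MORPH + cond, memory = memory)
  }
  act <- active_cells(sessions)
  ref <- sessions[["1"]]
  pv_curve <- purrr::map_dfr(1:7, function(cond) {
    tibble(cond = cond,
           pv = pv_correlation(ref, sessions[[as.character(cond)]],
                               cells = act)$mean)
  })
  structure(list(sessions = sessions, pv_curve = pv_curve,
                 realign_at = realign_at, memory = memory,
                 network = net_a, network_realigned = net_b),
            class = "hm_realign")
}

#' Parametric search against reference metric curves
#'
#' Scores a grid of candidate values of one model parameter (`alpha`, `beta`
#' or `delta`) by equal-weight least squares between the simulated metric
#' curves and user-supplied reference curves, and returns the best fit.
#' `alpha` is scored on DG metrics (no recurrence), `beta` on CA3 without
#' recurrent collaterals, `delta` on CA3 with recurrence. Reference curves
#' are not bundled: supply digitized experimental values or self-generated
#' curves.
#'
#' @param config Base [morph_config()].
#' @param param One of `"alpha"`, `"beta"`, `"delta"`.
#' @param grid Numeric vector of candidate values (non-empty).
#' @param reference Tibble with columns `metric` ("pv", "overlap",
#'   "spatial", "pv_auto"), `cond` (comparison condition vs 1; NA for
#'   `pv_auto`) and `value`.
#' @param conditions Conditions simulated for the curves.
#' @param slot_base Seed-slot offset (use a different one when generating
#'   the reference from the model itself).
#' @param k_range Candidate cluster counts (delta search only).
#' @return A list of class `hm_search`: `table` (tibble `value`, `score`),
#'   `best` (argmin), `curves` (per grid point), `param`.
#' @export
parametric_search <- function(config, param = c("alpha", "beta", "delta"),
                              grid, reference, conditions = c(1, 2, 4, 7),
                              slot_base = SLOT_MORPH, k_range = NULL) {
  param <- match.arg(param)
  if (!length(grid)) {
    abort("Parameter grid must be non-empty.",
          class = "hippomorph_argument_error")
  }
  curves <- list()
  scores <- numeric(length(grid))
  for (g in seq_along(grid)) {
    cfg <- config
    cfg[[param]] <- grid[g]
    cur <- metric_curve_for(cfg, param, conditions, slot_base, k_range)
    curves[[g]] <- dplyr::mutate(cur, value_param = grid[g])
    joined <- dplyr::inner_join(
      reference, cur, by = c("metric", "cond"), suffix = c("_ref", "_sim"))
    scores[g] <- sum((joined$value_ref - joined$value_sim)^2)
  }
  best <- grid[which.min(scores)]
  structure(list(table = tibble(value = grid, score = scores), best = best,
                 curves = dplyr::bind_rows(curves), param = param),
            class = "hm_search")
}

# Simulate the metric curve for one parameter setting.
metric_curve_for <- function(cfg, param, conditions, slot_base, k_range) {
  conditions <- sort(unique(c(1L, as.integer(conditions))))
  if (param == "alpha") {
    plan <- tibble(condition = conditions, duration_s = cfg$session_s,
                   slot = slot_base + conditions)
    net <- build_network(cfg, conditions = conditions, dg_session_plan = plan,
                         regions = "dg")
    sessions <- list()
    for (cond in conditions) {
      sessions[[as.character(cond)]] <-
        net$dg_sessions[[sprintf("%d:%d", cond, slot_base + cond)]]
    }
    return(region_metric_curve(sessions, ref = 1))
  }
  net <- build_network(cfg, conditions = unique(c(conditions, 7L)))
  memory <- if (param == "delta") train_memory(net, k_range = k_range)$memory
  sessions <- list()
  for (cond in conditions) {
    sessions[[as.character(cond)]] <-
      simulate_ca3_session(net, cond, slot_base + cond, memory = memory)
  }
  region_metric_curve(sessions, ref = 1)
}

#' @export
print.hm_morph <- function(x, ...) {
  cat(sprintf("<hm_morph> conditions %s; CA3 on/off%s; memory: %d connected cells\n",
              paste(names(x$ca3_on), collapse = " "),
              if (length(x$dg)) " + DG" else "",
              sum(Matrix::rowSums(x$memory$w) > 0)))
  invisible(x)
}

#' @export
#' @method tidy hm_morph
tidy.hm_morph <- function(x, ref = 1, ...) morph_metrics(x, ref = ref)

#' @export
#' @method glance hm_morph
glance.hm_morph <- function(x, ...) {
  m <- morph_metrics(x)
  pv <- function(reg, rec, cond) {
    v <- m$value[m$region == reg & m$recurrence == rec &
                   m$metric == "pv" & m$cond == cond]
    if (length(v)) v else NA_real_
  }
  tibble(
    pv_gain_small = pv("ca3", TRUE, 2) - pv("ca3", FALSE, 2),
    pv_gain_large = pv("ca3", TRUE, 7) - pv("ca3", FALSE, 7),
    pv_dg_small = pv("dg", FALSE, 2),
    pv_ca3_on_small = pv("ca3", TRUE, 2),
    n_cells_memory = sum(Matrix::rowSums(x$memory$w) > 0)
  )
}

#' @export
print.hm_search <- function(x, ...) {
  cat(sprintf("<hm_search> %s grid of %d; best = %g\n", x$param,
              nrow(x$table), x$best))
  invisible(x)
}
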