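# Shared small-scale fixtures, built once per test run.

tiny_config <- function(...) {
  # reduced convergence widens the relative input spread; soften the LEC
  # clipping so small populations stay active
  morph_config(scale = 0.02, session_s = 40, lec_rectify_q = 0.05, ...)
}

small_config <- function(...) {
  morph_config(scale = 0.05, session_s = 60, lec_rectify_q = 0.05, ...)
}

.fixtures <- new.env(parent = emptyenv())

# Cached tiny network with CA3 maps for conditions 1,2,4,7 and DG sessions.
tiny_network <- function() {
  if (is.null(.fixtures$net)) {
    cfg <- tiny_config()
    .fixtures$net <- build_network(
      cfg, conditions = c(1, 2, 4, 7),
      dg_session_plan = tibble::tibble(condition = c(1, 2, 7),
                                       duration_s = 40, slot = 31:33)
    )
  }
  .fixtures$net
}

tiny_memory <- function() {
  if (is.null(.fixtures$mem)) {
    net <- tiny_network()
    s1 <- simulate_ca3_session(net, 1, 1)
    s7 <- simulate_ca3_session(net, 7, 2)
    .fixtures$mem <- build_memory(s1, s7)
  }
  .fixtures$mem
}

# A deterministic hm_trajectory visiting given bins uniformly (for analysis
# oracles): one sample per (bin, repeat).
grid_trajectory <- function(bins = 16, box = 80, reps = 4, dt = 0.0365) {
  ctr <- expand.grid(ix = seq_len(bins), iy = seq_len(bins))
  w <- box / bins
  x <- rep((ctr$ix - 0.5) * w, reps)
  y <- rep((ctr$iy - 0.5) * w, reps)
  df <- tibble::tibble(time_s = (seq_along(x) - 1) * dt, x_cm = x, y_cm = y)
  structure(df, box_cm = box, dt_s = dt, condition = 1L,
            class = c("hm_trajectory", class(tibble::tibble())))
}

# Build an hm_session directly from a counts matrix (for metric oracles).
session_from_counts <- function(counts, occupancy, box = 80, duration = NULL,
                                condition = 1, region = "ca3") {
  structure(list(
    counts = counts, occupancy = occupancy,
    duration_s = duration %||% sum(occupancy),
    condition = condition, region = region, box_cm = box,
    analysis_bins = nrow(occupancy), n_cells = nrow(counts),
    spikes = NULL, first_spike_ms = numeric(0), delays_ms = numeric(0)
  ), class = "hm_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reduced-scale morphing study shared by the acceptance tests: quarter-
# scale populations (2000 granule cells of an 20,000 pool, 500 CA3 cells),
# 600 s DG sessions, 300 s CA3 sessions, 120 s learning-protocol sessions.
acceptance_fixture <- function() {
  if (!is.null(.fixtures$acc)) return(.fixtures$acc)
  cfg <- morph_config(scale = 0.25, session_s = 120)
  t0 <- Sys.time()
  net <- build_network(
    cfg, conditions = 1:7,
    dg_session_plan = tibble::tibble(condition = c(1, 2, 7),
                                     duration_s = 600, slot = 31:33)
  )
  dg <- net$dg_sessions
  names(dg) <- sub(":.*", "", names(dg))
  dg_minutes <- as.numeric(difftime(Sys.time(), t0, units = "mins"))
  tr1 <- simulate_ca3_session(net, 1, 1, duration_s = 300)
  tr7 <- simulate_ca3_session(net, 7, 2, duration_s = 300)
  memory <- build_memory(tr1, tr7)
  ca3_on <- list(); ca3_off <- list()
  for (cond in c(1, 2, 7)) {
    key <- as.character(cond)
    ca3_off[[key]] <- simulate_ca3_session(net, cond, 10 + cond,
                                           duration_s = 300)
    ca3_on[[key]] <- simulate_ca3_session(net, cond, 10 + cond,
                                          memory = memory, duration_s = 300)
  }
  .fixtures$acc <- list(cfg = cfg, net = net, dg = dg, memory = memory,
                        train_square = tr1, ca3_on = ca3_on,
                        ca3_off = ca3_off, dg_minutes = dg_minutes)
  .fixtures$acc
}

pv_between <- function(sessions, a, b, cells) {
  pv_correlation(sessions[[as.character(a)]], sessions[[as.character(b)]],
                 cells = cells)$mean
}

mean_overlap <- function(sessions, a, b) {
  act <- active_cells(sessions[c(as.character(a), as.character(b))])
  mean(compare_cells(sessions[[as.character(a)]],
                     sessions[[as.character(b)]],
                     cells = act)$rate_overlap, na.rm = TRUE)
}
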