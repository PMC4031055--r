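#' Generate a synthetic random-foraging trajectory
#'
#' Simulates a virtual rat foraging in a square box using an
#' Ornstein-Uhlenbeck heading process with a slowly varying speed, sampled at
#' one position per gamma cycle (36.5 ms by default) so that every simulated
#' cycle is bound to exactly one position. Walls are reflective. With the
#' default speed (~20 cm/s mean) a 600 s session covers every 5x5 cm bin of the
#' 16x16 analysis grid.
#'
#' @param duration_s Session duration in seconds (must be > 0).
#' @param box_cm Side of the square box in cm (must be > 0; 80 cm default, the
#'   size implied by 16x16 bins of 5x5 cm).
#' @param speed_params List with elements `mean` (cm/s), `sd` (cm/s, SD of the
#'   stationary speed distribution), `v_max` (cm/s hard cap), `tau_speed` (s,
#'   speed relaxation time) and `turn_rate` (rad/sqrt(s), heading diffusion).
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param dt_s Position sampling step in seconds (defaults to one gamma cycle).
#' @param condition Morph condition index in 1..7 carried as metadata.
#' @return A tibble of class `hm_trajectory` with columns `time_s`, `x_cm`,
#'   `y_cm` and attributes `box_cm`, `dt_s`, `condition`.
#' @export
#' @examples
#' traj <- generate_trajectory(10, seed = 1)
#' head(traj)
generate_trajectory <- function(duration_s = 600, box_cm = 80,
                                speed_params = list(), seed = 1,
                                dt_s = 0.0365, condition = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be positive.", class = "hippomorph_argument_error")
  }
  if (!is.numeric(box_cm) || box_cm <= 0) {
    abort("`box_cm` must be positive.", class = "hippomorph_argument_error")
  }
  sp <- utils::modifyList(
    list(mean = 20, sd = 8, v_max = 60, tau_speed = 1.5, turn_rate = 1.2),
    speed_params
  )
  n <- max(2L, as.integer(ceiling(duration_s / dt_s)))
  withr_seed(seed, {
    x <- numeric(n); y <- numeric(n)
    x[1] <- runif(1, 0.1, 0.9) * box_cm
    y[1] <- runif(1, 0.1, 0.9) * box_cm
    theta <- runif(1, 0, 2 * pi)
    v <- sp$mean
    a_v <- exp(-dt_s / sp$tau_speed)
    sd_v <- sp$sd * sqrt(1 - a_v^2)
    dth <- rnorm(n) * sp$turn_rate * sqrt(dt_s)
    eps_v <- rnorm(n) * sd_v
    for (k in 2:n) {
      v <- sp$mean + a_v * (v - sp$mean) + eps_v[k]
      v <- min(max(v, 1), sp$v_max)
      theta <- theta + dth[k]
      xn <- x[k - 1] + v * dt_s * cos(theta)
      yn <- y[k - 1] + v * dt_s * sin(theta)
      # wall contact: fold the overshoot back in (reflective), then let the
      # heading slide along the wall (thigmotaxis keeps corners visited)
      if (xn < 0 || xn > box_cm) {
        xn <- if (xn < 0) -xn else 2 * box_cm - xn
        theta <- if (sin(theta) >= 0) pi / 2 else -pi / 2
      }
      if (yn < 0 || yn > box_cm) {
        yn <- if (yn < 0) -yn else 2 * box_cm - yn
        theta <- if (cos(theta) >= 0) 0 else pi
      }
      x[k] <- min(max(xn, 0), box_cm)
      y[k] <- min(max(yn, 0), box_cm)
    }
    new_trajectory(
      tibble(time_s = (seq_len(n) - 1) * dt_s, x_cm = x, y_cm = y),
      box_cm = box_cm, dt_s = dt_s, condition = condition
    )
  })
}

new_trajectory <- function(df, box_cm, dt_s, condition = 1L) {
  structure(df, box_cm = box_cm, dt_s = dt_s, condition = as.integer(condition),
            class = c("hm_trajectory", class(tibble())))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Read a trajectory from a plain-text position table
#'
#' Expects comma-separated columns `time_s,x_cm,y_cm` (header optional).
#' Positions are validated against the box bounds.
#'
#' @param path File path.
#' @param box_cm Box side in cm used for validation.
#' @param condition Morph condition index carried as metadata.
#' @return An `hm_trajectory` tibble.
#' @export
load_trajectory <- function(path, box_cm = 80, condition = 1L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  start <- if (length(lines) && grepl("[A-Za-z]", lines[[1]])) 2L else 1L
  if (length(lines) < start) {
    abort("Trajectory file contains no data rows.",
          class = "hippomorph_parse_error")
  }
  rows <- lapply(seq.int(start, length(lines)), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(lines[[i]], ",")[[1]]))
    if (length(f) < 3 || anyNA(f[1:3])) {
      abort(sprintf("Malformed trajectory row at line %d: '%s'", i, lines[[i]]),
            class = "hippomorph_parse_error")
    }
    f[1:3]
  })
  m <- do.call(rbind, rows)
  df <- tibble(time_s = m[, 1], x_cm = m[, 2], y_cm = m[, 3])
  bad <- which(df$x_cm < 0 | df$x_cm > box_cm | df$y_cm < 0 | df$y_cm > box_cm)
  if (length(bad)) {
    abort(sprintf("Position outside the %g cm box at data row %d.",
                  box_cm, bad[[1]]),
          class = "hippomorph_validation_error")
  }
  dt <- if (nrow(df) > 1) stats::median(diff(df$time_s)) else 0.0365
  new_trajectory(df, box_cm = box_cm, dt_s = dt, condition = condition)
}

#' Write a trajectory as a plain-text position table
#'
#' @param trajectory An `hm_trajectory` (or any tibble with `time_s`, `x_cm`,
#'   `y_cm`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(as_tibble(trajectory)[c("time_s", "x_cm", "y_cm")], path)
  invisible(path)
}

#' Occupancy map of a trajectory
#'
#' Time spent in each spatial bin; each position sample contributes one
#' sampling step of occupancy, so the total equals the session duration.
#'
#' @param trajectory An `hm_trajectory`.
#' @param bins Number of bins per side (16 for the 5x5 cm analysis grid).
#' @return A `bins` x `bins` matrix of seconds (rows: x bins, cols: y bins).
#' @export
occupancy_map <- function(trajectory, bins = 16) {
  box <- attr(trajectory, "box_cm")
  dt <- attr(trajectory, "dt_s")
  idx <- position_bins(trajectory$x_cm, trajectory$y_cm, box, bins)
  occ <- tabulate(idx, nbins = bins * bins) * dt
  matrix(occ, nrow = bins, ncol = bins)
}

# Linear bin index (column-major over x fast) for positions in [0, box].
position_bins <- function(x, y, box, bins) {
  ix <- pmin(pmax(floor(x / box * bins), 0), bins - 1)
  iy <- pmin(pmax(floor(y / box * bins), 0), bins - 1)
  as.integer(ix + bins * iy + 1)
}

# Centers (cm) of the linear bin indices 1..bins^2.
bin_centers <- function(box, bins) {
  w <- box / bins
  ix <- (seq_len(bins * bins) - 1) %% bins
  iy <- (seq_len(bins * bins) - 1) %/% bins
  cbind(x = (ix + 0.5) * w, y = (iy + 0.5) * w)
}

#' @export
print.hm_trajectory <- function(x, ...) {
  cat(sprintf("<hm_trajectory> %d samples, %.1f s, box %g cm, condition %d\n",
              nrow(x), nrow(x) * attr(x, "dt_s"), attr(x, "box_cm"),
              attr(x, "condition")))
  NextMethod()
}
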