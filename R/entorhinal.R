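#' Create a medial entorhinal (grid cell) population
#'
#' Grid-cell tuning follows the standard three-cosine interference model: the
#' rate is the rectified-scaled sum of three plane-wave cosines whose wave
#' vectors are 60 degrees apart, producing a triangular lattice. Spacings are
#' drawn uniformly from `spacing_range`, orientations uniformly over one
#' lattice sector, and phase offsets uniformly over the box. Grid cells are
#' insensitive to morphing.
#'
#' @param n Number of cells.
#' @param box_cm Box side (cm).
#' @param spacing_range Range of grid spacings (cm).
#' @param peak_rate Rate at a lattice vertex (Hz).
#' @param sharpness Tuning exponent applied to the normalized cosine sum
#'   (>= 1). 1 gives the plain three-cosine interference pattern, whose
#'   troughs stay at a third of the peak; larger values sharpen the vertices
#'   toward the compact, near-zero-background fields of recorded grid cells
#'   (the knob used to tailor the maps' spatial information).
#' @param seed Integer seed.
#' @return A tibble with columns `cell`, `spacing_cm`, `orientation`,
#'   `phase_x`, `phase_y`, `peak_rate`, `sharpness`.
#' @export
make_mec_population <- function(n, box_cm = 80, spacing_range = c(30, 70),
                                peak_rate = 20, sharpness = 1, seed = 1) {
  withr_seed(seed, tibble(
    cell = seq_len(n),
    spacing_cm = runif(n, spacing_range[1], spacing_range[2]),
    orientation = runif(n, 0, pi / 3),
    phase_x = runif(n, 0, box_cm),
    phase_y = runif(n, 0, box_cm),
    peak_rate = peak_rate,
    sharpness = sharpness
  ))
}

#' Grid-cell firing rate at given positions
#'
#' Evaluates the three-cosine grid model for a single cell. The rate peaks at
#' `peak_rate` on the lattice vertices (e.g. at the phase offset) and is
#' periodic under translation by any lattice basis vector.
#'
#' @param params A one-row data frame as returned by [make_mec_population()]
#'   (or a list with the same fields).
#' @param x,y Position coordinates in cm (vectorized).
#' @return Firing rates in Hz (nonnegative).
#' @export
#' @examples
#' pop <- make_mec_population(1, seed = 2)
#' grid_rate(pop[1, ], pop$phase_x, pop$phase_y)  # peak_rate at a vertex
grid_rate <- function(params, x, y) {
  th <- params$orientation[[1]] + c(0, pi / 3, 2 * pi / 3)
  kmag <- 4 * pi / (sqrt(3) * params$spacing_cm[[1]])
  dx <- x - params$phase_x[[1]]
  dy <- y - params$phase_y[[1]]
  g <- 0
  for (a in th) g <- g + cos(kmag * (cos(a) * dx + sin(a) * dy))
  s <- if (is.null(params$sharpness)) 1 else params$sharpness[[1]]
  params$peak_rate[[1]] * ((g + 1.5) / 4.5)^s
}

#' Rate maps of a grid-cell population on the 1 cm grid
#'
#' @param pop Population tibble from [make_mec_population()].
#' @param box_cm Box side (cm).
#' @param res_cm Bin side (cm); 1 cm gives the 80x80 input-map grid.
#' @return A `nrow(pop)` x `n_bins^2` matrix of rates (Hz), columns indexed by
#'   the linear bin index of [position_bins()].
#' @export
mec_rate_maps <- function(pop, box_cm = 80, res_cm = 1) {
  bins <- as.integer(round(box_cm / res_cm))
  ctr <- bin_centers(box_cm, bins)
  n <- nrow(pop)
  out <- matrix(0, n, bins * bins)
  th0 <- c(0, pi / 3, 2 * pi / 3)
  kmag <- 4 * pi / (sqrt(3) * pop$spacing_cm)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 1000))
  for (cc in chunks) {
    acc <- matrix(0, length(cc), bins * bins)
    for (a in th0) {
      # wave vector of each cell for this lattice direction
      ang <- pop$orientation[cc] + a
      kx <- kmag[cc] * cos(ang)
      ky <- kmag[cc] * sin(ang)
      phase <- kx * pop$phase_x[cc] + ky * pop$phase_y[cc]
      acc <- acc + cos(outer(kx, ctr[, "x"]) + outer(ky, ctr[, "y"]) - phase)
    }
    s <- if (is.null(pop$sharpness)) rep(1, length(cc)) else pop$sharpness[cc]
    out[cc, ] <- ((acc + 1.5) / 4.5)^s * pop$peak_rate[cc]
  }
  out
}

#' Realign a grid-cell population
#'
#' Draws a fresh orientation and phase offset for every cell while keeping each
#' cell's spatial frequency (grid spacing) unchanged, emulating the grid
#' realignment that accompanies global remapping.
#'
#' @param pop Population tibble from [make_mec_population()].
#' @param seed Integer seed.
#' @param box_cm Box side (cm) for phase draws.
#' @return The realigned population tibble.
#' @export
realign_grids <- function(pop, seed = 1, box_cm = 80) {
  n <- nrow(pop)
  withr_seed(seed, {
    pop$orientation <- runif(n, 0, pi / 3)
    pop$phase_x <- runif(n, 0, box_cm)
    pop$phase_y <- runif(n, 0, box_cm)
    pop
  })
}

#' Create a lateral entorhinal (morph-sensitive) population
#'
#' Each LEC cell carries two independent smooth nonnegative rate maps (one for
#' the square family, one for the round family) and a private morph transition
#' degree `c_star` drawn uniformly on (1, 7). At morph condition `c` the cell
#' expresses map A if `c < c_star` and map B otherwise, i.e. a sharp per-cell
#' switch; because thresholds are uniform across the population, the summed
#' population input changes smoothly along the morph axis. Maps are built from
#' coarse spatial white noise, bilinearly upsampled to the 1 cm grid, shifted
#' to a zero minimum and peak-normalized, yielding broad, weakly tuned,
#' low-spatial-information blobs (the flat tuning keeps the summed population
#' drive tightly bunched under the local maximum, which is what lets the
#' competitive gamma cycle produce graded rates).
#'
#' @param n Number of cells.
#' @param box_cm Box side (cm).
#' @param res_cm Input-map bin side (cm).
#' @param coarse_k Number of coarse noise nodes per side; the spatial scale of
#'   the blobs is about `box_cm / (coarse_k - 1)`.
#' @param rectify_q Quantile at which maps are clipped to zero before
#'   normalization (0 = shift to the minimum only; larger values silence the
#'   cell over that fraction of the box and sharpen its tuning). The default
#'   0.05 keeps the summed population drive flat enough that the whole box
#'   stays above the first-spike horizon, which coherent place fields and
#'   the gamma rhythm require; larger values trade field quality for
#'   stronger morph sensitivity and sparser activity.
#' @param seed Integer seed.
#' @return A list of class `lec_population` with fields `map_a`, `map_b`
#'   (`n` x `n_bins^2` matrices, peak-normalized to 1), `c_star`, `box_cm`,
#'   `res_cm`.
#' @export
make_lec_population <- function(n, box_cm = 80, res_cm = 1, coarse_k = 6,
                                rectify_q = 0.05, seed = 1) {
  bins <- as.integer(round(box_cm / res_cm))
  up <- bilinear_upsampler(coarse_k, box_cm, bins)
  withr_seed(seed, {
    mk <- function() {
      z <- matrix(rnorm(n * coarse_k^2), n, coarse_k^2) %*% up
      thr <- if (rectify_q <= 0) {
        apply(z, 1, min)
      } else {
        apply(z, 1, quantile, rectify_q)
      }
      z <- pmax(sweep(z, 1, thr), 0)
      mx <- row_maxima(z)
      mx[mx == 0] <- 1
      z / mx
    }
    structure(list(map_a = mk(), map_b = mk(),
                   c_star = runif(n, 1, 7),
                   box_cm = box_cm, res_cm = res_cm),
              class = "lec_population")
  })
}

# Sparse (k^2 x bins^2) bilinear interpolation operator from a k x k node grid
# spanning [0, box] to the centers of a bins x bins grid.
bilinear_upsampler <- function(k, box, bins) {
  ctr <- bin_centers(box, bins)
  step <- box / (k - 1)
  gx <- ctr[, "x"] / step
  gy <- ctr[, "y"] / step
  ix <- pmin(floor(gx), k - 2); fx <- gx - ix
  iy <- pmin(floor(gy), k - 2); fy <- gy - iy
  node <- function(dx, dy) (ix + dx) + k * (iy + dy) + 1
  wts <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  nodes <- cbind(node(0, 0), node(1, 0), node(0, 1), node(1, 1))
  np <- nrow(ctr)
  as.matrix(Matrix::sparseMatrix(
    i = as.vector(nodes), j = rep(seq_len(np), 4), x = as.vector(wts),
    dims = c(k * k, np)
  ))
}

row_maxima <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}

#' LEC firing rate at a position and morph condition
#'
#' @param pop An `lec_population`.
#' @param x,y Position (cm, scalars).
#' @param c Morph condition in `[1, 7]`.
#' @param cells Cell indices to evaluate (default all).
#' @return Rates (dimensionless map units, peak 1) for the selected cells.
#' @export
lec_rate <- function(pop, x, y, c, cells = NULL) {
  if (!is.numeric(c) || length(c) != 1 || c < 1 || c > 7) {
    abort("Morph condition `c` must lie in [1, 7].",
          class = "hippomorph_argument_error")
  }
  bins <- as.integer(round(pop$box_cm / pop$res_cm))
  b <- position_bins(x, y, pop$box_cm, bins)
  if (is.null(cells)) cells <- seq_len(nrow(pop$map_a))
  use_a <- c < pop$c_star[cells]
  ifelse(use_a, pop$map_a[cells, b], pop$map_b[cells, b])
}

#' LEC population rate maps at a morph condition
#'
#' @inheritParams lec_rate
#' @return An `n` x `n_bins^2` matrix: row i is map A where `c < c_star[i]`,
#'   map B otherwise.
#' @export
lec_rate_maps <- function(pop, c) {
  if (c < 1 || c > 7) {
    abort("Morph condition `c` must lie in [1, 7].",
          class = "hippomorph_argument_error")
  }
  out <- pop$map_a
  sw <- which(pop$c_star <= c)
  if (length(sw)) out[sw, ] <- pop$map_b[sw, ]
  out
}

#' Draw feedforward synaptic weights from the synapse-size distribution
#'
#' Synaptic strengths follow a right-skewed lognormal, matching the measured
#' distribution of spine/synapse sizes; the absolute scale is immaterial
#' because feedforward input is normalized by the population mean maximum.
#'
#' @param n_synapses Number of weights to draw (> 0).
#' @param seed Integer seed.
#' @param meanlog,sdlog Lognormal parameters.
#' @return Positive numeric vector of length `n_synapses`.
#' @export
sample_feedforward_weights <- function(n_synapses, seed = 1, meanlog = -0.5,
                                       sdlog = 0.78) {
  if (!is.numeric(n_synapses) || n_synapses <= 0) {
    abort("`n_synapses` must be positive.", class = "hippomorph_argument_error")
  }
  withr_seed(seed, rlnorm(n_synapses, meanlog, sdlog))
}

# Deterministic per-cell RNG seed below 2^31.
cell_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

#' Build feedforward synapse matrices for a target population
#'
#' Assigns each target cell its fixed random presynaptic MEC and LEC partners
#' with lognormal synaptic weights. For DG, only the cells whose mean synaptic
#' weight falls in the top `top_fraction` of a conceptual pool of
#' `n_cells / top_fraction` granule cells are instantiated (the expected-low
#' -activity convention: weaker cells never win the gamma competition).
#'
#' @param n_cells Number of simulated target cells.
#' @param n_mec,n_lec Sizes of the MEC and LEC populations.
#' @param conv_mec,conv_lec Synapses per target cell from each stream
#'   (1200/1500 for DG targets, 1400/1500 for CA3 targets).
#' @param seed Integer seed.
#' @param top_fraction If non-NULL (e.g. 0.1 for DG), simulate the top
#'   weight-percentile cells of a pool of `n_cells / top_fraction`.
#' @param meanlog,sdlog Lognormal weight parameters.
#' @return A list of class `ff_weights`: sparse matrices `w_mec`
#'   (`n_cells` x `n_mec`) and `w_lec`, `pool_ids` (indices of the simulated
#'   cells within the conceptual pool), `pool_size`.
#' @export
build_feedforward_weights <- function(n_cells, n_mec, n_lec, conv_mec,
                                      conv_lec, seed = 1, top_fraction = NULL,
                                      meanlog = -0.5, sdlog = 0.78) {
  stopifnot(conv_mec <= n_mec, conv_lec <= n_lec, n_cells >= 1)
  nsyn <- conv_mec + conv_lec
  if (is.null(top_fraction)) {
    pool_size <- n_cells
    keep <- seq_len(n_cells)
    mean_ratio <- 1
  } else {
    pool_size <- as.integer(round(n_cells / top_fraction))
    means <- numeric(pool_size)
    for (i in seq_len(pool_size)) {
      set.seed(cell_seed(seed, i))
      means[i] <- mean(rlnorm(nsyn, meanlog, sdlog))
    }
    keep <- order(means, decreasing = TRUE)[seq_len(n_cells)]
    keep <- sort(keep)
    # input normalization is defined over the whole population; the selected
    # top decile has higher mean weights, so normalization constants computed
    # from the simulated cells must be scaled by this ratio
    mean_ratio <- mean(means) / mean(means[keep])
  }
  wm <- matrix(0, length(keep), conv_mec)
  jm <- matrix(0L, length(keep), conv_mec)
  wl <- matrix(0, length(keep), conv_lec)
  jl <- matrix(0L, length(keep), conv_lec)
  for (k in seq_along(keep)) {
    set.seed(cell_seed(seed, keep[k]))
    w <- rlnorm(nsyn, meanlog, sdlog)
    wm[k, ] <- w[seq_len(conv_mec)]
    wl[k, ] <- w[conv_mec + seq_len(conv_lec)]
    jm[k, ] <- sample.int(n_mec, conv_mec)
    jl[k, ] <- sample.int(n_lec, conv_lec)
  }
  n <- length(keep)
  w_mec <- Matrix::sparseMatrix(i = rep(seq_len(n), conv_mec),
                                j = as.vector(jm), x = as.vector(wm),
                                dims = c(n, n_mec))
  rm(jm, wm)
  w_lec <- Matrix::sparseMatrix(i = rep(seq_len(n), conv_lec),
                                j = as.vector(jl), x = as.vector(wl),
                                dims = c(n, n_lec))
  rm(jl, wl)
  structure(list(
    w_mec = w_mec, w_lec = w_lec,
    pool_ids = keep, pool_size = pool_size, mean_ratio = mean_ratio
  ), class = "ff_weights")
}

# Raw (unnormalized) MEC input term: weights %*% maps.
mec_raw_term <- function(weights, mec_maps) {
  as.matrix(weights$w_mec %*% mec_maps)
}

# Raw LEC input term at `condition`; if `prev` (list(raw, condition)) is given
# with prev$condition <= condition, only the newly switched cells are applied.
lec_raw_term <- function(weights, lec_pop, condition, prev = NULL) {
  if (is.null(prev)) {
    raw <- as.matrix(weights$w_lec %*% lec_pop$map_a)
    sw <- which(lec_pop$c_star <= condition)
  } else {
    stopifnot(prev$condition <= condition)
    raw <- prev$raw
    sw <- which(lec_pop$c_star <= condition & lec_pop$c_star > prev$condition)
  }
  if (length(sw)) {
    raw <- raw + as.matrix(weights$w_lec[, sw, drop = FALSE] %*%
                             (lec_pop$map_b[sw, , drop = FALSE] -
                                lec_pop$map_a[sw, , drop = FALSE]))
  }
  list(raw = raw, condition = condition)
}

#' Normalized entorhinal drive for a target population
#'
#' Computes the two feedforward input terms and their normalization constants:
#' each term (summed weighted presynaptic rates) is divided by the population
#' mean of its per-cell maximum over all positions, so that after
#' normalization the mean over cells of the per-cell spatial maximum is 1.
#' Constants are computed in the square (condition 1) environment.
#'
#' @param weights An `ff_weights` object.
#' @param mec_maps Matrix from [mec_rate_maps()].
#' @param lec_pop An `lec_population`.
#' @return A list of class `ec_terms` with `mec_term` (normalized matrix),
#'   `z_mec`, `z_lec`, and references to `weights` and `lec_pop`.
#' @export
compute_ec_terms <- function(weights, mec_maps, lec_pop) {
  mr <- weights$mean_ratio %||% 1
  raw_m <- mec_raw_term(weights, mec_maps)
  z_mec <- max(mean(row_maxima(raw_m)) * mr, 1e-12)
  l1 <- lec_raw_term(weights, lec_pop, 1)
  z_lec <- max(mean(row_maxima(l1$raw)) * mr, 1e-12)
  structure(list(mec_term = raw_m / z_mec, z_mec = z_mec, z_lec = z_lec,
                 weights = weights, lec_pop = lec_pop,
                 lec_base = l1$raw),
            class = "ec_terms")
}

#' Entorhinal input map at a morph condition
#'
#' The per-cell, per-position entorhinal drive
#' `alpha * MEC_term + (1 - alpha) * LEC_term`, each term normalized by its
#' population mean-maximum. With `alpha = 1` the drive is independent of the
#' morph condition.
#'
#' @param terms An `ec_terms` object from [compute_ec_terms()].
#' @param condition Morph condition in `[1, 7]`.
#' @param alpha MEC/LEC mixing factor in `[0, 1]`.
#' @return A cells x positions matrix of normalized drive (dimensionless;
#'   multiply by `g_ff` for nA).
#' @export
ec_input_map <- function(terms, condition, alpha) {
  if (alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].", class = "hippomorph_argument_error")
  }
  lec <- lec_raw_term(terms$weights, terms$lec_pop, condition,
                      prev = list(raw = terms$lec_base, condition = 1))
  alpha * terms$mec_term + (1 - alpha) * (lec$raw / terms$z_lec)
}

#' Entorhinal input current for single cells at a position
#'
#' Evaluates the normalized, alpha-mixed entorhinal drive for selected cells
#' at one position and converts it to a current with the feedforward gain.
#'
#' @param terms An `ec_terms` object (carries the normalization constants; an
#'   error is raised if they are absent).
#' @param cells Cell indices.
#' @param x,y Position (cm).
#' @param condition Morph condition in `[1, 7]`.
#' @param alpha Mixing factor in `[0, 1]`.
#' @param g_ff Feedforward gain (nA); the default converts drive to nA.
#' @return Currents in nA (nonnegative).
#' @export
ec_input_current <- function(terms, cells, x, y, condition, alpha,
                             g_ff = neuron_params()$g_ff) {
  if (!inherits(terms, "ec_terms") || is.null(terms$z_mec) ||
      is.null(terms$z_lec)) {
    abort("Normalization constants missing: build `terms` with compute_ec_terms().",
          class = "hippomorph_state_error")
  }
  if (condition < 1 || condition > 7) {
    abort("Morph condition must lie in [1, 7].",
          class = "hippomorph_argument_error")
  }
  if (alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].", class = "hippomorph_argument_error")
  }
  pop <- terms$lec_pop
  bins <- as.integer(round(pop$box_cm / pop$res_cm))
  b <- position_bins(x, y, pop$box_cm, bins)
  lec_maps <- lec_rate_maps(pop, condition)
  lec_raw <- as.numeric(terms$weights$w_lec[cells, , drop = FALSE] %*%
                          lec_maps[, b])
  g_ff * (alpha * terms$mec_term[cells, b] +
            (1 - alpha) * lec_raw / terms$z_lec)
}
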