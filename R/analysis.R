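# Remapping analysis battery: occupancy-normalized rate maps with Gaussian
# smoothing, place-field detection, population-vector correlation and
# autocorrelation, rate overlap and spatial correlation. Conventions follow
# the experimental morphing literature: 16x16 analysis bins, 5 cm smoothing
# kernel, cells active above 0.1 Hz, PV inclusion above 1 Hz peak.

# Gaussian kernel weights between all bin pairs of a square grid.
smoothing_kernel <- function(box, bins, h) {
  ctr <- bin_centers(box, bins)
  d2 <- outer(ctr[, "x"], ctr[, "x"], "-")^2 +
    outer(ctr[, "y"], ctr[, "y"], "-")^2
  exp(-d2 / (2 * h^2))
}

# Smooth rows of a cells x bins^2 rate matrix; sources and targets are the
# visited bins only. Returns a cells x n_visited matrix.
smooth_rate_matrix <- function(rates, visited, box, bins, h) {
  if (h <= 1e-9) return(rates[, visited, drop = FALSE])
  g <- smoothing_kernel(box, bins, h)
  gv <- g[visited, visited, drop = FALSE]
  denom <- colSums(gv)
  sweep(rates[, visited, drop = FALSE] %*% gv, 2, denom, "/")
}

#' Occupancy-normalized, Gaussian-smoothed rate map of one cell
#'
#' Divides the spike count in each spatial bin by the occupancy time of that
#' bin, then smooths with a Gaussian kernel of `h` cm SD, averaging only over
#' visited bins. Unvisited bins are flagged invalid (NA in the smoothed map)
#' and must be excluded from correlations, not zero-filled.
#'
#' @param spikes A tibble with `x_cm`, `y_cm` columns (e.g. one cell's rows of
#'   a session spike table), or `NULL` for a silent cell.
#' @param trajectory The session's `hm_trajectory`.
#' @param bins Analysis grid side (16).
#' @param h Smoothing kernel SD in cm (5).
#' @return A list of class `hm_rate_map`: `rate` (smoothed bins x bins matrix,
#'   Hz, NA where unvisited), `raw`, `occupancy`, `box_cm`, `bins`, `h`.
#' @export
compute_rate_map <- function(spikes, trajectory, bins = 16, h = 5) {
  box <- attr(trajectory, "box_cm")
  occ <- occupancy_map(trajectory, bins)
  cnt <- numeric(bins * bins)
  if (!is.null(spikes) && nrow(spikes)) {
    b <- position_bins(spikes$x_cm, spikes$y_cm, box, bins)
    cnt <- tabulate(b, nbins = bins * bins)
  }
  rate_map_from_counts(cnt, occ, box, bins, h)
}

rate_map_from_counts <- function(counts, occupancy, box, bins, h) {
  occ_v <- as.vector(occupancy)
  visited <- occ_v > 0
  raw <- numeric(length(occ_v))
  raw[visited] <- counts[visited] / occ_v[visited]
  sm <- raw
  sm[visited] <- smooth_rate_matrix(matrix(raw, 1), visited, box, bins, h)
  sm[!visited] <- NA_real_
  structure(list(
    rate = matrix(sm, bins, bins), raw = matrix(raw, bins, bins),
    occupancy = occupancy, box_cm = box, bins = bins, h = h
  ), class = "hm_rate_map")
}

#' Smoothed rate maps for every cell of a session
#'
#' @param session An `hm_session`.
#' @param h Smoothing kernel SD (cm).
#' @return A cells x bins^2 matrix of smoothed rates over visited bins (NA at
#'   unvisited bins), with attributes `visited`, `occupancy`, `box_cm`,
#'   `bins`.
#' @export
session_rate_maps <- function(session, h = 5) {
  occ_v <- as.vector(session$occupancy)
  visited <- occ_v > 0
  bins <- session$analysis_bins
  raw <- matrix(0, session$n_cells, bins * bins)
  raw[, visited] <- sweep(session$counts[, visited, drop = FALSE], 2,
                          occ_v[visited], "/")
  out <- matrix(NA_real_, session$n_cells, bins * bins)
  out[, visited] <- smooth_rate_matrix(raw, visited, session$box_cm, bins, h)
  structure(out, visited = visited, occupancy = session$occupancy,
            box_cm = session$box_cm, bins = bins)
}

#' Extract one cell's rate map object from a session
#'
#' @param session An `hm_session`.
#' @param cell Cell index.
#' @param h Smoothing kernel SD (cm).
#' @return An `hm_rate_map`.
#' @export
cell_rate_map <- function(session, cell, h = 5) {
  bins <- session$analysis_bins
  rate_map_from_counts(session$counts[cell, ], session$occupancy,
                       session$box_cm, bins, h)
}

#' Detect place fields in a rate map
#'
#' A place field is a connected set of bins (4-connectivity by default) all
#' above 20% of the field peak, containing more than `min_bins` and fewer
#' than `max_bins` bins, with a peak rate of at least `peak_min` Hz. Fields
#' are extracted greedily from the highest remaining peak; bins of rejected
#' blobs are also removed so each bin belongs to at most one candidate.
#'
#' @param map An `hm_rate_map` or a bins x bins matrix (NA = unvisited).
#' @param peak_min Minimum peak rate (Hz).
#' @param min_bins,max_bins Exclusive size bounds (standard rule: 8 < n < 128).
#' @param frac Member bins must exceed `frac` of the field peak.
#' @param connectivity 4 or 8.
#' @return A tibble with one row per field: `field`, `peak_rate`, `size`,
#'   `peak_x`, `peak_y` (bin indices), `bins` (list-column of linear indices).
#' @export
detect_place_fields <- function(map, peak_min = 2, min_bins = 8,
                                max_bins = 128, frac = 0.2,
                                connectivity = 4) {
  m <- if (inherits(map, "hm_rate_map")) map$rate else map
  bins <- nrow(m)
  work <- m
  work[is.na(work)] <- 0
  out <- list()
  repeat {
    pk <- which.max(work)
    if (!length(pk) || work[pk] < peak_min) break
    peak <- work[pk]
    member <- flood_fill(work > frac * peak, pk, bins, connectivity)
    n <- length(member)
    if (n > min_bins && n < max_bins) {
      out[[length(out) + 1]] <- tibble(
        peak_rate = peak, size = n,
        peak_x = (pk - 1) %% bins + 1, peak_y = (pk - 1) %/% bins + 1,
        bins = list(member)
      )
    }
    work[member] <- 0
  }
  res <- if (length(out)) dplyr::bind_rows(out) else {
    tibble(peak_rate = numeric(0), size = integer(0), peak_x = integer(0),
           peak_y = integer(0), bins = list())
  }
  dplyr::mutate(res, field = dplyr::row_number(), .before = 1)
}

# Connected component of TRUE cells containing `start` (linear index).
flood_fill <- function(mask, start, bins, connectivity = 4) {
  if (!mask[start]) return(start)
  seen <- logical(length(mask))
  stack <- start
  seen[start] <- TRUE
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand.grid(dx = -1:1, dy = -1:1) |>
      apply(1, identity, simplify = FALSE) |>
      Filter(f = function(o) any(o != 0))
  }
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    cx <- (cur - 1) %% bins + 1
    cy <- (cur - 1) %/% bins + 1
    for (o in offs) {
      nx <- cx + o[1]; ny <- cy + o[2]
      if (nx >= 1 && nx <= bins && ny >= 1 && ny <= bins) {
        ni <- (ny - 1) * bins + nx
        if (mask[ni] && !seen[ni]) {
          seen[ni] <- TRUE
          stack <- c(stack, ni)
        }
      }
    }
  }
  which(seen)
}

#' Place fields for every cell of a session
#'
#' @param session An `hm_session`.
#' @param cells Cell indices (default: all cells with at least one spike).
#' @param h Smoothing kernel SD (cm).
#' @inheritParams detect_place_fields
#' @return A tibble of fields with a `cell` column.
#' @export
session_place_fields <- function(session, cells = NULL, h = 5, peak_min = 2,
                                 min_bins = 8, max_bins = 128) {
  maps <- session_rate_maps(session, h)
  bins <- attr(maps, "bins")
  if (is.null(cells)) cells <- which(rowSums(session$counts) > 0)
  purrr::map_dfr(cells, function(i) {
    f <- detect_place_fields(matrix(maps[i, ], bins, bins),
                             peak_min = peak_min, min_bins = min_bins,
                             max_bins = max_bins)
    if (nrow(f)) dplyr::mutate(f, cell = i, .before = 1) else f
  })
}

#' Cells active in at least one session
#'
#' A cell is active if its session-mean firing rate exceeds 0.1 Hz (strictly)
#' in at least one of the supplied sessions (the morphing steps of an
#' experiment).
#'
#' @param ... `hm_session` objects (or a single list of them).
#' @param threshold_hz Activity threshold (exclusive).
#' @return Integer vector of active cell indices.
#' @export
active_cells <- function(..., threshold_hz = 0.1) {
  sessions <- list(...)
  if (length(sessions) == 1 && !inherits(sessions[[1]], "hm_session")) {
    sessions <- sessions[[1]]
  }
  act <- lapply(sessions, function(s) session_mean_rates(s) > threshold_hz)
  which(Reduce(`|`, act))
}

# Per-bin Pearson correlation across cells of two rate matrices.
pv_core <- function(ma, mb, valid_bins, cells) {
  r <- rep(NA_real_, length(valid_bins))
  for (b in which(valid_bins)) {
    va <- ma[cells, b]; vb <- mb[cells, b]
    if (length(va) >= 2 && sd(va) > 0 && sd(vb) > 0) {
      r[b] <- cor(va, vb)
    }
  }
  r
}

#' Population-vector correlation between two sessions
#'
#' For every spatial bin visited in both sessions, the vector of all included
#' cells' smoothed rates in session A is Pearson-correlated with the matching
#' vector in session B. Included cells are those in `cells` (typically the
#' active set of the experiment) whose peak smoothed rate exceeds
#' `include_hz` in both sessions. Bins with fewer than two included cells or
#' zero variance are excluded.
#'
#' @param session_a,session_b `hm_session` objects over the same cell set and
#'   binning (trajectories may differ).
#' @param cells Candidate cell indices (default: all).
#' @param include_hz Peak-rate inclusion threshold (Hz).
#' @param h Smoothing kernel SD (cm).
#' @return A list of class `hm_pv`: `bins` (tibble with `bin`, `x`, `y`, `r`),
#'   `mean` (mean over valid bins), `n_cells` (included cells).
#' @export
pv_correlation <- function(session_a, session_b, cells = NULL,
                           include_hz = 1, h = 5) {
  if (session_a$n_cells != session_b$n_cells ||
      session_a$analysis_bins != session_b$analysis_bins) {
    abort("Sessions must share cell set and binning.",
          class = "hippomorph_validation_error")
  }
  ma <- session_rate_maps(session_a, h)
  mb <- session_rate_maps(session_b, h)
  if (is.null(cells)) cells <- seq_len(session_a$n_cells)
  pk_a <- suppressWarnings(apply(ma, 1, max, na.rm = TRUE))
  pk_b <- suppressWarnings(apply(mb, 1, max, na.rm = TRUE))
  inc <- intersect(cells, which(pk_a > include_hz & pk_b > include_hz))
  valid <- attr(ma, "visited") & attr(mb, "visited")
  r <- if (length(inc) >= 2) pv_core(ma, mb, valid, inc) else {
    rep(NA_real_, length(valid))
  }
  bins <- session_a$analysis_bins
  structure(list(
    bins = tibble(bin = seq_along(r),
                  x = (seq_along(r) - 1) %% bins + 1,
                  y = (seq_along(r) - 1) %/% bins + 1, r = r),
    mean = mean(r, na.rm = TRUE),
    n_cells = length(inc)
  ), class = "hm_pv")
}

#' @export
print.hm_pv <- function(x, ...) {
  cat(sprintf("<hm_pv> mean PV correlation %.3f over %d bins (%d cells)\n",
              x$mean, sum(!is.na(x$bins$r)), x$n_cells))
  invisible(x)
}

#' Population-vector autocorrelation at a distance
#'
#' Mean Pearson correlation between the population vectors of bin pairs
#' separated by `distance` (within half a bin), within the same session:
#' a measure of how well the population discriminates unrelated positions.
#' Each unordered bin pair contributes once.
#'
#' @param session An `hm_session`.
#' @param distance Separation in cm (50 by default).
#' @param tol Distance tolerance in cm (half a bin).
#' @param cells Candidate cells (default all); peak-rate inclusion as in
#'   [pv_correlation()], applied within this session.
#' @param include_hz Peak-rate threshold (Hz).
#' @param h Smoothing SD (cm).
#' @return A list: `mean` (NA with a message if no qualifying pairs),
#'   `n_pairs`.
#' @export
pv_autocorrelation_distance <- function(session, distance = 50, tol = 2.5,
                                        cells = NULL, include_hz = 1, h = 5) {
  ma <- session_rate_maps(session, h)
  bins <- session$analysis_bins
  if (is.null(cells)) cells <- seq_len(session$n_cells)
  pk <- suppressWarnings(apply(ma, 1, max, na.rm = TRUE))
  inc <- intersect(cells, which(pk > include_hz))
  valid <- which(attr(ma, "visited"))
  ctr <- bin_centers(session$box_cm, bins)
  dd <- as.matrix(stats::dist(ctr[valid, , drop = FALSE]))
  qual <- which(upper.tri(dd) & abs(dd - distance) <= tol, arr.ind = TRUE)
  rs <- c()
  if (length(inc) >= 2 && nrow(qual)) {
    for (k in seq_len(nrow(qual))) {
      va <- ma[inc, valid[qual[k, 1]]]
      vb <- ma[inc, valid[qual[k, 2]]]
      if (sd(va) > 0 && sd(vb) > 0) rs <- c(rs, cor(va, vb))
    }
  }
  if (!length(rs)) {
    return(list(mean = NA_real_, n_pairs = 0L))
  }
  list(mean = mean(rs), n_pairs = length(rs))
}

#' Rate overlap between two rate maps of the same cell
#'
#' The mean rate in the less active condition divided by the mean rate in the
#' more active condition (occupancy-weighted means, i.e. total spikes over
#' total time). 1 means no rate change; values near 0 mean strong rate
#' remapping. If only one map is silent the overlap is 0; if both are silent
#' the overlap is undefined (NA) and should be excluded from averages.
#'
#' @param map_a,map_b `hm_rate_map` objects of the same cell in two
#'   conditions.
#' @return A single number in `[0, 1]`, or NA if both maps are silent.
#' @export
rate_overlap <- function(map_a, map_b) {
  mean_rate <- function(m) {
    occ <- as.vector(m$occupancy)
    sum(as.vector(m$raw)[occ > 0] * occ[occ > 0]) / sum(occ)
  }
  ra <- mean_rate(map_a); rb <- mean_rate(map_b)
  if (ra == 0 && rb == 0) return(NA_real_)
  min(ra, rb) / max(ra, rb)
}

#' Spatial correlation between two rate maps
#'
#' Pearson correlation of the smoothed rate maps over bins valid in both
#' (visited in both sessions). NA (flagged) if either map is constant or
#' fewer than 3 mutually valid bins exist.
#'
#' @param map_a,map_b `hm_rate_map` objects (same binning).
#' @return Pearson r, or NA.
#' @export
spatial_correlation <- function(map_a, map_b) {
  va <- as.vector(map_a$rate); vb <- as.vector(map_b$rate)
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(va[ok]) == 0 || sd(vb[ok]) == 0) return(NA_real_)
  cor(va[ok], vb[ok])
}

#' Per-cell remapping metrics between two sessions
#'
#' Convenience wrapper computing, for each cell, the rate overlap and spatial
#' correlation between its rate maps in two sessions.
#'
#' @param session_a,session_b `hm_session` objects over the same cells.
#' @param cells Cell indices (default: cells active in either session).
#' @param h Smoothing SD (cm).
#' @return A tibble with `cell`, `rate_overlap`, `spatial_corr`, and the mean
#'   rates in the two sessions.
#' @export
compare_cells <- function(session_a, session_b, cells = NULL, h = 5) {
  if (is.null(cells)) cells <- active_cells(session_a, session_b)
  occ_a <- as.vector(session_a$occupancy); occ_b <- as.vector(session_b$occupancy)
  ma <- session_rate_maps(session_a, h); mb <- session_rate_maps(session_b, h)
  mr_a <- rowSums(session_a$counts) / session_a$duration_s
  mr_b <- rowSums(session_b$counts) / session_b$duration_s
  ok <- !is.na(ma[1, ]) & !is.na(mb[1, ])
  purrr::map_dfr(cells, function(i) {
    ov <- if (mr_a[i] == 0 && mr_b[i] == 0) NA_real_ else {
      min(mr_a[i], mr_b[i]) / max(mr_a[i], mr_b[i])
    }
    va <- ma[i, ok]; vb <- mb[i, ok]
    sc <- if (sum(ok) >= 3 && sd(va) > 0 && sd(vb) > 0) cor(va, vb) else NA_real_
    tibble(cell = i, rate_overlap = ov, spatial_corr = sc,
           mean_rate_a = mr_a[i], mean_rate_b = mr_b[i])
  })
}

#' Spatial information score of a rate map
#'
#' Skaggs information in bits per spike,
#' sum over bins of p_i (lambda_i / lambda) log2(lambda_i / lambda).
#'
#' @param map An `hm_rate_map`.
#' @return Bits per spike (NA for a silent map).
#' @export
spatial_information <- function(map) {
  occ <- as.vector(map$occupancy)
  lam <- as.vector(map$raw)
  ok <- occ > 0
  p <- occ[ok] / sum(occ[ok])
  l <- lam[ok]
  lbar <- sum(p * l)
  if (lbar == 0) return(NA_real_)
  pos <- l > 0
  sum(p[pos] * (l[pos] / lbar) * log2(l[pos] / lbar))
}
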