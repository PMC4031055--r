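#' Cluster CA3 cells by the spatial correlation of their rate maps
#'
#' Partitions active cells with k-medoids (PAM) on the distance
#' `1 - spatial correlation` between smoothed rate maps, choosing the number
#' of clusters that maximizes the mean silhouette width over a candidate
#' range (2 .. min(50, n/5) by default). k-medoids is the well-defined
#' counterpart of k-means for a non-Euclidean correlation distance.
#'
#' @param rate_maps Cells x bins matrix of smoothed rates (NA columns for
#'   unvisited bins are dropped).
#' @param k_range Candidate cluster counts; NULL for the default range.
#' @return An integer vector of cluster labels (one per row of `rate_maps`),
#'   with attribute `k`.
#' @export
cluster_ca3 <- function(rate_maps, k_range = NULL) {
  m <- as.matrix(rate_maps)
  keep_cols <- colSums(is.na(m)) == 0
  m <- m[, keep_cols, drop = FALSE]
  n <- nrow(m)
  if (n < 2) {
    abort("Clustering needs at least 2 cells with valid rate maps.",
          class = "hippomorph_argument_error")
  }
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn("Cells with constant rate maps assigned to their own single cluster.")
  }
  cm <- suppressWarnings(cor(t(m)))
  cm[!is.finite(cm)] <- 0
  d <- as.dist(1 - cm)
  if (max(d) < 1e-9) {
    warn("All rate maps identical; falling back to a single cluster.")
    return(structure(rep(1L, n), k = 1L))
  }
  if (is.null(k_range)) {
    k_range <- 2:max(2, min(50, floor(n / 5)))
    if (length(k_range) > 16) {
      k_range <- unique(round(seq(min(k_range), max(k_range), length.out = 16)))
    }
  }
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (!length(k_range)) k_range <- 2L
  best <- NULL; best_sil <- -Inf
  for (k in k_range) {
    fit <- cluster::pam(d, k, pamonce = 5)
    sil <- fit$silinfo$avg.width
    if (sil > best_sil) { best_sil <- sil; best <- fit }
  }
  structure(as.integer(best$clustering), k = length(unique(best$clustering)))
}

# Within-cluster weight matrix over `n_cells`, entries 1/n(C) for same-cluster
# pairs of `cells` (self included: incoming sums equal 1).
cluster_weight_matrix <- function(cells, labels, n_cells) {
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (cl in unique(labels)) {
    members <- cells[labels == cl]
    nc <- length(members)
    g <- expand.grid(a = members, b = members)
    i <- c(i, g$a); j <- c(j, g$b); x <- c(x, rep(1 / nc, nc * nc))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n_cells, n_cells))
}

#' Build the CA3 recurrent memory matrix from the two extreme environments
#'
#' Emulates familiarization with the square (condition 1) and round
#' (condition 7) environments: in each, active cells (session mean rate above
#' `threshold_hz`) are clustered by rate-map correlation, same-cluster cells
#' are interconnected with weight `1/n(C)` so every clustered cell's incoming
#' weights sum to 1, and the final weight of each cell pair is the maximum
#' over the two conditions. Both training sessions must come from
#' recurrence-free simulations.
#'
#' @param session_square,session_round Recurrence-free CA3 `hm_session`s in
#'   conditions 1 and 7.
#' @param h Smoothing SD (cm) for the rate maps used in clustering.
#' @param k_range Candidate cluster counts (see [cluster_ca3()]).
#' @param threshold_hz Activity threshold (Hz).
#' @return A list of class `hm_memory`: `w` (sparse n x n), `clusters`
#'   (list of per-condition tibbles), `n_cells`.
#' @export
build_memory <- function(session_square, session_round, h = 5,
                         k_range = NULL, threshold_hz = 0.1) {
  if (session_square$n_cells != session_round$n_cells) {
    abort("Training sessions must cover the same cell set.",
          class = "hippomorph_validation_error")
  }
  n <- session_square$n_cells
  one <- function(session) {
    act <- which(session_mean_rates(session) > threshold_hz)
    if (length(act) < 2) {
      warn("Fewer than 2 active cells; empty memory for this condition.")
      return(list(w = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0), dims = c(n, n)),
                  tab = tibble(cell = integer(0), cluster = integer(0))))
    }
    maps <- session_rate_maps(session, h)
    labels <- cluster_ca3(maps[act, , drop = FALSE], k_range)
    list(w = cluster_weight_matrix(act, labels, n),
         tab = tibble(cell = act, cluster = as.integer(labels)))
  }
  sq <- one(session_square)
  rd <- one(session_round)
  structure(list(
    w = pmax_sparse(sq$w, rd$w),
    clusters = list(square = sq$tab, round = rd$tab),
    n_cells = n
  ), class = "hm_memory")
}

# Element-wise maximum of two sparse matrices.
pmax_sparse <- function(a, b) {
  d <- (a - b)
  b + d * (d > 0)
}

#' Update the memory matrix after a session (experience-dependent learning)
#'
#' Builds a temporary connection matrix from the session's active cells with
#' the same clustering construction as [build_memory()], then moves the
#' weights among active-cell pairs toward it by a convex combination with
#' learning factor `l_rate`; pairs involving an inactive cell are untouched.
#' No renormalization is applied after the update.
#'
#' @param memory An `hm_memory`.
#' @param session The just-finished `hm_session`.
#' @param l_rate Learning factor in `[0, 1]`; 0 leaves the memory unchanged,
#'   1 replaces active-pair weights with the temporary matrix.
#' @param h,k_range,threshold_hz As in [build_memory()].
#' @return The updated `hm_memory`.
#' @export
update_memory <- function(memory, session, l_rate, h = 5, k_range = NULL,
                          threshold_hz = 0.1) {
  if (!is.numeric(l_rate) || l_rate < 0 || l_rate > 1) {
    abort("`l_rate` must lie in [0, 1].", class = "hippomorph_argument_error")
  }
  if (l_rate == 0) return(memory)
  act <- which(session_mean_rates(session) > threshold_hz)
  if (length(act) < 2) return(memory)
  maps <- session_rate_maps(session, h)
  labels <- cluster_ca3(maps[act, , drop = FALSE], k_range)
  w_tmp <- cluster_weight_matrix(act, labels, memory$n_cells)
  w <- memory$w
  block_old <- as.matrix(w[act, act, drop = FALSE])
  block_tmp <- as.matrix(w_tmp[act, act, drop = FALSE])
  w[act, act] <- (1 - l_rate) * block_old + l_rate * block_tmp
  memory$w <- Matrix::drop0(w)
  memory
}

#' @export
print.hm_memory <- function(x, ...) {
  cat(sprintf(
    "<hm_memory> %d cells; %d square-cluster cells (k=%d), %d round-cluster cells (k=%d), %d nonzero weights\n",
    x$n_cells, nrow(x$clusters$square),
    length(unique(x$clusters$square$cluster)),
    nrow(x$clusters$round), length(unique(x$clusters$round$cluster)),
    Matrix::nnzero(x$w)))
  invisible(x)
}

#' @export
#' @method tidy hm_memory
tidy.hm_memory <- function(x, ...) {
  w <- as(x$w, "TsparseMatrix")
  tibble(from = w@j + 1L, to = w@i + 1L, weight = w@x)
}

#' @export
#' @method glance hm_memory
glance.hm_memory <- function(x, ...) {
  inc <- Matrix::rowSums(x$w)
  tibble(
    n_cells = x$n_cells,
    n_connected = sum(inc > 0),
    n_edges = Matrix::nnzero(x$w),
    mean_incoming = mean(inc[inc > 0]),
    k_square = length(unique(x$clusters$square$cluster)),
    k_round = length(unique(x$clusters$round$cluster))
  )
}
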