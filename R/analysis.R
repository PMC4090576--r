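# Online analysis operators: per-cut summary statistics, Savitzky-Golay
# filtering with local-trend forecasting, K-means and quality-threshold
# clustering of trajectory ensembles, and peak/frequency detection.

#' Summary statistics of one time-cut
#'
#' Sample mean, standard deviation (n-1 denominator) and quantiles (linear
#' interpolation between order statistics, [stats::quantile()] type 7) of
#' the ensemble values at one grid time, per observed species.
#'
#' @param cut a `time_cut` (see [new_aligner()]).
#' @param levels quantile levels in `[0, 1]`.
#' @param species subset of species to summarise (default: all in the cut).
#' @return a data frame with one row per species: `time`, `species`, `mean`,
#'   `sd`, and one `q<level>` column per level.
#' @export
summary_stats <- function(cut, levels = c(0.05, 0.25, 0.5, 0.75, 0.95),
                          species = NULL) {
  stopifnot(inherits(cut, "time_cut"))
  if (!nrow(cut$values)) stop("empty time-cut")
  if (any(levels < 0 | levels > 1)) stop("quantile levels must be in [0, 1]")
  sp <- species %||% colnames(cut$values)
  rows <- lapply(sp, function(s) {
    v <- cut$values[, s]
    qs <- quantile(v, probs = levels, names = FALSE, type = 7)
    rec <- data.frame(time = cut$time, species = s, mean = mean(v),
                      sd = if (length(v) > 1) sd(v) else 0)
    for (i in seq_along(levels)) rec[[sprintf("q%02d", round(100 * levels[i]))]] <- qs[i]
    rec
  })
  do.call(rbind, rows)
}

# ---- Savitzky-Golay ---------------------------------------------------------

#' Savitzky-Golay convolution coefficients
#'
#' Least-squares local polynomial filter: fits a polynomial of degree
#' `order` over a symmetric window and evaluates it (or its `deriv`-th
#' derivative) at the centre. Smoothing coefficients (`deriv = 0`) sum to 1;
#' first-derivative coefficients sum to 0 and must be divided by the
#' sampling step on application. The filter reproduces polynomials up to
#' degree `order` exactly, which is what preserves peak heights and local
#' moments that a plain moving average flattens.
#'
#' @param window odd window length (> `order`).
#' @param order polynomial degree.
#' @param deriv derivative order: 0 (smoothing) or 1 (slope).
#' @return numeric coefficient vector of length `window`, applied by inner
#'   product with the raw window values.
#' @examples
#' 35 * savgol_coefficients(5, 2)  # the classic (-3, 12, 17, 12, -3) stencil
#' @export
savgol_coefficients <- function(window, order, deriv = 0) {
  stopifnot(window %% 2 == 1, window >= 3, deriv %in% c(0, 1))
  if (order >= window) stop("polynomial order must be below the window length")
  h <- (window - 1) / 2
  A <- outer(seq(-h, h), 0:order, `^`)          # Vandermonde on the stencil
  # row `deriv` of (A'A)^{-1} A' gives the centre value of the fitted
  # polynomial's deriv-th coefficient; scale by deriv! for the derivative
  G <- solve(crossprod(A), t(A))
  factorial(deriv) * G[deriv + 1, ]
}

#' Savitzky-Golay filtering and one-step forecast of a trajectory window
#'
#' For each trajectory in a sliding-window block, computes the smoothed
#' centre value \eqn{\hat x_i}, the smoothed derivative \eqn{\hat x'_i}
#' (scaled by `1/delta_s`), and the forecast point
#' \eqn{x^E_i = \hat x_i + \hat x'_i \Delta_S} — the value one sampling step
#' ahead along the local trend. These (value, forecast) pairs are the
#' clustering features.
#'
#' @param window_values an n-by-width numeric matrix (one row per
#'   trajectory, columns = consecutive cuts), or a `window_block` together
#'   with `species`.
#' @param delta_s sampling step.
#' @param sg_window,sg_order filter window (odd, `<=` block width) and
#'   polynomial order.
#' @param species when passing a `window_block`: species to extract.
#' @return a data frame with columns `trajectory`, `smoothed`, `derivative`,
#'   `forecast`.
#' @export
filter_and_forecast <- function(window_values, delta_s, sg_window = NULL,
                                sg_order = 3, species = NULL) {
  if (inherits(window_values, "window_block")) {
    stopifnot(!is.null(species))
    window_values <- window_matrix(window_values, species)
  }
  stopifnot(is.matrix(window_values), delta_s > 0)
  width <- ncol(window_values)
  if (width %% 2 != 1) stop("window width must be odd")
  sg_window <- sg_window %||% min(width, 9L)
  if (sg_window > width) stop("sg_window must not exceed the block width")
  c0 <- savgol_coefficients(sg_window, sg_order, 0)
  c1 <- savgol_coefficients(sg_window, sg_order, 1)
  # centre the filter stencil on the block centre
  off <- (width - sg_window) / 2
  sub <- window_values[, (off + 1):(off + sg_window), drop = FALSE]
  xhat <- as.vector(sub %*% c0)
  dx <- as.vector(sub %*% c1) / delta_s
  data.frame(trajectory = seq_len(nrow(window_values)) - 1L,
             smoothed = xhat, derivative = dx,
             forecast = xhat + dx * delta_s)
}

# ---- clustering -------------------------------------------------------------

as_points_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points)) points <- matrix(points, ncol = 1)
  storage.mode(points) <- "double"
  points
}

#' K-means clustering of trajectory feature points
#'
#' Lloyd iterations from a deterministic seeded start: `k` distinct points
#' are chosen as initial centres using a private RNG stream, then points are
#' assigned to the nearest centre (Euclidean) and centres recomputed until
#' the largest centre movement is below `1e-6` or 100 iterations. A cluster
#' that empties is repaired by reseeding it with the point farthest from its
#' assigned centre. Intended for switch-like systems where the number of
#' stable states is known in advance.
#'
#' @param points numeric matrix (rows = trajectories, columns = features,
#'   typically the smoothed value and forecast), or a vector for 1-D.
#' @param k number of clusters (`1 <= k <= n`).
#' @param seed deterministic initialisation seed.
#' @return an object of class `cluster_assignment`: list with `method`,
#'   `labels` (1-based cluster per point), `centers` (k x d matrix),
#'   `sizes`, `objective` (within-cluster sum of squares trace across
#'   iterations, non-increasing).
#' @export
kmeans_cluster <- function(points, k, seed = 1) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  stopifnot(k >= 1)
  if (k > n) stop("k must not exceed the number of points")
  rng <- ssa_rng_state_cpp(seed)
  draw <- function() ssa_rng_u01_cpp(rng)
  # seed with k distinct rows (distinct indices; duplicated coordinates in
  # the data are allowed and later repaired if a cluster empties)
  init <- integer(0)
  while (length(init) < k) {
    cand <- floor(draw() * n) + 1L
    if (!(cand %in% init)) init <- c(init, cand)
  }
  centers <- pts[init, , drop = FALSE]
  obj_trace <- numeric(0)
  labels <- rep(1L, n)
  for (iter in seq_len(100)) {
    d2 <- dist2_to_centers(pts, centers)
    labels <- max.col(-d2, ties.method = "first")
    # repair empty clusters with the farthest point
    repeat {
      sizes <- tabulate(labels, k)
      empty <- which(sizes == 0)
      if (!length(empty)) break
      far <- which.max(d2[cbind(seq_len(n), labels)])
      labels[far] <- empty[1]
      centers[empty[1], ] <- pts[far, ]
      d2 <- dist2_to_centers(pts, centers)
    }
    obj_trace <- c(obj_trace, sum(d2[cbind(seq_len(n), labels)]))
    new_centers <- centers
    for (j in seq_len(k))
      new_centers[j, ] <- colMeans(pts[labels == j, , drop = FALSE])
    move <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (move < 1e-6) break
  }
  structure(list(method = "kmeans", labels = labels, centers = centers,
                 sizes = tabulate(labels, k), objective = obj_trace),
            class = "cluster_assignment")
}

dist2_to_centers <- function(pts, centers) {
  n <- nrow(pts); k <- nrow(centers)
  out <- matrix(0, n, k)
  for (j in seq_len(k))
    out[, j] <- rowSums((pts - matrix(centers[j, ], n, ncol(pts),
                                      byrow = TRUE))^2)
  out
}

#' Quality-threshold (QT) clustering
#'
#' Classic QT: every point seeds a candidate cluster that grows greedily by
#' the point whose inclusion least increases the cluster diameter (maximum
#' pairwise Euclidean distance), as long as the diameter stays within
#' `diameter_threshold`. The largest candidate (ties: lowest seed index) is
#' committed, its points removed, and the procedure repeats. Committed
#' clusters smaller than `min_size` are reported as unclustered
#' (`NA` label). Unlike K-means the number of clusters is discovered, at a
#' higher computational cost.
#'
#' @param points as in [kmeans_cluster()].
#' @param diameter_threshold maximum allowed cluster diameter (> 0).
#' @param min_size smallest reportable cluster.
#' @return a `cluster_assignment` (labels `NA` for unclustered points);
#'   `centers` are cluster means.
#' @export
qt_cluster <- function(points, diameter_threshold, min_size = 1L) {
  stopifnot(diameter_threshold > 0)
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  remaining <- seq_len(n)
  labels <- rep(NA_integer_, n)
  next_label <- 0L
  while (length(remaining) > 0) {
    best <- NULL
    for (seed_pos in seq_along(remaining)) {
      members <- remaining[seed_pos]
      cand <- setdiff(remaining, members)
      # maxd[i]: diameter if candidate point i joined the current cluster
      maxd <- D[cand, members[1]]
      repeat {
        ok <- which(maxd <= diameter_threshold)
        if (!length(cand) || !length(ok)) break
        pick <- ok[which.min(maxd[ok])]
        members <- c(members, cand[pick])
        newcol <- D[cand, cand[pick]]
        maxd <- pmax(maxd, newcol)[-pick]
        cand <- cand[-pick]
      }
      if (is.null(best) || length(members) > length(best))
        best <- members
      if (length(best) >= length(remaining)) break  # cannot be beaten
    }
    next_label <- next_label + 1L
    labels[best] <- next_label
    remaining <- setdiff(remaining, best)
  }
  # drop clusters below min_size, then relabel compactly by decreasing size
  sizes <- tabulate(labels, next_label)
  small <- which(sizes < min_size)
  labels[labels %in% small] <- NA_integer_
  kept <- sort(unique(labels[!is.na(labels)]))
  labels <- match(labels, kept)
  k <- length(kept)
  centers <- matrix(NA_real_, k, ncol(pts))
  for (j in seq_len(k))
    centers[j, ] <- colMeans(pts[which(labels == j), , drop = FALSE])
  structure(list(method = "qt", labels = labels, centers = centers,
                 sizes = tabulate(labels, k)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %s: %d clusters over %d points\n",
              x$method, nrow(x$centers), length(x$labels)))
  for (j in seq_len(nrow(x$centers)))
    cat(sprintf("  cluster %d: size %d, center (%s)\n", j, x$sizes[j],
                paste(signif(x$centers[j, ], 5), collapse = ", ")))
  if (anyNA(x$labels))
    cat(sprintf("  unclustered: %d\n", sum(is.na(x$labels))))
  invisible(x)
}

# ---- peak / frequency detection ---------------------------------------------

#' Detect peaks in a sampled trajectory
#'
#' The series is Savitzky-Golay smoothed; candidate peaks are the
#' `+` to `-` sign changes of the smoothed derivative, refined to the local
#' maximum of the smoothed series within half a filter window. Peaks whose
#' prominence over the higher of the two neighbouring smoothed minima is
#' below `min_height_frac` times the smoothed series range are discarded;
#' peaks closer than `min_separation` samples are merged keeping the higher.
#'
#' @param x numeric series sampled on a uniform grid.
#' @param times sample times (default `0, 1, 2, ...`).
#' @param sg_window,sg_order Savitzky-Golay parameters (`length(x)` must
#'   exceed `sg_window`).
#' @param min_height_frac minimum prominence as a fraction of the smoothed
#'   series range.
#' @param min_separation minimum peak separation in samples.
#' @return numeric vector of peak times (strictly increasing).
#' @examples
#' t <- seq(0, 4 * pi, by = 0.1)
#' detect_peaks(sin(t), times = t)  # close to pi/2 and 5 pi/2
#' @export
detect_peaks <- function(x, times = seq_along(x) - 1, sg_window = 9L,
                         sg_order = 3L, min_height_frac = 0.1,
                         min_separation = 2L) {
  n <- length(x)
  stopifnot(n == length(times), n > sg_window)
  h <- (sg_window - 1L) %/% 2L
  c0 <- savgol_coefficients(sg_window, sg_order, 0)
  c1 <- savgol_coefficients(sg_window, sg_order, 1)
  # interior smoothed values / derivative (edges are left untouched: a peak
  # needs a full stencil anyway)
  sm <- x
  dv <- rep(NA_real_, n)
  idx <- (h + 1L):(n - h)
  win <- vapply(idx, function(i) x[(i - h):(i + h)], numeric(sg_window))
  sm[idx] <- as.vector(c0 %*% win)
  dv[idx] <- as.vector(c1 %*% win)
  interior <- idx[-length(idx)]
  cand <- interior[!is.na(dv[interior]) & !is.na(dv[interior + 1L]) &
                     dv[interior] > 0 & dv[interior + 1L] <= 0]
  if (!length(cand)) return(numeric(0))
  # refine to the local max of the smoothed series
  cand <- vapply(cand, function(i) {
    lo <- max(h + 1L, i - h); hi <- min(n - h, i + h)
    (lo:hi)[which.max(sm[lo:hi])]
  }, integer(1))
  cand <- sort(unique(cand))
  # prominence filter against neighbouring smoothed minima
  rng <- diff(range(sm[idx]))
  if (rng > 0 && min_height_frac > 0) {
    keep <- vapply(seq_along(cand), function(j) {
      i <- cand[j]
      left0 <- if (j == 1) h + 1L else cand[j - 1L]
      right0 <- if (j == length(cand)) n - h else cand[j + 1L]
      lmin <- min(sm[left0:i]); rmin <- min(sm[i:right0])
      (sm[i] - max(lmin, rmin)) >= min_height_frac * rng
    }, logical(1))
    cand <- cand[keep]
  }
  # merge close peaks, keeping the higher
  if (length(cand) > 1 && min_separation > 0) {
    merged <- cand[1]
    for (i in cand[-1]) {
      last <- merged[length(merged)]
      if (i - last < min_separation) {
        if (sm[i] > sm[last]) merged[length(merged)] <- i
      } else merged <- c(merged, i)
    }
    cand <- merged
  }
  times[cand]
}

#' Oscillation periods from detected peaks
#'
#' Local periods are successive peak-time differences per trajectory;
#' trajectories with fewer than two peaks contribute nothing. The ensemble
#' series pools all local periods (stamped at the later peak), sorts them by
#' time, and applies a centred moving average of `ma_window` events over
#' trajectories and time.
#'
#' @param peaks a list of per-trajectory peak-time vectors (or a single
#'   numeric vector for one trajectory).
#' @param ma_window moving-average window (number of period events).
#' @return list with `local` (data frame: trajectory, time, period) and `ma`
#'   (data frame: time, period_ma).
#' @examples
#' peak_periods(c(2, 4.5, 7))$local$period  # 2.5 2.5
#' @export
peak_periods <- function(peaks, ma_window = 25L) {
  if (is.numeric(peaks)) peaks <- list(peaks)
  rows <- do.call(rbind, lapply(seq_along(peaks), function(i) {
    pt <- peaks[[i]]
    if (length(pt) < 2) return(NULL)
    if (any(diff(pt) <= 0)) stop("peak times must be strictly increasing")
    data.frame(trajectory = i - 1L, time = pt[-1], period = diff(pt))
  }))
  if (is.null(rows))
    return(list(local = data.frame(trajectory = integer(0), time = numeric(0),
                                   period = numeric(0)),
                ma = data.frame(time = numeric(0), period_ma = numeric(0))))
  rows <- rows[order(rows$time, rows$trajectory), ]
  rownames(rows) <- NULL
  w <- min(ma_window, nrow(rows))
  ma <- if (w >= 1) {
    cs <- cumsum(rows$period)
    k <- nrow(rows)
    half <- (w - 1) %/% 2
    period_ma <- vapply(seq_len(k), function(i) {
      lo <- max(1, i - half); hi <- min(k, i + (w - 1 - half))
      (cs[hi] - if (lo > 1) cs[lo - 1] else 0) / (hi - lo + 1)
    }, numeric(1))
    data.frame(time = rows$time, period_ma = period_ma)
  } else data.frame(time = numeric(0), period_ma = numeric(0))
  list(local = rows, ma = ma)
}

# ---- synthetic ensembles for exercising the analysis operators --------------

#' Synthetic time-cut ensembles with known structure
#'
#' Deterministic-given-seed generators used to exercise the analysis
#' operators without the simulator:
#'
#' * `"bimodal_switcher"`: each trajectory sits at one of two modes
#'   (assigned by fair coin) plus Gaussian noise — a caricature of a
#'   bistable ensemble.
#' * `"sinusoid"`: phase-shared sinusoid plus noise — a caricature of an
#'   oscillatory ensemble.
#' * `"constant"`: a constant level plus noise.
#'
#' @param kind one of `"bimodal_switcher"`, `"sinusoid"`, `"constant"`.
#' @param n trajectories; `length` number of cuts; `delta_s` grid step.
#' @param params named list: modes (`modes`, 2 values), `period`,
#'   `amplitude`, `level`, `noise_sd` as applicable.
#' @param seed deterministic seed.
#' @param species species name stamped on the cuts.
#' @return list of `time_cut` objects.
#' @export
synth_ensemble <- function(kind = c("bimodal_switcher", "sinusoid", "constant"),
                           n = 20, length = 21, delta_s = 1,
                           params = list(), seed = 1, species = "X") {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(modes = c(0, 100), period = 20, amplitude = 10,
                              level = 50, noise_sd = 1), params)
  if (p$noise_sd < 0 || n < 1 || length < 1) stop("invalid parameters")
  rng <- ssa_rng_state_cpp(seed)
  draw <- function() ssa_rng_u01_cpp(rng)
  # Box-Muller from the private stream keeps the generator independent of
  # the global R RNG state
  gauss <- function() {
    u1 <- draw(); u2 <- draw()
    sqrt(-2 * log(1 - u1)) * cos(2 * pi * u2)
  }
  base <- switch(kind,
    bimodal_switcher = {
      mode <- vapply(seq_len(n), function(i) p$modes[1 + (draw() >= 0.5)],
                     numeric(1))
      function(i, t) mode[i]
    },
    sinusoid = function(i, t) p$level + p$amplitude * sin(2 * pi * t / p$period),
    constant = function(i, t) p$level)
  lapply(seq_len(length) - 1L, function(j) {
    t <- j * delta_s
    v <- vapply(seq_len(n), function(i) base(i, t) + p$noise_sd * gauss(),
                numeric(1))
    structure(list(index = j, time = t,
                   values = matrix(v, n, 1, dimnames = list(NULL, species))),
              class = "time_cut")
  })
}
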