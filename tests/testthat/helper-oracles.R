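# Independent oracles used across the suite. These never call the code paths
# they check.

# Positive real roots of the Schlogl mean-field rate polynomial
# dA/dt = 0.015 A^2 - (1e-4/6) A^3 + 200 - 3.5 A, with stability from the
# sign of the derivative.
schlogl_fixed_points <- function() {
  coefs <- c(200, -3.5, 0.015, -1e-4 / 6) # ascending powers
  r <- polyroot(coefs)
  r <- sort(Re(r[abs(Im(r)) < 1e-8]))
  dcoefs <- coefs[-1] * seq_along(coefs[-1])
  slope <- vapply(r, function(a) sum(dcoefs * a^(0:2)), numeric(1))
  data.frame(root = r, stable = slope < 0)
}

# Savitzky-Golay center coefficients by explicit least squares: fit a
# degree-`order` polynomial to the unit stencil with lm() and read the
# fitted value / slope at 0 as a linear function of the responses.
sg_ls_oracle <- function(window, order, deriv = 0) {
  h <- (window - 1) / 2
  x <- seq(-h, h)
  vapply(seq_len(window), function(i) {
    y <- as.numeric(seq_len(window) == i)
    fit <- stats::lm(y ~ poly(x, order, raw = TRUE))
    unname(coef(fit)[deriv + 1]) * factorial(deriv)
  }, numeric(1))
}

# Largest point subset with diameter <= threshold, by exhaustive enumeration
# (n <= ~15). Returns the subset size.
qt_max_cluster_size <- function(points, threshold) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 1)
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  best <- 1L
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) <= best) next
    if (max(D[members, members]) <= threshold) best <- length(members)
  }
  best
}

# Per-trajectory series matrix (n x cuts) for one species of a cut stream.
cuts_to_matrix <- function(cuts, species) {
  vapply(cuts, function(cut) cut$values[, species],
         numeric(nrow(cuts[[1]]$values)))
}

# Mean period of the Neurospora mean-field ODE (Goldbeter-scaled counts),
# integrated with deSolve; repression by nuclear FRQ.
neurospora_ode_period <- function(condition = "dark", t_end = 400,
                                  transient = 48) {
  vs_of <- if (condition == "dark") function(t) 160 else
    function(t) if ((t %% 24) < 12) 160 else 200
  rhs <- function(t, y, p) {
    M <- y[1]; FC <- y[2]; FN <- y[3]
    dM <- vs_of(t) * 100^4 / (100^4 + FN^4) - 50.5 * M / (50 + M)
    dFC <- 0.5 * M - 140 * FC / (13 + FC) - 0.5 * FC + 0.6 * FN
    dFN <- 0.5 * FC - 0.6 * FN
    list(c(dM, dFC, dFN))
  }
  out <- deSolve::ode(c(M = 360, FC = 100, FN = 100),
                      seq(0, t_end, by = 0.05), rhs, NULL)
  M <- out[, "M"]; t <- out[, "time"]
  pk <- which(diff(sign(diff(M))) == -2) + 1
  pk <- t[pk]
  pk <- pk[pk > transient]
  mean(diff(pk))
}

# Mean SSA inter-peak period of a builtin Neurospora ensemble, measured with
# the package's own peak detector (the quantity under test).
ssa_mean_period <- function(condition, n = 16, base_seed = 1, t_end = 200,
                            delta_s = 0.25, transient = 48) {
  m <- builtin_model("neurospora", condition, T_phase = 12)
  periods <- unlist(lapply(seq_len(n) - 1L, function(i) {
    tr <- run_trajectory(m, seed = base_seed + i, t_end = t_end,
                         delta_s = delta_s)
    pk <- detect_peaks(tr$M, times = tr$time)
    diff(pk[pk >= transient])
  }))
  mean(periods)
}
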