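cut_of <- function(values, species = "A", index = 0, time = 0) {
  structure(list(index = index, time = time,
                 values = matrix(values, ncol = 1,
                                 dimnames = list(NULL, species))),
            class = "time_cut")
}

test_that("summary statistics match their textbook definitions", {
  rec <- summary_stats(cut_of(c(1, 2, 3, 4)), levels = c(0, 0.5, 1))
  expect_equal(rec$mean, 2.5)
  expect_equal(rec$sd, sd(c(1, 2, 3, 4)))
  expect_equal(rec$sd, 1.29099, tolerance = 1e-5)
  expect_equal(rec$q50, 2.5)
  expect_equal(c(rec$q00, rec$q100), c(1, 4))   # levels {0,1} give (min, max)
  const <- summary_stats(cut_of(c(5, 5, 5)))
  expect_equal(const$sd, 0)
  expect_true(all(const[, grep("^q", names(const))] == 5))
  expect_error(summary_stats(cut_of(numeric(0))), "empty")
})

test_that("Savitzky-Golay coefficients match the least-squares oracle and the classic stencil", {
  expect_equal(savgol_coefficients(5, 2, 0), c(-3, 12, 17, 12, -3) / 35)
  for (cfg in list(c(5, 2), c(7, 3), c(9, 4), c(11, 2))) {
    for (d in 0:1) {
      expect_equal(savgol_coefficients(cfg[1], cfg[2], d),
                   sg_ls_oracle(cfg[1], cfg[2], d),
                   tolerance = 1e-10)
    }
    expect_equal(sum(savgol_coefficients(cfg[1], cfg[2], 0)), 1)
    expect_equal(sum(savgol_coefficients(cfg[1], cfg[2], 1)), 0)
  }
  # independent cross-check against the signal package
  expect_equal(savgol_coefficients(9, 3, 0),
               unclass(signal::sgolay(3, 9))[5, ],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(savgol_coefficients(5, 5), "order")
})

test_that("filtering reproduces polynomials exactly and forecasts along the trend", {
  width <- 9
  x <- seq_len(width)
  lin <- matrix(2 * x + 1, nrow = 1)
  fp <- filter_and_forecast(lin, delta_s = 1, sg_window = 9, sg_order = 3)
  expect_equal(fp$derivative, 2)
  expect_equal(fp$forecast, fp$smoothed + 2)
  const <- matrix(rep(5, width), nrow = 1)
  fc <- filter_and_forecast(const, delta_s = 0.5)
  expect_equal(fc$derivative, 0)
  expect_equal(fc$forecast, fc$smoothed)
  quad <- matrix((x - 5)^2, nrow = 1)
  fq <- filter_and_forecast(quad, delta_s = 1, sg_window = 9, sg_order = 3)
  expect_equal(fq$smoothed, 0)           # raw centre value, exactly
  # derivative scaling follows the sampling step
  fh <- filter_and_forecast(lin, delta_s = 0.25, sg_window = 9, sg_order = 3)
  expect_equal(fh$derivative, 8)         # 2 per sample / 0.25 per sample
})

test_that("k-means separates well-separated groups and matches stats::kmeans", {
  km <- kmeans_cluster(c(0, 1, 10, 11), k = 2, seed = 4)
  expect_equal(sort(as.vector(km$centers)), c(0.5, 10.5))
  expect_equal(km$sizes, c(2L, 2L))
  expect_length(unique(km$labels[1:2]), 1)
  expect_false(km$labels[1] == km$labels[3])
  one <- kmeans_cluster(c(3, 5, 10), k = 1)
  expect_equal(as.vector(one$centers), 6)
  expect_error(kmeans_cluster(1:3, k = 5), "exceed")
  # objective non-increasing; partition covers all points
  rng <- ssa_rng_state_cpp(99)
  pts <- cbind(vapply(1:40, function(i) 10 * ssa_rng_u01_cpp(rng), numeric(1)),
               vapply(1:40, function(i) 10 * ssa_rng_u01_cpp(rng), numeric(1)))
  km2 <- kmeans_cluster(pts, k = 3, seed = 1)
  expect_true(all(diff(km2$objective) <= 1e-9))
  expect_equal(sum(km2$sizes), 40)
  expect_false(anyNA(km2$labels))
  # independent cross-check on separated data
  sep <- rbind(pts, pts + 100)
  km3 <- kmeans_cluster(sep, k = 2, seed = 1)
  ref <- stats::kmeans(sep, centers = 2, algorithm = "Lloyd")
  expect_equal(sort(km3$centers[, 1]), sort(unname(ref$centers[, 1])),
               tolerance = 1e-6)
})

test_that("QT clustering commits largest-diameter-feasible groups first", {
  qt <- qt_cluster(c(1, 2, 3, 10), diameter_threshold = 2.5)
  expect_equal(qt$labels, c(1L, 1L, 1L, 2L))
  expect_equal(as.vector(qt$centers), c(2, 10))
  all_one <- qt_cluster(c(1, 2, 3, 10), diameter_threshold = 100)
  expect_equal(all_one$labels, rep(1L, 4))
  singles <- qt_cluster(c(1, 5, 9), diameter_threshold = 0.5)
  expect_equal(singles$sizes, rep(1L, 3))
  # min_size filtering reports small groups as unclustered
  qt2 <- qt_cluster(c(1, 2, 3, 10), diameter_threshold = 2.5, min_size = 2)
  expect_equal(qt2$labels, c(1L, 1L, 1L, NA))
})

test_that("QT invariants hold on random instances against brute force", {
  rng <- ssa_rng_state_cpp(123)
  for (rep in 1:8) {
    n <- 8 + rep %% 4
    pts <- vapply(seq_len(n), function(i) 20 * ssa_rng_u01_cpp(rng), numeric(1))
    thr <- 2 + 10 * ssa_rng_u01_cpp(rng)
    qt <- qt_cluster(pts, diameter_threshold = thr)
    labs <- qt$labels
    expect_equal(sum(qt$sizes), n)
    for (lab in unique(labs)) {
      members <- pts[labs == lab]
      if (length(members) > 1)
        expect_lte(max(dist(members)), thr)
    }
    # the first committed cluster never exceeds the best possible subset
    expect_lte(max(qt$sizes), qt_max_cluster_size(pts, thr))
  }
})

test_that("cluster-size-weighted centre means reconstruct the cut mean", {
  rng <- ssa_rng_state_cpp(5)
  vals <- vapply(1:60, function(i)
    100 * (ssa_rng_u01_cpp(rng) > 0.5) + 5 * ssa_rng_u01_cpp(rng), numeric(1))
  km <- kmeans_cluster(vals, k = 2, seed = 2)
  expect_equal(sum(km$sizes * km$centers[, 1]) / length(vals), mean(vals))
  qt <- qt_cluster(vals, diameter_threshold = 20)
  expect_equal(sum(qt$sizes * qt$centers[, 1]) / length(vals), mean(vals))
})

test_that("peaks of a sine are found at the crests with the right spacing", {
  t <- seq(0, 4 * pi, by = 0.1)
  pk <- detect_peaks(sin(t), times = t)
  expect_length(pk, 2)
  expect_equal(pk[1], pi / 2, tolerance = 0.05)
  expect_equal(diff(pk), 2 * pi, tolerance = 0.02)
  expect_length(detect_peaks(seq(0, 10, by = 0.1)), 0)   # monotone: no peaks
})

test_that("mild noise does not change the detected peak count after smoothing", {
  t <- seq(0, 6 * pi, by = 0.1)
  clean <- detect_peaks(sin(t), times = t)
  rng <- ssa_rng_state_cpp(31)
  noise <- vapply(seq_along(t), function(i) 0.05 * (ssa_rng_u01_cpp(rng) - 0.5),
                  numeric(1))
  noisy <- detect_peaks(sin(t) + noise, times = t)
  expect_length(noisy, length(clean))
  expect_equal(noisy, clean, tolerance = 0.1)
})

test_that("local periods and their moving average follow the peak streams", {
  pp <- peak_periods(c(2, 4.5, 7))
  expect_equal(pp$local$period, c(2.5, 2.5))
  empty <- peak_periods(c(3))
  expect_equal(nrow(empty$local), 0)
  two <- peak_periods(list(c(0, 10, 20), c(5, 17)), ma_window = 3)
  expect_equal(nrow(two$local), 3)
  expect_equal(sort(two$local$period), c(10, 10, 12))
  expect_equal(nrow(two$ma), 3)
  expect_true(all(two$ma$period_ma >= 10 & two$ma$period_ma <= 12))
})

test_that("synthetic ensembles have their constructed structure", {
  cuts <- synth_ensemble("bimodal_switcher", n = 30, length = 11, seed = 8,
                         params = list(modes = c(0, 100), noise_sd = 1))
  cuts2 <- synth_ensemble("bimodal_switcher", n = 30, length = 11, seed = 8,
                          params = list(modes = c(0, 100), noise_sd = 1))
  expect_identical(cuts, cuts2)                 # same seed, same stream
  qt <- qt_cluster(cuts[[5]]$values[, 1], diameter_threshold = 10)
  expect_equal(nrow(qt$centers), 2)
  expect_equal(sort(round(qt$centers[, 1], -1)), c(0, 100))

  sc <- synth_ensemble("sinusoid", n = 3, length = 121, delta_s = 1, seed = 2,
                       params = list(period = 20, amplitude = 10,
                                     noise_sd = 0.2))
  series <- cuts_to_matrix(sc, "X")
  pk <- detect_peaks(series[1, ], times = 0:120)
  expect_equal(mean(diff(pk)), 20, tolerance = 0.05)
})
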