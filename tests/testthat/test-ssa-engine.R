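test_that("mass-action propensities follow the combinatorial convention", {
  expect_equal(propensity(reaction(c(A = 2), c(A = 3), 0.03), c(A = 4)),
               0.03 * 4 * 3 / 2)
  expect_equal(propensity(reaction(c(A = 3), c(A = 2), 0.0001), c(A = 3)),
               0.0001)
  expect_equal(propensity(reaction("B", c("B", "A"), 200), c(A = 0, B = 1)),
               200)
  # below-multiplicity counts give zero
  expect_equal(propensity(reaction(c(A = 3), c(A = 2), 0.0001), c(A = 2)), 0)
  # function rates evaluate directly, no extra multiplicity factor
  rx <- reaction("M", character(), rate_michaelis("M", 50.5, 50))
  expect_equal(propensity(rx, c(M = 50)), 25.25)
})

test_that("a single decay fires once and an absorbing task finishes at t_end", {
  m <- ssa_model("decay", "A", list(reaction("A", character(), 3.5)),
                 init = c(A = 1))
  task <- new_simulation_task(m, 0, base_seed = 5)
  res <- ssa_step(task, m, t_end = 100, delta_s = 1)
  expect_equal(unname(res$task$counts["A"]), 0L)
  expect_gt(res$task$clock, 0)
  # now absorbing: next step runs to t_end and finishes
  res2 <- ssa_step(res$task, m, t_end = 100, delta_s = 1)
  expect_true(res2$task$done)
  expect_equal(res2$task$clock, 100)
})

test_that("a proposed firing across a schedule boundary moves the clock without firing", {
  sch <- piecewise_schedule(1e-9, 5, 12)
  m <- ssa_model("forced", "X",
                 list(reaction(character(), "X",
                               rate_hill_repression("X", sch, K_I = 100, n = 1))),
                 init = c(X = 0))
  task <- new_simulation_task(m, 0, base_seed = 1)
  # dark-phase propensity 1e-9: the first waiting time is astronomically
  # long, so the step must stop exactly at the boundary, unchanged
  res <- ssa_step(task, m, t_end = 100, delta_s = 1)
  expect_equal(res$task$clock, 12)
  expect_equal(unname(res$task$counts["X"]), 0L)
  # light phase: now the reaction actually fires
  res2 <- ssa_step(res$task, m, t_end = 100, delta_s = 1)
  expect_equal(unname(res2$task$counts["X"]), 1L)
  expect_lt(res2$task$clock, 14)
})

test_that("advancing in quanta or in one call yields identical samples", {
  m <- builtin_model("schlogl")
  one <- advance_to(new_simulation_task(m, 0, base_seed = 3), m,
                    t_target = 5, t_end = 5, delta_s = 0.05)
  task <- new_simulation_task(m, 0, base_seed = 3)
  pieces <- list()
  for (q in seq(0.25, 5, by = 0.25)) {
    r <- advance_to(task, m, t_target = q, t_end = 5, delta_s = 0.05)
    task <- r$task
    pieces[[length(pieces) + 1L]] <- r$chunk$counts
  }
  expect_equal(do.call(cbind, pieces), one$chunk$counts)
  expect_equal(task$counts, one$task$counts)
  expect_equal(task$clock, one$task$clock)
})

test_that("trajectories are bit-reproducible for a fixed seed", {
  m <- builtin_model("neurospora", "dark")
  a <- run_trajectory(m, seed = 11, t_end = 20, delta_s = 0.25)
  b <- run_trajectory(m, seed = 11, t_end = 20, delta_s = 0.25)
  expect_identical(a, b)
  c <- run_trajectory(m, seed = 12, t_end = 20, delta_s = 0.25)
  expect_false(identical(a$M, c$M))
})

test_that("an empty reaction list yields a constant series of the right length", {
  m <- ssa_model("still", "A", list(), init = c(A = 7))
  tr <- run_trajectory(m, seed = 1, t_end = 3, delta_s = 0.5)
  expect_equal(nrow(tr), 7)           # floor(3/0.5) + 1
  expect_equal(tr$A, rep(7L, 7))
  expect_equal(tr$time, seq(0, 3, by = 0.5))
})

test_that("buffered species stay constant over a run", {
  m <- builtin_model("schlogl")
  tr <- run_trajectory(m, seed = 2, t_end = 5, delta_s = 0.1)
  expect_equal(tr$B, rep(1L, nrow(tr)))
  expect_true(all(tr$A >= 0))
})

test_that("waiting times of a single first-order reaction are Exp(c*n)", {
  # A -> A with A buffered at n = 5, c = 2: constant propensity c*n = 10
  m <- ssa_model("exp", "A", list(reaction("A", "A", 2, buffered = "A")),
                 init = c(A = 5))
  compiled <- ssastream:::compile_model(m)
  task <- new_simulation_task(m, 0, base_seed = 42)
  ndraw <- 10000
  clocks <- numeric(ndraw)
  for (i in seq_len(ndraw)) {
    task <- ssa_step(task, m, t_end = 1e9, delta_s = 1e6,
                     compiled = compiled)$task
    clocks[i] <- task$clock
  }
  waits <- diff(c(0, clocks))
  rate <- 2 * 5
  se <- (1 / rate) / sqrt(ndraw)
  expect_lt(abs(mean(waits) - 1 / rate), 3 * se)
})

test_that("a Schlogl ensemble started at the unstable point splits between both basins", {
  m <- builtin_model("schlogl")
  fp <- schlogl_fixed_points()
  finals <- vapply(0:119, function(i)
    utils::tail(run_trajectory(m, seed = 100 + i, t_end = 8, delta_s = 0.5)$A, 1),
    numeric(1))
  low <- finals < fp$root[2]
  expect_gt(mean(low), 0)
  expect_lt(mean(low), 1)
  # each basin's occupants sit near its fixed point
  expect_equal(mean(finals[low]), fp$root[1], tolerance = 0.25)
  expect_equal(mean(finals[!low]), fp$root[3], tolerance = 0.25)
})

test_that("a long dark-condition trajectory oscillates with several mRNA peaks", {
  m <- builtin_model("neurospora", "dark")
  tr <- run_trajectory(m, seed = 7, t_end = 200, delta_s = 0.25)
  pk <- detect_peaks(tr$M, times = tr$time)
  expect_gt(length(pk), 3)
})
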