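make_chunk <- function(task_id, indices, values, species = "A") {
  structure(list(task_id = task_id, indices = as.integer(indices),
                 times = as.numeric(indices),
                 counts = matrix(as.integer(values), nrow = length(species),
                                 dimnames = list(species, NULL)),
                 species = species),
            class = "trajectory_chunk")
}

test_that("task generation produces n tasks with pairwise distinct streams", {
  m <- builtin_model("schlogl")
  tasks <- generate_tasks(m, 480, base_seed = 9)
  expect_length(tasks, 480)
  expect_equal(vapply(tasks, `[[`, integer(1), "task_id"), 0:479)
  states <- vapply(tasks, function(tk) paste(as.integer(tk$rng), collapse = ","),
                   character(1))
  expect_false(anyDuplicated(states) > 0)
  expect_length(generate_tasks(m, 0), 0)
})

test_that("scheduling picks the slowest task, breaking ties by id", {
  m <- ssa_model("still", "A", list(), init = c(A = 1))
  tasks <- generate_tasks(m, 3, base_seed = 1)
  tasks[[1]]$clock <- 3.0; tasks[[2]]$clock <- 1.0; tasks[[3]]$clock <- 2.0
  expect_equal(schedule_next(tasks)$task_id, 1L)
  tasks2 <- generate_tasks(m, 2, base_seed = 1)
  tasks2[[1]]$task_id <- 7L; tasks2[[2]]$task_id <- 2L
  tasks2[[1]]$clock <- 1.0; tasks2[[2]]$clock <- 1.0
  expect_equal(schedule_next(tasks2)$task_id, 2L)
  tasks[[1]]$done <- tasks[[2]]$done <- tasks[[3]]$done <- TRUE
  expect_error(schedule_next(tasks), "done")
})

test_that("alignment releases a cut only when all tasks delivered it, in order", {
  al <- new_aligner(2, "A")
  expect_length(al$offer(make_chunk(1, 0:1, c(5, 6))), 0)
  cuts <- al$offer(make_chunk(0, 0, 3))
  expect_length(cuts, 1)
  expect_equal(cuts[[1]]$index, 0)
  expect_equal(unname(cuts[[1]]$values[, "A"]), c(3L, 5L))
  cuts2 <- al$offer(make_chunk(0, 1, 4))
  expect_equal(cuts2[[1]]$index, 1)

  # n = 1 passes chunks straight through in order
  al1 <- new_aligner(1, "A")
  out <- al1$offer(make_chunk(0, 0:4, 10:14))
  expect_equal(vapply(out, `[[`, numeric(1), "index"), 0:4)

  # duplicates and gaps are detected
  al2 <- new_aligner(2, "A")
  al2$offer(make_chunk(0, 0, 1))
  expect_error(al2$offer(make_chunk(0, 0, 1)), "duplicate")
  expect_error(al2$offer(make_chunk(1, 1, 1)), "gap")
})

test_that("alignment conserves every sample across random interleavings", {
  n <- 3
  chunks <- list()
  for (tid in 0:(n - 1)) {
    splits <- list(0:2, 3:4, 5:9)
    for (s in splits)
      chunks[[length(chunks) + 1L]] <-
        make_chunk(tid, s, 100 * tid + s)
  }
  # out-of-order across tasks, in-order within each task
  by_task <- split(seq_along(chunks),
                   vapply(chunks, `[[`, numeric(1), "task_id"))
  interleaved <- unlist(Map(c, by_task[[2]], by_task[[3]], by_task[[1]]))
  cuts <- align(chunks[interleaved], n, species = "A")
  expect_length(cuts, 10)
  expect_equal(vapply(cuts, `[[`, numeric(1), "index"), 0:9)
  total_in <- sum(lengths(lapply(chunks, `[[`, "indices")))
  total_out <- sum(vapply(cuts, function(cut) nrow(cut$values), numeric(1)))
  expect_equal(total_out, total_in)
  for (cut in cuts)
    expect_equal(unname(cut$values[, "A"]),
                 as.integer(100 * (0:2) + cut$index))
})

test_that("sliding windows are centred, strided, and never partial", {
  cuts <- align(list(make_chunk(0, 0:6, 1:7)), 1, species = "A")
  w <- sliding_windows(cuts, width = 5, stride = 1)
  expect_equal(vapply(w, `[[`, numeric(1), "center_index"), c(2, 3, 4))
  expect_length(w[[1]]$cuts, 5)
  w2 <- sliding_windows(cuts, width = 5, stride = 5)
  expect_equal(vapply(w2, `[[`, numeric(1), "center_index"), 2)
  expect_length(sliding_windows(cuts[1:4], width = 5), 0)
  expect_error(new_windower(4), "width")
})

test_that("workflow outputs are invariant to worker count and quantum size", {
  m <- builtin_model("schlogl")
  base <- run_workflow(m, n_trajectories = 16, t_end = 2, delta_s = 0.1,
                       base_seed = 7, workers = 1,
                       clustering = list(method = "kmeans", species = "A",
                                         k = 2, every = 10))
  for (cfg in list(list(workers = 4), list(workers = 3, quantum = 0.3),
                   list(workers = 16, quantum = 2))) {
    alt <- run_workflow(m, n_trajectories = 16, t_end = 2, delta_s = 0.1,
                        base_seed = 7, workers = cfg$workers,
                        quantum = cfg$quantum %||% 1,
                        clustering = list(method = "kmeans", species = "A",
                                          k = 2, every = 10))
    expect_identical(alt$stats, base$stats)
    expect_identical(alt$clusters, base$clusters)
  }
  # and at file level: the stats CSV is byte-identical
  f1 <- tempfile(); f2 <- tempfile()
  write.csv(base$stats, f1, row.names = FALSE)
  alt <- run_workflow(m, n_trajectories = 16, t_end = 2, delta_s = 0.1,
                      base_seed = 7, workers = 4,
                      clustering = list(method = "kmeans", species = "A",
                                        k = 2, every = 10))
  write.csv(alt$stats, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a reaction-free model gives a constant mean and zero spread", {
  m <- ssa_model("still", "A", list(), init = c(A = 4))
  wf <- run_workflow(m, n_trajectories = 5, t_end = 1, delta_s = 0.25,
                     base_seed = 1)
  expect_equal(wf$stats$mean, rep(4, 5))
  expect_equal(wf$stats$sd, rep(0, 5))
  expect_equal(wf$stats$q50, rep(4, 5))
})

test_that("slowest-first scheduling keeps the incomplete-cut buffer within the lag bound", {
  m <- builtin_model("schlogl")
  wf <- run_workflow(m, n_trajectories = 12, t_end = 2, delta_s = 0.05,
                     quantum = 0.5, base_seed = 3)
  # max task lag under slowest-first is one quantum
  expect_lte(wf$aligner_peak_buffer, 0.5 / 0.05 + 1)
})

test_that("the workflow emits peak records for an oscillatory ensemble", {
  m <- builtin_model("neurospora", "dark")
  wf <- run_workflow(m, n_trajectories = 10, t_end = 150, delta_s = 0.25,
                     base_seed = 2, peaks = list(species = "M"))
  expect_gt(nrow(wf$peaks$peaks), 10)
  expect_true(all(wf$peaks$periods$period > 0))
  expect_equal(nrow(wf$peaks$ma), nrow(wf$peaks$periods))
})
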