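# Streamed ensemble workflow: task generation -> worker pool advancing tasks
# in simulation-time quanta under slowest-first scheduling -> alignment of
# per-task sample chunks into time-cuts -> summary statistics and sliding
# windows feeding the analysis operators. Execution is sequential but honours
# the scheduling contract, so outputs are identical for any worker count.

#' Generate an ensemble of simulation tasks
#'
#' @param model an [ssa_model].
#' @param n number of trajectories (>= 0).
#' @param base_seed ensemble base seed; task `i` uses stream seed
#'   `base_seed + i`.
#' @param t0 grid origin.
#' @return list of `ssa_task` objects with ids `0 ... n-1`.
#' @export
generate_tasks <- function(model, n, base_seed = 1, t0 = 0) {
  stopifnot(n >= 0)
  lapply(seq_len(n) - 1L,
         function(i) new_simulation_task(model, task_id = i,
                                         base_seed = base_seed, t0 = t0))
}

#' Pick the next task to advance (slowest first)
#'
#' Returns the unfinished task with the smallest simulation clock, ties
#' broken by lowest `task_id` — the scheduling rule that keeps trajectories
#' aligned and the transient buffer of incomplete time-cuts small.
#'
#' @param tasks list of `ssa_task` objects.
#' @return the selected task, with attribute `"index"` giving its position
#'   in `tasks`; errors if all tasks are done.
#' @export
schedule_next <- function(tasks) {
  idx <- schedule_next_index(tasks)
  if (is.na(idx)) stop("all simulation tasks are done")
  out <- tasks[[idx]]
  attr(out, "index") <- idx
  out
}

schedule_next_index <- function(tasks) {
  live <- which(!vapply(tasks, `[[`, logical(1), "done"))
  if (!length(live)) return(NA_integer_)
  clocks <- vapply(tasks[live], `[[`, numeric(1), "clock")
  ids <- vapply(tasks[live], `[[`, integer(1), "task_id")
  live[order(clocks, ids)[1]]
}

# ---- alignment of chunks into time-cuts -------------------------------------

#' Streaming alignment of trajectory chunks into time-cuts
#'
#' A time-cut at grid index `i` holds, for every observed species, one value
#' per trajectory, ordered by `task_id`. `new_aligner()` creates a stateful
#' aligner; `$offer(chunk)` ingests one chunk and returns the (possibly
#' empty) list of cuts completed by it, emitted in strictly increasing index
#' order: cut `i` is released exactly when all `n` tasks have delivered
#' sample `i`. Duplicate `(task, index)` deliveries and gaps in a task's
#' index sequence are errors. `$peak_buffer()` reports the maximum number of
#' incomplete cuts ever buffered (the memory-contract instrumentation).
#'
#' `align()` is the batch convenience wrapper: it pushes a list of chunks
#' through a fresh aligner and returns all cuts.
#'
#' @param n number of trajectories in the ensemble.
#' @param species character vector of species carried by the chunks.
#' @param t0,delta_s sampling grid.
#' @return for `new_aligner()`, an environment with functions `offer`,
#'   `peak_buffer`; for `align()`, a list of `time_cut` objects.
#' @export
new_aligner <- function(n, species, t0 = 0, delta_s = 1) {
  stopifnot(n >= 1)
  buf <- list()        # keyed by as.character(index): list(values, filled)
  next_emit <- 0L      # lowest not-yet-emitted index
  delivered <- integer(n)  # next expected sample index per task (gap check)
  peak <- 0L
  nsp <- length(species)

  offer <- function(chunk) {
    stopifnot(inherits(chunk, "trajectory_chunk"))
    tid <- chunk$task_id
    if (tid < 0 || tid >= n) stop("chunk task_id out of range")
    out <- list()
    for (k in seq_along(chunk$indices)) {
      i <- chunk$indices[k]
      if (i < delivered[tid + 1L])
        stop(sprintf("duplicate sample (task %d, index %d)", tid, i))
      if (i > delivered[tid + 1L])
        stop(sprintf("gap in task %d samples: expected index %d, got %d",
                     tid, delivered[tid + 1L], i))
      delivered[tid + 1L] <<- i + 1L
      key <- as.character(i)
      slot <- buf[[key]]
      if (is.null(slot))
        slot <- list(values = matrix(NA_integer_, n, nsp,
                                     dimnames = list(NULL, species)),
                     filled = 0L)
      slot$values[tid + 1L, ] <- chunk$counts[, k]
      slot$filled <- slot$filled + 1L
      buf[[key]] <<- slot
      peak <<- max(peak, length(buf))
      # release complete cuts in index order
      while (TRUE) {
        key0 <- as.character(next_emit)
        slot0 <- buf[[key0]]
        if (is.null(slot0) || slot0$filled < n) break
        out[[length(out) + 1L]] <-
          structure(list(index = next_emit,
                         time = t0 + next_emit * delta_s,
                         values = slot0$values),
                    class = "time_cut")
        buf[[key0]] <<- NULL
        next_emit <<- next_emit + 1L
      }
    }
    out
  }
  env <- new.env(parent = emptyenv())
  env$offer <- offer
  env$peak_buffer <- function() peak
  env
}

#' @rdname new_aligner
#' @param chunks list of `trajectory_chunk` objects (any interleaving).
#' @export
align <- function(chunks, n, species = NULL, t0 = 0, delta_s = 1) {
  if (is.null(species)) {
    if (!length(chunks)) stop("cannot infer species from an empty chunk list")
    species <- chunks[[1]]$species
  }
  al <- new_aligner(n, species, t0, delta_s)
  cuts <- list()
  for (ch in chunks) cuts <- c(cuts, al$offer(ch))
  cuts
}

# ---- sliding windows --------------------------------------------------------

#' Sliding windows over the stream of time-cuts
#'
#' Windows of `width` consecutive cuts, centred on grid indices advancing by
#' `stride`. The first window is emitted once `width` cuts are buffered
#' (centre `(width-1)/2`); trailing partial windows are never emitted.
#' `new_windower()` creates the stateful stream version
#' (`$offer(cut)` returns completed windows); `sliding_windows()` is the
#' batch wrapper.
#'
#' @param width window length \eqn{\Delta_W}: odd, >= 3.
#' @param stride centre advance per window (>= 1); 1 gives maximally
#'   overlapping windows.
#' @return for `new_windower()`, an environment with `offer`; for
#'   `sliding_windows()`, a list of `window_block` objects with fields
#'   `center_index`, `center_time`, `cuts`.
#' @export
new_windower <- function(width, stride = 1L) {
  stopifnot(width >= 3, width %% 2 == 1, stride >= 1)
  half <- (width - 1L) %/% 2L
  buf <- list()
  next_center <- half
  offer <- function(cut) {
    stopifnot(inherits(cut, "time_cut"))
    buf[[length(buf) + 1L]] <<- cut
    out <- list()
    repeat {
      if (!length(buf)) break
      first_idx <- buf[[1]]$index
      # window for next_center spans [next_center - half, next_center + half]
      if (buf[[length(buf)]]$index < next_center + half) break
      lo <- next_center - half - first_idx + 1L
      hi <- next_center + half - first_idx + 1L
      cuts <- buf[lo:hi]
      out[[length(out) + 1L]] <-
        structure(list(center_index = next_center,
                       center_time = cuts[[half + 1L]]$time,
                       cuts = cuts),
                  class = "window_block")
      next_center <<- next_center + as.integer(stride)
      drop <- next_center - half - first_idx
      if (drop > 0) buf <<- buf[-seq_len(min(drop, length(buf)))]
    }
    out
  }
  env <- new.env(parent = emptyenv())
  env$offer <- offer
  env
}

#' @rdname new_windower
#' @param cuts list of `time_cut` objects in index order.
#' @export
sliding_windows <- function(cuts, width, stride = 1L) {
  w <- new_windower(width, stride)
  out <- list()
  for (cut in cuts) out <- c(out, w$offer(cut))
  out
}

# per-trajectory matrix (width x n) for one species of a window block
window_matrix <- function(block, species) {
  vapply(block$cuts, function(cut) cut$values[, species],
         numeric(nrow(block$cuts[[1]]$values)))
}

# ---- the full workflow ------------------------------------------------------

#' Run the pipelined simulation-analysis workflow
#'
#' End-to-end composition: task generation, quantum-sliced advancement of the
#' ensemble under slowest-first scheduling over `workers` dispatch slots,
#' alignment into time-cuts, per-cut summary statistics, and (optionally)
#' sliding-window trajectory clustering and per-trajectory peak detection.
#' Outputs are identical for any `workers` and `quantum` setting at fixed
#' `base_seed`: parallel dispatch changes only the interleaving, never a
#' trajectory's private random stream.
#'
#' @param model an [ssa_model].
#' @param n_trajectories ensemble size.
#' @param t_end simulation horizon.
#' @param delta_s sampling step \eqn{\Delta_S}.
#' @param quantum simulation-time quantum per dispatch (default
#'   `10 * delta_s`).
#' @param workers dispatch slots; affects interleaving only.
#' @param base_seed ensemble seed.
#' @param levels quantile levels for the summary statistics.
#' @param window,stride sliding-window length (odd) and stride for
#'   clustering.
#' @param clustering `NULL`, or a list with elements `method` (`"kmeans"` or
#'   `"qt"`), `species`, and method parameters (`k` and optional `seed` for
#'   K-means; `threshold`, `min_size` for QT), plus optional `sg_window`,
#'   `sg_order` (Savitzky-Golay smoothing used to build the
#'   (filtered value, forecast) feature pairs) and either `every` (cluster
#'   every m-th emitted window; default 1) or `at` (numeric vector of window
#'   center times to cluster, matched within `delta_s / 2`).
#' @param peaks `NULL`, or a list with elements `species` and optional
#'   `sg_window`, `sg_order`, `min_height_frac`, `min_separation`,
#'   `transient` (discard peaks before this time), `ma_window` (moving-average
#'   window for the ensemble period series).
#' @param store_raw keep the full sampled ensemble in the result (off by
#'   default; the analysis itself is streaming).
#' @param observed species to sample (default the model's observed set).
#' @param t0 start time.
#' @return an object of class `ssa_workflow` with components `stats`
#'   (data frame: time, species, mean, sd, one column per quantile level),
#'   `clusters` (data frame of per-window assignments or `NULL`), `peaks`
#'   (list: `peaks` per-trajectory data frame, `periods`, `ma` ensemble
#'   moving average; or `NULL`), `raw` (named list of n-by-cuts matrices if
#'   `store_raw`), and `config`.
#' @examples
#' m <- builtin_model("schlogl")
#' wf <- run_workflow(m, n_trajectories = 8, t_end = 2, delta_s = 0.1,
#'                    base_seed = 7)
#' head(wf$stats)
#' @export
run_workflow <- function(model, n_trajectories, t_end, delta_s,
                         quantum = 10 * delta_s, workers = 1L, base_seed = 1,
                         levels = c(0.05, 0.25, 0.5, 0.75, 0.95),
                         window = 9L, stride = 1L,
                         clustering = NULL, peaks = NULL,
                         store_raw = FALSE, observed = model$observed,
                         t0 = 0) {
  stopifnot(n_trajectories >= 1, t_end > t0, delta_s > 0, quantum > 0,
            workers >= 1)
  compiled <- compile_model(model)
  n <- as.integer(n_trajectories)
  tasks <- generate_tasks(model, n, base_seed, t0)
  aligner <- new_aligner(n, compiled$species, t0, delta_s)
  ncuts <- floor((t_end - t0) / delta_s + 1e-9) + 1L

  want_cluster <- !is.null(clustering)
  if (want_cluster) {
    clustering$sg_window <- clustering$sg_window %||% min(window, 9L)
    clustering$sg_order <- clustering$sg_order %||% 3L
    clustering$every <- clustering$every %||% 1L
    windower <- new_windower(window, stride)
    cluster_rows <- list()
    wcount <- 0L
  }
  want_peaks <- !is.null(peaks)
  keep_species <- unique(c(if (want_peaks) peaks$species,
                           if (store_raw) observed))
  keep <- lapply(keep_species, function(s) matrix(NA_integer_, n, ncuts))
  names(keep) <- keep_species

  stats_rows <- vector("list", ncuts)

  process_cut <- function(cut) {
    rec <- summary_stats(cut, levels, species = observed)
    stats_rows[[cut$index + 1L]] <<- rec
    for (s in keep_species) keep[[s]][, cut$index + 1L] <<- cut$values[, s]
    if (want_cluster) {
      for (block in windower$offer(cut)) {
        wcount <<- wcount + 1L
        if (!is.null(clustering$at)) {
          if (!any(abs(clustering$at - block$center_time) < delta_s / 2)) next
        } else if ((wcount - 1L) %% clustering$every != 0L) next
        cluster_rows[[length(cluster_rows) + 1L]] <<-
          cluster_window(block, clustering, delta_s)
      }
    }
  }

  # worker pool: fill `workers` slots with the slowest pending tasks, advance
  # each by one quantum, feed resulting chunks to the aligner
  repeat {
    live <- which(!vapply(tasks, `[[`, logical(1), "done"))
    if (!length(live)) break
    clocks <- vapply(tasks[live], `[[`, numeric(1), "clock")
    ids <- vapply(tasks[live], `[[`, integer(1), "task_id")
    slots <- live[order(clocks, ids)][seq_len(min(workers, length(live)))]
    for (i in slots) {
      tk <- tasks[[i]]
      res <- advance_task(tk, compiled,
                          t_target = min(tk$clock + quantum, t_end),
                          t_end = t_end, delta_s = delta_s)
      tasks[[i]] <- res$task
      if (length(res$chunk$indices))
        for (cut in aligner$offer(res$chunk)) process_cut(cut)
    }
  }

  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL

  clusters <- if (want_cluster && length(cluster_rows))
    do.call(rbind, cluster_rows) else NULL

  peak_out <- NULL
  if (want_peaks) {
    p <- peaks
    series <- keep[[p$species]]
    times <- t0 + (seq_len(ncuts) - 1L) * delta_s
    per_traj <- lapply(seq_len(n), function(i) {
      pt <- detect_peaks(series[i, ], times = times,
                         sg_window = p$sg_window %||% 9L,
                         sg_order = p$sg_order %||% 3L,
                         min_height_frac = p$min_height_frac %||% 0.1,
                         min_separation = p$min_separation %||% 2L)
      pt[pt >= (p$transient %||% 0)]
    })
    periods <- peak_periods(per_traj, ma_window = p$ma_window %||% 25L)
    pk_df <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (!length(per_traj[[i]])) return(NULL)
      data.frame(trajectory = i - 1L, peak_time = per_traj[[i]])
    }))
    peak_out <- list(peaks = pk_df, periods = periods$local,
                     ma = periods$ma, species = p$species)
  }

  structure(list(stats = stats, clusters = clusters, peaks = peak_out,
                 raw = if (store_raw) keep[observed] else NULL,
                 aligner_peak_buffer = aligner$peak_buffer(),
                 config = list(model = model$name, n = n, t_end = t_end,
                               delta_s = delta_s, quantum = quantum,
                               workers = workers, base_seed = base_seed,
                               window = window, stride = stride,
                               levels = levels, t0 = t0,
                               observed = observed)),
            class = "ssa_workflow")
}

cluster_window <- function(block, cfg, delta_s) {
  mat <- window_matrix(block, cfg$species)  # n x width
  fp <- filter_and_forecast(mat, delta_s, cfg$sg_window, cfg$sg_order)
  pts <- cbind(fp$smoothed, fp$forecast)
  asg <- if (cfg$method == "kmeans")
    kmeans_cluster(pts, k = cfg$k, seed = cfg$seed %||% 1)
  else
    qt_cluster(pts, diameter_threshold = cfg$threshold,
               min_size = cfg$min_size %||% 1L)
  data.frame(time = block$center_time, method = cfg$method,
             species = cfg$species,
             trajectory = seq_len(nrow(pts)) - 1L,
             label = asg$labels,
             center = asg$centers[ifelse(is.na(asg$labels), NA, asg$labels), 1],
             size = asg$sizes[asg$labels])
}

#' @export
print.ssa_workflow <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ssa_workflow> %s: %d trajectories, t in [%g, %g], delta_s = %g\n",
              cfg$model, cfg$n, cfg$t0, cfg$t_end, cfg$delta_s))
  cat(sprintf("  stats: %d time-cuts x %d species\n",
              length(unique(x$stats$time)), length(unique(x$stats$species))))
  if (!is.null(x$clusters))
    cat(sprintf("  clusters: %d windows (%s)\n",
                length(unique(x$clusters$time)), x$clusters$method[1]))
  if (!is.null(x$peaks))
    cat(sprintf("  peaks: %d detected on species %s; mean local period %.3g\n",
                if (is.null(x$peaks$peaks)) 0L else nrow(x$peaks$peaks),
                x$peaks$species,
                mean(x$peaks$periods$period)))
  invisible(x)
}

#' Plot ensemble summary statistics
#'
#' Mean trajectory with a +/- one standard deviation band per species.
#'
#' @param x an `ssa_workflow` result.
#' @param species species to show (default: all observed).
#' @param ... passed to [matplot()].
#' @export
plot.ssa_workflow <- function(x, species = NULL, ...) {
  st <- x$stats
  sp <- species %||% unique(st$species)
  first <- TRUE
  cols <- seq_along(sp)
  for (i in seq_along(sp)) {
    d <- st[st$species == sp[i], ]
    if (first) {
      plot(d$time, d$mean, type = "n",
           ylim = range(c(d$mean - d$sd, d$mean + d$sd)),
           xlab = "time", ylab = "molecule count", ...)
      first <- FALSE
    }
    polygon(c(d$time, rev(d$time)), c(d$mean - d$sd, rev(d$mean + d$sd)),
            col = grDevices::adjustcolor(cols[i], alpha.f = 0.2), border = NA)
    lines(d$time, d$mean, col = cols[i])
  }
  legend("topright", legend = sp, lty = 1, col = cols, bty = "n")
  invisible(x)
}
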