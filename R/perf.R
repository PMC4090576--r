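# Analytic pipeline/farm performance model: service times per stream item.
# A pipeline's service time is its slowest stage; a farm of n equivalent
# workers divides its worker's service time by n. Worker counts are sized so
# every farm matches the slowest sequential stage.

#' Pipeline service time
#'
#' The service time (average interdeparture time of stream items) of a
#' pipeline is the maximum of its stages' service times: the bottleneck sets
#' the throughput.
#'
#' @param stages numeric vector of per-stage service times (seconds per
#'   stream item), optionally named.
#' @return the bottleneck service time.
#' @examples
#' pipeline_service_time(c(generation = 0, sim = 5.3, align = 0.11,
#'                         windows = 0.02, stat = 0.33))
#' @export
pipeline_service_time <- function(stages) {
  if (!length(stages)) stop("a pipeline needs at least one stage")
  stopifnot(is.numeric(stages), all(stages >= 0))
  max(stages)
}

#' Farm service time
#'
#' A farm replicating a worker with service time `Ts_worker` over `n`
#' on-demand workers has service time `Ts_worker / n`.
#'
#' @param Ts_worker worker service time (> 0).
#' @param n number of workers (>= 1).
#' @return the farm service time.
#' @export
farm_service_time <- function(Ts_worker, n) {
  stopifnot(Ts_worker > 0)
  if (any(n < 1)) stop("a farm needs at least one worker")
  Ts_worker / n
}

#' Optimal farm worker count
#'
#' Number of workers that makes a farm's service time match the slowest
#' sequential (non-farmed) stage: `round(Ts_worker / Ts_bottleneck)`, at
#' least 1. More workers would idle behind the bottleneck; fewer would make
#' the farm the bottleneck.
#'
#' @param Ts_worker service time of the farmed worker (> 0).
#' @param Ts_bottleneck service time of the slowest sequential stage (> 0).
#' @return integer worker count.
#' @examples
#' optimal_workers(5.3, 0.11)   # 48 simulation engines
#' optimal_workers(0.33, 0.11)  # 3 statistic engines
#' @export
optimal_workers <- function(Ts_worker, Ts_bottleneck) {
  stopifnot(Ts_worker > 0, Ts_bottleneck > 0)
  max(1L, as.integer(round(Ts_worker / Ts_bottleneck)))
}

#' Speedup upper bound of the pipelined workflow
#'
#' Total sequential execution time per stream item divided by the slowest
#' stage service time — the best possible speedup once every farm is sized
#' to the bottleneck, combining pipeline and farm contributions.
#'
#' @param T_total total sequential time per item (> 0).
#' @param Ts_bottleneck slowest stage service time (> 0).
#' @param round report rounded to the nearest integer (default), or raw.
#' @return the speedup bound.
#' @examples
#' speedup_bound(5.8, 0.11)  # 53
#' @export
speedup_bound <- function(T_total, Ts_bottleneck, round = TRUE) {
  stopifnot(T_total > 0, Ts_bottleneck > 0)
  s <- T_total / Ts_bottleneck
  if (round) as.integer(base::round(s)) else s
}

#' Total node count of the deployed workflow
#'
#' Simulation engines plus statistic engines plus the 3 fixed pipeline nodes
#' (task generation, trajectory alignment, window generation) plus the 4
#' runtime support nodes (two dispatch-gather pairs).
#'
#' @param n_sim simulation engines (>= 1).
#' @param n_stat statistic engines (>= 1).
#' @return integer node count.
#' @examples
#' node_count(20, 3)  # 30
#' @export
node_count <- function(n_sim, n_stat) {
  stopifnot(n_sim >= 1, n_stat >= 1)
  as.integer(n_sim + n_stat + 3L + 4L)
}

#' Size the farms of a simulation-analysis pipeline from stage timings
#'
#' Convenience wrapper: given the measured sequential per-item service times
#' of the pipeline stages, returns the bottleneck among the non-farmed
#' stages, the recommended worker counts for the simulation and statistics
#' farms, and the overall speedup bound.
#'
#' @param Ts_sim simulation-engine service time.
#' @param Ts_stat statistic-engine service time.
#' @param Ts_other service times of the non-farmed stages (e.g. generation,
#'   alignment, window generation).
#' @param T_total total sequential time per item (default: sum of all
#'   stages).
#' @return list with `bottleneck`, `sim_workers`, `stat_workers`,
#'   `speedup_bound`, `nodes`.
#' @examples
#' size_pipeline(Ts_sim = 5.3, Ts_stat = 0.33,
#'               Ts_other = c(generation = 0, alignment = 0.11,
#'                            windows = 0.02))
#' @export
size_pipeline <- function(Ts_sim, Ts_stat, Ts_other, T_total = NULL) {
  bottleneck <- pipeline_service_time(Ts_other)
  T_total <- T_total %||% (Ts_sim + Ts_stat + sum(Ts_other))
  sim_workers <- optimal_workers(Ts_sim, bottleneck)
  stat_workers <- optimal_workers(Ts_stat, bottleneck)
  list(bottleneck = bottleneck,
       sim_workers = sim_workers,
       stat_workers = stat_workers,
       speedup_bound = speedup_bound(T_total, bottleneck),
       nodes = node_count(sim_workers, stat_workers))
}
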