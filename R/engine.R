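# Exact stochastic simulation: Gillespie direct method with combinatorial
# mass-action propensities, function rates, and exact handling of
# piecewise-constant time dependence (advance to the boundary without firing,
# then redraw -- exact by memorylessness).

#' Create a simulation task
#'
#' A task carries one trajectory's evolving state: molecule counts, the
#' simulation clock, a private deterministic RNG stream (seeded
#' `base_seed + task_id`), and a cursor on the sampling grid
#' \eqn{t_i = t_0 + i \Delta_S}. Tasks are value objects: advancing a task
#' returns an updated copy, so a run can be replayed or resliced freely.
#'
#' @param model an [ssa_model].
#' @param task_id integer id, also the RNG stream offset.
#' @param base_seed ensemble base seed.
#' @param t0 grid origin (default 0).
#' @return an object of class `ssa_task`.
#' @export
new_simulation_task <- function(model, task_id = 0L, base_seed = 1, t0 = 0) {
  stopifnot(inherits(model, "ssa_model"), task_id >= 0, base_seed >= 0)
  structure(list(task_id = as.integer(task_id),
                 counts = model$init,
                 clock = t0, t0 = t0,
                 rng = ssa_rng_state_cpp(base_seed + task_id),
                 next_sample_index = 0L,
                 done = FALSE),
            class = "ssa_task")
}

#' Propensity of a reaction in a given state
#'
#' Mass-action laws use the combinatorial convention: the propensity is the
#' kinetic constant times the number of distinct reactant tuples,
#' \eqn{c \prod_s \binom{n_s}{m_s}} (so `n*(n-1)/2` for a pair, zero whenever
#' any count is below its multiplicity). Function rates evaluate to the
#' propensity directly.
#'
#' @param rx an [reaction()] object.
#' @param counts named vector of molecule counts.
#' @param t simulation time (only used by time-dependent rate laws).
#' @return a non-negative number.
#' @examples
#' propensity(reaction(c(A = 2), c(A = 3), 0.03), c(A = 4))  # 0.03 * choose(4,2)
#' @export
propensity <- function(rx, counts, t = 0) {
  stopifnot(inherits(rx, "ssa_reaction"))
  if (rx$rate$type == "mass_action") {
    m <- rx$reactants
    if (length(m) == 0) return(rx$rate$c)
    return(rx$rate$c * prod(choose(counts[names(m)], m)))
  }
  eval_rate_law(rx$rate, counts, t)
}

advance_task <- function(task, compiled, t_target, t_end, delta_s,
                         max_events = -1L) {
  res <- ssa_advance_cpp(task$counts, task$clock, task$rng,
                         compiled$react, compiled$net, compiled$type,
                         compiled$par, compiled$spi, compiled$funs,
                         compiled$species, compiled$Tb,
                         task$t0, delta_s, task$next_sample_index,
                         t_target, t_end, as.integer(max_events))
  first <- res$first_index
  k <- ncol(res$samples)
  chunk <- structure(list(task_id = task$task_id,
                          indices = if (k) seq(first, length.out = k) else integer(0),
                          times = if (k) task$t0 + seq(first, length.out = k) * delta_s
                                  else numeric(0),
                          counts = res$samples,
                          species = compiled$species),
                     class = "trajectory_chunk")
  task$counts <- setNames(res$counts, names(task$counts))
  task$clock <- res$clock
  task$rng <- res$rng
  task$next_sample_index <- res$next_sample_index
  task$done <- res$done
  list(task = task, chunk = chunk)
}

#' Advance a task by one Gillespie step
#'
#' One step is one of: a reaction firing (exponential waiting time from the
#' total propensity, reaction chosen proportionally to its propensity), an
#' advance to the next piecewise-rate boundary without firing, or — if all
#' propensities are zero — a jump to the next boundary or to `t_end`
#' (marking the task done).
#'
#' @param task an `ssa_task`.
#' @param model the model it runs.
#' @param t_end simulation horizon.
#' @param delta_s sampling step \eqn{\Delta_S} (> 0).
#' @param compiled optional pre-compiled model (internal reuse).
#' @return list with elements `task` (updated) and `chunk` (samples emitted
#'   by this step, possibly empty).
#' @export
ssa_step <- function(task, model, t_end, delta_s,
                     compiled = compile_model(model)) {
  stopifnot(inherits(task, "ssa_task"), !task$done)
  advance_task(task, compiled, t_target = t_end, t_end = t_end,
               delta_s = delta_s, max_events = 1L)
}

#' Advance a task to a target simulation time
#'
#' Applies Gillespie steps until the clock reaches `t_target` (the clock may
#' overshoot by at most one event) or the task finishes, and emits every
#' pending grid sample \eqn{t_i \le} clock. Samples take the value of the
#' state at the largest event time \eqn{\le t_i} (right-continuous step
#' sampling), so results are identical however the run is sliced into quanta.
#'
#' @inheritParams ssa_step
#' @param t_target time to advance to (> current clock).
#' @return list with elements `task` and `chunk`.
#' @export
advance_to <- function(task, model, t_target, t_end, delta_s,
                       compiled = compile_model(model)) {
  stopifnot(inherits(task, "ssa_task"))
  if (!task$done && t_target <= task$clock)
    stop("t_target must exceed the task clock")
  advance_task(task, compiled, t_target = min(t_target, t_end),
               t_end = t_end, delta_s = delta_s, max_events = -1L)
}

#' Run one full trajectory
#'
#' Convenience wrapper over [advance_to()]: simulates from `t0` to `t_end`
#' and returns the sampled series on the grid `t0 + i * delta_s`,
#' `i = 0, ..., floor((t_end - t0)/delta_s)`. Bit-reproducible for a fixed
#' seed.
#'
#' @param model an [ssa_model].
#' @param seed RNG seed of this trajectory's stream.
#' @param t_end simulation horizon (> `t0`).
#' @param delta_s sampling step.
#' @param t0 start time.
#' @return a `data.frame` with a `time` column and one column per species.
#' @examples
#' m <- builtin_model("schlogl")
#' tr <- run_trajectory(m, seed = 1, t_end = 2, delta_s = 0.1)
#' head(tr)
#' @export
run_trajectory <- function(model, seed, t_end, delta_s, t0 = 0) {
  stopifnot(t_end > t0)
  task <- new_simulation_task(model, task_id = 0L, base_seed = seed, t0 = t0)
  compiled <- compile_model(model)
  res <- advance_task(task, compiled, t_target = t_end, t_end = t_end,
                      delta_s = delta_s, max_events = -1L)
  chunk <- res$chunk
  out <- data.frame(time = chunk$times)
  for (s in seq_along(chunk$species))
    out[[chunk$species[s]]] <- chunk$counts[s, ]
  attr(out, "seed") <- seed
  class(out) <- c("ssa_trajectory", class(out))
  out
}

#' Simulate trajectories from a model
#'
#' [stats::simulate()] method: runs `nsim` independent trajectories with
#' per-trajectory seeds `seed + 0, ..., seed + nsim - 1`.
#'
#' @param object an [ssa_model].
#' @param nsim number of trajectories.
#' @param seed base seed (required for reproducibility; default 1).
#' @param t_end,delta_s,t0 as in [run_trajectory()].
#' @param ... unused.
#' @return a list of trajectory data frames.
#' @importFrom stats simulate
#' @export
simulate.ssa_model <- function(object, nsim = 1, seed = 1, t_end, delta_s,
                               t0 = 0, ...) {
  lapply(seq_len(nsim) - 1L,
         function(i) run_trajectory(object, seed = seed + i, t_end = t_end,
                                    delta_s = delta_s, t0 = t0))
}

#' @export
plot.ssa_trajectory <- function(x, species = NULL, ...) {
  sp <- species %||% setdiff(names(x), "time")
  matplot(x$time, as.matrix(x[sp]), type = "s", lty = 1,
          xlab = "time", ylab = "molecule count", ...)
  legend("topright", legend = sp, lty = 1, col = seq_along(sp), bty = "n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
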