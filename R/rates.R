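#' Piecewise light/dark schedules for time-varying rate parameters
#'
#' A schedule describes a rate parameter that alternates between two values
#' with a fixed phase length, emulating external forcing such as dark/light
#' alternation: the value is `low_value` on \eqn{[2nT, (2n+1)T)} and
#' `high_value` on \eqn{[(2n+1)T, (2n+2)T)}, so the full forcing period is
#' \eqn{2T}. A constant schedule always evaluates to its single value.
#'
#' @param low_value value taken on the first (e.g. dark) phase; must be >= 0.
#' @param high_value value taken on the second (e.g. light) phase; must be >= 0.
#' @param phase_length phase length \eqn{T} (> 0), in model time units
#'   (hours for the circadian model).
#' @return an object of class `pw_schedule`.
#' @examples
#' sch <- piecewise_schedule(160, 200, phase_length = 12)
#' eval_schedule(sch, 5)   # dark phase -> 160
#' eval_schedule(sch, 13)  # light phase -> 200
#' @seealso [eval_schedule()], [builtin_model()]
#' @export
piecewise_schedule <- function(low_value, high_value, phase_length) {
  stopifnot(is.numeric(low_value), low_value >= 0,
            is.numeric(high_value), high_value >= 0,
            is.numeric(phase_length), phase_length > 0)
  structure(list(low_value = low_value, high_value = high_value,
                 phase_length = phase_length),
            class = "pw_schedule")
}

#' @rdname piecewise_schedule
#' @param value the constant value (>= 0).
#' @export
constant_schedule <- function(value) {
  stopifnot(is.numeric(value), value >= 0)
  structure(list(low_value = value, high_value = value, phase_length = 0),
            class = "pw_schedule")
}

#' Evaluate a piecewise schedule at a time point
#'
#' @param schedule a [piecewise_schedule()] or [constant_schedule()].
#' @param t time (>= 0); may be a vector.
#' @return the schedule value(s) at `t`.
#' @export
eval_schedule <- function(schedule, t) {
  stopifnot(inherits(schedule, "pw_schedule"), is.numeric(t))
  if (any(t < 0)) stop("schedule evaluation requires t >= 0")
  if (schedule$phase_length <= 0) return(rep(schedule$low_value, length(t)))
  pos <- t %% (2 * schedule$phase_length)
  ifelse(pos < schedule$phase_length, schedule$low_value, schedule$high_value)
}

#' Hill-type repression rate
#'
#' Propensity of a transcription-like process repressed by `repressor_count`
#' molecules of its product: \eqn{v_s K_I^n / (c^n + K_I^n)}. At zero
#' repressor the rate equals `v_s`; at `repressor_count == K_I` it is halved;
#' it decreases monotonically with the repressor count. `n` is the Hill
#' coefficient (degree of cooperativity), `K_I` the repression threshold in
#' molecule counts.
#'
#' @param repressor_count non-negative molecule count (vectorised).
#' @param v_s maximal rate (> 0).
#' @param K_I repression threshold (> 0), molecule counts.
#' @param n Hill coefficient, integer >= 1.
#' @return the rate, same length as `repressor_count`.
#' @examples
#' hill_repression_rate(100, v_s = 160, K_I = 100, n = 4)  # half-repression: 80
#' @export
hill_repression_rate <- function(repressor_count, v_s, K_I, n) {
  stopifnot(all(repressor_count >= 0), v_s > 0, K_I > 0, n >= 1)
  v_s * K_I^n / (repressor_count^n + K_I^n)
}

#' Michaelis-Menten rate
#'
#' Saturating degradation-type rate \eqn{v_{max} c / (K + c)}: zero at zero
#' count, half-maximal at `count == K`, approaching `v_max` as the count
#' grows.
#'
#' @param count non-negative molecule count (vectorised).
#' @param v_max maximal rate (> 0).
#' @param K Michaelis constant (> 0), molecule counts.
#' @return the rate, same length as `count`.
#' @examples
#' michaelis_rate(50, v_max = 50.5, K = 50)  # half-saturation: 25.25
#' @export
michaelis_rate <- function(count, v_max, K) {
  stopifnot(all(count >= 0), v_max > 0, K > 0)
  v_max * count / (K + count)
}

# ---- rate-law constructors ---------------------------------------------------

#' Rate laws for reactions
#'
#' A reaction's rate law is either classical mass action with a kinetic
#' constant `c` (the propensity is `c` times the number of distinct reactant
#' tuples, i.e. the product of binomial coefficients `choose(n_s, m_s)` over
#' reactant species), or a rate *function* whose value, evaluated on the
#' current state and time, **is** the propensity directly (no additional
#' multiplicity factor). The latter convention is what makes the circadian
#' model's published parameter set coincide with its mean-field ODE after
#' scaling concentrations to molecule counts.
#'
#' Three function-rate forms are recognised natively by the compiled
#' simulator core (and are therefore fast): Hill repression driven by a
#' (possibly time-varying) maximal rate, Michaelis-Menten, and any of these
#' with a [piecewise_schedule()]. Arbitrary R functions `f(counts, t)` are
#' also accepted via `rate_function()` and evaluated by callback (slower).
#'
#' @param c non-negative mass-action kinetic constant.
#' @return an object of class `rate_law`.
#' @examples
#' rate_mass_action(0.03)
#' rate_hill_repression("FRQin", constant_schedule(160), K_I = 100, n = 4)
#' rate_michaelis("M", v_max = 50.5, K = 50)
#' rate_function(function(counts, t) 2.5 * counts[["A"]] / (1 + t))
#' @name rate_law
#' @export
rate_mass_action <- function(c) {
  stopifnot(is.numeric(c), length(c) == 1)
  if (is.na(c) || c < 0) stop("mass-action constant must be non-negative")
  structure(list(type = "mass_action", c = c), class = "rate_law")
}

#' @rdname rate_law
#' @param species name of the species whose count drives the function rate.
#' @param schedule a [piecewise_schedule()] or [constant_schedule()] giving
#'   the maximal rate \eqn{v_s(t)}.
#' @param K_I,n Hill repression threshold and coefficient.
#' @export
rate_hill_repression <- function(species, schedule, K_I, n) {
  stopifnot(is.character(species), length(species) == 1,
            inherits(schedule, "pw_schedule"), K_I > 0, n >= 1)
  structure(list(type = "hill", species = species, schedule = schedule,
                 K_I = K_I, n = n), class = "rate_law")
}

#' @rdname rate_law
#' @param v_max,K Michaelis-Menten maximal rate and constant.
#' @export
rate_michaelis <- function(species, v_max, K) {
  stopifnot(is.character(species), length(species) == 1, v_max > 0, K > 0)
  structure(list(type = "michaelis", species = species, v_max = v_max, K = K),
            class = "rate_law")
}

#' @rdname rate_law
#' @param f a function `(counts, t) -> rate` where `counts` is a named
#'   numeric vector of molecule counts; must return a finite non-negative
#'   scalar.
#' @export
rate_function <- function(f) {
  stopifnot(is.function(f))
  structure(list(type = "rfun", f = f), class = "rate_law")
}

#' @export
print.rate_law <- function(x, ...) {
  switch(x$type,
    mass_action = cat(sprintf("mass_action(%g)\n", x$c)),
    hill = cat(sprintf("hill_repression(%s; v_s=%g%s, K_I=%g, n=%d)\n",
                       x$species, x$schedule$low_value,
                       if (x$schedule$phase_length > 0)
                         sprintf("/%g T=%g", x$schedule$high_value,
                                 x$schedule$phase_length) else "",
                       x$K_I, as.integer(x$n))),
    michaelis = cat(sprintf("michaelis(%s; v_max=%g, K=%g)\n",
                            x$species, x$v_max, x$K)),
    rfun = cat("rate_function(<R function>)\n"))
  invisible(x)
}

# evaluate a rate law in R (reference path; the compiled core mirrors this)
eval_rate_law <- function(rate, counts, t) {
  switch(rate$type,
    mass_action = stop("mass-action laws are evaluated via propensity()"),
    hill = hill_repression_rate(counts[[rate$species]],
                                eval_schedule(rate$schedule, t),
                                rate$K_I, rate$n),
    michaelis = michaelis_rate(counts[[rate$species]], rate$v_max, rate$K),
    rfun = {
      a <- rate$f(counts, t)
      if (!is.finite(a) || a < 0)
        stop("rate function returned a negative or non-finite value")
      a
    })
}
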