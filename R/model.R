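# Reaction-system representation: flat chemical notation, mass-action or
# function rates, optional buffered species whose counts never change.

as_multiset <- function(x, what = "species") {
  if (is.null(x) || length(x) == 0) return(integer(0))
  if (is.character(x)) {
    tab <- table(x)
    out <- as.integer(tab)
    names(out) <- names(tab)
    return(out)
  }
  if (is.numeric(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(what, " multiset given as numbers must be named")
    if (any(x != round(x)) || any(x < 1))
      stop(what, " multiplicities must be integers >= 1")
    return(setNames(as.integer(x), names(x)))
  }
  stop("cannot interpret ", what, " specification")
}

#' Define a reaction
#'
#' Reactants and products are multisets of species, given either as character
#' vectors with repetition (`c("A", "A")`) or as named counts (`c(A = 2)`).
#' Species listed in `buffered` take part in the kinetics but their counts
#' are never changed by firing (e.g. a chemostatted feed species).
#'
#' @param reactants,products species multisets; either may be empty
#'   (creation/degradation).
#' @param rate a [rate_law] object, or a single non-negative number which is
#'   taken as a mass-action constant.
#' @param buffered character vector of species held constant by this reaction.
#' @return an object of class `ssa_reaction`.
#' @examples
#' reaction(c(A = 2), c(A = 3), 0.03)                  # A + A -> 3 A
#' reaction("B", c("B", "A"), 200, buffered = "B")     # buffered feed
#' @export
reaction <- function(reactants, products, rate, buffered = character()) {
  if (is.numeric(rate) && !inherits(rate, "rate_law")) rate <- rate_mass_action(rate)
  stopifnot(inherits(rate, "rate_law"), is.character(buffered))
  structure(list(reactants = as_multiset(reactants, "reactant"),
                 products = as_multiset(products, "product"),
                 rate = rate, buffered = buffered),
            class = "ssa_reaction")
}

#' @export
print.ssa_reaction <- function(x, ...) {
  fmt <- function(ms) {
    if (length(ms) == 0) return("0")
    paste(ifelse(ms > 1, paste0(ms, "*", names(ms)), names(ms)), collapse = " + ")
  }
  cat(fmt(x$reactants), "->", fmt(x$products), "@ ")
  print(x$rate)
  invisible(x)
}

#' Construct a reaction-system model
#'
#' @param name model name (free text).
#' @param species character vector of species names (fixed for a run).
#' @param reactions list of [reaction()] objects.
#' @param init named vector of non-negative integer initial counts; species
#'   not named start at 0.
#' @param observed species to sample along trajectories (default: all).
#' @param phase_length optional phase length of external piecewise forcing,
#'   used to place exact rate-change boundaries during simulation; inferred
#'   automatically from scheduled rate laws, only needed for custom
#'   time-dependent [rate_function()]s.
#' @return a validated object of class `ssa_model`.
#' @seealso [builtin_model()], [validate_model()], [run_trajectory()]
#' @export
ssa_model <- function(name, species, reactions, init, observed = species,
                      phase_length = NULL) {
  stopifnot(is.character(species), length(species) >= 1,
            is.list(reactions))
  init_full <- setNames(rep(0L, length(species)), species)
  if (!missing(init) && length(init)) {
    if (is.null(names(init))) stop("init must be a named vector")
    init_full[names(init)] <- as.integer(init)
  }
  model <- structure(list(name = name, species = species,
                          reactions = reactions, init = init_full,
                          observed = observed,
                          phase_length = phase_length),
                     class = "ssa_model")
  validate_model(model)
}

#' Validate a model
#'
#' Checks that every species referenced by a reaction (reactants, products,
#' buffered set, function-rate drivers) is declared, that multiplicities are
#' positive integers, that mass-action constants are non-negative, and that
#' initial counts are non-negative integers. Returns the model unchanged.
#'
#' @param model an `ssa_model`.
#' @return the model, invisibly checked.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "ssa_model"))
  sp <- model$species
  if (anyDuplicated(sp)) stop("duplicated species name")
  if (any(model$init < 0)) stop("negative initial count")
  if (!all(model$observed %in% sp))
    stop("observed species not declared: ",
         paste(setdiff(model$observed, sp), collapse = ", "))
  for (i in seq_along(model$reactions)) {
    rx <- model$reactions[[i]]
    if (!inherits(rx, "ssa_reaction")) stop("reactions must be built with reaction()")
    refs <- c(names(rx$reactants), names(rx$products), rx$buffered)
    if (rx$rate$type %in% c("hill", "michaelis")) refs <- c(refs, rx$rate$species)
    bad <- setdiff(refs, sp)
    if (length(bad))
      stop(sprintf("reaction %d references undeclared species: %s",
                   i, paste(unique(bad), collapse = ", ")))
    if (rx$rate$type == "mass_action" && rx$rate$c < 0)
      stop(sprintf("reaction %d has a negative rate constant", i))
  }
  model
}

#' @export
print.ssa_model <- function(x, ...) {
  cat(sprintf("<ssa_model> %s: %d species, %d reactions\n",
              x$name, length(x$species), length(x$reactions)))
  cat("  species: ", paste(x$species, collapse = " "), "\n")
  nz <- x$init[x$init > 0]
  cat("  init:    ",
      if (length(nz)) paste(names(nz), nz, sep = "=", collapse = " ") else "(all 0)",
      "\n")
  for (rx in x$reactions) { cat("  "); print(rx) }
  invisible(x)
}

#' Built-in models
#'
#' Three classic stochastic systems used throughout the package:
#'
#' * `"schlogl"` — the Schlogl bistable network: `A + A -> 3 A` (c = 0.03),
#'   `3 A -> A + A` (c = 0.0001), `B -> B + A` (c = 200, B buffered),
#'   `A -> 0` (c = 3.5); initial `A = 250`, `B = 1`. Starting near the
#'   unstable fixed point, trajectories split between two stable states
#'   (around 86 and 567 molecules of A) under intrinsic noise.
#' * `"lambda_phage"` — a simplified lysis/lysogeny switch for phage lambda:
#'   repressor CI dimerises, CI2 binds the phage DNA at an enhancing site
#'   (`DpCI2`), a repressing site (`DmCI2`), or both (`DpmCI2`); RNA
#'   polymerase P transcribes from `DpCI2`, producing two CI monomers per
#'   transcript; CI is slowly degraded. Constants 0.05, 0.5, 0.026 (x4),
#'   0.13 (x2), 40, 0.0007; initial `CI = 10, D = 1, P = 1`. Total DNA and
#'   polymerase are conserved.
#' * `"neurospora"` — circadian oscillations of the fungal frq gene:
#'   transcription of mRNA M with Hill repression by nuclear protein FRQin,
#'   translation to cytosolic FRQ, Michaelis-Menten degradation of M and
#'   FRQ, and nuclear transport both ways. Parameters (counts scaled at
#'   1 nM = 100 molecules): `v_m = 50.5`, `v_d = 140`, `k_s = 0.5`,
#'   `k_1 = 0.5`, `k_2 = 0.6`, `K_m = 50`, `K_I = 100`, `K_d = 13`, `n = 4`.
#'   In constant dark `v_s = 160`; under dark/light alternation `v_s`
#'   switches 160/200 with phase length `T_phase` (default 12 h, a 24 h
#'   forcing period). Time unit: hours.
#'
#' @param name one of `"schlogl"`, `"lambda_phage"`, `"neurospora"`.
#' @param condition for `"neurospora"`: `"dark"` (constant `v_s = 160`) or
#'   `"alternate"` (160/200 piecewise schedule).
#' @param T_phase for `"neurospora"` under `"alternate"`: phase length in
#'   hours.
#' @return an `ssa_model`.
#' @examples
#' builtin_model("schlogl")
#' builtin_model("neurospora", condition = "alternate", T_phase = 12)
#' @export
builtin_model <- function(name, condition = c("dark", "alternate"),
                          T_phase = 12) {
  switch(match.arg(name, c("schlogl", "lambda_phage", "neurospora")),
    schlogl = ssa_model(
      "schlogl", species = c("A", "B"),
      reactions = list(
        reaction(c(A = 2), c(A = 3), 0.03),
        reaction(c(A = 3), c(A = 2), 0.0001),
        reaction("B", c("B", "A"), 200, buffered = "B"),
        reaction("A", character(), 3.5)),
      init = c(A = 250, B = 1), observed = "A"),
    lambda_phage = ssa_model(
      "lambda_phage",
      species = c("CI", "CI2", "D", "DpCI2", "DmCI2", "DpmCI2", "P"),
      reactions = list(
        reaction(c(CI = 2), "CI2", 0.05),
        reaction("CI2", c(CI = 2), 0.5),
        reaction(c("CI2", "D"), "DpCI2", 0.026),
        reaction("DpCI2", c("CI2", "D"), 0.026),
        reaction(c("CI2", "D"), "DmCI2", 0.026),
        reaction("DmCI2", c("CI2", "D"), 0.026),
        reaction(c("DpCI2", "CI2"), "DpmCI2", 0.13),
        reaction("DpmCI2", c("DpCI2", "CI2"), 0.13),
        # transcription: two CI monomers per transcript, template and
        # polymerase unchanged
        reaction(c("DpCI2", "P"), c("DpCI2", "P", "CI", "CI"), 40),
        reaction("CI", character(), 0.0007)),
      init = c(CI = 10, D = 1, P = 1), observed = "CI"),
    neurospora = {
      condition <- match.arg(condition)
      vs <- if (condition == "dark") constant_schedule(160)
            else piecewise_schedule(160, 200, T_phase)
      ssa_model(
        "neurospora", species = c("M", "FRQ", "FRQin"),
        reactions = list(
          # frq transcription, repressed by nuclear FRQ
          reaction("FRQin", c("FRQin", "M"),
                   rate_hill_repression("FRQin", vs, K_I = 100, n = 4)),
          reaction("M", c("M", "FRQ"), 0.5),                   # translation k_s
          reaction("M", character(), rate_michaelis("M", 50.5, 50)),     # f_M
          reaction("FRQ", character(), rate_michaelis("FRQ", 140, 13)),  # f_d
          reaction("FRQ", "FRQin", 0.5),                       # k_1 import
          reaction("FRQin", "FRQ", 0.6)),                      # k_2 export
        init = c(M = 360, FRQ = 100, FRQin = 100),
        observed = c("M", "FRQ", "FRQin"))
    })
}

# ---- compilation for the C++ core -------------------------------------------

# Lower a model to the flat numeric encoding the compiled stepper consumes.
compile_model <- function(model) {
  validate_model(model)
  sp <- model$species
  nsp <- length(sp)
  nrx <- length(model$reactions)
  react <- matrix(0L, nsp, nrx, dimnames = list(sp, NULL))
  net <- matrix(0L, nsp, nrx, dimnames = list(sp, NULL))
  type <- integer(nrx)
  par <- matrix(0, 5, nrx)
  spi <- integer(nrx)
  funs <- vector("list", max(nrx, 1))
  Tb <- if (is.null(model$phase_length)) 0 else model$phase_length
  for (j in seq_len(nrx)) {
    rx <- model$reactions[[j]]
    react[names(rx$reactants), j] <- rx$reactants
    net[names(rx$reactants), j] <- net[names(rx$reactants), j] - rx$reactants
    net[names(rx$products), j] <- net[names(rx$products), j] + rx$products
    net[rx$buffered, j] <- 0L
    r <- rx$rate
    spi[j] <- -1L
    switch(r$type,
      mass_action = { type[j] <- 0L; par[1, j] <- r$c },
      hill = {
        type[j] <- 1L
        par[1, j] <- r$schedule$low_value
        par[2, j] <- r$schedule$high_value
        par[3, j] <- r$schedule$phase_length
        par[4, j] <- r$K_I
        par[5, j] <- r$n
        spi[j] <- match(r$species, sp) - 1L
        if (r$schedule$phase_length > 0)
          Tb <- if (Tb > 0) min(Tb, r$schedule$phase_length) else
            r$schedule$phase_length
      },
      michaelis = {
        type[j] <- 2L
        par[1, j] <- r$v_max
        par[2, j] <- r$K
        spi[j] <- match(r$species, sp) - 1L
      },
      rfun = { type[j] <- 3L; funs[[j]] <- r$f })
  }
  list(react = react, net = net, type = type, par = par, spi = spi,
       funs = funs, species = sp, Tb = Tb)
}
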