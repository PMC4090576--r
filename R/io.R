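# Plain-text model files and tabular trajectory stores.
#
# Model format, one rule per line, '#' comments, ASCII:
#   init: A=250 B=1
#   buffered: B
#   A A -> A A A @ mass_action(0.03)
#   2*A -> 3*A @ mass_action(0.03)        (equivalent)
#   FRQin -> FRQin M @ function(f_FRQ)
# Species are whitespace-separated names with optional integer
# multiplicities (`2*A`); an empty side denotes creation/degradation.
# Function names are resolved from a registry supplied by the caller
# (rate_law objects or plain R functions (counts, t) -> rate).

parse_side <- function(txt, line_no) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(character(0))
  toks <- strsplit(txt, "[[:space:]]+")[[1]]
  out <- character(0)
  for (tok in toks) {
    m <- regmatches(tok, regexec("^([0-9]+)\\*(.+)$", tok))[[1]]
    if (length(m)) {
      out <- c(out, rep(m[3], as.integer(m[2])))
    } else {
      if (grepl("[*@>]", tok))
        stop(sprintf("line %d: malformed species token '%s'", line_no, tok))
      out <- c(out, tok)
    }
  }
  out
}

#' Read a model from a plain-text rule file
#'
#' @param path file path.
#' @param functions named list resolving `function(name)` rate annotations:
#'   each element a [rate_law] object or a function `(counts, t) -> rate`.
#' @param name model name (default: file base name).
#' @param observed observed species (default: all).
#' @return a validated [ssa_model].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("init: A=250 B=1", "buffered: B",
#'              "A A -> A A A @ mass_action(0.03)",
#'              "3*A -> 2*A @ mass_action(0.0001)",
#'              "B -> B A @ mass_action(200)",
#'              "A -> @ mass_action(3.5)"), f)
#' parse_model_file(f)
#' @export
parse_model_file <- function(path, functions = list(), name = NULL,
                             observed = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  init <- integer(0)
  buffered <- character(0)
  reactions <- list()
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt)) next
    if (grepl("^init:", txt)) {
      for (kv in strsplit(trimws(sub("^init:", "", txt)), "[[:space:]]+")[[1]]) {
        parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
        if (length(parts) != 2 || is.na(suppressWarnings(as.integer(parts[2]))))
          stop(sprintf("line %d: malformed init entry '%s'", ln, kv))
        init[parts[1]] <- as.integer(parts[2])
      }
      next
    }
    if (grepl("^buffered:", txt)) {
      buffered <- c(buffered,
                    strsplit(trimws(sub("^buffered:", "", txt)),
                             "[[:space:]]+")[[1]])
      next
    }
    if (!grepl("->", txt, fixed = TRUE))
      stop(sprintf("line %d: expected a reaction arrow '->' in '%s'", ln, txt))
    halves <- strsplit(txt, "->", fixed = TRUE)[[1]]
    if (length(halves) != 2)
      stop(sprintf("line %d: malformed arrow", ln))
    rhs <- strsplit(halves[2], "@", fixed = TRUE)[[1]]
    if (length(rhs) != 2)
      stop(sprintf("line %d: missing '@ rate' annotation", ln))
    rate_txt <- trimws(rhs[2])
    m <- regmatches(rate_txt,
                    regexec("^mass_action\\(([-0-9.eE+]+)\\)$", rate_txt))[[1]]
    if (length(m)) {
      rate <- rate_mass_action(as.numeric(m[2]))
    } else {
      m <- regmatches(rate_txt,
                      regexec("^function\\(([[:alnum:]_.]+)\\)$", rate_txt))[[1]]
      if (!length(m))
        stop(sprintf("line %d: unparseable rate annotation '%s'", ln, rate_txt))
      f <- functions[[m[2]]]
      if (is.null(f))
        stop(sprintf("line %d: rate function '%s' not found in registry",
                     ln, m[2]))
      rate <- if (inherits(f, "rate_law")) f else rate_function(f)
    }
    reactions[[length(reactions) + 1L]] <-
      reaction(parse_side(halves[1], ln), parse_side(rhs[1], ln), rate,
               buffered = buffered)
  }
  if (!length(reactions)) stop("no reactions in model file '", path, "'")
  species <- unique(c(names(init),
                      unlist(lapply(reactions, function(rx)
                        c(names(rx$reactants), names(rx$products),
                          rx$buffered,
                          if (rx$rate$type %in% c("hill", "michaelis"))
                            rx$rate$species)))))
  ssa_model(name %||% sub("\\.[^.]*$", "", basename(path)), species,
            reactions, init, observed = observed %||% species)
}

# ---- raw trajectory store ---------------------------------------------------

fmt_num <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
         formatC(x, format = "g", digits = 6))
}

#' Write / read a raw trajectory store
#'
#' CSV with a `time` column and one `species:task_id` column per trajectory
#' and observed species; fixed `%.6g` float formatting and integer counts,
#' so identical inputs always produce byte-identical files.
#' `read_trajectories(write_trajectories(...))` is the identity for integer
#' counts.
#'
#' @param store list with elements `time` (numeric vector) and `values`
#'   (named list, one n-by-length(time) integer matrix per species; rows are
#'   trajectories ordered by task id). The `raw` component of a
#'   [run_workflow()] result (with its config times) fits after wrapping via
#'   `as_trajectory_store()`.
#' @param path file path.
#' @return `write_trajectories`: the path, invisibly; `read_trajectories`:
#'   a store list as above.
#' @export
write_trajectories <- function(store, path) {
  stopifnot(is.list(store), !is.null(store$time), is.list(store$values))
  sp <- names(store$values)
  cols <- character(0)
  data <- list(time = fmt_num(store$time))
  for (s in sp) {
    mat <- store$values[[s]]
    if (!is.null(dim(mat)) && ncol(mat) != length(store$time))
      stop("species ", s, ": matrix columns must match time grid")
    for (i in seq_len(nrow(mat))) {
      cn <- sprintf("%s:%d", s, i - 1L)
      cols <- c(cols, cn)
      data[[cn]] <- fmt_num(mat[i, ])
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("time", cols), collapse = ","), con)
  if (length(store$time))
    writeLines(do.call(paste, c(data, sep = ",")), con)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty trajectory file")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (header[1] != "time") stop("first column must be 'time'")
  ncol <- length(header)
  body <- lines[-1]
  cells <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(cells) != ncol)
  if (length(bad))
    stop(sprintf("row %d has %d fields, expected %d", bad[1],
                 lengths(cells)[bad[1]], ncol))
  mat <- matrix(NA_real_, length(body), ncol)
  for (r in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[r]]))
    if (anyNA(v)) stop(sprintf("row %d: non-numeric cell", r))
    mat[r, ] <- v
  }
  time <- mat[, 1]
  values <- list()
  if (ncol > 1) {
    specs <- strsplit(header[-1], ":", fixed = TRUE)
    sp <- vapply(specs, `[[`, character(1), 1)
    for (s in unique(sp)) {
      cols <- which(sp == s) + 1L
      values[[s]] <- t(mat[, cols, drop = FALSE])
    }
  }
  list(time = time, values = values)
}

#' @rdname write_trajectories
#' @param wf an `ssa_workflow` run with `store_raw = TRUE`.
#' @export
as_trajectory_store <- function(wf) {
  stopifnot(inherits(wf, "ssa_workflow"))
  if (is.null(wf$raw)) stop("workflow was run without store_raw = TRUE")
  cfg <- wf$config
  ncuts <- ncol(wf$raw[[1]])
  list(time = cfg$t0 + (seq_len(ncuts) - 1) * cfg$delta_s, values = wf$raw)
}

#' Read a workflow configuration file
#'
#' YAML with keys `model` (builtin name or rule-file path), `n_trajectories`,
#' `t_end`, `delta_s`, and optionally `quantum`, `workers`, `base_seed`,
#' `window`, `stride`, `levels`, `clustering`, `peaks`, `store_raw`.
#'
#' @param path YAML file path.
#' @return a named list ready to splice into [run_workflow()] after
#'   resolving `model`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package")
  cfg <- yaml::yaml.load_file(path)
  for (f in c("model", "n_trajectories", "t_end", "delta_s"))
    if (is.null(cfg[[f]])) stop("config misses required field '", f, "'")
  stopifnot(cfg$n_trajectories >= 1, cfg$t_end > 0, cfg$delta_s > 0)
  if (!is.null(cfg$quantum) && cfg$quantum < cfg$delta_s)
    stop("quantum must be at least delta_s")
  cfg
}
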