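# World-specification files (JSON or YAML), random-world generation and CSV
# helpers backing the command-line interface.

#' Load a world specification file
#'
#' Reads a structured JSON or YAML world description and returns validated
#' objects. Two forms are accepted, exactly one per file:
#' \describe{
#'   \item{full}{`pursuits:` a list of `{label, reward, duration,
#'     frequency}` records plus `default_rate`; yields a
#'     [forgo_world()].}
#'   \item{reduced}{`r_in`, `t_in`, `r_out`, `t_out` (optionally a `choice:`
#'     block with `ss: {reward, duration}`, `ll: {reward, duration}`);
#'     yields a list with `pursuit` and `outside` (and `ss`, `ll` when the
#'     choice block is present).}
#' }
#' All numbers must be finite; durations and the outside time must be
#' strictly positive. Validation failures name the offending field.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [forgo_world()] (full form) or a list with elements `pursuit`
#'   and `outside` (reduced form).
#' @examples
#' tf <- tempfile(fileext = ".json")
#' writeLines('{"r_in": 4, "t_in": 4, "r_out": 0.7, "t_out": 3}', tf)
#' load_world_spec(tf)
#' @export
load_world_spec <- function(path) {
  if (!file.exists(path)) stop("world spec file not found: ", path)
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  parse_world_spec(spec)
}

parse_world_spec <- function(spec) {
  if (!is.list(spec)) stop("world spec must be a mapping/object")
  full <- "pursuits" %in% names(spec)
  reduced <- all(c("r_in", "t_in", "r_out", "t_out") %in% names(spec))
  if (full && reduced)
    stop("world spec mixes full ('pursuits') and reduced (r_in/t_in/...) forms")
  if (!full && !reduced)
    stop("world spec needs either 'pursuits' + 'default_rate' or ",
         "r_in, t_in, r_out, t_out")
  if (full) {
    ps <- spec$pursuits
    if (!is.list(ps)) stop("field 'pursuits' must be a list of records")
    pursuits <- vector("list", length(ps))
    freqs <- numeric(length(ps))
    for (i in seq_along(ps)) {
      rec <- ps[[i]]
      for (fld in c("reward", "duration", "frequency"))
        check_num(rec[[fld]], paste0("pursuits[", i, "].", fld))
      if (rec$duration <= 0)
        stop("field pursuits[", i, "].duration must be > 0")
      if (rec$frequency <= 0)
        stop("field pursuits[", i, "].frequency must be > 0")
      pursuits[[i]] <- pursuit(rec$reward, rec$duration, label = rec$label)
      freqs[i] <- rec$frequency
    }
    default_rate <- if (is.null(spec$default_rate)) 0 else spec$default_rate
    check_num(default_rate, "default_rate")
    forgo_world(pursuits, freqs, default_rate)
  } else {
    for (fld in c("r_in", "t_in", "r_out", "t_out"))
      check_num(spec[[fld]], fld)
    if (spec$t_in < 0) stop("field t_in must be >= 0")
    if (spec$t_out <= 0) stop("field t_out must be > 0")
    out <- list(pursuit = pursuit(spec$r_in, spec$t_in),
                outside = outside_context(spec$r_out, spec$t_out))
    if (!is.null(spec$choice)) {
      for (side in c("ss", "ll")) {
        rec <- spec$choice[[side]]
        if (is.null(rec)) stop("field choice.", side, " is required")
        check_num(rec$reward, paste0("choice.", side, ".reward"))
        check_num(rec$duration, paste0("choice.", side, ".duration"))
        if (rec$duration <= 0)
          stop("field choice.", side, ".duration must be > 0")
        out[[side]] <- pursuit(rec$reward, rec$duration, label = side)
      }
    }
    out
  }
}

check_num <- function(x, field) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("field '", field, "' must be a single finite number")
  invisible(x)
}

#' Write a world specification file
#'
#' Serialises a [forgo_world()] (full form) or a `pursuit` + `outside` pair
#' (reduced form) so that [load_world_spec()] round-trips it unchanged.
#'
#' @param x A [forgo_world()], or a list with elements `pursuit` and
#'   `outside`.
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_world_spec <- function(x, path) {
  spec <- if (inherits(x, "forgo_world")) {
    list(pursuits = lapply(seq_along(x$pursuits), function(i) {
      p <- x$pursuits[[i]]
      rec <- list(reward = p$reward, duration = p$duration,
                  frequency = x$frequencies[i])
      if (!is.null(p$label)) rec$label <- p$label
      rec
    }), default_rate = x$default_rate)
  } else if (is.list(x) && inherits(x$pursuit, "pursuit") &&
             inherits(x$outside, "outside_context")) {
    list(r_in = x$pursuit$reward, t_in = x$pursuit$duration,
         r_out = x$outside$outside_reward, t_out = x$outside$outside_time)
  } else stop("cannot serialise object of class ", paste(class(x), collapse = "/"))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(spec, path)
  else
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a random valid forgo world
#'
#' Draws a world for property tests: durations uniform on `(0.1, 10)`,
#' rewards (any sign) uniform on `(-5, 10)`, encounter frequencies uniform
#' on `(0.05, 2)` and a default rate uniform on `(0, 1)`, all overridable.
#' Deterministic given `seed`.
#'
#' @param n_pursuits Number of pursuit types (>= 0).
#' @param seed Integer seed.
#' @param ranges Named list overriding any of `duration`, `reward`,
#'   `frequency`, `default_rate`, each a `c(min, max)` pair.
#' @return A [forgo_world()].
#' @examples
#' generate_random_world(3, seed = 42)
#' @export
generate_random_world <- function(n_pursuits, seed = 0L, ranges = list()) {
  stopifnot(is.numeric(n_pursuits), length(n_pursuits) == 1L, n_pursuits >= 0)
  rg <- utils::modifyList(list(duration = c(0.1, 10), reward = c(-5, 10),
                               frequency = c(0.05, 2),
                               default_rate = c(0, 1)), ranges)
  set.seed(as.integer(seed))
  n <- as.integer(n_pursuits)
  pursuits <- lapply(seq_len(n), function(i) {
    pursuit(stats::runif(1, rg$reward[1], rg$reward[2]),
            stats::runif(1, rg$duration[1], rg$duration[2]))
  })
  forgo_world(pursuits,
              frequencies = stats::runif(n, rg$frequency[1], rg$frequency[2]),
              default_rate = stats::runif(1, rg$default_rate[1],
                                          rg$default_rate[2]))
}
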