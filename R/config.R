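#' Build and validate a simulation configuration
#'
#' Collects every parameter of a run and validates it.  Defaults follow the
#' standard protocol: p1 = p2 = r = 1, a common sensitivity k for all three
#' species, L = 300.  The microscopic exchange rate m = 2 * M * N
#' (N = L * L) is derived and attached; it is never set directly and may
#' exceed 1 since it only enters the normalized event probabilities.
#'
#' @param L lattice side; the lattice holds N = L * L sites.  Must be even
#'   (the two territories are the top and bottom halves) and at least 4.
#' @param M mobility; positive real.  Microscopic exchange rate m = 2 M N.
#' @param k common territorial sensitivity coefficient, shorthand that sets
#'   `k_A`, `k_B` and `k_C` unless they are given individually.
#' @param k_A,k_B,k_C per-species sensitivity coefficients (non-negative).
#'   Intraspecific competition for species i runs at rate `k_i * p2`.
#' @param p1 interspecific (cyclic predation) rate, non-negative.
#' @param p2 intraspecific base rate, non-negative.
#' @param r reproduction rate, non-negative.
#' @param T_max run length in generations (one generation = N pairwise
#'   attempts).  Defaults to N, the classic protocol.
#' @param seed integer seed; a run is a deterministic function of the
#'   validated config (including the seed).
#' @param intraspecific_mode `"territorial"` (same species, different genus
#'   only) or `"traditional"` (any same-species pair).
#' @param record_every density-recording stride in generations; generation 0
#'   and the final generation are always recorded.
#' @param empty_frac initial vacancy probability per site (the remaining mass
#'   is split uniformly over the three territory-appropriate species labels).
#' @param actor_sampling `"site"` draws the interaction actor uniformly over
#'   all N sites (drawing a vacancy wastes the attempt); `"occupied"` draws
#'   uniformly over currently occupied sites.  `"site"` is the default: it
#'   keeps the per-individual clock tied to real time even when mortality
#'   drives the density down, which matters in traditional mode at large k.
#' @return a validated `rps_config` object (a list) with derived `m` and `N`.
#' @examples
#' cfg <- rps_config(L = 100, M = 1e-5, k = 5, T_max = 500, seed = 1)
#' cfg$m  # 2 * 1e-5 * 10000
#' @export
rps_config <- function(L = 300L, M = 1e-5, k = 0,
                       k_A = k, k_B = k, k_C = k,
                       p1 = 1, p2 = 1, r = 1,
                       T_max = NULL, seed = 1L,
                       intraspecific_mode = c("territorial", "traditional"),
                       record_every = 1L,
                       empty_frac = 0.25,
                       actor_sampling = c("site", "occupied")) {
  intraspecific_mode <- match.arg(intraspecific_mode)
  actor_sampling <- match.arg(actor_sampling)
  if (is.null(T_max)) T_max <- as.integer(L)^2
  cfg <- list(
    L = L, M = M, k_A = k_A, k_B = k_B, k_C = k_C,
    p1 = p1, p2 = p2, r = r, T_max = T_max, seed = seed,
    intraspecific_mode = intraspecific_mode,
    record_every = record_every, empty_frac = empty_frac,
    actor_sampling = actor_sampling
  )
  validate_config(cfg)
}

#' Validate a configuration and attach derived quantities
#'
#' Checks every field, normalizes integer fields, and attaches the derived
#' exchange rate `m = 2 * M * N` and the site count `N = L * L`.  Invalid
#' combinations raise an error naming the offending field.
#'
#' @param config a list with the fields of [rps_config()].
#' @return the normalized `rps_config` object.
#' @export
validate_config <- function(config) {
  stop_cfg <- function(...) stop("invalid configuration: ", ..., call. = FALSE)
  num1 <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      stop_cfg(field, " must be a single finite number")
    }
    as.numeric(x)
  }
  L <- num1(config$L, "L")
  if (L != round(L)) stop_cfg("L must be an integer")
  if (L < 4) stop_cfg("L must be at least 4")
  if (L %% 2 != 0) stop_cfg("L must be even")
  config$L <- as.integer(L)
  config$N <- config$L^2

  config$M <- num1(config$M, "M")
  if (config$M <= 0) stop_cfg("M must be positive")
  for (f in c("k_A", "k_B", "k_C")) {
    config[[f]] <- num1(config[[f]], f)
    if (config[[f]] < 0) stop_cfg(f, " must be non-negative")
  }
  # zero rates are allowed (they switch a reaction off, e.g. the r = 0
  # variant used in conservation checks); negatives are not
  for (f in c("p1", "p2", "r")) {
    config[[f]] <- num1(config[[f]], f)
    if (config[[f]] < 0) stop_cfg(f, " must be non-negative")
  }

  T_max <- num1(config$T_max, "T_max")
  if (T_max != round(T_max) || T_max <= 0) stop_cfg("T_max must be a positive integer")
  config$T_max <- as.integer(T_max)

  rec <- num1(config$record_every, "record_every")
  if (rec != round(rec) || rec <= 0) stop_cfg("record_every must be a positive integer")
  config$record_every <- as.integer(rec)

  seed <- num1(config$seed, "seed")
  if (seed != round(seed)) stop_cfg("seed must be an integer")
  config$seed <- seed

  config$empty_frac <- num1(config$empty_frac, "empty_frac")
  if (config$empty_frac < 0 || config$empty_frac >= 1) {
    stop_cfg("empty_frac must be in [0, 1)")
  }
  if (!config$intraspecific_mode %in% c("territorial", "traditional")) {
    stop_cfg("intraspecific_mode must be 'territorial' or 'traditional'")
  }
  if (!config$actor_sampling %in% c("site", "occupied")) {
    stop_cfg("actor_sampling must be 'site' or 'occupied'")
  }

  config$m <- 2 * config$M * config$N
  structure(config, class = "rps_config")
}

#' @export
print.rps_config <- function(x, ...) {
  cat(sprintf(
    "rps_config: L=%d (N=%d)  M=%g (m=%g)  k=(%g,%g,%g)  p1=%g p2=%g r=%g\n",
    x$L, x$N, x$M, x$m, x$k_A, x$k_B, x$k_C, x$p1, x$p2, x$r
  ))
  cat(sprintf(
    "  T_max=%d  seed=%d  mode=%s  record_every=%d  empty_frac=%g  actor=%s\n",
    x$T_max, as.integer(x$seed), x$intraspecific_mode, x$record_every,
    x$empty_frac, x$actor_sampling
  ))
  invisible(x)
}

#' Normalized event probabilities for one actor species
#'
#' For a pair of adjacent sites the four event types are drawn with
#' probabilities p1 / D, k * p2 / D, r / D and m / D where
#' D = p1 + k * p2 + r + m.  k is the sensitivity coefficient of the actor's
#' species, so with distinct k_A, k_B, k_C the mix depends on the actor.
#'
#' @param config a validated [rps_config()].
#' @param k sensitivity coefficient to use; defaults to `config$k_A`.
#' @return an `rps_event_probs` named vector
#'   (interspecific, intraspecific, reproduction, migration), summing to 1.
#' @examples
#' cfg <- rps_config(L = 300, M = 1e-5, k = 5)
#' event_probabilities(cfg)  # denominator 1 + 5 + 1 + 1.8 = 8.8
#' @export
event_probabilities <- function(config, k = config$k_A) {
  if (!inherits(config, "rps_config")) config <- validate_config(config)
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k < 0) {
    stop("k must be a single non-negative number")
  }
  denom <- config$p1 + k * config$p2 + config$r + config$m
  if (denom == 0) stop("event probability denominator is zero")
  p <- c(
    interspecific = config$p1 / denom,
    intraspecific = k * config$p2 / denom,
    reproduction = config$r / denom,
    migration = config$m / denom
  )
  structure(p, class = c("rps_event_probs", "numeric"))
}

# 3 x 4 per-species probability matrix in kernel layout
event_prob_matrix <- function(config) {
  rbind(
    event_probabilities(config, config$k_A),
    event_probabilities(config, config$k_B),
    event_probabilities(config, config$k_C)
  )
}

#' Read a configuration from a JSON file
#'
#' The file must contain a single JSON object whose keys are
#' [rps_config()] arguments (minus the `k` shorthand, which is accepted too);
#' unknown keys are rejected.
#'
#' @param path path to a JSON config file.
#' @return a validated `rps_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw[["_comment"]] <- NULL # annotation key, ignored
  known <- names(formals(rps_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(rps_config, raw)
}

#' Write a configuration to a JSON file
#'
#' @param config a validated `rps_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "rps_config")) config <- validate_config(config)
  fields <- config[c(
    "L", "M", "k_A", "k_B", "k_C", "p1", "p2", "r", "T_max", "seed",
    "intraspecific_mode", "record_every", "empty_frac", "actor_sampling"
  )]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
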