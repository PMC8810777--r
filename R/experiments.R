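#' Specify a replicated parameter sweep
#'
#' A sweep runs `replicates` independent simulations at each value of the
#' swept variable and aggregates a scalar measurement with its standard
#' error.  Each (value, replicate) cell gets its own distinct seed,
#' `base_seed + (value_index - 1) * replicates + (replicate - 1)`, stored in
#' the result so any single run is reproducible in isolation.
#'
#' @param base a validated [rps_config()] providing every non-swept
#'   parameter.
#' @param sweep_variable `"k"` (sets the common sensitivity of all three
#'   species) or `"M"`.
#' @param values numeric vector of swept values.
#' @param replicates runs per value (>= 1).
#' @param measurement one of `"extinction_time_low"`,
#'   `"extinction_time_high"` (first-crossing generation of the regime's
#'   extinction event, run with `record_every = 1` and an event-driven early
#'   stop), `"width_at_t"` (interface width W at generation `t_measure`), or
#'   `"phase_state"` (1 if all three species are alive at `base$T_max`).
#' @param t_measure measurement generation for `"width_at_t"`
#'   (default 1000).
#' @param censor_at optional censoring horizon for the extinction
#'   measurements: runs are simulated at most to this generation and
#'   unfinished ones enter the aggregate at the censoring value.
#' @param base_seed first seed of the seed grid; defaults to `base$seed`.
#' @return an `rps_sweep_spec`.
#' @export
sweep_spec <- function(base, sweep_variable = c("k", "M"), values, replicates,
                       measurement = c(
                         "extinction_time_low", "extinction_time_high",
                         "width_at_t", "phase_state"
                       ),
                       t_measure = 1000L, censor_at = NULL,
                       base_seed = NULL) {
  if (!inherits(base, "rps_config")) base <- validate_config(base)
  sweep_variable <- match.arg(sweep_variable)
  measurement <- match.arg(measurement)
  if (length(values) < 1 || anyNA(values)) stop("values must be non-empty")
  if (anyDuplicated(values) > 0) stop("swept values must be distinct")
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.null(base_seed)) base_seed <- base$seed
  structure(
    list(
      base = base, sweep_variable = sweep_variable, values = as.numeric(values),
      replicates = as.integer(replicates), measurement = measurement,
      t_measure = as.integer(t_measure), censor_at = censor_at,
      base_seed = base_seed
    ),
    class = "rps_sweep_spec"
  )
}

sweep_seed <- function(spec, value_index, replicate) {
  spec$base_seed + (value_index - 1) * spec$replicates + (replicate - 1)
}

config_for_value <- function(spec, value, seed, mode = NULL) {
  base <- spec$base
  if (spec$sweep_variable == "k") {
    base$k_A <- base$k_B <- base$k_C <- value
  } else {
    base$M <- value
  }
  base$seed <- seed
  if (!is.null(mode)) base$intraspecific_mode <- mode
  validate_config(unclass(base))
}

measure_replicate <- function(spec, value, seed, mode = NULL) {
  m <- spec$measurement
  if (m %in% c("extinction_time_low", "extinction_time_high")) {
    cfg <- config_for_value(spec, value, seed, mode)
    if (!is.null(spec$censor_at)) cfg$T_max <- as.integer(spec$censor_at)
    cfg$record_every <- 1L # exact first-crossing resolution
    cfg <- validate_config(unclass(cfg))
    defn <- if (m == "extinction_time_low") "low_mobility" else "high_mobility"
    stopw <- if (m == "extinction_time_low") "genus_loss" else "two_species"
    traj <- run_simulation(cfg, stop_when = stopw)
    rec <- extinction_time(traj, defn, censor_at = spec$censor_at)
    if (rec$status == "undetermined") {
      stop("extinction undetermined at T_max; set censor_at or raise T_max")
    }
    c(measurement = rec$time, censored = as.integer(rec$censored))
  } else if (m == "width_at_t") {
    cfg <- config_for_value(spec, value, seed, mode)
    cfg$T_max <- spec$t_measure
    cfg$record_every <- spec$t_measure
    cfg <- validate_config(unclass(cfg))
    traj <- run_simulation(cfg)
    c(measurement = interface_width(traj$final_state)$W, censored = 0L)
  } else { # phase_state
    cfg <- config_for_value(spec, value, seed, mode)
    cfg$record_every <- cfg$T_max
    cfg <- validate_config(unclass(cfg))
    traj <- run_simulation(cfg, stop_when = "single_species")
    alive <- summarize_lattice(traj$final_state)$species_alive
    c(measurement = as.integer(length(alive) == 3), censored = 0L)
  }
}

#' Execute a sweep specification
#'
#' @param spec an [sweep_spec()].
#' @param mode optional intraspecific-mode override (used by
#'   [sweep_traditional_vs_territorial()] to run both arms on one seed grid).
#' @return an `rps_sweep`: `rows` (one row per replicate: value, replicate,
#'   seed, measurement, censored) and `aggregate` (per value: mean,
#'   standard_error = sample sd / sqrt(n), n, n_censored).  With n = 1 the
#'   standard error is reported as 0.
#' @export
run_sweep <- function(spec, mode = NULL) {
  stopifnot(inherits(spec, "rps_sweep_spec"))
  rows <- do.call(rbind, lapply(seq_along(spec$values), function(i) {
    do.call(rbind, lapply(seq_len(spec$replicates), function(j) {
      seed <- sweep_seed(spec, i, j)
      res <- measure_replicate(spec, spec$values[i], seed, mode)
      data.frame(
        value = spec$values[i], replicate = j, seed = seed,
        measurement = res[["measurement"]], censored = res[["censored"]]
      )
    }))
  }))
  structure(
    list(rows = rows, aggregate = aggregate_sweep(rows), spec = spec,
         mode = if (is.null(mode)) spec$base$intraspecific_mode else mode),
    class = "rps_sweep"
  )
}

#' Aggregate per-replicate sweep rows
#'
#' @param rows data.frame with columns value, measurement, censored.
#' @return data.frame of (value, mean, standard_error, n, n_censored); the
#'   standard error is the sample standard deviation over replicates divided
#'   by sqrt(n), 0 when n = 1.
#' @export
aggregate_sweep <- function(rows) {
  out <- do.call(rbind, lapply(split(rows, rows$value), function(d) {
    n <- nrow(d)
    data.frame(
      value = d$value[1],
      mean = mean(d$measurement),
      standard_error = if (n > 1) sd(d$measurement) / sqrt(n) else 0,
      n = n,
      n_censored = sum(d$censored)
    )
  }))
  out <- out[order(out$value), ]
  rownames(out) <- NULL
  out
}

#' @export
print.rps_sweep <- function(x, ...) {
  cat(sprintf(
    "rps_sweep: %s over %s (%d replicates, mode %s)\n",
    x$spec$measurement, x$spec$sweep_variable, x$spec$replicates, x$mode
  ))
  print(x$aggregate)
  invisible(x)
}

#' Extinction time versus sensitivity k
#'
#' Replicated sweep of the regime-appropriate average extinction time over a
#' grid of sensitivity values.  The extinction definition is chosen
#' explicitly through the spec's measurement, never inferred from M; a spec
#' sweeping M is rejected (mixed mobility regimes in one extinction sweep
#' are not meaningful).
#'
#' @param spec an [sweep_spec()] with `sweep_variable = "k"` and an
#'   extinction measurement.
#' @return an `rps_sweep`.
#' @export
sweep_extinction_vs_k <- function(spec) {
  stopifnot(inherits(spec, "rps_sweep_spec"))
  if (spec$sweep_variable != "k") {
    stop("extinction sweeps vary k; sweeping M would mix mobility regimes")
  }
  if (!spec$measurement %in% c("extinction_time_low", "extinction_time_high")) {
    stop("spec$measurement must be an extinction-time measurement")
  }
  run_sweep(spec)
}

#' Matched-seed comparison of traditional and territorial intraspecific modes
#'
#' Runs the extinction sweep twice on the same seed grid, once with
#' territory-sensitive intraspecific competition (same species, different
#' genus) and once with traditional intraspecific competition (any
#' same-species pair), and reports both aggregates.  Censored replicates
#' enter the means at the censoring value.
#'
#' @param spec an [sweep_spec()] with `sweep_variable = "k"` and the
#'   low-mobility extinction measurement.
#' @return an `rps_paired_sweep`: list with elements `territorial` and
#'   `traditional`, both `rps_sweep` objects on identical seeds.
#' @export
sweep_traditional_vs_territorial <- function(spec) {
  stopifnot(inherits(spec, "rps_sweep_spec"))
  if (spec$sweep_variable != "k") stop("mode comparison sweeps vary k")
  if (spec$measurement != "extinction_time_low") {
    stop("the mode comparison is defined for the low-mobility regime")
  }
  structure(
    list(
      territorial = run_sweep(spec, mode = "territorial"),
      traditional = run_sweep(spec, mode = "traditional")
    ),
    class = "rps_paired_sweep"
  )
}

#' Interface width at a fixed generation versus sensitivity k
#'
#' @param spec an [sweep_spec()] with `sweep_variable = "k"` and
#'   `measurement = "width_at_t"`; `t_measure` defaults to 1000.
#' @return an `rps_sweep` of W values.
#' @export
sweep_width_vs_k <- function(spec) {
  stopifnot(inherits(spec, "rps_sweep_spec"))
  if (spec$sweep_variable != "k") stop("width sweeps vary k")
  if (spec$measurement != "width_at_t") {
    stop("spec$measurement must be 'width_at_t'")
  }
  run_sweep(spec)
}

#' Coexistence probability across a mobility grid
#'
#' For each mobility value, runs `replicates` simulations to `base$T_max`
#' generations (default N) and scores coexistence (all three species alive
#' at the end).  The transition midpoint is where the interpolated
#' coexistence probability crosses 1/2 on a log10(M) axis; it is `NA` when
#' the grid does not bracket 1/2 or when no fit is meaningful (single value
#' or single replicate).
#'
#' @param spec an [sweep_spec()] with `sweep_variable = "M"` and
#'   `measurement = "phase_state"`.
#' @return an `rps_phase_scan`: `rows`, `aggregate` (mean = coexistence
#'   probability), and `midpoint` (estimated critical mobility).
#' @export
phase_scan_mobility <- function(spec) {
  stopifnot(inherits(spec, "rps_sweep_spec"))
  if (spec$sweep_variable != "M") stop("phase scans vary M")
  if (spec$measurement != "phase_state") {
    stop("spec$measurement must be 'phase_state'")
  }
  sw <- run_sweep(spec)
  midpoint <- if (length(spec$values) < 2 || spec$replicates < 2) {
    NA_real_
  } else {
    transition_midpoint(sw$aggregate$value, sw$aggregate$mean,
      n = sw$aggregate$n
    )
  }
  structure(
    list(rows = sw$rows, aggregate = sw$aggregate, midpoint = midpoint,
         spec = spec),
    class = "rps_phase_scan"
  )
}

# M at which the fitted coexistence probability crosses 1/2.  With
# replicate counts available a binomial logistic fit on log10(M) pools the
# whole grid (stable at modest replicate counts); otherwise, or when the
# fit degenerates (separation, upward slope), fall back to linear
# interpolation of the first 0.5-crossing.
transition_midpoint <- function(M, prob, n = NULL) {
  if (!is.null(n) && length(unique(M)) >= 2) {
    x <- log10(M)
    succ <- round(prob * n)
    fit <- suppressWarnings(tryCatch(
      stats::glm(cbind(succ, n - succ) ~ x, family = stats::binomial()),
      error = function(e) NULL
    ))
    if (!is.null(fit) && fit$converged) {
      b <- stats::coef(fit)
      if (is.finite(b[2]) && b[2] < 0) {
        mid <- 10^(-b[1] / b[2])
        # trust the fit only when the crossing lies inside the grid
        if (mid >= min(M) && mid <= max(M)) {
          return(unname(mid))
        }
      }
    }
  }
  o <- order(M)
  M <- M[o]
  prob <- prob[o]
  for (i in seq_len(length(M) - 1)) {
    p0 <- prob[i]
    p1 <- prob[i + 1]
    if ((p0 - 0.5) * (p1 - 0.5) <= 0 && p0 != p1) {
      f <- (p0 - 0.5) / (p0 - p1)
      return(10^(log10(M[i]) + f * (log10(M[i + 1]) - log10(M[i]))))
    }
    if (p0 == 0.5 && p1 == 0.5) {
      return(sqrt(M[i] * M[i + 1]))
    }
  }
  NA_real_
}

#' @export
print.rps_phase_scan <- function(x, ...) {
  cat(sprintf(
    "rps_phase_scan: %d mobility values x %d replicates; midpoint M_c ~ %s\n",
    length(x$spec$values), x$spec$replicates, format(x$midpoint, digits = 3)
  ))
  print(x$aggregate)
  invisible(x)
}

#' One-sided monotone-trend test
#'
#' Kendall rank correlation between a swept value and a measurement, one
#' sided.  Used for the monotonicity claims (extinction time non-decreasing
#' in k; interface width decreasing in k), which it tests more robustly at
#' small replicate counts than pairwise standard-error overlap.
#'
#' @param value swept values (per replicate or per aggregate point).
#' @param measurement matched measurements.
#' @param alternative `"increasing"` or `"decreasing"`.
#' @return a list with `p.value` and `tau`.
#' @export
rps_trend_test <- function(value, measurement,
                           alternative = c("increasing", "decreasing")) {
  alternative <- match.arg(alternative)
  ct <- suppressWarnings(cor.test(
    value, measurement,
    method = "kendall",
    alternative = if (alternative == "increasing") "greater" else "less",
    exact = FALSE
  ))
  list(p.value = ct$p.value, tau = unname(ct$estimate))
}

#' Read a sweep specification from a JSON file
#'
#' The JSON object must have a `base` object of [rps_config()] fields plus
#' the [sweep_spec()] fields; unknown keys are rejected.
#'
#' @param path JSON file path.
#' @return an `rps_sweep_spec`.
#' @export
read_sweep_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c(
    "base", "sweep_variable", "values", "replicates", "measurement",
    "t_measure", "censor_at", "base_seed", "_comment"
  )
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) stop("unknown sweep key(s): ", paste(bad, collapse = ", "))
  raw[["_comment"]] <- NULL
  base_known <- names(formals(rps_config))
  bad <- setdiff(names(raw$base), c(base_known, "_comment"))
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  raw$base[["_comment"]] <- NULL
  base <- do.call(rps_config, raw$base)
  args <- raw[setdiff(names(raw), "base")]
  do.call(sweep_spec, c(list(base = base), args))
}
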