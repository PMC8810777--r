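#' Survival-state summary of a lattice
#'
#' Counts the seven site states and classifies the label composition.
#' A species is alive iff either of its genera has positive count.  Labels:
#' \describe{
#'   \item{full_coexistence}{all three species alive and at least one species
#'     still carries both genera}
#'   \item{reduced_coexistence}{all three species alive, exactly one genus
#'     per species}
#'   \item{one_species_extinct}{exactly two species alive}
#'   \item{two_species_extinct}{exactly one species alive, both its genera}
#'   \item{uniform}{exactly one genus label alive}
#'   \item{all_dead}{no individuals left}
#' }
#'
#' @param state an `rps_lattice` (or integer code matrix).
#' @return an `rps_survival` list: `counts` (named over the 7 labels),
#'   `species_alive`, `genera_alive`, `state_label`.
#' @export
summarize_lattice <- function(state) {
  state <- as_lattice(state)
  counts <- lattice_counts(state)
  genus_counts <- counts[RPS_LABELS[-1]]
  genera_alive <- names(genus_counts)[genus_counts > 0]
  species_counts <- c(
    A = unname(counts["A1"] + counts["A2"]),
    B = unname(counts["B1"] + counts["B2"]),
    C = unname(counts["C1"] + counts["C2"])
  )
  species_alive <- names(species_counts)[species_counts > 0]

  ns <- length(species_alive)
  nl <- length(genera_alive)
  state_label <-
    if (ns == 0) "all_dead"
    else if (nl == 1) "uniform"
    else if (ns == 1) "two_species_extinct"
    else if (ns == 2) "one_species_extinct"
    else if (nl == 3) "reduced_coexistence"
    else "full_coexistence"

  structure(
    list(
      counts = counts, species_alive = species_alive,
      genera_alive = genera_alive, state_label = state_label
    ),
    class = "rps_survival"
  )
}

#' @export
summary.rps_lattice <- function(object, ...) summarize_lattice(object)

#' @export
print.rps_survival <- function(x, ...) {
  cat(
    "rps_survival:", x$state_label, "\n  species alive:",
    if (length(x$species_alive)) paste(x$species_alive, collapse = " ") else "-",
    "\n  genera alive: ",
    if (length(x$genera_alive)) paste(x$genera_alive, collapse = " ") else "-", "\n"
  )
  print(x$counts)
  invisible(x)
}

#' Extinction time from a density trajectory
#'
#' Two regime-specific first-crossing definitions:
#' \describe{
#'   \item{low_mobility}{the first generation at which every species has lost
#'     at least one genus (for every X, count(X1) = 0 or count(X2) = 0)}
#'   \item{high_mobility}{the first generation at which at least two species
#'     have total count 0}
#' }
#' If the event never occurs in the trajectory, the record is censored at
#' `censor_at` provided the trajectory reaches that generation; otherwise the
#' record carries an explicit `"undetermined"` status rather than a number.
#' For exact first-crossing times, record densities every generation
#' (`record_every = 1`).
#'
#' @param trajectory an `rps_trajectory` or a densities data.frame with
#'   columns generation, A1..C2.
#' @param definition `"low_mobility"` or `"high_mobility"`.
#' @param censor_at optional censoring generation: runs that never reach the
#'   event report `time = censor_at` with `censored = TRUE`.
#' @return an `rps_extinction` list: `definition`, `time`, `censored`,
#'   `censored_at`, `status` (`"observed"`, `"censored"` or `"undetermined"`).
#' @export
extinction_time <- function(trajectory,
                            definition = c("low_mobility", "high_mobility"),
                            censor_at = NULL) {
  definition <- match.arg(definition)
  dens <- if (inherits(trajectory, "rps_trajectory")) {
    trajectory$densities
  } else {
    as.data.frame(trajectory)
  }
  need <- c("generation", "A1", "A2", "B1", "B2", "C1", "C2")
  if (!all(need %in% names(dens))) {
    stop(
      "trajectory must have columns ",
      paste(need, collapse = ", ")
    )
  }

  hit <- if (definition == "low_mobility") {
    (dens$A1 == 0 | dens$A2 == 0) &
      (dens$B1 == 0 | dens$B2 == 0) &
      (dens$C1 == 0 | dens$C2 == 0)
  } else {
    ((dens$A1 + dens$A2 == 0) +
      (dens$B1 + dens$B2 == 0) +
      (dens$C1 + dens$C2 == 0)) >= 2
  }

  rec <- function(time, censored, status) {
    structure(
      list(
        definition = definition, time = time, censored = censored,
        censored_at = censor_at, status = status
      ),
      class = "rps_extinction"
    )
  }

  if (any(hit)) {
    return(rec(dens$generation[which(hit)[1]], FALSE, "observed"))
  }
  last_gen <- max(dens$generation)
  if (!is.null(censor_at) && last_gen >= censor_at) {
    return(rec(censor_at, TRUE, "censored"))
  }
  rec(NA_integer_, FALSE, "undetermined")
}

#' @export
print.rps_extinction <- function(x, ...) {
  cat(sprintf(
    "rps_extinction (%s): time = %s [%s]\n",
    x$definition, format(x$time), x$status
  ))
  invisible(x)
}

#' Default analysis window: the central third of rows
#'
#' The interface-width statistic only scans rows near the territorial
#' boundary to avoid the periodic top/bottom boundary: the central L/3 rows,
#' split evenly about the interface between rows L/2 and L/2 + 1.  For
#' L = 300 this is rows 101..200.
#'
#' @param L lattice side.
#' @return an integer vector of row indices.
#' @export
default_window <- function(L) {
  h <- round(L / 6)
  seq.int(L / 2 - h + 1, L / 2 + h)
}

#' Penetration coordinate of a territory class in one column
#'
#' Pools the three species of a genus.  For territory 1 (genus-1
#' individuals, codes A1/B1/C1): if any genus-1 individual in column `j`
#' within the window lies inside territory 2 (row > L/2), returns the deepest
#' such row (the farthest invasion); otherwise returns the largest genus-1
#' row in territory 1 (nearest to the interface); `NA` if the column holds no
#' genus-1 individual in the window.  Territory 2 is symmetric with minima.
#'
#' @param state an `rps_lattice`.
#' @param j column index (1-based).
#' @param territory 1 or 2.
#' @param window row indices to scan; default [default_window()].
#' @return a row index, or `NA_integer_` when absent.
#' @export
column_penetration <- function(state, j, territory, window = NULL) {
  state <- as_lattice(state)
  L <- state$L
  if (is.null(window)) window <- default_window(L)
  window <- as.integer(window)
  if (any(window < 1L | window > L)) stop("window rows out of range")
  if (length(j) != 1 || j < 1 || j > L) stop("invalid column index")
  if (!territory %in% c(1, 2)) stop("territory must be 1 or 2")

  codes <- if (territory == 1) c(1L, 3L, 5L) else c(2L, 4L, 6L)
  col <- state$grid[window, j]
  rows <- window[col %in% codes]
  if (length(rows) == 0) {
    return(NA_integer_)
  }
  half <- L %/% 2L
  if (territory == 1) {
    invaded <- rows[rows > half]
    if (length(invaded) > 0) max(invaded) else max(rows)
  } else {
    invaded <- rows[rows <= half]
    if (length(invaded) > 0) min(invaded) else min(rows)
  }
}

#' Interface width statistic
#'
#' For each column j, P1_j and P2_j are the [column_penetration()]
#' coordinates of the two territory classes and the per-column width is
#' I_j = P1_j - P2_j when P1_j > P2_j, else 0.  Columns where either class is
#' absent contribute I_j = 0.  The statistic is W = sum_j I_j / L, the mean
#' interpenetration depth in row units over all L columns.
#'
#' @param state an `rps_lattice`.
#' @param window row indices to scan; default [default_window()].
#' @return an `rps_interface_width` list: `P1`, `P2`, `I` (length-L
#'   vectors), `W`, `window`.
#' @export
interface_width <- function(state, window = NULL) {
  state <- as_lattice(state)
  L <- state$L
  if (is.null(window)) window <- default_window(L)
  window <- as.integer(window)
  if (any(window < 1L | window > L)) stop("window rows out of range")

  half <- L %/% 2L
  sub <- state$grid[window, , drop = FALSE]
  g1 <- sub == 1L | sub == 3L | sub == 5L
  g2 <- sub == 2L | sub == 4L | sub == 6L

  P1 <- rep(NA_integer_, L)
  P2 <- rep(NA_integer_, L)
  for (j in seq_len(L)) {
    r1 <- window[g1[, j]]
    if (length(r1) > 0) {
      inv <- r1[r1 > half]
      P1[j] <- if (length(inv) > 0) max(inv) else max(r1)
    }
    r2 <- window[g2[, j]]
    if (length(r2) > 0) {
      inv <- r2[r2 <= half]
      P2[j] <- if (length(inv) > 0) min(inv) else min(r2)
    }
  }
  I <- ifelse(!is.na(P1) & !is.na(P2) & P1 > P2, P1 - P2, 0L)
  structure(
    list(P1 = P1, P2 = P2, I = as.numeric(I), W = sum(I) / L, window = window),
    class = "rps_interface_width"
  )
}

#' @export
print.rps_interface_width <- function(x, ...) {
  cat(sprintf(
    "rps_interface_width: W = %.4f over %d columns (window rows %d..%d)\n",
    x$W, length(x$I), min(x$window), max(x$window)
  ))
  invisible(x)
}

#' Brute-force oracle for the interface width
#'
#' A deliberately naive cell-by-cell re-implementation of
#' [interface_width()], used in tests as an independent cross-check.  It
#' scans every cell of every column with explicit loops and applies the
#' definition literally.
#'
#' @inheritParams interface_width
#' @return an `rps_interface_width` (same contract as [interface_width()]).
#' @export
interface_width_oracle <- function(state, window = NULL) {
  state <- as_lattice(state)
  L <- state$L
  if (is.null(window)) window <- default_window(L)
  window <- as.integer(window)
  half <- L %/% 2L
  genus1_labels <- c("A1", "B1", "C1")
  genus2_labels <- c("A2", "B2", "C2")

  P1 <- rep(NA_integer_, L)
  P2 <- rep(NA_integer_, L)
  I <- numeric(L)
  for (j in 1:L) {
    rows1 <- integer(0)
    rows2 <- integer(0)
    for (i in window) {
      lab <- rps_label(state$grid[i, j])
      if (lab %in% genus1_labels) rows1 <- c(rows1, i)
      if (lab %in% genus2_labels) rows2 <- c(rows2, i)
    }
    if (length(rows1) > 0) {
      invading <- rows1[rows1 > half]
      if (length(invading) > 0) {
        P1[j] <- max(invading) # deepest invader in territory 2
      } else {
        P1[j] <- max(rows1) # nearest to the interface from above
      }
    }
    if (length(rows2) > 0) {
      invading <- rows2[rows2 <= half]
      if (length(invading) > 0) {
        P2[j] <- min(invading)
      } else {
        P2[j] <- min(rows2)
      }
    }
    if (!is.na(P1[j]) && !is.na(P2[j]) && P1[j] > P2[j]) {
      I[j] <- P1[j] - P2[j]
    } else {
      I[j] <- 0
    }
  }
  structure(
    list(P1 = P1, P2 = P2, I = I, W = sum(I) / L, window = window),
    class = "rps_interface_width"
  )
}
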