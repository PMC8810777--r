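#' Build a small exact lattice fixture
#'
#' Deterministic constructor for hand-checkable lattice states: a background
#' fill plus explicit placements.  Used throughout the tests so observables
#' can be verified without running simulations.
#'
#' @param L small even lattice side.
#' @param placements `data.frame` with columns `row`, `col`, `label`
#'   (labels "A1".."C2", "E", or codes 0..6); may be `NULL` for a uniform
#'   lattice.  Out-of-bounds or duplicated coordinates raise an error.
#' @param fill background label (default `"E"`).
#' @return an `rps_lattice` at generation 0.
#' @examples
#' fx <- make_fixture(6, data.frame(row = 5, col = 2, label = "A1"))
#' interface_width(fx, window = 1:6)$W
#' @export
make_fixture <- function(L, placements = NULL, fill = "E") {
  if (length(L) != 1 || L < 2 || L %% 2 != 0) stop("L must be a small even integer")
  fill_code <- if (is.numeric(fill)) as.integer(fill) else rps_code(fill)
  grid <- matrix(fill_code, L, L)
  if (!is.null(placements)) {
    placements <- as.data.frame(placements)
    if (!all(c("row", "col", "label") %in% names(placements))) {
      stop("placements needs columns row, col, label")
    }
    if (any(placements$row < 1 | placements$row > L |
      placements$col < 1 | placements$col > L)) {
      stop("placement out of bounds")
    }
    if (anyDuplicated(placements[, c("row", "col")]) > 0) {
      stop("duplicate placement coordinates")
    }
    codes <- if (is.numeric(placements$label)) {
      as.integer(placements$label)
    } else {
      rps_code(as.character(placements$label))
    }
    grid[cbind(placements$row, placements$col)] <- codes
  }
  storage.mode(grid) <- "integer"
  new_lattice(grid, 0L)
}

#' Build a scripted density trajectory
#'
#' Produces an object with the same densities contract as
#' [run_simulation()] output, from an explicit script of per-generation
#' counts — the test input for [extinction_time()].
#'
#' @param script `data.frame` with a strictly increasing `generation` column
#'   and counts `A1`, `A2`, `B1`, `B2`, `C1`, `C2` (an `E` column is optional
#'   and passed through).
#' @return an `rps_trajectory` with `status = "scripted"`.
#' @export
make_density_trajectory <- function(script) {
  script <- as.data.frame(script)
  need <- c("generation", "A1", "A2", "B1", "B2", "C1", "C2")
  if (!all(need %in% names(script))) {
    stop("script needs columns ", paste(need, collapse = ", "))
  }
  if (any(diff(script$generation) <= 0)) {
    stop("generations must be strictly increasing")
  }
  if (any(script[need[-1]] < 0)) stop("counts must be non-negative")
  if (!"E" %in% names(script)) script$E <- 0L
  structure(
    list(
      densities = script[, c(need, "E")],
      event_counts = NULL,
      status = "scripted",
      final_state = NULL,
      generation = max(script$generation),
      config = NULL
    ),
    class = "rps_trajectory"
  )
}
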