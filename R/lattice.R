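new_lattice <- function(grid, generation = 0L) {
  structure(
    list(grid = grid, L = nrow(grid), generation = as.integer(generation)),
    class = "rps_lattice"
  )
}

#' Draw the initial lattice
#'
#' Each site independently becomes a vacancy with probability
#' `config$empty_frac` (default 1/4) and otherwise holds one of the three
#' species uniformly, carrying the genus of its territory: genus 1 in the top
#' half (rows 1..L/2), genus 2 in the bottom half.  The draw is a
#' deterministic function of `config$seed` and identical to the
#' initialization performed inside [run_simulation()].
#'
#' @param config a validated [rps_config()].
#' @return an `rps_lattice`: integer L x L grid (site codes 0..6),
#'   `generation = 0`.
#' @export
init_lattice <- function(config) {
  if (!inherits(config, "rps_config")) config <- validate_config(config)
  grid <- rps_kernel_init(config$L, config$empty_frac, config$seed)
  new_lattice(grid, 0L)
}

#' @export
print.rps_lattice <- function(x, ...) {
  counts <- lattice_counts(x)
  cat(sprintf("rps_lattice: %d x %d, generation %d\n", x$L, x$L, x$generation))
  print(counts)
  invisible(x)
}

# named counts of the 7 site states
lattice_counts <- function(state) {
  tab <- tabulate(state$grid + 1L, nbins = 7L)
  setNames(tab, RPS_LABELS)
}

as_lattice <- function(x) {
  if (inherits(x, "rps_lattice")) return(x)
  if (is.matrix(x)) return(new_lattice(x))
  stop("expected an rps_lattice or an integer matrix of site codes")
}

#' Write a lattice as plain-text CSV (codes 0-6)
#'
#' One CSV row per lattice row, no header: the tiny-fixture codec.  A JSON
#' sidecar `<path>.json` records L and the generation so snapshots round-trip
#' exactly.
#'
#' @param state an `rps_lattice`.
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_lattice_csv <- function(state, path, sidecar = TRUE) {
  state <- as_lattice(state)
  write.table(state$grid, path,
    sep = ",", row.names = FALSE,
    col.names = FALSE
  )
  if (sidecar) {
    jsonlite::write_json(
      list(L = state$L, generation = state$generation, labels = RPS_LABELS),
      paste0(path, ".json"),
      auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' Read a lattice from plain-text CSV (codes 0-6)
#'
#' @param path CSV path written by [write_lattice_csv()].
#' @param generation generation counter to attach; if a JSON sidecar
#'   `<path>.json` exists its generation wins.
#' @return an `rps_lattice`.
#' @export
read_lattice_csv <- function(path, generation = 0L) {
  grid <- as.matrix(read.table(path, sep = ",", header = FALSE))
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  if (nrow(grid) != ncol(grid)) stop("lattice CSV must be square")
  if (any(grid < 0L | grid > 6L)) stop("site codes must be in 0..6")
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$generation)) generation <- meta$generation
    if (!is.null(meta$L) && meta$L != nrow(grid)) {
      stop("sidecar L does not match the CSV grid")
    }
  }
  new_lattice(grid, generation)
}
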