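STATUS_LABELS <- c(
  "0" = "completed", "1" = "single_label", "2" = "all_dead",
  "3" = "genus_loss", "4" = "two_species", "5" = "single_species"
)

STOP_MODES <- c(none = 0L, genus_loss = 1L, two_species = 2L, single_species = 3L)

#' Run a full Monte-Carlo simulation
#'
#' Initializes the lattice (unless `init` is given) and iterates generations
#' of N pairwise interaction attempts until `config$T_max` or an early-stop
#' condition.  A run is a deterministic function of the validated config:
#' all draws (initialization, actor, neighbour direction, event type,
#' intraspecific loser) come from one generator seeded with `config$seed`,
#' consumed in that fixed order.
#'
#' Runs always stop early once at most one label remains alive (no further
#' event can change the label composition qualitatively; densities for the
#' remaining generations are constant).  `stop_when` adds an observable-
#' driven stop used by the extinction experiments so runs do not simulate
#' past the measured event.
#'
#' @param config a validated [rps_config()].
#' @param init optional `rps_lattice` (or integer code matrix) to start from
#'   instead of the seeded random initialization.
#' @param stop_when extra early-stop condition: `"none"`, `"genus_loss"`
#'   (every species has lost at least one genus — the low-mobility extinction
#'   event), `"two_species"` (two whole species gone — the high-mobility
#'   event), or `"single_species"` (at most one species left — phase scans).
#' @param snapshots_at generations at which to keep full lattice snapshots.
#' @return an `rps_trajectory`: `densities` (data.frame with columns
#'   generation, A1..C2, E recorded every `record_every` generations plus
#'   generation 0 and the final generation), `event_counts` (attempted and
#'   applied totals per event type), `status`, `final_state`, `snapshots`,
#'   and the `config`.
#' @examples
#' cfg <- rps_config(L = 50, M = 1e-5, k = 2, T_max = 100, seed = 7,
#'                   record_every = 10)
#' traj <- run_simulation(cfg)
#' tail(traj$densities)
#' @export
run_simulation <- function(config, init = NULL,
                           stop_when = c("none", "genus_loss", "two_species",
                                         "single_species"),
                           snapshots_at = integer(0)) {
  if (!inherits(config, "rps_config")) config <- validate_config(config)
  stop_when <- match.arg(stop_when)
  init_grid <- if (is.null(init)) NULL else as_lattice(init)$grid
  if (!is.null(init_grid)) storage.mode(init_grid) <- "integer"

  res <- rps_kernel_run(
    init_grid, config$L, config$empty_frac, event_prob_matrix(config),
    config$intraspecific_mode == "traditional", config$T_max,
    config$record_every, config$seed, STOP_MODES[[stop_when]],
    config$actor_sampling == "site", as.integer(snapshots_at)
  )

  dens <- as.data.frame(res$densities)
  # kernel column order: generation, E, A1, A2, B1, B2, C1, C2
  names(dens) <- c("generation", RPS_LABELS)
  dens <- dens[, c("generation", "A1", "A2", "B1", "B2", "C1", "C2", "E")]

  ev <- data.frame(
    event = c("interspecific", "intraspecific", "reproduction", "migration"),
    attempted = res$attempted, applied = res$applied
  )

  snaps <- lapply(seq_along(res$snapshots), function(i) {
    new_lattice(res$snapshots[[i]], res$snapshot_gens[i])
  })

  structure(
    list(
      densities = dens,
      event_counts = ev,
      empty_actor_attempts = res$empty_actor_attempts,
      status = STATUS_LABELS[[as.character(res$status)]],
      final_state = new_lattice(res$final_grid, res$generation),
      generation = res$generation,
      snapshots = snaps,
      config = config
    ),
    class = "rps_trajectory"
  )
}

#' @export
print.rps_trajectory <- function(x, ...) {
  cat(sprintf(
    "rps_trajectory: L=%d, %d generations (status: %s), %d density records\n",
    x$config$L, x$generation, x$status, nrow(x$densities)
  ))
  print(utils::tail(x$densities, 1))
  invisible(x)
}

#' Advance a lattice by one generation
#'
#' Performs exactly N = L*L pairwise interaction attempts (failed reactions
#' count) and increments the generation counter.  The draws come from a fresh
#' generator seeded with `seed`, so the result is reproducible; composing
#' [step_generation()] calls with distinct seeds is *not* the same stream as
#' one [run_simulation()] call.
#'
#' @param state an `rps_lattice`.
#' @param config a validated [rps_config()] (rates and mode; `T_max` ignored).
#' @param seed seed for this generation's draws; defaults to
#'   `config$seed + generation` so successive calls differ.
#' @return a list: `state` (the advanced `rps_lattice`), `status`, and
#'   `event_counts` for the generation.
#' @export
step_generation <- function(state, config, seed = NULL) {
  if (!inherits(config, "rps_config")) config <- validate_config(config)
  state <- as_lattice(state)
  if (nrow(state$grid) != config$L) stop("state and config disagree on L")
  if (is.null(seed)) seed <- config$seed + state$generation
  grid <- state$grid
  storage.mode(grid) <- "integer"
  res <- rps_kernel_run(
    grid, config$L, config$empty_frac, event_prob_matrix(config),
    config$intraspecific_mode == "traditional", 1L, 1L, seed, 0L,
    config$actor_sampling == "site", integer(0)
  )
  list(
    state = new_lattice(res$final_grid, state$generation + res$generation),
    status = STATUS_LABELS[[as.character(res$status)]],
    event_counts = data.frame(
      event = c("interspecific", "intraspecific", "reproduction", "migration"),
      attempted = res$attempted, applied = res$applied
    ),
    empty_actor_attempts = res$empty_actor_attempts
  )
}

#' Attempt a single forced pair event
#'
#' Applies one drawn event type to an adjacent (actor, neighbour) pair under
#' the reaction rules: interspecific predation kills the neighbour if the
#' actor's species beats it in the cycle A > B > C > A; intraspecific
#' competition kills one of the two uniformly if they are the same species
#' (and, in territorial mode, of different genera); reproduction copies the
#' actor into a vacant neighbour; migration exchanges the two sites
#' unconditionally.  Any other pairing fails and leaves the grid untouched.
#'
#' @param state an `rps_lattice` (or integer code matrix).
#' @param actor,neighbor integer vectors `c(row, col)`, 1-based; must be von
#'   Neumann adjacent under periodic wrap and the actor must be occupied.
#' @param event_type one of `"interspecific"`, `"intraspecific"`,
#'   `"reproduction"`, `"migration"`.
#' @param intraspecific_mode `"territorial"` or `"traditional"`.
#' @param u_loser number in [0,1) resolving the intraspecific coin
#'   (`< 0.5` kills the actor); drawn from R's RNG when `NULL`.
#' @return an `rps_event_outcome`: `event_type`, `applied`, `sites_changed`
#'   (0-2 rows of (row, col)), and the resulting `state`.
#' @export
attempt_pair_event <- function(state, actor, neighbor, event_type,
                               intraspecific_mode = c("territorial", "traditional"),
                               u_loser = NULL) {
  state <- as_lattice(state)
  intraspecific_mode <- match.arg(intraspecific_mode)
  ev <- match(
    match.arg(event_type, c(
      "interspecific", "intraspecific",
      "reproduction", "migration"
    )),
    c("interspecific", "intraspecific", "reproduction", "migration")
  ) - 1L
  if (is.null(u_loser)) u_loser <- runif(1)
  grid <- state$grid
  storage.mode(grid) <- "integer"
  res <- rps_kernel_event(
    grid, actor[1], actor[2], neighbor[1], neighbor[2],
    ev, intraspecific_mode == "traditional", u_loser
  )
  changed <- res$sites_changed
  colnames(changed) <- c("row", "col")
  structure(
    list(
      event_type = event_type, applied = res$applied,
      sites_changed = changed,
      state = new_lattice(res$grid, state$generation)
    ),
    class = "rps_event_outcome"
  )
}
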