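# dynamics: single pair events, generation stepping, full runs

test_that("attempt_pair_event applies the reaction rules", {
  # two adjacent occupied sites in a 4x4 lattice
  base <- make_fixture(4, data.frame(
    row = c(2, 2), col = c(2, 3),
    label = c("A1", "B2")
  ))

  # interspecific: A beats B across genera; the loser's site empties
  out <- attempt_pair_event(base, c(2, 2), c(2, 3), "interspecific")
  expect_true(out$applied)
  expect_equal(out$state$grid[2, 3], 0)
  expect_equal(out$state$grid[2, 2], 1)
  expect_equal(nrow(out$sites_changed), 1)

  # the cycle is directional: B does not beat A
  rev <- attempt_pair_event(base, c(2, 3), c(2, 2), "interspecific")
  expect_false(rev$applied)
  expect_identical(rev$state$grid, base$grid)

  # C beats A
  ca <- make_fixture(4, data.frame(row = c(1, 1), col = c(1, 2), label = c("C2", "A1")))
  expect_true(attempt_pair_event(ca, c(1, 1), c(1, 2), "interspecific")$applied)

  # intraspecific in territorial mode needs different genera
  same <- make_fixture(4, data.frame(row = c(2, 2), col = c(2, 3), label = c("A1", "A1")))
  expect_false(attempt_pair_event(same, c(2, 2), c(2, 3), "intraspecific")$applied)
  # ... but fires in traditional mode, killing one of the two
  trad <- attempt_pair_event(same, c(2, 2), c(2, 3), "intraspecific",
    intraspecific_mode = "traditional", u_loser = 0.7
  )
  expect_true(trad$applied)
  expect_equal(trad$state$grid[2, 3], 0) # u >= 0.5: neighbour dies
  trad2 <- attempt_pair_event(same, c(2, 2), c(2, 3), "intraspecific",
    intraspecific_mode = "traditional", u_loser = 0.2
  )
  expect_equal(trad2$state$grid[2, 2], 0) # u < 0.5: actor dies

  # cross-genus pair fires in territorial mode too
  cross <- make_fixture(4, data.frame(row = c(2, 2), col = c(2, 3), label = c("A1", "A2")))
  hit <- attempt_pair_event(cross, c(2, 2), c(2, 3), "intraspecific", u_loser = 0.9)
  expect_true(hit$applied)
  expect_equal(hit$state$grid[2, 3], 0)

  # reproduction copies the actor (genus inherited) into a vacancy only
  rep1 <- make_fixture(4, data.frame(row = 3, col = 3, label = "C2"))
  off <- attempt_pair_event(rep1, c(3, 3), c(3, 4), "reproduction")
  expect_true(off$applied)
  expect_equal(off$state$grid[3, 4], 6) # C2: offspring inherits the genus
  full <- make_fixture(4, data.frame(row = c(3, 3), col = c(3, 4), label = c("A1", "C2")))
  expect_false(attempt_pair_event(full, c(3, 3), c(3, 4), "reproduction")$applied)

  # migration exchanges contents unconditionally (species or vacancy)
  mig <- attempt_pair_event(full, c(3, 3), c(3, 4), "migration")
  expect_true(mig$applied)
  expect_equal(mig$state$grid[3, 3], 6)
  expect_equal(mig$state$grid[3, 4], 1)

  # periodic wrap adjacency is honoured; non-adjacent pairs are an error
  wrap <- make_fixture(4, data.frame(row = c(1, 4), col = c(1, 1), label = c("A1", "E")))
  expect_true(attempt_pair_event(wrap, c(1, 1), c(4, 1), "reproduction")$applied)
  expect_error(
    attempt_pair_event(base, c(2, 2), c(4, 4), "interspecific"),
    "adjacent"
  )
  expect_error(
    attempt_pair_event(base, c(1, 1), c(1, 2), "interspecific"),
    "empty"
  )
})

test_that("step_generation performs N attempts and conserves sites", {
  cfg <- quick_config(L = 10, M = 1e-3, k = 2, seed = 9)
  lat <- init_lattice(cfg)
  stepped <- step_generation(lat, cfg, seed = 101)
  expect_equal(stepped$state$generation, 1)
  # exactly N = 100 attempts: drawn events plus wasted empty-actor draws
  expect_equal(
    sum(stepped$event_counts$attempted) + stepped$empty_actor_attempts, 100
  )
  expect_equal(length(stepped$state$grid), 100)
  # reproducible for a fixed seed
  again <- step_generation(lat, cfg, seed = 101)
  expect_identical(again$state$grid, stepped$state$grid)
})

test_that("migration-only dynamics conserve occupancy (random walkers)", {
  # two individuals so the single-label early stop does not trigger;
  # p1 = p2 = r = 0 leaves pure migration
  pair <- make_fixture(6, data.frame(
    row = c(2, 5), col = c(2, 5),
    label = c("B1", "A2")
  ))
  cfg <- rps_config(L = 6, M = 10, k = 0, p1 = 0, p2 = 0, r = 0, T_max = 20, seed = 4)
  traj <- run_simulation(cfg, init = pair)
  counts <- summarize_lattice(traj$final_state)$counts
  expect_equal(unname(counts["B1"]), 1)
  expect_equal(unname(counts["A2"]), 1)
  expect_equal(sum(counts), 36)
  expect_equal(traj$generation, 20)
  # the walkers moved with overwhelming probability over 720 attempts
  expect_false(identical(traj$final_state$grid, pair$grid))
})

test_that("single-label early stop freezes the run immediately", {
  lone <- make_fixture(6, data.frame(row = 2, col = 2, label = "B1"))
  cfg <- rps_config(L = 6, M = 10, T_max = 20, seed = 4)
  traj <- run_simulation(cfg, init = lone)
  expect_equal(traj$status, "single_label")
  expect_equal(traj$generation, 0)
})

test_that("r = 0 makes total occupancy non-increasing", {
  cfg <- rps_config(
    L = 20, M = 1e-3, k = 3, r = 0, T_max = 100,
    seed = 12, record_every = 1
  )
  traj <- run_simulation(cfg)
  occ <- occupied_total(traj$densities)
  expect_true(all(diff(occ) <= 0))
})

test_that("site count is conserved and every density row sums to N", {
  cfg <- quick_config(L = 16, M = 1e-3, k = 4, T_max = 80, seed = 21, record_every = 1)
  traj <- run_simulation(cfg)
  sums <- rowSums(traj$densities[, -1])
  expect_true(all(sums == 256))
})

test_that("k = 0 fires zero intraspecific events in either mode", {
  for (mode in c("territorial", "traditional")) {
    cfg <- rps_config(
      L = 30, M = 1e-4, k = 0, T_max = 150, seed = 31,
      intraspecific_mode = mode, record_every = 50
    )
    traj <- run_simulation(cfg)
    ev <- traj$event_counts
    expect_equal(ev$attempted[ev$event == "intraspecific"], 0)
    expect_equal(ev$applied[ev$event == "intraspecific"], 0)
  }
})

test_that("k = 0 makes territorial and traditional modes identical runs", {
  cfg_t <- rps_config(L = 24, M = 1e-4, k = 0, T_max = 120, seed = 55, record_every = 10)
  cfg_d <- rps_config(
    L = 24, M = 1e-4, k = 0, T_max = 120, seed = 55, record_every = 10,
    intraspecific_mode = "traditional"
  )
  a <- run_simulation(cfg_t)
  b <- run_simulation(cfg_d)
  expect_identical(a$densities, b$densities)
  expect_identical(a$final_state$grid, b$final_state$grid)
})

test_that("high mobility makes migration dominate the event mix", {
  # m = 2 M N must dwarf p1 + k p2 + r = 3: M = 0.2, L = 30 gives m = 360
  cfg <- rps_config(L = 30, M = 0.2, k = 1, T_max = 30, seed = 77, record_every = 10)
  p_migr <- event_probabilities(cfg)[["migration"]]
  expect_gt(p_migr, 0.99)
  traj <- run_simulation(cfg)
  ev <- traj$event_counts
  frac <- ev$attempted[ev$event == "migration"] / sum(ev$attempted)
  # binomial expectation check against the drawn probability
  n <- sum(ev$attempted)
  expect_lt(abs(frac - p_migr), 4 * sqrt(p_migr * (1 - p_migr) / n) + 1e-3)
})

test_that("identical config and seed reproduce the trajectory exactly", {
  cfg <- quick_config(L = 26, M = 1e-4, k = 6, T_max = 150, seed = 1234, record_every = 1)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$densities, b$densities)
  expect_identical(a$final_state$grid, b$final_state$grid)
  expect_identical(a$event_counts, b$event_counts)
  # occupied-actor sampling variant is deterministic too, and distinct
  cfg_occ <- quick_config(
    L = 26, M = 1e-4, k = 6, T_max = 150, seed = 1234,
    record_every = 1, actor_sampling = "occupied"
  )
  c1 <- run_simulation(cfg_occ)
  c2 <- run_simulation(cfg_occ)
  expect_identical(c1$densities, c2$densities)
  expect_false(identical(a$densities, c1$densities))
})

test_that("an all-empty lattice reports all_dead instead of looping", {
  empty <- make_fixture(6)
  cfg <- rps_config(L = 6, M = 1e-3, T_max = 10, seed = 2)
  traj <- run_simulation(cfg, init = empty)
  expect_equal(traj$status, "all_dead")
  expect_equal(summarize_lattice(traj$final_state)$state_label, "all_dead")
})

test_that("snapshots are captured at the requested generations", {
  cfg <- quick_config(L = 12, M = 1e-3, k = 1, T_max = 40, seed = 6, record_every = 5)
  traj <- run_simulation(cfg, snapshots_at = c(10, 25))
  expect_equal(length(traj$snapshots), 2)
  expect_equal(vapply(traj$snapshots, function(s) s$generation, numeric(1)), c(10, 25))
  expect_equal(
    unname(summarize_lattice(traj$snapshots[[1]])$counts %*% rep(1, 7))[1], 144
  )
})
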