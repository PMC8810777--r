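# shared helpers: tiny configs and randomized fixtures built in code

quick_config <- function(L = 20, M = 1e-4, k = 1, T_max = 50, seed = 1, ...) {
  rps_config(L = L, M = M, k = k, T_max = T_max, seed = seed, ...)
}

# random lattice with arbitrary label mixing (not territory-respecting),
# for observable stress tests
random_fixture <- function(L, p_empty = 0.3, generation = 0L) {
  codes <- sample(0:6, L * L,
    replace = TRUE,
    prob = c(p_empty, rep((1 - p_empty) / 6, 6))
  )
  make_fixture(L, data.frame(
    row = rep(seq_len(L), L),
    col = rep(seq_len(L), each = L),
    label = codes
  ))
}

# total occupancy from a densities row
occupied_total <- function(dens) {
  rowSums(dens[, c("A1", "A2", "B1", "B2", "C1", "C2")])
}

expect_same_width <- function(state, window = NULL) {
  a <- interface_width(state, window = window)
  b <- interface_width_oracle(state, window = window)
  expect_identical(a$P1, b$P1)
  expect_identical(a$P2, b$P2)
  expect_equal(a$I, b$I)
  expect_equal(a$W, b$W)
}
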