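// Monte-Carlo kernel for the territorial rock-paper-scissors lattice game.
//
// Site codes: 0 = E (empty), 1 = A1, 2 = A2, 3 = B1, 4 = B2, 5 = C1, 6 = C2.
// Grids are L x L integer matrices (column-major, as in R); rows are indexed
// top to bottom, territory 1 is the top half (rows 1..L/2).
//
// All randomness flows through one xoshiro256++ stream per call, seeded via
// splitmix64 from a user seed, so a run is replayable bit-for-bit.  Draw
// order per attempt: actor, neighbour direction, event type, then (only for
// an applicable intraspecific event) the loser coin.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer in [0, n), unbiased enough for n << 2^64
  uint32_t bounded(uint32_t n) {
    return (uint32_t)(((__uint128_t)next() * n) >> 64);
  }
};

inline int species_of(int code) { return (code - 1) / 2; }  // 0=A,1=B,2=C
inline int genus_of(int code) { return (code - 1) % 2; }    // 0=genus 1

// Action resulting from drawing event `ev` (0=inter,1=intra,2=repro,3=migr)
// for actor code ca against neighbour code cb.  u_loser resolves the
// intraspecific coin.  Returns 0 = reaction fails, 1 = neighbour dies,
// 2 = actor dies, 3 = neighbour becomes copy of actor, 4 = swap contents.
inline int decide_event(int ca, int cb, int ev, bool traditional,
                        double u_loser) {
  switch (ev) {
  case 0:  // interspecific: cyclic A > B > C > A, any genus pairing
    if (cb == 0) return 0;
    {
      int sa = species_of(ca), sb = species_of(cb);
      if (sa != sb && (sa + 1) % 3 == sb) return 1;
    }
    return 0;
  case 1:  // intraspecific: same species; territorial mode needs i != j
    if (cb == 0) return 0;
    {
      int sa = species_of(ca), sb = species_of(cb);
      if (sa == sb && (traditional || genus_of(ca) != genus_of(cb)))
        return (u_loser < 0.5) ? 2 : 1;
    }
    return 0;
  case 2:  // reproduction needs a vacancy; offspring inherits the genus
    return cb == 0 ? 3 : 0;
  case 3:  // migration: unconditional exchange with species or vacancy
    return 4;
  }
  return 0;
}

inline bool stop_single_label(const int *counts, int &alive_code) {
  int n_alive = 0;
  alive_code = 0;
  for (int c = 1; c <= 6; ++c)
    if (counts[c] > 0) { ++n_alive; alive_code = c; }
  return n_alive <= 1;
}

inline bool stop_genus_loss(const int *counts) {
  for (int s = 0; s < 3; ++s)
    if (counts[2 * s + 1] > 0 && counts[2 * s + 2] > 0) return false;
  return true;
}

inline bool stop_two_species(const int *counts) {
  int n_dead = 0;
  for (int s = 0; s < 3; ++s)
    if (counts[2 * s + 1] + counts[2 * s + 2] == 0) ++n_dead;
  return n_dead >= 2;
}

inline bool stop_single_species(const int *counts) {
  int n_alive = 0;
  for (int s = 0; s < 3; ++s)
    if (counts[2 * s + 1] + counts[2 * s + 2] > 0) ++n_alive;
  return n_alive <= 1;
}

}  // namespace

// Run the Monte-Carlo dynamics.  If `init` is NULL the lattice is drawn from
// the same stream (territory-appropriate label or vacancy per site, vacancy
// probability empty_frac, species uniform).  One generation = N pairwise
// attempts; failed reactions consume an attempt.
//
// probs: 3 x 4 matrix of event probabilities (rows = actor species A, B, C;
// columns = interspecific, intraspecific, reproduction, migration).
// stop_mode: 0 none, 1 stop when every species has lost a genus, 2 stop when
// two whole species are gone, 3 stop when at most one species remains.
// Runs always stop when at most one label remains alive.  actor_all_sites:
// draw the actor among all sites (an empty actor wastes the attempt) instead
// of among occupied sites.
//
// Status codes: 0 = ran to n_gens, 1 = single label left, 2 = all dead,
// 3 = genus-loss stop, 4 = two-species stop, 5 = single-species stop.
// [[Rcpp::export]]
List rps_kernel_run(Nullable<IntegerMatrix> init, int L, double empty_frac,
                    NumericMatrix probs, bool traditional, int n_gens,
                    int record_every, double seed, int stop_mode,
                    bool actor_all_sites, IntegerVector snapshot_at) {
  const int N = L * L;
  Xoshiro256pp rng((uint64_t)(int64_t)seed);

  std::vector<int> grid(N);
  int counts[7] = {0, 0, 0, 0, 0, 0, 0};

  if (init.isNotNull()) {
    IntegerMatrix g(init.get());
    if (g.nrow() != L || g.ncol() != L) stop("init grid must be L x L");
    for (int i = 0; i < N; ++i) {
      grid[i] = g[i];
      if (grid[i] < 0 || grid[i] > 6) stop("invalid site code in init grid");
      ++counts[grid[i]];
    }
  } else {
    // column-major site order; territory decided by row
    for (int i = 0; i < N; ++i) {
      int row = i % L;
      int genus = (row < L / 2) ? 0 : 1;  // genus 1 on top
      if (rng.unif() < empty_frac) {
        grid[i] = 0;
      } else {
        int sp = (int)rng.bounded(3);
        grid[i] = 2 * sp + 1 + genus;
      }
      ++counts[grid[i]];
    }
  }

  // occupied-site list with O(1) sample / insert / delete
  std::vector<int> occ;
  occ.reserve(N);
  std::vector<int> pos(N, -1);
  for (int i = 0; i < N; ++i)
    if (grid[i] != 0) { pos[i] = (int)occ.size(); occ.push_back(i); }

  // cumulative event probabilities per actor species
  double cum[3][4];
  for (int s = 0; s < 3; ++s) {
    double acc = 0.0;
    for (int e = 0; e < 4; ++e) { acc += probs(s, e); cum[s][e] = acc; }
    if (acc > 1.0 + 1e-9) stop("event probabilities exceed 1");
  }

  auto occ_remove = [&](int site) {
    int p = pos[site];
    int last = occ.back();
    occ[p] = last;
    pos[last] = p;
    occ.pop_back();
    pos[site] = -1;
  };
  auto occ_add = [&](int site) {
    pos[site] = (int)occ.size();
    occ.push_back(site);
  };

  std::vector<int> rec;  // rows of (generation, counts[0..6])
  auto record = [&](int gen) {
    rec.push_back(gen);
    for (int c = 0; c < 7; ++c) rec.push_back(counts[c]);
  };
  record(0);

  long long attempted[4] = {0, 0, 0, 0};
  long long applied[4] = {0, 0, 0, 0};
  long long empty_actor = 0;

  std::vector<int> snaps(snapshot_at.begin(), snapshot_at.end());
  std::sort(snaps.begin(), snaps.end());
  size_t snap_i = 0;
  List snap_grids;
  IntegerVector snap_gens;

  int status = 0;
  int alive_code = 0;
  int gen = 0;
  int last_recorded = 0;

  {
    int dummy;
    if (stop_single_label(counts, dummy)) {
      status = (occ.empty()) ? 2 : 1;
      goto done;
    }
  }

  for (gen = 1; gen <= n_gens; ++gen) {
    for (int att = 0; att < N; ++att) {
      if (occ.empty()) { status = 2; goto done; }
      int a;
      if (actor_all_sites) {
        a = (int)rng.bounded((uint32_t)N);
        // direction drawn even for a wasted attempt keeps the documented
        // fixed draw order (actor, direction, event, loser)
        int dir_waste = (int)rng.bounded(4);
        (void)dir_waste;
        if (grid[a] == 0) { ++empty_actor; continue; }
        // re-use dir_waste as the direction below
        int row = a % L, col = a / L, nb;
        switch (dir_waste) {
        case 0: nb = (row == 0) ? a + L - 1 : a - 1; break;
        case 1: nb = (row == L - 1) ? a - L + 1 : a + 1; break;
        case 2: nb = (col == 0) ? a + N - L : a - L; break;
        default: nb = (col == L - 1) ? a - N + L : a + L; break;
        }
        int ca = grid[a];
        int sa = species_of(ca);
        double u = rng.unif();
        int ev = 3;
        if (u < cum[sa][0]) ev = 0;
        else if (u < cum[sa][1]) ev = 1;
        else if (u < cum[sa][2]) ev = 2;
        else if (u >= cum[sa][3]) { continue; }  // no-event tail (never hit)
        ++attempted[ev];
        double ul = 0.0;
        if (ev == 1) {
          int cb = grid[nb];
          if (cb != 0 && species_of(cb) == sa &&
              (traditional || genus_of(ca) != genus_of(cb)))
            ul = rng.unif();
        }
        int act = decide_event(ca, grid[nb], ev, traditional, ul);
        if (act == 0) continue;
        ++applied[ev];
        switch (act) {
        case 1: --counts[grid[nb]]; ++counts[0]; grid[nb] = 0; occ_remove(nb); break;
        case 2: --counts[ca]; ++counts[0]; grid[a] = 0; occ_remove(a); break;
        case 3: grid[nb] = ca; ++counts[ca]; --counts[0]; occ_add(nb); break;
        case 4: {
          int cb = grid[nb];
          grid[a] = cb; grid[nb] = ca;
          if (cb == 0) { occ[pos[a]] = nb; pos[nb] = pos[a]; pos[a] = -1; }
          break;
        }
        }
        continue;
      }
      // default: actor uniform among occupied sites
      a = occ[rng.bounded((uint32_t)occ.size())];
      int dir = (int)rng.bounded(4);
      int row = a % L, col = a / L, nb;
      switch (dir) {
      case 0: nb = (row == 0) ? a + L - 1 : a - 1; break;          // up
      case 1: nb = (row == L - 1) ? a - L + 1 : a + 1; break;      // down
      case 2: nb = (col == 0) ? a + N - L : a - L; break;          // left
      default: nb = (col == L - 1) ? a - N + L : a + L; break;     // right
      }
      int ca = grid[a];
      int sa = species_of(ca);
      double u = rng.unif();
      int ev;
      if (u < cum[sa][0]) ev = 0;
      else if (u < cum[sa][1]) ev = 1;
      else if (u < cum[sa][2]) ev = 2;
      else ev = 3;
      ++attempted[ev];
      double ul = 0.0;
      if (ev == 1) {
        int cb = grid[nb];
        if (cb != 0 && species_of(cb) == sa &&
            (traditional || genus_of(ca) != genus_of(cb)))
          ul = rng.unif();
      }
      int act = decide_event(ca, grid[nb], ev, traditional, ul);
      if (act == 0) continue;
      ++applied[ev];
      switch (act) {
      case 1: --counts[grid[nb]]; ++counts[0]; grid[nb] = 0; occ_remove(nb); break;
      case 2: --counts[ca]; ++counts[0]; grid[a] = 0; occ_remove(a); break;
      case 3: grid[nb] = ca; ++counts[ca]; --counts[0]; occ_add(nb); break;
      case 4: {
        int cb = grid[nb];
        grid[a] = cb; grid[nb] = ca;
        if (cb == 0) { occ[pos[a]] = nb; pos[nb] = pos[a]; pos[a] = -1; }
        break;
      }
      }
    }

    if (gen % record_every == 0) { record(gen); last_recorded = gen; }

    while (snap_i < snaps.size() && snaps[snap_i] <= gen) {
      if (snaps[snap_i] == gen) {
        IntegerMatrix g(L, L);
        std::copy(grid.begin(), grid.end(), g.begin());
        snap_grids.push_back(g);
        snap_gens.push_back(gen);
      }
      ++snap_i;
    }

    if (stop_single_label(counts, alive_code)) {
      status = occ.empty() ? 2 : 1;
      break;
    }
    if (stop_mode == 1 && stop_genus_loss(counts)) { status = 3; break; }
    if (stop_mode == 2 && stop_two_species(counts)) { status = 4; break; }
    if (stop_mode == 3 && stop_single_species(counts)) { status = 5; break; }
  }
  if (gen > n_gens) gen = n_gens;

done:
  if (last_recorded != gen) record(gen);

  int n_rows = (int)rec.size() / 8;
  IntegerMatrix dens(n_rows, 8);
  for (int i = 0; i < n_rows; ++i)
    for (int j = 0; j < 8; ++j) dens(i, j) = rec[i * 8 + j];

  IntegerMatrix final_grid(L, L);
  std::copy(grid.begin(), grid.end(), final_grid.begin());

  NumericVector att_v(4), app_v(4);
  for (int e = 0; e < 4; ++e) { att_v[e] = (double)attempted[e]; app_v[e] = (double)applied[e]; }

  return List::create(
      _["densities"] = dens, _["final_grid"] = final_grid,
      _["generation"] = gen, _["status"] = status,
      _["attempted"] = att_v, _["applied"] = app_v,
      _["empty_actor_attempts"] = (double)empty_actor,
      _["snapshots"] = snap_grids, _["snapshot_gens"] = snap_gens);
}

// Apply one forced event to a pair of sites; the test-facing twin of the
// kernel's inner step.  Coordinates are 1-based.  u_loser resolves the
// intraspecific coin (< 0.5 kills the actor).
// [[Rcpp::export]]
List rps_kernel_event(IntegerMatrix grid, int actor_row, int actor_col,
                      int nb_row, int nb_col, int event_type, bool traditional,
                      double u_loser) {
  int L = grid.nrow();
  if (grid.ncol() != L) stop("grid must be square");
  auto wrapdist = [L](int a, int b) {
    int d = std::abs(a - b);
    return std::min(d, L - d);
  };
  if (wrapdist(actor_row, nb_row) + wrapdist(actor_col, nb_col) != 1)
    stop("actor and neighbor must be von Neumann adjacent under periodic wrap");
  int ca = grid(actor_row - 1, actor_col - 1);
  int cb = grid(nb_row - 1, nb_col - 1);
  if (ca == 0) stop("actor site is empty");
  if (event_type < 0 || event_type > 3) stop("invalid event type");

  int act = decide_event(ca, cb, event_type, traditional, u_loser);
  IntegerMatrix out = clone(grid);
  IntegerMatrix changed(0, 2);
  if (act == 1) {
    out(nb_row - 1, nb_col - 1) = 0;
    changed = IntegerMatrix(1, 2);
    changed(0, 0) = nb_row; changed(0, 1) = nb_col;
  } else if (act == 2) {
    out(actor_row - 1, actor_col - 1) = 0;
    changed = IntegerMatrix(1, 2);
    changed(0, 0) = actor_row; changed(0, 1) = actor_col;
  } else if (act == 3) {
    out(nb_row - 1, nb_col - 1) = ca;
    changed = IntegerMatrix(1, 2);
    changed(0, 0) = nb_row; changed(0, 1) = nb_col;
  } else if (act == 4) {
    out(actor_row - 1, actor_col - 1) = cb;
    out(nb_row - 1, nb_col - 1) = ca;
    if (ca != cb) {
      changed = IntegerMatrix(2, 2);
      changed(0, 0) = actor_row; changed(0, 1) = actor_col;
      changed(1, 0) = nb_row; changed(1, 1) = nb_col;
    }
  }
  return List::create(_["applied"] = act != 0, _["grid"] = out,
                      _["sites_changed"] = changed);
}

// Draw an initial lattice on its own stream (init_lattice contract: same
// seed, same grid; identical to the in-run initialization draw order).
// [[Rcpp::export]]
IntegerMatrix rps_kernel_init(int L, double empty_frac, double seed) {
  Xoshiro256pp rng((uint64_t)(int64_t)seed);
  IntegerMatrix g(L, L);
  int N = L * L;
  for (int i = 0; i < N; ++i) {
    int row = i % L;
    int genus = (row < L / 2) ? 0 : 1;
    if (rng.unif() < empty_frac) g[i] = 0;
    else g[i] = 2 * (int)rng.bounded(3) + 1 + genus;
  }
  return g;
}
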