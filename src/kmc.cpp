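// Kinetic Monte Carlo core: confined phantom bead-spring polymer on a simple
// cubic lattice coupled to a protein hopping on the surface sites of the box.
// The master equation is sampled exactly with a null-event (rejection) scheme:
// every candidate move carries a constant rate cap, waiting times are
// exponential in the total cap, and a drawn candidate is executed with
// probability (true rate)/(cap).  Thinned events advance time but change
// nothing, which reproduces Gillespie sampling of the full rate table.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Portable counter-seeded RNG (splitmix64 -> xoshiro256++).  Each simulation
// run gets its own stream derived from (master seed, run index) so ensembles
// are reproducible independently of scheduling or call order.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  inline double expo() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return -std::log(u);
  }
  inline int below(int n) { return (int)(unif() * n); }
};

static inline uint64_t mix_seed(uint64_t master, uint64_t run) {
  uint64_t z = master * 0x9e3779b97f4a7c15ULL + run + 0x632be59bd9b4e019ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};

static inline bool in_box(int x, int y, int z, int L) {
  return x >= 0 && x < L && y >= 0 && y < L && z >= 0 && z < L;
}
static inline bool on_surface(int x, int y, int z, int L) {
  return x == 0 || x == L - 1 || y == 0 || y == L - 1 || z == 0 || z == L - 1;
}

// Harmonic bond energy in kBT; distances in lattice units.
static inline double bond_energy(int dx, int dy, int dz, double ks, double b) {
  double d = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
  double e = d - b;
  return ks * e * e;
}

struct Chain {
  std::vector<int> x, y, z;
  int n;
  bool ring;
  double ks, b;
  Chain(int n_, bool ring_, double ks_, double b_)
    : x(n_), y(n_), z(n_), n(n_), ring(ring_), ks(ks_), b(b_) {}

  double total_energy() const {
    double u = 0.0;
    int nb = ring ? n : n - 1;
    for (int i = 0; i < nb; ++i) {
      int j = (i + 1) % n;
      u += bond_energy(x[j] - x[i], y[j] - y[i], z[j] - z[i], ks, b);
    }
    return u;
  }

  // Energy change when bead i moves to (nx, ny, nz): only its (at most two)
  // bonds are affected.
  double delta_u(int i, int nx, int ny, int nz) const {
    double du = 0.0;
    if (n == 1) return 0.0;
    int nbr[2];
    int m = 0;
    if (ring) {
      nbr[m++] = (i + n - 1) % n;
      nbr[m++] = (i + 1) % n;
      if (n == 2) m = 1;  // a 2-ring has a single distinct neighbour
    } else {
      if (i > 0) nbr[m++] = i - 1;
      if (i < n - 1) nbr[m++] = i + 1;
    }
    for (int k = 0; k < m; ++k) {
      int j = nbr[k];
      du += bond_energy(nx - x[j], ny - y[j], nz - z[j], ks, b)
          - bond_energy(x[i] - x[j], y[i] - y[j], z[i] - z[j], ks, b);
    }
    return du;
  }
};

// Lay the chain down as a lattice random walk, growing in both directions
// from an anchor bead; steps that would leave the allowed region are
// resampled.  With bounds lo > hi the walk is unconfined (free chain).
// For a ring the walk is a kinetic bridge: each step is additionally
// resampled until closure remains feasible (the last bead must end one
// lattice step from the anchor), so the initial state has no stretched
// closing bond.
static void init_chain_walk(Chain &c, int lo, int hi, int anchor,
                            int ax, int ay, int az, Xoshiro &rng) {
  c.x[anchor] = ax; c.y[anchor] = ay; c.z[anchor] = az;
  // closure target: final L1 distance to the anchor (rings only); a ring
  // with an odd bead count cannot close at distance 1, so aim for 0 there
  // (a zero-length bond costs only ks*b^2 and relaxes immediately)
  const bool bridge = c.ring && c.n > 2;
  const int target = bridge ? (c.n % 2 == 0 ? 1 : 0) : -1;
  for (int dir = -1; dir <= 1; dir += 2) {
    int i = anchor;
    if (dir == 1 && bridge) continue;   // rings grow one way, towards closure
    while (true) {
      int j = i + dir;
      if (bridge) {
        if (j < 0) j += c.n;
        if (j == anchor) break;
      } else if (j < 0 || j >= c.n) {
        break;
      }
      // steps remaining after this one, counting the closing bond
      int steps_left = 0;
      if (bridge) {
        int placed = (anchor - j + c.n) % c.n;   // beads placed after this
        steps_left = c.n - 1 - placed;
      }
      int nx, ny, nz;
      for (;;) {
        int d = rng.below(6);
        nx = c.x[i] + DX[d]; ny = c.y[i] + DY[d]; nz = c.z[i] + DZ[d];
        if (lo <= hi && !(nx >= lo && nx <= hi && ny >= lo && ny <= hi &&
                          nz >= lo && nz <= hi))
          continue;
        if (bridge) {
          int l1 = std::abs(nx - ax) + std::abs(ny - ay) + std::abs(nz - az);
          int need = l1 - target;
          if (need > steps_left || ((steps_left - need) & 1)) continue;
        }
        break;
      }
      c.x[j] = nx; c.y[j] = ny; c.z[j] = nz;
      i = j;
    }
  }
}

static void random_interior_site(int L, Xoshiro &rng, int &x, int &y, int &z) {
  x = 1 + rng.below(L - 2);
  y = 1 + rng.below(L - 2);
  z = 1 + rng.below(L - 2);
}

static void random_surface_site(int L, Xoshiro &rng, int &x, int &y, int &z) {
  do {
    x = rng.below(L); y = rng.below(L); z = rng.below(L);
  } while (!on_surface(x, y, z, L));
}

// ---------------------------------------------------------------------------
// Target-search run.
// capture_mode: 0 = protein and binding-site bead on the same lattice site
//               1 = binding-site bead on any surface site (membrane target)
//               2 = Chebyshev distance <= 1 between protein and site bead
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List kmc_search_cpp(int n_cell, int n_dna, bool ring, IntegerVector site_idx,
                    int n_p, double k2d, double kdna, double ks, double b,
                    bool dna_mobile, bool protein_mobile, int capture_mode,
                    bool init_site_on_surface, int init_mode,
                    double max_time, double master_seed, double run_index) {
  const int L = n_cell;
  if (L < 3) stop("n_cell must be >= 3");
  if (n_dna < 1) stop("n_dna must be >= 1");
  Xoshiro rng(mix_seed((uint64_t)master_seed, (uint64_t)run_index));

  const int ns = site_idx.size();
  std::vector<int> sites(ns);
  std::vector<char> is_site(n_dna, 0);
  for (int k = 0; k < ns; ++k) {
    int s = site_idx[k];
    if (s < 0 || s >= n_dna) stop("binding-site index out of range");
    sites[k] = s;
    is_site[s] = 1;
  }

  Chain chain(n_dna, ring, ks, b);
  int anchor = 0, ax, ay, az;
  if (init_site_on_surface) {
    // frozen-DNA mode: the binding-site bead anchors the chain at a random
    // membrane site; the rest of the (immobile) chain may lie anywhere
    anchor = sites[0];
    random_surface_site(L, rng, ax, ay, az);
    init_chain_walk(chain, 0, L - 1, anchor, ax, ay, az, rng);
  } else if (init_mode == 1) {        // walk anchored at the cell centre
    ax = ay = az = L / 2;
    init_chain_walk(chain, 0, L - 1, anchor, ax, ay, az, rng);
  } else if (init_mode == 2) {        // walk confined to the interior
    random_interior_site(L, rng, ax, ay, az);
    init_chain_walk(chain, 1, L - 2, anchor, ax, ay, az, rng);
  } else {                            // uniform anchor, whole box
    ax = rng.below(L); ay = rng.below(L); az = rng.below(L);
    init_chain_walk(chain, 0, L - 1, anchor, ax, ay, az, rng);
  }

  std::vector<int> px(n_p), py(n_p), pz(n_p);
  for (int p = 0; p < n_p; ++p)
    random_surface_site(L, rng, px[p], py[p], pz[p]);

  const double rate_p = protein_mobile ? k2d : 0.0;
  const double rate_b = dna_mobile ? kdna : 0.0;
  const double cap_protein = 6.0 * n_p * rate_p;
  const double cap_beads = 6.0 * n_dna * rate_b;
  const double R = cap_protein + cap_beads;
  if (capture_mode != 1 && R <= 0.0)
    stop("no mobile species: total move rate is zero");
  const double w_protein = (R > 0.0) ? cap_protein / R : 0.0;

  // capture test helpers ---------------------------------------------------
  auto site_captured = [&](int s) -> bool {
    if (capture_mode == 1)
      return on_surface(chain.x[s], chain.y[s], chain.z[s], L);
    for (int p = 0; p < n_p; ++p) {
      int dx = std::abs(chain.x[s] - px[p]);
      int dy = std::abs(chain.y[s] - py[p]);
      int dz = std::abs(chain.z[s] - pz[p]);
      if (capture_mode == 2) {
        if (dx <= 1 && dy <= 1 && dz <= 1) return true;
      } else {
        if (dx == 0 && dy == 0 && dz == 0) return true;
      }
    }
    return false;
  };
  auto any_captured = [&]() -> bool {
    for (int k = 0; k < ns; ++k)
      if (site_captured(sites[k])) return true;
    return false;
  };

  double t = 0.0;
  long long attempts = 0, accepted = 0;
  bool captured = any_captured();
  bool censored = false;

  if (!captured && R <= 0.0)
    stop("no mobile species: total move rate is zero");

  while (!captured) {
    t += rng.expo() / R;
    ++attempts;
    if (t > max_time) { censored = true; break; }
    if (rng.unif() < w_protein) {
      int p = (n_p > 1) ? rng.below(n_p) : 0;
      int d = rng.below(6);
      int nx = px[p] + DX[d], ny = py[p] + DY[d], nz = pz[p] + DZ[d];
      if (!in_box(nx, ny, nz, L) || !on_surface(nx, ny, nz, L)) continue;
      px[p] = nx; py[p] = ny; pz[p] = nz;
      ++accepted;
      if (capture_mode != 1) captured = any_captured();
    } else {
      int i = rng.below(n_dna);
      int d = rng.below(6);
      int nx = chain.x[i] + DX[d], ny = chain.y[i] + DY[d],
          nz = chain.z[i] + DZ[d];
      if (!in_box(nx, ny, nz, L)) continue;
      double du = chain.delta_u(i, nx, ny, nz);
      if (du > 0.0 && rng.unif() >= std::exp(-du)) continue;
      chain.x[i] = nx; chain.y[i] = ny; chain.z[i] = nz;
      ++accepted;
      if (is_site[i]) captured = site_captured(i);
    }
    if ((attempts & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["fpt"] = censored ? NA_REAL : t,
                      _["censored"] = censored,
                      _["attempts"] = (double)attempts,
                      _["accepted"] = (double)accepted);
}

// Initial-state generator exposed for distributional tests.
// [[Rcpp::export]]
List kmc_init_cpp(int n_cell, int n_dna, bool init_site_on_surface,
                  int init_mode, int anchor, double master_seed,
                  double run_index) {
  const int L = n_cell;
  Xoshiro rng(mix_seed((uint64_t)master_seed, (uint64_t)run_index));
  Chain chain(n_dna, false, 0.0, 1.0);
  int ax, ay, az;
  if (init_site_on_surface) {
    random_surface_site(L, rng, ax, ay, az);
    init_chain_walk(chain, 0, L - 1, anchor, ax, ay, az, rng);
  } else if (init_mode == 1) {
    anchor = 0; ax = ay = az = L / 2;
    init_chain_walk(chain, 0, L - 1, anchor, ax, ay, az, rng);
  } else if (init_mode == 2) {
    anchor = 0;
    random_interior_site(L, rng, ax, ay, az);
    init_chain_walk(chain, 1, L - 2, anchor, ax, ay, az, rng);
  } else {
    anchor = 0;
    ax = rng.below(L); ay = rng.below(L); az = rng.below(L);
    init_chain_walk(chain, 0, L - 1, anchor, ax, ay, az, rng);
  }
  int px, py, pz;
  random_surface_site(L, rng, px, py, pz);
  IntegerMatrix beads(n_dna, 3);
  for (int i = 0; i < n_dna; ++i) {
    beads(i, 0) = chain.x[i]; beads(i, 1) = chain.y[i]; beads(i, 2) = chain.z[i];
  }
  return List::create(_["beads"] = beads,
                      _["protein"] = IntegerVector::create(px, py, pz));
}

// Free (unconfined) chain: used for k_DNA calibration against the target
// centre-of-mass diffusivity and for equilibrium bond statistics.
// [[Rcpp::export]]
List kmc_free_chain_cpp(int n_dna, bool ring, double kdna, double ks, double b,
                        double t_total, double sample_dt, double master_seed,
                        double run_index, bool return_bond) {
  Xoshiro rng(mix_seed((uint64_t)master_seed, (uint64_t)run_index));
  Chain chain(n_dna, ring, ks, b);
  init_chain_walk(chain, 0, -1, 0, 0, 0, 0, rng);

  const double R = 6.0 * n_dna * kdna;
  if (R <= 0.0) stop("kdna must be positive");
  const int n_samp = (int)std::floor(t_total / sample_dt) + 1;
  NumericMatrix com(n_samp, 3);
  IntegerMatrix bond(return_bond ? n_samp : 1, 3);

  double t = 0.0;
  int k = 0;
  auto record = [&]() {
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < n_dna; ++i) { cx += chain.x[i]; cy += chain.y[i]; cz += chain.z[i]; }
    com(k, 0) = cx / n_dna; com(k, 1) = cy / n_dna; com(k, 2) = cz / n_dna;
    if (return_bond && n_dna >= 2) {
      bond(k, 0) = chain.x[1] - chain.x[0];
      bond(k, 1) = chain.y[1] - chain.y[0];
      bond(k, 2) = chain.z[1] - chain.z[0];
    }
    ++k;
  };
  record();
  long long attempts = 0;
  while (k < n_samp) {
    t += rng.expo() / R;
    while (k < n_samp && t >= k * sample_dt) record();
    if (k >= n_samp) break;
    int i = rng.below(n_dna);
    int d = rng.below(6);
    int nx = chain.x[i] + DX[d], ny = chain.y[i] + DY[d], nz = chain.z[i] + DZ[d];
    double du = chain.delta_u(i, nx, ny, nz);
    if (du > 0.0 && rng.unif() >= std::exp(-du)) continue;
    chain.x[i] = nx; chain.y[i] = ny; chain.z[i] = nz;
    if (((++attempts) & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["com"] = com, _["dt"] = sample_dt);
  if (return_bond) out["bond"] = bond;
  return out;
}

// Protein-only surface walk started at the centre of the z = 0 face; reports
// sampled positions and whether the walker ever left that face (MSD checks
// against 4*D*t are only valid away from edges).
// [[Rcpp::export]]
List kmc_protein_walk_cpp(int n_cell, double k2d, double t_total,
                          double sample_dt, double master_seed,
                          double run_index) {
  const int L = n_cell;
  Xoshiro rng(mix_seed((uint64_t)master_seed, (uint64_t)run_index));
  int px = L / 2, py = L / 2, pz = 0;
  const double R = 6.0 * k2d;
  const int n_samp = (int)std::floor(t_total / sample_dt) + 1;
  IntegerMatrix pos(n_samp, 3);
  bool left_face = false;
  double t = 0.0;
  int k = 0;
  auto record = [&]() { pos(k, 0) = px; pos(k, 1) = py; pos(k, 2) = pz; ++k; };
  record();
  while (k < n_samp) {
    t += rng.expo() / R;
    while (k < n_samp && t >= k * sample_dt) record();
    if (k >= n_samp) break;
    int d = rng.below(6);
    int nx = px + DX[d], ny = py + DY[d], nz = pz + DZ[d];
    if (!in_box(nx, ny, nz, L) || !on_surface(nx, ny, nz, L)) continue;
    px = nx; py = ny; pz = nz;
    if (pz != 0) left_face = true;
  }
  return List::create(_["pos"] = pos, _["left_face"] = left_face);
}

// Accepted-event trace for a toy system (one free bead in a box plus one
// surface protein, no springs) used to cross-check the null-event scheme
// against a direct Gillespie sampler written independently in R.
// [[Rcpp::export]]
List kmc_event_trace_cpp(int n_cell, double k2d, double kdna, int n_events,
                         double master_seed, double run_index) {
  const int L = n_cell;
  Xoshiro rng(mix_seed((uint64_t)master_seed, (uint64_t)run_index));
  int bx = rng.below(L), by = rng.below(L), bz = rng.below(L);
  int px, py, pz;
  random_surface_site(L, rng, px, py, pz);
  const double R = 6.0 * k2d + 6.0 * kdna;
  NumericVector dwell(n_events);
  IntegerVector type(n_events);
  double since = 0.0;
  int k = 0;
  while (k < n_events) {
    since += rng.expo() / R;
    if (rng.unif() < 6.0 * k2d / R) {
      int d = rng.below(6);
      int nx = px + DX[d], ny = py + DY[d], nz = pz + DZ[d];
      if (!in_box(nx, ny, nz, L) || !on_surface(nx, ny, nz, L)) continue;
      px = nx; py = ny; pz = nz;
      dwell[k] = since; type[k] = 0; since = 0.0; ++k;
    } else {
      int d = rng.below(6);
      int nx = bx + DX[d], ny = by + DY[d], nz = bz + DZ[d];
      if (!in_box(nx, ny, nz, L)) continue;
      bx = nx; by = ny; bz = nz;
      dwell[k] = since; type[k] = 1; since = 0.0; ++k;
    }
  }
  return List::create(_["dwell"] = dwell, _["type"] = type);
}

// Total spring energy of a configuration (beads: n x 3 lattice coordinates).
// [[Rcpp::export]]
double spring_energy_cpp(IntegerMatrix beads, double ks, double b, bool ring) {
  int n = beads.nrow();
  Chain chain(n, ring, ks, b);
  for (int i = 0; i < n; ++i) {
    chain.x[i] = beads(i, 0); chain.y[i] = beads(i, 1); chain.z[i] = beads(i, 2);
  }
  return chain.total_energy();
}

// 8-connectivity connected-component labelling of a binary mask.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}
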