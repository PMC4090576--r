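#include <Rcpp.h>
#include <cstring>
#include <cmath>
#include <cstdint>

// Gillespie direct-method core. One trajectory is advanced event by event;
// the per-task RNG state travels with the task (32 raw bytes, xoshiro256++),
// so results are invariant to how the advancement is sliced into quanta and
// to the interleaving of tasks.

static inline uint64_t rotl64(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  uint64_t next() {
    const uint64_t result = rotl64(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl64(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  double u01() { return (next() >> 11) * 0x1.0p-53; }
};

static void load_state(const Rcpp::RawVector &raw, Xoshiro &rng) {
  if (raw.size() != 32) Rcpp::stop("rng state must be 32 raw bytes");
  std::memcpy(rng.s, RAW(raw), 32);
}

static Rcpp::RawVector save_state(const Xoshiro &rng) {
  Rcpp::RawVector raw(32);
  std::memcpy(RAW(raw), rng.s, 32);
  return raw;
}

// [[Rcpp::export]]
Rcpp::RawVector ssa_rng_state_cpp(double seed) {
  if (!R_finite(seed) || seed < 0) Rcpp::stop("seed must be a non-negative number");
  uint64_t x = (uint64_t) seed;
  Xoshiro rng;
  for (int i = 0; i < 4; ++i) rng.s[i] = splitmix64(x);
  // xoshiro must not start from the all-zero state (cannot happen via splitmix,
  // but keep the guard explicit)
  if (!(rng.s[0] | rng.s[1] | rng.s[2] | rng.s[3])) rng.s[0] = 1;
  return save_state(rng);
}

// [[Rcpp::export]]
double ssa_rng_u01_cpp(Rcpp::RawVector state) {
  Xoshiro rng;
  load_state(state, rng);
  double u = rng.u01();
  std::memcpy(RAW(state), rng.s, 32); // advance in place
  return u;
}

// rate-law type codes (kept in sync with compile_model() on the R side)
enum { RL_MASS_ACTION = 0, RL_HILL = 1, RL_MICHAELIS = 2, RL_RFUN = 3 };

// v_s(t): piecewise-constant forcing with period 2T; low on [2nT, (2n+1)T)
static inline double schedule_value(double lo, double hi, double T, double t) {
  if (T <= 0) return lo;
  double period = 2.0 * T;
  double pos = t - std::floor(t / period) * period;
  if (pos < 0) pos += period;
  return (pos < T) ? lo : hi;
}

// combinatorial count of reactant tuples: prod_s choose(n_s, m_s)
static inline double combinations(int n, int m) {
  if (n < m) return 0.0;
  double acc = 1.0;
  for (int i = 0; i < m; ++i) acc *= (double)(n - i) / (double)(m - i);
  return acc;
}

struct ModelSpec {
  int nsp, nrx;
  const int *react;  // nsp x nrx reactant multiplicities
  const int *net;    // nsp x nrx state change (buffered rows zeroed)
  const int *type;
  const double *par; // 5 x nrx
  const int *spi;    // 0-based species index for hill/michaelis
  Rcpp::List funs;
  Rcpp::CharacterVector species;
};

static double propensity_one(const ModelSpec &m, int j, const std::vector<int> &x,
                             double t) {
  const double *p = m.par + 5 * j;
  double a;
  switch (m.type[j]) {
  case RL_MASS_ACTION: {
    a = p[0];
    const int *col = m.react + m.nsp * j;
    for (int s = 0; s < m.nsp && a > 0; ++s)
      if (col[s] > 0) a *= combinations(x[s], col[s]);
    break;
  }
  case RL_HILL: {
    // v_s(t) * K^n / (count^n + K^n), repression by species spi
    double vs = schedule_value(p[0], p[1], p[2], t);
    double K = p[3]; int n = (int) p[4];
    double cn = std::pow((double) x[m.spi[j]], n);
    double Kn = std::pow(K, n);
    a = vs * Kn / (cn + Kn);
    break;
  }
  case RL_MICHAELIS: {
    double cnt = (double) x[m.spi[j]];
    a = p[0] * cnt / (p[1] + cnt);
    break;
  }
  case RL_RFUN: {
    Rcpp::Function f = m.funs[j];
    Rcpp::NumericVector xs(m.nsp);
    for (int s = 0; s < m.nsp; ++s) xs[s] = x[s];
    xs.names() = m.species;
    a = Rcpp::as<double>(f(xs, t));
    break;
  }
  default:
    Rcpp::stop("unknown rate-law type code");
  }
  if (!R_finite(a) || a < 0)
    Rcpp::stop("rate function for reaction %d returned a negative or non-finite value",
               j + 1);
  return a;
}

// Advance one simulation task. Emits every grid sample t_i = t0 + i*ds whose
// covering state (state after the last event with time <= t_i) is known, i.e.
// all t_i <= clock on return. Stops when clock >= t_target, when the task
// reaches t_end (done), or after max_events steps (a step is an event firing,
// a boundary advance, or an absorbing-state advance); max_events < 0 means
// no limit.
// [[Rcpp::export]]
Rcpp::List ssa_advance_cpp(Rcpp::IntegerVector counts0, double clock0,
                           Rcpp::RawVector rng0, Rcpp::IntegerMatrix react,
                           Rcpp::IntegerMatrix net, Rcpp::IntegerVector type,
                           Rcpp::NumericMatrix par, Rcpp::IntegerVector spi,
                           Rcpp::List funs, Rcpp::CharacterVector species,
                           double Tb, double t0, double ds, int next_idx0,
                           double t_target, double t_end, int max_events) {
  const int nsp = counts0.size();
  const int nrx = type.size();
  if (react.nrow() != nsp || net.nrow() != nsp || react.ncol() != nrx ||
      net.ncol() != nrx || par.ncol() != nrx)
    Rcpp::stop("inconsistent model spec dimensions");
  if (ds <= 0) Rcpp::stop("delta_s must be positive");

  ModelSpec m;
  m.nsp = nsp; m.nrx = nrx;
  m.react = INTEGER(react); m.net = INTEGER(net);
  m.type = INTEGER(type); m.par = REAL(par); m.spi = INTEGER(spi);
  m.funs = funs; m.species = species;

  std::vector<int> x(counts0.begin(), counts0.end());
  double clock = clock0;
  Xoshiro rng;
  load_state(rng0, rng);

  // last grid index that belongs to the run
  const long imax = (long) std::floor((t_end - t0) / ds + 1e-9);
  long next_idx = next_idx0;

  std::vector<int> samples; // column-major nsp x k
  auto emit_upto = [&](double tlim, bool inclusive) {
    while (next_idx <= imax) {
      double ti = t0 + next_idx * ds;
      if (inclusive ? (ti > tlim) : (ti >= tlim)) break;
      for (int s = 0; s < nsp; ++s) samples.push_back(x[s]);
      ++next_idx;
    }
  };

  std::vector<double> a(nrx);
  bool done = false;
  int events = 0;

  while (!done && clock < t_target) {
    if (max_events >= 0 && events >= max_events) break;

    double nb = R_PosInf;
    if (Tb > 0) {
      nb = (std::floor(clock / Tb) + 1.0) * Tb;
      while (nb <= clock) nb += Tb;
    }

    double a0 = 0.0;
    for (int j = 0; j < nrx; ++j) { a[j] = propensity_one(m, j, x, clock); a0 += a[j]; }

    if (a0 <= 0.0) {
      // absorbing under current rates: jump to the next rate change, or finish
      if (nb < t_end) { emit_upto(nb, true); clock = nb; ++events; continue; }
      emit_upto(t_end, true); clock = t_end; done = true; ++events; break;
    }

    double tau = -std::log(1.0 - rng.u01()) / a0;
    double tn = clock + tau;

    if (nb < t_end && tn > nb) {
      // crossing a piecewise-rate boundary: move there without firing and
      // redraw (exact for piecewise-constant rates by memorylessness)
      emit_upto(nb, true); clock = nb; ++events; continue;
    }
    if (tn > t_end) { emit_upto(t_end, true); clock = t_end; done = true; ++events; break; }

    // select reaction j with probability a_j / a0
    double r = rng.u01() * a0;
    int j = 0;
    double acc = a[0];
    while (r > acc && j < nrx - 1) acc += a[++j];

    emit_upto(tn, false);          // samples strictly before the event keep the old state
    const int *dn = m.net + nsp * j;
    for (int s = 0; s < nsp; ++s) {
      x[s] += dn[s];
      if (x[s] < 0)
        Rcpp::stop("species count went negative firing reaction %d (stoichiometry bug)",
                   j + 1);
    }
    clock = tn;
    emit_upto(clock, true);        // grid points hit exactly take the post-event state
    ++events;
  }
  if (clock >= t_end) done = true;

  int k = (int) (samples.size() / nsp);
  Rcpp::IntegerMatrix smp(nsp, k);
  if (k > 0) std::copy(samples.begin(), samples.end(), smp.begin());

  Rcpp::IntegerVector counts1(x.begin(), x.end());
  counts1.names() = counts0.names();
  return Rcpp::List::create(
      Rcpp::Named("counts") = counts1, Rcpp::Named("clock") = clock,
      Rcpp::Named("rng") = save_state(rng),
      Rcpp::Named("next_sample_index") = (double) next_idx,
      Rcpp::Named("first_index") = (double) next_idx0,
      Rcpp::Named("done") = done, Rcpp::Named("samples") = smp,
      Rcpp::Named("events") = events);
}
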