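// Exact stochastic simulation (Gillespie direct method) of the allosteric
// signaling network, with piecewise-constant substrate production.
//
// Channel order and rate-vector layout mirror R/reactions.R:
//   rates = (beta, gammaS, gammaP, kA_on, kA_off, kAstar_on, kAstar_off,
//            alpha, alpha_star, alphaS, alphaS_star, nu, nu_star,
//            kB_on, kB_off)
// sigmaA codes 1..4 = A, A*, AS, A*S; sigmaB codes 1..2 = B, BP.
//
// Randomness comes from a self-contained xoshiro256++ generator seeded via
// splitmix64, so each trajectory/replicate is independently and
// reproducibly seeded (replicate r uses base_seed + r) without touching
// R's global RNG stream.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

namespace {

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in the open interval (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct State {
  int a, b;
  long s, p;
};

inline int propensities(const double *r, double beta, const State &st,
                        double *w) {
  w[0] = beta;                                    // 0 -> S
  w[1] = r[1] * st.s;                             // S -> 0
  w[2] = (st.a == 1) ? r[3] * st.s : 0.0;         // A + S -> AS
  w[3] = (st.a == 3) ? r[4] : 0.0;                // AS -> A + S
  w[4] = (st.a == 2) ? r[5] * st.s : 0.0;         // A* + S -> A*S
  w[5] = (st.a == 4) ? r[6] : 0.0;                // A*S -> A* + S
  w[6] = (st.a == 1) ? r[7] : 0.0;                // A -> A*
  w[7] = (st.a == 2) ? r[8] : 0.0;                // A* -> A
  w[8] = (st.a == 3) ? r[9] : 0.0;                // AS -> A*S
  w[9] = (st.a == 4) ? r[10] : 0.0;               // A*S -> AS
  w[10] = (st.a == 3) ? r[11] : 0.0;              // AS -> A + P
  w[11] = (st.a == 4) ? r[12] : 0.0;              // A*S -> A* + P
  w[12] = r[2] * st.p;                            // P -> 0
  w[13] = (st.b == 1) ? r[13] * st.p : 0.0;       // B + P -> BP
  w[14] = (st.b == 2) ? r[14] : 0.0;              // BP -> B + P
  return 15;
}

inline void apply(int j, State &st) {
  switch (j) {
    case 0: ++st.s; break;
    case 1: --st.s; break;
    case 2: st.a = 3; --st.s; break;
    case 3: st.a = 1; ++st.s; break;
    case 4: st.a = 4; --st.s; break;
    case 5: st.a = 2; ++st.s; break;
    case 6: st.a = 2; break;
    case 7: st.a = 1; break;
    case 8: st.a = 4; break;
    case 9: st.a = 3; break;
    case 10: st.a = 1; ++st.p; break;
    case 11: st.a = 2; ++st.p; break;
    case 12: --st.p; break;
    case 13: st.b = 2; --st.p; break;
    case 14: st.b = 1; ++st.p; break;
  }
}

// Advance one replicate from time t to t_target.  Waiting-time draws never
// cross a segment boundary: at each boundary the clock is re-drawn, which
// is exact for piecewise-constant rates by the memoryless property.
// Recorder is called after every executed reaction event.
template <class Rec>
void advance(const double *r, const std::vector<double> &seg_start,
             const std::vector<double> &seg_beta, State &st, double &t,
             double t_target, Xoshiro &rng, Rec rec) {
  const size_t nseg = seg_start.size();
  double w[15];
  while (t < t_target) {
    size_t k = nseg - 1;
    while (k > 0 && seg_start[k] > t) --k;
    double bnd = (k + 1 < nseg) ? seg_start[k + 1] : t_target;
    if (bnd > t_target) bnd = t_target;
    propensities(r, seg_beta[k], st, w);
    double atot = 0.0;
    for (int j = 0; j < 15; ++j) atot += w[j];
    if (atot <= 0.0) {        // quiescent: hold state to the next boundary
      t = bnd;
      continue;
    }
    double dt = -std::log(rng.unif()) / atot;
    if (t + dt >= bnd) {
      t = bnd;
      continue;
    }
    t += dt;
    double u = rng.unif() * atot;
    int j = 0;
    double c = w[0];
    while (u > c && j < 14) c += w[++j];
    apply(j, st);
    rec(t, st);
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix ssa_trajectory_cpp(Rcpp::NumericVector rates,
                                       Rcpp::IntegerVector init,
                                       Rcpp::NumericVector seg_start,
                                       Rcpp::NumericVector seg_beta,
                                       double t_end, double seed,
                                       double max_events) {
  std::vector<double> ss(seg_start.begin(), seg_start.end());
  std::vector<double> sb(seg_beta.begin(), seg_beta.end());
  State st{init[0], init[1], init[2], init[3]};
  double t = ss[0];
  Xoshiro rng(static_cast<uint64_t>(seed));
  std::vector<double> rec_t, rec_a, rec_b, rec_s, rec_p;
  const double cap = max_events;
  advance(REAL(rates), ss, sb, st, t, t_end, rng,
          [&](double tt, const State &x) {
            if (static_cast<double>(rec_t.size()) >= cap)
              Rcpp::stop("event cap exceeded (%g events)", cap);
            rec_t.push_back(tt);
            rec_a.push_back(x.a);
            rec_b.push_back(x.b);
            rec_s.push_back(static_cast<double>(x.s));
            rec_p.push_back(static_cast<double>(x.p));
          });
  const int n = static_cast<int>(rec_t.size());
  Rcpp::NumericMatrix out(n, 5);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = rec_t[i];
    out(i, 1) = rec_a[i];
    out(i, 2) = rec_b[i];
    out(i, 3) = rec_s[i];
    out(i, 4) = rec_p[i];
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix ssa_finals_cpp(Rcpp::NumericVector rates,
                                   Rcpp::IntegerVector init,
                                   Rcpp::NumericVector seg_start,
                                   Rcpp::NumericVector seg_beta,
                                   double t_obs, int n, double base_seed) {
  std::vector<double> ss(seg_start.begin(), seg_start.end());
  std::vector<double> sb(seg_beta.begin(), seg_beta.end());
  Rcpp::IntegerMatrix out(n, 4);
  for (int r = 0; r < n; ++r) {
    State st{init[0], init[1], init[2], init[3]};
    double t = ss[0];
    Xoshiro rng(static_cast<uint64_t>(base_seed) +
                static_cast<uint64_t>(r) + 1ULL);
    advance(REAL(rates), ss, sb, st, t, t_obs, rng,
            [](double, const State &) {});
    out(r, 0) = st.a;
    out(r, 1) = st.b;
    out(r, 2) = static_cast<int>(st.s);
    out(r, 3) = static_cast<int>(st.p);
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List ssa_grid_cpp(Rcpp::NumericVector rates, Rcpp::IntegerVector init,
                        Rcpp::NumericVector seg_start,
                        Rcpp::NumericVector seg_beta,
                        Rcpp::NumericVector t_grid, int n,
                        double base_seed) {
  std::vector<double> ss(seg_start.begin(), seg_start.end());
  std::vector<double> sb(seg_beta.begin(), seg_beta.end());
  const int ng = t_grid.size();
  Rcpp::NumericVector sum_s(ng), sum_p(ng), sum_s2(ng), sum_p2(ng);
  Rcpp::IntegerMatrix ab_counts(8, ng);
  for (int r = 0; r < n; ++r) {
    State st{init[0], init[1], init[2], init[3]};
    double t = ss[0];
    Xoshiro rng(static_cast<uint64_t>(base_seed) +
                static_cast<uint64_t>(r) + 1ULL);
    for (int g = 0; g < ng; ++g) {
      advance(REAL(rates), ss, sb, st, t, t_grid[g], rng,
              [](double, const State &) {});
      sum_s[g] += st.s;
      sum_p[g] += st.p;
      sum_s2[g] += static_cast<double>(st.s) * st.s;
      sum_p2[g] += static_cast<double>(st.p) * st.p;
      ab_counts((st.a - 1) + 4 * (st.b - 1), g) += 1;
    }
    if (r % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("sum_s") = sum_s,
                            Rcpp::Named("sum_p") = sum_p,
                            Rcpp::Named("sum_s2") = sum_s2,
                            Rcpp::Named("sum_p2") = sum_p2,
                            Rcpp::Named("ab_counts") = ab_counts,
                            Rcpp::Named("n") = n);
}
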