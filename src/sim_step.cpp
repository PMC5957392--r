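// Annual update of the invasion state: maturation, stochastic logistic local
// growth, seed production and log-normal dispersal, corridor transport along
// the road network, habitat-scaled establishment, and carrying-capacity
// truncation. Seeds are pre-thinned by the establishment frequency (an exact
// thinning: the per-seed establishment probability factorizes as
// establishment_freq * rel_estab[destination class], and the constant factor
// is applied before dispersal), so only establishment-candidate seeds are
// dispersed individually. Uses R's RNG throughout.

#include <Rcpp.h>
using namespace Rcpp;

static const int ROAD_CODE = 7;

// [[Rcpp::export]]
List sim_step_cpp(IntegerMatrix adults_in, IntegerMatrix juveniles_in,
                  IntegerMatrix codes, NumericVector r_eff, NumericVector K,
                  NumericVector rel_estab, double fecundity,
                  double estab_freq, double corridor_usage, double meanlog,
                  double sdlog, double cell_size, IntegerMatrix road_id,
                  IntegerMatrix road_dist, IntegerVector road_exit,
                  bool kill_barrier_adults) {
  const int nr = adults_in.nrow(), nc = adults_in.ncol();
  IntegerMatrix adults = clone(adults_in);
  IntegerMatrix juv(nr, nc); // new juveniles of this year

  // (1) maturation
  for (int i = 0; i < nr * nc; ++i) {
    adults[i] += juveniles_in[i];
  }

  // (2) local logistic growth with stochastic rounding
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int N = adults(r, c);
      if (N <= 0) continue;
      int code = codes(r, c);
      if (code < 0 || code > 10) stop("unknown class code %d", code);
      double k = K[code];
      double re = r_eff[code];
      if (re <= 0.0 || k <= 0.0) continue;
      double inc = re * N * (1.0 - N / k);
      int whole = (int)std::floor(inc);
      double frac = inc - whole;
      if (unif_rand() < frac) whole += 1;
      int nn = N + whole;
      if (nn < 0) nn = 0;
      adults(r, c) = nn;
    }
  }

  // (3)-(5) seed production, dispersal, corridor transport, establishment
  const int n_road = road_exit.size();
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int N = adults(r, c);
      if (N <= 0) continue;
      double n_seeds = (double)N * fecundity;
      int cand = (int)R::rbinom(n_seeds, estab_freq);
      for (int s = 0; s < cand; ++s) {
        double dist = R::rlnorm(meanlog, sdlog);
        double ang = 2.0 * M_PI * unif_rand();
        double dx = dist * std::cos(ang) / cell_size;
        double dy = dist * std::sin(ang) / cell_size;
        int dc = (int)std::floor(c + 0.5 + dx);
        int dr = (int)std::floor(r + 0.5 + dy);
        if (dr < 0 || dr >= nr || dc < 0 || dc >= nc) continue; // lost
        int code = codes(dr, dc);
        if (code == ROAD_CODE) {
          if (n_road == 0 || unif_rand() >= corridor_usage) continue;
          int ri = road_id(dr, dc) - 1; // 1-based from R
          if (ri < 0) continue;
          double d2 = R::rlnorm(meanlog, sdlog);
          int want = (int)std::lround(d2 / cell_size);
          // largest reachable graph distance <= want (distances from a cell
          // over a connected component fill 0..max, so it exists)
          int best = 0, count = 0;
          for (int j = 0; j < n_road; ++j) {
            int d = road_dist(ri, j);
            if (d < 0 || d > want) continue;
            if (d > best) {
              best = d;
              count = 1;
            } else if (d == best) {
              ++count;
            }
          }
          if (count == 0) continue;
          int pick = (int)std::floor(unif_rand() * count);
          if (pick >= count) pick = count - 1;
          int exit_idx = -1;
          for (int j = 0; j < n_road; ++j) {
            int d = road_dist(ri, j);
            if (d == best) {
              if (pick == 0) {
                exit_idx = j;
                break;
              }
              --pick;
            }
          }
          if (exit_idx < 0) continue;
          int dest_cell = road_exit[exit_idx]; // 1-based cell index, 0 = none
          if (dest_cell <= 0) continue;
          dr = (dest_cell - 1) % nr;
          dc = (dest_cell - 1) / nr;
          code = codes(dr, dc);
          if (code == ROAD_CODE) continue;
        }
        double pe = rel_estab[code];
        if (pe <= 0.0) continue;
        if (adults(dr, dc) > 0 || juv(dr, dc) > 0) continue; // occupied
        if (unif_rand() < pe) juv(dr, dc) = 1;
      }
    }
  }

  // (6) carrying-capacity truncation (and optional founder senescence on
  // barrier habitat)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int code = codes(r, c);
      double k = K[code];
      // K = 0 marks barrier habitat: only founders can sit there, and they
      // persist until the senescence flag removes them, so truncation only
      // applies to growing habitat
      if (k > 0.0 && adults(r, c) > k) adults(r, c) = (int)std::floor(k);
      if (kill_barrier_adults && rel_estab[code] <= 0.0) {
        adults(r, c) = 0;
        juv(r, c) = 0;
      }
    }
  }

  return List::create(_["adults"] = adults, _["juveniles"] = juv);
}
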