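// Spatial kinetic Monte Carlo (spatial Gillespie) engine.
//
// State: integer copy numbers per (chamber, species) on an n_side x n_side
// periodic lattice. Events are same-chamber reactions (propensity =
// rate_const * n1 [* n2]) and diffusion hops to one of the four nearest
// neighbours (total per-molecule rate hop[s]; direction uniform). Species
// confined to a cluster mask may only hop between chambers carrying the
// same mask label; a draw of a blocked direction is a null event, which
// leaves the sampled process statistically exact (self-transition /
// uniformization argument). Chamber totals live in a binary sum tree for
// O(log N) chamber selection; per-chamber per-reaction propensities are
// cached (chamber-major for locality) and updated incrementally.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List sim_kmc_cpp(IntegerMatrix counts0,
                 IntegerVector mask_a,
                 IntegerVector mask_k,
                 NumericVector hop,
                 IntegerVector conf,     // 0 free, 1 nkg2d-mask, 2 kir-mask
                 int n_side,
                 IntegerVector r1,       // first reactant (0-based)
                 IntegerVector r2,       // second reactant or -1
                 NumericVector rconst,   // per-combination propensity (1/s)
                 IntegerVector s_off,    // CSR offsets into s_sp/s_delta
                 IntegerVector s_sp,
                 IntegerVector s_delta,
                 NumericVector sample_times,
                 double max_events) {
  const int n_ch = counts0.nrow();
  const int n_sp = counts0.ncol();
  const int n_rx = r1.size();
  const int n_samp = sample_times.size();
  if (n_ch != n_side * n_side) stop("counts rows must equal n_side^2");

  // chamber-major copy numbers: cnt[s + c*n_sp]
  std::vector<int> cnt((size_t)n_ch * n_sp);
  for (int c = 0; c < n_ch; ++c)
    for (int s = 0; s < n_sp; ++s)
      cnt[s + (size_t)c * n_sp] = counts0(c, s);

  std::vector<double> hp(n_ch, 0.0), rpsum(n_ch, 0.0);
  std::vector<double> rp((size_t)n_ch * n_rx, 0.0);
  std::vector<double> tot(n_sp, 0.0);

  // neighbour table (periodic)
  std::vector<int> nb((size_t)n_ch * 4);
  for (int c = 0; c < n_ch; ++c) {
    int row = c % n_side, col = c / n_side;
    nb[4 * (size_t)c + 0] = (row + 1) % n_side + col * n_side;
    nb[4 * (size_t)c + 1] = (row + n_side - 1) % n_side + col * n_side;
    nb[4 * (size_t)c + 2] = row + ((col + 1) % n_side) * n_side;
    nb[4 * (size_t)c + 3] = row + ((col + n_side - 1) % n_side) * n_side;
  }

  // species -> reactions having it as a reactant
  std::vector<std::vector<int>> sp_rxns(n_sp);
  for (int j = 0; j < n_rx; ++j) {
    sp_rxns[r1[j]].push_back(j);
    if (r2[j] >= 0 && r2[j] != r1[j]) sp_rxns[r2[j]].push_back(j);
  }

  auto prop = [&](int j, int c) -> double {
    const int *cc = &cnt[(size_t)c * n_sp];
    double p = rconst[j] * cc[r1[j]];
    if (r2[j] >= 0) p *= cc[r2[j]];
    return p;
  };

  int p2 = 1;
  while (p2 < n_ch) p2 <<= 1;
  std::vector<double> tree(2 * (size_t)p2, 0.0);
  auto tree_set = [&](int c, double v) {
    size_t i = p2 + c;
    tree[i] = v;
    for (i >>= 1; i >= 1; i >>= 1) tree[i] = tree[2 * i] + tree[2 * i + 1];
  };

  auto rebuild = [&]() {
    for (int c = 0; c < n_ch; ++c) {
      const int *cc = &cnt[(size_t)c * n_sp];
      double h = 0.0, rs = 0.0;
      for (int s = 0; s < n_sp; ++s) h += hop[s] * cc[s];
      for (int j = 0; j < n_rx; ++j) {
        double p = prop(j, c);
        rp[(size_t)c * n_rx + j] = p;
        rs += p;
      }
      hp[c] = h;
      rpsum[c] = rs;
      tree[p2 + c] = h + rs;
    }
    for (int c = n_ch; c < p2; ++c) tree[p2 + c] = 0.0;
    for (int i = p2 - 1; i >= 1; --i) tree[i] = tree[2 * i] + tree[2 * i + 1];
  };

  for (int s = 0; s < n_sp; ++s) {
    double t = 0.0;
    for (int c = 0; c < n_ch; ++c) t += cnt[s + (size_t)c * n_sp];
    tot[s] = t;
  }
  rebuild();

  // apply a copy-number change and update caches for chamber c
  auto apply_delta = [&](int c, int s, int d) {
    int &x = cnt[s + (size_t)c * n_sp];
    x += d;
    if (x < 0) stop("internal-consistency error: negative copy number");
    hp[c] += d * hop[s];
    double *rpc = &rp[(size_t)c * n_rx];
    for (int j : sp_rxns[s]) {
      double np = prop(j, c);
      rpsum[c] += np - rpc[j];
      rpc[j] = np;
    }
    tot[s] += d;
  };

  NumericMatrix out(n_samp, n_sp);
  int si = 0;
  double t = 0.0;
  double n_events = 0.0, since_rebuild = 0.0;

  auto record_until = [&](double tnow) {
    while (si < n_samp && sample_times[si] <= tnow) {
      for (int s = 0; s < n_sp; ++s) out(si, s) = tot[s];
      ++si;
    }
  };
  record_until(0.0);  // a sample at time 0 records the initial state

  const double t_end = sample_times[n_samp - 1];
  while (si < n_samp) {
    double T = tree[1];
    if (T <= 0.0) {  // absorbing state: remaining samples = current state
      record_until(t_end);
      break;
    }
    double dt = -std::log(R::unif_rand()) / T;
    t += dt;
    record_until(t);
    if (si >= n_samp) break;
    if (++n_events > max_events)
      stop("event budget exceeded (max_events = %.0f)", max_events);

    // select chamber by tree descent
    double u = R::unif_rand() * T;
    size_t node = 1;
    while (node < (size_t)p2) {
      node <<= 1;
      if (u >= tree[node]) { u -= tree[node]; ++node; }
    }
    int c = (int)(node - p2);
    if (c >= n_ch) c = n_ch - 1;

    double r = u;
    if (r < hp[c]) {
      // diffusion hop: pick species, then direction
      const int *cc = &cnt[(size_t)c * n_sp];
      int s_hop = n_sp - 1;
      for (int s = 0; s < n_sp; ++s) {
        double hr = hop[s] * cc[s];
        if (r < hr) { s_hop = s; break; }
        r -= hr;
      }
      int dir = (int)(4.0 * R::unif_rand());
      if (dir > 3) dir = 3;
      int c2 = nb[4 * (size_t)c + dir];
      bool allowed = true;
      if (conf[s_hop] == 1) allowed = (mask_a[c] == mask_a[c2]);
      else if (conf[s_hop] == 2) allowed = (mask_k[c] == mask_k[c2]);
      if (allowed && c2 != c) {
        apply_delta(c, s_hop, -1);
        apply_delta(c2, s_hop, +1);
        tree_set(c2, hp[c2] + rpsum[c2]);
      }
      tree_set(c, hp[c] + rpsum[c]);
    } else {
      r -= hp[c];
      const double *rpc = &rp[(size_t)c * n_rx];
      int jfire = -1;
      for (int j = 0; j < n_rx; ++j) {
        if (r < rpc[j]) { jfire = j; break; }
        r -= rpc[j];
      }
      if (jfire < 0) {  // numerical slack: refresh this chamber, move on
        const int *cc = &cnt[(size_t)c * n_sp];
        double h = 0.0, rs = 0.0;
        for (int s = 0; s < n_sp; ++s) h += hop[s] * cc[s];
        for (int j = 0; j < n_rx; ++j) {
          double p = prop(j, c);
          rp[(size_t)c * n_rx + j] = p;
          rs += p;
        }
        hp[c] = h;
        rpsum[c] = rs;
        tree_set(c, h + rs);
        continue;
      }
      for (int k = s_off[jfire]; k < s_off[jfire + 1]; ++k)
        apply_delta(c, s_sp[k], s_delta[k]);
      tree_set(c, hp[c] + rpsum[c]);
    }

    if (++since_rebuild >= 4e6) {  // periodic refresh against FP drift
      rebuild();
      since_rebuild = 0.0;
    }
  }

  IntegerMatrix final_counts(n_ch, n_sp);
  for (int c = 0; c < n_ch; ++c)
    for (int s = 0; s < n_sp; ++s)
      final_counts(c, s) = cnt[s + (size_t)c * n_sp];
  return List::create(_["totals"] = out,
                      _["final_counts"] = final_counts,
                      _["n_events"] = n_events,
                      _["t_final"] = t);
}
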