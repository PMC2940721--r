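#include <Rcpp.h>
using namespace Rcpp;

// Partition-function dynamic programs over annotated binding sites.
//
// Sites arrive sorted by start (0-based), with end = start + length.
// q for site i in bin b is qbase[i] * conc(tf[i], b), where qbase folds the
// binding constant and the LLR mismatch penalty. Cooperativity omega applies
// to adjacent bound pairs of partner TFs whose edge-to-edge gap d satisfies
// 0 < d <= coop_range. Because adjacent bound sites never overlap, the ends
// of bound sites increase along a configuration, so summing over the nearest
// occupied site to the left enumerates every configuration exactly once.

static inline double pair_omega(int ti, int tj, double gap,
                                const NumericMatrix &omega, double coop_range) {
  if (gap <= 0.0 || gap > coop_range) return 1.0;
  return omega(ti, tj);
}

// Direct-interaction model, multiplicative activation (every bound TF
// contributes its alpha to Q). Linear in n when coop_range bounds the
// lookback: non-cooperative mass is accumulated in prefix sums over sites
// ordered by end, and only sites within coop_range are rescanned.
// [[Rcpp::export]]
List dp_direct_cpp(IntegerVector start, IntegerVector end, IntegerVector tf,
                   NumericVector qbase, NumericMatrix conc,
                   NumericVector alpha, NumericMatrix omega,
                   double coop_range, double q_btm) {
  const int n = start.size();
  const int nbins = conc.ncol();
  NumericVector z_on(nbins), z_off(nbins), expr(nbins);

  // indices ordered by end coordinate (stable)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return end[a] < end[b]; });

  std::vector<double> zoff(n), zon(n);
  for (int b = 0; b < nbins; ++b) {
    double s_off = 0.0, s_on = 0.0;  // prefix sums over closed sites
    int ptr = 0;
    double tot_off = 0.0, tot_on = 0.0;
    for (int i = 0; i < n; ++i) {
      while (ptr < n && end[ord[ptr]] <= start[i]) {
        s_off += zoff[ord[ptr]];
        s_on += zon[ord[ptr]];
        ++ptr;
      }
      // cooperative correction: closed sites within coop_range of start[i]
      double c_off = 0.0, c_on = 0.0;
      for (int t = ptr - 1; t >= 0; --t) {
        int j = ord[t];
        double gap = (double)start[i] - (double)end[j];
        if (gap > coop_range) break;
        double w = pair_omega(tf[i], tf[j], gap, omega, coop_range);
        if (w != 1.0) {
          c_off += (w - 1.0) * zoff[j];
          c_on += (w - 1.0) * zon[j];
        }
      }
      double q = qbase[i] * conc(tf[i], b);
      zoff[i] = q * (1.0 + s_off + c_off);
      zon[i] = q * alpha[tf[i]] * (1.0 + s_on + c_on);
      tot_off += zoff[i];
      tot_on += zon[i];
    }
    z_off[b] = 1.0 + tot_off;
    z_on[b] = 1.0 + tot_on;
    expr[b] = q_btm * z_on[b] / (q_btm * z_on[b] + z_off[b]);
  }
  return List::create(_["z_on"] = z_on, _["z_off"] = z_off, _["expression"] = expr);
}

// Z_OFF-style DP with an arbitrary per-site weight factor folded into q;
// used for the limited-contact correction terms. `use` masks sites.
static double dp_weight_sum(const IntegerVector &start, const IntegerVector &end,
                            const IntegerVector &tf, const std::vector<double> &q,
                            const std::vector<char> &use,
                            const NumericMatrix &omega, double coop_range) {
  const int n = start.size();
  std::vector<double> z(n, 0.0);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!use[i]) continue;
    double s = 1.0;
    for (int j = 0; j < i; ++j) {
      if (!use[j] || end[j] > start[i]) continue;
      double gap = (double)start[i] - (double)end[j];
      s += pair_omega(tf[i], tf[j], gap, omega, coop_range) * z[j];
    }
    z[i] = q[i] * s;
    tot += z[i];
  }
  return 1.0 + tot;
}

// Limited-contact activation: at most n_ma bound activators contact the BTM.
// Q(sigma) = prod(alpha_R over bound repressors) * sum over non-empty contact
// subsets of bound activators of size <= n_ma of prod(alpha_A); Q = 1 when no
// activator is bound. The DP carries a contact-count dimension; the all-empty
// contact assignment for configurations with >= 1 bound activator is removed
// by subtracting (Z0 - Z_noact), both plain weight-sum DPs.
// [[Rcpp::export]]
List dp_limited_cpp(IntegerVector start, IntegerVector end, IntegerVector tf,
                    IntegerVector is_act, NumericVector qbase, NumericMatrix conc,
                    NumericVector alpha, NumericMatrix omega,
                    double coop_range, double q_btm, int n_ma) {
  const int n = start.size();
  const int nbins = conc.ncol();
  const int nc = n_ma + 1;  // contact counts 0..n_ma
  NumericVector z_on(nbins), z_off(nbins), expr(nbins);

  std::vector<double> q(n), zoffv(n);
  std::vector<char> all(n, 1), reponly(n);
  for (int i = 0; i < n; ++i) reponly[i] = is_act[i] ? 0 : 1;
  std::vector<double> zon(n * nc);

  for (int b = 0; b < nbins; ++b) {
    for (int i = 0; i < n; ++i) q[i] = qbase[i] * conc(tf[i], b);

    // Z_OFF: plain weight sum over all sites
    double zoff_tot = dp_weight_sum(start, end, tf, q, all, omega, coop_range);

    // contact-count DP
    std::fill(zon.begin(), zon.end(), 0.0);
    double contact_tot = 1.0;
    std::vector<double> T(nc);
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < nc; ++c) T[c] = (c == 0) ? 1.0 : 0.0;
      for (int j = 0; j < i; ++j) {
        if (end[j] > start[i]) continue;
        double gap = (double)start[i] - (double)end[j];
        double w = pair_omega(tf[i], tf[j], gap, omega, coop_range);
        for (int c = 0; c < nc; ++c) T[c] += w * zon[j * nc + c];
      }
      if (is_act[i]) {
        for (int c = nc - 1; c >= 0; --c) {
          double v = T[c];                       // bound, no contact
          if (c >= 1) v += alpha[tf[i]] * T[c - 1];  // bound, contacting
          zon[i * nc + c] = q[i] * v;
        }
      } else {
        for (int c = 0; c < nc; ++c) zon[i * nc + c] = q[i] * alpha[tf[i]] * T[c];
      }
      for (int c = 0; c < nc; ++c) contact_tot += zon[i * nc + c];
    }

    // remove the zero-contact term of configurations with >= 1 bound activator
    std::vector<double> qg(n);
    for (int i = 0; i < n; ++i) qg[i] = is_act[i] ? q[i] : q[i] * alpha[tf[i]];
    double z0 = dp_weight_sum(start, end, tf, qg, all, omega, coop_range);
    double znoact = dp_weight_sum(start, end, tf, qg, reponly, omega, coop_range);

    z_off[b] = zoff_tot;
    z_on[b] = contact_tot - (z0 - znoact);
    expr[b] = q_btm * z_on[b] / (q_btm * z_on[b] + z_off[b]);
  }
  return List::create(_["z_on"] = z_on, _["z_off"] = z_off, _["expression"] = expr);
}
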