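#include <Rcpp.h>
using namespace Rcpp;

// Weighted pool-adjacent-violators on a short vector of group means.
// Produces the weighted least-squares isotonic (non-decreasing) fit.
static void pava_inc(double *y, const double *w, int n) {
  std::vector<double> level(n), weight(n);
  std::vector<int> count(n);
  int m = 0;
  for (int i = 0; i < n; ++i) {
    level[m] = y[i];
    weight[m] = w[i];
    count[m] = 1;
    ++m;
    while (m > 1 && level[m - 2] > level[m - 1]) {
      double wsum = weight[m - 2] + weight[m - 1];
      level[m - 2] = (weight[m - 2] * level[m - 2] +
                      weight[m - 1] * level[m - 1]) / wsum;
      weight[m - 2] = wsum;
      count[m - 2] += count[m - 1];
      --m;
    }
  }
  int pos = 0;
  for (int b = 0; b < m; ++b)
    for (int j = 0; j < count[b]; ++j) y[pos++] = level[b];
}

// [[Rcpp::export(name = ".pavaCpp")]]
NumericVector pava_cpp(NumericVector y, NumericVector w, bool increasing) {
  int n = y.size();
  NumericVector out(n);
  if (increasing) {
    std::copy(y.begin(), y.end(), out.begin());
    pava_inc(REAL(out), REAL(w), n);
  } else {
    // non-increasing fit = reflected non-decreasing fit
    std::vector<double> yr(n), wr(n);
    for (int i = 0; i < n; ++i) {
      yr[i] = y[n - 1 - i];
      wr[i] = w[n - 1 - i];
    }
    pava_inc(yr.data(), wr.data(), n);
    for (int i = 0; i < n; ++i) out[i] = yr[n - 1 - i];
  }
  return out;
}

// Williams trend statistic for one row under a given sample->group map.
// group: 0-based, ordered by increasing concentration, group 0 = control.
// Returns the signed statistic (max over the two orderings) via *tbar and
// the pooled within-group SD via *sd.
static void williams_row(const double *x, const int *group, int nsamp,
                         int ngrp, double *mean_buf, double *w_buf,
                         double *tbar, double *sd) {
  std::vector<double> sum(ngrp, 0.0), sumsq(ngrp, 0.0);
  std::vector<int> n(ngrp, 0);
  for (int i = 0; i < nsamp; ++i) {
    int g = group[i];
    sum[g] += x[i];
    sumsq[g] += x[i] * x[i];
    ++n[g];
  }
  double sse = 0.0;
  for (int g = 0; g < ngrp; ++g) {
    mean_buf[g] = sum[g] / n[g];
    w_buf[g] = (double)n[g];
    sse += sumsq[g] - sum[g] * sum[g] / n[g];
  }
  double s2 = sse / (nsamp - ngrp);
  double se2 = s2 * (1.0 / n[ngrp - 1] + 1.0 / n[0]);
  double m0 = mean_buf[0];

  std::vector<double> inc(mean_buf, mean_buf + ngrp);
  pava_inc(inc.data(), w_buf, ngrp);
  double diff_inc = inc[ngrp - 1] - m0;

  std::vector<double> dec(ngrp), wdec(ngrp);
  for (int g = 0; g < ngrp; ++g) {
    dec[g] = mean_buf[ngrp - 1 - g];
    wdec[g] = w_buf[ngrp - 1 - g];
  }
  pava_inc(dec.data(), wdec.data(), ngrp); // reflected => non-increasing
  double diff_dec = m0 - dec[0];           // dec[0] is amalgamated top mean

  double t_inc, t_dec;
  if (se2 > 0.0) {
    double se = std::sqrt(se2);
    t_inc = diff_inc / se;
    t_dec = diff_dec / se;
  } else {
    t_inc = (diff_inc == 0.0) ? 0.0
            : (diff_inc > 0 ? R_PosInf : R_NegInf);
    t_dec = (diff_dec == 0.0) ? 0.0
            : (diff_dec > 0 ? R_PosInf : R_NegInf);
  }
  *sd = std::sqrt(std::max(s2, 0.0));
  *tbar = (t_inc >= t_dec) ? t_inc : -t_dec;
}

// [[Rcpp::export(name = ".williamsStatCpp")]]
NumericMatrix williams_stat_cpp(NumericMatrix mat, IntegerVector group,
                                int ngroups) {
  int ng = mat.nrow(), ns = mat.ncol();
  NumericMatrix out(ng, 2);
  std::vector<double> row(ns), mbuf(ngroups), wbuf(ngroups);
  for (int r = 0; r < ng; ++r) {
    for (int j = 0; j < ns; ++j) row[j] = mat(r, j);
    double t, s;
    williams_row(row.data(), INTEGER(group), ns, ngroups,
                 mbuf.data(), wbuf.data(), &t, &s);
    out(r, 0) = t;
    out(r, 1) = s;
  }
  return out;
}

// Count permutations with |t*| >= |t_obs| per row. permGroups holds one
// permuted sample->group assignment per row (B x nsamples). Ties count as
// exceedances (conservative).
// [[Rcpp::export(name = ".williamsPermCountCpp")]]
IntegerVector williams_perm_count_cpp(NumericMatrix mat, IntegerVector group,
                                      IntegerMatrix permGroups, int ngroups) {
  int ng = mat.nrow(), ns = mat.ncol(), B = permGroups.nrow();
  IntegerVector count(ng);
  std::vector<double> row(ns), mbuf(ngroups), wbuf(ngroups);
  std::vector<int> perm(ns);
  for (int r = 0; r < ng; ++r) {
    for (int j = 0; j < ns; ++j) row[j] = mat(r, j);
    double tobs, s;
    williams_row(row.data(), INTEGER(group), ns, ngroups,
                 mbuf.data(), wbuf.data(), &tobs, &s);
    double athr = std::fabs(tobs);
    int c = 0;
    for (int b = 0; b < B; ++b) {
      for (int j = 0; j < ns; ++j) perm[j] = permGroups(b, j);
      double t, sp;
      williams_row(row.data(), perm.data(), ns, ngroups,
                   mbuf.data(), wbuf.data(), &t, &sp);
      if (std::fabs(t) >= athr) ++c;
    }
    count[r] = c;
  }
  return count;
}
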