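#include <Rcpp.h>
using namespace Rcpp;

// Daily population-hazard aggregation for one departure state.
//
// Each subject's daily hazard over the day interval (u, u+1] is looked up
// directly in the ratetable array `haz` (n_age x n_year x 2, column-major)
// at the attained age floor((age_days + u) / dpy) and calendar year
// floor(year + u / dpy), both clamped at the table edges. A record with risk
// interval (tstart, tstop] contributes on every whole day it is at risk:
// ceil(tstart) <= u <= tstop - 1.
//
// Returns num[u] = sum of hazards of subjects at risk on day u and
// den[u] = their count, u = 0 .. n_days - 1.
// [[Rcpp::export]]
List cpp_pop_daily(NumericVector tstart, NumericVector tstop,
                   IntegerVector subj, NumericVector age_days,
                   NumericVector year, IntegerVector sexi,
                   NumericVector haz, int n_age, int n_year,
                   int age0, int year0, int n_days, double dpy) {
  const int n_rec = tstart.size();
  NumericVector num(n_days);
  IntegerVector den(n_days);
  for (int r = 0; r < n_rec; ++r) {
    int u0 = (int)std::ceil(tstart[r]);
    if (u0 < 0) u0 = 0;
    int u1 = (int)std::floor(tstop[r] - 1.0);
    if (u1 >= n_days) u1 = n_days - 1;
    const int i = subj[r];
    const double ad = age_days[i];
    const double y = year[i];
    const int soff = sexi[i] * n_age * n_year;
    for (int u = u0; u <= u1; ++u) {
      int ai = (int)std::floor((ad + u) / dpy) - age0;
      if (ai < 0) ai = 0;
      if (ai >= n_age) ai = n_age - 1;
      int yi = (int)std::floor(y + u / dpy) - year0;
      if (yi < 0) yi = 0;
      if (yi >= n_year) yi = n_year - 1;
      num[u] += haz[ai + n_age * yi + soff];
      den[u] += 1;
    }
  }
  return List::create(_["num"] = num, _["den"] = den);
}

// Product integral P(grid[0]-, grid[g]) = prod_{v <= g} (I + dL(v)).
//
// dL is n_grid x M (hazard increments per grid point per transition), from/to
// are 1-based state indices per transition, K the number of states. Diagonal
// increments are -(row sums of the off-diagonal increments). Returns a
// K x K x n_grid array; entry (h, j, g) is the probability of being in j at
// grid[g] given h just before grid[1].
// [[Rcpp::export]]
NumericVector cpp_prod_integral(NumericMatrix dL, IntegerVector from,
                                IntegerVector to, int K) {
  const int n_grid = dL.nrow();
  const int M = dL.ncol();
  NumericVector out(K * K * (R_xlen_t)n_grid);
  std::vector<double> P(K * K, 0.0), Pn(K * K, 0.0), A(K * K, 0.0);
  for (int h = 0; h < K; ++h) P[h + K * h] = 1.0;
  for (int g = 0; g < n_grid; ++g) {
    // A = I + dL(g)
    std::fill(A.begin(), A.end(), 0.0);
    for (int h = 0; h < K; ++h) A[h + K * h] = 1.0;
    for (int m = 0; m < M; ++m) {
      double d = dL(g, m);
      if (d != 0.0) {
        int f = from[m] - 1, t = to[m] - 1;
        A[f + K * t] += d;
        A[f + K * f] -= d;
      }
    }
    // Pn = P * A
    for (int j = 0; j < K; ++j) {
      for (int h = 0; h < K; ++h) {
        double s = 0.0;
        for (int l = 0; l < K; ++l) s += P[h + K * l] * A[l + K * j];
        Pn[h + K * j] = s;
      }
    }
    std::copy(Pn.begin(), Pn.end(), P.begin());
    std::copy(P.begin(), P.end(), out.begin() + (R_xlen_t)g * K * K);
  }
  out.attr("dim") = IntegerVector::create(K, K, n_grid);
  return out;
}

// Masked daily hazard matrix for a set of records: out(u, r) is record r's
// subject's daily hazard over (u, u+1] if the record is at risk on that whole
// day (d0[r] <= u <= d1[r]), else 0. Same table-lookup conventions as
// cpp_pop_daily.
// [[Rcpp::export]]
NumericMatrix cpp_masked_hazard(NumericVector age_days, NumericVector year,
                                IntegerVector sexi, IntegerVector d0,
                                IntegerVector d1, NumericVector haz,
                                int n_age, int n_year, int age0, int year0,
                                int n_days, double dpy) {
  const int n_rec = age_days.size();
  NumericMatrix out(n_days, n_rec);
  for (int r = 0; r < n_rec; ++r) {
    const double ad = age_days[r];
    const double y = year[r];
    const int soff = sexi[r] * n_age * n_year;
    int u1 = d1[r] < n_days - 1 ? d1[r] : n_days - 1;
    for (int u = d0[r] > 0 ? d0[r] : 0; u <= u1; ++u) {
      int ai = (int)std::floor((ad + u) / dpy) - age0;
      if (ai < 0) ai = 0;
      if (ai >= n_age) ai = n_age - 1;
      int yi = (int)std::floor(y + u / dpy) - year0;
      if (yi < 0) yi = 0;
      if (yi >= n_year) yi = n_year - 1;
      out(u, r) = haz[ai + n_age * yi + soff];
    }
  }
  return out;
}
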