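// Monte-Carlo kernel for the per-draw trial likelihood.
//
// Each parameter draw (sigma, b, p) needs a fresh response-cell table:
// thresholds are calibrated from p on a pooled sample of decision variables,
// per-condition cell frequencies are tabulated from the same draws, and the
// lapse mixture is applied analytically. A shared pool of standard-normal
// deviates is rescaled by each draw's sigma (common random numbers).
//
// Because the same pool is used for calibration and frequency estimation,
// a sample's decision and confidence are functions of its rank: the k1
// smallest decision variables fall below the decision threshold, and the
// cumulative rounded counts of the target conditional distribution cut each
// branch into confidence bins. The kernel therefore partitions by rank with
// nth_element instead of placing explicit thresholds; for continuous
// variables this is identical to the R reference path
// (calibrate_thresholds / assign_responses), and a consistency test pins
// the two. Explicit threshold values, when needed, come from the R path.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <utility>
#include <vector>

using namespace Rcpp;

// round-half-up, matching the R helper round_half_up()
static inline long iround_up(double x) {
  return static_cast<long>(std::floor(x + 0.5));
}

typedef std::pair<double, int> zc_cond;  // (confidence variable, condition)

struct Workspace {
  std::vector<double> x1, x2, zd, p1, p2;
  std::vector<int> idx;
  std::vector<zc_cond> branch[2];
  void resize(int n) {
    x1.resize(n); x2.resize(n); zd.resize(n); idx.resize(n);
  }
};

// one draw's cell counts; returns false when a decision branch is degenerate
static bool cell_counts_one(int N,
                            const double* e1, const double* e2,
                            const double* mu1, const double* mu2,
                            const int* cond, int ncond,
                            int model, double sigma,
                            const double* p,  // 12 cells, decision-major
                            const double* contrasts, int K,
                            int min_branch,
                            Workspace& ws, std::vector<int>& counts) {
  const double sd = sigma / std::sqrt(2.0);
  ws.resize(N);
  std::fill(counts.begin(), counts.end(), 0);

  for (int j = 0; j < N; ++j) {
    ws.x1[j] = mu1[j] + sd * e1[j];
    ws.x2[j] = mu2[j] + sd * e2[j];
  }

  if (model == 2) {  // Bayes: posterior over intervals, log-space max shift
    const double inv = 1.0 / (sigma * sigma);
    ws.p1.resize(N); ws.p2.resize(N);
    std::vector<double> la(2 * K);
    for (int j = 0; j < N; ++j) {
      double m = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        const double d1 = ws.x1[j] - contrasts[k];
        const double d2 = ws.x2[j] - contrasts[k];
        la[k]     = -(d1 * d1 + ws.x2[j] * ws.x2[j]) * inv;      // i = 1
        la[K + k] = -(ws.x1[j] * ws.x1[j] + d2 * d2) * inv;      // i = 2
        if (la[k] > m) m = la[k];
        if (la[K + k] > m) m = la[K + k];
      }
      double a = 0.0, b = 0.0;
      for (int k = 0; k < K; ++k) {
        a += std::exp(la[k] - m);
        b += std::exp(la[K + k] - m);
      }
      ws.p1[j] = a / (a + b);
      ws.p2[j] = b / (a + b);
      ws.zd[j] = ws.p2[j];
    }
  } else {
    for (int j = 0; j < N; ++j) ws.zd[j] = ws.x2[j] - ws.x1[j];
  }

  // decision split from p(d = 1): the k1 smallest z^D take decision 1
  double pd[2] = {0.0, 0.0};
  for (int c = 0; c < 6; ++c) { pd[0] += p[c]; pd[1] += p[6 + c]; }
  long k1 = iround_up(pd[0] * N);
  if (k1 < 0) k1 = 0;
  if (k1 > N) k1 = N;
  if ((k1 > 0 && k1 < min_branch) || (N - k1 > 0 && N - k1 < min_branch))
    return false;

  const double* zd = ws.zd.data();
  int* idx = ws.idx.data();
  for (int j = 0; j < N; ++j) idx[j] = j;
  if (k1 > 0 && k1 < N) {
    std::nth_element(idx, idx + k1, idx + N,
                     [zd](int a, int b) { return zd[a] < zd[b]; });
  }

  // gather (confidence variable, condition) per branch
  ws.branch[0].clear(); ws.branch[1].clear();
  ws.branch[0].reserve(k1); ws.branch[1].reserve(N - k1);
  for (int r = 0; r < N; ++r) {
    const int j = idx[r];
    const int dj = r < k1 ? 0 : 1;  // 0-based decision - 1
    double z;
    if (model == 0) z = dj ? ws.x2[j] - ws.x1[j] : ws.x1[j] - ws.x2[j];
    else if (model == 1) z = dj ? ws.x2[j] : ws.x1[j];
    else z = dj ? ws.p2[j] : ws.p1[j];
    ws.branch[dj].push_back(zc_cond(z, cond[j]));
  }

  // per-branch confidence bins from cumulative rounded conditional counts
  for (int d0 = 0; d0 < 2; ++d0) {
    std::vector<zc_cond>& zb = ws.branch[d0];
    const long nd = static_cast<long>(zb.size());
    if (nd == 0) continue;  // unreachable branch
    double cum = 0.0;
    long prev = 0;
    for (int c = 0; c < 6; ++c) {
      long k;
      if (c < 5) {
        cum += p[d0 * 6 + c] / pd[d0];
        k = iround_up(cum * nd);
        if (k < prev) k = prev;
        if (k > nd) k = nd;
      } else {
        k = nd;
      }
      if (k > prev && k < nd) {
        std::nth_element(zb.begin() + prev, zb.begin() + k, zb.begin() + nd);
      }
      for (long r = prev; r < k; ++r) {
        ++counts[zb[r].second * 12 + d0 * 6 + c];
      }
      prev = k;
    }
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_loglik_draws(NumericVector e1, NumericVector e2,
                               NumericVector mu1, NumericVector mu2,
                               IntegerVector cond, int ncond,
                               int model,
                               NumericVector sigma, NumericVector lapse,
                               NumericMatrix p,
                               NumericVector contrasts,
                               NumericVector data_counts,
                               int n_per_condition, int min_branch) {
  const int N = e1.size();
  const int ndraw = sigma.size();
  NumericVector out(ndraw);

  std::vector<int> nz;
  for (int i = 0; i < data_counts.size(); ++i)
    if (data_counts[i] > 0) nz.push_back(i);
  if (nz.empty()) return out;  // no trials: likelihood is identically 1

  Workspace ws;
  std::vector<int> counts(ncond * 12);
  std::vector<double> pr(12);

  for (int t = 0; t < ndraw; ++t) {
    for (int c = 0; c < 12; ++c) pr[c] = p(t, c);
    const bool ok = cell_counts_one(N, e1.begin(), e2.begin(),
                                    mu1.begin(), mu2.begin(),
                                    cond.begin(), ncond, model, sigma[t],
                                    pr.data(), contrasts.begin(),
                                    contrasts.size(), min_branch, ws, counts);
    if (!ok) {
      out[t] = R_NegInf;
      continue;
    }
    const double b = lapse[t];
    double ll = 0.0;
    for (size_t i = 0; i < nz.size(); ++i) {
      const int idx = nz[i];
      const double pcell =
        (1.0 - b) * counts[idx] / static_cast<double>(n_per_condition) + b / 12.0;
      if (pcell <= 0.0) { ll = R_NegInf; break; }
      ll += data_counts[idx] * std::log(pcell);
    }
    out[t] = ll;
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cell_table(NumericVector e1, NumericVector e2,
                             NumericVector mu1, NumericVector mu2,
                             IntegerVector cond, int ncond,
                             int model, double sigma, double lapse,
                             NumericVector p,
                             NumericVector contrasts,
                             int n_per_condition, int min_branch) {
  const int N = e1.size();
  Workspace ws;
  std::vector<int> counts(ncond * 12);
  const bool ok = cell_counts_one(N, e1.begin(), e2.begin(),
                                  mu1.begin(), mu2.begin(),
                                  cond.begin(), ncond, model, sigma,
                                  p.begin(), contrasts.begin(),
                                  contrasts.size(), min_branch, ws, counts);
  if (!ok) stop("degenerate decision branch in cell-table computation");
  NumericVector out(ncond * 12);
  for (int i = 0; i < ncond * 12; ++i) {
    out[i] = (1.0 - lapse) * counts[i] / static_cast<double>(n_per_condition) +
      lapse / 12.0;
  }
  return out;
}
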