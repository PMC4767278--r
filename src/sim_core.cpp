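#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

extern "C" void wc_sigmoid_batch(int n, const double *x, double *out,
                                 double gain, double offset);

namespace {

// Edges regrouped by delay value so the history row is resolved once per
// (step, delay) instead of once per edge.
struct EdgeGroups {
  std::vector<int> src, dst;
  std::vector<double> w;
  std::vector<int> group_delay;   // delay of each group
  std::vector<int> group_end;     // exclusive end index of each group
};

EdgeGroups group_by_delay(const IntegerVector &src, const IntegerVector &dst,
                          const NumericVector &w, const IntegerVector &d) {
  const int m = src.size();
  std::vector<int> ord(m);
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return d[a] < d[b]; });
  EdgeGroups g;
  g.src.resize(m); g.dst.resize(m); g.w.resize(m);
  for (int i = 0; i < m; ++i) {
    g.src[i] = src[ord[i]];
    g.dst[i] = dst[ord[i]];
    g.w[i] = w[ord[i]];
  }
  for (int i = 0; i < m; ++i) {
    int di = d[ord[i]];
    if (g.group_delay.empty() || g.group_delay.back() != di) {
      g.group_delay.push_back(di);
      g.group_end.push_back(i + 1);
    } else {
      g.group_end.back() = i + 1;
    }
  }
  return g;
}

inline void accumulate(const EdgeGroups &g, int t, int L, int n_units,
                       const std::vector<double> &hist,
                       const double *init_row, double *ext) {
  int start = 0;
  for (size_t gi = 0; gi < g.group_delay.size(); ++gi) {
    const int td = t - g.group_delay[gi];
    const double *row = (td < 0) ? init_row
                                 : &hist[(size_t)(td % L) * n_units];
    const int end = g.group_end[gi];
    for (int k = start; k < end; ++k) ext[g.dst[k]] += g.w[k] * row[g.src[k]];
    start = end;
  }
}

} // namespace

// Delay-coupled Wilson-Cowan lattice integrator.
//
// Fixed-step integration at dt with staggered (Gauss-Seidel) updating: the
// whole E field is stepped first, then the I field is stepped using the
// freshly updated E for the intra-unit term. Inter-unit coupling always
// reads the excitatory history buffer at (t - delay); the buffer holds the
// state at the *start* of each step, so a zero-delay edge transmits the
// pre-update value of the current step, and pre-history (t - delay < 0)
// reads the initial state.
//
// noise: n_steps x n_macrocolumns matrix of standard Gaussian draws, scaled
// by z inside the sigmoid argument of the E equation and shared within each
// macrocolumn. drive: length-n_steps stimulus added to the E sigmoid
// argument of masked units (empty = no drive).
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int n_units,
              IntegerVector exc_src, IntegerVector exc_dst,
              NumericVector exc_w, IntegerVector exc_d,
              IntegerVector inh_src, IntegerVector inh_dst,
              NumericVector inh_w, IntegerVector inh_d,
              NumericVector par,  // w_ee w_ie w_ei w_ii e0 i0 tau_e tau_i gain offset
              NumericMatrix noise, double z, IntegerVector mc_of,
              NumericVector drive, LogicalVector mask,
              double dt, NumericVector E_init, NumericVector I_init,
              bool keep_units, bool staggered = true) {
  const int n_steps = noise.nrow();
  const double w_ee = par[0], w_ie = par[1], w_ei = par[2], w_ii = par[3];
  const double e0 = par[4], i0 = par[5], tau_e = par[6], tau_i = par[7];
  const double gain = par[8], offset = par[9];
  const bool has_drive = drive.size() > 0;

  int maxd = 0;
  for (int k = 0; k < exc_d.size(); ++k) if (exc_d[k] > maxd) maxd = exc_d[k];
  for (int k = 0; k < inh_d.size(); ++k) if (inh_d[k] > maxd) maxd = inh_d[k];
  const int L = maxd + 1;

  EdgeGroups ge = group_by_delay(exc_src, exc_dst, exc_w, exc_d);
  EdgeGroups gi = group_by_delay(inh_src, inh_dst, inh_w, inh_d);

  std::vector<double> hist((size_t)L * n_units);
  std::vector<double> E(E_init.begin(), E_init.end());
  std::vector<double> I(I_init.begin(), I_init.end());
  std::vector<double> init_row(E_init.begin(), E_init.end());

  std::vector<double> ext_e(n_units), ext_i(n_units);
  std::vector<double> arg(n_units), sg(n_units);
  std::vector<double> zxi(n_units);

  int n_mask = 0;
  for (int i = 0; i < n_units; ++i) if (mask[i]) ++n_mask;
  if (n_mask == 0) stop("empty mask");

  NumericVector mask_mean(n_steps);
  NumericMatrix e_series = keep_units ? NumericMatrix(n_steps, n_units)
                                      : NumericMatrix(0, 0);

  for (int t = 0; t < n_steps; ++t) {
    double *row_t = &hist[(size_t)(t % L) * n_units];
    std::copy(E.begin(), E.end(), row_t);

    std::fill(ext_e.begin(), ext_e.end(), 0.0);
    std::fill(ext_i.begin(), ext_i.end(), 0.0);
    accumulate(ge, t, L, n_units, hist, init_row.data(), ext_e.data());
    accumulate(gi, t, L, n_units, hist, init_row.data(), ext_i.data());

    const double drv = has_drive ? drive[t] : 0.0;
    for (int i = 0; i < n_units; ++i) zxi[i] = z * noise(t, mc_of[i]);

    // E field
    for (int i = 0; i < n_units; ++i) {
      double a = w_ee * E[i] + w_ie * I[i] + e0 + ext_e[i] + zxi[i];
      if (has_drive && mask[i]) a += drv;
      arg[i] = a;
    }
    wc_sigmoid_batch(n_units, arg.data(), sg.data(), gain, offset);
    if (staggered) {
      for (int i = 0; i < n_units; ++i)
        E[i] += dt * (-E[i] + sg[i]) / tau_e;
      // I field uses the freshly updated E
      for (int i = 0; i < n_units; ++i)
        arg[i] = w_ei * E[i] + w_ii * I[i] + i0 + ext_i[i];
    } else {
      // simultaneous: I field sees the pre-update E
      for (int i = 0; i < n_units; ++i)
        arg[i] = w_ei * E[i] + w_ii * I[i] + i0 + ext_i[i];
      for (int i = 0; i < n_units; ++i)
        E[i] += dt * (-E[i] + sg[i]) / tau_e;
    }
    wc_sigmoid_batch(n_units, arg.data(), sg.data(), gain, offset);
    double acc = 0.0, chk = 0.0;
    for (int i = 0; i < n_units; ++i) {
      I[i] += dt * (-I[i] + sg[i]) / tau_i;
      chk += E[i] + I[i];
      if (mask[i]) acc += E[i];
    }
    if (!std::isfinite(chk))
      stop("non-finite state at step %d", t + 1);
    mask_mean[t] = acc / n_mask;
    if (keep_units)
      for (int i = 0; i < n_units; ++i) e_series(t, i) = E[i];
  }

  return List::create(_["mask_mean"] = mask_mean,
                      _["e_series"] = e_series,
                      _["E_final"] = NumericVector(E.begin(), E.end()),
                      _["I_final"] = NumericVector(I.begin(), I.end()));
}
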