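#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-frame self-motion decoding along a whole trajectory.
//
// For every frame: ray-trace the pixel validity mask against the circular
// platform, evaluate the analytic curvilinear flow (deg/s) from the
// ground-truth (v_z, omega_y), add Gaussian sensing noise, and decode
// (v_hat, omega_hat) with the two-stage Gaussian-tuned template match.
// Per-pixel Gaussian terms with exponents above EXP_CUT are skipped; at
// that cut a term is ~1e-13 of a peak contribution, far below double
// rounding in the profile sums.

static const double EXP_CUT = 30.0;

static double readout(const std::vector<double>& prof,
                      const NumericVector& axis, int method, int half) {
  int n = prof.size(), pk = 0;
  for (int i = 1; i < n; ++i) if (prof[i] > prof[pk]) pk = i;
  if (method == 0) return axis[pk];                    // max
  int lo = 0, hi = n - 1;
  if (method == 2) {                                   // local vector sum
    lo = std::max(0, pk - half);
    hi = std::min(n - 1, pk + half);
  }
  double sw = 0.0, swa = 0.0;
  for (int i = lo; i <= hi; ++i) { sw += prof[i]; swa += prof[i] * axis[i]; }
  if (sw <= 0.0) return axis[pk];
  return swa / sw;
}

// [[Rcpp::export]]
List fg_estimate_series(NumericVector px, NumericVector py,
                        NumericVector heading_deg, NumericVector vz,
                        NumericVector wy, NumericVector theta_deg,
                        NumericVector phi_deg, double h, double gamma_deg,
                        double platform_radius, double dmin, double dmax,
                        double sigma_flow, NumericVector v_samples,
                        NumericVector w_samples, double sigma_v,
                        double sigma_w, int readout_method,
                        double window_fraction) {
  const double d2r = M_PI / 180.0, r2d = 180.0 / M_PI;
  const int T = px.size(), n = theta_deg.size();
  const int nv = v_samples.size(), nw = w_samples.size();
  const double g = gamma_deg * d2r;
  const double sg = std::sin(g), cg = std::cos(g);
  const double R2 = platform_radius * platform_radius;

  // per-pixel geometry and basis fields
  std::vector<double> ox(n), oz(n), a1(n), a2(n), b1(n), b2(n), dcf(n),
      bb(n);
  std::vector<bool> valid0(n);
  for (int l = 0; l < n; ++l) {
    double th = theta_deg[l] * d2r, ph = phi_deg[l] * d2r;
    double sth = std::sin(th), cth = std::cos(th);
    double sph = std::sin(ph), cph = std::cos(ph);
    double s = sg * cth * cph - cg * sph;      // ground-normal denominator
    bool ok = s > 1e-12;
    double D = ok ? h / s : 0.0;
    ok = ok && D > dmin && D <= dmax;
    valid0[l] = ok;
    double t_th = sth / cph * cg;
    double t_ph = cph * sg + cth * sph * cg;
    a1[l] = s * t_th * r2d;                    // (1/h) a v_z -> deg/s
    a2[l] = s * t_ph * r2d;
    b1[l] = -cg + cth * sph / cph * sg;
    b2[l] = -sth * sg;
    dcf[l] = a1[l] * -b2[l] + a2[l] * b1[l];   // a . b_perp
    bb[l] = b1[l] * b1[l] + b2[l] * b2[l];
    ox[l] = D * sth * cph;                     // horizontal hit offsets
    oz[l] = D * (sg * sph + cg * cth * cph);
  }

  const double v0 = v_samples[0],
      v_step = nv > 1 ? v_samples[1] - v_samples[0] : 1.0;
  const double w0 = w_samples[0],
      w_step = nw > 1 ? w_samples[1] - w_samples[0] : 1.0;
  // windowed accumulation assumes a uniform axis; thinned banks may have
  // uneven spacing, in which case every sample is evaluated
  bool unif_v = true, unif_w = true;
  for (int j = 2; j < nv; ++j)
    if (std::fabs(v_samples[j] - v_samples[j - 1] - v_step) > 1e-9)
      unif_v = false;
  for (int k = 2; k < nw; ++k)
    if (std::fabs(w_samples[k] - w_samples[k - 1] - w_step) > 1e-9)
      unif_w = false;
  const int half_v = std::max(1, (int)std::lround(window_fraction * nv / 2.0));
  const int half_w = std::max(1, (int)std::lround(window_fraction * nw / 2.0));
  const double Mv = sigma_v * std::sqrt(2.0 * EXP_CUT);

  NumericVector v_hat(T), w_hat(T), cert_v(T), cert_w(T);
  IntegerVector n_valid(T);
  std::vector<double> ft(n), fp(n), prof_v(nv), prof_w(nw);
  std::vector<int> idx; idx.reserve(n);

  RNGScope rng;

  for (int t = 0; t < T; ++t) {
    double hd = heading_deg[t] * d2r;
    double ch = std::cos(hd), sh = std::sin(hd);
    idx.clear();
    for (int l = 0; l < n; ++l) {
      if (!valid0[l]) continue;
      double gx = px[t] + oz[l] * ch + ox[l] * sh;
      double gy = py[t] + oz[l] * sh - ox[l] * ch;
      if (gx * gx + gy * gy <= R2) idx.push_back(l);
    }
    n_valid[t] = idx.size();
    if (idx.empty()) {
      v_hat[t] = NA_REAL; w_hat[t] = NA_REAL;
      cert_v[t] = NA_REAL; cert_w[t] = NA_REAL;
      continue;
    }
    for (int l : idx) {
      ft[l] = a1[l] * vz[t] / h + b1[l] * wy[t];
      fp[l] = a2[l] * vz[t] / h + b2[l] * wy[t];
      if (sigma_flow > 0.0) {
        ft[l] += R::rnorm(0.0, sigma_flow);
        fp[l] += R::rnorm(0.0, sigma_flow);
      }
    }

    // linear profile: residual (psi . b_perp h - a . b_perp v_j)
    std::fill(prof_v.begin(), prof_v.end(), 0.0);
    const double inv2sv = 1.0 / (2.0 * sigma_v * sigma_v);
    for (int l : idx) {
      double cc = (ft[l] * -b2[l] + fp[l] * b1[l]) * h;
      double d = dcf[l];
      int jlo = 0, jhi = nv - 1;
      if (unif_v && std::fabs(d) > 1e-14) {
        double lo = (cc - Mv) / d, hiv = (cc + Mv) / d;
        if (lo > hiv) std::swap(lo, hiv);
        jlo = std::max(0, (int)std::ceil((lo - v0) / v_step));
        jhi = std::min(nv - 1, (int)std::floor((hiv - v0) / v_step));
      } else if (std::fabs(cc) > Mv) {
        continue;
      }
      for (int j = jlo; j <= jhi; ++j) {
        double r = cc - d * v_samples[j];
        prof_v[j] += std::exp(-r * r * inv2sv);
      }
    }
    v_hat[t] = readout(prof_v, v_samples, readout_method, half_v);
    cert_v[t] = *std::max_element(prof_v.begin(), prof_v.end()) /
        idx.size();

    // rotational profile: residual ||psi - (1/h) a v_hat - b w_k||
    std::fill(prof_w.begin(), prof_w.end(), 0.0);
    const double inv2sw = 1.0 / (2.0 * sigma_w * sigma_w);
    for (int l : idx) {
      double r1 = ft[l] - a1[l] * v_hat[t] / h;
      double r2 = fp[l] - a2[l] * v_hat[t] / h;
      double A = r1 * r1 + r2 * r2;
      double C = bb[l];
      if (C < 1e-14) continue;
      double B = r1 * b1[l] + r2 * b2[l];
      double mu = B / C;
      double e0 = (A - B * B / C) * inv2sw;
      if (e0 > EXP_CUT) continue;
      double hw = std::sqrt((EXP_CUT - e0) / (C * inv2sw));
      int klo = 0, khi = nw - 1;
      if (unif_w) {
        klo = std::max(0, (int)std::ceil((mu - hw - w0) / w_step));
        khi = std::min(nw - 1, (int)std::floor((mu + hw - w0) / w_step));
      }
      for (int k = klo; k <= khi; ++k) {
        double dw = w_samples[k] - mu;
        prof_w[k] += std::exp(-(e0 + C * dw * dw * inv2sw));
      }
    }
    w_hat[t] = readout(prof_w, w_samples, readout_method, half_w);
    cert_w[t] = *std::max_element(prof_w.begin(), prof_w.end()) /
        idx.size();
  }

  return List::create(_["v_hat"] = v_hat, _["omega_hat"] = w_hat,
                      _["certainty_v"] = cert_v,
                      _["certainty_omega"] = cert_w,
                      _["n_valid"] = n_valid);
}
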