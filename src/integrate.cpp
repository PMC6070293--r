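#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Discrete Laplace-Beltrami application: (Lf)_i = sum_j (w_ij / a_i) (f_j - f_i)
// with symmetric finite-volume weights w_ij = edge_length / centroid_distance.
// The shared weights make the operator exactly conservative:
// sum_i a_i (Lf)_i = 0 for every field f.
static inline void lap_apply(const std::vector<int> &ei,
                             const std::vector<int> &ej,
                             const std::vector<double> &w,
                             const std::vector<double> &inv_a,
                             const double *f, double *out, int n) {
  for (int i = 0; i < n; ++i) out[i] = 0.0;
  const int m = ei.size();
  for (int e = 0; e < m; ++e) {
    int i = ei[e], j = ej[e];
    double flux = w[e] * (f[j] - f[i]);
    out[i] += flux * inv_a[i];
    out[j] -= flux * inv_a[j];
  }
}

static void unpack_edges(IntegerVector ei, IntegerVector ej, NumericVector w,
                         std::vector<int> &vi, std::vector<int> &vj,
                         std::vector<double> &vw) {
  const int m = ei.size();
  vi.resize(m); vj.resize(m); vw.resize(m);
  for (int e = 0; e < m; ++e) {
    vi[e] = ei[e] - 1;
    vj[e] = ej[e] - 1;
    vw[e] = w[e];
  }
}

// [[Rcpp::export]]
NumericVector lap_apply_cpp(IntegerVector ei, IntegerVector ej,
                            NumericVector w, NumericVector areas,
                            NumericVector f) {
  const int n = areas.size();
  std::vector<int> vi, vj;
  std::vector<double> vw;
  unpack_edges(ei, ej, w, vi, vj, vw);
  std::vector<double> inv_a(n);
  for (int i = 0; i < n; ++i) inv_a[i] = 1.0 / areas[i];
  NumericVector out(n);
  std::vector<double> tmp(n);
  lap_apply(vi, vj, vw, inv_a, REAL(f), tmp.data(), n);
  for (int i = 0; i < n; ++i) out[i] = tmp[i];
  return out;
}

// Linear surface species: dC/dt = D Lap C + source_i - r C.
// Records the unweighted mean of C over each readout region every
// `record_every` steps (frame 0 = state right after t = 0, i.e. post-bleach).
// If store_fields, also stores full snapshots at the same frames.
// If ss_tol > 0, stops early once max|dC/dt| / max(C, eps) < ss_tol (1/s).
// [[Rcpp::export]]
List integrate_linear_cpp(IntegerVector ei, IntegerVector ej, NumericVector w,
                          NumericVector areas, NumericVector C0, double D,
                          double r, NumericVector source, double dt,
                          int n_steps, int record_every, List regions,
                          bool store_fields, double ss_tol) {
  const int n = areas.size();
  std::vector<int> vi, vj;
  std::vector<double> vw;
  unpack_edges(ei, ej, w, vi, vj, vw);
  std::vector<double> inv_a(n);
  for (int i = 0; i < n; ++i) inv_a[i] = 1.0 / areas[i];

  std::vector<double> C(C0.begin(), C0.end()), lap(n);
  const int nr = regions.size();
  std::vector<std::vector<int>> reg(nr);
  for (int k = 0; k < nr; ++k) {
    IntegerVector rk = regions[k];
    reg[k].assign(rk.begin(), rk.end());
    for (auto &x : reg[k]) x -= 1;
  }
  int n_frames = n_steps / record_every + 1;
  NumericMatrix trace(n_frames, nr);
  NumericVector frame_t(n_frames);
  NumericMatrix fields;
  if (store_fields) fields = NumericMatrix(n, n_frames);

  auto record = [&](int frame, double t) {
    frame_t[frame] = t;
    for (int k = 0; k < nr; ++k) {
      double s = 0.0;
      for (int idx : reg[k]) s += C[idx];
      trace(frame, k) = reg[k].empty() ? NA_REAL : s / reg[k].size();
    }
    if (store_fields)
      for (int i = 0; i < n; ++i) fields(i, frame) = C[i];
  };
  record(0, 0.0);

  int frame = 1, steps_done = 0;
  bool converged = false;
  for (int step = 1; step <= n_steps; ++step) {
    lap_apply(vi, vj, vw, inv_a, C.data(), lap.data(), n);
    double max_rate = 0.0, max_c = 0.0;
    for (int i = 0; i < n; ++i) {
      double dC = D * lap[i] + source[i] - r * C[i];
      C[i] += dt * dC;
      if (C[i] < 0) C[i] = 0;
      double ar = std::fabs(dC);
      if (ar > max_rate) max_rate = ar;
      if (C[i] > max_c) max_c = C[i];
    }
    steps_done = step;
    if (step % record_every == 0 && frame < n_frames)
      record(frame++, step * dt);
    if (ss_tol > 0 && max_rate < ss_tol * std::max(max_c, 1e-300)) {
      converged = true;
      break;
    }
    if (step % 1000 == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(C[i]))
          stop("non-finite concentration at step %d", step);
    }
  }
  NumericVector Cend(n);
  for (int i = 0; i < n; ++i) Cend[i] = C[i];
  List out = List::create(
      _["times"] = frame_t, _["trace"] = trace, _["C"] = Cend,
      _["n_frames"] = frame, _["steps"] = steps_done,
      _["converged"] = converged);
  if (store_fields) out["fields"] = fields;
  return out;
}

struct PatchParams {
  double D_RT, D_RD, D_GAP, r_RT, r_RD, r_GAP;
  double k0p, k1p, k2p, k1n, k2n, k3n, Csat, h, Ectot, jRDp, rnoise, V;
};

static PatchParams read_params(NumericVector p) {
  PatchParams q;
  q.D_RT = p["D_RT"]; q.D_RD = p["D_RD"]; q.D_GAP = p["D_GAP"];
  q.r_RT = p["r_RT"]; q.r_RD = p["r_RD"]; q.r_GAP = p["r_GAP"];
  q.k0p = p["k0p"]; q.k1p = p["k1p"]; q.k2p = p["k2p"];
  q.k1n = p["k1n"]; q.k2n = p["k2n"]; q.k3n = p["k3n"];
  q.Csat = p["Csat"]; q.h = p["h"]; q.Ectot = p["Ectot"];
  q.jRDp = p["jRDp"]; q.rnoise = p["rnoise"]; q.V = p["V"];
  return q;
}

static inline double hill_term(double c, double Csat, double h) {
  if (c <= 0) return 0.0;
  if (h == 2.0) {
    double c2 = c * c;
    return c2 / (Csat * Csat + c2);
  }
  double ch = std::pow(c, h);
  return ch / (std::pow(Csat, h) + ch);
}

// Quasi-static GEF patch model (three PDE fields, GEF from the closed form).
// mod0/mod2 are per-cell multipliers on k0p / k2n. Noise converts RD to RT as
// dN/da = dt * p * rnoise * C_RD with p ~ U(0,1) drawn per cell per step.
// [[Rcpp::export]]
List integrate_patch_cpp(IntegerVector ei, IntegerVector ej, NumericVector w,
                         NumericVector areas, NumericVector p,
                         NumericVector CRT0, NumericVector CRD0,
                         NumericVector CGAP0, NumericVector mod0,
                         NumericVector mod2, double dt, int n_steps,
                         int record_every, bool store_fields) {
  const int n = areas.size();
  PatchParams pp = read_params(p);
  std::vector<int> vi, vj;
  std::vector<double> vw;
  unpack_edges(ei, ej, w, vi, vj, vw);
  std::vector<double> inv_a(n), a(n);
  for (int i = 0; i < n; ++i) { a[i] = areas[i]; inv_a[i] = 1.0 / a[i]; }

  std::vector<double> RT(CRT0.begin(), CRT0.end());
  std::vector<double> RD(CRD0.begin(), CRD0.end());
  std::vector<double> GAP(CGAP0.begin(), CGAP0.end());
  std::vector<double> GEF(n), lRT(n), lRD(n), lGAP(n);

  int n_frames = n_steps / record_every + 1;
  NumericVector frame_t(n_frames), max_rt(n_frames), ec_t(n_frames);
  IntegerVector argmax_rt(n_frames);
  NumericMatrix fRT, fRD, fGAP;
  if (store_fields) {
    fRT = NumericMatrix(n, n_frames);
    fRD = NumericMatrix(n, n_frames);
    fGAP = NumericMatrix(n, n_frames);
  }
  double clip_total = 0.0;  // clipped mass (molecules), all fields

  double Ec = pp.Ectot;
  auto gef_update = [&]() {
    double integral = 0.0;
    for (int i = 0; i < n; ++i)
      integral += a[i] * (pp.k1p * RT[i] + pp.k2p * RT[i] * RT[i]) / pp.V;
    Ec = pp.Ectot / (1.0 + integral);
    double c1 = pp.k1p * Ec / pp.V, c2 = pp.k2p * Ec / pp.V;
    for (int i = 0; i < n; ++i) GEF[i] = c1 * RT[i] + c2 * RT[i] * RT[i];
  };

  auto record = [&](int frame, double t) {
    frame_t[frame] = t;
    double m = -1.0; int am = 0;
    for (int i = 0; i < n; ++i)
      if (RT[i] > m) { m = RT[i]; am = i; }
    max_rt[frame] = m;
    argmax_rt[frame] = am + 1;
    ec_t[frame] = Ec;
    if (store_fields)
      for (int i = 0; i < n; ++i) {
        fRT(i, frame) = RT[i];
        fRD(i, frame) = RD[i];
        fGAP(i, frame) = GAP[i];
      }
  };
  gef_update();
  record(0, 0.0);

  int frame = 1;
  const bool noisy = pp.rnoise > 0;
  for (int step = 1; step <= n_steps; ++step) {
    gef_update();
    lap_apply(vi, vj, vw, inv_a, RT.data(), lRT.data(), n);
    lap_apply(vi, vj, vw, inv_a, RD.data(), lRD.data(), n);
    lap_apply(vi, vj, vw, inv_a, GAP.data(), lGAP.data(), n);
    for (int i = 0; i < n; ++i) {
      double act = pp.k0p * mod0[i] * GEF[i] * RD[i];
      double noise = noisy ? unif_rand() * pp.rnoise * RD[i] : 0.0;
      double hyd = (pp.k1n + pp.k2n * mod2[i] * GAP[i]) * RT[i];
      double dRT = pp.D_RT * lRT[i] + act + noise - hyd - pp.r_RT * RT[i];
      double dRD = pp.D_RD * lRD[i] + pp.jRDp + hyd - act - noise -
                   pp.r_RD * RD[i];
      double dGAP = pp.D_GAP * lGAP[i] +
                    pp.k3n * hill_term(RT[i], pp.Csat, pp.h) -
                    pp.r_GAP * GAP[i];
      RT[i] += dt * dRT;
      RD[i] += dt * dRD;
      GAP[i] += dt * dGAP;
      if (RT[i] < 0) { clip_total -= RT[i] * a[i]; RT[i] = 0; }
      if (RD[i] < 0) { clip_total -= RD[i] * a[i]; RD[i] = 0; }
      if (GAP[i] < 0) { clip_total -= GAP[i] * a[i]; GAP[i] = 0; }
    }
    if (step % record_every == 0 && frame < n_frames) {
      gef_update();
      record(frame++, step * dt);
      if (!std::isfinite(RT[0]) || !std::isfinite(max_rt[frame - 1]))
        stop("non-finite state at step %d", step);
    }
  }

  NumericVector outRT(n), outRD(n), outGAP(n);
  for (int i = 0; i < n; ++i) {
    outRT[i] = RT[i]; outRD[i] = RD[i]; outGAP[i] = GAP[i];
  }
  List out = List::create(
      _["times"] = frame_t, _["max_rt"] = max_rt, _["argmax_rt"] = argmax_rt,
      _["ec"] = ec_t, _["clip_total"] = clip_total, _["CRT"] = outRT,
      _["CRD"] = outRD, _["CGAP"] = outGAP);
  if (store_fields) {
    out["fRT"] = fRT; out["fRD"] = fRD; out["fGAP"] = fGAP;
  }
  return out;
}

// Expanded model with explicit GEF binding kinetics (four PDE fields):
// dC_GEF/dt = D_GEF Lap C_GEF + rho1 (Ec/V) C_RT + rho2 (Ec/V) C_RT^2
//             - r_GEF C_GEF,  Ec = Ectot - sum_i a_i C_GEF_i.
// [[Rcpp::export]]
List integrate_expanded_cpp(IntegerVector ei, IntegerVector ej,
                            NumericVector w, NumericVector areas,
                            NumericVector p, double rho1, double rho2,
                            double r_GEF, double D_GEF, NumericVector CRT0,
                            NumericVector CRD0, NumericVector CGAP0,
                            NumericVector CGEF0, double dt, int n_steps,
                            int record_every, bool store_fields) {
  const int n = areas.size();
  PatchParams pp = read_params(p);
  std::vector<int> vi, vj;
  std::vector<double> vw;
  unpack_edges(ei, ej, w, vi, vj, vw);
  std::vector<double> inv_a(n), a(n);
  for (int i = 0; i < n; ++i) { a[i] = areas[i]; inv_a[i] = 1.0 / a[i]; }

  std::vector<double> RT(CRT0.begin(), CRT0.end());
  std::vector<double> RD(CRD0.begin(), CRD0.end());
  std::vector<double> GAP(CGAP0.begin(), CGAP0.end());
  std::vector<double> GEF(CGEF0.begin(), CGEF0.end());
  std::vector<double> lRT(n), lRD(n), lGAP(n), lGEF(n);

  int n_frames = n_steps / record_every + 1;
  NumericVector frame_t(n_frames), max_rt(n_frames), ec_t(n_frames);
  IntegerVector argmax_rt(n_frames);
  NumericMatrix fRT, fGEF;
  if (store_fields) {
    fRT = NumericMatrix(n, n_frames);
    fGEF = NumericMatrix(n, n_frames);
  }
  double clip_total = 0.0;

  auto ec_now = [&]() {
    double bound = 0.0;
    for (int i = 0; i < n; ++i) bound += a[i] * GEF[i];
    return pp.Ectot - bound;
  };

  auto record = [&](int frame, double t) {
    frame_t[frame] = t;
    double m = -1.0; int am = 0;
    for (int i = 0; i < n; ++i)
      if (RT[i] > m) { m = RT[i]; am = i; }
    max_rt[frame] = m;
    argmax_rt[frame] = am + 1;
    ec_t[frame] = ec_now();
    if (store_fields)
      for (int i = 0; i < n; ++i) {
        fRT(i, frame) = RT[i];
        fGEF(i, frame) = GEF[i];
      }
  };
  record(0, 0.0);

  int frame = 1;
  const bool noisy = pp.rnoise > 0;
  for (int step = 1; step <= n_steps; ++step) {
    lap_apply(vi, vj, vw, inv_a, RT.data(), lRT.data(), n);
    lap_apply(vi, vj, vw, inv_a, RD.data(), lRD.data(), n);
    lap_apply(vi, vj, vw, inv_a, GAP.data(), lGAP.data(), n);
    lap_apply(vi, vj, vw, inv_a, GEF.data(), lGEF.data(), n);
    // the free pool Ec couples every cell through the binding flux and
    // is the stiff direction of the GEF kinetics; treating the scalar
    // Ec implicitly within the step keeps the explicit update of all
    // fields stable without restricting dt below the reaction scales:
    // Ec* = (Ectot - sum_i a_i [GEF_i + dt (D lap - r_GEF GEF_i)])
    //       / (1 + dt sum_i a_i (rho1 RT_i + rho2 RT_i^2) / V)
    double bound_pred = 0.0, bsum = 0.0;
    for (int i = 0; i < n; ++i) {
      bound_pred += a[i] * (GEF[i] + dt * (D_GEF * lGEF[i] -
                                           r_GEF * GEF[i]));
      bsum += a[i] * (rho1 * RT[i] + rho2 * RT[i] * RT[i]);
    }
    double Ec = (pp.Ectot - bound_pred) / (1.0 + dt * bsum / pp.V);
    double EcV = Ec / pp.V;
    for (int i = 0; i < n; ++i) {
      double act = pp.k0p * GEF[i] * RD[i];
      double noise = noisy ? unif_rand() * pp.rnoise * RD[i] : 0.0;
      double hyd = (pp.k1n + pp.k2n * GAP[i]) * RT[i];
      double dRT = pp.D_RT * lRT[i] + act + noise - hyd - pp.r_RT * RT[i];
      double dRD = pp.D_RD * lRD[i] + pp.jRDp + hyd - act - noise -
                   pp.r_RD * RD[i];
      double dGAP = pp.D_GAP * lGAP[i] +
                    pp.k3n * hill_term(RT[i], pp.Csat, pp.h) -
                    pp.r_GAP * GAP[i];
      double dGEF = D_GEF * lGEF[i] + rho1 * EcV * RT[i] +
                    rho2 * EcV * RT[i] * RT[i] - r_GEF * GEF[i];
      RT[i] += dt * dRT;
      RD[i] += dt * dRD;
      GAP[i] += dt * dGAP;
      GEF[i] += dt * dGEF;
      if (RT[i] < 0) { clip_total -= RT[i] * a[i]; RT[i] = 0; }
      if (RD[i] < 0) { clip_total -= RD[i] * a[i]; RD[i] = 0; }
      if (GAP[i] < 0) { clip_total -= GAP[i] * a[i]; GAP[i] = 0; }
      if (GEF[i] < 0) { clip_total -= GEF[i] * a[i]; GEF[i] = 0; }
    }
    if (step % record_every == 0 && frame < n_frames) {
      record(frame++, step * dt);
      if (!std::isfinite(max_rt[frame - 1]))
        stop("non-finite state at step %d", step);
    }
  }

  NumericVector outRT(n), outRD(n), outGAP(n), outGEF(n);
  for (int i = 0; i < n; ++i) {
    outRT[i] = RT[i]; outRD[i] = RD[i]; outGAP[i] = GAP[i]; outGEF[i] = GEF[i];
  }
  List out = List::create(
      _["times"] = frame_t, _["max_rt"] = max_rt, _["argmax_rt"] = argmax_rt,
      _["ec"] = ec_t, _["clip_total"] = clip_total, _["CRT"] = outRT,
      _["CRD"] = outRD, _["CGAP"] = outGAP, _["CGEF"] = outGEF);
  if (store_fields) {
    out["fRT"] = fRT; out["fGEF"] = fGEF;
  }
  return out;
}
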