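#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Surface-of-revolution helpers for a spherocylinder with cylinder radius
// `rad`, cylinder half-length `hc` (cylinder spans z in [-hc, hc]) and cap
// sphere radius `rt` (>= rad; caps meet the cylinder rim at z = +-hc).
// The meridian arc coordinate s runs from the front pole (max z) to the back
// pole. All quadrature uses the exact area element dA = rho(s) dphi ds.

struct CapsuleGeom {
  double rad, hc, rt;
  double theta_max;   // polar angle at the cap rim
  double s_cap;       // meridian arc length of one cap
  double s_total;     // pole-to-pole meridian arc length
  double zc_front;    // front cap sphere center (on axis)
  CapsuleGeom(double rad_, double hc_, double rt_)
      : rad(rad_), hc(hc_), rt(rt_) {
    theta_max = std::asin(std::min(1.0, rad / rt));
    s_cap = rt * theta_max;
    s_total = 2.0 * s_cap + 2.0 * hc;
    zc_front = hc - std::sqrt(std::max(0.0, rt * rt - rad * rad));
  }
  // position on the meridian: s -> (rho, z)
  void at(double s, double &rho, double &z) const {
    if (s < s_cap) {                      // front cap, s=0 at pole
      double th = s / rt;
      rho = rt * std::sin(th);
      z = zc_front + rt * std::cos(th);
    } else if (s < s_cap + 2.0 * hc) {    // cylinder
      rho = rad;
      z = hc - (s - s_cap);
    } else {                              // back cap
      double th = (s_total - s) / rt;
      rho = rt * std::sin(th);
      z = -(zc_front + rt * std::cos(th));
    }
  }
};

// [[Rcpp::export]]
List measure_voronoi_cpp(NumericMatrix gen, NumericVector gen_s,
                         double rad, double hc, double rt,
                         int n_s, int n_phi, double s_window) {
  const int ng = gen.nrow();
  CapsuleGeom geom(rad, hc, rt);
  const double ds = geom.s_total / n_s;
  const double dphi = 2.0 * M_PI / n_phi;

  // generators sorted by meridian coordinate for windowed nearest search
  std::vector<int> order(ng);
  for (int i = 0; i < ng; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return gen_s[a] < gen_s[b]; });
  std::vector<double> sorted_s(ng);
  for (int i = 0; i < ng; ++i) sorted_s[i] = gen_s[order[i]];

  std::vector<double> area(ng, 0.0), cx(ng, 0.0), cy(ng, 0.0), cz(ng, 0.0);
  // boundary length accumulated separately for meridian- and
  // azimuth-oriented grid segments; the true (straight) Voronoi edge
  // length is the quadrature sum of the two, which removes the
  // staircase bias for obliquely oriented edges
  std::map<std::pair<int, int>, std::pair<double, double>> edge_len;

  std::vector<int> owner_prev(n_phi), owner_cur(n_phi);

  for (int is = 0; is < n_s; ++is) {
    double s_mid = (is + 0.5) * ds;
    double rho, z;
    geom.at(s_mid, rho, z);
    double cell_area = rho * dphi * ds;

    // candidate generators within the meridian window
    double lo = s_mid - s_window, hi = s_mid + s_window;
    int i0 = std::lower_bound(sorted_s.begin(), sorted_s.end(), lo) -
             sorted_s.begin();
    int i1 = std::upper_bound(sorted_s.begin(), sorted_s.end(), hi) -
             sorted_s.begin();
    if (i0 >= i1) { i0 = 0; i1 = ng; }  // fallback: search everything

    for (int ip = 0; ip < n_phi; ++ip) {
      double phi = (ip + 0.5) * dphi;
      double x = rho * std::cos(phi), y = rho * std::sin(phi);
      double best = R_PosInf;
      int who = -1;
      for (int k = i0; k < i1; ++k) {
        int g = order[k];
        double dx = x - gen(g, 0), dy = y - gen(g, 1), dz = z - gen(g, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) { best = d2; who = g; }
      }
      owner_cur[ip] = who;
      area[who] += cell_area;
      cx[who] += cell_area * x;
      cy[who] += cell_area * y;
      cz[who] += cell_area * z;
    }

    // boundary crossings: phi direction (meridian segments, length ds)
    for (int ip = 0; ip < n_phi; ++ip) {
      int jp = (ip + 1) % n_phi;
      int a = owner_cur[ip], b = owner_cur[jp];
      if (a != b) {
        std::pair<int, int> key(std::min(a, b), std::max(a, b));
        edge_len[key].first += ds;
      }
    }
    // s direction (azimuthal arcs at the shared row boundary)
    if (is > 0) {
      double rho_b, z_b;
      geom.at(is * ds, rho_b, z_b);
      double seg = rho_b * dphi;
      for (int ip = 0; ip < n_phi; ++ip) {
        int a = owner_prev[ip], b = owner_cur[ip];
        if (a != b) {
          std::pair<int, int> key(std::min(a, b), std::max(a, b));
          edge_len[key].second += seg;
        }
      }
    }
    std::swap(owner_prev, owner_cur);
  }

  const int ne = edge_len.size();
  IntegerVector ei(ne), ej(ne);
  NumericVector el(ne);
  int k = 0;
  for (auto &kv : edge_len) {
    ei[k] = kv.first.first + 1;   // 1-based for R
    ej[k] = kv.first.second + 1;
    el[k] = std::sqrt(kv.second.first * kv.second.first +
                      kv.second.second * kv.second.second);
    ++k;
  }
  NumericVector a_out(ng);
  NumericMatrix centroid(ng, 3);
  for (int i = 0; i < ng; ++i) {
    a_out[i] = area[i];
    if (area[i] > 0) {
      centroid(i, 0) = cx[i] / area[i];
      centroid(i, 1) = cy[i] / area[i];
      centroid(i, 2) = cz[i] / area[i];
    }
  }
  return List::create(_["area"] = a_out, _["centroid"] = centroid,
                      _["edge_i"] = ei, _["edge_j"] = ej,
                      _["edge_len"] = el);
}
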