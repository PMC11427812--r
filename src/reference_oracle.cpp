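#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Brute-force reference implementations used to validate the optimizers.
// They share no code with the R-side geometry: the ellipse feasibility
// test below uses dense boundary sampling rather than the closest-point
// root solve, and the search is an exhaustive grid, not Nelder-Mead.

namespace {

// ellipse (a, b, theta) centred at (cx, cy) does not overlap a disc of
// radius rho centred at (px, py)?  Boundary sampled at m points.
bool ellipse_disc_ok(double cx, double cy, double a, double b,
                     double c, double s, double px, double py, double rho,
                     const std::vector<double> &ct,
                     const std::vector<double> &st, double feas_tol) {
  double rx = px - cx, ry = py - cy;
  double u = c * rx + s * ry;
  double v = -s * rx + c * ry;
  double eu = u / a, ev = v / b;
  if (eu * eu + ev * ev <= 1.0) return false;  // centre inside ellipse
  double lim = (rho - feas_tol);
  double lim2 = lim * lim;
  size_t m = ct.size();
  for (size_t k = 0; k < m; ++k) {
    double dxk = a * ct[k] - u;
    double dyk = b * st[k] - v;
    if (dxk * dxk + dyk * dyk < lim2) return false;
  }
  return true;
}

bool slice_ok(double cx, double cy, double a, double b, double c, double s,
              const NumericVector &px, const NumericVector &py,
              const NumericVector &rho, const std::vector<double> &ct,
              const std::vector<double> &st, double feas_tol) {
  int nd = px.size();
  for (int j = 0; j < nd; ++j) {
    if (!ellipse_disc_ok(cx, cy, a, b, c, s, px[j], py[j], rho[j], ct, st,
                         feas_tol))
      return false;
  }
  return true;
}

}  // namespace

// Exhaustive grid search for the maximal-a in-plane ellipse with fixed b.
// Grid: centre offsets in [-half, half]^2 at `step`, orientation at
// `theta_step_deg`; per cell the maximal feasible a in [b, a_hi] is found
// by bisection (feasibility is monotone in a) against a sampled-boundary
// overlap test with `m_samples` points.
// [[Rcpp::export]]
NumericVector cpp_grid_ellipse(NumericVector dx, NumericVector dy,
                               NumericVector rho, double b, double x0,
                               double y0, double half, double step,
                               double theta_step_deg, double a_hi,
                               double a_tol, int m_samples,
                               double feas_tol) {
  int nxy = (int)std::floor(2.0 * half / step + 1e-9) + 1;
  int nth = (int)std::round(180.0 / theta_step_deg);
  std::vector<double> ct(m_samples), st(m_samples);
  for (int k = 0; k < m_samples; ++k) {
    double t = 2.0 * M_PI * k / m_samples;
    ct[k] = std::cos(t);
    st[k] = std::sin(t);
  }
  double best_a = -1.0, bx = x0, by = y0, bth = 0.0;
  for (int it = 0; it < nth; ++it) {
    double th = it * theta_step_deg * M_PI / 180.0;
    double c = std::cos(th), s = std::sin(th);
    for (int ix = 0; ix < nxy; ++ix) {
      double cx = x0 - half + ix * step;
      for (int iy = 0; iy < nxy; ++iy) {
        double cy = y0 - half + iy * step;
        if (!slice_ok(cx, cy, b, b, c, s, dx, dy, rho, ct, st, feas_tol))
          continue;  // even the circle overlaps here
        double lo = b, hi = a_hi;
        if (slice_ok(cx, cy, a_hi, b, c, s, dx, dy, rho, ct, st, feas_tol)) {
          lo = a_hi;
        } else {
          while (hi - lo > a_tol) {
            double mid = 0.5 * (lo + hi);
            if (slice_ok(cx, cy, mid, b, c, s, dx, dy, rho, ct, st,
                         feas_tol))
              lo = mid;
            else
              hi = mid;
          }
        }
        if (lo > best_a) {
          best_a = lo;
          bx = cx;
          by = cy;
          bth = th;
        }
      }
    }
  }
  return NumericVector::create(_["x"] = bx, _["y"] = by, _["a"] = best_a,
                               _["theta"] = bth);
}

// Exhaustive 2-D grid search for the maximal spherical probe in a plane.
// [[Rcpp::export]]
NumericVector cpp_grid_sphere(NumericVector ax, NumericVector ay,
                              NumericVector az, NumericVector ar, double z,
                              double x0, double y0, double half,
                              double step) {
  int nxy = (int)std::floor(2.0 * half / step + 1e-9) + 1;
  int na = ax.size();
  double best = -1e300, bx = x0, by = y0;
  for (int ix = 0; ix < nxy; ++ix) {
    double px = x0 - half + ix * step;
    for (int iy = 0; iy < nxy; ++iy) {
      double py = y0 - half + iy * step;
      double cl = 1e300;
      for (int j = 0; j < na; ++j) {
        double dxj = px - ax[j], dyj = py - ay[j], dzj = z - az[j];
        double d = std::sqrt(dxj * dxj + dyj * dyj + dzj * dzj) - ar[j];
        if (d < cl) cl = d;
      }
      if (cl > best) {
        best = cl;
        bx = px;
        by = py;
      }
    }
  }
  return NumericVector::create(_["x"] = bx, _["y"] = by, _["radius"] = best);
}

// ---------------------------------------------------------------------------
// Production clearance kernel (shared by the R-level ellipse operations).
// Signed distance from a point to an axis-aligned ellipse via safeguarded
// bisection on the closest-point parameterisation; negative inside.

namespace {

double signed_point_ellipse_1(double px, double py, double a, double b) {
  double pu = std::fabs(px), pv = std::fabs(py);
  if (std::fabs(a - b) < 1e-12) return std::sqrt(pu * pu + pv * pv) - a;
  double E = (pu / a) * (pu / a) + (pv / b) * (pv / b);
  bool inside = E < 1.0;
  if (inside && pv < 1e-12) {  // interior point on the major axis
    double crit = (a * a - b * b) / a;
    if (pu >= crit) return -(a - pu);
    double xs = a * a * pu / (a * a - b * b);
    double ys = b * std::sqrt(std::max(1.0 - (xs / a) * (xs / a), 0.0));
    return -std::sqrt((pu - xs) * (pu - xs) + ys * ys);
  }
  double lo, hi;
  if (inside) {
    lo = -b * b * (1.0 - 1e-14);
    hi = 0.0;
  } else {
    lo = 0.0;
    hi = std::sqrt(a * pu * a * pu + b * pv * b * pv);
  }
  for (int i = 0; i < 64; ++i) {
    double mid = 0.5 * (lo + hi);
    double fa = a * pu / (mid + a * a);
    double fb = b * pv / (mid + b * b);
    if (fa * fa + fb * fb - 1.0 > 0.0)
      lo = mid;
    else
      hi = mid;
  }
  double t = 0.5 * (lo + hi);
  double xs = a * a * pu / (t + a * a);
  double ys = b * b * pv / (t + b * b);
  double d = std::sqrt((xs - pu) * (xs - pu) + (ys - pv) * (ys - pv));
  return inside ? -d : d;
}

}  // namespace

// Minimum over discs of (signed distance to the ellipse boundary - rho).
// [[Rcpp::export]]
double cpp_ellipse_clearance(double x, double y, double a, double b,
                             double theta, NumericVector dx,
                             NumericVector dy, NumericVector rho) {
  int n = dx.size();
  double c = std::cos(theta), s = std::sin(theta);
  double best = R_PosInf;
  for (int j = 0; j < n; ++j) {
    double rx = dx[j] - x, ry = dy[j] - y;
    double u = c * rx + s * ry;
    double v = -s * rx + c * ry;
    double cl = signed_point_ellipse_1(u, v, a, b) - rho[j];
    if (cl < best) best = cl;
  }
  return best;
}
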