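// Compton image reconstruction kernels: cone back-projection, the
// stochastic origin ensemble sampler, and the analytical
// spherical-harmonics inversion. The image plane is parameterized by an
// origin and two in-plane unit axes; pixel (i, j) sits at
// origin + uc[i] * uaxis + vc[j] * vaxis. Images are nu x nv matrices
// with the u index running along the rows.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// angular distance between the cone half-angle and the apex->pixel ray
static inline double delta_theta(const double *apex, const double *axis,
                                 double omega, const double *pix) {
  double s[3];
  for (int k = 0; k < 3; k++) s[k] = pix[k] - apex[k];
  double n = std::sqrt(s[0]*s[0] + s[1]*s[1] + s[2]*s[2]);
  if (n < 1e-12) return M_PI;
  double ct = (s[0]*axis[0] + s[1]*axis[1] + s[2]*axis[2]) / n;
  if (ct > 1) ct = 1; else if (ct < -1) ct = -1;
  return std::fabs(std::acos(ct) - omega);
}

static void pixel_centers(const NumericVector &origin,
                          const NumericVector &uaxis,
                          const NumericVector &vaxis,
                          const NumericVector &uc, const NumericVector &vc,
                          std::vector<double> &pix) {
  int nu = uc.size(), nv = vc.size();
  pix.resize(3 * nu * nv);
  for (int j = 0; j < nv; j++)
    for (int i = 0; i < nu; i++) {
      int q = j * nu + i;
      for (int k = 0; k < 3; k++)
        pix[3 * q + k] = origin[k] + uc[i] * uaxis[k] + vc[j] * vaxis[k];
    }
}

// cones: columns ax, ay, az (apex), tx, ty, tz (axis), omega, weight
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix cones, NumericVector origin,
                              NumericVector uaxis, NumericVector vaxis,
                              NumericVector uc, NumericVector vc,
                              double sigma_rad, double min_total,
                              bool area_weight) {
  int nu = uc.size(), nv = vc.size(), np = nu * nv;
  std::vector<double> pix;
  pixel_centers(origin, uaxis, vaxis, uc, vc, pix);
  double nrm[3] = {uaxis[1]*vaxis[2] - uaxis[2]*vaxis[1],
                   uaxis[2]*vaxis[0] - uaxis[0]*vaxis[2],
                   uaxis[0]*vaxis[1] - uaxis[1]*vaxis[0]};
  NumericMatrix img(nu, nv);
  std::vector<double> w(np);
  double inv2s2 = 1.0 / (2.0 * sigma_rad * sigma_rad);
  int n_dropped = 0;
  for (int e = 0; e < cones.nrow(); e++) {
    double apex[3] = {cones(e, 0), cones(e, 1), cones(e, 2)};
    double axis[3] = {cones(e, 3), cones(e, 4), cones(e, 5)};
    double omega = cones(e, 6), evw = cones(e, 7);
    double tot = 0;
    for (int q = 0; q < np; q++) {
      double dt = delta_theta(apex, axis, omega, &pix[3 * q]);
      w[q] = std::exp(-dt * dt * inv2s2);
      if (area_weight) {
        const double *p = &pix[3 * q];
        double s0 = p[0]-apex[0], s1 = p[1]-apex[1], s2 = p[2]-apex[2];
        double r2 = s0*s0 + s1*s1 + s2*s2;
        if (r2 > 1e-12) {
          double cb = std::fabs(s0*nrm[0] + s1*nrm[1] + s2*nrm[2]) /
            std::sqrt(r2);
          w[q] *= cb * 1e4 / r2;
        } else w[q] = 0;
      }
      tot += w[q];
    }
    // a cone whose intersection with the grid carries less kernel mass
    // than one fully-hit pixel would be blown up by the per-event
    // normalization; treat it as missing the image plane
    if (tot < min_total) { n_dropped++; continue; }
    for (int q = 0; q < np; q++) img[q] += evw * w[q] / tot;
  }
  img.attr("n_dropped") = n_dropped;
  return img;
}

// per-event list of pixels within delta of the cone surface (1-based)
// [[Rcpp::export]]
List cpp_cone_bands(NumericMatrix cones, NumericVector origin,
                    NumericVector uaxis, NumericVector vaxis,
                    NumericVector uc, NumericVector vc, double delta_rad) {
  int nu = uc.size(), nv = vc.size(), np = nu * nv;
  std::vector<double> pix;
  pixel_centers(origin, uaxis, vaxis, uc, vc, pix);
  List out(cones.nrow());
  for (int e = 0; e < cones.nrow(); e++) {
    double apex[3] = {cones(e, 0), cones(e, 1), cones(e, 2)};
    double axis[3] = {cones(e, 3), cones(e, 4), cones(e, 5)};
    double omega = cones(e, 6);
    std::vector<int> band;
    for (int q = 0; q < np; q++)
      if (delta_theta(apex, axis, omega, &pix[3 * q]) <= delta_rad)
        band.push_back(q + 1);
    out[e] = wrap(band);
  }
  return out;
}

// Stochastic origin ensemble on precomputed cone bands. Acceptance for
// moving one event from its current pixel (occupancy lambda, including
// the event) to a proposed pixel (occupancy lambda', excluding it):
// A = min(1, (lambda' + 1) / lambda). The returned image averages the
// occupancy over the iterations after burn-in (default: the second
// half), which removes the Monte Carlo clumping noise of a single
// ensemble snapshot; the final snapshot is returned as well.
// [[Rcpp::export]]
List cpp_soe(List bands, int n_pixels, int n_iter, int burn_in) {
  int n_ev = bands.size();
  std::vector<std::vector<int>> bd(n_ev);
  std::vector<int> active;
  for (int e = 0; e < n_ev; e++) {
    IntegerVector b = bands[e];
    bd[e].assign(b.begin(), b.end());
    if (!bd[e].empty()) active.push_back(e);
  }
  std::vector<int> occ(n_pixels, 0), cur(n_ev, -1);
  for (int e : active) {
    int pick = bd[e][(int)(unif_rand() * bd[e].size())] - 1;
    cur[e] = pick;
    occ[pick]++;
  }
  IntegerVector initial(occ.begin(), occ.end());
  std::vector<double> accum(n_pixels, 0.0);
  int n_accum = 0;
  int n_act = active.size();
  for (int it = 0; it < n_iter; it++) {
    for (int rep = 0; rep < n_act; rep++) {
      int e = active[(int)(unif_rand() * n_act)];
      const std::vector<int> &b = bd[e];
      int prop = b[(int)(unif_rand() * b.size())] - 1;
      if (prop == cur[e]) continue;
      double lam = occ[cur[e]];           // includes the moving event
      double lamp = occ[prop];            // excludes it
      double acc = (lamp + 1.0) / lam;
      if (acc >= 1.0 || unif_rand() < acc) {
        occ[cur[e]]--;
        occ[prop]++;
        cur[e] = prop;
      }
    }
    if (it >= burn_in) {
      for (int q = 0; q < n_pixels; q++) accum[q] += occ[q];
      n_accum++;
    }
  }
  NumericVector mean_img(n_pixels);
  for (int q = 0; q < n_pixels; q++)
    mean_img[q] = n_accum > 0 ? accum[q] / n_accum : occ[q];
  return List::create(_["initial"] = initial,
                      _["mean"] = mean_img,
                      _["final"] = IntegerVector(occ.begin(), occ.end()),
                      _["assignment"] = IntegerVector(cur.begin(), cur.end()),
                      _["n_dropped"] = n_ev - n_act);
}

// Analytical inversion: image(s) = sum_e sum_n coeff(n, e) P_n(s . t_e)
// with coeff(n, e) = (2n+1) / (4 pi H_n(E_e)) * P_n(cos omega_e)
// computed by the caller. P_n evaluated by the Bonnet recurrence.
// With area_weight, each pixel's series value is multiplied by the
// solid angle it subtends at the event apex (|cos beta| / r^2, with r
// in units of 100 mm), converting the direction-space inversion to an
// emission density per unit plane area.
// [[Rcpp::export]]
NumericMatrix cpp_aa(NumericMatrix cones, NumericMatrix coeff,
                     NumericVector origin, NumericVector uaxis,
                     NumericVector vaxis, NumericVector uc,
                     NumericVector vc, bool area_weight) {
  int nu = uc.size(), nv = vc.size(), np = nu * nv;
  int n_max = coeff.nrow() - 1;
  std::vector<double> pix;
  pixel_centers(origin, uaxis, vaxis, uc, vc, pix);
  double nrm[3] = {uaxis[1]*vaxis[2] - uaxis[2]*vaxis[1],
                   uaxis[2]*vaxis[0] - uaxis[0]*vaxis[2],
                   uaxis[0]*vaxis[1] - uaxis[1]*vaxis[0]};
  NumericMatrix img(nu, nv);
  for (int e = 0; e < cones.nrow(); e++) {
    double apex[3] = {cones(e, 0), cones(e, 1), cones(e, 2)};
    double axis[3] = {cones(e, 3), cones(e, 4), cones(e, 5)};
    const double *cf = &coeff(0, e);
    for (int q = 0; q < np; q++) {
      double s[3];
      for (int k = 0; k < 3; k++) s[k] = pix[3 * q + k] - apex[k];
      double n2 = std::sqrt(s[0]*s[0] + s[1]*s[1] + s[2]*s[2]);
      if (n2 < 1e-12) continue;
      double x = (s[0]*axis[0] + s[1]*axis[1] + s[2]*axis[2]) / n2;
      if (x > 1) x = 1; else if (x < -1) x = -1;
      double pm1 = 1.0, p0 = x, acc = cf[0];
      if (n_max >= 1) acc += cf[1] * x;
      for (int n = 2; n <= n_max; n++) {
        double pn = ((2.0 * n - 1.0) * x * p0 - (n - 1.0) * pm1) / n;
        acc += cf[n] * pn;
        pm1 = p0; p0 = pn;
      }
      if (area_weight) {
        double cb = std::fabs(s[0]*nrm[0] + s[1]*nrm[1] + s[2]*nrm[2]) / n2;
        acc *= cb * 1e4 / (n2 * n2);
      }
      img[q] += acc;
    }
  }
  return img;
}
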