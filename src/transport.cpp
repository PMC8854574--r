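// Photon-transport Monte Carlo over axis-aligned box volumes.
//
// Physics: exponential free paths against the total linear attenuation,
// process choice proportional to the partial coefficients; photoelectric
// absorption deposits the remaining energy, Compton scattering (angle
// sampled from Klein-Nishina by rejection) deposits the electron energy
// and continues the scattered photon, pair production deposits
// E - 1022 keV and launches two back-to-back 511 keV annihilation
// photons. Volumes flagged "terminal" (the phantom in attenuation-only
// mode) remove interacting photons without recording a deposit, except
// for an optional budget of Compton scatters. Energies keV, lengths mm,
// times ns. Uses R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double MEC2 = 511.0;
static const double C_MM_NS = 299.792458;
static const double EPS = 1e-6;

struct Material {
  std::vector<double> e, loge;
  std::vector<double> photo, compton, pair;
  std::vector<double> lphoto, lcompton;

  void init(const List &m) {
    NumericVector ev = m["energy"], ph = m["photo"], co = m["compton"],
                  pa = m["pair"];
    int n = ev.size();
    e.assign(ev.begin(), ev.end());
    photo.assign(ph.begin(), ph.end());
    compton.assign(co.begin(), co.end());
    pair.assign(pa.begin(), pa.end());
    loge.resize(n); lphoto.resize(n); lcompton.resize(n);
    for (int i = 0; i < n; i++) {
      loge[i] = std::log(e[i]);
      lphoto[i] = photo[i] > 0 ? std::log(photo[i]) : 0.0;
      lcompton[i] = compton[i] > 0 ? std::log(compton[i]) : 0.0;
    }
  }

  // per-process coefficients at energy q (clamped to the grid range)
  void mu(double q, double &mp, double &mc, double &mpair) const {
    int n = e.size();
    if (q <= e[0]) { mp = photo[0]; mc = compton[0]; mpair = pair[0]; return; }
    if (q >= e[n - 1]) {
      mp = photo[n - 1]; mc = compton[n - 1]; mpair = pair[n - 1]; return;
    }
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; if (e[mid] <= q) lo = mid; else hi = mid; }
    double lq = std::log(q);
    double f = (lq - loge[lo]) / (loge[hi] - loge[lo]);
    mp = (photo[lo] > 0 && photo[hi] > 0)
       ? std::exp(lphoto[lo] + f * (lphoto[hi] - lphoto[lo]))
       : photo[lo] + (photo[hi] - photo[lo]) * (q - e[lo]) / (e[hi] - e[lo]);
    mc = (compton[lo] > 0 && compton[hi] > 0)
       ? std::exp(lcompton[lo] + f * (lcompton[hi] - lcompton[lo]))
       : compton[lo] + (compton[hi] - compton[lo]) * (q - e[lo]) / (e[hi] - e[lo]);
    mpair = pair[lo] + (pair[hi] - pair[lo]) * (q - e[lo]) / (e[hi] - e[lo]);
  }
};

struct Photon {
  double p[3], d[3], e, t;
  int phantom_budget;
};

// relative Klein-Nishina differential cross-section (forward value 1)
static inline double kn_dcs(double e, double cw) {
  double a = e / MEC2;
  double pp = 1.0 / (1.0 + a * (1.0 - cw));
  return 0.5 * pp * pp * (pp + 1.0 / pp - (1.0 - cw * cw));
}

static inline double sample_kn_cos(double e) {
  for (int k = 0; k < 10000; k++) {
    double cw = unif_rand() * 2.0 - 1.0;
    if (unif_rand() < kn_dcs(e, cw)) return cw;
  }
  return 1.0; // unreachable in practice
}

// rotate direction d by polar angle (cw) and uniform azimuth
static void deflect(double *d, double cw) {
  double sw = std::sqrt(std::max(0.0, 1.0 - cw * cw));
  double phi = 2.0 * M_PI * unif_rand();
  double u[3], v[3];
  if (std::fabs(d[0]) < 0.9) { u[0] = 0; u[1] = -d[2]; u[2] = d[1]; }
  else { u[0] = -d[1]; u[1] = d[0]; u[2] = 0; }
  double nu = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  for (int k = 0; k < 3; k++) u[k] /= nu;
  v[0] = d[1]*u[2] - d[2]*u[1];
  v[1] = d[2]*u[0] - d[0]*u[2];
  v[2] = d[0]*u[1] - d[1]*u[0];
  double cphi = std::cos(phi), sphi = std::sin(phi);
  for (int k = 0; k < 3; k++)
    d[k] = sw * (cphi * u[k] + sphi * v[k]) + cw * d[k];
}

// slab-method intersection; returns false on miss
static inline bool box_intersect(const double *p, const double *d,
                                 const double *box, double &tin, double &tout) {
  tin = -1e300; tout = 1e300;
  for (int k = 0; k < 3; k++) {
    double c = box[k], h = box[3 + k];
    if (std::fabs(d[k]) < 1e-12) {
      if (std::fabs(p[k] - c) > h) return false;
    } else {
      double t1 = (c - h - p[k]) / d[k];
      double t2 = (c + h - p[k]) / d[k];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tin) tin = t1;
      if (t2 < tout) tout = t2;
    }
  }
  return tout > tin;
}

// [[Rcpp::export]]
NumericMatrix cpp_transport(NumericMatrix emissions, NumericMatrix boxes,
                            List materials, IntegerVector box_material,
                            IntegerVector box_terminal,
                            double floor_kev, double e_cut,
                            int max_phantom_scatter) {
  int n_hist = emissions.nrow(), n_box = boxes.nrow();
  std::vector<Material> mats(materials.size());
  for (int i = 0; i < (int)mats.size(); i++)
    mats[i].init(as<List>(materials[i]));

  // flat copies of the box table for fast access
  std::vector<double> bx(n_box * 6);
  for (int b = 0; b < n_box; b++)
    for (int k = 0; k < 6; k++) bx[b * 6 + k] = boxes(b, k);

  std::vector<double> out; // history, box, x, y, z, e, t
  out.reserve(4096);

  for (int h = 0; h < n_hist; h++) {
    std::vector<Photon> stack;
    Photon pri;
    for (int k = 0; k < 3; k++) { pri.p[k] = emissions(h, k); pri.d[k] = emissions(h, 3 + k); }
    pri.e = emissions(h, 6); pri.t = emissions(h, 7);
    pri.phantom_budget = max_phantom_scatter;
    stack.push_back(pri);

    while (!stack.empty()) {
      Photon ph = stack.back();
      stack.pop_back();
      bool alive = true;
      for (int step = 0; step < 10000 && alive; step++) {
        // locate: inside a box, or distance to the next box entry
        int inside = -1;
        double inside_tout = 0, next_tin = 1e300;
        for (int b = 0; b < n_box; b++) {
          double tin, tout;
          if (!box_intersect(ph.p, ph.d, &bx[b * 6], tin, tout)) continue;
          if (tin < EPS && tout > EPS) { inside = b; inside_tout = tout; break; }
          if (tin >= EPS && tin < next_tin) next_tin = tin;
        }
        if (inside < 0) {
          if (next_tin > 1e299) { alive = false; break; } // escapes the scene
          for (int k = 0; k < 3; k++) ph.p[k] += ph.d[k] * (next_tin + EPS);
          ph.t += (next_tin + EPS) / C_MM_NS;
          continue;
        }
        const Material &mat = mats[box_material[inside] - 1];
        double mp, mc, mpair;
        mat.mu(ph.e, mp, mc, mpair);
        double mtot = mp + mc + mpair;
        double s = (mtot > 0) ? -std::log(unif_rand()) / mtot : 1e300;
        if (s >= inside_tout) { // crosses the volume without interacting
          for (int k = 0; k < 3; k++) ph.p[k] += ph.d[k] * (inside_tout + EPS);
          ph.t += (inside_tout + EPS) / C_MM_NS;
          continue;
        }
        for (int k = 0; k < 3; k++) ph.p[k] += ph.d[k] * s;
        ph.t += s / C_MM_NS;
        double u = unif_rand() * mtot;
        bool terminal = box_terminal[inside] != 0;
        if (terminal) {
          // attenuation-only volume: optionally allow Compton scatters
          if (u >= mp && u < mp + mc && ph.phantom_budget > 0) {
            ph.phantom_budget--;
            double cw = sample_kn_cos(ph.e);
            double enew = ph.e / (1.0 + ph.e / MEC2 * (1.0 - cw));
            deflect(ph.d, cw);
            ph.e = enew;
            if (ph.e < e_cut) { alive = false; }
            continue;
          }
          alive = false;
          continue;
        }
        if (u < mp) { // photoelectric: full local absorption
          if (ph.e >= floor_kev) {
            double row[7] = {(double)(h + 1), (double)(inside + 1),
                             ph.p[0], ph.p[1], ph.p[2], ph.e, ph.t};
            out.insert(out.end(), row, row + 7);
          }
          alive = false;
        } else if (u < mp + mc) { // Compton
          double cw = sample_kn_cos(ph.e);
          double enew = ph.e / (1.0 + ph.e / MEC2 * (1.0 - cw));
          double edep = ph.e - enew;
          if (enew < e_cut) { edep = ph.e; } // scattered photon below cutoff
          if (edep >= floor_kev) {
            double row[7] = {(double)(h + 1), (double)(inside + 1),
                             ph.p[0], ph.p[1], ph.p[2], edep, ph.t};
            out.insert(out.end(), row, row + 7);
          }
          if (enew < e_cut) { alive = false; }
          else { deflect(ph.d, cw); ph.e = enew; }
        } else { // pair production
          double edep = ph.e - 2.0 * MEC2;
          if (edep >= floor_kev) {
            double row[7] = {(double)(h + 1), (double)(inside + 1),
                             ph.p[0], ph.p[1], ph.p[2], edep, ph.t};
            out.insert(out.end(), row, row + 7);
          }
          // two back-to-back annihilation photons, isotropic axis
          double cw = unif_rand() * 2.0 - 1.0;
          double sw = std::sqrt(1.0 - cw * cw);
          double phi = 2.0 * M_PI * unif_rand();
          Photon g1, g2;
          for (int k = 0; k < 3; k++) { g1.p[k] = ph.p[k]; g2.p[k] = ph.p[k]; }
          g1.d[0] = sw * std::cos(phi); g1.d[1] = sw * std::sin(phi); g1.d[2] = cw;
          for (int k = 0; k < 3; k++) g2.d[k] = -g1.d[k];
          g1.e = g2.e = MEC2;
          g1.t = g2.t = ph.t;
          g1.phantom_budget = g2.phantom_budget = ph.phantom_budget;
          stack.push_back(g1);
          stack.push_back(g2);
          alive = false;
        }
      }
    }
  }

  int n_hit = out.size() / 7;
  NumericMatrix res(n_hit, 7);
  for (int i = 0; i < n_hit; i++)
    for (int k = 0; k < 7; k++) res(i, k) = out[i * 7 + k];
  colnames(res) = CharacterVector::create("history", "box", "x", "y", "z",
                                          "e", "t");
  return res;
}
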