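// Monte-Carlo pencil-beam photon transport with Klein-Nishina Compton
// sampling and forced-detection (point-detector) variance reduction.
//
// Geometry convention: beam along +x, scan raster in (y, z), cylindrical
// body with axis along z centered at the origin.  Lengths in mm; linear
// attenuation coefficients are passed from R in units of 1/mm on a log-log
// interpolation grid.
//
// Estimators:
//  * Compton background: analog random walk; at every incoherent vertex a
//    weighted event is scored toward the point detector (directional
//    probability x solid angle x escape transmission).
//  * Fluorescence: a track-length (expected-value) estimator integrates the
//    K-line production along every flown path segment inside a deposit and
//    scores its direct detection; sampled photoelectric vertices on the
//    marker spawn an analog fluorescence photon for the (small) scattered
//    fluorescence channel, whose direct detection is NOT scored again.
//  * Analog mode (forced = false): no virtual scoring; an event is scored
//    when an escaping photon crosses the detector aperture disc.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double MEC2 = 511.0;
static const double RE2 = 7.940787e-26;

struct Interp {
  std::vector<double> lx, ly;
  void init(const NumericVector& E, const NumericVector& v) {
    lx.resize(E.size()); ly.resize(E.size());
    for (int i = 0; i < E.size(); ++i) {
      lx[i] = std::log(E[i]);
      ly[i] = std::log(std::max(v[i], 1e-300));
    }
  }
  double at(double E) const {
    double x = std::log(E);
    if (x <= lx.front()) return std::exp(ly.front());
    if (x >= lx.back()) return std::exp(ly.back());
    size_t hi = std::lower_bound(lx.begin(), lx.end(), x) - lx.begin();
    size_t lo = hi - 1;
    double f = (x - lx[lo]) / (lx[hi] - lx[lo]);
    return std::exp(ly[lo] + f * (ly[hi] - ly[lo]));
  }
};

struct Vec3 { double x, y, z; };
static inline Vec3 vadd(Vec3 a, Vec3 b) { return {a.x+b.x, a.y+b.y, a.z+b.z}; }
static inline Vec3 vsub(Vec3 a, Vec3 b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline Vec3 vscale(Vec3 a, double s) { return {a.x*s, a.y*s, a.z*s}; }
static inline double vdot(Vec3 a, Vec3 b) { return a.x*b.x+a.y*b.y+a.z*b.z; }
static inline double vnorm(Vec3 a) { return std::sqrt(vdot(a, a)); }
static inline Vec3 vunit(Vec3 a) { double n = vnorm(a); return vscale(a, 1.0/n); }
static inline Vec3 vcross(Vec3 a, Vec3 b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}

struct MarkerElement {
  Interp photo, inc, coh;   // mass coefficients, cm^2/g
  double k_edge, omega_k, jump;
  std::vector<double> line_E, line_frac;
  std::vector<int> line_code;
};

struct Deposit {
  int shape;       // 0 sphere, 1 box
  Vec3 c;
  double p1, p2, p3;
  int elem;        // index into marker elements
  double conc;     // g/cm^3
};

struct Engine {
  double R, H2;                 // body radius, half length (mm)
  Interp b_photo, b_inc, b_coh; // body linear attenuation, 1/mm
  bool use_coh;
  std::vector<MarkerElement> elems;
  std::vector<Deposit> deps;
  Vec3 det;                     // detector center (mm)
  double det_area;              // mm^2
  double cutoff;
  bool forced;
  double polarization;

  double body_mu_active(double E) const {
    double m = b_photo.at(E) + b_inc.at(E);
    if (use_coh) m += b_coh.at(E);
    return m;
  }
  double dep_mu_active(const Deposit& d, double E) const {
    const MarkerElement& el = elems[d.elem];
    double m = el.photo.at(E) + el.inc.at(E);
    if (use_coh) m += el.coh.at(E);
    return m * d.conc * 0.1;
  }

  bool ray_body(Vec3 o, Vec3 u, double& t0, double& t1) const {
    t0 = -1e30; t1 = 1e30;
    double a = u.x*u.x + u.y*u.y;
    if (a < 1e-14) {
      if (o.x*o.x + o.y*o.y > R*R) return false;
    } else {
      double b = 2.0 * (o.x*u.x + o.y*u.y);
      double c = o.x*o.x + o.y*o.y - R*R;
      double disc = b*b - 4*a*c;
      if (disc <= 0) return false;
      double sq = std::sqrt(disc);
      t0 = (-b - sq) / (2*a); t1 = (-b + sq) / (2*a);
    }
    if (std::fabs(u.z) < 1e-14) {
      if (std::fabs(o.z) > H2) return false;
    } else {
      double ta = (-H2 - o.z) / u.z, tb = (H2 - o.z) / u.z;
      t0 = std::max(t0, std::min(ta, tb));
      t1 = std::min(t1, std::max(ta, tb));
    }
    return t1 > t0;
  }

  bool ray_dep(const Deposit& d, Vec3 o, Vec3 u, double& s0, double& s1) const {
    if (d.shape == 0) {
      Vec3 oc = vsub(o, d.c);
      double b = 2.0 * vdot(oc, u);
      double c = vdot(oc, oc) - d.p1 * d.p1;
      double disc = b*b - 4*c;
      if (disc <= 0) return false;
      double sq = std::sqrt(disc);
      s0 = (-b - sq) / 2; s1 = (-b + sq) / 2;
      return true;
    }
    double ext[3] = {d.p1, d.p2, d.p3};
    double oo[3] = {o.x - d.c.x, o.y - d.c.y, o.z - d.c.z};
    double uu[3] = {u.x, u.y, u.z};
    s0 = -1e30; s1 = 1e30;
    for (int i = 0; i < 3; ++i) {
      double h = ext[i] / 2;
      if (std::fabs(uu[i]) < 1e-14) {
        if (std::fabs(oo[i]) > h) return false;
      } else {
        double ta = (-h - oo[i]) / uu[i], tb = (h - oo[i]) / uu[i];
        s0 = std::max(s0, std::min(ta, tb));
        s1 = std::min(s1, std::max(ta, tb));
      }
    }
    return s1 > s0;
  }

  // transmission from point p toward the detector at energy E
  double escape_T(Vec3 p, double E) const {
    Vec3 u = vunit(vsub(det, p));
    double dist = vnorm(vsub(det, p));
    double t0, t1, tau = 0.0;
    if (ray_body(p, u, t0, t1)) {
      double a = std::max(t0, 0.0), b = std::min(t1, dist);
      if (b > a) tau += body_mu_active(E) * (b - a);
    }
    for (size_t i = 0; i < deps.size(); ++i) {
      double s0, s1;
      if (!ray_dep(deps[i], p, u, s0, s1)) continue;
      double a = std::max(s0, 0.0), b = std::min(s1, dist);
      if (b > a) tau += dep_mu_active(deps[i], E) * (b - a);
    }
    return std::exp(-tau);
  }
};

static inline double kn_dcs_unpol(double E, double cth) {
  double k = E / MEC2;
  double r = 1.0 / (1.0 + k * (1.0 - cth));
  double s2 = 1.0 - cth * cth;
  return 0.5 * RE2 * r * r * (r + 1.0 / r - s2);
}

static inline double kn_total(double E) {
  double k = E / MEC2;
  return 2.0 * M_PI * RE2 * (
    (1 + k) / (k * k) * (2 * (1 + k) / (1 + 2 * k) - std::log(1 + 2 * k) / k)
      + std::log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / ((1 + 2 * k) * (1 + 2 * k)));
}

// mixture of unpolarized and linearly polarized KN differential cross
// sections; phi measured from the polarization axis in the scatter frame
static inline double kn_dcs_mix(double E, double cth, double cphi2, double P) {
  double k = E / MEC2;
  double r = 1.0 / (1.0 + k * (1.0 - cth));
  double s2 = 1.0 - cth * cth;
  double unpol = r + 1.0 / r - s2;
  if (P <= 0.0) return 0.5 * RE2 * r * r * unpol;
  double pol = r + 1.0 / r - 2.0 * s2 * cphi2;
  return 0.5 * RE2 * r * r * ((1.0 - P) * unpol + P * pol);
}

static double sample_kn_costheta(double E) {
  // rejection against the forward maximum (dcs is maximal at theta = 0)
  double fmax = kn_dcs_unpol(E, 1.0);
  for (;;) {
    double cth = 2.0 * unif_rand() - 1.0;
    if (unif_rand() * fmax <= kn_dcs_unpol(E, cth)) return cth;
  }
}

struct EventSink {
  std::vector<double> energy, weight;
  std::vector<int> mult, origin;
  void push(double E, int m, int o, double w) {
    energy.push_back(E); mult.push_back(m);
    origin.push_back(o); weight.push_back(w);
  }
};

// [[Rcpp::export]]
NumericVector cpp_sample_compton(double E0, int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::acos(sample_kn_costheta(E0));
  return out;
}

// rotate unit vector d by polar angle theta about itself with azimuth phi
// measured from reference axis e1 (e1 perpendicular to d)
static Vec3 rotate_dir(Vec3 d, Vec3 e1, double cth, double phi) {
  Vec3 e2 = vcross(d, e1);
  double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
  Vec3 out = vadd(vscale(d, cth),
                  vadd(vscale(e1, sth * std::cos(phi)),
                       vscale(e2, sth * std::sin(phi))));
  return vunit(out);
}

static Vec3 perp_axis(Vec3 d, Vec3 pref) {
  Vec3 e = vsub(pref, vscale(d, vdot(pref, d)));
  double n = vnorm(e);
  if (n < 1e-9) {
    Vec3 alt = {1, 0, 0};
    e = vsub(alt, vscale(d, vdot(alt, d)));
    n = vnorm(e);
    if (n < 1e-9) { Vec3 alt2 = {0, 0, 1};
      e = vsub(alt2, vscale(d, vdot(alt2, d))); n = vnorm(e); }
  }
  return vscale(e, 1.0 / n);
}

// [[Rcpp::export]]
List cpp_run_position(List body, List markers, NumericMatrix deposits,
                      List beam, List detector, List opts) {
  Engine eng;
  eng.R = as<double>(body["radius"]);
  eng.H2 = as<double>(body["half_length"]);
  NumericVector gE = body["grid_keV"];
  eng.b_photo.init(gE, body["mu_photo"]);
  eng.b_inc.init(gE, body["mu_inc"]);
  eng.b_coh.init(gE, body["mu_coh"]);

  List melems = markers;
  for (int i = 0; i < melems.size(); ++i) {
    List m = melems[i];
    MarkerElement el;
    el.photo.init(gE, m["photo"]);
    el.inc.init(gE, m["inc"]);
    el.coh.init(gE, m["coh"]);
    el.k_edge = as<double>(m["k_edge"]);
    el.omega_k = as<double>(m["omega_k"]);
    el.jump = as<double>(m["jump"]);
    NumericVector le = m["line_E"], lf = m["line_frac"];
    IntegerVector lc = m["line_code"];
    el.line_E.assign(le.begin(), le.end());
    el.line_frac.assign(lf.begin(), lf.end());
    el.line_code.assign(lc.begin(), lc.end());
    eng.elems.push_back(el);
  }
  for (int i = 0; i < deposits.nrow(); ++i) {
    Deposit d;
    d.shape = (int)deposits(i, 0);
    d.c = {deposits(i, 1), deposits(i, 2), deposits(i, 3)};
    d.p1 = deposits(i, 4); d.p2 = deposits(i, 5); d.p3 = deposits(i, 6);
    d.elem = (int)deposits(i, 7);
    d.conc = deposits(i, 8);
    eng.deps.push_back(d);
  }

  double e_mean = as<double>(beam["energy"]);
  double sigma_E = as<double>(beam["sigma"]);
  double yc = as<double>(beam["yc"]), zc = as<double>(beam["zc"]);
  double bw = as<double>(beam["width"]), bh = as<double>(beam["height"]);
  double x_start = as<double>(beam["x_start"]);

  NumericVector dpos = detector["position"];
  eng.det = {dpos[0], dpos[1], dpos[2]};
  eng.det_area = as<double>(detector["area"]);

  int n_prim = as<int>(opts["n_primaries"]);
  eng.cutoff = as<double>(opts["cutoff"]);
  eng.forced = as<bool>(opts["forced"]);
  eng.use_coh = as<bool>(opts["coherent"]);
  eng.polarization = as<double>(opts["polarization"]);
  Vec3 pol_pref = {0.0, 1.0, 0.0};  // synchrotron horizontal axis

  double det_radius = std::sqrt(eng.det_area / M_PI);

  EventSink sink;
  sink.energy.reserve(2 * n_prim);
  long transmitted = 0;

  for (int ip = 0; ip < n_prim; ++ip) {
    double E = e_mean;
    if (sigma_E > 0) {
      do { E = e_mean + sigma_E * norm_rand(); } while (E <= eng.cutoff);
    }
    Vec3 pos = {x_start, yc + (unif_rand() - 0.5) * bw,
                zc + (unif_rand() - 0.5) * bh};
    Vec3 dir = {1.0, 0.0, 0.0};
    int nscat = 0;
    int origin = 0;
    bool interacted = false;
    bool pol_active = eng.polarization > 0;
    bool alive = true;

    while (alive) {
      // collect segments ahead of the photon
      double t0, t1;
      bool inbody = eng.ray_body(pos, dir, t0, t1);
      if (!inbody || t1 <= 1e-9) {
        // escapes without further interaction
        if (!eng.forced) {
          // analog detection: ray crosses the detector aperture disc
          Vec3 vp = vsub(eng.det, pos);
          double along = vdot(vp, dir);
          if (along > 0) {
            double miss2 = vdot(vp, vp) - along * along;
            if (miss2 < det_radius * det_radius)
              sink.push(E, nscat, origin, 1.0);
          }
        }
        if (!interacted && origin == 0) transmitted++;
        break;
      }
      double a = std::max(t0, 0.0);
      // breakpoints: body entry/exit plus deposit boundaries
      std::vector<double> bp;
      bp.push_back(a); bp.push_back(t1);
      std::vector<double> ds0(eng.deps.size()), ds1(eng.deps.size());
      std::vector<bool> hit(eng.deps.size(), false);
      for (size_t i = 0; i < eng.deps.size(); ++i) {
        double s0, s1;
        if (eng.ray_dep(eng.deps[i], pos, dir, s0, s1)) {
          s0 = std::max(s0, a); s1 = std::min(s1, t1);
          if (s1 > s0) {
            hit[i] = true; ds0[i] = s0; ds1[i] = s1;
            bp.push_back(s0); bp.push_back(s1);
          }
        }
      }
      std::sort(bp.begin(), bp.end());
      bp.erase(std::unique(bp.begin(), bp.end()), bp.end());

      double xi = -std::log(unif_rand());
      double t_int = -1.0;
      int dep_at = -1;
      for (size_t s = 0; s + 1 < bp.size() && t_int < 0; ++s) {
        double sa = bp[s], sb = bp[s + 1];
        if (sb <= sa) continue;
        double mid = 0.5 * (sa + sb);
        int dcur = -1;
        for (size_t i = 0; i < eng.deps.size(); ++i) {
          if (!hit[i]) continue;
          if (mid >= ds0[i] && mid <= ds1[i]) { dcur = (int)i; break; }
        }
        double mu = eng.body_mu_active(E);
        if (dcur >= 0) mu += eng.dep_mu_active(eng.deps[dcur], E);
        double len = sb - sa;
        double flown = len;
        if (mu * len >= xi) { // interaction inside this segment
          flown = xi / mu;
          t_int = sa + flown;
          dep_at = dcur;
        } else {
          xi -= mu * len;
        }
        // track-length fluorescence estimator over the flown part
        if (eng.forced && dcur >= 0 && flown > 1e-12) {
          const Deposit& d = eng.deps[dcur];
          const MarkerElement& el = eng.elems[d.elem];
          if (E > el.k_edge) {
            Vec3 midp = vadd(pos, vscale(dir, sa + 0.5 * flown));
            double dist2 = vdot(vsub(eng.det, midp), vsub(eng.det, midp));
            double dOmega = eng.det_area / dist2;
            double tau_K = el.photo.at(E) * (1.0 - 1.0 / el.jump) *
              d.conc * 0.1;  // K-shell vacancies per mm
            for (size_t l = 0; l < el.line_E.size(); ++l) {
              double w = flown * tau_K * el.omega_k * el.line_frac[l] *
                dOmega / (4.0 * M_PI) * eng.escape_T(midp, el.line_E[l]);
              if (w > 0) sink.push(el.line_E[l], 0, el.line_code[l], w);
            }
          }
        }
      }
      if (t_int < 0) {
        // traversed the body without interacting: escape (body is convex)
        if (!eng.forced) {
          Vec3 vp = vsub(eng.det, pos);
          double along = vdot(vp, dir);
          if (along > 0) {
            double miss2 = vdot(vp, vp) - along * along;
            if (miss2 < det_radius * det_radius)
              sink.push(E, nscat, origin, 1.0);
          }
        }
        if (!interacted && origin == 0) transmitted++;
        break;
      }

      interacted = true;
      pos = vadd(pos, vscale(dir, t_int));

      // channel selection
      double b_ph = eng.b_photo.at(E), b_in = eng.b_inc.at(E);
      double b_co = eng.use_coh ? eng.b_coh.at(E) : 0.0;
      double d_ph = 0, d_in = 0, d_co = 0;
      const MarkerElement* el = nullptr;
      if (dep_at >= 0) {
        const Deposit& d = eng.deps[dep_at];
        el = &eng.elems[d.elem];
        double f = d.conc * 0.1;
        d_ph = el->photo.at(E) * f;
        d_in = el->inc.at(E) * f;
        d_co = eng.use_coh ? el->coh.at(E) * f : 0.0;
      }
      double tot = b_ph + b_in + b_co + d_ph + d_in + d_co;
      double u = unif_rand() * tot;

      if (u < b_ph) {
        alive = false;                       // absorbed in bulk
      } else if (u < b_ph + d_ph) {
        alive = false;                       // photoelectric on marker
        if (el && E > el->k_edge) {
          // spawn analog fluorescence photon (scattered-fluorescence
          // channel; direct detection is handled by the track-length
          // estimator above)
          if (unif_rand() < (1.0 - 1.0 / el->jump) * el->omega_k) {
            double r = unif_rand();
            size_t l = 0;
            double acc = 0.0;
            for (; l < el->line_E.size(); ++l) {
              acc += el->line_frac[l];
              if (r <= acc) break;
            }
            if (l >= el->line_E.size()) l = el->line_E.size() - 1;
            E = el->line_E[l];
            origin = el->line_code[l];
            nscat = 0;
            double cth = 2.0 * unif_rand() - 1.0;
            double phi = 2.0 * M_PI * unif_rand();
            double sth = std::sqrt(1.0 - cth * cth);
            dir = {sth * std::cos(phi), sth * std::sin(phi), cth};
            pol_active = false;
            alive = E > eng.cutoff;
          }
        }
      } else if (u < b_ph + d_ph + b_in + d_in) {
        // incoherent (Compton) scatter
        Vec3 e1 = perp_axis(dir, pol_pref);
        double P = pol_active ? eng.polarization : 0.0;
        if (eng.forced) {
          Vec3 vd = vsub(eng.det, pos);
          double dist = vnorm(vd);
          Vec3 ud = vscale(vd, 1.0 / dist);
          double cth_d = vdot(ud, dir);
          double E_out = E / (1.0 + (E / MEC2) * (1.0 - cth_d));
          if (E_out > eng.cutoff) {
            double cphi2 = 0.0;
            if (P > 0) {
              Vec3 e2 = vcross(dir, e1);
              double px = vdot(ud, e1), py = vdot(ud, e2);
              double n2 = px * px + py * py;
              cphi2 = n2 > 1e-12 ? px * px / n2 : 0.0;
            }
            double pdir = kn_dcs_mix(E, cth_d, cphi2, P) / kn_total(E);
            double w = pdir * (eng.det_area / (dist * dist)) *
              eng.escape_T(pos, E_out);
            sink.push(E_out, nscat + 1, origin, w);
          }
        }
        double cth = sample_kn_costheta(E);
        double phi;
        if (P > 0) {
          double k = E / MEC2;
          double r = 1.0 / (1.0 + k * (1.0 - cth));
          double base = r + 1.0 / r;
          double s2 = 1.0 - cth * cth;
          double fmax = (1.0 - P) * (base - s2) + P * base;
          for (;;) {
            phi = 2.0 * M_PI * unif_rand();
            double c2 = std::cos(phi) * std::cos(phi);
            double f = (1.0 - P) * (base - s2) + P * (base - 2.0 * s2 * c2);
            if (unif_rand() * fmax <= f) break;
          }
        } else {
          phi = 2.0 * M_PI * unif_rand();
        }
        dir = rotate_dir(dir, e1, cth, phi);
        E = E / (1.0 + (E / MEC2) * (1.0 - cth));
        nscat++;
        pol_active = false;
        if (E <= eng.cutoff) alive = false;
      } else {
        // coherent (Rayleigh): energy preserved, Thomson angular shape
        if (eng.forced) {
          Vec3 vd = vsub(eng.det, pos);
          double dist = vnorm(vd);
          double cth_d = vdot(vscale(vd, 1.0 / dist), dir);
          double pdir = 3.0 / (16.0 * M_PI) * (1.0 + cth_d * cth_d);
          double w = pdir * (eng.det_area / (dist * dist)) *
            eng.escape_T(pos, E);
          sink.push(E, nscat, origin, w);
        }
        double cth;
        for (;;) { // Thomson shape 1 + cos^2
          cth = 2.0 * unif_rand() - 1.0;
          if (unif_rand() * 2.0 <= 1.0 + cth * cth) break;
        }
        Vec3 e1 = perp_axis(dir, pol_pref);
        dir = rotate_dir(dir, e1, cth, 2.0 * M_PI * unif_rand());
      }
    }
  }

  return List::create(
    _["energy"] = wrap(sink.energy),
    _["multiplicity"] = wrap(sink.mult),
    _["origin"] = wrap(sink.origin),
    _["weight"] = wrap(sink.weight),
    _["transmitted_fraction"] = (double)transmitted / (double)n_prim,
    _["n_primaries"] = n_prim);
}

// [[Rcpp::export]]
NumericVector cpp_bin_gaussian(NumericVector energy, NumericVector weight,
                               NumericVector sigma, NumericVector edges) {
  int nb = edges.size() - 1;
  NumericVector counts(nb);
  const double inv_sqrt2 = 0.7071067811865476;
  for (int i = 0; i < energy.size(); ++i) {
    double E = energy[i], s = sigma[i], w = weight[i];
    if (w == 0) continue;
    if (s <= 0) {
      int b = std::upper_bound(edges.begin(), edges.end(), E) -
        edges.begin() - 1;
      if (b >= 0 && b < nb) counts[b] += w;
      continue;
    }
    double lo = E - 5 * s, hi = E + 5 * s;
    int b0 = std::upper_bound(edges.begin(), edges.end(), lo) -
      edges.begin() - 1;
    int b1 = std::upper_bound(edges.begin(), edges.end(), hi) -
      edges.begin() - 1;
    b0 = std::max(b0, 0); b1 = std::min(b1, nb - 1);
    if (b1 < b0) continue;
    double prev = 0.5 * (1.0 + std::erf((edges[b0] - E) / s * inv_sqrt2));
    for (int b = b0; b <= b1; ++b) {
      double cur = 0.5 * (1.0 + std::erf((edges[b + 1] - E) / s * inv_sqrt2));
      counts[b] += w * (cur - prev);
      prev = cur;
    }
  }
  return counts;
}
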