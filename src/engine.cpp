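// Overdamped Langevin engine for myotube nuclear-positioning simulations.
//
// Entities: circular bodies (nuclei, centrosome-like bodies) that translate
// but do not rotate; semiflexible microtubules discretized as vertex chains
// (harmonic bending, stiff stretching penalty); nucleation sites fixed on
// body surfaces; Hookean connectors (NE-anchored dynein/kinesin motors,
// cytoplasmic passive and motile crosslinkers) with first-order binding
// kinetics and a linear force-velocity law. The elliptical boundary confines
// bodies and fibers; a soft excluded-volume force acts between bodies and
// between bodies and fibers, never between two fibers.
//
// Per-step order (fixed): force accumulation -> Langevin motion ->
// MT plus-end dynamics -> connector kinetics (walk, detach, attach) ->
// nucleation. All randomness is drawn from R's RNG.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------- formulas

// [[Rcpp::export]]
double cpp_growth_speed(double v0, double f_antagonistic, double fg,
                        double L_polymerized, double L_max) {
  double f = f_antagonistic > 0 ? f_antagonistic : 0.0;
  double pool = 1.0 - L_polymerized / L_max;
  if (pool < 0) pool = 0;
  double v = v0 * pool * std::exp(-f / fg);
  if (v < 0) v = 0;
  if (v > v0) v = v0;
  return v;
}

// [[Rcpp::export]]
double cpp_catastrophe_rate(double v, double v0, double t_free,
                            double t_stalled) {
  double x = (v0 > 0) ? v / v0 : 0.0;
  if (x < 0) x = 0;
  if (x > 1) x = 1;
  return 1.0 / (t_stalled + (t_free - t_stalled) * x);
}

// [[Rcpp::export]]
double cpp_motor_velocity(double f_opposing, double v0, double f_stall) {
  double f = f_opposing > 0 ? f_opposing : 0.0;
  double v = v0 * (1.0 - f / f_stall);
  if (v < 0) v = 0;
  if (v > v0) v = v0;
  return v;
}

// first-order event over one time step
static inline bool event_occurs(double rate, double dt) {
  if (rate <= 0) return false;
  return unif_rand() < 1.0 - std::exp(-rate * dt);
}

// steps until the next success of a per-step Bernoulli(1 - exp(-rate dt));
// sampling the geometric waiting time once is equivalent to drawing every
// step and far cheaper
static inline long event_wait_steps(double rate, double dt) {
  if (rate <= 0) return 1000000000L;
  double p = 1.0 - std::exp(-rate * dt);
  if (p >= 1) return 1;
  double u = unif_rand();
  if (u <= 0) u = 1e-300;
  long w = 1 + (long)std::floor(std::log(u) / std::log1p(-p));
  return w < 1 ? 1 : w;
}

// ---------------------------------------------------------------- ellipse

// nearest boundary point of the axis-aligned ellipse (a, b); robust
// bisection on the boundary angle in the first quadrant, tolerance 1e-9 um
static void ellipse_nearest(double x, double y, double a, double b,
                            double& ox, double& oy) {
  double sx = x < 0 ? -1.0 : 1.0, sy = y < 0 ? -1.0 : 1.0;
  double px = std::fabs(x), py = std::fabs(y);
  if (px < 1e-300 && py < 1e-300) { ox = 0.0; oy = sy * b; return; }
  // g(th) = (a^2-b^2) sin th cos th - a px sin th + b py cos th, root in
  // [0, pi/2]; g(0) = b py >= 0, g(pi/2) = -a px <= 0
  double lo = 0.0, hi = M_PI / 2.0;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double s = std::sin(mid), c = std::cos(mid);
    double g = (a * a - b * b) * s * c - a * px * s + b * py * c;
    if (g >= 0) lo = mid; else hi = mid;
    double ex1 = a * std::cos(lo), ey1 = b * std::sin(lo);
    double ex2 = a * std::cos(hi), ey2 = b * std::sin(hi);
    if (std::fabs(ex1 - ex2) < 1e-10 && std::fabs(ey1 - ey2) < 1e-10) break;
  }
  double th = 0.5 * (lo + hi);
  ox = sx * a * std::cos(th); oy = sy * b * std::sin(th);
}

static inline void conf_force(double x, double y, double a, double b,
                              double k, double radius, double& fx,
                              double& fy) {
  double ea = a - radius, eb = b - radius;
  double q = (x * x) / (ea * ea) + (y * y) / (eb * eb);
  if (q <= 1.0) { fx = 0; fy = 0; return; }
  double nx, ny;
  ellipse_nearest(x, y, ea, eb, nx, ny);
  fx = k * (nx - x); fy = k * (ny - y);
}

// [[Rcpp::export]]
NumericVector cpp_ellipse_nearest_point(double x, double y, double a,
                                        double b) {
  double ox, oy;
  ellipse_nearest(x, y, a, b, ox, oy);
  return NumericVector::create(ox, oy);
}

// [[Rcpp::export]]
NumericVector cpp_confinement_force(double x, double y, double a, double b,
                                    double k, double radius) {
  double fx, fy;
  conf_force(x, y, a, b, k, radius, fx, fy);
  return NumericVector::create(fx, fy);
}

// [[Rcpp::export]]
NumericVector cpp_steric_force(double ax, double ay, double ra, double bx,
                               double by, double rb, double k) {
  double dx = bx - ax, dy = by - ay;
  double d = std::sqrt(dx * dx + dy * dy), rr = ra + rb;
  if (d >= rr) return NumericVector::create(0.0, 0.0, 0.0, 0.0);
  double ux, uy;
  if (d < 1e-12) { ux = 1.0; uy = 0.0; }  // deterministic fallback axis
  else { ux = dx / d; uy = dy / d; }
  double f = k * (rr - d);
  // push A away from B (-u), B away from A (+u)
  return NumericVector::create(-f * ux, -f * uy, f * ux, f * uy);
}

// single head next to an always-available filament: first-order
// binding/unbinding; returns the fraction of steps spent bound
// [[Rcpp::export]]
double cpp_bound_fraction_toy(double k_on, double k_off, double dt,
                              int steps) {
  bool bound = false;
  long nb = 0;
  for (int i = 0; i < steps; ++i) {
    if (bound) { if (event_occurs(k_off, dt)) bound = false; }
    else       { if (event_occurs(k_on, dt)) bound = true; }
    if (bound) ++nb;
  }
  return double(nb) / double(steps);
}

// ---------------------------------------------------------------- entities

struct Species {
  double v0, f_stall, k_on, k_off, capt, spring_k, f_unbind;
  int dir;      // +1 plus-directed, -1 minus-directed, 0 passive
  bool motor;
};

struct MT {
  std::vector<double> px, py, fx, fy, kv;
  double len;          // bookkept polymer length
  int state;           // 1 growing, -1 shrinking
  int site;            // nucleation site index, -1 if unanchored
  double d0x, d0y;     // direction used while len ~ 0
  double tipfx, tipfy; // external force on the plus vertex
  std::uint32_t gen;   // generation counter for stale-head detection
  bool alive;
  int nseg() const { return (int)px.size() - 1; }
};

struct Head {           // MT-binding head of a connector
  bool bound = false;
  int mt = -1;
  std::uint32_t gen = 0;
  double s = 0;         // abscissa from the minus end, um
  long evt = 0;         // step of the next binding/unbinding attempt
};

struct Engine {
  // parameters
  double a, b, dt, kT, visc, conf_k, steric_k, anchor_k;
  double seg_target, stretch_k, rigid, drag_per_len;
  double v_grow0, v_shrink, fg, t_free, t_stalled, nuc_rate, nuc_angle_sd;
  double Lmax, Lpoly;
  double ext_fx, ext_fy;
  Species sp[4];       // dynein, kif5b, map4, map7kif5b

  // bodies
  std::vector<int> body_kind;
  std::vector<double> bx, by, brad, bdrag, bfx, bfy;
  std::vector<int> body_nucleates;

  // sites
  std::vector<int> site_body, site_mt;
  std::vector<double> site_cos, site_sin;
  std::vector<int> site_active;

  // NE motor anchors
  std::vector<int> anc_body, anc_species;
  std::vector<double> anc_cos, anc_sin;
  std::vector<Head> anc_head;

  // cytoplasmic crosslinkers (two heads)
  std::vector<int> link_species;
  std::vector<double> lx, ly;
  std::vector<Head> link_head1, link_head2;

  // fibers
  std::vector<MT> mts;
  std::vector<int> free_slots;

  // binding grid over fiber segments
  double cell = 3.0;
  int gnx = 0, gny = 0;
  std::vector<std::vector<int>> gcells;
  std::vector<int> gused;
  std::vector<int> seg_mt, seg_idx;

  // bookkeeping
  double time = 0;
  long nucleations = 0, nuc_plus = 0, nuc_minus = 0;
  long catastrophes = 0, removals = 0, rescues = 0;
  long attaches = 0, detaches = 0;
  double first_nucleation_time = -1;
  double max_cons_err = 0, max_net_internal = 0, max_disp = 0;
  double acc_body_force = 0; long acc_body_force_n = 0;
  double acc_anchor_bound = 0; long acc_anchor_steps = 0;
  long cur_step = 0;
  bool grid_dirty = true;
  std::vector<long> site_evt;    // next nucleation attempt per site
  double comp_fx = 0, comp_fy = 0;   // confinement+external compensation
  // stability audit: per-dof spring-stiffness tallies (pN/um) collected
  // during force accumulation, used to pick the mechanics substep count
  std::vector<double> bk;            // per body
  double rmax = 0;                   // max stiffness/drag ratio seen
  long max_substeps_used = 1;
};

// ----------------------------------------------------------- fiber helpers
//
// Discretization convention: interior segments carry a rest length of
// exactly seg_target; the tip (plus-end) segment carries the remainder,
// so polymerized length appears and disappears at the plus end only.

static inline int mt_want_nseg(double len, double seg_target) {
  int n = (int)std::ceil(len / seg_target - 1e-12);
  return n < 1 ? 1 : n;
}

static inline double mt_rest(const MT& m, int s, double seg_target) {
  int ns = m.nseg();
  if (s < ns - 1) return seg_target;
  double tip = m.len - seg_target * (ns - 1);
  return tip > 0 ? tip : 0.0;
}

static void mt_point(const MT& m, double s, double& x, double& y,
                     int& seg, double& w, double seg_target) {
  int ns = m.nseg();
  if (m.len < 1e-12) { seg = 0; w = 0; x = m.px[0]; y = m.py[0]; return; }
  if (s < 0) s = 0;
  if (s > m.len) s = m.len;
  double interior = seg_target * (ns - 1);
  if (s < interior) {
    seg = (int)(s / seg_target);
    if (seg > ns - 1) seg = ns - 1;
    w = s / seg_target - seg;
  } else {
    seg = ns - 1;
    double tip = m.len - interior;
    w = tip > 1e-12 ? (s - interior) / tip : 1.0;
    if (w > 1) w = 1;
  }
  x = (1 - w) * m.px[seg] + w * m.px[seg + 1];
  y = (1 - w) * m.py[seg] + w * m.py[seg + 1];
}

static void mt_tangent(const MT& m, int seg, double& tx, double& ty) {
  double dx = m.px[seg + 1] - m.px[seg], dy = m.py[seg + 1] - m.py[seg];
  double d = std::sqrt(dx * dx + dy * dy);
  if (d < 1e-12) { tx = m.d0x; ty = m.d0y; return; }
  tx = dx / d; ty = dy / d;
}

// re-discretize the polyline (geometry-preserving): new vertices sit at
// arc positions proportional to the rest-length fractions of the new
// segmentation, so the tip segment keeps the remainder
static void mt_resample(MT& m, int ns_new, double seg_target) {
  int ns = m.nseg();
  if (ns_new == ns) return;
  std::vector<double> cum(ns + 1, 0.0);
  for (int i = 0; i < ns; ++i) {
    double dx = m.px[i + 1] - m.px[i], dy = m.py[i + 1] - m.py[i];
    cum[i + 1] = cum[i] + std::sqrt(dx * dx + dy * dy);
  }
  double tot = cum[ns];
  std::vector<double> nx(ns_new + 1), ny(ns_new + 1);
  nx[0] = m.px[0]; ny[0] = m.py[0];
  nx[ns_new] = m.px[ns]; ny[ns_new] = m.py[ns];
  int j = 0;
  for (int i = 1; i < ns_new; ++i) {
    double frac = m.len > 1e-12 ? (i * seg_target) / m.len : 1.0;
    if (frac > 1) frac = 1;
    double target = tot * frac;
    while (j < ns - 1 && cum[j + 1] < target) ++j;
    double seg_len = cum[j + 1] - cum[j];
    double w = seg_len > 1e-12 ? (target - cum[j]) / seg_len : 0.0;
    nx[i] = (1 - w) * m.px[j] + w * m.px[j + 1];
    ny[i] = (1 - w) * m.py[j] + w * m.py[j + 1];
  }
  m.px.swap(nx); m.py.swap(ny);
  m.fx.assign(ns_new + 1, 0.0); m.fy.assign(ns_new + 1, 0.0);
  m.kv.assign(ns_new + 1, 0.0);
}

static void mt_check_resample(MT& m, double seg_target) {
  int want = mt_want_nseg(m.len, seg_target);
  if (want != m.nseg()) mt_resample(m, want, seg_target);
}

// --------------------------------------------------------------- the engine

static double pget(const List& p, const char* k) {
  return as<double>(p[k]);
}

static void setup(Engine& E, const List& st) {
  List p = st["params"];
  E.a = as<double>(st["a"]); E.b = as<double>(st["b"]);
  E.dt = pget(p, "dt");
  E.kT = pget(p, "temperature_kT");
  E.visc = pget(p, "viscosity");
  E.conf_k = pget(p, "confinement_k");
  E.steric_k = pget(p, "steric_k");
  E.anchor_k = pget(p, "anchor_k");
  E.seg_target = pget(p, "mt_segment_length");
  E.stretch_k = pget(p, "mt_stretch_k");
  E.rigid = pget(p, "mt_rigidity");
  E.drag_per_len = pget(p, "mt_drag_per_length");
  E.v_grow0 = pget(p, "v_grow0");
  E.v_shrink = pget(p, "v_shrink");
  E.fg = pget(p, "force_sensitivity_fg");
  E.t_free = pget(p, "cat_time_free");
  E.t_stalled = pget(p, "cat_time_stalled");
  E.nuc_rate = pget(p, "nucleation_rate");
  E.nuc_angle_sd = pget(p, "nucleation_angle_sd");
  E.Lmax = as<double>(st["pool_Lmax"]);
  E.Lpoly = as<double>(st["pool_Lpoly"]);
  E.ext_fx = pget(p, "external_fx");
  E.ext_fy = pget(p, "external_fy");
  const char* pre[4] = {"dynein", "kif5b", "map4", "map7kif5b"};
  int dirs[4] = {-1, 1, 0, 1};
  bool motor[4] = {true, true, false, true};
  for (int i = 0; i < 4; ++i) {
    std::string s(pre[i]);
    Species& S = E.sp[i];
    S.dir = dirs[i]; S.motor = motor[i];
    S.v0 = motor[i] ? pget(p, (s + "_v0").c_str()) : 0.0;
    S.f_stall = motor[i] ? pget(p, (s + "_f_stall").c_str()) : 1.0;
    S.k_on = pget(p, (s + "_k_on").c_str());
    S.k_off = pget(p, (s + "_k_off").c_str());
    S.capt = pget(p, (s + "_capture_radius").c_str());
    S.spring_k = pget(p, (s + "_spring_k").c_str());
    S.f_unbind = pget(p, (s + "_f_unbind").c_str());
  }

  E.body_kind = as<std::vector<int>>(st["body_kind"]);
  E.bx = as<std::vector<double>>(st["body_x"]);
  E.by = as<std::vector<double>>(st["body_y"]);
  E.brad = as<std::vector<double>>(st["body_radius"]);
  E.bdrag = as<std::vector<double>>(st["body_drag"]);
  E.body_nucleates = as<std::vector<int>>(st["body_nucleates"]);
  E.bfx.assign(E.bx.size(), 0.0); E.bfy.assign(E.bx.size(), 0.0);
  E.bk.assign(E.bx.size(), 0.0);

  E.site_body = as<std::vector<int>>(st["site_body"]);
  std::vector<double> sang = as<std::vector<double>>(st["site_angle"]);
  E.site_active = as<std::vector<int>>(st["site_active"]);
  for (double aa : sang) {
    E.site_cos.push_back(std::cos(aa));
    E.site_sin.push_back(std::sin(aa));
  }
  E.site_mt.assign(E.site_body.size(), -1);

  E.anc_body = as<std::vector<int>>(st["anchor_body"]);
  std::vector<double> aang = as<std::vector<double>>(st["anchor_angle"]);
  E.anc_species = as<std::vector<int>>(st["anchor_species"]);
  for (double aa : aang) {
    E.anc_cos.push_back(std::cos(aa));
    E.anc_sin.push_back(std::sin(aa));
  }
  E.anc_head.assign(E.anc_body.size(), Head());

  E.link_species = as<std::vector<int>>(st["link_species"]);
  E.lx = as<std::vector<double>>(st["link_x"]);
  E.ly = as<std::vector<double>>(st["link_y"]);
  E.link_head1.assign(E.lx.size(), Head());
  E.link_head2.assign(E.lx.size(), Head());

  // pre-existing fibers (tests and arranged scenarios)
  std::vector<int> msite = as<std::vector<int>>(st["mt_site"]);
  std::vector<double> mx = as<std::vector<double>>(st["mt_x"]);
  std::vector<double> my = as<std::vector<double>>(st["mt_y"]);
  std::vector<double> mdx = as<std::vector<double>>(st["mt_dir_x"]);
  std::vector<double> mdy = as<std::vector<double>>(st["mt_dir_y"]);
  std::vector<double> mlen = as<std::vector<double>>(st["mt_length"]);
  std::vector<int> mstate = as<std::vector<int>>(st["mt_state"]);
  for (size_t i = 0; i < mx.size(); ++i) {
    MT m;
    double dn = std::sqrt(mdx[i] * mdx[i] + mdy[i] * mdy[i]);
    double ux = dn > 0 ? mdx[i] / dn : 1.0, uy = dn > 0 ? mdy[i] / dn : 0.0;
    int ns = mt_want_nseg(mlen[i], E.seg_target);
    for (int j = 0; j <= ns; ++j) {
      double arc = j < ns ? std::min(j * E.seg_target, mlen[i]) : mlen[i];
      m.px.push_back(mx[i] + ux * arc);
      m.py.push_back(my[i] + uy * arc);
    }
    m.fx.assign(ns + 1, 0.0); m.fy.assign(ns + 1, 0.0);
    m.kv.assign(ns + 1, 0.0);
    m.len = mlen[i]; m.state = mstate[i];
    m.site = msite[i]; m.d0x = ux; m.d0y = uy;
    m.gen = 1; m.alive = true; m.tipfx = m.tipfy = 0;
    if (m.site >= 0) E.site_mt[m.site] = (int)E.mts.size();
    E.mts.push_back(m);
  }

  // initial event schedules
  for (size_t ia = 0; ia < E.anc_head.size(); ++ia)
    E.anc_head[ia].evt = event_wait_steps(E.sp[E.anc_species[ia]].k_on, E.dt);
  for (size_t il = 0; il < E.lx.size(); ++il) {
    E.link_head1[il].evt = event_wait_steps(E.sp[E.link_species[il]].k_on, E.dt);
    E.link_head2[il].evt = event_wait_steps(E.sp[E.link_species[il]].k_on, E.dt);
  }
  E.site_evt.resize(E.site_body.size());
  for (size_t is = 0; is < E.site_body.size(); ++is)
    E.site_evt[is] = event_wait_steps(E.nuc_rate, E.dt);

  E.gnx = (int)std::ceil(2 * E.a / E.cell) + 3;
  E.gny = (int)std::ceil(2 * E.b / E.cell) + 3;
  E.gcells.assign((size_t)E.gnx * E.gny, {});
  E.time = as<double>(st["time"]);
}

static inline int grid_ix(const Engine& E, double x) {
  int i = (int)std::floor((x + E.a) / E.cell) + 1;
  if (i < 0) i = 0;
  if (i >= E.gnx) i = E.gnx - 1;
  return i;
}
static inline int grid_iy(const Engine& E, double y) {
  int i = (int)std::floor((y + E.b) / E.cell) + 1;
  if (i < 0) i = 0;
  if (i >= E.gny) i = E.gny - 1;
  return i;
}

static void build_grid(Engine& E, double margin) {
  for (int c : E.gused) E.gcells[c].clear();
  E.gused.clear();
  E.seg_mt.clear(); E.seg_idx.clear();
  for (size_t im = 0; im < E.mts.size(); ++im) {
    MT& m = E.mts[im];
    if (!m.alive) continue;
    for (int s = 0; s < m.nseg(); ++s) {
      int id = (int)E.seg_mt.size();
      E.seg_mt.push_back((int)im); E.seg_idx.push_back(s);
      double x1 = std::min(m.px[s], m.px[s + 1]) - margin;
      double x2 = std::max(m.px[s], m.px[s + 1]) + margin;
      double y1 = std::min(m.py[s], m.py[s + 1]) - margin;
      double y2 = std::max(m.py[s], m.py[s + 1]) + margin;
      for (int ix = grid_ix(E, x1); ix <= grid_ix(E, x2); ++ix)
        for (int iy = grid_iy(E, y1); iy <= grid_iy(E, y2); ++iy) {
          int c = iy * E.gnx + ix;
          if (E.gcells[c].empty()) E.gused.push_back(c);
          E.gcells[c].push_back(id);
        }
    }
  }
}

// closest point search among fiber segments near (x, y); returns true when
// a segment lies within 'capt'; ties broken by distance then lowest MT id
static bool nearest_segment(const Engine& E, double x, double y, double capt,
                            int exclude_mt, int& best_mt, double& best_s) {
  const double seg_target_g = E.seg_target;
  double best_d2 = capt * capt;
  best_mt = -1; best_s = 0;
  bool found = false;
  int ix = grid_ix(E, x), iy = grid_iy(E, y);
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy) {
      int jx = ix + dx, jy = iy + dy;
      if (jx < 0 || jx >= E.gnx || jy < 0 || jy >= E.gny) continue;
      const std::vector<int>& cell = E.gcells[(size_t)jy * E.gnx + jx];
      for (int id : cell) {
        int im = E.seg_mt[id], is = E.seg_idx[id];
        if (im == exclude_mt) continue;
        const MT& m = E.mts[im];
        double x1 = m.px[is], y1 = m.py[is];
        double ddx = m.px[is + 1] - x1, ddy = m.py[is + 1] - y1;
        double L2 = ddx * ddx + ddy * ddy;
        double t = L2 > 1e-18 ? ((x - x1) * ddx + (y - y1) * ddy) / L2 : 0.0;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        double cx = x1 + t * ddx - x, cy = y1 + t * ddy - y;
        double d2 = cx * cx + cy * cy;
        bool better = d2 < best_d2 - 1e-18 ||
          (std::fabs(d2 - best_d2) <= 1e-18 && found && im < best_mt);
        if (d2 <= best_d2 && (!found || better)) {
          double rest = m.len - seg_target_g * (m.nseg() - 1);
          double s_at = is < m.nseg() - 1 ? (is + t) * seg_target_g
                                          : seg_target_g * is + t * rest;
          best_d2 = d2; best_mt = im; best_s = s_at;
          found = true;
        }
      }
    }
  return found;
}

// distribute a force applied at abscissa s onto the flanking vertices,
// tracking the tip share for growth attenuation
static void apply_on_fiber(Engine& E, MT& m, int seg, double w, double fx,
                           double fy) {
  m.fx[seg] += (1 - w) * fx; m.fy[seg] += (1 - w) * fy;
  m.fx[seg + 1] += w * fx;   m.fy[seg + 1] += w * fy;
  if (seg + 1 == (int)m.px.size() - 1) {
    m.tipfx += w * fx; m.tipfy += w * fy;
  }
  if (seg == (int)m.px.size() - 1) { m.tipfx += fx; m.tipfy += fy; }
}

static inline double head_spk(const Engine& E, int species) {
  return E.sp[species].spring_k;
}

// world position of an NE anchor
static inline void anchor_pos(const Engine& E, int ia, double& x, double& y) {
  int ib = E.anc_body[ia];
  x = E.bx[ib] + E.brad[ib] * E.anc_cos[ia];
  y = E.by[ib] + E.brad[ib] * E.anc_sin[ia];
}

static void accumulate_forces(Engine& E) {
  size_t nb = E.bx.size();
  for (size_t i = 0; i < nb; ++i) { E.bfx[i] = 0; E.bfy[i] = 0; E.bk[i] = 0; }
  for (MT& m : E.mts) {
    if (!m.alive) continue;
    std::fill(m.fx.begin(), m.fx.end(), 0.0);
    std::fill(m.fy.begin(), m.fy.end(), 0.0);
    std::fill(m.kv.begin(), m.kv.end(), 0.0);
    m.tipfx = m.tipfy = 0;
  }
  E.comp_fx = 0; E.comp_fy = 0;

  // fiber internal elasticity
  for (MT& m : E.mts) {
    if (!m.alive) continue;
    int ns = m.nseg();
    for (int s = 0; s < ns; ++s) {
      double rest = mt_rest(m, s, E.seg_target);
      double dx = m.px[s + 1] - m.px[s], dy = m.py[s + 1] - m.py[s];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < 1e-12) continue;
      double f = E.stretch_k * (d - rest) / d;  // tension per unit separation
      m.fx[s] += f * dx; m.fy[s] += f * dy;
      m.fx[s + 1] -= f * dx; m.fy[s + 1] -= f * dy;
      m.kv[s] += E.stretch_k; m.kv[s + 1] += E.stretch_k;
    }
    if (ns >= 2) {
      double l0 = E.seg_target;
      double kb = E.rigid / (l0 * l0 * l0);
      for (int v = 1; v < ns; ++v) {
        double cx = m.px[v - 1] - 2 * m.px[v] + m.px[v + 1];
        double cy = m.py[v - 1] - 2 * m.py[v] + m.py[v + 1];
        m.fx[v - 1] -= kb * cx; m.fy[v - 1] -= kb * cy;
        m.fx[v] += 2 * kb * cx; m.fy[v] += 2 * kb * cy;
        m.fx[v + 1] -= kb * cx; m.fy[v + 1] -= kb * cy;
        m.kv[v - 1] += kb; m.kv[v] += 4 * kb; m.kv[v + 1] += kb;
      }
    }
    // minus-end anchoring spring to the nucleation site
    if (m.site >= 0) {
      int ib = E.site_body[m.site];
      double axp = E.bx[ib] + E.brad[ib] * E.site_cos[m.site];
      double ayp = E.by[ib] + E.brad[ib] * E.site_sin[m.site];
      double fx = E.anchor_k * (axp - m.px[0]);
      double fy = E.anchor_k * (ayp - m.py[0]);
      m.fx[0] += fx; m.fy[0] += fy;
      E.bfx[ib] -= fx; E.bfy[ib] -= fy;
      m.kv[0] += E.anchor_k; E.bk[ib] += E.anchor_k;
    }
  }

  // confinement (bodies to the radius-reduced ellipse, vertices to the full)
  for (size_t i = 0; i < nb; ++i) {
    double f0, f1;
    conf_force(E.bx[i], E.by[i], E.a, E.b, E.conf_k, E.brad[i], f0, f1);
    E.bfx[i] += f0; E.bfy[i] += f1;
    E.comp_fx += f0; E.comp_fy += f1;
    if (f0 != 0 || f1 != 0) E.bk[i] += E.conf_k;
    E.bfx[i] += E.ext_fx; E.bfy[i] += E.ext_fy;
    E.comp_fx += E.ext_fx; E.comp_fy += E.ext_fy;
  }
  for (MT& m : E.mts) {
    if (!m.alive) continue;
    for (size_t v = 0; v < m.px.size(); ++v) {
      double q = (m.px[v] * m.px[v]) / (E.a * E.a) +
                 (m.py[v] * m.py[v]) / (E.b * E.b);
      if (q <= 1.0) continue;
      double f0, f1;
      conf_force(m.px[v], m.py[v], E.a, E.b, E.conf_k, 0.0, f0, f1);
      m.fx[v] += f0; m.fy[v] += f1;
      E.comp_fx += f0; E.comp_fy += f1;
      m.kv[v] += E.conf_k;
      if (v + 1 == m.px.size()) { m.tipfx += f0; m.tipfy += f1; }
    }
  }

  // soft excluded volume: body-body
  for (size_t i = 0; i + 1 < nb; ++i)
    for (size_t j = i + 1; j < nb; ++j) {
      double dx = E.bx[j] - E.bx[i], dy = E.by[j] - E.by[i];
      double rr = E.brad[i] + E.brad[j];
      double d2 = dx * dx + dy * dy;
      if (d2 >= rr * rr) continue;
      double d = std::sqrt(d2);
      double ux = d > 1e-12 ? dx / d : 1.0, uy = d > 1e-12 ? dy / d : 0.0;
      double f = E.steric_k * (rr - d);
      E.bfx[i] -= f * ux; E.bfy[i] -= f * uy;
      E.bfx[j] += f * ux; E.bfy[j] += f * uy;
      E.bk[i] += E.steric_k; E.bk[j] += E.steric_k;
    }

  // body-fiber (closest point of each segment; fibers have zero radius;
  // fiber-fiber contacts are exempt by construction)
  for (MT& m : E.mts) {
    if (!m.alive) continue;
    int ns = m.nseg();
    for (size_t ib = 0; ib < nb; ++ib) {
      double cxb = E.bx[ib], cyb = E.by[ib], r = E.brad[ib];
      for (int s = 0; s < ns; ++s) {
        double x1 = m.px[s], y1 = m.py[s];
        double dx = m.px[s + 1] - x1, dy = m.py[s + 1] - y1;
        // cheap reject on the segment bounding box
        double lox = std::min(x1, x1 + dx), hix = std::max(x1, x1 + dx);
        if (cxb < lox - r || cxb > hix + r) continue;
        double loy = std::min(y1, y1 + dy), hiy = std::max(y1, y1 + dy);
        if (cyb < loy - r || cyb > hiy + r) continue;
        double L2 = dx * dx + dy * dy;
        double t = L2 > 1e-18 ? ((cxb - x1) * dx + (cyb - y1) * dy) / L2 : 0.0;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        double px = x1 + t * dx, py = y1 + t * dy;
        double ex = px - cxb, ey = py - cyb;
        double d2 = ex * ex + ey * ey;
        if (d2 >= r * r) continue;
        double d = std::sqrt(d2);
        double ux = d > 1e-12 ? ex / d : 1.0, uy = d > 1e-12 ? ey / d : 0.0;
        double f = E.steric_k * (r - d);
        apply_on_fiber(E, m, s, t, f * ux, f * uy);
        E.bfx[ib] -= f * ux; E.bfy[ib] -= f * uy;
        m.kv[s] += E.steric_k; m.kv[s + 1] += E.steric_k;
        E.bk[ib] += E.steric_k;
      }
    }
  }

  // connector springs
  for (size_t ia = 0; ia < E.anc_body.size(); ++ia) {
    Head& h = E.anc_head[ia];
    if (!h.bound) continue;
    MT& m = E.mts[h.mt];
    double axp, ayp; anchor_pos(E, (int)ia, axp, ayp);
    int seg; double w, hx, hy;
    mt_point(m, h.s, hx, hy, seg, w, E.seg_target);
    double k = head_spk(E, E.anc_species[ia]);
    double fx = k * (axp - hx), fy = k * (ayp - hy);  // force on the MT head
    apply_on_fiber(E, m, seg, w, fx, fy);
    E.bfx[E.anc_body[ia]] -= fx; E.bfy[E.anc_body[ia]] -= fy;
    m.kv[seg] += k; m.kv[seg + 1] += k; E.bk[E.anc_body[ia]] += k;
  }
  for (size_t il = 0; il < E.lx.size(); ++il) {
    Head& h1 = E.link_head1[il];
    Head& h2 = E.link_head2[il];
    if (!h1.bound || !h2.bound) continue;
    MT& m1 = E.mts[h1.mt];
    MT& m2 = E.mts[h2.mt];
    int s1, s2; double w1, w2, x1, y1, x2, y2;
    mt_point(m1, h1.s, x1, y1, s1, w1, E.seg_target);
    mt_point(m2, h2.s, x2, y2, s2, w2, E.seg_target);
    double k = head_spk(E, E.link_species[il]);
    double fx = k * (x2 - x1), fy = k * (y2 - y1);  // on head1 toward head2
    apply_on_fiber(E, m1, s1, w1, fx, fy);
    apply_on_fiber(E, m2, s2, w2, -fx, -fy);
    m1.kv[s1] += k; m1.kv[s1 + 1] += k;
    m2.kv[s2] += k; m2.kv[s2 + 1] += k;
  }
  for (size_t i = 0; i < nb; ++i) {
    if (E.body_kind[i] != 0) continue;
    E.acc_body_force += std::sqrt(E.bfx[i] * E.bfx[i] + E.bfy[i] * E.bfy[i]);
    ++E.acc_body_force_n;
  }
}

static inline double vertex_drag(const Engine& E, const MT& m) {
  (void)m;
  double leff = E.seg_target > 1.0 ? E.seg_target : 1.0;  // drag floor
  return E.drag_per_len * leff;
}

// stability-limited mechanics substep count from the stiffness tallies
static int substeps_needed(const Engine& E) {
  double rmax = 0;
  for (size_t i = 0; i < E.bx.size(); ++i) {
    double r = E.bk[i] / E.bdrag[i];
    if (r > rmax) rmax = r;
  }
  for (const MT& m : E.mts) {
    if (!m.alive) continue;
    double g = vertex_drag(E, m);
    for (double k : m.kv) {
      double r = k / g;
      if (r > rmax) rmax = r;
    }
  }
  int n = (int)std::ceil(E.dt * rmax / 0.8);
  if (n < 1) n = 1;
  if (n > 2) n = 2;   // beyond this the exponential relaxation takes over
  return n;
}

// displacement factor of the diagonally-implicit (exponential) update:
// a dof loaded with local spring stiffness k relaxes toward its local
// equilibrium as exp(-k dt / g); for small k dt / g this is the explicit
// Euler step, for stiff clusters it is unconditionally stable
static inline double etd_factor(double k, double dt, double g) {
  double z = k * dt / g;
  if (z < 0.1) return 1.0;
  return (1.0 - std::exp(-z)) / z;
}

static void langevin_move(Engine& E, double dt, double noise_dt) {
  double maxd2 = 0;
  double netx = -E.comp_fx, nety = -E.comp_fy;
  for (size_t i = 0; i < E.bx.size(); ++i) {
    netx += E.bfx[i]; nety += E.bfy[i];
    double g = E.bdrag[i];
    double c = etd_factor(E.bk[i], dt, g);
    double sig = noise_dt > 0 ? std::sqrt(2 * E.kT * noise_dt * c / g) : 0.0;
    double dx = E.bfx[i] / g * dt * c +
      (E.kT > 0 && sig > 0 ? sig * norm_rand() : 0.0);
    double dy = E.bfy[i] / g * dt * c +
      (E.kT > 0 && sig > 0 ? sig * norm_rand() : 0.0);
    E.bx[i] += dx; E.by[i] += dy;
    double d2 = dx * dx + dy * dy;
    if (d2 > maxd2) maxd2 = d2;
  }
  for (MT& m : E.mts) {
    if (!m.alive) continue;
    double g = vertex_drag(E, m);
    for (size_t v = 0; v < m.px.size(); ++v) {
      netx += m.fx[v]; nety += m.fy[v];
      double c = etd_factor(m.kv[v], dt, g);
      double sig = noise_dt > 0 ?
        std::sqrt(2 * E.kT * noise_dt * c / g) : 0.0;
      double dx = m.fx[v] / g * dt * c +
        (E.kT > 0 && sig > 0 ? sig * norm_rand() : 0.0);
      double dy = m.fy[v] / g * dt * c +
        (E.kT > 0 && sig > 0 ? sig * norm_rand() : 0.0);
      m.px[v] += dx; m.py[v] += dy;
      double d2 = dx * dx + dy * dy;
      if (d2 > maxd2) maxd2 = d2;
    }
  }
  double nd = std::sqrt(netx * netx + nety * nety);
  if (nd > E.max_net_internal) E.max_net_internal = nd;
  double md = std::sqrt(maxd2);
  if (md > E.max_disp) E.max_disp = md;
  if (md > E.a)
    stop("numerical blow-up: a displacement of %g um exceeds the domain; "
         "reduce dt or stiffnesses", md);
}

// free crosslinkers diffuse with their own drag; the walk is aggregated
// over 'dt' (several event steps) since unbound diffusion is slow at this
// viscosity; moves leaving the cell are rejected
static void diffuse_links(Engine& E, double dt, double D) {
  if (E.kT <= 0 || D <= 0) return;
  double sig = std::sqrt(2 * D * dt);
  for (size_t il = 0; il < E.lx.size(); ++il) {
    if (E.link_head1[il].bound || E.link_head2[il].bound) continue;
    double nx2 = E.lx[il] + sig * norm_rand();
    double ny2 = E.ly[il] + sig * norm_rand();
    if ((nx2 * nx2) / (E.a * E.a) + (ny2 * ny2) / (E.b * E.b) <= 1.0) {
      E.lx[il] = nx2; E.ly[il] = ny2;
    }
  }
}

static void free_heads_of(Engine& E, int im) {
  // lazily handled through generation counters; nothing to scan
  (void)E; (void)im;
}

static void mt_dynamics(Engine& E) {
  for (size_t im = 0; im < E.mts.size(); ++im) {
    MT& m = E.mts[im];
    if (!m.alive) continue;
    if (m.state == 1) {
      int last = m.nseg();
      double tx, ty;
      if (m.len < 1e-9) { tx = m.d0x; ty = m.d0y; }
      else mt_tangent(m, last - 1, tx, ty);
      double fpar = -(m.tipfx * tx + m.tipfy * ty);
      double f_ant = fpar > 0 ? fpar : 0.0;
      double v = cpp_growth_speed(E.v_grow0, f_ant, E.fg, E.Lpoly, E.Lmax);
      double dL = v * E.dt;
      if (E.Lpoly + dL > E.Lmax) dL = E.Lmax - E.Lpoly;
      if (dL > 0) {
        m.px[last] += tx * dL; m.py[last] += ty * dL;
        m.len += dL; E.Lpoly += dL;
      }
      double rate = cpp_catastrophe_rate(v, E.v_grow0, E.t_free, E.t_stalled);
      if (event_occurs(rate, E.dt)) {
        m.state = -1;
        ++E.catastrophes;
      }
      mt_check_resample(m, E.seg_target);
    } else {
      double dL = E.v_shrink * E.dt;
      if (m.len <= dL) {
        E.Lpoly -= m.len;
        if (E.Lpoly < 0) E.Lpoly = 0;
        m.alive = false;
        m.len = 0;
        ++m.gen;
        if (m.site >= 0) E.site_mt[m.site] = -1;
        E.free_slots.push_back((int)im);
        E.grid_dirty = true;
        ++E.removals;
        free_heads_of(E, (int)im);
        continue;
      }
      // retract the plus end geometrically by dL
      double rem = dL;
      while (rem > 0 && m.px.size() > 1) {
        size_t last = m.px.size() - 1;
        double dx = m.px[last] - m.px[last - 1];
        double dy = m.py[last] - m.py[last - 1];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d > rem) {
          m.px[last] -= dx / d * rem; m.py[last] -= dy / d * rem;
          rem = 0;
        } else if (m.px.size() > 2) {
          m.px.pop_back(); m.py.pop_back();
          m.fx.pop_back(); m.fy.pop_back(); m.kv.pop_back();
          rem -= d;
        } else {
          m.px[last] = m.px[0] + (d > 1e-12 ? dx / d : m.d0x) * 1e-9;
          m.py[last] = m.py[0] + (d > 1e-12 ? dy / d : m.d0y) * 1e-9;
          rem = 0;
        }
      }
      m.len -= dL; E.Lpoly -= dL;
      if (E.Lpoly < 0) E.Lpoly = 0;
      mt_check_resample(m, E.seg_target);
    }
  }
  // clamp abscissae of bound heads (end dwell / stale references)
  auto fix_head = [&](Head& h) {
    if (!h.bound) return;
    if (h.mt < 0 || !E.mts[h.mt].alive || E.mts[h.mt].gen != h.gen) {
      h.bound = false; h.mt = -1;
      h.evt = E.cur_step;   // may retry binding immediately
      return;
    }
    if (h.s > E.mts[h.mt].len) h.s = E.mts[h.mt].len;
    if (h.s < 0) h.s = 0;
  };
  for (Head& h : E.anc_head) fix_head(h);
  for (Head& h : E.link_head1) fix_head(h);
  for (Head& h : E.link_head2) fix_head(h);
}

static void connector_kinetics(Engine& E) {
  // --- walk bound motor heads (linear force-velocity, end dwell)
  for (size_t ia = 0; ia < E.anc_body.size(); ++ia) {
    Head& h = E.anc_head[ia];
    if (!h.bound) continue;
    const Species& S = E.sp[E.anc_species[ia]];
    if (!S.motor) continue;
    MT& m = E.mts[h.mt];
    int seg; double w, hx, hy;
    mt_point(m, h.s, hx, hy, seg, w, E.seg_target);
    double tx, ty; mt_tangent(m, seg, tx, ty);
    double axp, ayp; anchor_pos(E, (int)ia, axp, ayp);
    double fx = S.spring_k * (axp - hx), fy = S.spring_k * (ayp - hy);
    double f_op = -(fx * tx + fy * ty) * S.dir;
    double v = cpp_motor_velocity(f_op, S.v0, S.f_stall);
    h.s += S.dir * v * E.dt;
    if (h.s < 0) h.s = 0;
    if (h.s > m.len) h.s = m.len;
  }
  for (size_t il = 0; il < E.lx.size(); ++il) {
    const Species& S = E.sp[E.link_species[il]];
    Head& h1 = E.link_head1[il];
    Head& h2 = E.link_head2[il];
    if (S.motor && h2.bound) {   // head2 is the motile (Kif5b) head
      MT& m = E.mts[h2.mt];
      int seg; double w, hx, hy;
      mt_point(m, h2.s, hx, hy, seg, w, E.seg_target);
      double v;
      if (h1.bound) {
        MT& m1 = E.mts[h1.mt];
        int s1; double w1, x1, y1;
        mt_point(m1, h1.s, x1, y1, s1, w1, E.seg_target);
        double tx, ty; mt_tangent(m, seg, tx, ty);
        double fx = S.spring_k * (x1 - hx), fy = S.spring_k * (y1 - hy);
        double f_op = -(fx * tx + fy * ty) * S.dir;
        v = cpp_motor_velocity(f_op, S.v0, S.f_stall);
      } else {
        v = S.v0;
      }
      h2.s += S.dir * v * E.dt;
      if (h2.s < 0) h2.s = 0;
      if (h2.s > m.len) h2.s = m.len;
    }
  }

  // --- detachment: first-order, optionally load-accelerated (Kramers
  // exponential in the spring force; f_unbind = Inf restores pure
  // force-independent kinetics)
  auto detach_rate = [&](const Species& S, double f) {
    if (!std::isfinite(S.f_unbind) || S.f_unbind <= 0) return S.k_off;
    double z = f / S.f_unbind;
    if (z > 30) z = 30;
    return S.k_off * std::exp(z);
  };
  auto head_force = [&](const Head& h, double ox, double oy, double k) {
    int seg; double w, hx, hy;
    mt_point(E.mts[h.mt], h.s, hx, hy, seg, w, E.seg_target);
    double dx = ox - hx, dy = oy - hy;
    return k * std::sqrt(dx * dx + dy * dy);
  };
  auto try_detach = [&](Head& h, const Species& S, double f) {
    if (!h.bound) return;
    if (!event_occurs(detach_rate(S, f), E.dt)) return;
    h.bound = false; h.mt = -1;
    ++E.detaches;
    h.evt = E.cur_step + event_wait_steps(S.k_on, E.dt);
  };
  for (size_t ia = 0; ia < E.anc_body.size(); ++ia) {
    Head& h = E.anc_head[ia];
    if (!h.bound) continue;
    const Species& S = E.sp[E.anc_species[ia]];
    double axp, ayp; anchor_pos(E, (int)ia, axp, ayp);
    try_detach(h, S, head_force(h, axp, ayp, S.spring_k));
  }
  for (size_t il = 0; il < E.lx.size(); ++il) {
    const Species& S = E.sp[E.link_species[il]];
    Head& h1 = E.link_head1[il];
    Head& h2 = E.link_head2[il];
    double f = 0;
    if (h1.bound && h2.bound) {
      int sg; double w, x1, y1, x2, y2;
      mt_point(E.mts[h1.mt], h1.s, x1, y1, sg, w, E.seg_target);
      mt_point(E.mts[h2.mt], h2.s, x2, y2, sg, w, E.seg_target);
      f = S.spring_k * std::hypot(x2 - x1, y2 - y1);
    }
    try_detach(h1, S, f);
    try_detach(h2, S, f);
  }

  // --- update stored positions of crosslinkers from their bound heads
  for (size_t il = 0; il < E.lx.size(); ++il) {
    Head& h1 = E.link_head1[il];
    Head& h2 = E.link_head2[il];
    if (h1.bound) {
      int seg; double w;
      mt_point(E.mts[h1.mt], h1.s, E.lx[il], E.ly[il], seg, w, E.seg_target);
    } else if (h2.bound) {
      int seg; double w;
      mt_point(E.mts[h2.mt], h2.s, E.lx[il], E.ly[il], seg, w, E.seg_target);
    }
  }

  // --- attachment (first-order, nearest eligible MT point)
  double maxc = 0;
  for (int i = 0; i < 4; ++i) if (E.sp[i].capt > maxc) maxc = E.sp[i].capt;
  // cell membership only; closest points use live geometry, so a stale
  // grid just needs margin to cover a few steps of fiber motion
  if (E.cur_step % 5 == 0 || E.grid_dirty) {
    build_grid(E, maxc + 0.25);
    E.grid_dirty = false;
  }
  // the first-order event fires on its scheduled step; on success the
  // head binds the nearest eligible MT point within its capture radius
  auto try_attach = [&](Head& h, const Species& S, double x, double y,
                        int exclude) {
    if (E.cur_step < h.evt) return;
    h.evt = E.cur_step + event_wait_steps(S.k_on, E.dt);
    int bm; double bs;
    if (!nearest_segment(E, x, y, S.capt, exclude, bm, bs)) return;
    h.bound = true; h.mt = bm; h.gen = E.mts[bm].gen; h.s = bs;
    ++E.attaches;
  };
  for (size_t ia = 0; ia < E.anc_body.size(); ++ia) {
    Head& h = E.anc_head[ia];
    if (h.bound) continue;
    double axp, ayp; anchor_pos(E, (int)ia, axp, ayp);
    try_attach(h, E.sp[E.anc_species[ia]], axp, ayp, -1);
  }
  for (size_t il = 0; il < E.lx.size(); ++il) {
    const Species& S = E.sp[E.link_species[il]];
    Head& h1 = E.link_head1[il];
    Head& h2 = E.link_head2[il];
    if (!h1.bound)
      try_attach(h1, S, E.lx[il], E.ly[il], h2.bound ? h2.mt : -1);
    if (!h2.bound)
      try_attach(h2, S, E.lx[il], E.ly[il], h1.bound ? h1.mt : -1);
  }
}

static void tally_bound(Engine& E) {
  if (E.anc_head.empty()) return;
  long nb = 0;
  for (const Head& h : E.anc_head) if (h.bound) ++nb;
  E.acc_anchor_bound += double(nb) / double(E.anc_head.size());
  ++E.acc_anchor_steps;
}

static void nucleation(Engine& E) {
  for (size_t is = 0; is < E.site_body.size(); ++is) {
    if (E.cur_step < E.site_evt[is]) continue;
    E.site_evt[is] = E.cur_step + event_wait_steps(E.nuc_rate, E.dt);
    if (E.site_mt[is] >= 0 || !E.site_active[is]) continue;
    int ib = E.site_body[is];
    if (!E.body_nucleates[ib]) continue;
    if (E.Lpoly >= E.Lmax - 1e-12) continue;       // exhausted pool
    double x = E.bx[ib] + E.brad[ib] * E.site_cos[is];
    double y = E.by[ib] + E.brad[ib] * E.site_sin[is];
    double dir = unif_rand() < 0.5 ? 1.0 : -1.0;   // +x or -x, equal odds
    // near-horizontal nucleation: axial direction plus Gaussian angle noise
    double ang = (dir > 0 ? 0.0 : M_PI) + E.nuc_angle_sd * norm_rand();
    MT m;
    m.px = {x, x}; m.py = {y, y};
    m.fx = {0, 0}; m.fy = {0, 0}; m.kv = {0, 0};
    m.len = 0; m.state = 1; m.site = (int)is;
    m.d0x = std::cos(ang); m.d0y = std::sin(ang);
    m.tipfx = m.tipfy = 0;
    m.alive = true;
    int slot;
    if (!E.free_slots.empty()) {
      slot = E.free_slots.back(); E.free_slots.pop_back();
      m.gen = E.mts[slot].gen + 1;
      E.mts[slot] = m;
    } else {
      slot = (int)E.mts.size();
      m.gen = 1;
      E.mts.push_back(m);
    }
    E.site_mt[is] = slot;
    E.grid_dirty = true;
    ++E.nucleations;
    if (dir > 0) ++E.nuc_plus; else ++E.nuc_minus;
    if (E.first_nucleation_time < 0) E.first_nucleation_time = E.time;
  }
}

// [[Rcpp::export]]
List engine_run(List state, double duration, int frame_stride) {
  Engine E;
  setup(E, state);
  if (duration < 0) stop("duration must be >= 0");
  if (frame_stride < 1) frame_stride = 1;
  long nsteps = (long)std::llround(duration / E.dt);
  long nframes_max = nsteps / frame_stride + 2;
  size_t nb = E.bx.size();
  NumericMatrix frames(nframes_max, 1 + 2 * nb);
  long fr = 0;
  auto record = [&]() {
    frames(fr, 0) = E.time;
    for (size_t i = 0; i < nb; ++i) {
      frames(fr, 1 + 2 * i) = E.bx[i];
      frames(fr, 2 + 2 * i) = E.by[i];
    }
    ++fr;
  };
  record();
  double link_D = pget(as<List>(state["params"]), "crosslinker_diffusion");
  for (long step = 0; step < nsteps; ++step) {
    E.cur_step = step;
    int n_sub = 1;
    for (int sub = 0; sub < n_sub; ++sub) {
      accumulate_forces(E);
      if (sub == 0) {
        n_sub = substeps_needed(E);
        if (n_sub > E.max_substeps_used) E.max_substeps_used = n_sub;
      }
      langevin_move(E, E.dt / n_sub, sub == 0 ? E.dt : 0.0);
    }
    if (step % 10 == 0) diffuse_links(E, 10 * E.dt, link_D);
    mt_dynamics(E);
    connector_kinetics(E);
    tally_bound(E);
    nucleation(E);
    E.time += E.dt;
    // conservation audit
    double tot = 0;
    for (const MT& m : E.mts) if (m.alive) tot += m.len;
    double err = std::fabs(tot - E.Lpoly);
    if (err > E.max_cons_err) E.max_cons_err = err;
    if ((step + 1) % frame_stride == 0 && step + 1 < nsteps) record();
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  if (nsteps > 0) record();
  frames = frames(Range(0, fr - 1), _);

  // final fibers
  List mt_x, mt_y;
  std::vector<double> mt_len;
  std::vector<int> mt_state, mt_site;
  for (const MT& m : E.mts) {
    if (!m.alive) continue;
    mt_x.push_back(NumericVector(m.px.begin(), m.px.end()));
    mt_y.push_back(NumericVector(m.py.begin(), m.py.end()));
    mt_len.push_back(m.len);
    mt_state.push_back(m.state);
    mt_site.push_back(m.site);
  }
  long anc_bound = 0, anc_self = 0, anc_other = 0;
  for (size_t ia = 0; ia < E.anc_head.size(); ++ia) {
    const Head& h = E.anc_head[ia];
    if (!h.bound) continue;
    ++anc_bound;
    const MT& m = E.mts[h.mt];
    int host = m.site >= 0 ? E.site_body[m.site] : -1;
    if (host == E.anc_body[ia]) ++anc_self; else ++anc_other;
  }
  long link_bound = 0, link_bridging = 0;
  for (size_t il = 0; il < E.lx.size(); ++il) {
    if (E.link_head1[il].bound) ++link_bound;
    if (E.link_head2[il].bound) ++link_bound;
    if (E.link_head1[il].bound && E.link_head2[il].bound) ++link_bridging;
  }

  return List::create(
    _["body_x"] = NumericVector(E.bx.begin(), E.bx.end()),
    _["body_y"] = NumericVector(E.by.begin(), E.by.end()),
    _["frames"] = frames,
    _["mt_x"] = mt_x, _["mt_y"] = mt_y,
    _["mt_length"] = NumericVector(mt_len.begin(), mt_len.end()),
    _["mt_state"] = IntegerVector(mt_state.begin(), mt_state.end()),
    _["mt_site"] = IntegerVector(mt_site.begin(), mt_site.end()),
    _["events"] = NumericVector::create(
      _["nucleations"] = (double)E.nucleations,
      _["nucleations_plus_x"] = (double)E.nuc_plus,
      _["nucleations_minus_x"] = (double)E.nuc_minus,
      _["catastrophes"] = (double)E.catastrophes,
      _["removals"] = (double)E.removals,
      _["rescues"] = (double)E.rescues,
      _["attachments"] = (double)E.attaches,
      _["detachments"] = (double)E.detaches,
      _["first_nucleation_time"] = E.first_nucleation_time),
    _["pool"] = List::create(_["L_max"] = E.Lmax,
                             _["L_polymerized"] = E.Lpoly),
    _["anchor_mt"] = [&]() {
      IntegerVector v(E.anc_head.size());
      for (size_t ia = 0; ia < E.anc_head.size(); ++ia)
        v[ia] = E.anc_head[ia].bound ? E.anc_head[ia].mt + 1 : NA_INTEGER;
      return v;
    }(),
    _["connectors"] = NumericVector::create(
      _["ne_heads_bound"] = (double)anc_bound,
      _["ne_bound_self"] = (double)anc_self,
      _["ne_bound_other"] = (double)anc_other,
      _["link_heads_bound"] = (double)link_bound,
      _["links_bridging"] = (double)link_bridging),
    _["diagnostics"] = NumericVector::create(
      _["max_conservation_error"] = E.max_cons_err,
      _["max_net_internal_force"] = E.max_net_internal,
      _["max_step_displacement"] = E.max_disp,
      _["max_substeps"] = (double)E.max_substeps_used,
      _["mean_nucleus_force"] = E.acc_body_force_n > 0 ?
        E.acc_body_force / E.acc_body_force_n : 0.0,
      _["mean_anchor_bound"] = E.acc_anchor_steps > 0 ?
        E.acc_anchor_bound / E.acc_anchor_steps : 0.0),
    _["time"] = E.time);
}
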