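// Core simulation kernels: whisker arc geometry, quasistatic bending against
// oriented rectangles, head-centric field operations (Gaussian blobs, rigid
// bilinear remap, obstacle shadowing, IOR), the salience-to-protraction
// transform, and the full per-sample sensorimotor loop.
//
// Accumulations over grid cells are performed in mirror-paired order (row iy
// with row ny-1-iy) so that a world mirrored about the head midline produces
// a bitwise-mirrored simulation under mirrored noise streams.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double DEG = M_PI / 180.0;
static const double ARC_STEP = 1.0;    // mm, whisker arc discretisation
static const double DK_MAX = 0.25;     // 1/mm, bending solver search bound
static const double DK_TOL = 1e-4;     // 1/mm, bisection tolerance
static const double BLOB_CUT = 4.0;    // Gaussian blob support, in sigmas

// ---------------------------------------------------------------------------
// RNG: splitmix64 stream with Box-Muller normals
// ---------------------------------------------------------------------------

struct Rng {
  uint64_t s;
  bool has_spare;
  double spare;
  explicit Rng(uint64_t seed) : s(seed), has_spare(false), spare(0.0) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1;
    do { u1 = unif(); } while (u1 <= 0.0);
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// Pose and frames
// ---------------------------------------------------------------------------

struct Pose {
  double fx, fy, nx, ny, cb, sb; // fovea, neck, cos/sin of bearing
  void set(double fx_, double fy_, double nx_, double ny_) {
    fx = fx_; fy = fy_; nx = nx_; ny = ny_;
    double bx = fx - nx, by = fy - ny;
    double n = std::sqrt(bx * bx + by * by);
    cb = bx / n; sb = by / n;
  }
  inline void w_from_h(double hx, double hy, double &wx, double &wy) const {
    wx = fx + cb * hx - sb * hy;
    wy = fy + sb * hx + cb * hy;
  }
  inline void h_from_w(double wx, double wy, double &hx, double &hy) const {
    double dx = wx - fx, dy = wy - fy;
    hx = cb * dx + sb * dy;
    hy = -sb * dx + cb * dy;
  }
  double bearing() const { return std::atan2(sb, cb); }
};

static Pose pose_from_vec(NumericVector v) {
  Pose p;
  p.set(v[0], v[1], v[2], v[3]);
  return p;
}

// ---------------------------------------------------------------------------
// Obstacles (oriented rectangles)
// ---------------------------------------------------------------------------

struct Obst {
  double cx, cy, hx, hy, ca, sa, circ;
};

static std::vector<Obst> parse_obstacles(NumericMatrix m) {
  // columns: cx, cy, hx, hy, angle_rad
  std::vector<Obst> out;
  for (int i = 0; i < m.nrow(); ++i) {
    Obst o;
    o.cx = m(i, 0); o.cy = m(i, 1);
    o.hx = m(i, 2); o.hy = m(i, 3);
    o.ca = std::cos(m(i, 4)); o.sa = std::sin(m(i, 4));
    o.circ = std::sqrt(o.hx * o.hx + o.hy * o.hy);
    out.push_back(o);
  }
  return out;
}

// penetration depth (> 0 strictly inside, 0 otherwise)
static inline double obs_depth(const Obst &o, double px, double py) {
  double dx = px - o.cx, dy = py - o.cy;
  double qx = o.ca * dx + o.sa * dy;
  double qy = -o.sa * dx + o.ca * dy;
  double ex = o.hx - std::fabs(qx);
  double ey = o.hy - std::fabs(qy);
  if (ex > 0.0 && ey > 0.0) return std::min(ex, ey);
  return 0.0;
}

// distance to the rectangle (0 if inside)
static inline double obs_dist(const Obst &o, double px, double py) {
  double dx = px - o.cx, dy = py - o.cy;
  double qx = o.ca * dx + o.sa * dy;
  double qy = -o.sa * dx + o.ca * dy;
  double ox = std::fabs(qx) - o.hx;
  double oy = std::fabs(qy) - o.hy;
  double ax = std::max(ox, 0.0), ay = std::max(oy, 0.0);
  return std::sqrt(ax * ax + ay * ay);
}

// distance to the rectangle boundary (inside points return their depth)
static inline double obs_boundary_dist(const Obst &o, double px, double py) {
  double d = obs_depth(o, px, py);
  if (d > 0.0) return d;
  return obs_dist(o, px, py);
}

// does the open segment a->b cross the rectangle interior?
static inline bool seg_crosses(const Obst &o, double ax, double ay,
                               double bx, double by) {
  double dxa = ax - o.cx, dya = ay - o.cy;
  double pax = o.ca * dxa + o.sa * dya, pay = -o.sa * dxa + o.ca * dya;
  double dxb = bx - o.cx, dyb = by - o.cy;
  double pbx = o.ca * dxb + o.sa * dyb, pby = -o.sa * dxb + o.ca * dyb;
  double dx = pbx - pax, dy = pby - pay;
  double tmin = 0.0, tmax = 1.0;
  // x slab
  if (std::fabs(dx) < 1e-12) {
    if (std::fabs(pax) > o.hx) return false;
  } else {
    double t1 = (-o.hx - pax) / dx, t2 = (o.hx - pax) / dx;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
    if (tmin > tmax) return false;
  }
  // y slab
  if (std::fabs(dy) < 1e-12) {
    if (std::fabs(pay) > o.hy) return false;
  } else {
    double t1 = (-o.hy - pay) / dy, t2 = (o.hy - pay) / dy;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
    if (tmin > tmax) return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// Whisker arcs and quasistatic bending
// ---------------------------------------------------------------------------

struct Whisk {
  int side;         // +1 left, -1 right
  double bx, by;    // base, head frame
  double L, kappa;  // length (mm), rest curvature (1/mm, rostral positive)
  double gain, nom, amp;
};

static std::vector<Whisk> parse_whiskers(NumericMatrix m) {
  // columns: side, bx, by, L, kappa, gain, nom, amp
  std::vector<Whisk> out;
  for (int i = 0; i < m.nrow(); ++i) {
    Whisk w;
    w.side = (int)m(i, 0);
    w.bx = m(i, 1); w.by = m(i, 2);
    w.L = m(i, 3); w.kappa = m(i, 4);
    w.gain = m(i, 5); w.nom = m(i, 6); w.amp = m(i, 7);
    out.push_back(w);
  }
  return out;
}

// standard-math heading of the shaft at the base, head frame, for
// protraction angle theta (radians, measured from caudal, increasing rostral)
static inline double shaft_heading(int side, double theta_rad) {
  return side > 0 ? (M_PI - theta_rad) : (theta_rad - M_PI);
}

// standard-math signed curvature from the rostral-positive convention
static inline double std_curvature(int side, double kappa) {
  return side > 0 ? -kappa : kappa;
}

// point at arc length s on a constant-curvature arc
static inline void arc_pt(double bx, double by, double phi, double k,
                          double s, double &px, double &py) {
  if (std::fabs(k) < 1e-12) {
    px = bx + s * std::cos(phi);
    py = by + s * std::sin(phi);
  } else {
    double a0 = phi, a1 = phi + k * s;
    px = bx + (std::sin(a1) - std::sin(a0)) / k;
    py = by - (std::cos(a1) - std::cos(a0)) / k;
  }
}

// max penetration of the arc into candidate obstacles; worst = obstacle index
static double arc_penetration(double bx, double by, double phi, double k,
                              double L, const std::vector<Obst> &obs,
                              const std::vector<int> &cand, int *worst) {
  int n = (int)std::ceil(L / ARC_STEP);
  if (n < 1) n = 1;
  double best = 0.0;
  if (worst) *worst = -1;
  for (int j = 0; j <= n; ++j) {
    double s = L * (double)j / (double)n;
    double px, py;
    arc_pt(bx, by, phi, k, s, px, py);
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      double d = obs_depth(obs[cand[ci]], px, py);
      if (d > best) {
        best = d;
        if (worst) *worst = cand[ci];
      }
    }
  }
  return best;
}

struct BendOut {
  double kappa_p;   // perturbed curvature, rostral-positive convention
  double delta;     // deviation at arc length d from base (mm)
  double csig;      // saturated contact signal in [0, 1]
  bool contact;
  double cpx, cpy;  // contact point, world
  bool clamped;
};

static BendOut bend_one(const Whisk &w, double theta_deg, const Pose &pose,
                        const std::vector<Obst> &obs, double d_meas) {
  BendOut out;
  out.kappa_p = w.kappa;
  out.delta = 0.0; out.csig = 0.0;
  out.contact = false; out.clamped = false;
  out.cpx = NA_REAL; out.cpy = NA_REAL;
  if (obs.empty()) return out;

  double bwx, bwy;
  pose.w_from_h(w.bx, w.by, bwx, bwy);
  std::vector<int> cand;
  for (size_t i = 0; i < obs.size(); ++i) {
    double dx = bwx - obs[i].cx, dy = bwy - obs[i].cy;
    if (std::sqrt(dx * dx + dy * dy) <= w.L + obs[i].circ + 1.0)
      cand.push_back((int)i);
  }
  if (cand.empty()) return out;

  double theta = theta_deg * DEG;
  double phi = shaft_heading(w.side, theta) + pose.bearing();
  double k0 = std_curvature(w.side, w.kappa);
  // caudal adjustment dk moves the standard curvature by +dk on the left
  // side and -dk on the right side
  double ks = w.side > 0 ? 1.0 : -1.0;

  int worst0 = -1;
  double pen0 = arc_penetration(bwx, bwy, phi, k0, w.L, obs, cand, &worst0);
  if (pen0 <= 0.0) return out;

  out.contact = true;
  int constraining = worst0;
  double lo = 0.0, hi = DK_MAX;
  int worst_hi = -1;
  double pen_hi = arc_penetration(bwx, bwy, phi, k0 + ks * hi, w.L, obs,
                                  cand, &worst_hi);
  double dk;
  if (pen_hi > 0.0) {
    out.clamped = true;
    dk = DK_MAX;
    constraining = worst_hi;
  } else {
    while (hi - lo > DK_TOL) {
      double mid = 0.5 * (lo + hi);
      int worst_mid = -1;
      double pen = arc_penetration(bwx, bwy, phi, k0 + ks * mid, w.L, obs,
                                   cand, &worst_mid);
      if (pen > 0.0) {
        lo = mid;
        constraining = worst_mid;
      } else {
        hi = mid;
      }
    }
    dk = hi; // non-penetrating side of the bracket
  }

  double kp = k0 + ks * dk;
  out.kappa_p = w.kappa - dk; // back to the rostral-positive convention

  // deviation of the point at arc length d_meas
  double s = std::min(d_meas, w.L);
  double ux, uy, px, py;
  arc_pt(bwx, bwy, phi, k0, s, ux, uy);
  arc_pt(bwx, bwy, phi, kp, s, px, py);
  double ddx = px - ux, ddy = py - uy;
  out.delta = std::sqrt(ddx * ddx + ddy * ddy);
  out.csig = std::tanh(w.gain * out.delta);

  // contact point: perturbed-arc point nearest the constraining obstacle
  int n = (int)std::ceil(w.L / ARC_STEP);
  double bestd = R_PosInf;
  for (int j = 0; j <= n; ++j) {
    double ss = w.L * (double)j / (double)n;
    double qx, qy;
    arc_pt(bwx, bwy, phi, kp, ss, qx, qy);
    double d = obs_boundary_dist(obs[constraining], qx, qy);
    if (d < bestd) {
      bestd = d;
      out.cpx = qx; out.cpy = qy;
    }
  }
  return out;
}

// measured shaft angle: base angle plus the chord offset to the point two
// thirds along the (possibly perturbed) shaft; chord of a circular arc of
// curvature k subtends k*s/2 at the base
static inline double measured_angle_cpp(double theta_deg, double kappa_p,
                                        double L) {
  return theta_deg + (kappa_p * L / 3.0) / DEG;
}

// ---------------------------------------------------------------------------
// Head-centric field grid
// ---------------------------------------------------------------------------

struct Grid {
  int nx, ny;
  double res;
  double x0, y0;
  Grid(double res_) : res(res_), x0(-20.0), y0(-60.0) {
    nx = (int)std::lround(80.0 / res_);
    ny = (int)std::lround(120.0 / res_);
  }
  inline double cx(int ix) const { return x0 + (ix + 0.5) * res; }
  inline double cy(int iy) const { return y0 + (iy + 0.5) * res; }
  inline int idx(int ix, int iy) const { return ix + nx * iy; }
  int ncell() const { return nx * ny; }
};

typedef std::vector<double> Field;

static void add_blob(Field &f, const Grid &g, double px, double py,
                     double amp, double sigma, bool ignore_outside) {
  if (ignore_outside) {
    if (px < g.x0 || px > g.x0 + g.nx * g.res ||
        py < g.y0 || py > g.y0 + g.ny * g.res)
      return;
  }
  double r = BLOB_CUT * sigma;
  int ix0 = std::max(0, (int)std::floor((px - r - g.x0) / g.res - 0.5));
  int ix1 = std::min(g.nx - 1, (int)std::ceil((px + r - g.x0) / g.res - 0.5));
  int iy0 = std::max(0, (int)std::floor((py - r - g.y0) / g.res - 0.5));
  int iy1 = std::min(g.ny - 1, (int)std::ceil((py + r - g.y0) / g.res - 0.5));
  double inv = 1.0 / (2.0 * sigma * sigma);
  for (int iy = iy0; iy <= iy1; ++iy) {
    double dy = g.cy(iy) - py;
    for (int ix = ix0; ix <= ix1; ++ix) {
      double dx = g.cx(ix) - px;
      f[g.idx(ix, iy)] += amp * std::exp(-(dx * dx + dy * dy) * inv);
    }
  }
}

// rigid remap: value at head-frame x in the new pose estimates the value at
// the same world location under the old pose (bilinear, zero outside)
static void warp_field(const Field &src, Field &dst, const Grid &g,
                       const Pose &pold, const Pose &pnew) {
  double ca = pold.cb * pnew.cb + pold.sb * pnew.sb;  // cos(b_new - b_old)
  double sa = pold.cb * pnew.sb - pold.sb * pnew.cb;  // sin(b_new - b_old)
  double tx, ty;
  pold.h_from_w(pnew.fx, pnew.fy, tx, ty);
  for (int iy = 0; iy < g.ny; ++iy) {
    double hy = g.cy(iy);
    for (int ix = 0; ix < g.nx; ++ix) {
      double hx = g.cx(ix);
      double ox = ca * hx - sa * hy + tx;
      double oy = sa * hx + ca * hy + ty;
      double u = (ox - g.x0) / g.res - 0.5;
      double v = (oy - g.y0) / g.res - 0.5;
      int i0 = (int)std::floor(u), j0 = (int)std::floor(v);
      double fu = u - i0, fv = v - j0;
      double acc = 0.0;
      for (int dj = 0; dj <= 1; ++dj) {
        int j = j0 + dj;
        if (j < 0 || j >= g.ny) continue;
        double wv = dj ? fv : 1.0 - fv;
        for (int di = 0; di <= 1; ++di) {
          int i = i0 + di;
          if (i < 0 || i >= g.nx) continue;
          double wu = di ? fu : 1.0 - fu;
          acc += wu * wv * src[g.idx(i, j)];
        }
      }
      dst[g.idx(ix, iy)] = acc;
    }
  }
}

// obstacle inhibition: 1 inside an obstacle or when the fovea-to-cell
// segment crosses an obstacle interior (shadowing), else 0
static void shadow_field(Field &f, const Grid &g, const Pose &pose,
                         const std::vector<Obst> &obs) {
  for (int iy = 0; iy < g.ny; ++iy) {
    for (int ix = 0; ix < g.nx; ++ix) {
      double wx, wy;
      pose.w_from_h(g.cx(ix), g.cy(iy), wx, wy);
      double val = 0.0;
      for (size_t k = 0; k < obs.size(); ++k) {
        if (obs_depth(obs[k], wx, wy) > 0.0 ||
            seg_crosses(obs[k], pose.fx, pose.fy, wx, wy)) {
          val = 1.0;
          break;
        }
      }
      f[g.idx(ix, iy)] = val;
    }
  }
}

static void ior_field_fill(Field &f, const Grid &g, const Pose &pose,
                           const std::vector<double> &vx,
                           const std::vector<double> &vy,
                           double sigma, double gain) {
  std::fill(f.begin(), f.end(), 0.0);
  for (size_t k = 0; k < vx.size(); ++k) {
    double hx, hy;
    pose.h_from_w(vx[k], vy[k], hx, hy);
    add_blob(f, g, hx, hy, gain, sigma, false);
  }
}

// mirror-paired accumulation of the arbitrated protraction angle (Eq. 6
// style weighted sum); W2 holds the caudal-bias weights, P the proposals
static void theta_hat_all(const Field &S, const Grid &g, NumericMatrix &W2,
                          NumericMatrix &P, double ag, double ae,
                          const std::vector<Whisk> &wh, bool flip,
                          std::vector<double> &out) {
  int ncell = g.ncell();
  std::vector<double> u(ncell);
  bool sq = std::fabs(ae - 2.0) < 1e-12;
  for (int e = 0; e < ncell; ++e) {
    int src = e;
    if (flip) {
      int ix = e % g.nx, iy = e / g.nx;
      src = g.idx(ix, g.ny - 1 - iy);
    }
    double a = ag * S[src];
    u[e] = sq ? a * a : std::pow(a, ae);
  }
  int half = g.ny / 2;
  for (size_t j = 0; j < wh.size(); ++j) {
    double num = 0.0, den = 0.0;
    for (int iy = 0; iy < half; ++iy) {
      for (int ix = 0; ix < g.nx; ++ix) {
        int e1 = g.idx(ix, iy);
        int e2 = g.idx(ix, g.ny - 1 - iy);
        double w1 = u[e1] * W2(e1, j);
        double w2 = u[e2] * W2(e2, j);
        num += (w1 * P(e1, j) + w2 * P(e2, j));
        den += (w1 + w2);
      }
    }
    if (g.ny % 2) { // odd grids: middle row is its own mirror
      int iy = half;
      for (int ix = 0; ix < g.nx; ++ix) {
        int e = g.idx(ix, iy);
        double w = u[e] * W2(e, j);
        num += w * P(e, j);
        den += w;
      }
    }
    out[j] = den > 0.0 ? num / den : wh[j].nom;
  }
}

// mirror-paired max and mean
static void field_max_mean(const Field &f, const Grid &g, double &mx,
                           double &mn) {
  mx = 0.0;
  double acc = 0.0;
  int half = g.ny / 2;
  for (int iy = 0; iy < half; ++iy) {
    for (int ix = 0; ix < g.nx; ++ix) {
      double a = f[g.idx(ix, iy)];
      double b = f[g.idx(ix, g.ny - 1 - iy)];
      acc += (a + b);
      if (a > mx) mx = a;
      if (b > mx) mx = b;
    }
  }
  if (g.ny % 2) {
    for (int ix = 0; ix < g.nx; ++ix) {
      double a = f[g.idx(ix, half)];
      acc += a;
      if (a > mx) mx = a;
    }
  }
  mn = acc / (double)g.ncell();
}

// ---------------------------------------------------------------------------
// Standalone kernel wrappers (module-level operations)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix arc_points_cpp(double bx, double by, int side, double theta_deg,
                             double kappa, double L, double step) {
  if (step <= 0.0) stop("step must be positive");
  double phi = shaft_heading(side, theta_deg * DEG);
  double k = std_curvature(side, kappa);
  int n = (int)std::ceil(L / step);
  if (n < 1) n = 1;
  NumericMatrix out(n + 1, 2);
  for (int j = 0; j <= n; ++j) {
    double s = L * (double)j / (double)n;
    double px, py;
    arc_pt(bx, by, phi, k, s, px, py);
    out(j, 0) = px;
    out(j, 1) = py;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix bend_whiskers_cpp(NumericMatrix whiskers, NumericVector theta_deg,
                                NumericVector pose4, NumericMatrix obstacles,
                                double d_meas) {
  std::vector<Whisk> wh = parse_whiskers(whiskers);
  std::vector<Obst> obs = parse_obstacles(obstacles);
  Pose pose = pose_from_vec(pose4);
  int n = (int)wh.size();
  NumericMatrix out(n, 8);
  colnames(out) = CharacterVector::create("kappa_p", "delta", "contact_signal",
                                          "contact", "contact_x", "contact_y",
                                          "clamped", "theta_meas");
  for (int i = 0; i < n; ++i) {
    BendOut b = bend_one(wh[i], theta_deg[i], pose, obs, d_meas);
    out(i, 0) = b.kappa_p;
    out(i, 1) = b.delta;
    out(i, 2) = b.csig;
    out(i, 3) = b.contact ? 1.0 : 0.0;
    out(i, 4) = b.cpx;
    out(i, 5) = b.cpy;
    out(i, 6) = b.clamped ? 1.0 : 0.0;
    out(i, 7) = measured_angle_cpp(theta_deg[i], b.kappa_p, wh[i].L);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix warp_field_cpp(NumericMatrix f, double res,
                             NumericVector pose_old4, NumericVector pose_new4) {
  Grid g(res);
  if (f.nrow() != g.nx || f.ncol() != g.ny) stop("field has wrong shape");
  Field src(f.begin(), f.end()), dst(g.ncell(), 0.0);
  warp_field(src, dst, g, pose_from_vec(pose_old4), pose_from_vec(pose_new4));
  NumericMatrix out(g.nx, g.ny);
  std::copy(dst.begin(), dst.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericMatrix blob_field_cpp(NumericMatrix f, double res, NumericMatrix pts,
                             NumericVector amps, double sigma,
                             bool ignore_outside) {
  Grid g(res);
  if (f.nrow() != g.nx || f.ncol() != g.ny) stop("field has wrong shape");
  Field acc(f.begin(), f.end());
  for (int i = 0; i < pts.nrow(); ++i)
    add_blob(acc, g, pts(i, 0), pts(i, 1), amps[i], sigma, ignore_outside);
  NumericMatrix out(g.nx, g.ny);
  std::copy(acc.begin(), acc.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericMatrix shadow_field_cpp(double res, NumericVector pose4,
                               NumericMatrix obstacles) {
  Grid g(res);
  std::vector<Obst> obs = parse_obstacles(obstacles);
  Field f(g.ncell(), 0.0);
  shadow_field(f, g, pose_from_vec(pose4), obs);
  NumericMatrix out(g.nx, g.ny);
  std::copy(f.begin(), f.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericMatrix ior_field_cpp(double res, NumericVector pose4,
                            NumericMatrix pts_world, double sigma,
                            double gain) {
  Grid g(res);
  Field f(g.ncell(), 0.0);
  std::vector<double> vx, vy;
  for (int i = 0; i < pts_world.nrow(); ++i) {
    vx.push_back(pts_world(i, 0));
    vy.push_back(pts_world(i, 1));
  }
  ior_field_fill(f, g, pose_from_vec(pose4), vx, vy, sigma, gain);
  NumericMatrix out(g.nx, g.ny);
  std::copy(f.begin(), f.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector theta_hat_cpp(NumericMatrix S, NumericMatrix W2, NumericMatrix P,
                            double activity_gain, double activity_exponent,
                            NumericVector nom, double res) {
  Grid g(res);
  if (S.nrow() != g.nx || S.ncol() != g.ny) stop("field has wrong shape");
  Field s(S.begin(), S.end());
  std::vector<Whisk> wh(nom.size());
  for (int i = 0; i < nom.size(); ++i) wh[i].nom = nom[i];
  std::vector<double> out(nom.size());
  theta_hat_all(s, g, W2, P, activity_gain, activity_exponent, wh, false, out);
  return wrap(out);
}

// [[Rcpp::export]]
NumericMatrix obstacle_distance_cpp(NumericMatrix pts, NumericMatrix obstacles) {
  std::vector<Obst> obs = parse_obstacles(obstacles);
  NumericMatrix out(pts.nrow(), (int)obs.size());
  for (int i = 0; i < pts.nrow(); ++i)
    for (size_t k = 0; k < obs.size(); ++k)
      out(i, k) = obs_dist(obs[k], pts(i, 0), pts(i, 1));
  return out;
}

// ---------------------------------------------------------------------------
// Full simulation loop
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sim_run_cpp(List par, NumericMatrix whiskers, NumericMatrix obstacles,
                 NumericMatrix P, NumericMatrix W2, double duration,
                 double seed, NumericVector init_pose, int head_mode,
                 NumericVector head_dir, double head_speed, bool flip_noise,
                 bool flip_attention, int log_mode) {
  // parameters
  double res = as<double>(par["grid_resolution"]);
  double dt = as<double>(par["sample_dt"]);
  double T_osc = as<double>(par["oscillator_period"]);
  double sep = as<double>(par["fovea_neck_sep"]);
  double d_meas = as<double>(par["deformation_dist"]);
  double sig_t = as<double>(par["tactile_blob_width"]) / 2.0;
  double sig_o = as<double>(par["other_blob_width"]) / 2.0;
  double other_gain = as<double>(par["other_gain"]);
  double noise_gain = as<double>(par["noise_gain"]);
  double noise_bw = as<double>(par["noise_bandwidth"]);
  double T_ior = as<double>(par["ior_memory"]);
  double sig_i = as<double>(par["ior_width"]) / 2.0;
  double ior_gain = as<double>(par["ior_gain"]);
  double ior_max = as<double>(par["ior_max"]);
  double T_fov = as<double>(par["foveation_period"]);
  double ag = as<double>(par["activity_gain"]);
  double ae = as<double>(par["activity_exponent"]);
  double gamma = as<double>(par["modulation_strength"]);
  double duty = as<double>(par["duty_cycle"]);
  double tau_w = as<double>(par["whisk_tau"]);
  double lam = as<double>(par["excitation_decay"]);

  Grid g(res);
  int ncell = g.ncell();
  if (P.nrow() != ncell || W2.nrow() != ncell)
    stop("proposal tables have wrong shape");
  std::vector<Whisk> wh = parse_whiskers(whiskers);
  std::vector<Obst> obs = parse_obstacles(obstacles);
  int nw = (int)wh.size();
  if (P.ncol() != nw) stop("proposal tables have wrong number of whiskers");

  // RNG streams: tactile noise, other noise, other-target location
  Rng master((uint64_t)seed);
  Rng rng_nt(master.next_u64());
  Rng rng_no(master.next_u64());
  Rng rng_tg(master.next_u64());

  double a_ar = std::exp(-2.0 * M_PI * noise_bw * dt);
  double s_ar = std::sqrt(1.0 - a_ar * a_ar);

  // state
  Pose pose = pose_from_vec(init_pose);
  Pose pose_prev = pose;
  double f0x = pose.fx, f0y = pose.fy;
  Field E_t(ncell, 0.0), E_o(ncell, 0.0);
  Field I_t(ncell, 0.0), I_o(ncell, 0.0);
  Field H_obs(ncell, 0.0), H_ior(ncell, 0.0), H(ncell, 0.0);
  Field S_t(ncell, 0.0), S_o(ncell, 0.0);
  Field tmp(ncell, 0.0), tmpL(ncell, 0.0), tmpR(ncell, 0.0);
  Field n_t(ncell, 0.0), n_o(ncell, 0.0);
  std::vector<double> zbuf(ncell);

  // stationary start for the coloured noise
  for (int k = 0; k < 2; ++k) {
    Rng &r = k == 0 ? rng_nt : rng_no;
    Field &nf = k == 0 ? n_t : n_o;
    for (int e = 0; e < ncell; ++e) zbuf[e] = r.norm();
    for (int iy = 0; iy < g.ny; ++iy) {
      int src_iy = flip_noise ? (g.ny - 1 - iy) : iy;
      for (int ix = 0; ix < g.nx; ++ix)
        nf[g.idx(ix, iy)] = zbuf[g.idx(ix, src_iy)];
    }
  }

  std::vector<double> theta(nw), theta_hat(nw), theta_max(nw);
  for (int i = 0; i < nw; ++i) theta[i] = wh[i].nom;

  std::vector<double> ior_x, ior_y, ior_t;
  int channel = 1; // 0 tactile, 1 other
  double plan_sx = pose.fx, plan_sy = pose.fy;
  double plan_tx = pose.fx, plan_ty = pose.fy;
  double plan_t0 = 0.0;

  int nsamp = (int)std::llround(duration / dt) + 1;
  long prev_cycle = -1;

  // logs
  NumericVector Lt(nsamp), Lfx(nsamp), Lfy(nsamp), Lnx(nsamp), Lny(nsamp),
      Lbear(nsamp), Ltick(nsamp), Lq(nsamp), Lchan(nsamp), Lclamp(nsamp),
      Ltgx(nsamp), Ltgy(nsamp), Lcontrast(nsamp);
  bool full = (log_mode == 0);
  NumericMatrix Ltb(full ? nsamp : 1, nw), Ltm(full ? nsamp : 1, nw),
      Ltmx(full ? nsamp : 1, nw), Lc(full ? nsamp : 1, nw),
      Lcx(full ? nsamp : 1, nw), Lcy(full ? nsamp : 1, nw);
  NumericVector Lmbl(nsamp), Lmbr(nsamp), Lmml(nsamp), Lmmr(nsamp),
      Lncl(nsamp), Lncr(nsamp);

  std::vector<BendOut> bends(nw);

  for (int i = 0; i < nsamp; ++i) {
    double t = i * dt;

    // (1) oscillator
    long cyc = (long)std::floor(t / T_osc + 1e-9);
    bool tick = (cyc > prev_cycle);
    prev_cycle = cyc;
    double phase = t / T_osc - (double)cyc;
    int q = phase >= (1.0 - duty) - 1e-9 ? 1 : 0;

    // (2) bending and contact at current angles and pose
    bool any_clamp = false;
    for (int j = 0; j < nw; ++j) {
      bends[j] = bend_one(wh[j], theta[j], pose, obs, d_meas);
      if (bends[j].clamped) any_clamp = true;
    }

    // (3) input maps and excitation updates
    // tactile input: per-side accumulation keeps the blob sum order
    // symmetric under a mirrored world
    std::fill(tmpL.begin(), tmpL.end(), 0.0);
    std::fill(tmpR.begin(), tmpR.end(), 0.0);
    for (int j = 0; j < nw; ++j) {
      if (bends[j].contact && bends[j].csig > 0.0) {
        double hx, hy;
        pose.h_from_w(bends[j].cpx, bends[j].cpy, hx, hy);
        add_blob(wh[j].side > 0 ? tmpL : tmpR, g, hx, hy, bends[j].csig,
                 sig_t, true);
      }
    }
    for (int e = 0; e < ncell; ++e)
      I_t[e] = std::min(1.0, tmpL[e] + tmpR[e]);

    std::fill(I_o.begin(), I_o.end(), 0.0);
    if (tick) {
      double u1 = rng_tg.unif(), u2 = rng_tg.unif();
      double px = g.x0 + g.nx * g.res * u1;
      double py = g.y0 + g.ny * g.res * u2;
      if (flip_noise) py = -py;
      add_blob(I_o, g, px, py, other_gain, sig_o, true);
      for (int e = 0; e < ncell; ++e) I_o[e] = std::min(1.0, I_o[e]);
    }

    // coloured noise update
    for (int k = 0; k < 2; ++k) {
      Rng &r = k == 0 ? rng_nt : rng_no;
      Field &nf = k == 0 ? n_t : n_o;
      for (int e = 0; e < ncell; ++e) zbuf[e] = r.norm();
      for (int iy = 0; iy < g.ny; ++iy) {
        int src_iy = flip_noise ? (g.ny - 1 - iy) : iy;
        for (int ix = 0; ix < g.nx; ++ix) {
          int e = g.idx(ix, iy);
          nf[e] = a_ar * nf[e] + s_ar * zbuf[g.idx(ix, src_iy)];
        }
      }
    }

    // leaky-max excitation updates with remap of the previous sample's state
    for (int k = 0; k < 2; ++k) {
      Field &E = k == 0 ? E_t : E_o;
      Field &I = k == 0 ? I_t : I_o;
      if (i == 0) {
        std::copy(E.begin(), E.end(), tmp.begin());
      } else {
        warp_field(E, tmp, g, pose_prev, pose);
      }
      for (int e = 0; e < ncell; ++e) {
        double v = std::max(lam * tmp[e], I[e]);
        E[e] = std::min(1.0, std::max(0.0, v));
      }
    }

    // (4) IOR memory update at ticks
    if (tick) {
      ior_x.push_back(pose.fx);
      ior_y.push_back(pose.fy);
      ior_t.push_back(t);
      size_t keep = 0;
      for (size_t k = 0; k < ior_t.size(); ++k) {
        if (t - ior_t[k] <= T_ior) {
          ior_x[keep] = ior_x[k];
          ior_y[keep] = ior_y[k];
          ior_t[keep] = ior_t[k];
          ++keep;
        }
      }
      ior_x.resize(keep); ior_y.resize(keep); ior_t.resize(keep);
    }

    // (5) inhibition and salience (every sample: protraction control is
    // instantaneous)
    if (!obs.empty()) {
      shadow_field(H_obs, g, pose, obs);
    }
    ior_field_fill(H_ior, g, pose, ior_x, ior_y, sig_i, ior_gain);
    for (int e = 0; e < ncell; ++e) {
      double h = H_obs[e] + std::min(H_ior[e], ior_max);
      H[e] = std::min(1.0, h);
      double et = std::min(1.0, std::max(0.0, E_t[e] + noise_gain * n_t[e]));
      double eo = std::min(1.0, std::max(0.0, E_o[e] + noise_gain * n_o[e]));
      S_t[e] = et * (1.0 - H[e]);
      S_o[e] = eo * (1.0 - H[e]);
    }

    double mx_t, mn_t, mx_o, mn_o;
    field_max_mean(S_t, g, mx_t, mn_t);
    field_max_mean(S_o, g, mx_o, mn_o);

    // channel re-selection and foveation planning at ticks
    if (tick) {
      if (mx_t > mx_o) channel = 0;
      else if (mx_o > mx_t) channel = 1;
      // tie: keep previous channel
      if (head_mode == 0) {
        const Field &S = channel == 0 ? S_t : S_o;
        double mx = channel == 0 ? mx_t : mx_o;
        double tgx = pose.fx, tgy = pose.fy;
        if (mx > 0.0) {
          double bestd = R_PosInf;
          int best = -1;
          for (int e = 0; e < ncell; ++e) {
            if (S[e] == mx) {
              int ix = e % g.nx, iy = e / g.nx;
              double wx, wy;
              pose.w_from_h(g.cx(ix), g.cy(iy), wx, wy);
              double dx = wx - pose.fx, dy = wy - pose.fy;
              double d = dx * dx + dy * dy;
              if (best < 0 || d < bestd) {
                bestd = d;
                best = e;
                tgx = wx; tgy = wy;
              }
            }
          }
        }
        plan_sx = pose.fx; plan_sy = pose.fy;
        plan_tx = tgx; plan_ty = tgy;
        plan_t0 = t;
      }
    }

    // (6) whisker control: salience-to-protraction transform
    const Field &S_sel = channel == 0 ? S_t : S_o;
    double C = channel == 0 ? mx_t - mn_t : mx_o - mn_o;
    C = std::min(1.0, std::max(0.0, C));
    theta_hat_all(S_sel, g, W2, P, ag, ae, wh, flip_attention, theta_hat);

    double mbl = 0.0, mbr = 0.0, mml = 0.0, mmr = 0.0;
    int nl = 0, nr = 0, ncl = 0, ncr = 0;
    for (int j = 0; j < nw; ++j) {
      theta_max[j] = wh[j].nom + gamma * C * (theta_hat[j] - wh[j].nom);
      double tmeas = measured_angle_cpp(theta[j], bends[j].kappa_p, wh[j].L);
      if (full) {
        Ltb(i, j) = theta[j];
        Ltm(i, j) = tmeas;
        Ltmx(i, j) = theta_max[j];
        Lc(i, j) = bends[j].csig;
        Lcx(i, j) = bends[j].cpx;
        Lcy(i, j) = bends[j].cpy;
      }
      if (wh[j].side > 0) {
        mbl += theta[j]; mml += tmeas; ++nl;
        if (bends[j].csig > 0.0) ++ncl;
      } else {
        mbr += theta[j]; mmr += tmeas; ++nr;
        if (bends[j].csig > 0.0) ++ncr;
      }
    }
    Lmbl[i] = mbl / nl; Lmbr[i] = mbr / nr;
    Lmml[i] = mml / nl; Lmmr[i] = mmr / nr;
    Lncl[i] = ncl; Lncr[i] = ncr;

    // core log row (state at time t)
    Lt[i] = t;
    Lfx[i] = pose.fx; Lfy[i] = pose.fy;
    Lnx[i] = pose.nx; Lny[i] = pose.ny;
    Lbear[i] = pose.bearing() / DEG;
    Ltick[i] = tick ? 1.0 : 0.0;
    Lq[i] = q;
    Lchan[i] = channel;
    Lclamp[i] = any_clamp ? 1.0 : 0.0;
    Ltgx[i] = plan_tx; Ltgy[i] = plan_ty;
    Lcontrast[i] = C;

    // whisking drive towards the instantaneous target angle
    for (int j = 0; j < nw; ++j) {
      double target = q ? theta_max[j] : theta_max[j] - wh[j].amp;
      theta[j] += (dt / tau_w) * (target - theta[j]);
    }

    // (7) head advance to the next sample's pose
    if (i + 1 < nsamp) {
      double tn = (i + 1) * dt;
      double nfx, nfy;
      if (head_mode == 1) {
        nfx = f0x + head_dir[0] * head_speed * tn;
        nfy = f0y + head_dir[1] * head_speed * tn;
      } else {
        double tau = (tn - plan_t0) / T_fov;
        tau = std::min(1.0, std::max(0.0, tau));
        double sc = tau * tau * tau * (10.0 + tau * (-15.0 + 6.0 * tau));
        nfx = plan_sx + (plan_tx - plan_sx) * sc;
        nfy = plan_sy + (plan_ty - plan_sy) * sc;
      }
      double dx = pose.nx - nfx, dy = pose.ny - nfy;
      double dn = std::sqrt(dx * dx + dy * dy);
      double nnx, nny;
      if (dn < 1e-12) {
        nnx = pose.nx; nny = pose.ny;
      } else {
        nnx = nfx + sep * dx / dn;
        nny = nfy + sep * dy / dn;
      }
      pose_prev = pose;
      pose.set(nfx, nfy, nnx, nny);
    }
  }

  List core = List::create(
      _["t"] = Lt, _["fovea_x"] = Lfx, _["fovea_y"] = Lfy, _["neck_x"] = Lnx,
      _["neck_y"] = Lny, _["bearing_deg"] = Lbear, _["tick"] = Ltick,
      _["q"] = Lq, _["channel"] = Lchan, _["clamped"] = Lclamp,
      _["target_x"] = Ltgx, _["target_y"] = Ltgy, _["contrast"] = Lcontrast,
      _["mean_base_l"] = Lmbl, _["mean_base_r"] = Lmbr,
      _["mean_meas_l"] = Lmml, _["mean_meas_r"] = Lmmr,
      _["n_contact_l"] = Lncl, _["n_contact_r"] = Lncr);
  List out = List::create(_["core"] = core);
  if (full) {
    out["theta_base"] = Ltb;
    out["theta_meas"] = Ltm;
    out["theta_max"] = Ltmx;
    out["contact"] = Lc;
    out["contact_x"] = Lcx;
    out["contact_y"] = Lcy;
  }
  // final fields, for debugging and field dumps
  NumericMatrix fSt(g.nx, g.ny), fSo(g.nx, g.ny), fH(g.nx, g.ny),
      fEt(g.nx, g.ny), fEo(g.nx, g.ny);
  std::copy(S_t.begin(), S_t.end(), fSt.begin());
  std::copy(S_o.begin(), S_o.end(), fSo.begin());
  std::copy(H.begin(), H.end(), fH.begin());
  std::copy(E_t.begin(), E_t.end(), fEt.begin());
  std::copy(E_o.begin(), E_o.end(), fEo.begin());
  out["fields"] = List::create(_["S_tactile"] = fSt, _["S_other"] = fSo,
                               _["H"] = fH, _["E_tactile"] = fEt,
                               _["E_other"] = fEo);
  return out;
}
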