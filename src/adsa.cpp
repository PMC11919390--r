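#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Young-Laplace arc integration (Bashforth-Adams form, apex origin)
//
// State from the apex: psi (inclination from horizontal, rad), r (radial
// coordinate), u (signed vertical coordinate, u = 0 at apex, u < 0 below it).
//   dpsi/ds = 2/R0 - u/lc^2 - sin(psi)/r      (sin(psi)/r -> 1/R0 at apex)
//   dr/ds   = cos(psi)
//   du/ds   = -sin(psi)
// Fixed-step classical RK4; the apex singularity is handled by the analytic
// limit of sin(psi)/r, which RK4 only needs at s = 0 exactly.
// ---------------------------------------------------------------------------

struct YLState { double psi, r, u; };

static inline void yl_deriv(const YLState& y, double R0, double inv_lc2,
                            double* d) {
  double sp_over_r;
  if (y.r < 1e-14) {
    sp_over_r = 1.0 / R0;
  } else {
    sp_over_r = std::sin(y.psi) / y.r;
  }
  d[0] = 2.0 / R0 - y.u * inv_lc2 - sp_over_r;
  d[1] = std::cos(y.psi);
  d[2] = -std::sin(y.psi);
}

static inline void rk4_step(YLState& y, double h, double R0, double inv_lc2) {
  double k1[3], k2[3], k3[3], k4[3];
  YLState t;
  yl_deriv(y, R0, inv_lc2, k1);
  t.psi = y.psi + 0.5 * h * k1[0];
  t.r = y.r + 0.5 * h * k1[1];
  t.u = y.u + 0.5 * h * k1[2];
  yl_deriv(t, R0, inv_lc2, k2);
  t.psi = y.psi + 0.5 * h * k2[0];
  t.r = y.r + 0.5 * h * k2[1];
  t.u = y.u + 0.5 * h * k2[2];
  yl_deriv(t, R0, inv_lc2, k3);
  t.psi = y.psi + h * k3[0];
  t.r = y.r + h * k3[1];
  t.u = y.u + h * k3[2];
  yl_deriv(t, R0, inv_lc2, k4);
  y.psi += h / 6.0 * (k1[0] + 2.0 * k2[0] + 2.0 * k3[0] + k4[0]);
  y.r += h / 6.0 * (k1[1] + 2.0 * k2[1] + 2.0 * k3[1] + k4[1]);
  y.u += h / 6.0 * (k1[2] + 2.0 * k2[2] + 2.0 * k3[2] + k4[2]);
}

// Integrate to smax, returning n_out states evenly spaced in s (first row is
// the apex).  min_steps caps the step at smax/min_steps.
// [[Rcpp::export]]
NumericMatrix yl_arc_cpp(double R0, double lc, double smax, int n_out,
                         int min_steps = 2000) {
  if (!(R0 > 0.0) || !(lc > 0.0) || !(smax > 0.0))
    stop("R0, lc and smax must all be positive");
  if (n_out < 2) stop("n_out must be >= 2");
  int sub = (int)std::ceil((double)min_steps / (double)(n_out - 1));
  if (sub < 1) sub = 1;
  double ds = smax / ((double)(n_out - 1) * sub);
  double inv_lc2 = 1.0 / (lc * lc);

  NumericMatrix out(n_out, 4);
  colnames(out) = CharacterVector::create("s", "psi", "r", "u");
  YLState y; y.psi = 0.0; y.r = 0.0; y.u = 0.0;
  out(0, 0) = 0.0; out(0, 1) = 0.0; out(0, 2) = 0.0; out(0, 3) = 0.0;
  double s = 0.0;
  for (int i = 1; i < n_out; ++i) {
    for (int j = 0; j < sub; ++j) {
      rk4_step(y, ds, R0, inv_lc2);
      s += ds;
      if (!std::isfinite(y.psi) || !std::isfinite(y.r) ||
          y.psi > M_PI + 1e-9 || y.r < -1e-9) {
        stop("Young-Laplace integration failed at s = %f "
             "(psi = %f rad, r = %f)", s, y.psi, y.r);
      }
    }
    out(i, 0) = s;
    out(i, 1) = y.psi;
    out(i, 2) = y.r;
    out(i, 3) = y.u;
  }
  return out;
}

// Minimum squared distance from each probe point to a set of trial points
// (exhaustive search; trial sets are ~1000 points so this is cheap and
// exactly reproducible).
// [[Rcpp::export]]
NumericVector nearest_sqdist_cpp(NumericVector px, NumericVector pz,
                                 NumericVector tx, NumericVector tz) {
  int n = px.size(), m = tx.size();
  if (pz.size() != n || tz.size() != m) stop("coordinate length mismatch");
  if (m == 0) stop("empty trial set");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double xi = px[i], zi = pz[i];
    for (int j = 0; j < m; ++j) {
      double dx = tx[j] - xi, dz = tz[j] - zi;
      double d = dx * dx + dz * dz;
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// Mean squared nearest-point distance between an observed profile and the
// trial points of an integrated Young-Laplace arc translated by z0.
// Returns -1.0 when the integration leaves the valid domain so optimizers
// can treat the parameter set as infeasible without an R-level exception.
// [[Rcpp::export]]
double yl_lambda_cpp(double R0, double lc, double z0, double smax,
                     NumericVector Rexp, NumericVector Zexp,
                     int n_trial = 1000, int min_steps = 2000) {
  if (!(R0 > 0.0) || !(lc > 0.0) || !(smax > 0.0)) return -1.0;
  int sub = (int)std::ceil((double)min_steps / (double)(n_trial - 1));
  if (sub < 1) sub = 1;
  double ds = smax / ((double)(n_trial - 1) * sub);
  double inv_lc2 = 1.0 / (lc * lc);

  std::vector<double> tr(n_trial), tz(n_trial);
  YLState y; y.psi = 0.0; y.r = 0.0; y.u = 0.0;
  tr[0] = 0.0; tz[0] = z0;
  for (int i = 1; i < n_trial; ++i) {
    for (int j = 0; j < sub; ++j) {
      rk4_step(y, ds, R0, inv_lc2);
      if (!std::isfinite(y.psi) || !std::isfinite(y.r) ||
          y.psi > M_PI + 1e-9 || y.r < -1e-9)
        return -1.0;
    }
    tr[i] = y.r;
    tz[i] = y.u + z0;
  }
  int n = Rexp.size();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double xi = Rexp[i], zi = Zexp[i];
    for (int j = 0; j < n_trial; ++j) {
      double dx = tr[j] - xi, dz = tz[j] - zi;
      double d = dx * dx + dz * dz;
      if (d < best) best = d;
    }
    acc += best;
  }
  return acc / (double)n;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a 3D logical array (dims = c(nz, ny, nx),
// column-major as stored by R).  connectivity 26 or 6.  Background = 0.
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity = 26) {
  if (dims.size() != 3) stop("dims must have length 3");
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 26 && connectivity != 6)
    stop("connectivity must be 6 or 26");

  std::vector<int> parent(n, -1);
  // first pass: union with already-visited neighbours (lower linear index)
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!mask[i]) continue;
        parent[i] = (int)i;
        for (int ddx = -1; ddx <= 0; ++ddx) {
          for (int ddy = -1; ddy <= 1; ++ddy) {
            for (int ddz = -1; ddz <= 1; ++ddz) {
              if (ddx == 0 && (ddy > 0 || (ddy == 0 && ddz >= 0))) continue;
              if (connectivity == 6 &&
                  std::abs(ddx) + std::abs(ddy) + std::abs(ddz) != 1)
                continue;
              int xx = x + ddx, yy = y + ddy, zz = z + ddz;
              if (xx < 0 || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
              R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
              if (!mask[j]) continue;
              int ri = uf_find(parent, (int)i);
              int rj = uf_find(parent, (int)j);
              if (ri != rj) parent[ri] = rj;
            }
          }
        }
      }
    }
  }
  // second pass: compact labels
  IntegerVector labels(n, 0);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (parent[i] < 0) continue;
    int r = uf_find(parent, (int)i);
    if (remap[r] == 0) remap[r] = ++next;
    labels[i] = remap[r];
  }
  return labels;
}

// ---------------------------------------------------------------------------
// Meridional ray tracer for confocal imaging of a spherical cap through an
// oil-immersion objective into aqueous buffer.
//
// Geometry (x lateral, z axial, all um): substrate plane at z = 0, cap =
// {z >= 0} intersected with the sphere of radius Rs centred at (0, zc).
// Immersion oil below z = 0 (coverslip treated as index-matched); buffer
// above except inside the cap (index n_cond).
//
// For each nominal focal position (x0, znom) a fan of rays uniform in pupil
// coordinate converges as it would in homogeneous oil, refracts by Snell's
// law at z = 0 (into buffer, or directly into the condensate beneath the
// cap) and again at the spherical cap surface.  The recorded intensity is
// the fraction of pairwise ray-ray crossing points (the caustic cloud that
// replaces the ideal focus) lying inside the fluorescent condensate.
// Everything is deterministic.
// ---------------------------------------------------------------------------

struct Seg { double x, z, dx, dz, len; };

static inline bool snell_plane(double n1, double n2, double sa, double* sb,
                               double* cb) {
  double s = n1 * sa / n2;
  if (std::fabs(s) >= 1.0) return false;
  *sb = s;
  *cb = std::sqrt(1.0 - s * s);
  return true;
}

// vector Snell at a surface with unit outward normal (nx, nz); d incident
// unit direction; returns false on total internal reflection
static inline bool snell_vec(double n1, double n2, double dx, double dz,
                             double nx, double nz, double* ox, double* oz) {
  double cosi = -(dx * nx + dz * nz);
  if (cosi < 0) { nx = -nx; nz = -nz; cosi = -cosi; }
  double eta = n1 / n2;
  double sin2t = eta * eta * (1.0 - cosi * cosi);
  if (sin2t > 1.0) return false;
  double k = eta * cosi - std::sqrt(1.0 - sin2t);
  *ox = eta * dx + k * nx;
  *oz = eta * dz + k * nz;
  double nrm = std::sqrt(*ox * *ox + *oz * *oz);
  *ox /= nrm; *oz /= nrm;
  return true;
}

// unpolarised Fresnel power transmittance for incidence/transmission
// cosines (both interfaces planar locally)
static inline double fresnel_T(double n1, double n2, double cosi,
                               double cost) {
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  double R = 0.5 * (rs * rs + rp * rp);
  return 1.0 - R;
}

// Snell refraction that also reports the energy transmittance
static inline bool snell_vec_T(double n1, double n2, double dx, double dz,
                               double nx, double nz, double* ox, double* oz,
                               double* T) {
  double cosi = -(dx * nx + dz * nz);
  if (cosi < 0) { nx = -nx; nz = -nz; cosi = -cosi; }
  double eta = n1 / n2;
  double sin2t = eta * eta * (1.0 - cosi * cosi);
  if (sin2t > 1.0) return false;
  double cost = std::sqrt(1.0 - sin2t);
  double k = eta * cosi - cost;
  *ox = eta * dx + k * nx;
  *oz = eta * dz + k * nz;
  double nrm = std::sqrt(*ox * *ox + *oz * *oz);
  *ox /= nrm; *oz /= nrm;
  *T = fresnel_T(n1, n2, cosi, cost);
  return true;
}

// first sphere intersection with t > eps; returns t or -1
static inline double sphere_hit(double px, double pz, double dx, double dz,
                                double zc, double Rs, double tmin) {
  double ocx = px, ocz = pz - zc;
  double b = dx * ocx + dz * ocz;
  double c = ocx * ocx + ocz * ocz - Rs * Rs;
  double disc = b * b - c;
  if (disc <= 0) return -1.0;
  double sq = std::sqrt(disc);
  double t1 = -b - sq, t2 = -b + sq;
  if (t1 > tmin) return t1;
  if (t2 > tmin) return t2;
  return -1.0;
}

// [[Rcpp::export]]
NumericMatrix trace_apparent_image_cpp(double Rs, double zc,
                                       double n_oil, double n_buf,
                                       double n_cond, double num_ap,
                                       int n_rays,
                                       NumericVector xg, NumericVector zg) {
  if (num_ap <= 0 || num_ap >= n_oil) stop("require 0 < NA < n_oil");
  if (n_rays < 4) stop("n_rays must be >= 4");
  int nxg = xg.size(), nzg = zg.size();
  NumericMatrix img(nzg, nxg);
  double r_contact2 = Rs * Rs - zc * zc;  // contact radius squared
  double sa_max = num_ap / n_oil;
  double Lmax = 6.0 * (Rs + 1.0);
  std::vector<Seg> segs;
  std::vector<int> ray_start, ray_len;
  std::vector<double> ray_T;
  std::vector<char> ray_cls;

  for (int ix = 0; ix < nxg; ++ix) {
    double x0 = xg[ix];
    for (int iz = 0; iz < nzg; ++iz) {
      double znom = zg[iz];
      segs.clear(); ray_start.clear(); ray_len.clear(); ray_T.clear();
      ray_cls.clear();
      // build refracted polylines for the fan
      for (int k = 0; k < n_rays; ++k) {
        double rho = -1.0 + (2.0 * k + 1.0) / n_rays;  // pupil coordinate
        double sa = rho * sa_max;
        double ca = std::sqrt(1.0 - sa * sa);
        double xat0 = x0 - (sa / ca) * znom;  // ray position at z = 0
        bool under_cap = (xat0 * xat0 < r_contact2);
        // the planar refraction at the sample base is governed by the bulk
        // aqueous medium; the condensate index enters only through the
        // additional mismatch at the spherical cap surface
        double sb, cb;
        if (!snell_plane(n_oil, n_buf, sa, &sb, &cb)) continue;  // TIR
        double Tray = fresnel_T(n_oil, n_buf, ca, cb);
        int start = (int)segs.size();
        double px = xat0, pz = 0.0, dx = sb, dz = cb;
        double used = 0.0;
        if (under_cap) {
          // rays entering through the drop base: the condensate-buffer
          // step is applied only at the lateral cap surface (see docs);
          // these rays propagate as in the bulk medium
          segs.push_back({px, pz, dx, dz, Lmax});
        } else {
          // in buffer; may enter the cap and exit again
          double t = sphere_hit(px, pz, dx, dz, zc, Rs, 1e-9);
          if (t > 0 && t < Lmax) {
            segs.push_back({px, pz, dx, dz, t});
            used += t;
            double qx = px + t * dx, qz = pz + t * dz;
            double nx = qx / Rs, nz = (qz - zc) / Rs;
            double ox, oz, Tin;
            if (snell_vec_T(n_buf, n_cond, dx, dz, nx, nz, &ox, &oz, &Tin)) {
              Tray *= Tin;
              double t2 = sphere_hit(qx, qz, ox, oz, zc, Rs, 1e-9);
              if (t2 > 0 && t2 < Lmax - used) {
                segs.push_back({qx, qz, ox, oz, t2});
                used += t2;
                double q2x = qx + t2 * ox, q2z = qz + t2 * oz;
                double n2x = q2x / Rs, n2z = (q2z - zc) / Rs;
                double o2x, o2z, Tout;
                if (snell_vec_T(n_cond, n_buf, ox, oz, n2x, n2z, &o2x, &o2z,
                                &Tout)) {
                  Tray *= Tout;
                  segs.push_back({q2x, q2z, o2x, o2z, Lmax - used});
                }
              } else {
                segs.push_back({qx, qz, ox, oz, Lmax - used});
              }
            }
          } else {
            segs.push_back({px, pz, dx, dz, Lmax});
          }
        }
        ray_start.push_back(start);
        ray_len.push_back((int)segs.size() - start);
        ray_T.push_back(Tray);
        ray_cls.push_back((char)(segs.size() - start > 1));
      }
      // pairwise crossings; each crossing is weighted by the local
      // crossing density along the axis (estimated from k-nearest
      // neighbours in z), so that the recorded signal follows the
      // concentration of the caustic as a confocal detector would
      // (illumination times detection), not the raw crossing count
      int nrk = (int)ray_start.size();
      std::vector<double> cz, cx, cT;
      std::vector<char> cin;
      for (int a = 0; a < nrk; ++a) {
        for (int b = a + 1; b < nrk; ++b) {
          if (ray_cls[a] != ray_cls[b]) continue;
          bool found = false;
          for (int sa_i = 0; sa_i < ray_len[a] && !found; ++sa_i) {
            const Seg& A = segs[ray_start[a] + sa_i];
            for (int sb_i = 0; sb_i < ray_len[b] && !found; ++sb_i) {
              const Seg& B = segs[ray_start[b] + sb_i];
              double cross = A.dx * B.dz - A.dz * B.dx;
              if (std::fabs(cross) < 1e-14) continue;
              double rx = B.x - A.x, rz = B.z - A.z;
              double s = (rx * B.dz - rz * B.dx) / cross;
              double t = (rx * A.dz - rz * A.dx) / cross;
              if (s > 1e-9 && s <= A.len && t > 1e-9 && t <= B.len) {
                double qx = A.x + s * A.dx, qz = A.z + s * A.dz;
                double ddx = qx, ddz = qz - zc;
                cz.push_back(qz);
                cx.push_back(qx);
                cT.push_back(ray_T[a] * ray_T[b]);
                cin.push_back(qz > 0 &&
                              ddx * ddx + ddz * ddz < Rs * Rs);
                found = true;
              }
            }
          }
        }
      }
      int tot = (int)cz.size();
      if (tot == 0) { img(iz, ix) = 0.0; continue; }
      // separable axial/lateral k-NN density of the crossing cloud; the
      // squared density emulates the conjugate illumination-detection
      // weighting of a confocal pinhole, concentrating the signal on the
      // dominant caustic and suppressing displaced ghost clouds
      std::vector<double> dz_(tot, 0.0), dx_(tot, 0.0);
      std::vector<int> ord(tot);
      int m = std::max(3, tot / 20);
      for (int k = 0; k < tot; ++k) ord[k] = k;
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return cz[a] < cz[b]; });
      for (int k = 0; k < tot; ++k) {
        int lo = std::max(0, k - m), hi = std::min(tot - 1, k + m);
        dz_[ord[k]] = (double)(hi - lo) /
          (cz[ord[hi]] - cz[ord[lo]] + 1e-9);
      }
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return cx[a] < cx[b]; });
      for (int k = 0; k < tot; ++k) {
        int lo = std::max(0, k - m), hi = std::min(tot - 1, k + m);
        dx_[ord[k]] = (double)(hi - lo) /
          (cx[ord[hi]] - cx[ord[lo]] + 1e-9);
      }
      double win = 0.0, wtot = 0.0;
      for (int k = 0; k < tot; ++k) {
        double w = cT[k] * std::sqrt(dz_[k]);
        wtot += w;
        if (cin[k]) win += w;
      }
      img(iz, ix) = win / wtot;
    }
  }
  return img;
}
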