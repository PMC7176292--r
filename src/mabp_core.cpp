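// Core numerics for mABP sampling: mollifier kernel, grid deposition with
// overfill protection, multilinear bias interpolation, and BAOAB Langevin
// integrators for the shipped analytic toy systems.
//
// Grid cells are stored column-major (index i + bins[0]*j), matching R
// array layout. Bias is defined on cell centers; V(cell) = b*kT*log(c*S+1)
// is evaluated lazily from the accumulated mollified weight S.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Mollifier: quartic bump w(r) ~ (1 - (r/alpha)^2)^2 on |r| <= alpha bins,
// normalized to unit mass. Product form in 2D.
static std::vector<double> bump_profile(int alpha) {
  if (alpha < 1) stop("mollifier half-width must be a positive integer");
  int n = 2 * alpha + 1;
  std::vector<double> w(n);
  double tot = 0.0;
  for (int k = -alpha; k <= alpha; ++k) {
    double u = (double)k / (double)alpha;
    double v = 1.0 - u * u;
    w[k + alpha] = v * v;
    tot += w[k + alpha];
  }
  for (int i = 0; i < n; ++i) w[i] /= tot;
  return w;
}

// [[Rcpp::export]]
NumericVector mollifier_profile_cpp(int alpha) {
  std::vector<double> w = bump_profile(alpha);
  return NumericVector(w.begin(), w.end());
}

// ---------------------------------------------------------------------------
// Light-weight view of an R-side bias_grid list. The weight vector is
// wrapped without copying so deposits mutate the caller's grid in place;
// R-level wrappers duplicate the vector first when functional semantics
// are wanted.
struct GridRef {
  int ndim;
  int bins[2];
  double lo[2], hi[2], h[2];
  bool per[2];
  double b, c, flim, kT;
  int alpha;
  NumericVector S;
  std::vector<double> prof;
  double w0; // central kernel weight (product over dims)
};

static GridRef grid_ref(List g) {
  GridRef G;
  IntegerVector bins = g["bins"];
  NumericVector lo = g["lo"], hi = g["hi"];
  LogicalVector per = g["periodic"];
  G.ndim = bins.size();
  if (G.ndim < 1 || G.ndim > 2) stop("grids must be 1D or 2D");
  for (int d = 0; d < G.ndim; ++d) {
    G.bins[d] = bins[d];
    G.lo[d] = lo[d];
    G.hi[d] = hi[d];
    G.h[d] = (hi[d] - lo[d]) / bins[d];
    G.per[d] = per[d];
  }
  G.b = as<double>(g["b"]);
  G.c = as<double>(g["c"]);
  G.flim = as<double>(g["flim"]);
  G.kT = as<double>(g["kT"]);
  G.alpha = as<int>(g["alpha"]);
  G.S = as<NumericVector>(g["weight"]);
  G.prof = bump_profile(G.alpha);
  G.w0 = 1.0;
  for (int d = 0; d < G.ndim; ++d) G.w0 *= G.prof[G.alpha];
  return G;
}

static inline int wrap_idx(int i, int n) {
  int r = i % n;
  return (r < 0) ? r + n : r;
}

// Bin index of the cell containing x along dim d; clamped at edges for
// non-periodic dims (clamped deposits are counted, not errors).
static inline int center_idx(const GridRef& G, int d, double x, bool* clamped) {
  int i = (int)std::floor((x - G.lo[d]) / G.h[d]);
  if (G.per[d]) return wrap_idx(i, G.bins[d]);
  if (i < 0) { *clamped = true; return 0; }
  if (i >= G.bins[d]) { *clamped = true; return G.bins[d] - 1; }
  return i;
}

// Cell bias, hard-capped at the fill limit: deposit gating keeps growth
// smooth, while the cap guarantees V <= flim exactly even where kernel
// tails from neighboring deposits continue to add weight.
static inline double cell_V(const GridRef& G, int lin) {
  double v = G.b * G.kT * std::log1p(G.c * G.S[lin]);
  return (G.flim > 0.0 && v > G.flim) ? G.flim : v;
}

// One overfill-protected deposit centered on the cell containing x.
// Returns the applied scale g in [0,1]. The scale is the linear ramp
// 1 - V_center/flim, additionally capped so the center cell can never be
// pushed past flim by a single large deposit.
static double deposit_one(GridRef& G, const double* x, bool* clamped) {
  if (!(G.flim > 0.0)) return 0.0; // disabled bias
  int ci[2] = {0, 0};
  for (int d = 0; d < G.ndim; ++d) {
    if (!R_finite(x[d])) stop("non-finite CV value in deposit");
    ci[d] = center_idx(G, d, x[d], clamped);
  }
  int lin = (G.ndim == 1) ? ci[0] : ci[0] + G.bins[0] * ci[1];
  double Vc = cell_V(G, lin);
  double g = 1.0 - Vc / G.flim;
  if (g <= 0.0) return 0.0;
  if (g > 1.0) g = 1.0;
  // exact cap: never let the center cell's post-deposit V exceed flim
  double Slim = std::expm1(G.flim / (G.b * G.kT)) / G.c;
  double room = (Slim - G.S[lin]) / G.w0;
  if (room < g) g = room;
  if (g <= 0.0) return 0.0;

  int a = G.alpha;
  if (G.ndim == 1) {
    for (int k = -a; k <= a; ++k) {
      int i = ci[0] + k;
      if (G.per[0]) i = wrap_idx(i, G.bins[0]);
      else if (i < 0 || i >= G.bins[0]) continue; // truncate at edges
      G.S[i] += g * G.prof[k + a];
    }
  } else {
    for (int k1 = -a; k1 <= a; ++k1) {
      int j = ci[1] + k1;
      if (G.per[1]) j = wrap_idx(j, G.bins[1]);
      else if (j < 0 || j >= G.bins[1]) continue;
      double wj = G.prof[k1 + a];
      for (int k0 = -a; k0 <= a; ++k0) {
        int i = ci[0] + k0;
        if (G.per[0]) i = wrap_idx(i, G.bins[0]);
        else if (i < 0 || i >= G.bins[0]) continue;
        G.S[i + G.bins[0] * j] += g * wj * G.prof[k0 + a];
      }
    }
  }
  return g;
}

// [[Rcpp::export]]
List grid_deposit_cpp(List grid, NumericMatrix pts) {
  GridRef G = grid_ref(grid);
  if (pts.ncol() != G.ndim) stop("point dimensionality does not match grid");
  int n = pts.nrow(), nclamp = 0;
  NumericVector gs(n);
  double x[2];
  for (int r = 0; r < n; ++r) {
    bool cl = false;
    for (int d = 0; d < G.ndim; ++d) x[d] = pts(r, d);
    gs[r] = deposit_one(G, x, &cl);
    if (cl) ++nclamp;
  }
  return List::create(_["g"] = gs, _["n_clamped"] = nclamp);
}

// Multilinear interpolation of V and its analytic gradient at a point.
// Non-periodic dims clamp to the edge cell value with zero outward gradient.
static void bias_at(const GridRef& G, const double* x, double* val, double* grad) {
  int i0[2], i1[2];
  double f[2];
  for (int d = 0; d < G.ndim; ++d) {
    double u = (x[d] - G.lo[d]) / G.h[d] - 0.5;
    if (G.per[d]) {
      int n = G.bins[d];
      u -= (double)n * std::floor(u / (double)n); // wrap into [0, n)
      if (u >= n) u = 0.0;                        // fp guard
      int i = (int)std::floor(u);
      if (i >= n) i = n - 1; // guard fp edge
      i0[d] = i;
      i1[d] = wrap_idx(i + 1, n);
      f[d] = u - i;
    } else {
      if (u <= 0.0) { i0[d] = i1[d] = 0; f[d] = 0.0; }
      else if (u >= G.bins[d] - 1.0) { i0[d] = i1[d] = G.bins[d] - 1; f[d] = 0.0; }
      else {
        int i = (int)std::floor(u);
        i0[d] = i; i1[d] = i + 1; f[d] = u - i;
      }
    }
  }
  if (G.ndim == 1) {
    double V0 = cell_V(G, i0[0]), V1 = cell_V(G, i1[0]);
    *val = (1.0 - f[0]) * V0 + f[0] * V1;
    grad[0] = (i0[0] == i1[0]) ? 0.0 : (V1 - V0) / G.h[0];
  } else {
    int nb = G.bins[0];
    double V00 = cell_V(G, i0[0] + nb * i0[1]);
    double V10 = cell_V(G, i1[0] + nb * i0[1]);
    double V01 = cell_V(G, i0[0] + nb * i1[1]);
    double V11 = cell_V(G, i1[0] + nb * i1[1]);
    double fx = f[0], fy = f[1];
    *val = V00 * (1 - fx) * (1 - fy) + V10 * fx * (1 - fy) +
           V01 * (1 - fx) * fy + V11 * fx * fy;
    grad[0] = (i0[0] == i1[0]) ? 0.0
      : ((V10 - V00) * (1 - fy) + (V11 - V01) * fy) / G.h[0];
    grad[1] = (i0[1] == i1[1]) ? 0.0
      : ((V01 - V00) * (1 - fx) + (V11 - V10) * fx) / G.h[1];
  }
}

// [[Rcpp::export]]
List grid_bias_eval_cpp(List grid, NumericMatrix pts) {
  GridRef G = grid_ref(grid);
  if (pts.ncol() != G.ndim) stop("point dimensionality does not match grid");
  int n = pts.nrow();
  NumericVector val(n);
  NumericMatrix grad(n, G.ndim);
  double x[2], v, gr[2];
  for (int r = 0; r < n; ++r) {
    for (int d = 0; d < G.ndim; ++d) {
      x[d] = pts(r, d);
      if (!R_finite(x[d])) stop("non-finite CV value in bias evaluation");
    }
    bias_at(G, x, &v, gr);
    val[r] = v;
    for (int d = 0; d < G.ndim; ++d) grad(r, d) = gr[d];
  }
  return List::create(_["value"] = val, _["gradient"] = grad);
}

// ---------------------------------------------------------------------------
// Analytic toy potentials (energies in kcal/mol, lengths in Angstrom or
// radians, unit masses).
//   1 harmonic     : U = 0.5*k*sum(x^2)              pars = (k)
//   2 double_well  : U = h*(x^2-1)^2                 pars = (h), 1D
//   3 mueller_brown: scaled 4-Gaussian surface       pars = (scale), 2D
//   4 cosine_well  : U = A*(1-cos(x))                pars = (A), 1D periodic
static const double MB_A[4]  = {-200.0, -100.0, -170.0, 15.0};
static const double MB_a[4]  = {-1.0, -1.0, -6.5, 0.7};
static const double MB_b[4]  = {0.0, 0.0, 11.0, 0.6};
static const double MB_c[4]  = {-10.0, -10.0, -6.5, 0.7};
static const double MB_x0[4] = {1.0, 0.0, -0.5, -1.0};
static const double MB_y0[4] = {0.0, 0.5, 1.5, 1.0};

static double pot_force(int id, const double* p, const double* x, int nd, double* f) {
  switch (id) {
  case 1: {
    double U = 0.0;
    for (int d = 0; d < nd; ++d) { U += 0.5 * p[0] * x[d] * x[d]; f[d] = -p[0] * x[d]; }
    return U;
  }
  case 2: {
    double q = x[0] * x[0] - 1.0;
    f[0] = -4.0 * p[0] * x[0] * q;
    return p[0] * q * q;
  }
  case 3: {
    double U = 0.0; f[0] = 0.0; f[1] = 0.0;
    for (int t = 0; t < 4; ++t) {
      double dx = x[0] - MB_x0[t], dy = x[1] - MB_y0[t];
      double e = p[0] * MB_A[t] *
        std::exp(MB_a[t] * dx * dx + MB_b[t] * dx * dy + MB_c[t] * dy * dy);
      U += e;
      f[0] -= e * (2.0 * MB_a[t] * dx + MB_b[t] * dy);
      f[1] -= e * (MB_b[t] * dx + 2.0 * MB_c[t] * dy);
    }
    return U;
  }
  case 4: {
    f[0] = -p[0] * std::sin(x[0]);
    return p[0] * (1.0 - std::cos(x[0]));
  }
  default:
    stop("unknown potential id");
  }
  return 0.0; // not reached
}

// BAOAB Langevin on an analytic potential whose coordinates are the CVs.
// noise must be n_steps x ndim of standard normals (generated from R's RNG
// for seed determinism). If a grid is supplied, its interpolated bias force
// is added; if do_deposit, one overfill-protected deposit is made per step.
// [[Rcpp::export]]
List run_langevin_cpp(int pot_id, NumericVector pars, NumericVector x0,
                      double kT, double gamma, double dt, int n_steps,
                      int stride, NumericMatrix noise, SEXP grid_sexp,
                      bool do_deposit) {
  int nd = x0.size();
  if (noise.nrow() < n_steps || noise.ncol() != nd)
    stop("noise matrix has wrong shape");
  bool has_grid = !Rf_isNull(grid_sexp);
  GridRef G;
  if (has_grid) {
    G = grid_ref(List(grid_sexp));
    if (G.ndim != nd) stop("CV dimensionality does not match grid");
  }

  std::vector<double> x(nd), v(nd, 0.0), f(nd), fb(nd);
  double p[4] = {0, 0, 0, 0};
  for (int i = 0; i < pars.size() && i < 4; ++i) p[i] = pars[i];
  for (int d = 0; d < nd; ++d) x[d] = x0[d];

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * kT);

  pot_force(pot_id, p, x.data(), nd, f.data());
  if (has_grid) {
    double e;
    bias_at(G, x.data(), &e, fb.data());
    for (int d = 0; d < nd; ++d) f[d] -= fb[d];
  }

  int nsave = n_steps / stride;
  NumericMatrix frames(nsave, nd);
  int isave = 0, nclamp = 0, steps_done = 0;
  bool blowup = false;

  for (int s = 0; s < n_steps; ++s) {
    for (int d = 0; d < nd; ++d) v[d] += 0.5 * dt * f[d];
    for (int d = 0; d < nd; ++d) x[d] += 0.5 * dt * v[d];
    for (int d = 0; d < nd; ++d) v[d] = c1 * v[d] + c2 * noise(s, d);
    for (int d = 0; d < nd; ++d) x[d] += 0.5 * dt * v[d];
    pot_force(pot_id, p, x.data(), nd, f.data());
    if (has_grid) {
      double e;
      bias_at(G, x.data(), &e, fb.data());
      for (int d = 0; d < nd; ++d) f[d] -= fb[d];
    }
    for (int d = 0; d < nd; ++d) v[d] += 0.5 * dt * f[d];
    if (has_grid && do_deposit) {
      bool cl = false;
      deposit_one(G, x.data(), &cl);
      if (cl) ++nclamp;
    }
    steps_done = s + 1;
    bool bad = false;
    for (int d = 0; d < nd; ++d) if (!R_finite(x[d]) || std::fabs(x[d]) > 1e3) bad = true;
    if (bad) { blowup = true; break; }
    if ((s + 1) % stride == 0 && isave < nsave) {
      for (int d = 0; d < nd; ++d) frames(isave, d) = x[d];
      ++isave;
    }
  }

  return List::create(_["frames"] = frames, _["n_saved"] = isave,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["n_clamped"] = nclamp, _["blowup"] = blowup,
                      _["steps_done"] = steps_done);
}

// ---------------------------------------------------------------------------
// Host-guest binding toy: a small ligand of point particles (two labelled
// groups) diffusing above two fixed receptor reference points, with a
// designed binding pocket (per-atom Gaussian wells at the constructed bound
// pose), an entrance barrier on the anchor atom, an optional decoy well on
// the ligand centroid (spurious-escape channel), flat-bottom cylindrical and
// CV-cap restraints, and a half-space wall standing in for the receptor body.

struct HGSys {
  int nlig;
  NumericMatrix bonds;   // nb x 4: i, j (0-based), r0, k
  NumericMatrix pocket;  // nlig x 3 designed bound pose
  double pocket_eps, pocket_w;
  double barrier_B, barrier_r0, barrier_sigma;
  double decoy_eps, decoy_w;
  double decoy_pos[3];
  double wall_k, wall_z;
  double refA[3], refB[3];
  IntegerVector g1, g2;  // 0-based atom indices per CV group
  double cyl_x, cyl_y, cyl_R, k_cyl;
  double cv_cap, k_cap;
  double kT, gamma, dt;
};

static HGSys hg_sys(List s) {
  HGSys S;
  S.nlig = as<int>(s["nlig"]);
  S.bonds = as<NumericMatrix>(s["bonds"]);
  S.pocket = as<NumericMatrix>(s["pocket"]);
  S.pocket_eps = as<double>(s["pocket_eps"]);
  S.pocket_w = as<double>(s["pocket_w"]);
  S.barrier_B = as<double>(s["barrier_B"]);
  S.barrier_r0 = as<double>(s["barrier_r0"]);
  S.barrier_sigma = as<double>(s["barrier_sigma"]);
  S.decoy_eps = as<double>(s["decoy_eps"]);
  S.decoy_w = as<double>(s["decoy_w"]);
  NumericVector dp = s["decoy_pos"], rA = s["refA"], rB = s["refB"];
  for (int d = 0; d < 3; ++d) { S.decoy_pos[d] = dp[d]; S.refA[d] = rA[d]; S.refB[d] = rB[d]; }
  S.wall_k = as<double>(s["wall_k"]);
  S.wall_z = as<double>(s["wall_z"]);
  S.g1 = as<IntegerVector>(s["g1"]);
  S.g2 = as<IntegerVector>(s["g2"]);
  S.cyl_x = as<double>(s["cyl_x"]);
  S.cyl_y = as<double>(s["cyl_y"]);
  S.cyl_R = as<double>(s["cyl_R"]);
  S.k_cyl = as<double>(s["k_cyl"]);
  S.cv_cap = as<double>(s["cv_cap"]);
  S.k_cap = as<double>(s["k_cap"]);
  S.kT = as<double>(s["kT"]);
  S.gamma = as<double>(s["gamma"]);
  S.dt = as<double>(s["dt"]);
  return S;
}

// RMS distance of a group of atoms to a single reference point, plus its
// gradient factor: d(cv)/d(x_i) = (x_i - ref) / (m * cv).
static double hg_cv(const double* x, const IntegerVector& grp, const double* ref) {
  double ss = 0.0;
  int m = grp.size();
  for (int q = 0; q < m; ++q) {
    int i = grp[q];
    for (int d = 0; d < 3; ++d) {
      double dd = x[3 * i + d] - ref[d];
      ss += dd * dd;
    }
  }
  return std::sqrt(ss / m);
}

// Physical + restraint energy and forces; also reports the two CVs and the
// monitor distance (anchor atom to its pocket site).
static double hg_force(const HGSys& S, const double* x, double* f,
                       double* cv1, double* cv2, double* monitor) {
  int n = S.nlig;
  for (int i = 0; i < 3 * n; ++i) f[i] = 0.0;
  double U = 0.0;

  // bonds
  for (int b = 0; b < S.bonds.nrow(); ++b) {
    int i = (int)S.bonds(b, 0), j = (int)S.bonds(b, 1);
    double r0 = S.bonds(b, 2), kb = S.bonds(b, 3);
    double dx[3], r2 = 0.0;
    for (int d = 0; d < 3; ++d) { dx[d] = x[3 * i + d] - x[3 * j + d]; r2 += dx[d] * dx[d]; }
    double r = std::sqrt(r2);
    if (r < 1e-12) continue;
    double dr = r - r0;
    U += 0.5 * kb * dr * dr;
    double fac = -kb * dr / r;
    for (int d = 0; d < 3; ++d) { f[3 * i + d] += fac * dx[d]; f[3 * j + d] -= fac * dx[d]; }
  }

  // pocket wells (per-atom Gaussians at the designed pose)
  double w2 = S.pocket_w * S.pocket_w;
  for (int i = 0; i < n; ++i) {
    double dx[3], r2 = 0.0;
    for (int d = 0; d < 3; ++d) { dx[d] = x[3 * i + d] - S.pocket(i, d); r2 += dx[d] * dx[d]; }
    double e = -S.pocket_eps * std::exp(-r2 / (2.0 * w2));
    U += e;
    for (int d = 0; d < 3; ++d) f[3 * i + d] += e * dx[d] / w2; // -dU/dx
  }

  // monitor distance: anchor atom to its pocket site
  {
    double r2 = 0.0;
    for (int d = 0; d < 3; ++d) { double dd = x[d] - S.pocket(0, d); r2 += dd * dd; }
    *monitor = std::sqrt(r2);
  }

  // entrance barrier: Gaussian shell on the ligand centroid's distance to
  // the pocket centroid (a tilt-proof stand-in for the steric entry cost)
  if (S.barrier_B > 0.0) {
    double cog[3] = {0, 0, 0}, pc[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        cog[d] += x[3 * i + d] / n;
        pc[d] += S.pocket(i, d) / n;
      }
    double dx[3], r2 = 0.0;
    for (int d = 0; d < 3; ++d) { dx[d] = cog[d] - pc[d]; r2 += dx[d] * dx[d]; }
    double r = std::sqrt(r2);
    if (r > 1e-12) {
      double u = (r - S.barrier_r0) / S.barrier_sigma;
      double e = S.barrier_B * std::exp(-0.5 * u * u);
      U += e;
      double dUdr = -e * u / S.barrier_sigma;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) f[3 * i + d] -= dUdr * dx[d] / (r * n);
    }
  }

  // decoy well on the ligand centroid
  if (S.decoy_eps > 0.0) {
    double cog[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) cog[d] += x[3 * i + d] / n;
    double dx[3], r2 = 0.0;
    for (int d = 0; d < 3; ++d) { dx[d] = cog[d] - S.decoy_pos[d]; r2 += dx[d] * dx[d]; }
    double dw2 = S.decoy_w * S.decoy_w;
    double e = -S.decoy_eps * std::exp(-r2 / (2.0 * dw2));
    U += e;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) f[3 * i + d] += e * dx[d] / (dw2 * n);
  }

  // receptor-body wall: atoms pay to go below wall_z
  if (S.wall_k > 0.0) {
    for (int i = 0; i < n; ++i) {
      double dz = x[3 * i + 2] - S.wall_z;
      if (dz < 0.0) {
        U += 0.5 * S.wall_k * dz * dz;
        f[3 * i + 2] -= S.wall_k * dz;
      }
    }
  }

  // flat-bottom cylinder on the centroid (axis +z)
  {
    double cog[2] = {0, 0};
    for (int i = 0; i < n; ++i) { cog[0] += x[3 * i] / n; cog[1] += x[3 * i + 1] / n; }
    double rx = cog[0] - S.cyl_x, ry = cog[1] - S.cyl_y;
    double rho = std::sqrt(rx * rx + ry * ry);
    if (rho > S.cyl_R && rho > 1e-12) {
      double dr = rho - S.cyl_R;
      U += 0.5 * S.k_cyl * dr * dr;
      double fac = -S.k_cyl * dr / rho / n;
      for (int i = 0; i < n; ++i) { f[3 * i] += fac * rx; f[3 * i + 1] += fac * ry; }
    }
  }

  // CVs and flat-bottom cap
  double c1 = hg_cv(x, S.g1, S.refA);
  double c2v = hg_cv(x, S.g2, S.refB);
  *cv1 = c1;
  *cv2 = c2v;
  const IntegerVector* grps[2] = {&S.g1, &S.g2};
  const double* refs[2] = {S.refA, S.refB};
  double cvs[2] = {c1, c2v};
  for (int q = 0; q < 2; ++q) {
    double cv = cvs[q];
    if (cv > S.cv_cap && cv > 1e-12) {
      double ex = cv - S.cv_cap;
      U += 0.5 * S.k_cap * ex * ex;
      double dUdcv = S.k_cap * ex;
      const IntegerVector& grp = *grps[q];
      int m = grp.size();
      for (int t = 0; t < m; ++t) {
        int i = grp[t];
        for (int d = 0; d < 3; ++d)
          f[3 * i + d] -= dUdcv * (x[3 * i + d] - refs[q][d]) / (m * cv);
      }
    }
  }
  return U;
}

// [[Rcpp::export]]
List hostguest_energy_cpp(List sys, NumericVector x) {
  HGSys S = hg_sys(sys);
  if (x.size() != 3 * S.nlig) stop("coordinate vector has wrong length");
  std::vector<double> f(3 * S.nlig);
  double cv1, cv2, mon;
  double U = hg_force(S, x.begin(), f.data(), &cv1, &cv2, &mon);
  return List::create(_["energy"] = U,
                      _["force"] = NumericVector(f.begin(), f.end()),
                      _["cv"] = NumericVector::create(cv1, cv2),
                      _["monitor"] = mon);
}

// [[Rcpp::export]]
List run_hostguest_cpp(List sys, SEXP grid_sexp, bool do_deposit, int n_steps,
                       int stride, NumericMatrix noise, NumericVector x0) {
  HGSys S = hg_sys(sys);
  int nf = 3 * S.nlig;
  if (x0.size() != nf) stop("coordinate vector has wrong length");
  if (noise.nrow() < n_steps || noise.ncol() != nf)
    stop("noise matrix has wrong shape");
  bool has_grid = !Rf_isNull(grid_sexp);
  GridRef G;
  if (has_grid) {
    G = grid_ref(List(grid_sexp));
    if (G.ndim != 2) stop("host-guest runs require a 2D grid");
  }

  std::vector<double> x(x0.begin(), x0.end()), v(nf, 0.0), f(nf);
  double cv1, cv2, mon;
  double c1 = std::exp(-S.gamma * S.dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * S.kT);

  // add bias chain-rule force onto f given current x and cv values
  auto add_bias = [&](double* ff, double a1, double a2) {
    double xv[2] = {a1, a2}, e, gr[2];
    bias_at(G, xv, &e, gr);
    const IntegerVector* grps[2] = {&S.g1, &S.g2};
    const double* refs[2] = {S.refA, S.refB};
    double cvs[2] = {a1, a2};
    for (int q = 0; q < 2; ++q) {
      if (cvs[q] < 1e-9) continue;
      const IntegerVector& grp = *grps[q];
      int m = grp.size();
      for (int t = 0; t < m; ++t) {
        int i = grp[t];
        for (int d = 0; d < 3; ++d)
          ff[3 * i + d] -= gr[q] * (x[3 * i + d] - refs[q][d]) / (m * cvs[q]);
      }
    }
  };

  hg_force(S, x.data(), f.data(), &cv1, &cv2, &mon);
  if (has_grid) add_bias(f.data(), cv1, cv2);

  int nsave = n_steps / stride;
  NumericMatrix frames(nsave, nf), cvt(nsave, 2);
  NumericVector mont(nsave);
  int isave = 0, nclamp = 0, steps_done = 0;
  bool blowup = false;

  for (int s = 0; s < n_steps; ++s) {
    for (int d = 0; d < nf; ++d) v[d] += 0.5 * S.dt * f[d];
    for (int d = 0; d < nf; ++d) x[d] += 0.5 * S.dt * v[d];
    for (int d = 0; d < nf; ++d) v[d] = c1 * v[d] + c2 * noise(s, d);
    for (int d = 0; d < nf; ++d) x[d] += 0.5 * S.dt * v[d];
    hg_force(S, x.data(), f.data(), &cv1, &cv2, &mon);
    if (has_grid) add_bias(f.data(), cv1, cv2);
    for (int d = 0; d < nf; ++d) v[d] += 0.5 * S.dt * f[d];
    if (has_grid && do_deposit) {
      bool cl = false;
      double xv[2] = {cv1, cv2};
      deposit_one(G, xv, &cl);
      if (cl) ++nclamp;
    }
    steps_done = s + 1;
    bool bad = false;
    for (int d = 0; d < nf; ++d) if (!R_finite(x[d]) || std::fabs(x[d]) > 1e3) bad = true;
    if (bad) { blowup = true; break; }
    if ((s + 1) % stride == 0 && isave < nsave) {
      for (int d = 0; d < nf; ++d) frames(isave, d) = x[d];
      cvt(isave, 0) = cv1;
      cvt(isave, 1) = cv2;
      mont[isave] = mon;
      ++isave;
    }
  }

  return List::create(_["frames"] = frames, _["cv_trace"] = cvt,
                      _["monitor"] = mont, _["n_saved"] = isave,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["n_clamped"] = nclamp, _["blowup"] = blowup,
                      _["steps_done"] = steps_done);
}

// Analytic toy potential evaluated on a vector of points (for quadrature
// oracles and landscape comparisons).
// [[Rcpp::export]]
NumericVector pot_energy_cpp(int pot_id, NumericVector pars, NumericMatrix pts) {
  int n = pts.nrow(), nd = pts.ncol();
  NumericVector out(n);
  double p[4] = {0, 0, 0, 0};
  for (int i = 0; i < pars.size() && i < 4; ++i) p[i] = pars[i];
  std::vector<double> f(nd), x(nd);
  for (int r = 0; r < n; ++r) {
    for (int d = 0; d < nd; ++d) x[d] = pts(r, d);
    out[r] = pot_force(pot_id, p, x.data(), nd, f.data());
  }
  return out;
}
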