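// Hot loop of the projected Riemannian SGD trainer. Semantics mirror the
// R-level objective exactly (the R functions remain the reference for the
// gradient-correctness tests); this file only provides the per-epoch
// stochastic pass, the structural constraint projections, and the settling
// sweeps at compiled speed. All randomness comes from R's RNG, so a run is
// reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double EPS_DENOM = 1e-15;

struct Cfg {
  int dim, n_negatives, burn_in_epochs, cone_warmup_epochs, epochs;
  int polish_sweeps, final_sweeps;
  double delta, K, margin, lambda_root, lambda_child, lambda_cone,
      lambda_nonhier, lr, burn_in_factor, anneal_frac, anneal_floor,
      eps_ball, max_step;
};

// --- small vector helpers on rows of a flat row-major matrix ------------
static inline double row_norm2(const std::vector<double>& X, int i, int d) {
  double s = 0;
  for (int j = 0; j < d; ++j) s += X[i * d + j] * X[i * d + j];
  return s;
}

static inline void project_row(std::vector<double>& X, int i, int d,
                               double eps_ball) {
  double n2 = row_norm2(X, i, d);
  double lim = 1.0 - eps_ball;
  if (n2 > lim * lim) {
    double f = lim / std::sqrt(n2);
    for (int j = 0; j < d; ++j) X[i * d + j] *= f;
  }
}

static inline void rescale_row(std::vector<double>& X, int i, int d,
                               double target_norm) {
  double n = std::sqrt(row_norm2(X, i, d));
  if (n < EPS_DENOM) return;
  double f = target_norm / n;
  for (int j = 0; j < d; ++j) X[i * d + j] *= f;
}

static inline double clip_factor(double step_norm, double cap) {
  return (step_norm > cap) ? cap / step_norm : 1.0;
}

static inline double origin_dist(double r) { return 2.0 * std::atanh(r); }

static inline double angle_at(const double* x, const double* y, int d) {
  double nx2 = 0, sb = 0, ny2 = 0;
  for (int j = 0; j < d; ++j) {
    nx2 += x[j] * x[j];
    ny2 += y[j] * y[j];
    double df = x[j] - y[j];
    sb += df * df;
  }
  double den = 2.0 * std::sqrt(nx2 * sb);
  if (den < EPS_DENOM) den = EPS_DENOM;
  double c = (ny2 - nx2 - sb) / den;
  if (c > 1) c = 1;
  if (c < -1) c = -1;
  return std::acos(c);
}

static inline double aperture(double r, double K) {
  double arg = K * (1.0 - r * r) / std::max(r, EPS_DENOM);
  if (arg > 1.0) return NA_REAL;
  return std::asin(arg);
}

static double cone_r_min_c(double K) {
  return (std::sqrt(1.0 + 4.0 * K * K) - 1.0) / (2.0 * K);
}

static double apex_ceiling_c(double K, double psi_min) {
  double s = std::sin(psi_min);
  return (std::sqrt(s * s + 4.0 * K * K) - s) / (2.0 * K);
}

// --- RNG (R's, deterministic under set.seed) ----------------------------
static inline int rand_below(int n) {  // uniform on 0..n-1
  int k;
  do { k = (int)std::floor(unif_rand() * n); } while (k >= n);
  return k;
}

// --- structural projections --------------------------------------------
static void prox_ordering(std::vector<double>& X, int p, int c, int d,
                          const Cfg& cfg) {
  if (cfg.lambda_child <= 0) return;
  double rp = std::sqrt(row_norm2(X, p, d));
  double rc = std::sqrt(row_norm2(X, c, d));
  double viol = origin_dist(rp) - origin_dist(rc) + cfg.margin;
  if (viol <= 0) return;
  double t = std::min(1.0, cfg.lambda_child) * std::min(viol, 0.5);
  // fac * |grad d0|^2 = 1; grad d0 = (2/((1-r^2) r)) x
  double fac_p = (1 - rp * rp) * (1 - rp * rp) / 4.0;
  double fac_c = (1 - rc * rc) * (1 - rc * rc) / 4.0;
  double gp = 2.0 / ((1 - rp * rp) * std::max(rp, EPS_DENOM));
  double gc = 2.0 / ((1 - rc * rc) * std::max(rc, EPS_DENOM));
  double sp = (t / 2) * fac_p * gp;  // coordinate scale on x_p (inward)
  double sc = (t / 2) * fac_c * gc;  // on x_c (outward)
  double cap_p = clip_factor(sp * rp, 0.5), cap_c = clip_factor(sc * rc, 0.5);
  for (int j = 0; j < d; ++j) {
    X[p * d + j] -= cap_p * sp * X[p * d + j];
    X[c * d + j] += cap_c * sc * X[c * d + j];
  }
  project_row(X, p, d, cfg.eps_ball);
  project_row(X, c, d, cfg.eps_ball);
}

// slerp the member toward the apex ray at constant radius; rotate the apex
// toward the member (norm-preserving) at a capped rate
static void prox_cone(std::vector<double>& X, int xi, int yi, int d,
                      const Cfg& cfg, double lambda, double landing,
                      double axis_rot, double rot_cap) {
  if (lambda <= 0) return;
  double a0 = std::sqrt(row_norm2(X, xi, d));
  double ny = std::sqrt(row_norm2(X, yi, d));
  double psi = aperture(a0, cfg.K);
  if (ISNAN(psi)) return;  // gated apex
  const double* x = &X[xi * d];
  const double* y = &X[yi * d];
  double ang = angle_at(x, y, d);
  double e = ang - psi;
  if (e <= 0) return;
  double relax = std::min(1.0, lambda);

  std::vector<double> xh(d), e2(d), ynew(d);
  // member rotation about the origin
  if (ny > a0 + EPS_DENOM && a0 >= EPS_DENOM) {
    double cphi = 0;
    for (int j = 0; j < d; ++j) xh[j] = x[j] / a0;
    for (int j = 0; j < d; ++j) cphi += xh[j] * (y[j] / ny);
    if (cphi > 1) cphi = 1;
    if (cphi < -1) cphi = -1;
    double phi = std::acos(cphi);
    if (phi > 1e-12) {
      double ne2 = 0;
      for (int j = 0; j < d; ++j) {
        e2[j] = y[j] / ny - cphi * xh[j];
        ne2 += e2[j] * e2[j];
      }
      ne2 = std::sqrt(ne2);
      if (ne2 >= EPS_DENOM) {
        for (int j = 0; j < d; ++j) e2[j] /= ne2;
        double target = psi * (1.0 - (1.0 - landing) * relax);
        double lo = 0, hi = 1;
        for (int it = 0; it < 12; ++it) {
          double mid = 0.5 * (lo + hi);
          double aa = (1 - mid) * phi;
          for (int j = 0; j < d; ++j)
            ynew[j] = ny * (std::cos(aa) * xh[j] + std::sin(aa) * e2[j]);
          if (angle_at(x, ynew.data(), d) <= target) hi = mid; else lo = mid;
        }
        if (relax < 1) hi *= relax;
        double capped = std::min(hi, rot_cap / std::max(phi, EPS_DENOM));
        double aa = (1 - capped) * phi;
        for (int j = 0; j < d; ++j)
          X[yi * d + j] = ny * (std::cos(aa) * xh[j] + std::sin(aa) * e2[j]);
        project_row(X, yi, d, cfg.eps_ball);
      }
    }
  }
  // apex consensus rotation toward the member, norm preserving
  // gradient of the apex angle wrt x (axis-rotation part only)
  {
    double nx2 = 0, ny2 = 0, sb = 0;
    const double* yv = &X[yi * d];
    for (int j = 0; j < d; ++j) {
      nx2 += x[j] * x[j];
      ny2 += yv[j] * yv[j];
      double df = x[j] - yv[j];
      sb += df * df;
    }
    double a = std::sqrt(std::max(nx2, EPS_DENOM * EPS_DENOM));
    double b = std::sqrt(std::max(sb, EPS_DENOM * EPS_DENOM));
    double num = ny2 - nx2 - sb;
    double den = std::max(2 * a * b, EPS_DENOM);
    double cb = num / den;
    double ccl = cb > 1 ? 1 : (cb < -1 ? -1 : cb);
    bool active = std::fabs(cb) < 1;
    double dth = active ? -1.0 / std::max(std::sqrt(1 - ccl * ccl), EPS_DENOM)
                        : 0.0;
    std::vector<double> gx(d);
    double ng = 0;
    for (int j = 0; j < d; ++j) {
      double dnum = -2 * x[j] - 2 * (x[j] - yv[j]);
      double dden = 2 * (b / a) * x[j] + 2 * (a / b) * (x[j] - yv[j]);
      gx[j] = dth * (dnum * den - num * dden) / (den * den);
      ng += gx[j] * gx[j];
    }
    ng = std::sqrt(ng);
    if (ng >= EPS_DENOM && a0 >= EPS_DENOM) {
      double rot = relax * std::min(axis_rot, e) * a0;
      for (int j = 0; j < d; ++j) X[xi * d + j] -= gx[j] * (rot / ng);
      rescale_row(X, xi, d, a0);
      project_row(X, xi, d, cfg.eps_ball);
    }
  }
}

static void prox_roots(std::vector<double>& X, const std::vector<int>& roots,
                       int d, const Cfg& cfg) {
  if (cfg.lambda_root <= 0) return;
  for (size_t i = 0; i < roots.size(); ++i) {
    int r = roots[i];
    double rr = std::sqrt(row_norm2(X, r, d));
    double viol = origin_dist(rr) - cfg.delta;
    if (viol <= 0) continue;
    double t = std::min(1.0, cfg.lambda_root) * (viol + 0.01);
    double fac = (1 - rr * rr) * (1 - rr * rr) / 4.0;
    double g = 2.0 / ((1 - rr * rr) * std::max(rr, EPS_DENOM));
    double s = t * fac * g;
    double cap = clip_factor(s * rr, 0.5);
    for (int j = 0; j < d; ++j) X[r * d + j] -= cap * s * X[r * d + j];
    project_row(X, r, d, cfg.eps_ball);
  }
}

struct Clamps {
  double floor_r, parent_ceil, vh_ceil, outer;
};

static void clamp_all(std::vector<double>& X, int d,
                      const std::vector<int>& apex_idx,
                      const std::vector<int>& parent_idx,
                      const std::vector<int>& vh_apex_idx,
                      const Clamps& cl, bool use_cones, int n) {
  if (use_cones) {
    for (size_t i = 0; i < apex_idx.size(); ++i) {
      int a = apex_idx[i];
      double r = std::sqrt(row_norm2(X, a, d));
      if (r < cl.floor_r) rescale_row(X, a, d, cl.floor_r);
    }
    for (size_t i = 0; i < parent_idx.size(); ++i) {
      int a = parent_idx[i];
      double r = std::sqrt(row_norm2(X, a, d));
      if (r > cl.parent_ceil) rescale_row(X, a, d, cl.parent_ceil);
    }
    for (size_t i = 0; i < vh_apex_idx.size(); ++i) {
      int a = vh_apex_idx[i];
      double r = std::sqrt(row_norm2(X, a, d));
      if (r > cl.vh_ceil) rescale_row(X, a, d, cl.vh_ceil);
    }
  }
  for (int i = 0; i < n; ++i) {
    double r = std::sqrt(row_norm2(X, i, d));
    if (r > cl.outer) rescale_row(X, i, d, cl.outer);
  }
}

// nearest-cone rule for multi-cone members
static bool nearest_cone_ok(const std::vector<double>& X, int d, int xi,
                            int yi, double K,
                            const std::vector<std::vector<int> >& mem_apex) {
  const std::vector<int>& ap = mem_apex[yi];
  if (ap.size() < 2) return true;
  double v_this = NA_REAL, v_min = R_PosInf;
  for (size_t i = 0; i < ap.size(); ++i) {
    int a = ap[i];
    double ra = std::sqrt(row_norm2(X, a, d));
    double psi = aperture(ra, K);
    double v = ISNAN(psi) ? 0.0
                          : angle_at(&X[a * d], &X[yi * d], d) - psi;
    if (a == xi) v_this = v;
    if (v < v_min) v_min = v;
  }
  return !ISNAN(v_this) && v_this <= v_min + 0.01;
}

static void structural_sweep(std::vector<double>& X, int d, const Cfg& cfg,
                             bool cones_on,
                             const std::vector<int>& edge_src,
                             const std::vector<int>& edge_dst,
                             const std::vector<int>& edge_struct,
                             const std::vector<int>& edge_apex,
                             const std::vector<int>& edge_member,
                             const std::vector<int>& roots,
                             const std::vector<int>& apex_idx,
                             const std::vector<int>& parent_idx,
                             const std::vector<int>& vh_apex_idx,
                             const std::vector<std::vector<int> >& mem_apex,
                             const Clamps& cl, int n, double landing,
                             double axis_rot, double rot_cap) {
  int m = edge_src.size();
  for (int e = 0; e < m; ++e) {
    if (edge_struct[e] == 1) {
      prox_ordering(X, edge_src[e], edge_dst[e], d, cfg);
      if (cones_on && cfg.lambda_cone > 0 &&
          nearest_cone_ok(X, d, edge_src[e], edge_dst[e], cfg.K, mem_apex)) {
        prox_cone(X, edge_src[e], edge_dst[e], d, cfg, cfg.lambda_cone,
                  landing, axis_rot, rot_cap);
      }
    } else if (edge_struct[e] == 2 && cones_on && cfg.lambda_nonhier > 0 &&
               nearest_cone_ok(X, d, edge_apex[e], edge_member[e], cfg.K,
                               mem_apex)) {
      prox_cone(X, edge_apex[e], edge_member[e], d, cfg, cfg.lambda_nonhier,
                landing, axis_rot, rot_cap);
    }
  }
  prox_roots(X, roots, d, cfg);
  bool use_cones = cfg.lambda_cone > 0 || cfg.lambda_nonhier > 0;
  clamp_all(X, d, apex_idx, parent_idx, vh_apex_idx, cl, use_cones && cones_on,
            n);
}

// hyperbolic distance and its Euclidean gradients for one (u, cand) pair
struct DistGrad {
  double dist;
  std::vector<double> gu, gv;
};

static void dist_grad_pair(const std::vector<double>& X, int u, int v, int d,
                           DistGrad& out) {
  double su = row_norm2(X, u, d), sv = row_norm2(X, v, d);
  double sq = 0, uv = 0;
  for (int j = 0; j < d; ++j) {
    double df = X[u * d + j] - X[v * d + j];
    sq += df * df;
    uv += X[u * d + j] * X[v * d + j];
  }
  double a = 1 - su, b = 1 - sv;
  double gam = 1 + 2 * sq / (a * b);
  out.dist = std::acosh(gam);
  double den = std::sqrt(std::max(gam * gam - 1.0, 0.0));
  if (den < EPS_DENOM) den = EPS_DENOM;
  double cu = 4.0 / (b * den), cv = 4.0 / (a * den);
  double Au = (sv - 2 * uv + 1) / (a * a);
  double Av = (su - 2 * uv + 1) / (b * b);
  out.gu.resize(d);
  out.gv.resize(d);
  for (int j = 0; j < d; ++j) {
    out.gu[j] = cu * (Au * X[u * d + j] - X[v * d + j] / a);
    out.gv[j] = cv * (Av * X[v * d + j] - X[u * d + j] / b);
  }
}

// [[Rcpp::export]]
List cpp_train(NumericMatrix X0, List cfg_list, IntegerVector edge_src,
               IntegerVector edge_dst, IntegerVector edge_struct,
               IntegerVector edge_apex, IntegerVector edge_member,
               IntegerVector root_idx, IntegerVector apex_idx,
               IntegerVector parent_idx, IntegerVector vh_apex_idx,
               List candidates, List member_apexes,
               IntegerVector hier_parent, IntegerVector hier_child,
               IntegerVector vh_h, IntegerVector vh_v) {
  Cfg cfg;
  cfg.dim = as<int>(cfg_list["dim"]);
  cfg.n_negatives = as<int>(cfg_list["n_negatives"]);
  cfg.burn_in_epochs = as<int>(cfg_list["burn_in_epochs"]);
  cfg.cone_warmup_epochs = as<int>(cfg_list["cone_warmup_epochs"]);
  cfg.epochs = as<int>(cfg_list["epochs"]);
  cfg.polish_sweeps = as<int>(cfg_list["polish_sweeps"]);
  cfg.final_sweeps = as<int>(cfg_list["final_sweeps"]);
  cfg.delta = as<double>(cfg_list["delta"]);
  cfg.K = as<double>(cfg_list["K"]);
  cfg.margin = as<double>(cfg_list["margin"]);
  cfg.lambda_root = as<double>(cfg_list["lambda_root"]);
  cfg.lambda_child = as<double>(cfg_list["lambda_child"]);
  cfg.lambda_cone = as<double>(cfg_list["lambda_cone"]);
  cfg.lambda_nonhier = as<double>(cfg_list["lambda_nonhier"]);
  cfg.lr = as<double>(cfg_list["lr"]);
  cfg.burn_in_factor = as<double>(cfg_list["burn_in_factor"]);
  cfg.anneal_frac = as<double>(cfg_list["anneal_frac"]);
  cfg.anneal_floor = as<double>(cfg_list["anneal_floor"]);
  cfg.eps_ball = as<double>(cfg_list["eps_ball"]);
  cfg.max_step = as<double>(cfg_list["max_step"]);

  int n = X0.nrow(), d = X0.ncol();
  std::vector<double> X(n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) X[i * d + j] = X0(i, j);

  int m = edge_src.size();
  std::vector<int> esrc(m), edst(m), estr(m), eapx(m), emem(m);
  for (int e = 0; e < m; ++e) {
    esrc[e] = edge_src[e] - 1;
    edst[e] = edge_dst[e] - 1;
    estr[e] = edge_struct[e];
    eapx[e] = edge_apex[e] == NA_INTEGER ? -1 : edge_apex[e] - 1;
    emem[e] = edge_member[e] == NA_INTEGER ? -1 : edge_member[e] - 1;
  }
  std::vector<int> roots(root_idx.size()), apexs(apex_idx.size()),
      parents(parent_idx.size()), vhapex(vh_apex_idx.size());
  for (int i = 0; i < root_idx.size(); ++i) roots[i] = root_idx[i] - 1;
  for (int i = 0; i < apex_idx.size(); ++i) apexs[i] = apex_idx[i] - 1;
  for (int i = 0; i < parent_idx.size(); ++i) parents[i] = parent_idx[i] - 1;
  for (int i = 0; i < vh_apex_idx.size(); ++i) vhapex[i] = vh_apex_idx[i] - 1;

  std::vector<std::vector<int> > cand(n), mem_apex(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ci = candidates[i];
    cand[i].assign(ci.begin(), ci.end());
    for (size_t j = 0; j < cand[i].size(); ++j) cand[i][j] -= 1;
    if (!Rf_isNull(member_apexes[i])) {
      IntegerVector mi = member_apexes[i];
      mem_apex[i].assign(mi.begin(), mi.end());
      for (size_t j = 0; j < mem_apex[i].size(); ++j) mem_apex[i][j] -= 1;
    }
  }

  int nh = hier_parent.size(), nvh = vh_h.size();
  std::vector<int> hp(nh), hc(nh), vhh(nvh), vhv(nvh);
  for (int i = 0; i < nh; ++i) { hp[i] = hier_parent[i] - 1; hc[i] = hier_child[i] - 1; }
  for (int i = 0; i < nvh; ++i) { vhh[i] = vh_h[i] - 1; vhv[i] = vh_v[i] - 1; }

  Clamps cl;
  cl.floor_r = cone_r_min_c(cfg.K) * 1.05;
  cl.parent_ceil = apex_ceiling_c(cfg.K, 0.15);
  cl.vh_ceil = apex_ceiling_c(cfg.K, 0.1);
  cl.outer = apex_ceiling_c(cfg.K, 0.05);
  bool use_cones = cfg.lambda_cone > 0 || cfg.lambda_nonhier > 0;

  int anneal_start = cfg.epochs - (int)std::floor(cfg.anneal_frac * cfg.epochs);
  int k = cfg.n_negatives;
  int k1 = k + 1;
  bool replacement_warned = false;

  // hard-negative table
  int n_hard = std::min(10, k);
  std::vector<std::vector<int> > hard(n);
  NumericMatrix log_mat(cfg.epochs, 11);
  std::vector<int> stream_u(2 * m), stream_v(2 * m), perm(2 * m);
  std::vector<int> negs(k);
  std::vector<DistGrad> dg(k1);
  std::vector<double> gu(d);

  for (int epoch = 1; epoch <= cfg.epochs; ++epoch) {
    double lr_mult;
    if (epoch <= cfg.burn_in_epochs) lr_mult = cfg.burn_in_factor;
    else if (cfg.anneal_frac <= 0 || epoch <= anneal_start) lr_mult = 1.0;
    else {
      int span = cfg.epochs - anneal_start;
      double t = (double)(epoch - anneal_start) / std::max(span, 1);
      lr_mult = 1 - (1 - cfg.anneal_floor) * t;
    }
    double lr_eff = cfg.lr * lr_mult;
    bool cones_on = epoch > cfg.cone_warmup_epochs;

    if ((epoch - 1) % 10 == 0) {
      // refresh hard negatives: rank candidates by the acosh argument
      for (int i = 0; i < n; ++i) {
        std::vector<int>& ci = cand[i];
        if (ci.empty()) { hard[i].clear(); continue; }
        int nh_i = std::min((size_t)n_hard, ci.size());
        std::vector<std::pair<double, int> > score(ci.size());
        double si = row_norm2(X, i, d);
        for (size_t q = 0; q < ci.size(); ++q) {
          int cq = ci[q];
          double sq2 = 0;
          for (int j = 0; j < d; ++j) {
            double df = X[i * d + j] - X[cq * d + j];
            sq2 += df * df;
          }
          double gam = 1 + 2 * sq2 / ((1 - si) * (1 - row_norm2(X, cq, d)));
          score[q] = std::make_pair(gam, cq);
        }
        std::partial_sort(score.begin(), score.begin() + nh_i, score.end());
        hard[i].resize(nh_i);
        for (int q = 0; q < nh_i; ++q) hard[i][q] = score[q].second;
      }
    }

    double base_sum = 0;
    if (m) {
      for (int e = 0; e < m; ++e) {
        stream_u[e] = esrc[e]; stream_v[e] = edst[e];
        stream_u[m + e] = edst[e]; stream_v[m + e] = esrc[e];
      }
      for (int e = 0; e < 2 * m; ++e) perm[e] = e;
      for (int e = 2 * m - 1; e > 0; --e) {
        int j = rand_below(e + 1);
        std::swap(perm[e], perm[j]);
      }
      for (int pe = 0; pe < 2 * m; ++pe) {
        int e = perm[pe];
        int u = stream_u[e];
        std::vector<int>& pool = cand[u];
        int np = pool.size();
        if (np < k) {
          if (!replacement_warned) replacement_warned = true;
          for (int q = 0; q < k; ++q) negs[q] = pool[rand_below(np)];
        } else {
          // half hard negatives, half uniform from the remainder
          std::vector<int>& hp_u = hard[u];
          int k_hard = std::min((int)hp_u.size(), k / 2);
          std::vector<int> taken;
          // sample k_hard distinct from hard pool
          {
            std::vector<int> tmp(hp_u);
            for (int q = 0; q < k_hard; ++q) {
              int j = q + rand_below((int)tmp.size() - q);
              std::swap(tmp[q], tmp[j]);
              negs[q] = tmp[q];
            }
          }
          // uniform from pool minus chosen (rejection; chosen list tiny)
          int q = k_hard;
          while (q < k) {
            int cq = pool[rand_below(np)];
            bool dup = false;
            for (int t = 0; t < q; ++t) if (negs[t] == cq) { dup = true; break; }
            if (!dup) negs[q++] = cq;
          }
        }
        // distances + gradients u vs {v, negs}
        int cand_ids[64];
        cand_ids[0] = stream_v[e];
        for (int q = 0; q < k; ++q) cand_ids[q + 1] = negs[q];
        double mn = R_PosInf;
        for (int q = 0; q < k1; ++q) {
          dist_grad_pair(X, u, cand_ids[q], d, dg[q]);
          if (dg[q].dist < mn) mn = dg[q].dist;
        }
        double Z = 0;
        for (int q = 0; q < k1; ++q) Z += std::exp(-(dg[q].dist - mn));
        base_sum += dg[0].dist + std::log(Z) - mn;
        // weights: softmax minus, +1 on positive
        double fac_u = (1 - row_norm2(X, u, d));
        fac_u = fac_u * fac_u / 4.0;
        for (int j = 0; j < d; ++j) gu[j] = 0;
        for (int q = 0; q < k1; ++q) {
          double w = -std::exp(-(dg[q].dist - mn)) / Z + (q == 0 ? 1.0 : 0.0);
          for (int j = 0; j < d; ++j) gu[j] += w * dg[q].gu[j];
          // step candidate q
          int t = cand_ids[q];
          double fac_t = (1 - row_norm2(X, t, d));
          fac_t = fac_t * fac_t / 4.0;
          double sn = 0;
          for (int j = 0; j < d; ++j) {
            double s = lr_eff * fac_t * w * dg[q].gv[j];
            sn += s * s;
          }
          double cp = clip_factor(std::sqrt(sn), cfg.max_step);
          for (int j = 0; j < d; ++j)
            X[t * d + j] -= cp * lr_eff * fac_t * w * dg[q].gv[j];
          project_row(X, t, d, cfg.eps_ball);
        }
        double sn = 0;
        for (int j = 0; j < d; ++j) {
          double s = lr_eff * fac_u * gu[j];
          sn += s * s;
        }
        double cp = clip_factor(std::sqrt(sn), cfg.max_step);
        for (int j = 0; j < d; ++j) X[u * d + j] -= cp * lr_eff * fac_u * gu[j];
        project_row(X, u, d, cfg.eps_ball);

        // structural projections for this edge (first copy only)
        if (e < m) {
          if (estr[e] == 1) {
            prox_ordering(X, esrc[e], edst[e], d, cfg);
            if (cones_on && cfg.lambda_cone > 0 &&
                nearest_cone_ok(X, d, esrc[e], edst[e], cfg.K, mem_apex)) {
              prox_cone(X, esrc[e], edst[e], d, cfg, cfg.lambda_cone, 0.95,
                        0.005, 0.05);
            }
          } else if (estr[e] == 2 && cones_on && cfg.lambda_nonhier > 0 &&
                     nearest_cone_ok(X, d, eapx[e], emem[e], cfg.K,
                                     mem_apex)) {
            prox_cone(X, eapx[e], emem[e], d, cfg, cfg.lambda_nonhier, 0.95,
                      0.005, 0.05);
          }
        }
      }
    }
    if (!R_FINITE(base_sum)) stop("non-finite loss term: base");

    prox_roots(X, roots, d, cfg);
    if (cones_on && epoch > anneal_start && cfg.polish_sweeps > 0) {
      for (int s = 0; s < cfg.polish_sweeps; ++s) {
        structural_sweep(X, d, cfg, cones_on, esrc, edst, estr, eapx, emem,
                         roots, apexs, parents, vhapex, mem_apex, cl, n, 0.95,
                         0.005, 0.1);
      }
    }
    clamp_all(X, d, apexs, parents, vhapex, cl, use_cones, n);

    // ---- logging: penalty values + satisfaction rates -----------------
    double root_pen = 0, child_pen = 0, cone_h = 0, cone_v = 0;
    double root_rate = NA_REAL, order_rate = NA_REAL, cone_rate = NA_REAL;
    if (!roots.empty()) {
      int sat = 0;
      for (size_t i = 0; i < roots.size(); ++i) {
        double d0 = origin_dist(std::sqrt(row_norm2(X, roots[i], d)));
        root_pen += std::max(0.0, d0 - cfg.delta);
        if (d0 < cfg.delta) ++sat;
      }
      root_rate = (double)sat / roots.size();
    }
    if (nh) {
      int sat = 0, elig = 0, in_cone_n = 0;
      for (int i = 0; i < nh; ++i) {
        double dp = origin_dist(std::sqrt(row_norm2(X, hp[i], d)));
        double dc = origin_dist(std::sqrt(row_norm2(X, hc[i], d)));
        child_pen += std::max(0.0, dp - dc + cfg.margin);
        if (dp < dc) ++sat;
        double ra = std::sqrt(row_norm2(X, hp[i], d));
        double psi = aperture(ra, cfg.K);
        if (!ISNAN(psi)) {
          double ang = angle_at(&X[hp[i] * d], &X[hc[i] * d], d);
          cone_h += std::max(0.0, ang - psi);
          ++elig;
          if (ang <= psi) ++in_cone_n;
        }
      }
      order_rate = (double)sat / nh;
      if (elig) cone_rate = (double)in_cone_n / elig;
    }
    for (int i = 0; i < nvh; ++i) {
      double ra = std::sqrt(row_norm2(X, vhh[i], d));
      double psi = aperture(ra, cfg.K);
      if (!ISNAN(psi)) {
        double ang = angle_at(&X[vhh[i] * d], &X[vhv[i] * d], d);
        cone_v += std::max(0.0, ang - psi);
      }
    }
    double max_norm = 0;
    for (int i = 0; i < n; ++i)
      max_norm = std::max(max_norm, row_norm2(X, i, d));
    max_norm = std::sqrt(max_norm);
    double total = base_sum + cfg.lambda_root * root_pen +
                   cfg.lambda_child * child_pen + cfg.lambda_cone * cone_h +
                   cfg.lambda_nonhier * cone_v;
    if (!R_FINITE(total)) stop("non-finite loss term: penalties");
    log_mat(epoch - 1, 0) = epoch;
    log_mat(epoch - 1, 1) = total;
    log_mat(epoch - 1, 2) = base_sum;
    log_mat(epoch - 1, 3) = root_pen;
    log_mat(epoch - 1, 4) = child_pen;
    log_mat(epoch - 1, 5) = cone_h;
    log_mat(epoch - 1, 6) = cone_v;
    log_mat(epoch - 1, 7) = root_rate;
    log_mat(epoch - 1, 8) = order_rate;
    log_mat(epoch - 1, 9) = cone_rate;
    log_mat(epoch - 1, 10) = max_norm;
  }

  // settling phase: damped-axis alternating projections, members landing
  // well inside their cones
  if (cfg.epochs > 0 && cfg.final_sweeps > 0) {
    bool cones_on = cfg.epochs >= cfg.cone_warmup_epochs;
    for (int s = 0; s < cfg.final_sweeps; ++s) {
      structural_sweep(X, d, cfg, cones_on, esrc, edst, estr, eapx, emem,
                       roots, apexs, parents, vhapex, mem_apex, cl, n, 0.7,
                       0.01, R_PosInf);
    }
  }

  NumericMatrix Xout(n, d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) Xout(i, j) = X[i * d + j];
  return List::create(_["X"] = Xout, _["log"] = log_mat,
                      _["replacement"] = replacement_warned);
}
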