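#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"
using namespace Rcpp;

// Probabilistic streamline propagation under a per-voxel Watson orientation
// mixture. Euler integration in world mm; voxel lookup through the inverse
// affine; bidirectional tracking from each seed with both halves concatenated.
//
// Model arrays come in R column-major order:
//   mu    : (nx, ny, nz, K, 3)   compartment mean orientations (unit)
//   kappa : (nx, ny, nz, K)      Watson concentrations (Inf = deterministic)
//   frac  : (nx, ny, nz, K)      mixture weights, sum to 1 over compartments
//   ncomp : (nx, ny, nz)         number of valid compartments per voxel

struct Model {
  const double *mu, *kappa, *frac;
  const int *ncomp;
  int nx, ny, nz, K;
  long NV;
};

struct Params {
  int max_steps;
  double step, curv;
};

static inline long vox_index(const Model &m, int i, int j, int k) {
  return i + (long)m.nx * (j + (long)m.ny * k);
}

static inline bool in_grid(const Model &m, int i, int j, int k) {
  return i >= 0 && j >= 0 && k >= 0 && i < m.nx && j < m.ny && k < m.nz;
}

// world point -> containing voxel (nearest index); returns -1 if outside grid
static inline long point_voxel(const Model &m, const double *Ainv,
                               const double p[3]) {
  double idx[3];
  for (int r = 0; r < 3; ++r)
    idx[r] = Ainv[r] * p[0] + Ainv[r + 4] * p[1] + Ainv[r + 8] * p[2] +
             Ainv[r + 12];
  int i = (int)std::lround(idx[0]);
  int j = (int)std::lround(idx[1]);
  int k = (int)std::lround(idx[2]);
  if (!in_grid(m, i, j, k)) return -1;
  return vox_index(m, i, j, k);
}

static inline void orthonormal_frame(const double mu[3], double e1[3],
                                     double e2[3]) {
  double a[3] = {1.0, 0.0, 0.0};
  if (std::fabs(mu[0]) > 0.9) { a[0] = 0.0; a[1] = 1.0; }
  e1[0] = mu[1] * a[2] - mu[2] * a[1];
  e1[1] = mu[2] * a[0] - mu[0] * a[2];
  e1[2] = mu[0] * a[1] - mu[1] * a[0];
  double n = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int d = 0; d < 3; ++d) e1[d] /= n;
  e2[0] = mu[1] * e1[2] - mu[2] * e1[1];
  e2[1] = mu[2] * e1[0] - mu[0] * e1[2];
  e2[2] = mu[0] * e1[1] - mu[1] * e1[0];
}

// Sample a direction at voxel v. prev == NULL on the very first draw;
// otherwise the sign is aligned so dot(prev, out) >= 0. Returns false when
// the voxel carries no orientation model.
static bool sample_dir(const Model &m, long v, const double *prev, Pcg32 &rng,
                       double out[3]) {
  int nc = m.ncomp[v];
  if (nc < 1) return false;
  int c = 0;
  if (nc > 1) {
    double u = rng.unif(), acc = 0.0;
    for (c = 0; c < nc - 1; ++c) {
      acc += m.frac[v + m.NV * c];
      if (u < acc) break;
    }
  }
  double mu[3], e1[3], e2[3];
  for (int d = 0; d < 3; ++d) mu[d] = m.mu[v + m.NV * (c + m.K * d)];
  double kap = m.kappa[v + m.NV * c];
  orthonormal_frame(mu, e1, e2);
  watson_draw(mu, e1, e2, kap, rng, out);
  if (prev) {
    double dp = prev[0] * out[0] + prev[1] * out[1] + prev[2] * out[2];
    if (dp < 0) { out[0] = -out[0]; out[1] = -out[1]; out[2] = -out[2]; }
  }
  return true;
}

// Propagate one direction from x0 with initial direction d0, appending points
// (never the seed itself). Termination: leaving the mask/grid, curvature
// cosine below threshold, or max_steps.
static void track_half(const Model &m, const double *Ainv, const int *mask,
                       const Params &par, const double x0[3],
                       const double d0[3], Pcg32 &rng,
                       std::vector<double> &pts) {
  double x[3] = {x0[0], x0[1], x0[2]};
  double d[3] = {d0[0], d0[1], d0[2]};
  for (int s = 0; s < par.max_steps; ++s) {
    double xn[3] = {x[0] + par.step * d[0], x[1] + par.step * d[1],
                    x[2] + par.step * d[2]};
    long v = point_voxel(m, Ainv, xn);
    if (v < 0 || !mask[v]) break;
    pts.push_back(xn[0]); pts.push_back(xn[1]); pts.push_back(xn[2]);
    double dn[3];
    if (!sample_dir(m, v, d, rng, dn)) break;
    double dp = d[0] * dn[0] + d[1] * dn[1] + d[2] * dn[2];
    if (dp < par.curv) break;
    x[0] = xn[0]; x[1] = xn[1]; x[2] = xn[2];
    d[0] = dn[0]; d[1] = dn[1]; d[2] = dn[2];
  }
}

// Full bidirectional streamline: reversed backward half + seed + forward half.
// Row-major triplets in `out`.
static bool track_one(const Model &m, const double *Ainv, const int *mask,
                      const Params &par, const double seed_pt[3], Pcg32 &rng,
                      std::vector<double> &out) {
  long v0 = point_voxel(m, Ainv, seed_pt);
  if (v0 < 0 || !mask[v0]) return false;
  double d0[3];
  if (!sample_dir(m, v0, (const double *)0, rng, d0)) {
    out.push_back(seed_pt[0]); out.push_back(seed_pt[1]);
    out.push_back(seed_pt[2]);
    return true;
  }
  std::vector<double> back, fwd;
  double dneg[3] = {-d0[0], -d0[1], -d0[2]};
  track_half(m, Ainv, mask, par, seed_pt, dneg, rng, back);
  track_half(m, Ainv, mask, par, seed_pt, d0, rng, fwd);
  size_t nb = back.size() / 3;
  for (size_t i = nb; i > 0; --i) {
    out.push_back(back[3 * (i - 1)]);
    out.push_back(back[3 * (i - 1) + 1]);
    out.push_back(back[3 * (i - 1) + 2]);
  }
  out.push_back(seed_pt[0]); out.push_back(seed_pt[1]); out.push_back(seed_pt[2]);
  out.insert(out.end(), fwd.begin(), fwd.end());
  return true;
}

// Unique-visitation counting: each streamline increments a voxel at most once.
// Segments are sampled at intervals <= max_seg so no traversed voxel is
// skipped; `stamp` carries the last streamline id that touched each voxel.
static void count_streamline(const Model &m, const double *Ainv,
                             const int *cmask, const std::vector<double> &pts,
                             int sid, std::vector<int> &stamp,
                             std::vector<int> &cnt, double max_seg) {
  size_t np = pts.size() / 3;
  if (np == 0) return;
  double prev[3] = {pts[0], pts[1], pts[2]};
  long v = point_voxel(m, Ainv, prev);
  if (v >= 0 && cmask[v] && stamp[v] != sid) { stamp[v] = sid; cnt[v]++; }
  for (size_t p = 1; p < np; ++p) {
    double cur[3] = {pts[3 * p], pts[3 * p + 1], pts[3 * p + 2]};
    double dx = cur[0] - prev[0], dy = cur[1] - prev[1], dz = cur[2] - prev[2];
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    int nsub = (int)std::ceil(len / max_seg);
    if (nsub < 1) nsub = 1;
    for (int s = 1; s <= nsub; ++s) {
      double f = (double)s / nsub;
      double q[3] = {prev[0] + f * dx, prev[1] + f * dy, prev[2] + f * dz};
      long qv = point_voxel(m, Ainv, q);
      if (qv >= 0 && cmask[qv] && stamp[qv] != sid) { stamp[qv] = sid; cnt[qv]++; }
    }
    prev[0] = cur[0]; prev[1] = cur[1]; prev[2] = cur[2];
  }
}

static Model make_model(const NumericVector &mu, const NumericVector &kappa,
                        const NumericVector &frac, const IntegerVector &ncomp,
                        const IntegerVector &dims, int K) {
  Model m;
  m.mu = mu.begin(); m.kappa = kappa.begin(); m.frac = frac.begin();
  m.ncomp = ncomp.begin();
  m.nx = dims[0]; m.ny = dims[1]; m.nz = dims[2];
  m.K = K;
  m.NV = (long)m.nx * m.ny * m.nz;
  return m;
}

// [[Rcpp::export]]
List cpp_whole_brain_track(NumericVector mu, NumericVector kappa,
                           NumericVector frac, IntegerVector ncomp,
                           IntegerVector dims, int K, IntegerVector mask,
                           NumericMatrix affine, NumericMatrix affine_inv,
                           IntegerMatrix seed_voxels, int n_per_voxel,
                           int max_steps, double step_length, double curv,
                           double rng_seed, bool return_streamlines,
                           bool count_visits, IntegerVector count_mask,
                           double max_seg) {
  Model m = make_model(mu, kappa, frac, ncomp, dims, K);
  Params par; par.max_steps = max_steps; par.step = step_length; par.curv = curv;
  const double *Ainv = affine_inv.begin();
  const double *A = affine.begin();
  int nseed = seed_voxels.nrow();
  long total = (long)nseed * n_per_voxel;

  List out_lines(return_streamlines ? (int)total : 0);
  std::vector<int> stamp, cnt;
  if (count_visits) {
    stamp.assign(m.NV, -1);
    cnt.assign(m.NV, 0);
  }
  std::vector<double> pts;
  long sid = 0;
  for (int s = 0; s < nseed; ++s) {
    int i = seed_voxels(s, 0), j = seed_voxels(s, 1), k = seed_voxels(s, 2);
    long vlin = vox_index(m, i, j, k);
    double seed_pt[3];
    for (int r = 0; r < 3; ++r)
      seed_pt[r] = A[r] * i + A[r + 4] * j + A[r + 8] * k + A[r + 12];
    for (int t = 0; t < n_per_voxel; ++t, ++sid) {
      Pcg32 rng;
      rng.seed((uint64_t)rng_seed, (uint64_t)vlin, (uint64_t)t);
      pts.clear();
      if (!track_one(m, Ainv, mask.begin(), par, seed_pt, rng, pts))
        stop("seed voxel outside mask");
      if (count_visits)
        count_streamline(m, Ainv, count_mask.begin(), pts, (int)sid, stamp,
                         cnt, max_seg);
      if (return_streamlines) {
        size_t np = pts.size() / 3;
        NumericMatrix sm((int)np, 3);
        for (size_t p = 0; p < np; ++p) {
          sm(p, 0) = pts[3 * p]; sm(p, 1) = pts[3 * p + 1];
          sm(p, 2) = pts[3 * p + 2];
        }
        out_lines[(int)sid] = sm;
      }
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  List res;
  res["n_streamlines"] = (double)total;
  if (return_streamlines) res["streamlines"] = out_lines;
  if (count_visits) {
    IntegerVector acm(cnt.begin(), cnt.end());
    res["acm"] = acm;
  }
  return res;
}

// [[Rcpp::export]]
NumericMatrix cpp_track_one(NumericVector mu, NumericVector kappa,
                            NumericVector frac, IntegerVector ncomp,
                            IntegerVector dims, int K, IntegerVector mask,
                            NumericMatrix affine_inv, NumericVector seed_point,
                            int max_steps, double step_length, double curv,
                            double rng_seed, double voxel_key,
                            double stream_key) {
  Model m = make_model(mu, kappa, frac, ncomp, dims, K);
  Params par; par.max_steps = max_steps; par.step = step_length; par.curv = curv;
  Pcg32 rng;
  rng.seed((uint64_t)rng_seed, (uint64_t)voxel_key, (uint64_t)stream_key);
  double sp[3] = {seed_point[0], seed_point[1], seed_point[2]};
  std::vector<double> pts;
  if (!track_one(m, affine_inv.begin(), mask.begin(), par, sp, rng, pts))
    stop("seed point outside mask");
  size_t np = pts.size() / 3;
  NumericMatrix sm((int)np, 3);
  for (size_t p = 0; p < np; ++p) {
    sm(p, 0) = pts[3 * p]; sm(p, 1) = pts[3 * p + 1]; sm(p, 2) = pts[3 * p + 2];
  }
  return sm;
}

// [[Rcpp::export]]
IntegerVector cpp_count_visits(List streamlines, NumericMatrix affine_inv,
                               IntegerVector dims, IntegerVector mask,
                               double max_seg) {
  Model m;
  m.nx = dims[0]; m.ny = dims[1]; m.nz = dims[2];
  m.NV = (long)m.nx * m.ny * m.nz;
  m.K = 0; m.mu = 0; m.kappa = 0; m.frac = 0; m.ncomp = 0;
  std::vector<int> stamp(m.NV, -1), cnt(m.NV, 0);
  int n = streamlines.size();
  std::vector<double> pts;
  for (int s = 0; s < n; ++s) {
    NumericMatrix sm = streamlines[s];
    int np = sm.nrow();
    pts.resize((size_t)np * 3);
    for (int p = 0; p < np; ++p) {
      pts[3 * p] = sm(p, 0); pts[3 * p + 1] = sm(p, 1); pts[3 * p + 2] = sm(p, 2);
    }
    count_streamline(m, affine_inv.begin(), mask.begin(), pts, s, stamp, cnt,
                     max_seg);
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return IntegerVector(cnt.begin(), cnt.end());
}

// [[Rcpp::export]]
NumericVector cpp_watson_sample(NumericVector mean_dir, double kappa, int n,
                                double rng_seed) {
  Pcg32 rng;
  rng.seed((uint64_t)rng_seed, 0, 0);
  double mu[3] = {mean_dir[0], mean_dir[1], mean_dir[2]};
  double e1[3], e2[3];
  orthonormal_frame(mu, e1, e2);
  NumericVector out(3 * n);
  double x[3];
  for (int i = 0; i < n; ++i) {
    watson_draw(mu, e1, e2, kappa, rng, x);
    out[3 * i] = x[0]; out[3 * i + 1] = x[1]; out[3 * i + 2] = x[2];
  }
  out.attr("dim") = Dimension(3, n);
  return out;
}
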