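#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Threshold-free cluster enhancement by discrete threshold integration:
//   TFCE(v) = sum_{h = dh, 2dh, ... <= stat(v)} extent(cluster_h(v))^E * h^H * dh
// where cluster_h(v) is the connected component of {stat >= h} containing v.
// Connectivity: 6 (faces), 18 (+edges) or 26 (+corners).

static void neighbour_offsets(int conn, std::vector<int> &di,
                              std::vector<int> &dj, std::vector<int> &dk) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        if (nz == 0) continue;
        if (conn == 6 && nz > 1) continue;
        if (conn == 18 && nz > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
}

// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector stat, IntegerVector dims, double E,
                       double H, double dh, int conn) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long NV = (long)nx * ny * nz;
  NumericVector out(NV);
  double maxv = 0.0;
  for (long v = 0; v < NV; ++v)
    if (stat[v] > maxv) maxv = stat[v];
  if (maxv <= 0.0 || dh <= 0.0) return out;

  std::vector<int> di, dj, dk;
  neighbour_offsets(conn, di, dj, dk);
  int noff = di.size();

  std::vector<int> label(NV), members, queue;
  double tol = 1e-12 * maxv;
  int nsteps = (int)std::floor(maxv / dh + 1e-9);
  for (int s = 1; s <= nsteps; ++s) {
    double h = s * dh;
    std::fill(label.begin(), label.end(), 0);
    int next_label = 0;
    for (long v0 = 0; v0 < NV; ++v0) {
      if (stat[v0] + tol < h || label[v0]) continue;
      ++next_label;
      members.clear(); queue.clear();
      queue.push_back((int)v0);
      label[v0] = next_label;
      while (!queue.empty()) {
        int v = queue.back(); queue.pop_back();
        members.push_back(v);
        int k = v / (nx * ny), rem = v % (nx * ny);
        int j = rem / nx, i = rem % nx;
        for (int o = 0; o < noff; ++o) {
          int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          long w = ii + (long)nx * (jj + (long)ny * kk);
          if (stat[w] + tol >= h && !label[w]) {
            label[w] = next_label;
            queue.push_back((int)w);
          }
        }
      }
      double add = std::pow((double)members.size(), E) * std::pow(h, H) * dh;
      for (size_t t = 0; t < members.size(); ++t) out[members[t]] += add;
    }
  }
  return out;
}
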