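#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 3D binary morphology with the face-connected (connectivity-one) structuring
// element. Voxels outside the grid count as background (scipy convention).

static inline int nb_or(const char* in, R_xlen_t idx, int i, int j, int k,
                        int nx, int ny, int nz, R_xlen_t sy, R_xlen_t sz) {
  return (i > 0 && in[idx - 1]) || (i < nx - 1 && in[idx + 1]) ||
         (j > 0 && in[idx - sy]) || (j < ny - 1 && in[idx + sy]) ||
         (k > 0 && in[idx - sz]) || (k < nz - 1 && in[idx + sz]);
}

static void morph_once(const char* in, char* out, int nx, int ny, int nz,
                       bool dilate) {
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t row = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      const bool edge_jk = (j == 0 || j == ny - 1 || k == 0 || k == nz - 1);
      if (!edge_jk && nx > 2) {
        // interior of the row: branchless, auto-vectorisable
        if (dilate) {
          for (int i = 1; i < nx - 1; ++i) {
            const R_xlen_t idx = row + i;
            out[idx] = in[idx] | in[idx - 1] | in[idx + 1] |
                       in[idx - sy] | in[idx + sy] |
                       in[idx - sz] | in[idx + sz];
          }
        } else {
          for (int i = 1; i < nx - 1; ++i) {
            const R_xlen_t idx = row + i;
            out[idx] = in[idx] & in[idx - 1] & in[idx + 1] &
                       in[idx - sy] & in[idx + sy] &
                       in[idx - sz] & in[idx + sz];
          }
        }
        for (int i = 0; i < nx; i += nx - 1) {   // row ends
          const R_xlen_t idx = row + i;
          out[idx] = dilate
            ? (in[idx] | nb_or(in, idx, i, j, k, nx, ny, nz, sy, sz))
            : 0; // erosion: row-end voxels border the outside (background)
        }
      } else {
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t idx = row + i;
          if (dilate)
            out[idx] = in[idx] | nb_or(in, idx, i, j, k, nx, ny, nz, sy, sz);
          else
            out[idx] = 0; // voxels on a j/k face erode away (outside = 0)
        }
      }
    }
}

// [[Rcpp::export(name = ".morph_cpp")]]
IntegerVector morph_cpp(IntegerVector mask, IntegerVector dim, int iters,
                        bool dilate) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (iters < 1) return clone(mask);
  const R_xlen_t n = mask.size();
  // byte working buffers: a quarter of the memory traffic of int masks
  std::vector<char> a(n), b(n);
  const int* pm = INTEGER(mask);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = (char)(pm[i] != 0);
  char* pa = a.data();
  char* pb = b.data();
  for (int t = 0; t < iters; ++t) {
    morph_once(pa, pb, nx, ny, nz, dilate);
    std::swap(pa, pb);
  }
  IntegerVector out(n);
  out.attr("dim") = dim;
  int* po = INTEGER(out);
  for (R_xlen_t i = 0; i < n; ++i) po[i] = pa[i];
  return out;
}

static const int NB26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},
  {0,1,-1},{1,1,-1},{-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{1,0,0},
  {-1,1,0},{0,1,0},{1,1,0},{-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},
  {1,0,1},{-1,1,1},{0,1,1},{1,1,1}};
static const int NB6[6][3] = {
  {-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};

// Connected-component labelling; connectivity 6 (faces) or 26 (full cube).
// Components are numbered 1..n in scan order of their first (lowest linear
// index) voxel, giving a deterministic tie-break.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int* pm = INTEGER(mask);
  IntegerVector lab(n);
  int* pl = INTEGER(lab);
  const int (*nb)[3] = (connectivity == 6) ? NB6 : NB26;
  const int nnb = (connectivity == 6) ? 6 : 26;
  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!pm[seed] || pl[seed]) continue;
    pl[seed] = ++next_label;
    q.push(seed);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int t = 0; t < nnb; ++t) {
        int ii = i + nb[t][0], jj = j + nb[t][1], kk = k + nb[t][2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t at = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (pm[at] && !pl[at]) { pl[at] = next_label; q.push(at); }
      }
    }
  }
  lab.attr("n_components") = next_label;
  return lab;
}

// Remove every 26-connected component that touches the x/y border zone
// (index < margin or >= dim - margin, 0-based; z exempt). Implemented as a
// flood fill seeded from masked voxels in the border zone, so only exterior
// components are visited.
// [[Rcpp::export(name = ".remove_border_components_cpp")]]
IntegerVector remove_border_components_cpp(IntegerVector mask,
                                           IntegerVector dim, int margin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out = clone(mask);
  if (margin <= 0) return out;
  int* pm = INTEGER(out);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> visited(n, 0);
  std::queue<R_xlen_t> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool border = (i < margin || i >= nx - margin ||
                       j < margin || j >= ny - margin);
        if (!border) { i = nx - margin - 1; continue; } // skip interior run
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (pm[idx] && !visited[idx]) { visited[idx] = 1; q.push(idx); }
      }
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int i = (int)(cur % nx);
    int j = (int)((cur / nx) % ny);
    int k = (int)(cur / ((R_xlen_t)nx * ny));
    for (int t = 0; t < 26; ++t) {
      int ii = i + NB26[t][0], jj = j + NB26[t][1], kk = k + NB26[t][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      R_xlen_t at = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (pm[at] && !visited[at]) { visited[at] = 1; q.push(at); }
    }
  }
  for (R_xlen_t idx = 0; idx < n; ++idx) if (visited[idx]) pm[idx] = 0;
  return out;
}

// Separable Catmull-Rom cubic interpolation along one axis.
// Output sample m maps to input coordinate m * scale (voxel-centre units);
// indices are clamped at the ends (edge-value padding).
static void cr_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2.0 * t2 - t);
  w[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
  w[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

// [[Rcpp::export(name = ".resample_axis_cpp")]]
NumericVector resample_axis_cpp(NumericVector vol, IntegerVector dim, int axis,
                                int n_out, double scale) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int od[3] = {nx, ny, nz};
  od[axis] = n_out;
  NumericVector out((R_xlen_t)od[0] * od[1] * od[2]);
  out.attr("dim") = IntegerVector::create(od[0], od[1], od[2]);
  const double* pv = REAL(vol);
  double* po = REAL(out);
  const int n_in = dim[axis];
  std::vector<R_xlen_t> ofs(4 * (size_t)n_out); // clamped input offsets
  std::vector<double> wts(4 * (size_t)n_out);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t stride_in = (axis == 0) ? sx : (axis == 1) ? sy : sz;
  for (int m = 0; m < n_out; ++m) {
    double pos = m * scale;
    int b = (int)std::floor(pos);
    cr_weights(pos - b, &wts[4 * (size_t)m]);
    for (int qq = -1; qq <= 2; ++qq) {
      int ii = b + qq;
      if (ii < 0) ii = 0;
      if (ii > n_in - 1) ii = n_in - 1;
      ofs[4 * (size_t)m + (qq + 1)] = (R_xlen_t)ii * stride_in;
    }
  }
  const R_xlen_t osx = 1, osy = od[0], osz = (R_xlen_t)od[0] * od[1];
  const R_xlen_t stride_out = (axis == 0) ? osx : (axis == 1) ? osy : osz;
  int a1 = (axis == 0) ? 1 : 0;
  int a2 = (axis == 2) ? 1 : 2;
  const R_xlen_t in_s1 = (a1 == 0) ? sx : (a1 == 1) ? sy : sz;
  const R_xlen_t in_s2 = (a2 == 0) ? sx : (a2 == 1) ? sy : sz;
  const R_xlen_t out_s1 = (a1 == 0) ? osx : (a1 == 1) ? osy : osz;
  const R_xlen_t out_s2 = (a2 == 0) ? osx : (a2 == 1) ? osy : osz;
  if (axis == 0) {
    for (int c2 = 0; c2 < dim[a2]; ++c2)
      for (int c1 = 0; c1 < dim[a1]; ++c1) {
        const double* in_line = pv + c1 * in_s1 + c2 * in_s2;
        double* out_line = po + c1 * out_s1 + c2 * out_s2;
        for (int m = 0; m < n_out; ++m) {
          const double* w = &wts[4 * (size_t)m];
          const R_xlen_t* o = &ofs[4 * (size_t)m];
          out_line[m] = w[0] * in_line[o[0]] + w[1] * in_line[o[1]] +
                        w[2] * in_line[o[2]] + w[3] * in_line[o[3]];
        }
      }
  } else {
    // axis 1 or 2: keep the unit-stride axis (a1 = x) innermost so reads
    // and writes stay sequential
    for (int c2 = 0; c2 < dim[a2]; ++c2)
      for (int m = 0; m < n_out; ++m) {
        const double* w = &wts[4 * (size_t)m];
        const R_xlen_t* o = &ofs[4 * (size_t)m];
        const double* in0 = pv + c2 * in_s2;
        double* out_line = po + (R_xlen_t)m * stride_out + c2 * out_s2;
        const int n1 = dim[a1];
        for (int c1 = 0; c1 < n1; ++c1)
          out_line[c1] = w[0] * in0[c1 + o[0]] + w[1] * in0[c1 + o[1]] +
                         w[2] * in0[c1 + o[2]] + w[3] * in0[c1 + o[3]];
      }
  }
  return out;
}

// Summed-score aggregation: each cube (1-based centre voxel index triplet)
// adds its probability over the voxels of its side^3 extent, window
// [c - side/2 + 1, c + side/2] per axis, clipped to the grid.
// [[Rcpp::export(name = ".aggregate_scores_cpp")]]
List aggregate_scores_cpp(IntegerVector dim, IntegerMatrix centres,
                          NumericVector probs, int side) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int half = side / 2;
  NumericVector score((R_xlen_t)nx * ny * nz);
  IntegerVector cover((R_xlen_t)nx * ny * nz);
  double* ps = REAL(score);
  int* pc = INTEGER(cover);
  for (int c = 0; c < centres.nrow(); ++c) {
    const double p = probs[c];
    int x0 = centres(c, 0) - half;     // 0-based inclusive start
    int y0 = centres(c, 1) - half;
    int z0 = centres(c, 2) - half;
    int x1 = x0 + side - 1, y1 = y0 + side - 1, z1 = z0 + side - 1;
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (z0 < 0) z0 = 0;
    if (x1 > nx - 1) x1 = nx - 1;
    if (y1 > ny - 1) y1 = ny - 1;
    if (z1 > nz - 1) z1 = nz - 1;
    for (int k = z0; k <= z1; ++k)
      for (int j = y0; j <= y1; ++j) {
        R_xlen_t off = x0 + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = x0; i <= x1; ++i, ++off) {
          ps[off] += p;
          pc[off] += 1;
        }
      }
  }
  score.attr("dim") = dim;
  cover.attr("dim") = dim;
  return List::create(_["summed_score"] = score, _["coverage"] = cover);
}

// [[Rcpp::export(name = ".threshold_leq_cpp")]]
IntegerVector threshold_leq_cpp(NumericVector vals, double thr) {
  IntegerVector out(vals.size());
  const double* pv = REAL(vals);
  int* po = INTEGER(out);
  for (R_xlen_t i = 0; i < vals.size(); ++i) po[i] = pv[i] <= thr ? 1 : 0;
  out.attr("dim") = vals.attr("dim");
  return out;
}

// [[Rcpp::export(name = ".threshold_gt_cpp")]]
IntegerVector threshold_gt_cpp(NumericVector vals, double thr,
                               IntegerVector dim) {
  IntegerVector out(vals.size());
  const double* pv = REAL(vals);
  int* po = INTEGER(out);
  for (R_xlen_t i = 0; i < vals.size(); ++i) po[i] = pv[i] > thr ? 1 : 0;
  out.attr("dim") = dim;
  return out;
}
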