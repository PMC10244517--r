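// Label-map morphology on 3-D integer volumes: connected components
// (6/26-connectivity), two-largest-component filtering, enclosed-cavity hole
// filling, per-slice boundary erosion, 6-connectivity boundary extraction and
// an exact anisotropic squared Euclidean distance transform
// (Felzenszwalb-Huttenlocher lower envelope, one pass per axis).
#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cfloat>
#include <set>
#include <vector>
using namespace Rcpp;

struct Grid {
  int X, Y, Z;
  R_xlen_t n() const { return (R_xlen_t)X * Y * Z; }
  R_xlen_t idx(int x, int y, int z) const { return x + (R_xlen_t)X * (y + (R_xlen_t)Y * z); }
};

static Grid as_grid(const IntegerVector& dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  return Grid{dims[0], dims[1], dims[2]};
}

// flood-fill labelling of `mask` (non-zero = foreground); returns component
// ids 1.. in `comp`, component sizes in `sizes`
static int label_components(const std::vector<char>& mask, const Grid& g,
                            int connectivity, std::vector<int>& comp,
                            std::vector<R_xlen_t>& sizes) {
  comp.assign(g.n(), 0);
  sizes.clear();
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
        nb.push_back({dx, dy, dz});
      }
  int nc = 0;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < g.Z; ++z)
    for (int y = 0; y < g.Y; ++y)
      for (int x = 0; x < g.X; ++x) {
        const R_xlen_t i0 = g.idx(x, y, z);
        if (!mask[i0] || comp[i0]) continue;
        ++nc;
        R_xlen_t sz = 0;
        stack.clear();
        stack.push_back(i0);
        comp[i0] = nc;
        while (!stack.empty()) {
          const R_xlen_t i = stack.back();
          stack.pop_back();
          ++sz;
          const int cx = (int)(i % g.X), cy = (int)((i / g.X) % g.Y), cz = (int)(i / ((R_xlen_t)g.X * g.Y));
          for (const auto& d : nb) {
            const int nx = cx + d[0], ny = cy + d[1], nz = cz + d[2];
            if (nx < 0 || ny < 0 || nz < 0 || nx >= g.X || ny >= g.Y || nz >= g.Z) continue;
            const R_xlen_t j = g.idx(nx, ny, nz);
            if (mask[j] && !comp[j]) { comp[j] = nc; stack.push_back(j); }
          }
        }
        sizes.push_back(sz);
      }
  return nc;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims, int connectivity) {
  const Grid g = as_grid(dims);
  if (mask.size() != g.n()) stop("mask does not match dims");
  std::vector<char> m(g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i) m[i] = mask[i] != 0;
  std::vector<int> comp;
  std::vector<R_xlen_t> sizes;
  label_components(m, g, connectivity, comp, sizes);
  return IntegerVector(comp.begin(), comp.end());
}

// keep, per label id, only the two largest 26-connected components
// (rank-2 ties broken by lower component centroid along x)
// [[Rcpp::export]]
IntegerVector cpp_filter_components(IntegerVector labels, IntegerVector dims) {
  const Grid g = as_grid(dims);
  if (labels.size() != g.n()) stop("labels do not match dims");
  IntegerVector out = clone(labels);
  std::set<int> ids(labels.begin(), labels.end());
  ids.erase(0);
  std::vector<char> m(g.n());
  for (int id : ids) {
    for (R_xlen_t i = 0; i < g.n(); ++i) m[i] = labels[i] == id;
    std::vector<int> comp;
    std::vector<R_xlen_t> sizes;
    const int nc = label_components(m, g, 26, comp, sizes);
    if (nc <= 2) continue;
    std::vector<double> cx(nc, 0.0);
    for (R_xlen_t i = 0; i < g.n(); ++i)
      if (comp[i]) cx[comp[i] - 1] += (double)(i % g.X);
    for (int c = 0; c < nc; ++c) cx[c] /= (double)sizes[c];
    std::vector<int> ord(nc);
    for (int c = 0; c < nc; ++c) ord[c] = c;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (sizes[a] != sizes[b]) return sizes[a] > sizes[b];
      return cx[a] < cx[b];
    });
    std::vector<char> keep(nc, 0);
    keep[ord[0]] = 1;
    keep[ord[1]] = 1;
    for (R_xlen_t i = 0; i < g.n(); ++i)
      if (comp[i] && !keep[comp[i] - 1]) out[i] = 0;
  }
  return out;
}

// fill background cavities fully enclosed (6-connectivity, border-excluded)
// by a single muscle id
// [[Rcpp::export]]
IntegerVector cpp_fill_holes(IntegerVector labels, IntegerVector dims) {
  const Grid g = as_grid(dims);
  if (labels.size() != g.n()) stop("labels do not match dims");
  IntegerVector out = clone(labels);
  std::vector<char> bg(g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i) bg[i] = labels[i] == 0;
  std::vector<int> comp;
  std::vector<R_xlen_t> sizes;
  const int nc = label_components(bg, g, 6, comp, sizes);
  if (nc == 0) return out;
  // per background component: does it touch the border, and which labels bound it?
  std::vector<char> border(nc, 0);
  std::vector<int> owner(nc, -1);   // -1 none yet, -2 mixed
  for (int z = 0; z < g.Z; ++z)
    for (int y = 0; y < g.Y; ++y)
      for (int x = 0; x < g.X; ++x) {
        const R_xlen_t i = g.idx(x, y, z);
        if (!comp[i]) continue;
        const int c = comp[i] - 1;
        if (x == 0 || y == 0 || z == 0 || x == g.X - 1 || y == g.Y - 1 || z == g.Z - 1)
          border[c] = 1;
        const int dx[6] = {-1, 1, 0, 0, 0, 0}, dy[6] = {0, 0, -1, 1, 0, 0}, dz[6] = {0, 0, 0, 0, -1, 1};
        for (int k = 0; k < 6; ++k) {
          const int nx = x + dx[k], ny = y + dy[k], nz = z + dz[k];
          if (nx < 0 || ny < 0 || nz < 0 || nx >= g.X || ny >= g.Y || nz >= g.Z) continue;
          const int lb = labels[g.idx(nx, ny, nz)];
          if (lb == 0) continue;
          if (owner[c] == -1) owner[c] = lb;
          else if (owner[c] != lb) owner[c] = -2;
        }
      }
  for (R_xlen_t i = 0; i < g.n(); ++i) {
    if (!comp[i]) continue;
    const int c = comp[i] - 1;
    if (!border[c] && owner[c] > 0) out[i] = owner[c];
  }
  return out;
}

// per-axial-slice erosion with a 3x3 cross (4-connectivity), `width` passes;
// slice borders count as background
// [[Rcpp::export]]
IntegerVector cpp_erode_inplane(IntegerVector labels, IntegerVector dims, int width) {
  const Grid g = as_grid(dims);
  if (labels.size() != g.n()) stop("labels do not match dims");
  IntegerVector cur = clone(labels);
  for (int w = 0; w < width; ++w) {
    IntegerVector nxt = clone(cur);
    for (int z = 0; z < g.Z; ++z)
      for (int y = 0; y < g.Y; ++y)
        for (int x = 0; x < g.X; ++x) {
          const R_xlen_t i = g.idx(x, y, z);
          const int lb = cur[i];
          if (lb == 0) continue;
          bool keep = x > 0 && x < g.X - 1 && y > 0 && y < g.Y - 1;
          if (keep)
            keep = cur[g.idx(x - 1, y, z)] == lb && cur[g.idx(x + 1, y, z)] == lb &&
                   cur[g.idx(x, y - 1, z)] == lb && cur[g.idx(x, y + 1, z)] == lb;
          if (!keep) nxt[i] = 0;
        }
    cur = nxt;
  }
  return cur;
}

// boundary voxels: foreground with >= 1 six-neighbour outside the mask
// (the volume border counts as outside)
// [[Rcpp::export]]
LogicalVector cpp_boundary_mask(LogicalVector mask, IntegerVector dims) {
  const Grid g = as_grid(dims);
  if (mask.size() != g.n()) stop("mask does not match dims");
  LogicalVector out(g.n());
  for (int z = 0; z < g.Z; ++z)
    for (int y = 0; y < g.Y; ++y)
      for (int x = 0; x < g.X; ++x) {
        const R_xlen_t i = g.idx(x, y, z);
        if (!mask[i]) continue;
        bool bd = x == 0 || y == 0 || z == 0 || x == g.X - 1 || y == g.Y - 1 || z == g.Z - 1;
        if (!bd)
          bd = !mask[g.idx(x - 1, y, z)] || !mask[g.idx(x + 1, y, z)] ||
               !mask[g.idx(x, y - 1, z)] || !mask[g.idx(x, y + 1, z)] ||
               !mask[g.idx(x, y, z - 1)] || !mask[g.idx(x, y, z + 1)];
        out[i] = bd;
      }
  return out;
}

// "no seed" sentinel: large but finite so the lower-envelope arithmetic stays
// well defined; true squared distances here are << 1e12 mm^2
static const double EDT_INF = 1e20;

// 1-D squared-distance lower envelope (Felzenszwalb & Huttenlocher) with
// anisotropic sample spacing `h`
static void edt_1d(std::vector<double>& f, double h) {
  const int n = (int)f.size();
  if (n == 1) return;
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  const double h2 = h * h;
  int k = 0;
  v[0] = 0;
  zb[0] = -EDT_INF;
  zb[1] = EDT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) / (2.0 * h2 * (q - v[k]));
    while (s <= zb[k]) {
      --k;
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) / (2.0 * h2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    d[q] = f[v[k]] >= EDT_INF ? f[v[k]] : h2 * (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
  f = d;
}

// exact squared Euclidean distance (mm^2) to the nearest seed voxel centre
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector seeds, IntegerVector dims, NumericVector spacing) {
  const Grid g = as_grid(dims);
  if (seeds.size() != g.n()) stop("seeds do not match dims");
  if (spacing.size() != 3) stop("spacing must have length 3");
  std::vector<double> f(g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i) f[i] = seeds[i] ? 0.0 : EDT_INF;
  std::vector<double> line;
  // x pass
  line.resize(g.X);
  for (int z = 0; z < g.Z; ++z)
    for (int y = 0; y < g.Y; ++y) {
      for (int x = 0; x < g.X; ++x) line[x] = f[g.idx(x, y, z)];
      edt_1d(line, spacing[0]);
      for (int x = 0; x < g.X; ++x) f[g.idx(x, y, z)] = line[x];
    }
  // y pass
  line.resize(g.Y);
  for (int z = 0; z < g.Z; ++z)
    for (int x = 0; x < g.X; ++x) {
      for (int y = 0; y < g.Y; ++y) line[y] = f[g.idx(x, y, z)];
      edt_1d(line, spacing[1]);
      for (int y = 0; y < g.Y; ++y) f[g.idx(x, y, z)] = line[y];
    }
  // z pass
  line.resize(g.Z);
  for (int y = 0; y < g.Y; ++y)
    for (int x = 0; x < g.X; ++x) {
      for (int z = 0; z < g.Z; ++z) line[z] = f[g.idx(x, y, z)];
      edt_1d(line, spacing[2]);
      for (int z = 0; z < g.Z; ++z) f[g.idx(x, y, z)] = line[z];
    }
  NumericVector out(g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i) out[i] = f[i];
  return out;
}
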