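#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D neighbourhood offsets for 6/18/26-connectivity.
static void neighbourhood(int connectivity, std::vector<int> &dx,
                          std::vector<int> &dy, std::vector<int> &dz) {
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        const int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// Connected-component labelling by breadth-first search started at each
// yet-unlabelled foreground voxel in raster (column-major) order, so label
// k's first voxel precedes label k+1's: the labelling is deterministic.

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int nx, int ny, int nz,
                                   int connectivity) {
  const size_t n = static_cast<size_t>(nx) * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  std::vector<int> dx, dy, dz;
  neighbourhood(connectivity, dx, dy, dz);
  const int nn = dx.size();
  const int *m = LOGICAL(mask);
  int *L = INTEGER(lab);
  std::vector<size_t> queue;
  int next = 0;
  for (size_t p = 0; p < n; ++p) {
    if (m[p] != TRUE || L[p] != 0) continue;
    ++next;
    L[p] = next;
    queue.clear();
    queue.push_back(p);
    while (!queue.empty()) {
      const size_t q = queue.back();
      queue.pop_back();
      const int x = q % nx, y = (q / nx) % ny, z = q / (static_cast<size_t>(nx) * ny);
      for (int k = 0; k < nn; ++k) {
        const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const size_t r = xx + static_cast<size_t>(nx) * (yy + static_cast<size_t>(ny) * zz);
        if (m[r] == TRUE && L[r] == 0) {
          L[r] = next;
          queue.push_back(r);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

static void ball_offsets(double radius, std::vector<int> &dx,
                         std::vector<int> &dy, std::vector<int> &dz) {
  const int r = static_cast<int>(std::floor(radius));
  const double r2 = radius * radius + 1e-9;
  for (int c = -r; c <= r; ++c)
    for (int b = -r; b <= r; ++b)
      for (int a = -r; a <= r; ++a)
        if (a * a + b * b + c * c <= r2) {
          dx.push_back(a); dy.push_back(b); dz.push_back(c);
        }
}

// [[Rcpp::export]]
LogicalVector cpp_morph_ball(LogicalVector mask, int nx, int ny, int nz,
                             double radius, bool dilate) {
  const size_t n = static_cast<size_t>(nx) * ny * nz;
  LogicalVector out(n);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  std::vector<int> dx, dy, dz;
  ball_offsets(radius, dx, dy, dz);
  const int nn = dx.size();
  const int *m = LOGICAL(mask);
  int *o = LOGICAL(out);
  for (size_t p = 0; p < n; ++p) {
    const int x = p % nx, y = (p / nx) % ny, z = p / (static_cast<size_t>(nx) * ny);
    bool hit = dilate ? false : true;
    for (int k = 0; k < nn; ++k) {
      const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      bool val;
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        val = false;  // outside the grid counts as background
      else
        val = m[xx + static_cast<size_t>(nx) * (yy + static_cast<size_t>(ny) * zz)] == TRUE;
      if (dilate) {
        if (val) { hit = true; break; }
      } else {
        if (!val) { hit = false; break; }
      }
    }
    o[p] = hit ? TRUE : FALSE;
  }
  return out;
}

// Marker-based watershed by priority flooding of the gradient-magnitude
// image: labelled marker voxels seed a min-heap; voxels are popped in
// increasing gradient order (FIFO on ties) and propagate their label to
// unlabelled 6-neighbours.

struct WsNode {
  double value;
  size_t order;
  size_t index;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.value != b.value) return a.value > b.value;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_marker_watershed(NumericVector relief, IntegerVector markers,
                                   int nx, int ny, int nz) {
  const size_t n = static_cast<size_t>(nx) * ny * nz;
  IntegerVector lab(clone(markers));
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double *g = REAL(relief);
  int *L = INTEGER(lab);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> heap;
  size_t order = 0;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  // seed the heap only with marker voxels bordering unlabelled territory;
  // interior marker voxels keep their label and never enter the queue
  for (size_t p = 0; p < n; ++p) {
    if (L[p] <= 0) continue;
    const int x = p % nx, y = (p / nx) % ny, z = p / (static_cast<size_t>(nx) * ny);
    bool frontier = false;
    for (int k = 0; k < 6 && !frontier; ++k) {
      const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      if (L[xx + static_cast<size_t>(nx) * (yy + static_cast<size_t>(ny) * zz)] == 0)
        frontier = true;
    }
    if (frontier) heap.push({g[p], order++, p, L[p]});
  }
  while (!heap.empty()) {
    const WsNode node = heap.top();
    heap.pop();
    const int x = node.index % nx, y = (node.index / nx) % ny,
              z = node.index / (static_cast<size_t>(nx) * ny);
    for (int k = 0; k < 6; ++k) {
      const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const size_t r = xx + static_cast<size_t>(nx) * (yy + static_cast<size_t>(ny) * zz);
      if (L[r] == 0) {
        L[r] = node.label;
        heap.push({g[r], order++, r, node.label});
      }
    }
  }
  return lab;
}
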