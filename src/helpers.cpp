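#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// union-find with path halving
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Connected-component labelling of a binary matrix. Rows index x, columns
// index y. connectivity is 4 or 8; periodic wraps neighbours across both
// edges of the lattice. Background (0) pixels get label 0; foreground labels
// are 1..k in first-encounter order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const IntegerMatrix& mask, int connectivity,
                                   bool periodic) {
  const int nx = mask.nrow(), ny = mask.ncol(), n = nx * ny;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  // neighbour offsets: forward half-neighbourhood is enough for union-find
  std::vector<std::pair<int,int>> off = { {1, 0}, {0, 1} };
  if (connectivity == 8) {
    off.push_back({1, 1});
    off.push_back({1, -1});
  } else if (connectivity != 4) {
    stop("connectivity must be 4 or 8");
  }

  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (mask(i, j) == 0) continue;
      const int p = i + j * nx;
      for (auto& d : off) {
        int ii = i + d.first, jj = j + d.second;
        if (periodic) {
          ii = (ii + nx) % nx;
          jj = (jj + ny) % ny;
        } else if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) {
          continue;
        }
        if (mask(ii, jj) != 0) uf_union(parent, p, ii + jj * nx);
      }
    }
  }

  IntegerMatrix out(nx, ny);
  std::vector<int> lab(n, 0);
  int next = 0;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (mask(i, j) == 0) continue;
      int r = uf_find(parent, i + j * nx);
      if (lab[r] == 0) lab[r] = ++next;
      out(i, j) = lab[r];
    }
  }
  return out;
}

// Sequential topology-preserving thinning of a binary edge map on a
// (optionally periodic) lattice. A pixel is removed when it is 8-simple:
// its foreground 8-neighbours form exactly one 8-connected component and
// there are at least two of them (endpoints and isolated pixels are kept).
// Reduces hysteresis output to one-pixel-wide 8-connected chains, including
// diagonalising 4-connected staircases.
// [[Rcpp::export]]
IntegerMatrix thin_simple_cpp(IntegerMatrix mask, bool periodic) {
  const int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix m = clone(mask);
  const int dx[8] = { -1, -1, 0, 1, 1, 1, 0, -1 };
  const int dy[8] = { 0, 1, 1, 1, 0, -1, -1, -1 };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if (m(i, j) == 0) continue;
        int nb[8];
        int B = 0;
        for (int k = 0; k < 8; ++k) {
          int ii = i + dx[k], jj = j + dy[k];
          if (periodic) {
            ii = (ii + nx) % nx;
            jj = (jj + ny) % ny;
            nb[k] = m(ii, jj);
          } else {
            nb[k] = (ii < 0 || ii >= nx || jj < 0 || jj >= ny) ? 0 : m(ii, jj);
          }
          B += nb[k];
        }
        if (B < 2 || B > 6) continue;  // keep endpoints and near-full rings
        // count 8-components among the foreground neighbours (two ring
        // cells are adjacent when their offsets differ by <= 1 in each axis)
        int comp = 0;
        int root[8];
        for (int k = 0; k < 8; ++k) root[k] = -1;
        for (int k = 0; k < 8; ++k) {
          if (!nb[k]) continue;
          int rk = k;
          for (int l = 0; l < k; ++l) {
            if (!nb[l]) continue;
            int ddx = std::abs(dx[k] - dx[l]), ddy = std::abs(dy[k] - dy[l]);
            if (ddx <= 1 && ddy <= 1) {
              // merge: find roots
              int rl = l;
              while (root[rl] >= 0) rl = root[rl];
              while (root[rk] >= 0) rk = root[rk];
              if (rl != rk) root[std::max(rk, rl)] = std::min(rk, rl);
              rk = std::min(rk, rl);
            }
          }
        }
        for (int k = 0; k < 8; ++k)
          if (nb[k] && root[k] < 0) ++comp;
        if (comp == 1) {
          m(i, j) = 0;
          changed = true;
        }
      }
    }
  }
  return m;
}

// Blue-noise (dart-throwing) sampling of n points in a periodic Lx x Ly box
// with a minimum pairwise (minimum-image) distance. Uses R's RNG so results
// are reproducible under set.seed(). Errors if the requested density cannot
// be reached within the attempt budget.
// [[Rcpp::export]]
NumericMatrix poisson_disk_cpp(int n, double Lx, double Ly, double min_dist,
                               double max_attempts_per_point) {
  if (n <= 0) stop("n must be positive");
  const double r2 = min_dist * min_dist;
  // cell list: cell edge >= min_dist so only 3x3 neighbourhood is searched
  const int cx = std::max(1, (int)std::floor(Lx / min_dist));
  const int cy = std::max(1, (int)std::floor(Ly / min_dist));
  std::vector<std::vector<int>> cells((size_t)cx * cy);
  NumericMatrix pts(n, 2);
  const double budget = max_attempts_per_point * n + 1000.0;

  RNGScope scope;
  int placed = 0;
  double attempts = 0;
  while (placed < n) {
    if (attempts++ > budget)
      stop("could not place %d points at min_dist %.2f in %.0f x %.0f box "
           "(infeasible density)", n, min_dist, Lx, Ly);
    const double x = unif_rand() * Lx, y = unif_rand() * Ly;
    const int ci = std::min(cx - 1, (int)(x / Lx * cx));
    const int cj = std::min(cy - 1, (int)(y / Ly * cy));
    bool ok = true;
    for (int dj = -1; dj <= 1 && ok; ++dj) {
      for (int di = -1; di <= 1 && ok; ++di) {
        const int ni = (ci + di + cx) % cx, nj = (cj + dj + cy) % cy;
        for (int k : cells[(size_t)ni + (size_t)nj * cx]) {
          double dx = std::fabs(pts(k, 0) - x), dy = std::fabs(pts(k, 1) - y);
          if (dx > 0.5 * Lx) dx = Lx - dx;
          if (dy > 0.5 * Ly) dy = Ly - dy;
          if (dx * dx + dy * dy < r2) { ok = false; break; }
        }
      }
    }
    if (ok) {
      pts(placed, 0) = x;
      pts(placed, 1) = y;
      cells[(size_t)ci + (size_t)cj * cx].push_back(placed);
      ++placed;
    }
  }
  return pts;
}
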