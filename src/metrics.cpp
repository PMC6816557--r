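// Kernels behind the matrix-topology metrics: per-fiber median angular
// deviation (alignment), a fast path operating directly on the binned fiber
// lattice, Zhang-Suen skeleton thinning and skeleton path tracing.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// acute angle between two apolar orientations, in [0, pi/2]
static inline double acute_dev(double a, double b) {
  double d = std::fabs(a - b);
  d -= std::floor(d / M_PI) * M_PI; // positive modulo, avoiding libm fmod
  if (d >= M_PI) d -= M_PI;
  if (d > M_PI_2) d = M_PI - d;
  return d;
}

// weighted median: smallest value whose cumulative weight reaches half the
// total (pairs must be sorted by value)
static double wmedian_sorted(std::vector<std::pair<double, double> >& dv) {
  double tot = 0;
  for (size_t k = 0; k < dv.size(); k++) tot += dv[k].second;
  double half = tot / 2.0, acc = 0;
  for (size_t k = 0; k < dv.size(); k++) {
    acc += dv[k].second;
    if (acc >= half) return dv[k].first;
  }
  return dv.back().first;
}

// Per-fiber weighted median deviation to all other fibers within `radius`.
// NA when a fiber has no neighbour. O(n^2); intended for fields of up to a
// few tens of thousands of fibers.
// [[Rcpp::export]]
NumericVector cpp_field_median_dev(NumericVector x, NumericVector y,
                                   NumericVector th, NumericVector w,
                                   double radius, bool periodic,
                                   double W, double H) {
  int n = x.size();
  NumericVector out(n, NA_REAL);
  double r2 = radius * radius;
  std::vector<std::pair<double, double> > dv;
  for (int i = 0; i < n; i++) {
    dv.clear();
    for (int j = 0; j < n; j++) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (periodic) {
        dx -= W * std::round(dx / W);
        dy -= H * std::round(dy / H);
      }
      if (dx * dx + dy * dy > r2) continue;
      dv.push_back(std::make_pair(acute_dev(th[i], th[j]), w[j]));
    }
    if (dv.empty()) continue;
    std::sort(dv.begin(), dv.end());
    out[i] = wmedian_sorted(dv);
  }
  return out;
}

// Alignment on the fiber lattice itself. Every (grid point, bin) pair with a
// positive count is one fiber bundle of weight = count; neighbour weights per
// orientation channel are disk sums of the bin counts, with the focal bundle
// excluded from its own channel. Returns the count-weighted mean of the
// per-bundle weighted median deviations.
// [[Rcpp::export]]
List cpp_grid_align(NumericVector grid, int nx, int ny, int nbins,
                    double spacing, double radius, bool periodic) {
  int K = (int)std::floor(radius / spacing);
  std::vector<int> odx, ody;
  double rk2 = (radius / spacing) * (radius / spacing);
  if (!periodic || (2 * K + 1 <= nx && 2 * K + 1 <= ny)) {
    int Kc = std::min(K, std::max(nx, ny));
    for (int dy = -Kc; dy <= Kc; dy++)
      for (int dx = -Kc; dx <= Kc; dx++)
        if ((double)dx * dx + (double)dy * dy <= rk2) {
          odx.push_back(dx);
          ody.push_back(dy);
        }
  } else {
    // radius reaches beyond half the periodic box: enumerate every point
    // once with its minimum-image displacement
    for (int dy = 0; dy < ny; dy++) {
      for (int dx = 0; dx < nx; dx++) {
        double ddx = (dx > nx / 2) ? dx - nx : dx;
        double ddy = (dy > ny / 2) ? dy - ny : dy;
        if (ddx * ddx + ddy * ddy <= rk2) {
          odx.push_back(dx);
          ody.push_back(dy);
        }
      }
    }
  }
  int noff = (int)odx.size();

  int np = nx * ny;
  std::vector<double> S((size_t)np * nbins, 0.0);
  for (int iy = 0; iy < ny; iy++) {
    for (int ix = 0; ix < nx; ix++) {
      double* s = &S[(size_t)nbins * (ix + nx * iy)];
      for (int k = 0; k < noff; k++) {
        int ax = ix + odx[k], ay = iy + ody[k];
        if (periodic) {
          ax = (ax + nx) % nx;
          ay = (ay + ny) % ny;
        } else if (ax < 0 || ax >= nx || ay < 0 || ay >= ny) {
          continue;
        }
        const double* g = &grid[(size_t)nbins * (ax + nx * ay)];
        for (int b = 0; b < nbins; b++) s[b] += g[b];
      }
    }
  }

  // deviation table and per-focal-bin channel ordering by deviation
  std::vector<double> dev((size_t)nbins * nbins);
  std::vector<int> ord((size_t)nbins * nbins);
  for (int b = 0; b < nbins; b++) {
    std::vector<std::pair<double, int> > tmp(nbins);
    for (int c = 0; c < nbins; c++) {
      double d = acute_dev(b * M_PI / nbins, c * M_PI / nbins);
      dev[b * nbins + c] = d;
      tmp[c] = std::make_pair(d, c);
    }
    std::sort(tmp.begin(), tmp.end());
    for (int c = 0; c < nbins; c++) ord[b * nbins + c] = tmp[c].second;
  }

  double wsum = 0, dsum = 0;
  long nfib = 0;
  for (int p = 0; p < np; p++) {
    const double* g = &grid[(size_t)nbins * p];
    const double* s = &S[(size_t)nbins * p];
    for (int b = 0; b < nbins; b++) {
      double w = g[b];
      if (w <= 0) continue;
      double tot = 0;
      for (int c = 0; c < nbins; c++) tot += s[c];
      tot -= w; // exclude the focal bundle
      if (tot <= 0) continue;
      double half = tot / 2.0, acc = 0, med = 0;
      for (int k = 0; k < nbins; k++) {
        int c = ord[b * nbins + k];
        double wc = s[c] - (c == b ? w : 0.0);
        if (wc <= 0) continue;
        acc += wc;
        med = dev[b * nbins + c];
        if (acc >= half) break;
      }
      dsum += w * med;
      wsum += w;
      nfib++;
    }
  }
  return List::create(_["mean_dev"] = (wsum > 0 ? dsum / wsum : NA_REAL),
                      _["weight"] = wsum, _["n_fibers"] = (double)nfib);
}

// ---------------------------------------------------------------------------
// Zhang-Suen thinning of a binary mask to a 1-px skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(clone(mask));
  std::vector<std::pair<int, int> > kill;
  bool changed = true;
  // neighbours P2..P9 clockwise starting north (row-1)
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c);
  };
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; pass++) {
      kill.clear();
      for (int r = 0; r < nr; r++) {
        for (int c = 0; c < nc; c++) {
          if (!img(r, c)) continue;
          int p[8];
          int bsum = 0;
          for (int k = 0; k < 8; k++) {
            p[k] = at(r + dr[k], c + dc[k]);
            bsum += p[k];
          }
          if (bsum < 2 || bsum > 6) continue;
          int a = 0;
          for (int k = 0; k < 8; k++)
            if (!p[k] && p[(k + 1) % 8]) a++;
          if (a != 1) continue;
          if (pass == 0) {
            if (p[0] && p[2] && p[4]) continue;
            if (p[2] && p[4] && p[6]) continue;
          } else {
            if (p[0] && p[2] && p[6]) continue;
            if (p[0] && p[4] && p[6]) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); k++)
        img(kill[k].first, kill[k].second) = 0;
    }
  }
  return img;
}

// Trace skeleton paths and return absolute turning angles (radians) between
// consecutive chords sampled every `window` pixels of arc length.
// [[Rcpp::export]]
NumericVector cpp_trace_turning(IntegerMatrix skel, double window) {
  int nr = skel.nrow(), nc = skel.ncol();
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  std::vector<unsigned char> vis((size_t)nr * nc, 0);
  std::vector<double> turns;

  auto on = [&](int r, int c) -> bool {
    return r >= 0 && r < nr && c >= 0 && c < nc && skel(r, c) != 0;
  };
  auto degree = [&](int r, int c) -> int {
    int d = 0;
    for (int k = 0; k < 8; k++)
      if (on(r + dr[k], c + dc[k])) d++;
    return d;
  };

  auto walk = [&](int r0, int c0) {
    std::vector<std::pair<int, int> > path;
    int r = r0, c = c0;
    vis[(size_t)r * nc + c] = 1;
    path.push_back(std::make_pair(r, c));
    while (true) {
      int nrn = -1, ncn = -1;
      for (int k = 0; k < 8; k++) {
        int ar = r + dr[k], ac = c + dc[k];
        if (on(ar, ac) && !vis[(size_t)ar * nc + ac]) {
          nrn = ar; ncn = ac;
          break;
        }
      }
      if (nrn < 0) break;
      r = nrn; c = ncn;
      vis[(size_t)r * nc + c] = 1;
      path.push_back(std::make_pair(r, c));
    }
    if (path.size() < 3) return;
    // cumulative arc length, then resample every `window`
    size_t m = path.size();
    std::vector<double> s(m, 0.0);
    for (size_t k = 1; k < m; k++) {
      double d = (path[k].first != path[k - 1].first &&
                  path[k].second != path[k - 1].second)
                     ? M_SQRT2 : 1.0;
      s[k] = s[k - 1] + d;
    }
    double total = s[m - 1];
    if (total < 2 * window) return;
    int nsamp = (int)std::floor(total / window) + 1;
    std::vector<double> sx(nsamp), sy(nsamp);
    size_t k = 0;
    for (int q = 0; q < nsamp; q++) {
      double target = q * window;
      while (k + 1 < m && s[k + 1] < target) k++;
      if (k + 1 >= m) {
        sx[q] = path[m - 1].second;
        sy[q] = path[m - 1].first;
      } else {
        double t = (s[k + 1] > s[k]) ? (target - s[k]) / (s[k + 1] - s[k]) : 0;
        sx[q] = path[k].second + t * (path[k + 1].second - path[k].second);
        sy[q] = path[k].first + t * (path[k + 1].first - path[k].first);
      }
    }
    for (int q = 2; q < nsamp; q++) {
      double h1 = std::atan2(sy[q - 1] - sy[q - 2], sx[q - 1] - sx[q - 2]);
      double h2 = std::atan2(sy[q] - sy[q - 1], sx[q] - sx[q - 1]);
      double d = h2 - h1;
      d = std::atan2(std::sin(d), std::cos(d));
      turns.push_back(std::fabs(d));
    }
  };

  // endpoints first so open fibers are traced tip-to-tip
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++)
      if (on(r, c) && !vis[(size_t)r * nc + c] && degree(r, c) == 1)
        walk(r, c);
  // remaining components (loops, junction clusters)
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++)
      if (on(r, c) && !vis[(size_t)r * nc + c]) walk(r, c);

  return NumericVector(turns.begin(), turns.end());
}
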