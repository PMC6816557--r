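// Simulation engine: nematic self-propelled cells on top of a binned fiber
// lattice. Single-threaded; all randomness goes through R's RNG so that
// set.seed() in R makes runs bit-reproducible.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// positive modulo without libm's fmod (portability across glibc builds)
static inline double pos_mod(double v, double L) {
  double r = v - std::floor(v / L) * L;
  if (r >= L) r -= L;
  if (r < 0) r = 0;
  return r;
}

static inline double wrap_len(double v, double L) { return pos_mod(v, L); }

static inline double wrap_2pi(double a) { return pos_mod(a, 2.0 * M_PI); }

// 0-based orientation bin; bin b covers [b*pi/nbins, (b+1)*pi/nbins).
// A value within ~1e-9 below a bin boundary is treated as on the boundary,
// so exact multiples of pi/nbins land in the bin they open despite the
// rounding in pi-based arithmetic.
static inline int bin_of0(double theta, int nbins) {
  double t = pos_mod(theta, M_PI);
  double v = t * nbins / M_PI;
  int b = (int)std::floor(v);
  if (v - b > 1.0 - 1e-9) b += 1;
  b %= nbins;
  return b;
}

// Apolar representative of `other` (other or other+pi) within pi/2 of `ref`;
// ties keep `other` unmodified.
static inline double nematic_rep(double ref, double other) {
  double d = other - ref;
  d = std::atan2(std::sin(d), std::cos(d));
  if (std::fabs(d) <= M_PI_2) return wrap_2pi(other);
  return wrap_2pi(other + M_PI);
}

namespace {

struct HashGrid {
  int gx, gy;
  double hx, hy, W, H;
  std::vector<int> head, nxt;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             double h, double W_, double H_) {
    W = W_; H = H_;
    gx = std::max(1, (int)std::floor(W / h));
    gy = std::max(1, (int)std::floor(H / h));
    hx = W / gx; hy = H / gy;
    head.assign((size_t)gx * gy, -1);
    int n = (int)x.size();
    nxt.assign(n, -1);
    for (int i = 0; i < n; i++) {
      int cx = std::min(gx - 1, std::max(0, (int)(x[i] / hx)));
      int cy = std::min(gy - 1, std::max(0, (int)(y[i] / hy)));
      int c = cx + gx * cy;
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  template <class F>
  void neighbours(double xi, double yi, bool periodic, F f) const {
    int cx = std::min(gx - 1, std::max(0, (int)(xi / hx)));
    int cy = std::min(gy - 1, std::max(0, (int)(yi / hy)));
    int seen[9];
    int nseen = 0;
    for (int dy = -1; dy <= 1; dy++) {
      for (int dx = -1; dx <= 1; dx++) {
        int ax = cx + dx, ay = cy + dy;
        if (periodic) {
          ax = (ax + gx) % gx;
          ay = (ay + gy) % gy;
        } else if (ax < 0 || ax >= gx || ay < 0 || ay >= gy) {
          continue;
        }
        int c = ax + gx * ay;
        bool dup = false;
        for (int k = 0; k < nseen; k++) if (seen[k] == c) { dup = true; break; }
        if (dup) continue;
        seen[nseen++] = c;
        for (int j = head[c]; j != -1; j = nxt[j]) f(j);
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_run(NumericVector x0, NumericVector y0, NumericVector theta0,
             NumericVector speed0, NumericVector ux0, NumericVector uy0,
             NumericVector grid0, IntegerVector last0, List par,
             int nsteps, int record_every) {
  const double W = as<double>(par["W"]);
  const double H = as<double>(par["H"]);
  const double sd_eta = as<double>(par["sd_eta"]);
  const double w_c = as<double>(par["w_c"]);
  const double w_m = as<double>(par["w_m"]);
  const double dep = as<double>(par["dep"]);
  const double deg = as<double>(par["deg"]);
  const double rea = as<double>(par["rea"]);
  const bool fb = as<bool>(par["fb"]);
  const double d_lo = as<double>(par["d_lo"]);
  const double d_hi = as<double>(par["d_hi"]);
  const double vef = as<double>(par["ve"]);
  const double ovf = as<double>(par["ovf"]);
  const NumericVector off = par["off"];
  const NumericVector rad = par["rad"];
  const int nx = as<int>(par["nx"]);
  const int ny = as<int>(par["ny"]);
  const int nbins = as<int>(par["nbins"]);
  const bool periodic = as<bool>(par["periodic"]);

  const int n = x0.size();
  const int nb = off.size();
  const double wp = 1.0 - w_c - w_m;
  const double sx = W / nx, sy = H / ny;

  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> speed(speed0.begin(), speed0.end());
  std::vector<double> ux(ux0.begin(), ux0.end()), uy(uy0.begin(), uy0.end());
  std::vector<double> grid(grid0.begin(), grid0.end());
  std::vector<int> last(last0.begin(), last0.end());

  std::vector<double> newtheta(n), costh(n), sinth(n);

  double maxreach = 0;
  for (int b = 0; b < nb; b++)
    maxreach = std::max(maxreach, std::fabs(off[b]) + rad[b]);
  const double hsize = std::max(2.0 * maxreach, 1e-6);
  const double reach2 = hsize * hsize;

  int nrec = (record_every > 0) ? nsteps / record_every : 0;
  NumericMatrix rec_x(nrec, n), rec_y(nrec, n);
  IntegerVector rec_step(nrec);
  int irec = 0;

  HashGrid hash;
  RNGScope scope;

  auto grid_index = [&](double gx_, double gy_) -> int {
    int ix, iy;
    if (periodic) {
      ix = (int)std::floor(wrap_len(gx_, W) / sx);
      iy = (int)std::floor(wrap_len(gy_, H) / sy);
    } else {
      ix = (int)std::floor(gx_ / sx);
      iy = (int)std::floor(gy_ / sy);
    }
    ix = std::min(nx - 1, std::max(0, ix));
    iy = std::min(ny - 1, std::max(0, iy));
    return ix + nx * iy;
  };

  for (int step = 0; step < nsteps; step++) {
    for (int i = 0; i < n; i++) {
      costh[i] = std::cos(theta[i]);
      sinth[i] = std::sin(theta[i]);
    }
    hash.build(x, y, hsize, W, H);

    // --- phase 1: new orientations, synchronously from the time-t state ---
    for (int i = 0; i < n; i++) {
      double eta = norm_rand() * sd_eta;
      double xp = std::cos(theta[i] + eta), yp = std::sin(theta[i] + eta);

      double sc = 0, ss = 0;
      int nc = 0;
      hash.neighbours(x[i], y[i], periodic, [&](int j) {
        if (j == i) return;
        double dx = x[j] - x[i], dy = y[j] - y[i];
        if (periodic) {
          dx -= W * std::round(dx / W);
          dy -= H * std::round(dy / H);
        }
        if (dx * dx + dy * dy > reach2) return;
        bool touch = false;
        for (int a = 0; a < nb && !touch; a++) {
          for (int b = 0; b < nb; b++) {
            double ddx = dx + off[b] * costh[j] - off[a] * costh[i];
            double ddy = dy + off[b] * sinth[j] - off[a] * sinth[i];
            double rr = rad[a] + rad[b];
            if (ddx * ddx + ddy * ddy < rr * rr) { touch = true; break; }
          }
        }
        if (touch) {
          double rep = nematic_rep(theta[i], theta[j]);
          sc += std::cos(rep);
          ss += std::sin(rep);
          nc++;
        }
      });
      double xc = 0, yc = 0;
      if (nc > 0) { xc = sc / nc; yc = ss / nc; }

      // matrix guidance: Gillespie pick of an orientation bin under the head
      // (skipped entirely, without touching the RNG, when w_m = 0)
      double xm = 0, ym = 0, dsel = 0;
      bool hasf = false;
      int g = nbins * grid_index(x[i] + off[0] * costh[i],
                                 y[i] + off[0] * sinth[i]);
      double tot = 0;
      if (w_m > 0)
        for (int b = 0; b < nbins; b++) tot += grid[g + b];
      if (tot > 0) {
        double u = unif_rand() * tot, acc = 0;
        int bsel = nbins - 1;
        for (int b = 0; b < nbins; b++) {
          acc += grid[g + b];
          if (u < acc) { bsel = b; break; }
        }
        last[g / nbins] = bsel;
        dsel = grid[g + bsel];
        hasf = true;
        double rep = nematic_rep(theta[i], bsel * M_PI / nbins);
        xm = std::cos(rep);
        ym = std::sin(rep);
      }

      double wce = (nc > 0) ? w_c : 0.0;
      double fd = 1.0;
      if (fb) {
        fd = (dsel <= d_lo) ? 0.0
             : ((dsel >= d_hi) ? 1.0 : (dsel - d_lo) / (d_hi - d_lo));
      }
      double wme = hasf ? w_m * fd : 0.0;
      double S = wp + wce + wme;
      double X = 0, Y = 0;
      if (S > 0) {
        X = (wp * xp + wce * xc + wme * xm) / S;
        Y = (wp * yp + wce * yc + wme * ym) / S;
      }
      if (std::fabs(X) < 1e-15 && std::fabs(Y) < 1e-15)
        newtheta[i] = theta[i]; // degenerate combination: keep heading
      else
        newtheta[i] = wrap_2pi(std::atan2(Y, X));
    }

    // --- phase 2: matrix updates at the head grid point, new orientation ---
    for (int i = 0; i < n; i++) {
      double ct = std::cos(newtheta[i]), st = std::sin(newtheta[i]);
      int g = nbins * grid_index(x[i] + off[0] * ct, y[i] + off[0] * st);
      int b = bin_of0(newtheta[i], nbins);
      grid[g + b] += dep;
      if (deg > 0) {
        for (int k = 0; k < nbins; k++)
          grid[g + k] = std::max(0.0, grid[g + k] - deg);
      }
      if (rea > 0) {
        int bl = (b + nbins - 1) % nbins, br = (b + 1) % nbins;
        double m = std::min(rea, grid[g + bl]);
        grid[g + bl] -= m; grid[g + b] += m;
        m = std::min(rea, grid[g + br]);
        grid[g + br] -= m; grid[g + b] += m;
      }
    }

    // --- phase 3: positions with volume exclusion (cell centres unchanged
    // since phase 1, so the spatial hash is still valid) ---
    for (int i = 0; i < n; i++) {
      costh[i] = std::cos(newtheta[i]);
      sinth[i] = std::sin(newtheta[i]);
    }
    for (int i = 0; i < n; i++) {
      double ve = 1.0;
      hash.neighbours(x[i], y[i], periodic, [&](int j) {
        if (j == i || ve < 1.0) return;
        double dx = x[j] - x[i], dy = y[j] - y[i];
        if (periodic) {
          dx -= W * std::round(dx / W);
          dy -= H * std::round(dy / H);
        }
        if (dx * dx + dy * dy > reach2) return;
        for (int b = 0; b < nb; b++) {
          double ddx = dx + off[b] * costh[j] - off[0] * costh[i];
          double ddy = dy + off[b] * sinth[j] - off[0] * sinth[i];
          double rr = ovf * (rad[0] + rad[b]);
          if (ddx * ddx + ddy * ddy < rr * rr) { ve = vef; break; }
        }
      });
      double dxp = speed[i] * costh[i] * ve;
      double dyp = speed[i] * sinth[i] * ve;
      if (periodic) {
        x[i] = wrap_len(x[i] + dxp, W);
        y[i] = wrap_len(y[i] + dyp, H);
        ux[i] += dxp;
        uy[i] += dyp;
      } else {
        double xn = x[i] + dxp, yn = y[i] + dyp;
        if (xn < 0) { xn = -xn; newtheta[i] = wrap_2pi(M_PI - newtheta[i]); }
        else if (xn > W) { xn = 2 * W - xn; newtheta[i] = wrap_2pi(M_PI - newtheta[i]); }
        if (yn < 0) { yn = -yn; newtheta[i] = wrap_2pi(-newtheta[i]); }
        else if (yn > H) { yn = 2 * H - yn; newtheta[i] = wrap_2pi(-newtheta[i]); }
        x[i] = xn; y[i] = yn;
        ux[i] = xn; uy[i] = yn;
      }
      theta[i] = newtheta[i];
    }

    if (record_every > 0 && (step + 1) % record_every == 0) {
      for (int i = 0; i < n; i++) {
        rec_x(irec, i) = ux[i];
        rec_y(irec, i) = uy[i];
      }
      rec_step[irec] = step + 1;
      irec++;
    }
  }

  return List::create(
      _["x"] = NumericVector(x.begin(), x.end()),
      _["y"] = NumericVector(y.begin(), y.end()),
      _["theta"] = NumericVector(theta.begin(), theta.end()),
      _["ux"] = NumericVector(ux.begin(), ux.end()),
      _["uy"] = NumericVector(uy.begin(), uy.end()),
      _["grid"] = NumericVector(grid.begin(), grid.end()),
      _["last_selected"] = IntegerVector(last.begin(), last.end()),
      _["rec_step"] = rec_step, _["rec_x"] = rec_x, _["rec_y"] = rec_y);
}

// [[Rcpp::export]]
double cpp_nematic_rep(double ref, double other) {
  return nematic_rep(ref, other);
}

// [[Rcpp::export]]
int cpp_bin_of(double theta, int nbins) {
  return bin_of0(theta, nbins) + 1;
}
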