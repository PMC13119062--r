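// Hot loops of the simulation and analysis pipeline.
//
// Conventions shared with the R layer:
//  * image stacks are column-major numeric arrays dim = c(H, W, F);
//    element (row r, col c, frame f), all 0-based here, sits at
//    r + H * (c + W * f);
//  * continuous coordinates are in pixel units with the origin at the
//    field-of-view corner: pixel (r, c) spans x in [c, c+1), y in [r, r+1),
//    i.e. x runs along columns and y along rows;
//  * all RNG goes through R's generator so set.seed() controls everything.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

static const double INV_SQRT2 = 0.7071067811865475244;
static const double INV_SQRT2PI = 0.3989422804014326779;
static const double INV_SQRTPI = 0.5641895835477562869;

// Integral of a unit-area Gaussian centred at x0 (sd s) over pixel [c, c+1).
static inline double pix_erf(double c, double x0, double s) {
  const double a = (c - x0) * INV_SQRT2 / s;
  const double b = (c + 1.0 - x0) * INV_SQRT2 / s;
  return 0.5 * (std::erf(b) - std::erf(a));
}

// [[Rcpp::export]]
NumericVector cpp_render_spots(NumericVector img, int H, int W, int F,
                               NumericVector x_px, NumericVector y_px,
                               NumericVector sx_px, NumericVector sy_px,
                               NumericVector photons, IntegerVector frame0) {
  const int n = x_px.size();
  double* p = REAL(img);
  for (int k = 0; k < n; ++k) {
    const int f = frame0[k];
    if (f < 0 || f >= F) continue;
    const double x0 = x_px[k], y0 = y_px[k];
    const double sx = sx_px[k], sy = sy_px[k];
    const double N = photons[k];
    const int cx0 = std::max(0, (int)std::floor(x0 - 4.0 * sx - 1.0));
    const int cx1 = std::min(W - 1, (int)std::ceil(x0 + 4.0 * sx + 1.0));
    const int cy0 = std::max(0, (int)std::floor(y0 - 4.0 * sy - 1.0));
    const int cy1 = std::min(H - 1, (int)std::ceil(y0 + 4.0 * sy + 1.0));
    if (cx1 < cx0 || cy1 < cy0) continue;
    std::vector<double> ex(cx1 - cx0 + 1), ey(cy1 - cy0 + 1);
    for (int c = cx0; c <= cx1; ++c) ex[c - cx0] = pix_erf((double)c, x0, sx);
    for (int r = cy0; r <= cy1; ++r) ey[r - cy0] = pix_erf((double)r, y0, sy);
    const R_xlen_t base = (R_xlen_t)f * H * W;
    for (int c = cx0; c <= cx1; ++c) {
      const double Nex = N * ex[c - cx0];
      double* col = p + base + (R_xlen_t)c * H;
      for (int r = cy0; r <= cy1; ++r) col[r] += Nex * ey[r - cy0];
    }
  }
  return img;
}

// EMCCD camera model: photon shot noise (Poisson), electron-multiplication
// gain (Gamma with integer shape = photoelectron count, scale = gain),
// Gaussian read noise, constant offset.
// [[Rcpp::export]]
NumericVector cpp_emccd_noise(NumericVector mean_photons, double gain,
                              double read_sd, double offset) {
  const R_xlen_t n = mean_photons.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mu = mean_photons[i];
    double sig = 0.0;
    if (mu > 0) {
      const int ne = (int)R::rpois(mu);
      for (int j = 0; j < ne; ++j) sig += R::exp_rand();
    }
    out[i] = gain * sig + (read_sd > 0 ? R::norm_rand() * read_sd : 0.0) + offset;
  }
  return out;
}

// --- detection -------------------------------------------------------------

// Separable Gaussian blur of one frame into `out` (buffers supplied).
static void gauss_blur(const double* fr, int H, int W,
                       const std::vector<double>& kern, int R0,
                       std::vector<double>& tmp, std::vector<double>& out) {
  // along rows (y)
  for (int c = 0; c < W; ++c) {
    const double* col = fr + (R_xlen_t)c * H;
    for (int r = 0; r < H; ++r) {
      double s = 0.0, wsum = 0.0;
      const int lo = std::max(0, r - R0), hi = std::min(H - 1, r + R0);
      for (int k = lo; k <= hi; ++k) { const double w = kern[k - r + R0]; s += w * col[k]; wsum += w; }
      tmp[(R_xlen_t)c * H + r] = s / wsum;
    }
  }
  // along cols (x)
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double s = 0.0, wsum = 0.0;
      const int lo = std::max(0, c - R0), hi = std::min(W - 1, c + R0);
      for (int k = lo; k <= hi; ++k) { const double w = kern[k - c + R0]; s += w * tmp[(R_xlen_t)k * H + r]; wsum += w; }
      out[(R_xlen_t)c * H + r] = s / wsum;
    }
  }
}

// Box mean via running sums (separable), radius br.
static void box_mean(const std::vector<double>& in, int H, int W, int br,
                     std::vector<double>& tmp, std::vector<double>& out) {
  for (int c = 0; c < W; ++c) {
    const double* col = in.data() + (R_xlen_t)c * H;
    for (int r = 0; r < H; ++r) {
      const int lo = std::max(0, r - br), hi = std::min(H - 1, r + br);
      double s = 0.0;
      for (int k = lo; k <= hi; ++k) s += col[k];
      tmp[(R_xlen_t)c * H + r] = s / (hi - lo + 1);
    }
  }
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      const int lo = std::max(0, c - br), hi = std::min(W - 1, c + br);
      double s = 0.0;
      for (int k = lo; k <= hi; ++k) s += tmp[(R_xlen_t)k * H + r];
      out[(R_xlen_t)c * H + r] = s / (hi - lo + 1);
    }
  }
}

// Local-maximum candidates in a band-pass filtered stack.  Threshold is in
// multiples of the frame's robust (MAD-based) noise SD of the filtered image.
// [[Rcpp::export]]
DataFrame cpp_detect_spots(NumericVector stack, int H, int W, int F,
                           double sigma_px, int bg_radius, double thresh_sd,
                           int min_sep) {
  const int R0 = std::max(1, (int)std::ceil(3.0 * sigma_px));
  std::vector<double> kern(2 * R0 + 1);
  for (int k = -R0; k <= R0; ++k)
    kern[k + R0] = std::exp(-0.5 * k * k / (sigma_px * sigma_px));

  std::vector<double> tmp((R_xlen_t)H * W), sm((R_xlen_t)H * W),
      bg((R_xlen_t)H * W), diff((R_xlen_t)H * W), scratch((R_xlen_t)H * W);
  std::vector<int> out_f, out_r, out_c;
  std::vector<double> out_v;
  const double* p = REAL(stack);

  for (int f = 0; f < F; ++f) {
    const double* fr = p + (R_xlen_t)f * H * W;
    gauss_blur(fr, H, W, kern, R0, tmp, sm);
    box_mean(sm, H, W, bg_radius, tmp, bg);
    for (R_xlen_t i = 0; i < (R_xlen_t)H * W; ++i) diff[i] = sm[i] - bg[i];

    // robust SD = 1.4826 * MAD about zero (filtered image has ~zero median)
    scratch = diff;
    for (auto& v : scratch) v = std::fabs(v);
    const R_xlen_t mid = scratch.size() / 2;
    std::nth_element(scratch.begin(), scratch.begin() + mid, scratch.end());
    const double sd = 1.4826 * scratch[mid];
    const double thr = thresh_sd * (sd > 0 ? sd : 1e-12);

    std::vector<int> cr, cc;
    std::vector<double> cv;
    for (int c = 1; c < W - 1; ++c) {
      for (int r = 1; r < H - 1; ++r) {
        const double v = diff[(R_xlen_t)c * H + r];
        if (v <= thr) continue;
        bool ismax = true;
        for (int dc = -1; dc <= 1 && ismax; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const double w = diff[(R_xlen_t)(c + dc) * H + (r + dr)];
            if (w > v || (w == v && (dc < 0 || (dc == 0 && dr < 0)))) { ismax = false; break; }
          }
        if (ismax) { cr.push_back(r); cc.push_back(c); cv.push_back(v); }
      }
    }
    // non-maximum suppression within min_sep (keep brighter)
    const int nc = (int)cr.size();
    std::vector<bool> keep(nc, true);
    for (int i = 0; i < nc; ++i) {
      if (!keep[i]) continue;
      for (int j = 0; j < nc; ++j) {
        if (i == j || !keep[j]) continue;
        const int dr = cr[i] - cr[j], dc = cc[i] - cc[j];
        if (dr * dr + dc * dc < min_sep * min_sep && cv[j] > cv[i]) { keep[i] = false; break; }
      }
    }
    for (int i = 0; i < nc; ++i) {
      if (!keep[i]) continue;
      out_f.push_back(f + 1);
      out_r.push_back(cr[i] + 1);
      out_c.push_back(cc[i] + 1);
      out_v.push_back(cv[i]);
    }
  }
  return DataFrame::create(_["frame"] = out_f, _["row"] = out_r,
                           _["col"] = out_c, _["value"] = out_v);
}

// --- integrated-Gaussian fit ----------------------------------------------

// Solve A x = b for small symmetric positive definite A (in place, size np).
static bool solve_spd(double* A, double* b, int np) {
  for (int i = 0; i < np; ++i) {
    for (int j = i; j < np; ++j) {
      double s = A[i * np + j];
      for (int k = 0; k < i; ++k) s -= A[k * np + i] * A[k * np + j];
      if (i == j) {
        if (s <= 0) return false;
        A[i * np + i] = std::sqrt(s);
      } else A[i * np + j] = s / A[i * np + i];
    }
  }
  for (int i = 0; i < np; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= A[k * np + i] * b[k];
    b[i] = s / A[i * np + i];
  }
  for (int i = np - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < np; ++k) s -= A[i * np + k] * b[k];
    b[i] = s / A[i * np + i];
  }
  return true;
}

struct FitResult {
  double x, y, sx, sy, N, b, rss;
  int converged;
};

// Levenberg-Marquardt least squares fit of model b + N * Ex(x0,sx) * Ey(y0,sy)
// on a square window.  If !elliptical, sx == sy is a single parameter.
static FitResult fit_window(const double* fr, int H, int W, int r0, int c0,
                            int r1, int c1, bool elliptical, double init_s,
                            int max_iter) {
  const int nr = r1 - r0 + 1, nc = c1 - c0 + 1, nd = nr * nc;
  const int np = elliptical ? 6 : 5;
  std::vector<double> data(nd);
  double dmin = 1e300;
  for (int c = c0; c <= c1; ++c)
    for (int r = r0; r <= r1; ++r) {
      const double v = fr[(R_xlen_t)c * H + r];
      data[(c - c0) * nr + (r - r0)] = v;
      if (v < dmin) dmin = v;
    }
  // init: background = window min, centroid of excess signal
  double b = dmin, N = 0, mx = 0, my = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      const double e = data[c * nr + r] - b;
      N += e; mx += e * (c0 + c + 0.5); my += e * (r0 + r + 0.5);
    }
  if (N <= 0) N = 1.0;
  double x0 = mx / N, y0 = my / N, sx = init_s, sy = init_s;
  if (x0 < c0 || x0 > c1 + 1) x0 = c0 + nc / 2.0;
  if (y0 < r0 || y0 > r1 + 1) y0 = r0 + nr / 2.0;

  std::vector<double> ex(nc), ey(nr), dex(nc), dey(nr), dsx(nc), dsy(nr);
  std::vector<double> J(np), JtJ(np * np), Jtr(np), delta(np), Awork(np * np);
  double lambda = 1e-3, rss = 1e300;
  int converged = 0;

  auto compute_cols = [&](double x0_, double sx_, double y0_, double sy_) {
    for (int c = 0; c < nc; ++c) {
      const double cc = c0 + c;
      ex[c] = pix_erf(cc, x0_, sx_);
      const double u1 = (cc - x0_) * INV_SQRT2 / sx_;
      const double u2 = (cc + 1 - x0_) * INV_SQRT2 / sx_;
      const double g1 = std::exp(-u1 * u1), g2 = std::exp(-u2 * u2);
      dex[c] = -INV_SQRT2PI / sx_ * (g2 - g1);
      dsx[c] = -INV_SQRTPI / sx_ * (u2 * g2 - u1 * g1);
    }
    for (int r = 0; r < nr; ++r) {
      const double rr = r0 + r;
      ey[r] = pix_erf(rr, y0_, sy_);
      const double u1 = (rr - y0_) * INV_SQRT2 / sy_;
      const double u2 = (rr + 1 - y0_) * INV_SQRT2 / sy_;
      const double g1 = std::exp(-u1 * u1), g2 = std::exp(-u2 * u2);
      dey[r] = -INV_SQRT2PI / sy_ * (g2 - g1);
      dsy[r] = -INV_SQRTPI / sy_ * (u2 * g2 - u1 * g1);
    }
  };

  auto rss_at = [&](double x0_, double y0_, double sx_, double sy_, double N_, double b_) {
    double s = 0.0;
    for (int c = 0; c < nc; ++c) {
      const double exc = pix_erf(c0 + c, x0_, sx_);
      for (int r = 0; r < nr; ++r) {
        const double m = b_ + N_ * exc * pix_erf(r0 + r, y0_, sy_);
        const double d = m - data[c * nr + r];
        s += d * d;
      }
    }
    return s;
  };

  rss = rss_at(x0, y0, sx, sy, N, b);
  for (int it = 0; it < max_iter; ++it) {
    compute_cols(x0, sx, y0, sy);
    std::fill(JtJ.begin(), JtJ.end(), 0.0);
    std::fill(Jtr.begin(), Jtr.end(), 0.0);
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        const double m = b + N * ex[c] * ey[r];
        const double res = m - data[c * nr + r];
        J[0] = N * ey[r] * dex[c];
        J[1] = N * ex[c] * dey[r];
        if (elliptical) {
          J[2] = N * ey[r] * dsx[c];
          J[3] = N * ex[c] * dsy[r];
          J[4] = ex[c] * ey[r];
          J[5] = 1.0;
        } else {
          J[2] = N * (ey[r] * dsx[c] + ex[c] * dsy[r]);
          J[3] = ex[c] * ey[r];
          J[4] = 1.0;
        }
        for (int i = 0; i < np; ++i) {
          Jtr[i] += J[i] * res;
          for (int j = i; j < np; ++j) JtJ[i * np + j] += J[i] * J[j];
        }
      }
    }
    bool accepted = false;
    for (int tries = 0; tries < 12 && !accepted; ++tries) {
      Awork = JtJ;
      for (int i = 0; i < np; ++i) Awork[i * np + i] *= (1.0 + lambda);
      for (int i = 0; i < np; ++i) delta[i] = -Jtr[i];
      if (!solve_spd(Awork.data(), delta.data(), np)) { lambda *= 10; continue; }
      double nx = x0 + delta[0], ny = y0 + delta[1], nsx, nsy, nN, nb;
      if (elliptical) { nsx = sx + delta[2]; nsy = sy + delta[3]; nN = N + delta[4]; nb = b + delta[5]; }
      else { nsx = sx + delta[2]; nsy = nsx; nN = N + delta[3]; nb = b + delta[4]; }
      nsx = std::min(std::max(nsx, 0.3), 10.0);
      nsy = std::min(std::max(nsy, 0.3), 10.0);
      if (nN < 1.0) nN = 1.0;
      const double nrss = rss_at(nx, ny, nsx, nsy, nN, nb);
      if (nrss <= rss) {
        const double drel = (rss - nrss) / (rss + 1e-30);
        x0 = nx; y0 = ny; sx = nsx; sy = nsy; N = nN; b = nb; rss = nrss;
        lambda = std::max(lambda * 0.3, 1e-12);
        accepted = true;
        if (drel < 1e-12) { converged = 1; it = max_iter; }
      } else lambda *= 10;
    }
    if (!accepted) { converged = 1; break; }  // stalled at a minimum
  }
  FitResult out;
  out.x = x0; out.y = y0; out.sx = sx; out.sy = sy; out.N = N; out.b = b;
  out.rss = rss;
  // reject fits that ran out of the window
  out.converged = (x0 >= c0 - 1 && x0 <= c1 + 2 && y0 >= r0 - 1 && y0 <= r1 + 2) ? 1 : 0;
  return out;
}

// Batch fit of candidate spots.  frame/row/col are 1-based (R indexing).
// Returns px-unit x/y (FOV-corner origin), sigmas, photons-equivalent
// amplitude and background in the stack's count units.
// [[Rcpp::export]]
NumericMatrix cpp_fit_spots(NumericVector stack, int H, int W, int F,
                            IntegerVector frame, IntegerVector row,
                            IntegerVector col, int win, bool elliptical,
                            double init_sigma_px, int max_iter) {
  const int n = frame.size();
  NumericMatrix out(n, 8);
  colnames(out) = CharacterVector::create("x_px", "y_px", "sx_px", "sy_px",
                                          "amp", "bg", "rss", "ok");
  const double* p = REAL(stack);
  for (int k = 0; k < n; ++k) {
    const int f = frame[k] - 1, r = row[k] - 1, c = col[k] - 1;
    int r0 = std::max(0, r - win), r1 = std::min(H - 1, r + win);
    int c0 = std::max(0, c - win), c1 = std::min(W - 1, c + win);
    FitResult fr = fit_window(p + (R_xlen_t)f * H * W, H, W, r0, c0, r1, c1,
                              elliptical, init_sigma_px, max_iter);
    out(k, 0) = fr.x; out(k, 1) = fr.y; out(k, 2) = fr.sx; out(k, 3) = fr.sy;
    out(k, 4) = fr.N; out(k, 5) = fr.b; out(k, 6) = fr.rss; out(k, 7) = fr.converged;
  }
  return out;
}

// --- neighbor searches (uniform grid hash) ---------------------------------

struct Grid {
  double h;
  int dim;
  std::unordered_map<long long, std::vector<int>> cells;
  const NumericMatrix* pts;

  static long long key(int ix, int iy, int iz) {
    return ((long long)(ix + 1048576) << 42) ^ ((long long)(iy + 1048576) << 21) ^
           (long long)(iz + 1048576);
  }
  void build(const NumericMatrix& P, double cell) {
    pts = &P; h = cell; dim = P.ncol();
    for (int i = 0; i < P.nrow(); ++i) {
      const int ix = (int)std::floor(P(i, 0) / h);
      const int iy = (int)std::floor(P(i, 1) / h);
      const int iz = dim > 2 ? (int)std::floor(P(i, 2) / h) : 0;
      cells[key(ix, iy, iz)].push_back(i);
    }
  }
};

static inline double sqdist(const NumericMatrix& A, int i,
                            const NumericMatrix& B, int j, int dim) {
  double s = 0.0;
  for (int d = 0; d < dim; ++d) { const double t = A(i, d) - B(j, d); s += t * t; }
  return s;
}

// Count of B points within radius r of each A point (optionally excluding an
// identical index when A and B are the same table: exclude_self).
// [[Rcpp::export]]
IntegerVector cpp_count_within(NumericMatrix A, NumericMatrix B, double r,
                               bool exclude_self) {
  const int dim = A.ncol();
  Grid g; g.build(B, r);
  const double r2 = r * r;
  IntegerVector out(A.nrow());
  const int zlo = dim > 2 ? -1 : 0, zhi = dim > 2 ? 1 : 0;
  for (int i = 0; i < A.nrow(); ++i) {
    const int ix = (int)std::floor(A(i, 0) / r);
    const int iy = (int)std::floor(A(i, 1) / r);
    const int iz = dim > 2 ? (int)std::floor(A(i, 2) / r) : 0;
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = zlo; dz <= zhi; ++dz) {
          auto it = g.cells.find(Grid::key(ix + dx, iy + dy, iz + dz));
          if (it == g.cells.end()) continue;
          for (int j : it->second) {
            if (exclude_self && j == i) continue;
            if (sqdist(A, i, B, j, dim) <= r2) ++cnt;
          }
        }
    out[i] = cnt;
  }
  return out;
}

// Nearest neighbor in B for each A point; returns distance and 1-based index.
// [[Rcpp::export]]
List cpp_nn(NumericMatrix A, NumericMatrix B, double cell_hint) {
  const int dim = A.ncol(), nB = B.nrow();
  if (nB == 0) stop("empty reference point set");
  double h = cell_hint > 0 ? cell_hint : 1.0;
  Grid g; g.build(B, h);
  NumericVector dist(A.nrow());
  IntegerVector idx(A.nrow());
  for (int i = 0; i < A.nrow(); ++i) {
    const int ix = (int)std::floor(A(i, 0) / h);
    const int iy = (int)std::floor(A(i, 1) / h);
    const int iz = dim > 2 ? (int)std::floor(A(i, 2) / h) : 0;
    double best = 1e300; int bestj = -1;
    for (int ring = 0; ; ++ring) {
      bool any_cell = false;
      for (int dx = -ring; dx <= ring; ++dx)
        for (int dy = -ring; dy <= ring; ++dy) {
          const int zr = dim > 2 ? ring : 0;
          for (int dz = -zr; dz <= zr; ++dz) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != ring)
              continue;  // only the shell
            auto it = g.cells.find(Grid::key(ix + dx, iy + dy, iz + dz));
            if (it == g.cells.end()) continue;
            any_cell = true;
            for (int j : it->second) {
              const double d2 = sqdist(A, i, B, j, dim);
              if (d2 < best) { best = d2; bestj = j; }
            }
          }
        }
      (void)any_cell;
      // done once the found NN cannot be beaten by a farther shell
      if (bestj >= 0 && (double)ring * h >= std::sqrt(best)) break;
      if (ring > 4096) {  // degenerate grid; brute force fallback
        for (int j = 0; j < nB; ++j) {
          const double d2 = sqdist(A, i, B, j, dim);
          if (d2 < best) { best = d2; bestj = j; }
        }
        break;
      }
    }
    dist[i] = std::sqrt(best);
    idx[i] = bestj + 1;
  }
  return List::create(_["dist"] = dist, _["index"] = idx);
}

// --- merging of reappearing molecules --------------------------------------

// Streaming chain assignment: localizations sorted by frame; a localization
// joins the nearest open chain whose intensity-weighted centroid lies within
// `radius` and whose FIRST frame is less than `max_gap` frames back;
// otherwise it seeds a new chain.  Returns 1-based chain ids.
// [[Rcpp::export]]
IntegerVector cpp_merge_chains(IntegerVector frame, NumericMatrix XY,
                               NumericVector photons, double radius,
                               int max_gap) {
  const int n = frame.size(), dim = XY.ncol();
  IntegerVector id(n);
  struct Chain { double w; std::vector<double> cw; int first; };
  std::vector<Chain> chains;
  std::vector<int> open;  // indices into chains
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    const int f = frame[i];
    // close expired chains
    open.erase(std::remove_if(open.begin(), open.end(),
                              [&](int c) { return f - chains[c].first >= max_gap; }),
               open.end());
    double best = r2; int bestc = -1;
    for (int c : open) {
      double d2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        const double t = XY(i, d) - chains[c].cw[d] / chains[c].w;
        d2 += t * t;
      }
      if (d2 <= best) { best = d2; bestc = c; }
    }
    const double w = std::max(photons[i], 1e-12);
    if (bestc >= 0) {
      for (int d = 0; d < dim; ++d) chains[bestc].cw[d] += w * XY(i, d);
      chains[bestc].w += w;
      id[i] = bestc + 1;
    } else {
      Chain ch; ch.w = w; ch.first = f;
      ch.cw.resize(dim);
      for (int d = 0; d < dim; ++d) ch.cw[d] = w * XY(i, d);
      chains.push_back(ch);
      open.push_back((int)chains.size() - 1);
      id[i] = (int)chains.size();
    }
  }
  return id;
}
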