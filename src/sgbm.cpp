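// Semi-global block matching: sum-of-absolute-differences block cost,
// multi-path scanline aggregation with P1/P2 smoothness penalties,
// winner-take-all with deterministic ties toward smaller disparity,
// parabolic sub-pixel refinement, uniqueness filtering and a left-right
// consistency check.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <climits>
#include <cmath>

using namespace Rcpp;

// cost volume C[(d*H + y)*W + x]
static void compute_block_cost(const IntegerMatrix &left, const IntegerMatrix &right,
                               int minD, int numD, int block,
                               std::vector<int32_t> &C) {
  const int H = left.nrow(), W = left.ncol();
  const int r = block / 2;
  std::vector<int32_t> ad((size_t)H * W);
  std::vector<int64_t> rowsum((size_t)H * W);
  for (int d = 0; d < numD; ++d) {
    int shift = minD + d;
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        int xr = x - shift;
        // out-of-image correspondence: flat maximal cost, so such pixels
        // never win uniquely and the uniqueness filter drops them
        ad[(size_t)y * W + x] = (xr < 0 || xr > W - 1)
          ? 255 : std::abs(left(y, x) - right(y, xr));
      }
    }
    // box filter block x block with clamped borders (separable sliding sums)
    for (int y = 0; y < H; ++y) {
      int64_t s = 0;
      for (int k = -r; k <= r; ++k) {
        int xx = k < 0 ? 0 : (k > W - 1 ? W - 1 : k);
        s += ad[(size_t)y * W + xx];
      }
      rowsum[(size_t)y * W + 0] = s;
      for (int x = 1; x < W; ++x) {
        int xa = x + r; if (xa > W - 1) xa = W - 1;
        int xs = x - r - 1; if (xs < 0) xs = 0;
        s += ad[(size_t)y * W + xa] - ad[(size_t)y * W + xs];
        rowsum[(size_t)y * W + x] = s;
      }
    }
    size_t base = (size_t)d * H * W;
    for (int x = 0; x < W; ++x) {
      int64_t s = 0;
      for (int k = -r; k <= r; ++k) {
        int yy = k < 0 ? 0 : (k > H - 1 ? H - 1 : k);
        s += rowsum[(size_t)yy * W + x];
      }
      C[base + 0 * W + x] = (int32_t)s;
      for (int y = 1; y < H; ++y) {
        int ya = y + r; if (ya > H - 1) ya = H - 1;
        int ys = y - r - 1; if (ys < 0) ys = 0;
        s += rowsum[(size_t)ya * W + x] - rowsum[(size_t)ys * W + x];
        C[base + (size_t)y * W + x] = (int32_t)s;
      }
    }
  }
}

// aggregate cost volume C along one scanline direction, adding into S
static void aggregate_path(const std::vector<int32_t> &C, std::vector<int32_t> &S,
                           int H, int W, int numD, int dx, int dy,
                           int P1, int P2) {
  std::vector<int32_t> Lprev((size_t)W * numD), Lcur((size_t)W * numD);
  int y0 = dy >= 0 ? 0 : H - 1, y1 = dy >= 0 ? H : -1, ys = dy >= 0 ? 1 : -1;
  int x0 = dx >= 0 ? 0 : W - 1, x1 = dx >= 0 ? W : -1, xs = dx >= 0 ? 1 : -1;
  // Lprev holds L of row (y - dy); Lcur is filled along the row so
  // (x - dx) of the same row is available for horizontal components.
  for (int y = y0; y != y1; y += ys) {
    for (int x = x0; x != x1; x += xs) {
      int xp = x - dx, yp = y - dy;
      bool inside = xp >= 0 && xp < W && yp >= 0 && yp < H;
      const int32_t *Lp = NULL;
      if (inside) {
        Lp = (yp == y) ? &Lcur[(size_t)xp * numD] : &Lprev[(size_t)xp * numD];
      }
      int32_t *Lc = &Lcur[(size_t)x * numD];
      const int32_t *Cc = &C[0];
      if (!inside) {
        for (int d = 0; d < numD; ++d)
          Lc[d] = C[((size_t)d * H + y) * W + x];
      } else {
        int32_t minPrev = INT32_MAX;
        for (int d = 0; d < numD; ++d) if (Lp[d] < minPrev) minPrev = Lp[d];
        for (int d = 0; d < numD; ++d) {
          int32_t best = Lp[d];
          if (d > 0 && Lp[d - 1] + P1 < best) best = Lp[d - 1] + P1;
          if (d < numD - 1 && Lp[d + 1] + P1 < best) best = Lp[d + 1] + P1;
          if (minPrev + P2 < best) best = minPrev + P2;
          Lc[d] = C[((size_t)d * H + y) * W + x] + best - minPrev;
        }
      }
      (void)Cc;
    }
    for (int x = 0; x < W; ++x) {
      for (int d = 0; d < numD; ++d)
        S[((size_t)d * H + y) * W + x] += Lcur[(size_t)x * numD + d];
    }
    std::swap(Lprev, Lcur);
  }
}

// invalidate connected speckles: 4-connected components of pixels whose
// disparities differ by <= range, smaller than minSize pixels
static void speckle_filter(NumericMatrix &disp, int minSize, double range) {
  const int H = disp.nrow(), W = disp.ncol();
  std::vector<int> label((size_t)H * W, -1);
  std::vector<int> stackv;
  std::vector<int> members;
  int cur = 0;
  for (int y0 = 0; y0 < H; ++y0) {
    for (int x0 = 0; x0 < W; ++x0) {
      size_t i0 = (size_t)y0 * W + x0;
      if (label[i0] >= 0 || ISNA(disp(y0, x0))) continue;
      stackv.clear(); members.clear();
      stackv.push_back((int)i0);
      label[i0] = cur;
      while (!stackv.empty()) {
        int i = stackv.back(); stackv.pop_back();
        members.push_back(i);
        int y = i / W, x = i % W;
        double dv = disp(y, x);
        const int nx[4] = {x - 1, x + 1, x, x};
        const int ny[4] = {y, y, y - 1, y + 1};
        for (int k = 0; k < 4; ++k) {
          if (nx[k] < 0 || nx[k] >= W || ny[k] < 0 || ny[k] >= H) continue;
          size_t j = (size_t)ny[k] * W + nx[k];
          if (label[j] >= 0) continue;
          double dn = disp(ny[k], nx[k]);
          if (ISNA(dn) || std::fabs(dn - dv) > range) continue;
          label[j] = cur;
          stackv.push_back((int)j);
        }
      }
      if ((int)members.size() < minSize) {
        for (size_t t = 0; t < members.size(); ++t) {
          disp(members[t] / W, members[t] % W) = NA_REAL;
        }
      }
      ++cur;
    }
  }
}

// [[Rcpp::export]]
List cpp_sgbm(IntegerMatrix left, IntegerMatrix right, int minD, int numD,
              int block, int P1, int P2, int nPaths, double lrTol,
              int uniquenessRatio, int textureThreshold, int speckleWindow,
              double speckleRange, bool returnCost) {
  const int H = left.nrow(), W = left.ncol();
  std::vector<int32_t> C((size_t)numD * H * W);
  compute_block_cost(left, right, minD, numD, block, C);
  std::vector<int32_t> S((size_t)numD * H * W, 0);

  const int dirs8[8][2] = {{1, 0}, {-1, 0}, {0, 1}, {0, -1},
                           {1, 1}, {-1, -1}, {1, -1}, {-1, 1}};
  int nd = (nPaths == 8) ? 8 : (nPaths == 4 ? 4 : 1);
  for (int k = 0; k < nd; ++k)
    aggregate_path(C, S, H, W, numD, dirs8[k][0], dirs8[k][1], P1, P2);

  // texture mask: local intensity range of the left block window; pixels with
  // no signal (uniform/dark) cannot be matched reliably
  std::vector<bool> textured((size_t)H * W, true);
  if (textureThreshold > 0) {
    int r = block / 2 + 1;
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        int lo = 255, hi = 0;
        for (int yy = y - r; yy <= y + r; ++yy) {
          int yc = yy < 0 ? 0 : (yy > H - 1 ? H - 1 : yy);
          for (int xx = x - r; xx <= x + r; ++xx) {
            int xc = xx < 0 ? 0 : (xx > W - 1 ? W - 1 : xx);
            int v = left(yc, xc);
            if (v < lo) lo = v;
            if (v > hi) hi = v;
          }
        }
        if (hi - lo < textureThreshold) textured[(size_t)y * W + x] = false;
      }
    }
  }

  // winner-take-all on the left image
  NumericMatrix disp(H, W);
  std::vector<int> bestIdx((size_t)H * W, -1);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!textured[(size_t)y * W + x]) { disp(y, x) = NA_REAL; continue; }
      int32_t best = INT32_MAX, second = INT32_MAX;
      int bd = -1;
      for (int d = 0; d < numD; ++d) {
        int32_t v = S[((size_t)d * H + y) * W + x];
        if (v < best) { best = v; bd = d; }
      }
      // uniqueness: any cost outside d* +/- 1 that is too close invalidates
      bool ok = true;
      if (uniquenessRatio > 0) {
        for (int d = 0; d < numD; ++d) {
          if (std::abs(d - bd) <= 1) continue;
          int32_t v = S[((size_t)d * H + y) * W + x];
          if ((int64_t)v * 100 <= (int64_t)best * (100 + uniquenessRatio)) {
            ok = false; break;
          }
        }
      }
      (void)second;
      if (!ok) { disp(y, x) = NA_REAL; continue; }
      double dval = minD + bd;
      // a zero aggregated cost is an exact photometric match; the parabola
      // would only drag it toward whichever neighbour is cheaper
      if (best > 0 && bd > 0 && bd < numD - 1) {
        double c0 = S[((size_t)(bd - 1) * H + y) * W + x];
        double c1 = best;
        double c2 = S[((size_t)(bd + 1) * H + y) * W + x];
        double denom = c0 - 2.0 * c1 + c2;
        if (denom > 1e-9) {
          double delta = (c0 - c2) / (2.0 * denom);
          if (delta > 0.5) delta = 0.5;
          if (delta < -0.5) delta = -0.5;
          dval += delta;
        }
      }
      disp(y, x) = dval;
      bestIdx[(size_t)y * W + x] = bd;
    }
  }

  // right-view disparity from the same aggregated volume:
  // S_right(xr, d) = S(xr + minD + d, d)
  if (lrTol >= 0) {
    std::vector<double> dispR((size_t)H * W, NA_REAL);
    for (int y = 0; y < H; ++y) {
      for (int xr = 0; xr < W; ++xr) {
        int32_t best = INT32_MAX; int bd = -1;
        for (int d = 0; d < numD; ++d) {
          int xl = xr + minD + d;
          if (xl < 0 || xl >= W) continue;
          int32_t v = S[((size_t)d * H + y) * W + xl];
          if (v < best) { best = v; bd = d; }
        }
        if (bd >= 0) dispR[(size_t)y * W + xr] = minD + bd;
      }
    }
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        double dL = disp(y, x);
        if (ISNA(dL)) continue;
        int xr = (int)std::lround(x - dL);
        if (xr < 0 || xr >= W) { disp(y, x) = NA_REAL; continue; }
        double dR = dispR[(size_t)y * W + xr];
        if (ISNA(dR) || std::fabs(dL - dR) > lrTol) disp(y, x) = NA_REAL;
      }
    }
  }

  if (speckleWindow > 0) speckle_filter(disp, speckleWindow, speckleRange);

  List out = List::create(_["disparity"] = disp);
  if (returnCost) {
    Dimension dim(H, W, numD);
    NumericVector Sarr(dim);
    for (size_t i = 0; i < S.size(); ++i) {
      int d = i / ((size_t)H * W);
      size_t rem = i - (size_t)d * H * W;
      int y = rem / W, x = rem % W;
      Sarr[(size_t)d * H * W + (size_t)x * H + y] = S[i];
    }
    out["cost"] = Sarr;
  }
  return out;
}
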