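// z-buffer rasterizer for the simulated microscope and pattern projector.
// Vertices arrive already transformed into the rendering camera's frame (mm,
// +z forward); projection is an ideal pinhole (the synthetic rig renders
// without lens distortion). Shading = ambient + Lambertian spot + Phong
// specular + projected binary pattern with a projector-side shadow test.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static inline double edge_fn(double ax, double ay, double bx, double by,
                             double px, double py) {
  return (bx - ax) * (py - ay) - (by - ay) * (px - ax);
}

// [[Rcpp::export]]
List cpp_render(NumericMatrix V, IntegerMatrix F, NumericVector albedo,
                double fx, double fy, double cx, double cy,
                int width, int height, List shading,
                Nullable<IntegerMatrix> pattern_, Nullable<List> projector_,
                Nullable<NumericMatrix> proj_depth_, bool depth_only) {
  const int nF = F.nrow();
  const int W = width, H = height;
  const double znear = 1.0;

  std::vector<double> zbuf((size_t)W * H, std::numeric_limits<double>::infinity());
  std::vector<double> keybuf((size_t)W * H, std::numeric_limits<double>::infinity());
  std::vector<int> fidbuf((size_t)W * H, -1);
  std::vector<double> b0buf((size_t)W * H), b1buf((size_t)W * H);
  std::vector<int> i0buf((size_t)W * H), i1buf((size_t)W * H), i2buf((size_t)W * H);

  for (int f = 0; f < nF; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double Az = V(ia, 2), Bz = V(ib, 2), Cz = V(ic, 2);
    if (Az < znear || Bz < znear || Cz < znear) continue;
    double au = fx * V(ia, 0) / Az + cx, av = fy * V(ia, 1) / Az + cy;
    double bu = fx * V(ib, 0) / Bz + cx, bv = fy * V(ib, 1) / Bz + cy;
    double cu = fx * V(ic, 0) / Cz + cx, cv = fy * V(ic, 1) / Cz + cy;

    // permutation-invariant z-tie key from original vertex indices
    int s0 = ia, s1 = ib, s2 = ic, tmp;
    if (s0 > s1) { tmp = s0; s0 = s1; s1 = tmp; }
    if (s1 > s2) { tmp = s1; s1 = s2; s2 = tmp; }
    if (s0 > s1) { tmp = s0; s0 = s1; s1 = tmp; }
    double key = (double)s0 * 1e12 + (double)s1 * 1e6 + (double)s2;

    double area2 = edge_fn(au, av, bu, bv, cu, cv);
    if (std::fabs(area2) < 1e-12) continue;
    // normalize to counter-clockwise in screen space
    if (area2 < 0) {
      std::swap(ib, ic);
      std::swap(bu, cu); std::swap(bv, cv);
      std::swap(Bz, Cz);
      area2 = -area2;
    }
    int x0 = (int)std::floor(std::min(au, std::min(bu, cu)));
    int x1 = (int)std::ceil(std::max(au, std::max(bu, cu)));
    int y0 = (int)std::floor(std::min(av, std::min(bv, cv)));
    int y1 = (int)std::ceil(std::max(av, std::max(bv, cv)));
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0;
    if (x1 > W - 1) x1 = W - 1; if (y1 > H - 1) y1 = H - 1;
    if (x0 > x1 || y0 > y1) continue;

    for (int py = y0; py <= y1; ++py) {
      for (int px = x0; px <= x1; ++px) {
        double w0 = edge_fn(bu, bv, cu, cv, px, py);
        double w1 = edge_fn(cu, cv, au, av, px, py);
        double w2 = edge_fn(au, av, bu, bv, px, py);
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        double l0 = w0 / area2, l1 = w1 / area2, l2 = w2 / area2;
        double invz = l0 / Az + l1 / Bz + l2 / Cz;
        double z = 1.0 / invz;
        size_t idx = (size_t)py * W + px;
        if (z < zbuf[idx] || (z == zbuf[idx] && key < keybuf[idx])) {
          zbuf[idx] = z;
          keybuf[idx] = key;
          fidbuf[idx] = f;
          // perspective-correct barycentrics (weights on vertex attributes)
          double p0 = (l0 / Az) * z, p1 = (l1 / Bz) * z;
          b0buf[idx] = p0; b1buf[idx] = p1;
          i0buf[idx] = ia; i1buf[idx] = ib; i2buf[idx] = ic;
        }
      }
    }
  }

  NumericMatrix depth(H, W);
  for (int py = 0; py < H; ++py)
    for (int px = 0; px < W; ++px) {
      size_t idx = (size_t)py * W + px;
      depth(py, px) = std::isfinite(zbuf[idx]) ? zbuf[idx] : 0.0;
    }
  if (depth_only) {
    return List::create(_["depth"] = depth);
  }

  // shading parameters
  double ambient = as<double>(shading["ambient"]);
  double spot_power = as<double>(shading["spot_power"]);
  NumericVector sd = shading["spot_direction"];
  double spec_power = as<double>(shading["specular_power"]);
  double spec_exp = as<double>(shading["specular_exponent"]);
  double pattern_gain = as<double>(shading["pattern_gain"]);
  double lx = sd[0], ly = sd[1], lz = sd[2];
  double ln = std::sqrt(lx * lx + ly * ly + lz * lz);
  lx /= ln; ly /= ln; lz /= ln;

  bool has_pattern = pattern_.isNotNull() && projector_.isNotNull();
  IntegerMatrix pattern;
  double pfx = 0, pfy = 0, pcx = 0, pcy = 0;
  NumericMatrix pR, pDepth;
  NumericVector pT;
  int pW = 0, pH = 0;
  bool has_proj_depth = false;
  if (has_pattern) {
    pattern = as<IntegerMatrix>(pattern_);
    List proj(projector_);
    NumericMatrix K = proj["K"];
    pfx = K(0, 0); pfy = K(1, 1); pcx = K(0, 2); pcy = K(1, 2);
    pR = as<NumericMatrix>(proj["R"]);
    pT = as<NumericVector>(proj["T"]);
    pW = pattern.ncol(); pH = pattern.nrow();
    if (proj_depth_.isNotNull()) {
      pDepth = as<NumericMatrix>(proj_depth_);
      has_proj_depth = true;
    }
  }
  const double shadow_bias = 0.3; // mm

  NumericMatrix img(H, W);
  for (int py = 0; py < H; ++py) {
    for (int px = 0; px < W; ++px) {
      size_t idx = (size_t)py * W + px;
      int f = fidbuf[idx];
      if (f < 0) { img(py, px) = 0.0; continue; }
      double z = zbuf[idx];
      // camera-frame surface point from the pixel ray
      double Px = (px - cx) / fx * z, Py = (py - cy) / fy * z, Pz = z;
      int ia = i0buf[idx], ib = i1buf[idx], ic = i2buf[idx];
      double l0 = b0buf[idx], l1 = b1buf[idx], l2 = 1.0 - l0 - l1;
      double alb = l0 * albedo[ia] + l1 * albedo[ib] + l2 * albedo[ic];
      // face normal, oriented toward the camera
      double e1x = V(ib, 0) - V(ia, 0), e1y = V(ib, 1) - V(ia, 1), e1z = V(ib, 2) - V(ia, 2);
      double e2x = V(ic, 0) - V(ia, 0), e2y = V(ic, 1) - V(ia, 1), e2z = V(ic, 2) - V(ia, 2);
      double nx = e1y * e2z - e1z * e2y;
      double ny = e1z * e2x - e1x * e2z;
      double nz = e1x * e2y - e1y * e2x;
      double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
      if (nn < 1e-15) nn = 1.0;
      nx /= nn; ny /= nn; nz /= nn;
      if (nx * Px + ny * Py + nz * Pz > 0) { nx = -nx; ny = -ny; nz = -nz; }

      double ndotl = -(nx * lx + ny * ly + nz * lz);
      if (ndotl < 0) ndotl = 0;
      double intensity = alb * (ambient + spot_power * ndotl);

      if (spec_power > 0) {
        // reflect light direction about the normal; view direction = -P/|P|
        double dln = lx * nx + ly * ny + lz * nz;
        double rx = lx - 2 * dln * nx, ry = ly - 2 * dln * ny, rz = lz - 2 * dln * nz;
        double pn = std::sqrt(Px * Px + Py * Py + Pz * Pz);
        double vdx = -Px / pn, vdy = -Py / pn, vdz = -Pz / pn;
        double rdotv = rx * vdx + ry * vdy + rz * vdz;
        if (rdotv > 0) intensity += spec_power * std::pow(rdotv, spec_exp);
      }

      if (has_pattern && pattern_gain > 0) {
        double qx = pR(0, 0) * Px + pR(0, 1) * Py + pR(0, 2) * Pz + pT[0];
        double qy = pR(1, 0) * Px + pR(1, 1) * Py + pR(1, 2) * Pz + pT[1];
        double qz = pR(2, 0) * Px + pR(2, 1) * Py + pR(2, 2) * Pz + pT[2];
        if (qz > znear) {
          int pu = (int)std::lround(pfx * qx / qz + pcx);
          int pv = (int)std::lround(pfy * qy / qz + pcy);
          if (pu >= 0 && pu < pW && pv >= 0 && pv < pH && pattern(pv, pu) > 0) {
            bool lit = true;
            if (has_proj_depth) {
              double dref = pDepth(pv, pu);
              if (dref > 0 && qz > dref + shadow_bias) lit = false;
            }
            if (lit) intensity += pattern_gain * alb;
          }
        }
      }
      img(py, px) = intensity;
    }
  }
  return List::create(_["image"] = img, _["depth"] = depth);
}

// bilinear remap used by stereo rectification: out(y,x) = img(mapy(y,x), mapx(y,x))
// with 0-based source coordinates; out-of-source pixels become 0.
// [[Rcpp::export]]
NumericMatrix cpp_remap_bilinear(NumericMatrix img, NumericMatrix mapx,
                                 NumericMatrix mapy) {
  int H = mapx.nrow(), W = mapx.ncol();
  int sh = img.nrow(), sw = img.ncol();
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      double sx = mapx(y, x), sy = mapy(y, x);
      const double eps = 1e-9; // absorb rounding at the exact border
      if (!(sx >= -eps && sy >= -eps && sx <= sw - 1 + eps && sy <= sh - 1 + eps)) {
        out(y, x) = 0.0;
        continue;
      }
      if (sx < 0) sx = 0;
      if (sy < 0) sy = 0;
      if (sx > sw - 1) sx = sw - 1;
      if (sy > sh - 1) sy = sh - 1;
      int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      int x1 = x0 < sw - 1 ? x0 + 1 : x0;
      int y1 = y0 < sh - 1 ? y0 + 1 : y0;
      double ax = sx - x0, ay = sy - y0;
      out(y, x) = (1 - ay) * ((1 - ax) * img(y0, x0) + ax * img(y0, x1)) +
                  ay * ((1 - ax) * img(y1, x0) + ax * img(y1, x1));
    }
  }
  return out;
}
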