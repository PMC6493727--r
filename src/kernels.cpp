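#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
#include <queue>
#include <algorithm>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// k x k running median with edge replication. Values are 16-bit intensities
// stored as ints; k is odd and small, so insertion into a scratch buffer and
// nth_element is fast enough for megapixel frames.
static inline void med_swap(int& a, int& b) { if (b < a) std::swap(a, b); }

// optimal 19-comparison median-of-9 network
static inline int median9(int p[9]) {
  med_swap(p[1], p[2]); med_swap(p[4], p[5]); med_swap(p[7], p[8]);
  med_swap(p[0], p[1]); med_swap(p[3], p[4]); med_swap(p[6], p[7]);
  med_swap(p[1], p[2]); med_swap(p[4], p[5]); med_swap(p[7], p[8]);
  med_swap(p[0], p[3]); med_swap(p[5], p[8]); med_swap(p[4], p[7]);
  med_swap(p[3], p[6]); med_swap(p[1], p[4]); med_swap(p[2], p[5]);
  med_swap(p[4], p[7]); med_swap(p[4], p[2]); med_swap(p[6], p[4]);
  med_swap(p[4], p[2]);
  return p[4];
}

// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(const IntegerMatrix& img, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel must be odd and >= 1");
  const int H = img.nrow(), W = img.ncol(), h = k / 2;
  IntegerMatrix out(H, W);
  if (k == 3 && H >= 3 && W >= 3) {
    const int* x = INTEGER(img);
    int* y = INTEGER(out);
    int p[9];
    for (int c = 0; c < W; ++c) {
      const int cm = clampi(c - 1, 0, W - 1), cp = clampi(c + 1, 0, W - 1);
      const int* colm = x + (size_t)cm * H;
      const int* col0 = x + (size_t)c * H;
      const int* colp = x + (size_t)cp * H;
      for (int r = 0; r < H; ++r) {
        const int rm = clampi(r - 1, 0, H - 1), rp = clampi(r + 1, 0, H - 1);
        p[0] = colm[rm]; p[1] = colm[r]; p[2] = colm[rp];
        p[3] = col0[rm]; p[4] = col0[r]; p[5] = col0[rp];
        p[6] = colp[rm]; p[7] = colp[r]; p[8] = colp[rp];
        y[(size_t)c * H + r] = median9(p);
      }
    }
    return out;
  }
  std::vector<int> buf(k * k);
  const int mid = (k * k) / 2;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int n = 0;
      for (int dc = -h; dc <= h; ++dc) {
        const int cc = clampi(c + dc, 0, W - 1);
        for (int dr = -h; dr <= h; ++dr) {
          const int rr = clampi(r + dr, 0, H - 1);
          buf[n++] = img(rr, cc);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(r, c) = buf[mid];
    }
  }
  return out;
}

// Binary box morphology, separable (horizontal then vertical max/min pass).
// Pixels outside the image count as background for both operations.
static void box_pass(std::vector<unsigned char>& a, int H, int W, int h,
                     bool dilate) {
  std::vector<unsigned char> tmp((size_t)H * W);
  // horizontal
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      unsigned char v = dilate ? 0 : 1;
      for (int dc = -h; dc <= h; ++dc) {
        const int cc = c + dc;
        const unsigned char x =
          (cc < 0 || cc >= W) ? 0 : a[(size_t)cc * H + r];
        if (dilate) { if (x) { v = 1; break; } }
        else        { if (!x) { v = 0; break; } }
      }
      tmp[(size_t)c * H + r] = v;
    }
  }
  // vertical
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      unsigned char v = dilate ? 0 : 1;
      for (int dr = -h; dr <= h; ++dr) {
        const int rr = r + dr;
        const unsigned char x =
          (rr < 0 || rr >= H) ? 0 : tmp[(size_t)c * H + rr];
        if (dilate) { if (x) { v = 1; break; } }
        else        { if (!x) { v = 0; break; } }
      }
      a[(size_t)c * H + r] = v;
    }
  }
}

static LogicalMatrix box_morph(const LogicalMatrix& mask, int k, int iters,
                               bool dilate) {
  if (k < 1 || k % 2 == 0) stop("kernel must be odd and >= 1");
  const int H = mask.nrow(), W = mask.ncol(), h = k / 2;
  std::vector<unsigned char> a((size_t)H * W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      a[(size_t)c * H + r] = mask(r, c) ? 1 : 0;
  for (int it = 0; it < iters; ++it) box_pass(a, H, W, h, dilate);
  LogicalMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = a[(size_t)c * H + r] != 0;
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_box_dilate(const LogicalMatrix& mask, int k, int iters) {
  return box_morph(mask, k, iters, true);
}

// [[Rcpp::export]]
LogicalMatrix cpp_box_erode(const LogicalMatrix& mask, int k, int iters) {
  return box_morph(mask, k, iters, false);
}

// Componentwise interval test of an H x W x 3 (B,G,R) 16-bit array against
// per-channel [lo, up] bounds.
// [[Rcpp::export]]
LogicalMatrix cpp_color_mask(const IntegerVector& px, int H, int W,
                             const IntegerVector& lo, const IntegerVector& up) {
  LogicalMatrix out(H, W);
  const int* p = INTEGER(px);
  const size_t plane = (size_t)H * W;
  for (size_t i = 0; i < plane; ++i) {
    const int b = p[i], g = p[i + plane], r = p[i + 2 * plane];
    out[i] = b >= lo[0] && b <= up[0] && g >= lo[1] && g <= up[1] &&
             r >= lo[2] && r <= up[2];
  }
  return out;
}

// Rec. 601 luminance of an H x W x 3 (B,G,R) array, optionally zeroed
// outside a mask.
// [[Rcpp::export]]
IntegerMatrix cpp_luminance(const IntegerVector& px, int H, int W,
                            Nullable<LogicalMatrix> mask = R_NilValue) {
  IntegerMatrix out(H, W);
  const int* p = INTEGER(px);
  const size_t plane = (size_t)H * W;
  if (mask.isNotNull()) {
    LogicalMatrix m(mask);
    for (size_t i = 0; i < plane; ++i)
      out[i] = m[i] ? (int)std::lround(0.114 * p[i] + 0.587 * p[i + plane] +
                                       0.299 * p[i + 2 * plane]) : 0;
  } else {
    for (size_t i = 0; i < plane; ++i)
      out[i] = (int)std::lround(0.114 * p[i] + 0.587 * p[i + plane] +
                                0.299 * p[i + 2 * plane]);
  }
  return out;
}

// Grey-level box max filter (separable), used to find local maxima of the
// distance transform when seeding segmentation markers.
// [[Rcpp::export]]
NumericMatrix cpp_box_maxfilter(const NumericMatrix& img, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel must be odd and >= 1");
  const int H = img.nrow(), W = img.ncol(), h = k / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c) {          // horizontal pass
    const int c0 = std::max(0, c - h), c1 = std::min(W - 1, c + h);
    for (int r = 0; r < H; ++r) {
      double v = img(r, c0);
      for (int cc = c0 + 1; cc <= c1; ++cc)
        if (img(r, cc) > v) v = img(r, cc);
      tmp(r, c) = v;
    }
  }
  for (int c = 0; c < W; ++c) {          // vertical pass
    for (int r = 0; r < H; ++r) {
      const int r0 = std::max(0, r - h), r1 = std::min(H - 1, r + h);
      double v = tmp(r0, c);
      for (int rr = r0 + 1; rr <= r1; ++rr)
        if (tmp(rr, c) > v) v = tmp(rr, c);
      out(r, c) = v;
    }
  }
  return out;
}

// Sobel gradients with replicated borders; returns gx (along columns / x)
// and gy (along rows / y).
// [[Rcpp::export]]
List cpp_sobel(const NumericMatrix& img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix gx(H, W), gy(H, W);
  for (int c = 0; c < W; ++c) {
    const int cm = clampi(c - 1, 0, W - 1), cp = clampi(c + 1, 0, W - 1);
    for (int r = 0; r < H; ++r) {
      const int rm = clampi(r - 1, 0, H - 1), rp = clampi(r + 1, 0, H - 1);
      const double tl = img(rm, cm), tc = img(rm, c), tr = img(rm, cp);
      const double ml = img(r, cm),                  mr = img(r, cp);
      const double bl = img(rp, cm), bc = img(rp, c), br = img(rp, cp);
      gx(r, c) = (tr + 2.0 * mr + br) - (tl + 2.0 * ml + bl);
      gy(r, c) = (bl + 2.0 * bc + br) - (tl + 2.0 * tc + tr);
    }
  }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}

// Canny core: non-maximum suppression of the gradient magnitude perpendicular
// to the edge, then hysteresis linking (8-connected) between tmin and tmax.
// The caller smooths the image and supplies Sobel gradients.
// [[Rcpp::export]]
LogicalMatrix cpp_canny_nms(const NumericMatrix& gx, const NumericMatrix& gy,
                            double tmin, double tmax) {
  if (!(tmin < tmax)) stop("t_min must be < t_max");
  const int H = gx.nrow(), W = gx.ncol();
  NumericMatrix mag(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      mag(r, c) = std::sqrt(gx(r, c) * gx(r, c) + gy(r, c) * gy(r, c));

  // 0 = none, 1 = weak, 2 = strong
  IntegerMatrix cls(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const double m = mag(r, c);
      if (m < tmin) continue;
      // quantize gradient direction into 4 sectors
      const double ax = std::fabs(gx(r, c)), ay = std::fabs(gy(r, c));
      int dr1, dc1;
      if (ax >= 2.414 * ay)       { dr1 = 0; dc1 = 1; }          // horizontal gradient
      else if (ay >= 2.414 * ax)  { dr1 = 1; dc1 = 0; }          // vertical gradient
      else if ((gx(r, c) > 0) == (gy(r, c) > 0)) { dr1 = 1; dc1 = 1; }
      else                        { dr1 = 1; dc1 = -1; }
      const int ra = clampi(r + dr1, 0, H - 1), ca = clampi(c + dc1, 0, W - 1);
      const int rb = clampi(r - dr1, 0, H - 1), cb = clampi(c - dc1, 0, W - 1);
      if (m >= mag(ra, ca) && m >= mag(rb, cb))
        cls(r, c) = (m >= tmax) ? 2 : 1;
    }
  }

  // hysteresis: BFS from strong pixels through weak ones
  LogicalMatrix out(H, W);
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (cls(r, c) == 2) { out(r, c) = true; q.push(std::make_pair(r, c)); }
  while (!q.empty()) {
    const int r = q.front().first, c = q.front().second; q.pop();
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (cls(rr, cc) == 1 && !out(rr, cc)) {
          out(rr, cc) = true;
          q.push(std::make_pair(rr, cc));
        }
      }
    }
  }
  return out;
}

// Circular Hough Transform vote accumulation. Each edge pixel casts votes
// along +/- its gradient direction at every candidate radius; per radius the
// (a,b) accumulator is pooled over a 3x3 centre neighbourhood (absorbing
// gradient-direction quantization) and cells with pooled votes >=
// voteFrac * 2*pi*R are returned as peak candidates. Greedy non-maximum
// suppression happens in R.
// [[Rcpp::export]]
DataFrame cpp_cht_candidates(const LogicalMatrix& edges,
                             const NumericMatrix& gx, const NumericMatrix& gy,
                             const IntegerVector& radii, double voteFrac) {
  const int H = edges.nrow(), W = edges.ncol();
  // gather edge pixels and unit gradient directions once
  std::vector<int> er, ec;
  std::vector<double> ux, uy;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!edges(r, c)) continue;
      const double g = std::sqrt(gx(r, c) * gx(r, c) + gy(r, c) * gy(r, c));
      if (g <= 0) continue;
      er.push_back(r); ec.push_back(c);
      ux.push_back(gx(r, c) / g); uy.push_back(gy(r, c) / g);
    }
  }
  std::vector<int> acc((size_t)H * W, 0);
  std::vector<size_t> touched;
  touched.reserve(4 * er.size());
  std::vector<int> out_r, out_c, out_R, out_v;
  const size_t nE = er.size();
  for (int ri = 0; ri < radii.size(); ++ri) {
    const int R = radii[ri];
    for (size_t t = 0; t < touched.size(); ++t) acc[touched[t]] = 0;
    touched.clear();
    for (size_t i = 0; i < nE; ++i) {
      for (int s = -1; s <= 1; s += 2) {
        const int a = (int)std::lround(er[i] + s * R * uy[i]);
        const int b = (int)std::lround(ec[i] + s * R * ux[i]);
        if (a >= 0 && a < H && b >= 0 && b < W) {
          const size_t idx = (size_t)b * H + a;
          if (acc[idx] == 0) touched.push_back(idx);
          acc[idx]++;
        }
      }
    }
    const double thr = voteFrac * 2.0 * M_PI * R;
    // only cells that received a direct vote can be pooled peaks
    for (size_t t = 0; t < touched.size(); ++t) {
      const int r = (int)(touched[t] % H), c = (int)(touched[t] / H);
      int v = 0;
      for (int dc = -2; dc <= 2; ++dc) {
        const int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        for (int dr = -2; dr <= 2; ++dr) {
          const int rr = r + dr;
          if (rr < 0 || rr >= H) continue;
          v += acc[(size_t)cc * H + rr];
        }
      }
      if (v >= thr) {
        out_r.push_back(r); out_c.push_back(c);
        out_R.push_back(R); out_v.push_back(v);
      }
    }
  }
  return DataFrame::create(_["row"] = out_r, _["col"] = out_c,
                           _["radius"] = out_R, _["votes"] = out_v);
}

// Complete a labeling over a mask: mask pixels without a label adopt the
// smallest positive 8-neighbour label, iterated `iters` times with
// double buffering (so the result is independent of scan order). Used to
// hand every colour-mask pixel to its segmented object after the edge-based
// stages, whose localization sits a pixel or two inside the mask.
// [[Rcpp::export]]
IntegerMatrix cpp_label_complete(const IntegerMatrix& labels,
                                 const LogicalMatrix& mask, int iters) {
  const int H = labels.nrow(), W = labels.ncol();
  IntegerMatrix cur = clone(labels);
  // gather the unlabeled mask pixels once; each sweep reads `cur` and
  // stages its writes, so the result is scan-order independent
  std::vector<int> pr, pc;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (mask(r, c) && cur(r, c) == 0) { pr.push_back(r); pc.push_back(c); }
  for (int it = 0; it < iters && !pr.empty(); ++it) {
    std::vector<int> nr, nc, nl;
    std::vector<int> rest_r, rest_c;
    for (size_t i = 0; i < pr.size(); ++i) {
      const int r = pr[i], c = pc[i];
      int best = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        const int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        for (int dr = -1; dr <= 1; ++dr) {
          const int rr = r + dr;
          if (rr < 0 || rr >= H) continue;
          const int l = cur(rr, cc);
          if (l > 0 && (best == 0 || l < best)) best = l;
        }
      }
      if (best > 0) { nr.push_back(r); nc.push_back(c); nl.push_back(best); }
      else { rest_r.push_back(r); rest_c.push_back(c); }
    }
    if (nr.empty()) break;
    for (size_t i = 0; i < nr.size(); ++i) cur(nr[i], nc[i]) = nl[i];
    pr.swap(rest_r);
    pc.swap(rest_c);
  }
  return cur;
}

// 8-connected labeling of a binary mask (label 0 = background).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        const int cr = q.front().first, cc = q.front().second; q.pop();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            const int rr = cr + dr, c2 = cc + dc;
            if (rr < 0 || rr >= H || c2 < 0 || c2 >= W) continue;
            if (mask(rr, c2) && lab(rr, c2) == 0) {
              lab(rr, c2) = next;
              q.push(std::make_pair(rr, c2));
            }
          }
        }
      }
    }
  }
  return lab;
}
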