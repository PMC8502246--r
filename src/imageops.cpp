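#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pixel convention shared with the R side: u = column, v = row, both
// 0-based, origin at the top-left pixel centre.

// Bilinear resampling: out(u, v) = img(map %*% (u, v, 1)) where map sends
// output pixel coordinates to source pixel coordinates. Pixels that fall
// outside the source grid (any corner of the bilinear cell missing or NA)
// become NA.
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(NumericMatrix img, NumericMatrix map,
                                int out_rows, int out_cols) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(out_rows, out_cols);
  const double m11 = map(0, 0), m12 = map(0, 1), m13 = map(0, 2);
  const double m21 = map(1, 0), m22 = map(1, 1), m23 = map(1, 2);
  const double m31 = map(2, 0), m32 = map(2, 1), m33 = map(2, 2);
  for (int v = 0; v < out_rows; ++v) {
    for (int u = 0; u < out_cols; ++u) {
      double w = m31 * u + m32 * v + m33;
      if (w == 0.0) { out(v, u) = NA_REAL; continue; }
      double su = (m11 * u + m12 * v + m13) / w;
      double sv = (m21 * u + m22 * v + m23) / w;
      int u0 = (int)std::floor(su), v0 = (int)std::floor(sv);
      if (u0 < 0 || v0 < 0 || u0 + 1 > nc - 1 || v0 + 1 > nr - 1) {
        // allow exact right/bottom border
        if (su >= 0 && sv >= 0 && su <= nc - 1 && sv <= nr - 1) {
          if (u0 == nc - 1) u0--;
          if (v0 == nr - 1) v0--;
        } else { out(v, u) = NA_REAL; continue; }
      }
      double fu = su - u0, fv = sv - v0;
      double p00 = img(v0, u0),     p01 = img(v0, u0 + 1);
      double p10 = img(v0 + 1, u0), p11 = img(v0 + 1, u0 + 1);
      if (ISNAN(p00) || ISNAN(p01) || ISNAN(p10) || ISNAN(p11)) {
        out(v, u) = NA_REAL; continue;
      }
      out(v, u) = (1 - fv) * ((1 - fu) * p00 + fu * p01) +
                  fv * ((1 - fu) * p10 + fu * p11);
    }
  }
  return out;
}

// 8- or 4-connected component labelling (iterative stack flood fill).
// mask: logical matrix (NA treated as background). Labels start at 1 in
// raster-scan order of the first pixel encountered.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int du8[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  const int dv8[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  const int du4[4] = {1, 0, -1, 0};
  const int dv4[4] = {0, 1, 0, -1};
  int next = 0;
  std::vector<int> stack;
  for (int v = 0; v < nr; ++v) {
    for (int u = 0; u < nc; ++u) {
      if (lab(v, u) != 0) continue;
      if (mask(v, u) != TRUE) continue;
      ++next;
      stack.clear();
      stack.push_back(v + nr * u);
      lab(v, u) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pv = p % nr, pu = p / nr;
        for (int k = 0; k < nnb; ++k) {
          int qu = pu + (connectivity == 8 ? du8[k] : du4[k]);
          int qv = pv + (connectivity == 8 ? dv8[k] : dv4[k]);
          if (qu < 0 || qv < 0 || qu >= nc || qv >= nr) continue;
          if (lab(qv, qu) == 0 && mask(qv, qu) == TRUE) {
            lab(qv, qu) = next;
            stack.push_back(qv + nr * qu);
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour boundary tracing with Jacob's stopping criterion for one
// label. Returns the ordered outer boundary as an n x 2 matrix of (u, v)
// and the traced path length (closed ring; steps weighted 1 / sqrt(2)).
// [[Rcpp::export]]
List cpp_trace_contour(IntegerMatrix lab, int label) {
  const int nr = lab.nrow(), nc = lab.ncol();
  // clockwise on screen (v grows downward), starting East
  const int du[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  const int dv[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  int su = -1, sv = -1;
  for (int v = 0; v < nr && su < 0; ++v)
    for (int u = 0; u < nc; ++u)
      if (lab(v, u) == label) { su = u; sv = v; break; }
  if (su < 0) stop("label not present");
  std::vector<int> cu, cv;
  cu.push_back(su); cv.push_back(sv);
  // backtrack starts due West of the start pixel (background by scan order)
  int bu = su, bv = sv;      // current boundary pixel
  int pu = su - 1, pv = sv;  // previous (background) pixel
  const int p0u = pu, p0v = pv;
  long guard = 8L * (long)nr * (long)nc + 16;
  while (guard-- > 0) {
    // direction index of backtrack relative to current
    int d0 = 0;
    for (int k = 0; k < 8; ++k)
      if (bu + du[k] == pu && bv + dv[k] == pv) { d0 = k; break; }
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (d0 + k) % 8;
      int qu = bu + du[d], qv = bv + dv[d];
      if (qu >= 0 && qv >= 0 && qu < nc && qv < nr && lab(qv, qu) == label) {
        found = d; break;
      }
      pu = qu; pv = qv;  // last examined background pixel
    }
    if (found < 0) break;  // isolated pixel
    int nu = bu + du[found], nv = bv + dv[found];
    // stop when the tracer state repeats its initial state: back at the
    // start pixel with the original backtrack, so the walk would repeat
    if (nu == su && nv == sv && pu == p0u && pv == p0v) break;
    cu.push_back(nu); cv.push_back(nv);
    bu = nu; bv = nv;
  }
  int n = cu.size();
  NumericMatrix contour(n, 2);
  double per = 0.0;
  for (int i = 0; i < n; ++i) {
    contour(i, 0) = cu[i];
    contour(i, 1) = cv[i];
    int j = (i + 1) % n;
    int step_u = std::abs(cu[j] - cu[i]), step_v = std::abs(cv[j] - cv[i]);
    if (step_u <= 1 && step_v <= 1 && (step_u + step_v) > 0)
      per += (step_u + step_v == 2) ? M_SQRT2 : 1.0;
    else if (step_u + step_v > 0)
      per += std::sqrt((double)(step_u * step_u + step_v * step_v));
  }
  if (n == 1) per = 0.0;
  return List::create(_["contour"] = contour, _["perimeter"] = per);
}

// Paint filled discs into an integer raster (used by the scene renderer).
// cx, cy are 0-based fractional (col, row) centres, r in pixels.
// [[Rcpp::export]]
void cpp_fill_discs(IntegerMatrix grid, NumericVector cx, NumericVector cy,
                    NumericVector r, int value) {
  const int nr = grid.nrow(), nc = grid.ncol();
  for (int i = 0; i < cx.size(); ++i) {
    double x = cx[i], y = cy[i], rad = r[i], r2 = rad * rad;
    int u0 = std::max(0, (int)std::floor(x - rad));
    int u1 = std::min(nc - 1, (int)std::ceil(x + rad));
    int v0 = std::max(0, (int)std::floor(y - rad));
    int v1 = std::min(nr - 1, (int)std::ceil(y + rad));
    for (int v = v0; v <= v1; ++v) {
      double dy = v - y;
      for (int u = u0; u <= u1; ++u) {
        double dx = u - x;
        if (dx * dx + dy * dy <= r2) grid(v, u) = value;
      }
    }
  }
}

// Nearest-neighbour sample of an integer raster at fractional (row, col)
// positions (1-based, R indexing); out-of-range -> fill.
// [[Rcpp::export]]
IntegerVector cpp_sample_nearest(IntegerMatrix grid, NumericVector rows,
                                 NumericVector cols, int fill) {
  const int nr = grid.nrow(), nc = grid.ncol();
  int n = rows.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int r = (int)std::lround(rows[i]) - 1;
    int c = (int)std::lround(cols[i]) - 1;
    out[i] = (r < 0 || c < 0 || r >= nr || c >= nc) ? fill : grid(r, c);
  }
  return out;
}

// Bilinear sample of lut[label] over an integer label raster at fractional
// (row, col) positions (1-based): models the sensor PSF averaging class
// reflectances across cell boundaries. Out-of-range clamps to the edge.
// [[Rcpp::export]]
NumericVector cpp_sample_lut_bilinear(IntegerMatrix grid, NumericVector lut,
                                      NumericVector rows,
                                      NumericVector cols) {
  const int nr = grid.nrow(), nc = grid.ncol();
  int n = rows.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double r = rows[i] - 1.0, c = cols[i] - 1.0;
    if (r < 0) r = 0; if (c < 0) c = 0;
    if (r > nr - 1) r = nr - 1; if (c > nc - 1) c = nc - 1;
    int r0 = (int)r, c0 = (int)c;
    if (r0 == nr - 1 && nr > 1) r0--;
    if (c0 == nc - 1 && nc > 1) c0--;
    double fr = r - r0, fc = c - c0;
    int r1 = (nr > 1) ? r0 + 1 : r0, c1 = (nc > 1) ? c0 + 1 : c0;
    out[i] = (1 - fr) * ((1 - fc) * lut[grid(r0, c0)] +
                         fc * lut[grid(r0, c1)]) +
             fr * ((1 - fc) * lut[grid(r1, c0)] +
                   fc * lut[grid(r1, c1)]);
  }
  return out;
}

// Same bilinear scheme over a plain numeric raster (albedo field).
// [[Rcpp::export]]
NumericVector cpp_sample_bilinear(NumericMatrix grid, NumericVector rows,
                                  NumericVector cols) {
  const int nr = grid.nrow(), nc = grid.ncol();
  int n = rows.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double r = rows[i] - 1.0, c = cols[i] - 1.0;
    if (r < 0) r = 0; if (c < 0) c = 0;
    if (r > nr - 1) r = nr - 1; if (c > nc - 1) c = nc - 1;
    int r0 = (int)r, c0 = (int)c;
    if (r0 == nr - 1 && nr > 1) r0--;
    if (c0 == nc - 1 && nc > 1) c0--;
    double fr = r - r0, fc = c - c0;
    int r1 = (nr > 1) ? r0 + 1 : r0, c1 = (nc > 1) ? c0 + 1 : c0;
    out[i] = (1 - fr) * ((1 - fc) * grid(r0, c0) + fc * grid(r0, c1)) +
             fr * ((1 - fc) * grid(r1, c0) + fc * grid(r1, c1));
  }
  return out;
}
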