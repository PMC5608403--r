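// Hot loops of the per-frame pipeline: separable convolution for the LoG
// blob filter, 8-connected labeling, perinuclear ring statistics, and the
// territorial cell renderer. Semantics mirror the R reference
// implementations of the exported per-cell operations.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Convolve columns with k1 then rows with k2 (replicate boundary).
static void conv_cols(const double* src, double* dst, int nr, int nc,
                      const double* k, int h) {
  for (int c = 0; c < nc; ++c) {
    const double* col = src + (size_t)c * nr;
    double* out = dst + (size_t)c * nr;
    for (int r = 0; r < std::min(h, nr); ++r) {
      double acc = 0.0;
      for (int j = -h; j <= h; ++j) {
        int rr = r + j; if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        acc += col[rr] * k[j + h];
      }
      out[r] = acc;
    }
    for (int r = h; r < nr - h; ++r) {
      double acc = 0.0;
      const double* p = col + r - h;
      for (int j = 0; j <= 2 * h; ++j) acc += p[j] * k[j];
      out[r] = acc;
    }
    for (int r = std::max(h, nr - h); r < nr; ++r) {
      double acc = 0.0;
      for (int j = -h; j <= h; ++j) {
        int rr = r + j; if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        acc += col[rr] * k[j + h];
      }
      out[r] = acc;
    }
  }
}

static void conv_rows(const double* src, double* dst, int nr, int nc,
                      const double* k, int h) {
  // accumulate shifted columns: dst[, c] = sum_j k[j] * src[, c+j-h]
  std::fill(dst, dst + (size_t)nr * nc, 0.0);
  for (int c = 0; c < nc; ++c) {
    double* out = dst + (size_t)c * nr;
    for (int j = -h; j <= h; ++j) {
      int cc = c + j; if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
      const double* col = src + (size_t)cc * nr;
      const double w = k[j + h];
      for (int r = 0; r < nr; ++r) out[r] += w * col[r];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix conv_sep2(const NumericMatrix& img, const NumericVector& k1,
                        const NumericVector& k2) {
  const int nr = img.nrow(), nc = img.ncol();
  const int h1 = (k1.size() - 1) / 2, h2 = (k2.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  conv_cols(img.begin(), tmp.begin(), nr, nc, k1.begin(), h1);
  conv_rows(tmp.begin(), out.begin(), nr, nc, k2.begin(), h2);
  return out;
}

// Full LoG blob response (sign-flipped): G''xG + GxG'' applied to `img`.
// [[Rcpp::export]]
NumericMatrix log_response_cpp(const NumericMatrix& img,
                               const NumericVector& g,
                               const NumericVector& gpp) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hg = (g.size() - 1) / 2, hp = (gpp.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), t1(nr, nc), t2(nr, nc);
  conv_cols(img.begin(), tmp.begin(), nr, nc, gpp.begin(), hp);
  conv_rows(tmp.begin(), t1.begin(), nr, nc, g.begin(), hg);
  conv_cols(img.begin(), tmp.begin(), nr, nc, g.begin(), hg);
  conv_rows(tmp.begin(), t2.begin(), nr, nc, gpp.begin(), hp);
  for (size_t i = 0; i < (size_t)nr * nc; ++i) t1[i] = -(t1[i] + t2[i]);
  return t1;
}

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass 8-connected labeling of a logical matrix.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(const LogicalMatrix& bw) {
  const int nr = bw.nrow(), nc = bw.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!bw(r, c)) continue;
      int best = 0;
      int neigh[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      int labs[4], nlab = 0;
      for (int k = 0; k < 4; ++k) {
        int rr = neigh[k][0], cc = neigh[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) { labs[nlab++] = l; if (best == 0 || l < best) best = l; }
      }
      if (best == 0) {
        ++next; parent.push_back(next); lab(r, c) = next;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < nlab; ++k) uf_union(parent, best, labs[k]);
      }
    }
  }
  std::vector<int> remap(next + 1, 0);
  int nfinal = 0;
  for (int l = 1; l <= next; ++l) {
    int root = uf_find(parent, l);
    if (remap[root] == 0) remap[root] = ++nfinal;
    remap[l] = remap[root];
  }
  for (int i = 0; i < nr * nc; ++i) if (lab[i] > 0) lab[i] = remap[lab[i]];
  return lab;
}

// Mean of the brightest `frac` fraction of the ring pixels of each label.
// The ring is background within (inner, outer] of any nucleus, restricted
// to the disk of radius r_eff + outer + 1 around the label's centroid.
// [[Rcpp::export]]
NumericVector ring_top_means(const IntegerMatrix& mask,
                             const NumericMatrix& bg_dist,
                             const NumericMatrix& img,
                             const NumericVector& c_row,
                             const NumericVector& c_col,
                             const NumericVector& area,
                             double inner, double outer, double frac) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int n = c_row.size();
  NumericVector out(n, NA_REAL);
  std::vector<double> vals;
  for (int l = 0; l < n; ++l) {
    double reach = std::sqrt(area[l] / M_PI) + outer + 1.0;
    double reach2 = reach * reach;
    int r0 = std::max(0, (int)std::floor(c_row[l] - 1 - reach));
    int r1 = std::min(nr - 1, (int)std::ceil(c_row[l] - 1 + reach));
    int c0 = std::max(0, (int)std::floor(c_col[l] - 1 - reach));
    int c1 = std::min(nc - 1, (int)std::ceil(c_col[l] - 1 + reach));
    vals.clear();
    for (int c = c0; c <= c1; ++c) {
      double dc = c - (c_col[l] - 1);
      for (int r = r0; r <= r1; ++r) {
        if (mask(r, c) != 0) continue;
        double d = bg_dist(r, c);
        if (d <= inner || d > outer) continue;
        double dr = r - (c_row[l] - 1);
        if (dr * dr + dc * dc > reach2) continue;
        vals.push_back(img(r, c));
      }
    }
    if (vals.empty()) continue;
    int k = std::max(1, (int)std::ceil(frac * vals.size()));
    std::nth_element(vals.begin(), vals.begin() + (k - 1), vals.end(),
                     std::greater<double>());
    double acc = 0.0;
    for (int i = 0; i < k; ++i) acc += vals[i];
    out[l] = acc / k;
  }
  return out;
}

// Resolve pairwise overlaps: push cells apart until centers are at least
// r_i + r_j + gap apart (a few relaxation sweeps).
// [[Rcpp::export]]
List resolve_overlaps_cpp(NumericVector pr, NumericVector pc,
                          const NumericVector& radius, double gap,
                          int iters) {
  const int n = pr.size();
  NumericVector r_out = clone(pr), c_out = clone(pc);
  for (int it = 0; it < iters; ++it) {
    bool any = false;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double lim = radius[i] + radius[j] + gap;
        double dr = r_out[j] - r_out[i], dc = c_out[j] - c_out[i];
        double d2 = dr * dr + dc * dc;
        if (d2 >= lim * lim) continue;
        any = true;
        double d = std::sqrt(d2);
        if (d < 1e-6) { dr = 1.0; dc = 0.0; d = 1.0; }
        double push = (lim - d) / 2.0;
        r_out[i] -= dr / d * push; c_out[i] -= dc / d * push;
        r_out[j] += dr / d * push; c_out[j] += dc / d * push;
      }
    }
    if (!any) break;
  }
  return List::create(_["pr"] = r_out, _["pc"] = c_out);
}

// Chamfer (3,4)/3 distance of background pixels (mask == 0) to the nearest
// foreground pixel, capped at `cap` (values beyond the cap are exact
// enough for gating, not for measurement).
// [[Rcpp::export]]
NumericMatrix chamfer_dist_cpp(const IntegerMatrix& mask, double cap) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e9;
  NumericMatrix d(nr, nc);
  for (size_t i = 0; i < (size_t)nr * nc; ++i) d[i] = mask[i] != 0 ? 0.0 : BIG;
  const double a = 1.0, b = 4.0 / 3.0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = d(r, c);
      if (v == 0.0) continue;
      if (r > 0) v = std::min(v, d(r - 1, c) + a);
      if (c > 0) v = std::min(v, d(r, c - 1) + a);
      if (r > 0 && c > 0) v = std::min(v, d(r - 1, c - 1) + b);
      if (r < nr - 1 && c > 0) v = std::min(v, d(r + 1, c - 1) + b);
      d(r, c) = v;
    }
  }
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = d(r, c);
      if (v == 0.0) continue;
      if (r < nr - 1) v = std::min(v, d(r + 1, c) + a);
      if (c < nc - 1) v = std::min(v, d(r, c + 1) + a);
      if (r < nr - 1 && c < nc - 1) v = std::min(v, d(r + 1, c + 1) + b);
      if (r > 0 && c < nc - 1) v = std::min(v, d(r - 1, c + 1) + b);
      d(r, c) = std::min(v, cap);
    }
  }
  return d;
}

// Territorial cell areas: nucleus pixel count and owned-cytoplasm pixel
// count per cell. Nuclei are disks; a cytoplasm pixel belongs to the cell
// with the nearest nucleus edge and never overlaps any nucleus.
static void ownership(const NumericVector& pr, const NumericVector& pc,
                      const NumericVector& radius, double w,
                      int nr, int nc,
                      std::vector<int>& owner, std::vector<double>& owner_d,
                      std::vector<int>& nuc_owner) {
  const int n = pr.size();
  std::fill(owner.begin(), owner.end(), -1);
  std::fill(owner_d.begin(), owner_d.end(), 1e30);
  std::fill(nuc_owner.begin(), nuc_owner.end(), -1);
  for (int i = 0; i < n; ++i) {
    double r = radius[i];
    int r0 = std::max(0, (int)std::floor(pr[i] - 1 - r));
    int r1 = std::min(nr - 1, (int)std::ceil(pr[i] - 1 + r));
    int c0 = std::max(0, (int)std::floor(pc[i] - 1 - r));
    int c1 = std::min(nc - 1, (int)std::ceil(pc[i] - 1 + r));
    for (int c = c0; c <= c1; ++c) {
      double dc = c - (pc[i] - 1);
      for (int rr = r0; rr <= r1; ++rr) {
        double dr = rr - (pr[i] - 1);
        if (dr * dr + dc * dc <= r * r) nuc_owner[(size_t)c * nr + rr] = i;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    double r = radius[i], rw = r + w;
    int r0 = std::max(0, (int)std::floor(pr[i] - 1 - rw));
    int r1 = std::min(nr - 1, (int)std::ceil(pr[i] - 1 + rw));
    int c0 = std::max(0, (int)std::floor(pc[i] - 1 - rw));
    int c1 = std::min(nc - 1, (int)std::ceil(pc[i] - 1 + rw));
    for (int c = c0; c <= c1; ++c) {
      double dc = c - (pc[i] - 1);
      for (int rr = r0; rr <= r1; ++rr) {
        double dr = rr - (pr[i] - 1);
        double d2 = dr * dr + dc * dc;
        if (d2 > rw * rw || d2 <= r * r) continue;
        size_t px = (size_t)c * nr + rr;
        if (nuc_owner[px] >= 0) continue;
        double edge = std::sqrt(d2) - r;
        if (edge < owner_d[px]) { owner_d[px] = edge; owner[px] = i; }
      }
    }
  }
}

// [[Rcpp::export]]
List cell_areas_cpp(const NumericVector& pr, const NumericVector& pc,
                    const NumericVector& radius, double cyto_width,
                    int nr, int nc) {
  const int n = pr.size();
  std::vector<int> owner((size_t)nr * nc), nuc_owner((size_t)nr * nc);
  std::vector<double> owner_d((size_t)nr * nc);
  ownership(pr, pc, radius, cyto_width, nr, nc, owner, owner_d, nuc_owner);
  IntegerVector a_n(n), a_c(n);
  for (size_t px = 0; px < (size_t)nr * nc; ++px) {
    if (nuc_owner[px] >= 0) a_n[nuc_owner[px]]++;
    else if (owner[px] >= 0) a_c[owner[px]]++;
  }
  return List::create(_["a_n"] = a_n, _["a_c"] = a_c);
}

// Paint per-cell nuclear and cytoplasmic values into channel images
// (additive over a constant background).
// [[Rcpp::export]]
List render_channels_cpp(const NumericVector& pr, const NumericVector& pc,
                         const NumericVector& radius, double cyto_width,
                         int nr, int nc,
                         const NumericMatrix& nuc_vals,
                         const NumericMatrix& cyto_vals,
                         double background) {
  const int n = pr.size(), nch = nuc_vals.ncol();
  std::vector<int> owner((size_t)nr * nc), nuc_owner((size_t)nr * nc);
  std::vector<double> owner_d((size_t)nr * nc);
  ownership(pr, pc, radius, cyto_width, nr, nc, owner, owner_d, nuc_owner);
  List out(nch);
  for (int ch = 0; ch < nch; ++ch) {
    NumericMatrix img(nr, nc);
    std::fill(img.begin(), img.end(), background);
    for (size_t px = 0; px < (size_t)nr * nc; ++px) {
      if (nuc_owner[px] >= 0) img[px] += nuc_vals(nuc_owner[px], ch);
      else if (owner[px] >= 0) img[px] += cyto_vals(owner[px], ch);
    }
    out[ch] = img;
  }
  return out;
}
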