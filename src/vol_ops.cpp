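#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// All voxel kernels use 0-based (i,j,k) index order with i fastest, matching
// R's column-major array layout: linear = i + ni*(j + nj*k).

static inline R_xlen_t lin(int i, int j, int k, int ni, int nj) {
  return (R_xlen_t)i + (R_xlen_t)ni * ((R_xlen_t)j + (R_xlen_t)nj * k);
}

// Trilinear sampling at continuous 0-based index coordinates; coordinates
// outside [0, n-1] per axis return `fill` (NA_REAL allowed).
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(const NumericVector& vol, const IntegerVector& dim,
                                   const NumericVector& ui, const NumericVector& uj,
                                   const NumericVector& uk, double fill) {
  const int ni = dim[0], nj = dim[1], nk = dim[2];
  const R_xlen_t n = ui.size();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = ui[p], y = uj[p], z = uk[p];
    if (!(x >= 0.0 && x <= ni - 1.0 && y >= 0.0 && y <= nj - 1.0 &&
          z >= 0.0 && z <= nk - 1.0)) {
      out[p] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == ni - 1) i0--;
    if (j0 == nj - 1) j0--;
    if (k0 == nk - 1) k0--;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c00 = vol[lin(i0, j0, k0, ni, nj)] * (1 - fx) + vol[lin(i0 + 1, j0, k0, ni, nj)] * fx;
    double c10 = vol[lin(i0, j0 + 1, k0, ni, nj)] * (1 - fx) + vol[lin(i0 + 1, j0 + 1, k0, ni, nj)] * fx;
    double c01 = vol[lin(i0, j0, k0 + 1, ni, nj)] * (1 - fx) + vol[lin(i0 + 1, j0, k0 + 1, ni, nj)] * fx;
    double c11 = vol[lin(i0, j0 + 1, k0 + 1, ni, nj)] * (1 - fx) + vol[lin(i0 + 1, j0 + 1, k0 + 1, ni, nj)] * fx;
    out[p] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
  }
  return out;
}

// Nearest-neighbour sampling at continuous 0-based index coordinates.
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(const NumericVector& vol, const IntegerVector& dim,
                                 const NumericVector& ui, const NumericVector& uj,
                                 const NumericVector& uk, double fill) {
  const int ni = dim[0], nj = dim[1], nk = dim[2];
  const R_xlen_t n = ui.size();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = ui[p], y = uj[p], z = uk[p];
    if (!(x >= -0.5 && x < ni - 0.5 && y >= -0.5 && y < nj - 0.5 &&
          z >= -0.5 && z < nk - 0.5)) {
      out[p] = fill;
      continue;
    }
    int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5), k = (int)std::floor(z + 0.5);
    out[p] = vol[lin(i, j, k, ni, nj)];
  }
  return out;
}

// Median filter over a spherical voxel neighbourhood (offsets with squared
// norm <= radius^2); neighbourhoods are truncated at the volume boundary.
// [[Rcpp::export]]
NumericVector cpp_median_filter(const NumericVector& vol, const IntegerVector& dim,
                                int radius) {
  const int ni = dim[0], nj = dim[1], nk = dim[2];
  std::vector<int> di, dj, dk;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      for (int c = -radius; c <= radius; ++c)
        if (a * a + b * b + c * c <= radius * radius) {
          di.push_back(a); dj.push_back(b); dk.push_back(c);
        }
  const size_t noff = di.size();
  NumericVector out((R_xlen_t)ni * nj * nk);
  std::vector<double> buf(noff);
  for (int k = 0; k < nk; ++k)
    for (int j = 0; j < nj; ++j)
      for (int i = 0; i < ni; ++i) {
        size_t m = 0;
        for (size_t o = 0; o < noff; ++o) {
          int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
          if (ii >= 0 && ii < ni && jj >= 0 && jj < nj && kk >= 0 && kk < nk)
            buf[m++] = vol[lin(ii, jj, kk, ni, nj)];
        }
        size_t mid = m / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + m);
        double med = buf[mid];
        if (m % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + mid);
          med = 0.5 * (med + lo);
        }
        out[lin(i, j, k, ni, nj)] = med;
      }
  return out;
}

static void run_minmax_axis(std::vector<double>& lo, std::vector<double>& hi,
                            int ni, int nj, int nk, int axis, int h1, int h2) {
  // sliding truncated window [p-h1, p+h2] along one axis, O(n*w) direct scan
  int nA = axis == 0 ? ni : (axis == 1 ? nj : nk);
  std::vector<double> tlo(nA), thi(nA), slo(nA), shi(nA);
  int nB, nC;
  if (axis == 0) { nB = nj; nC = nk; } else if (axis == 1) { nB = ni; nC = nk; } else { nB = ni; nC = nj; }
  for (int c = 0; c < nC; ++c)
    for (int b = 0; b < nB; ++b) {
      for (int a = 0; a < nA; ++a) {
        R_xlen_t id = axis == 0 ? lin(a, b, c, ni, nj) : (axis == 1 ? lin(b, a, c, ni, nj) : lin(b, c, a, ni, nj));
        tlo[a] = lo[id]; thi[a] = hi[id];
      }
      for (int a = 0; a < nA; ++a) {
        int p0 = std::max(0, a - h1), p1 = std::min(nA - 1, a + h2);
        double mn = tlo[p0], mx = thi[p0];
        for (int p = p0 + 1; p <= p1; ++p) {
          if (tlo[p] < mn) mn = tlo[p];
          if (thi[p] > mx) mx = thi[p];
        }
        slo[a] = mn; shi[a] = mx;
      }
      for (int a = 0; a < nA; ++a) {
        R_xlen_t id = axis == 0 ? lin(a, b, c, ni, nj) : (axis == 1 ? lin(b, a, c, ni, nj) : lin(b, c, a, ni, nj));
        lo[id] = slo[a]; hi[id] = shi[a];
      }
    }
}

// Local min and max over a centred cubic window of `window` voxels per axis
// (truncated at the boundary); separable sweep over the three axes.
// slicewise = true restricts the window to in-plane (i,j) only.
// [[Rcpp::export]]
List cpp_local_minmax(const NumericVector& vol, const IntegerVector& dim,
                      int window, bool slicewise) {
  const int ni = dim[0], nj = dim[1], nk = dim[2];
  const R_xlen_t n = (R_xlen_t)ni * nj * nk;
  int h1 = (window - 1) / 2, h2 = window - 1 - h1;
  std::vector<double> lo(vol.begin(), vol.end()), hi(vol.begin(), vol.end());
  run_minmax_axis(lo, hi, ni, nj, nk, 0, h1, h2);
  run_minmax_axis(lo, hi, ni, nj, nk, 1, h1, h2);
  if (!slicewise) run_minmax_axis(lo, hi, ni, nj, nk, 2, h1, h2);
  NumericVector rlo(n), rhi(n);
  std::copy(lo.begin(), lo.end(), rlo.begin());
  std::copy(hi.begin(), hi.end(), rhi.begin());
  return List::create(_["lo"] = rlo, _["hi"] = rhi);
}

// Connected-component labelling (BFS); labels assigned in linear scan order,
// so label 1 contains the foreground voxel with the lowest linear index.
// connectivity: 6, 18 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector& mask, const IntegerVector& dim,
                                   int connectivity) {
  const int ni = dim[0], nj = dim[1], nk = dim[2];
  const R_xlen_t n = (R_xlen_t)ni * nj * nk;
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  IntegerVector labels(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    labels[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = (int)(cur % ni), rem = (int)(cur / ni);
      int j = rem % nj, k = rem / nj;
      for (size_t o = 0; o < di.size(); ++o) {
        int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
        if (ii < 0 || ii >= ni || jj < 0 || jj >= nj || kk < 0 || kk >= nk) continue;
        R_xlen_t t = lin(ii, jj, kk, ni, nj);
        if (mask[t] && labels[t] == 0) {
          labels[t] = next;
          q.push(t);
        }
      }
    }
  }
  return labels;
}

// Block-mean downsampling by an integer factor per axis; trailing partial
// blocks are averaged over the voxels present.
// [[Rcpp::export]]
NumericVector cpp_block_mean(const NumericVector& vol, const IntegerVector& dim,
                             int factor) {
  const int ni = dim[0], nj = dim[1], nk = dim[2];
  const int mi = (ni + factor - 1) / factor, mj = (nj + factor - 1) / factor,
            mk = (nk + factor - 1) / factor;
  NumericVector out((R_xlen_t)mi * mj * mk);
  for (int k = 0; k < mk; ++k)
    for (int j = 0; j < mj; ++j)
      for (int i = 0; i < mi; ++i) {
        double s = 0; int cnt = 0;
        for (int kk = k * factor; kk < std::min(nk, (k + 1) * factor); ++kk)
          for (int jj = j * factor; jj < std::min(nj, (j + 1) * factor); ++jj)
            for (int ii = i * factor; ii < std::min(ni, (i + 1) * factor); ++ii) {
              s += vol[lin(ii, jj, kk, ni, nj)];
              ++cnt;
            }
        out[lin(i, j, k, mi, mj)] = s / cnt;
      }
  out.attr("dim") = IntegerVector::create(mi, mj, mk);
  return out;
}

static void run_mean_axis(std::vector<double>& v, int ni, int nj, int nk,
                          int axis, int r) {
  if (r <= 0) return;
  int nA = axis == 0 ? ni : (axis == 1 ? nj : nk);
  int nB, nC;
  if (axis == 0) { nB = nj; nC = nk; } else if (axis == 1) { nB = ni; nC = nk; } else { nB = ni; nC = nj; }
  std::vector<double> t(nA), s(nA);
  for (int c = 0; c < nC; ++c)
    for (int b = 0; b < nB; ++b) {
      for (int a = 0; a < nA; ++a) {
        R_xlen_t id = axis == 0 ? lin(a, b, c, ni, nj) : (axis == 1 ? lin(b, a, c, ni, nj) : lin(b, c, a, ni, nj));
        t[a] = v[id];
      }
      for (int a = 0; a < nA; ++a) {
        int p0 = std::max(0, a - r), p1 = std::min(nA - 1, a + r);
        double acc = 0;
        for (int p = p0; p <= p1; ++p) acc += t[p];
        s[a] = acc / (p1 - p0 + 1);
      }
      for (int a = 0; a < nA; ++a) {
        R_xlen_t id = axis == 0 ? lin(a, b, c, ni, nj) : (axis == 1 ? lin(b, a, c, ni, nj) : lin(b, c, a, ni, nj));
        v[id] = s[a];
      }
    }
}

// Separable box blur with per-axis radii (window 2r+1, truncated at edges).
// [[Rcpp::export]]
NumericVector cpp_box_blur(const NumericVector& vol, const IntegerVector& dim,
                           int ri, int rj, int rk) {
  const int ni = dim[0], nj = dim[1], nk = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  run_mean_axis(v, ni, nj, nk, 0, ri);
  run_mean_axis(v, ni, nj, nk, 1, rj);
  run_mean_axis(v, ni, nj, nk, 2, rk);
  NumericVector out((R_xlen_t)ni * nj * nk);
  std::copy(v.begin(), v.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Joint histogram with partial-volume interpolation: each sample distributes
// its trilinear weights over the moving-image neighbour values, making the
// histogram (and hence mutual information) smooth in the transform.
// fbin: 1-based fixed-image bin per sample; samples outside moving are
// skipped. Returns an (nbins x nbins) matrix [fixed, moving].
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist_pv(const NumericVector& vol, const IntegerVector& dim,
                                const NumericVector& ui, const NumericVector& uj,
                                const NumericVector& uk, const IntegerVector& fbin,
                                int nbins, double m_lo, double m_hi) {
  const int ni = dim[0], nj = dim[1], nk = dim[2];
  const R_xlen_t n = ui.size();
  NumericMatrix joint(nbins, nbins);
  const double scale = (m_hi > m_lo) ? nbins / (m_hi - m_lo) : 0.0;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = ui[p], y = uj[p], z = uk[p];
    if (!(x >= 0.0 && x <= ni - 1.0 && y >= 0.0 && y <= nj - 1.0 &&
          z >= 0.0 && z <= nk - 1.0)) continue;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == ni - 1) i0--;
    if (j0 == nj - 1) j0--;
    if (k0 == nk - 1) k0--;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int fb = fbin[p] - 1;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
          if (w <= 0) continue;
          double val = vol[lin(i0 + dx, j0 + dy, k0 + dz, ni, nj)];
          int mb = (int)std::floor((val - m_lo) * scale);
          if (mb < 0) mb = 0;
          if (mb >= nbins) mb = nbins - 1;
          joint(fb, mb) += w;
        }
  }
  return joint;
}
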