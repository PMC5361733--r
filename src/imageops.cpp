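#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All volumes are R arrays with dim = c(nz, ny, nx), column-major, so the
// linear index of voxel (z, y, x) (0-based) is z + nz * (y + ny * x).
// Connectivity is 26-neighbourhood throughout.

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// Separable Gaussian convolution along each axis; sigma in voxels per axis
// (order z, y, x). Symmetric (mirror) boundary. Axes with negligible sigma
// are skipped, so sigma = 0 is the identity.
// [[Rcpp::export]]
NumericVector cpp_gauss_sep(NumericVector vol, IntegerVector dim,
                            NumericVector sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  std::vector<double> cur(vol.begin(), vol.end()), nxt(n);

  int len[3] = {nz, ny, nx};
  // strides along each axis in the linear layout
  int stride[3] = {1, nz, nz * ny};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 1e-8) continue;
    int r = (int)std::ceil(3.0 * s);
    if (r < 1) r = 1;
    std::vector<double> w(2 * r + 1);
    double tot = 0.0;
    for (int k = -r; k <= r; ++k) {
      w[k + r] = std::exp(-0.5 * (double)k * k / (s * s));
      tot += w[k + r];
    }
    for (double &v : w) v /= tot;
    if (w[0] < 1e-12 && r == 1) {
      // kernel is numerically an identity (e.g. axial sigma ~0.04 voxels)
      if (w[r] > 1.0 - 1e-9) continue;
    }
    int L = len[ax], st = stride[ax];
    // iterate over all 1-D lines along this axis
    int nline = n / L;
    std::vector<double> line(L);
    for (int li = 0; li < nline; ++li) {
      // decompose line index into the two other coordinates
      int base;
      if (ax == 0) {            // lines along z: li over (y, x)
        int y = li % ny, x = li / ny;
        base = lin(0, y, x, nz, ny);
      } else if (ax == 1) {     // lines along y: li over (z, x)
        int z = li % nz, x = li / nz;
        base = lin(z, 0, x, nz, ny);
      } else {                  // lines along x: li over (z, y)
        int z = li % nz, y = li / nz;
        base = lin(z, y, 0, nz, ny);
      }
      // gather the line once, convolve, scatter back
      for (int i = 0; i < L; ++i) line[i] = cur[base + i * st];
      int lo = std::min(r, L), hi = std::max(L - r, 0);
      for (int i = 0; i < lo; ++i) {        // left boundary (mirror)
        double acc = 0.0;
        for (int k = -r; k <= r; ++k) {
          int j = i + k;
          if (j < 0) j = -j - 1;
          if (j >= L) j = 2 * L - j - 1;
          if (j < 0) j = 0;
          if (j >= L) j = L - 1;
          acc += w[k + r] * line[j];
        }
        nxt[base + i * st] = acc;
      }
      for (int i = lo; i < hi; ++i) {       // interior, no checks
        double acc = 0.0;
        const double *lp = &line[i - r];
        for (int k = 0; k <= 2 * r; ++k) acc += w[k] * lp[k];
        nxt[base + i * st] = acc;
      }
      for (int i = std::max(hi, lo); i < L; ++i) {  // right boundary
        double acc = 0.0;
        for (int k = -r; k <= r; ++k) {
          int j = i + k;
          if (j < 0) j = -j - 1;
          if (j >= L) j = 2 * L - j - 1;
          if (j < 0) j = 0;
          if (j >= L) j = L - 1;
          acc += w[k + r] * line[j];
        }
        nxt[base + i * st] = acc;
      }
    }
    cur.swap(nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labelling of a logical mask. Labels are assigned
// in scan-discovery order starting at 1; 0 is background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int i0 = 0; i0 < n; ++i0) {
    if (!mask[i0] || lab[i0] != 0) continue;
    ++next;
    lab[i0] = next;
    stack.push_back(i0);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            int j = lin(zz, yy, xx, nz, ny);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Grayscale morphological reconstruction by dilation of `marker` under
// `mask` (marker is clamped below mask). Vincent's hybrid algorithm:
// one raster sweep, one anti-raster sweep that seeds a FIFO queue, then
// queue propagation to the fixpoint.
// [[Rcpp::export]]
NumericVector cpp_reconstruct(NumericVector marker, NumericVector mask,
                              IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  std::vector<double> rec(n);
  double recMin = R_PosInf;
  for (int i = 0; i < n; ++i) {
    rec[i] = std::min(marker[i], mask[i]);
    if (rec[i] < recMin) recMin = rec[i];
  }

  // forward raster sweep: max over the 13 already-visited neighbours;
  // voxels already at their mask ceiling cannot grow and are skipped
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (rec[i] >= mask[i]) continue;
        double m = rec[i];
        for (int dx = -1; dx <= 0; ++dx) {
          int xx = x + dx;
          if (xx < 0) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            if (dx == 0 && dy > 0) break;
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              if (dx == 0 && dy == 0 && dz >= 0) break;
              int zz = z + dz;
              if (zz < 0 || zz >= nz) continue;
              double v = rec[lin(zz, yy, xx, nz, ny)];
              if (v > m) m = v;
            }
          }
        }
        m = std::min(m, (double)mask[i]);
        if (m > rec[i]) rec[i] = m;
      }

  // anti-raster sweep; voxels whose update could still propagate are queued
  std::vector<int> fifo;
  for (int x = nx - 1; x >= 0; --x)
    for (int y = ny - 1; y >= 0; --y)
      for (int z = nz - 1; z >= 0; --z) {
        int i = lin(z, y, x, nz, ny);
        double m = rec[i];
        if (m < mask[i]) {
          for (int dx = 0; dx <= 1; ++dx) {
            int xx = x + dx;
            if (xx >= nx) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              if (dx == 0 && dy < 0) continue;
              int yy = y + dy;
              if (yy < 0 || yy >= ny) continue;
              for (int dz = -1; dz <= 1; ++dz) {
                if (dx == 0 && dy == 0 && dz <= 0) continue;
                int zz = z + dz;
                if (zz < 0 || zz >= nz) continue;
                double v = rec[lin(zz, yy, xx, nz, ny)];
                if (v > m) m = v;
              }
            }
          }
          m = std::min(m, (double)mask[i]);
          if (m > rec[i]) rec[i] = m;
        }
        // queue if some anti-raster neighbour could still grow from here;
        // nothing can grow from a voxel sitting at the running minimum
        if (rec[i] <= recMin) continue;
        for (int dx = 0; dx <= 1; ++dx) {
          int xx = x + dx;
          if (xx >= nx) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            if (dx == 0 && dy < 0) continue;
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              if (dx == 0 && dy == 0 && dz <= 0) continue;
              int zz = z + dz;
              if (zz < 0 || zz >= nz) continue;
              int j = lin(zz, yy, xx, nz, ny);
              if (rec[j] < rec[i] && rec[j] < mask[j]) {
                fifo.push_back(i);
                dx = 2; dy = 2; dz = 2;   // break all
              }
            }
          }
        }
      }

  // FIFO propagation
  size_t qi = 0;
  while (qi < fifo.size()) {
    int i = fifo[qi++];
    int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
    double ri = rec[i];
    for (int dx = -1; dx <= 1; ++dx) {
      int xx = x + dx;
      if (xx < 0 || xx >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          int j = lin(zz, yy, xx, nz, ny);
          if (rec[j] < ri && mask[j] != rec[j]) {
            double v = std::min(ri, (double)mask[j]);
            if (v > rec[j]) {
              rec[j] = v;
              fifo.push_back(j);
            }
          }
        }
      }
    }
    if (fifo.size() > (size_t)50 * n) stop("reconstruction did not converge");
  }

  NumericVector out(rec.begin(), rec.end());
  out.attr("dim") = dim;
  return out;
}

// Histogram counts of `v` in `n_bins` equal bins over [lo, hi]; values at
// hi land in the last bin.
// [[Rcpp::export]]
IntegerVector cpp_hist_counts(NumericVector v, double lo, double hi,
                              int n_bins) {
  IntegerVector out(n_bins);
  double bw = (hi - lo) / n_bins;
  int n = v.size();
  for (int i = 0; i < n; ++i) {
    int b = (int)((v[i] - lo) / bw);
    if (b < 0) b = 0;
    if (b >= n_bins) b = n_bins - 1;
    ++out[b];
  }
  return out;
}

// Regional maxima as equal-valued plateaus with no strictly greater
// neighbour. A plateau must additionally have at least one strictly lower
// neighbour: a constant image (reconstruction flattened everything) has no
// maxima, which keeps blank channels and sub-height peaks spot-free.
// [[Rcpp::export]]
LogicalVector cpp_regional_maxima(NumericVector vol, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  LogicalVector out(n, false);
  std::vector<char> seen(n, 0);
  std::vector<int> plateau, stack;
  double vmin = R_PosInf;
  for (int i = 0; i < n; ++i)
    if (vol[i] < vmin) vmin = vol[i];
  for (int i0 = 0; i0 < n; ++i0) {
    if (seen[i0]) continue;
    double v = vol[i0];
    if (v == vmin) { seen[i0] = 1; continue; }  // a global-minimum plateau
                                                // has no lower neighbour
    bool has_higher = false, has_lower = false;
    plateau.clear();
    stack.clear();
    seen[i0] = 1;
    stack.push_back(i0);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      plateau.push_back(i);
      int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            int j = lin(zz, yy, xx, nz, ny);
            double vj = vol[j];
            if (vj > v) has_higher = true;
            else if (vj < v) has_lower = true;
            else if (!seen[j]) { seen[j] = 1; stack.push_back(j); }
          }
        }
      }
    }
    if (!has_higher && has_lower)
      for (int i : plateau) out[i] = true;
  }
  out.attr("dim") = dim;
  return out;
}
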