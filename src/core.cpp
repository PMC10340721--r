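#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labelling of a 3D logical array (dim = c(nz, ny, nx)).
// Labels are assigned in scan order (z fastest); callers re-order afterwards.
// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;

  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  int next_label = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == TRUE && lab[i] == 0) {
      ++next_label;
      lab[i] = next_label;
      stack.push_back(i);
      while (!stack.empty()) {
        R_xlen_t cur = stack.back();
        stack.pop_back();
        int z = (int)(cur % nz);
        int y = (int)((cur / nz) % ny);
        int x = (int)(cur / ((R_xlen_t)nz * ny));
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int zz = z + dz;
              if (zz < 0 || zz >= nz) continue;
              R_xlen_t j = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
              if (mask[j] == TRUE && lab[j] == 0) {
                lab[j] = next_label;
                stack.push_back(j);
              }
            }
          }
        }
      }
    }
  }
  return lab;
}

static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nz, int ny, int nx, int axis,
                      const NumericVector& k) {
  const int r = ((int)k.size() - 1) / 2;
  const int dim[3] = {nz, ny, nx};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  const int nd = dim[axis];
  const R_xlen_t sd = stride[axis];
  // iterate over all lines along `axis`
  int oa1 = (axis == 0) ? 1 : 0;
  int oa2 = (axis == 2) ? 1 : 2;
  for (int b = 0; b < dim[oa2]; ++b) {
    for (int a = 0; a < dim[oa1]; ++a) {
      R_xlen_t base = (R_xlen_t)a * stride[oa1] + (R_xlen_t)b * stride[oa2];
      for (int i = 0; i < nd; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int j = i + t;
          if (j < 0) j = 0;               // clamp-to-edge padding
          else if (j >= nd) j = nd - 1;
          acc += k[t + r] * in[base + (R_xlen_t)j * sd];
        }
        out[base + (R_xlen_t)i * sd] = acc;
      }
    }
  }
}

// Separable convolution of a 3D array (dim = c(nz, ny, nx)) with 1D kernels
// per axis; clamp-to-edge padding. An empty kernel (length 1, value 1) is a
// no-op for that axis.
// [[Rcpp::export]]
NumericVector sep_conv_3d(NumericVector img, NumericVector kz,
                          NumericVector ky, NumericVector kx) {
  IntegerVector dims = img.attr("dim");
  if (dims.size() != 3) stop("img must be a 3D array");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = img.size();
  std::vector<double> a(img.begin(), img.end()), b(n);
  if (kz.size() > 1) { conv_axis(a, b, nz, ny, nx, 0, kz); a.swap(b); }
  if (ky.size() > 1) { conv_axis(a, b, nz, ny, nx, 1, ky); a.swap(b); }
  if (kx.size() > 1) { conv_axis(a, b, nz, ny, nx, 2, kx); a.swap(b); }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
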