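#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdlib>

using namespace Rcpp;

// Arrays arrive as flat vectors in R's column-major order with
// dim = c(nz, ny, nx): linear index i = z + nz*(y + ny*x), 0-based here.

static std::vector<std::array<int, 3> > conn_offsets(int connectivity) {
    std::vector<std::array<int, 3> > off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                if (dz == 0 && dy == 0 && dx == 0) continue;
                int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                std::array<int, 3> a = {{dz, dy, dx}};
                off.push_back(a);
            }
    return off;
}

// Connected-component labeling of a 3D logical array (6/18/26-connectivity).
// Labels are assigned in raster-scan order of each component's first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (mask.size() != n) stop("mask length does not match dim");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");

    std::vector<std::array<int, 3> > off = conn_offsets(connectivity);
    IntegerVector labels(n, 0);
    std::vector<R_xlen_t> stack;
    int next_label = 0;

    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i] || labels[i] != 0) continue;
        ++next_label;
        labels[i] = next_label;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t cur = stack.back();
            stack.pop_back();
            int z = (int)(cur % nz);
            R_xlen_t rest = cur / nz;
            int y = (int)(rest % ny);
            int x = (int)(rest / ny);
            for (size_t k = 0; k < off.size(); ++k) {
                int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                    continue;
                R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
                if (mask[j] && labels[j] == 0) {
                    labels[j] = next_label;
                    stack.push_back(j);
                }
            }
        }
    }
    labels.attr("n_labels") = next_label;
    return labels;
}

// Median filter over the (2r+1)^3 neighborhood with edge replication.
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector x, IntegerVector dim, int radius) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (x.size() != n) stop("array length does not match dim");
    if (radius < 1) stop("radius must be >= 1");

    const int w = 2 * radius + 1;
    const int m = w * w * w;
    NumericVector out(n);
    std::vector<double> buf(m);

    for (int xx = 0; xx < nx; ++xx) {
        for (int yy = 0; yy < ny; ++yy) {
            for (int zz = 0; zz < nz; ++zz) {
                int k = 0;
                for (int dx = -radius; dx <= radius; ++dx) {
                    int cx = std::min(std::max(xx + dx, 0), nx - 1);
                    for (int dy = -radius; dy <= radius; ++dy) {
                        int cy = std::min(std::max(yy + dy, 0), ny - 1);
                        R_xlen_t base = (R_xlen_t)nz * (cy + (R_xlen_t)ny * cx);
                        for (int dz = -radius; dz <= radius; ++dz) {
                            int cz = std::min(std::max(zz + dz, 0), nz - 1);
                            buf[k++] = x[cz + base];
                        }
                    }
                }
                std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
                out[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] = buf[m / 2];
            }
        }
    }
    return out;
}

// 1-D convolution along one axis (0 = z, 1 = y, 2 = x) with replicated edges.
// kernel must have odd length; applied three times this gives a separable
// Gaussian blur.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector x, IntegerVector dim,
                            NumericVector kernel, int axis) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (x.size() != n) stop("array length does not match dim");
    const int klen = kernel.size();
    if (klen % 2 == 0) stop("kernel length must be odd");
    const int kr = klen / 2;

    NumericVector out(n);
    int len, s1, s2, stride;
    // stride along the filtered axis; s1/s2 iterate the other two axes
    if (axis == 0) { len = nz; stride = 1; s1 = ny; s2 = nx; }
    else if (axis == 1) { len = ny; stride = nz; s1 = nz; s2 = nx; }
    else if (axis == 2) { len = nx; stride = nz * ny; s1 = nz; s2 = ny; }
    else stop("axis must be 0, 1 or 2");

    for (int b = 0; b < s2; ++b) {
        for (int a = 0; a < s1; ++a) {
            R_xlen_t base;
            if (axis == 0)      base = (R_xlen_t)nz * (a + (R_xlen_t)ny * b);
            else if (axis == 1) base = a + (R_xlen_t)nz * ny * b;
            else                base = a + (R_xlen_t)nz * b;
            for (int i = 0; i < len; ++i) {
                double acc = 0.0;
                for (int k = -kr; k <= kr; ++k) {
                    int j = std::min(std::max(i + k, 0), len - 1);
                    acc += kernel[k + kr] * x[base + (R_xlen_t)j * stride];
                }
                out[base + (R_xlen_t)i * stride] = acc;
            }
        }
    }
    return out;
}

// One 6-neighborhood binary erosion pass (voxels on the array border are
// eroded, i.e. the outside counts as background).
// [[Rcpp::export]]
LogicalVector cpp_erode6(LogicalVector mask, IntegerVector dim) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (mask.size() != n) stop("mask length does not match dim");
    LogicalVector out(n);
    for (int xx = 0; xx < nx; ++xx)
        for (int yy = 0; yy < ny; ++yy)
            for (int zz = 0; zz < nz; ++zz) {
                R_xlen_t i = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
                bool keep = mask[i];
                if (keep) {
                    if (zz == 0 || zz == nz - 1 || yy == 0 || yy == ny - 1 ||
                        xx == 0 || xx == nx - 1) {
                        keep = false;
                    } else {
                        keep = mask[i - 1] && mask[i + 1] &&
                               mask[i - nz] && mask[i + nz] &&
                               mask[i - (R_xlen_t)nz * ny] &&
                               mask[i + (R_xlen_t)nz * ny];
                    }
                }
                out[i] = keep;
            }
    return out;
}
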