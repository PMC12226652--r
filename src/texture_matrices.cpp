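#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// The 13 unique 3D direction vectors (one of each +/- pair of the 26
// neighbourhood), used by the GLCM and GLRLM builders.
static const int DIR13[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {1, 1, 0}, {-1, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {-1, 0, 1}, {0, 1, 1}, {0, -1, 1},
    {1, 1, 1}, {-1, 1, 1}, {1, -1, 1}, {-1, -1, 1}
};

inline int idx3(int i, int j, int k, int d1, int d2) {
    return i + d1 * (j + d2 * k);
}

// Gray-level co-occurrence counts. `levels` is a column-major 3D integer
// array with 0 marking voxels outside the ROI. Returns an Ng x Ng x 13
// array of symmetric pair counts at Chebyshev offset `dist` * direction.
// [[Rcpp::export]]
NumericVector cppGlcmCounts(IntegerVector levels, IntegerVector dim, int ng, int dist) {
    int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    NumericVector out(static_cast<R_xlen_t>(ng) * ng * 13);
    for (int k = 0; k < d3; ++k)
        for (int j = 0; j < d2; ++j)
            for (int i = 0; i < d1; ++i) {
                int li = levels[idx3(i, j, k, d1, d2)];
                if (li <= 0) continue;
                for (int a = 0; a < 13; ++a) {
                    int ii = i + DIR13[a][0] * dist;
                    int jj = j + DIR13[a][1] * dist;
                    int kk = k + DIR13[a][2] * dist;
                    if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
                        continue;
                    int lj = levels[idx3(ii, jj, kk, d1, d2)];
                    if (lj <= 0) continue;
                    out[(li - 1) + static_cast<R_xlen_t>(ng) * ((lj - 1) + static_cast<R_xlen_t>(ng) * a)] += 1.0;
                    out[(lj - 1) + static_cast<R_xlen_t>(ng) * ((li - 1) + static_cast<R_xlen_t>(ng) * a)] += 1.0;
                }
            }
    out.attr("dim") = IntegerVector::create(ng, ng, 13);
    return out;
}

// Gray-level run-length counts: maximal runs of equal level along each of the
// 13 directions. Returns Ng x Lmax x 13 where Lmax = max(dim).
// [[Rcpp::export]]
NumericVector cppGlrlmCounts(IntegerVector levels, IntegerVector dim, int ng) {
    int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    int lmax = std::max(d1, std::max(d2, d3));
    NumericVector out(static_cast<R_xlen_t>(ng) * lmax * 13);
    for (int a = 0; a < 13; ++a) {
        int dx = DIR13[a][0], dy = DIR13[a][1], dz = DIR13[a][2];
        for (int k = 0; k < d3; ++k)
            for (int j = 0; j < d2; ++j)
                for (int i = 0; i < d1; ++i) {
                    int li = levels[idx3(i, j, k, d1, d2)];
                    if (li <= 0) continue;
                    // run starts here iff the predecessor is absent or differs
                    int pi = i - dx, pj = j - dy, pk = k - dz;
                    bool start = pi < 0 || pi >= d1 || pj < 0 || pj >= d2 || pk < 0 || pk >= d3;
                    if (!start) {
                        int lp = levels[idx3(pi, pj, pk, d1, d2)];
                        start = (lp != li);
                    }
                    if (!start) continue;
                    int len = 1;
                    int ci = i + dx, cj = j + dy, ck = k + dz;
                    while (ci >= 0 && ci < d1 && cj >= 0 && cj < d2 && ck >= 0 && ck < d3 &&
                           levels[idx3(ci, cj, ck, d1, d2)] == li) {
                        ++len;
                        ci += dx; cj += dy; ck += dz;
                    }
                    out[(li - 1) + static_cast<R_xlen_t>(ng) * ((len - 1) + static_cast<R_xlen_t>(lmax) * a)] += 1.0;
                }
    }
    out.attr("dim") = IntegerVector::create(ng, lmax, 13);
    return out;
}

// Gray-level size-zone decomposition: 26-connected components of equal level.
// Returns a two-column matrix (level, zone size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cppGlszmZones(IntegerVector levels, IntegerVector dim) {
    int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    R_xlen_t n = static_cast<R_xlen_t>(d1) * d2 * d3;
    std::vector<char> seen(n, 0);
    std::vector<int> zl, zs;
    std::vector<int> stack;
    for (R_xlen_t s = 0; s < n; ++s) {
        int lv = levels[s];
        if (lv <= 0 || seen[s]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(static_cast<int>(s));
        seen[s] = 1;
        while (!stack.empty()) {
            int cur = stack.back();
            stack.pop_back();
            ++size;
            int i = cur % d1, rem = cur / d1;
            int j = rem % d2, k = rem / d2;
            for (int dk = -1; dk <= 1; ++dk)
                for (int dj = -1; dj <= 1; ++dj)
                    for (int di = -1; di <= 1; ++di) {
                        if (di == 0 && dj == 0 && dk == 0) continue;
                        int ii = i + di, jj = j + dj, kk = k + dk;
                        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
                            continue;
                        int q = idx3(ii, jj, kk, d1, d2);
                        if (!seen[q] && levels[q] == lv) {
                            seen[q] = 1;
                            stack.push_back(q);
                        }
                    }
        }
        zl.push_back(lv);
        zs.push_back(size);
    }
    IntegerMatrix out(zl.size(), 2);
    for (size_t r = 0; r < zl.size(); ++r) {
        out(r, 0) = zl[r];
        out(r, 1) = zs[r];
    }
    return out;
}

// Gray-level dependence counts: for every ROI voxel, the number of in-ROI
// neighbours within Chebyshev distance `dist` whose level differs by at most
// `alpha`. Returns Ng x maxDep matrix; column c holds dependence c-1
// (i.e. dependence size j = c).
// [[Rcpp::export]]
NumericMatrix cppGldmCounts(IntegerVector levels, IntegerVector dim, int ng, int alpha, int dist) {
    int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    int w = 2 * dist + 1;
    int maxDep = w * w * w; // dependence = neighbour count + 1 <= 27 for dist 1
    NumericMatrix out(ng, maxDep);
    for (int k = 0; k < d3; ++k)
        for (int j = 0; j < d2; ++j)
            for (int i = 0; i < d1; ++i) {
                int li = levels[idx3(i, j, k, d1, d2)];
                if (li <= 0) continue;
                int dep = 0;
                for (int dk = -dist; dk <= dist; ++dk)
                    for (int dj = -dist; dj <= dist; ++dj)
                        for (int di = -dist; di <= dist; ++di) {
                            if (di == 0 && dj == 0 && dk == 0) continue;
                            int ii = i + di, jj = j + dj, kk = k + dk;
                            if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
                                continue;
                            int lj = levels[idx3(ii, jj, kk, d1, d2)];
                            if (lj <= 0) continue;
                            if (std::abs(lj - li) <= alpha) ++dep;
                        }
                out(li - 1, dep) += 1.0; // column dep+1 <-> dependence size dep+1
            }
    return out;
}

// Neighbourhood gray-tone difference statistics. Returns Ng x 2 matrix with
// columns (n_i, s_i): voxel count per level (voxels having at least one valid
// neighbour) and summed absolute difference from the neighbourhood mean.
// [[Rcpp::export]]
NumericMatrix cppNgtdmStats(IntegerVector levels, IntegerVector dim, int ng, int dist) {
    int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    NumericMatrix out(ng, 2);
    for (int k = 0; k < d3; ++k)
        for (int j = 0; j < d2; ++j)
            for (int i = 0; i < d1; ++i) {
                int li = levels[idx3(i, j, k, d1, d2)];
                if (li <= 0) continue;
                double sum = 0.0;
                int cnt = 0;
                for (int dk = -dist; dk <= dist; ++dk)
                    for (int dj = -dist; dj <= dist; ++dj)
                        for (int di = -dist; di <= dist; ++di) {
                            if (di == 0 && dj == 0 && dk == 0) continue;
                            int ii = i + di, jj = j + dj, kk = k + dk;
                            if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
                                continue;
                            int lj = levels[idx3(ii, jj, kk, d1, d2)];
                            if (lj <= 0) continue;
                            sum += lj;
                            ++cnt;
                        }
                if (cnt > 0) {
                    out(li - 1, 0) += 1.0;
                    out(li - 1, 1) += std::fabs(li - sum / cnt);
                }
            }
    return out;
}

static void conv1d_axis(std::vector<double> &buf, const std::vector<double> &src,
                        int n, const NumericVector &k, bool wrap) {
    int kl = k.size();
    int half = (kl - 1) / 2;
    for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int t = 0; t < kl; ++t) {
            int p = i + t - half;
            if (wrap) {
                p %= n;
                if (p < 0) p += n;
            } else {
                if (p < 0) p = 0;
                if (p >= n) p = n - 1;
            }
            acc += src[p] * k[t];
        }
        buf[i] = acc;
    }
}

// Separable 3D convolution with odd-length kernels along x, y, z.
// wrap = TRUE uses circular boundaries (stationary random fields),
// wrap = FALSE clamps to the edge (image smoothing).
// [[Rcpp::export]]
NumericVector cppSepConv3d(NumericVector x, IntegerVector dim,
                           NumericVector kx, NumericVector ky, NumericVector kz,
                           bool wrap) {
    int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    R_xlen_t n = static_cast<R_xlen_t>(d1) * d2 * d3;
    NumericVector out(clone(x));
    std::vector<double> line, buf;
    if (kx.size() > 1) {
        line.resize(d1); buf.resize(d1);
        for (int k = 0; k < d3; ++k)
            for (int j = 0; j < d2; ++j) {
                R_xlen_t base = static_cast<R_xlen_t>(d1) * (j + static_cast<R_xlen_t>(d2) * k);
                for (int i = 0; i < d1; ++i) line[i] = out[base + i];
                conv1d_axis(buf, line, d1, kx, wrap);
                for (int i = 0; i < d1; ++i) out[base + i] = buf[i];
            }
    }
    if (ky.size() > 1) {
        line.resize(d2); buf.resize(d2);
        for (int k = 0; k < d3; ++k)
            for (int i = 0; i < d1; ++i) {
                for (int j = 0; j < d2; ++j)
                    line[j] = out[idx3(i, j, k, d1, d2)];
                conv1d_axis(buf, line, d2, ky, wrap);
                for (int j = 0; j < d2; ++j)
                    out[idx3(i, j, k, d1, d2)] = buf[j];
            }
    }
    if (kz.size() > 1) {
        line.resize(d3); buf.resize(d3);
        for (int j = 0; j < d2; ++j)
            for (int i = 0; i < d1; ++i) {
                for (int k = 0; k < d3; ++k)
                    line[k] = out[idx3(i, j, k, d1, d2)];
                conv1d_axis(buf, line, d3, kz, wrap);
                for (int k = 0; k < d3; ++k)
                    out[idx3(i, j, k, d1, d2)] = buf[k];
            }
    }
    out.attr("dim") = dim;
    (void)n;
    return out;
}

// Block-mean downsampling by integer factors; trailing partial blocks dropped.
// [[Rcpp::export]]
NumericVector cppBlockMean3d(NumericVector x, IntegerVector dim, IntegerVector f) {
    int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    int f1 = f[0], f2 = f[1], f3 = f[2];
    int n1 = d1 / f1, n2 = d2 / f2, n3 = d3 / f3;
    NumericVector out(static_cast<R_xlen_t>(n1) * n2 * n3);
    double inv = 1.0 / (static_cast<double>(f1) * f2 * f3);
    for (int k = 0; k < n3; ++k)
        for (int j = 0; j < n2; ++j)
            for (int i = 0; i < n1; ++i) {
                double acc = 0.0;
                for (int ck = k * f3; ck < (k + 1) * f3; ++ck)
                    for (int cj = j * f2; cj < (j + 1) * f2; ++cj)
                        for (int ci = i * f1; ci < (i + 1) * f1; ++ci)
                            acc += x[idx3(ci, cj, ck, d1, d2)];
                out[i + static_cast<R_xlen_t>(n1) * (j + static_cast<R_xlen_t>(n2) * k)] = acc * inv;
            }
    out.attr("dim") = IntegerVector::create(n1, n2, n3);
    return out;
}

// Trilinear interpolation of a 3D grid (voxel centre at origin + (i-1)*spacing)
// at arbitrary physical points, clamping to the grid edge.
// [[Rcpp::export]]
NumericVector cppTrilinear(NumericVector x, IntegerVector dim,
                           NumericVector origin, NumericVector spacing,
                           NumericMatrix pts) {
    int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    int np = pts.nrow();
    NumericVector out(np);
    for (int p = 0; p < np; ++p) {
        double u = (pts(p, 0) - origin[0]) / spacing[0];
        double v = (pts(p, 1) - origin[1]) / spacing[1];
        double w = (pts(p, 2) - origin[2]) / spacing[2];
        if (u < 0) u = 0; if (u > d1 - 1) u = d1 - 1;
        if (v < 0) v = 0; if (v > d2 - 1) v = d2 - 1;
        if (w < 0) w = 0; if (w > d3 - 1) w = d3 - 1;
        int i0 = static_cast<int>(std::floor(u)); if (i0 > d1 - 2) i0 = std::max(0, d1 - 2);
        int j0 = static_cast<int>(std::floor(v)); if (j0 > d2 - 2) j0 = std::max(0, d2 - 2);
        int k0 = static_cast<int>(std::floor(w)); if (k0 > d3 - 2) k0 = std::max(0, d3 - 2);
        double fu = u - i0, fv = v - j0, fw = w - k0;
        int i1 = std::min(i0 + 1, d1 - 1);
        int j1 = std::min(j0 + 1, d2 - 1);
        int k1 = std::min(k0 + 1, d3 - 1);
        double c000 = x[idx3(i0, j0, k0, d1, d2)], c100 = x[idx3(i1, j0, k0, d1, d2)];
        double c010 = x[idx3(i0, j1, k0, d1, d2)], c110 = x[idx3(i1, j1, k0, d1, d2)];
        double c001 = x[idx3(i0, j0, k1, d1, d2)], c101 = x[idx3(i1, j0, k1, d1, d2)];
        double c011 = x[idx3(i0, j1, k1, d1, d2)], c111 = x[idx3(i1, j1, k1, d1, d2)];
        double c00 = c000 * (1 - fu) + c100 * fu;
        double c10 = c010 * (1 - fu) + c110 * fu;
        double c01 = c001 * (1 - fu) + c101 * fu;
        double c11 = c011 * (1 - fu) + c111 * fu;
        double c0 = c00 * (1 - fv) + c10 * fv;
        double c1 = c01 * (1 - fv) + c11 * fv;
        out[p] = c0 * (1 - fw) + c1 * fw;
    }
    return out;
}

static void boxpass_circular(std::vector<double> &dst, const std::vector<double> &src,
                             int n, int w) {
    // circular moving average of odd width w
    int half = w / 2;
    double inv = 1.0 / w;
    double acc = 0.0;
    for (int t = -half; t <= half; ++t) {
        int p = t % n; if (p < 0) p += n;
        acc += src[p];
    }
    for (int i = 0; i < n; ++i) {
        dst[i] = acc * inv;
        int add = (i + half + 1) % n;
        int rem = (i - half) % n; if (rem < 0) rem += n;
        acc += src[add] - src[rem];
    }
}

// Cascaded circular box filters along each axis (three boxes per axis
// approximate a Gaussian); box widths are odd, width 1 = identity.
// [[Rcpp::export]]
NumericVector cppBoxBlur3d(NumericVector x, IntegerVector dim,
                           IntegerVector bx, IntegerVector by, IntegerVector bz) {
    int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    NumericVector out(clone(x));
    std::vector<double> line, buf;
    // axis 1
    line.resize(d1); buf.resize(d1);
    for (int k = 0; k < d3; ++k)
        for (int j = 0; j < d2; ++j) {
            R_xlen_t base = static_cast<R_xlen_t>(d1) * (j + static_cast<R_xlen_t>(d2) * k);
            for (int i = 0; i < d1; ++i) line[i] = out[base + i];
            for (int b = 0; b < bx.size(); ++b)
                if (bx[b] > 1) { boxpass_circular(buf, line, d1, bx[b]); line.swap(buf); }
            for (int i = 0; i < d1; ++i) out[base + i] = line[i];
        }
    // axis 2
    line.resize(d2); buf.resize(d2);
    for (int k = 0; k < d3; ++k)
        for (int i = 0; i < d1; ++i) {
            for (int j = 0; j < d2; ++j) line[j] = out[idx3(i, j, k, d1, d2)];
            for (int b = 0; b < by.size(); ++b)
                if (by[b] > 1) { boxpass_circular(buf, line, d2, by[b]); line.swap(buf); }
            for (int j = 0; j < d2; ++j) out[idx3(i, j, k, d1, d2)] = line[j];
        }
    // axis 3
    line.resize(d3); buf.resize(d3);
    for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
            for (int k = 0; k < d3; ++k) line[k] = out[idx3(i, j, k, d1, d2)];
            for (int b = 0; b < bz.size(); ++b)
                if (bz[b] > 1) { boxpass_circular(buf, line, d3, bz[b]); line.swap(buf); }
            for (int k = 0; k < d3; ++k) out[idx3(i, j, k, d1, d2)] = line[k];
        }
    out.attr("dim") = dim;
    return out;
}
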