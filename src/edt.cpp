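#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared Euclidean distance transform (lower envelope of parabolas),
// with physical sample step. f holds squared distances on input.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double step) {
    const double INF = std::numeric_limits<double>::infinity();
    // build the lower envelope from finite parabolas only (infinite ones
    // can never contribute and would poison the intersection arithmetic)
    int k = -1;
    for (int q = 0; q < n; ++q) {
        if (!(f[q] < INF)) continue;
        if (k < 0) {
            k = 0;
            v[0] = q;
            z[0] = -INF;
            z[1] = INF;
            continue;
        }
        double qq = q * step;
        double s;
        for (;;) {
            double vv = v[k] * step;
            s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * (qq - vv));
            if (s <= z[k] && k > 0) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    if (k < 0) {  // no finite input on this line
        for (int q = 0; q < n; ++q) d[q] = INF;
        return;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double qq = q * step;
        while (z[k + 1] < qq) ++k;
        double vv = v[k] * step;
        d[q] = (qq - vv) * (qq - vv) + f[v[k]];
    }
}

// Exact anisotropic Euclidean distance (mm) from every voxel centre to the
// nearest seed voxel centre. Separable three-pass algorithm; O(N) per axis.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector seed, IntegerVector dims,
                    NumericVector spacing) {
    const double INF = std::numeric_limits<double>::infinity();
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (seed.size() != n)
        stop("seed length does not match dims");
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = (seed[i] == TRUE) ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (fastest-varying axis)
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
            bool any = false;
            for (int i = 0; i < nx; ++i) {
                f[i] = out[base + i];
                if (f[i] < INF) any = true;
            }
            if (!any) continue;
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
        }
    // pass along y
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + i;
            for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
        }
    // pass along z
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)j * nx + i;
            for (int k = 0; k < nz; ++k) f[k] = out[base + k * nxy];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int k = 0; k < nz; ++k) out[base + k * nxy] = d[k];
        }

    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = std::sqrt(out[i]);
    return out;
}
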