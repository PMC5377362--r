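#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact squared Euclidean distance transform of a 3D voxel set, computed by
// the separable lower-envelope algorithm (Felzenszwalb & Huttenlocher 2012).
// Each axis pass solves d(x) = min_y ( s^2 (x - y)^2 + f(y) ) exactly, so the
// composition over the three axes gives the exact squared distance to the
// nearest "on" voxel, with per-axis spacing s in physical units.

static const double INF = std::numeric_limits<double>::infinity();

// One 1D pass over f (length n, grid step s, s2 = s^2). Overwrites f with the
// transform. Parabolas with infinite height (no source yet) are skipped.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s2) {
    int k = -1; // index of rightmost parabola in the envelope
    for (int q = 0; q < n; ++q) {
        if (f[q] == INF) continue;
        if (k < 0) {
            k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
            continue;
        }
        for (;;) {
            int p = v[k];
            double s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
                       (2.0 * s2 * (q - p));
            if (s <= z[k]) {
                --k;
                if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; break; }
            } else {
                ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
                break;
            }
        }
    }
    if (k < 0) {
        for (int q = 0; q < n; ++q) d[q] = INF;
    } else {
        int j = 0;
        for (int q = 0; q < n; ++q) {
            while (z[j + 1] < q) ++j;
            int p = v[j];
            d[q] = s2 * (q - p) * (q - p) + f[p];
        }
    }
    for (int q = 0; q < n; ++q) f[q] = d[q];
}

// [[Rcpp::export(name = ".edt_sq")]]
Rcpp::NumericVector edt_sq(Rcpp::LogicalVector on, Rcpp::IntegerVector dim,
                           Rcpp::NumericVector spacing) {
    const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
    const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    Rcpp::NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = on[i] ? 0.0 : INF;

    int nmax = std::max(n1, std::max(n2, n3));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // axis 1 (fastest-varying index)
    double s2 = spacing[0] * spacing[0];
    for (int k3 = 0; k3 < n3; ++k3)
        for (int k2 = 0; k2 < n2; ++k2) {
            R_xlen_t base = (R_xlen_t)k3 * n1 * n2 + (R_xlen_t)k2 * n1;
            for (int i = 0; i < n1; ++i) f[i] = out[base + i];
            dt1d(f, d, v, z, n1, s2);
            for (int i = 0; i < n1; ++i) out[base + i] = f[i];
        }

    // axis 2
    s2 = spacing[1] * spacing[1];
    for (int k3 = 0; k3 < n3; ++k3)
        for (int k1 = 0; k1 < n1; ++k1) {
            R_xlen_t base = (R_xlen_t)k3 * n1 * n2 + k1;
            for (int i = 0; i < n2; ++i) f[i] = out[base + (R_xlen_t)i * n1];
            dt1d(f, d, v, z, n2, s2);
            for (int i = 0; i < n2; ++i) out[base + (R_xlen_t)i * n1] = f[i];
        }

    // axis 3
    s2 = spacing[2] * spacing[2];
    R_xlen_t plane = (R_xlen_t)n1 * n2;
    for (int k2 = 0; k2 < n2; ++k2)
        for (int k1 = 0; k1 < n1; ++k1) {
            R_xlen_t base = (R_xlen_t)k2 * n1 + k1;
            for (int i = 0; i < n3; ++i) f[i] = out[base + (R_xlen_t)i * plane];
            dt1d(f, d, v, z, n3, s2);
            for (int i = 0; i < n3; ++i) out[base + (R_xlen_t)i * plane] = f[i];
        }

    return out;
}
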