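#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Midranks of one series (ties averaged), written into out.
static void midranks(const double* x, int n, std::vector<int>& ord,
                     double* out) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [x](int a, int b) { return x[a] < x[b]; });
    int i = 0;
    while (i < n) {
        int j = i;
        while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
        double r = 0.5 * (i + j) + 1.0;  // average of 1-based ranks i+1..j+1
        for (int k = i; k <= j; ++k) out[ord[k]] = r;
        i = j + 1;
    }
}

// Kendall's W over cubic neighborhoods.
// Y:    Vin x n matrix, one row per in-mask voxel's time series.
// nbr:  Vin x K matrix of 1-based row indices into Y (0 = member missing /
//       out of mask); column 1 is the voxel itself.
// Returns W (Vin), Keff (in-mask member counts) and the count of
// degenerate (zero-denominator) voxels among those meeting minNeighbors.
// [[Rcpp::export(name = ".cppRehoMap")]]
List cppRehoMap(const NumericMatrix& Y, const IntegerMatrix& nbr,
                int minNeighbors, bool tieCorrection) {
    const int V = Y.nrow(), n = Y.ncol(), K = nbr.ncol();
    NumericMatrix R(V, n);
    NumericVector tie(V);
    std::vector<char> isConst(V);
    std::vector<int> ord(n);
    std::vector<double> buf(n), rk(n);
    for (int v = 0; v < V; ++v) {
        for (int t = 0; t < n; ++t) buf[t] = Y(v, t);
        midranks(buf.data(), n, ord, rk.data());
        isConst[v] = (buf[ord[0]] == buf[ord[n - 1]]);
        for (int t = 0; t < n; ++t) R(v, t) = rk[t];
        if (tieCorrection) {
            // sum of t^3 - t over tie groups of this series
            double tt = 0.0;
            int i = 0;
            while (i < n) {
                int j = i;
                while (j + 1 < n && buf[ord[j + 1]] == buf[ord[i]]) ++j;
                double g = j - i + 1;
                tt += g * g * g - g;
                i = j + 1;
            }
            tie[v] = tt;
        }
    }
    NumericVector W(V), Keff(V);
    int nDegenerate = 0;
    std::vector<double> acc(n);
    const double n3n = (double)n * n * n - n;
    for (int v = 0; v < V; ++v) {
        std::fill(acc.begin(), acc.end(), 0.0);
        int kEff = 0, kConst = 0;
        double tsum = 0.0;
        for (int m = 0; m < K; ++m) {
            int idx = nbr(v, m);
            if (idx <= 0) continue;
            ++kEff;
            const int row = idx - 1;
            if (isConst[row]) ++kConst;
            for (int t = 0; t < n; ++t) acc[t] += R(row, t);
            if (tieCorrection) tsum += tie[row];
        }
        Keff[v] = kEff;
        if (kEff < minNeighbors) { W[v] = 0.0; continue; }
        if (kConst == kEff) {   // all-constant neighborhood: no ranking
            W[v] = 0.0;
            ++nDegenerate;
            continue;
        }
        // midranks preserve per-series totals, so Rbar = kEff (n+1)/2
        const double rbar = kEff * (n + 1) * 0.5;
        double S = 0.0;
        for (int t = 0; t < n; ++t) {
            const double d = acc[t] - rbar;
            S += d * d;
        }
        double denom = (double)kEff * kEff * n3n;
        if (tieCorrection) denom -= kEff * tsum;
        if (denom <= 0.0) {
            W[v] = 0.0;
            ++nDegenerate;
            continue;
        }
        double w = 12.0 * S / denom;
        W[v] = std::min(1.0, std::max(0.0, w));
    }
    return List::create(_["W"] = W, _["Keff"] = Keff,
                        _["nDegenerate"] = nDegenerate);
}

// Separable 1D convolution along one axis of a 3D/4D array flattened to
// (d1, d2, d3, d4) column-major; zero padding outside the grid.
// [[Rcpp::export(name = ".cppConvAxis")]]
NumericVector cppConvAxis(const NumericVector& arr,
                          const IntegerVector& dims, int axis,
                          const NumericVector& kernel) {
    const int nd = dims.size();
    int d[4] = {1, 1, 1, 1};
    for (int i = 0; i < nd; ++i) d[i] = dims[i];
    const int r = (kernel.size() - 1) / 2;
    NumericVector out(arr.size());
    const R_xlen_t s1 = 1, s2 = d[0], s3 = (R_xlen_t)d[0] * d[1],
        s4 = (R_xlen_t)d[0] * d[1] * d[2];
    const R_xlen_t stride[4] = {s1, s2, s3, s4};
    const int ax = axis - 1;
    const int nAx = d[ax];
    const R_xlen_t sAx = stride[ax];
    // iterate over all lines along the chosen axis
    int od[3]; // the other three dims
    R_xlen_t os[3];
    int q = 0;
    for (int i = 0; i < 4; ++i)
        if (i != ax) { od[q] = d[i]; os[q] = stride[i]; ++q; }
    std::vector<double> line(nAx);
    for (int a = 0; a < od[0]; ++a)
        for (int b = 0; b < od[1]; ++b)
            for (int c = 0; c < od[2]; ++c) {
                const R_xlen_t base = a * os[0] + b * os[1] + c * os[2];
                for (int i = 0; i < nAx; ++i)
                    line[i] = arr[base + i * sAx];
                for (int i = 0; i < nAx; ++i) {
                    double acc = 0.0;
                    const int lo = std::max(-r, -i),
                        hi = std::min(r, nAx - 1 - i);
                    for (int k = lo; k <= hi; ++k)
                        acc += kernel[k + r] * line[i + k];
                    out[base + i * sAx] = acc;
                }
            }
    return out;
}
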