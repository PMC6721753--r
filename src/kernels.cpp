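#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---- particle rendering -------------------------------------------------
//
// Each particle is an anti-aliased disc (4x4 subpixel coverage) convolved
// with an isotropic Gaussian of the particle's defocus sigma, normalised so
// that the post-blur peak equals the particle's marker intensity, then added
// into the frame.  Peak normalisation is the intensity calibration: a
// "positive" level stays a "positive" level whether the object is in focus
// or blurred, while the footprint spreads with sigma.

static void blur_patch(std::vector<double> &patch, int w, double sigma) {
    int h = (int)std::ceil(3.5 * sigma);
    if (h < 1) return;
    std::vector<double> kern(2 * h + 1);
    double s2 = 2.0 * sigma * sigma, ksum = 0.0;
    for (int k = -h; k <= h; ++k) {
        kern[k + h] = std::exp(-(double)(k * k) / s2);
        ksum += kern[k + h];
    }
    for (size_t k = 0; k < kern.size(); ++k) kern[k] /= ksum;
    std::vector<double> tmp(patch.size());
    // rows
    for (int j = 0; j < w; ++j)
        for (int i = 0; i < w; ++i) {
            double acc = 0.0;
            for (int k = -h; k <= h; ++k) {
                int ii = i + k;
                if (ii >= 0 && ii < w) acc += kern[k + h] * patch[ii + (size_t)j * w];
            }
            tmp[i + (size_t)j * w] = acc;
        }
    // cols
    for (int j = 0; j < w; ++j)
        for (int i = 0; i < w; ++i) {
            double acc = 0.0;
            for (int k = -h; k <= h; ++k) {
                int jj = j + k;
                if (jj >= 0 && jj < w) acc += kern[k + h] * tmp[i + (size_t)jj * w];
            }
            patch[i + (size_t)j * w] = acc;
        }
}

// [[Rcpp::export]]
void cpp_add_particles(NumericMatrix frame, NumericVector row, NumericVector col,
                       NumericVector radius_px, NumericVector sigma_px,
                       NumericVector amplitude) {
    const int nr = frame.nrow(), nc = frame.ncol();
    const int ss = 4;                       // subpixel grid per axis
    const double ssf = 1.0 / (ss * ss);
    for (int p = 0; p < row.size(); ++p) {
        double amp = amplitude[p];
        if (!(amp > 0)) continue;
        double r0 = row[p], c0 = col[p];
        double rad = radius_px[p], sig = sigma_px[p];
        if (sig < 0) sig = 0;
        int ri = (int)std::lround(r0), ci = (int)std::lround(c0);
        int pad = (int)std::ceil(rad + 4.0 * sig + 2.0);
        int w = 2 * pad + 1;
        std::vector<double> patch((size_t)w * w, 0.0);
        double rad2 = rad * rad;
        for (int j = 0; j < w; ++j) {
            double x = ci - pad + j;
            for (int i = 0; i < w; ++i) {
                double y = ri - pad + i;
                int cnt = 0;
                for (int a = 0; a < ss; ++a) {
                    double dy = y + (a + 0.5) / ss - 0.5 - r0;
                    for (int b = 0; b < ss; ++b) {
                        double dx = x + (b + 0.5) / ss - 0.5 - c0;
                        if (dy * dy + dx * dx <= rad2) ++cnt;
                    }
                }
                if (cnt) patch[i + (size_t)j * w] = cnt * ssf;
            }
        }
        if (sig > 0.05) blur_patch(patch, w, sig);
        double maxv = 0.0;
        for (size_t k = 0; k < patch.size(); ++k)
            if (patch[k] > maxv) maxv = patch[k];
        if (maxv <= 0) {                    // sub-resolution particle: point deposit
            if (ri >= 0 && ri < nr && ci >= 0 && ci < nc) frame(ri, ci) += amp;
            continue;
        }
        double scale = amp / maxv;
        for (int j = 0; j < w; ++j) {
            int cj = ci - pad + j;
            if (cj < 0 || cj >= nc) continue;
            for (int i = 0; i < w; ++i) {
                int rj = ri - pad + i;
                if (rj < 0 || rj >= nr) continue;
                double v = patch[i + (size_t)j * w];
                if (v > 0) frame(rj, cj) += scale * v;
            }
        }
    }
}

// ---- connected components ----------------------------------------------
//
// Two-pass union-find labelling of a binary mask, 4- or 8-connectivity.
// Labels are consecutive integers 1..L in raster-scan order of first pixel.

static int uf_find(std::vector<int> &par, int x) {
    while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
    return x;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
    const int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> par;
    par.push_back(0);
    int next = 0;
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (!mask(i, j)) continue;
            int neigh[4]; int nn = 0;
            if (i > 0 && mask(i - 1, j)) neigh[nn++] = lab(i - 1, j);
            if (j > 0 && mask(i, j - 1)) neigh[nn++] = lab(i, j - 1);
            if (connectivity == 8) {
                if (i > 0 && j > 0 && mask(i - 1, j - 1)) neigh[nn++] = lab(i - 1, j - 1);
                if (i < nr - 1 && j > 0 && mask(i + 1, j - 1)) neigh[nn++] = lab(i + 1, j - 1);
            }
            if (nn == 0) {
                ++next;
                par.push_back(next);
                lab(i, j) = next;
            } else {
                int m = uf_find(par, neigh[0]);
                for (int k = 1; k < nn; ++k) {
                    int r = uf_find(par, neigh[k]);
                    if (r < m) { par[m] = r; m = r; }
                    else par[r] = m;
                }
                lab(i, j) = m;
            }
        }
    }
    // consecutive relabel in raster order (column-major scan as built)
    std::vector<int> newlab(next + 1, 0);
    int L = 0;
    for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
            int l = lab(i, j);
            if (!l) continue;
            int r = uf_find(par, l);
            if (!newlab[r]) newlab[r] = ++L;
            lab(i, j) = newlab[r];
        }
    return lab;
}

// ---- per-label statistics ----------------------------------------------
//
// vals: one column per channel, nrow(vals) == nr*nc in column-major frame
// order.  Returns per-label pixel count, per-channel sum / sum of squares /
// min / max, coordinate moment sums (0-based row/col), and the edge-count
// perimeter (number of 4-neighbour pixel edges facing background, another
// label, or the frame border).

// [[Rcpp::export]]
List cpp_region_stats(IntegerMatrix lab, NumericMatrix vals) {
    const int nr = lab.nrow(), nc = lab.ncol(), nch = vals.ncol();
    int L = 0;
    for (int k = 0; k < nr * nc; ++k) if (lab[k] > L) L = lab[k];
    IntegerVector area(L), perim(L);
    NumericMatrix sum(L, nch), sumsq(L, nch), minv(L, nch), maxv(L, nch);
    std::fill(minv.begin(), minv.end(), R_PosInf);
    std::fill(maxv.begin(), maxv.end(), R_NegInf);
    NumericVector sr(L), sc(L), srr(L), scc(L), src(L);
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            int l = lab(i, j);
            if (!l) continue;
            int li = l - 1;
            ++area[li];
            sr[li] += i; sc[li] += j;
            srr[li] += (double)i * i; scc[li] += (double)j * j; src[li] += (double)i * j;
            if (i == 0 || lab(i - 1, j) != l) ++perim[li];
            if (i == nr - 1 || lab(i + 1, j) != l) ++perim[li];
            if (j == 0 || lab(i, j - 1) != l) ++perim[li];
            if (j == nc - 1 || lab(i, j + 1) != l) ++perim[li];
            size_t px = (size_t)j * nr + i;
            for (int ch = 0; ch < nch; ++ch) {
                double v = vals(px, ch);
                sum(li, ch) += v;
                sumsq(li, ch) += v * v;
                if (v < minv(li, ch)) minv(li, ch) = v;
                if (v > maxv(li, ch)) maxv(li, ch) = v;
            }
        }
    }
    return List::create(_["area"] = area, _["perimeter"] = perim,
                        _["sum"] = sum, _["sumsq"] = sumsq,
                        _["min"] = minv, _["max"] = maxv,
                        _["sum_r"] = sr, _["sum_c"] = sc,
                        _["sum_rr"] = srr, _["sum_cc"] = scc, _["sum_rc"] = src);
}

// ---- fast Gaussian noise ------------------------------------------------
//
// splitmix64 + Box-Muller.  Seeded explicitly per frame from the R random
// stream so renders stay reproducible under set.seed() without paying the
// per-value cost of R's rnorm on multi-gigapixel cohorts.

// [[Rcpp::export]]
NumericVector cpp_gaussian_noise(int n, double sd, double seed1, double seed2) {
    NumericVector out(n);
    uint64_t s = ((uint64_t)(uint32_t)seed1 << 32) ^ (uint64_t)(uint32_t)seed2;
    s ^= 0x9E3779B97F4A7C15ULL;
    auto next = [&s]() {
        s += 0x9E3779B97F4A7C15ULL;
        uint64_t z = s;
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    };
    const double TWO_PI = 6.283185307179586;
    int i = 0;
    while (i < n) {
        double u1 = (next() >> 11) * (1.0 / 9007199254740992.0);
        double u2 = (next() >> 11) * (1.0 / 9007199254740992.0);
        if (u1 <= 0) u1 = 1e-300;
        double r = std::sqrt(-2.0 * std::log(u1));
        out[i++] = sd * r * std::cos(TWO_PI * u2);
        if (i < n) out[i++] = sd * r * std::sin(TWO_PI * u2);
    }
    return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
    const int nr = img.nrow(), nc = img.ncol();
    std::vector<double> patch(img.begin(), img.end());
    // reuse separable blur on the full image (column-major: treat as w x w
    // is not possible; inline a rectangular version)
    int h = (int)std::ceil(3.5 * sigma);
    if (h < 1) return clone(img);
    std::vector<double> kern(2 * h + 1);
    double s2 = 2.0 * sigma * sigma, ksum = 0.0;
    for (int k = -h; k <= h; ++k) { kern[k + h] = std::exp(-(double)(k * k) / s2); ksum += kern[k + h]; }
    for (size_t k = 0; k < kern.size(); ++k) kern[k] /= ksum;
    std::vector<double> tmp((size_t)nr * nc);
    for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
            double acc = 0.0, wsum = 0.0;
            for (int k = -h; k <= h; ++k) {
                int ii = i + k;
                if (ii >= 0 && ii < nr) { acc += kern[k + h] * patch[ii + (size_t)j * nr]; wsum += kern[k + h]; }
            }
            tmp[i + (size_t)j * nr] = acc / wsum;
        }
    NumericMatrix out(nr, nc);
    for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
            double acc = 0.0, wsum = 0.0;
            for (int k = -h; k <= h; ++k) {
                int jj = j + k;
                if (jj >= 0 && jj < nc) { acc += kern[k + h] * tmp[i + (size_t)jj * nr]; wsum += kern[k + h]; }
            }
            out(i, j) = acc / wsum;
        }
    return out;
}
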