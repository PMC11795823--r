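#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Bilinear lookup with edge clamping; r, c are 0-based fractional indices.
static inline double bilin(const arma::mat& A, double r, double c) {
    const int H = A.n_rows, W = A.n_cols;
    if (r < 0.0) r = 0.0;
    if (r > H - 1.0) r = H - 1.0;
    if (c < 0.0) c = 0.0;
    if (c > W - 1.0) c = W - 1.0;
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    int r1 = r0 + 1 < H ? r0 + 1 : H - 1;
    int c1 = c0 + 1 < W ? c0 + 1 : W - 1;
    double fr = r - r0, fc = c - c0;
    return A(r0, c0) * (1 - fr) * (1 - fc) + A(r1, c0) * fr * (1 - fc) +
           A(r0, c1) * (1 - fr) * fc + A(r1, c1) * fr * fc;
}

// out(x) = img(x + d(x)), pull warping on the same grid.
// [[Rcpp::export]]
arma::mat warp_bilinear_cpp(const arma::mat& img, const arma::mat& drow,
                            const arma::mat& dcol) {
    const int H = img.n_rows, W = img.n_cols;
    arma::mat out(H, W);
    for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r)
            out(r, c) = bilin(img, r + drow(r, c), c + dcol(r, c));
    return out;
}

// Sample img at arbitrary 0-based (row, col) positions.
// [[Rcpp::export]]
arma::vec sample_bilinear_cpp(const arma::mat& img, const arma::vec& rows,
                              const arma::vec& cols) {
    const int n = rows.n_elem;
    arma::vec out(n);
    for (int i = 0; i < n; ++i) out(i) = bilin(img, rows(i), cols(i));
    return out;
}

// Separable Gaussian blur, kernel truncated at 3 sigma and renormalized at
// the image edges (equivalent to normalized convolution with replicate-free
// borders).
// [[Rcpp::export]]
arma::mat gaussian_blur_cpp(const arma::mat& img, double sigma) {
    if (sigma <= 0.0) return img;
    const int H = img.n_rows, W = img.n_cols;
    const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
    arma::vec k(2 * rad + 1);
    for (int i = -rad; i <= rad; ++i)
        k(i + rad) = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    k /= arma::accu(k);

    arma::mat tmp(H, W);
    for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
            double s = 0.0, wsum = 0.0;
            const int lo = std::max(-rad, -r), hi = std::min(rad, H - 1 - r);
            for (int i = lo; i <= hi; ++i) {
                s += k(i + rad) * img(r + i, c);
                wsum += k(i + rad);
            }
            tmp(r, c) = s / wsum;
        }
    }
    arma::mat out(H, W);
    for (int c = 0; c < W; ++c) {
        const int lo0 = std::max(-rad, -c), hi0 = std::min(rad, W - 1 - c);
        for (int r = 0; r < H; ++r) {
            double s = 0.0, wsum = 0.0;
            for (int i = lo0; i <= hi0; ++i) {
                s += k(i + rad) * tmp(r, c + i);
                wsum += k(i + rad);
            }
            out(r, c) = s / wsum;
        }
    }
    return out;
}

// Bilinear resize with pixel-center alignment.
// [[Rcpp::export]]
arma::mat resize_bilinear_cpp(const arma::mat& img, int H2, int W2) {
    const int H = img.n_rows, W = img.n_cols;
    arma::mat out(H2, W2);
    const double sr = (double)H / H2, sc = (double)W / W2;
    for (int c = 0; c < W2; ++c) {
        const double cc = (c + 0.5) * sc - 0.5;
        for (int r = 0; r < H2; ++r)
            out(r, c) = bilin(img, (r + 0.5) * sr - 0.5, cc);
    }
    return out;
}

// One pyramid level of Thirion demons. The accumulated field (drow, dcol)
// maps fixed-grid coordinates into the moving image: warped(x) = m(x + d(x)).
// Per iteration the classic force
//   u(x) = -(m(x+d) - f(x)) * grad f(x) / (|grad f(x)|^2 + (m(x+d)-f(x))^2)
// is added and the field Gaussian-smoothed. Stops when the relative SSD
// improvement over `window` iterations drops below `tol`, keeping the
// best-SSD field seen.
// [[Rcpp::export]]
List demons_level_cpp(const arma::mat& fixed, const arma::mat& moving,
                      arma::mat drow, arma::mat dcol, double sigma,
                      int max_iter, double tol, int window) {
    const int H = fixed.n_rows, W = fixed.n_cols;

    // fixed-image gradient, central differences with edge replication
    arma::mat gr(H, W), gc(H, W);
    for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
            const int rp = r + 1 < H ? r + 1 : r, rm = r > 0 ? r - 1 : r;
            const int cp = c + 1 < W ? c + 1 : c, cm = c > 0 ? c - 1 : c;
            gr(r, c) = (fixed(rp, c) - fixed(rm, c)) / (double)(rp - rm > 0 ? rp - rm : 1);
            gc(r, c) = (fixed(r, cp) - fixed(r, cm)) / (double)(cp - cm > 0 ? cp - cm : 1);
        }
    const arma::mat g2 = gr % gr + gc % gc;

    std::vector<double> ssd_hist;
    double best_ssd = arma::datum::inf;
    arma::mat best_dr = drow, best_dc = dcol;

    for (int iter = 0; iter < max_iter; ++iter) {
        arma::mat mw = warp_bilinear_cpp(moving, drow, dcol);
        arma::mat diff = mw - fixed;
        const double ssd = arma::accu(diff % diff);
        ssd_hist.push_back(ssd);
        if (ssd < best_ssd) {
            best_ssd = ssd;
            best_dr = drow;
            best_dc = dcol;
        }
        if ((int)ssd_hist.size() > window) {
            const double ref = std::max(ssd_hist[0], 1e-12);
            const double prev = ssd_hist[ssd_hist.size() - 1 - window];
            if ((prev - ssd) / ref < tol) break;
        }
        // demons force; denominator guard keeps flat/zero-residual pixels at 0
        arma::mat ur(H, W), uc(H, W);
        for (int c = 0; c < W; ++c)
            for (int r = 0; r < H; ++r) {
                const double d = diff(r, c);
                const double den = g2(r, c) + d * d;
                if (den < 1e-12) {
                    ur(r, c) = 0.0;
                    uc(r, c) = 0.0;
                } else {
                    ur(r, c) = -d * gr(r, c) / den;
                    uc(r, c) = -d * gc(r, c) / den;
                }
            }
        drow = gaussian_blur_cpp(drow + ur, sigma);
        dcol = gaussian_blur_cpp(dcol + uc, sigma);
    }
    return List::create(_["drow"] = best_dr, _["dcol"] = best_dc,
                        _["ssd"] = ssd_hist, _["best_ssd"] = best_ssd);
}
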