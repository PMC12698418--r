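// Compiled kernels for the per-ROI feature extraction path: Zhang-Suen
// thinning, GLCM accumulation, and the FFT Gabor filter bank. These are the
// per-pixel inner loops; all orchestration stays in R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Zhang-Suen topology-preserving thinning. Out-of-bounds neighbours are
// background. Neighbour order P2..P9 clockwise from north; rows grow down.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> m(nr * nc);
  for (int i = 0; i < nr * nc; i++) m[i] = mask[i] ? 1 : 0;
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  std::vector<int> del;
  del.reserve(1024);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; sub++) {
      del.clear();
      for (int c = 0; c < nc; c++) {
        for (int r = 0; r < nr; r++) {
          if (!m[c * nr + r]) continue;
          int p[8];
          for (int k = 0; k < 8; k++) {
            int rr = r + dr[k], cc = c + dc[k];
            p[k] = (rr < 0 || rr >= nr || cc < 0 || cc >= nc)
                       ? 0 : m[cc * nr + rr];
          }
          int b = 0, a = 0;
          for (int k = 0; k < 8; k++) {
            b += p[k];
            if (p[k] == 0 && p[(k + 1) % 8] == 1) a++;
          }
          if (b < 2 || b > 6 || a != 1) continue;
          bool ok;
          if (sub == 0) {
            ok = (p[0] * p[2] * p[4] == 0) && (p[2] * p[4] * p[6] == 0);
          } else {
            ok = (p[0] * p[2] * p[6] == 0) && (p[0] * p[4] * p[6] == 0);
          }
          if (ok) del.push_back(c * nr + r);
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t i = 0; i < del.size(); i++) m[del[i]] = 0;
      }
    }
  }
  // Staircase cleanup: remove pixels whose skeleton neighbours form a single
  // 8-connected clump among themselves (their removal keeps the neighbours
  // mutually connected). Zhang-Suen leaves such redundant corner pixels on
  // oblique runs, which would otherwise masquerade as degree-3 junctions.
  // True junctions have >= 2 separate arms and are kept; endpoints (single
  // neighbour) are kept.
  bool removed = true;
  while (removed) {
    removed = false;
    for (int c = 0; c < nc; c++) {
      for (int r = 0; r < nr; r++) {
        if (!m[c * nr + r]) continue;
        int nb_r[8], nb_c[8], nn = 0;
        for (int k = 0; k < 8; k++) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (m[cc * nr + rr]) { nb_r[nn] = rr; nb_c[nn] = cc; nn++; }
        }
        if (nn < 2) continue;
        int comp[8];
        for (int i = 0; i < nn; i++) comp[i] = i;
        for (int i = 0; i < nn; i++) {
          for (int j = i + 1; j < nn; j++) {
            if (std::abs(nb_r[i] - nb_r[j]) <= 1 &&
                std::abs(nb_c[i] - nb_c[j]) <= 1) {
              int ci = comp[i], cj = comp[j];
              if (ci != cj) {
                for (int t = 0; t < nn; t++) {
                  if (comp[t] == cj) comp[t] = ci;
                }
              }
            }
          }
        }
        bool one = true;
        for (int i = 1; i < nn; i++) {
          if (comp[i] != comp[0]) { one = false; break; }
        }
        if (one) { m[c * nr + r] = 0; removed = true; }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < nr * nc; i++) out[i] = m[i] == 1;
  return out;
}

// Stamp a polyline onto an image with an isotropic Gaussian footprint per
// vertex, accumulating by pixelwise max (ridge with Gaussian cross-profile
// and peak amp). Coordinates are 1-based fractional (row, col); vertices
// outside the canvas contribute their in-canvas kernel part.
// [[Rcpp::export]]
NumericMatrix cpp_render_polyline(NumericMatrix img, NumericVector rows,
                                  NumericVector cols, double sigma_px,
                                  double amp) {
  const int n = img.nrow(), m = img.ncol();
  const int rad = std::max(1, int(std::ceil(3.0 * sigma_px)));
  const double inv2s2 = 1.0 / (2.0 * sigma_px * sigma_px);
  for (int i = 0; i < rows.size(); i++) {
    const int ri = int(std::lround(rows[i])), ci = int(std::lround(cols[i]));
    if (ri < 1 - rad || ri > n + rad || ci < 1 - rad || ci > m + rad) continue;
    const int r0 = std::max(1, ri - rad), r1 = std::min(n, ri + rad);
    const int c0 = std::max(1, ci - rad), c1 = std::min(m, ci + rad);
    for (int c = c0; c <= c1; c++) {
      const double dc2 = double(c - ci) * double(c - ci);
      for (int r = r0; r <= r1; r++) {
        const double d2 = double(r - ri) * double(r - ri) + dc2;
        const double v = amp * std::exp(-d2 * inv2s2);
        if (v > img(r - 1, c - 1)) img(r - 1, c - 1) = v;
      }
    }
  }
  return img;
}

// Symmetric normalized GLCM statistics (contrast, correlation, energy,
// uniformity) for each (dr, dc) offset. Rows of the result follow the
// offset order; an offset with no valid pixel pair yields NA in all four
// columns (the caller applies the degenerate convention).
// [[Rcpp::export]]
NumericMatrix cpp_glcm_stats(IntegerMatrix q, int G,
                             IntegerVector drv, IntegerVector dcv) {
  const int nr = q.nrow(), nc = q.ncol(), K = drv.size();
  NumericMatrix out(K, 4);
  std::vector<double> P(G * G);
  for (int k = 0; k < K; k++) {
    const int dr = drv[k], dc = dcv[k];
    std::fill(P.begin(), P.end(), 0.0);
    double npairs = 0.0;
    const int r0 = std::max(0, -dr), r1 = std::min(nr, nr - dr);
    const int c0 = std::max(0, -dc), c1 = std::min(nc, nc - dc);
    for (int c = c0; c < c1; c++) {
      for (int r = r0; r < r1; r++) {
        const int i = q(r, c) - 1, j = q(r + dr, c + dc) - 1;
        P[i * G + j] += 1.0;
        P[j * G + i] += 1.0; // symmetric
        npairs += 2.0;
      }
    }
    if (npairs == 0.0) {
      out(k, 0) = out(k, 1) = out(k, 2) = out(k, 3) = NA_REAL;
      continue;
    }
    double mu = 0.0;
    for (int i = 0; i < G; i++) {
      double pi_ = 0.0;
      for (int j = 0; j < G; j++) pi_ += P[i * G + j];
      mu += (i + 1) * pi_ / npairs;
    }
    double var = 0.0, contrast = 0.0, corr = 0.0, energy = 0.0, unif = 0.0;
    for (int i = 0; i < G; i++) {
      double pi_ = 0.0;
      for (int j = 0; j < G; j++) {
        const double p = P[i * G + j] / npairs;
        pi_ += p;
        const double d = double(i - j);
        contrast += d * d * p;
        corr += (i + 1 - mu) * (j + 1 - mu) * p;
        energy += p * p;
        unif += p / (1.0 + d * d);
      }
      var += (i + 1 - mu) * (i + 1 - mu) * pi_;
    }
    out(k, 0) = contrast;
    out(k, 1) = var < 1e-300 ? 0.0 : corr / var;
    out(k, 2) = energy;
    out(k, 3) = unif;
  }
  colnames(out) = CharacterVector::create("contrast", "correlation",
                                          "energy", "uniformity");
  return out;
}

// Complex Gabor kernel laid out for circular convolution (center at (0,0)
// with wrap-around), then transformed to the frequency domain. Bandwidth 1
// octave (sigma_x = 0.5622 lambda), aspect ratio 0.5 (sigma_y = 2 sigma_x),
// carrier along the filter orientation; rows grow downward, so the math
// y-axis is the negated row coordinate.
static arma::cx_mat gabor_kernel_fft_cpp(int nr, int nc, double lambda,
                                         double theta) {
  const double sx = 0.5622 * lambda;
  const double sy = sx / 0.5;
  arma::cx_mat kern(nr, nc);
  const double ct = std::cos(theta), st = std::sin(theta);
  for (int c = 0; c < nc; c++) {
    const double x = (c <= (nc - 1) / 2) ? double(c) : double(c - nc);
    for (int r = 0; r < nr; r++) {
      const double ymath = -((r <= (nr - 1) / 2) ? double(r) : double(r - nr));
      const double xr = x * ct + ymath * st;
      const double yr = -x * st + ymath * ct;
      const double env = std::exp(-(xr * xr / (2 * sx * sx) +
                                    yr * yr / (2 * sy * sy)));
      const double ph = 2.0 * M_PI * xr / lambda;
      kern(r, c) = std::complex<double>(env * std::cos(ph),
                                        env * std::sin(ph));
    }
  }
  return arma::fft2(kern);
}

// Session cache of kernel DFT banks, keyed by image size and bank layout.
static std::map<std::string, arma::cx_cube> gabor_bank_cache;

// Mean and population variance of the response-magnitude image of each
// filter in the Gabor bank (scale-major, orientation-minor slice order);
// convolution is circular via the FFT.
// [[Rcpp::export]]
NumericMatrix cpp_gabor_stats(const arma::mat& img, NumericVector lambdas,
                              NumericVector thetas) {
  const int nr = img.n_rows, nc = img.n_cols;
  const double N = double(nr) * double(nc);
  std::ostringstream ks;
  ks << nr << "x" << nc;
  for (int i = 0; i < lambdas.size(); i++) ks << "|l" << lambdas[i];
  for (int i = 0; i < thetas.size(); i++) ks << "|t" << thetas[i];
  const std::string key = ks.str();
  if (gabor_bank_cache.find(key) == gabor_bank_cache.end()) {
    arma::cx_cube bank(nr, nc, lambdas.size() * thetas.size());
    int k = 0;
    for (int s = 0; s < lambdas.size(); s++) {
      for (int o = 0; o < thetas.size(); o++) {
        bank.slice(k++) = gabor_kernel_fft_cpp(nr, nc, lambdas[s], thetas[o]);
      }
    }
    gabor_bank_cache[key] = bank;
  }
  const arma::cx_cube& kfft = gabor_bank_cache[key];
  arma::cx_mat F = arma::fft2(
      arma::cx_mat(img, arma::mat(nr, nc, arma::fill::zeros)));
  const int n = kfft.n_slices;
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; i++) {
    arma::cx_mat R = arma::ifft2(F % kfft.slice(i));
    arma::mat mag = arma::abs(R);
    const double mu = arma::accu(mag) / N;
    arma::mat d = mag - mu;
    out(i, 0) = mu;
    out(i, 1) = arma::accu(d % d) / N;
  }
  colnames(out) = CharacterVector::create("mean", "variance");
  return out;
}

// Drop all cached Gabor banks (memory hygiene for large image sizes).
// [[Rcpp::export]]
void cpp_gabor_cache_clear() { gabor_bank_cache.clear(); }
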