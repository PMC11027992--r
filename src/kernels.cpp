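// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Synthetic EEG synthesis in the frequency domain.
//
// chanAmp:  nBins x nCh  per-bin complex-coefficient scale for channel noise
//           (bins are the positive-frequency DFT bins 1..nBins; DC excluded)
// srcAmp:   nBins x nSrc per-bin scale for shared latent sources
// srcWeight: nCh x nSrc  mixing weight of each source into each channel
// winGain:  nCh x nWin   per-window channel gain (microstate modulation)
// winStart: 0-based start sample of each window; winLen: its length
//
// RNG draws come from R's stream (set.seed upstream) in a fixed order:
// all sources bin-by-bin, then all channels bin-by-bin, two normals per bin.
// Channels are synthesized two at a time: the Hermitian spectra of a channel
// pair are packed into one complex inverse transform (real part = first
// channel, imaginary part = second), and all transforms run in one batched
// call.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
arma::mat cpp_synth_eeg(int nSamp,
                        const arma::mat& chanAmp,
                        const arma::mat& srcAmp,
                        const arma::mat& srcWeight,
                        const arma::mat& winGain,
                        const arma::ivec& winStart,
                        const arma::ivec& winLen) {
  const int nBins = chanAmp.n_rows;
  const int nCh = chanAmp.n_cols;
  const int nSrc = srcAmp.n_cols;
  if (nBins >= nSamp / 2)
    stop("too many synthesis bins for the record length");

  arma::cx_mat src(nBins, nSrc);
  for (int s = 0; s < nSrc; ++s)
    for (int j = 0; j < nBins; ++j) {
      double re = norm_rand(), im = norm_rand();
      src(j, s) = std::complex<double>(re * srcAmp(j, s), im * srcAmp(j, s));
    }

  const int nPair = (nCh + 1) / 2;
  arma::cx_mat packed(nSamp, nPair, arma::fill::zeros);
  std::vector<std::complex<double>> v(nCh > 1 ? 2 : 1);
  for (int c = 0; c < nCh; ++c) {
    const int pc = c / 2;
    const bool second = (c % 2) == 1;
    for (int j = 0; j < nBins; ++j) {
      double re = norm_rand(), im = norm_rand();
      std::complex<double> z(re * chanAmp(j, c), im * chanAmp(j, c));
      for (int s = 0; s < nSrc; ++s) z += srcWeight(c, s) * src(j, s);
      // pack pair (x, y) as x + i y; both spectra are Hermitian
      if (second) {
        packed(j + 1, pc) += std::complex<double>(-z.imag(), z.real());
        packed(nSamp - 1 - j, pc) +=
          std::complex<double>(z.imag(), z.real());
      } else {
        packed(j + 1, pc) += z;
        packed(nSamp - 1 - j, pc) += std::conj(z);
      }
    }
  }

  arma::cx_mat zt = arma::ifft(packed);
  arma::mat out(nSamp, nCh);
  for (int c = 0; c < nCh; ++c) {
    if (c % 2 == 0) out.col(c) = arma::real(zt.col(c / 2));
    else out.col(c) = arma::imag(zt.col(c / 2));
  }

  const int nWin = winGain.n_cols;
  for (int w = 0; w < nWin; ++w) {
    int a = winStart(w), len = winLen(w);
    if (a + len > nSamp) len = nSamp - a;
    for (int ch = 0; ch < nCh; ++ch) {
      const double g = winGain(ch, w);
      if (g != 1.0) {
        double* col = out.colptr(ch);
        for (int t = a; t < a + len; ++t) col[t] *= g;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Zero-phase forward-backward filtering through a cascade of second-order
// sections. sos has one row per section: b0 b1 b2 a0 a1 a2 (a0 == 1).
// Odd (mirror) end padding limits start-up transients.
// ---------------------------------------------------------------------------
static void run_sos(std::vector<double>& x, const arma::mat& sos) {
  const int n = (int)x.size();
  for (arma::uword s = 0; s < sos.n_rows; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    for (int t = 0; t < n; ++t) {
      const double xt = x[t];
      const double yt = b0 * xt + z1;
      z1 = b1 * xt - a1 * yt + z2;
      z2 = b2 * xt - a2 * yt;
      x[t] = yt;
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_sosfiltfilt(const arma::mat& x, const arma::mat& sos, int padlen) {
  const int n = x.n_rows, nCh = x.n_cols;
  if (padlen >= n) padlen = n - 1;
  const int m = n + 2 * padlen;
  arma::mat out(n, nCh);
  std::vector<double> buf(m);
  for (int c = 0; c < nCh; ++c) {
    const double* xc = x.colptr(c);
    for (int t = 0; t < padlen; ++t)
      buf[t] = 2.0 * xc[0] - xc[padlen - t];
    std::memcpy(&buf[padlen], xc, n * sizeof(double));
    for (int t = 0; t < padlen; ++t)
      buf[padlen + n + t] = 2.0 * xc[n - 1] - xc[n - 2 - t];
    run_sos(buf, sos);
    std::reverse(buf.begin(), buf.end());
    run_sos(buf, sos);
    std::reverse(buf.begin(), buf.end());
    std::memcpy(out.colptr(c), &buf[padlen], n * sizeof(double));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-window, per-channel standard deviation (denominator win - 1).
// x is samples x channels; trailing partial window is dropped.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
arma::mat cpp_window_sd(const arma::mat& x, int win) {
  const int n = x.n_rows, nCh = x.n_cols;
  const int nWin = n / win;
  arma::mat out(nWin, nCh);
  for (int c = 0; c < nCh; ++c) {
    const double* xc = x.colptr(c);
    for (int w = 0; w < nWin; ++w) {
      double s = 0.0, s2 = 0.0;
      const double* p = xc + (size_t)w * win;
      for (int t = 0; t < win; ++t) {
        s += p[t]; s2 += p[t] * p[t];
      }
      const double mu = s / win;
      const double var = (s2 - win * mu * mu) / (win - 1.0);
      out(w, c) = var > 0.0 ? std::sqrt(var) : 0.0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fused preprocessing: zero-phase SOS band-pass, amplitude-threshold segment
// rejection (a segment is bad when any channel exceeds rejectSd times its
// post-filter SD), and average re-referencing of the retained samples.
// rejectSd < 0 skips rejection. Returns the retained samples x channels
// matrix and the 1-based indices of rejected segments.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_preprocess(const arma::mat& x, const arma::mat& sos, int padlen,
                    double rejectSd, int segLen) {
  arma::mat f = cpp_sosfiltfilt(x, sos, padlen);
  const int n = f.n_rows, nCh = f.n_cols;
  std::vector<int> bad;
  arma::uvec keepIdx;
  if (rejectSd >= 0.0 && n >= segLen) {
    const int nSeg = n / segLen;
    const bool tail = n > nSeg * segLen;
    const int nBlk = nSeg + (tail ? 1 : 0);
    std::vector<char> badBlk(nBlk, 0);
    for (int c = 0; c < nCh; ++c) {
      const double* fc = f.colptr(c);
      double s = 0.0, s2 = 0.0;
      for (int t = 0; t < n; ++t) { s += fc[t]; s2 += fc[t] * fc[t]; }
      const double mu = s / n;
      const double lim = rejectSd * std::sqrt(s2 / n - mu * mu);
      for (int b = 0; b < nBlk; ++b) {
        if (badBlk[b]) continue;
        const int a = b * segLen;
        const int e = std::min(n, a + segLen);
        for (int t = a; t < e; ++t)
          if (std::fabs(fc[t]) > lim) { badBlk[b] = 1; break; }
      }
    }
    int nKeep = 0;
    for (int b = 0; b < nBlk; ++b) {
      const int a = b * segLen, e = std::min(n, a + segLen);
      if (!badBlk[b]) nKeep += e - a;
      else if (b < nSeg) bad.push_back(b + 1);
    }
    if (nKeep == 0) stop("all segments rejected during preprocessing");
    if (nKeep < n) {
      arma::mat kept(nKeep, nCh);
      int row = 0;
      for (int b = 0; b < nBlk; ++b) {
        if (badBlk[b]) continue;
        const int a = b * segLen, e = std::min(n, a + segLen);
        kept.rows(row, row + e - a - 1) = f.rows(a, e - 1);
        row += e - a;
      }
      f = kept;
    }
  }
  // average re-reference: subtract the across-channel mean at every sample
  const int m = f.n_rows;
  arma::vec rm(m, arma::fill::zeros);
  for (int c = 0; c < nCh; ++c) rm += f.col(c);
  rm /= nCh;
  for (int c = 0; c < nCh; ++c) f.col(c) -= rm;
  return List::create(_["xt"] = f,
                      _["bad"] = IntegerVector(bad.begin(), bad.end()));
}

// Per-window, per-channel max absolute value (artifact screening).
// [[Rcpp::export]]
arma::mat cpp_window_max_abs(const arma::mat& x, int win) {
  const int n = x.n_rows, nCh = x.n_cols;
  const int nWin = n / win;
  arma::mat out(nWin, nCh);
  for (int c = 0; c < nCh; ++c) {
    const double* xc = x.colptr(c);
    for (int w = 0; w < nWin; ++w) {
      double m = 0.0;
      const double* p = xc + (size_t)w * win;
      for (int t = 0; t < win; ++t) {
        const double v = std::fabs(p[t]);
        if (v > m) m = v;
      }
      out(w, c) = m;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// LZ76 phrase count by exhaustive-history sequential parsing.
//
// The next phrase starting at position i is the shortest s[i..j] that is NOT
// a substring of s[0..j-1]; the final (possibly reproducible) phrase is
// counted. Substring queries against the growing prefix are answered by an
// online suffix automaton (flat preallocated arrays), giving linear total
// time.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
int cpp_lz76(const IntegerVector& s, int nsym) {
  const int n = s.size();
  if (n < 1) stop("empty sequence");
  if (nsym < 2 || nsym > 64) stop("alphabet size out of range");
  const int maxStates = 2 * n + 4;
  std::vector<int> len(maxStates), link(maxStates);
  std::vector<int> nxt((size_t)maxStates * nsym, -1);
  int nStates = 1, last = 0;
  len[0] = 0; link[0] = -1;

  auto sa_extend = [&](int c) {
    const int cur = nStates++;
    len[cur] = len[last] + 1;
    link[cur] = -1;
    std::fill(&nxt[(size_t)cur * nsym], &nxt[(size_t)cur * nsym + nsym], -1);
    int p = last;
    while (p != -1 && nxt[(size_t)p * nsym + c] == -1) {
      nxt[(size_t)p * nsym + c] = cur;
      p = link[p];
    }
    if (p == -1) {
      link[cur] = 0;
    } else {
      const int q = nxt[(size_t)p * nsym + c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        const int clone = nStates++;
        len[clone] = len[p] + 1;
        link[clone] = link[q];
        std::memcpy(&nxt[(size_t)clone * nsym], &nxt[(size_t)q * nsym],
                    nsym * sizeof(int));
        while (p != -1 && nxt[(size_t)p * nsym + c] == q) {
          nxt[(size_t)p * nsym + c] = clone;
          p = link[p];
        }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  };

  int count = 0, pos = 0;
  while (pos < n) {
    int state = 0, j = pos;
    bool closed = false;
    while (j < n) {
      const int c = s[j];
      if (c < 0 || c >= nsym) stop("symbol outside alphabet");
      const int nx = nxt[(size_t)state * nsym + c]; // query vs s[0..j-1]
      sa_extend(c);                                 // automaton holds s[0..j]
      if (nx == -1) {                // s[pos..j] unseen -> phrase closes here
        ++count; pos = j + 1; closed = true; break;
      }
      state = nx; ++j;
    }
    if (!closed) { ++count; break; } // trailing reproducible phrase
  }
  return count;
}

// ---------------------------------------------------------------------------
// Plug-in histogram mutual information (natural log) for a set of channel
// pairs. bins is n x nCh of 0-based bin indices, all < B. Marginals are
// accumulated from the joint table after the single pass over samples.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_mi_pairs(const IntegerMatrix& bins, int B,
                           const IntegerMatrix& pairs) {
  const int n = bins.nrow();
  const int P = pairs.nrow();
  NumericVector out(P);
  std::vector<int> joint((size_t)B * B), mx(B), my(B);
  const double dn = (double)n;
  for (int p = 0; p < P; ++p) {
    const int cx = pairs(p, 0), cy = pairs(p, 1);
    std::fill(joint.begin(), joint.end(), 0);
    const int* __restrict ix = &bins(0, cx);
    const int* __restrict iy = &bins(0, cy);
    for (int t = 0; t < n; ++t) ++joint[ix[t] * B + iy[t]];
    std::fill(mx.begin(), mx.end(), 0);
    std::fill(my.begin(), my.end(), 0);
    for (int a = 0; a < B; ++a)
      for (int b = 0; b < B; ++b) {
        const int nij = joint[a * B + b];
        mx[a] += nij; my[b] += nij;
      }
    // accumulate in sorted order so the estimate is exactly symmetric in
    // its arguments (the transposed table yields the same multiset of terms)
    std::vector<double> terms;
    terms.reserve(64);
    for (int a = 0; a < B; ++a) {
      if (!mx[a]) continue;
      const int* row = &joint[a * B];
      for (int b = 0; b < B; ++b)
        if (row[b])
          terms.push_back((row[b] / dn) *
                          std::log((row[b] * dn) / ((double)mx[a] * my[b])));
    }
    std::sort(terms.begin(), terms.end());
    double I = 0.0;
    for (double v : terms) I += v;
    out[p] = I;
  }
  return out;
}

// Equal-width bin indices per channel. With trimSd > 0 the binned range is
// mean +/- trimSd standard deviations (values outside fall into the edge
// bins), which keeps histogram resolution in the bulk of the distribution;
// trimSd <= 0 uses the full observed range.
// [[Rcpp::export]]
IntegerMatrix cpp_equal_width_bins(const arma::mat& x, int B,
                                   double trimSd) {
  const int n = x.n_rows, nCh = x.n_cols;
  IntegerMatrix out(n, nCh);
  for (int c = 0; c < nCh; ++c) {
    double lo, hi;
    if (trimSd > 0.0 && std::isfinite(trimSd)) {
      const double mu = arma::mean(x.col(c));
      const double sd = arma::stddev(x.col(c));
      lo = mu - trimSd * sd;
      hi = mu + trimSd * sd;
    } else {
      lo = x.col(c).min();
      hi = x.col(c).max();
    }
    const double w = hi - lo;
    int* oc = &out(0, c);
    if (w <= 0.0) {
      std::fill(oc, oc + n, 0);
      continue;
    }
    const double f = B / w;
    const double* xc = x.colptr(c);
    for (int t = 0; t < n; ++t) {
      int b = (int)((xc[t] - lo) * f);
      oc[t] = b >= B ? B - 1 : (b < 0 ? 0 : b);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Lloyd k-means with k-means++ seeding and multiple restarts, driven by R's
// RNG for seed determinism. Ties in nearest-centre assignment go to the
// lowest centre index (strict improvement required to switch).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_kmeans(const arma::mat& X, int k, int nstart, int maxIter,
                double tol) {
  const int n = X.n_rows, d = X.n_cols;
  if (k > n) stop("more clusters than observations");
  arma::mat bestC(k, d);
  arma::ivec bestA(n);
  double bestW = R_PosInf;
  int bestIter = 0;

  arma::vec d2(n);
  arma::ivec assign(n);
  arma::mat C(k, d);

  for (int start = 0; start < nstart; ++start) {
    // k-means++ seeding
    int first = (int)std::floor(unif_rand() * n);
    if (first >= n) first = n - 1;
    C.row(0) = X.row(first);
    for (int i = 0; i < n; ++i) {
      const arma::rowvec diff = X.row(i) - C.row(0);
      d2(i) = arma::dot(diff, diff);
    }
    for (int c = 1; c < k; ++c) {
      const double tot = arma::accu(d2);
      int pick;
      if (tot <= 0.0) {
        pick = (int)std::floor(unif_rand() * n);
        if (pick >= n) pick = n - 1;
      } else {
        const double u = unif_rand() * tot;
        double acc = 0.0;
        pick = n - 1;
        for (int i = 0; i < n; ++i) {
          acc += d2(i);
          if (u <= acc) { pick = i; break; }
        }
      }
      C.row(c) = X.row(pick);
      for (int i = 0; i < n; ++i) {
        const arma::rowvec diff = X.row(i) - C.row(c);
        const double v = arma::dot(diff, diff);
        if (v < d2(i)) d2(i) = v;
      }
    }

    // Lloyd iterations
    int it = 0;
    for (; it < maxIter; ++it) {
      bool changed = (it == 0);
      for (int i = 0; i < n; ++i) {
        int bj = 0; double bd = R_PosInf;
        for (int c = 0; c < k; ++c) {
          const arma::rowvec diff = X.row(i) - C.row(c);
          const double v = arma::dot(diff, diff);
          if (v < bd) { bd = v; bj = c; }
        }
        if (it > 0 && assign(i) != bj) changed = true;
        assign(i) = bj;
      }
      if (it > 0 && !changed) break;
      arma::mat newC(k, d, arma::fill::zeros);
      arma::ivec cnt(k, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        newC.row(assign(i)) += X.row(i);
        ++cnt(assign(i));
      }
      for (int c = 0; c < k; ++c) {
        if (cnt(c) == 0) {
          // re-seed an empty cluster at the point farthest from its centre
          int far = 0; double fd = -1.0;
          for (int i = 0; i < n; ++i) {
            const arma::rowvec diff = X.row(i) - C.row(assign(i));
            const double v = arma::dot(diff, diff);
            if (v > fd) { fd = v; far = i; }
          }
          newC.row(c) = X.row(far);
        } else {
          newC.row(c) /= (double)cnt(c);
        }
      }
      const double shift = arma::accu(arma::square(newC - C));
      C = newC;
      if (shift < tol) { ++it; break; }
    }
    // final assignment/wss for the converged centres
    double wss = 0.0;
    for (int i = 0; i < n; ++i) {
      int bj = 0; double bd = R_PosInf;
      for (int c = 0; c < k; ++c) {
        const arma::rowvec diff = X.row(i) - C.row(c);
        const double v = arma::dot(diff, diff);
        if (v < bd) { bd = v; bj = c; }
      }
      assign(i) = bj; wss += bd;
    }
    if (wss < bestW) {
      bestW = wss; bestC = C; bestA = assign; bestIter = it;
    }
  }
  return List::create(_["centers"] = bestC,
                      _["cluster"] = IntegerVector(bestA.begin(), bestA.end()),
                      _["tot.withinss"] = bestW,
                      _["iter"] = bestIter);
}

// ---------------------------------------------------------------------------
// Squared-magnitude column FFTs of a real matrix (used for the
// segment-averaged spectrum). Columns are packed in pairs into one complex
// transform and unpacked via the Hermitian identities, halving the FFT work.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
arma::mat cpp_fft_pow(const arma::mat& x) {
  const int n = x.n_rows, m = x.n_cols;
  const int nPair = (m + 1) / 2;
  arma::cx_mat packed(n, nPair);
  for (int p = 0; p < nPair; ++p) {
    const double* a = x.colptr(2 * p);
    if (2 * p + 1 < m) {
      const double* b = x.colptr(2 * p + 1);
      std::complex<double>* z = packed.colptr(p);
      for (int t = 0; t < n; ++t) z[t] = std::complex<double>(a[t], b[t]);
    } else {
      std::complex<double>* z = packed.colptr(p);
      for (int t = 0; t < n; ++t) z[t] = std::complex<double>(a[t], 0.0);
    }
  }
  arma::cx_mat F = arma::fft(packed);
  arma::mat out(n, m);
  for (int p = 0; p < nPair; ++p) {
    const std::complex<double>* f = F.colptr(p);
    double* o1 = out.colptr(2 * p);
    double* o2 = (2 * p + 1 < m) ? out.colptr(2 * p + 1) : nullptr;
    for (int k = 0; k < n; ++k) {
      const int kr = (k == 0) ? 0 : n - k;
      const double reA = 0.5 * (f[k].real() + f[kr].real());
      const double imA = 0.5 * (f[k].imag() - f[kr].imag());
      o1[k] = reA * reA + imA * imA;
      if (o2) {
        const double reB = 0.5 * (f[k].imag() + f[kr].imag());
        const double imB = 0.5 * (f[kr].real() - f[k].real());
        o2[k] = reB * reB + imB * imB;
      }
    }
  }
  return out;
}
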