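// Small hot loops behind the adaptive max pooling and global max pooling
// operators. Everything else in the network is BLAS-bound matrix algebra
// and stays in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Accumulate vals into a zero vector of length n at (1-based) idx,
// summing duplicates.
// [[Rcpp::export]]
NumericVector cpp_scatter_add(int n, IntegerVector idx, NumericVector vals) {
  NumericVector out(n);
  const int m = idx.size();
  for (int i = 0; i < m; ++i) out[idx[i] - 1] += vals[i];
  return out;
}

// Adaptive max pool of a C x L matrix to C x T using 1-based inclusive bin
// boundaries starts/ends (length T). Returns the bin maxima and the
// (1-based) input column index of the first maximum per bin.
// [[Rcpp::export]]
List cpp_adaptive_maxpool(NumericMatrix X, IntegerVector starts,
                          IntegerVector ends, bool relu) {
  const int C = X.nrow();
  const int T = starts.size();
  NumericMatrix out(C, T);
  IntegerMatrix amax(C, T);
  const double *xp = X.begin();
  double *op = out.begin();
  int *ap = amax.begin();
  for (int t = 0; t < T; ++t) {
    const int s = starts[t] - 1, e = ends[t] - 1;
    double *oc = op + (size_t)t * C;
    int *ac = ap + (size_t)t * C;
    std::memcpy(oc, xp + (size_t)s * C, C * sizeof(double));
    for (int c = 0; c < C; ++c) ac[c] = s + 1;
    for (int j = s + 1; j <= e; ++j) {
      const double *xc = xp + (size_t)j * C;
      for (int c = 0; c < C; ++c)
        if (xc[c] > oc[c]) { oc[c] = xc[c]; ac[c] = j + 1; }
    }
    if (relu)
      for (int c = 0; c < C; ++c) if (oc[c] < 0.0) oc[c] = 0.0;
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// Global max over the position blocks of a (B*Lout) x F activation matrix
// whose rows are ordered position-major (row = b + t*B). Returns the B x F
// maxima and the (1-based) position index of the first maximum.
// [[Rcpp::export]]
List cpp_blockmax(NumericMatrix act, int B, int Lout) {
  const int F = act.ncol();
  NumericMatrix out(B, F);
  IntegerMatrix amax(B, F);
  for (int f = 0; f < F; ++f) {
    for (int b = 0; b < B; ++b) {
      double best = act(b, f);
      int bestt = 0;
      for (int t = 1; t < Lout; ++t) {
        const double v = act(t * B + b, f);
        if (v > best) { best = v; bestt = t; }
      }
      out(b, f) = best;
      amax(b, f) = bestt + 1;
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// Row-wise max of a matrix (used by the stable softmax).
// [[Rcpp::export]]
NumericVector cpp_rowmax(NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = X(i, 0);
    for (int j = 1; j < m; ++j) if (X(i, j) > best) best = X(i, j);
    out[i] = best;
  }
  return out;
}

// Sparse backward of the TextCNN kernel: gradients flow only through the
// per-(sequence, filter) argmax positions of the global max pool.
// dPooled, amax, pooled: B x F. Farr: B x P x Cin (passed flat with dims).
// W: F x Cin x k (flat). sel: 1-based dense-output positions (length Lout).
// Returns dW, db and dFarr (same shape as Farr).
// [[Rcpp::export]]
List cpp_textcnn_bw(NumericMatrix dPooled, IntegerMatrix amax,
                    NumericMatrix pooled, NumericVector Farr,
                    IntegerVector fdim, NumericVector W, IntegerVector wdim,
                    IntegerVector sel) {
  const int B = fdim[0], P = fdim[1], Cin = fdim[2];
  const int F = wdim[0], k = wdim[2];
  NumericVector dW(F * Cin * k), db(F), dFarr(B * P * Cin);
  for (int f = 0; f < F; ++f) {
    for (int b = 0; b < B; ++b) {
      if (pooled(b, f) <= 0.0) continue;  // ReLU inactive at the argmax
      const double g = dPooled(b, f);
      if (g == 0.0) continue;
      const int t0 = sel[amax(b, f) - 1] - 1;  // dense position (0-based)
      db[f] += g;
      for (int j = 0; j < k; ++j) {
        const size_t fbase = (size_t)b + (size_t)(t0 + j) * B;
        for (int c = 0; c < Cin; ++c) {
          const size_t fi = fbase + (size_t)c * B * P;
          const size_t wi = (size_t)f + (size_t)c * F + (size_t)j * F * Cin;
          dW[wi] += g * Farr[fi];
          dFarr[fi] += g * W[wi];
        }
      }
    }
  }
  dW.attr("dim") = wdim;
  dFarr.attr("dim") = fdim;
  return List::create(_["dW"] = dW, _["db"] = db, _["dFarr"] = dFarr);
}

// im2col: X (Cin x L) -> C (Cin*k x Lout), column t stacks the k input
// columns t..t+k-1.
static arma::mat im2col(const arma::mat &X, int k) {
  const int Cin = X.n_rows, L = X.n_cols, Lout = L - k + 1;
  arma::mat C(Cin * k, Lout);
  for (int t = 0; t < Lout; ++t) {
    double *dst = C.colptr(t);
    for (int j = 0; j < k; ++j)
      std::memcpy(dst + j * Cin, X.colptr(t + j), Cin * sizeof(double));
  }
  return C;
}

// Valid stride-1 1D convolution as one GEMM over the im2col matrix.
// X: Cin x L; Wflat: Cout x Cin*k (kernel-offset major); b: Cout.
// [[Rcpp::export]]
arma::mat cpp_conv1d_fw(const arma::mat &X, const arma::mat &Wflat,
                        const arma::vec &b, int k) {
  arma::mat out = Wflat * im2col(X, k);
  out.each_col() += b;
  return out;
}

// Backward of cpp_conv1d_fw; dX is skipped when needInputGrad is false
// (first encoder stage: the encoding has no parameters upstream).
// [[Rcpp::export]]
List cpp_conv1d_bw(const arma::mat &X, const arma::mat &Wflat,
                   const arma::mat &dOut, int k, bool needInputGrad) {
  const int Cin = X.n_rows, L = X.n_cols;
  const int Lout = dOut.n_cols;
  arma::mat C = im2col(X, k);
  arma::mat dW = dOut * C.t();
  arma::vec db = arma::sum(dOut, 1);
  arma::mat dX(Cin, L, arma::fill::zeros);
  if (needInputGrad) {
    arma::mat dC = Wflat.t() * dOut;  // Cin*k x Lout
    for (int t = 0; t < Lout; ++t) {
      const double *src = dC.colptr(t);
      for (int j = 0; j < k; ++j) {
        double *dst = dX.colptr(t + j);
        const double *s2 = src + j * Cin;
        for (int c = 0; c < Cin; ++c) dst[c] += s2[c];
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// ---- Long-short term attention, full batch forward/backward ----------------
// Per sequence: per-head Q/K/V projections; short branch = segment-windowed
// keys/values; long branch = column-softmax dynamic projection to r rows;
// separate layer norms per branch (skipped when r == 0); scaled dot-product
// attention over the concatenated key set with dropout on the attention
// probabilities; heads concatenated and mixed by Wo. The forward stores its
// intermediates in an external pointer consumed by the backward; dropout is
// kept as a byte mask rather than a second dense matrix.

struct LnCache { arma::mat xhat; arma::vec inv; };

struct HeadCache {
  arma::mat Pm;
  arma::mat Khn, Vhn, Kbarn, Vbarn;
  LnCache lnKs, lnVs, lnKl, lnVl;
  std::vector<arma::mat> A;
  std::vector<arma::Mat<unsigned char> > mask;
};

struct SeqCache {
  arma::mat x, Q, K, V, O;
  std::vector<HeadCache> heads;
};

struct LstaCache {
  std::vector<SeqCache> seqs;
  std::vector<int> segStart, segEnd;
};

static arma::mat lnForward(const arma::mat &x, const arma::vec &g,
                           const arma::vec &b, LnCache &cc) {
  const double eps = 1e-5;
  arma::vec mu = arma::mean(x, 1);
  arma::mat xc = x.each_col() - mu;
  arma::vec v = arma::mean(arma::square(xc), 1);
  cc.inv = 1.0 / arma::sqrt(v + eps);
  cc.xhat = xc.each_col() % cc.inv;
  arma::mat out = cc.xhat.each_row() % g.t();
  out.each_row() += b.t();
  return out;
}

static arma::mat lnBackward(const arma::mat &dout, const LnCache &cc,
                            const arma::vec &g, arma::vec &dg,
                            arma::vec &db) {
  dg += arma::sum(dout % cc.xhat, 0).t();
  db += arma::sum(dout, 0).t();
  arma::mat dxhat = dout.each_row() % g.t();
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % cc.xhat, 1);
  arma::mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= cc.xhat.each_col() % m2;
  dx.each_col() %= cc.inv;
  return dx;
}

static arma::mat rowSoftmax(const arma::mat &x) {
  arma::mat e = arma::exp(x.each_col() - arma::max(x, 1));
  return e.each_col() / arma::sum(e, 1);
}

// Gather sequence b from a (B, P, d) R array into a P x d matrix.
static arma::mat sliceSeq(const double *X, int b, int B, int P, int d) {
  arma::mat x(P, d);
  for (int c = 0; c < d; ++c) {
    double *dst = x.colptr(c);
    const double *src = X + (size_t)b + (size_t)c * B * P;
    for (int t = 0; t < P; ++t) dst[t] = src[(size_t)t * B];
  }
  return x;
}

static void scatterSeq(double *X, const arma::mat &x, int b, int B, int P,
                       int d) {
  for (int c = 0; c < d; ++c) {
    const double *src = x.colptr(c);
    double *dst = X + (size_t)b + (size_t)c * B * P;
    for (int t = 0; t < P; ++t) dst[(size_t)t * B] = src[t];
  }
}

// [[Rcpp::export]]
List cpp_lsta_batch_fw(NumericVector Xarr, IntegerVector dims,
                       const arma::mat &Wq, const arma::mat &Wk,
                       const arma::mat &Wv, const arma::cube &Wp,
                       List lnPars, const arma::mat &Wo, const arma::vec &bo,
                       int dk, int r, int window, double dropout,
                       bool training) {
  const int B = dims[0], P = dims[1];
  const int d = Wq.n_rows;
  const int N = Wq.n_cols / dk;
  const double invs = 1.0 / std::sqrt((double)dk);
  const bool drop = training && dropout > 0;
  const double scale = drop ? 1.0 / (1.0 - dropout) : 1.0;
  XPtr<LstaCache> cache(new LstaCache(), true);
  for (int s = 0; s < P; s += window) {
    cache->segStart.push_back(s);
    cache->segEnd.push_back(std::min(s + window, P) - 1);
  }
  const int nseg = cache->segStart.size();
  arma::vec g_sk, b_sk, g_sv, b_sv, g_lk, b_lk, g_lv, b_lv;
  if (r > 0) {
    g_sk = as<arma::vec>(lnPars["sk_g"]); b_sk = as<arma::vec>(lnPars["sk_b"]);
    g_sv = as<arma::vec>(lnPars["sv_g"]); b_sv = as<arma::vec>(lnPars["sv_b"]);
    g_lk = as<arma::vec>(lnPars["lk_g"]); b_lk = as<arma::vec>(lnPars["lk_b"]);
    g_lv = as<arma::vec>(lnPars["lv_g"]); b_lv = as<arma::vec>(lnPars["lv_b"]);
  }
  NumericVector out(B * P * d);
  for (int b = 0; b < B; ++b) {
    SeqCache sc;
    sc.x = sliceSeq(Xarr.begin(), b, B, P, d);
    sc.Q = sc.x * Wq;
    sc.K = sc.x * Wk;
    sc.V = sc.x * Wv;
    sc.O.zeros(P, N * dk);
    for (int h = 0; h < N; ++h) {
      HeadCache hc;
      const arma::mat Kh = sc.K.cols(h * dk, (h + 1) * dk - 1);
      const arma::mat Vh = sc.V.cols(h * dk, (h + 1) * dk - 1);
      if (r > 0) {
        arma::mat S = Kh * Wp.slice(h);               // P x r
        arma::mat e = arma::exp(S.each_row() - arma::max(S, 0));
        hc.Pm = e.each_row() / arma::sum(e, 0);       // column softmax
        hc.Khn = lnForward(Kh, g_sk, b_sk, hc.lnKs);
        hc.Vhn = lnForward(Vh, g_sv, b_sv, hc.lnVs);
        hc.Kbarn = lnForward(hc.Pm.t() * Kh, g_lk, b_lk, hc.lnKl);
        hc.Vbarn = lnForward(hc.Pm.t() * Vh, g_lv, b_lv, hc.lnVl);
      } else {
        hc.Khn = Kh;
        hc.Vhn = Vh;
        hc.Kbarn.set_size(0, dk);
        hc.Vbarn.set_size(0, dk);
      }
      for (int si = 0; si < nseg; ++si) {
        const int s0 = cache->segStart[si], s1 = cache->segEnd[si];
        arma::mat Kcat = arma::join_cols(hc.Khn.rows(s0, s1), hc.Kbarn);
        arma::mat Vcat = arma::join_cols(hc.Vhn.rows(s0, s1), hc.Vbarn);
        arma::mat A = rowSoftmax(
          sc.Q.submat(s0, h * dk, s1, (h + 1) * dk - 1) * Kcat.t() * invs);
        if (drop) {
          arma::Mat<unsigned char> m(A.n_rows, A.n_cols);
          arma::mat Ad(A.n_rows, A.n_cols);
          for (arma::uword i = 0; i < A.n_elem; ++i) {
            const bool keep = R::unif_rand() >= dropout;
            m[i] = keep;
            Ad[i] = keep ? A[i] * scale : 0.0;
          }
          sc.O.submat(s0, h * dk, s1, (h + 1) * dk - 1) = Ad * Vcat;
          hc.mask.push_back(std::move(m));
        } else {
          sc.O.submat(s0, h * dk, s1, (h + 1) * dk - 1) = A * Vcat;
        }
        hc.A.push_back(std::move(A));
      }
      sc.heads.push_back(std::move(hc));
    }
    arma::mat o = sc.O * Wo;
    o.each_row() += bo.t();
    scatterSeq(out.begin(), o, b, B, P, d);
    cache->seqs.push_back(std::move(sc));
  }
  out.attr("dim") = IntegerVector::create(B, P, d);
  return List::create(_["out"] = out, _["cache"] = cache);
}

// [[Rcpp::export]]
List cpp_lsta_batch_bw(NumericVector dArr, SEXP cachePtr, const arma::mat &Wq,
                       const arma::mat &Wk, const arma::mat &Wv,
                       const arma::cube &Wp, List lnPars, const arma::mat &Wo,
                       int dk, int r, double dropout, bool training) {
  XPtr<LstaCache> cache(cachePtr);
  const int B = cache->seqs.size();
  const int d = Wq.n_rows;
  const int N = Wq.n_cols / dk;
  const int P = cache->seqs[0].x.n_rows;
  const double invs = 1.0 / std::sqrt((double)dk);
  const bool drop = training && dropout > 0;
  const double scale = drop ? 1.0 / (1.0 - dropout) : 1.0;
  arma::mat dWq(arma::size(Wq), arma::fill::zeros), dWk(dWq), dWv(dWq);
  arma::mat dWo(arma::size(Wo), arma::fill::zeros);
  arma::vec dbo(Wo.n_cols, arma::fill::zeros);
  arma::cube dWp(Wp.n_rows, Wp.n_cols, Wp.n_slices, arma::fill::zeros);
  arma::vec g_sk, g_sv, g_lk, g_lv;
  arma::vec dg_sk(dk, arma::fill::zeros), db_sk(dg_sk), dg_sv(dg_sk),
    db_sv(dg_sk), dg_lk(dg_sk), db_lk(dg_sk), dg_lv(dg_sk), db_lv(dg_sk);
  if (r > 0) {
    g_sk = as<arma::vec>(lnPars["sk_g"]);
    g_sv = as<arma::vec>(lnPars["sv_g"]);
    g_lk = as<arma::vec>(lnPars["lk_g"]);
    g_lv = as<arma::vec>(lnPars["lv_g"]);
  }
  NumericVector dXout(B * P * d);
  const int nseg = cache->segStart.size();
  for (int b = 0; b < B; ++b) {
    SeqCache &sc = cache->seqs[b];
    arma::mat dOut = sliceSeq(dArr.begin(), b, B, P, d);
    dWo += sc.O.t() * dOut;
    dbo += arma::sum(dOut, 0).t();
    arma::mat dO = dOut * Wo.t();
    arma::mat dQ(P, N * dk, arma::fill::zeros), dK(dQ), dV(dQ);
    for (int h = 0; h < N; ++h) {
      HeadCache &hc = sc.heads[h];
      const arma::mat Kh = sc.K.cols(h * dk, (h + 1) * dk - 1);
      const arma::mat Vh = sc.V.cols(h * dk, (h + 1) * dk - 1);
      arma::mat dKhn(P, dk, arma::fill::zeros), dVhn(dKhn);
      arma::mat dKbarn, dVbarn;
      if (r > 0) { dKbarn.zeros(r, dk); dVbarn.zeros(r, dk); }
      for (int si = 0; si < nseg; ++si) {
        const int s0 = cache->segStart[si], s1 = cache->segEnd[si];
        const int w = s1 - s0 + 1;
        arma::mat Kcat = arma::join_cols(hc.Khn.rows(s0, s1), hc.Kbarn);
        arma::mat Vcat = arma::join_cols(hc.Vhn.rows(s0, s1), hc.Vbarn);
        arma::mat dOseg = dO.submat(s0, h * dk, s1, (h + 1) * dk - 1);
        arma::mat Adrop = hc.A[si];
        if (drop) {
          const arma::Mat<unsigned char> &m = hc.mask[si];
          for (arma::uword i = 0; i < Adrop.n_elem; ++i)
            Adrop[i] = m[i] ? Adrop[i] * scale : 0.0;
        }
        arma::mat dA = dOseg * Vcat.t();
        arma::mat dVcat = Adrop.t() * dOseg;
        if (drop) {
          const arma::Mat<unsigned char> &m = hc.mask[si];
          for (arma::uword i = 0; i < dA.n_elem; ++i)
            dA[i] = m[i] ? dA[i] * scale : 0.0;
        }
        // softmax backward: dA0 = A % (dA - rowsums(dA % A))
        arma::mat dA0 = hc.A[si] % (dA.each_col()
                                      - arma::sum(dA % hc.A[si], 1));
        dQ.submat(s0, h * dk, s1, (h + 1) * dk - 1) += dA0 * Kcat * invs;
        arma::mat dKcat = dA0.t()
          * sc.Q.submat(s0, h * dk, s1, (h + 1) * dk - 1) * invs;
        dKhn.rows(s0, s1) += dKcat.rows(0, w - 1);
        dVhn.rows(s0, s1) += dVcat.rows(0, w - 1);
        if (r > 0) {
          dKbarn += dKcat.rows(w, w + r - 1);
          dVbarn += dVcat.rows(w, w + r - 1);
        }
      }
      arma::mat dKh, dVh;
      if (r > 0) {
        dKh = lnBackward(dKhn, hc.lnKs, g_sk, dg_sk, db_sk);
        dVh = lnBackward(dVhn, hc.lnVs, g_sv, dg_sv, db_sv);
        arma::mat dKbar = lnBackward(dKbarn, hc.lnKl, g_lk, dg_lk, db_lk);
        arma::mat dVbar = lnBackward(dVbarn, hc.lnVl, g_lv, dg_lv, db_lv);
        arma::mat dPm = Kh * dKbar.t() + Vh * dVbar.t();
        dKh += hc.Pm * dKbar;
        dVh += hc.Pm * dVbar;
        arma::mat dS = hc.Pm % (dPm.each_row()
                                  - arma::sum(dPm % hc.Pm, 0));
        dKh += dS * Wp.slice(h).t();
        dWp.slice(h) += Kh.t() * dS;
      } else {
        dKh = dKhn;
        dVh = dVhn;
      }
      dK.cols(h * dk, (h + 1) * dk - 1) = dKh;
      dV.cols(h * dk, (h + 1) * dk - 1) = dVh;
    }
    dWq += sc.x.t() * dQ;
    dWk += sc.x.t() * dK;
    dWv += sc.x.t() * dV;
    arma::mat dx = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    scatterSeq(dXout.begin(), dx, b, B, P, d);
  }
  dXout.attr("dim") = IntegerVector::create(B, P, d);
  return List::create(
    _["dX"] = dXout, _["dWq"] = dWq, _["dWk"] = dWk, _["dWv"] = dWv,
    _["dWp"] = dWp, _["dWo"] = dWo, _["dbo"] = dbo,
    _["dln"] = List::create(
      _["sk_g"] = dg_sk, _["sk_b"] = db_sk, _["sv_g"] = dg_sv,
      _["sv_b"] = db_sv, _["lk_g"] = dg_lk, _["lk_b"] = db_lk,
      _["lv_g"] = dg_lv, _["lv_b"] = db_lv));
}

// Backward of the adaptive max pool: route dPool (C x T) to the argmax
// input positions (C x L), summing duplicates.
// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bw(NumericMatrix dPool, IntegerMatrix amax,
                             int L) {
  const int C = dPool.nrow(), T = dPool.ncol();
  NumericMatrix dX(C, L);
  double *dxp = dX.begin();
  const double *dp = dPool.begin();
  const int *ap = amax.begin();
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < C; ++c) {
      const size_t i = (size_t)t * C + c;
      dxp[(size_t)(ap[i] - 1) * C + c] += dp[i];
    }
  return dX;
}

// ---- Bi-LSTM, batched forward/backward -------------------------------------
// Standard gates (sigmoid i/f/o, tanh candidate), zero initial states,
// fused weights [i f o g] each H columns. Input and output use the R array
// layout (B, P, C): element (b, t, c) at b + t*B + c*B*P.

struct LstmDirCache {
  arma::cube i, f, o, g, tc, hPrev, cPrev;  // each B x H x P
  std::vector<int> times;
  arma::mat Xts;  // B*P x Cin gathered inputs in visit order blocks
};

struct BilstmCache { LstmDirCache fwd, bwd; int B, P, Cin, H; };

static inline double sigm(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static void lstmDirForward(const double *X, int B, int P, int Cin,
                           const arma::mat &Wx, const arma::mat &Wh,
                           const arma::vec &bias, bool reverse,
                           double *out, int outOffset, int outStride,
                           LstmDirCache &cc) {
  const int H = Wh.n_rows;
  cc.i.set_size(B, H, P); cc.f.set_size(B, H, P); cc.o.set_size(B, H, P);
  cc.g.set_size(B, H, P); cc.tc.set_size(B, H, P);
  cc.hPrev.set_size(B, H, P); cc.cPrev.set_size(B, H, P);
  cc.times.resize(P);
  cc.Xts.set_size(B * P, Cin);
  arma::mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  arma::mat Xt(B, Cin);
  for (int kk = 0; kk < P; ++kk) {
    const int t = reverse ? (P - 1 - kk) : kk;
    cc.times[kk] = t;
    for (int ci = 0; ci < Cin; ++ci)
      for (int b = 0; b < B; ++b)
        Xt(b, ci) = X[b + (size_t)t * B + (size_t)ci * B * P];
    cc.Xts.rows(kk * B, (kk + 1) * B - 1) = Xt;
    arma::mat Z = Xt * Wx + h * Wh;
    Z.each_row() += bias.t();
    cc.hPrev.slice(kk) = h;
    cc.cPrev.slice(kk) = c;
    for (int j = 0; j < H; ++j) {
      for (int b = 0; b < B; ++b) {
        const double iv = sigm(Z(b, j));
        const double fv = sigm(Z(b, H + j));
        const double ov = sigm(Z(b, 2 * H + j));
        const double gv = std::tanh(Z(b, 3 * H + j));
        const double cv = fv * c(b, j) + iv * gv;
        const double tcv = std::tanh(cv);
        cc.i(b, j, kk) = iv; cc.f(b, j, kk) = fv; cc.o(b, j, kk) = ov;
        cc.g(b, j, kk) = gv; cc.tc(b, j, kk) = tcv;
        c(b, j) = cv;
        h(b, j) = ov * tcv;
        out[b + (size_t)t * B + (size_t)(outOffset + j) * outStride] = h(b, j);
      }
    }
  }
}

static void lstmDirBackward(const double *dOut, int B, int P, int Cin,
                            const arma::mat &Wx, const arma::mat &Wh,
                            int outOffset, int outStride,
                            const LstmDirCache &cc, arma::mat &dWx,
                            arma::mat &dWh, arma::vec &db, double *dX) {
  const int H = Wh.n_rows;
  arma::mat dhNext(B, H, arma::fill::zeros), dcNext(B, H, arma::fill::zeros);
  arma::mat dZ(B, 4 * H);
  for (int kk = P - 1; kk >= 0; --kk) {
    const int t = cc.times[kk];
    for (int j = 0; j < H; ++j) {
      for (int b = 0; b < B; ++b) {
        const double dh = dOut[b + (size_t)t * B
                               + (size_t)(outOffset + j) * outStride]
                          + dhNext(b, j);
        const double iv = cc.i(b, j, kk), fv = cc.f(b, j, kk);
        const double ov = cc.o(b, j, kk), gv = cc.g(b, j, kk);
        const double tcv = cc.tc(b, j, kk);
        const double dov = dh * tcv;
        const double dc = dcNext(b, j) + dh * ov * (1.0 - tcv * tcv);
        const double div = dc * gv;
        const double dgv = dc * iv;
        const double dfv = dc * cc.cPrev(b, j, kk);
        dcNext(b, j) = dc * fv;
        dZ(b, j) = div * iv * (1.0 - iv);
        dZ(b, H + j) = dfv * fv * (1.0 - fv);
        dZ(b, 2 * H + j) = dov * ov * (1.0 - ov);
        dZ(b, 3 * H + j) = dgv * (1.0 - gv * gv);
      }
    }
    const arma::mat Xt = cc.Xts.rows(kk * B, (kk + 1) * B - 1);
    dWx += Xt.t() * dZ;
    dWh += cc.hPrev.slice(kk).t() * dZ;
    db += arma::sum(dZ, 0).t();
    arma::mat dXt = dZ * Wx.t();
    for (int ci = 0; ci < Cin; ++ci)
      for (int b = 0; b < B; ++b)
        dX[b + (size_t)t * B + (size_t)ci * B * P] += dXt(b, ci);
    dhNext = dZ * Wh.t();
  }
}

// [[Rcpp::export]]
List cpp_bilstm_fw(NumericVector Xarr, IntegerVector dims,
                   const arma::mat &fWx, const arma::mat &fWh,
                   const arma::vec &fb, const arma::mat &bWx,
                   const arma::mat &bWh, const arma::vec &bb) {
  const int B = dims[0], P = dims[1], Cin = dims[2];
  const int H = fWh.n_rows;
  XPtr<BilstmCache> cache(new BilstmCache(), true);
  cache->B = B; cache->P = P; cache->Cin = Cin; cache->H = H;
  NumericVector out(B * P * 2 * H);
  lstmDirForward(Xarr.begin(), B, P, Cin, fWx, fWh, fb, false,
                 out.begin(), 0, B * P, cache->fwd);
  lstmDirForward(Xarr.begin(), B, P, Cin, bWx, bWh, bb, true,
                 out.begin(), H, B * P, cache->bwd);
  out.attr("dim") = IntegerVector::create(B, P, 2 * H);
  return List::create(_["out"] = out, _["cache"] = cache);
}

// [[Rcpp::export]]
List cpp_bilstm_bw(NumericVector dOut, SEXP cachePtr, const arma::mat &fWx,
                   const arma::mat &fWh, const arma::mat &bWx,
                   const arma::mat &bWh) {
  XPtr<BilstmCache> cache(cachePtr);
  const int B = cache->B, P = cache->P, Cin = cache->Cin, H = cache->H;
  NumericVector dX(B * P * Cin);
  arma::mat dfWx(arma::size(fWx), arma::fill::zeros),
    dfWh(arma::size(fWh), arma::fill::zeros),
    dbWx(arma::size(bWx), arma::fill::zeros),
    dbWh(arma::size(bWh), arma::fill::zeros);
  arma::vec dfb(4 * H, arma::fill::zeros), dbb(4 * H, arma::fill::zeros);
  lstmDirBackward(dOut.begin(), B, P, Cin, fWx, fWh, 0, B * P, cache->fwd,
                  dfWx, dfWh, dfb, dX.begin());
  lstmDirBackward(dOut.begin(), B, P, Cin, bWx, bWh, H, B * P, cache->bwd,
                  dbWx, dbWh, dbb, dX.begin());
  dX.attr("dim") = IntegerVector::create(B, P, Cin);
  return List::create(_["dX"] = dX, _["f_Wx"] = dfWx, _["f_Wh"] = dfWh,
                      _["f_b"] = dfb, _["b_Wx"] = dbWx, _["b_Wh"] = dbWh,
                      _["b_b"] = dbb);
}

// Batched TextCNN convolution for one kernel: Farr (B, P, Cin) in R array
// layout, W flat (F x Cin*k... passed as F, Cin, k dims), bias F. Computes
// the conv at the strided positions sel (1-based dense positions), applies
// ReLU implicitly via the later max (callers pool immediately), and
// returns the (B*Lout) x F activation matrix (position-major rows).
// [[Rcpp::export]]
NumericMatrix cpp_textcnn_conv(NumericVector Farr, IntegerVector fdim,
                               const arma::mat &Wflat, const arma::vec &b,
                               int k, IntegerVector sel) {
  const int B = fdim[0], P = fdim[1], Cin = fdim[2];
  const int F = Wflat.n_rows;
  const int Lout = sel.size();
  arma::mat G(B * Lout, Cin * k);
  const double *fp = Farr.begin();
  for (int j = 0; j < k; ++j)
    for (int ci = 0; ci < Cin; ++ci) {
      double *dst = G.colptr(j * Cin + ci);
      for (int t = 0; t < Lout; ++t) {
        const int tp = sel[t] - 1 + j;
        std::memcpy(dst + (size_t)t * B,
                    fp + (size_t)tp * B + (size_t)ci * B * P,
                    B * sizeof(double));
      }
    }
  arma::mat conv = G * Wflat.t();
  conv.each_row() += b.t();
  return wrap(conv);
}
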