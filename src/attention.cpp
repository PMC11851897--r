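// Window-local multi-head self-attention. The R side supplies the token
// QKV matrix plus precomputed window-partition indices (gather order,
// inverse permutation, shift/pad masks, relative-position index); these
// kernels perform the windowed gather, per-window per-head attention and
// the scatter back to token order, with the matching backward pass.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// QKV: (B*N) x 3C in token order. gidx: 1-based source row per windowed
// position (padding rows listed in pad, 1-based). inv: 1-based windowed
// row for each token. relTab: (2M-1)^2 x heads. rp: M2 x M2 1-based
// indices into relTab. maskCube: (M2, M2, nW) additive masks (may be a
// 1-slice zero cube when unused, flagged by useMask = false).
// [[Rcpp::export(name = ".cpp_wattn_fwd")]]
List cpp_wattn_fwd(const arma::mat& QKV, const arma::uvec& gidx,
                   const arma::uvec& pad, const arma::uvec& inv,
                   int M2, int C, int heads, int nW,
                   const arma::mat& relTab, const arma::umat& rp,
                   const arma::cube& maskCube, bool useMask,
                   double scale, bool keep) {
  const arma::uword nwin = gidx.n_elem;
  const int nSl = nwin / M2;
  const int dh = C / heads;
  arma::mat QKVw(nwin, 3 * C);
  for (arma::uword k = 0; k < nwin; ++k)
    QKVw.row(k) = QKV.row(gidx[k] - 1);
  for (arma::uword j = 0; j < pad.n_elem; ++j)
    QKVw.row(pad[j] - 1).zeros();

  // per-head relative position bias matrices
  std::vector<arma::mat> bias(heads, arma::mat(M2, M2));
  for (int h = 0; h < heads; ++h)
    for (int j = 0; j < M2; ++j)
      for (int i = 0; i < M2; ++i)
        bias[h](i, j) = relTab(rp(i, j) - 1, h);

  arma::mat O(nwin, C, arma::fill::zeros);
  arma::cube A;
  if (keep) A.set_size(M2, M2, (size_t)nSl * heads);
  for (int i = 0; i < nSl; ++i) {
    const int r0 = i * M2, r1 = (i + 1) * M2 - 1;
    const int w = i % nW;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dh, c1 = c0 + dh - 1;
      arma::mat S = QKVw.submat(r0, c0, r1, c1) *
        QKVw.submat(r0, C + c0, r1, C + c1).t() * scale + bias[h];
      if (useMask) S += maskCube.slice(w);
      arma::colvec mx = arma::max(S, 1);
      S.each_col() -= mx;
      S = arma::exp(S);
      arma::colvec rs = arma::sum(S, 1);
      S.each_col() /= rs;
      O.submat(r0, c0, r1, c1) = S *
        QKVw.submat(r0, 2 * C + c0, r1, 2 * C + c1);
      if (keep) A.slice((size_t)i * heads + h) = S;
    }
  }
  arma::mat attn(inv.n_elem, C);
  for (arma::uword t = 0; t < inv.n_elem; ++t)
    attn.row(t) = O.row(inv[t] - 1);
  if (keep)
    return List::create(Named("attn") = attn, Named("QKVw") = QKVw,
                        Named("A") = A);
  return List::create(Named("attn") = attn);
}

// [[Rcpp::export(name = ".cpp_wattn_bwd")]]
List cpp_wattn_bwd(const arma::mat& QKVw, const arma::cube& A,
                   const arma::mat& dAttn, const arma::uvec& gidx,
                   const arma::uvec& inv, int M2, int C, int heads,
                   const arma::umat& rp, int nTab, double scale) {
  const arma::uword nwin = gidx.n_elem;
  const int nSl = nwin / M2;
  const int dh = C / heads;
  arma::mat dO(nwin, C, arma::fill::zeros);
  for (arma::uword t = 0; t < inv.n_elem; ++t)
    dO.row(inv[t] - 1) = dAttn.row(t);

  arma::mat dQKVw(nwin, 3 * C, arma::fill::zeros);
  arma::mat dTab(nTab, heads, arma::fill::zeros);
  for (int i = 0; i < nSl; ++i) {
    const int r0 = i * M2, r1 = (i + 1) * M2 - 1;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dh, c1 = c0 + dh - 1;
      const arma::mat& Ah = A.slice((size_t)i * heads + h);
      arma::mat dOh = dO.submat(r0, c0, r1, c1);
      arma::mat dA = dOh *
        QKVw.submat(r0, 2 * C + c0, r1, 2 * C + c1).t();
      arma::colvec rs = arma::sum(dA % Ah, 1);
      arma::mat dS = Ah % (dA.each_col() - rs);
      for (int j = 0; j < M2; ++j)
        for (int ii = 0; ii < M2; ++ii)
          dTab(rp(ii, j) - 1, h) += dS(ii, j);
      dQKVw.submat(r0, c0, r1, c1) =
        dS * QKVw.submat(r0, C + c0, r1, C + c1) * scale;
      dQKVw.submat(r0, C + c0, r1, C + c1) =
        dS.t() * QKVw.submat(r0, c0, r1, c1) * scale;
      dQKVw.submat(r0, 2 * C + c0, r1, 2 * C + c1) = Ah.t() * dOh;
    }
  }
  // scatter windowed gradients back to token order (each real token
  // appears exactly once; padding rows are dropped)
  arma::mat dQKV(inv.n_elem, 3 * C);
  for (arma::uword t = 0; t < inv.n_elem; ++t)
    dQKV.row(t) = dQKVw.row(inv[t] - 1);
  return List::create(Named("dQKV") = dQKV, Named("dTab") = dTab);
}
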