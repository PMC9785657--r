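// FCN training core: 1-D conv blocks (same padding) + batch norm + ReLU,
// global average pooling, 2-way softmax head, Adam. All randomness
// (initial weights, minibatch orders) is drawn in R and passed in, so the
// compiled path is bit-deterministic given the R seed.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

// x: T x C -> T x (k*C), zero-padded "same"; column (ki*C + c)
mat im2col(const mat& x, int k) {
  const int T = x.n_rows, C = x.n_cols;
  const int pl = (k - 1) / 2;
  mat xp(T + k - 1, C, fill::zeros);
  xp.rows(pl, pl + T - 1) = x;
  mat out(T, k * C);
  for (int ki = 0; ki < k; ++ki)
    out.cols(ki * C, (ki + 1) * C - 1) = xp.rows(ki, ki + T - 1);
  return out;
}

mat col2im(const mat& dcol, int k, int C, int T) {
  const int pl = (k - 1) / 2;
  mat dxp(T + k - 1, C, fill::zeros);
  for (int ki = 0; ki < k; ++ki)
    dxp.rows(ki, ki + T - 1) += dcol.cols(ki * C, (ki + 1) * C - 1);
  return dxp.rows(pl, pl + T - 1);
}

// W cube (k, C, F) -> (k*C, F), row index ki*C + c
mat flatten_kernel(const cube& w) {
  const int k = w.n_rows, C = w.n_cols, F = w.n_slices;
  mat out(k * C, F);
  for (int f = 0; f < F; ++f)
    for (int ki = 0; ki < k; ++ki)
      for (int c = 0; c < C; ++c)
        out(ki * C + c, f) = w(ki, c, f);
  return out;
}

cube fold_kernel(const mat& g, int k, int C) {
  const int F = g.n_cols;
  cube out(k, C, F);
  for (int f = 0; f < F; ++f)
    for (int ki = 0; ki < k; ++ki)
      for (int c = 0; c < C; ++c)
        out(ki, c, f) = g(ki * C + c, f);
  return out;
}

struct AdamState {
  mat m, v;
  AdamState() {}
  explicit AdamState(const mat& p) : m(size(p), fill::zeros),
                                     v(size(p), fill::zeros) {}
};

void adam(mat& par, const mat& g, AdamState& st, double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  st.m = b1 * st.m + (1 - b1) * g;
  st.v = b2 * st.v + (1 - b2) * square(g);
  par -= lr * (st.m / (1 - std::pow(b1, t))) /
         (sqrt(st.v / (1 - std::pow(b2, t))) + eps);
}

} // namespace

// [[Rcpp::export(name = ".fcn_train_core")]]
Rcpp::List fcn_train_core(const arma::cube& X,        // T x C x n
                          const arma::ivec& labels,   // 0/1 per trial
                          const arma::ivec& lens,     // original lengths
                          Rcpp::List init,            // initial model params
                          const arma::imat& orders,   // epochs x n, 1-based
                          int batch_size, double lr,
                          double bn_eps, double bn_momentum,
                          bool masked_gap) {
  const int T = X.n_rows, n = X.n_slices;
  const int epochs = orders.n_rows;

  Rcpp::List blocks_in = init["blocks"];
  const int L = blocks_in.size();
  std::vector<cube> W(L);
  std::vector<mat> Wm(L);
  std::vector<rowvec> b(L), gamma(L), beta(L), rmean(L), rvar(L);
  std::vector<int> ks(L), cin(L);
  for (int l = 0; l < L; ++l) {
    Rcpp::List bl = blocks_in[l];
    W[l] = Rcpp::as<cube>(bl["W"]);
    ks[l] = W[l].n_rows; cin[l] = W[l].n_cols;
    b[l] = Rcpp::as<rowvec>(bl["b"]);
    gamma[l] = Rcpp::as<rowvec>(bl["gamma"]);
    beta[l] = Rcpp::as<rowvec>(bl["beta"]);
    rmean[l] = Rcpp::as<rowvec>(bl["mean"]);
    rvar[l] = Rcpp::as<rowvec>(bl["var"]);
  }
  Rcpp::List head = init["head"];
  mat headW = Rcpp::as<mat>(head["W"]);
  rowvec headb = Rcpp::as<rowvec>(head["b"]);
  const int F_last = headW.n_rows;

  // Adam states (vectors handled as 1-row mats)
  std::vector<AdamState> sW(L), sb(L), sg(L), sbe(L);
  for (int l = 0; l < L; ++l) {
    Wm[l] = flatten_kernel(W[l]);
    sW[l] = AdamState(Wm[l]);
    sb[l] = AdamState(mat(b[l])); sg[l] = AdamState(mat(gamma[l]));
    sbe[l] = AdamState(mat(beta[l]));
  }
  AdamState sHW(headW);
  AdamState sHb{mat(headb)};

  vec losses(epochs, fill::zeros);
  int tstep = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int bs = std::min(batch_size, n - start);
      uvec idx(bs);
      for (int i = 0; i < bs; ++i) idx[i] = orders(ep, start + i) - 1;

      // forward
      std::vector<mat> xcols(L), yhs(L);
      std::vector<rowvec> vs(L);
      std::vector<umat> masks(L);
      mat act(bs * T, cin[0]);
      for (int i = 0; i < bs; ++i)
        act.rows(i * T, (i + 1) * T - 1) = X.slice(idx[i]);

      for (int l = 0; l < L; ++l) {
        mat xcol(bs * T, ks[l] * cin[l]);
        for (int i = 0; i < bs; ++i)
          xcol.rows(i * T, (i + 1) * T - 1) =
            im2col(act.rows(i * T, (i + 1) * T - 1), ks[l]);
        mat y = xcol * Wm[l];
        y.each_row() += b[l];
        rowvec m = mean(y, 0);
        mat yc = y.each_row() - m;
        rowvec v = mean(square(yc), 0);
        rowvec isd = 1.0 / sqrt(v + bn_eps);
        mat yh = yc.each_row() % isd;
        mat z = yh.each_row() % gamma[l];
        z.each_row() += beta[l];
        umat mask = z > 0;
        act = z % mask;
        rmean[l] = bn_momentum * rmean[l] + (1 - bn_momentum) * m;
        rvar[l] = bn_momentum * rvar[l] + (1 - bn_momentum) * v;
        xcols[l] = std::move(xcol); yhs[l] = std::move(yh);
        vs[l] = v; masks[l] = std::move(mask);
      }

      mat g(bs, F_last);
      for (int i = 0; i < bs; ++i) {
        if (masked_gap) {
          int nl = std::min<int>(lens[idx[i]], T);
          g.row(i) = mean(act.rows(i * T, i * T + nl - 1), 0);
        } else {
          g.row(i) = mean(act.rows(i * T, (i + 1) * T - 1), 0);
        }
      }
      mat logits = g * headW;
      logits.each_row() += headb;
      vec mx = max(logits, 1);
      mat e = exp(logits.each_col() - mx);
      mat p = e.each_col() / sum(e, 1);
      for (int i = 0; i < bs; ++i)
        ep_loss -= std::log(std::max(p(i, labels[idx[i]]), 1e-12));

      // backward
      mat dlog = p;
      for (int i = 0; i < bs; ++i) dlog(i, labels[idx[i]]) -= 1.0;
      dlog /= bs;
      mat gHW = g.t() * dlog;
      rowvec gHb = sum(dlog, 0);
      mat dg = dlog * headW.t();

      mat dh(bs * T, F_last, fill::zeros);
      for (int i = 0; i < bs; ++i) {
        if (masked_gap) {
          int nl = std::min<int>(lens[idx[i]], T);
          dh.rows(i * T, i * T + nl - 1) = repmat(dg.row(i) / nl, nl, 1);
        } else {
          dh.rows(i * T, (i + 1) * T - 1) = repmat(dg.row(i) / T, T, 1);
        }
      }

      std::vector<mat> gWm(L);
      std::vector<rowvec> gb(L), gg(L), gbe(L);
      for (int l = L - 1; l >= 0; --l) {
        mat dz = dh % masks[l];
        gg[l] = sum(dz % yhs[l], 0);
        gbe[l] = sum(dz, 0);
        mat dyh = dz.each_row() % gamma[l];
        const double nn = dyh.n_rows;
        rowvec s1 = sum(dyh, 0);
        rowvec s2 = sum(dyh % yhs[l], 0);
        mat dy = nn * dyh;
        dy.each_row() -= s1;
        dy -= yhs[l].each_row() % s2;
        dy.each_row() /= (nn * sqrt(vs[l] + bn_eps));
        gWm[l] = xcols[l].t() * dy;
        gb[l] = sum(dy, 0);
        if (l > 0) {
          mat dxcol = dy * Wm[l].t();
          dh.set_size(bs * T, cin[l]);
          for (int i = 0; i < bs; ++i)
            dh.rows(i * T, (i + 1) * T - 1) =
              col2im(dxcol.rows(i * T, (i + 1) * T - 1), ks[l], cin[l], T);
        }
      }

      ++tstep;
      for (int l = 0; l < L; ++l) {
        adam(Wm[l], gWm[l], sW[l], lr, tstep);
        mat bm(b[l]), gm(gamma[l]), bem(beta[l]);
        adam(bm, mat(gb[l]), sb[l], lr, tstep); b[l] = bm.row(0);
        adam(gm, mat(gg[l]), sg[l], lr, tstep); gamma[l] = gm.row(0);
        adam(bem, mat(gbe[l]), sbe[l], lr, tstep); beta[l] = bem.row(0);
      }
      adam(headW, gHW, sHW, lr, tstep);
      mat hbm(headb);
      adam(hbm, mat(gHb), sHb, lr, tstep); headb = hbm.row(0);
    }
    losses[ep] = ep_loss / n;
  }

  Rcpp::List blocks_out(L);
  for (int l = 0; l < L; ++l) {
    blocks_out[l] = Rcpp::List::create(
      Rcpp::Named("W") = fold_kernel(Wm[l], ks[l], cin[l]),
      Rcpp::Named("b") = Rcpp::NumericVector(b[l].begin(), b[l].end()),
      Rcpp::Named("gamma") = Rcpp::NumericVector(gamma[l].begin(), gamma[l].end()),
      Rcpp::Named("beta") = Rcpp::NumericVector(beta[l].begin(), beta[l].end()),
      Rcpp::Named("mean") = Rcpp::NumericVector(rmean[l].begin(), rmean[l].end()),
      Rcpp::Named("var") = Rcpp::NumericVector(rvar[l].begin(), rvar[l].end()));
  }
  return Rcpp::List::create(
    Rcpp::Named("blocks") = blocks_out,
    Rcpp::Named("head") = Rcpp::List::create(
      Rcpp::Named("W") = headW,
      Rcpp::Named("b") = Rcpp::NumericVector(headb.begin(), headb.end())),
    Rcpp::Named("losses") = losses);
}
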