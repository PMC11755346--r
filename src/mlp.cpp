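// Two-tower MLP core: forward pass, backpropagation, Adam with uniform L2
// weight decay. Single precision: the training sets here are O(10^4) rows and
// float sgemm roughly doubles throughput; all results are returned as doubles.
//
// Layer convention (every tower): hidden layers ReLU, final layer linear.
// Dot fusion:    score = <sample_tower(x_s), drug_tower(x_d)>
// Concat fusion: score = post_tower([sample_tower(x_s), drug_tower(x_d)])
// The L2 penalty alpha * sum(W^2) covers all weight matrices, never biases.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::fmat;
using arma::frowvec;
using arma::fvec;
using arma::uvec;

namespace {

struct Tower {
  std::vector<fmat> W;     // (in x out) per layer
  std::vector<frowvec> b;  // (1 x out) per layer
  int size() const { return static_cast<int>(W.size()); }
};

Tower tower_from_list(Rcpp::List layers) {
  Tower tw;
  for (int i = 0; i < layers.size(); ++i) {
    Rcpp::List lay = layers[i];
    tw.W.push_back(arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(lay["W"])));
    tw.b.push_back(arma::conv_to<frowvec>::from(Rcpp::as<arma::rowvec>(lay["b"])));
  }
  return tw;
}

Rcpp::List tower_to_list(const Tower& tw) {
  Rcpp::List out(tw.size());
  for (int i = 0; i < tw.size(); ++i) {
    out[i] = Rcpp::List::create(
        Rcpp::Named("W") = arma::conv_to<arma::mat>::from(tw.W[i]),
        Rcpp::Named("b") = arma::conv_to<arma::rowvec>::from(tw.b[i]));
  }
  return out;
}

// Forward pass caching post-activation outputs of every layer.
fmat tower_forward(const fmat& X, const Tower& tw, std::vector<fmat>& acts) {
  acts.clear();
  const fmat* cur = &X;
  for (int l = 0; l < tw.size(); ++l) {
    fmat Z = (*cur) * tw.W[l];
    Z.each_row() += tw.b[l];
    if (l + 1 < tw.size()) Z = arma::clamp(Z, 0.0f, arma::Datum<float>::inf);
    acts.push_back(std::move(Z));
    cur = &acts.back();
  }
  return acts.back();
}

// Backpropagate dOut (gradient w.r.t. tower output) through the tower.
// Accumulates weight/bias gradients; returns gradient w.r.t. the input when
// want_dx is set (needed to split the concat gradient between the towers).
fmat tower_backward(const fmat& X, const Tower& tw, const std::vector<fmat>& acts,
                    fmat dOut, std::vector<fmat>& dW, std::vector<frowvec>& db,
                    bool want_dx) {
  const int L = tw.size();
  if (static_cast<int>(dW.size()) != L) {  // reuse buffers across batches
    dW.assign(L, fmat());
    db.assign(L, frowvec());
  }
  for (int l = L - 1; l >= 0; --l) {
    if (l < L - 1) {  // ReLU derivative via the cached post-activation
      dOut %= arma::conv_to<fmat>::from(acts[l] > 0.0f);
    }
    const fmat& Ain = (l == 0) ? X : acts[l - 1];
    dW[l] = Ain.t() * dOut;
    db[l] = arma::sum(dOut, 0);
    if (l > 0 || want_dx) dOut = dOut * tw.W[l].t();
  }
  return dOut;
}

fvec model_forward(const fmat& Xs, const fmat& Xd, const Tower& ts, const Tower& td,
                   const Tower& tp, bool dot, std::vector<fmat>& as,
                   std::vector<fmat>& ad, std::vector<fmat>& ap, fmat& cat) {
  fmat Vs = tower_forward(Xs, ts, as);
  fmat Vd = tower_forward(Xd, td, ad);
  if (dot) return arma::sum(Vs % Vd, 1);
  cat = arma::join_rows(Vs, Vd);
  fmat out = tower_forward(cat, tp, ap);
  return out.col(0);
}

double l2_penalty(const Tower& tw) {
  double s = 0.0;
  for (const fmat& W : tw.W) s += arma::accu(arma::square(W));
  return s;
}

// MSE + alpha * sum W^2 for one batch, with gradients for every parameter.
double loss_and_grads(const fmat& Xs, const fmat& Xd, const fvec& y, const Tower& ts,
                      const Tower& td, const Tower& tp, bool dot, double alpha,
                      std::vector<fmat>& dWs, std::vector<frowvec>& dbs,
                      std::vector<fmat>& dWd, std::vector<frowvec>& dbd,
                      std::vector<fmat>& dWp, std::vector<frowvec>& dbp,
                      double* mse_out) {
  std::vector<fmat> as, ad, ap;
  fmat cat;
  fvec pred = model_forward(Xs, Xd, ts, td, tp, dot, as, ad, ap, cat);
  const float n = static_cast<float>(y.n_elem);
  fvec resid = pred - y;
  double mse = arma::dot(resid, resid) / n;
  if (mse_out) *mse_out = mse;

  fmat g = resid * (2.0f / n);  // d(MSE)/d(pred), n x 1
  fmat dVs, dVd;
  if (dot) {
    const fmat& Vs = as.back();
    const fmat& Vd = ad.back();
    dVs = Vd.each_col() % g.col(0);
    dVd = Vs.each_col() % g.col(0);
    dWp.clear();
    dbp.clear();
  } else {
    fmat dCat = tower_backward(cat, tp, ap, g, dWp, dbp, true);
    const arma::uword ks = as.back().n_cols;
    dVs = dCat.cols(0, ks - 1);
    dVd = dCat.cols(ks, dCat.n_cols - 1);
  }
  tower_backward(Xs, ts, as, dVs, dWs, dbs, false);
  tower_backward(Xd, td, ad, dVd, dWd, dbd, false);

  double pen = 0.0;
  if (alpha > 0.0) {
    const float a2 = static_cast<float>(2.0 * alpha);
    for (int l = 0; l < ts.size(); ++l) dWs[l] += a2 * ts.W[l];
    for (int l = 0; l < td.size(); ++l) dWd[l] += a2 * td.W[l];
    for (int l = 0; l < tp.size(); ++l) dWp[l] += a2 * tp.W[l];
    pen = alpha * (l2_penalty(ts) + l2_penalty(td) + l2_penalty(tp));
  }
  return mse + pen;
}

struct AdamState {
  std::vector<fmat> mW, vW;
  std::vector<fmat> mb, vb;  // biases kept as fmat(1, k) for uniform code
  void init(const Tower& tw) {
    for (int l = 0; l < tw.size(); ++l) {
      mW.push_back(arma::zeros<fmat>(arma::size(tw.W[l])));
      vW.push_back(arma::zeros<fmat>(arma::size(tw.W[l])));
      mb.push_back(arma::zeros<fmat>(1, tw.b[l].n_elem));
      vb.push_back(arma::zeros<fmat>(1, tw.b[l].n_elem));
    }
  }
};

void adam_step(fmat& param, const fmat& grad, fmat& m, fmat& v, float lr_t,
               float beta1, float beta2, float eps) {
  m = beta1 * m + (1.0f - beta1) * grad;
  v = beta2 * v + (1.0f - beta2) * arma::square(grad);
  param -= lr_t * m / (arma::sqrt(v) + eps);
}

void adam_update(Tower& tw, const std::vector<fmat>& dW, const std::vector<frowvec>& db,
                 AdamState& st, float lr_t, float beta1, float beta2, float eps) {
  for (int l = 0; l < tw.size(); ++l) {
    adam_step(tw.W[l], dW[l], st.mW[l], st.vW[l], lr_t, beta1, beta2, eps);
    fmat gb(db[l]);
    fmat bmat(tw.b[l]);
    adam_step(bmat, gb, st.mb[l], st.vb[l], lr_t, beta1, beta2, eps);
    tw.b[l] = bmat.row(0);
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List mlp_train_cpp(const arma::mat& Xs, const arma::mat& Xd, const arma::vec& y,
                         Rcpp::List sample_layers, Rcpp::List drug_layers,
                         Rcpp::List post_layers, bool dot, double alpha, double lr,
                         int epochs, int batch_size, const arma::imat& order,
                         const arma::mat& Xs_val, const arma::mat& Xd_val,
                         const arma::vec& y_val, double beta1 = 0.9,
                         double beta2 = 0.999, double eps = 1e-7) {
  // Transposed copies: a minibatch is then a set of contiguous columns, and
  // the per-batch gather is cache-friendly (row gathers from a column-major
  // matrix dominate the epoch time otherwise).
  fmat fXsT = arma::conv_to<fmat>::from(Xs.t());
  fmat fXdT = arma::conv_to<fmat>::from(Xd.t());
  fvec fy = arma::conv_to<fvec>::from(y);
  const bool has_val = Xs_val.n_rows > 0;
  fmat fXs_val, fXd_val;
  fvec fy_val;
  if (has_val) {
    fXs_val = arma::conv_to<fmat>::from(Xs_val);
    fXd_val = arma::conv_to<fmat>::from(Xd_val);
    fy_val = arma::conv_to<fvec>::from(y_val);
  }

  Tower ts = tower_from_list(sample_layers);
  Tower td = tower_from_list(drug_layers);
  Tower tp = tower_from_list(post_layers);
  AdamState ss, sd, sp;
  ss.init(ts);
  sd.init(td);
  sp.init(tp);

  const arma::uword n = fXsT.n_cols;
  const float b1 = static_cast<float>(beta1), b2 = static_cast<float>(beta2),
              ep = static_cast<float>(eps);
  arma::mat history(epochs, 2);
  history.fill(arma::datum::nan);
  std::vector<fmat> dWs, dWd, dWp;
  std::vector<frowvec> dbs, dbd, dbp;
  long step = 0;

  for (int e = 0; e < epochs; ++e) {
    double sse = 0.0;
    for (arma::uword start = 0; start < n; start += batch_size) {
      const arma::uword stop = std::min(n - 1, start + batch_size - 1);
      uvec idx(stop - start + 1);
      for (arma::uword i = start; i <= stop; ++i)
        idx[i - start] = static_cast<arma::uword>(order(i, e));
      fmat bXs = fXsT.cols(idx).t();
      fmat bXd = fXdT.cols(idx).t();
      fvec by = fy.elem(idx);
      double mse = 0.0;
      loss_and_grads(bXs, bXd, by, ts, td, tp, dot, alpha, dWs, dbs, dWd, dbd, dWp,
                     dbp, &mse);
      sse += mse * by.n_elem;
      ++step;
      const float lr_t = static_cast<float>(
          lr * std::sqrt(1.0 - std::pow(beta2, step)) / (1.0 - std::pow(beta1, step)));
      adam_update(ts, dWs, dbs, ss, lr_t, b1, b2, ep);
      adam_update(td, dWd, dbd, sd, lr_t, b1, b2, ep);
      if (!dot) adam_update(tp, dWp, dbp, sp, lr_t, b1, b2, ep);
    }
    const double epoch_mse = sse / n;
    if (!std::isfinite(epoch_mse)) {
      Rcpp::stop("training diverged (non-finite loss at epoch %d); reduce learning_rate",
                 e + 1);
    }
    history(e, 0) = epoch_mse;
    if (has_val) {
      std::vector<fmat> as, ad, ap;
      fmat cat;
      fvec pv = model_forward(fXs_val, fXd_val, ts, td, tp, dot, as, ad, ap, cat);
      fvec r = pv - fy_val;
      history(e, 1) = arma::dot(r, r) / r.n_elem;
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(Rcpp::Named("sample") = tower_to_list(ts),
                            Rcpp::Named("drug") = tower_to_list(td),
                            Rcpp::Named("post") = tower_to_list(tp),
                            Rcpp::Named("history") = history);
}

// [[Rcpp::export]]
arma::vec mlp_predict_cpp(const arma::mat& Xs, const arma::mat& Xd,
                          Rcpp::List sample_layers, Rcpp::List drug_layers,
                          Rcpp::List post_layers, bool dot) {
  Tower ts = tower_from_list(sample_layers);
  Tower td = tower_from_list(drug_layers);
  Tower tp = tower_from_list(post_layers);
  if (Xs.n_rows == 0) return arma::vec();
  std::vector<fmat> as, ad, ap;
  fmat cat;
  fvec pred = model_forward(arma::conv_to<fmat>::from(Xs), arma::conv_to<fmat>::from(Xd),
                            ts, td, tp, dot, as, ad, ap, cat);
  return arma::conv_to<arma::vec>::from(pred);
}

// Full-batch penalized loss and exact gradients; used by the gradient-check
// tests against numerical differentiation.
// [[Rcpp::export]]
Rcpp::List mlp_loss_grad_cpp(const arma::mat& Xs, const arma::mat& Xd,
                             const arma::vec& y, Rcpp::List sample_layers,
                             Rcpp::List drug_layers, Rcpp::List post_layers, bool dot,
                             double alpha) {
  Tower ts = tower_from_list(sample_layers);
  Tower td = tower_from_list(drug_layers);
  Tower tp = tower_from_list(post_layers);
  std::vector<fmat> dWs, dWd, dWp;
  std::vector<frowvec> dbs, dbd, dbp;
  double loss = loss_and_grads(arma::conv_to<fmat>::from(Xs),
                               arma::conv_to<fmat>::from(Xd),
                               arma::conv_to<fvec>::from(y), ts, td, tp, dot, alpha,
                               dWs, dbs, dWd, dbd, dWp, dbp, nullptr);
  Tower gs{dWs, {}}, gd{dWd, {}}, gp{dWp, {}};
  for (auto& v : dbs) gs.b.push_back(v);
  for (auto& v : dbd) gd.b.push_back(v);
  for (auto& v : dbp) gp.b.push_back(v);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("sample") = tower_to_list(gs),
                            Rcpp::Named("drug") = tower_to_list(gd),
                            Rcpp::Named("post") = tower_to_list(gp));
}
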