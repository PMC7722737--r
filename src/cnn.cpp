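// Training loop of the dual-output convolutional classifier.
//
// Layout contract (shared with the R reference implementation): the im2col
// matrix has one row per (sample, position) with position fastest within a
// sample; pooling/flattening reshapes rely on it. All randomness (epoch
// shuffles, dropout masks) is drawn from R's RNG so set.seed() governs the
// whole run, and the R forward/backward in R/model.R serves as the oracle.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void elu_ip(arma::mat& z) {
  z.transform([](double v) { return v > 0 ? v : std::expm1(v); });
}

// given pre-activation z and a = elu(z), overwrite z with elu'(z)
static inline void elu_grad_ip(arma::mat& z, const arma::mat& a) {
  for (arma::uword i = 0; i < z.n_elem; ++i) z[i] = z[i] > 0 ? 1.0 : a[i] + 1.0;
}

static double focal_elem(double p, double y, double gamma, double alpha) {
  const double eps = 1e-7;
  p = std::min(std::max(p, eps), 1 - eps);
  double pt = y == 1 ? p : 1 - p;
  double at = y == 1 ? alpha : 1 - alpha;
  return -at * std::pow(1 - pt, gamma) * std::log(pt);
}

static double focal_grad_elem(double p, double y, double gamma, double alpha) {
  const double eps = 1e-7;
  p = std::min(std::max(p, eps), 1 - eps);
  if (y == 1) {
    return alpha * (gamma * std::pow(1 - p, gamma - 1) * std::log(p) -
                    std::pow(1 - p, gamma) / p);
  }
  return (1 - alpha) * (-gamma * std::pow(p, gamma - 1) * std::log(1 - p) +
                        std::pow(p, gamma) / (1 - p));
}

struct Params {
  arma::mat Wc, Wd, Wo;
  arma::rowvec bc, bd, bo;
};

struct Adam {
  Params m, v;
  long t = 0;
  static Params zeros_like(const Params& p) {
    Params z;
    z.Wc.zeros(arma::size(p.Wc)); z.Wd.zeros(arma::size(p.Wd)); z.Wo.zeros(arma::size(p.Wo));
    z.bc.zeros(p.bc.n_elem); z.bd.zeros(p.bd.n_elem); z.bo.zeros(p.bo.n_elem);
    return z;
  }
};

template <typename T>
static void adam_one(T& w, const T& g, T& m, T& v, double lr, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  const double c1 = 1 - std::pow(b1, (double) t), c2 = 1 - std::pow(b2, (double) t);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}

// forward pass without dropout; returns P3 (B x 2)
static arma::mat fwd_eval(const arma::mat& C1, const Params& w, int Lc, int ps,
                          int nf) {
  const int B = C1.n_rows / Lc, W = Lc / ps;
  arma::mat Z1 = C1 * w.Wc;
  Z1.each_row() += w.bc;
  elu_ip(Z1);
  arma::mat P(W * B, nf);
  for (int f = 0; f < nf; ++f) {
    arma::mat V(const_cast<double*>(Z1.colptr(f)), ps, (arma::uword) B * W, false, true);
    P.col(f) = arma::mean(V, 0).t();
  }
  arma::mat Fm(B, (arma::uword) W * nf);
  for (int f = 0; f < nf; ++f) {
    arma::mat slab(P.colptr(f), W, B, false, true);
    Fm.cols((arma::uword) f * W, (arma::uword) f * W + W - 1) = slab.t();
  }
  arma::mat Z2 = Fm * w.Wd;
  Z2.each_row() += w.bd;
  elu_ip(Z2);
  arma::mat Z3 = Z2 * w.Wo;
  Z3.each_row() += w.bo;
  return 1.0 / (1.0 + arma::exp(-Z3));
}

static double focal_mean(const arma::mat& P3, const arma::mat& Y, double gamma,
                         double alpha) {
  double s = 0;
  for (arma::uword i = 0; i < P3.n_elem; ++i) {
    s += focal_elem(P3[i], Y[i], gamma, alpha);
  }
  return s / P3.n_elem;
}

// [[Rcpp::export]]
List cnn_train_cpp(const arma::mat& C1_all, const arma::mat& targets,
                   Nullable<NumericMatrix> val_C1_, Nullable<NumericMatrix> val_targets_,
                   List weights0, int conv_out, int pool_size, int conv_filters,
                   double conv_dropout, double dense_dropout,
                   double gamma, double alpha, double lr0, double lr_decay,
                   bool l2_mode, int batch_size, int n_epochs, int patience,
                   bool early_stop) {
  const int Lc = conv_out, ps = pool_size, nf = conv_filters, W = Lc / ps;
  const int n = targets.n_rows;
  Params w;
  w.Wc = as<arma::mat>(weights0["Wc"]); w.bc = as<arma::rowvec>(weights0["bc"]);
  w.Wd = as<arma::mat>(weights0["Wd"]); w.bd = as<arma::rowvec>(weights0["bd"]);
  w.Wo = as<arma::mat>(weights0["Wo"]); w.bo = as<arma::rowvec>(weights0["bo"]);
  Adam ad;
  ad.m = Adam::zeros_like(w);
  ad.v = Adam::zeros_like(w);

  arma::mat valC1, valY;
  bool has_val = val_C1_.isNotNull();
  if (has_val) {
    valC1 = as<arma::mat>(val_C1_.get());
    valY = as<arma::mat>(val_targets_.get());
  }

  std::vector<double> train_log, val_log;
  double best_val = R_PosInf;
  Params best_w = w;
  int wait = 0;

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    const double lr = l2_mode ? lr0 : lr0 / (1 + lr_decay * (epoch - 1));
    IntegerVector perm = Rcpp::sample(n, n, false); // R RNG, 1-based
    double loss_sum = 0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int bs = std::min(batch_size, n - start);
      arma::uvec rows((arma::uword) bs * Lc);
      arma::mat Y(bs, targets.n_cols);
      for (int b = 0; b < bs; ++b) {
        const int s = perm[start + b] - 1;
        for (int l = 0; l < Lc; ++l) rows[(arma::uword) b * Lc + l] = (arma::uword) s * Lc + l;
        Y.row(b) = targets.row(s);
      }
      arma::mat C1 = C1_all.rows(rows);

      // forward with dropout
      arma::mat Z1 = C1 * w.Wc;
      Z1.each_row() += w.bc;
      arma::mat A1 = Z1;
      elu_ip(A1);
      arma::mat P((arma::uword) W * bs, nf);
      for (int f = 0; f < nf; ++f) {
        arma::mat V(A1.colptr(f), ps, (arma::uword) bs * W, false, true);
        P.col(f) = arma::mean(V, 0).t();
      }
      arma::mat mask1;
      if (conv_dropout > 0) {
        NumericVector u = Rcpp::runif(P.n_elem);
        mask1.set_size(arma::size(P));
        for (arma::uword i = 0; i < P.n_elem; ++i) {
          mask1[i] = u[i] >= conv_dropout ? 1.0 / (1 - conv_dropout) : 0.0;
        }
        P %= mask1;
      }
      arma::mat Fm(bs, (arma::uword) W * nf);
      for (int f = 0; f < nf; ++f) {
        arma::mat slab(P.colptr(f), W, bs, false, true);
        Fm.cols((arma::uword) f * W, (arma::uword) f * W + W - 1) = slab.t();
      }
      arma::mat Z2 = Fm * w.Wd;
      Z2.each_row() += w.bd;
      arma::mat A2 = Z2;
      elu_ip(A2);
      arma::mat mask2, D2 = A2;
      if (dense_dropout > 0) {
        NumericVector u = Rcpp::runif(A2.n_elem);
        mask2.set_size(arma::size(A2));
        for (arma::uword i = 0; i < A2.n_elem; ++i) {
          mask2[i] = u[i] >= dense_dropout ? 1.0 / (1 - dense_dropout) : 0.0;
        }
        D2 %= mask2;
      }
      arma::mat Z3 = D2 * w.Wo;
      Z3.each_row() += w.bo;
      arma::mat P3 = 1.0 / (1.0 + arma::exp(-Z3));

      loss_sum += focal_mean(P3, Y, gamma, alpha);
      ++n_batches;

      // backward
      arma::mat dZ3(arma::size(P3));
      for (arma::uword i = 0; i < P3.n_elem; ++i) {
        dZ3[i] = focal_grad_elem(P3[i], Y[i], gamma, alpha) / P3.n_elem *
                 P3[i] * (1 - P3[i]);
      }
      arma::mat gWo = D2.t() * dZ3;
      arma::rowvec gbo = arma::sum(dZ3, 0);
      arma::mat dD2 = dZ3 * w.Wo.t();
      if (dense_dropout > 0) dD2 %= mask2;
      elu_grad_ip(Z2, A2);          // Z2 now holds elu'(Z2)
      arma::mat dZ2 = dD2 % Z2;
      arma::mat gWd = Fm.t() * dZ2;
      arma::rowvec gbd = arma::sum(dZ2, 0);
      arma::mat dF = dZ2 * w.Wd.t();
      arma::mat dP((arma::uword) W * bs, nf);
      for (int f = 0; f < nf; ++f) {
        arma::mat slab = dF.cols((arma::uword) f * W, (arma::uword) f * W + W - 1).t();
        dP.col(f) = arma::vectorise(slab);
      }
      if (conv_dropout > 0) dP %= mask1;
      dP /= ps;
      arma::mat dA1(arma::size(A1));
      for (int f = 0; f < nf; ++f) {
        arma::mat V(dA1.colptr(f), ps, (arma::uword) bs * W, false, true);
        V.each_row() = dP.col(f).t();
      }
      elu_grad_ip(Z1, A1);          // Z1 now holds elu'(Z1)
      dA1 %= Z1;
      arma::mat gWc = C1.t() * dA1;
      arma::rowvec gbc = arma::sum(dA1, 0);

      if (l2_mode) {
        gWc += lr_decay * w.Wc;
        gWd += lr_decay * w.Wd;
        gWo += lr_decay * w.Wo;
      }
      ++ad.t;
      adam_one(w.Wc, gWc, ad.m.Wc, ad.v.Wc, lr, ad.t);
      adam_one(w.bc, gbc, ad.m.bc, ad.v.bc, lr, ad.t);
      adam_one(w.Wd, gWd, ad.m.Wd, ad.v.Wd, lr, ad.t);
      adam_one(w.bd, gbd, ad.m.bd, ad.v.bd, lr, ad.t);
      adam_one(w.Wo, gWo, ad.m.Wo, ad.v.Wo, lr, ad.t);
      adam_one(w.bo, gbo, ad.m.bo, ad.v.bo, lr, ad.t);
    }
    const double train_loss = loss_sum / n_batches;
    if (!std::isfinite(train_loss)) {
      stop("training diverged (non-finite loss) at epoch %d", epoch);
    }
    train_log.push_back(train_loss);
    if (has_val) {
      arma::mat vp = fwd_eval(valC1, w, Lc, ps, nf);
      double vl = focal_mean(vp, valY, gamma, alpha);
      val_log.push_back(vl);
      if (early_stop) {
        if (vl < best_val) {
          best_val = vl;
          best_w = w;
          wait = 0;
        } else if (++wait > patience) break;
      }
    }
    if (epoch % 8 == 0) Rcpp::checkUserInterrupt();
  }

  const Params& fin = (has_val && early_stop) ? best_w : w;
  return List::create(
    _["weights"] = List::create(
      _["Wc"] = fin.Wc, _["bc"] = NumericVector(fin.bc.begin(), fin.bc.end()),
      _["Wd"] = fin.Wd, _["bd"] = NumericVector(fin.bd.begin(), fin.bd.end()),
      _["Wo"] = fin.Wo, _["bo"] = NumericVector(fin.bo.begin(), fin.bo.end())),
    _["train_loss"] = train_log, _["val_loss"] = val_log);
}
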