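// 1D convolutional classifier: conv(linear) -> ReLU -> max-pool ->
// dropout -> flatten -> dense(2) -> softmax, trained with mini-batch
// adadelta under a per-filter max-norm constraint.  Single-threaded;
// all randomness (batch order, dropout masks) comes from one mt19937
// stream seeded by the caller.
//
// Internal layouts are chosen for contiguous access: activations are
// kept feature-major (flat x batch); ReLU commutes with max, so pooling
// runs on the linear convolution output and rectifies the pooled value.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Adadelta {
  arma::mat Eg2, Edx2;
  double rho, eps;
  Adadelta(arma::uword r, arma::uword c, double rho_, double eps_)
      : Eg2(r, c, arma::fill::zeros), Edx2(r, c, arma::fill::zeros),
        rho(rho_), eps(eps_) {}
  void step(arma::mat &param, const arma::mat &grad) {
    Eg2 = rho * Eg2 + (1.0 - rho) * arma::square(grad);
    arma::mat dx = -arma::sqrt(Edx2 + eps) / arma::sqrt(Eg2 + eps) % grad;
    Edx2 = rho * Edx2 + (1.0 - rho) * arma::square(dx);
    param += dx;
  }
};

struct Shapes {
  int d, kernel, F, conv_len, pool_size, pool_stride, pool_len, flat;
};

// XbT: d x B (one column per sample).  Fills cols (conv_len*B x kernel),
// conv = cols * Wc.t(), then pools with ReLU fused and bias added.
// pooledT: flat x B with flat index f*pool_len + p; argmax stores the
// winning conv position, or -1 when the rectified maximum is zero.
static void forward_batch(const arma::mat &XbT, const arma::mat &Wc,
                          const arma::vec &bc, const Shapes &sh,
                          arma::mat &cols, arma::mat &conv,
                          arma::mat &pooledT, arma::imat &argmax) {
  const int B = XbT.n_cols;
  cols.set_size(sh.conv_len * B, sh.kernel);
  for (int j = 0; j < sh.kernel; ++j) {
    double *cp = cols.colptr(j);
    for (int b = 0; b < B; ++b) {
      const double *xp = XbT.colptr(b) + j;
      std::memcpy(cp + b * sh.conv_len, xp, sh.conv_len * sizeof(double));
    }
  }
  conv = cols * Wc.t();                       // (conv_len*B) x F, linear

  pooledT.set_size(sh.flat, B);
  argmax.set_size(sh.flat, B);
  for (int f = 0; f < sh.F; ++f) {
    const double *cf = conv.colptr(f);
    const double bias = bc[f];
    for (int b = 0; b < B; ++b) {
      const double *base = cf + b * sh.conv_len;
      double *out = pooledT.colptr(b) + f * sh.pool_len;
      arma::sword *am = argmax.colptr(b) + f * sh.pool_len;
      for (int p = 0; p < sh.pool_len; ++p) {
        const int start = p * sh.pool_stride;
        double best = base[start];
        int best_i = start;
        for (int q = 1; q < sh.pool_size && start + q < sh.conv_len; ++q) {
          if (base[start + q] > best) { best = base[start + q]; best_i = start + q; }
        }
        const double act = best + bias;
        if (act > 0.0) { out[p] = act; am[p] = best_i; }
        else           { out[p] = 0.0; am[p] = -1; }
      }
    }
  }
}

static void softmax_cols(arma::mat &logits) {
  for (arma::uword b = 0; b < logits.n_cols; ++b) {
    arma::vec c = logits.col(b);
    c -= c.max();
    c = arma::exp(c);
    logits.col(b) = c / arma::accu(c);
  }
}

// [[Rcpp::export]]
List cnn_train_cpp(const arma::mat &X, const arma::ivec &y, arma::mat Wc,
                   arma::vec bc, arma::mat Wd, arma::vec bd, int n_filters,
                   int kernel, int pool_size, int pool_stride, double dropout,
                   double max_norm, int batch_size, int epochs, double rho,
                   double eps, int seed) {
  const int n = X.n_rows;
  Shapes sh;
  sh.d = X.n_cols;
  sh.kernel = kernel;
  sh.F = n_filters;
  sh.conv_len = sh.d - kernel + 1;
  sh.pool_size = pool_size;
  sh.pool_stride = pool_stride;
  sh.pool_len = (sh.conv_len - pool_size) / pool_stride + 1;
  sh.flat = sh.F * sh.pool_len;
  const int K = Wd.n_cols;
  const double keep = 1.0 - dropout;

  std::mt19937 rng(static_cast<unsigned>(seed));
  const std::uint32_t keep_thresh =
      static_cast<std::uint32_t>(keep * 4294967295.0);

  Adadelta opt_Wc(Wc.n_rows, Wc.n_cols, rho, eps);
  Adadelta opt_bc(bc.n_elem, 1, rho, eps);
  Adadelta opt_Wd(Wd.n_rows, Wd.n_cols, rho, eps);
  Adadelta opt_bd(bd.n_elem, 1, rho, eps);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector loss(epochs);
  arma::mat cols, conv, pooledT, XbT;
  arma::imat argmax;
  bool ok = true;
  int bad_epoch = -1;

  for (int ep = 0; ep < epochs && ok; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int B = std::min(batch_size, n - start);
      XbT.set_size(sh.d, B);
      arma::ivec yb(B);
      for (int b = 0; b < B; ++b) {
        const int i = order[start + b];
        for (int j = 0; j < sh.d; ++j) XbT(j, b) = X(i, j);
        yb[b] = y[i];
      }
      forward_batch(XbT, Wc, bc, sh, cols, conv, pooledT, argmax);

      // inverted dropout on the flattened activations (train time only)
      arma::mat droppedT = pooledT;
      if (dropout > 0.0) {
        const double scale = 1.0 / keep;
        double *dp = droppedT.memptr();
        const arma::uword nel = droppedT.n_elem;
        for (arma::uword t = 0; t < nel; ++t)
          dp[t] = (rng() < keep_thresh) ? dp[t] * scale : 0.0;
      }

      arma::mat logits = Wd.t() * droppedT;   // K x B
      logits.each_col() += bd;
      softmax_cols(logits);

      arma::mat glogits = logits;             // becomes dL/dlogits (mean CE)
      for (int b = 0; b < B; ++b) {
        ep_loss += -std::log(std::max(logits(yb[b], b), 1e-300)) / n;
        glogits(yb[b], b) -= 1.0;
      }
      glogits /= B;

      arma::mat gWd = droppedT * glogits.t();          // flat x K
      arma::vec gbd = arma::sum(glogits, 1);
      arma::mat gdropT = Wd * glogits;                 // flat x B
      // dropout gate: zeroed activations carried no gradient
      if (dropout > 0.0) {
        const double *dp = droppedT.memptr();
        double *gp = gdropT.memptr();
        const arma::uword nel = gdropT.n_elem;
        const double scale = 1.0 / keep;
        for (arma::uword t = 0; t < nel; ++t)
          gp[t] = (dp[t] != 0.0) ? gp[t] * scale : 0.0;
      }

      // backward through pool+ReLU: scatter into dWc/gbc at the argmax
      arma::mat gWc(sh.F, sh.kernel, arma::fill::zeros);
      arma::vec gbc(sh.F, arma::fill::zeros);
      for (int b = 0; b < B; ++b) {
        const double *gcol = gdropT.colptr(b);
        const arma::sword *acol = argmax.colptr(b);
        const double *xcol = XbT.colptr(b);
        for (int f = 0; f < sh.F; ++f) {
          double acc_b = 0.0;
          double acc0 = 0.0, acc1 = 0.0, acc2 = 0.0;  // kernel = 3 fast path
          const int off = f * sh.pool_len;
          for (int p = 0; p < sh.pool_len; ++p) {
            const double g = gcol[off + p];
            const arma::sword pos = acol[off + p];
            if (g != 0.0 && pos >= 0) {
              acc_b += g;
              if (sh.kernel == 3) {
                acc0 += g * xcol[pos];
                acc1 += g * xcol[pos + 1];
                acc2 += g * xcol[pos + 2];
              } else {
                for (int j = 0; j < sh.kernel; ++j)
                  gWc(f, j) += g * xcol[pos + j];
              }
            }
          }
          gbc[f] += acc_b;
          if (sh.kernel == 3) {
            gWc(f, 0) += acc0; gWc(f, 1) += acc1; gWc(f, 2) += acc2;
          }
        }
      }

      opt_Wc.step(Wc, gWc);
      arma::mat bc_m(bc.memptr(), bc.n_elem, 1, false, true);
      opt_bc.step(bc_m, arma::mat(gbc.memptr(), gbc.n_elem, 1, false, true));
      opt_Wd.step(Wd, gWd);
      arma::mat bd_m(bd.memptr(), bd.n_elem, 1, false, true);
      opt_bd.step(bd_m, arma::mat(gbd.memptr(), gbd.n_elem, 1, false, true));

      // max-norm constraint on each convolution filter's kernel vector
      for (int f = 0; f < sh.F; ++f) {
        const double nrm = arma::norm(Wc.row(f), 2);
        if (nrm > max_norm) Wc.row(f) *= max_norm / nrm;
      }
    }
    loss[ep] = ep_loss;
    if (!std::isfinite(ep_loss)) { ok = false; bad_epoch = ep + 1; }
  }

  return List::create(_["Wc"] = Wc, _["bc"] = bc, _["Wd"] = Wd, _["bd"] = bd,
                      _["loss"] = loss, _["ok"] = ok, _["epoch"] = bad_epoch);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(const arma::mat &X, const arma::mat &Wc,
                          const arma::vec &bc, const arma::mat &Wd,
                          const arma::vec &bd, int n_filters, int kernel,
                          int pool_size, int pool_stride) {
  const int n = X.n_rows;
  Shapes sh;
  sh.d = X.n_cols;
  sh.kernel = kernel;
  sh.F = n_filters;
  sh.conv_len = sh.d - kernel + 1;
  sh.pool_size = pool_size;
  sh.pool_stride = pool_stride;
  sh.pool_len = (sh.conv_len - pool_size) / pool_stride + 1;
  sh.flat = sh.F * sh.pool_len;

  const int batch = 256;
  arma::mat out(n, Wd.n_cols);
  arma::mat cols, conv, pooledT, XbT;
  arma::imat argmax;
  for (int start = 0; start < n; start += batch) {
    const int B = std::min(batch, n - start);
    XbT.set_size(sh.d, B);
    for (int b = 0; b < B; ++b)
      for (int j = 0; j < sh.d; ++j) XbT(j, b) = X(start + b, j);
    forward_batch(XbT, Wc, bc, sh, cols, conv, pooledT, argmax);
    arma::mat logits = Wd.t() * pooledT;  // dropout is the identity here
    logits.each_col() += bd;
    softmax_cols(logits);
    out.rows(start, start + B - 1) = logits.t();
  }
  return out;
}
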