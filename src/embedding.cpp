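// Subword-aware embedding trainers.  All objectives are single-threaded
// and driven by a private mt19937 stream so runs are bit-reproducible.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

static arma::mat init_input(int n_rows, int dim, std::mt19937 &rng) {
  std::uniform_real_distribution<double> unif(-1.0 / std::sqrt((double)dim), 1.0 / std::sqrt((double)dim));
  arma::mat m(n_rows, dim);
  for (int i = 0; i < n_rows; ++i)
    for (int j = 0; j < dim; ++j) m(i, j) = unif(rng);
  return m;
}

// Supervised: predict the sentence class from the weighted average of its
// gram vectors; exact softmax over classes, linearly decaying SGD.
// Vectors are kept column-per-token internally (contiguous updates) and
// transposed on return.
// [[Rcpp::export]]
List ft_supervised(List bag_ids, List bag_w, IntegerVector y,
                   int n_grams, int n_classes, int dim,
                   double lr0, int epochs, int seed) {
  const int n_sent = bag_ids.size();
  std::mt19937 rng(static_cast<unsigned>(seed));
  arma::mat input = init_input(n_grams, dim, rng).t();   // dim x n_grams
  arma::mat output(dim, n_classes, arma::fill::zeros);
  NumericVector loss(epochs);

  std::vector<std::vector<int>> ids(n_sent);
  std::vector<std::vector<double>> w(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    ids[s] = as<std::vector<int>>(bag_ids[s]);
    w[s] = as<std::vector<double>>(bag_w[s]);
  }

  std::vector<int> order(n_sent);
  for (int s = 0; s < n_sent; ++s) order[s] = s;

  const double total = static_cast<double>(epochs) * n_sent;
  double seen = 0.0;
  arma::vec h(dim), p(n_classes), grad_h(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    for (int si = 0; si < n_sent; ++si) {
      const int s = order[si];
      const double lr = lr0 * (1.0 - seen / total);
      seen += 1.0;
      const std::vector<int> &gi = ids[s];
      const std::vector<double> &gw = w[s];
      const size_t m = gi.size();

      h.zeros();
      double *hp = h.memptr();
      for (size_t t = 0; t < m; ++t) {
        const double *zp = input.colptr(gi[t]);
        const double wt = gw[t];
        for (int j = 0; j < dim; ++j) hp[j] += wt * zp[j];
      }

      p = output.t() * h;
      p -= p.max();
      p = arma::exp(p);
      p /= arma::accu(p);
      ep_loss += -std::log(std::max(p(y[s]), 1e-300));

      p(y[s]) -= 1.0;                       // dL/dscore
      grad_h = output * p;
      for (int k = 0; k < n_classes; ++k) output.col(k) -= (lr * p(k)) * h;
      const double *gp = grad_h.memptr();
      for (size_t t = 0; t < m; ++t) {
        double *zp = input.colptr(gi[t]);
        const double a = lr * gw[t];
        for (int j = 0; j < dim; ++j) zp[j] -= a * gp[j];
      }
    }
    loss[ep] = ep_loss / n_sent;
  }
  return List::create(_["input"] = input.t(), _["output"] = output.t(),
                      _["loss"] = loss);
}

static int sample_negative(const std::vector<double> &cum, std::mt19937 &rng,
                           std::uniform_real_distribution<double> &unif01) {
  double u = unif01(rng);
  return std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
}

// Skip-gram with negative sampling: the centre word's subword average
// predicts each context word.
// [[Rcpp::export]]
List ft_skipgram(List sent_word_ids, List word_gram_ids, NumericVector unigram,
                 int n_grams, int dim, double lr0, int ws, int epochs,
                 int neg, int seed) {
  const int n_sent = sent_word_ids.size();
  const int n_words = word_gram_ids.size();
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif01(0.0, 1.0);
  arma::mat input = init_input(n_grams, dim, rng);
  arma::mat output(n_words, dim, arma::fill::zeros);
  NumericVector loss(epochs);

  std::vector<std::vector<int>> sents(n_sent);
  for (int s = 0; s < n_sent; ++s)
    sents[s] = as<std::vector<int>>(sent_word_ids[s]);
  std::vector<std::vector<int>> grams(n_words);
  for (int wid = 0; wid < n_words; ++wid)
    grams[wid] = as<std::vector<int>>(word_gram_ids[wid]);

  std::vector<double> cum(n_words);
  double acc = 0.0;
  for (int i = 0; i < n_words; ++i) { acc += unigram[i]; cum[i] = acc; }
  cum[n_words - 1] = 1.0;

  std::vector<int> order(n_sent);
  for (int s = 0; s < n_sent; ++s) order[s] = s;
  long total_tokens = 0;
  for (int s = 0; s < n_sent; ++s) total_tokens += sents[s].size();
  const double total = static_cast<double>(epochs) * total_tokens;
  double seen = 0.0;

  arma::vec h(dim), grad_h(dim);
  std::uniform_int_distribution<int> win(1, ws);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    long n_pairs = 0;
    for (int si = 0; si < n_sent; ++si) {
      const std::vector<int> &sent = sents[order[si]];
      const int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        const double lr = lr0 * (1.0 - seen / total);
        seen += 1.0;
        const std::vector<int> &gi = grams[sent[pos]];
        const double inv = 1.0 / gi.size();
        h.zeros();
        for (size_t t = 0; t < gi.size(); ++t) h += input.row(gi[t]).t();
        h *= inv;

        const int b = win(rng);
        grad_h.zeros();
        bool touched = false;
        for (int off = -b; off <= b; ++off) {
          const int cpos = pos + off;
          if (off == 0 || cpos < 0 || cpos >= len) continue;
          touched = true;
          // one positive + `neg` sampled negatives
          for (int k = 0; k <= neg; ++k) {
            int target;
            double label;
            if (k == 0) { target = sent[cpos]; label = 1.0; }
            else { target = sample_negative(cum, rng, unif01); label = 0.0; }
            const double score = arma::dot(output.row(target).t(), h);
            const double pred = sigmoid(score);
            ep_loss += label > 0.5 ? -std::log(std::max(pred, 1e-300))
                                   : -std::log(std::max(1.0 - pred, 1e-300));
            ++n_pairs;
            const double g = lr * (pred - label);
            grad_h += g * output.row(target).t();
            output.row(target) -= (g * h).t();
          }
        }
        if (touched) {
          grad_h *= inv;
          for (size_t t = 0; t < gi.size(); ++t)
            input.row(gi[t]) -= grad_h.t();
        }
      }
    }
    loss[ep] = n_pairs > 0 ? ep_loss / n_pairs : 0.0;
  }
  return List::create(_["input"] = input, _["output"] = output, _["loss"] = loss);
}

// CBOW with negative sampling: the averaged subword vectors of the
// context window predict the centre word.
// [[Rcpp::export]]
List ft_cbow(List sent_word_ids, List word_gram_ids, NumericVector unigram,
             int n_grams, int dim, double lr0, int ws, int epochs,
             int neg, int seed) {
  const int n_sent = sent_word_ids.size();
  const int n_words = word_gram_ids.size();
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif01(0.0, 1.0);
  arma::mat input = init_input(n_grams, dim, rng);
  arma::mat output(n_words, dim, arma::fill::zeros);
  NumericVector loss(epochs);

  std::vector<std::vector<int>> sents(n_sent);
  for (int s = 0; s < n_sent; ++s)
    sents[s] = as<std::vector<int>>(sent_word_ids[s]);
  std::vector<std::vector<int>> grams(n_words);
  for (int wid = 0; wid < n_words; ++wid)
    grams[wid] = as<std::vector<int>>(word_gram_ids[wid]);

  std::vector<double> cum(n_words);
  double acc = 0.0;
  for (int i = 0; i < n_words; ++i) { acc += unigram[i]; cum[i] = acc; }
  cum[n_words - 1] = 1.0;

  std::vector<int> order(n_sent);
  for (int s = 0; s < n_sent; ++s) order[s] = s;
  long total_tokens = 0;
  for (int s = 0; s < n_sent; ++s) total_tokens += sents[s].size();
  const double total = static_cast<double>(epochs) * total_tokens;
  double seen = 0.0;

  arma::vec h(dim), grad_h(dim);
  std::uniform_int_distribution<int> win(1, ws);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    long n_pairs = 0;
    for (int si = 0; si < n_sent; ++si) {
      const std::vector<int> &sent = sents[order[si]];
      const int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        const double lr = lr0 * (1.0 - seen / total);
        seen += 1.0;
        const int b = win(rng);
        h.zeros();
        std::vector<int> ctx_grams;
        int n_ctx = 0;
        for (int off = -b; off <= b; ++off) {
          const int cpos = pos + off;
          if (off == 0 || cpos < 0 || cpos >= len) continue;
          const std::vector<int> &gi = grams[sent[cpos]];
          const double inv = 1.0 / gi.size();
          for (size_t t = 0; t < gi.size(); ++t) {
            h += inv * input.row(gi[t]).t();
            ctx_grams.push_back(gi[t]);
          }
          ++n_ctx;
        }
        if (n_ctx == 0) continue;
        h /= n_ctx;
        grad_h.zeros();
        for (int k = 0; k <= neg; ++k) {
          int target;
          double label;
          if (k == 0) { target = sent[pos]; label = 1.0; }
          else { target = sample_negative(cum, rng, unif01); label = 0.0; }
          const double score = arma::dot(output.row(target).t(), h);
          const double pred = sigmoid(score);
          ep_loss += label > 0.5 ? -std::log(std::max(pred, 1e-300))
                                 : -std::log(std::max(1.0 - pred, 1e-300));
          ++n_pairs;
          const double g = lr * (pred - label);
          grad_h += g * output.row(target).t();
          output.row(target) -= (g * h).t();
        }
        grad_h /= n_ctx;
        // distribute through each context word's subword average
        size_t t = 0;
        for (int off = -b; off <= b; ++off) {
          const int cpos = pos + off;
          if (off == 0 || cpos < 0 || cpos >= len) continue;
          const std::vector<int> &gi = grams[sent[cpos]];
          const double inv = 1.0 / gi.size();
          for (size_t u = 0; u < gi.size(); ++u, ++t)
            input.row(ctx_grams[t]) -= (inv * grad_h).t();
        }
      }
    }
    loss[ep] = n_pairs > 0 ? ep_loss / n_pairs : 0.0;
  }
  return List::create(_["input"] = input, _["output"] = output, _["loss"] = loss);
}
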