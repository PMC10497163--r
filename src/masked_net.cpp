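// Masked-tile conditional network: a fully connected net (3 hidden layers of
// 49 units, ReLU) mapping a masked-board encoding (49 tile values with the
// masked entry zeroed + 49 mask indicators) to 49 red-probabilities.
// Trained with Adam on binary cross-entropy summed over all 49 outputs.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Net {
  arma::mat W1, W2, W3, Wo;
  arma::vec b1, b2, b3, bo;
};

Net net_from_list(const List& w) {
  Net n;
  n.W1 = as<arma::mat>(w["W1"]); n.b1 = as<arma::vec>(w["b1"]);
  n.W2 = as<arma::mat>(w["W2"]); n.b2 = as<arma::vec>(w["b2"]);
  n.W3 = as<arma::mat>(w["W3"]); n.b3 = as<arma::vec>(w["b3"]);
  n.Wo = as<arma::mat>(w["Wo"]); n.bo = as<arma::vec>(w["bo"]);
  return n;
}

List net_to_list(const Net& n) {
  return List::create(
    Named("W1") = n.W1, Named("b1") = n.b1,
    Named("W2") = n.W2, Named("b2") = n.b2,
    Named("W3") = n.W3, Named("b3") = n.b3,
    Named("Wo") = n.Wo, Named("bo") = n.bo);
}

arma::mat forward_probs(const Net& n, const arma::mat& X) {
  arma::mat h1 = n.W1 * X; h1.each_col() += n.b1; h1.transform([](double v){ return v > 0 ? v : 0.0; });
  arma::mat h2 = n.W2 * h1; h2.each_col() += n.b2; h2.transform([](double v){ return v > 0 ? v : 0.0; });
  arma::mat h3 = n.W3 * h2; h3.each_col() += n.b3; h3.transform([](double v){ return v > 0 ? v : 0.0; });
  arma::mat o = n.Wo * h3; o.each_col() += n.bo;
  return 1.0 / (1.0 + arma::exp(-o));
}

arma::mat glorot(int rows, int cols, std::mt19937_64& rng) {
  double lim = std::sqrt(6.0 / (rows + cols));
  std::uniform_real_distribution<double> unif(-lim, lim);
  arma::mat m(rows, cols);
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = unif(rng);
  return m;
}

struct Adam {
  arma::mat m, v;
  Adam(int r, int c) : m(r, c, arma::fill::zeros), v(r, c, arma::fill::zeros) {}
  void step(arma::mat& w, const arma::mat& g, double lr, double t) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * (g % g);
    arma::mat mh = m / (1.0 - std::pow(0.9, t));
    arma::mat vh = v / (1.0 - std::pow(0.999, t));
    w -= lr * mh / (arma::sqrt(vh) + 1e-8);
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_train_masked_net(IntegerMatrix boards, int max_epochs, int batch_size,
                          double lr, double early_acc, int early_window,
                          int seed) {
  const int n_cells = boards.nrow();
  const int n = boards.ncol();
  const int n_in = 2 * n_cells;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  arma::mat B(n_cells, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n_cells; ++i) B(i, j) = boards(i, j);

  Net net;
  net.W1 = glorot(n_cells, n_in, rng); net.b1.zeros(n_cells);
  net.W2 = glorot(n_cells, n_cells, rng); net.b2.zeros(n_cells);
  net.W3 = glorot(n_cells, n_cells, rng); net.b3.zeros(n_cells);
  net.Wo = glorot(n_cells, n_cells, rng); net.bo.zeros(n_cells);

  Adam aW1(n_cells, n_in), aW2(n_cells, n_cells), aW3(n_cells, n_cells),
       aWo(n_cells, n_cells);
  Adam ab1(n_cells, 1), ab2(n_cells, 1), ab3(n_cells, 1), abo(n_cells, 1);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector acc_history;
  double adam_t = 0.0;
  int epochs_run = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    int correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      int bs = std::min(batch_size, n - start);
      arma::mat X(n_in, bs, arma::fill::zeros);
      arma::mat Y(n_cells, bs);
      std::vector<int> mask_idx(bs);
      for (int j = 0; j < bs; ++j) {
        int col = order[start + j];
        int mi = static_cast<int>(unif01(rng) * n_cells);
        if (mi >= n_cells) mi = n_cells - 1;
        mask_idx[j] = mi;
        for (int i = 0; i < n_cells; ++i) {
          X(i, j) = B(i, col);
          Y(i, j) = B(i, col);
        }
        X(mi, j) = 0.0;
        X(n_cells + mi, j) = 1.0;
      }
      // forward, keeping intermediates for backprop
      arma::mat z1 = net.W1 * X; z1.each_col() += net.b1;
      arma::mat h1 = arma::clamp(z1, 0.0, arma::datum::inf);
      arma::mat z2 = net.W2 * h1; z2.each_col() += net.b2;
      arma::mat h2 = arma::clamp(z2, 0.0, arma::datum::inf);
      arma::mat z3 = net.W3 * h2; z3.each_col() += net.b3;
      arma::mat h3 = arma::clamp(z3, 0.0, arma::datum::inf);
      arma::mat o = net.Wo * h3; o.each_col() += net.bo;
      arma::mat P = 1.0 / (1.0 + arma::exp(-o));
      if (!P.is_finite()) stop("masked-net training produced non-finite outputs");

      for (int j = 0; j < bs; ++j) {
        bool pred = P(mask_idx[j], j) >= 0.5;
        bool truth = Y(mask_idx[j], j) >= 0.5;
        if (pred == truth) ++correct;
      }

      // BCE summed over outputs, mean over the batch: dL/do = (P - Y)/bs
      arma::mat dO = (P - Y) / bs;
      arma::mat dWo = dO * h3.t();
      arma::vec dbo = arma::sum(dO, 1);
      arma::mat dh3 = net.Wo.t() * dO; dh3.elem(arma::find(z3 <= 0)).zeros();
      arma::mat dW3 = dh3 * h2.t();
      arma::vec db3 = arma::sum(dh3, 1);
      arma::mat dh2 = net.W3.t() * dh3; dh2.elem(arma::find(z2 <= 0)).zeros();
      arma::mat dW2 = dh2 * h1.t();
      arma::vec db2 = arma::sum(dh2, 1);
      arma::mat dh1 = net.W2.t() * dh2; dh1.elem(arma::find(z1 <= 0)).zeros();
      arma::mat dW1 = dh1 * X.t();
      arma::vec db1 = arma::sum(dh1, 1);

      adam_t += 1.0;
      aW1.step(net.W1, dW1, lr, adam_t); ab1.step(net.b1, db1, lr, adam_t);
      aW2.step(net.W2, dW2, lr, adam_t); ab2.step(net.b2, db2, lr, adam_t);
      aW3.step(net.W3, dW3, lr, adam_t); ab3.step(net.b3, db3, lr, adam_t);
      aWo.step(net.Wo, dWo, lr, adam_t); abo.step(net.bo, dbo, lr, adam_t);
    }
    double acc = static_cast<double>(correct) / n;
    acc_history.push_back(acc);
    epochs_run = epoch + 1;
    if (epochs_run >= early_window) {
      double s = 0.0;
      for (int k = 0; k < early_window; ++k)
        s += acc_history[acc_history.size() - 1 - k];
      if (s / early_window >= early_acc) break;
    }
  }

  return List::create(
    Named("weights") = net_to_list(net),
    Named("accuracy") = acc_history,
    Named("epochs") = epochs_run);
}

// [[Rcpp::export]]
NumericMatrix cpp_masked_net_predict(List weights, NumericMatrix X) {
  Net net = net_from_list(weights);
  arma::mat Xa(X.begin(), X.nrow(), X.ncol(), false);
  arma::mat P = forward_probs(net, Xa);
  return wrap(P);
}

// [[Rcpp::export]]
List cpp_gibbs_sample_net(List weights, int n_boards, int n_sweeps,
                          double init_p, int min_red, int max_retries,
                          int seed) {
  Net net = net_from_list(weights);
  const int n_cells = net.Wo.n_rows;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  IntegerMatrix out(n_cells, n_boards);
  IntegerVector updates(n_boards);
  std::vector<int> perm(n_cells);

  for (int b = 0; b < n_boards; ++b) {
    int n_updates = 0;
    bool accepted = false;
    for (int attempt = 0; attempt <= max_retries && !accepted; ++attempt) {
      n_updates = 0;                 // each retry is a fresh chain
      arma::vec x(n_cells);
      for (int i = 0; i < n_cells; ++i) x(i) = unif01(rng) < init_p ? 1.0 : 0.0;
      arma::vec input(2 * n_cells, arma::fill::zeros);
      for (int s = 0; s < n_sweeps; ++s) {
        for (int i = 0; i < n_cells; ++i) perm[i] = i;
        std::shuffle(perm.begin(), perm.end(), rng);
        for (int k = 0; k < n_cells; ++k) {
          int pos = perm[k];
          input.zeros();
          for (int i = 0; i < n_cells; ++i) input(i) = x(i);
          input(pos) = 0.0;
          input(n_cells + pos) = 1.0;
          arma::mat P = forward_probs(net, input);
          double p = P(pos, 0);
          if (p < 0.0 || p > 1.0 || !std::isfinite(p))
            stop("conditional model produced a probability outside [0, 1]");
          x(pos) = unif01(rng) < p ? 1.0 : 0.0;
          ++n_updates;
        }
      }
      if (arma::accu(x) >= min_red) {
        for (int i = 0; i < n_cells; ++i) out(i, b) = static_cast<int>(x(i));
        accepted = true;
      }
    }
    if (!accepted)
      stop("Gibbs sampling: retry cap reached without a board of >= %d red tiles",
           min_red);
    updates[b] = n_updates;
  }
  return List::create(Named("boards") = out, Named("updates") = updates);
}
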