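// Gapped-core network training and scoring.
//
// Peptides arrive as 0-based residue codes (row-padded with -1); each 9-mer
// window is encoded by concatenating the scaled substitution-matrix rows of
// its residues (enc: 20 residues x 20 features). One network = input ->
// `hidden` sigmoid units -> 1 sigmoid output. Training presents each peptide
// once per epoch in shuffled order, picks the window with the highest current
// prediction (ties to the smallest offset), and takes one stochastic
// gradient step on squared error for that window only.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Net {
  std::vector<double> w1; // nin x h, column-major (k + j * nin)
  std::vector<double> b1; // h
  std::vector<double> w2; // h
  double b2;
  int nin, h;
};

static void encode_window(const IntegerMatrix& codes, const NumericMatrix& enc,
                          int i, int off, int motif_len, double* x) {
  for (int p = 0; p < motif_len; ++p) {
    int aa = codes(i, off + p);
    const double* row = &enc(aa, 0);
    int nrow = enc.nrow();
    for (int k = 0; k < 20; ++k) x[p * 20 + k] = row[(size_t)k * nrow];
  }
}

static double forward(const Net& net, const double* x, double* hact) {
  double out = net.b2;
  for (int j = 0; j < net.h; ++j) {
    double a = net.b1[j];
    const double* wj = &net.w1[(size_t)j * net.nin];
    for (int k = 0; k < net.nin; ++k) a += wj[k] * x[k];
    double hj = sigmoid(a);
    hact[j] = hj;
    out += net.w2[j] * hj;
  }
  return sigmoid(out);
}

// [[Rcpp::export]]
List cpp_train_network(IntegerMatrix codes, IntegerVector lengths,
                       NumericVector targets, IntegerVector train_idx,
                       NumericMatrix enc, int motif_len, int hidden,
                       int epochs, double lr0, double lr1, int seed) {
  const int nin = motif_len * 20;
  Net net;
  net.nin = nin;
  net.h = hidden;
  net.w1.resize((size_t)nin * hidden);
  net.b1.resize(hidden);
  net.w2.resize(hidden);

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(-0.1, 0.1);
  for (int j = 0; j < hidden; ++j)
    for (int k = 0; k < nin; ++k) net.w1[(size_t)j * nin + k] = unif(rng);
  for (int j = 0; j < hidden; ++j) net.b1[j] = unif(rng);
  for (int j = 0; j < hidden; ++j) net.w2[j] = unif(rng);
  net.b2 = unif(rng);

  std::vector<int> order(train_idx.begin(), train_idx.end());
  std::vector<double> x(nin), hact(hidden), hbest(hidden);

  for (int epoch = 0; epoch < epochs; ++epoch) {
    double lr = (epochs > 1)
        ? lr0 + (lr1 - lr0) * (double)epoch / (double)(epochs - 1)
        : lr0;
    std::shuffle(order.begin(), order.end(), rng);
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int i = order[oi];
      int n_off = lengths[i] - motif_len + 1;
      int best_off = 0;
      double best_pred = -1.0;
      for (int off = 0; off < n_off; ++off) {
        encode_window(codes, enc, i, off, motif_len, x.data());
        double pred = forward(net, x.data(), hact.data());
        if (pred > best_pred) { // strict: ties keep the smallest offset
          best_pred = pred;
          best_off = off;
          std::copy(hact.begin(), hact.end(), hbest.begin());
        }
      }
      if (!std::isfinite(best_pred))
        stop("non-finite prediction during training (peptide %d)", i + 1);
      encode_window(codes, enc, i, best_off, motif_len, x.data());
      double y = best_pred;
      double err = y - targets[i];
      double dout = err * y * (1.0 - y);
      for (int j = 0; j < hidden; ++j) {
        double hj = hbest[j];
        double dh = dout * net.w2[j] * hj * (1.0 - hj);
        net.w2[j] -= lr * dout * hj;
        double* wj = &net.w1[(size_t)j * nin];
        for (int k = 0; k < nin; ++k) wj[k] -= lr * dh * x[k];
        net.b1[j] -= lr * dh;
      }
      net.b2 -= lr * dout;
    }
  }

  NumericMatrix w1(nin, hidden);
  for (int j = 0; j < hidden; ++j)
    for (int k = 0; k < nin; ++k) w1(k, j) = net.w1[(size_t)j * nin + k];
  return List::create(_["w1"] = w1,
                      _["b1"] = NumericVector(net.b1.begin(), net.b1.end()),
                      _["w2"] = NumericVector(net.w2.begin(), net.w2.end()),
                      _["b2"] = net.b2);
}

static Net net_from_list(const List& lst) {
  NumericMatrix w1 = lst["w1"];
  NumericVector b1 = lst["b1"], w2 = lst["w2"];
  Net net;
  net.nin = w1.nrow();
  net.h = w1.ncol();
  net.w1.assign(w1.begin(), w1.end());
  net.b1.assign(b1.begin(), b1.end());
  net.w2.assign(w2.begin(), w2.end());
  net.b2 = as<double>(lst["b2"]);
  return net;
}

// Best-window prediction and offset per peptide per network.
// [[Rcpp::export]]
List cpp_score_peptides(IntegerMatrix codes, IntegerVector lengths,
                        NumericMatrix enc, int motif_len, List networks) {
  int n = codes.nrow(), nnet = networks.size();
  NumericMatrix pred(n, nnet);
  IntegerMatrix offs(n, nnet);
  int nin = motif_len * 20;
  std::vector<double> x(nin);
  for (int w = 0; w < nnet; ++w) {
    Net net = net_from_list(networks[w]);
    std::vector<double> hact(net.h);
    for (int i = 0; i < n; ++i) {
      int n_off = lengths[i] - motif_len + 1;
      double best_pred = -1.0;
      int best_off = 0;
      for (int off = 0; off < n_off; ++off) {
        encode_window(codes, enc, i, off, motif_len, x.data());
        double p = forward(net, x.data(), hact.data());
        if (p > best_pred) { best_pred = p; best_off = off; }
      }
      pred(i, w) = best_pred;
      offs(i, w) = best_off;
    }
  }
  return List::create(_["pred"] = pred, _["offset"] = offs);
}

// Per-offset predictions of one network for every peptide (NA beyond the
// peptide's last window).
// [[Rcpp::export]]
NumericMatrix cpp_offset_predictions(IntegerMatrix codes, IntegerVector lengths,
                                     NumericMatrix enc, int motif_len,
                                     List network) {
  Net net = net_from_list(network);
  int n = codes.nrow();
  int max_off = 0;
  for (int i = 0; i < n; ++i)
    max_off = std::max(max_off, (int)lengths[i] - motif_len + 1);
  NumericMatrix out(n, max_off);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> x(net.nin), hact(net.h);
  for (int i = 0; i < n; ++i) {
    int n_off = lengths[i] - motif_len + 1;
    for (int off = 0; off < n_off; ++off) {
      encode_window(codes, enc, i, off, motif_len, x.data());
      out(i, off) = forward(net, x.data(), hact.data());
    }
  }
  return out;
}
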