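// Linear-chain CRF: SGD training with L2 weight decay and a per-epoch L1
// proximal step, log-domain forward-backward for gradients, Viterbi for
// decoding. Feature model: per-token sparse binary attributes tied to each
// state label, plus BOS->y, y->y' and y->EOS transition weights (all states
// and all transitions are parameterised, matching the
// feature.possible_states / feature.possible_transitions = 1 setting).

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (double x : v) if (x > m) m = x;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

struct Weights {
  int A, L;
  std::vector<double> state;  // A x L
  std::vector<double> trans;  // L x L
  std::vector<double> init;   // L
  std::vector<double> fin;    // L
  Weights(int A_, int L_) : A(A_), L(L_),
    state((size_t)A_ * L_, 0.0), trans((size_t)L_ * L_, 0.0),
    init(L_, 0.0), fin(L_, 0.0) {}
};

// node scores for one sequence: T x L
static void node_scores(const std::vector<std::vector<int>>& feats,
                        const Weights& w, std::vector<double>& s) {
  int T = feats.size(), L = w.L;
  s.assign((size_t)T * L, 0.0);
  for (int t = 0; t < T; ++t)
    for (int a : feats[t])
      for (int y = 0; y < L; ++y)
        s[(size_t)t * L + y] += w.state[(size_t)a * L + y];
}

// returns log Z; fills alpha, beta (T x L, log domain)
static double forward_backward(const std::vector<double>& s, int T, int L,
                               const Weights& w,
                               std::vector<double>& alpha,
                               std::vector<double>& beta) {
  alpha.assign((size_t)T * L, 0.0);
  beta.assign((size_t)T * L, 0.0);
  std::vector<double> tmp(L);
  for (int y = 0; y < L; ++y) alpha[y] = w.init[y] + s[y];
  for (int t = 1; t < T; ++t)
    for (int y = 0; y < L; ++y) {
      for (int yp = 0; yp < L; ++yp)
        tmp[yp] = alpha[(size_t)(t - 1) * L + yp] + w.trans[(size_t)yp * L + y];
      alpha[(size_t)t * L + y] = logsumexp(tmp) + s[(size_t)t * L + y];
    }
  for (int y = 0; y < L; ++y) beta[(size_t)(T - 1) * L + y] = w.fin[y];
  for (int t = T - 2; t >= 0; --t)
    for (int y = 0; y < L; ++y) {
      for (int yn = 0; yn < L; ++yn)
        tmp[yn] = w.trans[(size_t)y * L + yn] + s[(size_t)(t + 1) * L + yn] +
                  beta[(size_t)(t + 1) * L + yn];
      beta[(size_t)t * L + y] = logsumexp(tmp);
    }
  std::vector<double> fin(L);
  for (int y = 0; y < L; ++y)
    fin[y] = alpha[(size_t)(T - 1) * L + y] + w.fin[y];
  return logsumexp(fin);
}

// [[Rcpp::export(name = ".crf_train_cpp")]]
List crf_train_cpp(List feat_seqs, List label_seqs, int n_attr, int n_label,
                   double c1, double c2, int max_iter, double eta0,
                   int seed, double epsilon) {
  int N = feat_seqs.size();
  if (N == 0) stop("empty training data");
  // unpack once
  std::vector<std::vector<std::vector<int>>> X(N);
  std::vector<std::vector<int>> Y(N);
  for (int i = 0; i < N; ++i) {
    List fs = feat_seqs[i];
    IntegerVector ys = label_seqs[i];
    int T = fs.size();
    X[i].resize(T);
    Y[i].assign(ys.begin(), ys.end());
    for (int t = 0; t < T; ++t) {
      IntegerVector f = fs[t];
      X[i][t].assign(f.begin(), f.end());
    }
  }
  Weights w(n_attr, n_label);
  int L = n_label;
  double lambda = c2 / std::max(1, N);  // L2 strength per instance
  std::mt19937 rng(seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  std::vector<double> s, alpha, beta, loss_log;
  double prev_loss = R_PosInf;
  long step = 0;
  for (int epoch = 0; epoch < max_iter; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double total_nll = 0.0;
    double eta = eta0;
    for (int oi = 0; oi < N; ++oi) {
      int i = order[oi];
      int T = X[i].size();
      if (T == 0) continue;
      eta = eta0 / (1.0 + lambda * eta0 * (double)step);
      ++step;
      node_scores(X[i], w, s);
      double logZ = forward_backward(s, T, L, w, alpha, beta);
      // gold score
      double gold = w.init[Y[i][0]] + s[Y[i][0]];
      for (int t = 1; t < T; ++t)
        gold += w.trans[(size_t)Y[i][t - 1] * L + Y[i][t]] +
                s[(size_t)t * L + Y[i][t]];
      gold += w.fin[Y[i][T - 1]];
      total_nll += logZ - gold;
      // marginals and updates (gradient ascent on loglik, decay for L2)
      // state features
      for (int t = 0; t < T; ++t) {
        for (int y = 0; y < L; ++y) {
          double p = std::exp(alpha[(size_t)t * L + y] +
                              beta[(size_t)t * L + y] - logZ);
          double g = ((Y[i][t] == y) ? 1.0 : 0.0) - p;
          if (g == 0.0) continue;
          for (int a : X[i][t])
            w.state[(size_t)a * L + y] += eta * g;
        }
      }
      // initial / final
      for (int y = 0; y < L; ++y) {
        double p0 = std::exp(alpha[y] + beta[y] - logZ);
        w.init[y] += eta * (((Y[i][0] == y) ? 1.0 : 0.0) - p0);
        double pT = std::exp(alpha[(size_t)(T - 1) * L + y] +
                             beta[(size_t)(T - 1) * L + y] - logZ);
        w.fin[y] += eta * (((Y[i][T - 1] == y) ? 1.0 : 0.0) - pT);
      }
      // pairwise marginals
      for (int t = 0; t + 1 < T; ++t)
        for (int yp = 0; yp < L; ++yp)
          for (int y = 0; y < L; ++y) {
            double p = std::exp(alpha[(size_t)t * L + yp] +
                                w.trans[(size_t)yp * L + y] +
                                s[(size_t)(t + 1) * L + y] +
                                beta[(size_t)(t + 1) * L + y] - logZ);
            double g = ((Y[i][t] == yp && Y[i][t + 1] == y) ? 1.0 : 0.0) - p;
            w.trans[(size_t)yp * L + y] += eta * g;
          }
      // L2 decay on all weights (scalar, applied lazily would be faster;
      // data sizes here keep this affordable)
      double decay = 1.0 - eta * lambda;
      if (decay < 1.0) {
        for (auto& v : w.state) v *= decay;
        for (auto& v : w.trans) v *= decay;
        for (auto& v : w.init) v *= decay;
        for (auto& v : w.fin) v *= decay;
      }
    }
    // per-epoch L1 proximal step (elastic-net companion to the SGD/L2 core)
    if (c1 > 0.0) {
      double thr = c1 * eta / std::max(1, N);
      auto shrink = [thr](double v) {
        if (v > thr) return v - thr;
        if (v < -thr) return v + thr;
        return 0.0;
      };
      for (auto& v : w.state) v = shrink(v);
      for (auto& v : w.trans) v = shrink(v);
    }
    loss_log.push_back(total_nll);
    if (epoch > 0 && std::fabs(prev_loss - total_nll) <
        epsilon * (std::fabs(prev_loss) + 1e-12)) {
      prev_loss = total_nll;
      break;
    }
    prev_loss = total_nll;
  }
  NumericMatrix state(n_attr, L), trans(L, L);
  for (int a = 0; a < n_attr; ++a)
    for (int y = 0; y < L; ++y) state(a, y) = w.state[(size_t)a * L + y];
  for (int yp = 0; yp < L; ++yp)
    for (int y = 0; y < L; ++y) trans(yp, y) = w.trans[(size_t)yp * L + y];
  return List::create(_["state"] = state, _["trans"] = trans,
                      _["init"] = NumericVector(w.init.begin(), w.init.end()),
                      _["final"] = NumericVector(w.fin.begin(), w.fin.end()),
                      _["loss"] = NumericVector(loss_log.begin(),
                                                loss_log.end()));
}

// [[Rcpp::export(name = ".crf_viterbi_cpp")]]
IntegerVector crf_viterbi_cpp(List feats, NumericMatrix state,
                              NumericMatrix trans, NumericVector init,
                              NumericVector fin) {
  int T = feats.size(), L = init.size();
  if (T == 0) return IntegerVector(0);
  std::vector<double> s((size_t)T * L, 0.0);
  for (int t = 0; t < T; ++t) {
    IntegerVector f = feats[t];
    for (int a : f) {
      if (a < 0 || a >= state.nrow()) continue;
      for (int y = 0; y < L; ++y) s[(size_t)t * L + y] += state(a, y);
    }
  }
  std::vector<double> delta((size_t)T * L);
  std::vector<int> back((size_t)T * L, 0);
  for (int y = 0; y < L; ++y) delta[y] = init[y] + s[y];
  for (int t = 1; t < T; ++t)
    for (int y = 0; y < L; ++y) {
      double best = R_NegInf; int arg = 0;
      for (int yp = 0; yp < L; ++yp) {
        double v = delta[(size_t)(t - 1) * L + yp] + trans(yp, y);
        if (v > best) { best = v; arg = yp; }
      }
      delta[(size_t)t * L + y] = best + s[(size_t)t * L + y];
      back[(size_t)t * L + y] = arg;
    }
  double best = R_NegInf; int arg = 0;
  for (int y = 0; y < L; ++y) {
    double v = delta[(size_t)(T - 1) * L + y] + fin[y];
    if (v > best) { best = v; arg = y; }
  }
  IntegerVector out(T);
  out[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) out[t - 1] = back[(size_t)t * L + out[t]];
  return out;
}
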