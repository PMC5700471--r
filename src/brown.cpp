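// Greedy agglomerative Brown clustering. Words (pre-sorted by descending
// frequency) are introduced one at a time into a working set of at most
// C clusters; each introduction is followed by the merge that loses the
// least average mutual information of the cluster bigram distribution.
// Afterwards the C clusters are merged down to a single root, and every
// word receives the bit-string path of its leaf cluster in the merge tree.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

namespace {

struct Node {
  int left = -1, right = -1;   // children node ids, -1 for leaf
  int cluster = -1;            // initial cluster id for leaves
};

// contribution of one cell to the mutual information, in raw counts
inline double qterm(double c, double rl, double cr, double N) {
  if (c <= 0.0 || rl <= 0.0 || cr <= 0.0) return 0.0;
  return (c / N) * std::log(c * N / (rl * cr));
}

struct Merger {
  std::vector<std::vector<double>> M;  // cluster bigram counts
  std::vector<double> rs, cs;          // row / col sums
  double N = 0.0;
  std::vector<int> node;               // tree node per active cluster
  std::vector<Node>& tree;

  explicit Merger(std::vector<Node>& tree_) : tree(tree_) {}

  int size() const { return (int)node.size(); }

  // delta MI if clusters a and b were merged
  double delta(int a, int b) const {
    int K = size();
    double before = 0.0, after = 0.0;
    double rm = rs[a] + rs[b], cm = cs[a] + cs[b];
    for (int j = 0; j < K; ++j) {
      if (j == a || j == b) continue;
      before += qterm(M[a][j], rs[a], cs[j], N) +
                qterm(M[b][j], rs[b], cs[j], N) +
                qterm(M[j][a], rs[j], cs[a], N) +
                qterm(M[j][b], rs[j], cs[b], N);
      after += qterm(M[a][j] + M[b][j], rm, cs[j], N) +
               qterm(M[j][a] + M[j][b], rs[j], cm, N);
    }
    before += qterm(M[a][a], rs[a], cs[a], N) + qterm(M[a][b], rs[a], cs[b], N) +
              qterm(M[b][a], rs[b], cs[a], N) + qterm(M[b][b], rs[b], cs[b], N);
    after += qterm(M[a][a] + M[a][b] + M[b][a] + M[b][b], rm, cm, N);
    return after - before;
  }

  void merge(int a, int b) {
    if (a > b) std::swap(a, b);
    int K = size();
    for (int j = 0; j < K; ++j) M[a][j] += M[b][j];
    for (int i = 0; i < K; ++i) M[i][a] += M[i][b];
    rs[a] += rs[b];
    cs[a] += cs[b];
    Node parent;
    parent.left = node[a];
    parent.right = node[b];
    tree.push_back(parent);
    node[a] = (int)tree.size() - 1;
    // drop b
    M.erase(M.begin() + b);
    for (auto& row : M) row.erase(row.begin() + b);
    rs.erase(rs.begin() + b);
    cs.erase(cs.begin() + b);
    node.erase(node.begin() + b);
  }

  void best_merge() {
    int K = size();
    double best = -std::numeric_limits<double>::infinity();
    int ba = 0, bb = 1;
    for (int a = 0; a < K; ++a)
      for (int b = a + 1; b < K; ++b) {
        double d = delta(a, b);
        if (d > best) { best = d; ba = a; bb = b; }
      }
    merge(ba, bb);
  }
};

}  // namespace

// sentences: list of integer vectors of word ids (0-based, frequency order);
// returns per-word bit-string paths (index = word id + 1).
// [[Rcpp::export(name = ".brown_cluster_cpp")]]
CharacterVector brown_cluster_cpp(List sentences, int n_words, int n_clusters) {
  if (n_words <= 0) return CharacterVector(0);
  int C = std::min(n_clusters, n_words);
  // word-level bigram counts (dense; vocabularies here are small)
  std::vector<std::vector<double>> W((size_t)n_words,
                                     std::vector<double>(n_words, 0.0));
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sent = sentences[s];
    for (int t = 0; t + 1 < sent.size(); ++t) {
      int a = sent[t], b = sent[t + 1];
      if (a < 0 || b < 0 || a >= n_words || b >= n_words) continue;
      W[a][b] += 1.0;
    }
  }
  std::vector<Node> tree;
  Merger mg(tree);
  std::vector<int> wac(n_words, -1);  // word -> active cluster index
  std::vector<std::vector<int>> members;  // active cluster -> words

  auto add_word = [&](int w) {
    int K = mg.size();
    mg.M.push_back(std::vector<double>(K + 1, 0.0));
    for (int i = 0; i < K; ++i) mg.M[i].push_back(0.0);
    mg.rs.push_back(0.0);
    mg.cs.push_back(0.0);
    Node leaf;
    tree.push_back(leaf);
    mg.node.push_back((int)tree.size() - 1);
    members.push_back({w});
    wac[w] = K;
    // add bigram mass between w and all added words (both directions)
    for (int v = 0; v < n_words; ++v) {
      if (wac[v] < 0) continue;
      double cwv = W[w][v], cvw = W[v][w];
      if (cwv > 0) {
        mg.M[K][wac[v]] += cwv;
        mg.rs[K] += cwv;
        mg.cs[wac[v]] += cwv;
        mg.N += cwv;
      }
      if (v != w && cvw > 0) {
        mg.M[wac[v]][K] += cvw;
        mg.rs[wac[v]] += cvw;
        mg.cs[K] += cvw;
        mg.N += cvw;
      }
    }
  };

  // wrap merge so the word map stays in sync
  auto do_best_merge = [&]() {
    int K = mg.size();
    double best = -std::numeric_limits<double>::infinity();
    int ba = 0, bb = 1;
    for (int a = 0; a < K; ++a)
      for (int b = a + 1; b < K; ++b) {
        double d = mg.delta(a, b);
        if (d > best) { best = d; ba = a; bb = b; }
      }
    if (ba > bb) std::swap(ba, bb);
    mg.merge(ba, bb);
    for (int w : members[bb]) members[ba].push_back(w);
    members.erase(members.begin() + bb);
    for (int c = 0; c < (int)members.size(); ++c)
      for (int w : members[c]) wac[w] = c;
  };

  for (int w = 0; w < n_words; ++w) {
    add_word(w);
    if (mg.size() > C) do_best_merge();
  }
  while (mg.size() > 1) do_best_merge();

  // assign bit paths by DFS from the root
  CharacterVector out(n_words);
  std::vector<std::pair<int, std::string>> stack;
  stack.push_back({mg.node[0], ""});
  std::vector<std::string> node_path(tree.size());
  while (!stack.empty()) {
    auto [id, path] = stack.back();
    stack.pop_back();
    node_path[id] = path;
    if (tree[id].left >= 0) {
      stack.push_back({tree[id].left, path + "0"});
      stack.push_back({tree[id].right, path + "1"});
    }
  }
  // leaf nodes map to the words that ended in that leaf's cluster; leaves
  // were created per added word but clusters carry many words after phase-1
  // merges, so walk members via the final tree: every word's path is the
  // path of the deepest node that still distinguishes its phase-1 leaf.
  // The tree's leaves are exactly the per-word additions in order.
  int leaf_seen = 0;
  for (size_t id = 0; id < tree.size(); ++id) {
    if (tree[id].left < 0) {
      std::string p = node_path[id];
      if (p.empty()) p = "0";
      out[leaf_seen++] = p;
      if (leaf_seen >= n_words) break;
    }
  }
  return out;
}
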