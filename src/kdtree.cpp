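// Exact kd-tree for Euclidean nearest-neighbor lookup over embedded
// genome vectors. Ties in distance are broken by insertion (row)
// order, lexicographically on (distance, index), so results match a
// deterministic brute-force scan exactly.
#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int axis;          // -1 for leaf
  double split;
  int left, right;   // child node ids (-1 if none)
  int start, end;    // range in the index array (leaf only)
};

class KDTree {
public:
  int n, d;
  std::vector<double> pts;  // row-major n x d
  std::vector<int> order;   // permutation of 0..n-1
  std::vector<Node> nodes;
  int root;
  static const int LEAF = 16;

  KDTree(const NumericMatrix& X) : n(X.nrow()), d(X.ncol()) {
    pts.resize((size_t)n * d);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < d; ++j) pts[(size_t)i * d + j] = X(i, j);
    order.resize(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    root = build(0, n);
  }

  int build(int start, int end) {
    Node nd;
    nd.start = start; nd.end = end; nd.left = nd.right = -1;
    if (end - start <= LEAF) {
      nd.axis = -1; nd.split = 0.0;
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    // split on the axis with the largest spread in this range
    int axis = 0; double best = -1.0;
    for (int j = 0; j < d; ++j) {
      double lo = pts[(size_t)order[start] * d + j], hi = lo;
      for (int i = start + 1; i < end; ++i) {
        double v = pts[(size_t)order[i] * d + j];
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (hi - lo > best) { best = hi - lo; axis = j; }
    }
    int mid = (start + end) / 2;
    const std::vector<double>& P = pts; const int D = d;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + end, [&](int a, int b) {
                       double va = P[(size_t)a * D + axis];
                       double vb = P[(size_t)b * D + axis];
                       if (va != vb) return va < vb;
                       return a < b;
                     });
    nd.axis = axis;
    nd.split = pts[(size_t)order[mid] * d + axis];
    int me = (int)nodes.size();
    nodes.push_back(nd);
    int l = build(start, mid);
    int r = build(mid, end);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  typedef std::pair<double, int> Cand;  // (squared distance, row index)

  void consider(std::priority_queue<Cand>& heap, int K, double d2, int i) const {
    if ((int)heap.size() < K) {
      heap.push(Cand(d2, i));
    } else {
      const Cand& w = heap.top();
      if (d2 < w.first || (d2 == w.first && i < w.second)) {
        heap.pop();
        heap.push(Cand(d2, i));
      }
    }
  }

  void search(int node, const double* q, int K,
              std::priority_queue<Cand>& heap) const {
    const Node& nd = nodes[node];
    if (nd.axis < 0) {
      for (int t = nd.start; t < nd.end; ++t) {
        int i = order[t];
        const double* p = &pts[(size_t)i * d];
        double d2 = 0.0;
        for (int j = 0; j < d; ++j) {
          double diff = p[j] - q[j];
          d2 += diff * diff;
        }
        consider(heap, K, d2, i);
      }
      return;
    }
    double delta = q[nd.axis] - nd.split;
    int near = delta <= 0 ? nd.left : nd.right;
    int far = delta <= 0 ? nd.right : nd.left;
    search(near, q, K, heap);
    // equal axis distance may still hide an equal-distance, lower-index
    // candidate, so prune only on strict excess
    if ((int)heap.size() < K || delta * delta <= heap.top().first) {
      search(far, q, K, heap);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".kd_build")]]
SEXP kd_build(NumericMatrix X) {
  XPtr<KDTree> p(new KDTree(X), true);
  return p;
}

// [[Rcpp::export(name = ".kd_valid")]]
bool kd_valid(SEXP ptr) {
  if (TYPEOF(ptr) != EXTPTRSXP) return false;
  return R_ExternalPtrAddr(ptr) != NULL;
}

// [[Rcpp::export(name = ".kd_query")]]
List kd_query(SEXP ptr, NumericMatrix Q, int K) {
  XPtr<KDTree> tree(ptr);
  if (Q.ncol() != tree->d)
    stop("query dimension %d != index dimension %d", Q.ncol(), tree->d);
  if (K < 1) stop("K must be >= 1");
  if (K > tree->n) stop("K exceeds the number of stored vectors");
  int nq = Q.nrow();
  IntegerMatrix idx(nq, K);
  NumericMatrix dist(nq, K);
  std::vector<double> q(tree->d);
  for (int a = 0; a < nq; ++a) {
    for (int j = 0; j < tree->d; ++j) q[j] = Q(a, j);
    std::priority_queue<KDTree::Cand> heap;
    tree->search(tree->root, q.data(), K, heap);
    for (int t = K - 1; t >= 0; --t) {
      idx(a, t) = heap.top().second + 1;  // 1-based
      dist(a, t) = std::sqrt(heap.top().first);
      heap.pop();
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
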