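// Exact k-th nearest neighbour distances between point sets.
//
// Two backends: a k-d tree (default) and a brute-force scan used as an
// in-package oracle for the tree. Both return Euclidean distances and are
// exact; ties in distance are immaterial because only the k-th distance
// value is consumed downstream.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

inline double sqdist(const double *a, const double *b, int d, int na, int nb) {
  double s = 0.0;
  for (int j = 0; j < d; ++j) {
    const double diff = a[(std::size_t)j * na] - b[(std::size_t)j * nb];
    s += diff * diff;
  }
  return s;
}

struct KDNode {
  int lo, hi;        // range in idx (leaf when left < 0)
  int dim;
  double split;
  int left, right;
};

class KDTree {
public:
  KDTree(const double *pts, int n, int d, int leaf_size = 16)
      : pts_(pts), n_(n), d_(d), leaf_size_(leaf_size), idx_(n) {
    for (int i = 0; i < n; ++i) idx_[i] = i;
    if (n > 0) build(0, n);
  }

  // k-th smallest distance from q (row iq of query matrix with nq rows),
  // optionally skipping reference index `skip` (leave-one-out).
  double kth_dist(const double *q, int nq, int k, int skip) const {
    std::priority_queue<double> heap;  // max-heap of best k squared distances
    search(0, q, nq, k, skip, heap);
    return std::sqrt(heap.top());
  }

private:
  const double *pts_;
  int n_, d_, leaf_size_;
  std::vector<int> idx_;
  std::vector<KDNode> nodes_;

  int build(int lo, int hi) {
    KDNode node;
    node.lo = lo;
    node.hi = hi;
    node.left = node.right = -1;
    node.dim = 0;
    node.split = 0.0;
    int me = (int)nodes_.size();
    nodes_.push_back(node);
    if (hi - lo > leaf_size_) {
      // split along the dimension with the largest spread
      int dim = 0;
      double best = -1.0;
      for (int j = 0; j < d_; ++j) {
        double mn = R_PosInf, mx = R_NegInf;
        for (int i = lo; i < hi; ++i) {
          const double v = pts_[(std::size_t)j * n_ + idx_[i]];
          if (v < mn) mn = v;
          if (v > mx) mx = v;
        }
        if (mx - mn > best) { best = mx - mn; dim = j; }
      }
      if (best > 0.0) {
        const int mid = lo + (hi - lo) / 2;
        const double *base = pts_ + (std::size_t)dim * n_;
        std::nth_element(idx_.begin() + lo, idx_.begin() + mid,
                         idx_.begin() + hi,
                         [base](int a, int b) { return base[a] < base[b]; });
        // capture before the recursive builds reorder idx_
        const double split = base[idx_[mid]];
        const int l = build(lo, mid);
        const int r = build(mid, hi);
        nodes_[me].dim = dim;
        nodes_[me].split = split;
        nodes_[me].left = l;
        nodes_[me].right = r;
      }
    }
    return me;
  }

  void scan_leaf(const KDNode &node, const double *q, int nq, int k, int skip,
                 std::priority_queue<double> &heap) const {
    for (int i = node.lo; i < node.hi; ++i) {
      const int p = idx_[i];
      if (p == skip) continue;
      const double d2 = sqdist(q, pts_ + p, d_, nq, n_);
      if ((int)heap.size() < k) {
        heap.push(d2);
      } else if (d2 < heap.top()) {
        heap.pop();
        heap.push(d2);
      }
    }
  }

  void search(int ni, const double *q, int nq, int k, int skip,
              std::priority_queue<double> &heap) const {
    const KDNode &node = nodes_[ni];
    if (node.left < 0) {
      scan_leaf(node, q, nq, k, skip, heap);
      return;
    }
    const double qv = q[(std::size_t)node.dim * nq];
    const double gap = qv - node.split;
    const int near = gap <= 0 ? node.left : node.right;
    const int far = gap <= 0 ? node.right : node.left;
    search(near, q, nq, k, skip, heap);
    if ((int)heap.size() < k || gap * gap < heap.top())
      search(far, q, nq, k, skip, heap);
  }
};

}  // namespace

// [[Rcpp::export(name = ".kth_nn_dist_tree")]]
NumericVector kth_nn_dist_tree(NumericMatrix query, NumericMatrix ref, int k,
                               bool self) {
  const int nq = query.nrow(), nr = ref.nrow(), d = query.ncol();
  if (ref.ncol() != d) stop("query and ref dimensions differ");
  const int avail = self ? nr - 1 : nr;
  if (k < 1 || k > avail) stop("k must be in [1, %d]", avail);
  if (self && nq != nr) stop("self search requires query == ref");
  KDTree tree(&ref(0, 0), nr, d);
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i)
    out[i] = tree.kth_dist(&query(i, 0), nq, k, self ? i : -1);
  return out;
}

// [[Rcpp::export(name = ".kth_nn_dist_brute")]]
NumericVector kth_nn_dist_brute(NumericMatrix query, NumericMatrix ref, int k,
                                bool self) {
  const int nq = query.nrow(), nr = ref.nrow(), d = query.ncol();
  if (ref.ncol() != d) stop("query and ref dimensions differ");
  const int avail = self ? nr - 1 : nr;
  if (k < 1 || k > avail) stop("k must be in [1, %d]", avail);
  if (self && nq != nr) stop("self search requires query == ref");
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    std::priority_queue<double> heap;
    for (int j = 0; j < nr; ++j) {
      if (self && j == i) continue;
      const double d2 = sqdist(&query(i, 0), &ref(j, 0), d, nq, nr);
      if ((int)heap.size() < k) {
        heap.push(d2);
      } else if (d2 < heap.top()) {
        heap.pop();
        heap.push(d2);
      }
    }
    out[i] = std::sqrt(heap.top());
  }
  return out;
}
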