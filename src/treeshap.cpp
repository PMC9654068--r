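// Exact per-instance Shapley attributions for tree ensembles, using the
// path-dependent polynomial-time tree algorithm, plus a double-precision
// raw-score traversal used for local-accuracy checks. All arithmetic is in
// double precision.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Tree {
  std::vector<int> feature, yes, no, miss;
  std::vector<double> split, value, cover;
};

struct PathElement {
  int d;        // feature index that split this path segment (-1 at root)
  double z;     // fraction of zero (feature-absent) paths flowing through
  double o;     // fraction of one (feature-present) paths flowing through
  double w;     // permutation weight
};

static void extend_path(std::vector<PathElement> &m, double pz, double po,
                        int pi) {
  int l = (int)m.size();
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1.0) / (l + 1.0);
    m[i].w = pz * m[i].w * (l - i) / (l + 1.0);
  }
}

static void unwind_path(std::vector<PathElement> &m, int k) {
  int l = (int)m.size() - 1;
  double o = m[k].o, z = m[k].z;
  double nxt = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (o != 0) {
      double t = m[j].w;
      m[j].w = nxt * (l + 1.0) / ((j + 1.0) * o);
      nxt = t - m[j].w * z * (l - j) / (l + 1.0);
    } else {
      m[j].w = m[j].w * (l + 1.0) / (z * (l - j));
    }
  }
  for (int j = k; j < l; ++j) {
    m[j].d = m[j + 1].d;
    m[j].z = m[j + 1].z;
    m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

static void recurse(const Tree &tr, int node, std::vector<PathElement> m,
                    double pz, double po, int pi, const double *x,
                    double *phi) {
  extend_path(m, pz, po, pi);
  if (tr.feature[node] < 0) {  // leaf
    double v = tr.value[node];
    for (int i = 1; i < (int)m.size(); ++i) {
      std::vector<PathElement> tmp = m;
      unwind_path(tmp, i);
      double w = 0;
      for (const PathElement &e : tmp) w += e.w;
      phi[m[i].d] += w * (m[i].o - m[i].z) * v;
    }
    return;
  }
  int d = tr.feature[node];
  double xv = x[d];
  int hot, cold;
  if (ISNAN(xv)) {
    hot = tr.miss[node];
    cold = (hot == tr.yes[node]) ? tr.no[node] : tr.yes[node];
  } else if ((float)xv < (float)tr.split[node]) {  // xgboost compares in float32
    hot = tr.yes[node];
    cold = tr.no[node];
  } else {
    hot = tr.no[node];
    cold = tr.yes[node];
  }
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)m.size(); ++i) {
    if (m[i].d == d) { k = i; break; }
  }
  if (k >= 0) {
    iz = m[k].z;
    io = m[k].o;
    unwind_path(m, k);
  }
  double rj = tr.cover[node];
  recurse(tr, hot, m, iz * tr.cover[hot] / rj, io, d, x, phi);
  recurse(tr, cold, m, iz * tr.cover[cold] / rj, 0.0, d, x, phi);
}

static Tree as_tree(const List &t) {
  Tree tr;
  IntegerVector f = t["feature"], y = t["yes"], n = t["no"], mi = t["missing"];
  NumericVector s = t["split"], v = t["value"], c = t["cover"];
  tr.feature.assign(f.begin(), f.end());
  tr.yes.assign(y.begin(), y.end());
  tr.no.assign(n.begin(), n.end());
  tr.miss.assign(mi.begin(), mi.end());
  tr.split.assign(s.begin(), s.end());
  tr.value.assign(v.begin(), v.end());
  tr.cover.assign(c.begin(), c.end());
  return tr;
}

// cover-weighted expected leaf value of a tree
static double tree_expectation(const Tree &tr, int node) {
  if (tr.feature[node] < 0) return tr.value[node];
  double ey = tree_expectation(tr, tr.yes[node]);
  double en = tree_expectation(tr, tr.no[node]);
  return (tr.cover[tr.yes[node]] * ey + tr.cover[tr.no[node]] * en) /
         tr.cover[node];
}

static double tree_leaf_value(const Tree &tr, const double *x) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    double xv = x[tr.feature[node]];
    if (ISNAN(xv))
      node = tr.miss[node];
    else
      node = ((float)xv < (float)tr.split[node]) ? tr.yes[node] : tr.no[node];
  }
  return tr.value[node];
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
NumericMatrix treeshap_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol(), nt = trees.size();
  std::vector<Tree> forest;
  forest.reserve(nt);
  for (int t = 0; t < nt; ++t) forest.push_back(as_tree(trees[t]));
  double base = 0;
  for (const Tree &tr : forest) base += tree_expectation(tr, 0);

  NumericMatrix out(n, p + 1);
  std::vector<double> x(p), phi(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) x[j] = X(i, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (const Tree &tr : forest) {
      std::vector<PathElement> m;
      recurse(tr, 0, m, 1.0, 1.0, -1, x.data(), phi.data());
    }
    for (int j = 0; j < p; ++j) out(i, j) = phi[j];
    out(i, p) = base;
  }
  return out;
}

// [[Rcpp::export(name = ".tree_predict_cpp")]]
NumericVector tree_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol(), nt = trees.size();
  std::vector<Tree> forest;
  forest.reserve(nt);
  for (int t = 0; t < nt; ++t) forest.push_back(as_tree(trees[t]));
  NumericVector out(n);
  std::vector<double> x(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) x[j] = X(i, j);
    double s = 0;
    for (const Tree &tr : forest) s += tree_leaf_value(tr, x.data());
    out[i] = s;
  }
  return out;
}
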