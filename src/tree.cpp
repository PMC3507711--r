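// C4.5-style tree induction core.
//
// Attributes arrive pre-encoded: numeric columns as 0-based rank codes over
// each column's sorted distinct values (num_codes, with the actual values in
// num_values), nominal columns as 1-based level codes in Xnom;
// attr_type/attr_col map schema order onto the two matrices. Gain ratio
// (information gain / split information, in bits) selects the split; ties
// keep the earliest attribute in schema order, and for a numeric attribute
// the lowest optimal threshold. Numeric thresholds are midpoints of
// consecutive distinct sorted values present in the node. Nominal splits
// are multiway over the full declared domain; empty branches become leaves
// carrying the parent's majority label. A nominal attribute is tested at
// most once per root-to-leaf path.
//
// Numeric split search is histogram-based over the rank codes (falling back
// to gather-and-sort when a node is much smaller than a column's code
// range), so nodes partition only their row list and no per-column order
// needs maintaining. Candidate gains carry the C4.5 (release 8) MDL
// correction for continuous attributes: gain - log2(d - 1) / n with d the
// number of distinct values in the node, which removes the bias toward
// many-valued numeric attributes and stops noise-driven chain growth.
// Entropies are assembled from a precomputed x*log2(x) table over integer
// counts.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
#include <cmath>
using namespace Rcpp;

namespace {

const double EPS_GAIN = 1e-12;

struct FlatTree {
  std::vector<int> attr;           // 1-based schema attribute index, 0 = leaf
  std::vector<int> type;           // 0 leaf, 1 nominal, 2 numeric
  std::vector<double> thr;         // numeric threshold (NA otherwise)
  std::vector<int> label;          // 1-based majority class
  std::vector<std::vector<int>> kids;  // 1-based node ids
  std::vector<std::vector<int>> counts; // per-class training counts
  std::vector<int> depth;
  std::vector<int> nn;             // rows (with bootstrap multiplicity)

  int new_node(int d) {
    attr.push_back(0); type.push_back(0); thr.push_back(NA_REAL);
    label.push_back(1); kids.push_back({}); counts.push_back({});
    depth.push_back(d); nn.push_back(0);
    return (int)attr.size() - 1;
  }
};

struct SplitCand {
  double ratio = -1.0;
  double thr = NA_REAL;   // numeric threshold
  int code = -1;          // numeric: split after this rank code
};

struct Builder {
  const IntegerMatrix& Codes;      // n x pnum rank codes (0-based)
  const IntegerMatrix& Xnom;
  int K;
  const IntegerVector& attr_type;  // 0 nominal, 1 numeric (schema order)
  const IntegerVector& attr_col;   // 0-based column in the kind's matrix
  const IntegerVector& nom_levels; // per nominal column
  std::vector<const double*> vals; // per numeric column: sorted distinct values
  std::vector<int> ncodes;         // per numeric column: number of codes
  int min_leaf, max_depth, msub;
  int m;                           // number of attributes
  FlatTree tree;
  std::vector<bool> nominal_used;
  std::vector<double> xl;          // xl[c] = c * log2(c)
  std::vector<int> yv;             // 0-based class code per table row
  std::vector<int> hist;           // histogram scratch, (max_codes) * K
  std::vector<long long> pair_buf; // (code, class) gather scratch

  Builder(const IntegerMatrix& Cd, const IntegerMatrix& Xo, const IntegerVector& yy,
          int K_, const IntegerVector& at, const IntegerVector& ac,
          const IntegerVector& nl, const List& num_values,
          int ml, int md, int ms, int n_root)
    : Codes(Cd), Xnom(Xo), K(K_), attr_type(at), attr_col(ac),
      nom_levels(nl), min_leaf(ml), max_depth(md), msub(ms) {
    m = at.size();
    nominal_used.assign(m, false);
    xl.resize(n_root + 1);
    xl[0] = 0.0;
    for (int c = 1; c <= n_root; ++c) xl[c] = c * std::log2((double)c);
    int n_table = yy.size();
    yv.resize(n_table);
    for (int r = 0; r < n_table; ++r) yv[r] = yy[r] - 1;
    int pnum = num_values.size();
    vals.resize(pnum);
    ncodes.resize(pnum);
    int max_codes = 1;
    for (int q = 0; q < pnum; ++q) {
      NumericVector v = num_values[q];
      vals[q] = v.begin();
      ncodes[q] = v.size();
      if (ncodes[q] > max_codes) max_codes = ncodes[q];
    }
    hist.assign((size_t)max_codes * K, 0);
    pair_buf.reserve(n_root);
  }

  std::vector<int> class_counts(const std::vector<int>& rows) {
    std::vector<int> cnt(K, 0);
    for (int r : rows) cnt[yv[r]]++;
    return cnt;
  }

  static int majority(const std::vector<int>& cnt) {
    int best = 0;
    for (size_t i = 1; i < cnt.size(); ++i) if (cnt[i] > cnt[best]) best = (int)i;
    return best + 1;  // ties keep the earliest label
  }

  double n_entropy(const std::vector<int>& cnt) const {
    double s = 0.0;
    int n = 0;
    for (int c : cnt) { s += xl[c]; n += c; }
    return xl[n] - s;
  }

  // choose candidate attributes at this node (fresh uniform subsample)
  std::vector<int> candidates() {
    std::vector<int> avail;
    for (int a = 0; a < m; ++a) {
      if (attr_type[a] == 0 && nominal_used[a]) continue;
      avail.push_back(a);
    }
    if (msub >= (int)avail.size()) return avail;
    // partial Fisher-Yates over avail using R's RNG, then schema order
    int na = (int)avail.size();
    for (int i = 0; i < msub; ++i) {
      int j = i + (int)(unif_rand() * (na - i));
      if (j >= na) j = na - 1;
      std::swap(avail[i], avail[j]);
    }
    std::vector<int> out(avail.begin(), avail.begin() + msub);
    std::sort(out.begin(), out.end());
    return out;
  }

  // Gain ratio of a nominal split, or -1 when not admissible.
  double eval_nominal(int a, const std::vector<int>& rows, double nH_node) {
    int c = attr_col[a], L = nom_levels[c], n = (int)rows.size();
    std::vector<int> bsize(L, 0);
    std::vector<int> bcnt((size_t)L * K, 0);
    const int* col = &Xnom(0, c);
    for (int r : rows) {
      int code = col[r] - 1;
      bsize[code]++;
      bcnt[(size_t)code * K + yv[r]]++;
    }
    int ok = 0, nonempty = 0;
    for (int b = 0; b < L; ++b) {
      if (bsize[b] > 0) nonempty++;
      if (bsize[b] >= min_leaf) ok++;
    }
    if (nonempty < 2 || ok < 2) return -1.0;
    double n_cond = 0.0, n_si = 0.0;
    for (int b = 0; b < L; ++b) {
      if (bsize[b] == 0) continue;
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += xl[bcnt[(size_t)b * K + k]];
      n_cond += xl[bsize[b]] - s;
      n_si += xl[bsize[b]];
    }
    n_si = xl[n] - n_si;
    double gain = (nH_node - n_cond) / n;
    double si = n_si / n;
    if (gain <= EPS_GAIN || si <= EPS_GAIN) return -1.0;
    return gain / si;
  }

  // Scan per-code class counts laid out in `counts` for codes in
  // `code_list` (ascending, each with class-count block of K). Shared by
  // the histogram and sort paths.
  SplitCand scan_numeric(int q, int n, double nH_node,
                         const std::vector<int>& code_list,
                         const int* cnts /* K per code, code_list order */) {
    SplitCand best;
    int d = (int)code_list.size();
    if (d < 2) return best;
    double penalty = std::log2((double)(d - 1)) / n;
    const double inv_n = 1.0 / n;
    std::vector<int> left(K, 0);
    int l = 0;
    double best_raw = -1.0;
    int best_code = -1;
    for (int t = 0; t < d - 1; ++t) {
      for (int k = 0; k < K; ++k) left[k] += cnts[(size_t)t * K + k];
      l = 0;
      for (int k = 0; k < K; ++k) l += left[k];
      int r = n - l;
      if (l < min_leaf || r < min_leaf) continue;
      double sl = 0.0, sr = 0.0;
      for (int k = 0; k < K; ++k) {
        sl += xl[left[k]];
        sr += xl[node_cnt[k] - left[k]];
      }
      double n_cond = (xl[l] - sl) + (xl[r] - sr);
      double gain = (nH_node - n_cond) * inv_n - penalty;
      if (gain <= EPS_GAIN) continue;
      double si = (xl[n] - xl[l] - xl[r]) * inv_n;
      if (si <= EPS_GAIN) continue;
      double ratio = gain / si;
      if (ratio > best_raw) {  // ties keep the lowest threshold
        best_raw = ratio;
        best_code = t;
      }
    }
    if (best_code >= 0) {
      best.ratio = best_raw;
      best.code = code_list[best_code];
      double lo = vals[q][code_list[best_code]];
      double hi = vals[q][code_list[best_code + 1]];
      best.thr = lo + (hi - lo) / 2.0;
    }
    return best;
  }

  std::vector<int> node_cnt;  // class counts of the node under evaluation

  // Best numeric split for attribute a over the node's rows.
  SplitCand eval_numeric(int a, const std::vector<int>& rows, double nH_node) {
    int q = attr_col[a];
    int n = (int)rows.size();
    int d_col = ncodes[q];
    const int* code_col = &Codes(0, q);
    if (n >= d_col / 8) {
      // histogram path: per-code class counts over the full code range
      int* h = hist.data();
      std::memset(h, 0, sizeof(int) * (size_t)d_col * K);
      for (int r : rows) h[(size_t)code_col[r] * K + yv[r]]++;
      // compact nonempty codes in place
      code_scratch.clear();
      cnt_scratch.clear();
      for (int code = 0; code < d_col; ++code) {
        int tot = 0;
        for (int k = 0; k < K; ++k) tot += h[(size_t)code * K + k];
        if (tot == 0) continue;
        code_scratch.push_back(code);
        for (int k = 0; k < K; ++k)
          cnt_scratch.push_back(h[(size_t)code * K + k]);
      }
      return scan_numeric(q, n, nH_node, code_scratch, cnt_scratch.data());
    }
    // small-node path: gather (code, class) pairs and sort
    pair_buf.clear();
    for (int r : rows)
      pair_buf.push_back(((long long)code_col[r] << 8) | yv[r]);
    std::sort(pair_buf.begin(), pair_buf.end());
    code_scratch.clear();
    cnt_scratch.clear();
    int prev = -1;
    for (long long e : pair_buf) {
      int code = (int)(e >> 8), k = (int)(e & 0xff);
      if (code != prev) {
        code_scratch.push_back(code);
        cnt_scratch.resize(cnt_scratch.size() + K, 0);
        prev = code;
      }
      cnt_scratch[cnt_scratch.size() - K + k]++;
    }
    return scan_numeric(q, n, nH_node, code_scratch, cnt_scratch.data());
  }

  std::vector<int> code_scratch;
  std::vector<int> cnt_scratch;

  int build(std::vector<int>& rows, int d) {
    int id = tree.new_node(d);
    std::vector<int> cnt = class_counts(rows);
    int n = (int)rows.size();
    tree.counts[id] = cnt;
    tree.nn[id] = n;
    tree.label[id] = majority(cnt);

    bool pure = false;
    for (int k = 0; k < K; ++k) if (cnt[k] == n) pure = true;
    if (pure || n < 2 * min_leaf || d >= max_depth) return id;

    std::vector<int> cand = candidates();
    node_cnt = cnt;
    double nH_node = n_entropy(cnt);
    int best_attr = -1;
    double best_ratio = -1.0;
    SplitCand best_sc;
    for (int a : cand) {
      if (attr_type[a] == 0) {
        double ratio = eval_nominal(a, rows, nH_node);
        if (ratio > best_ratio + EPS_GAIN) {
          best_ratio = ratio;
          best_attr = a;
          best_sc = SplitCand();
        }
      } else {
        SplitCand sc = eval_numeric(a, rows, nH_node);
        if (sc.ratio > best_ratio + EPS_GAIN) {
          best_ratio = sc.ratio;
          best_attr = a;
          best_sc = sc;
        }
      }
    }
    if (best_attr < 0) return id;

    int L;
    std::vector<std::vector<int>> crow;
    if (attr_type[best_attr] == 0) {
      int c = attr_col[best_attr];
      L = nom_levels[c];
      tree.attr[id] = best_attr + 1;
      tree.type[id] = 1;
      crow.resize(L);
      const int* col = &Xnom(0, c);
      for (int r : rows) crow[col[r] - 1].push_back(r);
    } else {
      int q = attr_col[best_attr];
      L = 2;
      tree.attr[id] = best_attr + 1;
      tree.type[id] = 2;
      tree.thr[id] = best_sc.thr;
      crow.resize(2);
      const int* col = &Codes(0, q);
      for (int r : rows) crow[col[r] <= best_sc.code ? 0 : 1].push_back(r);
    }
    rows.clear(); rows.shrink_to_fit();

    bool is_nominal = tree.type[id] == 1;
    if (is_nominal) nominal_used[best_attr] = true;
    std::vector<int> kid_ids(L);
    for (int b = 0; b < L; ++b) {
      if (crow[b].empty()) {
        int kid = tree.new_node(d + 1);
        tree.counts[kid].assign(K, 0);
        tree.label[kid] = tree.label[id];  // parent majority
        kid_ids[b] = kid;
      } else {
        kid_ids[b] = build(crow[b], d + 1);
      }
    }
    if (is_nominal) nominal_used[best_attr] = false;
    tree.kids[id] = kid_ids;
    return id;
  }
};

}  // namespace

// [[Rcpp::export]]
List grow_tree_cpp(IntegerMatrix num_codes, List num_values,
                   IntegerMatrix Xnom, IntegerVector y,
                   int K, IntegerVector attr_type, IntegerVector attr_col,
                   IntegerVector nom_levels, int min_leaf, int max_depth,
                   int msub, IntegerVector rows0) {
  int n0 = rows0.size();
  Builder b(num_codes, Xnom, y, K, attr_type, attr_col, nom_levels,
            num_values, min_leaf, max_depth, msub, n0);
  std::vector<int> rows(rows0.begin(), rows0.end());
  RNGScope scope;  // attribute subsampling uses R's RNG
  b.build(rows, 0);

  int nn = (int)b.tree.attr.size();
  IntegerMatrix counts(nn, K);
  List kids(nn);
  for (int i = 0; i < nn; ++i) {
    for (int k = 0; k < K; ++k) counts(i, k) = b.tree.counts[i][k];
    IntegerVector kv(b.tree.kids[i].size());
    for (size_t j = 0; j < b.tree.kids[i].size(); ++j)
      kv[j] = b.tree.kids[i][j] + 1;  // 1-based
    kids[i] = kv;
  }
  return List::create(
    _["attr"] = IntegerVector(b.tree.attr.begin(), b.tree.attr.end()),
    _["type"] = IntegerVector(b.tree.type.begin(), b.tree.type.end()),
    _["threshold"] = NumericVector(b.tree.thr.begin(), b.tree.thr.end()),
    _["label"] = IntegerVector(b.tree.label.begin(), b.tree.label.end()),
    _["kids"] = kids,
    _["counts"] = counts,
    _["depth"] = IntegerVector(b.tree.depth.begin(), b.tree.depth.end()),
    _["n"] = IntegerVector(b.tree.nn.begin(), b.tree.nn.end()));
}

// [[Rcpp::export]]
IntegerVector predict_tree_cpp(IntegerVector attr, IntegerVector type,
                               NumericVector threshold, IntegerVector label,
                               List kids, IntegerVector attr_typ,
                               IntegerVector attr_col,
                               NumericMatrix Xnum, IntegerMatrix Xnom) {
  int n = Xnum.nrow() > 0 ? Xnum.nrow() : Xnom.nrow();
  IntegerVector out(n);
  std::vector<IntegerVector> kv(kids.size());
  for (int i = 0; i < kids.size(); ++i) kv[i] = kids[i];
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (type[node] != 0) {
      int a = attr[node] - 1;
      int c = attr_col[a];
      int nxt = -1;
      if (type[node] == 1) {
        int code = Xnom(i, c);
        if (code != NA_INTEGER && code >= 1 && code <= kv[node].size())
          nxt = kv[node][code - 1] - 1;
      } else {
        double v = Xnum(i, c);
        if (!NumericVector::is_na(v))
          nxt = kv[node][v <= threshold[node] ? 0 : 1] - 1;
      }
      if (nxt < 0) break;  // out-of-domain value: node majority
      node = nxt;
    }
    out[i] = label[node];
  }
  return out;
}
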