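// Hash-consed expression DAG with exact prime-field evaluation.
//
// All symbolic expressions handled by the package (dynamics, outputs, Lie
// derivatives, Jacobians) are stored as nodes of a shared DAG.  Nodes are
// deduplicated structurally on creation, so repeated subexpressions cost
// nothing and forward-mode differentiation stays polynomial in practice.
// Evaluation is exact arithmetic in GF(p) for a prime p < 2^31: products of
// two residues fit in int64, so no multiprecision library is needed.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_map>

using namespace Rcpp;

typedef int64_t i64;
typedef uint64_t u64;

enum Op { OP_CONST = 0, OP_VAR = 1, OP_ADD = 2, OP_SUB = 3,
          OP_MUL = 4, OP_DIV = 5, OP_NEG = 6, OP_POW = 7 };

struct Dag {
  std::vector<int> op, a1, a2;
  std::vector<i64> cval;                 // constant value when op == CONST
  std::vector<std::string> varnames;
  std::unordered_map<u64, int> nmap;     // structural hash-consing
  std::unordered_map<i64, int> cmap;     // constant value -> node id
  std::unordered_map<u64, int> dmemo;    // (node, var) -> derivative node id
  int n() const { return (int)op.size(); }
};

static const i64 FOLD_MAX = ((i64)1 << 60);
static const int POW_MAX = (1 << 20);    // |exponent| bound (fits hash key)

static inline u64 node_key(int o, int x, int y) {
  // x is a node id (< 2^29 nodes supported); y is a node id or, for POW,
  // a signed exponent bounded by POW_MAX.
  return ((u64)o << 58) | ((u64)(u64)x << 29) | (u64)(u64)(y + (1 << 28));
}

static int mknode(Dag* d, int o, int x, int y, i64 c) {
  d->op.push_back(o); d->a1.push_back(x); d->a2.push_back(y);
  d->cval.push_back(c);
  return d->n();
}

static inline bool iscon(Dag* d, int id) { return d->op[id - 1] == OP_CONST; }
static inline i64 conval(Dag* d, int id) { return d->cval[id - 1]; }

static int constnode(Dag* d, i64 v) {
  auto it = d->cmap.find(v);
  if (it != d->cmap.end()) return it->second;
  int id = mknode(d, OP_CONST, 0, 0, v);
  d->cmap[v] = id;
  return id;
}

static int nd(Dag* d, int o, int x, int y);

static int negnode(Dag* d, int x) { return nd(d, OP_NEG, x, 0); }

// Smart constructor: folds constants, prunes algebraic identities, and
// hash-conses.  Identities used (0*x = 0, x/x = 1, ...) are valid for
// rational functions over a field at generic points, which is the only
// semantics the engines rely on.
static int nd(Dag* d, int o, int x, int y) {
  switch (o) {
  case OP_ADD: {
    if (iscon(d, x) && conval(d, x) == 0) return y;
    if (iscon(d, y) && conval(d, y) == 0) return x;
    if (iscon(d, x) && iscon(d, y)) {
      i64 a = conval(d, x), b = conval(d, y);
      if (std::llabs(a) < FOLD_MAX && std::llabs(b) < FOLD_MAX)
        return constnode(d, a + b);
    }
    if (x > y) std::swap(x, y);          // commutative normal form
    break;
  }
  case OP_SUB: {
    if (x == y) return constnode(d, 0);
    if (iscon(d, y) && conval(d, y) == 0) return x;
    if (iscon(d, x) && conval(d, x) == 0) return negnode(d, y);
    if (iscon(d, x) && iscon(d, y)) {
      i64 a = conval(d, x), b = conval(d, y);
      if (std::llabs(a) < FOLD_MAX && std::llabs(b) < FOLD_MAX)
        return constnode(d, a - b);
    }
    break;
  }
  case OP_MUL: {
    if (iscon(d, x)) {
      i64 a = conval(d, x);
      if (a == 0) return x;
      if (a == 1) return y;
      if (a == -1) return negnode(d, y);
    }
    if (iscon(d, y)) {
      i64 b = conval(d, y);
      if (b == 0) return y;
      if (b == 1) return x;
      if (b == -1) return negnode(d, x);
    }
    if (iscon(d, x) && iscon(d, y)) {
      i64 a = conval(d, x), b = conval(d, y);
      if (std::llabs(a) < ((i64)1 << 30) && std::llabs(b) < ((i64)1 << 30))
        return constnode(d, a * b);
    }
    if (x > y) std::swap(x, y);
    break;
  }
  case OP_DIV: {
    if (iscon(d, y)) {
      i64 b = conval(d, y);
      if (b == 0) stop("division by the constant zero");
      if (b == 1) return x;
      if (b == -1) return negnode(d, x);
      if (iscon(d, x)) {
        i64 a = conval(d, x);
        if (a % b == 0) return constnode(d, a / b);
      }
    }
    if (iscon(d, x) && conval(d, x) == 0) return x;
    if (x == y) return constnode(d, 1);
    break;
  }
  case OP_NEG: {
    if (iscon(d, x)) return constnode(d, -conval(d, x));
    if (d->op[x - 1] == OP_NEG) return d->a1[x - 1];
    break;
  }
  case OP_POW: {
    if (std::llabs((i64)y) > POW_MAX) stop("exponent too large");
    if (y == 0) return constnode(d, 1);
    if (y == 1) return x;
    if (iscon(d, x)) {
      i64 a = conval(d, x);
      if (a == 0 && y > 0) return constnode(d, 0);
      if (a == 1) return constnode(d, 1);
      if (y > 0 && y <= 40 && std::llabs(a) > 1) {
        i64 r = 1; bool ok = true;
        for (int i = 0; i < y; i++) {
          if (std::llabs(r) > ((i64)1 << 50) / std::llabs(a)) { ok = false; break; }
          r *= a;
        }
        if (ok) return constnode(d, r);
      }
    }
    if (d->op[x - 1] == OP_POW) {
      i64 e2 = (i64)d->a2[x - 1] * y;
      if (std::llabs(e2) <= POW_MAX) return nd(d, OP_POW, d->a1[x - 1], (int)e2);
    }
    break;
  }
  }
  u64 key = node_key(o, x, y);
  auto it = d->nmap.find(key);
  if (it != d->nmap.end()) return it->second;
  int id = mknode(d, o, x, y, 0);
  d->nmap[key] = id;
  return id;
}

static int ddiff(Dag* d, int id, int var) {
  u64 key = ((u64)id << 21) | (u64)var;
  auto it = d->dmemo.find(key);
  if (it != d->dmemo.end()) return it->second;
  int o = d->op[id - 1], x = d->a1[id - 1], y = d->a2[id - 1];
  int r = 0;
  switch (o) {
  case OP_CONST: r = constnode(d, 0); break;
  case OP_VAR:   r = constnode(d, x == var ? 1 : 0); break;
  case OP_ADD:   r = nd(d, OP_ADD, ddiff(d, x, var), ddiff(d, y, var)); break;
  case OP_SUB:   r = nd(d, OP_SUB, ddiff(d, x, var), ddiff(d, y, var)); break;
  case OP_NEG:   r = negnode(d, ddiff(d, x, var)); break;
  case OP_MUL:
    r = nd(d, OP_ADD, nd(d, OP_MUL, ddiff(d, x, var), y),
                      nd(d, OP_MUL, x, ddiff(d, y, var)));
    break;
  case OP_DIV:
    r = nd(d, OP_DIV,
           nd(d, OP_SUB, nd(d, OP_MUL, ddiff(d, x, var), y),
                         nd(d, OP_MUL, x, ddiff(d, y, var))),
           nd(d, OP_POW, y, 2));
    break;
  case OP_POW:
    r = nd(d, OP_MUL,
           nd(d, OP_MUL, constnode(d, y), nd(d, OP_POW, x, y - 1)),
           ddiff(d, x, var));
    break;
  }
  d->dmemo[key] = r;
  return r;
}

// ---------------------------------------------------------------- field ops

static inline i64 addm(i64 a, i64 b, i64 p) { i64 s = a + b; return s >= p ? s - p : s; }
static inline i64 subm(i64 a, i64 b, i64 p) { i64 s = a - b; return s < 0 ? s + p : s; }
static inline i64 mulm(i64 a, i64 b, i64 p) { return (a * b) % p; }  // a,b < 2^31

static i64 powm(i64 a, i64 e, i64 p) {
  i64 r = 1; a %= p;
  while (e > 0) {
    if (e & 1) r = mulm(r, a, p);
    a = mulm(a, a, p);
    e >>= 1;
  }
  return r;
}

static inline i64 invm(i64 a, i64 p) { return powm(a, p - 2, p); }

static inline i64 tomod(i64 v, i64 p) { i64 r = v % p; return r < 0 ? r + p : r; }

// Backward closure of a set of target nodes (children precede parents).
static std::vector<char> closure(Dag* d, const IntegerVector& targets) {
  int n = d->n();
  std::vector<char> need(n, 0);
  for (int i = 0; i < targets.size(); i++) {
    int t = targets[i];
    if (t < 1 || t > n) stop("node id out of range");
    need[t - 1] = 1;
  }
  for (int id = n; id >= 1; id--) {
    if (!need[id - 1]) continue;
    int o = d->op[id - 1];
    if (o == OP_CONST || o == OP_VAR) continue;
    need[d->a1[id - 1] - 1] = 1;
    if (o == OP_ADD || o == OP_SUB || o == OP_MUL || o == OP_DIV)
      need[d->a2[id - 1] - 1] = 1;
  }
  return need;
}

// ------------------------------------------------------------ DAG interface

// [[Rcpp::export]]
SEXP cpp_dag_create(CharacterVector vars) {
  Dag* d = new Dag();
  for (int i = 0; i < vars.size(); i++) d->varnames.push_back(as<std::string>(vars[i]));
  XPtr<Dag> ptr(d, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_dag_add_var(SEXP p, std::string name) {
  XPtr<Dag> d(p);
  d->varnames.push_back(name);
  return (int)d->varnames.size();
}

// [[Rcpp::export]]
CharacterVector cpp_dag_vars(SEXP p) {
  XPtr<Dag> d(p);
  return wrap(d->varnames);
}

// [[Rcpp::export]]
int cpp_dag_size(SEXP p) {
  XPtr<Dag> d(p);
  return d->n();
}

// [[Rcpp::export]]
int cpp_dag_var(SEXP p, int index) {
  XPtr<Dag> d(p);
  if (index < 1 || index > (int)d->varnames.size()) stop("variable index out of range");
  u64 key = node_key(OP_VAR, index, 0);
  auto it = d->nmap.find(key);
  if (it != d->nmap.end()) return it->second;
  int id = mknode(d.get(), OP_VAR, index, 0, 0);
  d->nmap[key] = id;
  return id;
}

// [[Rcpp::export]]
int cpp_dag_const(SEXP p, double value) {
  XPtr<Dag> d(p);
  if (value != std::floor(value) || std::fabs(value) > 4.5e15)
    stop("constants must be integer-valued");
  return constnode(d.get(), (i64)value);
}

// [[Rcpp::export]]
int cpp_dag_op(SEXP p, int opcode, int x, int y) {
  XPtr<Dag> d(p);
  int n = d->n();
  if (x < 1 || x > n) stop("node id out of range");
  if (opcode != OP_POW && opcode != OP_NEG && (y < 1 || y > n))
    stop("node id out of range");
  return nd(d.get(), opcode, x, y);
}

// [[Rcpp::export]]
int cpp_dag_diff(SEXP p, int id, int var) {
  XPtr<Dag> d(p);
  if (id < 1 || id > d->n()) stop("node id out of range");
  if (var < 1 || var > (int)d->varnames.size()) stop("variable index out of range");
  return ddiff(d.get(), id, var);
}

// [[Rcpp::export]]
List cpp_dag_info(SEXP p, int id) {
  XPtr<Dag> d(p);
  if (id < 1 || id > d->n()) stop("node id out of range");
  return List::create(_["op"] = d->op[id - 1], _["a1"] = d->a1[id - 1],
                      _["a2"] = d->a2[id - 1],
                      _["cval"] = (double)d->cval[id - 1]);
}

// ------------------------------------------------------------- scalar eval

// [[Rcpp::export]]
List cpp_dag_eval(SEXP p, IntegerVector out_ids, NumericVector var_vals,
                  double prime) {
  XPtr<Dag> d(p);
  i64 pp = (i64)prime;
  int n = d->n();
  std::vector<char> need = closure(d.get(), out_ids);
  std::vector<i64> val(n, 0);
  bool ok = true; int bad = 0;
  for (int id = 1; id <= n && ok; id++) {
    if (!need[id - 1]) continue;
    int o = d->op[id - 1], x = d->a1[id - 1], y = d->a2[id - 1];
    i64 v = 0;
    switch (o) {
    case OP_CONST: v = tomod(d->cval[id - 1], pp); break;
    case OP_VAR: {
      if (x > var_vals.size()) { ok = false; bad = id; break; }
      v = tomod((i64)var_vals[x - 1], pp);
      break;
    }
    case OP_ADD: v = addm(val[x - 1], val[y - 1], pp); break;
    case OP_SUB: v = subm(val[x - 1], val[y - 1], pp); break;
    case OP_MUL: v = mulm(val[x - 1], val[y - 1], pp); break;
    case OP_DIV: {
      if (val[y - 1] == 0) { ok = false; bad = id; break; }
      v = mulm(val[x - 1], invm(val[y - 1], pp), pp);
      break;
    }
    case OP_NEG: v = subm(0, val[x - 1], pp); break;
    case OP_POW: {
      i64 b = val[x - 1];
      if (y < 0) {
        if (b == 0) { ok = false; bad = id; break; }
        v = powm(invm(b, pp), -(i64)y, pp);
      } else v = powm(b, y, pp);
      break;
    }
    }
    val[id - 1] = v;
  }
  NumericVector out(out_ids.size());
  if (ok) for (int i = 0; i < out_ids.size(); i++) out[i] = (double)val[out_ids[i] - 1];
  return List::create(_["values"] = out, _["ok"] = ok, _["bad"] = bad);
}

// ------------------------------------------------------------- series eval

struct SeriesWork {
  std::vector<i64> buf;   // nodes x L, row-major per node
  int L;
  i64* row(int id) { return buf.data() + (size_t)(id - 1) * L; }
};

// Evaluate needed nodes as truncated power series up to `trunc` coefficients.
// Returns false (and bad node) on division by a series with zero constant term.
static bool eval_series(Dag* d, const std::vector<char>& need, SeriesWork& w,
                        const std::vector<std::vector<i64> >& varser,
                        int trunc, i64 p, int* bad) {
  int n = d->n();
  std::vector<i64> tmp(w.L), tmp2(w.L);
  for (int id = 1; id <= n; id++) {
    if (!need[id - 1]) continue;
    int o = d->op[id - 1], x = d->a1[id - 1], y = d->a2[id - 1];
    i64* r = w.row(id);
    switch (o) {
    case OP_CONST:
      r[0] = tomod(d->cval[id - 1], p);
      for (int k = 1; k < trunc; k++) r[k] = 0;
      break;
    case OP_VAR: {
      const std::vector<i64>& vs = varser[x - 1];
      for (int k = 0; k < trunc; k++) r[k] = k < (int)vs.size() ? vs[k] : 0;
      break;
    }
    case OP_ADD: {
      i64 *a = w.row(x), *b = w.row(y);
      for (int k = 0; k < trunc; k++) r[k] = addm(a[k], b[k], p);
      break;
    }
    case OP_SUB: {
      i64 *a = w.row(x), *b = w.row(y);
      for (int k = 0; k < trunc; k++) r[k] = subm(a[k], b[k], p);
      break;
    }
    case OP_NEG: {
      i64* a = w.row(x);
      for (int k = 0; k < trunc; k++) r[k] = subm(0, a[k], p);
      break;
    }
    case OP_MUL: {
      i64 *a = w.row(x), *b = w.row(y);
      for (int k = 0; k < trunc; k++) {
        i64 s = 0;
        for (int i = 0; i <= k; i++) s = addm(s, mulm(a[i], b[k - i], p), p);
        tmp[k] = s;
      }
      for (int k = 0; k < trunc; k++) r[k] = tmp[k];
      break;
    }
    case OP_DIV: {
      i64 *a = w.row(x), *b = w.row(y);
      if (b[0] == 0) { *bad = id; return false; }
      i64 ib0 = invm(b[0], p);
      for (int k = 0; k < trunc; k++) {
        i64 s = a[k];
        for (int i = 1; i <= k; i++) s = subm(s, mulm(b[i], tmp[k - i], p), p);
        tmp[k] = mulm(s, ib0, p);
      }
      for (int k = 0; k < trunc; k++) r[k] = tmp[k];
      break;
    }
    case OP_POW: {
      i64* a = w.row(x);
      int e = y;
      std::vector<i64> base(a, a + trunc);
      if (e < 0) {
        if (base[0] == 0) { *bad = id; return false; }
        i64 ib0 = invm(base[0], p);
        // reciprocal series
        for (int k = 0; k < trunc; k++) {
          if (k == 0) { tmp[0] = ib0; continue; }
          i64 s = 0;
          for (int i = 1; i <= k; i++) s = addm(s, mulm(base[i], tmp[k - i], p), p);
          tmp[k] = subm(0, mulm(s, ib0, p), p);
        }
        base.assign(tmp.begin(), tmp.begin() + trunc);
        e = -e;
      }
      // binary exponentiation with truncated multiplication
      std::vector<i64> acc(trunc, 0); acc[0] = 1;
      while (e > 0) {
        if (e & 1) {
          for (int k = 0; k < trunc; k++) {
            i64 s = 0;
            for (int i = 0; i <= k; i++) s = addm(s, mulm(acc[i], base[k - i], p), p);
            tmp2[k] = s;
          }
          acc.assign(tmp2.begin(), tmp2.begin() + trunc);
        }
        e >>= 1;
        if (e > 0) {
          for (int k = 0; k < trunc; k++) {
            i64 s = 0;
            for (int i = 0; i <= k; i++) s = addm(s, mulm(base[i], base[k - i], p), p);
            tmp2[k] = s;
          }
          base.assign(tmp2.begin(), tmp2.begin() + trunc);
        }
      }
      for (int k = 0; k < trunc; k++) r[k] = acc[k];
      break;
    }
    }
    for (int k = trunc; k < w.L; k++) r[k] = 0;
  }
  return true;
}

// [[Rcpp::export]]
List cpp_dag_eval_series(SEXP p, IntegerVector out_ids, NumericMatrix var_ser,
                         double prime) {
  XPtr<Dag> d(p);
  i64 pp = (i64)prime;
  int L = var_ser.ncol();
  int n = d->n();
  if ((double)n * L > 6e8) stop("series workspace too large");
  std::vector<char> need = closure(d.get(), out_ids);
  std::vector<std::vector<i64> > varser(var_ser.nrow());
  for (int i = 0; i < var_ser.nrow(); i++) {
    varser[i].resize(L);
    for (int k = 0; k < L; k++) varser[i][k] = tomod((i64)var_ser(i, k), pp);
  }
  SeriesWork w; w.L = L; w.buf.assign((size_t)n * L, 0);
  int bad = 0;
  bool ok = eval_series(d.get(), need, w, varser, L, pp, &bad);
  NumericMatrix out(out_ids.size(), L);
  if (ok)
    for (int i = 0; i < out_ids.size(); i++) {
      i64* r = w.row(out_ids[i]);
      for (int k = 0; k < L; k++) out(i, k) = (double)r[k];
    }
  return List::create(_["values"] = out, _["ok"] = ok, _["bad"] = bad);
}

// Power-series solution of the specialized augmented ODE system.
// Variables 1..naug of the DAG are the augmented state components; t_var
// (0 if absent) is the time variable with series t.  f_nodes[i] == 0 means
// the i-th component has identically zero dynamics (a parameter).
// [[Rcpp::export]]
List cpp_dag_series_ode(SEXP p, IntegerVector f_nodes, NumericVector x0,
                        int t_var, int L, double prime) {
  XPtr<Dag> d(p);
  i64 pp = (i64)prime;
  int naug = f_nodes.size();
  int nv = (int)d->varnames.size();
  int n = d->n();
  IntegerVector targets;
  for (int i = 0; i < naug; i++) if (f_nodes[i] > 0) targets.push_back(f_nodes[i]);
  std::vector<char> need(n, 0);
  if (targets.size() > 0) need = closure(d.get(), targets);

  std::vector<std::vector<i64> > varser(nv);
  for (int i = 0; i < nv; i++) varser[i].assign(L, 0);
  for (int i = 0; i < naug; i++) varser[i][0] = tomod((i64)x0[i], pp);
  if (t_var > 0 && L > 1) varser[t_var - 1][1] = 1;

  SeriesWork w; w.L = L; w.buf.assign((size_t)n * L, 0);
  int bad = 0;
  std::vector<i64> inv_k(L + 1, 1);
  for (int k = 1; k <= L; k++) inv_k[k] = invm(k, pp);

  for (int k = 0; k + 1 < L; k++) {
    if (!eval_series(d.get(), need, w, varser, k + 1, pp, &bad))
      return List::create(_["ok"] = false, _["bad"] = bad);
    for (int i = 0; i < naug; i++) {
      i64 fk = f_nodes[i] > 0 ? w.row(f_nodes[i])[k] : 0;
      varser[i][k + 1] = mulm(fk, inv_k[k + 1], pp);
    }
  }
  // residual check: coefficient k of f(series) must equal (k+1) x_{k+1}
  bool resid_ok = true;
  if (!eval_series(d.get(), need, w, varser, L, pp, &bad))
    return List::create(_["ok"] = false, _["bad"] = bad);
  for (int i = 0; i < naug && resid_ok; i++) {
    for (int k = 0; k + 1 < L; k++) {
      i64 fk = f_nodes[i] > 0 ? w.row(f_nodes[i])[k] : 0;
      if (mulm((i64)(k + 1), varser[i][k + 1], pp) != fk) { resid_ok = false; break; }
    }
  }
  NumericMatrix xser(naug, L);
  for (int i = 0; i < naug; i++)
    for (int k = 0; k < L; k++) xser(i, k) = (double)varser[i][k];
  return List::create(_["ok"] = true, _["bad"] = 0, _["xser"] = xser,
                      _["resid_ok"] = resid_ok);
}

// Sensitivity series X(t) solving X' = J(t) X, X(0) = I, where only the
// first n rows of the (np x np) Jacobian are nonzero (parameter rows of the
// augmented system vanish).  Jser rows are (i-1)*np + j for i in 1..n.
// [[Rcpp::export]]
NumericMatrix cpp_sens_series(NumericMatrix Jser, int n, int np, double prime) {
  i64 p = (i64)prime;
  int L = Jser.ncol();
  std::vector<i64> X((size_t)np * np * L, 0);
  // X[(i,j,k)] = X[((i-1)*np + (j-1))*L + k]
  for (int i = 0; i < np; i++) X[((size_t)i * np + i) * L] = 1;
  std::vector<i64> J((size_t)n * np * L);
  for (int r = 0; r < n * np; r++)
    for (int k = 0; k < L; k++) J[(size_t)r * L + k] = tomod((i64)Jser(r, k), p);
  for (int k = 0; k + 1 < L; k++) {
    i64 ik = invm(k + 1, p);
    for (int i = 0; i < n; i++) {
      for (int j = 0; j < np; j++) {
        i64 s = 0;
        for (int sdx = 0; sdx <= k; sdx++) {
          // sum_l J_sdx[i,l] * X_{k-sdx}[l,j]
          i64 acc = 0;
          for (int l = 0; l < np; l++) {
            i64 jv = J[((size_t)i * np + l) * L + sdx];
            if (jv == 0) continue;
            acc = addm(acc, mulm(jv, X[((size_t)l * np + j) * L + (k - sdx)], p), p);
          }
          s = addm(s, acc, p);
        }
        X[((size_t)i * np + j) * L + (k + 1)] = mulm(s, ik, p);
      }
    }
  }
  NumericMatrix out(np * np, L);
  for (int r = 0; r < np * np; r++)
    for (int k = 0; k < L; k++) out(r, k) = (double)X[(size_t)r * L + k];
  return out;
}

// Stack the series coefficients of H(t) X(t) into the coefficient Jacobian:
// block row for order k holds the t^k coefficient of d y / d x0.
// [[Rcpp::export]]
NumericMatrix cpp_stack_jac(NumericMatrix Hser, NumericMatrix Xser, int m,
                            int np, int n_orders, double prime) {
  i64 p = (i64)prime;
  int L = Hser.ncol();
  if (n_orders > L) stop("not enough series coefficients");
  NumericMatrix out(m * n_orders, np);
  for (int k = 0; k < n_orders; k++) {
    for (int o = 0; o < m; o++) {
      for (int j = 0; j < np; j++) {
        i64 s = 0;
        for (int sdx = 0; sdx <= k; sdx++) {
          i64 acc = 0;
          for (int l = 0; l < np; l++) {
            i64 hv = tomod((i64)Hser(o * np + l, sdx), p);
            if (hv == 0) continue;
            acc = addm(acc, mulm(hv, tomod((i64)Xser(l * np + j, k - sdx), p), p), p);
          }
          s = addm(s, acc, p);
        }
        out(k * m + o, j) = (double)s;
      }
    }
  }
  return out;
}

// ------------------------------------------------------------------- rank

static int rank_elim(std::vector<i64>& M, int nr, int nc, i64 p) {
  int rank = 0;
  for (int c = 0; c < nc && rank < nr; c++) {
    int piv = -1;
    for (int r = rank; r < nr; r++)
      if (M[(size_t)r * nc + c] != 0) { piv = r; break; }
    if (piv < 0) continue;
    if (piv != rank)
      for (int j = c; j < nc; j++)
        std::swap(M[(size_t)piv * nc + j], M[(size_t)rank * nc + j]);
    i64 ip = invm(M[(size_t)rank * nc + c], p);
    for (int r = rank + 1; r < nr; r++) {
      i64 f = M[(size_t)r * nc + c];
      if (f == 0) continue;
      f = mulm(f, ip, p);
      for (int j = c; j < nc; j++)
        M[(size_t)r * nc + j] =
          subm(M[(size_t)r * nc + j], mulm(f, M[(size_t)rank * nc + j], p), p);
    }
    rank++;
  }
  return rank;
}

// [[Rcpp::export]]
int cpp_mod_rank(NumericMatrix mat, double prime) {
  i64 p = (i64)prime;
  int nr = mat.nrow(), nc = mat.ncol();
  std::vector<i64> M((size_t)nr * nc);
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++) M[(size_t)r * nc + c] = tomod((i64)mat(r, c), p);
  return rank_elim(M, nr, nc, p);
}

// Rank of the matrix and of the matrix with each single column removed.
// Returns c(full_rank, rank_without_col_1, ..., rank_without_col_nc).
// [[Rcpp::export]]
IntegerVector cpp_mod_rank_drop(NumericMatrix mat, double prime) {
  i64 p = (i64)prime;
  int nr = mat.nrow(), nc = mat.ncol();
  std::vector<i64> M0((size_t)nr * nc);
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++) M0[(size_t)r * nc + c] = tomod((i64)mat(r, c), p);
  IntegerVector out(nc + 1);
  {
    std::vector<i64> M = M0;
    out[0] = rank_elim(M, nr, nc, p);
  }
  for (int drop = 0; drop < nc; drop++) {
    std::vector<i64> M((size_t)nr * (nc - 1));
    for (int r = 0; r < nr; r++) {
      int cc = 0;
      for (int c = 0; c < nc; c++) {
        if (c == drop) continue;
        M[(size_t)r * (nc - 1) + cc] = M0[(size_t)r * nc + c];
        cc++;
      }
    }
    out[drop + 1] = rank_elim(M, nr, nc - 1, p);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_mod_inv(double a, double prime) {
  i64 p = (i64)prime;
  i64 aa = tomod((i64)a, p);
  if (aa == 0) stop("zero has no inverse");
  return (double)invm(aa, p);
}

// [[Rcpp::export]]
double cpp_mod_pow(double a, double e, double prime) {
  i64 p = (i64)prime;
  i64 aa = tomod((i64)a, p);
  i64 ee = (i64)e;
  if (ee < 0) { aa = invm(aa, p); ee = -ee; }
  return (double)powm(aa, ee, p);
}
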