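// Child-Sum TreeLSTM and multichannel CNN sentence encoders.
//
// Forward passes follow the standard transition equations; backward passes are
// exact analytic gradients (backpropagation through structure for the tree,
// backprop through argmax for the max-pool), verified against central finite
// differences in the test suite. All computations are double precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// children-first traversal order: stable sort by decreasing depth, then index
static std::vector<int> topo_order(const IntegerVector& parent) {
  int n = parent.size();
  std::vector<int> depth(n, 0);
  for (int i = 0; i < n; ++i) {
    int j = i, d = 0;
    while (parent[j] != 0) { j = parent[j] - 1; ++d; if (d > n) stop("cycle in tree"); }
    depth[i] = d;
  }
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (depth[a] != depth[b]) return depth[a] > depth[b];
    return a < b;
  });
  return ord;
}

// [[Rcpp::export]]
List cpp_treelstm_forward(const arma::mat& X, IntegerVector parent, List par,
                          const arma::mat& hmask, std::string readout) {
  const mat Wi = par["W_i"], Wf = par["W_f"], Wo = par["W_o"], Wu = par["W_u"];
  const mat Ui = par["U_i"], Uf = par["U_f"], Uo = par["U_o"], Uu = par["U_u"];
  const vec bi = par["b_i"], bf = par["b_f"], bo = par["b_o"], bu = par["b_u"];
  const uword dh = Wi.n_rows, N = X.n_cols;
  if (Wi.n_cols != X.n_rows) stop("input width does not match W matrices");
  if (hmask.n_rows != dh || hmask.n_cols != N) stop("dropout mask shape mismatch");

  std::vector<int> ord = topo_order(parent);
  mat H(dh, N), Hm(dh, N), C(dh, N), I(dh, N), O(dh, N), U(dh, N);
  mat Fg(dh, N, arma::fill::zeros);   // forget gate on the edge parent(j) -> j
  mat Hsum(dh, N, arma::fill::zeros); // sum of masked child hidden states
  int root = -1;

  // precompute Wx once per gate
  mat WiX = Wi * X, WfX = Wf * X, WoX = Wo * X, WuX = Wu * X;

  std::vector<std::vector<int>> children(N);
  for (uword j = 0; j < N; ++j) {
    if (parent[j] == 0) root = j; else children[parent[j] - 1].push_back(j);
  }
  if (root < 0) stop("no root node");

  for (int idx : ord) {
    uword j = idx;
    vec hsum(dh, arma::fill::zeros);
    for (int k : children[j]) hsum += Hm.col(k);
    Hsum.col(j) = hsum;
    vec ij = sigmoid(WiX.col(j) + Ui * hsum + bi);
    vec oj = sigmoid(WoX.col(j) + Uo * hsum + bo);
    vec uj = arma::tanh(WuX.col(j) + Uu * hsum + bu);
    vec cj = ij % uj;
    for (int k : children[j]) {
      vec fjk = sigmoid(WfX.col(j) + Uf * Hm.col(k) + bf);
      Fg.col(k) = fjk;
      cj += fjk % C.col(k);
    }
    vec hj = oj % arma::tanh(cj);
    I.col(j) = ij; O.col(j) = oj; U.col(j) = uj; C.col(j) = cj;
    H.col(j) = hj; Hm.col(j) = hmask.col(j) % hj;
  }

  vec r = (readout == "o") ? vec(O.col(root)) : vec(Hm.col(root));
  return List::create(_["r"] = r, _["H"] = H, _["Hm"] = Hm, _["C"] = C,
                      _["I"] = I, _["O"] = O, _["U"] = U, _["Fg"] = Fg,
                      _["Hsum"] = Hsum, _["root"] = root + 1);
}

// [[Rcpp::export]]
List cpp_treelstm_backward(const arma::mat& X, IntegerVector parent, List par,
                           List cache, const arma::mat& hmask, const arma::vec& g,
                           std::string readout) {
  const mat Wi = par["W_i"], Wf = par["W_f"], Wo = par["W_o"], Wu = par["W_u"];
  const mat Ui = par["U_i"], Uf = par["U_f"], Uo = par["U_o"], Uu = par["U_u"];
  const mat H = cache["H"], Hm = cache["Hm"], C = cache["C"], I = cache["I"],
            O = cache["O"], U = cache["U"], Fg = cache["Fg"], Hsum = cache["Hsum"];
  const uword dh = Wi.n_rows, din = Wi.n_cols, N = X.n_cols;
  int root = as<int>(cache["root"]) - 1;

  std::vector<int> ord = topo_order(parent);
  std::vector<std::vector<int>> children(N);
  for (uword j = 0; j < N; ++j)
    if (parent[j] != 0) children[parent[j] - 1].push_back(j);

  mat dHm(dh, N, arma::fill::zeros), dC(dh, N, arma::fill::zeros);
  mat dX(din, N, arma::fill::zeros);
  mat dWi(dh, din, arma::fill::zeros), dWf(dh, din, arma::fill::zeros),
      dWo(dh, din, arma::fill::zeros), dWu(dh, din, arma::fill::zeros);
  mat dUi(dh, dh, arma::fill::zeros), dUf(dh, dh, arma::fill::zeros),
      dUo(dh, dh, arma::fill::zeros), dUu(dh, dh, arma::fill::zeros);
  vec dbi(dh, arma::fill::zeros), dbf(dh, arma::fill::zeros),
      dbo(dh, arma::fill::zeros), dbu(dh, arma::fill::zeros);

  if (readout != "o") dHm.col(root) += g;

  // parents before children
  for (auto it = ord.rbegin(); it != ord.rend(); ++it) {
    uword j = *it;
    vec tc = arma::tanh(C.col(j));
    vec dh_raw = hmask.col(j) % dHm.col(j);
    vec do_ = dh_raw % tc;
    if (readout == "o" && (int)j == root) do_ += g;
    vec dc = dC.col(j) + dh_raw % O.col(j) % (1.0 - tc % tc);
    vec da_o = do_ % O.col(j) % (1.0 - O.col(j));
    vec di = dc % U.col(j);
    vec da_i = di % I.col(j) % (1.0 - I.col(j));
    vec du = dc % I.col(j);
    vec da_u = du % (1.0 - U.col(j) % U.col(j));

    dWi += da_i * X.col(j).t(); dUi += da_i * Hsum.col(j).t(); dbi += da_i;
    dWo += da_o * X.col(j).t(); dUo += da_o * Hsum.col(j).t(); dbo += da_o;
    dWu += da_u * X.col(j).t(); dUu += da_u * Hsum.col(j).t(); dbu += da_u;
    dX.col(j) += Wi.t() * da_i + Wo.t() * da_o + Wu.t() * da_u;

    vec dhsum = Ui.t() * da_i + Uo.t() * da_o + Uu.t() * da_u;
    for (int k : children[j]) {
      vec f = Fg.col(k);
      vec df = dc % C.col(k);
      vec da_f = df % f % (1.0 - f);
      dWf += da_f * X.col(j).t(); dUf += da_f * Hm.col(k).t(); dbf += da_f;
      dC.col(k) += dc % f;
      dHm.col(k) += dhsum + Uf.t() * da_f;
      dX.col(j) += Wf.t() * da_f;
    }
  }

  return List::create(
    _["W_i"] = dWi, _["W_f"] = dWf, _["W_o"] = dWo, _["W_u"] = dWu,
    _["U_i"] = dUi, _["U_f"] = dUf, _["U_o"] = dUo, _["U_u"] = dUu,
    _["b_i"] = dbi, _["b_f"] = dbf, _["b_o"] = dbo, _["b_u"] = dbu,
    _["X"] = dX);
}

// zero-pad a channel matrix to at least width k (split left/right)
static mat pad_to(const mat& X, int k, int& left) {
  int N = X.n_cols;
  if (N >= k) { left = 0; return X; }
  int total = k - N;
  left = total / 2;
  mat Xp(X.n_rows, k, arma::fill::zeros);
  Xp.cols(left, left + N - 1) = X;
  return Xp;
}

// [[Rcpp::export]]
List cpp_mccnn_forward(List Xs, List W, List b, IntegerVector kernel_sizes) {
  int nch = Xs.size(), K = kernel_sizes.size();
  std::vector<mat> Xv(nch);
  for (int c = 0; c < nch; ++c) Xv[c] = as<mat>(Xs[c]);
  const uword din = Xv[0].n_rows, N = Xv[0].n_cols;
  for (int c = 1; c < nch; ++c)
    if (Xv[c].n_rows != din || Xv[c].n_cols != N)
      stop("channel shape mismatch");

  List Zs(K), amaxs(K);
  int dh_total = 0;
  std::vector<vec> rparts(K);
  for (int q = 0; q < K; ++q) {
    int k = kernel_sizes[q];
    List Wq = W[q];
    vec bq = as<vec>(b[q]);
    int dh = bq.n_elem;
    dh_total += dh;
    int left = 0;
    std::vector<mat> Xp(nch);
    for (int c = 0; c < nch; ++c) Xp[c] = pad_to(Xv[c], k, left);
    int Np = Xp[0].n_cols;
    int nw = Np - k + 1;
    mat Z(dh, nw);
    for (int i = 0; i < nw; ++i) {
      vec a = bq;
      for (int c = 0; c < nch; ++c) {
        const mat& Wc = as<mat>(Wq[c]);
        vec win = arma::vectorise(Xp[c].cols(i, i + k - 1));
        a += Wc * win;
      }
      Z.col(i) = arma::tanh(a);
    }
    IntegerVector amax(dh);
    vec rh(dh);
    for (int t = 0; t < dh; ++t) {
      arma::rowvec row = Z.row(t);
      uword best = 0;
      for (uword i = 1; i < (uword)nw; ++i) if (row[i] > row[best]) best = i;
      amax[t] = best + 1;  // 1-based for the R side
      rh[t] = row[best];
    }
    rparts[q] = rh;
    Zs[q] = Z;
    amaxs[q] = amax;
  }
  vec r(dh_total);
  int off = 0;
  for (int q = 0; q < K; ++q) {
    r.subvec(off, off + rparts[q].n_elem - 1) = rparts[q];
    off += rparts[q].n_elem;
  }
  return List::create(_["r"] = r, _["Z"] = Zs, _["amax"] = amaxs);
}

// [[Rcpp::export]]
List cpp_mccnn_backward(List Xs, List W, List b, IntegerVector kernel_sizes,
                        List cache, const arma::vec& g) {
  int nch = Xs.size(), K = kernel_sizes.size();
  std::vector<mat> Xv(nch);
  for (int c = 0; c < nch; ++c) Xv[c] = as<mat>(Xs[c]);
  const uword din = Xv[0].n_rows, N = Xv[0].n_cols;
  List Zs = cache["Z"], amaxs = cache["amax"];

  List dW(K); List db(K);
  std::vector<mat> dX(nch, mat(din, N, arma::fill::zeros));
  int off = 0;
  for (int q = 0; q < K; ++q) {
    int k = kernel_sizes[q];
    List Wq = W[q];
    vec bq = as<vec>(b[q]);
    int dh = bq.n_elem;
    mat Z = as<mat>(Zs[q]);
    IntegerVector amax = amaxs[q];
    vec gq = g.subvec(off, off + dh - 1);
    off += dh;

    int left = 0;
    std::vector<mat> Xp(nch);
    for (int c = 0; c < nch; ++c) Xp[c] = pad_to(Xv[c], k, left);
    int Np = Xp[0].n_cols;
    int nw = Np - k + 1;

    List dWq(nch);
    std::vector<mat> dWv(nch, mat(dh, k * din, arma::fill::zeros));
    vec dbq(dh, arma::fill::zeros);
    std::vector<mat> dXp(nch, mat(din, Np, arma::fill::zeros));
    for (int i = 0; i < nw; ++i) {
      vec da(dh, arma::fill::zeros);
      bool any = false;
      for (int t = 0; t < dh; ++t) {
        if (amax[t] - 1 == i) {
          da[t] = gq[t] * (1.0 - Z(t, i) * Z(t, i));
          any = true;
        }
      }
      if (!any) continue;
      dbq += da;
      for (int c = 0; c < nch; ++c) {
        const mat& Wc = as<mat>(Wq[c]);
        vec win = arma::vectorise(Xp[c].cols(i, i + k - 1));
        dWv[c] += da * win.t();
        vec dwin = Wc.t() * da;
        dXp[c].cols(i, i + k - 1) += arma::reshape(dwin, din, k);
      }
    }
    for (int c = 0; c < nch; ++c) {
      dWq[c] = dWv[c];
      dX[c] += dXp[c].cols(left, left + N - 1);
    }
    dW[q] = dWq;
    db[q] = dbq;
  }
  List dXl(nch);
  for (int c = 0; c < nch; ++c) dXl[c] = dX[c];
  return List::create(_["W"] = dW, _["b"] = db, _["X"] = dXl);
}
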