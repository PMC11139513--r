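// Batched matrix products over sample-indexed cubes (rows x cols x samples).
// A cube with one slice broadcasts across the batch; gradients w.r.t. a
// broadcast operand are accumulated over slices by cube_bmm_sum.
// Inputs are viewed in place (no copy); only the result is allocated.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static cube view_cube(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 3) Rcpp::stop("expected a 3-d array");
  return cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
}

// [[Rcpp::export]]
Rcpp::NumericVector cube_bmm(const Rcpp::NumericVector& A,
                             const Rcpp::NumericVector& B,
                             bool ta = false, bool tb = false) {
  cube Ac = view_cube(A), Bc = view_cube(B);
  uword S = std::max(Ac.n_slices, Bc.n_slices);
  uword m = ta ? Ac.n_cols : Ac.n_rows;
  uword n = tb ? Bc.n_rows : Bc.n_cols;
  Rcpp::NumericVector out(m * n * S);
  out.attr("dim") = Rcpp::IntegerVector::create(m, n, S);
  cube Oc(out.begin(), m, n, S, false, true);
  for (uword s = 0; s < S; ++s) {
    const mat& a = Ac.slice(Ac.n_slices == 1 ? 0 : s);
    const mat& b = Bc.slice(Bc.n_slices == 1 ? 0 : s);
    mat& o = Oc.slice(s);
    if (!ta && !tb)      o = a * b;
    else if (ta && !tb)  o = a.t() * b;
    else if (!ta && tb)  o = a * b.t();
    else                 o = a.t() * b.t();
  }
  return out;
}

// sum_s op(A_s) * op(B_s); the reduction used for broadcast-operand gradients
// [[Rcpp::export]]
Rcpp::NumericVector cube_bmm_sum(const Rcpp::NumericVector& A,
                                 const Rcpp::NumericVector& B,
                                 bool ta = false, bool tb = false) {
  cube Ac = view_cube(A), Bc = view_cube(B);
  uword S = std::max(Ac.n_slices, Bc.n_slices);
  uword m = ta ? Ac.n_cols : Ac.n_rows;
  uword n = tb ? Bc.n_rows : Bc.n_cols;
  mat acc(m, n, fill::zeros);
  for (uword s = 0; s < S; ++s) {
    const mat& a = Ac.slice(Ac.n_slices == 1 ? 0 : s);
    const mat& b = Bc.slice(Bc.n_slices == 1 ? 0 : s);
    if (!ta && !tb)      acc += a * b;
    else if (ta && !tb)  acc += a.t() * b;
    else if (!ta && tb)  acc += a * b.t();
    else                 acc += a.t() * b.t();
  }
  Rcpp::NumericVector out(m * n);
  out.attr("dim") = Rcpp::IntegerVector::create(m, n);
  mat Om(out.begin(), m, n, false, true);
  Om = acc;
  return out;
}

// row-wise softmax within each slice (over columns)
// [[Rcpp::export]]
Rcpp::NumericVector cube_softmax_rows(const Rcpp::NumericVector& X) {
  cube Xc = view_cube(X);
  Rcpp::NumericVector out(X.size());
  out.attr("dim") = X.attr("dim");
  cube Oc(out.begin(), Xc.n_rows, Xc.n_cols, Xc.n_slices, false, true);
  for (uword s = 0; s < Xc.n_slices; ++s) {
    mat e = exp(Xc.slice(s).each_col() - max(Xc.slice(s), 1));
    Oc.slice(s) = e.each_col() / sum(e, 1);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cube_softmax_rows_grad(const Rcpp::NumericVector& G,
                                           const Rcpp::NumericVector& O) {
  cube Gc = view_cube(G), Oc = view_cube(O);
  Rcpp::NumericVector out(G.size());
  out.attr("dim") = G.attr("dim");
  cube Rc(out.begin(), Gc.n_rows, Gc.n_cols, Gc.n_slices, false, true);
  for (uword s = 0; s < Gc.n_slices; ++s) {
    vec rs = sum(Gc.slice(s) % Oc.slice(s), 1);
    Rc.slice(s) = (Gc.slice(s).each_col() - rs) % Oc.slice(s);
  }
  return out;
}

// row-wise layer normalization (no affine terms) within each slice
// [[Rcpp::export]]
Rcpp::NumericVector cube_layernorm_rows(const Rcpp::NumericVector& X,
                                        double eps = 1e-5) {
  cube Xc = view_cube(X);
  Rcpp::NumericVector out(X.size());
  out.attr("dim") = X.attr("dim");
  cube Oc(out.begin(), Xc.n_rows, Xc.n_cols, Xc.n_slices, false, true);
  for (uword s = 0; s < Xc.n_slices; ++s) {
    mat xc = Xc.slice(s).each_col() - mean(Xc.slice(s), 1);
    vec sd = sqrt(mean(xc % xc, 1) + eps);
    Oc.slice(s) = xc.each_col() / sd;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cube_layernorm_rows_grad(const Rcpp::NumericVector& G,
                                             const Rcpp::NumericVector& X,
                                             double eps = 1e-5) {
  cube Gc = view_cube(G), Xc = view_cube(X);
  Rcpp::NumericVector out(G.size());
  out.attr("dim") = G.attr("dim");
  cube Rc(out.begin(), Gc.n_rows, Gc.n_cols, Gc.n_slices, false, true);
  for (uword s = 0; s < Gc.n_slices; ++s) {
    mat xc = Xc.slice(s).each_col() - mean(Xc.slice(s), 1);
    vec sd = sqrt(mean(xc % xc, 1) + eps);
    mat y = xc.each_col() / sd;
    mat g = Gc.slice(s);
    mat tmp = (g.each_col() - mean(g, 1)) - (y.each_col() % mean(g % y, 1));
    Rc.slice(s) = tmp.each_col() / sd;
  }
  return out;
}
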