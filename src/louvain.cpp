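#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Greedy multi-level (Louvain-style) modularity maximization on a dense
// symmetric nonnegative matrix with resolution gamma.
//
// Convention: the aggregated matrix M stores M(c,c) = total internal weight
// counted twice, so row sums (including the diagonal) are community degrees
// and sum(M) == 2m is invariant across levels.
//
// Determinism: the level-0 node visit order is supplied by the caller;
// aggregated levels use natural order. Ties in the community gain are broken
// toward the smallest community index; moves need a gain > tol.

static const double TOL = 1e-12;

// one level of local moving; membership is modified in place, returns true
// if any node moved
static bool local_move(const arma::mat& M, arma::ivec& membership,
                       const arma::ivec& order, double gamma, double two_m) {
  const int n = M.n_rows;
  arma::vec k(n);                     // node degrees (incl. self weight)
  for (int i = 0; i < n; ++i) k(i) = arma::accu(M.row(i));
  arma::vec tot(n, arma::fill::zeros); // community total degrees
  for (int i = 0; i < n; ++i) tot(membership(i)) += k(i);

  bool any_move = false, improved = true;
  while (improved) {
    improved = false;
    for (int oi = 0; oi < n; ++oi) {
      const int i = order(oi);
      const int ci = membership(i);
      // links from i to each community (self weight excluded)
      arma::vec l(n, arma::fill::zeros);
      for (int j = 0; j < n; ++j)
        if (j != i) l(membership(j)) += M(i, j);
      const double base = l(ci) - gamma * k(i) * (tot(ci) - k(i)) / two_m;
      int best_c = ci;
      double best_gain = 0.0;
      int empty_c = -1;
      for (int c = 0; c < n; ++c) {
        if (c == ci) continue;
        if (l(c) == 0.0 && tot(c) == 0.0) {
          if (empty_c < 0) empty_c = c;  // candidate for splitting i off
          continue;
        }
        double gain = l(c) - gamma * k(i) * tot(c) / two_m - base;
        if (gain > best_gain + TOL ||
            (gain > best_gain - TOL && best_gain > TOL && c < best_c)) {
          best_gain = gain;
          best_c = c;
        }
      }
      // moving i into a fresh singleton community gains -base
      if (empty_c >= 0 && tot(ci) > k(i) && -base > best_gain + TOL) {
        best_gain = -base;
        best_c = empty_c;
      }
      if (best_c != ci) {
        tot(ci) -= k(i);
        tot(best_c) += k(i);
        membership(i) = best_c;
        improved = true;
        any_move = true;
      }
    }
  }
  return any_move;
}

// [[Rcpp::export]]
IntegerVector louvain_membership(const arma::mat& W, double gamma,
                                 const IntegerVector& order0) {
  const int n0 = W.n_rows;
  const double two_m = arma::accu(W);
  if (two_m <= 0.0) return IntegerVector(n0, 0);

  arma::ivec node_comm(n0);           // community of each original node
  for (int i = 0; i < n0; ++i) node_comm(i) = i;

  arma::mat M = W;
  arma::ivec order(n0), order_orig(n0);
  for (int i = 0; i < n0; ++i) order(i) = order_orig(i) = order0[i] - 1;

  while (true) {
    const int n = M.n_rows;
    arma::ivec membership(n);
    for (int i = 0; i < n; ++i) membership(i) = i;
    bool moved = local_move(M, membership, order, gamma, two_m);
    if (!moved) break;

    // compact labels
    arma::ivec relabel(n, arma::fill::value(-1));
    int nc = 0;
    for (int i = 0; i < n; ++i)
      if (relabel(membership(i)) < 0) relabel(membership(i)) = nc++;
    for (int i = 0; i < n; ++i) membership(i) = relabel(membership(i));
    for (int i = 0; i < n0; ++i) node_comm(i) = membership(node_comm(i));
    if (nc == n) break;

    // aggregate
    arma::mat A(nc, nc, arma::fill::zeros);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        A(membership(i), membership(j)) += M(i, j);
    M = A;
    order.set_size(nc);
    for (int i = 0; i < nc; ++i) order(i) = i;
  }

  // final refinement at the original scale: single-node moves (including
  // splits into fresh communities) from the multi-level solution
  {
    arma::ivec memb = node_comm;
    local_move(W, memb, order_orig, gamma, two_m);
    node_comm = memb;
  }

  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) out[i] = node_comm(i) + 1;
  return out;
}
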