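// Felsenstein pruning over 61 codon states, with per-pattern scaling.
// Trees arrive as ape-style edge matrices in postorder; P matrices are
// precomputed per edge in R (eigendecomposition of the reversible GY94
// generator) and passed in as a cube.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int NS = 61;

// build tip partial matrix (NS x npat) for tip `tip` (1-based codon
// index per pattern, 0 = missing -> all ones)
static arma::mat tip_partial(const IntegerMatrix& patterns, int tip_row,
                             int npat) {
  arma::mat L(NS, npat, arma::fill::zeros);
  for (int p = 0; p < npat; ++p) {
    int st = patterns(tip_row, p);
    if (st == 0) {
      L.col(p).ones();
    } else {
      L(st - 1, p) = 1.0;
    }
  }
  return L;
}

// [[Rcpp::export]]
NumericVector cpp_codon_loglik(IntegerMatrix edge, NumericVector Pcube,
                               IntegerMatrix patterns, NumericVector pi,
                               int nnode, int ntip) {
  const int E = edge.nrow();
  const int npat = patterns.ncol();
  arma::cube P(Pcube.begin(), NS, NS, E, false);
  arma::vec piv(pi.begin(), NS);

  std::vector<arma::mat> part(nnode + 1);
  std::vector<bool> has(nnode + 1, false);
  arma::rowvec offset(npat, arma::fill::zeros);

  for (int e = 0; e < E; ++e) {
    int par = edge(e, 0);
    int chi = edge(e, 1);
    arma::mat Lc = (chi <= ntip) ? tip_partial(patterns, chi - 1, npat)
                                 : part[chi];
    arma::mat tmp = P.slice(e) * Lc;
    if (!has[par]) {
      part[par] = tmp;
      has[par] = true;
    } else {
      part[par] %= tmp;
    }
    // rescale the parent's partial to guard against underflow
    arma::rowvec m = arma::max(part[par], 0);
    for (int p = 0; p < npat; ++p) {
      if (m(p) > 0 && (m(p) < 1e-200 || m(p) > 1e200)) {
        part[par].col(p) /= m(p);
        offset(p) += std::log(m(p));
      }
    }
  }
  int root = edge(E - 1, 0);
  NumericVector out(npat);
  for (int p = 0; p < npat; ++p) {
    double s = arma::dot(piv, part[root].col(p));
    out[p] = (s > 0) ? std::log(s) + offset(p) : R_NegInf;
  }
  return out;
}

// Per-edge conditional partials for branch-length line search:
// for edge e = (parent, child) returns
//   L  = clade partial below `child` (at the child end of the edge)
//   R  = partial of everything else, evaluated at the parent end
//        (root prior included), so that the per-pattern likelihood is
//        sum_ij R_i P(t)_ij L_j, up to exp(offset).
// [[Rcpp::export]]
List cpp_codon_edge_partials(IntegerMatrix edge, NumericVector Pcube,
                             IntegerMatrix patterns, NumericVector pi,
                             int nnode, int ntip) {
  const int E = edge.nrow();
  const int npat = patterns.ncol();
  arma::cube P(Pcube.begin(), NS, NS, E, false);
  arma::vec piv(pi.begin(), NS);

  // post-order: clade partials and per-edge P * L_child products
  std::vector<arma::mat> part(nnode + 1);
  std::vector<bool> has(nnode + 1, false);
  arma::mat nodeoff(npat, nnode + 1, arma::fill::zeros);
  arma::cube tmp(NS, npat, E);
  arma::cube Lout(NS, npat, E);
  arma::mat tmpoff(npat, E, arma::fill::zeros);

  for (int e = 0; e < E; ++e) {
    int par = edge(e, 0);
    int chi = edge(e, 1);
    arma::mat Lc = (chi <= ntip) ? tip_partial(patterns, chi - 1, npat)
                                 : part[chi];
    Lout.slice(e) = Lc;
    tmp.slice(e) = P.slice(e) * Lc;
    arma::vec choff = (chi <= ntip) ? arma::vec(npat, arma::fill::zeros)
                                    : arma::vec(nodeoff.col(chi));
    tmpoff.col(e) = choff;
    if (!has[par]) {
      part[par] = tmp.slice(e);
      nodeoff.col(par) = choff;
      has[par] = true;
    } else {
      part[par] %= tmp.slice(e);
      nodeoff.col(par) += choff;
    }
    arma::rowvec m = arma::max(part[par], 0);
    for (int p = 0; p < npat; ++p) {
      if (m(p) > 0 && m(p) < 1e-150) {
        part[par].col(p) /= m(p);
        nodeoff(p, par) += std::log(m(p));
      }
    }
  }
  int root = edge(E - 1, 0);

  // children lists
  std::vector<std::vector<int>> child_edges(nnode + 1);
  for (int e = 0; e < E; ++e) child_edges[edge(e, 0)].push_back(e);

  // pre-order: above-partials A per node, R per edge
  std::vector<arma::mat> A(nnode + 1);
  arma::mat Aoff(npat, nnode + 1, arma::fill::zeros);
  A[root] = arma::repmat(piv, 1, npat);
  arma::cube Rout(NS, npat, E);
  arma::mat offset(npat, E, arma::fill::zeros);

  for (int e = E - 1; e >= 0; --e) {
    int par = edge(e, 0);
    int chi = edge(e, 1);
    arma::mat R = A[par];
    arma::vec roff = arma::vec(Aoff.col(par));
    for (int s : child_edges[par]) {
      if (s == e) continue;
      R %= tmp.slice(s);
      roff += arma::vec(tmpoff.col(s));
    }
    // rescale
    arma::rowvec m = arma::max(R, 0);
    for (int p = 0; p < npat; ++p) {
      if (m(p) > 0 && m(p) < 1e-150) {
        R.col(p) /= m(p);
        roff(p) += std::log(m(p));
      }
    }
    Rout.slice(e) = R;
    // offset of the edge objective: R side plus L side
    arma::vec loff = (chi <= ntip) ? arma::vec(npat, arma::fill::zeros)
                                   : arma::vec(nodeoff.col(chi));
    offset.col(e) = roff + loff;
    if (chi > ntip) {
      A[chi] = P.slice(e).t() * R;
      Aoff.col(chi) = roff;
    }
  }

  return List::create(_["L"] = Lout, _["R"] = Rout, _["offset"] = offset);
}
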