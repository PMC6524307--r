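// Hot kernels: exhaustive in-window block matching and batch orthogonal
// matching pursuit. Everything else lives in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the feature matrix used by the match distance: one column per
// candidate anchor (all integer positions, row-major order). Features are
// raw block pixels when lam2d == 0, otherwise 2D-transformed and
// hard-thresholded blocks (w2d is the analysis matrix, threshold lam2d).
// Either way the squared column distance / n_block^2 equals the
// prefilter distance.
static arma::mat candidate_features(const arma::mat& img, int nb,
                                    const arma::mat& w2d, double lam2d) {
  const int nr = img.n_rows - nb + 1;
  const int nc = img.n_cols - nb + 1;
  arma::mat feat(nb * nb, (size_t)nr * nc);
  arma::mat block(nb, nb), tb(nb, nb);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      block = img.submat(r, c, r + nb - 1, c + nb - 1);
      size_t col = (size_t)r * nc + c;  // row-major anchor index
      if (lam2d > 0) {
        tb = w2d * block * w2d.t();
        tb.for_each([lam2d](double& v) { if (std::abs(v) <= lam2d) v = 0; });
        feat.col(col) = arma::vectorise(tb);
      } else {
        feat.col(col) = arma::vectorise(block);
      }
    }
  }
  return feat;
}

// Match one reference anchor against every candidate anchored inside the
// window x window box centred on it (clipped at the borders).
// Members: reference first, then remaining candidates ordered by
// (distance, row-major scan order), subject to the tau filter unless
// exact_depth, truncated to n_number.
static void match_one(const arma::mat& feat, int nr, int nc, int nb,
                      int ref_r, int ref_c, int n_number, int window,
                      double tau, bool exact_depth,
                      std::vector<int>& out_r, std::vector<int>& out_c,
                      std::vector<double>& out_d) {
  const int half = (window - 1) / 2;
  const int r0 = std::max(0, ref_r - half), r1 = std::min(nr - 1, ref_r + half);
  const int c0 = std::max(0, ref_c - half), c1 = std::min(nc - 1, ref_c + half);
  const double n2 = (double)nb * nb;
  const arma::vec ref_feat = feat.col((size_t)ref_r * nc + ref_c);

  std::vector<int> cr, cc;
  std::vector<double> cd;
  cr.reserve((r1 - r0 + 1) * (c1 - c0 + 1));
  for (int r = r0; r <= r1; ++r) {
    for (int c = c0; c <= c1; ++c) {
      if (r == ref_r && c == ref_c) continue;
      double d = arma::accu(arma::square(feat.col((size_t)r * nc + c)
                                         - ref_feat)) / n2;
      if (!exact_depth && d > tau) continue;
      cr.push_back(r); cc.push_back(c); cd.push_back(d);
    }
  }
  std::vector<size_t> ord(cd.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&cd](size_t a, size_t b) { return cd[a] < cd[b]; });

  out_r.clear(); out_c.clear(); out_d.clear();
  out_r.push_back(ref_r); out_c.push_back(ref_c); out_d.push_back(0.0);
  for (size_t k = 0; k < ord.size() && (int)out_r.size() < n_number; ++k) {
    out_r.push_back(cr[ord[k]]);
    out_c.push_back(cc[ord[k]]);
    out_d.push_back(cd[ord[k]]);
  }
}

// [[Rcpp::export(name = ".cpp_block_match")]]
List cpp_block_match(const arma::mat& img, const arma::ivec& anchors_r,
                     const arma::ivec& anchors_c, int n_block, int n_number,
                     int window, double tau, double lam2d,
                     const arma::mat& w2d, bool exact_depth) {
  const int nr = img.n_rows - n_block + 1;
  const int nc = img.n_cols - n_block + 1;
  if (nr < 1 || nc < 1) stop("image smaller than the block size");
  arma::mat feat = candidate_features(img, n_block, w2d, lam2d);

  const int n_ref = anchors_r.n_elem * anchors_c.n_elem;
  List members(n_ref), dists(n_ref);
  IntegerMatrix refs(n_ref, 2);
  std::vector<int> mr, mc;
  std::vector<double> md;
  int g = 0;
  for (arma::uword i = 0; i < anchors_r.n_elem; ++i) {
    for (arma::uword j = 0; j < anchors_c.n_elem; ++j, ++g) {
      int rr = anchors_r[i], rc = anchors_c[j];
      if (rr < 0 || rr >= nr || rc < 0 || rc >= nc)
        stop("reference block out of bounds");
      match_one(feat, nr, nc, n_block, rr, rc, n_number, window, tau,
                exact_depth, mr, mc, md);
      refs(g, 0) = rr; refs(g, 1) = rc;
      IntegerMatrix mm(mr.size(), 2);
      for (size_t k = 0; k < mr.size(); ++k) {
        mm(k, 0) = mr[k]; mm(k, 1) = mc[k];
      }
      members[g] = mm;
      dists[g] = NumericVector(md.begin(), md.end());
    }
  }
  return List::create(_["ref"] = refs, _["members"] = members,
                      _["distances"] = dists);
}

// Batch orthogonal matching pursuit: one column of X per signal.
// Greedy atom selection by largest absolute correlation with the
// residual (ties resolved to the lowest index), least-squares refit on
// the selected set, stop at cdfr atoms or when the residual l2 norm
// drops to tol_rel * ||x||.
// [[Rcpp::export(name = ".cpp_omp_batch")]]
List cpp_omp_batch(const arma::mat& D, const arma::mat& X, int cdfr,
                   double tol_rel) {
  if (D.n_rows != X.n_rows) stop("signal length does not match atom length");
  if (cdfr < 1) stop("sparsity cap must be >= 1");
  const arma::uword G = X.n_cols;
  List idx_out(G), coef_out(G);
  NumericVector rnorm_out(G);
  arma::vec r, x, corr, alpha;
  for (arma::uword g = 0; g < G; ++g) {
    x = X.col(g);
    r = x;
    const double tol = tol_rel * arma::norm(x);
    std::vector<arma::uword> sel;
    arma::uvec selv;
    while ((int)sel.size() < cdfr && arma::norm(r) > tol) {
      corr = D.t() * r;
      for (arma::uword s : sel) corr[s] = 0;  // never re-pick an atom
      arma::uword best = 0;
      double bestv = -1.0;
      for (arma::uword k = 0; k < corr.n_elem; ++k) {
        double a = std::abs(corr[k]);
        if (a > bestv) { bestv = a; best = k; }
      }
      if (bestv <= 1e-14) break;  // residual orthogonal to the dictionary
      sel.push_back(best);
      selv = arma::uvec(sel);
      alpha = arma::solve(D.cols(selv), x);
      r = x - D.cols(selv) * alpha;
    }
    if (sel.empty()) {
      idx_out[g] = IntegerVector(0);
      coef_out[g] = NumericVector(0);
      rnorm_out[g] = arma::norm(x);
    } else {
      IntegerVector iv(sel.size());
      NumericVector cv(sel.size());
      for (size_t k = 0; k < sel.size(); ++k) {
        iv[k] = sel[k] + 1;  // 1-based for R
        cv[k] = alpha[k];
      }
      idx_out[g] = iv;
      coef_out[g] = cv;
      rnorm_out[g] = arma::norm(r);
    }
  }
  return List::create(_["indices"] = idx_out, _["coeffs"] = coef_out,
                      _["residual_norm"] = rnorm_out);
}
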