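// Sum-of-trees sampler: backfitting MCMC with grow/prune/change proposals,
// conjugate normal leaves, and probit latent augmentation for binary outcomes.
// All randomness goes through R's RNG so set.seed() controls a fit end to end.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int var;     // -1 leaf, -2 dead slot, >=0 split feature (0-based)
  double cut;  // split value: x <= cut goes left
  int left, right, parent;
  int depth;
  double mu;
};

typedef std::vector<Node> Tree;

double psplit(double alpha, double beta, int depth) {
  return alpha * std::pow(1.0 + depth, -beta);
}

// log integrated likelihood of one leaf (constant terms that cancel in
// ratios are dropped): residual count n and sum s under N(mu, sigma2),
// mu ~ N(0, tau2)
double lml(double n, double s, double sigma2, double tau2) {
  double d = sigma2 + n * tau2;
  return 0.5 * std::log(sigma2 / d) + tau2 * s * s / (2.0 * sigma2 * d);
}

void collect(const Tree& tr, std::vector<int>& leaves, std::vector<int>& nogs) {
  leaves.clear();
  nogs.clear();
  for (size_t i = 0; i < tr.size(); ++i) {
    const Node& nd = tr[i];
    if (nd.var == -2) continue;
    if (nd.var == -1) {
      leaves.push_back((int)i);
    } else if (tr[nd.left].var == -1 && tr[nd.right].var == -1) {
      nogs.push_back((int)i);
    }
  }
}

int runif_int(int k) {  // uniform on 0..k-1
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

// one Metropolis-Hastings structural move on one tree
void propose_move(Tree& tr, std::vector<int>& assign,
                  const NumericMatrix& X,
                  const std::vector<std::vector<double> >& cutvals,
                  const std::vector<double>& r,
                  double sigma2, double tau2,
                  double alpha, double beta,
                  double pgrow, double pprune,
                  int minobs) {
  std::vector<int> leaves, nogs;
  collect(tr, leaves, nogs);
  const int n = X.nrow(), p = X.ncol();
  const double u = unif_rand();

  if (u < pgrow) {
    int b = leaves[runif_int((int)leaves.size())];
    int v = runif_int(p);
    if (cutvals[v].empty()) return;
    double cv = cutvals[v][runif_int((int)cutvals[v].size())];
    double nL = 0, sL = 0, nR = 0, sR = 0;
    for (int i = 0; i < n; ++i) {
      if (assign[i] != b) continue;
      if (X(i, v) <= cv) { nL += 1; sL += r[i]; } else { nR += 1; sR += r[i]; }
    }
    if (nL < minobs || nR < minobs) return;
    int d = tr[b].depth;
    double ps = psplit(alpha, beta, d), psc = psplit(alpha, beta, d + 1);
    int nognew = (int)nogs.size() + 1;
    int par = tr[b].parent;
    if (par >= 0) {
      int sib = (tr[par].left == b) ? tr[par].right : tr[par].left;
      if (tr[sib].var == -1) nognew -= 1;  // parent stops being no-grandchild
    }
    double logA = std::log(ps) + 2.0 * std::log(1.0 - psc) - std::log(1.0 - ps)
      + lml(nL, sL, sigma2, tau2) + lml(nR, sR, sigma2, tau2)
      - lml(nL + nR, sL + sR, sigma2, tau2)
      + std::log(pprune) - std::log((double)nognew)
      - std::log(pgrow) + std::log((double)leaves.size());
    if (std::log(unif_rand()) < logA) {
      Node ch; ch.var = -1; ch.cut = 0; ch.left = ch.right = -1;
      ch.parent = b; ch.depth = d + 1; ch.mu = 0;
      tr.push_back(ch); int li = (int)tr.size() - 1;
      tr.push_back(ch); int ri = (int)tr.size() - 1;
      tr[b].var = v; tr[b].cut = cv; tr[b].left = li; tr[b].right = ri;
      for (int i = 0; i < n; ++i)
        if (assign[i] == b) assign[i] = (X(i, v) <= cv) ? li : ri;
    }
  } else if (u < pgrow + pprune) {
    if (nogs.empty()) return;
    int g = nogs[runif_int((int)nogs.size())];
    int li = tr[g].left, ri = tr[g].right;
    double nL = 0, sL = 0, nR = 0, sR = 0;
    for (int i = 0; i < n; ++i) {
      if (assign[i] == li) { nL += 1; sL += r[i]; }
      else if (assign[i] == ri) { nR += 1; sR += r[i]; }
    }
    int d = tr[g].depth;
    double ps = psplit(alpha, beta, d), psc = psplit(alpha, beta, d + 1);
    int nleavesnew = (int)leaves.size() - 1;
    double logA = -(std::log(ps) + 2.0 * std::log(1.0 - psc) - std::log(1.0 - ps))
      + lml(nL + nR, sL + sR, sigma2, tau2)
      - lml(nL, sL, sigma2, tau2) - lml(nR, sR, sigma2, tau2)
      + std::log(pgrow) - std::log((double)nleavesnew)
      - std::log(pprune) + std::log((double)nogs.size());
    if (std::log(unif_rand()) < logA) {
      tr[li].var = -2; tr[ri].var = -2;
      tr[g].var = -1; tr[g].left = tr[g].right = -1;
      for (int i = 0; i < n; ++i)
        if (assign[i] == li || assign[i] == ri) assign[i] = g;
    }
  } else {
    // change the split rule of a node whose children are both leaves;
    // uniform rule prior and symmetric proposal cancel, leaving the
    // likelihood ratio
    if (nogs.empty()) return;
    int g = nogs[runif_int((int)nogs.size())];
    int v = runif_int(p);
    if (cutvals[v].empty()) return;
    double cv = cutvals[v][runif_int((int)cutvals[v].size())];
    int li = tr[g].left, ri = tr[g].right;
    double nLo = 0, sLo = 0, nRo = 0, sRo = 0;
    double nLn = 0, sLn = 0, nRn = 0, sRn = 0;
    for (int i = 0; i < n; ++i) {
      bool inL = (assign[i] == li), inR = (assign[i] == ri);
      if (!inL && !inR) continue;
      if (inL) { nLo += 1; sLo += r[i]; } else { nRo += 1; sRo += r[i]; }
      if (X(i, v) <= cv) { nLn += 1; sLn += r[i]; } else { nRn += 1; sRn += r[i]; }
    }
    if (nLn < minobs || nRn < minobs) return;
    double logA = lml(nLn, sLn, sigma2, tau2) + lml(nRn, sRn, sigma2, tau2)
      - lml(nLo, sLo, sigma2, tau2) - lml(nRo, sRo, sigma2, tau2);
    if (std::log(unif_rand()) < logA) {
      tr[g].var = v; tr[g].cut = cv;
      for (int i = 0; i < n; ++i)
        if (assign[i] == li || assign[i] == ri)
          assign[i] = (X(i, v) <= cv) ? li : ri;
    }
  }
}

}  // namespace

// Returns a list with the stored forest (one row per node:
// draw, tree, node, var, cut, left, right, mu; ids 1-based, var 0 = leaf),
// sigma draws (continuous mode), and per-draw in-sample sums of trees.
// [[Rcpp::export]]
List bart_mcmc_cpp(NumericMatrix X, NumericVector y, int type,
                   int ntree, int nburn, int ndraw,
                   double alpha, double beta, double tau2,
                   double nu, double lambda, double sigma2_init,
                   double pgrow, double pprune,
                   int numcut, int minobs, double offset) {
  RNGScope scope;
  const int n = X.nrow(), p = X.ncol();

  // cutpoint grids: midpoints of consecutive unique values, thinned to
  // at most numcut per feature (binary features get their single midpoint)
  std::vector<std::vector<double> > cutvals(p);
  for (int j = 0; j < p; ++j) {
    std::vector<double> v(n);
    for (int i = 0; i < n; ++i) v[i] = X(i, j);
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
    int m = (int)v.size();
    if (m < 2) continue;
    if (m - 1 <= numcut) {
      for (int k = 0; k + 1 < m; ++k) cutvals[j].push_back(0.5 * (v[k] + v[k + 1]));
    } else {
      for (int k = 1; k <= numcut; ++k) {
        int idx = (int)std::floor((double)k * (m - 1) / (numcut + 1.0));
        if (idx > m - 2) idx = m - 2;
        cutvals[j].push_back(0.5 * (v[idx] + v[idx + 1]));
      }
      cutvals[j].erase(std::unique(cutvals[j].begin(), cutvals[j].end()),
                       cutvals[j].end());
    }
  }

  std::vector<Tree> trees(ntree);
  std::vector<std::vector<int> > assign(ntree, std::vector<int>(n, 0));
  for (int t = 0; t < ntree; ++t) {
    Node root; root.var = -1; root.cut = 0; root.left = root.right = -1;
    root.parent = -1; root.depth = 0; root.mu = 0;
    trees[t].push_back(root);
  }
  std::vector<std::vector<double> > treefit(ntree, std::vector<double>(n, 0.0));
  std::vector<double> allfit(n, 0.0), r(n), yt(n);
  double sigma2 = (type == 1) ? 1.0 : sigma2_init;
  if (type == 0) for (int i = 0; i < n; ++i) yt[i] = y[i];

  std::vector<double> out_rows;  // flat forest storage
  out_rows.reserve((size_t)ndraw * ntree * 8 * 3);
  NumericVector sigma_draws(ndraw);
  NumericMatrix trainfit(ndraw, n);

  std::vector<int> leaves, nogs;
  for (int it = 0; it < nburn + ndraw; ++it) {
    if (type == 1) {
      // probit latent draws z ~ N(G + offset, 1) truncated by the label,
      // via stable tail-quantile sampling
      for (int i = 0; i < n; ++i) {
        double m = allfit[i] + offset;
        double uu = unif_rand(), z;
        if (y[i] > 0.5) {
          double pup = R::pnorm(0.0, m, 1.0, 0, 0);  // P(Z > 0)
          z = m + R::qnorm(uu * pup, 0.0, 1.0, 0, 0);
        } else {
          double plo = R::pnorm(0.0, m, 1.0, 1, 0);  // P(Z < 0)
          z = m + R::qnorm(uu * plo, 0.0, 1.0, 1, 0);
        }
        if (!std::isfinite(z)) z = (y[i] > 0.5) ? std::max(0.0, m) : std::min(0.0, m);
        yt[i] = z - offset;
      }
    }

    for (int t = 0; t < ntree; ++t) {
      for (int i = 0; i < n; ++i) r[i] = yt[i] - (allfit[i] - treefit[t][i]);
      propose_move(trees[t], assign[t], X, cutvals, r, sigma2, tau2,
                   alpha, beta, pgrow, pprune, minobs);
      // redraw leaf values from their conjugate posteriors
      collect(trees[t], leaves, nogs);
      std::vector<double> cnt(leaves.size(), 0.0), sum(leaves.size(), 0.0);
      std::vector<int> leafpos(trees[t].size(), -1);
      for (size_t l = 0; l < leaves.size(); ++l) leafpos[leaves[l]] = (int)l;
      for (int i = 0; i < n; ++i) {
        int l = leafpos[assign[t][i]];
        cnt[l] += 1; sum[l] += r[i];
      }
      for (size_t l = 0; l < leaves.size(); ++l) {
        double d = sigma2 + cnt[l] * tau2;
        double pm = tau2 * sum[l] / d;
        double pv = sigma2 * tau2 / d;
        trees[t][leaves[l]].mu = pm + norm_rand() * std::sqrt(pv);
      }
      for (int i = 0; i < n; ++i) {
        double nf = trees[t][assign[t][i]].mu;
        allfit[i] += nf - treefit[t][i];
        treefit[t][i] = nf;
      }
    }

    if (type == 0) {
      double ssr = 0.0;
      for (int i = 0; i < n; ++i) { double e = yt[i] - allfit[i]; ssr += e * e; }
      sigma2 = (nu * lambda + ssr) / R::rchisq(nu + n);
    }

    if (it >= nburn) {
      int d = it - nburn;
      sigma_draws[d] = std::sqrt(sigma2);
      for (int i = 0; i < n; ++i) trainfit(d, i) = allfit[i];
      for (int t = 0; t < ntree; ++t) {
        // compact alive nodes in index order, remapping child pointers
        const Tree& tr = trees[t];
        std::vector<int> remap(tr.size(), -1);
        int nid = 0;
        for (size_t k = 0; k < tr.size(); ++k)
          if (tr[k].var != -2) remap[k] = ++nid;  // 1-based
        for (size_t k = 0; k < tr.size(); ++k) {
          const Node& nd = tr[k];
          if (nd.var == -2) continue;
          out_rows.push_back(d + 1);
          out_rows.push_back(t + 1);
          out_rows.push_back(remap[k]);
          out_rows.push_back(nd.var < 0 ? 0 : nd.var + 1);
          out_rows.push_back(nd.var < 0 ? 0.0 : nd.cut);
          out_rows.push_back(nd.var < 0 ? 0 : remap[nd.left]);
          out_rows.push_back(nd.var < 0 ? 0 : remap[nd.right]);
          out_rows.push_back(nd.mu);
        }
      }
    }
  }

  size_t nrows = out_rows.size() / 8;
  NumericMatrix forest((int)nrows, 8);
  for (size_t i = 0; i < nrows; ++i)
    for (int j = 0; j < 8; ++j) forest((int)i, j) = out_rows[i * 8 + j];
  colnames(forest) = CharacterVector::create("draw", "tree", "node", "var",
                                             "cut", "left", "right", "mu");
  return List::create(_["forest"] = forest,
                      _["sigma"] = sigma_draws,
                      _["trainfit"] = trainfit);
}

// Evaluate a stored forest on new rows. Rows of `forest` must be grouped by
// draw then tree with nodes in id order (as emitted by bart_mcmc_cpp).
// Returns an ndraw x nrow(Xnew) matrix of sums of trees (no offset, no link).
// [[Rcpp::export]]
NumericMatrix forest_predict_cpp(NumericMatrix forest, NumericMatrix Xnew,
                                 int ndraw) {
  const int nr = forest.nrow(), nn = Xnew.nrow();
  NumericMatrix out(ndraw, nn);
  int row = 0;
  while (row < nr) {
    int d = (int)forest(row, 0);
    int start = row;
    // find extent of this (draw, tree) block
    double tree = forest(row, 1);
    while (row < nr && (int)forest(row, 0) == d && forest(row, 1) == tree) ++row;
    int blocklen = row - start;
    (void)blocklen;
    for (int i = 0; i < nn; ++i) {
      int node = 1;
      for (;;) {
        int ridx = start + node - 1;
        int v = (int)forest(ridx, 3);
        if (v == 0) { out(d - 1, i) += forest(ridx, 7); break; }
        node = (Xnew(i, v - 1) <= forest(ridx, 4))
                 ? (int)forest(ridx, 5) : (int)forest(ridx, 6);
      }
    }
  }
  return out;
}
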