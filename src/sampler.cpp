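#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Bernoulli log-likelihood contribution of one row at linear predictor e
static inline double row_ll(int y, double e) {
  return y * e - log1pexp_(e);
}

// Log posterior of the hierarchical dyadic model in natural (centred)
// parameters. Random effects enter as a_k ~ N(0, sg), b_i ~ N(0, si),
// c_d ~ N(0, sd), and for directional behaviour d_j ~ N(0, sr).
// Fixed effects and covariate coefficients have N(0, prior_sd) priors,
// standard deviations have U(0, sig_upper) priors.
// [[Rcpp::export]]
double cpp_log_posterior(IntegerVector y, IntegerVector yprev,
                         IntegerVector g, IntegerVector i1, IntegerVector i2,
                         IntegerVector dd, NumericMatrix X,
                         double alpha, double beta, NumericVector delta,
                         NumericVector a, NumericVector b, NumericVector c,
                         NumericVector drec,
                         double sg, double si, double sdy, double sr,
                         bool directional, double prior_sd, double sig_upper) {
  const int n = y.size(), p = delta.size();
  if (sg <= 0.0 || sg > sig_upper || si <= 0.0 || si > sig_upper ||
      sdy <= 0.0 || sdy > sig_upper)
    return R_NegInf;
  if (directional && (sr <= 0.0 || sr > sig_upper)) return R_NegInf;

  double lp = 0.0;
  for (int r = 0; r < n; ++r) {
    double e = alpha + beta * yprev[r] + a[g[r]] + c[dd[r]];
    e += directional ? (b[i1[r]] + drec[i2[r]]) : (b[i1[r]] + b[i2[r]]);
    for (int j = 0; j < p; ++j) e += X(r, j) * delta[j];
    lp += row_ll(y[r], e);
  }
  for (int k = 0; k < a.size(); ++k) lp += R::dnorm(a[k], 0.0, sg, 1);
  for (int k = 0; k < b.size(); ++k) lp += R::dnorm(b[k], 0.0, si, 1);
  for (int k = 0; k < c.size(); ++k) lp += R::dnorm(c[k], 0.0, sdy, 1);
  if (directional)
    for (int k = 0; k < drec.size(); ++k) lp += R::dnorm(drec[k], 0.0, sr, 1);
  lp += R::dnorm(alpha, 0.0, prior_sd, 1) + R::dnorm(beta, 0.0, prior_sd, 1);
  for (int j = 0; j < p; ++j) lp += R::dnorm(delta[j], 0.0, prior_sd, 1);
  int nsig = directional ? 4 : 3;
  lp += -nsig * std::log(sig_upper);
  return lp;
}

// One MCMC chain: adaptive random-walk Metropolis-within-Gibbs on the
// non-centred parameterization (z-scores for every random effect, the
// SDs as scale factors). Proposal scales adapt towards 0.44 acceptance
// during warmup only. Draws are stored on the natural scale.
//
// trans_moves: optional exact eta-invariant translation moves between a
// weighted set of random-effect entries and the fixed effects. Each
// element is a list with parallel vectors `blk` (0 = b, 1 = d, 2 = c),
// `idx` (0-based entry within its block) and `w` (natural-scale weight),
// plus `lambda0` and `lambda` (length ncol(X)): for every data row the
// summed weight of participating entries equals lambda0 + X %*% lambda.
// The proposal shifts entry q by e * w_q on the natural scale (z shift
// e * w_q / sigma_block) and subtracts lambda0 * e from alpha and
// lambda_j * e from delta_j, leaving every linear predictor unchanged;
// only prior terms enter the Metropolis ratio.
// [[Rcpp::export]]
List cpp_fit_chain(IntegerVector y, IntegerVector yprev,
                   IntegerVector g, IntegerVector i1, IntegerVector i2,
                   IntegerVector dd, NumericMatrix X,
                   int ng, int ni, int nd, bool directional,
                   double prior_sd, double sig_upper,
                   int n_iter, int n_warmup, int thin,
                   double init_jitter, List trans_moves) {
  const int n = y.size(), p = X.ncol();
  const int nsig = directional ? 4 : 3;

  // row index lists
  std::vector<std::vector<int>> rows_g(ng), rows_b(ni), rows_r(ni), rows_dy(nd), rows_x(p);
  std::vector<int> rows_lag;
  for (int r = 0; r < n; ++r) {
    rows_g[g[r]].push_back(r);
    rows_dy[dd[r]].push_back(r);
    rows_b[i1[r]].push_back(r);
    if (directional) rows_r[i2[r]].push_back(r);
    else rows_b[i2[r]].push_back(r);
    if (yprev[r] == 1) rows_lag.push_back(r);
    for (int j = 0; j < p; ++j) if (X(r, j) != 0.0) rows_x[j].push_back(r);
  }

  // state (non-centred)
  double alpha = init_jitter * norm_rand();
  double beta  = init_jitter * norm_rand();
  std::vector<double> delta(p);
  for (int j = 0; j < p; ++j) delta[j] = init_jitter * norm_rand();
  std::vector<double> az(ng), bz(ni), cz(nd), dz(directional ? ni : 0);
  for (auto& v : az) v = init_jitter * norm_rand();
  for (auto& v : bz) v = init_jitter * norm_rand();
  for (auto& v : cz) v = init_jitter * norm_rand();
  for (auto& v : dz) v = init_jitter * norm_rand();
  double sg = 1.0, si = 1.0, sdy = 1.0, sr = 1.0;

  std::vector<double> eta(n);
  auto eta_row = [&](int r) {
    double e = alpha + beta * yprev[r] + sg * az[g[r]] + sdy * cz[dd[r]];
    e += directional ? (si * bz[i1[r]] + sr * dz[i2[r]])
                     : (si * (bz[i1[r]] + bz[i2[r]]));
    for (int j = 0; j < p; ++j) e += X(r, j) * delta[j];
    return e;
  };
  for (int r = 0; r < n; ++r) eta[r] = eta_row(r);
  for (int r = 0; r < n; ++r)
    if (!std::isfinite(row_ll(y[r], eta[r])))
      stop("non-finite log likelihood at initialization (row %d)", r + 1);

  // unpack covariate-compensated translation moves
  const int nmv = trans_moves.size();
  std::vector<std::vector<int>> mv_blk(nmv), mv_idx(nmv);
  std::vector<double> mv_l0(nmv);
  std::vector<std::vector<double>> mv_lam(nmv), mv_w(nmv);
  for (int m = 0; m < nmv; ++m) {
    List mv = trans_moves[m];
    IntegerVector bb = mv["blk"];
    mv_blk[m] = std::vector<int>(bb.begin(), bb.end());
    IntegerVector ii = mv["idx"];
    mv_idx[m] = std::vector<int>(ii.begin(), ii.end());
    NumericVector wv = mv["w"];
    mv_w[m] = std::vector<double>(wv.begin(), wv.end());
    mv_l0[m] = as<double>(mv["lambda0"]);
    NumericVector lm = mv["lambda"];
    mv_lam[m] = std::vector<double>(lm.begin(), lm.end());
  }

  // proposal scales: [alpha, beta, delta(p), sigmas(nsig), az, bz, cz, dz,
  //                   translation moves (nsig), scale moves (nsig),
  //                   covariate-compensated moves (nmv)]
  const int npar = 2 + p + nsig + ng + ni + nd + (directional ? ni : 0) +
    2 * nsig + nmv;
  std::vector<double> lsc(npar, 0.0);
  for (int k = 2 + p + nsig; k < npar; ++k) lsc[k] = std::log(0.5);
  std::vector<double> acc_sum(npar, 0.0);
  std::vector<int> acc_n(npar, 0);

  int iter_now = 0;
  auto adapt = [&](int id, double aprob) {
    acc_sum[id] += aprob; acc_n[id] += 1;
    if (iter_now < n_warmup) {
      double gam = std::pow(iter_now + 2.0, -0.6);
      lsc[id] += gam * (aprob - 0.44);
      if (lsc[id] < -8) lsc[id] = -8;
      if (lsc[id] > 4) lsc[id] = 4;
    }
  };

  // constant-shift update over a row subset
  auto upd_shift = [&](int id, double& par, const std::vector<int>& rows,
                       double coef, double prior_prec) {
    double step = std::exp(lsc[id]) * norm_rand();
    double prop = par + step;
    double dlp = -0.5 * prior_prec * (prop * prop - par * par);
    double shift = coef * step;
    for (int r : rows) dlp += row_ll(y[r], eta[r] + shift) - row_ll(y[r], eta[r]);
    double ap = dlp >= 0 ? 1.0 : std::exp(dlp);
    if (unif_rand() < ap) {
      par = prop;
      for (int r : rows) eta[r] += shift;
    }
    adapt(id, ap);
  };

  const int n_keep = (n_iter - n_warmup) / thin;
  const int ncol_out = 2 + p + nsig + ng + ni + nd + (directional ? ni : 0);
  NumericMatrix out(n_keep, ncol_out);
  int kept = 0;

  std::vector<int> all_rows(n);
  for (int r = 0; r < n; ++r) all_rows[r] = r;
  const double fprec = 1.0 / (prior_sd * prior_sd);

  for (iter_now = 0; iter_now < n_iter; ++iter_now) {
    upd_shift(0, alpha, all_rows, 1.0, fprec);
    upd_shift(1, beta, rows_lag, 1.0, fprec);

    for (int j = 0; j < p; ++j) {
      int id = 2 + j;
      double step = std::exp(lsc[id]) * norm_rand();
      double prop = delta[j] + step;
      double dlp = -0.5 * fprec * (prop * prop - delta[j] * delta[j]);
      for (int r : rows_x[j]) {
        double shift = X(r, j) * step;
        dlp += row_ll(y[r], eta[r] + shift) - row_ll(y[r], eta[r]);
      }
      double ap = dlp >= 0 ? 1.0 : std::exp(dlp);
      if (unif_rand() < ap) {
        for (int r : rows_x[j]) eta[r] += X(r, j) * step;
        delta[j] = prop;
      }
      adapt(id, ap);
    }

    // sigma updates: eta shifts depend on the z values per row
    for (int sidx = 0; sidx < nsig; ++sidx) {
      int id = 2 + p + sidx;
      double* sp = sidx == 0 ? &sg : sidx == 1 ? &si : sidx == 2 ? &sdy : &sr;
      double step = std::exp(lsc[id]) * norm_rand();
      double prop = *sp + step;
      double ap;
      if (prop < 0.0 || prop > sig_upper) {
        ap = 0.0;
      } else {
        double dlp = 0.0;
        for (int r = 0; r < n; ++r) {
          double zr;
          if (sidx == 0) zr = az[g[r]];
          else if (sidx == 1) zr = directional ? bz[i1[r]] : (bz[i1[r]] + bz[i2[r]]);
          else if (sidx == 2) zr = cz[dd[r]];
          else zr = dz[i2[r]];
          double shift = step * zr;
          dlp += row_ll(y[r], eta[r] + shift) - row_ll(y[r], eta[r]);
        }
        ap = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (unif_rand() < ap) {
          for (int r = 0; r < n; ++r) {
            double zr;
            if (sidx == 0) zr = az[g[r]];
            else if (sidx == 1) zr = directional ? bz[i1[r]] : (bz[i1[r]] + bz[i2[r]]);
            else if (sidx == 2) zr = cz[dd[r]];
            else zr = dz[i2[r]];
            eta[r] += step * zr;
          }
          *sp = prop;
        }
      }
      adapt(id, ap);
    }

    int base = 2 + p + nsig;
    for (int k = 0; k < ng; ++k) upd_shift(base + k, az[k], rows_g[k], sg, 1.0);
    base += ng;
    for (int k = 0; k < ni; ++k) upd_shift(base + k, bz[k], rows_b[k], si, 1.0);
    base += ni;
    for (int k = 0; k < nd; ++k) upd_shift(base + k, cz[k], rows_dy[k], sdy, 1.0);
    base += nd;
    if (directional)
      for (int k = 0; k < ni; ++k) upd_shift(base + k, dz[k], rows_r[k], sr, 1.0);

    // interweaving moves along eta-invariant ridges: these cost no
    // likelihood evaluations and decorrelate the intercept and the SDs
    // from their random-effect blocks.
    base += directional ? ni : 0;
    {
      // translations: shift a whole z-block by a constant, compensate alpha
      // so every linear predictor is unchanged; only priors change.
      struct Blk { std::vector<double>* z; double coef; };
      std::vector<Blk> blocks;
      blocks.push_back({&az, sg});
      blocks.push_back({&bz, directional ? si : 2.0 * si});
      blocks.push_back({&cz, sdy});
      if (directional) blocks.push_back({&dz, sr});
      for (size_t t = 0; t < blocks.size(); ++t) {
        int id = base + (int)t;
        std::vector<double>& z = *blocks[t].z;
        double coef = blocks[t].coef;
        if (coef < 1e-12) { adapt(id, 0.0); continue; }
        double e = std::exp(lsc[id]) * norm_rand();   // shift of alpha
        double dz_shift = -e / coef;                   // shift of each z
        double anew = alpha + e;
        double dlp = -0.5 * fprec * (anew * anew - alpha * alpha);
        for (size_t k = 0; k < z.size(); ++k) {
          double znew = z[k] + dz_shift;
          dlp += -0.5 * (znew * znew - z[k] * z[k]);
        }
        double ap = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (unif_rand() < ap) {
          alpha = anew;
          for (size_t k = 0; k < z.size(); ++k) z[k] += dz_shift;
        }
        adapt(id, ap);
      }
      // scale moves: sigma *= r, z /= r (eta invariant); Jacobian r^(1-nz)
      struct SBlk { std::vector<double>* z; double* s; };
      std::vector<SBlk> sblocks;
      sblocks.push_back({&az, &sg});
      sblocks.push_back({&bz, &si});
      sblocks.push_back({&cz, &sdy});
      if (directional) sblocks.push_back({&dz, &sr});
      for (size_t t = 0; t < sblocks.size(); ++t) {
        int id = base + nsig + (int)t;
        std::vector<double>& z = *sblocks[t].z;
        double& s = *sblocks[t].s;
        double u = std::exp(lsc[id]) * norm_rand();
        double r = std::exp(u);
        double snew = s * r;
        double ap;
        if (snew <= 0.0 || snew > sig_upper) {
          ap = 0.0;
        } else {
          double dlp = (1.0 - (double)z.size()) * u;
          double fac = 1.0 / (r * r) - 1.0;
          for (size_t k = 0; k < z.size(); ++k)
            dlp += -0.5 * z[k] * z[k] * fac;
          ap = dlp >= 0 ? 1.0 : std::exp(dlp);
          if (unif_rand() < ap) {
            s = snew;
            for (size_t k = 0; k < z.size(); ++k) z[k] /= r;
          }
        }
        adapt(id, ap);
      }
    }

    // covariate-compensated translations: shift a sex/role subset of a
    // z-block, absorb the shift into alpha and the matching sex-class
    // coefficients; eta is unchanged, only priors enter the ratio
    {
      int mbase = 2 + p + nsig + ng + ni + nd + (directional ? ni : 0) +
        2 * nsig;
      for (int m = 0; m < nmv; ++m) {
        int id = mbase + m;
        const std::vector<int>& bb = mv_blk[m];
        const std::vector<int>& kk = mv_idx[m];
        const std::vector<double>& ww = mv_w[m];
        double sig_min = sig_upper;
        for (int bq : bb) {
          double c0 = bq == 0 ? si : bq == 1 ? sr : sdy;
          if (c0 < sig_min) sig_min = c0;
        }
        if (sig_min < 1e-12) { adapt(id, 0.0); continue; }
        double e = std::exp(lsc[id]) * norm_rand();  // per-unit-weight shift
        double dlp = 0.0;
        for (size_t q = 0; q < kk.size(); ++q) {
          double coef = bb[q] == 0 ? si : bb[q] == 1 ? sr : sdy;
          std::vector<double>& z = bb[q] == 0 ? bz : bb[q] == 1 ? dz : cz;
          double znew = z[kk[q]] + e * ww[q] / coef;
          dlp += -0.5 * (znew * znew - z[kk[q]] * z[kk[q]]);
        }
        double anew = alpha - mv_l0[m] * e;
        dlp += -0.5 * fprec * (anew * anew - alpha * alpha);
        for (int j = 0; j < p; ++j) {
          if (mv_lam[m][j] == 0.0) continue;
          double dnew = delta[j] - mv_lam[m][j] * e;
          dlp += -0.5 * fprec * (dnew * dnew - delta[j] * delta[j]);
        }
        double ap = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (unif_rand() < ap) {
          for (size_t q = 0; q < kk.size(); ++q) {
            double coef = bb[q] == 0 ? si : bb[q] == 1 ? sr : sdy;
            std::vector<double>& z = bb[q] == 0 ? bz : bb[q] == 1 ? dz : cz;
            z[kk[q]] += e * ww[q] / coef;
          }
          alpha = anew;
          for (int j = 0; j < p; ++j) delta[j] -= mv_lam[m][j] * e;
        }
        adapt(id, ap);
      }
    }

    if (iter_now >= n_warmup && ((iter_now - n_warmup) % thin == 0) && kept < n_keep) {
      int cc = 0;
      out(kept, cc++) = alpha;
      out(kept, cc++) = beta;
      for (int j = 0; j < p; ++j) out(kept, cc++) = delta[j];
      out(kept, cc++) = sg;
      out(kept, cc++) = si;
      out(kept, cc++) = sdy;
      if (directional) out(kept, cc++) = sr;
      for (int k = 0; k < ng; ++k) out(kept, cc++) = sg * az[k];
      for (int k = 0; k < ni; ++k) out(kept, cc++) = si * bz[k];
      for (int k = 0; k < nd; ++k) out(kept, cc++) = sdy * cz[k];
      if (directional)
        for (int k = 0; k < ni; ++k) out(kept, cc++) = sr * dz[k];
      kept += 1;
    }
    if (iter_now % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc(npar);
  for (int k = 0; k < npar; ++k)
    acc[k] = acc_n[k] > 0 ? acc_sum[k] / acc_n[k] : NA_REAL;
  return List::create(_["draws"] = out, _["accept"] = acc);
}

// Posterior-predictive clique-rate simulator. W holds one row of dyadic
// edge probabilities per posterior draw; di/dj are 0-based node indices of
// each dyad within the group. For each draw, n_scans scans are simulated
// with every dyad an independent Bernoulli edge, and the fraction of scans
// containing a connected component of >= 3 individuals is returned.
// If vis_counts is non-empty, each simulated scan restricts edges to a
// uniformly chosen subset of nodes whose size is drawn from vis_counts,
// matching the observed per-scan visibility distribution.
// [[Rcpp::export]]
NumericVector cpp_clique_rates(NumericMatrix W, IntegerVector di, IntegerVector dj,
                               int n_nodes, int n_scans, IntegerVector vis_counts) {
  const int nsim = W.nrow(), ndy = W.ncol(), nv = vis_counts.size();
  NumericVector rate(nsim);
  std::vector<int> parent(n_nodes), csize(n_nodes), nodes(n_nodes);
  std::vector<bool> vis(n_nodes);

  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  for (int s = 0; s < nsim; ++s) {
    int hits = 0;
    for (int sc = 0; sc < n_scans; ++sc) {
      if (nv > 0) {
        int k = vis_counts[(int)(unif_rand() * nv) % nv];
        if (k > n_nodes) k = n_nodes;
        for (int t = 0; t < n_nodes; ++t) { nodes[t] = t; vis[t] = false; }
        for (int t = 0; t < k; ++t) {
          int pick = t + (int)(unif_rand() * (n_nodes - t)) % (n_nodes - t);
          std::swap(nodes[t], nodes[pick]);
          vis[nodes[t]] = true;
        }
        if (k < 3) continue;
      } else {
        std::fill(vis.begin(), vis.end(), true);
      }
      for (int t = 0; t < n_nodes; ++t) { parent[t] = t; csize[t] = 1; }
      bool found = false;
      for (int e = 0; e < ndy; ++e) {
        if (!vis[di[e]] || !vis[dj[e]]) continue;
        if (unif_rand() < W(s, e)) {
          int ra = find(di[e]), rb = find(dj[e]);
          if (ra != rb) {
            parent[ra] = rb;
            csize[rb] += csize[ra];
            if (csize[rb] >= 3) { found = true; break; }
          }
        }
      }
      if (found) ++hits;
    }
    rate[s] = (double)hits / n_scans;
  }
  return rate;
}
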