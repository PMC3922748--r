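// Gibbs samplers for the latent-factor multi-trait animal model and the
// recursive structural equation model with pedigree-correlated genetic
// effects. All conditionals are conjugate: fixed effects, latent
// vectors, loadings and structural coefficients are normal; remaining
// variances are scaled-inverse-chi-square truncated to [floor, Inf),
// sampled by inverse-CDF so the bound is respected exactly (never
// clamped).
//
// The additive-genetic prior enters through the sparse precision matrix
// Q = A^-1. Pedigree-correlated vectors (factor scores w_k and per-trait
// remaining effects delta_i) are updated single-site with an
// incrementally maintained Q %*% vector product, which keeps one sweep
// at O(nnz(Q)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925286766559;

// tau2 ~ InvGamma(shape a, rate b) restricted to [lo, Inf)
static double rtrunc_invgamma(double a, double b, double lo) {
  if (b <= 0.0) return std::max(lo, 1e-12);
  if (lo <= 0.0) {
    double x = R::rgamma(a, 1.0);
    if (x <= 0.0) x = 1e-300;
    return b / x;
  }
  double ub = b / lo;                       // x = b / tau2 <= ub
  double p = R::pgamma(ub, a, 1.0, 1, 0);
  if (!std::isfinite(p) || p <= 0.0) return lo;
  double u = R::runif(0.0, p);
  double x = R::qgamma(u, a, 1.0, 1, 0);
  if (!std::isfinite(x) || x <= 0.0) return lo;
  double out = b / x;
  return (out < lo) ? lo : out;             // guard rounding at the bound
}

// one single-site sweep for a pedigree-correlated vector g (length m)
// with prior precision Q / tau2g and per-animal data precision dvec /
// data weight bvec (likelihood terms already divided by the residual
// variance). qg must equal Q * g on entry and is maintained.
static void sweep_correlated(arma::vec& g, arma::vec& qg,
                             const arma::sp_mat& Q, const arma::vec& qdiag,
                             const arma::vec& bvec, const arma::vec& dvec,
                             double tau2g) {
  const arma::uword m = g.n_elem;
  for (arma::uword a = 0; a < m; ++a) {
    double prior_prec = qdiag[a] / tau2g;
    double prec = prior_prec + dvec[a];
    double prior_cross = (qg[a] - qdiag[a] * g[a]) / tau2g;
    double mu = (bvec[a] - prior_cross) / prec;
    double gnew = mu + R::rnorm(0.0, 1.0) / std::sqrt(prec);
    double delta = gnew - g[a];
    if (delta != 0.0) {
      for (arma::sp_mat::const_col_iterator it = Q.begin_col(a);
           it != Q.end_col(a); ++it) {
        qg[it.row()] += (*it) * delta;
      }
      g[a] = gnew;
    }
  }
}

struct GeneticBlock {
  arma::mat w;      // m x k factor scores, prior N(0, A) per column
  arma::mat s;      // k x t loadings
  arma::mat delta;  // m x t remaining effects, prior N(0, tau2u_i A)
  arma::vec tau2u;  // t
  arma::mat qw;     // Q * w
  arma::mat qdelta; // Q * delta
};

// subtract/add the genetic fitted part for phenotyped rows
static arma::mat genetic_fitted(const GeneticBlock& gb,
                                const arma::uvec& zidx) {
  arma::mat Wz = gb.w.rows(zidx);
  arma::mat Dz = gb.delta.rows(zidx);
  return Wz * gb.s + Dz;
}

// [[Rcpp::export]]
List gibbs_mtm_cpp(const arma::mat& Y, const arma::mat& X,
                   const arma::mat& XtX_chol, const arma::sp_mat& Q,
                   const arma::uvec& zidx, int k, double floor_e,
                   double floor_g, int n_iter, int burn_in, int thin,
                   bool keep_beta) {
  const arma::uword n = Y.n_rows, t = Y.n_cols, p = X.n_cols,
                    m = Q.n_rows;
  const int ku = k;
  if (burn_in >= n_iter)
    stop("no post-burn-in samples: burn_in >= n_iter");

  arma::vec qdiag(m);
  for (arma::uword a = 0; a < m; ++a) qdiag[a] = Q(a, a);

  // state
  arma::mat beta(p, t, arma::fill::zeros);
  arma::mat v(n, ku, arma::fill::zeros);
  arma::mat r(ku, t);
  GeneticBlock gb;
  gb.w.zeros(m, ku);
  gb.s.set_size(ku, t);
  gb.delta.zeros(m, t);
  gb.tau2u.set_size(t);
  for (arma::uword i = 0; i < t; ++i) {
    gb.tau2u[i] = std::max(0.5, floor_g);
    for (int q = 0; q < ku; ++q) {
      r(q, i) = 0.1 * R::rnorm(0.0, 1.0);
      gb.s(q, i) = 0.1 * R::rnorm(0.0, 1.0);
    }
  }
  gb.qw.zeros(m, ku);
  gb.qdelta.zeros(m, t);
  arma::vec tau2e(t);
  tau2e.fill(std::max(0.5, floor_e));

  arma::mat XB = X * beta;
  arma::mat VR = v * r;
  arma::mat GEN = genetic_fitted(gb, zidx);
  arma::mat E = Y - XB - VR - GEN;

  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep < 1) stop("no post-burn-in samples with this thinning");
  arma::cube G0s(t, t, n_keep), R0s(t, t, n_keep);
  arma::vec dev(n_keep), logpost(n_keep);
  arma::mat mu_sum(n, t, arma::fill::zeros);
  arma::vec tau2e_sum(t, arma::fill::zeros);
  arma::mat beta_sum(p, t, arma::fill::zeros);
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // ---- fixed effects, per trait
    for (arma::uword i = 0; i < t; ++i) {
      arma::vec ci = E.col(i) + XB.col(i);          // residual w/o X beta_i
      arma::vec xtc = X.t() * ci;
      arma::vec mean = arma::solve(
          arma::trimatu(XtX_chol),
          arma::solve(arma::trimatl(XtX_chol.t()), xtc));
      arma::vec z(p);
      for (arma::uword q = 0; q < p; ++q) z[q] = R::rnorm(0.0, 1.0);
      arma::vec bnew = mean +
        std::sqrt(tau2e[i]) * arma::solve(arma::trimatu(XtX_chol), z);
      arma::vec fit_new = X * bnew;
      E.col(i) += XB.col(i) - fit_new;
      XB.col(i) = fit_new;
      beta.col(i) = bnew;
    }

    // ---- residual latent vectors v (rows iid, shared precision)
    {
      arma::mat Cn = E + VR;                        // residual w/o v part
      arma::mat rDe = r;                            // k x t, scaled by 1/tau2e
      for (arma::uword i = 0; i < t; ++i) rDe.col(i) /= tau2e[i];
      arma::mat P = arma::eye(ku, ku) + rDe * r.t();
      arma::mat Uc = arma::chol(P);
      arma::mat Mean = arma::solve(P, rDe * Cn.t()).t();   // n x k
      arma::mat Z(n, ku);
      for (arma::uword q = 0; q < Z.n_elem; ++q) Z(q) = R::rnorm(0.0, 1.0);
      v = Mean + Z * arma::inv(arma::trimatu(Uc)).t();
      arma::mat VRnew = v * r;
      E += VR - VRnew;
      VR = VRnew;
    }

    // ---- residual loadings r, per trait (flat prior)
    {
      arma::mat VtV = v.t() * v;
      arma::mat Cn = E + VR;
      arma::mat Uv = arma::chol(VtV);
      for (arma::uword i = 0; i < t; ++i) {
        arma::vec mean = arma::solve(VtV, v.t() * Cn.col(i));
        arma::vec z(ku);
        for (int q = 0; q < ku; ++q) z[q] = R::rnorm(0.0, 1.0);
        r.col(i) = mean +
          std::sqrt(tau2e[i]) * arma::solve(arma::trimatu(Uv), z);
      }
      arma::mat VRnew = v * r;
      E += VR - VRnew;
      VR = VRnew;
    }

    // ---- genetic factor scores w_k, single-site with prior N(0, A)
    for (int q = 0; q < ku; ++q) {
      arma::vec sk = gb.s.row(q).t();               // t
      arma::vec sk_tau = sk / tau2e;
      double cc = arma::dot(sk, sk_tau);
      arma::vec acc(m, arma::fill::zeros), dvec(m, arma::fill::zeros);
      arma::vec base = E * sk_tau;                  // n
      for (arma::uword j = 0; j < n; ++j) {
        acc[zidx[j]] += base[j];
        dvec[zidx[j]] += cc;
      }
      arma::vec wq = gb.w.col(q);
      arma::vec bvec = acc + wq % dvec;
      arma::vec qg = gb.qw.col(q);
      arma::vec wold = wq;
      sweep_correlated(wq, qg, Q, qdiag, bvec, dvec, 1.0);
      gb.qw.col(q) = qg;
      gb.w.col(q) = wq;
      arma::vec dz = wq(zidx) - wold(zidx);
      E -= dz * sk.t();
    }

    // ---- genetic loadings s, per trait (flat prior)
    {
      arma::mat Wz = gb.w.rows(zidx);
      arma::mat WtW = Wz.t() * Wz;
      arma::mat C2 = E + Wz * gb.s;
      arma::mat Uw = arma::chol(WtW);
      for (arma::uword i = 0; i < t; ++i) {
        arma::vec mean = arma::solve(WtW, Wz.t() * C2.col(i));
        arma::vec z(ku);
        for (int q = 0; q < ku; ++q) z[q] = R::rnorm(0.0, 1.0);
        arma::vec snew = mean +
          std::sqrt(tau2e[i]) * arma::solve(arma::trimatu(Uw), z);
        E.col(i) += Wz * (gb.s.col(i) - snew);
        gb.s.col(i) = snew;
      }
    }

    // ---- remaining genetic effects delta_i, prior N(0, tau2u_i A)
    for (arma::uword i = 0; i < t; ++i) {
      arma::vec acc(m, arma::fill::zeros), dvec(m, arma::fill::zeros);
      for (arma::uword j = 0; j < n; ++j) {
        acc[zidx[j]] += E(j, i) / tau2e[i];
        dvec[zidx[j]] += 1.0 / tau2e[i];
      }
      arma::vec di = gb.delta.col(i);
      arma::vec bvec = acc + di % dvec;
      arma::vec qg = gb.qdelta.col(i);
      arma::vec dold = di;
      sweep_correlated(di, qg, Q, qdiag, bvec, dvec, gb.tau2u[i]);
      gb.qdelta.col(i) = qg;
      gb.delta.col(i) = di;
      E.col(i) -= di(zidx) - dold(zidx);
    }

    // ---- remaining variances (truncated scaled-inverse-chi-square)
    for (arma::uword i = 0; i < t; ++i) {
      double sse = arma::dot(E.col(i), E.col(i));
      tau2e[i] = rtrunc_invgamma(0.5 * n - 1.0, 0.5 * sse, floor_e);
      double quad = arma::dot(gb.delta.col(i), gb.qdelta.col(i));
      gb.tau2u[i] = rtrunc_invgamma(0.5 * m - 1.0, 0.5 * quad, floor_g);
    }

    // ---- record
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      arma::mat R0 = r.t() * r;
      R0.diag() += tau2e;
      arma::mat G0 = gb.s.t() * gb.s;
      G0.diag() += gb.tau2u;
      G0s.slice(kept) = G0;
      R0s.slice(kept) = R0;
      // deviance conditional on fixed and genetic effects, marginal
      // over the residual factor structure: y_j | . ~ N(mu_j, R0)
      arma::mat Resid = E + VR;                // y - X beta - Z u
      arma::mat Lc = arma::chol(R0, "lower");
      arma::mat Wm = arma::solve(arma::trimatl(Lc), Resid.t());
      double ldet = 0.0;
      for (arma::uword i = 0; i < t; ++i) ldet += std::log(Lc(i, i));
      double d = n * (t * std::log(TWOPI) + 2.0 * ldet) +
        arma::accu(Wm % Wm);
      dev[kept] = d;
      // monitoring log-posterior (up to a constant): conditional data
      // term plus the latent and genetic prior terms
      double dcond = 0.0;
      for (arma::uword i = 0; i < t; ++i) {
        double sse = arma::dot(E.col(i), E.col(i));
        dcond += n * std::log(TWOPI * tau2e[i]) + sse / tau2e[i];
      }
      double lp = -0.5 * dcond;
      for (int q = 0; q < ku; ++q) {
        lp -= 0.5 * arma::dot(v.col(q), v.col(q));
        lp -= 0.5 * arma::dot(gb.w.col(q), gb.qw.col(q));
      }
      for (arma::uword i = 0; i < t; ++i) {
        double quad = arma::dot(gb.delta.col(i), gb.qdelta.col(i));
        lp -= 0.5 * (quad / gb.tau2u[i] + m * std::log(gb.tau2u[i]));
      }
      logpost[kept] = lp;
      mu_sum += (Y - Resid);                   // X beta + Z u
      tau2e_sum += tau2e;
      if (keep_beta) beta_sum += beta;
      ++kept;
    }
  }

  return List::create(
    _["G0"] = G0s, _["R0"] = R0s, _["deviance"] = dev,
    _["logpost"] = logpost, _["mu_mean"] = mu_sum / kept,
    _["tau2e_mean"] = tau2e_sum / kept,
    _["beta_mean"] = beta_sum / std::max(kept, 1));
}

// [[Rcpp::export]]
List gibbs_sem_cpp(const arma::mat& Y, const arma::mat& X,
                   const arma::mat& XtX_chol, const arma::sp_mat& Q,
                   const arma::uvec& zidx, const arma::imat& lam_free,
                   int k, double floor_g, double psi_floor, int n_iter,
                   int burn_in, int thin) {
  const arma::uword n = Y.n_rows, t = Y.n_cols, p = X.n_cols,
                    m = Q.n_rows;
  const int ku = k;
  if (burn_in >= n_iter)
    stop("no post-burn-in samples: burn_in >= n_iter");

  arma::vec qdiag(m);
  for (arma::uword a = 0; a < m; ++a) qdiag[a] = Q(a, a);

  // parent lists from the free pattern (lam_free[i, pr] != 0: pr -> i)
  std::vector<arma::uvec> parents(t);
  arma::uword n_lambda = 0;
  for (arma::uword i = 0; i < t; ++i) {
    std::vector<arma::uword> ps;
    for (arma::uword pr = 0; pr < t; ++pr)
      if (lam_free(i, pr) != 0) ps.push_back(pr);
    parents[i] = arma::uvec(ps);
    n_lambda += ps.size();
  }

  arma::mat beta(p, t, arma::fill::zeros);
  arma::mat lambda(t, t, arma::fill::zeros);
  GeneticBlock gb;
  gb.w.zeros(m, ku);
  gb.s.set_size(ku, t);
  gb.delta.zeros(m, t);
  gb.tau2u.set_size(t);
  for (arma::uword i = 0; i < t; ++i) {
    gb.tau2u[i] = std::max(0.5, floor_g);
    for (int q = 0; q < ku; ++q) gb.s(q, i) = 0.1 * R::rnorm(0.0, 1.0);
  }
  gb.qw.zeros(m, ku);
  gb.qdelta.zeros(m, t);
  arma::vec psi(t);
  psi.fill(std::max(0.5, psi_floor));

  arma::mat XB = X * beta;
  arma::mat LY(n, t, arma::fill::zeros);            // (Lambda y) part
  arma::mat GEN = genetic_fitted(gb, zidx);
  arma::mat E = Y - LY - XB - GEN;

  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep < 1) stop("no post-burn-in samples with this thinning");
  arma::cube G0s(t, t, n_keep);
  arma::mat psis(t, n_keep);
  arma::mat lams(n_lambda, n_keep);
  arma::vec dev(n_keep), logpost(n_keep);
  arma::mat mu_sum(n, t, arma::fill::zeros);
  arma::vec psi_sum(t, arma::fill::zeros);
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // ---- structural coefficients, per child trait (flat prior)
    for (arma::uword i = 0; i < t; ++i) {
      const arma::uvec& ps = parents[i];
      if (ps.n_elem == 0) continue;
      arma::mat W = Y.cols(ps);
      arma::vec ci = E.col(i) + LY.col(i);          // residual w/o Lambda y
      arma::mat WtW = W.t() * W;
      arma::mat Uw = arma::chol(WtW);
      arma::vec mean = arma::solve(WtW, W.t() * ci);
      arma::vec z(ps.n_elem);
      for (arma::uword q = 0; q < ps.n_elem; ++q) z[q] = R::rnorm(0.0, 1.0);
      arma::vec lnew = mean +
        std::sqrt(psi[i]) * arma::solve(arma::trimatu(Uw), z);
      for (arma::uword q = 0; q < ps.n_elem; ++q) lambda(i, ps[q]) = lnew[q];
      arma::vec fit_new = W * lnew;
      E.col(i) += LY.col(i) - fit_new;
      LY.col(i) = fit_new;
    }

    // ---- fixed effects, per trait
    for (arma::uword i = 0; i < t; ++i) {
      arma::vec ci = E.col(i) + XB.col(i);
      arma::vec xtc = X.t() * ci;
      arma::vec mean = arma::solve(
          arma::trimatu(XtX_chol),
          arma::solve(arma::trimatl(XtX_chol.t()), xtc));
      arma::vec z(p);
      for (arma::uword q = 0; q < p; ++q) z[q] = R::rnorm(0.0, 1.0);
      arma::vec bnew = mean +
        std::sqrt(psi[i]) * arma::solve(arma::trimatu(XtX_chol), z);
      arma::vec fit_new = X * bnew;
      E.col(i) += XB.col(i) - fit_new;
      XB.col(i) = fit_new;
      beta.col(i) = bnew;
    }

    // ---- genetic factor scores
    for (int q = 0; q < ku; ++q) {
      arma::vec sk = gb.s.row(q).t();
      arma::vec sk_tau = sk / psi;
      double cc = arma::dot(sk, sk / psi);
      arma::vec acc(m, arma::fill::zeros), dvec(m, arma::fill::zeros);
      arma::vec base = E * sk_tau;
      for (arma::uword j = 0; j < n; ++j) {
        acc[zidx[j]] += base[j];
        dvec[zidx[j]] += cc;
      }
      arma::vec wq = gb.w.col(q);
      arma::vec bvec = acc + wq % dvec;
      arma::vec qg = gb.qw.col(q);
      arma::vec wold = wq;
      sweep_correlated(wq, qg, Q, qdiag, bvec, dvec, 1.0);
      gb.qw.col(q) = qg;
      gb.w.col(q) = wq;
      arma::vec dz = wq(zidx) - wold(zidx);
      E -= dz * sk.t();
    }

    // ---- genetic loadings
    {
      arma::mat Wz = gb.w.rows(zidx);
      arma::mat WtW = Wz.t() * Wz;
      arma::mat C2 = E + Wz * gb.s;
      arma::mat Uw = arma::chol(WtW);
      for (arma::uword i = 0; i < t; ++i) {
        arma::vec mean = arma::solve(WtW, Wz.t() * C2.col(i));
        arma::vec z(ku);
        for (int q = 0; q < ku; ++q) z[q] = R::rnorm(0.0, 1.0);
        arma::vec snew = mean +
          std::sqrt(psi[i]) * arma::solve(arma::trimatu(Uw), z);
        E.col(i) += Wz * (gb.s.col(i) - snew);
        gb.s.col(i) = snew;
      }
    }

    // ---- remaining genetic effects
    for (arma::uword i = 0; i < t; ++i) {
      arma::vec acc(m, arma::fill::zeros), dvec(m, arma::fill::zeros);
      for (arma::uword j = 0; j < n; ++j) {
        acc[zidx[j]] += E(j, i) / psi[i];
        dvec[zidx[j]] += 1.0 / psi[i];
      }
      arma::vec di = gb.delta.col(i);
      arma::vec bvec = acc + di % dvec;
      arma::vec qg = gb.qdelta.col(i);
      arma::vec dold = di;
      sweep_correlated(di, qg, Q, qdiag, bvec, dvec, gb.tau2u[i]);
      gb.qdelta.col(i) = qg;
      gb.delta.col(i) = di;
      E.col(i) -= di(zidx) - dold(zidx);
    }

    // ---- variances
    for (arma::uword i = 0; i < t; ++i) {
      double sse = arma::dot(E.col(i), E.col(i));
      psi[i] = rtrunc_invgamma(0.5 * n - 1.0, 0.5 * sse, psi_floor);
      double quad = arma::dot(gb.delta.col(i), gb.qdelta.col(i));
      gb.tau2u[i] = rtrunc_invgamma(0.5 * m - 1.0, 0.5 * quad, floor_g);
    }

    // ---- record
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      arma::mat G0 = gb.s.t() * gb.s;
      G0.diag() += gb.tau2u;
      G0s.slice(kept) = G0;
      psis.col(kept) = psi;
      arma::uword pos = 0;
      for (arma::uword i = 0; i < t; ++i)
        for (arma::uword q = 0; q < parents[i].n_elem; ++q)
          lams(pos++, kept) = lambda(i, parents[i][q]);
      double d = 0.0;
      for (arma::uword i = 0; i < t; ++i) {
        double sse = arma::dot(E.col(i), E.col(i));
        d += n * std::log(TWOPI * psi[i]) + sse / psi[i];
      }
      dev[kept] = d;
      double lp = -0.5 * d;
      for (int q = 0; q < ku; ++q)
        lp -= 0.5 * arma::dot(gb.w.col(q), gb.qw.col(q));
      for (arma::uword i = 0; i < t; ++i) {
        double quad = arma::dot(gb.delta.col(i), gb.qdelta.col(i));
        lp -= 0.5 * (quad / gb.tau2u[i] + m * std::log(gb.tau2u[i]));
      }
      logpost[kept] = lp;
      mu_sum += (Y - E);
      psi_sum += psi;
      ++kept;
    }
  }

  return List::create(
    _["G0"] = G0s, _["psi"] = psis, _["lambda"] = lams,
    _["deviance"] = dev, _["logpost"] = logpost,
    _["mu_mean"] = mu_sum / kept, _["psi_mean"] = psi_sum / kept);
}
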