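#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Traits are indexed 0 = teat liability, 1 = milk yield, 2 = somatic cell
// score throughout.  Row observation patterns: 0 = teat (one liability),
// 1 = test-day with MY and SCS, 2 = test-day with MY only, 3 = SCS only.
// All randomness uses R's RNG so set.seed() in R fixes the whole chain.

static double rtnorm_onesided_tail(double a) {
  // Robert (1995) exponential rejection for z ~ N(0,1) | z > a, a large.
  const double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (int k = 0; k < 10000; ++k) {
    const double z = a - std::log(R::unif_rand()) / alpha;
    const double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
    if (R::unif_rand() <= rho) return z;
  }
  return a + 1.0 / alpha; // fallback: mean of the proposal
}

static double rtnorm1(double mu, double sd, double lo, double hi) {
  double a = (lo == R_NegInf) ? R_NegInf : (lo - mu) / sd;
  double b = (hi == R_PosInf) ? R_PosInf : (hi - mu) / sd;
  double pa = (a == R_NegInf) ? 0.0 : R::pnorm(a, 0.0, 1.0, 1, 0);
  double pb = (b == R_PosInf) ? 1.0 : R::pnorm(b, 0.0, 1.0, 1, 0);
  if (pb - pa > 1e-10) {
    double z = R::qnorm(R::runif(pa, pb), 0.0, 1.0, 1, 0);
    if (a != R_NegInf && z < a) z = a;
    if (b != R_PosInf && z > b) z = b;
    return mu + sd * z;
  }
  // interval deep in a tail: work on the side nearer the bulk
  if (a != R_NegInf && a > 0.0) {
    for (int k = 0; k < 10000; ++k) {
      const double z = rtnorm_onesided_tail(a);
      if (b == R_PosInf || z <= b) return mu + sd * z;
    }
    return mu + sd * 0.5 * (a + ((b == R_PosInf) ? a + 1.0 : b));
  }
  if (b != R_PosInf && b < 0.0) {
    for (int k = 0; k < 10000; ++k) {
      const double z = -rtnorm_onesided_tail(-b);
      if (a == R_NegInf || z >= a) return mu + sd * z;
    }
    return mu + sd * 0.5 * (((a == R_NegInf) ? b - 1.0 : a) + b);
  }
  return mu + sd * 0.5 * ((a == R_NegInf ? b : a) + (b == R_PosInf ? a : b));
}

// [[Rcpp::export]]
NumericVector rtnorm_cpp(int n, NumericVector mean, NumericVector sd,
                         NumericVector lower, NumericVector upper) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = rtnorm1(mean[i % mean.size()], sd[i % sd.size()],
                     lower[i % lower.size()], upper[i % upper.size()]);
  return out;
}

static arma::vec rmvn_prec(const arma::mat& M, const arma::vec& rhs) {
  // draw from N(M^{-1} rhs, M^{-1}) given the precision M
  arma::mat U = arma::chol(M); // M = U' U
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), rhs));
  arma::vec z(M.n_rows);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return mu + arma::solve(arma::trimatu(U), z);
}

static arma::mat riwish(double df, const arma::mat& Scale) {
  // Sigma ~ IW(df, Scale) via Bartlett decomposition of W ~ Wishart(df, Scale^-1)
  const arma::uword p = Scale.n_rows;
  arma::mat L = arma::chol(arma::inv_sympd(arma::symmatu(Scale)), "lower");
  arma::mat T(p, p, arma::fill::zeros);
  for (arma::uword i = 0; i < p; ++i) {
    T(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (arma::uword j = 0; j < i; ++j) T(i, j) = R::norm_rand();
  }
  arma::mat LT = L * T;
  arma::mat W = LT * LT.t();
  return arma::symmatu(arma::inv_sympd(arma::symmatu(W)));
}

static void vech3_store(const arma::mat& X, double* out) {
  out[0] = X(0, 0); out[1] = X(1, 0); out[2] = X(2, 0);
  out[3] = X(1, 1); out[4] = X(2, 1); out[5] = X(2, 2);
}

typedef std::vector<std::vector<int>> IndexLists;

static IndexLists rows_by_level(const IntegerVector& idx, int nlev,
                                const std::vector<int>& keep_rows) {
  IndexLists out(nlev);
  for (int r : keep_rows) {
    const int j = idx[r];
    if (j >= 0) out[j].push_back(r);
  }
  return out;
}

// [[Rcpp::export]]
List gibbs_thl_cpp(IntegerVector pattern, NumericMatrix ymat, IntegerVector cat,
                   IntegerVector herd, IntegerVector cow, IntegerVector sire,
                   IntegerVector ps, IntegerVector hyg, IntegerVector qtr,
                   int n_herd, int n_cow, int n_sire, int n_ps,
                   arma::mat Ainv, int K, NumericVector thr_init,
                   int n_iter, int burn, int thin,
                   List prior, List start, bool fix_cov, bool estimate_r11,
                   bool store_effects, bool verbose) {
  const int n = pattern.size();
  std::vector<int> teat_rows, prod_rows, all_rows(n);
  for (int i = 0; i < n; ++i) {
    all_rows[i] = i;
    if (pattern[i] == 0) teat_rows.push_back(i); else prod_rows.push_back(i);
  }
  const int n_teat = (int)teat_rows.size(), n_prod = (int)prod_rows.size();
  const bool has_teat = n_teat > 0, has_prod = n_prod > 0;

  const int n_hyg = 4, n_qtr = 4;
  IndexLists by_herd = rows_by_level(herd, n_herd, all_rows);
  IndexLists by_cow  = rows_by_level(cow,  n_cow,  all_rows);
  IndexLists by_sire = rows_by_level(sire, n_sire, all_rows);
  IndexLists by_ps_t = rows_by_level(ps, n_ps, teat_rows);
  IndexLists by_ps_p = rows_by_level(ps, n_ps, prod_rows);
  IndexLists by_hyg  = rows_by_level(hyg, n_hyg, teat_rows);
  IndexLists by_qtr  = rows_by_level(qtr, n_qtr, teat_rows);

  // category membership among teat rows (for threshold updates)
  std::vector<std::vector<int>> by_cat(K > 0 ? K : 0);
  for (int r : teat_rows) by_cat[cat[r] - 1].push_back(r);

  // state
  arma::mat H  = as<arma::mat>(start["H"]);
  arma::mat P  = as<arma::mat>(start["P"]);
  arma::mat S  = as<arma::mat>(start["S"]);
  arma::mat Rp = as<arma::mat>(start["Rprod"]);
  double r11  = as<double>(start["r11"]);
  arma::mat Hinv = arma::inv_sympd(H), Pinv = arma::inv_sympd(P),
            Sinv = arma::inv_sympd(S), RpInv = arma::inv_sympd(Rp);

  const double pr_df3 = as<double>(prior["df3"]);
  const arma::mat pr_scale3 = as<arma::mat>(prior["scale3"]);
  const double pr_df2 = as<double>(prior["df2"]);
  const arma::mat pr_scale2 = as<arma::mat>(prior["scale2"]);
  const double pr_nu_e = as<double>(prior["nu_e"]);
  const double pr_s2_e = as<double>(prior["s2_e"]);

  arma::vec bt_ps(n_ps, arma::fill::zeros), bt_hyg(n_hyg, arma::fill::zeros),
            bt_qtr(n_qtr, arma::fill::zeros);
  arma::mat Bp(n_ps, 2, arma::fill::zeros);
  arma::mat Uh(n_herd, 3, arma::fill::zeros), Up(n_cow, 3, arma::fill::zeros),
            Us(n_sire, 3, arma::fill::zeros);

  NumericVector thr = clone(thr_init); // length K+1 with -Inf / +Inf ends
  arma::vec lam(n, arma::fill::zeros);
  arma::mat E(n, 3, arma::fill::zeros);
  for (int r : teat_rows) {
    // start liabilities at the midpoint of their category interval
    const int c = cat[r];
    double lo = thr[c - 1], hi = thr[c];
    double v = (lo == R_NegInf) ? hi - 0.5 : (hi == R_PosInf) ? lo + 0.5
               : 0.5 * (lo + hi);
    lam(r) = v;
    E(r, 0) = v;
  }
  for (int r : prod_rows) {
    E(r, 1) = (pattern[r] == 3) ? 0.0 : ymat(r, 1);
    E(r, 2) = (pattern[r] == 2) ? 0.0 : ymat(r, 2);
  }

  const int n_store = (n_iter > burn) ? (n_iter - burn + thin - 1) / thin : 0;
  int p_cov = 6 + 6 + 6 + 3 + 1 + (K == 4 ? 1 : 0);
  int p_eff = store_effects ? (n_ps + 3 + 3 + 2 * n_ps) : 0;
  NumericMatrix draws(n_store, p_cov + p_eff);
  int stored = 0;

  for (int it = 1; it <= n_iter; ++it) {
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
    const double sd_e = std::sqrt(r11);

    // 1. liabilities
    for (int r : teat_rows) {
      const double eta = lam(r) - E(r, 0);
      const int c = cat[r];
      const double v = rtnorm1(eta, sd_e, thr[c - 1], thr[c]);
      E(r, 0) = v - eta;
      lam(r) = v;
    }

    // 2. augment the missing production trait on incomplete test-day rows
    if (has_prod) {
      const double b21 = Rp(0, 1) / Rp(0, 0);
      const double s21 = std::sqrt(Rp(1, 1) - Rp(0, 1) * Rp(0, 1) / Rp(0, 0));
      const double b12 = Rp(0, 1) / Rp(1, 1);
      const double s12 = std::sqrt(Rp(0, 0) - Rp(0, 1) * Rp(0, 1) / Rp(1, 1));
      for (int r : prod_rows) {
        if (pattern[r] == 2) E(r, 2) = b21 * E(r, 1) + s21 * R::norm_rand();
        else if (pattern[r] == 3) E(r, 1) = b12 * E(r, 2) + s12 * R::norm_rand();
      }
    }

    // 3. teat fixed effects (flat prior, scalar conditionals)
    if (has_teat) {
      for (int j = 0; j < n_ps; ++j) {
        const std::vector<int>& rw = by_ps_t[j];
        if (rw.empty()) continue;
        double sum = 0.0;
        for (int r : rw) { E(r, 0) += bt_ps(j); sum += E(r, 0); }
        const double m = sum / rw.size(), v = r11 / rw.size();
        bt_ps(j) = m + std::sqrt(v) * R::norm_rand();
        for (int r : rw) E(r, 0) -= bt_ps(j);
      }
      for (int j = 1; j < n_hyg; ++j) { // level 1 is the reference (0)
        const std::vector<int>& rw = by_hyg[j];
        if (rw.empty()) continue;
        double sum = 0.0;
        for (int r : rw) { E(r, 0) += bt_hyg(j); sum += E(r, 0); }
        bt_hyg(j) = sum / rw.size() + std::sqrt(r11 / rw.size()) * R::norm_rand();
        for (int r : rw) E(r, 0) -= bt_hyg(j);
      }
      for (int j = 1; j < n_qtr; ++j) {
        const std::vector<int>& rw = by_qtr[j];
        if (rw.empty()) continue;
        double sum = 0.0;
        for (int r : rw) { E(r, 0) += bt_qtr(j); sum += E(r, 0); }
        bt_qtr(j) = sum / rw.size() + std::sqrt(r11 / rw.size()) * R::norm_rand();
        for (int r : rw) E(r, 0) -= bt_qtr(j);
      }
    }

    // 4. production fixed effects (bivariate per parity-stage class)
    if (has_prod) {
      for (int j = 0; j < n_ps; ++j) {
        const std::vector<int>& rw = by_ps_p[j];
        if (rw.empty()) continue;
        arma::vec sum(2, arma::fill::zeros);
        for (int r : rw) {
          E(r, 1) += Bp(j, 0); E(r, 2) += Bp(j, 1);
          sum(0) += E(r, 1); sum(1) += E(r, 2);
        }
        arma::mat M = (double)rw.size() * RpInv;
        arma::vec b = rmvn_prec(M, RpInv * sum);
        Bp(j, 0) = b(0); Bp(j, 1) = b(1);
        for (int r : rw) { E(r, 1) -= b(0); E(r, 2) -= b(1); }
      }
    }

    // 5.-7. random effects: herd, cow permanent environment, sire
    for (int eff = 0; eff < 3; ++eff) {
      const IndexLists& lists = (eff == 0) ? by_herd : (eff == 1) ? by_cow : by_sire;
      arma::mat& U = (eff == 0) ? Uh : (eff == 1) ? Up : Us;
      const arma::mat& Kinv = (eff == 0) ? Hinv : (eff == 1) ? Pinv : Sinv;
      const int nlev = (eff == 0) ? n_herd : (eff == 1) ? n_cow : n_sire;
      const double inv_r11 = 1.0 / r11;
      const double w11 = RpInv(0, 0), w12 = RpInv(0, 1), w22 = RpInv(1, 1);
      for (int j = 0; j < nlev; ++j) {
        arma::mat M = Kinv;
        arma::vec rhs(3, arma::fill::zeros);
        if (eff == 2) {
          // numerator-relationship shrinkage: precision a^{jj} S^-1 and
          // coupling to the other sires through off-diagonal A^-1 terms
          M = Ainv(j, j) * Kinv;
          arma::rowvec w = Ainv.row(j) * U; // includes own term, remove it
          arma::vec coup = w.t() - Ainv(j, j) * U.row(j).t();
          rhs = -Kinv * coup;
        }
        const std::vector<int>& rw = lists[j];
        const double u0 = U(j, 0), u1 = U(j, 1), u2 = U(j, 2);
        double m00 = 0, m11 = 0, m12 = 0, m22 = 0, r0 = 0, r1 = 0, r2 = 0;
        for (int r : rw) {
          if (pattern[r] == 0) {
            const double e0 = E(r, 0) + u0;
            E(r, 0) = e0;
            m00 += inv_r11;
            r0 += e0;
          } else {
            const double e1 = E(r, 1) + u1, e2 = E(r, 2) + u2;
            E(r, 1) = e1; E(r, 2) = e2;
            m11 += w11; m12 += w12; m22 += w22;
            r1 += w11 * e1 + w12 * e2;
            r2 += w12 * e1 + w22 * e2;
          }
        }
        M(0, 0) += m00; M(1, 1) += m11; M(2, 2) += m22;
        M(1, 2) += m12; M(2, 1) += m12;
        rhs(0) += r0 * inv_r11; rhs(1) += r1; rhs(2) += r2;
        arma::vec u = rmvn_prec(M, rhs);
        for (int r : rw) {
          if (pattern[r] == 0) E(r, 0) -= u(0);
          else { E(r, 1) -= u(1); E(r, 2) -= u(2); }
        }
        U.row(j) = u.t();
      }
    }

    // 8. covariance matrices
    if (!fix_cov) {
      H = riwish(pr_df3 + n_herd, pr_scale3 + Uh.t() * Uh);
      P = riwish(pr_df3 + n_cow, pr_scale3 + Up.t() * Up);
      S = riwish(pr_df3 + n_sire, pr_scale3 + Us.t() * Ainv * Us);
      Hinv = arma::inv_sympd(H); Pinv = arma::inv_sympd(P);
      Sinv = arma::inv_sympd(S);
      if (has_prod) {
        arma::mat SR = pr_scale2;
        double s11 = 0, s12 = 0, s22 = 0;
        for (int r : prod_rows) {
          const double e1 = E(r, 1), e2 = E(r, 2);
          s11 += e1 * e1; s12 += e1 * e2; s22 += e2 * e2;
        }
        SR(0, 0) += s11; SR(0, 1) += s12; SR(1, 0) += s12; SR(1, 1) += s22;
        Rp = riwish(pr_df2 + n_prod, SR);
        RpInv = arma::inv_sympd(Rp);
      }
      if (has_teat && estimate_r11) {
        double sse = 0.0;
        for (int r : teat_rows) sse += E(r, 0) * E(r, 0);
        r11 = (pr_nu_e * pr_s2_e + sse) / R::rchisq(pr_nu_e + n_teat);
      }
    }

    // 9. free threshold of the 4-category trait (t1 = 0, t2 = 1 pinned)
    if (K == 4 && has_teat) {
      double lo = thr[2], hi = R_PosInf;
      for (int r : by_cat[2]) if (lam(r) > lo) lo = lam(r);
      for (int r : by_cat[3]) if (lam(r) < hi) hi = lam(r);
      thr[3] = R::runif(lo, hi);
    }

    // 10. store
    if (it > burn && (it - burn - 1) % thin == 0) {
      std::vector<double> row(p_cov + p_eff);
      vech3_store(S, &row[0]);
      vech3_store(P, &row[6]);
      vech3_store(H, &row[12]);
      row[18] = Rp(0, 0); row[19] = Rp(1, 0); row[20] = Rp(1, 1);
      row[21] = r11;
      int k = 22;
      if (K == 4) row[k++] = thr[3];
      if (store_effects) {
        for (int j = 0; j < n_ps; ++j) row[k++] = bt_ps(j);
        for (int j = 1; j < 4; ++j) row[k++] = bt_hyg(j);
        for (int j = 1; j < 4; ++j) row[k++] = bt_qtr(j);
        for (int j = 0; j < n_ps; ++j) row[k++] = Bp(j, 0);
        for (int j = 0; j < n_ps; ++j) row[k++] = Bp(j, 1);
      }
      for (int c = 0; c < p_cov + p_eff; ++c) {
        if (!std::isfinite(row[c]))
          stop("non-finite sampler state at iteration %d", it);
        draws(stored, c) = row[c];
      }
      ++stored;
    }
    if (verbose && it % 10000 == 0)
      Rcout << "iteration " << it << " / " << n_iter << "\n";
  }

  return List::create(_["draws"] = draws, _["n_stored"] = stored,
                      _["n_teat"] = n_teat, _["n_prod"] = n_prod,
                      _["thresholds"] = thr);
}
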