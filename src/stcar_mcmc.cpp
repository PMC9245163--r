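// MCMC engine for the spatio-temporal clustering-adjacency model.
//
// Model: Y_it ~ Poisson(E_it R_it), log R_it = x_it'beta + phi_it + theta_t;
// phi_t ~ N(0, tau2_t Q(rho_t, W_t)^-1) with Leroux precision
// Q = rho (diag(W1) - W) + (1 - rho) I; theta is AR(1); W_t is a discrete
// parameter over a fixed candidate set and is updated by a two-move
// Metropolis-Hastings step (move 1: same clustering method, cluster count
// within a +/- s window; move 2: same cluster count, different method).
//
// Candidates are all subgraphs of the border-sharing graph, so each is
// stored as a keep-mask over the border edge list; phi' (diag(W1)-W) phi
// reduces to a sum of squared differences over retained edges, and the
// log-determinant of Q comes from cached eigenvalues of diag(W1) - W.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Incidence {
  std::vector<int> offset;   // size n+1
  std::vector<int> edge;     // edge index per incidence
  std::vector<int> other;    // opposite endpoint per incidence
};

Incidence build_incidence(const IntegerVector& ei, const IntegerVector& ej,
                          int n) {
  int nE = ei.size();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < nE; e++) { deg[ei[e]]++; deg[ej[e]]++; }
  Incidence inc;
  inc.offset.assign(n + 1, 0);
  for (int i = 0; i < n; i++) inc.offset[i + 1] = inc.offset[i] + deg[i];
  inc.edge.assign(2 * nE, 0);
  inc.other.assign(2 * nE, 0);
  std::vector<int> pos(inc.offset.begin(), inc.offset.end() - 1);
  for (int e = 0; e < nE; e++) {
    inc.edge[pos[ei[e]]] = e; inc.other[pos[ei[e]]++] = ej[e];
    inc.edge[pos[ej[e]]] = e; inc.other[pos[ej[e]]++] = ei[e];
  }
  return inc;
}

// sum over retained edges of candidate m of (phi_i - phi_j)^2 at period t
double quad_edges(const LogicalMatrix& keep, const IntegerVector& ei,
                  const IntegerVector& ej, const NumericMatrix& phi,
                  int m, int t) {
  double s = 0.0;
  int nE = ei.size();
  const int* kc = keep.begin() + (size_t)m * nE;
  const double* ph = phi.begin() + (size_t)t * phi.nrow();
  for (int e = 0; e < nE; e++) {
    if (kc[e]) {
      double d = ph[ei[e]] - ph[ej[e]];
      s += d * d;
    }
  }
  return s;
}

double logdet_Q(const NumericMatrix& eig, int m, double rho) {
  double s = 0.0;
  for (int i = 0; i < eig.nrow(); i++)
    s += std::log(rho * eig(i, m) + 1.0 - rho);
  return s;
}

double rtrunc01_norm(double mean, double sd) {
  double pa = R::pnorm(0.0, mean, sd, 1, 0);
  double pb = R::pnorm(1.0, mean, sd, 1, 0);
  if (pb - pa < 1e-12) return mean < 0.5 ? 0.0 : 1.0;
  double u = pa + R::unif_rand() * (pb - pa);
  double x = R::qnorm(u, mean, sd, 1, 0);
  if (x < 0.0) x = 0.0;
  if (x > 1.0) x = 1.0;
  return x;
}

}  // namespace

// [[Rcpp::export(name = ".stcar_mcmc")]]
List stcar_mcmc(NumericMatrix Y, NumericMatrix E, NumericVector Xflat,
                int p,
                IntegerVector ei, IntegerVector ej, LogicalMatrix keep,
                NumericMatrix rowsums, NumericMatrix eig,
                IntegerVector lookup, int M, int K, int n_t_cand,
                bool variantB, int s_window,
                bool estimate_rho, double rho_init,
                double beta_var, double tau2_shape, double tau2_scale,
                double sig2_shape, double sig2_scale,
                int n_iter, int burn_in, int thin,
                NumericVector beta_init, NumericMatrix phi_init,
                NumericVector theta_init, NumericVector tau2_init,
                double sigma2_init, double alpha_init,
                IntegerVector w_init, IntegerVector latent_c_init,
                LogicalVector update_flags, bool adapt) {
  int n = Y.nrow(), T = Y.ncol();
  bool up_beta = update_flags[0], up_phi = update_flags[1],
       up_theta = update_flags[2], up_tau2 = update_flags[3],
       up_sig = update_flags[4], up_rho = update_flags[5],
       up_w = update_flags[6];
  // identifiability centring can be switched off for prior-recovery checks
  bool do_centre = update_flags.size() > 7 ? (bool)update_flags[7] : true;

  Incidence inc = build_incidence(ei, ej, n);

  // state
  NumericVector beta = clone(beta_init);
  NumericMatrix phi = clone(phi_init);
  NumericVector theta = clone(theta_init);
  NumericVector tau2 = clone(tau2_init);
  double sigma2 = sigma2_init, alpha = alpha_init;
  int n_rho = variantB ? T : 1;
  NumericVector rho(n_rho, rho_init);
  std::vector<int> wcur(T), latc(T);
  for (int t = 0; t < T; t++) {
    wcur[t] = variantB ? w_init[t] : w_init[0];
    latc[t] = variantB ? latent_c_init[t] : latent_c_init[0];
  }

  // linear predictor pieces: xb_it = sum_q x_itq beta_q
  NumericMatrix xb(n, T);
  for (int t = 0; t < T; t++)
    for (int i = 0; i < n; i++) {
      double v = 0.0;
      for (int q = 0; q < p; q++) v += Xflat[i + n * t + n * T * q] * beta[q];
      xb(i, t) = v;
    }

  // step sizes (adapted in burn-in toward ~45% acceptance)
  double step_phi = 0.1, step_theta = 0.05, step_beta = 0.01, step_rho = 0.5;
  double acc_phi = 0, try_phi = 0, acc_theta = 0, try_theta = 0;
  double acc_beta = 0, try_beta = 0, acc_rho = 0, try_rho = 0;
  double acc_w1 = 0, try_w1 = 0, acc_w2 = 0, try_w2 = 0;
  double accT_phi = 0, tryT_phi = 0, accT_theta = 0, tryT_theta = 0;
  double accT_beta = 0, tryT_beta = 0, accT_rho = 0, tryT_rho = 0;

  int n_keep = 0;
  for (int it = burn_in; it < n_iter; it++)
    if ((it - burn_in) % thin == 0) n_keep++;
  NumericMatrix s_beta(n_keep, p), s_theta(n_keep, T), s_tau2(n_keep, T);
  NumericVector s_sigma2(n_keep), s_alpha(n_keep), s_dev(n_keep);
  NumericMatrix s_rho(n_keep, n_rho);
  IntegerMatrix s_w(n_keep, variantB ? T : 1);
  NumericMatrix s_risk(n_keep, n * T);
  int keep_row = 0;

  auto lookup_idx = [&](int c, int k, int t) {
    // c,k 1-based; t 0-based period (collapsed to 0 for variant A)
    int tt = variantB ? t : 0;
    return lookup[(c - 1) + M * (k - 1) + M * K * tt] - 1;  // 0-based
  };
  auto win_size = [&](int k) {
    return std::min(K, k + s_window) - std::max(1, k - s_window);
  };

  // per-sweep caches: edge quadratic form of the current W per period,
  // and sum of squared phi per period
  std::vector<double> qcur(T, 0.0), phi_ss(T, 0.0);
  auto refresh_quads = [&]() {
    for (int t = 0; t < T; t++) {
      qcur[t] = quad_edges(keep, ei, ej, phi, wcur[t], t);
      double s2 = 0.0;
      for (int i = 0; i < n; i++) s2 += phi(i, t) * phi(i, t);
      phi_ss[t] = s2;
    }
  };
  refresh_quads();

  // one W Metropolis-Hastings move over the periods in [t0, t1)
  auto w_move = [&](int t0, int t1, bool move1) {
    int cur = wcur[t0];
    int c_cur, k_cur;
    if (cur == 0) { c_cur = latc[t0]; k_cur = 1; }
    else {
      // decode from candidate index: caller passes candC/candK implicitly
      // through the lookup layout: index-1 = (c-1) + M*(k-2) + M*(K-1)*tt
      int rem = cur - 1;
      int tt = rem / (M * (K - 1));
      rem -= tt * M * (K - 1);
      k_cur = rem / M + 2;
      c_cur = rem % M + 1;
    }
    int prop, c_p = c_cur, k_p = k_cur;
    double log_hastings = 0.0;
    if (move1) {
      int lo = std::max(1, k_cur - s_window), hi = std::min(K, k_cur + s_window);
      int nw = hi - lo;  // window size excluding k_cur
      if (nw <= 0) return;
      int pick = (int)std::floor(R::unif_rand() * nw);
      if (pick >= nw) pick = nw - 1;
      k_p = lo + pick;
      if (k_p >= k_cur) k_p++;
      log_hastings = std::log((double)win_size(k_cur)) -
                     std::log((double)win_size(k_p));
    } else {
      if (M < 2) return;
      int pick = (int)std::floor(R::unif_rand() * (M - 1));
      if (pick >= M - 1) pick = M - 2;
      c_p = pick + 1;
      if (c_p >= c_cur) c_p++;
    }
    prop = (k_p == 1) ? 0 : lookup_idx(c_p, k_p, t0);
    if (move1) try_w1 += 1; else try_w2 += 1;
    double la = log_hastings;
    std::vector<double> qprop(t1 - t0, 0.0);
    if (prop != cur) {
      // the log-determinant is period-free (shared rho within a scope)
      double r = rho[variantB ? t0 : 0];
      la += 0.5 * (t1 - t0) * (logdet_Q(eig, prop, r) - logdet_Q(eig, cur, r));
      for (int t = t0; t < t1; t++) {
        qprop[t - t0] = quad_edges(keep, ei, ej, phi, prop, t);
        la -= r * (qprop[t - t0] - qcur[t]) / (2.0 * tau2[t]);
      }
    }
    if (la >= 0.0 || R::unif_rand() < std::exp(la)) {
      for (int t = t0; t < t1; t++) {
        latc[t] = c_p;
        if (prop != cur) { wcur[t] = prop; qcur[t] = qprop[t - t0]; }
      }
      if (move1) acc_w1 += 1; else acc_w2 += 1;
    }
  };

  for (int it = 0; it < n_iter; it++) {
    // --- beta: random-walk MH per coefficient, prior N(0, beta_var)
    if (up_beta) {
      for (int q = 0; q < p; q++) {
        double prop = beta[q] + step_beta * R::norm_rand();
        double diff = prop - beta[q];
        double la = (beta[q] * beta[q] - prop * prop) / (2.0 * beta_var);
        bool is_intercept = (q == 0);
        if (is_intercept) {
          // x = 1 everywhere: la += diff * sum(Y) - (e^diff - 1) sum(E e^eta)
          double sy = 0.0, se = 0.0;
          for (int t = 0; t < T; t++)
            for (int i = 0; i < n; i++) {
              sy += Y(i, t);
              se += E(i, t) * std::exp(xb(i, t) + phi(i, t) + theta[t]);
            }
          la += diff * sy - (std::exp(diff) - 1.0) * se;
        } else {
          for (int t = 0; t < T; t++)
            for (int i = 0; i < n; i++) {
              double x = Xflat[i + n * t + n * T * q];
              double cur_eta = xb(i, t) + phi(i, t) + theta[t];
              la += Y(i, t) * x * diff -
                    E(i, t) * (std::exp(cur_eta + x * diff) - std::exp(cur_eta));
            }
        }
        try_beta += 1; tryT_beta += 1;
        if (la >= 0.0 || R::unif_rand() < std::exp(la)) {
          acc_beta += 1; accT_beta += 1;
          beta[q] = prop;
          if (is_intercept) {
            for (int t = 0; t < T; t++)
              for (int i = 0; i < n; i++) xb(i, t) += diff;
          } else {
            for (int t = 0; t < T; t++)
              for (int i = 0; i < n; i++)
                xb(i, t) += Xflat[i + n * t + n * T * q] * diff;
          }
        }
      }
    }

    // --- phi: elementwise random-walk MH against Poisson likelihood x
    //     Leroux full conditional
    if (up_phi) {
      int nE = ei.size();
      for (int t = 0; t < T; t++) {
        double r = rho[variantB ? t : 0];
        int m = wcur[t];
        const int* kc = keep.begin() + (size_t)m * nE;
        for (int i = 0; i < n; i++) {
          double nbr = 0.0;
          for (int a = inc.offset[i]; a < inc.offset[i + 1]; a++)
            if (kc[inc.edge[a]]) nbr += phi(inc.other[a], t);
          double d = r * rowsums(i, m) + 1.0 - r;
          double pm = r * nbr / d;
          double cur = phi(i, t);
          double prop = cur + step_phi * R::norm_rand();
          double base = xb(i, t) + theta[t];
          double la = Y(i, t) * (prop - cur) -
                      E(i, t) * (std::exp(base + prop) - std::exp(base + cur)) -
                      d * ((prop - pm) * (prop - pm) -
                           (cur - pm) * (cur - pm)) / (2.0 * tau2[t]);
          try_phi += 1; tryT_phi += 1;
          if (la >= 0.0 || R::unif_rand() < std::exp(la)) {
            phi(i, t) = prop;
            acc_phi += 1; accT_phi += 1;
          }
        }
        // re-centre phi_t, absorbing the mean into theta_t
        if (do_centre) {
          double mu = 0.0;
          for (int i = 0; i < n; i++) mu += phi(i, t);
          mu /= n;
          for (int i = 0; i < n; i++) phi(i, t) -= mu;
          theta[t] += mu;
        }
      }
      refresh_quads();
    }

    // --- theta: elementwise random-walk MH against Poisson likelihood x
    //     AR(1) prior
    if (up_theta) {
      for (int t = 0; t < T; t++) {
        double cur = theta[t];
        double prop = cur + step_theta * R::norm_rand();
        double la = 0.0;
        for (int i = 0; i < n; i++) {
          double base = xb(i, t) + phi(i, t);
          la += Y(i, t) * (prop - cur) -
                E(i, t) * (std::exp(base + prop) - std::exp(base + cur));
        }
        double prev_mean = (t == 0) ? 0.0 : alpha * theta[t - 1];
        la -= ((prop - prev_mean) * (prop - prev_mean) -
               (cur - prev_mean) * (cur - prev_mean)) / (2.0 * sigma2);
        if (t < T - 1) {
          la -= ((theta[t + 1] - alpha * prop) * (theta[t + 1] - alpha * prop) -
                 (theta[t + 1] - alpha * cur) * (theta[t + 1] - alpha * cur)) /
                (2.0 * sigma2);
        }
        try_theta += 1; tryT_theta += 1;
        if (la >= 0.0 || R::unif_rand() < std::exp(la)) {
          theta[t] = prop;
          acc_theta += 1; accT_theta += 1;
        }
      }
      // re-centre theta, absorbing the mean into the intercept
      if (do_centre) {
        double mu = 0.0;
        for (int t = 0; t < T; t++) mu += theta[t];
        mu /= T;
        for (int t = 0; t < T; t++) theta[t] -= mu;
        if (p > 0) {
          beta[0] += mu;
          for (int t = 0; t < T; t++)
            for (int i = 0; i < n; i++) xb(i, t) += mu;
        }
      }
    }

    // --- tau2_t: conjugate inverse-gamma Gibbs draw per period
    if (up_tau2) {
      for (int t = 0; t < T; t++) {
        double r = rho[variantB ? t : 0];
        double quad = r * qcur[t] + (1.0 - r) * phi_ss[t];
        double shape = tau2_shape + 0.5 * n;
        double scale = tau2_scale + 0.5 * quad;
        tau2[t] = scale / R::rgamma(shape, 1.0);
      }
    }

    // --- sigma2 (inverse-gamma Gibbs) and alpha (truncated-normal Gibbs)
    if (up_sig) {
      double ss = theta[0] * theta[0];
      for (int t = 1; t < T; t++) {
        double d = theta[t] - alpha * theta[t - 1];
        ss += d * d;
      }
      sigma2 = (sig2_scale + 0.5 * ss) / R::rgamma(sig2_shape + 0.5 * T, 1.0);
      double denom = 0.0, cross = 0.0;
      for (int t = 1; t < T; t++) {
        denom += theta[t - 1] * theta[t - 1];
        cross += theta[t] * theta[t - 1];
      }
      if (denom <= 1e-300) {
        alpha = R::unif_rand();
      } else {
        alpha = rtrunc01_norm(cross / denom, std::sqrt(sigma2 / denom));
      }
    }

    // --- rho: random-walk MH on the logit scale (uniform prior + Jacobian)
    if (up_rho && estimate_rho) {
      for (int rix = 0; rix < n_rho; rix++) {
        double cur = rho[rix];
        double lcur = std::log(cur / (1.0 - cur));
        double lprop = lcur + step_rho * R::norm_rand();
        double prop = 1.0 / (1.0 + std::exp(-lprop));
        double la = std::log(prop * (1.0 - prop)) -
                    std::log(cur * (1.0 - cur));
        int t0 = variantB ? rix : 0, t1 = variantB ? rix + 1 : T;
        // within a scope the current W is common, so the log-determinant
        // difference is computed once
        la += 0.5 * (t1 - t0) *
              (logdet_Q(eig, wcur[t0], prop) - logdet_Q(eig, wcur[t0], cur));
        for (int t = t0; t < t1; t++) {
          la -= ((prop - cur) * qcur[t] + (cur - prop) * phi_ss[t]) /
                (2.0 * tau2[t]);
        }
        try_rho += 1; tryT_rho += 1;
        if (la >= 0.0 || R::unif_rand() < std::exp(la)) {
          rho[rix] = prop;
          acc_rho += 1; accT_rho += 1;
        }
      }
    }

    // --- W: two sequential Metropolis-Hastings moves
    if (up_w) {
      if (variantB) {
        for (int t = 0; t < T; t++) {
          w_move(t, t + 1, true);
          w_move(t, t + 1, false);
        }
      } else {
        w_move(0, T, true);
        w_move(0, T, false);
      }
    }

    // --- burn-in step-size adaptation
    if (adapt && it < burn_in && (it + 1) % 100 == 0) {
      auto tune = [](double& step, double& acc, double& tries, double lo,
                     double hi) {
        if (tries > 0) {
          double rate = acc / tries;
          if (rate > hi) step *= 1.3;
          else if (rate < lo) step /= 1.3;
        }
        acc = 0; tries = 0;
      };
      tune(step_phi, acc_phi, try_phi, 0.35, 0.55);
      tune(step_theta, acc_theta, try_theta, 0.35, 0.55);
      tune(step_beta, acc_beta, try_beta, 0.35, 0.55);
      tune(step_rho, acc_rho, try_rho, 0.35, 0.55);
    }

    // --- retain
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int q = 0; q < p; q++) s_beta(keep_row, q) = beta[q];
      for (int t = 0; t < T; t++) {
        s_theta(keep_row, t) = theta[t];
        s_tau2(keep_row, t) = tau2[t];
      }
      s_sigma2[keep_row] = sigma2;
      s_alpha[keep_row] = alpha;
      for (int rix = 0; rix < n_rho; rix++) s_rho(keep_row, rix) = rho[rix];
      if (variantB) {
        for (int t = 0; t < T; t++) s_w(keep_row, t) = wcur[t] + 1;
      } else {
        s_w(keep_row, 0) = wcur[0] + 1;
      }
      double dev = 0.0;
      for (int t = 0; t < T; t++)
        for (int i = 0; i < n; i++) {
          double risk = std::exp(xb(i, t) + phi(i, t) + theta[t]);
          s_risk(keep_row, i + n * t) = risk;
          dev += R::dpois(Y(i, t), E(i, t) * risk, 1);
        }
      if (!std::isfinite(dev)) {
        stop("non-finite log-posterior at iteration %d; "
             "check the data scale and initial values", it + 1);
      }
      s_dev[keep_row] = -2.0 * dev;
      keep_row++;
    }
  }

  NumericMatrix phi_out = clone(phi);
  return List::create(
      _["beta"] = s_beta, _["theta"] = s_theta, _["tau2"] = s_tau2,
      _["sigma2"] = s_sigma2, _["alpha"] = s_alpha, _["rho"] = s_rho,
      _["w"] = s_w, _["risk"] = s_risk, _["deviance"] = s_dev,
      _["final_phi"] = phi_out,
      _["acceptance"] = NumericVector::create(
          _["phi"] = tryT_phi > 0 ? accT_phi / tryT_phi : NA_REAL,
          _["theta"] = tryT_theta > 0 ? accT_theta / tryT_theta : NA_REAL,
          _["beta"] = tryT_beta > 0 ? accT_beta / tryT_beta : NA_REAL,
          _["rho"] = tryT_rho > 0 ? accT_rho / tryT_rho : NA_REAL,
          _["w_move1"] = try_w1 > 0 ? acc_w1 / try_w1 : NA_REAL,
          _["w_move2"] = try_w2 > 0 ? acc_w2 / try_w2 : NA_REAL),
      _["steps"] = NumericVector::create(
          _["phi"] = step_phi, _["theta"] = step_theta,
          _["beta"] = step_beta, _["rho"] = step_rho));
}
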