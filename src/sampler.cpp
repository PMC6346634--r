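#include <Rcpp.h>
using namespace Rcpp;

// Per-tree-year latent updates for the seed-shadow sampler.
//
// For every tree-year (i, t), in canonical order:
//  * conditional fecundity psi: random-walk Metropolis on log psi against
//    the Poisson trap likelihood and the log-normal prior
//    log psi ~ N(eta_it, sigma_e) (or an improper flat prior on psi when
//    flat_psi is set). When rho_it = 0 the likelihood is free of psi and
//    the update is an exact draw from the prior.
//  * maturation rho: Bernoulli full conditional combining the probit
//    size prior with the likelihood of switching the tree's contribution
//    on or off. Trees with a forced status (forced >= 0) are skipped.
//
// The Poisson log-likelihood difference for a change dpsi of tree j's
// fecundity decomposes as
//   sum_{s: y_st > 0} y_st log(1 + S_sj dpsi / lambda_st)  -  AS_j dpsi,
// with AS_j = sum_s A_s S_sj the tree's effort-weighted shadow total, so
// logarithms are only taken at traps that caught seeds that year.
//
// lambda (traps x years) is maintained incrementally and modified in
// place, as are log_psi and rho. Uses R's RNG stream.
//
// [[Rcpp::export]]
List cpp_sweep_tree_years(List S_list, List tree_idx, List trap_idx,
                          IntegerMatrix Y, NumericVector A,
                          NumericMatrix lambda, NumericMatrix log_psi,
                          IntegerMatrix rho, NumericMatrix eta,
                          double sigma_e, NumericVector mat_prob,
                          IntegerVector forced, double step_psi,
                          bool flat_psi, bool update_psi, bool update_rho) {
  const int n_plot = S_list.size();
  const int n_year = lambda.ncol();
  int psi_acc = 0, psi_try = 0;

  for (int p = 0; p < n_plot; ++p) {
    NumericMatrix S = S_list[p];
    IntegerVector ti = tree_idx[p];   // 1-based global tree indices
    IntegerVector si = trap_idx[p];   // 1-based global trap indices
    const int nt = ti.size(), ns = si.size();

    // effort-weighted shadow totals AS_j and the per-year lists of
    // local traps with positive counts
    std::vector<double> AS(nt, 0.0);
    for (int j = 0; j < nt; ++j) {
      double acc = 0.0;
      for (int s = 0; s < ns; ++s) acc += A[si[s] - 1] * S(s, j);
      AS[j] = acc;
    }
    std::vector< std::vector<int> > pos(n_year);
    for (int t = 0; t < n_year; ++t) {
      for (int s = 0; s < ns; ++s) {
        if (Y(si[s] - 1, t) > 0) pos[t].push_back(s);
      }
    }

    for (int j = 0; j < nt; ++j) {
      const int i = ti[j] - 1;
      for (int t = 0; t < n_year; ++t) {
        double lp = log_psi(i, t);
        double psi = std::exp(lp);
        int r = rho(i, t);
        const std::vector<int>& ps = pos[t];
        const int np = ps.size();

        if (update_psi) {
          if (r == 0) {
            if (!flat_psi) {  // exact prior draw; likelihood is flat
              lp = eta(i, t) + sigma_e * norm_rand();
              log_psi(i, t) = lp;
              psi = std::exp(lp);
            }
          } else {
            ++psi_try;
            const double lp_new = lp + step_psi * norm_rand();
            const double psi_new = std::exp(lp_new);
            const double dpsi = psi_new - psi;
            double dll = -AS[j] * dpsi;
            bool impossible = false;
            for (int q = 0; q < np; ++q) {
              const int s = ps[q];
              const int sg = si[s] - 1;
              const double ratio = S(s, j) * dpsi / lambda(sg, t);
              if (ratio <= -1.0) { impossible = true; break; }
              dll += Y(sg, t) * std::log1p(ratio);
            }
            double dprior;
            if (flat_psi) {
              dprior = lp_new - lp;  // flat on psi => density exp(lp) in lp
            } else {
              const double z_new = (lp_new - eta(i, t)) / sigma_e;
              const double z_old = (lp - eta(i, t)) / sigma_e;
              dprior = 0.5 * (z_old * z_old - z_new * z_new);
            }
            if (!impossible &&
                std::log(unif_rand()) < dll + dprior) {
              ++psi_acc;
              for (int s = 0; s < ns; ++s) {
                const int sg = si[s] - 1;
                lambda(sg, t) += S(s, j) * dpsi;
              }
              log_psi(i, t) = lp_new;
              lp = lp_new;
              psi = psi_new;
            }
          }
        }

        if (update_rho && forced[i] < 0) {
          // log odds of rho = 1 vs 0 given everything else
          const double m = mat_prob[i];
          int r_new;
          if (m <= 0.0) r_new = 0;
          else if (m >= 1.0) r_new = 1;
          else {
            // likelihood difference of having the tree on vs off
            double dll = -AS[j] * psi;
            bool off_impossible = false;
            for (int q = 0; q < np; ++q) {
              const int s = ps[q];
              const int sg = si[s] - 1;
              const double base =
                lambda(sg, t) - (r == 1 ? S(s, j) * psi : 0.0);
              if (base <= 0.0) { off_impossible = true; break; }
              dll += Y(sg, t) * std::log1p(S(s, j) * psi / base);
            }
            if (off_impossible) r_new = 1;
            else {
              const double logit1 = std::log(m) - std::log1p(-m) + dll;
              const double p1 = 1.0 / (1.0 + std::exp(-logit1));
              r_new = (unif_rand() < p1) ? 1 : 0;
            }
          }
          if (r_new != r) {
            const double dpsi = (r_new == 1 ? psi : -psi);
            for (int s = 0; s < ns; ++s) {
              const int sg = si[s] - 1;
              lambda(sg, t) += S(s, j) * dpsi;
            }
            rho(i, t) = r_new;
            r = r_new;
          }
        } else if (forced[i] >= 0 && rho(i, t) != forced[i]) {
          const double dpsi = (forced[i] == 1 ? psi : -psi);
          for (int s = 0; s < ns; ++s) {
            const int sg = si[s] - 1;
            lambda(sg, t) += S(s, j) * dpsi;
          }
          rho(i, t) = forced[i];
        }
      }
    }
  }
  return List::create(_["psi_accept"] = psi_acc, _["psi_try"] = psi_try);
}

// Poisson log likelihood of the count matrix given intensities, omitting
// the lgamma(y+1) data constant (used for Metropolis ratios on u).
// [[Rcpp::export]]
double cpp_loglik_counts(IntegerMatrix Y, NumericVector A,
                         NumericMatrix lambda) {
  double ll = 0.0;
  for (int t = 0; t < Y.ncol(); ++t) {
    for (int s = 0; s < Y.nrow(); ++s) {
      const double lam = lambda(s, t);
      const int y = Y(s, t);
      if (y > 0) {
        if (lam <= 0.0) return R_NegInf;
        ll += y * std::log(A[s] * lam);
      }
      ll -= A[s] * lam;
    }
  }
  return ll;
}
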