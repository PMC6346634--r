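#' Model specification for the seed-shadow analysis
#'
#' The data-generating model: each censused tree `i` has a latent
#' maturation status `rho` (0/1) and a conditional fecundity `psi`
#' (seeds per year); realised fecundity is `f = rho * psi`. On the log
#' scale, conditional fecundity follows
#' `log psi_it = b0 + bD * log(dbh) + bL * [logged] + bHL * [hunted_logged]
#'  (+ diameter-by-regime interactions) + a_i + gamma_tg + e_it`,
#' with per-tree random intercepts `a_i ~ N(0, sigma2_a)`, year effects
#' `gamma_tg ~ N(0, sigma2_g)` shared by all trees of regime `g` in year
#' `t` (coherent within, but not among, disturbance regimes), and
#' tree-year residuals `e_it ~ N(0, sigma2_e)`. Expected seed density at a
#' trap is the fecundity-weighted 2Dt seed shadow, and counts are
#' conditionally Poisson: `y_s ~ Poisson(A_s * lambda_s)` with
#' `lambda_s = sum_i S_si f_i`. Random and year effects make the counts
#' marginally overdispersed.
#'
#' @param interactions include diameter-by-regime interaction terms in the
#'   fixed effects
#' @param psi_prior prior for conditional fecundity: `"lognormal"` (the
#'   hierarchical model above) or `"flat"` (improper uniform on `psi > 0`;
#'   useful for analytic toy checks)
#' @param maturation a [maturation_model()]
#' @param priors a [prior_spec()]
#' @return list of class `seedshadow_model`
#' @export
model_spec <- function(interactions = FALSE,
                       psi_prior = c("lognormal", "flat"),
                       maturation = maturation_model(),
                       priors = prior_spec()) {
  psi_prior <- match.arg(psi_prior)
  structure(list(interactions = interactions, psi_prior = psi_prior,
                 maturation = maturation, priors = priors),
            class = "seedshadow_model")
}

#' Maturation sub-model
#'
#' Time-static probit on log diameter: the probability that a tree of
#' diameter `dbh` (cm) is reproductively active is
#' `Phi((log dbh - mu_log_dbh) / sigma_log_dbh)`. A tree at
#' `dbh = exp(mu_log_dbh)` is mature with probability one half.
#'
#' @param mu_log_dbh log-diameter threshold (log cm); default `log(20)`
#' @param sigma_log_dbh spread on the log-diameter scale; must be positive
#' @export
maturation_model <- function(mu_log_dbh = log(20), sigma_log_dbh = 0.5) {
  if (!is.finite(sigma_log_dbh) || sigma_log_dbh <= 0) {
    stop("sigma_log_dbh must be finite and positive", call. = FALSE)
  }
  list(mu_log_dbh = mu_log_dbh, sigma_log_dbh = sigma_log_dbh)
}

#' @rdname maturation_model
#' @param dbh_cm diameter at breast height, cm (vectorised, positive)
#' @param m a [maturation_model()]
#' @return probability of maturity, nondecreasing in `dbh_cm`
#' @export
maturation_probability <- function(dbh_cm, m = maturation_model()) {
  stopifnot(all(dbh_cm > 0))
  stats::pnorm((log(dbh_cm) - m$mu_log_dbh) / m$sigma_log_dbh)
}

#' Prior specification
#'
#' The dispersal scale `u` carries a flat (uniform) prior on
#' `[u_min, u_max]`; the default bounds correspond to mean dispersal
#' distances of 1-150 m, comfortably wider than any plausible estimate
#' for these stands. Fixed-effect coefficients get independent
#' `N(0, beta_sd^2)` priors (weakly informative at the default scale).
#' Variance components are inverse-gamma with fixed shape (degrees of
#' freedom) and configurable scale, which keeps their full conditionals
#' conjugate.
#'
#' @param u_mean_range_m mean-dispersal-distance range (m) defining the
#'   flat-prior support for `u` via [u_from_mean()]
#' @param beta_sd prior standard deviation of fixed effects
#' @param var_shape inverse-gamma shape for all variance components
#' @param var_scale_a,var_scale_g,var_scale_e inverse-gamma scales for the
#'   individual, year and residual variances
#' @export
prior_spec <- function(u_mean_range_m = c(1, 150), beta_sd = 10,
                       var_shape = 2, var_scale_a = 0.1,
                       var_scale_g = 0.1, var_scale_e = 0.1) {
  stopifnot(length(u_mean_range_m) == 2, u_mean_range_m[1] > 0,
            u_mean_range_m[2] > u_mean_range_m[1],
            beta_sd > 0, var_shape > 0,
            var_scale_a > 0, var_scale_g > 0, var_scale_e > 0)
  list(u_min = u_from_mean(u_mean_range_m[1]),
       u_max = u_from_mean(u_mean_range_m[2]),
       beta_sd = beta_sd, var_shape = var_shape,
       var_scale_a = var_scale_a, var_scale_g = var_scale_g,
       var_scale_e = var_scale_e)
}

#' Fixed-effect design matrix for log conditional fecundity
#'
#' Columns: intercept, log diameter, indicators for the disturbed regimes
#' (protected is the reference level) and, optionally, centred
#' log-diameter-by-regime interactions.
#'
#' @param trees tree census data frame (`dbh_cm`, `regime`)
#' @param interactions include diameter-by-regime interactions
#' @return numeric matrix, one row per tree
#' @export
fecundity_design <- function(trees, interactions = FALSE) {
  regime <- factor(trees$regime, levels = REGIME_LEVELS)
  ld <- log(trees$dbh_cm)
  X <- cbind(intercept = 1, log_dbh = ld,
             logged = as.numeric(regime == "logged"),
             hunted_logged = as.numeric(regime == "hunted_logged"))
  if (interactions) {
    ldc <- ld - mean(ld)
    X <- cbind(X, `log_dbh:logged` = ldc * X[, "logged"],
               `log_dbh:hunted_logged` = ldc * X[, "hunted_logged"])
  }
  rownames(X) <- if (!is.null(trees$tree_id)) as.character(trees$tree_id)
  X
}

#' Linear predictor of log conditional fecundity
#'
#' `eta_it = x_i' beta + a_i + gamma_tg`: fixed effects of size and regime
#' plus the tree's random intercept and its regime's year effect.
#'
#' @param trees tree census data frame
#' @param beta named fixed-effect vector matching [fecundity_design()]
#'   columns (missing names are treated as zero)
#' @param a per-tree random intercepts (scalar or one per tree)
#' @param gamma year effect(s) applying to these trees (scalar or one per
#'   tree)
#' @param interactions as in [fecundity_design()]
#' @return vector of log-fecundity means, one per tree
#' @export
linear_predictor <- function(trees, beta, a = 0, gamma = 0,
                             interactions = FALSE) {
  X <- fecundity_design(trees, interactions)
  b <- numeric(ncol(X))
  names(b) <- colnames(X)
  if (is.null(names(beta))) {
    stopifnot(length(beta) == ncol(X))
    b[] <- beta
  } else {
    unknown <- setdiff(names(beta), colnames(X))
    if (length(unknown)) stop("unknown coefficient(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    b[names(beta)] <- beta
  }
  stopifnot(all(is.finite(b)), all(is.finite(a)), all(is.finite(gamma)))
  as.vector(X %*% b) + a + gamma
}

#' Expected seed density at traps
#'
#' `lambda_s = sum_i S_si f_i`: the trap intensities (seeds per m^2 per
#' year) implied by a seed-shadow matrix and a fecundity vector. Linear
#' and additive in `f`.
#'
#' @param S seed-shadow matrix from [shadow_matrix()] (traps x trees)
#' @param f fecundity vector (seeds per year, `f >= 0`), or a trees x
#'   years matrix, in which case a traps x years intensity matrix is
#'   returned
#' @export
trap_intensity <- function(S, f) {
  if (any(f < 0)) stop("fecundity must be non-negative", call. = FALSE)
  if (ncol(S) == 0) {
    if (is.matrix(f)) return(matrix(0, nrow(S), ncol(f)))
    return(rep(0, nrow(S)))
  }
  out <- S %*% f
  if (is.matrix(f)) out else as.vector(out)
}

#' Poisson trap-count log likelihood
#'
#' `sum_s [ y_s log(A_s lambda_s) - A_s lambda_s - log(y_s!) ]`. A zero
#' intensity with a positive count yields `-Inf` (impossible data), which
#' is a valid return value, not an error.
#'
#' @param y observed counts (non-negative integers)
#' @param A sampling effort per observation (m^2 yr)
#' @param lambda expected seed density per observation (`>= 0`)
#' @export
log_likelihood_counts <- function(y, A, lambda) {
  stopifnot(length(A) %in% c(1L, length(y)),
            length(lambda) %in% c(1L, length(y)))
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  sum(stats::dpois(y, A * lambda, log = TRUE))
}

#' Joint log prior density
#'
#' Flat on `u` inside its bounds (and `-Inf` outside), independent
#' normals on `beta`, inverse-gamma on each variance component. Latent
#' states are excluded; their (log-normal) contribution is handled inside
#' the sampler.
#'
#' @param beta fixed-effect vector
#' @param u dispersal scale(s), m^2
#' @param sigma2_a,sigma2_g,sigma2_e variance components
#' @param priors a [prior_spec()]
#' @return log prior density (additive constants included); `-Inf`
#'   outside the support
#' @export
log_prior <- function(beta, u, sigma2_a, sigma2_g, sigma2_e,
                      priors = prior_spec()) {
  if (any(u < priors$u_min) || any(u > priors$u_max)) return(-Inf)
  if (any(c(sigma2_a, sigma2_g, sigma2_e) <= 0)) return(-Inf)
  lp <- -length(u) * log(priors$u_max - priors$u_min)
  lp <- lp + sum(stats::dnorm(beta, 0, priors$beta_sd, log = TRUE))
  lp + dinvgamma_log(sigma2_a, priors$var_shape, priors$var_scale_a) +
    dinvgamma_log(sigma2_g, priors$var_shape, priors$var_scale_g) +
    dinvgamma_log(sigma2_e, priors$var_shape, priors$var_scale_e)
}

dinvgamma_log <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}
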