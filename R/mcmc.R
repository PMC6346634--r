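#' Sampler configuration
#'
#' Metropolis-within-Gibbs settings. Defaults follow the analysis
#' protocol: 50,000 iterations with the first 1,000 discarded as
#' pre-convergence burn-in and thinning of 10. Proposal scales apply to
#' random-walk Metropolis moves on log conditional fecundity and log
#' dispersal scale; when `adapt` is `TRUE` they are tuned by
#' Robbins-Monro recursion during burn-in only (targeting 35 %
#' acceptance) and frozen afterwards, preserving the stationary
#' distribution.
#'
#' @param n_iter total MCMC iterations
#' @param burn_in iterations discarded before retention (`< n_iter`)
#' @param thin retain every `thin`-th post-burn-in iteration
#' @param rng_seed integer seed; the chain is deterministic given it
#' @param step_psi initial SD of log-fecundity proposals
#' @param step_u initial SD of log-dispersal-scale proposals
#' @param adapt adapt proposal scales during burn-in
#' @param n_inner latent-state sweeps (fecundity and maturation updates)
#'   composed into each recorded iteration; the latent field is the
#'   slowest-mixing block and extra sweeps are cheap at field-realistic
#'   stand sizes
#' @export
sampler_config <- function(n_iter = 50000, burn_in = 1000, thin = 10,
                           rng_seed = 1, step_psi = 0.5, step_u = 0.3,
                           adapt = TRUE, n_inner = 3) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1,
            step_psi > 0, step_u > 0, n_inner >= 1)
  list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
       thin = as.integer(thin), rng_seed = as.integer(rng_seed),
       step_psi = step_psi, step_u = step_u, adapt = isTRUE(adapt),
       n_inner = as.integer(n_inner))
}

# Assemble per-plot structures in a canonical order (sorted by plot and
# id), so chain output is invariant to the row order of the inputs.
prep_fit_data <- function(trees, traps, counts, species = NULL) {
  if (!is.null(species)) counts <- counts[counts$species == species, ]
  sp <- unique(counts$species)
  if (length(sp) != 1) {
    stop("counts must contain exactly one species per fit; got: ",
         paste(sp, collapse = ", "), " (use `species = ` to select)",
         call. = FALSE)
  }
  if (!is.null(trees$species)) {
    # only conspecific stems are candidate sources for a species' seeds
    trees <- trees[trees$species == sp, , drop = FALSE]
    if (!nrow(trees)) {
      stop("no censused trees of species ", sp, call. = FALSE)
    }
  }
  # plots without a single conspecific stem carry no signal for this
  # species; counts there must be zero (the model predicts none)
  has_tree <- unique(trees$plot_id)
  orphan <- counts[!(counts$plot_id %in% has_tree) & counts$count > 0, ]
  if (nrow(orphan)) {
    stop("positive ", sp, " counts in plot(s) without conspecific ",
         "stems: ", paste(unique(orphan$plot_id), collapse = ", "),
         call. = FALSE)
  }
  traps <- traps[traps$plot_id %in% has_tree, , drop = FALSE]
  counts <- counts[counts$plot_id %in% has_tree, , drop = FALSE]
  trees <- trees[order(trees$plot_id, trees$tree_id), , drop = FALSE]
  traps <- traps[order(traps$plot_id, traps$trap_id), , drop = FALSE]
  rownames(trees) <- rownames(traps) <- NULL
  years <- sort(unique(counts$year))
  Y <- matrix(0L, nrow(traps), length(years),
              dimnames = list(traps$trap_id, years))
  Y[cbind(match(counts$trap_id, traps$trap_id),
          match(counts$year, years))] <- as.integer(counts$count)
  if (sum(Y) == 0) {
    stop("species ", sp, " has no positive trap count anywhere; ",
         "its fecundity and dispersal are unidentifiable", call. = FALSE)
  }
  if ("effort_A" %in% names(counts)) {
    A <- counts$effort_A[match(traps$trap_id, counts$trap_id)]
    A[is.na(A)] <- (traps$area_m2 * traps$season_fraction)[is.na(A)]
  } else {
    A <- traps$area_m2 * traps$season_fraction
  }
  plots <- unique(traps$plot_id)
  tree_idx <- lapply(plots, function(p) which(trees$plot_id == p))
  trap_idx <- lapply(plots, function(p) which(traps$plot_id == p))
  D_list <- lapply(seq_along(plots), function(k) {
    distance_matrix(traps[trap_idx[[k]], , drop = FALSE],
                    trees[tree_idx[[k]], , drop = FALSE])
  })
  regime_tree <- as.character(trees$regime)
  regime_plot <- vapply(tree_idx, function(ix) regime_tree[ix[1]], "")
  regimes <- REGIME_LEVELS[REGIME_LEVELS %in% regime_tree]
  list(species = sp, trees = trees, traps = traps, years = years,
       Y = Y, A = A, plots = plots, tree_idx = tree_idx,
       trap_idx = trap_idx, D_list = D_list,
       regime_tree = regime_tree, regime_plot = regime_plot,
       regimes = regimes)
}

shadow_from_distance <- function(D, u) {
  S <- 1 / (pi * u * (1 + D^2 / u)^2)
  dim(S) <- dim(D)
  S
}

lambda_from_state <- function(d, S_list, f) {
  lambda <- matrix(0, nrow(d$Y), ncol(d$Y), dimnames = dimnames(d$Y))
  for (k in seq_along(S_list)) {
    lambda[d$trap_idx[[k]], ] <-
      S_list[[k]] %*% f[d$tree_idx[[k]], , drop = FALSE]
  }
  lambda
}

#' Fit the seed-shadow model by Metropolis-within-Gibbs sampling
#'
#' One species at a time (only conspecific stems act as sources), the
#' sampler cycles through: (1) per-tree-year conditional fecundity `psi`
#' by random-walk Metropolis on the log scale; (2) maturation status
#' `rho` from its Bernoulli full conditional for trees without a forced
#' status (both repeated `n_inner` times per iteration); (3) fixed
#' effects `beta` from their exact Gaussian full conditional (the latent
#' log-fecundity layer is linear-Gaussian), plus slice-sampled group
#' moves that shift a coefficient together with the latent log-fecundity
#' field along its likelihood ridge; (4) the dispersal scale `u`, one
#' per disturbance regime, by random-walk Metropolis on `log u` under
#' the flat bounded prior, plus a coupled shear move of
#' `(log u, gamma, log psi)`; (5) tree random intercepts `a_i` and
#' year-by-regime effects `gamma_tg` from Gaussian full conditionals;
#' (6) variance components from conjugate inverse-gamma draws. The
#' trap-intensity field `lambda` is maintained incrementally. Chains are
#' deterministic given `config$rng_seed` and invariant to input row
#' order.
#'
#' @param trees,traps,counts data frames as returned by the readers (or
#'   the simulator)
#' @param species species to fit (required when `counts` has several)
#' @param model a [model_spec()]
#' @param config a [sampler_config()]
#' @param fixed optional list pinning parts of the model: `u` (a single
#'   scale or named per-regime vector, m^2) fixes the kernel; `f` (tree x
#'   year fecundity matrix, rows matching sorted tree ids) fixes the
#'   latent states; `rho` (per-tree 0/1 vector) forces maturation status,
#'   e.g. for trees with observed seed attribution
#' @param init optional list of starting values overriding the built-in
#'   data-driven initialization: any of `log_psi`, `rho`, `beta`, `a`,
#'   `gamma`, `u`, `sigma2_a`, `sigma2_g`, `sigma2_e` (useful for
#'   overdispersed multi-chain diagnostics)
#' @return object of class `seedshadow_samples`: retained draws of
#'   `beta`, per-regime `u` and mean dispersal distance, variance
#'   components; posterior-mean intensity and fecundity fields; deviance
#'   trace; acceptance-rate ledger
#' @export
run_chain <- function(trees, traps, counts, species = NULL,
                      model = model_spec(), config = sampler_config(),
                      fixed = list(), init = list()) {
  d <- prep_fit_data(trees, traps, counts, species)
  pr <- model$priors
  set.seed(config$rng_seed)

  n_tree <- nrow(d$trees); n_trap <- nrow(d$traps)
  n_year <- length(d$years)
  flat_psi <- model$psi_prior == "flat"

  # --- design matrix; drop unidentifiable (all-constant-zero) columns
  X <- fecundity_design(d$trees, model$interactions)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) any(v != 0)))
  X <- X[, keep, drop = FALSE]
  p_beta <- ncol(X)

  # --- fixed pieces
  fix_f <- !is.null(fixed$f)
  fix_u <- !is.null(fixed$u)
  sample_latent <- !fix_f && !flat_psi

  # --- dispersal scale per regime
  if (fix_u) {
    u <- if (is.null(names(fixed$u))) {
      stats::setNames(rep(fixed$u[[1]], length(d$regimes)), d$regimes)
    } else {
      stats::setNames(fixed$u[d$regimes], d$regimes)
    }
    check_u(u)
  } else {
    u <- stats::setNames(rep(u_from_mean(25), length(d$regimes)), d$regimes)
  }
  S_list <- lapply(seq_along(d$plots), function(k) {
    shadow_from_distance(d$D_list[[k]], u[[d$regime_plot[k]]])
  })

  # --- latent state init (data-driven, deterministic)
  if (fix_f) {
    f <- fixed$f
    stopifnot(nrow(f) == n_tree, ncol(f) == n_year)
    rho <- matrix(as.integer(f > 0), n_tree, n_year)
    log_psi <- log(pmax(f, 1e-12))
  } else {
    # method-of-moments start: share each trap's counts among trees in
    # proportion to their shadows, then rescale by the tree's expected
    # trap-capture fraction so psi0 is on the seeds-per-year scale
    attributed <- capture <- numeric(n_tree)
    for (k in seq_along(d$plots)) {
      S <- S_list[[k]]
      si <- d$trap_idx[[k]]
      wt <- sweep(S, 1, pmax(rowSums(S), 1e-300), "/")
      attributed[d$tree_idx[[k]]] <-
        colSums(wt * rowSums(d$Y[si, , drop = FALSE]))
      capture[d$tree_idx[[k]]] <- as.vector(d$A[si] %*% S)
    }
    psi_mom <- attributed / (n_year * pmax(capture, 1e-12))
    floor0 <- max(stats::median(psi_mom[psi_mom > 0]), 1)
    psi0 <- pmax(psi_mom, floor0)
    log_psi <- matrix(log(psi0), n_tree, n_year)
    rho <- matrix(as.integer(d$trees$dbh_cm >=
                               stats::median(d$trees$dbh_cm)),
                  n_tree, n_year)
  }
  forced <- rep(-1L, n_tree)
  if (!is.null(fixed$rho)) forced <- as.integer(fixed$rho)
  if (fix_f) forced <- rho[, 1]
  for (i in which(forced >= 0)) rho[i, ] <- forced[i]

  # --- fixed-effect / random-effect init
  if (!is.null(fixed$beta)) {
    beta <- stats::setNames(numeric(p_beta), colnames(X))
    beta[names(fixed$beta)[names(fixed$beta) %in% colnames(X)]] <-
      fixed$beta[names(fixed$beta) %in% colnames(X)]
  } else {
    yfit <- log_psi[, 1]
    beta <- stats::setNames(
      tryCatch(stats::lm.fit(X, yfit)$coefficients,
               error = function(e) numeric(p_beta)), colnames(X))
    beta[!is.finite(beta)] <- 0
  }
  sample_beta <- is.null(fixed$beta) && sample_latent
  a <- numeric(n_tree)
  gamma <- matrix(0, n_year, length(d$regimes),
                  dimnames = list(d$years, d$regimes))
  sigma2_a <- pr$var_scale_a; sigma2_g <- pr$var_scale_g
  sigma2_e <- pr$var_scale_e
  mat_prob <- maturation_probability(d$trees$dbh_cm, model$maturation)
  g_of_tree <- match(d$regime_tree, d$regimes)

  # explicit starting values override the data-driven defaults
  if (!is.null(init$log_psi)) log_psi[] <- init$log_psi
  if (!is.null(init$rho)) rho[] <- as.integer(init$rho)
  if (!is.null(init$beta)) beta[names(init$beta)] <- init$beta
  if (!is.null(init$a)) a[] <- init$a
  if (!is.null(init$gamma)) gamma[] <- init$gamma
  if (!is.null(init$sigma2_a)) sigma2_a <- init$sigma2_a
  if (!is.null(init$sigma2_g)) sigma2_g <- init$sigma2_g
  if (!is.null(init$sigma2_e)) sigma2_e <- init$sigma2_e
  if (!is.null(init$u) && !fix_u) {
    u[] <- if (is.null(names(init$u))) init$u else init$u[d$regimes]
    S_list <- lapply(seq_along(d$plots), function(k) {
      shadow_from_distance(d$D_list[[k]], u[[d$regime_plot[k]]])
    })
  }

  f <- rho * exp(log_psi)
  lambda <- lambda_from_state(d, S_list, f)
  if (!is.finite(cpp_loglik_counts(d$Y, d$A, lambda))) {
    # a positive count at a trap with zero reachable fecundity
    rho[] <- 1L
    for (i in which(forced == 0)) rho[i, ] <- 0L
    lambda <- lambda_from_state(d, S_list, rho * exp(log_psi))
    if (!is.finite(cpp_loglik_counts(d$Y, d$A, lambda))) {
      stop("non-finite log posterior at initialization: positive counts ",
           "at traps with no possible seed source", call. = FALSE)
    }
  }

  # --- bookkeeping
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  par_names <- c(paste0("beta_", colnames(X)),
                 paste0("u_", d$regimes),
                 paste0("disp_", d$regimes),
                 "sigma2_a", "sigma2_g", "sigma2_e")
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  deviance <- numeric(n_keep)
  lambda_sum <- matrix(0, n_trap, n_year)
  f_sum <- matrix(0, n_tree, n_year)
  step_psi <- config$step_psi
  step_u <- stats::setNames(rep(config$step_u, length(d$regimes)),
                            d$regimes)
  step_uc <- step_u
  step_b <- rep(0.1, p_beta)
  # which design columns are constant within every plot (regime dummies,
  # intercept): their group moves have closed-form likelihood rays
  plot_x <- do.call(rbind, lapply(d$tree_idx, function(ix) {
    apply(X[ix, , drop = FALSE], 2, function(v) v[1])
  }))
  plot_const <- vapply(seq_len(p_beta), function(j) {
    all(vapply(d$tree_idx, function(ix)
      length(unique(X[ix, j])) == 1, TRUE))
  }, TRUE)
  plot_Y <- vapply(seq_along(d$plots), function(k)
    sum(d$Y[d$trap_idx[[k]], , drop = FALSE]), 0)
  plot_of_trap <- integer(n_trap)
  for (k in seq_along(d$plots)) plot_of_trap[d$trap_idx[[k]]] <- k
  plot_x_trap <- plot_x[plot_of_trap, , drop = FALSE]
  XtX <- crossprod(X)
  acc_psi <- c(0, 0)
  acc_u <- stats::setNames(rep(0, length(d$regimes)), d$regimes)
  try_u <- acc_uc <- try_uc <- acc_u
  acc_b <- try_b <- rep(0, p_beta)
  tau2 <- pr$beta_sd^2
  kstore <- 0

  for (it in seq_len(config$n_iter)) {
    in_burn <- it <= config$burn_in

    # (1)-(2) latent fecundity and maturation
    if (!fix_f) {
      eta <- matrix(as.vector(X %*% beta) + a, n_tree, n_year) +
        t(gamma)[g_of_tree, , drop = FALSE]
      for (rep_in in seq_len(config$n_inner)) {
        sw <- cpp_sweep_tree_years(S_list, d$tree_idx, d$trap_idx, d$Y,
                                   d$A, lambda, log_psi, rho, eta,
                                   sqrt(sigma2_e), mat_prob, forced,
                                   step_psi, flat_psi, TRUE, !flat_psi)
        acc_psi <- acc_psi + c(sw$psi_accept, sw$psi_try)
        if (config$adapt && in_burn && sw$psi_try > 0) {
          rate <- sw$psi_accept / sw$psi_try
          step_psi <- step_psi * exp((rate - 0.35) / it^0.6)
        }
      }
      f <- rho * exp(log_psi)
    }

    # (4) dispersal scale per regime. Two Metropolis moves per regime:
    # a plain random walk on log u, and a coupled "shear" move shifting
    # log u, the regime's year effects and its latent log-fecundity
    # field together (u and total fecundity trade off along a likelihood
    # ridge; the joint shift walks along it while leaving the
    # fecundity-layer residuals invariant).
    if (!fix_u) {
      for (g in d$regimes) {
        ks <- which(d$regime_plot == g)
        gi <- match(g, d$regimes)
        trees_g <- unlist(d$tree_idx[ks])

        for (move in c("plain", "coupled")) {
          if (move == "coupled" && !sample_latent) next
          eps <- stats::rnorm(1) *
            if (move == "plain") step_u[g] else step_uc[g]
          u_new <- u[[g]] * exp(eps)
          if (move == "plain") try_u[g] <- try_u[g] + 1 else
            try_uc[g] <- try_uc[g] + 1
          if (u_new >= pr$u_min && u_new <= pr$u_max) {
            fscale <- if (move == "coupled") exp(eps) else 1
            ll_old <- ll_new <- 0
            S_new <- vector("list", length(ks))
            for (kk in seq_along(ks)) {
              k <- ks[kk]
              si <- d$trap_idx[[k]]
              S_new[[kk]] <- shadow_from_distance(d$D_list[[k]], u_new)
              lam_new <- S_new[[kk]] %*%
                (fscale * f[d$tree_idx[[k]], , drop = FALSE])
              ll_old <- ll_old + cpp_loglik_counts(
                d$Y[si, , drop = FALSE], d$A[si],
                lambda[si, , drop = FALSE])
              ll_new <- ll_new + cpp_loglik_counts(
                d$Y[si, , drop = FALSE], d$A[si], lam_new)
            }
            # flat prior on u with a log-u proposal: Jacobian term
            lr <- ll_new - ll_old + log(u_new) - log(u[[g]])
            if (move == "coupled") {
              lr <- lr + sum(stats::dnorm(gamma[, gi] + eps, 0,
                                          sqrt(sigma2_g), log = TRUE) -
                             stats::dnorm(gamma[, gi], 0,
                                          sqrt(sigma2_g), log = TRUE))
            }
            if (is.finite(lr) && log(stats::runif(1)) < lr) {
              if (move == "plain") acc_u[g] <- acc_u[g] + 1 else
                acc_uc[g] <- acc_uc[g] + 1
              u[[g]] <- u_new
              if (move == "coupled") {
                log_psi[trees_g, ] <- log_psi[trees_g, ] + eps
                f[trees_g, ] <- f[trees_g, ] * exp(eps)
                gamma[, gi] <- gamma[, gi] + eps
              }
              for (kk in seq_along(ks)) {
                k <- ks[kk]
                S_list[[k]] <- S_new[[kk]]
                lambda[d$trap_idx[[k]], ] <- S_list[[k]] %*%
                  f[d$tree_idx[[k]], , drop = FALSE]
              }
            }
          }
          if (config$adapt && in_burn) {
            if (move == "plain") {
              step_u[g] <- step_u[g] *
                exp((acc_u[g] / try_u[g] - 0.35) / it^0.6)
            } else {
              step_uc[g] <- step_uc[g] *
                exp((acc_uc[g] / try_uc[g] - 0.35) / it^0.6)
            }
          }
        }
      }
    }

    # group moves: shift one fixed-effect coordinate together with the
    # whole latent log-fecundity field (log psi += delta * x_j). The
    # fecundity-layer residuals are invariant under the joint shift, so
    # the conditional density along the ray involves only the count
    # likelihood and the beta prior. The likelihood is nearly flat along
    # these rays (aggregated fecundity trades off against beta), so the
    # ray is explored by slice sampling, which traverses flat ridges
    # without step-size tuning. These moves carry count information to
    # beta directly instead of routing it through the per-tree states.
    if (sample_beta) {
      for (j in rep(seq_len(p_beta), 2)) {
        xj <- X[, j]
        if (plot_const[j]) {
          # x_j is constant within every plot, so the move rescales each
          # plot's intensity field by exp(delta * c_k): the likelihood
          # along the ray is available in closed form from per-plot
          # count and exposure totals
          ALs <- vapply(seq_along(d$plots), function(k) {
            si <- d$trap_idx[[k]]
            sum(d$A[si] * lambda[si, , drop = FALSE])
          }, 0)
          ck <- plot_x[, j]
          g <- function(delta) {
            sum(delta * ck * plot_Y - (exp(delta * ck) - 1) * ALs) +
              stats::dnorm(beta[j] + delta, 0, pr$beta_sd, log = TRUE)
          }
        } else {
          g <- function(delta) {
            lam <- lambda_from_state(d, S_list, f * exp(delta * xj))
            cpp_loglik_counts(d$Y, d$A, lam) +
              stats::dnorm(beta[j] + delta, 0, pr$beta_sd, log = TRUE)
          }
        }
        delta <- slice_ray(g, w = step_b[j])
        if (delta != 0) {
          acc_b[j] <- acc_b[j] + 1
          beta[j] <- beta[j] + delta
          log_psi <- log_psi + delta * xj
          f <- f * exp(delta * xj)
          lambda <- if (plot_const[j]) {
            sweep(lambda, 1, exp(delta * plot_x_trap[, j]), "*")
          } else {
            lambda_from_state(d, S_list, f)
          }
        }
        try_b[j] <- try_b[j] + 1
        if (config$adapt && in_burn) {
          # keep the initial bracket near the typical accepted move
          step_b[j] <- step_b[j] +
            (2 * abs(delta) - step_b[j]) / max(it, 10)
        }
      }
    }

    # (3), (5), (6) linear-Gaussian layer over log psi
    if (sample_latent) {
      gam_tree <- t(gamma)[g_of_tree, , drop = FALSE]
      if (sample_beta) {
        z <- log_psi - a - gam_tree
        prec <- XtX * (n_year / sigma2_e) + diag(1 / tau2, p_beta)
        mu <- solve(prec, crossprod(X, rowSums(z)) / sigma2_e)
        R <- chol(prec)
        beta <- stats::setNames(
          as.vector(mu + backsolve(R, stats::rnorm(p_beta))),
          colnames(X))
      }
      xb <- as.vector(X %*% beta)
      w <- rowSums(log_psi - xb - gam_tree)
      v_a <- 1 / (n_year / sigma2_e + 1 / sigma2_a)
      a <- stats::rnorm(n_tree, v_a * w / sigma2_e, sqrt(v_a))
      resid_ag <- log_psi - xb - a
      for (gi in seq_along(d$regimes)) {
        rows <- which(g_of_tree == gi)
        n_g <- length(rows)
        if (!n_g) next
        for (t in seq_len(n_year)) {
          v_g <- 1 / (n_g / sigma2_e + 1 / sigma2_g)
          m_g <- v_g * sum(resid_ag[rows, t]) / sigma2_e
          gamma[t, gi] <- stats::rnorm(1, m_g, sqrt(v_g))
        }
      }
      r_all <- log_psi - xb - a - t(gamma)[g_of_tree, , drop = FALSE]
      sigma2_a <- rinvgamma(pr$var_shape + n_tree / 2,
                            pr$var_scale_a + sum(a^2) / 2)
      sigma2_g <- rinvgamma(pr$var_shape + length(gamma) / 2,
                            pr$var_scale_g + sum(gamma^2) / 2)
      sigma2_e <- rinvgamma(pr$var_shape + length(r_all) / 2,
                            pr$var_scale_e + sum(r_all^2) / 2)
    }

    # retain
    if (!in_burn && (it - config$burn_in) %% config$thin == 0) {
      kstore <- kstore + 1
      draws[kstore, ] <- c(beta, u, mean_distance(unlist(u)),
                           sigma2_a, sigma2_g, sigma2_e)
      deviance[kstore] <-
        -2 * sum(stats::dpois(d$Y, d$A * lambda, log = TRUE))
      lambda_sum <- lambda_sum + lambda
      f_sum <- f_sum + f
    }
  }

  structure(list(
    draws = draws[seq_len(kstore), , drop = FALSE],
    deviance = deviance[seq_len(kstore)],
    lambda_mean = lambda_sum / max(kstore, 1),
    f_mean = f_sum / max(kstore, 1),
    acceptance = list(
      psi = if (acc_psi[2] > 0) acc_psi[1] / acc_psi[2] else NA_real_,
      u = ifelse(try_u > 0, acc_u / try_u, NA_real_),
      beta_group = if (any(try_b > 0)) acc_b / pmax(try_b, 1) else NULL),
    steps = list(psi = step_psi, u = step_u, beta_group = step_b),
    species = d$species, regimes = d$regimes, years = d$years,
    Y = d$Y, A = d$A, trees = d$trees, traps = d$traps,
    model = model, config = config),
    class = "seedshadow_samples")
}

rinvgamma <- function(shape, scale) 1 / stats::rgamma(1, shape, rate = scale)

# Univariate slice sampler along a ray through the current state
# (Neal 2003: stepping out, then shrinkage). `g` is the log conditional
# density of the displacement; g(0) is the current state and must be
# finite. Returns the sampled displacement.
slice_ray <- function(g, w = 0.5, max_out = 8, max_shrink = 50) {
  g0 <- g(0)
  if (!is.finite(g0)) return(0)
  logy <- g0 - stats::rexp(1)
  L <- -stats::runif(1) * w
  R <- L + w
  k <- max_out
  while (k > 0 && is.finite(gl <- g(L)) && gl > logy) {
    L <- L - w; k <- k - 1
  }
  k <- max_out
  while (k > 0 && is.finite(gr <- g(R)) && gr > logy) {
    R <- R + w; k <- k - 1
  }
  for (i in seq_len(max_shrink)) {
    delta <- stats::runif(1, L, R)
    gd <- g(delta)
    if (is.finite(gd) && gd > logy) return(delta)
    if (delta < 0) L <- delta else R <- delta
  }
  0
}

#' @export
print.seedshadow_samples <- function(x, ...) {
  cat("seed-shadow fit:", x$species, "|", nrow(x$draws), "retained draws\n")
  cat("regimes:", paste(x$regimes, collapse = ", "), "\n")
  qs <- t(apply(x$draws, 2, stats::quantile,
                probs = c(0.025, 0.5, 0.975), type = 7))
  print(round(cbind(mean = colMeans(x$draws), qs), 3))
  cat("acceptance: psi", round(x$acceptance$psi, 2), "| u",
      paste(round(x$acceptance$u, 2), collapse = " "), "\n")
  invisible(x)
}

#' Deviance information criterion and prediction error
#'
#' `DIC = mean deviance + p_D`, with the effective parameter count
#' `p_D = mean deviance - deviance at the posterior-mean intensities`;
#' `RMSPE` is the root mean squared prediction error between observed
#' counts and `A * lambda-hat` over all trap-years.
#'
#' @param samples a `seedshadow_samples` object with at least 100
#'   retained draws
#' @return list with `DIC`, `p_D`, `mean_deviance`, `RMSPE`
#' @export
fit_metrics <- function(samples) {
  if (nrow(samples$draws) < 100) {
    stop("fit metrics need at least 100 retained draws", call. = FALSE)
  }
  mean_dev <- mean(samples$deviance)
  dev_at_mean <- -2 * sum(stats::dpois(samples$Y,
                                       samples$A * samples$lambda_mean,
                                       log = TRUE))
  p_d <- mean_dev - dev_at_mean
  pred <- samples$A * samples$lambda_mean
  list(DIC = mean_dev + p_d, p_D = p_d, mean_deviance = mean_dev,
       RMSPE = sqrt(mean((samples$Y - pred)^2)))
}

#' Convergence diagnostics
#'
#' Split-chain potential scale reduction (R-hat) and effective sample
#' size per scalar parameter. A single chain is split into halves; with
#' several chains each is split, giving 2m sequences. Parameters with
#' R-hat above 1.1 are flagged; constant sequences are reported with
#' `NA` R-hat, zero ESS and a flag rather than an error.
#'
#' @param samples a `seedshadow_samples`, a draws matrix, or a list of
#'   either (multiple chains)
#' @param flag_above flag threshold for R-hat
#' @return data frame: `parameter`, `rhat`, `ess`, `flagged`
#' @export
convergence_summary <- function(samples, flag_above = 1.1) {
  chains <- if (inherits(samples, "seedshadow_samples")) {
    list(samples$draws)
  } else if (is.matrix(samples)) {
    list(samples)
  } else {
    lapply(samples, function(s)
      if (inherits(s, "seedshadow_samples")) s$draws else s)
  }
  n <- min(vapply(chains, nrow, 0L))
  if (n < 8) stop("too few draws for convergence diagnostics",
                  call. = FALSE)
  pars <- colnames(chains[[1]])
  out <- data.frame(parameter = pars, rhat = NA_real_, ess = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  half <- n %/% 2
  for (j in seq_along(pars)) {
    segs <- list()
    for (ch in chains) {
      x <- ch[seq_len(2 * half), j]
      segs <- c(segs, list(x[1:half], x[(half + 1):(2 * half)]))
    }
    if (all(vapply(segs, stats::var, 0) == 0)) {
      out$ess[j] <- 0
      out$flagged[j] <- TRUE
      next
    }
    m <- length(segs)
    means <- vapply(segs, mean, 0)
    vars <- vapply(segs, stats::var, 0)
    W <- mean(vars)
    B <- half * stats::var(means)
    var_plus <- (half - 1) / half * W + B / half
    out$rhat[j] <- sqrt(var_plus / W)
    # ESS from pooled autocorrelation, initial positive sequence
    rho_sum <- 0
    x_all <- lapply(segs, function(x) x - mean(x))
    max_lag <- half - 2
    for (l in seq_len(max_lag)) {
      g <- mean(vapply(x_all, function(x) {
        mean(x[1:(half - l)] * x[(1 + l):half])
      }, 0)) / var_plus
      if (g < 0.01) break
      rho_sum <- rho_sum + g
    }
    out$ess[j] <- m * half / (1 + 2 * rho_sum)
    out$flagged[j] <- is.na(out$rhat[j]) || out$rhat[j] > flag_above
  }
  out
}
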