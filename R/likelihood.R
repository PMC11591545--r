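# Importance-sampling marginal likelihood, AIC/BIC, and the common-random-
# numbers OFV used for information-matrix standard errors.

# Structural predictions for a flat stack of parameter draws.
# phi_flat: (n_sub * n_mc) x p matrix, subject index fastest (draw-major
# blocks); returns the f vector of length n_obs * n_mc (same stacking).
.f_stack <- function(phi_flat, sdata, spec, n_mc) {
  n <- sdata$n_sub
  full <- matrix(NA_real_, nrow(phi_flat), 4L,
                 dimnames = list(NULL, c("CL", "V1", "Q", "V2")))
  for (p in spec$free) full[, p] <- exp(phi_flat[, p])
  for (p in names(spec$fixed)) full[, p] <- spec$fixed[[p]]
  if (spec$n_compartments == 1) { full[, "Q"] <- 0; full[, "V2"] <- 1 }
  pr <- sdata$pairs
  n_pairs <- nrow(pr)
  d_idx <- rep(seq_len(n_mc), each = n_pairs)
  gi <- (d_idx - 1L) * n + rep(pr$sub, n_mc)
  goi <- (d_idx - 1L) * sdata$n_obs + rep(pr$obs_row, n_mc)
  contrib <- .conc_contrib(full[gi, "CL"], full[gi, "V1"],
                           full[gi, "Q"], full[gi, "V2"],
                           rep(pr$tt, n_mc), rep(pr$amt, n_mc),
                           rep(pr$dur, n_mc))
  as.numeric(rowsum(contrib, goi))
}

# n_sub x n_mc matrix of per-subject conditional log-likelihoods.
.cond_ll_stack <- function(phi_flat, sdata, spec, a, b, n_mc) {
  n <- sdata$n_sub
  f <- .f_stack(phi_flat, sdata, spec, n_mc)
  y <- rep(sdata$obs$y, n_mc)
  s <- .res_sd(f, spec$error, a, b)
  ll <- dnorm(y, f, s, log = TRUE)
  g_sub <- rep((seq_len(n_mc) - 1L) * n, each = sdata$n_obs) +
    rep(sdata$obs$sub, n_mc)
  matrix(as.numeric(rowsum(ll, g_sub)), n, n_mc)
}

# OFV by importance sampling with externally supplied standard-normal draws
# Z (n_sub x n_mc x p) and a fixed proposal; smooth in the parameters, which
# is what the finite-difference information matrix needs.
.ofv_is <- function(beta, omega, a, b, sdata, spec, X, prop_mean, prop_sd, Z) {
  free <- spec$free
  p <- length(free)
  n <- sdata$n_sub
  n_mc <- dim(Z)[2] / p
  m <- matrix(unlist(lapply(free, function(pp) X[[pp]] %*% beta[[pp]])),
              n, p, dimnames = list(NULL, free))
  # draws: phi[i, d, k] = prop_mean[i,k] + prop_sd[i,k] * Z[i, (d-1)p+k]
  phi_flat <- matrix(NA_real_, n * n_mc, p, dimnames = list(NULL, free))
  lq <- matrix(0, n, n_mc)
  lp <- matrix(0, n, n_mc)
  for (k in seq_len(p)) {
    zz <- Z[, seq(k, n_mc * p, by = p), drop = FALSE] # n x n_mc
    draw <- prop_mean[, k] + prop_sd[, k] * zz
    phi_flat[, k] <- as.numeric(draw) # subject-fastest stacking
    lq <- lq + dnorm(draw, prop_mean[, k], prop_sd[, k], log = TRUE)
    lp <- lp + dnorm(draw, m[, k], omega[[free[k]]], log = TRUE)
  }
  llmat <- .cond_ll_stack(phi_flat, sdata, spec, a, b, n_mc)
  lw <- llmat + lp - lq
  ll_sub <- apply(lw, 1L, logsumexp) - log(n_mc)
  # per-subject Monte Carlo SE of the log-likelihood (delta method)
  se2 <- vapply(seq_len(n), function(i) {
    w <- exp(lw[i, ] - max(lw[i, ]))
    (sd(w) / (mean(w) * sqrt(n_mc)))^2
  }, numeric(1))
  list(ofv = -2 * sum(ll_sub), mc_se = 2 * sqrt(sum(se2)), ll_sub = ll_sub)
}

#' Marginal likelihood, AIC and BIC by importance sampling
#'
#' Estimates each subject's marginal log-likelihood by importance sampling
#' around the empirical Bayes distribution of the random effects (normal
#' proposal centred at the conditional mean with `inflation` times the
#' conditional SD), and reports the objective function value
#' `OFV = -2 log L`, `AIC = OFV + 2 P` and `BIC = OFV + log(n_subjects) P`,
#' where `P` counts free typical values, covariate coefficients, IIV SDs and
#' residual-error parameters (fixed parameters such as Q are excluded).
#'
#' @param fit a [fit_popmodel()] result
#' @param n_mc importance-sampling draws per subject
#' @param seed integer seed
#' @param inflation proposal SD inflation factor (> 1 guards tails)
#' @return list with `ofv`, `aic`, `bic`, `mc_se` (Monte Carlo SE of the
#'   OFV), `n_param`, and per-subject log-likelihoods `ll_sub`
#' @export
log_likelihood <- function(fit, n_mc = 10000L, seed = 1L, inflation = 1.3) {
  stopifnot(inherits(fit, "pk_fit"))
  n_mc <- as.integer(n_mc)
  free <- fit$spec$free
  p <- length(free)
  prop <- .is_proposal(fit, inflation)
  Z <- withr::with_seed(derive_seed(seed, "is_loglik"), {
    array(rnorm(fit$sdata$n_sub * n_mc * p), dim = c(fit$sdata$n_sub, n_mc * p))
  })
  res <- .ofv_is(fit$run$beta, fit$omega, fit$error[["a"]], fit$error[["b"]],
                 fit$sdata, fit$spec, fit$run$X, prop$mean, prop$sd, Z)
  P <- length(free) + sum(lengths(fit$beta)) + length(fit$omega) +
    switch(fit$spec$error, proportional = 1L, constant = 1L, combined = 2L)
  list(ofv = res$ofv, aic = res$ofv + 2 * P,
       bic = res$ofv + log(fit$sdata$n_sub) * P,
       mc_se = res$mc_se, n_param = P, ll_sub = res$ll_sub)
}

.is_proposal <- function(fit, inflation) {
  free <- fit$spec$free
  n <- fit$sdata$n_sub
  sd0 <- fit$run$phi_sd
  # keep the proposal at least a fraction of the prior width so a collapsed
  # conditional SD cannot starve the sampler
  floor_sd <- matrix(rep(0.1 * fit$omega[free], each = n), n)
  prop_sd <- pmax(inflation * sd0, floor_sd)
  if (any(!is.finite(prop_sd)) || any(prop_sd <= 0)) {
    abort(paste("Degenerate importance-sampling proposal (zero SD);",
                "increase `inflation` or check the fitted variabilities."))
  }
  list(mean = fit$run$phi_mean, sd = prop_sd)
}
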