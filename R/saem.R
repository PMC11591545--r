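# SAEM engine for the nonlinear mixed-effects model.
#
# Individual log-parameters phi_{i,p} = X_i beta_p + eta_{i,p},
# eta ~ N(0, omega_p^2) independently per parameter (diagonal omega), with
# the analytic infusion model as structural prediction and a
# proportional / constant / combined residual-error model. The E-step runs
# a short Metropolis chain per subject (one independence kernel from the
# conditional prior plus random-walk kernels, all subjects vectorized); the
# M-step updates fixed effects by weighted least squares on stochastic
# approximations of the sufficient statistics.

#' Model specification for the population fit
#'
#' @param n_compartments 1 or 2 (the three-compartment structure is not an
#'   estimation target of this package)
#' @param fixed named vector of structural parameters held fixed, e.g.
#'   `c(Q = 0.476)` to fix the inter-compartmental clearance to the
#'   literature value. Fixed parameters are excluded from estimation, from
#'   IIV, and from the free-parameter count of AIC/BIC.
#' @param error residual error model: `y = f(1 + b eps)` (proportional),
#'   `y = f + a eps` (constant), or `sd = a + b f` (combined)
#' @param covariates named list mapping a structural parameter to covariate
#'   column names entering as power models on the median-normalized
#'   covariate, e.g. `list(CL = "CRCL")`
#' @return object of class `model_spec`
#' @export
model_spec <- function(n_compartments = 2,
                       fixed = c(Q = 0.476),
                       error = c("proportional", "constant", "combined"),
                       covariates = list()) {
  error <- match.arg(error)
  struct <- switch(as.character(n_compartments),
                   "1" = c("CL", "V1"),
                   "2" = c("CL", "V1", "Q", "V2"),
                   abort("`n_compartments` must be 1 or 2."))
  fixed <- fixed[names(fixed) %in% struct]
  free <- setdiff(struct, names(fixed))
  if (length(free) == 0L) abort("At least one structural parameter must be free.")
  if (!all(names(covariates) %in% free)) {
    abort("Covariate effects are only allowed on free parameters.")
  }
  structure(list(n_compartments = n_compartments, struct = struct,
                 fixed = fixed, free = free, error = error,
                 covariates = covariates),
            class = "model_spec")
}

#' SAEM run settings
#'
#' @param n_burn exploratory iterations (step size 1, simulated annealing on
#'   the variance components)
#' @param n_smooth smoothing iterations (decreasing step size `1/k`)
#' @param n_rw random-walk Metropolis kernels per iteration (plus one
#'   independence kernel)
#' @param anneal variance annealing factor in the exploratory phase
#' @param tol relative-change tolerance on the estimates used to flag
#'   convergence over the final iterations
#' @param n_mc_ll Monte Carlo size of the importance-sampling likelihood
#'   computed at the end of the fit (refine with [log_likelihood()])
#' @param n_ebe MCMC iterations used for the empirical Bayes summaries
#' @param omega_floor,b_floor numerical lower bounds keeping the chain alive
#'   when a variance component collapses toward zero
#' @return list of class `saem_control`
#' @export
saem_control <- function(n_burn = 500L, n_smooth = 200L, n_rw = 2L,
                         anneal = 0.95, tol = 1e-3,
                         n_mc_ll = 1000L, n_ebe = 400L,
                         omega_floor = 1e-3, b_floor = 1e-6) {
  structure(list(n_burn = as.integer(n_burn), n_smooth = as.integer(n_smooth),
                 n_rw = as.integer(n_rw), anneal = anneal, tol = tol,
                 n_mc_ll = as.integer(n_mc_ll), n_ebe = as.integer(n_ebe),
                 omega_floor = omega_floor, b_floor = b_floor),
            class = "saem_control")
}

# Prepare flat structures for fast likelihood evaluation. Only
# total-concentration observations enter the fit.
.saem_data <- function(d, spec) {
  d <- validate_pkdata(d)
  ids <- sort(unique(d$ID))
  n_sub <- length(ids)
  sub_of <- match(d$ID, ids)
  obs_keep <- d$EVID == 0L & d$ANALYTE == "total" & !is.na(d$DV)
  obs <- tibble::tibble(sub = sub_of[obs_keep], time = d$TIME[obs_keep],
                        y = d$DV[obs_keep])
  o <- order(obs$sub, obs$time)
  obs <- obs[o, ]
  doses <- tibble::tibble(sub = sub_of[d$EVID == 1L],
                          time = d$TIME[d$EVID == 1L],
                          amt = d$AMT[d$EVID == 1L],
                          dur = d$DUR[d$EVID == 1L])
  pairs <- list()
  for (r in seq_len(nrow(obs))) {
    dd <- doses[doses$sub == obs$sub[r] & doses$time < obs$time[r], ]
    if (nrow(dd) == 0L) {
      abort(sprintf("Observation at t=%g for subject %s precedes every dose.",
                    obs$time[r], ids[obs$sub[r]]))
    }
    pairs[[r]] <- tibble::tibble(obs_row = r, sub = obs$sub[r],
                                 tt = obs$time[r] - dd$time,
                                 amt = dd$amt, dur = dd$dur)
  }
  pairs <- dplyr::bind_rows(pairs)
  # one covariate row per subject
  first <- match(ids, d$ID)
  covs <- tibble::as_tibble(d[first, intersect(c("WT", "BSA", "AGE", "CRCL",
                                                 "ALB", "PB"), names(d))])
  list(ids = ids, n_sub = n_sub, obs = obs, pairs = pairs, covs = covs,
       n_obs = nrow(obs))
}

# Design matrix (intercept + log median-normalized covariates) per free
# parameter, from the spec's covariate map.
.design_mats <- function(sdata, spec) {
  lapply(setNames(spec$free, spec$free), function(p) {
    cvs <- spec$covariates[[p]]
    X <- matrix(1, sdata$n_sub, 1L, dimnames = list(NULL, "(Intercept)"))
    for (cv in cvs %||% character()) {
      v <- sdata$covs[[cv]]
      if (is.null(v) || anyNA(v)) {
        bad <- if (is.null(v)) "all" else paste(sdata$ids[is.na(v)], collapse = ", ")
        abort(sprintf("Covariate %s missing for subjects: %s", cv, bad))
      }
      X <- cbind(X, setNames(data.frame(log(v / median(v))), cv))
      X <- as.matrix(X)
    }
    X
  })
}

# f(phi): structural predictions for all observations given the n_sub x p
# matrix of free log-parameters.
.predict_f <- function(phi, sdata, spec) {
  full <- matrix(NA_real_, sdata$n_sub, 4L,
                 dimnames = list(NULL, c("CL", "V1", "Q", "V2")))
  for (p in spec$free) full[, p] <- exp(phi[, p])
  for (p in names(spec$fixed)) full[, p] <- spec$fixed[[p]]
  if (spec$n_compartments == 1) { full[, "Q"] <- 0; full[, "V2"] <- 1 }
  pr <- sdata$pairs
  contrib <- .conc_contrib(full[pr$sub, "CL"], full[pr$sub, "V1"],
                           full[pr$sub, "Q"], full[pr$sub, "V2"],
                           pr$tt, pr$amt, pr$dur)
  as.numeric(rowsum(contrib, pr$obs_row))
}

.res_sd <- function(f, err, a, b) {
  switch(err,
         proportional = pmax(b * abs(f), 1e-12),
         constant = pmax(a, 1e-12),
         combined = pmax(a + b * abs(f), 1e-12))
}

# per-subject log p(y | phi)
.ll_subject <- function(phi, sdata, spec, a, b) {
  f <- .predict_f(phi, sdata, spec)
  s <- .res_sd(f, spec$error, a, b)
  ll <- dnorm(sdata$obs$y, f, s, log = TRUE)
  as.numeric(rowsum(ll, sdata$obs$sub))
}

# Core SAEM loop. init: list(typical named vector, omega named vector,
# error_a, error_b). Returns estimates, trace, EBE summaries.
.saem_run <- function(sdata, spec, init, control, seed) {
  free <- spec$free
  p <- length(free)
  n <- sdata$n_sub
  X <- .design_mats(sdata, spec)
  beta <- lapply(setNames(free, free), function(pp) {
    b0 <- numeric(ncol(X[[pp]]))
    b0[1] <- log(init$typical[[pp]])
    b0
  })
  omega <- pmax(init$omega[free], control$omega_floor)
  names(omega) <- free
  a_err <- init$error_a
  b_err <- max(init$error_b, control$b_floor)

  K <- control$n_burn + control$n_smooth
  trace <- matrix(NA_real_, K, p + p + 2,
                  dimnames = list(NULL, c(paste0("mu_", free),
                                          paste0("omega_", free), "a", "b")))

  withr::with_seed(derive_seed(seed, "saem"), {
    prior_mean <- function() {
      matrix(unlist(lapply(free, function(pp) X[[pp]] %*% beta[[pp]])),
             n, p, dimnames = list(NULL, free))
    }
    m <- prior_mean()
    phi <- m + matrix(rnorm(n * p, 0, 0.1), n, p) %*% diag(omega, p)
    colnames(phi) <- free
    ll <- .ll_subject(phi, sdata, spec, a_err, b_err)
    s1 <- phi; s2 <- phi^2
    s_err <- NULL
    rho <- 0.4 # RW scale (relative to omega), adapted in burn-in

    for (k in seq_len(K)) {
      gamma <- if (k <= control$n_burn) 1 else 1 / (k - control$n_burn)
      m <- prior_mean()

      # independence kernel from the conditional prior
      phi_star <- m + matrix(rnorm(n * p), n, p) %*% diag(omega, p)
      colnames(phi_star) <- free
      ll_star <- .ll_subject(phi_star, sdata, spec, a_err, b_err)
      acc <- log(runif(n)) < (ll_star - ll)
      phi[acc, ] <- phi_star[acc, , drop = FALSE]
      ll[acc] <- ll_star[acc]

      # random-walk kernels
      for (rep in seq_len(control$n_rw)) {
        phi_star <- phi + matrix(rnorm(n * p), n, p) %*% diag(rho * omega, p)
        colnames(phi_star) <- free
        ll_star <- .ll_subject(phi_star, sdata, spec, a_err, b_err)
        dprior <- rowSums(dnorm(phi_star, m, rep(omega, each = n), log = TRUE) -
                          dnorm(phi, m, rep(omega, each = n), log = TRUE))
        acc <- log(runif(n)) < (ll_star - ll + dprior)
        phi[acc, ] <- phi_star[acc, , drop = FALSE]
        ll[acc] <- ll_star[acc]
        if (k <= control$n_burn) {
          rho <- max(0.01, min(10, rho * exp(0.05 * (mean(acc) - 0.3))))
        }
      }

      # stochastic approximation of sufficient statistics
      s1 <- s1 + gamma * (phi - s1)
      s2 <- s2 + gamma * (phi^2 - s2)
      f_cur <- .predict_f(phi, sdata, spec)
      res <- sdata$obs$y - f_cur
      err_stat <- switch(spec$error,
                         proportional = mean((res / pmax(abs(f_cur), 1e-12))^2),
                         constant = mean(res^2),
                         combined = NULL)
      if (!is.null(err_stat)) {
        s_err <- if (is.null(s_err)) err_stat else s_err + gamma * (err_stat - s_err)
      }

      # M-step
      for (pp in free) {
        XtX <- crossprod(X[[pp]])
        beta[[pp]] <- as.numeric(solve(XtX, crossprod(X[[pp]], s1[, pp])))
        fitted <- as.numeric(X[[pp]] %*% beta[[pp]])
        w2 <- mean(s2[, pp] - 2 * fitted * s1[, pp] + fitted^2)
        w2 <- max(w2, control$omega_floor^2)
        if (k <= control$n_burn) w2 <- max(w2, control$anneal * omega[[pp]]^2)
        omega[[pp]] <- sqrt(w2)
      }
      if (spec$error == "proportional") {
        b_new <- sqrt(max(s_err, control$b_floor^2))
        if (k <= control$n_burn) b_new <- max(b_new, sqrt(control$anneal) * b_err)
        b_err <- b_new
      } else if (spec$error == "constant") {
        a_new <- sqrt(max(s_err, control$b_floor^2))
        if (k <= control$n_burn) a_new <- max(a_new, sqrt(control$anneal) * a_err)
        a_err <- a_new
      } else {
        opt <- optim(c(log(max(a_err, 1e-6)), log(max(b_err, 1e-6))),
                     function(th) {
                       s <- pmax(exp(th[1]) + exp(th[2]) * abs(f_cur), 1e-12)
                       -sum(dnorm(res, 0, s, log = TRUE))
                     }, method = "Nelder-Mead", control = list(maxit = 30))
        a_err <- exp(log(a_err) + gamma * (opt$par[1] - log(a_err)))
        b_err <- exp(log(b_err) + gamma * (opt$par[2] - log(b_err)))
      }

      trace[k, ] <- c(vapply(free, function(pp) beta[[pp]][1], numeric(1)),
                      omega, a_err, b_err)
    }

    # empirical Bayes summaries at the final estimates
    m <- prior_mean()
    eb_n <- 0L
    eb_mean <- matrix(0, n, p, dimnames = list(NULL, free))
    eb_m2 <- eb_mean
    warm <- control$n_ebe %/% 4L
    for (k in seq_len(control$n_ebe)) {
      phi_star <- m + matrix(rnorm(n * p), n, p) %*% diag(omega, p)
      colnames(phi_star) <- free
      ll_star <- .ll_subject(phi_star, sdata, spec, a_err, b_err)
      acc <- log(runif(n)) < (ll_star - ll)
      phi[acc, ] <- phi_star[acc, , drop = FALSE]
      ll[acc] <- ll_star[acc]
      for (rep in seq_len(control$n_rw)) {
        phi_star <- phi + matrix(rnorm(n * p), n, p) %*% diag(rho * omega, p)
        colnames(phi_star) <- free
        ll_star <- .ll_subject(phi_star, sdata, spec, a_err, b_err)
        dprior <- rowSums(dnorm(phi_star, m, rep(omega, each = n), log = TRUE) -
                          dnorm(phi, m, rep(omega, each = n), log = TRUE))
        acc <- log(runif(n)) < (ll_star - ll + dprior)
        phi[acc, ] <- phi_star[acc, , drop = FALSE]
        ll[acc] <- ll_star[acc]
      }
      if (k > warm) {
        eb_n <- eb_n + 1L
        delta <- phi - eb_mean
        eb_mean <- eb_mean + delta / eb_n
        eb_m2 <- eb_m2 + delta * (phi - eb_mean)
      }
    }
    eb_sd <- sqrt(eb_m2 / max(eb_n - 1L, 1L))
  })

  # convergence: relative drift of the estimates across the final 10% of
  # the smoothing phase
  tail_n <- max(10L, control$n_smooth %/% 10L)
  tail_tr <- trace[(K - tail_n + 1L):K, , drop = FALSE]
  drift <- apply(tail_tr, 2, function(v) {
    span <- max(v) - min(v)
    span / max(abs(v[length(v)]), 1e-8)
  })
  converged <- all(drift < control$tol * 10)

  list(beta = beta, omega = omega, a = a_err, b = b_err,
       phi_mean = eb_mean, phi_sd = eb_sd, prior_mean = prior_mean(),
       trace = tibble::as_tibble(trace) |> dplyr::mutate(iter = dplyr::row_number()),
       converged = converged, drift = drift, rho = rho, X = X)
}
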