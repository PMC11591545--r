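#' Standard errors of the population estimates
#'
#' Relative standard errors (`RSE = 100 * SE / estimate`) per parameter,
#' either from the observed Fisher information of the importance-sampling
#' marginal likelihood (finite differences on a common-random-numbers OFV,
#' so the objective is smooth in the parameters) or from a nonparametric
#' [bootstrap_fit()]. Typical values, IIV SDs and error parameters are
#' differentiated on the log scale, which makes the reported RSE invariant
#' to unit rescaling.
#'
#' @param fit a [fit_popmodel()] result
#' @param method `"fim"` or `"bootstrap"`
#' @param n_mc Monte Carlo size of the common-random-numbers likelihood
#' @param seed integer seed
#' @param n_boot bootstrap replicates (bootstrap method only)
#' @return tibble `term`, `estimate`, `se`, `rse` (percent); for the FIM
#'   method the estimate covariance matrix (log scale) is attached as
#'   attribute `"cov"`. The RSE vector is also attached to later
#'   [tidy()] calls via attribute `"rse"` on the returned tibble.
#' @export
standard_errors <- function(fit, method = c("fim", "bootstrap"),
                            n_mc = 1000L, seed = 1L, n_boot = 200L) {
  stopifnot(inherits(fit, "pk_fit"))
  method <- match.arg(method)
  if (method == "bootstrap") {
    bt <- bootstrap_fit(fit$data, fit$spec, n_boot = n_boot, seed = seed,
                        init = default_init(fit$spec))
    est <- tidy(fit)[c("term", "estimate")]
    out <- dplyr::left_join(est,
                            dplyr::summarise(dplyr::group_by(bt$replicates, .data$term),
                                             se = sd(.data$estimate), .groups = "drop"),
                            by = "term")
    out$rse <- 100 * out$se / abs(out$estimate)
    return(out)
  }

  free <- fit$spec$free
  p <- length(free)
  # theta: per free param its beta vector (intercept = log typical, then
  # covariate coefficients), then log omega, then log error parameters
  beta0 <- fit$run$beta
  theta <- c(unlist(beta0),
             log(as.numeric(fit$omega[free])),
             switch(fit$spec$error,
                    proportional = log(fit$error[["b"]]),
                    constant = log(fit$error[["a"]]),
                    combined = log(c(fit$error[["a"]], fit$error[["b"]]))))
  nb <- lengths(beta0)
  terms <- c(unlist(lapply(free, function(pp) {
               cvs <- fit$spec$covariates[[pp]]
               c(pp, if (length(cvs)) paste0("beta_", pp, "_", cvs))
             })),
             paste0("omega_", free),
             switch(fit$spec$error, proportional = "b", constant = "a",
                    combined = c("a", "b")))

  unpack <- function(th) {
    i <- 0L
    beta <- lapply(setNames(free, free), function(pp) {
      out <- th[i + seq_len(nb[[pp]])]
      i <<- i + nb[[pp]]
      out
    })
    omega <- setNames(exp(th[i + seq_len(p)]), free); i <- i + p
    err <- exp(th[(i + 1L):length(th)])
    a <- fit$error[["a"]]; b <- fit$error[["b"]]
    if (fit$spec$error == "proportional") b <- err[1]
    if (fit$spec$error == "constant") a <- err[1]
    if (fit$spec$error == "combined") { a <- err[1]; b <- err[2] }
    list(beta = beta, omega = omega, a = a, b = b)
  }

  prop <- .is_proposal(fit, inflation = 1.3)
  Z <- withr::with_seed(derive_seed(seed, "fim"), {
    array(rnorm(fit$sdata$n_sub * n_mc * p),
          dim = c(fit$sdata$n_sub, n_mc * p))
  })
  obj <- function(th) {
    pars <- unpack(th)
    .ofv_is(pars$beta, pars$omega, pars$a, pars$b, fit$sdata, fit$spec,
            fit$run$X, prop$mean, prop$sd, Z)$ofv
  }

  q <- length(theta)
  h <- 5e-3 * (1 + abs(theta))
  f0 <- obj(theta)
  H <- matrix(NA_real_, q, q)
  fp <- numeric(q); fm <- numeric(q)
  for (i in seq_len(q)) {
    e <- theta; e[i] <- theta[i] + h[i]; fp[i] <- obj(e)
    e[i] <- theta[i] - h[i]; fm[i] <- obj(e)
    H[i, i] <- (fp[i] + fm[i] - 2 * f0) / h[i]^2
  }
  if (q > 1L) {
    for (i in seq_len(q - 1L)) for (j in (i + 1L):q) {
      e <- theta
      e[i] <- theta[i] + h[i]; e[j] <- theta[j] + h[j]; fpp <- obj(e)
      e[j] <- theta[j] - h[j]; fpm <- obj(e)
      e[i] <- theta[i] - h[i]; fmm <- obj(e)
      e[j] <- theta[j] + h[j]; fmp <- obj(e)
      H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
    }
  }
  covm <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(covm) || any(diag(covm) <= 0)) {
    abort(paste("The information matrix is singular or not positive",
                "definite; use method = \"bootstrap\" instead."))
  }
  se_log <- sqrt(diag(covm))
  est <- tidy(fit)
  out <- tibble::tibble(term = terms, se_log = se_log)
  out <- dplyr::left_join(est[c("term", "estimate")], out, by = "term")
  # log-scale SE is the relative SE of a positive parameter; covariate
  # coefficients are estimated on the identity scale
  is_beta <- grepl("^beta_", out$term)
  out$se <- ifelse(is_beta, out$se_log, abs(out$estimate) * out$se_log)
  out$rse <- 100 * out$se / abs(out$estimate)
  out$se_log <- NULL
  attr(out, "cov") <- covm
  attr(out, "terms") <- terms
  out
}
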