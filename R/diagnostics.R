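# Goodness of fit, visual predictive check, bootstrap, shrinkage, and
# conditioning diagnostics for a fitted population model.

#' Goodness-of-fit summaries
#'
#' Observed versus predicted concentrations with the R-squared of the
#' ordinary least-squares regression of observed on predicted, for both the
#' population predictions (typical values plus covariate effects, random
#' effects at zero) and the individual predictions (empirical Bayes
#' estimates).
#'
#' @param fit a [fit_popmodel()] result
#' @return list with `r2_population`, `r2_individual`, and a tibble `table`
#'   (`id`, `time`, `obs`, `ppred`, `ipred`)
#' @export
gof <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  sdata <- fit$sdata
  if (sdata$n_obs < 3L) abort("Need at least 3 observations for goodness of fit.")
  ppred <- .predict_f(fit$run$prior_mean, sdata, fit$spec)
  ipred <- .predict_f(fit$run$phi_mean, sdata, fit$spec)
  tab <- tibble::tibble(id = sdata$ids[sdata$obs$sub], time = sdata$obs$time,
                        obs = sdata$obs$y, ppred = ppred, ipred = ipred)
  r2 <- function(pred) summary(lm(tab$obs ~ pred))$r.squared
  list(r2_population = r2(ppred), r2_individual = r2(ipred), table = tab)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the observed design (same doses,
#' same sampling times) from the fitted model, applies the same
#' quantification-limit censoring and QL/2 imputation as the analysis
#' pipeline, and compares observed concentration percentiles against the
#' simulated prediction bands per time bin. Bins are exact nominal times
#' when the design has few distinct times, quantile bins otherwise.
#'
#' @param fit a [fit_popmodel()] result
#' @param n_sim number of simulated replicates
#' @param probs percentiles to check, in (0, 1)
#' @param seed integer seed
#' @param ql quantification limit applied to simulated (and observed) values
#'   before percentile computation; `NULL` disables censoring
#' @param band nominal coverage of the prediction band around each
#'   simulated percentile
#' @param max_exact_bins exact-time binning is used when the design has at
#'   most this many distinct times
#' @return tibble of class `vpc_result`: one row per bin x percentile with
#'   observed value and band bounds; attributes `n_sim`, `seed`
#' @export
vpc <- function(fit, n_sim = 10000L, probs = c(0.1, 0.5, 0.9), seed = 1L,
                ql = 12.5, band = 0.95, max_exact_bins = 10L) {
  stopifnot(inherits(fit, "pk_fit"))
  sdata <- fit$sdata
  if (sdata$n_obs == 0L) abort("The design has no observations.")
  n_sim <- as.integer(n_sim)
  n <- sdata$n_sub
  p <- length(fit$spec$free)
  m <- fit$run$prior_mean
  omega <- fit$omega

  censor <- function(y) {
    if (!is.null(ql)) y[y < ql] <- ql / 2
    y
  }

  ysim <- withr::with_seed(derive_seed(seed, "vpc"), {
    eta <- matrix(rnorm(n * n_sim * p), n * n_sim, p) %*%
      diag(omega[fit$spec$free], p)
    phi_flat <- m[rep(seq_len(n), n_sim), , drop = FALSE] + eta
    colnames(phi_flat) <- fit$spec$free
    f <- .f_stack(phi_flat, sdata, fit$spec, n_sim)
    s <- .res_sd(f, fit$spec$error, fit$error[["a"]], fit$error[["b"]])
    matrix(f + s * rnorm(length(f)), sdata$n_obs, n_sim)
  })
  ysim <- censor(ysim)
  yobs <- censor(sdata$obs$y)

  times <- sdata$obs$time
  uniq <- sort(unique(times))
  if (length(uniq) <= max_exact_bins) {
    bin <- match(times, uniq)
    bin_label <- uniq
  } else {
    brk <- quantile(times, seq(0, 1, length.out = max_exact_bins + 1L))
    bin <- cut(times, unique(brk), include.lowest = TRUE, labels = FALSE)
    bin_label <- tapply(times, bin, median)
  }

  out <- list()
  for (q in probs) {
    obs_q <- tapply(yobs, bin, quantile, probs = q, names = FALSE)
    sim_q <- apply(ysim, 2L, function(col) {
      tapply(col, bin, quantile, probs = q, names = FALSE)
    })
    if (is.null(dim(sim_q))) sim_q <- matrix(sim_q, nrow = 1L)
    lo <- apply(sim_q, 1L, quantile, probs = (1 - band) / 2, names = FALSE)
    hi <- apply(sim_q, 1L, quantile, probs = 1 - (1 - band) / 2, names = FALSE)
    md <- apply(sim_q, 1L, median)
    out[[length(out) + 1L]] <- tibble::tibble(
      bin_time = as.numeric(bin_label), percentile = 100 * q,
      observed = as.numeric(obs_q), sim_median = md,
      band_lower = lo, band_upper = hi,
      n_obs_bin = as.numeric(table(bin)))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("vpc_result", class(res))
  attr(res, "n_sim") <- n_sim
  attr(res, "seed") <- seed
  res
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples *subjects* with replacement to the original cohort size,
#' refits each replicate, and summarizes the re-estimates by their mean and
#' 2.5th/97.5th percentiles. Record-level resampling would be invalid for
#' sparse repeated measures. Failed refits are logged and excluded; a
#' quality warning is attached when more than 20% fail.
#'
#' @param data the analysis dataset
#' @param spec a [model_spec()]
#' @param n_boot number of bootstrap replicates
#' @param seed integer seed (serial execution; bit-reproducible)
#' @param control a [saem_control()]; the default shortens the likelihood
#'   computation since only the estimates are collected
#' @param init initial values, as in [fit_popmodel()]
#' @return object of class `bootstrap_result`: tibble `replicates` (one row
#'   per replicate and term), tibble `summary` (`term`, `mean`, `ci_lower`,
#'   `ci_upper`), `n_failed`, `quality_warning`
#' @export
bootstrap_fit <- function(data, spec = model_spec(), n_boot = 1000L, seed = 1L,
                          control = saem_control(n_mc_ll = 200L),
                          init = default_init(spec)) {
  data <- validate_pkdata(data)
  ids <- unique(data$ID)
  if (length(ids) < 3L) abort("Bootstrap needs at least 3 subjects.")
  reps <- list()
  n_failed <- 0L
  for (bb in seq_len(n_boot)) {
    take <- withr::with_seed(derive_seed(seed, paste0("boot_draw", bb)),
                             sample(ids, length(ids), replace = TRUE))
    dat_b <- dplyr::bind_rows(lapply(seq_along(take), function(j) {
      block <- data[data$ID == take[j], ]
      block$ID <- j
      block
    }))
    est <- tryCatch({
      ft <- suppressWarnings(
        fit_popmodel(dat_b, spec, init = init, control = control,
                     seed = derive_seed(seed, paste0("boot_fit", bb))))
      dplyr::mutate(tidy(ft)[c("term", "estimate")], replicate = bb)
    }, error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1L else reps[[length(reps) + 1L]] <- est
  }
  replicates <- dplyr::bind_rows(reps)
  summary <- replicates |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(mean = mean(.data$estimate),
                     ci_lower = quantile(.data$estimate, 0.025, names = FALSE),
                     ci_upper = quantile(.data$estimate, 0.975, names = FALSE),
                     .groups = "drop")
  structure(list(replicates = replicates, summary = summary,
                 n_boot = n_boot, n_failed = n_failed,
                 quality_warning = n_failed > 0.2 * n_boot,
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d replicates, %d failed%s\n",
              x$n_boot, x$n_failed,
              if (x$quality_warning) "  ** >20% failures, interpret with care **" else ""))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Eta-shrinkage of the empirical Bayes estimates
#'
#' `100 * (1 - SD(EBE eta) / omega)` per random effect: near 0 for rich
#' individual data, near 100% when the individual data carry no information
#' and the EBEs collapse to the population mean.
#'
#' @param fit a [fit_popmodel()] result
#' @return tibble `param`, `omega`, `sd_ebe`, `shrinkage` (percent)
#' @export
shrinkage <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  eta <- fit$run$phi_mean - fit$run$prior_mean
  tibble::tibble(
    param = fit$spec$free,
    omega = as.numeric(fit$omega[fit$spec$free]),
    sd_ebe = apply(eta, 2L, sd),
    shrinkage = 100 * (1 - apply(eta, 2L, sd) / as.numeric(fit$omega[fit$spec$free])))
}

#' Condition ratio of the estimate correlation matrix
#'
#' Ratio of the largest to the smallest eigenvalue of the correlation
#' matrix of the parameter estimates (from the information-matrix
#' covariance, or any covariance supplied). Values near 1 indicate a
#' well-conditioned model; large values flag overparameterization. The
#' ratio is capped at `cap` and flagged when the correlation matrix is
#' numerically singular.
#'
#' @param fit a [fit_popmodel()] result
#' @param cov optional covariance matrix of the estimates (defaults to the
#'   one computed by [standard_errors()] with `method = "fim"`)
#' @param cap upper bound reported for singular cases
#' @return the eigenvalue ratio (>= 1), with attribute `capped`
#' @export
condition_ratio <- function(fit, cov = NULL, cap = 1e12) {
  if (is.null(cov)) {
    se <- standard_errors(fit, method = "fim")
    cov <- attr(se, "cov")
  }
  s <- sqrt(diag(cov))
  if (any(s <= 0)) {
    out <- cap
    attr(out, "capped") <- TRUE
    return(out)
  }
  cr <- cov / tcrossprod(s)
  ev <- eigen(cr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) / cap) {
    out <- cap
    attr(out, "capped") <- TRUE
    return(out)
  }
  out <- max(ev) / min(ev)
  attr(out, "capped") <- FALSE
  out
}
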