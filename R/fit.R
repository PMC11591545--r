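#' Fit the population pharmacokinetic model
#'
#' Maximum-marginal-likelihood estimation of the nonlinear mixed-effects
#' model by SAEM: log-normal inter-individual variability on every free
#' structural parameter, the chosen residual-error model, and optional
#' power-model covariate effects. Only total-concentration observations
#' enter the fit; below-quantification-limit records are expected to have
#' been imputed beforehand with [impute_bql()] (the fit does not silently
#' censor). The run is deterministic given `seed` and `control`.
#'
#' Initial typical values default to published dalbavancin estimates
#' (CL 0.057 L/h, V1 10 L, V2 10 L) rather than any value the data were
#' generated from, so recovery experiments are not seeded with their own
#' truth.
#'
#' @param data a PK dataset in the [validate_pkdata()] layout
#' @param spec a [model_spec()]
#' @param init named list with elements `typical` (named vector of starting
#'   structural values), `omega` (named vector of starting IIV SDs),
#'   `error_a`, `error_b`
#' @param control a [saem_control()]
#' @param seed integer seed
#' @return object of class `pk_fit`: estimates on the natural scale,
#'   covariate coefficients, empirical Bayes summaries, convergence flag and
#'   estimate trace, and importance-sampling OFV/AIC/BIC (refine with
#'   [log_likelihood()]). Methods: [tidy()], [glance()], `print()`,
#'   [gof()], [vpc()], [shrinkage()], [standard_errors()].
#' @export
#' @examples
#' \donttest{
#' d <- impute_bql(generate_cohort(cohort_config(n_subjects = 20), seed = 9))
#' ft <- fit_popmodel(d, control = saem_control(n_burn = 150, n_smooth = 80),
#'                    seed = 1)
#' tidy(ft)
#' }
fit_popmodel <- function(data, spec = model_spec(),
                         init = default_init(spec),
                         control = saem_control(), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(control, "saem_control"))
  init <- .check_init(init, spec)
  sdata <- .saem_data(data, spec)
  run <- .saem_run(sdata, spec, init, control, seed)

  typical <- setNames(vapply(spec$free, function(p) exp(run$beta[[p]][1]),
                             numeric(1)), spec$free)
  betas <- lapply(run$beta, function(b) if (length(b) > 1L) b[-1L] else NULL)
  betas <- purrr::compact(purrr::imap(betas, function(b, p) {
    if (is.null(b)) return(NULL)
    setNames(b, spec$covariates[[p]])
  }))

  eta_mean <- run$phi_mean - run$prior_mean
  ebe <- tibble::tibble(
    id = rep(sdata$ids, times = length(spec$free)),
    param = rep(spec$free, each = sdata$n_sub),
    eta = as.numeric(eta_mean),
    eta_sd = as.numeric(run$phi_sd),
    value = as.numeric(exp(run$phi_mean)))

  fit <- structure(list(
    typical = typical, omega = run$omega, beta = betas,
    error = c(a = run$a, b = run$b),
    spec = spec, control = control, seed = seed,
    data = tibble::as_tibble(data),
    sdata = sdata, run = run, ebe = ebe,
    converged = run$converged, trace = run$trace,
    n_subjects = sdata$n_sub, n_obs = sdata$n_obs), class = "pk_fit")
  if (!fit$converged) {
    warn(paste0("SAEM estimate drift above tolerance in the final iterations (",
                paste(sprintf("%s=%.2g", names(run$drift), run$drift),
                      collapse = ", "), "); treat estimates with care."))
  }
  ll <- log_likelihood(fit, n_mc = control$n_mc_ll, seed = seed)
  fit$ofv <- ll$ofv; fit$aic <- ll$aic; fit$bic <- ll$bic
  fit$ofv_se <- ll$mc_se; fit$n_param <- ll$n_param
  fit
}

#' Default initial values for a model specification
#'
#' Published dalbavancin typical values (CL 0.057, V1 10, V2 10; Q 0.5 when
#' free), IIV SDs 0.3, proportional error 0.2.
#'
#' @param spec a [model_spec()]
#' @return init list for [fit_popmodel()]
#' @export
default_init <- function(spec) {
  typ <- c(CL = 0.057, V1 = 10, Q = 0.5, V2 = 10)
  list(typical = typ[spec$free],
       omega = setNames(rep(0.3, length(spec$free)), spec$free),
       error_a = 5, error_b = 0.2)
}

.check_init <- function(init, spec) {
  if (!all(spec$free %in% names(init$typical))) {
    abort("`init$typical` must name every free structural parameter.")
  }
  if (any(init$typical[spec$free] <= 0)) abort("Initial values must be positive.")
  if (is.null(init$omega)) init$omega <- setNames(rep(0.3, length(spec$free)),
                                                  spec$free)
  if (!all(spec$free %in% names(init$omega))) {
    abort("`init$omega` must name every free structural parameter.")
  }
  init$error_a <- init$error_a %||% 5
  init$error_b <- init$error_b %||% 0.2
  init
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit> %d-compartment NLME (SAEM), %d subjects, %d observations\n",
              x$spec$n_compartments, x$n_subjects, x$n_obs))
  cat(sprintf("  OFV %.2f (MC se %.2f)  AIC %.2f  BIC %.2f  [%s]\n",
              x$ofv, x$ofv_se, x$aic, x$bic,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @describeIn fit_popmodel Tidy parameter table: typical values, covariate
#'   coefficients, IIV SDs and residual-error parameters, with `rse` filled
#'   after [standard_errors()].
#' @param x a `pk_fit`
#' @param ... unused
#' @method tidy pk_fit
#' @export
tidy.pk_fit <- function(x, ...) {
  rows <- list(
    tibble::tibble(term = names(x$typical), type = "typical",
                   estimate = as.numeric(x$typical)),
    if (length(x$beta)) {
      dplyr::bind_rows(purrr::imap(x$beta, function(b, p) {
        tibble::tibble(term = paste0("beta_", p, "_", names(b)),
                       type = "covariate", estimate = as.numeric(b))
      }))
    },
    tibble::tibble(term = paste0("omega_", names(x$omega)), type = "iiv_sd",
                   estimate = as.numeric(x$omega)))
  err <- switch(x$spec$error,
                proportional = tibble::tibble(term = "b", type = "error",
                                              estimate = x$error[["b"]]),
                constant = tibble::tibble(term = "a", type = "error",
                                          estimate = x$error[["a"]]),
                combined = tibble::tibble(term = c("a", "b"), type = "error",
                                          estimate = as.numeric(x$error)))
  out <- dplyr::bind_rows(c(rows, list(err)))
  se <- attr(x, "rse")
  out$rse <- if (!is.null(se)) se[match(out$term, names(se))] else NA_real_
  out
}

#' @describeIn fit_popmodel One-row model summary (OFV, AIC, BIC, counts,
#'   convergence).
#' @method glance pk_fit
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_obs = x$n_obs,
                 n_param = x$n_param, ofv = x$ofv, ofv_mc_se = x$ofv_se,
                 aic = x$aic, bic = x$bic, converged = x$converged)
}

#' Fitted population model as a simulation-ready object
#'
#' Converts a `pk_fit` into the [pop_model()] used by the simulation and
#' target-attainment functions (typical values at the covariate medians).
#'
#' @param fit a `pk_fit`
#' @return a [pop_model()]
#' @export
as_pop_model <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  full <- c(fit$typical, fit$spec$fixed)
  if (fit$spec$n_compartments == 1) {
    full <- c(full, c(Q = 0, V2 = 1)[setdiff(c("Q", "V2"), names(full))])
  }
  pop_model(pk_params(CL = full[["CL"]], V1 = full[["V1"]],
                      Q = full[["Q"]], V2 = full[["V2"]]),
            omega = fit$omega,
            error_b = if (fit$spec$error == "constant") 0 else fit$error[["b"]])
}
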