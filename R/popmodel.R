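#' Population pharmacokinetic model
#'
#' Couples a typical-subject parameter set with log-normal inter-individual
#' variability (IIV) and a proportional residual-error SD. The `omega` values
#' are the *standard deviations* of the log-scale random effects (the
#' convention of SAEM-based tools), not variances: an individual parameter is
#' `typical * exp(eta)` with `eta ~ N(0, omega^2)`. Parameters without an
#' `omega` entry (here typically `Q`) are identical across individuals.
#'
#' @param typical a [pk_params()] object of typical values
#' @param omega named numeric vector of log-scale random-effect SDs, names
#'   among `CL`, `V1`, `Q`, `V2`
#' @param error_b proportional residual error SD (unitless multiplier)
#' @return object of class `pop_model`
#' @seealso [dalbavancin_popmodel()] for the shipped dalbavancin model,
#'   [sample_population()]
#' @export
pop_model <- function(typical, omega = c(CL = 0, V1 = 0, V2 = 0), error_b = 0) {
  stopifnot(inherits(typical, "pk_params"))
  if (is.null(names(omega)) || !all(names(omega) %in% c("CL", "V1", "Q", "V2"))) {
    abort("`omega` must be named with a subset of CL, V1, Q, V2.")
  }
  if (any(omega < 0)) abort("`omega` entries must be >= 0.")
  if (error_b < 0) abort("`error_b` must be >= 0.")
  structure(list(typical = typical, omega = omega, error_b = error_b),
            class = "pop_model")
}

#' @export
print.pop_model <- function(x, ...) {
  cat("<pop_model> log-normal IIV, proportional residual error\n")
  print(x$typical)
  cat("  omega (log-scale SD):",
      paste(sprintf("%s=%.3g", names(x$omega), x$omega), collapse = ", "), "\n")
  cat(sprintf("  error b = %.3g\n", x$error_b))
  invisible(x)
}

#' Population dalbavancin model for suppressive therapy
#'
#' The two-compartment dalbavancin population model for adults on
#' long-interval suppressive therapy: typical values from
#' [dalbavancin_params()], log-scale IIV SDs `omega_CL = 0.230`,
#' `omega_V1 = 0.260`, `omega_V2 = 0.410` (none on the fixed `Q`), and
#' proportional residual error `b = 0.100`.
#'
#' @return a [pop_model()]
#' @export
dalbavancin_popmodel <- function() {
  pop_model(dalbavancin_params(),
            omega = c(CL = 0.230, V1 = 0.260, V2 = 0.410),
            error_b = 0.100)
}

#' Draw a virtual population
#'
#' Samples `n` individuals from a [pop_model()]: independent log-scale random
#' effects `eta_p ~ N(0, omega_p^2)` per parameter and individual, individual
#' parameter `typical_p * exp(eta_p)`. Reproducible for a given `seed`.
#'
#' @param model a [pop_model()]
#' @param n number of individuals (>= 1)
#' @param seed integer seed
#' @return tibble with one row per individual: `id`, parameter columns `CL`,
#'   `V1`, `Q`, `V2`, and the sampled effects `eta_CL`, ... for parameters
#'   with IIV. Carries the model and seed as attributes.
#' @export
#' @examples
#' pop <- sample_population(dalbavancin_popmodel(), n = 500, seed = 42)
#' median(pop$CL) # close to the typical 0.050 L/h
sample_population <- function(model, n, seed) {
  stopifnot(inherits(model, "pop_model"))
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be >= 1.")
  typ <- model$typical
  out <- tibble::tibble(id = seq_len(n),
                        CL = rep(typ$CL, n), V1 = rep(typ$V1, n),
                        Q = rep(typ$Q, n), V2 = rep(typ$V2, n))
  withr::with_seed(derive_seed(seed, "sample_population"), {
    for (p in names(model$omega)) {
      if (model$omega[[p]] > 0) {
        eta <- rnorm(n, 0, model$omega[[p]])
        out[[paste0("eta_", p)]] <- eta
        out[[p]] <- out[[p]] * exp(eta)
      } else {
        out[[paste0("eta_", p)]] <- rep(0, n)
      }
    }
  })
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  out
}

#' Simulate concentration profiles for a virtual population
#'
#' Evaluates each individual's analytic concentration profile under a
#' regimen; row `i` of the underlying matrix equals [conc_profile()] with
#' individual `i`'s parameters.
#'
#' @param population tibble from [sample_population()] (or any data frame
#'   with columns `id`, `CL`, `V1`, `Q`, `V2`)
#' @param regimen a [regimen()]
#' @param times numeric time grid, h
#' @return long tibble `id`, `time`, `conc` (mg/L)
#' @export
simulate_profiles <- function(population, regimen, times) {
  cc <- conc_matrix(population, regimen, times)
  ids <- population$id %||% seq_len(nrow(population))
  tibble::tibble(id = rep(ids, times = length(times)),
                 time = rep(times, each = nrow(population)),
                 conc = as.numeric(cc))
}

#' Percentile bands of simulated profiles
#'
#' Summarizes [simulate_profiles()] output into per-time percentile curves,
#' the tidy data behind a regimen's concentration-band plot.
#'
#' @param profiles long tibble from [simulate_profiles()]
#' @param probs percentile levels in (0, 1)
#' @return tibble `time`, one column `p<level>` per percentile
#' @export
profile_bands <- function(profiles, probs = c(0.05, 0.5, 0.95)) {
  stopifnot(all(probs > 0 & probs < 1))
  out <- profiles |>
    dplyr::group_by(.data$time) |>
    dplyr::reframe(level = paste0("p", probs * 100),
                   value = quantile(.data$conc, probs, names = FALSE)) |>
    tidyr::pivot_wider(names_from = "level", values_from = "value")
  dplyr::arrange(out, .data$time)
}

#' Apply proportional residual error to predicted concentrations
#'
#' Emulates observed concentrations as `y = c * (1 + b * eps)` with
#' `eps ~ N(0, 1)` i.i.d. Values may come out negative for large `b`;
#' downstream quantification-limit handling governs those. Used when
#' generating synthetic observations and VPC replicates, never inside
#' PTA exposure calculations.
#'
#' @param conc numeric vector/matrix of model-predicted concentrations, or a
#'   data frame with a `conc` column (a column `obs` is then added)
#' @param b proportional error SD (>= 0)
#' @param seed integer seed
#' @return same shape as `conc` with noise applied
#' @export
add_residual_error <- function(conc, b, seed) {
  if (b < 0) abort("`b` must be >= 0.")
  if (is.data.frame(conc)) {
    conc$obs <- add_residual_error(conc$conc, b, seed)
    return(conc)
  }
  withr::with_seed(derive_seed(seed, "residual_error"), {
    eps <- rnorm(length(conc))
  })
  out <- conc * (1 + b * eps)
  if (is.matrix(conc)) dim(out) <- dim(conc)
  out
}
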