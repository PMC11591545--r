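# Free-drug exposure, probability of target attainment, and cumulative
# fraction of response.

#' fAUC/MIC targets for Staphylococcus aureus
#'
#' The free-AUC24/MIC thresholds used for dalbavancin against *S. aureus*:
#' > 27.1 for net stasis, > 53.3 for 1-log kill, > 111.1 for 2-log kill.
#'
#' @return named numeric vector `stasis`, `log1kill`, `log2kill`
#' @export
pkpd_targets <- function() {
  c(stasis = 27.1, log1kill = 53.3, log2kill = 111.1)
}

#' Free AUC of the last 24 h before redosing
#'
#' The conservative exposure metric for suppressive therapy: the unbound AUC
#' over the final 24 h of a dosing interval, evaluated at every scheduled
#' redosing time of the evaluation cycle (by default the last simulated
#' cycle, i.e. approximate steady state) and reduced to the *worst* interval
#' within the cycle. Free concentrations are `(1 - pb/100)` times total.
#'
#' @param params a [pk_params()] for one subject, or a population data frame
#'   (one row per individual) as from [sample_population()]
#' @param regimen a cyclic [regimen()]
#' @param pb protein binding in percent, `0 <= pb <= 100`
#' @param cycle evaluation cycle (default the final one; use 1 for
#'   first-course behaviour)
#' @return free AUC24 in mg·h/L, one value per individual
#' @export
#' @examples
#' fauc_tail(dalbavancin_params(), regimen_preset("1500_q3w"), pb = 99)
fauc_tail <- function(params, regimen, pb, cycle = NULL) {
  if (!is.numeric(pb) || pb < 0 || pb > 100) {
    abort("`pb` must be a protein-binding percentage in [0, 100].")
  }
  ends <- redose_times(regimen, cycle = cycle)
  first_dose <- min(expand_regimen(regimen)$start_time)
  if (any(ends - 24 < first_dose)) {
    abort("A dosing interval is shorter than the 24-h evaluation window.")
  }
  ev <- expand_regimen(regimen)
  pars <- .pars_df(params)
  per_end <- vapply(ends, function(te) auc_vec(pars, ev, te - 24, te),
                    numeric(nrow(pars)))
  if (is.null(dim(per_end))) per_end <- matrix(per_end, nrow = nrow(pars))
  worst <- apply(per_end, 1L, min)
  (1 - pb / 100) * worst
}

#' Probability of target attainment at one MIC
#'
#' Fraction (in percent) of a virtual population whose free tail AUC24 over
#' MIC strictly exceeds the PK/PD threshold.
#'
#' @param population data frame of individuals ([sample_population()])
#' @param regimen a cyclic [regimen()]
#' @param mic minimum inhibitory concentration, mg/L (> 0)
#' @param pb protein binding, percent
#' @param threshold fAUC24/MIC threshold (default: stasis, 27.1)
#' @param cycle evaluation cycle passed to [fauc_tail()]
#' @return PTA in percent
#' @export
pta <- function(population, regimen, mic, pb, threshold = pkpd_targets()[["stasis"]],
                cycle = NULL) {
  if (is.null(nrow(population)) || nrow(population) == 0L) {
    abort("The virtual population is empty.")
  }
  if (!is.numeric(mic) || any(mic <= 0)) abort("`mic` must be positive.")
  fa <- fauc_tail(population, regimen, pb, cycle = cycle)
  100 * mean(fa / mic > threshold)
}

#' PTA across a MIC grid
#'
#' Computes individual free tail exposures once and vectorizes the
#' strict-threshold comparison over the MIC grid.
#'
#' @inheritParams pta
#' @param mic_grid strictly increasing vector of MICs, mg/L
#' @return tibble of class `pta_result` with columns `mic`, `pta` plus
#'   metadata columns `regimen`, `pb`, `threshold`; attributes `n_subjects`.
#' @export
#' @examples
#' pop <- sample_population(dalbavancin_popmodel(), 2000, seed = 7)
#' pta_curve(pop, regimen_preset("1500_q3w"), pb = 99)
pta_curve <- function(population, regimen, mic_grid = mic_grid_default(), pb,
                      threshold = pkpd_targets()[["stasis"]], cycle = NULL) {
  if (is.unsorted(mic_grid, strictly = TRUE)) {
    abort("`mic_grid` must be strictly increasing.")
  }
  if (any(mic_grid <= 0)) abort("MICs must be positive.")
  if (is.null(nrow(population)) || nrow(population) == 0L) {
    abort("The virtual population is empty.")
  }
  fa <- fauc_tail(population, regimen, pb, cycle = cycle)
  ptas <- vapply(mic_grid, function(m) 100 * mean(fa / m > threshold), numeric(1))
  out <- tibble::tibble(regimen = attr(regimen, "label"),
                        pb = pb, threshold = threshold,
                        mic = mic_grid, pta = ptas)
  class(out) <- c("pta_result", class(out))
  attr(out, "n_subjects") <- nrow(population)
  out
}

#' Default EUCAST-style MIC grid
#'
#' Doubling dilutions from 0.016 to 2 mg/L, the support used for PTA curves
#' and MIC frequency distributions.
#' @return numeric vector
#' @export
mic_grid_default <- function() c(0.016, 0.03, 0.06, 0.125, 0.25, 0.5, 1, 2)

#' MIC frequency distribution
#'
#' @param mic strictly increasing MIC values in mg/L within \[0.016, 2\]
#' @param frequency nonnegative frequencies summing to 1 (tolerance 1e-9)
#' @return tibble of class `mic_distribution`
#' @seealso [read_mic_distribution()] for the CSV format, and the packaged
#'   synthetic EUCAST-style snapshot in
#'   `system.file("extdata", "mic_saureus_dalbavancin_synthetic.csv",
#'   package = "dalbapop")`
#' @export
mic_distribution <- function(mic, frequency) {
  if (length(mic) != length(frequency) || length(mic) == 0L) {
    abort("`mic` and `frequency` must be equal-length, non-empty.")
  }
  if (is.unsorted(mic, strictly = TRUE)) abort("MICs must be strictly increasing.")
  if (any(mic < 0.016 - 1e-12) || any(mic > 2 + 1e-12)) {
    abort("MICs must lie within [0.016, 2] mg/L.")
  }
  if (any(frequency < 0)) abort("Frequencies must be >= 0.")
  if (abs(sum(frequency) - 1) > 1e-9) abort("Frequencies must sum to 1.")
  out <- tibble::tibble(mic = mic, frequency = frequency)
  class(out) <- c("mic_distribution", class(out))
  out
}

#' Read a MIC frequency distribution from CSV
#'
#' Expected header: `mic_mg_per_L,frequency`.
#'
#' @param path CSV file path
#' @return a [mic_distribution()]
#' @export
read_mic_distribution <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("mic_mg_per_L", "frequency") %in% names(d))) {
    abort("MIC distribution CSV needs columns `mic_mg_per_L,frequency`.")
  }
  mic_distribution(d$mic_mg_per_L, d$frequency)
}

#' Packaged synthetic S. aureus MIC distribution
#'
#' Loads the EUCAST-style *S. aureus* dalbavancin MIC frequency snapshot that
#' ships with the package. The table is a synthetic stand-in shaped like the
#' public wild-type distribution (mass concentrated at 0.03--0.06 mg/L); it
#' is a configuration input, not a reference dataset.
#'
#' @return a [mic_distribution()]
#' @export
mic_saureus_synthetic <- function() {
  read_mic_distribution(system.file("extdata",
                                    "mic_saureus_dalbavancin_synthetic.csv",
                                    package = "dalbapop"))
}

#' Cumulative fraction of response
#'
#' Expected PTA over a pathogen's MIC frequency distribution:
#' `CFR = sum_i pta(mic_i) * freq_i`. Every MIC of the distribution must be
#' present in the PTA grid; no interpolation is performed.
#'
#' @param pta_result a [pta_curve()] result
#' @param dist a [mic_distribution()]
#' @return one-row tibble of class `cfr_result`: `regimen`, `pb`,
#'   `threshold`, `cfr` (percent)
#' @export
cfr <- function(pta_result, dist) {
  stopifnot(inherits(pta_result, "pta_result"), inherits(dist, "mic_distribution"))
  idx <- match(dist$mic, pta_result$mic)
  if (anyNA(idx)) {
    missing <- dist$mic[is.na(idx)]
    abort(paste0("MICs absent from the PTA grid: ",
                 paste(missing, collapse = ", "),
                 ". Recompute the PTA curve on a grid covering the distribution."))
  }
  out <- tibble::tibble(regimen = pta_result$regimen[1L],
                        pb = pta_result$pb[1L],
                        threshold = pta_result$threshold[1L],
                        cfr = sum(pta_result$pta[idx] * dist$frequency))
  class(out) <- c("cfr_result", class(out))
  out
}

#' Desirability of a PTA or CFR result
#'
#' A target attainment is desirable when it reaches at least 90%.
#'
#' @param x a `pta_result`, a `cfr_result`, or a numeric percentage
#' @param mic for a `pta_result`, the MIC at which to query
#' @return logical
#' @export
desirable <- function(x, mic = NULL) {
  val <- if (inherits(x, "cfr_result")) {
    x$cfr
  } else if (inherits(x, "pta_result")) {
    if (is.null(mic)) abort("Provide `mic` to query a PTA curve.")
    i <- match(mic, x$mic)
    if (is.na(i)) abort("`mic` is not on the PTA grid.")
    x$pta[i]
  } else if (is.numeric(x)) {
    x
  } else {
    abort("`x` must be a pta_result, cfr_result, or numeric percentage.")
  }
  val >= 90
}
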