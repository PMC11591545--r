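# Synthetic study-replica cohorts with known ground truth.

#' Configuration of a synthetic suppressive-therapy cohort
#'
#' Defaults emulate the outpatient ventricular-assist-device study design:
#' 13 subjects on 1500 mg dalbavancin (0.5-h infusion) on day 1 and day 8 of
#' a 6-week cycle; three sparse samples per subject (30 min after the end of
#' the day-1 infusion, pre-dose trough on day 8, pre-redosing trough at week
#' 6); one engineered renally impaired subject (CrCl < 30 mL/min) whose dose
#' is reduced to 1000 mg; covariates drawn from the cohort's demographic
#' summaries; per-subject protein binding uniform on 96--98%; quantification
#' limits 12.5 mg/L (total) and 1 mg/L (unbound).
#'
#' @param n_subjects cohort size
#' @param truth generating [pop_model()]
#' @param regimen dosing [regimen()]
#' @param sample_times nominal sampling times, h
#' @param dose_reduction_mg reduced amount for low-CrCl subjects
#' @param crcl_cutoff CrCl (mL/min) below which the dose is reduced
#' @param force_low_crcl engineer exactly one subject below the cutoff
#'   (mirrors the study cohort); set `FALSE` for purely random covariates
#' @param pb_range protein-binding range in percent (uniform per subject)
#' @param ql_total,ql_unbound quantification limits, mg/L
#' @param n_missing observations dropped at random (strict replica mode uses
#'   1 to match a 38-of-39 sample count; default 0)
#' @param covariate_effects optional named list of power-model effects used
#'   by the generator, e.g. `list(CL = c(CRCL = 0.75))` scales each
#'   subject's CL by `(CRCL/median(CRCL))^0.75`; default none (covariates
#'   carry no effect, matching the null covariate result in this population)
#' @return config list of class `cohort_config`
#' @export
cohort_config <- function(n_subjects = 13L,
                          truth = dalbavancin_popmodel(),
                          regimen = regimen_preset("1500_d1_d8_q6w"),
                          sample_times = c(1, 168, 1008),
                          dose_reduction_mg = 1000,
                          crcl_cutoff = 30,
                          force_low_crcl = TRUE,
                          pb_range = c(96, 98),
                          ql_total = 12.5, ql_unbound = 1,
                          n_missing = 0L,
                          covariate_effects = list()) {
  stopifnot(inherits(truth, "pop_model"), inherits(regimen, "pk_regimen"))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) abort("`n_subjects` must be >= 1.")
  if (any(pb_range < 0) || any(pb_range >= 100) || pb_range[1] > pb_range[2]) {
    abort("`pb_range` must lie within [0, 100) and be ordered.")
  }
  horizon <- max(expand_regimen(regimen)$start_time) +
    (attr(regimen, "cycle_length") %||% max(sample_times))
  if (any(sample_times < 0) || max(sample_times) > horizon) {
    abort("Sampling times must fall inside the simulated horizon.")
  }
  structure(list(n_subjects = n_subjects, truth = truth, regimen = regimen,
                 sample_times = sample_times,
                 dose_reduction_mg = dose_reduction_mg,
                 crcl_cutoff = crcl_cutoff, force_low_crcl = force_low_crcl,
                 pb_range = pb_range, ql_total = ql_total,
                 ql_unbound = ql_unbound, n_missing = as.integer(n_missing),
                 covariate_effects = covariate_effects),
            class = "cohort_config")
}

#' Sample subject covariates
#'
#' Draws per-subject demographics calibrated to the study cohort: age
#' ~ N(57, 9) truncated to \[30, 85\] years; BSA ~ N(1.95, 0.17) on
#' \[1.4, 2.6\] m^2; CrCl ~ N(90.8, 34.73) on \[30, 200\] mL/min (with one
#' engineered subject uniform on \[15, 30\) when `force_low_crcl`); albumin
#' ~ N(42.5, 5.7) on \[25, 60\] mg/dL; weight log-normal with median 76 kg
#' and interquartile range 20 kg; protein binding uniform on `pb_range`.
#'
#' @param cfg a [cohort_config()]
#' @param seed integer seed
#' @return tibble `id, WT, BSA, AGE, CRCL, ALB, PB`
#' @export
sample_covariates <- function(cfg, seed) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_subjects
  rtrunc <- function(n, mean, sd, lo, hi) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  withr::with_seed(derive_seed(seed, "covariates"), {
    # log-normal weight: sigma solves IQR = median * 2*sinh(z75*sigma)
    sig_w <- asinh((20 / 76) / 2) / qnorm(0.75)
    out <- tibble::tibble(
      id = seq_len(n),
      WT = exp(rnorm(n, log(76), sig_w)),
      BSA = rtrunc(n, 1.95, 0.17, 1.4, 2.6),
      AGE = rtrunc(n, 57, 9, 30, 85),
      CRCL = rtrunc(n, 90.8, 34.73, 30, 200),
      ALB = rtrunc(n, 42.5, 5.7, 25, 60),
      PB = runif(n, cfg$pb_range[1], cfg$pb_range[2])
    )
    if (cfg$force_low_crcl) out$CRCL[1L] <- runif(1, 15, cfg$crcl_cutoff)
  })
  out
}

#' Generate a synthetic study cohort with ground truth
#'
#' Full forward simulation of the study design: covariates, individual
#' parameters `typical * exp(eta)` (optionally modulated by configured
#' covariate effects), dosing per regimen with the CrCl-triggered dose
#' reduction, true concentration profiles from the analytic model, total and
#' unbound observations with proportional residual error, and BQL flags
#' where the simulated value falls below the analyte's quantification limit
#' (`DV` is kept as simulated; imputation is a separate, explicit step,
#' [impute_bql()]). Ground truth (etas, individual parameters, true
#' concentrations, per-subject binding) is attached for recovery tests and
#' never consumed by the fitting path.
#'
#' @param cfg a [cohort_config()]
#' @param seed integer seed; identical seeds reproduce the cohort exactly
#' @return the dataset tibble ([validate_pkdata()] layout) with attributes
#'   `truth` (tibble of per-subject parameters and etas), `config`, `seed`
#' @export
#' @examples
#' d <- generate_cohort(cohort_config(), seed = 20)
#' cohort_truth(d)
generate_cohort <- function(cfg, seed) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_subjects
  cov <- sample_covariates(cfg, seed)
  typ <- cfg$truth$typical
  omega <- cfg$truth$omega
  b <- cfg$truth$error_b

  withr::with_seed(derive_seed(seed, "cohort"), {
    pars <- tibble::tibble(id = seq_len(n),
                           CL = rep(typ$CL, n), V1 = rep(typ$V1, n),
                           Q = rep(typ$Q, n), V2 = rep(typ$V2, n))
    for (p in names(omega)) {
      eta <- if (omega[[p]] > 0) rnorm(n, 0, omega[[p]]) else rep(0, n)
      pars[[paste0("eta_", p)]] <- eta
      pars[[p]] <- pars[[p]] * exp(eta)
    }
    for (p in names(cfg$covariate_effects)) {
      eff <- cfg$covariate_effects[[p]]
      for (cv in names(eff)) {
        pars[[p]] <- pars[[p]] * (cov[[cv]] / median(cov[[cv]]))^eff[[cv]]
      }
    }

    ev <- expand_regimen(cfg$regimen)
    reduced <- cov$CRCL < cfg$crcl_cutoff
    # truncate the dose list to what precedes the last sample; later cycles
    # carry no information for these observations
    ev <- ev[ev$start_time < max(cfg$sample_times), , drop = FALSE]

    true_conc <- conc_matrix(pars, ev, cfg$sample_times) # n x n_times
    scale <- ifelse(reduced, cfg$dose_reduction_mg / ev$amount[1L], 1)
    true_conc <- true_conc * scale # dose linearity

    eps_t <- matrix(rnorm(n * length(cfg$sample_times)), n)
    eps_u <- matrix(rnorm(n * length(cfg$sample_times)), n)
    obs_total <- true_conc * (1 + b * eps_t)
    fu <- (100 - cov$PB) / 100
    obs_unb <- true_conc * fu * (1 + b * eps_u)

    rows <- list()
    for (i in seq_len(n)) {
      amt <- if (reduced[i]) cfg$dose_reduction_mg else ev$amount
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ID = i, TIME = ev$start_time, EVID = 1L,
        AMT = if (reduced[i]) rep(cfg$dose_reduction_mg, nrow(ev)) else ev$amount,
        DUR = ev$duration, DV = NA_real_, BQL = NA_integer_,
        ANALYTE = NA_character_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ID = i, TIME = cfg$sample_times, EVID = 0L,
        AMT = NA_real_, DUR = NA_real_,
        DV = obs_total[i, ], BQL = as.integer(obs_total[i, ] < cfg$ql_total),
        ANALYTE = "total")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ID = i, TIME = cfg$sample_times, EVID = 0L,
        AMT = NA_real_, DUR = NA_real_,
        DV = obs_unb[i, ], BQL = as.integer(obs_unb[i, ] < cfg$ql_unbound),
        ANALYTE = "unbound")
    }
    d <- dplyr::bind_rows(rows)
    d <- dplyr::left_join(d, cov, by = c(ID = "id"))
    d <- dplyr::arrange(d, .data$ID, .data$TIME, dplyr::desc(.data$EVID))

    if (cfg$n_missing > 0L) {
      obs_idx <- which(d$EVID == 0L & d$ANALYTE == "total")
      drop <- sample(obs_idx, min(cfg$n_missing, length(obs_idx)))
      d <- d[-drop, , drop = FALSE]
    }
  })

  truth <- dplyr::left_join(pars, cov, by = "id")
  truth$true_conc <- lapply(seq_len(n), function(i) {
    tibble::tibble(time = cfg$sample_times, conc = true_conc[i, ])
  })
  d <- validate_pkdata(d)
  attr(d, "truth") <- truth
  attr(d, "config") <- cfg
  attr(d, "seed") <- seed
  attr(d, "config_hash") <- config_hash(list(n = n, seed = seed,
                                             times = cfg$sample_times))
  d
}

#' @rdname generate_cohort
#' @param d a generated cohort
#' @export
cohort_truth <- function(d) {
  attr(d, "truth") %||% abort("No ground truth attached to this dataset.")
}

#' Write a cohort with its ground-truth sidecar
#'
#' Emits the dataset CSV plus a `truth.json` sidecar alongside it (the
#' sidecar is for auditing and recovery tests; the fitting path never reads
#' it).
#'
#' @param d a [generate_cohort()] result
#' @param path CSV path; the sidecar is written next to it
#' @return `path`, invisibly
#' @export
write_cohort <- function(d, path) {
  write_pkdata(d, path)
  truth <- cohort_truth(d)
  truth$true_conc <- NULL
  jsonlite::write_json(list(config_hash = attr(d, "config_hash"),
                            seed = attr(d, "seed"),
                            truth = truth),
                       file.path(dirname(path), "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Concentration summary of a cohort at the nominal sampling times
#'
#' Mean and SD of total concentrations by nominal sampling time, computed
#' after QL/2 imputation (so sub-QL troughs enter at 6.25 mg/L, matching
#' how sparse study data are summarized), plus the BQL fraction.
#'
#' @param d PK dataset
#' @return tibble `time, n, mean, sd, n_bql`
#' @export
summarize_cohort <- function(d) {
  d <- tibble::as_tibble(d)
  if (nrow(d) == 0L) abort("Empty dataset.")
  cfg <- attr(d, "config")
  di <- impute_bql(d, ql_total = cfg$ql_total %||% 12.5,
                   ql_unbound = cfg$ql_unbound %||% 1)
  obs <- dplyr::filter(di, .data$EVID == 0L, .data$ANALYTE == "total")
  if (nrow(obs) == 0L) abort("No total-concentration observations to summarize.")
  obs |>
    dplyr::group_by(time = .data$TIME) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$DV), sd = sd(.data$DV),
                     n_bql = sum(.data$BQL == 1L), .groups = "drop")
}
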