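# Analytic two-compartment IV-infusion kinetics, vectorized over individuals.
#
# Everything below works elementwise on parameter vectors (one element per
# individual) with scalar or vector times, so population simulation and SAEM
# likelihood evaluations share one code path. The one-compartment limit
# (Q = 0) is handled by zeroing the beta-phase coefficient.

# Hybrid constants for parameter vectors. Returns list of vectors
# alpha, beta, cA, cB; for Q == 0 beta is set to 1 (inert: cB = 0).
.macro_vec <- function(CL, V1, Q, V2) {
  k10 <- CL / V1
  k12 <- Q / V1
  k21 <- Q / V2
  a1 <- k10 + k12 + k21
  a0 <- k10 * k21
  disc <- pmax(a1^2 - 4 * a0, 0)
  alpha <- (a1 + sqrt(disc)) / 2
  beta <- ifelse(alpha > 0, a0 / alpha, 0)
  one <- Q == 0
  span <- alpha - beta
  cA <- ifelse(one, 1 / V1, (alpha - k21) / (V1 * span))
  cB <- ifelse(one, 0, (k21 - beta) / (V1 * span))
  beta <- ifelse(one, 1, beta) # inert placeholder, cB == 0
  list(alpha = alpha, beta = beta, cA = cA, cB = cB)
}

# Central concentration contribution of one infusion, elementwise.
# tt: time since infusion start (vector or scalar), amt/dur likewise.
.conc_contrib <- function(CL, V1, Q, V2, tt, amt, dur) {
  n <- max(length(CL), length(tt), length(amt))
  CL <- rep_len(CL, n); V1 <- rep_len(V1, n)
  Q <- rep_len(Q, n); V2 <- rep_len(V2, n)
  tt <- rep_len(tt, n); amt <- rep_len(amt, n); dur <- rep_len(dur, n)
  m <- .macro_vec(CL, V1, Q, V2)
  R0 <- amt / dur
  out <- numeric(n)
  during <- tt > 0 & tt <= dur
  post <- tt > dur
  if (any(during)) {
    i <- during
    out[i] <- R0[i] * (m$cA[i] / m$alpha[i] * one_m_exp(m$alpha[i] * tt[i]) +
                       m$cB[i] / m$beta[i] * one_m_exp(m$beta[i] * tt[i]))
  }
  if (any(post)) {
    i <- post
    tp <- tt[i] - dur[i]
    out[i] <- R0[i] *
      (m$cA[i] / m$alpha[i] * one_m_exp(m$alpha[i] * dur[i]) * exp(-m$alpha[i] * tp) +
       m$cB[i] / m$beta[i] * one_m_exp(m$beta[i] * dur[i]) * exp(-m$beta[i] * tp))
  }
  out
}

# Exact integral of one infusion's contribution over [w0, w1] measured from
# the infusion start (w0 may be negative; the pre-dose part contributes 0).
.auc_contrib <- function(CL, V1, Q, V2, w0, w1, amt, dur) {
  n <- max(length(CL), length(w0), length(w1), length(amt))
  CL <- rep_len(CL, n); V1 <- rep_len(V1, n)
  Q <- rep_len(Q, n); V2 <- rep_len(V2, n)
  w0 <- rep_len(w0, n); w1 <- rep_len(w1, n)
  amt <- rep_len(amt, n); dur <- rep_len(dur, n)
  m <- .macro_vec(CL, V1, Q, V2)
  R0 <- amt / dur
  term <- function(coef, lam) {
    G <- R0 * coef / lam
    # during-infusion overlap
    a <- pmin(pmax(w0, 0), dur)
    b <- pmin(pmax(w1, 0), dur)
    dur_part <- ifelse(b > a,
                       G * ((b - a) + (exp(-lam * b) - exp(-lam * a)) / lam),
                       0)
    # post-infusion overlap, measured from end of infusion
    a2 <- pmax(w0, dur) - dur
    b2 <- pmax(w1, dur) - dur
    post_part <- ifelse(b2 > a2,
                        G * one_m_exp(lam * dur) *
                          (exp(-lam * a2) - exp(-lam * b2)) / lam,
                        0)
    dur_part + post_part
  }
  term(m$cA, m$alpha) + term(m$cB, m$beta)
}

.pars_df <- function(params) {
  if (inherits(params, "pk_params")) {
    tibble::tibble(CL = params$CL, V1 = params$V1, Q = params$Q, V2 = params$V2)
  } else if (is.data.frame(params)) {
    need <- c("CL", "V1", "Q", "V2")
    if (!all(need %in% names(params))) {
      abort("Parameter data frame needs columns CL, V1, Q, V2.")
    }
    tibble::as_tibble(params[need])
  } else {
    abort("`params` must be a pk_params object or a data frame of individuals.")
  }
}

.events_df <- function(r) {
  if (inherits(r, "pk_regimen")) return(expand_regimen(r))
  if (is.data.frame(r)) {
    need <- c("start_time", "amount", "duration")
    if (!all(need %in% names(r))) {
      abort("Event data frame needs columns start_time, amount, duration.")
    }
    return(tibble::as_tibble(r[need]))
  }
  abort("`regimen` must be a pk_regimen or a data frame of dose events.")
}

# n_individuals x n_times matrix of total central concentrations.
conc_matrix <- function(params, events, times) {
  if (length(times) == 0L) abort("The time grid is empty.")
  if (any(times < 0)) abort("Times must be non-negative.")
  pars <- .pars_df(params)
  ev <- .events_df(events)
  n <- nrow(pars)
  out <- matrix(0, n, length(times))
  for (j in seq_along(times)) {
    acc <- numeric(n)
    for (e in seq_len(nrow(ev))) {
      tt <- times[j] - ev$start_time[e]
      if (tt <= 0) next
      acc <- acc + .conc_contrib(pars$CL, pars$V1, pars$Q, pars$V2,
                                 tt, ev$amount[e], ev$duration[e])
    }
    out[, j] <- acc
  }
  out
}

# Per-individual AUC over [t0, t1], exact.
auc_vec <- function(params, events, t0, t1) {
  pars <- .pars_df(params)
  ev <- .events_df(events)
  acc <- numeric(nrow(pars))
  for (e in seq_len(nrow(ev))) {
    acc <- acc + .auc_contrib(pars$CL, pars$V1, pars$Q, pars$V2,
                              t0 - ev$start_time[e], t1 - ev$start_time[e],
                              ev$amount[e], ev$duration[e])
  }
  acc
}

#' Concentration-time profile of a dosing regimen
#'
#' Total (bound + unbound) central-compartment concentration of the
#' two-compartment infusion model, by analytic superposition over every dose
#' event of the expanded regimen. The solution is exact: closed-form
#' biexponential kinetics during and after each infusion, summed over doses.
#'
#' @param params a [pk_params()] object (one subject)
#' @param regimen a [regimen()], or a data frame of dose events with columns
#'   `start_time`, `amount`, `duration`
#' @param times numeric vector of times (h, >= 0)
#' @return tibble with columns `time` (h) and `conc` (mg/L)
#' @seealso [auc_window()], [simulate_profiles()] for virtual populations
#' @export
#' @examples
#' conc_profile(dalbavancin_params(), regimen_preset("1500_q3w"),
#'              times = c(1, 168, 504))
conc_profile <- function(params, regimen, times) {
  stopifnot(inherits(params, "pk_params"))
  cc <- conc_matrix(params, regimen, times)
  tibble::tibble(time = times, conc = as.numeric(cc[1L, ]))
}

#' Area under the concentration-time curve over a window
#'
#' Exact analytic integral of the superposed infusion solution over
#' `[t0, t1]`; additive over adjacent windows. With `t1` far beyond the last
#' dose this converges to the mass-balance limit `sum(dose)/CL`.
#'
#' @inheritParams conc_profile
#' @param t0,t1 window bounds in hours, `0 <= t0 < t1`
#' @return AUC in mg·h/L
#' @export
#' @examples
#' p <- dalbavancin_params()
#' r <- regimen(1, 1500, cycle_weeks = NULL)
#' auc_window(p, r, 0, 5e4) # approaches 1500 / CL
auc_window <- function(params, regimen, t0, t1) {
  stopifnot(inherits(params, "pk_params"))
  if (!is.numeric(t0) || !is.numeric(t1) || t0 < 0 || t1 <= t0) {
    abort("Need 0 <= t0 < t1.")
  }
  auc_vec(params, regimen, t0, t1)[1L]
}
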