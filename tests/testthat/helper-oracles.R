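# Independent numerical oracles used across the suite.

# High-accuracy ODE solution of the two-compartment infusion system,
# integrated piecewise between infusion on/off boundaries so the forcing is
# smooth within each segment.
ode_conc_oracle <- function(p, events, times, rtol = 1e-11, atol = 1e-13) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  k10 <- p$CL / p$V1
  k12 <- p$Q / p$V1
  k21 <- p$Q / p$V2
  ends <- events$start_time + events$duration
  bounds <- sort(unique(c(0, events$start_time, ends, times)))
  bounds <- bounds[bounds <= max(times)]
  if (max(bounds) < max(times)) bounds <- c(bounds, max(times))
  deriv <- function(t, y, parms) {
    list(c(parms$R0 - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  y <- c(0, 0)
  out <- rep(NA_real_, length(times))
  out[times == 0] <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    mid <- (t0 + t1) / 2
    R0 <- sum(events$amount / events$duration *
                (mid >= events$start_time & mid < ends))
    idx <- which(times > t0 & times <= t1)
    seg <- sort(unique(c(t0, times[idx], t1)))
    sol <- deSolve::lsoda(y, seg, deriv, parms = list(R0 = R0),
                          rtol = rtol, atol = atol)
    out[idx] <- sol[match(times[idx], seg), 2]
    y <- as.numeric(sol[nrow(sol), 2:3])
  }
  out / p$V1
}

# Composite-trapezoid AUC of a concentration curve on a dense grid.
trapz_auc_oracle <- function(conc_fun, t0, t1, step = 1 / 3600) {
  tg <- seq(t0, t1, by = step)
  cv <- conc_fun(tg)
  sum((cv[-1] + cv[-length(cv)]) / 2) * step
}

# Small helper: a study-replica cohort with QL/2 imputation applied, ready
# for fitting.
replica_cohort <- function(n, seed, ...) {
  impute_bql(generate_cohort(cohort_config(n_subjects = n, ...), seed = seed))
}

# Short SAEM schedule for tests that only need a converged-enough fit.
fast_ctrl <- function(...) {
  saem_control(n_burn = 200L, n_smooth = 100L, n_mc_ll = 300L, n_ebe = 200L, ...)
}
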