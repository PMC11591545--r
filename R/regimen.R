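#' Define a cyclic intravenous dosing regimen
#'
#' A regimen is an ordered set of infusion events within one dosing cycle,
#' optionally repeated every `cycle_weeks` for `n_cycles` cycles. Clinical
#' "day n" labelling maps to start time `(n - 1) * 24` h, so day 1 = 0 h and
#' day 8 = 168 h.
#'
#' @param day vector of dosing days within one cycle (day 1 = start of cycle)
#' @param amount_mg dose amounts in mg, recycled to `length(day)`
#' @param duration_h infusion durations in hours (> 0), recycled
#' @param cycle_weeks cycle length in weeks, or `NULL` for a single
#'   non-repeating course
#' @param n_cycles number of cycles simulated (ignored when
#'   `cycle_weeks` is `NULL`); the default 6 is enough to approach steady
#'   state for half-lives around two weeks
#' @param label short text label used in result tables and plots
#'
#' @return A tibble of per-cycle events (`day`, `start_time`, `amount`,
#'   `duration`) of class `pk_regimen`, carrying the cycle structure as
#'   attributes.
#' @seealso [regimen_preset()] for the studied dalbavancin regimens,
#'   [expand_regimen()], [redose_times()]
#' @export
#' @examples
#' regimen(day = c(1, 8), amount_mg = 1500, cycle_weeks = 6, label = "d1+d8 q6w")
regimen <- function(day, amount_mg, duration_h = 0.5, cycle_weeks = NULL,
                    n_cycles = 6L, label = NULL) {
  if (length(day) < 1L) abort("A regimen needs at least one dose event.")
  amount_mg <- rep_len(amount_mg, length(day))
  duration_h <- rep_len(duration_h, length(day))
  if (any(day < 1)) abort("Dose `day` must be >= 1 (day 1 is time 0).")
  if (any(amount_mg <= 0)) abort("Dose amounts must be positive.")
  if (any(duration_h <= 0)) abort("Infusion durations must be positive.")
  start <- (day - 1) * 24
  o <- order(start)
  start <- start[o]; day <- day[o]
  amount_mg <- amount_mg[o]; duration_h <- duration_h[o]
  if (anyDuplicated(start)) abort("Dose start times within a cycle must be distinct.")
  if (!is.null(cycle_weeks)) {
    assert_positive_scalar(cycle_weeks, "cycle_weeks")
    n_cycles <- as.integer(n_cycles)
    if (n_cycles < 1L) abort("`n_cycles` must be >= 1.")
    if (max(start) >= cycle_weeks * 168) {
      abort("All dose events must start inside one cycle length.")
    }
  } else {
    n_cycles <- 1L
  }
  out <- tibble::tibble(day = day, start_time = start,
                        amount = amount_mg, duration = duration_h)
  structure(out,
            class = c("pk_regimen", class(out)),
            cycle_length = if (is.null(cycle_weeks)) NULL else cycle_weeks * 168,
            n_cycles = n_cycles,
            label = label %||% sprintf("%g mg x%d", amount_mg[1], length(day)))
}

#' @export
print.pk_regimen <- function(x, ...) {
  cl <- attr(x, "cycle_length")
  cat(sprintf("<pk_regimen> %s\n", attr(x, "label")))
  if (!is.null(cl)) {
    cat(sprintf("  cycle %g weeks, %d cycles\n", cl / 168, attr(x, "n_cycles")))
  } else {
    cat("  single course (no cycling)\n")
  }
  NextMethod()
}

#' Expand a regimen into its full dose-event list
#'
#' Repeats the within-cycle events every cycle for `n_cycles` cycles and
#' returns one row per administered infusion, sorted by start time.
#'
#' @param r a [regimen()]
#' @param n_cycles optional override of the regimen's cycle count
#' @return tibble with `start_time`, `amount`, `duration` (strictly
#'   increasing start times)
#' @export
expand_regimen <- function(r, n_cycles = NULL) {
  stopifnot(inherits(r, "pk_regimen"))
  cl <- attr(r, "cycle_length")
  nc <- as.integer(n_cycles %||% attr(r, "n_cycles"))
  if (is.null(cl)) nc <- 1L
  offs <- (seq_len(nc) - 1L) * (cl %||% 0)
  out <- tidyr::expand_grid(offset = offs,
                            tibble::as_tibble(r)[c("start_time", "amount", "duration")])
  out <- dplyr::transmute(out,
                          start_time = .data$offset + .data$start_time,
                          amount = .data$amount, duration = .data$duration)
  out <- dplyr::arrange(out, .data$start_time)
  if (any(diff(out$start_time) <= 0)) {
    abort("Expanded regimen has non-increasing dose start times.")
  }
  out
}

#' Scheduled redosing times of the evaluation cycle
#'
#' Returns the times at which a *next* dose is scheduled during the final
#' simulated cycle: the start times of every within-cycle dose after the
#' first, plus the start of the (hypothetical) next cycle. These are the
#' interval ends at which pre-redosing exposure (e.g. the last-24-h free AUC)
#' is evaluated. For a single-course regimen the only redosing time is the
#' end of the course's nominal interval, which requires a cycle structure, so
#' an error is raised.
#'
#' @param r a [regimen()]
#' @param cycle which cycle to evaluate (default: the last one)
#' @return numeric vector of redosing times, h
#' @export
redose_times <- function(r, cycle = NULL) {
  stopifnot(inherits(r, "pk_regimen"))
  cl <- attr(r, "cycle_length")
  if (is.null(cl)) {
    abort("Regimen has no cycle structure; no redosing time is defined.")
  }
  nc <- attr(r, "n_cycles")
  cyc <- as.integer(cycle %||% nc)
  if (cyc < 1L || cyc > nc) abort("`cycle` outside the simulated range.")
  off <- (cyc - 1L) * cl
  within <- r$start_time[-1L]
  sort(c(off + within, off + cl))
}

#' Preset dalbavancin regimens for suppressive therapy
#'
#' The six long-interval regimens studied for ventricular assist device
#' infection suppression, all as 0.5-h infusions and simulated for 6 cycles
#' by default:
#' \describe{
#'   \item{`"1500_d1_d8_q6w"`}{1500 mg on day 1 and day 8, repeated every 6 weeks}
#'   \item{`"1500_d1_d15_q6w"`}{1500 mg on day 1 and day 15, every 6 weeks}
#'   \item{`"1000_q2w"`}{1000 mg every 2 weeks}
#'   \item{`"1500_q3w"`}{1500 mg every 3 weeks}
#'   \item{`"1500_q4w"`}{1500 mg every 4 weeks}
#'   \item{`"1500_q5w"`}{1500 mg every 5 weeks}
#' }
#'
#' @param name preset name, one of the above
#' @param n_cycles number of simulated cycles
#' @return a [regimen()]
#' @export
#' @examples
#' regimen_preset("1500_q3w")
regimen_preset <- function(name = regimen_presets(), n_cycles = 6L) {
  name <- match.arg(name)
  switch(name,
    "1500_d1_d8_q6w" = regimen(c(1, 8), 1500, cycle_weeks = 6,
                               n_cycles = n_cycles, label = "1500 mg d1+d8 q6w"),
    "1500_d1_d15_q6w" = regimen(c(1, 15), 1500, cycle_weeks = 6,
                                n_cycles = n_cycles, label = "1500 mg d1+d15 q6w"),
    "1000_q2w" = regimen(1, 1000, cycle_weeks = 2,
                         n_cycles = n_cycles, label = "1000 mg q2w"),
    "1500_q3w" = regimen(1, 1500, cycle_weeks = 3,
                         n_cycles = n_cycles, label = "1500 mg q3w"),
    "1500_q4w" = regimen(1, 1500, cycle_weeks = 4,
                         n_cycles = n_cycles, label = "1500 mg q4w"),
    "1500_q5w" = regimen(1, 1500, cycle_weeks = 5,
                         n_cycles = n_cycles, label = "1500 mg q5w")
  )
}

#' @rdname regimen_preset
#' @export
regimen_presets <- function() {
  c("1500_d1_d8_q6w", "1500_d1_d15_q6w", "1000_q2w",
    "1500_q3w", "1500_q4w", "1500_q5w")
}

#' Read or write a regimen as YAML
#'
#' Serialization format: a map with `events` (list of `{day, amount_mg,
#' duration_h}`), optional `cycle_weeks`, `n_cycles`, and `label`.
#'
#' @param path file path
#' @param r a [regimen()]
#' @return `read_regimen()` returns a [regimen()]; `write_regimen()` returns
#'   `path` invisibly.
#' @export
read_regimen <- function(path) {
  y <- yaml::read_yaml(path)
  ev <- dplyr::bind_rows(y$events)
  regimen(day = ev$day, amount_mg = ev$amount_mg,
          duration_h = ev$duration_h %||% 0.5,
          cycle_weeks = y$cycle_weeks,
          n_cycles = y$n_cycles %||% 6L,
          label = y$label)
}

#' @rdname read_regimen
#' @export
write_regimen <- function(r, path) {
  stopifnot(inherits(r, "pk_regimen"))
  y <- list(
    label = attr(r, "label"),
    cycle_weeks = if (is.null(attr(r, "cycle_length"))) NULL else attr(r, "cycle_length") / 168,
    n_cycles = attr(r, "n_cycles"),
    events = purrr::pmap(tibble::as_tibble(r)[c("day", "amount", "duration")],
                         function(day, amount, duration) {
                           list(day = day, amount_mg = amount, duration_h = duration)
                         })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
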