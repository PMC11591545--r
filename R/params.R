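#' Structural parameters of the two-compartment model
#'
#' Bundle clearance and volume parameters of the mammillary two-compartment
#' intravenous model. All parameters must be strictly positive; `Q = 0` is
#' accepted as the degenerate one-compartment limit (the peripheral
#' compartment is then disconnected), which is useful in tests and for
#' one-compartment comparison fits.
#'
#' @param CL total body clearance, L/h
#' @param V1 central volume of distribution, L
#' @param Q inter-compartmental clearance, L/h (0 collapses the model to one
#'   compartment)
#' @param V2 peripheral volume of distribution, L
#'
#' @return An object of class `pk_params` (a named list).
#' @seealso [dalbavancin_params()] for the shipped dalbavancin estimates,
#'   [micro_rates()], [macro_constants()], [terminal_half_life()]
#' @export
#' @examples
#' p <- pk_params(CL = 0.050, V1 = 6.5, Q = 0.476, V2 = 15.4)
#' terminal_half_life(p) / 24 # days
pk_params <- function(CL, V1, Q, V2) {
  assert_positive_scalar(CL, "CL")
  assert_positive_scalar(V1, "V1")
  assert_positive_scalar(V2, "V2")
  if (!is.numeric(Q) || length(Q) != 1L || !is.finite(Q) || Q < 0) {
    abort("`Q` must be a single finite number >= 0.")
  }
  structure(list(CL = CL, V1 = V1, Q = Q, V2 = V2), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params> two-compartment IV model\n")
  cat(sprintf("  CL = %.4g L/h   V1 = %.4g L\n  Q  = %.4g L/h   V2 = %.4g L\n",
              x$CL, x$V1, x$Q, x$V2))
  cat(sprintf("  terminal half-life %.3g h (%.3g d)\n",
              terminal_half_life(x), terminal_half_life(x) / 24))
  invisible(x)
}

#' Typical dalbavancin parameters for long-term suppressive therapy
#'
#' Typical-value estimates of the two-compartment dalbavancin model in adult
#' patients on long-interval suppressive therapy (ventricular assist device
#' cohort): CL 0.050 L/h, V1 6.5 L, Q 0.476 L/h (fixed to a literature
#' value), V2 15.4 L. These are the defaults used throughout the simulation
#' functions.
#'
#' @return A [pk_params()] object.
#' @export
dalbavancin_params <- function() {
  pk_params(CL = 0.050, V1 = 6.5, Q = 0.476, V2 = 15.4)
}

#' First-order micro rate constants
#'
#' @param p a [pk_params()] object
#' @return Named list with `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2` (1/h).
#'   For `Q = 0` both transfer constants are zero.
#' @export
micro_rates <- function(p) {
  stopifnot(inherits(p, "pk_params"))
  list(k10 = p$CL / p$V1, k12 = p$Q / p$V1, k21 = p$Q / p$V2)
}

#' Hybrid (macro) disposition constants
#'
#' Reparameterize the micro constants into the biexponential form: `alpha`
#' and `beta` are the roots of \eqn{s^2 - (k10+k12+k21) s + k10 k21 = 0}
#' with `alpha >= beta`, and `coefA`, `coefB` are the unit-bolus central
#' concentration coefficients so that a bolus of dose D gives
#' \eqn{C(t) = D (A e^{-\alpha t} + B e^{-\beta t})}.
#'
#' In the one-compartment limit (`Q = 0`) `alpha = k10`, `beta = 0` and the
#' whole bolus response is carried by the alpha term.
#'
#' @param p a [pk_params()] object
#' @return Named list `alpha`, `beta` (1/h), `coefA`, `coefB` (1/L).
#' @export
macro_constants <- function(p) {
  k <- micro_rates(p)
  if (p$Q == 0) {
    return(list(alpha = k$k10, beta = 0, coefA = 1 / p$V1, coefB = 0))
  }
  a1 <- k$k10 + k$k12 + k$k21
  a0 <- k$k10 * k$k21
  disc <- a1^2 - 4 * a0
  if (disc < 0) disc <- 0 # numerically impossible for positive rates
  alpha <- (a1 + sqrt(disc)) / 2
  beta <- a0 / alpha # stable form of the smaller root
  if (alpha - beta <= 1e-12 * alpha) {
    abort("Repeated disposition roots (alpha == beta) are not supported.")
  }
  list(alpha = alpha, beta = beta,
       coefA = (alpha - k$k21) / (p$V1 * (alpha - beta)),
       coefB = (k$k21 - beta) / (p$V1 * (alpha - beta)))
}

#' Terminal elimination half-life
#'
#' `ln(2)` over the slowest disposition rate constant: `beta` for a genuine
#' two-compartment parameter set, `k10` in the one-compartment limit
#' (`Q = 0`, where the peripheral compartment never sees drug).
#'
#' @param p a [pk_params()] object
#' @return half-life in hours
#' @export
terminal_half_life <- function(p) {
  m <- macro_constants(p)
  if (m$beta > 0) log(2) / m$beta else log(2) / micro_rates(p)$k10
}

#' @method tidy pk_params
#' @export
tidy.pk_params <- function(x, ...) {
  tibble::tibble(
    term = c("CL", "V1", "Q", "V2"),
    estimate = c(x$CL, x$V1, x$Q, x$V2),
    unit = c("L/h", "L", "L/h", "L")
  )
}
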