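#' Two-compartment disposition parameters
#'
#' Container for the micro-parameterisation of an intravenous-bolus
#' two-compartment disposition model: total clearance `CL`, central volume
#' `Vc`, peripheral volume `Vp` and intercompartmental clearance `Q`.
#' Gadoxetate disposition after an IV bolus is biphasic (rapid distribution
#' over the first ~10 min, slow elimination thereafter), which is the minimal
#' structure a two-compartment model captures.
#'
#' @param clearance_total Total body clearance, mL/min.
#' @param v_central Central compartment volume, mL.
#' @param v_peripheral Peripheral compartment volume, mL.
#' @param intercompartment_clearance Distributional clearance Q, mL/min.
#' @return An object of class `disposition_params`.
#' @examples
#' dp <- disposition_params(12.7, 121, 148, 6)
#' biexponential_concentration(dp, dose = 30, t = c(0, 1, 10, 90))
#' @export
disposition_params <- function(clearance_total, v_central, v_peripheral,
                               intercompartment_clearance) {
  vals <- c(clearance_total = clearance_total, v_central = v_central,
            v_peripheral = v_peripheral,
            intercompartment_clearance = intercompartment_clearance)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all disposition parameters must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "disposition_params")
}

#' Convert micro-constants to biexponential macro-constants
#'
#' For an IV bolus into the central compartment, the serum concentration is
#' `C(t) = A exp(-alpha t) + B exp(-beta t)`. This computes `(A, alpha, B,
#' beta)` from `(CL, Vc, Vp, Q)` via the usual eigenvalue decomposition of
#' the two-compartment rate matrix: with `k10 = CL/Vc`, `k12 = Q/Vc`,
#' `k21 = Q/Vp`, `alpha` and `beta` are the roots of
#' `s^2 - (k10 + k12 + k21) s + k10 k21`.
#'
#' Volumes are in mL and dose in µmol, so coefficients come out in µmol/L
#' (the factor 1000 converts µmol/mL to µmol/L).
#'
#' @param params A [disposition_params()] object.
#' @param dose Administered dose, µmol.
#' @return A list with components `A`, `alpha`, `B`, `beta` (concentrations
#'   in µmol/L, rate constants in 1/min). Always `alpha > beta > 0` and
#'   `A, B > 0`.
#' @export
micro_to_macro <- function(params, dose) {
  stopifnot(inherits(params, "disposition_params"))
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive", call. = FALSE)
  vc <- params$v_central
  k10 <- params$clearance_total / vc
  k12 <- params$intercompartment_clearance / vc
  k21 <- params$intercompartment_clearance / params$v_peripheral
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  c0 <- 1000 * dose / vc               # µmol/L
  list(A = c0 * (alpha - k21) / (alpha - beta),
       alpha = alpha,
       B = c0 * (k21 - beta) / (alpha - beta),
       beta = beta)
}

#' Recover micro-constants from biexponential macro-constants
#'
#' Inverse of [micro_to_macro()]: given `(A, alpha, B, beta)` for a known
#' dose, recover `(CL, Vc, Vp, Q)`. Used mainly to round-trip parameter
#' sets and to construct disposition parameters from a target curve shape.
#'
#' @param A,alpha,B,beta Macro-constants (µmol/L and 1/min).
#' @param dose Dose in µmol.
#' @return A [disposition_params()] object.
#' @export
macro_to_micro <- function(A, alpha, B, beta, dose) {
  if (any(c(A, alpha, B, beta, dose) <= 0)) {
    stop("macro-constants and dose must be positive", call. = FALSE)
  }
  if (alpha <= beta) stop("requires alpha > beta", call. = FALSE)
  vc <- 1000 * dose / (A + B)
  k21 <- (A * beta + B * alpha) / (A + B)
  k10 <- alpha * beta / k21
  k12 <- alpha + beta - k21 - k10
  disposition_params(clearance_total = k10 * vc,
                     v_central = vc,
                     v_peripheral = k12 * vc / k21,
                     intercompartment_clearance = k12 * vc)
}

#' Evaluate the IV-bolus biexponential concentration
#'
#' @param params A [disposition_params()] object.
#' @param dose Dose, µmol.
#' @param t Vector of times, min (all `>= 0`).
#' @return Concentrations in µmol/L; `C(0) = 1000 * dose / v_central`.
#' @export
biexponential_concentration <- function(params, dose, t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  m <- micro_to_macro(params, dose)
  m$A * exp(-m$alpha * t) + m$B * exp(-m$beta * t)
}
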