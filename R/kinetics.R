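#' Micro rate constants of the two-tissue compartment model
#'
#' Constructs and validates the rate-constant set of the 2TC model:
#' \code{K1} (perfusion, mL/cm^3/min), \code{k2}, \code{k3}, \code{k4}
#' (transfer rates, 1/min) and the fractional blood volume \code{vB}
#' (unitless, in \[0, 1)).
#'
#' @param K1,k2,k3,k4 Non-negative rate constants; \code{k4} must be positive
#'   for the binding outcomes to be defined.
#' @param vB Fractional blood volume in \[0, 1).
#' @return An object of class \code{"rate_constants"}.
#' @examples
#' rc <- rate_constants(K1 = 0.2, k2 = 0.1, k3 = 0.05, k4 = 0.025, vB = 0.05)
#' rates_to_outcomes(rc)
#' @export
rate_constants <- function(K1, k2, k3, k4, vB = 0) {
  stopifnot(is.numeric(K1), is.numeric(k2), is.numeric(k3), is.numeric(k4),
            is.numeric(vB), length(K1) == 1L)
  if (K1 < 0 || k2 < 0 || k3 < 0) stop("K1, k2, k3 must be >= 0")
  if (k4 <= 0) stop("k4 must be > 0")
  if (vB < 0 || vB >= 1) stop("vB must lie in [0, 1)")
  structure(list(K1 = unname(K1), k2 = unname(k2), k3 = unname(k3),
                 k4 = unname(k4), vB = unname(vB)),
            class = "rate_constants")
}

#' Binding outcomes derived from rate constants
#'
#' Computes the macro (binding) outcome parameters of the 2TC model:
#' total and non-displaceable volumes of distribution
#' \eqn{V_T = (K_1/k_2)(1 + k_3/k_4)}, \eqn{V_{ND} = K_1/k_2}, the binding
#' potentials \eqn{BP_P = K_1 k_3 / (k_2 k_4)} and \eqn{BP_{ND} = k_3/k_4}.
#'
#' @param rc A \code{rate_constants} object with \code{k2 > 0}.
#' @return An object of class \code{"binding_outcomes"} with fields
#'   \code{VT}, \code{VND}, \code{BPP}, \code{BPND}.
#' @export
rates_to_outcomes <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  if (rc$k2 <= 0) stop("k2 must be > 0 for binding outcomes")
  if (rc$k4 <= 0) stop("k4 must be > 0 for binding outcomes")
  VND <- rc$K1 / rc$k2
  BPND <- rc$k3 / rc$k4
  structure(list(VT = VND * (1 + BPND), VND = VND,
                 BPP = VND * BPND, BPND = BPND),
            class = "binding_outcomes")
}

#' Rate constants from the binding parameterisation
#'
#' Inverts the outcome relationships: the model is parameterised by
#' (\code{K1}, \code{VND}, \code{BPND}, \code{k4}, \code{vB}), which map back
#' to micro constants through \code{k2 = K1/VND} and \code{k3 = BPND * k4}.
#' This parameterisation keeps every parameter biologically interpretable and
#' is the one used by the hierarchical model and the NLS baseline.
#'
#' @param K1 Perfusion rate (>= 0).
#' @param VND Non-displaceable distribution volume (> 0).
#' @param BPND Non-displaceable binding potential (>= 0).
#' @param k4 Dissociation rate (> 0).
#' @param vB Fractional blood volume in \[0, 1).
#' @return A \code{rate_constants} object.
#' @export
outcomes_to_rates <- function(K1, VND, BPND, k4, vB = 0) {
  if (VND <= 0) stop("VND must be > 0")
  if (BPND < 0) stop("BPND must be >= 0")
  rate_constants(K1 = K1, k2 = K1 / VND, k3 = BPND * k4, k4 = k4, vB = vB)
}

#' Bi-exponential impulse response of the 2TC model
#'
#' Decomposes the tissue impulse response into
#' \eqn{IRF(t) = \phi_1 e^{-\theta_1 t} + \phi_2 e^{-\theta_2 t}} with
#' \eqn{\theta_{1,2} = ((k_2+k_3+k_4) \pm \sqrt{(k_2+k_3+k_4)^2 - 4 k_2 k_4})/2}.
#' At \eqn{t = 0} the response equals \code{K1}.
#'
#' @param rc A \code{rate_constants} object.
#' @return An object of class \code{"exp_irf"} with fields \code{phi1},
#'   \code{phi2}, \code{theta1}, \code{theta2} (\code{theta1 >= theta2}).
#' @export
impulse_response <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  v <- cpp_irf_decompose(rc$K1, rc$k2, rc$k3, rc$k4)
  structure(list(phi1 = v[1], phi2 = v[2], theta1 = v[3], theta2 = v[4]),
            class = "exp_irf")
}

#' PET frame schedule
#'
#' @param start,end Frame start and end times in minutes; frames must be
#'   positive-length, non-overlapping and ordered.
#' @return An object of class \code{"frame_schedule"} with fields
#'   \code{start}, \code{end}, \code{duration}, \code{midpoint}.
#' @export
frame_schedule <- function(start, end) {
  stopifnot(length(start) == length(end), length(start) >= 1L)
  if (any(start < 0)) stop("frame start times must be >= 0")
  if (any(end <= start)) stop("frame durations must be > 0")
  if (length(start) > 1L && any(start[-1] < end[-length(end)] - 1e-12))
    stop("frames must not overlap")
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 duration = as.numeric(end - start),
                 midpoint = as.numeric((start + end) / 2)),
            class = "frame_schedule")
}

#' Default 20-frame acquisition schedule
#'
#' Three 20-second frames followed by 3 x 1, 3 x 2, 2 x 5 and 9 x 10 minute
#' frames (115 min total), a typical schedule for a long acquisition.
#'
#' @return A \code{frame_schedule}.
#' @export
default_schedule <- function() {
  dur <- c(rep(1 / 3, 3), rep(1, 3), rep(2, 3), rep(5, 2), rep(10, 9))
  end <- cumsum(dur)
  frame_schedule(start = end - dur, end = end)
}

#' Analytic convolution of the AIF with a decaying exponential
#'
#' Evaluates \eqn{(AIF \otimes e^{-\theta s})(t)} in closed form, handling all
#' three pieces of the parametric input function (zero before \code{t0},
#' linear rise to \code{tp}, tri-exponential tail) and the coincident-rate
#' case \eqn{\theta = \lambda_i} through its analytic limit
#' \eqn{t e^{-\theta t}}.
#'
#' @param aif An \code{aif_parameters} object.
#' @param theta Decay rate (1/min, > 0; \code{theta = 0} is handled as the
#'   integrated-input limit).
#' @param t Numeric vector of times (min).
#' @return Numeric vector of convolved concentrations.
#' @export
convolve_exponential <- function(aif, theta, t) {
  stopifnot(inherits(aif, "aif_parameters"), theta >= 0, all(t >= 0))
  cpp_conv_exp(as_aif_vector(aif), theta, as.numeric(t))
}

#' Predict a time-activity curve from the 2TC forward model
#'
#' Evaluates \eqn{C_T(t) = (1 - v_B)(IRF \otimes C_P)(t) + v_B C_B(t)} at the
#' frame midpoints of the schedule, with the tissue convolution computed in
#' closed form against the parametric AIF.
#'
#' @param rc A \code{rate_constants} object.
#' @param aif An \code{aif_parameters} object describing \eqn{C_P}.
#' @param cb Per-frame whole-blood mean concentrations (one per frame).
#' @param sched A \code{frame_schedule}.
#' @param delay Scalar time shift (min) applied to the blood curves relative
#'   to the TAC; default 0.
#' @return An object of class \code{"predicted_tac"}: list with \code{values}
#'   (kBq/mL per frame) and the \code{schedule}.
#' @export
predict_tac <- function(rc, aif, cb, sched, delay = 0) {
  stopifnot(inherits(rc, "rate_constants"), inherits(aif, "aif_parameters"),
            inherits(sched, "frame_schedule"))
  if (length(cb) != length(sched$midpoint))
    stop("cb must have one value per frame (", length(sched$midpoint),
         " frames, got ", length(cb), ")")
  vals <- cpp_predict_tac(rc$K1, rc$k2, rc$k3, rc$k4, rc$vB,
                          as_aif_vector(aif), as.numeric(cb),
                          sched$midpoint, delay)
  structure(list(values = vals, schedule = sched), class = "predicted_tac")
}
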