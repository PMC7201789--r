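#' SAFE layer parameters
#'
#' The SAFE (safety auxiliary feedback element) layer is a sliding-mode
#' reference-conditioning outer loop: when the estimated insulin-on-board
#' exceeds its limit, a switching law emits a discontinuous signal of
#' amplitude `W` that a first-order filter turns into a smooth upward shift of
#' the glucose reference, which in turn makes the inner controller cut insulin.
#'
#' @param tau Sliding-surface time constant in min (> 0). Default 10.
#' @param W Switching amplitude in mg/dl (> 0). Default 350.
#' @param lambda Reference-filter rate in min^-1 (> 0). Default 0.1.
#' @return An object of class `safe_params`.
#' @export
safe_params <- function(tau = 10, W = 350, lambda = 0.1) {
  stopifnot(tau > 0, W > 0, lambda > 0)
  structure(list(tau = tau, W = W, lambda = lambda), class = "safe_params")
}

#' Sliding function of the SAFE layer
#'
#' \deqn{\sigma = (\hat{IOB} - \bar{IOB}) + \tau (\dot{\hat{IOB}} - \dot{\bar{IOB}})}
#' Positive sigma means the IOB estimate is above (or moving above) its limit.
#'
#' @param iob_hat Current IOB estimate, U.
#' @param iob_bar Current IOB limit, U.
#' @param d_iob_hat Time derivative of the estimate, U/min (discrete backward
#'   difference at the controller period).
#' @param d_iob_bar Time derivative of the limit, U/min. The limit is
#'   piecewise constant in this stack, so callers pass 0.
#' @param tau Sliding time constant, min (> 0).
#' @return sigma, in U.
#' @export
sliding_sigma <- function(iob_hat, iob_bar, d_iob_hat, d_iob_bar, tau) {
  stopifnot(tau > 0)
  (iob_hat - iob_bar) + tau * (d_iob_hat - d_iob_bar)
}

#' Switching law
#'
#' @param sigma Sliding-function value, U.
#' @param W Switching amplitude, mg/dl (> 0).
#' @return `W` when `sigma > 0` (strict), else 0.
#' @export
switching <- function(sigma, W) {
  stopifnot(W > 0)
  ifelse(sigma > 0, W, 0)
}

#' Advance the conditioned-reference filter
#'
#' Integrates \deqn{\dot G_{rf} = -\lambda (G_{rf} - G_r) + \omega} for `dt`
#' minutes with `omega` held constant, using the exact exponential update of
#' the first-order system, so the conditioned reference is continuous across
#' switching and matches the analytic solution at any step size.
#'
#' @param g_rf Current conditioned reference, mg/dl.
#' @param g_r Nominal glucose reference, mg/dl.
#' @param omega Switching-law output held over the step, mg/dl.
#' @param lambda Filter rate, min^-1 (> 0).
#' @param dt Step in minutes (> 0).
#' @return The conditioned reference after `dt` minutes, mg/dl.
#' @export
filter_reference <- function(g_rf, g_r, omega, lambda, dt) {
  stopifnot(lambda > 0, dt > 0)
  target <- g_r + omega / lambda
  target + (g_rf - target) * exp(-lambda * dt)
}
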