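#' The BCM plasticity rule and its time scales
#'
#' The rule couples a Hebbian-like weight update through the nonlinearity
#' \eqn{\phi(v; \theta) = v (v - \theta)} with a sliding homeostatic
#' threshold that low-pass filters the squared response:
#' \deqn{\tau_w \, dw/dt = v \, x \, (v - \theta), \qquad
#'       \tau_\theta \, d\theta/dt = v^2 - \theta.}
#' Only the ratio \eqn{\tau = \tau_\theta / \tau_w} matters for the phase
#' portrait of the averaged equations; the individual factors set the clock.
#'
#' @param tau_w weight time-scale factor (time units), positive.
#' @param tau_theta threshold time-scale factor, positive.
#' @return An object of class `"bcm_rule"` with elements `tau_w`,
#'   `tau_theta`, `tau` (the ratio), `phi` and `threshold_update`.
#' @examples
#' r <- bcm_rule(tau_w = 25, tau_theta = 25 * 0.25)
#' r$phi(2, 2)   # vanishes at v = theta
#' @export
bcm_rule <- function(tau_w = 1, tau_theta = tau_w) {
  stopifnot(tau_w > 0, tau_theta > 0)
  structure(
    list(
      tau_w = tau_w,
      tau_theta = tau_theta,
      tau = tau_theta / tau_w,
      phi = function(v, theta) v * (v - theta),
      threshold_update = function(v, theta) v^2 - theta
    ),
    class = "bcm_rule"
  )
}

#' @export
print.bcm_rule <- function(x, ...) {
  cat(sprintf("BCM rule: phi(v, theta) = v (v - theta), tau_w = %g, tau_theta = %g (tau = %g)\n",
              x$tau_w, x$tau_theta, x$tau))
  invisible(x)
}
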