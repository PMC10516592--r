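#' Left-flat sigmoid trajectory function
#'
#' Mean trajectory of a regional volume against CAP score: exactly constant at
#' `v0` up to the changepoint `tau`, then declining along a half-logistic ramp
#' towards the asymptote `v0 - delta`:
#' \deqn{f(c) = v_0 - \delta \, S\!\left(\frac{c - \tau}{s}\right)_{+}, \quad
#'       S(u) = \frac{2}{1 + e^{-u}} - 1,}
#' with \eqn{S} applied only for \eqn{c > \tau}.  The curve is continuous at
#' `tau`, monotone non-increasing for `delta >= 0`, and sigmoidal (concave
#' then convex) right of the changepoint.  The flat left limb encodes the
#' observation that carriers very far from onset have essentially normal
#' volumes.
#'
#' @param cap CAP score(s) at which to evaluate.
#' @param v0 Pre-changepoint level, response units.
#' @param delta Total eventual drop, response units (>= 0).
#' @param tau Changepoint: CAP score at first slope change.
#' @param scale Transition width, CAP units (> 0).
#' @return Numeric vector of trajectory values.
#' @export
#' @examples
#' left_flat_sigmoid(c(250, 300, 350), v0 = 10, delta = 4, tau = 300, scale = 50)
left_flat_sigmoid <- function(cap, v0, delta, tau, scale) {
  stopifnot(scale > 0, delta >= 0)
  v0 - delta * half_logistic_ramp(cap, tau, scale)
}

#' Half-logistic ramp
#'
#' The unit-amplitude shape underlying [left_flat_sigmoid()]: 0 for
#' `cap <= tau`, rising to 1 as `cap` grows, with slope `1/(2*scale)` at the
#' changepoint.
#'
#' @inheritParams left_flat_sigmoid
#' @return Values in `[0, 1)`.
#' @export
half_logistic_ramp <- function(cap, tau, scale) {
  u <- (cap - tau) / scale
  r <- ifelse(u > 0, 2 / (1 + exp(-u)) - 1, 0)
  as.numeric(r)
}
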