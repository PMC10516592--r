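#' @export
print.flatsig <- function(x, digits = 4, ...) {
  cat("Left-flat sigmoid trajectory fit\n")
  if (!is.null(x$roi)) cat("  ROI:", x$roi, "\n")
  p <- x$params
  cat(sprintf("  v0 = %.*g, delta = %.*g, tau = %.*g, scale = %.*g\n",
              digits, p$v0, digits, p$delta, digits, p$tau, digits, p$scale))
  if (length(x$covariate_coefs)) {
    cat("  covariates:\n")
    print(round(x$covariate_coefs, digits))
  }
  cat(sprintf("  n = %d, RSS = %.*g, sigma = %.*g, converged = %s\n",
              x$n, digits, x$rss, digits, x$sigma, x$converged))
  invisible(x)
}

#' @export
summary.flatsig <- function(object, ...) {
  cmp <- compare_models(object)
  structure(list(fit = object, comparison = cmp), class = "summary.flatsig")
}

#' @export
print.summary.flatsig <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$comparison)
  tab <- data.frame(
    model = c("sigmoid", "linear", "constant"),
    rss = c(x$fit$rss, x$fit$linear$rss, x$fit$constant$rss),
    aic = c(x$fit$aic, x$fit$linear$aic, x$fit$constant$aic),
    bic = c(x$fit$bic, x$fit$linear$bic, x$fit$constant$bic)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.flatsig <- function(object, ...) object$coefficients

#' @export
fitted.flatsig <- function(object, ...) object$fitted.values

#' @export
residuals.flatsig <- function(object, ...) object$residuals

#' @export
nobs.flatsig <- function(object, ...) object$n

#' @export
logLik.flatsig <- function(object, ...) {
  ll <- .gauss_ll(object$rss, object$n)
  structure(ll, df = object$df[["p_sig"]] + 1, nobs = object$n,
            class = "logLik")
}

#' Predict from a left-flat sigmoid fit
#'
#' With `newdata = NULL`, returns fitted values.  Otherwise `newdata` must
#' contain the CAP column and any covariates in the model formula; covariate
#' columns may be omitted entirely, in which case the prediction is the bare
#' trajectory (covariates at reference levels / centred zero), i.e. the trend
#' line.
#'
#' @param object A [flatsig()] fit.
#' @param newdata Optional data frame.
#' @param cap Name of the CAP column in `newdata`.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.flatsig <- function(object, newdata = NULL, cap = "cap", ...) {
  if (is.null(newdata)) return(object$fitted.values)
  p <- object$params
  mu <- left_flat_sigmoid(newdata[[cap]], p$v0, p$delta, p$tau, p$scale)
  vars <- setdiff(all.vars(stats::delete.response(object$terms)), cap)
  if (length(vars) && all(vars %in% names(newdata))) {
    Z <- stats::model.matrix(stats::delete.response(object$terms), newdata)
    Z <- Z[, setdiff(colnames(Z), "(Intercept)"), drop = FALSE]
    keep <- intersect(colnames(Z), names(object$covariate_coefs))
    if (length(keep)) mu <- mu + as.numeric(Z[, keep, drop = FALSE] %*%
                                              object$covariate_coefs[keep])
  }
  mu
}

#' Fitted trajectory on a CAP grid
#'
#' Evaluates the fitted mean curve with covariates at reference levels and
#' centred ICV zero — the machine-readable analogue of a summary trend line.
#'
#' @param fit A [flatsig()] fit.
#' @param cap_grid CAP values; default 101 points over the observed range.
#' @return Data frame with columns `cap` and `value`.
#' @export
trend_line <- function(fit, cap_grid = NULL) {
  stopifnot(inherits(fit, "flatsig"))
  if (is.null(cap_grid))
    cap_grid <- seq(min(fit$model$cap), max(fit$model$cap), length.out = 101)
  p <- fit$params
  data.frame(cap = cap_grid,
             value = left_flat_sigmoid(cap_grid, p$v0, p$delta, p$tau, p$scale))
}

#' Simulate responses from a fitted trajectory model
#'
#' Parametric simulation: fitted mean plus homoscedastic Gaussian noise with
#' the residual standard deviation.
#'
#' @param object A [flatsig()] fit.
#' @param nsim Number of response vectors.
#' @param seed Optional RNG seed (global RNG state is restored afterwards).
#' @param ... Unused.
#' @return Data frame with `nsim` columns.
#' @export
simulate.flatsig <- function(object, nsim = 1, seed = NULL, ...) {
  gen <- function() {
    as.data.frame(replicate(
      nsim, object$fitted.values + stats::rnorm(object$n, 0, object$sigma),
      simplify = FALSE),
      col.names = paste0("sim_", seq_len(nsim)))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Plot a fitted trajectory
#'
#' Partial-residual scatter (response minus covariate contributions) against
#' CAP, with the fitted left-flat sigmoid overlaid and the changepoint marked.
#'
#' @param x A [flatsig()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.flatsig <- function(x, ...) {
  p <- x$params
  zb <- if (length(x$covariate_coefs))
    as.numeric(x$model$Z %*% x$covariate_coefs) else 0
  partial <- x$model$y - zb
  graphics::plot(x$model$cap, partial, xlab = "CAP score",
                 ylab = "response (covariate-adjusted)",
                 col = grDevices::grey(0.45), pch = 16, cex = 0.6, ...)
  tl <- trend_line(x)
  graphics::lines(tl$cap, tl$value, lwd = 2)
  graphics::abline(v = p$tau, lty = 2)
  invisible(x)
}
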