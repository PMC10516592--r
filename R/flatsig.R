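#' Build a fit-ready design for one ROI
#'
#' Assigns CAP scores (unless a `cap` column is already present), constructs
#' the response ([make_response()]) and returns a data frame ready for
#' [flatsig()]: columns `response`, `cap`, `study`, `group` (factors with the
#' alphabetically first level as reference), `icv_c` (ICV mean-centred over
#' the analysis rows) and `subject_id`.
#'
#' @param records Cohort data frame (see [read_cohort()]).
#' @param roi ROI column name.
#' @param normalize_wbv Divide the response by whole-brain volume?
#' @param cap_config A [cap_config()]; ignored when `records$cap` exists.
#' @param min_obs Minimum number of scans required.
#' @return Data frame with attribute `"roi"`.
#' @export
design_response <- function(records, roi, normalize_wbv = FALSE,
                            cap_config = cap_config(), min_obs = 20) {
  if (!("cap" %in% names(records)))
    records <- assign_cap(records, cap_config, quiet = TRUE)
  if (nrow(records) < min_obs)
    stop("fewer than min_obs = ", min_obs, " observations after CAP assignment")
  d <- data.frame(
    response = make_response(records, roi, normalize_wbv),
    cap = records$cap,
    study = factor(records$study, levels = sort(unique(records$study))),
    group = factor(records$group, levels = sort(unique(records$group))),
    icv_c = records$icv - mean(records$icv),
    subject_id = records$subject_id,
    stringsAsFactors = FALSE
  )
  attr(d, "roi") <- roi
  attr(d, "normalize_wbv") <- normalize_wbv
  d
}

#' Covariate formula for a design
#'
#' `response ~ study + group + icv_c`, dropping factors with fewer than two
#' observed levels (e.g. a single-study cohort) and, optionally, the ICV term.
#'
#' @param design Output of [design_response()].
#' @param use_icv Keep the centred ICV covariate?
#' @return A formula.
#' @export
design_formula <- function(design, use_icv = TRUE) {
  rhs <- character(0)
  if (nlevels(droplevels(design$study)) > 1L) rhs <- c(rhs, "study")
  if (nlevels(droplevels(design$group)) > 1L) rhs <- c(rhs, "group")
  if (use_icv && stats::sd(design$icv_c) > 0) rhs <- c(rhs, "icv_c")
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste("response ~", paste(rhs, collapse = " + ")),
                    env = globalenv())
}

#' Fit a left-flat sigmoidal trajectory against CAP score
#'
#' Least-squares fit of
#' \deqn{y = v_0 - \delta\,S\!\big((cap-\tau)/s\big)_+ + Z\beta + \varepsilon}
#' where the formula supplies the response and the additive covariates
#' \eqn{Z} (study, group, centred ICV, ...), and the CAP score enters through
#' the left-flat sigmoid.  Estimation is by nested profiling: an outer grid on
#' the changepoint \eqn{\tau}, an inner search over the transition width
#' \eqn{s} (log-spaced grid plus a continuous golden-section refinement at the
#' selected changepoint), and innermost linear least squares in
#' \eqn{(v_0, \delta, \beta)} with \eqn{\delta \ge 0} enforced.  The optimiser
#' is deterministic: identical data give bit-identical fits.
#'
#' Nested ordinary least-squares fits with the same covariates — a linear
#' trend in CAP, and a constant (no CAP term) — are fitted alongside for model
#' comparison; see [compare_models()].
#'
#' @param formula Model formula `response ~ covariates` (covariates only; the
#'   CAP term is implicit).  Use `response ~ 1` for no covariates.
#' @param data Data frame, typically from [design_response()].
#' @param cap Name of the CAP-score column.  Default `"cap"`.
#' @param subject Name of the subject-identifier column used for block
#'   resampling at inference time; `NULL` treats every scan as its own block.
#' @param tau_grid Changepoint search grid; `NULL` for the default (multiples
#'   of `tau_step` spanning the 5th–95th CAP percentiles, plus one point at
#'   the observed minimum).
#' @param tau_step Grid spacing, CAP units.
#' @param scale_bounds Length-2 bounds for the transition width; `NULL` for
#'   the default `c(tau_step/2, 20 * CAP range)`.
#' @param n_scale Number of log-spaced width values in the inner grid.
#' @param min_obs Minimum observations.
#' @param refine_tol Tolerance of the continuous width refinement (log scale).
#' @return An object of class `"flatsig"`.
#' @seealso [compare_models()], [bootstrap_tau_sd()], [bootstrap_model_pvalue()]
#' @export
#' @examples
#' set.seed(1)
#' cap <- runif(120, 100, 600)
#' y <- left_flat_sigmoid(cap, 10, 4, 300, 50) + rnorm(120, 0, 0.2)
#' fit <- flatsig(response ~ 1, data.frame(response = y, cap = cap))
#' coef(fit)
flatsig <- function(formula, data, cap = "cap", subject = NULL,
                    tau_grid = NULL, tau_step = 5, scale_bounds = NULL,
                    n_scale = 25, min_obs = 20, refine_tol = 1e-9) {
  stopifnot(is.data.frame(data))
  if (!(cap %in% names(data))) stop("CAP column '", cap, "' not found")
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  Z <- stats::model.matrix(attr(mf, "terms"), mf)
  Z <- Z[, setdiff(colnames(Z), "(Intercept)"), drop = FALSE]
  x <- data[[cap]]
  n <- length(y)
  if (n < min_obs) stop("fewer than min_obs = ", min_obs, " observations")
  if (any(!is.finite(x))) stop("non-finite CAP values")
  subj <- if (is.null(subject)) as.character(seq_len(n)) else as.character(data[[subject]])
  engine <- make_engine(x, Z, tau_grid = tau_grid, tau_step = tau_step,
                        scale_bounds = scale_bounds, n_scale = n_scale,
                        refine_tol = refine_tol)
  fit <- engine_fit(engine, y)
  lin <- engine_linear(engine, y)
  con <- engine_constant(engine, y)
  q <- ncol(Z)
  p_sig <- q + 4; p_lin <- q + 2; p_con <- q + 1
  ab <- .aic_bic(fit$rss, n, p_sig)
  ab_lin <- .aic_bic(lin$rss, n, p_lin)
  ab_con <- .aic_bic(con$rss, n, p_con)
  structure(list(
    params = list(v0 = fit$v0, delta = fit$delta, tau = fit$tau,
                  scale = fit$scale),
    coefficients = c(v0 = fit$v0, delta = fit$delta, tau = fit$tau,
                     scale = fit$scale, fit$beta),
    covariate_coefs = fit$beta,
    rss = fit$rss, n = n, df = c(p_sig = p_sig, p_lin = p_lin, p_con = p_con),
    sigma = sqrt(fit$rss / max(n - p_sig, 1)),
    aic = ab[["aic"]], bic = ab[["bic"]],
    converged = fit$converged,
    profile = fit$profile,
    fitted.values = as.numeric(fit$fitted),
    residuals = as.numeric(fit$residuals),
    linear = list(coefficients = lin$coefficients, rss = lin$rss,
                  fitted = as.numeric(lin$fitted),
                  residuals = as.numeric(lin$residuals),
                  aic = ab_lin[["aic"]], bic = ab_lin[["bic"]]),
    constant = list(coefficients = con$coefficients, rss = con$rss,
                    aic = ab_con[["aic"]], bic = ab_con[["bic"]]),
    model = list(y = as.numeric(y), cap = x, Z = Z, subject = subj),
    engine = engine,
    terms = attr(mf, "terms"),
    roi = attr(data, "roi"),
    call = match.call()
  ), class = "flatsig")
}

#' Ordinary linear-trend fit with the same covariates
#'
#' Convenience wrapper exposing the linear reference model that [flatsig()]
#' fits alongside the sigmoid: `y ~ 1 + cap + Z` by ordinary least squares.
#'
#' @inheritParams flatsig
#' @return List with `coefficients`, `rss`, `aic`, `bic`, `n`.
#' @export
fit_linear <- function(formula, data, cap = "cap") {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  Z <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- cbind(Z, cap = data[[cap]])
  f <- stats::lm.fit(X, y)
  rss <- sum(f$residuals^2)
  n <- length(y)
  ab <- .aic_bic(rss, n, ncol(X))
  list(coefficients = f$coefficients, rss = rss, n = n,
       aic = ab[["aic"]], bic = ab[["bic"]])
}

#' Constant (no CAP trend) fit with the same covariates
#' @inheritParams flatsig
#' @return List with `coefficients`, `rss`, `aic`, `bic`, `n`.
#' @export
fit_constant <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  f <- stats::lm.fit(X, y)
  rss <- sum(f$residuals^2)
  n <- length(y)
  ab <- .aic_bic(rss, n, ncol(X))
  list(coefficients = f$coefficients, rss = rss, n = n,
       aic = ab[["aic"]], bic = ab[["bic"]])
}

#' Compare the sigmoid against its nested linear and constant models
#'
#' The three models share covariates and differ only in the CAP term: none
#' (constant), a straight line, or the left-flat sigmoid.  The improvement
#' statistic is F-like,
#' \deqn{T = \frac{(RSS_{lin} - RSS_{sig})/RSS_{sig} \times (n - p_{sig})}{p_{sig} - p_{lin}},}
#' but because the changepoint is estimated its null distribution is not F;
#' p-values come from [bootstrap_model_pvalue()].  When no bootstrap p-value
#' is supplied, preference falls back to BIC.
#'
#' @param fit A [flatsig()] fit.
#' @param p_value Optional bootstrap p-value for the sigmoid-vs-linear
#'   comparison.
#' @param alpha Significance level used with `p_value`.
#' @return Object of class `"flatsig_anova"`.
#' @export
compare_models <- function(fit, p_value = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "flatsig"))
  n <- fit$n
  p_sig <- fit$df[["p_sig"]]; p_lin <- fit$df[["p_lin"]]
  stat <- (fit$linear$rss - fit$rss) / fit$rss * (n - p_sig) / (p_sig - p_lin)
  preferred <- if (!is.null(p_value)) p_value < alpha else fit$bic < fit$linear$bic
  structure(list(
    sigmoid_rss = fit$rss, linear_rss = fit$linear$rss,
    constant_rss = fit$constant$rss,
    stat = stat, n = n, df = c(p_sig = p_sig, p_lin = p_lin),
    p_value = p_value, alpha = alpha,
    sigmoid_preferred = as.logical(preferred),
    basis = if (is.null(p_value)) "bic" else "bootstrap"
  ), class = "flatsig_anova")
}

#' @export
print.flatsig_anova <- function(x, ...) {
  cat("Model comparison (shared covariates)\n")
  cat(sprintf("  RSS: constant %.6g >= linear %.6g >= sigmoid %.6g\n",
              x$constant_rss, x$linear_rss, x$sigmoid_rss))
  cat(sprintf("  improvement statistic: %.4g\n", x$stat))
  if (!is.null(x$p_value))
    cat(sprintf("  bootstrap p-value: %.4g\n", x$p_value))
  cat(sprintf("  sigmoid preferred: %s (by %s)\n", x$sigmoid_preferred, x$basis))
  invisible(x)
}
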