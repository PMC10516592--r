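#' Bootstrap options
#'
#' Settings for the semi-parametric bootstrap: residuals are resampled around
#' a fitted parametric mean (parametric mean + nonparametric residuals).  With
#' `resample_unit = "subject"` a subject's whole residual vector moves
#' together, preserving the within-subject correlation that the point fit
#' (which pools scans) ignores.
#'
#' @param n_reps Number of bootstrap replicates.
#' @param resample_unit `"subject"` (block) or `"scan"` (i.i.d.).
#' @param seed Integer seed; identical options give bit-identical results.
#' @param alpha Significance level for the sigmoid-vs-linear decision.
#' @param null_model Null mean for the model-comparison p-value: the fitted
#'   `"linear"` model (default) or the `"constant"` model.
#' @return Object of class `"bootstrap_opts"`.
#' @export
bootstrap_opts <- function(n_reps = 999,
                           resample_unit = c("subject", "scan"),
                           seed = 1L, alpha = 0.05,
                           null_model = c("linear", "constant")) {
  resample_unit <- match.arg(resample_unit)
  null_model <- match.arg(null_model)
  stopifnot(n_reps >= 1, alpha > 0, alpha < 1)
  structure(list(n_reps = as.integer(n_reps), resample_unit = resample_unit,
                 seed = as.integer(seed), alpha = alpha,
                 null_model = null_model),
            class = "bootstrap_opts")
}

# Resample residuals in subject blocks.  Designs stay fixed: each subject
# slot receives the whole residual vector of a donor subject drawn (with
# replacement) from the subjects with the same number of scans, so vector
# lengths always match and the within-subject correlation structure of the
# residual field is preserved exactly.
.resample_residuals <- function(blocks, resid, unit) {
  if (unit == "scan")
    return(sample(resid, length(resid), replace = TRUE))
  sizes <- lengths(blocks)
  out <- numeric(length(resid))
  for (k in unique(sizes)) {
    slots <- which(sizes == k)
    donors <- slots[sample.int(length(slots), length(slots), replace = TRUE)]
    for (j in seq_along(slots)) {
      out[blocks[[slots[j]]]] <- resid[blocks[[donors[j]]]]
    }
  }
  out
}

.subject_blocks <- function(subject) {
  split(seq_along(subject), subject)
}

#' Bootstrap standard deviation of the changepoint
#'
#' Semi-parametric residual bootstrap around the fitted sigmoid mean: the
#' fitted values are kept, residual vectors are resampled in subject blocks
#' and re-attached, and the full profile fit is repeated per replicate.  The
#' changepoint SD is the sample SD of the replicate changepoint estimates.
#' Replicates whose refit lands on the changepoint-grid boundary are dropped
#' (with accounting) rather than retried, keeping the procedure deterministic.
#'
#' @param fit A converged [flatsig()] fit.
#' @param options A [bootstrap_opts()].
#' @return List: `tau_sd`, `taus` (retained replicate estimates),
#'   `n_effective`, `n_dropped`, `flagged` (TRUE when more than 20% of
#'   replicates failed to converge).
#' @export
bootstrap_tau_sd <- function(fit, options = bootstrap_opts()) {
  stopifnot(inherits(fit, "flatsig"), inherits(options, "bootstrap_opts"))
  blocks <- .subject_blocks(fit$model$subject)
  mu <- fit$fitted.values
  resid <- fit$residuals
  engine <- fit$engine
  taus <- numeric(options$n_reps)
  conv <- logical(options$n_reps)
  with_seed(options$seed, {
    for (b in seq_len(options$n_reps)) {
      ystar <- mu + .resample_residuals(blocks, resid, options$resample_unit)
      f <- engine_fit(engine, ystar)
      taus[b] <- f$tau
      conv[b] <- f$converged
    }
  })
  kept <- taus[conv]
  n_drop <- sum(!conv)
  flagged <- n_drop > 0.2 * options$n_reps
  if (flagged)
    warning(sprintf("%d of %d bootstrap replicates non-converged (> 20%%)",
                    n_drop, options$n_reps))
  tau_sd <- if (length(kept) >= 2L) stats::sd(kept) else 0
  list(tau_sd = tau_sd, taus = kept, n_effective = length(kept),
       n_dropped = n_drop, flagged = flagged)
}

#' Bootstrap p-value for sigmoid over linear
#'
#' Null datasets are generated from the fitted null model (linear by default):
#' its fitted values plus subject-block resampled null-model residuals.  Both
#' models are refitted on every null dataset and the observed improvement
#' statistic is compared against its null distribution with the add-one
#' convention, \eqn{p = (\#\{T^*_b \ge T\} + 1)/(B + 1)}, so p is never 0 and
#' never exceeds 1.
#'
#' @inheritParams bootstrap_tau_sd
#' @return List: `p_value`, `stat_observed`, `stats_null`, `n_reps`.
#' @export
bootstrap_model_pvalue <- function(fit, options = bootstrap_opts()) {
  stopifnot(inherits(fit, "flatsig"), inherits(options, "bootstrap_opts"))
  engine <- fit$engine
  blocks <- .subject_blocks(fit$model$subject)
  n <- fit$n
  p_sig <- fit$df[["p_sig"]]; p_lin <- fit$df[["p_lin"]]
  stat_of <- function(rss_sig, rss_lin)
    (rss_lin - rss_sig) / rss_sig * (n - p_sig) / (p_sig - p_lin)
  stat_obs <- stat_of(fit$rss, fit$linear$rss)
  if (options$null_model == "linear") {
    null_fitted <- fit$linear$fitted
    null_resid <- fit$linear$residuals
  } else {
    con <- engine_constant(engine, fit$model$y)
    null_fitted <- as.numeric(con$fitted)
    null_resid <- as.numeric(con$residuals)
  }
  stats_null <- numeric(options$n_reps)
  with_seed(options$seed, {
    for (b in seq_len(options$n_reps)) {
      ystar <- null_fitted + .resample_residuals(blocks, null_resid,
                                                 options$resample_unit)
      fs <- engine_fit(engine, ystar)
      fl <- engine_linear(engine, ystar)
      stats_null[b] <- stat_of(fs$rss, fl$rss)
    }
  })
  p <- (sum(stats_null >= stat_obs) + 1) / (options$n_reps + 1)
  list(p_value = p, stat_observed = stat_obs, stats_null = stats_null,
       n_reps = options$n_reps)
}

#' Changepoint inference for one fitted ROI
#'
#' Runs [bootstrap_tau_sd()] and [bootstrap_model_pvalue()] on a fit and
#' returns a one-row changepoint record.  The two bootstraps use decoupled
#' seed streams derived from `options$seed`.
#'
#' @param fit A [flatsig()] fit.
#' @param options A [bootstrap_opts()].
#' @param roi ROI label; defaults to the label carried by the fit.
#' @return One-row data frame: `roi`, `tau_hat`, `tau_sd`, `p_value`,
#'   `n_effective_reps`, `sigmoid_preferred`.
#' @export
changepoint <- function(fit, options = bootstrap_opts(), roi = NULL) {
  roi <- roi %||% (fit$roi %||% "response")
  opts_sd <- options
  opts_sd$seed <- options$seed
  opts_p <- options
  opts_p$seed <- options$seed + 10007L
  bs <- bootstrap_tau_sd(fit, opts_sd)
  bp <- bootstrap_model_pvalue(fit, opts_p)
  data.frame(roi = roi,
             tau_hat = fit$params$tau,
             tau_sd = bs$tau_sd,
             p_value = bp$p_value,
             n_effective_reps = bs$n_effective,
             sigmoid_preferred = bp$p_value < options$alpha,
             stringsAsFactors = FALSE)
}

#' Ranked changepoint table
#'
#' Keeps only ROIs where the sigmoid beat the linear model, sorted by
#' ascending changepoint (ties: smaller SD, then name) — earliest-affected
#' regions first.
#'
#' @param results Data frame of [changepoint()] rows (one per ROI).
#' @param adjust_p Apply Benjamini-Hochberg correction across ROIs before
#'   filtering?  Off by default (per-ROI reporting).
#' @param alpha Significance level used when `adjust_p = TRUE`.
#' @return Filtered, sorted data frame.
#' @export
changepoint_table <- function(results, adjust_p = FALSE, alpha = 0.05) {
  stopifnot(is.data.frame(results))
  if (anyDuplicated(results$roi)) stop("one row per ROI expected")
  if (adjust_p) {
    results$p_adjusted <- stats::p.adjust(results$p_value, method = "BH")
    results$sigmoid_preferred <- results$p_adjusted < alpha
  }
  out <- results[results$sigmoid_preferred, , drop = FALSE]
  out <- out[order(out$tau_hat, out$tau_sd, out$roi), , drop = FALSE]
  rownames(out) <- NULL
  out
}
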