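#' Analysis run configuration
#'
#' Bundles and validates everything an end-to-end run needs.  The resolved
#' configuration is serialized into every output directory so a run can be
#' reproduced exactly.
#'
#' @param rois ROI names to analyse.
#' @param normalize Logical vector of response types to run: `FALSE` for raw
#'   volume (ICV as covariate), `TRUE` for whole-brain-normalized.
#' @param cap A [cap_config()].
#' @param bootstrap A [bootstrap_opts()], or `NULL` to skip bootstrap
#'   inference (model preference then falls back to BIC).
#' @param use_icv Keep ICV as a covariate (also in the normalized analysis)?
#' @param tau_step,min_obs Passed to [flatsig()].
#' @param exclusions Rule list for [apply_exclusions()].
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(rois = roi_catalog(),
                       normalize = c(FALSE, TRUE),
                       cap = cap_config(),
                       bootstrap = bootstrap_opts(),
                       use_icv = TRUE,
                       tau_step = 5,
                       min_obs = 20,
                       exclusions = list(qc = TRUE)) {
  stopifnot(is.character(rois), length(rois) >= 1,
            is.logical(normalize), inherits(cap, "cap_config"))
  if (!is.null(bootstrap)) stopifnot(inherits(bootstrap, "bootstrap_opts"))
  structure(list(rois = rois, normalize = normalize, cap = cap,
                 bootstrap = bootstrap, use_icv = use_icv,
                 tau_step = tau_step, min_obs = min_obs,
                 exclusions = exclusions),
            class = "run_config")
}

.config_as_list <- function(x) {
  if (is.list(x)) lapply(unclass(x), .config_as_list) else x
}

#' Simulate a cohort and write it to disk
#'
#' Writes the cohort CSV plus a JSON provenance file holding the full
#' scenario.  Identical scenarios (including seed) give byte-identical CSVs.
#'
#' @param scenario A [cohort_scenario()].
#' @param out_csv Output CSV path.
#' @return The cohort data frame, invisibly.
#' @export
run_simulate <- function(scenario, out_csv) {
  cohort <- generate_cohort(scenario)
  write_cohort(cohort, out_csv)
  prov <- scenario
  prov$roi_truths <- lapply(prov$roi_truths, unlist)
  jsonlite::write_json(unclass(prov),
                       paste0(sub("\\.csv$", "", out_csv), "_scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' End-to-end changepoint analysis of a cohort
#'
#' For every requested ROI and response type (raw and/or whole-brain
#' normalized): applies exclusions, assigns CAP scores, fits the left-flat
#' sigmoid plus its nested linear and constant models, optionally runs the
#' bootstrap changepoint inference, and assembles the ranked changepoint
#' table, trend-line curves on a CAP grid, and a per-scan spaghetti export
#' for external plotting.
#'
#' @param cohort Cohort data frame or a CSV path readable by [read_cohort()].
#' @param config A [run_config()].
#' @param outdir Optional output directory; when given, writes
#'   `changepoints.csv`, `trend_lines.csv`, `spaghetti.csv`, `fits.json`,
#'   `exclusions.json` and `config.json`.
#' @return List: `fits` (named list of [flatsig()] objects),
#'   `comparisons`, `results` (all per-ROI rows), `table` (ranked, preferred
#'   only), `trend_lines`, `spaghetti`, `exclusions`.
#' @export
run_fit <- function(cohort, config = run_config(), outdir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  ex <- apply_exclusions(cohort, config$exclusions)
  kept <- assign_cap(ex$kept, config$cap, quiet = TRUE)
  fits <- list(); comps <- list(); rows <- list()
  trends <- list(); spag <- list()
  for (nw in config$normalize) {
    tag <- if (nw) "normalized" else "raw"
    for (roi in config$rois) {
      key <- paste(roi, tag, sep = ".")
      d <- design_response(kept, roi, normalize_wbv = nw,
                           min_obs = config$min_obs)
      fml <- design_formula(d, use_icv = config$use_icv)
      fit <- flatsig(fml, d, subject = "subject_id",
                     tau_step = config$tau_step, min_obs = config$min_obs)
      fit$roi <- roi
      if (!is.null(config$bootstrap)) {
        row <- changepoint(fit, config$bootstrap, roi = roi)
        cmp <- compare_models(fit, p_value = row$p_value,
                              alpha = config$bootstrap$alpha)
      } else {
        cmp <- compare_models(fit)
        row <- data.frame(roi = roi, tau_hat = fit$params$tau,
                          tau_sd = NA_real_, p_value = NA_real_,
                          n_effective_reps = 0L,
                          sigmoid_preferred = cmp$sigmoid_preferred,
                          stringsAsFactors = FALSE)
      }
      row$response <- tag
      row$converged <- fit$converged
      fits[[key]] <- fit
      comps[[key]] <- cmp
      rows[[key]] <- row
      tl <- trend_line(fit)
      tl$roi <- roi; tl$response <- tag
      trends[[key]] <- tl
      spag[[key]] <- data.frame(roi = roi, response = tag,
                                subject_id = d$subject_id,
                                study = as.character(d$study),
                                group = as.character(d$group),
                                cap = d$cap, value = d$response,
                                stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, c(rows, make.row.names = FALSE))
  tables <- lapply(split(results, results$response), changepoint_table)
  out <- list(fits = fits, comparisons = comps, results = results,
              table = tables, trend_lines = do.call(rbind, trends),
              spaghetti = do.call(rbind, spag), exclusions = ex$counts)
  if (!is.null(outdir)) .write_run_outputs(out, config, outdir)
  out
}

.write_run_outputs <- function(out, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$results, file.path(outdir, "changepoints.csv"),
                   row.names = FALSE)
  utils::write.csv(out$trend_lines, file.path(outdir, "trend_lines.csv"),
                   row.names = FALSE)
  utils::write.csv(out$spaghetti, file.path(outdir, "spaghetti.csv"),
                   row.names = FALSE)
  fit_json <- lapply(out$fits, function(f)
    list(params = f$params, covariate_coefs = as.list(f$covariate_coefs),
         rss = f$rss, n = f$n, aic = f$aic, bic = f$bic,
         converged = f$converged, profile = f$profile))
  jsonlite::write_json(fit_json, file.path(outdir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(out$exclusions),
                       file.path(outdir, "exclusions.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(.config_as_list(config),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Compare CAP-assignment variants side by side
#'
#' Re-runs the fit stage under the three control-handling schemes
#' (multiplier, CAP = age, carriers only) for raw and/or normalized
#' responses, and reports the changepoint estimate and model preference per
#' variant plus the Spearman rank correlation of the changepoint orderings
#' across variants — the robustness check that the overall pattern should not
#' depend on how controls are placed on the CAP axis.
#'
#' @param cohort Cohort data frame or CSV path.
#' @param config A [run_config()]; its `cap` entry supplies the multiplier
#'   and age filter, and `bootstrap = NULL` is typical here (BIC preference).
#' @param normalize Response types to include.
#' @return List: `table` (one row per ROI x response, tau/preference columns
#'   per scheme), `spearman` (correlation matrix of changepoint orderings).
#' @export
run_compare_variants <- function(cohort, config = run_config(bootstrap = NULL),
                                 normalize = config$normalize) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  schemes <- c("multiplier", "age_identity", "exclude")
  per <- list()
  for (sch in schemes) {
    cfg <- config
    cfg$cap <- cap_config(threshold_L = config$cap$threshold_L,
                          control_scheme = sch,
                          control_multiplier = config$cap$control_multiplier,
                          control_age_cap = config$cap$control_age_cap)
    cfg$normalize <- normalize
    res <- run_fit(cohort, cfg)$results
    res <- res[, c("roi", "response", "tau_hat", "sigmoid_preferred")]
    names(res)[3:4] <- paste(c("tau", "preferred"), sch, sep = "_")
    per[[sch]] <- res
  }
  tab <- Reduce(function(a, b) merge(a, b, by = c("roi", "response")), per)
  tau_cols <- paste0("tau_", schemes)
  rho <- stats::cor(tab[tau_cols], method = "spearman")
  list(table = tab, spearman = rho)
}
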