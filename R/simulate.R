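# Synthetic multi-study longitudinal cohort generator.  The generator inverts
# the analysis model: each ROI volume is a left-flat sigmoid in CAP plus
# additive study/group/ICV effects and Gaussian noise, observed over 1-5
# roughly annual visits per subject across three study arms with batch
# offsets.  It exists so every analysis stage is testable without access to
# the restricted imaging tables.

# truncated normal via inverse-CDF, vectorised
.rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Default per-ROI trajectory truths (synthetic)
#'
#' Synthetic ground-truth parameters for the default scenario: basal ganglia
#' structures get earlier changepoints and larger fractional drops than
#' cortical grey/white regions, and hippocampus/cerebellum get late, shallow
#' declines.  Baseline volumes are order-of-magnitude realistic (mm^3).
#' These are package fixtures for simulation, not estimates from any study.
#'
#' @return Named list of `list(v0, delta, tau, scale)` per ROI.
#' @export
default_roi_truths <- function() {
  t1 <- function(v0, dfrac, tau, scale)
    list(v0 = v0, delta = dfrac * v0, tau = tau, scale = scale)
  list(
    putamen           = t1(8000,  0.45, 250, 70),
    caudate           = t1(7000,  0.40, 260, 70),
    globus_pallidus   = t1(2600,  0.40, 300, 70),
    nucleus_accumbens = t1(1000,  0.35, 310, 75),
    substantia_nigra  = t1(600,   0.30, 320, 80),
    PrCWM             = t1(12000, 0.20, 330, 80),
    thalamus          = t1(12000, 0.18, 380, 90),
    PrCG              = t1(14000, 0.14, 400, 90),
    SFG               = t1(30000, 0.12, 410, 90),
    SFWM              = t1(20000, 0.15, 405, 90),
    SPG               = t1(14000, 0.12, 420, 95),
    SPWM              = t1(10000, 0.14, 415, 95),
    SOG               = t1(8000,  0.10, 440, 100),
    SOWM              = t1(6000,  0.12, 435, 100),
    STG               = t1(18000, 0.12, 425, 95),
    STWM              = t1(10000, 0.13, 430, 95),
    hippocampus       = t1(7500,  0.08, 450, 110),
    cerebellum        = t1(130000, 0.07, 450, 110)
  )
}

#' Cohort generation scenario
#'
#' Generative parameters for a synthetic multi-study cohort.  Defaults mirror
#' the merged three-study table this analysis targets: 178 controls and 357
#' carriers; study mix ~12/36/52%; control CAG 15-31 (mean 20.4, sd 3.5);
#' carrier CAG 38-55 (mean 42.7, sd 2.4); enrollment ages 18-72 with carrier
#' age pulled down for longer repeats (so CAP stays in the observed 150-630
#' range); 1-5 visits about a year apart with 0.85 per-visit retention;
#' study-level batch offsets and an ICV (head-size) effect on every volume;
#' whole-brain volume declining by its own sigmoid so normalized analyses
#' have non-trivial structure; homoscedastic Gaussian noise per ROI
#' (fraction of the baseline level); a small artefact rate flagged
#' `qc_pass = FALSE`.
#'
#' @param n_control,n_carrier Subjects per arm.
#' @param study_weights Sampling weights for studies A/B/C (sum to 1).
#' @param cag_range_control,cag_range_carrier Integer CAG ranges.
#' @param cag_mean_control,cag_sd_control,cag_mean_carrier,cag_sd_carrier
#'   Moments of the (truncated) CAG distributions.
#' @param age_range Enrollment age range, years.
#' @param age_mean_control,age_sd_control,age_mean_carrier,age_sd_carrier
#'   Moments of the (truncated) enrollment-age distributions.
#' @param age_cag_slope Years of mean enrollment age per CAG unit above the
#'   carrier mean (negative: long repeats enroll younger).
#' @param max_visits,visit_gap,visit_gap_jitter,retention Longitudinal design:
#'   visit cap, mean inter-visit gap (years), gap jitter, per-visit retention.
#' @param icv_mean,icv_sd Intracranial volume distribution, mm^3.
#' @param wbv_frac Baseline whole-brain / ICV fraction.
#' @param wbv_truth Whole-brain decline truth:
#'   `list(delta_frac, tau, scale)` on the fraction scale.
#' @param study_offset_frac,group_offset_frac Additive batch/group offsets as
#'   fractions of each ROI's baseline level (reference levels 0).
#' @param icv_slope_frac ICV effect: an ICV one mean above average raises each
#'   volume by this fraction of its baseline.
#' @param roi_truths Per-ROI trajectory truths; see [default_roi_truths()].
#' @param noise_sd_fraction Noise SD as a fraction of each ROI's baseline.
#' @param noise Noise family: `"gaussian"` or heavier-tailed `"t5"` for
#'   robustness experiments.
#' @param artefact_rate Fraction of scans flagged `qc_pass = FALSE`.
#' @param manifest_cap Baseline CAP above which a carrier is labelled
#'   manifest.
#' @param threshold_L CAP threshold constant used by the generator.
#' @param seed Integer seed; generation is fully reproducible.
#' @return Object of class `"cohort_scenario"`.
#' @export
cohort_scenario <- function(n_control = 178, n_carrier = 357,
                            study_weights = c(A = 0.12, B = 0.36, C = 0.52),
                            cag_range_control = c(15, 31),
                            cag_range_carrier = c(38, 55),
                            cag_mean_control = 20.4, cag_sd_control = 3.5,
                            cag_mean_carrier = 42.7, cag_sd_carrier = 2.4,
                            age_range = c(18, 72),
                            age_mean_control = 45.2, age_sd_control = 11.0,
                            age_mean_carrier = 43.6, age_sd_carrier = 11.3,
                            age_cag_slope = -2.5,
                            max_visits = 5, visit_gap = 1,
                            visit_gap_jitter = 0.15, retention = 0.85,
                            icv_mean = 1.5e6, icv_sd = 1.3e5,
                            wbv_frac = 0.80,
                            wbv_truth = list(delta_frac = 0.10, tau = 250,
                                             scale = 120),
                            study_offset_frac = c(A = 0, B = 0.02, C = -0.02),
                            group_offset_frac = c(control = 0,
                                                  premanifest = 0,
                                                  manifest = -0.01),
                            icv_slope_frac = 0.3,
                            roi_truths = default_roi_truths(),
                            noise_sd_fraction = 0.03,
                            noise = c("gaussian", "t5"),
                            artefact_rate = 0.02,
                            manifest_cap = 400,
                            threshold_L = 33.66,
                            seed = 1L) {
  sc <- list(n_control = n_control, n_carrier = n_carrier,
             study_weights = study_weights,
             cag_range_control = cag_range_control,
             cag_range_carrier = cag_range_carrier,
             cag_mean_control = cag_mean_control, cag_sd_control = cag_sd_control,
             cag_mean_carrier = cag_mean_carrier, cag_sd_carrier = cag_sd_carrier,
             age_range = age_range,
             age_mean_control = age_mean_control, age_sd_control = age_sd_control,
             age_mean_carrier = age_mean_carrier, age_sd_carrier = age_sd_carrier,
             age_cag_slope = age_cag_slope,
             max_visits = max_visits, visit_gap = visit_gap,
             visit_gap_jitter = visit_gap_jitter, retention = retention,
             icv_mean = icv_mean, icv_sd = icv_sd,
             wbv_frac = wbv_frac, wbv_truth = wbv_truth,
             study_offset_frac = study_offset_frac,
             group_offset_frac = group_offset_frac,
             icv_slope_frac = icv_slope_frac,
             roi_truths = roi_truths,
             noise_sd_fraction = noise_sd_fraction,
             noise = match.arg(noise),
             artefact_rate = artefact_rate,
             manifest_cap = manifest_cap,
             threshold_L = threshold_L,
             seed = as.integer(seed))
  validate_scenario(structure(sc, class = "cohort_scenario"))
}

#' Validate a cohort scenario
#' @param scenario A [cohort_scenario()].
#' @return The scenario, invisibly classed, or an error.
#' @export
validate_scenario <- function(scenario) {
  s <- scenario
  stopifnot(s$n_control >= 0, s$n_carrier >= 0,
            s$n_control + s$n_carrier > 0)
  if (abs(sum(s$study_weights) - 1) > 1e-8)
    stop("study_weights must sum to 1")
  ordered2 <- function(r) length(r) == 2 && r[1] < r[2]
  if (!ordered2(s$cag_range_control) || !ordered2(s$cag_range_carrier) ||
      !ordered2(s$age_range))
    stop("infeasible range(s): must be ordered pairs")
  stopifnot(s$noise_sd_fraction >= 0, s$artefact_rate >= 0, s$artefact_rate <= 1,
            s$retention > 0, s$retention <= 1, s$max_visits >= 1,
            s$icv_mean > 0, s$icv_sd >= 0,
            s$wbv_frac > 0, s$wbv_frac < 1,
            s$threshold_L > 0)
  for (nm in names(s$roi_truths)) {
    t <- s$roi_truths[[nm]]
    if (t$v0 <= 0 || t$delta < 0 || t$delta >= t$v0 || t$scale <= 0)
      stop("infeasible trajectory truth for ROI ", nm)
  }
  invisible(scenario)
}

#' Default Huntington's-disease-like scenario
#'
#' [cohort_scenario()] with its defaults: the basal ganglia circuit declining
#' early and steeply, cortical regions later and shallower, hippocampus and
#' cerebellum nearly spared.  Arguments override individual defaults.
#'
#' @param ... Overrides passed to [cohort_scenario()].
#' @return A `"cohort_scenario"`.
#' @export
default_hd_scenario <- function(...) cohort_scenario(...)

#' Generate a synthetic cohort
#'
#' Draws subjects (study, group, CAG, enrollment age, ICV), advances them
#' through visits, and emits one scan row per visit with whole-brain and ROI
#' volumes generated from the scenario's trajectory truths.  Carriers' CAP
#' used for generation is `age * (CAG - L)` at each scan; controls are
#' generated on the flat limb (their volumes do not decline).  The output has
#' no `cap` column: CAP assignment, including the control scheme and under-40
#' filter, is analysis-time work for [assign_cap()].
#'
#' @param scenario A [cohort_scenario()].
#' @return Cohort data frame (one row per scan) satisfying the scan-record
#'   invariants.
#' @export
generate_cohort <- function(scenario) {
  s <- validate_scenario(scenario)
  with_seed(s$seed, {
    n <- s$n_control + s$n_carrier
    carrier <- rep(c(FALSE, TRUE), c(s$n_control, s$n_carrier))
    study <- sample(names(s$study_weights), n, replace = TRUE,
                    prob = s$study_weights)
    cag <- numeric(n)
    if (s$n_control > 0)
      cag[!carrier] <- round(.rtnorm(s$n_control, s$cag_mean_control,
                                     s$cag_sd_control,
                                     s$cag_range_control[1] - 0.49,
                                     s$cag_range_control[2] + 0.49))
    if (s$n_carrier > 0)
      cag[carrier] <- round(.rtnorm(s$n_carrier, s$cag_mean_carrier,
                                    s$cag_sd_carrier,
                                    s$cag_range_carrier[1] - 0.49,
                                    s$cag_range_carrier[2] + 0.49))
    cag <- pmin(pmax(cag, ifelse(carrier, s$cag_range_carrier[1],
                                 s$cag_range_control[1])),
                ifelse(carrier, s$cag_range_carrier[2], s$cag_range_control[2]))
    age0 <- numeric(n)
    if (s$n_control > 0)
      age0[!carrier] <- .rtnorm(s$n_control, s$age_mean_control,
                                s$age_sd_control, s$age_range[1], s$age_range[2])
    if (s$n_carrier > 0) {
      mu_age <- s$age_mean_carrier +
        s$age_cag_slope * (cag[carrier] - s$cag_mean_carrier)
      age0[carrier] <- .rtnorm(s$n_carrier, mu_age, s$age_sd_carrier,
                               s$age_range[1], s$age_range[2])
    }
    icv <- stats::rnorm(n, s$icv_mean, s$icv_sd)
    # visit counts: sequential per-visit retention, capped
    nv <- rep(1L, n)
    if (s$max_visits > 1L) {
      for (v in 2:s$max_visits) {
        stay <- stats::runif(n) < s$retention
        nv <- nv + as.integer(stay & nv == (v - 1L))
      }
    }
    rows_subj <- rep(seq_len(n), nv)
    visit <- unlist(lapply(nv, function(k) seq_len(k) - 1L), use.names = FALSE)
    gaps <- s$visit_gap +
      stats::runif(length(visit), -s$visit_gap_jitter, s$visit_gap_jitter)
    gaps[visit == 0L] <- 0
    age <- age0[rows_subj] + unlist(lapply(split(gaps, rows_subj), cumsum),
                                    use.names = FALSE)
    m <- length(rows_subj)
    carrier_scan <- carrier[rows_subj]
    cap_gen <- ifelse(carrier_scan,
                      age * (cag[rows_subj] - s$threshold_L), 0)
    # group label from baseline CAP
    cap0 <- ifelse(carrier, age0 * (cag - s$threshold_L), 0)
    group_subj <- ifelse(!carrier, "control",
                         ifelse(cap0 > s$manifest_cap, "manifest",
                                "premanifest"))
    group <- group_subj[rows_subj]
    icv_scan <- icv[rows_subj]
    rnoise <- function(m, sd) {
      if (sd == 0) return(numeric(m))
      if (s$noise == "gaussian") stats::rnorm(m, 0, sd)
      else stats::rt(m, df = 5) * sd / sqrt(5 / 3)
    }
    wt <- s$wbv_truth
    wb_frac <- s$wbv_frac *
      (1 - wt$delta_frac * half_logistic_ramp(cap_gen, wt$tau, wt$scale))
    whole_brain <- icv_scan * wb_frac +
      rnoise(m, s$noise_sd_fraction * 0.3 * s$wbv_frac * s$icv_mean)
    df <- data.frame(
      subject_id = sprintf("S%04d", rows_subj),
      study = study[rows_subj],
      group = group,
      visit_index = visit,
      age = age,
      cag = ifelse(carrier_scan, cag[rows_subj], NA_real_),
      icv = icv_scan,
      whole_brain = whole_brain,
      stringsAsFactors = FALSE
    )
    so <- s$study_offset_frac[df$study]
    go <- s$group_offset_frac[df$group]
    for (nm in names(s$roi_truths)) {
      t <- s$roi_truths[[nm]]
      mu <- left_flat_sigmoid(cap_gen, t$v0, t$delta, t$tau, t$scale) +
        (so + go) * t$v0 +
        s$icv_slope_frac * (t$v0 / s$icv_mean) * (icv_scan - s$icv_mean)
      df[[nm]] <- pmax(mu + rnoise(m, s$noise_sd_fraction * t$v0), 1)
    }
    # clinical passthrough scores (not modelled, carried as columns)
    df$TMS <- pmax(0, round(0.08 * pmax(cap_gen - 300, 0) +
                              rnoise(m, 2)))
    df$SDMT <- pmax(5, round(54 - 0.04 * pmax(cap_gen - 250, 0) +
                               rnoise(m, 5)))
    df$TFC <- pmin(13, pmax(0, round(13 - 0.012 * pmax(cap_gen - 350, 0) +
                                       rnoise(m, 0.4))))
    df$BDI <- pmax(0, round(5 + rnoise(m, 4)))
    df$qc_pass <- stats::runif(m) >= s$artefact_rate
    df
  })
}
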