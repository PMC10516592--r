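#' CAP score configuration
#'
#' The CAG-Age Product (CAP) score, \eqn{Age \times (CAG - L)}, places
#' mutation carriers with different repeat lengths on a common disease-burden
#' axis.  Controls carry no expansion, so they receive a surrogate CAP under
#' one of two schemes: a fixed multiple of age (\code{"multiplier"}), chosen so
#' that the control CAP distribution overlaps the low end of the carrier
#' range, or the age itself (\code{"age_identity"}).  A third scheme,
#' \code{"exclude"}, drops controls entirely for carriers-only analyses.
#'
#' Controls are admitted only below \code{control_age_cap} years (default 40):
#' young controls stand in for carriers very far from onset, whose regional
#' volumes are essentially indistinguishable from normal.  Set
#' \code{control_age_cap = Inf} to disable the filter.
#'
#' @param threshold_L Repeat-length threshold constant \eqn{L} in the CAP
#'   formula, in CAG units.  Default 33.66.
#' @param control_scheme How controls receive a surrogate CAP:
#'   \code{"multiplier"} (age times \code{control_multiplier}),
#'   \code{"age_identity"} (CAP = age), or \code{"exclude"} (controls
#'   dropped).
#' @param control_multiplier Dimensionless multiplier for the
#'   \code{"multiplier"} scheme.  Default 5.6, which places the mean control
#'   CAP near the low-to-middle carrier range at typical control ages.
#' @param control_age_cap Maximum control age (years) admitted to analysis.
#' @param include_controls Logical; \code{FALSE} is equivalent to
#'   \code{control_scheme = "exclude"}.
#'
#' @return An object of class \code{"cap_config"}: a validated list of the
#'   above fields.
#' @seealso [cap_for_carrier()], [cap_for_control()], [assign_cap()]
#' @export
#' @examples
#' cfg <- cap_config()
#' cap_for_carrier(50, 43.66, cfg)   # 500
cap_config <- function(threshold_L = 33.66,
                       control_scheme = c("multiplier", "age_identity", "exclude"),
                       control_multiplier = 5.6,
                       control_age_cap = 40,
                       include_controls = TRUE) {
  control_scheme <- match.arg(control_scheme)
  if (!isTRUE(include_controls)) control_scheme <- "exclude"
  stopifnot(is.numeric(threshold_L), length(threshold_L) == 1L, threshold_L > 0)
  if (control_scheme == "multiplier" &&
      (!is.numeric(control_multiplier) || control_multiplier <= 0)) {
    stop("'control_multiplier' must be > 0 under the multiplier scheme")
  }
  stopifnot(is.numeric(control_age_cap), control_age_cap > 0)
  structure(
    list(threshold_L = threshold_L,
         control_scheme = control_scheme,
         control_multiplier = control_multiplier,
         control_age_cap = control_age_cap,
         include_controls = control_scheme != "exclude"),
    class = "cap_config"
  )
}

#' @export
print.cap_config <- function(x, ...) {
  cat("CAP configuration\n")
  cat(sprintf("  CAP = Age x (CAG - %.4g)\n", x$threshold_L))
  cat(sprintf("  control scheme: %s", x$control_scheme))
  if (x$control_scheme == "multiplier")
    cat(sprintf(" (CAP = %.4g x Age)", x$control_multiplier))
  if (x$control_scheme == "age_identity") cat(" (CAP = Age)")
  cat("\n")
  if (x$include_controls)
    cat(sprintf("  controls admitted below age %.4g\n", x$control_age_cap))
  else
    cat("  controls excluded (carriers only)\n")
  invisible(x)
}

# expansion threshold below which a CAG length is not treated as a carrier
.CAG_EXPANSION_MIN <- 36

#' CAP score for a mutation carrier
#'
#' Computes \eqn{CAP = Age \times (CAG - L)}.  Vectorised over `age` and
#' `cag`.
#'
#' @param age Age at scan, years; must be positive.
#' @param cag CAG repeat length; must be in the expansion range (>= 36).
#'   Route shorter repeats through [cap_for_control()].
#' @param config A [cap_config()].
#' @param subject_id Optional identifiers used in error messages.
#' @return Numeric CAP scores.
#' @export
cap_for_carrier <- function(age, cag, config = cap_config(), subject_id = NULL) {
  stopifnot(inherits(config, "cap_config"))
  if (any(!is.finite(age)) || any(age <= 0))
    stop("invalid input: 'age' must be positive and finite")
  bad <- !is.finite(cag) | cag < .CAG_EXPANSION_MIN
  if (any(bad)) {
    who <- if (is.null(subject_id)) paste0("position ", which(bad)) else subject_id[bad]
    stop("CAG below the expansion range (< ", .CAG_EXPANSION_MIN,
         ") for: ", paste(unique(who), collapse = ", "),
         "; route non-carriers through cap_for_control()")
  }
  age * (cag - config$threshold_L)
}

#' Surrogate CAP score for a control
#'
#' Under `control_scheme = "age_identity"` the CAP is the age itself; under
#' `"multiplier"` it is `age * control_multiplier`.  Vectorised over `age`.
#'
#' @inheritParams cap_for_carrier
#' @return Numeric surrogate CAP scores.
#' @export
cap_for_control <- function(age, config = cap_config()) {
  stopifnot(inherits(config, "cap_config"))
  if (any(!is.finite(age)) || any(age <= 0))
    stop("invalid input: 'age' must be positive and finite")
  switch(config$control_scheme,
         age_identity = age,
         multiplier   = age * config$control_multiplier,
         exclude      = stop("control_scheme is 'exclude'; controls carry no CAP"))
}

#' Assign CAP scores to a cohort table
#'
#' Fills the `cap` column of a per-scan cohort table (see [read_cohort()]):
#' carriers get \eqn{Age \times (CAG - L)}, controls get their surrogate CAP,
#' and controls at or above `control_age_cap` (or all controls, under the
#' `"exclude"` scheme) are dropped.  A carrier is any row with
#' `group != "control"`.
#'
#' @param records Data frame with at least `subject_id`, `group`, `age`, and
#'   `cag` (for carriers).
#' @param config A [cap_config()].
#' @param quiet Suppress the record-count message.
#' @return The retained rows with a finite `cap` column, attribute
#'   `"n_dropped"` holding the number of rows removed.
#' @export
assign_cap <- function(records, config = cap_config(), quiet = FALSE) {
  stopifnot(is.data.frame(records), inherits(config, "cap_config"))
  needed <- c("subject_id", "group", "age")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  n0 <- nrow(records)
  if (n0 == 0L) {
    records$cap <- numeric(0)
    attr(records, "n_dropped") <- 0L
    return(records)
  }
  is_control <- records$group == "control"
  if (any(!is_control)) {
    if (!("cag" %in% names(records)) || anyNA(records$cag[!is_control])) {
      bad <- if ("cag" %in% names(records)) {
        unique(records$subject_id[!is_control & is.na(records$cag)])
      } else unique(records$subject_id[!is_control])
      stop("carrier(s) with missing CAG: ", paste(bad, collapse = ", "))
    }
  }
  keep <- rep(TRUE, n0)
  if (config$control_scheme == "exclude") {
    keep[is_control] <- FALSE
  } else if (is.finite(config$control_age_cap)) {
    keep[is_control & records$age >= config$control_age_cap] <- FALSE
  }
  out <- records[keep, , drop = FALSE]
  ic <- is_control[keep]
  cap <- numeric(nrow(out))
  if (any(!ic))
    cap[!ic] <- cap_for_carrier(out$age[!ic], out$cag[!ic], config,
                                subject_id = out$subject_id[!ic])
  if (any(ic)) cap[ic] <- cap_for_control(out$age[ic], config)
  out$cap <- cap
  attr(out, "n_dropped") <- n0 - nrow(out)
  if (!quiet)
    message(sprintf("assign_cap: %d of %d records retained (%d dropped)",
                    nrow(out), n0, n0 - nrow(out)))
  out
}
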