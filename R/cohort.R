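#' Region-of-interest catalogue
#'
#' The default analysis set: the basal ganglia circuit (putamen, caudate,
#' globus pallidus, nucleus accumbens, substantia nigra), the thalamus, five
#' cortical gyri with the white matter beneath them, and two commonly used
#' comparison regions (hippocampus, cerebellum).  Bilateral structures are
#' represented by a single column (left + right summed at read time).
#'
#' @param extra Additional ROI names to append.
#' @return Character vector of ROI column names.
#' @export
roi_catalog <- function(extra = character()) {
  base <- c("putamen", "caudate", "globus_pallidus", "nucleus_accumbens",
            "substantia_nigra", "thalamus",
            "PrCG", "PrCWM", "SFG", "SFWM", "SPG", "SPWM",
            "SOG", "SOWM", "STG", "STWM",
            "hippocampus", "cerebellum")
  unique(c(base, extra))
}

#' ROIs forming the basal ganglia circuit
#' @return Character vector.
#' @export
basal_ganglia_rois <- function() {
  c("putamen", "caudate", "globus_pallidus", "nucleus_accumbens",
    "substantia_nigra")
}

.mandatory_cols <- c("subject_id", "study", "group", "visit_index", "age",
                     "icv", "whole_brain")
.clinical_cols <- c("TMS", "SDMT", "TFC", "BDI")

# sum columns written as <roi>_left/<roi>_right into a single <roi> column
.merge_hemispheres <- function(df) {
  lefts <- grep("_left$", names(df), value = TRUE)
  for (lc in lefts) {
    roi <- sub("_left$", "", lc)
    rc <- paste0(roi, "_right")
    if (rc %in% names(df)) {
      df[[roi]] <- df[[lc]] + df[[rc]]
      df[[lc]] <- NULL
      df[[rc]] <- NULL
    }
  }
  df
}

#' Read a per-scan cohort table
#'
#' One row per scan.  Mandatory columns: `subject_id`, `study`, `group`,
#' `visit_index`, `age`, `icv`, `whole_brain`; plus `cag` (may be empty for
#' controls), optional `qc_pass`, optional clinical scores (`TMS`, `SDMT`,
#' `TFC`, `BDI`, carried through untouched) and one column per ROI volume in
#' mm^3.  ROI columns may be split as `<roi>_left` / `<roi>_right`, in which
#' case the pair is summed into `<roi>` (hemispheres are analysed together).
#'
#' Rows violating the volume invariants (`icv > whole_brain > 0`, every ROI
#' volume in `(0, whole_brain)`) are flagged `qc_pass = FALSE` with a warning
#' rather than dropped; exclusion is the job of [apply_exclusions()].
#'
#' @param path CSV file path.
#' @param rois ROI columns expected; defaults to those found in the file.
#' @return Data frame of typed scan records.
#' @export
read_cohort <- function(path, rois = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.mandatory_cols, names(df))
  if (length(miss)) stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  df <- .merge_hemispheres(df)
  df$subject_id <- as.character(df$subject_id)
  df$study <- as.character(df$study)
  df$group <- as.character(df$group)
  num_cols <- setdiff(names(df), c("subject_id", "study", "group", "qc_pass"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "")
    if (length(bad))
      stop("column '", cc, "': non-numeric value(s) at row(s) ",
           paste(bad, collapse = ", "))
    df[[cc]] <- v
  }
  df$visit_index <- as.integer(df$visit_index)
  if (!("qc_pass" %in% names(df))) df$qc_pass <- TRUE
  df$qc_pass <- as.logical(df$qc_pass)
  df$qc_pass[is.na(df$qc_pass)] <- TRUE
  dup <- duplicated(df[c("subject_id", "visit_index")])
  if (any(dup))
    stop("duplicate (subject, visit) row(s): ",
         paste(df$subject_id[dup], df$visit_index[dup], sep = "/", collapse = ", "))
  validate_cohort(df, rois = rois)
}

#' Validate scan-record invariants
#'
#' Flags (does not drop) rows with inconsistent volumes; errors on structural
#' violations (non-increasing age across a subject's visits).
#'
#' @param df Cohort data frame.
#' @param rois ROI columns to check; `NULL` means every recognised ROI column.
#' @return `df` with `qc_pass` updated.
#' @export
validate_cohort <- function(df, rois = NULL) {
  if (is.null(rois))
    rois <- intersect(roi_catalog(), names(df))
  bad <- !(df$icv > df$whole_brain & df$whole_brain > 0)
  for (r in rois) {
    v <- df[[r]]
    bad <- bad | !(v > 0 & v < df$whole_brain)
  }
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warning(sum(bad), " row(s) violate volume invariants; flagged qc_pass = FALSE")
    df$qc_pass[bad] <- FALSE
  }
  ds <- df[order(df$subject_id, df$visit_index), ]
  same <- duplicated(ds$subject_id)           # row continues previous subject
  bad_age <- same & c(FALSE, diff(ds$age) <= 0)
  if (any(bad_age))
    stop("visits with non-increasing age for subject(s): ",
         paste(unique(ds$subject_id[bad_age]), collapse = ", "))
  df
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: a read of the written file reproduces every
#' field (exactly for strings/integers, to full double precision for
#' volumes).
#'
#' @param df Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  for (cc in names(out)[num]) out[[cc]] <- format(out[[cc]], digits = 17, trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply declarative exclusion rules
#'
#' Partitions a cohort into kept and excluded scans, with one reason per
#' excluded row (first matching rule wins) and per-rule counts, mirroring the
#' sample-accounting discipline of multi-site imaging studies.
#'
#' Available rules: `qc` (drop `qc_pass == FALSE`), `require_covariates`
#' (drop rows with missing values in the named columns), `max_volume_z`
#' (drop rows whose whole-brain volume lies more than the given number of
#' robust z-units from the cohort median).
#'
#' @param records Cohort data frame.
#' @param rules List, e.g. `list(qc = TRUE, require_covariates = c("age","icv"),
#'   max_volume_z = 4)`.
#' @return List with elements `kept` (data frame), `excluded` (data frame with
#'   a `reason` column) and `counts` (named integer vector per rule).
#' @export
apply_exclusions <- function(records,
                             rules = list(qc = TRUE)) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  mark <- function(idx, why) {
    new <- idx & is.na(reason)
    reason[new] <<- why
  }
  if (isTRUE(rules$qc) && "qc_pass" %in% names(records))
    mark(!records$qc_pass, "qc_fail")
  if (!is.null(rules$require_covariates)) {
    cols <- intersect(rules$require_covariates, names(records))
    if (length(cols)) {
      miss <- Reduce(`|`, lapply(records[cols], is.na))
      mark(miss, "missing_covariate")
    }
  }
  if (!is.null(rules$max_volume_z) && n > 1L) {
    wb <- records$whole_brain
    z <- abs(wb - stats::median(wb)) / (stats::mad(wb) + .Machine$double.eps)
    mark(z > rules$max_volume_z, "implausible_volume")
  }
  excl <- !is.na(reason)
  counts <- table(factor(reason[excl]))
  list(kept = records[!excl, , drop = FALSE],
       excluded = cbind(records[excl, , drop = FALSE],
                        reason = reason[excl]),
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Construct the regression response for one ROI
#'
#' Either the raw ROI volume in mm^3 (head size enters the model later as an
#' ICV covariate) or the dimensionless ratio of the ROI volume to whole-brain
#' volume.  Normalisation isolates preferential atrophy: a region declining
#' no faster than the whole brain has a flat or increasing ratio.
#'
#' @param records Cohort data frame.
#' @param roi ROI column name.
#' @param normalize_wbv Logical; divide by `whole_brain`?
#' @return Numeric response vector, one value per scan.
#' @export
make_response <- function(records, roi, normalize_wbv = FALSE) {
  if (!(roi %in% names(records)))
    stop("ROI '", roi, "' absent from the cohort table")
  v <- records[[roi]]
  if (anyNA(v)) stop("ROI '", roi, "' has missing values")
  if (normalize_wbv) v / records$whole_brain else v
}
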