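# Shared fixtures: small generators and the brute-force oracle used to
# cross-check the profile fitter.

# single-ROI scenario with a known changepoint
one_roi_scenario <- function(tau = 300, delta = 3200, n_control = 30,
                             n_carrier = 60, seed = 1, ...) {
  default_hd_scenario(
    n_control = n_control, n_carrier = n_carrier,
    roi_truths = list(putamen = list(v0 = 8000, delta = delta,
                                     tau = tau, scale = 70)),
    seed = seed, ...)
}

# cohort generated from a straight declining line (no changepoint), with a
# subject-level random intercept so the block bootstrap has real structure
gen_linear_cohort <- function(n_subj = 50, seed = 1, slope = -5,
                              intercept = 10000, b_sd = 120, e_sd = 240) {
  set.seed(seed)
  nv <- sample(1:4, n_subj, replace = TRUE)
  id <- rep(seq_len(n_subj), nv)
  cap0 <- runif(n_subj, 100, 600)
  visit <- unlist(lapply(nv, seq_len)) - 1
  cap <- cap0[id] + visit * 10
  b0 <- rnorm(n_subj, 0, b_sd)
  y <- intercept + slope * cap + b0[id] + rnorm(length(id), 0, e_sd)
  data.frame(response = y, cap = cap, subject_id = sprintf("S%03d", id))
}

# sigmoid-truth dataset without any cohort structure
gen_sigmoid_data <- function(n = 150, seed = 1, v0 = 10, delta = 4,
                             tau = 300, scale = 50, noise = 0.3) {
  set.seed(seed)
  cap <- runif(n, 100, 600)
  y <- left_flat_sigmoid(cap, v0, delta, tau, scale) + rnorm(n, 0, noise)
  data.frame(response = y, cap = cap)
}

# independent brute-force fitter: exhaustive (tau x scale) grid, plain
# lm.fit per grid point, delta >= 0 enforced by dropping the ramp column
brute_force_rss <- function(y, cap, Z = NULL, tau_grid, scale_grid) {
  if (is.null(Z)) Z <- matrix(0, length(y), 0)
  X0 <- cbind(1, Z)
  best <- Inf
  for (tau in tau_grid) {
    for (s in scale_grid) {
      u <- (cap - tau) / s
      ramp <- ifelse(u > 0, 2 / (1 + exp(-u)) - 1, 0)
      f <- stats::lm.fit(cbind(X0, ramp), y)
      rss <- if (-f$coefficients[["ramp"]] >= 0) sum(f$residuals^2)
             else sum(stats::lm.fit(X0, y)$residuals^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# tiny cohort CSV fixture written in code
write_fixture_csv <- function(path, icv_bad_row = FALSE) {
  df <- data.frame(
    subject_id = c("a", "a", "b", "b", "c", "d"),
    study = c("A", "A", "B", "B", "C", "A"),
    group = c("control", "control", "premanifest", "premanifest",
              "manifest", "control"),
    visit_index = c(0, 1, 0, 1, 0, 0),
    age = c(30, 31, 45, 46.1, 52, 36),
    cag = c(NA, NA, 42, 42, 44, NA),
    icv = rep(1.5e6, 6),
    whole_brain = rep(1.2e6, 6),
    caudate_left = c(3500, 3490, 3300, 3250, 2800, 3520),
    caudate_right = c(3450, 3445, 3310, 3260, 2790, 3480),
    putamen = c(8000, 7990, 7500, 7400, 6200, 8050)
  )
  if (icv_bad_row) df$icv[3] <- 1e6  # below whole_brain
  utils::write.csv(df, path, row.names = FALSE)
  df
}
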