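test_that("noise-free single-study cohorts lie exactly on the true curve", {
  sc <- one_roi_scenario(seed = 2, n_control = 0, n_carrier = 40,
                         noise_sd_fraction = 0,
                         study_weights = c(A = 1, B = 0, C = 0),
                         study_offset_frac = c(A = 0, B = 0, C = 0),
                         group_offset_frac = c(control = 0, premanifest = 0,
                                               manifest = 0),
                         icv_slope_frac = 0, artefact_rate = 0)
  coh <- generate_cohort(sc)
  cap <- coh$age * (coh$cag - 33.66)
  t <- sc$roi_truths$putamen
  expect_equal(coh$putamen,
               left_flat_sigmoid(cap, t$v0, t$delta, t$tau, t$scale),
               tolerance = 1e-9)
})

test_that("generation is reproducible from the seed and varies across seeds", {
  sc <- one_roi_scenario(seed = 5)
  expect_identical(generate_cohort(sc), generate_cohort(sc))
  sc2 <- one_roi_scenario(seed = 6)
  expect_false(identical(generate_cohort(sc), generate_cohort(sc2)))
})

test_that("generated records satisfy the scan-record invariants", {
  coh <- generate_cohort(default_hd_scenario(seed = 12, n_control = 60,
                                             n_carrier = 120))
  expect_true(all(coh$icv > coh$whole_brain))
  expect_true(all(coh$whole_brain > 0))
  for (r in intersect(roi_catalog(), names(coh))) {
    expect_true(all(coh[[r]] > 0 & coh[[r]] < coh$whole_brain))
  }
  # strictly increasing age within subject
  bys <- split(coh$age, coh$subject_id)
  expect_true(all(vapply(bys, function(a) all(diff(a) > 0), logical(1))))
  # carriers labelled by baseline CAP
  expect_setequal(unique(coh$group), c("control", "premanifest", "manifest"))
})

test_that("sampled demographics match the scenario distributions", {
  sc <- default_hd_scenario(seed = 30, n_control = 700, n_carrier = 1300,
                            max_visits = 1)
  coh <- generate_cohort(sc)
  ctrl <- coh$group == "control"
  expect_true(all(coh$cag[!ctrl] >= 38 & coh$cag[!ctrl] <= 55))
  expect_true(all(is.na(coh$cag[ctrl])))
  expect_true(all(coh$age >= 18 & coh$age <= 72))
  expect_equal(mean(coh$cag[!ctrl]), 42.7, tolerance = 0.02)
  expect_equal(sd(coh$cag[!ctrl]), 2.4, tolerance = 0.15)
  # study mix close to the sampling weights
  mix <- prop.table(table(coh$study))
  expect_equal(as.numeric(mix[c("A", "B", "C")]), c(0.12, 0.36, 0.52),
               tolerance = 0.15)
  # carrier CAP spans the intended disease range
  cap <- coh$age[!ctrl] * (coh$cag[!ctrl] - 33.66)
  expect_gt(min(cap), 50); expect_lt(max(cap), 1000)
  expect_equal(mean(cap), 378, tolerance = 0.15)
})

test_that("visit counts follow the retention process", {
  sc <- default_hd_scenario(seed = 31, n_control = 500, n_carrier = 500,
                            retention = 0.85)
  coh <- generate_cohort(sc)
  nv <- table(table(coh$subject_id))
  expect_equal(length(unique(coh$subject_id)), 1000L)
  # geometric-ish decay: each additional visit retained ~85% of the time
  p21 <- sum(table(coh$subject_id) >= 2) / 1000
  expect_equal(p21, 0.85, tolerance = 0.1)
  expect_true(max(table(coh$subject_id)) <= sc$max_visits)
})

test_that("default scenario orders basal ganglia before cortex by construction", {
  sc <- default_hd_scenario()
  expect_silent(validate_scenario(sc))
  truths <- sc$roi_truths
  bg_taus <- vapply(truths[basal_ganglia_rois()], `[[`, numeric(1), "tau")
  ctx_taus <- vapply(truths[c("PrCG", "SFG", "SPG", "SOG", "STG")], `[[`,
                     numeric(1), "tau")
  expect_lt(max(bg_taus), min(ctx_taus))
})

test_that("infeasible scenarios are rejected", {
  expect_error(cohort_scenario(study_weights = c(A = 0.5, B = 0.5, C = 0.5)),
               "sum to 1")
  expect_error(cohort_scenario(age_range = c(72, 18)), "range")
  expect_error(cohort_scenario(roi_truths = list(bad = list(v0 = 100, delta = 200,
                                                            tau = 300, scale = 50))),
               "infeasible")
})
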