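test_that("carrier CAP follows Age x (CAG - L)", {
  cfg <- cap_config()
  expect_identical(cap_for_carrier(50, 43.66, cfg), 500)
  # a repeat length equal to the threshold would give CAP exactly 0; the
  # formula is checked at the threshold via a raised threshold constant
  expect_identical(cap_for_carrier(20, 36, cap_config(threshold_L = 36)), 0)
  expect_equal(cap_for_carrier(20, 36, cfg), 20 * (36 - 33.66))
  expect_equal(cap_for_carrier(43.6, 42.7, cfg), 394.144, tolerance = 1e-9)
})

test_that("carrier CAP is exactly linear in age and CAG", {
  cfg <- cap_config()
  ages <- seq(20, 70, by = 5)
  cags <- seq(38, 55, by = 1)
  for (cg in c(38, 44, 50)) {
    d1 <- diff(cap_for_carrier(ages, rep(cg, length(ages)), cfg))
    expect_equal(d1, rep(5 * (cg - cfg$threshold_L), length(d1)))
  }
  for (a in c(25, 45, 65)) {
    d2 <- diff(cap_for_carrier(rep(a, length(cags)), cags, cfg))
    expect_equal(d2, rep(a, length(d2)))
  }
})

test_that("carrier CAP rejects invalid inputs with informative errors", {
  cfg <- cap_config()
  expect_error(cap_for_carrier(-1, 42, cfg), "age")
  expect_error(cap_for_carrier(40, 30, cfg, subject_id = "sub9"), "sub9")
  expect_error(cap_for_carrier(40, 30, cfg), "expansion")
})

test_that("control CAP schemes behave as configured", {
  expect_identical(cap_for_control(35, cap_config(control_scheme = "age_identity")), 35)
  expect_equal(cap_for_control(35, cap_config(control_multiplier = 5.6)), 196)
  # multiplier matching a cohort-mean control CAP of 252.9 at mean age 45.2
  m <- 252.9 / 45.2
  expect_equal(m, 5.595, tolerance = 1e-3)
  expect_equal(cap_for_control(45.2, cap_config(control_multiplier = m)), 252.9)
  ages <- runif(50, 20, 39)
  expect_identical(cap_for_control(ages, cap_config(control_scheme = "age_identity")),
                   ages)
})

test_that("assign_cap fills carriers, filters controls, handles errors", {
  df <- data.frame(
    subject_id = c("c1", "c2", "c3", "k1", "k2"),
    group = c("premanifest", "manifest", "premanifest", "control", "control"),
    age = c(40, 50, 35, 30, 45),
    cag = c(42, 44, 46, NA, NA)
  )
  out <- assign_cap(df, cap_config(), quiet = TRUE)
  expect_equal(nrow(out), 4L)        # 45-year-old control dropped
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_true(all(is.finite(out$cap)))
  carriers <- out$group != "control"
  expect_equal(out$cap[carriers], out$age[carriers] * (out$cag[carriers] - 33.66))

  # empty input passes through
  empty <- assign_cap(df[0, ], cap_config(), quiet = TRUE)
  expect_equal(nrow(empty), 0L)

  # carrier missing CAG names the subject
  bad <- df; bad$cag[1] <- NA
  expect_error(assign_cap(bad, cap_config(), quiet = TRUE), "c1")

  # carriers-only mode drops all controls regardless of age
  co <- assign_cap(df, cap_config(control_scheme = "exclude"), quiet = TRUE)
  expect_true(all(co$group != "control"))

  # age filter disabled keeps the 45-year-old control
  nofilter <- assign_cap(df, cap_config(control_age_cap = Inf), quiet = TRUE)
  expect_equal(nrow(nofilter), 5L)
})

test_that("assign_cap is idempotent and order-independent", {
  sc <- one_roi_scenario(seed = 11, n_control = 20, n_carrier = 30)
  coh <- generate_cohort(sc)
  cfg <- cap_config()
  a1 <- assign_cap(coh, cfg, quiet = TRUE)
  a2 <- assign_cap(a1, cfg, quiet = TRUE)
  expect_equal(a1$cap, a2$cap)
  perm <- sample(nrow(coh))
  a3 <- assign_cap(coh[perm, ], cfg, quiet = TRUE)
  key <- function(d) d[order(d$subject_id, d$visit_index), c("subject_id", "cap")]
  expect_equal(key(a1), key(a3), ignore_attr = TRUE)
})

test_that("synthetic carrier CAPs equal age x (cag - L) elementwise", {
  coh <- generate_cohort(one_roi_scenario(seed = 5, n_control = 40, n_carrier = 60))
  out <- assign_cap(coh, cap_config(), quiet = TRUE)
  k <- out$group != "control"
  expect_equal(out$cap[k], out$age[k] * (out$cag[k] - 33.66))
})
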