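test_that("TyG follows its formula with unit consistency", {
  expect_equal(compute_tyg(2, 1), 0) # ln(2 * 1 / 2) = ln(1)
  expect_equal(compute_tyg(100, 100), log(5000))
  # mmol/L inputs equal to the mg/dL case after conversion give identical TyG
  expect_equal(compute_tyg(100 / 88.57, 100 / 18.018, units = "mmol/L"),
               compute_tyg(100, 100))
  # mmol/L without conversion applies the formula to the raw values
  expect_equal(compute_tyg(2, 1, units = "mmol/L", convert = FALSE), 0)
  # non-positive inputs propagate as missing
  expect_true(is.na(compute_tyg(0, 100)))
  expect_true(is.na(compute_tyg(100, -1)))
  expect_true(is.na(compute_tyg(NA, 100)))
})

test_that("TG/HDL-C ratio is scale-free and guards the denominator", {
  expect_equal(compute_tg_hdl_ratio(1.5, 1.5), 1)
  expect_equal(compute_tg_hdl_ratio(3, 1.5), 2)
  expect_equal(compute_tg_hdl_ratio(3 * 88.57, 1.5 * 88.57), 2)
  expect_true(is.na(compute_tg_hdl_ratio(3, 0)))
  expect_true(is.na(compute_tg_hdl_ratio(NA, 2)))
})

test_that("winsorize clips at type-7 quantiles and is idempotent/monotone", {
  x <- as.numeric(1:100)
  expect_identical(winsorize(x, 0, 0), x)

  w <- winsorize(x, 0.025)
  expect_equal(min(w), quantile(x, 0.025, type = 1, names = FALSE))
  expect_equal(max(w), quantile(x, 0.975, type = 1, names = FALSE))

  set.seed(9)
  for (i in 1:20) {
    v <- rnorm(200)
    v[sample(200, 10)] <- NA
    f <- runif(1, 0, 0.2)
    w1 <- winsorize(v, f)
    expect_equal(winsorize(w1, f), w1, tolerance = 1e-12) # idempotent
    expect_identical(is.na(w1), is.na(v))                 # NA untouched
    ok <- !is.na(v)
    expect_true(all(diff(w1[ok][order(v[ok])]) >= -1e-12)) # monotone
  }
  expect_error(winsorize(x, 0.5), class = "mediscreen_config_error")
})

test_that("complete-case filtering counts removals by requirement set", {
  co <- tibble::tibble(
    id = 1:10, A = rep(0:1, 5),
    y = c(NA, NA, NA, 4:10),
    m = c(1, NA, 3, NA, 5:10)
  )
  # no missingness in the required set: identity
  full <- complete_case_filter(co, c("id", "A"))
  expect_identical(full$cohort, co)
  expect_identical(full$n_removed, 0L)
  # TE column set removes the 3 missing-y rows
  te <- complete_case_filter(co, c("A", "y"))
  expect_identical(te$n_removed, 3L)
  # mediation set removes the union: rows 1-4
  med <- complete_case_filter(co, c("A", "y", "m"))
  expect_identical(med$n_removed, 4L)
  expect_error(complete_case_filter(co, "zz"), "unknown")
})

test_that("mediator response filter removes exactly the coded rows", {
  co <- tibble::tibble(A = rep(0:1, 5),
                       activity = c(10, -1, 30, -3, 50, 60, -1, 80, NA, 100))
  out <- mediator_response_filter(co, "activity", c(-1, -3))
  expect_identical(out$n_removed, 3L)
  expect_true(all(out$cohort$activity >= 0, na.rm = TRUE))
  # NA mediator rows are retained (handled by complete-case, not this filter)
  expect_identical(sum(is.na(out$cohort$activity)), 1L)
  # no codes present: identity
  clean <- tibble::tibble(activity = c(1, 2, 3))
  expect_identical(mediator_response_filter(clean, "activity")$n_removed, 0L)
  expect_error(mediator_response_filter(co, "activity", c(2)),
               class = "mediscreen_config_error")
})

test_that("filters commute: response filter and complete-case", {
  co <- tibble::tibble(A = rep(0:1, 5), y = c(NA, 2:10),
                       activity = c(10, -1, NA, -3, 50, 60, -1, 80, NA, 100))
  cols <- c("A", "y", "activity")
  a <- complete_case_filter(
    mediator_response_filter(co, "activity")$cohort, cols
  )$cohort
  b <- mediator_response_filter(
    complete_case_filter(co, cols)$cohort, "activity"
  )$cohort
  expect_identical(a, b)
})

test_that("repeated measurements average per subject, composites first", {
  long <- tibble::tibble(
    subject_id = c("s1", "s1", "s2", "s3"),
    tg = c(100, 200, 90, NA),
    glucose = c(100, 50, 100, 80)
  )
  long$tyg <- compute_tyg(long$tg, long$glucose)
  avg <- average_repeated_measurements(long, value_cols = c("tg", "tyg"))
  expect_equal(avg$tg[avg$subject_id == "s1"], 150)
  # composite computed per contemporaneous pair, then averaged ...
  expect_equal(avg$tyg[avg$subject_id == "s1"],
               mean(c(compute_tyg(100, 100), compute_tyg(200, 50))))
  # ... which differs from the composite of the averaged components
  expect_false(isTRUE(all.equal(avg$tyg[avg$subject_id == "s1"],
                                compute_tyg(150, 75))))
  # single measurement passes through; all-missing becomes NA
  expect_equal(avg$tg[avg$subject_id == "s2"], 90)
  expect_true(is.na(avg$tg[avg$subject_id == "s3"]))
})

test_that("Cohen's d matches its pooled-SD definition", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(4)
  x <- rnorm(2000, 1, 1)
  y <- rnorm(2000, 0, 1)
  expect_equal(cohens_d(x, y), 1, tolerance = 0.1)
  # formula oracle on arbitrary samples
  a <- rexp(37)
  b <- rexp(53) * 2
  sp <- sqrt(((36) * var(a) + (52) * var(b)) / (37 + 53 - 2))
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_true(is.na(cohens_d(rep(1, 5), rep(1, 5))))
})

test_that("Welch's t from summaries matches a raw two-sample oracle", {
  res <- welch_t(27.96, 4.62, 386, 26.80, 3.58, 55572)
  expect_equal(round(res$t, 2), 4.92)

  expect_equal(welch_t(5, 1, 10, 5, 2, 20)$t, 0)
  expect_equal(welch_t(5, 1, 10, 5, 2, 20)$p, 1)

  # construct raw samples with exactly the requested summaries and compare
  # against stats::t.test
  make_sample <- function(m, s, n) {
    v <- scale(rnorm(n))[, 1] * s + m
    v
  }
  set.seed(8)
  x <- make_sample(2.3, 1.7, 41)
  y <- make_sample(1.1, 0.9, 29)
  ours <- welch_t(mean(x), sd(x), 41, mean(y), sd(y), 29)
  ref <- stats::t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)

  expect_error(welch_t(1, 0, 5, 1, 0, 5), "zero variance")
})

test_that("composite trait columns are built with missingness propagation", {
  co <- tibble::tibble(tg = c(100, NA, 90), glu = c(100, 90, NA),
                       hdl = c(50, 60, 0))
  specs <- list(
    trait_spec("tyg", kind = "composite", composite = "tyg",
               components = c(triglycerides = "tg", glucose = "glu")),
    trait_spec("tg_hdl", kind = "composite", composite = "tg_hdl",
               components = c(triglycerides = "tg", hdl_c = "hdl"))
  )
  built <- mediscreen:::build_trait_columns(co, specs)
  expect_equal(built$tyg[1], log(100 * 100 / 2))
  expect_true(all(is.na(built$tyg[2:3])))
  expect_equal(built$tg_hdl[1], 2)
  expect_true(is.na(built$tg_hdl[3])) # zero HDL denominator
  expect_error(
    trait_spec("x", kind = "composite", composite = "tyg"),
    class = "mediscreen_config_error"
  )
})
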