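# five-point dispersal-marker test and skyline post-processing

m7c3c <- marker_ages(clade_age = 5.2, ancestor_age = 11.8,
                     founder_age_sink = 4.4,
                     founder_age_extended_source = 4.2,
                     expansion_onset_source = 7.5,
                     expansion_onset_sink = 5.2)
hg_e <- marker_ages(24.0, 39.2, 8.8, 6.4, 7, 8)
b4a1a <- marker_ages(9.9, 14.7, 7.3, 8.5, 10, 10)

test_that("the reference verdict sets are reproduced under the default config", {
  v_m7 <- evaluate_criteria(m7c3c)
  expect_equal(attr(v_m7, "n_passed"), 5)
  expect_true(all(v_m7))

  v_e <- evaluate_criteria(hg_e)
  expect_equal(attr(v_e, "n_passed"), 0)
  expect_false(any(v_e))

  v_b <- evaluate_criteria(b4a1a)
  expect_equal(attr(v_b, "n_passed"), 0)
  expect_false(any(v_b))
})

test_that("verdicts are invariant to joint rescaling of ages and config", {
  cfg_years <- criteria_config(arrival_window = c(6000, 8000),
                               clade_window = c(4500, 5500),
                               founder_target = 4500,
                               extended_founder_bound = 4000,
                               tolerance = 500, onset_margin = 500)
  m7_years <- marker_ages(5200, 11800, 4400, 4200, 7500, 5200)
  v_scaled <- evaluate_criteria(m7_years, cfg_years)
  v_ka <- evaluate_criteria(m7c3c)
  expect_equal(as.logical(v_scaled), as.logical(v_ka))
  expect_equal(attr(v_scaled, "n_passed"), attr(v_ka, "n_passed"))
})

test_that("interval-overlap semantics widen the borderline calls", {
  # point estimate 5.7 fails (c), but its interval reaches the target
  ages <- marker_ages(5.2, 11.8, 5.7, 4.2, 7.5, 5.2,
                      intervals = list(founder_age_sink = c(4.3, 7.1)))
  expect_false(evaluate_criteria(ages)[["c"]])
  v <- evaluate_criteria(ages, criteria_config(use_intervals = TRUE))
  expect_true(v[["c"]])
})

test_that("missing fields name the criterion they block", {
  bad <- m7c3c
  bad$founder_age_sink <- NA_real_
  expect_error(evaluate_criteria(bad), "criterion \\(c\\)")
})

test_that("expansion increments follow slope and conserve total change", {
  # constant trajectory: all increments zero
  flat <- skyline_trajectory(seq(0, 5000, 500), rep(2000, 11))
  inc <- expansion_increments(flat)
  expect_true(all(inc$increment == 0))

  # linear growth of 1,000 individuals per 100 years: increment 10
  tr <- skyline_trajectory(c(0, 5000), c(51000, 1000))
  inc <- expansion_increments(tr)
  expect_true(all(abs(inc$increment - 10) < 1e-9))
  # conservation: increments times the unit recover the net change
  expect_equal(sum(inc$increment) * 100, 51000 - 1000)

  expect_error(expansion_increments(skyline_trajectory(0, 10)),
               "at least two")
  expect_error(skyline_trajectory(c(5, 1), c(10, 10)), "increasing")
})

test_that("logistic growth peaks within one step of its inflection", {
  t <- seq(0, 10000, 100)
  n <- 10000 / (1 + exp((t - 5000) / 800))
  tr <- skyline_trajectory(t, n)
  inc <- expansion_increments(tr)
  det <- detect_expansion(inc)
  expect_true(det$defined)
  expect_lte(abs(det$peak - 5000), 100)
  expect_gt(det$onset, det$peak)   # onset is older than the peak
  # conservation on the interpolated grid
  expect_equal(sum(inc$increment) * 100, n[1] - n[length(n)],
               tolerance = 1e-6)
})

test_that("flat series are flagged undefined and two-phase growth shows both maxima", {
  flat <- expansion_increments(skyline_trajectory(c(0, 1000), c(500, 500)))
  det <- detect_expansion(flat)
  expect_false(det$defined)
  expect_true(is.na(det$peak))

  # two growth phases: global maximum is primary, both reported
  t <- seq(0, 12000, 100)
  n <- 8000 / (1 + exp((t - 3000) / 300)) +
       3000 / (1 + exp((t - 9000) / 300))
  det2 <- detect_expansion(expansion_increments(skyline_trajectory(t, n)))
  expect_true(det2$defined)
  expect_lte(abs(det2$peak - 3000), 200)
  expect_true(any(abs(det2$local_peaks - 9000) <= 200))
})

test_that("skyline tables read back as trajectories", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time\tmedian\tlower\tupper",
               "0\t5000\t3000\t8000", "1000\t2000\t1500\t4000"), p)
  tr <- read_skyline(p)
  expect_s3_class(tr, "skyline_trajectory")
  expect_equal(tr$sizes, c(5000, 2000))
})
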