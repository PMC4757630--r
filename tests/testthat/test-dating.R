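# rho, Saillard sigma, effective sample size, ages and rate calibration

test_that("rho is the mean mutational distance to the founder", {
  expect_equal(rho(rep(1, 4)), 1)
  expect_equal(rho(rep(0, 5)), 0)
  expect_equal(rho(c(0, 1, 1, 2)), 1)
  expect_error(rho(numeric(0)), "zero members")
})

test_that("Saillard sigma matches hand-computed sums", {
  # star of n members, one step each: sigma^2 = 1/n
  expect_equal(saillard_sigma(rep(1, 4), rep(1, 4), 4), 0.5)
  # single member at distance 3: sigma = sqrt(3)
  expect_equal(saillard_sigma(3, 1, 1), sqrt(3))
  # two members sharing a 1-step branch plus one private step each:
  # sigma^2 = (2^2 * 1 + 1 + 1) / 2^2 = 1.5
  expect_equal(saillard_sigma(c(1, 1, 1), c(2, 1, 1), 2)^2, 1.5)
})

test_that("clusters built from trees satisfy the star identities", {
  members <- data.frame(sample_id = paste0("s", 1:4),
                        node = paste0("n", 1:4), distance = 1)
  cl <- founder_cluster("f", members, branch_lengths = rep(1, 4),
                        branch_members = rep(1, 4))
  expect_equal(cl$rho, 1)
  expect_equal(cl$m, 4)
  expect_equal(cl$sigma^2, cl$rho / cl$n)
  expect_equal(cl$n_eff, cl$n)
})

test_that("effective n is rho/sigma^2, capped by star equality only", {
  # shared-branch cluster: distances {2, 2}, sigma^2 = 1.5, n_eff = 4/3
  s <- saillard_sigma(c(1, 1, 1), c(2, 1, 1), 2)
  expect_equal(effective_n(2, s), 4 / 3)
  expect_equal(effective_n(0, 0, n = 7), 7)
  expect_error(effective_n(0, 0), "n required")
})

test_that("sigma^2 >= rho/n and n_eff <= n on random trees", {
  for (s in 1:200) {
    cl <- random_cluster(s)
    expect_gte(cl$sigma^2 + 1e-12, cl$rho / cl$n)
    expect_lte(cl$n_eff, cl$n + 1e-9)
    # star equality needs every member on its own unit branch
    is_star <- all(cl$members$distance == 1) &&
      !anyDuplicated(cl$members$node) && max(table(cl$members$node)) == 1
    if (is_star) expect_equal(cl$n_eff, cl$n)
  }
})

test_that("ages scale linearly with rho under each clock", {
  expect_equal(age_estimate(1, 0, clock_preset("hvs1"))$age, 16677)
  expect_equal(age_estimate(1, 0, clock_preset("mtdna_phylo"))$age, 3624)
  expect_equal(age_estimate(0, 0, clock_preset("hvs1"))$age, 0)
  a2 <- age_estimate(2, 0.5, clock_preset("hvs1"))
  expect_equal(a2$age, 2 * 16677)
  expect_equal(a2$lower, 1.5 * 16677)
  expect_equal(a2$upper, 2.5 * 16677)
  expect_true(a2$lower <= a2$age && a2$age <= a2$upper)
  # negative lower bounds are floored at zero
  expect_equal(age_estimate(0.1, 0.5, clock_preset("hvs1"))$lower, 0)
  # STR clock needs the panel size
  expect_error(age_estimate(1, 0, clock_preset("ystr_calibrated")), "n_loci")
  astr <- age_estimate(2.3256, 0, clock_preset("ystr_calibrated"),
                       n_loci = 19)
  expect_equal(astr$age, 3000, tolerance = 1e-6)
})

test_that("STR rate calibration inverts the closed-form age product", {
  expect_equal(calibrate_str_rate(2.3256, 3000, 19), 4.08e-5)
  expect_equal(calibrate_str_rate(2 * 2.3256, 3000, 19), 2 * 4.08e-5)
  expect_error(calibrate_str_rate(0, 3000, 19), "uninformative")
})
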