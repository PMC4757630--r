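# continuous-Poisson migration-time posteriors, scans and partitions

mock_cluster <- function(rho, n_eff, n = ceiling(n_eff)) {
  structure(list(founder_node = "f", n = n, m = rho * n, rho = rho,
                 sigma = if (rho > 0) sqrt(rho / n_eff) else 0,
                 n_eff = n_eff, criterion = "f1"),
            class = "founder_cluster")
}

test_that("posterior mass sits at the youngest time for mutation-free clusters", {
  cl <- mock_cluster(0, 10)
  grid <- seq(0, 70000, 200)
  post <- migration_posterior(cl, grid, clock = clock_preset("hvs1"))
  expect_equal(post[1], 1)
  expect_equal(sum(post), 1)
})

test_that("the posterior mode tracks rho times the clock", {
  cl <- mock_cluster(1, 10)
  grid <- seq(0, 70000, 200)
  post <- migration_posterior(cl, grid, clock = clock_preset("hvs1"))
  expect_equal(sum(post), 1, tolerance = 1e-12)
  mode <- grid[which.max(post)]
  expect_lte(abs(mode - 16677), 200)
  # monotone: a larger rho at fixed n_eff never gives a younger mode
  modes <- vapply(seq(0.2, 2, by = 0.2), function(r) {
    p <- migration_posterior(mock_cluster(r, 10), grid,
                             clock = clock_preset("hvs1"))
    grid[which.max(p)]
  }, 1)
  expect_true(all(diff(modes) >= 0))
})

test_that("times with equal likelihood split the posterior exactly in half", {
  # lambda^m e^-lambda equal at lambda = 1 and 2 when m = 1/log(2)
  q <- clock_preset("hvs1")$years_per_mutation
  cl <- mock_cluster(1 / log(2), 1)
  post <- migration_posterior(cl, c(q, 2 * q), clock = clock_preset("hvs1"))
  expect_equal(post, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("STR and sequence clocks agree on the likelihood scale", {
  cl <- mock_cluster(2.3256, 20)
  post <- migration_posterior(cl, c(1500, 3000, 6000),
                              clock = clock_preset("ystr_calibrated"),
                              n_loci = 19)
  expect_equal(which.max(post), 2)   # mode at rho/(rate * n_loci) = 3000
  expect_error(migration_posterior(cl, c(1500, 3000),
                                   clock = clock_preset("ystr_calibrated")),
               "n_loci")
})

test_that("scans aggregate founder posteriors by sink counts", {
  cl <- mock_cluster(1, 10)
  scan1 <- scan_migrations(list(cl), clock_preset("hvs1"))
  expect_equal(length(scan1$grid), 351)
  expect_equal(scan1$aggregate, as.numeric(scan1$per_founder[1, ]))

  # two founders of equal sink counts with rho*Q at 4,500 and 8,000
  q <- clock_preset("hvs1")$years_per_mutation
  cl45 <- mock_cluster(4500 / q, 100, n = 20)
  cl80 <- mock_cluster(8000 / q, 100, n = 20)
  scan2 <- scan_migrations(list(cl45, cl80), clock_preset("hvs1"))
  agg <- scan2$aggregate
  expect_equal(sum(agg), 1, tolerance = 1e-12)
  # bimodal: local maxima within one grid step of each pulse time
  local_max <- scan2$grid[which(diff(sign(diff(agg))) == -2) + 1]
  expect_true(any(abs(local_max - 4500) <= 200))
  expect_true(any(abs(local_max - 8000) <= 200))
  expect_error(scan_migrations(list(), clock_preset("hvs1")), "empty")

  # halving the grid resolution leaves the mode within the coarser step
  coarse <- scan_migrations(list(cl45), clock_preset("hvs1"), step = 400)
  fine <- scan_migrations(list(cl45), clock_preset("hvs1"), step = 200)
  expect_lte(abs(scan_mode(coarse) - scan_mode(fine)), 400)
})

test_that("migration models validate their event times and priors", {
  expect_equal(migration_model_preset("mtdna")$event_times,
               c(500, 4500, 8000, 50000))
  expect_equal(migration_model_preset("ystr")$event_times,
               c(500, 4500, 8000, 20000))
  expect_error(migration_model(c(500, 400)), "strictly increasing")
  expect_error(migration_model(c(500, 4500), prior = c(0.2, 0.2)),
               "probability vector")
  m <- migration_model(c(500, 4500), prior = c(0.9, 0.1))
  expect_equal(sum(m$prior), 1)
})

test_that("partitions put a Neolithic-aged founder on the 4.5 ka event", {
  q <- clock_preset("hvs1")$years_per_mutation
  cl <- mock_cluster(4500 / q, 50)
  part <- partition_migrations(list(cl), migration_model_preset("mtdna"),
                               clock_preset("hvs1"))
  expect_equal(sum(part$fractions), 1, tolerance = 1e-12)
  expect_gte(part$fractions[["4500"]], 0.9)
  # single founder: fractions equal its posterior row
  expect_equal(as.numeric(part$fractions),
               as.numeric(part$per_founder[1, ]))
})

test_that("posterior rows always sum to one", {
  q <- clock_preset("hvs1")$years_per_mutation
  founders <- lapply(c(0, 0.1, 0.5, 1, 2, 4), function(r)
    mock_cluster(r, 5 + r))
  scan <- scan_migrations(founders, clock_preset("hvs1"))
  expect_true(all(abs(rowSums(scan$per_founder) - 1) < 1e-12))
  part <- partition_migrations(founders, migration_model_preset("mtdna"),
                               clock_preset("hvs1"))
  expect_true(all(abs(rowSums(part$per_founder) - 1) < 1e-12))
  expect_equal(sum(part$fractions), 1, tolerance = 1e-12)
})
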