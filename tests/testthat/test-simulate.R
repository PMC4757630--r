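# two-deme simulator: determinism, mutation-process moments, limits

test_that("identical seeds give byte-identical datasets", {
  sc <- sim_scenario(data.frame(time_years = 3000, fraction = 1),
                     n_source = 50, n_sink = 40, seed = 9)
  expect_identical(simulate_two_deme(sc), simulate_two_deme(sc))
  sc2 <- sim_scenario(data.frame(time_years = 3000, fraction = 1),
                      n_source = 50, n_sink = 40, seed = 10)
  expect_false(identical(simulate_two_deme(sc)$data,
                         simulate_two_deme(sc2)$data))
})

test_that("scenarios validate pulses and require a seed", {
  expect_error(sim_scenario(data.frame(time_years = 3000, fraction = 0.5),
                            seed = 1), "sum to 1")
  expect_error(sim_scenario(data.frame(time_years = -5, fraction = 1),
                            seed = 1), "positive")
  expect_error(sim_scenario(data.frame(time_years = 3000, fraction = 1)),
               "seed")
  expect_error(sim_scenario(data.frame(time_years = 50000, fraction = 1),
                            source_depth_years = 24000, seed = 1),
               "younger than the source")
})

test_that("an effectively infinite clock leaves sink samples on their founders", {
  slow <- clock_spec("frozen", years_per_mutation = 1e12)
  sc <- sim_scenario(data.frame(time_years = 3000, fraction = 1),
                     clock = slow, n_source = 40, n_sink = 30, seed = 3)
  sim <- simulate_two_deme(sc)
  fstate <- sim$founders$state[match(sim$truth$founder_id,
                                     sim$founders$founder_id)]
  sink <- sim$data[sim$data$role == "sink", ]
  expect_true(all(vapply(seq_len(nrow(sink)), function(i)
    identical(paste(sink$variants[[i]], collapse = " "), fstate[i]), NA)))
  # with no mutations anywhere, the scan resolves everything to T = 0
  fit <- suppressWarnings(founder_analysis(sim$data))
  expect_equal(scan_mode(fit$scan), 0)
  expect_equal(fit$scan$aggregate[1], 1)
})

test_that("sink mutation counts match the Poisson mean", {
  t_pulse <- 4000
  q <- clock_preset("hvs1")$years_per_mutation
  sc <- sim_scenario(data.frame(time_years = t_pulse, fraction = 1),
                     n_source = 30, n_sink = 1000, seed = 17)
  sim <- simulate_two_deme(sc)
  fstate <- lapply(sim$founders$state, function(s) {
    v <- strsplit(s, " ")[[1]]; v[nzchar(v)]
  })
  names(fstate) <- sim$founders$founder_id
  sink <- sim$data[sim$data$role == "sink", ]
  d <- vapply(seq_len(nrow(sink)), function(i) {
    f <- fstate[[sim$truth$founder_id[i]]]
    v <- sink$variants[[i]]
    length(setdiff(v, f)) + length(setdiff(f, v))
  }, 1)
  mu <- t_pulse / q
  se <- sqrt(mu / length(d))
  # observed distance slightly undershoots the event count when recurrent
  # hits collide, so allow that on the low side
  expect_lte(mean(d), mu + 3 * se)
  expect_gte(mean(d), mu - 3 * se - 0.02)
})

test_that("single-lineage STR displacement variance matches the random walk", {
  r <- 4.08e-5
  t_age <- 3000
  sim <- simulate_star_clade(10000, t_age, clock_preset("ystr_calibrated"),
                             n_loci = 19, seed = 23)
  d <- sweep(foundertrace:::str_repeat_matrix(sim$data), 2, sim$founder)
  lambda <- r * t_age
  n <- length(d)
  se <- sqrt((2 * lambda^2 + lambda) / n)
  expect_lte(abs(mean(d^2) - lambda), 3 * se)
})

test_that("star clades have the closed-form expected rho", {
  sim0 <- simulate_star_clade(5, 0, clock_preset("ystr_calibrated"),
                              seed = 2)
  m0 <- foundertrace:::str_repeat_matrix(sim0$data)
  expect_true(all(sweep(m0, 2, sim0$founder) == 0))

  sim <- simulate_star_clade(500, 3000, clock_preset("ystr_calibrated"),
                             n_loci = 19, seed = 31)
  steps <- rowSums(abs(sweep(foundertrace:::str_repeat_matrix(sim$data), 2,
                             sim$founder)))
  mu <- 4.08e-5 * 3000 * 19            # 2.3256 total steps per lineage
  se <- stats::sd(steps) / sqrt(length(steps))
  # single-step cancellations bias the observed displacement slightly low
  expect_lte(mean(steps), mu + 3 * se)
  expect_gte(mean(steps), mu - 3 * se - 0.15)

  sim2 <- simulate_star_clade(500, 6000, clock_preset("ystr_calibrated"),
                              n_loci = 19, seed = 31)
  steps2 <- rowSums(abs(sweep(foundertrace:::str_repeat_matrix(sim2$data), 2,
                              sim2$founder)))
  # doubling the age doubles the expected displacement (within noise)
  expect_equal(mean(steps2) / mean(steps), 2, tolerance = 0.15)
})

test_that("truth tables are consistent with the emitted dataset", {
  sc <- sim_scenario(data.frame(time_years = c(4500, 8000),
                                fraction = c(0.5, 0.5)),
                     n_source = 50, n_sink = 60, seed = 12)
  sim <- simulate_two_deme(sc)
  expect_equal(nrow(sim$truth), 60)
  expect_setequal(sim$truth$sample_id,
                  sim$data$sample_id[sim$data$role == "sink"])
  expect_true(all(sim$truth$founder_id %in% sim$founders$founder_id))
  expect_setequal(unique(sim$truth$entry_time), c(4500, 8000))
  # pulse fractions respected exactly by largest-remainder allocation
  expect_equal(as.numeric(table(sim$truth$entry_time)), c(30, 30))
})
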