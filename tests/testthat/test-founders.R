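# founder identification under the f1/f2 criteria

fixture_tree <- function() {
  net <- reduced_median_network(founder_fixture())
  root_network(net, "outgroup_consensus", outgroup = character(0))
}

test_that("a one-derived-branch candidate survives f1 but dissolves under f2", {
  tree <- fixture_tree()
  f1 <- identify_founders(tree, "f1")
  # sink1 sits on the candidate itself, sink2 one step below
  cl1 <- f1[[which(vapply(f1, function(c) c$founder_node, "") == "16090A")]]
  expect_equal(cl1$n, 2)
  expect_equal(sort(cl1$members$distance), c(0, 1))
  expect_equal(cl1$rho, 0.5)

  f2 <- identify_founders(tree, "f2")
  # the candidate has a single source-derived branch: members climb to root
  expect_equal(vapply(f2, function(c) c$founder_node, ""), "ref")
  expect_equal(sort(f2[[1]]$members$distance), c(1, 2))
  expect_equal(f2[[1]]$rho, 1.5)
  expect_gte(f2[[1]]$rho, cl1$rho)   # climbing can only lengthen distances
})

test_that("sink samples are conserved across criteria", {
  tree <- fixture_tree()
  n1 <- sum(vapply(identify_founders(tree, "f1"), function(c) c$n, 1))
  n2 <- sum(vapply(identify_founders(tree, "f2"), function(c) c$n, 1))
  expect_equal(n1, n2)
})

test_that("a sink identical to a well-supported source state is its own founder", {
  tree <- fixture_tree()
  # the root state has two source-derived branches: qualifies under both
  for (crit in c("f1", "f2")) {
    fs <- identify_founders(tree, crit)
    expect_true(all(vapply(fs, function(c) c$n, 1) > 0))
    expect_true(all(unlist(lapply(fs, function(c) c$members$distance)) >= 0))
  }
})

test_that("sink-only data collapses to a single root cluster with a warning", {
  h <- hvs1_haplotypes(paste0("s", 1:3), "pop", rep("sink", 3),
                       list(character(0), "16189C", c("16189C", "16217C")))
  tree <- root_network(reduced_median_network(h), "outgroup_consensus",
                       outgroup = character(0))
  expect_warning(fs <- identify_founders(tree, "f1"), "assigned to the root")
  expect_length(fs, 1)
  expect_equal(fs[[1]]$founder_node, tree$root)
  expect_equal(fs[[1]]$n, 3)
})

test_that("every sink sample belongs to exactly one cluster", {
  sc <- sim_scenario(data.frame(time_years = 3000, fraction = 1),
                     n_source = 60, n_sink = 50, seed = 5)
  sim <- simulate_two_deme(sc)
  fit <- suppressWarnings(founder_analysis(sim$data))
  ids <- unlist(lapply(fit$founders, function(c) c$members$sample_id))
  expect_equal(sort(ids), sort(sim$truth$sample_id))
})
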