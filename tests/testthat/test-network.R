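# median-joining and reduced-median construction, weighting, rooting

test_that("median-joining collapses duplicates and links single steps", {
  m2 <- rbind(a = c(1, 0), b = c(1, 0))
  colnames(m2) <- c("x", "y")
  net <- median_joining_network(m2)
  expect_equal(nrow(net$states), 1)
  expect_equal(nrow(net$edges), 0)
  expect_length(net$samples[[1]], 2)

  p <- str_profiles(c("s1", "s2"), "pop", c("source", "source"), "hg",
                    matrix(c(12L, 13L), 2, 1,
                           dimnames = list(NULL, "DYS393")))
  net <- median_joining_network(p)
  expect_equal(nrow(net$states), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$character, "DYS393")
})

test_that("the classic median triple gains one median node at length 3", {
  m <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1))
  colnames(m) <- paste0("v", 1:3)
  net <- median_joining_network(m, weights = stats::setNames(rep(1, 3),
                                                             colnames(m)))
  expect_equal(sum(net$kind == "median"), 1)
  expect_equal(net$cost, 3)
  expect_equal(net$cost, oracle_steiner_cost(m, rep(1, 3)))
})

test_that("network length matches the brute-force Steiner minimum on small inputs", {
  for (s in c(2, 7, 11, 19, 25, 33, 42, 55)) {
    n <- 3 + (s %% 4)
    p <- 4 + (s %% 2)
    m <- random_binary_haps(n, p, s)
    w <- stats::setNames(sample(1:3, p, replace = TRUE), colnames(m))
    net <- median_joining_network(m, weights = w)
    expect_equal(net$cost, oracle_steiner_cost(m, as.numeric(w)),
                 info = paste("fixture seed", s))
  }
})

test_that("every edge changes exactly one character by one step", {
  for (s in c(3, 14)) {
    m <- random_binary_haps(5, 5, s)
    net <- median_joining_network(m)
    for (e in seq_len(nrow(net$edges))) {
      d <- abs(net$states[net$edges$from[e], ] - net$states[net$edges$to[e], ])
      expect_equal(sum(d), 1)
      expect_equal(colnames(net$states)[d == 1], net$edges$character[e])
    }
  }
  # STR profiles two repeats apart are joined through a unit-step path
  p <- str_profiles(c("s1", "s2"), "pop", c("source", "source"), "hg",
                    matrix(c(12L, 14L), 2, 1,
                           dimnames = list(NULL, "DYS393")))
  net <- median_joining_network(p)
  expect_equal(nrow(net$edges), 2)
  expect_true(any(net$kind == "path"))
})

test_that("networks never cost more than the observed-only spanning tree", {
  for (s in 1:10) {
    m <- random_binary_haps(5, 6, s + 100)
    w <- stats::setNames(sample(1:5, 6, replace = TRUE), colnames(m))
    net <- median_joining_network(m, weights = w)
    expect_lte(net$cost, oracle_mst_cost(oracle_dist(m, as.numeric(w))) + 1e-9)
  }
})

test_that("reduced-median output on compatible data is the perfect phylogeny", {
  m <- rbind(r = c(0, 0, 0), a = c(1, 0, 0), ab = c(1, 1, 0), c = c(0, 0, 1))
  colnames(m) <- c("A", "B", "C")
  net <- reduced_median_network(m)
  expect_equal(nrow(net$edges), 3)       # one edge per variant character
  expect_setequal(net$edges$character, c("A", "B", "C"))

  single <- reduced_median_network(rbind(x = c(1, 0)))
  expect_equal(nrow(single$states), 1)
  expect_equal(nrow(single$edges), 0)
})

test_that("reduced-median resolves a reticulation by recurring the faster character", {
  m <- rbind(h1 = c(0, 0), h2 = c(1, 0), h3 = c(0, 1), h4 = c(1, 1))
  colnames(m) <- c("A", "B")
  net <- reduced_median_network(m, weights = c(A = 1, B = 10))
  # both resolutions enumerated: recurring A costs 2*1 + 10, recurring B 2*10 + 1
  expect_equal(net$cost, 12)
  expect_equal(sum(net$edges$character == "A"), 2)
  expect_equal(sum(net$edges$character == "B"), 1)
  # equal weights: reticulation kept
  net_eq <- reduced_median_network(m, weights = c(A = 5, B = 5))
  expect_equal(nrow(net_eq$edges), 4)
  expect_error(reduced_median_network(rbind(a = c(0, 2))), "binary")
})

test_that("occurrence counts map linearly onto reversed weights", {
  expect_equal(occurrence_weights(c(locusA = 9, locusB = 1)),
               c(locusA = 1L, locusB = 10L))
  expect_equal(occurrence_weights(c(a = 4, b = 4, c = 4)),
               c(a = 10L, b = 10L, c = 10L))
  expect_equal(unname(occurrence_weights(c(8, 1, 4.5))), c(1L, 10L, 6L))
})

test_that("iterative STR reweighting reaches a stable network", {
  # locus A mutates on every link, others never
  reps <- cbind(DYS393 = c(10L, 11L, 12L, 13L), DYS19 = 14L, DYS390 = 21L)
  p <- str_profiles(paste0("s", 1:4), "pop", rep("source", 4), "hg", reps)
  it <- iterate_str_weights(p)
  expect_true(it$scheme$converged)
  expect_lte(it$scheme$iteration_count, 3)
  expect_equal(unname(it$scheme$weights["DYS393"]), 1L)
  expect_equal(unname(it$scheme$weights["DYS19"]), 10L)
  expect_equal(unname(it$scheme$weights["DYS390"]), 10L)

  # all loci with equal occurrence counts keep the standard weight
  reps2 <- cbind(DYS393 = c(10L, 11L), DYS19 = c(14L, 15L))
  p2 <- str_profiles(c("a", "b"), "pop", rep("source", 2), "hg", reps2)
  it2 <- iterate_str_weights(p2)
  expect_true(it2$scheme$converged)
  expect_true(all(it2$scheme$weights == 10L))
  expect_error(iterate_str_weights(p2[1, ]), "two distinct")
})

test_that("midpoint and outgroup rooting pick the expected nodes", {
  # 3-node path a - b - c with unit weights: midpoint is b
  m <- rbind(a = c(0, 0), b = c(1, 0), c = c(1, 1))
  colnames(m) <- c("A", "B")
  net <- median_joining_network(m, weights = c(A = 1, B = 1))
  expect_equal(root_network(net, "midpoint")$root, "A")   # state of b

  # 5-leaf star around a hub: midpoint is the hub
  hub <- rbind(hub = c(0, 0, 0, 0, 0), diag(5))
  colnames(hub) <- paste0("v", 1:5)
  rownames(hub) <- c("hub", paste0("l", 1:5))
  net2 <- median_joining_network(hub,
                                 weights = stats::setNames(rep(1, 5),
                                                           colnames(hub)))
  expect_equal(root_network(net2, "midpoint")$root, "ref")

  # outgroup equal to an observed node roots there
  tr <- root_network(net, "outgroup_consensus", outgroup = c("16189C"))
  expect_equal(tr$root, "ref")  # token not segregating: nearest is ref
  tr2 <- root_network(net, "outgroup_consensus", outgroup = c(A = 1, B = 1))
  expect_equal(tr2$root, "A+B")
  expect_error(root_network(net, "outgroup_consensus"), "outgroup")
})

test_that("reweighting and construction are deterministic", {
  reps <- cbind(DYS393 = c(10L, 11L, 12L), DYS19 = c(14L, 14L, 15L))
  p <- str_profiles(paste0("s", 1:3), "pop", rep("source", 3), "hg", reps)
  a <- iterate_str_weights(p)
  b <- iterate_str_weights(p)
  expect_identical(a$scheme$weights, b$scheme$weights)
  expect_identical(a$network$edges, b$network$edges)
})
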