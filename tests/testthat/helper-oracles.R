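# Independent oracles and small fixture builders used across the suite.

# weighted L1 distance matrix between rows
oracle_dist <- function(m, w) {
  k <- nrow(m)
  d <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    d[i, j] <- sum(w * abs(m[i, ] - m[j, ]))
  d
}

# MST cost by naive Prim on a dense distance matrix
oracle_mst_cost <- function(d) {
  k <- nrow(d)
  if (k < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, k - 1))
  cost <- 0
  for (step in seq_len(k - 1)) {
    sub <- d[in_tree, !in_tree, drop = FALSE]
    cost <- cost + min(sub)
    pick <- which(!in_tree)[which(sub == min(sub), arr.ind = TRUE)[1, 2]]
    in_tree[pick] <- TRUE
  }
  cost
}

# median closure: repeatedly add component-wise medians of all triples
oracle_median_closure <- function(m, cap = 200) {
  keys <- apply(m, 1, paste, collapse = ",")
  repeat {
    k <- nrow(m)
    added <- FALSE
    for (i in seq_len(k)) for (j in seq_len(k)) for (l in seq_len(k)) {
      if (i >= j || j >= l) next
      s <- m[i, ] + m[j, ] + m[l, ]
      med <- s - pmax(m[i, ], m[j, ], m[l, ]) - pmin(m[i, ], m[j, ], m[l, ])
      key <- paste(med, collapse = ",")
      if (!key %in% keys) {
        m <- rbind(m, med)
        keys <- c(keys, key)
        added <- TRUE
      }
    }
    if (!added || nrow(m) > cap) break
  }
  m
}

# brute-force weighted Steiner minimum over median-closure candidates:
# exhaustively tries every subset of candidate median vectors as Steiner
# points and keeps the cheapest spanning tree
oracle_steiner_cost <- function(obs, w) {
  closure <- oracle_median_closure(obs)
  n_obs <- nrow(obs)
  cands <- if (nrow(closure) > n_obs)
    closure[(n_obs + 1):nrow(closure), , drop = FALSE] else NULL
  best <- oracle_mst_cost(oracle_dist(obs, w))
  if (!is.null(cands)) {
    nc <- nrow(cands)
    max_extra <- max(0, n_obs - 2)
    for (size in seq_len(min(nc, max_extra))) {
      subsets <- utils::combn(nc, size)
      for (col in seq_len(ncol(subsets))) {
        m <- rbind(obs, cands[subsets[, col], , drop = FALSE])
        best <- min(best, oracle_mst_cost(oracle_dist(m, w)))
      }
    }
  }
  best
}

# random binary haplotype fixture (distinct rows)
random_binary_haps <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n * p, 1, 0.4), n, p)
    if (!anyDuplicated(m)) break
  }
  colnames(m) <- paste0("v", seq_len(p))
  rownames(m) <- paste0("h", seq_len(n))
  m
}

# random rooted cluster tree with unit branches and random member placement
random_cluster <- function(seed, max_nodes = 8) {
  set.seed(seed)
  k <- sample(2:max_nodes, 1)
  parent <- c(NA, vapply(2:k, function(i) sample(i - 1, 1), 1L))
  nodes <- paste0("n", seq_len(k))
  member_nodes <- list()
  member_samples <- list()
  placed <- sample(2:k, sample(seq_len(k - 1), 1))
  sid <- 0
  for (v in placed) {
    cnt <- sample(1:3, 1)
    member_nodes[[nodes[v]]] <- cnt
    member_samples[[nodes[v]]] <- paste0("s", sid + seq_len(cnt))
    sid <- sid + cnt
  }
  tree <- list(nodes = nodes,
               parent = stats::setNames(c(NA, nodes[parent[-1]]), nodes))
  cl <- foundertrace:::cluster_from_tree(tree, nodes[1], member_nodes,
                                         member_samples)
  cl
}

# best-match recovery of true founder types by inferred clusters
membership_recovery <- function(sim, fit) {
  assign <- do.call(rbind, lapply(seq_along(fit$founders), function(i)
    data.frame(sample_id = fit$founders[[i]]$members$sample_id,
               cluster = i)))
  tr <- sim$truth
  tr$type <- sim$founders$state[match(tr$founder_id,
                                      sim$founders$founder_id)]
  mm <- merge(assign, tr, by = "sample_id")
  tab <- table(mm$cluster, mm$type)
  sum(apply(tab, 1, max)) / nrow(mm)
}

# minimal hand-built source/sink HVS-I fixture: root with two
# source-derived branches, one candidate with a single source-derived
# branch, two sink samples under it
founder_fixture <- function() {
  hvs1_haplotypes(
    sample_id = c("src1", "src3", "src4", "src5", "sink1", "sink2"),
    population = "fix",
    role = c("source", "source", "source", "source", "sink", "sink"),
    variants = list(character(0),            # src1 at the root state
                    "16090A",                # src3: candidate node A
                    c("16090A", "16140T"),   # src4: derived branch under A
                    "16200T",                # src5: second root branch
                    "16090A",                # sink1 at A
                    c("16090A", "16150C")))  # sink2 one step below A
}
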