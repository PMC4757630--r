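#' Simulation scenarios for two-deme founder analysis
#'
#' Defines a source/sink world with known migration history: source
#' diversity accrues along a Yule-like branching genealogy of the stated
#' depth; at each migration pulse a set of founder types is drawn from the
#' source lineages extant at the pulse time; sink lineages then descend
#' from those founders and mutate independently for pulse-time years.
#' HVS-I sequences evolve under a finite-sites model (mutations placed
#' uniformly over `n_sites` positions, recurrent mutation allowed); STR
#' profiles evolve under a strict single-step model (per-locus symmetric
#' +/-1 moves at the clock's per-locus rate).
#'
#' @param pulses data frame with columns `time_years` and `fraction`
#'   (fractions of sink lineages entering at each pulse; must sum to 1).
#' @param clock a `clock_spec`; a sequence clock yields HVS-I haplotypes,
#'   an STR clock yields Y-STR profiles.
#' @param n_source,n_sink sample sizes.
#' @param n_founders founder types drawn per pulse.
#' @param n_sites scored HVS-I positions (default 350, emulating
#'   16,051--16,400).
#' @param n_loci STR panel size (default 19).
#' @param source_depth_years age of the source genealogy.
#' @param growth_rate source expansion rate per year: split times follow a
#'   truncated-exponential density towards the present (default 6e-4,
#'   about 1.5 per cent per 25-year generation, typical of Holocene human
#'   expansions; 0 gives uniform split times).
#' @param n_clades number of ancient source clades: the first
#'   `n_clades - 1` splits are placed in the oldest quarter of the
#'   genealogy, emulating haplogroup structure (an ancient radiation whose
#'   clades each expand towards the present).
#' @param seed mandatory integer seed; identical seeds give byte-identical
#'   datasets.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(pulses, clock = clock_preset("hvs1"),
                         n_source = 500L, n_sink = 200L, n_founders = 6L,
                         n_sites = 350L, n_loci = 19L,
                         source_depth_years = 24000, growth_rate = 6e-4,
                         n_clades = 6L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  pulses <- as.data.frame(pulses)
  if (!all(c("time_years", "fraction") %in% names(pulses)))
    stop("pulses needs columns time_years and fraction", call. = FALSE)
  if (abs(sum(pulses$fraction) - 1) > 1e-8)
    stop("pulse fractions must sum to 1", call. = FALSE)
  if (any(pulses$time_years <= 0))
    stop("pulse times must be positive", call. = FALSE)
  if (any(pulses$time_years >= source_depth_years))
    stop("pulses must be younger than the source genealogy", call. = FALSE)
  structure(list(pulses = pulses, clock = clock,
                 n_source = as.integer(n_source),
                 n_sink = as.integer(n_sink),
                 n_founders = as.integer(n_founders),
                 n_sites = as.integer(n_sites), n_loci = as.integer(n_loci),
                 source_depth_years = source_depth_years,
                 growth_rate = growth_rate, n_clades = as.integer(n_clades),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

BASES <- c("A", "C", "G", "T")

# apply one mutation draw: u in 1..3 selects among the bases != current
mutate_base <- function(current, u) {
  alt <- (1:4)[-current]
  alt[u]
}

# ---- source genealogy ------------------------------------------------------

# Yule-like branching: one lineage at the stated depth splits until n tips
# are extant at the present.  Split times follow a truncated-exponential
# density proportional to exp(-growth_rate * t) on [0, depth], emulating a
# source population expanding towards the present (growth_rate = 0 gives
# uniform split times).  Returns per-node parent pointers, branch
# intervals and time-stamped mutation events.
simulate_source_tree <- function(n, depth, mut_rate_per_year, n_targets,
                                 growth_rate = 0, n_clades = 1L) {
  parent <- c(NA_integer_)
  t_birth <- c(depth)
  t_end <- c(NA_real_)
  extant <- c(1L)
  n_deep <- min(n_clades - 1L, n - 1L)
  u <- stats::runif(n - 1L - n_deep)
  recent <- if (growth_rate > 0) {
    -log(1 - u * (1 - exp(-growth_rate * depth))) / growth_rate
  } else {
    u * depth
  }
  deep <- if (n_deep > 0) stats::runif(n_deep, 0.75 * depth, depth) else
    numeric(0)
  splits <- sort(c(deep, recent), decreasing = TRUE)
  for (ts in splits) {
    l <- if (length(extant) == 1) extant else sample(extant, 1)
    t_end[l] <- ts
    for (k in 1:2) {
      parent <- c(parent, l)
      t_birth <- c(t_birth, ts)
      t_end <- c(t_end, NA_real_)
      extant <- c(extant, length(parent))
    }
    extant <- setdiff(extant, l)
  }
  t_end[is.na(t_end)] <- 0
  # mutations per branch: times, targets (site or locus), base/step draws
  muts <- lapply(seq_along(parent), function(i) {
    len <- t_birth[i] - t_end[i]
    k <- stats::rpois(1, len * mut_rate_per_year)
    if (k == 0) return(NULL)
    data.frame(time = stats::runif(k, t_end[i], t_birth[i]),
               target = sample.int(n_targets, k, replace = TRUE),
               draw = sample.int(3L, k, replace = TRUE),     # base choice
               step = c(1L, -1L)[sample.int(2L, k, replace = TRUE)])
  })
  list(parent = parent, t_birth = t_birth, t_end = t_end, tips = extant,
       muts = muts)
}

# number of sampled (modern) tips descending from each node
descendant_counts <- function(tree) {
  n <- length(tree$parent)
  cnt <- numeric(n)
  cnt[tree$tips] <- 1
  for (i in rev(seq_len(n))) {            # children always follow parents
    p <- tree$parent[i]
    if (!is.na(p)) cnt[p] <- cnt[p] + cnt[i]
  }
  cnt
}

# state of a lineage at time t BP (mutations older than t applied in order)
lineage_state_at <- function(tree, node, t, root_state, marker) {
  path <- integer(0)
  v <- node
  while (!is.na(v)) {
    path <- c(v, path)
    v <- tree$parent[v]
  }
  ev <- do.call(rbind, tree$muts[path])
  st <- root_state
  if (!is.null(ev) && nrow(ev)) {
    ev <- ev[ev$time > t, , drop = FALSE]
    ev <- ev[order(-ev$time), , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      tg <- ev$target[r]
      if (marker == "hvs1") {
        st[tg] <- mutate_base(st[tg], ev$draw[r])
      } else {
        st[tg] <- st[tg] + ev$step[r]
      }
    }
  }
  st
}

# ---- main generators -------------------------------------------------------

#' Simulate a two-deme source/sink dataset with known migration history
#'
#' See [sim_scenario()] for the generative model.  Sink lineages alive at
#' a pulse descend star-like from founder types drawn from the source
#' genealogy at the pulse time, so the true founder identity and entry
#' time of every sink sample are known.
#'
#' @param scenario a `sim_scenario`.
#' @return list with components `data` (an `hvs1_haplotypes` or
#'   `str_profiles` object containing source and sink samples with roles),
#'   `truth` (data frame `sample_id`, `founder_id`, `entry_time`),
#'   `founders` (data frame of founder types per pulse) and, for HVS-I,
#'   `reference` (the synthetic reference sequence used for variant
#'   notation).
#' @export
simulate_two_deme <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  sc <- scenario
  marker <- if (is_sequence_clock(sc$clock)) "hvs1" else "str"
  if (marker == "hvs1") {
    n_targets <- sc$n_sites
    rate_per_year <- 1 / sc$clock$years_per_mutation
    root_state <- sample.int(4L, sc$n_sites, replace = TRUE)
    reference <- BASES[root_state]
  } else {
    n_targets <- sc$n_loci
    rate_per_year <- sc$clock$rate_per_locus_per_year * sc$n_loci
    root_state <- rep(14L, sc$n_loci)
    reference <- NULL
  }

  tree <- simulate_source_tree(sc$n_source, sc$source_depth_years,
                               rate_per_year, n_targets,
                               growth_rate = sc$growth_rate,
                               n_clades = sc$n_clades)

  # modern source sample: state of each tip at the present
  source_states <- t(vapply(tree$tips, function(tp)
    lineage_state_at(tree, tp, 0, root_state, marker),
    integer(n_targets)))

  # Founder types per pulse: snapshots of lineages extant at the pulse.
  # A migrant is a random individual of the source population, so founder
  # types are drawn weighted by their share of the modern source sample
  # (common types are the likely founders).  Distinct pulses draw distinct
  # haplotype types where possible — founder analysis cannot in principle
  # separate the contributions of identical types carried twice, and the
  # emulated migrations carried distinguishable lineage packages.
  n_desc <- descendant_counts(tree)
  founders <- vector("list", nrow(sc$pulses))
  used_types <- character(0)
  for (p in order(-sc$pulses$time_years)) {  # oldest pulse first
    tp <- sc$pulses$time_years[p]
    alive <- which(tree$t_birth >= tp & tree$t_end <= tp)
    st_alive <- t(vapply(alive, function(l)
      lineage_state_at(tree, l, tp, root_state, marker),
      integer(n_targets)))
    labels <- apply(st_alive, 1, paste, collapse = ",")
    wt <- tapply(n_desc[alive], labels, sum)
    avail <- setdiff(names(wt), used_types)
    if (!length(avail)) avail <- names(wt)   # reuse only if unavoidable
    k <- min(sc$n_founders, length(avail))
    pick_types <- if (length(avail) == 1) avail else
      sample(avail, k, prob = wt[avail])
    used_types <- union(used_types, pick_types)
    founders[[p]] <- st_alive[match(pick_types, labels), , drop = FALSE]
    attr(founders[[p]], "type_weight") <- as.numeric(wt[pick_types])
  }

  # sink lineages: star-like descent from the pulse founders; each migrant
  # is a random individual, so founder types contribute in proportion to
  # their source frequency
  counts <- allocate_counts(sc$pulses$fraction, sc$n_sink)
  sink_states <- matrix(0L, sc$n_sink, n_targets)
  truth <- data.frame(sample_id = sprintf("sink_%03d", seq_len(sc$n_sink)),
                      founder_id = NA_character_,
                      entry_time = NA_real_, stringsAsFactors = FALSE)
  i <- 0L
  for (p in seq_len(nrow(sc$pulses))) {
    tp <- sc$pulses$time_years[p]
    for (s in seq_len(counts[p])) {
      i <- i + 1L
      fidx <- sample.int(nrow(founders[[p]]), 1,
                         prob = attr(founders[[p]], "type_weight"))
      st <- founders[[p]][fidx, ]
      k <- stats::rpois(1, tp * rate_per_year)
      if (k > 0) {
        tg <- sample.int(n_targets, k, replace = TRUE)
        dr <- sample.int(if (marker == "hvs1") 3L else 2L, k, replace = TRUE)
        for (r in seq_len(k)) {
          if (marker == "hvs1") {
            st[tg[r]] <- mutate_base(st[tg[r]], dr[r])
          } else {
            st[tg[r]] <- st[tg[r]] + c(1L, -1L)[dr[r]]
          }
        }
      }
      sink_states[i, ] <- st
      truth$founder_id[i] <- paste0("pulse", p, "_f", fidx)
      truth$entry_time[i] <- tp
    }
  }

  source_ids <- sprintf("src_%03d", seq_len(nrow(source_states)))
  if (marker == "hvs1") {
    tokens <- function(states) {
      lapply(seq_len(nrow(states)), function(r) {
        d <- which(states[r, ] != root_state)
        vapply(d, function(s) paste0(16050L + s, BASES[states[r, s]]), "")
      })
    }
    data <- hvs1_haplotypes(
      sample_id = c(source_ids, truth$sample_id),
      population = rep(c("source_pop", "sink_pop"),
                       c(length(source_ids), nrow(truth))),
      role = rep(c("source", "sink"), c(length(source_ids), nrow(truth))),
      variants = c(tokens(source_states), tokens(sink_states)))
    founder_tab <- founder_table(founders, sc, function(st) {
      d <- which(st != root_state)
      paste(vapply(d, function(s) paste0(16050L + s, BASES[st[s]]), ""),
            collapse = " ")
    })
    list(data = data, truth = truth, founders = founder_tab,
         reference = reference)
  } else {
    loci <- if (sc$n_loci <= length(YSTR_PANEL)) YSTR_PANEL[seq_len(sc$n_loci)]
            else paste0("L", seq_len(sc$n_loci))
    repeats <- rbind(source_states, sink_states)
    colnames(repeats) <- loci
    data <- str_profiles(
      sample_id = c(source_ids, truth$sample_id),
      population = rep(c("source_pop", "sink_pop"),
                       c(length(source_ids), nrow(truth))),
      role = rep(c("source", "sink"), c(length(source_ids), nrow(truth))),
      snp_haplogroup = "sim", repeats = repeats)
    founder_tab <- founder_table(founders, sc, function(st)
      paste(st, collapse = "-"))
    list(data = data, truth = truth, founders = founder_tab)
  }
}

founder_table <- function(founders, sc, fmt) {
  do.call(rbind, lapply(seq_along(founders), function(p) {
    data.frame(founder_id = paste0("pulse", p, "_f",
                                   seq_len(nrow(founders[[p]]))),
               pulse_time = sc$pulses$time_years[p],
               state = apply(founders[[p]], 1, fmt),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a star-like clade of known age
#'
#' All lineages descend independently from a single founder for
#' `age_years`, so the expected rho equals age times the total mutation
#' rate — the closed form inverted by [calibrate_str_rate()].
#'
#' @param n number of lineages (>= 2).
#' @param age_years clade age.
#' @param clock a `clock_spec` (STR clock gives repeat profiles, sequence
#'   clock gives HVS-I haplotypes).
#' @param n_loci,n_sites panel/segment sizes.
#' @param seed mandatory seed.
#' @return list with `data` (profiles/haplotypes, role `"sink"`) and
#'   `founder` (the founder state vector).
#' @export
simulate_star_clade <- function(n, age_years, clock, n_loci = 19L,
                                n_sites = 350L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n >= 2, age_years >= 0)
  set.seed(seed)
  if (is_sequence_clock(clock)) {
    root_state <- sample.int(4L, n_sites, replace = TRUE)
    rate <- 1 / clock$years_per_mutation
    n_targets <- n_sites
  } else {
    root_state <- rep(14L, n_loci)
    rate <- clock$rate_per_locus_per_year * n_loci
    n_targets <- n_loci
  }
  states <- matrix(0L, n, n_targets)
  for (i in seq_len(n)) {
    st <- root_state
    k <- stats::rpois(1, age_years * rate)
    if (k > 0) {
      tg <- sample.int(n_targets, k, replace = TRUE)
      dr <- sample.int(if (is_sequence_clock(clock)) 3L else 2L, k,
                       replace = TRUE)
      for (r in seq_len(k)) {
        if (is_sequence_clock(clock)) {
          st[tg[r]] <- mutate_base(st[tg[r]], dr[r])
        } else {
          st[tg[r]] <- st[tg[r]] + c(1L, -1L)[dr[r]]
        }
      }
    }
    states[i, ] <- st
  }
  ids <- sprintf("clade_%03d", seq_len(n))
  if (is_sequence_clock(clock)) {
    variants <- lapply(seq_len(n), function(r) {
      d <- which(states[r, ] != root_state)
      vapply(d, function(s) paste0(16050L + s, BASES[states[r, s]]), "")
    })
    data <- hvs1_haplotypes(ids, "clade", rep("sink", n), variants)
  } else {
    loci <- if (n_loci <= length(YSTR_PANEL)) YSTR_PANEL[seq_len(n_loci)]
            else paste0("L", seq_len(n_loci))
    colnames(states) <- loci
    data <- str_profiles(ids, "clade", rep("sink", n), "sim", states)
  }
  list(data = data, founder = root_state)
}
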