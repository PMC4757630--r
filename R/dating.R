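#' Founder clusters
#'
#' A founder cluster collects the sink-side samples descending from one
#' founder haplotype, together with the statistics used to date it: the
#' rho statistic (mean mutational distance of members to the founder), the
#' Saillard standard error sigma, which accounts for shared internal
#' branches in non-star-like genealogies, and the star-equivalent
#' effective sample size n_eff = rho / sigma^2 — the number of independent
#' lineages a perfectly star-like cluster would need to give the same
#' uncertainty.  n_eff never exceeds the actual member count, with
#' equality exactly when the cluster subtree is star-like.
#'
#' @param founder_node label of the founder haplotype state.
#' @param members data frame with columns `sample_id`, `node`, `distance`
#'   (mutation steps from the member's node to the founder).
#' @param branch_lengths,branch_members parallel vectors describing the
#'   cluster subtree: for every branch segment its length in mutations and
#'   the number of members descending through it.  For a star these are
#'   unit branches with one member each.
#' @return an object of class `founder_cluster`.
#' @export
founder_cluster <- function(founder_node, members, branch_lengths,
                            branch_members) {
  n <- nrow(members)
  if (n == 0) stop("founder cluster has zero members", call. = FALSE)
  m <- sum(members$distance)
  rho <- m / n
  sigma <- saillard_sigma(branch_lengths, branch_members, n)
  structure(list(founder_node = founder_node, members = members,
                 n = n, m = m, rho = rho, sigma = sigma,
                 n_eff = effective_n(rho, sigma, n = n)),
            class = "founder_cluster")
}

#' @export
print.founder_cluster <- function(x, ...) {
  cat("Founder cluster at '", x$founder_node, "': n = ", x$n,
      ", rho = ", format(round(x$rho, 4)),
      ", sigma = ", format(round(x$sigma, 4)),
      ", n_eff = ", format(round(x$n_eff, 2)), "\n", sep = "")
  if (!is.null(x$age))
    cat("  age:", round(x$age$age), "years [",
        round(x$age$lower), ";", round(x$age$upper), "]\n")
  invisible(x)
}

#' The rho statistic
#'
#' Mean number of mutations separating cluster members from the founder
#' node; an unbiased estimator of the expected mutation count since
#' founding, convertible to years via a molecular clock.
#'
#' @param x a `founder_cluster`, or a numeric vector of per-member
#'   mutational distances.
#' @return mean distance (numeric scalar).
#' @examples
#' rho(c(0, 1, 1, 2))  # 1
#' @export
rho <- function(x) UseMethod("rho")

#' @export
rho.founder_cluster <- function(x) x$rho

#' @export
rho.default <- function(x) {
  if (!length(x)) stop("zero members", call. = FALSE)
  mean(x)
}

#' Saillard standard error of rho
#'
#' For a rooted cluster subtree decomposed into branch segments with
#' lengths `l` (mutations) and member counts `b` (samples descending
#' through each segment), the variance of rho is sum(b^2 * l) / n^2.  For
#' a star-like cluster this reduces to rho / n; in general
#' sigma^2 >= rho / n, with equality only for stars.
#'
#' @param l branch lengths in mutations.
#' @param b members descending through each branch.
#' @param n number of members.
#' @return sigma (numeric scalar).
#' @examples
#' saillard_sigma(rep(1, 4), rep(1, 4), 4)    # star of 4: sqrt(1/4)
#' saillard_sigma(c(1, 1, 1), c(2, 1, 1), 2)  # shared branch: sqrt(1.5)
#' @export
saillard_sigma <- function(l, b, n) {
  if (n <= 0) stop("zero members", call. = FALSE)
  stopifnot(length(l) == length(b))
  sqrt(sum(b^2 * l)) / n
}

#' Star-equivalent effective sample size
#'
#' The number of samples a completely star-like cluster would need to
#' match the uncertainty of the observed one: n_eff = rho / sigma^2.  When
#' rho is zero the cluster carries no mutational information and n_eff is
#' defined as the actual sample count.
#'
#' @param rho,sigma cluster statistics.
#' @param n actual member count (required when rho = 0).
#' @return effective sample size (numeric scalar).
#' @export
effective_n <- function(rho, sigma, n = NULL) {
  if (rho == 0) {
    if (is.null(n)) stop("n required when rho = 0", call. = FALSE)
    return(as.numeric(n))
  }
  rho / sigma^2
}

#' Convert rho to an age with a molecular clock
#'
#' Sequence clocks: age = rho x years-per-mutation.  STR clocks: rho is
#' the mean total repeat displacement per lineage across the panel, and
#' age = rho / (rate x n_loci).  The +/- 1 sigma interval is converted
#' identically and floored at zero.
#'
#' @param rho,sigma cluster statistics (sigma may be 0).
#' @param clock a `clock_spec`.
#' @param n_loci number of STR loci scored (required for STR clocks).
#' @return list with `age`, `lower`, `upper` (years), class `age_estimate`.
#' @examples
#' age_estimate(1, 0, clock_preset("hvs1"))$age  # 16677
#' @export
age_estimate <- function(rho, sigma = 0, clock, n_loci = NULL) {
  stopifnot(inherits(clock, "clock_spec"))
  if (is_sequence_clock(clock)) {
    f <- clock$years_per_mutation
  } else {
    if (is.null(n_loci))
      stop("n_loci required for an STR clock", call. = FALSE)
    f <- 1 / (clock$rate_per_locus_per_year * n_loci)
  }
  out <- list(age = max(0, rho * f),
              lower = max(0, (rho - sigma) * f),
              upper = max(0, (rho + sigma) * f),
              clock = clock$name)
  class(out) <- "age_estimate"
  out
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(round(x$age), "years [", round(x$lower), ";", round(x$upper),
      "] (", x$clock, "clock )\n")
  invisible(x)
}

#' Calibrate an average STR mutation rate from a clade of known age
#'
#' Inverts the STR age formula on a dated clade: given the clade's rho (in
#' total repeat steps per lineage over the panel) and an externally
#' established age — e.g. the radiocarbon-dated settlement of Remote
#' Oceania at 3,000 years for its star-like Y-STR clade — the average rate
#' per locus per year is rho / (age x n_loci).
#'
#' @param clade a `founder_cluster`, or a numeric rho value.
#' @param assumed_age_years externally established clade age (> 0).
#' @param n_loci number of STR loci in the panel.
#' @return mutations per locus per year.
#' @examples
#' calibrate_str_rate(2.3256, 3000, 19)  # 4.08e-05
#' @export
calibrate_str_rate <- function(clade, assumed_age_years, n_loci) {
  r <- if (inherits(clade, "founder_cluster")) clade$rho else as.numeric(clade)
  stopifnot(assumed_age_years > 0, n_loci > 0)
  if (r == 0)
    stop("clade rho is zero: calibration is uninformative", call. = FALSE)
  r / (assumed_age_years * n_loci)
}

# ---- clusters from rooted trees -------------------------------------------

# build a founder_cluster from a rooted tree: members are the given sink
# samples sitting at nodes of the tree; branch decomposition follows the
# union of member-to-founder paths (unit-step edges).
cluster_from_tree <- function(tree, founder, member_nodes, member_samples) {
  path_up <- function(v) {
    p <- character(0)
    while (v != founder) {
      p <- c(p, v)
      v <- tree$parent[v]
      if (is.na(v)) stop("node not below founder", call. = FALSE)
    }
    p
  }
  edge_members <- list()
  members <- NULL
  for (nd in names(member_nodes)) {
    cnt <- member_nodes[[nd]]
    pth <- path_up(nd)                    # edges identified by child node
    for (ch in pth)
      edge_members[[ch]] <- (edge_members[[ch]] %||% 0) + cnt
    members <- rbind(members,
                     data.frame(sample_id = member_samples[[nd]],
                                node = nd,
                                distance = length(pth),
                                stringsAsFactors = FALSE))
  }
  b <- unlist(edge_members) %||% numeric(0)
  founder_cluster(founder, members,
                  branch_lengths = rep(1, length(b)), branch_members = b)
}

# treat an entire rooted tree as one clade: all observed samples are
# members, the root is the founder (used e.g. for STR rate calibration)
clade_cluster <- function(tree, roles = c("source", "sink", "excluded")) {
  member_nodes <- list(); member_samples <- list()
  for (v in tree$nodes) {
    s <- tree$samples[[v]]
    if (is.null(s) || !length(s)) next
    keep <- rowSums(tree$roles[v, roles, drop = FALSE]) > 0
    if (!keep) next
    member_nodes[[v]] <- length(s)
    member_samples[[v]] <- s
  }
  cluster_from_tree(tree, tree$root, member_nodes, member_samples)
}
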