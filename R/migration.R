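#' Migration models
#'
#' A migration model fixes a small set of candidate migration event times
#' (years before present) with a prior over them.  Presets follow the
#' four-migration models used for Island Southeast Asia: recent gene flow
#' at 0.5 ka, Neolithic immigration at 4.5 ka, postglacial expansions at
#' 8 ka, and first settlement at 50 ka for mtDNA or 20 ka for Y-STR data
#' (STR dating saturates for ancient clades, so the older event is placed
#' at the observed 20 ka peak instead).
#'
#' @param event_times strictly increasing positive times in years BP.
#' @param prior probability vector over the events (default uniform).
#' @return an object of class `migration_model`.
#' @export
migration_model <- function(event_times, prior = NULL) {
  event_times <- as.numeric(event_times)
  if (any(event_times <= 0) || is.unsorted(event_times, strictly = TRUE))
    stop("event times must be strictly increasing and positive",
         call. = FALSE)
  if (is.null(prior)) prior <- rep(1 / length(event_times),
                                   length(event_times))
  if (length(prior) != length(event_times) ||
      abs(sum(prior) - 1) > 1e-8 || any(prior < 0))
    stop("prior must be a probability vector over the events", call. = FALSE)
  structure(list(event_times = event_times, prior = prior / sum(prior)),
            class = "migration_model")
}

#' @rdname migration_model
#' @param marker `"mtdna"` (0.5/4.5/8/50 ka) or `"ystr"` (0.5/4.5/8/20 ka).
#' @export
migration_model_preset <- function(marker = c("mtdna", "ystr")) {
  marker <- match.arg(marker)
  times <- if (marker == "mtdna") c(500, 4500, 8000, 50000)
           else c(500, 4500, 8000, 20000)
  migration_model(times)
}

#' @export
print.migration_model <- function(x, ...) {
  cat("Migration model: events at",
      paste(x$event_times / 1000, collapse = ", "), "ka; prior",
      paste(round(x$prior, 3), collapse = "/"), "\n")
  invisible(x)
}

#' Posterior probability of migration times for one founder cluster
#'
#' The likelihood of an entry time T uses a continuous-Poisson form with
#' the cluster's star-equivalent effective sample size: the effective
#' mutation count is m = n_eff x rho, the expected count under T is
#' lambda(T) = n_eff x T / Q for a sequence clock with Q years per
#' mutation (or n_eff x T x rate x n_loci for an STR clock), and
#' L(T) is proportional to lambda^m exp(-lambda).  Computation is in log
#' space, so the likelihood never underflows to an all-zero row.  A
#' cluster with no mutations (m = 0) carries no coalescent information
#' beyond recency and resolves to the youngest candidate time as a point
#' mass.
#'
#' @param cluster a `founder_cluster`.
#' @param times candidate times in years BP.
#' @param prior prior over `times` (default uniform).
#' @param clock a `clock_spec`.
#' @param n_loci panel size for STR clocks.
#' @return posterior probability vector over `times` (sums to 1).
#' @export
migration_posterior <- function(cluster, times, prior = NULL, clock,
                                n_loci = NULL) {
  stopifnot(inherits(cluster, "founder_cluster"),
            inherits(clock, "clock_spec"))
  times <- as.numeric(times)
  if (is.null(prior)) prior <- rep(1 / length(times), length(times))
  stopifnot(length(prior) == length(times))
  n_eff <- cluster$n_eff
  m_eff <- n_eff * cluster$rho
  rate_per_year <- if (is_sequence_clock(clock)) {
    1 / clock$years_per_mutation
  } else {
    if (is.null(n_loci)) stop("n_loci required for an STR clock",
                              call. = FALSE)
    clock$rate_per_locus_per_year * n_loci
  }
  if (m_eff == 0) {
    post <- as.numeric(times == min(times))
    return(post / sum(post))
  }
  lambda <- n_eff * times * rate_per_year
  loglik <- ifelse(lambda > 0, m_eff * log(lambda) - lambda, -Inf)
  logpost <- loglik + log(prior)
  post <- exp(logpost - logsumexp(logpost))
  post / sum(post)
}

#' Migration-time scan
#'
#' Evaluates every founder cluster's migration-time posterior on a regular
#' grid (by default 0 to 70,000 years BP in 200-year intervals, 351
#' points) and aggregates across founders weighting by sink sample count,
#' giving a probabilistic profile of immigration bursts.
#'
#' @param founders a `founder_clusters` list (or list of
#'   `founder_cluster`).
#' @param clock a `clock_spec`.
#' @param grid_start,grid_end,step scan grid in years BP.
#' @param prior optional prior over grid points.
#' @param n_loci panel size for STR clocks.
#' @return an object of class `migration_scan` with `grid`,
#'   `per_founder` (founder x grid matrix of posteriors) and `aggregate`.
#' @export
scan_migrations <- function(founders, clock, grid_start = 0,
                            grid_end = 70000, step = 200, prior = NULL,
                            n_loci = NULL) {
  if (!length(founders)) stop("empty founder list", call. = FALSE)
  grid <- seq(grid_start, grid_end, by = step)
  per <- t(vapply(founders, function(cl)
    migration_posterior(cl, grid, prior, clock, n_loci),
    numeric(length(grid))))
  rownames(per) <- vapply(founders, function(cl) cl$founder_node, "")
  colnames(per) <- grid
  n <- vapply(founders, function(cl) cl$n, 1)
  aggregate <- as.numeric(t(per) %*% (n / sum(n)))
  structure(list(grid = grid, per_founder = per, aggregate = aggregate,
                 weights = n, clock = clock$name),
            class = "migration_scan")
}

#' @export
print.migration_scan <- function(x, ...) {
  cat("Migration-time scan:", nrow(x$per_founder), "founders on",
      length(x$grid), "grid points (", x$grid[1], "-",
      x$grid[length(x$grid)], "years )\n")
  cat("  aggregate mode at", scan_mode(x), "years BP\n")
  invisible(x)
}

#' Mode of the aggregate scan profile
#' @param scan a `migration_scan`.
#' @return grid time (years BP) with maximal aggregate probability.
#' @export
scan_mode <- function(scan) scan$grid[which.max(scan$aggregate)]

#' @export
plot.migration_scan <- function(x, ...) {
  graphics::plot(x$grid / 1000, x$aggregate, type = "l",
                 xlab = "years BP (ka)",
                 ylab = "aggregate migration probability", ...)
  invisible(x)
}

#' Partition founders among fixed migration events
#'
#' Computes each founder cluster's posterior over the model's event times
#' and the overall per-event fractions, weighting founders by their sink
#' sample counts so that fractions describe the sampled sink population.
#'
#' @param founders a `founder_clusters` list.
#' @param model a `migration_model`.
#' @param clock a `clock_spec`.
#' @param n_loci panel size for STR clocks.
#' @return an object of class `migration_partition` with `per_founder`
#'   (founder x event probability matrix) and `fractions`.
#' @export
partition_migrations <- function(founders, model, clock, n_loci = NULL) {
  if (!length(founders)) stop("empty founder list", call. = FALSE)
  stopifnot(inherits(model, "migration_model"))
  per <- t(vapply(founders, function(cl)
    migration_posterior(cl, model$event_times, model$prior, clock, n_loci),
    numeric(length(model$event_times))))
  rownames(per) <- vapply(founders, function(cl) cl$founder_node, "")
  colnames(per) <- model$event_times
  n <- vapply(founders, function(cl) cl$n, 1)
  fractions <- as.numeric(t(per) %*% (n / sum(n)))
  names(fractions) <- model$event_times
  structure(list(event_times = model$event_times, per_founder = per,
                 fractions = fractions, weights = n,
                 criterion = founders[[1]]$criterion %||% NA_character_,
                 clock = clock$name),
            class = "migration_partition")
}

#' @export
print.migration_partition <- function(x, ...) {
  cat("Migration partition (criterion ", x$criterion, "):\n", sep = "")
  print(round(stats::setNames(x$fractions,
                              paste0(x$event_times / 1000, " ka")), 3))
  invisible(x)
}
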