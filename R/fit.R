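#' Founder analysis of a source/sink haplotype dataset
#'
#' The central fitting function of the package.  Given HVS-I haplotypes or
#' Y-STR profiles with source/sink roles, it (1) builds a haplotype
#' network — reduced-median for HVS-I, median-joining with iterative locus
#' reweighting for STRs; (2) roots it; (3) identifies founder clusters in
#' the sink under the chosen criterion; (4) dates each cluster with the
#' rho statistic, Saillard errors and star-equivalent effective sample
#' sizes; and (5) runs the Bayesian migration-time scan and, if event
#' times are supplied (or left at the marker's preset), the fixed-window
#' migration partition.
#'
#' @param data an `hvs1_haplotypes` or `str_profiles` object with roles.
#' @param clock a `clock_spec`; defaults to the HVS-I clock for sequence
#'   data and the calibrated Y-STR rate for profiles.
#' @param criterion founder stringency, `"f1"` (>= 1 source-derived branch)
#'   or `"f2"` (>= 2).
#' @param weights `"iterate"` (STR default: iterative reweighting),
#'   `"flat"`, or an explicit weight vector / `weight_scheme`.
#' @param root_method `"outgroup"` or `"midpoint"`.  The default outgroup
#'   for HVS-I data is the ancestral reference state (no variants); for
#'   STR data, when no outgroup is given, midpoint rooting is used.
#' @param outgroup outgroup profile for outgroup rooting (see
#'   [root_network()]).
#' @param events migration event times in years BP, a `migration_model`,
#'   or `NULL` for the marker preset (mtDNA 0.5/4.5/8/50 ka; Y-STR
#'   0.5/4.5/8/20 ka).
#' @param scan_end,scan_step migration-time scan grid (default 0--70 ka at
#'   200-year intervals).
#' @param epsilon network relaxation parameter.
#' @return an object of class `founder_analysis` with components
#'   `network`, `tree`, `founders`, `scan`, `partition`, `clock`,
#'   `criterion`, `n_loci` and `call`; see [summary.founder_analysis()].
#' @examples
#' sc <- sim_scenario(data.frame(time_years = 4500, fraction = 1),
#'                    n_source = 30, n_sink = 40, seed = 7)
#' sim <- simulate_two_deme(sc)
#' fit <- founder_analysis(sim$data)
#' coef(fit)               # per-event migration fractions
#' @export
founder_analysis <- function(data, clock = NULL,
                             criterion = c("f1", "f2"),
                             weights = NULL,
                             root_method = c("outgroup", "midpoint"),
                             outgroup = NULL, events = NULL,
                             scan_end = 70000, scan_step = 200,
                             epsilon = 0) {
  criterion <- match.arg(criterion)
  root_method <- match.arg(root_method)
  cl <- match.call()

  if (inherits(data, "hvs1_haplotypes")) {
    marker <- "hvs1"
    clock <- clock %||% clock_preset("hvs1")
    n_loci <- NULL
    wts <- if (is.null(weights) || identical(weights, "flat")) NULL
           else if (identical(weights, "iterate"))
             stop("iterative reweighting applies to STR profiles",
                  call. = FALSE)
           else weights
    network <- reduced_median_network(data, weights = wts,
                                      epsilon = epsilon)
    scheme <- NULL
    if (root_method == "outgroup" && is.null(outgroup))
      outgroup <- character(0)            # ancestral reference state
  } else if (inherits(data, "str_profiles")) {
    marker <- "str"
    clock <- clock %||% clock_preset("ystr_calibrated")
    n_loci <- length(attr(data, "loci"))
    if (is.null(weights) || identical(weights, "iterate")) {
      it <- iterate_str_weights(data, epsilon = epsilon)
      network <- it$network
      scheme <- it$scheme
    } else {
      wts <- if (identical(weights, "flat")) NULL else weights
      network <- median_joining_network(data, weights = wts,
                                        epsilon = epsilon)
      scheme <- NULL
    }
    if (root_method == "outgroup" && is.null(outgroup))
      root_method <- "midpoint"
  } else {
    stop("data must be hvs1_haplotypes or str_profiles", call. = FALSE)
  }

  tree <- if (root_method == "midpoint") {
    root_network(network, "midpoint")
  } else {
    root_network(network, "outgroup_consensus", outgroup = outgroup)
  }

  founders <- identify_founders(tree, criterion)
  scan <- scan_migrations(founders, clock, grid_end = scan_end,
                          step = scan_step, n_loci = n_loci)
  model <- if (is.null(events)) {
    migration_model_preset(if (marker == "hvs1") "mtdna" else "ystr")
  } else if (inherits(events, "migration_model")) {
    events
  } else {
    migration_model(events)
  }
  partition <- partition_migrations(founders, model, clock,
                                    n_loci = n_loci)

  structure(list(call = cl, marker = marker, clock = clock,
                 criterion = criterion, network = network,
                 weight_scheme = scheme, tree = tree, founders = founders,
                 scan = scan, partition = partition, model = model,
                 n_loci = n_loci),
            class = "founder_analysis")
}

#' @export
print.founder_analysis <- function(x, ...) {
  cat("Founder analysis (", if (x$marker == "hvs1") "mtDNA HVS-I"
      else "Y-STR", ", criterion ", x$criterion, ")\n", sep = "")
  cat("  network:", nrow(x$network$states), "nodes, cost",
      format(x$network$cost), "; root '", x$tree$root, "'\n")
  cat("  founders:", length(x$founders), "clusters,",
      sum(vapply(x$founders, function(c) c$n, 1)), "sink samples\n")
  cat("  scan mode:", scan_mode(x$scan), "years BP\n")
  cat("  partition fractions:\n")
  print(round(stats::setNames(x$partition$fractions,
                              paste0(x$model$event_times / 1000, " ka")), 3))
  invisible(x)
}

#' Summarise a founder analysis
#'
#' @param object a `founder_analysis` fit.
#' @param ... unused.
#' @return list with the per-founder table (rho, sigma, effective n, age)
#'   and the migration fractions, class `summary.founder_analysis`.
#' @export
summary.founder_analysis <- function(object, ...) {
  structure(list(marker = object$marker, criterion = object$criterion,
                 clock = object$clock$name,
                 founders = summary(object$founders, clock = object$clock,
                                    n_loci = object$n_loci),
                 scan_mode = scan_mode(object$scan),
                 fractions = object$partition$fractions,
                 event_times = object$model$event_times),
            class = "summary.founder_analysis")
}

#' @export
print.summary.founder_analysis <- function(x, ...) {
  cat("Founder analysis summary (", x$marker, ", criterion ", x$criterion,
      ", clock ", x$clock, ")\n\n", sep = "")
  print(cbind(x$founders[, c("founder", "n", "rho", "sigma", "n_eff")],
              age = round(x$founders$age)), digits = 4)
  cat("\nScan mode:", x$scan_mode, "years BP\n")
  cat("Migration fractions:\n")
  print(round(stats::setNames(x$fractions,
                              paste0(x$event_times / 1000, " ka")), 3))
  invisible(x)
}

#' @export
coef.founder_analysis <- function(object, ...) {
  stats::setNames(object$partition$fractions,
                  paste0(object$model$event_times / 1000, " ka"))
}

#' @export
plot.founder_analysis <- function(x, ...) {
  graphics::plot(x$scan$grid / 1000, x$scan$aggregate, type = "l",
                 xlab = "migration time (ka BP)",
                 ylab = "aggregate posterior probability",
                 main = paste0("Migration-time scan (", x$criterion, ")"),
                 ...)
  graphics::abline(v = x$model$event_times / 1000, lty = 3,
                   col = "grey50")
  invisible(x)
}
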