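#' Molecular clock specifications
#'
#' A clock converts a mutation count per lineage (the rho statistic) into
#' years.  Sequence clocks are expressed as years per mutation over the
#' scored range; STR clocks as mutations per locus per year, so that an age
#' follows from the mean total repeat displacement per lineage divided by
#' (rate x number of loci).
#'
#' Built-in presets:
#' \describe{
#'   \item{`hvs1`}{HVS-I control-region clock for rCRS positions
#'     16,051--16,400: one mutation every 16,677 years.}
#'   \item{`mtdna_phylo`}{Whole-mtDNA phylogenetic clock corrected for
#'     purifying selection: one mutation every 3,624 years.}
#'   \item{`synonymous`}{Whole-mtDNA synonymous clock: one substitution
#'     every 7,884 years.}
#'   \item{`ystr_calibrated`}{19-locus Y-STR rate calibrated on the
#'     settlement of Remote Oceania: 4.08e-5 mutations per locus per year.}
#'   \item{`ystr_zhivotovsky`}{Evolutionary Y-STR rate of Zhivotovsky et
#'     al.: 6.9e-4 per 25 years, i.e. 2.76e-5 mutations per locus per year.}
#' }
#'
#' @param name preset name, or use `clock_spec()` to build a custom clock.
#' @return an object of class `clock_spec` with fields `name`, exactly one
#'   of `years_per_mutation` / `rate_per_locus_per_year`, and
#'   `applicable_range`.
#' @examples
#' clock_preset("hvs1")
#' clock_spec("pedigree", rate_per_locus_per_year = 2e-3)
#' @export
clock_preset <- function(name = c("hvs1", "mtdna_phylo", "synonymous",
                                  "ystr_calibrated", "ystr_zhivotovsky")) {
  name <- match.arg(name)
  switch(name,
    hvs1 = clock_spec("hvs1", years_per_mutation = 16677,
                      applicable_range = "HVS-I 16051-16400"),
    mtdna_phylo = clock_spec("mtdna_phylo", years_per_mutation = 3624,
                             applicable_range = "whole mtDNA, selection-corrected"),
    synonymous = clock_spec("synonymous", years_per_mutation = 7884,
                            applicable_range = "whole mtDNA, synonymous sites"),
    ystr_calibrated = clock_spec("ystr_calibrated",
                                 rate_per_locus_per_year = 4.08e-5,
                                 applicable_range = "19-locus Y-STR panel"),
    ystr_zhivotovsky = clock_spec("ystr_zhivotovsky",
                                  rate_per_locus_per_year = zhivotovsky_rate(),
                                  applicable_range = "Y-STR evolutionary rate")
  )
}

#' @rdname clock_preset
#' @param years_per_mutation years per mutation for a sequence clock.
#' @param rate_per_locus_per_year mutations per locus per year for an STR
#'   clock.  Exactly one of the two rates must be given.
#' @param applicable_range free-text descriptor of where the clock applies.
#' @export
clock_spec <- function(name, years_per_mutation = NULL,
                       rate_per_locus_per_year = NULL,
                       applicable_range = "") {
  if (is.null(years_per_mutation) == is.null(rate_per_locus_per_year))
    stop("exactly one of 'years_per_mutation' and 'rate_per_locus_per_year' ",
         "must be set", call. = FALSE)
  if (!is.null(years_per_mutation) &&
      (!is.numeric(years_per_mutation) || years_per_mutation <= 0))
    stop("'years_per_mutation' must be a positive number", call. = FALSE)
  if (!is.null(rate_per_locus_per_year) &&
      (!is.numeric(rate_per_locus_per_year) || rate_per_locus_per_year <= 0))
    stop("'rate_per_locus_per_year' must be a positive number", call. = FALSE)
  structure(list(name = as.character(name)[1],
                 years_per_mutation = years_per_mutation,
                 rate_per_locus_per_year = rate_per_locus_per_year,
                 applicable_range = applicable_range),
            class = "clock_spec")
}

#' @export
print.clock_spec <- function(x, ...) {
  cat("Clock:", x$name, "\n")
  if (is_sequence_clock(x)) {
    cat("  one mutation every", format(x$years_per_mutation), "years\n")
  } else {
    cat("  ", format(x$rate_per_locus_per_year),
        "mutations per locus per year\n")
  }
  if (nzchar(x$applicable_range)) cat("  range:", x$applicable_range, "\n")
  invisible(x)
}

is_sequence_clock <- function(clock) !is.null(clock$years_per_mutation)

#' Convert the Zhivotovsky effective Y-STR rate to a per-year rate
#'
#' The widely used evolutionary Y-STR mutation rate is quoted as 6.9e-4
#' mutations per 25 years per locus; per year that is 2.76e-5.
#'
#' @param rate_per_25y mutations per locus per 25-year generation.
#' @return mutations per locus per year.
#' @examples
#' zhivotovsky_rate()  # 2.76e-05
#' @export
zhivotovsky_rate <- function(rate_per_25y = 6.9e-4) {
  stopifnot(is.numeric(rate_per_25y), rate_per_25y > 0)
  rate_per_25y / 25
}
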