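#' Configuration for the five-point dispersal-marker test
#'
#' A clear-cut "out-of-Taiwan" marker is expected to satisfy five
#' phylogeographic criteria: (a) the window in which rice-agriculturists
#' reached Taiwan from South China (~6--8 ka) is bracketed by the age of
#' the ancestral mainland clade above and the insular subclade below;
#' (b) the insular, Austronesian-specific subclade arose after that
#' arrival (~5.5 ka) but before the out-of-Taiwan dispersal (~4.5 ka);
#' (c) the founder age into the sink (ISEA) is ~4.5 ka; (d) the founder
#' age from the extended source (Taiwan plus the Philippines) into the
#' rest of the sink is below ~4 ka; and (e) the clade's demographic
#' expansion in the source predates its expansion in the sink.
#'
#' Point-estimate semantics are used, with a symmetric tolerance for (c)
#' and (d) and an onset margin for (e); these are the loosest symmetric
#' rules consistent with the three reference verdict sets.
#'
#' @param arrival_window window of agriculturist arrival in the source, ka.
#' @param clade_window admissible insular subclade ages, ka.
#' @param founder_target expected sink founder age, ka.
#' @param extended_founder_bound upper bound for the extended-source
#'   founder age, ka.
#' @param tolerance symmetric tolerance for (c) and (d), ka.
#' @param onset_margin minimum lead of the source expansion onset over the
#'   sink onset for (e), ka.
#' @param use_intervals if `TRUE`, criteria (b)--(d) use
#'   confidence-interval overlap (from `marker_ages(intervals = ...)`)
#'   instead of point estimates; the default is point-estimate semantics.
#' @return an object of class `criteria_config`.
#' @export
criteria_config <- function(arrival_window = c(6, 8),
                            clade_window = c(4.5, 5.5),
                            founder_target = 4.5,
                            extended_founder_bound = 4,
                            tolerance = 0.5,
                            onset_margin = 0.5,
                            use_intervals = FALSE) {
  stopifnot(arrival_window[1] < arrival_window[2],
            clade_window[1] < clade_window[2], tolerance >= 0,
            onset_margin >= 0)
  structure(list(arrival_window = arrival_window,
                 clade_window = clade_window,
                 founder_target = founder_target,
                 extended_founder_bound = extended_founder_bound,
                 tolerance = tolerance, onset_margin = onset_margin,
                 use_intervals = isTRUE(use_intervals)),
            class = "criteria_config")
}

#' Marker age set for the dispersal-criteria test
#'
#' @param clade_age age of the insular subclade, ka.
#' @param ancestor_age age of the ancestral (mainland) clade, ka.
#' @param founder_age_sink founder age from the source into the sink, ka.
#' @param founder_age_extended_source founder age from the extended source
#'   (source plus intermediate region) into the rest of the sink, ka.
#' @param expansion_onset_source,expansion_onset_sink expansion onset
#'   times from skyline increments, ka.
#' @param intervals optional named list of `c(lower, upper)` intervals.
#' @return an object of class `marker_ages`.
#' @export
marker_ages <- function(clade_age, ancestor_age, founder_age_sink,
                        founder_age_extended_source,
                        expansion_onset_source, expansion_onset_sink,
                        intervals = NULL) {
  vals <- c(clade_age = clade_age, ancestor_age = ancestor_age,
            founder_age_sink = founder_age_sink,
            founder_age_extended_source = founder_age_extended_source,
            expansion_onset_source = expansion_onset_source,
            expansion_onset_sink = expansion_onset_sink)
  if (any(vals < 0)) stop("ages must be non-negative", call. = FALSE)
  structure(c(as.list(vals), list(intervals = intervals)),
            class = "marker_ages")
}

#' Evaluate a candidate dispersal marker against the five criteria
#'
#' See [criteria_config()] for the meaning of criteria (a)--(e).  Missing
#' age fields raise an error naming the criterion they block.
#'
#' @param ages a `marker_ages` object.
#' @param config a `criteria_config` (defaults reproduce the reference
#'   verdicts for haplogroups M7c3c, E and B4a1a).
#' @return an object of class `criteria_verdict`: named logical vector
#'   `a`..`e` plus attributes `n_passed` and `config`.
#' @examples
#' m7c3c <- marker_ages(5.2, 11.8, 4.4, 4.2, 7.5, 5.2)
#' evaluate_criteria(m7c3c)   # 5/5
#' @export
evaluate_criteria <- function(ages, config = criteria_config()) {
  stopifnot(inherits(ages, "marker_ages"), inherits(config, "criteria_config"))
  blocks <- c(clade_age = "a", ancestor_age = "a", founder_age_sink = "c",
              founder_age_extended_source = "d",
              expansion_onset_source = "e", expansion_onset_sink = "e")
  for (f in names(blocks)) {
    if (is.null(ages[[f]]) || is.na(ages[[f]]))
      stop("missing field '", f, "' blocks criterion (", blocks[[f]], ")",
           call. = FALSE)
  }
  iv <- function(field) {
    if (config$use_intervals && !is.null(ages$intervals[[field]]))
      ages$intervals[[field]]
    else rep(ages[[field]], 2)
  }
  clade <- iv("clade_age")
  founder <- iv("founder_age_sink")
  ext <- iv("founder_age_extended_source")
  verdict <- c(
    a = ages$clade_age <= config$arrival_window[1] &&
        ages$ancestor_age >= config$arrival_window[2],
    b = clade[2] >= config$clade_window[1] &&
        clade[1] <= config$clade_window[2],
    c = founder[2] >= config$founder_target - config$tolerance &&
        founder[1] <= config$founder_target + config$tolerance,
    d = ext[1] <= config$extended_founder_bound + config$tolerance,
    e = ages$expansion_onset_source >=
        ages$expansion_onset_sink + config$onset_margin
  )
  structure(verdict, n_passed = sum(verdict), config = config,
            class = "criteria_verdict")
}

#' @export
print.criteria_verdict <- function(x, ...) {
  cat("Dispersal-marker criteria:", attr(x, "n_passed"), "/ 5 passed\n")
  for (k in names(x))
    cat("  (", k, ") ", if (x[[k]]) "pass" else "fail", "\n", sep = "")
  invisible(x)
}
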