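#' Map STR change counts onto graduated weights
#'
#' Linearly interpolates per-locus occurrence counts onto the weight range
#' \[1, 10\], reversed: the locus with the most observed changes gets
#' weight 1 (fastest, least reliable) and the locus with the fewest gets
#' weight 10.  If all counts are equal every locus keeps the standard
#' weight of 10.
#'
#' @param counts named numeric vector of per-character change counts.
#' @return named integer weights in \[1, 10\].
#' @examples
#' occurrence_weights(c(locusA = 9, locusB = 1))  # A -> 1, B -> 10
#' @export
occurrence_weights <- function(counts) {
  counts <- unlist(counts)
  cmin <- min(counts); cmax <- max(counts)
  if (cmax == cmin) {
    w <- rep(10L, length(counts))
  } else {
    w <- as.integer(round(10 - 9 * (counts - cmin) / (cmax - cmin)))
  }
  names(w) <- names(counts)
  w
}

#' Iteratively reweight STR loci from network change counts
#'
#' Starting from a flat standard weight (10) on every locus, builds a
#' median-joining network, counts how often each locus changes across the
#' network's links, converts the counts into a graduated weighting scheme
#' via [occurrence_weights()], and repeats until the network's edge set is
#' stable (or `max_iter` is reached, in which case the result is flagged
#' as not converged rather than erroring).
#'
#' @param profiles an `str_profiles` object (or state matrix); at least two
#'   distinct profiles are required.
#' @param initial_weight starting weight for every locus (default 10).
#' @param max_iter iteration cap (default 10).
#' @param epsilon passed to [median_joining_network()].
#' @return list with components `scheme` (a `weight_scheme`) and `network`
#'   (the final `haplotype_network`).
#' @export
iterate_str_weights <- function(profiles, initial_weight = 10L,
                                max_iter = 10L, epsilon = 0) {
  enc <- encode_haplotypes(profiles)
  if (nrow(enc$states) < 2)
    stop("at least two distinct profiles are required", call. = FALSE)
  chars <- enc$characters
  w <- stats::setNames(rep(as.integer(initial_weight), length(chars)), chars)
  prev_sig <- NULL
  net <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    net <- mj_build(enc, w, epsilon)
    sig <- paste(net$edges$from, net$edges$to, net$edges$character,
                 collapse = ";")
    if (identical(sig, prev_sig)) {
      converged <- TRUE
      break
    }
    prev_sig <- sig
    counts <- stats::setNames(numeric(length(chars)), chars)
    tab <- table(net$edges$character)
    counts[names(tab)] <- as.numeric(tab)
    w_new <- occurrence_weights(counts)
    if (identical(w_new, w)) {            # fixed point: same net next round
      converged <- TRUE
      break
    }
    w <- w_new
  }
  list(scheme = weight_scheme(w, iteration_count = it, converged = converged),
       network = net)
}
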