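#' Build a reduced-median network of binary haplotypes
#'
#' Characters must be binary (derived versus reference state); HVS-I
#' haplotypes are encoded this way automatically, with multistate positions
#' split into one binary character per derived state.  On conflict-free
#' (compatible) data the result is the unique perfect phylogeny.  Where two
#' characters are incompatible, the reticulation (a four-cycle with the two
#' characters on opposite sides) is reduced by letting the lower-weight
#' (faster) character recur: one edge of the higher-weight character is
#' removed, which yields the cheaper of the two resolutions.  Cycles
#' between characters of equal weight are left as reticulations.
#'
#' @param haplotypes an `hvs1_haplotypes` object or a binary state matrix.
#' @param weights per-character weights (see [median_joining_network()]).
#' @param epsilon spanning-network relaxation, default 0.
#' @return a `haplotype_network` object.
#' @export
reduced_median_network <- function(haplotypes, weights = NULL, epsilon = 0) {
  enc <- encode_haplotypes(haplotypes)
  if (nrow(enc$states) == 0) stop("empty input", call. = FALSE)
  if (!all(enc$states %in% 0:1))
    stop("reduced-median networks require binary characters", call. = FALSE)
  w <- resolve_weights(weights, enc$characters)
  net <- mj_build(enc, w, epsilon)
  reduce_parallelisms(net)
}

# resolve four-cycles with paired character labels (a,b,a,b) in favour of
# the lower-weight character recurring, by deleting one edge of the
# higher-weight character; deterministic tie-breaks by node label.
reduce_parallelisms <- function(net) {
  repeat {
    sq <- find_square(net)
    if (is.null(sq)) break
    wts <- net$character_weights[sq$chars]
    if (wts[1] == wts[2]) break           # equal weights: keep reticulation
    drop_char <- sq$chars[which.max(wts)]
    cand <- sq$edges[sq$edges$character == drop_char, , drop = FALSE]
    cand <- cand[order(cand$from, cand$to), , drop = FALSE]
    drop <- cand[nrow(cand), ]            # lexicographically last
    keep <- !(net$edges$from == drop$from & net$edges$to == drop$to &
                net$edges$character == drop$character)
    net$edges <- net$edges[keep, , drop = FALSE]
    net <- prune_dangling(net)
  }
  net$cost <- network_cost(net)
  net
}

# locate one chordless four-cycle whose opposite edges carry the same two
# distinct characters with unequal weights; NULL if none
find_square <- function(net) {
  e <- net$edges
  if (nrow(e) < 4) return(NULL)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  emap <- split(seq_len(nrow(e)), key(e$from, e$to))
  verts <- rownames(net$states)
  adj <- lapply(stats::setNames(verts, verts), function(v) {
    rows <- which(e$from == v | e$to == v)
    data.frame(u = ifelse(e$from[rows] == v, e$to[rows], e$from[rows]),
               ch = e$character[rows], stringsAsFactors = FALSE)
  })
  for (v in verts) {
    nb <- adj[[v]]
    if (nrow(nb) < 2) next
    for (a in seq_len(nrow(nb))) {
      for (b in seq_len(nrow(nb))) {
        if (a == b || nb$ch[a] == nb$ch[b]) next
        x <- nb$u[a]; y <- nb$u[b]          # v -chA- x, v -chB- y
        nx <- adj[[x]]
        cl <- nx$u[nx$ch == nb$ch[b]]       # x -chB- z
        for (z in cl) {
          if (z == v) next
          nz <- adj[[z]]
          if (any(nz$u == y & nz$ch == nb$ch[a])) {
            chs <- c(nb$ch[a], nb$ch[b])
            if (net$character_weights[chs[1]] ==
                net$character_weights[chs[2]]) next
            rows <- unique(c(
              emap[[key(v, x)]], emap[[key(v, y)]],
              emap[[key(x, z)]], emap[[key(z, y)]]))
            sqe <- e[rows, , drop = FALSE]
            sqe <- sqe[sqe$character %in% chs, , drop = FALSE]
            if (nrow(sqe) < 4) next
            return(list(chars = sort(chs), edges = sqe))
          }
        }
      }
    }
  }
  NULL
}

# drop inferred nodes left with degree <= 1 after edge removal
prune_dangling <- function(net) {
  repeat {
    deg <- stats::setNames(numeric(nrow(net$states)), rownames(net$states))
    tab <- table(c(net$edges$from, net$edges$to))
    deg[names(tab)] <- as.numeric(tab)
    drop <- names(deg)[deg <= 1 & !net$observed]
    if (!length(drop)) break
    keep <- !(rownames(net$states) %in% drop)
    net$states <- net$states[keep, , drop = FALSE]
    net$observed <- net$observed[keep]
    net$kind <- net$kind[keep]
    net$samples <- net$samples[keep]
    net$roles <- net$roles[keep, , drop = FALSE]
    live <- !(net$edges$from %in% drop | net$edges$to %in% drop)
    net$edges <- net$edges[live, , drop = FALSE]
  }
  net
}
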