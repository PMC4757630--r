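#' Haplotype networks
#'
#' A `haplotype_network` connects observed haplotype states (plus inferred
#' median, i.e. Steiner/consensus, vectors) by single-step edges: every
#' edge changes exactly one character by exactly one step (one base change
#' for sequence data, one repeat unit for STRs).  Each character carries an
#' integer weight in \[1, 10\]; the weighted cost of a link is the
#' character weight times the number of steps.
#'
#' @name haplotype_network
#' @keywords internal
NULL

# ---- weight schemes --------------------------------------------------------

#' Character weight scheme
#'
#' @param weights named numeric vector of per-character weights in \[1,10\].
#' @param iteration_count number of reweighting iterations that produced it.
#' @param converged whether the iterative scheme reached a stable network.
#' @return an object of class `weight_scheme`.
#' @export
weight_scheme <- function(weights, iteration_count = 0L, converged = TRUE) {
  weights <- unlist(weights)
  if (any(weights < 1 | weights > 10))
    stop("weights must lie in [1, 10]", call. = FALSE)
  structure(list(weights = weights, iteration_count = as.integer(iteration_count),
                 converged = isTRUE(converged)),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Weight scheme over", length(x$weights), "characters",
      if (x$iteration_count > 0)
        paste0("(", x$iteration_count, " iterations, ",
               if (x$converged) "converged" else "not converged", ")"),
      "\n")
  print(x$weights)
  invisible(x)
}

resolve_weights <- function(weights, characters, default = 10) {
  if (is.null(weights)) {
    w <- rep(default, length(characters))
    names(w) <- characters
    return(w)
  }
  if (inherits(weights, "weight_scheme")) weights <- weights$weights
  if (is.null(names(weights)) && length(weights) == length(characters))
    names(weights) <- characters
  w <- weights[characters]
  if (anyNA(w))
    stop("weights missing for character(s): ",
         paste(characters[is.na(w)], collapse = ", "), call. = FALSE)
  names(w) <- characters
  w
}

# ---- minimum spanning structures ------------------------------------------

# deterministic Kruskal on an edge list (ties broken by input order)
kruskal_edges <- function(i, j, d, n) {
  ord <- order(d, i, j)
  uf <- uf_new(n)
  pick <- integer(0)
  cost <- 0
  for (e in ord) {
    ri <- uf_find(uf, i[e]); rj <- uf_find(uf, j[e])
    if (ri != rj) {
      uf[ri] <- rj
      pick <- c(pick, e)
      cost <- cost + d[e]
      if (length(pick) == n - 1L) break
    }
  }
  list(edges = cbind(i = i[pick], j = j[pick], d = d[pick]), cost = cost,
       connected = length(pick) == n - 1L)
}

mst_of_matrix <- function(D) {
  k <- nrow(D)
  if (k < 2) return(list(edges = cbind(i = integer(0), j = integer(0),
                                       d = numeric(0)),
                         cost = 0, connected = TRUE))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  kruskal_edges(idx[, 1], idx[, 2], D[idx], k)
}

# epsilon-relaxed minimum spanning network: an edge at distance d is kept
# when its endpoints are not already connected using only edges shorter
# than d - epsilon.
build_msn <- function(D, eps = 0) {
  k <- nrow(D)
  out <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("i", "j", "d")))
  if (k < 2) return(out)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[idx]
  ord <- order(d, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]; d <- d[ord]
  levels <- unique(d)
  if (eps == 0) {
    # incremental: components below the current level are maintained by
    # union-ing every edge of each finished level
    uf <- uf_new(k)
    n_comp <- k
    pos <- 1L
    keep <- logical(length(d))
    for (lv in levels) {
      if (n_comp == 1L) break
      last <- pos
      while (last <= length(d) && d[last] == lv) last <- last + 1L
      at <- pos:(last - 1L)
      roots <- vapply(seq_len(k), function(v) uf_find(uf, v), 1L)
      keep[at] <- roots[idx[at, 1]] != roots[idx[at, 2]]
      for (e in at[keep[at]]) {
        ri <- uf_find(uf, idx[e, 1]); rj <- uf_find(uf, idx[e, 2])
        if (ri != rj) {
          uf[ri] <- rj
          n_comp <- n_comp - 1L
        }
      }
      pos <- last
    }
    feas <- which(keep)
    if (length(feas))
      out <- cbind(i = idx[feas, 1], j = idx[feas, 2], d = d[feas])
    return(out)
  }
  for (lv in levels) {
    uf <- uf_new(k)
    for (e in which(d < lv - eps - 1e-9)) {
      ri <- uf_find(uf, idx[e, 1]); rj <- uf_find(uf, idx[e, 2])
      if (ri != rj) uf[ri] <- rj
    }
    roots <- vapply(seq_len(k), function(v) uf_find(uf, v), 1L)
    if (length(unique(roots)) == 1L) break   # already connected below level
    at <- which(d == lv)
    feas <- at[roots[idx[at, 1]] != roots[idx[at, 2]]]
    if (length(feas))
      out <- rbind(out, cbind(i = idx[feas, 1], j = idx[feas, 2], d = d[feas]))
  }
  out
}

# ---- median-joining construction ------------------------------------------

#' Build a median-joining haplotype network
#'
#' Observed haplotypes are connected through an epsilon-relaxed minimum
#' spanning network; median (consensus) vectors of linked triples are then
#' added greedily whenever they reduce the total weighted network length,
#' and obsolete medians are pruned.  The total weighted length of the
#' result never exceeds that of a weighted minimum spanning tree on the
#' observed haplotypes alone.  Ties are broken by lexicographic node label
#' so the construction is deterministic.
#'
#' @param profiles an `str_profiles` object, an `hvs1_haplotypes` object
#'   (encoded as binary characters), or an integer state matrix.
#' @param weights a `weight_scheme`, a named weight vector, or `NULL` for
#'   the standard flat weight of 10 on every character.
#' @param epsilon non-negative relaxation of the spanning-network
#'   feasibility rule; 0 (default) gives the sparsest network.
#' @return a `haplotype_network` object.
#' @examples
#' m <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1))
#' net <- median_joining_network(m)
#' net$cost  # 3: one median vector joins the classic triple
#' @export
median_joining_network <- function(profiles, weights = NULL, epsilon = 0) {
  enc <- encode_haplotypes(profiles)
  if (nrow(enc$states) == 0) stop("empty input", call. = FALSE)
  w <- resolve_weights(weights, enc$characters)
  mj_build(enc, w, epsilon)
}

mj_build <- function(enc, w, epsilon = 0, max_medians = 500L) {
  states <- enc$states
  observed <- rep(TRUE, nrow(states))
  names(observed) <- rownames(states)

  if (nrow(states) > 1) {
    repeat {
      D <- wdist_matrix(states, w)
      mst <- mst_of_matrix(D)
      msn <- build_msn(D, epsilon)
      cand <- mj_candidates(states, msn)
      if (!length(cand)) break
      best <- NULL
      for (lab in sort(names(cand))) {
        v <- cand[[lab]]
        dm <- wdist_to(states, v, w)
        k <- nrow(states)
        test <- kruskal_edges(c(mst$edges[, "i"], seq_len(k)),
                              c(mst$edges[, "j"], rep(k + 1L, k)),
                              c(mst$edges[, "d"], dm), k + 1L)
        if (test$cost < mst$cost - 1e-9 &&
            (is.null(best) || test$cost < best$cost - 1e-9)) {
          best <- list(label = lab, v = v, cost = test$cost)
        }
      }
      if (is.null(best)) break
      states <- rbind(states, matrix(best$v, 1,
                                     dimnames = list(best$label, colnames(states))))
      observed <- c(observed, stats::setNames(FALSE, best$label))
      if (sum(!observed) >= max_medians) break
    }
  }

  # final spanning network and pruning of dangling medians
  D <- wdist_matrix(states, w)
  msn <- build_msn(D, epsilon)
  keep <- rep(TRUE, nrow(states))
  repeat {
    deg <- tabulate(c(msn[, "i"], msn[, "j"]), nbins = nrow(states))
    drop <- which(keep & !observed & deg <= 1)
    if (!length(drop)) break
    keep[drop] <- FALSE
    live <- msn[, "i"] %in% which(keep) & msn[, "j"] %in% which(keep)
    msn <- msn[live, , drop = FALSE]
  }
  old_idx <- which(keep)
  states <- states[keep, , drop = FALSE]
  observed <- observed[keep]
  remap <- match(seq_along(keep), old_idx)
  msn[, "i"] <- remap[msn[, "i"]]
  msn[, "j"] <- remap[msn[, "j"]]

  finalize_network(states, observed, msn, enc, w)
}

# medians of triples linked through a shared node in the spanning network
mj_candidates <- function(states, msn) {
  if (!nrow(msn)) return(list())
  k <- nrow(states)
  adj <- vector("list", k)
  for (e in seq_len(nrow(msn))) {
    i <- msn[e, "i"]; j <- msn[e, "j"]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- rownames(states)
  cand <- list()
  marker <- if (all(states %in% 0:1)) "binary" else "str"
  for (v in seq_len(k)) {
    nb <- adj[[v]]
    if (length(nb) < 2) next
    nb <- sort(unique(nb))
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a >= b) next
        u <- nb[a]; wn <- nb[b]
        x <- states[u, ]; y <- states[v, ]; z <- states[wn, ]
        med <- x + y + z - pmax(x, y, z) - pmin(x, y, z)
        lab <- state_labels(matrix(med, 1, dimnames = list(NULL, colnames(states))),
                            marker)
        if (lab %in% seen || !is.null(cand[[lab]])) next
        cand[[lab]] <- med
      }
    }
  }
  cand
}

# turn a node set plus spanning-network links into the final single-step
# network: links spanning several characters/steps are subdivided through
# inferred intermediate states.
finalize_network <- function(states, observed, msn, enc, w) {
  marker <- if (enc$marker == "hvs1") "hvs1" else enc$marker
  lab_mode <- if (marker %in% c("hvs1", "binary")) "binary" else "str"
  nodes <- rownames(states)
  kind <- stats::setNames(ifelse(observed, "observed", "median"), nodes)
  edges <- list()
  add_state <- function(v, lab) {
    states <<- rbind(states, matrix(v, 1, dimnames = list(lab, colnames(states))))
    observed <<- c(observed, stats::setNames(FALSE, lab))
    kind <<- c(kind, stats::setNames("path", lab))
    nodes <<- rownames(states)
  }
  if (nrow(msn)) {
    for (e in seq_len(nrow(msn))) {
      a <- msn[e, "i"]; b <- msn[e, "j"]
      cur <- states[a, ]
      cur_lab <- nodes[a]
      target <- states[b, ]
      diffc <- which(cur != target)
      for (cc in diffc[order(colnames(states)[diffc])]) {
        while (cur[cc] != target[cc]) {
          step <- sign(target[cc] - cur[cc])
          nxt <- cur
          nxt[cc] <- cur[cc] + step
          nxt_lab <- state_labels(matrix(nxt, 1,
                                         dimnames = list(NULL, colnames(states))),
                                  lab_mode)
          if (!nxt_lab %in% rownames(states)) add_state(nxt, nxt_lab)
          key <- paste(sort(c(cur_lab, nxt_lab)), collapse = "\r")
          edges[[key]] <- c(from = min(cur_lab, nxt_lab),
                            to = max(cur_lab, nxt_lab),
                            character = colnames(states)[cc])
          cur <- nxt
          cur_lab <- nxt_lab
        }
      }
    }
  }
  edf <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(from = m[, "from"], to = m[, "to"], character = m[, "character"],
               weight = as.numeric(w[m[, "character"]]),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(from = character(0), to = character(0),
               character = character(0), weight = numeric(0))
  }
  edf <- edf[order(edf$from, edf$to, edf$character), , drop = FALSE]
  rownames(edf) <- NULL

  samples <- enc$samples[rownames(states)]
  names(samples) <- rownames(states)
  roles <- matrix(0, nrow(states), 3,
                  dimnames = list(rownames(states),
                                  c("source", "sink", "excluded")))
  common <- intersect(rownames(enc$roles), rownames(states))
  roles[common, ] <- enc$roles[common, , drop = FALSE]

  net <- structure(list(states = states, observed = observed, kind = kind,
                        samples = samples, roles = roles,
                        sample_roles = enc$sample_roles, edges = edf,
                        character_weights = w, marker = marker),
                   class = "haplotype_network")
  net$cost <- network_cost(net)
  net
}

#' Total weighted length of a haplotype network
#'
#' The weighted cost of a minimum spanning tree over the network's
#' observed haplotypes and deliberately added median vectors (inferred
#' single-step path intermediates are optional waypoints, not required
#' structure).  For reticulation-free networks this equals the sum of all
#' link lengths; it never exceeds the cost of a weighted minimum spanning
#' tree on the observed haplotypes alone.
#' @param net a `haplotype_network`.
#' @return numeric cost.
#' @export
network_cost <- function(net) {
  keep <- net$kind %in% c("observed", "median")
  if (sum(keep) < 2) return(0)
  D <- wdist_matrix(net$states[keep, , drop = FALSE], net$character_weights)
  mst_of_matrix(D)$cost
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Haplotype network:", nrow(x$states), "nodes (",
      sum(x$observed), "observed ), ", nrow(x$edges), "edges, cost",
      format(x$cost), "\n")
  invisible(x)
}

node_counts <- function(net) {
  vapply(net$samples, function(s) if (is.null(s)) 0L else length(s), 1L)
}

#' Convert a haplotype network to an igraph graph
#'
#' Vertices carry `name`, `observed`, `count`, `source`, `sink` attributes;
#' edges carry `character` and `weight`.
#' @param net a `haplotype_network`.
#' @return an igraph object.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "character", "weight")],
    directed = FALSE,
    vertices = data.frame(name = rownames(net$states),
                          observed = net$observed,
                          count = node_counts(net),
                          source = net$roles[, "source"],
                          sink = net$roles[, "sink"],
                          stringsAsFactors = FALSE))
  g
}
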