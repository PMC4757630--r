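# internal: encode haplotype collections as integer state matrices for the
# network builders.
#
# HVS-I haplotypes are encoded as binary characters, one per observed
# derived variant token (so a multistate position contributes one binary
# character per derived state).  STR profiles are encoded as their integer
# repeat counts.  Identical haplotypes are collapsed into one node carrying
# the sample list and per-role counts.

encode_haplotypes <- function(data) {
  if (inherits(data, "hvs1_haplotypes")) {
    chars <- sort(unique(unlist(data$variants)))
    m <- matrix(0L, nrow(data), length(chars),
                dimnames = list(data$sample_id, chars))
    for (i in seq_len(nrow(data))) m[i, data$variants[[i]]] <- 1L
    marker <- "hvs1"
  } else if (inherits(data, "str_profiles")) {
    m <- str_repeat_matrix(data)
    chars <- colnames(m)
    marker <- "str"
  } else if (is.matrix(data)) {          # raw state matrix (binary or counts)
    m <- data
    storage.mode(m) <- "integer"
    if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
    if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
    chars <- colnames(m)
    marker <- if (all(m %in% 0:1)) "binary" else "str"
  } else {
    stop("cannot encode object of class ", paste(class(data), collapse = "/"),
         call. = FALSE)
  }
  labels <- state_labels(m, marker)
  keep <- !duplicated(labels)
  states <- m[keep, , drop = FALSE]
  rownames(states) <- labels[keep]
  ord <- order(rownames(states))
  states <- states[ord, , drop = FALSE]
  node_of <- match(labels, rownames(states))
  samples <- split(rownames(m), rownames(states)[node_of])
  samples <- samples[rownames(states)]
  roles <- if (is.data.frame(data) && "role" %in% names(data)) {
    t(vapply(samples, function(s) {
      r <- data$role[match(s, data$sample_id)]
      c(source = sum(r == "source"), sink = sum(r == "sink"),
        excluded = sum(r == "excluded"))
    }, c(source = 0, sink = 0, excluded = 0)))
  } else {
    cbind(source = lengths(samples), sink = 0, excluded = 0)
  }
  sample_roles <- if (is.data.frame(data) && "role" %in% names(data)) {
    stats::setNames(data$role, data$sample_id)
  } else {
    stats::setNames(rep("source", nrow(m)), rownames(m))
  }
  list(states = states, characters = chars, samples = samples,
       roles = roles, sample_roles = sample_roles, marker = marker)
}

state_labels <- function(m, marker) {
  if (marker %in% c("hvs1", "binary")) {
    apply(m, 1, function(r) {
      v <- colnames(m)[r != 0]
      if (!length(v)) "ref" else paste(v, collapse = "+")
    })
  } else {
    apply(m, 1, paste, collapse = "-")
  }
}

# weighted L1 distance between one state vector and the rows of a matrix
wdist_to <- function(states, v, w) {
  as.numeric(abs(sweep(states, 2, v)) %*% w)
}

# full weighted distance matrix
wdist_matrix <- function(states, w) {
  k <- nrow(states)
  d <- matrix(0, k, k, dimnames = list(rownames(states), rownames(states)))
  for (i in seq_len(k)) {
    d[i, ] <- wdist_to(states, states[i, ], w)
  }
  d
}

# unweighted step distance (total mutation steps)
step_dist_to <- function(states, v) {
  as.numeric(abs(sweep(states, 2, v)) %*% rep(1, ncol(states)))
}
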