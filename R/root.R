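#' Root a haplotype network
#'
#' Extracts a minimum-weighted-cost spanning tree from the network
#' (deterministic Kruskal, ties broken by edge labels) and designates a
#' root node.  With `method = "midpoint"` the root is the node minimising
#' the maximum weighted path length to any observed haplotype; a midpoint
#' falling mid-edge is snapped to the nearer incident node, so the root is
#' always a haplotype state.  With `method = "outgroup_consensus"` the root
#' is the network node (observed or median) closest in weighted state
#' distance to the supplied outgroup profile — typically the per-locus
#' modal (consensus) haplotype of the nearest available sister clade, or
#' the ancestral reference state for HVS-I data.
#'
#' @param net a connected `haplotype_network`.
#' @param method `"midpoint"` or `"outgroup_consensus"`.
#' @param outgroup for `"outgroup_consensus"`: a named state vector over
#'   the network's characters, a one-row `str_profiles` object, or for
#'   HVS-I networks a character vector of variant tokens (use
#'   `character(0)` for the reference state).
#' @return an object of class `rooted_haplotype_tree` with parent pointers,
#'   per-edge mutation steps and weights, and the node metadata of the
#'   network.
#' @export
root_network <- function(net, method = c("midpoint", "outgroup_consensus"),
                         outgroup = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(net, "haplotype_network"))
  nodes <- rownames(net$states)
  k <- length(nodes)
  if (k > 1 && !nrow(net$edges))
    stop("network is disconnected (no edges)", call. = FALSE)
  i <- match(net$edges$from, nodes)
  j <- match(net$edges$to, nodes)
  mst <- kruskal_edges(i, j, net$edges$weight, k)
  if (!mst$connected) stop("network is disconnected", call. = FALSE)
  tree_edges <- net$edges[match(paste(mst$edges[, "i"], mst$edges[, "j"]),
                                paste(i, j)), , drop = FALSE]

  root <- if (method == "midpoint") {
    midpoint_node(nodes, tree_edges, net)
  } else {
    if (is.null(outgroup))
      stop("outgroup profile required for outgroup_consensus rooting",
           call. = FALSE)
    og <- outgroup_state(outgroup, net)
    d <- wdist_to(net$states, og, net$character_weights)
    nodes[order(d, nodes)[1]]
  }

  orient_tree(net, tree_edges, root)
}

midpoint_node <- function(nodes, tree_edges, net) {
  D <- tree_distances(nodes, tree_edges, weighted = TRUE)
  obs <- nodes[net$observed]
  ecc <- apply(D[, obs, drop = FALSE], 1, max)
  nodes[order(ecc, nodes)[1]]
}

outgroup_state <- function(outgroup, net) {
  chars <- colnames(net$states)
  if (inherits(outgroup, "str_profiles")) {
    m <- str_repeat_matrix(outgroup)
    if (nrow(m) != 1) stop("outgroup must be a single profile", call. = FALSE)
    v <- m[1, chars]
  } else if (is.character(outgroup)) {     # HVS-I variant tokens
    v <- stats::setNames(rep(0L, length(chars)), chars)
    toks <- toupper(outgroup); toks <- sub("D$", "d", toks)
    unknown <- setdiff(toks, chars)
    v[intersect(toks, chars)] <- 1L
    if (length(unknown))
      message(length(unknown), " outgroup variant(s) not segregating in the ",
              "network ignored")
  } else {
    v <- outgroup[chars]
  }
  if (anyNA(v)) stop("outgroup does not cover all network characters",
                     call. = FALSE)
  as.numeric(v)
}

# distances along a spanning tree (steps are all 1 after subdivision, so
# unweighted distance = edge count = mutation steps)
tree_distances <- function(nodes, tree_edges, weighted = TRUE) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree_edges$from, to = tree_edges$to,
               weight = if (weighted) tree_edges$weight else 1,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  igraph::distances(g, weights = igraph::E(g)$weight)[nodes, nodes,
                                                      drop = FALSE]
}

# orient the spanning tree away from the root into parent pointers
orient_tree <- function(net, tree_edges, root) {
  nodes <- rownames(net$states)
  adj <- lapply(stats::setNames(seq_along(nodes), nodes), function(x) NULL)
  for (e in seq_len(nrow(tree_edges))) {
    f <- tree_edges$from[e]; t <- tree_edges$to[e]
    adj[[f]] <- rbind(adj[[f]], data.frame(u = t, ch = tree_edges$character[e],
                                           w = tree_edges$weight[e]))
    adj[[t]] <- rbind(adj[[t]], data.frame(u = f, ch = tree_edges$character[e],
                                           w = tree_edges$weight[e]))
  }
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  pchar <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  pweight <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  queue <- root
  visited[root] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      u <- nb$u[r]
      if (!visited[u]) {
        visited[u] <- TRUE
        parent[u] <- v
        pchar[u] <- nb$ch[r]
        pweight[u] <- nb$w[r]
        queue <- c(queue, u)
      }
    }
  }
  structure(list(nodes = nodes, parent = parent, parent_character = pchar,
                 parent_weight = pweight, root = root,
                 states = net$states, observed = net$observed,
                 samples = net$samples, roles = net$roles,
                 sample_roles = net$sample_roles, marker = net$marker,
                 character_weights = net$character_weights),
            class = "rooted_haplotype_tree")
}

#' @export
print.rooted_haplotype_tree <- function(x, ...) {
  cat("Rooted haplotype tree:", length(x$nodes), "nodes, root '",
      x$root, "'\n", sep = "")
  invisible(x)
}

# unweighted mutation steps from each node to the root (each parent edge is
# a single one-character step)
steps_to_root <- function(tree) {
  depth <- stats::setNames(rep(NA_real_, length(tree$nodes)), tree$nodes)
  depth[tree$root] <- 0
  compute <- function(v) {
    if (!is.na(depth[v])) return(depth[v])
    d <- compute(tree$parent[v]) + 1
    depth[v] <<- d
    d
  }
  for (v in tree$nodes) compute(v)
  depth
}

children_of <- function(tree) {
  kids <- lapply(stats::setNames(tree$nodes, tree$nodes), function(x) character(0))
  for (v in tree$nodes) {
    p <- tree$parent[v]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], v)
  }
  kids
}

#' Convert a rooted haplotype tree to an ape phylo object
#'
#' Observed haplotype nodes that are internal in the tree are exported as
#' zero-length pendant tips so that sample-bearing states remain visible as
#' labelled tips; branch lengths are mutation steps.
#' @param tree a `rooted_haplotype_tree`.
#' @return an object of class `phylo`.
#' @export
as_phylo <- function(tree) {
  kids <- children_of(tree)
  if (length(tree$nodes) == 1) {
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2), edge.length = 0,
                          tip.label = tree$nodes, Nnode = 1L),
                     class = "phylo"))
  }
  bfs <- tree$root
  qi <- 1L
  while (qi <= length(bfs)) {
    bfs <- c(bfs, kids[[bfs[qi]]])
    qi <- qi + 1L
  }
  # give every sample-bearing or observed internal node a pendant tip
  tips <- character(0); tip_parent <- character(0); tip_len <- numeric(0)
  for (v in tree$nodes) {
    if (length(kids[[v]]) == 0) {
      tips <- c(tips, v); tip_parent <- c(tip_parent, v); tip_len <- c(tip_len, 0)
    } else if (tree$observed[v]) {
      tips <- c(tips, paste0(v, "_obs")); tip_parent <- c(tip_parent, v)
      tip_len <- c(tip_len, 0)
    }
  }
  internal <- bfs[vapply(kids[bfs], length, 1L) > 0]
  if (!length(internal)) internal <- tree$root
  n_tip <- length(tips)
  node_id <- c(stats::setNames(seq_len(n_tip), tips),
               stats::setNames(n_tip + seq_along(internal), internal))
  edge <- NULL; elen <- NULL
  for (v in internal) {
    for (u in kids[[v]]) {
      child_id <- if (length(kids[[u]]) == 0) node_id[u] else node_id[u]
      edge <- rbind(edge, c(node_id[v], child_id))
      elen <- c(elen, 1)
    }
  }
  for (t in seq_along(tips)) {
    pv <- tip_parent[t]
    if (tips[t] != pv) {                   # pendant duplicate of internal node
      edge <- rbind(edge, c(node_id[pv], node_id[tips[t]]))
      elen <- c(elen, tip_len[t])
    }
  }
  phy <- list(edge = edge, edge.length = elen, tip.label = tips,
              node.label = internal, Nnode = length(internal))
  class(phy) <- "phylo"
  phy <- ape::collapse.singles(phy)
  phy
}
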