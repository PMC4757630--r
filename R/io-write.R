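#' Write pipeline results to standard formats
#'
#' Serialises a pipeline stage's result: haplotype networks as GraphML
#' (node observation counts and per-edge change labels/weights preserved),
#' rooted trees as Newick, scan/partition results as tab-separated tables,
#' and run metadata as a machine-readable JSON report.
#'
#' @param result the object to write: a `haplotype_network`
#'   (`kind = "network_graphml"`), a `rooted_haplotype_tree`
#'   (`"tree_newick"`), a `migration_scan` / `migration_partition` /
#'   data frame (`"table"`), or a list (`"report"`).
#' @param path output file.
#' @param kind one of `"network_graphml"`, `"tree_newick"`, `"table"`,
#'   `"report"`.
#' @return the path, invisibly.
#' @export
write_results <- function(result, path,
                          kind = c("network_graphml", "tree_newick",
                                   "table", "report")) {
  kind <- match.arg(kind)
  switch(kind,
    network_graphml = {
      stopifnot(inherits(result, "haplotype_network"))
      igraph::write_graph(as_igraph(result), path, format = "graphml")
    },
    tree_newick = {
      stopifnot(inherits(result, "rooted_haplotype_tree"))
      ape::write.tree(as_phylo(result), file = path)
    },
    table = {
      tab <- result_table(result)
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    report = {
      stopifnot(is.list(result))
      jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    })
  invisible(path)
}

# tabular form of scan/partition results (one row per grid point / event)
result_table <- function(x) {
  if (inherits(x, "migration_scan")) {
    cbind(data.frame(time = x$grid, aggregate = x$aggregate),
          as.data.frame(t(x$per_founder)))
  } else if (inherits(x, "migration_partition")) {
    cbind(data.frame(time = x$event_times, fraction = x$fractions),
          as.data.frame(t(x$per_founder)))
  } else if (is.data.frame(x) || is.matrix(x)) {
    as.data.frame(x)
  } else {
    stop("cannot tabulate object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
}

#' Read a GraphML haplotype network written by [write_results()]
#'
#' Returns the igraph representation; write/read round-trips preserve the
#' graph up to isomorphism with identical node and edge labels.
#' @param path GraphML file.
#' @return an igraph object.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Build a machine-readable run report
#'
#' @param inputs named list describing input files/objects.
#' @param seed RNG seed used, if any.
#' @param config named list of configuration values; a digest (sum of
#'   character codes of its serialised form) is included so runs can be
#'   compared cheaply.
#' @return list suitable for `write_results(kind = "report")`.
#' @export
run_report <- function(inputs = list(), seed = NULL, config = list()) {
  ser <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  list(inputs = inputs, seed = seed, config = config,
       config_digest = sum(utf8ToInt(ser)),
       r_version = as.character(getRversion()),
       timestamp = format(Sys.time(), tz = "UTC"))
}
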