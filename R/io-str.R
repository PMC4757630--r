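#' Read Y-STR repeat-count profiles
#'
#' Reads a tab-separated table with a header naming the loci.  Required
#' metadata columns are `sample_id`, `population`, `role` and
#' `snp_haplogroup`; every remaining column is treated as an STR locus with
#' integer repeat counts.  The locus set must be identical across rows
#' (enforced by the rectangular table) and repeat counts must be positive
#' integers: fractional alleles such as `12.2` are rejected, naming the
#' offending cell.
#'
#' A column named `DYS426` is rejected by default (the locus types
#' inconsistently and is excluded from the canonical 19-locus panel); pass
#' `allow_dys426 = TRUE` to keep it anyway.
#'
#' @param path file to read.
#' @param allow_dys426 keep a DYS426 column instead of erroring.
#' @return an object of class `str_profiles`: a data frame with the four
#'   metadata columns plus one integer column per locus, and attribute
#'   `loci`.
#' @export
read_str_profiles <- function(path, allow_dys426 = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  meta_cols <- c("sample_id", "population", "role", "snp_haplogroup")
  miss <- setdiff(meta_cols, names(tab))
  if (length(miss))
    stop("profile table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  loci <- setdiff(names(tab), meta_cols)
  if ("DYS426" %in% loci && !allow_dys426)
    stop("column DYS426 present: this locus is excluded from the panel ",
         "(inconsistent typing); use allow_dys426 = TRUE to override",
         call. = FALSE)
  if (!length(loci)) stop("no STR locus columns found", call. = FALSE)
  repeats <- matrix(NA_integer_, nrow(tab), length(loci),
                    dimnames = list(NULL, loci))
  for (lc in loci) {
    v <- tab[[lc]]
    num <- suppressWarnings(as.numeric(v))
    bad <- is.na(num) | num != round(num) | num <= 0
    if (any(bad)) {
      i <- which(bad)[1]
      stop("non-integer repeat value '", v[i], "' at sample '",
           tab$sample_id[i], "', locus ", lc, call. = FALSE)
    }
    repeats[, lc] <- as.integer(num)
  }
  str_profiles(sample_id = tab$sample_id, population = tab$population,
               role = tab$role, snp_haplogroup = tab$snp_haplogroup,
               repeats = repeats)
}

#' Construct a Y-STR profile collection
#'
#' @param sample_id,population,role,snp_haplogroup character vectors.
#' @param repeats integer matrix of repeat counts, one column per locus
#'   (column names are the locus names).  DYS389II is stored as reported
#'   (not DYS389I-subtracted); any normalisation is the data provider's
#'   responsibility.
#' @return an `str_profiles` data frame with attribute `loci`.
#' @export
str_profiles <- function(sample_id, population, role, snp_haplogroup,
                         repeats) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  role <- as.character(role)
  bad_role <- setdiff(unique(role), c("source", "sink", "excluded"))
  if (length(bad_role))
    stop("invalid role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  repeats <- as.matrix(repeats)
  if (is.null(colnames(repeats))) stop("repeat matrix must name its loci",
                                       call. = FALSE)
  storage.mode(repeats) <- "integer"
  if (any(repeats <= 0) || anyNA(repeats))
    stop("repeat counts must be positive integers", call. = FALSE)
  out <- data.frame(sample_id = sample_id,
                    population = as.character(population),
                    role = role,
                    snp_haplogroup = as.character(snp_haplogroup),
                    stringsAsFactors = FALSE)
  for (lc in colnames(repeats)) out[[lc]] <- repeats[, lc]
  attr(out, "loci") <- colnames(repeats)
  class(out) <- c("str_profiles", "data.frame")
  out
}

#' @export
print.str_profiles <- function(x, ...) {
  cat("Y-STR profiles:", nrow(x), "samples,", length(attr(x, "loci")),
      "loci\n")
  cat("  roles:", paste(names(table(x$role)), table(x$role),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write Y-STR profiles as a tab-separated table
#'
#' Inverse of [read_str_profiles()].
#' @param x an `str_profiles` object.
#' @param path output path.
#' @export
write_str_profiles <- function(x, path) {
  stopifnot(inherits(x, "str_profiles"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

str_repeat_matrix <- function(x) {
  loci <- attr(x, "loci")
  m <- as.matrix(as.data.frame(x)[, loci, drop = FALSE])
  rownames(m) <- x$sample_id
  m
}
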