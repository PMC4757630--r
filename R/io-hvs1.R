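#' Read HVS-I haplotypes
#'
#' Reads mitochondrial control-region (HVS-I) haplotypes either from a
#' variant-notation table or from an aligned FASTA over the scored rCRS
#' segment.  Variants are stored as tokens of the form
#' `"<position><derived base>"` (e.g. `"16189C"`), with `"d"` marking a
#' deletion (`"16166d"`).  Positions are 1-based rCRS coordinates and the
#' scored range is closed on both ends.
#'
#' The variant table is tab-separated with a header and columns
#' `sample_id`, `population`, `role` (`source`, `sink` or `excluded`),
#' `variants` (whitespace-separated tokens; empty for the reference state)
#' and optionally `haplogroup`.
#'
#' FASTA input must be aligned to the reference segment.  Because the
#' reader works offline it does not ship the rCRS itself: the reference is
#' taken from the sequence named by `reference` (default: the first
#' sequence in the file).  Alignment columns where the reference is gapped
#' (insertions relative to it) are ignored; a `-` in a sample at a
#' reference position is scored as a deletion.  Ambiguous bases are
#' rejected: the founder analysis requires complete coverage of the range.
#'
#' @param path file to read.
#' @param format `"variant_table"` or `"fasta"`.
#' @param range closed interval of rCRS positions to score; variants
#'   outside it are dropped with a message reporting the count.
#' @param metadata for FASTA input, a data frame with columns `sample_id`,
#'   `population`, `role` (and optionally `haplogroup`) keyed by sequence
#'   name.
#' @param reference for FASTA input, the name of the reference sequence in
#'   the alignment (default first sequence).
#' @return an object of class `hvs1_haplotypes`: a data frame with columns
#'   `sample_id`, `population`, `role`, `haplogroup` and a list column
#'   `variants` of token vectors, plus attributes `range` and `n_dropped`.
#' @export
read_hvs1 <- function(path, format = c("variant_table", "fasta"),
                      range = c(16051L, 16400L), metadata = NULL,
                      reference = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "variant_table") {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             colClasses = "character", check.names = FALSE)
    need <- c("sample_id", "population", "role", "variants")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    variants <- lapply(seq_len(nrow(tab)), function(i) {
      toks <- strsplit(trimws(tab$variants[i]), "\\s+")[[1]]
      toks <- toks[nzchar(toks)]
      for (tk in toks) validate_variant_token(tk, line = i + 1L)
      toks
    })
    hvs1_haplotypes(sample_id = tab$sample_id, population = tab$population,
                    role = tab$role, variants = variants,
                    haplogroup = tab[["haplogroup"]], range = range)
  } else {
    aln <- ape::read.FASTA(path)
    seqs <- toupper(vapply(as.character(aln), paste, "", collapse = ""))
    if (length(seqs) < 2) stop("FASTA must contain a reference plus samples",
                               call. = FALSE)
    ref_name <- reference %||% names(seqs)[1]
    if (!ref_name %in% names(seqs))
      stop("reference sequence '", ref_name, "' not in alignment",
           call. = FALSE)
    if (length(unique(nchar(seqs))) != 1)
      stop("sequences are not aligned (unequal lengths)", call. = FALSE)
    ref <- strsplit(seqs[[ref_name]], "")[[1]]
    keep <- ref != "-"                      # drop insertion columns
    if (sum(keep) != range[2] - range[1] + 1L)
      stop("reference covers ", sum(keep), " positions but the range ",
           range[1], "-", range[2], " has ", range[2] - range[1] + 1L,
           call. = FALSE)
    pos <- seq.int(range[1], range[2])
    samples <- setdiff(names(seqs), ref_name)
    refk <- ref[keep]
    variants <- lapply(samples, function(nm) {
      s <- strsplit(seqs[[nm]], "")[[1]][keep]
      bad <- !(s %in% c("A", "C", "G", "T", "-"))
      if (any(bad))
        stop("sample '", nm, "' has ambiguous/missing base at position ",
             pos[which(bad)[1]], "; complete coverage of the range is required",
             call. = FALSE)
      diff <- which(s != refk)
      vapply(diff, function(j)
        paste0(pos[j], if (s[j] == "-") "d" else s[j]), ""
      )
    })
    meta <- resolve_metadata(samples, metadata)
    hvs1_haplotypes(sample_id = samples, population = meta$population,
                    role = meta$role, variants = variants,
                    haplogroup = meta$haplogroup, range = range)
  }
}

resolve_metadata <- function(samples, metadata) {
  if (is.null(metadata)) {
    return(list(population = rep("unknown", length(samples)),
                role = rep("sink", length(samples)),
                haplogroup = NULL))
  }
  idx <- match(samples, metadata$sample_id)
  if (anyNA(idx))
    stop("metadata missing sample(s): ",
         paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
  list(population = metadata$population[idx], role = metadata$role[idx],
       haplogroup = metadata$haplogroup[idx])
}

validate_variant_token <- function(token, line = NA) {
  if (!grepl("^[0-9]+([ACGTacgt]|d)$", token))
    stop("malformed variant token '", token, "'",
         if (!is.na(line)) paste0(" at line ", line), call. = FALSE)
  invisible(TRUE)
}

token_position <- function(tokens) as.integer(sub("([ACGTacgt]|d)$", "", tokens))
token_state <- function(tokens) toupper(sub("^[0-9]+", "", tokens))

#' Construct an HVS-I haplotype collection
#'
#' Validates roles, rejects duplicate sample ids and duplicate positions
#' within a haplotype, and drops variants outside `range` (reporting the
#' dropped count with a message and in the `n_dropped` attribute).
#' Range filtering is idempotent.
#'
#' @param sample_id,population,role,haplogroup character vectors (haplogroup
#'   optional).
#' @param variants list of character vectors of variant tokens.
#' @param range closed interval of scoreable positions.
#' @return an `hvs1_haplotypes` data frame.
#' @export
hvs1_haplotypes <- function(sample_id, population, role, variants,
                            haplogroup = NULL, range = c(16051L, 16400L)) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  role <- as.character(role)
  bad_role <- setdiff(unique(role), c("source", "sink", "excluded"))
  if (length(bad_role))
    stop("invalid role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  dropped <- 0L
  variants <- lapply(seq_along(variants), function(i) {
    toks <- toupper(as.character(variants[[i]]))
    toks <- sub("D$", "d", toks)
    pos <- token_position(toks)
    keep <- pos >= range[1] & pos <= range[2]
    dropped <<- dropped + sum(!keep)
    toks <- toks[keep]
    if (anyDuplicated(pos[keep]))
      stop("duplicate variant position in sample '", sample_id[i], "'",
           call. = FALSE)
    sort(toks)
  })
  if (dropped > 0)
    message(dropped, " variant(s) outside range [", range[1], ", ",
            range[2], "] dropped")
  out <- data.frame(sample_id = sample_id,
                    population = as.character(population),
                    role = role,
                    haplogroup = if (is.null(haplogroup))
                                   rep(NA_character_, length(sample_id))
                                 else as.character(haplogroup),
                    stringsAsFactors = FALSE)
  out$variants <- variants
  attr(out, "range") <- as.integer(range)
  attr(out, "n_dropped") <- dropped
  class(out) <- c("hvs1_haplotypes", "data.frame")
  out
}

#' @export
print.hvs1_haplotypes <- function(x, ...) {
  rng <- attr(x, "range")
  cat("HVS-I haplotypes:", nrow(x), "samples, range [",
      rng[1], ",", rng[2], "]\n")
  cat("  roles:", paste(names(table(x$role)), table(x$role),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write HVS-I haplotypes as a variant table
#'
#' Inverse of `read_hvs1(format = "variant_table")`; read-write-read
#' round-trips are identity.
#'
#' @param x an `hvs1_haplotypes` object.
#' @param path output path.
#' @export
write_hvs1 <- function(x, path) {
  stopifnot(inherits(x, "hvs1_haplotypes"))
  tab <- data.frame(sample_id = x$sample_id, population = x$population,
                    role = x$role,
                    haplogroup = ifelse(is.na(x$haplogroup), "", x$haplogroup),
                    variants = vapply(x$variants, paste, "", collapse = " "),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
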