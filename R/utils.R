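# internal helpers shared across modules

# canonical 19-locus Y-STR panel (DYS426 excluded for inconsistent typing)
YSTR_PANEL <- c("DYS388", "DYS393", "DYS392", "DYS19", "DYS390", "DYS391",
                "DYS425", "DYS389I", "DYS389II", "DYS460", "DYS461",
                "DYS438", "DYS448", "DYS458", "DYS437", "DYS439",
                "H4", "A10", "DYS635")

HVS1_RANGE <- c(16051L, 16400L)

#' Canonical Y-STR locus panel
#'
#' Returns the 19 locus names of the canonical panel (DYS426 is excluded
#' because of inconsistent typing across datasets).
#' @return character vector of length 19.
#' @export
ystr_panel <- function() YSTR_PANEL

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable union-find used by the network builders
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) {
  while (uf[i] != i) {
    uf[i] <- uf[uf[i]]
    i <- uf[i]
  }
  i
}

# log-sum-exp for posterior normalisation
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# round a fractional allocation to integers preserving the total
# (largest-remainder rule; deterministic ties by index order)
allocate_counts <- function(fractions, total) {
  raw <- fractions * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}
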