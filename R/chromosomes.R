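#' Canonical chromosome labels
#'
#' Chromosomes are ordered numerically 1-22, then X, Y, MT. Input labels may
#' carry a "chr" prefix (stripped on load) and "M" is accepted as an alias for
#' "MT". Probes or calls on any other contig are dropped with a message.
#'
#' @return Character vector of the 25 canonical labels in sort order.
#' @export
chromosome_levels <- function() {
  c(as.character(1:22), "X", "Y", "MT")
}

# Normalize free-form chromosome labels; non-canonical become NA.
normalize_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  x[x == "M"] <- "MT"
  x[!x %in% chromosome_levels()] <- NA_character_
  x
}

chrom_rank <- function(x) {
  match(x, chromosome_levels())
}

# Locale-independent ordering used everywhere names take part in a sort,
# so results are byte-identical across machines.
radix_order <- function(...) {
  order(..., method = "radix")
}
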