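#' Genomic region sets
#'
#' Region sets hold intervals such as telomeric, centromeric or
#' segmental-duplication tracks used for region-restricted validation.
#' Intervals are stored 1-based inclusive; BED input (0-based half-open) is
#' converted on load by rtracklayer. Overlapping intervals are merged.
#'
#' @param chrom,start,end Vectors defining intervals (1-based inclusive).
#' @param label Region-set label, e.g. `"telomeric"`, `"centromeric"`,
#'   `"segdup"` or any custom tag.
#' @return A `region_set`: list with `label` and a reduced `GRanges`.
#' @export
region_set <- function(chrom, start, end, label = "custom") {
  chrom <- normalize_chrom(chrom)
  if (any(is.na(chrom))) {
    message(sum(is.na(chrom)), " region(s) on non-canonical chromosomes dropped")
    keep <- !is.na(chrom)
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  }
  if (any(start < 1 | end < start)) {
    stop("regions must satisfy 1 <= start <= end", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom, ranges = IRanges::IRanges(start = start, end = end))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  structure(list(label = label, granges = gr), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set '", x$label, "': ", length(x$granges),
      " merged interval(s), ", sum(GenomicRanges::width(x$granges)),
      " bp total\n", sep = "")
  invisible(x)
}

#' Read a BED3 file as a region set
#'
#' @param path BED file (0-based half-open, as the format specifies).
#' @param label Region-set label.
#' @return A [region_set()].
#' @export
read_regions <- function(path, label = "custom") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr), label = label)
}

callset_granges <- function(cs) {
  GenomicRanges::GRanges(
    seqnames = cs$chrom,
    ranges = IRanges::IRanges(start = cs$start, end = cs$end))
}

#' Restrict a callset to (or away from) a region set
#'
#' A call overlaps a region when they share at least one base pair
#' (1-based inclusive arithmetic: a call ending at 2000 does not overlap a
#' region starting at 2001). `mode = "overlapping"` keeps the overlapping
#' calls, `mode = "excluding"` the complement; together the two modes
#' partition the input.
#'
#' @param cs A [callset()].
#' @param regions A [region_set()].
#' @param mode `"overlapping"` or `"excluding"`.
#' @return Filtered [callset()].
#' @export
restrict_to_regions <- function(cs, regions,
                                mode = c("overlapping", "excluding")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cs, "callset"), inherits(regions, "region_set"))
  if (nrow(cs) == 0) return(cs)
  call_gr <- callset_granges(cs)
  lvls <- union(GenomeInfoDb::seqlevels(call_gr),
                GenomeInfoDb::seqlevels(regions$granges))
  GenomeInfoDb::seqlevels(call_gr) <- lvls
  reg <- regions$granges
  GenomeInfoDb::seqlevels(reg) <- lvls
  hits <- GenomicRanges::countOverlaps(call_gr, reg) > 0
  keep <- if (mode == "overlapping") hits else !hits
  callset(cs[keep, , drop = FALSE],
          label = paste0(attr(cs, "label"), ":", regions$label, ":", mode),
          qc_tier = callset_tier(cs))
}

#' Summary statistics of a callset
#'
#' Reports, overall and split by CNV type: total call count, number of
#' samples with at least one call, mean calls per such sample, mean and
#' median call size, and mean confidence.
#'
#' @param cs A [callset()].
#' @return Tibble with rows `all`, `deletion`, `duplication`.
#' @export
callset_summary <- function(cs) {
  stopifnot(inherits(cs, "callset"))
  one <- function(sub, label) {
    n_samp <- length(unique(sub$sample_id))
    tibble::tibble(
      cnv_type = label,
      n_calls = nrow(sub),
      n_samples = n_samp,
      mean_calls_per_sample = if (n_samp > 0) nrow(sub) / n_samp else NA_real_,
      mean_size_bp = if (nrow(sub) > 0) mean(sub$length_bp) else NA_real_,
      median_size_bp = if (nrow(sub) > 0) stats::median(sub$length_bp)
                       else NA_real_,
      mean_confidence = if (any(!is.na(sub$confidence)))
        mean(sub$confidence, na.rm = TRUE) else NA_real_)
  }
  dplyr::bind_rows(
    one(cs, "all"),
    one(cs[cs$cnv_type == "deletion", , drop = FALSE], "deletion"),
    one(cs[cs$cnv_type == "duplication", , drop = FALSE], "duplication"))
}
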