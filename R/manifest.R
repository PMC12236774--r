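#' Construct an array manifest
#'
#' A manifest is the annotated probe table of one genotyping array: probe
#' name, chromosome, genomic position, and three per-probe intensity
#' annotations -- B-allele frequency (BAF), mean log-R ratio (LRR mean) and
#' its standard deviation (LRR sd). The constructor normalizes chromosome
#' labels (dropping probes on non-canonical contigs with a message), checks
#' probe-name uniqueness, and sorts probes ascending by
#' (chromosome, position, name). Co-located probes with distinct names are
#' allowed; duplicate names are an error because names are the join key for
#' every downstream step.
#'
#' Missing BAF/LRR annotations are encoded as `NA`, never 0 (0 is a legal
#' BAF); probes with a missing annotation are ineligible for the matching
#' method that uses it.
#'
#' @param probes Data frame with columns `name`, `chrom`, `pos`, and
#'   optionally `baf`, `lrr_mean`, `lrr_sd` (missing columns are filled with
#'   `NA`).
#' @param label Manifest label (array name); used for orientation tie-breaks
#'   and reporting.
#' @return A `manifest`: a tibble with the six probe columns, sorted, with a
#'   `label` attribute.
#' @export
manifest <- function(probes, label = "manifest") {
  probes <- tibble::as_tibble(probes)
  required <- c("name", "chrom", "pos")
  missing_cols <- setdiff(required, names(probes))
  if (length(missing_cols) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("baf", "lrr_mean", "lrr_sd")) {
    if (!col %in% names(probes)) probes[[col]] <- NA_real_
  }
  probes <- probes[, c("name", "chrom", "pos", "baf", "lrr_mean", "lrr_sd")]
  probes$name <- as.character(probes$name)
  probes$pos <- as.numeric(probes$pos)
  for (col in c("baf", "lrr_mean", "lrr_sd")) {
    probes[[col]] <- as.numeric(probes[[col]])
  }

  if (any(is.na(probes$name) | probes$name == "")) {
    stop("probe names must be non-empty", call. = FALSE)
  }
  chrom <- normalize_chrom(probes$chrom)
  n_drop <- sum(is.na(chrom))
  if (n_drop > 0) {
    message(n_drop, " probe(s) on non-canonical chromosomes dropped")
    probes <- probes[!is.na(chrom), , drop = FALSE]
    chrom <- chrom[!is.na(chrom)]
  }
  probes$chrom <- chrom
  if (nrow(probes) > 0) {
    if (any(is.na(probes$pos)) || any(probes$pos < 1)) {
      stop("probe positions must be integers >= 1", call. = FALSE)
    }
    if (anyDuplicated(probes$name)) {
      dup <- unique(probes$name[duplicated(probes$name)])
      stop("duplicate probe name(s) in manifest: ",
           paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
    }
    bad_baf <- !is.na(probes$baf) & (probes$baf < 0 | probes$baf > 1)
    if (any(bad_baf)) stop("BAF values must lie in [0, 1]", call. = FALSE)
    bad_sd <- !is.na(probes$lrr_sd) & probes$lrr_sd < 0
    if (any(bad_sd)) stop("LRR sd values must be >= 0", call. = FALSE)
    probes <- probes[radix_order(chrom_rank(probes$chrom), probes$pos,
                                 probes$name), , drop = FALSE]
  }
  structure(probes, label = as.character(label),
            class = c("manifest", class(tibble::tibble())))
}

#' @export
print.manifest <- function(x, ...) {
  cat("Array manifest '", manifest_label(x), "': ", nrow(x), " probes on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  NextMethod()
}

#' Manifest label
#' @param m A `manifest`.
#' @return The label string.
#' @export
manifest_label <- function(m) {
  attr(m, "label", exact = TRUE) %||% "manifest"
}

manifest_dialects <- c("annotated_tsv", "annotated_csv", "pfb")

annotated_header <- c("Name", "Chr", "Position", "BAF", "LRR_mean", "LRR_sd")
pfb_header <- c("Name", "Chr", "Position", "PFB")

#' Read an array manifest or PFB file
#'
#' Two annotated dialects (`Name Chr Position BAF LRR_mean LRR_sd`, tab- or
#' comma-separated) and the PennCNV PFB layout (`Name Chr Position PFB`,
#' tab-separated) are supported. The PFB column maps onto the `baf` field and
#' the LRR annotations are flagged missing, which makes a PFB-loaded manifest
#' usable for position- and BAF-based matching only.
#'
#' @param path File to read.
#' @param dialect One of `"annotated_tsv"`, `"annotated_csv"`, `"pfb"`.
#' @param label Manifest label; defaults to the file name without extension.
#' @return A [manifest()].
#' @export
read_manifest <- function(path, dialect = c("annotated_tsv", "annotated_csv",
                                            "pfb"),
                          label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  delim <- if (dialect == "annotated_csv") "," else "\t"
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = c("", "NA"), progress = FALSE,
                           show_col_types = FALSE)
  header <- if (dialect == "pfb") pfb_header else annotated_header
  missing_cols <- setdiff(header, names(raw))
  if (length(missing_cols) > 0) {
    stop("manifest file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(raw$Position))
  bad <- which(is.na(pos) & !is.na(raw$Position))
  if (length(bad) > 0) {
    stop("unparseable Position at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  if (dialect == "pfb") {
    probes <- tibble::tibble(name = raw$Name, chrom = raw$Chr, pos = pos,
                             baf = suppressWarnings(as.numeric(raw$PFB)),
                             lrr_mean = NA_real_, lrr_sd = NA_real_)
  } else {
    probes <- tibble::tibble(name = raw$Name, chrom = raw$Chr, pos = pos,
                             baf = suppressWarnings(as.numeric(raw$BAF)),
                             lrr_mean = suppressWarnings(as.numeric(raw$LRR_mean)),
                             lrr_sd = suppressWarnings(as.numeric(raw$LRR_sd)))
  }
  manifest(probes, label = label)
}

#' Write an array manifest
#'
#' Writing then re-reading an annotated dialect reproduces the manifest
#' field-for-field (readr emits shortest round-trip representations of
#' doubles). The PFB dialect keeps only name/chromosome/position/BAF.
#'
#' @param m A [manifest()].
#' @inheritParams read_manifest
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path, dialect = c("annotated_tsv",
                                                "annotated_csv", "pfb")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "manifest"))
  if (dialect == "pfb") {
    out <- tibble::tibble(Name = m$name, Chr = m$chrom, Position = m$pos,
                          PFB = m$baf)
    readr::write_tsv(out, path, na = "NA", progress = FALSE)
  } else {
    out <- tibble::tibble(Name = m$name, Chr = m$chrom, Position = m$pos,
                          BAF = m$baf, LRR_mean = m$lrr_mean,
                          LRR_sd = m$lrr_sd)
    if (dialect == "annotated_csv") {
      readr::write_csv(out, path, na = "NA", progress = FALSE)
    } else {
      readr::write_tsv(out, path, na = "NA", progress = FALSE)
    }
  }
  invisible(path)
}

#' Distribution summary of a manifest
#'
#' Computes the per-manifest summaries used to compare matched probe subsets
#' against a full array: coverage rate, inter-marker gap statistics (gaps
#' between consecutive probes within each chromosome, pooled genome-wide,
#' reported in bp and as log10), and median/IQR of the BAF, LRR-mean and
#' LRR-sd annotations over non-missing values. Quantiles use linear
#' interpolation (R's default type 7) so summaries are reproducible.
#'
#' @param m A [manifest()].
#' @param parent_size Probe count of the full array this manifest was drawn
#'   from; `coverage_rate = nrow(m) / parent_size`. Defaults to `nrow(m)`
#'   (coverage 1 for a full manifest).
#' @return One-row tibble with `n_probes`, `coverage_rate`, `gap_median_bp`,
#'   `gap_iqr_bp`, `gap_log10_median`, `gap_log10_iqr`, and median/IQR pairs
#'   for `baf`, `lrr_mean`, `lrr_sd`. Statistics over empty inputs are `NA`.
#' @export
summarize_manifest <- function(m, parent_size = NULL) {
  stopifnot(inherits(m, "manifest"))
  n <- nrow(m)
  if (is.null(parent_size)) parent_size <- n
  coverage <- if (parent_size > 0) n / parent_size else NA_real_

  gaps <- numeric(0)
  if (n > 1) {
    gaps <- unlist(lapply(split(m$pos, m$chrom), function(p) diff(sort(p))),
                   use.names = FALSE)
  }
  med_iqr <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    c(stats::median(x), stats::IQR(x, type = 7))
  }
  g <- med_iqr(gaps)
  b <- med_iqr(m$baf)
  lm_ <- med_iqr(m$lrr_mean)
  ls_ <- med_iqr(m$lrr_sd)
  tibble::tibble(
    n_probes = n,
    coverage_rate = coverage,
    gap_median_bp = g[1],
    gap_iqr_bp = g[2],
    gap_log10_median = log10(g[1]),
    gap_log10_iqr = log10(g[2]),
    baf_median = b[1], baf_iqr = b[2],
    lrr_mean_median = lm_[1], lrr_mean_iqr = lm_[2],
    lrr_sd_median = ls_[1], lrr_sd_iqr = ls_[2]
  )
}
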