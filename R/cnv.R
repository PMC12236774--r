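#' Construct a CNV callset
#'
#' A callset is a table of copy-number calls in the PennCNV idiom: one call
#' per row with sample, 1-based inclusive coordinates
#' (`length_bp = end - start + 1`), integer copy number 0-4 (2 is not a
#' call), SNP support count, confidence score, and optional boundary probe
#' names. The derived `cnv_type` is `"deletion"` for copy number < 2 and
#' `"duplication"` for copy number > 2. Calls are sorted by
#' (sample, chromosome, start) and exact duplicate rows are dropped with a
#' message.
#'
#' @param calls Data frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `copy_number`, and optionally `num_snps`, `confidence`,
#'   `start_snp`, `end_snp`.
#' @param label Callset label.
#' @param qc_tier QC tier tag: `"raw"`, `"low"` or `"medium"`.
#' @return A `callset` tibble with attributes `label` and `qc_tier`.
#' @export
callset <- function(calls, label = "callset", qc_tier = "raw") {
  calls <- tibble::as_tibble(calls)
  required <- c("sample_id", "chrom", "start", "end", "copy_number")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0) {
    stop("callset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"num_snps" %in% names(calls)) calls$num_snps <- NA_integer_
  if (!"confidence" %in% names(calls)) calls$confidence <- NA_real_
  if (!"start_snp" %in% names(calls)) calls$start_snp <- NA_character_
  if (!"end_snp" %in% names(calls)) calls$end_snp <- NA_character_

  calls$sample_id <- as.character(calls$sample_id)
  calls$chrom <- normalize_chrom(calls$chrom)
  if (any(is.na(calls$chrom))) {
    n <- sum(is.na(calls$chrom))
    message(n, " call(s) on non-canonical chromosomes dropped")
    calls <- calls[!is.na(calls$chrom), , drop = FALSE]
  }
  calls$start <- as.numeric(calls$start)
  calls$end <- as.numeric(calls$end)
  calls$copy_number <- as.integer(calls$copy_number)
  if (nrow(calls) > 0) {
    if (any(calls$start < 1 | calls$end < calls$start)) {
      stop("calls must satisfy 1 <= start <= end", call. = FALSE)
    }
    if (any(calls$copy_number == 2L) ||
        any(calls$copy_number < 0L | calls$copy_number > 4L)) {
      stop("copy_number must be an integer in 0-4 and != 2", call. = FALSE)
    }
  }
  calls$cnv_type <- ifelse(calls$copy_number < 2L, "deletion", "duplication")
  calls$length_bp <- calls$end - calls$start + 1
  calls$num_snps <- as.integer(calls$num_snps)
  calls$confidence <- as.numeric(calls$confidence)
  col_order <- c("sample_id", "chrom", "start", "end", "copy_number",
                 "cnv_type", "num_snps", "length_bp", "confidence",
                 "start_snp", "end_snp")
  calls <- calls[, col_order]
  dup <- duplicated(calls)
  if (any(dup)) {
    message(sum(dup), " exact duplicate call(s) dropped")
    calls <- calls[!dup, , drop = FALSE]
  }
  calls <- calls[radix_order(calls$sample_id, chrom_rank(calls$chrom),
                             calls$start, calls$end), , drop = FALSE]
  structure(calls, label = as.character(label), qc_tier = qc_tier,
            class = c("callset", class(tibble::tibble())))
}

#' @export
print.callset <- function(x, ...) {
  cat("CNV callset '", attr(x, "label"), "' (QC tier: ", attr(x, "qc_tier"),
      "): ", nrow(x), " calls across ", length(unique(x$sample_id)),
      " sample(s)\n", sep = "")
  NextMethod()
}

callset_tier <- function(x) attr(x, "qc_tier", exact = TRUE) %||% "raw"

rawcnv_pattern <- paste0(
  "^chr([^:[:space:]]+):([0-9]+)-([0-9]+)[[:space:]]+",
  "numsnp=([0-9]+)[[:space:]]+length=([0-9,]+)[[:space:]]+",
  "state([0-9]+),cn=([0-9]+)[[:space:]]+(\\S+)",
  "(?:[[:space:]]+startsnp=(\\S+))?(?:[[:space:]]+endsnp=(\\S+))?",
  "(?:[[:space:]]+conf=(\\S+))?[[:space:]]*$")

#' Parse PennCNV rawcnv text
#'
#' Reads the one-line-per-call rawcnv format, e.g.
#' `chr1:1000-2000 numsnp=10 length=1001 state2,cn=1 S1 startsnp=rs1
#' endsnp=rs2 conf=15.13`. `conf=` (and the boundary SNP fields) are
#' optional. Lines that do not parse, calls with `cn=2`, copy numbers above
#' 4, or `start > end` are rejected; rejected lines are reported with line
#' numbers in the `"rejected"` attribute (and a warning).
#'
#' @param x Path to a rawcnv file, or a character vector of lines.
#' @param label Callset label (defaults to the file name).
#' @return A [callset()].
#' @export
parse_rawcnv <- function(x, label = NULL) {
  if (length(x) == 1 && file.exists(x) && !grepl("\n", x)) {
    if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(x))
    lines <- readr::read_lines(x, progress = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (is.null(label)) label <- "callset"
  lines_keep <- which(nzchar(trimws(lines)))
  rejected <- tibble::tibble(line = integer(), text = character(),
                             reason = character())
  if (length(lines_keep) == 0) {
    cs <- callset(tibble::tibble(sample_id = character(), chrom = character(),
                                 start = numeric(), end = numeric(),
                                 copy_number = integer()), label = label)
    attr(cs, "rejected") <- rejected
    return(cs)
  }
  m <- regmatches(lines[lines_keep], regexec(rawcnv_pattern, lines[lines_keep]))
  ok <- lengths(m) == 12
  bad <- lines_keep[!ok]
  if (length(bad) > 0) {
    rejected <- dplyr::bind_rows(rejected, tibble::tibble(
      line = bad, text = lines[bad], reason = "malformed line"))
  }
  fields <- do.call(rbind, m[ok])
  if (is.null(fields)) fields <- matrix(character(), ncol = 12)
  lineno <- lines_keep[ok]
  calls <- tibble::tibble(
    sample_id = fields[, 9],
    chrom = fields[, 2],
    start = as.numeric(fields[, 3]),
    end = as.numeric(fields[, 4]),
    copy_number = as.integer(fields[, 8]),
    num_snps = as.integer(fields[, 5]),
    confidence = suppressWarnings(as.numeric(fields[, 12])),
    start_snp = ifelse(fields[, 10] == "", NA_character_, fields[, 10]),
    end_snp = ifelse(fields[, 11] == "", NA_character_, fields[, 11]))

  drop_cn2 <- calls$copy_number == 2L
  drop_cnhi <- calls$copy_number > 4L
  drop_coord <- calls$end < calls$start | calls$start < 1
  drop <- drop_cn2 | drop_cnhi | drop_coord
  if (any(drop)) {
    reason <- dplyr::case_when(
      drop_cn2 ~ "cn=2 is not a CNV call",
      drop_cnhi ~ "copy number above 4",
      TRUE ~ "invalid coordinates")
    rejected <- dplyr::bind_rows(rejected, tibble::tibble(
      line = lineno[drop], text = lines[lineno[drop]],
      reason = reason[drop]))
    calls <- calls[!drop, , drop = FALSE]
  }
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " rawcnv line(s) rejected (see attr 'rejected')",
            call. = FALSE)
  }
  cs <- callset(calls, label = label)
  attr(cs, "rejected") <- rejected[radix_order(rejected$line), , drop = FALSE]
  cs
}

# PennCNV HMM state for a copy number (1-2 deletions, 5-6 duplications).
cn_to_state <- function(cn) ifelse(cn < 2L, cn + 1L, cn + 2L)

#' Write a callset in PennCNV rawcnv format
#'
#' Inverse of [parse_rawcnv()]: `parse_rawcnv(write_rawcnv(cs))` reproduces
#' the callset field-for-field. Optional fields (`startsnp`/`endsnp`,
#' `conf`) are omitted when missing.
#'
#' @param cs A [callset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rawcnv <- function(cs, path) {
  stopifnot(inherits(cs, "callset"))
  lines <- character(nrow(cs))
  for (i in seq_len(nrow(cs))) {
    parts <- c(
      sprintf("chr%s:%s-%s", cs$chrom[i],
              format(cs$start[i], scientific = FALSE, trim = TRUE),
              format(cs$end[i], scientific = FALSE, trim = TRUE)),
      sprintf("numsnp=%d", cs$num_snps[i]),
      sprintf("length=%s",
              format(cs$length_bp[i], scientific = FALSE, trim = TRUE)),
      sprintf("state%d,cn=%d", cn_to_state(cs$copy_number[i]),
              cs$copy_number[i]),
      cs$sample_id[i])
    if (!is.na(cs$start_snp[i])) {
      parts <- c(parts, sprintf("startsnp=%s", cs$start_snp[i]))
    }
    if (!is.na(cs$end_snp[i])) {
      parts <- c(parts, sprintf("endsnp=%s", cs$end_snp[i]))
    }
    if (!is.na(cs$confidence[i])) {
      parts <- c(parts, sprintf("conf=%s", format(cs$confidence[i],
                                                  digits = 15, trim = TRUE,
                                                  scientific = FALSE)))
    }
    lines[i] <- paste(parts, collapse = " ")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a per-sample QC table
#'
#' Tab-separated with header columns `sample_id lrr_mean lrr_sd baf_mean
#' baf_sd baf_drift wf` (the PennCNV sample-quality statistics; `call_count`
#' optional -- when absent it is computed from the callset being filtered).
#'
#' @param path TSV file.
#' @return Tibble of per-sample QC statistics.
#' @export
read_sample_qc <- function(path) {
  qc <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "lrr_mean", "lrr_sd", "baf_mean", "baf_sd",
                "baf_drift", "wf")
  missing_cols <- setdiff(required, names(qc))
  if (length(missing_cols) > 0) {
    stop("sample QC table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  qc$sample_id <- as.character(qc$sample_id)
  qc
}

#' QC stringency tier
#'
#' A tier bundles call-level thresholds (minimum SNP support, minimum
#' length, minimum confidence; all boundary-inclusive) with sample-level
#' caps (LRR sd, BAF drift, waviness factor, total calls per sample; a
#' failing sample loses all of its calls). A tier with every threshold at
#' its permissive extreme is the identity filter. The shipped `low` and
#' `medium` presets are provisional working defaults, not cohort-calibrated
#' constants; tune them to your data.
#'
#' @param min_num_snps,min_length_bp,min_confidence Call-level minima
#'   (calls with a missing confidence fail an active `min_confidence`).
#' @param max_sample_lrr_sd,max_sample_baf_drift,max_sample_wf,max_calls_per_sample
#'   Sample-level caps (inclusive).
#' @param name Tier tag recorded on filtered callsets.
#' @return A `qc_tier` list.
#' @export
qc_tier <- function(min_num_snps = 0, min_length_bp = 0, min_confidence = 0,
                    max_sample_lrr_sd = Inf, max_sample_baf_drift = Inf,
                    max_sample_wf = Inf, max_calls_per_sample = Inf,
                    name = "custom") {
  vals <- list(min_num_snps = min_num_snps, min_length_bp = min_length_bp,
               min_confidence = min_confidence,
               max_sample_lrr_sd = max_sample_lrr_sd,
               max_sample_baf_drift = max_sample_baf_drift,
               max_sample_wf = max_sample_wf,
               max_calls_per_sample = max_calls_per_sample)
  if (any(unlist(vals) < 0)) stop("QC thresholds must be >= 0", call. = FALSE)
  structure(c(vals, list(name = name)), class = "qc_tier")
}

#' @rdname qc_tier
#' @export
qc_tier_raw <- function() qc_tier(name = "raw")

#' @rdname qc_tier
#' @export
qc_tier_low <- function() {
  qc_tier(min_num_snps = 10, min_length_bp = 20e3, name = "low")
}

#' @rdname qc_tier
#' @export
qc_tier_medium <- function() {
  qc_tier(min_num_snps = 10, min_length_bp = 20e3, min_confidence = 10,
          max_sample_lrr_sd = 0.30, max_sample_baf_drift = 0.01,
          max_sample_wf = 0.05, max_calls_per_sample = 100, name = "medium")
}

tier_uses_sample_filters <- function(tier) {
  is.finite(tier$max_sample_lrr_sd) || is.finite(tier$max_sample_baf_drift) ||
    is.finite(tier$max_sample_wf) || is.finite(tier$max_calls_per_sample)
}

#' Apply a QC tier to a callset
#'
#' Removes calls failing the call-level thresholds and all calls from
#' samples failing the sample-level caps. Idempotent, and a strictly
#' stricter tier never retains more calls. Per-criterion removal counts are
#' attached as the `"qc_log"` attribute.
#'
#' @param cs A [callset()].
#' @param tier A [qc_tier()].
#' @param samples Per-sample QC table (see [read_sample_qc()]); required
#'   when the tier activates any sample-level cap other than the call-count
#'   cap. `call_count`, if absent, is computed from `cs`.
#' @return Filtered [callset()] with `qc_tier` set to the tier's name.
#' @export
apply_qc <- function(cs, tier, samples = NULL) {
  stopifnot(inherits(cs, "callset"), inherits(tier, "qc_tier"))
  keep <- rep(TRUE, nrow(cs))
  log <- c(num_snps = 0L, length = 0L, confidence = 0L, sample = 0L)

  fail <- !is.na(cs$num_snps) & cs$num_snps < tier$min_num_snps |
    (is.na(cs$num_snps) & tier$min_num_snps > 0)
  log["num_snps"] <- sum(fail & keep); keep <- keep & !fail
  fail <- cs$length_bp < tier$min_length_bp
  log["length"] <- sum(fail & keep); keep <- keep & !fail
  if (tier$min_confidence > 0) {
    fail <- is.na(cs$confidence) | cs$confidence < tier$min_confidence
    log["confidence"] <- sum(fail & keep); keep <- keep & !fail
  }

  metric_filters_active <- is.finite(tier$max_sample_lrr_sd) ||
    is.finite(tier$max_sample_baf_drift) || is.finite(tier$max_sample_wf)
  if (metric_filters_active || is.finite(tier$max_calls_per_sample)) {
    counts <- table(cs$sample_id)
    bad_samples <- character(0)
    if (metric_filters_active) {
      if (is.null(samples)) {
        stop("sample-level QC thresholds are active but no sample QC table ",
             "was supplied", call. = FALSE)
      }
      unknown <- setdiff(unique(cs$sample_id), samples$sample_id)
      if (length(unknown) > 0) {
        stop("sample(s) missing from the QC table: ",
             paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
      }
      s <- samples[match(unique(cs$sample_id), samples$sample_id), ]
      bad <- s$lrr_sd > tier$max_sample_lrr_sd |
        s$baf_drift > tier$max_sample_baf_drift | s$wf > tier$max_sample_wf
      bad_samples <- s$sample_id[bad]
    }
    over <- names(counts)[counts > tier$max_calls_per_sample]
    bad_samples <- union(bad_samples, over)
    fail <- cs$sample_id %in% bad_samples
    log["sample"] <- sum(fail & keep); keep <- keep & !fail
  }

  out <- callset(cs[keep, , drop = FALSE], label = attr(cs, "label"),
                 qc_tier = tier$name)
  attr(out, "qc_log") <- log
  out
}

#' Default CNV size bins
#'
#' Half-open bins `[lo, hi)` in bp: `<100kb`, `100kb-500kb`, `500kb-1Mb`,
#' `>=1Mb`. A boundary length (exactly 100 kb, say) falls in the lower bin.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
default_size_bins <- function() {
  list("<100kb" = c(0, 1e5), "100kb-500kb" = c(1e5, 5e5),
       "500kb-1Mb" = c(5e5, 1e6), ">=1Mb" = c(1e6, Inf))
}

#' Stratify a callset by call length
#'
#' @param cs A [callset()].
#' @param bins Named list of half-open `[lo, hi)` bp intervals; must not
#'   overlap. Defaults to [default_size_bins()].
#' @param include_all Prepend an `"all"` stratum containing every call.
#' @return Named list of [callset()]s, one per bin.
#' @export
stratify_by_size <- function(cs, bins = default_size_bins(),
                             include_all = TRUE) {
  stopifnot(inherits(cs, "callset"))
  edges <- do.call(rbind, bins)
  if (nrow(edges) > 1) {
    o <- order(edges[, 1])
    if (any(edges[o, 2][-nrow(edges)] > edges[o, 1][-1])) {
      stop("size bins must not overlap", call. = FALSE)
    }
  }
  out <- list()
  if (include_all) out[["all"]] <- cs
  for (nm in names(bins)) {
    lo <- bins[[nm]][1]; hi <- bins[[nm]][2]
    sub <- cs[cs$length_bp >= lo & cs$length_bp < hi, , drop = FALSE]
    out[[nm]] <- callset(sub, label = paste0(attr(cs, "label"), ":", nm),
                         qc_tier = callset_tier(cs))
  }
  out
}
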