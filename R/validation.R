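#' Overlap rule for callset comparison
#'
#' Defines when a test call is validated by a truth call: by default the
#' two must come from the same sample and have the same CNV type, and any
#' >= 1 bp overlap counts. `min_fraction` tightens this to require a single
#' truth call to cover at least that fraction of the test call's length.
#'
#' @param same_sample Require sample identity (default `TRUE`).
#' @param same_type Require identical CNV type (default `TRUE`).
#' @param min_fraction Fraction of the test call that must be covered by one
#'   truth call, in `[0, 1]`; 0 means any >= 1 bp overlap.
#' @return An `overlap_rule` list.
#' @export
overlap_rule <- function(same_sample = TRUE, same_type = TRUE,
                         min_fraction = 0) {
  if (min_fraction < 0 || min_fraction > 1) {
    stop("min_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(same_sample = isTRUE(same_sample),
                 same_type = isTRUE(same_type),
                 min_fraction = min_fraction), class = "overlap_rule")
}

#' Partial confusion counts
#'
#' TP and FP are counted on the test side (a test call is TP when validated
#' by a truth call, so `tp + fp` equals the number of test calls), FN on the
#' truth side (truth calls not covered by any test call). True negatives
#' are deliberately absent: without knowing the true copy-number state of
#' every genomic segment, TN is undefined for CNV callsets.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts: TP =", x$tp, " FP =", x$fp, " FN =", x$fn,
      "(TN undetermined)\n")
  invisible(x)
}

#' Classify test calls against a truth callset
#'
#' Builds the partial confusion matrix. A (test, truth) pair matches when
#' it satisfies the [overlap_rule()]; a test call is TP iff it participates
#' in at least one matching pair, FP otherwise, and a truth call is covered
#' iff it participates in at least one matching pair (many-to-one overlaps
#' allowed on both sides). FN is the number of uncovered truth calls. When
#' `same_sample` is on and a test sample is absent from the truth set, its
#' calls count as FP with a warning.
#'
#' @param test,truth [callset()]s, QC'd consistently.
#' @param rule An [overlap_rule()].
#' @return A `classification`: list with `counts` ([confusion_counts()]),
#'   `test_labels` (per test call: `label` = `"TP"`/`"FP"`), and
#'   `truth_labels` (per truth call: logical `covered`).
#' @export
classify_calls <- function(test, truth, rule = overlap_rule()) {
  stopifnot(inherits(test, "callset"), inherits(truth, "callset"),
            inherits(rule, "overlap_rule"))
  if (rule$same_sample && nrow(test) > 0) {
    missing_samples <- setdiff(unique(test$sample_id),
                               unique(truth$sample_id))
    if (length(missing_samples) > 0) {
      warning(length(missing_samples), " test sample(s) absent from the ",
              "truth set; their calls count as false positives",
              call. = FALSE)
    }
  }
  group_key <- function(cs) {
    key <- cs$chrom
    if (rule$same_sample) key <- paste(cs$sample_id, key, sep = "|")
    if (rule$same_type) key <- paste(key, cs$cnv_type, sep = "|")
    key
  }
  tp_flag <- logical(nrow(test))
  covered <- logical(nrow(truth))
  if (nrow(test) > 0 && nrow(truth) > 0) {
    tkey <- group_key(test)
    ukey <- group_key(truth)
    lvls <- union(tkey, ukey)
    test_gr <- GenomicRanges::GRanges(
      seqnames = factor(tkey, levels = lvls),
      ranges = IRanges::IRanges(start = test$start, end = test$end))
    truth_gr <- GenomicRanges::GRanges(
      seqnames = factor(ukey, levels = lvls),
      ranges = IRanges::IRanges(start = truth$start, end = truth$end))
    hits <- GenomicRanges::findOverlaps(test_gr, truth_gr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh) > 0) {
      ov_width <- pmin(test$end[qh], truth$end[sh]) -
        pmax(test$start[qh], truth$start[sh]) + 1
      ok <- ov_width >= pmax(1, rule$min_fraction * test$length_bp[qh])
      tp_flag[unique(qh[ok])] <- TRUE
      covered[unique(sh[ok])] <- TRUE
    }
  }
  counts <- confusion_counts(tp = sum(tp_flag), fp = sum(!tp_flag),
                             fn = sum(!covered))
  test_labels <- tibble::tibble(
    sample_id = test$sample_id, chrom = test$chrom, start = test$start,
    end = test$end, cnv_type = test$cnv_type,
    label = ifelse(tp_flag, "TP", "FP"))
  truth_labels <- tibble::tibble(
    sample_id = truth$sample_id, chrom = truth$chrom, start = truth$start,
    end = truth$end, cnv_type = truth$cnv_type, covered = covered)
  structure(list(counts = counts, test_labels = test_labels,
                 truth_labels = truth_labels), class = "classification")
}

# Vectorized metric formulas with the zero-denominator -> NA policy.
metrics_from_counts <- function(tp, fp, fn) {
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  ppv <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  f1 <- ifelse(!is.na(sens) & !is.na(ppv) & (sens + ppv) > 0,
               2 * ppv * sens / (ppv + sens), NA_real_)
  fmi <- ifelse(!is.na(sens) & !is.na(ppv), sqrt(ppv * sens), NA_real_)
  ji <- ifelse(tp + fp + fn > 0, tp / (tp + fp + fn), NA_real_)
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 sensitivity = sens, fnr = 1 - sens,
                 ppv = ppv, fdr = 1 - ppv,
                 f1 = f1, fmi = fmi, ji = ji)
}

#' Validation metrics from confusion counts
#'
#' Derives the seven metrics: sensitivity (recall) `tp/(tp+fn)`, false
#' negative rate `1 - sensitivity`, positive predictive value (precision)
#' `tp/(tp+fp)`, false discovery rate `1 - ppv`, F1 (harmonic mean of
#' precision and recall), Fowlkes-Mallows index (their geometric mean), and
#' Jaccard index `tp/(tp+fp+fn)`. A metric whose denominator is zero is
#' `NA`, never 0.
#'
#' @param x A [confusion_counts()], a `classification`, or a data frame
#'   with columns `tp`, `fp`, `fn` (vectorized row-wise).
#' @return Tibble with the counts and the seven metric columns.
#' @export
compute_metrics <- function(x) {
  if (inherits(x, "classification")) x <- x$counts
  if (inherits(x, "confusion_counts")) {
    return(metrics_from_counts(x$tp, x$fp, x$fn))
  }
  if (is.data.frame(x) && all(c("tp", "fp", "fn") %in% names(x))) {
    if (any(c(x$tp, x$fp, x$fn) < 0)) {
      stop("counts must be >= 0", call. = FALSE)
    }
    return(metrics_from_counts(x$tp, x$fp, x$fn))
  }
  stop("x must be confusion counts, a classification, or a data frame ",
       "with tp/fp/fn columns", call. = FALSE)
}

#' Stratified validation
#'
#' Re-runs the classification within strata defined by CNV size bins, CNV
#' type, and optionally genomic region sets, filtering both callsets
#' identically before each classification. The genome-wide size x type
#' cross always includes the unstratified `all`/`all` cell; each region set
#' adds rows (per type, sizes pooled) restricted to calls overlapping it.
#'
#' @param test,truth [callset()]s.
#' @param rule An [overlap_rule()].
#' @param size_bins Named list of `[lo, hi)` bp bins ([default_size_bins()]).
#' @param types Type strata; subset of `c("all", "deletion", "duplication")`.
#' @param regions Optional list of [region_set()]s.
#' @return Tidy tibble: `region`, `size_bin`, `cnv_type`, counts, metrics.
#' @export
evaluate_stratified <- function(test, truth, rule = overlap_rule(),
                                size_bins = default_size_bins(),
                                types = c("all", "deletion", "duplication"),
                                regions = NULL) {
  types <- match.arg(types, several.ok = TRUE)
  by_type <- function(cs, type) {
    if (type == "all") cs
    else callset(cs[cs$cnv_type == type, , drop = FALSE],
                 label = attr(cs, "label"), qc_tier = callset_tier(cs))
  }
  eval_cell <- function(test_sub, truth_sub, region, size_bin, type) {
    # stratum filters legitimately empty out samples; the absent-sample
    # warning is only meaningful for whole-callset comparisons
    cc <- suppressWarnings(classify_calls(test_sub, truth_sub, rule))$counts
    dplyr::bind_cols(tibble::tibble(region = region, size_bin = size_bin,
                                    cnv_type = type),
                     compute_metrics(cc))
  }
  test_sizes <- stratify_by_size(test, size_bins, include_all = TRUE)
  truth_sizes <- stratify_by_size(truth, size_bins, include_all = TRUE)
  rows <- list()
  for (bin in names(test_sizes)) {
    for (type in types) {
      rows[[length(rows) + 1]] <- eval_cell(
        by_type(test_sizes[[bin]], type), by_type(truth_sizes[[bin]], type),
        "genome-wide", bin, type)
    }
  }
  for (rs in regions %||% list()) {
    test_r <- restrict_to_regions(test, rs, "overlapping")
    truth_r <- restrict_to_regions(truth, rs, "overlapping")
    for (type in types) {
      rows[[length(rows) + 1]] <- eval_cell(
        by_type(test_r, type), by_type(truth_r, type), rs$label, "all", type)
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-sample precision table
#'
#' Aggregates the per-call labels of [classify_calls()] into per-sample TP,
#' FP and PPV, sorted descending by PPV (the layout of sample-performance
#' bar plots). Samples with no test calls do not appear.
#'
#' @param classification Output of [classify_calls()].
#' @return Tibble `sample_id`, `tp`, `fp`, `ppv`.
#' @export
samplewise_ppv <- function(classification) {
  stopifnot(inherits(classification, "classification"))
  labels <- classification$test_labels
  if (nrow(labels) == 0) {
    return(tibble::tibble(sample_id = character(), tp = integer(),
                          fp = integer(), ppv = numeric()))
  }
  tab <- labels |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(tp = sum(.data$label == "TP"),
                     fp = sum(.data$label == "FP"), .groups = "drop") |>
    dplyr::mutate(ppv = .data$tp / (.data$tp + .data$fp))
  tab[radix_order(-tab$ppv, tab$sample_id), , drop = FALSE]
}

#' Attribute false positives to poorly performing samples
#'
#' Flags samples with per-sample PPV strictly below `threshold` and reports
#' what fraction of samples they are and what fraction of all false
#' positives they account for, together with the confusion counts of the
#' callset retained after excluding them (their truth calls are excluded
#' too, as in a sample-removal QC step).
#'
#' @param classification Output of [classify_calls()].
#' @param threshold PPV cutoff in `[0, 1]`; comparison is strict (`<`).
#' @return List: `threshold`, `flagged_samples`, `frac_samples_flagged`,
#'   `frac_fp_attributed`, `retained_counts`.
#' @export
fp_attribution <- function(classification, threshold) {
  stopifnot(inherits(classification, "classification"))
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  tab <- samplewise_ppv(classification)
  flagged <- tab$sample_id[tab$ppv < threshold]
  total_fp <- sum(tab$fp)
  frac_fp <- if (total_fp > 0) sum(tab$fp[tab$sample_id %in% flagged]) /
    total_fp else 0
  keep <- !tab$sample_id %in% flagged
  tl <- classification$truth_labels
  fn_kept <- sum(!tl$covered & !tl$sample_id %in% flagged)
  list(threshold = threshold,
       flagged_samples = flagged,
       frac_samples_flagged = if (nrow(tab) > 0)
         length(flagged) / nrow(tab) else 0,
       frac_fp_attributed = frac_fp,
       retained_counts = confusion_counts(tp = sum(tab$tp[keep]),
                                          fp = sum(tab$fp[keep]),
                                          fn = fn_kept))
}

#' Parameter-selection curves over a d_max grid
#'
#' Turns per-(method, d_max) confusion counts into smoothed,
#' full-set-scaled metric curves. Raw metrics are computed per grid point,
#' smoothed by local regression on the log10(d_max) axis (loess,
#' configurable span), and scaled against the metrics of a full-manifest
#' reference callset. The default scaling is the ratio
#' `metric / full-set metric`; pass a different `scale_fun` (e.g. a
#' difference) to change the convention.
#'
#' @param results Data frame with columns `method`, `d_max`, `tp`, `fp`,
#'   `fn`: one row per grid point per method.
#' @param full_set_reference A [confusion_counts()] for the full-manifest
#'   callset, or `NULL` to skip scaling (scaled = smoothed).
#' @param span Loess span on log10(d_max); default 0.75.
#' @param scale_fun Function `(metric_value, reference_value) -> scaled`.
#' @param metrics Which metrics to carry; default the five headline ones.
#' @return Tibble `method`, `d_max`, `metric`, `raw`, `smoothed`, `scaled`
#'   (class `metric_curve`). With fewer than 4 grid points smoothing is
#'   skipped with a warning and raw values pass through.
#' @export
build_metric_curves <- function(results, full_set_reference = NULL,
                                span = 0.75,
                                scale_fun = function(value, reference)
                                  value / reference,
                                metrics = c("sensitivity", "ppv", "f1",
                                            "fmi", "ji")) {
  stopifnot(is.data.frame(results),
            all(c("method", "d_max", "tp", "fp", "fn") %in% names(results)))
  ref_metrics <- if (!is.null(full_set_reference)) {
    compute_metrics(full_set_reference)
  } else NULL
  long <- dplyr::bind_cols(results[, c("method", "d_max")],
                           compute_metrics(results)) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "raw") |>
    dplyr::select(dplyr::all_of(c("method", "d_max", "metric", "raw"))) |>
    dplyr::arrange(.data$method, .data$metric, .data$d_max)
  smooth_one <- function(df) {
    ok <- !is.na(df$raw)
    if (sum(ok) < 4) {
      warning("fewer than 4 grid points for method '", df$method[1],
              "', metric '", df$metric[1],
              "': smoothing skipped", call. = FALSE)
      df$smoothed <- df$raw
      return(df)
    }
    fit <- stats::loess(raw ~ log10(d_max), data = df[ok, ], span = span,
                        degree = 2,
                        control = stats::loess.control(surface = "direct"))
    df$smoothed <- as.numeric(stats::predict(fit,
                                             newdata = data.frame(d_max = df$d_max)))
    df
  }
  pieces <- split(long, list(long$method, long$metric), drop = TRUE)
  out <- dplyr::bind_rows(lapply(pieces, smooth_one)) |>
    dplyr::arrange(.data$method, .data$metric, .data$d_max) |>
    dplyr::select(dplyr::all_of(c("method", "d_max", "metric", "raw",
                                  "smoothed")))
  if (!is.null(ref_metrics)) {
    ref_vec <- unlist(ref_metrics[1, ])
    out$scaled <- scale_fun(out$smoothed, unname(ref_vec[out$metric]))
  } else {
    out$scaled <- out$smoothed
  }
  class(out) <- c("metric_curve", class(out))
  out
}

#' Select an operating d_max from a metric curve
#'
#' Plateau-onset heuristic standing in for visual inspection of the curves:
#' for each method, the smallest grid `d_max` whose value is within
#' `tolerance` of the curve's maximum, i.e. the first point at which the
#' curve has effectively saturated (its peak, plateau or inflection).
#'
#' @param curve A [build_metric_curves()] result, or any data frame with
#'   `method`, `d_max`, `metric` and the value column.
#' @param metric Metric to select on (default `"ppv"`).
#' @param tolerance Fraction of the maximum the value may fall short by;
#'   default 0.05.
#' @param value_col Column holding the curve values (default `"scaled"`).
#' @return Tibble `method`, `d_max`.
#' @export
select_dmax <- function(curve, metric = "ppv", tolerance = 0.05,
                        value_col = "scaled") {
  stopifnot(is.data.frame(curve), value_col %in% names(curve))
  df <- curve[curve$metric == metric, , drop = FALSE]
  if (nrow(df) < 2) stop("curve needs at least 2 grid points", call. = FALSE)
  df |>
    dplyr::group_by(.data$method) |>
    dplyr::arrange(.data$d_max, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) {
      v <- g[[value_col]]
      if (all(is.na(v))) stop("curve values are all missing", call. = FALSE)
      target <- (1 - tolerance) * max(v, na.rm = TRUE)
      tibble::tibble(d_max = g$d_max[which(!is.na(v) & v >= target)[1]])
    }) |>
    dplyr::ungroup()
}
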