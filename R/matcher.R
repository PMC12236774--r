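#' Matching parameters
#'
#' The matcher takes two tuning parameters: `d_max`, the maximum allowable
#' genomic distance (bp) from which a matching-manifest probe may be
#' selected, and `method`, the per-probe metric whose absolute difference is
#' minimized when several candidates fall within `d_max`. The four methods
#' are genomic `distance` (the field's "position" method; both spellings are
#' accepted), `baf`, `lrr_mean` and `lrr_sd`.
#'
#' @param d_max Maximum allowable distance in bp; integer > 0. The bound is
#'   inclusive: a candidate exactly `d_max` away is eligible.
#' @param method One of `"distance"` (alias `"position"`), `"baf"`,
#'   `"lrr_mean"`, `"lrr_sd"`.
#' @return A `match_params` list.
#' @export
match_params <- function(d_max, method = c("distance", "position", "baf",
                                           "lrr_mean", "lrr_sd")) {
  method <- match.arg(method)
  if (method == "position") method <- "distance"
  d_max <- as.numeric(d_max)
  if (length(d_max) != 1 || is.na(d_max) || d_max <= 0) {
    stop("d_max must be a single positive number of base pairs",
         call. = FALSE)
  }
  structure(list(d_max = d_max, method = method), class = "match_params")
}

#' The standard d_max sweep grid
#'
#' Twelve log-spaced distances from 10 bp to 5 Mb used when profiling how
#' matched coverage and downstream callset quality respond to `d_max`.
#'
#' @return Numeric vector of 12 distances in bp.
#' @export
default_dmax_grid <- function() {
  c(10, 50, 100, 500, 1e3, 5e3, 1e4, 5e4, 1e5, 5e5, 1e6, 5e6)
}

#' Orient two manifests into reference and matching roles
#'
#' The smaller manifest drives the greedy loop (the *reference*); candidates
#' are drawn from the larger (the *matching* manifest). Ties in size are
#' broken by lexicographic label order.
#'
#' @param a,b Two non-empty [manifest()]s.
#' @return Named list `list(reference =, matching =)`.
#' @export
orient_manifests <- function(a, b) {
  stopifnot(inherits(a, "manifest"), inherits(b, "manifest"))
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("cannot orient an empty manifest", call. = FALSE)
  }
  swap <- nrow(b) < nrow(a) ||
    (nrow(a) == nrow(b) && manifest_label(b) < manifest_label(a))
  if (swap) list(reference = b, matching = a)
  else list(reference = a, matching = b)
}

empty_pairs <- function() {
  tibble::tibble(ref_name = character(), match_name = character(),
                 chrom = character(), ref_pos = numeric(),
                 match_pos = numeric(), stage = character(),
                 distance_bp = numeric(), metric_diff = numeric())
}

#' Stage 1: exact matching
#'
#' Pairs every reference probe whose locus also occurs in the matching
#' manifest -- the consensus-probe intersection that cross-array CNV studies
#' have traditionally used on its own. With the default positional key a
#' locus is `(chrom, pos)`; co-located candidates are resolved by preferring
#' an identically named probe, then the lexicographically smallest name, and
#' each matching probe is consumed at most once. With `key = "name"` the
#' intersection is taken on probe names instead (probes must share a
#' chromosome; the recorded distance is then the positional offset between
#' the two arrays' coordinates for that name).
#'
#' @param reference,matching Sorted [manifest()]s.
#' @param key `"position"` (default) or `"name"`.
#' @return Tibble of matched pairs with `stage = "exact"`.
#' @export
exact_match <- function(reference, matching, key = c("position", "name")) {
  key <- match.arg(key)
  if (nrow(reference) == 0 || nrow(matching) == 0) return(empty_pairs())

  if (key == "name") {
    common <- intersect(reference$name, matching$name)
    ri <- match(common, reference$name)
    mi <- match(common, matching$name)
    same_chr <- reference$chrom[ri] == matching$chrom[mi]
    if (any(!same_chr)) {
      message(sum(!same_chr),
              " name-shared probe(s) on different chromosomes skipped")
    }
    ri <- ri[same_chr]; mi <- mi[same_chr]
    pairs <- tibble::tibble(
      ref_name = reference$name[ri], match_name = matching$name[mi],
      chrom = reference$chrom[ri], ref_pos = reference$pos[ri],
      match_pos = matching$pos[mi], stage = "exact",
      distance_bp = abs(reference$pos[ri] - matching$pos[mi]),
      metric_diff = 0)
    return(pairs[radix_order(chrom_rank(pairs$chrom), pairs$ref_pos,
                             pairs$ref_name), , drop = FALSE])
  }

  rkey <- paste(reference$chrom, reference$pos)
  mkey <- paste(matching$chrom, matching$pos)
  shared <- intersect(rkey, mkey)
  if (length(shared) == 0) return(empty_pairs())
  ri_all <- which(rkey %in% shared)
  mi_all <- which(mkey %in% shared)

  out_ri <- integer(0)
  out_mi <- integer(0)
  # fast path: loci where each side has exactly one probe
  r_tab <- table(rkey[ri_all]); m_tab <- table(mkey[mi_all])
  simple <- shared[r_tab[shared] == 1 & m_tab[shared] == 1]
  if (length(simple) > 0) {
    out_ri <- ri_all[match(simple, rkey[ri_all])]
    out_mi <- mi_all[match(simple, mkey[mi_all])]
  }
  # co-located loci: visit reference probes in name order; each prefers an
  # identically named candidate, then the smallest remaining name
  multi <- setdiff(shared, simple)
  for (loc in multi) {
    rs <- ri_all[rkey[ri_all] == loc]
    ms <- mi_all[mkey[mi_all] == loc]
    rs <- rs[radix_order(reference$name[rs])]
    avail <- sort(matching$name[ms], method = "radix")
    for (r in rs) {
      if (length(avail) == 0) break
      pick <- if (reference$name[r] %in% avail) reference$name[r]
              else avail[1]
      out_ri <- c(out_ri, r)
      out_mi <- c(out_mi, ms[match(pick, matching$name[ms])])
      avail <- setdiff(avail, pick)
    }
  }
  pairs <- tibble::tibble(
    ref_name = reference$name[out_ri], match_name = matching$name[out_mi],
    chrom = reference$chrom[out_ri], ref_pos = reference$pos[out_ri],
    match_pos = matching$pos[out_mi], stage = "exact",
    distance_bp = 0, metric_diff = 0)
  pairs[radix_order(chrom_rank(pairs$chrom), pairs$ref_pos,
                    pairs$ref_name), , drop = FALSE]
}

method_column <- function(method) {
  switch(method, distance = NULL, baf = "baf", lrr_mean = "lrr_mean",
         lrr_sd = "lrr_sd")
}

#' Stage 2: nearest-neighbour matching within d_max
#'
#' The greedy loop of the algorithm. Reference probes (those left unpaired
#' by [exact_match()]) are visited in ascending (chromosome, position, name)
#' order; for each, the candidate set is every unconsumed matching-manifest
#' probe on the same chromosome within `d_max` bp (inclusive). The candidate
#' minimizing the method metric's absolute difference (the genomic distance
#' itself when `method = "distance"`) is selected, consumed, and never
#' offered to a later reference probe. Ties are broken by smaller distance,
#' then by smaller candidate name. Under a BAF/LRR method, candidates with a
#' missing annotation are skipped (never treated as difference 0), and a
#' reference probe missing the annotation is left unmatched; both skip
#' counts are attached as the `"skipped"` attribute.
#'
#' The candidate search is a windowed scan over per-chromosome sorted
#' positions, so genome-scale manifests run in minutes; an exhaustive
#' rescan-per-probe implementation exists in the test-suite as the
#' correctness oracle.
#'
#' @param reference_residual,matching_residual Manifests excluding all
#'   stage-1 probes.
#' @param params A [match_params()].
#' @return Tibble of matched pairs with `stage = "nearby"`, plus attribute
#'   `skipped = c(candidates_missing_annotation, reference_missing_annotation)`.
#' @export
proximity_match <- function(reference_residual, matching_residual, params) {
  stopifnot(inherits(params, "match_params"))
  ref <- reference_residual
  mat <- matching_residual
  d_max <- params$d_max
  mcol <- method_column(params$method)
  skipped_cand <- 0L
  skipped_ref <- 0L

  out <- vector("list", length(unique(ref$chrom)))
  i_out <- 0L
  for (chr in unique(ref$chrom)) {
    rsub <- ref[ref$chrom == chr, , drop = FALSE]
    msub <- mat[mat$chrom == chr, , drop = FALSE]
    if (nrow(msub) == 0) next
    mpos <- msub$pos
    mname <- msub$name
    mann <- if (!is.null(mcol)) msub[[mcol]] else NULL
    consumed <- logical(nrow(msub))
    rann <- if (!is.null(mcol)) rsub[[mcol]] else NULL

    res_ri <- integer(nrow(rsub)); res_mi <- integer(nrow(rsub)); n_hit <- 0L
    for (i in seq_len(nrow(rsub))) {
      p <- rsub$pos[i]
      lo <- findInterval(p - d_max - 1, mpos) + 1L
      hi <- findInterval(p + d_max, mpos)
      if (hi < lo) next
      idx <- lo:hi
      idx <- idx[!consumed[idx]]
      if (length(idx) == 0) next
      if (!is.null(mcol)) {
        if (is.na(rann[i])) { skipped_ref <- skipped_ref + 1L; next }
        miss <- is.na(mann[idx])
        skipped_cand <- skipped_cand + sum(miss)
        idx <- idx[!miss]
        if (length(idx) == 0) next
        diffs <- abs(mann[idx] - rann[i])
      } else {
        diffs <- abs(mpos[idx] - p)
      }
      dist <- abs(mpos[idx] - p)
      best <- idx[radix_order(diffs, dist, mname[idx])[1]]
      consumed[best] <- TRUE
      n_hit <- n_hit + 1L
      res_ri[n_hit] <- i; res_mi[n_hit] <- best
    }
    if (n_hit > 0) {
      ri <- res_ri[seq_len(n_hit)]; mi <- res_mi[seq_len(n_hit)]
      md <- if (is.null(mcol)) abs(msub$pos[mi] - rsub$pos[ri])
            else abs(msub[[mcol]][mi] - rsub[[mcol]][ri])
      i_out <- i_out + 1L
      out[[i_out]] <- tibble::tibble(
        ref_name = rsub$name[ri], match_name = msub$name[mi],
        chrom = chr, ref_pos = rsub$pos[ri], match_pos = msub$pos[mi],
        stage = "nearby", distance_bp = abs(msub$pos[mi] - rsub$pos[ri]),
        metric_diff = md)
    }
  }
  pairs <- if (i_out > 0) dplyr::bind_rows(out[seq_len(i_out)])
           else empty_pairs()
  attr(pairs, "skipped") <- c(candidates_missing_annotation = skipped_cand,
                              reference_missing_annotation = skipped_ref)
  pairs
}

#' Run the full two-stage matcher
#'
#' Orients the two manifests (smaller = reference), takes the exact
#' positional intersection (stage 1), then greedily pairs the remaining
#' reference probes with their best unconsumed candidate within `d_max`
#' (stage 2). The result is a strict 1:1 pairing: every probe of either
#' array appears in at most one pair, and
#' `nrow(pairs) + length(unmatched_ref)` equals the reference size. Output
#' is fully deterministic for identical inputs.
#'
#' @param a,b Two [manifest()]s (orientation chosen internally unless
#'   `orient = FALSE`, in which case `a` is the reference).
#' @param params A [match_params()].
#' @param orient Apply [orient_manifests()] first (default `TRUE`).
#' @param exact_key Passed to [exact_match()].
#' @return A `markermatch_result`: list with `params`, `pairs` (tibble),
#'   `unmatched_ref`, `unmatched_matching` (name vectors), `ref_label`,
#'   `matching_label`, `n_ref`, `n_matching`.
#' @export
run_markermatch <- function(a, b, params, orient = TRUE,
                            exact_key = c("position", "name")) {
  stopifnot(inherits(params, "match_params"))
  exact_key <- match.arg(exact_key)
  if (orient) {
    o <- orient_manifests(a, b)
    reference <- o$reference; matching <- o$matching
  } else {
    reference <- a; matching <- b
  }
  ex <- exact_match(reference, matching, key = exact_key)
  ref_res <- reference[!reference$name %in% ex$ref_name, , drop = FALSE]
  mat_res <- matching[!matching$name %in% ex$match_name, , drop = FALSE]
  nb <- proximity_match(ref_res, mat_res, params)
  pairs <- dplyr::bind_rows(ex, nb)
  pairs <- pairs[radix_order(chrom_rank(pairs$chrom), pairs$ref_pos,
                             pairs$ref_name), , drop = FALSE]
  res <- structure(list(
    params = params,
    pairs = pairs,
    unmatched_ref = setdiff(reference$name, pairs$ref_name),
    unmatched_matching = setdiff(matching$name, pairs$match_name),
    ref_label = manifest_label(reference),
    matching_label = manifest_label(matching),
    n_ref = nrow(reference),
    n_matching = nrow(matching),
    skipped = attr(nb, "skipped")
  ), class = "markermatch_result")
  stopifnot(nrow(res$pairs) + length(res$unmatched_ref) == res$n_ref)
  res
}

#' @export
print.markermatch_result <- function(x, ...) {
  cat("MarkerMatch result: ", x$ref_label, " (reference, n=", x$n_ref,
      ") vs ", x$matching_label, " (matching, n=", x$n_matching, ")\n",
      "  d_max = ", format(x$params$d_max, big.mark = ","), " bp, method = ",
      x$params$method, "\n",
      "  pairs: ", nrow(x$pairs), " (", sum(x$pairs$stage == "exact"),
      " exact, ", sum(x$pairs$stage == "nearby"), " nearby); reference ",
      "coverage ", sprintf("%.3f", nrow(x$pairs) / x$n_ref), "\n", sep = "")
  invisible(x)
}

#' Extract the matched probe subsets of both arrays
#'
#' Returns, for each array, the manifest restricted to its matched probes --
#' the probe lists handed to the CNV caller so both arrays are called on
#' harmonized content.
#'
#' @param result A `markermatch_result`.
#' @param a,b The manifests the result was produced from (either order;
#'   resolved by label).
#' @return List `list(reference =, matching =)` of manifests with sizes equal
#'   to `nrow(result$pairs)`.
#' @export
export_matched_manifests <- function(result, a, b) {
  stopifnot(inherits(result, "markermatch_result"))
  labels <- c(manifest_label(a), manifest_label(b))
  if (result$ref_label == labels[1]) {
    reference <- a; matching <- b
  } else if (result$ref_label == labels[2]) {
    reference <- b; matching <- a
  } else {
    stop("neither manifest label matches the result's reference label",
         call. = FALSE)
  }
  take <- function(m, nms, suffix) {
    missing <- setdiff(nms, m$name)
    if (length(missing) > 0) {
      stop("probe name(s) in result absent from manifest '",
           manifest_label(m), "': ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    manifest(m[m$name %in% nms, , drop = FALSE],
             label = paste0(manifest_label(m), suffix))
  }
  list(reference = take(reference, result$pairs$ref_name, "-MAT"),
       matching = take(matching, result$pairs$match_name, "-MAT"))
}

#' Sweep d_max and method over a grid
#'
#' Runs the matcher for every (d_max, method) combination and summarizes
#' each matched pair of probe subsets: coverage of both arrays, pair and
#' exact-stage counts, and the gap/BAF/LRR distribution summaries of the
#' matched subsets. The exact stage is invariant to both parameters and is
#' computed once.
#'
#' @param a,b Two [manifest()]s.
#' @param d_max_grid Strictly increasing distances in bp; defaults to
#'   [default_dmax_grid()].
#' @param methods Character vector of methods.
#' @return Tibble, one row per (d_max, method).
#' @export
sweep_markermatch <- function(a, b, d_max_grid = default_dmax_grid(),
                              methods = c("distance", "baf", "lrr_mean",
                                          "lrr_sd")) {
  if (is.unsorted(d_max_grid, strictly = TRUE)) {
    stop("d_max_grid must be strictly increasing", call. = FALSE)
  }
  methods <- vapply(methods, function(m) match_params(1, m)$method, "")
  o <- orient_manifests(a, b)
  grid <- expand.grid(d_max = d_max_grid, method = unname(methods),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    params <- match_params(grid$d_max[i], grid$method[i])
    res <- run_markermatch(o$reference, o$matching, params, orient = FALSE)
    mm <- export_matched_manifests(res, o$reference, o$matching)
    sr <- summarize_manifest(mm$reference, parent_size = res$n_ref)
    sm <- summarize_manifest(mm$matching, parent_size = res$n_matching)
    tibble::tibble(
      d_max = params$d_max, method = params$method,
      n_pairs = nrow(res$pairs),
      n_exact = sum(res$pairs$stage == "exact"),
      coverage_ref = sr$coverage_rate,
      coverage_matching = sm$coverage_rate,
      ref_gap_median_bp = sr$gap_median_bp,
      ref_baf_median = sr$baf_median,
      ref_lrr_mean_median = sr$lrr_mean_median,
      ref_lrr_sd_median = sr$lrr_sd_median,
      match_gap_median_bp = sm$gap_median_bp,
      match_baf_median = sm$baf_median,
      match_lrr_mean_median = sm$lrr_mean_median,
      match_lrr_sd_median = sm$lrr_sd_median)
  })
  dplyr::bind_rows(rows)
}

#' Write a match result as a tab-separated table
#'
#' Columns: `ref_name match_name chrom ref_pos match_pos stage distance_bp
#' metric_diff`.
#'
#' @param result A `markermatch_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_match_table <- function(result, path) {
  readr::write_tsv(result$pairs, path, na = "NA", progress = FALSE)
  invisible(path)
}
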