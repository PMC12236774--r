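# Naive reference implementation of the two-stage matcher: a full rescan of
# all unconsumed candidates for every reference probe, with the same
# orientation, iteration-order and tie-break rules as the packaged matcher
# but none of its windowed-search machinery. Kept deliberately simple and
# slow; it is the correctness oracle the optimized matcher is checked
# against, never part of the package itself.
naive_markermatch <- function(a, b, params, orient = TRUE) {
  if (orient) {
    swap <- nrow(b) < nrow(a) ||
      (nrow(a) == nrow(b) &&
         attr(b, "label", exact = TRUE) < attr(a, "label", exact = TRUE))
    if (swap) { tmp <- a; a <- b; b <- tmp }
  }
  chrom_levels <- c(as.character(1:22), "X", "Y", "MT")
  rk <- function(x) match(x, chrom_levels)
  ref <- as.data.frame(a)
  mat <- as.data.frame(b)
  ref <- ref[order(rk(ref$chrom), ref$pos, ref$name, method = "radix"), ]
  mat <- mat[order(rk(mat$chrom), mat$pos, mat$name, method = "radix"), ]
  consumed <- logical(nrow(mat))
  mcol <- switch(params$method, distance = NULL, baf = "baf",
                 lrr_mean = "lrr_mean", lrr_sd = "lrr_sd")

  rows <- list()
  matched_ref <- logical(nrow(ref))

  # stage 1: exact positional intersection
  for (i in seq_len(nrow(ref))) {
    cand <- which(!consumed & mat$chrom == ref$chrom[i] &
                    mat$pos == ref$pos[i])
    if (length(cand) == 0) next
    same <- cand[mat$name[cand] == ref$name[i]]
    pick <- if (length(same) > 0) same[1]
            else cand[order(mat$name[cand], method = "radix")[1]]
    consumed[pick] <- TRUE
    matched_ref[i] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(
      ref_name = ref$name[i], match_name = mat$name[pick],
      chrom = ref$chrom[i], ref_pos = ref$pos[i], match_pos = mat$pos[pick],
      stage = "exact", distance_bp = 0, metric_diff = 0)
  }

  # stage 2: full rescan of unconsumed candidates within d_max
  for (i in seq_len(nrow(ref))) {
    if (matched_ref[i]) next
    cand <- which(!consumed & mat$chrom == ref$chrom[i] &
                    abs(mat$pos - ref$pos[i]) <= params$d_max)
    if (!is.null(mcol)) {
      if (is.na(ref[[mcol]][i])) next
      cand <- cand[!is.na(mat[[mcol]][cand])]
    }
    if (length(cand) == 0) next
    diffs <- if (is.null(mcol)) abs(mat$pos[cand] - ref$pos[i])
             else abs(mat[[mcol]][cand] - ref[[mcol]][i])
    dist <- abs(mat$pos[cand] - ref$pos[i])
    pick <- cand[order(diffs, dist, mat$name[cand], method = "radix")[1]]
    consumed[pick] <- TRUE
    matched_ref[i] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(
      ref_name = ref$name[i], match_name = mat$name[pick],
      chrom = ref$chrom[i], ref_pos = ref$pos[i], match_pos = mat$pos[pick],
      stage = "nearby", distance_bp = abs(mat$pos[pick] - ref$pos[i]),
      metric_diff = diffs[cand == pick][1])
  }

  pairs <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(ref_name = character(), match_name = character(),
               chrom = character(), ref_pos = numeric(),
               match_pos = numeric(), stage = character(),
               distance_bp = numeric(), metric_diff = numeric())
  pairs <- pairs[order(rk(pairs$chrom), pairs$ref_pos, pairs$ref_name,
                       method = "radix"), ]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_ref = ref$name[!matched_ref],
       unmatched_matching = mat$name[!consumed])
}

# Strip a markermatch_result down to the plain structures the oracle emits.
result_as_plain <- function(res) {
  pairs <- as.data.frame(res$pairs)
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched_ref = res$unmatched_ref,
       unmatched_matching = res$unmatched_matching)
}
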