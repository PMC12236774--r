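#' Configuration for simulating a paired array manifest
#'
#' The generator emulates the regime of a sparse array matched against a
#' dense one at a 1:100 scale of real products: a base pool of candidate
#' probe positions is drawn uniformly (without replacement) per chromosome;
#' the *reference* (sparse) array is a subsample of the pool; the *matching*
#' (dense) array is built from an exact copy of a fraction of the reference
#' positions (`shared_fraction`, the consensus content two products share),
#' a positionally jittered counterpart for every other reference probe, and
#' independent extra probes subsampled from the rest of the pool. The
#' intended probe correspondences and their distances are returned, so
#' matcher output can be checked against construction.
#'
#' Defaults give a 6,000-probe reference vs a 24,000-probe matching array on
#' a 24 Mb three-chromosome genome, with 19% exact positional overlap and
#' counterpart jitter of sd 3 kb -- sparse/dense densities, exact-overlap
#' fraction and a d_max = 10 kb operating regime proportionate to
#' real-product pairs.
#'
#' BAF annotations are drawn from a mixture (point masses near 0 and 1 for
#' homozygous-cluster probes plus a Beta bulk) so that BAF-based matching
#' has meaningful variation; LRR mean is Normal(-0.002, 0.002) and LRR sd is
#' log-Normal with median 0.10, matching the magnitudes seen on real
#' products.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n_base_probes Size of the base position pool.
#' @param ref_fraction,matching_fraction Subsampling fractions in (0, 1].
#' @param shared_fraction Fraction of reference probes whose exact position
#'   also appears on the matching array.
#' @param jitter_sd_bp Positional jitter (sd, bp) of non-shared counterparts.
#' @param baf_dist List `p_zero`, `p_one`, `shape1`, `shape2` for the BAF
#'   mixture.
#' @param lrr_mean_dist List `mean`, `sd`.
#' @param lrr_sd_dist List `meanlog`, `sdlog`.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An `array_sim_config` list.
#' @export
array_sim_config <- function(chrom_lengths = c("1" = 12e6, "2" = 8e6,
                                               "3" = 4e6),
                             n_base_probes = 30000,
                             ref_fraction = 0.2,
                             matching_fraction = 0.75,
                             shared_fraction = 0.19,
                             jitter_sd_bp = 3000,
                             baf_dist = list(p_zero = 0.35, p_one = 0.1,
                                             shape1 = 2, shape2 = 2),
                             lrr_mean_dist = list(mean = -0.002, sd = 0.002),
                             lrr_sd_dist = list(meanlog = log(0.10),
                                                sdlog = 0.3),
                             seed = 1L) {
  chrom_lengths <- unlist(chrom_lengths)
  stopifnot(all(chrom_lengths > 0), !is.null(names(chrom_lengths)),
            n_base_probes >= 1,
            ref_fraction > 0, ref_fraction <= 1,
            matching_fraction > 0, matching_fraction <= 1,
            shared_fraction >= 0, shared_fraction <= 1,
            jitter_sd_bp >= 0)
  if (n_base_probes > sum(chrom_lengths)) {
    stop("n_base_probes exceeds the total chromosome length", call. = FALSE)
  }
  structure(list(chrom_lengths = chrom_lengths,
                 n_base_probes = n_base_probes,
                 ref_fraction = ref_fraction,
                 matching_fraction = matching_fraction,
                 shared_fraction = shared_fraction,
                 jitter_sd_bp = jitter_sd_bp,
                 baf_dist = baf_dist, lrr_mean_dist = lrr_mean_dist,
                 lrr_sd_dist = lrr_sd_dist, seed = as.integer(seed)),
            class = "array_sim_config")
}

draw_baf <- function(n, d) {
  u <- stats::runif(n)
  out <- stats::rbeta(n, d$shape1, d$shape2)
  near0 <- u < d$p_zero
  near1 <- u >= d$p_zero & u < d$p_zero + d$p_one
  out[near0] <- pmin(abs(stats::rnorm(sum(near0), 0, 0.01)), 1)
  out[near1] <- pmax(1 - abs(stats::rnorm(sum(near1), 0, 0.01)), 0)
  out
}

draw_annotations <- function(n, cfg) {
  tibble::tibble(
    baf = draw_baf(n, cfg$baf_dist),
    lrr_mean = stats::rnorm(n, cfg$lrr_mean_dist$mean, cfg$lrr_mean_dist$sd),
    lrr_sd = stats::rlnorm(n, cfg$lrr_sd_dist$meanlog, cfg$lrr_sd_dist$sdlog))
}

#' Simulate a pair of array manifests with known correspondences
#'
#' @param cfg An [array_sim_config()].
#' @return List `reference` ([manifest()], labelled `"ref_array"`),
#'   `matching` (`"match_array"`), `truth_pairs` (tibble `ref_name`,
#'   `match_name`, `chrom`, `ref_pos`, `match_pos`, `kind`
#'   (`"shared"`/`"jittered"`), `distance_bp`), and `config`.
#' @export
simulate_array_pair <- function(cfg = array_sim_config()) {
  stopifnot(inherits(cfg, "array_sim_config"))
  set.seed(cfg$seed)
  lens <- cfg$chrom_lengths
  n_per <- round(cfg$n_base_probes * lens / sum(lens))

  base <- dplyr::bind_rows(lapply(names(lens), function(chr) {
    tibble::tibble(chrom = chr,
                   pos = sort(sample.int(lens[[chr]], n_per[[chr]])))
  }))
  n_base <- nrow(base)
  ref_idx <- sort(sample.int(n_base, round(cfg$ref_fraction * n_base)))
  ref <- base[ref_idx, , drop = FALSE]
  ref$name <- sprintf("A%06d", seq_len(nrow(ref)))

  shared <- stats::runif(nrow(ref)) < cfg$shared_fraction

  used <- new.env(parent = emptyenv())
  mark <- function(chr, p) assign(paste(chr, p), TRUE, envir = used)
  taken <- function(chr, p) exists(paste(chr, p), envir = used)
  # counterpart positions must not collide with each other or with any
  # reference position, so exact-stage output is exactly the shared set
  for (i in seq_len(nrow(ref))) mark(ref$chrom[i], ref$pos[i])

  cp_pos <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    if (shared[i]) {
      cp_pos[i] <- ref$pos[i]
    } else {
      len <- lens[[ref$chrom[i]]]
      target <- min(max(ref$pos[i] + round(stats::rnorm(1, 0,
                                           max(cfg$jitter_sd_bp, 1))), 1), len)
      # reuse the per-chromosome hash through a closure over `used`
      key_ok <- function(p) p >= 1 && p <= len && !taken(ref$chrom[i], p)
      p <- if (key_ok(target)) target else NA
      if (is.na(p)) {
        for (try in 1:20) {
          cand <- min(max(ref$pos[i] + round(stats::rnorm(1, 0,
                                             max(cfg$jitter_sd_bp, 1))), 1), len)
          if (key_ok(cand)) { p <- cand; break }
        }
      }
      if (is.na(p)) {
        for (step in 1:100000) {
          hit <- FALSE
          for (cand in c(target + step, target - step)) {
            if (key_ok(cand)) { p <- cand; hit <- TRUE; break }
          }
          if (hit) break
        }
      }
      if (is.na(p)) stop("could not place a jittered counterpart",
                         call. = FALSE)
      cp_pos[i] <- p
      mark(ref$chrom[i], p)
    }
  }

  extras_pool <- base[-ref_idx, , drop = FALSE]
  ex_idx <- sort(sample.int(nrow(extras_pool),
                            round(cfg$matching_fraction * nrow(extras_pool))))
  extras <- extras_pool[ex_idx, , drop = FALSE]
  collide <- vapply(seq_len(nrow(extras)),
                    function(i) taken(extras$chrom[i], extras$pos[i]),
                    logical(1))
  extras <- extras[!collide, , drop = FALSE]

  match_tab <- dplyr::bind_rows(
    tibble::tibble(chrom = ref$chrom, pos = cp_pos,
                   kind = ifelse(shared, "shared", "jittered"),
                   ref_name = ref$name),
    tibble::tibble(chrom = extras$chrom, pos = extras$pos, kind = "extra",
                   ref_name = NA_character_))
  match_tab <- match_tab[radix_order(chrom_rank(match_tab$chrom),
                                     match_tab$pos), , drop = FALSE]
  match_tab$name <- sprintf("B%06d", seq_len(nrow(match_tab)))

  ref_m <- manifest(dplyr::bind_cols(ref[, c("name", "chrom", "pos")],
                                     draw_annotations(nrow(ref), cfg)),
                    label = "ref_array")
  match_m <- manifest(dplyr::bind_cols(match_tab[, c("name", "chrom", "pos")],
                                       draw_annotations(nrow(match_tab), cfg)),
                      label = "match_array")

  tp <- match_tab[!is.na(match_tab$ref_name), , drop = FALSE]
  ri <- match(tp$ref_name, ref$name)
  truth_pairs <- tibble::tibble(
    ref_name = tp$ref_name, match_name = tp$name, chrom = tp$chrom,
    ref_pos = ref$pos[ri], match_pos = tp$pos, kind = tp$kind,
    distance_bp = abs(tp$pos - ref$pos[ri]))
  truth_pairs <- truth_pairs[radix_order(chrom_rank(truth_pairs$chrom),
                                         truth_pairs$ref_pos), , drop = FALSE]
  list(reference = ref_m, matching = match_m, truth_pairs = truth_pairs,
       config = cfg)
}

#' Configuration for simulating a truth/test callset pair
#'
#' Truth calls are drawn per sample (count ~ Poisson(`cnv_rate_per_sample`),
#' sizes log-uniform between `size_range`, type ~
#' Bernoulli(`dup_fraction`), placed without overlap within a sample); each
#' truth call is detected in the test set with probability
#' `detection_sensitivity`, its boundaries jittered by
#' `boundary_jitter_sd_bp` (clamped so the detected call still overlaps its
#' source and no other truth call); false-positive calls are added per
#' sample at Poisson rate `fp_rate_per_sample`, placed to avoid all truth
#' intervals of that sample. The generator's own bookkeeping of expected
#' TP/FP/FN is returned, so classification can be checked against it.
#'
#' Defaults describe the recovery study the package tests itself on:
#' 500 samples at 10 truth CNVs each (~5,000 truth calls), detection
#' sensitivity 0.80, and an FP load of 8/9 calls per sample so the expected
#' test-set PPV is 0.90.
#'
#' @param n_samples Number of samples.
#' @param cnv_rate_per_sample Mean truth calls per sample.
#' @param size_range Log-uniform bounds (bp) for call sizes, `lo < hi`.
#' @param dup_fraction Probability a call is a duplication.
#' @param detection_sensitivity Per-call detection probability in `[0, 1]`.
#' @param fp_rate_per_sample Mean false-positive calls per sample.
#' @param boundary_jitter_sd_bp Boundary jitter sd (bp) of detected calls.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param seed Integer seed.
#' @return A `callset_sim_config` list.
#' @export
callset_sim_config <- function(n_samples = 500,
                               cnv_rate_per_sample = 10,
                               size_range = c(1e4, 2e6),
                               dup_fraction = 0.4,
                               detection_sensitivity = 0.8,
                               fp_rate_per_sample = 8 / 9,
                               boundary_jitter_sd_bp = 500,
                               chrom_lengths = c("1" = 120e6, "2" = 80e6,
                                                 "3" = 40e6),
                               seed = 1L) {
  chrom_lengths <- unlist(chrom_lengths)
  stopifnot(n_samples >= 1, cnv_rate_per_sample >= 0,
            length(size_range) == 2, size_range[1] > 0,
            size_range[1] < size_range[2],
            dup_fraction >= 0, dup_fraction <= 1,
            detection_sensitivity >= 0, detection_sensitivity <= 1,
            fp_rate_per_sample >= 0, boundary_jitter_sd_bp >= 0,
            all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  structure(list(n_samples = n_samples,
                 cnv_rate_per_sample = cnv_rate_per_sample,
                 size_range = size_range, dup_fraction = dup_fraction,
                 detection_sensitivity = detection_sensitivity,
                 fp_rate_per_sample = fp_rate_per_sample,
                 boundary_jitter_sd_bp = boundary_jitter_sd_bp,
                 chrom_lengths = chrom_lengths, seed = as.integer(seed)),
            class = "callset_sim_config")
}

rloguniform <- function(n, lo, hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

# Place `n` non-overlapping intervals of the given sizes on the genome,
# avoiding `avoid` (a per-chromosome list of existing intervals). Bounded
# rejection sampling; infeasible draws are dropped with a message.
place_intervals <- function(sizes, chrom_lengths, avoid, max_tries = 50) {
  existing <- avoid
  probs <- chrom_lengths / sum(chrom_lengths)
  kept <- logical(length(sizes))
  out <- tibble::tibble(chrom = character(length(sizes)),
                        start = numeric(length(sizes)),
                        end = numeric(length(sizes)))
  for (i in seq_along(sizes)) {
    size <- round(sizes[i])
    for (try in seq_len(max_tries)) {
      chr <- sample(names(chrom_lengths), 1, prob = probs)
      len <- chrom_lengths[[chr]]
      if (size > len) next
      start <- sample.int(len - size + 1, 1)
      end <- start + size - 1
      ex <- existing[[chr]]
      clash <- !is.null(ex) && any(start <= ex$end & end >= ex$start)
      if (!clash) {
        existing[[chr]] <- rbind(ex, data.frame(start = start, end = end))
        out$chrom[i] <- chr; out$start[i] <- start; out$end[i] <- end
        kept[i] <- TRUE
        break
      }
    }
  }
  if (any(!kept)) {
    message(sum(!kept), " simulated interval(s) dropped: no placement found")
  }
  list(intervals = out[kept, , drop = FALSE], existing = existing)
}

#' Simulate a truth/test callset pair with known confusion structure
#'
#' @param cfg A [callset_sim_config()].
#' @return List `truth` ([callset()]), `test` ([callset()]), `expected`
#'   ([confusion_counts()] from the generator's bookkeeping), `config`.
#'   With the default >= 1 bp overlap rule, [classify_calls()] on the pair
#'   reproduces `expected` exactly.
#' @export
simulate_callset_pair <- function(cfg = callset_sim_config()) {
  stopifnot(inherits(cfg, "callset_sim_config"))
  set.seed(cfg$seed)
  lens <- cfg$chrom_lengths
  truth_rows <- list()
  test_rows <- list()
  n_tp <- 0L; n_fp <- 0L; n_truth <- 0L

  draw_cn <- function(n, dup) {
    ifelse(dup,
           ifelse(stats::runif(n) < 0.9, 3L, 4L),
           ifelse(stats::runif(n) < 0.9, 1L, 0L))
  }
  snps_for <- function(len_bp) {
    pmax(1L, as.integer(round(len_bp / stats::runif(length(len_bp),
                                                    1500, 3000))))
  }

  for (s in seq_len(cfg$n_samples)) {
    sid <- sprintf("S%04d", s)
    n_cnv <- stats::rpois(1, cfg$cnv_rate_per_sample)
    truth_s <- NULL
    existing <- list()
    if (n_cnv > 0) {
      sizes <- rloguniform(n_cnv, cfg$size_range[1], cfg$size_range[2])
      pl <- place_intervals(sizes, lens, existing)
      existing <- pl$existing
      iv <- pl$intervals
      if (nrow(iv) > 0) {
        dup <- stats::runif(nrow(iv)) < cfg$dup_fraction
        truth_s <- tibble::tibble(
          sample_id = sid, chrom = iv$chrom, start = iv$start, end = iv$end,
          copy_number = draw_cn(nrow(iv), dup),
          num_snps = snps_for(iv$end - iv$start + 1),
          confidence = round(stats::rgamma(nrow(iv), shape = 2.5,
                                           scale = 20), 3))
        truth_rows[[length(truth_rows) + 1]] <- truth_s
        n_truth <- n_truth + nrow(truth_s)
      }
    }

    # detected copies of truth calls, boundary-jittered but clamped to keep
    # >=1 bp overlap with the source and stay clear of neighbouring truth
    if (!is.null(truth_s) && nrow(truth_s) > 0 &&
        cfg$detection_sensitivity > 0) {
      det <- stats::runif(nrow(truth_s)) < cfg$detection_sensitivity
      if (any(det)) {
        d <- truth_s[det, , drop = FALSE]
        jit <- function(n) round(stats::rnorm(n, 0,
                                              max(cfg$boundary_jitter_sd_bp,
                                                  0)))
        s_new <- d$start + if (cfg$boundary_jitter_sd_bp > 0) jit(nrow(d)) else 0
        e_new <- d$end + if (cfg$boundary_jitter_sd_bp > 0) jit(nrow(d)) else 0
        for (k in seq_len(nrow(d))) {
          same_chr <- truth_s$chrom == d$chrom[k] &
            !(truth_s$start == d$start[k] & truth_s$end == d$end[k])
          prev_end <- suppressWarnings(
            max(truth_s$end[same_chr & truth_s$end < d$start[k]], 0))
          next_start <- suppressWarnings(
            min(truth_s$start[same_chr & truth_s$start > d$end[k]],
                lens[[d$chrom[k]]] + 1))
          s_new[k] <- min(max(s_new[k], prev_end + 1, 1), d$end[k])
          e_new[k] <- max(min(e_new[k], next_start - 1, lens[[d$chrom[k]]]),
                          d$start[k])
          if (s_new[k] > e_new[k]) s_new[k] <- e_new[k]
        }
        test_rows[[length(test_rows) + 1]] <- tibble::tibble(
          sample_id = sid, chrom = d$chrom, start = s_new, end = e_new,
          copy_number = d$copy_number,
          num_snps = snps_for(e_new - s_new + 1),
          confidence = round(stats::rgamma(nrow(d), shape = 2.5,
                                           scale = 20), 3))
        n_tp <- n_tp + nrow(d)
      }
    }

    # false positives: placed to avoid every truth interval of this sample
    n_f <- stats::rpois(1, cfg$fp_rate_per_sample)
    if (n_f > 0) {
      sizes <- rloguniform(n_f, cfg$size_range[1], cfg$size_range[2])
      pl <- place_intervals(sizes, lens, existing)
      iv <- pl$intervals
      if (nrow(iv) > 0) {
        dup <- stats::runif(nrow(iv)) < cfg$dup_fraction
        test_rows[[length(test_rows) + 1]] <- tibble::tibble(
          sample_id = sid, chrom = iv$chrom, start = iv$start, end = iv$end,
          copy_number = draw_cn(nrow(iv), dup),
          num_snps = snps_for(iv$end - iv$start + 1),
          confidence = round(stats::rgamma(nrow(iv), shape = 1.5,
                                           scale = 10), 3))
        n_fp <- n_fp + nrow(iv)
      }
    }
  }

  empty <- tibble::tibble(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          copy_number = integer())
  truth <- callset(if (length(truth_rows)) dplyr::bind_rows(truth_rows)
                   else empty, label = "truth")
  test <- callset(if (length(test_rows)) dplyr::bind_rows(test_rows)
                  else empty, label = "test")
  list(truth = truth, test = test,
       expected = confusion_counts(tp = n_tp, fp = n_fp, fn = n_truth - n_tp),
       config = cfg)
}
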