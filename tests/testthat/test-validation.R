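test_that("identical callsets give a perfect confusion matrix", {
  set.seed(2)
  sim <- simulate_callset_pair(callset_sim_config(n_samples = 10, seed = 2))
  cls <- classify_calls(sim$truth, sim$truth)
  expect_equal(cls$counts$tp, nrow(sim$truth))
  expect_equal(cls$counts$fp, 0)
  expect_equal(cls$counts$fn, 0)

  empty <- toy_callset(character(), character(), numeric(), numeric(),
                       integer())
  cls2 <- classify_calls(empty, sim$truth)
  expect_equal(cls2$counts$tp, 0)
  expect_equal(cls2$counts$fn, nrow(sim$truth))
})

test_that("type and sample identity are enforced by the overlap rule", {
  test <- toy_callset("S1", "1", 1000, 2000, copy_number = 1)
  truth <- toy_callset(c("S1", "S1"), "1", c(1500, 1000), c(2500, 2000),
                       copy_number = c(1, 3))
  cls <- classify_calls(test, truth)
  expect_equal(cls$counts$tp, 1)
  expect_equal(cls$counts$fp, 0)
  expect_equal(cls$counts$fn, 1)  # the duplication stays uncovered

  no_type <- classify_calls(test, truth, overlap_rule(same_type = FALSE))
  expect_equal(no_type$counts$fn, 0)

  other_sample <- toy_callset("S2", "1", 1000, 2000, copy_number = 1)
  expect_warning(cls3 <- classify_calls(other_sample, truth),
                 "absent from")
  expect_equal(cls3$counts$fp, 1)
})

test_that("classification agrees with an exhaustive all-pairs oracle", {
  brute <- function(test, truth, min_fraction = 0) {
    match_pair <- function(i, j) {
      if (test$sample_id[i] != truth$sample_id[j]) return(FALSE)
      if (test$cnv_type[i] != truth$cnv_type[j]) return(FALSE)
      if (test$chrom[i] != truth$chrom[j]) return(FALSE)
      ov <- min(test$end[i], truth$end[j]) - max(test$start[i],
                                                 truth$start[j]) + 1
      ov >= max(1, min_fraction * test$length_bp[i])
    }
    tp_flag <- vapply(seq_len(nrow(test)), function(i)
      any(vapply(seq_len(nrow(truth)), function(j) match_pair(i, j),
                 TRUE)), TRUE)
    cov <- vapply(seq_len(nrow(truth)), function(j)
      any(vapply(seq_len(nrow(test)), function(i) match_pair(i, j),
                 TRUE)), TRUE)
    c(tp = sum(tp_flag), fp = sum(!tp_flag), fn = sum(!cov))
  }
  set.seed(13)
  for (i in 1:5) {
    sim <- simulate_callset_pair(callset_sim_config(
      n_samples = 6, cnv_rate_per_sample = 6, seed = 13 + i))
    for (mf in c(0, 0.5)) {
      cls <- suppressWarnings(
        classify_calls(sim$test, sim$truth, overlap_rule(min_fraction = mf)))
      expect_equal(c(tp = cls$counts$tp, fp = cls$counts$fp,
                     fn = cls$counts$fn),
                   brute(sim$test, sim$truth, mf))
    }
  }
})

test_that("raising min_fraction never increases TP", {
  set.seed(17)
  sim <- simulate_callset_pair(callset_sim_config(n_samples = 15,
                                                  seed = 17))
  tps <- vapply(c(0, 0.25, 0.5, 0.9, 1), function(mf)
    classify_calls(sim$test, sim$truth,
                   overlap_rule(min_fraction = mf))$counts$tp, 1)
  expect_true(all(diff(tps) <= 0))
})

test_that("metric formulas match hand-derived values and zero policy", {
  m <- compute_metrics(confusion_counts(tp = 9, fp = 1, fn = 3))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$ppv, 0.9)
  expect_equal(round(m$f1, 4), 0.8182)
  expect_equal(round(m$fmi, 4), 0.8216)
  expect_equal(round(m$ji, 4), 0.6923)
  expect_equal(m$fnr, 0.25)
  expect_equal(m$fdr, 1 - 0.9)

  perfect <- compute_metrics(confusion_counts(5, 0, 0))
  expect_true(all(perfect[, c("sensitivity", "ppv", "f1", "fmi",
                              "ji")] == 1))

  nothing <- compute_metrics(confusion_counts(0, 0, 0))
  expect_true(all(is.na(nothing[, c("sensitivity", "ppv", "f1", "fmi",
                                    "ji")])))
  expect_error(compute_metrics(data.frame(tp = -1, fp = 0, fn = 0)), ">= 0")
})

test_that("metric identities hold on random counts", {
  set.seed(4)
  n <- 2000
  counts <- data.frame(tp = rpois(n, 5), fp = rpois(n, 3), fn = rpois(n, 4))
  m <- compute_metrics(counts)
  ok <- !is.na(m$sensitivity) & !is.na(m$ppv)
  expect_equal(m$fnr[ok], 1 - m$sensitivity[ok], tolerance = 1e-12)
  expect_equal(m$fdr[ok], 1 - m$ppv[ok], tolerance = 1e-12)
  ok3 <- ok & !is.na(m$f1) & !is.na(m$ji)
  expect_equal(m$f1[ok3], 2 * m$ji[ok3] / (1 + m$ji[ok3]),
               tolerance = 1e-12)
  expect_true(all(m$fmi[ok3] >= m$f1[ok3] - 1e-12))
  expect_true(all(m$f1[ok3] >= m$ji[ok3] - 1e-12))
})

test_that("stratified evaluation matches per-stratum brute enumeration", {
  set.seed(41)
  sim <- simulate_callset_pair(callset_sim_config(n_samples = 10, seed = 41))
  tab <- evaluate_stratified(sim$test, sim$truth)
  allrow <- tab[tab$size_bin == "all" & tab$cnv_type == "all", ]
  glob <- classify_calls(sim$test, sim$truth)$counts
  expect_equal(allrow$tp, glob$tp)
  expect_equal(allrow$fp, glob$fp)
  expect_equal(allrow$fn, glob$fn)

  # conservation within every stratum
  expect_true(all(tab$tp + tab$fp ==
                    vapply(seq_len(nrow(tab)), function(i) {
                      sub <- sim$test
                      if (tab$size_bin[i] != "all") {
                        bin <- default_size_bins()[[tab$size_bin[i]]]
                        sub <- sub[sub$length_bp >= bin[1] &
                                     sub$length_bp < bin[2], ]
                      }
                      if (tab$cnv_type[i] != "all") {
                        sub <- sub[sub$cnv_type == tab$cnv_type[i], ]
                      }
                      nrow(sub)
                    }, 1)))

  dels_only <- callset(sim$truth[sim$truth$cnv_type == "deletion", ],
                       label = "dels")
  t2 <- evaluate_stratified(dels_only, dels_only)
  duprow <- t2[t2$size_bin == "all" & t2$cnv_type == "duplication", ]
  expect_equal(duprow$tp + duprow$fp + duprow$fn, 0)
  expect_true(is.na(duprow$ppv))
})

test_that("regional strata restrict both callsets before classifying", {
  test <- toy_callset(c("S1", "S1"), "1", c(1000, 50000), c(2000, 60000),
                      copy_number = 1)
  truth <- toy_callset("S1", "1", 1500, 2500, copy_number = 1)
  reg <- region_set("1", 1, 10000, label = "telomeric")
  tab <- evaluate_stratified(test, truth, regions = list(reg))
  telo <- tab[tab$region == "telomeric" & tab$cnv_type == "all", ]
  expect_equal(telo$tp, 1)
  expect_equal(telo$fp, 0)  # the distal call is outside the region
  genome <- tab[tab$region == "genome-wide" & tab$size_bin == "all" &
                  tab$cnv_type == "all", ]
  expect_equal(genome$fp, 1)
})

test_that("per-sample PPV conserves global counts and sorts descending", {
  set.seed(6)
  sim <- simulate_callset_pair(callset_sim_config(n_samples = 12, seed = 6))
  cls <- classify_calls(sim$test, sim$truth)
  tab <- samplewise_ppv(cls)
  expect_equal(sum(tab$tp), cls$counts$tp)
  expect_equal(sum(tab$fp), cls$counts$fp)
  expect_true(all(diff(tab$ppv) <= 0))
  expect_true(all(tab$tp + tab$fp > 0))  # samples without test calls absent
})

test_that("FP attribution flags low-PPV samples with strict comparison", {
  test <- toy_callset(c(rep("bad", 5), rep("good", 10)), "1",
                      start = seq(1e6, 15e6, 1e6),
                      end = seq(1e6, 15e6, 1e6) + 1e4, copy_number = 1)
  truth <- toy_callset("good", "1", seq(6e6, 14e6, 1e6),
                       seq(6e6, 14e6, 1e6) + 1e4, copy_number = 1)
  cls <- suppressWarnings(classify_calls(test, truth))
  # bad: tp=0 fp=5 (ppv 0); good: tp=9 fp=1 (ppv 0.9)
  fa <- fp_attribution(cls, 0.1)
  expect_equal(fa$frac_samples_flagged, 0.5)
  expect_equal(fa$frac_fp_attributed, 5 / 6)
  expect_equal(fa$retained_counts$tp, 9)
  expect_equal(fa$retained_counts$fp, 1)

  none <- fp_attribution(cls, 0)
  expect_equal(none$frac_samples_flagged, 0)
  expect_equal(none$frac_fp_attributed, 0)

  all_fp <- fp_attribution(cls, 1)
  expect_true("bad" %in% all_fp$flagged_samples)
})

test_that("excluding low-PPV samples cannot lower aggregate PPV", {
  set.seed(77)
  for (i in 1:5) {
    sim <- simulate_callset_pair(callset_sim_config(
      n_samples = 30, fp_rate_per_sample = 3, seed = 77 + i))
    cls <- classify_calls(sim$test, sim$truth)
    before <- compute_metrics(cls)$ppv
    fa <- fp_attribution(cls, 0.5)
    tab <- samplewise_ppv(cls)
    flagged_below_aggregate <- all(
      tab$ppv[tab$sample_id %in% fa$flagged_samples] < before)
    if (flagged_below_aggregate && length(fa$flagged_samples) > 0) {
      expect_gte(compute_metrics(fa$retained_counts)$ppv, before)
    }
  }
})

test_that("curves smooth on log10(d_max) and scale against the full set", {
  grid <- default_dmax_grid()
  res <- data.frame(method = "distance", d_max = grid, tp = 50, fp = 50,
                    fn = 50)
  curve <- build_metric_curves(res, confusion_counts(100, 0, 0))
  ppv <- curve[curve$metric == "ppv", ]
  expect_equal(ppv$smoothed, rep(0.5, 12), tolerance = 1e-8)
  expect_equal(ppv$scaled, ppv$smoothed)  # full-set metric is 1

  # linear-in-log10 raw values are reproduced by loess
  tp <- round(10 * log10(grid))
  res2 <- data.frame(method = "distance", d_max = grid, tp = tp,
                     fp = 100 - tp, fn = 10)
  curve2 <- build_metric_curves(res2, NULL)
  ppv2 <- curve2[curve2$metric == "ppv", ]
  expect_equal(ppv2$smoothed, ppv2$raw, tolerance = 0.02)

  short <- data.frame(method = "distance", d_max = c(10, 100), tp = c(1, 2),
                      fp = 1, fn = 1)
  expect_warning(c3 <- build_metric_curves(short, NULL, metrics = "ppv"),
                 "smoothing skipped")
  expect_equal(c3$smoothed[c3$metric == "ppv"],
               c3$raw[c3$metric == "ppv"])
})

test_that("d_max selection finds the plateau onset", {
  grid <- default_dmax_grid()
  flat <- tibble::tibble(method = "distance", d_max = grid, metric = "ppv",
                         scaled = 0.9)
  expect_equal(select_dmax(flat)$d_max, 10)

  peak <- tibble::tibble(method = "distance", d_max = grid, metric = "ppv",
                         scaled = c(1:6, 12, 5:1) / 12)
  expect_equal(select_dmax(peak, tolerance = 0)$d_max, 1e4)

  rising <- tibble::tibble(method = "distance", d_max = grid, metric = "ppv",
                           scaled = c(0.2, 0.3, 0.45, 0.6, 0.75, 0.88,
                                      rep(0.95, 6)))
  expect_equal(select_dmax(rising)$d_max, 1e4)
  expect_error(select_dmax(flat[1, ]), "at least 2")
})
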