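test_that("orientation picks the smaller manifest, labels break ties", {
  small <- random_manifest(5, "S")
  big <- random_manifest(9, "B")
  o <- orient_manifests(big, small)
  expect_equal(manifest_label(o$reference), "S")
  o2 <- orient_manifests(small, big)
  expect_equal(manifest_label(o2$reference), "S")

  a <- toy_manifest("a", "1", 1, label = "A")
  b <- toy_manifest("b", "1", 2, label = "B")
  expect_equal(manifest_label(orient_manifests(b, a)$reference), "A")
  expect_error(orient_manifests(a, toy_manifest(character(), character(),
                                                numeric())), "empty")
})

test_that("exact matching intersects on (chrom, pos) with name-aware ties", {
  m <- random_manifest(50, "I", colocate_frac = 0)
  ex <- exact_match(m, m)
  expect_equal(nrow(ex), 50)
  expect_true(all(ex$stage == "exact" & ex$distance_bp == 0))

  r <- toy_manifest(c("a", "b"), "1", c(100, 200))
  s <- toy_manifest(c("x", "y"), "1", c(100, 300))
  ex2 <- exact_match(r, s)
  expect_equal(ex2$ref_name, "a")
  expect_equal(ex2$match_name, "x")

  disjoint <- toy_manifest(c("q", "r"), "1", c(900, 950))
  expect_equal(nrow(exact_match(r, disjoint)), 0)

  # co-located loci: identical name preferred, then smallest name
  r3 <- toy_manifest(c("p1", "p9"), "1", c(5, 5))
  s3 <- toy_manifest(c("p9", "p0"), "1", c(5, 5))
  ex3 <- exact_match(r3, s3)
  expect_equal(ex3$match_name[ex3$ref_name == "p9"], "p9")
  expect_equal(ex3$match_name[ex3$ref_name == "p1"], "p0")
})

test_that("exact matching can key on names instead of coordinates", {
  r <- toy_manifest(c("rs1", "rs2"), "1", c(100, 200))
  s <- toy_manifest(c("rs1", "rs3"), "1", c(140, 200))
  ex <- exact_match(r, s, key = "name")
  expect_equal(ex$ref_name, "rs1")
  expect_equal(ex$distance_bp, 40)
})

test_that("proximity matching respects d_max inclusively and greedy order", {
  r <- toy_manifest("A", "1", 100)
  s <- toy_manifest("B", "1", 150)
  p <- proximity_match(r, s, match_params(60, "distance"))
  expect_equal(p$match_name, "B")
  expect_equal(p$distance_bp, 50)

  expect_equal(nrow(proximity_match(r, s, match_params(10, "distance"))), 0)
  # boundary inclusive
  expect_equal(nrow(proximity_match(r, s, match_params(50, "distance"))), 1)

  # the spec's worked 2x2: method changes the assignment
  r2 <- toy_manifest(c("A", "B"), "1", c(100, 200), baf = c(0.5, 0.5))
  s2 <- toy_manifest(c("C", "D"), "1", c(110, 210), baf = c(0.9, 0.5))
  by_baf <- proximity_match(r2, s2, match_params(150, "baf"))
  expect_equal(by_baf$match_name[by_baf$ref_name == "A"], "D")
  expect_equal(by_baf$match_name[by_baf$ref_name == "B"], "C")
  by_dist <- proximity_match(r2, s2, match_params(150, "distance"))
  expect_equal(by_dist$match_name[by_dist$ref_name == "A"], "C")
  expect_equal(by_dist$match_name[by_dist$ref_name == "B"], "D")
})

test_that("missing annotations are skipped, never treated as zero difference", {
  r <- toy_manifest("A", "1", 100, baf = 0.5)
  s <- toy_manifest(c("near", "far"), "1", c(110, 190),
                    baf = c(NA_real_, 0.6))
  p <- proximity_match(r, s, match_params(100, "baf"))
  expect_equal(p$match_name, "far")
  expect_equal(attr(p, "skipped")[["candidates_missing_annotation"]], 1)

  r_na <- toy_manifest("A", "1", 100)
  p2 <- proximity_match(r_na, s, match_params(100, "baf"))
  expect_equal(nrow(p2), 0)
  expect_equal(attr(p2, "skipped")[["reference_missing_annotation"]], 1)
})

test_that("full runs are 1:1, conserve counts and handle containment", {
  m <- random_manifest(40, "M", colocate_frac = 0)
  res <- run_markermatch(m, m, match_params(10, "distance"))
  expect_equal(nrow(res$pairs), 40)
  expect_true(all(res$pairs$stage == "exact"))
  expect_equal(length(res$unmatched_ref), 0)

  set.seed(3)
  big <- random_manifest(120, "B", colocate_frac = 0)
  sub <- manifest(big[sample.int(120, 30), ], label = "S")
  res2 <- run_markermatch(big, sub, match_params(5, "distance"))
  expect_equal(manifest_label(sub), res2$ref_label)
  expect_equal(nrow(res2$pairs), 30)
  expect_equal(length(res2$unmatched_ref), 0)
})

test_that("matched manifests export exactly the paired probes", {
  a <- random_manifest(30, "A", colocate_frac = 0)
  b <- random_manifest(60, "B", colocate_frac = 0)
  res <- run_markermatch(a, b, match_params(1000, "distance"))
  mm <- export_matched_manifests(res, a, b)
  expect_equal(nrow(mm$reference), nrow(res$pairs))
  expect_equal(nrow(mm$matching), nrow(res$pairs))
  expect_setequal(mm$reference$name, res$pairs$ref_name)
  expect_setequal(mm$matching$name, res$pairs$match_name)
  # order of arguments must not matter
  mm2 <- export_matched_manifests(res, b, a)
  expect_equal(strip_meta(mm2$reference), strip_meta(mm$reference))

  none <- run_markermatch(toy_manifest("a", "1", 1, label = "A"),
                          toy_manifest("b", "2", 1, label = "B"),
                          match_params(10, "distance"))
  mm3 <- export_matched_manifests(none, toy_manifest("a", "1", 1, label = "A"),
                                  toy_manifest("b", "2", 1, label = "B"))
  expect_equal(nrow(mm3$reference), 0)
})

test_that("sweep rows agree with single runs and the exact stage is reused", {
  a <- random_manifest(25, "A", colocate_frac = 0)
  b <- random_manifest(50, "B", colocate_frac = 0)
  sw <- sweep_markermatch(a, b, d_max_grid = c(10, 1000),
                          methods = c("distance", "baf"))
  expect_equal(nrow(sw), 4)
  one <- run_markermatch(a, b, match_params(1000, "distance"))
  row <- sw[sw$d_max == 1000 & sw$method == "distance", ]
  expect_equal(row$n_pairs, nrow(one$pairs))
  expect_equal(row$n_exact, sum(one$pairs$stage == "exact"))
  expect_equal(length(unique(sw$n_exact)), 1)

  idsw <- sweep_markermatch(a, a, d_max_grid = c(10, 100))
  expect_true(all(idsw$coverage_ref == 1 & idsw$coverage_matching == 1))
  expect_error(sweep_markermatch(a, b, d_max_grid = c(100, 10)),
               "increasing")
})

test_that("coverage saturates once d_max exceeds all candidate distances", {
  # all nearest-candidate distances constructed to lie in (100, 1000]
  r <- toy_manifest(sprintf("r%02d", 1:10), "1", seq(10000, 100000, 10000),
                    baf = (1:10) / 10, lrr_mean = 0, lrr_sd = 0.1)
  offsets <- c(150, 300, 450, 600, 750, 900, 1000, 200, 350, 500)
  s <- toy_manifest(sprintf("s%02d", 1:10), "1",
                    seq(10000, 100000, 10000) + offsets,
                    baf = (10:1) / 10, lrr_mean = 0, lrr_sd = 0.1)
  sw <- sweep_markermatch(r, s, d_max_grid = c(100, 1000))
  expect_true(all(sw$coverage_ref[sw$d_max == 100] == 0))
  expect_true(all(sw$coverage_ref[sw$d_max == 1000] == 1))
})

test_that("position is accepted as an alias for the distance method", {
  expect_equal(match_params(10, "position")$method, "distance")
  expect_error(match_params(0, "distance"), "positive")
  expect_error(match_params(10, "what"))
})

test_that("optimized matcher equals the naive full-rescan oracle", {
  set.seed(99)
  for (i in 1:30) {
    n_ref <- sample(5:60, 1)
    n_mat <- sample(5:120, 1)
    a <- random_manifest(n_ref, "A", max_pos = 2000, na_frac = 0.15,
                         colocate_frac = 0.15)
    b <- random_manifest(n_mat, "B", max_pos = 2000, na_frac = 0.15,
                         colocate_frac = 0.15)
    method <- sample(c("distance", "baf", "lrr_mean", "lrr_sd"), 1)
    params <- match_params(sample(c(10, 100, 1000), 1), method)
    res <- run_markermatch(a, b, params)
    expect_identical(result_as_plain(res), naive_markermatch(a, b, params),
                     info = sprintf("instance %d (%s, d_max=%g)", i,
                                    method, params$d_max))
  }
})

test_that("matcher invariants hold on random instances", {
  set.seed(123)
  for (i in 1:60) {
    a <- random_manifest(sample(3:50, 1), "A", max_pos = 3000,
                         na_frac = 0.2, colocate_frac = 0.1)
    b <- random_manifest(sample(3:80, 1), "B", max_pos = 3000,
                         na_frac = 0.2, colocate_frac = 0.1)
    params <- match_params(sample(c(5, 50, 500), 1),
                           sample(c("distance", "baf"), 1))
    res <- run_markermatch(a, b, params)
    p <- res$pairs
    expect_false(any(duplicated(p$ref_name)))
    expect_false(any(duplicated(p$match_name)))
    expect_true(all(p$distance_bp[p$stage == "nearby"] <= params$d_max))
    expect_true(all(p$distance_bp[p$stage == "exact"] == 0))
    expect_lte(nrow(p), min(res$n_ref, res$n_matching))
    expect_equal(nrow(p) + length(res$unmatched_ref), res$n_ref)
  }
})

test_that("stage-1 pairs are invariant to d_max and method", {
  set.seed(5)
  a <- random_manifest(40, "A", max_pos = 2000, colocate_frac = 0.2)
  b <- random_manifest(80, "B", max_pos = 2000, colocate_frac = 0.2)
  exact_sets <- lapply(
    list(match_params(10, "distance"), match_params(1000, "baf"),
         match_params(100000, "lrr_sd")),
    function(p) {
      pr <- run_markermatch(a, b, p)$pairs
      pr[pr$stage == "exact", c("ref_name", "match_name")]
    })
  expect_identical(exact_sets[[1]], exact_sets[[2]])
  expect_identical(exact_sets[[1]], exact_sets[[3]])
})
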