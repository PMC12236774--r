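# Drop container metadata (labels, QC logs, rejection reports) so equality
# checks compare the data fields alone.
strip_meta <- function(x) {
  x <- as.data.frame(x)
  for (a in c("label", "qc_tier", "rejected", "qc_log")) attr(x, a) <- NULL
  rownames(x) <- NULL
  x
}

# Random test instances, built directly (not via the package's simulator)
# so matcher tests do not depend on the module they help validate.

random_manifest <- function(n, label, chroms = c("1", "2", "X"),
                            max_pos = 5e4, na_frac = 0.1,
                            colocate_frac = 0.1) {
  chrom <- sample(chroms, n, replace = TRUE)
  pos <- sample.int(max_pos, n, replace = TRUE)
  # force some shared loci so co-location tie rules get exercised
  n_co <- floor(n * colocate_frac)
  if (n_co >= 2) {
    idx <- sample.int(n, n_co)
    chrom[idx] <- chrom[idx[1]]
    pos[idx] <- pos[idx[1]]
  }
  ann <- function() {
    x <- runif(n)
    x[runif(n) < na_frac] <- NA_real_
    x
  }
  markermatch::manifest(
    data.frame(name = sprintf("%s%05d", label, seq_len(n)), chrom = chrom,
               pos = pos, baf = ann(), lrr_mean = ann() - 0.5,
               lrr_sd = ann()),
    label = label)
}

toy_manifest <- function(name, chrom, pos, baf = NA_real_,
                         lrr_mean = NA_real_, lrr_sd = NA_real_,
                         label = "toy") {
  markermatch::manifest(
    tibble::tibble(name = name, chrom = chrom, pos = pos, baf = baf,
                   lrr_mean = lrr_mean, lrr_sd = lrr_sd), label = label)
}

toy_callset <- function(sample_id, chrom, start, end, copy_number,
                        num_snps = 10L, confidence = 20, label = "toy") {
  markermatch::callset(
    tibble::tibble(sample_id = sample_id, chrom = chrom, start = start,
                   end = end, copy_number = copy_number,
                   num_snps = num_snps, confidence = confidence),
    label = label)
}
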