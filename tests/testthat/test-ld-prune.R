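test_that("genotype_matrix validates, sorts, and rejects monomorphic SNPs", {
  dos <- cbind(a = c(0, 1, 2, 1), b = c(1, 1, 1, 1), c = c(0, 0, 1, 2))
  expect_error(genotype_matrix(dos, chrom = c("1", "1", "1"),
                               pos = c(1, 2, 3)), "monomorphic")
  dos2 <- cbind(b = c(0, 1, 2, 1), a = c(0, 0, 1, 2))
  g <- genotype_matrix(dos2, chrom = c("1", "1"), pos = c(20, 10))
  expect_equal(g$snp_ids, c("a", "b"))  # re-sorted by position
  expect_error(genotype_matrix(cbind(a = c(0, 3, 1)), "1", 1), "dosages")
})

test_that("pairwise_r2 is squared Pearson correlation over complete pairs", {
  dos <- cbind(a = c(0, 1, 2, 0, 1, 2), b = c(0, 1, 2, 0, 1, 2),
               c = c(2, 1, 0, 2, 1, 0), d = c(0, 1, 0, 2, 1, 2),
               e = c(0, 0, 1, 1, 2, 2))
  g <- genotype_matrix(dos, chrom = rep("1", 5), pos = 1:5)
  expect_equal(pairwise_r2(g, "a", "b"), 1.0)          # identical vectors
  expect_equal(pairwise_r2(g, "a", "c"), 1.0)          # perfect negative
  expect_equal(pairwise_r2(g, "e", "d"), 0.25)         # hand-computed
  expect_error(pairwise_r2(g, 1, 1), "differ")

  miss <- cbind(a = c(0, 1, NA, NA, NA, 2), b = c(1, NA, 0, 1, 2, NA))
  gm <- genotype_matrix(miss, chrom = c("1", "1"), pos = 1:2)
  expect_error(pairwise_r2(gm, 1, 2), "fewer than 3")
})

test_that("snp_maf folds the allele frequency at 0.5", {
  dos <- cbind(a = c(1, 1, 1, 1, 1, 0),
               b = c(0, 0, 0, 2, 0, 0),
               c = c(0, 1, 1, 2, 2, 2))
  # make column a's frequency exactly 0.5 via an extra heterozygote row
  dos <- rbind(dos, c(2, 0, 0))
  g <- genotype_matrix(dos, chrom = rep("1", 3), pos = 1:3)
  expect_equal(snp_maf(g, "a"), min(mean(dos[, 1]) / 2,
                                    1 - mean(dos[, 1]) / 2))
  expect_equal(snp_maf(g, "b"), 2 / 14)
  expect_equal(snp_maf(g, "c"), min(8 / 14, 6 / 14))
  dos2 <- cbind(allone = c(1, 1, 1, 1, 0, 2))  # mean dosage 1 -> maf 0.5
  g2 <- genotype_matrix(dos2, "1", 1)
  expect_equal(snp_maf(g2, 1), 0.5)
})

test_that("pruning keeps everything under the threshold and applies the MAF rule", {
  set.seed(1)
  # near-independent SNPs: nothing should be removed
  dos <- matrix(sample(0:2, 50 * 12, TRUE), 50, 12)
  colnames(dos) <- sprintf("s%02d", 1:12)
  g <- make_ld_dosages(60, 12, block = 1, flip = 1, seed = 2)
  pr <- ld_prune(g, window = 5, step = 2, r2_max = 0.999)
  expect_equal(pr$kept, g$snp_ids)
  expect_equal(nrow(pr$removed), 0)

  # duplicated SNP pair: the smaller-MAF copy is removed
  common <- c(0, 1, 2, 0, 1, 2, 0, 1)
  rare <- c(0, 0, 1, 0, 0, 1, 0, 0)
  dup <- cbind(s1 = rare, s2 = common, s3 = rare)  # s1/s3 duplicates, r2 = 1
  g2 <- genotype_matrix(dup[, c(1, 3)], chrom = c("1", "1"), pos = c(10, 20))
  pr2 <- ld_prune(g2, window = 2, step = 1, r2_max = 0.2)
  # identical MAF: tie broken by removing the larger position
  expect_equal(pr2$kept, "s1")
  expect_equal(pr2$removed$reason, "maf_tie_larger_pos")
  g3 <- genotype_matrix(cbind(lo = rare, hi = common),
                        chrom = c("1", "1"), pos = c(10, 20))
  r2_12 <- pairwise_r2(g3, 1, 2)
  pr3 <- ld_prune(g3, window = 2, step = 1, r2_max = min(0.2, r2_12 / 2))
  expect_equal(pr3$removed$removed_id, "lo")  # smaller MAF goes
  expect_equal(pr3$removed$reason, "smaller_maf")
})

test_that("pruning matches the literal greedy-scan oracle", {
  for (seed in 1:4) {
    g <- make_ld_dosages(50, 60, block = 6, flip = 0.2, seed = seed)
    pr <- ld_prune(g, window = 4, step = 2, r2_max = 0.2)
    expect_identical(pr$kept, prune_oracle(g, 4, 2, 0.2))
    expect_setequal(c(pr$kept, pr$removed$removed_id), g$snp_ids)
    expect_length(intersect(pr$kept, pr$removed$removed_id), 0)
  }
})

test_that("pruning invariants: window cleanliness, monotonicity, chromosome independence, determinism", {
  g <- make_ld_dosages(60, 80, block = 8, flip = 0.15, seed = 9, n_chrom = 2)
  pr <- ld_prune(g, window = 6, step = 3, r2_max = 0.3)
  expect_true(kept_windows_clean(g, pr$kept, 6, 0.3))

  # raising the threshold never shrinks the kept set
  sizes <- vapply(c(0.1, 0.3, 0.6, 0.9),
                  function(t) length(ld_prune(g, 6, 3, t)$kept), 0)
  expect_true(all(diff(sizes) >= 0))

  # pruning two chromosomes together equals pruning them separately
  both <- ld_prune(g, 6, 3, 0.3)$kept
  per_chrom <- unlist(lapply(unique(g$chrom), function(ch) {
    sel <- g$chrom == ch
    gc <- genotype_matrix(g$dosages[, sel, drop = FALSE],
                          chrom = g$chrom[sel], pos = g$pos[sel])
    ld_prune(gc, 6, 3, 0.3)$kept
  }))
  expect_identical(both, per_chrom)

  expect_identical(ld_prune(g, 6, 3, 0.3), ld_prune(g, 6, 3, 0.3))
  expect_error(ld_prune(g, window = 1), "window")
  expect_error(ld_prune(g, window = 4, step = 5), "step")
  expect_error(ld_prune(g, r2_max = 1.5), "r2_max")
})

test_that("genotype panel round-trips through plain-text files", {
  g <- make_ld_dosages(20, 15, block = 3, seed = 4)
  fd <- tempfile(fileext = ".tsv")
  fm <- tempfile(fileext = ".map")
  write_genotype_matrix(g, fd, fm)
  back <- read_genotype_matrix(fd, fm)
  expect_equal(back$snp_ids, g$snp_ids)
  expect_equal(unname(back$dosages), unname(g$dosages))
  expect_equal(back$pos, g$pos)
})
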