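# Fixture builders; constructed in code, independent of the package's own
# simulator where they serve as its cross-check.

# Block-correlated dosage matrix: each block starts from a fresh random
# column and chains mutated copies, giving decaying LD within blocks.
make_ld_dosages <- function(n_ind, n_snp, block = 5, flip = 0.15, seed = 1,
                            n_chrom = 1) {
  set.seed(seed)
  dos <- matrix(0L, n_ind, n_snp)
  col <- NULL
  for (j in seq_len(n_snp)) {
    if ((j - 1) %% block == 0)
      col <- sample(0:2, n_ind, replace = TRUE, prob = c(0.45, 0.40, 0.15))
    mut <- runif(n_ind) < flip
    col[mut] <- sample(0:2, sum(mut), replace = TRUE)
    while (length(unique(col)) < 2)
      col[sample(n_ind, 1)] <- sample(0:2, 1)
    dos[, j] <- col
  }
  colnames(dos) <- sprintf("s%04d", seq_len(n_snp))
  chrom <- as.character(rep(seq_len(n_chrom), length.out = n_snp))
  chrom <- sort(chrom)
  genotype_matrix(dos, chrom = chrom,
                  pos = unlist(lapply(table(chrom), seq_len)) * 100)
}

# small summary-stat data frame in the read_summary_stats() layout
make_stats <- function(rsid, chrom = "1", pos = seq_along(rsid) * 1000,
                       p = runif(length(rsid)), ea = "A", oa = "G",
                       maf = 0.3) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa,
             p = p, maf = maf, effect_sign = NA_character_,
             stringsAsFactors = FALSE)
}
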