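#' Configuration for the two-trait GWAS simulator
#'
#' Defines the generative model for a pair of synthetic GWAS summary-statistic
#' tables with known pleiotropic structure. Each SNP is assigned one of four
#' association classes with probabilities `class_probs`: null for both traits
#' (`"00"`), associated with trait 1 only (`"10"`), trait 2 only (`"01"`), or
#' both (`"11"`). Non-null z-scores follow a scale mixture of normals,
#' `z ~ N(0, 1 + tau^2)`, so effects are symmetric in sign, matching the
#' two-sided p-values the cFDR machinery consumes. Two-sided p-values are
#' computed exactly from the z-scores, never resampled.
#'
#' The accompanying genotype panel (used only for LD pruning) is generated as
#' two latent haplotypes per individual with AR(1) correlation `rho` between
#' adjacent SNPs within blocks of `block_size` SNPs, thresholded at the
#' per-SNP minor-allele-frequency quantile and summed to dosages in
#' \{0, 1, 2\}.
#'
#' @param n_snps Number of SNPs shared by the two synthetic studies.
#' @param class_probs Probabilities `(pi00, pi10, pi01, pi11)` of the four
#'   association classes; non-negative, summing to 1 (tolerance 1e-12).
#' @param tau1,tau2 Non-negative effect-scale parameters: the standard
#'   deviation of a non-null z-score for trait t is `sqrt(1 + tau_t^2)`.
#' @param n_individuals Individuals in the genotype panel.
#' @param block_size SNPs per LD block (>= 1).
#' @param rho Within-block adjacent-SNP latent correlation, in (-1, 1).
#' @param maf_range Interval within (0, 0.5] from which per-SNP minor allele
#'   frequencies are drawn uniformly.
#' @param n_chrom Number of chromosomes the SNPs are laid out on.
#' @param seed Integer root seed; sub-streams for class labels, trait-1
#'   z-scores, trait-2 z-scores and genotypes are derived from it
#'   deterministically.
#' @return A `simulation_config` list.
#' @seealso [simulate_summary_pair()]
#' @export
#' @examples
#' cfg <- simulation_config(n_snps = 1000, seed = 7)
#' pair <- simulate_summary_pair(cfg)
#' table(pair$truth$class)
simulation_config <- function(n_snps = 20000,
                              class_probs = c(0.90, 0.025, 0.025, 0.05),
                              tau1 = 4, tau2 = 4,
                              n_individuals = 200,
                              block_size = 10,
                              rho = 0.8,
                              maf_range = c(0.05, 0.5),
                              n_chrom = 2,
                              seed = 1) {
  if (!is_count(n_snps)) stop_config("n_snps must be a positive integer")
  if (length(class_probs) != 4 || any(is.na(class_probs)) ||
      any(class_probs < 0) || abs(sum(class_probs) - 1) > 1e-12)
    stop_config("class_probs must be 4 non-negative values summing to 1")
  if (tau1 < 0 || tau2 < 0) stop_config("tau1 and tau2 must be non-negative")
  if (!is_count(n_individuals)) stop_config("n_individuals must be a positive integer")
  if (!is_count(block_size)) stop_config("block_size must be >= 1")
  if (abs(rho) >= 1) stop_config("rho must lie in (-1, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 ||
      maf_range[1] > maf_range[2] || maf_range[2] > 0.5)
    stop_config("maf_range must satisfy 0 < lower <= upper <= 0.5")
  if (!is_count(n_chrom)) stop_config("n_chrom must be a positive integer")
  structure(list(n_snps = as.integer(n_snps), class_probs = class_probs,
                 tau1 = tau1, tau2 = tau2,
                 n_individuals = as.integer(n_individuals),
                 block_size = as.integer(block_size), rho = rho,
                 maf_range = maf_range, n_chrom = as.integer(n_chrom),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# non-palindromic allele pairs only, so synthetic pairs always survive
# ambiguity filtering during harmonization
.allele_pairs <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))

#' Simulate a pair of GWAS summary-statistic tables with known truth
#'
#' Draws per-SNP association classes, trait z-scores and a block-LD genotype
#' panel under the model described in [simulation_config()]. Identical
#' configurations (including the seed) reproduce identical output. Positions
#' are strictly increasing within each chromosome. Each random component
#' (class labels and layout, trait-1 z-scores, trait-2 z-scores, genotypes)
#' consumes its own deterministic sub-stream of the root seed, so e.g.
#' skipping genotype generation leaves the summary statistics unchanged.
#'
#' @param config A [simulation_config()].
#' @param include_genotypes Generate the dosage panel (default `TRUE`). The
#'   summary statistics are identical either way.
#' @return A `simulated_study_pair` list with elements `stats1` and `stats2`
#'   (summary-stat data frames: rsid, chrom, pos, effect_allele, other_allele,
#'   p, maf), `truth` (data frame rsid, class in \{"00","10","01","11"\}),
#'   `genotypes` (a [genotype_matrix()] or `NULL`) and `config`.
#' @export
simulate_summary_pair <- function(config, include_genotypes = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_snps

  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, 4L)

  # stream 1: class labels, genomic layout, MAF, alleles
  set.seed(sub_seeds[1])
  cls <- sample(c("00", "10", "01", "11"), n, replace = TRUE,
                prob = config$class_probs)
  chrom_sizes <- diff(round(seq(0, n, length.out = config$n_chrom + 1)))
  chrom <- rep(as.character(seq_len(config$n_chrom)), times = chrom_sizes)
  gaps <- sample.int(9000L, n, replace = TRUE) + 1000L
  chrom_f <- factor(chrom, levels = unique(chrom))
  pos <- unlist(lapply(split(gaps, chrom_f), cumsum), use.names = FALSE)
  maf <- runif(n, config$maf_range[1], config$maf_range[2])
  pair_idx <- sample.int(length(.allele_pairs), n, replace = TRUE)
  ea <- vapply(.allele_pairs[pair_idx], `[`, "", 1L)
  oa <- vapply(.allele_pairs[pair_idx], `[`, "", 2L)
  rsid <- sprintf("snp%06d", seq_len(n))

  # streams 2 and 3: trait z-scores
  set.seed(sub_seeds[2])
  z1 <- rnorm(n) * ifelse(cls %in% c("10", "11"), sqrt(1 + config$tau1^2), 1)
  set.seed(sub_seeds[3])
  z2 <- rnorm(n) * ifelse(cls %in% c("01", "11"), sqrt(1 + config$tau2^2), 1)
  p1 <- pmax(2 * pnorm(-abs(z1)), 1e-300)
  p2 <- pmax(2 * pnorm(-abs(z2)), 1e-300)

  mk_stats <- function(p) data.frame(
    rsid = rsid, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa,
    p = p, maf = maf, stringsAsFactors = FALSE)

  genotypes <- NULL
  if (include_genotypes) {
    set.seed(sub_seeds[4])
    dos <- simulate_dosages(n, config$n_individuals, config$block_size,
                            config$rho, maf, chrom)
    colnames(dos) <- rsid
    genotypes <- genotype_matrix(dos, chrom = chrom, pos = pos)
  }

  structure(list(stats1 = mk_stats(p1), stats2 = mk_stats(p2),
                 truth = data.frame(rsid = rsid, class = cls,
                                    stringsAsFactors = FALSE),
                 genotypes = genotypes, config = config),
            class = "simulated_study_pair")
}

# latent AR(1) haplotype model; blocks never span chromosomes
simulate_dosages <- function(n_snps, n_ind, block_size, rho, maf, chrom) {
  thr <- qnorm(1 - maf)  # latent > thr  <=>  minor allele present
  dos <- matrix(0L, nrow = n_ind, ncol = n_snps)
  draw_hap <- function(cols) {
    m <- length(cols)
    lat <- matrix(0, n_ind, m)
    lat[, 1] <- rnorm(n_ind)
    if (m > 1) {
      innov <- sqrt(1 - rho^2)
      for (t in 2:m) lat[, t] <- rho * lat[, t - 1] + innov * rnorm(n_ind)
    }
    lat
  }
  for (ch in unique(chrom)) {
    cols_ch <- which(chrom == ch)
    blocks <- split(cols_ch, ceiling(seq_along(cols_ch) / block_size))
    for (cols in blocks) {
      lat1 <- draw_hap(cols)
      lat2 <- draw_hap(cols)
      thr_b <- matrix(thr[cols], n_ind, length(cols), byrow = TRUE)
      dos[, cols] <- (lat1 > thr_b) + (lat2 > thr_b)
    }
  }
  # pruning rejects monomorphic SNPs; re-draw degenerate columns by flipping
  # one individual, keeping allele count as close to target as possible
  for (j in seq_len(ncol(dos))) {
    if (length(unique(dos[, j])) < 2L) {
      dos[1L, j] <- if (dos[1L, j] == 0L) 1L else dos[1L, j] - 1L
    }
  }
  dos
}

#' Realized false discovery rate and power of a call set
#'
#' Scores a set of called SNPs against simulated ground truth. A call is a
#' true positive when its truth class belongs to `positive_classes`.
#'
#' @param calls Character vector of called SNP ids (may be empty).
#' @param truth Data frame with columns `rsid` and `class`, as produced by
#'   [simulate_summary_pair()].
#' @param positive_classes Truth classes counted as positives
#'   (default `"11"`, the shared/pleiotropic class).
#' @return List with `fdr` (false calls / calls; 0 when no calls) and `power`
#'   (true calls / positives; 0 when there are no positives).
#' @export
realized_fdr_power <- function(calls, truth, positive_classes = "11") {
  stopifnot(is.data.frame(truth), all(c("rsid", "class") %in% names(truth)))
  calls <- as.character(calls)
  missing <- setdiff(calls, truth$rsid)
  if (length(missing))
    stop("call ids absent from truth: ", paste(utils::head(missing, 5), collapse = ", "))
  cls <- truth$class[match(calls, truth$rsid)]
  n_pos <- sum(truth$class %in% positive_classes)
  fdr <- if (length(calls) == 0) 0 else mean(!(cls %in% positive_classes))
  power <- if (n_pos == 0) 0 else sum(cls %in% positive_classes) / n_pos
  list(fdr = fdr, power = power)
}
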