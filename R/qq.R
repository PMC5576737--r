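#' Conditional Q-Q stratified enrichment data
#'
#' Builds the data behind conditional Q-Q plots: for each conditional-trait
#' threshold `t`, the stratum of SNPs with conditional p-value `p_j <= t` is
#' extracted and the principal p-values within it are ranked. The nominal
#' axis is `-log10(p_i)` (sorted ascending in p), and the empirical quantile
#' for rank r (1-based) is `r / (n_stratum + 1)`, reported as
#' `-log10` as well; the `n + 1` denominator keeps the top rank finite.
#' Leftward/upward deflection of tighter strata from the identity line
#' indicates cross-trait enrichment.
#'
#' @param pv A [paired_pvalues()] object or data frame with `p1`, `p2`.
#' @param principal Principal trait (1 or 2); the other trait conditions the
#'   strata.
#' @param thresholds Strictly decreasing conditional p-value cuts in (0, 1]
#'   (default `c(1, 0.1, 0.01, 0.001)`; the first stratum normally contains
#'   all SNPs).
#' @return A list of `qq_stratum` objects, one per threshold, each with
#'   elements `threshold`, `n_snps`, `nominal_neglog_p` and
#'   `empirical_neglog_q` (matched vectors; empty when the stratum is empty).
#' @export
conditional_qq_data <- function(pv, principal = 1L,
                                thresholds = c(1, 0.1, 0.01, 0.001)) {
  stopifnot(all(c("p1", "p2") %in% names(pv)))
  if (any(thresholds <= 0) || any(thresholds > 1) ||
      any(diff(thresholds) >= 0))
    stop_config("thresholds must be strictly decreasing, each in (0, 1]")
  principal <- as.integer(principal)
  if (!principal %in% c(1L, 2L)) stop_config("principal must be 1 or 2")
  p_i <- if (principal == 1L) pv$p1 else pv$p2
  p_j <- if (principal == 1L) pv$p2 else pv$p1
  lapply(thresholds, function(t) {
    p_s <- sort(p_i[p_j <= t])
    n_s <- length(p_s)
    q <- if (n_s) seq_len(n_s) / (n_s + 1) else numeric(0)
    structure(list(threshold = t, n_snps = n_s,
                   nominal_neglog_p = -log10(p_s),
                   empirical_neglog_q = -log10(q)),
              class = "qq_stratum")
  })
}

#' Enrichment shift between two Q-Q strata
#'
#' Quantifies the leftward/upward deflection of one Q-Q stratum relative to a
#' reference as the median, over a fixed grid of matched empirical quantiles,
#' of the difference in nominal `-log10` p-values (stratum minus reference),
#' interpolating each stratum's nominal curve at the grid quantiles. The grid
#' is uniform on the quantile scale over the overlap of the two strata's
#' quantile ranges, so the median reflects the bulk of the distribution
#' rather than the extreme tail. Positive values mean the stratum's p-values
#' are smaller than the reference's at matched quantiles, i.e. cross-trait
#' enrichment.
#'
#' @param stratum,reference Non-empty `qq_stratum` objects from
#'   [conditional_qq_data()].
#' @param grid_size Number of grid points spanning the overlap of the two
#'   empirical-quantile ranges (default 101).
#' @return Median nominal `-log10(p)` shift (0 for a stratum compared with
#'   itself; exactly 1 when the stratum's p-values are the reference's
#'   times 0.1).
#' @export
qq_shift <- function(stratum, reference, grid_size = 101) {
  for (s in list(stratum, reference))
    if (!inherits(s, "qq_stratum") || s$n_snps == 0)
      stop("qq_shift requires non-empty qq_stratum inputs")
  # rank r pairs quantile r/(n+1) (ascending) with -log10 of the r-th
  # smallest p (descending); both stored vectors are already rank-matched
  qs <- 10^(-stratum$empirical_neglog_q)
  ys <- stratum$nominal_neglog_p
  qr <- 10^(-reference$empirical_neglog_q)
  yr <- reference$nominal_neglog_p
  lo <- max(min(qs), min(qr))
  hi <- min(max(qs), max(qr))
  if (!(hi > lo)) stop("strata have no overlapping quantile range")
  grid <- seq(lo, hi, length.out = grid_size)
  fs <- approx(qs, ys, xout = grid, ties = "ordered")$y
  fr <- approx(qr, yr, xout = grid, ties = "ordered")$y
  median(fs - fr)
}

#' Serialize conditional Q-Q data as a long TSV
#'
#' One row per (threshold, rank): columns threshold, rank, nominal_neglog_p,
#' empirical_neglog_q.
#'
#' @param qq List of `qq_stratum` objects from [conditional_qq_data()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_qq_data <- function(qq, path) {
  rows <- lapply(qq, function(s) {
    if (s$n_snps == 0) return(NULL)
    data.frame(threshold = s$threshold, rank = seq_len(s$n_snps),
               nominal_neglog_p = s$nominal_neglog_p,
               empirical_neglog_q = s$empirical_neglog_q)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(threshold = numeric(0), rank = integer(0),
                     nominal_neglog_p = numeric(0),
                     empirical_neglog_q = numeric(0))
  write_tsv(df, path)
}
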