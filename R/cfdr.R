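#' Paired p-values for two traits over shared SNPs
#'
#' Validated container for the paired p-value vectors the cFDR estimator
#' consumes. All p-values must lie in (0, 1]; floor extreme values upstream
#' with [apply_p_floor()].
#'
#' @param rsid Character SNP ids (unique).
#' @param p1,p2 p-value vectors for trait 1 and trait 2, same length as
#'   `rsid`.
#' @return A `paired_pvalues` data frame with columns rsid, p1, p2.
#' @export
paired_pvalues <- function(rsid, p1, p2) {
  n <- length(rsid)
  stopifnot(length(p1) == n, length(p2) == n)
  if (n == 0) stop_config("at least one SNP required")
  if (anyDuplicated(rsid)) stop_config("duplicated rsids")
  for (p in list(p1, p2))
    if (anyNA(p) || any(p <= 0) || any(p > 1))
      stop_config("p-values must lie in (0, 1] with no missing values")
  structure(data.frame(rsid = as.character(rsid), p1 = p1, p2 = p2,
                       stringsAsFactors = FALSE),
            class = c("paired_pvalues", "data.frame"))
}

# 2-d dominance count with inclusive ties: out[k] = #{m : x[m] <= x[k] and
# y[m] <= y[k]}. Fenwick-tree sweep over x in ascending order; groups of
# equal x are inserted before being queried so ties count mutually.
dominance_count <- function(x, y) {
  n <- length(x)
  ry <- match(y, sort(unique(y)))
  m_max <- max(ry)
  tree <- integer(m_max)
  ord <- order(x)
  res <- integer(n)
  xs <- x[ord]
  grp_end <- c(which(diff(xs) > 0), n)
  start <- 1L
  for (g in grp_end) {
    idx <- ord[start:g]
    for (k in idx) {
      i <- ry[k]
      while (i <= m_max) { tree[i] <- tree[i] + 1L; i <- i + bitwAnd(i, -i) }
    }
    for (k in idx) {
      i <- ry[k]; s <- 0L
      while (i > 0L) { s <- s + tree[i]; i <- i - bitwAnd(i, -i) }
      res[k] <- s
    }
    start <- g + 1L
  }
  res
}

# prefix-max analogue of the sweep above: out[k] = max of v[m] over
# x[m] <= x[k], y[m] <= y[k] (includes k itself)
dominance_max <- function(x, y, v) {
  n <- length(x)
  ry <- match(y, sort(unique(y)))
  m_max <- max(ry)
  tree <- rep(-Inf, m_max)
  ord <- order(x)
  res <- numeric(n)
  xs <- x[ord]
  grp_end <- c(which(diff(xs) > 0), n)
  start <- 1L
  for (g in grp_end) {
    idx <- ord[start:g]
    for (k in idx) {
      i <- ry[k]
      while (i <= m_max) {
        if (v[k] > tree[i]) tree[i] <- v[k]
        i <- i + bitwAnd(i, -i)
      }
    }
    for (k in idx) {
      i <- ry[k]; s <- -Inf
      while (i > 0L) { if (tree[i] > s) s <- tree[i]; i <- i - bitwAnd(i, -i) }
      res[k] <- s
    }
    start <- g + 1L
  }
  res
}

#' Empirical conditional false discovery rate
#'
#' For each SNP k with principal-trait p-value `p_i(k)` and conditional-trait
#' p-value `p_j(k)`, estimates the conditional FDR
#' `Pr(null for principal | P_i <= p_i(k), P_j <= p_j(k))` by the empirical
#' ratio
#' \deqn{\widehat{cFDR}(k) = p_i(k) \times
#'   \frac{|\{m : p_j(m) \le p_j(k)\}|}{|\{m : p_i(m) \le p_i(k),\ p_j(m) \le p_j(k)\}|},}
#' capped at 1. Counts are inclusive, so the denominator is at least 1 (the
#' SNP counts itself) and ties are permutation-invariant. The computation is
#' an O(N log N) Fenwick-tree sweep whose counts agree exactly with the
#' double-loop definition.
#'
#' With `monotone = TRUE`, each SNP's value is replaced by the maximum
#' estimate over all SNPs it dominates in both p-values, enforcing that the
#' cFDR is non-decreasing in the principal p-value within every conditioning
#' stratum (off by default).
#'
#' @param pv A [paired_pvalues()] object (or data frame with columns
#'   `p1`, `p2`).
#' @param principal Which trait is the principal one: 1 (p1 conditioned on
#'   p2) or 2 (p2 conditioned on p1).
#' @param monotone Enforce two-dimensional monotonicity (default `FALSE`).
#' @return Numeric vector of cFDR values in (0, 1], in input SNP order.
#' @export
empirical_cfdr <- function(pv, principal = 1L, monotone = FALSE) {
  stopifnot(all(c("p1", "p2") %in% names(pv)))
  principal <- as.integer(principal)
  if (!principal %in% c(1L, 2L)) stop_config("principal must be 1 or 2")
  p_i <- if (principal == 1L) pv$p1 else pv$p2
  p_j <- if (principal == 1L) pv$p2 else pv$p1
  num <- rank(p_j, ties.method = "max")
  den <- dominance_count(p_i, p_j)
  est <- pmin(p_i * num / den, 1)
  if (monotone) est <- pmin(dominance_max(p_i, p_j, est), 1)
  est
}

#' Conjunction cFDR
#'
#' The conjunction cFDR (ccFDR) estimates the probability that a SNP is null
#' for either trait; it is the elementwise maximum of the two directional
#' cFDR vectors.
#'
#' @param cfdr_a,cfdr_b Directional cFDR vectors of equal length, values in
#'   (0, 1].
#' @return Elementwise maximum.
#' @export
conjunction_cfdr <- function(cfdr_a, cfdr_b) {
  if (length(cfdr_a) != length(cfdr_b))
    stop("cFDR vectors must have equal length")
  pmax(cfdr_a, cfdr_b)
}

#' Significance calls at a strict threshold
#'
#' Flags values strictly smaller than `alpha`; a value exactly equal to the
#' threshold is not significant.
#'
#' @param values cFDR or ccFDR vector, values in (0, 1].
#' @param alpha Threshold (default 0.05).
#' @return Logical vector, `value < alpha`.
#' @export
call_significant <- function(values, alpha = 0.05) {
  values < alpha
}

#' Run the full cFDR analysis on a merged panel
#'
#' Restricts the panel to the pruned SNP set, computes the empirical cFDR in
#' both conditioning directions (trait 1 given trait 2, and the reverse), the
#' conjunction ccFDR, and significance flags at `alpha`.
#'
#' @param panel Merged panel from [harmonize_merge()] (columns rsid, chrom,
#'   pos, p1, p2).
#' @param kept Optional character vector of SNPs to retain (e.g.
#'   `ld_prune(...)$kept`); every id must be present in the panel. `NULL`
#'   keeps all SNPs.
#' @param alpha Significance threshold for all three calls (default 0.05).
#' @param monotone Passed to [empirical_cfdr()].
#' @return A `cfdr_table` data frame sorted by (chrom, pos) with columns
#'   rsid, chrom, pos, p1, p2, cfdr_1_given_2, cfdr_2_given_1, ccfdr,
#'   sig_1_given_2, sig_2_given_1, sig_conjunction.
#' @export
run_cfdr_pipeline <- function(panel, kept = NULL, alpha = 0.05,
                              monotone = FALSE) {
  stopifnot(is.data.frame(panel),
            all(c("rsid", "chrom", "pos", "p1", "p2") %in% names(panel)))
  if (!is.null(kept)) {
    missing <- setdiff(kept, panel$rsid)
    if (length(missing))
      stop("kept SNP(s) absent from panel: ",
           paste(utils::head(missing, 5), collapse = ", "))
    panel <- panel[panel$rsid %in% kept, , drop = FALSE]
  }
  panel <- panel[genomic_order(panel$chrom, panel$pos), , drop = FALSE]
  pv <- paired_pvalues(panel$rsid, panel$p1, panel$p2)
  c12 <- empirical_cfdr(pv, principal = 1L, monotone = monotone)
  c21 <- empirical_cfdr(pv, principal = 2L, monotone = monotone)
  cc <- conjunction_cfdr(c12, c21)
  out <- data.frame(rsid = panel$rsid, chrom = panel$chrom, pos = panel$pos,
                    p1 = panel$p1, p2 = panel$p2,
                    cfdr_1_given_2 = c12, cfdr_2_given_1 = c21, ccfdr = cc,
                    sig_1_given_2 = call_significant(c12, alpha),
                    sig_2_given_1 = call_significant(c21, alpha),
                    sig_conjunction = call_significant(cc, alpha),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cfdr_table", "data.frame")
  out
}

#' Write / read a cFDR table as TSV
#'
#' @param table A `cfdr_table` from [run_cfdr_pipeline()].
#' @param path File path.
#' @return `write_cfdr_table` returns `path` invisibly; `read_cfdr_table`
#'   returns the table.
#' @export
write_cfdr_table <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}

#' @rdname write_cfdr_table
#' @export
read_cfdr_table <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(rsid = "character", chrom = "character",
                                   pos = "numeric", p1 = "numeric",
                                   p2 = "numeric", cfdr_1_given_2 = "numeric",
                                   cfdr_2_given_1 = "numeric",
                                   ccfdr = "numeric",
                                   sig_1_given_2 = "logical",
                                   sig_2_given_1 = "logical",
                                   sig_conjunction = "logical"),
                    stringsAsFactors = FALSE)
  class(out) <- c("cfdr_table", "data.frame")
  out
}
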