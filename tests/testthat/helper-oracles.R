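# Independent oracles used only by the tests.

# Literal double-loop transcription of the cFDR estimator definition.
brute_cfdr <- function(p_i, p_j) {
  n <- length(p_i)
  out <- numeric(n)
  for (k in seq_len(n)) {
    num <- sum(p_j <= p_j[k])
    den <- sum(p_i <= p_i[k] & p_j <= p_j[k])
    out[k] <- min(1, p_i[k] * num / den)
  }
  out
}

# Literal transcription of the windowed greedy pruning scan: per chromosome,
# window over the first `window` kept SNPs, evaluate pairs in order, remove
# the smaller-MAF member of any pair with r2 > r2_max (tie: larger position),
# restart pair evaluation over remaining window members, advance by `step`,
# and repeat whole passes to a fixed point.
prune_oracle <- function(g, window, step, r2_max) {
  mafs <- vapply(seq_along(g$snp_ids), function(j) {
    x <- g$dosages[, j]
    x <- x[!is.na(x)]
    f <- mean(x) / 2
    min(f, 1 - f)
  }, numeric(1))
  kept_ids <- character(0)
  for (ch in unique(g$chrom)) {
    kept <- which(g$chrom == ch)
    repeat {
      any_removed <- FALSE
      ws <- 1L
      while (ws <= length(kept)) {
        win <- kept[ws:min(ws + window - 1L, length(kept))]
        scanning <- TRUE
        while (scanning && length(win) >= 2) {
          scanning <- FALSE
          m <- length(win)
          for (a in 1:(m - 1)) {
            for (b in (a + 1):m) {
              x <- g$dosages[, win[a]]
              y <- g$dosages[, win[b]]
              ok <- !is.na(x) & !is.na(y)
              r2 <- suppressWarnings(stats::cor(x[ok], y[ok])^2)
              if (!is.na(r2) && r2 > r2_max) {
                i <- win[a]; j <- win[b]
                drop <- if (mafs[i] < mafs[j]) i
                        else if (mafs[j] < mafs[i]) j
                        else if (g$pos[i] >= g$pos[j]) i else j
                win <- win[win != drop]
                kept <- kept[kept != drop]
                any_removed <- TRUE
                scanning <- TRUE
                break
              }
            }
            if (scanning) break
          }
        }
        ws <- ws + step
      }
      if (!any_removed) break
    }
    kept_ids <- c(kept_ids, g$snp_ids[kept])
  }
  kept_ids
}

# check that no pair of kept SNPs co-occurring within `window` consecutive
# kept positions on a chromosome exceeds r2_max
kept_windows_clean <- function(g, kept, window, r2_max) {
  idx <- match(kept, g$snp_ids)
  for (ch in unique(g$chrom[idx])) {
    kc <- idx[g$chrom[idx] == ch]
    for (s in seq_along(kc)) {
      e <- min(s + window - 1L, length(kc))
      if (e == s) next
      for (a in s:(e - 1)) for (b in (a + 1):e) {
        if (pairwise_r2(g, kc[a], kc[b]) > r2_max) return(FALSE)
      }
    }
  }
  TRUE
}
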