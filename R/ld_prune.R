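#' Genotype dosage matrix for LD computation
#'
#' Container for an individuals-by-SNPs dosage matrix used only to compute
#' pairwise r-squared (and MAF) during LD pruning. Dosages are minor-allele
#' counts in \{0, 1, 2\}; missing values are `NA`. SNPs are sorted by
#' (chrom, pos) on construction; monomorphic SNPs (fewer than two distinct
#' observed dosage values) are rejected.
#'
#' @param dosages Numeric/integer matrix, individuals in rows, SNPs in
#'   columns; values 0, 1, 2 or `NA`.
#' @param chrom Chromosome label per SNP.
#' @param pos 1-based position per SNP.
#' @param snp_ids SNP identifiers; defaults to `colnames(dosages)`.
#' @return A `genotype_matrix` list with elements `dosages`, `snp_ids`,
#'   `chrom`, `pos`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, snp_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  n_snp <- ncol(dosages)
  if (is.null(snp_ids)) stop_config("snp_ids required (or set colnames)")
  stopifnot(length(snp_ids) == n_snp, length(chrom) == n_snp,
            length(pos) == n_snp)
  if (anyDuplicated(snp_ids)) stop_config("duplicated SNP ids")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop_config("dosages must be 0, 1, 2 or NA")
  poly <- vapply(seq_len(n_snp), function(j) {
    length(unique(dosages[!is.na(dosages[, j]), j])) >= 2L
  }, logical(1))
  if (!all(poly))
    stop_config("monomorphic SNP(s) rejected: ",
                paste(utils::head(snp_ids[!poly], 5), collapse = ", "))
  o <- genomic_order(chrom, pos)
  dosages <- dosages[, o, drop = FALSE]
  colnames(dosages) <- snp_ids[o]
  structure(list(dosages = dosages, snp_ids = unname(snp_ids[o]),
                 chrom = unname(as.character(chrom)[o]),
                 pos = unname(pos[o])),
            class = "genotype_matrix")
}

resolve_snp_index <- function(g, i) {
  if (is.character(i)) {
    j <- match(i, g$snp_ids)
    if (is.na(j)) stop("unknown SNP id: ", i)
    return(j)
  }
  as.integer(i)
}

#' Pairwise linkage disequilibrium as squared Pearson correlation
#'
#' Computes r-squared between two SNPs as the squared Pearson correlation of
#' their dosage vectors over individuals with non-missing dosages at both.
#'
#' @param g A [genotype_matrix()].
#' @param i,j SNP indices (or ids); must differ.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(g, i, j) {
  stopifnot(inherits(g, "genotype_matrix"))
  i <- resolve_snp_index(g, i); j <- resolve_snp_index(g, j)
  if (i == j) stop("i and j must differ")
  x <- g$dosages[, i]; y <- g$dosages[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3)
    stop("undefined LD: fewer than 3 pairwise-complete individuals")
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined LD: SNP constant over pairwise-complete individuals")
  cor(x, y)^2
}

#' Minor allele frequency from dosages
#'
#' @param g A [genotype_matrix()].
#' @param j SNP index or id.
#' @return `min(f, 1 - f)` where `f` is the mean dosage over non-missing
#'   individuals divided by 2.
#' @export
snp_maf <- function(g, j) {
  stopifnot(inherits(g, "genotype_matrix"))
  j <- resolve_snp_index(g, j)
  x <- g$dosages[, j]
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("all dosages missing for SNP ", g$snp_ids[j])
  f <- mean(x) / 2
  min(f, 1 - f)
}

#' Windowed greedy LD pruning with MAF-based removal
#'
#' Reduces a SNP set to approximate linkage equilibrium. Within each
#' chromosome, a window of `window` currently-kept SNPs is scanned: every
#' within-window pair is evaluated in order and, whenever r-squared exceeds
#' `r2_max`, the member with the smaller minor allele frequency is removed
#' (on an exact MAF tie, the SNP at the larger genomic position), after which
#' pair evaluation restarts over the window's remaining members. When no
#' pair in the window exceeds the threshold, the window start advances by
#' `step` kept SNPs. Whole passes over each chromosome are repeated until a
#' pass removes nothing, so on termination no pair of kept SNPs that
#' co-occurs in a scanned window exceeds `r2_max`. Windows never span
#' chromosomes.
#'
#' @param g A [genotype_matrix()].
#' @param window Window size in SNPs (default 20, >= 2).
#' @param step Window shift in kept SNPs (default 5; 1 <= step <= window).
#' @param r2_max LD threshold (default 0.2); pairs with r-squared strictly
#'   greater are broken up.
#' @return A `prune_result` list: `kept` (ordered rsid vector) and `removed`
#'   (data frame removed_id, partner_id, r2, reason).
#' @export
ld_prune <- function(g, window = 20, step = 5, r2_max = 0.2) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is_count(window) || window < 2) stop_config("window must be >= 2")
  if (!is_count(step) || step < 1 || step > window)
    stop_config("step must satisfy 1 <= step <= window")
  if (!(r2_max >= 0 && r2_max <= 1)) stop_config("r2_max must lie in [0, 1]")
  n <- length(g$snp_ids)
  if (n == 0)
    return(structure(list(kept = character(0), removed = empty_removed()),
                     class = "prune_result"))

  mafs <- vapply(seq_len(n), function(j) snp_maf(g, j), numeric(1))
  removed_list <- list()

  kept_all <- character(0)
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    kept <- idx
    repeat {
      removed_any <- FALSE
      ws <- 1L
      while (ws <= length(kept)) {
        we <- min(ws + window - 1L, length(kept))
        if (we > ws) {
          win <- kept[ws:we]
          repeat {
            viol <- first_violation(g, win, mafs, r2_max)
            if (is.null(viol)) break
            removed_list[[length(removed_list) + 1L]] <-
              data.frame(removed_id = g$snp_ids[viol$drop],
                         partner_id = g$snp_ids[viol$partner],
                         r2 = viol$r2, reason = viol$reason,
                         stringsAsFactors = FALSE)
            win <- win[win != viol$drop]
            kept <- kept[kept != viol$drop]
            removed_any <- TRUE
            if (length(win) < 2L) break
          }
        }
        ws <- ws + step
      }
      if (!removed_any) break
    }
    kept_all <- c(kept_all, g$snp_ids[kept])
  }
  removed <- if (length(removed_list)) do.call(rbind, removed_list) else
    empty_removed()
  structure(list(kept = kept_all, removed = removed), class = "prune_result")
}

empty_removed <- function() data.frame(removed_id = character(0),
                                       partner_id = character(0),
                                       r2 = numeric(0),
                                       reason = character(0),
                                       stringsAsFactors = FALSE)

# first window pair (in scan order) with r2 > threshold, with the removal
# decision: smaller MAF goes; exact tie -> larger position goes
first_violation <- function(g, win, mafs, r2_max) {
  m <- length(win)
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      i <- win[a]; j <- win[b]
      r2 <- pairwise_r2(g, i, j)
      if (r2 > r2_max) {
        if (mafs[i] < mafs[j]) drop <- i
        else if (mafs[j] < mafs[i]) drop <- j
        else drop <- if (g$pos[i] >= g$pos[j]) i else j
        reason <- if (mafs[i] == mafs[j]) "maf_tie_larger_pos" else "smaller_maf"
        return(list(drop = drop, partner = if (drop == i) j else i,
                    r2 = r2, reason = reason))
      }
    }
  }
  NULL
}

#' Write / read a genotype panel as plain text
#'
#' The dosage file is a whitespace-delimited table, individuals as rows,
#' header of SNP ids (`NA` for missing); the map file has three columns
#' rsid, chrom, pos.
#'
#' @param g A [genotype_matrix()].
#' @param dosage_path,map_path File paths.
#' @return `write_genotype_matrix` returns the paths invisibly;
#'   `read_genotype_matrix` returns a [genotype_matrix()].
#' @export
write_genotype_matrix <- function(g, dosage_path, map_path) {
  write.table(g$dosages, dosage_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  write.table(data.frame(rsid = g$snp_ids, chrom = g$chrom, pos = g$pos),
              map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(dosage_path, map_path))
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(dosage_path, map_path) {
  dos <- as.matrix(read.table(dosage_path, header = TRUE, sep = "\t",
                              check.names = FALSE))
  map <- read.table(map_path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric"))
  ord <- match(colnames(dos), map$rsid)
  if (anyNA(ord)) stop("map file does not cover all SNPs in dosage file")
  genotype_matrix(dos, chrom = map$chrom[ord], pos = map$pos[ord])
}
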