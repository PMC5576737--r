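#' Read a GWAS summary-statistic table
#'
#' Parses a tab- or whitespace-delimited text file (optionally gzipped) of
#' per-SNP association results into the validated layout the rest of the
#' pipeline expects. Column roles are assigned through `column_map`, a named
#' character vector mapping role names to column names in the file. Roles
#' `rsid`, `chrom`, `pos` and `p` are mandatory; `effect_allele`,
#' `other_allele`, `maf` and `effect_sign` are optional.
#'
#' Rows whose chromosome, position or p-value cannot be parsed (including
#' p outside (0, 1] and chromosomes other than 1-22, X, Y, MT) are dropped
#' with a message stating the count. Exact zero p-values are replaced by
#' `p_floor` (and counted in the message), since downstream log transforms
#' and the cFDR ratio require strictly positive p.
#'
#' @param path File path; `.gz` input is accepted.
#' @param column_map Named character vector, e.g.
#'   `c(rsid = "SNP", chrom = "CHR", pos = "BP", p = "P")`.
#' @param p_floor Replacement for p-values of exactly 0 (default 1e-300).
#' @return A data frame with columns rsid, chrom, pos, effect_allele,
#'   other_allele, p, maf, effect_sign (optional columns `NA` when absent
#'   from the file).
#' @export
read_summary_stats <- function(path, column_map, p_floor = 1e-300) {
  if (!file.exists(path)) stop("file not found: ", path)
  required <- c("rsid", "chrom", "pos", "p")
  if (!all(required %in% names(column_map)))
    stop("column_map must assign columns for: ",
         paste(setdiff(required, names(column_map)), collapse = ", "))
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character", showProgress = FALSE)
  missing_cols <- setdiff(unname(column_map), names(dt))
  if (length(missing_cols))
    stop("columns not present in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (nrow(dt) == 0) stop("no data rows in ", path)

  get <- function(role) {
    if (role %in% names(column_map)) dt[[column_map[[role]]]] else
      rep(NA_character_, nrow(dt))
  }
  out <- data.frame(
    rsid = get("rsid"),
    chrom = toupper(sub("^chr", "", get("chrom"), ignore.case = TRUE)),
    pos = suppressWarnings(as.numeric(get("pos"))),
    effect_allele = toupper(get("effect_allele")),
    other_allele = toupper(get("other_allele")),
    p = suppressWarnings(as.numeric(get("p"))),
    maf = suppressWarnings(as.numeric(get("maf"))),
    effect_sign = get("effect_sign"),
    stringsAsFactors = FALSE)

  n_zero <- sum(!is.na(out$p) & out$p == 0)
  out$p[!is.na(out$p) & out$p == 0] <- p_floor
  bad <- is.na(out$pos) | out$pos < 1 | is.na(out$p) | out$p < 0 | out$p > 1 |
    is.na(chrom_rank(out$chrom)) | is.na(out$rsid) | out$rsid == ""
  if (any(bad)) {
    message(sum(bad), " row(s) dropped from ", basename(path),
            " (unparseable chrom/pos/p)")
    out <- out[!bad, , drop = FALSE]
  }
  if (n_zero > 0)
    message(n_zero, " zero p-value(s) floored at ", format(p_floor))
  if (nrow(out) == 0) stop("no valid rows after parsing ", path)
  dup <- unique(out$rsid[duplicated(out$rsid)])
  if (length(dup))
    stop("duplicated rsid(s) in ", basename(path), ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Floor extreme p-values
#'
#' Replaces every p-value below `floor` by `floor`, leaving all other values
#' untouched. Keeps extremely significant SNPs (p down to ~1e-250 occur in
#' large meta-analyses) finite under `-log10` and inside the open interval
#' the cFDR ratio requires.
#'
#' @param table Summary-stat data frame with a `p` column.
#' @param floor Lower bound, in (0, 1); default 1e-300.
#' @return The table with floored p-values.
#' @export
apply_p_floor <- function(table, floor = 1e-300) {
  stopifnot(is.data.frame(table), "p" %in% names(table))
  if (!(floor > 0 && floor < 1)) stop_config("floor must lie in (0, 1)")
  table$p <- pmax(table$p, floor)
  table
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize and merge two summary-stat tables into a paired panel
#'
#' Intersects two tables by rsid and reconciles alleles, mirroring the usual
#' combination of common SNPs across two GWAS. For each shared rsid:
#' identical allele pairs are retained as `direct`; pairs that match after
#' complementing both alleles are retained as `strand_flipped`; palindromic
#' (A/T or C/G) SNPs, whose strand cannot be resolved without frequencies,
#' are dropped when `drop_ambiguous` is `TRUE`; irreconcilable alleles, and
#' rsids whose chrom/pos disagree between sources, are dropped as mismatches
#' (counted, not fatal). When either table lacks allele columns the merge
#' keys on rsid alone and rows are marked `direct`.
#'
#' @param t1,t2 Summary-stat data frames ([read_summary_stats()] layout);
#'   trait 1 and trait 2.
#' @param drop_ambiguous Drop palindromic SNPs (default `TRUE`).
#' @return A merged-panel data frame sorted by (chrom, pos) with columns
#'   rsid, chrom, pos, p1, p2, maf (taken from t1 when available, else t2)
#'   and alignment_note in \{"direct", "strand_flipped"\}. Dropped rsids and
#'   their reasons are attached as `attr(, "dropped")`.
#' @export
harmonize_merge <- function(t1, t2, drop_ambiguous = TRUE) {
  stopifnot(is.data.frame(t1), is.data.frame(t2))
  shared <- intersect(t1$rsid, t2$rsid)
  i1 <- match(shared, t1$rsid)
  i2 <- match(shared, t2$rsid)

  note <- rep("direct", length(shared))
  pos_conflict <- t1$chrom[i1] != t2$chrom[i2] | t1$pos[i1] != t2$pos[i2]
  note[pos_conflict] <- "dropped_mismatch"

  has_alleles <- !is.na(t1$effect_allele[i1]) & !is.na(t1$other_allele[i1]) &
    !is.na(t2$effect_allele[i2]) & !is.na(t2$other_allele[i2])
  idx <- which(has_alleles & note == "direct")
  if (length(idx)) {
    a1 <- t1$effect_allele[i1[idx]]; b1 <- t1$other_allele[i1[idx]]
    a2 <- t2$effect_allele[i2[idx]]; b2 <- t2$other_allele[i2[idx]]
    same <- (a1 == a2 & b1 == b2) | (a1 == b2 & b1 == a2)
    ca1 <- unname(.complement[a1]); cb1 <- unname(.complement[b1])
    flipped <- !same & !is.na(ca1) & !is.na(cb1) &
      ((ca1 == a2 & cb1 == b2) | (ca1 == b2 & cb1 == a2))
    palindromic <- !is.na(ca1) & ca1 == b1  # A/T or C/G
    note[idx[same]] <- "direct"
    note[idx[flipped]] <- "strand_flipped"
    note[idx[!same & !flipped]] <- "dropped_mismatch"
    if (drop_ambiguous)
      note[idx[palindromic & (same | flipped)]] <- "dropped_ambiguous"
  }

  dropped <- data.frame(rsid = shared, note = note,
                        stringsAsFactors = FALSE)
  dropped <- dropped[startsWith(dropped$note, "dropped"), , drop = FALSE]
  if (nrow(dropped))
    message(nrow(dropped), " shared SNP(s) dropped during harmonization (",
            sum(dropped$note == "dropped_ambiguous"), " ambiguous, ",
            sum(dropped$note == "dropped_mismatch"), " mismatched)")

  keep <- !startsWith(note, "dropped")
  maf <- t1$maf[i1]
  use2 <- is.na(maf) & !is.na(t2$maf[i2])
  maf[use2] <- t2$maf[i2][use2]
  panel <- data.frame(rsid = shared[keep],
                      chrom = t1$chrom[i1[keep]],
                      pos = t1$pos[i1[keep]],
                      p1 = t1$p[i1[keep]],
                      p2 = t2$p[i2[keep]],
                      maf = maf[keep],
                      alignment_note = note[keep],
                      stringsAsFactors = FALSE)
  panel <- panel[genomic_order(panel$chrom, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "dropped") <- dropped
  panel
}

#' Write / read a merged panel as TSV
#'
#' The TSV columns are rsid, chr, pos, p_trait1, p_trait2, maf,
#' alignment_note. Numeric columns are serialized with 17 significant digits
#' so that a write/read round trip reproduces the panel exactly.
#'
#' @param panel A merged panel from [harmonize_merge()].
#' @param path Output (or input) file path.
#' @return `write_merged_panel` returns `path` invisibly; `read_merged_panel`
#'   returns the panel data frame.
#' @export
write_merged_panel <- function(panel, path) {
  out <- data.frame(rsid = panel$rsid, chr = panel$chrom, pos = panel$pos,
                    p_trait1 = panel$p1, p_trait2 = panel$p2,
                    maf = panel$maf, alignment_note = panel$alignment_note,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' @rdname write_merged_panel
#' @export
read_merged_panel <- function(path) {
  dt <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c(rsid = "character", chr = "character",
                                  pos = "numeric", p_trait1 = "numeric",
                                  p_trait2 = "numeric", maf = "numeric",
                                  alignment_note = "character"),
                   stringsAsFactors = FALSE)
  data.frame(rsid = dt$rsid, chrom = dt$chr, pos = dt$pos,
             p1 = dt$p_trait1, p2 = dt$p_trait2, maf = dt$maf,
             alignment_note = dt$alignment_note, stringsAsFactors = FALSE)
}
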