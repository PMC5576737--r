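#' MHC region configuration
#'
#' Coordinates of the major histocompatibility complex (6p21.3) and its
#' class I / class III / class II sub-regions, used to annotate pleiotropic
#' hits. The defaults are conventional GRCh37 coordinates and can be
#' overridden for other builds or boundary conventions. Intervals are closed;
#' sub-intervals must lie within the MHC span and may share boundaries but
#' not interiors (the first matching sub-interval, in the order given, wins).
#'
#' @param mhc_chrom Chromosome carrying the MHC (default `"6"`).
#' @param mhc_span Closed interval `c(start, end)` of the full MHC region.
#' @param class_spans Named list of labelled closed sub-intervals.
#' @param build Genome build label (documentation only).
#' @return A `region_config` list.
#' @export
region_config <- function(mhc_chrom = "6",
                          mhc_span = c(28477797, 33448354),
                          class_spans = list(
                            "class I" = c(29640000, 31360000),
                            "class III" = c(31360000, 32300000),
                            "class II" = c(32300000, 33080000)),
                          build = "GRCh37") {
  stopifnot(length(mhc_span) == 2, mhc_span[1] <= mhc_span[2])
  for (s in class_spans) {
    stopifnot(length(s) == 2, s[1] <= s[2])
    if (s[1] < mhc_span[1] || s[2] > mhc_span[2])
      stop_config("class sub-interval outside the MHC span")
  }
  if (length(class_spans) > 1) {
    ss <- do.call(rbind, class_spans)
    ss <- ss[order(ss[, 1]), , drop = FALSE]
    if (any(ss[-1, 1] < ss[-nrow(ss), 2]))
      stop_config("class sub-intervals overlap")
  }
  structure(list(mhc_chrom = as.character(mhc_chrom), mhc_span = mhc_span,
                 class_spans = class_spans, build = build),
            class = "region_config")
}

#' Classify positions relative to the MHC region
#'
#' @param chrom,pos Vectors of chromosome labels and positions.
#' @param cfg A [region_config()].
#' @return Character vector with values `"outside"`, `"MHC-unclassified"`,
#'   or a class label from `cfg$class_spans` (first match in the configured
#'   order; interval boundaries are included).
#' @export
classify_region <- function(chrom, pos, cfg = region_config()) {
  stopifnot(inherits(cfg, "region_config"), length(chrom) == length(pos))
  out <- rep("outside", length(chrom))
  in_mhc <- as.character(chrom) == cfg$mhc_chrom &
    pos >= cfg$mhc_span[1] & pos <= cfg$mhc_span[2]
  out[in_mhc] <- "MHC-unclassified"
  for (lbl in rev(names(cfg$class_spans))) {
    s <- cfg$class_spans[[lbl]]
    out[in_mhc & pos >= s[1] & pos <= s[2]] <- lbl
  }
  out
}

#' Manhattan-plot data for a cFDR table
#'
#' Emits one row per SNP with the `-log10` of the selected FDR column, a
#' genome-wide cumulative x-coordinate, and a flag for points above the
#' customary significance line (`-log10(0.05) ~ 1.3`; the flag uses the
#' strict rule FDR < `alpha`, so a value exactly at the threshold sits on the
#' line but is not flagged).
#'
#' @param table A `cfdr_table` from [run_cfdr_pipeline()].
#' @param which Column to plot: `"dir1"` (cfdr_1_given_2), `"dir2"`
#'   (cfdr_2_given_1) or `"conjunction"` (ccfdr).
#' @param alpha Significance line (default 0.05).
#' @return Data frame rsid, chrom, pos, x (cumulative position),
#'   neglog_fdr, above_line.
#' @export
manhattan_data <- function(table, which = c("dir1", "dir2", "conjunction"),
                           alpha = 0.05) {
  which <- match.arg(which)
  col <- switch(which, dir1 = "cfdr_1_given_2", dir2 = "cfdr_2_given_1",
                conjunction = "ccfdr")
  val <- table[[col]]
  chroms <- unique(table$chrom[order(chrom_rank(table$chrom))])
  offsets <- setNames(numeric(length(chroms)), chroms)
  run <- 0
  for (ch in chroms) {
    offsets[ch] <- run
    run <- run + max(table$pos[table$chrom == ch])
  }
  data.frame(rsid = table$rsid, chrom = table$chrom, pos = table$pos,
             x = table$pos + offsets[as.character(table$chrom)],
             neglog_fdr = -log10(val),
             above_line = val < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pleiotropic-locus report
#'
#' One row per conjunction-significant SNP (ccFDR < alpha as recorded in the
#' table's `sig_conjunction` flag), sorted by genomic position, carrying the
#' raw p-values, both directional cFDRs, the ccFDR, an MHC region label, and
#' pass-through functional annotation (role, neighboring gene) when a map is
#' supplied. Annotation is never fetched from external services.
#'
#' @param table A `cfdr_table` from [run_cfdr_pipeline()].
#' @param annotations Optional data frame with columns rsid, role,
#'   neighbor_gene; unannotated SNPs get `NA`.
#' @param cfg A [region_config()] for the region label.
#' @return Data frame rsid, chrom, pos, role, neighbor_gene, raw_p1, raw_p2,
#'   cfdr_1_given_2, cfdr_2_given_1, ccfdr, region_label.
#' @export
build_report <- function(table, annotations = NULL, cfg = region_config()) {
  stopifnot(is.data.frame(table))
  sig <- table[table$sig_conjunction, , drop = FALSE]
  sig <- sig[genomic_order(sig$chrom, sig$pos), , drop = FALSE]
  role <- gene <- rep(NA_character_, nrow(sig))
  if (!is.null(annotations) && nrow(sig)) {
    m <- match(sig$rsid, annotations$rsid)
    role <- as.character(annotations$role[m])
    gene <- as.character(annotations$neighbor_gene[m])
  }
  out <- data.frame(rsid = sig$rsid, chrom = sig$chrom, pos = sig$pos,
                    role = role, neighbor_gene = gene,
                    raw_p1 = sig$p1, raw_p2 = sig$p2,
                    cfdr_1_given_2 = sig$cfdr_1_given_2,
                    cfdr_2_given_1 = sig$cfdr_2_given_1,
                    ccfdr = sig$ccfdr,
                    region_label = classify_region(sig$chrom, sig$pos, cfg),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write the pleiotropy report as TSV
#'
#' p-values and FDR columns are rendered in scientific notation with two
#' digits after the decimal point (e.g. `4.39E-02`); serialization is
#' bit-stable for fixed input.
#'
#' @param report Data frame from [build_report()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- report
  for (col in c("raw_p1", "raw_p2", "cfdr_1_given_2", "cfdr_2_given_1",
                "ccfdr")) {
    v <- sprintf("%.2E", out[[col]])
    v[is.na(out[[col]])] <- "NA"
    out[[col]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Reported pleiotropic loci for femoral-neck BMD and rheumatoid arthritis
#'
#' Loads the bundled reference table of 30 loci reported as shared between
#' femoral-neck bone mineral density and rheumatoid arthritis by a published
#' conjunction-cFDR analysis of two large GWAS meta-analyses: per SNP, the
#' raw p-values, the two directional cFDR values and the published ccFDR.
#' Used as a worked example and as ground truth for the conjunction
#' arithmetic.
#'
#' @return Data frame with columns rsid, chrom, role, neighbor_gene,
#'   p_fnk_bmd, p_ra, cfdr_fnk_given_ra, cfdr_ra_given_fnk, ccfdr.
#' @export
example_pleiotropy_table <- function() {
  path <- system.file("extdata", "fnk_bmd_ra_pleiotropic_loci.tsv",
                      package = "pleiocfdr", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c("character", "character", "character",
                            "character", "numeric", "numeric", "numeric",
                            "numeric", "numeric"),
             stringsAsFactors = FALSE)
}
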