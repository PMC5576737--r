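# shared internal helpers

# canonical chromosome ordering used for all genomic sorts
.chrom_levels <- c(as.character(1:22), "X", "Y", "MT")

chrom_rank <- function(chrom) match(as.character(chrom), .chrom_levels)

genomic_order <- function(chrom, pos) order(chrom_rank(chrom), pos)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 1

stop_config <- function(...) stop(..., call. = FALSE)

# format a numeric column so that read.table round-trips it bit-for-bit
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
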