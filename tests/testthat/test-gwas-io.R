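write_stats_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

std_map <- c(rsid = "SNP", chrom = "CHR", pos = "BP", p = "P",
             effect_allele = "A1", other_allele = "A2", maf = "MAF")

test_that("read_summary_stats parses, drops bad rows, enforces uniqueness", {
  f <- write_stats_file(c("SNP\tCHR\tBP\tP\tA1\tA2\tMAF",
                          "rs1\t1\t100\t0.5\tA\tG\t0.2",
                          "rs2\t2\t200\t0.01\tC\tT\t0.1",
                          "rs3\tX\t300\t0.99\tG\tA\t0.4"))
  tab <- read_summary_stats(f, std_map)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$rsid, c("rs1", "rs2", "rs3"))
  expect_equal(tab$p, c(0.5, 0.01, 0.99))

  # unparseable p dropped with a message
  f2 <- write_stats_file(c("SNP\tCHR\tBP\tP\tA1\tA2\tMAF",
                           "rs1\t1\t100\t0.5\tA\tG\t0.2",
                           "rs2\t1\t200\tNA\tC\tT\t0.1",
                           "rs3\t1\t300\t0.2\tG\tA\t0.4"))
  expect_message(tab2 <- read_summary_stats(f2, std_map), "dropped")
  expect_equal(tab2$rsid, c("rs1", "rs3"))

  # duplicated rsid is fatal and named
  f3 <- write_stats_file(c("SNP\tCHR\tBP\tP\tA1\tA2\tMAF",
                           "rs1\t1\t100\t0.5\tA\tG\t0.2",
                           "rs1\t1\t200\t0.1\tC\tT\t0.1"))
  expect_error(read_summary_stats(f3, std_map), "rs1")

  # zero p-values are floored, not dropped
  f4 <- write_stats_file(c("SNP\tCHR\tBP\tP",
                           "rs1\t1\t100\t0"))
  expect_message(tab4 <- read_summary_stats(f4, c(rsid = "SNP", chrom = "CHR",
                                                  pos = "BP", p = "P")),
                 "floored")
  expect_equal(tab4$p, 1e-300)

  expect_error(read_summary_stats(f, std_map[c("rsid", "chrom")]),
               "column_map")
})

test_that("apply_p_floor replaces only sub-floor values", {
  tab <- make_stats(c("a", "b", "c"), p = c(1e-310, 0.5, 1e-300))
  out <- apply_p_floor(tab, 1e-300)
  expect_equal(out$p, c(1e-300, 0.5, 1e-300))
  tab2 <- make_stats(c("a", "b"), p = c(0.2, 0.9))
  expect_identical(apply_p_floor(tab2), tab2)
  expect_error(apply_p_floor(tab, floor = 2), "floor")
})

test_that("harmonize_merge intersects, resolves strands, drops ambiguity", {
  t1 <- make_stats(paste0("rs", 1:10), p = seq(0.1, 1, 0.1))
  expect_silent(panel <- harmonize_merge(t1, t1))
  expect_equal(nrow(panel), 10)
  expect_true(all(panel$alignment_note == "direct"))

  # palindromic SNP dropped by default, kept when allowed
  t_at1 <- make_stats("rsAT", ea = "A", oa = "T", p = 0.3)
  expect_message(panel2 <- harmonize_merge(rbind(t1, t_at1),
                                           rbind(t1, t_at1)), "ambiguous")
  expect_false("rsAT" %in% panel2$rsid)
  expect_equal(attr(panel2, "dropped")$note, "dropped_ambiguous")
  panel2b <- harmonize_merge(rbind(t1, t_at1), rbind(t1, t_at1),
                             drop_ambiguous = FALSE)
  expect_true("rsAT" %in% panel2b$rsid)

  # strand flip: G/A in one study, C/T in the other (complement map oracle)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  t_ga <- make_stats("rsF", ea = "G", oa = "A", p = 0.2)
  t_ct <- make_stats("rsF", ea = comp[["G"]], oa = comp[["A"]], p = 0.4)
  panel3 <- harmonize_merge(rbind(t1, t_ga), rbind(t1, t_ct))
  expect_equal(panel3$alignment_note[panel3$rsid == "rsF"], "strand_flipped")

  # irreconcilable alleles and chrom/pos conflicts drop as mismatch
  t_m1 <- make_stats("rsM", ea = "A", oa = "G", p = 0.2)
  t_m2 <- make_stats("rsM", ea = "A", oa = "C", p = 0.4)
  expect_message(panel4 <- harmonize_merge(rbind(t1, t_m1), rbind(t1, t_m2)),
                 "mismatch")
  expect_false("rsM" %in% panel4$rsid)
  t_pc <- make_stats("rs1", pos = 99999, p = 0.5)
  expect_message(panel5 <- harmonize_merge(t1, rbind(t1[-1, ], t_pc)),
                 "mismatch")
  expect_false("rs1" %in% panel5$rsid)

  # merge keys on rsid alone when alleles are absent
  t_na1 <- make_stats(c("x", "y"), ea = NA_character_, oa = NA_character_,
                      p = c(0.1, 0.2))
  t_na2 <- make_stats(c("y", "x"), pos = c(2000, 1000),
                      ea = "A", oa = "G", p = c(0.4, 0.3))
  panel6 <- harmonize_merge(t_na1, t_na2)
  expect_equal(sort(panel6$rsid), c("x", "y"))
  expect_true(all(panel6$alignment_note == "direct"))
})

test_that("harmonize_merge membership is symmetric and bounded", {
  set.seed(8)
  t1 <- make_stats(paste0("rs", 1:30), p = runif(30),
                   ea = sample(c("A", "C", "G", "T"), 30, TRUE))
  t1$other_allele <- vapply(t1$effect_allele, function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
  t2 <- t1[sample(30, 20), ]
  t2$p <- runif(20)
  flip <- sample(20, 5)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  t2$effect_allele[flip] <- comp[t2$effect_allele[flip]]
  t2$other_allele[flip] <- comp[t2$other_allele[flip]]
  a <- suppressMessages(harmonize_merge(t1, t2))
  b <- suppressMessages(harmonize_merge(t2, t1))
  expect_setequal(a$rsid, b$rsid)
  expect_lte(nrow(a), min(nrow(t1), nrow(t2)))
  expect_false(is.unsorted(chrom_order <- order(a$pos)))  # single chrom
})

test_that("merged panel round-trips through TSV exactly", {
  set.seed(5)
  t1 <- make_stats(paste0("rs", 1:50), p = runif(50)^10)
  t2 <- t1
  t2$p <- runif(50)^10
  panel <- harmonize_merge(t1, t2)
  f <- tempfile(fileext = ".tsv")
  write_merged_panel(panel, f)
  back <- read_merged_panel(f)
  attr(panel, "dropped") <- NULL
  expect_identical(back, panel)
})
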