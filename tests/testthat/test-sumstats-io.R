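test_that("canonical summary statistics round-trip through disk", {
  ss <- make_sumstats(c("rs1", "rs2", "rs3"), beta = c(0.2, -0.1, 0),
                      p = c(1e-8, 0.5, 1), a1 = c("A", "C", "G"),
                      a2 = c("G", "T", "C"), freq = c(0.1, 0.5, 0.9))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, f)
  back <- read_sumstats(f)
  attributes(back) <- attributes(back)[c("names", "row.names", "class")]
  expect_equal(back, ss)
  expect_true(file.exists(paste0(f, ".prov.json")))
})

test_that("duplicate SNP keys and missing columns are rejected", {
  ss <- make_sumstats(c("rs1", "rs2"), pos = c(100, 100))
  expect_error(validate_sumstats(ss), "duplicated")
  f <- withr::local_tempfile(fileext = ".tsv")
  ok <- make_sumstats(c("rs1", "rs2"))
  utils::write.table(ok[, -6], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(f), "BETA")
})

test_that("a renamed-column dialect reads identically to the canonical one", {
  ss <- make_sumstats(c("rs1", "rs2"), beta = c(0.3, -0.2), p = c(0.01, 0.2))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, f1)
  giant <- stats::setNames(
    ss, c("MarkerName", "CHR", "POS", "Allele1", "Allele2", "b", "SE",
          "p", "Freq.Allele1.HapMapCEU"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(giant, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_sumstats(f2, dialect = "giant"), read_sumstats(f1),
               ignore_attr = TRUE)
})

test_that("rows with unparseable P values are dropped with a warning", {
  ss <- make_sumstats(c("rs1", "rs2", "rs3"))
  ss$P <- c("0.5", "not_a_number", "2.0")
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ss, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(out <- read_sumstats(f), "dropped")
  expect_equal(out$SNP, "rs1")
  expect_equal(attr(out, "io_log")$n_dropped, 2L)
})

test_that("harmonize performs the documented allele algebra", {
  target <- freq_table(matrix(0.4, 3, 1, dimnames = list(NULL, "p")),
                       make_snps(c("rs1", "rs2", "rs3"),
                                 a1 = c("G", "T", "A"),
                                 a2 = c("A", "C", "T")))
  ss <- make_sumstats(c("rs1", "rs2", "rs3"), a1 = c("A", "A", "A"),
                      a2 = c("G", "G", "T"), beta = 0.2, freq = 0.3)
  h <- harmonize(ss, target)
  log <- attr(h, "harmonize_log")
  # rs1: target counts our A2 -> negate beta, flip frequency
  expect_equal(h$BETA[h$SNP == "rs1"], -0.2)
  expect_equal(h$FREQ_A1[h$SNP == "rs1"], 0.7)
  # rs2: strand flip A/G -> T/C, sign preserved
  expect_equal(h$BETA[h$SNP == "rs2"], 0.2)
  # rs3: palindromic A/T dropped
  expect_false("rs3" %in% h$SNP)
  expect_equal(log$n_palindromic, 1L)
  expect_equal(log$n_swapped, 1L)
  expect_equal(log$n_strand_flipped, 1L)
})

test_that("harmonize is idempotent and invariant to input allele frame", {
  target <- freq_table(matrix(0.4, 2, 1, dimnames = list(NULL, "p")),
                       make_snps(c("rs1", "rs2"), a1 = c("G", "C"),
                                 a2 = c("A", "T")))
  ss <- make_sumstats(c("rs1", "rs2"), a1 = c("A", "C"), a2 = c("G", "T"),
                      beta = c(0.2, -0.4), freq = c(0.3, 0.8))
  h1 <- harmonize(ss, target)
  h2 <- harmonize(h1, target)
  expect_equal(h2, h1, ignore_attr = TRUE)
  # same information with A1/A2 swapped (beta negated, freq flipped)
  flipped <- ss
  flipped$A1 <- ss$A2; flipped$A2 <- ss$A1
  flipped$BETA <- -ss$BETA; flipped$FREQ_A1 <- 1 - ss$FREQ_A1
  expect_equal(harmonize(flipped, target), h1, ignore_attr = TRUE)
})

test_that("pseudo-haploidization halves homozygotes and coin-flips hets", {
  hom <- make_panel(matrix(c(0, 2, 2, 0), 2, 2))
  ph <- pseudo_haploidize(hom, seed = 1)
  expect_equal(unname(ph$geno), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(ph$ploidy, 1L)
  het <- make_panel(matrix(1L, 10000, 1))
  draws <- pseudo_haploidize(het, seed = 2)$geno
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 10000))
  expect_identical(pseudo_haploidize(het, seed = 3)$geno,
                   pseudo_haploidize(het, seed = 3)$geno)
  expect_warning(pseudo_haploidize(draws_panel <- pseudo_haploidize(het, seed = 2)),
                 "already")
})

test_that("allele frequencies from panels keep exact count bookkeeping", {
  one <- make_panel(matrix(2L, 1, 1))
  fr <- allele_freqs(one)
  expect_equal(as.numeric(fr$freq), 1)
  expect_equal(as.integer(fr$x), 2L)
  expect_equal(fr$n, 2L)
  three <- make_panel(matrix(c(0L, 1L, 2L), 3, 1))
  fr3 <- allele_freqs(three)
  expect_equal(as.numeric(fr3$freq), 0.5)
  expect_equal(as.integer(fr3$x), 3L)
  expect_equal(fr3$n, 6L)
  hap <- pseudo_haploidize(three, seed = 4)
  expect_equal(allele_freqs(hap)$n, 3L)
})

test_that("LD-block files convert from 0-based half-open on load", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000", "chr1\t1000\t2500", "chr2\t10\t20"), f)
  b <- read_ld_blocks(f)
  expect_equal(b$start, c(1L, 1001L, 11L))
  expect_equal(b$end, c(1000L, 2500L, 20L))
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000", "chr1\t500\t2500"), f2)
  expect_error(read_ld_blocks(f2), "overlapping")
})

test_that("frequency tables round-trip through the long TSV format", {
  spec <- drift_spec(M = 3, L = 20, F = diag(0.02, 3), seed = 5)
  fr <- simulate_frequencies(spec)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_freq_table(fr, f)
  back <- read_freq_table(f)
  expect_equal(back$freq, fr$freq)
  expect_equal(back$x, fr$x)
  expect_equal(back$n, fr$n)
  expect_equal(back$snps, fr$snps, ignore_attr = TRUE)
})
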