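make_sds <- function(id, chr = 1L, pos = seq_along(id) * 1e5,
                     daf = 0.5, sds = 0, aa = "G", da = "A") {
  n <- length(id)
  data.frame(CHR = rep_len(chr, n), POS = rep_len(pos, n), ID = id,
             AA = rep_len(aa, n), DA = rep_len(da, n),
             DAF = rep_len(daf, n), SDS = rep_len(sds, n),
             stringsAsFactors = FALSE)
}

test_that("frequency-bin normalization z-scores each 1% bin", {
  sds <- make_sds(sprintf("s%d", 1:6),
                  daf = c(0.105, 0.106, 0.107, 0.501, 0.502, 0.503),
                  sds = c(1, 2, 3, 5, 6, 10))
  out <- normalize_sds(sds)
  expect_equal(out$SDS_NORM[1:3], c(-1, 0, 1))
  expect_equal(mean(out$SDS_NORM[4:6]), 0, tolerance = 1e-12)
  expect_equal(sd(out$SDS_NORM[4:6]), 1, tolerance = 1e-12)
  # already-normalized input is a fixed point
  again <- normalize_sds(transform(out, SDS = SDS_NORM))
  expect_equal(again$SDS_NORM, out$SDS_NORM, tolerance = 1e-12)
})

test_that("MHC SNPs are excluded and singleton bins dropped", {
  sds <- make_sds(c("in_mhc", "keep1", "keep2", "lonely"),
                  chr = c(6, 1, 1, 1),
                  pos = c(30e6, 1e5, 2e5, 3e5),
                  daf = c(0.3, 0.3, 0.305, 0.87))
  expect_warning(out <- normalize_sds(sds), "single SNP")
  expect_false("in_mhc" %in% out$ID)
  expect_false("lonely" %in% out$ID)
  expect_setequal(out$ID, c("keep1", "keep2"))
  log <- attr(out, "norm_log")
  expect_equal(log$n_mhc, 1L)
  expect_equal(log$n_singleton_bins, 1L)
})

test_that("every occupied bin is exactly mean-zero unit-variance", {
  set.seed(40)
  sds <- make_sds(sprintf("s%d", 1:5000), daf = runif(5000, 0.01, 0.99),
                  sds = rnorm(5000, 2, 3))
  out <- suppressWarnings(normalize_sds(sds))
  bin <- floor(out$DAF * 100)
  mus <- tapply(out$SDS_NORM, bin, mean)
  sds_ <- tapply(out$SDS_NORM, bin, sd)
  expect_lt(max(abs(mus)), 1e-10)
  expect_lt(max(abs(sds_ - 1)), 1e-10)
})

test_that("trait alignment implements the full sign algebra", {
  # enumerate derived-allele identity x effect sign, incl. strand flips
  cases <- expand.grid(derived_is = c("A1", "A2", "A1_flip", "A2_flip",
                                      "neither"),
                       beta = c(0.1, -0.1), stringsAsFactors = FALSE)
  ids <- sprintf("c%d", seq_len(nrow(cases)))
  da <- c(A1 = "A", A2 = "G", A1_flip = "T", A2_flip = "C",
          neither = "A")[cases$derived_is]
  a1 <- ifelse(cases$derived_is == "neither", "C", "A")
  a2 <- ifelse(cases$derived_is == "neither", "G", "G")
  sds <- make_sds(ids, pos = seq_along(ids) * 1e5, da = unname(da),
                  aa = "N")  # AA unused by alignment
  sds$SDS_NORM <- 0.7
  ss <- make_sumstats(ids, pos = seq_along(ids) * 1e5, a1 = a1, a2 = a2,
                      beta = cases$beta)
  out <- align_tsds(sds, ss)
  want_sign <- ifelse(cases$derived_is %in% c("A1", "A1_flip"),
                      sign(cases$beta), -sign(cases$beta))
  keep <- cases$derived_is != "neither"
  expect_equal(out$TSDS, 0.7 * want_sign[keep][match(out$ID, ids[keep])])
  expect_equal(attr(out, "align_log")$n_allele_mismatch, 2L)
  # zero effect sizes are dropped, tallied
  ss0 <- make_sumstats("z1", beta = 0)
  sds0 <- make_sds("z1"); sds0$SDS_NORM <- 1
  out0 <- align_tsds(sds0, ss0)
  expect_equal(nrow(out0), 0L)
  expect_equal(attr(out0, "align_log")$n_zero_beta, 1L)
})

test_that("a perfectly monotone score gives Spearman rho of one", {
  set.seed(41)
  p <- runif(500)
  tr <- trend(-log10(p), p, jackknife_blocks = 20)
  expect_equal(tr$rho, 1)
  expect_gt(tr$slope, 0)
  neg <- trend(log10(p), p, jackknife_blocks = 20)
  expect_equal(neg$rho, -1)
  expect_equal(neg$slope, -tr$slope)
})

test_that("block jackknife on singleton blocks equals the classical SE", {
  jk <- polystrat:::block_jackknife(4, 4, function(idx) mean(c(1, 2, 3, 4)[idx]))
  expect_equal(jk$se, sqrt((3 / 4) * (0.25 + 1 / 36 + 1 / 36 + 0.25)),
               tolerance = 1e-12)
  expect_equal(jk$se, sd(1:4) / sqrt(4), tolerance = 1e-12)
  # the fast Pearson path agrees with the generic jackknife
  set.seed(42)
  x <- rnorm(200); y <- 0.3 * x + rnorm(200)
  fast <- polystrat:::pearson_jackknife(x, y, 25)
  slow <- polystrat:::block_jackknife(200, 25,
                                      function(idx) cor(x[idx], y[idx]))
  expect_equal(fast$estimate, slow$estimate, tolerance = 1e-12)
  expect_equal(fast$se, slow$se, tolerance = 1e-12)
})

test_that("a null trend is flat and binned means behave", {
  set.seed(43)
  n <- 5000
  score <- rnorm(n); p <- runif(n)
  tr <- trend(score, p, bin_size = 1000, jackknife_blocks = 100)
  expect_lt(abs(tr$rho), 0.05)
  expect_gt(tr$p_jack, 1e-4)
  expect_equal(nrow(tr$bins), 5L)
  expect_false(any(tr$bins$partial))
  tr2 <- trend(score[1:4500], p[1:4500], bin_size = 1000,
               jackknife_blocks = 100)
  expect_true(tr2$bins$partial[5])
  # negating the score negates both statistics exactly
  trn <- trend(-score, p, bin_size = 1000, jackknife_blocks = 100)
  expect_equal(trn$rho, -tr$rho)
  expect_equal(trn$slope, -tr$slope)
  expect_error(trend(rep(1, 100), runif(100)), "constant")
})

test_that("the genome-wide-significant shift test matches the normal oracle", {
  expect_equal(gw_sig_shift(rep(0, 100))$z, 0)
  expect_equal(gw_sig_shift(rep(0, 100))$p, 1)
  x <- rnorm(100)
  x <- x - mean(x) + 0.3
  res <- gw_sig_shift(x)
  expect_equal(res$z, 3, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-3), tolerance = 1e-12)
  expect_equal(res$p, 0.0026998, tolerance = 1e-4)
  expect_error(gw_sig_shift(numeric(0)), "no genome-wide")
})
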