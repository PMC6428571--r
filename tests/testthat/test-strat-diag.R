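two_pop_panel <- function(l = 300, n = 60, fst = 0.15, seed = 50) {
  spec <- drift_spec(M = 2, L = l, F = diag(fst, 2), seed = seed)
  fr <- simulate_frequencies(spec)
  list(freqs = fr,
       panel = simulate_genotype_panel(fr, n_per_pop = n, seed = seed + 1))
}

test_that("PCA separates simulated populations and ignores null structure", {
  tp <- two_pop_panel()
  pcs <- compute_pcs(tp$panel, K = 4)
  lab <- as.integer(factor(tp$panel$ind$pop))
  expect_gt(abs(cor(pcs$scores[, 1], lab)), 0.99)
  expect_lt(max(abs(colMeans(pcs$scores))), 1e-10)
  # one homogeneous population: no component tracks an arbitrary split
  spec <- drift_spec(M = 1, L = 400, F = diag(0, 1), seed = 52)
  fr <- simulate_frequencies(spec)
  pan <- simulate_genotype_panel(fr, n_per_pop = 100, seed = 53)
  pcs0 <- compute_pcs(pan, K = 2)
  half <- rep(1:2, each = 50)
  expect_lt(abs(cor(pcs0$scores[, 1], half)), 0.3)
})

test_that("duplicating every individual preserves the PC directions", {
  tp <- two_pop_panel(l = 100, n = 25)
  pan <- tp$panel
  dup <- geno_panel(rbind(pan$geno, pan$geno),
                    pan$snps,
                    transform(rbind(pan$ind, pan$ind),
                              id = sprintf("d%d", seq_len(2 * nrow(pan$ind)))))
  p1 <- compute_pcs(pan, K = 2)
  p2 <- compute_pcs(dup, K = 2)
  n <- nrow(pan$geno)
  expect_equal(p2$scores[1:n, 1], p2$scores[n + 1:n, 1], ignore_attr = TRUE)
  expect_gt(abs(cor(p1$scores[, 1], p2$scores[1:n, 1])), 1 - 1e-8)
})

test_that("PC loadings are exact regression coefficients", {
  set.seed(54)
  g <- matrix(rbinom(60 * 3, 2, 0.5), 60, 3)
  pan <- make_panel(g)
  # fabricate scores equal to half the first SNP's count: loading 0.5
  pcs <- structure(list(scores = cbind(PC1 = 0.5 * (g[, 1] - mean(g[, 1]))),
                        varexp = 1, snps_used = pan$snps$id, K = 1L),
                   class = "pc_scores")
  load <- pc_loadings(pcs, pan, sex = NULL)
  expect_equal(load["s1", "PC1"], 0.5, tolerance = 1e-10)
  # loadings match lm() with a sex covariate, SNP by SNP
  tp <- two_pop_panel(l = 20, n = 30)
  real <- compute_pcs(tp$panel, K = 2)
  lo <- pc_loadings(real, tp$panel)
  sex <- tp$panel$ind$sex
  for (j in c(1, 7, 20)) {
    fit <- lm(real$scores[, 2] ~ sex + tp$panel$geno[, j])
    expect_equal(unname(lo[j, 2]), unname(coef(fit)[3]), tolerance = 1e-8)
  }
  # monomorphic SNPs give missing loadings
  pan2 <- make_panel(cbind(g, 1L))
  pcs2 <- structure(list(scores = cbind(PC1 = rnorm(60)), varexp = 1,
                         snps_used = pan2$snps$id, K = 1L),
                    class = "pc_scores")
  expect_true(is.na(pc_loadings(pcs2, pan2, sex = NULL)["s4", 1]))
})

test_that("six-individual loadings match the closed-form normal equations", {
  g <- matrix(c(0, 1, 2, 0, 1, 2), 6, 1)
  sexn <- c(0, 0, 0, 1, 1, 1)
  score <- c(0.1, 0.4, 0.9, 0.2, 0.5, 1.1)
  pan <- make_panel(g)
  pan$ind$sex <- ifelse(sexn == 1, "M", "F")
  pcs <- structure(list(scores = cbind(PC1 = score - mean(score)),
                        varexp = 1, snps_used = "s1", K = 1L),
                   class = "pc_scores")
  x <- cbind(1, sexn, g[, 1])
  beta_hat <- solve(t(x) %*% x, t(x) %*% (score - mean(score)))
  expect_equal(unname(pc_loadings(pcs, pan)["s1", 1]),
               unname(beta_hat[3]), tolerance = 1e-12)
})

test_that("loading correlations flag a constructed signal and not noise", {
  set.seed(55)
  l <- 2000
  loadings <- cbind(PC1 = rnorm(l), PC2 = rnorm(l))
  rownames(loadings) <- sprintf("s%d", 1:l)
  v <- setNames(3 * loadings[, "PC1"], rownames(loadings))
  res <- loading_correlations(v, loadings, n_jackknife = 100)
  expect_equal(res$r[res$pc == "PC1"], 1, tolerance = 1e-12)
  expect_true(res$bonferroni[res$pc == "PC1"])
  vnull <- setNames(rnorm(l), rownames(loadings))
  res0 <- loading_correlations(vnull, loadings, n_jackknife = 100)
  expect_true(all(abs(res0$r) < 0.1))
  # jackknife SE on null data is near the analytic 1/sqrt(L - 3)
  expect_lt(max(res0$se), 1.5 / sqrt(l - 3))
  expect_gt(min(res0$se), 0.5 / sqrt(l - 3))
  expect_warning(loading_correlations(vnull[1:50], loadings[1:50, ],
                                      n_jackknife = 1000),
                 "blocks reduced")
})

test_that("frequency contrasts follow the trait-increasing allele", {
  fr <- freq_table(cbind(GBR = c(0.6, 0.6), TSI = c(0.4, 0.4)),
                   make_snps(c("s1", "s2")))
  ss <- make_sumstats(c("s1", "s2"), beta = c(0.5, -0.5))
  fc <- freq_contrast(fr, "GBR", "TSI", ss)
  expect_equal(fc$DELTA, c(0.2, -0.2))
  # flipping the reported allele frame leaves the contrast unchanged
  flipped <- ss
  flipped$A1 <- ss$A2; flipped$A2 <- ss$A1
  flipped$BETA <- -ss$BETA; flipped$FREQ_A1 <- 1 - ss$FREQ_A1
  h <- harmonize(flipped, fr)
  expect_equal(freq_contrast(fr, "GBR", "TSI", h)$DELTA, fc$DELTA)
  # zero-effect SNPs are dropped and tallied
  ss0 <- make_sumstats(c("s1", "s2"), beta = c(0.5, 0))
  fc0 <- freq_contrast(fr, "GBR", "TSI", ss0)
  expect_equal(nrow(fc0), 1L)
  expect_equal(attr(fc0, "contrast_log")$n_zero_beta, 1L)
})

test_that("MAF heat maps bin, average, and mask below the count threshold", {
  set.seed(56)
  n <- 1200
  fa <- runif(n, 0.05, 0.95); fb <- runif(n, 0.05, 0.95)
  hm <- maf_bin_heatmap(rep(0.1, n), fa, fb, bin_width = 0.25, min_count = 10)
  expect_equal(hm$mean[!hm$mask], rep(0.1, sum(!hm$mask)),
               ignore_attr = TRUE)
  expect_true(all(is.na(hm$mean[hm$mask])))
  expect_equal(sum(hm$count), n)
  # exact threshold: 299 masked, 300 kept
  v299 <- maf_bin_heatmap(rep(1, 299), rep(0.1, 299), rep(0.1, 299))
  expect_true(v299$mask[3, 3])
  v300 <- maf_bin_heatmap(rep(1, 300), rep(0.1, 300), rep(0.1, 300))
  expect_false(v300$mask[3, 3])
  # antisymmetric quantity gives an antisymmetric map
  maf_a <- pmin(fa, 1 - fa); maf_b <- pmin(fb, 1 - fb)
  hma <- maf_bin_heatmap(maf_a - maf_b, fa, fb, bin_width = 0.1,
                         min_count = 5)
  m <- hma$mean
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if (!is.na(m[i, j]) && !is.na(m[j, i]) && i != j)
      expect_lt(abs(m[i, j] + m[j, i]), 0.1)
  expect_error(maf_bin_heatmap(numeric(0), numeric(0), numeric(0)), "empty")
})
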