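# Standard study conditions shared by the calibration/power tests.
#
# Bias scale: the stratification coefficient is set so that the expected
# absolute bias E|a * delta| equals the GWAS standard error, i.e. the
# systematic error is the same size as the sampling error — the regime in
# which an uncorrected GWAS looks clean marginally but its errors are
# structured along the population axis.

# E[p(1-p)] for ancestral frequencies ~ U(lo, hi)
unif_het_moment <- function(lo = 0.05, hi = 0.95) {
  (hi + lo) / 2 - (hi^2 + hi * lo + lo^2) / 3
}

# sd of delta = axis' p under the drift model Var(p) = 2 p(1-p) F
delta_sd <- function(F, axis, lo = 0.05, hi = 0.95) {
  sqrt(2 * unif_het_moment(lo, hi) *
         as.numeric(axis %*% F %*% axis))
}

# a with E|a * delta| = se, delta approximately normal
bias_for_se <- function(se, F, axis, lo = 0.05, hi = 0.95) {
  se / (delta_sd(F, axis, lo, hi) * sqrt(2 / pi))
}

# six-population European-transect conditions (drift scale, latitudes)
transect_conditions <- function() {
  M <- 6
  list(M = M, F = diag(0.02, M) + 0.01,
       Y = seq(40, 65, length.out = M),
       beta_sd = 0.02, se = 0.01)
}

# latitude-aligned unit contrast (centered, unit norm)
latitude_axis <- function(Y) {
  yc <- Y - mean(Y)
  yc / sqrt(sum(yc^2))
}

# One Qx / latitude-test replicate under the transect conditions:
# L ascertained SNPs, bias a along the latitude axis, tests against the
# true drift matrix.
qx_replicate <- function(L, a, seed, cond = transect_conditions()) {
  ax <- latitude_axis(cond$Y)
  spec <- drift_spec(M = cond$M, L = L, F = cond$F, Y = cond$Y, seed = seed)
  fr <- simulate_frequencies(spec)
  gs <- gwas_sim_spec(
    true_beta_law = function(L) stats::rnorm(L, 0, cond$beta_sd),
    se = cond$se, bias_coeff = a, bias_axis = ax, seed = seed + 1L)
  ss <- simulate_gwas(fr, gs)
  sc <- polygenic_scores(ss, fr)
  qx_test(sc, cond$F, Y = cond$Y)
}

# One tSDS trend replicate in a two-population (GBR/TSI-like) setting:
# cline coefficient c on the SDS scores, bias a on the effect sizes, no
# true selection. Returns the trend over L SNPs.
tsds_replicate <- function(L, a, cline, seed, noise_sd = 1,
                           se = 0.01, beta_sd = 0.02) {
  spec <- drift_spec(M = 2, L = L, F = diag(0.02, 2), seed = seed)
  fr <- simulate_frequencies(spec)
  ss <- simulate_gwas(fr, gwas_sim_spec(
    true_beta_law = function(L) stats::rnorm(L, 0, beta_sd),
    se = se, bias_coeff = a, bias_axis = c(1, -1), seed = seed + 1L))
  sds <- simulate_sds(fr, cline_coeff = cline, noise_sd = noise_sd,
                      seed = seed + 2L)
  al <- align_tsds(suppressWarnings(normalize_sds(sds)), ss)
  trend(al$TSDS, al$P, jackknife_blocks = 100)
}

# cline coefficient under which the frequency cline explains ~20% of the
# raw SDS variance (cline sd = 0.5 against unit score noise)
cline_for_20pct <- function(F = diag(0.02, 2), axis = c(1, -1)) {
  0.5 / delta_sd(F, axis)
}

# Two-population panel + confounded GWAS for the PC-loading diagnostics.
strat_diag_replicate <- function(L, n_per_pop, a, seed, se = 0.01,
                                 beta_sd = 0.02) {
  spec <- drift_spec(M = 2, L = L, F = diag(0.02, 2), seed = seed)
  fr <- simulate_frequencies(spec)
  ss <- simulate_gwas(fr, gwas_sim_spec(
    true_beta_law = function(L) stats::rnorm(L, 0, beta_sd),
    se = se, bias_coeff = a, bias_axis = c(1, -1), seed = seed + 1L))
  pan <- simulate_genotype_panel(fr, n_per_pop = n_per_pop,
                                 seed = seed + 2L)
  pcs <- compute_pcs(pan, K = 5, maf_min = 0.01)
  lo <- pc_loadings(pcs, pan)
  v <- stats::setNames(ss$BETA, ss$SNP)
  loading_correlations(v, lo, n_jackknife = 1000)
}
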