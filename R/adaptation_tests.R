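# Tests of population score differentiation against the neutral-drift
# null: F estimation, the Qx overdispersion statistic, the latitude-cline
# statistic, and an empirical null by random SNP ascertainment.

#' Estimate the drift covariance matrix F
#'
#' Averages, over putatively neutral SNPs, the outer product of the
#' standardized frequency deviations
#' `(p_l. - pbar_l) / sqrt(2 pbar_l (1 - pbar_l))` (the package-wide
#' half-heterozygosity standardization under which the drift null of
#' [qx_test()] is exactly `2 V_A F`). By default `pbar_l` is
#' the across-population mean, in which case only the mean-centered
#' projection `T F T'` of the drift matrix is identifiable — which is all
#' that [qx_test()] and [latitude_test()] use. Supplying known ancestral
#' frequencies (e.g. those recorded by [simulate_frequencies()]) makes
#' the full F identifiable. The estimate is symmetrized and projected to
#' the positive-semidefinite cone (negative eigenvalues clipped at zero,
#' clip magnitude reported).
#'
#' @param null_freqs a [freq_table()] of null (non-ascertained) SNPs.
#' @param ancestral optional vector of ancestral frequencies per SNP.
#' @param min_snps warn below this many usable SNPs.
#' @return M x M matrix `F_hat` with attributes `n_snps`,
#'   `n_monomorphic` and `psd_clip`.
#' @export
estimate_F <- function(null_freqs, ancestral = NULL, min_snps = 100L) {
  stopifnot(inherits(null_freqs, "freq_table"))
  p <- null_freqs$freq
  ctr <- ancestral %||% rowMeans(p)
  if (length(ctr) != nrow(p)) stop("ancestral must have one frequency per SNP")
  poly <- ctr > 0 & ctr < 1
  n_mono <- sum(!poly)
  p <- p[poly, , drop = FALSE]; ctr <- ctr[poly]
  if (nrow(p) < min_snps)
    warning("only ", nrow(p), " polymorphic null SNPs; F estimate will be noisy")
  d <- (p - ctr) / sqrt(2 * ctr * (1 - ctr))
  f_hat <- crossprod(d) / nrow(d)
  f_hat <- (f_hat + t(f_hat)) / 2
  e <- eigen(f_hat, symmetric = TRUE)
  clip <- -min(e$values, 0)
  if (clip > 0)
    f_hat <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  dimnames(f_hat) <- list(null_freqs$pops, null_freqs$pops)
  attr(f_hat, "n_snps") <- nrow(d)
  attr(f_hat, "n_monomorphic") <- n_mono
  attr(f_hat, "psd_clip") <- clip
  f_hat
}

#' Qx overdispersion test
#'
#' Under neutral drift the vector of mean-centered population polygenic
#' scores is multivariate normal with covariance `2 V_A F`. With the
#' centering projection `T = I - 11'/M`, the statistic
#' `Qx = Ztilde' (2 V_A T F T')^+ Ztilde` (pseudo-inverse on the
#' rank-(M-1) contrast space) is chi-square with `M - 1` degrees of
#' freedom under the null. If the centered drift matrix is numerically
#' rank deficient, the degrees of freedom are reduced to the rank and
#' this is reported.
#'
#' @param scores a `score_result` from [polygenic_scores()], or a named
#'   numeric vector of raw scores (then `V_A` must be given).
#' @param F_hat M x M drift matrix (e.g. from [estimate_F()]).
#' @param V_A additive genic variance; defaults to the one in `scores`.
#' @param Y optional latitudes; when present, [latitude_test()] results
#'   are included.
#' @return an object of class `qx_result` with `qx`, `dof`, `p_qx`, and
#'   (when `Y` is given) `lat_stat`, `p_lat`.
#' @export
qx_test <- function(scores, F_hat, V_A = NULL, Y = NULL) {
  z <- if (inherits(scores, "score_result")) {
    V_A <- V_A %||% scores$V_A
    stats::setNames(scores$populations$Z, scores$populations$pop)
  } else scores
  if (is.null(V_A)) stop("V_A must be supplied with raw scores")
  m <- length(z)
  if (m < 2) stop("Qx needs >= 2 populations")
  ctr <- diag(m) - 1 / m
  zt <- as.numeric(ctr %*% z)
  s <- 2 * V_A * (ctr %*% F_hat %*% ctr)
  pin <- sym_pinv(s)
  dof <- min(m - 1L, pin$rank)
  qx <- as.numeric(zt %*% pin$inv %*% zt)
  res <- list(qx = qx, dof = dof, p_qx = stats::pchisq(qx, dof, lower.tail = FALSE),
              rank_deficient = pin$rank < m - 1L,
              V_A = V_A, F_hat = F_hat)
  if (!is.null(Y)) res <- c(res, latitude_test(z, F_hat, V_A, Y))
  structure(res, class = "qx_result")
}

#' @export
print.qx_result <- function(x, ...) {
  cat(sprintf("<qx_result> Qx = %.4g on %d dof, P = %.4g\n",
              x$qx, x$dof, x$p_qx))
  if (!is.null(x$lat_stat))
    cat(sprintf("  latitude statistic = %.4g, P = %.4g\n", x$lat_stat, x$p_lat))
  if (!is.null(x$empirical_p))
    cat(sprintf("  empirical P (random ascertainment, %d draws) = %.4g\n",
                length(x$null_qx), x$empirical_p))
  invisible(x)
}

#' Latitude-cline test for polygenic scores
#'
#' Tests whether scores covary linearly with latitude more than drift
#' allows: with mean-centered latitudes `Y`, the projection `Y'Z` is
#' normal with variance `2 V_A Y'FY` under the null.
#'
#' @param scores raw scores (named vector or `score_result`).
#' @param F_hat drift matrix.
#' @param V_A additive genic variance.
#' @param Y latitudes per population (degrees), at least two distinct.
#' @return list with `lat_stat` (standardized statistic) and `p_lat`
#'   (two-sided normal P).
#' @export
latitude_test <- function(scores, F_hat, V_A = NULL, Y = NULL) {
  z <- if (inherits(scores, "score_result")) {
    V_A <- V_A %||% scores$V_A
    stats::setNames(scores$populations$Z, scores$populations$pop)
  } else scores
  if (length(unique(Y)) < 2) stop("Y must contain >= 2 distinct latitudes")
  yc <- Y - mean(Y)
  v <- 2 * V_A * as.numeric(yc %*% F_hat %*% yc)
  if (v <= 0) stop("Y'FY <= 0: drift matrix carries no variance along the latitude contrast")
  t_stat <- sum(yc * z) / sqrt(v)
  list(lat_stat = t_stat, p_lat = 2 * stats::pnorm(-abs(t_stat)))
}

#' Empirical Qx null by random SNP ascertainment
#'
#' Re-ascertains random SNP sets of the same size as the observed set
#' (optionally matched to its mean-frequency deciles), recomputes Qx with
#' the same effect-size routing, and reports the empirical P value
#' `(1 + #\{null >= observed\}) / (1 + n_draws)` together with a
#' Kolmogorov-Smirnov check of whether the null chi-square P values are
#' uniform — the paper-style diagnostic that a stratified GWAS fails.
#'
#' @param sumstats harmonized summary statistics (the SNP pool with betas).
#' @param freqs frequency table covering the pool.
#' @param F_hat drift matrix.
#' @param ascertained_ids SNP ids of the observed ascertained set.
#' @param n_draws number of random ascertainments.
#' @param frequency_match match null draws to the observed set's
#'   mean-frequency deciles.
#' @param seed integer seed.
#' @return `qx_result` for the observed set augmented with
#'   `empirical_p`, `null_qx`, `null_p` and `ks` (the uniformity test).
#' @export
empirical_qx_null <- function(sumstats, freqs, F_hat, ascertained_ids,
                              n_draws = 500L, frequency_match = FALSE,
                              seed = NULL) {
  validate_sumstats(sumstats)
  set_seed_if(seed)
  pool <- sumstats[sumstats$SNP %in% freqs$snps$id, , drop = FALSE]
  if (!all(ascertained_ids %in% pool$SNP))
    stop("ascertained SNPs missing from the pool")
  k <- length(ascertained_ids)
  if (nrow(pool) < 2 * k)
    warning("candidate pool is small relative to the ascertained set")
  qx_of <- function(ids) {
    ss <- pool[match(ids, pool$SNP), , drop = FALSE]
    sc <- polygenic_scores(ss, subset_freqs(freqs, ids))
    qx_test(sc, F_hat)
  }
  obs <- qx_of(ascertained_ids)
  p_bar_pool <- rowMeans(freqs$freq)[match(pool$SNP, freqs$snps$id)]
  strata <- NULL
  if (frequency_match) {
    br <- unique(stats::quantile(p_bar_pool, probs = seq(0, 1, 0.1)))
    strata <- cut(p_bar_pool, br, include.lowest = TRUE)
    obs_strata <- table(strata[match(ascertained_ids, pool$SNP)])
    avail <- table(strata)
    short <- names(obs_strata)[obs_strata > avail[names(obs_strata)]]
    if (length(short))
      stop("frequency matching infeasible in stratum ", short[1])
  }
  draw_ids <- function() {
    if (is.null(strata)) return(sample(pool$SNP, k))
    unlist(lapply(names(obs_strata)[obs_strata > 0], function(s)
      sample(pool$SNP[strata == s], obs_strata[[s]])), use.names = FALSE)
  }
  null_qx <- numeric(n_draws); null_p <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    r <- qx_of(draw_ids())
    null_qx[i] <- r$qx; null_p[i] <- r$p_qx
  }
  obs$empirical_p <- (1 + sum(null_qx >= obs$qx)) / (1 + n_draws)
  obs$null_qx <- null_qx
  obs$null_p <- null_p
  obs$ks <- suppressWarnings(stats::ks.test(null_p, "punif"))
  obs
}
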