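# Trait-aligned SDS analysis: per-frequency-bin normalization, sign
# alignment to the trait-increasing allele, trend statistics with
# block-jackknife errors, and the genome-wide-significant shift test.

#' Normalize SDS scores within 1% derived-allele-frequency bins
#'
#' Removes the strong dependence of raw SDS on allele frequency by
#' z-scoring within each 1% DAF bin (bins \[0, 0.01), ..., \[0.99, 1\];
#' sample standard deviation with n-1 denominator). SNPs in the MHC
#' region are excluded first; a bin with a single SNP has no defined SD
#' and that SNP is dropped with a warning.
#'
#' @param sds SDS data.frame (`CHR`, `POS`, `ID`, `AA`, `DA`, `DAF`,
#'   `SDS`), as from [read_sds()] or [simulate_sds()].
#' @param mhc MHC bounds `c(chr, start, end)`; default chr6:25-35 Mb.
#'   `NULL` disables the exclusion.
#' @return the table restricted to retained SNPs with an added
#'   `SDS_NORM` column; drop counts in `attr(, "norm_log")`.
#' @export
normalize_sds <- function(sds, mhc = c(6, 25e6, 35e6)) {
  stopifnot(all(c("DAF", "SDS") %in% names(sds)))
  if (any(sds$DAF <= 0 | sds$DAF >= 1))
    stop("DAF must lie strictly inside (0, 1)")
  n_mhc <- 0L
  if (!is.null(mhc)) {
    in_mhc <- sds$CHR == mhc[1] & sds$POS >= mhc[2] & sds$POS <= mhc[3]
    n_mhc <- sum(in_mhc)
    sds <- sds[!in_mhc, , drop = FALSE]
  }
  bin <- pmin(floor(sds$DAF * 100), 99)
  cnt <- table(bin)
  singleton_bins <- as.numeric(names(cnt)[cnt < 2])
  if (length(singleton_bins)) {
    warning(length(singleton_bins),
            " frequency bin(s) with a single SNP dropped (SD undefined)")
    keep <- !(bin %in% singleton_bins)
    sds <- sds[keep, , drop = FALSE]
    bin <- bin[keep]
  }
  mu <- stats::ave(sds$SDS, bin, FUN = mean)
  sd <- stats::ave(sds$SDS, bin, FUN = stats::sd)
  sds$SDS_NORM <- (sds$SDS - mu) / sd
  attr(sds, "norm_log") <- list(n_mhc = n_mhc,
                                n_singleton_bins = length(singleton_bins))
  sds
}

#' Align SDS scores to the trait-increasing allele (tSDS)
#'
#' Signs each normalized SDS so that a positive value means the
#' trait-increasing allele has risen in frequency: if the derived allele
#' is the trait-increasing allele (effect of the derived allele > 0) the
#' score is kept, otherwise negated. Strand-flipped allele matches are
#' resolved via complements; SNPs whose derived allele matches neither
#' GWAS allele, and SNPs with an exactly zero effect, are dropped and
#' tallied.
#'
#' @param sds normalized SDS table (needs `SDS_NORM`; see
#'   [normalize_sds()]).
#' @param sumstats harmonized summary statistics providing `A1`, `A2`
#'   and `BETA` per SNP.
#' @return the matched table with columns `TSDS`, `BETA_DERIVED` and the
#'   GWAS `P`, in genomic order; drop counts in `attr(, "align_log")`.
#' @export
align_tsds <- function(sds, sumstats) {
  stopifnot("SDS_NORM" %in% names(sds))
  validate_sumstats(sumstats)
  idx <- match(sds$ID, sumstats$SNP)
  matched <- !is.na(idx)
  x <- sds[matched, , drop = FALSE]
  ss <- sumstats[idx[matched], , drop = FALSE]
  da <- toupper(x$DA)
  cda <- complement_allele(da)
  beta_d <- rep(NA_real_, nrow(x))
  is_a1 <- da == ss$A1 | (da != ss$A2 & cda == ss$A1)
  is_a2 <- da == ss$A2 | (da != ss$A1 & cda == ss$A2)
  beta_d[is_a1 & !is_a2] <- ss$BETA[is_a1 & !is_a2]
  beta_d[is_a2 & !is_a1] <- -ss$BETA[is_a2 & !is_a1]
  n_allele_mismatch <- sum(is.na(beta_d))
  n_zero_beta <- sum(beta_d == 0, na.rm = TRUE)
  keep <- !is.na(beta_d) & beta_d != 0
  out <- x[keep, , drop = FALSE]
  out$BETA_DERIVED <- beta_d[keep]
  out$TSDS <- ifelse(out$BETA_DERIVED > 0, out$SDS_NORM, -out$SDS_NORM)
  out$P <- ss$P[keep]
  out <- out[order(out$CHR, out$POS), , drop = FALSE]
  attr(out, "align_log") <- list(n_unmatched = sum(!matched),
                                 n_allele_mismatch = n_allele_mismatch,
                                 n_zero_beta = n_zero_beta)
  out
}

#' Trend of a per-SNP score across GWAS significance
#'
#' The selection-style trend statistic: Spearman correlation between a
#' per-SNP score (tSDS, or any other column such as a two-population
#' frequency contrast) and the strength of GWAS association. Ranks of
#' `-P` are used so that a positive correlation means higher scores at
#' stronger associations. Standard errors and P values come from a
#' delete-one-block jackknife over contiguous blocks in genomic order;
#' an un-binned least-squares slope on the significance-rank scale with
#' its analytic P, and binned score means (least to most significant),
#' are also returned.
#'
#' @param score numeric per-SNP score, in genomic order.
#' @param p GWAS P values aligned with `score`.
#' @param bin_size SNPs per display bin (default 1000); a smaller final
#'   bin is flagged.
#' @param jackknife_blocks number of contiguous jackknife blocks
#'   (default 100, i.e. leave out 1% of SNPs at a time).
#' @return an object of class `trend_result`: `rho`, `se`, `p_jack`,
#'   `slope`, `slope_se`, `slope_p`, `n_snps`, `n_blocks` and a `bins`
#'   data.frame.
#' @export
trend <- function(score, p, bin_size = 1000L, jackknife_blocks = 100L) {
  stopifnot(length(score) == length(p))
  ok <- is.finite(score) & is.finite(p)
  score <- score[ok]; p <- p[ok]
  n <- length(score)
  if (n < 3) stop("need >= 3 SNPs for a trend")
  if (stats::sd(score) == 0 || stats::sd(p) == 0)
    stop("constant score or constant P values: trend undefined")
  sig_rank <- rank(-p)  # high rank = most significant
  rho_fun <- function(idx) stats::cor(score[idx], sig_rank[idx],
                                      method = "spearman")
  jk <- block_jackknife(n, jackknife_blocks, rho_fun)
  # un-binned least-squares slope of score on the significance rank scale
  x <- sig_rank
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (score - mean(score))) / sxx
  resid <- score - mean(score) - slope * (x - mean(x))
  slope_se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  slope_p <- 2 * stats::pt(-abs(slope / slope_se), df = n - 2)
  ord <- order(sig_rank)  # least significant first
  bin_id <- ceiling(seq_len(n) / bin_size)
  bins <- data.frame(
    bin = unique(bin_id),
    mean_score = as.numeric(tapply(score[ord], bin_id, mean)),
    n = as.integer(tapply(score[ord], bin_id, length)))
  bins$partial <- bins$n < bin_size
  structure(list(rho = jk$estimate, se = jk$se, p_jack = jk$p,
                 slope = slope, slope_se = slope_se, slope_p = slope_p,
                 n_snps = n, n_blocks = jk$n_blocks, bins = bins),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(paste0("<trend_result> Spearman rho = %.4g ",
                     "(jackknife SE %.3g, P = %.3g) over %d SNPs\n"),
              x$rho, x$se, x$p_jack, x$n_snps))
  cat(sprintf("  un-binned slope = %.4g (P = %.3g); %d bins\n",
              x$slope, x$slope_p, nrow(x$bins)))
  invisible(x)
}

#' Mean tSDS shift at genome-wide-significant SNPs
#'
#' For an LD-independent set of genome-wide-significant SNPs, each tSDS
#' is standard normal under neutrality, so the mean over n SNPs has null
#' distribution N(0, 1/n). Reports `z = mean * sqrt(n)` and its
#' two-sided P value.
#'
#' @param tsds tSDS values at independent significant SNPs (e.g. the
#'   `TSDS` column of [align_tsds()] restricted to a clumped
#'   `P < 5e-8` set).
#' @return list with `mean`, `z`, `p`, `n` and the input `values`.
#' @export
gw_sig_shift <- function(tsds) {
  tsds <- tsds[is.finite(tsds)]
  n <- length(tsds)
  if (n == 0) stop("no genome-wide-significant SNPs supplied")
  z <- mean(tsds) * sqrt(n)
  list(mean = mean(tsds), z = z, p = 2 * stats::pnorm(-abs(z)), n = n,
       values = tsds)
}
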