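# Population-level polygenic scores: raw and centered-standardized scores
# and Beta-posterior credible intervals.

#' Raw population polygenic scores
#'
#' The score of a population is the sum over ascertained SNPs of the
#' effect-allele frequency weighted by the effect size:
#' `Z_m = sum_l beta_l * p_lm`.
#'
#' @param beta named numeric vector of effect sizes (names = SNP ids), or
#'   a harmonized summary-statistics data.frame (its `BETA` is used).
#' @param freqs a [freq_table()]; SNPs missing a frequency in any
#'   population are dropped and tallied.
#' @return named numeric vector of per-population scores, with
#'   `attr(, "n_dropped")`.
#' @export
polygenic_score <- function(beta, freqs) {
  stopifnot(inherits(freqs, "freq_table"))
  if (is.data.frame(beta)) beta <- stats::setNames(beta$BETA, beta$SNP)
  idx <- match(names(beta), freqs$snps$id)
  complete <- !is.na(idx) &
    apply(is.finite(freqs$freq[pmax(idx, 1L), , drop = FALSE]), 1, all)
  n_dropped <- sum(!complete)
  if (!any(complete)) stop("no ascertained SNP has frequencies in every population")
  z <- as.numeric(t(freqs$freq[idx[complete], , drop = FALSE]) %*% beta[complete])
  names(z) <- freqs$pops
  attr(z, "n_dropped") <- n_dropped
  z
}

#' Center and standardize population polygenic scores
#'
#' Standardized scores are `(Z_m - mu) / sqrt(V_A)` with
#' `mu = sum_l beta_l * pbar_l` and the additive genic variance
#' `V_A = sum_l beta_l^2 * pbar_l (1 - pbar_l)`, where `pbar_l` is the
#' unweighted mean allele frequency across the analyzed populations.
#' Standardized scores sum to zero across populations by construction.
#'
#' @inheritParams polygenic_score
#' @param z raw scores from [polygenic_score()] (recomputed when `NULL`).
#' @return list with `z_std`, `mu`, `V_A`, `p_bar` and the raw `z`.
#' @export
standardize_scores <- function(beta, freqs, z = NULL) {
  stopifnot(inherits(freqs, "freq_table"))
  if (ncol(freqs$freq) < 2) stop("standardization needs >= 2 populations")
  if (is.data.frame(beta)) beta <- stats::setNames(beta$BETA, beta$SNP)
  z <- z %||% polygenic_score(beta, freqs)
  idx <- match(names(beta), freqs$snps$id)
  keep <- !is.na(idx)
  beta <- beta[keep]; idx <- idx[keep]
  p_bar <- rowMeans(freqs$freq[idx, , drop = FALSE])
  mu <- sum(beta * p_bar)
  V_A <- sum(beta^2 * p_bar * (1 - p_bar))
  if (V_A <= 0)
    stop("V_A = 0: all effects zero or all SNPs fixed at mean frequency 0/1")
  list(z = z, z_std = (z - mu) / sqrt(V_A), mu = mu, V_A = V_A,
       p_bar = stats::setNames(p_bar, names(beta)))
}

#' Beta-posterior credible half-widths for population scores
#'
#' Treats the underlying frequency at each locus in each population as
#' Beta-distributed a posteriori, updating a Uniform prior with the
#' observed allele counts: posterior `Beta(1 + x, 1 + n - x)`. The score
#' variance is `V_Z(m) = sum_l beta_l^2 * Var_posterior(l, m)` (loci and
#' populations independent, no LD correction) and the 95% credible
#' half-width is `1.96 * sqrt(V_Z)`.
#'
#' @inheritParams polygenic_score
#' @return list with per-population `V_Z` and `half_width` (raw trait
#'   units).
#' @export
credible_interval <- function(beta, freqs) {
  stopifnot(inherits(freqs, "freq_table"))
  if (is.null(freqs$x) || is.null(freqs$n))
    stop("credible intervals require allele counts (x, n) in the frequency table")
  if (is.data.frame(beta)) beta <- stats::setNames(beta$BETA, beta$SNP)
  idx <- match(names(beta), freqs$snps$id)
  if (anyNA(idx)) stop("SNPs missing from frequency table: ",
                       paste(utils::head(names(beta)[is.na(idx)], 5), collapse = ", "))
  if (any(freqs$n == 0))
    stop("n = 0 haploid observations for population(s): ",
         paste(freqs$pops[freqs$n == 0], collapse = ", "))
  x <- freqs$x[idx, , drop = FALSE]
  n <- matrix(freqs$n, nrow(x), ncol(x), byrow = TRUE)
  a <- 1 + x; b <- 1 + n - x
  var_post <- (a * b) / ((a + b)^2 * (a + b + 1))
  v_z <- as.numeric(t(var_post) %*% beta^2)
  names(v_z) <- freqs$pops
  list(V_Z = v_z, half_width = 1.96 * sqrt(v_z))
}

#' Population polygenic scores with credible intervals
#'
#' One-shot wrapper assembling raw scores, centered-standardized scores
#' and (when allele counts are available) 95% credible half-widths in
#' both raw and standardized units.
#'
#' @param sumstats harmonized summary statistics for the ascertained SNPs.
#' @param freqs a [freq_table()] covering those SNPs.
#' @return an object of class `score_result`: `$populations` data.frame
#'   (`pop`, `Z`, `Z_std`, `V_Z`, `ci_raw`, `ci_std`), plus `$mu`,
#'   `$V_A`, `$p_bar`, `$n_snps`.
#' @export
polygenic_scores <- function(sumstats, freqs) {
  validate_sumstats(sumstats)
  beta <- stats::setNames(sumstats$BETA, sumstats$SNP)
  beta <- beta[names(beta) %in% freqs$snps$id]
  if (!length(beta)) stop("no ascertained SNPs present in the frequency table")
  z <- polygenic_score(beta, freqs)
  st <- standardize_scores(beta, freqs, z = z)
  ci <- if (!is.null(freqs$x)) credible_interval(beta, freqs) else NULL
  populations <- data.frame(
    pop = freqs$pops, Z = as.numeric(z), Z_std = as.numeric(st$z_std),
    V_Z = if (is.null(ci)) NA_real_ else as.numeric(ci$V_Z),
    ci_raw = if (is.null(ci)) NA_real_ else as.numeric(ci$half_width),
    ci_std = if (is.null(ci)) NA_real_ else as.numeric(ci$half_width) / sqrt(st$V_A),
    stringsAsFactors = FALSE)
  structure(list(populations = populations, mu = st$mu, V_A = st$V_A,
                 p_bar = st$p_bar, n_snps = length(beta),
                 n_dropped = attr(z, "n_dropped")),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> %d SNPs, %d populations; mu = %.4g, V_A = %.4g\n",
              x$n_snps, nrow(x$populations), x$mu, x$V_A))
  print(x$populations, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a score result as TSV plus JSON sidecar
#' @param scores a `score_result`.
#' @param path output TSV path; `mu`, `V_A` and the SNP count go to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "score_result"))
  utils::write.table(scores$populations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(mu = scores$mu, V_A = scores$V_A,
                            n_snps = scores$n_snps),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
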