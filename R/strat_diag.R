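# Stratification diagnostics: PCA of a genotype panel, per-SNP PC
# loadings, correlations of effect sizes (or SDS) with loadings, the
# two-population frequency contrast of trait-increasing alleles, and
# MAF-binned heat maps.

#' Principal components of a genotype panel
#'
#' PCA of the individuals x SNPs matrix of centered (and by default
#' 1/sqrt(ploidy * p(1-p))-standardized) allele counts, after a MAF
#' floor, optional exclusion intervals (e.g. MHC, inversions, long-LD
#' regions) and optional r^2 pruning. Missing genotypes are mean-imputed
#' here (and only here). Scores have zero mean by construction.
#'
#' @param panel a [geno_panel()].
#' @param K number of components; reduced with a warning if it exceeds
#'   the matrix rank.
#' @param maf_min minor-allele-frequency floor (default 0.05).
#' @param exclude optional data.frame of intervals (`chr`, `start`,
#'   `end`, 1-based inclusive) to remove before PCA.
#' @param prune_r2,prune_window optional [prune()] parameters applied to
#'   the filtered SNP set.
#' @param standardize scale counts to unit variance under
#'   Hardy-Weinberg (default TRUE); FALSE centers only.
#' @return an object of class `pc_scores`: `$scores` (individuals x K,
#'   zero-mean), `$varexp`, `$snps_used`.
#' @export
compute_pcs <- function(panel, K = 10L, maf_min = 0.05, exclude = NULL,
                        prune_r2 = NULL, prune_window = 1e6,
                        standardize = TRUE) {
  stopifnot(inherits(panel, "geno_panel"))
  g <- panel$geno
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    nas <- which(is.na(g), arr.ind = TRUE)
    g[nas] <- mu[nas[, 2]]
  }
  p <- colMeans(g) / panel$ploidy
  keep <- pmin(p, 1 - p) > maf_min
  if (!is.null(exclude)) {
    for (b in seq_len(nrow(exclude))) {
      keep <- keep & !(panel$snps$chr == exclude$chr[b] &
                         panel$snps$pos >= exclude$start[b] &
                         panel$snps$pos <= exclude$end[b])
    }
  }
  ids <- panel$snps$id[keep]
  if (!is.null(prune_r2))
    ids <- prune(panel, prune_r2, prune_window, ids = ids)
  sel <- match(ids, panel$snps$id)
  x <- g[, sel, drop = FALSE]
  p <- p[sel]
  x <- sweep(x, 2, panel$ploidy * p)
  if (standardize)
    x <- sweep(x, 2, sqrt(panel$ploidy * p * (1 - p)), "/")
  sv <- svd(x)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (K > rank) {
    warning("K = ", K, " exceeds numerical rank ", rank, "; reduced")
    K <- rank
  }
  scores <- sv$u[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], K)
  dimnames(scores) <- list(panel$ind$id, sprintf("PC%d", seq_len(K)))
  structure(list(scores = scores, varexp = sv$d[seq_len(K)]^2 / sum(sv$d^2),
                 snps_used = ids, K = K),
            class = "pc_scores")
}

#' Per-SNP principal-component loadings by regression
#'
#' For each SNP and component, the loading is the allele-count
#' coefficient in a least-squares regression of the PC score on
#' (intercept, sex, allele count). Because the loading comes from a
#' regression rather than from the SVD itself, it is computable for SNPs
#' beyond the set PCA was run on. Monomorphic SNPs get `NA`.
#'
#' @param pcs a `pc_scores` object from [compute_pcs()].
#' @param panel the [geno_panel()] sharing individuals with `pcs`.
#' @param sex optional per-individual covariate (default: the panel's
#'   `sex` metadata); ignored when absent or constant.
#' @param ids SNPs to compute loadings for (default: all panel SNPs).
#' @return L x K numeric matrix of loadings (rownames = SNP ids).
#' @export
pc_loadings <- function(pcs, panel, sex = NULL, ids = NULL) {
  stopifnot(inherits(pcs, "pc_scores"), inherits(panel, "geno_panel"),
            nrow(pcs$scores) == nrow(panel$geno))
  sex <- sex %||% panel$ind$sex
  ids <- ids %||% panel$snps$id
  g <- panel$geno[, match(ids, panel$snps$id), drop = FALSE]
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    nas <- which(is.na(g), arr.ind = TRUE)
    g[nas] <- mu[nas[, 2]]
  }
  # Frisch-Waugh: residualize both counts and scores on (intercept, sex),
  # then the loading is the simple-regression coefficient of the residuals
  covars <- if (!is.null(sex) && length(unique(sex)) > 1)
    stats::model.matrix(~sex) else matrix(1, nrow(g), 1)
  qr_c <- qr(covars)
  g_res <- qr.resid(qr_c, g)
  s_res <- qr.resid(qr_c, pcs$scores)
  denom <- colSums(g_res^2)
  load <- crossprod(g_res, s_res) / denom
  load[denom <= 1e-12, ] <- NA_real_
  rownames(load) <- ids
  load
}

#' Correlations of a per-SNP vector with PC loadings
#'
#' Pearson correlation, per principal component, between a per-SNP
#' quantity (GWAS effect estimates, SDS, ...) and the SNP loadings, with
#' standard errors and P values from a delete-one-block jackknife over
#' contiguous blocks in genomic order. Two significance flags are
#' reported: nominal (P < 0.05) and Bonferroni-corrected for `n_pcs`
#' tests (P < 0.05 / n_pcs; 0.0025 at the default 20).
#'
#' @param v named per-SNP numeric vector (names = SNP ids), e.g. `BETA`.
#' @param loadings loading matrix from [pc_loadings()], rows in genomic
#'   order.
#' @param n_jackknife number of jackknife blocks (default 1000); reduced
#'   with a warning when there are fewer SNPs.
#' @param n_pcs number of tests assumed by the Bonferroni flag
#'   (default 20).
#' @return data.frame with one row per PC: `pc`, `r`, `se`, `p`,
#'   `nominal`, `bonferroni`.
#' @export
loading_correlations <- function(v, loadings, n_jackknife = 1000L,
                                 n_pcs = 20L) {
  common <- intersect(names(v), rownames(loadings))
  if (!length(common)) stop("no SNPs shared between v and loadings")
  v <- v[common]
  loadings <- loadings[common, , drop = FALSE]
  ok <- is.finite(v) & apply(is.finite(loadings), 1, all)
  v <- v[ok]; loadings <- loadings[ok, , drop = FALSE]
  n <- length(v)
  if (n < n_jackknife) {
    warning("fewer SNPs (", n, ") than jackknife blocks; blocks reduced")
    n_jackknife <- n
  }
  res <- lapply(seq_len(ncol(loadings)), function(k) {
    jk <- pearson_jackknife(v, loadings[, k], n_jackknife)
    data.frame(pc = colnames(loadings)[k] %||% sprintf("PC%d", k),
               r = jk$estimate, se = jk$se, p = jk$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$nominal <- out$p < 0.05
  out$bonferroni <- out$p < 0.05 / n_pcs
  out
}

#' Two-population frequency contrast of the trait-increasing allele
#'
#' For each SNP, the difference `p_A - p_B` in the frequency of the
#' trait-increasing allele between two populations: when the effect of
#' the counted allele is negative, the contrast is computed for the
#' other allele (i.e. negated). SNPs with an exactly zero effect, or
#' absent from either population, are dropped and tallied.
#'
#' @param freqs a [freq_table()] containing both populations.
#' @param pop_a,pop_b population labels (contrast is A minus B).
#' @param sumstats harmonized summary statistics (effects refer to the
#'   table's counted allele A1).
#' @return data.frame `SNP`, `CHR`, `POS`, `DELTA`, `P` in genomic
#'   order; drop counts in `attr(, "contrast_log")`.
#' @export
freq_contrast <- function(freqs, pop_a, pop_b, sumstats) {
  stopifnot(inherits(freqs, "freq_table"))
  validate_sumstats(sumstats)
  idx <- match(sumstats$SNP, freqs$snps$id)
  present <- !is.na(idx)
  ss <- sumstats[present, , drop = FALSE]
  pa <- freqs$freq[idx[present], pop_a]
  pb <- freqs$freq[idx[present], pop_b]
  nonzero <- ss$BETA != 0
  delta <- ifelse(ss$BETA > 0, pa - pb, pb - pa)
  out <- data.frame(SNP = ss$SNP, CHR = ss$CHR, POS = ss$POS,
                    DELTA = delta, P = ss$P,
                    stringsAsFactors = FALSE)[nonzero, , drop = FALSE]
  out <- out[order(out$CHR, out$POS), ]
  rownames(out) <- NULL
  attr(out, "contrast_log") <- list(n_missing = sum(!present),
                                    n_zero_beta = sum(!nonzero))
  out
}

#' Two-population MAF-binned heat map of a per-SNP quantity
#'
#' Bins SNPs on minor-allele frequency in each of two populations and
#' reports the per-cell mean of a per-SNP quantity and the per-cell SNP
#' count; cells below the count threshold are masked.
#'
#' @param values per-SNP numeric vector.
#' @param freq_a,freq_b aligned allele frequencies in populations A and
#'   B (any allele; the minor-allele fold is applied internally).
#' @param bin_width MAF bin width (default 0.05).
#' @param min_count cells with fewer SNPs are masked (default 300).
#' @return an object of class `binned_heatmap`: `$mean`, `$count`,
#'   `$mask` matrices (rows = population-A bins) and `$breaks`.
#' @export
maf_bin_heatmap <- function(values, freq_a, freq_b, bin_width = 0.05,
                            min_count = 300L) {
  stopifnot(length(values) == length(freq_a),
            length(values) == length(freq_b))
  if (!length(values)) stop("empty input")
  maf_a <- pmin(freq_a, 1 - freq_a)
  maf_b <- pmin(freq_b, 1 - freq_b)
  breaks <- seq(0, 0.5 + bin_width * 1e-9, by = bin_width)
  ia <- pmin(findInterval(maf_a, breaks, rightmost.closed = TRUE),
             length(breaks) - 1)
  ib <- pmin(findInterval(maf_b, breaks, rightmost.closed = TRUE),
             length(breaks) - 1)
  nb <- length(breaks) - 1
  cnt <- matrix(0L, nb, nb)
  sm <- matrix(0, nb, nb)
  for (i in seq_along(values)) {
    cnt[ia[i], ib[i]] <- cnt[ia[i], ib[i]] + 1L
    sm[ia[i], ib[i]] <- sm[ia[i], ib[i]] + values[i]
  }
  mean_mat <- ifelse(cnt > 0, sm / cnt, NA_real_)
  mask <- cnt < min_count
  mean_mat[mask] <- NA_real_
  lab <- sprintf("[%.2f,%.2f)", breaks[-length(breaks)], breaks[-1])
  dimnames(mean_mat) <- dimnames(cnt) <- dimnames(mask) <- list(lab, lab)
  structure(list(mean = mean_mat, count = cnt, mask = mask,
                 breaks = breaks),
            class = "binned_heatmap")
}
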