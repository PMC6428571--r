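#' Per-population allele-frequency table
#'
#' Container for effect-allele frequencies of L SNPs in M populations,
#' optionally with the allele counts (x successes out of n haploid
#' observations) that the Beta-posterior credible intervals require.
#'
#' @param freq numeric L x M matrix of effect-allele frequencies in
#'   \[0, 1\]; column names are population labels, row names SNP ids.
#' @param snps data.frame with one row per SNP and columns `id`, `chr`,
#'   `pos` (1-based), `A1` (effect/counted allele), `A2`.
#' @param x optional integer L x M matrix of effect-allele counts.
#' @param n optional integer vector (length M) of haploid sample sizes.
#' @param ancestral optional numeric vector of ancestral frequencies
#'   (recorded by the simulator; used e.g. by [estimate_F()]).
#' @param latitudes optional numeric vector of population latitudes
#'   (degrees), used by [latitude_test()].
#' @return an object of class `freq_table`.
#' @export
freq_table <- function(freq, snps, x = NULL, n = NULL, ancestral = NULL,
                       latitudes = NULL) {
  freq <- as.matrix(freq)
  stopifnot(is.numeric(freq), nrow(freq) == nrow(snps))
  if (any(freq < 0 | freq > 1)) stop("frequencies must lie in [0, 1]")
  req <- c("id", "chr", "pos", "A1", "A2")
  if (!all(req %in% names(snps)))
    stop("snps must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(snps$id)) stop("duplicate SNP ids in frequency table")
  rownames(freq) <- snps$id
  if (is.null(colnames(freq)))
    colnames(freq) <- sprintf("pop%d", seq_len(ncol(freq)))
  if (!is.null(x)) {
    x <- as.matrix(x)
    if (is.null(n)) stop("allele counts x given without haploid sizes n")
    stopifnot(all(dim(x) == dim(freq)), length(n) == ncol(freq))
    if (any(x < 0) || any(t(x) > n)) stop("allele counts must satisfy 0 <= x <= n")
    dimnames(x) <- dimnames(freq)
  }
  if (!is.null(latitudes) && length(latitudes) != ncol(freq))
    stop("latitudes must have one entry per population")
  structure(list(freq = freq, snps = as.data.frame(snps), x = x, n = n,
                 ancestral = ancestral, latitudes = latitudes,
                 pops = colnames(freq)),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d SNPs x %d populations (%s)%s\n",
              nrow(x$freq), ncol(x$freq),
              paste(utils::head(x$pops, 6), collapse = ", "),
              if (is.null(x$x)) "" else "; allele counts present"))
  invisible(x)
}

#' @export
dim.freq_table <- function(x) dim(x$freq)

#' Subset a frequency table by SNP id
#' @param x a [freq_table()].
#' @param ids SNP ids to keep (order respected).
#' @return a `freq_table` restricted to `ids`.
#' @export
subset_freqs <- function(x, ids) {
  stopifnot(inherits(x, "freq_table"))
  idx <- match(ids, x$snps$id)
  if (anyNA(idx)) stop("unknown SNP ids: ",
                       paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  freq_table(x$freq[idx, , drop = FALSE], x$snps[idx, , drop = FALSE],
             x = if (!is.null(x$x)) x$x[idx, , drop = FALSE],
             n = x$n, ancestral = x$ancestral[idx], latitudes = x$latitudes)
}

#' Genotype reference panel
#'
#' Individuals x SNPs allele-count matrix with per-individual metadata
#' (population, sex, latitude) and per-SNP metadata. Diploid panels hold
#' counts 0/1/2; pseudo-haploid panels (see [pseudo_haploidize()]) hold 0/1.
#'
#' @param geno integer matrix, individuals in rows, SNPs in columns.
#' @param snps per-SNP data.frame (`id`, `chr`, `pos`, `A1`, `A2`);
#'   positions must be strictly increasing within each chromosome.
#' @param ind per-individual data.frame (`id`, `pop`, `sex`, `latitude`).
#' @param ploidy 2 (diploid) or 1 (pseudo-haploid).
#' @return an object of class `geno_panel`.
#' @export
geno_panel <- function(geno, snps, ind, ploidy = 2L) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) == nrow(snps), nrow(geno) == nrow(ind),
            ploidy %in% c(1L, 2L))
  rng <- range(geno, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > ploidy)
    stop("allele counts outside ploidy bounds [0, ", ploidy, "]")
  for (ch in unique(snps$chr)) {
    p <- snps$pos[snps$chr == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  colnames(geno) <- snps$id
  rownames(geno) <- ind$id
  structure(list(geno = geno, snps = as.data.frame(snps),
                 ind = as.data.frame(ind), ploidy = as.integer(ploidy)),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("<geno_panel> %d individuals x %d SNPs, ploidy %d, %d population(s)\n",
              nrow(x$geno), ncol(x$geno), x$ploidy,
              length(unique(x$ind$pop))))
  invisible(x)
}

#' Validate a GWAS summary-statistics table
#'
#' Checks the canonical per-SNP schema used throughout the package:
#' columns `SNP`, `CHR`, `POS`, `A1` (effect allele), `A2`, `BETA`, `SE`,
#' `P`, `FREQ_A1`; ACGT alleles; finite `BETA`/`SE`; `P` in (0, 1\];
#' no duplicated (chromosome, position, allele-pair) keys.
#'
#' @param x data.frame to validate.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_sumstats <- function(x) {
  req <- c("SNP", "CHR", "POS", "A1", "A2", "BETA", "SE", "P", "FREQ_A1")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(x$A1 %in% DNA_BASES) || !all(x$A2 %in% DNA_BASES))
    stop("alleles must be single bases A/C/G/T")
  if (any(!is.finite(x$BETA)) || any(!is.finite(x$SE)))
    stop("BETA and SE must be finite")
  if (any(x$P <= 0 | x$P > 1)) stop("P values must lie in (0, 1]")
  if (any(x$FREQ_A1 < 0 | x$FREQ_A1 > 1)) stop("FREQ_A1 must lie in [0, 1]")
  key <- paste(x$CHR, x$POS,
               pmin(x$A1, x$A2), pmax(x$A1, x$A2), sep = ":")
  if (anyDuplicated(key)) {
    dup <- x$SNP[duplicated(key) | duplicated(key, fromLast = TRUE)]
    stop("duplicated (chr, pos, allele-pair) keys: ",
         paste(utils::head(unique(dup), 5), collapse = ", "))
  }
  if (anyDuplicated(x$SNP)) stop("duplicated SNP ids")
  invisible(x)
}
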