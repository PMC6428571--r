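# Ascertainment of independent trait-associated SNPs: lowest-P-per-LD-block,
# greedy P-value clumping, and sliding-window r^2 pruning.

#' Pick the lowest-P SNP in each LD block
#'
#' For each non-overlapping LD block, selects the SNP with the smallest
#' GWAS P value; ties are broken deterministically by lowest position,
#' then lexicographic id. SNPs falling outside every block are excluded
#' and tallied.
#'
#' @param sumstats harmonized summary-statistics data.frame.
#' @param blocks LD-block intervals as returned by [read_ld_blocks()]
#'   (`chr`, `start`, `end`, 1-based inclusive).
#' @return character vector of selected SNP ids in genomic order, with
#'   `attr(, "n_outside")` counting SNPs outside all blocks.
#' @export
lowest_p_per_block <- function(sumstats, blocks) {
  validate_sumstats(sumstats)
  key <- rep(NA_integer_, nrow(sumstats))
  for (b in seq_len(nrow(blocks))) {
    hit <- sumstats$CHR == blocks$chr[b] &
      sumstats$POS >= blocks$start[b] & sumstats$POS <= blocks$end[b]
    key[hit] <- b
  }
  inside <- !is.na(key)
  ss <- sumstats[inside, , drop = FALSE]
  ord <- order(ss$P, ss$POS, ss$SNP)
  ss <- ss[ord, ]
  pick <- ss[!duplicated(key[inside][ord]), , drop = FALSE]
  ids <- pick$SNP[order(pick$CHR, pick$POS)]
  attr(ids, "n_outside") <- sum(!inside)
  ids
}

#' Genotypic r-squared between two SNPs
#'
#' Squared Pearson correlation of the 0/1/2 allele-count vectors
#' (genotypic, not haplotypic, LD — appropriate for unphased panels).
#' A monomorphic SNP has undefined correlation and is treated as
#' `r^2 = 0` with a warning, since nothing can be clumped on it.
#'
#' @param panel a [geno_panel()].
#' @param snp_i,snp_j SNP ids or column indices.
#' @return r-squared in \[0, 1\].
#' @export
genotypic_r2 <- function(panel, snp_i, snp_j) {
  stopifnot(inherits(panel, "geno_panel"))
  gi <- panel$geno[, snp_i]; gj <- panel$geno[, snp_j]
  if (stats::var(gi) == 0 || stats::var(gj) == 0) {
    warning("monomorphic SNP: r^2 undefined, treated as 0")
    return(0)
  }
  stats::cor(gi, gj)^2
}

# r^2 of one SNP against a set of SNPs, vectorized; monomorphic -> 0.
r2_vec <- function(geno, i, js) {
  gi <- geno[, i]
  if (stats::var(gi) == 0) return(rep(0, length(js)))
  gj <- geno[, js, drop = FALSE]
  v <- apply(gj, 2, stats::var)
  r <- rep(0, length(js))
  ok <- v > 0
  if (any(ok)) r[ok] <- as.vector(stats::cor(gi, gj[, ok, drop = FALSE]))^2
  r
}

#' Clumping parameters
#'
#' @param p1 index-SNP P-value threshold (SNPs below it seed clumps).
#' @param p2 secondary threshold (SNPs below it can be absorbed).
#' @param r2 LD threshold; SNPs with `r^2 >=` this value to an index are
#'   absorbed.
#' @param window physical window in bp, measured index-SNP-to-candidate.
#' @return an object of class `clump_spec`.
#' @export
clump_spec <- function(p1 = 5e-8, p2 = 1, r2 = 0.1, window = 1e6) {
  stopifnot(p1 > 0, p1 <= 1, p2 > 0, p2 <= 1, r2 >= 0, r2 <= 1, window > 0)
  structure(list(p1 = p1, p2 = p2, r2 = r2, window = window),
            class = "clump_spec")
}

#' Greedy P-value clumping
#'
#' Forms clumps preferentially around the most significant SNPs: indices
#' are taken in ascending P order (ties broken by position then id) among
#' SNPs with `P < p1`; each new index absorbs every still-unassigned SNP
#' with `P < p2` on the same chromosome, within `window` bp and with
#' genotypic `r^2 >=` the threshold to the index. Each SNP appears in at
#' most one clump. SNPs absent from the LD panel are excluded and tallied.
#'
#' @param sumstats harmonized summary-statistics data.frame.
#' @param panel LD reference [geno_panel()].
#' @param spec a [clump_spec()].
#' @return character vector of index-SNP ids sorted by genomic position,
#'   with attributes `clumps` (named list of member ids per index) and
#'   `n_uncovered` (SNPs missing from the panel).
#' @export
clump <- function(sumstats, panel, spec = clump_spec()) {
  validate_sumstats(sumstats)
  stopifnot(inherits(spec, "clump_spec"), inherits(panel, "geno_panel"))
  covered <- sumstats$SNP %in% panel$snps$id
  ss <- sumstats[covered & sumstats$P < spec$p2, , drop = FALSE]
  cand <- ss[ss$P < spec$p1, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no SNPs below the index threshold p1 = ", spec$p1)
    out <- character(0)
    attr(out, "clumps") <- list()
    attr(out, "n_uncovered") <- sum(!covered)
    return(out)
  }
  cand <- cand[order(cand$P, cand$POS, cand$SNP), ]
  assigned <- stats::setNames(rep(FALSE, nrow(ss)), ss$SNP)
  clumps <- list()
  for (k in seq_len(nrow(cand))) {
    id <- cand$SNP[k]
    if (assigned[[id]]) next
    assigned[[id]] <- TRUE
    near <- which(!assigned & ss$CHR == cand$CHR[k] &
                    abs(ss$POS - cand$POS[k]) <= spec$window)
    if (length(near)) {
      r2 <- r2_vec(panel$geno, id, match(ss$SNP[near], panel$snps$id))
      members <- near[r2 >= spec$r2]
      assigned[members] <- TRUE
      clumps[[id]] <- ss$SNP[members]
    } else clumps[[id]] <- character(0)
  }
  idx <- names(clumps)
  pos <- sumstats$POS[match(idx, sumstats$SNP)]
  chr <- sumstats$CHR[match(idx, sumstats$SNP)]
  out <- idx[order(chr, pos)]
  attr(out, "clumps") <- clumps[out]
  attr(out, "n_uncovered") <- sum(!covered)
  out
}

#' Sliding-window LD pruning
#'
#' Scans SNPs in genomic order and drops any SNP whose genotypic `r^2`
#' with an already-retained SNP within the window reaches the threshold;
#' the earlier-position SNP is always the one kept, making the output
#' deterministic.
#'
#' @param panel a [geno_panel()].
#' @param r2_threshold retained pairs must have `r^2 <` this value.
#' @param window physical window in bp.
#' @param ids optional subset of SNP ids to prune (default: all panel SNPs).
#' @return character vector of retained SNP ids in genomic order.
#' @export
prune <- function(panel, r2_threshold = 0.2, window = 1e6, ids = NULL) {
  stopifnot(inherits(panel, "geno_panel"))
  snps <- panel$snps
  if (!is.null(ids)) snps <- snps[snps$id %in% ids, , drop = FALSE]
  snps <- snps[order(snps$chr, snps$pos, snps$id), ]
  kept_id <- character(0); kept_chr <- character(0); kept_pos <- numeric(0)
  for (k in seq_len(nrow(snps))) {
    near <- which(kept_chr == snps$chr[k] &
                    abs(kept_pos - snps$pos[k]) <= window)
    ok <- TRUE
    if (length(near)) {
      r2 <- r2_vec(panel$geno, snps$id[k],
                   match(kept_id[near], panel$snps$id))
      ok <- all(r2 < r2_threshold)
    }
    if (ok) {
      kept_id <- c(kept_id, snps$id[k])
      kept_chr <- c(kept_chr, as.character(snps$chr[k]))
      kept_pos <- c(kept_pos, snps$pos[k])
    }
  }
  kept_id
}
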