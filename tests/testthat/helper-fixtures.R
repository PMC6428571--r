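# Shared fixtures and independent brute-force oracles.

# canonical summary-statistics data.frame from parallel vectors
make_sumstats <- function(id, chr = 1L, pos = seq_along(id) * 1e5,
                          a1 = "A", a2 = "G", beta = 0.1, se = 0.01,
                          p = 0.5, freq = 0.5) {
  n <- length(id)
  data.frame(SNP = id, CHR = rep_len(chr, n), POS = rep_len(pos, n),
             A1 = rep_len(a1, n), A2 = rep_len(a2, n),
             BETA = rep_len(beta, n), SE = rep_len(se, n),
             P = rep_len(p, n), FREQ_A1 = rep_len(freq, n),
             stringsAsFactors = FALSE)
}

make_snps <- function(id, chr = 1L, pos = seq_along(id) * 1e5,
                      a1 = "A", a2 = "G") {
  n <- length(id)
  data.frame(id = id, chr = rep_len(chr, n), pos = rep_len(pos, n),
             A1 = rep_len(a1, n), A2 = rep_len(a2, n),
             stringsAsFactors = FALSE)
}

# panel from an explicit genotype matrix (individuals x SNPs)
make_panel <- function(geno, chr = 1L, pos = seq_len(ncol(geno)) * 1e5,
                       pop = "popA", ploidy = 2L) {
  ids <- sprintf("s%d", seq_len(ncol(geno)))
  snps <- make_snps(ids, chr = chr, pos = pos)
  ind <- data.frame(id = sprintf("i%d", seq_len(nrow(geno))),
                    pop = rep_len(pop, nrow(geno)),
                    sex = rep_len(c("F", "M"), nrow(geno)),
                    latitude = NA_real_, stringsAsFactors = FALSE)
  geno_panel(geno, snps, ind, ploidy = ploidy)
}

# Naive reference clumper, written directly from the verbal definition:
# repeatedly take the unassigned SNP with the smallest P among those
# below p1 (ties: position, then id), then sweep over every other SNP
# and absorb it if unassigned, below p2, on the same chromosome, within
# the window and with r^2 at or above the threshold.
brute_clump <- function(ss, r2, p1, p2, r2_thresh, window) {
  ss <- ss[ss$P < p2, , drop = FALSE]
  r2 <- r2[ss$SNP, ss$SNP, drop = FALSE]
  assigned <- rep(FALSE, nrow(ss))
  indices <- character(0)
  repeat {
    cand <- which(!assigned & ss$P < p1)
    if (!length(cand)) break
    cand <- cand[order(ss$P[cand], ss$POS[cand], ss$SNP[cand])]
    i <- cand[1]
    assigned[i] <- TRUE
    indices <- c(indices, ss$SNP[i])
    for (j in seq_len(nrow(ss))) {
      if (assigned[j]) next
      if (ss$CHR[j] == ss$CHR[i] &&
          abs(ss$POS[j] - ss$POS[i]) <= window &&
          r2[i, j] >= r2_thresh)
        assigned[j] <- TRUE
    }
  }
  indices[order(ss$CHR[match(indices, ss$SNP)],
                ss$POS[match(indices, ss$SNP)])]
}

# Naive reference pruner: walk SNPs in (chr, pos, id) order and keep a
# SNP only if every already-kept SNP within the window has r^2 below
# the threshold.
brute_prune <- function(snps, r2, r2_thresh, window) {
  snps <- snps[order(snps$chr, snps$pos, snps$id), , drop = FALSE]
  kept <- character(0)
  for (i in seq_len(nrow(snps))) {
    ok <- TRUE
    for (k in kept) {
      krow <- snps[snps$id == k, ]
      if (krow$chr == snps$chr[i] &&
          abs(krow$pos - snps$pos[i]) <= window &&
          r2[k, snps$id[i]] >= r2_thresh) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, snps$id[i])
  }
  kept
}

# empirical genotypic r^2 matrix of a panel, by definition
panel_r2_matrix <- function(panel) {
  r <- suppressWarnings(stats::cor(panel$geno))
  r[!is.finite(r)] <- 0
  r2 <- r^2
  dimnames(r2) <- list(panel$snps$id, panel$snps$id)
  r2
}

# random small clump/prune instance for oracle fuzzing
random_ld_instance <- function(n_snps, n_ind = 40) {
  base <- matrix(rbinom(n_ind * n_snps, 2, runif(n_snps, 0.2, 0.8)),
                 n_ind, n_snps, byrow = TRUE)
  # copy some columns with noise to create real LD
  for (j in seq_len(n_snps)) {
    if (j > 1 && runif(1) < 0.4) {
      src <- sample(j - 1, 1)
      flip <- rbinom(n_ind, 1, 0.15)
      base[, j] <- ifelse(flip == 1, 2 - base[, src], base[, src])
    }
  }
  chr <- sample(1:2, n_snps, replace = TRUE)
  pos <- integer(n_snps)
  for (ch in unique(chr))
    pos[chr == ch] <- sort(sample(1:50, sum(chr == ch))) * 1e5
  ord <- order(chr, pos)
  panel <- make_panel(base[, ord, drop = FALSE], chr = chr[ord],
                      pos = pos[ord])
  ss <- make_sumstats(panel$snps$id, chr = panel$snps$chr,
                      pos = panel$snps$pos,
                      p = runif(n_snps, 1e-12, 1))
  list(panel = panel, ss = ss)
}
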