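#' Specification of a neutral-drift simulation
#'
#' Defines the ground truth for the synthetic populations: `M` populations
#' whose allele frequencies drift away from an ancestral frequency with
#' covariance structure `F`, i.e. exactly the multivariate-normal model
#' that the Qx null assumes. Per-SNP ancestral frequencies are drawn from
#' `ancestral_freq_law` (default Uniform(0.05, 0.95)).
#'
#' @param M number of populations (>= 1).
#' @param L number of SNPs.
#' @param F M x M symmetric positive-semidefinite drift covariance matrix
#'   (dimensionless); a scalar is expanded to `F * I`.
#' @param Y optional latitude per population (degrees).
#' @param ancestral_freq_law either a length-2 numeric range for a uniform
#'   law on (0, 1), or a function of `L` returning ancestral frequencies.
#' @param n_hap haploid sample size per population for the binomial allele
#'   counts (scalar or length-M vector).
#' @param pops population labels.
#' @param seed integer seed; every simulation from this spec is bit-
#'   reproducible given the seed.
#' @return an object of class `drift_spec`.
#' @export
drift_spec <- function(M, L, F, Y = NULL,
                       ancestral_freq_law = c(0.05, 0.95),
                       n_hap = 100L, pops = sprintf("pop%d", seq_len(M)),
                       seed = NULL) {
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  if (is.numeric(F) && length(F) == 1L && !is.matrix(F)) F <- diag(F, M)
  F <- as.matrix(F)
  if (!isTRUE(all.equal(F, t(F), tolerance = 1e-12)))
    stop("F must be symmetric")
  ev <- eigen(F, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf("F is not positive semidefinite (min eigenvalue %.3g)",
                 min(ev)))
  if (nrow(F) != M) stop("F must be M x M")
  if (!is.null(Y) && length(Y) != M) stop("Y must have one latitude per population")
  n_hap <- rep_len(as.integer(n_hap), M)
  structure(list(M = M, L = as.integer(L), F = F, Y = Y,
                 ancestral_freq_law = ancestral_freq_law,
                 n_hap = n_hap, pops = pops, seed = seed),
            class = "drift_spec")
}

# Default SNP metadata: SNPs spread evenly over 22 autosomes with strictly
# increasing positions, and a non-palindromic allele pair per SNP so that
# simulated tables survive harmonization untouched.
simulate_snp_meta <- function(L) {
  chr <- sort(rep_len(1:22, L))
  pos <- integer(L)
  for (ch in unique(chr)) {
    k <- sum(chr == ch)
    pos[chr == ch] <- seq_len(k) * 10000L
  }
  a1 <- sample(DNA_BASES, L, replace = TRUE)
  # pick A2 uniformly among the two non-self, non-complement bases
  alt <- cbind(A = sample(c("C", "G"), L, TRUE), C = sample(c("A", "T"), L, TRUE),
               G = sample(c("A", "T"), L, TRUE), T = sample(c("C", "G"), L, TRUE))
  a2 <- alt[cbind(seq_len(L), match(a1, DNA_BASES))]
  data.frame(id = sprintf("snp%06d", seq_len(L)), chr = chr, pos = pos,
             A1 = a1, A2 = a2, stringsAsFactors = FALSE)
}

#' Simulate population allele frequencies under multivariate-normal drift
#'
#' For each SNP, the vector of population frequencies is the ancestral
#' frequency plus a multivariate-normal perturbation with covariance
#' `2 p(1-p) F`, clipped to \[0.001, 0.999\]. Allele counts are drawn
#' Binomial(n_hap, p) per population. The ancestral frequencies are
#' recorded in the result for parameter-recovery tests.
#'
#' Throughout the package, F is the covariance matrix of allele-frequency
#' deviations standardized by `sqrt(2 p(1-p))` (half the expected
#' heterozygosity), so that the polygenic-score drift null is exactly
#' `Z ~ MVN(0, 2 V_A F)` with `V_A = sum beta^2 pbar (1-pbar)`;
#' [estimate_F()] uses the same scaling.
#'
#' @param spec a [drift_spec()].
#' @return a [freq_table()] with counts, recorded ancestral frequencies
#'   and (if given) latitudes.
#' @export
simulate_frequencies <- function(spec) {
  stopifnot(inherits(spec, "drift_spec"))
  set_seed_if(spec$seed)
  L <- spec$L; M <- spec$M
  snps <- simulate_snp_meta(L)
  law <- spec$ancestral_freq_law
  pbar <- if (is.function(law)) law(L) else stats::runif(L, law[1], law[2])
  if (any(pbar <= 0 | pbar >= 1)) stop("ancestral frequencies must lie in (0, 1)")
  e <- eigen(spec$F, symmetric = TRUE)
  B <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), M)
  eps <- matrix(stats::rnorm(L * M), L, M) %*% t(B) * sqrt(2 * pbar * (1 - pbar))
  p <- pmin(pmax(pbar + eps, 0.001), 0.999)
  x <- matrix(stats::rbinom(L * M, size = rep(spec$n_hap, each = L),
                            prob = p), L, M)
  colnames(p) <- colnames(x) <- spec$pops
  freq_table(p, snps, x = x, n = spec$n_hap, ancestral = pbar,
             latitudes = spec$Y)
}

#' Specification of a (possibly confounded) simulated GWAS
#'
#' Effect estimates are the true effects plus sampling noise plus a
#' stratification-bias term `a * delta_l`, where `delta_l` is a frequency
#' contrast along an axis of population structure. This is the mechanism
#' by which an uncorrected GWAS assigns artificially large effects to
#' alleles differentiated along that axis.
#'
#' @param true_beta_law function of `L` returning true effects (trait
#'   units per A1 allele), or a fixed numeric vector.
#' @param se per-SNP sampling standard error of the effect estimate
#'   (scalar or vector, >= 0).
#' @param bias_coeff stratification-bias coefficient `a` (trait units per
#'   unit frequency contrast).
#' @param bias_axis vector over populations defining the contrast
#'   `delta_l = sum_m axis_m p_lm`; must sum to 0. Default: first minus
#'   last population.
#' @param selection_set SNP ids flagged as targets of simulated selection
#'   (ground truth consumed by [simulate_sds()]).
#' @param gwas_weights population weights for the reported effect-allele
#'   frequency (default: first population only, mimicking a single-cohort
#'   GWAS).
#' @param seed integer seed.
#' @return an object of class `gwas_sim_spec`.
#' @export
gwas_sim_spec <- function(true_beta_law = function(L) stats::rnorm(L, 0, 0.02),
                          se = 0.01, bias_coeff = 0, bias_axis = NULL,
                          selection_set = character(0),
                          gwas_weights = NULL, seed = NULL) {
  if (any(se < 0)) stop("se must be >= 0")
  if (!is.null(bias_axis) && abs(sum(bias_axis)) > 1e-8)
    stop("bias_axis must sum to 0")
  structure(list(true_beta_law = true_beta_law, se = se,
                 bias_coeff = bias_coeff, bias_axis = bias_axis,
                 selection_set = selection_set,
                 gwas_weights = gwas_weights, seed = seed),
            class = "gwas_sim_spec")
}

default_axis <- function(M) {
  ax <- numeric(M); ax[1] <- 1; ax[M] <- -1
  ax
}

#' Simulate GWAS summary statistics over simulated populations
#'
#' @param freqs a [freq_table()], typically from [simulate_frequencies()].
#' @param spec a [gwas_sim_spec()].
#' @return a canonical summary-statistics data.frame (see
#'   [validate_sumstats()]) with attributes `beta_true` (recorded true
#'   effects) and `delta` (the per-SNP stratification contrast).
#' @export
simulate_gwas <- function(freqs, spec) {
  stopifnot(inherits(freqs, "freq_table"), inherits(spec, "gwas_sim_spec"))
  set_seed_if(spec$seed)
  L <- nrow(freqs$freq); M <- ncol(freqs$freq)
  beta_true <- if (is.function(spec$true_beta_law))
    spec$true_beta_law(L) else spec$true_beta_law
  if (length(beta_true) != L) stop("true effects and frequency table disagree on L")
  bad <- setdiff(spec$selection_set, freqs$snps$id)
  if (length(bad)) stop("selection_set contains unknown SNP ids: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  axis <- spec$bias_axis %||% default_axis(M)
  if (length(axis) != M) stop("bias_axis length must equal the number of populations")
  delta <- as.numeric(freqs$freq %*% axis)
  se <- rep_len(spec$se, L)
  beta_hat <- beta_true + spec$bias_coeff * delta + stats::rnorm(L, 0, se)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(beta_hat / se)),
              # se = 0 has no sampling distribution; emit a documented
              # 0-adjacent sentinel for nonzero estimates, 1 otherwise
              ifelse(beta_hat == 0, 1, .Machine$double.xmin))
  w <- spec$gwas_weights %||% c(1, rep(0, M - 1))
  w <- w / sum(w)
  out <- data.frame(SNP = freqs$snps$id, CHR = freqs$snps$chr,
                    POS = freqs$snps$pos, A1 = freqs$snps$A1,
                    A2 = freqs$snps$A2, BETA = beta_hat, SE = se,
                    P = pmax(p, .Machine$double.xmin),
                    FREQ_A1 = as.numeric(freqs$freq %*% w),
                    stringsAsFactors = FALSE)
  validate_sumstats(out)
  attr(out, "beta_true") <- beta_true
  attr(out, "delta") <- delta
  attr(out, "selection_set") <- spec$selection_set
  out
}

#' Simulate SDS-like scores with a frequency-cline confound and true selection
#'
#' Raw scores are built from three components: a cline term proportional
#' to the frequency contrast along an axis of population structure (the
#' confound that arises when the sequencing panel is itself structured),
#' a true-selection term of size `selection_coeff` on the selected SNPs
#' oriented along the sign of the true effect (so that trait alignment
#' accumulates it coherently), and Gaussian noise. The derived allele of
#' each simulated score is defined to be the effect allele A1.
#'
#' @param freqs a [freq_table()].
#' @param cline_coeff cline confound coefficient (score units per unit
#'   frequency contrast).
#' @param selection_coeff mean score shift at selected SNPs (score units).
#' @param selection_set SNP ids under simulated selection.
#' @param noise_sd standard deviation of the score noise.
#' @param beta_true per-SNP true effects used to orient the selection
#'   term (e.g. `attr(sumstats, "beta_true")`); required when
#'   `selection_coeff != 0`.
#' @param cline_axis contrast vector over populations (sums to 0);
#'   default first minus last population.
#' @param daf_pop population whose frequency is reported as the derived
#'   allele frequency (index or name; default 1, the GWAS-like cohort).
#' @param seed integer seed.
#' @return an SDS table: data.frame with columns `CHR`, `POS`, `ID`,
#'   `AA` (ancestral allele), `DA` (derived allele), `DAF`, `SDS`.
#' @export
simulate_sds <- function(freqs, cline_coeff = 0, selection_coeff = 0,
                         selection_set = character(0), noise_sd = 1,
                         beta_true = NULL, cline_axis = NULL, daf_pop = 1,
                         seed = NULL) {
  stopifnot(inherits(freqs, "freq_table"))
  set_seed_if(seed)
  L <- nrow(freqs$freq); M <- ncol(freqs$freq)
  bad <- setdiff(selection_set, freqs$snps$id)
  if (length(bad)) stop("selection_set contains unknown SNP ids: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  axis <- cline_axis %||% default_axis(M)
  if (abs(sum(axis)) > 1e-8) stop("cline_axis must sum to 0")
  delta <- as.numeric(freqs$freq %*% axis)
  sel <- freqs$snps$id %in% selection_set
  sel_term <- numeric(L)
  if (selection_coeff != 0 && any(sel)) {
    if (is.null(beta_true)) stop("beta_true is required to orient the selection term")
    sel_term[sel] <- selection_coeff * sign(beta_true[sel])
  }
  sds <- cline_coeff * delta + sel_term + stats::rnorm(L, 0, noise_sd)
  data.frame(CHR = freqs$snps$chr, POS = freqs$snps$pos,
             ID = freqs$snps$id, AA = freqs$snps$A2, DA = freqs$snps$A1,
             DAF = freqs$freq[, daf_pop], SDS = sds,
             stringsAsFactors = FALSE)
}

#' Simulate a diploid genotype reference panel
#'
#' Draws diploid allele counts Binomial(2, p_lm) per individual, SNP and
#' population. Optionally, consecutive SNPs within a window share a
#' latent haplotype indicator with a stated correlation, which induces
#' block LD sufficient for exercising clumping and pruning (marginal
#' frequencies are preserved).
#'
#' @param freqs a [freq_table()].
#' @param n_per_pop individuals per population (scalar or vector).
#' @param sex_ratio probability an individual is male.
#' @param ld optional `list(window = <n SNPs>, rho = <latent correlation>)`.
#' @param seed integer seed.
#' @return a diploid [geno_panel()].
#' @export
simulate_genotype_panel <- function(freqs, n_per_pop, sex_ratio = 0.5,
                                    ld = NULL, seed = NULL) {
  stopifnot(inherits(freqs, "freq_table"))
  set_seed_if(seed)
  L <- nrow(freqs$freq); M <- ncol(freqs$freq)
  n_per_pop <- rep_len(as.integer(n_per_pop), M)
  if (any(n_per_pop < 1)) stop("n_per_pop must be >= 1")
  blocks <- if (is.null(ld)) NULL else {
    stopifnot(ld$window >= 1, ld$rho >= 0, ld$rho <= 1)
    # block structure follows genomic order; blocks never span chromosomes
    paste(freqs$snps$chr,
          ceiling(seq_len(L) / ld$window))
  }
  geno_list <- vector("list", M)
  for (m in seq_len(M)) {
    n <- n_per_pop[m]; p <- freqs$freq[, m]
    if (is.null(blocks)) {
      g <- matrix(stats::rbinom(n * L, 2L, rep(p, each = n)), n, L)
    } else {
      thr <- stats::qnorm(p)
      g <- matrix(0L, n, L)
      for (h in 1:2) {
        ub <- matrix(stats::rnorm(n * length(unique(blocks))), n)
        colnames(ub) <- unique(blocks)
        z <- ld$rho * ub[, blocks, drop = FALSE] +
          sqrt(1 - ld$rho^2) * matrix(stats::rnorm(n * L), n, L)
        g <- g + (z < matrix(thr, n, L, byrow = TRUE))
      }
    }
    geno_list[[m]] <- g
  }
  geno <- do.call(rbind, geno_list)
  lat <- if (!is.null(freqs$latitudes)) rep(freqs$latitudes, n_per_pop) else NA_real_
  ind <- data.frame(
    id = sprintf("ind%05d", seq_len(sum(n_per_pop))),
    pop = rep(freqs$pops, n_per_pop),
    sex = ifelse(stats::rbinom(sum(n_per_pop), 1, sex_ratio) == 1, "M", "F"),
    latitude = lat, stringsAsFactors = FALSE)
  geno_panel(geno, freqs$snps, ind, ploidy = 2L)
}
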