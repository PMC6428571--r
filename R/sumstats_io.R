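# Reading, writing and harmonizing GWAS summary statistics and the
# auxiliary tables (frequency tables, SDS tables, LD-block intervals).

# Built-in column dialects: canonical field -> file column name.
SUMSTATS_DIALECTS <- list(
  canonical = c(SNP = "SNP", CHR = "CHR", POS = "POS", A1 = "A1", A2 = "A2",
                BETA = "BETA", SE = "SE", P = "P", FREQ_A1 = "FREQ_A1"),
  # GIANT-style meta-analysis columns (augmented with CHR/POS)
  giant = c(SNP = "MarkerName", CHR = "CHR", POS = "POS",
            A1 = "Allele1", A2 = "Allele2", BETA = "b", SE = "SE",
            P = "p", FREQ_A1 = "Freq.Allele1.HapMapCEU"),
  # Neale-lab-style UK Biobank columns
  neale = c(SNP = "rsid", CHR = "chr", POS = "pos", A1 = "alt", A2 = "ref",
            BETA = "beta", SE = "se", P = "pval", FREQ_A1 = "minor_AF")
)

#' Read GWAS summary statistics
#'
#' Reads a whitespace/tab-delimited summary-statistics file under a named
#' column dialect, validates it against the canonical schema and reports
#' malformed rows. Rows with unparseable or out-of-range P values are
#' dropped with a warning; a missing mandatory column is an error.
#'
#' @param path file path.
#' @param dialect one of `"canonical"`, `"giant"`, `"neale"`, or a named
#'   character vector mapping canonical fields to file column names.
#' @return validated canonical summary-statistics data.frame; the number
#'   of dropped rows is recorded in `attr(, "io_log")`.
#' @export
read_sumstats <- function(path, dialect = "canonical") {
  if (!file.exists(path)) stop("no such file: ", path)
  map <- if (is.character(dialect) && length(dialect) == 1L) {
    if (!dialect %in% names(SUMSTATS_DIALECTS))
      stop("unknown dialect '", dialect, "'; known: ",
           paste(names(SUMSTATS_DIALECTS), collapse = ", "))
    SUMSTATS_DIALECTS[[dialect]]
  } else dialect
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  miss <- setdiff(unname(map), names(raw))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  out <- stats::setNames(raw[, unname(map)], names(map))
  out$A1 <- toupper(out$A1); out$A2 <- toupper(out$A2)
  out$P <- suppressWarnings(as.numeric(out$P))
  out$BETA <- suppressWarnings(as.numeric(out$BETA))
  out$SE <- suppressWarnings(as.numeric(out$SE))
  bad <- is.na(out$P) | out$P <= 0 | out$P > 1
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable or out-of-range P value dropped")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  validate_sumstats(out)
  attr(out, "io_log") <- list(path = path, n_read = nrow(raw),
                              n_dropped = sum(bad))
  out
}

#' Write GWAS summary statistics (canonical dialect)
#'
#' Writes a tab-delimited canonical table plus a JSON provenance sidecar
#' (`<path>.prov.json`) recording the content hash and row count, so that
#' round-tripping through [read_sumstats()] is the identity.
#'
#' @param table canonical summary-statistics data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  validate_sumstats(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_provenance(path, list(n_snps = nrow(table)))
  invisible(path)
}

write_provenance <- function(path, extra = list()) {
  prov <- c(list(file = basename(path),
                 md5 = unname(tools::md5sum(path))), extra)
  jsonlite::write_json(prov, paste0(path, ".prov.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prov)
}

#' Harmonize summary statistics to a target's counted allele
#'
#' Aligns each effect estimate to the allele counted by the target
#' frequency table or genotype panel: if the target counts this table's
#' A2, the effect is negated and the reported frequency mapped to
#' `1 - f`; strand-flipped matches (complementary alleles) are resolved;
#' palindromic A/T and C/G SNPs and SNPs with incompatible allele pairs
#' are dropped. Harmonizing an already-harmonized table is a no-op.
#'
#' @param sumstats canonical summary-statistics data.frame.
#' @param target a [freq_table()] or [geno_panel()] whose `snps` metadata
#'   defines the counted allele (its A1).
#' @return harmonized summary statistics restricted to matched SNPs, in
#'   the target's allele frame; action counts are in `attr(, "harmonize_log")`.
#' @export
harmonize <- function(sumstats, target) {
  validate_sumstats(sumstats)
  tsnp <- if (inherits(target, c("freq_table", "geno_panel"))) target$snps
          else as.data.frame(target)
  idx <- match(sumstats$SNP, tsnp$id)
  by_pos <- FALSE
  if (all(is.na(idx))) { # fall back to (chr, pos) keys
    idx <- match(paste(sumstats$CHR, sumstats$POS),
                 paste(tsnp$chr, tsnp$pos))
    by_pos <- TRUE
  }
  matched <- !is.na(idx)
  ss <- sumstats[matched, , drop = FALSE]
  tt <- tsnp[idx[matched], , drop = FALSE]
  pal <- is_palindromic(ss$A1, ss$A2)
  same <- !pal & ss$A1 == tt$A1 & ss$A2 == tt$A2
  swap <- !pal & ss$A1 == tt$A2 & ss$A2 == tt$A1
  ca1 <- complement_allele(ss$A1); ca2 <- complement_allele(ss$A2)
  flip <- !pal & !same & !swap & ca1 == tt$A1 & ca2 == tt$A2
  flip_swap <- !pal & !same & !swap & !flip & ca1 == tt$A2 & ca2 == tt$A1
  keep <- same | swap | flip | flip_swap
  negate <- swap | flip_swap
  out <- ss[keep, , drop = FALSE]
  out$BETA <- ifelse(negate[keep], -out$BETA, out$BETA)
  out$FREQ_A1 <- ifelse(negate[keep], 1 - out$FREQ_A1, out$FREQ_A1)
  out$A1 <- tt$A1[keep]; out$A2 <- tt$A2[keep]
  if (by_pos) out$SNP <- tt$id[keep]
  rownames(out) <- NULL
  attr(out, "harmonize_log") <- list(
    n_input = nrow(sumstats), n_unmatched = sum(!matched),
    n_palindromic = sum(pal), n_same = sum(same), n_swapped = sum(swap),
    n_strand_flipped = sum(flip), n_flip_swapped = sum(flip_swap),
    n_incompatible = sum(!keep & !pal))
  out
}

#' Pseudo-haploidize a diploid genotype panel
#'
#' Replaces each diploid genotype by a single randomly sampled allele
#' (0 -> 0, 2 -> 1, heterozygote -> Bernoulli(1/2)), the representation
#' used for ancient-DNA comparability.
#'
#' @param panel a diploid [geno_panel()].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a ploidy-1 [geno_panel()].
#' @export
pseudo_haploidize <- function(panel, seed = NULL) {
  stopifnot(inherits(panel, "geno_panel"))
  if (panel$ploidy == 1L) {
    warning("panel is already pseudo-haploid; returning unchanged")
    return(panel)
  }
  set_seed_if(seed)
  g <- panel$geno
  het <- which(g == 1L)
  h <- g %/% 2L
  h[het] <- stats::rbinom(length(het), 1L, 0.5)
  geno_panel(h, panel$snps, panel$ind, ploidy = 1L)
}

#' Per-population allele frequencies from a genotype panel
#'
#' @param panel a [geno_panel()].
#' @param grouping population label per individual (default: the panel's
#'   `pop` metadata); every individual must belong to exactly one group.
#' @return a [freq_table()] with counted-allele frequencies, allele
#'   counts `x` and haploid sizes `n = ploidy * n_individuals`.
#' @export
allele_freqs <- function(panel, grouping = NULL) {
  stopifnot(inherits(panel, "geno_panel"))
  grouping <- grouping %||% panel$ind$pop
  if (length(grouping) != nrow(panel$geno))
    stop("grouping must assign each individual to a population")
  grouping <- as.character(grouping)
  pops <- unique(grouping)
  n_ind <- table(factor(grouping, levels = pops))
  if (any(n_ind == 0)) stop("empty population(s): ",
                            paste(names(n_ind)[n_ind == 0], collapse = ", "))
  x <- t(rowsum(panel$geno, grouping)[pops, , drop = FALSE])
  n <- panel$ploidy * as.integer(n_ind)
  p <- sweep(x, 2, n, "/")
  lat <- if (!all(is.na(panel$ind$latitude)))
    vapply(pops, function(g) panel$ind$latitude[grouping == g][1], numeric(1))
  else NULL
  freq_table(p, panel$snps, x = x, n = n, latitudes = lat)
}

#' Read an SDS score table
#'
#' Expects the published per-SNP layout: columns `CHR`, `POS`, `ID`,
#' `AA` (ancestral allele), `DA` (derived allele), `DAF` (derived-allele
#' frequency) and `SDS` (raw score).
#'
#' @param path tab-delimited file path.
#' @return SDS data.frame in genomic order.
#' @export
read_sds <- function(path) {
  x <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("CHR", "POS", "ID", "AA", "DA", "DAF", "SDS")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (any(x$DAF <= 0 | x$DAF >= 1))
    stop("DAF must lie strictly inside (0, 1)")
  x[order(x$CHR, x$POS), req]
}

#' Read LD-block intervals from a BED-like file
#'
#' Input intervals are 0-based half-open (BED convention) and are
#' converted on load to the package's 1-based inclusive representation.
#'
#' @param path whitespace-delimited file with columns chrom, start, end
#'   (no header, or a header line starting with `chr`/`#`).
#' @return data.frame with `chr`, `start`, `end` (1-based inclusive).
#' @export
read_ld_blocks <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^#|^chr\\b|start", first, ignore.case = TRUE) &&
    !grepl("^chr[0-9XY]+\\s", first)
  x <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  x <- x[, 1:3]
  names(x) <- c("chr", "start", "end")
  x$chr <- sub("^chr", "", as.character(x$chr))
  blocks <- data.frame(chr = x$chr, start = x$start + 1L, end = x$end,
                       stringsAsFactors = FALSE)
  for (ch in unique(blocks$chr)) {
    b <- blocks[blocks$chr == ch, ]
    b <- b[order(b$start), ]
    if (any(b$start[-1] <= b$end[-nrow(b)]))
      stop("overlapping LD blocks on chromosome ", ch)
  }
  blocks[order(blocks$chr, blocks$start), ]
}

#' Write a frequency table as long-format TSV
#'
#' One row per SNP x population with columns `SNP`, `CHR`, `POS`, `A1`,
#' `A2`, `POP`, `FREQ`, `X`, `N`; [read_freq_table()] inverts it.
#'
#' @param freqs a [freq_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(freqs, path) {
  stopifnot(inherits(freqs, "freq_table"))
  M <- ncol(freqs$freq)
  long <- data.frame(
    SNP = rep(freqs$snps$id, M), CHR = rep(freqs$snps$chr, M),
    POS = rep(freqs$snps$pos, M), A1 = rep(freqs$snps$A1, M),
    A2 = rep(freqs$snps$A2, M), POP = rep(freqs$pops, each = nrow(freqs$freq)),
    FREQ = as.vector(freqs$freq),
    X = if (is.null(freqs$x)) NA_integer_ else as.vector(freqs$x),
    N = if (is.null(freqs$n)) NA_integer_ else rep(freqs$n, each = nrow(freqs$freq)),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(path, list(n_snps = nrow(freqs$freq), n_pops = M))
  invisible(path)
}

#' Read a long-format frequency table written by [write_freq_table()]
#' @param path file path.
#' @return a [freq_table()].
#' @export
read_freq_table <- function(path) {
  long <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  pops <- unique(long$POP)
  ids <- unique(long$SNP)
  snps <- long[match(ids, long$SNP), c("SNP", "CHR", "POS", "A1", "A2")]
  names(snps) <- c("id", "chr", "pos", "A1", "A2")
  shape <- function(col) {
    m <- matrix(NA_real_, length(ids), length(pops),
                dimnames = list(ids, pops))
    m[cbind(match(long$SNP, ids), match(long$POP, pops))] <- long[[col]]
    m
  }
  p <- shape("FREQ")
  x <- if (!all(is.na(long$X))) shape("X")
  n <- if (!all(is.na(long$N)))
    as.integer(long$N[match(pops, long$POP)])
  freq_table(p, snps, x = x, n = n)
}
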