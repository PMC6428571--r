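# End-to-end orchestration: simulate (or load) -> harmonize -> ascertain
# -> score -> drift tests -> tSDS -> diagnostics, driven by a YAML config
# with explicit seeds, writing TSV/JSON results plus a provenance log.

#' Run the full analysis pipeline from a configuration
#'
#' The configuration (a YAML file path or an equivalent nested list)
#' either describes a simulation (`simulate:` block with population
#' number, drift matrix, latitudes, GWAS noise/bias and SDS parameters)
#' or points at input files (`input:` block with summary-statistics and
#' frequency-table paths). Ascertainment (`ascertain:`) supports the
#' `"pthresh"` strategy (top SNPs by P value below a threshold; the
#' gw-sig regime is `p < 5e-8`, the sub-sig regime `p < 0.01`) and
#' `"block"` (lowest P per LD block, needs a `blocks` BED path). Results
#' are written under `out` when given: `scores.tsv(.json)`, `qx.json`,
#' `tsds.json`, `trend_bins.tsv` and `provenance.json`. Every stochastic
#' stage is seeded from the single top-level `seed`, so a rerun with the
#' same config is bit-identical.
#'
#' @param config YAML path or list.
#' @param seed overrides the config's seed when non-NULL.
#' @param out_dir overrides the config's output directory.
#' @return (invisibly) a list with the per-stage objects (`freqs`,
#'   `sumstats`, `ascertained`, `scores`, `qx`, `tsds_trend`, ...) and
#'   the provenance record.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  out_dir <- out_dir %||% cfg$out
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  prov <- list(package_version = as.character(utils::packageVersion("polystrat")),
               seed = seed, stages = list())
  note <- function(stage, ...) {
    prov$stages[[stage]] <<- list(...)
  }

  # --- inputs: simulate or load ------------------------------------------
  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    M <- s$M %||% 6L
    Fm <- diag(s$F_diag %||% 0.02, M) + (s$F_offdiag %||% 0)
    spec <- drift_spec(M = M, L = s$L %||% 1000L, F = Fm,
                       Y = s$latitudes %||% seq(40, 65, length.out = M),
                       n_hap = s$n_hap %||% 100L, seed = seed)
    freqs <- simulate_frequencies(spec)
    g <- s$gwas %||% list()
    gspec <- gwas_sim_spec(
      true_beta_law = function(L) stats::rnorm(L, 0, g$beta_sd %||% 0.02),
      se = g$se %||% 0.01, bias_coeff = g$bias_coeff %||% 0,
      bias_axis = g$bias_axis, seed = seed + 1L)
    sumstats <- simulate_gwas(freqs, gspec)
    sds <- NULL
    if (!is.null(s$sds)) {
      sds <- simulate_sds(freqs, cline_coeff = s$sds$cline_coeff %||% 0,
                          selection_coeff = s$sds$selection_coeff %||% 0,
                          selection_set = s$sds$selection_set %||% character(0),
                          noise_sd = s$sds$noise_sd %||% 1,
                          beta_true = attr(sumstats, "beta_true"),
                          seed = seed + 2L)
    }
    note("simulate", M = M, L = nrow(freqs$freq),
         bias_coeff = g$bias_coeff %||% 0)
  } else if (!is.null(cfg$input)) {
    sumstats <- read_sumstats(cfg$input$sumstats,
                              cfg$input$dialect %||% "canonical")
    freqs <- read_freq_table(cfg$input$freqs)
    sumstats <- harmonize(sumstats, freqs)
    sds <- if (!is.null(cfg$input$sds)) read_sds(cfg$input$sds)
    note("load", n_snps = nrow(sumstats),
         harmonize = attr(sumstats, "harmonize_log"))
  } else stop("config must contain exactly one frequency source ",
              "('simulate' or 'input' block)")

  # --- ascertainment ------------------------------------------------------
  asc <- cfg$ascertain %||% list(strategy = "pthresh", p = 1)
  ascertained <- switch(
    asc$strategy %||% "pthresh",
    pthresh = {
      hit <- sumstats$SNP[sumstats$P < (asc$p %||% 5e-8)]
      if (!is.null(asc$max_snps) && length(hit) > asc$max_snps) {
        ord <- order(sumstats$P[match(hit, sumstats$SNP)])
        hit <- hit[ord[seq_len(asc$max_snps)]]
      }
      hit
    },
    block = lowest_p_per_block(sumstats, read_ld_blocks(asc$blocks)),
    stop("unknown ascertainment strategy: ", asc$strategy))
  if (!length(ascertained)) stop("ascertainment stage returned no SNPs")
  note("ascertain", strategy = asc$strategy %||% "pthresh",
       n_ascertained = length(ascertained))

  # --- scores and drift tests --------------------------------------------
  ss_asc <- sumstats[match(ascertained, sumstats$SNP), , drop = FALSE]
  scores <- polygenic_scores(ss_asc, subset_freqs(freqs, ascertained))
  null_ids <- setdiff(freqs$snps$id, ascertained)
  f_hat <- if (length(null_ids) >= 100)
    estimate_F(subset_freqs(freqs, null_ids))
  else estimate_F(freqs)
  qx <- qx_test(scores, f_hat, Y = freqs$latitudes)
  note("qx", qx = qx$qx, p_qx = qx$p_qx, n_snps = scores$n_snps)

  # --- tSDS ---------------------------------------------------------------
  tsds_trend <- NULL
  if (!is.null(sds)) {
    aligned <- align_tsds(normalize_sds(sds), sumstats)
    tsds_trend <- trend(aligned$TSDS, aligned$P,
                        bin_size = cfg$tsds$bin_size %||% 1000L,
                        jackknife_blocks = cfg$tsds$jackknife_blocks %||% 100L)
    note("tsds", rho = tsds_trend$rho, p_jack = tsds_trend$p_jack,
         n_snps = tsds_trend$n_snps)
  }

  # --- outputs ------------------------------------------------------------
  if (!is.null(out_dir)) {
    write_scores(scores, file.path(out_dir, "scores.tsv"))
    jsonlite::write_json(
      list(qx = qx$qx, dof = qx$dof, p_qx = qx$p_qx,
           lat_stat = qx$lat_stat, p_lat = qx$p_lat),
      file.path(out_dir, "qx.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(tsds_trend)) {
      jsonlite::write_json(
        list(rho = tsds_trend$rho, se = tsds_trend$se,
             p_jack = tsds_trend$p_jack, slope = tsds_trend$slope,
             slope_p = tsds_trend$slope_p, n_snps = tsds_trend$n_snps),
        file.path(out_dir, "tsds.json"), auto_unbox = TRUE, digits = NA)
      utils::write.table(tsds_trend$bins,
                         file.path(out_dir, "trend_bins.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(freqs = freqs, sumstats = sumstats,
                 ascertained = ascertained, scores = scores, qx = qx,
                 tsds_trend = tsds_trend, provenance = prov,
                 out_dir = out_dir))
}
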