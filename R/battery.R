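#' End-to-end motif alpha pipeline for one motif
#'
#' Runs scan -> flank extension -> chromosome filter -> block-map lift ->
#' site classification -> MK table and alpha on a pair of genomes. This
#' is the unit the shuffled-motif null battery repeats per control motif.
#'
#' @param motif Motif string.
#' @param src_genome,dst_genome Source and destination genomes.
#' @param map [block_map()] from source to destination.
#' @param snps Polymorphism table for the source genome.
#' @param flank_bp Flank length (default 7).
#' @param maf_min MAF filter (default 0.05).
#' @param n_boot Bootstrap resamples for the CI (default 1000); 0 skips
#'   the bootstrap.
#' @param level CI level (default 0.99).
#' @param seed Integer seed.
#' @return List with `motif`, `n_instances`, `n_segments` (mapped),
#'   `table`, `records`, `segments`, `pairs` and `estimate` (an
#'   `alpha_estimate`, or `NULL` when alpha is undefined or `n_boot = 0`,
#'   in which case `alpha` alone is reported when defined).
#' @export
motif_alpha_pipeline <- function(motif, src_genome, dst_genome, map, snps,
                                 flank_bp = 7, maf_min = 0.05,
                                 n_boot = 1000, level = 0.99, seed = 1) {
  inst <- scan_motif(src_genome, motif)
  seg <- build_segments(inst, src_genome, flank_bp = flank_bp)
  seg <- filter_segments(seg, src_genome)$segments
  pairs <- lift_segments(seg, map, src_genome, dst_genome)
  records <- classify_segment_sites(pairs, snps, maf_min = maf_min,
                                    genome = src_genome)
  tab <- build_mk_table(records)
  est <- NULL
  a <- tryCatch(alpha_mk(tab), error = function(e) NA_real_)
  if (n_boot > 0 && !is.na(a) && length(unique(records$segment_id)) >= 2) {
    est <- tryCatch(
      bootstrap_alpha(records, n_boot = n_boot, level = level, seed = seed),
      error = function(e) NULL)
  }
  list(motif = motif, n_instances = length(inst),
       n_segments = sum(pairs$status == "mapped"),
       table = tab, alpha = a, estimate = est,
       records = records, segments = seg, pairs = pairs)
}

#' Shuffled-motif empirical null battery
#'
#' Pushes the focal motif and every two-position shuffling of it through
#' the identical scan -> segment -> lift -> classify -> alpha pipeline.
#' Selection specific to the focal motif should give it an alpha
#' exceeding every shuffled motif's alpha; raw and Bonferroni-adjusted
#' bootstrap p-values are reported across the battery.
#'
#' @inheritParams motif_alpha_pipeline
#' @param motifs Control motifs; default [shuffle_motifs()] of `motif`.
#' @return List with `summary` (data.frame: one row per motif with
#'   `motif`, `focal`, `n_instances`, `n_segments`, the four MK counts,
#'   `alpha`, `ci_low`, `ci_high`, `p_boot`, `p_boot_adj`, `p_g`,
#'   `p_fisher`) and `focal_exceeds_all` (logical). Motifs with no
#'   occurrences or undefined alpha appear as no-data rows.
#' @export
shuffle_null_battery <- function(motif, src_genome, dst_genome, map, snps,
                                 motifs = shuffle_motifs(motif),
                                 flank_bp = 7, maf_min = 0.05,
                                 n_boot = 1000, level = 0.99, seed = 1) {
  stopifnot(length(motifs) >= 1)
  all_motifs <- c(motif, motifs)
  rows <- lapply(seq_along(all_motifs), function(i) {
    m <- all_motifs[i]
    res <- motif_alpha_pipeline(m, src_genome, dst_genome, map, snps,
                                flank_bp = flank_bp, maf_min = maf_min,
                                n_boot = n_boot, level = level,
                                seed = substream_seed(seed, i))
    est <- res$estimate
    data.frame(
      motif = m, focal = i == 1L,
      n_instances = res$n_instances, n_segments = res$n_segments,
      D_core = res$table$D_core, D_flank = res$table$D_flank,
      P_core = res$table$P_core, P_flank = res$table$P_flank,
      alpha = res$alpha,
      ci_low = if (is.null(est)) NA_real_ else est$ci_low,
      ci_high = if (is.null(est)) NA_real_ else est$ci_high,
      p_boot = if (is.null(est)) NA_real_ else est$p_boot,
      p_g = if (is.null(est)) NA_real_ else est$p_g,
      p_fisher = if (is.null(est)) NA_real_ else est$p_fisher)
  })
  summary <- do.call(rbind, rows)
  summary$p_boot_adj <- pmin(1, summary$p_boot * length(motifs))
  shuf_alpha <- summary$alpha[!summary$focal]
  focal_alpha <- summary$alpha[summary$focal]
  list(summary = summary,
       focal_exceeds_all = !is.na(focal_alpha) &&
         all(is.na(shuf_alpha) | focal_alpha > shuf_alpha))
}
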