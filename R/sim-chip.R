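#' Simulate ChIP reads and peaks for one factor
#'
#' Background reads fall uniformly over the genome at
#' `chip_background_per_bp` per replicate; bound genes receive
#' `chip_enrichment`-fold expected signal within +/-350 bp of their TSS.
#' Each replicate also emits a narrowPeak-style peak at every bound TSS,
#' so the conservative (replicate-intersected) peak set recovers the
#' bound genes.
#'
#' @param gene_models Gene models ([simulate_annotation()]).
#' @param bound_ids Character vector of bound gene ids.
#' @param config A [sim_config()].
#' @param label Factor label for the sample metadata.
#' @param half_width TSS window half-width for the enrichment (350 bp).
#' @param seed Integer seed (defaults to the config's chip substream).
#' @return List with `reads` (named list of width-1 `GRanges`, one per
#'   replicate sample), `peaks` (named list of peak `GRanges` per
#'   replicate) and `samples` (data.frame `sample`, `factor`,
#'   `replicate`).
#' @export
simulate_chip <- function(gene_models, bound_ids, config,
                          label = "factor1", half_width = 350,
                          seed = substream_seed(config$seed, "chip")) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$chrom_specs
  si <- GenomeInfoDb::Seqinfo(seqnames = spec$name, seqlengths = spec$length)
  genes <- gene_models$genes
  g_tss <- tss(genes)
  bound <- S4Vectors::mcols(genes)$gene_id %in% bound_ids
  win_len <- 2 * half_width + 1
  with_seed(seed, {
    reads <- list()
    peaks <- list()
    for (r in seq_len(config$n_replicates)) {
      n_bg <- stats::rpois(1, config$chip_background_per_bp * sum(spec$length))
      chrom <- sample(spec$name, n_bg, replace = TRUE, prob = spec$length)
      pos <- vapply(spec$length[match(chrom, spec$name)],
                    function(L) sample.int(L, 1L), 1L)
      extra_chrom <- character(0); extra_pos <- integer(0)
      for (gi in which(bound)) {
        lam <- (config$chip_enrichment - 1) *
          config$chip_background_per_bp * win_len
        n_extra <- stats::rpois(1, max(lam, 0))
        if (n_extra > 0) {
          tpos <- BiocGenerics::start(g_tss)[gi]
          L <- spec$length[spec$name ==
                             as.character(GenomeInfoDb::seqnames(genes))[gi]]
          p <- sample(seq(max(1, tpos - half_width),
                          min(L, tpos + half_width)), n_extra,
                      replace = TRUE)
          extra_chrom <- c(extra_chrom,
                           rep(as.character(GenomeInfoDb::seqnames(genes))[gi],
                               n_extra))
          extra_pos <- c(extra_pos, p)
        }
      }
      id <- sprintf("%s_rep%d", label, r)
      reads[[id]] <- GenomicRanges::GRanges(
        c(chrom, extra_chrom),
        IRanges::IRanges(c(pos, extra_pos), width = 1L), seqinfo = si)
      if (any(bound)) {
        tpos <- BiocGenerics::start(g_tss)[bound]
        jitter <- sample(-10:10, sum(bound), replace = TRUE)
        lim <- spec$length[match(as.character(
          GenomeInfoDb::seqnames(genes))[bound], spec$name)]
        pk <- GenomicRanges::GRanges(
          GenomeInfoDb::seqnames(genes)[bound],
          IRanges::IRanges(pmax(1L, tpos + jitter - 150L),
                           pmin(lim, tpos + jitter + 150L)), seqinfo = si)
        S4Vectors::mcols(pk)$score <- round(stats::runif(sum(bound), 50, 1000))
        peaks[[id]] <- BiocGenerics::sort(pk)
      } else {
        peaks[[id]] <- GenomicRanges::GRanges(seqinfo = si)
      }
    }
    list(reads = reads, peaks = peaks,
         samples = data.frame(sample = names(reads), factor = label,
                              replicate = seq_len(config$n_replicates)))
  })
}

#' Simulate a multi-factor ChIP experiment
#'
#' Calls [simulate_chip()] once per factor with independent seed
#' substreams; factors differ in their bound gene sets (the "factor
#' effect" replicate clustering should recover).
#'
#' @param gene_models Gene models.
#' @param bound_sets Named list: factor label -> character vector of
#'   bound gene ids.
#' @param config A [sim_config()].
#' @param half_width TSS window half-width (350 bp).
#' @return As [simulate_chip()], concatenated across factors.
#' @export
simulate_chip_experiment <- function(gene_models, bound_sets, config,
                                     half_width = 350) {
  parts <- lapply(seq_along(bound_sets), function(i) {
    simulate_chip(gene_models, bound_sets[[i]], config,
                  label = names(bound_sets)[i], half_width = half_width,
                  seed = substream_seed(config$seed, 100L + i))
  })
  list(reads = do.call(c, lapply(parts, `[[`, "reads")),
       peaks = do.call(c, lapply(parts, `[[`, "peaks")),
       samples = do.call(rbind, lapply(parts, `[[`, "samples")))
}
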