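#' Run the full synthetic study end to end
#'
#' Orchestrates every stage in dependency order: simulate annotation and
#' genome with planted motifs; evolve divergence and polymorphism; scan
#' the motif; build, filter and lift flanked segments; classify sites and
#' estimate alpha with bootstrap CIs per stratum; optionally run the
#' shuffled-motif null battery; simulate and summarize a multi-factor
#' ChIP experiment; and run the Brownian-motion phylogenetic ANOVA on a
#' fixture tree. All stage outputs are written as plain-text files under
#' `outdir` together with a JSON manifest of parameters and file digests;
#' the same config and seed reproduce byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param n_boot Bootstrap resamples for alpha CIs.
#' @param run_battery Run the shuffled-motif battery (the slowest stage).
#' @param battery_boot Bootstrap resamples inside the battery.
#' @return Invisibly, a list with the in-memory results of every stage
#'   (`genome`, `truth`, `annotation`, `divergence`, `snps`,
#'   `instances`, `records`, `mk`, `battery`, `chip`, `phylo`,
#'   `manifest`).
#' @export
run_full <- function(config, outdir, n_boot = 1000, run_battery = FALSE,
                     battery_boot = 200) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ann <- stage("annotation", simulate_annotation(config))
  write_gene_models(ann, p("genes.gff3"))
  sim <- stage("genome", simulate_genome(config, annotation = ann))
  write_genome(sim$genome, p("genome_src.fa"))
  write_instances_bed(sim$truth, p("truth_motifs.bed"))
  div <- stage("divergence", simulate_divergence(sim$genome, sim$truth, config))
  write_genome(div$genome, p("genome_dst.fa"))
  write_block_map(div$block_map, p("blocks.tsv"))
  snps <- stage("polymorphism", simulate_polymorphism(sim$genome, sim$truth,
                                                      config))
  write_vcf(snps, p("snps.vcf"), genome = sim$genome)

  inst <- stage("scan", scan_motif(sim$genome, config$motif))
  write_instances_bed(inst, p("instances.bed"))
  freq <- genome_frequency(inst, sim$genome, id = "source")
  utils::write.table(freq, p("motif_frequency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  seg <- stage("segments", {
    s <- build_segments(inst, sim$genome)
    filter_segments(s, sim$genome)$segments
  })
  pairs <- stage("lift", lift_segments(seg, div$block_map, sim$genome,
                                       div$genome))
  records <- stage("classify", {
    r <- classify_segment_sites(pairs, snps, genome = sim$genome)
    add_exonic_stratum(r, seg, ann$exons)
  })
  write_site_records(records, p("site_records.tsv"))

  mk <- stage("mk", {
    strata <- c("all", "X", "autosome", "exonic", "intergenic")
    rows <- lapply(strata, function(st) {
      tab <- build_mk_table(records, stratum = st)
      est <- tryCatch({
        sub <- switch(st,
          all = records,
          X = records[records$chrom_class == "X", ],
          autosome = records[records$chrom_class == "autosome", ],
          exonic = records[records$stratum_exon == "exonic", ],
          intergenic = records[records$stratum_exon == "intergenic", ])
        bootstrap_alpha(sub, n_boot = n_boot, seed = config$seed)
      }, error = function(e) NULL)
      data.frame(
        stratum = st, n_segments = length(unique(
          records$segment_id[switch(st,
            all = TRUE,
            X = records$chrom_class == "X",
            autosome = records$chrom_class == "autosome",
            exonic = records$stratum_exon == "exonic",
            intergenic = records$stratum_exon == "intergenic")])),
        D_core = tab$D_core, D_flank = tab$D_flank,
        P_core = tab$P_core, P_flank = tab$P_flank,
        alpha = if (is.null(est)) NA_real_ else est$alpha,
        ci_low = if (is.null(est)) NA_real_ else est$ci_low,
        ci_high = if (is.null(est)) NA_real_ else est$ci_high,
        p_boot = if (is.null(est)) NA_real_ else est$p_boot,
        p_g = if (is.null(est)) NA_real_ else est$p_g,
        p_fisher = if (is.null(est)) NA_real_ else est$p_fisher)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
  utils::write.table(mk, p("mk_summary.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  battery <- NULL
  if (run_battery) {
    battery <- stage("shuffle_null", shuffle_null_battery(
      config$motif, sim$genome, div$genome, div$block_map, snps,
      n_boot = battery_boot, seed = config$seed))
    utils::write.table(battery$summary, p("shuffle_battery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  chip <- stage("chip", {
    gid <- S4Vectors::mcols(ann$genes)$gene_id
    n_bound <- max(1L, floor(length(gid) / 5))
    bound_sets <- with_seed(substream_seed(config$seed, "chip"), list(
      Dmel_Zeus = sample(gid, n_bound),
      Dsim_Zeus = sample(gid, n_bound),
      Dyak_Caf40 = sample(gid, n_bound)))
    ex <- simulate_chip_experiment(ann, bound_sets, config)
    m <- normalize_signal(tss_window_counts(ex$reads, ann,
                                            samples = ex$samples))
    pca <- pca_cluster_check(m)
    enr <- chromosome_enrichment(m, ann, sim$genome, n_perm = 1000,
                                 seed = config$seed)
    cons <- intersect_replicate_peaks(ex$peaks[["Dmel_Zeus_rep1"]],
                                      ex$peaks[["Dmel_Zeus_rep2"]])
    utils::write.table(
      data.frame(gene_id = rownames(m), m, check.names = FALSE),
      p("signal_matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_narrowpeak(cons, p("conservative_peaks.narrowPeak"))
    utils::write.table(enr$tests, p("chrom_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(matrix = m, pca = pca, enrichment = enr,
         conservative_peaks = cons,
         bound = bound_genes(cons, ann), bound_sets = bound_sets)
  })

  phylo <- stage("phylo", {
    fx <- fixture_tree()
    traits <- simulate_bm_traits(fx$tree, sigma2 = 1, group_effect = -2,
                                 group_tips = names(fx$groups)[
                                   fx$groups == "with_Zeus"],
                                 seed = substream_seed(config$seed, "traits"))
    res <- phyl_anova(fx$tree, traits, fx$groups, n_sim = 1000,
                      seed = config$seed)
    utils::write.table(
      data.frame(f_obs = res$f_obs, p_phylo = res$p_phylo,
                 sigma2_hat = res$sigma2_hat),
      p("phylo_anova.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  files <- list.files(outdir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "motifmk",
    version = as.character(utils::packageVersion("motifmk")),
    seed = config$seed,
    motif = config$motif,
    n_motifs = config$n_motifs,
    rates = list(mu_flank = config$mu_flank, mu_core = config$mu_core,
                 theta_flank = config$theta_flank,
                 theta_core = config$theta_core),
    digests = as.list(tools::md5sum(files)))
  names(manifest$digests) <- basename(files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(genome = sim$genome, truth = sim$truth, annotation = ann,
                 divergence = div, snps = snps, instances = inst,
                 records = records, mk = mk, battery = battery,
                 chip = chip, phylo = phylo, manifest = manifest))
}
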