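#' Simulation configuration for the synthetic study
#'
#' Bundles every parameter of the synthetic-data generators: chromosome
#' layout, GC content, number and placement of planted motifs, per-site
#' substitution probabilities at motif cores versus elsewhere (the
#' divergence regime), per-site polymorphism probabilities and the minor
#' allele frequency spectrum (the polymorphism regime), gene-model and
#' ChIP-signal settings.
#'
#' The default rates encode an adaptive regime: substitutions are enriched
#' and polymorphism depleted at motif cores relative to flanking sequence,
#' with an analytic adaptive fraction
#' `alpha* = 1 - (mu_flank * theta_core) / (mu_core * theta_flank) = 0.75`.
#' Setting the core rates equal to the flank rates gives the neutral
#' regime.
#'
#' @param seed Integer master seed; fans out to per-generator substreams.
#' @param chrom_specs data.frame with columns `name`, `length` (bp) and
#'   `class` (`"X"`, `"autosome"`, `"dot"` or `"unassembled"`).
#' @param gc_content GC fraction of the background sequence.
#' @param n_motifs Number of motif copies to plant.
#' @param motif Core motif string (default `ACTGCTT`).
#' @param exon_proximity_bias Fraction of planted motifs forced within
#'   1 kb of an exon (requires an annotation at planting time).
#' @param chrom_weights Optional per-chromosome placement weights (named);
#'   default proportional to length.
#' @param mu_flank,mu_core Per-site substitution probabilities for the
#'   divergence simulator (flank = everywhere outside planted cores).
#' @param theta_flank,theta_core Per-site polymorphism probabilities.
#' @param maf_spectrum Minor-allele-frequency spectrum: either a function
#'   `n -> numeric` or a numeric vector sampled with replacement; values in
#'   (0, 0.5]. Default: folded neutral (1/i) spectrum for a 205-line panel.
#' @param indel_fraction Fraction of simulated variants emitted as 2-bp
#'   indels (for sensitivity runs; default 0).
#' @param n_genes Number of gene models.
#' @param gene_length_range Min/max gene span in bp.
#' @param exons_per_gene Max exons per gene (1 to this many).
#' @param chip_enrichment Fold ChIP signal at bound TSSs.
#' @param chip_background_per_bp Expected background reads per bp per
#'   replicate.
#' @param n_replicates ChIP replicates per factor.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_specs = data.frame(
                         name = c("chrX", "chr2", "chr3", "chr4", "chrU"),
                         length = c(60000L, 80000L, 80000L, 10000L, 10000L),
                         class = c("X", "autosome", "autosome", "dot",
                                   "unassembled")),
                       gc_content = 0.42,
                       n_motifs = 500,
                       motif = "ACTGCTT",
                       exon_proximity_bias = 0,
                       chrom_weights = NULL,
                       mu_flank = 0.05, mu_core = 0.10,
                       theta_flank = 0.08, theta_core = 0.04,
                       maf_spectrum = maf_spectrum_neutral(205),
                       indel_fraction = 0,
                       n_genes = 100,
                       gene_length_range = c(500L, 3000L),
                       exons_per_gene = 3L,
                       chip_enrichment = 5,
                       chip_background_per_bp = 0.02,
                       n_replicates = 4L) {
  stopifnot(
    is.data.frame(chrom_specs),
    all(c("name", "length", "class") %in% names(chrom_specs)),
    all(chrom_specs$length > 0),
    !anyDuplicated(chrom_specs$name),
    is_probability(gc_content),
    is_probability(c(mu_flank, mu_core, theta_flank, theta_core,
                     exon_proximity_bias, indel_fraction)),
    n_motifs >= 0, n_genes >= 0, chip_enrichment >= 0,
    n_replicates >= 1
  )
  assert_motif(motif)
  bad <- setdiff(chrom_specs$class, c("X", "autosome", "dot", "unassembled"))
  if (length(bad)) stop("unknown chromosome class: ", bad, call. = FALSE)
  if (is.null(chrom_weights)) {
    chrom_weights <- stats::setNames(chrom_specs$length / sum(chrom_specs$length),
                                     chrom_specs$name)
  }
  structure(list(
    seed = as.integer(seed), chrom_specs = chrom_specs,
    gc_content = gc_content, n_motifs = as.integer(n_motifs), motif = motif,
    exon_proximity_bias = exon_proximity_bias, chrom_weights = chrom_weights,
    mu_flank = mu_flank, mu_core = mu_core,
    theta_flank = theta_flank, theta_core = theta_core,
    maf_spectrum = maf_spectrum, indel_fraction = indel_fraction,
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    exons_per_gene = as.integer(exons_per_gene),
    chip_enrichment = chip_enrichment,
    chip_background_per_bp = chip_background_per_bp,
    n_replicates = as.integer(n_replicates)
  ), class = "sim_config")
}

#' Folded neutral allele-frequency spectrum
#'
#' Returns a sampler for minor allele frequencies under the standard
#' neutral site-frequency spectrum (probability of derived count i
#' proportional to 1/i) folded to (0, 0.5] for a panel of `n_lines`
#' chromosomes.
#'
#' @param n_lines Number of sampled chromosomes in the panel.
#' @return A function `n -> numeric` drawing `n` MAF values.
#' @export
maf_spectrum_neutral <- function(n_lines = 205) {
  i <- seq_len(floor(n_lines / 2))
  w <- 1 / i + ifelse(n_lines - i != i, 1 / (n_lines - i), 0)
  maf <- i / n_lines
  function(n) sample(maf, n, replace = TRUE, prob = w)
}

draw_maf <- function(spectrum, n) {
  out <- if (is.function(spectrum)) spectrum(n)
         else sample(spectrum, n, replace = TRUE)
  if (n > 0 && (!is.numeric(out) || any(out <= 0 | out > 0.5))) {
    stop("maf_spectrum must yield values in (0, 0.5]", call. = FALSE)
  }
  out
}
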