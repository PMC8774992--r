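test_that("simulators are deterministic given a seed", {
  cfg <- sim_config(seed = 11, n_motifs = 40, n_genes = 20)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(BiocGenerics::start(a$truth), BiocGenerics::start(b$truth))
  expect_identical(simulate_polymorphism(a$genome, a$truth, cfg),
                   simulate_polymorphism(b$genome, b$truth, cfg))
  da <- simulate_divergence(a$genome, a$truth, cfg)
  db <- simulate_divergence(b$genome, b$truth, cfg)
  expect_identical(as.character(da$genome), as.character(db$genome))
})

test_that("motif planting honors counts, overlap and truth soundness", {
  cfg0 <- sim_config(seed = 2, n_motifs = 0,
                     chrom_specs = data.frame(name = "chr1", length = 1000L,
                                              class = "autosome"),
                     n_genes = 0)
  expect_length(simulate_genome(cfg0)$truth, 0)

  cfg <- sim_config(seed = 5, n_motifs = 50,
                    chrom_specs = data.frame(name = "chr1", length = 100000L,
                                             class = "autosome"),
                    n_genes = 0)
  sim <- simulate_genome(cfg)
  expect_length(sim$truth, 50)
  # planted copies never overlap
  expect_false(any(GenomicRanges::countOverlaps(sim$truth,
                                                ignore.strand = TRUE) > 1))
  # every planted copy is recovered by the scan (truth subset of scan)
  hits <- scan_motif(sim$genome, cfg$motif)
  ov <- GenomicRanges::findOverlaps(sim$truth, hits, type = "equal",
                                    ignore.strand = TRUE)
  expect_length(unique(S4Vectors::queryHits(ov)), 50)
  expect_gte(length(hits), 50)
})

test_that("planting rejects infeasible configurations", {
  tiny <- sim_config(seed = 1, chrom_specs = data.frame(
    name = "chr1", length = 5L, class = "autosome"), n_motifs = 1,
    n_genes = 0)
  expect_error(simulate_genome(tiny), "shortest chromosome")
  packed <- sim_config(seed = 1, chrom_specs = data.frame(
    name = "chr1", length = 100L, class = "autosome"), n_motifs = 50,
    n_genes = 0)
  expect_error(simulate_genome(packed), "infeasible")
})

test_that("exon-proximity bias forces placement near exons", {
  cfg <- sim_config(seed = 8, n_motifs = 60, n_genes = 30,
                    exon_proximity_bias = 1)
  ann <- simulate_annotation(cfg)
  sim <- simulate_genome(cfg, annotation = ann)
  expect_equal(exon_proximity_fraction(sim$truth, ann$exons), 1)
})

test_that("divergence rates follow binomial expectations", {
  cfg <- sim_config(seed = 13,
                    chrom_specs = data.frame(name = "chr1",
                                             length = 1000000L,
                                             class = "autosome"),
                    n_motifs = 0, n_genes = 0,
                    mu_flank = 0.01, mu_core = 0.1)
  sim <- simulate_genome(cfg)
  # zero rates leave the genome untouched
  cfg0 <- sim_config(seed = 13, chrom_specs = cfg$chrom_specs,
                     n_motifs = 0, n_genes = 0, mu_flank = 0, mu_core = 0)
  d0 <- simulate_divergence(sim$genome, sim$truth, cfg0)
  expect_identical(as.character(d0$genome), as.character(sim$genome))
  expect_equal(nrow(d0$log), 0)
  # 1e6 flank sites at mu 0.01: count within 3 binomial SDs of 1e4
  d <- simulate_divergence(sim$genome, sim$truth, cfg)
  expect_lt(abs(nrow(d$log) - 1e4), 3 * sqrt(1e6 * 0.01 * 0.99))
  expect_true(all(d$log$class == "flank"))
  # logged substitutions are exactly the changed sites
  expect_equal(sum(strsplit(as.character(sim$genome[[1]]), "")[[1]] !=
                     strsplit(as.character(d$genome[[1]]), "")[[1]]),
               nrow(d$log))
})

test_that("polymorphism rates and the MAF spectrum behave", {
  spec1 <- data.frame(name = "chr1", length = 100000L, class = "autosome")
  cfg <- sim_config(seed = 21, chrom_specs = spec1, n_motifs = 0,
                    n_genes = 0, theta_flank = 0.01, theta_core = 0)
  sim <- simulate_genome(cfg)
  snps <- simulate_polymorphism(sim$genome, sim$truth, cfg)
  expect_lt(abs(nrow(snps) - 1000), 3 * sqrt(1e5 * 0.01 * 0.99))
  expect_true(all(snps$maf > 0 & snps$maf <= 0.5))
  # theta = 0 everywhere gives an empty set
  cfg0 <- sim_config(seed = 21, chrom_specs = spec1, n_motifs = 0,
                     n_genes = 0, theta_flank = 0, theta_core = 0)
  expect_equal(nrow(simulate_polymorphism(sim$genome, sim$truth, cfg0)), 0)
  # point mass below the 5% MAF filter: nothing survives
  cfg_low <- sim_config(seed = 21, chrom_specs = spec1, n_motifs = 0,
                        n_genes = 0, theta_flank = 0.01, theta_core = 0,
                        maf_spectrum = 0.02)
  low <- simulate_polymorphism(sim$genome, sim$truth, cfg_low)
  expect_gt(nrow(low), 0)
  expect_equal(nrow(filter_snps(low, maf_min = 0.05)), 0)
})

test_that("annotation round-trips through GFF3 and respects strand", {
  cfg <- sim_config(seed = 31, n_genes = 25)
  ann <- simulate_annotation(cfg)
  expect_length(ann$genes, 25)
  # non-overlapping genes, every gene has >= 1 exon
  expect_false(any(GenomicRanges::countOverlaps(ann$genes,
                                                ignore.strand = TRUE) > 1))
  expect_setequal(unique(S4Vectors::mcols(ann$exons)$gene_id),
                  S4Vectors::mcols(ann$genes)$gene_id)
  # TSS is the 5' end: start for +, end for -
  t0 <- tss(ann$genes)
  plus <- as.character(BiocGenerics::strand(ann$genes)) == "+"
  expect_equal(BiocGenerics::start(t0)[plus],
               BiocGenerics::start(ann$genes)[plus])
  expect_equal(BiocGenerics::start(t0)[!plus],
               BiocGenerics::end(ann$genes)[!plus])
  path <- tempfile(fileext = ".gff3")
  write_gene_models(ann, path)
  back <- read_gene_models(path)
  expect_equal(BiocGenerics::start(back$genes), BiocGenerics::start(ann$genes))
  expect_equal(BiocGenerics::end(back$exons), BiocGenerics::end(ann$exons))
  expect_equal(S4Vectors::mcols(back$genes)$gene_id,
               S4Vectors::mcols(ann$genes)$gene_id)
  # empty annotation gives an empty GFF3 body
  cfg0 <- sim_config(seed = 31, n_genes = 0)
  ann0 <- simulate_annotation(cfg0)
  expect_length(ann0$genes, 0)
})

test_that("ChIP simulation enriches bound TSS windows", {
  cfg <- sim_config(seed = 41, n_genes = 60, chip_enrichment = 10,
                    n_replicates = 2)
  ann <- simulate_annotation(cfg)
  gid <- S4Vectors::mcols(ann$genes)$gene_id
  set.seed(1)
  bound <- sample(gid, 6)
  ex <- simulate_chip(ann, bound, cfg, label = "f")
  m <- normalize_signal(tss_window_counts(ex$reads, ann,
                                          samples = ex$samples))
  avg <- rowMeans(m)
  # bound genes rank in the top decile of normalized signal
  expect_true(all(rank(-avg)[bound] <= ceiling(length(gid) / 10)))
  # peaks emitted at bound TSSs in every replicate
  cons <- intersect_replicate_peaks(ex$peaks[[1]], ex$peaks[[2]])
  expect_setequal(bound_genes(cons, ann), bound)
  # zero-read genome gives an all-zero matrix
  empty <- lapply(ex$reads, function(r) r[0])
  m0 <- tss_window_counts(empty, ann, samples = ex$samples)
  expect_true(all(m0 == 0))
})

test_that("Brownian traits follow the closed-form increment variance", {
  two <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(unname(simulate_bm_traits(two, sigma2 = 0, seed = 1)),
               c(0, 0))
  d <- vapply(1:4000, function(i) {
    x <- simulate_bm_traits(two, sigma2 = 1, seed = i)
    x[["a"]] - x[["b"]]
  }, numeric(1))
  # difference of two independent BM tips has variance 2 * sigma2
  expect_lt(abs(var(d) - 2), 4 * sqrt(2 / 4000) * 2)
  # group effect shifts only the designated tips
  x <- simulate_bm_traits(two, sigma2 = 0, group_effect = 3,
                          group_tips = "a", seed = 1)
  expect_equal(unname(x), c(3, 0))
})
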