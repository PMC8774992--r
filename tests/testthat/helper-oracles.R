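# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately avoid the package's own code paths.

# naive sliding-window motif scan: checks every position on both strands
oracle_scan <- function(seqs, motif) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  m <- nchar(motif)
  rows <- list()
  for (chrom in names(seqs)) {
    s <- as.character(seqs[[chrom]])
    L <- nchar(s)
    if (L < m) next
    for (i in seq_len(L - m + 1)) {
      w <- substr(s, i, i + m - 1)
      if (w == motif) {
        rows[[length(rows) + 1]] <- data.frame(chrom = chrom, start = i,
                                               strand = "+")
      }
      if (w == rc) {
        rows[[length(rows) + 1]] <- data.frame(chrom = chrom, start = i,
                                               strand = "-")
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# brute-force read-in-window counter (double loop)
oracle_window_counts <- function(read_pos, tss_pos, half_width, chrom_len) {
  vapply(tss_pos, function(t) {
    lo <- max(1, t - half_width)
    hi <- min(chrom_len, t + half_width)
    sum(read_pos >= lo & read_pos <= hi)
  }, numeric(1))
}

random_genome <- function(len, seed, gc = 0.5,
                          classes = "autosome", n_chrom = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = ""), "")
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  genome_sequence(seqs, classes)
}

# site records for hand-built segments: seg_counts is a matrix with
# columns D_core, D_flank, P_core, P_flank (one row per segment)
records_from_counts <- function(seg_counts, flank_bp = 7, core_len = 7) {
  len <- core_len + 2 * flank_bp
  rows <- lapply(seq_len(nrow(seg_counts)), function(i) {
    cls <- rep("flank", len)
    cls[(flank_bp + 1):(flank_bp + core_len)] <- "core"
    fixed <- integer(len)
    poly <- integer(len)
    core_idx <- which(cls == "core")
    flank_idx <- which(cls == "flank")
    fixed[core_idx[seq_len(seg_counts[i, "D_core"])]] <- 1L
    fixed[flank_idx[seq_len(seg_counts[i, "D_flank"])]] <- 1L
    free_core <- setdiff(core_idx, which(fixed == 1L))
    free_flank <- setdiff(flank_idx, which(fixed == 1L))
    poly[free_core[seq_len(seg_counts[i, "P_core"])]] <- 1L
    poly[free_flank[seq_len(seg_counts[i, "P_flank"])]] <- 1L
    data.frame(segment_id = sprintf("hseg%04d", i), chrom = "chr1",
               pos = seq_len(len), class = cls,
               fixed_diff = fixed, polymorphic = poly)
  })
  do.call(rbind, rows)
}

counts_tab <- function(D_core, D_flank, P_core, P_flank) {
  structure(list(D_core = D_core, D_flank = D_flank, P_core = P_core,
                 P_flank = P_flank, stratum = "all"), class = "mk_table")
}

# binomial generative null/alternative at the table level: per-segment
# counts drawn independently at the given per-site rates
simulate_segment_counts <- function(n_seg, mu_core, mu_flank,
                                    theta_core, theta_flank,
                                    core_len = 7, flank_len = 14) {
  d_c <- rbinom(n_seg, core_len, mu_core)
  d_f <- rbinom(n_seg, flank_len, mu_flank)
  p_c <- rbinom(n_seg, core_len, theta_core)
  p_f <- rbinom(n_seg, flank_len, theta_flank)
  cbind(D_core = d_c, D_flank = d_f, P_core = p_c, P_flank = p_f)
}

# minimal adaptive/neutral genome pipeline fixture shared by tests
mk_pipeline_fixture <- function(seed, n_motifs = 300, chrom_len = 60000L,
                                mu_core = 0.10, mu_flank = 0.05,
                                theta_core = 0.04, theta_flank = 0.08) {
  cfg <- sim_config(
    seed = seed,
    chrom_specs = data.frame(name = "chr2", length = chrom_len,
                             class = "autosome"),
    n_motifs = n_motifs, n_genes = 0,
    mu_core = mu_core, mu_flank = mu_flank,
    theta_core = theta_core, theta_flank = theta_flank)
  sim <- simulate_genome(cfg)
  div <- simulate_divergence(sim$genome, sim$truth, cfg)
  snps <- simulate_polymorphism(sim$genome, sim$truth, cfg)
  inst <- scan_motif(sim$genome, cfg$motif)
  seg <- filter_segments(build_segments(inst, sim$genome), sim$genome)$segments
  pairs <- lift_segments(seg, div$block_map, sim$genome, div$genome)
  records <- classify_segment_sites(pairs, snps, genome = sim$genome)
  list(config = cfg, sim = sim, div = div, snps = snps, inst = inst,
       seg = seg, pairs = pairs, records = records)
}
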