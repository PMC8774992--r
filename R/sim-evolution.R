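# logical mask of core (planted-motif) positions per chromosome
core_masks <- function(genome, truth) {
  masks <- lapply(BiocGenerics::width(genome), logical)
  names(masks) <- names(genome)
  if (length(truth)) {
    ch <- as.character(GenomeInfoDb::seqnames(truth))
    for (i in seq_along(truth)) {
      masks[[ch[i]]][BiocGenerics::start(truth)[i]:BiocGenerics::end(truth)[i]] <- TRUE
    }
  }
  masks
}

mutate_base <- function(base) {
  # draw a uniformly random different base
  idx <- match(base, BASES)
  BASES[((idx - 1L + sample.int(3L, length(base), replace = TRUE)) %% 4L) + 1L]
}

#' Simulate divergence between two genomes
#'
#' Every site mutates independently: core sites of planted motifs with
#' probability `mu_core`, all other sites with probability `mu_flank`.
#' The returned block map is the identity lift (one full-length block per
#' chromosome at identity 1), so coordinate mapping between the two
#' genomes is exact; `block_shuffle` fragments the blocks and assigns
#' random identities to exercise mapping failures.
#'
#' @param genome Ancestral genome ([genome_sequence()]).
#' @param truth Planted-motif `GRanges` from [simulate_genome()].
#' @param config A [sim_config()].
#' @param block_shuffle If `TRUE`, fragment blocks into ~2 kb pieces with
#'   identities drawn from U(0.85, 1) and drop 10% of pieces.
#' @return List with `genome` (diverged), `block_map` (see [block_map()])
#'   and `log`, a data.frame of substitutions (`chrom`, `pos`, `ref`,
#'   `alt`, `class`).
#' @export
simulate_divergence <- function(genome, truth, config, block_shuffle = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  masks <- core_masks(genome, truth)
  with_seed(substream_seed(config$seed, "divergence"), {
    logs <- list()
    out <- as.character(genome)
    for (chrom in names(genome)) {
      chars <- strsplit(out[[chrom]], "")[[1]]
      p <- rep(config$mu_flank, length(chars))
      p[masks[[chrom]]] <- config$mu_core
      hit <- stats::runif(length(chars)) < p
      if (any(hit)) {
        ref <- chars[hit]
        alt <- mutate_base(ref)
        chars[hit] <- alt
        logs[[chrom]] <- data.frame(
          chrom = chrom, pos = which(hit), ref = ref, alt = alt,
          class = ifelse(masks[[chrom]][hit], "core", "flank"))
      }
      out[[chrom]] <- paste(chars, collapse = "")
    }
    diverged <- genome_sequence(Biostrings::DNAStringSet(out),
                                chrom_classes(genome))
    bm <- identity_block_map(genome)
    if (block_shuffle) bm <- shuffle_blocks(bm)
    log <- if (length(logs)) do.call(rbind, logs) else
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), class = character(0))
    rownames(log) <- NULL
    list(genome = diverged, block_map = bm, log = log)
  })
}

shuffle_blocks <- function(bm, piece = 2000L, drop = 0.1,
                           id_range = c(0.85, 1)) {
  pieces <- list()
  for (i in seq_len(nrow(bm$blocks))) {
    b <- bm$blocks[i, ]
    starts <- seq(b$src_start, b$src_end, by = piece)
    ends <- pmin(starts + piece - 1L, b$src_end)
    off <- starts - b$src_start
    pieces[[i]] <- data.frame(
      src_chrom = b$src_chrom, src_start = starts, src_end = ends,
      dst_chrom = b$dst_chrom, dst_start = b$dst_start + off,
      dst_end = b$dst_start + off + (ends - starts),
      dst_strand = "+",
      identity = stats::runif(length(starts), id_range[1], id_range[2]))
  }
  blocks <- do.call(rbind, pieces)
  keep <- stats::runif(nrow(blocks)) >= drop
  block_map(blocks[keep, , drop = FALSE], min_match = bm$min_match)
}

#' Simulate segregating polymorphism
#'
#' Biallelic SNPs are placed independently per site: motif core sites with
#' probability `theta_core`, all other sites with probability
#' `theta_flank`. Each SNP's minor allele frequency is drawn from the
#' configured spectrum. With `indel_fraction > 0` that fraction of
#' variants is emitted as 2-bp deletions for filter-sensitivity runs.
#'
#' @inheritParams simulate_divergence
#' @return data.frame with `chrom`, `pos` (1-based), `ref`, `alt`, `maf`,
#'   `type` (`"snp"` or `"indel"`); write with [write_vcf()].
#' @export
simulate_polymorphism <- function(genome, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  masks <- core_masks(genome, truth)
  with_seed(substream_seed(config$seed, "polymorphism"), {
    rows <- list()
    for (chrom in names(genome)) {
      chars <- strsplit(as.character(genome[[chrom]]), "")[[1]]
      p <- rep(config$theta_flank, length(chars))
      p[masks[[chrom]]] <- config$theta_core
      hit <- which(stats::runif(length(chars)) < p)
      if (!length(hit)) next
      ref <- chars[hit]
      alt <- mutate_base(ref)
      type <- ifelse(stats::runif(length(hit)) < config$indel_fraction,
                     "indel", "snp")
      # represent indels as a 2-bp deletion anchored at the site
      del <- type == "indel" & hit < length(chars)
      ref[del] <- paste0(ref[del], chars[hit[del] + 1L])
      rows[[chrom]] <- data.frame(
        chrom = chrom, pos = hit, ref = ref, alt = alt,
        maf = draw_maf(config$maf_spectrum, length(hit)), type = type)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), maf = numeric(0), type = character(0))
    rownames(out) <- NULL
    out
  })
}
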