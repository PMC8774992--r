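#' Scan a genome for all occurrences of a core motif
#'
#' Finds every exact occurrence of `motif` on the forward strand and every
#' occurrence of its reverse complement (reported on the minus strand).
#' Overlapping matches are all reported; positions containing `N` never
#' match. A palindromic motif would be reported once per strand at the same
#' interval.
#'
#' @param genome A genome ([genome_sequence()]).
#' @param motif Single DNA string over `{A,C,G,T}`, length >= 1.
#' @return A [GenomicRanges::GRanges] sorted by (chrom, start, strand) with
#'   metadata column `match` holding the genomic-strand bases (equal to
#'   `motif` on `+`, to `revcomp(motif)` on `-`).
#' @examples
#' g <- genome_sequence(c(chr1 = "ACTGCTTAAGCAGT"))
#' scan_motif(g, "ACTGCTT")
#' @export
scan_motif <- function(genome, motif) {
  assert_motif(motif)
  rc <- revcomp(motif)
  hit_gr <- function(pattern, strand) {
    m <- Biostrings::vmatchPattern(pattern, genome, fixed = TRUE)
    r <- unlist(m, use.names = FALSE)
    gr <- GenomicRanges::GRanges(
      seqnames = rep(names(genome), S4Vectors::elementNROWS(m)),
      ranges = r,
      strand = rep(strand, length(r)),
      seqinfo = genome_seqinfo(genome))
    S4Vectors::mcols(gr)$match <- rep(pattern, length(gr))
    gr
  }
  out <- c(hit_gr(motif, "+"), hit_gr(rc, "-"))
  o <- order(as.integer(GenomeInfoDb::seqnames(out)),
             BiocGenerics::start(out),
             as.integer(BiocGenerics::strand(out)))
  out[o]
}

#' Genome-wide motif frequency, raw and per megabase
#'
#' @param instances Result of [scan_motif()].
#' @param genome The genome scanned.
#' @param id Genome/species identifier for the output row.
#' @return A data.frame with one row per chromosome class plus an `"all"`
#'   row: columns `id`, `class`, `count`, `genome_bp`, `density_per_mb`.
#' @export
genome_frequency <- function(instances, genome, id = "genome") {
  if (sum(BiocGenerics::width(genome)) == 0L) {
    stop("zero-length genome", call. = FALSE)
  }
  cls <- chrom_classes(genome)
  inst_cls <- cls[as.character(GenomeInfoDb::seqnames(instances))]
  per <- function(which_cls) {
    keep_chrom <- names(cls)[cls %in% which_cls]
    bp <- sum(as.numeric(BiocGenerics::width(genome)[names(genome) %in% keep_chrom]))
    n <- if (length(instances)) sum(inst_cls %in% which_cls) else 0L
    data.frame(id = id, class = paste(which_cls, collapse = "+"),
               count = n, genome_bp = bp,
               density_per_mb = if (bp > 0) n / (bp / 1e6) else 0)
  }
  rows <- lapply(unique(cls), per)
  all_row <- data.frame(id = id, class = "all", count = length(instances),
                        genome_bp = sum(as.numeric(BiocGenerics::width(genome))),
                        density_per_mb = length(instances) /
                          (sum(as.numeric(BiocGenerics::width(genome))) / 1e6))
  rbind(all_row, do.call(rbind, rows))
}

#' All two-position shufflings of a motif
#'
#' Enumerates every unordered position pair of `motif`, swaps the two
#' letters, and returns the distinct resulting strings. The original motif
#' is excluded, as is its reverse complement if a swap happens to produce
#' it (it would match the same genomic sites). Every member is a
#' permutation of the motif's letters. For `ACTGCTT` this yields 17
#' distinct control motifs.
#'
#' @param motif DNA string, length >= 2.
#' @return Character vector of distinct shuffled motifs.
#' @export
shuffle_motifs <- function(motif) {
  assert_motif(motif)
  n <- nchar(motif)
  if (n < 2L) stop("motif must have length >= 2", call. = FALSE)
  chars <- strsplit(motif, "")[[1]]
  out <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      sw <- chars
      sw[c(i, j)] <- sw[c(j, i)]
      out <- c(out, paste(sw, collapse = ""))
    }
  }
  out <- unique(out)
  setdiff(out, c(motif, revcomp(motif)))
}

#' Count motif instances in strand-aware promoter windows
#'
#' The promoter is the `upstream_bp` window immediately upstream of each
#' gene's TSS (strand-aware; truncated at chromosome edges). An instance is
#' counted, regardless of its own strand, when its interval lies fully
#' within the window.
#'
#' @param gene_models `GRanges` of genes with strand and a `gene_id`
#'   metadata column (as from [simulate_annotation()] or [read_gene_models()]).
#' @param instances Result of [scan_motif()].
#' @param upstream_bp Window size upstream of the TSS (default 500).
#' @return Integer vector of counts named by `gene_id`.
#' @export
promoter_motif_count <- function(gene_models, instances, upstream_bp = 500) {
  stopifnot(upstream_bp > 0)
  sl <- GenomeInfoDb::seqlengths(gene_models)
  chrom <- as.character(GenomeInfoDb::seqnames(gene_models))
  off <- !is.na(sl[chrom]) &
    (BiocGenerics::end(gene_models) > sl[chrom] |
       BiocGenerics::start(gene_models) < 1L)
  if (any(off)) {
    warning(sum(off), " gene(s) extend off their chromosome; dropped")
    gene_models <- gene_models[!off]
    chrom <- chrom[!off]
  }
  plus <- as.character(BiocGenerics::strand(gene_models)) != "-"
  tss <- ifelse(plus, BiocGenerics::start(gene_models),
                BiocGenerics::end(gene_models))
  win_start <- ifelse(plus, tss - upstream_bp, tss + 1L)
  win_end <- ifelse(plus, tss - 1L, tss + upstream_bp)
  win_start <- pmax(win_start, 1L)
  if (length(sl)) {
    lim <- sl[chrom]
    win_end <- ifelse(is.na(lim), win_end, pmin(win_end, lim))
  }
  ok <- win_end >= win_start
  wins <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    pmin(win_start, win_end), pmax(win_end, win_start)))
  counts <- integer(length(gene_models))
  hits <- GenomicRanges::findOverlaps(instances, wins[ok],
                                      type = "within", ignore.strand = TRUE)
  tab <- tabulate(S4Vectors::subjectHits(hits), nbins = sum(ok))
  counts[ok] <- tab
  stats::setNames(counts, S4Vectors::mcols(gene_models)$gene_id)
}

#' Fraction of motif instances within a distance of any exon
#'
#' Distance is the gap between intervals (0 for overlapping or abutting
#' intervals); the threshold is closed, so an instance exactly `within_bp`
#' away still counts. Strand-agnostic.
#'
#' @param instances `GRanges` of motif instances.
#' @param exons `GRanges` of exons.
#' @param within_bp Distance threshold in bp (default 1000).
#' @return Fraction in `[0, 1]`; `NaN` when `instances` is empty.
#' @export
exon_proximity_fraction <- function(instances, exons, within_bp = 1000) {
  if (length(instances) == 0L) return(NaN)
  if (length(exons) == 0L) return(0)
  d <- GenomicRanges::distanceToNearest(instances, exons, ignore.strand = TRUE)
  n_near <- sum(S4Vectors::mcols(d)$distance <= within_bp)
  n_near / length(instances)
}

#' Annotation-matched exon-proximity comparison between two genomes
#'
#' The genome with more annotated exonic sequence has its exons randomly
#' downsampled until their total length matches the other genome's
#' (stopping at the first exon whose inclusion reaches the target), the
#' exon-proximity fractions are compared by Fisher's Exact Test, and the
#' procedure is iterated; the reported p-value is conservatively the
#' maximum over iterations.
#'
#' @param instances_a,exons_a Instances and exons for the larger annotation.
#' @param instances_b,exons_b Instances and exons for the smaller annotation.
#' @param within_bp Proximity threshold (default 1000).
#' @param n_iter Number of downsampling iterations (default 10).
#' @param seed Integer seed.
#' @return List with `p` (max over iterations) and `iterations`, a
#'   data.frame of per-iteration p-values, downsampled totals and counts.
#' @export
downsampled_proximity_test <- function(instances_a, exons_a,
                                       instances_b, exons_b,
                                       within_bp = 1000, n_iter = 10,
                                       seed = 1) {
  exons_a <- GenomicRanges::reduce(exons_a, ignore.strand = TRUE)
  exons_b <- GenomicRanges::reduce(exons_b, ignore.strand = TRUE)
  bp_a <- sum(as.numeric(BiocGenerics::width(exons_a)))
  bp_b <- sum(as.numeric(BiocGenerics::width(exons_b)))
  if (bp_b > bp_a) {
    message("second annotation is larger; swapping roles")
    return(downsampled_proximity_test(instances_b, exons_b,
                                      instances_a, exons_a,
                                      within_bp, n_iter, seed))
  }
  n_b_in <- round(exon_proximity_fraction(instances_b, exons_b, within_bp) *
                    length(instances_b))
  rows <- with_seed(substream_seed(seed, "downsample"), {
    lapply(seq_len(n_iter), function(it) {
      ord <- sample(length(exons_a))
      cum <- cumsum(as.numeric(BiocGenerics::width(exons_a)[ord]))
      keep <- ord[seq_len(which(cum >= bp_b)[1])]
      ds <- exons_a[keep]
      n_a_in <- round(exon_proximity_fraction(instances_a, ds, within_bp) *
                        length(instances_a))
      tab <- matrix(c(n_a_in, length(instances_a) - n_a_in,
                      n_b_in, length(instances_b) - n_b_in), nrow = 2)
      data.frame(iter = it,
                 downsampled_bp = sum(as.numeric(BiocGenerics::width(ds))),
                 within_a = n_a_in, total_a = length(instances_a),
                 within_b = n_b_in, total_b = length(instances_b),
                 p = stats::fisher.test(tab)$p.value)
    })
  })
  iterations <- do.call(rbind, rows)
  list(p = max(iterations$p), iterations = iterations)
}
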