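#' Extend motif instances into fixed-length flanked segments
#'
#' Each instance is extended `flank_bp` base pairs in both directions
#' (21-bp segments for the 7-bp core with default flanks). Segments that
#' would overrun a chromosome end are dropped, not trimmed, so every
#' segment has identical length and per-class site totals stay
#' proportional to segment counts.
#'
#' @param instances Motif instances ([scan_motif()]).
#' @param genome The genome the instances came from.
#' @param flank_bp Flank length on each side (default 7).
#' @return `GRanges` of segments with `segment_id`, `motif_strand`,
#'   `core_start`/`core_end` (genomic) metadata and a `flank_bp`
#'   attribute in `metadata()`; positions `flank_bp+1 .. flank_bp+m`
#'   within a segment are core, the rest flank. Dropped-count reported
#'   via message.
#' @export
build_segments <- function(instances, genome, flank_bp = 7) {
  stopifnot(flank_bp >= 0)
  if (length(instances) == 0L) {
    out <- GenomicRanges::GRanges(seqinfo = genome_seqinfo(genome))
    S4Vectors::metadata(out)$flank_bp <- as.integer(flank_bp)
    return(out)
  }
  chrom <- as.character(GenomeInfoDb::seqnames(instances))
  s <- BiocGenerics::start(instances) - flank_bp
  e <- BiocGenerics::end(instances) + flank_bp
  sl <- stats::setNames(BiocGenerics::width(genome), names(genome))[chrom]
  keep <- s >= 1L & e <= sl
  if (any(!keep)) {
    message(sum(!keep), " segment(s) overran a chromosome end; dropped")
  }
  seg <- GenomicRanges::GRanges(chrom[keep],
                                IRanges::IRanges(s[keep], e[keep]),
                                seqinfo = genome_seqinfo(genome))
  S4Vectors::mcols(seg)$segment_id <- sprintf("seg%06d", seq_along(seg))
  S4Vectors::mcols(seg)$motif_strand <-
    as.character(BiocGenerics::strand(instances))[keep]
  S4Vectors::mcols(seg)$core_start <- BiocGenerics::start(instances)[keep]
  S4Vectors::mcols(seg)$core_end <- BiocGenerics::end(instances)[keep]
  S4Vectors::metadata(seg)$flank_bp <- as.integer(flank_bp)
  seg
}

#' Remove segments on unassembled or heterochromatic contigs
#'
#' Alignment is unreliable on unassembled ("chrU"-like) contigs, so their
#' segments are excluded from the McDonald-Kreitman analysis.
#'
#' @param segments Segments from [build_segments()].
#' @param genome The source genome (supplies chromosome classes).
#' @param drop_classes Chromosome classes to remove.
#' @return List with `segments` (retained) and `log` (data.frame of
#'   per-reason rejection counts).
#' @export
filter_segments <- function(segments, genome,
                            drop_classes = "unassembled") {
  cls <- chrom_classes(genome)[as.character(GenomeInfoDb::seqnames(segments))]
  drop <- cls %in% drop_classes
  log <- data.frame(reason = paste0("filtered_chrom:", drop_classes),
                    n = vapply(drop_classes,
                               function(dc) sum(cls == dc), 0L))
  kept <- segments[!drop]
  S4Vectors::metadata(kept)$flank_bp <- S4Vectors::metadata(segments)$flank_bp
  list(segments = kept, log = log)
}
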