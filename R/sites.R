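#' Orientation-minimizing difference count between equal-length sequences
#'
#' Compares `seq_a` against both `seq_b` and its reverse complement and
#' returns the smaller Hamming distance together with the orientation
#' that achieved it (ties go to forward).
#'
#' @param seq_a,seq_b Equal-length DNA strings.
#' @return List with `n_diff` and `orientation` (`"forward"`/`"reverse"`).
#' @examples
#' count_differences("ACTGCTT", "AAGCAGT") # 0 differences, reverse
#' @export
count_differences <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  a <- strsplit(seq_a, "")[[1]]
  fwd <- sum(a != strsplit(seq_b, "")[[1]])
  rev <- sum(a != strsplit(revcomp(seq_b), "")[[1]])
  if (fwd <= rev) list(n_diff = fwd, orientation = "forward")
  else list(n_diff = rev, orientation = "reverse")
}

filter_snps <- function(snps, maf_min = 0.05, snp_only = TRUE) {
  keep <- snps$maf > maf_min
  if (snp_only) keep <- keep & snps$type == "snp"
  snps[keep, , drop = FALSE]
}

#' Per-site divergence/polymorphism records for mapped segments
#'
#' For every `mapped` segment pair, each site is labelled core or flank
#' (by its offset within the fixed-length segment), scored as a fixed
#' interspecies difference under the orientation chosen by
#' [count_differences()], and scored as polymorphic when a surviving SNP
#' (minor allele frequency strictly above `maf_min`; indels excluded when
#' `snp_only`) overlaps the source position. A site that is both
#' polymorphic and divergent is counted only as polymorphic.
#'
#' @param pairs Output of [lift_segments()].
#' @param snps Polymorphism table ([simulate_polymorphism()] or
#'   [read_vcf()]).
#' @param maf_min Minor-allele-frequency filter (default 0.05, strict).
#' @param snp_only Drop indel records (default TRUE).
#' @param genome Optional source genome; adds a `chrom_class` column.
#' @return data.frame with one row per site: `segment_id`, `chrom`,
#'   `pos`, `class` (`core`/`flank`), `fixed_diff`, `polymorphic` (0/1),
#'   and `chrom_class` when `genome` is supplied.
#' @export
classify_segment_sites <- function(pairs, snps, maf_min = 0.05,
                                   snp_only = TRUE, genome = NULL) {
  flank_bp <- attr(pairs, "flank_bp")
  if (is.null(flank_bp)) stop("pairs lack a flank_bp attribute")
  mp <- pairs[pairs$status == "mapped", , drop = FALSE]
  if (nrow(mp) == 0L) {
    return(data.frame(segment_id = character(0), chrom = character(0),
                      pos = integer(0), class = character(0),
                      fixed_diff = integer(0), polymorphic = integer(0)))
  }
  len <- nchar(mp$src_seq[1])
  stopifnot(all(nchar(mp$src_seq) == len), all(nchar(mp$dst_seq) == len))
  A <- matrix(unlist(strsplit(mp$src_seq, "")), nrow = len)
  B <- matrix(unlist(strsplit(mp$dst_seq, "")), nrow = len)
  Brc <- matrix(unlist(strsplit(revcomp(mp$dst_seq), "")), nrow = len)
  fwd <- colSums(A != B)
  rev <- colSums(A != Brc)
  use_rev <- rev < fwd
  D <- A != B
  D[, use_rev] <- (A != Brc)[, use_rev]
  cls <- rep("flank", len)
  cls[(flank_bp + 1L):(len - flank_bp)] <- "core"
  sn <- filter_snps(snps, maf_min, snp_only)
  snp_key <- if (nrow(sn)) paste(sn$chrom, sn$pos) else character(0)
  n <- nrow(mp)
  pos <- rep(mp$start, each = len) + rep(seq_len(len) - 1L, times = n)
  chrom <- rep(mp$chrom, each = len)
  poly <- as.integer(paste(chrom, pos) %in% snp_key)
  fixed <- as.integer(as.vector(D)) * (1L - poly)  # polymorphic wins
  out <- data.frame(
    segment_id = rep(mp$segment_id, each = len),
    chrom = chrom, pos = pos, class = rep(cls, times = n),
    fixed_diff = fixed, polymorphic = poly,
    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    out$chrom_class <- chrom_classes(genome)[out$chrom]
  }
  out
}

#' Label site records exonic or intergenic
#'
#' A segment is exonic when its motif core interval lies within
#' `within_bp` of an exon (the same closed 1-kb proximity rule used for
#' the exon-bias analysis); all its sites inherit the label.
#'
#' @param records Site records from [classify_segment_sites()].
#' @param segments The segments the records came from.
#' @param exons Exon `GRanges`.
#' @param within_bp Proximity threshold (default 1000).
#' @return `records` with an added `stratum_exon` column
#'   (`"exonic"`/`"intergenic"`).
#' @export
add_exonic_stratum <- function(records, segments, exons, within_bp = 1000) {
  core <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(segments),
    IRanges::IRanges(S4Vectors::mcols(segments)$core_start,
                     S4Vectors::mcols(segments)$core_end))
  lab <- rep("intergenic", length(segments))
  if (length(exons)) {
    d <- GenomicRanges::distanceToNearest(core, exons, ignore.strand = TRUE)
    near <- S4Vectors::queryHits(d)[S4Vectors::mcols(d)$distance <= within_bp]
    lab[near] <- "exonic"
  }
  names(lab) <- S4Vectors::mcols(segments)$segment_id
  records$stratum_exon <- lab[records$segment_id]
  records
}
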