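#' Pairwise genome alignment block map
#'
#' An ungapped-block stand-in for liftOver chains: each block aligns an
#' equal-length interval of the source and destination genomes at a given
#' identity fraction. A segment lifts only when it lies entirely within a
#' single block whose identity reaches `min_match` (liftOver's default
#' 0.95).
#'
#' @param blocks data.frame with columns `src_chrom`, `src_start`,
#'   `src_end`, `dst_chrom`, `dst_start`, `dst_end`, `dst_strand`
#'   (`"+"`/`"-"`), `identity` in `[0,1]`. Coordinates are 1-based
#'   inclusive in R; the TSV interchange format is 0-based half-open.
#' @param min_match Minimum identity for a successful lift (default 0.95).
#' @return Object of class `block_map`.
#' @export
block_map <- function(blocks, min_match = 0.95) {
  need <- c("src_chrom", "src_start", "src_end", "dst_chrom",
            "dst_start", "dst_end", "dst_strand", "identity")
  if (!all(need %in% names(blocks))) {
    stop("block map requires columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any((blocks$src_end - blocks$src_start) !=
          (blocks$dst_end - blocks$dst_start))) {
    stop("malformed block: src and dst lengths differ", call. = FALSE)
  }
  if (!is_probability(blocks$identity)) {
    stop("block identity must lie in [0,1]", call. = FALSE)
  }
  blocks <- blocks[order(blocks$src_chrom, blocks$src_start), , drop = FALSE]
  by_chrom <- split(blocks, blocks$src_chrom)
  for (b in by_chrom) {
    if (nrow(b) > 1 && any(b$src_start[-1] <= b$src_end[-nrow(b)])) {
      stop("blocks overlap on the source genome", call. = FALSE)
    }
  }
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, min_match = min_match),
            class = "block_map")
}

#' @rdname block_map
#' @param genome Source genome; the identity map has one full-length
#'   block per chromosome at identity 1.
#' @export
identity_block_map <- function(genome, min_match = 0.95) {
  block_map(data.frame(
    src_chrom = names(genome), src_start = 1L,
    src_end = BiocGenerics::width(genome),
    dst_chrom = names(genome), dst_start = 1L,
    dst_end = BiocGenerics::width(genome),
    dst_strand = "+", identity = 1), min_match = min_match)
}

#' Read / write the block map TSV (0-based half-open coordinates)
#'
#' @param map A `block_map`.
#' @param path File path.
#' @export
write_block_map <- function(map, path) {
  out <- map$blocks
  out$src_start <- out$src_start - 1L
  out$dst_start <- out$dst_start - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_block_map
#' @param min_match Minimum identity threshold.
#' @export
read_block_map <- function(path, min_match = 0.95) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$src_start <- tab$src_start + 1L
  tab$dst_start <- tab$dst_start + 1L
  block_map(tab, min_match = min_match)
}

#' Lift motif segments through a block map
#'
#' A segment contained in a single block of identity >= `min_match` maps
#' by coordinate offset (strand-aware); a segment touching two or more
#' blocks, or only partially covered by one, is `split`; one inside a
#' low-identity block is `below_min_match`; one touching no block is
#' `unmapped`. Only `mapped` pairs carry sequences and proceed to the
#' McDonald-Kreitman site classification.
#'
#' @param segments Segments from [build_segments()]/[filter_segments()].
#' @param map A [block_map()].
#' @param src_genome,dst_genome Genomes supplying the source and
#'   destination sequences (plus-strand bases).
#' @return data.frame, one row per segment: `segment_id`, `chrom`,
#'   `start`, `end`, `motif_strand`, `status`, `dst_chrom`, `dst_start`,
#'   `dst_end`, `block_strand`, `src_seq`, `dst_seq`; `flank_bp`
#'   attribute is carried over.
#' @export
lift_segments <- function(segments, map, src_genome, dst_genome) {
  stopifnot(inherits(map, "block_map"))
  n <- length(segments)
  res <- data.frame(
    segment_id = if (n) S4Vectors::mcols(segments)$segment_id else character(0),
    chrom = as.character(GenomeInfoDb::seqnames(segments)),
    start = BiocGenerics::start(segments),
    end = BiocGenerics::end(segments),
    motif_strand = if (n) S4Vectors::mcols(segments)$motif_strand else character(0),
    status = rep("unmapped", n),
    dst_chrom = NA_character_, dst_start = NA_integer_,
    dst_end = NA_integer_, block_strand = NA_character_,
    src_seq = NA_character_, dst_seq = NA_character_,
    stringsAsFactors = FALSE)
  b <- map$blocks
  if (n && nrow(b)) {
    bgr <- GenomicRanges::GRanges(b$src_chrom,
                                  IRanges::IRanges(b$src_start, b$src_end))
    sgr <- GenomicRanges::GRanges(res$chrom,
                                  IRanges::IRanges(res$start, res$end))
    n_touch <- GenomicRanges::countOverlaps(sgr, bgr)
    within <- GenomicRanges::findOverlaps(sgr, bgr, type = "within")
    res$status[n_touch >= 1L] <- "split"
    qi <- S4Vectors::queryHits(within)
    bi <- S4Vectors::subjectHits(within)
    low <- b$identity[bi] < map$min_match
    res$status[qi[low]] <- "below_min_match"
    ok <- qi[!low]
    bo <- bi[!low]
    if (length(ok)) {
      res$status[ok] <- "mapped"
      off_s <- res$start[ok] - b$src_start[bo]
      off_e <- res$end[ok] - b$src_start[bo]
      plus <- b$dst_strand[bo] == "+"
      res$dst_chrom[ok] <- b$dst_chrom[bo]
      res$dst_start[ok] <- ifelse(plus, b$dst_start[bo] + off_s,
                                  b$dst_end[bo] - off_e)
      res$dst_end[ok] <- ifelse(plus, b$dst_start[bo] + off_e,
                                b$dst_end[bo] - off_s)
      res$block_strand[ok] <- b$dst_strand[bo]
      res$src_seq[ok] <- as.character(Biostrings::subseq(
        src_genome[res$chrom[ok]], res$start[ok], res$end[ok]))
      res$dst_seq[ok] <- as.character(Biostrings::subseq(
        dst_genome[res$dst_chrom[ok]], res$dst_start[ok], res$dst_end[ok]))
    }
  }
  attr(res, "flank_bp") <- S4Vectors::metadata(segments)$flank_bp
  res
}
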