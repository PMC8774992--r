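BASES <- c("A", "C", "G", "T")

random_chrom_chars <- function(len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  BASES[sample.int(4L, len, replace = TRUE, prob = p)]
}

#' Simulate a genome with planted motif instances
#'
#' Each chromosome is i.i.d. random sequence at the configured GC content;
#' `n_motifs` non-overlapping copies of the motif are then written in
#' (forward or reverse-complement orientation with equal probability).
#' Chromosomes are chosen by `chrom_weights`; with `exon_proximity_bias`
#' and an annotation, that fraction of copies is placed within 1 kb of an
#' exon. Chance background occurrences of the motif can also arise and are
#' not part of the truth set.
#'
#' @param config A [sim_config()].
#' @param annotation Optional gene models from [simulate_annotation()]
#'   (needed when `exon_proximity_bias > 0`).
#' @return List with `genome` (a [genome_sequence()]) and `truth`, a
#'   `GRanges` of planted instances with strand and `match` column.
#' @export
simulate_genome <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  m <- nchar(config$motif)
  spec <- config$chrom_specs
  if (m > min(spec$length)) {
    stop("motif longer than shortest chromosome", call. = FALSE)
  }
  if (config$n_motifs * m > 0.5 * sum(spec$length)) {
    stop("infeasible placement: too many motifs for genome size",
         call. = FALSE)
  }
  if (config$exon_proximity_bias > 0 && is.null(annotation)) {
    stop("exon_proximity_bias > 0 requires an annotation", call. = FALSE)
  }
  motif_rc <- revcomp(config$motif)
  with_seed(substream_seed(config$seed, "genome"), {
    chars <- lapply(spec$length, random_chrom_chars, gc = config$gc_content)
    names(chars) <- spec$name
    occupied <- lapply(chars, function(x) logical(length(x)))
    truth_rows <- vector("list", config$n_motifs)
    w <- config$chrom_weights[spec$name]
    exons <- if (!is.null(annotation)) annotation$exons else NULL
    n_placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * max(config$n_motifs, 1L)
    while (n_placed < config$n_motifs) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("infeasible placement: could not place all motifs",
             call. = FALSE)
      }
      biased <- config$exon_proximity_bias > 0 &&
        stats::runif(1) < config$exon_proximity_bias &&
        length(exons) > 0
      if (biased) {
        e <- exons[sample.int(length(exons), 1L)]
        chrom <- as.character(GenomeInfoDb::seqnames(e))
        L <- spec$length[spec$name == chrom]
        lo <- max(1L, BiocGenerics::start(e) - 1000L - m)
        hi <- min(L - m + 1L, BiocGenerics::end(e) + 1001L)
        if (hi < lo) next
        pos <- sample(seq.int(lo, hi), 1L)
      } else {
        chrom <- sample(spec$name, 1L, prob = w)
        L <- spec$length[spec$name == chrom]
        pos <- sample.int(L - m + 1L, 1L)
      }
      span <- pos:(pos + m - 1L)
      if (any(occupied[[chrom]][span])) next
      occupied[[chrom]][span] <- TRUE
      strand <- sample(c("+", "-"), 1L)
      seq_in <- if (strand == "+") config$motif else motif_rc
      chars[[chrom]][pos:(pos + m - 1L)] <- strsplit(seq_in, "")[[1]]
      n_placed <- n_placed + 1L
      truth_rows[[n_placed]] <- data.frame(
        chrom = chrom, start = pos, end = pos + m - 1L,
        strand = strand, match = seq_in)
    }
    seqs <- Biostrings::DNAStringSet(vapply(chars, paste, "", collapse = ""))
    genome <- genome_sequence(seqs, spec$class)
    truth <- if (config$n_motifs == 0L) {
      GenomicRanges::GRanges(seqinfo = genome_seqinfo(genome))
    } else {
      tr <- do.call(rbind, truth_rows)
      gr <- GenomicRanges::GRanges(tr$chrom,
                                   IRanges::IRanges(tr$start, tr$end),
                                   strand = tr$strand,
                                   seqinfo = genome_seqinfo(genome))
      S4Vectors::mcols(gr)$match <- tr$match
      BiocGenerics::sort(gr, ignore.strand = TRUE)
    }
    list(genome = genome, truth = truth)
  })
}

#' Simulate non-overlapping gene models with exons
#'
#' Genes are placed without overlap; each has 1 to `exons_per_gene` exons
#' inside its span and a random strand. The TSS is the 5' end of the gene
#' respecting strand.
#'
#' @param config A [sim_config()].
#' @return List of class `gene_models` with `genes` and `exons` `GRanges`
#'   (both carry `gene_id`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$chrom_specs
  si <- GenomeInfoDb::Seqinfo(seqnames = spec$name,
                              seqlengths = spec$length)
  if (config$n_genes == 0L) {
    empty <- GenomicRanges::GRanges(seqinfo = si)
    S4Vectors::mcols(empty)$gene_id <- character(0)
    return(structure(list(genes = empty, exons = empty),
                     class = "gene_models"))
  }
  if (config$n_genes * config$gene_length_range[1] > 0.8 * sum(spec$length)) {
    stop("genome too small for n_genes", call. = FALSE)
  }
  with_seed(substream_seed(config$seed, "annotation"), {
    occupied <- stats::setNames(
      replicate(nrow(spec), IRanges::IRanges(), simplify = FALSE), spec$name)
    genes <- vector("list", config$n_genes)
    exon_rows <- list()
    placed <- 0L
    attempts <- 0L
    while (placed < config$n_genes) {
      attempts <- attempts + 1L
      if (attempts > 200L * config$n_genes) {
        stop("genome too small for n_genes", call. = FALSE)
      }
      chrom <- sample(spec$name, 1L, prob = spec$length)
      L <- spec$length[spec$name == chrom]
      w <- sample(seq(config$gene_length_range[1],
                      config$gene_length_range[2]), 1L)
      if (w >= L) next
      s <- sample.int(L - w, 1L)
      cand <- IRanges::IRanges(s, s + w - 1L)
      if (length(IRanges::findOverlaps(cand, occupied[[chrom]])) > 0) next
      occupied[[chrom]] <- c(occupied[[chrom]], cand)
      placed <- placed + 1L
      id <- sprintf("g%04d", placed)
      strand <- sample(c("+", "-"), 1L)
      genes[[placed]] <- data.frame(chrom = chrom, start = s,
                                    end = s + w - 1L, strand = strand,
                                    gene_id = id)
      n_ex <- sample.int(config$exons_per_gene, 1L)
      # lay exons left to right with random gaps, clipped to the span
      cur <- s
      for (k in seq_len(n_ex)) {
        ew <- sample(50:300, 1L)
        if (cur + ew - 1L > s + w - 1L) {
          if (k == 1L) { ew <- w; cur <- s } else break
        }
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          chrom = chrom, start = cur, end = min(cur + ew - 1L, s + w - 1L),
          strand = strand, gene_id = id)
        cur <- cur + ew + sample(20:500, 1L)
      }
    }
    gtab <- do.call(rbind, genes)
    etab <- do.call(rbind, exon_rows)
    to_gr <- function(tab) {
      gr <- GenomicRanges::GRanges(tab$chrom,
                                   IRanges::IRanges(tab$start, tab$end),
                                   strand = tab$strand, seqinfo = si)
      S4Vectors::mcols(gr)$gene_id <- tab$gene_id
      BiocGenerics::sort(gr, ignore.strand = TRUE)
    }
    structure(list(genes = to_gr(gtab), exons = to_gr(etab)),
              class = "gene_models")
  })
}

#' Transcription start sites of gene models
#'
#' @param genes `GRanges` of genes with strand.
#' @return Width-1 `GRanges` at each gene's 5' end.
#' @export
tss <- function(genes) {
  GenomicRanges::resize(genes, width = 1L, fix = "start")
}
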