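#' Genome container with chromosome class labels
#'
#' A genome is represented as a [Biostrings::DNAStringSet] whose element
#' metadata carries a chromosome class, one of `"X"`, `"autosome"`, `"dot"`
#' or `"unassembled"`. The class labels drive downstream filtering
#' (unassembled/heterochromatic contigs are excluded from the
#' McDonald-Kreitman analysis) and stratified contrasts (X vs autosome).
#'
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector of
#'   uppercase DNA sequences.
#' @param classes Character vector of chromosome classes, one per sequence
#'   (recycled if length 1).
#' @return A `DNAStringSet` with a `class` metadata column.
#' @examples
#' g <- genome_sequence(c(chr2 = "ACGTACGT", chrX = "TTTTAAAA"),
#'                      classes = c("autosome", "X"))
#' chrom_classes(g)
#' @export
genome_sequence <- function(seqs, classes = "autosome") {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  nm <- names(seqs)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == "")) {
    stop("chromosome names must be present and unique", call. = FALSE)
  }
  if (any(BiocGenerics::width(seqs) == 0L)) {
    stop("zero-length chromosome", call. = FALSE)
  }
  classes <- rep_len(classes, length(seqs))
  bad <- setdiff(classes, c("X", "autosome", "dot", "unassembled"))
  if (length(bad)) {
    stop("unknown chromosome class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  S4Vectors::mcols(seqs)$class <- classes
  seqs
}

#' @rdname genome_sequence
#' @param genome A genome as returned by [genome_sequence()].
#' @export
chrom_classes <- function(genome) {
  cls <- S4Vectors::mcols(genome)$class
  if (is.null(cls)) cls <- rep("autosome", length(genome))
  stats::setNames(cls, names(genome))
}

genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = BiocGenerics::width(genome))
}

#' Read / write a genome as FASTA plus a chromosome-class table
#'
#' The FASTA file holds the sequences; chromosome classes travel in a
#' two-column TSV (`chrom`, `class`) next to it, since FASTA has no slot
#' for them.
#'
#' @param genome A genome ([genome_sequence()]).
#' @param fasta Path to the FASTA file.
#' @param classes_tsv Path to the class table; defaults to `<fasta>.classes.tsv`.
#' @return `write_genome()` returns `fasta` invisibly; `read_genome()`
#'   returns a genome.
#' @export
write_genome <- function(genome, fasta,
                         classes_tsv = paste0(fasta, ".classes.tsv")) {
  Biostrings::writeXStringSet(genome, fasta)
  utils::write.table(
    data.frame(chrom = names(genome), class = chrom_classes(genome)),
    classes_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta)
}

#' @rdname write_genome
#' @export
read_genome <- function(fasta, classes_tsv = paste0(fasta, ".classes.tsv")) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  cls <- "autosome"
  if (file.exists(classes_tsv)) {
    tab <- utils::read.table(classes_tsv, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    cls <- tab$class[match(names(seqs), tab$chrom)]
  }
  genome_sequence(seqs, cls)
}
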