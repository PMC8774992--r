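#' Write variants as a minimal VCF v4.2
#'
#' Emits the site table from [simulate_polymorphism()] with the minor
#' allele frequency in `INFO/AF`. Reading back requires the vcfR package.
#'
#' @param snps data.frame with `chrom`, `pos`, `ref`, `alt`, `maf`, `type`.
#' @param path Output file.
#' @param genome Optional genome for `##contig` header lines.
#' @export
write_vcf <- function(snps, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##INFO=<ID=AF,Number=A,Type=Float,",
                  "Description=\"Minor allele frequency\">"))
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                          BiocGenerics::width(genome)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  body <- if (nrow(snps)) {
    paste(snps$chrom, snps$pos, ".", snps$ref, snps$alt, ".", "PASS",
          sprintf("AF=%g", snps$maf), sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @return `read_vcf()` returns the site table (`type` inferred from
#'   allele lengths).
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fx) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      maf = numeric(0), type = character(0)))
  }
  af <- as.numeric(sub(".*AF=([0-9.eE+-]+).*", "\\1", fx$INFO))
  data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS), ref = fx$REF,
             alt = fx$ALT, maf = af,
             type = ifelse(nchar(fx$REF) == 1 & nchar(fx$ALT) == 1,
                           "snp", "indel"))
}

#' Write / read gene models as GFF3
#'
#' @param gene_models List with `genes` and `exons` `GRanges`.
#' @param path File path.
#' @export
write_gene_models <- function(gene_models, path) {
  g <- gene_models$genes
  e <- gene_models$exons
  gg <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(g),
                               IRanges::IRanges(BiocGenerics::start(g),
                                                BiocGenerics::end(g)),
                               strand = BiocGenerics::strand(g))
  S4Vectors::mcols(gg) <- S4Vectors::DataFrame(
    type = "gene", ID = S4Vectors::mcols(g)$gene_id)
  ee <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(e),
                               IRanges::IRanges(BiocGenerics::start(e),
                                                BiocGenerics::end(e)),
                               strand = BiocGenerics::strand(e))
  S4Vectors::mcols(ee) <- S4Vectors::DataFrame(
    type = "exon", Parent = S4Vectors::mcols(e)$gene_id)
  rtracklayer::export(c(gg, ee), path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  gid <- as.character(genes$ID)
  eid <- vapply(exons$Parent, function(p) as.character(p)[1], "")
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = gid)
  S4Vectors::mcols(exons) <- S4Vectors::DataFrame(gene_id = eid)
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write motif instances (or any ranges) as BED6
#'
#' Instances are written 0-based half-open with `name` = matched motif
#' and `score` = 0.
#'
#' @param instances `GRanges` with a `match` column.
#' @param path File path.
#' @export
write_instances_bed <- function(instances, path) {
  out <- instances
  nm <- S4Vectors::mcols(out)$match
  S4Vectors::mcols(out) <- NULL
  S4Vectors::mcols(out)$name <- if (is.null(nm)) "." else nm
  S4Vectors::mcols(out)$score <- 0L
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' @rdname write_instances_bed
#' @export
read_instances_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(match = gr$name)
  gr
}

#' Write / read peaks in narrowPeak format
#'
#' @param peaks Peak `GRanges` (optional `score` column).
#' @param path File path.
#' @export
write_narrowpeak <- function(peaks, path) {
  score <- S4Vectors::mcols(peaks)$score
  if (is.null(score)) score <- 0L
  tab <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = BiocGenerics::start(peaks) - 1L,
    end = BiocGenerics::end(peaks),
    name = sprintf("peak%d", seq_along(peaks)),
    score = score, strand = ".",
    signalValue = score, pValue = -1, qValue = -1,
    peak = floor(BiocGenerics::width(peaks) / 2))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @export
read_narrowpeak <- function(path) {
  rtracklayer::import(path, format = "BED",
                      extraCols = c(signalValue = "numeric",
                                    pValue = "numeric", qValue = "numeric",
                                    peak = "integer"))
}

#' Write / read site records as TSV
#'
#' @param records Site records ([classify_segment_sites()]).
#' @param path File path.
#' @export
write_site_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_records
#' @export
read_site_records <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
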