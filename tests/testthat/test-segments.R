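make_inst <- function(chrom, start, len = 7, strand = "+", seqinfo) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start, start + len - 1),
                               strand = strand, seqinfo = seqinfo)
  S4Vectors::mcols(gr)$match <- strrep("A", len)
  gr
}

test_that("segments extend 7 bp each side to 21 bp with a centered core", {
  g <- random_genome(1000, 3)
  si <- GenomeInfoDb::Seqinfo("chr1", 1000)
  inst <- make_inst("chr1", 101, seqinfo = si)  # core [101,107]
  seg <- build_segments(inst, g)
  expect_equal(BiocGenerics::width(seg), 21)
  expect_equal(BiocGenerics::start(seg), 94)
  expect_equal(BiocGenerics::end(seg), 114)
  expect_equal(S4Vectors::mcols(seg)$core_start, 101)
  expect_equal(S4Vectors::mcols(seg)$core_end, 107)
  # flank 0 keeps the instance interval, all core
  seg0 <- build_segments(inst, g, flank_bp = 0)
  expect_equal(BiocGenerics::width(seg0), 7)
})

test_that("segments overrunning a chromosome end are dropped, not trimmed", {
  g <- random_genome(100, 3)
  si <- GenomeInfoDb::Seqinfo("chr1", 100)
  inst <- c(make_inst("chr1", 4, seqinfo = si),    # left flank underflows
            make_inst("chr1", 50, seqinfo = si),
            make_inst("chr1", 92, seqinfo = si))   # right flank overflows
  expect_message(seg <- build_segments(inst, g), "dropped")
  expect_length(seg, 1)
  expect_equal(BiocGenerics::start(seg), 43)
})

test_that("chromosome-class filtering partitions the input", {
  g <- genome_sequence(c(chr2 = strrep("A", 1000), chrU = strrep("A", 1000)),
                       classes = c("autosome", "unassembled"))
  si <- genome_sequence(c(chr2 = strrep("A", 1000), chrU = strrep("A", 1000)),
                        classes = c("autosome", "unassembled"))
  inst <- c(make_inst("chr2", 100, seqinfo = GenomeInfoDb::Seqinfo(
    c("chr2", "chrU"), c(1000, 1000))),
    make_inst("chrU", 100, seqinfo = GenomeInfoDb::Seqinfo(
      c("chr2", "chrU"), c(1000, 1000))),
    make_inst("chrU", 300, seqinfo = GenomeInfoDb::Seqinfo(
      c("chr2", "chrU"), c(1000, 1000))))
  seg <- build_segments(inst, g)
  fs <- filter_segments(seg, g)
  expect_length(fs$segments, 1)
  expect_equal(fs$log$n, 2L)
  expect_equal(length(fs$segments) + sum(fs$log$n), length(seg))
  # all-chrU input leaves nothing
  fs2 <- filter_segments(seg[as.character(
    GenomeInfoDb::seqnames(seg)) == "chrU"], g)
  expect_length(fs2$segments, 0)
})

test_that("identity lift maps every segment to itself", {
  fix <- mk_pipeline_fixture(seed = 61, n_motifs = 30, chrom_len = 20000L)
  pairs <- fix$pairs
  expect_true(all(pairs$status == "mapped"))
  expect_equal(pairs$dst_start, pairs$start)
  expect_equal(pairs$dst_end, pairs$end)
  # partition invariant over statuses
  expect_equal(nrow(pairs), length(fix$seg))
})

test_that("lift distinguishes split, below_min_match and unmapped", {
  g <- random_genome(400, 7)
  si <- GenomeInfoDb::Seqinfo("chr1", 400)
  inst <- c(make_inst("chr1", 60, seqinfo = si),   # within block 1
            make_inst("chr1", 95, seqinfo = si),   # spans blocks 1/2
            make_inst("chr1", 150, seqinfo = si),  # within low-identity block
            make_inst("chr1", 300, seqinfo = si))  # no block
  seg <- build_segments(inst, g)
  bm <- block_map(data.frame(
    src_chrom = "chr1", src_start = c(40, 101, 140),
    src_end = c(100, 139, 200),
    dst_chrom = "chrA", dst_start = c(240, 301, 340),
    dst_end = c(300, 339, 400),
    dst_strand = "+", identity = c(1, 1, 0.90)))
  dst <- random_genome(500, 8)
  names(dst) <- "chrA"
  pairs <- lift_segments(seg, bm, g, dst)
  expect_equal(pairs$status,
               c("mapped", "split", "below_min_match", "unmapped"))
  expect_equal(pairs$dst_start[1], 240 + (53 - 40))
  # mapped sequences come from the right places and have equal length
  expect_equal(nchar(pairs$src_seq[1]), nchar(pairs$dst_seq[1]))
  expect_equal(pairs$src_seq[1],
               as.character(Biostrings::subseq(g[["chr1"]], 53, 73)))
})

test_that("minus-strand blocks map coordinates reversed", {
  g <- genome_sequence(c(chr1 = strrep("ACGTT", 40)))      # 200 bp
  dst_seq <- revcomp(as.character(g[["chr1"]]))
  dst <- genome_sequence(c(chrB = dst_seq))
  bm <- block_map(data.frame(src_chrom = "chr1", src_start = 1,
                             src_end = 200, dst_chrom = "chrB",
                             dst_start = 1, dst_end = 200,
                             dst_strand = "-", identity = 1))
  si <- GenomeInfoDb::Seqinfo("chr1", 200)
  inst <- make_inst("chr1", 50, seqinfo = si)
  seg <- build_segments(inst, g)        # [43, 63]
  pairs <- lift_segments(seg, bm, g, dst)
  expect_equal(pairs$status, "mapped")
  expect_equal(pairs$dst_start, 200 - 63 + 1)
  expect_equal(pairs$dst_end, 200 - 43 + 1)
  # destination plus-strand bases are the reverse complement of the source
  expect_equal(revcomp(pairs$dst_seq), pairs$src_seq)
  # and the orientation-minimizing count sees zero differences
  expect_equal(count_differences(pairs$src_seq, pairs$dst_seq)$n_diff, 0)
})

test_that("malformed blocks are rejected at load time", {
  expect_error(block_map(data.frame(
    src_chrom = "chr1", src_start = 1, src_end = 100, dst_chrom = "chrA",
    dst_start = 1, dst_end = 90, dst_strand = "+", identity = 1)),
    "lengths differ")
  expect_error(block_map(data.frame(
    src_chrom = "chr1", src_start = c(1, 50), src_end = c(100, 149),
    dst_chrom = "chrA", dst_start = c(1, 50), dst_end = c(100, 149),
    dst_strand = "+", identity = 1)), "overlap")
})

test_that("block map TSV round-trips through 0-based coordinates", {
  bm <- block_map(data.frame(
    src_chrom = "chr1", src_start = 11, src_end = 110, dst_chrom = "chrA",
    dst_start = 21, dst_end = 120, dst_strand = "+", identity = 0.97))
  path <- tempfile(fileext = ".tsv")
  write_block_map(bm, path)
  raw <- read.table(path, header = TRUE)
  expect_equal(raw$src_start, 10)  # 0-based on disk
  back <- read_block_map(path)
  expect_equal(back$blocks, bm$blocks)
})

test_that("count_differences minimizes over orientation", {
  expect_equal(count_differences("ACTGCTT", "AAGCAGT"),
               list(n_diff = 0, orientation = "reverse"))
  expect_equal(count_differences("ACTGCTT", "ACTGCTT"),
               list(n_diff = 0, orientation = "forward"))
  expect_equal(count_differences("ACTGCTT", "ACTGCTA"),
               list(n_diff = 1, orientation = "forward"))
  expect_error(count_differences("ACT", "ACTG"), "equal length")
  # symmetry and bound over random pairs
  set.seed(4)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    ab <- count_differences(a, b)$n_diff
    expect_equal(ab, count_differences(b, a)$n_diff)
    expect_lte(ab, 21)
  }
})

test_that("site classification separates classes, filters MAF, and lets polymorphism win", {
  src <- genome_sequence(c(chr1 = strrep("ACGTA", 20)))  # 100 bp
  dst_chars <- strsplit(as.character(src[["chr1"]]), "")[[1]]
  # two differences inside the core [48,54] of segment [41,61]
  dst_chars[c(49, 52)] <- c("G", "A")
  stopifnot(dst_chars[49] != strsplit(as.character(src[["chr1"]]), "")[[1]][49])
  dst <- genome_sequence(stats::setNames(
    Biostrings::DNAStringSet(paste(dst_chars, collapse = "")), "chr1"))
  si <- GenomeInfoDb::Seqinfo("chr1", 100)
  inst <- make_inst("chr1", 48, seqinfo = si)
  seg <- build_segments(inst, src)
  pairs <- lift_segments(seg, identity_block_map(src), src, dst)
  snps <- data.frame(chrom = "chr1", pos = c(43, 45),
                     ref = "A", alt = "T", maf = c(0.2, 0.04),
                     type = "snp")
  rec <- classify_segment_sites(pairs, snps)
  tab <- build_mk_table(rec)
  expect_equal(tab$D_core, 2)
  expect_equal(tab$D_flank, 0)
  expect_equal(tab$P_core, 0)
  expect_equal(tab$P_flank, 1)  # the MAF-0.04 SNP is filtered out
  # a site both polymorphic and divergent counts only as polymorphic
  dst_chars2 <- dst_chars
  dst_chars2[43] <- "C"
  dst2 <- genome_sequence(stats::setNames(
    Biostrings::DNAStringSet(paste(dst_chars2, collapse = "")), "chr1"))
  pairs2 <- lift_segments(seg, identity_block_map(src), src, dst2)
  rec2 <- classify_segment_sites(pairs2, snps)
  tab2 <- build_mk_table(rec2)
  expect_equal(tab2$D_flank, 0)
  expect_equal(tab2$P_flank, 1)
  # with no variants and identical sequences everything is zero
  pairs3 <- lift_segments(seg, identity_block_map(src), src, src)
  rec3 <- classify_segment_sites(pairs3, snps[0, ])
  expect_true(all(rec3$fixed_diff == 0) && all(rec3$polymorphic == 0))
})
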