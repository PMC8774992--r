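#' Per-gene TSS-window read counts
#'
#' Counts read positions falling in the closed window
#' `[TSS - half_width, TSS + half_width]` of each gene, per sample.
#' Windows are truncated at chromosome edges; genes without a usable TSS
#' are excluded with a warning. Half-widths of 100, 500 and 1000 bp are
#' the standard sensitivity settings around the 350 bp default.
#'
#' @param reads Named list of width-1 read-position `GRanges`, one per
#'   sample.
#' @param gene_models Gene models (list with `genes`) or a gene `GRanges`.
#' @param half_width Window half-width in bp (default 350).
#' @param samples Optional sample metadata data.frame (`sample`,
#'   `factor`, `replicate`); matched to `names(reads)`.
#' @return Numeric matrix genes x samples with a `samples` attribute and
#'   `half_width` attribute (a signal matrix).
#' @export
tss_window_counts <- function(reads, gene_models, half_width = 350,
                              samples = NULL) {
  genes <- if (is.list(gene_models) && !methods::is(gene_models, "GRanges"))
    gene_models$genes else gene_models
  ok <- !is.na(BiocGenerics::start(genes))
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) without TSS excluded")
    genes <- genes[ok]
  }
  t0 <- tss(genes)
  sl <- GenomeInfoDb::seqlengths(t0)[as.character(GenomeInfoDb::seqnames(t0))]
  lo <- pmax(1L, BiocGenerics::start(t0) - half_width)
  hi <- BiocGenerics::start(t0) + half_width
  hi <- ifelse(is.na(sl), hi, pmin(hi, sl))
  wins <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(t0),
                                 IRanges::IRanges(lo, hi))
  mat <- vapply(reads, function(r)
    GenomicRanges::countOverlaps(wins, r, ignore.strand = TRUE),
    numeric(length(wins)))
  if (length(wins) == 1L) mat <- matrix(mat, nrow = 1,
                                        dimnames = list(NULL, names(reads)))
  rownames(mat) <- S4Vectors::mcols(genes)$gene_id
  if (is.null(samples)) {
    samples <- data.frame(sample = colnames(mat),
                          factor = sub("_rep[0-9]+$", "", colnames(mat)),
                          replicate = seq_len(ncol(mat)))
  }
  attr(mat, "samples") <- samples
  attr(mat, "half_width") <- half_width
  mat
}

#' Scale each sample to its own mean signal
#'
#' Divides every sample (column) by its mean count, removing sequencing
#' depth differences between experiments; each sample's post-scaling mean
#' is 1. Idempotent.
#'
#' @param mat Signal matrix from [tss_window_counts()].
#' @return Normalized signal matrix (attributes preserved).
#' @export
normalize_signal <- function(mat) {
  mu <- colMeans(mat)
  if (any(mu == 0)) stop("all-zero sample: cannot normalize", call. = FALSE)
  out <- sweep(mat, 2, mu, "/")
  attributes(out)[c("samples", "half_width")] <-
    attributes(mat)[c("samples", "half_width")]
  out
}

#' PCA of samples with a silhouette check of factor clustering
#'
#' Mean-centred PCA over samples of the normalized gene-by-gene signal;
#' the silhouette score of the factor labels in PC1-PC2 space measures
#' how cleanly replicates of each factor cluster.
#'
#' @param mat Signal matrix (normalize first).
#' @param labels Factor labels per sample; defaults to the `samples`
#'   attribute.
#' @param k Number of components to return (default 2).
#' @return List with `coords` (samples x k), `var_explained`,
#'   `silhouette` (mean silhouette width), `labels`.
#' @export
pca_cluster_check <- function(mat, labels = NULL, k = 2) {
  if (ncol(mat) < 3) stop("need at least 3 samples", call. = FALSE)
  if (is.null(labels)) labels <- attr(mat, "samples")$factor
  stopifnot(length(labels) == ncol(mat))
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(coords[, 1:min(2, k), drop = FALSE]))
  list(coords = coords,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       silhouette = mean(sil[, "sil_width"]),
       labels = labels)
}

factor_profiles <- function(mat, samples = attr(mat, "samples")) {
  labs <- unique(samples$factor)
  vapply(labs, function(f)
    rowMeans(mat[, samples$factor == f, drop = FALSE]),
    numeric(nrow(mat)))
}

#' Binding-profile divergence between factors relative to a reference
#'
#' Euclidean distances between factor-mean normalized profiles,
#' `d(a, ref)` and `d(b, ref)`, with a one-sided permutation test of
#' `d(a, ref) > d(b, ref)` obtained by shuffling replicate-to-factor
#' assignments between `a` and `b`.
#'
#' @param mat Normalized signal matrix.
#' @param factor_a,factor_b,factor_ref Factor labels.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `d_a_ref`, `d_b_ref`, `p`.
#' @export
protein_divergence <- function(mat, factor_a, factor_b, factor_ref,
                               n_perm = 1000, seed = 1) {
  samples <- attr(mat, "samples")
  ref <- rowMeans(mat[, samples$factor == factor_ref, drop = FALSE])
  ia <- which(samples$factor == factor_a)
  ib <- which(samples$factor == factor_b)
  dist_to_ref <- function(cols) sqrt(sum((rowMeans(
    mat[, cols, drop = FALSE]) - ref)^2))
  d_a <- dist_to_ref(ia)
  d_b <- dist_to_ref(ib)
  obs <- d_a - d_b
  pool <- c(ia, ib)
  perm <- with_seed(substream_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(i) {
      take <- sample(seq_along(pool), length(ia))
      dist_to_ref(pool[take]) - dist_to_ref(pool[-take])
    }, numeric(1))
  })
  list(d_a_ref = d_a, d_b_ref = d_b,
       p = (1 + sum(perm >= obs)) / (1 + n_perm))
}

#' Per-chromosome signal medians and X-vs-autosome enrichment test
#'
#' For each factor, the median normalized TSS signal is computed per
#' chromosome; the X-vs-autosome statistic is the ratio of the median
#' over X-linked genes to the median over autosomal genes, tested by
#' permuting the chromosome-class labels over genes (two-sided on the
#' log ratio).
#'
#' @param mat Normalized signal matrix.
#' @param gene_models Gene models supplying each gene's chromosome.
#' @param genome Genome supplying chromosome classes.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `medians` (data.frame factor x chromosome) and
#'   `tests` (data.frame: factor, `x_auto_ratio`, `p`).
#' @export
chromosome_enrichment <- function(mat, gene_models, genome,
                                  n_perm = 1000, seed = 1) {
  genes <- gene_models$genes
  gid <- S4Vectors::mcols(genes)$gene_id
  chrom <- stats::setNames(as.character(GenomeInfoDb::seqnames(genes)), gid)
  cls <- chrom_classes(genome)[chrom[rownames(mat)]]
  prof <- factor_profiles(mat)
  med_rows <- list()
  for (f in colnames(prof)) {
    for (ch in unique(chrom[rownames(mat)])) {
      med_rows[[length(med_rows) + 1L]] <- data.frame(
        factor = f, chrom = ch,
        median = stats::median(prof[chrom[rownames(mat)] == ch, f]))
    }
  }
  is_x <- cls == "X"
  is_auto <- cls == "autosome"
  tests <- lapply(colnames(prof), function(f) {
    v <- prof[, f]
    obs <- stats::median(v[is_x]) / stats::median(v[is_auto])
    idx <- which(is_x | is_auto)
    nx <- sum(is_x)
    perm <- with_seed(substream_seed(seed, "permutation") +
                        match(f, colnames(prof)), {
      vapply(seq_len(n_perm), function(i) {
        px <- sample(idx, nx)
        stats::median(v[px]) / stats::median(v[setdiff(idx, px)])
      }, numeric(1))
    })
    data.frame(factor = f, x_auto_ratio = obs,
               p = (1 + sum(abs(log(perm)) >= abs(log(obs)))) / (1 + n_perm))
  })
  list(medians = do.call(rbind, med_rows), tests = do.call(rbind, tests))
}

#' Conservative peak set from two replicates
#'
#' Keeps only genomic intervals covered by peaks in both replicates,
#' trimmed to the intersection; the result is sorted and non-overlapping.
#'
#' @param peaks_rep1,peaks_rep2 Peak `GRanges`.
#' @return `GRanges` of intersected peaks.
#' @export
intersect_replicate_peaks <- function(peaks_rep1, peaks_rep2) {
  GenomicRanges::intersect(
    GenomicRanges::reduce(peaks_rep1, ignore.strand = TRUE),
    GenomicRanges::reduce(peaks_rep2, ignore.strand = TRUE),
    ignore.strand = TRUE)
}

#' Genes overlapping the conservative peak set
#'
#' @param peaks Conservative peaks ([intersect_replicate_peaks()]).
#' @param gene_models Gene models.
#' @return Character vector of bound gene ids (gene span overlaps >= 1
#'   peak, strand-agnostic).
#' @export
bound_genes <- function(peaks, gene_models) {
  genes <- gene_models$genes
  hit <- GenomicRanges::countOverlaps(genes, peaks, ignore.strand = TRUE) > 0
  S4Vectors::mcols(genes)$gene_id[hit]
}

#' Rank replicates by inter-replicate signal correlation
#'
#' Helper for choosing the "two best replicates" of a factor: replicates
#' are ranked by their mean Pearson correlation with the other replicates
#' of the same factor.
#'
#' @param mat Signal matrix.
#' @param factor_label Factor whose replicates to rank.
#' @return data.frame `sample`, `mean_cor`, sorted best first.
#' @export
rank_replicates <- function(mat, factor_label) {
  samples <- attr(mat, "samples")
  cols <- which(samples$factor == factor_label)
  stopifnot(length(cols) >= 2)
  cc <- stats::cor(mat[, cols, drop = FALSE])
  mc <- (rowSums(cc) - 1) / (ncol(cc) - 1)
  out <- data.frame(sample = colnames(mat)[cols], mean_cor = mc)
  out[order(-out$mean_cor), ]
}

#' Two-sided permutation (sampled randomization) test
#'
#' Tests a difference in mean or median between two samples by pooling
#' and re-splitting; the p-value carries the +1 correction so it lies in
#' (0, 1].
#'
#' @param values_a,values_b Numeric vectors.
#' @param stat `"mean"` or `"median"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return p-value.
#' @export
permutation_test <- function(values_a, values_b, stat = c("mean", "median"),
                             n_perm = 1000, seed = 1) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else stats::median
  obs <- abs(f(values_a) - f(values_b))
  pool <- c(values_a, values_b)
  na <- length(values_a)
  perm <- with_seed(substream_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample(length(pool), na)
      abs(f(pool[idx]) - f(pool[-idx]))
    }, numeric(1))
  })
  (1 + sum(perm >= obs)) / (1 + n_perm)
}
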