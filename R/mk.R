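#' McDonald-Kreitman 2x2 table at motif resolution
#'
#' Sums fixed differences and polymorphic sites over core and flank site
#' classes: the motif core plays the role of the selected class ("dN")
#' and the immediately flanking sites the neutral reference ("dS"). An
#' optional stratum restricts the records before summing.
#'
#' @param records Site records from [classify_segment_sites()] (optionally
#'   through [add_exonic_stratum()]).
#' @param stratum One of `"all"`, `"X"`, `"autosome"` (requires a
#'   `chrom_class` column) or `"exonic"`, `"intergenic"` (requires
#'   `stratum_exon`).
#' @return Object of class `mk_table`: list with `D_core`, `D_flank`,
#'   `P_core`, `P_flank` and the stratum label.
#' @export
build_mk_table <- function(records, stratum = "all") {
  if (stratum %in% c("X", "autosome")) {
    stopifnot("chrom_class" %in% names(records))
    records <- records[records$chrom_class == stratum, , drop = FALSE]
  } else if (stratum %in% c("exonic", "intergenic")) {
    stopifnot("stratum_exon" %in% names(records))
    records <- records[records$stratum_exon == stratum, , drop = FALSE]
  } else if (stratum != "all") {
    stop("unknown stratum: ", stratum, call. = FALSE)
  }
  core <- records$class == "core"
  structure(list(
    D_core = sum(records$fixed_diff[core]),
    D_flank = sum(records$fixed_diff[!core]),
    P_core = sum(records$polymorphic[core]),
    P_flank = sum(records$polymorphic[!core]),
    stratum = stratum), class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  cat(sprintf("MK table [%s]\n", x$stratum))
  m <- matrix(c(x$D_core, x$P_core, x$D_flank, x$P_flank), nrow = 2,
              byrow = TRUE,
              dimnames = list(c("core", "flank"),
                              c("fixed (D)", "polymorphic (P)")))
  print(m)
  a <- tryCatch(alpha_mk(x), error = function(e) NA_real_)
  cat(sprintf("alpha = %s\n", format(a)))
  invisible(x)
}

#' Adaptive substitution fraction alpha from an MK table
#'
#' `alpha = 1 - (D_flank * P_core) / (D_core * P_flank)`, the proportion
#' of core-site fixed differences attributable to positive selection.
#' Undefined when `D_core = 0` or `P_flank = 0` (signalled as an error,
#' never silently 0).
#'
#' @param table An `mk_table`, or the four counts.
#' @param D_core,D_flank,P_core,P_flank Counts, used when `table` is
#'   missing.
#' @return alpha (at most 1).
#' @examples
#' alpha_mk(D_core = 20, D_flank = 10, P_core = 5, P_flank = 10) # 0.75
#' @export
alpha_mk <- function(table, D_core, D_flank, P_core, P_flank) {
  if (!missing(table)) {
    D_core <- table$D_core; D_flank <- table$D_flank
    P_core <- table$P_core; P_flank <- table$P_flank
  }
  if (D_core == 0 || P_flank == 0) {
    stop("alpha undefined: D_core = 0 or P_flank = 0", call. = FALSE)
  }
  unname(1 - (D_flank * P_core) / (D_core * P_flank))
}

#' G and Fisher tests of the MK table
#'
#' Both tests are applied to the 2x2 (fixed vs polymorphic) x (core vs
#' flank) table: the G test is the likelihood-ratio statistic on 1 df
#' without continuity correction; Fisher's Exact Test is two-sided. With
#' a zero margin Fisher returns 1 and the G test is reported `NA` with a
#' warning.
#'
#' @param table An `mk_table`.
#' @return List with `p_g`, `g_stat` and `p_fisher`.
#' @export
mk_tests <- function(table) {
  m <- matrix(c(table$D_core, table$D_flank, table$P_core, table$P_flank),
              nrow = 2)
  if (sum(m) == 0) stop("empty MK table", call. = FALSE)
  p_fisher <- stats::fisher.test(m)$p.value
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero margin: G test undefined")
    return(list(p_g = NA_real_, g_stat = NA_real_, p_fisher = p_fisher))
  }
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  terms <- ifelse(m > 0, m * log(m / e), 0)
  g <- 2 * sum(terms)
  list(p_g = stats::pchisq(g, df = 1, lower.tail = FALSE),
       g_stat = g, p_fisher = p_fisher)
}

# per-segment (D_core, D_flank, P_core, P_flank) count matrix
segment_count_matrix <- function(records) {
  ids <- factor(records$segment_id)
  core <- records$class == "core"
  cbind(
    D_core = as.vector(rowsum(records$fixed_diff * core, ids)),
    D_flank = as.vector(rowsum(records$fixed_diff * !core, ids)),
    P_core = as.vector(rowsum(records$polymorphic * core, ids)),
    P_flank = as.vector(rowsum(records$polymorphic * !core, ids)))
}

counts_to_table <- function(cnt, stratum = "all") {
  structure(list(D_core = cnt[1], D_flank = cnt[2],
                 P_core = cnt[3], P_flank = cnt[4], stratum = stratum),
            class = "mk_table")
}

#' Bootstrap alpha with percentile confidence intervals
#'
#' Segments are resampled with replacement (each segment's sites move
#' together, respecting within-segment linkage); alpha is recomputed from
#' the aggregated table of each resample and a percentile interval at
#' `level` is formed. Resamples with undefined alpha are excluded from
#' the percentiles and their fraction reported. A one-sided bootstrap
#' p-value for alpha > 0 (the fraction of resamples with alpha <= 0) is
#' included alongside the G and Fisher tests of the observed table.
#'
#' @param records Site records.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.99).
#' @param seed Integer seed.
#' @return List of class `alpha_estimate`: `alpha`, `ci_low`, `ci_high`,
#'   `level`, `n_boot`, `n_segments`, `undefined_frac`, `p_boot`, `p_g`,
#'   `p_fisher`.
#' @export
bootstrap_alpha <- function(records, n_boot = 1000, level = 0.99, seed = 1) {
  cnt <- segment_count_matrix(records)
  n <- nrow(cnt)
  if (n < 2L) stop("need at least 2 segments to bootstrap", call. = FALSE)
  obs_tab <- counts_to_table(colSums(cnt))
  obs_alpha <- alpha_mk(obs_tab)
  boot <- with_seed(substream_seed(seed, "bootstrap"), {
    vapply(seq_len(n_boot), function(b) {
      tab <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      s <- crossprod(tab, cnt)[1, ]
      if (s["D_core"] == 0 || s["P_flank"] == 0) return(NA_real_)
      1 - (s["D_flank"] * s["P_core"]) / (s["D_core"] * s["P_flank"])
    }, numeric(1))
  })
  ok <- boot[!is.na(boot)]
  if (!length(ok)) stop("alpha undefined in every bootstrap resample",
                        call. = FALSE)
  undef <- mean(is.na(boot))
  if (undef > 0) message(sprintf(
    "%.1f%% of resamples had undefined alpha; excluded", 100 * undef))
  qs <- stats::quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  tests <- mk_tests(obs_tab)
  structure(list(
    alpha = obs_alpha, ci_low = qs[1], ci_high = qs[2], level = level,
    n_boot = n_boot, n_segments = n, undefined_frac = undef,
    p_boot = (1 + sum(ok <= 0)) / (1 + length(ok)),
    p_g = tests$p_g, p_fisher = tests$p_fisher),
    class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf(
    "alpha = %.4f  [%d%% CI %.4f, %.4f]  (%d segments, %d resamples)\n",
    x$alpha, round(100 * x$level), x$ci_low, x$ci_high,
    x$n_segments, x$n_boot))
  cat(sprintf("p_boot(alpha>0) = %.4g  p_G = %.4g  p_Fisher = %.4g\n",
              x$p_boot, x$p_g, x$p_fisher))
  invisible(x)
}

#' Alpha against a synonymous-site neutral reference
#'
#' Recomputes alpha with supplied synonymous-site divergence and
#' polymorphism counts replacing the flank counts (their extraction from
#' an annotation is up to the caller).
#'
#' @param table An `mk_table` (supplies `D_core`, `P_core`).
#' @param D_syn,P_syn Synonymous-site fixed-difference and polymorphism
#'   counts.
#' @return alpha computed as `1 - (D_syn * P_core) / (D_core * P_syn)`.
#' @export
synonymous_reference_alpha <- function(table, D_syn, P_syn) {
  if (D_syn == 0 || table$D_core == 0 || P_syn == 0) {
    stop("alpha undefined with these reference counts", call. = FALSE)
  }
  1 - (D_syn * table$P_core) / (table$D_core * P_syn)
}

#' Permutation contrast of alpha between two strata
#'
#' Computes `delta = alpha(stratum_a) - alpha(stratum_b)` from aggregate
#' tables and builds the null by permuting stratum labels over segments
#' (two-sided p on `|delta|`).
#'
#' @param records Site records carrying the stratum column.
#' @param stratum_col Column name holding the labels (`"chrom_class"` or
#'   `"stratum_exon"`).
#' @param stratum_a,stratum_b The two labels to contrast.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `delta`, `alpha_a`, `alpha_b`, `p`,
#'   `undefined_frac` (permutations with undefined alpha, excluded).
#' @export
stratified_alpha_contrast <- function(records, stratum_col, stratum_a,
                                      stratum_b, n_perm = 1000, seed = 1) {
  stopifnot(stratum_col %in% names(records))
  lab_by_seg <- tapply(records[[stratum_col]], records$segment_id,
                       function(x) x[1])
  cnt <- segment_count_matrix(records)
  labs <- lab_by_seg[sort(unique(records$segment_id))]
  in_a <- labs == stratum_a
  in_b <- labs == stratum_b
  if (!any(in_a) || !any(in_b)) stop("empty stratum", call. = FALSE)
  seg_alpha <- function(sel) {
    s <- colSums(cnt[sel, , drop = FALSE])
    if (s["D_core"] == 0 || s["P_flank"] == 0) return(NA_real_)
    1 - (s["D_flank"] * s["P_core"]) / (s["D_core"] * s["P_flank"])
  }
  alpha_a <- seg_alpha(in_a)
  alpha_b <- seg_alpha(in_b)
  if (is.na(alpha_a) || is.na(alpha_b)) {
    stop("alpha undefined in an observed stratum", call. = FALSE)
  }
  delta <- alpha_a - alpha_b
  idx <- which(in_a | in_b)
  n_a <- sum(in_a)
  perm <- with_seed(substream_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(i) {
      pa <- sample(idx, n_a)
      d <- seg_alpha(pa)
      e <- seg_alpha(setdiff(idx, pa))
      if (is.na(d) || is.na(e)) NA_real_ else d - e
    }, numeric(1))
  })
  undef <- mean(is.na(perm))
  if (undef > 0.5) stop("alpha undefined in >50% of permutations",
                        call. = FALSE)
  ok <- perm[!is.na(perm)]
  list(delta = delta, alpha_a = alpha_a, alpha_b = alpha_b,
       p = (1 + sum(abs(ok) >= abs(delta))) / (1 + length(ok)),
       undefined_frac = undef)
}
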