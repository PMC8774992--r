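#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over character vectors of A/C/G/T/N strings.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp("ACTGCTT") # "AAGCAGT"
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic per-component seed derivation: one user seed fans out to
# independent substreams so adding a generator does not perturb the others.
# Kept below 2^31 - 1 (R integers are 32 bit).
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    genome = 1L, annotation = 2L, divergence = 3L, polymorphism = 4L,
    chip = 5L, traits = 6L, bootstrap = 7L, permutation = 8L,
    downsample = 9L, battery = 10L, phylo = 11L
  )
  k <- if (is.character(stream)) offsets[[stream]] else as.integer(stream)
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}

# run code under a local RNG state so library functions never disturb the
# caller's random stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

is_probability <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)

assert_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 1L ||
      grepl("[^ACGT]", motif)) {
    stop("`motif` must be a single non-empty string over {A,C,G,T}",
         call. = FALSE)
  }
  invisible(motif)
}
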