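# Internal helpers: seeded evaluation, DNA string utilities, k-mer indexing.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded simulation
#' internals never perturb the caller's random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and an index; keeps every seed
# inside the 32-bit signed range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T/N.
#' @return reverse-complemented character scalar.
#' @keywords internal
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Encode a DNA string as integer codes A=0 C=1 G=2 T=3, N/other = NA.
dna_codes <- function(x) {
  raw <- utf8ToInt(x)
  codes <- rep(NA_integer_, length(raw))
  codes[raw == 65L] <- 0L # A
  codes[raw == 67L] <- 1L # C
  codes[raw == 71L] <- 2L # G
  codes[raw == 84L] <- 3L # T
  codes
}

# 1-based index of each k-mer starting at positions 1..(n-k+1) of a code
# vector; NA where the window touches an ambiguous base.
kmer_indices <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  idx <- rep(0, m)
  bad <- rep(FALSE, m)
  for (j in seq_len(k)) {
    cj <- codes[j:(j + m - 1L)]
    bad <- bad | is.na(cj)
    cj[is.na(cj)] <- 0L
    idx <- idx * 4 + cj
  }
  out <- as.integer(idx) + 1L
  out[bad] <- NA_integer_
  out
}

# All k-mers in index order consistent with kmer_indices()
# (first base is the most significant digit).
all_kmers <- function(k) {
  grid <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; we need the last position
  # fastest so that index = sum(code * 4^(k-j)) matches.
  ord <- do.call(paste0, rev(grid))
  ord
}

# Index (1-based) of k-mer strings under the same encoding.
kmer_to_index <- function(kmers) {
  k <- nchar(kmers[1L])
  vapply(kmers, function(s) {
    codes <- dna_codes(s)
    if (anyNA(codes) || length(codes) != k) return(NA_integer_)
    as.integer(sum(codes * 4^((k - 1L):0L))) + 1L
  }, integer(1L), USE.NAMES = FALSE)
}

# substring() wrapper returning NA-context-free uppercase windows.
seq_window <- function(seq, start0, width) {
  substr(seq, start0 + 1L, start0 + width)
}

info_log <- function(fmt, ...) {
  if (isTRUE(getOption("metameth.quiet", TRUE))) return(invisible(NULL))
  message(sprintf(fmt, ...))
  invisible(NULL)
}
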