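#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`,
#' and restores the previous state so library functions never perturb
#' the session RNG. A `NULL` seed evaluates `code` under the current
#' stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Random DNA sequence
#'
#' @param n Length in bases.
#' @return A single uppercase DNA string drawn uniformly over A/C/G/T
#'   from the current RNG stream.
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of character DNA sequences
#'
#' @param x Character vector of DNA strings (IUPAC letters).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' All k-mers of a sequence
#'
#' @param seq A single DNA string.
#' @param k k-mer length.
#' @return Character vector of the `nchar(seq) - k + 1` substrings of
#'   length `k`, in order; empty when the sequence is shorter than `k`.
#' @keywords internal
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

# Point mutations at a fixed per-base rate; substitutions only, never
# to the same base. Uses the current RNG stream.
mutate_dna <- function(seq, rate) {
  n <- nchar(seq)
  if (n == 0L || rate <= 0) return(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- bases[bases != chars[p]]
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  paste(chars, collapse = "")
}

# Extract substrings of one long string at vectorised start positions.
substr_many <- function(seq, start0, width) {
  substring(seq, start0 + 1L, start0 + width)
}
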