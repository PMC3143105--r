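#' @keywords internal
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

READ_CLASSES <- c("PR19_A10", "PR19_U1", "OTHER_19MER",
                  "P_PIRNA", "S_PIRNA", "PIRNA_AMBIGUOUS", "OTHER")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet A, C, G, T, N.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Extract reference slice on 0-based half-open coordinates, padding positions
# outside [0, nchar(ref)) with N.  `ref` is a single sequence string.
ref_slice <- function(ref, start, end) {
  L <- nchar(ref)
  pad_left <- pmax(0L, pmin(end, 0L) - start)
  pad_right <- pmax(0L, end - pmax(start, L))
  s <- pmax(start, 0L)
  e <- pmin(end, L)
  core <- substring(ref, s + 1L, e)
  core[e < s] <- ""
  paste0(strrep("N", pad_left), core, strrep("N", pad_right))
}

# 5' end reference coordinate of an alignment: leftmost base for '+',
# rightmost base for '-' (0-based).
five_prime_coord <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

# Run code with a private RNG stream so package randomness never perturbs
# (nor depends on) the caller's .Random.seed beyond the documented seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a per-stage seed from a global seed; keeps values in 32-bit range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 7919 + sum(utf8ToInt(stage))) %% 2147483647
}

check_alphabet <- function(seqs, what = "sequence") {
  bad <- grep("[^ACGTN]", seqs)
  if (length(bad)) {
    stop(sprintf("%s %d contains characters outside A/C/G/T/N", what, bad[1]),
         call. = FALSE)
  }
  invisible(TRUE)
}
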