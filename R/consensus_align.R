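# Self-contained short-read mapper for small references (repeat consensus
# sequences, synthetic genomes).  End-to-end, substitutions only, both
# strands, with a multi-hit suppression cap — the behaviour of an external
# -v-mode aligner at desk scale.  Candidate placements come from
# Biostrings::matchPattern; mismatches are then recounted under the rule
# that N never matches anything, and placements above the cap are filtered.

#' Build the composite LTR-internal-LTR repeat reference
#'
#' The internal repeat sequence is flanked on both sides by a copy of the
#' LTR, giving an LTR-containing consensus for mapping.
#'
#' @param ltr_sequence LTR sequence (non-empty DNA string).
#' @param internal_sequence Internal repeat sequence.
#' @return The concatenated sequence `LTR + internal + LTR`.
#' @export
build_composite_reference <- function(ltr_sequence, internal_sequence) {
  if (!nzchar(ltr_sequence) || !nzchar(internal_sequence))
    stop("LTR and internal sequences must be non-empty", call. = FALSE)
  paste0(ltr_sequence, internal_sequence, ltr_sequence)
}

# Mismatch count between a read and a same-length reference slice,
# with N (on either side) counting as a mismatch.
count_mismatches <- function(read, slice) {
  a <- strsplit(read, "", fixed = TRUE)[[1]]
  b <- strsplit(slice, "", fixed = TRUE)[[1]]
  sum(a != b | a == "N" | b == "N")
}

# All end-to-end placements of `read_seq` on one reference sequence
# (character string) with <= max_mismatches substitutions, both strands.
map_read_one <- function(read_seq, ref_seq, max_mismatches) {
  subject <- Biostrings::DNAString(ref_seq)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") read_seq else revcomp(read_seq)
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  max.mismatch = max_mismatches,
                                  with.indels = FALSE, fixed = TRUE)
    if (!length(m)) next
    start0 <- Biostrings::start(m) - 1L
    end0 <- Biostrings::end(m)
    mm <- vapply(seq_along(m), function(i)
      count_mismatches(pat, ref_slice(ref_seq, start0[i], end0[i])), integer(1))
    keep <- mm <= max_mismatches
    if (!any(keep)) next
    hits[[strand]] <- data.frame(start = start0[keep], end = end0[keep],
                                 strand = strand, mismatches = mm[keep],
                                 stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, unname(hits))
}

#' Map one read against a reference set
#'
#' Finds all end-to-end placements of the read on either strand of every
#' reference with at most `max_mismatches` substitutions (no indels).  N in
#' the read or reference never counts as a match.  If the total number of
#' placements exceeds `max_hits` the read is suppressed: an empty result is
#' returned with attribute `exceeded = TRUE`.
#'
#' @param read A read data frame row (`id`, `seq`, `count`) or a bare
#'   sequence string.
#' @param reference A `ReferenceSet` (named character vector).
#' @param max_mismatches 0, 1 or 2.
#' @param max_hits Multi-hit suppression cap.
#' @return Alignment data frame (possibly empty).
#' @export
map_read <- function(read, reference, max_mismatches = 0L, max_hits = 50000L) {
  reference <- as_reference_set(reference)
  if (is.character(read) && is.null(dim(read))) {
    read <- data.frame(id = "read", seq = toupper(read[1]), count = 1L,
                       stringsAsFactors = FALSE)
  }
  stopifnot(max_mismatches %in% 0:2)
  per_ref <- lapply(names(reference), function(rn) {
    if (nchar(read$seq) > nchar(reference[[rn]])) return(NULL)
    h <- map_read_one(read$seq, reference[[rn]], max_mismatches)
    if (!nrow(h)) return(NULL)
    data.frame(read_id = read$id, ref_id = rn, h, seq = read$seq,
               count = read$count, stringsAsFactors = FALSE)
  })
  per_ref <- per_ref[!vapply(per_ref, is.null, logical(1))]
  out <- if (length(per_ref)) do.call(rbind, per_ref) else empty_alignments()
  out <- out[, names(empty_alignments())]
  if (nrow(out) > max_hits) {
    res <- empty_alignments()
    attr(res, "exceeded") <- TRUE
    return(res)
  }
  attr(out, "exceeded") <- FALSE
  rownames(out) <- NULL
  out
}

#' Map a read library against a reference set
#'
#' Applies [map_read()] per read and reports unmapped and suppressed reads.
#'
#' @param reads Read data frame (`id`, `seq`, `count`).
#' @param references `ReferenceSet`.
#' @param max_mismatches Substitution budget (0-2).
#' @param max_hits Multi-hit suppression cap.
#' @return List with `alignments` (one row per placement) and `unmapped`
#'   (data frame `read_id`, `reason` in `no_hit`/`exceeded_max_hits`).
#' @export
map_library <- function(reads, references, max_mismatches = 0L,
                        max_hits = 50000L) {
  references <- as_reference_set(references)
  alns <- vector("list", nrow(reads))
  unmapped <- list()
  for (i in seq_len(nrow(reads))) {
    a <- map_read(reads[i, , drop = FALSE], references, max_mismatches, max_hits)
    if (nrow(a)) {
      alns[[i]] <- a
    } else {
      reason <- if (isTRUE(attr(a, "exceeded"))) "exceeded_max_hits" else "no_hit"
      unmapped[[length(unmapped) + 1L]] <-
        data.frame(read_id = reads$id[i], reason = reason,
                   stringsAsFactors = FALSE)
    }
  }
  alns <- alns[!vapply(alns, is.null, logical(1))]
  list(
    alignments = if (length(alns)) do.call(rbind, alns) else empty_alignments(),
    unmapped = if (length(unmapped)) do.call(rbind, unmapped) else
      data.frame(read_id = character(0), reason = character(0),
                 stringsAsFactors = FALSE))
}

#' Two-pass mapping: repeat database then consensus
#'
#' Pass 1 maps exactly (0 mismatches, large `max_hits`) against a repeat
#' sequence database to select reads likely to originate from the repeat
#' family; pass 2 remaps the selected reads to the consensus reference with
#' a relaxed mismatch budget.
#'
#' @param reads Read data frame.
#' @param repeat_db `ReferenceSet` of genomic repeat copies (pass 1).
#' @param consensus `ReferenceSet` of consensus sequence(s) (pass 2).
#' @param pass1_max_hits Multi-hit cap for pass 1 (default 50000).
#' @param pass2_max_mismatches Mismatch budget for pass 2 (default 2).
#' @param pass2_max_hits Multi-hit cap for pass 2 (default 10).
#' @return List with `alignments` (pass-2 placements), `pass1_ids` (ids that
#'   survived pass 1) and `unmapped` reports from both passes.
#' @export
map_two_pass <- function(reads, repeat_db, consensus,
                         pass1_max_hits = 50000L, pass2_max_mismatches = 2L,
                         pass2_max_hits = 10L) {
  p1 <- map_library(reads, repeat_db, max_mismatches = 0L,
                    max_hits = pass1_max_hits)
  keep_ids <- unique(p1$alignments$read_id)
  p2_in <- reads[reads$id %in% keep_ids, , drop = FALSE]
  p2 <- map_library(p2_in, consensus, max_mismatches = pass2_max_mismatches,
                    max_hits = pass2_max_hits)
  list(alignments = p2$alignments, pass1_ids = keep_ids,
       unmapped_pass1 = p1$unmapped, unmapped_pass2 = p2$unmapped)
}
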