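# Read-exclusion rules applied before mapping.  Three filters: homopolymer
# runs, a tRNA-derived fragment, and simple-repeat patterns that cause
# mapping artefacts against LINE-internal repeats (LINE mode only).

TRNA_FRAGMENT <- "CCGGGTTTCGGCACC"

SIMPLE_REPEATS <- c(strrep("GGA", 4), strrep("CCT", 4),
                    strrep("GAA", 4), strrep("CTT", 4))

#' Test for a long homopolymer run
#'
#' TRUE when some single-base run is strictly longer than `max_run`
#' (i.e. run length >= max_run + 1).
#'
#' @param sequence Character vector of DNA sequences.
#' @param max_run Longest permitted run (default 8).
#' @return Logical vector.
#' @export
has_long_homopolymer <- function(sequence, max_run = 8L) {
  stopifnot(all(nzchar(sequence)))
  grepl(sprintf("(.)\\1{%d}", max_run), sequence, perl = TRUE)
}

#' Test for the tRNA-derived contaminant fragment
#'
#' Matches the fragment CCGGGTTTCGGCACC as a substring; by default the
#' reverse complement is also searched (conservative contamination filter).
#'
#' @param sequence Character vector of DNA sequences.
#' @param both_strands Also match the reverse-complement pattern.
#' @return Logical vector.
#' @export
matches_trna_fragment <- function(sequence, both_strands = TRUE) {
  hit <- grepl(TRNA_FRAGMENT, sequence, fixed = TRUE)
  if (both_strands) hit <- hit | grepl(revcomp(TRNA_FRAGMENT), sequence,
                                       fixed = TRUE)
  hit
}

#' Test for simple-repeat patterns
#'
#' TRUE when any of (GGA)4, (CCT)4, (GAA)4, (CTT)4 occurs as a substring.
#' The pipeline applies this rule only in LINE mode.
#'
#' @param sequence Character vector of DNA sequences.
#' @param patterns Patterns to search (full repeat units).
#' @return Logical vector.
#' @export
matches_simple_repeat <- function(sequence, patterns = SIMPLE_REPEATS) {
  hit <- rep(FALSE, length(sequence))
  for (p in patterns) hit <- hit | grepl(p, sequence, fixed = TRUE)
  hit
}

#' Filter a read library by the pre-mapping exclusion rules
#'
#' A read is removed if any active rule fires: homopolymer runs > `max_run`,
#' the tRNA fragment (both rules always active), and simple repeats in
#' `mode = "line"` only.  Removal counts are attributed to the first firing
#' rule in that order.
#'
#' @param reads Read data frame (`id`, `seq`, `count`).
#' @param mode `"general"` or `"line"`.
#' @param max_run Homopolymer threshold.
#' @param trna_both_strands Match the tRNA fragment in both orientations.
#' @return List with `kept` (read data frame) and `removed` (data frame of
#'   per-rule record and copy counts).
#' @export
filter_reads <- function(reads, mode = c("general", "line"), max_run = 8L,
                         trna_both_strands = TRUE) {
  mode <- match.arg(mode)
  n <- nrow(reads)
  hp <- if (n) has_long_homopolymer(reads$seq, max_run) else logical(0)
  trna <- if (n) matches_trna_fragment(reads$seq, trna_both_strands) else logical(0)
  rep4 <- if (n && mode == "line") matches_simple_repeat(reads$seq) else
    rep(FALSE, n)
  first_rule <- rep(NA_character_, n)
  first_rule[rep4] <- "simple_repeat"
  first_rule[trna] <- "trna_fragment"
  first_rule[hp] <- "homopolymer"
  drop <- !is.na(first_rule)
  removed <- data.frame(
    rule = c("homopolymer", "trna_fragment", "simple_repeat"),
    records = c(sum(first_rule == "homopolymer", na.rm = TRUE),
                sum(first_rule == "trna_fragment", na.rm = TRUE),
                sum(first_rule == "simple_repeat", na.rm = TRUE)),
    copies = c(sum(reads$count[which(first_rule == "homopolymer")]),
               sum(reads$count[which(first_rule == "trna_fragment")]),
               sum(reads$count[which(first_rule == "simple_repeat")])),
    stringsAsFactors = FALSE)
  kept <- reads[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}
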