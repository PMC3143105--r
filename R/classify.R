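# The core computation: assign each aligned read to the pr19RNA / primary
# piRNA / secondary piRNA classes from its length, internal bases and
# flanking reference bases.
#
# Motifs (read positions 1 and 10 of the motif notation are indices 0 and 9):
#   pr19RNA (A10):  19-nt read, downstream flank = V N8 A (no U immediately
#                   downstream, A 10 nt downstream of the 3' end)
#   pr19RNA (U1):   19-nt read with U immediately downstream of the 3' end
#                   (released by secondary-piRNA-guided cleavage)
#   primary piRNA:  24-30 nt, U at position 1, not A at position 10 (U N8 B)
#   secondary piRNA: 24-30 nt, not U at position 1, A at position 10 (V N8 A)
# 24-30-nt reads satisfying both or neither motif are PIRNA_AMBIGUOUS so the
# classification is total.

#' Attach reference flanks to alignments
#'
#' For every alignment, extracts `F` bases of upstream and downstream
#' reference sequence in read orientation: for minus-strand alignments the
#' downstream flank is the reverse complement of `reference[start - F, start)`.
#' Positions beyond the reference edge are filled with N.  `down_flank`
#' position 1 is the base immediately 3' of the read; position `F` is the
#' F-th downstream base.
#'
#' @param alignments Alignment data frame.
#' @param reference `ReferenceSet` covering the alignments' `ref_id`s.
#' @param F Flank length (default 10).
#' @return The alignment data frame with `up_flank` and `down_flank` columns.
#' @export
extract_flanks <- function(alignments, reference, F = 10L) {
  reference <- as_reference_set(reference)
  n <- nrow(alignments)
  up <- character(n)
  down <- character(n)
  for (rn in unique(alignments$ref_id)) {
    idx <- which(alignments$ref_id == rn)
    ref <- reference[[rn]]
    if (is.null(ref)) stop("reference not found: ", rn, call. = FALSE)
    s <- alignments$start[idx]
    e <- alignments$end[idx]
    plus <- alignments$strand[idx] == "+"
    if (any(plus)) {
      # '+' strand: upstream is left of the read, downstream right of it.
      up[idx[plus]] <- ref_slice(ref, s[plus] - F, s[plus])
      down[idx[plus]] <- ref_slice(ref, e[plus], e[plus] + F)
    }
    if (any(!plus)) {
      # '-' strand: read orientation flips both flanks onto the other side.
      up[idx[!plus]] <- revcomp(ref_slice(ref, e[!plus], e[!plus] + F))
      down[idx[!plus]] <- revcomp(ref_slice(ref, s[!plus] - F, s[!plus]))
    }
  }
  alignments$up_flank <- up
  alignments$down_flank <- down
  alignments
}

#' Classify flanked reads into pr19RNA / piRNA classes
#'
#' Vectorised, total classification.  19-nt reads: U immediately downstream
#' gives `PR19_U1` (which takes precedence, since the A10 motif's V excludes
#' U); otherwise A at downstream position 10 gives `PR19_A10`; otherwise
#' `OTHER_19MER`.  A 19mer whose 10th downstream base is N (reference edge)
#' is `OTHER_19MER` with the `edge` flag set.  24-30-nt reads: 5' U without
#' A10 is `P_PIRNA`; A10 without 5' U is `S_PIRNA`; both or neither is
#' `PIRNA_AMBIGUOUS`.  Everything else is `OTHER`.
#'
#' @param flanked Data frame from [extract_flanks()] (needs `seq`,
#'   `down_flank` with flank length >= 10).
#' @return The input with `class` (factor over the class levels) and `edge`
#'   (logical) columns.
#' @export
classify_reads <- function(flanked) {
  n <- nrow(flanked)
  if (n && any(nchar(flanked$down_flank) < 10L))
    stop("classification requires down_flank length >= 10", call. = FALSE)
  len <- nchar(flanked$seq)
  down1 <- substr(flanked$down_flank, 1L, 1L)
  down10 <- substr(flanked$down_flank, 10L, 10L)
  read1 <- substr(flanked$seq, 1L, 1L)
  read10 <- substr(flanked$seq, 10L, 10L)
  cls <- rep("OTHER", n)
  edge <- rep(FALSE, n)
  is19 <- len == 19L
  cls[is19] <- "OTHER_19MER"
  cls[is19 & down1 == "T"] <- "PR19_U1"
  a10 <- is19 & down1 != "T" & down10 == "A"
  cls[a10] <- "PR19_A10"
  at_edge <- is19 & down1 != "T" & down10 == "N"
  cls[at_edge] <- "OTHER_19MER"
  edge[at_edge] <- TRUE
  pir <- len >= 24L & len <= 30L
  u1 <- read1 == "T"
  ia10 <- read10 == "A"
  cls[pir & u1 & !ia10] <- "P_PIRNA"
  cls[pir & !u1 & ia10] <- "S_PIRNA"
  cls[pir & (u1 == ia10)] <- "PIRNA_AMBIGUOUS"
  flanked$class <- factor(cls, levels = READ_CLASSES)
  flanked$edge <- edge
  flanked
}

#' Classify an aligned library and summarise per class
#'
#' Convenience composition of [extract_flanks()] and [classify_reads()],
#' plus a per-class, per-strand, per-length summary table.
#'
#' @param alignments Alignment data frame.
#' @param reference `ReferenceSet`.
#' @param F Flank length (default 10).
#' @param weight `"copy"` (counts weighted by read copy number, the default)
#'   or `"unique"` (each distinct aligned sequence counted once).
#' @return List with `reads` (classified alignment data frame) and `summary`
#'   (data frame `class`, `strand`, `length`, `count`).
#' @export
classify_library <- function(alignments, reference, F = 10L,
                             weight = c("copy", "unique")) {
  weight <- match.arg(weight)
  cl <- classify_reads(extract_flanks(alignments, reference, F))
  w <- if (weight == "copy") cl$count else rep(1L, nrow(cl))
  if (nrow(cl)) {
    summary <- stats::aggregate(
      w, by = list(class = cl$class, strand = cl$strand,
                   length = nchar(cl$seq)), FUN = sum)
    names(summary)[4] <- "count"
    summary <- summary[order(summary$class, summary$strand, summary$length), ]
    rownames(summary) <- NULL
  } else {
    summary <- data.frame(class = factor(character(0), levels = READ_CLASSES),
                          strand = character(0), length = integer(0),
                          count = numeric(0))
  }
  list(reads = cl, summary = summary)
}
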