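# Signature analytics: length histograms, Shannon sequence logos extended
# past the 3' end, 5'-end offset densities between read classes, ping-pong
# adjacency-configuration counting, per-position 5'-end coverage, RPM
# normalisation and the ddCT fold-change utility.

#' Copy-weighted read length histogram
#'
#' @param classified Classified alignment data frame.
#' @param by_strand Tabulate sense and antisense separately.
#' @param weight `"copy"` or `"unique"`.
#' @return Data frame `length`, `strand` (if `by_strand`), `count`.
#' @export
length_histogram <- function(classified, by_strand = TRUE,
                             weight = c("copy", "unique")) {
  weight <- match.arg(weight)
  if (!nrow(classified)) {
    return(if (by_strand)
      data.frame(length = integer(0), strand = character(0), count = numeric(0))
      else data.frame(length = integer(0), count = numeric(0)))
  }
  w <- if (weight == "copy") classified$count else rep(1L, nrow(classified))
  by <- list(length = nchar(classified$seq))
  if (by_strand) by$strand <- classified$strand
  out <- stats::aggregate(w, by = by, FUN = sum)
  names(out)[ncol(out)] <- "count"
  out[do.call(order, out[setdiff(names(out), "count")]), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# Build the position x read character matrix for the logo: reads anchored at
# their 5' ends, extended upstream from up_flank and, past each read's own
# 3' end, from down_flank.  Mixed-length reads leave N (excluded) in the
# unreachable middle positions.
logo_char_matrix <- function(flanked, upstream_ext, downstream_ext) {
  lens <- nchar(flanked$seq)
  L <- max(lens)
  Fup <- min(nchar(flanked$up_flank))
  Fdn <- min(nchar(flanked$down_flank))
  if (upstream_ext > Fup || downstream_ext > Fdn)
    stop("extension exceeds available flank length", call. = FALSE)
  ncol <- upstream_ext + L + downstream_ext
  full <- paste0(
    substring(flanked$up_flank, nchar(flanked$up_flank) - upstream_ext + 1L),
    flanked$seq,
    substring(flanked$down_flank, 1L, downstream_ext))
  mat <- matrix("N", nrow = nrow(flanked), ncol = ncol)
  for (i in seq_len(nrow(flanked))) {
    ch <- strsplit(full[i], "", fixed = TRUE)[[1]]
    # read body occupies columns up to its own length; its downstream
    # extension is appended immediately after its own 3' end.
    mat[i, seq_along(ch)] <- ch
  }
  mat
}

#' Shannon sequence logo with 3' extension
#'
#' Aligns reads at their 5' ends and computes per-position base frequencies
#' and information content 2 - H, where H is the Shannon entropy of the
#' column in bits.  Columns are: `upstream_ext` positions of upstream flank,
#' the read positions, and `downstream_ext` positions taken from each read's
#' own downstream flank (appended directly after its 3' end).  N bases are
#' excluded from a column's denominator; an all-N column has information NA.
#'
#' @param flanked_reads Data frame from [extract_flanks()].
#' @param upstream_ext,downstream_ext Number of flanking positions included.
#' @param weight `"copy"` or `"unique"`.
#' @return List of class `logo_matrix`: `freq` (4 x P matrix, rows A/C/G/T),
#'   `information` (bits, length P), `n` (non-N observations per column),
#'   `positions` (1-based read positions; flank positions are <= 0 upstream).
#' @export
sequence_logo <- function(flanked_reads, upstream_ext = 0L,
                          downstream_ext = 10L, weight = c("copy", "unique")) {
  weight <- match.arg(weight)
  stopifnot(nrow(flanked_reads) > 0)
  mat <- logo_char_matrix(flanked_reads, upstream_ext, downstream_ext)
  w <- if (weight == "copy") flanked_reads$count else rep(1L, nrow(flanked_reads))
  P <- ncol(mat)
  freq <- matrix(0, nrow = 4, ncol = P, dimnames = list(c("A", "C", "G", "T")))
  n <- numeric(P)
  for (j in seq_len(P)) {
    col <- mat[, j]
    keep <- col != "N"
    n[j] <- sum(w[keep])
    if (n[j] > 0) {
      tab <- tapply(w[keep], factor(col[keep], levels = c("A", "C", "G", "T")),
                    sum)
      tab[is.na(tab)] <- 0
      freq[, j] <- tab / n[j]
    }
  }
  info <- apply(freq, 2, function(p) {
    nz <- p[p > 0]
    2 - (-sum(nz * log2(nz)))
  })
  info[n == 0] <- NA_real_
  structure(list(freq = freq, information = info, n = n,
                 positions = seq_len(P) - upstream_ext),
            class = "logo_matrix")
}

#' 5'-end offset density between two read classes
#'
#' For every anchor read, tallies the 5' ends of query reads at signed
#' offsets measured in the anchor's reading direction: the 5' coordinate of
#' a minus-strand read is its rightmost base, and for a minus-strand anchor
#' positive offsets run leftward along the reference.  In the ping-pong
#' geometry a same-sense secondary piRNA immediately adjacent to a 19mer
#' sits at +19 and an antisense partner piRNA at +28.
#'
#' @param anchors,queries Classified alignment data frames sharing
#'   reference ids.
#' @param W Window radius (default 60).
#' @param normalise `"window"` (proportions of the tallied query mass within
#'   the window, default) or `"library"` (proportions of the total query
#'   copy count).
#' @param dedup_anchors Count each distinct anchor (reference, strand, 5'
#'   position) once (default TRUE).
#' @return Data frame `offset` (-W..W), `count`, `proportion`.
#' @export
offset_density <- function(anchors, queries, W = 60L,
                           normalise = c("window", "library"),
                           dedup_anchors = TRUE) {
  normalise <- match.arg(normalise)
  a5 <- five_prime_coord(anchors$start, anchors$end, anchors$strand)
  q5 <- five_prime_coord(queries$start, queries$end, queries$strand)
  adir <- ifelse(anchors$strand == "+", 1L, -1L)
  akey <- paste(anchors$ref_id, anchors$strand, a5)
  if (dedup_anchors) {
    keep <- !duplicated(akey)
    a5 <- a5[keep]; adir <- adir[keep]
    aref <- anchors$ref_id[keep]
  } else aref <- anchors$ref_id
  counts <- stats::setNames(numeric(2 * W + 1), as.character(-W:W))
  for (i in seq_along(a5)) {
    sel <- queries$ref_id == aref[i]
    if (!any(sel)) next
    off <- (q5[sel] - a5[i]) * adir[i]
    inw <- off >= -W & off <= W
    if (!any(inw)) next
    tal <- tapply(queries$count[sel][inw], off[inw], sum)
    counts[as.character(names(tal))] <- counts[as.character(names(tal))] +
      as.numeric(tal)
  }
  denom <- if (normalise == "window") sum(counts) else sum(queries$count)
  data.frame(offset = -W:W, count = as.numeric(counts),
             proportion = if (denom > 0) as.numeric(counts) / denom
             else rep(0, 2 * W + 1))
}

# 5'-position lookup sets per (ref, strand) for piRNA-sized and 19-nt reads.
position_sets <- function(classified, lengths_min, lengths_max) {
  len <- nchar(classified$seq)
  sel <- len >= lengths_min & len <= lengths_max
  sub <- classified[sel, , drop = FALSE]
  p5 <- five_prime_coord(sub$start, sub$end, sub$strand)
  split(p5, paste(sub$ref_id, sub$strand))
}

#' Count ping-pong adjacency configurations of 19mers
#'
#' For each 19mer with 5' coordinate `s` on strand `sigma` (offsets measured
#' in its own reading direction), flags (i) a same-strand piRNA-sized
#' (24-30 nt) read with 5' end at `s + 19` (immediately adjacent) and (ii)
#' an opposite-strand piRNA-sized read with 5' coordinate at `s + 28`
#' (10 nt past the 19mer's 3' terminal base), disregarding whether the
#' piRNA is primary or secondary.  Also reports the reciprocal statistics:
#' the fraction of secondary piRNAs immediately adjacent to a 19mer and the
#' fraction of primary piRNAs whose 5' end lies 10 nt downstream of an
#' opposite-strand 19mer's 3' end.
#'
#' @param classified Classified alignment data frame on one or more
#'   references.
#' @param weight `"copy"` or `"unique"`.
#' @return List: `per_read` (19mer rows plus `adjacent`, `antisense_partner`,
#'   `any_config` flags), `summary` (per strand: totals, flagged counts,
#'   percentages), `reciprocal` (secondary/primary piRNA statistics).
#' @export
count_configurations <- function(classified, weight = c("copy", "unique")) {
  weight <- match.arg(weight)
  len <- nchar(classified$seq)
  is19 <- len == 19L
  mers <- classified[is19, , drop = FALSE]
  pir_pos <- position_sets(classified, 24L, 30L)
  mer_pos <- position_sets(classified, 19L, 19L)
  other_strand <- function(s) if (s == "+") "-" else "+"
  has_at <- function(sets, ref, strand, pos) {
    p <- sets[[paste(ref, strand)]]
    !is.null(p) && pos %in% p
  }
  n <- nrow(mers)
  adjacent <- logical(n)
  partner <- logical(n)
  if (n) {
    s5 <- five_prime_coord(mers$start, mers$end, mers$strand)
    dir <- ifelse(mers$strand == "+", 1L, -1L)
    for (i in seq_len(n)) {
      adjacent[i] <- has_at(pir_pos, mers$ref_id[i], mers$strand[i],
                            s5[i] + 19L * dir[i])
      partner[i] <- has_at(pir_pos, mers$ref_id[i],
                           other_strand(mers$strand[i]),
                           s5[i] + 28L * dir[i])
    }
  }
  mers$adjacent <- adjacent
  mers$antisense_partner <- partner
  mers$any_config <- adjacent | partner
  w <- if (weight == "copy") mers$count else rep(1L, max(n, 0L))
  summary <- do.call(rbind, lapply(c("+", "-"), function(s) {
    sel <- mers$strand == s
    tot <- sum(w[sel])
    data.frame(strand = s, total = tot,
               adjacent = sum(w[sel & mers$adjacent]),
               antisense_partner = sum(w[sel & mers$antisense_partner]),
               any_config = sum(w[sel & mers$any_config]),
               pct_any = if (tot > 0) 100 * sum(w[sel & mers$any_config]) / tot
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  # Reciprocal: piRNAs relative to 19mers.
  pir <- classified[len >= 24L & len <= 30L, , drop = FALSE]
  wp <- if (weight == "copy") pir$count else rep(1L, nrow(pir))
  p5 <- five_prime_coord(pir$start, pir$end, pir$strand)
  pdir <- ifelse(pir$strand == "+", 1L, -1L)
  s_sel <- pir$class == "S_PIRNA"
  p_sel <- pir$class == "P_PIRNA"
  s_adj <- logical(nrow(pir))
  p_down <- logical(nrow(pir))
  for (i in seq_len(nrow(pir))) {
    if (s_sel[i]) {
      # a same-strand 19mer ends immediately 5' of this secondary piRNA
      s_adj[i] <- has_at(mer_pos, pir$ref_id[i], pir$strand[i],
                         p5[i] - 19L * pdir[i])
    }
    if (p_sel[i]) {
      # an opposite-strand 19mer whose 3' end lies 10 nt upstream of this
      # primary piRNA's 5' end: 19mer 5' coordinate = p5 + 28 * pdir
      p_down[i] <- has_at(mer_pos, pir$ref_id[i],
                          other_strand(pir$strand[i]),
                          p5[i] + 28L * pdir[i])
    }
  }
  reciprocal <- data.frame(
    statistic = c("s_piRNA_adjacent_to_19mer",
                  "p_piRNA_5p_10nt_downstream_of_19mer_3p"),
    total = c(sum(wp[s_sel]), sum(wp[p_sel])),
    flagged = c(sum(wp[s_sel & s_adj]), sum(wp[p_sel & p_down])),
    stringsAsFactors = FALSE)
  reciprocal$pct <- ifelse(reciprocal$total > 0,
                           100 * reciprocal$flagged / reciprocal$total,
                           NA_real_)
  list(per_read = mers, summary = summary, reciprocal = reciprocal)
}

#' Format a count pair as a percentage
#'
#' The formatter used by the configuration-counting report: `100 * n / total`
#' rounded to `digits` decimal places.
#'
#' @param n,total Numerator and denominator counts.
#' @param digits Decimal places (default 0).
#' @return Numeric percentage(s).
#' @export
format_pct <- function(n, total, digits = 0) {
  round(100 * n / total, digits)
}

#' Per-position 5'-end coverage density
#'
#' @param classified Classified alignment data frame.
#' @param reference `ReferenceSet` (single sequence or one of several; per
#'   reference arrays are returned).
#' @param classes Read classes to include (default all present).
#' @param use_five_prime_only Use only the 5'-end base (default TRUE); when
#'   FALSE the full read footprint is accumulated.
#' @param weight `"copy"` or `"unique"`.
#' @return Nested list `ref -> class -> strand -> numeric vector` of length
#'   `nchar(reference)`.
#' @export
coverage_density <- function(classified, reference, classes = NULL,
                             use_five_prime_only = TRUE,
                             weight = c("copy", "unique")) {
  weight <- match.arg(weight)
  reference <- as_reference_set(reference)
  if (is.null(classes)) classes <- unique(as.character(classified$class))
  w <- if (weight == "copy") classified$count else rep(1L, nrow(classified))
  out <- list()
  for (rn in names(reference)) {
    L <- nchar(reference[[rn]])
    out[[rn]] <- list()
    for (cl in classes) {
      out[[rn]][[cl]] <- list()
      for (s in c("+", "-")) {
        v <- numeric(L)
        sel <- which(classified$ref_id == rn &
                       as.character(classified$class) == cl &
                       classified$strand == s)
        for (i in sel) {
          if (use_five_prime_only) {
            p <- five_prime_coord(classified$start[i], classified$end[i], s)
            v[p + 1L] <- v[p + 1L] + w[i]
          } else {
            rng <- (classified$start[i] + 1L):classified$end[i]
            v[rng] <- v[rng] + w[i]
          }
        }
        out[[rn]][[cl]][[s]] <- v
      }
    }
  }
  out
}

#' Reads-per-million normalisation
#'
#' @param count Read count(s).
#' @param library_mappable_total Number of genomically mappable reads in the
#'   library (> 0).
#' @return `count * 1e6 / library_mappable_total`.
#' @export
rpm <- function(count, library_mappable_total) {
  if (!is.numeric(library_mappable_total) || library_mappable_total <= 0)
    stop("library_mappable_total must be > 0", call. = FALSE)
  count * 1e6 / library_mappable_total
}

#' Relative quantification by the 2^-ddCT method
#'
#' Fold change of a target in condition 1 relative to condition 2, each
#' normalised to a reference gene:
#' `2^-((ct_target_1 - ct_ref_1) - (ct_target_2 - ct_ref_2))`.
#'
#' @param ct_target_1,ct_ref_1 CT values for the target and reference gene
#'   in condition 1.
#' @param ct_target_2,ct_ref_2 Same for condition 2.
#' @return The fold change.
#' @export
fold_change_ddct <- function(ct_target_1, ct_ref_1, ct_target_2, ct_ref_2) {
  stopifnot(is.finite(ct_target_1), is.finite(ct_ref_1),
            is.finite(ct_target_2), is.finite(ct_ref_2))
  2^(-((ct_target_1 - ct_ref_1) - (ct_target_2 - ct_ref_2)))
}
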