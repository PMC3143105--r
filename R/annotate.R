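# Genome-wide 19mer annotation: random single-locus assignment of
# multi-mappers (reads at >= max_loci loci discarded), binning by the
# identity of the 10th downstream genomic base, and priority intersection
# of the 5'-end base with ordered annotation tracks.

#' Assign multi-mapping reads to single loci
#'
#' Reads mapping to `max_loci` or more loci are discarded (reported);
#' remaining reads are assigned one of their loci uniformly at random.
#' Deterministic for a fixed seed.
#'
#' @param alignments Alignment data frame; several rows per `read_id` mean
#'   several candidate loci.
#' @param max_loci Reads with at least this many loci are discarded
#'   (default 6, i.e. reads mapping to fewer than 6 loci are kept).
#' @param seed Integer seed for the random assignment.
#' @return List: `assigned` (one row per kept read), `discarded` (read ids
#'   with their locus counts), `n_unique`, `n_multi` (copy-weighted totals
#'   of retained uniquely and multiply mapping reads).
#' @export
assign_multimappers <- function(alignments, max_loci = 6L, seed = 1L) {
  if (!nrow(alignments)) {
    return(list(assigned = alignments,
                discarded = data.frame(read_id = character(0),
                                       n_loci = integer(0)),
                n_unique = 0, n_multi = 0))
  }
  loci_per_read <- table(alignments$read_id)
  too_many <- names(loci_per_read)[loci_per_read >= max_loci]
  keep <- !(alignments$read_id %in% too_many)
  kept <- alignments[keep, , drop = FALSE]
  assigned <- with_seed(seed, {
    idx <- split(seq_len(nrow(kept)), kept$read_id)
    pick <- vapply(idx, function(i)
      if (length(i) == 1L) i else i[sample.int(length(i), 1L)], integer(1))
    kept[sort(pick), , drop = FALSE]
  })
  first <- !duplicated(assigned$read_id)
  nl <- as.integer(loci_per_read[assigned$read_id[first]])
  cnt <- assigned$count[first]
  list(assigned = assigned,
       discarded = data.frame(read_id = too_many,
                              n_loci = as.integer(loci_per_read[too_many]),
                              stringsAsFactors = FALSE),
       n_unique = sum(cnt[nl == 1L]),
       n_multi = sum(cnt[nl > 1L]))
}

#' Identity of the 10th downstream genomic base
#'
#' For a plus-strand locus the base at `end + 9` (0-based); for a
#' minus-strand locus the complement of the base at `start - 10`.
#' Off-chromosome positions yield N.
#'
#' @param locus One-row data frame (`chrom` or `ref_id`, `start`, `end`,
#'   `strand`), or a data frame of many loci (vectorised).
#' @param genome `ReferenceSet`.
#' @return Character vector of bases in A/C/G/T/N.
#' @export
tenth_downstream_base <- function(locus, genome) {
  genome <- as_reference_set(genome)
  chrom <- if ("chrom" %in% names(locus)) locus$chrom else locus$ref_id
  if (any(!(chrom %in% names(genome))))
    stop("unknown chromosome: ", setdiff(chrom, names(genome))[1], call. = FALSE)
  if (any(locus$end - locus$start != 19L))
    warning("tenth_downstream_base applied to non-19-nt locus")
  out <- character(nrow(locus))
  plus <- locus$strand == "+"
  for (i in seq_len(nrow(locus))) {
    ref <- genome[[chrom[i]]]
    if (plus[i]) {
      out[i] <- ref_slice(ref, locus$end[i] + 9L, locus$end[i] + 10L)
    } else {
      out[i] <- revcomp(ref_slice(ref, locus$start[i] - 10L,
                                  locus$start[i] - 9L))
    }
  }
  out
}

#' Build an annotation track
#'
#' @param name Track name (e.g. `"repeats"`, `"clusters"`, `"genes"`).
#' @param priority Rank, 1 = highest.
#' @param intervals Interval data frame ([read_intervals_bed()]); the `name`
#'   column carries the category label (e.g. LINE, LTR, SINE for a repeat
#'   track).
#' @param category Fixed category for every interval of the track; when NULL
#'   the per-interval `name` is used.
#' @return A list of class `annotation_track`.
#' @export
annotation_track <- function(name, priority, intervals, category = NULL) {
  structure(list(name = name, priority = priority, intervals = intervals,
                 category = category), class = "annotation_track")
}

#' Annotate a locus against prioritised tracks
#'
#' Returns the category of the highest-priority track containing the
#' locus's 5'-end base; `"unannotated"` when no track matches.  A read
#' inside both a repeat and a piRNA cluster is annotated as the repeat when
#' the repeat track ranks higher — cluster and gene categories take only
#' reads not otherwise annotated.
#'
#' @param locus One-row (or many-row, vectorised) locus data frame with
#'   `chrom`/`ref_id`, `start`, `end`, `strand`.
#' @param tracks List of [annotation_track()] objects (any order; sorted by
#'   priority internally; priorities must be unique).
#' @return Character vector of categories.
#' @export
annotate_locus <- function(locus, tracks) {
  pri <- vapply(tracks, `[[`, numeric(1), "priority")
  if (anyDuplicated(pri)) stop("track priorities must be unique", call. = FALSE)
  tracks <- tracks[order(pri)]
  chrom <- if ("chrom" %in% names(locus)) locus$chrom else locus$ref_id
  pos <- five_prime_coord(locus$start, locus$end, locus$strand)
  out <- rep(NA_character_, nrow(locus))
  for (tr in tracks) {
    iv <- tr$intervals
    todo <- which(is.na(out))
    if (!length(todo)) break
    for (k in seq_len(nrow(iv))) {
      hit <- todo[chrom[todo] == iv$chrom[k] & pos[todo] >= iv$start[k] &
                    pos[todo] < iv$end[k]]
      if (length(hit)) {
        out[hit] <- if (is.null(tr$category)) iv$name[k] else tr$category
        todo <- setdiff(todo, hit)
      }
    }
  }
  out[is.na(out)] <- "unannotated"
  out
}

#' Genome-wide 19mer annotation table
#'
#' Composition of multi-mapper assignment, 10th-downstream-base binning and
#' priority annotation: rows are annotation categories, columns the
#' downstream-base bins A/C/G/T/N, entries copy-weighted read counts.
#'
#' @param alignments Genome alignment data frame (multiple rows per read
#'   allowed for multi-mappers).
#' @param genome `ReferenceSet`.
#' @param tracks List of [annotation_track()] objects.
#' @param seed Seed for the multi-mapper assignment.
#' @param max_loci Discard threshold passed to [assign_multimappers()].
#' @return List: `table` (category x base count matrix), `assigned`
#'   (annotated per-read data frame), `n_unique`, `n_multi`, `discarded`.
#' @export
annotate_genome_19mers <- function(alignments, genome, tracks, seed = 1L,
                                   max_loci = 6L) {
  asg <- assign_multimappers(alignments, max_loci = max_loci, seed = seed)
  a <- asg$assigned
  bases <- c("A", "C", "G", "T", "N")
  if (!nrow(a)) {
    tab <- matrix(0, nrow = 0, ncol = 5, dimnames = list(NULL, bases))
    return(list(table = tab, assigned = a, n_unique = 0, n_multi = 0,
                discarded = asg$discarded))
  }
  a$tenth_base <- tenth_downstream_base(a, genome)
  a$category <- annotate_locus(a, tracks)
  agg <- stats::aggregate(a$count,
                          by = list(category = a$category,
                                    base = factor(a$tenth_base, levels = bases)),
                          FUN = sum, drop = FALSE)
  agg$x[is.na(agg$x)] <- 0
  cats <- unique(agg$category)
  tab <- matrix(0, nrow = length(cats), ncol = 5,
                dimnames = list(cats, bases))
  tab[cbind(agg$category, as.character(agg$base))] <- agg$x
  list(table = tab, assigned = a, n_unique = asg$n_unique,
       n_multi = asg$n_multi, discarded = asg$discarded)
}
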