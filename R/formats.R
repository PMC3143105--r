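# Readers/writers for the external formats the pipeline touches.  All genomic
# coordinates are normalised to 0-based half-open intervals on ingestion; SAM
# (1-based) and wiggle (1-based) are converted at this boundary only.

#' Read small-RNA sequences from FASTA or FASTQ
#'
#' Sequences are uppercased and U is converted to T (reads are handled as
#' cDNA internally).  FASTQ qualities are discarded.  Identical sequences can
#' optionally be collapsed with summed copy counts.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param format `"auto"` (from the file extension), `"fasta"` or `"fastq"`.
#' @param collapse Collapse identical sequences, summing counts.
#' @param parse_counts Parse a trailing `_xN` copy-count suffix in record
#'   identifiers (the convention used by collapsed small-RNA libraries and by
#'   [simulate_library()]); otherwise every record has count 1.
#' @return A data frame with columns `id`, `seq`, `count`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           collapse = FALSE, parse_counts = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  ss <- tryCatch(Biostrings::readBStringSet(path, format = format),
                 error = function(e) {
                   stop(sprintf("failed to parse %s as %s: %s",
                                path, format, conditionMessage(e)),
                        call. = FALSE)
                 })
  seqs <- chartr("Uu", "Tt", as.character(ss))
  seqs <- toupper(seqs)
  check_alphabet(seqs, "record")
  if (!length(seqs)) warning("no sequences in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  counts <- rep(1L, length(seqs))
  if (parse_counts) {
    m <- regmatches(ids, regexpr("_x([0-9]+)$", ids))
    has <- lengths(regmatches(ids, gregexpr("_x[0-9]+$", ids))) > 0
    counts[has] <- as.integer(sub("^_x", "", m))
  }
  out <- data.frame(id = ids, seq = seqs, count = counts,
                    stringsAsFactors = FALSE)
  if (collapse && nrow(out)) {
    agg <- stats::aggregate(count ~ seq, data = out, FUN = sum)
    first_id <- out$id[!duplicated(out$seq)]
    names(first_id) <- out$seq[!duplicated(out$seq)]
    out <- data.frame(id = unname(first_id[agg$seq]), seq = agg$seq,
                      count = agg$count, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read a reference sequence set from FASTA
#'
#' @param path FASTA file.
#' @return A named character vector (a `ReferenceSet`): uppercase DNA with U
#'   converted to T, unique names, non-empty sequences.
#' @export
read_reference <- function(path) {
  df <- read_sequences(path, format = "fasta", parse_counts = FALSE)
  as_reference_set(stats::setNames(df$seq, df$id))
}

#' Validate and normalise a reference set
#'
#' @param x Named character vector of DNA sequences.
#' @return The validated named character vector.
#' @export
as_reference_set <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("reference sequences must be named", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("reference names must be unique", call. = FALSE)
  x <- toupper(chartr("Uu", "Tt", x))
  if (any(!nzchar(x))) stop("reference sequences must be non-empty", call. = FALSE)
  check_alphabet(x, "reference")
  x
}

# Canonical empty alignment table.
empty_alignments <- function() {
  data.frame(read_id = character(0), ref_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             mismatches = integer(0), seq = character(0), count = integer(0),
             stringsAsFactors = FALSE)
}

#' Import alignments from a minimal SAM file
#'
#' Accepts the restricted SAM dialect the pipeline emits: optional header,
#' FLAG bits 0x4/0x10, RNAME, POS, SEQ, and an all-match CIGAR (e.g. `19M`).
#' Records with indel/clip CIGARs or unmapped flags are skipped with a
#' warning; records whose RNAME is not in `references` are rejected.  For
#' reverse-strand records the stored read sequence is the reverse complement
#' of the SAM SEQ field, so `seq` always reads 5' to 3' along the read.
#' An optional `XC:i:` tag supplies the copy count (default 1).
#'
#' @param path SAM file.
#' @param references A `ReferenceSet` (named character vector).
#' @return Alignment data frame: `read_id`, `ref_id`, `start`, `end` (0-based
#'   half-open), `strand`, `mismatches` (NA when unknown), `seq`, `count`.
#' @export
read_alignments_sam <- function(path, references) {
  references <- as_reference_set(references)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  skipped_cigar <- 0L
  skipped_unmapped <- 0L
  skipped_ref <- 0L
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10) stop("malformed SAM record at line ", i, call. = FALSE)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) { skipped_unmapped <- skipped_unmapped + 1L; next }
    if (!grepl("^[0-9]+M$", f[6])) { skipped_cigar <- skipped_cigar + 1L; next }
    if (!(f[3] %in% names(references))) { skipped_ref <- skipped_ref + 1L; next }
    seq <- toupper(f[10])
    strand <- if (bitwAnd(flag, 16L) != 0L) "-" else "+"
    start <- as.integer(f[4]) - 1L
    count <- 1L
    xc <- grep("^XC:i:", f[-(1:11)], value = TRUE)
    if (length(xc)) count <- as.integer(sub("^XC:i:", "", xc[1]))
    recs[[i]] <- data.frame(
      read_id = f[1], ref_id = f[3], start = start,
      end = start + nchar(seq), strand = strand, mismatches = NA_integer_,
      seq = if (strand == "-") revcomp(seq) else seq, count = count,
      stringsAsFactors = FALSE)
  }
  if (skipped_cigar) warning(skipped_cigar, " record(s) skipped: non all-match CIGAR")
  if (skipped_unmapped) warning(skipped_unmapped, " unmapped record(s) skipped")
  if (skipped_ref) warning(skipped_ref, " record(s) rejected: RNAME not in references")
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs)) do.call(rbind, recs) else empty_alignments()
  attr(out, "skipped") <- c(cigar = skipped_cigar, unmapped = skipped_unmapped,
                            ref = skipped_ref)
  out
}

#' Write alignments as minimal SAM
#'
#' @param alignments Alignment data frame (see [read_alignments_sam()]).
#' @param references `ReferenceSet`, used for `@SQ` header lines.
#' @param path Output path.
#' @export
write_alignments_sam <- function(alignments, references, path) {
  references <- as_reference_set(references)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(references), nchar(references)))
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    seq_out <- ifelse(alignments$strand == "-", revcomp(alignments$seq),
                      alignments$seq)
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tXC:i:%d",
                    alignments$read_id, flag, alignments$ref_id,
                    alignments$start + 1L, nchar(alignments$seq), seq_out,
                    alignments$count)
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genomic intervals from BED (BED3 to BED6)
#'
#' @param path BED file.
#' @return Data frame `chrom`, `start`, `end` (0-based half-open), `name`,
#'   `score`, `strand` (`.` when absent).  Records with `start >= end` are
#'   rejected with a warning.
#' @export
read_intervals_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    name = character(0), score = numeric(0),
                    strand = character(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(out)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3)) stop("BED record with fewer than 3 fields at line ",
                       which(n < 3)[1], call. = FALSE)
  get <- function(k, default) vapply(fields, function(f)
    if (length(f) >= k) f[k] else default, character(1))
  out <- data.frame(
    chrom = get(1, ""), start = as.integer(get(2, NA)),
    end = as.integer(get(3, NA)), name = get(4, "."),
    score = suppressWarnings(as.numeric(get(5, "0"))),
    strand = get(6, "."), stringsAsFactors = FALSE)
  bad <- which(out$start >= out$end | !nzchar(out$chrom))
  if (length(bad)) {
    warning(length(bad), " BED record(s) rejected (start >= end or empty chrom)")
    out <- out[-bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write genomic intervals as BED6
#'
#' @param intervals Interval data frame (see [read_intervals_bed()]).
#' @param path Output path.
#' @export
write_intervals_bed <- function(intervals, path) {
  score <- intervals$score
  score[is.na(score)] <- 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", intervals$chrom, intervals$start,
                   intervals$end, intervals$name,
                   format(score, trim = TRUE, scientific = FALSE),
                   intervals$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-position density as fixedStep wiggle
#'
#' @param values Numeric vector of per-position values (finite).
#' @param chrom Chromosome / reference name.
#' @param path Output path.
#' @param start 0-based start position of `values[1]` (written 1-based).
#' @export
write_wiggle <- function(values, chrom, path, start = 0L) {
  if (any(!is.finite(values))) stop("wiggle values must be finite", call. = FALSE)
  hdr <- sprintf("fixedStep chrom=%s start=%d step=1", chrom, start + 1L)
  writeLines(c(hdr, format(values, trim = TRUE, scientific = FALSE)), path)
  invisible(path)
}

#' Write a table as TSV with header
#'
#' @param rows Data frame.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path Whitespace-delimited `chrom  size` file.
#' @return Data frame with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "size"))
  df$size <- as.integer(df$size)
  df
}
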