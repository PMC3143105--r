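# Synthetic ping-pong read simulator.  Generates labelled references,
# annotation tracks and small-RNA libraries with the exact cleavage
# geometry of piRNA-guided target slicing, so every pipeline stage can be
# tested against known ground truth.
#
# Configuration A (primary-piRNA-guided cleavage of a sense transcript):
# an antisense primary piRNA with 5'-terminal U pairs the sense strand;
# cleavage across from its guide position 10 (sense coordinate c, a sense
# A) releases a sense secondary piRNA starting at c - 9 (A at read position
# 10); a second cleavage 19 nt further upstream releases an exact sense
# 19mer covering [c - 28, c - 9), which therefore carries A 10 nt
# downstream of its 3' end.
#
# Configuration B mirrors this with a secondary piRNA as the guide: a sense
# primary piRNA starts at a sense U (coordinate d), the released sense
# 19mer covers [d - 19, d) (U immediately downstream of its 3' end), and
# the antisense secondary piRNA's 5' coordinate is d + 9.

#' Generate a random reference sequence
#'
#' @param length Sequence length (> 100).
#' @param composition Named base probabilities over A/C/G/T (default
#'   uniform).
#' @param seed Integer seed.
#' @param name Reference name.
#' @return A single-entry `ReferenceSet` (named character vector).
#' @export
random_reference <- function(length, composition = c(A = 0.25, C = 0.25,
                                                     G = 0.25, T = 0.25),
                             seed = 1L, name = "ref1") {
  if (length <= 100) stop("reference length must be > 100", call. = FALSE)
  composition <- composition / sum(composition)
  seq <- with_seed(seed, paste(sample(names(composition), length,
                                      replace = TRUE, prob = composition),
                               collapse = ""))
  as_reference_set(stats::setNames(seq, name))
}

# Shared emitter: one read with its truth alignment.  All coordinates are
# on the planted strand's view `view` (the reference for '+', its reverse
# complement for '-'); flip_coords maps them back to the forward reference.
emit_read <- function(id, view, L, start_v, end_v, strand, copies, ref_name,
                      true_class, event_id, configuration) {
  seq <- substr(view, start_v + 1L, end_v)
  if (strand == "+") {
    start <- start_v; end <- end_v
  } else {
    start <- L - end_v; end <- L - start_v
  }
  list(read = data.frame(id = id, seq = seq, count = copies,
                         stringsAsFactors = FALSE),
       aln = data.frame(read_id = id, ref_id = ref_name, start = start,
                        end = end, strand = strand, mismatches = 0L,
                        seq = seq, count = copies, stringsAsFactors = FALSE),
       truth = data.frame(read_id = id, true_class = true_class,
                          event_id = event_id, configuration = configuration,
                          stringsAsFactors = FALSE))
}

plant_event <- function(reference, site, configuration, p_len, s_len, copies,
                        event_id, strand = "+") {
  ref_name <- names(reference)[1]
  fwd <- reference[[1]]
  L <- nchar(fwd)
  view <- if (strand == "+") fwd else revcomp(fwd)
  base_at <- function(p) substr(view, p + 1L, p + 1L)
  parts <- list()
  if (configuration == "A") {
    c0 <- site
    if (base_at(c0) != "A" || base_at(c0 - 9L) == "T")
      stop("config A site constraint violated", call. = FALSE)
    if (c0 < 29L || c0 - 9L + s_len > L)
      stop("config A site leaves no room for reads", call. = FALSE)
    parts$pr19 <- emit_read(paste0(event_id, "_pr19"), view, L,
                            c0 - 28L, c0 - 9L, strand, copies[["pr19"]],
                            ref_name, "PR19_A10", event_id, "A")
    parts$s <- emit_read(paste0(event_id, "_s"), view, L,
                         c0 - 9L, c0 - 9L + s_len, strand, copies[["s"]],
                         ref_name, "S_PIRNA", event_id, "A")
    # antisense guide: 5' coordinate c0 on the view, running leftward
    other <- if (strand == "+") "-" else "+"
    parts$p <- emit_read(paste0(event_id, "_p"), view, L,
                         c0 - p_len + 1L, c0 + 1L, strand, copies[["p"]],
                         ref_name, "P_PIRNA", event_id, "A")
    # fix orientation: the guide read lies on the opposite strand, so its
    # sequence is the reverse complement of the view slice
    parts$p$aln$strand <- other
    parts$p$aln$seq <- revcomp(parts$p$aln$seq)
    parts$p$read$seq <- parts$p$aln$seq
  } else {
    d0 <- site
    if (base_at(d0) != "T" || base_at(d0 + 9L) == "A")
      stop("config B site constraint violated", call. = FALSE)
    if (d0 < 19L || d0 + p_len > L || d0 + 10L > L)
      stop("config B site leaves no room for reads", call. = FALSE)
    parts$pr19 <- emit_read(paste0(event_id, "_pr19"), view, L,
                            d0 - 19L, d0, strand, copies[["pr19"]],
                            ref_name, "PR19_U1", event_id, "B")
    parts$p <- emit_read(paste0(event_id, "_p"), view, L,
                         d0, d0 + p_len, strand, copies[["p"]],
                         ref_name, "P_PIRNA", event_id, "B")
    other <- if (strand == "+") "-" else "+"
    parts$s <- emit_read(paste0(event_id, "_s"), view, L,
                         d0 + 10L - s_len, d0 + 10L, strand, copies[["s"]],
                         ref_name, "S_PIRNA", event_id, "B")
    parts$s$aln$strand <- other
    parts$s$aln$seq <- revcomp(parts$s$aln$seq)
    parts$s$read$seq <- parts$s$aln$seq
  }
  list(reads = do.call(rbind, lapply(parts, `[[`, "read")),
       alignments = do.call(rbind, lapply(parts, `[[`, "aln")),
       truth = do.call(rbind, lapply(parts, `[[`, "truth")))
}

#' Plant a primary-piRNA-guided (configuration A) cleavage event
#'
#' Emits an antisense primary piRNA with 5' coordinate at `site`, a sense
#' secondary piRNA starting at `site - 9` (A at position 10) and a sense
#' 19mer covering `[site - 28, site - 9)` (A 10 nt downstream of its 3'
#' end).  The sense base at `site` must be A and the base at `site - 9`
#' must not be T.
#'
#' @param reference Single-entry `ReferenceSet`.
#' @param site Cleavage coordinate (0-based) on the planted strand's view.
#' @param p_len,s_len Primary/secondary piRNA lengths (24-30).
#' @param copies Named numeric vector `pr19`, `s`, `p` of copy counts.
#' @param event_id Identifier prefix for the emitted reads.
#' @param strand Strand the sense transcript of the event lies on.
#' @return List `reads`, `alignments`, `truth`.
#' @export
plant_config_A_event <- function(reference, site, p_len = 26L, s_len = 26L,
                                 copies = c(pr19 = 1, s = 1, p = 1),
                                 event_id = "evA1", strand = "+") {
  plant_event(reference, site, "A", p_len, s_len, copies, event_id, strand)
}

#' Plant a secondary-piRNA-guided (configuration B) cleavage event
#'
#' Emits a sense primary piRNA starting at `site` (5' U), a sense 19mer
#' covering `[site - 19, site)` (U immediately downstream of its 3' end)
#' and an antisense secondary piRNA with 5' coordinate `site + 9`.  The
#' sense base at `site` must be T and the base at `site + 9` must not be A.
#'
#' @inheritParams plant_config_A_event
#' @return List `reads`, `alignments`, `truth`.
#' @export
plant_config_B_event <- function(reference, site, p_len = 26L, s_len = 26L,
                                 copies = c(pr19 = 1, s = 1, p = 1),
                                 event_id = "evB1", strand = "+") {
  plant_event(reference, site, "B", p_len, s_len, copies, event_id, strand)
}

# Find a site satisfying the configuration constraint by resampling
# uniformly within [lo, hi]; the reference is never edited.
sample_site <- function(view, configuration, lo, hi, max_iter = 10000L) {
  base_at <- function(p) substr(view, p + 1L, p + 1L)
  for (i in seq_len(max_iter)) {
    p <- sample(lo:hi, 1L)
    ok <- if (configuration == "A") base_at(p) == "A" && base_at(p - 9L) != "T"
    else base_at(p) == "T" && base_at(p + 9L) != "A"
    if (ok) return(p)
  }
  stop("no valid site found after ", max_iter, " draws", call. = FALSE)
}

#' Add unstructured degradation background reads
#'
#' Uniform random positions, strands and lengths; truth class
#' `"background"`.
#'
#' @param reference Single-entry `ReferenceSet`.
#' @param n Number of background reads.
#' @param length_range Inclusive read length range (default 18-32).
#' @param seed Integer seed.
#' @param id_prefix Read id prefix (kept distinct from event ids).
#' @return List `reads`, `alignments`, `truth`.
#' @export
add_background <- function(reference, n, length_range = c(18L, 32L),
                           seed = 1L, id_prefix = "bg") {
  ref_name <- names(reference)[1]
  fwd <- reference[[1]]
  L <- nchar(fwd)
  if (n == 0L) {
    return(list(reads = data.frame(id = character(0), seq = character(0),
                                   count = integer(0)),
                alignments = empty_alignments(),
                truth = data.frame(read_id = character(0),
                                   true_class = character(0),
                                   event_id = character(0),
                                   configuration = character(0))))
  }
  with_seed(seed, {
    pool <- seq.int(length_range[1], length_range[2])
    len <- pool[sample.int(length(pool), n, replace = TRUE)]
    start <- vapply(len, function(l) sample.int(L - l + 1L, 1L) - 1L,
                    integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    fwd_seq <- substring(fwd, start + 1L, start + len)
    seq <- ifelse(strand == "+", fwd_seq, revcomp(fwd_seq))
    id <- sprintf("%s%06d", id_prefix, seq_len(n))
    list(reads = data.frame(id = id, seq = seq, count = 1L,
                            stringsAsFactors = FALSE),
         alignments = data.frame(read_id = id, ref_id = ref_name,
                                 start = start, end = start + len,
                                 strand = strand, mismatches = 0L, seq = seq,
                                 count = 1L, stringsAsFactors = FALSE),
         truth = data.frame(read_id = id, true_class = "background",
                            event_id = NA_character_,
                            configuration = "background",
                            stringsAsFactors = FALSE))
  })
}

#' Default simulation configuration
#'
#' The defaults emulate an adult mouse testis small-RNA library mapped to a
#' repeat consensus: both cleavage configurations on both strands, piRNA
#' lengths unimodal over 24-30 nt (Mili-like peak at 26 or Miwi-like peak
#' at 30), heavy-tailed (log-normal) per-event copy counts, pr19RNAs about
#' 2.5-fold more abundant than secondary piRNAs, and an unstructured
#' degradation background.
#'
#' @param seed Mandatory integer seed.
#' @param ref_length Reference length (default 10000).
#' @param composition Base composition of the reference.
#' @param n_events_A,n_events_B Events per configuration.
#' @param copy_meanlog,copy_sdlog Log-normal parameters of the secondary
#'   piRNA per-event copy count.
#' @param pirna_peak Mode of the piRNA length distribution (26 Mili-like,
#'   30 Miwi-like).
#' @param pr19_s_ratio Target pr19RNA : secondary piRNA copy ratio.
#' @param p_level Primary piRNA copy level relative to secondary piRNAs.
#' @param background_n Number of background reads.
#' @param background_length_range Background length range.
#' @param antisense_fraction Fraction of events whose sense transcript lies
#'   on the minus strand (repeats are transcribed from both strands).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, ref_length = 10000L,
                       composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       n_events_A = 50L, n_events_B = 50L,
                       copy_meanlog = 1, copy_sdlog = 0.8,
                       pirna_peak = 26L, pr19_s_ratio = 2.5, p_level = 1,
                       background_n = 0L,
                       background_length_range = c(18L, 32L),
                       antisense_fraction = 0.5) {
  stopifnot(!missing(seed))
  structure(list(seed = as.integer(seed), ref_length = as.integer(ref_length),
                 composition = composition, n_events_A = n_events_A,
                 n_events_B = n_events_B, copy_meanlog = copy_meanlog,
                 copy_sdlog = copy_sdlog, pirna_peak = pirna_peak,
                 pr19_s_ratio = pr19_s_ratio, p_level = p_level,
                 background_n = background_n,
                 background_length_range = background_length_range,
                 antisense_fraction = antisense_fraction),
            class = "sim_config")
}

sample_pirna_length <- function(n, peak) {
  lens <- 24:30
  w <- stats::dnorm(lens, mean = peak, sd = 1.5)
  sample(lens, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate a small-RNA library with ping-pong ground truth
#'
#' Plants `n_events_A` configuration-A and `n_events_B` configuration-B
#' events at constraint-satisfying sites (resampled, never edited) on a
#' random reference, adds background, and returns reads, true alignments
#' and a truth table.  Fully deterministic for a fixed seed.
#'
#' @param config A [sim_config()] object.
#' @param reference Optional pre-built single-entry `ReferenceSet`; by
#'   default one is generated from the config.
#' @param out_dir Optional directory: writes `reads.fasta` (counts encoded
#'   as `_xN` id suffixes), `truth.sam` and `truth.tsv`.
#' @return List `reference`, `reads`, `alignments`, `truth`, `config`.
#' @export
simulate_library <- function(config, reference = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(reference))
    reference <- random_reference(config$ref_length, config$composition,
                                  seed = derive_seed(config$seed, "reference"))
  fwd <- reference[[1]]
  L <- nchar(fwd)
  rc <- revcomp(fwd)
  parts <- with_seed(derive_seed(config$seed, "events"), {
    n_tot <- config$n_events_A + config$n_events_B
    configs <- rep(c("A", "B"), c(config$n_events_A, config$n_events_B))
    strands <- ifelse(stats::runif(n_tot) < config$antisense_fraction,
                      "-", "+")
    p_len <- sample_pirna_length(n_tot, config$pirna_peak)
    s_len <- sample_pirna_length(n_tot, config$pirna_peak)
    s_cop <- pmax(1, round(stats::rlnorm(n_tot, config$copy_meanlog,
                                         config$copy_sdlog)))
    lapply(seq_len(n_tot), function(i) {
      view <- if (strands[i] == "+") fwd else rc
      lo <- 31L
      hi <- L - 32L
      site <- sample_site(view, configs[i], lo, hi)
      copies <- c(pr19 = max(1, round(config$pr19_s_ratio * s_cop[i])),
                  s = s_cop[i],
                  p = max(1, round(config$p_level * s_cop[i])))
      plant_event(reference, site, configs[i], p_len[i], s_len[i], copies,
                  sprintf("ev%s%04d", configs[i], i), strands[i])
    })
  })
  bg <- add_background(reference, config$background_n,
                       config$background_length_range,
                       seed = derive_seed(config$seed, "background"))
  reads <- rbind(do.call(rbind, lapply(parts, `[[`, "reads")), bg$reads)
  alignments <- rbind(do.call(rbind, lapply(parts, `[[`, "alignments")),
                      bg$alignments)
  truth <- rbind(do.call(rbind, lapply(parts, `[[`, "truth")), bg$truth)
  rownames(reads) <- rownames(alignments) <- rownames(truth) <- NULL
  out <- list(reference = reference, reads = reads, alignments = alignments,
              truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(paste0(">", reads$id, "_x", reads$count, "\n", reads$seq),
               file.path(out_dir, "reads.fasta"))
    write_alignments_sam(alignments, reference,
                         file.path(out_dir, "truth.sam"))
    write_table(truth, file.path(out_dir, "truth.tsv"))
  }
  out
}

#' Simulate a toy annotated genome with planted events
#'
#' Builds a multi-chromosome random genome with labelled feature intervals
#' (a piRNA cluster, an LTR repeat inside the cluster, a LINE repeat and a
#' RefSeq gene per chromosome) and plants configuration-A events inside
#' designated features, so the expected annotation category of every
#' planted 19mer is known by construction.
#'
#' @param seed Integer seed.
#' @param chrom_lengths Named integer vector of chromosome lengths
#'   (default two chromosomes of 30 kb).
#' @param events_per_feature Configuration-A events planted per feature.
#' @return List: `genome` (`ReferenceSet`), `tracks` (list of
#'   [annotation_track()]: repeats priority 1, clusters 2, genes 3),
#'   `chrom_sizes`, `reads`, `alignments`, `truth` (with
#'   `expected_category`).
#' @export
simulate_genome <- function(seed, chrom_lengths = c(chr1 = 30000L,
                                                    chr2 = 30000L),
                            events_per_feature = 3L) {
  genome <- character(0)
  repeats <- clusters <- genes <- list()
  all_parts <- list()
  for (ci in seq_along(chrom_lengths)) {
    cn <- names(chrom_lengths)[ci]
    L <- chrom_lengths[[ci]]
    ref <- random_reference(L, seed = derive_seed(seed, paste0("chrom", ci)),
                            name = cn)
    genome[cn] <- ref[[1]]
    cluster <- c(1000L, 12000L)
    ltr <- c(2000L, 3500L)                 # inside the cluster
    line <- c(14000L, 16000L)
    gene <- c(20000L, 25000L)
    repeats[[length(repeats) + 1L]] <- data.frame(
      chrom = cn, start = c(ltr[1], line[1]), end = c(ltr[2], line[2]),
      name = c("LTR", "LINE"), score = 0, strand = ".",
      stringsAsFactors = FALSE)
    clusters[[length(clusters) + 1L]] <- data.frame(
      chrom = cn, start = cluster[1], end = cluster[2], name = "Clusters",
      score = 0, strand = ".", stringsAsFactors = FALSE)
    genes[[length(genes) + 1L]] <- data.frame(
      chrom = cn, start = gene[1], end = gene[2], name = "RefSeq", score = 0,
      strand = ".", stringsAsFactors = FALSE)
    feats <- list(LTR = ltr, Clusters = c(4000L, 12000L), RefSeq = gene,
                  unannotated = c(26000L, L - 100L))
    parts <- with_seed(derive_seed(seed, paste0("events", ci)), {
      lapply(names(feats), function(fn) {
        lapply(seq_len(events_per_feature), function(k) {
          # pr19 spans [site-28, site-9); keep the whole 19mer inside the
          # feature so its 5'-end base determines the category
          site <- sample_site(ref[[1]], "A", feats[[fn]][1] + 29L,
                              feats[[fn]][2] - 31L)
          ev <- plant_event(ref, site, "A", 26L, 26L,
                            c(pr19 = 2, s = 1, p = 1),
                            sprintf("%s_%s_ev%d", cn, fn, k), "+")
          ev$truth$expected_category <- fn
          ev
        })
      })
    })
    all_parts <- c(all_parts, unlist(parts, recursive = FALSE))
  }
  reads <- do.call(rbind, lapply(all_parts, `[[`, "reads"))
  alignments <- do.call(rbind, lapply(all_parts, `[[`, "alignments"))
  truth <- do.call(rbind, lapply(all_parts, `[[`, "truth"))
  alignments$chrom <- alignments$ref_id
  rownames(reads) <- rownames(alignments) <- rownames(truth) <- NULL
  list(genome = as_reference_set(genome),
       tracks = list(
         annotation_track("repeats", 1, do.call(rbind, repeats)),
         annotation_track("clusters", 2, do.call(rbind, clusters),
                          category = "Clusters"),
         annotation_track("genes", 3, do.call(rbind, genes),
                          category = "RefSeq")),
       chrom_sizes = data.frame(chrom = names(chrom_lengths),
                                size = as.integer(chrom_lengths),
                                stringsAsFactors = FALSE),
       reads = reads, alignments = alignments, truth = truth)
}
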