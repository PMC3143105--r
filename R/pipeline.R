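# Orchestration: end-to-end consensus and genome workflows, cross-library
# comparison, and run manifests.  A single global seed fans out to
# per-stage seeds through derive_seed(), so every stage is independently
# reproducible.

write_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$tables))
    write_table(bundle$tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  manifest <- bundle$manifest
  writeLines(c("# pr19scan run manifest",
               paste0(names(manifest), "\t",
                      vapply(manifest, function(x)
                        paste(format(x, trim = TRUE), collapse = ","),
                        character(1)))),
             file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

#' Run the consensus-mapping workflow
#'
#' Filter, map (single- or two-pass), classify, and compute the signature
#' analytics against a repeat consensus reference: length histograms,
#' sequence logos per major class, 5'-end offset densities of piRNAs
#' relative to pr19RNAs, and the adjacency-configuration report.
#'
#' @param reads Read data frame (or path to FASTA/FASTQ).
#' @param consensus `ReferenceSet` (or FASTA path) of consensus
#'   sequence(s).
#' @param repeat_db Optional `ReferenceSet` of genomic repeat copies; when
#'   given, the two-pass protocol (exact pass against the database, then
#'   relaxed consensus pass) is used.
#' @param filter_mode `"general"` or `"line"`.
#' @param max_mismatches Consensus-pass mismatch budget (default 2).
#' @param max_hits Consensus-pass multi-hit cap (default 10).
#' @param F Flank length for classification (default 10).
#' @param W Offset-density window radius (default 60).
#' @param out_dir Optional output directory for TSV tables and manifest.
#' @return List: `classified`, `tables` (named data frames:
#'   `filter_report`, `length_histogram`, `class_summary`, `configurations`,
#'   `config_reciprocal`, `offsets_*`), `logos`, `manifest`.
#' @export
run_consensus_workflow <- function(reads, consensus, repeat_db = NULL,
                                   filter_mode = c("general", "line"),
                                   max_mismatches = 2L, max_hits = 10L,
                                   F = 10L, W = 60L, out_dir = NULL) {
  filter_mode <- match.arg(filter_mode)
  if (is.character(reads) && length(reads) == 1L)
    reads <- read_sequences(reads)
  if (is.character(consensus) && is.null(names(consensus)))
    consensus <- read_reference(consensus)
  consensus <- as_reference_set(consensus)
  flt <- filter_reads(reads, mode = filter_mode)
  if (is.null(repeat_db)) {
    mp <- map_library(flt$kept, consensus, max_mismatches = max_mismatches,
                      max_hits = max_hits)
    aln <- mp$alignments
  } else {
    mp <- map_two_pass(flt$kept, as_reference_set(repeat_db), consensus,
                       pass2_max_mismatches = max_mismatches,
                       pass2_max_hits = max_hits)
    aln <- mp$alignments
  }
  cls <- classify_library(aln, consensus, F = F)
  cfg <- count_configurations(cls$reads)
  tables <- list(filter_report = flt$removed,
                 length_histogram = length_histogram(cls$reads),
                 class_summary = cls$summary,
                 configurations = cfg$summary,
                 config_reciprocal = cfg$reciprocal)
  # offset spectra of piRNA 5' ends relative to pr19RNA 5' ends
  anchors <- cls$reads[cls$reads$class %in% c("PR19_A10", "PR19_U1"), ,
                       drop = FALSE]
  for (qcl in c("S_PIRNA", "P_PIRNA")) {
    q <- cls$reads[cls$reads$class == qcl, , drop = FALSE]
    if (nrow(anchors) && nrow(q))
      tables[[paste0("offsets_pr19_", tolower(qcl))]] <-
        offset_density(anchors, q, W = W)
  }
  logos <- list()
  for (lcl in c("PR19_A10", "PR19_U1", "S_PIRNA", "P_PIRNA")) {
    sub <- cls$reads[cls$reads$class == lcl, , drop = FALSE]
    if (nrow(sub))
      logos[[lcl]] <- sequence_logo(sub, upstream_ext = 0L,
                                    downstream_ext = min(F, 10L))
  }
  manifest <- list(workflow = "consensus", filter_mode = filter_mode,
                   max_mismatches = max_mismatches, max_hits = max_hits,
                   flank = F, window = W,
                   n_reads_in = nrow(reads), n_reads_kept = nrow(flt$kept),
                   n_alignments = nrow(aln),
                   n_classified = nrow(cls$reads))
  bundle <- list(classified = cls$reads, tables = tables, logos = logos,
                 manifest = manifest)
  if (!is.null(out_dir)) write_outputs(bundle, out_dir)
  bundle
}

#' Run the genome-wide workflow
#'
#' Assign multi-mapping reads, annotate 19mers by category and 10th
#' downstream base, classify all reads from genomic flanks, tile the
#' genome, select tiles enriched for pr19RNAs and secondary piRNAs, and
#' compare their abundances with a paired Wilcoxon signed-rank test.
#'
#' @param alignments Genome alignment data frame (multiple loci per
#'   multi-mapping read) or a SAM path.
#' @param genome `ReferenceSet` or FASTA path.
#' @param tracks List of [annotation_track()] objects.
#' @param chrom_sizes Chromosome sizes data frame; derived from `genome`
#'   when NULL.
#' @param seed Global seed (fans out to stage seeds).
#' @param tile_width Tile width in bp (default 2500).
#' @param max_loci Multi-mapper discard threshold (default 6).
#' @param split_strand Strand-split tiles (default TRUE).
#' @param out_dir Optional output directory.
#' @return List: `annotation` (category x base table and totals),
#'   `classified`, `tile_counts`, `selected_tiles`, `wilcoxon`, `ratios`,
#'   `tables`, `manifest`.
#' @export
run_genome_workflow <- function(alignments, genome, tracks,
                                chrom_sizes = NULL, seed = 1L,
                                tile_width = 2500L, max_loci = 6L,
                                split_strand = TRUE, out_dir = NULL) {
  if (is.character(genome) && is.null(names(genome)))
    genome <- read_reference(genome)
  genome <- as_reference_set(genome)
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- read_alignments_sam(alignments, genome)
  if (is.null(chrom_sizes))
    chrom_sizes <- data.frame(chrom = names(genome), size = nchar(genome),
                              stringsAsFactors = FALSE)
  len <- alignments$end - alignments$start
  mers <- alignments[len == 19L, , drop = FALSE]
  annot <- annotate_genome_19mers(mers, genome, tracks,
                                  seed = derive_seed(seed, "multimappers"),
                                  max_loci = max_loci)
  # classification over singly-assigned reads of all lengths
  asg_all <- assign_multimappers(alignments, max_loci = max_loci,
                                 seed = derive_seed(seed, "multimappers"))
  cls <- classify_library(asg_all$assigned, genome)
  loci_per_read <- table(alignments$read_id)
  cls$reads$unique <- loci_per_read[cls$reads$read_id] == 1L
  tiles <- make_tiles(chrom_sizes, width = tile_width)
  tc <- count_tiles(cls$reads, tiles, split_strand = split_strand)
  sel <- select_enriched_tiles(tc)
  wil <- if (nrow(sel)) paired_wilcoxon(sel$pr19_A10, sel$s_piRNA) else NULL
  rs <- if (nrow(sel)) ratio_summary(sel) else NULL
  tables <- list(annotation = data.frame(category = rownames(annot$table),
                                         annot$table, check.names = FALSE),
                 tile_counts = tc, selected_tiles = sel)
  if (!is.null(rs)) tables$tile_scatter <- rs$scatter
  manifest <- list(workflow = "genome", seed = seed,
                   tile_width = tile_width, max_loci = max_loci,
                   n_alignments = nrow(alignments),
                   n_19mers_unique = annot$n_unique,
                   n_19mers_multi = annot$n_multi,
                   n_19mers_discarded = nrow(annot$discarded),
                   n_tiles_selected = nrow(sel),
                   wilcoxon_p = if (!is.null(wil)) wil$p.value else NA,
                   median_ratio = if (!is.null(rs)) rs$median else NA)
  bundle <- list(annotation = annot, classified = cls$reads,
                 tile_counts = tc, selected_tiles = sel, wilcoxon = wil,
                 ratios = rs, tables = tables, manifest = manifest)
  if (!is.null(out_dir)) write_outputs(bundle, out_dir)
  bundle
}

#' Compare class/length profiles across libraries at equal depth
#'
#' Normalises per-length, per-class counts of each library to reads per
#' million mappable reads; libraries with at most `min_mappable` mappable
#' reads are excluded with a warning.  Also reports a 19-nt peak statistic:
#' the ratio of 19mer RPM to the mean RPM of the neighbouring lengths 18
#' and 20.
#'
#' @param tables Named list of per-library count data frames with columns
#'   `length`, `count` (and optionally `class`).
#' @param totals Optional named numeric vector of mappable totals; by
#'   default the per-table count sum.
#' @param min_mappable Libraries must exceed this many mappable reads
#'   (default 100).
#' @return List: `profiles` (long data frame `library`, `length`, [class,]
#'   `count`, `rpm`), `peak19` (per-library peak statistic), `excluded`.
#' @export
compare_libraries <- function(tables, totals = NULL, min_mappable = 100) {
  stopifnot(length(tables) >= 2, !is.null(names(tables)))
  if (is.null(totals))
    totals <- vapply(tables, function(t) sum(t$count), numeric(1))
  excluded <- names(tables)[totals <= min_mappable]
  if (length(excluded))
    warning("excluded libraries with <= ", min_mappable, " mappable reads: ",
            paste(excluded, collapse = ", "))
  keep <- setdiff(names(tables), excluded)
  if (!length(keep)) stop("all libraries excluded", call. = FALSE)
  prof <- do.call(rbind, lapply(keep, function(nm) {
    t <- tables[[nm]]
    t$library <- nm
    t$rpm <- rpm(t$count, totals[[nm]])
    t
  }))
  rownames(prof) <- NULL
  peak19 <- do.call(rbind, lapply(keep, function(nm) {
    t <- prof[prof$library == nm, , drop = FALSE]
    at <- function(l) sum(t$rpm[t$length == l])
    flank <- mean(c(at(18L), at(20L)))
    data.frame(library = nm, rpm19 = at(19L), rpm_flank = flank,
               peak_ratio = if (flank > 0) at(19L) / flank else Inf,
               stringsAsFactors = FALSE)
  }))
  list(profiles = prof, peak19 = peak19, excluded = excluded)
}
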