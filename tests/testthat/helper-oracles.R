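# Independent oracles and small fixture builders.  These deliberately use
# naive algorithms (sliding windows, full enumeration) so they stay
# independent of the implementation paths they check.

# Naive O(|ref| * |read|) mapper: every offset, both strands, N never
# matches.
oracle_map <- function(read_seq, ref_seq, max_mm) {
  L <- nchar(ref_seq)
  n <- nchar(read_seq)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") read_seq else revcomp(read_seq)
    pa <- strsplit(pat, "")[[1]]
    for (s in 0:(L - n)) {
      sl <- strsplit(substr(ref_seq, s + 1, s + n), "")[[1]]
      mm <- sum(pa != sl | pa == "N" | sl == "N")
      if (mm <= max_mm)
        out[[length(out) + 1]] <- data.frame(start = s, end = s + n,
                                             strand = strand,
                                             mismatches = mm)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               mismatches = integer(0))
}

# Full enumeration of the signed-rank null over all 2^n sign vectors.
oracle_signed_rank_p <- function(x, y, alternative = "two.sided") {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.numeric(signs %*% r)
  mu <- sum(r) / 2
  switch(alternative,
         two.sided = mean(abs(Vs - mu) >= abs(V - mu) - 1e-9),
         greater = mean(Vs >= V - 1e-9),
         less = mean(Vs <= V + 1e-9))
}

# A tiny deterministic alignment table on a given reference.
make_aln <- function(ref_id, start, end, strand, seq, count = 1L,
                     read_id = NULL) {
  n <- max(length(start), length(seq))
  data.frame(read_id = read_id %||% sprintf("r%03d", seq_len(n)),
             ref_id = ref_id, start = start, end = end, strand = strand,
             mismatches = 0L, seq = seq, count = count,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic, well-spaced configuration-A/B events: scans forward from
# each requested anchor position for the first constraint-satisfying site,
# so no two events fall inside each other's offset window.
plant_spaced_events <- function(reference, anchors, configuration = "A",
                                strand = "+", copies = c(pr19 = 1, s = 1,
                                                         p = 1)) {
  view <- if (strand == "+") reference[[1]] else revcomp(reference[[1]])
  base_at <- function(p) substr(view, p + 1, p + 1)
  ok <- function(p) {
    if (configuration == "A") base_at(p) == "A" && base_at(p - 9) != "T"
    else base_at(p) == "T" && base_at(p + 9) != "A"
  }
  parts <- lapply(seq_along(anchors), function(i) {
    p <- anchors[i]
    while (!ok(p)) p <- p + 1
    f <- if (configuration == "A") plant_config_A_event else
      plant_config_B_event
    f(reference, p, copies = copies,
      event_id = sprintf("ev%s%03d", configuration, i), strand = strand)
  })
  list(reads = do.call(rbind, lapply(parts, `[[`, "reads")),
       alignments = do.call(rbind, lapply(parts, `[[`, "alignments")),
       truth = do.call(rbind, lapply(parts, `[[`, "truth")))
}
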