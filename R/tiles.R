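# 2.5 kb genome tiling, enriched-tile selection, pr19RNA vs secondary piRNA
# abundance comparison and the paired Wilcoxon signed-rank test.

#' Tile chromosomes into fixed-width windows
#'
#' Consecutive non-overlapping `[k*w, (k+1)*w)` tiles per chromosome; the
#' final partial tile is included.
#'
#' @param chrom_sizes Data frame `chrom`, `size` (see [read_chrom_sizes()]).
#' @param width Tile width in bp (default 2500).
#' @return Interval data frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand = "."`).
#' @export
make_tiles <- function(chrom_sizes, width = 2500L) {
  stopifnot(width > 0)
  rows <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    L <- chrom_sizes$size[i]
    if (L <= 0) return(NULL)
    starts <- seq.int(0L, L - 1L, by = width)
    data.frame(chrom = chrom_sizes$chrom[i], start = starts,
               end = pmin(starts + width, L),
               name = sprintf("%s_tile%d", chrom_sizes$chrom[i],
                              seq_along(starts)),
               score = 0, strand = ".", stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0), score = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Map a read class to the tile-count column it feeds.
tile_class_group <- function(class) {
  cl <- as.character(class)
  out <- rep(NA_character_, length(cl))
  out[cl == "PR19_A10"] <- "pr19_A10"
  out[cl %in% c("PR19_U1", "OTHER_19MER")] <- "other_19mer"
  out[cl == "S_PIRNA"] <- "s_piRNA"
  out[cl == "P_PIRNA"] <- "p_piRNA"
  out
}

#' Per-tile, per-strand counts of the four tile classes
#'
#' A read contributes (copy-weighted) to the tile containing its 5'-end
#' base.  Only uniquely mapping reads should be supplied; rows with a
#' logical `unique` column set to FALSE are excluded.
#'
#' @param classified Classified alignment data frame (chromosome in
#'   `ref_id` or `chrom`).
#' @param tiles Tile data frame from [make_tiles()] (constant width assumed
#'   within each chromosome).
#' @param split_strand Count strands separately (default TRUE); when FALSE
#'   both strands are merged into strand `"."`.
#' @return Data frame: tile coordinates, `strand`, and counts `pr19_A10`,
#'   `other_19mer`, `s_piRNA`, `p_piRNA` (zero-count tiles retained).
#' @export
count_tiles <- function(classified, tiles, split_strand = TRUE) {
  if ("unique" %in% names(classified))
    classified <- classified[classified$unique, , drop = FALSE]
  chrom <- if ("chrom" %in% names(classified)) classified$chrom else
    classified$ref_id
  width <- if (nrow(tiles)) max(tiles$end - tiles$start) else 2500L
  groups <- c("pr19_A10", "other_19mer", "s_piRNA", "p_piRNA")
  strands <- if (split_strand) c("+", "-") else "."
  grid <- expand.grid(tile = seq_len(nrow(tiles)), strand = strands,
                      stringsAsFactors = FALSE)
  out <- data.frame(chrom = tiles$chrom[grid$tile],
                    start = tiles$start[grid$tile],
                    end = tiles$end[grid$tile], strand = grid$strand,
                    stringsAsFactors = FALSE)
  for (g in groups) out[[g]] <- 0
  if (nrow(classified)) {
    grp <- tile_class_group(classified$class)
    keep <- !is.na(grp)
    cl <- classified[keep, , drop = FALSE]
    grp <- grp[keep]
    chrom <- chrom[keep]
    p5 <- five_prime_coord(cl$start, cl$end, cl$strand)
    bin_start <- (p5 %/% width) * width
    st <- if (split_strand) cl$strand else rep(".", nrow(cl))
    key_out <- paste(out$chrom, out$start, out$strand)
    key_read <- paste(chrom, bin_start, st)
    for (g in groups) {
      sel <- grp == g
      if (!any(sel)) next
      tal <- tapply(cl$count[sel], key_read[sel], sum)
      idx <- match(names(tal), key_out)
      ok <- !is.na(idx)
      out[[g]][idx[ok]] <- out[[g]][idx[ok]] + as.numeric(tal[ok])
    }
  }
  out
}

#' Select tiles enriched for pr19RNAs and secondary piRNAs
#'
#' Keeps (tile, strand) rows where pr19RNAs outnumber other 19mers, where
#' secondary piRNAs outnumber primary piRNAs (the same-strand abundant
#' p-piRNA exclusion), and where both a pr19RNA and a secondary piRNA are
#' present.
#'
#' @param tile_counts Data frame from [count_tiles()].
#' @param p_over_s_threshold Exclusion threshold: a tile is kept only when
#'   `p_piRNA < threshold * s_piRNA` (default 1, i.e. secondary piRNAs must
#'   strictly outnumber primary piRNAs on the strand).
#' @return Subset of `tile_counts`.
#' @export
select_enriched_tiles <- function(tile_counts, p_over_s_threshold = 1) {
  keep <- tile_counts$pr19_A10 > tile_counts$other_19mer &
    tile_counts$p_piRNA < p_over_s_threshold * tile_counts$s_piRNA &
    tile_counts$pr19_A10 > 0 & tile_counts$s_piRNA > 0
  out <- tile_counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences `x - y`.  Zero differences are
#' dropped (classic Wilcoxon; `zero_method = "pratt"` ranks them and drops
#' their contribution afterwards).  Ties receive mid-ranks.  The null
#' distribution is enumerated exactly (generating-function convolution over
#' doubled ranks, valid with ties) for `n <= exact_max` non-zero pairs, and
#' approximated by a normal with continuity correction beyond that.
#'
#' @param x,y Equal-length numeric vectors of paired values.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param zero_method `"wilcox"` (drop zeros) or `"pratt"`.
#' @param exact_max Largest n for exact enumeration (default 25).
#' @return List: `statistic` (V, sum of positive ranks), `p.value`, `n`
#'   (non-zero pairs), `method`.
#' @export
paired_wilcoxon <- function(x, y, alternative = c("two.sided", "greater",
                                                  "less"),
                            zero_method = c("wilcox", "pratt"),
                            exact_max = 25L) {
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero")
    return(list(statistic = 0, p.value = 1, n = 0L, method = "degenerate"))
  }
  V <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_max) {
    # exact null: V2 = sum over included ranks of 2*r_i * Bernoulli(1/2)
    w <- as.integer(round(2 * r))
    total <- sum(w)
    cnt <- numeric(total + 1L)
    cnt[1L] <- 1
    for (wi in w) {
      shifted <- c(rep(0, wi), cnt[seq_len(total + 1L - wi)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    vals <- 0:total
    v2 <- round(2 * V)
    p <- switch(alternative,
      two.sided = sum(probs[abs(vals - total / 2) >= abs(v2 - total / 2) - 1e-9]),
      greater = sum(probs[vals >= v2 - 1e-9]),
      less = sum(probs[vals <= v2 + 1e-9]))
    method <- "exact"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z_hi <- (V - mu - 0.5) / sigma
    z_lo <- (V - mu + 0.5) / sigma
    p <- switch(alternative,
      two.sided = min(1, 2 * min(stats::pnorm(z_hi, lower.tail = FALSE),
                                 stats::pnorm(z_lo))),
      greater = stats::pnorm(z_hi, lower.tail = FALSE),
      less = stats::pnorm(z_lo))
    method <- "normal_approximation"
  }
  list(statistic = V, p.value = min(1, p), n = n, method = method)
}

#' Summarise pr19RNA : secondary piRNA abundance ratios over selected tiles
#'
#' @param selected Data frame of enriched tiles ([select_enriched_tiles()]).
#' @return List: `ratios` (per-tile pr19/s ratios), `median`, `quartiles`,
#'   `scatter` (x = s_piRNA, y = pr19_A10 per tile, for abundance plots).
#' @export
ratio_summary <- function(selected) {
  if (!nrow(selected)) stop("no tiles selected", call. = FALSE)
  ratios <- selected$pr19_A10 / selected$s_piRNA
  list(ratios = ratios,
       median = stats::median(ratios),
       quartiles = stats::quantile(ratios, c(0.25, 0.75)),
       scatter = data.frame(chrom = selected$chrom, start = selected$start,
                            strand = selected$strand,
                            s_piRNA = selected$s_piRNA,
                            pr19_A10 = selected$pr19_A10,
                            ratio = ratios, stringsAsFactors = FALSE))
}
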