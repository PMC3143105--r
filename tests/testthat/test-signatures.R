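test_that("length histogram is copy-weighted and strand-split", {
  a <- rbind(make_aln("r", 0L, 19L, "+", strrep("A", 19), count = 1L, "x"),
             make_aln("r", 30L, 49L, "+", strrep("C", 19), count = 1L, "y"),
             make_aln("r", 60L, 86L, "-", strrep("G", 26), count = 1L, "z"))
  h <- length_histogram(a)
  expect_equal(h$count[h$length == 19 & h$strand == "+"], 2)
  expect_equal(h$count[h$length == 26 & h$strand == "-"], 1)
  expect_equal(nrow(length_histogram(a[0, ])), 0L)
})

test_that("logo information content spans 0 to 2 bits and handles N", {
  mk <- function(seqs) {
    data.frame(seq = seqs, up_flank = strrep("N", 10),
               down_flank = strrep("A", 10), count = 1L,
               stringsAsFactors = FALSE)
  }
  # conserved column: 2 bits; uniform column: 0 bits; half-half: 1 bit
  lg <- sequence_logo(mk(c("AA", "AC", "AG", "AT")), downstream_ext = 0)
  expect_equal(lg$information[1], 2.0)
  expect_equal(lg$information[2], 0.0)
  lg2 <- sequence_logo(mk(c("AC", "CC")), downstream_ext = 0)
  expect_equal(lg2$information[1], 1.0)
  expect_equal(unname(lg2$freq[, 1]), c(0.5, 0.5, 0, 0))
  # downstream extension columns come from the flanks; all-A flank = 2 bits
  lg3 <- sequence_logo(mk(c("AC", "CC")), downstream_ext = 3)
  expect_equal(lg3$information[3:5], rep(2.0, 3))
  # frequencies sum to 1 over non-N observations
  expect_true(all(abs(colSums(lg3$freq) - 1) < 1e-9))
  # all-N column is reported as missing
  mixed <- data.frame(seq = c("ACGTA", "AC"), up_flank = strrep("N", 10),
                      down_flank = strrep("N", 10), count = 1L,
                      stringsAsFactors = FALSE)
  lg4 <- sequence_logo(mixed, downstream_ext = 2)
  expect_true(all(is.na(lg4$information[6:7])))
})

test_that("logo information decreases with column entropy", {
  mk1 <- function(nA, nC) {
    data.frame(seq = c(rep("A", nA), rep("C", nC)),
               up_flank = strrep("N", 10), down_flank = strrep("N", 10),
               count = 1L, stringsAsFactors = FALSE)
  }
  infos <- sapply(list(c(8, 0), c(7, 1), c(6, 2), c(5, 3), c(4, 4)),
                  function(p) sequence_logo(mk1(p[1], p[2]),
                                            downstream_ext = 0)$information[1])
  expect_true(all(diff(infos) < 0))
  expect_true(all(infos >= 0 & infos <= 2))
})

test_that("offset density puts ping-pong partners at +19 and +28", {
  ref <- random_reference(30000, seed = 60)
  evA <- plant_spaced_events(ref, anchors = seq(500, 29000, by = 1500),
                             configuration = "A")
  cls <- classify_library(evA$alignments, ref)$reads
  anchors <- cls[cls$class == "PR19_A10", ]
  s_q <- cls[cls$class == "S_PIRNA", ]
  p_q <- cls[cls$class == "P_PIRNA", ]
  ds <- offset_density(anchors, s_q, W = 60)
  expect_equal(ds$proportion[ds$offset == 19], 1)
  expect_equal(sum(ds$proportion), 1)
  dp <- offset_density(anchors, p_q, W = 60)
  expect_equal(dp$proportion[dp$offset == 28], 1)
  # worked geometry: '+' anchor 5' at 100, same-sense query at 119 -> +19
  a <- make_aln("r", 100L, 119L, "+", strrep("G", 19), read_id = "a")
  q <- make_aln("r", 119L, 145L, "+", strrep("G", 26), read_id = "q")
  d1 <- offset_density(a, q, W = 60)
  expect_equal(d1$offset[d1$count > 0], 19)
  # antisense partner spanning [99,129): 5' coordinate 128 -> +28
  q2 <- make_aln("r", 99L, 129L, "-", strrep("G", 30), read_id = "q2")
  d2 <- offset_density(a, q2, W = 60)
  expect_equal(d2$offset[d2$count > 0], 28)
  # queries = anchors: single peak at 0 with proportion 1
  d0 <- offset_density(a, a, W = 60)
  expect_equal(d0$proportion[d0$offset == 0], 1)
})

test_that("mirrored (config B) events land at +19 same-sense / +28 antisense", {
  ref <- random_reference(30000, seed = 61)
  evB <- plant_spaced_events(ref, anchors = seq(500, 29000, by = 1500),
                             configuration = "B", strand = "-")
  cls <- classify_library(evB$alignments, ref)$reads
  anchors <- cls[cls$class == "PR19_U1", ]
  dp <- offset_density(anchors, cls[cls$class == "P_PIRNA", ], W = 60)
  expect_equal(dp$proportion[dp$offset == 19], 1)
  ds <- offset_density(anchors, cls[cls$class == "S_PIRNA", ], W = 60)
  expect_equal(ds$proportion[ds$offset == 28], 1)
})

test_that("configuration counting flags both ping-pong configurations", {
  ref <- random_reference(30000, seed = 62)
  evA <- plant_spaced_events(ref, anchors = seq(500, 14000, by = 1500),
                             configuration = "A")
  evB <- plant_spaced_events(ref, anchors = seq(15500, 29000, by = 1500),
                             configuration = "B")
  cls <- classify_library(rbind(evA$alignments, evB$alignments), ref)$reads
  cfg <- count_configurations(cls)
  # noise-free: every 19mer flagged in both configurations
  expect_true(all(cfg$per_read$adjacent))
  expect_true(all(cfg$per_read$antisense_partner))
  expect_equal(cfg$summary$pct_any[cfg$summary$total > 0],
               rep(100, sum(cfg$summary$total > 0)))
  # reciprocal statistics describe the primary-guided geometry, so they are
  # 100% on pure configuration-A data
  clsA <- classify_library(evA$alignments, ref)$reads
  expect_equal(count_configurations(clsA)$reciprocal$pct, c(100, 100))
  # an isolated 19mer gains no flags
  lone <- classify_library(make_aln("ref1", 25000L, 25019L, "+",
                                    substr(ref[[1]], 25001, 25019),
                                    read_id = "lone"), ref)$reads
  cfg2 <- count_configurations(rbind(cls[0, ], lone))
  expect_false(any(cfg2$per_read$any_config))
})

test_that("configuration percentages decay with increasing background", {
  pcts <- sapply(c(0, 150, 600), function(nbg) {
    sim <- simulate_library(sim_config(seed = 99, ref_length = 40000,
                                       n_events_A = 20, n_events_B = 20,
                                       background_n = nbg))
    cls <- classify_library(sim$alignments, sim$reference)$reads
    s <- count_configurations(cls)$summary
    100 * sum(s$any_config) / sum(s$total)
  })
  expect_equal(pcts[1], 100)
  expect_true(all(diff(pcts) < 0))
})

test_that("coverage density uses 5' ends and conserves copy mass", {
  ref <- random_reference(200, seed = 63, name = "r")
  a <- rbind(make_aln("r", 5L, 24L, "+", substr(ref[[1]], 6, 24),
                      count = 3L, read_id = "a"),
             make_aln("r", 5L, 24L, "-", revcomp(substr(ref[[1]], 6, 24)),
                      count = 2L, read_id = "b"))
  cls <- classify_reads(extract_flanks(a, ref))
  cov <- coverage_density(cls, ref)
  plus_total <- Reduce(`+`, lapply(cov$r, function(x) x[["+"]]))
  minus_total <- Reduce(`+`, lapply(cov$r, function(x) x[["-"]]))
  expect_equal(which(plus_total > 0), 6L)     # position 5, 1-based 6
  expect_equal(which(minus_total > 0), 24L)   # rightmost base 23, 1-based 24
  expect_equal(sum(plus_total) + sum(minus_total), sum(a$count))
})

test_that("rpm and ddCT utilities compute the textbook arithmetic", {
  expect_equal(rpm(500, 2e6), 250)
  expect_equal(rpm(0, 2e6), 0)
  expect_equal(rpm(500, 4e6), 125)   # doubled depth halves RPM
  expect_error(rpm(1, 0), "> 0")
  expect_equal(fold_change_ddct(20, 18, 20, 18), 1)
  expect_equal(fold_change_ddct(22, 18, 20, 18), 0.25)
  expect_equal(fold_change_ddct(19, 18, 20, 18), 2)
})
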