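test_that("extract_flanks follows strand geometry and pads with N", {
  ref <- as_reference_set(c(r = paste0(
    strrep("C", 100), strrep("G", 19), "GCTAGCTAGA",      # reads [100,119)
    strrep("C", 61), strrep("A", 9), "T",                 # [190,200) = A9 T
    strrep("G", 19), strrep("C", 5))))                    # read [200,219)
  # '+' read at [100,119): downstream flank read directly
  a <- make_aln("r", 100L, 119L, "+", strrep("G", 19))
  f <- extract_flanks(a, ref)
  expect_equal(f$down_flank, "GCTAGCTAGA")
  expect_equal(f$up_flank, strrep("C", 10))
  # '-' read at [200,219): down_flank = revcomp(ref[190,200))
  b <- make_aln("r", 200L, 219L, "-", revcomp(substr(ref[[1]], 201, 219)))
  g <- extract_flanks(b, ref)
  expect_equal(g$down_flank, revcomp(substr(ref[[1]], 191, 200)))
  expect_equal(g$down_flank, "ATTTTTTTTT")
  # '+' read ending 4 nt before the reference end pads with 6 N
  L <- nchar(ref[[1]])
  cc <- make_aln("r", L - 23L, L - 4L, "+",
                 substr(ref[[1]], L - 22L, L - 4L))
  h <- extract_flanks(cc, ref)
  expect_equal(nchar(h$down_flank), 10L)
  expect_equal(substr(h$down_flank, 5, 10), "NNNNNN")
})

test_that("motif classification matches the class definitions", {
  mk <- function(seq, down) {
    data.frame(seq = seq, down_flank = down, up_flank = strrep("N", 10),
               count = 1L, strand = "+", stringsAsFactors = FALSE)
  }
  n19 <- strrep("G", 19)
  expect_equal(as.character(classify_reads(mk(n19, "GCTAGCTAGA"))$class),
               "PR19_A10")
  expect_equal(as.character(classify_reads(mk(n19, "TGCATGCATG"))$class),
               "PR19_U1")
  expect_equal(as.character(classify_reads(mk(n19, "GGGGGGGGGG"))$class),
               "OTHER_19MER")
  # edge: 10th downstream base unknown
  e <- classify_reads(mk(n19, "GCTAGNNNNN"))
  expect_equal(as.character(e$class), "OTHER_19MER")
  expect_true(e$edge)
  # piRNA motifs on read bases
  p <- paste0("T", strrep("C", 8), "G", strrep("A", 16))      # 26 nt, U1, B10
  expect_equal(as.character(classify_reads(mk(p, n19))$class), "P_PIRNA")
  s <- paste0("G", strrep("C", 8), "A", strrep("G", 18))      # 28 nt, V1, A10
  expect_equal(as.character(classify_reads(mk(s, n19))$class), "S_PIRNA")
  amb <- paste0("T", strrep("C", 8), "A", strrep("G", 16))    # both motifs
  expect_equal(as.character(classify_reads(mk(amb, n19))$class),
               "PIRNA_AMBIGUOUS")
  expect_equal(as.character(classify_reads(mk("ACGT", n19))$class), "OTHER")
})

test_that("classification is total and recovers simulator truth exactly", {
  sim <- simulate_library(sim_config(seed = 42, ref_length = 20000,
                                     n_events_A = 25, n_events_B = 25))
  cls <- classify_library(sim$alignments, sim$reference)
  expect_equal(nrow(cls$reads), nrow(sim$alignments))
  expect_false(any(is.na(cls$reads$class)))
  got <- as.character(cls$reads$class)[match(sim$truth$read_id,
                                             cls$reads$read_id)]
  expect_equal(got, sim$truth$true_class)
})

test_that("uniform random flanks give ~3/16 PR19_A10 and ~1/4 A at +10", {
  sim <- simulate_library(sim_config(seed = 7, ref_length = 100000,
                                     n_events_A = 0, n_events_B = 0,
                                     background_n = 20000,
                                     background_length_range = c(19, 19)))
  cls <- classify_library(sim$alignments, sim$reference)
  inner <- cls$reads[!cls$reads$edge, ]
  frac_a10_class <- mean(inner$class == "PR19_A10")
  # P(no T at +1) * P(A at +10) = 0.75 * 0.25
  expect_lt(abs(frac_a10_class - 3 / 16), 3 * sqrt(3 / 16 * 13 / 16 / nrow(inner)))
  frac_a10 <- mean(substr(inner$down_flank, 10, 10) == "A")
  expect_lt(abs(frac_a10 - 0.25), 3 * sqrt(0.25 * 0.75 / nrow(inner)))
})

test_that("classify_library summarises per class, strand and length; unique mode", {
  ref <- random_reference(500, seed = 3)
  a <- rbind(make_aln("ref1", 100L, 119L, "+", substr(ref[[1]], 101, 119),
                      count = 4L, read_id = "a"),
             make_aln("ref1", 200L, 226L, "-",
                      revcomp(substr(ref[[1]], 201, 226)), count = 2L,
                      read_id = "b"))
  cls <- classify_library(a, ref)
  expect_equal(sum(cls$summary$count), 6)
  uni <- classify_library(a, ref, weight = "unique")
  expect_equal(sum(uni$summary$count), 2)
  emp <- classify_library(a[0, ], ref)
  expect_equal(nrow(emp$summary), 0L)
})
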