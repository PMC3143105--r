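test_that("random references are reproducible and respect composition", {
  r1 <- random_reference(5000, seed = 1)
  r2 <- random_reference(5000, seed = 1)
  expect_identical(r1, r2)
  expect_false(identical(r1, random_reference(5000, seed = 2)))
  allA <- random_reference(200, composition = c(A = 1, C = 0, G = 0, T = 0),
                           seed = 1)
  expect_equal(allA[[1]], strrep("A", 200))
  expect_error(random_reference(10), "> 100")
})

test_that("configuration-A geometry: pr19 at [c-28,c-9), s at c-9, p 5' at c", {
  # site 128 on a reference engineered to satisfy the constraints
  seq <- strrep("G", 300)
  substr(seq, 129, 129) <- "A"     # 0-based 128
  ref <- as_reference_set(c(r = seq))
  ev <- plant_config_A_event(ref, 128L, p_len = 30L, s_len = 26L)
  a <- ev$alignments
  pr19 <- a[a$read_id == "evA1_pr19", ]
  expect_equal(c(pr19$start, pr19$end, pr19$strand), c("100", "119", "+"))
  s <- a[a$read_id == "evA1_s", ]
  expect_equal(c(s$start, s$strand), c("119", "+"))
  p <- a[a$read_id == "evA1_p", ]
  expect_equal(p$strand, "-")
  expect_equal(p$end - 1L, 128L)   # antisense 5' coordinate
  # 5' overlap of guide and secondary piRNA is 10 nt
  expect_equal(p$end - s$start, 10L)
  # classifier recovers the construction
  cls <- classify_library(a, ref)$reads
  expect_equal(as.character(cls$class[match(ev$truth$read_id, cls$read_id)]),
               ev$truth$true_class)
  # site constraint enforcement
  expect_error(plant_config_A_event(ref, 127L), "constraint")
})

test_that("configuration-B geometry mirrors A with a U-biased 19mer", {
  seq <- strrep("G", 300)
  substr(seq, 120, 120) <- "T"     # 0-based 119
  ref <- as_reference_set(c(r = seq))
  ev <- plant_config_B_event(ref, 119L, p_len = 26L, s_len = 26L)
  a <- ev$alignments
  pr19 <- a[a$read_id == "evB1_pr19", ]
  expect_equal(c(pr19$start, pr19$end), c(100L, 119L))
  p <- a[a$read_id == "evB1_p", ]
  expect_equal(c(p$start, p$strand), c("119", "+"))
  s <- a[a$read_id == "evB1_s", ]
  expect_equal(s$strand, "-")
  expect_equal(s$end - 1L, 128L)
  # same-sense p-piRNA 5' at pr19 start + 19; antisense s-piRNA 5' at + 28
  expect_equal(p$start - pr19$start, 19L)
  expect_equal((s$end - 1L) - pr19$start, 28L)
  cls <- classify_library(a, ref)$reads
  expect_equal(as.character(cls$class[match(ev$truth$read_id, cls$read_id)]),
               ev$truth$true_class)
})

test_that("background reads are labelled, uniform-ish and id-disjoint", {
  ref <- random_reference(50000, seed = 8)
  bg <- add_background(ref, 4000, length_range = c(19, 19), seed = 3)
  expect_equal(nrow(bg$reads), 4000L)
  expect_true(all(bg$truth$true_class == "background"))
  cls <- classify_library(bg$alignments, ref)$reads
  frac <- mean(substr(cls$down_flank, 10, 10) == "A", na.rm = TRUE)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
  sim <- simulate_library(sim_config(seed = 12, n_events_A = 5,
                                     n_events_B = 5, background_n = 10))
  expect_false(any(grepl("^ev", sim$truth$read_id[
    sim$truth$true_class == "background"])))
  expect_equal(nrow(add_background(ref, 0)$reads), 0L)
})

test_that("simulated libraries are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 33, ref_length = 8000, n_events_A = 10,
                    n_events_B = 10, background_n = 50)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_library(cfg, out_dir = d1)
  simulate_library(cfg, out_dir = d2)
  for (f in c("reads.fasta", "truth.sam", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("simulated FASTA + SAM round-trip through the readers", {
  cfg <- sim_config(seed = 34, ref_length = 8000, n_events_A = 5,
                    n_events_B = 5)
  d <- withr::local_tempdir()
  sim <- simulate_library(cfg, out_dir = d)
  reads <- read_sequences(file.path(d, "reads.fasta"))
  expect_equal(sum(reads$count), sum(sim$reads$count))
  aln <- read_alignments_sam(file.path(d, "truth.sam"), sim$reference)
  expect_equal(aln[c("read_id", "start", "end", "strand", "seq", "count")],
               sim$alignments[c("read_id", "start", "end", "strand", "seq",
                                "count")])
})

test_that("synthetic genome plants events in the designated features", {
  sim <- simulate_genome(seed = 9)
  expect_equal(sum(nchar(sim$genome)), sum(sim$chrom_sizes$size))
  expect_setequal(unique(sim$truth$expected_category),
                  c("LTR", "Clusters", "RefSeq", "unannotated"))
  # chrom.sizes matches FASTA lengths per chromosome
  expect_equal(unname(nchar(sim$genome[sim$chrom_sizes$chrom])),
               sim$chrom_sizes$size)
})
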