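test_that("composite reference is LTR + internal + LTR", {
  expect_equal(build_composite_reference("AC", "GGGG"), "ACGGGGAC")
  expect_equal(nchar(build_composite_reference(strrep("A", 338),
                                               strrep("C", 7000))), 7676L)
  expect_error(build_composite_reference("", "GGGG"), "non-empty")
})

test_that("map_read finds exact and mismatched placements on both strands", {
  ref <- random_reference(200, seed = 11)
  read <- substr(ref[[1]], 41, 59)
  hit <- map_read(read, ref, max_mismatches = 0)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 40L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$mismatches, 0L)

  rc <- revcomp(substr(ref[[1]], 11, 36))
  hit2 <- map_read(rc, ref, max_mismatches = 0)
  expect_equal(hit2$start, 10L)
  expect_equal(hit2$end, 36L)
  expect_equal(hit2$strand, "-")

  # two substitutions found at mm=2 but not mm=0
  mut <- read
  substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(read, 3, 3))[1]
  substr(mut, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                 substr(read, 15, 15))[1]
  expect_equal(nrow(map_read(mut, ref, max_mismatches = 0)), 0L)
  h <- map_read(mut, ref, max_mismatches = 2)
  expect_true(any(h$start == 40 & h$mismatches == 2))
})

test_that("mapper agrees with the sliding-window oracle for mm 0-2", {
  set.seed(202)
  for (rep in 1:6) {
    ref <- random_reference(200, seed = 300 + rep)
    for (mm in 0:2) {
      # reads: an exact slice, a mutated slice, and a random sequence
      s <- sample(1:170, 1)
      exact <- substr(ref[[1]], s, s + 18)
      mut <- exact
      for (p in sample(1:19, mm)) {
        substr(mut, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(exact, p, p)), 1)
      }
      rand <- paste(sample(c("A", "C", "G", "T"), 19, replace = TRUE),
                    collapse = "")
      for (read in c(exact, mut, rand, revcomp(mut))) {
        got <- map_read(read, ref, max_mismatches = mm)
        want <- oracle_map(read, ref[[1]], mm)
        key <- function(d) sort(paste(d$start, d$end, d$strand, d$mismatches))
        expect_equal(key(got), key(want))
      }
    }
  }
})

test_that("N never counts as a match", {
  ref <- as_reference_set(c(r = paste0("AAAA", "ACGTACGTACGTACGTACG", "TTTT")))
  read_n <- "ACGTACGTACGTACGTACN"
  expect_equal(nrow(map_read(read_n, ref, max_mismatches = 0)), 0L)
  h <- map_read(read_n, ref, max_mismatches = 1)
  expect_true(any(h$start == 4 & h$mismatches == 1))
})

test_that("mapping a read and its reverse complement mirrors strand labels", {
  ref <- random_reference(250, seed = 21)
  read <- substr(ref[[1]], 101, 126)
  a <- map_read(read, ref, max_mismatches = 1)
  b <- map_read(revcomp(read), ref, max_mismatches = 1)
  flip <- c("+" = "-", "-" = "+")
  key <- function(d, s) sort(paste(d$start, d$end, s, d$mismatches))
  expect_equal(key(a, a$strand), key(b, unname(flip[b$strand])))
})

test_that("max_hits suppression and library mapping with unmapped report", {
  ref <- as_reference_set(c(r = strrep("ACGTACGTACGTACGTACGG", 3)))
  multi <- substr(ref[[1]], 1, 19)
  res <- map_read(multi, ref, max_mismatches = 0, max_hits = 1)
  expect_equal(nrow(res), 0L)
  expect_true(attr(res, "exceeded"))

  reads <- data.frame(id = c("a", "b", "c"),
                      seq = c(substr(ref[[1]], 5, 23),
                              substr(ref[[1]], 11, 30),
                              strrep("T", 19)),
                      count = 1L, stringsAsFactors = FALSE)
  lib <- map_library(reads, ref, max_mismatches = 0)
  expect_setequal(unique(lib$alignments$read_id), c("a", "b"))
  expect_equal(lib$unmapped$read_id, "c")
  expect_equal(lib$unmapped$reason, "no_hit")
})

test_that("two-pass mapping drops pass-1 failures from pass 2", {
  consensus <- random_reference(400, seed = 31, name = "cons")
  # repeat database: two genomic copies of a consensus segment
  db <- as_reference_set(c(copy1 = substr(consensus[[1]], 51, 250),
                           copy2 = substr(consensus[[1]], 101, 350)))
  inside <- substr(consensus[[1]], 120, 145)
  outside <- substr(consensus[[1]], 1, 26)   # on consensus but not in db
  reads <- data.frame(id = c("in", "out"), seq = c(inside, outside),
                      count = 1L, stringsAsFactors = FALSE)
  tp <- map_two_pass(reads, db, consensus)
  expect_equal(tp$pass1_ids, "in")
  expect_setequal(unique(tp$alignments$read_id), "in")
  expect_true("out" %in% tp$unmapped_pass1$read_id)
})
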