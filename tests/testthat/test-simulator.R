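test_that("synthetic reference is deterministic with valid annotation", {
  lib <- make_te_library(4, seed = 1)
  ref1 <- make_synthetic_reference(1e5, lib, n_copies = 8, seed = 2)
  ref2 <- make_synthetic_reference(1e5, lib, n_copies = 8, seed = 2)
  expect_identical(ref1$genome, ref2$genome)
  expect_identical(ref1$annotation, ref2$annotation)
  expect_equal(nrow(ref1$annotation), 8)
  expect_true(all(ref1$annotation$start >= 0 & ref1$annotation$end <= 1e5))
  expect_equal(nchar(ref1$genome[[1]]), 1e5)
  # planted copies read back from the genome match the library
  a <- ref1$annotation[1, ]
  seq <- substr(ref1$genome[[1]], a$start + 1, a$end)
  cons <- lib$sequence[lib$family == a$family]
  expect_equal(seq, if (a$strand == "+") cons else revcomp(cons))

  ref0 <- make_synthetic_reference(1e5, lib, n_copies = 0, seed = 3)
  expect_equal(nrow(ref0$annotation), 0)
})

test_that("mutated genomes conserve lengths and report a full truth set", {
  lib <- te_library(c("teA", "teB"), c(rand_dna(5000), rand_dna(1000)))
  ann <- tibble::tibble(contig = "chrS", start = 20000, end = 21500,
                        strand = "+", family = "teB", copy_id = "teB#1")
  g <- c(chrS = rand_dna(1e5))
  substr(g[[1]], 20001, 21500) <- substr(lib$sequence[2], 1, 1500)

  libA <- te_library("teA", lib$sequence[1])
  mutA <- mutate_genome(g, ann[0, ], libA, n_insertions = 1, n_excisions = 0,
                        seed = 4)
  expect_equal(nchar(mutA$genome[[1]]), 1e5 + 5000)
  mutA6 <- mutate_genome(g, ann[0, ], libA, n_insertions = 1, n_excisions = 0,
                         tsd_len = 6, seed = 4)
  expect_equal(nchar(mutA6$genome[[1]]), 1e5 + 5006)

  mutE <- mutate_genome(g, ann, lib, n_insertions = 0, n_excisions = 1,
                        seed = 5)
  expect_equal(nchar(mutE$genome[[1]]), 1e5 - 1500)

  mut <- mutate_genome(g, ann, lib, n_insertions = 3, n_excisions = 1, seed = 6)
  expect_equal(nrow(mut$truth), 4)
  expect_equal(sum(mut$truth$kind == "insertion"), 3)
  expect_error(mutate_genome(g, ann, lib, n_excisions = 2), "not enough")
})

test_that("read simulation matches the coverage formula and error model", {
  g <- c(chrS = rand_dna(1e6))
  set.seed(7)
  reads <- simulate_reads(g, depth = 5, read_length = 90, seed = 8)
  expect_equal(nrow(reads), 27778)     # round(5 * 1e6 / 180)
  reads2 <- simulate_reads(g, depth = 5, read_length = 90, seed = 8)
  expect_identical(reads, reads2)

  # error-free reads are exact genome substrings / reverse complements
  g2 <- c(chrS = rand_dna(2e5))
  ef <- simulate_reads(g2, depth = 2, error_rate = 0, seed = 9)
  for (i in sample(nrow(ef), 20)) {
    expect_true(grepl(ef$seq1[i], g2[[1]], fixed = TRUE))
    expect_true(grepl(revcomp(ef$seq2[i]), g2[[1]], fixed = TRUE))
  }

  # fragment length distribution: mean within 1% of 500, truncated at 180
  many <- simulate_reads(g, depth = 18, error_rate = 0, seed = 10)
  expect_gt(nrow(many), 9e4)
  expect_lt(abs(mean(many$frag_end - many$frag_start) - 500), 5)
  expect_true(all(many$frag_end - many$frag_start >= 180))
})

test_that("pool mixing is binomial, deterministic and exact at frequency 1", {
  g <- c(chrS = rand_dna(2e5))
  v <- simulate_reads(g, depth = 9, seed = 11, prefix = "v")
  r <- simulate_reads(g, depth = 9, seed = 12, prefix = "r")
  expect_identical(mix_pools(v, r, 1), v)
  m1 <- mix_pools(v, r, 0.5, seed = 13)
  m2 <- mix_pools(v, r, 0.5, seed = 13)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), nrow(v))
  frac <- mean(startsWith(m1$qname, "v"))
  n <- nrow(v)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  expect_error(mix_pools(v, r[1:10, ], 0.01, seed = 14), "too small")
  expect_error(mix_pools(v, v, 0.5, seed = 15))
})

test_that("fastq and truth files round-trip", {
  g <- c(chrS = rand_dna(1.2e5))
  reads <- simulate_reads(g, depth = 0.5, seed = 16)
  prefix <- tempfile("reads")
  paths <- write_fastq_pairs(reads, prefix)
  l1 <- readLines(paths[1])
  expect_equal(length(l1), 4 * nrow(reads))
  expect_equal(sub("^@", "", l1[1]), reads$qname[1])
  expect_equal(l1[2], reads$seq1[1])

  lib <- make_te_library(2, seed = 17)
  ref <- make_synthetic_reference(1e5, lib, n_copies = 4, seed = 18)
  mut <- mutate_genome(ref$genome, ref$annotation, lib, 2, 2, seed = 19)
  tpath <- tempfile(fileext = ".tsv")
  write_truth(mut$truth, tpath)
  back <- read_truth(tpath)
  expect_equal(back$junction_plus, mut$truth$junction_plus)
  expect_equal(back$kind, mut$truth$kind)
})
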