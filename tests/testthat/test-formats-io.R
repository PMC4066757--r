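test_that("alignment reading preserves reads, parses clips and pairing", {
  seqA <- strrep("A", 90)
  clip_seq <- paste0(strrep("C", 10), strrep("A", 80))
  sam <- write_test_bam(c(
    sam_record("p1", 99, "chrT", 101, 60, "90M", "=", 511, 500, seqA),
    sam_record("c1", 0, "chrT", 201, 37, "10S80M", "*", 0, 0, clip_seq),
    sam_record("p1", 147, "chrT", 511, 60, "90M", "=", 101, -500, seqA),
    sam_record("u1", 69, "chrT", 701, 0, "*", "=", 701, 0, seqA),
    sam_record("u1", 137, "chrT", 701, 60, "90M", "=", 701, 0, seqA)
  ))
  aln <- read_alignments(sam)
  expect_equal(nrow(aln), 5)

  p1 <- dplyr::filter(aln, qname == "p1", is_first)
  expect_equal(p1$start, 100)          # 1-based 101 -> 0-based 100
  expect_equal(p1$end, 190)
  expect_equal(p1$strand, "+")
  expect_true(p1$proper && p1$is_unique)
  expect_equal(p1$mate_start, 510)

  c1 <- dplyr::filter(aln, qname == "c1")
  expect_equal(c1$clip_left, 10)       # CIGAR 10S80M
  expect_equal(c1$end - c1$start, 80)  # aligned span excludes the clip
  expect_equal(c1$clip_left_seq, strrep("C", 10))
  expect_equal(c1$clip_right, 0)

  u1 <- dplyr::filter(aln, qname == "u1", unmapped)
  expect_equal(nrow(u1), 1)
  expect_false(u1$is_unique)
  expect_equal(u1$seq, seqA)           # sequence kept for TE matching

  # region queries select by overlap; an empty region is not an error
  bam <- Rsamtools::asBam(sam, destination = sub("\\.sam$", "", sam),
                          overwrite = TRUE, indexDestination = TRUE)
  hit <- read_alignments(bam, region = list(contig = "chrT", start = 0, end = 150))
  expect_true("p1" %in% hit$qname && !"c1" %in% hit$qname)
  none <- read_alignments(bam, region = list(contig = "chrT", start = 5000, end = 6000))
  expect_equal(nrow(none), 0)
})

test_that("TE library loading tokenises names, uppercases, rejects duplicates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">pogo some description", "acgtacgtacgt",
               ">roo", "GGGTTTAAACCC",
               ">jockey", "ATATATATAT"), fa)
  lib <- load_te_library(fa)
  expect_equal(nrow(lib), 3)
  expect_equal(lib$family, c("pogo", "roo", "jockey"))
  expect_equal(lib$sequence[1], "ACGTACGTACGT")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), fa)
  expect_error(load_te_library(fa), "duplicate")
  writeLines(character(0), fa)
  expect_error(load_te_library(fa))
})

test_that("annotation loading converts coordinates per dialect", {
  rm_out <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat class/family begin end (left) ID",
    "",
    " 1234  1.5  0.2  0.3  chr2L  1001  1500  (100)  +  roo  LTR/Bel  1  500  (0)  1",
    "  800  2.0  0.1  0.0  chr2L  1200  1700  (100)  C  jockey  LINE/Jockey  1  501  (0)  2"
  ), rm_out)
  ann <- load_te_annotation(rm_out, dialect = "repeatmasker_out")
  expect_equal(ann$start[1], 1000)     # 1-based inclusive -> 0-based half-open
  expect_equal(ann$end[1], 1500)
  expect_equal(ann$strand, c("+", "-"))
  expect_equal(nrow(ann), 2)           # overlapping annotations kept unmerged

  # conversion is self-inverse
  expect_equal(ann$start + 1, c(1001, 1200))
  expect_equal(ann$end, c(1500, 1700))

  bed <- tempfile(fileext = ".bed")
  writeLines("chr2L\t999\t1500\troo", bed)
  annb <- load_te_annotation(bed, dialect = "bed")
  expect_equal(annb$start, 999)
  expect_equal(annb$end, 1500)
  expect_equal(annb$family, "roo")

  writeLines("chr2L\tnot_a_number\t1500\troo", bed)
  expect_error(load_te_annotation(bed, dialect = "bed"), "line 1")
})

make_events_fixture <- function() {
  tibble::tibble(
    contig = c("chr2L", "chr2L", "chr2L"),
    start = c(500, 100, 100),
    end = c(900, 600, 600),
    family = c("pogo", "roo", "jockey"),
    strand = c("+", "-", "+"),
    kind = "insertion",
    junction_plus = c(700, NA, 105),
    junction_minus = c(695, NA, 100),
    junction_resolution = c("base", "interval_midpoint", "base"),
    support_sides = c("both", "left_only", "both"),
    T = c(3L, 5L, 7L),
    R = c(1L, 0L, 93L),
    frequency = c(0.75, 1, 0.07)
  )
}

test_that("event tables round-trip and sort deterministically", {
  ev <- make_events_fixture()
  path <- tempfile(fileext = ".tsv")
  write_events(ev, path, config = tepool_config(insert_mean = 500))
  lines <- readLines(path)
  expect_true(any(grepl("^# insert_mean = 500", lines)))
  back <- read_events(path)
  expect_equal(nrow(back), 3)
  # tie at start 100 broken by family: jockey before roo
  expect_equal(back$family, c("jockey", "roo", "pogo"))
  expect_equal(back$frequency, c(0.07, 1, 0.75), tolerance = 1e-6)
  ord <- order(match(back$family, ev$family))
  for (col in c("contig", "start", "end", "strand", "kind",
                "junction_resolution", "support_sides", "T", "R")) {
    expect_equal(back[[col]][ord], ev[[col]], ignore_attr = TRUE)
  }
  # T=3, R=1 prints as 0.750000
  expect_true(any(grepl("\t0\\.750000\t", lines)))

  write_events(ev[0, ], path)
  empty <- read_events(path)
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty)[1:3], c("contig", "start", "end"))

  bed <- tempfile(fileext = ".bed")
  write_events_bed(ev, bed)
  b <- read.table(bed, sep = "\t")
  expect_equal(b$V5, c(70, 1000, 750)) # round(frequency * 1000)
})

test_that("insert-size estimation recovers library statistics", {
  aln <- dplyr::bind_rows(lapply(1:200, function(i) {
    make_pair(paste0("q", i), 1000 + i, 1000 + i + 480 + (i %% 41))
  }))
  st <- estimate_insert_stats(aln)
  expect_true(abs(st$insert_mean - 500) < 15)
  expect_true(st$insert_sd > 0)
})
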