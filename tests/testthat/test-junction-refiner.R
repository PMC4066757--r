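test_that("clip collection respects the extended window bounds", {
  ev <- tibble::tibble(event_id = 1L, contig = "chrT", start = 1000, end = 1200,
                       kind = "insertion", family = "roo")
  clip <- function(q, point, side, len = 10) {
    if (side == "leading") {
      make_aln(list(qname = q, start = point, end = point + 80,
                    clip_left = as.integer(len),
                    clip_left_seq = strrep("C", len), cigar = "10S80M"))
    } else {
      make_aln(list(qname = q, start = point - 80, end = point,
                    clip_right = as.integer(len),
                    clip_right_seq = strrep("C", len), cigar = "80M10S"))
    }
  }
  aln <- dplyr::bind_rows(
    clip("at_lower", 980, "leading"),    # exactly start - 20: included
    clip("above", 1225, "trailing"),     # end + 25: excluded
    make_aln(list(qname = "both_ends", start = 1050, end = 1130,
                  clip_left = 5L, clip_left_seq = "CCCCC",
                  clip_right = 6L, clip_right_seq = "GGGGGG",
                  cigar = "5S79M6S"))
  )
  got <- collect_clips(ev, aln, window = 20)
  expect_true("at_lower" %in% got$qname)
  expect_false("above" %in% got$qname)
  expect_equal(sum(got$qname == "both_ends"), 2) # two candidate clip points
})

test_that("insertion clips need 7 nt and a perfect consensus match", {
  lib <- te_library("roo", rand_dna(400))
  ev <- tibble::tibble(event_id = 1L, contig = "chrT", start = 1000,
                       end = 1200, kind = "insertion", family = "roo",
                       strand = "+")
  good12 <- substr(lib$sequence, 1, 12)
  bad12 <- good12
  substr(bad12, 6, 6) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad12, 6, 6))[1]
  clips <- tibble::tibble(
    qname = c("short", "mismatch", "good", "revcomp"),
    contig = "chrT", point = 1100,
    clip_side = "trailing",
    clip_seq = c(substr(good12, 1, 6), bad12, good12, rc_chr(good12)),
    clip_len = c(6L, 12L, 12L, 12L)
  )
  acc <- validate_clips(clips, ev, lib)
  expect_equal(acc, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("absence clips must continue on the other side of the TE", {
  genome <- c(chrT = rand_dna(3000))
  ev <- tibble::tibble(event_id = 1L, contig = "chrT", start = 1000,
                       end = 2000, kind = "absence", family = "roo")
  beyond_end <- substr(genome[[1]], 2001, 2012)   # right of the TE
  before_start <- substr(genome[[1]], 989, 1000)  # left of the TE
  clips <- tibble::tibble(
    qname = c("left_ok", "right_ok", "wrong_seq", "far_point"),
    contig = "chrT",
    point = c(1000, 2000, 1000, 1500),
    clip_side = c("trailing", "leading", "trailing", "trailing"),
    clip_seq = c(beyond_end, before_start, rand_dna(12), beyond_end),
    clip_len = 12L
  )
  acc <- validate_clips(clips, ev, library = NULL, genome = genome)
  expect_equal(acc, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("junction refinement picks the modal clip point with leftmost ties", {
  ev <- tibble::tibble(event_id = 1L, contig = "chrT", start = 1000,
                       end = 1200, kind = "insertion", family = "roo")
  clips <- tibble::tibble(
    qname = paste0("q", 1:5), contig = "chrT",
    point = c(1005, 1005, 1005, 1005, 1007),
    clip_side = "trailing", clip_seq = "X", clip_len = 10L
  )
  clips$point <- c(1005, 1005, 1005, 1005, 1007)
  r <- refine_junction(ev, clips[c(1, 2, 3, 4, 5), ])
  expect_equal(r$junction_plus, 1005)  # 4 reads beat 1
  expect_equal(r$junction_resolution, "base")

  tie <- clips[1:4, ]
  tie$point <- c(1005, 1005, 1007, 1007)
  expect_equal(refine_junction(ev, tie)$junction_plus, 1005) # tie -> leftmost

  # shuffling the clips never changes the estimate
  set.seed(42)
  expect_equal(refine_junction(ev, clips[sample(5), ]),
               refine_junction(ev, clips))

  # no accepted clips: insertion falls back to the interval midpoint
  none <- refine_junction(ev, clips[0, ])
  expect_equal(none$junction_resolution, "interval_midpoint")
  expect_true(is.na(none$junction_plus))

  eva <- dplyr::mutate(ev, kind = "absence")
  fb <- refine_junction(eva, clips[0, ])
  expect_equal(fb$junction_resolution, "annotated_boundary")
  expect_equal(c(fb$junction_plus, fb$junction_minus), c(1000, 1200))
})

test_that("TSD length is the signed junction difference", {
  expect_equal(tsd_length(1005, 1000), 5)   # 5 nt duplication
  expect_equal(tsd_length(1000, 1000), 0)   # blunt insertion
  expect_equal(tsd_length(998, 1000), -2)   # target-site depletion
  expect_true(is.na(tsd_length(NA, 1000)))
})
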