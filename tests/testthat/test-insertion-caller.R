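test_that("interval estimates follow anchor geometry and clamp at contig ends", {
  # + strand anchor ending at 1000: junction within the next insert_mean bp
  iv <- interval_estimate("+", 910, 1000, 500)
  expect_equal(c(iv$ivl_start, iv$ivl_end), c(1000, 1500))
  iv <- interval_estimate("-", 1000, 1090, 500)
  expect_equal(c(iv$ivl_start, iv$ivl_end), c(500, 1000))
  iv <- interval_estimate("+", 1810, 1900, 500, contig_length = 2000)
  expect_equal(c(iv$ivl_start, iv$ivl_end), c(1900, 2000))
  expect_warning(
    iv <- interval_estimate("-", 0, 90, 500, contig_length = 2000, pad = 0),
    "discarded"
  )
  expect_true(is.na(iv$ivl_start))
  # junction-facing pad widens towards the anchor
  iv <- interval_estimate("+", 910, 1000, 500, pad = 20)
  expect_equal(c(iv$ivl_start, iv$ivl_end), c(980, 1500))
})

test_that("orientation follows the FR truth table and flipping is an involution", {
  expect_equal(infer_orientation("+", "+"), "-")
  expect_equal(infer_orientation("+", "-"), "+")
  expect_equal(infer_orientation("-", "+"), "+")
  expect_equal(infer_orientation("-", "-"), "-")
  for (a in c("+", "-")) for (t in c("+", "-")) {
    expect_true(infer_orientation(a, t) != infer_orientation(a, flip <- setdiff(c("+", "-"), t)))
  }
})

test_that("discordant extraction keeps anchor + distant TE mate pairs only", {
  lib <- te_library("P-element", rand_dna(500))
  te_read <- substr(lib$sequence, 101, 190)
  aln <- dplyr::bind_rows(
    make_pair("conc", 1000, 1500),                       # proper pair: excluded
    make_aln(list(qname = "d1", start = 2000, end = 2090, strand = "+",
                  mapq = 60L, proper = FALSE, is_first = TRUE)),
    make_aln(list(qname = "d1", flag = 4L, start = NA, end = NA,
                  unmapped = TRUE, mapq = 0L, is_unique = FALSE,
                  proper = FALSE, is_first = FALSE, seq = te_read)),
    make_aln(list(qname = "d2", start = 3000, end = 3090, strand = "+",
                  proper = FALSE, is_first = TRUE)),
    make_aln(list(qname = "d2", start = NA, end = NA, unmapped = TRUE,
                  mapq = 0L, is_unique = FALSE, proper = FALSE,
                  is_first = FALSE, seq = rand_dna(90)))   # no TE family
  )
  sup <- extract_discordant(aln, lib, insert_mean = 500)
  expect_equal(sup$qname, "d1")
  expect_equal(sup$family, "P-element")
  expect_equal(sup$side, "left")
  expect_equal(sup$orientation, infer_orientation("+", "+"))
})

test_that("clustering intersects overlapping intervals within family and strand", {
  base <- tibble::tibble(
    qname = c("a", "b"), contig = "chrT", anchor_start = 0, anchor_end = 1,
    anchor_strand = "+", family = "roo", te_strand = "-", orientation = "+",
    side = c("left", "right")
  )
  sup <- dplyr::mutate(base, ivl_start = c(100, 400), ivl_end = c(600, 900))
  ev <- cluster_supports(sup)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start, ev$end), c(400, 600))
  expect_equal(ev$T, 2L)
  expect_equal(ev$support_sides, "both")

  sup2 <- dplyr::mutate(base, ivl_start = c(100, 700), ivl_end = c(600, 900))
  expect_equal(nrow(cluster_supports(sup2)), 2)

  # same interval, opposite orientations: never clustered together
  sup3 <- dplyr::mutate(base, ivl_start = 100, ivl_end = 600,
                        orientation = c("+", "-"))
  expect_equal(nrow(cluster_supports(sup3)), 2)
})

test_that("clustering is permutation-invariant and refined intervals are intersections", {
  set.seed(500)
  for (trial in 1:30) {
    n <- sample(2:40, 1)
    s <- sample(0:2000, n, replace = TRUE)
    sup <- tibble::tibble(
      qname = paste0("q", seq_len(n)), contig = "chrT",
      anchor_start = 0, anchor_end = 1, anchor_strand = "+",
      family = "roo", te_strand = "-", orientation = "+",
      side = sample(c("left", "right"), n, TRUE),
      ivl_start = s, ivl_end = s + sample(50:600, n, TRUE)
    )
    ev1 <- cluster_supports(sup)
    ev2 <- cluster_supports(sup[sample(n), ])
    expect_equal(ev1, ev2)
    # refined interval is a subset of every member interval and non-empty
    for (i in seq_len(nrow(ev1))) {
      members <- sup[match(ev1$qnames[[i]], sup$qname), ]
      expect_true(ev1$start[i] < ev1$end[i])
      expect_true(all(ev1$start[i] >= members$ivl_start &
                        ev1$end[i] <= members$ivl_end))
    }
    expect_equal(sum(ev1$T), n)
  }
})

test_that("sweep chaining equals the O(n^2) transitive-closure oracle", {
  set.seed(501)
  for (trial in 1:500) {
    n <- sample(2:200, 1)
    s <- sample(0:5000, n, replace = TRUE)
    e <- s + sample(1:800, n, replace = TRUE)
    canon <- function(x) match(x, unique(x))
    expect_equal(canon(overlap_chains(s, e)), canon(oracle_overlap_clusters(s, e)))
  }
})
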