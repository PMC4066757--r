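truth_fix <- tibble::tibble(
  kind = c("insertion", "insertion", "excision"),
  contig = "chrT",
  family = c("roo", "pogo", "jockey"),
  orientation = c("+", "-", "+"),
  junction_plus = c(1050, 5000, 8000),
  junction_minus = c(1050, 5000, 9000),
  tsd = c(0, 0, NA),
  copy_id = c(NA, NA, "jockey#3"),
  designed_frequency = c(0.5, 0.5, 1)
)

pred_base <- tibble::tibble(
  contig = "chrT",
  start = c(1000, 4800, 8000),
  end = c(1100, 5300, 9000),
  family = c("roo", "pogo", "jockey"),
  strand = c("+", "-", "+"),
  kind = c("insertion", "insertion", "absence"),
  copy_id = c(NA, NA, "jockey#3"),
  junction_plus = c(1055, NA, 8000),
  junction_minus = c(1050, NA, 9000),
  junction_resolution = c("base", "interval_midpoint", "base"),
  frequency = c(0.45, 0.62, 1)
)

test_that("matching follows the recovery criteria", {
  m <- match_events(pred_base, truth_fix)
  expect_true(all(m$truth$detected))
  expect_true(all(m$predictions$label == "TP"))

  # wrong orientation: FP and FN
  p2 <- dplyr::mutate(pred_base, strand = c("-", "-", "+"))
  m2 <- match_events(p2, truth_fix)
  expect_false(m2$truth$detected[1])
  expect_equal(m2$predictions$label[1], "FP")

  # interval not containing the junction: FP and FN
  p3 <- pred_base
  p3$start[1] <- 1100; p3$end[1] <- 1200
  m3 <- match_events(p3, truth_fix)
  expect_false(m3$truth$detected[1])
  expect_equal(m3$predictions$label[1], "FP")

  # labels partition predictions and truth
  for (mm in list(m, m2, m3)) {
    rep <- metrics_report(mm)
    ov <- dplyr::filter(rep, is.na(designed_frequency))
    expect_equal(sum(ov$tp + ov$fp), nrow(pred_base))
    expect_equal(sum(ov$tp + ov$fn), nrow(truth_fix))
  }

  # each prediction matches at most one truth (duplicate truths go FN)
  t_dup <- dplyr::bind_rows(truth_fix[1, ], truth_fix[1, ], truth_fix[2:3, ])
  m4 <- match_events(pred_base, t_dup)
  expect_equal(sum(m4$truth$detected[1:2]), 1)
})

test_that("junction scoring uses the 5 nt window on either strand", {
  m <- match_events(pred_base, truth_fix)
  s <- score_junctions(m)
  expect_equal(s$junction_found, 2 / 3)   # midpoint resolution not "found"
  expect_equal(s$junction_correct, 1)     # |1055 - 1050| = 5 counts

  p <- pred_base
  p$junction_plus[1] <- 1056
  p$junction_minus[1] <- 1056
  s2 <- score_junctions(match_events(p, truth_fix))
  expect_equal(s2$junction_correct, 0.5)  # distance 6: found but incorrect
})

test_that("feeding truth back as predictions is scored perfectly", {
  perfect <- tibble::tibble(
    contig = truth_fix$contig,
    start = truth_fix$junction_plus - 50,
    end = truth_fix$junction_plus + 50,
    family = truth_fix$family,
    strand = truth_fix$orientation,
    kind = ifelse(truth_fix$kind == "excision", "absence", "insertion"),
    copy_id = truth_fix$copy_id,
    junction_plus = truth_fix$junction_plus,
    junction_minus = truth_fix$junction_minus,
    junction_resolution = "base",
    frequency = truth_fix$designed_frequency
  )
  rep <- metrics_report(match_events(perfect, truth_fix))
  ov <- dplyr::filter(rep, is.na(designed_frequency))
  expect_true(all(ov$sensitivity == 1))
  expect_true(all(ov$precision == 1))
  expect_true(all(ov$fdr == 0))
  expect_true(all(ov$mean_freq_error == 0))
  expect_true(all(ov$junction_correct == 1))
  # sensitivity = TP/(TP+FN), precision = 1 - FDR by construction
  expect_equal(ov$sensitivity, ov$tp / (ov$tp + ov$fn))
  expect_equal(ov$precision, 1 - ov$fdr)
})

test_that("reports are reproducible and tidy/glance behave", {
  m <- match_events(pred_base, truth_fix)
  r1 <- metrics_report(m)
  r2 <- metrics_report(m)
  expect_identical(r1, r2)
  td <- generics::tidy(r1)
  expect_true(all(c("measure", "value") %in% names(td)))
  gl <- generics::glance(r1)
  expect_equal(nrow(gl), 2)            # one overall row per kind
})
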