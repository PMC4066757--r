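# Scores predicted events against a simulator truth set. An insertion is
# recovered when the predicted interval estimate contains the true junction
# and family and orientation are correct; an excision is recovered when the
# corresponding annotated copy is reported absent. Junction base estimates
# count as correct within 5 nt of the truth.

#' Match predicted events against a truth set
#'
#' Insertion truths match predictions of the same contig, family and
#' orientation whose interval `[start, end)` contains the true junction;
#' excision truths match absence predictions referencing the annotated copy.
#' Each prediction matches at most one truth record, assigned greedily by
#' distance between the predicted interval midpoint and the true junction.
#'
#' @param predicted Event tibble (insertion and/or absence calls).
#' @param truth Truth tibble from [mutate_genome()] (optionally with a
#'   `designed_frequency` column).
#' @return List with `truth` (per-truth labels, matched prediction fields)
#'   and `predictions` (per-prediction `label` of `"TP"`/`"FP"`).
#' @export
match_events <- function(predicted, truth) {
  predicted <- mutate(ungroup(predicted), pred_row = row_number())
  truth <- mutate(ungroup(truth), truth_row = row_number())
  pred_label <- rep("FP", nrow(predicted))
  t_pred <- rep(NA_integer_, nrow(truth))

  cand <- bind_rows(
    # insertions
    inner_join(
      truth %>% filter(.data$kind == "insertion"),
      predicted %>% filter(.data$kind == "insertion"),
      by = c("contig", "family"), suffix = c("_t", "_p"),
      relationship = "many-to-many"
    ) %>%
      filter(.data$orientation == .data$strand,
             .data$junction_plus_t >= .data$start,
             .data$junction_plus_t < .data$end) %>%
      mutate(dist = abs((.data$start + .data$end) / 2 - .data$junction_plus_t)) %>%
      select("truth_row", "pred_row", "dist"),
    # excisions
    inner_join(
      truth %>% filter(.data$kind == "excision") %>%
        select("truth_row", "contig", t_copy = "copy_id"),
      predicted %>% filter(.data$kind == "absence") %>%
        select("pred_row", "contig", "copy_id") %>%
        mutate(copy = strsplit(.data$copy_id, ",")) %>%
        tidyr::unnest("copy"),
      by = "contig", relationship = "many-to-many"
    ) %>%
      filter(.data$t_copy == .data$copy) %>%
      mutate(dist = 0) %>%
      select("truth_row", "pred_row", "dist")
  )

  cand <- arrange(cand, .data$dist, .data$truth_row, .data$pred_row)
  used_pred <- logical(nrow(predicted))
  used_truth <- logical(nrow(truth))
  for (i in seq_len(nrow(cand))) {
    tr <- cand$truth_row[i]
    pr <- cand$pred_row[i]
    if (used_pred[pr] || used_truth[tr]) next
    used_pred[pr] <- TRUE
    used_truth[tr] <- TRUE
    t_pred[tr] <- pr
    pred_label[pr] <- "TP"
  }

  truth <- truth %>% mutate(
    detected = !is.na(t_pred),
    pred_row = t_pred,
    pred_frequency = predicted$frequency[t_pred],
    pred_resolution = predicted$junction_resolution[t_pred],
    pred_junction_plus = predicted$junction_plus[t_pred],
    pred_junction_minus = predicted$junction_minus[t_pred]
  )
  predictions <- mutate(predicted, label = pred_label)
  list(truth = truth, predictions = predictions)
}

#' Junction recovery rates among matched events
#'
#' `junction_found` is the fraction of true positives with a base-resolution
#' junction estimate; `junction_correct` is the fraction of those whose
#' estimate lies within `tol` nt of the true junction on either strand.
#'
#' @param matched Output of [match_events()].
#' @param tol Tolerance (nt, default 5).
#' @return One-row tibble with `junction_found`, `junction_correct`, and the
#'   underlying counts.
#' @export
score_junctions <- function(matched, tol = 5) {
  tp <- filter(matched$truth, .data$detected)
  found <- tp$pred_resolution == "base"
  correct <- junction_correct_flags(tp, tol)
  tibble(
    n_tp = nrow(tp),
    n_base = sum(found),
    junction_found = if (nrow(tp)) mean(found) else NA_real_,
    junction_correct = if (sum(found)) mean(correct[found]) else NA_real_
  )
}

junction_correct_flags <- function(tp, tol = 5) {
  okp <- !is.na(tp$pred_junction_plus) &
    abs(tp$pred_junction_plus - tp$junction_plus) <= tol
  okm <- !is.na(tp$pred_junction_minus) &
    abs(tp$pred_junction_minus - tp$junction_minus) <= tol
  okp | okm
}

#' Sensitivity / precision / FDR / frequency-error report
#'
#' One row per (kind, designed frequency) plus an overall row per kind
#' (`designed_frequency = NA`). False positives are binned by their
#' estimated frequency (nearest designed bin) in the stratified rows.
#'
#' @param matched Output of [match_events()].
#' @param tol Junction tolerance (nt).
#' @return Tibble of class `tepool_metrics` with columns `kind`,
#'   `designed_frequency`, `tp`, `fp`, `fn`, `sensitivity`, `precision`,
#'   `fdr`, `mean_freq_error`, `junction_found`, `junction_correct`.
#' @export
metrics_report <- function(matched, tol = 5) {
  truth <- matched$truth %>%
    mutate(kind = if_else(.data$kind == "excision", "absence", .data$kind))
  truth$correct_junction <- junction_correct_flags(truth, tol)
  preds <- matched$predictions
  has_freq <- "designed_frequency" %in% names(truth)

  one_cell <- function(tr, fp) {
    tp <- sum(tr$detected)
    fn <- sum(!tr$detected)
    tpd <- filter(tr, .data$detected)
    found <- tpd$pred_resolution == "base"
    tibble(
      tp = tp, fp = fp, fn = fn,
      sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
      precision = if (tp + fp) tp / (tp + fp) else NA_real_,
      fdr = if (tp + fp) fp / (tp + fp) else NA_real_,
      mean_freq_error = if (has_freq && tp > 0)
        mean(abs(tpd$pred_frequency - tpd$designed_frequency)) else NA_real_,
      junction_found = if (tp) mean(found) else NA_real_,
      junction_correct = if (sum(found)) mean(tpd$correct_junction[found])
        else NA_real_
    )
  }

  rows <- list()
  for (k in unique(truth$kind)) {
    pk <- if_else(k == "absence", "absence", "insertion")
    tr_k <- filter(truth, .data$kind == k)
    fp_k <- filter(preds, .data$label == "FP", .data$kind == pk)
    rows[[length(rows) + 1]] <- bind_cols(
      tibble(kind = k, designed_frequency = NA_real_),
      one_cell(tr_k, nrow(fp_k))
    )
    if (has_freq) {
      freqs <- sort(unique(tr_k$designed_frequency))
      fp_bin <- if (nrow(fp_k)) {
        freqs[vapply(fp_k$frequency,
                     function(f) which.min(abs(freqs - f)), integer(1))]
      } else numeric(0)
      for (fq in freqs) {
        rows[[length(rows) + 1]] <- bind_cols(
          tibble(kind = k, designed_frequency = fq),
          one_cell(filter(tr_k, .data$designed_frequency == fq),
                   sum(fp_bin == fq))
        )
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("tepool_metrics", class(tibble()))
  out
}
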