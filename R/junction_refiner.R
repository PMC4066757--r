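# Resolves event junctions to base-pair resolution from soft-clipped reads.
# Reads clipped at their trailing (3') end approach a junction from the left
# and estimate the plus-strand junction; leading clips approach from the
# right and estimate the minus-strand junction. The signed difference
# junction_plus - junction_minus is the target site duplication length.

# All candidate clip points of a read table: one row per soft-clipped read
# end with its genomic clip point and clipped sequence.
clip_table <- function(aln, min_clip = 1) {
  mapped <- filter(aln, !.data$unmapped)
  bind_rows(
    mapped %>% filter(.data$clip_left >= min_clip) %>%
      mutate(point = .data$start, clip_side = "leading",
             clip_seq = .data$clip_left_seq, clip_len = .data$clip_left),
    mapped %>% filter(.data$clip_right >= min_clip) %>%
      mutate(point = .data$end, clip_side = "trailing",
             clip_seq = .data$clip_right_seq, clip_len = .data$clip_right)
  ) %>%
    select("qname", "contig", "point", "clip_side", "clip_seq", "clip_len")
}

#' Collect candidate soft-clipped reads for events
#'
#' Returns soft-clip points falling inside each event's interval estimate
#' extended by `window` bp in both directions (inclusive lower bound,
#' exclusive upper bound). A read clipped at both ends contributes two
#' candidate points.
#'
#' @param events Event tibble with `event_id`, `contig`, `start`, `end`.
#' @param aln Alignment tibble.
#' @param window Extension of the interval estimate (bp).
#' @return Tibble of candidate clips keyed by `event_id`.
#' @export
collect_clips <- function(events, aln, window = 20) {
  clips <- clip_table(aln)
  if (nrow(clips) == 0 || nrow(events) == 0) {
    return(mutate(clips[0, ], event_id = integer()))
  }
  ctg <- sort(unique(c(clips$contig, events$contig)))
  pts <- GenomicRanges::GRanges(factor(clips$contig, ctg),
                                IRanges::IRanges(clips$point + 1, width = 1))
  win <- GenomicRanges::GRanges(
    factor(events$contig, ctg),
    IRanges::IRanges(pmax(events$start - window, 0) + 1, events$end + window))
  ov <- GenomicRanges::findOverlaps(pts, win)
  tibble(event_id = events$event_id[S4Vectors::subjectHits(ov)],
         clips[S4Vectors::queryHits(ov), ])
}

#' Validate candidate clips against an event
#'
#' A clip supports an insertion junction when it is at least `min_clip` nt
#' long and matches the event family's consensus perfectly (either TE
#' strand, anywhere in the consensus, so truncated copies and internal
#' junctions validate). For absence events the clipped portion must map
#' perfectly to the genomic sequence on the other side of the spanned TE,
#' and the clip point must lie near the matching annotated boundary:
#' trailing clips belong to the left (start) boundary and continue beyond
#' the TE end; leading clips belong to the right (end) boundary and
#' continue from before the TE start.
#'
#' @param clips Candidate clip tibble for one event ([collect_clips()] rows).
#' @param event One-row event tibble.
#' @param library `te_library` (used for insertion events).
#' @param genome Named character vector of contig sequences (absence events).
#' @param min_clip Minimum clip length (nt).
#' @param boundary_tol How far (bp) an absence clip point may sit from the
#'   annotated boundary it refines.
#' @return Logical vector, `TRUE` for accepted clips.
#' @export
validate_clips <- function(clips, event, library, genome = NULL,
                           min_clip = 7, boundary_tol = 20) {
  if (nrow(clips) == 0) return(logical(0))
  ok <- clips$clip_len >= min_clip
  if (event$kind == "insertion") {
    cons <- library$sequence[match(event$family, library$family)]
    cons_rc <- revcomp(cons)
    idx <- which(ok)
    ok[idx] <- vapply(clips$clip_seq[idx], function(s) {
      grepl(s, cons, fixed = TRUE) || grepl(s, cons_rc, fixed = TRUE)
    }, logical(1))
  } else {
    if (is.null(genome)) abort("absence clip validation needs the genome")
    gseq <- genome[[event$contig]]
    te_start <- event$start
    te_end <- event$end
    idx <- which(ok)
    ok[idx] <- vapply(idx, function(i) {
      len <- clips$clip_len[i]
      if (clips$clip_side[i] == "trailing") {
        if (abs(clips$point[i] - te_start) > boundary_tol) return(FALSE)
        win <- substr(gseq, te_end + 1, min(nchar(gseq), te_end + len + 20))
      } else {
        if (abs(clips$point[i] - te_end) > boundary_tol) return(FALSE)
        win <- substr(gseq, max(1, te_start - len - 20 + 1), te_start)
      }
      grepl(clips$clip_seq[i], win, fixed = TRUE)
    }, logical(1))
  }
  ok
}

#' Refine an event junction from accepted clips
#'
#' Per clip side, the junction is the clip point supported by the most
#' accepted clips (ties broken towards the smaller coordinate). Trailing
#' clips give `junction_plus`, leading clips `junction_minus`. Without any
#' accepted clip the surrogate is the interval midpoint (insertions) or the
#' annotated boundaries (absences).
#'
#' @param event One-row event tibble.
#' @param clips Accepted clips for this event.
#' @return One-row tibble: `junction_plus`, `junction_minus`,
#'   `junction_resolution`, `n_clips_plus`, `n_clips_minus`.
#' @export
refine_junction <- function(event, clips) {
  tr <- clips$point[clips$clip_side == "trailing"]
  le <- clips$point[clips$clip_side == "leading"]
  if (length(tr) + length(le) > 0) {
    tibble(
      junction_plus = if (length(tr)) mode_min(tr) else NA_real_,
      junction_minus = if (length(le)) mode_min(le) else NA_real_,
      junction_resolution = "base",
      n_clips_plus = length(tr), n_clips_minus = length(le)
    )
  } else if (event$kind == "insertion") {
    tibble(junction_plus = NA_real_, junction_minus = NA_real_,
           junction_resolution = "interval_midpoint",
           n_clips_plus = 0L, n_clips_minus = 0L)
  } else {
    tibble(junction_plus = event$start, junction_minus = event$end,
           junction_resolution = "annotated_boundary",
           n_clips_plus = 0L, n_clips_minus = 0L)
  }
}

#' Refine junctions for a whole event table
#'
#' Orchestrates [collect_clips()], [validate_clips()] and
#' [refine_junction()] over every event and records the supporting clip
#' read names (they count towards `T`).
#'
#' @param events Pre-frequency event tibble (must carry `event_id`).
#' @param aln Alignment tibble.
#' @param library `te_library`.
#' @param genome Named character vector of contig sequences.
#' @param config A [tepool_config()].
#' @return `events` with junction columns and a `clip_qnames` list-column.
#' @export
refine_junctions <- function(events, aln, library, genome = NULL,
                             config = tepool_config()) {
  if (nrow(events) == 0) {
    return(mutate(events, junction_plus = numeric(), junction_minus = numeric(),
                  junction_resolution = character(), n_clips_plus = integer(),
                  n_clips_minus = integer(), clip_qnames = list()))
  }
  cand <- collect_clips(events, aln, window = config$clip_window)
  res <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    cl <- filter(cand, .data$event_id == ev$event_id)
    acc <- cl[validate_clips(cl, ev, library, genome,
                             min_clip = config$min_clip), , drop = FALSE]
    bind_cols(refine_junction(ev, acc),
              tibble(clip_qnames = list(unique(acc$qname))))
  })
  bind_cols(events, res)
}

#' Target site duplication length
#'
#' Signed difference between the plus- and minus-strand junction estimates:
#' positive values are duplication lengths, negative values target-site
#' deletions, `NA` when either strand lacks a base estimate.
#'
#' @param junction_plus,junction_minus Per-strand junction coordinates.
#' @return Integer-valued numeric vector of TSD lengths.
#' @export
tsd_length <- function(junction_plus, junction_minus) {
  junction_plus - junction_minus
}
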