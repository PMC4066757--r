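# Population frequency of an event is T/(T+R): T = read pairs supporting the
# event (discordant pairs plus junction-delineating clipped reads, counted
# once per pair), R = concordant both-unique pairs whose fragment spans the
# estimated junction with enough flank on both sides.

#' Count supporting read pairs (T)
#'
#' Distinct read pairs contributing either a discordant support or an
#' accepted junction clip; a pair contributing both counts once.
#'
#' @param discordant_qnames,clip_qnames Character vectors of pair names.
#' @return Integer count.
#' @export
count_supporting <- function(discordant_qnames, clip_qnames = character()) {
  length(unique(c(discordant_qnames, clip_qnames)))
}

#' Concordant fragments table
#'
#' Both-unique FR pairs whose outer span is within the concordance band;
#' these are the candidate reference-consistent pairs.
#'
#' @param aln Alignment tibble.
#' @param insert_mean,insert_sd Library insert statistics (bp).
#' @param span_z Concordance band half-width in standard deviations.
#' @return Tibble `qname`, `contig`, `frag_start`, `frag_end`.
#' @export
concordant_fragments <- function(aln, insert_mean, insert_sd, span_z = 3) {
  pr <- pair_alignments(aln) %>%
    filter(.data$is_unique_1, .data$is_unique_2,
           .data$contig_1 == .data$contig_2,
           .data$strand_1 != .data$strand_2)
  if (nrow(pr) == 0) {
    return(tibble(qname = character(), contig = character(),
                  frag_start = numeric(), frag_end = numeric()))
  }
  left_first <- pr$start_1 <= pr$start_2
  fwd <- ifelse(left_first, pr$strand_1, pr$strand_2)
  pr %>%
    mutate(frag_start = pmin(.data$start_1, .data$start_2),
           frag_end = pmax(.data$end_1, .data$end_2)) %>%
    filter(fwd == "+",
           .data$frag_end - .data$frag_start <= insert_mean + span_z * insert_sd) %>%
    select(qname = "qname", contig = "contig_1", "frag_start", "frag_end")
}

# pairs spanning given junction points with >= m bp on each side, excluding
# per-event support pairs. points: tibble(event_id, contig, point).
count_spanning <- function(points, fragments, exclude, m = 7) {
  if (nrow(points) == 0) return(integer(0))
  counts <- integer(nrow(points))
  if (nrow(fragments) == 0) return(counts)
  ctg <- sort(unique(c(points$contig, fragments$contig)))
  shrunk_start <- fragments$frag_start + m
  shrunk_end <- fragments$frag_end - m
  keep <- shrunk_start <= shrunk_end
  fr <- fragments[keep, , drop = FALSE]
  fr_r <- GenomicRanges::GRanges(factor(fr$contig, ctg),
                                 IRanges::IRanges(shrunk_start[keep] + 1,
                                                  shrunk_end[keep]))
  pt_r <- GenomicRanges::GRanges(factor(points$contig, ctg),
                                 IRanges::IRanges(points$point + 1, width = 1))
  ov <- GenomicRanges::findOverlaps(pt_r, fr_r)
  if (length(ov) == 0) return(counts)
  hits <- tibble(row = S4Vectors::queryHits(ov),
                 qname = fr$qname[S4Vectors::subjectHits(ov)])
  hits <- hits %>%
    mutate(excluded = purrr::map2_lgl(.data$row, .data$qname,
                                      function(r, q) q %in% exclude[[points$event_id[r]]])) %>%
    filter(!.data$excluded)
  tab <- table(hits$row)
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' Count reference-consistent read pairs (R)
#'
#' For insertion events, R is the number of concordant both-unique pairs
#' whose fragment contains the estimated junction (base estimate when
#' available, otherwise the interval midpoint surrogate) with at least
#' `ref_flank` bp between the junction and both fragment ends. For absence
#' events both annotated boundaries are measured and the two spanning-pair
#' counts averaged, since each boundary samples the same local reference
#' coverage. Pairs already counted in T never count towards R.
#'
#' @param events Event tibble with junction columns and `qnames`/
#'   `clip_qnames` list-columns.
#' @param fragments Output of [concordant_fragments()].
#' @param ref_flank Minimum junction-to-fragment-end distance (bp).
#' @return Integer vector of R counts aligned with `events` rows.
#' @export
count_reference <- function(events, fragments, ref_flank = 7) {
  if (nrow(events) == 0) return(integer(0))
  exclude <- purrr::map2(events$qnames, events$clip_qnames,
                         function(a, b) unique(c(a, b)))
  is_ins <- events$kind == "insertion"
  R <- integer(nrow(events))
  if (any(is_ins)) {
    ev <- events[is_ins, ]
    j <- dplyr::coalesce(ev$junction_plus, ev$junction_minus,
                         floor((ev$start + ev$end) / 2))
    pts <- tibble(event_id = which(is_ins), contig = ev$contig, point = j)
    R[is_ins] <- count_spanning(pts, fragments, exclude, m = ref_flank)
  }
  if (any(!is_ins)) {
    ev <- events[!is_ins, ]
    idx <- which(!is_ins)
    left <- count_spanning(tibble(event_id = idx, contig = ev$contig,
                                  point = ev$start),
                           fragments, exclude, m = ref_flank)
    right <- count_spanning(tibble(event_id = idx, contig = ev$contig,
                                   point = ev$end),
                            fragments, exclude, m = ref_flank)
    R[!is_ins] <- as.integer(round((left + right) / 2))
  }
  R
}

#' Population frequency estimate
#'
#' @param T Supporting pair count (>= 1).
#' @param R Reference-consistent pair count (>= 0).
#' @return `T / (T + R)`, in (0, 1].
#' @export
estimate_frequency <- function(T, R) {
  if (any(T < 1)) abort("frequency is undefined for events with T = 0")
  if (any(R < 0)) abort("R must be non-negative")
  T / (T + R)
}

#' Attach T, R and frequency to refined events
#'
#' @param events Refined event tibble (with `qnames` and `clip_qnames`).
#' @param fragments Output of [concordant_fragments()].
#' @param config A [tepool_config()].
#' @return Events with `T`, `R`, `frequency`; events without any supporting
#'   pair are dropped with a warning.
#' @export
add_frequencies <- function(events, fragments, config = tepool_config()) {
  if (nrow(events) == 0) {
    return(mutate(events, R = integer(), frequency = numeric()))
  }
  events$T <- purrr::map2_int(events$qnames, events$clip_qnames,
                              function(a, b) count_supporting(a, b))
  drop <- events$T == 0
  if (any(drop)) {
    warn(sprintf("dropping %d event(s) without supporting pairs", sum(drop)))
    events <- events[!drop, , drop = FALSE]
  }
  events$R <- count_reference(events, fragments, ref_flank = config$ref_flank)
  events$frequency <- estimate_frequency(events$T, events$R)
  events
}
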