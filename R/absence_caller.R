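# Detects reference-annotated TEs that are absent from sample genomes: both
# mates map uniquely, the fragment spans much more than the insert size, the
# intervening region contains one or more annotated TE copies, and the span
# minus the spanned TE length is again consistent with the library.

#' Extract long-spanning candidate pairs for absence detection
#'
#' Keeps FR-oriented pairs with both mates uniquely mapped whose outer
#' fragment span exceeds `insert_mean + span_z * insert_sd` but stays below
#' `max_span` (larger spans are treated as mapping artifacts).
#'
#' @param aln Alignment tibble from [read_alignments()].
#' @param insert_mean,insert_sd Library insert statistics (bp).
#' @param span_z Concordance band half-width in standard deviations.
#' @param max_span Maximum believable fragment span (bp).
#' @return Candidate tibble: `qname`, `contig`, `outer_start`, `outer_end`,
#'   `inner_start`, `inner_end`, `span` (outer).
#' @export
extract_long_span <- function(aln, insert_mean, insert_sd, span_z = 3,
                              max_span = 10000) {
  pr <- pair_alignments(aln)
  pr <- pr %>%
    filter(.data$is_unique_1, .data$is_unique_2,
           .data$contig_1 == .data$contig_2,
           .data$strand_1 != .data$strand_2)
  if (nrow(pr) == 0) return(empty_long_span())
  left_first <- pr$start_1 <= pr$start_2
  fwd <- ifelse(left_first, pr$strand_1, pr$strand_2)
  pr <- pr %>%
    mutate(outer_start = pmin(.data$start_1, .data$start_2),
           outer_end = pmax(.data$end_1, .data$end_2),
           inner_start = pmin(.data$end_1, .data$end_2),
           inner_end = pmax(.data$start_1, .data$start_2),
           span = .data$outer_end - .data$outer_start) %>%
    filter(fwd == "+",
           .data$span > insert_mean + span_z * insert_sd,
           .data$span < max_span,
           .data$inner_start <= .data$inner_end) %>%
    select(qname = "qname", contig = "contig_1", "outer_start", "outer_end",
           "inner_start", "inner_end", "span")
  pr
}

empty_long_span <- function() {
  tibble(qname = character(), contig = character(), outer_start = numeric(),
         outer_end = numeric(), inner_start = numeric(),
         inner_end = numeric(), span = numeric())
}

#' Check that long-span candidates bracket annotated TE copies
#'
#' A candidate becomes an absence support when at least one annotated TE
#' copy lies fully inside its inner span (both junctions bracketed) and the
#' TE-subtracted span is consistent with the library insert size:
#' `|span - sum(TE lengths) - insert_mean| <= span_z * insert_sd`.
#'
#' @param candidates Output of [extract_long_span()].
#' @param annotation TE annotation tibble ([load_te_annotation()]).
#' @inheritParams extract_long_span
#' @return Support tibble with `copy_ids` (list-column of spanned copies),
#'   `copy_set` (canonical key), `adjusted_span`, plus candidate columns.
#' @export
check_te_span <- function(candidates, annotation, insert_mean, insert_sd,
                          span_z = 3) {
  empty <- candidates[0, ] %>%
    mutate(copy_ids = list(), copy_set = character(),
           adjusted_span = numeric())
  if (nrow(candidates) == 0 || nrow(annotation) == 0) return(empty)
  ctg <- sort(unique(c(candidates$contig, annotation$contig)))
  cand_r <- GenomicRanges::GRanges(
    factor(candidates$contig, ctg),
    IRanges::IRanges(candidates$inner_start + 1, candidates$inner_end))
  ann_r <- GenomicRanges::GRanges(
    factor(annotation$contig, ctg),
    IRanges::IRanges(annotation$start + 1, annotation$end))
  ov <- GenomicRanges::findOverlaps(ann_r, cand_r, type = "within")
  if (length(ov) == 0) return(empty)
  hits <- tibble(cand = S4Vectors::subjectHits(ov),
                 ann = S4Vectors::queryHits(ov)) %>%
    mutate(copy_id = annotation$copy_id[.data$ann],
           te_len = annotation$end[.data$ann] - annotation$start[.data$ann]) %>%
    arrange(.data$cand, .data$copy_id) %>%
    group_by(.data$cand) %>%
    summarise(copy_ids = list(.data$copy_id),
              copy_set = paste(.data$copy_id, collapse = ","),
              te_total = sum(.data$te_len), .groups = "drop")
  out <- candidates[hits$cand, , drop = FALSE] %>%
    mutate(copy_ids = hits$copy_ids, copy_set = hits$copy_set,
           adjusted_span = .data$span - hits$te_total) %>%
    filter(abs(.data$adjusted_span - insert_mean) <= span_z * insert_sd)
  out
}

#' Cluster absence supports into events
#'
#' Supports sharing an identical spanned-copy set form one event, anchored
#' to the annotated copy interval(s).
#'
#' @param supports Output of [check_te_span()].
#' @param annotation TE annotation tibble.
#' @return Pre-frequency absence event tibble with `copy_id`, annotated
#'   interval, `family`, `strand`, `kind`, `T` and a `qnames` list-column.
#' @export
cluster_absence <- function(supports, annotation) {
  if (nrow(supports) == 0) {
    return(tibble(contig = character(), start = numeric(), end = numeric(),
                  family = character(), strand = character(),
                  kind = character(), copy_id = character(),
                  support_sides = character(), T = integer(), qnames = list()))
  }
  ann <- annotation %>% select("copy_id", ann_start = "start",
                               ann_end = "end", ann_family = "family",
                               ann_strand = "strand")
  supports %>%
    group_by(.data$contig, .data$copy_set) %>%
    summarise(copy_ids = .data$copy_ids[1],
              T = dplyr::n(),
              qnames = list(unique(.data$qname)), .groups = "drop") %>%
    mutate(info = purrr::map(.data$copy_ids, function(ids) {
      a <- ann[match(ids, ann$copy_id), ]
      tibble(start = min(a$ann_start), end = max(a$ann_end),
             family = paste(unique(a$ann_family), collapse = ","),
             strand = if (dplyr::n_distinct(a$ann_strand) == 1)
               a$ann_strand[1] else "*")
    })) %>%
    tidyr::unnest("info") %>%
    mutate(kind = "absence", support_sides = "both",
           copy_id = .data$copy_set) %>%
    select("contig", "start", "end", "family", "strand", "kind", "copy_id",
           "support_sides", "T", "qnames") %>%
    arrange(.data$contig, .data$start, .data$family)
}
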