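# High-level entry points tying the modules together: BAM in, event tibble
# out.

finalize_events <- function(events, aln, library, genome, config) {
  events <- mutate(events, event_id = row_number())
  events <- refine_junctions(events, aln, library, genome, config)
  frags <- concordant_fragments(aln, config$insert_mean, config$insert_sd,
                                config$span_z)
  events <- add_frequencies(events, frags, config)
  events <- filter_events(events, min_reads = config$min_reads,
                          min_freq = config$min_freq)
  class(events) <- c("tepool_events", class(tibble()))
  events
}

#' Call sample-specific TE insertions from a BAM file
#'
#' Full insertion pipeline: discordant-pair extraction, TE family
#' assignment, interval clustering, soft-clip junction refinement and
#' frequency estimation.
#'
#' @param bam Coordinate-sorted BAM path (or an alignment tibble from
#'   [read_alignments()]).
#' @param library TE consensus library ([load_te_library()]).
#' @param genome Optional named character vector of contig sequences.
#' @param config A [tepool_config()]; `insert_mean` is estimated from
#'   proper pairs when unset.
#' @return Event tibble of class `tepool_events`.
#' @export
call_te_insertions <- function(bam, library, genome = NULL,
                               config = tepool_config()) {
  aln <- if (is.character(bam)) {
    read_alignments(bam, mapq_unique = config$mapq_unique)
  } else bam
  if (is.na(config$insert_mean)) {
    st <- estimate_insert_stats(aln)
    config$insert_mean <- st$insert_mean
    config$insert_sd <- st$insert_sd
  }
  contig_lengths <- tapply(aln$end, aln$contig, max, na.rm = TRUE)
  supports <- extract_discordant(aln, library,
                                 insert_mean = config$insert_mean,
                                 max_mismatch = config$max_mismatch,
                                 contig_lengths = contig_lengths,
                                 n_is_wildcard = config$n_is_wildcard,
                                 junction_pad = config$junction_pad)
  events <- cluster_supports(supports)
  finalize_events(events, aln, library, genome, config)
}

#' Call reference-annotated TEs absent from the sample
#'
#' Full absence pipeline: long-span pair extraction, TE-span consistency
#' check, clustering by spanned copy set, boundary clip refinement and
#' frequency estimation.
#'
#' @inheritParams call_te_insertions
#' @param annotation Reference TE annotation ([load_te_annotation()]).
#' @return Event tibble of class `tepool_events`.
#' @export
call_te_absences <- function(bam, annotation, genome = NULL,
                             library = NULL, config = tepool_config()) {
  aln <- if (is.character(bam)) {
    read_alignments(bam, mapq_unique = config$mapq_unique)
  } else bam
  if (is.na(config$insert_mean)) {
    st <- estimate_insert_stats(aln)
    config$insert_mean <- st$insert_mean
    config$insert_sd <- st$insert_sd
  }
  cand <- extract_long_span(aln, config$insert_mean, config$insert_sd,
                            span_z = config$span_z,
                            max_span = config$max_span)
  supports <- check_te_span(cand, annotation, config$insert_mean,
                            config$insert_sd, span_z = config$span_z)
  events <- cluster_absence(supports, annotation)
  finalize_events(events, aln, library, genome, config)
}

#' Filter events by support and frequency
#'
#' @param events Event tibble.
#' @param min_reads Minimum supporting pair count `T` (the published human
#'   analysis used "more than eight reads", i.e. `min_reads = 9`).
#' @param min_freq Minimum estimated frequency.
#' @return Filtered event tibble.
#' @export
filter_events <- function(events, min_reads = 1, min_freq = 0) {
  filter(events, .data$T >= min_reads, .data$frequency >= min_freq)
}
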