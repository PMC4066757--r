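#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over plain character vectors. `N` maps to
#' `N`; input is uppercased first.
#'
#' @param x Character vector of nucleotide sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# log(sum(exp(x))) without overflow; handles -Inf-only input.
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Most frequent value; ties broken by the smallest value.
mode_min <- function(x) {
  tab <- table(x)
  hits <- names(tab)[tab == max(tab)]
  min(as.numeric(hits))
}

#' Default run configuration
#'
#' Bundles the tunable parameters shared by the callers. Values follow the
#' method's published constants where one exists (7 nt minimum clip, 20 bp
#' clip window, 10 kb span cap, 3 mismatches against the TE consensus) and
#' documented defaults elsewhere (mapping quality >= 20 as the uniqueness
#' proxy, span z of 3 for "significantly longer than the insert size",
#' reference flank of 7 bp mirroring the clip rule).
#'
#' @param insert_mean Mean library insert size (outer fragment length, bp).
#'   `NA` means estimate from proper pairs.
#' @param insert_sd Insert size standard deviation (bp).
#' @param span_z Number of insert-size standard deviations beyond the mean
#'   before a pair counts as "significantly longer" (absence detection).
#' @param max_span Maximum outer span (bp) considered for absence evidence;
#'   larger spans are treated as mapping artifacts.
#' @param min_clip Minimum soft-clip length (nt) for junction evidence.
#' @param clip_window Extension (bp) of the interval estimate when
#'   collecting soft-clipped reads.
#' @param max_mismatch Maximum mismatches when assigning a read to a TE
#'   consensus family.
#' @param mapq_unique Minimum mapping quality for a read to count as
#'   uniquely mapped.
#' @param ref_flank Minimum distance (bp) between a junction and both
#'   fragment ends for a pair to count as reference-consistent.
#' @param junction_pad Junction-facing extension of anchor interval
#'   estimates (bp), absorbing soft-clip overhangs and target site
#'   duplications; see [interval_estimate()].
#' @param min_reads Minimum supporting pair count `T` for a reported event.
#' @param min_freq Minimum estimated frequency for a reported event.
#' @param n_is_wildcard Should `N` match any base in TE consensus matching?
#' @return A list of class `tepool_config`.
#' @export
tepool_config <- function(insert_mean = NA_real_, insert_sd = 50,
                          span_z = 3, max_span = 10000,
                          min_clip = 7, clip_window = 20,
                          max_mismatch = 3, mapq_unique = 20,
                          ref_flank = 7, min_reads = 1, min_freq = 0,
                          junction_pad = 20, n_is_wildcard = TRUE) {
  cfg <- list(
    insert_mean = insert_mean, insert_sd = insert_sd, span_z = span_z,
    max_span = max_span, min_clip = min_clip, clip_window = clip_window,
    max_mismatch = max_mismatch, mapq_unique = mapq_unique,
    ref_flank = ref_flank, min_reads = min_reads, min_freq = min_freq,
    junction_pad = junction_pad, n_is_wildcard = n_is_wildcard
  )
  num <- vapply(cfg[names(cfg) != "n_is_wildcard"], as.numeric, numeric(1))
  if (any(!is.na(num) & num < 0)) abort("configuration values must be non-negative")
  structure(cfg, class = "tepool_config")
}

config_header_lines <- function(config) {
  vals <- vapply(config, function(v) paste(format(v), collapse = ","), character(1))
  paste0("# ", names(config), " = ", vals)
}
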