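# Detects sample-specific TE insertions from discordant read pairs: one
# uniquely mapped anchor plus a mate that is unmapped or multi-mapping and
# matches a TE consensus. Anchors give interval estimates that are clustered
# into events.

#' Interval estimate for a junction from an anchor read
#'
#' The junction must lie in the interval beginning at the insertion-facing
#' end of the anchor and extending into the genome by the mean insert size:
#' a `+`-strand anchor ending (exclusively) at `e` gives `[e, e + insert_mean)`,
#' a `-`-strand anchor starting at `s` gives `[s - insert_mean, s)`. Intervals
#' are clamped to `[0, contig_length)`.
#'
#' With a local (soft-clipping) aligner an anchor can extend up to the
#' junction and a few bases beyond it through microhomology with the
#' inserted sequence, and target site duplications shift the two per-strand
#' junctions apart; `pad` widens the interval on the junction-facing side to
#' absorb these overhangs so the intersection of clustered intervals still
#' contains the junction.
#'
#' @param strand Anchor strand vector (`"+"`/`"-"`).
#' @param start,end Anchor alignment coordinates (0-based half-open).
#' @param insert_mean Mean library insert size (bp).
#' @param contig_length Contig length for clamping (default unbounded).
#' @param pad Junction-facing extension (bp, default 0).
#' @return Tibble with `ivl_start`, `ivl_end`; rows where clamping empties
#'   the interval carry `NA`.
#' @export
interval_estimate <- function(strand, start, end, insert_mean,
                              contig_length = Inf, pad = 0) {
  lo <- ifelse(strand == "+", end - pad, start - insert_mean)
  hi <- ifelse(strand == "+", end + insert_mean, start + pad)
  lo <- pmax(lo, 0)
  hi <- pmin(hi, contig_length)
  bad <- !(lo < hi)
  if (any(bad)) {
    warn(sprintf("%d interval estimate(s) empty after clamping; discarded",
                 sum(bad)))
    lo[bad] <- NA_real_
    hi[bad] <- NA_real_
  }
  tibble(ivl_start = lo, ivl_end = hi)
}

#' Infer insertion orientation from anchor and TE strands
#'
#' In an FR library the mate's expected genomic strand is the opposite of
#' the anchor's; the insertion is `+`-oriented exactly when the TE strand of
#' the mate differs from the anchor strand.
#'
#' @param anchor_strand Genomic strand of the anchor read.
#' @param te_strand Strand on which the mate (as sequenced) matches the TE
#'   consensus.
#' @return Character vector of event orientations (`"+"`/`"-"`).
#' @export
infer_orientation <- function(anchor_strand, te_strand) {
  ifelse(anchor_strand == te_strand, "-", "+")
}

#' Extract discordant-pair insertion supports
#'
#' Keeps read pairs with exactly one uniquely mapped mate whose other mate
#' is unmapped or multi-mapping *away from* the anchor (a multi-mapper that
#' the aligner placed concordantly beside its anchor is local, not distant,
#' evidence), and whose sequence matches a TE consensus within
#' `max_mismatch`. Each support carries the interval estimate and inferred
#' orientation.
#'
#' @param aln Alignment tibble from [read_alignments()].
#' @param library TE consensus library ([te_library()]).
#' @param insert_mean Mean insert size (bp).
#' @param max_mismatch Maximum mismatches for TE assignment.
#' @param contig_lengths Optional named vector of contig lengths.
#' @param n_is_wildcard Passed to [best_te_hits()].
#' @param junction_pad Junction-facing interval extension (bp); see
#'   [interval_estimate()].
#' @return Support tibble: `qname`, `contig`, anchor coordinates/strand,
#'   `family`, `te_strand`, `orientation`, `side`, `ivl_start`, `ivl_end`.
#' @export
extract_discordant <- function(aln, library, insert_mean, max_mismatch = 3,
                               contig_lengths = NULL, n_is_wildcard = TRUE,
                               junction_pad = 20) {
  pr <- pair_alignments(aln)
  a1 <- pr$is_unique_1 & !pr$is_unique_2 & (pr$unmapped_2 | !pr$proper_2)
  a2 <- pr$is_unique_2 & !pr$is_unique_1 & (pr$unmapped_1 | !pr$proper_1)
  cand <- bind_rows(
    pr %>% filter(a1) %>%
      select(qname = "qname", contig = "contig_1", anchor_start = "start_1",
             anchor_end = "end_1", anchor_strand = "strand_1",
             mate_seq = "seq_2", mate_aln_strand = "strand_2",
             mate_unmapped = "unmapped_2"),
    pr %>% filter(a2) %>%
      select(qname = "qname", contig = "contig_2", anchor_start = "start_2",
             anchor_end = "end_2", anchor_strand = "strand_2",
             mate_seq = "seq_1", mate_aln_strand = "strand_1",
             mate_unmapped = "unmapped_1")
  )
  if (nrow(cand) == 0) return(empty_supports())
  # recover the read as sequenced: records with the reverse flag set store
  # the sequence reverse-complemented (also true for placed unmapped mates)
  flip <- cand$mate_aln_strand == "-"
  cand$mate_seq[flip] <- revcomp(cand$mate_seq[flip])
  hits <- best_te_hits(cand$mate_seq, library, max_mismatch = max_mismatch,
                       n_is_wildcard = n_is_wildcard)
  keep <- hits$status == "hit"
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_supports())
  cand$family <- hits$family[keep]
  cand$te_strand <- hits$te_strand[keep]
  cl <- if (is.null(contig_lengths)) Inf else
    unname(contig_lengths[cand$contig])
  ivl <- interval_estimate(cand$anchor_strand, cand$anchor_start,
                           cand$anchor_end, insert_mean, cl,
                           pad = junction_pad)
  cand %>%
    mutate(orientation = infer_orientation(.data$anchor_strand, .data$te_strand),
           side = if_else(.data$anchor_strand == "+", "left", "right"),
           ivl_start = ivl$ivl_start, ivl_end = ivl$ivl_end) %>%
    filter(!is.na(.data$ivl_start)) %>%
    select("qname", "contig", "anchor_start", "anchor_end", "anchor_strand",
           "family", "te_strand", "orientation", "side",
           "ivl_start", "ivl_end")
}

empty_supports <- function() {
  tibble(qname = character(), contig = character(),
         anchor_start = numeric(), anchor_end = numeric(),
         anchor_strand = character(), family = character(),
         te_strand = character(), orientation = character(),
         side = character(), ivl_start = numeric(), ivl_end = numeric())
}

#' Single-linkage chains of the interval-overlap relation
#'
#' Partitions intervals into the connected components of the ">= 1 nt
#' overlap" relation (transitive closure). Input order is irrelevant.
#'
#' @param start,end Interval coordinates (0-based half-open).
#' @return Integer chain ids aligned with the input, numbered by leftmost
#'   member.
#' @export
overlap_chains <- function(start, end) {
  ord <- order(start, end)
  s <- as.numeric(start[ord])
  e <- as.numeric(end[ord])
  chain_sorted <- cumsum(s >= dplyr::lag(cummax(e), default = -Inf))
  chain <- integer(length(s))
  chain[ord] <- chain_sorted
  chain
}

# Greedy left-to-right split of one single-linkage chain (rows sorted by
# ivl_start) into maximal runs whose common intersection is non-empty.
split_chain <- function(df) {
  run <- integer(nrow(df))
  cur <- 1L
  hi <- df$ivl_end[1]
  run[1] <- cur
  for (i in seq_len(nrow(df))[-1]) {
    if (df$ivl_start[i] >= hi) {
      cur <- cur + 1L
      hi <- df$ivl_end[i]
    } else {
      hi <- min(hi, df$ivl_end[i])
    }
    run[i] <- cur
  }
  run
}

#' Cluster discordant supports into insertion events
#'
#' Supports of the same TE family and orientation on the same contig whose
#' interval estimates overlap by at least one nucleotide are single-linkage
#' clustered; the intersection of the member intervals is the refined
#' interval estimate. Chains whose global intersection is empty are split
#' greedily left-to-right into maximal runs with a non-empty common
#' intersection, so a refined interval is always an intersection of its
#' members. Input order does not affect the result.
#'
#' @param supports Support tibble from [extract_discordant()].
#' @return Pre-frequency event tibble: `contig`, `start`, `end` (refined
#'   interval), `family`, `strand`, `kind`, `support_sides`, `T`, and a
#'   `qnames` list-column of supporting pair names.
#' @export
cluster_supports <- function(supports) {
  if (nrow(supports) == 0) {
    return(tibble(contig = character(), start = numeric(), end = numeric(),
                  family = character(), strand = character(),
                  kind = character(), support_sides = character(),
                  T = integer(), qnames = list()))
  }
  supports %>%
    arrange(.data$contig, .data$family, .data$orientation,
            .data$ivl_start, .data$ivl_end, .data$qname) %>%
    group_by(.data$contig, .data$family, .data$orientation) %>%
    mutate(chain = overlap_chains(.data$ivl_start, .data$ivl_end)) %>%
    group_by(.data$chain, .add = TRUE) %>%
    mutate(run = split_chain(dplyr::pick(dplyr::everything()))) %>%
    group_by(.data$contig, .data$family, .data$orientation,
             .data$chain, .data$run) %>%
    summarise(
      start = max(.data$ivl_start),
      end = min(.data$ivl_end),
      support_sides = if (all(c("left", "right") %in% .data$side)) "both"
        else if (all(.data$side == "left")) "left_only" else "right_only",
      T = dplyr::n(),
      qnames = list(unique(.data$qname)),
      .groups = "drop"
    ) %>%
    mutate(kind = "insertion", strand = .data$orientation) %>%
    select("contig", "start", "end", "family", "strand", "kind",
           "support_sides", "T", "qnames") %>%
    arrange(.data$contig, .data$start, .data$family, .data$strand)
}
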