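# Cross-population analytics: deviation of progeny frequencies from the
# Mendelian expectation, an exact Wright-Fisher drift null for one
# generation, and nucleotide composition around insertion junctions.

#' Frequency change relative to Mendelian expectation
#'
#' For an event with frequencies `f` in the progeny pool and `h`, `w` in the
#' two parental pools, the frequency change is `fc = f - (h + w) / 2`.
#' Events are parental (and get an `fc`) only when the frequency exceeds
#' `parental_threshold` in at least one parental pool; large positive `fc`
#' suggests positive selection, large negative `fc` purifying selection.
#'
#' @param f,h,w Numeric vectors of frequencies in `[0, 1]` (progeny, parent
#'   1, parent 2).
#' @param parental_threshold Minimum parental frequency (default 0.10).
#' @return Tibble with `f`, `h`, `w`, `parental` and `fc` (`NA` for
#'   non-parental events).
#' @export
frequency_change <- function(f, h, w, parental_threshold = 0.10) {
  if (any(c(f, h, w) < 0 | c(f, h, w) > 1, na.rm = TRUE)) {
    abort("frequencies must lie in [0, 1]")
  }
  parental <- pmax(h, w) > parental_threshold
  tibble(f = f, h = h, w = w, parental = parental,
         fc = if_else(parental, f - (h + w) / 2, NA_real_))
}

#' Wright-Fisher one-generation tail probability of a frequency change
#'
#' Exact tail probability, under one generation of binomial resampling of
#' `n_chromosomes` chromosomes, that the offspring frequency deviates from
#' the parental frequency by at least `delta`, maximised over all parental
#' frequencies on the grid `{0, 1/n, ..., 1}`:
#' `max_p P(|X/n - p| >= delta)` with `X ~ Binomial(n, p)`. Tails are summed
#' exactly in log space, so values far below double-precision epsilon (the
#' published bound is 1e-15 for 200 chromosomes and `delta = 0.3`) are
#' meaningful.
#'
#' @param n_chromosomes Number of chromosomes (`2 * population size`).
#' @param delta Minimum absolute frequency change, in (0, 1); `delta = 0`
#'   returns 1.
#' @return Tail probability.
#' @export
wf_change_tail <- function(n_chromosomes, delta) {
  n <- as.integer(n_chromosomes)
  if (n < 2) abort("n_chromosomes must be at least 2")
  if (delta < 0 || delta >= 1) abort("delta must be in [0, 1)")
  if (delta == 0) return(1)
  eps <- 1e-9
  log_tail <- function(p) {
    kl <- floor(n * (p - delta) + eps)
    ku <- ceiling(n * (p + delta) - eps)
    lo <- if (kl >= 0) logsumexp(dbinom(0:min(kl, n), n, p, log = TRUE)) else -Inf
    hi <- if (ku <= n) logsumexp(dbinom(max(ku, 0):n, n, p, log = TRUE)) else -Inf
    logsumexp(c(lo, hi))
  }
  exp(max(vapply((0:n) / n, log_tail, numeric(1))))
}

#' Mono- and dinucleotide composition around insertion junctions
#'
#' For events with base junction estimates on both strands, extracts the
#' sequence extending `window` bp on both sides of the midpoint between the
#' two junctions (a `2 * window` bp window) and compares its k-mer
#' frequencies (k = 1, 2) against flanking background sequence
#' (`background_flank` bp immediately upstream and downstream of the
#' window). The enrichment of a k-mer is its frequency in the junction
#' windows divided by its frequency in the background.
#'
#' @param events Event tibble with `junction_plus`/`junction_minus`.
#' @param genome Named character vector of contig sequences.
#' @param window Half-width of the junction window (bp).
#' @param background_flank Length of each background flank (bp).
#' @param fasta Optional path; when given, the junction windows are also
#'   written as FASTA (input for external motif discovery).
#' @return Tibble with `kmer`, `k`, `junction_count`, `background_count`,
#'   `junction_freq`, `background_freq`, `enrichment`.
#' @export
junction_composition <- function(events, genome, window = 15,
                                 background_flank = 100, fasta = NULL) {
  ok <- !is.na(events$junction_plus) & !is.na(events$junction_minus) &
    events$junction_resolution == "base"
  skipped <- sum(!ok)
  if (skipped > 0) {
    inform(sprintf("%d event(s) without both-strand base junctions skipped",
                   skipped))
  }
  ev <- events[ok, , drop = FALSE]
  if (nrow(ev) == 0) {
    warn("no events with both-strand base junctions")
    return(tibble(kmer = character(), k = integer(),
                  junction_count = numeric(), background_count = numeric(),
                  junction_freq = numeric(), background_freq = numeric(),
                  enrichment = numeric()))
  }
  mid <- floor((ev$junction_plus + ev$junction_minus) / 2)
  get_seq <- function(contig, from, to) { # 0-based half-open, clamped
    g <- genome[[contig]]
    substr(g, max(1, from + 1), min(nchar(g), to))
  }
  win <- vapply(seq_len(nrow(ev)), function(i) {
    get_seq(ev$contig[i], mid[i] - window, mid[i] + window)
  }, character(1))
  bg <- unlist(lapply(seq_len(nrow(ev)), function(i) {
    c(get_seq(ev$contig[i], mid[i] - window - background_flank, mid[i] - window),
      get_seq(ev$contig[i], mid[i] + window, mid[i] + window + background_flank))
  }))
  if (!is.null(fasta)) {
    writeLines(as.vector(rbind(
      paste0(">junction_", seq_along(win), "_", ev$contig, "_", mid),
      win
    )), fasta)
  }
  counts <- function(seqs, k) {
    f <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs), k)
    colSums(f)
  }
  out <- bind_rows(lapply(1:2, function(k) {
    jc <- counts(win, k)
    bc <- counts(bg, k)
    tibble(kmer = names(jc), k = k,
           junction_count = as.numeric(jc),
           background_count = as.numeric(bc),
           junction_freq = as.numeric(jc) / sum(jc),
           background_freq = as.numeric(bc) / sum(bc),
           enrichment = (as.numeric(jc) / sum(jc)) /
             (as.numeric(bc) / sum(bc)))
  }))
  out
}

#' TSD length summary by family
#'
#' Modal target-site-duplication length per TE family among events with
#' both-strand base junctions, restricted to families with more than
#' `min_sites` non-redundant sites.
#'
#' @param events Event tibble.
#' @param min_sites Minimum number of distinct sites per family.
#' @return Tibble with `family`, `n_sites`, `tsd_mode`.
#' @export
tsd_by_family <- function(events, min_sites = 50) {
  events %>%
    filter(!is.na(.data$junction_plus), !is.na(.data$junction_minus),
           .data$junction_resolution == "base") %>%
    distinct(.data$contig, .data$family, .data$junction_plus,
             .data$junction_minus) %>%
    mutate(tsd = tsd_length(.data$junction_plus, .data$junction_minus)) %>%
    group_by(.data$family) %>%
    summarise(n_sites = dplyr::n(), tsd_mode = mode_min(.data$tsd),
              .groups = "drop") %>%
    filter(.data$n_sites > min_sites)
}
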