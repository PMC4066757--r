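# Assigns non-uniquely-mapping / unmapped mates to the TE consensus family
# they match with fewest mismatches, scanning both strands for ungapped
# end-to-end placements of the read inside a consensus.

# One concatenated subject holding all consensi, separated by gap runs that
# can never participate in a valid placement; placements are filtered to lie
# entirely within a single family span.
build_te_index <- function(library, sep_len = 10L) {
  if (!inherits(library, "te_library")) {
    library <- te_library(library$family, library$sequence)
  }
  if (nrow(library) == 0) abort("empty TE library")
  sep <- strrep("-", sep_len)
  cat_seq <- paste(library$sequence, collapse = sep)
  starts <- cumsum(c(1, head(library$length, -1) + sep_len))
  list(
    subject = Biostrings::DNAString(cat_seq),
    family = library$family,
    fam_start = starts,                      # 1-based start in subject
    fam_end = starts + library$length - 1L   # 1-based inclusive end
  )
}

# Minimal-mismatch placements of one oriented pattern in the concatenated
# subject. Returns data frame of family index, 1-based offset, mismatches.
scan_one_strand <- function(pattern, index, max_mismatch, fixed) {
  m <- Biostrings::matchPattern(pattern, index$subject,
                                max.mismatch = max_mismatch,
                                with.indels = FALSE, fixed = fixed)
  if (length(m) == 0) return(NULL)
  st <- Biostrings::start(m)
  en <- Biostrings::end(m)
  fi <- findInterval(st, index$fam_start)
  ok <- fi >= 1 & st >= index$fam_start[fi] & en <= index$fam_end[fi]
  if (!any(ok)) return(NULL)
  st <- st[ok]; fi <- fi[ok]
  mm <- Biostrings::neditStartingAt(pattern, index$subject, starting.at = st,
                                    with.indels = FALSE, fixed = fixed)
  data.frame(fam = fi, offset = st - index$fam_start[fi], mismatches = mm)
}

#' Best TE consensus hit for a read sequence
#'
#' Scans both strands of every consensus for an ungapped end-to-end placement
#' of the read and returns the placement with globally fewest mismatches, if
#' that minimum is at most `max_mismatch`. A tie between *different* families
#' at the minimal mismatch count is ambiguous and yields no hit. Reads
#' shorter than 20 nt are rejected as uninformative.
#'
#' @param read_seq A nucleotide string (length >= 20).
#' @param library A `te_library` (see [te_library()]).
#' @param max_mismatch Maximum tolerated mismatches (default 3).
#' @param n_is_wildcard If `TRUE` (default) `N` in read or consensus matches
#'   any base; otherwise `N` only matches `N`.
#' @return A one-row tibble with `family`, `te_strand`, `mismatches`,
#'   `te_offset` (0-based offset on the consensus), or `NULL` if no
#'   (unambiguous) placement exists.
#' @export
best_te_hit <- function(read_seq, library, max_mismatch = 3,
                        n_is_wildcard = TRUE) {
  hits <- best_te_hits(read_seq, library, max_mismatch = max_mismatch,
                       n_is_wildcard = n_is_wildcard)
  if (is.na(hits$family[1])) return(NULL)
  select(hits, "family", "te_strand", "mismatches", "te_offset")
}

#' Best TE hits for many reads
#'
#' Vectorised form of [best_te_hit()]. Reads made only of A/C/G/T first go
#' through an exact multi-pattern pass; only reads without an exact placement
#' fall back to the mismatch scan, so error-free data resolve quickly. The
#' result is identical to applying the single-read definition to every read.
#'
#' @param read_seqs Character vector of read sequences.
#' @inheritParams best_te_hit
#' @return Tibble with one row per read: `read_idx`, `family` (`NA` when no
#'   unambiguous hit), `te_strand`, `mismatches`, `te_offset`, `status`
#'   (`"hit"`, `"none"`, `"ambiguous"` or `"too_short"`).
#' @export
best_te_hits <- function(read_seqs, library, max_mismatch = 3,
                         n_is_wildcard = TRUE) {
  index <- build_te_index(library, sep_len = max(10L, max_mismatch + 2L))
  fixed <- !n_is_wildcard
  n <- length(read_seqs)
  read_seqs <- toupper(read_seqs)
  out <- tibble(read_idx = seq_len(n), family = NA_character_,
                te_strand = NA_character_, mismatches = NA_integer_,
                te_offset = NA_integer_, status = "none")
  too_short <- is.na(read_seqs) | nchar(read_seqs) < 20
  out$status[too_short] <- "too_short"
  todo <- which(!too_short)

  resolve <- function(cand) {
    # cand: data frame with fam, offset, mismatches, strand
    mmin <- min(cand$mismatches)
    cand <- cand[cand$mismatches == mmin, , drop = FALSE]
    fams <- unique(cand$fam)
    if (length(fams) > 1) return(list(status = "ambiguous"))
    cand <- cand[order(cand$strand, cand$offset), , drop = FALSE]
    list(status = "hit", fam = cand$fam[1], strand = cand$strand[1],
         offset = cand$offset[1], mismatches = mmin)
  }

  # exact multi-pattern pass
  clean <- todo[!grepl("[^ACGT]", read_seqs[todo])]
  lib_has_n <- any(grepl("N", library$sequence))
  if (length(clean) > 100 && !(n_is_wildcard && lib_has_n)) {
    widths <- nchar(read_seqs[clean])
    for (w in unique(widths)) {
      ii <- clean[widths == w]
      fwd <- Biostrings::DNAStringSet(read_seqs[ii])
      exact_hits <- vector("list", length(ii))
      for (strand in c("+", "-")) {
        pats <- if (strand == "+") fwd else Biostrings::reverseComplement(fwd)
        mi <- Biostrings::matchPDict(Biostrings::PDict(pats), index$subject)
        sl <- Biostrings::startIndex(mi)
        for (k in seq_along(ii)) {
          st <- sl[[k]]
          if (is.null(st) || length(st) == 0) next
          fi <- findInterval(st, index$fam_start)
          ok <- fi >= 1 & st >= index$fam_start[fi] &
            (st + w - 1L) <= index$fam_end[fi]
          if (!any(ok)) next
          exact_hits[[k]] <- rbind(exact_hits[[k]],
            data.frame(fam = fi[ok], offset = st[ok] - index$fam_start[fi[ok]],
                       mismatches = 0L, strand = strand))
        }
      }
      solved <- !vapply(exact_hits, is.null, logical(1))
      for (k in which(solved)) {
        r <- resolve(exact_hits[[k]])
        i <- ii[k]
        out$status[i] <- r$status
        if (r$status == "hit") {
          out$family[i] <- index$family[r$fam]
          out$te_strand[i] <- r$strand
          out$mismatches[i] <- r$mismatches
          out$te_offset[i] <- r$offset
        }
      }
      todo <- setdiff(todo, ii[solved])
    }
  }

  with_strand <- function(df, s) {
    if (is.null(df)) return(NULL)
    df$strand <- s
    df
  }
  for (i in todo) {
    pat <- Biostrings::DNAString(read_seqs[i])
    cand <- rbind(
      with_strand(scan_one_strand(pat, index, max_mismatch, fixed), "+"),
      with_strand(scan_one_strand(Biostrings::reverseComplement(pat), index,
                                  max_mismatch, fixed), "-")
    )
    if (is.null(cand) || nrow(cand) == 0) next
    r <- resolve(cand)
    out$status[i] <- r$status
    if (r$status == "hit") {
      out$family[i] <- index$family[r$fam]
      out$te_strand[i] <- r$strand
      out$mismatches[i] <- r$mismatches
      out$te_offset[i] <- r$offset
    }
  }
  out
}
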