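# Independent brute-force oracles and small fixture builders shared by the
# tests. The oracles deliberately avoid the code paths they check.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc_chr <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# Brute-force minimal-mismatch TE hit: every offset x both strands x every
# family, plain character comparison; N matches anything when wildcard.
# Returns list(status, family, strand, mm, offset) mirroring best_te_hit's
# contract (ambiguous = distinct families tied at the minimum).
oracle_te_hit <- function(read, library, max_mismatch, n_is_wildcard = TRUE) {
  rl <- nchar(read)
  if (rl < 20) return(list(status = "too_short"))
  rfwd <- strsplit(read, "")[[1]]
  rrev <- strsplit(rc_chr(read), "")[[1]]
  all_hits <- list()
  for (fi in seq_len(nrow(library))) {
    cons <- strsplit(library$sequence[fi], "")[[1]]
    if (length(cons) < rl) next
    offs <- 0:(length(cons) - rl)
    idx <- outer(seq_len(rl), offs, `+`)
    wins <- matrix(cons[idx], nrow = rl)
    for (strand in c("+", "-")) {
      rch <- if (strand == "+") rfwd else rrev
      neq <- wins != rch
      if (n_is_wildcard) neq <- neq & rch != "N" & wins != "N"
      mm <- colSums(neq)
      all_hits[[length(all_hits) + 1]] <-
        data.frame(family = library$family[fi], strand = strand,
                   offset = offs, mm = mm)
    }
  }
  hits <- do.call(rbind, all_hits)
  hits <- hits[hits$mm <= max_mismatch, , drop = FALSE]
  if (nrow(hits) == 0) return(list(status = "none"))
  hits <- hits[hits$mm == min(hits$mm), , drop = FALSE]
  if (length(unique(hits$family)) > 1) return(list(status = "ambiguous"))
  hits <- hits[order(hits$strand, hits$offset), , drop = FALSE]
  list(status = "hit", family = hits$family[1], strand = hits$strand[1],
       mm = hits$mm[1], offset = hits$offset[1])
}

# O(n^2) transitive closure of the >=1 nt interval-overlap relation.
oracle_overlap_clusters <- function(start, end) {
  n <- length(start)
  adj <- outer(start, end, `<`) & outer(end, start, `>`)
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (i in seq_len(n)) new[i] <- min(comp[adj[i, ]])
    if (identical(new, comp)) break
    comp <- new
  }
  match(comp, unique(comp))
}

# Tiny SAM text -> indexed BAM for alignment-reading tests.
write_test_bam <- function(records, contigs = c(chrT = 10000)) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(contigs), "\tLN:", contigs))
  writeLines(c(hdr, records), sam)
  sam
}

sam_record <- function(qname, flag, rname, pos1, mapq, cigar, mrnm = "=",
                       mpos1 = 0, tlen = 0, seq = "A") {
  paste(qname, flag, rname, pos1, mapq, cigar, mrnm, mpos1, tlen, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

# Minimal alignment tibble builder for caller-level unit tests that bypass
# BAM files entirely.
make_aln <- function(...) {
  rows <- list(...)
  defaults <- list(qname = "q", flag = 0L, contig = "chrT", start = 0,
                   end = 90, strand = "+", mapq = 60L, cigar = "90M",
                   unmapped = FALSE, proper = TRUE, is_first = TRUE,
                   mate_contig = "chrT", mate_start = 0, mate_unmapped = FALSE,
                   mate_strand = "-", isize = 500L, is_unique = TRUE,
                   read_len = 90L, clip_left = 0L, clip_right = 0L,
                   clip_left_seq = "", clip_right_seq = "",
                   seq = strrep("A", 90))
  dplyr::bind_rows(lapply(rows, function(r) {
    out <- defaults
    out[names(r)] <- r
    tibble::as_tibble(out)
  }))
}

# One fragment -> two alignment rows (FR pair) for frequency/absence tests.
make_pair <- function(qname, frag_start, frag_end, contig = "chrT",
                      read_len = 90, mapq = 60L, proper = TRUE) {
  dplyr::bind_rows(
    tibble::tibble(qname = qname, flag = 99L, contig = contig,
                   start = frag_start, end = frag_start + read_len,
                   strand = "+", mapq = mapq, cigar = paste0(read_len, "M"),
                   unmapped = FALSE, proper = proper, is_first = TRUE,
                   mate_contig = contig, mate_start = frag_end - read_len,
                   mate_unmapped = FALSE, mate_strand = "-",
                   isize = as.integer(frag_end - frag_start),
                   is_unique = mapq >= 20, read_len = as.integer(read_len),
                   clip_left = 0L, clip_right = 0L, clip_left_seq = "",
                   clip_right_seq = "", seq = strrep("A", read_len)),
    tibble::tibble(qname = qname, flag = 147L, contig = contig,
                   start = frag_end - read_len, end = frag_end,
                   strand = "-", mapq = mapq, cigar = paste0(read_len, "M"),
                   unmapped = FALSE, proper = proper, is_first = FALSE,
                   mate_contig = contig, mate_start = frag_start,
                   mate_unmapped = FALSE, mate_strand = "+",
                   isize = as.integer(-(frag_end - frag_start)),
                   is_unique = mapq >= 20, read_len = as.integer(read_len),
                   clip_left = 0L, clip_right = 0L, clip_left_seq = "",
                   clip_right_seq = "", seq = strrep("A", read_len))
  )
}
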