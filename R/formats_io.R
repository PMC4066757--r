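#' Read paired-end alignments into a tibble
#'
#' Loads primary alignments from a BAM (or SAM, converted on the fly) file
#' into a flat tibble, one row per read, with 0-based half-open coordinates,
#' soft-clip lengths and sequences parsed from the CIGAR, and mate/pairing
#' information. Secondary and supplementary alignments are dropped; unmapped
#' reads are kept (their sequence may match a TE consensus).
#'
#' @param path Path to a coordinate-sorted BAM file (indexed if `region` is
#'   used) or a SAM file.
#' @param region Optional genomic interval `list(contig =, start =, end =)`
#'   in 0-based half-open coordinates; only overlapping reads are returned.
#' @param mapq_unique Minimum mapping quality for `is_unique`.
#' @return A tibble with one row per read: `qname`, `contig`, `start`,
#'   `end` (0-based half-open), `strand`, `mapq`, `is_unique`, `unmapped`,
#'   `proper`, `is_first`, `isize`, mate fields, clip lengths/sequences and
#'   the full read sequence (reference-oriented, as stored).
#' @export
read_alignments <- function(path, region = NULL, mapq_unique = 20) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  flag0 <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
            "mrnm", "mpos", "isize")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flag0, what = what)
  } else {
    gr <- GenomicRanges::GRanges(region$contig,
                                 IRanges::IRanges(region$start + 1, region$end))
    param <- Rsamtools::ScanBamParam(flag = flag0, what = what, which = gr)
  }
  res <- Rsamtools::scanBam(path, param = param)
  fields <- names(res[[1]])
  combine <- function(f) {
    parts <- lapply(res, `[[`, f)
    out <- if (length(parts) == 1) parts[[1]] else do.call(c, parts)
    if (is.atomic(out) || is.factor(out)) unname(out) else out
  }
  res <- setNames(lapply(fields, combine), fields)

  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  cigar <- res$cigar
  ref_width <- rep(0L, length(cigar))
  ok <- !is.na(cigar)
  ref_width[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  start <- ifelse(unmapped | is.na(res$pos), NA_integer_, res$pos - 1L)
  seqs <- as.character(res$seq)

  clip_left <- integer(length(cigar))
  clip_right <- integer(length(cigar))
  m <- regmatches(cigar, regexec("^([0-9]+)S", cigar))
  has <- lengths(m) == 2
  clip_left[has] <- as.integer(vapply(m[has], `[`, character(1), 2))
  m <- regmatches(cigar, regexec("([0-9]+)S$", cigar))
  has <- lengths(m) == 2
  clip_right[has] <- as.integer(vapply(m[has], `[`, character(1), 2))

  len <- nchar(seqs)
  cl <- as.integer(ifelse(unmapped, 0L, clip_left))
  cr <- as.integer(ifelse(unmapped, 0L, clip_right))
  tibble(
    qname = res$qname,
    flag = flag,
    contig = as.character(res$rname),
    start = start,
    end = start + ref_width,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = res$mapq,
    cigar = cigar,
    unmapped = unmapped,
    proper = bitwAnd(flag, 2L) > 0L,
    is_first = bitwAnd(flag, 64L) > 0L,
    mate_contig = as.character(res$mrnm),
    mate_start = ifelse(bitwAnd(flag, 8L) > 0L, NA_integer_, res$mpos - 1L),
    mate_unmapped = bitwAnd(flag, 8L) > 0L,
    mate_strand = ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
    isize = res$isize,
    is_unique = !unmapped & !is.na(res$mapq) & res$mapq >= mapq_unique,
    read_len = len,
    clip_left = cl,
    clip_right = cr,
    clip_left_seq = substr(seqs, 1L, cl),
    clip_right_seq = substr(seqs, len - cr + 1L, len),
    seq = seqs
  )
}

#' Pair mates of a read table
#'
#' Joins first and second mates by query name into one row per pair.
#'
#' @param aln Alignment tibble from [read_alignments()].
#' @return Tibble with suffixed columns `*_1` (first mate) and `*_2`.
#' @export
pair_alignments <- function(aln) {
  inner_join(filter(aln, .data$is_first),
             filter(aln, !.data$is_first),
             by = "qname", suffix = c("_1", "_2"))
}

#' Estimate insert-size statistics from proper pairs
#'
#' Median and MAD-derived standard deviation of the outer fragment length of
#' the first properly paired reads, as a robust stand-in for known library
#' statistics.
#'
#' @param aln Alignment tibble.
#' @param max_pairs Number of proper pairs to use.
#' @return List with `insert_mean` and `insert_sd`.
#' @export
estimate_insert_stats <- function(aln, max_pairs = 1e5) {
  spans <- aln$isize[aln$proper & !is.na(aln$isize) & aln$isize > 0]
  if (length(spans) == 0) abort("no proper pairs to estimate insert size from")
  spans <- head(spans, max_pairs)
  list(insert_mean = median(spans), insert_sd = mad(spans))
}

#' Load a TE consensus library from FASTA
#'
#' One entry per record; the family name is the first whitespace-delimited
#' token of the header. Sequences are uppercased; `N` is allowed.
#'
#' @param fasta_path Path to a FASTA file of TE consensus sequences.
#' @return A tibble with columns `family`, `sequence`, `length`, of class
#'   `te_library`.
#' @export
load_te_library <- function(fasta_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) == 0) abort("empty TE library FASTA")
  fam <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(fam)) {
    abort(paste0("duplicate family names in TE library: ",
                 paste(unique(fam[duplicated(fam)]), collapse = ", ")))
  }
  te_library(fam, unname(as.character(ss)))
}

#' Construct a TE library from sequences
#'
#' @param family Character vector of unique family names.
#' @param sequence Character vector of consensus sequences (A/C/G/T/N).
#' @return A `te_library` tibble.
#' @export
te_library <- function(family, sequence) {
  sequence <- unname(toupper(sequence))
  family <- unname(family)
  if (any(nchar(sequence) == 0)) abort("TE consensus sequences must be non-empty")
  if (any(grepl("[^ACGTN]", sequence))) abort("TE consensus alphabet is {A,C,G,T,N}")
  if (anyDuplicated(family)) abort("TE family names must be unique")
  structure(tibble(family = family, sequence = sequence,
                   length = nchar(sequence)),
            class = c("te_library", class(tibble())))
}

#' Load a genome FASTA as named character vector
#'
#' @param fasta_path Path to the genome FASTA.
#' @return Named character vector of uppercase contig sequences.
#' @export
load_genome <- function(fasta_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  nm <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  setNames(toupper(as.character(ss)), nm)
}

#' Load a reference TE annotation
#'
#' Reads annotated TE copies from RepeatMasker `.out` (1-based inclusive
#' coordinates, converted to 0-based half-open) or BED (taken as-is).
#' Overlapping annotations are retained unmerged.
#'
#' @param path Annotation file path.
#' @param dialect `"bed"` or `"repeatmasker_out"`.
#' @return Tibble with `contig`, `start`, `end`, `strand`, `family`,
#'   `copy_id` (unique per row).
#' @export
load_te_annotation <- function(path, dialect = c("bed", "repeatmasker_out")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !grepl("^(track|browser|#)", lines)
  if (dialect == "repeatmasker_out") {
    keep <- keep & !grepl("^\\s*(SW|score)", lines)
  }
  idx <- which(keep)
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  parse_row <- function(f, line_no) {
    if (dialect == "bed") {
      if (length(f) < 4 || anyNA(suppressWarnings(as.numeric(f[2:3]))))
        abort(paste0("unparseable BED line ", line_no))
      tibble(contig = f[1], start = as.numeric(f[2]), end = as.numeric(f[3]),
             family = f[4],
             strand = if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "*")
    } else {
      if (length(f) < 11 || anyNA(suppressWarnings(as.numeric(f[6:7]))))
        abort(paste0("unparseable RepeatMasker line ", line_no))
      tibble(contig = f[5], start = as.numeric(f[6]) - 1, end = as.numeric(f[7]),
             family = f[10], strand = if (f[9] == "C") "-" else "+")
    }
  }
  ann <- purrr::map2_dfr(fields, idx, parse_row)
  if (nrow(ann) == 0) {
    return(tibble(contig = character(), start = numeric(), end = numeric(),
                  strand = character(), family = character(),
                  copy_id = character()))
  }
  if (any(ann$start < 0 | ann$start >= ann$end)) abort("invalid annotation interval")
  ann %>%
    group_by(.data$family) %>%
    mutate(copy_id = paste0(.data$family, "#", row_number())) %>%
    ungroup() %>%
    select("contig", "start", "end", "strand", "family", "copy_id")
}

event_schema <- c("contig", "start", "end", "family", "strand", "kind",
                  "junction_plus", "junction_minus", "junction_resolution",
                  "support_sides", "T", "R", "frequency", "copy_id")

#' Write an event summary table
#'
#' Tab-delimited with header; 0-based half-open coordinates; frequency with
#' six decimals; rows sorted by (contig, start, family). The effective
#' configuration can be echoed as leading comment lines.
#'
#' @param events Event tibble (insertion or absence calls).
#' @param path Output file path.
#' @param config Optional `tepool_config` echoed as `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, config = NULL) {
  if (!"copy_id" %in% names(events)) events$copy_id <- NA_character_
  miss <- setdiff(event_schema, names(events))
  if (length(miss) > 0) abort(paste("events lack columns:", paste(miss, collapse = ", ")))
  out <- events %>%
    select(dplyr::all_of(event_schema)) %>%
    arrange(.data$contig, .data$start, .data$family) %>%
    mutate(frequency = sprintf("%.6f", .data$frequency))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(config_header_lines(config), con)
  writeLines(paste(event_schema, collapse = "\t"), con)
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con)
  }
  invisible(path)
}

#' Read an event summary table written by [write_events()]
#'
#' @param path Event summary path.
#' @return Event tibble.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  cols <- strsplit(lines[1], "\t")[[1]]
  classes <- c(junction_plus = "numeric", junction_minus = "numeric",
               copy_id = "character")
  df <- read.table(text = lines, header = TRUE, sep = "\t",
                   comment.char = "", stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = "NA",
                   colClasses = classes[intersect(names(classes), cols)])
  as_tibble(df)
}

#' Export events as BED6
#'
#' `name` is the TE family, `score` is `round(frequency * 1000)`.
#'
#' @inheritParams write_events
#' @export
write_events_bed <- function(events, path) {
  out <- events %>%
    arrange(.data$contig, .data$start, .data$family) %>%
    mutate(score = round(.data$frequency * 1000)) %>%
    select("contig", "start", "end", "family", "score", "strand")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
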