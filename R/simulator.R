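# Built-in structural-variant and read simulator: synthesises a reference
# genome with annotated TE copies, plants insertions/excisions into sample
# genomes, generates FR paired-end reads with normally distributed insert
# sizes and uniform substitution errors, and mixes variant/reference pools
# to set designed event frequencies. All operations are deterministic given
# their seed.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Synthetic TE consensus library
#'
#' Random consensus sequences named `TE01`, `TE02`, ... with lengths drawn
#' uniformly from `[min_length, max_length]`.
#'
#' @param n_families Number of TE families.
#' @param min_length,max_length Consensus length range (bp).
#' @param seed Random seed.
#' @return A [te_library()] tibble.
#' @export
make_te_library <- function(n_families = 10, min_length = 800,
                            max_length = 3000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(seq(min_length, max_length), n_families, replace = TRUE)
  te_library(sprintf("TE%02d", seq_len(n_families)),
             vapply(lens, random_dna, character(1)))
}

#' Synthetic reference genome with annotated TE copies
#'
#' An i.i.d. uniform A/C/G/T background of the requested length in which
#' `n_copies` full-length consensus copies are planted (substituted in
#' place) at non-overlapping uniformly drawn positions with random strands.
#' Families are assigned round-robin so every family contributes the same
#' number of reference copies.
#'
#' @param length Genome length (bp, >= 1e5).
#' @param library A [te_library()].
#' @param n_copies Number of TE copies to plant.
#' @param seed Random seed.
#' @param contig Contig name.
#' @param max_tries Placement retries before giving up.
#' @return List with `genome` (named character vector) and `annotation`
#'   (tibble as from [load_te_annotation()]).
#' @export
make_synthetic_reference <- function(length = 2e6, library, n_copies = 20,
                                     seed = NULL, contig = "chrS",
                                     max_tries = 1000) {
  if (length < 1e5) abort("synthetic genome length must be at least 100 kb")
  if (nrow(library) == 0) abort("library must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  genome <- random_dna(length)
  fams <- rep_len(library$family, n_copies)
  placed <- tibble(contig = character(), start = numeric(), end = numeric(),
                   strand = character(), family = character())
  for (fam in fams) {
    te_len <- library$length[library$family == fam]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(length - te_len, 1)
      if (all(s + te_len <= placed$start | s >= placed$end)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("could not place TE copies without overlap")
    strand <- sample(c("+", "-"), 1)
    seq <- library$sequence[library$family == fam]
    if (strand == "-") seq <- revcomp(seq)
    substr(genome, s + 1, s + te_len) <- seq
    placed <- bind_rows(placed, tibble(contig = contig, start = s,
                                       end = s + te_len, strand = strand,
                                       family = fam))
  }
  ann <- placed %>%
    arrange(.data$start) %>%
    group_by(.data$family) %>%
    mutate(copy_id = paste0(.data$family, "#", row_number())) %>%
    ungroup()
  list(genome = setNames(genome, contig), annotation = ann)
}

#' Plant insertions and excisions into a reference genome
#'
#' Insertions place the full consensus of a randomly chosen family, on a
#' random strand, at a uniformly drawn site, optionally duplicating the
#' `tsd_len` bases immediately upstream of the site (target site
#' duplication). Excisions delete entire annotated copies sampled without
#' replacement. Sites colliding with an excised span are resampled. Truth
#' records carry reference-frame junctions: for insertions,
#' `junction_plus = site` and `junction_minus = site - tsd_len`; for
#' excisions the annotated start/end boundaries.
#'
#' @param genome Named character vector (single contig).
#' @param annotation Reference TE annotation tibble.
#' @param library A [te_library()].
#' @param n_insertions,n_excisions Event counts.
#' @param tsd_len Designed TSD length for all insertions (bp, default 0).
#' @param seed Random seed.
#' @param min_edge Keep insertion sites this far from contig ends (bp).
#' @return List with `genome` (sample genome, same contig name) and `truth`
#'   (tibble of planted events).
#' @export
mutate_genome <- function(genome, annotation, library, n_insertions = 50,
                          n_excisions = 50, tsd_len = 0, seed = NULL,
                          min_edge = 1000) {
  if (!is.null(seed)) set.seed(seed)
  if (n_excisions > nrow(annotation)) {
    abort("not enough annotated copies to excise")
  }
  contig <- names(genome)[1]
  gseq <- genome[[1]]
  glen <- nchar(gseq)

  exc <- if (n_excisions > 0) {
    annotation[sample.int(nrow(annotation), n_excisions), , drop = FALSE]
  } else annotation[0, ]

  ins <- tibble(site = numeric(), family = character(), strand = character())
  while (nrow(ins) < n_insertions) {
    s <- sample(seq(min_edge, glen - min_edge), 1)
    if (any(s > exc$start & s < exc$end)) next    # collides with excised span
    if (any(abs(s - ins$site) < max(1, tsd_len))) next
    ins <- bind_rows(ins, tibble(
      site = s,
      family = sample(library$family, 1),
      strand = sample(c("+", "-"), 1)
    ))
  }

  edits <- bind_rows(
    tibble(pos = exc$start, del_end = exc$end, payload = ""),
    tibble(pos = ins$site, del_end = ins$site,
           payload = purrr::pmap_chr(ins, function(site, family, strand) {
             te <- library$sequence[library$family == family]
             if (strand == "-") te <- revcomp(te)
             dup <- if (tsd_len > 0) substr(gseq, site - tsd_len + 1, site) else ""
             paste0(te, dup)
           }))
  ) %>% arrange(.data$pos)

  pieces <- character(2 * nrow(edits) + 1)
  cursor <- 0
  for (i in seq_len(nrow(edits))) {
    pieces[2 * i - 1] <- substr(gseq, cursor + 1, edits$pos[i])
    pieces[2 * i] <- edits$payload[i]
    cursor <- edits$del_end[i]
  }
  pieces[2 * nrow(edits) + 1] <- substr(gseq, cursor + 1, glen)
  sample_seq <- paste(pieces, collapse = "")

  truth <- bind_rows(
    tibble(kind = "insertion", contig = contig, family = ins$family,
           orientation = ins$strand, junction_plus = ins$site,
           junction_minus = ins$site - tsd_len, tsd = tsd_len,
           copy_id = NA_character_),
    tibble(kind = "excision", contig = contig, family = exc$family,
           orientation = exc$strand, junction_plus = exc$start,
           junction_minus = exc$end, tsd = NA_real_, copy_id = exc$copy_id)
  )
  list(genome = setNames(sample_seq, contig), truth = truth)
}

#' Simulate FR paired-end reads
#'
#' Fragments are placed uniformly along the genome with insert sizes drawn
#' from a normal distribution truncated below at twice the read length (so
#' mates never overlap pathologically); mates are read inward from the two
#' fragment ends (FR). Substitution errors hit uniformly at `error_rate`
#' per base, replaced by one of the three alternative bases; no indels, no
#' GC or quality structure. The number of pairs is
#' `round(depth * genome_length / (2 * read_length))`.
#'
#' @param genome Named character vector of contig sequences.
#' @param depth Target haploid coverage.
#' @param read_length Read length (nt).
#' @param insert_mean,insert_sd Insert size distribution (bp).
#' @param error_rate Per-base substitution probability.
#' @param seed Random seed.
#' @param prefix Read name prefix (kept unique across pools to be mixed).
#' @return Tibble `qname`, `seq1`, `seq2`, plus the generating fragment
#'   coordinates `contig`, `frag_start`, `frag_end` (0-based half-open).
#' @export
simulate_reads <- function(genome, depth, read_length = 90,
                           insert_mean = 500, insert_sd = 50,
                           error_rate = 1e-4, seed = NULL, prefix = "sim") {
  if (!is.null(seed)) set.seed(seed)
  if (read_length >= insert_mean) abort("read_length must be below insert_mean")
  lens <- nchar(genome)
  total <- sum(lens)
  n <- round(depth * total / (2 * read_length))
  ctg_i <- if (length(genome) == 1) rep(1L, n) else
    sample(seq_along(genome), n, replace = TRUE, prob = lens)

  f <- round(rnorm(n, insert_mean, insert_sd))
  lo <- 2 * read_length
  bad <- which(f < lo | f > lens[ctg_i])
  while (length(bad) > 0) {
    f[bad] <- round(rnorm(length(bad), insert_mean, insert_sd))
    bad <- bad[f[bad] < lo | f[bad] > lens[ctg_i[bad]]]
  }
  s <- floor(runif(n) * (lens[ctg_i] - f)) # 0-based fragment start
  seq1 <- character(n)
  seq2 <- character(n)
  for (ci in unique(ctg_i)) {
    ii <- which(ctg_i == ci)
    g <- genome[[ci]]
    seq1[ii] <- substring(g, s[ii] + 1, s[ii] + read_length)
    seq2[ii] <- substring(g, s[ii] + f[ii] - read_length + 1, s[ii] + f[ii])
  }
  seq2 <- revcomp(seq2)

  if (error_rate > 0) {
    total_bases <- 2 * n * read_length
    nerr <- rbinom(1, total_bases, error_rate)
    if (nerr > 0) {
      idx <- sample.int(total_bases, nerr)
      read_i <- (idx - 1) %/% read_length + 1
      pos <- (idx - 1) %% read_length + 1
      for (k in seq_len(nerr)) {
        i <- read_i[k]
        if (i <= n) {
          old <- substr(seq1[i], pos[k], pos[k])
          substr(seq1[i], pos[k], pos[k]) <-
            sample(setdiff(c("A", "C", "G", "T"), old), 1)
        } else {
          i <- i - n
          old <- substr(seq2[i], pos[k], pos[k])
          substr(seq2[i], pos[k], pos[k]) <-
            sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
      }
    }
  }
  tibble(qname = paste0(prefix, "_", seq_len(n)), seq1 = seq1, seq2 = seq2,
         contig = names(genome)[ctg_i], frag_start = s, frag_end = s + f)
}

#' Mix variant and reference read pools at a designed frequency
#'
#' Draws the number of variant pairs from `Binomial(n, frequency)` where
#' `n` is the variant pool size, fills the remainder from the reference
#' pool, and preserves the total pair count. `frequency = 1` returns the
#' variant pool unchanged.
#'
#' @param variant_reads,reference_reads Read-pair tibbles from
#'   [simulate_reads()] (distinct name prefixes).
#' @param frequency Designed event frequency in (0, 1].
#' @param seed Random seed.
#' @return Pooled read-pair tibble.
#' @export
mix_pools <- function(variant_reads, reference_reads, frequency, seed = NULL) {
  if (frequency <= 0 || frequency > 1) abort("frequency must be in (0, 1]")
  if (frequency == 1) return(variant_reads)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(variant_reads)
  k <- rbinom(1, n, frequency)
  if (n - k > nrow(reference_reads)) abort("reference pool too small for mix")
  out <- bind_rows(
    variant_reads[sample.int(n, k), , drop = FALSE],
    reference_reads[sample.int(nrow(reference_reads), n - k), , drop = FALSE]
  )
  if (anyDuplicated(out$qname)) abort("pools to be mixed share read names")
  out
}

#' Write read pairs as a pair of FASTQ files
#'
#' Constant quality strings (`I`); the error model carries no quality
#' information.
#'
#' @param reads Read-pair tibble.
#' @param prefix Output path prefix; writes `<prefix>_1.fq`, `<prefix>_2.fq`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fq", "_2.fq"))
  for (m in 1:2) {
    seqs <- reads[[paste0("seq", m)]]
    qual <- strrep("I", nchar(seqs))
    writeLines(as.vector(rbind(paste0("@", reads$qname), seqs, "+", qual)),
               paths[m])
  }
  invisible(paths)
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write a TE annotation as BED
#'
#' @param annotation Annotation tibble.
#' @param path Output path.
#' @export
write_annotation_bed <- function(annotation, path) {
  out <- annotation %>%
    arrange(.data$contig, .data$start) %>%
    mutate(score = 0) %>%
    select("contig", "start", "end", "family", "score", "strand")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write / read a truth set
#'
#' Tab-delimited truth records with BED-compatible (0-based) junctions.
#'
#' @param truth Truth tibble from [mutate_genome()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t", comment.char = "",
                       stringsAsFactors = FALSE,
                       colClasses = c(copy_id = "character")))
}
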