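# End-to-end benchmark harnesses: simulate -> map (bwa) -> call -> score.
# These reproduce, at configurable scale, the two published evaluation
# designs: a pool of independently mutated genomes sequenced at equal depth
# (each event then has designed frequency 1/n_replicates), and a
# single-genome pool mixed with reference reads across a designed frequency
# range.

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1, n)
}

#' Pooled-replicates benchmark arm
#'
#' Builds a synthetic annotated reference, independently plants
#' `n_insertions` insertions and `n_excisions` excisions into
#' `n_replicates` copies of it, sequences each mutated genome at
#' `depth` coverage, pools all reads, maps them with bwa, runs both callers
#' and scores the calls against the pooled truth set. Each insertion has a
#' designed frequency of `1/n_replicates`; an annotated copy excised in `k`
#' replicates has designed frequency `k/n_replicates`.
#'
#' @param seed Integer seed driving every random choice.
#' @param genome_length,n_families,n_copies Synthetic reference parameters.
#' @param n_replicates Number of independently mutated genomes pooled.
#' @param n_insertions,n_excisions Events planted per replicate.
#' @param depth Coverage per replicate (pooled coverage is
#'   `n_replicates * depth`).
#' @param read_length,insert_mean,insert_sd,error_rate Read simulation
#'   parameters.
#' @param workdir Scratch directory (default a fresh tempdir).
#' @return List with `metrics` ([metrics_report()] tibble), `matched`,
#'   `events`, `truth`.
#' @export
sim_pooled_arm <- function(seed, genome_length = 2e6, n_families = 10,
                           n_copies = 20, n_replicates = 5,
                           n_insertions = 10, n_excisions = 10, depth = 5,
                           read_length = 90, insert_mean = 500,
                           insert_sd = 50, error_rate = 1e-4,
                           workdir = tempfile("arm")) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 2 + 2 * n_replicates)
  library <- make_te_library(n_families, seed = seeds[1])
  ref <- make_synthetic_reference(genome_length, library, n_copies,
                                  seed = seeds[2])
  ref_fa <- file.path(workdir, "ref.fa")
  write_genome_fasta(ref$genome, ref_fa)
  bwa_index(ref_fa)

  reads <- vector("list", n_replicates)
  truth <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    mut <- mutate_genome(ref$genome, ref$annotation, library,
                         n_insertions = n_insertions,
                         n_excisions = n_excisions,
                         seed = seeds[2 + r])
    reads[[r]] <- simulate_reads(mut$genome, depth,
                                 read_length = read_length,
                                 insert_mean = insert_mean,
                                 insert_sd = insert_sd,
                                 error_rate = error_rate,
                                 seed = seeds[2 + n_replicates + r],
                                 prefix = paste0("rep", r))
    truth[[r]] <- mutate(mut$truth, replicate = r)
  }
  pooled <- bind_rows(reads)
  fq <- write_fastq_pairs(pooled, file.path(workdir, "pool"))
  bam <- bwa_align_pairs(ref_fa, fq[1], fq[2], file.path(workdir, "pool"))

  truth_all <- bind_rows(truth)
  truth_ins <- truth_all %>%
    filter(.data$kind == "insertion") %>%
    mutate(designed_frequency = 1 / n_replicates)
  truth_exc <- truth_all %>%
    filter(.data$kind == "excision") %>%
    group_by(.data$contig, .data$copy_id, .data$family, .data$orientation,
             .data$junction_plus, .data$junction_minus, .data$kind) %>%
    summarise(designed_frequency = dplyr::n() / n_replicates,
              .groups = "drop") %>%
    mutate(tsd = NA_real_)
  truth_all <- bind_rows(truth_ins, truth_exc)

  config <- tepool_config(insert_mean = insert_mean, insert_sd = insert_sd)
  aln <- read_alignments(bam, mapq_unique = config$mapq_unique)
  ins_calls <- call_te_insertions(aln, library, genome = ref$genome, config = config)
  abs_calls <- call_te_absences(aln, ref$annotation, genome = ref$genome,
                          library = library, config = config)
  events <- bind_rows(ins_calls, abs_calls)
  matched <- match_events(events, truth_all)
  list(metrics = metrics_report(matched), matched = matched,
       events = events, truth = truth_all, library = library,
       annotation = ref$annotation, genome = ref$genome, workdir = workdir)
}

#' Designed-frequency sweep benchmark
#'
#' One synthetic reference; for every designed frequency an independently
#' mutated genome is sequenced at `depth` and mixed with reference-genome
#' reads so the planted events segregate at that frequency; each mixed pool
#' is mapped and called, and all pools are scored together.
#'
#' @inheritParams sim_pooled_arm
#' @param frequencies Designed event frequencies in (0, 1].
#' @param depth Pool coverage at every frequency.
#' @return List with `metrics`, combined `matched`, per-pool event list.
#' @export
sim_frequency_sweep <- function(seed, genome_length = 1e6,
                                frequencies = seq(0.1, 1, by = 0.1),
                                depth = 20, n_families = 10, n_copies = 20,
                                n_insertions = 10, n_excisions = 10,
                                read_length = 90, insert_mean = 500,
                                insert_sd = 50, error_rate = 1e-4,
                                workdir = tempfile("sweep")) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  nf <- length(frequencies)
  seeds <- derive_seeds(seed, 3 + 3 * nf)
  library <- make_te_library(n_families, seed = seeds[1])
  ref <- make_synthetic_reference(genome_length, library, n_copies,
                                  seed = seeds[2])
  ref_fa <- file.path(workdir, "ref.fa")
  write_genome_fasta(ref$genome, ref_fa)
  bwa_index(ref_fa)
  ref_reads <- simulate_reads(ref$genome, depth, read_length = read_length,
                              insert_mean = insert_mean,
                              insert_sd = insert_sd, error_rate = error_rate,
                              seed = seeds[3], prefix = "ref")

  config <- tepool_config(insert_mean = insert_mean, insert_sd = insert_sd)
  truth_acc <- list()
  pred_acc <- list()
  per_pool <- list()
  for (i in seq_along(frequencies)) {
    fq_i <- frequencies[i]
    mut <- mutate_genome(ref$genome, ref$annotation, library,
                         n_insertions = n_insertions,
                         n_excisions = n_excisions, seed = seeds[3 + i])
    var_reads <- simulate_reads(mut$genome, depth, read_length = read_length,
                                insert_mean = insert_mean,
                                insert_sd = insert_sd,
                                error_rate = error_rate,
                                seed = seeds[3 + nf + i], prefix = "var")
    pool <- mix_pools(var_reads, ref_reads, fq_i, seed = seeds[3 + 2 * nf + i])
    fqp <- write_fastq_pairs(pool, file.path(workdir, paste0("pool", i)))
    bam <- bwa_align_pairs(ref_fa, fqp[1], fqp[2],
                           file.path(workdir, paste0("pool", i)))
    aln <- read_alignments(bam, mapq_unique = config$mapq_unique)
    ins_calls <- call_te_insertions(aln, library, genome = ref$genome,
                              config = config)
    abs_calls <- call_te_absences(aln, ref$annotation, genome = ref$genome,
                            library = library, config = config)
    events <- bind_rows(ins_calls, abs_calls)
    truth_i <- mutate(mut$truth, designed_frequency = fq_i)
    matched <- match_events(events, truth_i)
    truth_acc[[i]] <- matched$truth
    pred_acc[[i]] <- matched$predictions
    per_pool[[i]] <- events
    unlink(c(fqp, bam, paste0(bam, ".bai")))
  }
  matched_all <- list(truth = bind_rows(truth_acc),
                      predictions = bind_rows(pred_acc))
  list(metrics = metrics_report(matched_all), matched = matched_all,
       per_pool = per_pool, library = library, annotation = ref$annotation,
       genome = ref$genome, workdir = workdir)
}
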