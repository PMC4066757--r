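# Thin wrapper around the external short-read aligner used by the test
# harness and example pipelines. Mapping itself is upstream of the caller:
# users normally supply their own coordinate-sorted BAM.

#' Index a reference FASTA for bwa
#'
#' @param ref_fasta Reference FASTA path.
#' @return `ref_fasta`, invisibly.
#' @export
bwa_index <- function(ref_fasta) {
  if (Sys.which("bwa") == "") abort("bwa not found on PATH")
  status <- system2("bwa", c("index", ref_fasta), stdout = FALSE, stderr = FALSE)
  if (status != 0) abort("bwa index failed")
  invisible(ref_fasta)
}

#' Map paired FASTQ files and produce a sorted, indexed BAM
#'
#' Runs `bwa mem` single-threaded (deterministic output order given fixed
#' inputs) and converts/sorts/indexes via Rsamtools.
#'
#' @param ref_fasta Indexed reference FASTA.
#' @param fq1,fq2 Paired FASTQ paths.
#' @param out_prefix Output prefix; produces `<out_prefix>.bam` + `.bam.bai`.
#' @param threads bwa threads.
#' @return Path to the sorted BAM.
#' @export
bwa_align_pairs <- function(ref_fasta, fq1, fq2, out_prefix, threads = 1) {
  if (Sys.which("bwa") == "") abort("bwa not found on PATH")
  sam <- paste0(out_prefix, ".sam")
  status <- system2("bwa", c("mem", "-t", threads, ref_fasta, fq1, fq2),
                    stdout = sam, stderr = FALSE)
  if (status != 0) abort("bwa mem failed")
  bam <- Rsamtools::asBam(sam, destination = out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}
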