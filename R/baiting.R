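#' Parameters for baited filter construction
#'
#' @param k K-mer length in bases (default 25, the length at which recall
#'   stays high while precision is already near its plateau).
#' @param levels Cascade depth; a k-mer must be observed at least `levels`
#'   times in the kept reads to be solid (default 2).
#' @param memory_bits Total bit budget for the structure being built.  For
#'   the cascading filter it is split equally across levels; for the
#'   transcriptome filter it is used whole.
#' @param min_shared_kmers Minimum number of transcriptome k-mers a read
#'   must share to be kept (default 1: a read sharing no k-mer with the
#'   transcriptome is discarded).
#' @return A list of class `baiting_params`.
#' @export
baiting_params <- function(k = 25L, levels = 2L, memory_bits = 8e6,
                           min_shared_kmers = 1L) {
  stopifnot(k >= 1, levels >= 1, memory_bits >= levels, min_shared_kmers >= 1)
  structure(list(k = as.integer(k), levels = as.integer(levels),
                 memory_bits = as.double(memory_bits),
                 min_shared_kmers = as.integer(min_shared_kmers)),
            class = "baiting_params")
}

#' Build a Bloom filter of the transcriptome
#'
#' Inserts every canonical k-mer of every transcript into a single Bloom
#' filter sized at `params$memory_bits`.  This filter is the bait used by
#' [bait_reads()] to discard WGS reads with no transcriptomic k-mer.
#'
#' @param transcripts Transcriptome: FASTA path, `DNAStringSet`, or named
#'   character vector.  Must contain at least one sequence.
#' @param params A [baiting_params()].
#' @return A [kmer_filter()] with its insert count recorded.
#' @export
build_transcriptome_filter <- function(transcripts, params = baiting_params()) {
  seqs <- as_seq_vector(transcripts, "fasta", "transcriptome")
  if (length(seqs) == 0) stop("empty transcriptome")
  short <- nchar(seqs) < params$k
  if (any(short))
    warning(sum(short), " transcript(s) shorter than k = ", params$k,
            " contribute no k-mers")
  tf <- kmer_filter(k = params$k, m = params$memory_bits, h = 4L)
  insert_sequences(tf, seqs)
  tf
}

#' Bait WGS reads against a transcriptome filter
#'
#' A read is kept iff at least `params$min_shared_kmers` of its canonical
#' k-mers query positive in the transcriptome filter; all other reads are
#' discarded (they cannot inform exon boundaries).  Reads shorter than `k`
#' have zero k-mers and are always discarded.  Input order is preserved.
#'
#' @param reads FASTQ path(s) (optionally gzipped), `DNAStringSet`, or
#'   character vector of read sequences.  Paired files are treated as
#'   independent single-end streams.
#' @param tf Transcriptome [kmer_filter()]; its `k` must equal `params$k`.
#' @param params A [baiting_params()].
#' @return A list: `kept` (named character vector of surviving reads),
#'   `keep` (logical vector over the input), `n_kept`, `n_discarded`.
#' @export
bait_reads <- function(reads, tf, params = baiting_params()) {
  stopifnot(inherits(tf, "kmer_filter"))
  if (tf$k != params$k)
    stop("transcriptome filter k (", tf$k, ") != params k (", params$k, ")")
  seqs <- as_seq_vector(reads, "fastq", "reads")
  if (length(seqs) == 0)
    return(list(kept = character(0), keep = logical(0),
                n_kept = 0L, n_discarded = 0L))
  shared <- cpp_bf_shared_counts(tf$ptr, seqs)
  keep <- shared >= params$min_shared_kmers
  list(kept = seqs[keep], keep = keep,
       n_kept = sum(keep), n_discarded = sum(!keep))
}

#' Build the cascading filter of solid k-mers from baited reads
#'
#' The three-step building stage in one call: Bloom-filter the
#' transcriptome (done by the caller, passed as `tf`), discard reads
#' sharing no k-mer with it, and insert every canonical k-mer of each
#' surviving read into a cascading Bloom filter.  Only the last cascade
#' level (the solid k-mers) is used downstream.
#'
#' @inheritParams bait_reads
#' @param backend `"bloom"` for the cascading Bloom filter, `"exact"` for
#'   the exact counting backend (same contract, no false positives; for
#'   oracle testing and small inputs).
#' @param bait If `FALSE`, skip read filtering and insert every read (the
#'   comparison mode showing what baiting buys: at equal memory the
#'   analysis-level false-positive rate is lower with baiting because far
#'   fewer k-mers are inserted).
#' @return A list of class `baited_solid_filter`: `filter` (the
#'   [cascading_kmer_filter()] or [exact_kmer_set()]), and `summary`
#'   (`n_kept`, `n_discarded`, `fpr` per level for the Bloom backend,
#'   `analysis_fpr` for the last level).
#' @export
build_baited_solid_filter <- function(reads, tf, params = baiting_params(),
                                      backend = c("bloom", "exact"),
                                      bait = TRUE) {
  backend <- match.arg(backend)
  seqs <- as_seq_vector(reads, "fastq", "reads")
  if (bait) {
    b <- bait_reads(seqs, tf, params)
    kept <- b$kept
    n_kept <- b$n_kept
    n_discarded <- b$n_discarded
  } else {
    kept <- seqs
    n_kept <- length(seqs)
    n_discarded <- 0L
  }
  filt <- if (backend == "bloom") {
    cascading_kmer_filter(k = params$k,
                          m_per_level = floor(params$memory_bits /
                                                params$levels),
                          h = 4L, levels = params$levels)
  } else {
    exact_kmer_set(k = params$k, levels = params$levels)
  }
  insert_sequences(filt, kept)
  fpr <- if (backend == "bloom") bf_fpr(filt) else rep(0, params$levels)
  structure(list(
    filter = filt,
    summary = list(n_kept = n_kept, n_discarded = n_discarded,
                   fpr = fpr, analysis_fpr = fpr[length(fpr)])),
    class = "baited_solid_filter")
}

#' @export
print.baited_solid_filter <- function(x, ...) {
  cat(sprintf("<baited_solid_filter> reads kept=%d discarded=%d\n",
              x$summary$n_kept, x$summary$n_discarded))
  cat(sprintf("  analysis-level FPR estimate: %.4g\n", x$summary$analysis_fpr))
  print(x$filter)
  invisible(x)
}
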