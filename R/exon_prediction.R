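#' Parameters for exon and splice-graph prediction
#'
#' @param k K-mer length (must equal the solid filter's `k`; default 25).
#' @param q Length-filter slack: predicted exons shorter than `k + q`
#'   bases are discarded as likely false positives (default 5).
#' @param max_overlap Relaxed-merge threshold: adjacent exons overlapping
#'   by strictly more than this many bases are merged (default 10).
#' @param polish If `TRUE`, overlapping exon pairs are inspected for the
#'   AG-GT splice signal and trimmed so the upstream exon ends in `AG` and
#'   the downstream starts with `GT`.
#' @return A list of class `prediction_params`.
#' @export
prediction_params <- function(k = 25L, q = 5L, max_overlap = 10L,
                              polish = FALSE) {
  stopifnot(k >= 1, q >= 0, max_overlap >= 0, is.logical(polish))
  structure(list(k = as.integer(k), q = as.integer(q),
                 max_overlap = as.integer(max_overlap),
                 polish = isTRUE(polish)),
            class = "prediction_params")
}

#' Solid-k-mer mask of a transcript
#'
#' Queries every k-mer window of the transcript against the solid set.
#' Position `p` (0-based) of the mask is `TRUE` iff the canonical k-mer
#' starting at `p` is solid; windows containing non-ACGT characters are
#' `FALSE`.  K-mers spanning an intron-exon boundary do not exist in the
#' genome, so their windows come back `FALSE` — this is the boundary
#' signal.
#'
#' @param transcript_seq A single nucleotide string.
#' @param solid Solid-k-mer backend: a [cascading_kmer_filter()], an
#'   [exact_kmer_set()], or a plain character vector of canonical k-mers
#'   (useful as a test oracle).
#' @param k K-mer length; defaults to the backend's `k`.
#' @return Logical vector of length `nchar(transcript_seq) - k + 1`;
#'   length 0 (with a warning) for transcripts shorter than `k`.
#' @export
positive_kmer_mask <- function(transcript_seq, solid, k = NULL) {
  stopifnot(is.character(transcript_seq), length(transcript_seq) == 1L)
  if (is.character(solid)) {
    if (is.null(k)) k <- nchar(solid[1])
    stopifnot(all(nchar(solid) == k))
  } else {
    if (is.null(k)) k <- solid$k
    if (k != solid$k)
      stop("k (", k, ") does not match the solid filter's k (", solid$k, ")")
  }
  if (nchar(transcript_seq) < k) {
    warning("transcript shorter than k = ", k, "; no exons can be predicted")
    return(logical(0))
  }
  if (inherits(solid, "cascading_kmer_filter"))
    return(cpp_cbf_mask(solid$ptr, transcript_seq))
  if (inherits(solid, "exact_kmer_set"))
    return(cpp_exact_mask(solid$ptr, transcript_seq))
  # character-set backend
  km <- canonical_kmers(transcript_seq, k)
  mask <- logical(nchar(transcript_seq) - k + 1)
  mask[km$pos + 1L] <- km$kmer %in% solid
  mask
}

#' Merge runs of positive k-mers into exon intervals
#'
#' Consecutive positive k-mers overlap by `k - 1` bases and are merged:
#' each maximal run of `TRUE` mask positions `i..j` becomes the interval
#' `[i, j + k)` (0-based half-open, transcript coordinates).  Runs are
#' disjoint in mask space, but the resulting intervals may overlap by up
#' to `k - 2` bases when separated by short `FALSE` gaps.
#'
#' @param mask Logical vector from [positive_kmer_mask()].
#' @param k K-mer length used to build the mask.
#' @return A `data.frame` with integer columns `start`, `end`.
#' @export
mask_to_intervals <- function(mask, k) {
  if (length(mask) == 0 || !any(mask))
    return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)            # 1-based inclusive run ends
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L,
             end = ends[keep] - 1L + as.integer(k))
}

#' Drop exons shorter than the minimum length
#'
#' Bloom-filter false positives produce spurious short exons of length
#' about `k`; intervals shorter than `k + q` bases are discarded.
#'
#' @param intervals `data.frame(start, end)`, sorted by `start`.
#' @param k K-mer length.
#' @param q Slack (default 5): the minimum kept length is `k + q`.
#' @return The surviving intervals.
#' @export
filter_short_exons <- function(intervals, k, q = 5L) {
  intervals[intervals$end - intervals$start >= k + q, , drop = FALSE]
}

#' Merge adjacent exons that overlap excessively
#'
#' Adjacent interval pairs overlapping by strictly more than `max_overlap`
#' bases are unioned, left to right, iterating to a fixpoint.  Pairs
#' overlapping by at most `max_overlap` bases, abutting, or separated by a
#' gap are left untouched (a moderate overlap is the expected footprint of
#' a genuine boundary whose junction k-mers are false positives).
#'
#' @param intervals `data.frame(start, end)`, sorted by `start`.
#' @param max_overlap Merge threshold in bases (default 10; strict
#'   inequality, so an overlap of exactly `max_overlap` is kept).
#' @return The merged intervals, sorted.
#' @export
merge_close_intervals <- function(intervals, max_overlap = 10L) {
  if (nrow(intervals) <= 1) return(intervals)
  repeat {
    start <- intervals$start
    end <- intervals$end
    out_s <- integer(0); out_e <- integer(0)
    cs <- start[1]; ce <- end[1]
    for (i in seq_len(nrow(intervals))[-1]) {
      if (ce - start[i] > max_overlap) {
        ce <- max(ce, end[i])
      } else {
        out_s <- c(out_s, cs); out_e <- c(out_e, ce)
        cs <- start[i]; ce <- end[i]
      }
    }
    out <- data.frame(start = c(out_s, cs), end = c(out_e, ce))
    if (nrow(out) == nrow(intervals)) return(out)
    intervals <- out
  }
}

#' Trim an overlapping exon pair at the AG-GT splice signal
#'
#' Inspects the overlap region of two consecutive predicted exons for the
#' splice-site motif as it appears in transcript space: the upstream exon
#' should end in the acceptor `AG` and the downstream exon begin with the
#' donor `GT`, i.e. the literal string `"AGGT"` straddles the true
#' boundary.  The leftmost occurrence of `"AGGT"` in
#' `transcript_seq[downstream$start, upstream$end)` wins; the boundary is
#' placed between its `AG` and `GT`, eliminating the overlap.  If the
#' motif is absent the pair is returned unchanged.
#'
#' @param upstream,downstream One-row `data.frame(start, end)` each
#'   (0-based half-open); must overlap (`upstream$end > downstream$start`).
#' @param transcript_seq The transcript sequence.
#' @return A list `(upstream, downstream)` of possibly trimmed intervals.
#' @export
polish_pair <- function(upstream, downstream, transcript_seq) {
  ov <- upstream$end - downstream$start
  if (ov <= 0)
    stop("polish_pair requires a positive overlap (got ", ov, ")")
  region <- substr(transcript_seq, downstream$start + 1L, upstream$end)
  hit <- as.integer(regexpr("AGGT", toupper(region), fixed = TRUE))
  if (hit > 0) {
    b <- downstream$start + (hit - 1L) + 2L
    upstream$end <- b
    downstream$start <- b
  }
  list(upstream = upstream, downstream = downstream)
}

#' Predict exons and assemble the splice graph
#'
#' For every transcript: query each k-mer against the solid set
#' ([positive_kmer_mask()]), merge runs into draft exons
#' ([mask_to_intervals()]), drop short false positives
#' ([filter_short_exons()]), merge excessive overlaps
#' ([merge_close_intervals()]), and, when `params$polish`, trim remaining
#' overlapping pairs at the AG-GT signal ([polish_pair()]).  Exons with
#' identical sequence (case-folded) collapse into a single node, so
#' transcripts sharing exons connect into one component — genes emerge as
#' the connected components of the graph.
#'
#' @param transcriptome FASTA path, `DNAStringSet`, or named character
#'   vector of transcript sequences.
#' @param solid Solid-k-mer backend (see [positive_kmer_mask()]).
#' @param params A [prediction_params()]; its `k` must match the backend.
#' @return An object of class `splice_graph`: `nodes`
#'   (`data.frame(exon_id, seq)`, ids `EXON` + 8-digit counter in
#'   first-encounter order), `coords`
#'   (`data.frame(exon_id, transcript_id, start, end)`), `links`
#'   (`data.frame(from, to, sep)` with `sep > 0` an overlap in bases, `0`
#'   abutting, `< 0` a gap), `paths` (named list of exon-id vectors),
#'   `transcript_len`, and `dropped` (transcripts with no surviving exon).
#' @export
build_splice_graph <- function(transcriptome, solid,
                               params = prediction_params()) {
  seqs <- as_seq_vector(transcriptome, "fasta", "transcriptome")
  if (length(seqs) == 0) stop("empty transcriptome")
  k <- params$k
  if (!is.character(solid) && solid$k != k)
    stop("params k (", k, ") does not match the solid filter's k (",
         solid$k, ")")

  seq2id <- new.env(parent = emptyenv())
  counter <- 0L
  node_ids <- character(0); node_seqs <- character(0)
  coords <- list(); links <- list(); paths <- list()
  dropped <- character(0)

  for (tid in names(seqs)) {
    tseq <- toupper(seqs[[tid]])
    if (nchar(tseq) < k) {
      warning("transcript '", tid, "' is shorter than k = ", k,
              "; skipped")
      dropped <- c(dropped, tid)
      next
    }
    mask <- positive_kmer_mask(tseq, solid, k)
    iv <- mask_to_intervals(mask, k)
    iv <- filter_short_exons(iv, k, params$q)
    iv <- merge_close_intervals(iv, params$max_overlap)
    if (params$polish && nrow(iv) > 1) {
      for (i in seq_len(nrow(iv) - 1)) {
        ov <- iv$end[i] - iv$start[i + 1]
        if (ov >= 4) {   # motif AGGT cannot fit in a smaller overlap
          res <- polish_pair(iv[i, ], iv[i + 1, ], tseq)
          iv$end[i] <- res$upstream$end
          iv$start[i + 1] <- res$downstream$start
        }
      }
    }
    if (nrow(iv) == 0) {
      dropped <- c(dropped, tid)
      next
    }
    ids <- character(nrow(iv))
    for (i in seq_len(nrow(iv))) {
      eseq <- substr(tseq, iv$start[i] + 1L, iv$end[i])
      id <- seq2id[[eseq]]
      if (is.null(id)) {
        counter <- counter + 1L
        id <- sprintf("EXON%08d", counter)
        assign(eseq, id, envir = seq2id)
        node_ids <- c(node_ids, id)
        node_seqs <- c(node_seqs, eseq)
      }
      ids[i] <- id
    }
    coords[[tid]] <- data.frame(exon_id = ids, transcript_id = tid,
                                start = iv$start, end = iv$end,
                                stringsAsFactors = FALSE)
    if (nrow(iv) > 1) {
      links[[tid]] <- data.frame(
        from = ids[-nrow(iv)], to = ids[-1],
        sep = iv$end[-nrow(iv)] - iv$start[-1],
        stringsAsFactors = FALSE)
    }
    paths[[tid]] <- ids
  }
  if (length(paths) == 0 && length(dropped) == length(seqs))
    message("no exons predicted for any transcript")

  link_df <- if (length(links)) unique(do.call(rbind, links)) else
    data.frame(from = character(0), to = character(0), sep = integer(0))
  rownames(link_df) <- NULL
  coord_df <- if (length(coords)) do.call(rbind, coords) else
    data.frame(exon_id = character(0), transcript_id = character(0),
               start = integer(0), end = integer(0))
  rownames(coord_df) <- NULL

  structure(list(
    nodes = data.frame(exon_id = node_ids, seq = node_seqs,
                       stringsAsFactors = FALSE),
    coords = coord_df,
    links = link_df,
    paths = paths,
    transcript_len = stats::setNames(nchar(seqs), names(seqs)),
    dropped = dropped),
    class = "splice_graph")
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf(
    "<splice_graph> %d exon nodes, %d links, %d transcript paths (%d dropped)\n",
    nrow(x$nodes), nrow(x$links), length(x$paths), length(x$dropped)))
  invisible(x)
}

#' Predicted exon intervals of a splice graph
#'
#' @param graph A [build_splice_graph()] result.
#' @return `data.frame(transcript_id, start, end)` of all predicted exon
#'   coordinates (0-based half-open, transcript space), suitable for
#'   [classify_predictions()].
#' @export
predicted_intervals <- function(graph) {
  stopifnot(inherits(graph, "splice_graph"))
  out <- graph$coords[, c("transcript_id", "start", "end")]
  rownames(out) <- NULL
  out
}
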