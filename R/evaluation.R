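#' Convert genome-coordinate exon annotations to transcript coordinates
#'
#' Reads GFF3 `exon` records (1-based inclusive, genome space) and maps
#' each transcript's exons into transcript space, taking strand and exon
#' order into account: exons are ordered 5'-to-3' (ascending genome
#' position on `+`, descending on `-`) and laid head to tail, so exon *i*
#' occupies `[c, c + len_i)` where `c` is the summed length of its
#' upstream exons.  For example, two `+`-strand exons at chr1:1,000-1,100
#' and chr1:1,500-1,600 of transcript A become `A:0-100` and `A:100-200`.
#'
#' @param gff3 Path to a GFF3 file (read with \pkg{rtracklayer}), or a
#'   `GRanges` already imported from one.  Exon records must carry a
#'   `Parent` attribute naming the transcript (an optional `transcript:`
#'   prefix is stripped); exons of a transcript must share one strand.
#' @return A BED-like `data.frame(transcript_id, start, end, rank)` in
#'   0-based half-open transcript coordinates, rows ordered by transcript
#'   and rank (5'-to-3').
#' @export
gff3_to_transcript_bed <- function(gff3) {
  gr <- if (methods::is(gff3, "GRanges")) gff3 else
    rtracklayer::import(gff3, format = "gff3")
  ex <- gr[as.character(gr$type) == "exon"]
  if (length(ex) == 0)
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), rank = integer(0)))
  parents <- ex$Parent
  if (is.null(parents) || any(lengths(parents) == 0))
    stop("exon record without a transcript Parent attribute")
  idx <- rep(seq_along(ex), lengths(parents))
  tid <- sub("^transcript:", "", unlist(parents))
  gstart <- BiocGenerics::start(ex)[idx]   # 1-based inclusive
  gend <- BiocGenerics::end(ex)[idx]
  strand <- as.character(BiocGenerics::strand(ex))[idx]

  out <- lapply(split(seq_along(tid), tid), function(ii) {
    st <- unique(strand[ii])
    if (length(st) != 1 || !st %in% c("+", "-"))
      stop("transcript '", tid[ii[1]],
           "': exons must share a single +/- strand")
    ord <- if (st == "+") ii[order(gstart[ii])] else ii[order(-gstart[ii])]
    len <- gend[ord] - gstart[ord] + 1L
    cum <- cumsum(c(0L, len[-length(len)]))
    data.frame(transcript_id = tid[ord[1]], start = cum, end = cum + len,
               rank = seq_along(ord), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify predicted exon intervals against a truth set
#'
#' A prediction is a true positive when some truth interval on the same
#' transcript overlaps it by at least `min_frac` of *both* lengths
#' (reciprocal overlap).  Matching is one-to-one: eligible
#' prediction-truth pairs are taken greedily by decreasing reciprocal
#' overlap fraction (ties toward the leftmost truth interval, then the
#' leftmost prediction), and each interval participates in at most one
#' match.  Unmatched predictions are false positives; unmatched truth
#' intervals are false negatives.  Note the difference from raw
#' `bedtools intersect` counting, which can double-count multi-hit
#' intervals; one-to-one matching guarantees
#' `tp <= min(n_pred, n_truth)`.
#'
#' @param pred,truth `data.frame(transcript_id, start, end)` in
#'   transcript coordinates (0-based half-open).
#' @param min_frac Reciprocal overlap threshold in `(0, 1]` (default
#'   0.95).
#' @return A list: `tp`, `fp`, `fn`, and `matches` (a `data.frame` of the
#'   matched pairs with their overlap fractions).
#' @export
classify_predictions <- function(pred, truth, min_frac = 0.95) {
  stopifnot(min_frac > 0, min_frac <= 1)
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0)
    return(list(tp = 0L, fp = np, fn = nt,
                matches = data.frame(pred = integer(0), truth = integer(0),
                                     frac = numeric(0))))
  p <- data.frame(pi = seq_len(np), transcript_id = pred$transcript_id,
                  ps = pred$start, pe = pred$end)
  t <- data.frame(ti = seq_len(nt), transcript_id = truth$transcript_id,
                  ts = truth$start, te = truth$end)
  pairs <- merge(p, t, by = "transcript_id")
  ov <- pmax(0L, pmin(pairs$pe, pairs$te) - pmax(pairs$ps, pairs$ts))
  frac <- pmin(ov / (pairs$pe - pairs$ps), ov / (pairs$te - pairs$ts))
  pairs <- pairs[frac >= min_frac, , drop = FALSE]
  frac <- frac[frac >= min_frac]
  ord <- order(-frac, pairs$ts, pairs$ps)
  pairs <- pairs[ord, , drop = FALSE]
  frac <- frac[ord]

  p_used <- logical(np); t_used <- logical(nt)
  mp <- integer(0); mt <- integer(0); mf <- numeric(0)
  for (i in seq_len(nrow(pairs))) {
    pi <- pairs$pi[i]; ti <- pairs$ti[i]
    if (!p_used[pi] && !t_used[ti]) {
      p_used[pi] <- TRUE; t_used[ti] <- TRUE
      mp <- c(mp, pi); mt <- c(mt, ti); mf <- c(mf, frac[i])
    }
  }
  tp <- length(mp)
  list(tp = tp, fp = np - tp, fn = nt - tp,
       matches = data.frame(pred = mp, truth = mt, frac = mf))
}

#' Precision, recall and F1 from classification counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, and the F1 score is the
#' harmonic mean `2PR / (P + R)`.  Zero-denominator cases are reported as
#' 0 with `degenerate = TRUE`.
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @return An object of class `eval_report`: `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `degenerate`.
#' @export
prf <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degenerate <- FALSE
  precision <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- TRUE; 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else { degenerate <- TRUE; 0 }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), precision = precision, recall = recall,
                 f1 = f1, degenerate = degenerate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f%s\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1,
    if (x$degenerate) "  (degenerate: zero denominator)" else ""))
  invisible(x)
}

#' Compare predictions against a GFF3 reference annotation
#'
#' Converts the reference to transcript coordinates
#' ([gff3_to_transcript_bed()]), intersects with the predictions at the
#' reciprocal-overlap threshold ([classify_predictions()]), and reports
#' precision/recall/F1 ([prf()]).
#'
#' @param pred A `splice_graph`, or a
#'   `data.frame(transcript_id, start, end)` of predicted intervals.
#' @param gff3 GFF3 path or `GRanges` (see [gff3_to_transcript_bed()]),
#'   or an already converted truth `data.frame`.
#' @param min_frac Reciprocal overlap threshold (default 0.95).
#' @return An `eval_report`.
#' @export
compare_to_gff3 <- function(pred, gff3, min_frac = 0.95) {
  if (inherits(pred, "splice_graph")) pred <- predicted_intervals(pred)
  truth <- if (is.data.frame(gff3)) gff3 else gff3_to_transcript_bed(gff3)
  cl <- classify_predictions(pred, truth, min_frac)
  prf(cl$tp, cl$fp, cl$fn)
}

#' Write an evaluation report as TSV
#'
#' @param report An [prf()] `eval_report`.
#' @param path Output path; columns tp, fp, fn, precision, recall, f1.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  df <- data.frame(tp = report$tp, fp = report$fp, fn = report$fn,
                   precision = report$precision, recall = report$recall,
                   f1 = report$f1)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
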