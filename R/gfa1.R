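# GFA1 dialect notes.  Segments are exons, links are intron-exon
# boundaries, paths are transcripts, containments record where each exon
# sits inside its transcript(s).  The L-line separation field encodes the
# signed separation between consecutive exons: an overlap of o bases as
# "oM", abutting exons as "0M", and a gap of g bases (created by the
# length filter) as "gG" — the gap operator is a dialect extension,
# standard GFA1 CIGARs cannot represent inter-segment gaps.

fmt_sep <- function(sep) {
  ifelse(sep >= 0, paste0(sep, "M"), paste0(-sep, "G"))
}

parse_sep <- function(s, lineno) {
  m <- regmatches(s, regexec("^([0-9]+)([MG])$", s))[[1]]
  if (length(m) == 0)
    stop("line ", lineno, ": bad separation string '", s, "'")
  n <- as.integer(m[2])
  if (m[3] == "M") n else -n
}

wrap_seq <- function(seq, width = 80L) {
  if (nchar(seq) <= width) return(seq)
  starts <- seq(1L, nchar(seq), by = width)
  paste(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))),
        collapse = "\n")
}

#' Write a splice graph as GFA1
#'
#' Emits a `H VN:Z:1.0` header; one `S` line per exon (id, sequence,
#' `LN:i:` length tag); one `L` line per link with `+ +` orientations and
#' the signed separation (see the dialect note on `gG` gaps); one `C`
#' line per (transcript, exon, offset) containment; and one `P` line per
#' transcript path (all `+`, with an `LN:i:` tag carrying the transcript
#' length).  Record blocks appear in the order S, L, C, P, each in
#' first-encounter order; fields are tab-delimited with LF line endings.
#'
#' @param graph A [build_splice_graph()] result.
#' @param file Optional path; when given the text is written there.
#' @param transcript_len Optional named lengths overriding
#'   `graph$transcript_len`.
#' @return The GFA1 text as a single string (invisibly when `file` is
#'   given).
#' @export
write_gfa1 <- function(graph, file = NULL, transcript_len = NULL) {
  stopifnot(inherits(graph, "splice_graph"))
  if (is.null(transcript_len)) transcript_len <- graph$transcript_len
  ids <- graph$nodes$exon_id
  bad <- setdiff(c(graph$links$from, graph$links$to,
                   graph$coords$exon_id, unlist(graph$paths)), ids)
  if (length(bad))
    stop("dangling exon reference(s): ", paste(unique(bad), collapse = ", "))

  lens <- nchar(graph$nodes$seq)
  s_lines <- sprintf("S\t%s\t%s\tLN:i:%d", ids, graph$nodes$seq, lens)
  l_lines <- if (nrow(graph$links)) {
    sprintf("L\t%s\t+\t%s\t+\t%s", graph$links$from, graph$links$to,
            fmt_sep(graph$links$sep))
  } else character(0)
  c_lines <- if (nrow(graph$coords)) {
    sprintf("C\t%s\t+\t%s\t+\t%d\t%dM",
            graph$coords$transcript_id, graph$coords$exon_id,
            graph$coords$start, graph$coords$end - graph$coords$start)
  } else character(0)
  p_lines <- vapply(names(graph$paths), function(tid) {
    sprintf("P\t%s\t%s\t*\tLN:i:%d", tid,
            paste0(graph$paths[[tid]], "+", collapse = ","),
            as.integer(transcript_len[[tid]]))
  }, character(1))

  txt <- paste0(paste(c("H\tVN:Z:1.0", s_lines, l_lines, c_lines, p_lines),
                      collapse = "\n"), "\n")
  if (!is.null(file)) {
    con <- file(file, "wb")  # binary mode pins LF endings
    writeChar(txt, con, eos = NULL)
    close(con)
    return(invisible(txt))
  }
  txt
}

#' Read a GFA1 splice graph
#'
#' Inverse of [write_gfa1()] on documents it produced; unknown optional
#' tags are ignored.  Malformed records, bad separation strings and
#' dangling references raise errors naming the offending line.
#'
#' @param x GFA1 text (single string or character vector of lines) or a
#'   file path.
#' @return A `splice_graph` (its `dropped` slot is empty: transcripts
#'   without exons are not represented in GFA1).
#' @export
read_gfa1 <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    x <- readLines(x)
  if (length(x) == 1) x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  lines <- x[nzchar(x)]

  node_ids <- character(0); node_seqs <- character(0)
  links <- list(); conts <- list(); paths <- list()
  path_len <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    rt <- f[1]
    if (rt == "H") next
    if (rt == "S") {
      if (length(f) < 3) stop("line ", i, ": malformed S record")
      node_ids <- c(node_ids, f[2]); node_seqs <- c(node_seqs, f[3])
    } else if (rt == "L") {
      if (length(f) < 6) stop("line ", i, ": malformed L record")
      links[[length(links) + 1L]] <- list(
        from = f[2], to = f[4], sep = parse_sep(f[6], i), lineno = i)
    } else if (rt == "C") {
      if (length(f) < 7) stop("line ", i, ": malformed C record")
      conts[[length(conts) + 1L]] <- list(
        transcript = f[2], exon = f[4], start = as.integer(f[6]), lineno = i)
    } else if (rt == "P") {
      if (length(f) < 3) stop("line ", i, ": malformed P record")
      segs <- strsplit(f[3], ",", fixed = TRUE)[[1]]
      if (!all(grepl("\\+$", segs)))
        stop("line ", i, ": only '+' path orientations are supported")
      ids <- sub("\\+$", "", segs)
      paths[[f[2]]] <- ids
      attr(paths[[f[2]]], "lineno") <- i
      ln <- grep("^LN:i:", f[-(1:3)], value = TRUE)
      if (length(ln)) path_len[[f[2]]] <- as.integer(sub("^LN:i:", "", ln[1]))
    } else {
      stop("line ", i, ": unknown record type '", rt, "'")
    }
  }

  seqs <- stats::setNames(node_seqs, node_ids)
  for (l in links)
    if (!l$from %in% node_ids || !l$to %in% node_ids)
      stop("line ", l$lineno, ": L record references undeclared segment")
  for (ct in conts) {
    if (!ct$exon %in% node_ids)
      stop("line ", ct$lineno, ": C record references undeclared segment")
  }
  for (tid in names(paths))
    if (!all(paths[[tid]] %in% node_ids))
      stop("line ", attr(paths[[tid]], "lineno"),
           ": P record references undeclared segment")
  for (ct in conts)
    if (!ct$transcript %in% names(paths))
      stop("line ", ct$lineno, ": C record container '", ct$transcript,
           "' is not a declared path")

  coord_df <- if (length(conts)) {
    data.frame(
      exon_id = vapply(conts, `[[`, character(1), "exon"),
      transcript_id = vapply(conts, `[[`, character(1), "transcript"),
      start = vapply(conts, `[[`, integer(1), "start"),
      stringsAsFactors = FALSE)
  } else data.frame(exon_id = character(0), transcript_id = character(0),
                    start = integer(0))
  coord_df$end <- coord_df$start + nchar(seqs[coord_df$exon_id])
  link_df <- if (length(links)) {
    data.frame(from = vapply(links, `[[`, character(1), "from"),
               to = vapply(links, `[[`, character(1), "to"),
               sep = vapply(links, `[[`, integer(1), "sep"),
               stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0), sep = integer(0))
  paths <- lapply(paths, function(p) { attributes(p) <- NULL; p })

  tlen <- vapply(names(paths), function(tid) {
    if (!is.null(path_len[[tid]])) return(path_len[[tid]])
    max(coord_df$end[coord_df$transcript_id == tid], 0L)
  }, integer(1))

  structure(list(
    nodes = data.frame(exon_id = node_ids, seq = node_seqs,
                       stringsAsFactors = FALSE),
    coords = coord_df,
    links = link_df,
    paths = paths,
    transcript_len = tlen,
    dropped = character(0)),
    class = "splice_graph")
}

#' Export exon sequences as FASTA
#'
#' One record per exon node; the header is the exon id followed by a
#' space and comma-separated coordinate descriptors
#' `transcript:start-end`.  Sequences are wrapped at 80 columns.
#'
#' @param graph A `splice_graph`.
#' @param file Optional output path.
#' @return FASTA text as a single string (empty for an empty graph).
#' @export
exons_to_fasta <- function(graph, file = NULL) {
  stopifnot(inherits(graph, "splice_graph"))
  if (nrow(graph$nodes) == 0) {
    txt <- ""
  } else {
    recs <- vapply(seq_len(nrow(graph$nodes)), function(i) {
      id <- graph$nodes$exon_id[i]
      cc <- graph$coords[graph$coords$exon_id == id, , drop = FALSE]
      desc <- paste(sprintf("%s:%d-%d", cc$transcript_id, cc$start, cc$end),
                    collapse = ",")
      paste0(">", id, " ", desc, "\n", wrap_seq(graph$nodes$seq[i]))
    }, character(1))
    txt <- paste0(paste(recs, collapse = "\n"), "\n")
  }
  if (!is.null(file)) { writeLines(sub("\n$", "", txt), file); return(invisible(txt)) }
  txt
}

#' Export N-gapped spliced transcripts as FASTA
#'
#' Each transcript is rebuilt from its exons in path order, joined by runs
#' of `N` of length `n_gap`.  When consecutive exons overlap by `o > 0`
#' bases the downstream exon's first `o` bases are trimmed before joining,
#' so no sequence is duplicated; with `n_gap = 0` and no filtered bases
#' this reconstructs the transcript substring exactly.
#'
#' @param graph A `splice_graph`.
#' @param n_gap Number of `N`s between consecutive exons (default 100).
#' @param file Optional output path.
#' @return FASTA text as a single string.
#' @export
gapped_transcripts_to_fasta <- function(graph, n_gap = 100L, file = NULL) {
  stopifnot(inherits(graph, "splice_graph"), n_gap >= 0)
  seqs <- stats::setNames(graph$nodes$seq, graph$nodes$exon_id)
  recs <- vapply(names(graph$paths), function(tid) {
    cc <- graph$coords[graph$coords$transcript_id == tid, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    pieces <- unname(seqs[cc$exon_id])
    if (nrow(cc) > 1) {
      ov <- cc$end[-nrow(cc)] - cc$start[-1]
      for (j in seq_along(ov))
        if (ov[j] > 0)
          pieces[j + 1] <- substr(pieces[j + 1], ov[j] + 1L,
                                  nchar(pieces[j + 1]))
    }
    paste0(">", tid, "\n",
           wrap_seq(paste(pieces, collapse = strrep("N", n_gap))))
  }, character(1))
  txt <- if (length(recs)) paste0(paste(recs, collapse = "\n"), "\n") else ""
  if (!is.null(file)) { writeLines(sub("\n$", "", txt), file); return(invisible(txt)) }
  txt
}
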