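# Sequence input normalization: user-facing functions accept a named
# character vector, a Biostrings XStringSet, or a FASTA/FASTQ file path
# (optionally gzipped); internally everything is a named character vector.

#' @keywords internal
as_seq_vector <- function(x, format = c("fasta", "fastq"), what = "sequences") {
  format <- match.arg(format)
  if (is.character(x) && length(x) == 0)
    return(stats::setNames(character(0), character(0)))
  if (is.character(x) && length(x) >= 1 &&
      all(file.exists(x)) && !any(grepl("^[ACGTNacgtn]+$", x))) {
    sets <- lapply(x, function(p) {
      tryCatch(
        Biostrings::readDNAStringSet(p, format = format),
        error = function(e) stop("failed to parse ", format, " file '", p,
                                 "': ", conditionMessage(e), call. = FALSE))
    })
    x <- do.call(c, sets)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x)))
      names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("cannot interpret ", what, " input of class ", class(x)[1])
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (names become headers).
#' @param path Output file.
#' @param width Line-wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write reads to FASTQ with constant qualities
#'
#' @param seqs Named character vector of reads.
#' @param path Output file (".gz" suffix triggers compression).
#' @param qual Single quality character applied to every base (default
#'   "I", Phred 40; the pipeline ignores qualities).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, qual = "I") {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  q <- Biostrings::BStringSet(strrep(qual, Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
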