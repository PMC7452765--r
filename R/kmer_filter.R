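#' Extract canonical k-mers from a sequence
#'
#' Slides a window of width `k` over `seq` and reports, for each window, the
#' lexicographic minimum of the window and its reverse complement (the
#' *canonical* k-mer).  Strand-neutral membership is required because WGS
#' reads come from both strands.  Windows containing any character outside
#' `A/C/G/T` (case-insensitive) are omitted, but the positions of the
#' remaining windows are preserved.
#'
#' @param seq A single nucleotide string.
#' @param k K-mer length (>= 1).  `k > nchar(seq)` yields zero rows.
#' @return A `data.frame` with columns `pos` (0-based window start) and
#'   `kmer` (canonical k-mer string).
#' @examples
#' canonical_kmers("ACNGTA", 3)
#' @export
canonical_kmers <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1)
  res <- cpp_canonical_kmers(seq, as.integer(k))
  data.frame(pos = res$pos, kmer = res$kmer, stringsAsFactors = FALSE)
}

#' Create a Bloom filter for k-mer membership
#'
#' A Bloom filter is a fixed-size bit array answering approximate set
#' membership: it never returns false negatives but may return false
#' positives at a rate governed by the array size `m`, the number of hash
#' functions `h`, and the number of elements inserted.  Hashing is double
#' hashing over two 64-bit FNV-1a/splitmix hashes of the k-mer string:
#' `h_i = (h1 + i * h2) mod m`.
#'
#' The returned object has reference semantics: [bf_insert()] modifies the
#' filter in place (and also returns it, invisibly).
#'
#' @param k K-mer length in bases.
#' @param m Filter size in bits.
#' @param h Number of hash functions (default 4, the value used by the
#'   ABySS Bloom filter implementation this design follows).
#' @return An object of class `kmer_filter`.
#' @seealso [bf_insert()], [bf_contains()], [bf_fpr()],
#'   [cascading_kmer_filter()]
#' @export
kmer_filter <- function(k = 25L, m, h = 4L) {
  stopifnot(k >= 1, m >= 1, h >= 1)
  structure(
    list(ptr = cpp_bf_new(as.integer(k), as.double(m), as.integer(h)),
         k = as.integer(k), m = as.double(m), h = as.integer(h)),
    class = "kmer_filter")
}

#' Insert k-mers into a Bloom filter
#'
#' Inserts each string of `kmers` verbatim (callers canonicalize; see
#' [canonical_kmers()] and [insert_sequences()]).  Every inserted k-mer is
#' guaranteed to query positive afterwards.
#'
#' @param f A [kmer_filter()].
#' @param kmers Character vector of k-mers, each of length `f$k` (anything
#'   else is an error).
#' @return The filter, invisibly (modified in place).
#' @export
bf_insert <- function(f, kmers) {
  stopifnot(inherits(f, "kmer_filter"))
  cpp_bf_insert(f$ptr, as.character(kmers))
  invisible(f)
}

#' Query a Bloom filter
#'
#' @inheritParams bf_insert
#' @return Logical vector: `TRUE` iff all `h` probed bits are set for the
#'   k-mer.  Inserted k-mers always return `TRUE`; never-inserted k-mers
#'   return `TRUE` only at the false-positive rate (see [bf_fpr()]).
#' @export
bf_contains <- function(f, kmers) {
  stopifnot(inherits(f, "kmer_filter"))
  cpp_bf_contains(f$ptr, as.character(kmers))
}

#' Analytic false-positive rate of a Bloom filter
#'
#' Classical approximation `(1 - exp(-h n / m))^h`, with `n` the number of
#' insert calls made so far (a proxy for distinct cardinality; repeated
#' insertions of the same k-mer inflate `n` and make the estimate
#' conservative).
#'
#' @param f A [kmer_filter()], or a [cascading_kmer_filter()] (in which
#'   case one rate per level is returned).
#' @return Probability in `[0, 1]` (vector for cascading filters).
#' @export
bf_fpr <- function(f) {
  if (inherits(f, "cascading_kmer_filter")) {
    info <- cpp_cbf_info(f$ptr)
    return((1 - exp(-info$h * info$n_inserted / info$m_per_level))^info$h)
  }
  stopifnot(inherits(f, "kmer_filter"))
  info <- cpp_bf_info(f$ptr)
  (1 - exp(-info$h * info$n_inserted / info$m))^info$h
}

#' Number of insert calls made on a filter
#'
#' @param f A [kmer_filter()] or [cascading_kmer_filter()] (vector per
#'   level) or [exact_kmer_set()] (distinct k-mer count).
#' @return Numeric count(s); never decreases over the life of a filter.
#' @export
n_inserted <- function(f) {
  if (inherits(f, "kmer_filter")) return(cpp_bf_info(f$ptr)$n_inserted)
  if (inherits(f, "cascading_kmer_filter"))
    return(cpp_cbf_info(f$ptr)$n_inserted)
  if (inherits(f, "exact_kmer_set")) return(cpp_exact_info(f$ptr)$n_distinct)
  stop("not a k-mer filter")
}

#' Create a cascading Bloom filter of solid k-mers
#'
#' An ordered stack of `levels` Bloom filters sharing `k`, `m_per_level`
#' and `h`.  Each [cbf_insert()] call places the k-mer into the first level
#' that does not already contain it, so a k-mer reaches level `i` only
#' after (at least) `i` occurrences; the last level therefore holds the
#' *solid* k-mers — those seen at least `levels` times, taken as free of
#' sequencing error.  Only the last level is used for exon prediction.
#'
#' @param k K-mer length.
#' @param m_per_level Bits per level.
#' @param h Hash functions per level.
#' @param levels Cascade depth (default 2: a k-mer must be seen twice to be
#'   solid).
#' @return An object of class `cascading_kmer_filter`, usable as the
#'   `solid` backend of [build_splice_graph()].
#' @export
cascading_kmer_filter <- function(k = 25L, m_per_level, h = 4L, levels = 2L) {
  stopifnot(k >= 1, m_per_level >= 1, h >= 1, levels >= 1)
  structure(
    list(ptr = cpp_cbf_new(as.integer(k), as.double(m_per_level),
                           as.integer(h), as.integer(levels)),
         k = as.integer(k), m_per_level = as.double(m_per_level),
         h = as.integer(h), levels = as.integer(levels)),
    class = "cascading_kmer_filter")
}

#' Insert k-mers into a cascading filter or exact k-mer set
#'
#' Cascade rule: the k-mer goes into the first level that does not already
#' contain it; if all levels contain it, nothing changes.  For an
#' [exact_kmer_set()] the occurrence count is incremented.
#'
#' @param c A [cascading_kmer_filter()] or [exact_kmer_set()].
#' @param kmers Character vector of k-mers of length `c$k` (verbatim).
#' @return `c`, invisibly (modified in place).
#' @export
cbf_insert <- function(c, kmers) {
  if (inherits(c, "exact_kmer_set")) {
    cpp_exact_insert(c$ptr, as.character(kmers))
  } else {
    stopifnot(inherits(c, "cascading_kmer_filter"))
    cpp_cbf_insert(c$ptr, as.character(kmers))
  }
  invisible(c)
}

#' Test k-mer solidity
#'
#' A k-mer is *solid* when it is present in the last cascade level, i.e.
#' it was inserted at least `levels` times (up to Bloom false positives).
#' For an [exact_kmer_set()] solidity is exactly `count >= levels`.
#'
#' @inheritParams cbf_insert
#' @return Logical vector.
#' @export
cbf_solid <- function(c, kmers) {
  if (inherits(c, "exact_kmer_set"))
    return(cpp_exact_solid(c$ptr, as.character(kmers)))
  stopifnot(inherits(c, "cascading_kmer_filter"))
  cpp_cbf_solid(c$ptr, as.character(kmers))
}

#' Query one level of a cascading filter
#'
#' @inheritParams cbf_insert
#' @param level 1-based level index.
#' @return Logical vector of membership at that level.
#' @export
cbf_contains_level <- function(c, kmers, level) {
  stopifnot(inherits(c, "cascading_kmer_filter"),
            level >= 1, level <= c$levels)
  cpp_cbf_contains_level(c$ptr, as.character(kmers), as.integer(level) - 1L)
}

#' Exact k-mer set backend
#'
#' A hash-map k-mer counter implementing the same insert/solid contract as
#' [cascading_kmer_filter()], but exactly: no false positives.  Intended as
#' a test oracle and for small inputs where memory is not a concern.
#'
#' @param k K-mer length.
#' @param levels Solidity threshold: a k-mer is solid iff its count is at
#'   least `levels`.
#' @return An object of class `exact_kmer_set`.
#' @export
exact_kmer_set <- function(k = 25L, levels = 2L) {
  stopifnot(k >= 1, levels >= 1)
  structure(
    list(ptr = cpp_exact_new(as.integer(k), as.integer(levels)),
         k = as.integer(k), levels = as.integer(levels)),
    class = "exact_kmer_set")
}

#' Exact occurrence counts
#'
#' @param c An [exact_kmer_set()].
#' @param kmers Character vector of k-mers.
#' @return Integer counts (0 for never-inserted k-mers).
#' @export
kmer_counts <- function(c, kmers) {
  stopifnot(inherits(c, "exact_kmer_set"))
  cpp_exact_count(c$ptr, as.character(kmers))
}

#' Insert every canonical k-mer of whole sequences
#'
#' Bulk canonicalizing insertion: each A/C/G/T window of each sequence is
#' canonicalized ([canonical_kmers()]) and inserted.  Sequences shorter
#' than `k` contribute nothing.
#'
#' @param f A [kmer_filter()], [cascading_kmer_filter()] or
#'   [exact_kmer_set()].
#' @param seqs Character vector of sequences.
#' @return `f`, invisibly.
#' @export
insert_sequences <- function(f, seqs) {
  seqs <- as.character(seqs)
  if (inherits(f, "kmer_filter")) {
    cpp_bf_insert_seqs(f$ptr, seqs)
  } else if (inherits(f, "cascading_kmer_filter")) {
    cpp_cbf_insert_seqs(f$ptr, seqs)
  } else if (inherits(f, "exact_kmer_set")) {
    cpp_exact_insert_seqs(f$ptr, seqs)
  } else stop("not a k-mer filter")
  invisible(f)
}

#' @export
print.kmer_filter <- function(x, ...) {
  info <- cpp_bf_info(x$ptr)
  cat(sprintf("<kmer_filter> k=%d m=%s bits h=%d n_inserted=%s FPR=%.3g\n",
              info$k, format(info$m, big.mark = ","), info$h,
              format(info$n_inserted, big.mark = ","), bf_fpr(x)))
  invisible(x)
}

#' @export
print.cascading_kmer_filter <- function(x, ...) {
  info <- cpp_cbf_info(x$ptr)
  cat(sprintf("<cascading_kmer_filter> k=%d levels=%d m/level=%s bits h=%d\n",
              info$k, info$levels, format(info$m_per_level, big.mark = ","),
              info$h))
  fpr <- bf_fpr(x)
  for (i in seq_len(info$levels))
    cat(sprintf("  level %d: n_inserted=%s FPR=%.3g%s\n", i,
                format(info$n_inserted[i], big.mark = ","), fpr[i],
                if (i == info$levels) "  (analysis level)" else ""))
  invisible(x)
}

#' @export
print.exact_kmer_set <- function(x, ...) {
  info <- cpp_exact_info(x$ptr)
  cat(sprintf("<exact_kmer_set> k=%d solidity threshold=%d distinct=%s\n",
              info$k, info$levels, format(info$n_distinct, big.mark = ",")))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

FILTER_MAGIC <- "EXOGRAPHCBF"
FILTER_VERSION <- 1L
HASH_ID <- "fnv1a64x2-double"

#' Write a cascading k-mer filter to a binary file
#'
#' Layout: magic string, format version, hash-function identifier, then
#' `k`, `h`, number of levels, bits per level, and for each level its
#' insert count and raw bit array.  The file is loadable with
#' [read_kmer_filter()] and is byte-identical for identical inputs.
#'
#' @param c A [cascading_kmer_filter()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kmer_filter <- function(c, path) {
  stopifnot(inherits(c, "cascading_kmer_filter"))
  info <- cpp_cbf_info(c$ptr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(FILTER_MAGIC, con, eos = NULL)
  writeBin(FILTER_VERSION, con, size = 4L, endian = "little")
  writeBin(nchar(HASH_ID), con, size = 4L, endian = "little")
  writeChar(HASH_ID, con, eos = NULL)
  writeBin(c(info$k, info$h, info$levels), con, size = 4L, endian = "little")
  writeBin(as.double(info$m_per_level), con, size = 8L, endian = "little")
  for (i in seq_len(info$levels)) {
    writeBin(as.double(info$n_inserted[i]), con, size = 8L, endian = "little")
    writeBin(as.raw(cpp_cbf_level_bits(c$ptr, i - 1L)), con)
  }
  invisible(path)
}

#' Read a cascading k-mer filter written by [write_kmer_filter()]
#'
#' @param path File path.
#' @return A [cascading_kmer_filter()].
#' @export
read_kmer_filter <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(FILTER_MAGIC), useBytes = TRUE)
  if (!identical(magic, FILTER_MAGIC))
    stop("not a filter file (bad magic): ", path)
  version <- readBin(con, "integer", size = 4L, endian = "little")
  if (version != FILTER_VERSION)
    stop("unsupported filter file version: ", version)
  nh <- readBin(con, "integer", size = 4L, endian = "little")
  hash_id <- readChar(con, nh, useBytes = TRUE)
  if (!identical(hash_id, HASH_ID))
    stop("filter built with unknown hash scheme: ", hash_id)
  ints <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  m <- readBin(con, "double", size = 8L, endian = "little")
  out <- cascading_kmer_filter(k = ints[1], m_per_level = m, h = ints[2],
                               levels = ints[3])
  nbytes <- ceiling(m / 8)
  for (i in seq_len(ints[3])) {
    n_ins <- readBin(con, "double", size = 8L, endian = "little")
    bits <- readBin(con, "raw", n = nbytes)
    cpp_cbf_set_level(out$ptr, i - 1L, n_ins, bits)
  }
  out
}
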