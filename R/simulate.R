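# Deterministic toy-data generator: a single-chromosome genome of spliced
# genes with canonical GT..AG introns, its transcriptome, a GFF3/BED truth
# annotation, and uniformly sampled error-bearing short reads.  This is the
# desk-scale test substrate for the whole pipeline.

with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

rand_seq <- function(n, gc) paste(rand_bases(n, gc), collapse = "")

# Exon sequence whose terminal bases avoid G.  An exon starting (or
# ending) with G would let the transcript k-mer that overhangs the
# junction by one base reproduce the genomic context, where the intron
# contributes its GT (or AG) signal base at that position; keeping G out
# of the terminal positions guarantees that every junction-spanning
# transcript k-mer is absent from the genome, which is the boundary
# signal the predictor relies on.
rand_exon <- function(n, gc) {
  b <- rand_bases(n, gc)
  caps <- sample(c("A", "C", "T"), 2, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, (1 - gc) / 2))
  b[1] <- caps[1]
  b[n] <- caps[2]
  paste(b, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Specification of a simulated toy genome
#'
#' @param n_genes Number of genes (default 20).
#' @param exons_per_gene Inclusive range of exon counts per gene
#'   (default 2-4).
#' @param exon_len Inclusive range of exon lengths in bases (default
#'   100-300; keep the minimum at or above `k + q` so the length filter is
#'   not the limiting factor).
#' @param intron_len Inclusive range of intron lengths (default 200-500;
#'   must allow at least 4 bases for the `GT..AG` splice signals).
#' @param intergenic_len Inclusive range of intergenic spacer lengths
#'   (default 200-500), also used for the chromosome flanks.
#' @param gc GC fraction of all generated sequence (default 0.5).
#' @param minus_strand_frac Fraction of genes placed on the minus strand
#'   (default 0: all genes on `+`).
#' @param seed RNG seed; the same spec yields byte-identical output.
#' @param k_check K-mer length for the junction-uniqueness screen
#'   (default 25): candidate genomes in which any transcript k-mer
#'   spanning an exon-exon junction also occurs in the genome are
#'   rejected and redrawn, guaranteeing clean boundary signals for
#'   exact-recovery tests.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(n_genes = 20L, exons_per_gene = c(2L, 4L),
                        exon_len = c(100L, 300L), intron_len = c(200L, 500L),
                        intergenic_len = c(200L, 500L), gc = 0.5,
                        minus_strand_frac = 0, seed = 42L, k_check = 25L) {
  stopifnot(n_genes >= 1, all(exons_per_gene >= 1), all(exon_len >= 1),
            all(intron_len >= 1), all(intergenic_len >= 1),
            gc > 0, gc < 1, minus_strand_frac >= 0, minus_strand_frac <= 1)
  if (min(intron_len) < 4)
    stop("introns must be at least 4 bp to carry the GT..AG signal")
  as_range <- function(x) as.integer(if (length(x) == 1) c(x, x) else x[1:2])
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = as_range(exons_per_gene),
                 exon_len = as_range(exon_len),
                 intron_len = as_range(intron_len),
                 intergenic_len = as_range(intergenic_len),
                 gc = gc, minus_strand_frac = minus_strand_frac,
                 seed = as.integer(seed), k_check = as.integer(k_check)),
            class = "genome_spec")
}

rint <- function(range, n = 1L) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a toy genome, transcriptome and truth annotation
#'
#' Lays `n_genes` spliced genes on one chromosome, separated (and
#' flanked) by random intergenic sequence.  Every intron starts with `GT`
#' and ends with `AG`; each transcript is the concatenation of its exons
#' in 5'-to-3' order.  Candidate genomes where a junction-spanning
#' transcript k-mer recurs anywhere in the genome are rejected and
#' redrawn (see `k_check` in [genome_spec()]).  Output is deterministic
#' in `spec$seed`.
#'
#' @param spec A [genome_spec()].
#' @param max_tries Maximum redraws of the whole genome before giving up
#'   on the uniqueness screen.
#' @return A list of class `genome_fixture`: `genome` (named character,
#'   one chromosome `chr1`), `transcripts` (named character), `gff3`
#'   (`data.frame` of GFF3 columns with gene/mRNA/exon records), `truth`
#'   (`data.frame(transcript_id, start, end, rank)` in transcript space),
#'   and `spec`.
#' @export
simulate_genome <- function(spec = genome_spec(), max_tries = 50L) {
  stopifnot(inherits(spec, "genome_spec"))
  with_local_seed(spec$seed, {
    for (try in seq_len(max_tries)) {
      fix <- simulate_genome_once(spec)
      if (junctions_unique(fix, spec$k_check)) return(fix)
    }
    stop("could not generate a genome with unique junction k-mers in ",
         max_tries, " tries; relax the spec or change the seed")
  })
}

simulate_genome_once <- function(spec) {
  pieces <- character(0)
  gff <- list()
  transcripts <- character(0)
  truth <- list()
  offset <- 0L   # 0-based genome offset

  add_piece <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    offset <<- offset + nchar(s)
  }
  add_piece(rand_seq(rint(spec$intergenic_len), spec$gc))

  for (g in seq_len(spec$n_genes)) {
    gid <- sprintf("gene%02d", g)
    tid <- sprintf("tr%02d", g)
    n_ex <- rint(spec$exons_per_gene)
    exlens <- rint(spec$exon_len, n_ex)
    inlens <- if (n_ex > 1) rint(spec$intron_len, n_ex - 1L) else integer(0)
    exons <- vapply(exlens, rand_exon, character(1), gc = spec$gc)
    introns <- vapply(inlens, function(l)
      paste0("GT", rand_seq(l - 4L, spec$gc), "AG"), character(1))
    strand <- if (stats::runif(1) < spec$minus_strand_frac) "-" else "+"

    body_parts <- character(2L * n_ex - 1L)
    body_parts[seq(1, by = 2, length.out = n_ex)] <- exons
    if (n_ex > 1) body_parts[seq(2, by = 2, length.out = n_ex - 1L)] <- introns
    body <- paste(body_parts, collapse = "")
    B <- nchar(body)

    # exon spans in body coordinates (0-based half-open, transcript order)
    estart <- cumsum(c(0L, head(exlens, -1) + inlens))
    eend <- estart + exlens
    # map to genome coordinates (1-based inclusive for GFF3)
    if (strand == "+") {
      gstart <- offset + estart + 1L
      gend <- offset + eend
    } else {
      gstart <- offset + B - eend + 1L
      gend <- offset + B - estart
    }
    gff[[length(gff) + 1L]] <- data.frame(
      seqid = "chr1", source = "exograph_sim",
      type = c("gene", "mRNA", rep("exon", n_ex)),
      start = c(offset + 1L, offset + 1L, gstart),
      end = c(offset + B, offset + B, gend),
      score = ".", strand = strand, phase = ".",
      attributes = c(sprintf("ID=%s", gid),
                     sprintf("ID=%s;Parent=%s", tid, gid),
                     sprintf("ID=%s.exon%d;Parent=%s", tid, seq_len(n_ex),
                             tid)),
      stringsAsFactors = FALSE)

    add_piece(if (strand == "+") body else revcomp(body))
    transcripts[[tid]] <- paste(exons, collapse = "")
    cum <- cumsum(c(0L, head(exlens, -1)))
    truth[[tid]] <- data.frame(transcript_id = tid, start = cum,
                               end = cum + exlens, rank = seq_len(n_ex),
                               stringsAsFactors = FALSE)
    add_piece(rand_seq(rint(spec$intergenic_len), spec$gc))
  }

  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  gff <- do.call(rbind, gff); rownames(gff) <- NULL
  structure(list(genome = c(chr1 = paste(pieces, collapse = "")),
                 transcripts = transcripts, gff3 = gff, truth = truth,
                 spec = spec),
            class = "genome_fixture")
}

# TRUE iff no junction-spanning transcript k-mer occurs in the genome
junctions_unique <- function(fix, k) {
  gset <- exact_kmer_set(k = k, levels = 1L)
  insert_sequences(gset, fix$genome)
  for (tid in names(fix$transcripts)) {
    tr <- fix$transcripts[[tid]]
    bounds <- fix$truth$end[fix$truth$transcript_id == tid]
    bounds <- bounds[-length(bounds)]   # internal junctions only
    for (e in bounds) {
      lo <- max(0L, e - k + 1L)
      hi <- min(nchar(tr) - k, e - 1L)
      if (hi < lo) next
      sub <- substr(tr, lo + 1L, hi + k)
      km <- canonical_kmers(sub, k)
      if (any(cbf_solid(gset, km$kmer))) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.genome_fixture <- function(x, ...) {
  cat(sprintf(
    "<genome_fixture> genome %s bp, %d transcripts, %d true exons (seed %d)\n",
    format(nchar(x$genome), big.mark = ","), length(x$transcripts),
    nrow(x$truth), x$spec$seed))
  invisible(x)
}

#' Write a genome fixture to disk
#'
#' @param fix A [simulate_genome()] result.
#' @param dir Output directory (created if needed).  Writes `genome.fa`,
#'   `transcripts.fa`, `annotation.gff3` and `truth.bed`.
#' @return Named vector of the four paths, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  stopifnot(inherits(fix, "genome_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             transcripts = file.path(dir, "transcripts.fa"),
             gff3 = file.path(dir, "annotation.gff3"),
             truth = file.path(dir, "truth.bed"))
  write_fasta(fix$genome, paths["genome"])
  write_fasta(fix$transcripts, paths["transcripts"])
  writeLines(c("##gff-version 3",
               apply(fix$gff3, 1, paste, collapse = "\t")),
             paths["gff3"])
  utils::write.table(fix$truth[, c("transcript_id", "start", "end")],
                     paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Specification of a simulated WGS read set
#'
#' @param coverage Fold genome coverage (> 0; default 30, inside the
#'   30-40x window where near-optimal exon recovery is expected).
#' @param read_len Read length in bases (default 100).
#' @param paired Simulate read pairs from both fragment ends (default
#'   `FALSE`).
#' @param insert_mean,insert_sd Fragment length distribution for paired
#'   mode (defaults 300 and 30).
#' @param error_rate Per-base substitution probability in `[0, 1)`
#'   (default 0; no indels are simulated).
#' @param seed RNG seed.
#' @return A list of class `read_spec`.
#' @export
read_spec <- function(coverage = 30, read_len = 100L, paired = FALSE,
                      insert_mean = 300, insert_sd = 30, error_rate = 0,
                      seed = 1L) {
  stopifnot(coverage > 0, read_len >= 1, error_rate >= 0, error_rate < 1)
  structure(list(coverage = coverage, read_len = as.integer(read_len),
                 paired = isTRUE(paired), insert_mean = insert_mean,
                 insert_sd = insert_sd, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_spec")
}

add_substitutions <- function(reads, rate) {
  if (rate <= 0) return(reads)
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0)) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in sample.int(length(ch), n_err[i]))
      ch[p] <- sample(setdiff(bases, ch[p]), 1)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate uniformly sampled WGS reads
#'
#' Fragment starts are uniform over the genome; each fragment is
#' reverse-complemented with probability 0.5; substitution errors are
#' i.i.d. at `error_rate`.  The fragment count is
#' `ceiling(coverage * genome_len / (read_len * (2 if paired else 1)))`,
#' so total sequenced bases approximate `coverage * genome_len`.
#' Deterministic in `spec$seed`.
#'
#' @param genome A [simulate_genome()] fixture, named character vector,
#'   `DNAStringSet`, or FASTA path.  Multi-sequence genomes are sampled
#'   proportionally to length.
#' @param spec A [read_spec()].
#' @return Single-end: a named character vector of reads.  Paired: a list
#'   `(r1, r2)` of named character vectors.  Use [write_fastq()] to
#'   export (qualities are constant; the pipeline ignores them).
#' @export
simulate_reads <- function(genome, spec = read_spec()) {
  stopifnot(inherits(spec, "read_spec"))
  if (inherits(genome, "genome_fixture")) genome <- genome$genome
  genome <- as_seq_vector(genome, "fasta", "genome")
  if (length(genome) == 0 || sum(nchar(genome)) == 0)
    stop("empty genome")
  glens <- nchar(genome)
  frag_len_needed <- if (spec$paired)
    max(spec$read_len, 1L) else spec$read_len
  if (all(glens < frag_len_needed))
    stop("read length ", spec$read_len,
         " exceeds every sequence in the genome")
  G <- sum(glens)
  per_frag <- spec$read_len * (if (spec$paired) 2L else 1L)
  n_frag <- ceiling(spec$coverage * G / per_frag)

  with_local_seed(spec$seed, {
    chrom <- if (length(genome) == 1) rep(1L, n_frag) else
      sample(seq_along(genome), n_frag, replace = TRUE, prob = glens)
    if (!spec$paired) {
      starts <- 1L + floor(stats::runif(n_frag) *
                             (glens[chrom] - spec$read_len + 1L))
      reads <- substring(genome[chrom], starts, starts + spec$read_len - 1L)
      flip <- stats::runif(n_frag) < 0.5
      if (any(flip)) reads[flip] <- revcomp(reads[flip])
      reads <- add_substitutions(reads, spec$error_rate)
      names(reads) <- sprintf("read%06d", seq_len(n_frag))
      reads
    } else {
      flen <- pmax(spec$read_len,
                   pmin(glens[chrom],
                        round(stats::rnorm(n_frag, spec$insert_mean,
                                           spec$insert_sd))))
      starts <- 1L + floor(stats::runif(n_frag) * (glens[chrom] - flen + 1L))
      left <- substring(genome[chrom], starts, starts + spec$read_len - 1L)
      right <- substring(genome[chrom], starts + flen - spec$read_len,
                         starts + flen - 1L)
      flip <- stats::runif(n_frag) < 0.5
      r1 <- ifelse(flip, revcomp(right), left)
      r2 <- ifelse(flip, left, right)
      r2 <- revcomp(r2)
      r1 <- add_substitutions(r1, spec$error_rate)
      r2 <- add_substitutions(r2, spec$error_rate)
      names(r1) <- sprintf("read%06d/1", seq_len(n_frag))
      names(r2) <- sprintf("read%06d/2", seq_len(n_frag))
      list(r1 = r1, r2 = r2)
    }
  })
}
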