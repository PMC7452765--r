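# Shared test helpers: independent oracles and cached fixtures.

BASES <- c("A", "C", "G", "T")

random_kmers <- function(n, k) {
  m <- matrix(sample(BASES, n * k, replace = TRUE), ncol = k)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# independent canonicalization: lexicographic min of k-mer and revcomp
oracle_canonical <- function(kmers) {
  rc <- oracle_revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# independent windowed canonical k-mer listing (keeps non-ACGT handling)
oracle_canonical_windows <- function(seq, k) {
  n <- nchar(seq) - k + 1
  if (n < 1) return(data.frame(pos = integer(0), kmer = character(0)))
  w <- substring(toupper(seq), 1:n, k:(n + k - 1))
  ok <- grepl("^[ACGT]+$", w)
  data.frame(pos = which(ok) - 1L, kmer = oracle_canonical(w[ok]),
             stringsAsFactors = FALSE)
}

# brute-force reimplementation of the one-to-one greedy reciprocal-overlap
# matcher, written with plain loops
oracle_classify <- function(pred, truth, min_frac = 0.95) {
  cand <- NULL
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(nrow(truth))) {
      if (pred$transcript_id[i] != truth$transcript_id[j]) next
      ov <- min(pred$end[i], truth$end[j]) - max(pred$start[i], truth$start[j])
      if (ov <= 0) next
      f <- min(ov / (pred$end[i] - pred$start[i]),
               ov / (truth$end[j] - truth$start[j]))
      if (f >= min_frac)
        cand <- rbind(cand, data.frame(i = i, j = j, f = f,
                                       ts = truth$start[j],
                                       ps = pred$start[i]))
    }
  }
  tp <- 0L
  if (!is.null(cand)) {
    cand <- cand[order(-cand$f, cand$ts, cand$ps), , drop = FALSE]
    pu <- logical(nrow(pred)); tu <- logical(nrow(truth))
    for (r in seq_len(nrow(cand))) {
      if (!pu[cand$i[r]] && !tu[cand$j[r]]) {
        pu[cand$i[r]] <- TRUE; tu[cand$j[r]] <- TRUE; tp <- tp + 1L
      }
    }
  }
  list(tp = tp, fp = nrow(pred) - tp, fn = nrow(truth) - tp)
}

# the default study fixture (20 genes, seed 42) and its 30x error-free
# reads are shared by several expensive tests; build them once
.cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.cache$fix)) .cache$fix <- simulate_genome(genome_spec())
  .cache$fix
}

default_reads30 <- function() {
  if (is.null(.cache$reads30))
    .cache$reads30 <- simulate_reads(default_fixture(),
                                     read_spec(coverage = 30, seed = 1))
  .cache$reads30
}

# exact-backend solid set for the default fixture at k = 25
default_exact_solid <- function() {
  if (is.null(.cache$solid)) {
    params <- baiting_params(k = 25, levels = 2, memory_bits = 1e6)
    tf <- build_transcriptome_filter(default_fixture()$transcripts, params)
    .cache$solid <- build_baited_solid_filter(default_reads30(), tf, params,
                                              backend = "exact")$filter
  }
  .cache$solid
}

# a synthetic splice_graph with randomized topology for round-trip tests
random_graph <- function(n_tr = 3, max_exons = 4) {
  pool_n <- sample(2:6, 1)
  pool <- random_kmers(pool_n, sample(8:30, 1))
  node_ids <- character(0); node_seqs <- character(0)
  seq2id <- list()
  coords <- NULL; links <- NULL; paths <- list(); tlen <- integer(0)
  for (t in seq_len(n_tr)) {
    tid <- sprintf("t%02d", t)
    picks <- sample(pool, sample(1:max_exons, 1), replace = TRUE)
    ids <- character(length(picks))
    start <- 0L; st <- integer(0); en <- integer(0)
    for (i in seq_along(picks)) {
      s <- picks[i]
      if (is.null(seq2id[[s]])) {
        id <- sprintf("EXON%08d", length(node_ids) + 1L)
        seq2id[[s]] <- id
        node_ids <- c(node_ids, id); node_seqs <- c(node_seqs, s)
      }
      ids[i] <- seq2id[[s]]
      if (i > 1) start <- en[i - 1] - sample(-5:5, 1)  # overlap/abut/gap
      start <- max(start, if (i > 1) st[i - 1] + 1L else 0L)
      st <- c(st, start); en <- c(en, start + nchar(s))
    }
    coords <- rbind(coords, data.frame(exon_id = ids, transcript_id = tid,
                                       start = st, end = en,
                                       stringsAsFactors = FALSE))
    if (length(ids) > 1)
      links <- rbind(links, data.frame(from = ids[-length(ids)], to = ids[-1],
                                       sep = en[-length(en)] - st[-1],
                                       stringsAsFactors = FALSE))
    paths[[tid]] <- ids
    tlen[tid] <- max(en) + sample(0:10, 1)
  }
  links <- if (is.null(links))
    data.frame(from = character(0), to = character(0), sep = integer(0))
  else unique(links)
  rownames(links) <- NULL
  rownames(coords) <- NULL
  structure(list(
    nodes = data.frame(exon_id = node_ids, seq = node_seqs,
                       stringsAsFactors = FALSE),
    coords = coords, links = links, paths = paths,
    transcript_len = tlen, dropped = character(0)),
    class = "splice_graph")
}

write_gff3_text <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}
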