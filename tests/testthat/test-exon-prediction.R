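test_that("positive_kmer_mask reflects solidity and junction gaps", {
  # all windows solid
  ex <- exact_kmer_set(k = 5, levels = 1)
  insert_sequences(ex, "ACGTACGTAC")
  expect_true(all(positive_kmer_mask("ACGTACGTAC", ex)))
  # no window solid
  expect_false(any(positive_kmer_mask(strrep("T", 10),
                                      exact_kmer_set(k = 5, levels = 1))))
  # junction-spanning windows are exactly the k-1 false positions
  set.seed(41)
  k <- 11
  exon1 <- paste(sample(BASES, 60, replace = TRUE), collapse = "")
  exon2 <- paste(sample(BASES, 60, replace = TRUE), collapse = "")
  solid <- unique(c(canonical_kmers(exon1, k)$kmer,
                    canonical_kmers(exon2, k)$kmer))
  tr <- paste0(exon1, exon2)
  mask <- positive_kmer_mask(tr, solid, k)
  junction <- (60 - k + 2):60   # 1-based mask indices spanning the boundary
  expect_false(any(mask[junction]))
  expect_true(all(mask[-junction]))
  expect_warning(positive_kmer_mask("ACGT", ex), "shorter than k")
})

test_that("mask runs merge into intervals with k-1 overlap arithmetic", {
  expect_equal(mask_to_intervals(rep(TRUE, 6), 5),
               data.frame(start = 0L, end = 10L))
  expect_equal(mask_to_intervals(c(TRUE, TRUE, FALSE, FALSE, TRUE), 5),
               data.frame(start = c(0L, 4L), end = c(6L, 9L)))
  expect_equal(nrow(mask_to_intervals(logical(0), 5)), 0L)
  expect_equal(nrow(mask_to_intervals(rep(FALSE, 8), 5)), 0L)
})

test_that("interval union equals the union of solid windows (coverage)", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    mask <- runif(sample(10:60, 1)) < 0.6
    iv <- mask_to_intervals(mask, k)
    covered <- integer(0)
    for (i in seq_len(nrow(iv)))
      covered <- union(covered, seq(iv$start[i], iv$end[i] - 1))
    brute <- if (any(mask)) {
      unique(unlist(lapply(which(mask) - 1L, function(p) p:(p + k - 1))))
    } else integer(0)
    expect_setequal(covered, brute)
  }
})

test_that("the length filter keeps exactly intervals >= k + q", {
  iv <- data.frame(start = c(0L, 100L), end = c(29L, 130L))
  kept <- filter_short_exons(iv, k = 25, q = 5)
  expect_equal(kept$start, 100L)          # 29 bp dropped, 30 bp kept
  expect_equal(nrow(filter_short_exons(iv, k = 25, q = 0)), 2L)
  expect_equal(nrow(filter_short_exons(iv[0, ], 25, 5)), 0L)
})

test_that("relaxed merging unions only excessive overlaps", {
  iv <- data.frame(start = c(0L, 38L), end = c(50L, 100L))   # overlap 12
  expect_equal(merge_close_intervals(iv, 10),
               data.frame(start = 0L, end = 100L))
  iv2 <- data.frame(start = c(0L, 45L), end = c(50L, 100L))  # overlap 5
  expect_equal(merge_close_intervals(iv2, 10), iv2)
  iv3 <- data.frame(start = c(0L, 40L), end = c(50L, 100L))  # overlap == 10
  expect_equal(merge_close_intervals(iv3, 10), iv3)          # strict rule
  disjoint <- data.frame(start = c(0L, 60L), end = c(50L, 90L))
  expect_equal(merge_close_intervals(disjoint, 10), disjoint)
  # cascaded merging reaches a fixpoint
  chain <- data.frame(start = c(0L, 30L, 60L), end = c(45L, 75L, 100L))
  expect_equal(merge_close_intervals(chain, 10),
               data.frame(start = 0L, end = 100L))
})

test_that("polishing trims at the leftmost AG-GT and only there", {
  tr <- paste0(strrep("A", 12), "CCAGGTAA", strrep("C", 10))
  up <- data.frame(start = 0L, end = 20L)
  dn <- data.frame(start = 12L, end = 30L)
  res <- polish_pair(up, dn, tr)
  expect_equal(res$upstream$end, 16L)
  expect_equal(res$downstream$start, 16L)
  expect_equal(substr(tr, 15, 16), "AG")
  expect_equal(substr(tr, 17, 18), "GT")
  # motif at offset 0: boundary sits 2 past the downstream start
  tr0 <- paste0(strrep("C", 12), "AGGTTTTT", strrep("C", 10))
  res0 <- polish_pair(up, dn, tr0)
  expect_equal(res0$downstream$start, 14L)
  # no motif: unchanged
  trx <- paste0(strrep("A", 30))
  resx <- polish_pair(up, dn, trx)
  expect_equal(resx$upstream, up)
  expect_equal(resx$downstream, dn)
  gap_up <- data.frame(start = 0L, end = 10L)
  gap_dn <- data.frame(start = 15L, end = 30L)
  expect_error(polish_pair(gap_up, gap_dn, tr), "overlap")
})

test_that("splice graph collapses shared exons and records paths", {
  set.seed(43)
  exA <- paste(sample(BASES, 80, replace = TRUE), collapse = "")
  exB <- paste(sample(BASES, 90, replace = TRUE), collapse = "")
  exC <- paste(sample(BASES, 70, replace = TRUE), collapse = "")
  k <- 11
  # solid set contains only within-exon k-mers: junctions stay dark
  solid <- unique(c(canonical_kmers(exA, k)$kmer, canonical_kmers(exB, k)$kmer,
                    canonical_kmers(exC, k)$kmer))
  trs <- c(iso1 = paste0(exA, exB), iso2 = paste0(exA, exC))
  g <- build_splice_graph(trs, solid, prediction_params(k = k, q = 5))
  expect_equal(nrow(g$nodes), 3L)             # exA shared, single node
  expect_equal(length(g$paths), 2L)
  expect_equal(g$paths$iso1[1], g$paths$iso2[1])
  expect_equal(g$nodes$exon_id, sprintf("EXON%08d", 1:3))
  # one gene: the graph is a single connected component
  edges <- unique(rbind(as.matrix(g$links[, 1:2])))
  comp <- unique(c(edges))
  expect_setequal(comp, g$nodes$exon_id)
  # coordinates index the transcript sequence exactly
  for (r in seq_len(nrow(g$coords))) {
    with(g$coords[r, ], {
      seq <- g$nodes$seq[g$nodes$exon_id == exon_id]
      expect_equal(substr(trs[[transcript_id]], start + 1, end), seq)
    })
  }
})

test_that("single-exon transcripts give one node, no links", {
  set.seed(44)
  tr <- paste(sample(BASES, 120, replace = TRUE), collapse = "")
  solid <- canonical_kmers(tr, 15)$kmer
  g <- build_splice_graph(c(t1 = tr), solid, prediction_params(k = 15))
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(nrow(g$links), 0L)
  expect_equal(g$paths$t1, "EXON00000001")
  expect_equal(g$nodes$seq, tr)
})

test_that("transcripts shorter than k are dropped with a warning", {
  solid <- exact_kmer_set(k = 25)
  expect_warning(
    g <- build_splice_graph(c(tiny = "ACGT", ok = strrep("ACGTG", 20)),
                            solid, prediction_params(k = 25)),
    "shorter than k")
  expect_equal(g$dropped, c("tiny", "ok"))  # 'ok' has no solid k-mers either
})

test_that("error-free exact-backend prediction recovers truth exactly", {
  fix <- default_fixture()
  g <- build_splice_graph(fix$transcripts, default_exact_solid(),
                          prediction_params(k = 25, q = 5))
  pred <- predicted_intervals(g)
  truth <- fix$truth[, c("transcript_id", "start", "end")]
  pred <- pred[order(pred$transcript_id, pred$start), ]
  truth <- truth[order(truth$transcript_id, truth$start), ]
  rownames(pred) <- rownames(truth) <- NULL
  expect_equal(pred, truth)
})

test_that("exon counts respond monotonically to q", {
  fix <- default_fixture()
  solid <- default_exact_solid()
  counts <- vapply(c(0L, 5L, 60L, 150L), function(q) {
    g <- build_splice_graph(fix$transcripts, solid,
                            prediction_params(k = 25, q = q))
    nrow(g$coords)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("raising the merge threshold never merges more exons", {
  # a mask with several short false gaps produces overlapping draft exons
  set.seed(45)
  solid <- exact_kmer_set(k = 7, levels = 1)
  tr <- paste(sample(BASES, 400, replace = TRUE), collapse = "")
  insert_sequences(solid, tr)
  masked <- positive_kmer_mask(tr, solid)
  masked[sample(length(masked), 60)] <- FALSE   # punch random holes
  counts <- vapply(c(0L, 3L, 10L, 50L), function(mo) {
    nrow(merge_close_intervals(mask_to_intervals(masked, 7), mo))
  }, numeric(1))
  # larger thresholds merge fewer pairs, so counts never decrease
  expect_true(all(diff(counts) >= 0))
})
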