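test_that("canonical k-mer extraction handles palindromes, revcomp and Ns", {
  expect_equal(canonical_kmers("ACGT", 4),
               data.frame(pos = 0L, kmer = "ACGT"))
  expect_equal(canonical_kmers("TTTT", 4),
               data.frame(pos = 0L, kmer = "AAAA"))
  # windows 0-2 contain the N and are omitted; positions are preserved
  expect_equal(canonical_kmers("ACNGTA", 3),
               data.frame(pos = 3L, kmer = "GTA"))
  expect_equal(nrow(canonical_kmers("ACG", 4)), 0L)   # k > len: empty
  expect_equal(canonical_kmers("acgttt", 3)$kmer,
               canonical_kmers("ACGTTT", 3)$kmer)     # case-insensitive
})

test_that("canonical extraction agrees with an independent implementation", {
  set.seed(11)
  for (k in c(3, 7, 25)) {
    seq <- paste(sample(c(BASES, "N"), 300, replace = TRUE,
                        prob = c(rep(0.24, 4), 0.04)), collapse = "")
    expect_equal(canonical_kmers(seq, k), oracle_canonical_windows(seq, k))
  }
})

test_that("inserted k-mers always query positive (no false negatives)", {
  set.seed(1)
  kmers <- random_kmers(1e4, 25)
  f <- kmer_filter(k = 25, m = 2^18, h = 4)
  bf_insert(f, kmers)
  expect_true(all(bf_contains(f, kmers)))
  expect_equal(n_inserted(f), 1e4)
})

test_that("empty and saturated filters answer as expected", {
  f <- kmer_filter(k = 5, m = 2^16, h = 4)
  expect_false(any(bf_contains(f, random_kmers(100, 5))))
  expect_equal(bf_fpr(f), 0)
  sat <- exograph:::cpp_bf_from_bits(5L, 1024, 4L, 0,
                                     as.raw(rep(0xFF, 128)))
  sat <- structure(list(ptr = sat, k = 5L, m = 1024, h = 4L),
                   class = "kmer_filter")
  expect_true(all(bf_contains(sat, random_kmers(100, 5))))
})

test_that("wrong-length k-mers are contract violations", {
  f <- kmer_filter(k = 5, m = 1024)
  expect_error(bf_insert(f, "AAAA"), "length")
  expect_error(bf_contains(f, "AAAAAA"), "length")
  c2 <- cascading_kmer_filter(k = 5, m_per_level = 1024)
  expect_error(cbf_insert(c2, "AAAA"), "length")
  expect_error(cbf_solid(c2, "AAAAAA"), "length")
})

test_that("analytic FPR matches the closed form and its limits", {
  f <- kmer_filter(k = 5, m = 64, h = 4)
  bf_insert(f, "AAAAA")
  expect_equal(bf_fpr(f), (1 - exp(-1 / 16))^4, tolerance = 1e-12)
  big <- kmer_filter(k = 5, m = 1e9, h = 4)
  bf_insert(big, "AAAAA")
  expect_lt(bf_fpr(big), 1e-30)   # m -> infinity at fixed n
})

test_that("empirical FPR tracks the analytic estimate at low occupancy", {
  set.seed(2)
  f <- kmer_filter(k = 25, m = 320000, h = 4)
  inserted <- random_kmers(2e4, 25)
  bf_insert(f, inserted)
  # occupancy stays at ~22% of bits, below the 25% regime of interest
  occupancy <- mean(as.integer(rawToBits(exograph:::cpp_bf_bits(f$ptr))))
  expect_lt(occupancy, 0.25)
  probes <- setdiff(oracle_canonical(random_kmers(1.1e5, 25)),
                    oracle_canonical(inserted))[1:1e5]
  emp <- mean(bf_contains(f, probes))
  expect_gt(emp, bf_fpr(f) / 2)
  expect_lt(emp, bf_fpr(f) * 2)
})

test_that("cascade insert rule advances k-mers one level per occurrence", {
  c2 <- cascading_kmer_filter(k = 5, m_per_level = 2^16, levels = 2)
  cbf_insert(c2, "ACGTA")
  expect_true(cbf_contains_level(c2, "ACGTA", 1))
  expect_false(cbf_contains_level(c2, "ACGTA", 2))
  expect_false(cbf_solid(c2, "ACGTA"))        # single occurrence: not solid
  cbf_insert(c2, "ACGTA")
  expect_true(cbf_contains_level(c2, "ACGTA", 2))
  expect_true(cbf_solid(c2, "ACGTA"))         # second occurrence: solid
  cbf_insert(c2, "ACGTA")                     # all levels full: no change
  expect_equal(n_inserted(c2), c(1, 1))
  expect_false(cbf_solid(c2, "TTTTT"))        # fresh k-mer
})

test_that("a one-level cascade degenerates to a plain Bloom filter", {
  c1 <- cascading_kmer_filter(k = 5, m_per_level = 2^16, levels = 1)
  f <- kmer_filter(k = 5, m = 2^16)
  km <- random_kmers(500, 5)
  cbf_insert(c1, km); bf_insert(f, km)
  probes <- random_kmers(500, 5)
  expect_equal(cbf_solid(c1, probes), bf_contains(f, probes))
})

test_that("presence at level i implies presence at all lower levels", {
  set.seed(3)
  c3 <- cascading_kmer_filter(k = 11, m_per_level = 2^16, levels = 3)
  km <- sample(random_kmers(300, 11), 2000, replace = TRUE)
  cbf_insert(c3, km)
  probes <- unique(km)
  for (lvl in 3:2) {
    hi <- cbf_contains_level(c3, probes, lvl)
    lo <- cbf_contains_level(c3, probes, lvl - 1)
    expect_true(all(lo[hi]))
  }
})

test_that("exact backend solidity equals brute-force count >= L", {
  set.seed(4)
  for (L in c(2, 3)) {
    km <- sample(oracle_canonical(random_kmers(200, 9)), 1500, replace = TRUE)
    ex <- exact_kmer_set(k = 9, levels = L)
    cbf_insert(ex, km)
    counts <- table(km)
    probes <- c(names(counts), oracle_canonical(random_kmers(50, 9)))
    expect_equal(cbf_solid(ex, probes),
                 as.vector(ifelse(is.na(counts[probes]), 0,
                                  counts[probes]) >= L))
    expect_equal(kmer_counts(ex, names(counts)),
                 unname(as.integer(counts)))
  }
})

test_that("Bloom and exact backends agree on every inserted k-mer", {
  set.seed(5)
  km <- sample(oracle_canonical(random_kmers(400, 15)), 3000, replace = TRUE)
  cb <- cascading_kmer_filter(k = 15, m_per_level = 2^18, levels = 2)
  ex <- exact_kmer_set(k = 15, levels = 2)
  cbf_insert(cb, km); cbf_insert(ex, km)
  probes <- unique(km)
  exact <- cbf_solid(ex, probes)
  bloom <- cbf_solid(cb, probes)
  expect_true(all(bloom[exact]))  # no false negatives propagate
  # disagreements are only Bloom false positives, at roughly the FPR
  expect_lt(mean(bloom & !exact), 0.01)
})

test_that("filter files round-trip byte-identically", {
  set.seed(6)
  cb <- cascading_kmer_filter(k = 21, m_per_level = 4096, levels = 2)
  insert_sequences(cb, random_kmers(50, 60))
  p1 <- tempfile(); p2 <- tempfile()
  write_kmer_filter(cb, p1)
  cb2 <- read_kmer_filter(p1)
  probes <- random_kmers(2000, 21)
  expect_equal(cbf_solid(cb2, probes), cbf_solid(cb, probes))
  expect_equal(n_inserted(cb2), n_inserted(cb))
  write_kmer_filter(cb2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_error(suppressWarnings(read_kmer_filter(tempfile())))
})
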