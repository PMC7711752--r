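# MinHash and HyperLogLog sketches and their distance estimators.

test_that("minhash sketches are deterministic and exact when unsaturated", {
  s <- random_dna(500, seed = 21)
  a <- minhash_sketch(s, k = 10, s = 1000, hash_seed = 42)
  b <- minhash_sketch(s, k = 10, s = 1000, hash_seed = 42)
  expect_identical(a$hashes, b$hashes)
  expect_true(all(diff(a$hashes) > 0))
  # genome with 3 distinct k-mers: sketch holds exactly those 3 hashes
  tiny <- minhash_sketch("AAAAAC", k = 5, s = 1000)
  expect_equal(length(tiny$hashes), length(kmer_set("AAAAAC", 5)))
  # different seed, different sketch
  c2 <- minhash_sketch(s, k = 10, s = 1000, hash_seed = 7)
  expect_false(identical(a$hashes, c2$hashes))
  expect_error(minhash_sketch(s, k = 10, s = 0), "s must")
})

test_that("sketch_jaccard has the trivial fixed points and guards", {
  s <- random_dna(3000, seed = 22)
  a <- minhash_sketch(s, k = 12, s = 500)
  expect_equal(sketch_jaccard(a, a), 1.0)
  b <- minhash_sketch(random_dna(3000, seed = 23), k = 12, s = 500)
  expect_equal(sketch_jaccard(a, b), sketch_jaccard(b, a))
  # unrelated genomes share essentially nothing
  expect_lt(sketch_jaccard(a, b), 0.01)
  wrong <- minhash_sketch(s, k = 12, s = 400)
  expect_error(sketch_jaccard(a, wrong), "incompatible")
})

test_that("sketch_jaccard tracks exact_jaccard within binomial noise", {
  ok <- 0L; n_case <- 10L
  for (i in seq_len(n_case)) {
    g <- random_dna(20000, seed = 30 + i)
    m <- mutate_genome(g, p_sub = 0.002 * i, seed = 60 + i)
    ka <- kmer_set(g, 16); kb <- kmer_set(m, 16)
    j <- exact_jaccard(ka, kb)
    jh <- sketch_jaccard(minhash_sketch(ka, s = 2000),
                         minhash_sketch(kb, s = 2000))
    if (abs(jh - j) <= 3 * sqrt(j * (1 - j) / 2000) + 1e-12) ok <- ok + 1L
  }
  expect_gte(ok, n_case - 1L)
})

test_that("mash distance transform matches its closed form", {
  expect_equal(mash_distance(1, 16), 0)
  expect_equal(mash_distance(1, 21), 0)
  expect_equal(mash_distance(0, 16), 1)          # capped, not infinite
  expect_equal(mash_distance(0.5, 16), -(1 / 16) * log(2 / 3))
  expect_equal(mash_distance(0.5, 16), 0.025342, tolerance = 1e-4)
  expect_error(mash_distance(1.2, 16), "\\[0, 1\\]")
  expect_error(mash_distance(-0.1, 16), "\\[0, 1\\]")
  # strictly decreasing in j
  j <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(mash_distance(j, 16)) < 0))
})

test_that("mash distance recovers the substitution rate of a mutated genome", {
  g <- random_dna(200000, seed = 77)
  for (p in c(0.005, 0.02)) {
    m <- mutate_genome(g, p_sub = p, seed = round(1000 * p))
    d <- mash_distance(exact_jaccard(kmer_set(g, 16), kmer_set(m, 16)), 16)
    expect_gt(d, 0.8 * p)
    expect_lt(d, 1.2 * p)
  }
})

test_that("hll registers are bounded and deterministic; cardinality tracks truth", {
  ks <- kmer_set(random_dna(30000, seed = 41), 16)
  h <- hll_sketch(ks, p = 10)
  expect_length(h$registers, 1024L)
  expect_true(all(h$registers >= 0 & h$registers <= 64 - 10 + 1))
  expect_identical(h$registers, hll_sketch(ks, p = 10)$registers)
  est <- hll_cardinality(h)
  expect_lt(abs(est - length(ks)) / length(ks), 3 * 1.04 / sqrt(1024))
  # empty input
  h0 <- hll_sketch(character(), k = 16, p = 8)
  expect_true(all(h0$registers == 0L))
  expect_equal(hll_cardinality(h0), 0)
  expect_error(hll_sketch(ks, p = 3), "p must")
  expect_error(hll_sketch(ks, p = 25), "p must")
})

test_that("hll similarity: identity is exact, disjoint sets are near zero", {
  a <- hll_sketch(random_dna(30000, seed = 43), k = 16, p = 12)
  expect_equal(hll_similarity(a, a), 1.0)
  b <- hll_sketch(random_dna(30000, seed = 44), k = 16, p = 12)
  expect_equal(hll_similarity(a, b), hll_similarity(b, a))
  expect_lt(hll_similarity(a, b), 0.05)
  expect_error(hll_similarity(a, hll_sketch("ACGTACGTAC", k = 8, p = 12)),
               "incompatible")
})

test_that("hll similarity approximates the exact Jaccard index", {
  g <- random_dna(50000, seed = 45)
  m <- mutate_genome(g, p_sub = 0.01, seed = 46)
  j <- exact_jaccard(kmer_set(g, 16), kmer_set(m, 16))
  jh <- hll_similarity(hll_sketch(g, 16, p = 14), hll_sketch(m, 16, p = 14))
  expect_lt(abs(jh - j), 5 * 1.04 / sqrt(2^14) * 10) # generous guard band
  expect_lt(abs(jh - j), 0.05)
})

test_that("rank order of mash distances is concordant with exact Jaccard", {
  g <- random_dna(30000, seed = 47)
  pairs <- lapply(seq(0.002, 0.04, length.out = 12), function(p)
    mutate_genome(g, p, seed = round(10000 * p)))
  kg <- kmer_set(g, 16)
  ex <- vapply(pairs, function(m) exact_jaccard(kg, kmer_set(m, 16)), numeric(1))
  sk <- vapply(pairs, function(m)
    mash_distance(sketch_jaccard(minhash_sketch(kg, s = 5000),
                                 minhash_sketch(m, k = 16, s = 5000)), 16),
    numeric(1))
  expect_lt(cor(ex, sk, method = "spearman"), -0.99)
})

test_that("sketches survive a JSON round trip exactly", {
  dir <- withr::local_tempdir()
  mh <- minhash_sketch(random_dna(2000, seed = 48), k = 14, s = 200, hash_seed = 5)
  f1 <- file.path(dir, "mh.json")
  write_sketch(mh, f1)
  mh2 <- read_sketch(f1)
  expect_identical(mh2$hashes, mh$hashes)
  expect_identical(mh2[c("k", "s", "hash_seed")], mh[c("k", "s", "hash_seed")])
  expect_equal(sketch_jaccard(mh, mh2), 1.0)
  hl <- hll_sketch(random_dna(2000, seed = 49), k = 14, p = 8, hash_seed = 5)
  f2 <- file.path(dir, "hll.json")
  write_sketch(hl, f2)
  hl2 <- read_sketch(f2)
  expect_identical(hl2$registers, hl$registers)
  expect_equal(hll_similarity(hl, hl2), 1.0)
})
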