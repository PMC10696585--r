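test_that("spectrum distances match hand computations", {
  a <- kmerSpectrum(c(AAAAA = 2L, AAACA = 1L), "a")
  b <- kmerSpectrum(c(AAAAA = 1L, AAAGA = 3L), "b")
  # 1 - 2*min_shared / (3 + 4) with one shared k-mer of min count 1
  expect_equal(brayCurtis(a, b), 1 - 2 / 7)
  # shared 1 of union 3
  expect_equal(jaccardPA(a, b), 2 / 3)
  expect_equal(brayCurtis(a, a), 0)
  expect_equal(jaccardPA(a, a), 0)
  disj <- kmerSpectrum(c(CCCCC = 9L), "c")
  expect_equal(brayCurtis(a, disj), 1)
  expect_equal(jaccardPA(a, disj), 1)
  # counts are irrelevant for presence/absence
  b2 <- kmerSpectrum(c(AAAAA = 2L, AAAGA = 6L), "b2")
  expect_equal(jaccardPA(a, b2), jaccardPA(a, b))
  wrongK <- kmerSpectrum(c(AAA = 1L), "w")
  expect_error(brayCurtis(a, wrongK), "lengths differ")
  expect_error(jaccardPA(a, wrongK), "lengths differ")
})

test_that("profile distances match hand computations", {
  p <- profileFromVector(c(t1 = 0.6, t2 = 0.4))
  q <- profileFromVector(c(t1 = 0.2, t2 = 0.3, t3 = 0.5))
  expect_equal(brayCurtis(p, q), 0.5)
  expect_equal(brayCurtis(p, p), 0)
  expect_equal(jaccardPA(p, q), 1 - 2 / 3)
  r <- profileFromVector(c(x = 1))
  expect_equal(brayCurtis(p, r), 1)
  expect_equal(jaccardPA(p, r), 1)
  # 25- and 25-taxon supports sharing 15 taxa
  s1 <- profileFromVector(setNames(rep(1, 25), paste0("t", 1:25)))
  s2 <- profileFromVector(setNames(rep(1, 25), paste0("t", 11:35)))
  expect_equal(jaccardPA(s1, s2), 1 - 15 / 35)
})

test_that("profile Bray-Curtis equals half the L1 distance", {
  set.seed(5)
  for (i in 1:10) {
    taxa <- paste0("t", 1:12)
    p <- profileFromVector(setNames(rexp(12), taxa))
    q <- profileFromVector(setNames(rexp(12), taxa))
    expect_equal(brayCurtis(p, q),
                 sum(abs(abundances(p) - abundances(q)[taxa])) / 2)
  }
})

test_that("spectrum distances agree with vegan on dense count tables", {
  set.seed(11)
  a <- countKmers(randomSeq(800, 21), 6, sampleId = "a")
  b <- countKmers(randomSeq(800, 22), 6, sampleId = "b")
  all6 <- union(kmerCounts(a)$kmer, kmerCounts(b)$kmer)
  tab <- rbind(a = spectrumAsNamed(a)[all6], b = spectrumAsNamed(b)[all6])
  tab[is.na(tab)] <- 0
  expect_equal(brayCurtis(a, b),
               as.numeric(vegan::vegdist(tab, "bray")),
               tolerance = 1e-12)
  expect_equal(jaccardPA(a, b),
               as.numeric(vegan::vegdist(tab, "jaccard", binary = TRUE)),
               tolerance = 1e-12)
})

test_that("profile distances agree with vegan", {
  set.seed(13)
  taxa <- paste0("t", 1:15)
  profs <- lapply(1:4, function(i) {
    v <- rexp(15) * rbinom(15, 1, 0.7)
    v[1] <- v[1] + 0.1  # keep support non-empty
    profileFromVector(setNames(v, taxa), sprintf("p%d", i))
  })
  tab <- t(vapply(profs, abundances, numeric(15)))
  D <- pairwiseMatrix(profs, "braycurtis")
  expect_equal(unname(D[lower.tri(D)]),
               as.numeric(vegan::vegdist(tab, "bray")), tolerance = 1e-12)
  DJ <- pairwiseMatrix(profs, "jaccard-pa")
  expect_equal(unname(DJ[lower.tri(DJ)]),
               as.numeric(vegan::vegdist(tab, "jaccard", binary = TRUE)),
               tolerance = 1e-12)
})

test_that("pairwiseMatrix equals a double-loop brute force", {
  set.seed(17)
  spectra <- lapply(1:5, function(i)
    countKmers(randomSeq(400, 30 + i), 8, sampleId = sprintf("s%d", i)))
  D <- pairwiseMatrix(spectra, "braycurtis")
  n <- length(spectra)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      want <- if (i == j) 0 else brayCurtis(spectra[[i]], spectra[[j]])
      expect_equal(D[i, j], want)
    }
  }
  expect_identical(D, t(D))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(rownames(D), sprintf("s%d", 1:5))
  # two identical samples give an all-zero matrix
  twin <- countKmers(randomSeq(400, 31), 8, sampleId = "twin")
  D0 <- pairwiseMatrix(list(spectra[[1]], twin), "braycurtis")
  expect_equal(unname(D0), matrix(0, 2, 2))
})

test_that("pairwiseMatrix validates its inputs", {
  a <- kmerSpectrum(c(AAA = 1L), "a")
  b <- kmerSpectrum(c(AAAA = 1L), "b")
  expect_error(pairwiseMatrix(list(a), "braycurtis"), "at least 2")
  expect_error(pairwiseMatrix(list(a, b), "braycurtis"), "lengths differ")
  p <- profileFromVector(c(t = 1))
  expect_error(pairwiseMatrix(list(a, p), "braycurtis"), "same class")
  expect_error(pairwiseMatrix(list(a, a), "braycurtis"), "duplicate")
})

test_that("distances are symmetric, bounded and zero only at equality", {
  set.seed(23)
  for (i in 1:8) {
    a <- countKmers(randomSeq(300, 50 + i), 9, sampleId = "a")
    b <- countKmers(randomSeq(300, 70 + i), 9, sampleId = "b")
    for (f in c(brayCurtis, jaccardPA)) {
      d <- f(a, b)
      expect_equal(d, f(b, a))
      expect_gte(d, 0); expect_lte(d, 1)
      expect_gt(d, 0)  # unrelated random sequences never coincide
      expect_equal(f(a, a), 0)
    }
  }
})
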