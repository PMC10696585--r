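test_that("all_taxa pools are independent uniform sequences", {
  pool <- generateGenomePool(2, 10000, "all_taxa", seed = 1)
  seqs <- as.character(poolGenomes(pool))
  a <- strsplit(seqs[1], "")[[1]]
  b <- strsplit(seqs[2], "")[[1]]
  identity <- mean(a == b)
  # expected 25% for unrelated uniform sequences, sd ~ 0.004
  expect_gt(identity, 0.22)
  expect_lt(identity, 0.28)
  expect_equal(unique(nchar(seqs)), 10000)
})

test_that("ancestor-derived pools match the binomial divergence model", {
  d <- 0.05
  pool <- generateGenomePool(3, 10000, "same_family",
                             perSiteDivergence = d, seed = 7)
  seqs <- lapply(as.character(poolGenomes(pool)), \(s) strsplit(s, "")[[1]])
  # two independently mutated copies differ at a site with probability
  # 2 d (1 - d) + d^2 * 2/3
  pDiff <- 2 * d * (1 - d) + d^2 * 2 / 3
  pairs <- combn(3, 2)
  obs <- apply(pairs, 2, function(ij)
    mean(seqs[[ij[1]]] != seqs[[ij[2]]]))
  expect_true(all(abs(obs - pDiff) < 0.012))
  # reduced-diversity pools share lineage labels
  expect_length(unique(poolTaxonomy(pool)$family), 1)
  expect_length(unique(poolTaxonomy(pool)$class), 1)
})

test_that("pool generation is deterministic and validates arguments", {
  p1 <- generateGenomePool(5, 1500, seed = 42)
  p2 <- generateGenomePool(5, 1500, seed = 42)
  expect_identical(as.character(poolGenomes(p1)),
                   as.character(poolGenomes(p2)))
  expect_error(generateGenomePool(1, 2000), "nGenomes")
  expect_error(generateGenomePool(3, 500), "genomeLengthBp")
  expect_error(generateGenomePool(3, 2000, perSiteDivergence = 0.5),
               "perSiteDivergence")
  expect_error(generateGenomePool(3, 2000, "nonsense"))
})

test_that("communities are log-normal draws normalized over nTaxa taxa", {
  pool <- tinyPool(8, 2000, seed = 3)
  prof <- drawCommunity(pool, 5, seed = 11)
  ab <- abundances(prof)
  expect_length(ab, 5)
  expect_true(all(ab > 0))
  expect_equal(sum(ab), 1, tolerance = 1e-12)
  expect_true(all(names(ab) %in% genomeIds(pool)))
  # exhaustive draw covers the pool
  full <- drawCommunity(pool, 8, seed = 12)
  expect_setequal(names(abundances(full)), genomeIds(pool))
  expect_error(drawCommunity(pool, 9, seed = 1), "exceeds pool size")
})

test_that("contamination spiking rescales and preserves normalization", {
  prof <- profileFromVector(c(g1 = 0.6, g2 = 0.4))
  spec <- contaminantSpec(phixContaminant(), 0.02)
  spiked <- spikeContamination(prof, spec)
  expect_equal(unname(abundances(spiked)), c(0.588, 0.392, 0.02))
  expect_equal(sum(abundances(spiked)), 1, tolerance = 1e-12)
  # zero fraction is a no-op
  expect_identical(spikeContamination(prof, contaminantSpec(
    phixContaminant(), 0)), prof)
  expect_error(contaminantSpec(phixContaminant(), 1), "fraction")
  expect_error(spikeContamination(spiked, spec), "already present")
})

test_that("zero-error reads are exact substrings of their source genome", {
  pool <- tinyPool(3, 2000, seed = 5)
  prof <- drawCommunity(pool, 2, seed = 6)
  cfg <- readSimConfig("hiseq", nPairs = 60, seed = 9, errorStart = 0,
                       errorEnd = 0)
  rs <- simulateReads(pool, prof, cfg)
  seqs <- as.character(poolGenomes(pool))
  for (i in seq_len(nPairs(rs))) {
    g <- seqs[rs@truth[i]]
    grc <- revComp(g)
    expect_true(grepl(rs@reads1[i], g, fixed = TRUE) ||
                  grepl(rs@reads1[i], grc, fixed = TRUE))
    expect_true(grepl(rs@reads2[i], g, fixed = TRUE) ||
                  grepl(rs@reads2[i], grc, fixed = TRUE))
  }
})

test_that("read counts follow the multinomial in the abundances", {
  pool <- tinyPool(2, 3000, seed = 5)
  ids <- genomeIds(pool)
  prof <- profileFromVector(setNames(c(0.9, 0.1), ids))
  rs <- simulateReads(pool, prof, readSimConfig("hiseq", nPairs = 1000,
                                                seed = 21))
  counts <- table(factor(rs@truth, levels = ids))
  # 99.9% binomial band for n = 1000, p = 0.1
  band <- qbinom(c(5e-4, 1 - 5e-4), 1000, 0.1)
  expect_gte(counts[[2]], band[1])
  expect_lte(counts[[2]], band[2])
  expect_equal(sum(counts), 1000)
  # independent multinomial draw lands in the same band
  set.seed(33)
  indep <- rmultinom(1, 1000, c(0.9, 0.1))[2, 1]
  expect_gte(indep, band[1])
  expect_lte(indep, band[2])
})

test_that("simulation is seed-deterministic and conserves read numbers", {
  pool <- tinyPool(3, 2000, seed = 2)
  prof <- drawCommunity(pool, 3, seed = 4)
  cfg <- readSimConfig("hiseq", nPairs = 80, seed = 13)
  rs1 <- simulateReads(pool, prof, cfg)
  rs2 <- simulateReads(pool, prof, cfg)
  expect_identical(rs1@reads1, rs2@reads1)
  expect_identical(rs1@reads2, rs2@reads2)
  expect_identical(rs1@truth, rs2@truth)
  rs3 <- simulateReads(pool, prof, readSimConfig("hiseq", nPairs = 80,
                                                 seed = 14))
  expect_false(identical(rs1@reads1, rs3@reads1))
  expect_equal(length(rs1@reads1) + length(rs1@reads2), 2 * 80)
  expect_equal(length(rs1@truth), 80)
})

test_that("technology presets set read length and error ramp", {
  expect_equal(readSimConfig("miseq", 10)@readLengthBp, 300)
  expect_equal(readSimConfig("hiseq", 10)@readLengthBp, 125)
  expect_equal(readSimConfig("novaseq", 10)@readLengthBp, 150)
  expect_error(readSimConfig("hiseq", 10, errorStart = 0.02,
                             errorEnd = 0.01), "errorStart")
  expect_error(readSimConfig("hiseq", 10, insertMeanBp = 100),
               "insertMeanBp")
})

test_that("taxa shorter than the insert are skipped with renormalization", {
  pool <- tinyPool(2, 2000, seed = 8)
  short <- new("Genome", genomeId = "tiny", speciesLabel = "tiny",
               familyLabel = "f", classLabel = "c",
               sequence = randomSeq(80, 1))
  prof <- profileFromVector(setNames(c(0.5, 0.3, 0.2),
                                     c(genomeIds(pool), "tiny")))
  expect_warning(
    rs <- simulateReads(pool, prof, readSimConfig("hiseq", nPairs = 40,
                                                  seed = 3),
                        contaminants = list(short)),
    "shorter than the mean insert")
  expect_false("tiny" %in% rs@truth)
  expect_equal(length(rs@truth), 40)
})

test_that("realized profiles estimate the expected profile", {
  pool <- tinyPool(4, 2000, seed = 10)
  ids <- genomeIds(pool)
  single <- profileFromVector(setNames(1, ids[1]))
  rs <- simulateReads(pool, single, readSimConfig("hiseq", nPairs = 30,
                                                  seed = 2))
  expect_equal(abundances(realizedProfile(rs)), setNames(1, ids[1]))

  prof <- drawCommunity(pool, 4, seed = 5)
  l1 <- function(n, seed) {
    rp <- realizedProfile(simulateReads(pool, prof,
                                        readSimConfig("hiseq", nPairs = n,
                                                      seed = seed)))
    sum(abs(abundances(prof) -
              abundances(rp)[names(abundances(prof))]))
  }
  # L1 error shrinks roughly as n^-1/2; compare two depths over replicates
  shallow <- mean(vapply(1:4, \(s) l1(100, s), 0))
  deep <- mean(vapply(1:4, \(s) l1(10000, 10 + s), 0))
  expect_lt(deep, shallow)
})

test_that("contaminant reads propagate into the realized profile", {
  pool <- tinyPool(3, 2000, seed = 12)
  prof <- drawCommunity(pool, 3, seed = 13)
  phix <- phixContaminant()
  spiked <- spikeContamination(prof, contaminantSpec(phix, 0.2))
  rs <- simulateReads(pool, spiked, readSimConfig("hiseq", nPairs = 400,
                                                  seed = 14),
                      contaminants = list(phix))
  expect_true("phix_like" %in% names(abundances(realizedProfile(rs))))
})

test_that("zero-error read k-mers are a subset of pool genome k-mers", {
  pool <- tinyPool(3, 2000, seed = 15)
  prof <- drawCommunity(pool, 3, seed = 16)
  rs <- simulateReads(pool, prof, readSimConfig("hiseq", nPairs = 50,
                                                seed = 17, errorStart = 0,
                                                errorEnd = 0))
  rk <- countKmers(rs, 21)
  gk <- countKmers(as.character(poolGenomes(pool)), 21)
  st <- kmerBeta:::cpp_pair_stats(rk@keys, rk@counts, gk@keys, gk@counts)
  expect_equal(st[["n_shared"]], nDistinctKmers(rk))
})

test_that("FASTQ and truth files round-trip with stable content", {
  pool <- tinyPool(2, 2000, seed = 18)
  prof <- drawCommunity(pool, 2, seed = 19)
  rs <- simulateReads(pool, prof, readSimConfig("hiseq", nPairs = 25,
                                                seed = 20))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- writeReadSet(rs, d1)
  p2 <- writeReadSet(rs, d2)
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  l1 <- readLines(p1[1])
  expect_length(l1, 4 * 25)
  expect_match(l1[1], "^@s")
  expect_identical(l1[seq(2, 100, by = 4)], rs@reads1)
  truth <- read.delim(p1[3])
  expect_equal(truth$genome_id, rs@truth)
  # FASTQ re-read through the file-based counter matches in-memory counts
  spFile <- countKmersFromFiles(p1[1:2], k = 15, sampleId = "f")
  spMem <- countKmers(rs, 15)
  expect_identical(spFile@keys, spMem@keys)
  expect_identical(spFile@counts, spMem@counts)
})
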