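# small shared fixtures and independent oracles

randomSeq <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revComp <- function(s)
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = ""),
    "", USE.NAMES = FALSE)

# brute-force k-mer counter: substring enumeration, independent of the
# packed rolling implementation
naiveCountKmers <- function(seqs, k, canonical = TRUE) {
  words <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  }))
  words <- words[!grepl("[^ACGT]", words)]
  if (canonical) words <- pmin(words, revComp(words))
  tab <- table(words)
  setNames(as.integer(tab), names(tab))
}

spectrumAsNamed <- function(sp) {
  df <- kmerCounts(sp)
  setNames(df$count, df$kmer)
}

tinyPool <- function(n = 4, len = 2000, seed = 1, mode = "all_taxa",
                     divergence = NULL)
  generateGenomePool(n, len, mode, perSiteDivergence = divergence,
                     seed = seed)

tinyProfiles <- function(pool, nSamples, nTaxa, seed0 = 100)
  lapply(seq_len(nSamples), function(i)
    drawCommunity(pool, nTaxa, seed = seed0 + i,
                  sampleId = sprintf("s%02d", i)))

profileFromVector <- function(ab, sampleId = "p")
  new("CommunityProfile", sampleId = sampleId, abundances = ab / sum(ab))

# labeled symmetric matrix from an upper-triangle spec
distMat <- function(labels, upper) {
  n <- length(labels)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  D[upper.tri(D)] <- upper
  D + t(D)
}

# random distinct k-mer strings (rejection on duplicates and on
# canonical collisions, so presence/absence sets have exact sizes)
randomKmers <- function(n, k, seed) {
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    w <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
               collapse = "")
    w <- min(w, revComp(w))
    if (!w %in% out) out <- c(out, w)
  }
  out
}
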