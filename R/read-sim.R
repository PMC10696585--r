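#' @importFrom stats rmultinom setNames
NULL

.TECH_PRESETS <- list(
  miseq   = list(readLengthBp = 300, errorStart = 0.001,  errorEnd = 0.010,
                 insertMeanBp = 800, insertSdBp = 60),
  hiseq   = list(readLengthBp = 125, errorStart = 0.001,  errorEnd = 0.005,
                 insertMeanBp = 350, insertSdBp = 30),
  novaseq = list(readLengthBp = 150, errorStart = 0.0005, errorEnd = 0.003,
                 insertMeanBp = 400, insertSdBp = 30))

#' Build a read-simulation configuration
#'
#' Platform presets (substitution-only error model, linear ramp over the
#' read): miseq 2x300 bp 0.1%->1%; hiseq 2x125 bp 0.1%->0.5%; novaseq
#' 2x150 bp 0.05%->0.3%. Any preset field can be overridden.
#'
#' @param technology `"miseq"`, `"hiseq"` or `"novaseq"`.
#' @param nPairs number of read pairs to simulate.
#' @param seed integer seed (simulation is byte-reproducible).
#' @param readLengthBp,insertMeanBp,insertSdBp,errorStart,errorEnd overrides
#'   of the preset values.
#' @return a [ReadSimConfig-class].
#' @export
readSimConfig <- function(technology = c("hiseq", "miseq", "novaseq"),
                          nPairs, seed = 1, readLengthBp = NULL,
                          insertMeanBp = NULL, insertSdBp = NULL,
                          errorStart = NULL, errorEnd = NULL) {
  technology <- match.arg(technology)
  p <- .TECH_PRESETS[[technology]]
  new("ReadSimConfig", technology = technology,
      readLengthBp = readLengthBp %||% p$readLengthBp,
      nPairs = as.numeric(nPairs),
      insertMeanBp = insertMeanBp %||% p$insertMeanBp,
      insertSdBp = insertSdBp %||% p$insertSdBp,
      errorStart = errorStart %||% p$errorStart,
      errorEnd = errorEnd %||% p$errorEnd,
      seed = as.numeric(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.phredString <- function(readLen, e0, e1) {
  p <- if (readLen == 1) e0 else e0 + (e1 - e0) * (seq_len(readLen) - 1) /
    (readLen - 1)
  q <- ifelse(p <= 0, 41L, pmin(41L, pmax(2L, as.integer(round(-10 * log10(p))))))
  intToUtf8(q + 33L)
}

#' Simulate paired-end reads from a community profile
#'
#' Per-taxon pair counts are multinomial in the relative abundances (an
#' abundance is a read proportion). Fragments start uniformly on the linear
#' source genome with both strands equally likely; R2 is the reverse
#' complement end of the fragment. Each base is substituted with probability
#' interpolated linearly from `errorStart` to `errorEnd` along the read
#' (uniform over the three alternative bases). Taxa whose genome is shorter
#' than the mean insert are skipped with a warning and their mass
#' renormalized. Deterministic for a fixed `config` seed.
#'
#' @param pool a [GenomePool-class] resolving the profile's taxa.
#' @param profile a [CommunityProfile-class].
#' @param config a [ReadSimConfig-class].
#' @param contaminants optional list of [ContaminantSpec-class] or
#'   [Genome-class] objects resolving contaminant ids in the profile.
#' @return a [ReadSet-class] with both mates and the per-pair truth table.
#' @examples
#' pool <- generateGenomePool(3, 2000, seed = 1)
#' prof <- drawCommunity(pool, 2, seed = 2)
#' rs <- simulateReads(pool, prof, readSimConfig("hiseq", nPairs = 50, seed = 3))
#' nPairs(rs)
#' @export
simulateReads <- function(pool, profile, config, contaminants = list()) {
  plan <- .simPlan(pool, profile, config, contaminants)
  reads <- cpp_simulate_pairs(plan$seqs, plan$taxonIdx,
                              as.integer(config@readLengthBp),
                              config@insertMeanBp, config@insertSdBp,
                              config@errorStart, config@errorEnd,
                              config@seed)
  qual <- .phredString(config@readLengthBp, config@errorStart,
                       config@errorEnd)
  new("ReadSet", sampleId = sampleId(profile), reads1 = reads$r1,
      reads2 = reads$r2, quality1 = qual, quality2 = qual,
      readIds = sprintf("%s_%07d", sampleId(profile),
                        seq_len(config@nPairs)),
      truth = plan$ids[plan$taxonIdx], config = config)
}

# resolve profile taxa to genome sequences and draw the per-pair source
# taxa (multinomial in the abundances); shared by simulateReads and the
# experiment runner's fused simulate-and-count path so both produce the
# same reads for a given config seed
.simPlan <- function(pool, profile, config, contaminants = list()) {
  stopifnot(is(pool, "GenomePool"), is(profile, "CommunityProfile"),
            is(config, "ReadSimConfig"))
  extra <- lapply(contaminants, function(x)
    if (is(x, "ContaminantSpec")) x@genome else x)
  extraSeqs <- setNames(vapply(extra, function(g) g@sequence, ""),
                        vapply(extra, function(g) g@genomeId, ""))

  ab <- abundances(profile)
  ids <- names(ab)
  inPool <- ids %in% genomeIds(pool)
  if (any(!inPool & !ids %in% names(extraSeqs)))
    stop("profile taxa not resolvable to a genome: ",
         paste(ids[!inPool & !ids %in% names(extraSeqs)], collapse = ", "))
  seqs <- character(length(ids))
  seqs[inPool] <- as.character(pool@genomes[ids[inPool]])
  seqs[!inPool] <- extraSeqs[ids[!inPool]]

  tooShort <- nchar(seqs) < config@insertMeanBp
  if (any(tooShort)) {
    warning("skipping taxa with genome shorter than the mean insert: ",
            paste(ids[tooShort], collapse = ", "))
    if (all(tooShort)) stop("no taxon long enough to simulate from")
    ids <- ids[!tooShort]; seqs <- seqs[!tooShort]
    ab <- ab[!tooShort] / sum(ab[!tooShort])
  }

  counts <- .withSeed(config@seed,
                      as.vector(rmultinom(1, size = config@nPairs,
                                          prob = ab)))
  list(ids = ids, seqs = seqs, counts = counts,
       taxonIdx = rep.int(seq_along(ids), counts))
}

# spectrum of a simulated sample without materializing the reads;
# identical to countKmers(simulateReads(...), k) for the same config
.simulateSpectrum <- function(plan, config, k, sampleId) {
  kc <- cpp_simulate_count(plan$seqs, plan$taxonIdx,
                           as.integer(config@readLengthBp),
                           config@insertMeanBp, config@insertSdBp,
                           config@errorStart, config@errorEnd,
                           config@seed, as.integer(k))
  .newSpectrum(kc, k, sampleId)
}

# realized profile straight from the simulation plan's truth counts
.planProfile <- function(plan, sampleId) {
  keep <- plan$counts > 0
  new("CommunityProfile", sampleId = sampleId,
      abundances = setNames(plan$counts[keep] / sum(plan$counts),
                            plan$ids[keep]))
}

#' Realized (read-based) taxonomic profile of a read set
#'
#' The fraction of read pairs attributed to each taxon by the truth table;
#' the idealized analogue of a read-classifier profile (perfect
#' classification assumed). An unbiased estimator of the expected profile,
#' converging as depth grows.
#'
#' @param readset a [ReadSet-class].
#' @return a [CommunityProfile-class].
#' @export
realizedProfile <- function(readset) {
  stopifnot(is(readset, "ReadSet"))
  if (length(readset@truth) == 0L) stop("empty read set")
  tab <- table(readset@truth)
  new("CommunityProfile", sampleId = readset@sampleId,
      abundances = setNames(as.numeric(tab) / sum(tab), names(tab)))
}

#' @rdname accessors
#' @export
setMethod("sampleId", "ReadSet", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("nPairs", "ReadSet", function(x) length(x@reads1))

#' @rdname accessors
#' @export
setMethod("truthTable", "ReadSet", function(x)
  data.frame(readId = x@readIds, genomeId = x@truth))

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet", object@sampleId, ":", length(object@reads1), "pairs of 2 x",
      object@config@readLengthBp, "bp (", object@config@technology, ")\n",
      " taxa:", length(unique(object@truth)), "\n")
})
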