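#' @importFrom stats rlnorm
NULL

#' Draw a mock community with log-normal relative abundances
#'
#' Samples `nTaxa` distinct genomes uniformly without replacement from the
#' pool, draws their raw weights from a log-normal distribution and
#' normalizes to relative abundances summing to one. Abundances are read
#' proportions: they parameterize the read simulator directly.
#'
#' @param pool a [GenomePool-class].
#' @param nTaxa community richness (<= pool size).
#' @param lognormalMu,lognormalSigma log-normal parameters of the raw
#'   weights (defaults 0 and 1).
#' @param seed integer seed.
#' @param sampleId sample identifier.
#' @return a [CommunityProfile-class] with exactly `nTaxa` positive entries.
#' @examples
#' pool <- generateGenomePool(6, 2000, seed = 1)
#' prof <- drawCommunity(pool, 3, seed = 2)
#' sum(abundances(prof))
#' @export
drawCommunity <- function(pool, nTaxa, lognormalMu = 0, lognormalSigma = 1,
                          seed = 1, sampleId = "sample1") {
  ids <- genomeIds(pool)
  if (nTaxa > length(ids))
    stop("nTaxa (", nTaxa, ") exceeds pool size (", length(ids), ")")
  if (lognormalSigma <= 0) stop("lognormalSigma must be > 0")
  ab <- .withSeed(seed, {
    chosen <- sample(ids, nTaxa)
    w <- rlnorm(nTaxa, meanlog = lognormalMu, sdlog = lognormalSigma)
    stats::setNames(w / sum(w), chosen)
  })
  new("CommunityProfile", sampleId = sampleId, abundances = ab)
}

#' Construct a contamination spike
#'
#' @param contaminantId profile id of the contaminant (defaults to the
#'   genome's own id).
#' @param fraction read fraction in \[0, 1) the contaminant contributes.
#' @param genome the contaminant [Genome-class], e.g. [hostContaminant()].
#' @return a [ContaminantSpec-class].
#' @export
contaminantSpec <- function(genome, fraction,
                            contaminantId = genome@genomeId) {
  new("ContaminantSpec", contaminantId = contaminantId,
      fraction = as.numeric(fraction), genome = genome)
}

#' Spike a community profile with a contaminant
#'
#' Adds the contaminant at abundance `fraction` and rescales the original
#' abundances by `1 - fraction` so the profile still sums to one. A zero
#' fraction returns the profile unchanged.
#'
#' @param profile a [CommunityProfile-class].
#' @param spec a [ContaminantSpec-class].
#' @return the spiked [CommunityProfile-class].
#' @examples
#' pool <- generateGenomePool(4, 2000, seed = 1)
#' prof <- drawCommunity(pool, 2, seed = 2)
#' spiked <- spikeContamination(prof, contaminantSpec(phixContaminant(), 0.02))
#' @export
spikeContamination <- function(profile, spec) {
  stopifnot(is(profile, "CommunityProfile"), is(spec, "ContaminantSpec"))
  if (spec@fraction == 0) return(profile)
  if (spec@contaminantId %in% names(profile@abundances))
    stop("contaminant id already present in profile: ", spec@contaminantId)
  ab <- c(profile@abundances * (1 - spec@fraction),
          stats::setNames(spec@fraction, spec@contaminantId))
  new("CommunityProfile", sampleId = profile@sampleId, abundances = ab)
}

#' @rdname accessors
#' @export
setMethod("abundances", "CommunityProfile", function(x) x@abundances)

#' @rdname accessors
#' @export
setMethod("sampleId", "CommunityProfile", function(x) x@sampleId)

setMethod("show", "CommunityProfile", function(object) {
  cat("CommunityProfile", object@sampleId, "with",
      length(object@abundances), "taxa (sum =",
      format(sum(object@abundances)), ")\n")
})
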