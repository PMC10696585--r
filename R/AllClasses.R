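#' @importFrom S4Vectors DataFrame
NULL

.DNA_BASES <- c("A", "C", "G", "T")

#' Genome: a synthetic reference sequence with lineage labels
#'
#' A single reference genome of the simulation universe. Sequences are plain
#' A/C/G/T strings; the species/family/class labels carry the taxonomic
#' structure used by the reduced-diversity pool modes.
#'
#' @slot genomeId single character identifier.
#' @slot speciesLabel,familyLabel,classLabel lineage labels.
#' @slot sequence single character string over A/C/G/T.
#' @exportClass Genome
setClass("Genome",
  representation(genomeId = "character", speciesLabel = "character",
                 familyLabel = "character", classLabel = "character",
                 sequence = "character"))

setValidity("Genome", function(object) {
  msg <- character()
  if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-empty string")
  if (length(object@sequence) != 1L)
    msg <- c(msg, "sequence must be a single string")
  else if (grepl("[^ACGT]", object@sequence))
    msg <- c(msg, "sequence may contain only A/C/G/T")
  else if (nchar(object@sequence) < 62L)
    msg <- c(msg, "sequence must be at least 62 bp (2 x max supported k)")
  if (length(msg)) msg else TRUE
})

#' GenomePool: the taxa universe of a simulated experiment
#'
#' A set of synthetic genomes with unique ids and lineage labels. In
#' `all_taxa` mode each genome is an independent uniform-random sequence; in
#' `same_class` / `same_family` mode all genomes descend from one ancestor
#' sequence by independent per-site substitution, emulating pools restricted
#' to one taxonomic class or family.
#'
#' @slot poolId single character identifier.
#' @slot genomes a [Biostrings::DNAStringSet] named by genome id.
#' @slot taxonomy a [S4Vectors::DataFrame] with columns `genomeId`,
#'   `species`, `family`, `class`.
#' @slot divergenceMode one of `"all_taxa"`, `"same_class"`, `"same_family"`.
#' @slot seed integer seed the pool was generated from.
#' @exportClass GenomePool
setClass("GenomePool",
  representation(poolId = "character", genomes = "DNAStringSet",
                 taxonomy = "DataFrame", divergenceMode = "character",
                 seed = "numeric"))

setValidity("GenomePool", function(object) {
  msg <- character()
  ids <- names(object@genomes)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "genome ids must be unique and non-NULL")
  if (!identical(as.character(object@taxonomy$genomeId), as.character(ids)))
    msg <- c(msg, "taxonomy rows must match genome ids in order")
  if (!object@divergenceMode %in% c("all_taxa", "same_class", "same_family"))
    msg <- c(msg, "divergenceMode must be all_taxa, same_class or same_family")
  if (object@divergenceMode == "same_class" &&
      length(unique(object@taxonomy$class)) > 1L)
    msg <- c(msg, "same_class pool must have a single class label")
  if (object@divergenceMode == "same_family" &&
      (length(unique(object@taxonomy$family)) > 1L ||
       length(unique(object@taxonomy$class)) > 1L))
    msg <- c(msg, "same_family pool must have single family and class labels")
  if (length(msg)) msg else TRUE
})

#' CommunityProfile: ground-truth relative abundances of one sample
#'
#' Per-sample map from genome id to relative abundance. Abundances are read
#' proportions (the convention of the read simulator), are non-negative and
#' sum to one; this vector is the ground truth behind the "expected
#' taxonomic" beta-diversity distances.
#'
#' @slot sampleId single character identifier.
#' @slot abundances named numeric vector summing to 1.
#' @exportClass CommunityProfile
setClass("CommunityProfile",
  representation(sampleId = "character", abundances = "numeric"))

setValidity("CommunityProfile", function(object) {
  msg <- character()
  ab <- object@abundances
  if (length(ab) < 1L) msg <- c(msg, "profile must contain at least one taxon")
  if (is.null(names(ab)) || anyDuplicated(names(ab)) || any(!nzchar(names(ab))))
    msg <- c(msg, "abundances must have unique non-empty names")
  if (any(ab < 0)) msg <- c(msg, "abundances must be non-negative")
  if (abs(sum(ab) - 1) > 1e-9) msg <- c(msg, "abundances must sum to 1")
  if (length(msg)) msg else TRUE
})

#' ContaminantSpec: a contamination spike
#'
#' Pairs a contaminant genome (host-like or PhiX-like) with the fraction of
#' reads it should contribute to a sample.
#'
#' @slot contaminantId id under which the contaminant appears in profiles.
#' @slot fraction read fraction in \[0, 1).
#' @slot genome the contaminant [Genome].
#' @exportClass ContaminantSpec
setClass("ContaminantSpec",
  representation(contaminantId = "character", fraction = "numeric",
                 genome = "Genome"))

setValidity("ContaminantSpec", function(object) {
  if (length(object@fraction) != 1L || object@fraction < 0 ||
      object@fraction >= 1)
    return("fraction must be a single value in [0, 1)")
  TRUE
})

#' ReadSimConfig: paired-end read simulation parameters
#'
#' Platform presets set read length and the per-base substitution-rate ramp
#' (probability interpolated linearly from `errorStart` at the first cycle
#' to `errorEnd` at the last). Fragment (insert) lengths are normal with the
#' given mean/sd.
#'
#' @slot technology `"miseq"`, `"hiseq"` or `"novaseq"`.
#' @slot readLengthBp read length in bp.
#' @slot nPairs number of read pairs (the sequencing depth).
#' @slot insertMeanBp,insertSdBp fragment length distribution (bp).
#' @slot errorStart,errorEnd substitution probabilities at first/last cycle.
#' @slot seed integer seed.
#' @exportClass ReadSimConfig
setClass("ReadSimConfig",
  representation(technology = "character", readLengthBp = "numeric",
                 nPairs = "numeric", insertMeanBp = "numeric",
                 insertSdBp = "numeric", errorStart = "numeric",
                 errorEnd = "numeric", seed = "numeric"))

setValidity("ReadSimConfig", function(object) {
  msg <- character()
  if (object@nPairs < 1) msg <- c(msg, "nPairs must be >= 1")
  if (object@errorStart < 0 || object@errorStart > object@errorEnd ||
      object@errorEnd >= 0.1)
    msg <- c(msg, "need 0 <= errorStart <= errorEnd < 0.1")
  if (object@readLengthBp + 1 > object@insertMeanBp)
    msg <- c(msg, "insertMeanBp must be at least readLengthBp + 1")
  if (length(msg)) msg else TRUE
})

#' ReadSet: simulated paired reads plus their source-taxon truth table
#'
#' Holds both mates in memory together with the per-pair source genome id
#' (the "truth table"), which substitutes for a read classifier when
#' computing realized taxonomic profiles. Qualities encode each cycle's
#' substitution probability as a Phred+33 score and are shared by all reads
#' of a mate.
#'
#' @slot sampleId sample identifier.
#' @slot reads1,reads2 character vectors of read sequences (R1/R2).
#' @slot quality1,quality2 single Phred+33 quality strings.
#' @slot readIds read id stems (`<sample>_<serial>`); mates append /1, /2.
#' @slot truth character vector of source genome ids, one per pair.
#' @slot config the [ReadSimConfig] used.
#' @exportClass ReadSet
setClass("ReadSet",
  representation(sampleId = "character", reads1 = "character",
                 reads2 = "character", quality1 = "character",
                 quality2 = "character", readIds = "character",
                 truth = "character", config = "ReadSimConfig"))

setValidity("ReadSet", function(object) {
  n <- length(object@reads1)
  if (length(object@reads2) != n || length(object@truth) != n ||
      length(object@readIds) != n)
    return("reads1, reads2, readIds and truth must have equal length")
  TRUE
})

#' KmerSpectrum: canonical k-mer counts of one sample
#'
#' The multiset of canonical k-mers (lexicographic minimum of a k-mer and
#' its reverse complement) of a sample at fixed k <= 31. Keys are stored
#' 2-bit packed as raw 64-bit words in ascending (= lexicographic) order;
#' use [kmerCounts()] to decode small spectra to strings.
#'
#' @slot sampleId sample identifier.
#' @slot k k-mer length (1..31).
#' @slot keys raw vector, 8 bytes per packed canonical k-mer, sorted.
#' @slot counts positive integer count per key.
#' @exportClass KmerSpectrum
setClass("KmerSpectrum",
  representation(sampleId = "character", k = "integer", keys = "raw",
                 counts = "integer"))

setValidity("KmerSpectrum", function(object) {
  msg <- character()
  if (object@k < 1L || object@k > 31L) msg <- c(msg, "k must be in 1..31")
  if (length(object@keys) != 8L * length(object@counts))
    msg <- c(msg, "keys must hold 8 bytes per count")
  if (length(object@counts) && any(object@counts <= 0L))
    msg <- c(msg, "counts must be positive")
  if (!cpp_keys_sorted_unique(object@keys))
    msg <- c(msg, "keys must be strictly ascending")
  if (length(msg)) msg else TRUE
})

#' KmerSketch: bottom-s MinHash sketch of a k-mer spectrum
#'
#' The s smallest seeded 64-bit hash values over the distinct canonical
#' k-mers of a sample, each with its count. Sketches are comparable only at
#' equal k and hash seed.
#'
#' @slot sampleId sample identifier.
#' @slot k k-mer length.
#' @slot s sketch size (maximum number of retained hashes).
#' @slot hashes raw vector, 8 bytes per hash, ascending.
#' @slot counts k-mer count per retained hash.
#' @slot hashSeed seed of the hash function.
#' @exportClass KmerSketch
setClass("KmerSketch",
  representation(sampleId = "character", k = "integer", s = "numeric",
                 hashes = "raw", counts = "integer", hashSeed = "numeric"))

setValidity("KmerSketch", function(object) {
  msg <- character()
  if (object@s < 1) msg <- c(msg, "s must be >= 1")
  if (length(object@hashes) != 8L * length(object@counts))
    msg <- c(msg, "hashes must hold 8 bytes per count")
  if (length(object@counts) > object@s)
    msg <- c(msg, "sketch holds more than s entries")
  if (!cpp_keys_sorted_unique(object@hashes))
    msg <- c(msg, "hashes must be strictly ascending")
  if (length(msg)) msg else TRUE
})

#' ExperimentConfig: one simulated benchmarking experiment
#'
#' Describes a full experiment grid (samples, pools, depths, technologies,
#' k-mer lengths, sketch sizes, abundance filters) for [runExperiment()].
#' `depths` and `genomeLengthBp` are given at full scale and are divided by
#' `scaleFactor` before simulation, which preserves per-taxon coverage.
#' Construct with [experimentConfig()].
#'
#' @slot experiment one of simset1_technical, simset2_contamination,
#'   simset3_richness, simset4_taxonomy, sketch_effect, filter_effect.
#' @slot nSamples number of simulated metagenomes per arm.
#' @slot poolSize genomes per pool (one entry per arm for simset3).
#' @slot nTaxa community richness (one entry per arm for simset3).
#' @slot genomeLengthBp full-scale genome length in bp.
#' @slot depths full-scale sequencing depths in read pairs.
#' @slot technologies platform presets to simulate.
#' @slot ks k-mer lengths.
#' @slot sketchSizes bottom-s sketch sizes (sketch_effect).
#' @slot filterMins minimum-abundance filter thresholds (filter_effect).
#' @slot contamArms named list of contamination fraction ranges `c(lo, hi)`
#'   (simset2); names starting with `host` use the host-like contaminant,
#'   others the PhiX-like one.
#' @slot lengthSpread `c(lo, hi)` multiplicative range of per-genome
#'   lengths around `genomeLengthBp` (log-uniform), emulating the size
#'   heterogeneity of complete bacterial genomes; `c(1, 1)` fixes all
#'   lengths.
#' @slot spectrumFilterMin minimum k-mer abundance applied to every
#'   spectrum before distance computation (the Simka-style setting used
#'   by the benchmark grids); 0 disables filtering.
#' @slot lognormalMu,lognormalSigma community log-normal parameters.
#' @slot masterSeed master seed; all internal seeds derive from it.
#' @slot scaleFactor joint divisor on depths and genome length.
#' @exportClass ExperimentConfig
setClass("ExperimentConfig",
  representation(experiment = "character", nSamples = "numeric",
                 poolSize = "numeric", nTaxa = "numeric",
                 genomeLengthBp = "numeric", depths = "numeric",
                 technologies = "character", ks = "numeric",
                 sketchSizes = "numeric", filterMins = "numeric",
                 contamArms = "list", lengthSpread = "numeric",
                 spectrumFilterMin = "numeric",
                 lognormalMu = "numeric", lognormalSigma = "numeric",
                 masterSeed = "numeric", scaleFactor = "numeric"))

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  ok <- c("simset1_technical", "simset2_contamination", "simset3_richness",
          "simset4_taxonomy", "sketch_effect", "filter_effect")
  if (!object@experiment %in% ok)
    msg <- c(msg, paste("experiment must be one of:",
                        paste(ok, collapse = ", ")))
  if (object@scaleFactor < 1) msg <- c(msg, "scaleFactor must be >= 1")
  if (length(object@depths) < 1L || any(object@depths < 1))
    msg <- c(msg, "depths must be a non-empty positive vector")
  if (length(object@ks) < 1L || any(object@ks < 1 | object@ks > 31))
    msg <- c(msg, "ks must be in 1..31")
  if (length(object@poolSize) != length(object@nTaxa))
    msg <- c(msg, "poolSize and nTaxa must have one entry per arm")
  if (any(object@nTaxa > object@poolSize))
    msg <- c(msg, "nTaxa cannot exceed poolSize in any arm")
  if (length(object@lengthSpread) != 2L || any(object@lengthSpread <= 0) ||
      object@lengthSpread[1] > object@lengthSpread[2])
    msg <- c(msg, "lengthSpread must be an ascending positive c(lo, hi)")
  if (length(object@spectrumFilterMin) != 1L ||
      object@spectrumFilterMin < 0)
    msg <- c(msg, "spectrumFilterMin must be a single value >= 0")
  if (length(msg)) msg else TRUE
})
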