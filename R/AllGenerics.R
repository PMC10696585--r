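#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))

#' @rdname accessors
#' @export
setGeneric("totalKmers", function(x) standardGeneric("totalKmers"))

#' @rdname accessors
#' @export
setGeneric("nDistinctKmers", function(x) standardGeneric("nDistinctKmers"))

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setGeneric("sketchSize", function(x) standardGeneric("sketchSize"))

#' @rdname accessors
#' @export
setGeneric("hashSeed", function(x) standardGeneric("hashSeed"))

#' Bray-Curtis dissimilarity between two samples
#'
#' Abundance-weighted Bray-Curtis dissimilarity,
#' `1 - 2 * sum_w min(c_a(w), c_b(w)) / (total_a + total_b)`,
#' where `w` runs over canonical k-mers ([KmerSpectrum] method), taxa
#' ([CommunityProfile] method) or the merged bottom-m hash window
#' ([KmerSketch] method). For normalized profiles this equals half the L1
#' distance.
#'
#' @param a,b two objects of the same class (and same k / hash seed where
#'   applicable).
#' @return a dissimilarity in \[0, 1\].
#' @seealso [jaccardPA()], [pairwiseMatrix()]
#' @export
setGeneric("brayCurtis", function(a, b) standardGeneric("brayCurtis"))

#' Presence/absence Jaccard distance between two samples
#'
#' `1 - |A intersect B| / |A union B|` over distinct canonical k-mers
#' ([KmerSpectrum]), taxa with positive abundance ([CommunityProfile]), or
#' estimated from the merged bottom-m hash window ([KmerSketch]): with m =
#' min(s, |union|), the estimate is the shared fraction among the m
#' smallest hashes of the union.
#'
#' @inheritParams brayCurtis
#' @return a distance in \[0, 1\].
#' @export
setGeneric("jaccardPA", function(a, b) standardGeneric("jaccardPA"))
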