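#' Bottom-s MinHash sketch of a k-mer spectrum
#'
#' Hashes every distinct canonical k-mer with a seeded 64-bit mixing hash
#' and keeps the `s` smallest hash values together with their counts. A
#' sketch is an order-of-magnitude-smaller stand-in for the full spectrum
#' from which both distances can be estimated; sketches are comparable only
#' at equal k and hash seed. Distinct k-mers colliding on a 64-bit hash
#' abort with an error.
#'
#' @param spectrum a [KmerSpectrum-class].
#' @param s sketch size (>= 1). With `s >=` the number of distinct k-mers
#'   the sketch is lossless and sketched distances equal exact ones.
#' @param hashSeed integer seed of the hash function (default 0).
#' @return a [KmerSketch-class].
#' @examples
#' sp <- kmerSpectrum(c(ACGTA = 2L, CCCCC = 1L, GGGTT = 3L))
#' sketchSpectrum(sp, s = 2)
#' @export
sketchSpectrum <- function(spectrum, s, hashSeed = 0) {
  stopifnot(is(spectrum, "KmerSpectrum"))
  if (s < 1) stop("s must be >= 1")
  sk <- cpp_sketch(spectrum@keys, spectrum@counts, as.numeric(s),
                   as.numeric(hashSeed))
  new("KmerSketch", sampleId = spectrum@sampleId, k = spectrum@k,
      s = as.numeric(s), hashes = sk$hashes, counts = sk$counts,
      hashSeed = as.numeric(hashSeed))
}

.checkComparable <- function(a, b) {
  if (a@k != b@k) stop("k-mer lengths differ (", a@k, " vs ", b@k, ")")
  if (a@hashSeed != b@hashSeed)
    stop("hash seeds differ; sketches are not comparable")
}

.sketchStats <- function(a, b) {
  cpp_sketch_pair_stats(a@hashes, a@counts, b@hashes, b@counts,
                        min(a@s, b@s))
}

#' @rdname jaccardPA
#' @export
setMethod("jaccardPA", signature("KmerSketch", "KmerSketch"),
  function(a, b) {
    .checkComparable(a, b)
    st <- .sketchStats(a, b)
    if (st[["m"]] == 0) stop("cannot compare two empty sketches")
    1 - st[["n_shared"]] / st[["m"]]
  })

#' @rdname brayCurtis
#' @export
setMethod("brayCurtis", signature("KmerSketch", "KmerSketch"),
  function(a, b) {
    .checkComparable(a, b)
    st <- .sketchStats(a, b)
    if (st[["total_a"]] + st[["total_b"]] == 0)
      stop("cannot compare two empty sketches")
    1 - 2 * st[["sum_min"]] / (st[["total_a"]] + st[["total_b"]])
  })

#' @rdname accessors
#' @export
setMethod("sampleId", "KmerSketch", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("kmerLength", "KmerSketch", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("sketchSize", "KmerSketch", function(x) x@s)

#' @rdname accessors
#' @export
setMethod("hashSeed", "KmerSketch", function(x) x@hashSeed)

#' @rdname accessors
#' @export
setMethod("nDistinctKmers", "KmerSketch", function(x) length(x@counts))

setMethod("show", "KmerSketch", function(object) {
  cat("KmerSketch", object@sampleId, ": k =", object@k, ", s =",
      format(object@s), ",", length(object@counts), "entries, hash seed",
      object@hashSeed, "\n")
})
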