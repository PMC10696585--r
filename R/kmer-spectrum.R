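#' Count canonical k-mers
#'
#' Every window of length `k` not containing an ambiguous (non-ACGT) base
#' contributes one count to its canonical form, the lexicographic minimum of
#' the k-mer and its reverse complement. For a [ReadSet-class] both mates
#' are counted. `k` is capped at 31 (2-bit packing in a 64-bit word).
#'
#' @param x a [ReadSet-class], a character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param k k-mer length, 1..31.
#' @param canonical collapse a k-mer with its reverse complement (default);
#'   set `FALSE` to count forward k-mers only.
#' @param sampleId sample id recorded in the spectrum.
#' @return a [KmerSpectrum-class].
#' @examples
#' sp <- countKmers("ACGTT", k = 3, sampleId = "ex")
#' kmerCounts(sp)
#' @export
setGeneric("countKmers", function(x, k, canonical = TRUE, sampleId = NULL)
  standardGeneric("countKmers"))

.newSpectrum <- function(kc, k, sampleId)
  new("KmerSpectrum", sampleId = sampleId, k = as.integer(k),
      keys = kc$keys, counts = kc$counts)

#' @rdname countKmers
#' @export
setMethod("countKmers", "character", function(x, k, canonical = TRUE,
                                              sampleId = NULL) {
  if (length(x) == 0L) stop("empty sequence source")
  .newSpectrum(cpp_count_kmers(x, as.integer(k), canonical), k,
               sampleId %||% "sample1")
})

#' @rdname countKmers
#' @export
setMethod("countKmers", "ReadSet", function(x, k, canonical = TRUE,
                                            sampleId = NULL) {
  .newSpectrum(cpp_count_kmers(c(x@reads1, x@reads2), as.integer(k),
                               canonical), k, sampleId %||% x@sampleId)
})

#' @rdname countKmers
#' @export
setMethod("countKmers", "DNAStringSet", function(x, k, canonical = TRUE,
                                                 sampleId = NULL) {
  countKmers(as.character(x), k, canonical, sampleId %||% "sample1")
})

#' Count k-mers of FASTA/FASTQ files
#'
#' Reads one or more (optionally gzipped) FASTA or FASTQ files -- e.g. the
#' two mates of a paired run -- and counts their canonical k-mers as one
#' sample.
#'
#' @param files paths to FASTA/FASTQ files.
#' @param k,canonical,sampleId as in [countKmers()].
#' @param format `"fastq"` or `"fasta"`; guessed from the first file's
#'   extension by default.
#' @return a [KmerSpectrum-class].
#' @export
countKmersFromFiles <- function(files, k, canonical = TRUE,
                                sampleId = "sample1", format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", files[1], ignore.case = TRUE))
      "fastq" else "fasta"
  }
  seqs <- unlist(lapply(files, function(f)
    as.character(Biostrings::readDNAStringSet(f, format = format))))
  countKmers(unname(seqs), k, canonical, sampleId)
}

#' Construct a k-mer spectrum from explicit counts
#'
#' Convenience constructor (fixtures, small examples): k-mer strings are
#' canonicalized, aggregated and sorted.
#'
#' @param counts named positive integer vector; names are k-mer strings of
#'   a common length.
#' @param sampleId sample id.
#' @param canonical canonicalize the input k-mers (default).
#' @return a [KmerSpectrum-class].
#' @export
kmerSpectrum <- function(counts, sampleId = "sample1", canonical = TRUE) {
  if (is.null(names(counts))) stop("counts must be named by k-mer strings")
  k <- unique(nchar(names(counts)))
  if (length(k) != 1L) stop("all k-mers must have the same length")
  kc <- cpp_build_spectrum(names(counts), as.integer(counts), as.integer(k),
                           canonical)
  .newSpectrum(kc, k, sampleId)
}

#' Filter a spectrum by k-mer abundance
#'
#' Keeps k-mers with `minAbundance <= count <= maxAbundance`. The Simka-like
#' preset is `minAbundance = 2` (drop singletons); the package default is no
#' filtering, because minimum-abundance filtering degrades the agreement
#' with taxonomic distances in the simulated experiments.
#'
#' @param spectrum a [KmerSpectrum-class].
#' @param minAbundance minimum retained count (>= 0).
#' @param maxAbundance maximum retained count (default unbounded).
#' @return the filtered [KmerSpectrum-class] (possibly empty).
#' @export
filterSpectrum <- function(spectrum, minAbundance = 0, maxAbundance = Inf) {
  stopifnot(is(spectrum, "KmerSpectrum"))
  if (minAbundance < 0) stop("minAbundance must be >= 0")
  if (minAbundance > maxAbundance)
    stop("minAbundance must not exceed maxAbundance")
  kc <- cpp_filter_counts(spectrum@keys, spectrum@counts,
                          as.integer(minAbundance), as.numeric(maxAbundance))
  .newSpectrum(kc, spectrum@k, spectrum@sampleId)
}

#' Decode a spectrum to k-mer strings
#'
#' Intended for small spectra (tests, inspection, TSV export): decoding a
#' multi-million-k-mer spectrum to strings is memory-heavy.
#'
#' @param spectrum a [KmerSpectrum-class].
#' @return a `data.frame` with columns `kmer` (lexicographically sorted)
#'   and `count`.
#' @export
kmerCounts <- function(spectrum) {
  stopifnot(is(spectrum, "KmerSpectrum"))
  data.frame(kmer = cpp_decode_kmers(spectrum@keys, spectrum@k),
             count = spectrum@counts)
}

#' @rdname accessors
#' @export
setMethod("sampleId", "KmerSpectrum", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("kmerLength", "KmerSpectrum", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("totalKmers", "KmerSpectrum", function(x) sum(as.numeric(x@counts)))

#' @rdname accessors
#' @export
setMethod("nDistinctKmers", "KmerSpectrum", function(x) length(x@counts))

setMethod("show", "KmerSpectrum", function(object) {
  cat("KmerSpectrum", object@sampleId, ": k =", object@k, ",",
      length(object@counts), "distinct /", format(totalKmers(object)),
      "total k-mers\n")
})
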