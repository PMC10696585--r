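#' @importFrom utils read.table write.table
NULL

.openOut <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

#' Write a read set as paired gzip FASTQ plus truth table
#'
#' Writes `<sample>_R1.fastq.gz`, `<sample>_R2.fastq.gz` (Phred+33, read
#' ids `<sample>_<serial>/1` and `/2`) and `<sample>_truth.tsv` with
#' columns `read_id`, `genome_id`.
#'
#' @param readset a [ReadSet-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
writeReadSet <- function(readset, dir) {
  stopifnot(is(readset, "ReadSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(readset@sampleId,
                                 c("_R1.fastq.gz", "_R2.fastq.gz",
                                   "_truth.tsv")))
  writeMate <- function(path, reads, qual, mate) {
    con <- .openOut(path)
    on.exit(close(con))
    writeLines(as.vector(rbind(paste0("@", readset@readIds, "/", mate),
                               reads, "+", qual)), con)
  }
  writeMate(paths[1], readset@reads1, readset@quality1, 1L)
  writeMate(paths[2], readset@reads2, readset@quality2, 2L)
  write.table(data.frame(read_id = readset@readIds,
                         genome_id = readset@truth),
              paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a genome pool as FASTA plus taxonomy table
#'
#' @param pool a [GenomePool-class].
#' @param fastaPath output FASTA path (`.gz` allowed).
#' @param taxonomyPath optional TSV path for the lineage table.
#' @export
writePoolFasta <- function(pool, fastaPath, taxonomyPath = NULL) {
  stopifnot(is(pool, "GenomePool"))
  Biostrings::writeXStringSet(pool@genomes, fastaPath,
                              compress = grepl("\\.gz$", fastaPath))
  if (!is.null(taxonomyPath))
    write.table(as.data.frame(pool@taxonomy), taxonomyPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(fastaPath)
}

#' Write community profiles as a tidy TSV
#'
#' Columns `sample_id`, `genome_id`, `abundance`; one row per (sample,
#' taxon).
#'
#' @param profiles list of [CommunityProfile-class] objects.
#' @param path output TSV path.
#' @export
writeProfiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(sample_id = p@sampleId, genome_id = names(p@abundances),
               abundance = unname(p@abundances))))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write k-mer spectra as sorted TSV
#'
#' Format: a header line `#sample_id=<id>\tk=<k>` followed by
#' `kmer<TAB>count` records in lexicographic k-mer order; `.gz` paths are
#' compressed. Intended for desk-scale spectra.
#'
#' @param spectrum a [KmerSpectrum-class].
#' @param path TSV path (`.gz` allowed).
#' @return `writeSpectrum()` the path, invisibly; `readSpectrum()` the
#'   [KmerSpectrum-class].
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "KmerSpectrum"))
  con <- .openOut(path)
  on.exit(close(con))
  writeLines(c(sprintf("#sample_id=%s\tk=%d", spectrum@sampleId, spectrum@k),
               sprintf("%s\t%d", cpp_decode_kmers(spectrum@keys, spectrum@k),
                       spectrum@counts)), con)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1],
                    regexec("^#sample_id=(\\S+)\tk=(\\d+)$", lines[1]))[[1]]
  if (length(hdr) != 3L) stop("missing spectrum header in ", path)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  kmerSpectrum(stats::setNames(as.integer(vapply(body, `[`, "", 2L)),
                               vapply(body, `[`, "", 1L)),
               sampleId = hdr[2], canonical = FALSE)
}

#' Read and write labeled distance matrices as TSV
#'
#' Square TSV with sample ids as header row and first column.
#'
#' @param D labeled symmetric distance matrix.
#' @param path TSV path.
#' @return `writeDistanceMatrix()` the path, invisibly;
#'   `readDistanceMatrix()` the matrix.
#' @export
writeDistanceMatrix <- function(D, path) {
  .checkDistanceMatrix(D)
  write.table(D, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  M <- as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE))
  colnames(M) <- rownames(M)
  .checkDistanceMatrix(M)
}
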