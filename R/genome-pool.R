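#' @importFrom Biostrings DNAStringSet
#' @importFrom stats runif
NULL

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.randomCodes <- function(n) sample.int(4L, n, replace = TRUE)

.codesToSeq <- function(codes) paste(.DNA_BASES[codes], collapse = "")

# substitute each site independently with probability d; the new base is
# uniform over the three alternatives
.mutateCodes <- function(codes, d) {
  hit <- which(runif(length(codes)) < d)
  if (length(hit))
    codes[hit] <- ((codes[hit] - 1L +
                    sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  codes
}

#' Generate a synthetic genome pool
#'
#' Builds the taxa universe of a simulated experiment. In `all_taxa` mode
#' every genome is an independent uniform-random A/C/G/T sequence (expected
#' pairwise identity 25%). In `same_class` / `same_family` mode one ancestor
#' sequence is drawn and each genome is derived from it by substituting each
#' site independently with probability `perSiteDivergence`, emulating pools
#' restricted to a single taxonomic class (default divergence 0.15) or
#' family (default 0.05).
#'
#' @param nGenomes number of genomes (>= 2).
#' @param genomeLengthBp genome length in bp (>= 1000).
#' @param divergenceMode `"all_taxa"`, `"same_class"` or `"same_family"`.
#' @param perSiteDivergence per-site substitution probability from the
#'   ancestor (ignored for `all_taxa`); must lie in \[0, 0.3\].
#' @param seed integer seed; pools are byte-identical for a fixed seed.
#' @param poolId pool identifier.
#' @param lengthRange optional `c(min, max)` in bp: per-genome lengths are
#'   drawn log-uniformly from this range (both >= 1000), emulating the
#'   size heterogeneity of complete bacterial genomes; the default `NULL`
#'   gives every genome exactly `genomeLengthBp`.
#' @return a [GenomePool-class].
#' @examples
#' pool <- generateGenomePool(4, 2000, seed = 1)
#' genomeIds(pool)
#' @export
generateGenomePool <- function(nGenomes, genomeLengthBp = 50000,
                               divergenceMode = c("all_taxa", "same_class",
                                                  "same_family"),
                               perSiteDivergence = NULL, seed = 1,
                               poolId = "pool1", lengthRange = NULL) {
  divergenceMode <- match.arg(divergenceMode)
  if (nGenomes < 2) stop("nGenomes must be >= 2")
  if (genomeLengthBp < 1000) stop("genomeLengthBp must be >= 1000")
  if (!is.null(lengthRange)) {
    if (length(lengthRange) != 2L || any(lengthRange < 1000) ||
        lengthRange[1] > lengthRange[2])
      stop("lengthRange must be c(min, max) with both >= 1000 bp")
  }
  if (is.null(perSiteDivergence))
    perSiteDivergence <- switch(divergenceMode, all_taxa = 0,
                                same_class = 0.15, same_family = 0.05)
  if (perSiteDivergence < 0 || perSiteDivergence > 0.3)
    stop("perSiteDivergence must be in [0, 0.3]")

  ids <- sprintf("g%03d", seq_len(nGenomes))
  seqs <- .withSeed(seed, {
    lens <- if (is.null(lengthRange)) rep(genomeLengthBp, nGenomes)
      else round(exp(runif(nGenomes, log(lengthRange[1]),
                           log(lengthRange[2]))))
    if (divergenceMode == "all_taxa") {
      vapply(seq_len(nGenomes), function(i)
        .codesToSeq(.randomCodes(lens[i])), "")
    } else {
      # ancestor at the maximum length; shorter genomes are mutated
      # prefixes, so relatedness is preserved across the size spread
      anc <- .randomCodes(max(lens))
      vapply(seq_len(nGenomes), function(i)
        .codesToSeq(.mutateCodes(anc[seq_len(lens[i])],
                                 perSiteDivergence)), "")
    }
  })
  names(seqs) <- ids
  fam <- switch(divergenceMode,
                all_taxa = sprintf("family_%03d", seq_len(nGenomes)),
                same_class = sprintf("family_%03d", seq_len(nGenomes)),
                same_family = rep("family_001", nGenomes))
  cls <- if (divergenceMode == "all_taxa")
    sprintf("class_%03d", seq_len(nGenomes)) else rep("class_001", nGenomes)
  new("GenomePool", poolId = poolId, genomes = DNAStringSet(seqs),
      taxonomy = DataFrame(genomeId = ids, species = paste0("sp_", ids),
                           family = fam, class = cls),
      divergenceMode = divergenceMode, seed = as.numeric(seed))
}

#' @rdname accessors
#' @param x an object of this package.
#' @export
setMethod("genomeIds", "GenomePool", function(x) names(x@genomes))

#' Pool sequences and taxonomy
#'
#' @param pool a [GenomePool-class].
#' @return `poolGenomes()` the [Biostrings::DNAStringSet] of sequences;
#'   `poolTaxonomy()` the lineage [S4Vectors::DataFrame].
#' @export
poolGenomes <- function(pool) pool@genomes

#' @rdname poolGenomes
#' @export
poolTaxonomy <- function(pool) pool@taxonomy

#' Extract one genome from a pool
#'
#' @param pool a [GenomePool-class].
#' @param genomeId a genome id of the pool.
#' @return a [Genome-class].
#' @export
getGenome <- function(pool, genomeId) {
  if (!genomeId %in% names(pool@genomes)) stop("unknown genome id: ", genomeId)
  tx <- pool@taxonomy[pool@taxonomy$genomeId == genomeId, ]
  new("Genome", genomeId = genomeId, speciesLabel = tx$species,
      familyLabel = tx$family, classLabel = tx$class,
      sequence = as.character(pool@genomes[[genomeId]]))
}

#' Synthetic contaminant genomes
#'
#' `hostContaminant()` builds a long host-like genome (default 500 kb, the
#' scaled analogue of a eukaryotic host: many foreign k-mers) and
#' `phixContaminant()` a 5386 bp PhiX-like spike-in genome (few foreign
#' k-mers). Both are uniform-random sequences.
#'
#' @param lengthBp host genome length in bp.
#' @param seed integer seed.
#' @return a [Genome-class].
#' @export
hostContaminant <- function(lengthBp = 5e5, seed = 101) {
  seqc <- .withSeed(seed, .codesToSeq(.randomCodes(lengthBp)))
  new("Genome", genomeId = "host_like", speciesLabel = "host",
      familyLabel = "host_family", classLabel = "host_class",
      sequence = seqc)
}

#' @rdname hostContaminant
#' @export
phixContaminant <- function(seed = 102) {
  seqc <- .withSeed(seed, .codesToSeq(.randomCodes(5386L)))
  new("Genome", genomeId = "phix_like", speciesLabel = "phiX174",
      familyLabel = "phix_family", classLabel = "phix_class",
      sequence = seqc)
}

setMethod("show", "Genome", function(object) {
  cat("Genome", object@genomeId, "(", nchar(object@sequence), "bp )",
      "\n  lineage:", object@speciesLabel, "/", object@familyLabel, "/",
      object@classLabel, "\n")
})

setMethod("show", "GenomePool", function(object) {
  w <- range(Biostrings::width(object@genomes))
  len <- if (w[1] == w[2]) paste(w[1], "bp") else
    paste0(w[1], "-", w[2], " bp")
  cat("GenomePool", object@poolId, "with", length(object@genomes),
      "genomes of", len, "\n",
      " mode:", object@divergenceMode, " seed:", object@seed, "\n")
})
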