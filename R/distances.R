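.checkSameK <- function(a, b) {
  if (a@k != b@k)
    stop("k-mer lengths differ (", a@k, " vs ", b@k, ")")
}

#' @rdname brayCurtis
#' @export
setMethod("brayCurtis", signature("KmerSpectrum", "KmerSpectrum"),
  function(a, b) {
    .checkSameK(a, b)
    if (length(a@counts) == 0L || length(b@counts) == 0L)
      stop("cannot compute Bray-Curtis on an empty spectrum")
    st <- cpp_pair_stats(a@keys, a@counts, b@keys, b@counts)
    1 - 2 * st[["sum_min"]] / (totalKmers(a) + totalKmers(b))
  })

#' @rdname jaccardPA
#' @export
setMethod("jaccardPA", signature("KmerSpectrum", "KmerSpectrum"),
  function(a, b) {
    .checkSameK(a, b)
    if (length(a@counts) == 0L && length(b@counts) == 0L)
      stop("cannot compute Jaccard on two empty spectra")
    st <- cpp_pair_stats(a@keys, a@counts, b@keys, b@counts)
    1 - st[["n_shared"]] / st[["n_union"]]
  })

# align two profiles on the union of their taxa (absent taxon = 0)
.alignProfiles <- function(p, q) {
  taxa <- union(names(p@abundances), names(q@abundances))
  m <- cbind(p = p@abundances[match(taxa, names(p@abundances))],
             q = q@abundances[match(taxa, names(q@abundances))])
  m[is.na(m)] <- 0
  m
}

#' @rdname brayCurtis
#' @export
setMethod("brayCurtis", signature("CommunityProfile", "CommunityProfile"),
  function(a, b) {
    m <- .alignProfiles(a, b)
    1 - 2 * sum(pmin(m[, 1], m[, 2])) / (sum(m[, 1]) + sum(m[, 2]))
  })

#' @rdname jaccardPA
#' @export
setMethod("jaccardPA", signature("CommunityProfile", "CommunityProfile"),
  function(a, b) {
    m <- .alignProfiles(a, b) > 0
    1 - sum(m[, 1] & m[, 2]) / sum(m[, 1] | m[, 2])
  })

#' All-vs-all distance matrix
#'
#' Applies [brayCurtis()] or [jaccardPA()] to every unordered pair of a
#' homogeneous list of samples ([KmerSpectrum-class],
#' [CommunityProfile-class] or [KmerSketch-class] objects) and returns a
#' labeled symmetric matrix with zero diagonal.
#'
#' @param items list of >= 2 samples of one class (same k / hash seed).
#' @param metric `"braycurtis"` or `"jaccard-pa"`.
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
pairwiseMatrix <- function(items, metric = c("braycurtis", "jaccard-pa")) {
  metric <- match.arg(metric)
  if (length(items) < 2L) stop("need at least 2 items")
  cls <- unique(vapply(items, function(x) class(x)[1], ""))
  if (length(cls) != 1L) stop("items must all be of the same class")
  labels <- vapply(items, sampleId, "")
  if (anyDuplicated(labels)) stop("duplicate sample ids")
  fun <- if (metric == "braycurtis") brayCurtis else jaccardPA
  n <- length(items)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      D[i, j] <- D[j, i] <- fun(items[[i]], items[[j]])
    }
  }
  D
}
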