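#' @importFrom stats as.dist cor cutree hclust cmdscale median
#' @importFrom vegan adonis2
NULL

.checkDistanceMatrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix")
  if (is.null(rownames(D)) ||
      !identical(rownames(D), colnames(D)))
    stop("D must carry identical row and column sample ids")
  if (any(abs(D - t(D)) > 1e-12)) stop("D must be symmetric")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  invisible(D)
}

#' Upper-triangle vector of a distance matrix
#'
#' Strictly-upper-triangle entries in a fixed order (samples sorted by
#' label, then row-major), the per-pair vector all matrix-vs-matrix
#' comparisons operate on; length `n (n - 1) / 2`.
#'
#' @param D labeled symmetric distance matrix with zero diagonal.
#' @return numeric vector of the `n(n-1)/2` pairwise distances.
#' @export
upperTriangle <- function(D) {
  .checkDistanceMatrix(D)
  o <- order(rownames(D))
  M <- D[o, o, drop = FALSE]
  t(M)[lower.tri(M)]
}

.matchedTriangles <- function(D1, D2) {
  .checkDistanceMatrix(D1)
  .checkDistanceMatrix(D2)
  if (!setequal(rownames(D1), rownames(D2)))
    stop("distance matrices carry different sample ids")
  list(u1 = upperTriangle(D1), u2 = upperTriangle(D2))
}

#' Spearman correlation between two distance matrices
#'
#' Rank correlation (average ranks for ties) between the upper-triangle
#' vectors of two distance matrices over the same samples; the agreement
#' statistic used throughout the benchmarking experiments. This is the
#' plain per-pair correlation, not a Mantel test.
#'
#' @param D1,D2 labeled symmetric distance matrices over the same samples.
#' @param condition optional named list of experiment factors carried into
#'   the result.
#' @return list with `rho`, `nPairsCompared` and `condition`.
#' @export
spearmanMatrices <- function(D1, D2, condition = list()) {
  tr <- .matchedTriangles(D1, D2)
  if (stats::sd(tr$u1) == 0 || stats::sd(tr$u2) == 0)
    stop("zero variance in a distance vector; correlation undefined")
  list(rho = cor(tr$u1, tr$u2, method = "spearman"),
       nPairsCompared = length(tr$u1), condition = condition)
}

#' Per-pair absolute difference summary of two distance matrices
#'
#' Median, mean and maximum of `|d1 - d2|` over the upper triangle; used to
#' quantify the cost of sketching or abundance filtering against the exact
#' distances.
#'
#' @inheritParams spearmanMatrices
#' @return named numeric vector `c(median, mean, max)`.
#' @export
absDifferenceSummary <- function(D1, D2) {
  tr <- .matchedTriangles(D1, D2)
  d <- abs(tr$u1 - tr$u2)
  c(median = median(d), mean = mean(d), max = max(d))
}

#' Filter low-abundance taxa from a profile collection
#'
#' Removes taxa whose maximum relative abundance across samples is below
#' `minRelAbund` or whose prevalence (fraction of samples with positive
#' abundance) is below `minPrevalence`, then renormalizes each profile;
#' the pre-clustering cleanup used on real profile collections (defaults:
#' abundance < 0.01%, prevalence < 0.1%).
#'
#' @param profiles list of [CommunityProfile-class] objects.
#' @param minRelAbund minimum retained maximum relative abundance.
#' @param minPrevalence minimum retained prevalence, in \[0, 1\].
#' @return list of renormalized [CommunityProfile-class] objects.
#' @export
filterLowAbundance <- function(profiles, minRelAbund = 1e-4,
                               minPrevalence = 1e-3) {
  stopifnot(all(vapply(profiles, is, TRUE, "CommunityProfile")))
  if (minRelAbund < 0 || minRelAbund > 1 || minPrevalence < 0 ||
      minPrevalence > 1)
    stop("thresholds must lie in [0, 1]")
  taxa <- unique(unlist(lapply(profiles, function(p) names(p@abundances))))
  A <- vapply(profiles, function(p) {
    v <- p@abundances[match(taxa, names(p@abundances))]
    v[is.na(v)] <- 0
    v
  }, numeric(length(taxa)))
  A <- matrix(A, nrow = length(taxa), dimnames = list(taxa, NULL))
  keep <- apply(A, 1, max) >= minRelAbund &
    rowMeans(A > 0) >= minPrevalence
  if (!any(keep)) stop("all taxa removed by the filter")
  lapply(profiles, function(p) {
    ab <- p@abundances[names(p@abundances) %in% taxa[keep]]
    if (length(ab) == 0L || sum(ab) == 0)
      stop("sample ", p@sampleId, " lost all taxa")
    new("CommunityProfile", sampleId = p@sampleId, abundances = ab / sum(ab))
  })
}

#' Ward-D2 hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with Ward-D2 linkage (squared-distance
#' Lance-Williams update) cut into `nClusters` groups.
#'
#' @param D labeled symmetric distance matrix.
#' @param nClusters number of clusters (<= number of samples).
#' @return named integer vector of cluster labels.
#' @export
wardClusters <- function(D, nClusters) {
  .checkDistanceMatrix(D)
  if (nClusters > nrow(D)) stop("nClusters exceeds the number of samples")
  cutree(hclust(as.dist(D), method = "ward.D2"), k = nClusters)
}

#' Cluster purity against true sample groups
#'
#' Each cluster is assigned the group most frequent inside it; purity is
#' the fraction of samples whose group matches their cluster's assignment.
#' Purity is bounded below by the majority-group fraction and above by 1.
#'
#' @param labels named cluster labels (e.g. from [wardClusters()]).
#' @param groups named true group labels over the same samples.
#' @return purity in \[0, 1\].
#' @export
clusterPurity <- function(labels, groups) {
  if (length(labels) == 0L) stop("empty clustering")
  if (!is.null(names(labels)) && !is.null(names(groups))) {
    if (!setequal(names(labels), names(groups)))
      stop("labels and groups cover different samples")
    groups <- groups[names(labels)]
  } else if (length(labels) != length(groups)) {
    stop("labels and groups must have equal length")
  }
  correct <- sum(vapply(split(as.character(groups), labels),
                        function(g) max(table(g)), numeric(1)))
  correct / length(labels)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (pseudo-F from the
#' partitioned sums of squared distances, significance by permuting group
#' labels); computed via [vegan::adonis2()] with the add-one permutation
#' p-value `(1 + #{F* >= F}) / (1 + nPermutations)`.
#'
#' @param D labeled symmetric distance matrix.
#' @param groups group label per sample (named or in matrix order).
#' @param nPermutations number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list with `pseudoF`, `R2`, `pValue`, `nPermutations`.
#' @export
permanova <- function(D, groups, nPermutations = 999, seed = 1) {
  .checkDistanceMatrix(D)
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), rownames(D)))
      stop("group names do not match the distance matrix")
    groups <- groups[rownames(D)]
  }
  if (length(groups) != nrow(D))
    stop("need one group label per sample")
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("every group must be non-empty")
  fit <- .withSeed(seed,
    adonis2(as.dist(D) ~ grp, data = data.frame(grp = groups),
            permutations = nPermutations))
  list(pseudoF = fit$F[1], R2 = fit$R2[1], pValue = fit$`Pr(>F)`[1],
       nPermutations = nPermutations)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns coordinates
#' scaled by the square roots of the positive eigenvalues. Axes are
#' restricted to positive eigenvalues; negative eigenvalues (non-Euclidean
#' distances) are reported alongside.
#'
#' @param D labeled symmetric distance matrix.
#' @param nAxes number of axes requested (< number of samples).
#' @return list with `coordinates` (samples x axes) and `eigenvalues`
#'   (all n - 1).
#' @export
pcoa <- function(D, nAxes = 2) {
  .checkDistanceMatrix(D)
  if (nAxes >= nrow(D)) stop("nAxes must be smaller than the sample count")
  fit <- cmdscale(as.dist(D), k = nAxes, eig = TRUE)
  pos <- sum(fit$eig > sqrt(.Machine$double.eps))
  keep <- seq_len(min(nAxes, pos))
  coords <- fit$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("PCo", keep)
  list(coordinates = coords, eigenvalues = fit$eig)
}
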