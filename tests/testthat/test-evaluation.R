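# distance-based one-way pseudo-F, written independently of vegan
# (Anderson's partitioning of squared interpoint distances)
oracleF <- function(D, groups) {
  groups <- factor(groups)
  n <- nrow(D); a <- nlevels(groups)
  SST <- sum(D^2) / (2 * n)
  SSW <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    SSW <- SSW + sum(D[idx, idx]^2) / (2 * length(idx))
  }
  ((SST - SSW) / (a - 1)) / (SSW / (n - a))
}

test_that("upperTriangle returns the label-sorted row-major pair vector", {
  D <- distMat(c("b", "a", "c"), c(0.1, 0.2, 0.3))
  # after sorting labels to a, b, c the pairs are (a,b), (a,c), (b,c)
  expect_equal(upperTriangle(D),
               c(D["a", "b"], D["a", "c"], D["b", "c"]))
  expect_equal(upperTriangle(t(D)), upperTriangle(D))
  expect_length(upperTriangle(distMat(letters[1:2], 0.5)), 1)
  expect_length(upperTriangle(distMat(letters[1:5], runif(10))), 10)
  bad <- distMat(c("a", "b"), 0.5); bad[1, 2] <- 0.6
  expect_error(upperTriangle(bad), "symmetric")
})

test_that("spearmanMatrices matches a naive rank correlation", {
  set.seed(3)
  labels <- sprintf("s%02d", 1:10)
  D1 <- distMat(labels, runif(45))
  D2 <- distMat(labels, runif(45))
  got <- spearmanMatrices(D1, D2)
  u1 <- upperTriangle(D1); u2 <- upperTriangle(D2)
  # naive: average ranks then plain Pearson
  naiveRho <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(got$rho, naiveRho(u1, u2), tolerance = 1e-12)
  expect_equal(got$nPairsCompared, 45)
  expect_equal(spearmanMatrices(D1, D1)$rho, 1)
  inv <- 1 - D1; diag(inv) <- 0
  expect_equal(spearmanMatrices(D1, inv)$rho, -1)
  # a strictly monotone transform preserves rho = 1
  mono <- D1^3
  expect_equal(spearmanMatrices(D1, mono)$rho, 1)
  expect_error(spearmanMatrices(D1, distMat(letters[1:10], runif(45))),
               "different sample ids")
  flat <- distMat(labels, rep(0.5, 45))
  expect_error(spearmanMatrices(D1, flat), "zero variance")
})

test_that("absolute difference summaries are computed per pair", {
  labels <- letters[1:4]
  u <- c(0.2, 0.4, 0.6, 0.3, 0.5, 0.7)
  D1 <- distMat(labels, u)
  expect_equal(unname(absDifferenceSummary(D1, D1)),
               c(0, 0, 0))
  D2 <- distMat(labels, u + 0.1)
  expect_equal(absDifferenceSummary(D1, D2)[["median"]], 0.1)
  D3 <- distMat(letters[1:3], c(0.1, 0.2, 0.4))
  D4 <- distMat(letters[1:3], c(0.3, 0.1, 0.4))
  expect_equal(unname(absDifferenceSummary(D3, D4)),
               c(median(c(0.2, 0.1, 0)), mean(c(0.2, 0.1, 0)), 0.2))
})

test_that("low-abundance filtering removes rare taxa and renormalizes", {
  profs <- list(
    profileFromVector(c(t1 = 0.5, t2 = 0.4999, rare = 1e-6), "p1"),
    profileFromVector(c(t1 = 0.7, t2 = 0.3), "p2"))
  out <- filterLowAbundance(profs, minRelAbund = 1e-4,
                            minPrevalence = 1e-3)
  expect_false("rare" %in% names(abundances(out[[1]])))
  expect_equal(sum(abundances(out[[1]])), 1, tolerance = 1e-12)
  # zero thresholds are the identity
  same <- filterLowAbundance(profs, 0, 0)
  expect_equal(abundances(same[[1]]), abundances(profs[[1]]))
  # prevalence filter: taxon in 1 of 2 samples has prevalence 0.5
  out2 <- filterLowAbundance(list(
    profileFromVector(c(t1 = 0.9, solo = 0.1), "q1"),
    profileFromVector(c(t1 = 1), "q2")), 0, 0.6)
  expect_false("solo" %in% names(abundances(out2[[1]])))
  expect_error(filterLowAbundance(profs, 1, 1), "all taxa removed")
})

test_that("Ward clustering separates well-separated blobs", {
  labels <- sprintf("s%d", 1:6)
  D <- matrix(0.9, 6, 6, dimnames = list(labels, labels))
  D[1:3, 1:3] <- 0.1; D[4:6, 4:6] <- 0.1
  diag(D) <- 0
  cl <- wardClusters(D, 2)
  expect_length(unique(cl[1:3]), 1)
  expect_length(unique(cl[4:6]), 1)
  expect_false(cl[1] == cl[4])
  expect_equal(length(unique(wardClusters(D, 6))), 6)
  expect_error(wardClusters(D, 7), "exceeds")
})

test_that("cluster purity implements the majority-assignment formula", {
  groups <- c(a = "g1", b = "g1", c = "g2", d = "g2", e = "g2")
  perfect <- c(a = 1, b = 1, c = 2, d = 2, e = 2)
  expect_equal(clusterPurity(perfect, groups), 1)
  # cluster 1 = {g1, g1, g2} -> g1 (2 correct); cluster 2 = {g2, g2}
  mixed <- c(a = 1, b = 1, c = 1, d = 2, e = 2)
  expect_equal(clusterPurity(mixed, groups), 4 / 5)
  # one cluster over two balanced groups: majority fraction
  one <- setNames(rep(1, 4), letters[1:4])
  bal <- setNames(c("x", "x", "y", "y"), letters[1:4])
  expect_equal(clusterPurity(one, bal), 0.5)
  # bounds: majority fraction <= purity <= 1
  set.seed(8)
  for (i in 1:5) {
    g <- setNames(sample(c("u", "v", "w"), 12, replace = TRUE),
                  sprintf("s%d", 1:12))
    cl <- setNames(sample(1:4, 12, replace = TRUE), names(g))
    p <- clusterPurity(cl, g)
    expect_gte(p, max(table(g)) / 12)
    expect_lte(p, 1)
  }
  expect_error(clusterPurity(integer(0), character(0)), "empty")
})

test_that("PERMANOVA pseudo-F matches an exhaustive brute-force oracle", {
  set.seed(12)
  labels <- sprintf("s%d", 1:6)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(labels, labels)
  groups <- setNames(rep(c("g1", "g2"), each = 3), labels)
  fit <- permanova(D, groups, nPermutations = 999, seed = 5)
  expect_equal(fit$pseudoF, oracleF(D, groups), tolerance = 1e-10)
  # exhaustive null over all 6! label orders
  allIdx <- expand.grid(rep(list(1:6), 6))
  allIdx <- as.matrix(allIdx[apply(allIdx, 1, function(r)
    length(unique(r)) == 6), ])
  Fs <- apply(allIdx, 1, function(ord) oracleF(D, groups[ord]))
  pExh <- mean(Fs >= fit$pseudoF - 1e-12)
  expect_lt(abs(fit$pValue - pExh), 0.06)
  expect_gte(fit$pValue, 1 / 1000)
  expect_true(fit$R2 >= 0 && fit$R2 <= 1)
})

test_that("PERMANOVA flags clear structure and stays calibrated at null", {
  labels <- sprintf("s%d", 1:10)
  D <- matrix(0.9, 10, 10, dimnames = list(labels, labels))
  D[1:5, 1:5] <- 0.05; D[6:10, 6:10] <- 0.05
  diag(D) <- 0
  groups <- rep(c("a", "b"), each = 5)
  fit <- permanova(D, groups, nPermutations = 999, seed = 1)
  # only partition-preserving permutations can reproduce F, so p sits near
  # the attainable floor (~2 * (5!)^2 / 10! plus the add-one term)
  expect_lte(fit$pValue, 0.02)
  expect_gte(fit$pValue, 0.001)
  # null: random labels on unstructured distances -> roughly uniform p
  set.seed(44)
  ps <- vapply(1:20, function(i) {
    Dn <- distMat(labels, runif(45, 0.3, 0.8))
    permanova(Dn, sample(groups), nPermutations = 99, seed = i)$pValue
  }, 0)
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.8)
  expect_error(permanova(D, rep("a", 10)), "at least 2 groups")
  expect_error(permanova(D, groups[1:4]), "one group label per sample")
})

test_that("PCoA recovers planted configurations", {
  set.seed(21)
  pts <- cbind(rnorm(8), rnorm(8))
  labels <- sprintf("s%d", 1:8)
  D <- as.matrix(dist(pts)); dimnames(D) <- list(labels, labels)
  fit <- pcoa(D, nAxes = 2)
  X <- scale(fit$coordinates, scale = FALSE)
  Y <- scale(pts, scale = FALSE)
  # optimal rotation (orthogonal Procrustes); planted configuration must
  # be recovered up to rotation/reflection
  sv <- svd(crossprod(X, Y))
  R <- sv$u %*% t(sv$v)
  expect_lt(max(abs(X %*% R - Y)), 1e-8)
  # eigenvalue sum equals the total centered variance (trace identity)
  expect_equal(sum(fit$eigenvalues), sum(upperTriangle(D)^2) / 8,
               tolerance = 1e-10)
  # duplicate samples land on identical coordinates
  D2 <- rbind(cbind(D, dup = D[, 1]), dup = c(D[1, ], 0))
  rownames(D2) <- colnames(D2) <- c(labels, "dup")
  fit2 <- pcoa(D2, nAxes = 2)
  expect_equal(fit2$coordinates["dup", ], fit2$coordinates["s1", ],
               tolerance = 1e-8)
  expect_error(pcoa(D, nAxes = 8), "smaller")
})
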