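test_that("sample outlier exclusion matches direct connectivity z-scores", {
  set.seed(21)
  v <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:20)))
  base <- rnorm(50)
  v <- v + base                      # shared signal so correlations vary
  v[, "s7"] <- rnorm(50, mean = 10)  # one extreme sample
  res <- detectSampleOutliers(ExprMatrix(v, "log2fpkm1"))
  # brute-force recomputation of the standardized connectivity
  C <- cor(v)
  conn <- rowSums(C) - 1
  z <- (conn - mean(conn)) / sd(conn)
  expect_identical(res$excluded, names(z)[z < -2.5])
  expect_identical(res$excluded, "s7")
  expect_equal(unname(res$zscores), unname(z))

  # homogeneous samples: nothing excluded
  hom <- matrix(rnorm(40 * 8), 40, 8) + base[1:40]
  colnames(hom) <- sprintf("s%d", 1:8); rownames(hom) <- sprintf("g%d", 1:40)
  expect_length(detectSampleOutliers(ExprMatrix(hom, "log2fpkm1"))$excluded, 0L)
  expect_error(detectSampleOutliers(ExprMatrix(hom[, 1:3], "log2fpkm1")),
               "4 samples")
})

test_that("planted large-scale outliers are excluded to the expected sample count", {
  set.seed(31)
  nGene <- 100; nSample <- 475
  baseline <- rnorm(nGene, sd = 3)   # shared gene baseline correlates samples
  v <- baseline + matrix(rnorm(nGene * nSample), nGene, nSample)
  dimnames(v) <- list(sprintf("g%d", 1:nGene), sprintf("s%d", 1:nSample))
  # two outliers: independent profiles with a 10-noise-SD mean shift
  v[, c(10, 200)] <- matrix(rnorm(nGene * 2, mean = 10, sd = 3), nGene, 2)
  res <- detectSampleOutliers(ExprMatrix(v, "log2fpkm1"))
  expect_equal(ncol(res$matrix), 473L)
  expect_identical(sort(res$excluded), sort(colnames(v)[c(10, 200)]))
})

test_that("soft-threshold pick agrees with an independent scale-free fit", {
  cfg <- synthConfig(41, nBackground = 60, noiseSd = 0.4)
  sim <- genModuleExpression(c(40, 30), 60, 0.9, cfg)
  params <- coexpressionParams(candidatePowers = 1:12)
  st <- pickSoftThreshold(sim$matrix, params)
  # independent recomputation: fresh adjacency, equal-count binning, lm
  v <- exprValues(sim$matrix)
  fits <- vapply(params$candidatePowers, function(p) {
    k <- rowSums(abs(cor(t(v)))^p) - 1   # remove self term |cor|^p = 1
    br <- unique(quantile(k, seq(0, 1, 0.1)))
    bin <- cut(k, br, include.lowest = TRUE)
    fr <- as.numeric(table(bin)); mk <- tapply(k, bin, mean)
    keep <- fr > 0 & !is.na(mk)
    m <- lm(log10(fr[keep]) ~ log10(mk[keep]))
    -sign(coef(m)[2]) * suppressWarnings(summary(m)$r.squared)
  }, numeric(1))
  expect_equal(unname(st$fit$signedR2), unname(fits), tolerance = 1e-10)
  qualifying <- params$candidatePowers[fits >= 0.8]
  if (length(qualifying)) {
    expect_true(st$reached)
    expect_equal(st$beta, min(qualifying))
  } else {
    expect_false(st$reached)
    expect_equal(st$beta, params$candidatePowers[which.max(fits)])
  }
})

test_that("pure noise reaches no scale-free fit and is flagged", {
  set.seed(5)
  v <- matrix(rnorm(80 * 40), 80, 40,
              dimnames = list(sprintf("g%d", 1:80), sprintf("s%d", 1:40)))
  st <- pickSoftThreshold(ExprMatrix(v, "log2fpkm1"),
                          coexpressionParams(candidatePowers = 1:6))
  expect_false(st$reached)
})

test_that("duplicated genes keep connectivity at least 1 at every power", {
  set.seed(6)
  v <- matrix(rnorm(12 * 20), 12, 20)
  v[2, ] <- v[1, ]; v[4, ] <- -v[3, ]
  rownames(v) <- sprintf("g%d", 1:12); colnames(v) <- sprintf("s%d", 1:20)
  for (beta in c(1, 5, 14)) {
    A <- adjacencyMatrix(v, beta)
    expect_true(all(rowSums(A)[1:4] >= 1))
  }
})

test_that("adjacency equals |cor|^beta with zero diagonal", {
  set.seed(7)
  v <- matrix(rnorm(10 * 15), 10, 15,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:15)))
  for (beta in c(1, 2, 7)) {
    A <- adjacencyMatrix(v, beta)
    ref <- abs(cor(t(v)))^beta
    diag(ref) <- 0
    expect_equal(A, ref, tolerance = 1e-12)
    expect_true(all(A >= 0 & A <= 1))
    expect_true(isSymmetric(A))
  }
  # |cor| = 0.5 cases: anti-correlated pair at beta 1, correlated at beta 2
  x <- c(1, -1, 0, 2); y <- c(-1, 0, 1, -2)   # cor = -0.877...: build exact
  a <- c(1, 0, -1, 0); b <- c(-0.5, 1, 0.5, -1)  # cor(a, b) = -0.5 exactly?
  expect_equal(abs(cor(a, b))^1, adjacencyMatrix(rbind(g1 = a, g2 = b), 1)[1, 2])
  expect_equal(abs(cor(a, b))^2, adjacencyMatrix(rbind(g1 = a, g2 = b), 2)[1, 2])
  expect_error(adjacencyMatrix(rbind(g1 = rep(1, 4), g2 = b), 2), "constant")
})

test_that("TOM matches hand-computed and brute-force values", {
  A <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A[1, 2] <- A[2, 1] <- 0.5
  A[1, 3] <- A[3, 1] <- 0.5
  tom <- tomSimilarity(A)
  expect_equal(tom["a", "b"], 0.5)      # (0 + 0.5) / (min(1, .5) + 1 - .5)
  expect_equal(diag(tom), c(a = 1, b = 1, c = 1))
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(tomSimilarity(tri)[1, 2], 1)  # (1 + 1) / (2 + 1 - 1)
  zero <- matrix(0, 4, 4)
  expect_true(all(tomSimilarity(zero)[upper.tri(zero)] == 0))
  for (trial in 1:25) {
    A <- randomAdjacency(sample(3:15, 1), seed = trial)
    tom <- tomSimilarity(A)
    expect_equal(tom, bruteTom(A), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(tom))
  }
  expect_error(tomSimilarity(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(tomSimilarity(matrix(c(0.5, 0.2, 0.2, 0), 2, 2)), "diagonal")
})

test_that("module detection recovers planted blocks and applies the size rule", {
  cfg <- synthConfig(51, nBackground = 0, noiseSd = 0.3)
  sim <- genModuleExpression(c(40, 40), 80, 0.9, cfg)
  A <- adjacencyMatrix(sim$matrix, 6)
  cl <- clusterModules(tomSimilarity(A))
  expect_equal(sort(unique(cl$labels)), c(1L, 2L))
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cl$labels, sim$labels), 1)
})

test_that("blocks below the minimum module size stay unassigned", {
  cfg <- synthConfig(52, nBackground = 40, noiseSd = 0.3)
  sim <- genModuleExpression(c(10), 60, 0.9, cfg)
  A <- adjacencyMatrix(sim$matrix, 6)
  cl <- clusterModules(tomSimilarity(A))
  expect_true(all(cl$labels == 0L))
  # fewer genes than minModuleSize: warn and unassign
  tiny <- genModuleExpression(c(5), 30, 0.9,
                              synthConfig(53, nBackground = 0, noiseSd = 0.2))
  expect_warning(res <- clusterModules(tomSimilarity(
    adjacencyMatrix(tiny$matrix, 6))), "minModuleSize")
  expect_true(all(res$labels == 0L))
})

test_that("identical genes cluster into a single module", {
  set.seed(9)
  base <- rnorm(40)
  v <- t(replicate(35, base))
  rownames(v) <- sprintf("g%d", 1:35); colnames(v) <- sprintf("s%d", 1:40)
  tom <- tomSimilarity(adjacencyMatrix(v, 6))
  cl <- clusterModules(tom)
  expect_equal(unique(cl$labels), 1L)
})

test_that("module eigengenes match a direct SVD and obey the sign rule", {
  cfg <- synthConfig(61, nBackground = 0, noiseSd = 0.5)
  sim <- genModuleExpression(c(20, 15), 30, 0.8, cfg)
  labels <- sim$labels
  me <- moduleEigengenes(sim$matrix, labels)
  expect_equal(dim(me$eigengenes), c(2L, 30L))
  v <- exprValues(sim$matrix)
  for (m in 1:2) {
    z <- t(scale(t(v[names(labels)[labels == m], ])))
    sv <- svd(t(z))
    eg <- me$eigengenes[m, ]
    expect_equal(sum(eg^2), 1)
    expect_equal(abs(sum(eg * sv$u[, 1])), 1, tolerance = 1e-8)
    expect_equal(me$varExplained[[m]], sv$d[1]^2 / sum(sv$d^2))
    expect_gte(cor(eg, colMeans(z)), 0)
  }
  # rank-1 module: eigengene correlates perfectly with each member
  one <- genModuleExpression(c(6), 12, 1,
                             synthConfig(62, nBackground = 0, noiseSd = 0))
  m1 <- moduleEigengenes(one$matrix, one$labels)
  expect_equal(abs(cor(m1$eigengenes[1, ], exprValues(one$matrix)[1, ])), 1)
  # zero-variance member rejected
  bad <- exprValues(sim$matrix)
  bad[1, ] <- 3
  expect_error(moduleEigengenes(bad, labels), "zero-variance")
})

test_that("eigengene variance explained for noise modules matches direct SVD", {
  set.seed(63)
  v <- matrix(rnorm(25 * 40), 25, 40,
              dimnames = list(sprintf("g%d", 1:25), sprintf("s%d", 1:40)))
  labels <- setNames(rep(1L, 25), rownames(v))
  me <- moduleEigengenes(v, labels)
  sv <- svd(t(t(scale(t(v)))))
  expect_equal(me$varExplained[[1]], sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-8)
})

test_that("eigengene merging stops exactly at the correlation threshold", {
  cfg <- synthConfig(71, nBackground = 0, noiseSd = 0.2)
  # two modules driven by the same factor: eigengene correlation near 1
  sim <- genModuleExpression(c(30), 50, 0.9, cfg)
  v <- exprValues(sim$matrix)
  labels <- setNames(c(rep(1L, 15), rep(2L, 15)), rownames(v))
  merged <- mergeModules(v, labels)
  expect_equal(unique(merged[merged > 0]), 1L)

  # independent modules: eigengene correlation far below 0.75
  two <- genModuleExpression(c(15, 15), 50, 0.9, cfg)
  kept <- mergeModules(exprValues(two$matrix), two$labels)
  expect_equal(sort(unique(kept[kept > 0])), c(1L, 2L))

  # three near-duplicate modules: post-condition + idempotence
  tri <- genModuleExpression(c(45), 50, 0.95,
                             synthConfig(72, nBackground = 0, noiseSd = 0.1))
  lab3 <- setNames(rep(1:3, each = 15), rownames(exprValues(tri$matrix)))
  m3 <- mergeModules(exprValues(tri$matrix), lab3)
  final <- moduleEigengenes(exprValues(tri$matrix), m3)$eigengenes
  if (nrow(final) > 1) {
    C <- cor(t(final))
    expect_true(all(C[upper.tri(C)] <= 0.75))
  }
  expect_identical(mergeModules(exprValues(tri$matrix), m3), m3)
})

test_that("the full pipeline is deterministic and recovers planted labels", {
  cfg <- synthConfig(81, nBackground = 100, noiseSd = 0.4)
  sim <- genModuleExpression(c(50, 40, 30), 100, 0.9, cfg)
  r1 <- runCoexpression(sim$matrix)
  r2 <- runCoexpression(sim$matrix)
  expect_identical(r1$labels, r2$labels)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(r1$labels, sim$labels), 0.8)
})
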