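test_that("log-Z standardization yields mean-0, SD-1 rows", {
  set.seed(8)
  m <- matrix(rexp(60, rate = 1e-4), 10, 6,
              dimnames = list(paste0("met", 1:10), paste0("s", 1:6)))
  z <- logZscore(m)
  expect_equal(unname(rowMeans(z)), rep(0, 10), tolerance = 1e-10)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 10), tolerance = 1e-10)
})

test_that("constant features are dropped with a warning", {
  m <- rbind(a = c(5, 5, 5), b = c(1, 2, 3))
  expect_warning(z <- logZscore(m, pseudocount = 1), "zero-variance")
  expect_equal(rownames(z), "b")
  expect_error(logZscore(matrix(1, 2, 1)), "2 samples")
})

test_that("a 2x3 toy matrix standardizes to hand-computed values", {
  m <- rbind(f1 = c(1, 3, 7), f2 = c(10, 10, 40))
  z <- logZscore(m, pseudocount = 1)
  l <- log(c(1, 3, 7) + 1)
  expect_equal(unname(z["f1", ]), (l - mean(l)) / sd(l), tolerance = 1e-12)
})

test_that("identical items merge first at height zero", {
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  cl <- hierarchicalCluster(m, axis = "features")
  expect_equal(cl$tree$height[1], 0)
  first <- cl$tree$merge[1, ]
  expect_setequal(cl$tree$labels[-first], c("a", "b"))
})

test_that("average-linkage heights match the brute-force UPGMA oracle", {
  set.seed(13)
  for (rep in 1:5) {
    m <- matrix(rnorm(16), 4, 4,
                dimnames = list(letters[1:4], LETTERS[1:4]))
    cl <- hierarchicalCluster(m, axis = "features")
    expect_equal(sort(cl$tree$height),
                 sort(oracleUpgmaHeights(dist(m))), tolerance = 1e-10)
  }
})

test_that("clustering is invariant to input row order", {
  set.seed(14)
  m <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:5)))
  ref <- hierarchicalCluster(m, axis = "features")
  for (shuffle in 1:10) {
    perm <- sample(nrow(m))
    cl <- hierarchicalCluster(m[perm, ], axis = "features")
    expect_identical(cl$order, ref$order)
    expect_equal(as.matrix(cophenetic(cl$tree))[rownames(m), rownames(m)],
                 as.matrix(cophenetic(ref$tree))[rownames(m), rownames(m)],
                 tolerance = 1e-12)
  }
  mNA <- m; mNA[2, 3] <- NA
  expect_error(hierarchicalCluster(mNA, axis = "features"), "f2")
})

test_that("PCA identifies rank-1 structure and satisfies SVD identities", {
  # samples exactly on a line through feature space
  direction <- c(1, 2, 3, 4)
  m <- outer(direction, c(-2, -1, 0, 1, 2))
  rownames(m) <- paste0("f", 1:4); colnames(m) <- paste0("s", 1:5)
  pc <- pcaScores(m, k = 3)
  expect_equal(pc$varianceExplained[1], 1, tolerance = 1e-9)
  expect_true(all(diff(pc$varianceExplained) <= 1e-12))
  expect_lte(sum(pc$varianceExplained), 1 + 1e-12)
  # full reconstruction of the centered data
  set.seed(15)
  m2 <- matrix(rnorm(30), 6, 5)
  dimnames(m2) <- list(paste0("f", 1:6), paste0("s", 1:5))
  pc2 <- pcaScores(m2, k = 5)
  centered <- scale(t(m2), center = TRUE, scale = FALSE)  # samples x features
  expect_equal(pc2$scores %*% t(pc2$loadings), unname(centered),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(unname(crossprod(pc2$loadings)), diag(5), tolerance = 1e-8)
  expect_error(pcaScores(m2, k = 0), ">= 1")
  expect_error(pcaScores(m2, k = 10), "exceeds")
})

test_that("identical groups yield no differential features", {
  set.seed(16)
  base <- matrix(rexp(50 * 3, 1e-4), 50, 3)
  m <- cbind(base, base)
  colnames(m) <- paste0("s", 1:6)
  rownames(m) <- paste0("f", 1:50)
  groups <- setNames(rep(c("case", "ctrl"), each = 3), colnames(m))
  d <- differentialFeatures(m, groups, "case", "ctrl")
  expect_false(any(d$passes))
  expect_equal(d$fold_change, rep(1, 50))
})

test_that("planted fold changes are recovered exactly at low noise", {
  set.seed(17)
  n <- 100
  base <- exp(rnorm(n, 10, 1))
  noise <- function() exp(matrix(rnorm(n * 3, 0, 0.05), n, 3))
  ctrl <- base * noise()
  case <- base * noise()
  planted <- 1:10
  case[planted, ] <- case[planted, ] * 2
  m <- cbind(case, ctrl)
  dimnames(m) <- list(paste0("f", 1:n), paste0("s", 1:6))
  groups <- setNames(rep(c("case", "ctrl"), each = 3), colnames(m))
  d <- differentialFeatures(m, groups, "case", "ctrl")
  expect_setequal(d$feature[d$passes], paste0("f", planted))
})

test_that("zero control means are flagged and passed on p alone", {
  m <- rbind(f1 = c(10, 12, 11, 0, 0, 0), f2 = c(5, 6, 5, 5, 6, 5))
  colnames(m) <- paste0("s", 1:6)
  groups <- setNames(rep(c("case", "ctrl"), each = 3), colnames(m))
  expect_warning(d <- differentialFeatures(m, groups, "case", "ctrl"),
                 "zero control mean")
  expect_true(is.infinite(d$fold_change[1]))
})

test_that("swapping case and control inverts fold changes", {
  set.seed(18)
  sim <- simulateExpression(50, plantedPrograms = list(
    A = sprintf("GENE%04d", 1:5), B = character()), seed = 30)
  d1 <- callDegs(sim$matrix, sim$groups, "A", "B")$records
  d2 <- callDegs(sim$matrix, sim$groups, "B", "A")$records
  expect_equal(d1$fold_change, 1 / d2$fold_change, tolerance = 1e-10)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
})

test_that("row t-tests agree with stats::t.test", {
  set.seed(19)
  x <- matrix(rnorm(30), 5, 6)
  dimnames(x) <- list(paste0("f", 1:5), paste0("s", 1:6))
  groups <- setNames(rep(c("a", "b"), each = 3), colnames(x))
  d <- differentialFeatures(x - min(x) + 1, groups, "a", "b",
                            log2Input = TRUE)
  for (i in 1:5) {
    ref <- t.test((x - min(x) + 1)[i, 1:3], (x - min(x) + 1)[i, 4:6],
                  var.equal = TRUE)$p.value
    expect_equal(d$p_value[i], ref, tolerance = 1e-12)
  }
  dW <- differentialFeatures(x - min(x) + 1, groups, "a", "b",
                             log2Input = TRUE, varEqual = FALSE)
  refW <- t.test((x - min(x) + 1)[2, 1:3], (x - min(x) + 1)[2, 4:6])$p.value
  expect_equal(dW$p_value[2], refW, tolerance = 1e-12)
})

test_that("overrepresentation p-values match the hypergeometric tail oracle", {
  universe <- sprintf("g%03d", 1:100)
  collection <- list(setA = universe[1:10], setB = universe[11:40])
  selected <- c(universe[1:8], universe[50:51])
  rec <- oraFisher(selected, universe, collection)
  rowA <- rec[rec$set == "setA", ]
  expect_equal(rowA$k, 8)
  expect_equal(rowA$p_value, oracleHyperTail(8, 10, 10, 100),
               tolerance = 1e-12)
  # matches one-sided fisher.test as an independent cross-check
  ft <- fisher.test(matrix(c(8, 2, 2, 88), 2), alternative = "greater")
  expect_equal(rowA$p_value, ft$p.value, tolerance = 1e-12)
})

test_that("selecting the whole universe gives p = 1 everywhere", {
  universe <- sprintf("g%02d", 1:30)
  collection <- list(s1 = universe[1:5], s2 = universe[6:20])
  rec <- oraFisher(universe, universe, collection)
  expect_equal(rec$p_value, rep(1, 2))
})

test_that("ORA rejects empty selections and skips non-overlapping sets", {
  universe <- sprintf("g%02d", 1:30)
  expect_error(oraFisher(character(), universe, list(s = universe[1:3])),
               "empty")
  rec <- oraFisher(universe[1:3], universe,
                   list(inU = universe[1:5], outU = c("x1", "x2")))
  expect_equal(rec$set, "inU")
})

test_that("a planted pathway attains the smallest adjusted p", {
  set.seed(20)
  universe <- sprintf("MB%04d", 1:120)
  altered <- universe[1:15]
  db <- simulateTfDatabase(20, 12, universe, plantedTfs = "PLANTED",
                           degGenes = altered, plantedOverlapFraction = 0.8,
                           seed = 44)
  rec <- oraFisher(altered, universe, db$regulons)
  expect_equal(rec$set[1], "PLANTED")
  expect_true(all(rec$adjusted_p >= rec$p_value - 1e-15))
})
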