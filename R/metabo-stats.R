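#' Log-transform and row-standardize a feature matrix
#'
#' Per feature (row): `log(x + pseudocount)`, then subtract the row mean and
#' divide by the row sample standard deviation (Z-scoring, the usual
#' presentation for metabolite heatmaps). Rows with zero variance after the
#' log transform are dropped with a warning.
#'
#' @param m numeric matrix, features x samples, non-negative intensities.
#' @param pseudocount positive offset added before the log; default is half
#'   the smallest non-zero intensity in the matrix.
#' @return standardized matrix (possibly fewer rows); every remaining row
#'   has mean 0 and SD 1.
#' @examples
#' m <- matrix(rexp(12, 1e-3), 3, 4,
#'             dimnames = list(paste0("met", 1:3), paste0("s", 1:4)))
#' z <- logZscore(m)
#' rowMeans(z)
#' @export
logZscore <- function(m, pseudocount = NULL) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2L) stop("matrix must have >= 2 samples")
  if (any(m < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  if (is.null(pseudocount)) {
    nz <- m[m > 0]
    if (!length(nz)) stop("matrix has no positive entries")
    pseudocount <- min(nz) / 2
  }
  if (pseudocount <= 0) stop("'pseudocount' must be > 0")
  lg <- log(m + pseudocount)
  sds <- apply(lg, 1L, sd)
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    warning("dropping ", sum(flat), " zero-variance feature(s): ",
            paste(utils::head(rownames(m)[flat], 5L), collapse = ", "))
    lg <- lg[!flat, , drop = FALSE]
    sds <- sds[!flat]
  }
  (lg - rowMeans(lg)) / sds
}

#' Agglomerative hierarchical clustering with a deterministic order
#'
#' Average-linkage (UPGMA by default) agglomeration of the rows or columns
#' of a matrix. Items are sorted by identifier before clustering so equal
#' merge heights resolve to the pair with lexicographically smallest ids,
#' making tree and leaf order reproducible across platforms and input
#' orderings.
#'
#' @param m numeric matrix with row/column names.
#' @param axis `"features"` (rows) or `"samples"` (columns).
#' @param metric distance metric passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with `tree` (an `hclust`) and `order` (leaf labels in
#'   dendrogram order).
#' @examples
#' m <- matrix(rnorm(20), 5, 4, dimnames = list(letters[1:5], LETTERS[1:4]))
#' hierarchicalCluster(m, axis = "features")$order
#' @export
hierarchicalCluster <- function(m, axis = c("features", "samples"),
                                metric = "euclidean", linkage = "average") {
  axis <- match.arg(axis)
  x <- if (axis == "features") m else t(m)
  if (nrow(x) < 2L) stop("need >= 2 items on the clustered axis")
  if (is.null(rownames(x))) rownames(x) <- sprintf("item%03d", seq_len(nrow(x)))
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("NaN/NA in matrix at (%s, %s)",
                 rownames(x)[idx[1]], colnames(x)[idx[2]]))
  }
  x <- x[order(rownames(x)), , drop = FALSE]
  tree <- hclust(dist(x, method = metric), method = linkage)
  list(tree = tree, order = tree$labels[tree$order])
}

#' Principal component analysis of samples
#'
#' Singular-value decomposition of the feature-centered matrix, with samples
#' as observations. Used to visualise the internal structure of a
#' metabolomics data set with respect to variance.
#'
#' @param m numeric matrix, features x samples.
#' @param k number of components to return (default 3).
#' @return list with `scores` (samples x k), `loadings` (features x k,
#'   orthonormal columns), `varianceExplained` (length-k fractions,
#'   non-increasing, summing to <= 1 over all possible components).
#' @examples
#' m <- matrix(rnorm(60), 10, 6,
#'             dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
#' pcaScores(m, k = 2)$varianceExplained
#' @export
pcaScores <- function(m, k = 3L) {
  stopifnot(is.matrix(m))
  if (k <= 0L) stop("'k' must be >= 1")
  kmax <- min(dim(m))
  if (k > kmax)
    stop(sprintf("'k' = %d exceeds min(features, samples) = %d", k, kmax))
  x <- t(m)                     # samples x features
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  ev <- sv$d^2
  varFrac <- ev / sum(ev)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- colnames(m)
  loadings <- sv$v
  rownames(loadings) <- rownames(m)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(sv$d))
  list(scores = scores[, seq_len(k), drop = FALSE],
       loadings = loadings[, seq_len(k), drop = FALSE],
       varianceExplained = varFrac[seq_len(k)])
}

# Vectorized two-sample t-test on matrix rows; pooled-variance Student by
# default (the classical two-tailed test), Welch-Satterthwaite optionally.
rowTTest <- function(x, y, varEqual = TRUE) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1L, var); v2 <- apply(y, 1L, var)
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  list(statistic = t, p = p, df = df, meanCase = m1, meanControl = m2)
}

#' Differential features by fold change and t-test
#'
#' For each feature, the fold change is the case/control ratio of group
#' means on the linear intensity scale, and the p-value comes from a
#' two-tailed two-sample t-test on log-transformed intensities (or directly
#' on the values when `log2Input = TRUE`, for matrices already on the log2
#' scale). A feature passes when the fold change is at least `fcCut` in
#' either direction *and* p < `pCut` - the classical 1.5-fold / p < 0.01
#' altered-feature filter.
#'
#' @param m numeric matrix, features x samples. Linear intensities unless
#'   `log2Input = TRUE`.
#' @param groups named character vector mapping sample -> group.
#' @param case,control group labels to compare.
#' @param fcCut linear fold-change cutoff (default 1.5).
#' @param pCut p-value cutoff (default 0.01).
#' @param varEqual pooled-variance Student t (default, the classical
#'   two-tailed Student test); `FALSE` for Welch.
#' @param log2Input if `TRUE`, `m` is on the log2 scale: the test runs on
#'   the values as-is and fold change is `2^(mean difference)`.
#' @param pseudocount offset for the log transform of linear data (default:
#'   half the smallest non-zero value).
#' @return data.frame with columns `feature`, `fold_change`, `log2_fc`,
#'   `p_value`, `passes`, `direction` (`"up"`/`"down"`). Features whose
#'   control mean is zero get infinite fold change, pass on p alone, and
#'   trigger a warning.
#' @examples
#' sim <- simulateExpression(200, plantedPrograms = list(
#'   EGFR = sprintf("GENE%04d", 1:10), WT = character()), seed = 1)
#' d <- differentialFeatures(sim$matrix, sim$groups, "EGFR", "WT",
#'                           log2Input = TRUE)
#' head(d[d$passes, ])
#' @export
differentialFeatures <- function(m, groups, case, control,
                                 fcCut = 1.5, pCut = 0.01,
                                 varEqual = TRUE, log2Input = FALSE,
                                 pseudocount = NULL) {
  stopifnot(is.matrix(m), !is.null(names(groups)))
  for (g in c(case, control))
    if (!g %in% groups) stop(sprintf("group '%s' absent from 'groups'", g))
  caseCols <- names(groups)[groups == case]
  ctrlCols <- names(groups)[groups == control]
  if (length(caseCols) < 2L || length(ctrlCols) < 2L)
    stop("each group needs >= 2 replicates")
  if (fcCut < 1) stop("'fcCut' must be >= 1")
  x <- m[, caseCols, drop = FALSE]
  y <- m[, ctrlCols, drop = FALSE]
  if (log2Input) {
    tt <- rowTTest(x, y, varEqual)
    log2fc <- tt$meanCase - tt$meanControl
    fc <- 2^log2fc
  } else {
    if (any(m < 0)) stop("linear intensities must be >= 0")
    if (is.null(pseudocount)) {
      nz <- m[m > 0]
      pseudocount <- if (length(nz)) min(nz) / 2 else 1
    }
    tt <- rowTTest(log(x + pseudocount), log(y + pseudocount), varEqual)
    mc <- rowMeans(x); mctl <- rowMeans(y)
    fc <- mc / mctl
    log2fc <- log2(fc)
  }
  infFc <- !is.finite(fc)
  if (any(infFc))
    warning(sum(infFc), " feature(s) with zero control mean: fold change ",
            "infinite, pass decided by p-value alone")
  fcPass <- infFc | fc >= fcCut | fc <= 1 / fcCut
  passes <- fcPass & tt$p < pCut
  data.frame(
    feature = rownames(m) %||% as.character(seq_len(nrow(m))),
    fold_change = fc,
    log2_fc = log2fc,
    p_value = tt$p,
    passes = passes,
    direction = ifelse(log2fc >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overrepresentation analysis by one-sided Fisher's exact test
#'
#' Tests each annotated set for enrichment of the selected features within
#' the universe using the hypergeometric tail (one-sided Fisher's exact
#' test, `alternative = "greater"`), then adjusts p-values across tested
#' sets with Benjamini-Hochberg. Sets are intersected with the universe
#' first; sets with zero universe overlap are skipped.
#'
#' @param selected character vector of selected feature ids (subset of
#'   `universe`; ids outside are dropped with a warning).
#' @param universe character vector of all measurable feature ids.
#' @param collection named list set id -> member ids.
#' @return data.frame with one row per tested set: `set`, `k` (overlap with
#'   selection), `K` (set size in universe), `n` (selection size), `N`
#'   (universe size), `odds_ratio` (sample odds ratio of the 2x2 table),
#'   `p_value`, `adjusted_p`; sorted by p-value.
#' @examples
#' sets <- list(ssp = c("PHGDH", "PSAT1", "PSPH"), glyc = c("HK2", "LDHA"))
#' oraFisher(c("PSPH", "PHGDH"), c(unlist(sets), "GAPDH", "ACTB"), sets)
#' @export
oraFisher <- function(selected, universe, collection) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  universe <- unique(universe)
  selected <- unique(selected)
  if (!length(selected)) stop("empty selection")
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    warning(length(outside), " selected id(s) outside the universe dropped")
    selected <- intersect(selected, universe)
    if (!length(selected)) stop("selection has no overlap with the universe")
  }
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(unique(collection[[id]]), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, selected))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    orNum <- k * (N - K - n + k)
    orDen <- (K - k) * (n - k)
    or <- if (orDen == 0) {
      if (orNum == 0) NaN else Inf
    } else orNum / orDen
    data.frame(set = id, k = k, K = K, n = n, N = N, odds_ratio = or,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no set overlaps the universe")
  out <- do.call(rbind, rows)
  out$adjusted_p <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$set), , drop = FALSE]
}
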