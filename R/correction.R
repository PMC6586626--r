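#' Build a natural-abundance correction matrix for a fragment
#'
#' Column `j` (0-based) of the matrix is the theoretical mass-shift spectrum
#' of the fragment when exactly `j` labelable positions carry tracer:
#' the convolution of (i) a Binomial(`j`, purity) over the labeled positions
#' (a tracer atom fails to be heavy with probability 1 - purity), (ii) the
#' natural-abundance distribution of the remaining tracer-element atoms, and
#' (iii) the natural-abundance distribution of every non-tracer atom,
#' including derivatization atoms (H, N, O, Si, ...). Spectra are truncated
#' to the measured window M0..Mn; the truncated mass is recorded per column,
#' not redistributed.
#'
#' @param fragment a [FragmentSpec-class].
#' @param abundances abundance table from [naturalAbundances()].
#' @param tracer a [TracerSpec-class]; its element must match the fragment's
#'   tracer element.
#' @param purityCorrection if `FALSE`, tracer purity is ignored (treated as
#'   exactly 1).
#' @param correctTracerElement if `FALSE`, natural abundance of the tracer
#'   element in unlabeled positions is *not* corrected for (only non-tracer
#'   atoms contribute); the default performs the full correction.
#' @return a [CorrectionMatrix-class].
#' @examples
#' frag <- fragmentSpec("lactate", "C11H25O3Si2", "C", 3)
#' m <- buildCorrectionMatrix(frag, tracer = defaultTracers()$glucose_u13c6)
#' correctionMatrix(m)
#' @export
buildCorrectionMatrix <- function(fragment,
                                  abundances = naturalAbundances(),
                                  tracer,
                                  purityCorrection = TRUE,
                                  correctTracerElement = TRUE) {
  stopifnot(is(fragment, "FragmentSpec"), is(tracer, "TracerSpec"))
  if (tracer@element != fragment@tracerElement)
    stop(sprintf("tracer element '%s' does not match fragment tracer element '%s'",
                 tracer@element, fragment@tracerElement))
  validateAbundances(abundances)
  n <- fragment@nLabelable
  el <- fragment@tracerElement
  purity <- if (purityCorrection) tracer@purity else 1
  # spectrum of all atoms that are natural regardless of j: non-tracer atoms,
  # plus (optionally) tracer-element atoms beyond the labelable positions
  if (correctTracerElement) {
    baseNonTracer <- formulaDistribution(fragment@formula, abundances,
                                         exclude = el, excludeCount = n)
  } else {
    noTracer <- fragment@formula[names(fragment@formula) != el]
    baseNonTracer <- formulaDistribution(noTracer, abundances)
  }
  natTracerOne <- abundances[[el]]
  mat <- matrix(0, nrow = n + 1L, ncol = n + 1L,
                dimnames = list(paste0("M", 0:n), paste0("j", 0:n)))
  loss <- numeric(n + 1L)
  for (j in 0:n) {
    col <- dbinom(0:j, j, purity)          # labeled positions at purity
    if (correctTracerElement && n - j > 0L) {
      natRest <- elementDistribution(el, n - j, abundances)
      col <- convolveDist(col, natRest)    # unlabeled labelable positions
    }
    col <- convolveDist(col, baseNonTracer)
    keep <- col[seq_len(min(length(col), n + 1L))]
    loss[j + 1L] <- 1 - sum(keep)
    mat[seq_along(keep), j + 1L] <- keep
  }
  new("CorrectionMatrix", matrix = mat, fragment = fragment,
      purity = purity, truncationLoss = pmax(loss, 0))
}

#' Correct a raw isotopologue spectrum for natural abundance
#'
#' Solves `M x ~ raw` by non-negative least squares (Lawson-Hanson, via
#' \pkg{pracma}), where `M` is the fragment's theoretical-spectrum matrix,
#' then renormalizes `x` to sum 1. NNLS rather than matrix inversion keeps
#' corrected fractions non-negative when measurement noise would otherwise
#' drive the inverted solution below zero.
#'
#' @param raw non-negative numeric vector of raw intensities M0..Mn.
#' @param m a [CorrectionMatrix-class] with matching dimension.
#' @return numeric vector of corrected isotopologue fractions (sums to 1),
#'   named M0..Mn, with attribute `residual` (Euclidean NNLS residual of the
#'   unit-scaled spectrum).
#' @examples
#' frag <- fragmentSpec("glycine", "C10H24NO2Si2", "C", 2)
#' m <- buildCorrectionMatrix(frag, tracer = defaultTracers()$glucose_u13c6)
#' correctMid(correctionMatrix(m)[, 1], m)  # pure M0 pool
#' @export
correctMid <- function(raw, m) {
  stopifnot(is(m, "CorrectionMatrix"))
  mat <- m@matrix
  if (length(raw) != nrow(mat))
    stop(sprintf("raw spectrum has %d entries but matrix expects %d",
                 length(raw), nrow(mat)))
  if (any(is.na(raw))) stop("raw spectrum contains NA")
  if (any(raw < 0)) stop("raw spectrum must be non-negative")
  total <- sum(raw)
  if (total == 0) stop("all-zero raw spectrum cannot be corrected")
  scaled <- raw / total
  fit <- pracma::lsqnonneg(mat, scaled)
  x <- fit$x
  if (sum(x) <= 0)
    stop("degenerate NNLS solution: corrected spectrum is identically zero")
  out <- x / sum(x)
  names(out) <- rownames(mat)
  attr(out, "residual") <- sqrt(max(fit$resid.norm, 0))
  out
}

#' Fractional enrichment of a corrected MID
#'
#' Average labeled fraction of the labelable positions:
#' `sum(i * Mi) / n` for a corrected MID M0..Mn. 0 for an unlabeled pool,
#' 1 for a fully labeled pool.
#'
#' @param mid corrected-fraction MID vector (length n + 1, sums to 1).
#' @param tol tolerance on the unit-sum sanity check.
#' @return fraction in \[0, 1\].
#' @examples
#' fractionalEnrichment(c(0.4, 0, 0, 0.6))  # lactate 60% M3 -> 0.6
#' @export
fractionalEnrichment <- function(mid, tol = 1e-6) {
  n <- length(mid) - 1L
  if (n < 1L) stop("MID must cover at least one labelable position (n >= 1)")
  if (any(mid < -tol)) stop("corrected MID must be non-negative")
  if (abs(sum(mid) - 1) > max(tol, 1e-6))
    stop("input is not a corrected-fraction MID (does not sum to 1)")
  sum(seq(0L, n) * mid) / n
}

#' Per-group mean isotopologue fractions
#'
#' Averages corrected isotopologue fractions within sample groups (cell
#' lines), yielding the matrix behind a labeled-fraction-contribution
#' heatmap: rows are (metabolite, Mi) pairs, columns are groups.
#'
#' @param corrected long-format data.frame with columns `metabolite`,
#'   `isotopologue` (e.g. `"M2"`), `sample`, `fraction`.
#' @param grouping named character vector mapping sample -> group.
#' @return numeric matrix, rows named `"<metabolite>:Mi"`, columns = groups.
#'   Groups with no samples are dropped with a warning.
#' @export
fractionContributionTable <- function(corrected, grouping) {
  need <- c("metabolite", "isotopologue", "sample", "fraction")
  if (!all(need %in% names(corrected)))
    stop("'corrected' must have columns: ", paste(need, collapse = ", "))
  stopifnot(!is.null(names(grouping)))
  unknown <- setdiff(unique(corrected$sample), names(grouping))
  if (length(unknown))
    stop("samples without group assignment: ", paste(unknown, collapse = ", "))
  corrected$group <- unname(grouping[corrected$sample])
  empty <- setdiff(unique(grouping), corrected$group)
  if (length(empty))
    warning("groups with zero samples omitted: ", paste(empty, collapse = ", "))
  agg <- aggregate(fraction ~ metabolite + isotopologue + group,
                   data = corrected, FUN = mean)
  rows <- sort(unique(paste0(agg$metabolite, ":", agg$isotopologue)))
  cols <- sort(unique(agg$group))
  out <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
  out[cbind(paste0(agg$metabolite, ":", agg$isotopologue), agg$group)] <-
    agg$fraction
  out
}
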