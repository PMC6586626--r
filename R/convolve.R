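#' Convolve two non-negative mass-shift distributions
#'
#' Polynomial (Cauchy) product of two vectors indexed by mass shift 0, 1, ...
#' The result has length `length(p) + length(q) - 1` and total mass
#' `sum(p) * sum(q)`.
#'
#' @param p,q non-negative numeric vectors.
#' @return the convolved vector.
#' @examples
#' convolveDist(c(0.5, 0.5), c(0.5, 0.5))  # 0.25 0.50 0.25
#' @export
convolveDist <- function(p, q) {
  if (length(p) == 0L || length(q) == 0L)
    stop("cannot convolve an empty vector")
  if (any(p < 0) || any(q < 0))
    stop("convolution inputs must be non-negative")
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    idx <- i:(i + length(q) - 1L)
    out[idx] <- out[idx] + p[i] * q
  }
  out
}

#' Mass-shift distribution of a block of identical atoms
#'
#' Distribution of the total mass shift contributed by `count` independent
#' atoms of one element, each following the element's natural-abundance
#' vector; computed by repeated convolution (binary exponentiation).
#'
#' @param element element symbol present in `abundances`.
#' @param count number of atoms (>= 0); `count = 0` gives the delta `[1]`.
#' @param abundances abundance table from [naturalAbundances()].
#' @return numeric probability vector over mass shifts, summing to 1.
#' @examples
#' elementDistribution("C", 2)  # ~ Binomial(2, 0.0107) over shifts 0..2
#' @export
elementDistribution <- function(element, count, abundances = naturalAbundances()) {
  if (!element %in% names(abundances))
    stop(sprintf("unknown element '%s' in abundance table", element))
  count <- as.integer(count)
  if (count < 0L) stop("'count' must be >= 0")
  base <- abundances[[element]]
  out <- 1
  while (count > 0L) {
    if (count %% 2L == 1L) out <- convolveDist(out, base)
    count <- count %/% 2L
    if (count > 0L) base <- convolveDist(base, base)
  }
  out
}

# Natural-abundance spectrum of a whole atom block described by a formula
# vector, optionally excluding some atoms of one element (the tracer).
formulaDistribution <- function(formula, abundances, exclude = NULL,
                                excludeCount = 0L) {
  out <- 1
  for (el in names(formula)) {
    n <- formula[[el]]
    if (!is.null(exclude) && el == exclude) n <- n - excludeCount
    if (n < 0L)
      stop(sprintf("cannot exclude %d '%s' atoms from formula with %d",
                   excludeCount, el, formula[[el]]))
    if (n > 0L) out <- convolveDist(out, elementDistribution(el, n, abundances))
  }
  out
}
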