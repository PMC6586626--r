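#' Natural isotope abundances by mass shift
#'
#' Standard terrestrial isotopic abundances for the elements occurring in
#' methoxyamine/TMS/tBDMS-derivatized metabolite fragments. Each element maps
#' to a numeric vector of abundances ordered by nominal mass shift relative
#' to the lightest isotope (+0, +1, +2, ...); entries with no stable isotope
#' at that shift are 0 (e.g. sulfur has no +3 isotope). Values follow the
#' IUPAC/CIAAW representative terrestrial abundances.
#'
#' @param overrides optional named list of replacement abundance vectors,
#'   e.g. `list(C = c(1, 0))` to switch off 13C natural abundance.
#' @return named list of numeric abundance vectors, each summing to 1.
#' @examples
#' naturalAbundances()$C
#' naturalAbundances(overrides = list(C = c(1, 0)))$C
#' @export
naturalAbundances <- function(overrides = NULL) {
  ab <- list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Si = c(0.92223, 0.04685, 0.03092),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
    P  = 1
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    for (el in names(overrides)) ab[[el]] <- overrides[[el]]
  }
  validateAbundances(ab)
  ab
}

#' Validate an abundance table
#'
#' Checks that every element's abundance vector is non-negative and sums to 1
#' within `tol`.
#'
#' @param abundances named list of abundance vectors.
#' @param tol tolerance on the unit-sum check.
#' @return the table, invisibly; errors on violation.
#' @export
validateAbundances <- function(abundances, tol = 1e-9) {
  stopifnot(is.list(abundances), !is.null(names(abundances)))
  for (el in names(abundances)) {
    v <- abundances[[el]]
    if (!is.numeric(v) || any(v < 0))
      stop(sprintf("abundances for '%s' must be non-negative numbers", el))
    if (abs(sum(v) - 1) > tol)
      stop(sprintf("abundances for '%s' sum to %.12f, expected 1", el, sum(v)))
  }
  invisible(abundances)
}
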