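#' Parse an elemental formula string
#'
#' Parses Hill-style formula strings such as `"C11H25O3Si2"` into a named
#' integer vector of atom counts. Element symbols are one upper-case letter
#' optionally followed by one lower-case letter; a missing count means 1.
#' Repeated elements are summed.
#'
#' @param formula character(1) formula string.
#' @return named integer vector of atom counts.
#' @examples
#' parseFormula("C6H12O6")
#' parseFormula("C11H25O3Si2")
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[[:space:]]", "", formula)
  if (!nzchar(s)) stop("empty formula string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    covered <- unlist(Map(function(start, len) seq(start, start + len - 1L),
                          as.integer(m), attr(m, "match.length")))
    bad <- substr(s, setdiff(seq_len(nchar(s)), covered)[1],
                  setdiff(seq_len(nchar(s)), covered)[1])
    stop(sprintf("cannot parse formula '%s': unexpected token '%s'",
                 formula, bad))
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(sub("^[A-Z][a-z]?", "", paste0(tokens, "")))
  counts[is.na(counts)] <- 1L
  tot <- tapply(counts, elements, sum)
  out <- setNames(as.integer(tot), names(tot))
  # stable, chemistry-conventional order: C, H, then alphabetical
  ord <- c(intersect(c("C", "H"), names(out)),
           sort(setdiff(names(out), c("C", "H"))))
  out[ord]
}

#' Format an atom-count vector back into a formula string
#'
#' @param counts named integer vector of atom counts.
#' @return character(1) formula string.
#' @examples
#' formatFormula(c(C = 11L, H = 25L, O = 3L, Si = 2L))
#' @export
formatFormula <- function(counts) {
  counts <- counts[counts > 0]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}
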