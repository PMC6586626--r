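#' FragmentSpec: a measured metabolite fragment
#'
#' Describes the ion actually integrated from a GC-MS chromatogram: its full
#' elemental composition *including derivatization atoms* (tBDMS/TMS groups
#' contribute C, H and Si that all carry natural heavy isotopes), the tracer
#' element, and the number of positions that can carry tracer label
#' (`nLabelable`, the metabolite's own backbone atoms of the tracer element).
#'
#' @slot metabolite character(1), metabolite identifier.
#' @slot formula named integer vector of atom counts (e.g. `c(C = 11, H = 25,
#'   O = 3, Si = 2)`).
#' @slot tracerElement character(1), e.g. `"C"`.
#' @slot nLabelable integer(1), number of labelable tracer-element positions
#'   (`n`); the MID has `n + 1` entries M0..Mn.
#'
#' @seealso [fragmentSpec()], [buildCorrectionMatrix()]
#' @export
setClass("FragmentSpec",
  representation(
    metabolite = "character",
    formula = "integer",
    tracerElement = "character",
    nLabelable = "integer"
  )
)

setValidity("FragmentSpec", function(object) {
  msg <- character()
  if (length(object@metabolite) != 1L || !nzchar(object@metabolite))
    msg <- c(msg, "'metabolite' must be a single non-empty string")
  if (is.null(names(object@formula)) || any(!nzchar(names(object@formula))))
    msg <- c(msg, "'formula' must be a named vector of atom counts")
  if (any(object@formula < 0L))
    msg <- c(msg, "atom counts must be >= 0")
  if (length(object@tracerElement) != 1L)
    msg <- c(msg, "'tracerElement' must be a single element symbol")
  if (!object@tracerElement %in% names(object@formula))
    msg <- c(msg, sprintf("tracer element '%s' absent from formula",
                          object@tracerElement))
  else if (object@nLabelable > object@formula[[object@tracerElement]])
    msg <- c(msg, sprintf(
      "nLabelable (%d) exceeds %s atom count (%d) in formula",
      object@nLabelable, object@tracerElement,
      object@formula[[object@tracerElement]]))
  if (object@nLabelable < 0L)
    msg <- c(msg, "'nLabelable' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a FragmentSpec
#'
#' @param metabolite metabolite identifier.
#' @param formula either a named integer vector of atom counts or a formula
#'   string such as `"C11H25O3Si2"` (parsed with [parseFormula()]).
#' @param tracerElement element symbol carrying the label (default `"C"`).
#' @param nLabelable number of labelable tracer-element positions.
#' @return a [FragmentSpec-class] object.
#' @examples
#' fragmentSpec("lactate", "C11H25O3Si2", "C", 3)
#' @export
fragmentSpec <- function(metabolite, formula, tracerElement = "C", nLabelable) {
  if (is.character(formula) && length(formula) == 1L)
    formula <- parseFormula(formula)
  counts <- as.integer(formula)
  names(counts) <- names(formula)
  new("FragmentSpec",
      metabolite = as.character(metabolite),
      formula = counts,
      tracerElement = tracerElement,
      nLabelable = as.integer(nLabelable))
}

setMethod("show", "FragmentSpec", function(object) {
  cat(sprintf("FragmentSpec '%s': %s, %d labelable %s position(s)\n",
              object@metabolite, formatFormula(object@formula),
              object@nLabelable, object@tracerElement))
})

#' @describeIn fragmentSpec number of labelable positions `n`.
#' @param x a `FragmentSpec`.
#' @export
nLabelable <- function(x) {
  stopifnot(is(x, "FragmentSpec"))
  x@nLabelable
}

#' TracerSpec: an isotopic tracer reagent
#'
#' @slot name tracer reagent name, e.g. `"U-13C6 glucose"`.
#' @slot element labeled element symbol.
#' @slot labeledPositions number of labeled positions in the reagent.
#' @slot purity isotopic purity of the labeled positions, in (0, 1].
#'
#' @seealso [tracerSpec()], [defaultTracers()]
#' @export
setClass("TracerSpec",
  representation(
    name = "character",
    element = "character",
    labeledPositions = "integer",
    purity = "numeric"
  )
)

setValidity("TracerSpec", function(object) {
  msg <- character()
  if (object@purity <= 0 || object@purity > 1)
    msg <- c(msg, "'purity' must lie in (0, 1]")
  if (object@labeledPositions < 0L)
    msg <- c(msg, "'labeledPositions' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TracerSpec
#'
#' @param name reagent name.
#' @param element labeled element symbol (default `"C"`).
#' @param labeledPositions number of labeled positions.
#' @param purity isotopic purity in (0, 1].
#' @return a [TracerSpec-class] object.
#' @examples
#' tracerSpec("U-13C6 glucose", "C", 6, 0.99)
#' @export
tracerSpec <- function(name, element = "C", labeledPositions, purity = 0.99) {
  new("TracerSpec", name = name, element = element,
      labeledPositions = as.integer(labeledPositions),
      purity = as.numeric(purity))
}

setMethod("show", "TracerSpec", function(object) {
  cat(sprintf("TracerSpec '%s': %d labeled %s position(s), purity %.3f\n",
              object@name, object@labeledPositions, object@element,
              object@purity))
})

#' Commonly used tracer reagents
#'
#' Purities reflect typical commercial reagents: 99% for uniformly labeled
#' glucose and glutamine, 98% for uniformly labeled palmitate and for
#' singly/uniformly labeled lactate.
#'
#' @return named list of [TracerSpec-class] objects: `glucose_u13c6`,
#'   `glutamine_u13c5`, `palmitate_u13c16`, `lactate_u13c3`, `lactate_3_13c`.
#' @examples
#' defaultTracers()$glucose_u13c6
#' @export
defaultTracers <- function() {
  list(
    glucose_u13c6   = tracerSpec("U-13C6 glucose",   "C", 6L,  0.99),
    glutamine_u13c5 = tracerSpec("U-13C5 glutamine", "C", 5L,  0.99),
    palmitate_u13c16 = tracerSpec("U-13C16 palmitate", "C", 16L, 0.98),
    lactate_u13c3   = tracerSpec("U-13C3 lactate",   "C", 3L,  0.98),
    lactate_3_13c   = tracerSpec("3-13C lactate",    "C", 1L,  0.98)
  )
}

#' FluxRegime: genotype-level labeling regime
#'
#' Summarises, as steady-state branch fractions in \[0, 1\], how a genotype
#' routes carbon:
#' * `glycolyticLactateFraction` - fraction of the lactate pool that is
#'   glucose-derived (M3 under uniformly labeled glucose);
#' * `sspFraction` - fraction of the serine pool made de novo from glucose
#'   via the serine synthesis pathway (serine M3, glycine M2, one-carbon
#'   units feeding purines);
#' * `tcaFromLactateFraction` - fraction of TCA-cycle acetyl-CoA entry that
#'   is glucose/lactate-derived (citrate M2);
#' * `glutamineTcaFraction` - fraction of TCA intermediates that are
#'   glutamine-derived (glutamate M5 under uniformly labeled glutamine).
#'
#' @slot genotype one of `"EGFR"`, `"FGFR"`, `"RET"`, `"MET"`, `"WT"`.
#' @slot branchFractions named numeric vector of the four fractions above.
#' @seealso [fluxRegime()]
#' @export
setClass("FluxRegime",
  representation(genotype = "character", branchFractions = "numeric")
)

.REGIME_FLUXES <- c("glycolyticLactateFraction", "sspFraction",
                    "tcaFromLactateFraction", "glutamineTcaFraction")

setValidity("FluxRegime", function(object) {
  msg <- character()
  if (!object@genotype %in% c("EGFR", "FGFR", "RET", "MET", "WT"))
    msg <- c(msg, "genotype must be one of EGFR, FGFR, RET, MET, WT")
  if (!all(.REGIME_FLUXES %in% names(object@branchFractions)))
    msg <- c(msg, paste("branchFractions must name:",
                        paste(.REGIME_FLUXES, collapse = ", ")))
  bf <- object@branchFractions
  if (any(bf < 0 | bf > 1))
    msg <- c(msg, "all branch fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

# Genotype presets encode the qualitative phenotypes of the isogenic BAF3
# model: EGFR routes glucose into serine synthesis; FGFR maximises glycolytic
# lactate and recycles it into the TCA cycle; RET relies on glutamine
# anaplerosis; MET and parental (WT) cells are moderate in all branches.
.REGIME_PRESETS <- list(
  EGFR = c(glycolyticLactateFraction = 0.50, sspFraction = 0.60,
           tcaFromLactateFraction = 0.25, glutamineTcaFraction = 0.30),
  FGFR = c(glycolyticLactateFraction = 0.85, sspFraction = 0.15,
           tcaFromLactateFraction = 0.60, glutamineTcaFraction = 0.30),
  RET  = c(glycolyticLactateFraction = 0.30, sspFraction = 0.10,
           tcaFromLactateFraction = 0.20, glutamineTcaFraction = 0.70),
  MET  = c(glycolyticLactateFraction = 0.45, sspFraction = 0.20,
           tcaFromLactateFraction = 0.25, glutamineTcaFraction = 0.35),
  WT   = c(glycolyticLactateFraction = 0.40, sspFraction = 0.15,
           tcaFromLactateFraction = 0.20, glutamineTcaFraction = 0.30)
)

#' Construct a FluxRegime
#'
#' @param genotype one of `"EGFR"`, `"FGFR"`, `"RET"`, `"MET"`, `"WT"`.
#'   Determines preset branch fractions, individually overridable.
#' @param ... named branch-fraction overrides (see [FluxRegime-class]).
#' @return a [FluxRegime-class] object.
#' @examples
#' fluxRegime("EGFR")
#' fluxRegime("FGFR", tcaFromLactateFraction = 0.7)
#' @export
fluxRegime <- function(genotype = c("EGFR", "FGFR", "RET", "MET", "WT"), ...) {
  genotype <- match.arg(genotype)
  bf <- .REGIME_PRESETS[[genotype]]
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), .REGIME_FLUXES)
    if (length(bad))
      stop("unknown branch fraction(s): ", paste(bad, collapse = ", "))
    bf[names(overrides)] <- unlist(overrides)
  }
  new("FluxRegime", genotype = genotype, branchFractions = bf)
}

setMethod("show", "FluxRegime", function(object) {
  cat(sprintf("FluxRegime '%s':\n", object@genotype))
  for (f in .REGIME_FLUXES)
    cat(sprintf("  %-26s %.2f\n", f, object@branchFractions[[f]]))
})

#' @describeIn fluxRegime extract one branch fraction by name.
#' @param x a `FluxRegime`.
#' @param flux branch-fraction name.
#' @export
branchFraction <- function(x, flux) {
  stopifnot(is(x, "FluxRegime"))
  if (!flux %in% names(x@branchFractions))
    stop("unknown branch fraction: ", flux)
  unname(x@branchFractions[[flux]])
}

#' CorrectionMatrix: theoretical isotopologue spectra of a fragment
#'
#' Square matrix of size `(n+1) x (n+1)` whose column `j` (0-based) is the
#' theoretical mass-shift spectrum, truncated to the measured window M0..Mn,
#' of the fragment when exactly `j` labelable positions carry tracer at the
#' stated purity and every other atom follows natural isotope abundance.
#' Untruncated columns sum to 1; `truncationLoss` records the probability
#' mass falling above Mn per column.
#'
#' @slot matrix numeric matrix, rows M0..Mn, columns j = 0..n tracer atoms.
#' @slot fragment the [FragmentSpec-class] it was built for.
#' @slot purity tracer purity baked into the columns.
#' @slot truncationLoss numeric vector, per-column probability mass above Mn.
#' @seealso [buildCorrectionMatrix()], [correctMid()]
#' @export
setClass("CorrectionMatrix",
  representation(
    matrix = "matrix",
    fragment = "FragmentSpec",
    purity = "numeric",
    truncationLoss = "numeric"
  )
)

setValidity("CorrectionMatrix", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (any(m < 0)) msg <- c(msg, "matrix entries must be >= 0")
  if (nrow(m) != object@fragment@nLabelable + 1L)
    msg <- c(msg, "matrix dimension must equal nLabelable + 1")
  if (length(object@truncationLoss) != ncol(m))
    msg <- c(msg, "truncationLoss must have one entry per column")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrectionMatrix", function(object) {
  cat(sprintf(
    "CorrectionMatrix for '%s' (%s): %dx%d, purity %.3f, max truncation loss %.2e\n",
    object@fragment@metabolite, formatFormula(object@fragment@formula),
    nrow(object@matrix), ncol(object@matrix), object@purity,
    max(object@truncationLoss)))
})

#' @describeIn buildCorrectionMatrix extract the numeric matrix.
#' @param x a `CorrectionMatrix`.
#' @export
correctionMatrix <- function(x) {
  stopifnot(is(x, "CorrectionMatrix"))
  x@matrix
}

#' ContingencyTable2x2: genotype co-occurrence counts
#'
#' Cell counts for two binary genotype events A and B across a cohort:
#' carriers of both, A only, B only, and neither.
#'
#' @slot nBoth,nAOnly,nBOnly,nNeither non-negative integer counts.
#' @slot eventA,eventB event labels.
#' @seealso [contingencyTable2x2()], [fisherExact2x2()], [cooccurrenceRate()]
#' @export
setClass("ContingencyTable2x2",
  representation(
    nBoth = "integer", nAOnly = "integer",
    nBOnly = "integer", nNeither = "integer",
    eventA = "character", eventB = "character"
  )
)

setValidity("ContingencyTable2x2", function(object) {
  cells <- c(object@nBoth, object@nAOnly, object@nBOnly, object@nNeither)
  if (any(cells < 0L)) "all cell counts must be >= 0" else TRUE
})

#' Construct a 2x2 contingency table of genotype events
#'
#' @param nBoth,nAOnly,nBOnly,nNeither cell counts.
#' @param eventA,eventB event labels (annotation only).
#' @return a [ContingencyTable2x2-class] object.
#' @examples
#' contingencyTable2x2(58, 106, 20, 800, "EGFR_MUT", "PSPH_AMP")
#' @export
contingencyTable2x2 <- function(nBoth, nAOnly, nBOnly, nNeither,
                                eventA = "A", eventB = "B") {
  new("ContingencyTable2x2",
      nBoth = as.integer(nBoth), nAOnly = as.integer(nAOnly),
      nBOnly = as.integer(nBOnly), nNeither = as.integer(nNeither),
      eventA = eventA, eventB = eventB)
}

setMethod("show", "ContingencyTable2x2", function(object) {
  m <- as.matrix(object)
  cat(sprintf("ContingencyTable2x2 (%s x %s), n = %d\n",
              object@eventA, object@eventB, sum(m)))
  print(m)
})

#' @export
#' @describeIn contingencyTable2x2 coerce to a base 2x2 matrix
#'   (rows = event A yes/no, columns = event B yes/no).
#' @param x a `ContingencyTable2x2`.
#' @param ... unused.
setMethod("as.matrix", "ContingencyTable2x2", function(x, ...) {
  m <- matrix(c(x@nBoth, x@nAOnly, x@nBOnly, x@nNeither), nrow = 2L,
              dimnames = list(c("A+", "A-"), c("B+", "B-")))
  m
})
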