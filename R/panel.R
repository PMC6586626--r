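#' Default GC-MS fragment panel
#'
#' A panel of derivatized metabolite fragments spanning glycolysis, the
#' serine synthesis pathway, the TCA cycle and purine nucleotide synthesis.
#' Formulas are representative tBDMS/TMS-derivatized fragment compositions
#' (metabolite backbone plus derivatization carbons, hydrogens and silicons);
#' `nLabelable` counts the metabolite's own carbon positions that a 13C
#' tracer can reach.
#'
#' @return named list of [FragmentSpec-class] objects: `lactate` (n = 3),
#'   `serine` (n = 3), `glycine` (n = 2), `citrate` (n = 6), `glutamate`
#'   (n = 5), `inosine` (n = 10; the purine nucleoside whose M6-M9 states
#'   report combined ribose + glycine + one-carbon labeling).
#' @examples
#' defaultFragmentPanel()$lactate
#' @export
defaultFragmentPanel <- function() {
  list(
    lactate   = fragmentSpec("lactate",   "C11H25O3Si2",   "C", 3L),
    serine    = fragmentSpec("serine",    "C16H38NO3Si3",  "C", 3L),
    glycine   = fragmentSpec("glycine",   "C10H24NO2Si2",  "C", 2L),
    citrate   = fragmentSpec("citrate",   "C20H39O7Si3",   "C", 6L),
    glutamate = fragmentSpec("glutamate", "C19H42NO4Si3",  "C", 5L),
    inosine   = fragmentSpec("inosine",   "C22H44N4O5Si4", "C", 10L)
  )
}
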