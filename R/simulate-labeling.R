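# Labeling model: per metabolite, the steady-state MID is a two-component
# mixture of an unlabeled pool (delta at M0) and a labeled pool whose k
# tracer-reachable positions each carry heavy label with probability equal
# to tracer purity, i.e. Binomial(k, purity) over M0..Mk. The mixing weight
# is the genotype's branch fraction for the route that feeds the metabolite.

# Binomial labeled-state MID padded to length n + 1
labeledStateMid <- function(n, k, purity) {
  if (k > n) stop("labeled state exceeds number of labelable positions")
  out <- numeric(n + 1L)
  out[seq_len(k + 1L)] <- dbinom(0:k, k, purity)
  out
}

mixtureMid <- function(n, k, fraction, purity) {
  stopifnot(fraction >= 0, fraction <= 1)
  unlabeled <- c(1, numeric(n))
  (1 - fraction) * unlabeled + fraction * labeledStateMid(n, k, purity)
}

# Fraction of the ribose moiety of purine nucleosides that is glucose-derived
# (pentose phosphate pathway); near-complete turnover in proliferating cells.
.RIBOSE_GLUCOSE_FRACTION <- 0.9

tracerFamily <- function(tracer) {
  nm <- tolower(tracer@name)
  if (grepl("glucose", nm)) return("glucose")
  if (grepl("glutamine", nm)) return("glutamine")
  if (grepl("palmitate", nm)) return("palmitate")
  if (grepl("lactate", nm))
    return(if (tracer@labeledPositions == 1L) "lactate1" else "lactate3")
  stop(sprintf("unrecognised tracer '%s'", tracer@name))
}

# True MID of one panel metabolite under one regime and tracer.
trueMidFor <- function(metabolite, n, regime, tracer) {
  p <- tracer@purity
  fam <- tracerFamily(tracer)
  bf <- function(flux) branchFraction(regime, flux)
  unlabeled <- c(1, numeric(n))
  if (fam == "glucose") {
    switch(metabolite,
      lactate   = mixtureMid(n, 3L, bf("glycolyticLactateFraction"), p),
      serine    = mixtureMid(n, 3L, bf("sspFraction"), p),
      glycine   = mixtureMid(n, 2L, bf("sspFraction"), p),
      citrate   = mixtureMid(n, 2L, bf("tcaFromLactateFraction"), p),
      glutamate = mixtureMid(n, 2L, bf("tcaFromLactateFraction"), p),
      inosine   = purineNucleosideMid(n, bf("sspFraction"), p),
      stop(sprintf("no glucose labeling rule for metabolite '%s'", metabolite))
    )
  } else if (fam == "glutamine") {
    switch(metabolite,
      glutamate = mixtureMid(n, 5L, bf("glutamineTcaFraction"), p),
      citrate   = mixtureMid(n, 4L, bf("glutamineTcaFraction"), p),
      lactate   = ,
      serine    = ,
      glycine   = ,
      inosine   = unlabeled,
      stop(sprintf("no glutamine labeling rule for metabolite '%s'", metabolite))
    )
  } else if (fam %in% c("lactate3", "lactate1")) {
    k <- if (fam == "lactate3") c(lactate = 3L, citrate = 2L, glutamate = 2L)
         else                   c(lactate = 1L, citrate = 1L, glutamate = 1L)
    switch(metabolite,
      lactate   = mixtureMid(n, k[["lactate"]], bf("tcaFromLactateFraction"), p),
      citrate   = mixtureMid(n, k[["citrate"]], bf("tcaFromLactateFraction"), p),
      glutamate = mixtureMid(n, k[["glutamate"]], bf("tcaFromLactateFraction"), p),
      serine    = ,
      glycine   = ,
      inosine   = unlabeled,
      stop(sprintf("no lactate labeling rule for metabolite '%s'", metabolite))
    )
  } else { # palmitate: minor beta-oxidation entry into the TCA cycle
    switch(metabolite,
      citrate   = mixtureMid(n, 2L, 0.05, p),
      glutamate = mixtureMid(n, 2L, 0.03, p),
      lactate   = ,
      serine    = ,
      glycine   = ,
      inosine   = unlabeled,
      stop(sprintf("no palmitate labeling rule for metabolite '%s'", metabolite))
    )
  }
}

# Purine nucleoside (C10) MID under glucose tracer: convolution of
# independently labeled moieties - ribose (5 C, glucose-derived via PPP),
# glycine (2 C, SSP-derived), two formate one-carbon units (SSP-derived) and
# one CO2-derived carbon (unlabeled). High SSP flux populates M6-M9.
purineNucleosideMid <- function(n, sspFraction, purity) {
  if (n < 10L) stop("purine nucleoside fragment needs n >= 10")
  comp <- list(
    mixtureMid(5L, 5L, .RIBOSE_GLUCOSE_FRACTION, purity),  # ribose
    mixtureMid(2L, 2L, sspFraction, purity),               # glycine
    mixtureMid(1L, 1L, sspFraction, purity),               # formate 1
    mixtureMid(1L, 1L, sspFraction, purity),               # formate 2
    c(1, 0)                                                # CO2 carbon
  )
  out <- Reduce(convolveDist, comp)
  c(out, numeric(n + 1L - length(out)))[seq_len(n + 1L)]
}

#' Simulate steady-state tracer incorporation for a genotype
#'
#' Computes the true (noise-free, natural-abundance-free) mass isotopomer
#' distribution of every panel metabolite under a genotype's
#' [FluxRegime-class] and a given tracer. The model is a two-component
#' labeled/unlabeled mixture per metabolite (see package vignette); tracer
#' purity enters as a Binomial spread over the labeled positions.
#'
#' @param regime a [FluxRegime-class].
#' @param tracer a [TracerSpec-class] (see [defaultTracers()]).
#' @param panel named list of [FragmentSpec-class]; metabolites must have a
#'   labeling rule for the tracer (default panel metabolites all do).
#' @param seed integer seed recorded in the truth object (the computation is
#'   deterministic).
#' @return list with elements `mids` (named list metabolite -> MID vector,
#'   each summing to 1) and `truth` (list with `true_mids`, genotype, seed).
#' @examples
#' sim <- simulateLabeling(fluxRegime("FGFR"), defaultTracers()$glucose_u13c6)
#' round(sim$mids$lactate, 3)
#' @export
simulateLabeling <- function(regime, tracer, panel = defaultFragmentPanel(),
                             seed = 1L) {
  stopifnot(is(regime, "FluxRegime"), is(tracer, "TracerSpec"))
  mids <- lapply(panel, function(frag)
    trueMidFor(frag@metabolite, frag@nLabelable, regime, tracer))
  names(mids) <- vapply(panel, function(f) f@metabolite, character(1))
  bad <- names(mids)[vapply(mids, function(m) abs(sum(m) - 1) > 1e-9, logical(1))]
  if (length(bad))
    stop("internal error: MID does not sum to 1 for ", paste(bad, collapse = ", "))
  truth <- list(true_mids = mids, genotype = regime@genotype,
                tracer = tracer@name, seed = as.integer(seed))
  list(mids = mids, truth = truth)
}

#' Emit raw isotopologue spectra from true MIDs
#'
#' Forward model of the GC-MS measurement: each metabolite's raw spectrum is
#' the fragment's natural-abundance theoretical-spectrum matrix (built with
#' purity fixed at 1, since tracer purity is already part of the true MID)
#' multiplied by the true MID, scaled by a sample-specific total intensity,
#' with multiplicative Gaussian noise of coefficient of variation `noiseCv`
#' truncated at zero.
#'
#' @param trueMids named list metabolite -> true MID (from
#'   [simulateLabeling()]).
#' @param fragments named list of [FragmentSpec-class] covering the
#'   metabolites.
#' @param tracer a [TracerSpec-class] (recorded in the output table).
#' @param abundances abundance table from [naturalAbundances()].
#' @param samples character vector of sample names, or an integer count.
#' @param noiseCv multiplicative noise CV (>= 0).
#' @param intensityScale nominal total ion intensity per metabolite.
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @return data.frame with columns `metabolite`, `formula`, `tracer`,
#'   `sample`, `m0`..`mN` (NA beyond a fragment's n).
#' @examples
#' sim <- simulateLabeling(fluxRegime("EGFR"), defaultTracers()$glucose_u13c6)
#' raw <- emitRawSpectra(sim$mids, defaultFragmentPanel(),
#'                       defaultTracers()$glucose_u13c6, noiseCv = 0)
#' head(raw)
#' @export
emitRawSpectra <- function(trueMids, fragments,
                           tracer,
                           abundances = naturalAbundances(),
                           samples = 3L,
                           noiseCv = 0.05,
                           intensityScale = 1e6,
                           seed = 1L) {
  stopifnot(is.list(trueMids), !is.null(names(trueMids)))
  if (noiseCv < 0) stop("'noiseCv' must be >= 0")
  if (is.numeric(samples) && length(samples) == 1L)
    samples <- sprintf("S%02d", seq_len(samples))
  fragByMet <- setNames(fragments,
                        vapply(fragments, function(f) f@metabolite, character(1)))
  missing <- setdiff(names(trueMids), names(fragByMet))
  if (length(missing))
    stop("no fragment formula for metabolite(s): ",
         paste(missing, collapse = ", "))
  set.seed(as.integer(seed))
  maxN <- max(vapply(names(trueMids),
                     function(m) fragByMet[[m]]@nLabelable, integer(1)))
  rows <- list()
  for (met in names(trueMids)) {
    frag <- fragByMet[[met]]
    n <- frag@nLabelable
    cm <- buildCorrectionMatrix(frag, abundances, tracer,
                                purityCorrection = FALSE)
    theo <- as.numeric(cm@matrix %*% trueMids[[met]])
    for (s in samples) {
      scaleFac <- intensityScale * runif(1, 0.5, 1.5)
      noise <- if (noiseCv > 0) pmax(0, 1 + rnorm(n + 1L, 0, noiseCv)) else 1
      intens <- theo * scaleFac * noise
      pad <- rep(NA_real_, maxN - n)
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = met, formula = formatFormula(frag@formula),
        tracer = tracer@name, sample = s,
        t(c(intens, pad)), check.names = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:4)] <- paste0("m", 0:maxN)
  rownames(out) <- NULL
  out
}

#' Correct a raw-spectra table for natural abundance
#'
#' Applies [correctMid()] to every (metabolite, sample) spectrum of a table
#' produced by [emitRawSpectra()] (or read from TSV in the same layout).
#'
#' @param raw raw-spectra data.frame (columns `metabolite`, `sample`,
#'   `m0`...).
#' @param fragments named list of [FragmentSpec-class].
#' @param tracer a [TracerSpec-class].
#' @param abundances abundance table.
#' @param purityCorrection,correctTracerElement passed to
#'   [buildCorrectionMatrix()]. With the default forward model of
#'   [emitRawSpectra()], `purityCorrection = FALSE` recovers the true MID
#'   (purity included); `TRUE` additionally deconvolves tracer impurity.
#' @return list with `corrected` (long data.frame: metabolite, isotopologue,
#'   sample, fraction) and `enrichment` (data.frame: metabolite, sample,
#'   enrichment).
#' @export
correctSpectraTable <- function(raw, fragments, tracer,
                                abundances = naturalAbundances(),
                                purityCorrection = FALSE,
                                correctTracerElement = TRUE) {
  fragByMet <- setNames(fragments,
                        vapply(fragments, function(f) f@metabolite, character(1)))
  mats <- lapply(fragByMet, buildCorrectionMatrix, abundances = abundances,
                 tracer = tracer, purityCorrection = purityCorrection,
                 correctTracerElement = correctTracerElement)
  corr <- list(); enr <- list()
  for (i in seq_len(nrow(raw))) {
    met <- raw$metabolite[i]
    if (!met %in% names(fragByMet))
      stop("no fragment spec for metabolite: ", met)
    n <- fragByMet[[met]]@nLabelable
    spec <- as.numeric(raw[i, paste0("m", 0:n)])
    mid <- correctMid(spec, mats[[met]])
    corr[[i]] <- data.frame(metabolite = met, isotopologue = names(mid),
                            sample = raw$sample[i], fraction = as.numeric(mid),
                            stringsAsFactors = FALSE)
    enr[[i]] <- data.frame(metabolite = met, sample = raw$sample[i],
                           enrichment = fractionalEnrichment(as.numeric(mid)),
                           stringsAsFactors = FALSE)
  }
  list(corrected = do.call(rbind, corr), enrichment = do.call(rbind, enr))
}
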