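#' Caliper tumor volume
#'
#' `volume = length * width^2 / 2` in mm^3. By convention the larger caliper
#' measurement is the length; swapped inputs are re-ordered with a warning.
#'
#' @param length,width caliper measurements in mm (both > 0).
#' @return volume in mm^3 (vectorized).
#' @examples
#' tumorVolume(10, 5)  # 125
#' @export
tumorVolume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("caliper measurements must be > 0")
  swapped <- width > length
  if (any(swapped)) {
    warning(sum(swapped), " measurement(s) with width > length re-ordered")
    tmp <- length[swapped]
    length[swapped] <- width[swapped]
    width[swapped] <- tmp
  }
  length * width^2 / 2
}

#' Relative tumor volume series
#'
#' `RTV = Vt / V0`, the tumor volume on each measurement day relative to the
#' volume at the start of treatment.
#'
#' @param series data.frame with columns `day`, `length`, `width` (mm);
#'   days must be strictly increasing, the first row is baseline.
#' @return data.frame with columns `day`, `volume`, `rtv` (baseline rtv = 1).
#' @examples
#' relativeTumorVolume(data.frame(day = c(0, 3, 6),
#'                                length = c(8, 9, 11), width = c(5, 6, 7)))
#' @export
relativeTumorVolume <- function(series) {
  need <- c("day", "length", "width")
  if (!all(need %in% names(series)))
    stop("'series' must have columns: ", paste(need, collapse = ", "))
  if (nrow(series) < 1L) stop("empty measurement series")
  if (is.unsorted(series$day, strictly = TRUE))
    stop("days must be strictly increasing")
  vol <- tumorVolume(series$length, series$width)
  if (vol[1] == 0) stop("baseline volume is zero")
  data.frame(day = series$day, volume = vol, rtv = vol / vol[1])
}

#' Cell viability percentage
#'
#' `(OD_treated / OD_control) * 100`.
#'
#' @param odTreated,odControl optical densities (control > 0,
#'   treated >= 0).
#' @return viability percent (vectorized).
#' @examples
#' viabilityPercent(0.3, 0.6)  # 50
#' @export
viabilityPercent <- function(odTreated, odControl) {
  if (any(odControl <= 0)) stop("control OD must be > 0")
  if (any(odTreated < 0)) stop("treated OD must be >= 0")
  odTreated / odControl * 100
}

#' Cell growth inhibition percentage
#'
#' `(1 - OD_treated / OD_control) * 100`; negative values (growth
#' stimulation) are passed through.
#'
#' @inheritParams viabilityPercent
#' @return inhibition percent (vectorized).
#' @examples
#' growthInhibitionPercent(0.3, 0.6)  # 50
#' growthInhibitionPercent(0.9, 0.6)  # -50
#' @export
growthInhibitionPercent <- function(odTreated, odControl) {
  100 - viabilityPercent(odTreated, odControl)
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' Target-gene Ct values are normalized to the reference (housekeeping)
#' gene within sample and calibrator, and the difference of the two
#' delta-Ct values is exponentiated:
#' `ddCt = (Ct_target,sample - Ct_ref,sample) -
#'         (Ct_target,calibrator - Ct_ref,calibrator)`,
#' fold change `= 2^(-ddCt)`. Replicate Ct values are averaged
#' arithmetically first.
#'
#' @param ctTargetSample,ctRefSample,ctTargetCalibrator,ctRefCalibrator
#'   Ct values (> 0); each may be a vector of replicates (averaged).
#' @return n-fold expression change relative to the calibrator.
#' @examples
#' ddctFoldChange(24, 18, 25, 18)  # ddCt = -1 -> 2
#' @export
ddctFoldChange <- function(ctTargetSample, ctRefSample,
                           ctTargetCalibrator, ctRefCalibrator) {
  cts <- list(ctTargetSample, ctRefSample, ctTargetCalibrator,
              ctRefCalibrator)
  if (any(vapply(cts, function(x) !length(x) || anyNA(x), logical(1))))
    stop("all four Ct values must be present and non-missing")
  if (any(unlist(cts) <= 0)) stop("Ct values must be > 0")
  means <- vapply(cts, mean, numeric(1))
  ddct <- (means[1] - means[2]) - (means[3] - means[4])
  2^(-ddct)
}

#' Cell growth fold change
#'
#' `count_t / count_0` from cell-counting growth assays.
#'
#' @param countT cell count at the end of the assay (>= 0).
#' @param count0 baseline cell count (> 0).
#' @return fold change (vectorized).
#' @examples
#' growthFoldChange(300, 100)  # 3
#' @export
growthFoldChange <- function(countT, count0) {
  if (any(count0 <= 0)) stop("baseline count must be > 0")
  if (any(countT < 0)) stop("counts must be >= 0")
  countT / count0
}
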