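#' Joint cell probabilities of two Bernoulli events with given margins and
#' odds ratio
#'
#' Solves the Plackett problem: given marginal prevalences `prevA`, `prevB`
#' and odds ratio `psi = exp(logOdds)`, find the probability `p11` that both
#' events co-occur. For `psi != 1` this is the admissible root of the
#' quadratic `(psi - 1) p11^2 - S p11 + psi prevA prevB = 0` with
#' `S = 1 + (prevA + prevB)(psi - 1)`; for `psi = 1`, `p11 = prevA * prevB`.
#'
#' @param prevA,prevB marginal prevalences in \[0, 1\].
#' @param logOdds log odds ratio (finite).
#' @return named numeric vector `c(p11, p10, p01, p00)`.
#' @examples
#' cohortCellProbabilities(0.1, 0.2, log(3))
#' @export
cohortCellProbabilities <- function(prevA, prevB, logOdds) {
  if (prevA < 0 || prevA > 1 || prevB < 0 || prevB > 1)
    stop("prevalences must lie in [0, 1]")
  if (!is.finite(logOdds)) stop("'logOdds' must be finite")
  psi <- exp(logOdds)
  if (abs(psi - 1) < 1e-12) {
    p11 <- prevA * prevB
  } else {
    s <- 1 + (prevA + prevB) * (psi - 1)
    disc <- s^2 - 4 * psi * (psi - 1) * prevA * prevB
    if (disc < 0)
      stop(sprintf(
        "infeasible margins/odds combination: discriminant %.6g < 0", disc))
    p11 <- (s - sqrt(disc)) / (2 * (psi - 1))
  }
  lower <- max(0, prevA + prevB - 1)
  upper <- min(prevA, prevB)
  if (p11 < lower - 1e-9 || p11 > upper + 1e-9)
    stop(sprintf(
      "infeasible margins/odds combination: p11 = %.6g outside [%.6g, %.6g]",
      p11, lower, upper))
  p11 <- min(max(p11, lower), upper)
  cells <- c(p11 = p11, p10 = prevA - p11, p01 = prevB - p11,
             p00 = 1 - prevA - prevB + p11)
  cells[abs(cells) < 1e-12] <- 0
  if (any(cells < 0))
    stop("infeasible margins/odds combination: negative cell probability")
  cells
}

#' Simulate a patient cohort with two genotype events
#'
#' Draws `nPatients` from the joint Bernoulli distribution with the
#' requested marginal prevalences and log odds ratio (see
#' [cohortCellProbabilities()]), e.g. EGFR activating mutation and PSPH
#' focal amplification across a lung-cancer cohort.
#'
#' @param nPatients cohort size.
#' @param prevA,prevB marginal prevalences of events A and B.
#' @param logOdds log odds ratio of co-occurrence (0 = independence,
#'   positive = co-occurrence, negative = mutual exclusivity).
#' @param eventA,eventB event labels used in the output table.
#' @param seed integer RNG seed.
#' @return list with `calls` (long data.frame: `patient_id`, `event`,
#'   `status` in 0/1; two rows per patient) and `truth` (cell probabilities,
#'   sampled cell counts, `cohort_log_odds`, seed).
#' @examples
#' sim <- simulateCohort(500, 0.15, 0.1, log(4), seed = 3)
#' head(sim$calls)
#' sim$truth$cells
#' @export
simulateCohort <- function(nPatients, prevA, prevB, logOdds,
                           eventA = "EGFR_MUT", eventB = "PSPH_AMP",
                           seed = 1L) {
  stopifnot(nPatients >= 1)
  probs <- cohortCellProbabilities(prevA, prevB, logOdds)
  set.seed(as.integer(seed))
  counts <- as.integer(rmultinom(1, nPatients, probs))
  names(counts) <- names(probs)
  statusA <- rep(c(1L, 1L, 0L, 0L), counts)
  statusB <- rep(c(1L, 0L, 1L, 0L), counts)
  ids <- sprintf("P%05d", seq_len(nPatients))
  calls <- data.frame(
    patient_id = rep(ids, 2L),
    event = rep(c(eventA, eventB), each = nPatients),
    status = c(statusA, statusB),
    stringsAsFactors = FALSE)
  truth <- list(cell_probabilities = probs, cells = counts,
                cohort_log_odds = logOdds, seed = as.integer(seed))
  list(calls = calls, truth = truth)
}
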