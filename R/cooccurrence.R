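#' Tabulate two genotype events from a cohort call table
#'
#' Builds the 2x2 co-occurrence table (both / A only / B only / neither)
#' from a long-format call table with one row per (patient, event) and a
#' 0/1 status. Patients missing a status for either event are excluded and
#' counted in a message.
#'
#' @param calls data.frame with columns `patient_id`, `event`, `status`.
#' @param eventA,eventB event labels to cross-tabulate.
#' @return a [ContingencyTable2x2-class].
#' @examples
#' sim <- simulateCohort(100, 0.2, 0.2, 0, seed = 1)
#' contingencyFromCalls(sim$calls, "EGFR_MUT", "PSPH_AMP")
#' @export
contingencyFromCalls <- function(calls, eventA, eventB) {
  need <- c("patient_id", "event", "status")
  if (!all(need %in% names(calls)))
    stop("'calls' must have columns: ", paste(need, collapse = ", "))
  sub <- calls[calls$event %in% c(eventA, eventB), , drop = FALSE]
  statusOf <- function(ev) {
    s <- sub[sub$event == ev, , drop = FALSE]
    setNames(s$status, s$patient_id)
  }
  a <- statusOf(eventA); b <- statusOf(eventB)
  ids <- union(names(a), names(b))
  complete <- ids[ids %in% names(a) & ids %in% names(b) &
                    !is.na(a[match(ids, names(a))]) &
                    !is.na(b[match(ids, names(b))])]
  dropped <- length(ids) - length(complete)
  if (dropped > 0)
    message(dropped, " patient(s) with missing status excluded")
  av <- a[complete] == 1L
  bv <- b[complete] == 1L
  contingencyTable2x2(sum(av & bv), sum(av & !bv), sum(!av & bv),
                      sum(!av & !bv), eventA, eventB)
}

#' Fisher's exact test on a 2x2 genotype table
#'
#' Conditional hypergeometric test with the minimum-likelihood two-sided
#' rule (all tables with fixed margins whose point probability does not
#' exceed the observed one are summed), as implemented by
#' [stats::fisher.test()]. The odds ratio reported is the sample
#' (cross-product) odds ratio `(nBoth * nNeither) / (nAOnly * nBOnly)`;
#' when a zero cell makes it 0/undefined, a 0.5 continuity-corrected value
#' is also reported and flagged. Degenerate margins (an all-zero row or
#' column) give p = 1 and an undefined odds ratio.
#'
#' @param t a [ContingencyTable2x2-class].
#' @param alternative `"two.sided"` (default), `"greater"` (co-occurrence)
#'   or `"less"` (mutual exclusivity), in terms of the odds ratio.
#' @return list with `p_value`, `odds_ratio` (sample OR; may be 0, Inf or
#'   NaN), `odds_ratio_continuity` (0.5-corrected OR, NA unless a zero cell
#'   required it), `degenerate` flag, `direction` (`"co-occurrence"`,
#'   `"mutual-exclusivity"` or `"none"`), and the cell counts.
#' @examples
#' fisherExact2x2(contingencyTable2x2(10, 10, 10, 10))$p_value  # exactly 1
#' @export
fisherExact2x2 <- function(t, alternative = c("two.sided", "greater", "less")) {
  stopifnot(is(t, "ContingencyTable2x2"))
  alternative <- match.arg(alternative)
  m <- as.matrix(t)
  total <- sum(m)
  if (total < 1) stop("table total must be >= 1")
  rowZero <- any(rowSums(m) == 0)
  colZero <- any(colSums(m) == 0)
  cells <- list(n_both = t@nBoth, n_a_only = t@nAOnly,
                n_b_only = t@nBOnly, n_neither = t@nNeither)
  if (rowZero || colZero) {
    return(c(list(p_value = 1, odds_ratio = NaN,
                  odds_ratio_continuity = NA_real_,
                  degenerate = TRUE, direction = "none"), cells))
  }
  p <- fisher.test(m, alternative = alternative)$p.value
  orNum <- as.numeric(t@nBoth) * t@nNeither
  orDen <- as.numeric(t@nAOnly) * t@nBOnly
  or <- if (orDen == 0) {
    if (orNum == 0) NaN else Inf
  } else orNum / orDen
  orCont <- NA_real_
  if (any(m == 0))
    orCont <- ((t@nBoth + 0.5) * (t@nNeither + 0.5)) /
      ((t@nAOnly + 0.5) * (t@nBOnly + 0.5))
  direction <- if (is.nan(or) || or == 1) "none"
    else if (or > 1) "co-occurrence" else "mutual-exclusivity"
  c(list(p_value = p, odds_ratio = or, odds_ratio_continuity = orCont,
         degenerate = FALSE, direction = direction), cells)
}

#' Co-occurrence rate
#'
#' Fraction of patients carrying both events, over either the carriers of
#' event A or the whole cohort.
#'
#' @param t a [ContingencyTable2x2-class].
#' @param denominator `"event_a_carriers"` (default) or `"all"`.
#' @return fraction in \[0, 1\].
#' @examples
#' cooccurrenceRate(contingencyTable2x2(58, 106, 42, 900))  # 58/164
#' @export
cooccurrenceRate <- function(t, denominator = c("event_a_carriers", "all")) {
  stopifnot(is(t, "ContingencyTable2x2"))
  denominator <- match.arg(denominator)
  den <- switch(denominator,
                event_a_carriers = t@nBoth + t@nAOnly,
                all = t@nBoth + t@nAOnly + t@nBOnly + t@nNeither)
  if (den == 0) stop("zero denominator for co-occurrence rate")
  t@nBoth / den
}
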