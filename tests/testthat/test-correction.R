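# abundance table with every natural heavy isotope switched off
zeroAbundances <- function() {
  ab <- naturalAbundances()
  naturalAbundances(overrides = lapply(ab, function(v)
    c(1, numeric(length(v) - 1L))))
}

glc <- defaultTracers()$glucose_u13c6

test_that("zero natural abundance and purity 1 give the identity matrix", {
  frag <- fragmentSpec("lactate", "C11H25O3Si2", "C", 3)
  pure <- tracerSpec("U-13C6 glucose", "C", 6, purity = 1)
  m <- buildCorrectionMatrix(frag, zeroAbundances(), pure)
  expect_equal(unname(correctionMatrix(m)), diag(4), tolerance = 1e-12)
  expect_equal(m@truncationLoss, rep(0, 4), tolerance = 1e-12)
})

test_that("single-carbon fragment matrix matches direct enumeration", {
  frag <- fragmentSpec("co2", c(C = 1L), "C", 1)
  pure <- tracerSpec("tracer", "C", 1, purity = 1)
  m <- buildCorrectionMatrix(frag, naturalAbundances(), pure)
  expect_equal(unname(correctionMatrix(m)),
               matrix(c(0.9893, 0.0107, 0, 1), 2, 2), tolerance = 1e-12)
})

test_that("untruncated columns conserve probability across the panel", {
  for (frag in defaultFragmentPanel()) {
    m <- buildCorrectionMatrix(frag, tracer = glc)
    colSumsPlusLoss <- colSums(correctionMatrix(m)) + m@truncationLoss
    expect_equal(unname(colSumsPlusLoss), rep(1, nLabelable(frag) + 1L),
                 tolerance = 1e-12)
    expect_true(all(correctionMatrix(m) >= 0))
  }
})

test_that("carbon-only column spectra match the 2^n enumeration oracle", {
  frag <- fragmentSpec("c3", c(C = 3L), "C", 3)
  pure <- tracerSpec("tracer", "C", 3, purity = 1)
  m <- correctionMatrix(buildCorrectionMatrix(frag, naturalAbundances(), pure))
  # column 0: all three carbons natural
  expect_equal(unname(m[, 1]), enumCarbonSpectrum(3), tolerance = 1e-12)
  # column 1: one fixed heavy carbon, two natural (shifted enumeration)
  expect_equal(unname(m[, 2]), c(0, enumCarbonSpectrum(2)[1:3]),
               tolerance = 1e-12)
})

test_that("tracer element mismatch and oversize labelable counts are rejected", {
  frag <- fragmentSpec("lactate", "C11H25O3Si2", "C", 3)
  nTracer <- tracerSpec("15N tracer", "N", 1)
  expect_error(buildCorrectionMatrix(frag, tracer = nTracer),
               "does not match")
})

test_that("correctMid recovers exact column matches and random mixtures", {
  frag <- defaultFragmentPanel()$citrate
  m <- buildCorrectionMatrix(frag, tracer = glc)
  corrected <- correctMid(correctionMatrix(m)[, 1], m)
  expect_equal(as.numeric(corrected), c(1, rep(0, 6)), tolerance = 1e-10)
  set.seed(42)
  for (rep in 1:25) {
    v <- randomSimplex(7)
    raw <- as.numeric(correctionMatrix(m) %*% v)
    expect_equal(as.numeric(correctMid(raw, m)), v, tolerance = 1e-8)
  }
})

test_that("correctMid rejects degenerate input", {
  frag <- defaultFragmentPanel()$lactate
  m <- buildCorrectionMatrix(frag, tracer = glc)
  expect_error(correctMid(numeric(4), m), "all-zero")
  expect_error(correctMid(c(1, 2), m), "entries")
  expect_error(correctMid(c(-1, 0, 0, 1), m), "non-negative")
})

test_that("fully labeled pool with impure tracer corrects to the binomial", {
  # the labeled-pool MID carries Binomial(n, purity); correcting without
  # purity deconvolution must return exactly that binomial
  frag <- defaultFragmentPanel()$lactate
  lac <- defaultTracers()$lactate_u13c3        # purity 0.98
  sim <- simulateLabeling(fluxRegime("FGFR", tcaFromLactateFraction = 1),
                          lac)
  m <- buildCorrectionMatrix(frag, tracer = lac, purityCorrection = FALSE)
  raw <- as.numeric(correctionMatrix(m) %*% sim$mids$lactate)
  expect_equal(as.numeric(correctMid(raw, m)), dbinom(0:3, 3, 0.98),
               tolerance = 1e-8)
  # with purity deconvolution the labeled pool collapses onto M3
  mP <- buildCorrectionMatrix(frag, tracer = lac, purityCorrection = TRUE)
  expect_equal(as.numeric(correctMid(raw, mP)), c(0, 0, 0, 1), tolerance = 1e-6)
})

test_that("fractional enrichment covers the boundary and symmetric cases", {
  expect_equal(fractionalEnrichment(c(1, 0, 0, 0)), 0)
  expect_equal(fractionalEnrichment(c(0, 0, 0, 1)), 1)
  expect_equal(fractionalEnrichment(rep(1 / 3, 3)), 0.5)
  expect_error(fractionalEnrichment(1), "n >= 1")
  expect_error(fractionalEnrichment(c(0.7, 0.7)), "sum")
})

test_that("fractional enrichment is invariant to raw intensity scaling", {
  frag <- defaultFragmentPanel()$serine
  m <- buildCorrectionMatrix(frag, tracer = glc)
  set.seed(5)
  v <- randomSimplex(4)
  raw <- as.numeric(correctionMatrix(m) %*% v)
  e1 <- fractionalEnrichment(correctMid(raw, m))
  e2 <- fractionalEnrichment(correctMid(raw * 1e7, m))
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("fraction contribution table averages within groups", {
  corrected <- data.frame(
    metabolite = rep("lactate", 6),
    isotopologue = rep(c("M0", "M3"), 3),
    sample = rep(c("a1", "a2", "b1"), each = 2),
    fraction = c(0.4, 0.6, 0.2, 0.8, 1.0, 0.0))
  grouping <- c(a1 = "EGFR", a2 = "EGFR", b1 = "WT")
  tab <- fractionContributionTable(corrected, grouping)
  expect_equal(tab["lactate:M3", "EGFR"], 0.7)   # hand-computed mean
  expect_equal(tab["lactate:M0", "WT"], 1.0)
  # duplicated sample leaves the mean unchanged
  dup <- rbind(corrected, corrected[corrected$sample == "a1", ])
  expect_equal(fractionContributionTable(dup, grouping)["lactate:M3", "EGFR"],
               (0.6 * 2 + 0.8) / 3)
  # one sample per group reproduces the input
  one <- corrected[corrected$sample %in% c("a1", "b1"), ]
  tab1 <- fractionContributionTable(one, grouping[c("a1", "b1")])
  expect_equal(tab1["lactate:M3", "EGFR"], 0.6)
  expect_warning(
    fractionContributionTable(one, c(a1 = "EGFR", b1 = "WT", c1 = "RET")),
    "zero samples")
})
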