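test_that("contingency tabulation matches the generator's internal tally", {
  sim <- simulateCohort(300, 0.2, 0.25, 1, seed = 61)
  ct <- contingencyFromCalls(sim$calls, "EGFR_MUT", "PSPH_AMP")
  cells <- sim$truth$cells
  expect_equal(ct@nBoth, unname(cells["p11"]))
  expect_equal(ct@nAOnly, unname(cells["p10"]))
  expect_equal(ct@nBOnly, unname(cells["p01"]))
  expect_equal(ct@nNeither, unname(cells["p00"]))
})

test_that("edge cohorts tabulate correctly", {
  empty <- data.frame(patient_id = character(), event = character(),
                      status = integer())
  ct0 <- contingencyFromCalls(empty, "A", "B")
  expect_equal(as.numeric(as.matrix(ct0)), rep(0, 4))
  allBoth <- data.frame(patient_id = rep(c("p1", "p2"), 2),
                        event = rep(c("A", "B"), each = 2),
                        status = 1L)
  expect_equal(contingencyFromCalls(allBoth, "A", "B")@nBoth, 2L)
  # missing status excluded with a message
  miss <- rbind(allBoth, data.frame(patient_id = "p3", event = "A",
                                    status = 1L))
  expect_message(ctm <- contingencyFromCalls(miss, "A", "B"), "excluded")
  expect_equal(ctm@nBoth, 2L)
})

test_that("balanced independence gives p = 1 and OR = 1", {
  res <- fisherExact2x2(contingencyTable2x2(10, 10, 10, 10))
  expect_equal(res$p_value, 1)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$direction, "none")
})

test_that("two-sided p matches the enumeration oracle on random small tables", {
  set.seed(62)
  for (rep in 1:200) {
    cells <- as.integer(rmultinom(1, sample(1:30, 1), rep(0.25, 4)))
    ct <- contingencyTable2x2(cells[1], cells[2], cells[3], cells[4])
    res <- fisherExact2x2(ct)
    if (res$degenerate) {
      expect_equal(res$p_value, 1)
    } else {
      expect_equal(res$p_value,
                   oracleFisherTwoSided(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-12)
    }
  }
})

test_that("the test is symmetric in the two events and under joint swaps", {
  set.seed(63)
  for (rep in 1:50) {
    cells <- as.integer(rmultinom(1, 60, c(0.1, 0.3, 0.2, 0.4)))
    p1 <- fisherExact2x2(contingencyTable2x2(cells[1], cells[2], cells[3],
                                             cells[4]))$p_value
    # swap events A and B (transpose)
    p2 <- fisherExact2x2(contingencyTable2x2(cells[1], cells[3], cells[2],
                                             cells[4]))$p_value
    # simultaneous row+column swap
    p3 <- fisherExact2x2(contingencyTable2x2(cells[4], cells[3], cells[2],
                                             cells[1]))$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_equal(p1, p3, tolerance = 1e-12)
  }
})

test_that("EGFR/NRF2-style mutual exclusivity is detected from printed counts", {
  # 1940 patients, 44 event-A carriers, 106 event-B carriers, zero overlap
  ct <- contingencyTable2x2(0, 44, 106, 1790, "EGFR_MUT", "NRF2_MUT")
  res <- fisherExact2x2(ct)
  expect_equal(res$odds_ratio, 0)
  expect_equal(res$direction, "mutual-exclusivity")
  expect_equal(res$p_value, oracleFisherTwoSided(0, 44, 106, 1790),
               tolerance = 1e-12)
  expect_false(is.na(res$odds_ratio_continuity))
})

test_that("degenerate margins give p = 1 and an undefined odds ratio", {
  res <- fisherExact2x2(contingencyTable2x2(0, 0, 5, 7))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_true(is.nan(res$odds_ratio))
  expect_error(fisherExact2x2(contingencyTable2x2(0, 0, 0, 0)), ">= 1")
})

test_that("co-occurrence rates use the requested denominator", {
  ct <- contingencyTable2x2(58, 106, 42, 900)
  expect_equal(cooccurrenceRate(ct), 58 / 164)
  expect_equal(cooccurrenceRate(ct, "all"), 58 / 1106)
  expect_equal(cooccurrenceRate(contingencyTable2x2(5, 0, 2, 3)), 1)
  expect_equal(cooccurrenceRate(contingencyTable2x2(0, 9, 2, 3)), 0)
  expect_error(cooccurrenceRate(contingencyTable2x2(0, 0, 2, 3)),
               "denominator")
})

test_that("power against dependence increases with the log odds ratio", {
  rej <- c(lo1 = 0L, lo2 = 0L)
  nRep <- 120
  for (r in seq_len(nRep)) {
    for (nm in names(rej)) {
      lo <- if (nm == "lo1") 1 else 2
      sim <- simulateCohort(300, 0.15, 0.15, lo, seed = 7000 + 10 * r +
                              (lo == 2))
      ct <- contingencyFromCalls(sim$calls, "EGFR_MUT", "PSPH_AMP")
      if (fisherExact2x2(ct)$p_value < 0.05) rej[nm] <- rej[nm] + 1L
    }
  }
  expect_gt(rej["lo2"], rej["lo1"])
})
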