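test_that("metabolic filtering is case-insensitive", {
  expect_message(out <- filterMetabolic(c("Psph", "phgdh", "TP53"),
                                        c("PSPH", "PHGDH", "LDHA")),
                 "2 of 3")
  expect_setequal(out, c("PSPH", "PHGDH"))
  u <- c("A", "B")
  expect_message(expect_warning(
    out2 <- filterMetabolic(c("X", "Y"), u), "no overlap"))
  expect_length(out2, 0)
  expect_message(expect_equal(filterMetabolic(c("a", "b"), u), c("A", "B")))
  expect_error(filterMetabolic(character(), u), "non-empty")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(adjustBh(0.03), 0.03)
  expect_equal(adjustBh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(31)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- adjustBh(p)
    expect_equal(adj, oracleBH(p), tolerance = 1e-15)
    expect_true(all(adj >= p - 1e-15))
  }
  expect_error(adjustBh(c(0.1, NA)), "NA")
  expect_error(adjustBh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("null regulons are essentially never selected at alpha 0.0005", {
  universe <- sprintf("GENE%04d", 1:500)
  degs <- universe[1:50]
  db <- simulateTfDatabase(1000, 40, universe, seed = 55)  # all null
  enr <- suppressMessages(enrichTfs(degs, universe, db$regulons,
                                    alpha = 5e-4))
  expect_length(enr$selected, 0)
})

test_that("alpha = 1 selects every tested TF", {
  universe <- sprintf("GENE%04d", 1:100)
  db <- simulateTfDatabase(10, 10, universe, seed = 56)
  enr <- suppressMessages(enrichTfs(universe[1:10], universe, db$regulons,
                                    alpha = 1))
  expect_length(enr$selected, 10)
})

test_that("planted TFs are selected with no false positives across seeds", {
  universe <- sprintf("GENE%04d", 1:500)
  degs <- universe[1:50]
  planted <- sprintf("PTF%02d", 1:5)
  for (seed in 1:10) {
    db <- simulateTfDatabase(100, 40, universe, plantedTfs = planted,
                             degGenes = degs, plantedOverlapFraction = 0.8,
                             seed = seed)
    enr <- suppressMessages(enrichTfs(degs, universe, db$regulons,
                                      alpha = 5e-4))
    expect_setequal(enr$selected, planted)
    # planted TFs occupy the smallest adjusted p-values
    expect_setequal(enr$records$set[seq_along(planted)], planted)
  }
})

test_that("the sub-network keeps TF-target edges within the target set", {
  net <- buildSubnetwork("MYC", list(MYC = c("LDHA", "PSPH", "OUTSIDE")),
                         c("LDHA", "PSPH"), list())
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$to, c("LDHA", "PSPH"))
  expect_error(buildSubnetwork("NOPE", list(MYC = "LDHA"), "LDHA"),
               "NOPE")
})

test_that("multi-source PPI edges are merged with provenance union", {
  reg <- list(MYC = c("A", "B"), ATF4 = c("B", "C"))
  ppi <- list(
    data.frame(a = "B", b = "A", source = "string"),
    data.frame(a = c("A", "C"), b = c("B", "B"), source = "biogrid"))
  net <- buildSubnetwork(c("MYC", "ATF4"), reg, c("A", "B", "C"), ppi)
  ab <- net$edges[net$edges$type == "ppi" & net$edges$from == "A" &
                    net$edges$to == "B", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$sources, "biogrid;string")
  # shared target B is regulated by both TFs
  expect_equal(sum(net$edges$type == "tf-target" & net$edges$to == "B"), 2)
})

test_that("edge counts are invariant to input order and duplication", {
  reg <- list(TF1 = c("A", "B", "C"), TF2 = c("B", "C"))
  targets <- c("A", "B", "C")
  ppiA <- data.frame(a = c("A", "B", "A"), b = c("B", "C", "B"),
                     source = "db1")
  n1 <- buildSubnetwork(c("TF1", "TF2"), reg, targets, list(ppiA))
  n2 <- buildSubnetwork(c("TF2", "TF1"), reg, targets,
                        list(ppiA[c(3, 1, 2), ], ppiA))
  expect_equal(n1$edges[c("from", "to", "type")],
               n2$edges[c("from", "to", "type")])
})

test_that("SIF export writes one line per edge", {
  net <- buildSubnetwork("MYC", list(MYC = c("LDHA", "PSPH")),
                         c("LDHA", "PSPH"), list())
  path <- withr::local_tempfile(fileext = ".sif")
  writeSif(net, path)
  expect_equal(readLines(path),
               c("MYC\ttf-target\tLDHA", "MYC\ttf-target\tPSPH"))
})
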