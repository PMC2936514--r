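test_that("batch-size filter keeps only batches with MORE than the threshold", {
  design <- data.frame(drug = sprintf("d%02d", 1:51),
                       batch = rep(c("b25", "b26"), c(25L, 26L)))
  ps <- makeToyPS(design)
  kept <- filterInstances(ps, min_batch_size = 25L)
  expect_identical(unique(batchIds(kept)), "b26")
  expect_identical(ncol(kept), 26L)
  # a batch of exactly the threshold is excluded entirely
  expect_false(any(batchIds(kept) == "b25"))
})

test_that("vehicle controls are discarded and count toward nothing", {
  design <- data.frame(drug = c("d1", "d2", "d3", NA, NA),
                       batch = "b1",
                       control = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  ps <- makeToyPS(design)
  kept <- filterInstances(ps, min_batch_size = 2L)
  expect_identical(ncol(kept), 3L)
  expect_false(any(isControl(kept)))
  # 3 treatments is not > 3: batch dropped even though 5 arrays exist
  expect_warning(empty <- filterInstances(ps, min_batch_size = 3L),
                 "no instances survive")
  expect_identical(ncol(empty), 0L)
})

test_that("an all-control compendium filters to empty with a warning", {
  design <- data.frame(drug = c(NA, NA), batch = "b1",
                       control = c(TRUE, TRUE))
  ps <- makeToyPS(design)
  expect_warning(out <- filterInstances(ps, min_batch_size = 0L),
                 "no instances survive")
  expect_identical(ncol(out), 0L)
})

test_that("highest concentration is selected per drug and cell line", {
  design <- data.frame(drug = c("dA", "dA", "dA", "dB"),
                       batch = "b1",
                       conc = c(100, 10, 10, 5),
                       unit = c("nM", "uM", "uM", "uM"))
  ps <- makeToyPS(design)
  kept <- selectHighestConcentration(ps)
  # 100 nM < 10 uM after unit conversion; both 10 uM replicates remain
  expect_identical(colData(kept)$concentration_value, c(10, 10, 5))
  # irreconcilable units are refused
  design2 <- data.frame(drug = "dC", batch = "b1",
                        instance_id = c("x1", "x2"),
                        conc = c(1, 2), unit = c("uM", "mg/ml"))
  expect_error(selectHighestConcentration(makeToyPS(design2)),
               "irreconcilable")
})

test_that("concentration selection is per cell line, not global", {
  design <- data.frame(drug = "dA", batch = c("b1", "b2"),
                       cell_line = c("MCF7", "PC3"), conc = c(10, 1))
  ps <- makeToyPS(design)
  kept <- selectHighestConcentration(ps)
  expect_identical(ncol(kept), 2L)  # 1 uM PC3 instance is that line's max
})

test_that("population mean-centering does the stated arithmetic", {
  design <- data.frame(drug = c("d1", "d2"), batch = "b1")
  ps <- makeToyPS(design, values = matrix(c(2, 5, 4, 5), nrow = 2))
  cen <- meanCenterBatch(ps)
  expect_equal(unname(exprValues(cen)[1L, ]), c(-1, 1))
  expect_equal(unname(exprValues(cen)[2L, ]), c(0, 0))  # constant row -> 0

  design3 <- data.frame(drug = c("d1", "d2", "d3"), batch = "b1")
  ps3 <- makeToyPS(design3, values = matrix(c(1, 2, 6), nrow = 1))
  expect_equal(unname(exprValues(meanCenterBatch(ps3))[1L, ]), c(-2, -1, 3))
})

test_that("mean-centering is idempotent and zeroes per-batch means", {
  sim <- simulateCompendium(smallSimConfig(batches_per_cell_line = 3L))
  cen1 <- meanCenterBatch(sim$ps)
  cen2 <- meanCenterBatch(cen1)
  expect_equal(exprValues(cen1), exprValues(cen2), tolerance = 1e-12)
  x <- exprValues(cen1)
  for (b in unique(batchIds(cen1))) {
    bm <- rowMeans(x[, batchIds(cen1) == b, drop = FALSE])
    expect_lt(max(abs(bm)), 1e-9)
  }
})

test_that("a singleton batch cannot be population-centered", {
  design <- data.frame(drug = c("d1", "d2", "d3"),
                       batch = c("b1", "b1", "b2"))
  ps <- makeToyPS(design)
  expect_error(meanCenterBatch(ps), "fewer than 2 treatments")
})

test_that("control centering subtracts the batch's control mean", {
  design <- data.frame(drug = c("dA", "dB", NA, NA), batch = "b1",
                       control = c(FALSE, FALSE, TRUE, TRUE))
  vals <- matrix(c(5, 4, 4, 4,   # treatment 5 vs single-ish controls
                   4, 9, 3, 5),  # controls 3 and 5 -> mean 4
                 nrow = 2, byrow = TRUE)
  ps <- makeToyPS(design, values = vals)
  cen <- controlCenterBatch(ps)
  expect_identical(ncol(cen), 2L)           # controls dropped from output
  expect_equal(unname(exprValues(cen)[1L, ]), c(1, 0))
  expect_equal(unname(exprValues(cen)[2L, ]), c(0, 5))
  # a batch without controls is an error
  noctl <- makeToyPS(data.frame(drug = c("d1", "d2"), batch = "b9"))
  expect_error(controlCenterBatch(noctl), "no vehicle controls")
})

test_that("replicate merging averages columns within (drug, cell line)", {
  design <- data.frame(drug = c("dA", "dA", "dB"), batch = "b1")
  vals <- matrix(c(1, 3, 7,
                   -1, 1, 2), nrow = 2, byrow = TRUE)
  ps <- makeToyPS(design, values = vals)
  prof <- mergeReplicates(ps)
  a <- amplitudeValues(prof)
  expect_identical(ncol(prof), 2L)
  expect_equal(unname(a[, "dA.MCF7"]), c(2, 0))
  expect_equal(unname(a[, "dB.MCF7"]), c(7, 2))   # single instance: identity
  expect_identical(colData(prof)$n_instances,
                   unname(c("dA.MCF7" = 2L, "dB.MCF7" = 1L)[colnames(a)]))
})

test_that("the same drug in two cell lines yields two distinct profiles", {
  design <- data.frame(drug = "dA", batch = c("b1", "b2"),
                       cell_line = c("MCF7", "PC3"))
  prof <- mergeReplicates(makeToyPS(design))
  expect_identical(ncol(prof), 2L)
  expect_setequal(as.character(colData(prof)$cell_line), c("MCF7", "PC3"))
})

test_that("presence thresholds are inclusive", {
  design <- data.frame(drug = sprintf("d%02d", 1:10), batch = "b1")
  calls <- matrix("A", 3L, 10L)
  calls[1L, 1:5] <- "P"   # present in exactly half
  calls[2L, 1L] <- "P"    # present in exactly one tenth
  ps <- makeToyPS(design, values = matrix(0, 3L, 10L), calls = calls)
  half <- assignPresence(ps, threshold = 0.5)
  tenth <- assignPresence(ps, threshold = 0.1)
  expect_true("P001" %in% half@probes)
  expect_false("P002" %in% half@probes)
  expect_true(all(c("P001", "P002") %in% tenth@probes))
  expect_false("P003" %in% tenth@probes)   # never present
  expect_error(assignPresence(ps, threshold = 0),   "\\(0, 1\\]")
  expect_error(assignPresence(ps, cell_line = "PC3"), "no treatment")
})

test_that("marginal calls do not count as present", {
  design <- data.frame(drug = c("d1", "d2"), batch = "b1")
  calls <- matrix(c("M", "M"), 1L, 2L)
  ps <- makeToyPS(design, values = matrix(0, 1L, 2L), calls = calls)
  expect_length(assignPresence(ps, threshold = 0.5)@probes, 0L)
})

test_that("batch filter and concentration selection commute", {
  sim <- simulateCompendium(smallSimConfig(two_conc_fraction = 0.6,
                                           replicate_rate = 0.4, seed = 9L))
  ps <- sim$ps
  a <- selectHighestConcentration(filterInstances(ps, min_batch_size = 5L))
  b <- filterInstances(selectHighestConcentration(ps), min_batch_size = 5L)
  expect_identical(sort(colnames(a)), sort(colnames(b)))
})

test_that("centering removes the batch term exactly when signatures are off", {
  cfg <- smallSimConfig(signature_amplitude = 0, noise_sd = 0,
                        batch_sd = 1.2, regulation_effect = 0)
  sim <- simulateCompendium(cfg)
  cen <- meanCenterBatch(sim$ps)
  expect_lt(max(abs(exprValues(cen))), 1e-9)
})
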