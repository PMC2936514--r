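test_that("extreme query sets attain enrichment scores of exactly +/-1", {
  r <- randomRankedProfile(100L)
  expect_equal(ksEnrichment(r@probes[1:10], r)$value, 1)
  expect_equal(ksEnrichment(r@probes[91:100], r)$value, -1)
  expect_error(ksEnrichment(character(), r), "non-empty")
  expect_error(ksEnrichment(r@probes, r), "proper subset")
  expect_error(ksEnrichment(c("nope"), r), "absent")
})

test_that("the enrichment score matches the brute-force walk oracle", {
  set.seed(21)
  for (i in 1:500) {
    N <- sample(20:150, 1L)
    r <- randomRankedProfile(N)
    q <- sample(r@probes, sample.int(N - 1L, 1L))
    mode <- if (i %% 2L) "classic" else "weighted"
    es <- ksEnrichment(q, r, weighting = mode)$value
    oracle <- ksWalkOracle(r@probes %in% q, r@effective, weighting = mode)
    expect_equal(es, oracle, tolerance = 1e-12)
  }
})

test_that("enrichment scores stay within [-1, 1]", {
  set.seed(22)
  for (i in 1:2000) {
    N <- sample(10:80, 1L)
    r <- randomRankedProfile(N)
    q <- sample(r@probes, sample.int(N - 1L, 1L))
    es <- ksEnrichment(q, r, weighting = sample(c("classic", "weighted"),
                                                1L))$value
    expect_gte(es, -1)
    expect_lte(es, 1)
  }
})

test_that("self-comparison scores 1 and the reversed profile scores -1", {
  r <- randomRankedProfile(200L)
  s <- extractSignature(r, 20L)
  expect_equal(dipsPair(s, r, s, r), 1)
  # invert the profile: ranking reverses exactly (distinct values)
  v <- stats::setNames(-r@initial, r@probes)
  rr <- rankProfile(v, present = names(v))
  sr <- extractSignature(rr, 20L)
  expect_identical(rr@probes, rev(r@probes))
  expect_equal(dipsPair(s, r, sr, rr), -1)
})

test_that("the DIPS score is symmetric bit-for-bit", {
  set.seed(23)
  for (i in 1:200) {
    r1 <- randomRankedProfile(120L)
    r2 <- randomRankedProfile(120L)
    # shared probe universe
    v2 <- stats::setNames(r2@initial, r1@probes[order(r1@probes)])
    r2 <- rankProfile(v2, present = names(v2))
    s1 <- extractSignature(r1, 15L)
    s2 <- extractSignature(r2, 15L)
    expect_identical(dipsPair(s1, r1, s2, r2), dipsPair(s2, r2, s1, r1))
  }
})

test_that("DIPS of independent random profiles is centered near zero", {
  set.seed(24)
  mat <- matrix(stats::rnorm(1000L * 40L), nrow = 1000L,
                dimnames = list(sprintf("p%04d", 1:1000),
                                sprintf("D%02d", 1:40)))
  prof <- makeProfiles(mat, drug_ids = colnames(mat))
  pres <- makePresence(rownames(mat))
  dm <- dipsMatrix(prof, pres, n = 50L)
  null_scores <- dm@scores[upper.tri(dm@scores)]
  expect_gte(length(null_scores), 500L)
  expect_lt(abs(mean(null_scores[1:500])), 0.05)
  expect_equal(unname(diag(dm@scores)), rep(1, 40L))
})

test_that("weighted-mode pair scores agree between the public and matrix paths", {
  set.seed(25)
  mat <- matrix(stats::rnorm(200L * 6L), nrow = 200L,
                dimnames = list(sprintf("p%03d", 1:200),
                                sprintf("D%02d", 1:6)))
  prof <- makeProfiles(mat)
  pres <- makePresence(rownames(mat)[1:150])  # some probes Absent
  for (mode in c("classic", "weighted")) {
    dm <- dipsMatrix(prof, pres, n = 20L, weighting = mode)
    ranked <- rankProfiles(prof, pres)
    sigs <- lapply(ranked, extractSignature, n = 20L)
    for (k in 1:5) {
      i <- sample.int(6L, 1L); j <- sample.int(6L, 1L)
      expect_equal(dm@scores[i, j],
                   dipsPair(sigs[[i]], ranked[[i]], sigs[[j]], ranked[[j]],
                            weighting = mode), tolerance = 1e-12)
    }
  }
})

test_that("signature overlap below 90% with the partner profile is an error", {
  r1 <- randomRankedProfile(100L)
  s1 <- extractSignature(r1, 10L)
  v2 <- stats::setNames(stats::rnorm(60L), r1@probes[1:60])
  r2 <- rankProfile(v2, present = names(v2))
  s2 <- extractSignature(r2, 10L)
  expect_error(dipsPair(s1, r1, s2, r2), "90%")
})

test_that("cell-line combination averages the available scores per pair", {
  mk <- function(val, drugs, cl) {
    s <- matrix(c(1, val, val, 1), 2L, 2L, dimnames = list(drugs, drugs))
    new("DIPSMatrix", scores = s, cell_line = cl, weighting = "classic")
  }
  comb <- combineCellLines(list(mk(0.4, c("a", "b"), "HL60"),
                                mk(0.6, c("a", "b"), "MCF7"),
                                mk(0.8, c("a", "b"), "PC3")))
  expect_equal(comb@scores["a", "b"], 0.6)
  expect_identical(comb@cell_line, "combined")
  comb1 <- combineCellLines(list(mk(0.3, c("a", "b"), "HL60")))
  expect_equal(comb1@scores["a", "b"], 0.3)
  mixed <- combineCellLines(list(mk(0.5, c("a", "b"), "HL60"),
                                 mk(-0.5, c("a", "b"), "MCF7"),
                                 mk(0.9, c("a", "c"), "PC3")))
  expect_equal(mixed@scores["a", "b"], 0)
  expect_equal(mixed@scores["a", "c"], 0.9)
  expect_true(is.na(mixed@scores["b", "c"]))  # never co-profiled
})

test_that("the Pearson variant reproduces closed-form correlations", {
  mat <- cbind(x = c(1, 2, 3), y = c(1, 2, 4))
  rownames(mat) <- sprintf("p%d", 1:3)
  prof <- makeProfiles(mat)
  r <- pairwisePearson(prof)
  expect_equal(unname(diag(r)), c(1, 1))
  expect_equal(r[1L, 2L], 0.98198051, tolerance = 1e-7)
  neg <- makeProfiles(cbind(x = c(1, 2, 3), y = -c(1, 2, 3)))
  expect_equal(pairwisePearson(neg)[1L, 2L], -1)
  flat <- makeProfiles(cbind(x = c(1, 2, 3), y = c(2, 2, 2)))
  expect_warning(rf <- pairwisePearson(flat), "zero-variance")
  expect_true(is.na(rf[1L, 2L]))
})

test_that("instance pairs are assigned the four drug/batch categories", {
  design <- data.frame(drug = c("dA", "dA", "dA", "dB", "dB"),
                       batch = c("b1", "b1", "b2", "b1", "b2"))
  set.seed(26)
  ps <- makeToyPS(design, values = matrix(stats::rnorm(100L), 20L, 5L))
  pres <- makePresence(sprintf("P%03d", 1:20))
  suppressWarnings(out <- categorizePairs(ps, pres, n = 3L))
  sc <- out$scores
  lookup <- function(a, b)
    sc$category[(sc$instance_a == a & sc$instance_b == b) |
                  (sc$instance_a == b & sc$instance_b == a)]
  expect_identical(lookup("i01", "i02"), "same-drug/same-batch")
  expect_identical(lookup("i01", "i03"), "same-drug/different-batch")
  expect_identical(lookup("i01", "i04"), "different-drug/same-batch")
  expect_identical(lookup("i01", "i05"), "different-drug/different-batch")
  expect_identical(nrow(sc), 10L)
})

test_that("cross-cell-line merge keeps only jointly Present probes", {
  m1 <- makeProfiles(matrix(1:6, 3L, 2L,
                            dimnames = list(c("A", "B", "C"), NULL)),
                     cell_line = "HL60", drug_ids = c("d1", "d2"))
  m2 <- makeProfiles(matrix(1:6, 3L, 2L,
                            dimnames = list(c("B", "C", "D"), NULL)),
                     cell_line = "MCF7", drug_ids = c("d1", "d2"))
  p1 <- makePresence(c("A", "B", "C"), "HL60")
  p2 <- makePresence(c("B", "C"), "MCF7")
  p3 <- makePresence(c("B", "C", "D"), "MCF7")
  merged <- crossCellLineMerge(list(m1, m2), list(p1, p2, p3))
  expect_setequal(rownames(merged), c("B", "C"))
  expect_identical(ncol(merged), 4L)
  expect_error(crossCellLineMerge(list(m1), list(p1)), "at least two")
  expect_error(
    crossCellLineMerge(list(m1, m2),
                       list(makePresence("A"), makePresence("D"))),
    "no probe")
})
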