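relTable <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  d$confidence <- d$confidence %||% 0.9
  d$channel <- d$channel %||% "experimental"
  d
}

test_that("relation filtering is strict on confidence and channel", {
  rel <- relTable(drug_id = c("d1", "d2", "d3"), gene_id = "G1",
                  action = "inhibition",
                  confidence = c(0.71, 0.70, 0.90),
                  channel = c("experimental", "database", "textmining"))
  out <- filterRelations(rel)
  expect_identical(out$drug_id, "d1")     # 0.70 exact and textmining dropped
  expect_identical(nrow(filterRelations(rel, min_confidence = 0.5)), 2L)
})

test_that("binding actions fold into inhibition with manual overrides", {
  rel <- relTable(drug_id = c("d1", "d2"), gene_id = c("G1", "G2"),
                  action = c("binding", "activation"))
  out <- foldBindingActions(rel)
  expect_identical(out$action, c("inhibition", "activation"))
  ov <- data.frame(drug_id = "d1", gene_id = "G1", action = "activation")
  expect_identical(foldBindingActions(rel, ov)$action[1L], "activation")
  expect_error(foldBindingActions(relTable(drug_id = "d", gene_id = "G",
                                           action = "cleavage")),
               "unknown action")
})

test_that("target expression filtering is per cell line", {
  rel <- relTable(drug_id = c("d1", "d2"), gene_id = c("G1", "G2"),
                  action = "inhibition")
  pmap <- data.frame(probe_id = c("P1", "P2"), gene_id = c("G1", "G2"))
  pres <- list(MCF7 = makePresence("P1", "MCF7", threshold = 0.1),
               PC3 = makePresence(c("P1", "P2"), "PC3", threshold = 0.1))
  out <- filterExpressedTargets(rel, pres, pmap)
  expect_identical(out$expressed_in, c("MCF7,PC3", "PC3"))
  # a target Present nowhere is dropped
  pres0 <- list(MCF7 = makePresence(character(), "MCF7", threshold = 0.1))
  expect_identical(nrow(filterExpressedTargets(rel, pres0, pmap)), 0L)
})

test_that("a strong injected effect is detected with the right direction", {
  set.seed(41)
  n_bg <- 60L
  amp <- c(-2.0, -2.1, -1.9, stats::rnorm(n_bg, 0, 0.2))
  mat <- matrix(stats::rnorm((n_bg + 3L) * 5L, 0, 0.2), nrow = 5L)
  mat[3L, ] <- amp
  rownames(mat) <- sprintf("P%d", 1:5)
  prof <- makeProfiles(mat, drug_ids = sprintf("d%02d", seq_len(n_bg + 3L)))
  pmap <- data.frame(probe_id = "P3", gene_id = "G3")
  pres <- list(MCF7 = makePresence("P3", "MCF7", threshold = 0.1))
  res <- targetChangeTest(prof, "G3", c("d01", "d02", "d03"), pres, pmap,
                          action = "activation")
  expect_identical(res$summary$direction, "down")
  expect_lt(res$summary$anova_p, 0.01)
  expect_lt(res$by_cell_line$p, 0.01)
  # independent permutation oracle agrees that this is extreme
  p_perm <- permutationPOracle(amp, c(rep(TRUE, 3L), rep(FALSE, n_bg)),
                               B = 10000L)
  expect_lt(p_perm, 0.01)
})

test_that("Welch p-values track a permutation oracle on random cases", {
  set.seed(42)
  diffs <- numeric(20)
  for (i in 1:20) {
    x <- c(stats::rnorm(12, mean = stats::runif(1, -0.5, 0.5)),
           stats::rnorm(80))
    g <- c(rep(TRUE, 12), rep(FALSE, 80))
    p_welch <- stats::t.test(x[g], x[!g])$p.value
    p_perm <- permutationPOracle(x, g, B = 4000L)
    diffs[i] <- abs(p_welch - p_perm)
  }
  expect_lt(stats::median(diffs), 0.03)
  expect_lt(max(diffs), 0.1)
})

test_that("with a single cell line the ANOVA reduces to the pooled t-test", {
  set.seed(43)
  n <- 40L
  mat <- matrix(stats::rnorm(2L * n), nrow = 2L,
                dimnames = list(c("P1", "P2"), NULL))
  prof <- makeProfiles(mat, drug_ids = sprintf("d%02d", seq_len(n)))
  pmap <- data.frame(probe_id = "P1", gene_id = "G1")
  pres <- list(MCF7 = makePresence("P1", "MCF7", threshold = 0.1))
  res <- targetChangeTest(prof, "G1", c("d01", "d02", "d03", "d04"), pres,
                          pmap, action = "inhibition")
  x <- mat["P1", ]
  g <- seq_len(n) <= 4L
  p_student <- stats::t.test(x[g], x[!g], var.equal = TRUE)$p.value
  expect_equal(res$summary$anova_p, p_student, tolerance = 1e-12)
})

test_that("null per-target p-values are uniform", {
  set.seed(44)
  n <- 80L
  pvals <- numeric(500)
  pmap <- data.frame(probe_id = "P1", gene_id = "G1")
  pres <- list(MCF7 = makePresence("P1", "MCF7", threshold = 0.1))
  for (i in seq_along(pvals)) {
    mat <- matrix(stats::rnorm(n), nrow = 1L,
                  dimnames = list("P1", NULL))
    prof <- makeProfiles(mat, drug_ids = sprintf("d%02d", seq_len(n)))
    res <- targetChangeTest(prof, "G1", sample(sprintf("d%02d", 1:n), 5L),
                            pres, pmap)
    pvals[i] <- res$summary$anova_p
  }
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Benjamini-Hochberg q-values match the hand-computed step-up", {
  r <- data.frame(anova_p = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(multipleTesting(r)$q, rep(0.04, 4L))
  expect_equal(multipleTesting(data.frame(anova_p = 0.37))$q, 0.37)
  expect_equal(multipleTesting(data.frame(anova_p = c(1, 1)))$q, c(1, 1))
  mixed <- multipleTesting(data.frame(anova_p = c(0.001, NA, 0.5)))
  expect_true(is.na(mixed$q[2L]))
  expect_false(mixed$significant[2L])
  # monotone non-decreasing in p after sorting
  set.seed(45)
  p <- stats::runif(50)
  q <- multipleTesting(data.frame(anova_p = p))$q
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("the multi-target report lists drugs with >= 2 targets", {
  rel <- relTable(drug_id = c("dM", "dM", "dS", "dN", "dN"),
                  gene_id = c("G1", "G2", "G1", "G3", "G4"),
                  action = "inhibition")
  summ <- data.frame(gene_id = c("G1", "G2", "G3"), action = "inhibition",
                     direction = c("down", "down", "up"),
                     significant = c(TRUE, TRUE, FALSE))
  rep <- multiTargetReport(rel, summ)
  expect_false("dS" %in% rep$drug_id)          # single-target drug excluded
  row <- rep[rep$drug_id == "dM", ]
  expect_identical(row$n_targets, 2L)
  expect_identical(row$n_regulated_targets, 2L)
  expect_match(row$regulated_targets, "G1\\(down\\)")
  expect_identical(rep[rep$drug_id == "dN", ]$n_regulated_targets, 0L)
  # no significant results -> empty report
  summ0 <- summ
  summ0$significant <- FALSE
  expect_identical(multiTargetReport(rel[rel$drug_id == "dS", , drop = FALSE],
                                     summ0)$drug_id, character(0))
})

test_that("the end-to-end screen recovers injected feedback on synthetic data", {
  cfg <- smallSimConfig(n_cell_lines = 2L, n_probes = 400L, n_drugs = 30L,
                        treatments_per_batch = 16L, n_relations = 8L,
                        drugs_per_target = 2L, fraction_regulated = 0.5,
                        regulation_effect = 2, noise_sd = 0.4,
                        present_rate = 0.6, seed = 7L)
  sim <- simulateCompendium(cfg)
  cen <- meanCenterBatch(selectHighestConcentration(
    filterInstances(sim$ps, min_batch_size = 5L)))
  prof <- mergeReplicates(cen)
  pres <- presenceByCellLine(cen, threshold = 0.1)
  scr <- screenTargetRegulation(prof, sim$relations, pres, sim$probe_map)
  truth <- unique(sim$truth$relations[sim$truth$relations$regulated,
                                      c("gene_id", "action", "effect")])
  hit <- merge(scr$summary, truth, by = c("gene_id", "action"))
  expect_gt(nrow(hit), 0L)
  expect_true(all(hit$q < 0.05))
  expect_identical(hit$direction, ifelse(hit$effect > 0, "up", "down"))
})
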