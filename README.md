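# dipscore

Batch-aware normalization and similarity scoring of drug-perturbation
expression compendia, with a drug-target feedback-regulation screen.

## What problem it solves

Compendia like the Connectivity Map profile genome-wide expression of
cultured human cell lines (HL60, MCF7, PC3) under hundreds of
small-molecule treatments. The data are collected in production batches
whose profiles resemble each other regardless of treatment (the batch
effect), with few vehicle controls, partial replication and mixed
concentrations. `dipscore` is for analysts who want to compare drugs by
their transcriptional response, or ask whether a drug changes the mRNA
level of its own protein target (a feedback loop), without those biases
dominating the answer.

## The method

* **Population mean-centering.** For each probe *p* and production batch
  *B*, the expression change of treatment *t* is
  `x[p,t] − mean over all treatments t′ in B of x[p,t′]` — the
  heterogeneous treatment population, not the few vehicle controls, serves
  as background. This removes additive batch effects exactly and
  down-weights common stress responses. The classical control-based
  background is kept for comparison (`controlCenterBatch()`).
* **Two-step ranking & optimal signatures.** Probes not Present in a cell
  line (detection call `P` in < ½ of instances) have their amplitude set to
  0 before descending sorting, with the zeroed block sub-sorted by initial
  amplitude. A drug's optimal signature is its top-*n* and bottom-*n*
  ranked probes (*n* = 250 on full arrays).
* **DIPS score.** Drug pair similarity by bidirectional gene-set
  enrichment: the up/down signature sets of each drug are scored in the
  other drug's ranked profile with a Kolmogorov–Smirnov running-sum
  enrichment score (ES ∈ [−1, 1]); each direction contributes
  `(ES_up − ES_down)/2`, and the DIPS score is the mean of the two
  directions (+1 for self, −1 for the reversed profile, symmetric by
  construction). Per-cell-line scores combine as the mean over cell lines
  profiling both drugs.
* **Benchmarking.** ROC/AUC and unnormalized partial AUC (FPR < 0.1)
  against binary pair labels from 2D Tanimoto chemical similarity (> 0.8)
  or shared ATC level-4 codes, with Mann–Whitney tie handling.
* **Regulation screen.** Drug-target relations (confidence > 0.7,
  experimental/database evidence, `binding` folded into inhibition) are
  tested per target and action: per-cell-line Welch t-tests of the target's
  expression change under targeting versus all other drugs, a
  cross-cell-line fixed-effects ANOVA (cell line as blocking factor), and
  Benjamini–Hochberg q-values over the tested family.
* **Synthetic compendium generator.** `simulateCompendium()` draws a
  CMap-like dataset (batch effects, shared drug signatures, detection
  calls, replicates, concentrations, injected feedback, Tanimoto/ATC
  tables) with complete ground truth, so the whole pipeline is testable
  without external downloads.

## Worked example

```r
library(dipscore)

cfg <- simulationConfig(n_probes = 2000, n_drugs = 60, n_cell_lines = 3,
  batches_per_cell_line = 2, treatments_per_batch = 35, replicate_rate = 0.15,
  signature_size = 30, n_similar_groups = 15, similar_group_size = 3,
  n_relations = 50, drugs_per_target = 5, fraction_regulated = 0.5,
  controls_per_batch = 2, seed = 1)
sim <- simulateCompendium(cfg)
sim$ps
#> PerturbationSet: 2000 probes x 222 instances
#>   treatments: 210 | controls: 12 | drugs: 60 | batches: 6 | cell lines: HL60, MCF7, PC3
#>   detection calls: yes

ps   <- selectHighestConcentration(filterInstances(sim$ps, min_batch_size = 25))
cen  <- meanCenterBatch(ps)
prof <- mergeReplicates(cen)
pres <- presenceByCellLine(cen, 0.5)

dips <- lapply(sort(cellLines(prof)), function(cl)
  dipsMatrix(prof[, SummarizedExperiment::colData(prof)$cell_line == cl],
             pres[[cl]], n = 100))
combined <- combineCellLines(dips)
combined
#> DIPSMatrix [combined]: 60 x 60 drugs, classic KS weighting

m <- matchScoresToLabels(combined, labelsFromTanimoto(sim$tanimoto, 0.8))
rocCurve(m$scores, m$labels, fpr_cutoff = 0.1)
#> ROC: 45 positives / 1725 negatives; AUC = 0.9282 ; partial AUC (FPR < 0.1 ) = 0.05948

screen <- screenTargetRegulation(mergeReplicates(cen), sim$relations,
                                 presenceByCellLine(cen, 0.1), sim$probe_map)
head(screen$summary[order(screen$summary$q),
     c("gene_id", "action", "direction", "anova_p", "q", "significant")], 5)
#>    gene_id     action direction      anova_p            q significant
#> 7   G00948 inhibition        up 2.604647e-26 2.604647e-25        TRUE
#> 8   G01267 inhibition        up 1.057325e-22 5.286624e-22        TRUE
#> 5   G00843 inhibition        up 1.531601e-20 5.105338e-20        TRUE
#> 10  G01508 inhibition        up 4.889725e-16 1.222431e-15        TRUE
#> 2   G00241 activation      down 5.821057e-15 1.164211e-14        TRUE
```

The AUC of 0.93 says the combined DIPS score ranks truly similar drug pairs
(shared-signature groups, Tanimoto 0.9) far above unrelated pairs; the
screen's top hits are exactly the targets with injected feedback, with
inhibitors showing compensatory up-regulation and activators
desensitization-style down-regulation of the target mRNA.

`runPipeline()` (or the `inst/scripts/dips-pipeline.R` wrapper) runs all
stages from TSV inputs and writes per-stage TSV reports plus a JSON
manifest; see the vignette in `vignettes/dips-methodology.Rmd` for the
model, parameter and design details.

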