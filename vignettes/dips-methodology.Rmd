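---
title: "Normalizing and scoring heterogeneous drug-perturbation compendia"
author: "dipscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing and scoring heterogeneous drug-perturbation compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Compendia such as the Connectivity Map record genome-wide expression
responses of cultured human cell lines (HL60, MCF7, PC3) to hundreds of
small-molecule treatments, collected over many production batches, at
several concentrations, only partially replicated, and accompanied by only a
few vehicle controls per batch. Two analytical obstacles dominate:

1. **Batch effects.** Profiles measured in the same production batch
   resemble each other regardless of treatment. When expression changes are
   computed against the batch's few vehicle controls, the control noise is
   shared by every treatment in the batch, which further inflates
   within-batch similarity.
2. **Heterogeneous designs.** Drugs differ in concentration, replication and
   cell-line coverage, so profiles must be filtered, centered, merged and
   ranked consistently before any cross-drug comparison is meaningful.

`dipscore` implements a normalization and scoring procedure for such data:
per-batch **population mean-centering**, detection-call-aware **two-step
ranking**, a bidirectional Kolmogorov–Smirnov **profile-similarity score
(DIPS)** with ROC benchmarking against chemical-structure and ATC labels,
and a **drug-target regulation screen** that detects feedback loops —
drug-induced up- or down-regulation of the drug target's own mRNA.

# Preprocessing model

Let $x_{pt}$ be the log2 intensity of probe $p$ in treatment instance $t$
(RMA-summarized upstream; summarization from CEL files is out of scope and
the package consumes the summarized matrix). The stages are applied in this
order:

1. **Batch filter.** Only production batches with *strictly more than* 25
   drug treatments are retained (configurable); vehicle controls never count
   toward batch size. The strict reading keeps the threshold conservative
   and is exposed as `min_batch_size`.
2. **Concentration filter.** Per (drug, cell line), only instances at the
   highest tested concentration survive; ties are replicates and all stay.
   Standard molar units are converted to a common scale before comparison;
   irreconcilable units are an error rather than a silent guess.
3. **Population mean-centering.** For each probe and batch $B$,
   $\tilde x_{pt} = x_{pt} - \frac{1}{|B|}\sum_{t' \in B} x_{pt'}$, the mean
   running over *all drug treatments* of the batch (each treatment column
   once, replicates included as listed) rather than the vehicle controls.
   This removes any additive per-batch effect exactly and down-weights
   common stress responses. A batch with a single treatment cannot be
   centered and is an error. The classical control-based background
   ($x_{pt}$ minus the batch's control mean) is kept as
   `controlCenterBatch()` for comparison.
4. **Replicate merging.** Columns of the same (drug, cell line, platform)
   are averaged into one amplitude ("average difference") profile. Profiles
   from different microarray platforms are never merged.

Per-probe detection calls (P/A/M) accompany the matrix. A probe is *Present
in a cell line* when called `P` in at least a threshold fraction of that
cell line's treatment instances — 1/2 for ranking, 1/10 for the target
screen. Both thresholds are inclusive ("at least"), and marginal calls do
not count as present.

# Two-step ranking and the optimal signature

Profiles are ranked by both detection call and amplitude: the amplitude of
every non-Present probe is set to 0; probes are sorted descending by this
effective value; inside the zeroed block, probes are sub-sorted descending
by their initial amplitude. A Present probe whose amplitude is exactly 0 was
never "set to 0", so its sub-sort key is 0 and it falls between the zeroed
probes with positive and negative initial values. All remaining ties break
lexicographically by probe id — an arbitrary but documented and
reproducible choice.

The **optimal signature** of a profile is its top-$n$ and bottom-$n$ ranked
probes. $n = 250$ is the full-array default; the generator's smaller probe
universes use proportionally smaller $n$ (the package's tests and scripts
use $n = 100$ at 2,000 probes), since $2n$ may not exceed the list length.

# The DIPS score

For a query probe set $S$ in a ranked list of length $N$, the enrichment
score walks the list, incrementing by $w_i / \sum_{j \in S} w_j$ on hits and
decrementing by $1/(N - |S|)$ on misses; the ES is the running-sum value of
maximal absolute deviation, signed, so $\mathrm{ES} \in [-1, 1]$. Two
weighting schemes are provided: **classic** ($w_i = 1$, the default) and
**weighted** ($w_i = |\text{effective value}_i|$, exponent 1). The classic
scheme is the default because it is the plain Kolmogorov–Smirnov statistic
and makes the analytic extremes exact; the weighted variant is selectable
wherever a weighting argument appears. An exact $\pm$ tie in the maximal
deviation resolves to the positive branch (with a $10^{-12}$ comparison
tolerance so summation order cannot flip the sign).

For drugs $X$ and $Y$ in one cell line, both directions are queried: the up-
and down-sets of $X$'s signature in $Y$'s ranked profile and vice versa.
Because a concordant *down*-set produces a *negative* ES, a plain four-way
mean would cancel genuine signal; each query direction is therefore
summarized as $(\mathrm{ES}_{up} - \mathrm{ES}_{down})/2$ and the DIPS score
is the mean of the two directional scores. This combination is isolated in
one internal function so alternative averaging conventions can be swapped;
it yields exactly $+1$ for a self-comparison and $-1$ against the reversed
profile, and is symmetric bit-for-bit by construction. Scores from multiple
cell lines are combined as the arithmetic mean over the cell lines in which
both drugs were profiled. No null-based rescaling is applied: DIPS values
are reported raw, and significance enters only through the category t-tests
and the ROC benchmarks.

A Pearson-correlation variant (`pairwisePearson()`) supports the same
four-category read-out on amplitude vectors directly, and
`crossCellLineMerge()` restricts profiles to jointly Present probes for
cross-cell-line comparisons.

## The four drug/batch categories

Instance-level profile pairs fall into four categories: (i) same drug &
same batch, (ii) same drug & different batch, (iii) different drug & same
batch, (iv) different drug & different batch. A residual batch effect shows
as category (iii) scoring above (iv). `categorizePairs()` computes the
instance-level DIPS distributions and Welch t-tests between categories; the
batch-effect hypotheses are directional, so the package's own validation
uses one-sided tests (`alternative = "greater"`). On synthetic data the
control-centered background shows a large (iii) > (iv) gap — driven by the
control-noise offset shared within each batch — while population
mean-centering removes it and leaves replicate concordance, (ii) > (iii),
as the dominant signal. Category analyses run on instance-level profiles
because merged profiles would make category (i) undefined.

# Benchmarking

External labels declare a drug pair "truly similar": 2D Tanimoto chemical
similarity strictly above 0.8, or a shared ATC level-4 prefix (first five
characters; level prefix lengths are 1, 3, 4, 5, 7). A drug may carry
several ATC codes and any-vs-any prefix sharing counts; drugs without codes
are excluded, as are pairs with a label but no score (listwise). ROC curves
are computed over descending score thresholds with ties contributing
diagonal segments, so the trapezoidal AUC equals the Mann–Whitney
concordance probability with ties counted 1/2. The partial AUC at
FPR < 0.1 is reported *unnormalized* (a perfect classifier attains 0.1),
matching the conventional scale for this analysis.

# The drug-target regulation screen

Drug-target relations (STITCH-like: drug, gene, action, confidence,
evidence channel) are filtered to experimental/database channels with
confidence strictly above 0.7; `binding` actions fold into `inhibition`,
with a manual-override table for curated corrections. A target is tested
only in cell lines where at least one of its probes is Present at the 1/10
threshold (elsewhere its columns stay blank). Activators and inhibitors of
the same target are separate hypotheses, since their expected directions
are opposite and would cancel in a pooled test.

Per cell line, the target amplitude of each drug is the mean over the
target's Present probes (the least surprising reduction for multi-probe
targets, isolated in one helper), and a Welch two-sample t-test contrasts
targeting drugs against *all other* drugs — Welch because the background
group is large and heterogeneous. Across cell lines, a fixed-effects ANOVA
on the pooled per-drug amplitudes reports the targeting-group p-value; the
default design is additive two-way with cell line as a blocking factor
(`amplitude ~ cell_line + group`), with a pooled one-way alternative behind
the `anova` switch because the exact multi-cell-line design is a genuinely
open choice. With a single usable cell line the ANOVA reduces to the
one-way test, whose F equals the squared pooled (equal-variance) t
statistic. Benjamini–Hochberg q-values are computed over the whole family
of tested (target, action) hypotheses, with significance flagged at
q < 0.05. The background group includes drugs hitting the same target
through below-threshold relations — no exclusion rule is applied, a known
limitation.

# The synthetic compendium generator

Every stage is validated against a generator with full ground truth
(`simulateCompendium()`), drawing
$$x_{pt} = \mu_p + b_{B(t),p} + s_{d(t),p}\,c(t) + \delta\,\mathrm{sgn}(a)\,\mathbf{1}\{\text{feedback}\} + \varepsilon_{pt}$$
with $\mu_p \sim N(7, 1)$ (typical log2 microarray abundance),
$b \sim N(0, \sigma_b^2)$ per batch × probe, drug signatures $s$ of exactly
$k$ probes at $\pm$`signature_amplitude` (identical within "structurally
similar" drug groups), i.i.d. noise $\varepsilon \sim N(0, \sigma_e^2)$,
and feedback effects $\delta$ added to the target gene's probes with sign
$+1$ for inhibition and $-1$ for activation — so with positive $\delta$,
inhibitors induce compensatory target up-regulation and activators
desensitizing down-regulation. Detection calls are Present with probability
logistic in $\mu_p$ around the abundance quantile matching `present_rate`,
so presence correlates with abundance as on real arrays. Grouped drugs
share an ATC level-4 prefix and Tanimoto 0.9; between-group similarities
are Uniform(0, 0.6). Target genes are drawn from presence-prone (high
$\mu$) genes, as real screens only test expressed targets; a configurable
number of decoy relations (low confidence or text-mining channel, never
regulated) exercises the filters without diluting the design conditions.

Design choices the data layout forced: each cell line has
`batches_per_cell_line` × `treatments_per_batch` treatment slots; a
`replicate_rate` fraction of slots holds replicate instances of
already-included drugs (so not every drug appears in every cell line, which
exercises the combined-score rule); drugs flagged for two concentrations
get one instance at the lower dose, which carries `signature_amplitude/1.5`
— the configured amplitude applies at the highest concentration, so
post-filter data carry it exactly. Vehicle controls (`controls_per_batch`,
default off) share the batch term but no signature, enabling the
control-background comparison.

Default conditions: 2,000 probes, 100 drugs, 3 cell lines, 4 × 30-slot
batches per cell line, replicate rate 0.2, signatures of 30 probes at 1.5
log2 units, $\sigma_b = 0.8$, $\sigma_e = 0.5$, feedback $\delta = 1.5$.
These are realistic magnitudes for the platform: batch offsets comparable
to biological signatures, and signature/feedback effects three noise SDs.

## What the generator does and does not emulate

It reproduces additive batch structure, sparse shared signatures,
abundance-linked detection calls, replicates, concentration scaling,
injected feedback, and the full complement of external tables. It does not
model probe-level (CEL) data, realistic MAS5 call statistics,
non-additive or correlated batch effects, probe cross-hybridization, or
pharmacokinetics. Passing tests therefore demonstrate that the procedure
recovers known structure under the additive model — not that real CMap data
satisfy that model.

# Numerical choices and degenerate inputs

* Centering idempotence holds to $10^{-12}$; per-batch means after
  centering are below $10^{-9}$ in absolute value.
* Missing values are refused at load time with the offending probe and
  instance named; metadata referencing instances absent from the matrix
  aborts before any computation.
* Signature probes missing from a partner profile are tolerated up to a 10%
  deficit (the query restricts to shared probes); beyond that, an error.
* Zero-variance profiles yield `NA` Pearson correlations with a warning,
  never a silent 0.
* A query set equal to the whole ranked list, a batch without controls
  (control background), a singleton batch (population background), and
  category comparisons with fewer than two pairs are all explicit errors or
  warnings.

# Problem sizes used in validation

The package's own test suite and acceptance script run the full procedure
at desk scale: 2,000-probe universes, 60–200 drugs, up to three cell lines,
signature half-size 100, ten-target regulation screens with five annotated
drugs per target, and 50-replicate null calibrations at 500 probes — sizes
chosen so the complete validation executes in minutes while every stage
operates well away from its degenerate boundaries. The largest
normalization check uses a 5,000 × 500 matrix.

# Known limitations

* The KS/GSEA averaging convention for the four enrichment scores is an
  interpretation (documented above and isolated in one function).
* The background of the regulation screen is all other drugs, including
  near-duplicates of the tested drug.
* Cross-platform probe matching is exact-id only.
* The ROC benchmark treats label sets as gold standards; in the synthetic
  world labels derive from the same group structure as the shared
  signatures, so the benchmark measures recovery of that structure, not
  chemistry.
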