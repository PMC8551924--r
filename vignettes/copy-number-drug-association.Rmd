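---
title: "Copy-number-dependent drug susceptibility screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number-dependent drug susceptibility screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnassoc)
```

## The problem

Embryonal childhood tumors such as neuroblastoma are mutationally quiet: a
typical case carries only a handful of somatic point mutations, few of them
actionable. Their genomes are instead dominated by copy-number variation —
recurrent segmental chromosomal aberrations (1p loss, 11q loss, 17q gain) and
focal MYCN amplification — which plausibly modulate gene dosage and with it
the sensitivity of the tumor to inhibitors of the dosage-altered pathways.

`cnassoc` implements the computational arm of a study design that tests this
hypothesis: profile a small cohort of tumors on a targeted panel, screen
matched patient-derived cultures against a single-dose kinase-inhibitor
library, correlate gene copy number with per-drug cytotoxicity across the
cohort for every gene-drug pair, and corroborate the associations with a
probabilistic graphical model built from the copy-number data alone. Because
cohorts of this kind are small (a dozen or so patients) and the pair universe
is large (~55,000), every statistical convention — test calibration,
multiple-testing correction, tie-breaking, handling of degenerate genes —
matters, and each is pinned down and tested here.

No patient-level data ship with the package. A first-class synthetic cohort
generator reproduces the statistical structure the analysis assumes, with
full ground truth, so that error rates and power are measurable rather than
asserted.

## The synthetic cohort generator

`cohort_config()` + `simulate_cohort()` generate a cohort in three layers,
each on its own labeled RNG stream derived from one root seed (so enlarging
the drug library never perturbs the copy-number draws, and a fixed seed gives
a bit-identical cohort).

**Copy number.** Every gene sits on a chromosome arm of the 136-gene default
panel (2998 probes). Arm events are all-or-none per arm and sample: with the
default rates, 1p loss occurs in 31% of samples, 11q loss in 38%, 17q gain in
69%, shifting every gene on the arm by −1 or +1 copy from the diploid
baseline of 2. Focal amplification (default: MYCN with probability 0.23)
*overrides* the gene's arm state with a uniform draw from 10–40 copies, the
canonical "massive amplification" regime. Probe-level measurements are
`log2(copies / 2) + N(0, probe_noise_sd)` with `probe_noise_sd = 0.1` by
default — small relative to the single-copy log step of `log2(3/2) ≈ 0.585`,
as expected of a diagnostic-grade assay. Copies are clipped at zero; no
sub-arm breakpoints or clonal heterogeneity are simulated, which keeps the
ground truth interpretable at the cost of realism for focal intra-arm events.

**Drug response.** Latent cytotoxicity of drug $d$ in sample $s$ is

$$c_{ds} = \beta_d + \sum_{(g,d) \in \text{planted}} \alpha_{gd}\,(k_{gs} - 2)
          + \varepsilon_{ds}, \qquad \varepsilon_{ds} \sim N(0, \sigma_r^2),$$

clipped to $[-20, 100]$ (mild growth stimulation is allowed — in a kinase
screen a sizable minority of compounds show negative normalized
cytotoxicity). Baseline potencies $\beta_d \sim N(16.7,\,16.8^2)$ percent:
these two numbers are solved from the screen's marginal design conditions —
about 84% of compounds with positive mean cytotoxicity and about 17% above
the 33% hit threshold — and are fixed once. Each sample is one plate carrying
all compounds at a single dose, 8 DMSO vehicle wells near the full-viability
RLU scale (relative SD `dmso_cv = 0.02`), and 4 staurosporine positive
controls near 95% kill. Plate effects beyond the vehicle wells' jitter are
not simulated; the QC machinery is still exercised through the control wells.

**Variants.** Each sample carries Poisson(3.1) somatic variants over the
panel, with coverage, allele fraction, COSMIC status and population frequency
drawn so that a configurable fraction fails each downstream filter, plus a
38% recurrent-population-SNP flag rate (the observed proportion in cohorts of
this kind). These feed the variant-filtering stage; the package deliberately
does not model SNV-cytotoxicity association beyond enumerating it, since at
~3 mutations per case such a screen is underpowered by construction.

What passing tests on these cohorts shows — and what it does not: the
generator reproduces the *correlation structure* the analysis consumes
(arm-coherent gene dosage, dose-dependent response, plate-normalized
readout). It does not reproduce sequencing noise, culture adaptation,
pharmacokinetics or dose-response curves, so results here validate the
pipeline's statistics, not any biological claim about real tumors.

## Genomic profiling conventions

Gene-level log2 ratio is the **mean of the gene's probe log2 ratios**
(mean-of-logs), and absolute copies are `ploidy * 2^log2_ratio` with ploidy 2
by default (configurable; sex-chromosome genes are reported on the common
scale). Published per-gene summaries of this kind are not always consistent
under either aggregation convention (mean-of-logs versus log-of-means can
disagree by a few percent at amplified loci); we fix mean-of-logs and
document it rather than tuning to any printed table. Genes whose probes are
all missing are dropped with a warning.

Somatic variant filtering follows the printed inequalities exactly: coverage
**strictly greater than 100** reads, allele fraction **at least 0.10**
(inclusive), COSMIC-reported, population frequency **strictly below 0.01**;
each rejected record lists every criterion it failed, and recurrent
population SNPs are excluded with conserved bookkeeping
(`|input| = |remaining| + |excluded|`).

## Drug-screen normalization, QC and hits

Per plate, replicate compound wells are averaged at the RLU level and
normalized against the **median** of the DMSO wells (robust to a single bad
vehicle well):

$$\text{cytotoxicity}(c) = 100\,\bigl(1 - \mathrm{RLU}(c) /
  \operatorname{median}(\mathrm{RLU}_{\mathrm{DMSO}})\bigr).$$

A plate without a positive DMSO reference is marked unusable, never silently
rescaled. QC passes when the staurosporine control shows at least 80%
normalized cytotoxicity and the DMSO wells' coefficient of variation is at
most 0.2 — numeric stand-ins for the qualitative requirement of a hot
positive control and a quiet vehicle, both configurable. Failed plates
propagate as missing columns, excluded pairwise downstream. A drug is a hit
when its mean cytotoxicity across QC-passing samples **strictly exceeds 33%**;
mechanism-class summaries average the per-drug means within each class.

## The association screen

For every gene $g$ and drug $d$, the Pearson correlation $r_{gd}$ is computed
over pairwise-complete samples, transformed to Fisher's
$z = \operatorname{atanh}(r)$, and standardized as $z\sqrt{n-3}$. Pairs with
a constant vector (genes with no CNV) or fewer than `min_samples = 5`
complete observations are carried as *undefined* — excluded from the
multiplicity count $m$, never coerced to $p = 1$ — so that
`testable + undefined = genes x drugs` always holds. Benjamini-Hochberg is
applied over the testable pairs at `fdr_threshold = 0.1` (significance is
inclusive, $q \le 0.1$); the adjusted values come from `stats::p.adjust` and
the discovery set provably equals the literal step-up definition (tested
against a brute-force oracle).

**Why the p-value uses the exact Pearson null by default.** With 13 samples
and ~55,000 tests, the BH rejection boundary sits near $p \approx 10^{-4}$,
four standard deviations into the tail. There the normal approximation to
the Fisher-z null is markedly anti-conservative (its tail probability
understates the exact one by roughly a factor of three at $n = 13$), which
silently triples the realized false-discovery rate. `screen_config()`
therefore defaults to the exact two-sided null of the Pearson correlation —
Student $t$ with $n-2$ degrees of freedom on $r\sqrt{n-2}/\sqrt{1-r^2}$, the
same null `stats::cor.test` uses — while still reporting $z$ (the effect
scale used for ranking and network weights) and $z\sqrt{n-3}$. The normal
approximation remains available as `p_method = "normal"` for comparison.

Downstream of testing: `classify_against_expected()` cross-classifies every
pair by significance versus the drug library's target annotation (TP/FP/FN/TN,
always summing to the pair universe); `rank_by_effect()` orders pairs by the
signed product of the drug's mean cytotoxicity and the pair's $z$ — signed,
so strong negative associations of potent drugs rank at the bottom — with
deterministic (gene, drug) tie-breaks; `verify_against_annotation_sets()`
flags pairs present in any user-supplied external annotation.

## The pathway model

Studies of this design typically delegate their probabilistic graphical model
to an external pathway tool; here the same workflow — continuous copy-number
observations, pairwise Markov random field on a functional-interaction (FI)
network, permutation null, ±0.01 selection — is implemented as an exactly
solvable **Gaussian pairwise MRF**, chosen for deterministic, fast, exact
inference at desk scale. No numerical equivalence with any external tool is
claimed; the workflow and selection semantics are preserved.

Each gene $g$ carries a hidden activity $a_g$ with standard-normal prior.
An observed gene contributes a Gaussian observation of $a_g$ whose value is
the **rank-based normal score** of the gene's copy-number value across
samples (the empirical-distribution link; continuous, never discretized;
average ranks map a constant gene to all-zero scores), with observation noise
SD 1. Every FI edge $(g,h)$ contributes a potential penalizing
$(a_g - a_h)^2$ with precision `coupling_scale * fi_weight`
(`coupling_scale = 1` by default; 0 decouples the genes). The posterior is
jointly Gaussian, so the per-sample impact — the posterior mean of $a$ — is
one linear solve, exact on any graph topology.

**Real-versus-permuted comparison.** The permutation null shuffles sample
labels within each gene's row (preserving each gene's marginal, destroying
gene-sample linkage), 100 replicates by default. A subtlety forced a design
choice here: the per-sample posterior mean is linear in the observations, and
a within-gene permutation never changes the multiset of a gene's
observations, so the across-sample *mean* of the signed impact is exactly
permutation-invariant — a comparison built on it would select nothing, ever.
The per-gene summary compared between real and permuted runs is therefore
the **mean absolute posterior activity** across samples. This quantity
responds to precisely what permutation destroys: when an arm event aligns the
scores of FI-coupled neighbors within the same samples, their posteriors
reinforce and the mean magnitude rises; after permutation the neighbors
decohere and it falls. Genes whose real-minus-permuted difference lies
strictly outside $[-0.01, +0.01]$ are selected, after removing genes with no
CNV. On cohorts with the default 17q-gain frequency this margin is an order
of magnitude above the threshold for 17q genes, and the difference is
centered at zero for i.i.d. profiles — both properties are tested.

The FI network ships as a generator (`make_fi_network()`): a stochastic block
model over the panel with chromosome arms as blocks (within-arm density 0.5,
between 0.02, weights uniform on 0.5–1), a synthetic stand-in for a curated
interaction network; user edge lists load via `read_edge_list_tsv()`.
Selected genes are overlaid with drug-target annotations into a bipartite
graph; the significant screen pairs form a z-score-weighted network; both are
clustered by deterministic greedy modularity (ties broken toward fewer
modules; module ids ordered by size, then lexicographic anchor gene), with
optional hypergeometric enrichment against bundled toy gene sets,
BH-corrected. `compare_networks()` reports per-drug first-degree-neighbor
overlap (Jaccard) between the model-derived and z-score networks.

## Orchestration and reproducibility

`run_all()` executes simulate → profile → screen → associate → network,
writing each stage's outputs (probe TSV, plate CSV, minimal VCF, library TSV,
matrices, association TSV, GraphML networks) before the next stage reads
them back, and finishes with a JSON manifest of configuration, seeds, stage
counts and file digests. Runs with the same configuration and seed produce
byte-identical manifests; every manifest count is recountable from the
serialized tables. Heatmap ordering uses complete-linkage Euclidean
hierarchical clustering (`stats::hclust`, deterministic ties).

## Numerical choices and edge cases

* Correlations at $|r| = 1$ are clamped to $1 - 10^{-7}$ before `atanh`,
  with a warning.
* Copies are floored at 0.05 inside the probe-level `log2` only, so a
  pathological homozygous loss cannot produce non-finite ratios.
* BH runs on testable pairs only; empty input yields empty output.
* `hclust` merge order resolves ties by original index; single-row or
  single-column matrices get trivial orderings.
* The MRF precision matrix is positive definite by construction (unit prior),
  factored once per model and reused across permutation replicates.

## Benchmark problem sizes

The packaged FDR benchmark (`fdr_benchmark()`, also the basis of
`scripts/acceptance.R`) simulates 20 cohorts of 13 samples, 131 genes and 418
drugs (54,758 pairs) with 50 planted pairs at true correlation magnitude
$\approx 0.95$ (slope 20%/copy against binary one-copy gains,
$\sigma_r = 3.3$: $r = 10/\sqrt{100 + 3.3^2} = 0.950$) and measures the mean
false-discovery proportion of the BH discovery set at $q = 0.1$, with FDP
defined as 0 when nothing is discovered.

Two finite-sample artifacts shaped the benchmark's design, both documented in
`?fdr_benchmark`: planting each pair on its own binary-event gene lets
13-sample gain patterns collide between genes (probability
$2 \cdot 2^{-13}$ per pair, plus near-collisions), leaking genuine in-sample
correlation into nominally null pairs and biasing the measured FDP upward;
planting all pairs on a single gene removes the bias but lets one
tail-realization noise gene sweep in all planted drugs at once, making the
estimate heavy-tailed. The benchmark plants 50 pairs on 5 genes × 10 drugs,
keeping the collision bias negligible while capping such clusters. All other
genes carry only i.i.d. normal probe noise, so every null pair's test
statistic is exactly calibrated and the measured FDP reflects the
multiple-testing procedure itself. Its expectation sits at the BH boundary
$q \cdot m_0/m \approx 0.0999$ by construction, so individual 20-cohort runs
scatter by a few hundredths around 0.1 — the Monte-Carlo error the benchmark
reports alongside the mean.

## Known limitations

* Arm events are binary whole-arm shifts; no sub-arm segmentation, no
  multi-copy arm gains, no clonality.
* The screen is single-dose; no IC50s or dose-response modeling.
* The Gaussian MRF is a surrogate with the same interface and thresholds as
  pathway-tool practice, not a reimplementation of any specific tool; its
  impact scores are in posterior-mean units, comparable only within a run.
* With ~13 samples, correlation estimates are coarse ($\mathrm{SE}(z) =
  1/\sqrt{10}$); the pipeline quantifies this honestly rather than hiding it,
  which is why the exact-null default matters.
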