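---
title: "Methods: temporal selection, co-occurrence networks and gene linkage in rhizonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal selection, co-occurrence networks and gene linkage in rhizonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rhizonet` analyses a full-factorial soil-microbiome time series — five
nitrogen fertilization treatments (no input CK, low/high urea N1/N2,
low/high manure O1/O2), two compartments (bulk soil B, rhizosphere R),
five crop developmental stages (S1–S5) and six biological replicates,
300 samples in all — together with a 12-assay qPCR panel of
nitrogen-cycling marker genes. This vignette records the statistical
procedures, the modelling choices behind the synthetic-study generator,
and what the package's validation does and does not establish.

## Replicate-consensus filtering and temporal selection

Detection is count ≥ 1; no rarefaction is applied (none is part of the
procedure the pipeline implements). Within each (treatment, compartment)
stratum, every OTU gets one presence call per stage cell over that
cell's six replicates: *present* when detected in more than half of the
replicates (e.g. four of six), *absent* when detected in fewer than
half, *undefined* at exactly half. An OTU is retained in the stratum iff
it is never undefined at any stage and is present at one stage or more;
consistently absent OTUs are dropped. Two readings of the consensus rule
were possible — calls per stage cell, or pooled across the stratum's 30
samples — and the per-stage reading is used, because each stage is what
carries exactly six replicates.

"Relative abundance" is per-sample total-sum scaling, then averaged over
the six replicates of a stage. A retained OTU is *specifically enriched*
(*inhibited*) at the unique stage attaining the maximum (minimum) of its
five stage means; a tie at an extremum withholds that label, since a
specific stage must be unique. Stage profiles, standardized per OTU to
zero mean and unit variance (flat profiles become zero vectors), are
grouped with k-means, k = 3, k-means++ seeding, 25 restarts under one
seed.

Selection counts are compared between directions with a two-sided Welch
t-test on per-treatment counts (five treatments per side, per stage and
compartment). The unit of replication for this test is a documented
choice: treatments are the only replicated unit once counts are
aggregated per stage.

## Dissimilarity and permutation statistics

Bray–Curtis dissimilarity is computed on relative abundances,
d(x, y) = Σ|x_i − y_i| / Σ(x_i + y_i). PCoA is classical scaling:
eigendecomposition of the double-centered −d²/2, axes with positive
eigenvalues only. ANOSIM uses average ranks of all pairwise distances,
R = (r̄_between − r̄_within)/(n(n−1)/4); PERMANOVA partitions squared
distances, SS_total = Σ_{i<j} d²_{ij}/n, with pseudo-F =
(SS_between/(a−1))/(SS_within/(n−a)). Both tests permute sample labels;
p = (1 + #{permuted ≥ observed})/(1 + B), which keeps p in (0, 1].
Defaults are B = 999 under a caller-supplied seed. For designs of up to
a few hundred distinct labelings, `exact = TRUE` replaces sampling with
exhaustive enumeration of the label multiset, and the tests then report
the exact proportion of labelings at or above the observed statistic.
Each design factor is tested separately (one-factor form only);
multi-factor partitioning is out of scope.

## Co-occurrence networks

Networks are built per (treatment, compartment) stratum from the
stratum's 30 samples, restricted to its temporally specifically-selected
OTUs. Spearman ρ is Pearson correlation of average-ranked relative
abundances; two-sided p-values use the t approximation
t = ρ√((n−2)/(1−ρ²)), adequate at n = 30. Constant OTUs are excluded.
All unique pairs form one Benjamini–Hochberg family; an edge requires
|ρ| > 0.7 and q < 0.05. The absolute-value reading of the correlation
threshold is deliberate — signed networks need their negative edges —
and a flag (`abs_rho = FALSE`) switches to the literal one-sided
threshold. BH was chosen over empirical-null q-value estimation for
determinism.

Topology: mean local clustering coefficient (degree < 2 contributes 0),
mean shortest-path length over unordered pairs of the largest connected
component, and modularity Q of the detected partition on the sign-blind
unweighted skeleton. The null model is Erdős–Rényi G(n, m) with the
observed node and edge counts; observed metrics are compared against
the ensemble mean ± sd (100 draws by default).

## Keystone taxa

Modules come from greedy modularity maximization (fast-greedy
agglomeration) on the sign-blind skeleton; when the
connected-component partition scores at least as high, it is preferred
— this resolves floating-point ties in the merge sequence (a clique
component must be one module). Per node, within-module degree
z_i = (k_i,within − mean)/sd (z = 0 when the module sd is 0), and the
among-module participation coefficient c_i = 1 − Σ_m (k_i,m/k_i)². A
node is a keystone when c > 0.6 **or** z > 2.5 — the inclusive-or
reading, matching the role taxonomy in which connectors and module hubs
both qualify; `require_both = TRUE` gives the conjunctive variant.
Negative-correlation accounting uses the whole network's negative edge
count as denominator and tallies unordered phylum pairs restricted to
keystone phyla (intra-phylum pairs included).

## Phylum–gene linkage

Key phyla default to the phyla holding the most keystone taxa, capped at
five: using *all* phyla of a complete taxonomy would make the phylum
matrix compositionally collinear (rows sum to 1). Pairwise associations
are simple OLS fits per stratum with the two-sided slope t-test.

RDA takes the genes as responses and phylum abundances as explanatory
variables — the direction follows the question "do the key phyla explain
the gene profile". Gene copies are transformed ln(x + 1) and averaged
over technical replicates; both matrices are reduced to the 50 pooled
(treatment, compartment, stage) cells, phylum abundances averaged over
the six biological replicates, mirroring the pooled-template qPCR
design. The implementation is the definitional two-step: center, fit
multivariate OLS, and take the SVD of the fitted values; constrained
proportion = ‖fitted‖²/‖centered response‖²; explanatory scores are
correlations of the explanatory variables with the site scores. Rank
checks run on column-standardized copies of the explanatory matrix so a
genuinely varying rare phylum is never dropped as "collinear" merely for
being small; exactly collinear columns are reported by name.
Explanatory variables are centered only; `scale = TRUE` is available.

## Random-forest functional groups

Predictors are the compartment's temporally selected OTUs, relative
abundances averaged to the 25 pooled cells of that compartment; the
response is the gene's mean ln(copies + 1) per cell. Forests use 500
trees and mtry = ⌈p/3⌉; importance is the out-of-bag permutation
%IncMSE (mean MSE increase relative to the forest's OOB MSE). Model
significance permutes the response: p = (1 + #{permuted OOB R² ≥
observed})/(1 + B), B = 99 by default with 100-tree forests for the
permutation replicates (the model-level OOB fit stabilizes with far
fewer trees than per-predictor importances do). A gene's functional
group is its OTUs with positive %IncMSE in a model with p below 0.05;
process-level groups are unions over each process's genes. Gene-level
group differences use Kruskal–Wallis with BH adjustment across the
twelve assays per factor; when every observation ties, H is 0 by
convention.

A known limitation: with n = 25 cells and >1000 selected-OTU predictors
(the default-scale community), OOB-based model significance has little
power even when planted drivers rank at the very top of the importance
list — permuted responses also find spuriously correlated predictors
among thousands. The driver-recovery validation therefore runs at a
community size (about 300–400 OTUs, 200–350 predictors) where the test
is well powered; importance *ranking* remains reliable at full scale.

## The synthetic-study generator

The generator emulates the study design with planted, recoverable
structure. Counts follow a log-linear latent model: per-OTU baseline
(log-normal, sd 1.5), sparse design responses (30% of background OTUs
respond to each factor; effect sds default to 1, 1 and 0.5 log units for
stage, treatment and compartment), log-normal OTU-level noise (sd 0.7,
supplying NB-like overdispersion), then a multinomial draw per sample at
a log-normal library size (mean 37,770, log-sd 0.2, echoing per-sample
read counts varying about three-fold) — so column totals match the drawn
library sizes exactly. Multinomial sampling was preferred over drawing
NB counts and rescaling because rescaled counts cannot satisfy the
exact-total invariant.

Planted structure, all on the abundant tail so the consensus filter and
rank correlations behave:

- **Stage-selected OTUs** (100 enriched + 100 inhibited by default)
  carry full stage profiles whose planted stage sits a fixed margin
  (1.5 log units) above the maximum (below the minimum) of the other
  stages. They receive slightly higher sample-level noise (sd 1) than
  background: their signal lives in stage *means* (six replicates
  average the noise away) while the noise suppresses spurious pairwise
  correlations between OTUs with aligned or opposed profiles.
- **Keystone hub pairs** (5 pairs by default) load with opposite signs
  on a shared standard-normal factor, with loading √max(coupling, 0.99)
  — the configured `keystone_coupling` is the guaranteed *minimum*
  magnitude. Followers (50 per group) attach with alternating signs and
  two strengths (loadings 0.8 and 0.74 of a unit-variance latent):
  strong followers give the hubs their edges, weak ones form a sparse
  periphery that keeps the module's mean degree low, so the hubs — and
  only the hubs — stand out in within-module degree. Follower signs
  alternate so the group's total abundance is insensitive to the
  factor: an unbalanced group would swing the compositional denominator
  and inject shared noise into every relative abundance, which is also
  why background responses are sparse. Sign determines phylum, pinned
  to the planted negative phylum pairs, so every planted negative edge
  joins those pairs.
- **Gene-driver OTUs** (5 per driven gene) respond to the
  treatment x compartment x stage cell through a profile shared by the
  gene's driver set plus an idiosyncratic per-driver part (log-sds 0.95
  and 0.3): the shared part is what the gene follows and what makes
  each driver individually predictive; no other OTU shares it, which is
  what makes the planted relationship identifiable at all from 25–50
  cells. Profiles are built per compartment from a base multiset of
  stage values rescaled to an exact sample sd (every gene's signal has
  guaranteed spread in every compartment) and permuted independently
  within each (treatment, compartment) block — so cell profiles are
  idiosyncratic yet no treatment carries a systematic level or spread
  difference. Drivers keep low baselines (a large summed driver mass
  would swing the compositional denominator and couple every other OTU
  to the gene). The gene model's driver term is additionally normalized
  to each treatment's mean on the copy scale, so the organic-vs-mineral
  contrast comes from the planted fold change alone — the default
  plants 2.6 for nifH and 2.4 for the anammox 16S assay — and
  treatment-group ratios of cell means recover it exactly in the
  noise-free limit. `driver_effect` is the log-scale sd of the driver
  signal (default 2); the slope on the summed driver abundance is
  derived per gene as driver_effect / sd, keeping the signal comparable
  across community sizes. By default the fold-change showcase assays
  (nifH, anammox 16S) and the total-bacteria assay carry no drivers, so
  the two planted gene effects live on disjoint assays and each is
  cleanly measurable.

Gene copies are exp(baseline + driver term + fold effects) with
independent Gaussian log-scale noise (sd 0.3) per technical replicate,
three replicates per pooled cell, twelve assays with fixed
per-assay baselines (total-bacteria 16S highest).

What the generator does **not** emulate: phylogenetic correlation
between taxa, sequencing error or chimeras, zero inflation beyond the
multinomial, compositional effects of a dominant bloom taxon, soil
chemistry covariates, or read-level processing. Passing the validation
suite therefore shows the *procedures* are implemented correctly and can
recover structure of the planted kinds at realistic noise levels — not
that real soil data meet these assumptions.

## Problem sizes used in validation

The default configuration is 1500 OTUs x 300 samples; the end-to-end
pipeline run and the headline-quantity script use it directly. The
repeated-seed validation checks (keystone recovery, modularity vs null,
driver recovery, FDR calibration, coupling calibration) run on
150–400-OTU communities with the full 300-sample design — the package's
validation scale, chosen so that multi-seed Monte-Carlo checks complete
quickly while every structural property of the default configuration is
preserved. Seed counts in those checks (10–20 seeds) are fixed
properties of the checks, not tuned quantities.

## Numerical choices and degenerate inputs

- Permutation p-values include the observed statistic (+1/+1): valid,
  never zero.
- Constant distance matrices give ANOSIM R = 0, p = 1; a group of size 1
  is an error.
- PCoA drops axes with non-positive eigenvalues and flags truncation;
  one sample gives a zero-dimensional result.
- Spearman p-values are clamped into (0, 1]; constant OTUs are excluded
  from correlation matrices, and networks drop isolated nodes.
- k-means standardization maps flat profiles to zero vectors; duplicate
  profiles always share a label.
- Welch tests with two zero-variance samples return t = 0, p = 1 when
  the means agree.
- All randomness flows from explicit integer seeds through
  `withr::with_seed`; no global RNG state leaks.
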