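# rhizonet

Spatiotemporal analysis of soil bacterial communities under contrasting
nitrogen fertilization, from OTU count tables to nitrogen-cycling gene
predictions.

Soils under long-term mineral (urea) versus organic (manure) input
develop different bacterial communities, and those communities shift as
the crop develops. `rhizonet` implements an end-to-end pipeline for a
full-factorial sampling design — 5 fertilization treatments (CK, N1, N2,
O1, O2) x 2 compartments (bulk soil B, rhizosphere R) x 5 developmental
stages (S1–S5) x 6 replicates = 300 samples — together with a 12-assay
qPCR panel of nitrogen-cycling genes (nifH; AOB amoA, nxrA, comammox
clade A; napA, nirK, qnorB, nosZ; hzsB, anammox 16S; nrfA; total 16S).

The pipeline stages:

1. **Temporal selection** (`build_selection_catalog`). Within each
   (treatment, compartment) stratum an OTU is called *present* in a
   stage cell when detected in more than half of the 6 replicates,
   *absent* below half, *undefined* at exactly half. OTUs that are ever
   undefined, or absent at every stage, are excluded. For retained OTUs
   the stage with the highest (lowest) mean relative abundance marks the
   OTU as specifically *enriched* (*inhibited*) at that stage; stage
   profiles are grouped with k-means (k = 3).
2. **Community structure** (`bray_curtis`, `pcoa`, `anosim`,
   `permanova`). Bray–Curtis dissimilarity on relative abundances,
   classical-scaling ordination, and one-factor ANOSIM
   (R = (r̄_between − r̄_within) / (n(n−1)/4)) and PERMANOVA
   (pseudo-F, R² = SS_between/SS_total) with seeded permutation
   p-values; exhaustive enumeration is available for small designs.
3. **Co-occurrence networks** (`stratum_network`). Spearman rank
   correlations among the stratum's temporally selected OTUs over its 30
   samples; edges kept at |ρ| > 0.7 with BH-adjusted q < 0.05; topology
   (mean local clustering, mean shortest path, modularity) compared with
   Erdős–Rényi G(n, m) ensembles of identical size.
4. **Keystone taxa** (`keystone_analysis`). Greedy modularity modules;
   per node the within-module degree z-score and among-module
   participation coefficient c = 1 − Σ_m (k_m/k)²; keystones satisfy
   c > 0.6 or z > 2.5. Negative-edge mass is accounted per unordered
   phylum pair among keystone phyla.
5. **Phylum–gene links** (`aggregate_phyla`, `pairwise_lm`, `rda`).
   Pairwise OLS between key phyla per stratum and redundancy analysis of
   ln(copies + 1) gene abundances on phylum abundances over the 50
   pooled qPCR cells.
6. **Functional groups** (`rf_gene_analysis`). Regression random forests
   (500 trees) of each gene's cell-level abundance on selected-OTU
   relative abundances; %IncMSE permutation importance; model
   significance by permuting the response (OOB pseudo-R²); a gene's
   functional group is its positively important OTUs in a significant
   model, with Kruskal–Wallis + BH tests of gene abundances by design
   factor.

A seeded synthetic-study generator (`synthetic_config`,
`simulate_study`) emulates this design with planted, recoverable
structure — stage-enriched/inhibited OTUs, antagonistic keystone hub
pairs with negative inter-phylum couplings, and gene-driver OTUs — so
every stage of the pipeline is validated against a known ground truth.

## Worked example

```r
library(rhizonet)

cfg <- synthetic_config(n_otus = 300, n_keystone = 6,
                        n_enriched = 40, n_inhibited = 40, seed = 1)
sim <- simulate_study(cfg)

# community structure, Table-1 style
community_tests(sim$counts[, 1:120], sim$metadata[1:120, ],
                factors = c("treatment", "compartment"),
                n_permutations = 99, seed = 1)
#>        factor     anosim_R anosim_p permanova_F permanova_R2 permanova_p
#> 1   treatment  0.104478029     0.01   3.9509626  0.032397961        0.01
#> 2 compartment -0.005362994     0.71   0.9692801  0.008147314        0.57

# temporal selection + one stratum's co-occurrence network
catalog <- build_selection_catalog(sim$counts, sim$metadata, seed = 1)
net <- stratum_network(sim$counts, sim$metadata, catalog,
                       sim$taxonomy, "CK", "B")
ka  <- keystone_analysis(net)
head(ka$keystones)
#> [1] "OTU_00002" "OTU_00003" "OTU_00004" "OTU_00005" "OTU_00006" "OTU_00265"
sim$truth$planted_keystones
#> [1] "OTU_00001" "OTU_00002" "OTU_00003" "OTU_00004" "OTU_00005" "OTU_00006"

# organic-vs-mineral fold change of the nitrogen-fixation marker
fold_change(sim$genes, "nifH", c("O1", "O2"), c("N1", "N2"))
#> [1] 2.777238
```

The ANOSIM/PERMANOVA rows detect the planted fertilization effect on
community composition (p = 0.01 at 99 permutations) while the weaker
compartment effect stays non-significant in this 120-sample subset; the
keystone call recovers five of the six planted hub OTUs in this stratum
(plus one false positive); and the nifH fold change lands near the
planted organic-vs-mineral effect of 2.6.

The whole pipeline, writing every stage's tables plus a run manifest:

```r
run_pipeline(synthetic_config(seed = 42), "results_dir")
```

or from a shell, `inst/cli/rhizonet all --config cfg.yaml --outdir out`.

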