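# ceRNAnet

Inference of lncRNA–mRNA **competing endogenous RNA (ceRNA) networks** from
paired case/control expression profiles, with centrality-based hub
nomination and random-walk prioritisation of disease-associated lncRNAs.

lncRNAs can de-repress mRNAs by sponging the miRNAs they share; a
lncRNA–mRNA pair that shares many miRNA partners is a candidate ceRNA pair.
`ceRNAnet` is written for analysts with paired designs — the motivating
setting is eight patients with ovarian endometriosis, each contributing one
ectopic (EC) and one eutopic (EU) endometrial sample, profiled for mRNA,
lncRNA and miRNA expression — plus a miRNA–target interaction table and a
short list of known disease genes.

## The method

1. **Paired moderated differential expression.** Per-patient EC − EU log2
   differences are tested with an empirical-Bayes moderated one-sample
   t-test: per-feature variances are shrunk toward a common prior
   (s̃² = (d₀s₀² + d s²)/(d₀ + d), hyperparameters by moments matching on
   log s²), p-values BH-adjusted. A feature is significant at adjusted
   p < 0.05 with |log2FC| > 1 (fold change > 2).
2. **Hypergeometric ceRNA pair selection.** Interactions are restricted to
   differentially expressed RNAs. A pair whose mRNA has t miRNA partners,
   whose lncRNA has N, sharing r within a universe of T miRNAs, is scored by
   P(X ≥ r), X ~ Hypergeometric(T, t, N); pairs with p < 0.01 form the
   bipartite ceRNA network, each edge keeping its (T, t, N, r) evidence and
   shared miRNA identities.
3. **Hub nomination.** Degree, betweenness and closeness per node; hubs are
   the intersection of the three top-10 lists.
4. **Random walk with restart.** Pₜ₊₁ = (1 − r)WPₜ + rP₀ on the ceRNA
   network (restart r = 0.5, L1 convergence below 10⁻¹⁰), seeded at 1/n on
   each known disease gene. Each lncRNA receives an empirical p-value M/N
   from N seed-shuffled reruns (M = walks scoring strictly higher).
5. **Annotation.** A hub lncRNA's competing mRNAs with Pearson r > 0 and
   p < 0.05 feed an offline hypergeometric over-representation test against
   user-supplied GMT gene sets.

A synthetic-data module (`generateDataset`) emulates the paired design with
planted fold changes, planted ceRNA pairs, a planted hub and a planted
disease-proximal lncRNA, so the entire chain is testable offline.

## Worked example

```r
library(ceRNAnet)

ds <- generateDataset(syntheticConfig(rngSeed = 1))
de <- lapply(setNames(nm = rnaClasses(ds@expression)), function(cl)
  pairedModeratedTest(ds@expression, cl))
deSummary(de)
#>   rna_class up down total_significant tested
#> 1      mRNA 39   36                75    300
#> 2    lncRNA  8    7                15     60
#> 3     miRNA 20   18                38    150

net <- buildCernaNetwork(de, ds@interactions, alpha = 0.01)
net
#> CeRNANetwork: 41 lncRNA-mRNA competing pairs (p < 0.01)
#>   lncRNAs: 15  mRNAs: 40  miRNA universe: 38

hubIntersection(centralities(net), k = 10)
#> [1] "LNC0040"

res <- rwrPermutationTest(net, rwrConfig(
  seeds = truthManifest(ds)$seed_genes, nPermutations = 1000L, permSeed = 2L))
head(rankLncrnas(res), 3)
#>    lncrna     score p_value significant
#> 1 LNC0009 0.3333333   0.000        TRUE
#> 2 LNC0002 0.0000000   0.184       FALSE
#> 3 LNC0011 0.0000000   0.196       FALSE
```

All 75 + 15 + 38 significant calls are exactly the planted differentially
expressed features; the 41 retained pairs comprise the 40 planted ceRNA
pairs plus one chance pair. `LNC0040` — the planted hub, wired into 12
competing pairs — is the sole member of all three top-10 centrality lists,
and `LNC0009` — the planted disease-proximal lncRNA, which competes with
all four designated seed genes — ranks first with permutation p < 0.001.
`truthManifest(ds)` exposes the planted ground truth for comparison.

`runPipeline(pipelineConfig(outDir = "run1"))` executes all stages in
order, writes every stage table plus a GraphML export, and serialises a
machine-readable `report.json`.

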