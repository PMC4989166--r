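# cpPhylo

Comparative chloroplast phylogeography for co-distributed plant species.

Phylogeographers working on seed plants routinely survey one or two
chloroplast spacer regions across dozens of populations per species and ask
a common set of questions: how is haplotype variation distributed in space,
is there phylogeographic structure, did populations expand after the last
glaciation and when, and do co-distributed species occupy the same climatic
niche? cpPhylo packages that entire chain as tested, reusable R functions,
so a multi-species comparison (the setting where idiosyncratic responses of
species sharing one landscape become visible) can be run end-to-end,
reproduced with a seed, and validated against generators with known truth.

## What it computes

* **Haplotypes** — recoding of aligned cpDNA (FASTA in): substitutions per
  site, each indel and each declared inversion as a single mutation;
  collapsing into haplotypes (`CH1`, `CH2`, ... by first appearance) with
  per-population counts and mutational-step distance matrices.
* **Diversity & differentiation** — per-population *h* and π; *h*_S, *h*_T
  and unordered *G*_ST versus ordered *N*_ST (distance-weighted), with the
  permutation *U*-test for phylogeographic structure
  (*N*_ST > *G*_ST); OLS regression of diversity on latitude.
* **Spatial structure** — AMOVA on squared mutational distances
  (Φ-statistics) and a simulated-annealing search for the K geographically
  contiguous population groups maximizing *F*_CT, with an *F*_CT(K)
  plateau scan.
* **Networks** — median-joining haplotype networks (ε-relaxed minimum
  spanning network plus consensus median vectors, pruned).
* **Demography** — Tajima's *D* and Fu's *F*_S with coalescent p-values;
  mismatch distributions fitted to the sudden-expansion model
  (τ, θ₀, θ₁ by multistart least squares), SSD and raggedness with
  parametric-bootstrap p-values, and calendar dating via
  *T* = τ/(2 μ k g).
* **Niche overlap** — environmental-layer collinearity filtering
  (|r| ≤ 0.70), transparent suitability models, AUC evaluation, Schoener's
  *D* and Hellinger-based *I*, and the pooled-pseudoreplicate identity
  test.
* **Generators** — structured-coalescent haplotype data (island model,
  stepwise expansion, finite sites) and synthetic landscapes with
  occurrences from declared niches, both with truth records, both writing
  the exact file formats the analysis functions read.

## Worked example

Simulate a four-population species that expanded 100-fold (true τ = 5),
then run the core analyses:

```r
library(cpPhylo)

sc <- coalescentScenario(nPerDeme = rep(10, 4), Ne = 2e5, migration = 5e-5,
                         expansion = list(time = 1.25e5, ratio = 100),
                         mu = 1e-9, seqLength = 2000, generationTime = 10)
sim <- simulateCoalescent(sc, seed = 4)

hset <- collapseHaplotypes(recodeMutations(sim$alignment), sim$populations,
                           labelPrefix = "CH")
hset
#> HaplotypeSet: 20 haplotypes from 40 individuals in 4 population(s)

d <- pairwiseDifferences(hset)
round(unlist(differentiation(hset, d)[c("hS", "hT", "GST", "NST")]), 3)
#>    hS    hT   GST   NST
#> 0.922 0.936 0.014 0.013

ut <- nstGstPermutationTest(hset, d, nPerm = 999, seed = 1)
round(c(U = ut$U, p = ut$p), 3)
#>      U      p
#> -0.098  0.508
```

High within-population diversity, negligible differentiation and
*N*_ST ≈ *G*_ST (p = 0.51): migration keeps this simulated species
panmictic, so no phylogeographic structure is claimed. The mismatch
distribution, however, carries the expansion:

```r
hist <- mismatchHistogram(hset, d)
fit <- expansionGof(fitSuddenExpansion(hist, sum(popCounts(hset))),
                    nBoot = 1000, seed = 1)
fit
#> Sudden-expansion fit: tau = 3.992  theta0 = 3.316e-07  theta1 = 23.69
#> SSD = 0.002159  H_Rag = 0.0209  modality: unimodal
#> bootstrap: p_SSD = 0.7192807  p_rag = 0.7572428  tau 95% CI [ 1.72, 5.89 ]
```

A unimodal histogram, an expansion model that fits (p_SSD = 0.72, so the
model is not rejected), and τ̂ = 3.99 with a bootstrap CI bracketing the
true value 5. Dating uses per-species substitution rate, sequence length
and generation time; with the shipped preset for *Castanopsis tibetana*
and the published τ = 0.625:

```r
pre <- subset(datingPresets(), species == "C. tibetana")
dateExpansion(0.625, pre$mu, pre$k, pre$g, rounding = "published",
              tauCI = c(0, 3.438))
#> $T
#> [1] 9600
#> $CI
#> [1]     0 53000
```

an expansion dated 9,600 years before present (CI 0–53,000), i.e. early
Holocene. `runPipeline()` chains all stages (plus the niche comparison)
from one configuration and writes per-species CSV/JSON artifacts and a
cross-species report.

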