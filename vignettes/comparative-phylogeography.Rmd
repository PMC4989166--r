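---
title: "Comparative chloroplast phylogeography with cpPhylo: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative chloroplast phylogeography with cpPhylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpPhylo)
```

cpPhylo implements the analysis chain used in comparative phylogeography of
co-distributed plants from chloroplast (cpDNA) sequence data: from aligned
spacer sequences and population coordinates to haplotype networks,
diversity and differentiation statistics, spatial genetic structure,
demographic-expansion inference with calendar dating, and climatic-niche
overlap between species. This vignette records the models, the estimator
conventions, the numerical choices and the deliberate design decisions, so
that numbers produced by the package are interpretable and comparable
across runs.

## Haplotype recoding

cpDNA is haploid, maternally inherited and effectively non-recombining, so
each individual carries one haplotype and the locus has a single genealogy.
Variation in spacer alignments comes as substitutions, indels and small
inversions. The package treats **every mutational event as a single
character**:

* substitution sites are kept one column per site;
* each maximal gap run with a distinct span becomes one binary
  presence/absence column (simple indel coding); nested or overlapping runs
  get separate columns per distinct span;
* each user-declared inversion region becomes one binary orientation
  column, scored by whether a sample's subsequence is closer to the
  reference orientation or to its reverse complement. Inversions are
  **declared, not detected**: reliable automatic detection of small
  inversions in noisy spacer alignments is a research problem of its own.

Missing data policy: alignment columns where any sample carries `N` are
excluded entirely (complete-column deletion), and substitution sites
overlapped by any gap run are likewise excluded — the event is already
represented by its indel column. The payoff is that recoded vectors are
fully determined (no wildcards), two distinct haplotypes always differ by
at least one column, and an indel is never double-counted as an indel plus
the substitutions it covers. The cost is that substitution variation
hiding inside a gap region in other samples is ignored; for chloroplast
spacers, where gap regions are short, this is a minor loss.

Mutational-step distances between haplotypes count differing recoded
columns, so an indel or inversion contributes one step, matching the
single-mutation treatment. Nucleotide diversity divides by the full
alignment length L (gap columns included); a switch excludes
indel/inversion columns from distances where a substitution-only measure
is wanted.

## Diversity and differentiation

Per-population haplotype diversity uses the unbiased estimator
$h = \frac{n}{n-1}(1 - \sum_k p_k^2)$ and nucleotide diversity
$\pi = \frac{n}{n-1} \sum_{k<l} 2 p_k p_l d_{kl} / L$. Populations of size
one report both as missing.

Differentiation follows the ordered/unordered framework: with the 0/1
identity kernel one obtains $h_S$, $h_T$ and
$G_{ST} = (h_T - h_S)/h_T$; replacing the kernel by the mutational
distance $d_{kl}$ gives $v_S$, $v_T$ and $N_{ST}$. Conventions, chosen to
match the estimator family used by the classic cpDNA literature and fixed
so results are comparable across runs:

* population means are **unweighted** (each population counts once,
  regardless of sample size);
* the total-diversity small-sample correction uses the **harmonic mean**
  sample size: $\hat h_T = 1 - \sum_k \bar x_k^2 + \hat h_S / (P \tilde n)$,
  and analogously for $v_T$.

Whether the original analyses weighted populations by size is not
recoverable from published summaries; the unweighted convention is the
documented default.

$N_{ST} > G_{ST}$ indicates that closely related haplotypes co-occur
geographically, i.e. phylogeographic structure. The permutation U-test
builds the null by permuting haplotype labels **on the distance matrix**
while leaving frequencies untouched: $G_{ST}$ is invariant under this
permutation, so the test isolates exactly the ordering information.
$U = (N_{ST}^{obs} - \overline{N_{ST}^{perm}})/\mathrm{sd}(N_{ST}^{perm})$,
and the one-tailed p-value uses the add-one rule
$p = (1 + \#\{N_{ST}^{perm} \ge N_{ST}^{obs}\})/(B+1)$ so that p is never
zero. Default 1000 permutations. With a constant distance matrix the null
is degenerate ($N_{ST} \equiv G_{ST}$); U is undefined and p is reported
as 1.

The latitude regression of per-population h is ordinary least squares with
a two-sided slope test. The published analysis calls this a "multiple
regression" but reports only latitude; the implementation is univariate
with the per-population table exposed so further predictors can be added
by the user.

## AMOVA and the spatial annealing search

AMOVA decomposes molecular variance among groups, among populations within
groups, and within populations, using **squared** mutational distances
(the Phi-statistics convention of the SAMOVA/Arlequin family) and the
standard coefficient corrections for unequal sample sizes. Negative
variance-component estimates are reported as-is and flagged rather than
truncated, so that profiles remain comparable. With all individuals
identical the Phi statistics are undefined and flagged.

The spatial search ("SAMOVA") looks for the assignment of populations to
K geographically contiguous groups maximizing $F_{CT}$. Contiguity comes
from a Delaunay triangulation of population coordinates on the (lon, lat)
plane; at study extents of a few degrees the plate-carree distortion is
irrelevant to adjacency. The triangulation is computed by the
empty-circumcircle criterion with a deterministic symbolic perturbation so
co-circular layouts (e.g. four populations on a square) resolve
reproducibly; exactly collinear layouts fall back to a chain graph, and
duplicate coordinates are jittered with a warning.

The annealing schedule is geometric: start temperature 1, cooling factor
0.95, 100 proposed moves per temperature, stop below 1e-3; a move
reassigns one boundary population to an adjacent group and is legal only
when both source and target groups stay connected; 100 independent starts
by default, best result returned. The published description names no
schedule; these values make the search exhaustive-equivalent on problems
of the size tested (the test suite checks annealing against complete
enumeration of contiguous partitions for up to 8 populations). The
$F_{CT}(K)$ scan suggests the smallest K at which the forward increase
drops below a plateau threshold (default 0.01) and raises a
"no reliable grouping" flag when no K reaches a floor (default 0.5); both
thresholds are exposed because the criterion by which a grouping is
declared reliable is a judgement call, not a published rule.

## Median-joining networks

The network starts from the $\varepsilon$-relaxed minimum spanning
network, characterized through MST bottleneck distances: a link (u, v)
enters iff $d(u,v) \le B(u,v) + \varepsilon$, where B is the largest edge
on the MST path between u and v — for $\varepsilon = 0$ this is exactly
the union of all minimum spanning trees. Majority-consensus median
vectors of connected triplets (the "unsampled or extinct" intermediate
haplotypes drawn as small nodes in published figures) are added one at a
time while they strictly reduce total network length, then median vectors
not needed by any shortest connection are pruned; surviving medians are
junctions of degree at least 3. Defaults: $\varepsilon = 0$ (the usual
program default), all recoded columns weighted 1, a hard cap of 1000
medians, and lexicographic tie-breaking on node labels so output is
independent of input order.

## Demographic inference

**Tajima's D** contrasts $\hat\pi$ with $S/a_1$ using the standard
constants; **Fu's $F_S$** computes $S' = \Pr(K \ge k_{obs})$ under the
Ewens sampling formula with $\theta = \hat\pi$, through the unsigned
Stirling-number recursion in log space (stable to samples of hundreds),
and $F_S = \ln(S'/(1-S'))$. Both take p-values from neutral constant-size
coalescent simulations conditioned on the corresponding $\hat\theta$
(fixed-$\theta$ conditioning, the program-family convention): two-tailed
for D, and for $F_S$ the fraction of simulations at or below the observed
value. Negative values of both indicate expansion-like excesses of rare
variants and of haplotypes.

**Mismatch distributions** collect all n(n-1)/2 individual pairwise
differences. The sudden (stepwise) expansion model — a population at
scaled size $\theta_0$ jumping to $\theta_1$ at mutational time $\tau$
before present — has expected frequencies obtained here in closed form
from the piecewise-exponential coalescent mixture:
$$F_i = \hat F_i(\theta_1)\,P(i+1, a_1\tau) +
        \hat F_i(\theta_0)\, e^{\tau(1/\theta_0 - 1/\theta_1)}\,
        Q(i+1, a_0\tau),$$
with $\hat F_i(\theta) = \theta^i/(1+\theta)^{i+1}$ the stationary
geometric, $a = (\theta+1)/\theta$, and P/Q the regularized
incomplete-gamma tails, evaluated in log space. At $\tau = 0$ this reduces
exactly to the stationary case. Parameters are estimated by minimizing the
sum of squared deviations (SSD) between observed and expected relative
frequencies over $\tau, \theta_0 \ge 0$, $\theta_1 \ge \theta_0$, with a
moment-informed multistart grid refined by Nelder-Mead on squared
transformed parameters; the expected tail beyond the observed maximum is
folded into the last bin so both vectors are proper distributions. The
exported expected curve is truncated 20 bins past the observed maximum.
Harpending's raggedness uses the $x_{-1} = 0$ convention
($d_{max}+1$ terms).

Goodness of fit is a parametric bootstrap (default 1000 replicates):
samples of the original size are simulated under the fitted expansion,
refitted, and the p-value is the fraction of replicates whose SSD (or
raggedness) reaches the observed value; the percentile spread of the
replicate $\hat\tau$ gives its confidence interval. Modality of the
histogram is classified by counting local maxima of a 3-bin
moving-average smooth — a bimodal mismatch in a pooled sample is the
classic signature of deep regional structure rather than of expansion.

**Dating.** $\tau$ converts to time before present through
$T = \tau/(2\mu k g)$ with $\mu$ the substitution rate per site per year,
k the analysed sequence length and g the generation time in years.
Presets for the three focal species ship with the package
(`datingPresets()`). Two conventions deserve note. First, the published
dates are reproduced exactly when T is floored to the nearest hundred
years; this "published" rounding mode is provided alongside the default
"none". Second, the formula as printed yields generations if g sits in
the denominator, yet the associated dates are reported in years; the
package reproduces the printed convention verbatim and leaves the unit
question to the user's rate calibration. Substitution rates themselves
are consumed as inputs — estimating them from family-level phylogenies is
out of scope.

## Niche comparison

Environmental layers are handled as co-registered grids (headered ASCII
raster in/out). The collinearity filter scans layers in order and drops
any layer whose absolute Pearson correlation with an already-retained
layer exceeds 0.70 (the published threshold); the original study's
retained set (BIO1, BIO2, BIO3, BIO4, BIO12, BIO15, BIO19) ships as a
preset. Which member of a correlated pair survives is order-dependent —
the published analysis does not say how its choice was made, so the
greedy-in-order rule is the documented convention here.

Suitability comes from transparent presence-only models — a Gaussian
envelope (product of per-variable kernels around the presence mean,
rescaled to a maximum of 1) and a percentile envelope (classic BIOCLIM
minimum score). They stand where a maximum-entropy model stood in the
original workflow: the scientific content of this module is the
**comparison machinery**, which is model-agnostic by interface — any
externally produced suitability raster on the same grid can be fed
directly into the overlap and identity functions.

Overlap normalizes both surfaces to probability distributions over valid
cells and reports Schoener's $D = 1 - \frac12\sum|p_i - q_i|$ and the
Hellinger-based $I = 1 - \frac12\sum(\sqrt{p_i}-\sqrt{q_i})^2$, both 1
exactly when the normalized surfaces coincide and 0 on disjoint supports.
The identity test pools the two species' presence points, randomly
repartitions them into the original sample sizes, refits both models and
recomputes (D, I), 100 times by default; the test is one-tailed (niche
difference pushes observed overlap below the null), with the add-one
p-value. The null split always allocates the smaller sample size first,
which makes the null distribution invariant to swapping the two species
at the same seed. AUC model evaluation uses an 80/20 presence split
against uniformly sampled background cells, computed as the Mann-Whitney
rank statistic with ties counted half.

## Synthetic data and what passing tests mean

The coalescent generator simulates an island-model genealogy by competing
exponentials (within-deme coalescence, symmetric migration), an optional
stepwise size change, and Poisson mutations on branches — finite-sites by
default so recurrent hits are possible as in real cpDNA, with an
infinite-sites switch for clean theory checks. Truth records carry
$\theta = 2N_e\mu g k$ and $\tau = 2\mu g k t$. Demes sit on a west-east
axis with coordinates, so contiguity and latitude analyses run on
simulated data unchanged. The landscape generator produces smoothed
Gaussian random fields, a declared Gaussian niche per species, occurrences
sampled proportional to true suitability, and analytic true D/I.

The generators deliberately do not emulate: recombination or biparental
markers, selection, sequencing error, spatially biased sampling effort,
real topography/coastlines, or niche structure beyond an axis-aligned
Gaussian. Tests passing on these data therefore validate the estimators
under their own model assumptions; they do not certify behaviour under
ascertainment bias or model misspecification in field data.

Problem sizes used by the shipped validation suite (chosen to exercise
the asymptotics that matter while keeping a full run in minutes): samples
of 40-50 individuals, 100-200 replicates per calibration, permutation and
bootstrap counts of 99-199 inside replicated studies and 1000 as
single-run defaults, landscapes of 40 x 40 cells with 120-200 occurrences
per species.

## Known limitations

* **$\tau$/$\theta_0$ confounding.** In the sudden-expansion model the
  mismatch histogram constrains approximately $\tau + \theta_0$-worth of
  pre-expansion signal: when ancestral diversity is a sizeable fraction
  of $\tau$, $\hat\tau$ is biased upward by the same order regardless of
  estimator. Recovery studies (and trustworthy empirical dating) need
  $\theta_0 \ll \tau$ — which is the regime of the study system, where
  fitted ancestral cpDNA diversity is near zero. The bootstrap CI, not
  the point estimate, is the honest summary otherwise.
* Finite-sites recurrent mutation slightly deflates distances relative to
  the infinite-sites theory the expansion model assumes; at cpDNA spacer
  divergences this is a percent-level effect.
* The annealing search is exhaustive-equivalent on tested sizes but, like
  any stochastic optimizer, carries no global guarantee on much larger
  population systems; raise `nStarts` there.
* Contiguity on raw lon/lat is inappropriate for continental-scale or
  high-latitude layouts; project first if that is your case.
* The envelope suitability models ignore interactions between variables
  and will under-fit strongly curved niches; import an external
  suitability raster where that matters.
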