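---
title: "Genetical genomics in a partial diallel: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetical genomics in a partial diallel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelgg)
```

# The experiment this package models

`diallelgg` implements the analysis chain of a genetical-genomics
experiment in an outbred conifer pedigree: four full-sib families from a
2 x 2 partial diallel (two weevil-resistant mothers, two susceptible
fathers), 188 progeny profiled on 94 two-colour microarray hybridizations,
a framework map of 252 SNP markers on 13 linkage groups, 428 expression
traits, and ten conventional phenotypes (four height/leader growth traits,
two 3-class weevil-attack scores, two 5-class oviposition scores, and the
two year-sums). The pipeline maps phenotype QTLs (pQTLs) and expression
QTLs (eQTLs) by single-marker LOD scans, locates randomization-calibrated
eQTL hotspots, identifies positional candidate genes by collocation
permutation, and infers a direct co-expression network from shrinkage
partial correlations.

Everything runs on synthetic data with planted ground truth, so every
stage is testable end to end without external downloads. The generator is
first-class, seeded code, not a fixture.

# The simulator

**Meiosis.** Parents carry phased genotypes over the framework map; each
progeny receives one recombinant haplotype per parent. Crossovers between
adjacent markers at distance $d$ cM occur with the Haldane probability
$r = \tfrac12(1 - e^{-2d/100})$, independently across linkage groups and
without interference. Haldane was chosen over interference models because
it is the simplest standard model with a closed form that doubles as an
independent test oracle. Outbred genotypes are coded as transmitted-allele
indicators $x_p \in \{0, 1\}$ per parent, defined only where that parent
is heterozygous (an informative meiosis); this coding feeds the per-parent
QTL model directly, and a reader converts `"ab"`-style genotype strings on
input.

**Marker informativeness.** The study reports about 122 segregating SNPs
per cross out of 252, but not the underlying mechanism. We model each
parent as heterozygous at an independent Bernoulli(`het_fraction`)
fraction of markers and set the default `het_fraction = 0.28`, since a
locus segregates in a cross when either parent is heterozygous:
$1 - (1 - 0.28)^2 \approx 0.48 \approx 122/252$. This is the one place the
generator's default is calibrated to a reported summary rather than taken
from it directly.

**Expression.** A gene's latent genetic value is the sum of its planted
QTL effects $\beta_p x_p$ plus a polygenic background (many tiny marker
effects, default sd 0.3) that makes the family term of the network model
non-trivial. The measurement model adds an overall mean (default 8 on the
arsinh scale), a per-gene baseline (sd 1), centred fixed effects for dye,
replicate block, fabrication batch and experimenter, and a gene-level
residual (default sd 0.15). Raw fluorescence is produced by inverting the
stabilizing transform, `foreground = sinh(h) * scale + subgrid
background`, so the normalization module can round-trip the signal.
Planted eQTL architectures default to a Poisson mean of 10 QTLs per gene —
with 428 genes this emulates the heavily trans-regulated architecture of
the study, where 428 gene spots generated several thousand significant
eQTLs — with per-QTL effects of 0.4–0.8 and an optional cis QTL at the
gene's own locus.

**Phenotypes.** Continuous traits are normal liabilities; ordinal traits
threshold the liability (3 attack classes, 5 egg classes; thresholds give
moderate class prevalences). Within each trait group
(resistance = attack/egg/sums, growth = heights/leader) a set of shared
loci is drawn once — one allele, one parent, one effect size per locus,
expressed consistently in every trait of the group. That is the genetic
premise of a resistance QTL scored across seasons, and it is what makes
the year-sum traits detectable through the same parent. Default liability
effects (0.8–1.2 sd) give each locus roughly 10–15% of liability
variance, a realistic size for a mapped forest-tree QTL.

# Array design

Slides pair individuals within a cross to maximize the genetic distance
between co-hybridized samples (a "distant pair" design, which maximizes
informative allele contrasts). Genetic distance is the mismatch fraction
of genotype states over the cross's segregating loci, the simplest metric
consistent with counting allele differences. The optimizer is a greedy
farthest-neighbour construction refined by 2-exchange hill climbing with
restarts; exact maximum-weight matching was deliberately not used because
instance sizes are small (≤ 54), the published quantity of interest
(improvement over random pairing) is algorithm-agnostic, and the local
search is transparent to test — an exhaustive enumeration oracle covers
every instance up to n = 8 in the test suite, where the local optimum
always coincides with the global one. Odd cross sizes profile the most
distant individual twice. Dye orientation is balanced deterministically:
within every (block, batch, person, cross) stratum orientations differ by
at most one slide, and odd strata donate their extra slide so per-block
dye totals also differ by at most one.

The observed improvement over random pairing is reported as
$100 \cdot (\bar d_{\text{plan}} - \bar d_{\text{random}}) /
\bar d_{\text{random}}$; its exact value depends on the distance metric
and the heterozygosity of the simulated parents, so the package's tests
check that it is strictly positive rather than matching a specific
percentage.

# Normalization

Per spot, the local subgrid background is subtracted; negative net
intensities are retained because the arsinh transform is defined on all
reals (no ad-hoc flooring). Each slide-channel is stabilized by the
robust-affine transform $h = \operatorname{arsinh}((x - a_c)/b_c)$ with
$a_c$ the channel median and $b_c$ the channel MAD. This replaces
full maximum-likelihood VSN while keeping its contract — strictly
monotone, variance-stabilizing for multiplicative noise — which is all the
downstream analysis needs, because it consumes residuals, not absolute
scales. The transform stabilizes spots above the channel median (the log
regime); in the test oracle the spread-versus-rank trend of a simulated
lognormal intensity profile with multiplicative sd 0.3 over an additive
noise floor drops to below a quarter of the untransformed trend, measured
as mean-normalized rank-regression slopes. All channels are then
calibrated to median 0 / MAD 1 so expression level and variance are
array-independent (idempotent by construction).

Technical structure is removed per gene by ordinary least squares with
sum-to-zero factor coding — all effects fixed, as in the study's stated
model. The eQTL model removes dye + block + batch + person; the network
model additionally removes the family (cross) effect, so network edges
reflect within-family co-variation rather than family means. Residuals
are averaged per individual when an individual was measured more than
once; the averaging convention is ours, as the source analysis does not
state how repeat measurements were combined. Rank-deficient designs abort
with the aliased factors named rather than silently dropping columns.

# QTL mapping

At each framework marker the full model
$y = \mu_{\text{cross}} + \sum_p \beta_p x_p$ (over parents informative at
that marker) is fit against the cross-means null;
$\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$. A QTL is
significant at LOD ≥ 3.84 (inclusive) and must be detected for at least
one parent, operationalized as a drop-one-parent LOD at the same
threshold — the published rule names the requirement but not the
statistic, so the drop-one likelihood ratio is our concrete choice.
Scanning happens at framework markers only: the map's ~10 cM spacing
matches the 10 cM support-interval definition of the published threshold,
and interval mapping between markers is out of scope. Ordinal traits are
scanned as numeric class scores (no ordinal link is described in the
source). Adjacent significant markers of one trait within 10 cM merge
into a single support interval keeping the peak marker, so a broad QTL
counts once in hotspot tallies. An eQTL is *cis* when the gene's own
locus lies on the same linkage group within 10 cM, *trans* otherwise,
*unknown* without a gene locus.

Numerical edges: a perfect fit (RSS₁ = 0) is capped at LOD 99; traits
that are constant (overall or within crosses) score LOD 0 everywhere, via
a scale-aware degeneracy floor of $10^{-16}\sum y^2$; markers informative
in no parent are skipped.

# Hotspots

Per-marker eQTL counts are tested against uniformity with a Pearson
chi-squared test (df = M − 1). The hotspot threshold re-places the
observed number of significant eQTLs uniformly at random over the
framework markers and takes the maximum per-marker cluster size over
1,000 replicates — the global maximum, matching the published wording; a
95th-percentile-of-maxima mode is provided for sensitivity analysis
because the wording is ambiguous between the two. With the study's
numbers (4,221 eQTLs, 252 markers, 1,000 replicates) this lands at 38 ± a
couple of counts across seeds. Each replicate draws from its own
pre-drawn seed, which makes the threshold non-decreasing in both the
number of eQTLs and the number of replicates under a shared master seed —
a property the tests exercise directly. A hotspot with at least three
collocated significant pQTLs is classified `resistance`, `growth`, or
`both` by the trait groups of those pQTLs.

# Positional candidates

A gene is a positional candidate for a trait when at least 40% of its
eQTL markers coincide with the trait's pQTL markers and a permutation
p-value is ≤ 0.05 at 10,000 randomizations. The null re-places the gene's
(distinct) eQTL markers uniformly over all mapped markers, conditioning
on the observed pQTL landscape; which side the published "10,000
randomizations" permuted is not stated, so this choice is declared, and
an option re-places eQTLs according to an empirical marker-density weight
instead. Under the uniform null the intersection count is exactly
hypergeometric, so the implementation samples it directly — this is a
sampling shortcut, not an approximation, and the test suite checks it
against an exact enumeration on a 10-marker miniature. Collocation means
the identical framework marker (QTLs are single peak markers after
support merging); a window variant exists for sensitivity.

The default p-value is the add-one estimator
$(1 + \#\{\text{perm} \ge \text{obs}\})/(B + 1)$, which can never be zero
but is super-uniform for a discrete statistic — its null distribution has
large atoms (for a gene with 10 eQTLs and sparse pQTLs, a third of null
genes have p = 1), so a Kolmogorov–Smirnov uniformity check on raw
add-one p-values would reject for any implementation. Calibration is
therefore checked on the randomized-tie version
(`tie_break = "randomized"`), which is exactly uniform under the null;
candidate calls always use the conservative estimator. "General
resistance" candidates are genes that are candidates for all six
resistance traits — the strongest reading of the published composite
rule, which states no weaker quantitative criterion.

# Co-expression network

The sample correlation matrix of the family-corrected residuals is shrunk
towards the identity with the analytic optimal intensity
$\lambda = \min\!\big(1, \sum_{i \ne j}\widehat{\mathrm{Var}}(r_{ij}) /
\sum_{i \ne j} r_{ij}^2\big)$, and partial correlations are read off the
scaled negative inverse. Shrinkage keeps the matrix positive definite
when genes outnumber samples; inversion removes indirect (marginal-only)
correlations, so edges are direct conditional dependencies.

Edge probabilities come from a two-component mixture over the
off-diagonal partial correlations: a null density
$f_0(r;\kappa) \propto (1 - r^2)^{(\kappa - 3)/2}$ with unknown degrees
of freedom $\kappa$, and a uniform alternative on $(-1, 1)$. $\kappa$ is
profiled over a geometric grid (3.5 to 8000, 80 points — about 10%
resolution, ample for a parameter identified only up to tail behaviour)
with the null proportion $\eta_0$ fit by EM at each grid point; the edge
probability is one minus the local false discovery rate,
$1 - \eta_0 f_0(r)/f(r)$, clipped to $[0, 1]$. Edges are called at
probability ≥ 0.80, inclusive, mirroring the inclusive LOD convention.
The exact local-fdr configuration of the original software is not public;
the mixture contract above is what the package commits to, and it is
validated by: exact-null draws recovering $\kappa$, pure-noise data
yielding ≤ 1% edges, a planted strong dependency scoring > 0.9, and a
20-gene chain (n = 150, adjacent partial correlation 0.4) recovered with
precision ≥ 0.8 and recall ≥ 0.7. On the full default pipeline (428 genes,
188 individuals) shrinkage is strong and few or no edges pass 0.80 — the
expected conservative behaviour of this estimator at p ≫ n; the chain
benchmark, not the full run, is the calibrated recovery setting.

# End-to-end validation scenario

The pipeline-level check plants a *trans*-regulatory hotspot: 45 genes
each carrying a single eQTL at one marker (effect 0.4, acting through one
heterozygous parent — a polymorphic regulator allele), against 383
background genes with uniformly placed eQTLs, plus three resistance
pQTLs pinned at the same marker. Two scenario choices matter:

* **Fully informative parents** (`het_fraction = 1`). With partially
  informative parents, detected background eQTLs concentrate on the ~73%
  of markers that are informative somewhere, while the randomization null
  spreads over all 252 — the null is then anti-conservative and
  background maxima can cross the threshold. Full informativeness makes
  the uniform null exact for the detectable landscape, isolating the
  hotspot machinery from marker-informativeness confounding. (Real data
  are clumpier still; the study's own uniformity test rejected at
  $\chi^2 = 3{,}551$.)
* **Moderate hotspot effect** (0.4 ≈ 15–20% of expression variance).
  Strong enough for near-certain detection at the marker itself, weak
  enough that linked markers 20+ cM away stay below LOD 3.84, so the
  flagged set is exactly the planted marker rather than a smear along the
  linkage group.

Under these conditions the planted marker is the only hotspot and is
classified `resistance`, across seeds.

# Problem sizes and determinism

Every stochastic function takes an explicit `seed`; `run_all()` spawns a
named substream per stage from one master seed, so partial reruns are
bit-reproducible and two runs with the same config produce identical
manifests. The test suite runs the full study-scale scenario once
(252 markers, 188 individuals, 428 genes, ~25 s) and otherwise uses
reduced instances (26–52 markers, 40–200 genes); null calibration uses
200 traits and power checks 100 planted traits in single vectorized
scans. The acceptance script runs the 4,221 × 252 × 1,000 randomization
ten times and reports the modal maximum.

# What passing tests do and do not show

The generator emulates the study's statistical structure: segregation in
an outbred partial diallel, technical nuisance structure, planted
cis/trans architectures, ordinal liabilities, hotspot clustering. It does
not emulate spatial print-tip artefacts, saturation, spot-quality
failures, cross-hybridization between paralogues (a real concern for
conifer gene families), linkage-map error, or genotyping error. Passing
tests therefore demonstrate that the statistical machinery is correct and
calibrated under the stated model, not that the biological conclusions of
any particular dataset are robust to those unmodelled artefacts.

# Known limitations

* Single-marker regression only; no interval mapping, multi-QTL models or
  epistasis.
* Phase is taken as known; phase-unknown EM estimation of recombination
  is not implemented (the framework map is an input, not an output).
* Ordinal traits use numeric scores, not a cumulative-link model.
* The local-fdr mixture uses a uniform alternative; heavy non-null
  structure concentrated near zero would be absorbed into the null.
* The pairing optimizer is a local search; optimality is verified only up
  to the enumeration limit (n ≤ 8), although restarts make larger
  instances reliably optimal in practice.
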