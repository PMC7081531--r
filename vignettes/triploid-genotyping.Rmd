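---
title: "Genotype calling and pedigree analysis for induced triploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype calling and pedigree analysis for induced triploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triocall)
```

## The problem

Pressure-shock induced triploidy is standard practice in salmonid
aquaculture: retaining the second polar body leaves the egg with a pair of
maternal sister chromatids, so the offspring carries two maternal and one
paternal chromosome set. Standard SNP-array genotyping software only models
three diploid clusters and cannot call such individuals. `triocall`
implements a full workflow for this setting: dosage calling from
allele-signal contrasts, marker quality control, exclusion-ratio parentage
assignment, parental sex prediction from the asymmetric maternal
contribution, and maternal recombination mapping in the style of
gene-centromere analysis.

## The calling model

For each SNP and sample the two allele fluorescence signals are reduced to
one dimension, the contrast $c = \log_2(A_{signal}/B_{signal})$. Genotype
groups appear as clusters along the contrast axis: a triploid SNP can show
up to four clusters (BBB, ABB, AAB, AAA, i.e. A-dosage 0..3), a diploid SNP
up to three. Each marker is modelled as a univariate finite normal mixture

$$p(c) = \sum_{g=1}^{G} \pi_g \, \mathcal N(c \mid \mu_g, \sigma_g^2),$$

fit for every cluster count $G$ from 1 to ploidy + 1 under two variance
structures: `E` (one shared $\sigma^2$) and `V` (cluster-specific
$\sigma_g^2$). A triploid marker therefore sees $4 \times 2 = 8$ candidate
models and a diploid one $3 \times 2 = 6$.

### Initialization and the mean prior

EM on mixtures is sensitive to starting values, particularly when genotype
classes are very unbalanced. Each fit is seeded from a rough allele
frequency: observations are hard-assigned to the nearest reference contrast
mean, the implied mean dosage gives $\hat p$ (clipped to
$[1/2n,\,1 - 1/2n]$ so monomorphic-looking markers keep non-degenerate
expectations), and the $G$ dosage classes to seed are ranked by their
empirical assignment counts (ties broken by binomial mass, then lower
dosage). The $\mathrm{Binomial}(\text{ploidy}, \hat p)$ masses of the
selected classes, renormalized and rounded by largest remainder (with at
least one observation per cluster), give block sizes $n_1..n_G$; cutting the
sorted contrasts into consecutive blocks of those sizes yields initial
means.

The initial block means also serve as a prior: each $\mu_g$ carries a
conjugate normal prior centred on its block mean with precision
$\kappa/\sigma_g^2$, $\kappa = 1$ pseudo-observation (`em_control(kappa=)`).
This weakly anchors the left-to-right labelling against local optima while
leaving well-populated clusters essentially unbiased (the prior weight is
one observation against $n_g$). The variance M-step absorbs the conjugate
prior term, which keeps the penalized objective provably non-decreasing —
a property the test suite checks directly. Weights and variances are
otherwise unpenalized; whether the original implementation also constrained
variances is unknown, and leaving them free is the weaker assumption.

### Model selection by ICL

Each converged fit is scored on the larger-is-better scale

$$\mathrm{BIC} = 2\,\ell - k \log n, \qquad
  \mathrm{ICL} = \mathrm{BIC} - 2 \sum_{i,g} \hat z_{ig} \log \hat z_{ig},$$

with $k = 2G$ for `E` and $3G - 1$ for `V`. The entropy term penalizes
overlapping clusters, so ICL prefers well-separated solutions — the right
bias for genotype data, where true clusters are separated and apparent
extra structure usually reflects assay artefacts. ICL $\le$ BIC always,
with equality under hard classification. For each cluster count the better
variance mode is kept, the overall ICL winner classifies the marker, and

$$\Delta\mathrm{ICL} = \mathrm{ICL}_1 - \mathrm{ICL}_2$$

(the gap between the two best cluster *counts*) becomes the marker quality
statistic. An alternative reading — the gap between the two best models
overall, which can be two variance modes of the same count — was considered
and not implemented; the per-count reading matches the statistic's purpose
of flagging ambiguity in the number of genotype groups. When only one
cluster count is feasible the gap is stored as `Inf`: such markers are
never removed by the ΔICL rule alone, and fall to the call-rate and
mapping-collision filters instead.

### Cluster labelling and no-calls

With the maximum cluster count the left-to-right rank rule labels clusters
directly (lowest contrast = all-B). With fewer clusters each fitted mean is
matched to the nearest *reference contrast mean*; the shipped defaults are
the published large-panel estimates (−1.76/0.16/1.94 for diploids,
−1.97/−0.50/0.75/2.14 for triploids), and `estimate_reference_means()`
recomputes them from any dataset as the per-dosage means over markers
showing all clusters. If two clusters land nearest the same reference mean
the locus is ambiguous and the whole marker is a no-call. Per sample, the
call is the maximum-responsibility cluster and the uncertainty is one minus
that responsibility; uncertainty strictly above 0.15 (the array-software
default, kept for comparability) is a no-call. A call exactly at 0.15 is
kept, with a 1e-12 slack guarding the boundary against round-off.
Single-cluster markers have zero uncertainty by construction — a known
blind spot discussed below.

## Parentage, sex, and recombination

**Exclusion ratios.** A candidate parent homozygous for one allele cannot
have an offspring carrying only the other allele. Duos are ranked by
$\mathrm{ER} = \#\text{exclusions}/\#\text{markers called in both}$, using
only this sex-agnostic opposing-homozygote rule; full trio checks use the
complete rule tables, which `exclusion_table()` *derives* by enumerating
parental gamete/chromatid contributions rather than transcribing them (a
heterozygous mother can contribute AA, AB or BB as her retained chromatid
pair; a homozygous mother only her own pair). Missing genotypes never count
as exclusions and never enter the denominator. Candidates with ER strictly
below 0.002 are assigned; more than two assignments flag a conflict. The
threshold is configurable and should sit below the third-lowest candidate
ER per offspring, which `assign_parentage()` reports as a diagnostic —
on other chips or error regimes 0.002 need not transfer.

**Sex prediction.** Because the mother contributes two alleles, offspring
AAB/AAA exclude a BB mother and ABB/BBB exclude an AA mother, while any
non-opposing-homozygote combination is possible for a father. The
mother-specific exclusion ratio (`mother_er`, same denominator) separates
the sexes: an assigned parent with `mother_er` < 0.02 is labelled mother,
at or above 0.02 father. Two mothers (or fathers) for one offspring flag a
conflict — the signature of duplicated parental DNA or failed triploidy.

**Recombination.** At markers where the father is homozygous his
transmitted allele is known, so the maternal two-allele contribution of a
heterozygous mother is observable as homozygous or heterozygous. Near the
centromere recombination is suppressed and the retained sister-chromatid
pair is identical; the per-marker heterozygous fraction rises with distance
from the centromere, exactly as the second-division segregation frequency
in gene-centromere mapping. `recomb_profile()` computes this fraction over
informative trios, dropping Mendelian-impossible trios from both numerator
and denominator (they are genotyping errors, not recombination signal) and
keeping markers with at least 50 informative trios. The recommended QC for
this stage is deliberately looser than for parentage (ΔICL > 50, offspring
call rate ≥ 0.80, parent call rate ≥ 0.95) so the map stays dense; both
ΔICL comparisons are strict, for consistency. No Hardy–Weinberg assumption
is made — inherited maternal pairs are *not* in HWE, and the profile is a
pure count ratio. A per-mother crossover report
(`maternal_crossover_report()`) segments each offspring chromosome by runs
of at least 5 informative markers; it is a deterministic inspection aid,
not a genetic-map estimator, and map-distance calibration or interference
modelling are out of scope.

## The simulator

`simulate_dataset()` generates the whole study: a marker map, Hardy–
Weinberg diploid parents (MAF ~ U(0.05, 0.5)), a full-factorial cross
design, and offspring built mechanistically — per chromosome arm a
Poisson(1) chiasma count with uniform positions, each chiasma toggling the
retained pair's hom/het state distal to it with probability 0.5, maternal
contribution read off that state, one paternal allele per locus. The
resulting het fraction at scaled distance $d$ from the centromere has the
closed form $y(d) = (1 - e^{-2 s \lambda(d)})/2$ (`true_het_fraction()`),
and that curve — not any biological map — is the ground truth the
recombination module is tested against. The switch-process model has no
chiasma interference and its $y$ saturates at 1/2; real salmonid profiles
show interference and can approach 1 on long arms, so passing tests
demonstrate correct *recovery of the generative model*, not fidelity to
salmon biology.

Signals are drawn per marker around the reference means with a common
marker shift (SD 0.15 contrast units), cluster SDs uniform on
[0.08, 0.25] (half the markers heteroscedastic), optional "noisy" markers
with SD 0.6 emulating poorly separating assays, and dosage errors at rate
0.005 per cell in which the dosage is replaced by a *uniformly different*
dosage before the signal is drawn. Contrasts are de-transformed to positive
signal pairs with a fixed sum, so files round-trip through the
normalized-summary format. All noise parameters live in `sim_config()` and
a single seed (R's Mersenne–Twister) fully determines the output.

### What the error model implies for the ER threshold

Uniform dosage flips send errors to the *opposite homozygote* far more
often than real array miscalls do (which land almost entirely in adjacent
clusters). At ε = 0.005 in both generations this produces roughly
0.002 opposing-homozygote exclusions per marker for a *true* parent–
offspring duo — the same order as the 0.002 assignment threshold. On a
1000-marker panel (~400 markers surviving ΔICL > 150) a true duo then has
a sizeable chance of one exclusion, i.e. ER above threshold, so a fraction
of true parents goes unassigned at any panel size. Every assignment that
*is* made remains correct, with correct sex labels and no conflicts — the
published study likewise assigned both parents to 304 of 379 offspring.
Users simulating benchmark panels should treat `error_mode`/
`genotype_error_rate` with this in mind; the acceptance machinery reports
both assignment precision and both-parent recall.

### ΔICL sweeps and one-cluster markers

In threshold-sweep experiments (trio ER and no-call fraction versus ΔICL
cutoff) the parents enter as truth genotypes: in the motivating study the
parent generation is called by a separate upstream pipeline, and with few
simulated parents a single parent miscall injects threshold-independent
exclusions unrelated to the offspring filter being studied. Two structural
caveats remain. A very noisy marker whose contrasts collapse into one blob
often *selects one cluster* — and a one-cluster fit has zero classification
entropy, hence a large ΔICL, and zero call uncertainty, hence full call
rate: no threshold ever removes it, the same one-cluster blind spot known
from comparing mixture calling with the array vendor's pipeline. Conversely
clean low-MAF markers can have small ΔICL (sparse clusters make the count
uncertain) yet near-zero error. Both effects mean the ER-versus-threshold
curve is decreasing in the bulk but need not be sample-wise monotone at the
extremes of every simulated panel.

## Numerical choices

* EM: relative log-posterior tolerance 1e-6, at most 500 iterations,
  variance floor 1e-4 contrast units² (identical observations converge with
  the floor variance rather than collapsing). A cluster losing all mass
  marks the fit non-converged and excludes it from selection; a marker with
  every fit failed is 100% no-calls.
* Ties: equal ICL between cluster counts resolves to the smaller count;
  equal responsibilities resolve to the lower-contrast cluster.
* Strict versus non-strict: ΔICL filters are strict (`> 150` removes a
  marker at exactly 150), call-rate filters non-strict (`>= 0.95`), ER
  assignment strict (`< 0.002`), mother-ER boundary labels father
  (`>= 0.02`), uncertainty no-call strict (`> 0.15`).
* Duplicate detection: pairwise-complete Pearson correlation of dosage
  vectors, strict `> 0.99`, pairs with fewer than two shared markers
  skipped.

## Problem sizes

The test suite and the acceptance script run entirely on simulated panels
sized to the workflow's discriminating regimes: 1000 markers with a
10 × 10 factorial cross and 300 triploid offspring for end-to-end recovery;
600-marker panels with 10% injected noisy markers for threshold sweeps;
5 chromosomes × 400 markers × 300 meioses for recombination recovery; 200
markers at ≥ 8 SD cluster separation for cluster-count recovery; and
12-point fixtures for brute-force likelihood checks.

## Known limitations

One-cluster markers carry no uncertainty estimate (calls rest on reference
mapping alone); cluster-mean covariance across markers, batch effects, and
sex-chromosome-aware calling are not modelled; residual-tetraploid
("semi-fixed") SNPs common in salmonid genomes are neither simulated nor
diagnosed; parentage is purely exclusion-based, with no genotyping-error
likelihood; tetraploid × diploid triploids would invalidate the sex and
recombination logic, though calling and ER assignment would still apply.
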