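---
title: "PPL linkage analysis in extended pedigrees: models, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PPL linkage analysis in extended pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedppl)
```

## The model

`pedppl` measures linkage evidence with the posterior probability of
linkage (PPL). At each marker position the hypotheses compared are "a
diallelic trait locus is linked to this position" against "no trait locus
here" (θ = 0.5). The trait locus is never observed; everything about it —
its allele frequency, its effect parameterization, the recombination
fraction θ, and Smith's admixture proportion α of linked pedigrees — is
integrated out over finite grids with equal prior weight on every
admissible grid point. What survives the integration is the Bayes ratio

$$\mathrm{BR}_i \;=\; \int
  \frac{\alpha\,L_i(g,\theta) + (1-\alpha)\,L_i(g, 0.5)}{L_i(g, 0.5)}
  \; d\pi(g,\alpha,\theta),$$

the integrand being a ratio so that trait-model likelihood factors common
to the linked and unlinked hypotheses cancel; at a marker untyped in a
pedigree, or for a fully uninformative trait, $\mathrm{BR}_i = 1$ exactly.
The posterior is $\mathrm{PPL} = \pi\,\mathrm{BR} / (\pi\,\mathrm{BR} + 1 -
\pi)$ with prior π = 0.02: one expected trait locus in the genome, a
deliberately conservative choice under locus heterogeneity. A PPL of 20%
therefore means the data moved the probability tenfold above the prior;
1 − PPL is *not* interpreted as the probability of no gene. No
multiple-testing correction is applied: the PPL is a graded measure of
evidence at each position, not a decision rule.

Three trait parameterizations are supported:

* **DT** — penetrance vector $f = (f_{DD}, f_{Dd}, f_{dd})$, each the
  probability of affection given the genotype, under the ordering
  constraint $f_{DD} \ge f_{Dd} \ge f_{dd}$.
* **QT** — three genotypic means and SDs on the *standardized* trait scale
  (`standardize_qt()` is applied before analysis); normality is assumed
  within genotype, not at the population level; $\mu_{DD} \ge \mu_{Dd} \ge
  \mu_{dd}$.
* **QTT** — the QT model plus a threshold *t*: individuals without a
  measured value may be declared over (upper-tail probability) or under
  (lower tail) the threshold. Used for the anxiety phenotype, whose
  instrument is not administered to affected individuals.

The ordering constraints fix the allele-labelling convention (the D allele
never decreases risk); the model class is symmetric under relabelling
D ↔ d with $p \mapsto 1-p$ and the penetrance/mean vector reversed, a
property pinned by a unit test.

### Evidence accumulation

Two accumulation schemes are implemented, and their contrast is itself
informative about between-family heterogeneity:

* **pooled** — the product of per-pedigree admixture likelihood ratios is
  taken *inside* the integral: one shared draw of $(g, \alpha, \theta)$
  for all pedigrees.
* **sequential** — each pedigree's BR is integrated separately and the BRs
  are multiplied (in log space; order-invariant; for one pedigree the two
  schemes coincide, also pinned by tests).

Under pooling, α is shared across pedigrees. We examined the alternative
reading (α integrated per pedigree with only $(g,\theta)$ shared) in
simulation: it weakens the pooled/sequential contrast at linked loci and
changes nothing at unlinked ones, so the shared-α form is kept.

## The likelihood engine

Pedigree likelihoods are exact Elston–Stewart peels over the joint
two-locus genotype space: per individual, ordered (paternal, maternal)
allele pairs at the trait locus (4 states) × the marker (k² states for k
alleles). Ordered genotypes make phase explicit, so the uniform phase
marginalization happens automatically through the Hardy–Weinberg founder
prior and the Mendelian transmission table with recombination θ.

Numerical and structural choices:

* **Genotype-set restriction.** A typed individual's marker states are
  restricted to the (at most two) orderings of its observed genotype, so
  the joint state space is ≤ 8 for typed members; only untyped members
  carry the full 4k² states. This single-pass set recoding leaves the
  likelihood unchanged (excluded states have zero weight) and makes a
  30-member pedigree peel in milliseconds; the full iterated elimination
  would buy little here because the batched peeler (below) is matrix-bound,
  not state-bound.
* **Allele lumping.** Microsatellite alleles not observed within a
  pedigree are pooled into one residual allele carrying the remaining
  frequency mass; this is exact and keeps k small.
* **Vectorized trait-model batches.** The whole trait-parameter grid is
  peeled in one pass: every message between nuclear families is a
  states × models matrix, and the child-marginalization step is a pair of
  dense matrix products. This is what makes the integration over ~10³–10⁴
  grid models per θ tractable in plain R. Batches are chunked so peak
  memory stays bounded for large QTT grids.
* **Log-space rescaling.** Each message is rescaled by its per-model
  maximum with the log constant carried separately; likelihoods of
  30-member pedigrees would otherwise underflow doubles.
* **Connected components.** Childless founders (and any disconnected
  component) peel separately; their log-likelihoods add.
* **Zero likelihoods.** A likelihood of exactly zero (data inconsistent
  with the model, e.g. an uncorrected Mendelian error) is signalled as
  `-Inf`. Grid points impossible under both the linked and unlinked
  hypotheses (e.g. penetrances forcing an observed unaffected individual
  to be affected) contribute a likelihood ratio of 1 — no evidence either
  way — rather than 0/0; points impossible only under linkage contribute 0.
* **Loops.** Pedigree loops (consanguinity or marriage loops) are detected
  as cycles in the individual–nuclear-family membership graph and rejected
  as fatal: the peeler requires loop-free pedigrees, and loop-breaking is
  out of scope.
* **Map function.** Haldane's map function converts cM distances to
  recombination fractions wherever needed, θ = (1 − e^(−2d/100))/2; it has
  a closed form and matches the no-interference assumption of the
  gene-dropping simulator.

The peeler is verified against an independent full-enumeration oracle
(founder ordered genotypes × meiosis origin indicators) to a relative
error of 1e-10 on random 4–8-member pedigrees, and the integration against
a naive-loop quadrature oracle to 1e-8 on a six-member fixture.

## Priors and default grids

"Essentially uniform" priors over a finite range, with equal weight per
admissible point after the ordering constraints:

| parameter | default grid |
|---|---|
| θ | 0, 0.05, …, 0.5 |
| α | 0.1, 0.2, …, 1.0 |
| p (DT and QT) | 0.001, 0.01, 0.1, 0.3, 0.5 |
| DT penetrances | ordered triples on a 0.1 step over [0, 1] (286 triples) |
| QT means | ordered triples on a 0.5 step over [−3, 3] |
| QT common SD | 0.3, 0.5, 1, 2 |
| QTT threshold | 0, 0.5, …, 2.5 |

All are configurable through `prior_spec()`. The QT/QTT ranges are finite
because the trait is standardized first; ±3 SD covers any plausible
genotypic mean on that scale. Simulation-heavy analyses (and this
package's own simulation tests) use coarser declared grids — θ in steps of
0.1, α in steps of 0.2, p ∈ {0.01, 0.1, 0.5}, penetrance step 0.2 — which
preserve the statistic's behaviour at a fraction of the cost.

## Genotype cleaning

The pipeline applies, in order: marker missingness (drop SNPs above 5%,
microsatellites above 25%), sample missingness (mask individuals above the
same type-specific thresholds; pedigree structure is retained), Mendelian
errors, Hardy–Weinberg filtering (founders only; drop SNPs with p < 1e-10,
microsatellites below 1e-4), and LD thinning of SNPs (greedy left-to-right
per chromosome, dropping a SNP whose founder allele-dosage r² with any
retained SNP within a 50-marker window exceeds 0.20). Choices the
thresholds alone don't fix:

* *Missingness first*: masking and error-blanking change missingness
  counts, so missingness is computed first (and over samples that are not
  fully missing, which makes the pipeline idempotent — verified by test).
* *Mendelian-error limits*: more than 1 error drops a marker; an individual
  whose errors exceed 1% of their testable markers is masked; for retained
  markers the offending nuclear family's genotypes at that marker are set
  missing, preventing zero likelihoods downstream. The limits are
  configurable; published pipelines rarely state theirs.
* *HWE on founders only*: non-founders are correlated copies of founder
  alleles and would distort the test. The test is the chi-square
  goodness-of-fit against expected genotype proportions (df = genotype
  categories − alleles; monomorphic markers return p = 1). In the extreme
  tails the chi-square approximation and an exact conditional test can
  disagree substantially for degenerate counts; the test suite therefore
  checks calibration (no drops under true HWE) and gross violations (both
  tests drop), not tail-for-tail agreement.
* *Composite LD*: r² is the squared Pearson correlation of founder allele
  dosages (0/1/2), not haplotype r² — phase is unknown and dosage r² is
  deterministic.

## Phenotype engine

BAP-Q: 36 six-point Likert items in three 12-item subscales (aloofness,
pragmatic language, rigidity); reverse-keyed items map x → 7 − x; subscale
scores are item means and the total score is the mean of all items. The
instrument's true item key is not distributed with the package: the
default `bapq_key()` is a synthetic stand-in (documented as such) and the
real key should be supplied for real data. Self and informant reports are
averaged when both exist; otherwise the available rater is used, and the
rater provenance selects the matching cut-off column. Classification is
positive when *any* scored domain meets its sex- and rater-specific
cut-off (the 24 published cut-off values ship as defaults, e.g. averaged
aloof 4.03 for males, averaged pragmatic language 2.90 for females);
comparison is inclusive (score ≥ cut-off), the natural reading of "met
criteria", and pinned by boundary tests. Decisions where the instrument's
published description is silent, made once and flagged as interpretations:

* a subscale is scored when ≥ 10 of its 12 items are present (mean of the
  present items);
* "negative" requires ≥ 3 scored domains — a single low domain cannot
  clear someone;
* the total score acts as a fourth eligible domain in the any-domain rule.

Compound codings: for the ASD trait, BAP-positive relatives are coded
*unaffected* (the trait is ASD alone); for the BAP trait, ASD cases and
BAP-positive relatives are both affected. Secondary phenotypes use the
instruments' published cut-offs (core language < 84, non-word repetition
≤ 7, rapid naming < 84; pragmatic rating positive if ASD or MPRS-positive),
RBS-R totals and SRS t-scores as quantitative traits, and anxiety t-scores
as a QTT trait with unmeasured ASD cases over threshold and unmeasured
non-cases under.

## The simulator

`generate_cohort()` produces study bundles that exercise every pipeline
stage: three-generation pedigrees (founder couple, their children married
to unrelated founders, grandchildren; the default 3 × 3 template gives 17
members, matching the study design's 16–24 genotyped members per family),
gene-dropped genotypes (founder haplotypes from allele frequencies under
linkage equilibrium, transmissions with Haldane recombination, the hidden
trait locus inserted at its map position), phenotypes drawn from the
calibration distributions — anxiety N(51, 9) for non-ASD adults, RBS-R
N(26, 16) for cases / N(4, 7) for non-cases truncated at the instrument
floor of 0, SRS N(84, 14) / N(48, 11) — and rejection-sampled
ascertainment: a pedigree is retained only if ≥ 3 ASD cases span ≥ 2
nuclear families (no single nuclear family contains all cases). The
default marker panel is 50 SNPs at 4 cM plus interleaved 6-allele
microsatellites, echoing a dense microsatellite scan augmented with a
thinned SNP map.

BAP-Q item generation treats the broad phenotype as a carrier phenotype:
non-ASD adults carrying at least one disease allele draw their items from
a distribution shifted upward by a configurable amount (default +1.3 on
the Likert scale, giving carrier subscale means near the published
cut-offs so that a substantial fraction — not all — of carriers classify
positive). This is a generative stand-in: no published generative model
for BAP-Q items exists.

What the simulator does *not* emulate: marker–marker LD (panels are in
linkage equilibrium; the LD filter is tested on explicitly constructed
correlated columns), residual familial correlation beyond the trait locus,
assortative mating, and genotyping error. Passing tests on simulated
cohorts therefore demonstrate the statistical machinery, not robustness to
those real-data features.

## Pooled versus sequential under heterogeneity

The package's simulation suite probes the expected contrast between the
accumulation schemes with a 19-pedigree, two-locus experiment in which
each pedigree additionally draws its own trait model (allele frequency
log-uniform on [0.02, 0.4], dominance anywhere between recessive and
dominant, phenocopy rate up to 0.1) — an *extensive-heterogeneity* regime.
Across 20 replicates, sequential updating yields the larger PPL at the
linked markers in the clear majority of comparisons, as expected when no
shared trait model fits all pedigrees.

The second expected feature of that contrast — more of the unlinked genome
showing evidence against linkage (PPL < 2%) under sequential than pooled —
does **not** reproduce under this package's exact two-point analysis, and
the reversal is robust: it persists under mild and extensive model
heterogeneity, with weakly and highly informative unlinked markers, and
under both α-sharing conventions. The mechanism is visible in the
integrand: at a truly unlinked two-point marker each per-pedigree BR is
shrunk toward 1 by the α and grid averaging, while the pooled grid average
of a 19-pedigree product is far more dispersed and falls below the prior
more often. A single two-point marker simply carries much less
per-pedigree information than a dense multipoint position; users comparing
the two schemes on two-point scans should expect pooled, not sequential,
to flag more positions as evidence-against, and should read the
genome-fraction diagnostic accordingly. The heterogeneity test in the
package's suite asserts the multipoint-motivated direction for both halves
of the contrast and is therefore expected to fail on the second; it is
kept failing rather than weakened, as documentation of this limit of
two-point analysis.

## Problem sizes used by the test suite

Chosen to keep the full suite within a desk-scale run (~10 minutes on one
CPU): enumeration-oracle comparisons on 4–8-member pedigrees (the oracle
bails out and redraws beyond 2 × 10⁶ configurations); quadrature-oracle
comparison on a 6-member fixture with a 105-model grid; null-scan
calibration over 10 replicates × 20 unlinked markers × 4 pedigrees (200
marker-replicates, median PPL within 0.01 of the prior); the heterogeneity
experiment over 20 replicates × 19 pedigrees × 10 markers with the coarse
declared grids; generator calibration checks on 10,000 draws (2-SE
tolerance).

## Known limitations

* Two-point analysis only: positions are marker positions; no multipoint
  likelihoods, and the genome-fraction contrast above reflects that.
* Loop-free pedigrees only; loops are rejected, not broken.
* Sex-averaged θ; no imprinting, liability classes, or X-linked models.
* The QTT threshold grid lives on the standardized scale; traits whose
  censoring threshold is far outside ±3 SD need a custom grid.
* The default BAP-Q key is synthetic; results on real questionnaires
  require the instrument's published key and cut-offs appropriate to the
  rater mix.
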