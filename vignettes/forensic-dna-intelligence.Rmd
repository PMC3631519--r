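---
title: "Forensic DNA intelligence from genome-wide SNP genotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic DNA intelligence from genome-wide SNP genotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forensnp)
```

# Overview

forensnp implements the inference stack behind an "all-in-one" forensic DNA
intelligence workflow: starting from a genome-wide SNP genotype profile it
infers genetic sex, biparental continental ancestry (both a categorical PCA
assignment and quantitative admixture proportions), Y-chromosomal and
mitochondrial haplogroup origin, categorical eye and hair colour, and
pairwise relatedness. Because real chip cohorts cannot ship with a package,
a first-class synthetic-data module generates genotype data with the exact
statistical structure the inference methods assume, so every method can be
exercised and validated end to end.

This vignette records the models, their assumptions, the tunable parameters
and their defaults, the numerical choices, and what the synthetic data do
and do not establish about behaviour on real data.

# The synthetic cohort generator

## Drifted populations

Reference populations are simulated under the Balding–Nichols model: for a
marker with ancestral allele frequency $p$ drawn uniformly on a configurable
interval (default $[0.05, 0.95]$), population $k$'s frequency is

$$f_k \sim \mathrm{Beta}\!\left(p\,\tfrac{1-F_k}{F_k},\; (1-p)\tfrac{1-F_k}{F_k}\right),$$

where $F_k \in (0,1)$ is a per-population drift parameter with the property
that the expected Hudson $F_{ST}$ between two populations with drift $F$ is
approximately $F$ (we verified this against a Monte-Carlo evaluation with
$10^5$ replicate markers before freezing the simulator's tests). The default
drift values span 0.02–0.15, covering within-continent to between-continent
differentiation. All population frequencies are clamped to $[0.001, 0.999]$
so no marker is fixed and every likelihood below stays finite.

Individuals with admixture vector $q$ on the $K$-simplex draw autosomal
dosages $g_j \sim \mathrm{Binomial}(2, \sum_k q_k f_{kj})$, i.e. markers are
independent given ancestry. This deliberately omits linkage disequilibrium,
consistent with the pipeline's use of an LD-pruned marker subset for
ancestry; it means the simulator cannot exercise LD-aware methods (none are
in scope) and that confidence in real-data behaviour where strong LD
remains unpruned is limited.

Sex chromosomes follow array conventions: females draw two X doses, males
draw one X allele rendered as a homozygous diploid call (dosage 0 or 2),
carry a Y haplogroup path, and everyone carries a mitochondrial haplogroup
path drawn from the regional clade of an ancestry sampled from $q$. Y and
mtDNA markers are haploid states along one path of a fixture phylogeny: no
recombination, no heteroplasmy, no recurrent mutation.

## Relatives

Relative pairs are produced by gene-dropping through the minimal pedigree
realising the requested degree (first: parent–offspring or full siblings;
second: half-siblings, avuncular or grandparental; third: first cousins or
grand-avuncular; fourth: first cousins once removed). Founder haplotypes
carry distinct labels, so the realised IBD state of every pair at every
marker is known exactly and is recorded alongside the genotypes. Because
markers are independent (no recombination map), realised IBD fractions
concentrate much more tightly around their pedigree expectations than they
would along real chromosomes; the kinship sweep below is therefore an
easier problem at equal marker count than real data, which is the main
caveat to carry over.

`simulate_study_pedigrees()` reconstructs an 81-sample validation cohort
whose 3,240 pairs contain exactly 27 first-, 10 second-, 3 third- and 1
fourth-degree pair, the remainder unrelated.

## Degradation

`apply_quality_loss()` models quality loss as independent missingness at a
configurable rate plus symmetric genotype flips at an error rate. The
missingness-only default reflects that degraded chip data mostly lose calls;
the error profile of degraded samples is not characterised in the
literature we follow, so `error_rate` defaults to 0 and stays configurable.
No allele-specific dropout is modelled.

# Sample QC

A sample fails QC when strictly more than 10% of its genotype calls are
missing (`qc_call_rate()`); the threshold is the platform convention for
these arrays. Failed samples are still given an ancestry attempt in the
pipeline — genome-wide ancestry tolerates low call rates because its
information is spread over tens of thousands of partially redundant markers
— but carry their QC flag in every report.

Marker-level filtering keeps markers with cohort MAF strictly above 1% and
missingness strictly below 5% (the convention for the relatedness marker
set), with optional greedy windowed LD pruning (default $r^2 > 0.2$ within
a 50-marker window, step 5) used to build a low-LD ancestry subset. MAF is
computed on the analysis cohort itself.

# Sex inference

X-specific heterozygosity is the fraction of non-missing X-specific calls
(pseudoautosomal markers excluded) that are heterozygous; at least 100
informative calls are required (configurable). Male DNA yields values near
0 because the single X is rendered homozygous. The classical thresholds —
below 0.2 implies male, above 0.8 implies female, the closed interval
between them inconclusive — are combined with Y-marker evidence (Y call
rate at least 0.5, or a called Y haplogroup, means male DNA present; Y data
present but uncalled means absent).

One design point deserves emphasis. The raw heterozygous fraction of a
female profile is bounded by the markers' heterozygosity and in practice
sits near 0.3–0.4 for a realistic frequency spectrum, i.e. in the
"intermediate" zone; published workflows that quote a >0.8 female rule are
implicitly using a normalised heterozygosity. We keep the literal fraction
(it is the more transparent statistic) and let the two-pronged combination
carry the female call: an intermediate X with *no* Y calls is compatible
only with female (or heavily degraded single-source) DNA and yields a
female call with a single-evidence caveat, whereas an intermediate X *with*
male Y evidence is a mixture signature and stays inconclusive. Directly
conflicting prongs (e.g. male-like X but no Y calls) are inconclusive —
this is exactly the situation where a one-pronged X-only rule would
misclassify. A conflict flag is raised whenever a call contradicts the
recorded sex of the sample.

# Biparental ancestry

## Reference space

`fit_reference()` builds the reference from a labelled cohort: markers are
centred by $2\bar p_j$ and scaled by $\sqrt{2\bar p_j(1-\bar p_j)}$, the
standardised matrix is decomposed by PCA (default 3 components, matching
the dimensionality used for visual cluster inspection), and per-population
centroids are the mean reference coordinates. Query samples are projected
by least squares on the loadings restricted to their non-missing markers
(an orthonormal-loading projection renormalised by the retained loadings),
and assigned to the nearest centroid in Euclidean distance; ties break by
label order with a warning. Samples with calls on fewer than half the panel
markers are not projected. No rejection radius is applied: the categorical
path always returns the nearest group, and the quantitative path below is
the one that can refuse a single-group call.

## Quantitative admixture

Supervised admixture maximises the binomial mixture log-likelihood

$$\ell(q) = \sum_j g_j \log \pi_j + (2-g_j)\log(1-\pi_j), \qquad
\pi_j = \sum_k q_k f_{kj},$$

over the simplex with the reference frequencies $f_{kj}$ fixed — the
supervised counterpart of model-based clustering with $K$ populations of
distinct allele frequencies, which is the faithful minimal model when a
labelled reference is available. The EM update attributes each observed
allele to an ancestry in expectation and renormalises; $\ell$ is concave in
$q$ and non-decreasing across iterations (asserted in the tests, and
checked against an exhaustive simplex grid search on small instances).
Iteration stops when $\ell$ improves by less than $10^{-6}$ or after 500
iterations; non-convergence — common when the optimum sits on the simplex
boundary, where EM is sublinear — returns the best iterate with a warning
flag, whose proportions are in practice accurate to well below the
reporting resolution. Missing markers are skipped.

A sample is assigned to a single group when its largest admixture
proportion strictly exceeds 0.70, and to "multiple groups" otherwise. The
"probability" in this rule is interpreted as the admixture proportion
itself; that interpretation (rather than, say, a PCA-distance posterior) is
a documented design choice. Note the 0.70 rule makes a genuinely admixed
50/50 individual and an individual from an unrepresented intermediate
population indistinguishable — both land in "multiple groups", and the
tests assert this deliberately.

Reference-panel size matters: admixture error is bounded below by the
sampling noise of the estimated reference frequencies, so the shipped
simulations use HapMap-scale groups (tens of samples per population).
With 60 samples per population and 20,000 markers, a planted 50/50
admixture is recovered within ±0.05 per component.

# Uniparental lineages

Haplogroups are called against a rooted tree whose edges carry defining
variants. The caller scores every node by the fraction of its root-path
defining variants observed in the derived state (over non-missing calls)
and the count of derived states observed off the path, then picks the
deepest node with support at least 0.8 and at most 1 conflict; ties at
equal depth break by support. A profile with no non-missing calls at all is
`no_call` — for the Y tree this is the signal that no male DNA is present.
Calling is monotone (deeper derived variants never shallow the call), and
simulated lineage paths round-trip exactly at zero missingness.

The shipped trees are small abstract fixtures (~21 nodes, one top-level
clade per geographic region, labels like `A1a` rather than any published
nomenclature); real trees load through the same newick + annotation-TSV
format. Geographic labels drive a consistency report that cross-tabulates
paternal/maternal origin against the biparental assignment and flags
divergent lines as admixture signals (e.g. "paternal Africa / maternal
Western Eurasia" for a first-generation admixed individual) rather than
treating them as errors.

# Eye and hair colour

Both traits use multinomial logistic models over effect-allele dosages:
six SNPs and three categories (blue / intermediate / brown) for eye colour,
eighteen SNPs and four categories (black/dark-brown, brown/light-brown,
blonde/dark-blonde, red) for the chip-adjusted hair model — four MC1R
variants of the full published panel are absent from the array, and the
tests reproduce the consequence (degraded red recall) as a strict ordering.
The fit maximises an L2-penalised multinomial likelihood (ridge $10^{-4}$
on non-intercept terms; convex, hence deterministic) by quasi-Newton
optimisation with analytic gradients, and agrees with an independent
off-the-shelf multinomial implementation to better than $10^{-3}$ mean
absolute probability difference.

Published coefficient values for these models are not reprinted in the
source literature we follow; the package therefore treats coefficients as
loadable configuration (`read_phenotype_model()`) and ships defaults fitted
once on a planted-parameter synthetic cohort (`*_model_synthetic.tsv`,
generated by a scripted fit; the files reproduce the models' structure, not
any published values). Predictions require the full complement of predictor
SNPs; any missing predictor blocks the call. The eye call applies the
p > 0.7 rule (argmax category only if its probability strictly exceeds
0.7, else "undetermined"); the hair call applies a configurable
prediction-guide rule table, by default argmax with exact ties broken
toward the lighter shade (red is placed lightest in the tie order so a tie
never hides a red signal behind a darker call) — the published guide can be
encoded in the same table.

# Relatedness

For every sample pair, autosomal markers passing the MAF/missingness gates
(no LD pruning, matching the convention for this marker set) contribute an
IBS state: opposite homozygotes are state 0, identical genotypes state 2,
everything else state 1. The method-of-moments estimator converts observed
state counts into IBD proportions by subtracting the expectations for an
unrelated pair computed from allele frequencies, then
$\hat\pi = \hat k_2 + \hat k_1/2$, clamped to $[0,1]$.

Two numerical choices matter. First, when frequencies are estimated from
the analysis cohort itself, plug-in powers of sample frequencies are
biased; the estimator therefore uses unbiased factorial-moment estimators
of $p^aq^b$ from the allele counts, which removes a ≈+0.02 bias in
unrelated-pair $\hat\pi$ at cohort sizes around 80. Second, the component
estimates $\hat k_0,\hat k_1,\hat k_2$ are reported raw (noise can push
them slightly outside $[0,1]$) and only $\hat\pi$ is clamped; clamping the
components individually truncates their noise asymmetrically and re-biases
unrelated pairs upward.

Degrees of relatedness are assigned by binning $\hat\pi$ at the midpoints
of the expected sharing of adjacent degrees (0.375, 0.1875, 0.09375) with a
lower unrelated cutoff of 0.044 — so an observed 9% genome share falls in
the fourth-degree zone, consistent with how such a pair is interpreted in
practice. Bins are configurable. Both the mean IBS fraction and $\hat\pi$
are reported, but classification is driven by $\hat\pi$: "proportion of
genome shared" quoted for distant relatives is on the IBD scale. In
drifted or isolated cohorts analysed against external reference
frequencies, unrelated-pair $\hat\pi$ inflates and distant relatives are
overpredicted; the tests assert this direction.

# Pipeline and determinism

`run_all()` executes QC → sex → ancestry → lineage → phenotype → kinship,
isolates per-stage failures to the affected samples, and emits a versioned
consolidated report (TSV + JSON) with a run log. Every generator takes an
explicit seed and is bit-reproducible under it; the inference stages are
deterministic given their inputs. A declarative YAML configuration is
validated with all errors reported at once (unknown keys warn, for forward
compatibility), and a thin command-line interface
(`inst/cli/forensnp.R`) exposes the stages as subcommands.

# Problem sizes used in the shipped checks

The test-suite and acceptance checks run at deliberately reduced scale
chosen so the statistical claims are still sharp: 20,000 autosomal markers
for admixture recovery and the kinship sweep (the sweep's 3,240 pairs
classify 100% correctly there), 1,000 X markers for sex recovery, 2,000
markers for the general-purpose five-population world, and cohorts of tens
to a few hundred samples. These sizes were picked as the smallest at which
the corresponding estimators' sampling noise is comfortably inside the
asserted tolerances.

# Known limitations

- No LD simulation and no admixture-LD/ancestry-tract modelling; ancestry
  resolution is continental, not subcontinental.
- Mixtures are only flagged (inconclusive sex), never deconvolved.
- No imputation; no strand/allele harmonisation beyond exact matching.
- The shipped phenotype coefficients and haplogroup trees are synthetic
  stand-ins with realistic structure; substantive forensic use requires
  loading published models and real phylogenies through the documented
  formats.
- Kinship uses IBS moments, not likelihood or KING-robust estimators, and
  assumes an outbred, homogeneous cohort; inbreeding and structure inflate
  distant-relative calls.
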