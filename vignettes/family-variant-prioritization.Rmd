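---
title: "Models and methods for family-based variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for family-based variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedscreen)
```

pedscreen prioritizes candidate disease variants and genes in family-based
sequencing studies of rare, mostly Mendelian, disorders. This vignette is
the package's own account of the models it implements, the tunable
parameters and their defaults, the numerical choices made where the design
was genuinely open, and the limits of what the simulation-based tests can
show.

## Weighted allele frequencies

Minor-allele assignment and every downstream model depend on population
allele frequencies. Estimating them from a handful of ascertained families
is biased — a recessive disease allele is enriched in the very families
collected for the study — and setting an unobserved allele's frequency to
zero breaks likelihood-based tools downstream. Both problems are addressed
by pooling the sample frequency $f_s$ (over $n$ observed alleles) with an
external population frequency $f_e$ (over $m$ alleles):

$$f_w = \frac{n f_s + m f_e}{n + m},$$

with $f_w = f_s$ when no external source is supplied. $f_w$ is a convex
combination of the two frequencies and is strictly positive for any allele
observed in either source. The allele with the smaller $f_w$ at a variant
is declared the minor allele $D$; genotype dosages are then oriented so
that 2 counts copies of $D$. Two open points were settled as follows:

* **Tie at $f_w = 0.5$**: the alphabetically first allele is declared
  minor, so re-runs are reproducible.
* **Who counts toward $f_s$**: all genotyped members, founders and
  non-founders alike. The estimator is defined on "the sample" without
  restriction; the within-family correlation of alleles this induces is
  exactly the enrichment the external pooling is meant to damp, and a
  founders-only mode would discard most of the data in small studies.
* $n$ counts observed alleles (2 per non-missing genotype), not twice the
  sample size, so missingness does not dilute the sample evidence.

## Segregation scores

For each variant, a multiplicative score measures how consistent the
genotype/phenotype pattern is with an autosomal dominant or recessive
model with disease allele $D$. Each individual contributes one factor,
from a table of sub-unit weights (defaults shown; all user-overridable in
`segregation_params()`):

| model     | individual  | genotype | weight |
|-----------|-------------|----------|--------|
| dominant  | affected    | DD       | 0.8    |
| dominant  | affected    | dd       | 0.5    |
| dominant  | unaffected  | Dd       | 0.1    |
| dominant  | unaffected  | DD       | 0.01   |
| recessive | affected    | Dd       | 0.5    |
| recessive | affected    | dd       | 0.1    |
| recessive | unaffected  | DD       | 0.1    |
| any       | other cells | any      | 1      |

The sub-unit (rather than zero) weights tolerate genotyping error: one
model-violating genotype shrinks the score instead of vetoing the variant.
The weights encode roughly 50% detection sensitivity, a 20%
heterozygote-to-homozygote miscall rate and a 10% false-positive call
rate. Missing genotypes and unknown phenotypes contribute a neutral factor
of 1: absent data is no evidence either way. Scores are used for
*ranking* (rank 1 = best), with ties broken by genomic order so output is
deterministic. Because the score is a product over individuals, it
multiplies across families; a per-family mode
(`segregation_score_track(..., per_family =)`) is also exposed, since
family-specific mutations make the within-family product the natural
ranking unit.

## Weighted-sum gene statistic

The gene-level burden statistic follows the published weighted-sum
formulation: at variant $j$, with $m_j$ minor alleles among $n_U$
genotyped unaffected individuals,

$$q_j = \frac{m_j + 1}{2 n_U + 2}, \qquad
  w_j = \sqrt{n_j\, q_j (1 - q_j)}, \qquad
  \gamma_i = \sum_j \frac{c_{ij}}{w_j},$$

and the statistic $x$ is the rank sum of $\gamma$ over affected
individuals (midranks for ties). The +1 pseudo-count keeps rare-variant
weights finite; rare variants get large $1/w_j$ and dominate the burden.
Significance comes from permuting affection labels among individuals with
known status. One numerical point matters: the weights depend on which
individuals are labelled unaffected, so they are **re-estimated for every
permuted assignment**. Keeping the observed weights fixed under
permutation looks harmless but is measurably anti-conservative (the
observed weights are tilted toward the observed case/control split); with
re-estimation the null p-values are uniform, which the test suite checks
by simulation. When the number of distinct label assignments is at most
10,000 the permutation distribution is enumerated exactly (p is then
`#{x_perm >= x}/N`); otherwise 1,000 Monte-Carlo draws are used with the
positively biased, valid estimator $p = (1+b)/(1+B)$. Relatedness is
ignored by the default free permutation, matching the unrelated-samples
setting the statistic was designed for; a within-family permutation mode
is available for pedigree data. With no genotyped unaffected individuals,
$q_j$ falls back to the external frequency (same pseudo-counting) and the
result is flagged.

## Compound-heterozygosity rules

Five filtering rules target recessive compound heterozygosity (two
heterozygous variants in one gene, inherited in trans). Variant level:
(1) heterozygous in all affected individuals; (2) not homozygous for the
disease allele in any unaffected individual; (3) among affected children
heterozygous at the variant with both parents genotyped, at most one
parent heterozygous. Gene level: (4) at least two variants pass rules
1–3; (5) at least one passing variant transmitted from each parent. To
tolerate genotyping error, rules 1–3 are relaxed to a proportion
(`min_rule_proportion`, default 0.95) of the relevant denominator. The
ambiguous wording of that denominator ("affected individuals or
children") is resolved as: affected individuals for rules 1–2, affected
children for rule 3. Rule 3's denominator excludes children with an
ungenotyped parent. Rule-5 transmission is assigned only when exactly one
genotyped parent carries the minor allele; both-parents-heterozygous
configurations are phase-ambiguous and contribute no evidence. When a
parent of an affected child is itself affected, rule 5 is skipped under
the default `auto` policy — both disease alleles then descend from the
affected parent, so demanding biparental transmission would reject true
positives. Empty denominators pass vacuously, but a gene can only pass if
at least one genotyped affected individual exists.

## IBD sharing and region calling

Given externally computed pairwise IBD state probabilities on a cM grid
(Merlin-style tables), the sharing statistic at a grid point is the
proportion of *eligible* pairs with $P(\mathrm{IBD} \neq 0) = 1 - p_0$
strictly above `pair_threshold` (default 0.5). Eligible pairs are
within-family affected blood-relative pairs, excluding parent–offspring
pairs, which always share exactly one allele IBD and carry no signal.
Thresholds use strict inequality throughout ("greater than"). Regions are
maximal runs of consecutive grid points beyond the threshold; the same
caller serves LOD-style tracks (direction `"above"`) and p-value tracks
(`"below"`). Variants take the value of the grid point at or immediately
left of their cM position (left-closed intervals); variants outside the
grid span take the nearest endpoint and are flagged. The statistic is
pooled over families by default — it equals the eligible-pair-count
weighted mean of per-family statistics — with a per-family scope exposed
because the choice is genuinely open.

## Genetic maps and marker selection

Genetic positions are linearly interpolated in physical position between
reference-map anchors (sex-averaged Haldane scale). Outside the anchor
span, the terminal slope is extended and clipped at 0 cM; interpolation
of a monotone map is monotone. The Haldane map function
$\theta = \tfrac12(1 - e^{-2d/100})$ converts cM distances to
recombination fractions (used by the simulator) and is exactly inverted
by `haldane_d()`.

Multipoint IBD/linkage engines assume inter-marker linkage equilibrium,
so `select_informative_independent()` applies three sequential filters:
keep weighted MAF > 0.2; prune by variance inflation factor with target
VIF = 1 in sliding windows (window 50, step 5 — the documented defaults
of the standard pruning tool, since only the VIF target is prescribed);
and enforce ≥ 0.5 cM spacing by a greedy left-to-right scan. Exact
VIF = 1 is unattainable with sampled dosages — any finite-sample
correlation inflates the VIF — so the bound is applied with a 1e-9
tolerance and documented as such; with the default target this removes
markers aggressively, which is the stated intent (complete independence).
Dosages are coded 0/1/2 with pairwise-complete correlations; exact
collinearity is resolved by dropping the later column; monomorphic
columns count as VIF 1.

## The simulator and what it does (not) show

`simulate_study()` drops founder haplotypes through pedigree templates
with Haldane recombination, then injects one of three causal
configurations: family-specific rare dominant variants (ascertained so at
least two affected members form a non-parent-offspring blood pair),
distinct rare variants in one gene across unrelated cases, or a
compound-het pair in trans. Defaults are chosen to look like a targeted
sequencing study of a Mendelian disorder: a 100 cM region, 100 variants
in genes of 5, a frequency spectrum of 80% rare (U(0.001, 0.01)) and 20%
common (U(0.05, 0.5)) variants, full penetrance, no phenocopies, and a
clean genotyping channel (error rates configurable:
heterozygote-to-homozygote miscalls, false heterozygotes, missingness).
In the compound-het scenario, background copies of the two causal
variants are cleared within the family before injection so the designed
trans configuration is exact — this makes the zero-error sensitivity-1
property well defined rather than subject to rare background collisions.
True IBD is emitted as indicator records (p0, p1, p2 each 0 or 1) from
founder-allele identity, so the sharing machinery can be tested without
an external IBD engine.

The generator emulates segregation, recombination, ascertainment and
genotyping error. It does **not** emulate linkage disequilibrium in the
founder haplotypes (variants are drawn independently), population
structure, sequencing-depth-dependent error, or indels and de novo
events. Passing tests therefore demonstrate correctness of the scoring
machinery under clean Mendelian transmission, not robustness to
real-data artefacts beyond the modelled error channel.

## Strategy comparison at desk scale

The acceptance suite re-runs the two-strategy comparison at reduced
scale: 100 replicate 12-member families under the family-specific
scenario and 100 replicates of 10 unrelated cases (plus 10 controls)
under the shared-gene scenario, with rankings aggregated over replicates
into rank-cutoff ROC curves. The expected and observed result is an
ordering, not a number: segregation ranking dominates the weighted sum
(AUC difference beyond twice its bootstrap standard error) when each
family carries its own mutation, and the ordering reverses for unrelated
cases with distinct mutations in one gene. Exact AUCs and operating
points depend on simulation design details (pedigree structures, affected
counts, spectra) that are the generator's own choices here, so only the
ordering — with its uncertainty — is asserted. Problem sizes throughout
the test suite (replicate counts of 15–100, 10,000 sib pairs for the IBD
state check, 400 replicates for the p-value uniformity check) were chosen
as the smallest sizes at which the Monte-Carlo error bands (3 SE, or a
KS test at the 1% level) are meaningfully tight.

## Pipeline behaviour

`run_pipeline()` executes stages in a fixed order (map update → allele
frequencies → pruning → disease-model identification and IBD sharing →
regions), validates the whole configuration before running anything, and
writes one merged row per input variant — pruning narrows analysis marker
sets but never the reporting universe. Output is byte-identical for a
fixed seed regardless of how chromosome batches would be scheduled,
because every stochastic step (permutation p-values) derives its stream
from the configured seed. Exit semantics and a YAML front-end live in the
thin command-line wrapper `inst/cli/pedscreen.R`.

## Known limitations

* Segregation scores pool across families by default; whether per-family
  products should be ranked instead is data-dependent, and both modes are
  exposed.
* The weighted-sum permutation ignores relatedness by default; within
  pedigrees the within-family mode should be preferred.
* All models are autosomal; X/Y and mitochondrial variants are out of
  scope, as are multi-allelic sites.
* IBD probabilities are consumed, never inferred: the package expects an
  external multipoint engine (or the simulator's truth records) to supply
  them.
* Pedigree splitting for large families is supported only to the extent
  of reporting the bit size (2 × non-founders − founders) that drives the
  decision; the splitting optimisation itself is external.
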