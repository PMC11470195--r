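---
title: "Methods: SNP-based genetic monitoring of fragmented riverine populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-based genetic monitoring of fragmented riverine populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragpop)
```

## The monitoring problem

`fragpop` implements the genetic toolkit used to monitor small, fragmented
river-fish populations: a long-lived iteroparous species distributed across a
chain of sites separated by partial or complete barriers, sampled as
birth-year cohorts of juveniles plus adults, genotyped at a few thousand
reduced-representation SNPs. The management questions are (i) how inbred and
how genetically connected the sites are, (ii) how many breeders each site
retains, and (iii) how many outbred migrants would be needed to rescue the
most inbred sites. The package's own contribution is the end-to-end,
simulation-validated pipeline; every step is a function with tests against a
simulator whose truth is known.

## Data model and quality control

Genotypes are biallelic dosages (0/1/2 copies of the minor allele, `NA`
missing) with per-locus metadata (tag, map position, mean read depth, tag
reproducibility) and per-sample metadata (site, river distance in km,
capture date, total length). QC follows the conventional chain for DArT-style
data, in this fixed order: mean depth in [6, 50]; reproducibility >= 0.95
(strict `<` drops — the threshold's inclusivity is a convention we document
rather than a biological constant); locus missingness <= 10%; individual
missingness <= 20%; removal of loci whose heterozygote fraction
significantly exceeds 0.5 (exact binomial upper tail, Bonferroni-corrected
across tested loci by default — the correction used by the published filter
is not standardised, and Bonferroni is the conservative choice for an
artefact screen); one random SNP per sequencing tag (seeded); an optional
minor-allele-count >= 2 filter used only for sibship panels, where
singletons carry no pairwise information. Physical linkage is handled by LD
decay against map distance (background = mean r² of cross-chromosome pairs)
and thinning to one random locus per 50 kb window, with windows anchored at
position 0 — the simplest rule that is reproducible under a seed.

## Heterozygosity and effective inbreeding

Individual heterozygosity (PHt) is the fraction of an individual's called
loci that are heterozygous. Group summaries report per-locus Ho (heterozygote
fraction), He = 2p(1−p), and FIS = 1 − Ho/He averaged over loci with
He > 0, always on a caller-supplied fixed locus panel so groups are
comparable. He deliberately omits the 2n/(2n−1) small-sample correction:
group-level effective-inbreeding arithmetic, Fe = 1 − He_focal/He_reference,
is then exactly reproducible from printed He tables; the corrected variant
is available behind a flag. Fe is reported relative to an explicit outbred
reference (a large, diverse population; in the analysis scripts, the most
diverse site when no external reference is supplied). Fe(0, x) = 1, Fe is
strictly decreasing in the focal He, and negative values (focal more diverse
than the reference) are returned as-is with a warning rather than truncated.

## LD-based effective size

The central estimator is the single-sample linkage-disequilibrium method.
For each locus pair, the Burrows composite disequilibrium is computed from
unphased dosages over the jointly called individuals:
Δ = (1/S)·Σ x·y/2 − 2·p·q, r² = Δ²/(p(1−p)q(1−q)). `pair_r2()` reports this
plain descriptive form (identical dosage vectors give r² = 1 exactly).
Within `estimate_ne()` loci are first screened at Pcrit (default 0.01,
minor-allele frequency within the analysis group, mirroring per-group
screening semantics), pairs with fewer than 10 joint calls are dropped, and
the S_pair-weighted mean r² is rescaled by (S/(S−1))² — the standard
small-sample correction of the composite Δ — because the finite-sample
expectation subtracted next, E[r²] = 1/S + 3.19/S² (S >= 30) or
0.0018 + 0.907/S + 4.44/S² (S < 30) with S the weighted harmonic-mean joint
call count, is calibrated to the corrected statistic. We verified this on
iid Hardy–Weinberg genotypes: the plain mean r² sits at ((S−1)/S)² of the
expectation, and without the rescaling the estimator runs ~40–60% high. The
drift signal r²_drift = corrected mean − E[r²] is inverted through
N̂ = (1/3 + sqrt(1/9 − 2.76·r²_drift))/(2·r²_drift) for S >= 30 (analogous
constants 0.308/2.08 below), with non-positive signal mapping to infinity:
the estimator refuses to report a finite size without drift LD, which the
tests confirm on samples from an effectively infinite population.

Confidence intervals use a delete-one-individual jackknife on r²_drift
(normal-theory 95% interval truncated at zero, transformed through the drift
relation), chosen over percentile intervals for stability in the small
groups monitoring produces; such LD-based CIs are known to be somewhat
anticonservative, and the coverage test asserts only >= 60% at nominal 95%.
Pair weighting by S_pair and the exact weighting of the reference
implementation are not reproduced — the contract is parameter recovery
within tolerance (median within [70, 140] at true Ne = 100, S = 60, 2000
SNPs), not decimal agreement, because management decisions here are made at
the precision of "3 versus 128 breeders".

Raw single-cohort estimates (N̂b) mix the per-cycle number of breeders with
the per-generation effective size in iteroparous species. The adjustment
uses the two-trait life-history regression Nb/Ne = 0.485 + 0.758·log10(AL/α)
— base-10, the published regression's scale (AL = 23 y, α = 3 y gives
1.156) — then N̂b_adj = N̂b/(1.26 − 0.323·Nb/Ne) and N̂e_adj = N̂b_adj/(Nb/Ne).
Integer presentation rounds half up at the reporting layer only.

## Genetic rescue calculators

To reduce a site's effective inbreeding to a target (default Fe < 0.1, half
the level above which severe inbreeding depression is commonly observed),
the required fraction of breeders that must be outbred migrants is
f = 1 − sqrt(Fe_target/Fe_site), floored at zero, and the migrant count is
Nm = f·Nb/(1 − f). Both are implemented exactly as printed formulas;
monotonicity in both arguments is tested. Published worked examples of these
formulas are typically computed from rounded intermediate inputs and need
not be exactly reproducible from table values; the package keeps full
precision internally.

## Structure, ancestry, kinship

PCA runs on mean-imputed, column-centred dosages (the standard shortcut for
genotype PCoA), with component signs fixed by the largest-magnitude loading
so results are deterministic. Ancestry classification orients one axis by
reference individuals of known source and local origin and labels the
central band of the gap (default 50%) admixed — where F1 offspring of one
local and one source parent fall. The defaults are F1-oriented; backcrosses
are outside the method's reliable reach. Pairwise FST is Weir–Cockerham
(1984), ratio-of-sums across loci, negative estimates floored at zero in the
reported matrix with raw values retained. The Mantel test uses Pearson
correlation of upper triangles with joint row/column permutations and a
two-sided permutation p-value, (#{|r*| >= |r|} + 1)/(n_perm + 1), default
999 permutations.

Identity and sibship use a deliberate surrogate for full-likelihood sibship
reconstruction: symmetrized Queller–Goodnight moment relatedness with
dataset allele frequencies (computed including relatives — the bias is
acceptable at the validation tolerances), genotype mismatch rate for
duplicate detection (threshold 0.02, far above a 1% genotyping error rate
and far below full-sib mismatch), and single-linkage clustering of pairs
with r >= 0.35 (midway between the full-sib 0.5 and half-sib 0.25
expectations) into families. Pedigree simulations validate all three:
full-sib means in [0.4, 0.6], unrelated means within ±0.1, planted families
recovered and never merged at the default thresholds. Replicate-consensus
acceptance (as used with stochastic likelihood methods) has no analogue in
this deterministic surrogate.

## Growth and inbreeding depression

Length-based ageing uses fixed bins (YOY < 90 mm; 1–2 y up to 210 mm in the
wide-growth survey year, 180 mm after; 2–3 y to 270 mm; adults above
271 mm). Lengths in the two unassigned gaps (90–100 mm, 270–271 mm) go to
the nearer bin edge by default; a strict policy that leaves them unassigned
is available. Cohorts subtract the class age from the capture year, minus
one more when capture precedes the spawning month (default November,
austral spring). The growth curve is the Gompertz form
L(t) = b1·exp(−b2·exp(−b3·t)) — the standard fish-growth parameterisation
consistent with initial values (200, 0.5, 0.3) — fitted by
Levenberg–Marquardt least squares; ages enter as class midpoints (0.5, 1.5,
2.5 y) since exact ages are unknown. Size-at-age residuals feed a nested
model ladder (site; cohort; site + cohort; + interaction, skipped when
design cells are empty), compared by F-tests at α = 0.05; individual
heterozygosity is then added to the best structural model, and a significant
positive PHt term is the inbreeding-depression verdict. Null and power
calibration are part of the acceptance tests (false-positive rate <= 10% at
α = 0.05; power >= 80% at the simulated effect size).

## The simulator: what it emulates and what it does not

`simulate_metapop()` is a discrete-generation Wright–Fisher metapopulation:
unlinked neutral biallelic loci with shared ancestral frequencies from a
Beta(0.5, 0.5) truncated to [0.05, 0.95]; per-deme constant sizes; per-
offspring parent demes drawn from a row-stochastic migration matrix
(supporting asymmetric, barrier-broken stepping-stone patterns); Mendelian
transmission; an optional shared bottleneck "stem" before the split (so all
demes inherit correlated diversity loss); an optional large source
population evolved from the same ancestor; translocations that move source
individuals into a deme's breeding pool; and cohort sampling. Sampled
individuals are drawn as additional offspring of the parent pool rather
than as a subset of the standing deme: a monitored cohort is far larger
than the breeding population, and subsampling the standing generation
(e.g. 60 of 100) double-counts drift and sampling LD, which we measured as
a ~60% upward bias in N̂e. Its core oracles are closed forms: He decays as
(1 − 1/(2Ne)) per generation, FST between isolated demes accumulates as
1 − (1 − 1/(2Ne))^t, and allele-frequency trajectories are martingales.

`make_study_like()` freezes one study-like configuration: nine linearly
ordered demes (true Ne 8–130, small upstream, large downstream), stepping-
stone migration (rates 0.015–0.03) interrupted by barriers, a 22-generation
shared bottleneck at size 50 giving a source/local diversity ratio of about
1.4, translocations of 3 + 3 source fish into the largest downstream deme in
the last two generations (yielding a few F1 juveniles in the final cohorts),
and cohort samples of ~300 fish over six birth years plus adults, with
Gompertz-generated lengths (b1 = 400 mm, b2 = 2.3, b3 = 0.65, residual SD
8 mm, cohort offsets SD 6 mm) so the ageing rules and growth models close
the loop. Problem sizes in the test-suite properties (e.g. 1000–2000 loci,
20 replicates, 15–30 generations) are the package's chosen validation
scales: large enough for the closed-form oracles to bind, small enough to
run routinely.

Features of real data the simulator does not emulate — and which passing
tests therefore do not certify: overlapping generations and age structure
(the Nb/Ne distinction is handled analytically, not demographically),
census sizes larger than Ne, selection, mutation, physical linkage in the
main simulator (a Markov-chain linked-block generator exists solely to
exercise the LD-decay screen), genotyping error outside the kinship tests,
and locus ascertainment. Deme census equals Ne by construction, so
per-cohort sample sizes at tiny-Nb sites are realistic only because cohorts
are sampled as fresh offspring.

## Numerical and degenerate-input choices

Monomorphic-within-group loci are silently excluded from LD and FIS (they
carry no information); groups of clones return a flagged degenerate
estimate rather than an error; infinite N̂b propagates through the
adjustment; jackknife intervals whose lower drift bound reaches zero report
an infinite upper limit; the PCA of a constant matrix, a Mantel test on a
constant matrix, and a heterozygosity-distance model on constant distances
are all refused with explicit errors; empty interaction cells skip the
interaction model with a message. All randomised steps (one-per-tag,
thinning, permutations, simulation) take explicit seeds and are reproducible
bit-for-bit.

## Known limitations

The Ne estimator is validated for recovery and bias direction, not decimal
agreement with any particular published implementation; its CIs are
anticonservative at small sizes. The kinship surrogate cannot resolve
half-sibs and inherits the allele-frequency bias of moment estimators in
relative-rich samples. The ancestry classifier assumes the reference groups
separate cleanly on one PCA axis. The rescue calculators treat Fe and Nb as
known; in practice both carry wide uncertainty, and the package reports
them with full precision so that uncertainty can be propagated externally.
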