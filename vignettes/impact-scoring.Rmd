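---
title: "Evolution-informed impact scoring for single nucleotide variants"
author: "snvimpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution-informed impact scoring for single nucleotide variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`snvimpact` scores the functional impact of a single nucleotide variant
as the probability that it belongs to a class of *simulated* de novo
substitutions rather than to a class of *derived*, nearly fixed variants.
The idea, borrowed from the CADD family of predictors, is that variants
which rose to (near) fixation in natural populations have survived
purifying selection and are therefore depleted of deleterious effects,
while substitutions drawn fresh from the mutation process carry the full,
unselected spectrum of impact. A logistic regression trained to separate
the two classes on a rich annotation vector then transfers to arbitrary
variants: its probability of the simulated class is the impact score,
between 0 (neutral-like) and 1 (impact-like).

Assumptions worth keeping in mind:

- The proxy labels are noisy by construction. Some derived variants are
  mildly deleterious (drift), and many simulated variants are neutral.
  The classifier's ceiling on held-out proxy labels is therefore well
  below 1, and accuracy on the proxy task understates the quality of the
  *ranking* the scores induce.
- The score is a class probability under this particular training
  distribution, not a calibrated probability of phenotypic effect.
- Only SNVs are modeled — no indels, MNVs or structural variants.

## Training-set construction

**Derived variants.** Every position where both the reference and the
reconstructed ancestral base are defined and differ is a candidate; the
reference allele is the derived allele. The derived-allele population
frequency is computed as one minus the sum of alternate-allele
frequencies at the site, with sites absent from the population records
treated as fixed (frequency 1). Candidates below the threshold (default
0.9) are removed. The stored `alt` of a derived variant is the ancestral
allele, so both classes are represented as substitutions on the
reference genome.

**Mutation rates.** For every chromosome, ordered base pair and CpG
context, the rate is the count of positions with ancestral base `b1` and
reference base `b2` divided by the count of positions with ancestral
base `b1`, in that context. Zero denominators give undefined (NA) rates
that the simulator refuses to consume.

**CpG context follows the mutating sequence.** CpG-elevated mutation is
a property of the *source* base: a methylated ancestral CpG cytosine
deaminates toward T. The package therefore conditions rate estimation on
the ancestral dinucleotide (a C or G whose deciding ancestral neighbor
is unreconstructed has indeterminate context and is excluded), while the
de novo simulator and the per-variant CpG annotation condition on the
reference dinucleotide, because there the reference is the sequence
being mutated or annotated. A single reference-strand convention for
everything looks simpler but is not identifiable: at a reference-CpG
position the reference base is C or G *by definition*, so an
ancestor-to-reference comparison conditioned on reference context can
never observe the elevated C→T CpG transition — the substitution that
motivates the stratification in the first place.

**Simulation.** Over all positions carrying a reconstructed ancestral
base, every (position, alt) pair with alt ≠ ref is included
independently with probability proportional to
rate[ref → alt | context], calibrated to yield slightly more than the
requested count, then uniformly trimmed to the exact target. This
site-wise Bernoulli thinning mimics the mutation process, guarantees
each pair occurs at most once, and keeps expected substitution-type
counts exactly proportional to the configured rates — which a sequential
weighted draw without replacement would not (high-rate categories
deplete). An `exclusions` argument removes known segregating sites; a
`mutateFrom = "ancestor"` flag mutates the ancestral base instead of the
reference for users who prefer that reading. The simulated set is
randomly trimmed to match the derived count, so class sizes are exactly
balanced.

## Annotation and features

The consequence classifier assigns one of 14 categories with the fixed
severity order CS > SG > SL > NS > SN > S > U5 > U3 > NC > I > UP > DN >
IG (O = other as fallback); with multiple overlapping transcripts the
most severe call wins. Canonical splice covers the first and last two
intron bases, the splice region extends 8 bases into the intron and 3
into the exon, and upstream/downstream extend 500 bp — the same flank
the gene-window profiles use, keeping the annotator self-consistent.
Coding calls translate reference and mutant codons with the standard
genetic code and carry CDS/protein positions and their relative forms;
the Grantham distance is attached to non-synonymous calls from the
published 1974 matrix shipped as plain-text data (anchors: identity 0,
Leu–Ile 5, Cys–Trp 215).

A feature specification (YAML) declares base annotations — numeric,
indicator or categorical with their categories — an imputation default
per base, and combination rules pairing a categorical with a numeric
base. Expansion one-hot encodes categoricals, emits one column per
category for each combination (indicator × value), and replaces missing
values by the declared default, optionally with a missingness indicator
column. Defaults are 0 for conservation, shape and positional tracks and
the intergenic category for the consequence; amino-acid categoricals
have no default and encode missing (non-coding) rows as all zeros. The
shipped layout expands 38 base annotations to 110 base columns and 581
combination columns (Consequence × 25 numerics, oAA × 5, nAA × 6) — 691
in total, with composite names in the `SN_PhyloP` / `nAA_*_Grantham`
style. The combination inventory is configuration, not code: the
shipped spec transcribes the documented composite-name families and can
be revised without touching the package. A checksum of the spec travels with every
trained model so scoring refuses a mismatched layout.

Features are scaled by their *population* (n-denominator) standard
deviation computed on the training rows only, without centering — new
variants are always divided by the training SDs. Constant columns are
recorded and dropped from the model's view.

## The classifier

Training minimizes the summed negative log-likelihood plus (λ/2)·‖w‖²
with the intercept unpenalized, by Newton/IRLS with step halving
whenever a step fails to decrease the objective; convergence is a
gradient norm below 1e-8, capped at 100 iterations. The penalty sits on
the summed (not mean) likelihood, so a given λ means less regularization
on larger datasets; the selected constant is only meaningful relative to
this convention, which is pinned explicitly because logistic-regression
implementations normalize differently. The intercept is left unpenalized so the
class balance of the training set does not leak into the scores through
shrinkage.

λ is selected from {0.01, 0.1, 1, 10, 100} by five repeated random 90/10
sub-splits of the training rows (the same splits for every candidate),
taking the argmax of mean validation accuracy with ties broken toward
the larger penalty for stability. Accuracy uses the fixed 0.5
probability threshold. Evaluation on the held-out 10% reports this
accuracy and a rank-based ROC-AUC with ties counted one half. Feature
weights are reported ranked by magnitude; their sign reflects the
feature encoding and carries no biological directionality.

The score orientation is pinned by a unit test: derived = label 1, so
the impact score is 1 − P(y = 1). A silent flip would be the most
dangerous bug this package could have.

## Downstream analyses

- **Codon positions:** scores of all three alternates are reduced to a
  per-position minimum (a conservative estimate), grouped by position
  within the codon, restricted to single-transcript sense-strand genes
  (multi-transcript genes are excluded to avoid interaction effects).
  Pairwise two-sided Mann–Whitney U tests use exact enumeration for
  groups of at most 8 without ties and the normal approximation with
  continuity and tie correction otherwise. Bonferroni correction
  multiplies by the number of tests in the invocation: 3 genome-wide;
  per-gene results carry both the within-gene factor 3 and the global
  factor 3 × genes, since "Bonferroni corrected" can mean either family
  in practice. The fraction of genes significant per pair uses the
  global family by default.
- **AF bins:** left-open right-closed bins of width 0.025 on the
  non-reference allele frequency, first bin (0, 0.025]; rare alleles are
  AF < 0.05 (strict), common alleles the complement.
- **Thresholds:** strictly above 0.6, inclusive at 0.8, matching the
  wording of the conventions they implement; both comparators are
  exposed.
- **Gene windows:** per-position arithmetic mean of the three alternate
  scores across the gene ± 500 bp, clipped at chromosome ends with a
  warning; observed natural variants can be flagged on the profile.
- **Candidate re-ranking:** candidates are ordered by score descending
  with association p-value as tie-break, and the Spearman correlation
  between the two rankings is reported.

## The synthetic fixture

`makeFullFixture()` generates a complete input bundle with known truth.
The construction is ancestor-first: a random template sequence (GC
fraction 0.42, a fly-like composition) is taken as the ancestor, every
position is mutated forward with the configured CpG-stratified rates
(conditioned on the ancestral dinucleotide), and the result becomes the
reference; this makes the estimable conditional rates equal the
configured ones exactly in expectation, so estimator recovery can be
tested against binomial standard errors with no generator bias. Gene
models (single-transcript, sense-strand, intron-containing, valid
start/stop and frame) are inserted into the reference afterwards and
their footprint is masked out of the ancestor map, since those bases no
longer reflect the divergence process. Each position is then observed
with the configured coverage (gaps elsewhere), and the bundle is
serialized as FASTA, two-row MAF, population VCF (ancestral alleles
segregating at known residual frequencies, with a designated fraction
failing the AF filter), GFF3, a per-base track and interval BEDs.

The planted class signal is a conservation-like numeric track valued
N(effect, σ²) at simulated-variant positions and N(0, σ²) elsewhere,
giving the closed-form oracle AUC Φ(effect/(σ√2)) ≈ 0.921 at the default
effect 2, σ 1. Simulated variants are excluded from all three alternate
alleles at derived positions so the two classes occupy disjoint
positions and the oracle applies exactly.

Default scale: 100 kb, 20 genes, ancestral coverage 0.30 with transition
rate 0.05, transversion 0.0125 and CpG factor 2 — divergence chosen to
yield roughly 2,000 derived variants, matched by 2,000 trimmed simulated
variants; large enough for stable statistics, small enough that fixture
construction takes well under a minute and the full test suite a few
minutes. Rate-recovery checks use a separate 100 kb pair at full
coverage with transition 0.008, transversion 0.002 and CpG factor 10;
the simulator goodness-of-fit check draws 10,000 variants.

What the fixture does **not** emulate: linkage and demography (sites are
independent), selection (the planted signal is statistical, not
mechanistic), realistic annotation correlation structure (one
informative track plus uninformative intervals), multi-species alignment
complexity (a two-row MAF), or genome-scale data volume. Green tests on
the fixture therefore validate the machinery — estimators, solver,
contracts, orientations — not biological performance on real data.

## Numerical and degenerate-input choices

Every stochastic operation takes an explicit seed and derives
per-stage sub-seeds deterministically; there is no hidden global RNG
state, and regeneration with the same seed is byte-identical. Undefined
rates refuse simulation rather than defaulting to zero. Positions with
reference N or unreconstructed ancestor are excluded from calling and
simulation denominators. Score tables are written sorted by
(chromosome, position, alt) with six decimals so reruns are
byte-comparable; all coordinates exposed anywhere are 1-based and
inclusive, with 0-based half-open sources (BED, bedGraph, MAF starts)
converted at the I/O boundary and nowhere else. Applying the SD scaler
twice is refused via a scaled flag. Overlapping alignment blocks resolve
first-wins with a logged conflict count; duplicated ancestor rows within
a block (possible paralogy) use the first row and warn rather than
guessing.

## Known limitations

- The consequence classifier is a compact reimplementation, not a VEP
  replacement: regulatory-build categories, NMD, phased effects and
  transcript flags are out of scope; "O" absorbs what the 14 categories
  do not cover.
- Conservation and DNA-shape tracks are consumed, never computed.
- Penalty normalization and intercept handling vary across
  logistic-regression implementations; both are pinned here, and models
  trained with other stacks may differ numerically for exactly that
  reason.
- Per-chromosome rates are global, not windowed; local mutation-rate
  variation is not modeled.
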