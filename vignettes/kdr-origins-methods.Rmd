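---
title: "Counting the origins of kdr-type resistance: models and methods"
author: "kdrorigins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting the origins of kdr-type resistance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Pyrethroid insecticides act on the voltage-sensitive sodium channel
(*Vssc*).  In house flies, three target-site mutations confer resistance:
L1014F (*kdr*), L1014H (*kdr-his*) and M918T+L1014F (*super-kdr*).  A
recurring question for any resistance allele is whether it arose once and
spread, or arose repeatedly in separate populations — the answer changes
how resistance management should think about gene flow versus local
mutation.

The analysis this package implements answers that question from sequence
data.  The fragment of interest spans codon 1014 and the intron that
begins three bases downstream of it.  The intron is effectively neutral
and highly variable, so it records the genealogical background on which
each resistance mutation arose.  If all resistant alleles descended from a
single mutational event, resistant haplotypes should form a single clade
of the haplotype genealogy; if resistance arose repeatedly, resistant
haplotypes should be scattered among susceptible ones.

`kdrorigins` implements the full inference chain:

1. **Haplotype classification** — deduce the amino acids at codons
   918/1014, classify each allele, group haplotypes by exact intron
   identity, and name them in discovery order (`kdr1…`, `kdr-his1…`,
   `super-kdr1…`, `v1…` for susceptible).
2. **Model selection and likelihood** — reversible nucleotide models
   (JC69, K80, HKY85, GTR, each optionally +Γ) scored by the pruning
   algorithm, selected by BIC.
3. **Tree search** — replicated NNI hill-climbing maximum-likelihood
   search, with or without a monophyly constraint, plus nonparametric
   bootstrap support.
4. **The single-origin test** — a parametric-bootstrap (SOWH-style)
   comparison of the best tree against the best tree in which resistant
   alleles are constrained to be monophyletic.
5. **Origin counting** — maximal single-class clades and parsimony gain
   counts on a rooted display tree, with root-placement sensitivity.
6. **Synthetic data** — a generator that plants a known number of origins
   on a simulated genealogy, so every stage can be validated end to end.

## The test statistic

Let $\ell_1$ be the maximized log-likelihood over all tree topologies and
$\ell_0$ the maximum over topologies in which the resistant haplotypes
form one clade (a single branch separates them from everything else, as a
bipartition of the unrooted tree).  The statistic is

$$\delta = \ell_1 - \ell_0 \ge 0 .$$

Because the constrained space is a subset of the unconstrained space,
$\delta$ is nonnegative by construction.  Its null distribution is
obtained parametrically: model parameters and branch lengths are
re-estimated on the constrained tree, `n_reps` replicate alignments of the
same length are simulated on it, and both searches are re-run on every
replicate.  The p-value is the fraction of replicate $\delta_i$ that reach
the observed $\delta$, with ties counting against rejection (conservative)
and a zero count reported as the bound `p < 1/n_reps`, alongside the
$(r+1)/(n+1)$ corrected value.

Two implementation details matter for honesty of the test.  First, both
searches are heuristic; the constrained optimum is itself a valid member
of the unconstrained space, so `sowh_test()` pools it into the
unconstrained result, which removes spurious negative deltas from search
noise.  Second, replicate deltas that still come out marginally negative
are clamped to zero, which can only enlarge the p-value.  The same search
effort is used on the observed data and on every replicate, so search
imperfection affects numerator and denominator symmetrically.

## Substitution models and likelihood

State order is A, C, G, T throughout.  The rate matrix is
$Q_{ij} = s_{ij}\pi_j$ with family-specific exchangeabilities $s$,
rescaled so branch lengths are expected substitutions per site.
Transition matrices come from the spectral decomposition of the
$\pi$-symmetrised $Q$, which is exact for reversible families.  Rate
heterogeneity uses the standard equal-weight discrete-gamma approximation
(4 categories by default; category rates from `phangorn::discrete.gamma`,
normalized to mean 1).

Site likelihoods are computed by the pruning algorithm in compiled code,
with per-pattern rescaling so alignments of a hundred or more taxa do not
underflow.  Gaps and IUPAC ambiguity codes are missing data: the tip
partial likelihood is 1 over every compatible state.  Site patterns are
compressed before scoring.  The suite verifies the implementation against
exhaustive interior-state enumeration on all 4- and 5-taxon topologies and
against an independent implementation (`phangorn::pml`).

Model fitting choices, where standard practice varies:

* **Base frequencies** are empirical with a pseudocount of 1 per state,
  not maximized — a common default; it deviates slightly from full ML and
  is documented as such.
* **BIC** uses $-2\ell + k\log n$ with $n$ the number of *included* sites
  (mask-aware) and $k$ counting branch lengths plus family parameters
  (κ: 1; GTR exchangeabilities: 5; non-uniform frequencies: 3; γ shape: 1).
  Ties break toward fewer parameters.
* The candidate set is the 8-model grid {JC69, K80, HKY85, GTR} × {−, +Γ(4)},
  which spans the relevant complexity axis without reproducing an entire
  model-test battery.
* Candidates are fitted on one fixed starting topology (neighbor joining
  on JC distances), the usual model-selection practice.

## Branch lengths and tree search

Branch lengths are optimized one at a time by bounded Brent search on
$[10^{-8}, 10]$, sweeping over branches until the log-likelihood improves
by less than the tolerance (default $10^{-6}$, at most 20–30 sweeps).
Each branch is optimized against fully up-to-date partials, so the sweep
is exact coordinate ascent and the log-likelihood never decreases — a
property the tests assert.

The topology search is replicated hill-climbing: replicate 1 starts from
the NJ tree, later replicates from randomly NNI-perturbed copies
(`max(2, n/4)` random moves).  Each round evaluates every internal edge's
two NNI rearrangements by re-optimizing the central branch against cached
partials, applies the best non-conflicting improving set simultaneously
(falling back to the single best move if the joint application fails to
improve), re-optimizes branch lengths, and stops when no rearrangement
improves.  Equal-likelihood ties break toward the lexicographically
smallest canonical Newick string, making results reproducible.

A monophyly constraint is enforced by rejection: the starting tree is
built constraint-compatible (an average-linkage subtree for the
constrained taxa grafted onto an NJ backbone of the rest), and a
rearrangement is accepted only if the constraint bipartition survives.
Because an NNI changes exactly one bipartition, the check is local and
exact.  For a single monophyly constraint this is provably sound: every
accepted state satisfies the constraint, and within-clade and
outside-clade rearrangements remain fully explorable.

Bootstrap support resamples included sites with replacement, re-runs the
search with a small replicate count per pseudo-replicate (2, mirroring the
usual bootstrap economy), and reports the percentage of replicates
containing each focal bipartition.  Display output suppresses values of
50% and below, the conventional reporting threshold.  Midpoint rooting is
used for display and origin counting only; the likelihood of the unrooted
tree is invariant to root placement under reversible models, which the
tests also check.

## Origin counting

On a rooted display tree with tip classes, the package reports, per
resistance class:

* **clades** — the number of maximal subtrees whose tips all carry the
  class (the quantity usually read off a published tree);
* **min_gains** — the minimum number of susceptible→resistant transitions
  when the ancestral state (on a stem above the root) is susceptible and
  reversion is not allowed;
* **parsimony_changes** — the unconstrained Fitch count (gains and losses
  both allowed, free root);
* **clades_min/max_over_roots** — the range of the clade count across
  every possible root placement.  Midpoint rooting is a display
  convention, so the report makes root sensitivity explicit rather than
  hiding it.

All three counters are validated against exhaustive-labeling and
subset-scan oracles on every tree up to 8 tips.

The sequential-evolution check (`derive_sequential_pairs`) pairs each
super-kdr haplotype with kdr haplotypes sharing its exact intron — the
signature expected if M918T arose on an existing L1014F background.  The
package's compact reference fixture reproduces the published 18-haplotype
sharing structure (8 intron columns; every super-kdr paired with a kdr);
its intron strings are synthetic, only the sharing pattern and codon
states are real.

## The synthetic-data generator

The generator is the package's study-condition definition, not a tuning
knob.  Defaults:

| parameter | default | meaning |
|---|---|---|
| `n_taxa` | 64 | distinct haplotype sequences |
| `n_sites` / `intron_len` | 350 / 250 | fragment geometry (~350 bp with the adjacent intron dominating) |
| tree | Yule, height 0.1 | neutral intra-specific genealogy; height in substitutions/site at the intron rate |
| `k_kdr, k_kdrhis, k_superkdr` | 2, 3, 2 | planted independent origins, matching the multiple-origin structure the analysis targets |
| `exon_rate` | 0.1 | exon/intron rate ratio (purifying selection on coding sites) |
| `ambiguous_frac` | 0.1 | intron columns flagged alignment-ambiguous (the "strict" mask) |
| model | HKY85, π = (.3,.2,.2,.3), κ = 3 | AT-rich, transition-biased insect nuclear sequence |

Origins are branches sampled subject to the biology: kdr and kdr-his
origin subtrees are disjoint, each super-kdr origin is nested strictly
inside a kdr clade and leaves at least one plain-kdr tip there, and at
least one susceptible tip remains.  The realized per-class clade counts on
the true tree are required to equal the request, so "3 planted origins"
is guaranteed to mean 3 independent clades.  Codon states at 918/1014 are
deterministic given the class, so classification truth is unambiguous.

What the generator deliberately does **not** emulate: recombination
within the fragment, heterozygous reads and cloning artifacts, indel
evolution (alignment uncertainty is mimicked by column-wise ambiguity
masking, not by actual misalignment), coalescent population structure
(Yule genealogies keep the machinery test focused on inference, not
demography), and synonymous variation at the focal codons.  Passing tests
therefore validate the inference machinery under clean assumptions; they
do not certify behavior under recombination or severe misalignment.

## Validation problem sizes

The test suite validates the statistical behavior at desk scale, with
sizes chosen so the whole suite runs in minutes:

* likelihood oracle: all 4–5-taxon topologies × 30 sites, `1e-8` agreement;
* search oracle: 20 seeded runs at 4–6 taxa against exhaustive topology
  scoring;
* δ nonnegativity: 100 random 10-taxon data sets;
* type-I error: 100 Monte-Carlo runs of single-origin scenarios at
  32 taxa × 300 sites with 50 parametric-bootstrap replicates each,
  rejection rate at α = 0.05 required to fall in [0.01, 0.12] (the test is
  conservative by construction, so rates below nominal are expected);
* power: 20 runs of a 3-origin scenario (tree height 0.2, each origin
  clade ≥ 3 tips) with 20 replicates each, requiring the bound
  `p < 1/n_reps` in ≥ 90% of runs;
* parameter recovery: κ and γ-shape within 15% relative error in ≥ 90% of
  20 replicates at 16 taxa × 5000 sites.

## Numerical choices and degenerate inputs

* Branch lengths live in $[10^{-8}, 10]$; identical sequences drive
  estimates to the lower bound rather than zero.
* Brent tolerance scales with the current branch length
  ($10^{-7} + 3\times10^{-4}t$); a window around the current value is
  searched first and widened to the full bounds when the optimum presses
  against the window edge; a downhill result is never accepted.
* Per-pattern likelihood rescaling triggers below $10^{-120}$.
* Two-taxon trees bypass the tree engine (closed-form single-branch
  optimization); three-taxon trees have a single topology.
* Zero-diameter trees are midpoint-rooted arbitrarily with a warning and
  a flag.
* A sequence with unresolvable ambiguity at 918/1014 is classified
  `other` and reported, never guessed.
* Catalog naming depends on global discovery order, so the catalog is an
  explicit input/output and collisions across batches are resolved by
  reusing the matching (intron, codon-state) entry.

## Known limitations

* NNI hill-climbing explores less than SPR/TBR-based searches; the
  replicate/perturbation scheme mitigates but cannot eliminate local
  optima on hard landscapes.  The exhaustive-search acceptance check
  bounds this risk at small sizes only.
* The gains-only counter assumes irreversibility of resistance; the
  unconstrained Fitch count is reported alongside precisely because that
  assumption is contestable.
* Base frequencies are empirical rather than ML; BIC values are therefore
  conditional on that convention.
* The parametric bootstrap inherits the usual SOWH sensitivity to model
  misspecification: if the generating model fitted on the constrained
  tree is badly wrong, the null distribution of δ is too.
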