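---
title: "Modelling ORF decay and pseudogene evolution with orfdecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ORF decay and pseudogene evolution with orfdecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When a gene loses its function, selection on its protein sequence stops and
the open reading frame (ORF) starts to decay: frameshifting insertions and
deletions and premature stop codons accumulate at the neutral rate. A family
of receptor paralogs sequenced across a mammalian phylogeny therefore
carries two complementary signals of gene loss. First, the lesions
themselves: each disrupting mutation arose once on some branch of the
species tree and was inherited by every descendant. Second, the substitution
pattern: lineages that still encode a functional protein show a
nonsynonymous/synonymous rate ratio ω = dN/dS well below one (purifying
selection), while lineages that were already pseudogenes drift at ω = 1.

`orfdecay` turns this reasoning into a tested pipeline:

1. **Lesion scanning** (`detect_disruptions`, `scan_alignment`): find
   frameshifting indels and premature stops per sequence, in the
   coordinates of an intact reference ortholog.
2. **Dollo mapping and branch classification** (`map_events`,
   `classify_branches`): place each lesion once on the tree and separate
   branches into `intact`, founding-pseudogene (`psi2`) and
   inherited-pseudogene (`psi1`) classes.
3. **Codon-model ML** (`fit_codon_model` and friends): Goldman–Yang (GY94)
   likelihoods with branch models, site models M0/M1a/M2a/M3/M7/M8,
   branch-site model A and the free-ratio model, compared by
   likelihood-ratio tests.
4. **Neutral disruption rate** (`neutral_disruption_rate`, `prob_intact`):
   how often a dead ORF acquires a new lesion, per million years or per
   synonymous substitution, with Poisson uncertainty.
5. **Neutral decay simulation** (`simulate_decay`): the probability
   `p_dis(k)` that at most `k` disrupting mutations accumulate under
   neutral evolution over a given exposure — the forward-simulation
   counterpart of step 4.
6. **Correlated loss** (`categorize_branch_pairs`, `fisher_exact_2x2`,
   `spearman_branch_omega`): do two paralogs lose function on the same
   branches, and do their per-branch ω values co-vary?

A synthetic generator (`sim_scenario`, `simulate_codon_alignment`,
`inject_pseudogenization`) produces alignments with known branch classes,
site classes and lesions, so every stage is testable without external
data. `run_pipeline` chains all stages and writes tab-separated outputs
plus a reproducibility manifest.

## The codon model

The GY94 rate matrix over the 61 sense codons has entries

q_ij = 0 for changes at more than one nucleotide position, and otherwise
q_ij ∝ π_j · κ^[transition] · ω^[nonsynonymous],

with stationary codon frequencies π (F3X4 by default: the product of
empirical position-specific nucleotide frequencies, stops excluded,
renormalised), transition/transversion ratio κ and selection parameter ω.
Likelihoods are computed by Felsenstein pruning; the model is reversible,
so the likelihood is invariant to the root position (checked in the tests
against exhaustive enumeration over ancestral states and against
rerooting).

**Rate normalisation.** Branch models (including free-ratio) normalise the
generator of each branch class to one expected substitution per codon
site, so a branch length is always "substitutions per codon on that
branch". Site mixtures (M1a–M8, branch-site A) instead share a *single*
normalisation per edge — the proportion-weighted mean rate over classes —
so a branch length is the mixture-average substitution count and
high-ω classes evolve proportionally faster. This is the standard
site-model convention; normalising each class separately would silently
remove the rate contrast between classes and destroy most of the power of
the M7-vs-M8 comparison (we verified exactly this failure mode during
development, which is why the convention is stated so explicitly here).
The synthetic generator uses the same convention.

**Parameters and defaults.**

| parameter | default | meaning |
|---|---|---|
| κ | estimated (init 2) | transition/transversion rate ratio |
| ω bounds | [1e-6, 999] | estimates at the bounds are reported as dN = 0 / dS = 0 sentinels |
| π | `"F3X4"` | codon frequencies; `"equal"` or a numeric vector as alternatives |
| starts | ω = 0.5 and ω = 2 | two independent optimisations; both end points recorded |
| M7/M8 `ncat` | 10 | equal-probability beta classes, each at its class median |
| branch lengths | estimated jointly | `estimate_branch_lengths = FALSE` keeps the input tree |

Optimisation is BFGS on log/logit-transformed parameters
(`stats::optim`), proportions through an additive log-ratio transform,
ω ≥ 1 classes through 1 + exp(·) with an upper clamp at 999. A fit that
converges from neither start is flagged with a warning, never silently
returned. Free-ratio fits merge the two root-child edges into one ω class:
under a reversible model only their combined path is identifiable (the
pulley principle), and a separate ω per root edge would sit on a
likelihood ridge.

**Sentinels.** A branch with no synonymous change drives ω̂ to the upper
bound; it is reported as `flag = "ds_zero"` with estimate `Inf`. No
nonsynonymous change gives `flag = "dn_zero"` and estimate 0. Downstream
statistics (the Spearman correlation in particular) drop flagged branches
rather than ingesting infinities — the same exclusion rule the original
analyses applied.

**LRTs** use the plain chi-squared reference distribution with df equal to
the difference in free parameter counts, matching how such tables are
conventionally reported. For boundary nulls (M1a-vs-M2a, M7-vs-M8,
branch-site test 2) this choice is known to be conservative; the
calibration test in the suite therefore accepts rejection rates at or
below the binomial band around the nominal 5% for the branch-site test.

**Site posteriors** are naive empirical Bayes: posterior(class k | site)
∝ p_k · L_site(ω_k) at the maximum-likelihood estimates. Full Bayes
empirical Bayes (integrating over parameter uncertainty) is out of scope;
NEB posteriors are accurate in strong-signal regimes but overconfident
when parameters are poorly determined.

## Lesion scanning and sanitization

Coordinates are 1-based codon positions of the reference (an intact
ortholog), the same convention used to annotate lesions in comparative
figures. Within a taxon the reading frame is tracked through indels, so a
stop downstream of a frameshift is reported in the shifted frame — it
describes the broken protein — but only the first disruption on a
root-to-tip path determines pseudogenization timing. In-frame indels
(length divisible by three) are not disruptions. Stops within
`tail_tolerance` codons of the 3' end can be ignored (default 0: every
premature stop counts, since very 3'-proximal stops are only ambiguous
biologically, not computationally).

Two lesions are "the same event" when they match in kind, reference codon
and length — and, for nonsense lesions, in the stop triplet itself. Dollo
mapping then assigns each event to the branch above the most recent common
ancestor of its carriers if every tip below that ancestor carries it;
otherwise the carriers split into maximal fully-carrying clades, each an
independent origin (this is how recurrent same-position indels in
mutation-prone runs, e.g. poly-A stretches, are counted as several
events). Taxa flagged as allele-polymorphic keep their lesions in the
event table but do not found a pseudogene lineage unless requested.

Before likelihood analysis, `sanitize_alignment` applies the standard
cleaning rules: frameshifting insertion column runs are deleted; any
reference codon containing a stop in some taxon, or left partially deleted
by a frameshifting deletion, is deleted in **all** taxa. The removal log
is complete (a codon is removed iff it is logged) and sanitization is
idempotent; both are property-tested. The scanner derives lesions directly
from the alignment columns, so no separate events table is needed as
input. Codons containing gaps or ambiguity codes are treated as fully
missing in the likelihood (marginalised over compatible states); a fully
ambiguous taxon provably drops out of the likelihood, which the tests
check. Any residual manual curation steps applied to the original
alignments are not algorithmically specified anywhere and are therefore
not reproduced.

## Rates and decay simulation

`neutral_disruption_rate` counts events on `psi1` branches only — branches
whose ancestor was already disrupted, hence evolving neutrally for their
whole length — and divides by their summed exposure (branch times in myr
from a time-calibrated tree, or branch dS from a free-ratio fit).
The mean waiting time is exposure/n with delta-method standard error
(exposure/n)/√n, which reproduces the familiar "once every w ± se myr"
form; an exact Poisson interval is emitted alongside because the ±-form
understates the asymmetry at small n. With 7 events over 51.1 myr this
gives 7.3 ± 2.8 myr.

`simulate_decay` is a forward simulator of neutral ORF decay: per
replicate, Poisson(sub_rate · L · duration) substitutions land uniformly
with transition bias κ/(κ+2), Poisson(indel_rate · L · duration) indels
arrive with lengths from the configured model, and the disruption count is
the number of premature stops in the mutated sequence plus the number of
frameshifting indels. `p_dis(k)` is the fraction of replicates with count
≤ k. Defaults follow the published neutral rates for Old World monkeys:
10⁻⁹ substitutions and 10⁻¹⁰ indels per site per year, 10,000 replicates.
The default indel length model is 1 bp (every indel frameshifts) — the
most common indel class, and the sharpest operationalisation of
"disrupting indel"; a geometric length model is available via
`indel_length = "geometric"`.

Numerical choices worth stating: substitutions are applied as independent
draws from the start sequence (no multiple-hit bookkeeping), adequate at
the ~5% divergences involved and exactly matched by the analytic
cross-check `analytic_expected_count`, which combines the indel term
(rate · L · duration · Pr(frameshift)) with the exact stop-creation
fraction of the start sequence enumerated over all single-nucleotide
changes. The default start sequence is a random stop-free ORF with
uniform base composition and κ = 2; the stop-creation fraction — and hence
p_dis(0) — is moderately sensitive to both (an AT-rich start or a lower κ
raises the number of codons one step away from TAA/TAG/TGA). A real ORF
sequence can be supplied to pin this term. With the default composition,
the 1,044-nt/55-myr configuration gives p_dis(0) of a few × 10⁻⁴,
consistent with the published order of magnitude (6 × 10⁻⁴) within these
model assumptions.

## Correlated loss

`categorize_branch_pairs` counts branches (not species — every branch of
the shared tree contributes one observation; a species-level mode exists)
into the four loss categories of two paralogs, and `fisher_exact_2x2`
computes the two-sided exact p-value by hypergeometric enumeration with
the sum-of-smaller-probabilities convention and a 1 + 10⁻⁷ rounding
guard. On the published 3/4/1/31 table this yields 1155/82251 = 0.0140.
`spearman_branch_omega` correlates per-branch free-ratio ω values after
dropping dS = 0 / dN = 0 sentinel branches, with average-rank ties, an
exact permutation null for n ≤ 9 (without ties) and the t approximation
otherwise. No phylogenetic correction (independent contrasts) is applied —
branch values are used raw, which is a known caveat, not an oversight.

## The synthetic generator

`sim_scenario` fixes the study conditions the tests run under: a rooted
tree with branch lengths in substitutions per codon site, purifying
selection (default ω = 0.2) on intact lineages, optional site-class
mixtures on intact lineages, and a pseudogenization schedule — (branch,
fraction-along-branch) pairs after which the lineage evolves at ω = 1 and
carries lesions. Each scheduled event injects one guaranteed founding
lesion (random kind, non-colliding codon positions), so truth tables are
always realisable; stochastic extra lesions at the neutral rates can be
enabled when branch times are supplied. Simulation samples states from
cached transition matrices, so stop codons never arise by substitution —
every stop in a simulated alignment is an injected lesion.

What the generator deliberately does **not** emulate: alignment error,
indels under selection, rate variation beyond the configured classes,
base-composition heterogeneity across lineages, and polymorphism within
species. Tests passing on this generator therefore validate the
*inference machinery*, not robustness to real-data artefacts; the scanner
is exercised on hand-built edge-case fixtures separately.

## Problem sizes used in the test-suite

Simulation-based checks are sized to make the suite comfortably runnable
as a whole: the ledger-recovery check uses 10 scenarios at 20 taxa × 300
codons with branch lengths fixed at the generating values and a single
optimisation start; LRT size calibration uses 100 null replicates at 5
taxa × 60 codons with 3 beta classes, holding branch lengths and κ at
their generating values so the omega-class LRT size is measured without
nuisance-parameter optimisation noise; the M8 power and NEB checks use
5 replicates at 10 taxa × 300 codons with ω_s = 5. Thresholds (≥ 90%
recovery, the binomial band around 5%, ≥ 80% NEB top-class) are fixed
properties being asserted, not quantities tuned to the replicate counts.

## Known limitations

- NEB, not BEB, site identification; posteriors are overconfident for
  weakly informed parameters.
- Plain chi-squared LRT references; boundary tests are conservative.
- Branch models on rooted trees leave the two root edges' ω jointly
  identified only through their product path (merged automatically in the
  free-ratio model; user-specified branch models are taken as given).
- The decay simulator's stop term depends on start-sequence composition
  and κ; supply a real ORF to pin it.
- Dollo mapping assumes no exact reversal of a lesion and complete
  sequence data at every tip for carrier determination.
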