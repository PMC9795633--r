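---
title: "Allele-frequency trajectory analysis for evolve-and-resequence experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-frequency trajectory analysis for evolve-and-resequence experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evotraj)
```

## The problem

In an evolve-and-resequence experiment a clonal bacterial population is
propagated — in an animal host, or in its diet alone — and whole-population
(metagenomic) sequencing is performed at a series of time points. An upstream
polymorphism caller (e.g. breseq in polymorphism mode, rerun with a merged
candidate list so every candidate gets mutant/reference read counts in every
sample) produces a table of candidate mutations with per-sample read support.
From that table this package answers four questions:

1. Which candidates are real mutations rather than systematic mapping
   artifacts or sequencing errors? (*filtering*)
2. How fast does each population, or each hypermutator lineage inside it,
   accumulate mutations per bacterial generation? (*rates*)
3. Which mutations belong to which hypermutator lineage, and what is the
   base-substitution spectrum of each group? (*lineages and spectra*)
4. How are mutations nested into genotypes, and what are their corrected
   frequencies for a Muller plot? (*muller*)

A synthetic-experiment generator emulates the statistical structure all four
steps assume, so every step can be validated against known ground truth.

## Filtering model

Each candidate mutation has per-sample counts $m_s$ (reads supporting the
mutant allele) and $t_s$ (total reads at the site). Under the null hypothesis
of a sequencing artifact, the mutant reads arrive at one common rate
$\lambda$ across samples: $m_s \sim \text{Poisson}(\lambda t_s)$, with the
totals acting as offsets. A real mutation sweeping through a population
instead has sample-specific rates (sample as a fixed factor; with one
observation per sample this alternative is the saturated model
$\hat\lambda_s = m_s/t_s$). The likelihood-ratio statistic has the closed
form

$$ D = 2 \sum_s m_s \log\frac{m_s}{\hat\lambda t_s}, \qquad
   \hat\lambda = \frac{\sum_s m_s}{\sum_s t_s}, $$

with $0\log 0 = 0$, referred to $\chi^2$ with $S_\mathrm{eff}-1$ degrees of
freedom, where $S_\mathrm{eff}$ counts samples with nonzero coverage. A
single usable sample gives no contrast: the test reports $p = 1$. P-values
are never reported as exactly zero (clamped at the smallest double).

Three stages are applied in a fixed order:

1. **LRT + Benjamini–Hochberg** at FDR $q = 0.01$, pooled over the whole
   candidate list of the run (the merged candidate list spans
   treatments; per-treatment correction can be had by running treatments
   separately).
2. **Ubiquity**: a candidate whose frequency is $\ge 5\%$ in at least half
   of *all* samples pooled over treatments is removed. Real sweeps occur in
   one treatment; an artifact of the reference assembly is called everywhere
   at a similar low frequency. With an even number of samples, "at least
   half" triggers at exactly half (`ceiling(fraction * S)`).
3. **Persistence**, per treatment: keep a mutation iff its frequency range
   exceeds 20 percentage points, or it both peaks above 10% and appears in
   at most half the treatment's samples (`floor(fraction * S)` — "less than
   or equal to half"). "Appears" defaults to any nonzero unmasked frequency
   (`presence_thr = 0`), exposed as a parameter because the boundary is
   a design choice.

A mutation passing the persistence stage in *any* targeted treatment
survives. The filter report reconciles in/out counts stage by stage.

Zero-coverage cells are masked: they are excluded from the LRT, not counted
by the ubiquity or persistence stages, and contribute zero to summed
frequencies. The masked-as-zero summation convention is a documented choice;
the alternative (dropping samples) changes $M_s$ only when coverage is lost
at whole sites.

## Accumulation-rate model

Let $M_s$ be the summed frequency of all (post-filter) mutations in sample
$s$ and $g_s$ the elapsed bacterial generations. Under constant accumulation
with no initial mutations, $M_s = r\,g_s$; the zero-intercept least-squares
estimate is $\hat r = \sum M_s g_s / \sum g_s^2$ with
$\mathrm{SE} = \sqrt{(\mathrm{RSS}/(n-1))/\sum g_s^2}$ (the standard
through-origin convention, $n - p$ residual df with $p$ the number of
rates).

When hypermutator lineages coexist, each sample is a mixture. With lineage
fractions $f_{k,s}$ (estimated from the defining marker-allele frequencies,
proportionally renormalized when independent estimates sum slightly past
100%) the model becomes

$$ M_s = \sum_k r_k \, f_{k,s} \, g_s , $$

a no-intercept linear model over design columns $X_{s,k} = f_{k,s} g_s$.
This takes the lineage history literally at the sampled points only — each
mutator lineage is assumed to have arisen near the start and to hold one
constant rate — and no integration of the fraction history between samples
is attempted. Rate equality between two lineages is tested by an F-test
against the model with the two design columns summed; a numerically
saturated full fit (RSS at rounding error) reports infinite F with a
clamped p-value and a warning rather than a fabricated finite statistic.

Ordinary (unweighted) least squares is used throughout; the residual
variance of $M_s$ is not constant under read noise (it scales with the
number of segregating mutations), but weighting options would add parameters
the data cannot pin down at a dozen time points.

The doubling-time utility converts two population sizes into a generation
time, $g_t = \log 2\,(t_2-t_1)/(\log X_2 - \log X_1)$, the closed form for
exponential growth.

## Lineage assignment and spectra

A mutation is assigned to the hypermutator lineage whose marker-allele
trajectory is nearest in total Manhattan distance,
$D = \sum_s |p_s - f_{k,s}|$ over the samples where both are unmasked
(masked samples are dropped pairwise, never imputed), provided that distance
is below 0.4; ties below the cutoff are left unassigned with a flag. The
nearest-marker-with-cutoff rule is the only reading of "distance < 0.4 used
to classify" that yields a classification. The known failure mode is
inherited from the method itself: a mutation arising *late* inside a lineage
accumulates $\sum_{s<\text{arrival}} f_{k,s}$ distance before it appears and
lands beyond the cutoff — such late intra-lineage sweeps sit at distances
near 1 and stay unassigned here (the original analysis resolved them
manually; that curation is not reproduced).

Base substitutions are folded into the six strand-symmetric classes
(A:T→G:C, A:T→C:G, A:T→T:A, C:G→T:A, C:G→A:T, C:G→G:C); spectra count each
SNV once (not frequency-weighted), excluding indels with a reported count.
Strand relabeling of the input leaves spectra unchanged by construction.

## Genotype nesting and Muller export

Only mutations reaching at least 10% frequency enter the reconstruction,
minus an explicit exclusion list (mirroring the manual exclusion of calls
caused by one unresolved structural variant). Under purely asexual
reproduction a genotype's frequency can never exceed its parent's, and a
lineage is assumed not to mutate the same gene twice. The reconstruction is
a deterministic greedy containment pass: mutations in order of descending
peak frequency (ties: earlier first appearance, then id) are nested under
the deepest existing genotype that dominates them at every sample up to a
tolerance $\varepsilon$ and has no same-gene mutation on its path; anything
unplaceable becomes a new root-level genotype rather than a guess.
$\varepsilon$ defaults to 0.02 (read-noise scale at a few hundred x
coverage); at 150x depth the analysis scripts use 0.05 ($\approx 2\sigma$
for intermediate frequencies). The original analysis disambiguated a few
orderings by hand; no attempt is made to reproduce those judgements.

Because each mutation's frequency is estimated from its own reads, raw
genotype frequencies can be mutually inconsistent. Two corrections are
applied top-down: children are capped at their (already corrected) parent's
frequency, and sibling sets whose total exceeds their parent (root siblings:
exceeds 100%) are rescaled proportionally. Every adjustment is reported and
a warning is raised when any reaches 10 percentage points — corrections that
large indicate the nesting, not the measurement, is wrong. After correction
the exported tables satisfy child ≤ parent and per-sample conservation
exactly: the population table carries each genotype's *exclusive* frequency
and the ancestor's remainder, per generation, in the Parent/Identity and
Generation/Identity/Population layout the ggmuller package consumes.

## The synthetic-experiment generator

The generator emulates exactly the structure the analysis assumes:

* **Lineages** are disjoint population compartments with a constant
  per-generation accumulation rate $r_k$ and a per-sample fraction schedule
  $f_{k,s}$ (summing to ≤ 1; the remainder is nonmutator background). New
  mutations arrive as Poisson counts with mean $r_k \Delta g$ between
  samples and hitchhike at the lineage fraction thereafter — the minimal
  stochastic completion of a model that is deterministic in expectation. A
  deterministic mode replaces arrival counts by within-lineage weight ramps
  so the summed true frequency equals $r_k f_{k,s} g_s$ exactly, which the
  exact-recovery tests rely on.
* **Markers**: a lineage's defining allele is emitted as an ordinary row
  whose true frequency is the lineage fraction, so marker coherence can be
  checked end to end.
* **False positives** get one latent frequency per site, drawn around a low
  mean (default 4%) and constant across samples — precisely the signature
  the ubiquity and LRT stages remove.
* **Observation**: depth is negative-binomial per cell with configurable
  dispersion (0 = constant; defaults target the study's 124–193x mean
  coverage range), and mutant reads are
  $\text{Binomial}(t, f(1-e) + (1-f)e)$ with per-base error rate $e$.
* **Spectra**: SNV alleles are drawn from per-lineage six-class weights
  (mismatch-repair-deficient lineages concentrate on A:T→G:C), with the two
  ordered representations of a class equiprobable.
* Coordinates are synthetic positions on one circular contig with synthetic
  gene labels; no real genome content is used, and no read-level artifacts
  (mapping, indel realignment) are modelled.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: within-lineage sub-structure (every hitchhiker of
a lineage shares one trajectory, so genotype reconstruction inside a
hypermutator lineage is degenerate by construction and the analysis scripts
deduplicate trajectories before the Muller step), mapping artifacts with
sample-dependent rates, linkage between sites beyond lineage membership,
and real gene content. Late-arising mutations are genuinely present and
make the 0.4-cutoff classifier miss them, as in the original data.

## Default parameters

| Parameter | Default | Where it comes from |
|---|---|---|
| LRT FDR `fdr_q` | 0.01 | published cascade |
| Ubiquity threshold / fraction | 0.05 / 0.5 | published cascade |
| Persistence range / peak | 0.20 / 0.10 | published cascade |
| Persistence presence threshold | 0 (> 0 counts as appearing) | literal reading, exposed |
| Muller inclusion threshold | 0.10 | published cascade |
| Manhattan assignment cutoff | 0.4 | published classification |
| Containment tolerance ε | 0.02 | read-noise scale, exposed |
| Simulated depth | 150 | the study's 124–193x range |

Boundary conventions that the prose of a methods section leaves open are
fixed and tested: ubiquity uses `ceiling` (even sample counts trigger at
exactly half), persistence uses `floor` ("less than or equal to half"), the
Muller inclusion boundary is inclusive ("at least 10%").

## Problem sizes and numerical choices

The test-suite simulations are sized to be exact where exactness is claimed
and cheap elsewhere: exact-recovery checks use noise-free model data over
the fifteen mouse-host sampling points and the four fly cycles; type-I
control uses 1,000 constant-frequency sites at 21 samples; CI coverage uses
500 replicate experiments at 150x depth (with 14 residual df, the nominal
±1.96·SE interval covers ~93%, slightly under the asymptotic 95%); the
equal-rate null calibration uses 300 replicates. Exact frequency identities
in tests use depth-representable fractions (hundredths at 100x), since read
counts are integers. Degenerate inputs are handled explicitly: zero-coverage
samples reduce the LRT df, all-zero designs name the missing lineage,
saturated F-tests warn, and declining populations return a negative
generation time with a warning instead of an error.
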