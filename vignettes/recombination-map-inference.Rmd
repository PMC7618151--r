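---
title: "Inferring recombination maps from gamete Hi-C read pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring recombination maps from gamete Hi-C read pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombmapr)
```

## The inference problem

A Hi-C library prepared from bulk sperm captures pairs of DNA fragments
that were spatially close in the same haploid gamete nucleus. When the two
reads of a pair each cover at least one phased heterozygous site of the
donor, the pair is *informative*: reads matching different donor
haplotypes imply a crossover occurred between them in that gamete
(`X = C`); reads matching the same haplotype imply none (`X = N`). Each
informative pair is thus an interval-censored observation of the
recombination process — we learn whether (but not where) a crossover fell
between the pair's two outermost SNPs. The inference task is to recover
the per-basepair crossover rate landscape `r(x)` (in cM/bp) from hundreds
of thousands of such censored observations of varying span.

Three properties of the data shape the method:

* **Errors concentrate at short inserts.** Miscalled or misphased SNPs
  flip a read's apparent haplotype at a rate independent of insert size,
  while the probability of a genuine crossover grows linearly with insert
  size. Short-insert observed-C pairs are therefore almost all false, and
  uncorrected they produce sharp artifactual rate spikes.
* **Effective coverage varies along the chromosome** and collapses toward
  the ends, where sampling noise explodes.
* **Observations overlap.** A crossover seen by one pair is constrained by
  the many overlapping pairs that did *not* see one, which is what allows
  sub-insert localisation.

## Likelihoods, error correction, posteriors

Per read end, the probability that the observed haplotype assignment is
wrong composes the base-call error `b` (from the base quality) and phase
error `p` (from the phasing quality) as `e = b(1-p) + p(1-b)`,
treating the two as independent; exactly one of the two errors flips the
assignment. For an observed-C pair, `lc = (1-e1)(1-e2) + e1 e2` (no flip
or double flip) and `ln = e1(1-e2) + e2(1-e1)` (exactly one flip).
Observed-N pairs are pinned to `lc = 0, ln = 1`: an N call never generates
crossover evidence. This deliberately accepts false negatives, which are
uniform along the chromosome and therefore rescale the landscape without
distorting its shape.

The baseline rate `r*` is the crossover-likelihood mass of long-insert
pairs (> 1 Mb by default) per surveyed basepair, and the correction factor
`f` is the mean excess of short-insert (< 1 kb) crossover likelihood over
the baseline expectation `r* d`. We take the denominator of `f` to be the
count of *all* short informative pairs, not only observed-C ones: `f` is
then the per-pair false-positive rate, the quantity that an observed-C
pair's likelihood must be discounted by, and it coincides with the planted
status-flip rate in simulations. (With only C pairs present the two
readings agree.) `f` is clamped to `[0, 1)` and `lc - f` floored at 0 to
guard small-sample estimates.

The posterior for an observed-C pair combines the corrected likelihoods
with the uniform-rate prior `pc = r* d` (clamped to 1). For long N pairs
(> 1 Mb), a double crossover masquerades as N; with
`lambda = r* d` expected crossovers on the insert, the Poisson mass of
exactly two, `pd = lambda^2 e^(-lambda)/2`, replaces the zero crossover
likelihood. Crossover interference makes nearby double crossovers rare,
hence the restriction to long inserts. We read `lambda` as `r* d` because
the expected crossover count on an insert — not the per-bp rate — is the
dimensionally meaningful Poisson intensity for this event.

The operations are applied in a fixed order: classify, remove imbalanced
SNPs, estimate `r*` (raw likelihoods), estimate `f`, adjust long-N
likelihoods, compute posteriors, then build the map. Estimating `r*`
before the double-crossover adjustment avoids circularity (`pd` needs
`r*`).

## Map construction and the EM procedure

The map lives on the interval grid delimited by all bounding-SNP
coordinates inside the retained span; rates are constant within intervals,
which loses nothing because no observation distinguishes positions between
adjacent bounding SNPs. Pair spans are half-open `[left, right)`, so
interval lengths always sum exactly to the insert size `d`.

The initial map spreads each pair's posterior `P_i` uniformly along its
insert (density `P_i/d_i` per bp) and divides by the local effective
coverage `N_j` — the number of gametes surveyed there — giving
`rate_j = 100 * sum_i(P_i/d_i) / N_j` cM/bp.

The EM step lets overlapping pairs localise each other's crossovers. Each
crossover pair carries a fixed genetic mass
`G_i = (P_i/d_i) * sum_{j in span_i} len_j/N_j` — its posterior, with the
coverage normalisation baked in once, at the initial uniform spread. The
E-step redistributes `G_i` over the intervals of the pair's span
proportionally to the current `rate_j * len_j` (uniformly over the span
when its total rate is zero, the only tie-break needed); the M-step sets
`rate_j = sum_i w_ij / len_j`. Because every pair's weights sum to `G_i`
at each iteration, the total genetic length of the map is conserved
*exactly* throughout the EM — a property we consider essential, since the
EM's job is to reposition crossover probability, not to create or destroy
it. An alternative formulation re-divides by `N_j` at every M-step; under
constant coverage the two coincide, but the re-dividing form lets genetic
length drift wherever coverage varies within a span and has no fixed point
at the single-pair map. We chose the conserving form. The update is
computed with difference arrays and prefix sums, O(pairs + intervals) per
iteration, so chromosomes with 10^5 intervals refine in seconds.

Convergence is declared when the maximum per-interval relative rate change
(relative to the interval's rate, floored at 1e-9 of the maximum) drops
below `tol` (default 1e-4), up to `max_iter` (default 100) iterations,
returning the last iterate with a warning otherwise. Like any
unregularised maximum-likelihood deconvolution of interval-censored point
events, prolonged EM concentrates mass on intersections of overlapping
crossover pairs; the iteration cap and the bounding-SNP grid act as the
effective resolution limit, and bootstrap averaging smooths residual
spikiness.

## Supporting heuristics

* **Imbalanced SNPs.** A SNP bounding at least `c_min = 2` observed-C
  pairs and at most `n_max = 0` observed-N pairs is an artifact signature
  (a miscalled or misphased variant flips every pair it bounds). The SNP
  and all pairs it bounds are removed, iterating until stable — iteration
  only matters when `n_max > 0`, since with `n_max = 0` removals never
  expose new candidates.
* **Edge trimming.** The retained span runs from the first to the last
  interval whose effective coverage reaches `min_cov`; interior dips are
  kept. The default cutoff, 10% of the length-weighted median coverage,
  is our choice of a scale-free default that tracks each dataset's own
  coverage level.
* **Degenerate cases.** No long-insert pairs is an error (the baseline is
  undefined; the threshold should be lowered). No short pairs gives
  `f = 0`. Zero posterior denominators yield posterior 0. Zero coverage
  inside the retained span yields rate 0 with a warning.

## Uncertainty and map comparison

Pairs are resampled with replacement `B` times and the whole chain from
`r*` onward is rerun per resample (the imbalanced-SNP filter runs once, on
the observed data, since resampling multiplies pair counts and would
distort the bounding tallies). Replicate maps are evaluated on the union
grid over the intersection of retained spans; the envelope is the
percentile 2.5/97.5 interval per grid interval. Two maps differ
significantly wherever their 95% envelopes are disjoint (closed intervals:
touching envelopes intersect); mean-normalising first (dividing each map
and envelope by its length-weighted mean rate) isolates landscape-shape
differences from genome-wide rate offsets.

## What the simulator emulates — and what it does not

`simulate_pairs()` draws insert sizes from an empirical distribution (or
the synthetic log-uniform `synthetic_insert_sizes()`, matching the ~1/d
decay of Hi-C cis-contact distances between 200 bp and 5 Mb), places pairs
uniformly, snaps endpoints inward to a SNP grid of density 1/kb (the
heterozygosity regime where gamete Hi-C mapping is practical; endpoints
shared across pairs also set a realistic localisation floor), assigns true
crossover status by the Haldane mapping function
`p = (1 - e^(-2 d_M))/2` of the map distance between endpoints — chosen
over the linear cM/100 reading because it saturates correctly at 0.5 for
multi-Morgan inserts — and flips the observed status symmetrically with
probability `error_rate`. Quality fields are near-zero (`b = p = 1e-6`) so
the planted flip rate is the only error source. Generation stops when the
total surveyed length per bp reaches the coverage target, which lands
within a fraction of a percent of the target.

The bundled `sawtooth_reference_map()` oscillates linearly between 0.2 and
6 cM/Mb. Its default period is 7 Mb: long and incommensurate with the
usual evaluation bins, so the truth retains variance at every comparison
scale (a short period aliases away all coarse-scale signal and makes
broad-scale correlations meaningless). `make_fixture()` complements this
with base-level SAM + HapCUT2 fixtures containing planted breakpoints for
end-to-end read-level tests.

Deliberately not emulated: PCR duplicates and chimeric alignments
(assumed handled upstream), ligation artifacts and the contact-frequency
structure of real Hi-C, gene-conversion tracts, structural variation,
somatic-cell contamination, and coverage non-uniformity beyond endpoint
geometry. Passing simulation tests therefore demonstrates correctness of
the inference chain under its own error model, not robustness to every
real-data pathology; the imbalanced-SNP filter and `f` correction are the
designed defences for the latter.

At 1000x coverage on the sawtooth landscape, ~0.2 expected crossovers
fall in a 2 kb bin, so fine-scale bin correlations with the truth are
bounded by counting noise near 0.2 even for a perfect method; broad-scale
(1-5 Mb) correlations reach 0.87-0.98. The mean per-bp rate is recovered
to within ~10%; its sign and size depend on the interplay of Haldane
saturation of long-insert likelihoods (downward) and error inflation of
`r*` (upward).

## Problem sizes and numerical conventions

The test suite and acceptance script run entirely on generated data:
10-25 Mb chromosomes, effective coverages 300-3000x, 10 replicates for
monotonicity checks, 10 seeds for error-rate recovery, and brute-force
per-bp oracles on 10 kb toys with ~20 pairs — sizes at which every check
completes in seconds while the asymptotic behaviour is already visible.
Coordinates are 1-based; intervals half-open; rates stored in cM/bp and
written as cM/Mb with 1-based inclusive ends in the TSV dialect; phase
errors capped at 0.5 (a phase call cannot be worse than random); trio
phasing reports `phase_err = 0` for phased sites, since Mendelian
assignment is deterministic given correct genotypes (a genotype-quality
derived value would be a reasonable extension).

## Limitations

Diploid donors only (hemizygous sex chromosomes are out of reach);
crossovers only (no gene-conversion tract inference); absolute map lengths
inherit the edge-trimming truncation and any somatic contamination of the
library; fine-scale rates at modest coverage are noise-limited; and the
percentile bootstrap envelope is only as smooth as `B` allows.
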