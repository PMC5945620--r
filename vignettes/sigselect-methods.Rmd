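---
title: "Mutation and selection in cancer cohorts: the sigselect methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation and selection in cancer cohorts: the sigselect methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigselect)
```

## The problem

The driver mutations observed in a cancer reflect two evolutionary
forces. Mutagenic processes — smoking, APOBEC activity, mismatch-repair
failure, ageing — each leave a characteristic spectrum over the 96
trinucleotide substitution channels, biasing *which* DNA changes arise.
Selection then determines which of the arising mutations expand to
detectability. sigselect separates the two: it quantifies how strongly
per-sample mutational-process activity predicts the presence of
specific recurrent driver mutations, and it tests whether the observed
frequencies of alternative driver mutations can be explained by their
mutational likelihood alone — any residual imbalance is evidence of
differential selection, summarised as a relative risk.

## Channels and exposures

Every somatic SNV is classified by its reference base, alternate base
and flanking bases under the pyrimidine-strand convention:
purine-reference substitutions are reverse-complemented, so each event
lands in one of 96 channels (6 substitution classes × 16 flank
combinations, canonical COSMIC ordering). A cohort becomes a samples ×
96 count matrix; non-silent mutations in driver genes are excluded
from this matrix before fitting, so the driver events under study do
not contaminate the exposure estimates that are supposed to predict
them.

Exposures are fitted per sample by non-negative least squares (NNLS):
the raw count vector is regressed on the channel distributions of the
signatures active in the cancer type, with weights constrained to be
non-negative. NNLS is run on **counts**, not frequencies, so a sample
with 10,000 mutations is fitted with correspondingly more weight than
one with 30; the fitted activities (mutation-count scale) are then
normalised to exposures summing to 1, and signatures not active in the
type get exposure 0. The Lawson–Hanson active-set algorithm is
implemented in the package (no NNLS solver is available in the
dependency set); tests verify the Karush–Kuhn–Tucker conditions on
random instances and exactness inside the non-negative cone, and the
implementation was cross-checked against an independent reference
solver during development.

For whole-exome data a genome-derived catalog is first rescaled:
each channel probability is multiplied by the exome/genome frequency
ratio of its reference trinucleotide and the signature renormalised.
The rescaling rule is the standard reading of "re-scaled to the
trinucleotide frequencies of the exome"; the exact formula is not
fixed by the source material, which we record as an assumption. The
shipped frequency table (`trinucleotide_freqs_synthetic.tsv`) is a
clearly-labelled synthetic approximation from an independent-base model
(genome GC 40%, exome GC 49%); users with real genome/exome
trinucleotide counts should replace it — the file is an editable
fixture, not reference data.

### How many mutations are enough?

Exposure fitting degrades for sparsely mutated samples.
`calibrate_min_mutations()` quantifies this: each signature is treated
as a multinomial over the 96 channels, `n`-mutation datasets are
simulated from it, and each is refitted against the true signature
plus 14 randomly drawn decoys; a fit succeeds when the true signature
receives more than half the summed NNLS weight. Decoys are redrawn
fresh per replicate (the source procedure fixes one random set per
regression; redrawing averages over that choice and is controlled by
the single seed). The default analysis cutoff is 20 mutations per
sample, with a configuration override (a stricter 50 is conventional
for sensitivity analysis).

With the real COSMIC v2 30-signature catalog this procedure is
reported to give ≈80% mean accuracy at n = 20. That catalog cannot be
shipped or downloaded here, so the package's acceptance check runs the
procedure on a synthetic 30-signature stand-in (symmetric Dirichlet,
concentration 0.2 — chosen a priori to match the typical effective
channel spread, ~25 effective channels, of real catalogs). The
stand-in gives ≈0.97 accuracy at n = 20: random Dirichlet signatures
are nearly mutually orthogonal, whereas real signatures share
substantial channel mass (the flat signatures 3/5/8, the ubiquitous
C>T-at-CpG component), and that overlap — not the marginal spread — is
what drives misassignment. The 80% figure is therefore a property of
the real catalog's similarity structure; the corresponding acceptance
test is left failing by design rather than tuning the generator to
reproduce the number, and the calibration machinery itself is verified
by its contract properties (zero decoys give accuracy 1; the mean
accuracy curve is non-decreasing in n).

## Associations between processes and driver mutations

Within a cancer type, recurrent driver mutations (identical DNA
changes, keyed by gene/chromosome/position/alleles, occurring ≥4
times) are mapped to their *causal channel*. Signatures whose causal-
channel frequency is strictly above the unweighted mean across the
type's active signatures are the candidates tested ("above average"
could alternatively be exposure-weighted; the unweighted mean is the
default and a `weights` argument exposes the variant). For each
candidate, exposure in carriers is compared with non-carriers by a
one-sided Mann–Whitney U test (carrier-higher), exact for tie-free
groups of ≤20 and otherwise normal with tie correction and continuity
correction; a fully tied comparison returns p = 1. Benjamini–Hochberg
FDR control is applied over all tests in the scan — globally by
default, per cancer type behind a flag, since the source analysis does
not state which; global is the more conservative default for a scan
whose tests share samples only within a type.

Power for each test is estimated under a simple initiation model: the
mutation of interest is one of 10 mutations, one of which is required
for initiation. Per iteration the 9 decoy causal channels are drawn
uniformly from the 95 other channels (excluding the target's own
channel avoids a degenerate duplicated channel; logged as an
assumption), per-sample probabilities that the target occurred rather
than a decoy are computed from the exposure mixtures, m carriers are
drawn without replacement with probability proportional to these
(sequential renormalised draws, R's `sample()` semantics), and the
rank-sum test is run. Power is the fraction of iterations with
p < alpha; only at alpha = 1 is the comparison made inclusive so the
boundary case is exact.

## Differential selection

Under the multistage initiation model, a mutation sequence of length n
with per-year rates u₁…uₙ and post-sequence cancer rate λ gives
incidence I(t) = Σⱼ u₁(j)…uₙ(j) λⱼ tⁿ / n! in the low-rate regime.
Two mutations are *similar with relative risk r* when substituting one
for the other in any cancer-causing sequence multiplies the cancer
rate by r; then P(M₁ | M₁ ∪ M₂) = u₁r / (u₁r + u₂).

For a pair of common driver mutations in a cancer type, the test set
is the samples carrying exactly one of the two and no other mutation
in the set under consideration (the full set, not just the pair's
gene — the stricter reading of the exclusion rule). For each such
sample the causal-channel probabilities p₁, p₂ follow from its
exposure mixture, and under neutrality the count of M₁ carriers is
X ~ Poibin(q), qᵢ = pᵢ₁/(pᵢ₁+pᵢ₂). The Poisson binomial PMF is
computed exactly by iterative convolution and the two-sided p-value
uses the minimum-likelihood rule (sum of probabilities of outcomes no
more likely than observed, with a 1+1e-9 relative tolerance for
floating-point ties); a doubled-smaller-tail variant is available
behind a flag. Minimum-likelihood is chosen because it is exact,
standard for discrete tests, and reduces to tail-doubling only in
symmetric cases.

The relative risk is estimated by maximising
L = Π_{i∈I₁} qᵢ(r) · Π_{i∈I₂} (1 − qᵢ(r)) with
qᵢ(r) = r pᵢ₁/(r pᵢ₁ + pᵢ₂), via bounded one-dimensional optimisation
of log r on [−12, 12] (the source's optimiser and bounds are unstated;
this is an implementation choice). When one carrier class is empty the
likelihood is monotone and the estimate is reported as censored at the
boundary — never as a finite number. Confidence intervals are 2.5/97.5
percentiles over 100 bootstrap resamples of whole samples (carrier
label and probability pair jointly). Mutation-level scans apply the
same machinery to all pairs of "common" mutations (>1% of the gene
set's non-silent driver mutations in the type, jointly occurring ≥10
times) with BH over the pairwise p-values. `variance_explained()`
closes the loop: OLS of mutation frequencies on mean per-sample
probabilities, reporting R² and the slope sign. No gene-level
background-rate correction is applied in between-gene comparisons;
genes should be matched for background mutation rate externally — a
documented limitation inherited from the framework.

## The synthetic world

The generator produces the statistical structure the analysis assumes,
no more: per-sample exposures from a Dirichlet prior, burdens either
fixed or negative binomial (default mean 200, dispersion 1 — typical
exome-scale burden with realistic overdispersion, and enough mass
below 20 mutations that the cutoff filter is exercised), channel
counts multinomial in the exposure-weighted mixture, and each count
materialised as a record whose context matches its channel. Position
parity decides the emitted strand representation, so both strand
conventions are exercised while a given genomic position always keeps
one representation, as in a real MAF. Drivers are planted on top of the
passenger counts (the pipeline excludes them from fitting, so
passenger counts stay exactly multinomial): each sample receives a
driver drawn with probability rⱼ pᵢⱼ / Σₖ rₖ pᵢₖ — the multi-mutation
generalisation of the conditional-occurrence formula — with all records
of one driver sharing a fixed position so recurrence counting sees one
DNA change.

What a green test establishes, therefore, is that the pipeline
recovers the truth of *this* world: exposures within 0.05 mean
absolute error at burden ≥200, planted relative risks within the
stated log-scale tolerance with ≥85% bootstrap-CI coverage, planted
associations at FDR 0.05, and calibrated type-I error under the null.
Real cohorts violate this world in known ways — signature similarity
(see above), inter-sample heterogeneity of active processes, timing
mismatch between process activity and the selection window, calling
artefacts — so green tests validate the machinery, not biological
claims.

## Numerical and degenerate-case choices

* NNLS dual-feasibility tolerance 1e-10 relative to the problem scale;
  all-zero count rows are flagged and given all-zero exposures rather
  than an error.
* Poisson binomial PMF sums to 1 within 1e-12; the two-sided p-value
  is clamped to [PMF(observed), 1].
* Exact rank-sum only for tie-free groups of ≤20 per side (the exact
  null is the tie-free one); degenerate zero-variance comparisons
  return p = 1.
* Samples with p₁ + p₂ = 0 are excluded from selection tests with a
  warning; fewer than one comparable sample yields a no-test result.
* Every seeded procedure derives independent substreams from the
  single run seed and restores the caller's RNG state on exit.
* Thresholds default to the conventional values (≥20 mutations per
  sample, recurrence ≥4, FDR 0.05, common fraction 1%, joint
  occurrence ≥10) and are all configuration-exposed.
* Duplicate mutation records are kept (with a reported count), since
  source-cohort overlaps are resolved upstream of this package.

## Known limitations

Signature misassignment between similar processes propagates into both
analyses and is not modelled; the exome rescaling formula and the
"above average" rule are standard readings of underdetermined
descriptions; the selection framework assumes process uniformity in
time and across loci; and between-gene relative risks carry no
background-rate correction. The synthetic generator does not emulate
positional hotspots, clonality/timing structure, or sequencing error.
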