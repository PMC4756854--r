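---
title: "Methods: the hard-rod nucleosome model and the differential MNase-seq pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hard-rod nucleosome model and the differential MNase-seq pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical-mechanical model at the core of
`nucsense`, the conventions and regularizations of each analysis stage,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where several reasonable choices existed.

## 1. The hard-rod (Tonks gas) model

A nucleosome occupies `a = 147` bp. Chromosomes are finite 1D lattices
with hard walls at their ends; nucleosomes cannot overlap but are otherwise
free, and a per-start formation energy `u(s)` (units of thermal energy
k~B~T; lower = more favorable) plus a dimensionless chemical potential
`beta_mu` (histone-octamer availability) define the grand-canonical
ensemble with statistical weight `w(s) = exp(beta_mu - u(s))`.

**Forward problem.** `forward_solve()` computes the exact equilibrium
start probability `n(s)` by forward/backward partition-function recursions
(`Z_f(i) = Z_f(i-1) + w(i-a+1) Z_f(i-a)` and its mirror), implemented in
C++ entirely in the log domain: partition functions grow geometrically
with chromosome length, so on ~10^5^–10^8^ bp lattices only log-space
recursion is stable. Correctness is pinned two ways: exhaustive
configuration enumeration for small lattices (agreement to 1e-12) and
closed-form cases (a lattice of exactly one footprint has `n = 1/2` at
`u = 0, beta_mu = 0`; a two-footprint lattice has partition sum 150).

Derived quantities: occupancy `O(i)` (probability bp `i` is covered) and
the conditional start probability `p(s) = n(s) / (1 - O(s) + n(s))`.
The dyad of a rod starting at `s` is `s + (a-1)/2 = s + 73`.

**Inverse problem.** The model admits a closed-form inversion
(`invert_density()`):

```
u(s) = beta_mu - log p(s) + sum_{j = s..s+a-1} log(1 - p(j))
```

with `p = 0` at invalid starts. The contract is the roundtrip:
`invert_density(forward_solve(u))` returns `u` (interior starts, given
`beta_mu`) to better than 1e-8, and `forward_solve(invert_density(n))`
returns `n`. The model has an exact gauge freedom — adding a constant to
all energies and to `beta_mu` leaves `n` unchanged — so all energy
comparisons in the package are relative (genome-wide mean subtracted).

**Configuration sampling.** `sample_configurations()` draws statistically
exact genome snapshots by the standard sequential rule: walking left to
right, a rod starts at a free position `i` with probability
`w(i) Z(i+a..L) / Z(i..L)`. The marginal start frequency equals `n(s)`
(tested), and within one snapshot rods never overlap. The fragment
simulator harvests its libraries from these snapshots, which is what makes
dinucleosome fragments *real adjacent nucleosome pairs* with emergent
spacings rather than an ad hoc two-point distribution.

## 2. From observed dyad profiles to energies

Observed profiles are relative (per-chromosome mean normalized to 1), but
the inversion needs absolute probabilities. `dyad_profile_to_density()`
shifts a normalized dyad track to start coordinates and scales it by
`coverage / a` (a start density averages coverage/a per bp; the default
assumed coverage 0.8 reflects the typical 75–90% genomic nucleosome
coverage, and can be calibrated with `calibrate_mu()`).

Two regularizations:

* **shot-noise floor**: before inverting, observed densities are smoothed
  with the 21-bp moving average used for all averaged profiles, and `n` is
  floored at 1e-12 of its chromosome mean (floored positions are
  reported);
* **hot-spot clamp** (`o_max`, default 0.98): relative enrichments can
  imply occupancy ≥ 1 at the assumed genome-wide coverage, which the exact
  inversion rightly rejects as unphysical. Only the offending starts are
  scaled down, each by the smallest `o_max / O` ratio over its footprint;
  because occupancy is monotone in the start density this single pass can
  create no new violations, and the rest of the genome keeps the correct
  absolute scale. A *global* rescaling is deliberately avoided: the
  inversion is exact only at the correct absolute scale, and we measured
  that shrinking a correct density globally by 0.7 degrades energy
  recovery from r = 1.00 to r = 0.66.

A caution that shapes the whole pipeline: near full packing the inversion
is a steep function of density (du/d log n grows without bound as O → 1),
so at coverage 0.8 a smooth ±20% multiplicative bias in a density track
becomes several k~B~T of spurious energy. Exactly such biases are inherent
to differential-digestion libraries (Section 5).

## 3. Sequence energetics and the anchoring potential

`fit_sequence_model()` regresses inferred energies on 20 window counts
(4 mononucleotides over 147 bp, 16 dinucleotides over the 146 adjacent
pairs) plus an unpenalized intercept. The count design is exactly
collinear (mono counts sum to 147, dinucleotide counts to 146), so a small
ridge penalty (default `1e-3 * n_samples`) fixes the gauge; fitted
*coefficients* are only defined up to that gauge while *predictions* are
invariant, and all tests compare predictions. Starts whose footprint lies
within one footprint of a chromosome end are excluded (hard-wall boundary
effects), as are windows containing ambiguous bases. An optional
`symmetrize` flag averages each coefficient with its reverse-complement
partner for strand-symmetric energies; the default fits forward-strand
counts only.

`infer_anchoring_potential()` averages the normalized dyad density over
active TSS (strand-oriented, 21-bp smoothed), converts the averaged window
to an absolute start density with the same `coverage / a` scaling, and
applies the exact inversion on the window. Starts within one footprint of
the window edges are discarded (the window inversion assumes walls there),
and the potential is reported relative to its own mean. The well summary
(`anchoring_well()`) reports the argmin offset and the depth below the
*median* level, which is robust to the decaying density oscillations that
surround a genuine well. `full_model_energy()` adds the potential at
strand-oriented dyad offsets from the nearest active TSS (ties to the
left-most TSS).

## 4. Classification, sequence statistics and NRL

* `classify_chromatin()`: per bp, with all occupancy profiles normalized
  to per-chromosome mean 1, resistant/sensitive is a fixed threshold
  (default θ = 0.25) on complete-digestion minus combined-partial
  occupancy, open/closed the same threshold on partial-1n minus combined.
  θ is a display threshold, not a statistical test; raising it only
  shrinks the classified sets (tested monotonicity).
* `dinucleotide_profile()`: frequencies at each offset from the dyad,
  normalized by genome-wide values; group tracks WW = {AA, AT, TA, TT},
  SS = {CC, CG, GC, GG}, and the mixed pairs.
* `at_density_correlation()`: 500-bp non-overlapping windows (last partial
  window dropped; windows with > 10% ambiguous bases dropped), fragments
  assigned by midpoint so each counts once, densities normalized by their
  genome-wide mean.
* `nrl_spectrum()`: DFT of mean-removed dyad arrays, absolute magnitudes,
  frequency bin k of an N-bp array mapped to period N/k, linear
  interpolation onto the 100–225 bp grid in 0.01-bp steps,
  `smooth.spline` with smoothing parameter 0.8, scaled to maximum 1;
  NRL = argmax, linker = NRL − 147. Across many windows (for TSS-proximal
  estimates) *magnitudes* are averaged, never complex spectra, so phase
  differences between genes cannot cancel the periodicity. On noiseless
  impulse trains of ≥ 200 repeats the planted period is recovered within
  0.5 bp; short (2-kb) windows are bin-limited to ~16 bp resolution near
  175 bp.

Deterministic tie-breaks, stated once: even-length 1n fragments take the
lower-median midpoint `floor((start + end - 1)/2)`; dinucleosome quarter
points round half-up; the moving average shrinks its window symmetrically
at edges (so constants *and* linear ramps are exactly preserved); the 2D
Gaussian filter (σ = 3, radius 4σ) renormalizes its kernel at edges and
around missing values.

## 5. The synthetic study and what it shows

`simulate_mnase_experiment()` (defaults: seed 42, two 200-kb chromosomes)
generates:

* a genome of 2–10 kb blocks with GC drawn from [0.30, 0.60] — strong,
  block-scale base-composition heterogeneity;
* ~50 non-overlapping, strand-alternating genes per chromosome placed
  inside blocks; genes in A/T-rich blocks (GC < 0.45) are active with
  log-normal expression, all others silent with expression exactly 0
  (bimodal expression, with promoter A/T content coupled to activity);
  a DHS over every active promoter plus gene-distal DHS in A/T-rich
  blocks;
* a planted energy landscape: mono coefficients +0.02 k~B~T per A/T count
  and −0.02 per G/C, ±0.004 on WW/SS dinucleotides (genome-wide SD
  ≈ 0.7 k~B~T — too weak to phase arrays by itself), plus a Gaussian
  anchoring well (depth 3 k~B~T, σ = 20 bp) at dyad offset +60 from every
  active TSS; `beta_mu` calibrated to 80% genomic coverage;
* fragment libraries harvested from exact equilibrium snapshots with a
  planted MNase-sensitivity score, the logistic
  `1/(1 + exp(-15 (AT - 0.55)))` of footprint A/T fraction: complete
  digestion (HIGH_1n) retains a nucleosome with probability
  1 − sensitivity; the partial-digestion mononucleosome library (LOW_1n)
  with probability sensitivity; the dinucleosome library (LOW_2n) takes
  adjacent pairs with probability 1 − mean pair sensitivity, fragment
  length twice the actual spacing, gel-banded to 300–400 bp. Partial-
  digestion depths are split in proportion to the sensitive/resistant
  class masses (measured after the dinucleosome length filter, via a
  pilot draw), emulating pooled sequencing of one digestion. At 18 °C all
  sensitivity scores are multiplied by 0.2. Mononucleosome lengths are
  Normal(147, 6) truncated to [120, 160] for complete digestion and
  Normal(165, 8) truncated to [140, 190] for partial digestion, each
  fragment placed so that the dyad rule recovers the sampled dyad(s).
  A selection-free library (ALL_1n) is also emitted.

**What passing tests show.** The recovery experiments (sequence-energy
correlation ≥ 0.9 against the planted model; anchoring-well position
within ±5 bp and depth within 20%) validate the *inference machinery* —
dyad assignment, normalization, smoothing, density conversion, exact
inversion, ridge fit, window inversion — on data sampled at realistic
depth from the model's own equilibrium. They run on the selection-free
library, because with the planted, nearly binary block-scale sensitivity
the combined partial-digestion (1n+2n) map retains a residual ±0.2
log-unit regional library bias (the dinucleosome length window samples
regions with different spacings unequally), and the near-saturation
inversion amplifies that bias ~8-fold — enough to swamp a planted signal
whose total range is ~2 k~B~T. The combined-map fit is still computed and
reported by the pipeline, and its qualitative signs (sensitive and open
chromatin less stable than resistant and closed) hold.

**What the generator does not emulate.** Sequence-dependent MNase cut
preferences at single-nt resolution, mappability and duplicates,
cell-to-cell heterogeneity, and — importantly — the *narrowness* of real
sensitive loci: here sensitivity is a block property of roughly half the
genome, so the complete- and partial-digestion maps are strongly
anti-correlated, whereas in real chromatin (where sensitive nucleosomes
occupy narrow promoter/DHS loci) the two maps remain positively
correlated. One consequence is documented honestly in the acceptance
suite: the cooled (18 °C) complete-digestion map does *not* correlate
better with the warm partial-digestion map than with the warm
complete-digestion map under these study conditions — the corresponding
assertion fails by construction of the block-level sensitivity, and the
script reports both correlations as computed. Weaker orderings (the
cooled map is closer to the sensitive map than the warm complete-digestion
map is) do hold.

## 6. Problem sizes and determinism

All simulations in the test and acceptance suites use two 200-kb
chromosomes (~100 genes), 300k fragments per complete-digestion library
and a 600k-dyad partial-digestion budget; module tests use a 30-kb
single-chromosome version. These sizes give stable recovery statistics
while keeping the full suite fast. Every random stage draws from R's RNG
under an explicit seed and restores the caller's RNG state; the same seed
reproduces every artifact bit for bit, which the tests assert on the
written datasets.

## 7. Known limitations

* The hard-rod model has no nucleosome–nucleosome attraction, no linker
  potentials and no unwrapping sub-states; footprint is fixed at 147 bp.
* Energies inferred from selection-biased libraries are dominated by the
  digestion bias whenever the underlying sequence signal is weaker than
  the amplified bias; interpret combined-map energies as *digestion-
  weighted* effective energies, not pure histone–DNA affinities.
* The anchoring potential is inferred from an ensemble average over genes;
  it is an effective potential and inherits window-edge effects within one
  footprint of the metagene boundary (trimmed from the output).
* NRL resolution depends on array length; sub-bp grid spacing does not
  imply sub-bp accuracy on short windows.
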