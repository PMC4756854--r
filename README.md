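# nucsense

Differential MNase-seq analysis of nucleosome sensitivity and chromatin
accessibility.

## The problem

Micrococcal nuclease (MNase) digestion is the standard way to map
nucleosomes, but nucleosomal DNA is not uniformly protected: digestion at a
high MNase concentration recovers only **MNase-resistant** nucleosomes,
while **MNase-sensitive** nucleosomes — typically on A/T-rich DNA at
promoters, terminators, enhancers and DNase I hypersensitive sites (DHS) —
are over-digested and lost, and appear only in the mononucleosome band of a
partial (low-concentration) digestion. `nucsense` is for genomicists who
run such paired high/low-concentration MNase-seq experiments and want a
tested, reusable pipeline from aligned paired-end fragments to:

* normalized dyad-density and occupancy profiles (mononucleosome midpoints;
  dinucleosome fragments of 320–380 bp contribute two dyads at 1/4 and 3/4
  of the fragment), TSS/TTS metagenes and expression-sorted heatmaps;
* a per-bp classification into MNase-sensitive/resistant and open/closed
  chromatin (occupancy-difference threshold θ = 0.25), with overlap and
  functional-region composition summaries and DHS–TSS distance statistics;
* dinucleotide-frequency profiles around dyads (WW/SS/WS+SW groups,
  normalized to genome-wide values) and A/T-content vs read-density
  correlations in 500-bp windows;
* nucleosome repeat length (NRL) estimation by Fourier analysis (periods
  100–225 bp on a 0.01-bp grid, spline-smoothed, linker = NRL − 147);
* an exact 1D biophysical model of nucleosome positioning.

## The model

Nucleosomes are hard rods of footprint *a* = 147 bp on the genome lattice,
in equilibrium at dimensionless chemical potential βμ in an arbitrary
energy landscape *u(s)* (units k\_BT, one value per start position). The
equilibrium start probability n(s) follows from forward/backward
partition-function recursions with statistical weight
w(s) = exp(βμ − u(s)); the model is exactly solvable in both directions:

* **forward**: `forward_solve()` computes n(s) and the occupancy O(i)
  (probability bp i is covered) in O(L) time, log-domain stabilized;
* **inverse** (Percus inversion): with the conditional start probability
  p(s) = n(s) / (1 − O(s) + n(s)),

  u(s) = βμ − ln p(s) + Σ_{j=s}^{s+a−1} ln(1 − p(j)),

  so formation energies are recovered *exactly* from an observed dyad
  density (`invert_density()`); the roundtrip is the defining contract.

Inferred energies are interpreted with a ridge linear fit on mono- and
dinucleotide counts of each 147-bp window (`fit_sequence_model()`), and the
phasing of nucleosome arrays at active genes is explained by a
sequence-independent **anchoring potential** Φ(x): the exact inversion of
the averaged dyad density around active TSS reveals a potential well
centered on the +1 nucleosome, which anchors the downstream array by steric
exclusion (`infer_anchoring_potential()`, `full_model_energy()`).

A first-class synthetic-data generator (`simulate_mnase_experiment()`)
plants a known sequence-energy model, anchoring wells (depth 3 k\_BT at
dyad offset +60 from active TSS) and an A/T-driven sensitivity rule, draws
exact equilibrium configurations, and emits complete/partial digestion
fragment libraries with ground truth, so every stage is testable without
downloads.

## Worked example

```r
library(nucsense)

sim <- simulate_mnase_experiment(seed = 42)          # ~10 s, 2 x 200 kb
anchors <- subset(sim$genes, active, c(chrom, tss, strand))
names(anchors)[2] <- "pos"

# invert the observed dyad density and fit the sequence-energy model
prof <- normalize_per_chromosome(dyads_1n(sim$fragments$all_1n))
den  <- dyad_profile_to_density(smooth_moving_average(prof, 21), coverage = 0.8)
fit  <- fit_sequence_model(invert_density(den), sim$genome_obj$genome)
u_seq <- predict_sequence_energy(fit, sim$genome_obj$genome)
cor(unlist(u_seq$u), unlist(sim$truth$u_seq$u))
#> [1] 0.9993876

# recover the planted anchoring well at the +1 nucleosome
phi <- infer_anchoring_potential(prof, anchors, W = 1000, coverage = 0.8)
anchoring_well(phi)
#> $offset
#> [1] 60
#> $depth
#> [1] 2.964
```

The correlation of 0.999 says the pipeline (dyads → smoothing → exact
inversion → ridge fit → prediction) recovers the planted sequence
energetics essentially perfectly at this depth; the well is located at the
planted +60 bp dyad offset with depth within ~1% of the planted 3 k\_BT.

`run_pipeline(list(seed = 42, outdir = "out"))` runs every stage
(simulation, profiles, classification, sequence statistics, NRL, model) on
one config, writing bedGraph/TSV/JSON outputs plus a manifest with
parameter hashes and stage-level caching.

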