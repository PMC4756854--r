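# Shared fixtures, built in code. Simulations are memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

# full-scale synthetic experiment at the default study conditions
default_sim <- function() {
  if (is.null(.fixture_cache$default))
    .fixture_cache$default <- simulate_mnase_experiment(seed = 42)
  .fixture_cache$default
}

# small, fast experiment for module-level tests
tiny_sim <- function() {
  if (is.null(.fixture_cache$tiny))
    .fixture_cache$tiny <- simulate_mnase_experiment(
      seed = 7, n_chroms = 1L, chrom_length = 30000L,
      n_high_1n = 15000L, n_low_total = 30000L)
  .fixture_cache$tiny
}

active_anchors <- function(sim) {
  a <- sim$genes[sim$genes$active, c("chrom", "tss", "strand")]
  names(a)[2] <- "pos"
  a
}

silent_anchors <- function(sim) {
  a <- sim$genes[!sim$genes$active, c("chrom", "tss", "strand")]
  names(a)[2] <- "pos"
  a
}

norm_dyads <- function(fs) normalize_per_chromosome(dyads_1n(fs))

combined_low_profile <- function(sim) {
  normalize_per_chromosome(combine_profiles(dyads_1n(sim$fragments$low_1n),
                                            dyads_2n(sim$fragments$low_2n)))
}

# brute-force hard-rod density by exhaustive configuration enumeration
enum_density <- function(u, a, beta_mu) {
  S <- length(u)
  w <- exp(beta_mu - u)
  Z <- 0
  res <- numeric(S)
  recurse <- function(minstart, curprod, cur) {
    Z <<- Z + curprod
    for (s in cur) res[s] <<- res[s] + curprod
    if (minstart > S) return(invisible())
    for (s in minstart:S) recurse(s + a, curprod * w[s], c(cur, s))
  }
  recurse(1, 1, integer(0))
  res / Z
}

# local maxima rising above min_height times the segment mean, greedily
# enforcing a minimum separation
find_peaks <- function(v, offsets, min_height, min_sep = 120) {
  i <- which(diff(sign(diff(v))) < 0) + 1
  i <- i[v[i] > min_height * mean(v)]
  keep <- integer(0)
  for (j in i[order(v[i], decreasing = TRUE)])
    if (!length(keep) || all(abs(offsets[keep] - offsets[j]) >= min_sep))
      keep <- c(keep, j)
  sort(offsets[keep])
}

# the pipeline's parameter-recovery chain: dyads of a mononucleosome
# library -> normalized + smoothed profile -> absolute start density ->
# exact inversion -> ridge sequence fit -> predicted energies
recover_sequence_energies <- function(sim, fragments) {
  prof <- normalize_per_chromosome(dyads_1n(fragments))
  sm <- smooth_moving_average(prof, span = 21)
  den <- dyad_profile_to_density(sm, coverage = 0.8)
  u_inf <- invert_density(den, beta_mu = 0)
  fit <- fit_sequence_model(u_inf, sim$genome_obj$genome)
  list(fit = fit,
       u_seq = predict_sequence_energy(fit, sim$genome_obj$genome))
}
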