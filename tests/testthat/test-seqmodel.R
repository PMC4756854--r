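test_that("sequence features count mono- and dinucleotides", {
  g <- c(chr1 = "AAAACGTGGGCC")
  f <- sequence_features(g, "chr1", 0, a = 4)
  expect_equal(unname(f["A"]), 4)
  expect_equal(unname(f["AA"]), 3)
  f2 <- sequence_features(g, "chr1", 3, a = 4)  # "ACGT"
  expect_equal(unname(f2[c("A", "C", "G", "T")]), rep(1, 4))
  expect_equal(unname(f2[c("AC", "CG", "GT")]), rep(1, 3))

  set.seed(4)
  gr <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                       collapse = ""))
  for (s in sample(0:(3000 - 147), 5)) {
    f3 <- sequence_features(gr, "chr1", s, a = 147)
    expect_equal(sum(f3[1:4]), 147)
    expect_equal(sum(f3[5:20]), 146)
  }
  gn <- c(chr1 = "AANA")
  expect_null(sequence_features(gn, "chr1", 0, a = 4))
})

test_that("ridge fit recovers a planted model exactly without noise", {
  sim <- tiny_sim()
  genome <- sim$genome_obj$genome
  planted <- planted_sequence_model()
  u_true <- predict_sequence_energy(planted, genome)
  fit <- fit_sequence_model(u_true, genome)
  pred <- predict_sequence_energy(fit, genome)
  expect_gt(cor(unlist(pred$u), unlist(u_true$u)), 0.999)
  expect_gt(fit$r_squared, 0.999)
})

test_that("fit gauge: constants move only the intercept", {
  sim <- tiny_sim()
  genome <- sim$genome_obj$genome
  S <- nchar(genome[[1]]) - 146L
  const <- energy_landscape(list(chr1 = rep(2.5, S)), a = 147L)
  fit <- fit_sequence_model(const, genome)
  expect_lt(sqrt(sum(c(fit$mono_coeffs, fit$di_coeffs)^2)), 1e-6)
  expect_equal(fit$intercept, 2.5, tolerance = 1e-6)

  planted <- predict_sequence_energy(planted_sequence_model(), genome)
  f0 <- fit_sequence_model(planted, genome)
  shifted <- planted
  shifted$u <- lapply(shifted$u, `+`, 3)
  f1 <- fit_sequence_model(shifted, genome)
  expect_equal(f1$intercept - f0$intercept, 3, tolerance = 1e-6)
  expect_equal(f1$mono_coeffs, f0$mono_coeffs, tolerance = 1e-6)
  expect_equal(f1$r_squared, f0$r_squared, tolerance = 1e-6)

  fs <- fit_sequence_model(planted, genome, symmetrize = TRUE)
  expect_equal(fs$mono_coeffs[["A"]], fs$mono_coeffs[["T"]])
  expect_equal(fs$di_coeffs[["AC"]], fs$di_coeffs[["GT"]])  # revcomp pair
})

test_that("prediction is linear and respects zero models", {
  g <- tiny_sim()$genome_obj$genome
  zero <- planted_sequence_model()
  zero$mono_coeffs[] <- 0; zero$di_coeffs[] <- 0; zero$intercept <- 1.5
  pz <- predict_sequence_energy(zero, g)
  expect_true(all(abs(unlist(pz$u) - 1.5) < 1e-12))

  a <- planted_sequence_model()
  b <- planted_sequence_model()
  b$mono_coeffs <- c(A = 0.01, C = 0.02, G = -0.01, T = 0)
  b$intercept <- 0
  ab <- planted_sequence_model()
  ab$mono_coeffs <- a$mono_coeffs + b$mono_coeffs
  ab$di_coeffs <- a$di_coeffs + b$di_coeffs
  expect_equal(unlist(predict_sequence_energy(a, g)$u) +
                 unlist(predict_sequence_energy(b, g)$u),
               unlist(predict_sequence_energy(ab, g)$u),
               tolerance = 1e-10)
})

test_that("a flat dyad profile yields a flat anchoring potential", {
  p <- bp_profile(list(chr1 = rep(1, 10000)), kind = "dyad")
  p$normalized <- TRUE
  anch <- data.frame(chrom = "chr1", pos = 5000L, strand = "+")
  phi <- infer_anchoring_potential(p, anch, W = 1000)
  expect_lt(max(abs(phi$phi)), 0.02)
})

test_that("anchoring recovery on planted wells (location and depth)", {
  sim <- tiny_sim()
  prof <- norm_dyads(sim$fragments$all_1n)
  phi <- infer_anchoring_potential(prof, active_anchors(sim), W = 1000)
  w <- anchoring_well(phi)
  expect_lte(abs(w$offset - 60), 5)
  expect_lt(abs(w$depth - 3) / 3, 0.2)
})

test_that("full model adds the potential at strand-oriented dyad offsets", {
  S <- 2000L - 147L + 1L
  u_seq <- energy_landscape(list(chr1 = rep(0.4, S), chrEmpty = rep(0, S)),
                            a = 147L)
  phi <- planted_anchoring_potential()
  plus <- data.frame(chrom = "chr1", pos = 700L, strand = "+")
  uf <- full_model_energy(u_seq, phi, plus)
  expect_equal(uf$u$chrEmpty, u_seq$u$chrEmpty)  # gene-free chromosome
  s60 <- 700L + 60L - 73L   # start whose dyad is TSS+60
  expect_equal(uf$u$chr1[s60 + 1], 0.4 - 3, tolerance = 1e-9)

  minus <- data.frame(chrom = "chr1", pos = 700L, strand = "-")
  um <- full_model_energy(u_seq, phi, minus)
  sm60 <- 700L - 60L - 73L  # downstream on minus strand is genome-left
  expect_equal(um$u$chr1[sm60 + 1], 0.4 - 3, tolerance = 1e-9)
})

test_that("evaluate_models gives r = 1 when observed equals the model", {
  set.seed(17)
  S <- 6000L - 147L + 1L
  u <- energy_landscape(list(chr1 = runif(S, -0.5, 0.5)), a = 147L,
                        beta_mu = 1)
  den <- forward_solve(u)
  obs <- bp_profile(list(chr1 = start_to_dyad(den$n$chr1, 147L, 6000L)),
                    kind = "dyad")
  anch <- data.frame(chrom = "chr1", pos = 3000L, strand = "+")
  ev <- evaluate_models(obs, list(self = u), anch, beta_mu_grid = 1,
                        W = 1000)
  expect_equal(ev$r_dyad, 1, tolerance = 1e-9)
  expect_equal(ev$r_occupancy, 1, tolerance = 1e-9)
})

test_that("class-wise energy means are shift-invariant with defined signs", {
  sim <- tiny_sim()
  occ_high <- normalize_per_chromosome(occupancy(sim$fragments$high_1n))
  occ_low <- normalize_per_chromosome(occupancy(sim$fragments$low_1n))
  occ_tot <- normalize_per_chromosome(
    bp_profile(Map(`+`, occupancy(sim$fragments$low_1n)$values,
                   occupancy(sim$fragments$low_2n)$values),
               kind = "occupancy"))
  cm <- classify_chromatin(occ_high, occ_low, occ_tot)
  u <- sim$truth$u_seq
  eb <- energy_by_class(u, cm, "sensitivity")
  expect_gt(eb$difference, 0)  # sensitive (A/T-rich) less stable
  u2 <- u; u2$u <- lapply(u2$u, `+`, 5)
  eb2 <- energy_by_class(u2, cm, "sensitivity")
  expect_equal(eb2$difference, eb$difference, tolerance = 1e-9)
  expect_equal(eb2$means, eb$means, tolerance = 1e-9)
})
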