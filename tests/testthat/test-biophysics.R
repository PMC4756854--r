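test_that("analytic partition functions: single-site and two-rod lattices", {
  # L = a: empty or one rod, n(0) = 1/2 at u = 0, beta_mu = 0
  el <- energy_landscape(list(c1 = 0), a = 147L, beta_mu = 0,
                         chrom_sizes = c(c1 = 147L))
  d <- forward_solve(el)
  expect_equal(d$n$c1, 0.5)
  expect_equal(unique(round(d$O$c1, 12)), 0.5)

  # L = 2a, u = 0: Z = 1 empty + 148 single + 1 double = 150
  el2 <- energy_landscape(list(c1 = rep(0, 148)), a = 147L, beta_mu = 0)
  d2 <- forward_solve(el2)
  expect_equal(exp(unname(attr(d2, "logZ")["c1"])), 150, tolerance = 1e-12)
  expect_equal(d2$n$c1[1], 2 / 150, tolerance = 1e-12)
})

test_that("forward solver matches exhaustive enumeration on seeded landscapes", {
  set.seed(99)
  for (rep in 1:50) {
    a <- sample(2:4, 1)
    L <- sample((2 * a):16, 1)
    u <- runif(L - a + 1, -1, 1)
    bm <- runif(1, -1, 1)
    el <- energy_landscape(list(c1 = u), a = a, beta_mu = bm)
    n <- forward_solve(el)$n$c1
    expect_lt(max(abs(n - enum_density(u, a, bm))), 1e-12)
  }
})

test_that("Percus inversion is the exact inverse of the forward solver", {
  set.seed(1)
  u <- rnorm(10000 - 147 + 1, sd = 0.5)
  el <- energy_landscape(list(c1 = u), a = 147L, beta_mu = 2)
  d <- forward_solve(el)
  inv <- invert_density(d, beta_mu = 2)
  expect_lt(max(abs(inv$u$c1 - u)), 1e-8)
  d2 <- forward_solve(inv)
  expect_lt(max(abs(d2$n$c1 - d$n$c1)), 1e-8)

  # constant-field consistency
  elc <- energy_landscape(list(c1 = rep(1.3, 500)), a = 147L, beta_mu = 0)
  invc <- invert_density(forward_solve(elc), beta_mu = 0)
  expect_equal(invc$u$c1, rep(1.3, 500), tolerance = 1e-9)
})

test_that("uniform density gives the closed-form conditional probability", {
  nunif <- rep(1 / 294, 294 * 4 - 147 + 1)
  sd0 <- start_density(list(c1 = nunif), a = 147L)
  p <- start_p(sd0)$c1
  interior <- 200:800
  expect_equal(p[interior], rep(1 / 148, length(interior)),
               tolerance = 1e-12)
})

test_that("unphysical densities are rejected; near-zero densities flagged", {
  nbad <- rep(1 / 100, 1000)  # occupancy would reach 1.47
  expect_error(invert_density(start_density(list(c1 = nbad), a = 147L)),
               "unphysical")
  nz <- rep(1 / 400, 500); nz[200] <- 0
  inv <- invert_density(start_density(list(c1 = nz), a = 147L))
  expect_equal(attr(inv, "floored")$c1, 199L)
  expect_true(all(is.finite(inv$u$c1)))
})

test_that("gauge shift of energies and chemical potential leaves n unchanged", {
  set.seed(8)
  u <- runif(300, -1, 1)
  el1 <- energy_landscape(list(c1 = u), a = 10L, beta_mu = 0.7)
  el2 <- energy_landscape(list(c1 = u + 1.234), a = 10L,
                          beta_mu = 0.7 + 1.234)
  expect_equal(forward_solve(el1)$n, forward_solve(el2)$n,
               tolerance = 1e-12)
})

test_that("dyad/start index shifts are exact inverses and conserve mass", {
  v <- numeric(500); v[74] <- 2; v[300] <- 1
  s <- dyad_to_start(v, 147L)
  expect_equal(s[1], 2)          # dyad 73 (0-based) is start 0
  expect_equal(sum(s), sum(v))   # all mass interior here
  expect_equal(start_to_dyad(s, 147L, 500L), v)
  expect_error(dyad_to_start(v, 146L), "odd")
})

test_that("chemical-potential calibration reaches target coverage monotonically", {
  el <- energy_landscape(list(c1 = rep(0, 294 * 10)), a = 147L)
  bm <- calibrate_mu(el, 0.5)
  expect_lt(abs(attr(bm, "coverage") - 0.5), 1e-4)
  bm8 <- calibrate_mu(el, 0.8)
  expect_gt(as.numeric(bm8), as.numeric(bm))
  expect_lt(abs(attr(bm8, "coverage") - 0.8), 1e-4)
})

test_that("coverage sweeps are monotone in the chemical potential", {
  set.seed(13)
  el <- energy_landscape(list(c1 = runif(1000, -0.5, 0.5)), a = 147L)
  sw <- sweep_mu(el, c(-2, 0, 2, 4))
  cov <- vapply(sw, mean_coverage, numeric(1))
  expect_true(all(diff(cov) > 0))
  expect_true(all(unlist(lapply(sw, `[[`, "O")) <= 1))
  # beta_mu -> -infinity empties the lattice
  el$beta_mu <- -30
  expect_lt(max(forward_solve(el)$n$c1), 1e-10)
  expect_error(sweep_mu(el, numeric(0)), "nonempty")
})

test_that("long uniform lattices approach the Tonks-gas density", {
  el <- energy_landscape(list(c1 = rep(0, 50000)), a = 147L, beta_mu = 0)
  n <- forward_solve(el)$n$c1
  interior <- 2000:48000
  expect_lt(sd(n[interior]) / mean(n[interior]), 0.02)
})

test_that("configuration sampling reproduces the equilibrium density", {
  set.seed(42)
  u <- runif(28, -1, 1)  # a = 3, L = 30
  el <- energy_landscape(list(c1 = u), a = 3L, beta_mu = 0.5)
  n <- forward_solve(el)$n$c1
  cfg <- sample_configurations(el, 40000)$c1
  freq <- tabulate(cfg$start + 1L, nbins = 28) / 40000
  se <- sqrt(n * (1 - n) / 40000)
  expect_true(all(abs(freq - n) < 5 * se + 1e-4))
  # rods never overlap within a configuration
  by_cfg <- split(cfg$start, cfg$config)
  gaps <- unlist(lapply(by_cfg, function(s) diff(sort(s))))
  expect_true(all(gaps >= 3))
})

test_that("thermal energy reproduces printed values and rejects 0 K", {
  expect_equal(round(thermal_energy_kcal_per_mol(27), 2), 0.60)
  expect_equal(round(thermal_energy_kcal_per_mol(18), 2), 0.58)
  expect_error(thermal_energy_kcal_per_mol(-273.15), "absolute zero")
})

test_that("profile-to-density conversion clamps only unphysical hot spots", {
  v <- rep(1, 5000)
  v[2000:2200] <- 3   # hot region implying occupancy > 1 at coverage 0.8
  den <- dyad_profile_to_density(list(c1 = v), coverage = 0.8)
  expect_lte(max(den$O$c1), 0.98 + 1e-9)
  # far from the hot spot the scale is untouched
  expect_equal(den$n$c1[100], 0.8 / 147, tolerance = 1e-9)
  expect_error(dyad_profile_to_density(list(c1 = v), coverage = 0.8,
                                       o_max = NULL), "occupancy")
})
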