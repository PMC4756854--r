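make_fs <- function(frags, cs = c(chr1 = 2000L)) fragment_set(frags, cs)

test_that("1n dyads sit at fragment midpoints with the lower-median tie-break", {
  fs <- make_fs(data.frame(chrom = "chr1",
                           start = c(100L, 100L), end = c(247L, 248L)))
  d <- dyads_1n(fs)
  expect_equal(d$values$chr1[173 + 1], 2)  # odd 147 and even 148 both at 173
  expect_equal(sum(d$values$chr1), 2)

  # additivity: identical fragments accumulate counts
  fs10 <- make_fs(data.frame(chrom = "chr1", start = rep(100L, 10),
                             end = rep(247L, 10)))
  expect_equal(dyads_1n(fs10)$values$chr1[174], 10)
})

test_that("2n dyads at quarter points, restricted to the length window", {
  fs <- make_fs(data.frame(chrom = "chr1", start = c(1000L, 0L, 100L),
                           end = c(1360L, 250L, 420L)))
  d <- dyads_2n(fs)  # L = 360 kept; L = 250 dropped; L = 320 kept
  expect_equal(which(d$values$chr1 > 0) - 1L, c(180L, 340L, 1090L, 1270L))
  expect_equal(sum(d$values$chr1), 4)  # two dyads per retained fragment
})

test_that("occupancy counts covering fragments and conserves length mass", {
  fs <- make_fs(data.frame(chrom = "chr1", start = c(0L, 100L),
                           end = c(147L, 247L)))
  o <- occupancy(fs)
  expect_equal(o$values$chr1[1], 1)
  expect_equal(o$values$chr1[101], 2)     # overlap of both fragments
  expect_equal(o$values$chr1[148], 1)
  expect_equal(sum(o$values$chr1), sum(fragment_lengths(fs)))
})

test_that("per-chromosome normalization is exact and idempotent", {
  p <- bp_profile(list(c1 = rep(4, 100), c2 = c(0, 2)), kind = "dyad")
  n1 <- normalize_per_chromosome(p)
  expect_equal(n1$values$c1, rep(1, 100))
  expect_equal(n1$values$c2, c(0, 2))
  set.seed(3)
  pr <- bp_profile(list(c1 = runif(5000)), kind = "dyad")
  nr <- normalize_per_chromosome(pr)
  expect_equal(mean(nr$values$c1), 1, tolerance = 1e-12)
  expect_equal(normalize_per_chromosome(nr)$values, nr$values)
  expect_error(normalize_per_chromosome(
    bp_profile(list(c1 = numeric(10)), kind = "dyad")), "c1")
})

test_that("moving average keeps constants and ramps, spreads impulses", {
  expect_equal(smooth_moving_average(rep(5, 50), 21), rep(5, 50))
  imp <- numeric(101); imp[51] <- 1
  sm <- smooth_moving_average(imp, 21)
  expect_equal(sm[41:61], rep(1 / 21, 21))
  expect_equal(sum(sm), 1)
  ramp <- seq_len(200) * 0.5
  expect_equal(smooth_moving_average(ramp, 21), ramp)
  expect_error(smooth_moving_average(1:10, 4), "odd")
})

test_that("2D Gaussian smoothing preserves constants and symmetry", {
  m <- matrix(3.5, 20, 20)
  expect_equal(smooth_gaussian2d(m, 3), m)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  sm <- smooth_gaussian2d(imp, 3)
  expect_equal(sm[21, 21], 1 / (2 * pi * 9), tolerance = 0.01)
  expect_equal(sum(sm), 1, tolerance = 1e-5)
  expect_equal(sm, t(sm))
  # NA sentinels stay NA and do not leak into neighbours of a constant
  mna <- matrix(2, 15, 15); mna[4, 7] <- NA
  smna <- smooth_gaussian2d(mna, 2)
  expect_true(is.na(smna[4, 7]))
  expect_equal(smna[-4, ], matrix(2, 14, 15), ignore_attr = TRUE)
})

test_that("metagene rows are strand-oriented and edge-padded", {
  v <- seq(0, 999) / 1000
  p <- bp_profile(list(chr1 = v), kind = "dyad")
  anch <- data.frame(chrom = "chr1", pos = c(500L, 500L),
                     strand = c("+", "-"))
  mg <- metagene(p, anch, 10)
  expect_equal(mg[1, ], rev(mg[2, ]), ignore_attr = TRUE)
  expect_equal(unname(mg[1, "0"]), v[501])
  expect_equal(unname(mg[1, ]), v[491:511])

  # anchors near the chromosome edge get NA, excluded from column means
  mg2 <- metagene(p, data.frame(chrom = "chr1", pos = 3L, strand = "+"), 10)
  expect_true(all(is.na(mg2[1, 1:7])))
  cc <- bp_profile(list(chr1 = rep(1, 1000)), kind = "dyad")
  expect_equal(unname(metagene_average(metagene(cc, anch, 10))), rep(1, 21))
  expect_error(metagene(p, data.frame(chrom = "chrZ", pos = 5), 10),
               "unknown")
})

test_that("metagene of a mirror-symmetric profile is strand-independent", {
  v <- rep(1, 2000)
  centers <- c(300L, 900L, 1500L)
  for (cpos in centers) {
    off <- seq(-100, 100)
    v[cpos + off + 1] <- v[cpos + off + 1] + exp(-off^2 / 200)
  }
  p <- bp_profile(list(chr1 = v), kind = "dyad")
  plus <- data.frame(chrom = "chr1", pos = centers, strand = "+")
  minus <- data.frame(chrom = "chr1", pos = centers, strand = "-")
  expect_equal(metagene_average(metagene(p, plus, 150)),
               metagene_average(metagene(p, minus, 150)),
               ignore_attr = TRUE)
})

test_that("row sorting is stable, descending and idempotent", {
  m <- matrix(1:9, 3, 3)
  s <- sort_rows_by(m, c(1, 3, 2))
  expect_equal(attr(s, "order"), c(2L, 3L, 1L))
  s2 <- sort_rows_by(m, c(2, 1, 2))  # tie keeps input order
  expect_equal(attr(s2, "order"), c(1L, 3L, 2L))
  resort <- sort_rows_by(s, c(1, 3, 2)[attr(s, "order")])
  expect_equal(unname(resort[,]), unname(s[,]))
  expect_error(sort_rows_by(m, 1:2), "one sort value per row")
})

test_that("profile cross-correlation finds planted shifts", {
  set.seed(21)
  v <- as.numeric(stats::filter(rnorm(3000), rep(1, 10), sides = 2))
  v[is.na(v)] <- 0
  a <- bp_profile(list(c1 = v - min(v)), kind = "occupancy")
  r0 <- profile_crosscorrelation(a, a, 0)
  expect_equal(unname(r0["0"]), 1)

  shifted <- c(rep(mean(v - min(v)), 50), (v - min(v))[1:2950])
  b <- bp_profile(list(c1 = shifted), kind = "occupancy")
  r <- profile_crosscorrelation(a, b, 100)
  expect_equal(as.integer(names(which.max(r))), 50L)

  anti <- bp_profile(list(c1 = max(v) - v), kind = "occupancy")
  expect_equal(unname(profile_crosscorrelation(a, anti, 0)["0"]), -1)

  flat <- bp_profile(list(c1 = rep(2, 3000)), kind = "occupancy")
  expect_error(profile_crosscorrelation(a, flat, 5), "variance")
})

test_that("dyad counts are conserved through combination", {
  sim <- tiny_sim()
  d1 <- dyads_1n(sim$fragments$low_1n)
  d2 <- dyads_2n(sim$fragments$low_2n)
  comb <- combine_profiles(d1, d2)
  expect_equal(sum(unlist(comb$values)),
               sum(unlist(d1$values)) + sum(unlist(d2$values)))
  expect_equal(sum(unlist(d1$values)), n_fragments(sim$fragments$low_1n))
  len <- fragment_lengths(sim$fragments$low_2n)
  expect_equal(sum(unlist(d2$values)),
               2 * sum(len >= 320 & len <= 380))
})
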