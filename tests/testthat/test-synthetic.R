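test_that("genome generation is deterministic with clean block structure", {
  g1 <- generate_genome(3, n_chroms = 1, chrom_length = 20000)
  g2 <- generate_genome(3, n_chroms = 1, chrom_length = 20000)
  expect_identical(g1$genome, g2$genome)
  expect_false(grepl("[^ACGT]", g1$genome[["chr1"]]))
  # realized GC per block close to target
  s <- strsplit(g1$genome[["chr1"]], "")[[1]]
  for (k in seq_len(nrow(g1$blocks))) {
    b <- g1$blocks[k, ]
    gc <- mean(s[(b$start + 1):b$end] %in% c("G", "C"))
    expect_lt(abs(gc - b$gc), 0.03)
  }
  expect_equal(sum(g1$blocks$end - g1$blocks$start), 20000)
})

test_that("annotations are non-overlapping, strand-alternating, DHS-anchored", {
  sim <- tiny_sim()
  g <- sim$genes[order(sim$genes$chrom, sim$genes$start), ]
  by_chrom <- split(g, g$chrom)
  for (gc in by_chrom)
    if (nrow(gc) > 1)
      expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  # every active TSS within 200 bp of a DHS
  act <- sim$genes[sim$genes$active, ]
  for (i in seq_len(nrow(act))) {
    d <- sim$dhs[sim$dhs$chrom == act$chrom[i], ]
    expect_lt(min(pmax(d$start - act$tss[i], act$tss[i] - d$end + 1, 0)),
              200)
  }
  # expression is bimodal: silent exactly zero, active clearly positive
  expect_true(any(sim$genes$expression == 0))
  expect_gt(min(sim$genes$expression[sim$genes$active]), 1)
  dens <- density(log1p(sim$genes$expression))
  modes <- sum(diff(sign(diff(dens$y))) < 0)
  expect_gte(modes, 2)
})

test_that("planted landscape is calibrated and phases active promoters only", {
  # needs the full-scale study: with a handful of genes the gene-to-gene
  # phase differences that erase silent-gene ordering cannot average out
  sim <- default_sim()
  expect_equal(sim$truth$coverage, 0.8, tolerance = 0.01)
  # sequence energies alone are too weak to phase (< 1 kT scale)
  expect_lt(sd(unlist(sim$truth$u_seq$u)), 1)

  den <- sim$truth$density
  dy <- lapply(names(den$n), function(ch)
    start_to_dyad(den$n[[ch]], 147L, den$chrom_sizes[[ch]]))
  names(dy) <- names(den$n)
  prof <- normalize_per_chromosome(bp_profile(dy, kind = "dyad"))
  offs <- -500:900
  act <- smooth_moving_average(
    metagene_average(metagene(prof, active_anchors(sim), 900))[
      as.character(offs)], 21)
  sil <- smooth_moving_average(
    metagene_average(metagene(prof, silent_anchors(sim), 900))[
      as.character(offs)], 21)
  dw <- offs >= 0 & offs <= 800
  expect_gte(length(find_peaks(act[dw], offs[dw], 1.2)), 3)
  expect_equal(length(find_peaks(sil[dw], offs[dw], 1.2)), 0)
})

test_that("fragment libraries are deterministic and recover their dyads", {
  sim <- tiny_sim()
  f1 <- sample_fragments(99, sim$truth$density, sim$genome_obj, "LOW_1n",
                         5000)
  f2 <- sample_fragments(99, sim$truth$density, sim$genome_obj, "LOW_1n",
                         5000)
  expect_identical(f1$fragments, f2$fragments)
  expect_equal(n_fragments(f1), 5000L)

  # the 1n midpoint rule recovers every sampled dyad (fragments are stored
  # sorted, so compare as sorted multisets per chromosome)
  tr <- attr(f1, "truth")
  for (ch in unique(tr$chrom)) {
    fr <- f1$fragments[[ch]]
    mid <- (fr$start + fr$end - 1L) %/% 2L
    expect_gte(mean(abs(sort(mid) - sort(tr$dyad1[tr$chrom == ch])) <= 1),
               0.99)
  }

  # 2n: quarter-point placement recovers both dyads of adjacent pairs
  f3 <- sample_fragments(100, sim$truth$density, sim$genome_obj, "LOW_2n",
                         3000)
  tr3 <- attr(f3, "truth")
  for (ch in unique(tr3$chrom)) {
    fr3 <- f3$fragments[[ch]]
    L <- fr3$end - fr3$start
    expect_true(all(L >= 300 & L <= 400))
    rec <- data.frame(d1 = fr3$start + floor(L / 4 + 0.5),
                      d2 = fr3$start + floor(3 * L / 4 + 0.5))
    rec <- rec[order(rec$d1, rec$d2), ]
    tru <- tr3[tr3$chrom == ch, c("dyad1", "dyad2")]
    tru <- tru[order(tru$dyad1, tru$dyad2), ]
    expect_gte(mean(abs(rec$d1 - tru$dyad1) <= 1 &
                      abs(rec$d2 - tru$dyad2) <= 1), 0.99)
  }
  # adjacent nucleosomes cannot overlap
  expect_true(all(tr3$dyad2 - tr3$dyad1 >= 147))
})

test_that("fragment length distributions match the library design", {
  sim <- tiny_sim()
  len_h <- fragment_lengths(sim$fragments$high_1n)
  expect_equal(mean(len_h), 147, tolerance = 0.02)
  expect_true(all(len_h >= 120 & len_h <= 160))
  len_l <- fragment_lengths(sim$fragments$low_1n)
  expect_equal(mean(len_l), 165, tolerance = 0.02)
  expect_true(all(len_l >= 140 & len_l <= 190))
})

test_that("digestion selection depletes/enriches A/T-rich promoters", {
  sim <- tiny_sim()
  anch <- active_anchors(sim)
  up <- as.character(-300:-50)
  mgH <- metagene_average(metagene(norm_dyads(sim$fragments$high_1n),
                                   anch, 400))
  mgL <- metagene_average(metagene(norm_dyads(sim$fragments$low_1n),
                                   anch, 400))
  expect_gt(mean(mgL[up]), mean(mgH[up]))

  # sensitivity scores are the planted logistic of footprint A/T content
  sens <- sensitivity_scores(sim$genome_obj)
  at <- footprint_at_fraction(sim$genome_obj$genome)
  expect_equal(sens$chr1,
               1 / (1 + exp(-15 * (at$chr1 - 0.55))))
})

test_that("the written dataset reproduces bit-for-bit under one seed", {
  td1 <- file.path(tempdir(), "sda"); td2 <- file.path(tempdir(), "sdb")
  sim1 <- simulate_mnase_experiment(seed = 5, n_chroms = 1,
                                    chrom_length = 20000,
                                    n_high_1n = 3000, n_low_total = 6000)
  sim2 <- simulate_mnase_experiment(seed = 5, n_chroms = 1,
                                    chrom_length = 20000,
                                    n_high_1n = 3000, n_low_total = 6000)
  write_synthetic_dataset(sim1, td1)
  write_synthetic_dataset(sim2, td2)
  for (f in dir(td1))
    expect_identical(readLines(file.path(td1, f)),
                     readLines(file.path(td2, f)), label = f)
})
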