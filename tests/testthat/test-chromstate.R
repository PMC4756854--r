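mk_prof <- function(v, kind = "occupancy") {
  p <- bp_profile(list(chr1 = v), kind = kind)
  p$normalized <- TRUE
  p
}

test_that("threshold classification follows the occupancy-difference rule", {
  tot <- mk_prof(rep(1, 6))
  high <- mk_prof(c(1.3, 1.0, 0.7, 1.25, 1.2, 0.74))
  low <- mk_prof(c(1.0, 1.0, 0.6, 1.0, 1.3, 1.0))
  cm <- classify_chromatin(high, low, tot, theta = 0.25)
  sens_labels <- c("resistant", "sensitive", "unclassified")
  acc_labels <- c("open", "closed", "unclassified")
  expect_equal(sens_labels[cm$sensitivity$chr1],
               c("resistant", "unclassified", "sensitive", "unclassified",
                 "unclassified", "sensitive"))
  expect_equal(acc_labels[cm$accessibility$chr1],
               c("unclassified", "unclassified", "closed", "unclassified",
                 "open", "unclassified"))
  un <- bp_profile(list(chr1 = rep(1, 6)), kind = "occupancy")
  expect_error(classify_chromatin(un, low, tot), "normalized")
})

test_that("swapping the profile pair swaps resistant and sensitive exactly", {
  set.seed(31)
  tot <- mk_prof(runif(500, 0.5, 1.5))
  high <- mk_prof(runif(500, 0.5, 1.5))
  low <- mk_prof(rep(1, 500))
  cm1 <- classify_chromatin(high, low, tot)
  cm2 <- classify_chromatin(tot, low, high)
  m1 <- cm1$sensitivity$chr1
  m2 <- cm2$sensitivity$chr1
  expect_equal(m2[m1 == 1], rep(2L, sum(m1 == 1)))
  expect_equal(m2[m1 == 2], rep(1L, sum(m1 == 2)))
  expect_equal(m2[m1 == 3], rep(3L, sum(m1 == 3)))
})

test_that("raising theta only shrinks the classified sets", {
  set.seed(32)
  tot <- mk_prof(runif(2000, 0.5, 1.5))
  high <- mk_prof(runif(2000, 0.5, 1.5))
  low <- mk_prof(runif(2000, 0.5, 1.5))
  prev <- classify_chromatin(high, low, tot, theta = 0.1)
  for (th in c(0.25, 0.5, 1)) {
    cur <- classify_chromatin(high, low, tot, theta = th)
    for (ax in c("sensitivity", "accessibility")) {
      was_classified <- prev[[ax]]$chr1 != 3L
      now_classified <- cur[[ax]]$chr1 != 3L
      expect_true(all(!now_classified | was_classified))
      # labels never flip between resistant and sensitive
      both <- was_classified & now_classified
      expect_equal(cur[[ax]]$chr1[both], prev[[ax]]$chr1[both])
    }
    prev <- cur
  }
})

test_that("overlap summary reflects planted containment", {
  tot <- mk_prof(rep(1, 100))
  # sensitive subset of open: both driven by the same depletion of high/low
  high <- mk_prof(c(rep(0.5, 40), rep(1, 60)))
  low <- mk_prof(c(rep(1.5, 50), rep(1, 50)))
  cm <- classify_chromatin(high, low, tot)
  ov <- overlap_summary(cm)
  expect_equal(ov$fraction_open_sensitive, 40 / 50)
  expect_equal(unname(ov$counts["sensitive", "open"]), 40)
  # disjoint planting
  high2 <- mk_prof(c(rep(0.5, 40), rep(1, 60)))
  low2 <- mk_prof(c(rep(1, 60), rep(1.5, 40)))
  ov2 <- overlap_summary(classify_chromatin(high2, low2, tot))
  expect_equal(unname(ov2$counts["sensitive", "open"]), 0)
})

test_that("region composition fractions sum to one per axis", {
  tot <- mk_prof(rep(1, 100))
  high <- mk_prof(c(rep(1.3, 30), rep(1, 70)))
  low <- mk_prof(rep(1, 100))
  cm <- classify_chromatin(high, low, tot)
  rc <- region_composition(cm, list(all = data.frame(chrom = "chr1",
                                                     start = 0, end = 100),
                                    front = data.frame(chrom = "chr1",
                                                       start = 0, end = 30)))
  sums <- tapply(rc$fraction, interaction(rc$annotation, rc$axis), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  front_res <- rc[rc$annotation == "front" & rc$axis == "sensitivity" &
                    rc$label == "resistant", ]
  expect_equal(front_res$fraction, 1)
})

test_that("gene activity calls separate bimodal expression", {
  ac <- classify_gene_activity(c(0, 0, 0, 100, 100))
  expect_equal(sum(ac$active), 2)
  expect_equal(ac$boundary, 2)
  expect_true(all(!classify_gene_activity(c(0, 0, 0, 0))$active))
  expect_true(all(classify_gene_activity(c(5, 5, 5))$active))
  sim <- tiny_sim()
  ac2 <- classify_gene_activity(sim$genes$expression)
  expect_gte(mean(ac2$active == sim$genes$active), 0.95)
})

test_that("DHS-TSS distances use edges and half-open containment", {
  dhs <- data.frame(chrom = "chr1",
                    start = c(100L, 5000L, 20000L),
                    end = c(300L, 5200L, 20100L))
  tss <- data.frame(chrom = "chr1", pos = c(150L, 6400L))
  s <- dhs_tss_overlap_summary(dhs, tss, distances = c(1000, 5000))
  expect_equal(s$total, 3L)
  expect_equal(s$contains, 1L)
  expect_equal(s$distance, c(0, 6400 - 5199, 20000 - 6400))
  expect_equal(s$n_ge_1000, 2L)  # the containing DHS is excluded
  expect_equal(s$n_ge_5000, 1L)
  # percentages recompute from their own counts at 1 decimal place
  expect_equal(s$pct_contains, round(100 * s$contains / s$total, 1))
  expect_equal(s$pct_ge_1000, round(100 * s$n_ge_1000 / s$total, 1))
})

test_that("class maps export as label runs in BED", {
  tot <- mk_prof(rep(1, 10))
  high <- mk_prof(c(rep(1.5, 4), rep(1, 3), rep(0.5, 3)))
  low <- mk_prof(rep(1, 10))
  cm <- classify_chromatin(high, low, tot)
  path <- tempfile(fileext = ".bed")
  write_class_bed(cm, path, "sensitivity")
  tab <- read.table(path, sep = "\t")
  expect_equal(tab$V4, c("resistant", "unclassified", "sensitive"))
  expect_equal(tab$V2, c(0, 4, 7))
  expect_equal(tab$V3, c(4, 7, 10))
})
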