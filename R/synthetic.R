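# Synthetic MNase-seq experiment with planted ground truth: a toy genome
# with heterogeneous GC blocks, genes with bimodal expression coupled to
# promoter A/T content, a planted sequence-energy model plus anchoring
# wells at active TSS, equilibrium nucleosome placement, and fragment
# libraries emulating complete (high-concentration) and partial
# (low-concentration) digestion with A/T-driven MNase sensitivity.

# evaluate expr under a fixed RNG state, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a toy genome with blockwise GC content
#'
#' Chromosomes are concatenations of blocks of 2--10 kb whose GC content is
#' drawn uniformly from \code{gc_range}; bases are sampled independently
#' within each block. No ambiguous bases are emitted. Deterministic under
#' the seed.
#'
#' @param seed Integer seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (>= 10000).
#' @param gc_range GC-content range of the blocks.
#' @param block_range Block length range in bp.
#' @return List with genome (named character vector of sequences) and
#'   blocks (data.frame chrom, start, end, gc; 0-based half-open).
#' @export
generate_genome <- function(seed, n_chroms = 2L, chrom_length = 200000L,
                            gc_range = c(0.30, 0.60),
                            block_range = c(2000L, 10000L)) {
  if (chrom_length < 10000) stop("chrom_length must be >= 10000")
  .with_seed(seed, {
    genome <- character(0)
    blocks <- list()
    for (ci in seq_len(n_chroms)) {
      ch <- paste0("chr", ci)
      pos <- 0L
      seqs <- list()
      while (pos < chrom_length) {
        len <- min(round(runif(1, block_range[1], block_range[2])),
                   chrom_length - pos)
        gc <- runif(1, gc_range[1], gc_range[2])
        b <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
        seqs[[length(seqs) + 1]] <- paste(b, collapse = "")
        blocks[[length(blocks) + 1]] <-
          data.frame(chrom = ch, start = pos, end = pos + len, gc = gc)
        pos <- pos + len
      }
      genome[[ch]] <- paste(unlist(seqs), collapse = "")
    }
    list(genome = genome, blocks = do.call(rbind, blocks))
  })
}

#' Generate gene and DHS annotations for a synthetic genome
#'
#' Genes are non-overlapping, strand-alternating, and placed inside GC
#' blocks so that a gene's promoter, body and terminator share the block's
#' base composition. Genes in A/T-rich blocks (GC below
#' \code{gc_active_max}) are active with log-normal expression; all other
#' genes are silent with expression exactly 0, yielding the bimodal
#' expression distribution typical of a homogeneous cell population. A DHS
#' interval is planted over every active promoter (so every active TSS lies
#' within a DHS), plus a smaller number of gene-distal DHS in A/T-rich
#' blocks.
#'
#' @param seed Integer seed.
#' @param genome_obj Output of \code{\link{generate_genome}}.
#' @param genes_per_chrom Target gene count per chromosome.
#' @param gene_length_range Gene length range in bp.
#' @param gc_active_max GC cutoff below which a block is A/T-rich.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of active-gene
#'   expression.
#' @return List with genes (data.frame id, chrom, start, end, strand, tss,
#'   tts, expression, active) and dhs (data.frame chrom, start, end, name).
#' @export
generate_annotations <- function(seed, genome_obj, genes_per_chrom = 50L,
                                 gene_length_range = c(1200L, 2400L),
                                 gc_active_max = 0.45,
                                 expr_meanlog = 3, expr_sdlog = 0.7) {
  blocks <- genome_obj$blocks
  .with_seed(seed, {
    genes <- list(); dhs <- list(); gid <- 0L
    for (ch in names(genome_obj$genome)) {
      bsub <- blocks[blocks$chrom == ch, , drop = FALSE]
      cand <- list()
      for (k in seq_len(nrow(bsub))) {
        b <- bsub[k, ]
        pos <- b$start + 300L
        for (slot in 1:2) {   # at most two genes per block
          len <- round(runif(1, gene_length_range[1], gene_length_range[2]))
          if (pos + len + 300L > b$end) break
          cand[[length(cand) + 1]] <- data.frame(
            chrom = ch, start = pos, end = pos + len, gc = b$gc)
          pos <- pos + len + round(runif(1, 400, 800))
        }
      }
      cand <- do.call(rbind, cand)
      if (nrow(cand) > genes_per_chrom)
        cand <- cand[sort(sample.int(nrow(cand), genes_per_chrom)), ,
                     drop = FALSE]
      strand <- rep(c("+", "-"), length.out = nrow(cand))
      for (k in seq_len(nrow(cand))) {
        gid <- gid + 1L
        active <- cand$gc[k] < gc_active_max
        expr <- if (active) rlnorm(1, expr_meanlog, expr_sdlog) else 0
        pos <- .derive_tss_tts(cand$start[k], cand$end[k], strand[k])
        genes[[gid]] <- data.frame(
          id = sprintf("g%04d", gid), chrom = ch,
          start = cand$start[k], end = cand$end[k], strand = strand[k],
          tss = pos$tss, tts = pos$tts,
          expression = expr, active = active)
        if (active)
          dhs[[length(dhs) + 1]] <- data.frame(
            chrom = ch, start = pos$tss - 100L, end = pos$tss + 100L)
      }
      # gene-distal DHS in A/T-rich blocks, at least 1 kb from any gene
      at_blocks <- bsub[bsub$gc < gc_active_max, , drop = FALSE]
      gsub <- do.call(rbind, genes)
      gsub <- gsub[gsub$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(at_blocks))) {
        if (runif(1) > 0.35) next
        b <- at_blocks[k, ]
        if (b$end - b$start < 1000) next
        p <- round(runif(1, b$start + 200, b$end - 400))
        if (nrow(gsub) &&
            min(abs(c(gsub$start, gsub$end) - p)) < 1000) next
        dhs[[length(dhs) + 1]] <- data.frame(
          chrom = ch, start = p, end = p + round(runif(1, 150, 300)))
      }
    }
    genes <- do.call(rbind, genes)
    rownames(genes) <- NULL
    dhs <- do.call(rbind, dhs)
    dhs <- dhs[order(dhs$chrom, dhs$start), , drop = FALSE]
    dhs$name <- sprintf("dhs%04d", seq_len(nrow(dhs)))
    rownames(dhs) <- NULL
    list(genes = genes, dhs = dhs)
  })
}

#' Planted sequence-energy model
#'
#' Mono- and dinucleotide coefficients chosen so that A/T-rich footprints
#' have higher (less favorable) formation energy, with a weak WW/SS
#' dinucleotide texture; the genome-wide standard deviation of the
#' resulting energies is below 1 kT, so sequence alone cannot phase
#' nucleosome arrays.
#'
#' @param a Footprint in bp.
#' @return A \code{sequence_energy_model}.
#' @export
planted_sequence_model <- function(a = 147L) {
  mono <- c(A = 0.02, C = -0.02, G = -0.02, T = 0.02)
  di <- stats::setNames(numeric(16), .DINUCS)
  di[.WW] <- 0.004
  di[.SS] <- -0.004
  structure(list(intercept = 0, mono_coeffs = mono, di_coeffs = di,
                 a = a, ridge_lambda = 0, r_squared = NA_real_,
                 n_samples = 0L),
            class = "sequence_energy_model")
}

#' Planted anchoring potential
#'
#' A Gaussian well centered at dyad offset +60 bp downstream of the TSS
#' (depth 3 kT, sigma 20 bp), truncated at five sigma.
#'
#' @param depth Well depth in kT.
#' @param center Well center in dyad bp downstream of the TSS.
#' @param sigma Gaussian width in bp.
#' @return An \code{anchoring_potential} (baseline 0, minimum -depth).
#' @export
planted_anchoring_potential <- function(depth = 3, center = 60L,
                                        sigma = 20) {
  offsets <- seq(center - 5 * sigma, center + 5 * sigma)
  phi <- -depth * exp(-(offsets - center)^2 / (2 * sigma^2))
  structure(list(offsets = offsets, phi = phi),
            class = "anchoring_potential")
}

#' Plant the energy landscape and solve for the equilibrium density
#'
#' The true landscape is the planted sequence model evaluated on the genome
#' plus the planted anchoring well at every active TSS; the chemical
#' potential is calibrated so that nucleosomes cover the target fraction of
#' the genome, and the equilibrium start density is computed exactly.
#'
#' @param genome_obj Output of \code{\link{generate_genome}}.
#' @param genes Gene table from \code{\link{generate_annotations}}.
#' @param coverage Target genome-wide nucleosome coverage (default 0.8).
#' @param a Footprint in bp.
#' @param well_depth,well_center,well_sigma Anchoring-well parameters.
#' @return List with model (planted \code{sequence_energy_model}), phi
#'   (planted \code{anchoring_potential}), u_seq, u_full
#'   (\code{energy_landscape}s), beta_mu, and density
#'   (\code{start_density}).
#' @export
plant_energy_and_density <- function(genome_obj, genes, coverage = 0.8,
                                     a = 147L, well_depth = 3,
                                     well_center = 60L, well_sigma = 20) {
  model <- planted_sequence_model(a)
  phi <- planted_anchoring_potential(well_depth, well_center, well_sigma)
  u_seq <- predict_sequence_energy(model, genome_obj$genome)
  anchors <- genes[genes$active, c("chrom", "tss", "strand")]
  names(anchors)[2] <- "pos"
  u_full <- if (nrow(anchors)) full_model_energy(u_seq, phi, anchors)
            else u_seq
  beta_mu <- calibrate_mu(u_full, target_coverage = coverage)
  u_full$beta_mu <- as.numeric(beta_mu)
  density <- forward_solve(u_full)
  list(model = model, phi = phi, u_seq = u_seq, u_full = u_full,
       beta_mu = as.numeric(beta_mu), density = density,
       coverage = attr(beta_mu, "coverage"))
}

#' MNase-sensitivity scores of all nucleosome positions
#'
#' Sensitivity is a planted deterministic function of the footprint A/T
#' fraction: a logistic \code{1 / (1 + exp(-k (AT - AT0)))} with k = 15 and
#' midpoint AT0 = 0.55, so A/T-rich nucleosomes are MNase-sensitive. This
#' is the simplest mechanism consistent with the observed A/T-dependence of
#' differential digestion; it does not model MNase enzymology.
#'
#' @param genome_obj Output of \code{\link{generate_genome}} (or a genome
#'   accepted by \code{\link{footprint_at_fraction}}).
#' @param a Footprint in bp.
#' @param k Logistic steepness.
#' @param at0 Logistic midpoint A/T fraction.
#' @return Named list of per-start sensitivity vectors in [0, 1].
#' @export
sensitivity_scores <- function(genome_obj, a = 147L, k = 15, at0 = 0.55) {
  genome <- if (is.list(genome_obj) && !is.null(genome_obj$genome))
    genome_obj$genome else genome_obj
  at <- footprint_at_fraction(genome, a)
  lapply(at, function(f) 1 / (1 + exp(-k * (f - at0))))
}

# truncated-normal lengths by resampling
.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- round(rnorm(n, mean, sd))
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Sample a fragment library from the equilibrium density
#'
#' Exact equilibrium nucleosome configurations are drawn with
#' \code{\link{sample_configurations}} (the landscape is recovered from the
#' density by the exact inversion) and fragments are harvested from them
#' with library-specific retention:
#' \itemize{
#'   \item HIGH_1n (complete digestion): each placed nucleosome yields a
#'     mononucleosome fragment with probability 1 - sensitivity;
#'   \item LOW_1n (partial digestion): with probability sensitivity --
#'     MNase-sensitive chromatin is the part that partial digestion already
#'     cuts to mononucleosomes;
#'   \item ALL_1n: retention 1 for every nucleosome -- an idealized
#'     selection-free mononucleosome library representing all placed
#'     nucleosomes, used to validate the inference pipeline
#'     (dyads -> inversion -> sequence fit) independently of digestion
#'     selection;
#'   \item LOW_2n: adjacent nucleosome pairs within one configuration whose
#'     shared linker stayed uncut; a pair is retained with probability
#'     1 - mean pair sensitivity (dinucleosome fragments come from
#'     resistant chromatin), and its fragment length is twice the actual
#'     dyad spacing, gel-selected to the dinucleosome band (300--400 bp).
#' }
#' At 18C all sensitivity scores are multiplied by 0.2 before selection,
#' emulating the loss of MNase sensitivity at lower growth temperature.
#' Fragment lengths: HIGH_1n ~ Normal(147, 6) truncated to [120, 160];
#' LOW_1n ~ Normal(165, 8) truncated to [140, 190]. Each fragment is placed
#' so that the dyad rule (1n midpoint; 2n quarter points) recovers the
#' sampled dyad(s) up to rounding.
#'
#' @param seed Integer seed.
#' @param density \code{start_density} from
#'   \code{\link{plant_energy_and_density}}.
#' @param genome_obj Genome object (for sensitivity scores).
#' @param library "HIGH_1n", "LOW_1n", "LOW_2n" or "ALL_1n".
#' @param n_fragments Number of fragments to draw (> 0).
#' @param temperature "27C" or "18C".
#' @param band_2n Gel-selection window for dinucleosome fragment lengths.
#' @return A \code{fragment_set}; attribute "truth" is a data.frame with
#'   the sampled dyad position(s) and sensitivity score per fragment.
#' @export
sample_fragments <- function(seed, density, genome_obj,
                             library = c("HIGH_1n", "LOW_1n", "LOW_2n",
                                         "ALL_1n"),
                             n_fragments,
                             temperature = c("27C", "18C"),
                             band_2n = c(300L, 400L)) {
  library <- match.arg(library)
  temperature <- match.arg(temperature)
  stopifnot(inherits(density, "start_density"))
  if (n_fragments <= 0) stop("n_fragments must be positive")
  a <- density$a
  h <- (a - 1L) %/% 2L
  sens <- sensitivity_scores(genome_obj, a = a)
  tfac <- if (temperature == "18C") 0.2 else 1
  landscape <- invert_density(density, beta_mu = 0)

  # expected retained fragments per configuration, to size the batches
  e_per_cfg <- sum(vapply(names(density$n), function(ch) {
    s_eff <- sens[[ch]] * tfac
    ret <- switch(library, HIGH_1n = 1 - s_eff, LOW_1n = s_eff,
                  ALL_1n = rep(1, length(s_eff)),
                  LOW_2n = 0.5 * (1 - s_eff))
    sum(density$n[[ch]] * ret)
  }, numeric(1)))

  .with_seed(seed, {
    frags <- list(); truth <- list(); got <- 0L
    while (got < n_fragments) {
      k <- max(2L, ceiling((n_fragments - got) / max(e_per_cfg, 1) * 1.1))
      cfgs <- sample_configurations(landscape, k)
      for (ch in names(cfgs)) {
        cf <- cfgs[[ch]]
        if (nrow(cf) == 0) next
        L_ch <- density$chrom_sizes[[ch]]
        s_eff_all <- sens[[ch]] * tfac
        if (library != "LOW_2n") {
          s1 <- cf$start + 1L
          ret <- switch(library, HIGH_1n = 1 - s_eff_all[s1],
                        LOW_1n = s_eff_all[s1],
                        ALL_1n = rep(1, length(s1)))
          keep <- runif(length(s1)) < ret
          s1 <- s1[keep]
          if (!length(s1)) next
          d1 <- s1 - 1L + h
          len <- if (library == "LOW_1n")
            .rnorm_trunc(length(d1), 165, 8, 140, 190)
          else .rnorm_trunc(length(d1), 147, 6, 120, 160)
          fs <- d1 - (len - 1L) %/% 2L
          fe <- fs + len
          ok <- fs >= 0 & fe <= L_ch
          frags[[length(frags) + 1]] <-
            data.frame(chrom = ch, start = fs[ok], end = fe[ok])
          truth[[length(truth) + 1]] <-
            data.frame(chrom = ch, dyad1 = d1[ok], dyad2 = NA_integer_,
                       sensitivity = sens[[ch]][s1[ok]])
          got <- got + sum(ok)
        } else {
          # adjacent pairs within a configuration
          adj <- which(diff(cf$config) == 0)
          if (!length(adj)) next
          s1 <- cf$start[adj] + 1L
          s2 <- cf$start[adj + 1L] + 1L
          d1 <- s1 - 1L + h; d2 <- s2 - 1L + h
          len <- 2L * (d2 - d1)
          pair_sens <- (s_eff_all[s1] + s_eff_all[s2]) / 2
          keep <- len >= band_2n[1] & len <= band_2n[2] &
            runif(length(s1)) < (1 - pair_sens)
          if (!any(keep)) next
          d1 <- d1[keep]; d2 <- d2[keep]; len <- len[keep]
          fs <- d1 - as.integer(floor(len / 4 + 0.5))
          fe <- fs + len
          ok <- fs >= 0 & fe <= L_ch
          frags[[length(frags) + 1]] <-
            data.frame(chrom = ch, start = fs[ok], end = fe[ok])
          truth[[length(truth) + 1]] <-
            data.frame(chrom = ch, dyad1 = d1[ok], dyad2 = d2[ok],
                       sensitivity =
                         ((sens[[ch]][s1[keep]] +
                           sens[[ch]][s2[keep]]) / 2)[ok])
          got <- got + sum(ok)
        }
      }
      if (e_per_cfg < 1e-9 && got == 0L)
        stop("library retention leaves no fragments")
    }
    tab <- do.call(rbind, frags)
    tr <- do.call(rbind, truth)
    if (nrow(tab) > n_fragments) {
      tab <- tab[seq_len(n_fragments), , drop = FALSE]
      tr <- tr[seq_len(n_fragments), , drop = FALSE]
    }
    fset <- fragment_set(tab, density$chrom_sizes,
                         label = paste0("MNase", library,
                                        if (temperature == "18C") "_18C"
                                        else ""))
    rownames(tr) <- NULL
    attr(fset, "truth") <- tr
    fset
  })
}

#' Run the full synthetic experiment
#'
#' Generates genome, annotations, planted energies, equilibrium density and
#' all fragment libraries (complete digestion at 27C and 18C; partial
#' digestion 1n and 2n at 27C), optionally writing every artifact to disk
#' (genome.fa, genes.bed12, expression.tsv, dhs.bed, frags_*.bed,
#' truth.json). Fully deterministic under the seed.
#'
#' In the partial digestion each nucleosome has a single fate: sensitive
#' nucleosomes are released as mononucleosome fragments and resistant ones
#' stay in dinucleosome fragments, so the two libraries' depths are
#' allocated in proportion to the density-weighted sensitive and resistant
#' mass. This makes the combined 1n+2n dyad map an approximately unbiased
#' representation of all nucleosomes, which is what motivates fitting the
#' energy model on the combined partial-digestion data.
#'
#' @param seed Integer seed (default 42).
#' @param outdir Optional output directory.
#' @param n_chroms,chrom_length Genome dimensions.
#' @param coverage Target nucleosome coverage.
#' @param n_high_1n Fragments in the complete-digestion libraries.
#' @param n_low_total Total dyad budget of the partial-digestion libraries
#'   (split mass-proportionally between 1n fragments and 2n pairs).
#' @return List with genome_obj, genes, dhs, truth (planted model, phi,
#'   landscapes, beta_mu, density) and fragments (named list of
#'   \code{fragment_set}s: high_1n, low_1n, low_2n, high_1n_18C, all_1n).
#' @export
simulate_mnase_experiment <- function(seed = 42L, outdir = NULL,
                                      n_chroms = 2L,
                                      chrom_length = 200000L,
                                      coverage = 0.8,
                                      n_high_1n = 300000L,
                                      n_low_total = 600000L) {
  genome_obj <- generate_genome(seed, n_chroms, chrom_length)
  ann <- generate_annotations(seed + 1L, genome_obj)
  truth <- plant_energy_and_density(genome_obj, ann$genes,
                                    coverage = coverage)
  sens <- sensitivity_scores(genome_obj)
  frac_sens <- sum(unlist(Map(`*`, truth$density$n, sens))) /
    sum(unlist(truth$density$n))
  n_low_1n <- round(n_low_total * frac_sens)
  # the dinucleosome length window (320-380 of the 300-400 bp library)
  # discards part of the 2n material; a pilot draw estimates the kept
  # fraction so that the post-filter 2n dyad mass stays proportional to the
  # resistant class, as in a pooled partial digestion
  pilot <- sample_fragments(seed + 4L, truth$density, genome_obj,
                            "LOW_2n", 20000L, "27C")
  plen <- fragment_lengths(pilot)
  keep_2n <- max(mean(plen >= 320 & plen <= 380), 0.05)
  n_low_2n <- round(n_low_total * (1 - frac_sens) / 2 / keep_2n)
  fragments <- list(
    high_1n = sample_fragments(seed + 2L, truth$density, genome_obj,
                               "HIGH_1n", n_high_1n, "27C"),
    low_1n = sample_fragments(seed + 3L, truth$density, genome_obj,
                              "LOW_1n", n_low_1n, "27C"),
    low_2n = sample_fragments(seed + 4L, truth$density, genome_obj,
                              "LOW_2n", n_low_2n, "27C"),
    high_1n_18C = sample_fragments(seed + 5L, truth$density, genome_obj,
                                   "HIGH_1n", n_high_1n, "18C"),
    all_1n = sample_fragments(seed + 6L, truth$density, genome_obj,
                              "ALL_1n", n_low_total, "27C"))
  out <- list(genome_obj = genome_obj, genes = ann$genes, dhs = ann$dhs,
              truth = truth, fragments = fragments, seed = seed)
  if (!is.null(outdir)) write_synthetic_dataset(out, outdir)
  out
}

#' Write a synthetic dataset to disk
#'
#' @param sim Output of \code{\link{simulate_mnase_experiment}}.
#' @param outdir Output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_synthetic_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- Biostrings::DNAStringSet(sim$genome_obj$genome)
  Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fa"))
  sizes <- data.frame(chrom = names(sim$genome_obj$genome),
                      size = nchar(sim$genome_obj$genome))
  data.table::fwrite(sizes, file.path(outdir, "chrom.sizes"),
                     sep = "\t", col.names = FALSE)
  g <- sim$genes
  gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    name = g$id, score = 0L,
    thick = IRanges::IRanges(g$start + 1L, g$end),
    blocks = IRanges::IRangesList(
      lapply(g$end - g$start, function(w) IRanges::IRanges(1L, w))))
  rtracklayer::export(gr, file.path(outdir, "genes.bed12"), format = "bed")
  data.table::fwrite(data.frame(gene_id = g$id, value = g$expression),
                     file.path(outdir, "expression.tsv"), sep = "\t")
  data.table::fwrite(sim$dhs[, c("chrom", "start", "end", "name")],
                     file.path(outdir, "dhs.bed"),
                     sep = "\t", col.names = FALSE)
  fn <- c(high_1n = "frags_high1n.bed", low_1n = "frags_low1n.bed",
          low_2n = "frags_low2n.bed", high_1n_18C = "frags_high1n_18C.bed",
          all_1n = "frags_all1n.bed")
  for (k in names(fn))
    write_fragments(sim$fragments[[k]], file.path(outdir, fn[[k]]))
  truth <- list(
    seed = sim$seed,
    chrom_sizes = as.list(stats::setNames(sizes$size, sizes$chrom)),
    beta_mu = sim$truth$beta_mu,
    coverage = sim$truth$coverage,
    sequence_model = list(
      intercept = sim$truth$model$intercept,
      mono_coeffs = as.list(sim$truth$model$mono_coeffs),
      di_coeffs = as.list(sim$truth$model$di_coeffs)),
    anchoring_well = list(
      depth = -min(sim$truth$phi$phi),
      center = sim$truth$phi$offsets[which.min(sim$truth$phi$phi)]),
    active_genes = sim$genes$id[sim$genes$active])
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
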