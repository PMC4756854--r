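# Sequence-dependent nucleosome energetics: mono+dinucleotide linear model
# fitted to inferred formation energies, TSS anchoring potential, and the
# full (sequence + anchoring) positioning model.

.BASES <- c("A", "C", "G", "T")
# AA AC AG AT CA ... TT, matching pair code (first - 1) * 4 + second
.DINUCS <- paste0(rep(.BASES, each = 4), .BASES)
.WW <- c("AA", "AT", "TA", "TT")
.SS <- c("CC", "CG", "GC", "GG")

# chromosome sequence -> integer codes 1..4 (A,C,G,T), NA for ambiguous
.seq_codes <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    chs <- as.character(genome)
  } else if (is.character(genome)) {
    chs <- genome
  } else stop("genome must be a DNAStringSet or named character vector")
  if (is.null(names(chs))) stop("genome sequences must be named")
  lapply(chs, function(s) {
    v <- utf8ToInt(toupper(s))
    code <- rep(NA_integer_, length(v))
    code[v == 65L] <- 1L  # A
    code[v == 67L] <- 2L  # C
    code[v == 71L] <- 3L  # G
    code[v == 84L] <- 4L  # T
    code
  })
}

# pair codes 1..16 ((first-1)*4 + second), NA if either base ambiguous
.pair_codes <- function(code) {
  n <- length(code)
  if (n < 2) return(integer(0))
  (code[-n] - 1L) * 4L + code[-1]
}

# full-window sums: out[s] = sum(v[s..s+w-1]), s = 1..n-w+1; NA propagates
.winsum <- function(v, w) {
  cs <- c(0, cumsum(v))
  n <- length(v)
  cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
}

#' Mono- and dinucleotide counts of one nucleosomal window
#'
#' @param genome DNAStringSet or named character vector.
#' @param chrom Chromosome name.
#' @param start 0-based start of the window.
#' @param a Window (footprint) length in bp.
#' @return Named count vector (4 mononucleotides then 16 dinucleotides), or
#'   NULL when the window contains an ambiguous base. Mono counts sum to a,
#'   dinucleotide counts to a - 1.
#' @export
sequence_features <- function(genome, chrom, start, a = 147L) {
  codes <- .seq_codes(genome)
  if (!chrom %in% names(codes)) stop("unknown chromosome ", chrom)
  v <- codes[[chrom]]
  if (start < 0 || start + a > length(v))
    stop("window outside chromosome bounds")
  w <- v[(start + 1):(start + a)]
  if (anyNA(w)) return(NULL)
  mono <- tabulate(w, nbins = 4)
  di <- tabulate(.pair_codes(w), nbins = 16)
  stats::setNames(c(mono, di), c(.BASES, .DINUCS))
}

# count matrix (rows = valid starts, 20 cols) for one chromosome; rows with
# ambiguous bases are NA
.feature_matrix_chrom <- function(code, a) {
  L <- length(code)
  S <- L - a + 1L
  if (S < 1) stop("chromosome shorter than footprint")
  X <- matrix(0, nrow = S, ncol = 20,
              dimnames = list(NULL, c(.BASES, .DINUCS)))
  nan <- .winsum(as.numeric(is.na(code)), a) > 0
  code0 <- code; code0[is.na(code0)] <- 1L  # placeholder, masked below
  for (b in 1:4) X[, b] <- .winsum(as.numeric(code0 == b), a)
  pc <- .pair_codes(code0)
  for (d in 1:16) X[, 4 + d] <- .winsum(as.numeric(pc == d), a - 1L)
  X[nan, ] <- NA_real_
  X
}

#' Footprint A/T fraction for every valid start
#'
#' @param genome DNAStringSet or named character vector.
#' @param a Footprint in bp.
#' @return Named list of numeric vectors (length L - a + 1 per chromosome);
#'   ambiguous bases are excluded from both numerator and denominator.
#' @export
footprint_at_fraction <- function(genome, a = 147L) {
  codes <- .seq_codes(genome)
  out <- lapply(codes, function(code) {
    is_at <- as.numeric(code %in% c(1L, 4L))
    is_ok <- as.numeric(!is.na(code))
    at <- .winsum(is_at, a)
    ok <- .winsum(is_ok, a)
    ifelse(ok > 0, at / ok, NA_real_)
  })
  names(out) <- names(codes)
  out
}

#' Fit the mono+dinucleotide energy model
#'
#' Ridge least squares of inferred formation energies on the 20 count
#' features (4 mononucleotide + 16 dinucleotide) plus an unpenalized
#' intercept. The count design is exactly collinear (mono counts sum to the
#' footprint, dinucleotide counts to footprint - 1), so a small ridge
#' penalty fixes the gauge; predictions are gauge-invariant.
#'
#' @param energies An \code{energy_landscape} (typically from
#'   \code{\link{invert_density}} on the combined partial-digestion 1n+2n
#'   dyad profile).
#' @param genome DNAStringSet or named character vector.
#' @param sample_positions Optional named list of 0-based starts per
#'   chromosome to fit on; default uses all valid starts at least one
#'   footprint away from the chromosome ends (edge-affected starts are
#'   excluded).
#' @param ridge_lambda Ridge penalty; default 1e-3 * n_samples.
#' @param symmetrize Average each coefficient with its reverse-complement
#'   partner, making predicted energies strand-symmetric. Default FALSE
#'   (forward-strand counts only).
#' @return A \code{sequence_energy_model} with intercept, mono_coeffs,
#'   di_coeffs, a, ridge_lambda and r_squared.
#' @export
fit_sequence_model <- function(energies, genome, sample_positions = NULL,
                               ridge_lambda = NULL, symmetrize = FALSE) {
  stopifnot(inherits(energies, "energy_landscape"))
  a <- energies$a
  codes <- .seq_codes(genome)
  Xs <- list(); ys <- list()
  for (ch in names(energies$u)) {
    if (!ch %in% names(codes)) stop("chromosome ", ch, " not in genome")
    X <- .feature_matrix_chrom(codes[[ch]], a)
    y <- energies$u[[ch]]
    S <- length(y)
    keep <- rep(FALSE, S)
    if (is.null(sample_positions)) {
      # exclude starts whose footprint lies within a bp of a hard wall
      lo <- a + 1L; hi <- S - a
      if (hi >= lo) keep[lo:hi] <- TRUE
    } else {
      keep[sample_positions[[ch]] + 1L] <- TRUE
    }
    keep <- keep & !is.na(y) & is.finite(y) & !is.na(X[, 1])
    Xs[[ch]] <- X[keep, , drop = FALSE]
    ys[[ch]] <- y[keep]
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys, use.names = FALSE)
  if (nrow(X) <= ncol(X))
    stop("fewer usable positions (", nrow(X), ") than features")
  if (is.null(ridge_lambda)) ridge_lambda <- 1e-3 * nrow(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  A <- crossprod(Xc) + diag(ridge_lambda, ncol(X))
  beta <- solve(A, crossprod(Xc, y - ym))[, 1]
  if (symmetrize) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rc <- function(d) paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)])
    beta[.BASES] <- (beta[.BASES] + beta[comp[.BASES]]) / 2
    beta[.DINUCS] <- (beta[.DINUCS] + beta[rc(.DINUCS)]) / 2
  }
  intercept <- ym - sum(xm * beta)
  fitted <- as.numeric(X %*% beta) + intercept
  r2 <- 1 - sum((y - fitted)^2) / sum((y - ym)^2)
  structure(list(intercept = intercept,
                 mono_coeffs = beta[.BASES],
                 di_coeffs = beta[.DINUCS],
                 a = a, ridge_lambda = ridge_lambda,
                 r_squared = r2, n_samples = nrow(X)),
            class = "sequence_energy_model")
}

#' @export
print.sequence_energy_model <- function(x, ...) {
  cat(sprintf(
    "sequence_energy_model: a=%d, lambda=%.4g, R^2=%.4f (n=%d)\n",
    x$a, x$ridge_lambda, x$r_squared, x$n_samples))
  invisible(x)
}

#' Predict sequence-dependent energies genome-wide
#'
#' u_seq(s) = intercept + sum of coefficients times window counts, for every
#' valid start. Windows containing ambiguous bases get NA.
#'
#' @param model A \code{sequence_energy_model}.
#' @param genome DNAStringSet or named character vector.
#' @param beta_mu Chemical potential stored on the returned landscape.
#' @return An \code{energy_landscape}.
#' @export
predict_sequence_energy <- function(model, genome, beta_mu = 0) {
  stopifnot(inherits(model, "sequence_energy_model"))
  a <- model$a
  codes <- .seq_codes(genome)
  u <- lapply(codes, function(code) {
    nan <- .winsum(as.numeric(is.na(code)), a) > 0
    code0 <- code; code0[is.na(code0)] <- 1L
    mono_sc <- model$mono_coeffs[code0]
    di_sc <- model$di_coeffs[.pair_codes(code0)]
    out <- model$intercept + .winsum(mono_sc, a) + .winsum(di_sc, a - 1L)
    out[nan] <- NA_real_
    out
  })
  names(u) <- names(codes)
  energy_landscape(u, a = a, beta_mu = beta_mu)
}

#' Infer the sequence-independent TSS anchoring potential
#'
#' Averages the normalized dyad density over active TSS (strand-oriented),
#' rescales the average to an absolute start density consistent with the
#' assumed genome-wide coverage (a normalized dyad track has mean 1 per bp,
#' whereas a start density has mean coverage/a per bp), and applies the
#' exact hard-rod inversion on the window. The result is the effective
#' external potential Phi(x), indexed by dyad offset from the TSS and
#' reported relative to its own mean; starts within one footprint of the
#' window edges are discarded as edge-affected.
#'
#' @param dyad_profile Normalized \code{bp_profile} of kind "dyad".
#' @param anchors data.frame of active TSS: columns chrom, pos, strand.
#' @param W Half-window in bp (default 1000).
#' @param beta_mu Chemical potential assumed in the inversion.
#' @param coverage Assumed genome-wide nucleosome coverage (default 0.8).
#' @param a Footprint in bp.
#' @param span Moving-average span applied to the averaged dyad track.
#' @param o_max Occupancy ceiling passed to
#'   \code{\link{dyad_profile_to_density}}; NULL turns an unphysical
#'   averaged density into an error instead of a global shrink.
#' @return An \code{anchoring_potential}: list with offsets (dyad bp
#'   relative to TSS) and phi (kT, mean-centered).
#' @export
infer_anchoring_potential <- function(dyad_profile, anchors, W = 1000L,
                                      beta_mu = 0, coverage = 0.8,
                                      a = 147L, span = 21L, o_max = 0.95) {
  stopifnot(inherits(dyad_profile, "bp_profile"))
  if (!dyad_profile$normalized)
    stop("dyad profile must be normalized (per-chromosome mean 1)")
  if (nrow(as.data.frame(anchors)) < 1) stop("need at least one anchor")
  mg <- metagene(dyad_profile, anchors, W)
  avg <- metagene_average(mg)
  if (anyNA(avg)) stop("averaged dyad density has empty columns")
  avg <- smooth_moving_average(avg, span = span)
  sd_win <- dyad_profile_to_density(list(win = avg), a = a,
                                    coverage = coverage, o_max = o_max)
  u <- invert_density(sd_win, beta_mu = beta_mu)$u$win
  h <- (a - 1L) %/% 2L
  offsets <- seq_along(u) + h - (W + 1L)   # dyad offset of each start
  keep <- seq_along(u) > a & seq_along(u) <= length(u) - a
  offsets <- offsets[keep]; u <- u[keep]
  phi <- u - mean(u)
  structure(list(offsets = offsets, phi = phi), class = "anchoring_potential")
}

#' @export
print.anchoring_potential <- function(x, ...) {
  w <- anchoring_well(x)
  cat(sprintf(
    "anchoring_potential: offsets %d..%d, well at %+d bp, depth %.2f kT\n",
    min(x$offsets), max(x$offsets), w$offset, w$depth))
  invisible(x)
}

#' Locate the anchoring well of a potential
#'
#' @param phi An \code{anchoring_potential}.
#' @return List with offset (dyad bp of the minimum) and depth (kT below the
#'   median level of the potential).
#' @export
anchoring_well <- function(phi) {
  stopifnot(inherits(phi, "anchoring_potential"))
  i <- which.min(phi$phi)
  list(offset = phi$offsets[i],
       depth = stats::median(phi$phi) - phi$phi[i])
}

# nearest anchor (sorted positions) for each query; ties -> leftmost
.nearest_sorted <- function(query, pos) {
  idx <- findInterval(query, pos)
  left <- pmax(idx, 1L)
  right <- pmin(idx + 1L, length(pos))
  dl <- abs(query - pos[left])
  dr <- abs(query - pos[right])
  take_left <- idx >= 1 & (idx >= length(pos) | dl <= dr)
  ifelse(take_left, left, right)
}

#' Assemble the full positioning model
#'
#' Adds the anchoring potential, indexed by strand-oriented dyad offset from
#' the nearest active TSS, to the sequence-dependent energies. Dyads beyond
#' the potential's offset range keep the sequence energy alone; where
#' windows of two TSS overlap the nearest one wins, ties going to the
#' upstream (left-most) TSS.
#'
#' @param u_seq Sequence-dependent \code{energy_landscape}.
#' @param phi An \code{anchoring_potential}.
#' @param anchors data.frame of active TSS: chrom, pos, strand.
#' @return An \code{energy_landscape} for the full model.
#' @export
full_model_energy <- function(u_seq, phi, anchors) {
  stopifnot(inherits(u_seq, "energy_landscape"),
            inherits(phi, "anchoring_potential"))
  anchors <- as.data.frame(anchors)
  a <- u_seq$a
  h <- (a - 1L) %/% 2L
  off_min <- min(phi$offsets); off_max <- max(phi$offsets)
  u <- u_seq$u
  for (ch in names(u)) {
    sub <- anchors[anchors$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    ord <- order(sub$pos)
    pos <- sub$pos[ord]; strand <- sub$strand[ord]
    d <- seq_along(u[[ch]]) - 1L + h          # 0-based dyad per start
    ni <- .nearest_sorted(d, pos)
    offset <- ifelse(strand[ni] == "+", d - pos[ni], pos[ni] - d)
    hit <- offset >= off_min & offset <= off_max
    add <- numeric(length(d))
    add[hit] <- phi$phi[offset[hit] - off_min + 1L]
    u[[ch]] <- u[[ch]] + add
  }
  energy_landscape(u, a = a, beta_mu = u_seq$beta_mu,
                   chrom_sizes = u_seq$chrom_sizes)
}

#' Compare model predictions with observed profiles over TSS windows
#'
#' For every model and chemical potential, solves the hard-rod model and
#' correlates predicted dyad density and occupancy with the observed ones
#' over the concatenated +/-W windows around the anchors.
#'
#' @param observed Normalized \code{bp_profile} of observed dyad density.
#' @param models Named list of \code{energy_landscape}s (e.g.
#'   \code{list(seq = u_seq, full = u_full)}); NA energies are replaced by
#'   the landscape mean before solving.
#' @param anchors data.frame of active TSS: chrom, pos, strand.
#' @param beta_mu_grid Numeric vector of chemical potentials to scan.
#' @param W Half-window in bp.
#' @return data.frame with columns model, beta_mu, r_dyad, r_occupancy.
#' @export
evaluate_models <- function(observed, models, anchors, beta_mu_grid,
                            W = 1000L) {
  stopifnot(inherits(observed, "bp_profile"), length(beta_mu_grid) > 0,
            length(models) > 0, !is.null(names(models)))
  anchors <- as.data.frame(anchors)
  a <- models[[1]]$a
  # observed dyad and derived occupancy tracks per chromosome
  obs_dyad <- observed$values
  obs_occ <- lapply(names(obs_dyad), function(ch) {
    .occupancy_from_starts(dyad_to_start(obs_dyad[[ch]], a), a,
                           length(obs_dyad[[ch]]))
  })
  names(obs_occ) <- names(obs_dyad)
  win_idx <- lapply(names(obs_dyad), function(ch) {
    sub <- anchors[anchors$chrom == ch, , drop = FALSE]
    L <- length(obs_dyad[[ch]])
    if (nrow(sub) == 0) return(integer(0))
    unlist(lapply(sub$pos, function(p) {
      lo <- max(p - W, 0L); hi <- min(p + W, L - 1L)
      (lo:hi) + 1L
    }))
  })
  names(win_idx) <- names(obs_dyad)
  extract <- function(tracks)
    unlist(lapply(names(tracks), function(ch) tracks[[ch]][win_idx[[ch]]]),
           use.names = FALSE)
  obs_d <- extract(obs_dyad)
  obs_o <- extract(obs_occ)
  rows <- list()
  for (mn in names(models)) {
    m <- models[[mn]]
    m$u <- lapply(m$u, function(v) {
      v[!is.finite(v)] <- mean(v[is.finite(v)])
      v
    })
    for (bm in beta_mu_grid) {
      m$beta_mu <- bm
      den <- forward_solve(m)
      mod_dyad <- lapply(names(den$n), function(ch)
        start_to_dyad(den$n[[ch]], a, den$chrom_sizes[[ch]]))
      names(mod_dyad) <- names(den$n)
      mod_d <- extract(mod_dyad)
      mod_o <- extract(den$O)
      rows[[length(rows) + 1]] <- data.frame(
        model = mn, beta_mu = bm,
        r_dyad = cor(obs_d, mod_d),
        r_occupancy = cor(obs_o, mod_o))
    }
  }
  do.call(rbind, rows)
}

#' Mean formation energy by chromatin class
#'
#' Assigns each nucleosome start the majority chromatin label of its
#' footprint (ties are unclassified) and reports the mean energy per label
#' relative to the genome-wide mean energy, together with the difference
#' between the two classified labels.
#'
#' @param u An \code{energy_landscape}.
#' @param classmap A \code{chromatin_class_map}.
#' @param axis "sensitivity" (difference = sensitive - resistant) or
#'   "accessibility" (difference = open - closed).
#' @return List with means (named, relative to genome-wide mean), difference
#'   and counts; empty classes give NA means.
#' @export
energy_by_class <- function(u, classmap,
                            axis = c("sensitivity", "accessibility")) {
  axis <- match.arg(axis)
  stopifnot(inherits(u, "energy_landscape"),
            inherits(classmap, "chromatin_class_map"))
  a <- u$a
  labels <- .class_labels(axis)
  pair <- if (axis == "sensitivity") c("resistant", "sensitive")
          else c("closed", "open")
  acc_u <- list(); acc_lab <- list()
  for (ch in names(u$u)) {
    lab <- classmap[[axis]][[ch]]
    if (is.null(lab)) stop("classmap lacks chromosome ", ch)
    uu <- u$u[[ch]]
    c1 <- .winsum(as.numeric(lab == 1L), a)
    c2 <- .winsum(as.numeric(lab == 2L), a)
    maj <- rep(3L, length(uu))
    maj[c1 > pmax(c2, a - c1 - c2)] <- 1L
    maj[c2 > pmax(c1, a - c1 - c2)] <- 2L
    ok <- is.finite(uu)
    acc_u[[ch]] <- uu[ok]; acc_lab[[ch]] <- maj[ok]
  }
  uu <- unlist(acc_u, use.names = FALSE)
  lab <- unlist(acc_lab, use.names = FALSE)
  gw <- mean(uu)
  means <- vapply(1:3, function(k)
    if (any(lab == k)) mean(uu[lab == k]) - gw else NA_real_, numeric(1))
  names(means) <- labels
  list(means = means,
       difference = means[[pair[2]]] - means[[pair[1]]],
       counts = stats::setNames(tabulate(lab, 3), labels))
}
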