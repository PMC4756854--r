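# Dinucleotide-frequency profiles around nucleosome dyads and A/T-content
# vs read-density statistics.

#' Dinucleotide frequencies around dyads, relative to genome-wide values
#'
#' Fragments are aligned by their dyads (1n midpoints); for each offset x in
#' -W..W, the frequency of each dinucleotide at (dyad+x, dyad+x+1) is
#' computed across fragments and divided by that dinucleotide's genome-wide
#' frequency, so a uniformly sampled dyad set gives values near 1. Group
#' tracks average the normalized values over WW = \{AA,AT,TA,TT\},
#' SS = \{CC,CG,GC,GG\} and the mixed WS/SW dinucleotides; group tracks are
#' smoothed with a centered moving average.
#'
#' @param fragments A \code{fragment_set} (1n dyads are used) or a named
#'   list of 0-based dyad position vectors per chromosome.
#' @param genome DNAStringSet or named character vector.
#' @param W Half-window around the dyad in bp (default 250). Dyads closer
#'   than W+1 to a chromosome end are skipped.
#' @param span Moving-average span for the group tracks (NULL to disable).
#' @return A \code{dinuc_profile}: list with offsets, freq (16 x offsets
#'   matrix of normalized frequencies), groups (3 x offsets matrix: WW, SS,
#'   WSSW) and n_dyads.
#' @export
dinucleotide_profile <- function(fragments, genome, W = 250L, span = 21L) {
  codes <- .seq_codes(genome)
  if (inherits(fragments, "fragment_set")) {
    prof <- dyads_1n(fragments)
    dyads <- lapply(prof$values, function(v) {
      rep.int(seq_along(v) - 1L, v)
    })
  } else dyads <- fragments
  if (min(vapply(codes, length, integer(1))) < 2 * W + 2)
    stop("window too large for the genome")
  pair_codes <- lapply(codes, .pair_codes)
  # genome-wide dinucleotide frequencies (ambiguous pairs excluded)
  gw <- numeric(16)
  for (pc in pair_codes) gw <- gw + tabulate(pc[!is.na(pc)], 16)
  gw <- gw / sum(gw)
  offsets <- seq(-W, W)
  counts <- matrix(0, nrow = 16, ncol = length(offsets),
                   dimnames = list(.DINUCS, offsets))
  n_used <- 0
  for (ch in names(dyads)) {
    d <- dyads[[ch]]
    if (length(d) == 0) next
    pc <- pair_codes[[ch]]
    L <- length(codes[[ch]])
    d <- d[d - W >= 0 & d + W + 1 < L]
    n_used <- n_used + length(d)
    if (length(d) == 0) next
    for (j in seq_along(offsets)) {
      v <- pc[d + offsets[j] + 1L]       # pair starting at dyad+offset
      counts[, j] <- counts[, j] + tabulate(v[!is.na(v)], 16)
    }
  }
  if (n_used == 0) stop("no usable dyads")
  tot <- colSums(counts)
  freq <- sweep(counts, 2, pmax(tot, 1), "/") / gw
  grp <- rbind(WW = colMeans(freq[.WW, , drop = FALSE]),
               SS = colMeans(freq[.SS, , drop = FALSE]),
               WSSW = colMeans(freq[setdiff(.DINUCS, c(.WW, .SS)), ,
                                    drop = FALSE]))
  if (!is.null(span))
    grp <- t(apply(grp, 1, smooth_moving_average, span = span))
  colnames(grp) <- offsets
  structure(list(offsets = offsets, freq = freq, groups = grp,
                 n_dyads = n_used),
            class = "dinuc_profile")
}

#' @export
print.dinuc_profile <- function(x, ...) {
  cat(sprintf("dinuc_profile: offsets %d..%d, %d dyads\n",
              min(x$offsets), max(x$offsets), x$n_dyads))
  invisible(x)
}

#' A/T content vs read density in tiling windows
#'
#' Tiles each chromosome into non-overlapping windows (the last partial
#' window is dropped), assigns each fragment to the window containing its
#' midpoint, normalizes counts per set by the genome-wide mean window count,
#' and correlates density (or the density difference between two sets) with
#' window A/T fraction. Ambiguous bases are excluded from the A/T fraction;
#' windows with more than 10 percent ambiguous bases are dropped.
#'
#' @param fragments A \code{fragment_set} or a named list of them. With two
#'   or more sets the densities of all sets are tabulated; \code{difference}
#'   selects two labels to subtract.
#' @param genome DNAStringSet or named character vector.
#' @param window Window size in bp (default 500).
#' @param difference Optional character vector of two set names; adds a
#'   density-difference column (first minus second) and its correlation.
#' @return List with table (data.frame: chrom, start, at_fraction, one
#'   density column per set) and r (named correlations of A/T fraction with
#'   each density and with the difference when requested).
#' @export
at_density_correlation <- function(fragments, genome, window = 500L,
                                   difference = NULL) {
  if (inherits(fragments, "fragment_set"))
    fragments <- stats::setNames(list(fragments), fragments$label)
  stopifnot(length(fragments) >= 1, !is.null(names(fragments)))
  codes <- .seq_codes(genome)
  if (max(vapply(codes, length, integer(1))) < window)
    stop("genome shorter than one window")
  wins <- list()
  for (ch in names(codes)) {
    L <- length(codes[[ch]])
    nw <- L %/% window
    if (nw == 0) next
    idx <- rep(seq_len(nw), each = window)
    code <- codes[[ch]][seq_len(nw * window)]
    at <- tapply(code %in% c(1L, 4L), idx, sum)
    ok <- tapply(!is.na(code), idx, sum)
    wins[[ch]] <- data.frame(chrom = ch,
                             start = (seq_len(nw) - 1L) * window,
                             at_fraction = ifelse(ok > 0, at / ok, NA),
                             n_frac = 1 - ok / window)
  }
  tab <- do.call(rbind, wins)
  tab <- tab[!is.na(tab$at_fraction) & tab$n_frac <= 0.10, , drop = FALSE]
  rownames(tab) <- NULL
  for (set in names(fragments)) {
    fs <- fragments[[set]]
    if (n_fragments(fs) == 0) stop("fragment set '", set, "' is empty")
    cnt <- numeric(nrow(tab))
    for (ch in unique(tab$chrom)) {
      f <- fs$fragments[[ch]]
      rows <- which(tab$chrom == ch)
      if (is.null(f) || nrow(f) == 0) next
      mid <- (f$start + f$end - 1L) %/% 2L
      wi <- mid %/% window  # 0-based window index
      cnts <- tabulate(wi + 1L, nbins = max(tab$start[rows]) %/% window + 1L)
      cnt[rows] <- cnts[tab$start[rows] %/% window + 1L]
    }
    tab[[paste0("density_", set)]] <- cnt / mean(cnt)
  }
  dens_cols <- paste0("density_", names(fragments))
  r <- vapply(dens_cols, function(cc) cor(tab$at_fraction, tab[[cc]]),
              numeric(1))
  names(r) <- names(fragments)
  if (!is.null(difference)) {
    stopifnot(length(difference) == 2,
              all(difference %in% names(fragments)))
    dd <- tab[[paste0("density_", difference[1])]] -
          tab[[paste0("density_", difference[2])]]
    tab$density_difference <- dd
    if (var(dd) == 0) {
      warning("density difference has zero variance; correlation is NaN")
      r <- c(r, difference = NaN)
    } else {
      r <- c(r, difference = cor(tab$at_fraction, dd))
    }
  }
  tab$n_frac <- NULL
  list(table = tab, r = r)
}
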