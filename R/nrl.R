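# Nucleosome repeat length estimation by Fourier analysis of normalized
# dyad profiles.

#' Fourier spectrum of inter-nucleosome spacing
#'
#' Computes the discrete Fourier transform of one or more dyad-density
#' arrays (mean removed, no padding), takes absolute magnitudes, maps
#' frequency bin k of an N-bp array to period N/k, averages magnitudes
#' across arrays, linearly interpolates onto a period grid of
#' \code{period_range} with step \code{step} bp, smooths with a cubic
#' smoothing spline (\code{smooth.spline}, spar = 0.8) and scales to
#' maximum 1. The nucleosome repeat length (NRL) is the period of the
#' maximum; linker length = NRL - 147.
#'
#' When several arrays are given (e.g. per-gene windows around TSS),
#' magnitudes -- not complex spectra -- are averaged so that phase
#' differences between genes do not cancel the periodicity signal. Arrays
#' of equal length are averaged bin-wise before interpolation; unequal
#' lengths are interpolated first.
#'
#' @param arrays Numeric vector, or list of numeric vectors, of (normalized)
#'   dyad density.
#' @param period_range Period window in bp (default 100--225).
#' @param step Period grid step in bp (default 0.01).
#' @param spar Smoothing parameter of \code{smooth.spline}.
#' @return An \code{nrl_spectrum}: list with period, magnitude (max 1),
#'   nrl_estimate, linker_estimate and low_confidence (TRUE when the peak
#'   magnitude is below twice the median magnitude).
#' @export
nrl_spectrum <- function(arrays, period_range = c(100, 225), step = 0.01,
                         spar = 0.8) {
  if (!is.list(arrays)) arrays <- list(arrays)
  arrays <- arrays[vapply(arrays, length, integer(1)) > 0]
  if (length(arrays) == 0) stop("no input arrays")
  if (all(vapply(arrays, function(v) all(v == 0), logical(1))))
    stop("all-zero input array")
  if (min(vapply(arrays, length, integer(1))) < 2 * period_range[2])
    stop("arrays must be at least twice the longest period")
  grid <- seq(period_range[1], period_range[2], by = step)

  spec_one <- function(v) {
    v <- v - mean(v)
    m <- Mod(fft(v))
    N <- length(v)
    k <- seq_len(floor(N / 2))          # k = 0 (DC) excluded
    list(period = N / k, mag = m[k + 1])
  }
  lens <- vapply(arrays, length, integer(1))
  if (length(unique(lens)) == 1) {
    specs <- lapply(arrays, spec_one)
    mag <- Reduce(`+`, lapply(specs, `[[`, "mag")) / length(specs)
    period <- specs[[1]]$period
    interp <- approx(rev(period), rev(mag), xout = grid, rule = 2)$y
  } else {
    per_grid <- lapply(arrays, function(v) {
      s <- spec_one(v)
      approx(rev(s$period), rev(s$mag), xout = grid, rule = 2)$y
    })
    interp <- Reduce(`+`, per_grid) / length(per_grid)
  }
  sm <- predict(smooth.spline(grid, interp, spar = spar), grid)$y
  sm <- sm / max(sm)
  i <- which.max(sm)
  structure(list(period = grid,
                 magnitude = sm,
                 nrl_estimate = grid[i],
                 linker_estimate = grid[i] - 147,
                 low_confidence = max(sm) < 2 * stats::median(sm)),
            class = "nrl_spectrum")
}

#' @export
print.nrl_spectrum <- function(x, ...) {
  cat(sprintf("nrl_spectrum: NRL %.2f bp (linker %.2f bp)%s\n",
              x$nrl_estimate, x$linker_estimate,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Compare NRL estimates across conditions
#'
#' @param spectra Named list of \code{nrl_spectrum} objects (at least two),
#'   e.g. genome-wide vs TSS-proximal, or two digestion conditions.
#' @return List with estimates (data.frame of NRL and linker per label) and
#'   differences (data.frame of pairwise NRL differences, a - b).
#' @export
compare_nrl <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 2, !is.null(names(spectra)))
  est <- data.frame(
    label = names(spectra),
    nrl = vapply(spectra, `[[`, numeric(1), "nrl_estimate"),
    linker = vapply(spectra, `[[`, numeric(1), "linker_estimate"),
    row.names = NULL)
  prs <- utils::combn(names(spectra), 2)
  diffs <- data.frame(
    a = prs[1, ], b = prs[2, ],
    nrl_difference = est$nrl[match(prs[1, ], est$label)] -
      est$nrl[match(prs[2, ], est$label)],
    row.names = NULL)
  list(estimates = est, differences = diffs)
}

#' Per-gene dyad arrays around TSS for TSS-proximal NRL estimation
#'
#' @param dyad_profile A \code{bp_profile} of dyad density.
#' @param anchors data.frame of TSS anchors (chrom, pos, strand).
#' @param W Half-window in bp (default 1000).
#' @return List of numeric arrays (one per anchor, 2W+1 bp,
#'   strand-oriented), suitable for \code{\link{nrl_spectrum}}. Anchors too
#'   close to a chromosome edge are dropped.
#' @export
tss_dyad_arrays <- function(dyad_profile, anchors, W = 1000L) {
  mg <- metagene(dyad_profile, anchors, W)
  rows <- lapply(seq_len(nrow(mg)), function(i) mg[i, ])
  rows[!vapply(rows, anyNA, logical(1))]
}
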