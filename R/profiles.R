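# Dyad-density and occupancy profiles, smoothing, metagenes, heatmap
# matrices and cross-correlation.

#' Mononucleosome dyad counts
#'
#' Each fragment contributes one count at its midpoint; for even-length
#' fragments the lower median \code{floor((start + end - 1) / 2)} is used, a
#' deterministic tie-break biased by less than 1 bp.
#'
#' @param fragments A \code{fragment_set}.
#' @return Raw-count \code{bp_profile} of kind "dyad"; the total count equals
#'   the number of fragments.
#' @export
dyads_1n <- function(fragments) {
  stopifnot(inherits(fragments, "fragment_set"))
  values <- lapply(names(fragments$fragments), function(ch) {
    f <- fragments$fragments[[ch]]
    v <- numeric(fragments$chrom_sizes[[ch]])
    if (nrow(f)) {
      d <- (f$start + f$end - 1L) %/% 2L   # 0-based dyad
      tb <- tabulate(d + 1L, nbins = length(v))
      v <- as.numeric(tb)
    }
    v
  })
  names(values) <- names(fragments$fragments)
  bp_profile(values, kind = "dyad")
}

#' Dinucleosome dyad counts
#'
#' Fragments within the dinucleosome length window contribute two dyads, at
#' one-fourth and three-fourths of the fragment (offsets
#' \code{round(L/4)} and \code{round(3L/4)} from the fragment start,
#' round-half-up); fragments outside the window are ignored.
#'
#' @param fragments A \code{fragment_set}.
#' @param min_len,max_len Retained fragment-length window in bp.
#' @return Raw-count \code{bp_profile} of kind "dyad"; total count is twice
#'   the number of retained fragments.
#' @export
dyads_2n <- function(fragments, min_len = 320L, max_len = 380L) {
  stopifnot(inherits(fragments, "fragment_set"))
  rhu <- function(x) floor(x + 0.5)  # round half up, deterministic
  values <- lapply(names(fragments$fragments), function(ch) {
    f <- fragments$fragments[[ch]]
    v <- numeric(fragments$chrom_sizes[[ch]])
    if (nrow(f)) {
      len <- f$end - f$start
      keep <- len >= min_len & len <= max_len
      if (any(keep)) {
        s <- f$start[keep]; L <- len[keep]
        d <- c(s + rhu(L / 4), s + rhu(3 * L / 4))
        d <- d[d >= 0 & d < length(v)]
        v <- as.numeric(tabulate(d + 1L, nbins = length(v)))
      }
    }
    v
  })
  names(values) <- names(fragments$fragments)
  bp_profile(values, kind = "dyad")
}

#' Nucleosome occupancy (fragment coverage)
#'
#' The value at bp i is the number of fragments covering i, i.e. with
#' start <= i < end.
#'
#' @param fragments A \code{fragment_set}.
#' @return Raw \code{bp_profile} of kind "occupancy".
#' @export
occupancy <- function(fragments) {
  stopifnot(inherits(fragments, "fragment_set"))
  values <- lapply(names(fragments$fragments), function(ch) {
    f <- fragments$fragments[[ch]]
    n <- fragments$chrom_sizes[[ch]]
    delta <- numeric(n + 1L)
    if (nrow(f)) {
      st <- tabulate(f$start + 1L, nbins = n + 1L)
      en <- tabulate(f$end + 1L, nbins = n + 1L)
      delta <- st - en
    }
    cumsum(delta)[seq_len(n)]
  })
  names(values) <- names(fragments$fragments)
  bp_profile(values, kind = "occupancy")
}

#' Combine raw dyad profiles
#'
#' Sums raw counts bp by bp (e.g. 1n + 2n dyads from a partial digestion
#' before per-chromosome normalization).
#'
#' @param ... Raw \code{bp_profile}s on the same chromosomes.
#' @return Raw \code{bp_profile} of the summed counts.
#' @export
combine_profiles <- function(...) {
  profs <- list(...)
  stopifnot(length(profs) >= 1,
            all(vapply(profs, inherits, logical(1), "bp_profile")))
  if (any(vapply(profs, function(p) p$normalized, logical(1))))
    stop("combine raw (unnormalized) profiles, then normalize")
  base <- profs[[1]]
  for (p in profs[-1]) {
    stopifnot(identical(names(p$values), names(base$values)))
    base$values <- Map(`+`, base$values, p$values)
  }
  bp_profile(base$values, kind = base$kind)
}

#' Normalize a profile to per-chromosome mean 1
#'
#' @param profile A \code{bp_profile}.
#' @return The profile rescaled so every chromosome has mean exactly 1;
#'   idempotent.
#' @export
normalize_per_chromosome <- function(profile) {
  stopifnot(inherits(profile, "bp_profile"))
  values <- lapply(names(profile$values), function(ch) {
    v <- profile$values[[ch]]
    m <- mean(v)
    if (m == 0) stop("chromosome ", ch, " is all zero; cannot normalize")
    v / m
  })
  names(values) <- names(profile$values)
  bp_profile(values, kind = profile$kind, normalized = TRUE)
}

#' Moving-average smoothing
#'
#' Centered moving average with an odd span. Near the edges the window
#' shrinks symmetrically (no padding), so constant signals -- and linear
#' ramps everywhere, including at the edges -- are exactly unchanged.
#'
#' @param signal Numeric vector or \code{bp_profile}.
#' @param span Odd window width in bp (default 21).
#' @return Smoothed object of the same type.
#' @export
smooth_moving_average <- function(signal, span = 21L) {
  if (span < 1 || span %% 2 == 0) stop("span must be odd and >= 1")
  half <- (span - 1L) %/% 2L
  sm <- function(v) {
    n <- length(v)
    i <- seq_len(n)
    h <- pmin(half, i - 1L, n - i)
    cs <- cumsum(v)
    (cs[i + h] - c(0, cs)[i - h]) / (2 * h + 1)
  }
  if (inherits(signal, "bp_profile")) {
    values <- lapply(signal$values, sm)
    return(bp_profile(values, kind = signal$kind,
                      normalized = FALSE))
  }
  sm(as.numeric(signal))
}

# 1D Gaussian kernel, radius 4 sigma, normalized to sum 1
.gauss_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve rows or full vector with kernel, renormalizing at edges and
# across NA entries so that constants are preserved
.conv_renorm <- function(v, k) {
  r <- (length(k) - 1L) / 2L
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  num <- stats::filter(c(rep(0, r), v0, rep(0, r)), k, sides = 2)
  den <- stats::filter(c(rep(0, r), as.numeric(ok), rep(0, r)), k, sides = 2)
  out <- as.numeric(num / den)[(r + 1L):(r + length(v))]
  out[!ok] <- NA
  out
}

#' 2D Gaussian smoothing of a matrix
#'
#' Separable Gaussian filter (kernel radius 4 sigma). Edges and missing
#' entries are handled by kernel renormalization, so a constant matrix is
#' unchanged and NA sentinels stay NA without bleeding into neighbours.
#'
#' @param mat Numeric matrix (e.g. a metagene heatmap); may contain NA.
#' @param sigma Gaussian standard deviation in matrix cells (default 3).
#' @return Smoothed matrix of the same dimensions.
#' @export
smooth_gaussian2d <- function(mat, sigma = 3) {
  stopifnot(is.matrix(mat), sigma > 0)
  k <- .gauss_kernel(sigma)
  tmp <- t(apply(mat, 1, .conv_renorm, k = k))
  if (nrow(mat) == 1) tmp <- matrix(tmp, nrow = 1)
  out <- apply(tmp, 2, .conv_renorm, k = k)
  if (ncol(mat) == 1) out <- matrix(out, ncol = 1)
  dimnames(out) <- dimnames(mat)
  out
}

#' Metagene matrix around anchors
#'
#' Extracts profile values at offsets -W..W around each anchor,
#' strand-oriented: rows of minus-strand anchors are reversed so positive
#' offsets always point downstream. Offsets falling outside the chromosome
#' are NA and are excluded from column means.
#'
#' @param profile A \code{bp_profile}.
#' @param anchors data.frame with columns chrom, pos (0-based bp) and
#'   optionally strand ("+"/"-"; missing means "+"). Row names or an id
#'   column label the rows.
#' @param W Half-window in bp.
#' @return Matrix with one row per anchor and 2W+1 columns named by offset;
#'   attribute "offsets" holds the offset vector.
#' @export
metagene <- function(profile, anchors, W) {
  stopifnot(inherits(profile, "bp_profile"), W >= 1)
  anchors <- as.data.frame(anchors)
  if (is.null(anchors$strand)) anchors$strand <- "+"
  if (any(!(anchors$chrom %in% names(profile$values))))
    stop("anchor on unknown chromosome")
  offs <- seq(-W, W)
  mat <- matrix(NA_real_, nrow = nrow(anchors), ncol = length(offs))
  for (i in seq_len(nrow(anchors))) {
    v <- profile$values[[anchors$chrom[i]]]
    idx <- anchors$pos[i] + offs + 1L  # 1-based
    okv <- idx >= 1 & idx <= length(v)
    row <- rep(NA_real_, length(offs))
    row[okv] <- v[idx[okv]]
    if (anchors$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  colnames(mat) <- offs
  rownames(mat) <- if (!is.null(anchors$id)) anchors$id else rownames(anchors)
  attr(mat, "offsets") <- offs
  mat
}

#' Column means of a metagene matrix
#'
#' @param mat Matrix from \code{\link{metagene}}.
#' @return Numeric vector of per-offset means, NA entries excluded.
#' @export
metagene_average <- function(mat) {
  colMeans(mat, na.rm = TRUE)
}

#' Sort metagene rows by a value vector
#'
#' Stable sort (ties keep input order), as used to order genes by expression
#' from high to low in heatmap displays.
#'
#' @param mat Metagene matrix.
#' @param values One value per row.
#' @param descending Sort direction.
#' @return Matrix with reordered rows; attribute "order" holds the
#'   permutation applied.
#' @export
sort_rows_by <- function(mat, values, descending = TRUE) {
  if (length(values) != nrow(mat))
    stop("need exactly one sort value per row")
  ord <- order(values, decreasing = descending, method = "radix")
  out <- mat[ord, , drop = FALSE]
  attr(out, "offsets") <- attr(mat, "offsets")
  attr(out, "order") <- ord
  out
}

#' Cross-correlation of two profiles
#'
#' Pearson correlation between profile a and profile b shifted by each lag,
#' computed over the per-chromosome overlap and pooled across chromosomes
#' (no wrap-around, no mixing across chromosome boundaries). With
#' \code{b[i + lag] == a[i]} the maximum is at \code{lag}.
#'
#' @param a,b \code{bp_profile}s on the same chromosomes.
#' @param max_lag Maximum |lag| in bp.
#' @return Named numeric vector of r per lag, lags -max_lag..max_lag.
#' @export
profile_crosscorrelation <- function(a, b, max_lag) {
  stopifnot(inherits(a, "bp_profile"), inherits(b, "bp_profile"),
            max_lag >= 0)
  if (!identical(names(a$values), names(b$values)))
    stop("profiles must share the same chromosome set")
  if (any(vapply(a$values, var, numeric(1)) == 0) ||
      any(vapply(b$values, var, numeric(1)) == 0))
    stop("zero-variance chromosome in input profile")
  lags <- seq(-max_lag, max_lag)
  r <- vapply(lags, function(l) {
    xs <- list(); ys <- list()
    for (ch in names(a$values)) {
      va <- a$values[[ch]]; vb <- b$values[[ch]]
      n <- min(length(va), length(vb))
      if (l >= 0) {
        if (n - l < 2) next
        xs[[ch]] <- va[seq_len(n - l)]
        ys[[ch]] <- vb[(1 + l):n]
      } else {
        if (n + l < 2) next
        xs[[ch]] <- va[(1 - l):n]
        ys[[ch]] <- vb[seq_len(n + l)]
      }
    }
    cor(unlist(xs, use.names = FALSE), unlist(ys, use.names = FALSE))
  }, numeric(1))
  names(r) <- lags
  r
}
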