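# Classification of genomic bp into MNase-sensitive/resistant and
# open/closed chromatin, overlap and composition summaries, gene activity
# calling and DHS-TSS overlap statistics.

.class_labels <- function(axis) {
  switch(axis,
         sensitivity = c("resistant", "sensitive", "unclassified"),
         accessibility = c("open", "closed", "unclassified"),
         stop("unknown axis ", axis))
}

#' Classify chromatin from differential MNase occupancy profiles
#'
#' Per bp, with all profiles normalized to per-chromosome mean 1:
#' \itemize{
#'   \item resistant if occ_high - occ_total > theta; sensitive if
#'     occ_total - occ_high > theta; otherwise unclassified;
#'   \item open if occ_low - occ_total > theta; closed if
#'     occ_total - occ_low > theta; otherwise unclassified.
#' }
#' "Significantly higher/lower" is a fixed occupancy threshold (default
#' 0.25), not a statistical test.
#'
#' @param occ_high_1n Occupancy of complete-digestion mononucleosomes.
#' @param occ_low_1n Occupancy of partial-digestion mononucleosomes.
#' @param occ_total Combined partial-digestion 1n+2n occupancy.
#' @param theta Occupancy-difference threshold (> 0).
#' @return A \code{chromatin_class_map}: per-chromosome integer vectors
#'   (1 = first label, 2 = second, 3 = unclassified) on the sensitivity and
#'   accessibility axes, plus theta.
#' @export
classify_chromatin <- function(occ_high_1n, occ_low_1n, occ_total,
                               theta = 0.25) {
  for (p in list(occ_high_1n, occ_low_1n, occ_total)) {
    stopifnot(inherits(p, "bp_profile"))
    if (!p$normalized)
      stop("profiles must be normalized to per-chromosome mean 1")
  }
  if (theta <= 0) stop("theta must be > 0")
  if (!identical(names(occ_high_1n$values), names(occ_total$values)) ||
      !identical(names(occ_low_1n$values), names(occ_total$values)))
    stop("profiles must share the same chromosome set")
  sens <- list(); acc <- list()
  for (ch in names(occ_total$values)) {
    h <- occ_high_1n$values[[ch]]
    l <- occ_low_1n$values[[ch]]
    t <- occ_total$values[[ch]]
    s <- rep(3L, length(t))
    s[h - t > theta] <- 1L   # resistant
    s[t - h > theta] <- 2L   # sensitive
    o <- rep(3L, length(t))
    o[l - t > theta] <- 1L   # open
    o[t - l > theta] <- 2L   # closed
    sens[[ch]] <- s; acc[[ch]] <- o
  }
  structure(list(sensitivity = sens, accessibility = acc, theta = theta),
            class = "chromatin_class_map")
}

#' @export
print.chromatin_class_map <- function(x, ...) {
  n <- sum(vapply(x$sensitivity, length, integer(1)))
  cat(sprintf("chromatin_class_map: %d bp, theta=%.3g\n", n, x$theta))
  invisible(x)
}

#' Joint overlap of the two classification axes
#'
#' @param classmap A \code{chromatin_class_map}.
#' @return List with counts (3x3 bp-count table, sensitivity x
#'   accessibility), fraction_open_sensitive (of open bp, fraction also
#'   sensitive), fraction_closed_resistant, and the open-bp counts that are
#'   sensitive vs resistant.
#' @export
overlap_summary <- function(classmap) {
  stopifnot(inherits(classmap, "chromatin_class_map"))
  s <- unlist(classmap$sensitivity, use.names = FALSE)
  o <- unlist(classmap$accessibility, use.names = FALSE)
  counts <- table(factor(.class_labels("sensitivity")[s],
                         levels = .class_labels("sensitivity")),
                  factor(.class_labels("accessibility")[o],
                         levels = .class_labels("accessibility")))
  names(dimnames(counts)) <- c("sensitivity", "accessibility")
  open_total <- sum(counts[, "open"])
  closed_total <- sum(counts[, "closed"])
  list(counts = counts,
       open_sensitive = counts["sensitive", "open"],
       open_resistant = counts["resistant", "open"],
       fraction_open_sensitive =
         if (open_total > 0) counts["sensitive", "open"] / open_total
         else NA_real_,
       fraction_closed_resistant =
         if (closed_total > 0) counts["resistant", "closed"] / closed_total
         else NA_real_)
}

#' Chromatin-class composition of annotated regions
#'
#' @param classmap A \code{chromatin_class_map}.
#' @param annotations Named list of interval data.frames (chrom, start, end;
#'   0-based half-open).
#' @return data.frame with one row per annotation x axis x label carrying
#'   the bp count, the fraction of all annotated bp, and the fraction of
#'   classified bp only. Fractions over all bp sum to 1 per annotation and
#'   axis.
#' @export
region_composition <- function(classmap, annotations) {
  stopifnot(inherits(classmap, "chromatin_class_map"),
            is.list(annotations), !is.null(names(annotations)))
  rows <- list()
  for (name in names(annotations)) {
    iv <- as.data.frame(annotations[[name]])
    for (axis in c("sensitivity", "accessibility")) {
      labels <- .class_labels(axis)
      cnt <- c(0, 0, 0)
      for (k in seq_len(nrow(iv))) {
        ch <- iv$chrom[k]
        v <- classmap[[axis]][[ch]]
        if (is.null(v)) stop("annotation on unknown chromosome ", ch)
        lo <- max(iv$start[k], 0L) + 1L
        hi <- min(iv$end[k], length(v))
        if (hi < lo) next
        cnt <- cnt + tabulate(v[lo:hi], 3)
      }
      tot <- sum(cnt)
      tot_cls <- sum(cnt[1:2])
      rows[[length(rows) + 1]] <- data.frame(
        annotation = name, axis = axis, label = labels,
        bp = cnt,
        fraction = if (tot > 0) cnt / tot else rep(NA_real_, 3),
        fraction_classified = c(
          if (tot_cls > 0) cnt[1:2] / tot_cls else rep(NA_real_, 2),
          NA_real_))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call genes active or silent from expression values
#'
#' Expression distributions in such data are bimodal (a silent mode near
#' zero and an active log-normal mode). The threshold is placed at the
#' antimode of a kernel-density estimate of log1p(expression) between the
#' two largest modes; if the density is unimodal the median is used.
#'
#' @param expression Nonnegative numeric vector (one value per gene).
#' @return An \code{activity_call}: list with active (logical), threshold
#'   (on the log1p scale), and boundary (number of active genes, the row
#'   index separating active from silent in an expression-sorted display).
#' @export
classify_gene_activity <- function(expression) {
  if (length(expression) < 2) stop("need at least two genes")
  if (any(expression < 0)) stop("expression must be nonnegative")
  lx <- log1p(expression)
  if (max(lx) == min(lx)) {
    active <- rep(expression[1] > 0, length(expression))
    thr <- if (expression[1] > 0) -Inf else Inf
  } else {
    d <- density(lx)
    y <- d$y
    is_max <- which(diff(sign(diff(c(-Inf, y, -Inf)))) < 0)
    if (length(is_max) >= 2) {
      top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
      seg <- top2[1]:top2[2]
      thr <- d$x[seg[which.min(y[seg])]]
    } else {
      thr <- stats::median(lx)
    }
    active <- lx > thr
  }
  structure(list(active = active, threshold = thr,
                 boundary = sum(active)),
            class = "activity_call")
}

#' @export
print.activity_call <- function(x, ...) {
  cat(sprintf("activity_call: %d active / %d genes (log1p threshold %.3f)\n",
              sum(x$active), length(x$active), x$threshold))
  invisible(x)
}

#' Percentage arithmetic for DHS-TSS summaries
#'
#' @param count Numerator count(s).
#' @param total Denominator count.
#' @return Percentages rounded to 1 decimal place.
#' @export
percentage_of <- function(count, total) {
  round(100 * count / total, 1)
}

#' Summarize DHS positions relative to TSS
#'
#' For each DHS interval: whether it contains a TSS (half-open membership),
#' and the distance from the nearer DHS edge to the nearest TSS (0 when
#' contained). Reports counts and percentages (1 decimal place) of DHS
#' containing a TSS and of DHS at least each given distance from any TSS.
#'
#' @param dhs data.frame of DHS intervals (chrom, start, end; 0-based
#'   half-open).
#' @param tss data.frame of TSS positions (chrom, pos).
#' @param distances Distance cutoffs in bp (default 1000 and 5000).
#' @return List with total, contains (count), pct_contains, and per cutoff
#'   n_ge_<d> / pct_ge_<d>; element distance holds the per-DHS distances.
#' @export
dhs_tss_overlap_summary <- function(dhs, tss, distances = c(1000, 5000)) {
  dhs <- as.data.frame(dhs); tss <- as.data.frame(tss)
  n <- nrow(dhs)
  dist <- rep(Inf, n)
  for (ch in unique(dhs$chrom)) {
    di <- which(dhs$chrom == ch)
    pos <- sort(tss$pos[tss$chrom == ch])
    if (length(pos) == 0) next
    for (k in di) {
      s <- dhs$start[k]; e <- dhs$end[k]
      inside <- any(pos >= s & pos < e)
      if (inside) { dist[k] <- 0; next }
      # distance from the nearer edge to the nearest TSS
      dist[k] <- min(abs(pos - s), abs(pos - (e - 1L)))
    }
  }
  contains <- sum(dist == 0)
  out <- list(total = n, contains = contains,
              pct_contains = percentage_of(contains, n),
              distance = dist)
  for (d in distances) {
    cnt <- sum(dist >= d)
    out[[paste0("n_ge_", d)]] <- cnt
    out[[paste0("pct_ge_", d)]] <- percentage_of(cnt, n)
  }
  out
}

#' Write a chromatin class map as BED
#'
#' One record per maximal run of identical labels; the record name is the
#' label.
#'
#' @param classmap A \code{chromatin_class_map}.
#' @param path Output path.
#' @param axis Which classification axis to export.
#' @return \code{path}, invisibly.
#' @export
write_class_bed <- function(classmap, path,
                            axis = c("sensitivity", "accessibility")) {
  axis <- match.arg(axis)
  stopifnot(inherits(classmap, "chromatin_class_map"))
  labels <- .class_labels(axis)
  rows <- list()
  for (ch in names(classmap[[axis]])) {
    r <- rle(classmap[[axis]][[ch]])
    ends <- cumsum(r$lengths)
    rows[[ch]] <- data.frame(chrom = ch,
                             start = ends - r$lengths,
                             end = ends,
                             name = labels[r$values])
  }
  tab <- do.call(rbind, rows)
  data.table::fwrite(tab, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
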