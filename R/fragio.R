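# Readers/writers for genomic formats and the fragment data model.
# Package-wide convention: 0-based half-open intervals (BED dialect).

#' Read a chrom.sizes file
#'
#' @param path Two-column TSV: chromosome name, length in bp.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  stopifnot(file.exists(path))
  tab <- data.table::fread(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "size"))
  if (any(tab$size <= 0)) stop("non-positive chromosome length in ", path)
  sizes <- as.integer(tab$size)
  names(sizes) <- as.character(tab$chrom)
  sizes
}

.validate_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector of chromosome lengths")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  invisible(chrom_sizes)
}

#' Construct a fragment set
#'
#' A fragment set groups paired-end fragment intervals by chromosome, sorted
#' by start, together with the chromosome sizes. Duplicate fragments are
#' retained: no deduplication is applied at any stage.
#'
#' @param frags data.frame with columns chrom, start, end (0-based half-open).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param label Free-text label, e.g. "MNaseHIGH_1n".
#' @return A \code{fragment_set} object.
#' @export
fragment_set <- function(frags, chrom_sizes, label = "") {
  .validate_chrom_sizes(chrom_sizes)
  frags <- as.data.frame(frags)
  bad <- !(frags$chrom %in% names(chrom_sizes))
  if (any(bad))
    stop("unknown chromosome(s): ",
         paste(unique(frags$chrom[bad]), collapse = ", "))
  if (any(frags$end <= frags$start))
    stop("fragments must satisfy start < end (zero/negative length)")
  oob <- frags$start < 0 | frags$end > chrom_sizes[frags$chrom]
  n_oob <- sum(oob)
  if (n_oob > 0) {
    warning(n_oob, " out-of-bounds fragment(s) rejected")
    frags <- frags[!oob, , drop = FALSE]
  }
  per_chrom <- lapply(names(chrom_sizes), function(ch) {
    sub <- frags[frags$chrom == ch, c("start", "end"), drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    rownames(sub) <- NULL
    sub$start <- as.integer(sub$start)
    sub$end <- as.integer(sub$end)
    sub
  })
  names(per_chrom) <- names(chrom_sizes)
  structure(list(fragments = per_chrom,
                 chrom_sizes = chrom_sizes,
                 label = label,
                 n_rejected = n_oob),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  n <- sum(vapply(x$fragments, nrow, integer(1)))
  cat(sprintf("fragment_set '%s': %d fragments on %d chromosome(s)\n",
              x$label, n, length(x$chrom_sizes)))
  invisible(x)
}

#' Number of fragments in a fragment set
#' @param x A \code{fragment_set}.
#' @return Integer count.
#' @export
n_fragments <- function(x) {
  stopifnot(inherits(x, "fragment_set"))
  sum(vapply(x$fragments, nrow, integer(1)))
}

#' Fragment lengths of a fragment set
#' @param x A \code{fragment_set}.
#' @return Integer vector of end - start over all fragments.
#' @export
fragment_lengths <- function(x) {
  stopifnot(inherits(x, "fragment_set"))
  unlist(lapply(x$fragments, function(f) f$end - f$start), use.names = FALSE)
}

#' Read paired-end fragments from BED3 or BEDPE
#'
#' BED records are taken as fragment intervals directly. BEDPE mate pairs are
#' collapsed to the template span min(starts)..max(ends); both mates must map
#' to the same chromosome. Records with zero or negative length are an error;
#' records outside the chromosome bounds are rejected with a warning count.
#'
#' @param path Input file.
#' @param format "BED" or "BEDPE".
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param label Label stored on the returned set.
#' @return A \code{fragment_set}.
#' @export
read_fragments <- function(path, format = c("BED", "BEDPE"), chrom_sizes,
                           label = basename(path)) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  .validate_chrom_sizes(chrom_sizes)
  tab <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  if (format == "BED") {
    if (ncol(tab) < 3) stop("BED input needs >= 3 columns")
    frags <- data.frame(chrom = as.character(tab[[1]]),
                        start = as.integer(tab[[2]]),
                        end = as.integer(tab[[3]]))
  } else {
    if (ncol(tab) < 6) stop("BEDPE input needs >= 6 columns")
    if (any(tab[[1]] != tab[[4]]))
      stop("BEDPE mates on different chromosomes are not supported")
    frags <- data.frame(chrom = as.character(tab[[1]]),
                        start = as.integer(pmin(tab[[2]], tab[[5]])),
                        end = as.integer(pmax(tab[[3]], tab[[6]])))
  }
  bad <- which(is.na(frags$start) | is.na(frags$end))
  if (length(bad))
    stop("malformed coordinates at line ", bad[1], " of ", path)
  zl <- which(frags$end <= frags$start)
  if (length(zl))
    stop("zero/negative-length record at line ", zl[1], " of ", path)
  fragment_set(frags, chrom_sizes, label = label)
}

#' Write a fragment set as BED3
#'
#' @param x A \code{fragment_set}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fragments <- function(x, path) {
  stopifnot(inherits(x, "fragment_set"))
  tabs <- lapply(names(x$fragments), function(ch) {
    f <- x$fragments[[ch]]
    if (nrow(f) == 0) return(NULL)
    data.frame(chrom = ch, start = f$start, end = f$end)
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab)) tab <- data.frame(chrom = character(),
                                      start = integer(), end = integer())
  data.table::fwrite(tab, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a gene expression table
#'
#' @param path TSV with columns gene_id and value (header required).
#' @return Named numeric vector of expression values.
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  tab <- data.table::fread(path, header = TRUE, sep = "\t")
  if (!all(c("gene_id", "value") %in% names(tab)))
    stop("expression table needs columns gene_id, value")
  if (any(tab$value < 0)) stop("expression values must be nonnegative")
  v <- as.numeric(tab$value)
  names(v) <- as.character(tab$gene_id)
  v
}

# TSS/TTS per the strand rule: on + the TSS is the first bp of the interval
# and the TTS the last; on - they are swapped. Coordinates are 0-based bp.
.derive_tss_tts <- function(start, end, strand) {
  tss <- ifelse(strand == "+", start, end - 1L)
  tts <- ifelse(strand == "+", end - 1L, start)
  list(tss = as.integer(tss), tts = as.integer(tts))
}

#' Read gene annotations with expression
#'
#' Reads BED12 or GFF3 gene annotations, derives TSS/TTS per strand, and
#' joins an expression table by gene id. Ids absent from the expression table
#' get expression 0 with a warning reporting the count. Unstranded genes are
#' an error because metagene analyses require orientation.
#'
#' @param path Annotation file.
#' @param format "BED12" or "GFF3".
#' @param expression Named numeric vector (see \code{\link{read_expression}})
#'   or path to an expression TSV. NULL assigns 0 throughout.
#' @return data.frame with columns id, chrom, start, end, strand, tss, tts,
#'   expression (coordinates 0-based half-open).
#' @export
read_genes <- function(path, format = c("BED12", "GFF3"), expression = NULL) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "BED12") {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- if (!is.null(gr$name)) as.character(gr$name)
           else paste0("gene", seq_along(gr))
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID)
           else if (!is.null(gr$Name)) as.character(gr$Name)
           else paste0("gene", seq_along(gr))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("unstranded gene(s) in ", path, "; metagenes require orientation")
  # GRanges is 1-based closed; convert to 0-based half-open
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  pos <- .derive_tss_tts(start0, end0, strand)
  if (is.character(expression)) expression <- read_expression(expression)
  if (is.null(expression)) expression <- numeric(0)
  expr <- expression[ids]
  missing_ids <- is.na(expr)
  if (any(missing_ids) && length(expression) > 0)
    warning(sum(missing_ids), " gene id(s) absent from expression table; ",
            "expression set to 0")
  expr[missing_ids] <- 0
  data.frame(id = ids,
             chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = start0, end = end0, strand = strand,
             tss = pos$tss, tts = pos$tts,
             expression = as.numeric(expr),
             stringsAsFactors = FALSE)
}

#' Read a BED file of intervals
#'
#' @param path BED3+ file.
#' @return data.frame with chrom, start, end (0-based half-open) and name
#'   when present.
#' @export
read_intervals <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- as.character(gr$name)
  out
}

#' Construct a base-pair profile
#'
#' A profile is one numeric value per bp per chromosome (dyad density or
#' nucleosome occupancy).
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param kind "dyad" or "occupancy".
#' @param normalized Logical: per-chromosome mean already scaled to 1.
#' @return A \code{bp_profile} object.
#' @export
bp_profile <- function(values, kind = c("dyad", "occupancy"),
                       normalized = FALSE) {
  kind <- match.arg(kind)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("profile values must be a named list (one vector per chromosome)")
  if (any(vapply(values, function(v) any(v < 0), logical(1))))
    stop("profile values must be nonnegative")
  structure(list(values = lapply(values, as.numeric),
                 chrom_sizes = vapply(values, length, integer(1)),
                 kind = kind, normalized = normalized),
            class = "bp_profile")
}

#' @export
print.bp_profile <- function(x, ...) {
  cat(sprintf("bp_profile (%s%s): %d chromosome(s), %d bp total\n",
              x$kind, if (x$normalized) ", normalized" else "",
              length(x$values), sum(x$chrom_sizes)))
  invisible(x)
}

#' Write a profile as bedGraph or wiggle
#'
#' Adjacent base pairs with equal values are merged into one bedGraph record.
#' The written track round-trips through \code{\link{read_track}} exactly.
#'
#' @param profile A \code{bp_profile}.
#' @param path Output path.
#' @param format "bedGraph" or "wig".
#' @return \code{path}, invisibly.
#' @export
write_track <- function(profile, path, format = c("bedGraph", "wig")) {
  format <- match.arg(format)
  stopifnot(inherits(profile, "bp_profile"))
  if (any(vapply(profile$values, function(v) any(!is.finite(v)), logical(1))))
    stop("profile contains NaN/Inf; refusing to write")
  grs <- lapply(names(profile$values), function(ch) {
    v <- profile$values[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts, ends),
                           score = r$values)
  })
  gr <- suppressWarnings(do.call(c, grs))
  sl <- profile$chrom_sizes
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path,
                      format = if (format == "bedGraph") "bedGraph" else "wig")
  invisible(path)
}

#' Read a bedGraph/wiggle track into a dense profile
#'
#' @param path Track file.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param kind Profile kind for the result.
#' @return A \code{bp_profile}; bps without a record are 0.
#' @export
read_track <- function(path, chrom_sizes, kind = c("dyad", "occupancy")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  .validate_chrom_sizes(chrom_sizes)
  gr <- rtracklayer::import(path)
  values <- lapply(names(chrom_sizes), function(ch) {
    v <- numeric(chrom_sizes[[ch]])
    sub <- gr[as.character(GenomeInfoDb::seqnames(gr)) == ch]
    if (length(sub)) {
      s <- BiocGenerics::start(sub); e <- BiocGenerics::end(sub)
      for (i in seq_along(sub)) v[s[i]:e[i]] <- sub$score[i]
    }
    v
  })
  names(values) <- names(chrom_sizes)
  bp_profile(values, kind = kind, normalized = FALSE)
}
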