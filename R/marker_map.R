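#' Summarize a marker panel's polymorphism
#'
#' Per-chromosome and total counts of surveyed and polymorphic markers, the
#' polymorphic percentage (rounded to one decimal), and — when a genome is
#' supplied — the average spacing of polymorphic markers (chromosome length
#' in Mb divided by polymorphic count, two decimals; \code{NA} when a
#' chromosome has no polymorphic marker).
#'
#' @param panel Data frame of marker loci with columns \code{chrom} and
#'   logical \code{polymorphic} (optionally \code{class} with values
#'   \code{"SSR"}/\code{"InDel"}, counted separately when present).
#' @param genome Optional [genome_spec()] for the density column.
#' @return Data frame with one row per chromosome plus a \code{"Total"}
#'   row: columns \code{chrom}, (\code{ssr}, \code{indel} if classed),
#'   \code{surveyed}, \code{polymorphic}, \code{pct}, \code{density_mb}.
#' @export
summarize_marker_polymorphism <- function(panel, genome = NULL) {
  if (nrow(panel) == 0) stop("marker panel is empty")
  if (!all(c("chrom", "polymorphic") %in% names(panel)))
    stop("panel must have columns chrom and polymorphic")
  chroms <- if (!is.null(genome)) genome$chrom else unique(panel$chrom)
  classed <- "class" %in% names(panel)
  one <- function(sel, label, len) {
    p <- panel[sel, , drop = FALSE]
    surveyed <- nrow(p)
    poly <- sum(p$polymorphic)
    row <- data.frame(chrom = label, stringsAsFactors = FALSE)
    if (classed) {
      row$ssr <- sum(p$class == "SSR")
      row$indel <- sum(p$class == "InDel")
    }
    row$surveyed <- surveyed
    row$polymorphic <- poly
    row$pct <- if (surveyed > 0) round(100 * poly / surveyed, 1) else NA_real_
    row$density_mb <- if (!is.null(len) && poly > 0)
      round(len / 1e6 / poly, 2) else NA_real_
    row
  }
  rows <- lapply(seq_along(chroms), function(i)
    one(panel$chrom == chroms[i], chroms[i],
        if (!is.null(genome)) genome$length[i] else NULL))
  rows[[length(rows) + 1L]] <-
    one(rep(TRUE, nrow(panel)), "Total",
        if (!is.null(genome)) sum(genome$length) else NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call substituted segments from marker genotypes (graphical genotype)
#'
#' Implements the DD/DR/RR convention for estimating substituted segments
#' from a sparse marker panel: a maximal run of donor-type calls becomes a
#' segment; each boundary falls at the midpoint of the flanking
#' donor/recipient (DR) marker interval, so the segment length equals the
#' DD span plus half of each DR flank. A donor run touching the first
#' (last) polymorphic marker of a chromosome extends to the chromosome
#' start (end), since no recipient flank exists there. Missing calls are
#' transparent: runs are computed over non-missing markers only.
#'
#' @param calls Marker genotype table (columns \code{line}, \code{marker},
#'   \code{call} with symbols \code{"R"}, \code{"D"}, \code{"H"},
#'   \code{"."}); may contain one or many lines.
#' @param panel Data frame of marker loci (\code{marker}, \code{chrom},
#'   \code{pos}); every called marker must be present.
#' @param genome A [genome_spec()].
#' @param allow_het If \code{FALSE} (default, finished-line mode) a
#'   heterozygous call is an error; if \code{TRUE} heterozygous calls are
#'   treated as donor-informative for segment presence.
#' @return A [cssl_segments()] with source \code{"marker"}.
#' @export
call_marker_segments <- function(calls, panel, genome, allow_het = FALSE) {
  bad <- setdiff(calls$marker, panel$marker)
  if (length(bad) > 0)
    stop("calls refer to markers absent from the panel: ",
         paste(utils::head(bad, 3), collapse = ", "))
  if (!all(calls$call %in% c("R", "D", "H", ".")))
    stop("unknown genotype symbol in calls")
  if (any(calls$call == "H") && !allow_het)
    stop("heterozygous calls present; finished CSSLs are homozygous ",
         "(use allow_het = TRUE to treat them as donor-informative)")
  idx <- match(calls$marker, panel$marker)
  calls$chrom <- panel$chrom[idx]
  calls$pos <- panel$pos[idx]
  lines <- unique(calls$line)
  rows <- list()
  for (l in lines) {
    for (ch in genome$chrom) {
      cc <- calls[calls$line == l & calls$chrom == ch, , drop = FALSE]
      cc <- cc[cc$call != ".", , drop = FALSE]
      if (nrow(cc) == 0) next
      cc <- cc[order(cc$pos), , drop = FALSE]
      donor <- cc$call %in% c("D", "H")
      r <- rle(donor)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      L <- chrom_length(genome, ch)
      for (j in seq_along(r$values)) {
        if (!r$values[j]) next
        i1 <- starts[j]; i2 <- ends[j]
        seg_start <- if (i1 == 1L) 1
          else floor((cc$pos[i1 - 1L] + cc$pos[i1]) / 2)
        seg_end <- if (i2 == nrow(cc)) L + 1
          else floor((cc$pos[i2] + cc$pos[i2 + 1L]) / 2)
        rows[[length(rows) + 1L]] <-
          data.frame(line = l, chrom = ch, start = seg_start, end = seg_end,
                     stringsAsFactors = FALSE)
      }
    }
  }
  seg <- if (length(rows)) do.call(rbind, rows)
    else data.frame(line = character(), chrom = character(),
                    start = numeric(), end = numeric())
  cssl_segments(seg, lines = lines, genome = genome, source = "marker")
}

#' Estimated substituted-segment length from the DD/DR rule
#'
#' The estimated length of a substituted segment is the span flanked by two
#' donor-type markers (DD, counted in full) plus half of each flanking
#' donor/recipient (DR) interval.
#'
#' @param dd_span Span between the outermost donor-type markers of the run,
#'   in bp (0 for a single-marker run).
#' @param dr_left,dr_right Lengths of the flanking DR intervals in bp.
#' @return Estimated segment length in bp; vectorized.
#' @export
estimate_segment_length <- function(dd_span, dr_left, dr_right) {
  if (any(dd_span < 0) || any(dr_left < 0) || any(dr_right < 0))
    stop("spans must be non-negative")
  dd_span + dr_left / 2 + dr_right / 2
}
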