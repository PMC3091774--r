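#' Build the recombination bin partition of a population
#'
#' Overlaps between the lines' substituted segments delineate bins: per
#' chromosome, all segment start/end breakpoints across lines are pooled,
#' sorted and deduplicated; consecutive breakpoints bound candidate
#' intervals, of which those inside the union of donor segments become
#' bins. Regions never substituted in any line are not bins (they carry no
#' genotype contrast). Bin indices \code{x1, x2, ...} are assigned
#' genome-wide in positional order (chromosome order, then start).
#'
#' @param maps A [cssl_segments()] population.
#' @param genome A [genome_spec()] fixing chromosome order.
#' @return Data frame of class \code{bin_map}: columns \code{bin} (index),
#'   \code{name} (\code{"x<k>"}), \code{chrom}, \code{start}, \code{end}.
#' @export
build_bins <- function(maps, genome) {
  seg <- as.data.frame(maps)
  rows <- list()
  for (ch in genome$chrom) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) next
    bp <- sort(unique(c(s$start, s$end)))
    cand <- cbind(start = bp[-length(bp)], end = bp[-1])
    uni <- merge_intervals(as.matrix(s[, c("start", "end")]))
    ## a candidate interval is either inside the union or outside it,
    ## because union endpoints are themselves breakpoints
    keep <- iv_contains(uni, cand[, 1])
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) > 0)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = ch, start = cand[, 1], end = cand[, 2],
                   stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  out <- cbind(bin = seq_len(nrow(out)),
               name = if (nrow(out)) paste0("x", seq_len(nrow(out)))
                      else character(),
               out)
  rownames(out) <- NULL
  class(out) <- c("bin_map", "data.frame")
  out
}

#' Line x bin genotype matrix of +1/-1 codes
#'
#' Entry \code{+1} when the line's donor segments cover the bin, \code{-1}
#' otherwise. By construction of [build_bins()] coverage is all-or-nothing;
#' a partial overlap signals that bins and maps disagree and raises an
#' error.
#'
#' @param maps A [cssl_segments()] population.
#' @param bins A \code{bin_map} built from the same population.
#' @return Integer matrix (lines x bins) with \code{dimnames}; the bin
#'   table is attached as attribute \code{"bins"}.
#' @export
bin_genotypes <- function(maps, bins) {
  lines <- map_lines(maps)
  m <- matrix(-1L, nrow = length(lines), ncol = nrow(bins),
              dimnames = list(lines, bins$name))
  for (i in seq_along(lines)) {
    s <- segments_for_line(maps, lines[i])
    for (ch in unique(s$chrom)) {
      sc <- s[s$chrom == ch, , drop = FALSE]
      sel <- which(bins$chrom == ch)
      if (length(sel) == 0) next
      for (j in seq_len(nrow(sc))) {
        contained <- bins$start[sel] >= sc$start[j] &
                     bins$end[sel] <= sc$end[j]
        partial <- !contained & bins$start[sel] < sc$end[j] &
                   bins$end[sel] > sc$start[j]
        if (any(partial))
          stop("segment of line ", lines[i], " partially overlaps bin ",
               bins$name[sel][partial][1],
               "; bins were not built from these maps")
        m[i, sel[contained]] <- 1L
      }
    }
  }
  attr(m, "bins") <- bins
  m
}

#' Validate a bin genotype matrix for regression
#'
#' Drops constant columns (no genotype contrast) and collapses groups of
#' identical columns to their leftmost representative, so the design fed
#' to the stepwise regression is free of exact collinearity. The merged
#' physical span of each collapsed group is recorded: a QTL mapped to a
#' representative bin is only localized up to the group's span.
#'
#' @param matrix A matrix from [bin_genotypes()].
#' @return List with elements \code{matrix} (reduced, bins attribute
#'   updated with \code{span_start}/\code{span_end} columns) and
#'   \code{report} (list with \code{dropped} names and a \code{merged}
#'   data frame of representative/member pairs).
#' @export
validate_bins <- function(matrix) {
  bins <- attr(matrix, "bins")
  const <- apply(matrix, 2, function(col) length(unique(col)) == 1L)
  dropped <- colnames(matrix)[const]
  m <- matrix[, !const, drop = FALSE]
  keep_bins <- bins[!const, , drop = FALSE]
  pat <- apply(m, 2, paste, collapse = ",")
  rep_idx <- match(pat, pat)           # leftmost column with same pattern
  is_rep <- rep_idx == seq_along(pat)
  merged <- data.frame(representative = colnames(m)[rep_idx[!is_rep]],
                       member = colnames(m)[!is_rep],
                       stringsAsFactors = FALSE)
  keep_bins$span_start <- keep_bins$start
  keep_bins$span_end <- keep_bins$end
  for (g in unique(rep_idx)) {
    members <- which(rep_idx == g)
    same_chrom <- members[keep_bins$chrom[members] == keep_bins$chrom[g]]
    keep_bins$span_start[g] <- min(keep_bins$start[same_chrom])
    keep_bins$span_end[g] <- max(keep_bins$end[same_chrom])
  }
  out <- m[, is_rep, drop = FALSE]
  attr(out, "bins") <- keep_bins[is_rep, , drop = FALSE]
  list(matrix = out,
       report = list(dropped = dropped, merged = merged))
}
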