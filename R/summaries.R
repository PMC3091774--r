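#' Distribution of segments carried per line
#'
#' @param maps A [cssl_segments()] population (non-empty line set).
#' @return Data frame with columns \code{segments} (k) and \code{lines}
#'   (number of lines carrying exactly k segments), covering every k
#'   observed (including 0 when lines carry no segment), plus a
#'   \code{total} attribute equal to the number of lines.
#' @export
segment_count_distribution <- function(maps) {
  lines <- map_lines(maps)
  if (length(lines) == 0) stop("population has no lines")
  k <- vapply(lines, function(l) nrow(segments_for_line(maps, l)), 0L)
  tab <- table(k)
  out <- data.frame(segments = as.integer(names(tab)),
                    lines = as.integer(tab))
  attr(out, "total") <- length(lines)
  out
}

#' Chromosome and genome coverage of substituted segments
#'
#' For each chromosome: the summed length of all lines' segments (Mb), the
#' fold coverage (total / chromosome length), the union coverage length
#' obtained by merging overlapping segments across lines (Mb), and the
#' coverage rate (100 x union / chromosome length). The \code{"Genome"}
#' row aggregates: summed lengths, fold = grand total / genome length,
#' rate = 100 x union total / genome length. Values are unrounded;
#' round at presentation time (lengths to 2 decimals, rates to 1).
#'
#' @param maps A [cssl_segments()] population.
#' @param genome A [genome_spec()].
#' @return Data frame with columns \code{chrom}, \code{n_segments},
#'   \code{total_mb}, \code{fold}, \code{union_mb}, \code{rate_pct}.
#' @export
coverage_summary <- function(maps, genome) {
  seg <- as.data.frame(maps)
  if (nrow(seg) > 0 &&
      any(seg$end > chrom_length(genome, seg$chrom) + 1))
    stop("segments extend beyond the genome")
  rows <- lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]; L <- genome$length[i]
    s <- seg[seg$chrom == ch, , drop = FALSE]
    total <- sum(s$end - s$start)
    uni <- iv_total(merge_intervals(as.matrix(s[, c("start", "end")])))
    data.frame(chrom = ch, n_segments = nrow(s), total_mb = total / 1e6,
               fold = total / L, union_mb = uni / 1e6,
               rate_pct = 100 * uni / L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  G <- sum(genome$length)
  out <- rbind(out, data.frame(
    chrom = "Genome", n_segments = sum(out$n_segments),
    total_mb = sum(out$total_mb), fold = sum(out$total_mb) * 1e6 / G,
    union_mb = sum(out$union_mb),
    rate_pct = 100 * sum(out$union_mb) * 1e6 / G))
  rownames(out) <- NULL
  out
}

#' Minimum, maximum and mean substituted-segment length
#'
#' @param maps A [cssl_segments()] population with at least one segment.
#' @return Named numeric vector \code{c(min, max, mean)} in Mb (unrounded;
#'   the mean is total length / segment count). All \code{NA} with a
#'   warning when the population carries no segment.
#' @export
segment_length_stats <- function(maps) {
  seg <- as.data.frame(maps)
  if (nrow(seg) == 0) {
    warning("no segments; length statistics undefined")
    return(c(min = NA_real_, max = NA_real_, mean = NA_real_))
  }
  len <- (seg$end - seg$start) / 1e6
  c(min = min(len), max = max(len), mean = sum(len) / length(len))
}

#' Physical size of a 1-based end-exclusive interval
#'
#' The package-wide coordinate convention: an interval \code{[start, end)}
#' has \code{size = end - start}; e.g. the interval 39868630-40660285 has
#' size 791655 bp.
#'
#' @param start,end Numeric vectors, \code{end > start}.
#' @return \code{end - start}, vectorized.
#' @export
interval_size <- function(start, end) {
  if (any(end <= start)) stop("end must exceed start")
  end - start
}

#' Histogram of segment lengths in fixed Mb bins
#'
#' @param maps A [cssl_segments()] population.
#' @param breaks_mb Bin edges in Mb (default 0 to 25 by 1).
#' @return Data frame with columns \code{from_mb}, \code{to_mb},
#'   \code{n_segments}.
#' @export
segment_length_histogram <- function(maps, breaks_mb = seq(0, 25, by = 1)) {
  seg <- as.data.frame(maps)
  len <- (seg$end - seg$start) / 1e6
  h <- graphics::hist(len, breaks = c(breaks_mb, Inf), plot = FALSE,
                      right = FALSE)
  data.frame(from_mb = utils::head(h$breaks, -1),
             to_mb = utils::tail(h$breaks, -1),
             n_segments = h$counts)
}
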