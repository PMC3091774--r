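#' Genome specification
#'
#' A genome specification anchors every physical coordinate in the package:
#' an ordered set of chromosomes with their lengths in base pairs. All
#' intervals handled by the package are 1-based with an exclusive end, so
#' that \code{size = end - start}.
#'
#' @param chrom Character vector of unique chromosome names, in genome order.
#' @param length Numeric vector of chromosome lengths in bp, all positive.
#'
#' @return An object of class \code{genome_spec}: a data frame with columns
#'   \code{chrom} and \code{length}.
#' @examples
#' genome_spec(c("chr1", "chr2"), c(30e6, 20e6))
#' @export
genome_spec <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("genome must contain at least one chromosome")
  if (length(chrom) != length(length))
    stop("'chrom' and 'length' must have equal length")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive and finite")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_spec", "data.frame"))
}

#' Default rice genome used by the simulator
#'
#' Twelve chromosomes totalling about 372.2 Mb, the physical size of the
#' japonica reference assembly against which indica/japonica CSSL panels
#' are genotyped. Lengths are rounded to 0.1 Mb.
#'
#' @return A [genome_spec()] with chromosomes \code{chr1..chr12}.
#' @export
rice_genome <- function() {
  genome_spec(paste0("chr", 1:12),
              c(43.6, 35.9, 36.4, 35.2, 29.9, 31.3,
                29.7, 28.3, 23.0, 22.9, 28.5, 27.5) * 1e6)
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("Genome: %d chromosomes, %.2f Mb total\n",
              nrow(x), sum(x$length) / 1e6))
  print.data.frame(x, ...)
  invisible(x)
}

genome_length <- function(genome) sum(genome$length)

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$length[i]
}

## Run an expression with the RNG seeded locally: the caller's .Random.seed
## is untouched, so all randomness flows through the explicit seed argument.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("'seed' must be a single integer")
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Substituted-segment maps for a CSSL population
#'
#' The central container of the package: the donor-homozygous segments each
#' line carries on the recurrent-parent background. Stored as one data frame
#' with one row per segment and columns \code{line}, \code{chrom},
#' \code{start} (1-based), \code{end} (exclusive). Lines carrying no segment
#' are retained through the \code{lines} attribute so population summaries
#' and bin genotypes see them.
#'
#' @param segments Data frame with columns \code{line}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param lines Character vector of all line ids in the population,
#'   including lines without segments. Defaults to the lines present in
#'   \code{segments}.
#' @param genome Optional [genome_spec()]; when supplied, segments are
#'   validated against chromosome bounds.
#' @param source Provenance of the map: \code{"truth"}, \code{"marker"} or
#'   \code{"sequencing"}.
#'
#' @return An object of class \code{cssl_segments}.
#' @export
cssl_segments <- function(segments, lines = NULL, genome = NULL,
                          source = c("truth", "marker", "sequencing")) {
  source <- match.arg(source)
  need <- c("line", "chrom", "start", "end")
  if (!all(need %in% names(segments)))
    stop("segments must have columns: ", paste(need, collapse = ", "))
  segments <- as.data.frame(segments)[need]
  segments$line <- as.character(segments$line)
  segments$chrom <- as.character(segments$chrom)
  segments$start <- as.numeric(segments$start)
  segments$end <- as.numeric(segments$end)
  if (nrow(segments) > 0) {
    if (any(segments$start < 1)) stop("segment starts must be >= 1")
    if (any(segments$end <= segments$start))
      stop("segment end must exceed start (1-based, end-exclusive)")
    if (!is.null(genome)) {
      if (any(segments$end > chrom_length(genome, segments$chrom) + 1))
        stop("segment extends beyond chromosome end")
    }
    ord <- order(segments$line, segments$chrom, segments$start)
    segments <- segments[ord, , drop = FALSE]
    rownames(segments) <- NULL
    ## overlap check within line x chromosome
    key <- paste(segments$line, segments$chrom, sep = "\r")
    for (k in unique(key)) {
      s <- segments[key == k, , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop("overlapping segments within line ", s$line[1],
             " on ", s$chrom[1])
    }
  }
  if (is.null(lines)) lines <- unique(segments$line)
  structure(segments, lines = as.character(lines), source = source,
            class = c("cssl_segments", "data.frame"))
}

#' @export
print.cssl_segments <- function(x, ...) {
  cat(sprintf("CSSL substitution map (%s): %d lines, %d segments\n",
              attr(x, "source"), length(attr(x, "lines")), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

## subsetting keeps attributes
segments_for_line <- function(maps, line) {
  s <- as.data.frame(maps)
  s[s$line == line, , drop = FALSE]
}

#' Line ids of a population, including segment-free lines
#'
#' @param maps A [cssl_segments()] population.
#' @return Character vector of line ids.
#' @export
map_lines <- function(maps) attr(maps, "lines")

## ---- interval algebra (matrices with columns start, end; 1-based,
## end-exclusive) ----------------------------------------------------------

## merge overlapping or touching intervals; input need not be sorted
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(iv_empty())
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out_s <- numeric(nrow(iv)); out_e <- numeric(nrow(iv))
  n <- 0L; cs <- iv[1, 1]; ce <- iv[1, 2]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= ce) ce <- max(ce, iv[i, 2])
    else { n <- n + 1L; out_s[n] <- cs; out_e[n] <- ce; cs <- iv[i, 1]; ce <- iv[i, 2] }
  }
  n <- n + 1L; out_s[n] <- cs; out_e[n] <- ce
  cbind(start = out_s[seq_len(n)], end = out_e[seq_len(n)])
}

iv_empty <- function() cbind(start = numeric(0), end = numeric(0))

intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(iv_empty())
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1], b[, 1]); e <- pmin(a[i, 2], b[, 2])
    keep <- s < e
    if (any(keep)) out[[length(out) + 1L]] <- cbind(s[keep], e[keep])
  }
  if (length(out) == 0) return(iv_empty())
  iv <- do.call(rbind, out)
  colnames(iv) <- c("start", "end")
  merge_intervals(iv)
}

iv_total <- function(iv) if (nrow(iv) == 0) 0 else sum(iv[, 2] - iv[, 1])

## is position p (1-based) inside any interval?
iv_contains <- function(iv, p) {
  if (nrow(iv) == 0) return(rep(FALSE, length(p)))
  out <- rep(FALSE, length(p))
  for (i in seq_len(nrow(iv))) out <- out | (p >= iv[i, 1] & p < iv[i, 2])
  out
}
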