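#' Filter parent pileups into a parent-discriminating SNP catalog
#'
#' Applies the parent-level SNP discovery filters to per-read base calls
#' from the two parents: bases with Phred quality below 25 are removed;
#' sites with conflicting genotypes among the remaining reads of a parent
#' are excluded; sites whose overall read depth in a parent is 100 or more
#' are excluded (copy-number guard); sites left without any read in either
#' parent are excluded. A surviving site enters the catalog when the two
#' parents' consensus bases differ.
#'
#' @param reads Data frame with one row per read base: columns
#'   \code{chrom}, \code{pos}, \code{parent}
#'   (\code{"recipient"}/\code{"donor"}), \code{allele}, \code{qual}.
#'   Must be sorted by position within chromosome.
#' @param min_qual Minimum retained base quality (default 25; bases with
#'   quality strictly below are removed).
#' @param max_depth Depth bound (default 100; sites with depth >= this are
#'   excluded).
#' @return A \code{snp_catalog} data frame (\code{chrom}, \code{pos},
#'   \code{recipient}, \code{donor}).
#' @export
filter_parent_snps <- function(reads, min_qual = 25, max_depth = 100) {
  need <- c("chrom", "pos", "parent", "allele", "qual")
  if (!all(need %in% names(reads)))
    stop("reads must have columns: ", paste(need, collapse = ", "))
  for (ch in unique(reads$chrom)) {
    p <- reads$pos[reads$chrom == ch]
    if (is.unsorted(p)) stop("reads must be sorted by position within ",
                             "chromosome (", ch, " is not)")
  }
  key <- paste(reads$chrom, reads$pos, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    site <- reads[key == k, , drop = FALSE]
    consensus <- list()
    ok <- TRUE
    for (par in c("recipient", "donor")) {
      sp <- site[site$parent == par, , drop = FALSE]
      if (nrow(sp) == 0 || nrow(sp) >= max_depth) { ok <- FALSE; break }
      hi <- sp$allele[sp$qual >= min_qual]
      if (length(hi) == 0 || length(unique(hi)) > 1) { ok <- FALSE; break }
      consensus[[par]] <- hi[1]
    }
    if (!ok || consensus$recipient == consensus$donor) next
    out[[length(out) + 1L]] <-
      data.frame(chrom = site$chrom[1], pos = site$pos[1],
                 recipient = consensus$recipient, donor = consensus$donor,
                 stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
    else data.frame(chrom = character(), pos = numeric(),
                    recipient = character(), donor = character())
  rownames(res) <- NULL
  class(res) <- c("snp_catalog", "data.frame")
  res
}

#' Assign per-site parental origin calls for each line
#'
#' Restricts observations to catalog sites (observations at non-catalog
#' sites are skipped with a warning giving their count), and resolves
#' repeated observations of the same site in the same line by majority
#' origin, dropping ties — the per-line analogue of excluding
#' conflicting-genotype sites at the parent level.
#'
#' @param observations SNP observation table (columns \code{line},
#'   \code{chrom}, \code{pos}, \code{origin}).
#' @param catalog A \code{snp_catalog}.
#' @return Data frame of site origin calls: \code{line}, \code{chrom},
#'   \code{pos}, \code{origin}, sorted by line, chromosome, position.
#' @export
assign_site_origin <- function(observations, catalog) {
  if (nrow(observations) == 0)
    return(data.frame(line = character(), chrom = character(),
                      pos = numeric(), origin = character()))
  ## numeric site keys (chromosome index * offset + position) keep the
  ## joins fast on millions of observations
  chroms <- unique(catalog$chrom)
  off <- 10^ceiling(log10(max(catalog$pos) + 1))
  ck <- match(catalog$chrom, chroms) * off + catalog$pos
  oc <- match(observations$chrom, chroms)
  known <- !is.na(oc) & (oc * off + observations$pos) %in% ck
  if (any(!known))
    warning(sum(!known), " observation(s) at non-catalog sites skipped")
  obs <- observations[known, , drop = FALSE]
  if (nrow(obs) == 0)
    return(data.frame(line = character(), chrom = character(),
                      pos = numeric(), origin = character()))
  lines <- sort(unique(obs$line))
  gk <- (match(obs$line, lines) - 1) * off * (length(chroms) + 1) +
    match(obs$chrom, chroms) * off + obs$pos
  if (anyDuplicated(gk)) {
    d <- as.integer(obs$origin == "donor")
    nd <- rowsum(d, gk)
    nt <- rowsum(rep(1L, length(d)), gk)
    first <- !duplicated(gk)
    res <- obs[first, c("line", "chrom", "pos"), drop = FALSE]
    i <- match(gk[first], rownames(nd))
    res$origin <- ifelse(2 * nd[i, 1] > nt[i, 1], "donor",
                         ifelse(2 * nd[i, 1] < nt[i, 1], "recipient",
                                NA_character_))
    res <- res[!is.na(res$origin), , drop = FALSE]
  } else {
    res <- obs[, c("line", "chrom", "pos", "origin"), drop = FALSE]
  }
  res <- res[order(match(res$line, lines), match(res$chrom, chroms),
                   res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Dynamic sliding-window size from observed SNP density
#'
#' Scales the window (in SNP count) so that one window spans approximately
#' \code{target_span} bp at the line's observed SNP density, with a floor
#' of \code{min_size} SNPs; the result is forced odd (incremented when the
#' rounded value is even).
#'
#' @param n_calls Number of origin calls for the line (> 0).
#' @param genome_length Genome length in bp (> 0).
#' @param target_span Target physical span of one window in bp
#'   (default 200 kb).
#' @param min_size Minimum window size in SNPs (default 15).
#' @return An odd integer window size.
#' @export
auto_window_size <- function(n_calls, genome_length, target_span = 2e5,
                             min_size = 15L) {
  if (n_calls <= 0 || genome_length <= 0) stop("counts must be positive")
  w <- round(target_span * n_calls / genome_length)
  if (w %% 2 == 0) w <- w + 1
  max(min_size, w)
}

#' Sliding-window genotype calls over per-site origin calls
#'
#' Slides a window of \code{window_size} consecutive SNP origin calls
#' (step 1) along one line. A window is called donor when its donor votes
#' reach \code{ceiling(vote_threshold * window_size)}, recipient
#' symmetrically, and ambiguous otherwise. Windows are evaluated per
#' chromosome; a chromosome with fewer calls than the window size yields a
#' single whole-chromosome window decided by overall majority (noted via
#' \code{message()}).
#'
#' @param calls Origin calls for one line (columns \code{chrom},
#'   \code{pos}, \code{origin}); row order is irrelevant, sorting is
#'   internal.
#' @param window_size Odd integer >= 3.
#' @param vote_threshold Fraction in (0.5, 1] (default 0.8).
#' @return Data frame of window calls: \code{chrom}, \code{window},
#'   \code{first_pos}, \code{last_pos}, \code{donor_votes},
#'   \code{recipient_votes}, \code{call}.
#' @export
sliding_window_calls <- function(calls, window_size = 15L,
                                 vote_threshold = 0.8) {
  if (window_size < 3 || window_size %% 2 == 0)
    stop("window_size must be an odd integer >= 3")
  if (!(vote_threshold > 0.5 && vote_threshold <= 1))
    stop("vote_threshold must lie in (0.5, 1]")
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    n <- nrow(cc)
    d <- as.integer(cc$origin == "donor")
    if (n < window_size) {
      message("chromosome ", ch, ": ", n, " call(s) < window size ",
              window_size, "; single majority window")
      nd <- sum(d)
      call <- if (2 * nd > n) "donor" else if (2 * nd < n) "recipient"
              else "ambiguous"
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, window = 1L, first_pos = cc$pos[1], last_pos = cc$pos[n],
        donor_votes = nd, recipient_votes = n - nd, call = call,
        stringsAsFactors = FALSE)
      next
    }
    cs <- c(0L, cumsum(d))
    i <- seq_len(n - window_size + 1L)
    dv <- cs[i + window_size] - cs[i]
    need <- ceiling(vote_threshold * window_size)
    call <- ifelse(dv >= need, "donor",
                   ifelse(window_size - dv >= need, "recipient",
                          "ambiguous"))
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, window = i, first_pos = cc$pos[i],
      last_pos = cc$pos[i + window_size - 1L], donor_votes = dv,
      recipient_votes = window_size - dv, call = call,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), window = integer(),
                      first_pos = numeric(), last_pos = numeric(),
                      donor_votes = integer(), recipient_votes = integer(),
                      call = character())
  rownames(res) <- NULL
  attr(res, "window_size") <- window_size
  res
}

#' Merge window calls into genotype blocks
#'
#' Resolves ambiguous windows and converts the window-call track into
#' per-SNP genotypes via window centers, then into maximal blocks of
#' identical calls carrying their first/last supporting SNP positions.
#' An interior run of ambiguous windows between two differing decided
#' blocks is split at its midpoint (one-sided absorption would shift
#' every breakpoint in the same direction by a fraction of a window
#' span); runs at a chromosome edge or between agreeing blocks are
#' absorbed whole. A run of ambiguous windows longer than one window is
#' flagged as low-confidence via \code{message()}.
#'
#' @param windows Window-call table from [sliding_window_calls()].
#' @param calls The origin calls the windows were computed from.
#' @return Data frame of blocks: \code{chrom}, \code{call},
#'   \code{first_pos}, \code{last_pos}, \code{n_snps}.
#' @export
merge_window_calls <- function(windows, calls) {
  w <- attr(windows, "window_size")
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(windows$chrom)) {
    wc <- windows[windows$chrom == ch, , drop = FALSE]
    pos <- calls$pos[calls$chrom == ch]
    n <- length(pos)
    v <- wc$call
    dec <- v != "ambiguous"
    if (!any(dec)) next  # wholly ambiguous chromosome: no blocks
    amb_runs <- rle(!dec)
    if (any(amb_runs$lengths[amb_runs$values] > w))
      message("chromosome ", ch,
              ": low-confidence run of ambiguous windows absorbed")
    idx <- which(dec)
    for (i in which(!dec)) {
      li <- findInterval(i, idx)       # count of decided windows left of i
      ri <- li + 1L
      if (li == 0L) v[i] <- v[idx[ri]]               # leading run
      else if (ri > length(idx)) v[i] <- v[idx[li]]  # trailing run
      else {
        ## split the run at its midpoint between the flanking blocks
        mid <- (idx[li] + idx[ri]) / 2
        v[i] <- if (i <= mid) v[idx[li]] else v[idx[ri]]
      }
    }
    if (n < w || nrow(wc) == 1L) {
      snp_call <- rep(v[1], n)
    } else {
      half <- (w - 1L) %/% 2L
      centers <- seq_len(nrow(wc)) + half  # SNP index at each window center
      snp_call <- character(n)
      snp_call[seq_len(half)] <- v[1]
      snp_call[centers] <- v
      snp_call[(centers[length(centers)] + 1L):n] <- v[length(v)]
      snp_call <- snp_call[seq_len(n)]
    }
    r <- rle(snp_call)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, call = r$values, first_pos = pos[s], last_pos = pos[e],
      n_snps = r$lengths, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), call = character(),
                      first_pos = numeric(), last_pos = numeric(),
                      n_snps = integer())
  rownames(res) <- NULL
  res
}

#' Convert merged genotype blocks into a substitution map
#'
#' Donor blocks become segments. Each internal boundary is the integer
#' midpoint between the last SNP of one block and the first SNP of the
#' next; a donor block touching the chromosome's first (last) informative
#' SNP extends to the chromosome start (end).
#'
#' @param blocks Merged block table from the sliding-window caller
#'   (columns \code{chrom}, \code{call}, \code{first_pos},
#'   \code{last_pos}), ordered and non-overlapping within chromosome.
#' @param genome A [genome_spec()].
#' @param line Line id for the emitted map.
#' @return A [cssl_segments()] with source \code{"sequencing"}.
#' @export
blocks_to_segments <- function(blocks, genome, line = "line1") {
  rows <- list()
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    L <- chrom_length(genome, ch)
    for (j in seq_len(nrow(b))) {
      if (b$call[j] != "donor") next
      start <- if (j == 1L) 1
        else floor((b$last_pos[j - 1L] + b$first_pos[j]) / 2)
      end <- if (j == nrow(b)) L + 1
        else floor((b$last_pos[j] + b$first_pos[j + 1L]) / 2)
      rows[[length(rows) + 1L]] <-
        data.frame(line = line, chrom = ch, start = start, end = end,
                   stringsAsFactors = FALSE)
    }
  }
  seg <- if (length(rows)) do.call(rbind, rows)
    else data.frame(line = character(), chrom = character(),
                    start = numeric(), end = numeric())
  cssl_segments(seg, lines = line, genome = genome, source = "sequencing")
}

## Hierarchical refinement: re-scan each merged block at the minimum
## window size to recover short interior tracts of the opposite genotype
## (double-crossover products) that a density-scaled window cannot
## resolve. A block is re-scanned only when it holds at least two minimum
## windows; sub-blocks replace the parent when the re-scan splits it.
refine_blocks <- function(blocks, calls, w_min, vote_threshold) {
  out <- list()
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$pos), , drop = FALSE]
    pieces <- list()
    for (j in seq_len(nrow(b))) {
      if (b$n_snps[j] < 2L * w_min) { pieces[[j]] <- b[j, ]; next }
      idx <- which(cc$pos >= b$first_pos[j] & cc$pos <= b$last_pos[j])
      sub <- cc[idx, , drop = FALSE]
      win <- sliding_window_calls(sub, w_min, vote_threshold)
      rb <- merge_window_calls(win, sub)
      pieces[[j]] <- if (nrow(rb) > 1) rb else b[j, ]
    }
    out[[length(out) + 1L]] <- do.call(rbind, pieces)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sequencing-based genotyping of a CSSL population
#'
#' Full pipeline from SNP observations to substitution maps: per line,
#' origin calls are resolved against the catalog
#' ([assign_site_origin()]), the window size is chosen from the line's
#' observed SNP density ([auto_window_size()], unless \code{window_size}
#' is given), windows are called and merged, and blocks become segments
#' with midpoint breakpoints ([blocks_to_segments()]).
#'
#' @param observations SNP observation table for one or more lines.
#' @param catalog A \code{snp_catalog}.
#' @param genome A [genome_spec()].
#' When the working window exceeds \code{min_window}, every merged block
#' is re-scanned at \code{min_window} SNPs so that short tracts of the
#' opposite genotype inside a block — double-crossover products narrower
#' than one density-scaled window — are still detected; the re-scan
#' splits the block only when the small-window evidence supports it.
#' Set \code{refine = FALSE} to disable this second pass.
#'
#' @param window_size Fixed window size (odd, >= 3), or \code{NULL}
#'   (default) for dynamic sizing per line.
#' @param vote_threshold Window vote threshold (default 0.8).
#' @param target_span Target window span in bp for dynamic sizing
#'   (default 200 kb).
#' @param min_window Minimum window size in SNPs (default 15).
#' @param refine Re-scan blocks at \code{min_window} to recover short
#'   interior tracts (default \code{TRUE}).
#' @return A [cssl_segments()] population with source \code{"sequencing"}.
#' @export
seq_genotype <- function(observations, catalog, genome, window_size = NULL,
                         vote_threshold = 0.8, target_span = 2e5,
                         min_window = 15L, refine = TRUE) {
  calls <- assign_site_origin(observations, catalog)
  lines <- sort(unique(observations$line))   # row-order invariant
  by_line <- split(calls, factor(calls$line, levels = lines))
  maps <- list()
  for (l in lines) {
    cl <- by_line[[l]]
    if (is.null(cl) || nrow(cl) == 0) next
    w <- if (is.null(window_size))
      auto_window_size(nrow(cl), genome_length(genome), target_span,
                       min_size = min_window)
    else window_size
    win <- sliding_window_calls(cl, w, vote_threshold)
    blocks <- merge_window_calls(win, cl)
    if (refine && w > min_window)
      blocks <- refine_blocks(blocks, cl, min_window, vote_threshold)
    maps[[l]] <- as.data.frame(blocks_to_segments(blocks, genome, line = l))
  }
  seg <- do.call(rbind, maps)
  if (is.null(seg))
    seg <- data.frame(line = character(), chrom = character(),
                      start = numeric(), end = numeric())
  cssl_segments(seg, lines = lines, genome = genome, source = "sequencing")
}
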