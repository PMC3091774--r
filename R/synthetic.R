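#' Backcross breeding scheme
#'
#' Parameters of the simulated CSSL development programme: an F1 between
#' donor and recurrent parents is backcrossed to the recurrent parent
#' \code{n_backcrosses} times, self-crossed \code{n_selfings} times to fix
#' segments, and lines are retained by marker-assisted selection (MAS) when
#' they carry between one and \code{mas_max_segments} homozygous donor
#' segments. Recombination uses a constant rate in cM/Mb; crossover counts
#' per chromosome per meiosis are Poisson with mean equal to the genetic
#' length in Morgans, positions uniform, no interference.
#'
#' @param n_backcrosses Number of backcross generations (default 5).
#' @param n_selfings Number of selfing generations after the last backcross
#'   (default 2).
#' @param mas_max_segments MAS retention threshold on segment count
#'   (default 3); use \code{Inf} to disable selection entirely.
#' @param recomb_rate Recombination rate in cM per Mb (default 4,
#'   rice-typical genome-wide average).
#' @param seed Integer seed carried with the scheme (may be overridden at
#'   simulation time).
#' @return An object of class \code{breeding_scheme}.
#' @export
breeding_scheme <- function(n_backcrosses = 5, n_selfings = 2,
                            mas_max_segments = 3, recomb_rate = 4,
                            seed = 1L) {
  if (n_backcrosses < 0 || n_selfings < 0)
    stop("generation counts must be >= 0")
  if (!(mas_max_segments >= 0)) stop("mas_max_segments must be >= 0")
  if (!(recomb_rate > 0)) stop("recomb_rate must be > 0")
  structure(list(n_backcrosses = as.integer(n_backcrosses),
                 n_selfings = as.integer(n_selfings),
                 mas_max_segments = mas_max_segments,
                 recomb_rate = recomb_rate, seed = seed),
            class = "breeding_scheme")
}

#' Trait architecture for phenotype simulation
#'
#' Defines the linear bin-effect model used to simulate line-mean
#' phenotypes: \eqn{y_i = b_0 + \sum_k b_k x_{ik} + e_i}, where
#' \eqn{x_{ik} = +1} when line \eqn{i} is donor-homozygous at the position
#' of effect \eqn{k} and \eqn{-1} otherwise, and \eqn{e_i} is normal with
#' standard deviation \code{residual_sd}.
#'
#' @param b0 Trait baseline (overall mean, trait units, e.g. cm).
#' @param effects Data frame with columns \code{chrom}, \code{pos} (bp) and
#'   \code{effect} (\eqn{b_k}, trait units). May be empty.
#' @param residual_sd Residual standard deviation, \eqn{\ge 0}.
#' @param trait Trait name (default \code{"CL"}, culm length).
#' @return An object of class \code{qtl_spec}.
#' @export
qtl_spec <- function(b0, effects = data.frame(chrom = character(),
                                              pos = numeric(),
                                              effect = numeric()),
                     residual_sd = 0, trait = "CL") {
  if (!(residual_sd >= 0)) stop("residual_sd must be >= 0")
  effects <- as.data.frame(effects)
  if (nrow(effects) > 0 &&
      !all(c("chrom", "pos", "effect") %in% names(effects)))
    stop("effects must have columns chrom, pos, effect")
  structure(list(b0 = b0, effects = effects, residual_sd = residual_sd,
                 trait = trait), class = "qtl_spec")
}

#' Simulate a parent-discriminating SNP catalog
#'
#' Plants SNP sites that distinguish the donor from the recipient parent
#' along the genome. Per chromosome the number of sites is binomial in the
#' chromosome length at rate \code{snp_rate}; positions are uniform,
#' unique and sorted. Each site carries a recipient and a (different)
#' donor allele.
#'
#' @param genome A [genome_spec()].
#' @param snp_rate SNPs per bp, in (0, 0.1). The default 3.1e-3 gives the
#'   roughly 3 SNPs/kb density typical of an indica x japonica contrast
#'   (about 1.16 million sites on the default rice genome).
#' @param seed Integer seed.
#' @return A data frame of class \code{snp_catalog} with columns
#'   \code{chrom}, \code{pos}, \code{recipient}, \code{donor}.
#' @export
simulate_parents <- function(genome, snp_rate = 3.1e-3, seed = 1L) {
  if (!(snp_rate > 0 && snp_rate < 0.1))
    stop("snp_rate must lie in (0, 0.1)")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    per <- lapply(seq_len(nrow(genome)), function(i) {
      L <- genome$length[i]
      n <- stats::rbinom(1L, as.integer(L), snp_rate)
      pos <- sort(sample.int(as.integer(L), n))
      r <- sample.int(4L, n, replace = TRUE)
      d <- (r - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
      data.frame(chrom = genome$chrom[i], pos = pos,
                 recipient = bases[r], donor = bases[d],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per)
    rownames(out) <- NULL
    class(out) <- c("snp_catalog", "data.frame")
    out
  })
}

## ---- meiosis ------------------------------------------------------------

## haplotype: list (by chromosome name) of donor-interval matrices.
empty_hap <- function(genome) {
  h <- rep(list(iv_empty()), nrow(genome))
  names(h) <- genome$chrom
  h
}

full_hap <- function(genome) {
  h <- lapply(seq_len(nrow(genome)),
              function(i) cbind(start = 1, end = genome$length[i] + 1))
  names(h) <- genome$chrom
  h
}

## one gamete from a diploid (hap1, hap2); crossovers Poisson(Morgans),
## positions uniform, starting haplotype a fair coin per chromosome.
sim_gamete <- function(hap1, hap2, genome, recomb_rate) {
  out <- vector("list", nrow(genome))
  names(out) <- genome$chrom
  for (i in seq_len(nrow(genome))) {
    L <- genome$length[i]
    morgans <- recomb_rate * (L / 1e6) / 100
    nxo <- stats::rpois(1L, morgans)
    bp <- if (nxo > 0) sort(1 + floor(stats::runif(nxo) * (L - 1))) else numeric(0)
    cuts <- c(1, bp, L + 1)
    src <- (sample.int(2L, 1L) + seq_len(length(cuts) - 1L)) %% 2L  # alternates
    pieces <- list()
    for (j in seq_len(length(cuts) - 1L)) {
      chunk <- cbind(start = cuts[j], end = cuts[j + 1])
      if (cuts[j] >= cuts[j + 1]) next
      h <- if (src[j] == 0L) hap1[[i]] else hap2[[i]]
      pc <- intersect_intervals(chunk, h)
      if (nrow(pc) > 0) pieces[[length(pieces) + 1L]] <- pc
    }
    out[[i]] <- if (length(pieces)) merge_intervals(do.call(rbind, pieces))
                else iv_empty()
  }
  out
}

#' Simulate CSSL development by backcrossing, selfing and MAS
#'
#' Follows one plant per candidate line through the breeding scheme: the F1
#' (one full donor haplotype, one recurrent haplotype) is backcrossed to the
#' recurrent parent \code{n_backcrosses} times (each generation keeps one
#' gamete against a recurrent haplotype), then self-crossed
#' \code{n_selfings} times. The returned map is the donor-homozygous subset
#' (intersection of the two final haplotypes). When \code{mas_max_segments}
#' is finite, candidates are retained only if they carry between 1 and
#' \code{mas_max_segments} segments (idealized MAS on true segment count);
#' with \code{mas_max_segments = Inf} every candidate is returned,
#' which is the unselected population whose expected homozygous donor
#' fraction is \eqn{0.5^{(n_{bc}+1)} (1 - 0.5^{n_{self}})}.
#'
#' @param genome A [genome_spec()].
#' @param scheme A [breeding_scheme()].
#' @param n_lines Number of lines to return (>= 1).
#' @param seed Integer seed; defaults to the scheme's seed.
#' @param max_tries Cap on candidate plants simulated before giving up.
#' @return A [cssl_segments()] population with source \code{"truth"}.
#' @export
simulate_breeding <- function(genome, scheme, n_lines, seed = scheme$seed,
                              max_tries = 1000L * n_lines) {
  if (n_lines < 1) stop("n_lines must be >= 1")
  with_seed(seed, {
    select <- is.finite(scheme$mas_max_segments)
    segs <- list(); kept <- 0L; tries <- 0L
    while (kept < n_lines) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("MAS rejected too many candidates; relax mas_max_segments")
      hap1 <- full_hap(genome); hap2 <- empty_hap(genome)
      for (b in seq_len(scheme$n_backcrosses)) {
        hap1 <- sim_gamete(hap1, hap2, genome, scheme$recomb_rate)
        hap2 <- empty_hap(genome)
      }
      for (s in seq_len(scheme$n_selfings)) {
        g1 <- sim_gamete(hap1, hap2, genome, scheme$recomb_rate)
        g2 <- sim_gamete(hap1, hap2, genome, scheme$recomb_rate)
        hap1 <- g1; hap2 <- g2
      }
      hom <- lapply(seq_len(nrow(genome)),
                    function(i) intersect_intervals(hap1[[i]], hap2[[i]]))
      nseg <- sum(vapply(hom, nrow, 0L))
      if (select && (nseg < 1L || nseg > scheme$mas_max_segments)) next
      kept <- kept + 1L
      id <- sprintf("L%03d", kept)
      rows <- lapply(seq_len(nrow(genome)), function(i) {
        if (nrow(hom[[i]]) == 0) return(NULL)
        data.frame(line = id, chrom = genome$chrom[i],
                   start = hom[[i]][, 1], end = hom[[i]][, 2],
                   stringsAsFactors = FALSE)
      })
      segs[[kept]] <- do.call(rbind, rows)
    }
    all_lines <- sprintf("L%03d", seq_len(n_lines))
    seg_df <- do.call(rbind, segs)
    if (is.null(seg_df))
      seg_df <- data.frame(line = character(), chrom = character(),
                           start = numeric(), end = numeric())
    cssl_segments(seg_df, lines = all_lines, genome = genome,
                  source = "truth")
  })
}

#' Plant donor segments directly from a target distribution
#'
#' Emulates a finished CSSL library without breeding simulation: per line a
#' segment count is drawn from \code{count_weights} (counts 1, 2, ...),
#' segment lengths are log-uniform over \code{length_range}, chromosomes
#' are chosen proportional to physical length, and start positions are
#' uniform. Segments within a line never overlap; placement is retried a
#' bounded number of times. Defaults reproduce the published GR-map
#' population shape: 128 lines, count weights (54, 41, 18, 8, 5, 2) for 1-6
#' segments, lengths about 0.2-22 Mb.
#'
#' @param genome A [genome_spec()].
#' @param count_weights Positive weights for segment counts 1..K.
#' @param length_range Numeric \code{c(min, max)} segment length in bp; must
#'   fit inside the smallest chromosome.
#' @param n_lines Number of lines (default 128).
#' @param seed Integer seed.
#' @param max_retries Placement retries per segment before failing.
#' @return A [cssl_segments()] population with source \code{"truth"}.
#' @export
plant_segments <- function(genome, count_weights = c(54, 41, 18, 8, 5, 2),
                           length_range = c(2e5, 2.2e7), n_lines = 128,
                           seed = 1L, max_retries = 100L) {
  if (any(count_weights < 0) || sum(count_weights) <= 0)
    stop("count_weights must be non-negative with positive sum")
  if (length_range[1] <= 0 || length_range[2] < length_range[1])
    stop("invalid length_range")
  if (length_range[2] > min(genome$length))
    stop("length_range must fit within the smallest chromosome")
  with_seed(seed, {
    lines <- sprintf("L%03d", seq_len(n_lines))
    probs <- count_weights / sum(count_weights)
    lw <- genome$length / sum(genome$length)
    rows <- list()
    for (li in seq_len(n_lines)) {
      k <- sample.int(length(probs), 1L, prob = probs)
      placed <- list()  # per-chrom interval matrices
      for (s in seq_len(k)) {
        ok <- FALSE
        for (tr in seq_len(max_retries)) {
          len <- round(exp(stats::runif(1, log(length_range[1]),
                                        log(length_range[2]))))
          ci <- sample.int(nrow(genome), 1L, prob = lw)
          L <- genome$length[ci]
          if (len > L) next
          start <- 1 + floor(stats::runif(1) * (L - len + 1))
          cand <- cbind(start = start, end = start + len)
          prev <- placed[[genome$chrom[ci]]]
          if (!is.null(prev) &&
              nrow(intersect_intervals(cand, prev)) > 0) next
          placed[[genome$chrom[ci]]] <-
            rbind(if (is.null(prev)) NULL else prev, cand)
          rows[[length(rows) + 1L]] <-
            data.frame(line = lines[li], chrom = genome$chrom[ci],
                       start = start, end = start + len,
                       stringsAsFactors = FALSE)
          ok <- TRUE
          break
        }
        if (!ok) stop("could not place segment for line ", lines[li],
                      " after ", max_retries, " retries")
      }
    }
    cssl_segments(do.call(rbind, rows), lines = lines, genome = genome,
                  source = "truth")
  })
}

#' Simulate PCR-marker genotype calls for a population
#'
#' A marker is called donor-type (\code{"D"}) when its position falls
#' inside a donor segment of the line and recipient-type (\code{"R"})
#' otherwise; a fraction \code{missing_rate} of calls is replaced by the
#' missing symbol \code{"."}.
#'
#' @param maps A [cssl_segments()] population (the truth).
#' @param panel Data frame of marker loci with columns \code{marker},
#'   \code{chrom}, \code{pos} (and optionally \code{polymorphic}, in which
#'   case only polymorphic markers are scored).
#' @param missing_rate Fraction of calls set to missing (default 0).
#' @param seed Integer seed.
#' @return A marker genotype table: data frame with columns \code{line},
#'   \code{marker}, \code{call} (\code{"R"}, \code{"D"}, \code{"H"},
#'   \code{"."}).
#' @export
simulate_marker_genotypes <- function(maps, panel, missing_rate = 0,
                                      seed = 1L) {
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if ("polymorphic" %in% names(panel))
    panel <- panel[as.logical(panel$polymorphic), , drop = FALSE]
  with_seed(seed, {
    lines <- map_lines(maps)
    out <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      s <- segments_for_line(maps, lines[i])
      call <- rep("R", nrow(panel))
      for (ch in unique(s$chrom)) {
        iv <- as.matrix(s[s$chrom == ch, c("start", "end")])
        sel <- panel$chrom == ch
        call[sel][iv_contains(iv, panel$pos[sel])] <- "D"
      }
      miss <- stats::runif(nrow(panel)) < missing_rate
      call[miss] <- "."
      out[[i]] <- data.frame(line = lines[i], marker = panel$marker,
                             call = call, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate low-coverage SNP origin observations
#'
#' Each catalog site is independently observed with probability
#' \code{coverage} (the per-site chance that a re-sequencing read covers
#' it); the observed parental origin equals the line's true origin at the
#' site, flipped with probability \code{error_rate} (sequencing plus
#' alignment error). Phred base qualities and read depths are attached so
#' the quality filters can be exercised downstream. Defaults match a 0.13x
#' re-sequencing experiment with 1% call noise.
#'
#' @param maps A [cssl_segments()] truth population.
#' @param catalog A parent SNP catalog from [simulate_parents()].
#' @param coverage Per-site observation probability in (0, 1].
#' @param error_rate Flip probability in [0, 1).  (1 is allowed for
#'   degenerate testing.)
#' @param seed Integer seed.
#' @return Data frame with columns \code{line}, \code{chrom}, \code{pos},
#'   \code{origin} (\code{"recipient"}/\code{"donor"}), \code{qual},
#'   \code{depth}.
#' @export
simulate_snp_observations <- function(maps, catalog, coverage = 0.13,
                                      error_rate = 0.01, seed = 1L) {
  if (!(coverage > 0 && coverage <= 1)) stop("coverage must lie in (0, 1]")
  if (!(error_rate >= 0 && error_rate <= 1))
    stop("error_rate must lie in [0, 1]")
  with_seed(seed, {
    lines <- map_lines(maps)
    ns <- nrow(catalog)
    out <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      keep <- stats::runif(ns) < coverage
      idx <- which(keep)
      if (length(idx) == 0) next
      s <- segments_for_line(maps, lines[i])
      donor <- rep(FALSE, length(idx))
      for (ch in unique(s$chrom)) {
        iv <- as.matrix(s[s$chrom == ch, c("start", "end")])
        sel <- catalog$chrom[idx] == ch
        donor[sel] <- iv_contains(iv, catalog$pos[idx][sel])
      }
      flip <- stats::runif(length(idx)) < error_rate
      donor <- xor(donor, flip)
      out[[i]] <- data.frame(
        line = lines[i], chrom = catalog$chrom[idx],
        pos = catalog$pos[idx],
        origin = ifelse(donor, "donor", "recipient"),
        qual = sample(25:40, length(idx), replace = TRUE),
        depth = 1L + stats::rpois(length(idx), 0.2),
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
      res <- data.frame(line = character(), chrom = character(),
                        pos = numeric(), origin = character(),
                        qual = numeric(), depth = integer())
    rownames(res) <- NULL
    res
  })
}

#' Simulate line-mean phenotypes from the bin-effect model
#'
#' Evaluates \eqn{y_i = b_0 + \sum_k b_k x_{ik} + e_i} on a truth
#' population: \eqn{x_{ik} = +1} when line \eqn{i}'s donor segments cover
#' effect \eqn{k}'s position, \eqn{-1} otherwise; \eqn{e_i} is iid normal
#' with sd \code{residual_sd}.
#'
#' @param maps A [cssl_segments()] truth population.
#' @param qtl A [qtl_spec()].
#' @param seed Integer seed.
#' @param genome Optional [genome_spec()]; when given, effect positions are
#'   validated against it.
#' @return Data frame with columns \code{line}, \code{trait}, \code{value}.
#' @export
simulate_phenotypes <- function(maps, qtl, seed = 1L, genome = NULL) {
  if (!is.null(genome) && nrow(qtl$effects) > 0) {
    if (any(qtl$effects$pos < 1 |
            qtl$effects$pos > chrom_length(genome, qtl$effects$chrom)))
      stop("effect position outside genome")
  }
  with_seed(seed, {
    lines <- map_lines(maps)
    y <- rep(qtl$b0, length(lines))
    if (nrow(qtl$effects) > 0) {
      for (k in seq_len(nrow(qtl$effects))) {
        x <- donor_code(maps, qtl$effects$chrom[k], qtl$effects$pos[k])
        y <- y + qtl$effects$effect[k] * x
      }
    }
    y <- y + stats::rnorm(length(lines), 0, qtl$residual_sd)
    data.frame(line = lines, trait = qtl$trait, value = y,
               stringsAsFactors = FALSE)
  })
}

#' +1/-1 donor code of every line at a genome position
#'
#' @param maps A [cssl_segments()] population.
#' @param chrom,pos Chromosome name and 1-based position.
#' @return Named numeric vector over lines: \code{+1} donor, \code{-1}
#'   recipient.
#' @export
donor_code <- function(maps, chrom, pos) {
  lines <- map_lines(maps)
  x <- vapply(lines, function(l) {
    s <- segments_for_line(maps, l)
    s <- s[s$chrom == chrom, , drop = FALSE]
    if (nrow(s) == 0) -1
    else if (any(pos >= s$start & pos < s$end)) 1 else -1
  }, 0)
  names(x) <- lines
  x
}

#' Effect size giving a target explained-variance fraction
#'
#' For a single locus with realized codes \eqn{x \in \{-1,+1\}} across the
#' population, returns the effect \eqn{b} such that the locus explains
#' approximately \code{target_r2} of the phenotypic variance when the
#' residual sd is \code{residual_sd}:
#' \eqn{b = \sigma \sqrt{R^2/(1-R^2)} / sd(x)}.
#'
#' @param maps A [cssl_segments()] population.
#' @param chrom,pos Locus position.
#' @param target_r2 Target fraction of variance in (0, 1).
#' @param residual_sd Residual standard deviation (> 0).
#' @return The effect size in trait units.
#' @export
effect_for_r2 <- function(maps, chrom, pos, target_r2, residual_sd) {
  if (!(target_r2 > 0 && target_r2 < 1)) stop("target_r2 must be in (0,1)")
  if (!(residual_sd > 0)) stop("residual_sd must be > 0")
  x <- donor_code(maps, chrom, pos)
  sx <- stats::sd(x)
  if (sx == 0) stop("locus is monomorphic in this population")
  residual_sd * sqrt(target_r2 / (1 - target_r2)) / sx
}
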