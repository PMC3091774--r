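## TSV dialect used throughout: tab-separated, UTF-8, one '#'-prefixed
## header line naming the columns, '.' for missing values.

write_tsv_table <- function(df, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0) {
    body <- do.call(paste, c(lapply(df, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- "."
      col
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

read_tsv_table <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || !startsWith(lines[1], "#"))
    stop("missing '#'-prefixed header in ", path)
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (!identical(header, columns))
    stop("unexpected header in ", path, ": ",
         paste(header, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    out <- as.data.frame(stats::setNames(
      replicate(length(columns), character(0), simplify = FALSE), columns),
      stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(columns)))
    stop("malformed row at line ", which(nf != length(columns))[1] + 1L,
         " of ", path)
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(out) <- columns
  out
}

num <- function(x) {
  x[x == "."] <- NA
  as.numeric(x)
}

#' Read / write a marker genotype table
#'
#' TSV with columns \code{line}, \code{marker}, \code{call}; call symbols
#' are \code{R} (recipient), \code{D} (donor), \code{H} (heterozygous) and
#' \code{.} (missing). Reading validates the symbols and the uniqueness of
#' (line, marker) pairs; a malformed row raises an error naming its line
#' number.
#'
#' @param path File path.
#' @param table Marker genotype data frame.
#' @return \code{read_marker_table}: the table; \code{write_marker_table}:
#'   the path, invisibly.
#' @export
read_marker_table <- function(path) {
  out <- read_tsv_table(path, c("line", "marker", "call"))
  bad <- !out$call %in% c("R", "D", "H", ".")
  if (any(bad))
    stop("unknown call symbol '", out$call[bad][1], "' at line ",
         which(bad)[1] + 1L, " of ", path)
  if (anyDuplicated(paste(out$line, out$marker)))
    stop("duplicate (line, marker) pair in ", path)
  out
}

#' @rdname read_marker_table
#' @export
write_marker_table <- function(table, path) {
  write_tsv_table(table[, c("line", "marker", "call")], path)
}

#' Read / write substitution maps as BED
#'
#' Internal coordinates are 1-based with an exclusive end; BED is 0-based
#' half-open, so on export both bounds shrink by one:
#' \code{bed_start = start - 1}, \code{bed_end = end - 1}. The BED name
#' field carries the line id. The full population line list (including
#' segment-free lines) is preserved in a \code{#lines=} comment.
#'
#' @param maps A [cssl_segments()] population.
#' @param path File path.
#' @param genome A [genome_spec()] used to validate intervals on read.
#' @param source Map provenance recorded on the object read back.
#' @return \code{read_segments_bed}: a [cssl_segments()];
#'   \code{write_segments_bed}: the path, invisibly.
#' @export
write_segments_bed <- function(maps, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#lines=", paste(map_lines(maps), collapse = ",")), con)
  writeLines(paste0("#source=", attr(maps, "source")), con)
  s <- as.data.frame(maps)
  if (nrow(s) > 0)
    writeLines(sprintf("%s\t%d\t%d\t%s", s$chrom,
                       as.integer(s$start - 1), as.integer(s$end - 1),
                       s$line), con)
  invisible(path)
}

#' @rdname write_segments_bed
#' @export
read_segments_bed <- function(path, genome, source = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  line_list <- NULL
  ln <- meta[startsWith(meta, "#lines=")]
  if (length(ln) == 1)
    line_list <- strsplit(sub("^#lines=", "", ln), ",", fixed = TRUE)[[1]]
  if (is.null(source)) {
    sr <- meta[startsWith(meta, "#source=")]
    source <- if (length(sr) == 1) sub("^#source=", "", sr) else "truth"
  }
  if (length(body) == 0) {
    seg <- data.frame(line = character(), chrom = character(),
                      start = numeric(), end = numeric())
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 4)) stop("malformed BED row at line ",
                          which(nf < 4)[1], " of ", path)
    m <- do.call(rbind, lapply(fields, `[`, 1:4))
    seg <- data.frame(line = m[, 4], chrom = m[, 1],
                      start = as.numeric(m[, 2]) + 1,
                      end = as.numeric(m[, 3]) + 1,
                      stringsAsFactors = FALSE)
  }
  if (nrow(seg) > 0 && any(seg$end > chrom_length(genome, seg$chrom) + 1))
    stop("BED interval beyond chromosome end in ", path)
  cssl_segments(seg, lines = line_list, genome = genome, source = source)
}

#' Read / write SNP origin observations
#'
#' TSV with columns \code{line}, \code{chrom}, \code{pos}, \code{origin}
#' (\code{recipient}/\code{donor}), \code{qual}, \code{depth}.
#'
#' @param observations Observation data frame.
#' @param path File path.
#' @export
write_observations <- function(observations, path) {
  write_tsv_table(observations[, c("line", "chrom", "pos", "origin",
                                   "qual", "depth")], path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  out <- read_tsv_table(path, c("line", "chrom", "pos", "origin",
                                "qual", "depth"))
  out$pos <- num(out$pos); out$qual <- num(out$qual)
  out$depth <- as.integer(num(out$depth))
  bad <- !out$origin %in% c("recipient", "donor")
  if (any(bad)) stop("invalid origin at line ", which(bad)[1] + 1L,
                     " of ", path)
  if (nrow(out) > 0 && (any(out$pos < 1) || any(out$qual < 0) ||
                        any(out$depth < 1)))
    stop("invalid observation values in ", path)
  out
}

#' Read / write a parent SNP catalog
#'
#' TSV with columns \code{chrom}, \code{pos}, \code{recipient},
#' \code{donor} (the two parental alleles at each site).
#'
#' @param catalog A \code{snp_catalog}.
#' @param path File path.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv_table(catalog[, c("chrom", "pos", "recipient", "donor")], path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  out <- read_tsv_table(path, c("chrom", "pos", "recipient", "donor"))
  out$pos <- num(out$pos)
  if (anyDuplicated(paste(out$chrom, out$pos)))
    stop("duplicate catalog position in ", path)
  class(out) <- c("snp_catalog", "data.frame")
  out
}

#' Read / write a phenotype table
#'
#' TSV with columns \code{line}, \code{trait}, \code{value} (line means in
#' trait units); one value per line per trait.
#'
#' @param phenotypes Phenotype data frame.
#' @param path File path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write_tsv_table(phenotypes[, c("line", "trait", "value")], path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  out <- read_tsv_table(path, c("line", "trait", "value"))
  out$value <- num(out$value)
  if (anyDuplicated(paste(out$line, out$trait)))
    stop("more than one value per line per trait in ", path)
  out
}

#' Read / write a +1/-1 bin genotype matrix
#'
#' TSV with a \code{line} column followed by one column per bin
#' (\code{x1}, \code{x2}, ...); entries are +1/-1.
#'
#' @param matrix Matrix from [bin_genotypes()].
#' @param path File path.
#' @param bins Optional bin table to re-attach on read.
#' @export
write_bin_matrix <- function(matrix, path) {
  df <- data.frame(line = rownames(matrix), as.data.frame(matrix),
                   check.names = FALSE)
  write_tsv_table(df, path)
}

#' @rdname write_bin_matrix
#' @export
read_bin_matrix <- function(path, bins = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  out <- read_tsv_table(path, header)
  m <- as.matrix(out[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- out$line
  if (!all(m %in% c(-1L, 1L))) stop("bin matrix entries must be +1/-1")
  attr(m, "bins") <- bins
  m
}

#' Write bin definitions as BED
#'
#' BED intervals (0-based half-open) with the bin name (\code{x<k>}) in
#' the name field.
#'
#' @param bins A \code{bin_map} from [build_bins()].
#' @param path File path.
#' @export
write_bins_bed <- function(bins, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#bins", con)
  if (nrow(bins) > 0)
    writeLines(sprintf("%s\t%d\t%d\t%s", bins$chrom,
                       as.integer(bins$start - 1), as.integer(bins$end - 1),
                       bins$name), con)
  invisible(path)
}

#' Export per-line SNP origin observations as minimal VCF
#'
#' One single-sample VCF per line, named \code{<line>.vcf}: REF is the
#' recipient allele, ALT the donor allele, genotype \code{0/0} for a
#' recipient-origin observation and \code{1/1} for donor origin, with the
#' base quality as QUAL and the read depth in the DP format field.
#'
#' @param observations Observation data frame.
#' @param catalog The \code{snp_catalog} supplying REF/ALT alleles.
#' @param dir Output directory (created if absent).
#' @param genome Optional [genome_spec()] for contig header lines.
#' @return Character vector of the files written, invisibly.
#' @export
write_observations_vcf <- function(observations, catalog, dir,
                                   genome = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ck <- paste(catalog$chrom, catalog$pos, sep = "\r")
  files <- character(0)
  for (l in unique(observations$line)) {
    obs <- observations[observations$line == l, , drop = FALSE]
    i <- match(paste(obs$chrom, obs$pos, sep = "\r"), ck)
    if (anyNA(i)) stop("observation at non-catalog site for line ", l)
    path <- file.path(dir, paste0(l, ".vcf"))
    con <- file(path, "w", encoding = "UTF-8")
    writeLines("##fileformat=VCFv4.2", con)
    if (!is.null(genome))
      writeLines(sprintf("##contig=<ID=%s,length=%d>", genome$chrom,
                         as.integer(genome$length)), con)
    writeLines(c(
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", l), collapse = "\t")), con)
    gt <- ifelse(obs$origin == "donor", "1/1", "0/0")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%d\t.\t.\tGT:DP\t%s:%d",
                       obs$chrom, as.integer(obs$pos),
                       catalog$recipient[i], catalog$donor[i],
                       as.integer(obs$qual), gt, as.integer(obs$depth)),
               con)
    close(con)
    files <- c(files, path)
  }
  invisible(files)
}

#' Write a Table-5-style QTL report as TSV
#'
#' @param report Data frame from [qtl_report()].
#' @param path File path.
#' @export
write_qtl_table <- function(report, path) {
  write_tsv_table(report, path)
}

## ---- pipeline driver ----------------------------------------------------

pipeline_log <- function(...) message("[csslmap] ", sprintf(...))

#' Run the full CSSL analysis pipeline from a configuration file
#'
#' Executes the requested stages in order — \code{simulate} (population,
#' catalog, observations, marker calls, phenotypes),
#' \code{genotype_markers}, \code{genotype_seq}, \code{summarize},
#' \code{binmap}, \code{qtl} — writing each artifact as TSV/BED under
#' \code{out_dir} and logging per-stage record counts to standard error.
#' Configuration is YAML (or an equivalent named list); stage inputs are
#' validated before any computation, so e.g. requesting \code{qtl}
#' without a phenotype source fails immediately.
#'
#' @param config Path to a YAML configuration file, or a named list.
#' @param out_dir Output directory (default \code{"."}); created if
#'   absent.
#' @param seed Overrides the configuration's seed when non-NULL.
#' @return Invisibly, a named list of the in-memory artifacts (population
#'   maps, catalog, summaries, bin matrix, QTL fit and report).
#' @export
run_pipeline <- function(config, out_dir = ".", seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stages <- unlist(cfg$stages)
  if (is.null(stages)) stop("configuration error: no stages listed")
  known <- c("simulate", "genotype_markers", "genotype_seq", "summarize",
             "binmap", "qtl")
  if (!all(stages %in% known))
    stop("configuration error: unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  if (is.null(seed)) seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
  seed <- as.integer(seed)
  sim <- "simulate" %in% stages
  ## ---- validate stage inputs before any compute
  if (("genotype_markers" %in% stages) && !sim &&
      (is.null(cfg$inputs$marker_calls) || is.null(cfg$inputs$panel)))
    stop("configuration error: genotype_markers needs simulate or ",
         "inputs$marker_calls + inputs$panel")
  if (("genotype_seq" %in% stages) && !sim &&
      (is.null(cfg$inputs$observations) || is.null(cfg$inputs$catalog)))
    stop("configuration error: genotype_seq needs simulate or ",
         "inputs$observations + inputs$catalog")
  if (("qtl" %in% stages) && !sim && is.null(cfg$inputs$phenotypes))
    stop("configuration error: qtl stage needs simulate or ",
         "inputs$phenotypes")
  if ((("summarize" %in% stages) || ("binmap" %in% stages) ||
       ("qtl" %in% stages)) && !sim &&
      !("genotype_markers" %in% stages) && !("genotype_seq" %in% stages) &&
      is.null(cfg$inputs$segments))
    stop("configuration error: downstream stages need maps from a ",
         "genotyping stage, simulate, or inputs$segments")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  genome <- if (is.null(cfg$genome) || identical(cfg$genome, "rice"))
    rice_genome()
  else genome_spec(vapply(cfg$genome, `[[`, "", "chrom"),
                   vapply(cfg$genome, function(g) as.numeric(g$length), 0))
  art <- list(genome = genome)
  p <- function(name) file.path(out_dir, name)

  if (sim) {
    sc <- cfg$simulate
    g1 <- function(x, d) if (is.null(x)) d else x
    t0 <- Sys.time()
    maps <- plant_segments(
      genome,
      count_weights = g1(unlist(sc$count_weights), c(54, 41, 18, 8, 5, 2)),
      length_range = g1(unlist(sc$length_range), c(2e5, 2.2e7)),
      n_lines = g1(sc$n_lines, 128), seed = seed)
    catalog <- simulate_parents(genome, g1(sc$snp_rate, 3.1e-3),
                                seed = seed + 1L)
    obs <- simulate_snp_observations(maps, catalog,
                                     coverage = g1(sc$coverage, 0.13),
                                     error_rate = g1(sc$error_rate, 0.01),
                                     seed = seed + 2L)
    spacing <- g1(sc$marker_spacing, 1.5e6)
    panel <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
      pos <- seq(spacing / 2, genome$length[i], by = spacing)
      data.frame(marker = sprintf("M%s_%d", genome$chrom[i],
                                  seq_along(pos)),
                 chrom = genome$chrom[i], pos = pos,
                 stringsAsFactors = FALSE)
    }))
    calls <- simulate_marker_genotypes(maps, panel,
                                       g1(sc$missing_rate, 0),
                                       seed = seed + 3L)
    phcfg <- sc$phenotype
    b0 <- g1(phcfg$b0, 124)
    rsd <- g1(phcfg$residual_sd, 6)
    eff_chrom <- g1(phcfg$chrom, genome$chrom[1])
    eff_pos <- g1(phcfg$pos, round(0.92 * chrom_length(genome, eff_chrom)))
    eff <- if (!is.null(phcfg$target_r2))
      effect_for_r2(maps, eff_chrom, eff_pos, phcfg$target_r2, rsd)
    else g1(phcfg$effect, -13)
    phen <- simulate_phenotypes(
      maps, qtl_spec(b0, data.frame(chrom = eff_chrom, pos = eff_pos,
                                    effect = eff), rsd,
                     trait = g1(phcfg$trait, "CL")),
      seed = seed + 4L, genome = genome)
    write_segments_bed(maps, p("truth_segments.bed"))
    write_catalog(catalog, p("parent_snps.tsv"))
    write_observations(obs, p("snp_observations.tsv"))
    write_marker_table(calls, p("marker_calls.tsv"))
    write_phenotypes(phen, p("phenotypes.tsv"))
    pipeline_log("simulate: %d lines, %d truth segments, %d catalog SNPs, %d observations (%.1fs)",
                 length(map_lines(maps)), nrow(maps), nrow(catalog),
                 nrow(obs), as.numeric(Sys.time() - t0, units = "secs"))
    art$truth <- maps; art$catalog <- catalog; art$observations <- obs
    art$panel <- panel; art$marker_calls <- calls; art$phenotypes <- phen
  } else {
    if (!is.null(cfg$inputs$segments))
      art$truth <- read_segments_bed(cfg$inputs$segments, genome)
    if (!is.null(cfg$inputs$catalog))
      art$catalog <- read_catalog(cfg$inputs$catalog)
    if (!is.null(cfg$inputs$observations))
      art$observations <- read_observations(cfg$inputs$observations)
    if (!is.null(cfg$inputs$marker_calls))
      art$marker_calls <- read_marker_table(cfg$inputs$marker_calls)
    if (!is.null(cfg$inputs$panel)) {
      pn <- utils::read.delim(cfg$inputs$panel, comment.char = "")
      art$panel <- pn
    }
    if (!is.null(cfg$inputs$phenotypes))
      art$phenotypes <- read_phenotypes(cfg$inputs$phenotypes)
  }

  maps_for_analysis <- art$truth
  if ("genotype_markers" %in% stages) {
    t0 <- Sys.time()
    mm <- call_marker_segments(art$marker_calls, art$panel, genome)
    write_segments_bed(mm, p("mm_segments.bed"))
    pipeline_log("genotype_markers: %d segments across %d lines (%.1fs)",
                 nrow(mm), length(map_lines(mm)),
                 as.numeric(Sys.time() - t0, units = "secs"))
    art$mm_map <- mm
    maps_for_analysis <- mm
  }
  if ("genotype_seq" %in% stages) {
    t0 <- Sys.time()
    gr <- seq_genotype(art$observations, art$catalog, genome,
                       vote_threshold = if (is.null(cfg$genotype_seq$vote_threshold)) 0.8
                                        else cfg$genotype_seq$vote_threshold,
                       target_span = if (is.null(cfg$genotype_seq$target_span)) 2e5
                                     else cfg$genotype_seq$target_span)
    write_segments_bed(gr, p("gr_segments.bed"))
    pipeline_log("genotype_seq: %d segments across %d lines (%.1fs)",
                 nrow(gr), length(map_lines(gr)),
                 as.numeric(Sys.time() - t0, units = "secs"))
    art$gr_map <- gr
    maps_for_analysis <- gr
  }
  if ("summarize" %in% stages) {
    cov <- coverage_summary(maps_for_analysis, genome)
    cnt <- segment_count_distribution(maps_for_analysis)
    write_tsv_table(cov, p("coverage_summary.tsv"))
    write_tsv_table(cnt, p("segment_counts.tsv"))
    pipeline_log("summarize: %d segments, genome coverage %.1f%%",
                 cov$n_segments[nrow(cov)], cov$rate_pct[nrow(cov)])
    art$coverage <- cov; art$segment_counts <- cnt
  }
  if ("binmap" %in% stages || "qtl" %in% stages) {
    t0 <- Sys.time()
    bins <- build_bins(maps_for_analysis, genome)
    mat <- bin_genotypes(maps_for_analysis, bins)
    write_bins_bed(bins, p("bins.bed"))
    write_bin_matrix(mat, p("bin_matrix.tsv"))
    pipeline_log("binmap: %d bins, mean size %.0f bp (%.1fs)", nrow(bins),
                 if (nrow(bins)) mean(bins$end - bins$start) else 0,
                 as.numeric(Sys.time() - t0, units = "secs"))
    art$bins <- bins; art$bin_matrix <- mat
  }
  if ("qtl" %in% stages) {
    t0 <- Sys.time()
    qc <- cfg$qtl
    fit <- cssl_qtl(art$bin_matrix, art$phenotypes,
                    trait = qc$trait,
                    slentry = if (is.null(qc$slentry)) 0.01 else qc$slentry,
                    slstay = if (is.null(qc$slstay)) 0.01 else qc$slstay)
    rep <- qtl_report(fit)
    write_qtl_table(rep, p("qtl_table.tsv"))
    write_tsv_table(fit$trace, p("qtl_trace.tsv"))
    pipeline_log("qtl: %d QTL(s), model R-squared %.2f%% (%.1fs)",
                 nrow(rep), fit$model_r2,
                 as.numeric(Sys.time() - t0, units = "secs"))
    art$qtl_fit <- fit; art$qtl_table <- rep
  }
  invisible(art)
}
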