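## Shared fixtures and independent oracles used across the suite.

tiny_genome <- function() genome_spec(c("chr1", "chr2"), c(30e6, 30e6))

## evenly spaced marker panel
make_panel <- function(genome, spacing) {
  do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    pos <- seq(spacing / 2, genome$length[i], by = spacing)
    data.frame(marker = sprintf("M%s_%03d", genome$chrom[i], seq_along(pos)),
               chrom = genome$chrom[i], pos = pos,
               stringsAsFactors = FALSE)
  }))
}

## brute-force window vote evaluation: direct re-statement of the
## threshold rule, independent of the package's cumulative-sum path
oracle_window_calls <- function(origin, w, thr) {
  n <- length(origin)
  need <- ceiling(thr * w)
  vapply(seq_len(n - w + 1L), function(i) {
    d <- sum(origin[i:(i + w - 1L)] == "donor")
    if (d >= need) "donor"
    else if (w - d >= need) "recipient"
    else "ambiguous"
  }, "")
}

## all-subsets search: smallest subset of columns whose OLS fit attains
## the maximum R-squared (used on noiseless instances where that is 1)
oracle_min_perfect_subset <- function(x, y, tol = 1e-8) {
  m <- ncol(x)
  for (k in 0:m) {
    for (idx in if (k == 0) list(integer(0))
                else utils::combn(m, k, simplify = FALSE)) {
      X <- cbind(1, x[, idx, drop = FALSE])
      res <- stats::lm.fit(X, y)$residuals
      if (sum(res^2) < tol * max(1, sum((y - mean(y))^2)))
        return(sort(colnames(x)[idx]))
    }
  }
  stop("no perfect subset")
}

## independent stepwise oracle built on stats::lm + add1/drop1 F tests
oracle_stepwise <- function(x, y, slentry = 0.01, slstay = 0.01) {
  df <- data.frame(y = y, x, check.names = FALSE)
  selected <- character(0)
  last_removed <- NA_character_
  trace <- character(0)
  repeat {
    if (length(y) - length(selected) - 2 < 2) break
    cand <- setdiff(colnames(x), selected)
    if (length(cand) == 0) break
    form <- stats::as.formula(paste(
      "y ~", if (length(selected)) paste(sprintf("`%s`", selected),
                                         collapse = "+") else "1"))
    fit <- stats::lm(form, data = df)
    a1 <- stats::add1(fit, scope = stats::as.formula(
      paste("~ . +", paste(sprintf("`%s`", cand), collapse = "+"))),
      test = "F")
    p <- a1[["Pr(>F)"]][-1]
    names(p) <- gsub("`", "", rownames(a1)[-1])
    p <- p[!is.na(p)]
    if (length(p) == 0) break
    ## tie-break toward the leftmost bin (column order of x)
    ordr <- order(p, match(names(p), colnames(x)))
    best <- names(p)[ordr[1]]
    if (p[best] > slentry) break
    if (!is.na(last_removed) && best == last_removed) break
    selected <- c(selected, best)
    trace <- c(trace, paste0("+", best))
    repeat {
      form <- stats::as.formula(paste(
        "y ~", paste(sprintf("`%s`", selected), collapse = "+")))
      fit <- stats::lm(form, data = df)
      d1 <- stats::drop1(fit, test = "F")
      pd <- d1[["Pr(>F)"]][-1]
      names(pd) <- gsub("`", "", rownames(d1)[-1])
      worst <- names(pd)[which.max(pd)]
      if (pd[worst] <= slstay) break
      selected <- setdiff(selected, worst)
      last_removed <- worst
      trace <- c(trace, paste0("-", worst))
      if (length(selected) == 0) break
    }
  }
  list(selected = selected, trace = trace)
}

## random +1/-1 matrix with distinct, non-constant columns
random_bin_matrix <- function(n, m, seed) {
  set.seed(seed)
  repeat {
    x <- matrix(sample(c(-1L, 1L), n * m, replace = TRUE), n, m,
                dimnames = list(sprintf("L%02d", 1:n),
                                paste0("x", 1:m)))
    pat <- apply(x, 2, paste, collapse = "")
    if (!anyDuplicated(pat) &&
        all(apply(x, 2, function(c) length(unique(c)) > 1)))
      return(x)
  }
}

## match each truth segment to the single recovered segment overlapping
## it; returns boundary errors (NA when unmatched)
boundary_errors <- function(truth, recovered) {
  t <- as.data.frame(truth); r <- as.data.frame(recovered)
  errs <- rep(NA_real_, 2 * nrow(t))
  for (i in seq_len(nrow(t))) {
    cand <- r[r$line == t$line[i] & r$chrom == t$chrom[i] &
              r$start < t$end[i] & r$end > t$start[i], , drop = FALSE]
    if (nrow(cand) == 1) {
      errs[2 * i - 1] <- cand$start - t$start[i]
      errs[2 * i] <- cand$end - t$end[i]
    }
  }
  errs
}
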