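#' Ordinary least squares on +1/-1 bin codes
#'
#' Fits \eqn{y_i = b_0 + \sum_k b_k x_{ik} + e_i} for a given bin subset by
#' OLS. \eqn{R^2 = 1 - SSE/SST} with SST about the phenotype mean.
#'
#' @param x Bin genotype matrix (lines x bins, +1/-1), with line ids as
#'   row names.
#' @param y Numeric phenotype vector aligned with the rows of \code{x}.
#' @param selected Character vector of bin (column) names to include; may
#'   be empty for the intercept-only model.
#' @return List with \code{coefficients} (named, \code{(Intercept)}
#'   first), \code{sse}, \code{sst}, \code{r2}, \code{fitted},
#'   \code{residuals}, \code{df_residual}.
#' @export
fit_bin_model <- function(x, y, selected = colnames(x)) {
  if (length(y) != nrow(x)) stop("phenotype/matrix line mismatch")
  X <- cbind(`(Intercept)` = 1, x[, selected, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; offending bins: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  sst <- sum((y - mean(y))^2)
  sse <- sum(res^2)
  list(coefficients = beta, sse = sse, sst = sst,
       r2 = if (sst > 0) 1 - sse / sst else 0,
       fitted = fitted, residuals = res,
       df_residual = length(y) - ncol(X))
}

## Entry statistics for every candidate column given the current model.
## Returns F, p and the SSE reduction of each candidate (NA where the
## candidate is collinear with the current design).
entry_stats <- function(x, y, selected, candidates) {
  n <- length(y)
  Q <- qr.Q(qr(cbind(1, x[, selected, drop = FALSE])))
  r <- y - Q %*% crossprod(Q, y)
  Xc <- x[, candidates, drop = FALSE]
  Z <- Xc - Q %*% crossprod(Q, Xc)
  d <- colSums(Z^2)
  s <- drop(crossprod(Z, r))
  red <- ifelse(d > 1e-8 * n, s^2 / d, NA_real_)
  sse <- sum(r^2)
  df2 <- n - length(selected) - 2L
  denom <- pmax(sse - red, 0) / df2
  Fv <- ifelse(denom > 0, red / denom, Inf)
  p <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
  data.frame(bin = candidates, F = Fv, p = p, reduction = red,
             stringsAsFactors = FALSE)
}

## Partial F (and p) of each included variable in the current model:
## the square of its t statistic, on (1, n - p - 1) df.
drop_stats <- function(x, y, selected) {
  n <- length(y)
  X <- cbind(1, x[, selected, drop = FALSE])
  qx <- qr(X)
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  df <- n - ncol(X)
  s2 <- sum(res^2) / df
  ## covariance of beta = s2 * (X'X)^-1 from the (pivoted) QR of X
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot),
                                drop = FALSE]
  se <- sqrt(s2 * diag(xtx_inv))
  ## exact fits: zero residual variance gives se = 0; a nonzero
  ## coefficient is then infinitely significant, a zero one is not
  Fv <- ifelse(se > 0, (beta / se)^2,
               ifelse(abs(beta) > 1e-10, Inf, 0))
  p <- stats::pf(Fv, 1, df, lower.tail = FALSE)
  data.frame(bin = selected, F = Fv[-1], p = p[-1],
             stringsAsFactors = FALSE)
}

#' Stepwise bin selection and QTL model for a CSSL population
#'
#' The package's model fitter: stepwise multiple linear regression of a
#' line-mean phenotype on +1/-1 bin genotype codes, following the classic
#' F-based procedure. At each step the candidate with the smallest entry
#' p-value (partial F given the current model, 1 numerator df) is added if
#' its p is at most \code{slentry}; after every entry, included variables
#' whose partial F has p above \code{slstay} are removed (largest p
#' first), repeatedly. Selection terminates when no candidate qualifies,
#' when every retained variable is significant and nothing can enter, or
#' when the candidate to enter is the variable just removed (cycle
#' guard). Ties on p are broken toward the leftmost (smallest-index) bin.
#' Both thresholds default to 0.01.
#'
#' The explained variance is decomposed sequentially: the partial
#' R-squared of a selected bin is the increase in model sum of squares
#' when it entered, divided by the total sum of squares, in percent; the
#' model R-squared after k entries is the sum of the first k partials.
#' If removals occurred, partials are recomputed by refitting the entry
#' sequence of the final model.
#'
#' @param x Bin genotype matrix from [bin_genotypes()] (validated with
#'   [validate_bins()]; validation is applied internally when the matrix
#'   still contains constant or duplicate columns).
#' @param phenotypes A phenotype table (columns \code{line}, \code{trait},
#'   \code{value}) or a numeric vector named by line.
#' @param trait Trait to analyse when \code{phenotypes} holds several
#'   (default: the first).
#' @param slentry,slstay Entry/stay significance levels (default 0.01).
#' @return An object of class \code{cssl_qtl} with components
#'   \code{trace} (the stepwise event log), \code{selected} (bin names in
#'   entry order), \code{coefficients}, \code{partial_r2} and
#'   \code{model_r2} (percent), \code{F} (final-model partial F per
#'   retained bin), \code{fitted}, \code{residuals}, \code{bins},
#'   \code{n}, \code{trait}.  Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{plot}, plus [qtl_report()].
#' @examples
#' g <- genome_spec("chr1", 10e6)
#' maps <- plant_segments(g, count_weights = 1, length_range = c(1e6, 5e6),
#'                        n_lines = 40, seed = 7)
#' bins <- build_bins(maps, g)
#' m <- bin_genotypes(maps, bins)
#' ph <- simulate_phenotypes(maps,
#'   qtl_spec(100, data.frame(chrom = "chr1", pos = 5e6, effect = 8),
#'            residual_sd = 2), seed = 1)
#' fit <- cssl_qtl(m, ph)
#' print(fit)
#' @export
cssl_qtl <- function(x, phenotypes, trait = NULL, slentry = 0.01,
                     slstay = 0.01) {
  cl <- match.call()
  if (is.data.frame(phenotypes)) {
    if (is.null(trait)) trait <- phenotypes$trait[1]
    ph <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
    y <- ph$value[match(rownames(x), ph$line)]
    if (anyNA(y)) stop("phenotype missing for line(s): ",
                       paste(rownames(x)[is.na(y)], collapse = ", "))
  } else {
    y <- phenotypes[rownames(x)]
    if (anyNA(y)) stop("phenotype vector does not cover all lines")
    if (is.null(trait)) trait <- "trait"
  }
  report <- NULL
  if (!is.null(attr(x, "bins"))) {
    v <- validate_bins(x)
    if (length(v$report$dropped) > 0 || nrow(v$report$merged) > 0) {
      x <- v$matrix
      report <- v$report
    }
  }
  bins <- attr(x, "bins")
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  trace <- data.frame(step = integer(), action = character(),
                      bin = character(), F = numeric(), p = numeric(),
                      r2_after = numeric(), stringsAsFactors = FALSE)
  selected <- character(0)
  removed_any <- FALSE
  if (sst == 0) {
    warning("phenotype has no variance; empty model")
  } else {
    last_removed <- NA_character_
    step <- 0L
    repeat {
      if (n - length(selected) - 2L < 2L) {
        warning("selection halted: residual degrees of freedom exhausted")
        break
      }
      cand <- setdiff(colnames(x), selected)
      if (length(cand) == 0) break
      es <- entry_stats(x, y, selected, cand)
      es <- es[!is.na(es$p), , drop = FALSE]
      if (nrow(es) == 0) break
      best <- es[which.min(es$p), ]          # ties -> leftmost bin
      if (best$p > slentry) break
      if (!is.na(last_removed) && best$bin == last_removed) break
      step <- step + 1L
      selected <- c(selected, best$bin)
      fit <- fit_bin_model(x, y, selected)
      trace <- rbind(trace, data.frame(
        step = step, action = "enter", bin = best$bin, F = best$F,
        p = best$p, r2_after = fit$r2, stringsAsFactors = FALSE))
      repeat {
        ds <- drop_stats(x, y, selected)
        worst <- ds[which.max(ds$p), ]
        if (worst$p <= slstay) break
        step <- step + 1L
        selected <- setdiff(selected, worst$bin)
        last_removed <- worst$bin
        removed_any <- TRUE
        fit <- fit_bin_model(x, y, selected)
        trace <- rbind(trace, data.frame(
          step = step, action = "remove", bin = worst$bin, F = worst$F,
          p = worst$p, r2_after = fit$r2, stringsAsFactors = FALSE))
        if (length(selected) == 0) break
      }
    }
  }
  ## entry order of the bins retained in the final model
  entry_order <- unique(trace$bin[trace$action == "enter"])
  entry_order <- entry_order[entry_order %in% selected]
  if (removed_any)
    message("removals occurred; sequential partials recomputed over the ",
            "entry order of the final model")
  partial <- numeric(0)
  if (length(entry_order) > 0) {
    prev_ss <- 0
    partial <- numeric(length(entry_order))
    names(partial) <- entry_order
    for (k in seq_along(entry_order)) {
      f <- fit_bin_model(x, y, entry_order[seq_len(k)])
      ms <- f$sst - f$sse
      partial[k] <- 100 * (ms - prev_ss) / f$sst
      prev_ss <- ms
    }
  }
  final <- fit_bin_model(x, y, entry_order)
  Ffinal <- if (length(entry_order) > 0) {
    ds <- drop_stats(x, y, entry_order)
    stats::setNames(ds$F, ds$bin)
  } else numeric(0)
  structure(list(
    call = cl, trait = trait, n = n, slentry = slentry, slstay = slstay,
    trace = trace, selected = entry_order,
    coefficients = final$coefficients,
    partial_r2 = partial, model_r2 = sum(partial),
    F = Ffinal, r2 = final$r2, sse = final$sse, sst = final$sst,
    fitted = stats::setNames(final$fitted, rownames(x)),
    residuals = stats::setNames(final$residuals, rownames(x)),
    y = stats::setNames(y, rownames(x)),
    bins = bins, validate_report = report), class = "cssl_qtl")
}

#' @export
print.cssl_qtl <- function(x, ...) {
  cat(sprintf("CSSL stepwise QTL model for '%s' (n = %d lines)\n",
              x$trait, x$n))
  cat(sprintf("  SLENTRY = %g, SLSTAY = %g\n", x$slentry, x$slstay))
  if (length(x$selected) == 0) {
    cat("  no bin passed the entry threshold\n")
  } else {
    cat(sprintf("  %d bin(s) retained, model R-squared %.2f%%\n",
                length(x$selected), x$model_r2))
    print(qtl_report(x), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.cssl_qtl <- function(object, ...) {
  structure(list(fit = object), class = "summary.cssl_qtl")
}

#' @export
print.summary.cssl_qtl <- function(x, ...) {
  print(x$fit)
  cat("\nStepwise trace:\n")
  print(x$fit$trace, row.names = FALSE)
  cat("\nCoefficients:\n")
  print(x$fit$coefficients)
  invisible(x)
}

#' @export
coef.cssl_qtl <- function(object, ...) object$coefficients

#' @export
fitted.cssl_qtl <- function(object, ...) object$fitted

#' @export
residuals.cssl_qtl <- function(object, ...) object$residuals

#' Predict phenotypes for new bin genotypes
#'
#' @param object A fitted [cssl_qtl()] model.
#' @param newdata Matrix with (at least) the selected bin columns; when
#'   omitted, returns fitted values.
#' @param ... Unused.
#' @export
predict.cssl_qtl <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  b <- object$coefficients
  X <- cbind(1, newdata[, object$selected, drop = FALSE])
  drop(X %*% b[c("(Intercept)", object$selected)])
}

#' Plot the explained-variance profile of a QTL model
#'
#' Bars of per-bin partial R-squared at the bins' genome positions,
#' one panel strip per chromosome carrying a QTL.
#'
#' @param x A fitted [cssl_qtl()] model with a non-empty selection.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.cssl_qtl <- function(x, ...) {
  if (length(x$selected) == 0) {
    warning("empty model; nothing to plot")
    return(invisible(x))
  }
  rep <- qtl_report(x)
  graphics::barplot(rep$partial_r2_pct,
                    names.arg = paste0(rep$qtl, "\n", rep$bin),
                    ylab = "partial R-squared (%)",
                    main = sprintf("QTLs for %s", x$trait), ...)
  invisible(x)
}

#' Table of mapped QTLs
#'
#' One row per retained bin, named \code{q<trait><chrom>-<rank>} with the
#' rank running along each chromosome, sorted by chromosome then start.
#' The interval is the bin's physical interval, expanded to the merged
#' span when the bin represents a collapsed group of identical bins;
#' \code{size = end - start}. The model R-squared column is the running
#' sum of the partial R-squared values down the table; its last entry is
#' the full model R-squared. F is the final-model partial F.
#'
#' @param fit A fitted [cssl_qtl()] model.
#' @return Data frame with columns \code{qtl}, \code{bin}, \code{chrom},
#'   \code{start}, \code{end}, \code{size_bp}, \code{partial_r2_pct},
#'   \code{model_r2_pct}, \code{F}.
#' @export
qtl_report <- function(fit) {
  sel <- fit$selected
  if (length(sel) == 0)
    return(data.frame(qtl = character(), bin = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), size_bp = numeric(),
                      partial_r2_pct = numeric(),
                      model_r2_pct = numeric(), F = numeric()))
  bins <- fit$bins
  if (is.null(bins))
    bins <- data.frame(name = sel, chrom = NA_character_,
                       start = NA_real_, end = NA_real_,
                       stringsAsFactors = FALSE)
  i <- match(sel, bins$name)
  start <- if ("span_start" %in% names(bins)) bins$span_start[i]
           else bins$start[i]
  end <- if ("span_end" %in% names(bins)) bins$span_end[i]
         else bins$end[i]
  out <- data.frame(bin = sel, chrom = bins$chrom[i], start = start,
                    end = end, partial_r2_pct = unname(fit$partial_r2[sel]),
                    F = unname(fit$F[sel]), stringsAsFactors = FALSE)
  ord <- order(match(out$chrom, unique(bins$chrom)), out$start)
  out <- out[ord, , drop = FALSE]
  chrom_label <- sub("^chr", "", out$chrom)
  rank <- stats::ave(seq_len(nrow(out)), out$chrom, FUN = seq_along)
  out$qtl <- paste0("q", fit$trait, chrom_label, "-", rank)
  out$size_bp <- out$end - out$start
  out$model_r2_pct <- cumsum(out$partial_r2_pct)
  rownames(out) <- NULL
  out[, c("qtl", "bin", "chrom", "start", "end", "size_bp",
          "partial_r2_pct", "model_r2_pct", "F")]
}
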