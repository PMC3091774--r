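test_that("OLS on bin codes recovers exact linear structure", {
  x <- random_bin_matrix(20, 3, seed = 51)
  y <- 10 + 5 * x[, "x1"]
  f <- fit_bin_model(x, y, "x1")
  expect_equal(unname(f$coefficients), c(10, 5))
  expect_equal(f$r2, 1)

  const <- rep(7, 20)
  fc <- fit_bin_model(x, const, c("x1", "x2"))
  expect_equal(fc$r2, 0)
  expect_equal(unname(fc$coefficients[-1]), c(0, 0))

  set.seed(52)
  y2 <- 3 + x %*% c(1, -2, 0.5) + rnorm(20)
  f2 <- fit_bin_model(x, drop(y2))
  expect_equal(f2$r2, stats::cor(f2$fitted, drop(y2))^2)

  xdup <- cbind(x, x4 = x[, "x1"])
  expect_error(fit_bin_model(xdup, drop(y2)), "x4")
})

test_that("noiseless multi-bin phenotypes select exactly the causal set", {
  for (s in c(61, 62, 63)) {
    x <- random_bin_matrix(30, 10, seed = s)
    causal <- c("x2", "x5", "x9")
    y <- 50 + drop(x[, causal] %*% c(4, -3, 2))
    fit <- cssl_qtl(x, stats::setNames(y, rownames(x)))
    expect_setequal(fit$selected, causal)
    ## agrees with the minimal perfect subset by exhaustive search
    expect_equal(sort(fit$selected), oracle_min_perfect_subset(x, y))
    expect_equal(fit$model_r2, 100, tolerance = 1e-8)
  }
})

test_that("the stepwise trace matches an add1/drop1-based oracle on noisy data", {
  for (s in 71:75) {
    x <- random_bin_matrix(40, 12, seed = s)
    set.seed(s + 100)
    y <- 100 + drop(x[, c("x3", "x7")] %*% c(3, 2)) + rnorm(40, 0, 2)
    names(y) <- rownames(x)
    fit <- cssl_qtl(x, y)
    orc <- oracle_stepwise(x, y)
    expect_identical(fit$selected, setdiff(orc$selected, character(0)))
    ## entry/removal sequence identical
    got <- paste0(ifelse(fit$trace$action == "enter", "+", "-"),
                  fit$trace$bin)
    expect_identical(got, orc$trace)
  }
})

test_that("entry and final F statistics match direct lm computations", {
  x <- random_bin_matrix(40, 6, seed = 81)
  set.seed(82)
  y <- 10 + 2 * x[, "x2"] + rnorm(40)
  names(y) <- rownames(x)
  fit <- cssl_qtl(x, y)
  ## final-model partial F = squared t statistic of the coefficient
  lmfit <- stats::lm(y ~ x[, fit$selected, drop = FALSE])
  tt <- summary(lmfit)$coefficients[-1, "t value"]
  expect_equal(unname(fit$F), unname(tt^2), tolerance = 1e-10)
  ## first entry F equals the one-variable regression F
  f1 <- summary(stats::lm(y ~ x[, fit$trace$bin[1]]))$fstatistic[1]
  expect_equal(fit$trace$F[1], unname(f1), tolerance = 1e-10)
})

test_that("sequential partial R-squared decomposition has the stated identities", {
  ## single predictor: partial R2 = squared Pearson correlation
  x <- random_bin_matrix(30, 4, seed = 91)
  set.seed(92)
  y <- 5 + 4 * x[, "x1"] + rnorm(30, 0, 2)
  names(y) <- rownames(x)
  fit <- cssl_qtl(x, y)
  expect_equal(fit$selected, "x1")
  expect_equal(unname(fit$partial_r2["x1"]),
               100 * stats::cor(x[, "x1"], y)^2, tolerance = 1e-10)

  ## orthogonal predictors: sequential partials equal marginal R2,
  ## invariant to entry order
  had <- matrix(c(1, 1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, -1, -1, 1),
                4, 4, byrow = TRUE)
  xo <- had[rep(1:4, each = 8), 2:4]
  colnames(xo) <- paste0("x", 1:3)
  rownames(xo) <- sprintf("L%02d", 1:32)
  storage.mode(xo) <- "integer"
  set.seed(93)
  yo <- 20 + drop(xo %*% c(5, 3, 2)) + rnorm(32, 0, 1)
  names(yo) <- rownames(xo)
  fo <- cssl_qtl(xo, yo)
  expect_setequal(fo$selected, colnames(xo))
  marg <- vapply(colnames(xo), function(j)
    100 * stats::cor(xo[, j], yo)^2, 0)
  expect_equal(fo$partial_r2[fo$selected], marg[fo$selected],
               tolerance = 1e-10)

  ## running model R2 is non-decreasing and sums the partials
  expect_true(all(diff(c(0, cumsum(fo$partial_r2))) >= -1e-12))
  expect_equal(fo$model_r2, sum(fo$partial_r2), tolerance = 1e-12)
  expect_equal(fo$model_r2, 100 * fo$r2, tolerance = 1e-8)
})

test_that("degenerate phenotypes and empty selections are handled", {
  x <- random_bin_matrix(15, 3, seed = 101)
  y0 <- stats::setNames(rep(4, 15), rownames(x))
  expect_warning(fit <- cssl_qtl(x, y0), "no variance")
  expect_length(fit$selected, 0)
  rep0 <- qtl_report(fit)
  expect_equal(nrow(rep0), 0)
  expect_named(rep0, c("qtl", "bin", "chrom", "start", "end", "size_bp",
                       "partial_r2_pct", "model_r2_pct", "F"))

  set.seed(102)
  ynoise <- stats::setNames(rnorm(15), rownames(x))
  fitn <- cssl_qtl(x, ynoise, slentry = 1e-6, slstay = 1e-6)
  expect_length(fitn$selected, 0)
})

test_that("the trace is invariant to permuting line order", {
  g <- tiny_genome()
  maps <- plant_segments(g, n_lines = 40, length_range = c(1e6, 1e7),
                         seed = 111)
  bins <- build_bins(maps, g)
  m <- bin_genotypes(maps, bins)
  ph <- simulate_phenotypes(maps, qtl_spec(
    100, data.frame(chrom = "chr1",
                    pos = as.data.frame(maps)$start[1] + 10,
                    effect = 8), residual_sd = 3), seed = 112)
  fit1 <- cssl_qtl(m, ph)
  set.seed(113)
  perm <- sample.int(nrow(m))
  m2 <- m[perm, , drop = FALSE]
  attr(m2, "bins") <- attr(m, "bins")
  fit2 <- cssl_qtl(m2, ph)
  expect_identical(fit1$trace, fit2$trace)
  expect_equal(fit1$partial_r2, fit2$partial_r2)
})

test_that("reports name QTLs by chromosome rank with merged-span intervals", {
  bins <- data.frame(bin = 1:4, name = paste0("x", 1:4),
                     chrom = c("chr1", "chr1", "chr2", "chr2"),
                     start = c(100, 500, 100, 900),
                     end = c(500, 900, 900, 1200))
  x <- random_bin_matrix(30, 4, seed = 121)
  attr(x, "bins") <- bins
  set.seed(122)
  y <- 10 + 3 * x[, "x1"] + 2 * x[, "x2"] + 4 * x[, "x4"] + rnorm(30, 0, 0.5)
  names(y) <- rownames(x)
  fit <- cssl_qtl(x, y, trait = "CL")
  rep <- qtl_report(fit)
  expect_equal(rep$qtl, c("qCL1-1", "qCL1-2", "qCL2-1"))
  expect_equal(rep$size_bp, rep$end - rep$start)
  ## cumulative column ends at the model R2
  expect_equal(rep$model_r2_pct[nrow(rep)], fit$model_r2,
               tolerance = 1e-10)
  ## methods behave
  expect_equal(unname(predict(fit, x)), unname(fitted(fit)))
  expect_equal(stats::coef(fit)[["(Intercept)"]],
               unname(fit$coefficients[1]))
  expect_equal(unname(residuals(fit)), unname(y - fitted(fit)))
  expect_output(print(fit), "qCL1-1")
  expect_output(print(summary(fit)), "Stepwise trace")
})

test_that("selected-bin effects recover the planted values within 3 SE", {
  g <- rice_genome()
  maps <- plant_segments(g, n_lines = 128, seed = 131)
  bins <- build_bins(maps, g)
  m0 <- bin_genotypes(maps, bins)
  v <- validate_bins(m0)
  chrom <- "chr1"; pos <- 40.2e6
  b_true <- effect_for_r2(maps, chrom, pos, 0.70, 6)
  ## the column matching the causal locus pattern
  xc <- donor_code(maps, chrom, pos)
  hit <- which(apply(v$matrix, 2, function(col)
    all(col == xc[rownames(v$matrix)])))
  expect_length(hit, 1)
  bn <- colnames(v$matrix)[hit]
  ok <- 0L; reps <- 200L
  for (s in seq_len(reps)) {
    ph <- simulate_phenotypes(maps, qtl_spec(
      124, data.frame(chrom = chrom, pos = pos, effect = b_true), 6),
      seed = 1000 + s)
    fit <- cssl_qtl(v$matrix, ph)
    if (!(bn %in% fit$selected)) next
    est <- fit$coefficients[bn]
    se <- abs(est) / sqrt(fit$F[bn])
    if (abs(est - b_true) <= 3 * se) ok <- ok + 1L
  }
  expect_gte(ok / reps, 0.95)
})
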