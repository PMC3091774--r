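test_that("parent SNP catalog has binomial site counts, sorted unique positions", {
  g <- genome_spec("chr1", 1e6)
  counts <- vapply(1:100, function(s)
    nrow(simulate_parents(g, 1e-3, seed = s)), 0L)
  ## mean of 100 binomial(1e6, 1e-3) counts: 3-sigma band around 1000
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000) / sqrt(100) + 1)

  cat1 <- simulate_parents(tiny_genome(), 1e-4, seed = 11)
  cat2 <- simulate_parents(tiny_genome(), 1e-4, seed = 11)
  expect_identical(cat1, cat2)

  for (ch in unique(cat1$chrom)) {
    p <- cat1$pos[cat1$chrom == ch]
    expect_false(is.unsorted(p, strictly = TRUE))
    expect_true(all(p >= 1 & p <= chrom_length(tiny_genome(), ch)))
  }
  expect_true(all(cat1$recipient != cat1$donor))
  expect_error(simulate_parents(g, 0.5), "snp_rate")
  expect_error(simulate_parents(g, 0), "snp_rate")
})

test_that("crossover counts are Poisson with mean equal to genetic length", {
  ## 4 cM/Mb on 25 Mb = 1 Morgan: visible switch count of a gamete from a
  ## fully heterozygous plant equals the crossover count
  g <- genome_spec("chr1", 25e6)
  cnt <- csslmap:::with_seed(42, {
    h1 <- csslmap:::full_hap(g); h2 <- csslmap:::empty_hap(g)
    vapply(1:10000, function(i) {
      iv <- csslmap:::sim_gamete(h1, h2, g, 4)[[1]]
      b <- c(iv[, 1], iv[, 2])
      sum(!(b %in% c(1, 25e6 + 1)))
    }, 0)
  })
  expect_lt(abs(mean(cnt) - 1.0), 0.03)
})

test_that("unselected homozygous donor fraction matches the backcross-selfing expectation", {
  ## E[hom donor] = 0.5^(n_bc+1) * (1 - 0.5^n_self); with deep selfing this
  ## approaches the diploid donor fraction 0.5^(n_bc+1) after n_bc backcrosses
  g <- genome_spec("chr1", 40e6)
  sch <- breeding_scheme(n_backcrosses = 4, n_selfings = 6,
                         mas_max_segments = Inf, recomb_rate = 4)
  maps <- simulate_breeding(g, sch, 800, seed = 7)
  s <- as.data.frame(maps)
  frac <- sum(s$end - s$start) / (800 * 40e6)
  expect_lt(abs(frac - 0.5^5 * (1 - 0.5^6)), 0.005)
})

test_that("MAS retains only lines within the segment-count bound", {
  g <- tiny_genome()
  maps <- simulate_breeding(g, breeding_scheme(mas_max_segments = 1),
                            25, seed = 3)
  counts <- table(as.data.frame(maps)$line)
  expect_true(all(counts <= 1))
  expect_length(map_lines(maps), 25)
  ## every retained line carries at least one segment
  expect_setequal(names(counts), map_lines(maps))
})

test_that("planted populations follow the requested count distribution", {
  g <- rice_genome()
  one <- plant_segments(g, count_weights = 1, n_lines = 30, seed = 5)
  expect_true(all(table(as.data.frame(one)$line) == 1))

  ## mean segment count of the (54,41,18,8,5,2) distribution is 259/128
  w <- c(54, 41, 18, 8, 5, 2)
  means <- vapply(1:50, function(s) {
    m <- plant_segments(g, count_weights = w, n_lines = 128, seed = s)
    nrow(m) / 128
  }, 0)
  expect_lt(abs(mean(means) - sum(1:6 * w) / sum(w)), 0.05)

  expect_identical(plant_segments(g, n_lines = 20, seed = 9),
                   plant_segments(g, n_lines = 20, seed = 9))
  expect_error(plant_segments(g, length_range = c(1e6, 30e6)),
               "smallest chromosome")
})

test_that("planted segments never overlap and respect chromosome bounds", {
  g <- tiny_genome()
  for (s in 1:5) {
    maps <- plant_segments(g, length_range = c(2e5, 2e7), n_lines = 40,
                           seed = s)
    seg <- as.data.frame(maps)
    expect_true(all(seg$start >= 1))
    expect_true(all(seg$end <= chrom_length(g, seg$chrom) + 1))
    key <- paste(seg$line, seg$chrom)
    for (k in unique(key)) {
      sk <- seg[key == k, , drop = FALSE]
      sk <- sk[order(sk$start), ]
      if (nrow(sk) > 1)
        expect_true(all(sk$start[-1] >= sk$end[-nrow(sk)]))
    }
  }
})

test_that("marker genotype simulation observes the truth exactly when noiseless", {
  g <- tiny_genome()
  maps <- plant_segments(g, n_lines = 10, length_range = c(1e6, 1e7),
                         seed = 21)
  panel <- make_panel(g, 2e5)  # denser than the shortest segment
  calls <- simulate_marker_genotypes(maps, panel, missing_rate = 0,
                                     seed = 1)
  idx <- match(calls$marker, panel$marker)
  for (l in map_lines(maps)) {
    cl <- calls[calls$line == l, ]
    truth <- vapply(seq_len(nrow(panel)), function(j) {
      s <- segments_for_line(maps, l)
      s <- s[s$chrom == panel$chrom[j], , drop = FALSE]
      any(panel$pos[j] >= s$start & panel$pos[j] < s$end)
    }, TRUE)
    expect_identical(cl$call == "D", truth[idx[calls$line == l]])
  }
  all_missing <- simulate_marker_genotypes(maps, panel, missing_rate = 1,
                                           seed = 1)
  expect_true(all(all_missing$call == "."))
})

test_that("SNP observation counts and error model behave as specified", {
  g <- genome_spec("chr1", 20e6)
  catalog <- simulate_parents(g, 3e-3, seed = 2)  # ~60,000 sites
  maps <- plant_segments(g, count_weights = 1, length_range = c(2e6, 8e6),
                         n_lines = 1, seed = 3)
  obs <- simulate_snp_observations(maps, catalog, coverage = 0.13,
                                   error_rate = 0, seed = 4)
  ## binomial 99% interval around 0.13 * n sites
  n <- nrow(catalog)
  expect_lt(abs(nrow(obs) - 0.13 * n), 2.576 * sqrt(n * 0.13 * 0.87))

  truth <- csslmap:::segments_for_line(maps, "L001")
  in_seg <- obs$pos >= truth$start[1] & obs$pos < truth$end[1]
  expect_identical(obs$origin == "donor", in_seg)

  flipped <- simulate_snp_observations(maps, catalog, coverage = 0.13,
                                       error_rate = 1, seed = 4)
  in_seg_f <- flipped$pos >= truth$start[1] & flipped$pos < truth$end[1]
  expect_identical(flipped$origin == "donor", !in_seg_f)
  expect_true(all(obs$qual >= 25 & obs$depth >= 1))
})

test_that("phenotypes are the exact affine bin-effect model when noiseless", {
  g <- tiny_genome()
  maps <- plant_segments(g, n_lines = 16, length_range = c(1e6, 1e7),
                         seed = 8)
  base <- simulate_phenotypes(maps, qtl_spec(b0 = 100), seed = 1)
  expect_true(all(base$value == 100))

  pos <- as.data.frame(maps)$start[1] + 1000  # carried by >= 1 line
  spec1 <- qtl_spec(100, data.frame(chrom = as.data.frame(maps)$chrom[1],
                                    pos = pos, effect = 5))
  ph <- simulate_phenotypes(maps, spec1, seed = 1)
  x <- donor_code(maps, as.data.frame(maps)$chrom[1], pos)
  expect_equal(ph$value, 100 + 5 * x, ignore_attr = TRUE)
  expect_setequal(unique(ph$value), c(105, 95))
  expect_error(
    simulate_phenotypes(maps, qtl_spec(1, data.frame(
      chrom = "chr1", pos = 99e6, effect = 1)), genome = g),
    "outside")
})

test_that("effect sizing hits a 70% explained-variance target at n = 128", {
  g <- rice_genome()
  maps <- plant_segments(g, n_lines = 128, seed = 1)
  chrom <- "chr1"; pos <- 40.2e6
  b <- effect_for_r2(maps, chrom, pos, target_r2 = 0.70, residual_sd = 6)
  x <- donor_code(maps, chrom, pos)
  r2 <- vapply(1:200, function(s) {
    ph <- simulate_phenotypes(maps, qtl_spec(
      124, data.frame(chrom = chrom, pos = pos, effect = b), 6), seed = s)
    summary(stats::lm(ph$value ~ x))$r.squared
  }, 0)
  expect_lt(abs(mean(100 * r2) - 70), 3)
})
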