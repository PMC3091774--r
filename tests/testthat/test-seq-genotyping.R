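## build one parent's reads at a site
site_reads <- function(pos, parent, alleles, quals, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, parent = parent, allele = alleles,
             qual = quals, stringsAsFactors = FALSE)
}

test_that("parent SNP filters apply quality, conflict and depth rules", {
  clean_donor <- function(pos) site_reads(pos, "donor", c("G", "G"), c(30, 30))
  ## quality: a lone Q24 base removes the site; Q25 keeps it
  r24 <- rbind(site_reads(100, "recipient", "A", 24), clean_donor(100))
  r25 <- rbind(site_reads(100, "recipient", "A", 25), clean_donor(100))
  expect_equal(nrow(filter_parent_snps(r24)), 0)
  cat25 <- filter_parent_snps(r25)
  expect_equal(nrow(cat25), 1)
  expect_equal(cat25$recipient, "A")
  expect_equal(cat25$donor, "G")

  ## depth: site with 100 reads excluded, 99 retained
  deep <- function(n) site_reads(200, "recipient", rep("A", n), rep(30, n))
  expect_equal(nrow(filter_parent_snps(rbind(deep(100), clean_donor(200)))), 0)
  expect_equal(nrow(filter_parent_snps(rbind(deep(99), clean_donor(200)))), 1)

  ## conflicting genotypes among surviving reads exclude the site
  confl <- rbind(site_reads(300, "recipient", c("A", "C"), c(30, 30)),
                 clean_donor(300))
  expect_equal(nrow(filter_parent_snps(confl)), 0)
  ## conflict only among low-quality bases does not
  lowconf <- rbind(site_reads(300, "recipient", c("A", "C"), c(30, 10)),
                   clean_donor(300))
  expect_equal(nrow(filter_parent_snps(lowconf)), 1)

  ## identical consensus in both parents is not a SNP
  same <- rbind(site_reads(400, "recipient", "A", 30),
                site_reads(400, "donor", "A", 30))
  expect_equal(nrow(filter_parent_snps(same)), 0)

  unsorted <- rbind(site_reads(500, "recipient", "A", 30),
                    site_reads(100, "recipient", "A", 30))
  expect_error(filter_parent_snps(unsorted), "sorted")
})

test_that("site origin assignment uses majority with ties dropped", {
  catalog <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                        recipient = "A", donor = "G")
  obs <- data.frame(line = "L1", chrom = "chr1",
                    pos = c(100, 200, 200, 300, 300, 300),
                    origin = c("donor", "donor", "recipient",
                               "recipient", "recipient", "donor"))
  res <- assign_site_origin(obs, catalog)
  expect_equal(res$pos, c(100, 300))        # the tie at 200 is dropped
  expect_equal(res$origin, c("donor", "recipient"))

  off <- rbind(obs, data.frame(line = "L1", chrom = "chr1", pos = 999,
                               origin = "donor"))
  expect_warning(assign_site_origin(off, catalog), "non-catalog")
  empty <- assign_site_origin(obs[0, ], catalog)
  expect_equal(nrow(empty), 0)
})

test_that("window calls match the exhaustive vote oracle and locate breakpoints", {
  pos <- (1:100) * 1000
  truth <- c(rep("donor", 50), rep("recipient", 50))
  w <- 15; thr <- 0.8
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    origin <- ifelse(runif(100) < 0.05,
                     ifelse(truth == "donor", "recipient", "donor"), truth)
    calls <- data.frame(chrom = "chr1", pos = pos, origin = origin)
    win <- sliding_window_calls(calls, w, thr)
    expect_identical(win$call, oracle_window_calls(origin, w, thr))
    blocks <- merge_window_calls(win, calls)
    seg <- as.data.frame(blocks_to_segments(blocks,
                                            genome_spec("chr1", 101000)))
    ## exactly one donor segment starting at the chromosome edge, with its
    ## end within one window span of the true boundary at 50500
    if (nrow(seg) == 1 && abs(seg$end - 50500) <= w * 1000) hits <- hits + 1L
  }
  expect_equal(hits, 100L)
})

test_that("pure noise produces no donor blocks", {
  set.seed(7)
  n <- 20000
  origin <- ifelse(runif(n) < 0.10, "donor", "recipient")
  calls <- data.frame(chrom = "chr1", pos = seq_len(n) * 500,
                      origin = origin)
  win <- sliding_window_calls(calls, 15, 0.8)
  expect_false(any(win$call == "donor"))
  blocks <- merge_window_calls(win, calls)
  expect_true(all(blocks$call == "recipient"))
})

test_that("uniform donor calls give one whole-span donor block", {
  calls <- data.frame(chrom = "chr1", pos = (1:30) * 1e4, origin = "donor")
  win <- sliding_window_calls(calls, 15, 0.8)
  expect_true(all(win$call == "donor"))
  blocks <- merge_window_calls(win, calls)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$first_pos, 1e4)
  expect_equal(blocks$last_pos, 3e5)
})

test_that("window parameters are validated and short inputs fall back to majority", {
  calls <- data.frame(chrom = "chr1", pos = (1:5) * 100,
                      origin = c("donor", "donor", "donor", "recipient",
                                 "donor"))
  expect_error(sliding_window_calls(calls, 4, 0.8), "odd")
  expect_error(sliding_window_calls(calls, 15, 0.5), "vote_threshold")
  expect_message(win <- sliding_window_calls(calls, 15, 0.8),
                 "single majority")
  expect_equal(nrow(win), 1)
  expect_equal(win$call, "donor")
})

test_that("blocks become segments with midpoint and chromosome-edge breakpoints", {
  g <- genome_spec("chr1", 3e6)
  blocks <- data.frame(
    chrom = "chr1", call = c("recipient", "donor", "recipient"),
    first_pos = c(100000, 1000000, 2100000),
    last_pos = c(900000, 2000000, 2900000))
  seg <- as.data.frame(blocks_to_segments(blocks, g))
  expect_equal(seg$start, 950000)
  expect_equal(seg$end, 2050000)

  edge <- data.frame(chrom = "chr1", call = c("donor", "recipient"),
                     first_pos = c(5000, 1500000),
                     last_pos = c(1000000, 2900000))
  seg_e <- as.data.frame(blocks_to_segments(edge, g))
  expect_equal(seg_e$start, 1)

  none <- data.frame(chrom = "chr1", call = "recipient",
                     first_pos = 1, last_pos = 100)
  expect_equal(nrow(blocks_to_segments(none, g)), 0)
})

test_that("dynamic window size scales with observed SNP density", {
  expect_equal(auto_window_size(60000, 372e6, 2e5), 33)
  expect_equal(auto_window_size(3576, 372e6, 2e5), 15)
  ## an even rounded size is incremented to odd: 372e6/2e5 * 0.0001 ...
  expect_equal(auto_window_size(74400, 372e6, 2e5), 41)  # 40 -> 41
  expect_true(auto_window_size(1e6, 372e6, 2e5) %% 2 == 1)
  expect_error(auto_window_size(0, 372e6), "positive")
})

test_that("segment recovery is invariant to observation row order", {
  g <- genome_spec("chr1", 30e6)
  maps <- plant_segments(g, count_weights = 1, length_range = c(2e6, 1e7),
                         n_lines = 5, seed = 17)
  catalog <- simulate_parents(g, 2e-3, seed = 18)
  obs <- simulate_snp_observations(maps, catalog, coverage = 0.2,
                                   error_rate = 0.01, seed = 19)
  set.seed(20)
  shuffled <- obs[sample.int(nrow(obs)), ]
  m1 <- seq_genotype(obs, catalog, g)
  m2 <- seq_genotype(shuffled, catalog, g)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
})

test_that("noiseless full-coverage genotyping recovers truth to inter-SNP resolution", {
  g <- genome_spec("chr1", 20e6)
  maps <- plant_segments(g, count_weights = 1, length_range = c(2e6, 8e6),
                         n_lines = 10, seed = 23)
  catalog <- simulate_parents(g, 1e-3, seed = 24)
  obs <- simulate_snp_observations(maps, catalog, coverage = 1,
                                   error_rate = 0, seed = 25)
  rec <- seq_genotype(obs, catalog, g)
  errs <- boundary_errors(maps, rec)
  expect_false(anyNA(errs))
  ## breakpoints land within a few inter-SNP gaps (mean gap 1 kb)
  expect_lt(max(abs(errs)), 5000)
})

test_that("doubling coverage does not worsen median breakpoint error", {
  g <- genome_spec("chr1", 30e6)
  maps <- plant_segments(g, count_weights = c(1, 1),
                         length_range = c(2e6, 1e7), n_lines = 40,
                         seed = 29)
  catalog <- simulate_parents(g, 2e-3, seed = 30)
  med_err <- function(cov) {
    obs <- simulate_snp_observations(maps, catalog, coverage = cov,
                                     error_rate = 0.01, seed = 31)
    rec <- suppressMessages(seq_genotype(obs, catalog, g))
    stats::median(abs(boundary_errors(maps, rec)), na.rm = TRUE)
  }
  e1 <- med_err(0.1)
  e2 <- med_err(0.2)
  expect_lte(e2, e1)
})

test_that("block refinement resolves double-crossover gaps narrower than one window", {
  g <- genome_spec("chr1", 30e6)
  ## two donor segments separated by a 120 kb recipient gap: far smaller
  ## than the ~200 kb density-scaled window span at 0.13x coverage
  maps <- cssl_segments(data.frame(
    line = "L001", chrom = "chr1",
    start = c(5e6, 8.12e6), end = c(8e6, 11e6)), genome = g)
  catalog <- simulate_parents(g, 3.1e-3, seed = 61)
  obs <- simulate_snp_observations(maps, catalog, coverage = 0.13,
                                   error_rate = 0.01, seed = 62)
  rec <- as.data.frame(seq_genotype(obs, catalog, g))
  expect_equal(nrow(rec), 2)
  expect_lt(max(abs(c(rec$start - c(5e6, 8.12e6),
                      rec$end - c(8e6, 11e6)))), 5e4)
  ## without refinement the dynamic window merges the pair
  coarse <- as.data.frame(seq_genotype(obs, catalog, g, refine = FALSE))
  expect_equal(nrow(coarse), 1)
})
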