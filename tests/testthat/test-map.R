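test_that("expected-count arithmetic is exact closed form", {
  s <- expected_recombinant_stats(1630, 2.9e9, 6e4, 1700)
  expect_equal(s$molecules_per_gamete, 2.9e9 / 6e4)
  expect_equal(s$crossovers_per_gamete, 16.3)
  expect_equal(s$recombinant_frequency, 16.3 / (2.9e9 / 6e4), tolerance = 1e-12)
  expect_equal(s$expected_recombinants, 16.3 * 1700)

  s1 <- expected_recombinant_stats(96.55, 2.9e9, 6e4, 1700)
  expect_equal(s1$expected_recombinants, 0.9655 * 1700)
  expect_error(expected_recombinant_stats(-1, 1, 1, 1))
})

test_that("cM estimates reproduce hand arithmetic", {
  expect_equal(cm_estimate(31, 1736), 3100 / 1736)
  expect_equal(cm_estimate(6, 1366), 600 / 1366)
  expect_equal(cm_estimate(0, 100), 0)
  expect_equal(cm_estimate(5, 0), 0)
})

toy_crossovers <- function(mids, chrom = "chr1") {
  tibble::tibble(
    molecule_id = sprintf("x%03d", seq_along(mids)), barcode = bc("A"),
    chrom = chrom, interval_start = mids - 500, interval_end = mids + 500,
    resolution_bp = 1000, probability = 0.99, n_reads = 10L,
    n_variants_side_a = 5L, n_variants_side_b = 5L,
    frac_reads_concordant_side_a = 1, frac_reads_concordant_side_b = 1
  )
}

toy_molecules <- function(starts, chrom = "chr1", len = 60000) {
  tibble::tibble(
    molecule_id = sprintf("m%04d", seq_along(starts)), barcode = bc("A"),
    chrom = chrom, start = starts, end = starts + len, n_reads = 10L
  )
}

test_that("windowed maps conserve counts and estimate rates", {
  lens <- tibble::tibble(chrom = "chr1", length = 1e6)
  xo <- toy_crossovers(c(25000, 30000, 725000))
  mols <- toy_molecules(seq(0, 900000, by = 10000))
  m <- build_map(xo, mols, window_bp = 50000, chrom_lengths = lens)
  expect_equal(sum(m$n_crossovers), 3)
  expect_equal(m$n_crossovers[m$start == 0], 2L)
  expect_equal(m$n_crossovers[m$start == 700000], 1L)
  expect_equal(m$cM, cm_estimate(m$n_crossovers, m$n_molecules))

  # zero crossovers -> all-zero map
  empty <- build_map(toy_crossovers(numeric(0)), mols, window_bp = 50000,
                     chrom_lengths = lens)
  expect_true(all(empty$n_crossovers == 0))
  expect_true(all(empty$cM == 0))

  # midpoint molecule assignment conserves the molecule count
  m2 <- build_map(xo, mols, window_bp = 50000, chrom_lengths = lens,
                  molecule_assignment = "midpoint")
  expect_equal(sum(m2$n_molecules), nrow(mols))

  # sliding windows advance by step_bp
  sl <- build_map(xo, mols, window_bp = 50000, step_bp = 10000,
                  chrom_lengths = lens)
  expect_equal(sort(unique(diff(sort(unique(sl$start))))), 10000)

  bg <- tempfile(fileext = ".bedgraph")
  write_bedgraph(m, bg)
  expect_match(readLines(bg)[1], "bedGraph")
})

test_that("coldspot scan reports long crossover-free gaps", {
  lens <- tibble::tibble(chrom = "chr1", length = 1e6)
  cs <- detect_coldspots(toy_crossovers(c(100000, 700000)), lens)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$start, 100000)
  expect_equal(cs$end, 700000)
  expect_equal(cs$length_bp, 600000)

  # uniform crossovers every 100 kb leave no >= 500 kb gap
  dense <- detect_coldspots(toy_crossovers(seq(50000, 950000, by = 100000)),
                            lens)
  expect_equal(nrow(dense), 0)

  # an empty chromosome is one whole-length coldspot
  whole <- detect_coldspots(toy_crossovers(numeric(0)),
                            tibble::tibble(chrom = "chr2", length = 2e6))
  expect_equal(whole$length_bp, 2e6)
})

test_that("clustering test flags maximal clustering and reproduces with a seed", {
  regions <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6)
  clustered <- toy_crossovers(rep(25000, 40))
  t1 <- clustering_permutation_test(clustered, regions, window_bp = 50000,
                                    n_perm = 1000, seed = 3)
  expect_lte(t1$p_value, 1 / 1001 + 1e-12)
  expect_gt(t1$statistic, 1)
  expect_true(any(t1$windows$hotspot))
  expect_true(all(t1$windows$p > 0))

  t2 <- clustering_permutation_test(clustered, regions, window_bp = 50000,
                                    n_perm = 1000, seed = 3)
  expect_equal(t1$p_value, t2$p_value)
  expect_equal(t1$windows$p, t2$windows$p)

  expect_error(clustering_permutation_test(clustered, regions, n_perm = 0),
               "n_perm")
})

test_that("feature proximity test behaves at the two extremes", {
  lens <- tibble::tibble(chrom = "chr1", length = 1e6)
  feats <- tibble::tibble(chrom = "chr1",
                          start = seq(0, 9e5, by = 1e5),
                          end = seq(0, 9e5, by = 1e5) + 1000)
  inside <- toy_crossovers(seq(0, 9e5, by = 1e5) + 600)
  t_in <- feature_proximity_test(inside, feats, lens, n_perm = 200, seed = 5)
  expect_equal(t_in$median_observed, 0)
  expect_lt(t_in$p_value, 0.05)

  # features tiling the genome leave no signal: p close to 1
  tiling <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6)
  t_tile <- feature_proximity_test(inside, tiling, lens, n_perm = 200,
                                   seed = 5)
  expect_equal(t_tile$median_observed, 0)
  expect_gt(t_tile$p_value, 0.9)

  t_rep <- feature_proximity_test(inside, feats, lens, n_perm = 200, seed = 5)
  expect_equal(t_in$p_value, t_rep$p_value)
})

test_that("planted proximity to sparse features is detected", {
  # 1% feature coverage on a 10 Mb toy genome; crossovers planted 1 kb away
  lens <- tibble::tibble(chrom = "chr1", length = 1e7)
  feats <- tibble::tibble(chrom = "chr1",
                          start = seq(0, 9.9e6, by = 1e5),
                          end = seq(0, 9.9e6, by = 1e5) + 1000)
  planted <- toy_crossovers(feats$start[1:60] + 2000)
  hits <- 0
  for (s in 1:20) {
    t_p <- feature_proximity_test(planted, feats, lens, n_perm = 199,
                                  seed = s)
    hits <- hits + (t_p$p_value < 0.05)
  }
  expect_gte(hits, 19)
})
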