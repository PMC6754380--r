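# convenience: a phase object where H1 carries allele 0 everywhere
flat_phase <- function(positions, chrom = "chr1") {
  structure(
    list(
      variants = tibble::tibble(
        chrom = chrom, pos = as.numeric(positions), h1_allele = 0L,
        block_id = "B00001", n_molecules = 10L, n_mol_allele0 = 5L,
        n_mol_allele1 = 5L
      ),
      mec_cost = 0, n_blocks = 1, n_molecules = 10
    ),
    class = "lr_phase"
  )
}

one_molecule_amat <- function(alleles, quals = 30L, spacing = 1000,
                              id = "mol1") {
  n <- length(alleles)
  tibble::tibble(
    molecule_id = id, chrom = "chr1", pos = seq_len(n) * spacing,
    allele = as.integer(alleles), conflict = FALSE,
    max_qual = rep_len(as.integer(quals), n),
    n_reads_0 = as.integer(alleles == 0L), n_reads_1 = as.integer(alleles == 1L)
  )
}

test_that("posterior classes follow the likelihoods on canonical molecules", {
  ph <- flat_phase(1:10 * 1000)
  # all six observations match H1 at Q30
  pure <- score_molecules(one_molecule_amat(rep(0L, 6)), ph)
  expect_gt(pure$p_h1, 0.99)
  expect_equal(pure$class, "H1")
  expect_equal(pure$p_h1 + pure$p_h2 + pure$p_mix, 1, tolerance = 1e-9)

  # clean one-switch pattern: five H1 then five H2 observations
  rec <- score_molecules(one_molecule_amat(c(rep(0L, 5), rep(1L, 5))), ph,
                         prior_mix = 3.3e-4)
  expect_equal(rec$class, "RECOMBINANT")
  expect_equal(rec$best_switch_index, 5L)
  expect_equal(rec$switch_start, 5000)
  expect_equal(rec$switch_end, 6000)
  oracle <- oracle_score(c(rep(0L, 5), rep(1L, 5)), rep(30, 10), rep(0L, 10),
                         prior_mix = 3.3e-4)
  expect_equal(rec$p_mix, oracle$p_mix, tolerance = 1e-9)
  expect_equal(rec$best_switch_index, oracle$best_switch)

  # alternating pattern: one switch cannot explain it
  alt <- score_molecules(one_molecule_amat(rep(c(0L, 1L), 5)), ph)
  expect_lt(alt$p_mix, 0.5)
  expect_equal(alt$class, "AMBIGUOUS")

  # single informative variant is ambiguous by contract
  single <- score_molecules(one_molecule_amat(0L), ph)
  expect_equal(single$class, "AMBIGUOUS")

  # conflicted molecules are excluded
  amat_conf <- one_molecule_amat(c(0L, 0L, 1L))
  amat_conf$conflict[2] <- TRUE
  amat_conf$allele[2] <- NA_integer_
  expect_equal(score_molecules(amat_conf, ph)$class, "EXCLUDED")
})

test_that("posteriors and switch points match brute-force enumeration", {
  set.seed(99)
  ph_pos <- 1:20 * 500
  for (case in 1:30) {
    n <- sample(2:20, 1)
    alleles <- sample(c(0L, 1L), n, replace = TRUE)
    quals <- sample(c(20L, 30L, 40L), n, replace = TRUE)
    h1 <- sample(c(0L, 1L), n, replace = TRUE)
    ph <- flat_phase(ph_pos[1:n])
    ph$variants$h1_allele <- h1
    amat <- one_molecule_amat(alleles, spacing = 500)
    amat$max_qual <- quals
    got <- score_molecules(amat, ph, prior_mix = 1e-3)
    want <- oracle_score(alleles, quals, h1, prior_mix = 1e-3)
    expect_equal(got$p_h1, want$p_h1, tolerance = 1e-9)
    expect_equal(got$p_h2, want$p_h2, tolerance = 1e-9)
    expect_equal(got$p_mix, want$p_mix, tolerance = 1e-9)
    if (want$p_mix > 0.5) {
      # the chosen switch point must attain the enumerated maximum (distinct
      # switch points can tie exactly; then any maximizer is acceptable)
      eps <- 10^(-pmin(quals, 60) / 10)
      s <- got$best_switch_index
      lik_at <- function(s, first) {
        second <- 1L - first
        prod(ifelse(alleles[1:s] == first[1:s], 1 - eps[1:s], eps[1:s])) *
          prod(ifelse(alleles[(s + 1):n] == second[(s + 1):n],
                      1 - eps[(s + 1):n], eps[(s + 1):n]))
      }
      best_lik <- max(lik_at(want$best_switch, h1),
                      lik_at(want$best_switch, 1L - h1))
      got_lik <- max(lik_at(s, h1), lik_at(s, 1L - h1))
      expect_equal(got_lik, best_lik, tolerance = 1e-9)
    }
  }
})

test_that("relabelling haplotypes swaps p_h1/p_h2 and preserves p_mix", {
  ph <- flat_phase(1:8 * 1000)
  amat <- one_molecule_amat(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L))
  a <- score_molecules(amat, ph)
  ph$variants$h1_allele <- 1L - ph$variants$h1_allele
  b <- score_molecules(amat, ph)
  expect_equal(a$p_h1, b$p_h2, tolerance = 1e-12)
  expect_equal(a$p_h2, b$p_h1, tolerance = 1e-12)
  expect_equal(a$p_mix, b$p_mix, tolerance = 1e-12)
  expect_equal(a$switch_start, b$switch_start)
})

# build a scored-molecule scenario with read-level observations
switch_scenario <- function(side_a_alleles, side_b_alleles,
                            discordant_reads_b = 0) {
  n_a <- length(side_a_alleles); n_b <- length(side_b_alleles)
  n <- n_a + n_b
  positions <- seq_len(n) * 1000
  reads <- make_reads(positions - 50, ids = sprintf("r%02d", seq_len(n)))
  obs <- tibble::tibble(
    read_id = reads$read_id, chrom = "chr1", pos = positions,
    allele = as.integer(c(side_a_alleles, side_b_alleles)), base_qual = 30L
  )
  if (discordant_reads_b > 0) {
    # interleave the discordant reads so the best switch stays at the
    # side-a / side-b boundary
    flip <- n_a + seq(2, by = 2, length.out = discordant_reads_b)
    obs$allele[flip] <- 1L - obs$allele[flip]
  }
  assigned <- build_molecules(reads)
  list(assigned = assigned, obs = obs,
       amat = allele_matrix(assigned, obs),
       phase = flat_phase(positions))
}

test_that("crossover calling enforces the side-variant and read rules", {
  # five H1 then five H2 variants, all reads concordant: one event whose
  # interval spans the two flanking informative variants
  sc <- switch_scenario(rep(0L, 5), rep(1L, 5))
  calls <- score_molecules(sc$amat, sc$phase)
  xo <- call_crossovers(calls, sc$amat, sc$phase, sc$assigned, sc$obs)
  expect_equal(nrow(xo), 1)
  expect_equal(xo$interval_start, 5000)
  expect_equal(xo$interval_end, 6000)
  expect_equal(xo$resolution_bp, 1000)
  expect_equal(xo$n_variants_side_a, 5L)
  expect_equal(xo$probability, calls$p_mix)

  # two H1 then eight H2: side a has fewer than three variants -> no call
  sc2 <- switch_scenario(rep(0L, 2), rep(1L, 8))
  calls2 <- score_molecules(sc2$amat, sc2$phase)
  xo2 <- call_crossovers(calls2, sc2$amat, sc2$phase, sc2$assigned, sc2$obs)
  expect_equal(nrow(xo2), 0)
  if (calls2$class == "RECOMBINANT") {
    expect_equal(attr(xo2, "rejected")$reason, "too_few_side_variants")
  }
})

test_that("low read concordance on one side vetoes the call", {
  # side b: 12 informative reads of which 4 carry the wrong allele (67%
  # concordant); the error entries are interspersed so the best switch stays
  # uniquely at the side boundary
  sc <- switch_scenario(rep(0L, 8),
                        rep(c(1L, 1L, 0L), 4))
  calls <- score_molecules(sc$amat, sc$phase)
  expect_equal(calls$class, "RECOMBINANT")
  expect_equal(calls$best_switch_index, 8L)
  xo <- call_crossovers(calls, sc$amat, sc$phase, sc$assigned, sc$obs,
                        min_side_read_frac = 0.7)
  expect_equal(nrow(xo), 0)
  expect_equal(attr(xo, "rejected")$reason, "low_side_read_concordance")
})

test_that("haplotype-balance windows mask crossovers in distorted regions", {
  mols <- tibble::tibble(
    molecule_id = sprintf("m%03d", 1:130),
    barcode = bc("A"), chrom = "chr1",
    start = c(seq(0, 79000, length.out = 78),   # window 0: balanced
              seq(100000, 179000, length.out = 52)),  # window 1: 50 vs 2
    end = NA_real_, n_reads = 10L
  )
  mols$end <- mols$start + 1000
  calls <- tibble::tibble(
    molecule_id = mols$molecule_id,
    chrom = "chr1", n_informative = 10L, p_h1 = 0, p_h2 = 0, p_mix = 0,
    class = c(rep(c("H1", "H2"), 39), rep("H1", 50), rep("H2", 2)),
    best_switch_index = NA_integer_, switch_start = NA_real_,
    switch_end = NA_real_, switch_first_hap = NA_character_
  )
  mask <- haplotype_balance_mask(
    calls, mols, window_bp = 100000, min_ratio = 0.3,
    chrom_lengths = tibble::tibble(chrom = "chr1", length = 200000)
  )
  expect_equal(mask$masked, c(FALSE, TRUE))
  expect_equal(mask$n_h1[2], 50L)

  # a clean recombinant inside the masked window is discarded with reason
  sc <- switch_scenario(rep(0L, 5), rep(1L, 5))
  sc_calls <- score_molecules(sc$amat, sc$phase)
  masked_all <- tibble::tibble(chrom = "chr1", start = 0, end = 100000,
                               n_h1 = 50L, n_h2 = 1L, masked = TRUE)
  xo <- call_crossovers(sc_calls, sc$amat, sc$phase, sc$assigned, sc$obs,
                        mask = masked_all)
  expect_equal(nrow(xo), 0)
  expect_equal(attr(xo, "rejected")$reason, "masked_region")

  # fully balanced genome: empty mask leaves calls unchanged
  balanced <- dplyr::mutate(masked_all, n_h2 = 49L, masked = FALSE)
  xo2 <- call_crossovers(sc_calls, sc$amat, sc$phase, sc$assigned, sc$obs,
                         mask = balanced)
  expect_equal(nrow(xo2), 1)
})
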