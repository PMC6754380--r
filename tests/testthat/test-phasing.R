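test_that("allele matrix collapses reads per molecule and flags conflicts", {
  reads <- make_reads(c(0, 50, 2000), ids = c("r1", "r2", "r3"))
  assigned <- build_molecules(reads)
  obs <- tibble::tibble(
    read_id = c("r1", "r2", "r2", "r3"),
    chrom = "chr1",
    pos = c(100, 100, 120, 2100),
    allele = c(0L, 1L, 1L, 0L),
    base_qual = c(30L, 20L, 35L, 25L)
  )
  amat <- allele_matrix(assigned, obs)
  expect_equal(nrow(amat), 3)
  at100 <- amat[amat$pos == 100, ]
  expect_true(at100$conflict)            # r1 and r2 disagree
  expect_true(is.na(at100$allele))
  at120 <- amat[amat$pos == 120, ]
  expect_false(at120$conflict)
  expect_equal(at120$allele, 1L)
  expect_equal(at120$max_qual, 35L)
})

test_that("a perfectly consistent matrix phases with zero MEC cost", {
  ents <- purrr::map(1:6, function(i) {
    hap <- i %% 2
    list(pos = c(100, 200), allele = c(hap, hap))
  })
  names(ents) <- sprintf("m%d", 1:6)
  ph <- phase_variants(toy_amat(ents))
  expect_s3_class(ph, "lr_phase")
  expect_equal(ph$mec_cost, 0)
  expect_equal(ph$n_blocks, 1)
  # v1 and v2 co-phased: same H1 allele at both sites
  expect_equal(ph$variants$h1_allele[1], ph$variants$h1_allele[2])
})

test_that("a single flipped entry costs one correction and majority wins", {
  # 6 molecules x 2 variants, consistent except one flipped entry (12 entries)
  ents <- purrr::map(1:6, function(i) {
    hap <- i %% 2
    list(pos = c(100, 200), allele = c(hap, hap))
  })
  names(ents) <- sprintf("m%d", 1:6)
  ents$m1$allele[2] <- 1L - ents$m1$allele[2]
  amat <- toy_amat(ents)
  ph <- phase_variants(amat)
  expect_equal(ph$mec_cost, 1)
  # equals the exhaustive optimum
  inst <- data.frame(
    molecule = rep(1:6, each = 2), v = rep(1:2, 6),
    allele = unlist(purrr::map(ents, "allele"))
  )
  expect_equal(ph$mec_cost, oracle_mec_min(inst, 2))
  # majority configuration: variants still co-phased
  expect_equal(ph$variants$h1_allele[1], ph$variants$h1_allele[2])
})

test_that("unlinked variant groups become independent blocks with flip symmetry", {
  ents <- list(
    m1 = list(pos = c(100, 200), allele = c(0L, 0L)),
    m2 = list(pos = c(100, 200), allele = c(1L, 1L)),
    m3 = list(pos = c(5000, 5100), allele = c(0L, 1L)),
    m4 = list(pos = c(5000, 5100), allele = c(1L, 0L))
  )
  amat <- toy_amat(ents)
  ph <- phase_variants(amat)
  expect_equal(ph$n_blocks, 2)
  expect_equal(dplyr::n_distinct(ph$variants$block_id), 2)
  # relabelling H1/H2 within one block leaves the MEC cost unchanged
  flipped <- ph$variants
  b1 <- flipped$block_id == flipped$block_id[1]
  flipped$h1_allele[b1] <- 1L - flipped$h1_allele[b1]
  expect_equal(mec_cost(amat, flipped), mec_cost(amat, ph$variants))
})

test_that("solver reaches the exhaustive MEC optimum on small noisy instances", {
  for (seed in 1:20) {
    inst <- random_phasing_instance(V = sample(4:10, 1), M = sample(6:15, 1),
                                    noise = 0.1, seed = 1000 + seed)
    ph <- phase_variants(amat_from_instance(inst))
    got <- ph$mec_cost
    opt <- oracle_mec_min(inst$entries, inst$V)
    expect_equal(got, opt, info = paste("seed", seed))
    # local optimality: no single flip improves
    for (v in seq_len(inst$V)) {
      flipped <- ph$variants
      flipped$h1_allele[v] <- 1L - flipped$h1_allele[v]
      expect_gte(mec_cost(amat_from_instance(inst), flipped), got)
    }
  }
})

test_that("zero-error simulation phases to the planted haplotypes up to block flips", {
  sim <- dense_sim(seed = 77, n_molecules = 500, n_recombinant = 0,
                   genome_bp = 1e6, base_error_rate = 0)
  assigned <- build_molecules(sim$reads)
  amat <- allele_matrix(assigned, sim$observations)
  ph <- phase_variants(amat)
  expect_equal(ph$mec_cost, 0)
  joined <- dplyr::inner_join(ph$variants, sim$variants,
                              by = c("chrom", "pos"),
                              suffix = c("", "_truth"))
  agree <- joined |>
    dplyr::group_by(block_id) |>
    dplyr::summarise(frac = mean(h1_allele == h1_allele_truth))
  expect_true(all(agree$frac %in% c(0, 1)))
})

test_that("molecule-balance filter drops biased, thin and outlying variants", {
  ents <- c(
    # pos 100: 20 vs 1 molecules -> extreme allelic bias
    purrr::map(1:21, function(i) list(pos = 100, allele = as.integer(i > 20))),
    # pos 200: balanced 11 vs 11
    purrr::map(1:22, function(i) list(pos = 200, allele = i %% 2L)),
    # pos 300: only 3 molecules -> below min_count
    purrr::map(1:3, function(i) list(pos = 300, allele = i %% 2L))
  )
  names(ents) <- sprintf("m%02d", seq_along(ents))
  amat <- toy_amat(ents)
  ph <- phase_variants(amat)
  out <- filter_variants_by_molecule_balance(ph, amat, min_frac = 0.25,
                                             min_count = 4,
                                             coverage_sd = Inf)
  dropped <- attr(out, "balance_dropped")
  expect_equal(dropped$drop_reason[dropped$pos == 100], "allelic_bias")
  expect_equal(dropped$drop_reason[dropped$pos == 300], "low_molecule_count")
  expect_equal(out$variants$pos, 200)
})

test_that("molecule-coverage outliers are removed", {
  ents <- list()
  k <- 0
  for (p in seq(100, 2000, by = 100)) {      # 20 variants, 6 molecules each
    for (i in 1:6) {
      k <- k + 1
      ents[[k]] <- list(pos = p, allele = i %% 2L)
    }
  }
  for (i in 1:60) {                          # one variant with 10x coverage
    k <- k + 1
    ents[[k]] <- list(pos = 2100, allele = i %% 2L)
  }
  names(ents) <- sprintf("m%03d", seq_along(ents))
  amat <- toy_amat(ents)
  ph <- phase_variants(amat)
  out <- filter_variants_by_molecule_balance(ph, amat)
  dropped <- attr(out, "balance_dropped")
  expect_equal(dropped$drop_reason[dropped$pos == 2100],
               "molecule_coverage_outlier")
  expect_false(2100 %in% out$variants$pos)
  expect_true(all(seq(100, 2000, by = 100) %in% out$variants$pos))
})

test_that("balanced variants survive the balance filter", {
  ents <- purrr::map(1:19, function(i) {
    hap <- i %% 2
    list(pos = c(100, 200), allele = c(hap, hap))
  })
  names(ents) <- sprintf("m%02d", 1:19)
  amat <- toy_amat(ents)
  ph <- phase_variants(amat)
  out <- filter_variants_by_molecule_balance(ph, amat)
  expect_equal(nrow(out$variants), 2)   # 10 vs 9 split kept
  expect_equal(nrow(attr(out, "balance_dropped")), 0)
})
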