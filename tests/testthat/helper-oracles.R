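# Independent brute-force oracles used to validate the phasing and
# molecule-scoring implementations. Deliberately written as plain loops over
# explicit enumerations; they share no code with the package internals.

# Exhaustive MEC optimum: entries is a data frame with columns
# molecule (any id), v (variant index 1..V), allele (0/1).
oracle_mec_min <- function(entries, V) {
  mols <- unique(entries$molecule)
  best <- Inf
  for (code in 0:(2^(V - 1) - 1)) {
    phi <- c(0L, as.integer(intToBits(code))[seq_len(V - 1)])
    cost <- 0
    for (m in mols) {
      sub <- entries[entries$molecule == m, , drop = FALSE]
      mis1 <- sum(sub$allele != phi[sub$v])
      cost <- cost + min(mis1, nrow(sub) - mis1)
    }
    if (cost < best) best <- cost
  }
  best
}

# Brute-force molecule scoring: observations ordered by position.
# alleles, quals: observed allele and phred quality per informative site;
# h1: allele carried by haplotype 1 at each site.
oracle_score <- function(alleles, quals, h1, prior_mix) {
  eps <- 10^(-pmin(quals, 60) / 10)
  p_obs <- function(target) prod(ifelse(alleles == target, 1 - eps, eps))
  n <- length(alleles)
  l1 <- p_obs_vec(alleles, eps, h1)
  l2 <- p_obs_vec(alleles, eps, 1 - h1)
  lmix <- -Inf
  best_s <- NA_integer_
  best_dir <- NA_character_
  if (n >= 2) {
    for (s in 1:(n - 1)) {
      for (dir in c("H1", "H2")) {
        first <- if (dir == "H1") h1 else 1 - h1
        second <- 1 - first
        lik <- prod(ifelse(alleles[1:s] == first[1:s], 1 - eps[1:s], eps[1:s])) *
          prod(ifelse(alleles[(s + 1):n] == second[(s + 1):n],
                      1 - eps[(s + 1):n], eps[(s + 1):n]))
        if (lik > lmix) {
          lmix <- lik
          best_s <- s
          best_dir <- dir
        }
      }
    }
  }
  w <- c((1 - prior_mix) * l1, (1 - prior_mix) * l2,
         if (is.finite(lmix)) prior_mix * lmix else 0)
  w <- w / sum(w)
  list(p_h1 = w[1], p_h2 = w[2], p_mix = w[3], best_switch = best_s,
       first_hap = best_dir)
}

p_obs_vec <- function(alleles, eps, target) {
  prod(ifelse(alleles == target, 1 - eps, eps))
}

# Build an allele-matrix tibble for a set of molecules given per-molecule
# variant coverage and alleles (no conflicts).
toy_amat <- function(mol_entries, chrom = "chr1", qual = 30L) {
  purrr::imap_dfr(mol_entries, function(ent, id) {
    tibble::tibble(
      molecule_id = id,
      chrom = chrom,
      pos = as.numeric(ent$pos),
      allele = as.integer(ent$allele),
      conflict = FALSE,
      max_qual = qual,
      n_reads_0 = as.integer(ent$allele == 0L),
      n_reads_1 = as.integer(ent$allele == 1L)
    )
  })
}

# Random small phasing instance: V variants, M molecules, each molecule
# covers a contiguous variant stretch; entries flipped with prob noise.
random_phasing_instance <- function(V, M, noise, seed) {
  set.seed(seed)
  truth <- sample(c(0L, 1L), V, replace = TRUE)
  rows <- list()
  for (m in seq_len(M)) {
    a <- sample.int(V, 1)
    b <- min(V, a + sample.int(max(1, V - 1), 1))
    hap <- sample(c(0L, 1L), 1)
    vs <- a:b
    al <- ifelse(rep(hap, length(vs)) == 0L, truth[vs], 1L - truth[vs])
    flip <- runif(length(vs)) < noise
    al[flip] <- 1L - al[flip]
    rows[[m]] <- data.frame(molecule = m, v = vs, allele = al)
  }
  inst <- do.call(rbind, rows)
  # keep only variants that were covered, reindexed contiguously
  seen <- sort(unique(inst$v))
  inst$v <- match(inst$v, seen)
  list(entries = inst, V = length(seen), truth = truth[seen])
}

amat_from_instance <- function(inst, spacing = 100) {
  tibble::tibble(
    molecule_id = sprintf("m%02d", inst$entries$molecule),
    chrom = "chr1",
    pos = inst$entries$v * spacing,
    allele = inst$entries$allele,
    conflict = FALSE,
    max_qual = 30L,
    n_reads_0 = as.integer(inst$entries$allele == 0L),
    n_reads_1 = as.integer(inst$entries$allele == 1L)
  )
}
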