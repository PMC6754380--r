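#' Build the molecule-by-variant allele matrix
#'
#' Collapses read-level allele observations to one entry per (molecule,
#' variant). A molecule whose reads support both alleles of a variant gets a
#' `conflict` entry there (the entry's allele is NA); such molecules are
#' masked during phasing and excluded from crossover calling, because reads
#' from both alleles under one barcode are the signature of a barcode
#' collision rather than of a haploid gamete molecule.
#'
#' @param assigned_reads Output of [build_molecules()] (reads with
#'   `molecule_id`), optionally pre-filtered to retained molecules.
#' @param observations Read-level allele observations (see
#'   [read_allele_observations()]).
#' @return A tibble with one row per (molecule, covered variant):
#'   `molecule_id`, `chrom`, `pos`, `allele` (0/1, NA when conflicting),
#'   `conflict`, `max_qual` (highest phred base quality supporting the
#'   retained allele), `n_reads_0`, `n_reads_1`.
#' @export
allele_matrix <- function(assigned_reads, observations) {
  stopifnot("molecule_id" %in% names(assigned_reads))
  obs <- inner_join(
    observations,
    dplyr::select(assigned_reads, "read_id", "molecule_id"),
    by = "read_id"
  )
  if (nrow(obs) == 0) {
    return(tibble(molecule_id = character(), chrom = character(),
                  pos = double(), allele = integer(), conflict = logical(),
                  max_qual = integer(), n_reads_0 = integer(),
                  n_reads_1 = integer()))
  }
  key <- paste(obs$molecule_id, obs$chrom, obs$pos, sep = "\r")
  ukey <- unique(key)
  gid <- match(key, ukey)
  G <- length(ukey)
  n0 <- tabulate(gid[obs$allele == 0L], G)
  n1 <- tabulate(gid[obs$allele == 1L], G)
  # per-group max quality for each allele: ordered assignment, last wins
  qmax_for <- function(which_allele) {
    idx <- which(obs$allele == which_allele)
    q <- rep(NA_integer_, G)
    o <- idx[order(gid[idx], obs$base_qual[idx])]
    q[gid[o]] <- obs$base_qual[o]
    q
  }
  q0 <- qmax_for(0L)
  q1 <- qmax_for(1L)
  firsts <- !duplicated(gid)
  conflict <- n0 > 0 & n1 > 0
  allele <- ifelse(conflict, NA_integer_, ifelse(n1 > 0, 1L, 0L))
  tibble(
    molecule_id = obs$molecule_id[firsts][order(gid[firsts])],
    chrom = obs$chrom[firsts][order(gid[firsts])],
    pos = obs$pos[firsts][order(gid[firsts])],
    allele = as.integer(allele),
    conflict = conflict,
    max_qual = as.integer(ifelse(conflict, pmax(q0, q1, na.rm = TRUE),
                                 ifelse(allele == 1L, q1, q0))),
    n_reads_0 = n0,
    n_reads_1 = n1
  ) |>
    arrange(.data$molecule_id, .data$chrom, .data$pos)
}

#' Minimum-error-correction cost of a phasing
#'
#' The MEC cost is the smallest number of allele-matrix entries that must be
#' flipped so that every molecule is consistent with one haplotype. Given a
#' candidate phase (`h1_allele` per variant), each molecule is assigned to
#' the haplotype minimizing its own mismatches and the per-molecule minima
#' are summed. Conflict entries are excluded.
#'
#' @param amat Output of [allele_matrix()].
#' @param phase Tibble with `chrom`, `pos`, `h1_allele`.
#' @return A single non-negative number.
#' @export
mec_cost <- function(amat, phase) {
  e <- inner_join(filter(amat, !.data$conflict),
                  dplyr::select(phase, "chrom", "pos", "h1_allele"),
                  by = c("chrom", "pos"))
  if (nrow(e) == 0) return(0)
  mis1 <- as.integer(e$allele != e$h1_allele)
  per_mol <- rowsum(cbind(mis1, 1L - mis1), e$molecule_id)
  sum(pmin(per_mol[, 1], per_mol[, 2]))
}

#' Phase heterozygous variants from molecule co-observation
#'
#' Two-colors variant alleles into haplotypes H1/H2 by (approximately)
#' minimizing the minimum-error-correction cost over molecules, the objective
#' used by single-individual fragment phasers. Variants linked by at least one
#' shared molecule form a phase block (connected component); phase is defined
#' up to an H1/H2 relabelling within each block. The phasing stage treats
#' every molecule as non-recombinant; genuine crossover molecules are rare
#' enough that they act as a handful of error entries here and are recovered
#' later by [score_molecules()].
#'
#' The solver seeds each block by propagating the majority co-observation
#' vote along genomic order, then alternates molecule-assignment and
#' variant-phase majority updates (coordinate descent) to a local optimum;
#' small blocks additionally get seeded random restarts and a single-variant
#' flip search. Ties are broken deterministically from `seed`.
#'
#' @param amat Output of [allele_matrix()]. Conflict entries are masked.
#' @param seed Integer controlling tie-breaking and restarts (default 1729).
#' @param n_restarts Random restarts for blocks of at most `small_block`
#'   variants (default 12).
#' @param small_block Block size (variants) up to which restarts and the flip
#'   search are applied (default 25).
#' @param max_iter Coordinate-descent sweep cap per start (default 50).
#' @param link_depth Molecule-internal links are formed between observed
#'   variants up to this many observed steps apart (default 3); deeper links
#'   make the vote graph robust when per-molecule observations are sparse.
#' @return An object of class `lr_phase`: list with `variants` (tibble
#'   `chrom`, `pos`, `h1_allele`, `block_id`, `n_molecules`, `n_mol_allele0`,
#'   `n_mol_allele1`), `mec_cost`, `n_blocks`, `n_molecules`. Methods:
#'   [tidy.lr_phase()], [glance.lr_phase()].
#' @export
phase_variants <- function(amat, seed = 1729, n_restarts = 12,
                           small_block = 25, max_iter = 50, link_depth = 3) {
  entries <- filter(amat, !.data$conflict)
  vars <- entries |>
    distinct(.data$chrom, .data$pos) |>
    arrange(.data$chrom, .data$pos)
  V <- nrow(vars)
  if (V == 0) {
    return(new_lr_phase(
      mutate(vars, h1_allele = integer(), block_id = character(),
             n_molecules = integer(), n_mol_allele0 = integer(),
             n_mol_allele1 = integer()),
      mec = 0, n_blocks = 0, n_mol = 0
    ))
  }
  vars$v_idx <- seq_len(V)
  entries <- inner_join(entries, vars, by = c("chrom", "pos")) |>
    arrange(.data$molecule_id, .data$v_idx)
  m_idx <- match(entries$molecule_id, unique(entries$molecule_id))
  M <- max(m_idx)

  # molecule-internal links between nearby observed variants (up to
  # link_depth observed steps apart, so sparse observations still yield
  # several independent votes per variant)
  n_e <- nrow(entries)
  link_parts <- lapply(seq_len(link_depth), function(k) {
    if (n_e <= k) return(NULL)
    pre <- seq_len(n_e - k)
    post <- pre + k
    same_mol <- m_idx[pre] == m_idx[post]
    list(
      u = entries$v_idx[pre][same_mol],
      v = entries$v_idx[post][same_mol],
      w = 2L * (entries$allele[pre][same_mol] ==
                  entries$allele[post][same_mol]) - 1L
    )
  })
  all_u <- unlist(lapply(link_parts, `[[`, "u"))
  all_v <- unlist(lapply(link_parts, `[[`, "v"))
  all_w <- unlist(lapply(link_parts, `[[`, "w"))
  links <- if (length(all_u) == 0) {
    tibble(u = integer(), v = integer(), w = integer())
  } else {
    key <- (all_u - 1) * V + all_v     # unique pair key, doubles are exact
    o <- order(key)
    k2 <- key[o]
    w2 <- cumsum(all_w[o])
    ends <- c(k2[-1] != k2[-length(k2)], TRUE)
    ukey <- k2[ends]
    w_agg <- diff(c(0, w2[ends]))
    tibble(
      u = as.integer((ukey - 1) %/% V + 1),
      v = as.integer((ukey - 1) %% V + 1),
      w = as.integer(w_agg)
    )
  }

  # blocks = connected components of the link graph
  g <- igraph::graph_from_edgelist(cbind(links$u, links$v), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, V - igraph::vcount(g)))
  comp <- igraph::components(g)$membership

  # initialisation: genomic-order sweep assigning each variant by the
  # weighted majority over all already-assigned linked neighbours; variants
  # not yet reachable are deferred, and a stalled pass seeds a new block
  set.seed(seed)
  tie_bits <- sample(c(0L, 1L), V, replace = TRUE)
  phi <- majority_sweep_phase(links, V, tie_bits)

  # coordinate descent over all blocks at once
  ev <- entries$v_idx; ea <- entries$allele
  cd <- coordinate_descent(phi, ev, ea, m_idx, M, V, max_iter)
  phi <- cd$phi

  # segment-flip refinement: a locally self-consistent flipped run survives
  # single-variant moves, so suffix flips are tried at boundaries whose
  # spanning links disagree with the current phase
  phi <- suffix_flip_refine(phi, links, ev, ea, m_idx, M, V)
  phi <- coordinate_descent(phi, ev, ea, m_idx, M, V, max_iter)$phi

  # restarts + flip polish for small blocks
  comp_sizes <- tabulate(comp)
  small <- which(comp_sizes[comp[ev]] <= small_block)
  if (length(small) > 0 && (n_restarts > 0 || TRUE)) {
    for (b in unique(comp[ev[small]])) {
      vsel <- which(comp == b)
      esel <- which(comp[ev] == b)
      sub_v <- match(ev[esel], vsel)
      sub_m <- match(m_idx[esel], unique(m_idx[esel]))
      subM <- max(sub_m); subV <- length(vsel)
      best_phi <- phi[vsel]
      best_cost <- mec_cost_int(best_phi, sub_v, ea[esel], sub_m, subM)
      cand <- flip_search(best_phi, sub_v, ea[esel], sub_m, subM, subV)
      if (cand$cost < best_cost) { best_phi <- cand$phi; best_cost <- cand$cost }
      for (r in seq_len(n_restarts)) {
        phi0 <- sample(c(0L, 1L), subV, replace = TRUE)
        cd_r <- coordinate_descent(phi0, sub_v, ea[esel], sub_m, subM, subV, max_iter)
        cand <- flip_search(cd_r$phi, sub_v, ea[esel], sub_m, subM, subV)
        if (cand$cost < best_cost) { best_phi <- cand$phi; best_cost <- cand$cost }
      }
      phi[vsel] <- best_phi
    }
  }

  total_cost <- mec_cost_int(phi, ev, ea, m_idx, M)
  counts0 <- tabulate(ev[ea == 0L], V)
  counts1 <- tabulate(ev[ea == 1L], V)
  out_vars <- vars |>
    mutate(
      h1_allele = phi[.data$v_idx],
      block_id = sprintf("B%05d", comp[.data$v_idx]),
      n_molecules = counts0[.data$v_idx] + counts1[.data$v_idx],
      n_mol_allele0 = counts0[.data$v_idx],
      n_mol_allele1 = counts1[.data$v_idx]
    ) |>
    dplyr::select(-"v_idx")
  new_lr_phase(out_vars, mec = total_cost,
               n_blocks = length(unique(comp)), n_mol = M)
}

new_lr_phase <- function(variants, mec, n_blocks, n_mol) {
  structure(
    list(variants = variants, mec_cost = mec, n_blocks = n_blocks,
         n_molecules = n_mol),
    class = "lr_phase"
  )
}

#' @exportS3Method base::print
print.lr_phase <- function(x, ...) {
  cat("<lr_phase> ", nrow(x$variants), " variants in ", x$n_blocks,
      " block(s); MEC cost ", x$mec_cost, " over ", x$n_molecules,
      " molecules\n", sep = "")
  invisible(x)
}

# Genomic-order majority sweep over the aggregated co-observation links
# (positive weight = same phase). Each variant is assigned from the weighted
# majority of ALL its already-assigned neighbours, so a handful of
# sign-flipped links (e.g. through a genuine recombinant molecule) cannot
# seed a flipped run. Variants with no assigned neighbour are deferred to
# further passes; a pass that assigns nothing seeds the next unassigned
# variant as a new block root.
majority_sweep_phase <- function(links, V, tie_bits) {
  phi <- rep(NA_integer_, V)
  if (V == 0) return(integer(0))
  if (nrow(links) == 0) return(integer(V))
  from <- c(links$u, links$v)
  to <- c(links$v, links$u)
  w <- c(links$w, links$w)
  o <- order(from)
  to <- to[o]; w <- w[o]
  row_start <- c(0L, cumsum(tabulate(from[o], V))) + 1L
  n_left <- V
  repeat {
    progress <- FALSE
    for (v in seq_len(V)) {
      if (!is.na(phi[v])) next
      j0 <- row_start[v]; j1 <- row_start[v + 1L] - 1L
      if (j1 < j0) { phi[v] <- 0L; n_left <- n_left - 1L; progress <- TRUE; next }
      kk <- j0:j1
      nb_phi <- phi[to[kk]]
      ok <- !is.na(nb_phi)
      if (!any(ok)) next
      s <- sum(w[kk][ok] * ifelse(nb_phi[ok] == 0L, 1L, -1L))
      phi[v] <- if (s > 0) 0L else if (s < 0) 1L else tie_bits[v]
      n_left <- n_left - 1L
      progress <- TRUE
    }
    if (n_left == 0L) break
    if (!progress) {
      root <- which(is.na(phi))[1]
      phi[root] <- 0L
      n_left <- n_left - 1L
    }
  }
  phi
}

# Suffix-flip hill climb over segment boundaries. Boundary b sits between
# variants b and b+1 in genomic order; its support is the signed sum of link
# consistencies over links spanning it (negative = the phase disagrees with
# the molecules there). Because phase blocks are independent, flipping an
# entire suffix of the variant order only changes cost through links that
# span the chosen boundary.
suffix_flip_refine <- function(phi, links, ev, ea, em, M, V,
                               max_rounds = 25, max_tries = 12) {
  if (V < 2 || nrow(links) == 0) return(phi)
  cost <- mec_cost_int(phi, ev, ea, em, M)
  for (round in seq_len(max_rounds)) {
    happy <- links$w * ifelse(phi[links$u] == phi[links$v], 1L, -1L)
    d <- numeric(V)
    # link (u,v) spans boundaries u .. v-1
    d[links$u] <- d[links$u] + happy
    d[links$v] <- d[links$v] - happy
    score <- cumsum(d)[-V]
    cand <- order(score)
    cand <- cand[score[cand] < 0]
    if (length(cand) == 0) break
    cand <- head(cand, max_tries)
    best_gain <- 0
    best_phi <- NULL
    for (b in cand) {
      phi2 <- phi
      idx <- (b + 1L):V
      phi2[idx] <- 1L - phi2[idx]
      c2 <- mec_cost_int(phi2, ev, ea, em, M)
      if (cost - c2 > best_gain) {
        best_gain <- cost - c2
        best_phi <- phi2
      }
    }
    if (is.null(best_phi)) break
    phi <- best_phi
    cost <- cost - best_gain
  }
  phi
}

# integer-vector MEC cost (phi indexed by ev)
mec_cost_int <- function(phi, ev, ea, em, M) {
  mis1 <- as.integer(ea != phi[ev])
  c1 <- unname(rowsum(mis1, em, reorder = FALSE)[, 1])
  n <- unname(rowsum(rep(1L, length(em)), em, reorder = FALSE)[, 1])
  sum(pmin(c1, n - c1))
}

# alternate molecule-assignment / variant-majority updates until cost stalls
coordinate_descent <- function(phi, ev, ea, em, M, V = max(ev), max_iter = 50) {
  cost_prev <- Inf
  for (it in seq_len(max_iter)) {
    mis1 <- as.integer(ea != phi[ev])
    c1 <- unname(rowsum(mis1, em, reorder = FALSE)[, 1])
    n_m <- unname(rowsum(rep(1L, length(em)), em, reorder = FALSE)[, 1])
    cost <- sum(pmin(c1, n_m - c1))
    if (cost >= cost_prev) break
    cost_prev <- cost
    h_is_1 <- c1 <= n_m - c1      # TRUE: molecule on haplotype 1
    vote1 <- ifelse(h_is_1[em], ea, 1L - ea)   # vote for phi[v] = this
    n1 <- tabulate(ev[vote1 == 1L], V)
    nt <- tabulate(ev, V)
    phi <- ifelse(n1 * 2L > nt, 1L, ifelse(n1 * 2L < nt, 0L, phi))
  }
  list(phi = phi, cost = cost_prev)
}

# exhaustive single-variant flip hill-climb (small blocks only)
flip_search <- function(phi, ev, ea, em, M, V) {
  cost <- mec_cost_int(phi, ev, ea, em, M)
  repeat {
    improved <- FALSE
    for (v in seq_len(V)) {
      phi2 <- phi
      phi2[v] <- 1L - phi2[v]
      c2 <- mec_cost_int(phi2, ev, ea, em, M)
      if (c2 < cost) {
        phi <- phi2
        cost <- c2
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(phi = phi, cost = cost)
}

#' Drop variants with unbalanced molecule support or outlying coverage
#'
#' After molecules have been phased, a genuine heterozygous variant should be
#' supported by a similar number of molecules on each allele, and its
#' molecule/read coverage should resemble its chromosome's average. Variants
#' violating either pattern are usually artifacts of structural variation,
#' collapsed repeats or mis-assembly and are removed before crossover
#' calling.
#'
#' @param phase An [phase_variants()] result.
#' @param amat The [allele_matrix()] the phase was computed from.
#' @param min_frac Minimum minor-allele molecule fraction (default 0.25).
#' @param min_count Minimum total molecules covering the variant (default 4).
#' @param coverage_sd Variants whose molecule or read coverage deviates from
#'   their chromosome mean by more than this many standard deviations are
#'   dropped (default 3).
#' @return The `lr_phase` object with offending variants removed; the dropped
#'   set (with reasons) is attached as attribute `"balance_dropped"`.
#' @export
filter_variants_by_molecule_balance <- function(phase, amat, min_frac = 0.25,
                                                min_count = 4,
                                                coverage_sd = 3) {
  stopifnot(inherits(phase, "lr_phase"))
  cov <- amat |>
    group_by(.data$chrom, .data$pos) |>
    summarise(read_cov = sum(.data$n_reads_0 + .data$n_reads_1),
              .groups = "drop")
  v <- left_join(phase$variants, cov, by = c("chrom", "pos")) |>
    group_by(.data$chrom) |>
    mutate(
      mol_mean = mean(.data$n_molecules), mol_sd = sd(.data$n_molecules),
      read_mean = mean(.data$read_cov), read_sd = sd(.data$read_cov)
    ) |>
    ungroup() |>
    mutate(
      minor_frac = pmin(.data$n_mol_allele0, .data$n_mol_allele1) /
        pmax(.data$n_molecules, 1L),
      drop_reason = dplyr::case_when(
        .data$n_molecules < min_count ~ "low_molecule_count",
        .data$minor_frac < min_frac ~ "allelic_bias",
        !is.na(.data$mol_sd) & .data$mol_sd > 0 &
          abs(.data$n_molecules - .data$mol_mean) > coverage_sd * .data$mol_sd ~
          "molecule_coverage_outlier",
        !is.na(.data$read_sd) & .data$read_sd > 0 &
          abs(.data$read_cov - .data$read_mean) > coverage_sd * .data$read_sd ~
          "read_coverage_outlier",
        TRUE ~ NA_character_
      )
    )
  dropped <- v |>
    filter(!is.na(.data$drop_reason)) |>
    dplyr::select("chrom", "pos", "drop_reason")
  phase$variants <- v |>
    filter(is.na(.data$drop_reason)) |>
    dplyr::select(dplyr::all_of(names(phase$variants)))
  attr(phase, "balance_dropped") <- dropped
  phase
}
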