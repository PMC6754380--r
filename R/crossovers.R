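#' Score molecules against the two haplotypes and a one-switch mixture
#'
#' For each molecule, every informative entry (a non-conflict allele-matrix
#' entry at a phased variant) contributes `1 - eps` when the observed allele
#' matches the candidate haplotype and `eps` otherwise, with
#' `eps = 10^(-Q/10)` from the entry's base quality `Q`. Three models are
#' compared: pure haplotype 1, pure haplotype 2, and the best one-switch
#' mixture (H1-then-H2 or H2-then-H1 over the position-sorted entries).
#' Posteriors use prior mass `(1 - prior_mix, 1 - prior_mix, prior_mix)`,
#' normalized; `prior_mix` should be the expected frequency of recombinant
#' molecules (see [expected_recombinant_stats()]), ~3.3e-4 for a mouse-sized
#' genome and map.
#'
#' Molecules with a conflict entry at any variant are classed `EXCLUDED`
#' (likely barcode collisions); molecules covering fewer than two informative
#' variants are `AMBIGUOUS`. Otherwise the molecule is `RECOMBINANT` when
#' `p_mix >= call_threshold`, `H1`/`H2` when the corresponding posterior
#' reaches the threshold, and `AMBIGUOUS` otherwise. When several switch
#' points tie for the mixture maximum the leftmost is reported.
#'
#' @param amat Output of [allele_matrix()].
#' @param phase An [phase_variants()] result (after any variant filtering).
#' @param prior_mix Prior probability that a molecule is recombinant
#'   (default 3.3e-4).
#' @param call_threshold Posterior needed to assign a class (default 0.95).
#' @param qual_cap Base qualities are capped here to keep single overconfident
#'   base calls from dominating (default 60).
#' @return A tibble with one row per molecule: `molecule_id`, `chrom`,
#'   `n_informative`, `p_h1`, `p_h2`, `p_mix`, `class`, `best_switch_index`
#'   (entries on the first segment), `switch_start`/`switch_end` (positions of
#'   the informative variants flanking the best switch) and
#'   `switch_first_hap`. Attributes record the prior and threshold.
#' @export
score_molecules <- function(amat, phase, prior_mix = 3.3e-4,
                            call_threshold = 0.95, qual_cap = 60) {
  stopifnot(inherits(phase, "lr_phase"), prior_mix > 0, prior_mix < 1)
  conflicted <- amat |>
    filter(.data$conflict) |>
    distinct(.data$molecule_id)
  e <- amat |>
    filter(!.data$conflict) |>
    inner_join(dplyr::select(phase$variants, "chrom", "pos", "h1_allele"),
               by = c("chrom", "pos")) |>
    anti_join(conflicted, by = "molecule_id") |>
    arrange(.data$molecule_id, .data$chrom, .data$pos)

  all_mols <- unique(c(amat$molecule_id))
  if (nrow(e) == 0) {
    scored <- tibble(molecule_id = character(), chrom = character(),
                     n_informative = integer(), log_l1 = double(),
                     log_l2 = double(), log_lmix = double(),
                     best_switch_index = integer(), switch_start = double(),
                     switch_end = double(), switch_first_hap = character())
  } else {
    m_idx <- match(e$molecule_id, unique(e$molecule_id))
    eps <- pmax(10^(-pmin(e$max_qual, qual_cap) / 10), 1e-12)
    match1 <- e$allele == e$h1_allele
    l1 <- ifelse(match1, log1p(-eps), log(eps))
    l2 <- ifelse(match1, log(eps), log1p(-eps))
    n_m <- tabulate(m_idx)
    t1 <- unname(rowsum(l1, m_idx, reorder = FALSE)[, 1])
    t2 <- unname(rowsum(l2, m_idx, reorder = FALSE)[, 1])
    cum1 <- grouped_cumsum(l1, m_idx)
    cum2 <- grouped_cumsum(l2, m_idx)
    # switch after entry s (1 <= s <= n-1): H1->H2 is cum1[s] + t2 - cum2[s]
    s12 <- cum1 + t2[m_idx] - cum2
    s21 <- cum2 + t1[m_idx] - cum1
    within_idx <- unlist(lapply(n_m, seq_len), use.names = FALSE)
    is_switch <- within_idx < n_m[m_idx]
    best <- if (any(is_switch)) {
      tibble(
        m = m_idx[is_switch], s = within_idx[is_switch],
        l12 = s12[is_switch], l21 = s21[is_switch]
      ) |>
        mutate(lmix = pmax(.data$l12, .data$l21)) |>
        group_by(.data$m) |>
        summarise(
          log_lmix = max(.data$lmix),
          best_switch_index = .data$s[which.max(.data$lmix)],
          switch_first_hap = ifelse(
            .data$l12[which.max(.data$lmix)] >= .data$l21[which.max(.data$lmix)],
            "H1", "H2"),
          .groups = "drop"
        )
    } else {
      tibble(m = integer(), log_lmix = double(),
             best_switch_index = integer(), switch_first_hap = character())
    }
    first_of <- which(!duplicated(m_idx))
    scored <- tibble(
      m = seq_along(n_m),
      molecule_id = e$molecule_id[first_of],
      chrom = e$chrom[first_of],
      n_informative = n_m,
      log_l1 = t1, log_l2 = t2
    ) |>
      left_join(best, by = "m")
    # positions flanking the best switch
    pos_by_m <- split(e$pos, m_idx)
    scored <- scored |>
      mutate(
        switch_start = ifelse(is.na(.data$best_switch_index), NA_real_,
                              purrr::map2_dbl(pos_by_m[.data$m], .data$best_switch_index,
                                              ~ if (is.na(.y)) NA_real_ else .x[.y])),
        switch_end = ifelse(is.na(.data$best_switch_index), NA_real_,
                            purrr::map2_dbl(pos_by_m[.data$m], .data$best_switch_index,
                                            ~ if (is.na(.y)) NA_real_ else .x[.y + 1]))
      ) |>
      dplyr::select(-"m")
  }

  scored <- scored |>
    mutate(posterior_mix(.data$log_l1, .data$log_l2, .data$log_lmix, prior_mix)) |>
    mutate(
      class = dplyr::case_when(
        .data$n_informative < 2 ~ "AMBIGUOUS",
        .data$p_mix >= call_threshold ~ "RECOMBINANT",
        .data$p_h1 >= call_threshold ~ "H1",
        .data$p_h2 >= call_threshold ~ "H2",
        TRUE ~ "AMBIGUOUS"
      )
    ) |>
    dplyr::select("molecule_id", "chrom", "n_informative", "p_h1", "p_h2",
                  "p_mix", "class", "best_switch_index", "switch_start",
                  "switch_end", "switch_first_hap")

  # molecules excluded (conflict) or with no informative entries
  excluded <- tibble(molecule_id = conflicted$molecule_id) |>
    left_join(distinct(amat, .data$molecule_id, .data$chrom), by = "molecule_id") |>
    mutate(n_informative = NA_integer_, p_h1 = NA_real_, p_h2 = NA_real_,
           p_mix = NA_real_, class = "EXCLUDED",
           best_switch_index = NA_integer_, switch_start = NA_real_,
           switch_end = NA_real_, switch_first_hap = NA_character_)
  uninformative <- setdiff(all_mols, c(scored$molecule_id, excluded$molecule_id))
  rest <- tibble(molecule_id = uninformative) |>
    left_join(distinct(amat, .data$molecule_id, .data$chrom), by = "molecule_id") |>
    mutate(n_informative = 0L, p_h1 = NA_real_, p_h2 = NA_real_,
           p_mix = NA_real_, class = "AMBIGUOUS",
           best_switch_index = NA_integer_, switch_start = NA_real_,
           switch_end = NA_real_, switch_first_hap = NA_character_)
  out <- bind_rows(scored, excluded, rest) |> arrange(.data$molecule_id)
  attr(out, "prior_mix") <- prior_mix
  attr(out, "call_threshold") <- call_threshold
  out
}

# posterior over (H1, H2, mix) with prior mass (1-pi, 1-pi, pi), normalized
posterior_mix <- function(log_l1, log_l2, log_lmix, prior_mix) {
  log_lmix <- ifelse(is.na(log_lmix), -Inf, log_lmix)
  lp <- cbind(
    log(1 - prior_mix) + log_l1,
    log(1 - prior_mix) + log_l2,
    log(prior_mix) + log_lmix
  )
  mx <- apply(lp, 1, max)
  mx[!is.finite(mx)] <- 0
  w <- exp(lp - mx)
  tot <- rowSums(w)
  tibble(p_h1 = w[, 1] / tot, p_h2 = w[, 2] / tot, p_mix = w[, 3] / tot)
}

#' Mask windows with unbalanced haplotype coverage
#'
#' Genomic regions whose molecules do not split roughly evenly between the
#' two haplotypes indicate structural variation or assembly problems rather
#' than clean diploid sequence; crossover calls inside them are untrustworthy.
#' Windows are masked when the minor haplotype's share of classed (H1/H2)
#' molecules falls below `min_ratio`. Windows without classed molecules are
#' left unmasked (nothing can be called there anyway).
#'
#' @param calls Output of [score_molecules()].
#' @param molecules Output of [molecule_table()] (for molecule midpoints).
#' @param window_bp Window width (default 100 kb).
#' @param min_ratio Minimum minor-haplotype share (default 0.3).
#' @param chrom_lengths Tibble `chrom`, `length`; inferred from the molecules
#'   when NULL.
#' @return A tibble of windows with `n_h1`, `n_h2` and `masked`.
#' @export
haplotype_balance_mask <- function(calls, molecules, window_bp = 100000,
                                   min_ratio = 0.3, chrom_lengths = NULL) {
  chrom_lengths <- chrom_lengths %||% infer_chrom_lengths(molecules)
  check_chrom_lengths(chrom_lengths)
  wins <- purrr::map2_dfr(chrom_lengths$chrom, chrom_lengths$length,
                          ~ tile_windows(.x, .y, window_bp))
  mols <- molecules |>
    inner_join(dplyr::select(calls, "molecule_id", "class"), by = "molecule_id") |>
    filter(.data$class %in% c("H1", "H2")) |>
    mutate(mid = (.data$start + .data$end) / 2,
           win_start = floor(.data$mid / window_bp) * window_bp)
  counts <- mols |>
    count(.data$chrom, .data$win_start, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L)
  for (col in c("H1", "H2")) if (!col %in% names(counts)) counts[[col]] <- 0L
  wins |>
    left_join(counts, by = c("chrom", "start" = "win_start")) |>
    mutate(
      n_h1 = dplyr::coalesce(.data$H1, 0L),
      n_h2 = dplyr::coalesce(.data$H2, 0L),
      masked = (.data$n_h1 + .data$n_h2) > 0 &
        pmin(.data$n_h1, .data$n_h2) / pmax(.data$n_h1 + .data$n_h2, 1L) < min_ratio
    ) |>
    dplyr::select("chrom", "start", "end", "n_h1", "n_h2", "masked")
}

#' Call crossover events from scored molecules
#'
#' A `RECOMBINANT` molecule yields a crossover only when each side of its
#' best switch point carries at least `min_side_variants` informative
#' variants and at least `min_side_read_frac` of the reads with informative
#' observations on that side are phased to that side's haplotype (a read is
#' concordant when the majority of its informative observations on the side
#' match the side's haplotype). These rules tolerate small erroneous
#' within-side switches from single low-quality base calls while rejecting
#' noisy mosaics. The crossover interval runs from the last informative
#' variant of the first segment to the first informative variant of the
#' second; its length is the crossover's resolution. One crossover per
#' molecule is emitted. Calls whose interval midpoint falls in a masked
#' window (see [haplotype_balance_mask()]) are discarded with a reason.
#'
#' @param calls Output of [score_molecules()].
#' @param amat The [allele_matrix()] used for scoring.
#' @param phase The [phase_variants()] result used for scoring.
#' @param assigned_reads Output of [build_molecules()].
#' @param observations Read-level allele observations.
#' @param mask Optional window mask from [haplotype_balance_mask()].
#' @param min_side_variants Minimum informative variants per side (default 3).
#' @param min_side_read_frac Minimum concordant-read fraction per side
#'   (default 0.7).
#' @return A tibble of crossover events: `molecule_id`, `barcode`, `chrom`,
#'   `interval_start`, `interval_end`, `resolution_bp`, `probability`
#'   (`p_mix`), `n_reads`, per-side variant counts and concordant-read
#'   fractions. Rejected recombinant molecules are attached as attribute
#'   `"rejected"`.
#' @export
call_crossovers <- function(calls, amat, phase, assigned_reads, observations,
                            mask = NULL, min_side_variants = 3,
                            min_side_read_frac = 0.7) {
  rec <- filter(calls, .data$class == "RECOMBINANT",
                !is.na(.data$best_switch_index))
  empty <- tibble(
    molecule_id = character(), barcode = character(), chrom = character(),
    interval_start = double(), interval_end = double(),
    resolution_bp = double(), probability = double(), n_reads = integer(),
    n_variants_side_a = integer(), n_variants_side_b = integer(),
    frac_reads_concordant_side_a = double(),
    frac_reads_concordant_side_b = double()
  )
  if (nrow(rec) == 0) {
    attr(empty, "rejected") <- tibble(molecule_id = character(), reason = character())
    return(empty)
  }
  e <- amat |>
    filter(!.data$conflict) |>
    inner_join(dplyr::select(phase$variants, "chrom", "pos", "h1_allele"),
               by = c("chrom", "pos")) |>
    dplyr::semi_join(rec, by = "molecule_id")
  # per-molecule side split at the switch boundary
  e <- e |>
    inner_join(dplyr::select(rec, "molecule_id", "switch_start", "switch_end",
                             "switch_first_hap", "p_mix"),
               by = "molecule_id") |>
    mutate(
      side = ifelse(.data$pos <= .data$switch_start, "a", "b"),
      side_hap = ifelse(.data$side == "a", .data$switch_first_hap,
                        ifelse(.data$switch_first_hap == "H1", "H2", "H1")),
      side_allele = ifelse(.data$side_hap == "H1", .data$h1_allele,
                           1L - .data$h1_allele)
    )
  var_counts <- e |>
    count(.data$molecule_id, .data$side) |>
    tidyr::pivot_wider(names_from = "side", values_from = "n",
                       values_fill = 0L, names_prefix = "n_var_")
  for (col in c("n_var_a", "n_var_b")) {
    if (!col %in% names(var_counts)) var_counts[[col]] <- 0L
  }

  # read-level concordance per side: a read is phased to the side's haplotype
  # when the majority of its informative observations there match it
  obs <- observations |>
    inner_join(dplyr::select(assigned_reads, "read_id", "molecule_id"),
               by = "read_id") |>
    dplyr::semi_join(rec, by = "molecule_id") |>
    inner_join(dplyr::select(e, "molecule_id", "chrom", "pos", "side",
                             "side_allele"),
               by = c("molecule_id", "chrom", "pos"))
  read_conc <- obs |>
    group_by(.data$molecule_id, .data$side, .data$read_id) |>
    summarise(concordant = sum(.data$allele == .data$side_allele) * 2 > dplyr::n(),
              .groups = "drop") |>
    group_by(.data$molecule_id, .data$side) |>
    summarise(frac = mean(.data$concordant), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "side", values_from = "frac",
                       names_prefix = "frac_")
  for (col in c("frac_a", "frac_b")) {
    if (!col %in% names(read_conc)) read_conc[[col]] <- NA_real_
  }

  mol_info <- molecule_table(assigned_reads) |>
    dplyr::select("molecule_id", "barcode", "n_reads")
  out <- rec |>
    left_join(var_counts, by = "molecule_id") |>
    left_join(read_conc, by = "molecule_id") |>
    left_join(mol_info, by = "molecule_id") |>
    mutate(
      n_var_a = dplyr::coalesce(.data$n_var_a, 0L),
      n_var_b = dplyr::coalesce(.data$n_var_b, 0L),
      mid = (.data$switch_start + .data$switch_end) / 2
    )
  if (!is.null(mask)) {
    masked_wins <- filter(mask, .data$masked)
    win_bp <- if (nrow(mask) > 0) mask$end[1] - mask$start[1] else NA_real_
    out <- out |>
      mutate(win_start = floor(.data$mid / win_bp) * win_bp) |>
      left_join(
        mutate(dplyr::select(masked_wins, "chrom", "start"), in_mask = TRUE),
        by = c("chrom", "win_start" = "start")
      ) |>
      mutate(in_mask = dplyr::coalesce(.data$in_mask, FALSE))
  } else {
    out$in_mask <- FALSE
  }
  out <- out |>
    mutate(
      reject_reason = dplyr::case_when(
        .data$n_var_a < min_side_variants | .data$n_var_b < min_side_variants ~
          "too_few_side_variants",
        dplyr::coalesce(.data$frac_a, 0) < min_side_read_frac |
          dplyr::coalesce(.data$frac_b, 0) < min_side_read_frac ~
          "low_side_read_concordance",
        .data$in_mask ~ "masked_region",
        TRUE ~ NA_character_
      )
    )
  rejected <- out |>
    filter(!is.na(.data$reject_reason)) |>
    dplyr::select("molecule_id", reason = "reject_reason")
  kept <- out |>
    filter(is.na(.data$reject_reason)) |>
    dplyr::transmute(
      molecule_id = .data$molecule_id,
      barcode = .data$barcode,
      chrom = .data$chrom,
      interval_start = .data$switch_start,
      interval_end = .data$switch_end,
      resolution_bp = .data$switch_end - .data$switch_start,
      probability = .data$p_mix,
      n_reads = .data$n_reads,
      n_variants_side_a = .data$n_var_a,
      n_variants_side_b = .data$n_var_b,
      frac_reads_concordant_side_a = .data$frac_a,
      frac_reads_concordant_side_b = .data$frac_b
    )
  attr(kept, "rejected") <- rejected
  kept
}
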