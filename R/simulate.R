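#' Configuration for the gamete linked-read simulator
#'
#' Describes a desk-scale pool of haploid gametes sequenced as linked-reads:
#' two parental haplotypes differing at heterozygous SNPs, HMW molecules
#' partitioned into droplets (GEMs) whose barcode they share, a handful of
#' short reads per molecule, base-call errors, and planted crossovers.
#' Defaults mirror a mammalian-style linked-read gamete library: 60 kb
#' molecules, Poisson(8) reads of 150 bp each, heterozygous sites every
#' 50 bp (the hybrid-mouse / stickleback scale of inter-site distances),
#' base error 1e-3 (Q30) and one molecule per GEM (collision-free; raise
#' `molecules_per_gem` to study barcode collision).
#'
#' @param genome_bp Genome (single chromosome) length in bp.
#' @param chrom Chromosome name used in all outputs.
#' @param het_spacing_bp Spacing between heterozygous SNPs in bp.
#' @param spacing_dist `"fixed"` (regular grid) or `"exponential"` (mean
#'   `het_spacing_bp`).
#' @param molecule_len_bp Molecule length in bp (mean for the exponential
#'   option).
#' @param molecule_len_dist `"fixed"` or `"exponential"`.
#' @param reads_per_molecule Mean reads per molecule (Poisson, minimum 1).
#' @param read_len_bp Read length in bp.
#' @param base_error_rate Per-base substitution error probability in
#'   `[0, 1)`; emitted base qualities are the matching phred score.
#' @param n_molecules Number of non-recombinant molecules.
#' @param n_recombinant Number of recombinant molecules; each spans one
#'   planted crossover.
#' @param crossover_positions Optional fixed crossover positions (bp); when
#'   NULL, `n_recombinant` positions are drawn uniformly.
#' @param molecules_per_gem Molecules sharing each droplet barcode
#'   (default 1).
#' @param seed RNG seed.
#' @return A list of class `lr_sim_config`.
#' @export
sim_config <- function(genome_bp = 10e6, chrom = "chr1", het_spacing_bp = 50,
                       spacing_dist = c("fixed", "exponential"),
                       molecule_len_bp = 60000,
                       molecule_len_dist = c("fixed", "exponential"),
                       reads_per_molecule = 8, read_len_bp = 150,
                       base_error_rate = 1e-3, n_molecules = 10000,
                       n_recombinant = 500, crossover_positions = NULL,
                       molecules_per_gem = 1, seed = 1) {
  spacing_dist <- match.arg(spacing_dist)
  molecule_len_dist <- match.arg(molecule_len_dist)
  stopifnot(
    genome_bp > 0, het_spacing_bp > 0, molecule_len_bp > 0,
    molecule_len_bp < genome_bp, reads_per_molecule > 0, read_len_bp > 0,
    read_len_bp <= molecule_len_bp, base_error_rate >= 0, base_error_rate < 1,
    n_molecules >= 0, n_recombinant >= 0, molecules_per_gem >= 1
  )
  if (!is.null(crossover_positions)) {
    if (any(crossover_positions < 0 | crossover_positions >= genome_bp)) {
      stop("crossover positions must lie inside the genome [0, genome_bp)")
    }
  }
  structure(
    list(genome_bp = genome_bp, chrom = chrom,
         het_spacing_bp = het_spacing_bp, spacing_dist = spacing_dist,
         molecule_len_bp = molecule_len_bp,
         molecule_len_dist = molecule_len_dist,
         reads_per_molecule = reads_per_molecule, read_len_bp = read_len_bp,
         base_error_rate = base_error_rate, n_molecules = n_molecules,
         n_recombinant = n_recombinant,
         crossover_positions = crossover_positions,
         molecules_per_gem = molecules_per_gem, seed = seed),
    class = "lr_sim_config"
  )
}

#' Simulate a linked-read gamete pool with planted crossovers
#'
#' Two-stage generation: first non-recombinant molecules are drawn with a
#' random parental haplotype (H1 or H2); then recombinant haplotypes are
#' created by switching haplotype state at each planted crossover position
#' and one molecule is drawn spanning each crossover. The two sets are
#' merged, molecules are assigned to GEMs (`molecules_per_gem` molecules
#' share one 16-mer barcode), reads are placed uniformly within each
#' molecule, and each read reports the allele of its molecule's haplotype at
#' every covered SNP, flipped with probability `base_error_rate` (the
#' emitted base quality is the corresponding phred score, capped at Q60 for
#' error rate 0).
#'
#' @param config An [sim_config()] object.
#' @return A list of class `lr_sim` with elements `reads` (read-table
#'   tibble), `observations` (read-level allele observations), `variants`
#'   (tibble `chrom`, `pos`, `ref`, `alt`, `h1_allele` -- the planted truth
#'   phase), `truth` (list with `molecules`: per-molecule truth including
#'   `haplotype`, `crossover_pos`, `gem_id`, `barcode`; and `read_map`:
#'   read-to-truth-molecule assignment) and `config`.
#' @export
simulate_gamete_readset <- function(config) {
  stopifnot(inherits(config, "lr_sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  # heterozygous variant scaffold with random truth phase
  if (cfg$spacing_dist == "fixed") {
    vpos <- seq(cfg$het_spacing_bp, cfg$genome_bp - 1, by = cfg$het_spacing_bp)
  } else {
    gaps <- rexp(ceiling(2.5 * cfg$genome_bp / cfg$het_spacing_bp),
                 rate = 1 / cfg$het_spacing_bp)
    vpos <- floor(cumsum(gaps))
    vpos <- unique(vpos[vpos > 0 & vpos < cfg$genome_bp])
  }
  variants <- tibble(
    chrom = cfg$chrom, pos = as.numeric(vpos), ref = "A", alt = "C",
    h1_allele = sample(c(0L, 1L), length(vpos), replace = TRUE)
  )

  # molecules: stage 1 non-recombinant, stage 2 spanning planted crossovers
  draw_len <- function(n) {
    if (cfg$molecule_len_dist == "fixed") rep(cfg$molecule_len_bp, n)
    else pmax(cfg$read_len_bp, rexp(n, 1 / cfg$molecule_len_bp))
  }
  len1 <- draw_len(cfg$n_molecules)
  start1 <- floor(runif(cfg$n_molecules, 0, pmax(1, cfg$genome_bp - len1)))
  mol1 <- tibble(
    start = start1, end = pmin(start1 + len1, cfg$genome_bp),
    haplotype = sample(c("H1", "H2"), cfg$n_molecules, replace = TRUE),
    crossover_pos = NA_real_
  )
  xo <- cfg$crossover_positions %||%
    floor(runif(cfg$n_recombinant, 0.5 * cfg$molecule_len_bp,
                cfg$genome_bp - 0.5 * cfg$molecule_len_bp))
  n_rec <- length(xo)
  len2 <- draw_len(n_rec)
  lo <- pmax(0, xo - len2 + 1)
  hi <- pmin(xo, cfg$genome_bp - len2)
  start2 <- floor(runif(n_rec, lo, pmax(lo + 1, hi)))
  mol2 <- tibble(
    start = start2, end = pmin(start2 + len2, cfg$genome_bp),
    haplotype = sample(c("H1>H2", "H2>H1"), n_rec, replace = TRUE),
    crossover_pos = as.numeric(xo)
  )
  mols <- bind_rows(mol1, mol2)
  n_mol <- nrow(mols)
  if (n_mol == 0) stop("simulation has zero molecules")

  # GEM assignment: random grouping, one barcode per GEM
  gem_of <- sample(rep(seq_len(ceiling(n_mol / cfg$molecules_per_gem)),
                       each = cfg$molecules_per_gem)[seq_len(n_mol)])
  mols <- mols |>
    mutate(
      truth_mol_id = sprintf("T%06d", row_number()),
      chrom = cfg$chrom,
      gem_id = gem_of,
      barcode = index_barcode(gem_of)
    )

  # reads placed uniformly inside molecules
  n_reads <- pmax(1L, rpois(n_mol, cfg$reads_per_molecule))
  mol_rep <- rep(seq_len(n_mol), n_reads)
  rstart <- floor(mols$start[mol_rep] +
                    runif(length(mol_rep), 0,
                          pmax(1, (mols$end - mols$start)[mol_rep] - cfg$read_len_bp)))
  reads <- tibble(
    read_id = sprintf("R%07d", seq_along(mol_rep)),
    barcode = mols$barcode[mol_rep],
    chrom = cfg$chrom,
    start = rstart,
    end = rstart + cfg$read_len_bp,
    mapq = 60L,
    is_duplicate = FALSE
  )
  read_map <- tibble(read_id = reads$read_id,
                     truth_mol_id = mols$truth_mol_id[mol_rep])

  # allele observations: variants covered by each read, read off the
  # molecule's haplotype state at the variant, with base-call errors
  observations <- sim_observations(reads, mols[mol_rep, ], variants, cfg)

  out <- list(
    reads = reads,
    observations = observations,
    variants = variants,
    truth = list(
      molecules = dplyr::select(mols, "truth_mol_id", "barcode", "gem_id",
                                "chrom", "start", "end", "haplotype",
                                "crossover_pos"),
      read_map = read_map
    ),
    config = cfg
  )
  class(out) <- "lr_sim"
  out
}

# vectorized variant lookup per read; `mol_rows` is the per-read molecule row
sim_observations <- function(reads, mol_rows, variants, cfg) {
  vp <- variants$pos
  i0 <- findInterval(reads$start - 1, vp) + 1      # first variant >= start
  i1 <- findInterval(reads$end - 1, vp)            # last variant < end
  n_per <- pmax(0L, i1 - i0 + 1L)
  keep <- n_per > 0
  if (!any(keep)) {
    return(tibble(read_id = character(), chrom = character(), pos = double(),
                  allele = integer(), base_qual = integer()))
  }
  ridx <- rep(which(keep), n_per[keep])
  vidx <- sequence(n_per[keep], from = i0[keep])
  pos <- vp[vidx]
  h1a <- variants$h1_allele[vidx]
  hap <- mol_rows$haplotype[ridx]
  xo <- mol_rows$crossover_pos[ridx]
  state_h1 <- dplyr::case_when(
    hap == "H1" ~ TRUE,
    hap == "H2" ~ FALSE,
    hap == "H1>H2" ~ pos <= xo,
    hap == "H2>H1" ~ pos > xo
  )
  allele <- ifelse(state_h1, h1a, 1L - h1a)
  err <- cfg$base_error_rate > 0 &
    runif(length(allele)) < cfg$base_error_rate
  allele[err] <- 1L - allele[err]
  q <- if (cfg$base_error_rate > 0) {
    as.integer(round(-10 * log10(cfg$base_error_rate)))
  } else {
    60L
  }
  tibble(
    read_id = reads$read_id[ridx],
    chrom = cfg$chrom,
    pos = pos,
    allele = as.integer(allele),
    base_qual = q
  )
}

#' @exportS3Method base::print
print.lr_sim <- function(x, ...) {
  n_rec <- sum(!is.na(x$truth$molecules$crossover_pos))
  cat("<lr_sim> ", nrow(x$truth$molecules), " molecules (", n_rec,
      " recombinant), ", nrow(x$reads), " reads, ",
      nrow(x$variants), " heterozygous variants\n", sep = "")
  invisible(x)
}

#' Sensitivity of crossover detection against planted truth
#'
#' A planted recombinant molecule counts as recovered when a crossover call
#' carries the same barcode on the same chromosome and its interval contains
#' the planted position (with one molecule per GEM the barcode identifies
#' the molecule uniquely).
#'
#' @param truth The `truth` element of an [simulate_gamete_readset()] result
#'   (or the whole `lr_sim` object).
#' @param crossovers Crossover calls from [call_crossovers()].
#' @return A list with `sensitivity`, `n_planted`, `n_recovered`.
#' @export
evaluate_sensitivity <- function(truth, crossovers) {
  if (inherits(truth, "lr_sim")) truth <- truth$truth
  planted <- filter(truth$molecules, !is.na(.data$crossover_pos))
  n_planted <- nrow(planted)
  if (n_planted == 0) {
    return(list(sensitivity = NA_real_, n_planted = 0L, n_recovered = 0L))
  }
  hit <- planted |>
    left_join(
      dplyr::select(crossovers, "barcode", "chrom", "interval_start",
                    "interval_end"),
      by = c("barcode", "chrom"), relationship = "many-to-many"
    ) |>
    mutate(match = !is.na(.data$interval_start) &
             .data$crossover_pos >= .data$interval_start &
             .data$crossover_pos <= .data$interval_end) |>
    group_by(.data$truth_mol_id) |>
    summarise(recovered = any(.data$match), .groups = "drop")
  n_rec <- sum(hit$recovered)
  list(sensitivity = n_rec / n_planted, n_planted = n_planted,
       n_recovered = as.integer(n_rec))
}

#' Summarise false-positive crossover calls per genomic window
#'
#' For a run whose truth contains no planted crossovers every call is a
#' false positive. Calls are binned into windows (midpoint rule) and the
#' histogram of per-window FP counts is summarised.
#'
#' @param crossovers Crossover calls from [call_crossovers()].
#' @param chrom_lengths Tibble `chrom`, `length`.
#' @param window_bp Window width (default 100 kb).
#' @return A list of class `lr_fp_summary`: `histogram` (tibble `n_fp`,
#'   `n_windows`), `n_windows`, `pct_windows_with_fp`, `pct_windows_fp_free`.
#' @export
evaluate_false_positives <- function(crossovers, chrom_lengths,
                                     window_bp = 100000) {
  check_chrom_lengths(chrom_lengths)
  wins <- purrr::map2_dfr(chrom_lengths$chrom, chrom_lengths$length,
                          ~ tile_windows(.x, .y, window_bp))
  mids <- (crossovers$interval_start + crossovers$interval_end) / 2
  counts <- count_in_windows(wins, crossovers$chrom, mids, mids)
  hist <- tibble(n_fp = sort(unique(c(0L, counts)))) |>
    mutate(n_windows = vapply(.data$n_fp, function(k) sum(counts == k),
                              integer(1)))
  fp_window_summary(hist)
}

#' False-positive window arithmetic from a count histogram
#'
#' Computes the share of windows containing at least one false-positive
#' molecule from a histogram of per-window FP counts, e.g. one published for
#' a genome split into fixed windows.
#'
#' @param histogram Tibble with columns `n_fp` (FP calls per window) and
#'   `n_windows` (number of windows with that count).
#' @return A list of class `lr_fp_summary` (see
#'   [evaluate_false_positives()]).
#' @examples
#' fp_window_summary(tibble::tibble(n_fp = 0:3,
#'                                  n_windows = c(25889, 1335, 44, 1)))
#' @export
fp_window_summary <- function(histogram) {
  stopifnot(all(c("n_fp", "n_windows") %in% names(histogram)))
  total <- sum(histogram$n_windows)
  with_fp <- sum(histogram$n_windows[histogram$n_fp > 0])
  structure(
    list(histogram = as_tibble(histogram), n_windows = total,
         pct_windows_with_fp = 100 * with_fp / total,
         pct_windows_fp_free = 100 * (total - with_fp) / total),
    class = "lr_fp_summary"
  )
}

#' @exportS3Method base::print
print.lr_fp_summary <- function(x, ...) {
  cat("<lr_fp_summary> ", x$n_windows, " windows; ",
      sprintf("%.2f%%", x$pct_windows_with_fp), " contain a false positive\n",
      sep = "")
  invisible(x)
}
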