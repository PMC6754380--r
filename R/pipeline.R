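#' End-to-end crossover detection from screened reads
#'
#' Runs the full molecule-phasing pipeline: molecule reconstruction and
#' coverage filtering, allele-matrix construction, variant phasing, a first
#' round of molecule scoring, removal of variants with unbalanced molecule
#' support, re-scoring on the cleaned variant set, masking of
#' haplotype-unbalanced windows, and crossover calling.
#'
#' @param reads Screened read tibble (see [screen_reads()] /
#'   [load_barcoded_reads()]).
#' @param observations Read-level allele observations at filtered
#'   heterozygous variants.
#' @param molecule_params A [molecule_params()] object.
#' @param prior_mix,call_threshold Passed to [score_molecules()].
#' @param balance_min_frac,balance_min_count,balance_coverage_sd Passed to
#'   [filter_variants_by_molecule_balance()].
#' @param mask_window_bp,mask_min_ratio Passed to
#'   [haplotype_balance_mask()].
#' @param min_side_variants,min_side_read_frac Passed to
#'   [call_crossovers()].
#' @param phase_seed Seed for [phase_variants()].
#' @param chrom_lengths Optional tibble `chrom`, `length`.
#' @return An object of class `lr_result`: list with `molecules` (filtered
#'   molecule table), `phase` (`lr_phase` after balance filtering), `calls`
#'   (per-molecule scores), `crossovers` (called events), `mask` (window
#'   mask), `dropped_molecules`, and parameters. Methods:
#'   [tidy.lr_result()], [glance.lr_result()], [autoplot.lr_result()].
#' @export
detect_recombinant_molecules <- function(reads, observations,
                                         molecule_params = linkrec::molecule_params(),
                                         prior_mix = 3.3e-4,
                                         call_threshold = 0.95,
                                         balance_min_frac = 0.25,
                                         balance_min_count = 4,
                                         balance_coverage_sd = 3,
                                         mask_window_bp = 100000,
                                         mask_min_ratio = 0.3,
                                         min_side_variants = 3,
                                         min_side_read_frac = 0.7,
                                         phase_seed = 1729,
                                         chrom_lengths = NULL) {
  assigned <- build_molecules(reads, molecule_params)
  mol_all <- molecule_table(assigned)
  mol_filtered <- filter_molecules(mol_all, molecule_params)
  kept_mols <- filter(mol_filtered, .data$pass)
  assigned_kept <- dplyr::semi_join(assigned, kept_mols, by = "molecule_id")

  amat <- allele_matrix(assigned_kept, observations)
  phase <- phase_variants(amat, seed = phase_seed)

  calls1 <- score_molecules(amat, phase, prior_mix = prior_mix,
                            call_threshold = call_threshold)
  phase2 <- filter_variants_by_molecule_balance(
    phase, amat, min_frac = balance_min_frac, min_count = balance_min_count,
    coverage_sd = balance_coverage_sd
  )
  calls <- score_molecules(amat, phase2, prior_mix = prior_mix,
                           call_threshold = call_threshold)
  mask <- haplotype_balance_mask(calls, kept_mols,
                                 window_bp = mask_window_bp,
                                 min_ratio = mask_min_ratio,
                                 chrom_lengths = chrom_lengths)
  crossovers <- call_crossovers(calls, amat, phase2, assigned_kept,
                                observations, mask = mask,
                                min_side_variants = min_side_variants,
                                min_side_read_frac = min_side_read_frac)
  structure(
    list(
      molecules = kept_mols,
      dropped_molecules = filter(mol_filtered, !.data$pass),
      phase = phase2,
      first_pass_calls = calls1,
      calls = calls,
      mask = mask,
      crossovers = crossovers,
      params = list(
        molecule_params = molecule_params, prior_mix = prior_mix,
        call_threshold = call_threshold,
        balance_min_frac = balance_min_frac,
        balance_min_count = balance_min_count,
        balance_coverage_sd = balance_coverage_sd,
        mask_window_bp = mask_window_bp, mask_min_ratio = mask_min_ratio,
        min_side_variants = min_side_variants,
        min_side_read_frac = min_side_read_frac, phase_seed = phase_seed
      )
    ),
    class = "lr_result"
  )
}

#' @exportS3Method base::print
print.lr_result <- function(x, ...) {
  cls <- table(x$calls$class)
  cat("<lr_result> ", nrow(x$molecules), " molecules (",
      nrow(x$dropped_molecules), " dropped); classes: ",
      paste(names(cls), as.integer(cls), sep = "=", collapse = ", "),
      "; ", nrow(x$crossovers), " crossover(s) called\n", sep = "")
  invisible(x)
}

#' Tidy per-variant phasing results
#'
#' @param x An `lr_phase` object.
#' @param ... Unused.
#' @return The per-variant tibble (`chrom`, `pos`, `h1_allele`, `block_id`,
#'   molecule counts).
#' @export
tidy.lr_phase <- function(x, ...) x$variants

#' One-row summary of a phasing
#'
#' @param x An `lr_phase` object.
#' @param ... Unused.
#' @return A one-row tibble with variant/block/molecule counts and the MEC
#'   cost.
#' @export
glance.lr_phase <- function(x, ...) {
  tibble(
    n_variants = nrow(x$variants),
    n_blocks = x$n_blocks,
    n_molecules = x$n_molecules,
    mec_cost = x$mec_cost
  )
}

#' Tidy called crossovers
#'
#' @param x An `lr_result` object.
#' @param ... Unused.
#' @return The crossover-event tibble.
#' @export
tidy.lr_result <- function(x, ...) x$crossovers

#' One-row summary of a pipeline run
#'
#' @param x An `lr_result` object.
#' @param ... Unused.
#' @return A one-row tibble with molecule/class/crossover counts, the median
#'   crossover resolution and the mean call probability.
#' @export
glance.lr_result <- function(x, ...) {
  tibble(
    n_molecules = nrow(x$molecules),
    n_h1 = sum(x$calls$class == "H1"),
    n_h2 = sum(x$calls$class == "H2"),
    n_recombinant = sum(x$calls$class == "RECOMBINANT"),
    n_ambiguous = sum(x$calls$class == "AMBIGUOUS"),
    n_excluded = sum(x$calls$class == "EXCLUDED"),
    n_crossovers = nrow(x$crossovers),
    median_resolution_bp = stats::median(x$crossovers$resolution_bp),
    mean_probability = mean(x$crossovers$probability)
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
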