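#' Molecule-reconstruction parameters
#'
#' Controls how same-barcode reads are grouped into high-molecular-weight
#' (HMW) molecules and which reconstructed molecules are retained. The gap
#' and length caps guard against barcode collision (two molecules sharing a
#' droplet barcode from nearby genomic regions being fused into a spurious
#' "recombinant-like" molecule); suitable values depend on the library
#' construction, so all are exposed.
#'
#' @param max_read_gap Maximum distance in bp between the starts of two
#'   consecutive reads of one molecule (default 50 kb).
#' @param max_molecule_length Maximum molecule span in bp (default 200 kb).
#' @param min_reads Minimum reads per retained molecule (default 6; molecules
#'   below this are dropped as extreme-low coverage).
#' @param max_reads Maximum reads per retained molecule. The default `NULL`
#'   uses the per-dataset 99.5th percentile of reads-per-molecule as the
#'   extreme-high cutoff.
#' @return A list of class `lr_molecule_params`.
#' @export
molecule_params <- function(max_read_gap = 50000, max_molecule_length = 200000,
                            min_reads = 6, max_reads = NULL) {
  stopifnot(max_read_gap <= max_molecule_length,
            is.null(max_reads) || min_reads <= max_reads)
  structure(
    list(max_read_gap = max_read_gap,
         max_molecule_length = max_molecule_length,
         min_reads = min_reads, max_reads = max_reads),
    class = "lr_molecule_params"
  )
}

#' Group barcoded reads into molecules
#'
#' Within each (barcode, chromosome) group, reads sorted by start (ties broken
#' by `read_id`) are scanned left to right and a new molecule is opened
#' whenever the gap to the previous read exceeds `max_read_gap` or adding the
#' read would push the molecule span over `max_molecule_length`. Every read is
#' assigned to exactly one molecule; the result is independent of the input
#' row order.
#'
#' @param reads Screened read tibble (see [screen_reads()]).
#' @param params A [molecule_params()] object.
#' @return The read tibble with an added `molecule_id` column, sorted by
#'   molecule. Use [molecule_table()] for the per-molecule summary.
#' @examples
#' reads <- tibble::tibble(
#'   read_id = c("r1", "r2"), barcode = strrep("A", 16), chrom = "chr1",
#'   start = c(0, 30000), end = c(150, 30150), mapq = 60L, is_duplicate = FALSE
#' )
#' build_molecules(reads)  # one molecule spanning both reads
#' @export
build_molecules <- function(reads, params = molecule_params()) {
  validate_reads(reads)
  stopifnot(inherits(params, "lr_molecule_params"))
  if (nrow(reads) == 0) {
    return(mutate(as_tibble(reads), molecule_id = character()))
  }
  reads <- arrange(as_tibble(reads), .data$barcode, .data$chrom, .data$start,
                   .data$read_id)
  grp <- paste(reads$barcode, reads$chrom, sep = "\r")
  new_group <- grp != dplyr::lag(grp, default = "\r\r")

  # Greedy split: sequential scan because the span cap depends on the current
  # molecule's own start.
  n <- nrow(reads)
  split_here <- new_group
  gap_break <- c(TRUE, reads$start[-1] - reads$start[-n] > params$max_read_gap)
  mol_of <- integer(n)
  cur <- 0L
  cur_start <- -Inf
  for (i in seq_len(n)) {
    too_long <- reads$end[i] - cur_start > params$max_molecule_length
    if (new_group[i] || gap_break[i] || too_long) {
      cur <- cur + 1L
      cur_start <- reads$start[i]
    }
    mol_of[i] <- cur
  }
  reads$molecule_id <- sprintf("M%06d", mol_of)
  reads
}

#' Summarise reconstructed molecules
#'
#' @param assigned_reads Output of [build_molecules()].
#' @return A tibble with one row per molecule: `molecule_id`, `barcode`,
#'   `chrom`, `start`, `end` (span of member reads, 0-based half-open) and
#'   `n_reads`.
#' @export
molecule_table <- function(assigned_reads) {
  stopifnot("molecule_id" %in% names(assigned_reads))
  assigned_reads |>
    group_by(.data$molecule_id) |>
    summarise(
      barcode = first(.data$barcode),
      chrom = first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      n_reads = dplyr::n(),
      .groups = "drop"
    )
}

#' Filter molecules by read coverage
#'
#' Drops molecules with extreme low coverage (`n_reads < min_reads`, default
#' under 6 reads) or extreme high coverage (`n_reads` above `max_reads`, which
#' defaults to the dataset's 99.5th percentile -- a guard against collapsed
#' repeats and heavy barcode collision).
#'
#' @param molecules Output of [molecule_table()].
#' @param params A [molecule_params()] object.
#' @return The molecule tibble with added `pass` and `fail_reason`
#'   (`"low_coverage"` / `"high_coverage"`) columns.
#' @export
filter_molecules <- function(molecules, params = molecule_params()) {
  stopifnot(inherits(params, "lr_molecule_params"))
  max_reads <- params$max_reads %||%
    unname(quantile(molecules$n_reads, 0.995, type = 1, names = FALSE))
  if (nrow(molecules) == 0) max_reads <- Inf
  mutate(
    molecules,
    fail_reason = dplyr::case_when(
      .data$n_reads < params$min_reads ~ "low_coverage",
      .data$n_reads > max_reads ~ "high_coverage",
      TRUE ~ NA_character_
    ),
    pass = is.na(.data$fail_reason)
  )
}

#' Write a molecule report
#'
#' Emits the per-molecule table (chromosome, span, barcode, read count) as
#' BED or TSV via [write_intervals()].
#'
#' @param molecules Output of [molecule_table()] or [filter_molecules()].
#' @param path Output path (`.bed` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_molecule_report <- function(molecules, path) {
  cols <- intersect(c("chrom", "start", "end", "molecule_id", "barcode", "n_reads"),
                    names(molecules))
  write_intervals(dplyr::select(molecules, dplyr::all_of(cols)), path)
}
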