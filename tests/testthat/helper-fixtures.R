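# Programmatic fixtures: tiny read tables, VCF and SAM text written at test
# time (no stored binary data).

bc <- function(letter) strrep(letter, 16)

make_reads <- function(starts, barcode = bc("A"), chrom = "chr1",
                       read_len = 150, mapq = 60L, dup = FALSE,
                       ids = NULL) {
  n <- length(starts)
  tibble::tibble(
    read_id = ids %||% sprintf("r%03d", seq_len(n)),
    barcode = rep_len(barcode, n),
    chrom = rep_len(chrom, n),
    start = as.numeric(starts),
    end = as.numeric(starts) + read_len,
    mapq = rep_len(as.integer(mapq), n),
    is_duplicate = rep_len(dup, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small bcftools-flavoured VCF written as text.
write_test_vcf <- function(path, records) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##INFO=<ID=MQB,Number=1,Type=Float,Description=\"Mann-Whitney U test of Mapping Quality Bias\">",
    "##INFO=<ID=BQB,Number=1,Type=Float,Description=\"Mann-Whitney U test of Base Quality Bias\">",
    "##INFO=<ID=MQSB,Number=1,Type=Float,Description=\"Mann-Whitney U test of Mapping Quality vs Strand Bias\">",
    "##INFO=<ID=RPB,Number=1,Type=Float,Description=\"Mann-Whitney U test of Read Position Bias\">",
    "##INFO=<ID=IMF,Number=1,Type=Float,Description=\"Maximum fraction of reads supporting an indel\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"
  )
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(pos, ref = "A", alt = "C", qual = 150, gt = "0/1",
                       gq = 40, mqb = 0.5, bqb = 0.5, mqsb = 0.9, rpb = 0.5,
                       imf = NULL, dp = 50) {
  info <- c(
    sprintf("MQB=%g", mqb), sprintf("BQB=%g", bqb), sprintf("MQSB=%g", mqsb),
    sprintf("RPB=%g", rpb),
    if (!is.null(imf)) sprintf("IMF=%g", imf),
    sprintf("DP=%d", dp)
  )
  sprintf("chr1\t%d\t.\t%s\t%s\t%g\t.\t%s\tGT:GQ\t%s:%d",
          pos, ref, alt, qual, paste(info, collapse = ";"), gt, gq)
}

# A coordinate-sorted SAM with BX tags, converted to BAM via Rsamtools.
write_test_bam <- function(dir, sorted = TRUE) {
  sam <- file.path(dir, "test.sam")
  so <- if (sorted) "coordinate" else "unsorted"
  lines <- c(
    sprintf("@HD\tVN:1.6\tSO:%s", so),
    "@SQ\tSN:chr1\tLN:100000",
    # pos are 1-based in SAM; 30M reads
    paste0("q1\t0\tchr1\t101\t60\t30M\t*\t0\t0\t",
           strrep("A", 30), "\t", strrep("I", 30), "\tBX:Z:", bc("A"), "-1"),
    paste0("q2\t0\tchr1\t111\t60\t30M\t*\t0\t0\t",
           paste0(strrep("A", 10), "C", strrep("A", 19)), "\t",
           strrep("I", 30), "\tBX:Z:", bc("A"), "-1"),
    paste0("q3\t1024\tchr1\t121\t60\t30M\t*\t0\t0\t",
           strrep("A", 30), "\t", strrep("I", 30), "\tBX:Z:", bc("C"), "-1"),
    paste0("q4\t0\tchr1\t131\t60\t30M\t*\t0\t0\t",
           strrep("A", 30), "\t", strrep("I", 30))   # no BX tag
  )
  writeLines(lines, sam)
  Rsamtools::asBam(sam, file.path(dir, "test"), overwrite = TRUE,
                   indexDestination = FALSE)
}

# Shared small simulation for pipeline-level tests: dense reads so that
# essentially every planted crossover is flanked by >= 3 observed variants.
dense_sim <- function(seed, n_molecules = 800, n_recombinant = 40,
                      genome_bp = 2e6, base_error_rate = 0,
                      molecules_per_gem = 1, reads_per_molecule = 40) {
  simulate_gamete_readset(sim_config(
    genome_bp = genome_bp, het_spacing_bp = 50,
    reads_per_molecule = reads_per_molecule, n_molecules = n_molecules,
    n_recombinant = n_recombinant, base_error_rate = base_error_rate,
    molecules_per_gem = molecules_per_gem, seed = seed
  ))
}

run_pipeline <- function(sim, ...) {
  detect_recombinant_molecules(sim$reads, sim$observations, ...)
}

# Truth-side detectability: planted recombinants whose raw observations give
# at least `k` covered variants strictly on each side of the crossover.
detectable_planted <- function(sim, k = 6) {
  rm <- sim$truth$read_map
  obs <- dplyr::inner_join(sim$observations, rm, by = "read_id")
  planted <- dplyr::filter(sim$truth$molecules, !is.na(crossover_pos))
  counts <- obs |>
    dplyr::inner_join(
      dplyr::select(planted, truth_mol_id, crossover_pos),
      by = "truth_mol_id"
    ) |>
    dplyr::distinct(truth_mol_id, pos, crossover_pos) |>
    dplyr::group_by(truth_mol_id) |>
    dplyr::summarise(
      n_left = sum(pos <= crossover_pos),
      n_right = sum(pos > crossover_pos),
      .groups = "drop"
    )
  dplyr::semi_join(
    planted,
    dplyr::filter(counts, n_left >= k, n_right >= k),
    by = "truth_mol_id"
  )
}

# deterministic distinct barcodes for fixture reads
index_barcode_t <- function(i) {
  bases <- c("A", "C", "G", "T")
  paste(bases[((i %/% 4^(0:15)) %% 4) + 1], collapse = "")
}

toy_fp_calls <- function(mids) {
  tibble::tibble(
    molecule_id = sprintf("f%02d", seq_along(mids)), barcode = bc("A"),
    chrom = "chr1", interval_start = mids - 100, interval_end = mids + 100
  )
}
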