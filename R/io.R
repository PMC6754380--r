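#' Read a barcoded read table
#'
#' Reads the plain-text (TSV) read-table dialect used throughout the package:
#' one row per aligned read with columns `read_id`, `barcode` (16-nucleotide
#' droplet barcode), `chrom`, `start`, `end` (0-based, half-open), `mapq` and
#' `is_duplicate`. This dialect carries the same information as a
#' coordinate-sorted BAM with a `BX` barcode tag and is what the simulator
#' emits, so the whole pipeline can run without alignment binaries.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble of reads.
#' @seealso [load_barcoded_reads()] for screening, [read_allele_observations()]
#' @export
read_read_table <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      read_id = readr::col_character(),
      barcode = readr::col_character(),
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      mapq = readr::col_integer(),
      is_duplicate = readr::col_logical()
    )
  )
  validate_reads(out)
  out
}

#' Write a barcoded read table
#'
#' @param reads Tibble of reads (see [read_read_table()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_read_table <- function(reads, path) {
  validate_reads(reads)
  readr::write_tsv(reads, path)
  invisible(path)
}

#' Read per-read allele observations
#'
#' The observation table links reads to the heterozygous variants they cover:
#' columns `read_id`, `chrom`, `pos` (0-based variant position), `allele`
#' (0 = reference-style allele, 1 = alternate) and `base_qual` (phred).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble of allele observations.
#' @export
read_allele_observations <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      read_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      allele = readr::col_integer(),
      base_qual = readr::col_integer()
    )
  )
}

#' Write per-read allele observations
#'
#' @param observations Tibble as returned by [read_allele_observations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_observations <- function(observations, path) {
  readr::write_tsv(observations, path)
  invisible(path)
}

validate_reads <- function(reads) {
  need <- c("read_id", "barcode", "chrom", "start", "end", "mapq", "is_duplicate")
  miss <- setdiff(need, names(reads))
  if (length(miss) > 0) {
    stop("read table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(reads$start >= reads$end)) stop("read table has start >= end")
  invisible(reads)
}

#' Screen barcoded reads by whitelist, duplicate flag and mapping quality
#'
#' Applies the read-level filters used before molecule reconstruction: the
#' barcode must match the whitelist (when one is supplied), the read must not
#' be flagged as a PCR/optical duplicate, and its mapping quality must reach
#' `min_mapq`. The retained set is independent of input order.
#'
#' @param reads Tibble of reads (see [read_read_table()]).
#' @param whitelist Character vector of accepted 16-mer barcodes. An empty
#'   vector (the default) accepts every syntactically valid barcode.
#' @param min_mapq Minimum mapping quality; defaults to 30, a conventional
#'   proxy for uniquely mapped reads.
#' @return The retained reads, with an attribute `"screen_counts"` (a tibble
#'   of per-rule exclusion counts, retrievable with [screen_summary()]).
#' @examples
#' reads <- tibble::tibble(
#'   read_id = c("r1", "r2"), barcode = strrep(c("A", "C"), 16),
#'   chrom = "chr1", start = c(0, 100), end = c(150, 250),
#'   mapq = c(60L, 10L), is_duplicate = FALSE
#' )
#' screen_reads(reads, min_mapq = 30)
#' @export
screen_reads <- function(reads, whitelist = character(), min_mapq = 30) {
  validate_reads(reads)
  bad_barcode <- !grepl("^[ACGT]{16}$", reads$barcode)
  off_list <- if (length(whitelist) > 0) !(reads$barcode %in% whitelist) else rep(FALSE, nrow(reads))
  dup <- reads$is_duplicate %in% TRUE
  lowq <- reads$mapq < min_mapq
  drop_reason <- dplyr::case_when(
    bad_barcode ~ "invalid_barcode",
    off_list ~ "not_whitelisted",
    dup ~ "duplicate",
    lowq ~ "low_mapq",
    TRUE ~ NA_character_
  )
  kept <- reads[is.na(drop_reason), , drop = FALSE]
  counts <- tibble(reason = drop_reason[!is.na(drop_reason)]) |>
    dplyr::count(.data$reason, name = "n_reads")
  attr(kept, "screen_counts") <- counts
  kept
}

#' Summarise read-screening exclusions
#'
#' @param reads A tibble returned by [screen_reads()] or [load_barcoded_reads()].
#' @return A tibble with columns `reason` and `n_reads`.
#' @export
screen_summary <- function(reads) {
  attr(reads, "screen_counts") %||% tibble(reason = character(), n_reads = integer())
}

#' Load and screen barcoded reads from BAM or the read-table dialect
#'
#' Dispatches on the file extension: `.bam` is read through Rsamtools (the
#' barcode is taken from the `BX` tag, any `-1`-style suffix stripped;
#' reads without the tag are skipped and counted), anything else through
#' [read_read_table()]. The screening rules of [screen_reads()] are then
#' applied. BAM input must be coordinate-sorted (`SO:coordinate` in the
#' header); when `variants` is supplied, allele observations are extracted for
#' gapless alignments overlapping the variant positions.
#'
#' @param source Path to a `.bam` file or a read-table TSV.
#' @param whitelist,min_mapq Passed to [screen_reads()].
#' @param variants Optional variant tibble (columns `chrom`, `pos`, `ref`,
#'   `alt`) used to populate allele observations from BAM input.
#' @return A list of class `lr_readset` with elements `reads` (screened
#'   tibble), `observations` (tibble, possibly empty) and `screen`
#'   (exclusion counts).
#' @export
load_barcoded_reads <- function(source, whitelist = character(), min_mapq = 30,
                                variants = NULL) {
  if (grepl("\\.bam$", source, ignore.case = TRUE)) {
    parsed <- read_bam_reads(source, variants = variants)
    reads <- parsed$reads
    observations <- parsed$observations
    pre_counts <- parsed$skipped
  } else {
    reads <- read_read_table(source)
    obs_path <- sub("\\.tsv$", ".obs.tsv", source)
    observations <- if (file.exists(obs_path) && obs_path != source) {
      read_allele_observations(obs_path)
    } else {
      tibble(read_id = character(), chrom = character(), pos = double(),
             allele = integer(), base_qual = integer())
    }
    pre_counts <- tibble(reason = character(), n_reads = integer())
  }
  kept <- screen_reads(reads, whitelist = whitelist, min_mapq = min_mapq)
  observations <- dplyr::semi_join(observations, kept, by = "read_id")
  out <- list(
    reads = kept,
    observations = observations,
    screen = dplyr::bind_rows(pre_counts, screen_summary(kept))
  )
  class(out) <- "lr_readset"
  out
}

#' @exportS3Method base::print
print.lr_readset <- function(x, ...) {
  cat("<lr_readset> ", nrow(x$reads), " reads, ",
      nrow(x$observations), " allele observations\n", sep = "")
  if (nrow(x$screen) > 0) {
    cat("excluded:\n")
    print(x$screen)
  }
  invisible(x)
}

# BAM ingest via Rsamtools. Allele observations are extracted only for
# alignments whose CIGAR is a single match run (no indels/clips); other reads
# still contribute to molecule reconstruction.
read_bam_reads <- function(path, variants = NULL) {
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$text
  so <- unlist(hdr[names(hdr) == "@HD"])
  if (!any(grepl("^SO:coordinate$", so))) {
    stop("BAM input must be coordinate-sorted (SO:coordinate): ", path)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "mapq", "flag", "seq", "qual"),
    tag = "BX",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  bx <- b$tag$BX
  if (is.null(bx)) bx <- rep(NA_character_, length(b$qname))
  has_bx <- !is.na(bx)
  n_no_tag <- sum(!has_bx)
  cig_width <- cigar_ref_width(b$cigar)
  reads <- tibble(
    read_id = paste0(b$qname, "/", seq_along(b$qname)),
    barcode = sub("-[0-9]+$", "", bx),
    chrom = as.character(b$rname),
    start = b$pos - 1,
    end = b$pos - 1 + cig_width,
    mapq = as.integer(b$mapq),
    is_duplicate = bitwAnd(b$flag, 1024L) > 0
  )[has_bx, , drop = FALSE]
  observations <- tibble(read_id = character(), chrom = character(),
                         pos = double(), allele = integer(),
                         base_qual = integer())
  if (!is.null(variants) && nrow(variants) > 0) {
    gapless <- grepl("^[0-9]+M$", b$cigar) & has_bx
    idx <- which(gapless)
    if (length(idx) > 0) {
      seqs <- as.character(b$seq[idx])
      quals <- methods::as(b$qual[idx], "IntegerList")
      sub <- reads[match(idx, which(has_bx)), , drop = FALSE]
      obs <- purrr::map_dfr(seq_along(idx), function(k) {
        v <- variants[variants$chrom == sub$chrom[k] &
                        variants$pos >= sub$start[k] &
                        variants$pos < sub$end[k], , drop = FALSE]
        if (nrow(v) == 0) return(NULL)
        off <- v$pos - sub$start[k] + 1
        base <- substring(seqs[k], off, off)
        allele <- ifelse(base == v$ref, 0L, ifelse(base == v$alt, 1L, NA_integer_))
        tibble(read_id = sub$read_id[k], chrom = v$chrom, pos = v$pos,
               allele = allele, base_qual = as.integer(quals[[k]][off]))
      })
      observations <- dplyr::filter(obs, !is.na(.data$allele))
    }
  }
  list(
    reads = reads,
    observations = observations,
    skipped = if (n_no_tag > 0) {
      tibble(reason = "missing_barcode_tag", n_reads = n_no_tag)
    } else {
      tibble(reason = character(), n_reads = integer())
    }
  )
}

cigar_ref_width <- function(cigar) {
  ops <- stringr::str_match_all(cigar, "([0-9]+)([MIDNSHP=X])")
  vapply(ops, function(m) {
    if (nrow(m) == 0) return(0)
    w <- as.numeric(m[, 2])
    sum(w[m[, 3] %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
}

#' Write genomic intervals as BED or TSV
#'
#' BED output is 0-based half-open with up to one payload name column; TSV
#' output keeps every column. Both round-trip losslessly through
#' [read_intervals()]. Records with `start >= end` are rejected.
#'
#' @param records Tibble with `chrom`, `start`, `end` and optional payload
#'   columns.
#' @param path Output path.
#' @param format `"bed"` or `"tsv"` (default guessed from the extension,
#'   falling back to TSV).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(records, path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(records)))
  if (any(records$start >= records$end)) {
    stop("interval records with start >= end are not writable")
  }
  if (format == "bed") {
    gr <- GenomicRanges::GRanges(
      records$chrom,
      IRanges::IRanges(start = records$start + 1, end = records$end)
    )
    extra <- setdiff(names(records), c("chrom", "start", "end"))
    if (length(extra) > 0) {
      gr$name <- as.character(records[[extra[1]]])
    }
    rtracklayer::export.bed(gr, path)
  } else {
    readr::write_tsv(records, path)
  }
  invisible(path)
}

#' Read genomic intervals from BED or TSV
#'
#' @param path Input path.
#' @param format `"bed"` or `"tsv"`; guessed from the extension by default.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open) and any
#'   payload columns.
#' @export
read_intervals <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    gr <- rtracklayer::import.bed(path)
    out <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr)
    )
    if (!is.null(gr$name)) out$name <- gr$name
    out
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
}

#' Merge a set of feature intervals
#'
#' Collapses overlapping or bookended intervals per chromosome; the result is
#' the canonical non-overlapping form expected by [feature_proximity_test()].
#'
#' @param features Tibble with `chrom`, `start`, `end`.
#' @return A tibble of merged intervals sorted by chromosome and start.
#' @export
merge_intervals <- function(features) {
  stopifnot(all(c("chrom", "start", "end") %in% names(features)))
  if (nrow(features) == 0) return(dplyr::select(features, "chrom", "start", "end"))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start + 1, features$end)
  ))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  ) |> arrange(.data$chrom, .data$start)
}
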