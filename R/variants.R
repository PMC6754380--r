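#' Hard-filter thresholds for candidate variants
#'
#' Bundles the thresholds of the heterozygous-variant hard filter. Every
#' comparison is applied strictly in the rejecting direction, i.e. a record is
#' rejected when `MQB < mqb_min`, so a value exactly at a threshold passes.
#' The defaults are the filter used for linked-read gamete data called with
#' samtools/bcftools-style annotations.
#'
#' @param mqb_min,bqb_min,rpb_min Minimum Mann-Whitney U bias probabilities
#'   for mapping-quality, base-quality and read-position bias (default 0.4).
#' @param mqsb_min Minimum mapping-quality versus strand bias (default 0.8).
#' @param imf_low,imf_high Rejection band for the fraction of reads supporting
#'   an indel: records annotated with `IMF < imf_low` or `IMF > imf_high` are
#'   rejected (defaults 0.1 and 0.9).
#' @param dp_min,dp_max Read-depth bounds (defaults 5 and 220).
#' @param gq_min Minimum genotype quality (default 30).
#' @param qual_min Minimum variant quality (default 100).
#' @return A list of class `lr_thresholds`.
#' @export
filter_thresholds <- function(mqb_min = 0.4, bqb_min = 0.4, mqsb_min = 0.8,
                              rpb_min = 0.4, imf_low = 0.1, imf_high = 0.9,
                              dp_min = 5, dp_max = 220, gq_min = 30,
                              qual_min = 100) {
  stopifnot(dp_min < dp_max, imf_low < imf_high)
  structure(
    list(mqb_min = mqb_min, bqb_min = bqb_min, mqsb_min = mqsb_min,
         rpb_min = rpb_min, imf_low = imf_low, imf_high = imf_high,
         dp_min = dp_min, dp_max = dp_max, gq_min = gq_min,
         qual_min = qual_min),
    class = "lr_thresholds"
  )
}

het_genotypes <- c("0/1", "1/0", "0|1", "1|0")
hom_genotypes <- c("0/0", "1/1", "0|0", "1|1")

#' Apply the heterozygous-variant hard filter
#'
#' Retains biallelic heterozygous records passing every quality rule; each
#' rejected record is labelled with the first failing rule in a fixed order
#' (`ploidy`, `multiallelic`, `genotype`, `MQB`, `BQB`, `MQSB`, `RPB`, `IMF`,
#' `DP`, `GQ`, `QUAL`). A missing (NA) annotation passes that sub-filter; the
#' number of such pass-by-absence events per annotation is attached as the
#' `"missing_annotations"` attribute.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `genotype` and (optionally, NA allowed) `mqb`, `bqb`, `mqsb`, `rpb`,
#'   `imf`, `dp`, `gq`, `qual`. See [read_variants()].
#' @param thresholds A [filter_thresholds()] object.
#' @return The input tibble with added columns `pass` (logical) and
#'   `fail_reason` (NA for kept records). Kept and rejected rows partition the
#'   input.
#' @examples
#' v <- tibble::tibble(
#'   chrom = "chr1", pos = c(100, 200), ref = "A", alt = "C",
#'   genotype = c("0/1", "0/1"), mqb = 0.5, bqb = 0.5, mqsb = 0.9, rpb = 0.5,
#'   imf = NA_real_, dp = c(50, 4), gq = 40, qual = 150
#' )
#' apply_hard_filters(v)
#' @export
apply_hard_filters <- function(variants, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "lr_thresholds"))
  need <- c("chrom", "pos", "ref", "alt", "genotype")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) stop("variant table is missing: ", paste(miss, collapse = ", "))
  for (col in c("mqb", "bqb", "mqsb", "rpb", "imf", "dp", "gq", "qual")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_real_
  }
  gt <- gsub(" ", "", variants$genotype)
  n_alleles <- lengths(strsplit(gt, "[/|]"))
  multiallelic <- grepl(",", variants$alt) | grepl("[2-9]", gt)
  th <- thresholds

  fail_na <- function(x, bad) !is.na(x) & bad
  reason <- dplyr::case_when(
    is.na(gt) | n_alleles != 2 ~ "ploidy",
    multiallelic ~ "multiallelic",
    !(gt %in% het_genotypes) ~ "genotype",
    fail_na(variants$mqb, variants$mqb < th$mqb_min) ~ "MQB",
    fail_na(variants$bqb, variants$bqb < th$bqb_min) ~ "BQB",
    fail_na(variants$mqsb, variants$mqsb < th$mqsb_min) ~ "MQSB",
    fail_na(variants$rpb, variants$rpb < th$rpb_min) ~ "RPB",
    fail_na(variants$imf, variants$imf < th$imf_low | variants$imf > th$imf_high) ~ "IMF",
    fail_na(variants$dp, variants$dp < th$dp_min | variants$dp > th$dp_max) ~ "DP",
    fail_na(variants$gq, variants$gq < th$gq_min) ~ "GQ",
    fail_na(variants$qual, variants$qual < th$qual_min) ~ "QUAL",
    TRUE ~ NA_character_
  )
  out <- mutate(as_tibble(variants), pass = is.na(reason), fail_reason = reason)
  missing_counts <- purrr::map_int(
    c(mqb = "mqb", bqb = "bqb", mqsb = "mqsb", rpb = "rpb", imf = "imf",
      dp = "dp", gq = "gq", qual = "qual"),
    ~ sum(is.na(variants[[.x]]))
  )
  attr(out, "missing_annotations") <- missing_counts
  out
}

#' Read candidate variants from a VCF file
#'
#' Parses a VCF 4.x file (via vcfR) into the flat variant table consumed by
#' [apply_hard_filters()]. Positions are converted to the package's 0-based
#' convention. INFO annotations `MQB`, `BQB`, `MQSB`, `RPB`, `IMF`, `DP` and
#' the per-sample `GT`/`GQ` of the first sample are extracted; absent
#' annotations become NA.
#'
#' @param path Path to an uncompressed or gzipped VCF.
#' @return A tibble with one row per VCF record.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    if (is.null(x)) rep(NA_real_, nrow(fix)) else as.numeric(x)
  }
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT")[, 1],
                 error = function(e) rep(NA_character_, nrow(fix)))
  gq <- tryCatch(as.numeric(vcfR::extract.gt(v, element = "GQ")[, 1]),
                 error = function(e) rep(NA_real_, nrow(fix)))
  tibble(
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS) - 1,
    ref = fix$REF,
    alt = fix$ALT,
    genotype = unname(gt),
    mqb = info_num("MQB"),
    bqb = info_num("BQB"),
    mqsb = info_num("MQSB"),
    rpb = info_num("RPB"),
    imf = info_num("IMF"),
    dp = info_num("DP"),
    gq = unname(gq),
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
}

#' Write filtered variants and rejection reasons
#'
#' Writes the kept set and a rejection-reason table as TSV files.
#'
#' @param filtered Output of [apply_hard_filters()].
#' @param path Path for the kept set; the rejection table is written next to
#'   it with suffix `.rejected.tsv`.
#' @return `path`, invisibly.
#' @export
write_filtered_variants <- function(filtered, path) {
  stopifnot(all(c("pass", "fail_reason") %in% names(filtered)))
  readr::write_tsv(dplyr::select(filter(filtered, .data$pass), -"pass", -"fail_reason"), path)
  readr::write_tsv(
    dplyr::select(filter(filtered, !.data$pass), "chrom", "pos", "ref", "alt", "fail_reason"),
    sub("(\\.tsv)?$", ".rejected.tsv", path)
  )
  invisible(path)
}
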