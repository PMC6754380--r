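#' @importFrom rlang .data .env %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join inner_join anti_join bind_rows n row_number first last
#'   count distinct pull rename relocate if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile rbinom rpois runif sd setNames rexp p.adjust
#'   wilcox.test var
#' @importFrom utils head tail
NULL

# Truncate (toward zero) to `digits` decimal places; the convention used for
# printed map-interval rates (e.g. 1.7857 -> 1.78).
trunc_decimal <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

# Truncate to `digits` significant figures (3.372e-4 -> 3.3e-4 for digits = 2).
trunc_signif <- function(x, digits = 2) {
  ifelse(x == 0, 0, {
    k <- floor(log10(abs(x)))
    f <- 10^(digits - 1 - k)
    trunc(x * f) / f
  })
}

# Cumulative sum restarting at each new value of an (already grouped,
# contiguous) integer id vector. Used for per-molecule likelihood scans.
grouped_cumsum <- function(x, id) {
  cs <- cumsum(x)
  firsts <- !duplicated(id)
  offset <- rep(c(0, cs[which(firsts)[-1] - 1]), times = tabulate(match(id, unique(id))))
  cs - offset
}

# Deterministic 16-mer nucleotide barcode for an integer index.
index_barcode <- function(i) {
  bases <- c("A", "C", "G", "T")
  vapply(i, function(k) {
    digits <- integer(16)
    k <- k - 1
    for (j in 16:1) {
      digits[j] <- k %% 4
      k <- k %/% 4
    }
    paste(bases[digits + 1], collapse = "")
  }, character(1))
}

# Tile [0, len) into windows of width `window_bp` advancing by `step_bp`.
tile_windows <- function(chrom, len, window_bp, step_bp = window_bp) {
  stopifnot(window_bp > 0, step_bp > 0)
  starts <- seq(0, max(0, len - 1), by = step_bp)
  tibble(
    chrom = chrom,
    start = starts,
    end = pmin(starts + window_bp, len)
  )
}

# Infer chromosome lengths from any table carrying chrom plus end (or pos).
infer_chrom_lengths <- function(...) {
  tabs <- list(...)
  out <- purrr::map(tabs, function(x) {
    if (is.null(x) || nrow(x) == 0) return(NULL)
    endcol <- intersect(c("end", "interval_end", "pos"), names(x))[1]
    if (is.na(endcol)) return(NULL)
    dplyr::summarise(dplyr::group_by(x, .data$chrom),
                     length = max(.data[[endcol]]) + 1, .groups = "drop")
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) stop("cannot infer chromosome lengths; supply `chrom_lengths`")
  dplyr::summarise(dplyr::group_by(out, .data$chrom),
                   length = max(.data$length), .groups = "drop")
}

check_chrom_lengths <- function(chrom_lengths) {
  stopifnot(is.data.frame(chrom_lengths),
            all(c("chrom", "length") %in% names(chrom_lengths)),
            all(chrom_lengths$length > 0))
  invisible(chrom_lengths)
}
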