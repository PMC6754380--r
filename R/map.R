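#' Centimorgan estimate from recombinant and total molecule counts
#'
#' One centimorgan corresponds to one crossover per hundred meiotic
#' products, so an interval's rate is estimated as
#' `100 * n_recombinant / n_total` where the counts are haplotype-switching
#' and total mapped molecules over the interval.
#'
#' @param n_recombinant Number of recombinant (haplotype-switching)
#'   molecules.
#' @param n_total Total mapped molecules.
#' @return The rate in cM (vectorized; 0 when `n_total` is 0).
#' @examples
#' cm_estimate(31, 1736)  # ~1.79 cM; prints as 1.78 when truncated to 2 dp
#' @export
cm_estimate <- function(n_recombinant, n_total) {
  ifelse(n_total > 0, 100 * n_recombinant / n_total, 0)
}

#' Expected recombinant-molecule counts for a gamete pool
#'
#' Closed-form arithmetic linking a genetic map length to the number of
#' recombinant molecules expected in linked-read data: a gamete's genome
#' shatters into `genome_bp / molecule_bp` molecules; it carries
#' `map_cM / 100` crossovers on average, so that fraction of molecules is
#' recombinant; a pool of `n_gametes` gametes is expected to contain
#' `n_gametes * map_cM / 100` recombinant molecules.
#'
#' @param map_cM Genetic map length in centimorgans (genome-wide or for one
#'   chromosome).
#' @param genome_bp Assembled genome size in bp.
#' @param molecule_bp Average HMW molecule length in bp.
#' @param n_gametes Number of gametes in the pool.
#' @return A one-row tibble with `molecules_per_gamete`,
#'   `crossovers_per_gamete`, `recombinant_frequency` and
#'   `expected_recombinants`.
#' @examples
#' expected_recombinant_stats(1630, 2.9e9, 6e4, 1700)
#' @export
expected_recombinant_stats <- function(map_cM, genome_bp, molecule_bp,
                                       n_gametes) {
  stopifnot(map_cM > 0, genome_bp > 0, molecule_bp > 0, n_gametes > 0)
  molecules_per_gamete <- genome_bp / molecule_bp
  crossovers_per_gamete <- map_cM / 100
  freq <- crossovers_per_gamete / molecules_per_gamete
  stopifnot(freq < 1)
  tibble(
    map_cM = map_cM,
    genome_bp = genome_bp,
    molecule_bp = molecule_bp,
    n_gametes = n_gametes,
    molecules_per_gamete = molecules_per_gamete,
    crossovers_per_gamete = crossovers_per_gamete,
    recombinant_frequency = freq,
    expected_recombinants = crossovers_per_gamete * n_gametes
  )
}

#' Build a windowed recombination map
#'
#' Bins crossovers (by interval midpoint) and molecules into windows and
#' estimates each window's recombination rate with [cm_estimate()]. With
#' `step_bp < window_bp` the windows slide; by default they tile. Molecules
#' are counted in every window they overlap, matching the "mapped molecules
#' in the interval" denominator used for hotspot rates; set
#' `molecule_assignment = "midpoint"` to count each molecule once.
#'
#' @param crossovers Crossover tibble from [call_crossovers()] (needs
#'   `chrom`, `interval_start`, `interval_end`).
#' @param molecules Molecule tibble from [molecule_table()].
#' @param window_bp Window width in bp (default 50 kb).
#' @param step_bp Window step in bp (default `window_bp`).
#' @param chrom_lengths Optional tibble `chrom`, `length`; inferred from the
#'   molecules otherwise.
#' @param molecule_assignment `"overlap"` (default) or `"midpoint"`.
#' @return An `lr_map` object: a tibble of windows (`chrom`, `start`, `end`,
#'   `n_crossovers`, `n_molecules`, `cM`) with the window parameters as
#'   attributes.
#' @export
build_map <- function(crossovers, molecules, window_bp = 50000,
                      step_bp = window_bp, chrom_lengths = NULL,
                      molecule_assignment = c("overlap", "midpoint")) {
  molecule_assignment <- match.arg(molecule_assignment)
  stopifnot(step_bp <= window_bp)
  chrom_lengths <- chrom_lengths %||% infer_chrom_lengths(molecules, crossovers)
  check_chrom_lengths(chrom_lengths)
  wins <- purrr::map2_dfr(chrom_lengths$chrom, chrom_lengths$length,
                          ~ tile_windows(.x, .y, window_bp, step_bp))
  xo_mid <- if (nrow(crossovers) > 0) {
    mutate(crossovers, mid = (.data$interval_start + .data$interval_end) / 2)
  } else {
    tibble(chrom = character(), mid = double())
  }
  n_xo <- count_in_windows(wins, xo_mid$chrom, xo_mid$mid, xo_mid$mid)
  if (molecule_assignment == "midpoint") {
    mol_pos <- (molecules$start + molecules$end) / 2
    n_mol <- count_in_windows(wins, molecules$chrom, mol_pos, mol_pos)
  } else {
    n_mol <- count_in_windows(wins, molecules$chrom, molecules$start,
                              molecules$end)
  }
  out <- wins |>
    mutate(
      n_crossovers = n_xo,
      n_molecules = n_mol,
      cM = cm_estimate(.data$n_crossovers, .data$n_molecules)
    )
  structure(out, class = c("lr_map", class(out)),
            window_bp = window_bp, step_bp = step_bp,
            molecule_assignment = molecule_assignment)
}

# count items whose [s, e] intersects each window (points when s == e)
count_in_windows <- function(wins, chrom, s, e) {
  if (length(chrom) == 0) return(integer(nrow(wins)))
  out <- integer(nrow(wins))
  for (ch in unique(wins$chrom)) {
    wi <- which(wins$chrom == ch)
    ii <- which(chrom == ch)
    if (length(ii) == 0) next
    out[wi] <- vapply(wi, function(w) {
      sum(s[ii] < wins$end[w] & e[ii] >= wins$start[w])
    }, integer(1))
  }
  out
}

#' Export a recombination map as bedGraph
#'
#' @param map An [build_map()] result.
#' @param path Output path.
#' @param value Column to export (default `"cM"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(map, path, value = "cM") {
  stopifnot(value %in% names(map))
  lines <- sprintf("%s\t%d\t%d\t%g", map$chrom, as.integer(map$start),
                   as.integer(map$end), map[[value]])
  writeLines(c(sprintf("track type=bedGraph name=%s", value), lines), path)
  invisible(path)
}

#' Detect recombination coldspots
#'
#' Reports maximal intervals of at least `min_len_bp` without any crossover:
#' gaps between consecutive crossover midpoints, and terminal gaps between a
#' chromosome end and the nearest crossover. A chromosome without crossovers
#' is reported whole (when long enough).
#'
#' @param crossovers Crossover tibble (`chrom`, `interval_start`,
#'   `interval_end`).
#' @param chrom_lengths Tibble with `chrom`, `length`.
#' @param min_len_bp Minimum coldspot length (default 500 kb).
#' @return A tibble of intervals `chrom`, `start`, `end`, `length_bp`.
#' @export
detect_coldspots <- function(crossovers, chrom_lengths, min_len_bp = 500000) {
  check_chrom_lengths(chrom_lengths)
  purrr::map2_dfr(chrom_lengths$chrom, chrom_lengths$length, function(ch, len) {
    mids <- sort((crossovers$interval_start + crossovers$interval_end)[
      crossovers$chrom == ch] / 2)
    bounds <- c(0, mids, len)
    tibble(chrom = ch, start = head(bounds, -1), end = tail(bounds, -1))
  }) |>
    mutate(length_bp = .data$end - .data$start) |>
    filter(.data$length_bp >= min_len_bp) |>
    arrange(.data$chrom, .data$start)
}

#' Permutation test for crossover clustering and hotspot windows
#'
#' Compares the observed per-window crossover counts with counts obtained by
#' placing the same number of crossovers uniformly over the mappable regions
#' `n_perm` times. Clustering is summarized by the dispersion index
#' (variance/mean of window counts; 1 under uniformity) with an empirical
#' add-one p-value, so p is never exactly 0 and is exactly calibrated under
#' the uniform null. A Wilcoxon rank-sum p of observed versus pooled permuted
#' counts is reported alongside, and per-window empirical p-values with
#' Benjamini-Hochberg correction provide hotspot calls at FDR 0.05.
#'
#' @param crossovers Crossover tibble (`chrom`, `interval_start`,
#'   `interval_end`).
#' @param mappable_regions Tibble `chrom`, `start`, `end` of regions the null
#'   may place crossovers in (pass whole chromosomes when no mask applies).
#' @param window_bp Window width (default 50 kb).
#' @param n_perm Number of permutations (must be >= 1; default 1000).
#' @param seed RNG seed.
#' @return A list of class `lr_permtest`: `statistic` (observed dispersion
#'   index), `p_value`, `wilcoxon_p`, `n_perm` and `windows` (tibble with
#'   per-window counts, empirical p, BH-adjusted p and `hotspot` flag).
#' @export
clustering_permutation_test <- function(crossovers, mappable_regions,
                                        window_bp = 50000, n_perm = 1000,
                                        seed = 1) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  regions <- merge_intervals(mappable_regions)
  mids <- (crossovers$interval_start + crossovers$interval_end) / 2
  k <- length(mids)
  if (k == 0) stop("no crossovers supplied")
  wins <- purrr::pmap_dfr(regions, function(chrom, start, end, ...) {
    w <- tile_windows(chrom, end - start, window_bp)
    w$start <- w$start + start
    w$end <- w$end + start
    w
  })
  obs_counts <- count_in_windows(wins, crossovers$chrom, mids, mids)

  set.seed(seed)
  perm_pos <- sample_uniform_positions(regions, k * n_perm)
  win_of <- position_window_index(wins, perm_pos$chrom, perm_pos$pos)
  perm_id <- rep(seq_len(n_perm), each = k)
  ok <- !is.na(win_of)
  W <- nrow(wins)
  counts_mat <- matrix(
    tabulate((perm_id[ok] - 1L) * W + win_of[ok], nbins = n_perm * W),
    nrow = n_perm, byrow = TRUE
  )

  disp <- function(x) if (mean(x) == 0) 0 else var(x) / mean(x)
  stat_obs <- disp(obs_counts)
  stat_perm <- apply(counts_mat, 1, disp)
  p_global <- (1 + sum(stat_perm >= stat_obs)) / (n_perm + 1)
  wilc <- suppressWarnings(
    wilcox.test(obs_counts, as.vector(counts_mat), alternative = "greater")$p.value
  )
  exceed <- colSums(counts_mat >= rep(obs_counts, each = n_perm))
  p_win <- (1 + exceed) / (n_perm + 1)
  p_adj <- p.adjust(p_win, method = "BH")
  windows <- wins |>
    mutate(n_crossovers = obs_counts, p = p_win, p_adj = p_adj,
           hotspot = p_adj < 0.05)
  structure(
    list(statistic = stat_obs, p_value = p_global, wilcoxon_p = wilc,
         n_perm = n_perm, windows = windows),
    class = "lr_permtest"
  )
}

#' @exportS3Method base::print
print.lr_permtest <- function(x, ...) {
  cat("<lr_permtest> dispersion index ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4), " (", x$n_perm, " permutations), ",
      sum(x$windows$hotspot), " hotspot window(s)\n", sep = "")
  invisible(x)
}

#' Permutation test for crossover proximity to genomic features
#'
#' Tests whether crossovers sit closer to a feature set (e.g. CpG islands)
#' than uniformly placed positions would. The statistic is the median
#' distance from crossover midpoints to the nearest feature; the null
#' redraws the same number of positions uniformly over the chromosomes
#' `n_perm` times, and the add-one empirical p-value is the fraction of
#' permutations with a median at most the observed one.
#'
#' @param crossovers Crossover tibble (`chrom`, `interval_start`,
#'   `interval_end`).
#' @param features Feature intervals (`chrom`, `start`, `end`); merged
#'   internally.
#' @param chrom_lengths Tibble `chrom`, `length`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return A list of class `lr_proxtest`: `median_observed`, `median_null`
#'   (mean of permutation medians), `p_value`, `n_perm`, and the observed
#'   `distances`.
#' @export
feature_proximity_test <- function(crossovers, features, chrom_lengths,
                                   n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  check_chrom_lengths(chrom_lengths)
  feats <- merge_intervals(features)
  if (nrow(feats) == 0) stop("no features supplied")
  mids <- (crossovers$interval_start + crossovers$interval_end) / 2
  k <- length(mids)
  if (k == 0) stop("no crossovers supplied")
  obs_d <- nearest_feature_distance(crossovers$chrom, mids, feats)

  regions <- tibble(chrom = chrom_lengths$chrom, start = 0,
                    end = chrom_lengths$length)
  set.seed(seed)
  perm_pos <- sample_uniform_positions(regions, k * n_perm)
  perm_d <- nearest_feature_distance(perm_pos$chrom, perm_pos$pos, feats)
  perm_med <- vapply(split(perm_d, rep(seq_len(n_perm), each = k)),
                     stats::median, numeric(1))
  med_obs <- stats::median(obs_d)
  p <- (1 + sum(perm_med <= med_obs)) / (n_perm + 1)
  structure(
    list(median_observed = med_obs, median_null = mean(perm_med),
         p_value = p, n_perm = n_perm, distances = obs_d),
    class = "lr_proxtest"
  )
}

#' @exportS3Method base::print
print.lr_proxtest <- function(x, ...) {
  cat("<lr_proxtest> median distance ", x$median_observed,
      " bp (null ", round(x$median_null), " bp), p = ",
      signif(x$p_value, 4), " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

# uniform positions over a merged region set, proportionally to region length
sample_uniform_positions <- function(regions, n) {
  len <- regions$end - regions$start
  u <- runif(n, 0, sum(len))
  cum <- c(0, cumsum(len))
  ri <- findInterval(u, cum, rightmost.closed = TRUE)
  ri[ri > nrow(regions)] <- nrow(regions)
  tibble(
    chrom = regions$chrom[ri],
    pos = regions$start[ri] + (u - cum[ri])
  )
}

position_window_index <- function(wins, chrom, pos) {
  key_w <- paste0(wins$chrom, ":", floor(wins$start))
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(wins$chrom)) {
    wi <- which(wins$chrom == ch)
    pi <- which(chrom == ch)
    if (length(pi) == 0) next
    # windows tile contiguously within each mappable run
    ord <- order(wins$start[wi])
    starts <- wins$start[wi][ord]
    ends <- wins$end[wi][ord]
    j <- findInterval(pos[pi], starts)
    inside <- j >= 1 & pos[pi] < ends[pmax(j, 1)]
    idx[pi[inside]] <- wi[ord][j[inside]]
  }
  idx
}

# distance (bp) from positions to the nearest feature interval (0 inside)
nearest_feature_distance <- function(chrom, pos, feats) {
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(floor(pos) + 1, floor(pos) + 1))
  f <- GenomicRanges::GRanges(feats$chrom,
                              IRanges::IRanges(feats$start + 1, feats$end))
  hits <- GenomicRanges::distanceToNearest(q, f)
  d <- rep(NA_real_, length(pos))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  # positions on chromosomes without features: infinite distance
  d[is.na(d)] <- Inf
  d
}
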