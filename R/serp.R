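#' Sliding-window enrichment profile with Agresti-Coull intervals
#'
#' For every codon, footprint counts of the chaperone-selected and total
#' translatomes are summed over a sliding window (truncated at gene ends).
#' Writing `a` and `b` for the windowed selected and total counts, the
#' window is treated as `a` successes in `a + b` trials; the Agresti-Coull
#' interval on the proportion `p` is computed at `ci_level` and mapped to
#' an enrichment ratio through `r = p / (1 - p)`, scaled by the ratio of
#' total to selected library sizes. Windows with no reads in either
#' library are masked missing; unbounded ratios (windows with no total
#' reads) are clamped at `ratio_cap`.
#'
#' @param counts Long tibble of codon counts with columns `gene_id`,
#'   `replicate`, `library` (`"selected"` or `"total"`), `codon`, `count`.
#' @param window Window width in codons; defaults to
#'   `params$ci_window_profile`.
#' @param params A [serp_params()] list; `align` selects trailing
#'   (ribosome at the window's 3' edge) or centered windows.
#' @param lib_sizes Library sizes: tibble with `replicate`, `library`,
#'   `library_size`. Defaults to the `library_sizes` attribute of
#'   `counts`, falling back to column sums of the table itself.
#'
#' @return A tibble with `gene_id`, `replicate`, `codon`, `ratio`,
#'   `ci_low`, `ci_high`, `missing`.
#' @export
windowed_enrichment <- function(counts, window = NULL,
                                params = serp_params(),
                                lib_sizes = NULL) {
  window <- window %||% params$ci_window_profile
  stopifnot(window >= 1)
  lib_sizes <- lib_sizes %||% attr(counts, "library_sizes") %||%
    default_lib_sizes(counts)
  z <- qnorm(1 - (1 - params$ci_level) / 2)
  sf_tbl <- lib_sizes |>
    tidyr::pivot_wider(names_from = "library", values_from = "library_size") |>
    mutate(size_factor = .data$total / .data$selected)
  sf_of <- function(rep) {
    k <- match(rep, sf_tbl$replicate)
    if (is.na(k)) abort(sprintf("no library sizes for replicate '%s'", rep))
    sf_tbl$size_factor[k]
  }
  lens <- counts |> group_by(.data$gene_id) |>
    summarise(len = max(.data$codon), .groups = "drop")

  counts |>
    left_join(lens, by = "gene_id") |>
    group_by(.data$gene_id, .data$replicate) |>
    group_modify(function(df, key) {
      N <- df$len[1]
      sel <- tot <- numeric(N)
      d <- df[df$library == "selected", ]
      sel[d$codon] <- d$count
      d <- df[df$library == "total", ]
      tot[d$codon] <- d$count
      a <- roll_sum(sel, window, params$align)
      b <- roll_sum(tot, window, params$align)
      ac <- ac_ratio_ci(a, b, z, sf_of(key$replicate), params$ratio_cap)
      tibble(codon = seq_len(N), ratio = ac$ratio, ci_low = ac$lo,
             ci_high = ac$hi, missing = ac$missing)
    }) |>
    ungroup()
}

default_lib_sizes <- function(counts) {
  counts |>
    group_by(.data$replicate, .data$library) |>
    summarise(library_size = sum(.data$count), .groups = "drop")
}

# truncated rolling sum; "trailing" covers codons c-window+1 .. c,
# "centered" covers c - (window-1)%/%2 .. c + window%/%2
roll_sum <- function(x, window, align) {
  n <- length(x)
  S <- c(0, cumsum(as.numeric(x)))
  if (align == "trailing") {
    lo <- pmax(1L, seq_len(n) - window + 1L)
    hi <- seq_len(n)
  } else {
    lo <- pmax(1L, seq_len(n) - (window - 1L) %/% 2L)
    hi <- pmin(n, seq_len(n) + window %/% 2L)
  }
  S[hi + 1L] - S[lo]
}

#' Agresti-Coull confidence interval for a binomial proportion
#'
#' The add-z-squared-over-two interval: with `x` successes in `n` trials,
#' the center is `(x + z^2/2) / (n + z^2)` and the half-width
#' `z * sqrt(center * (1 - center) / (n + z^2))`, clamped to `[0, 1]`.
#'
#' @param x Number of successes (vectorized).
#' @param n Number of trials.
#' @param level Confidence level, default 0.95.
#' @return A tibble with `estimate` (`x/n`), `lower`, `upper`.
#' @export
#' @examples
#' agresti_coull(25, 50)
agresti_coull <- function(x, n, level = 0.95) {
  stopifnot(all(n > 0), all(x >= 0), all(x <= n))
  z <- qnorm(1 - (1 - level) / 2)
  ntil <- n + z^2
  ptil <- (x + z^2 / 2) / ntil
  half <- z * sqrt(ptil * (1 - ptil) / ntil)
  tibble(estimate = x / n,
         lower = pmax(0, ptil - half),
         upper = pmin(1, ptil + half))
}

# Agresti-Coull interval on p = a/(a+b), mapped through p/(1-p) and scaled
ac_ratio_ci <- function(a, b, z, size_factor, cap) {
  n <- a + b
  missing <- n == 0
  n[missing] <- 1  # placeholder, masked below
  level <- 2 * pnorm(z) - 1
  ci <- agresti_coull(a, n, level)
  plo <- ci$lower
  phi <- ci$upper
  phat <- ci$estimate
  to_ratio <- function(p) pmin(cap, pmax(0, p / (1 - p) * size_factor))
  ratio <- to_ratio(phat); lo <- to_ratio(plo); hi <- to_ratio(phi)
  ratio[missing] <- lo[missing] <- hi[missing] <- NA_real_
  list(ratio = ratio, lo = lo, hi = hi, missing = missing)
}

#' Average enrichment profiles across replicates
#'
#' Position-wise arithmetic mean of the ratio and CI bounds; a position is
#' missing when it is missing in any replicate.
#'
#' @param profiles Output of [windowed_enrichment()] (several replicates).
#' @return A tibble with `gene_id`, `codon`, `ratio`, `ci_low`, `ci_high`,
#'   `missing`, `n_reps`.
#' @export
average_replicates <- function(profiles) {
  profiles |>
    group_by(.data$gene_id, .data$codon) |>
    summarise(miss = any(.data$missing),
              ratio = mean(.data$ratio),
              ci_low = mean(.data$ci_low),
              ci_high = mean(.data$ci_high),
              n_reps = n(), .groups = "drop") |>
    mutate(ratio = if_else(.data$miss, NA_real_, .data$ratio),
           ci_low = if_else(.data$miss, NA_real_, .data$ci_low),
           ci_high = if_else(.data$miss, NA_real_, .data$ci_high)) |>
    rename(missing = "miss") |>
    select("gene_id", "codon", "ratio", "ci_low", "ci_high", "missing",
           "n_reps")
}

#' Per-gene chaperone engagement score
#'
#' Windowed CI profiles are computed per replicate with the wide
#' (`ci_window_score`, default 45 codon) window, averaged across
#' replicates, and the score is the highest replicate-averaged lower CI
#' bound, excluding the first `head_trim` (default 30) and last
#' `tail_trim` (default 10) codons to avoid initiation artifacts and reads
#' from nearby downstream genes.
#'
#' @inheritParams windowed_enrichment
#' @return A tibble with `gene_id` and `score`.
#' @export
engagement_score <- function(counts, params = serp_params(),
                             lib_sizes = NULL) {
  prof <- windowed_enrichment(counts, params$ci_window_score, params,
                              lib_sizes) |>
    average_replicates()
  lens <- prof |> group_by(.data$gene_id) |>
    summarise(len = max(.data$codon), .groups = "drop")
  short <- lens$gene_id[lens$len <= params$head_trim + params$tail_trim]
  if (length(short) > 0) {
    abort(sprintf("gene(s) too short for engagement score (<= %d codons): %s",
                  params$head_trim + params$tail_trim,
                  paste(short, collapse = ", ")))
  }
  prof |>
    left_join(lens, by = "gene_id") |>
    filter(.data$codon > params$head_trim,
           .data$codon <= .data$len - params$tail_trim,
           !.data$missing) |>
    group_by(.data$gene_id) |>
    summarise(score = max(.data$ci_low), .groups = "drop")
}

#' Chaperone binding onset and enrichment peaks
#'
#' Each codon of each replicate profile is scored 1 when the lower CI
#' bound exceeds `onset_threshold` (bound with high confidence), 0.2 when
#' the CI straddles it (low confidence), and 0 when the upper bound is
#' below it (not bound; missing codons also score 0). Replicates are
#' averaged, codons with average strictly above `onset_binding_cut` are
#' called bound, runs shorter than `min_peak_len` codons are discarded,
#' and the onset is the 5'-most codon of the first surviving peak.
#'
#' @param profiles Per-replicate enrichment profiles from
#'   [windowed_enrichment()] with the profile (15 codon) window.
#' @param params A [serp_params()] list.
#'
#' @return A tibble with one row per gene: `gene_id`, `onset` (codon or
#'   `NA`), `n_peaks`, and a `peaks` list-column of `(start, end)` tibbles.
#' @export
binding_onset <- function(profiles, params = serp_params()) {
  map <- params$binding_value_map
  thr <- params$onset_threshold
  profiles |>
    mutate(value = dplyr::case_when(
      is.na(.data$ci_low) | is.na(.data$ci_high) ~ map[["none"]],
      .data$ci_low > thr ~ map[["high"]],
      .data$ci_high < thr ~ map[["none"]],
      TRUE ~ map[["low"]])) |>
    group_by(.data$gene_id, .data$codon) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    arrange(.data$gene_id, .data$codon) |>
    group_by(.data$gene_id) |>
    group_modify(function(df, key) {
      bound <- df$value > params$onset_binding_cut
      r <- rle(bound)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= params$min_peak_len
      peaks <- tibble(start = df$codon[starts[keep]],
                      end = df$codon[ends[keep]])
      tibble(onset = if (nrow(peaks)) min(peaks$start) else NA_integer_,
             n_peaks = nrow(peaks), peaks = list(peaks))
    }) |>
    ungroup()
}

#' Single-molecule occupancy statistics
#'
#' Binding-event counts per nascent-chain fragment are divided by the
#' number of molecules measured and by the measurement time, then
#' normalized to sum to one across fragments. The standard error of each
#' normalized proportion `p` is `sqrt(p (1 - p) / N)` with `N` the number
#' of molecules of that fragment.
#'
#' @param events Non-negative event counts per fragment.
#' @param molecules Positive molecule counts per fragment.
#' @param time Positive measurement times per fragment.
#' @param fragment Optional fragment labels.
#'
#' @return A tibble with `fragment`, `events`, `molecules`, `time`,
#'   `fraction` (rate per molecule per time), `p` (normalized, sums to 1)
#'   and `se`.
#' @export
#' @examples
#' occupancy_stats(events = c(58, 65, 47), molecules = c(115, 226, 209),
#'                 time = c(1, 1, 1))
occupancy_stats <- function(events, molecules, time,
                            fragment = seq_along(events)) {
  if (any(molecules <= 0)) abort("molecules must be positive")
  if (any(time <= 0)) abort("time must be positive")
  frac <- events / molecules / time
  p <- frac / sum(frac)
  tibble(fragment = fragment, events = events, molecules = molecules,
         time = time, fraction = frac, p = p,
         se = sqrt(p * (1 - p) / molecules))
}
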