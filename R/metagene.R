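#' Metagene enrichment profile
#'
#' Genes are aligned to their start or stop codon, optionally shifted
#' toward the 5' end to account for the ribosomal exit tunnel, binned with
#' a fixed codon width (bin means, truncated final bin), and averaged
#' across genes with a normal-approximation 95% CI (mean +/- 1.96 SEM).
#'
#' @param profiles Replicate-averaged enrichment profiles
#'   ([average_replicates()]); per-replicate input is averaged first. The
#'   `ratio` column is summarized.
#' @param align `"start"` (positions 1, 2, ... from the start codon) or
#'   `"stop"` (positions ..., -1, 0 with 0 the stop-proximal codon).
#' @param params A [serp_params()] list (`metagene_bin` is used).
#' @param shift Shift in amino acids toward the 5' end (value measured at
#'   codon `c` is plotted at `c - shift`). Default 0; use
#'   `params$tunnel_shift` to place signals at the tunnel-exit position.
#'
#' @return A tibble with `bin` (index), `pos` (first codon position of the
#'   bin on the aligned axis), `n_genes`, `mean`, `ci_low`, `ci_high`.
#' @export
metagene <- function(profiles, align = c("start", "stop"),
                     params = serp_params(), shift = 0) {
  align <- match.arg(align)
  if ("replicate" %in% names(profiles)) {
    profiles <- average_replicates(profiles)
  }
  binw <- params$metagene_bin
  per_gene <- profiles |>
    group_by(.data$gene_id) |>
    mutate(pos = if (align == "start") .data$codon - shift else
      .data$codon - max(.data$codon) - shift) |>
    filter(if (align == "start") .data$pos >= 1 else .data$pos <= 0) |>
    mutate(bin = ceiling(.data$pos / binw)) |>
    group_by(.data$gene_id, .data$bin) |>
    summarise(value = mean(.data$ratio, na.rm = TRUE),
              pos = min(.data$pos), .groups = "drop") |>
    filter(is.finite(.data$value))
  per_gene |>
    group_by(.data$bin) |>
    summarise(pos = min(.data$pos), n_genes = n(),
              mean = mean(.data$value),
              sem = if (n() > 1) sd(.data$value) / sqrt(n()) else 0,
              .groups = "drop") |>
    mutate(ci_low = .data$mean - qnorm(0.975) * .data$sem,
           ci_high = .data$mean + qnorm(0.975) * .data$sem) |>
    select("bin", "pos", "n_genes", "mean", "ci_low", "ci_high") |>
    arrange(.data$bin)
}

#' Domain-wise metagene profile
#'
#' Every accepted domain is resampled to `domain_bins` bins and every
#' linker between consecutive accepted domains to `linker_bins` bins;
#' linkers longer than `max_linker` amino acids are excluded. Instances
#' are then averaged bin-wise across the data set with a 95% CI, yielding
#' one combined domain + linker curve.
#'
#' @param profiles Replicate-averaged enrichment profiles with columns
#'   `gene_id`, `codon`, `ratio`.
#' @param domains Domain annotations: tibble with `gene_id`, `start`,
#'   `end` (accepted, non-overlapping; see [assign_domains()]).
#' @param params A [serp_params()] list (`domain_bins`, `linker_bins`,
#'   `max_linker`).
#' @param shift Shift in amino acids toward the 5' end applied to the
#'   profiles before resampling (default 0).
#'
#' @return A tibble with `segment` (`"domain"` or `"linker"`), `bin`
#'   (1..`domain_bins` then 1..`linker_bins`), `position` (1..40 combined
#'   axis), `n`, `mean`, `ci_low`, `ci_high`.
#' @export
domain_metagene <- function(profiles, domains, params = serp_params(),
                            shift = 0) {
  if ("replicate" %in% names(profiles)) {
    profiles <- average_replicates(profiles)
  }
  kd <- params$domain_bins; kl <- params$linker_bins
  inst <- list()
  for (g in unique(domains$gene_id)) {
    dg <- domains[domains$gene_id == g, ] |> arrange(.data$start)
    pg <- profiles[profiles$gene_id == g, ] |> arrange(.data$codon)
    if (nrow(pg) == 0) next
    val <- rep(NA_real_, max(pg$codon))
    val[pg$codon] <- pg$ratio
    if (shift > 0) {
      val <- c(val[-seq_len(min(shift, length(val)))],
               rep(NA_real_, min(shift, length(val))))
    }
    for (k in seq_len(nrow(dg))) {
      span <- dg$start[k]:dg$end[k]
      inst[[length(inst) + 1L]] <-
        tibble(segment = "domain", bin = seq_len(kd),
               value = resample_bins(val[span], kd))
      if (k < nrow(dg)) {
        lstart <- dg$end[k] + 1L; lend <- dg$start[k + 1L] - 1L
        llen <- lend - lstart + 1L
        if (llen >= 1 && llen <= params$max_linker) {
          inst[[length(inst) + 1L]] <-
            tibble(segment = "linker", bin = seq_len(kl),
                   value = resample_bins(val[lstart:lend], kl))
        }
      }
    }
  }
  if (length(inst) == 0) {
    return(tibble(segment = character(), bin = integer(),
                  position = integer(), n = integer(), mean = double(),
                  ci_low = double(), ci_high = double()))
  }
  bind_rows(inst) |>
    filter(is.finite(.data$value)) |>
    group_by(.data$segment, .data$bin) |>
    summarise(n = n(), mean = mean(.data$value),
              sem = if (n() > 1) sd(.data$value) / sqrt(n()) else 0,
              .groups = "drop") |>
    mutate(ci_low = .data$mean - qnorm(0.975) * .data$sem,
           ci_high = .data$mean + qnorm(0.975) * .data$sem,
           position = if_else(.data$segment == "domain", .data$bin,
                              .data$bin + kd)) |>
    select("segment", "bin", "position", "n", "mean", "ci_low",
           "ci_high") |>
    arrange(.data$position)
}

#' Resample a profile segment to a fixed number of bins
#'
#' Segments at least as long as `k` are cut into `k` contiguous,
#' near-equal index ranges and averaged within each; shorter segments are
#' linearly interpolated at `k` equally spaced points.
#'
#' @param x Numeric vector (one domain or linker segment).
#' @param k Number of output bins.
#' @return Numeric vector of length `k`.
#' @export
#' @examples
#' resample_bins(1:60, 30)  # pairs of consecutive values averaged
resample_bins <- function(x, k) {
  len <- length(x)
  if (len == 0) abort("empty segment")
  if (len >= k) {
    edges <- floor(seq_len(k) * len / k)
    starts <- c(1L, head(edges, -1L) + 1L)
    vapply(seq_len(k),
           function(b) mean(x[starts[b]:edges[b]], na.rm = TRUE),
           numeric(1))
  } else {
    approx(seq_len(len), x, xout = seq(1, len, length.out = k))$y
  }
}
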