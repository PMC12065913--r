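#' Dynamic time warping distance between two profiles
#'
#' Classic unconstrained DTW dynamic program with match / insert / delete
#' steps. The default local cost is the absolute difference, and the
#' returned cost is the optimal accumulated path cost; `method =
#' "sqeuclid"` accumulates squared differences and returns the square root
#' of the optimum instead.
#'
#' @param x,y Non-empty numeric vectors (e.g. lower-CI enrichment
#'   profiles); lengths may differ.
#' @param method `"abs"` (default) or `"sqeuclid"`.
#'
#' @return A single non-negative cost.
#' @export
#' @examples
#' dtw_distance(c(0, 1), c(0, 1, 1))  # 0: warping absorbs the repeat
dtw_distance <- function(x, y, method = c("abs", "sqeuclid")) {
  method <- match.arg(method)
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) abort("empty series")
  local <- if (method == "abs") {
    function(a, b) abs(a - b)
  } else {
    function(a, b) (a - b)^2
  }
  prev <- numeric(m)
  prev[1] <- local(x[1], y[1])
  for (j in seq_len(m - 1) + 1) prev[j] <- prev[j - 1] + local(x[1], y[j])
  if (n > 1) {
    cur <- numeric(m)
    for (i in 2:n) {
      cur[1] <- prev[1] + local(x[i], y[1])
      for (j in seq_len(m - 1) + 1) {
        cur[j] <- local(x[i], y[j]) + min(prev[j], prev[j - 1], cur[j - 1])
      }
      tmp <- prev; prev <- cur; cur <- tmp
    }
  }
  if (method == "sqeuclid") sqrt(prev[m]) else prev[m]
}

#' Pairwise DTW distance matrix of enrichment profiles
#'
#' Genes shorter than `min_len` codons are excluded; the first
#' `head_trim` and last `tail_trim` codons of every profile are ignored;
#' entries are clipped at `clip`. Missing positions are treated as zero
#' enrichment evidence.
#'
#' @param profiles Replicate-averaged profiles ([average_replicates()]).
#' @param params A [serp_params()] list (trims).
#' @param value Profile column compared; default the lower CI bound,
#'   a conservative estimate of enrichment.
#' @param min_len Minimum gene length in codons (default 50).
#' @param clip Clip value for large costs (default 500).
#' @param method Passed to [dtw_distance()].
#'
#' @return A symmetric numeric matrix with zero diagonal, gene ids as
#'   dimnames, and attribute `clip`.
#' @export
profile_distance_matrix <- function(profiles, params = serp_params(),
                                    value = "ci_low", min_len = 50,
                                    clip = 500, method = "abs") {
  series <- trimmed_series(profiles, params, value, min_len)
  ids <- names(series)
  if (length(ids) < 2) abort("need at least two genes of sufficient length")
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (p in seq_along(ids)[-length(ids)]) {
    for (q in (p + 1):length(ids)) {
      D[p, q] <- D[q, p] <-
        min(clip, dtw_distance(series[[p]], series[[q]], method))
    }
  }
  attr(D, "clip") <- clip
  D
}

trimmed_series <- function(profiles, params, value, min_len) {
  out <- list()
  for (g in unique(profiles$gene_id)) {
    pg <- profiles[profiles$gene_id == g, ] |> arrange(.data$codon)
    N <- max(pg$codon)
    if (N < min_len) next
    v <- rep(0, N)
    ok <- !is.na(pg[[value]])
    v[pg$codon[ok]] <- pg[[value]][ok]
    keep <- seq.int(params$head_trim + 1L, N - params$tail_trim)
    out[[g]] <- v[keep]
  }
  out
}

#' Two-group substrate clustering (high/low affinity)
#'
#' Agglomerative hierarchical clustering with Ward linkage on a
#' (clipped) DTW cost matrix, cut into two clusters. The cluster with the
#' higher median engagement score is labelled `A` (high affinity), the
#' other `B`. Note Ward linkage on a non-Euclidean cost matrix is a
#' heuristic, used here deliberately: the costs are treated directly as
#' dissimilarities rather than embedded.
#'
#' @param D Distance matrix from [profile_distance_matrix()].
#' @param scores Engagement scores: tibble with `gene_id`, `score`
#'   ([engagement_score()]).
#'
#' @return An object of class `serp_clusters`: list with `assignment`
#'   (tibble `gene_id`, `cluster`), `hclust` and `scores`. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
cluster_ab <- function(D, scores) {
  if (nrow(D) < 2) abort("need at least two genes to cluster")
  hc <- hclust(as.dist(D), method = "ward.D2")
  grp <- cutree(hc, k = 2)
  med <- vapply(1:2, function(k) {
    s <- scores$score[match(names(grp)[grp == k], scores$gene_id)]
    median(s, na.rm = TRUE)
  }, numeric(1))
  a <- which.max(med)
  assignment <- tibble(gene_id = names(grp),
                       cluster = if_else(grp == a, "A", "B"))
  structure(list(assignment = assignment, hclust = hc, scores = scores),
            class = "serp_clusters")
}

#' @export
print.serp_clusters <- function(x, ...) {
  n <- table(x$assignment$cluster)
  cat(sprintf("<serp_clusters> %d genes: cluster A (high affinity) = %d, cluster B = %d\n",
              nrow(x$assignment), n[["A"]], n[["B"]]))
  invisible(x)
}

#' @rdname cluster_ab
#' @param x A `serp_clusters` object.
#' @param ... Unused.
#' @export
tidy.serp_clusters <- function(x, ...) {
  x$assignment |>
    left_join(x$scores, by = "gene_id")
}

#' @rdname cluster_ab
#' @export
glance.serp_clusters <- function(x, ...) {
  tidy(x) |>
    group_by(.data$cluster) |>
    summarise(n = n(), median_score = median(.data$score, na.rm = TRUE),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cluster",
                       values_from = c("n", "median_score")) |>
    mutate(n_genes = nrow(x$assignment))
}

#' Normalized cross-correlation at zero lag
#'
#' Pearson-form NCC: both signals are mean-subtracted and scaled to unit
#' norm before the zero-lag dot product, so the result lies in `[-1, 1]`
#' and is invariant to affine rescaling of either input (in particular,
#' raw and normalized model profiles give the same value). A constant
#' signal yields 0 by convention. `centered = FALSE` gives the raw
#' (non-centered) variant.
#'
#' @param model Numeric model profile (e.g. `tf_raw`), one value per codon.
#' @param serp Numeric SeRP-derived profile of equal length (e.g. the
#'   replicate-averaged lower CI bound); `NA`s are dropped pairwise.
#' @param centered Mean-subtract before correlating (default `TRUE`).
#'
#' @return A correlation in `[-1, 1]`.
#' @export
ncc <- function(model, serp, centered = TRUE) {
  if (length(model) != length(serp)) {
    abort(sprintf("profile lengths differ (%d vs %d)",
                  length(model), length(serp)))
  }
  ok <- !is.na(model) & !is.na(serp)
  x <- as.numeric(model[ok]); y <- as.numeric(serp[ok])
  if (length(x) == 0) return(0)
  if (centered) {
    x <- x - mean(x); y <- y - mean(y)
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' Three-set interactor overlap (Venn partition counts)
#'
#' Counts the exclusive and shared regions of the Venn partition of three
#' gene sets (e.g. the cluster-A substrates of TF, DnaK and GroEL).
#'
#' @param sets Named list of three character vectors.
#' @return A tibble with one row per region: `region` (e.g. `"TF"`,
#'   `"TF&DnaK"`, `"TF&DnaK&GroEL"`) and `count`.
#' @export
#' @examples
#' interactor_overlap(list(TF = c("a", "b"), DnaK = c("b", "c"),
#'                         GroEL = c("b")))
interactor_overlap <- function(sets) {
  if (length(sets) != 3 || is.null(names(sets))) {
    abort("`sets` must be a named list of three gene sets")
  }
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 3))[-1, ]
  names(combos) <- names(sets)
  purrr::map_dfr(seq_len(nrow(combos)), function(k) {
    pat <- unlist(combos[k, ])
    inside <- rep(TRUE, length(universe))
    for (s in seq_len(3)) {
      inside <- inside & (member[, s] == pat[s])
    }
    tibble(region = paste(names(sets)[pat], collapse = "&"),
           count = sum(inside))
  })
}
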