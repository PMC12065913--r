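#' Extract filtered, weighted residue-residue contacts
#'
#' Two residues are in contact when at least one pair of their atoms lies
#' within `max_atom_dist` of each other, both residues have pLDDT at or
#' above `min_plddt`, the pair passes the predicted-aligned-error filter,
#' and the residues are at least `min_seq_sep` apart on the chain. The
#' contact weight ("interaction strength") is the number of atoms involved
#' in the contacting residue pair: by default the count of distinct atoms,
#' across both residues, that take part in at least one qualifying atom
#' pair (`strength_mode = "pairs"` counts atom pairs instead).
#'
#' @param model A [struct_model()].
#' @param pae A [pae_matrix()] for the same protein.
#' @param params A [contact_params()] list.
#'
#' @return A tibble with columns `protein_id`, `i`, `j` (1-based residue
#'   indices, `i < j`), `strength` (positive integer) and `domain_label`
#'   (initially `"unassigned"`; see [label_contact_domains()]), carrying
#'   the protein length in attribute `n_residues`.
#' @seealso [assign_domains()], [label_contact_domains()], [predict_gene()]
#' @export
extract_contacts <- function(model, pae, params = contact_params()) {
  validate_struct_model(model)
  if (nrow(pae) != model$n_residues) {
    abort(sprintf("PAE dimension (%d) does not match protein length (%d)",
                  nrow(pae), model$n_residues))
  }
  pid <- attr(pae, "protein_id")
  if (!is.null(pid) && !identical(pid, model$protein_id)) {
    abort(sprintf("PAE protein_id (%s) differs from structure (%s)",
                  pid, model$protein_id))
  }

  keep_res <- which(model$plddt >= params$min_plddt)
  atoms <- model$atoms[model$atoms$residue %in% keep_res, , drop = FALSE]
  pairs <- close_atom_pairs(as.matrix(atoms[c("x", "y", "z")]),
                            atoms$residue, params$max_atom_dist,
                            params$min_seq_sep)
  empty <- tibble(protein_id = character(), i = integer(), j = integer(),
                  strength = integer(), domain_label = character())
  if (nrow(pairs) == 0) {
    return(finish_contact_map(empty, model$protein_id, model$n_residues))
  }

  # residue-level PAE filter on the surviving pairs
  m <- unclass(pae)
  pv <- switch(params$pae_rule,
               max = pmax(m[cbind(pairs$ri, pairs$rj)],
                          m[cbind(pairs$rj, pairs$ri)]),
               min = pmin(m[cbind(pairs$ri, pairs$rj)],
                          m[cbind(pairs$rj, pairs$ri)]))
  pairs <- pairs[pv <= params$max_pae, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(finish_contact_map(empty, model$protein_id, model$n_residues))
  }

  key <- paste(pairs$ri, pairs$rj)
  strength <- if (params$strength_mode == "atoms") {
    vapply(split(seq_len(nrow(pairs)), key), function(idx) {
      length(unique(c(pairs$ai[idx], pairs$aj[idx])))
    }, integer(1))
  } else {
    vapply(split(seq_len(nrow(pairs)), key), length, integer(1))
  }
  uniq <- !duplicated(key)
  out <- tibble(protein_id = model$protein_id,
                i = pairs$ri[uniq], j = pairs$rj[uniq],
                strength = as.integer(strength[match(key[uniq], names(strength))]),
                domain_label = "unassigned") |>
    arrange(.data$i, .data$j)
  finish_contact_map(out, model$protein_id, model$n_residues)
}

finish_contact_map <- function(tbl, protein_id, n_residues) {
  attr(tbl, "protein_id") <- protein_id
  attr(tbl, "n_residues") <- n_residues
  tbl
}

# All cross-residue atom pairs within `cutoff`, restricted to residue pairs
# separated by >= min_seq_sep on the chain. Row-chunked so the distance
# matrix never exceeds ~chunk x n doubles.
close_atom_pairs <- function(coords, residue, cutoff, min_seq_sep,
                             chunk = 1024L) {
  m <- nrow(coords)
  if (m < 2) {
    return(tibble(ri = integer(), rj = integer(),
                  ai = integer(), aj = integer()))
  }
  sq <- rowSums(coords^2)
  cut2 <- cutoff^2
  res <- vector("list", ceiling(m / chunk))
  for (k in seq_along(res)) {
    rows <- (((k - 1L) * chunk + 1L)):min(k * chunk, m)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(coords[rows, , drop = FALSE], coords)
    hit <- which(d2 <= cut2 + 1e-9, arr.ind = TRUE)
    p <- rows[hit[, 1L]]
    q <- hit[, 2L]
    keep <- q > p & (residue[q] - residue[p] >= min_seq_sep |
                       residue[p] - residue[q] >= min_seq_sep)
    p <- p[keep]; q <- q[keep]
    swap <- residue[p] > residue[q]
    ri <- ifelse(swap, residue[q], residue[p])
    rj <- ifelse(swap, residue[p], residue[q])
    ai <- ifelse(swap, q, p)
    aj <- ifelse(swap, p, q)
    res[[k]] <- tibble(ri = as.integer(ri), rj = as.integer(rj),
                       ai = as.integer(ai), aj = as.integer(aj))
  }
  bind_rows(res)
}

#' Greedy rank-ordered domain assignment
#'
#' Accepts candidate domains in similarity-rank order (rank 1 first).
#' Candidates of length 10 residues or shorter are rejected, as are
#' candidates whose positional overlap with the union of already-accepted
#' higher-ranked domains exceeds `max_overlap` of the candidate's own
#' length. Rank ties are broken deterministically: longer candidate first,
#' then smaller start, then id.
#'
#' @param candidates Data frame with columns `start`, `end` (1-based,
#'   inclusive), `rank` (1 = best) and `id`.
#' @param n_residues Protein length; candidates extending beyond it are an
#'   error.
#' @param min_len Minimum accepted length is `min_len + 1` (a domain must be
#'   strictly longer than `min_len` residues). Default 10.
#' @param max_overlap Maximum tolerated overlap fraction, measured relative
#'   to the candidate's length. Default 0.05.
#' @param protein_id Optional identifier stored on the result.
#'
#' @return A tibble of accepted domains (`start`, `end`, `rank`, `id`)
#'   sorted by `start`, with attributes `protein_id` and `n_residues`.
#' @export
#' @examples
#' cands <- tibble::tibble(start = c(1, 35, 60), end = c(40, 80, 75),
#'                         rank = c(1, 2, 3), id = c("a", "b", "c"))
#' assign_domains(cands, n_residues = 100)
assign_domains <- function(candidates, n_residues, min_len = 10,
                           max_overlap = 0.05, protein_id = NA_character_) {
  candidates <- as_tibble(candidates)
  out <- tibble(start = integer(), end = integer(), rank = integer(),
                id = character())
  if (nrow(candidates) > 0) {
    if (any(candidates$start > candidates$end)) abort("candidate with start > end")
    if (any(candidates$end > n_residues | candidates$start < 1)) {
      abort("candidate outside 1..n_residues")
    }
    len <- candidates$end - candidates$start + 1L
    ord <- order(candidates$rank, -len, candidates$start, candidates$id)
    covered <- logical(n_residues)
    acc <- logical(nrow(candidates))
    for (k in ord) {
      lk <- len[k]
      if (lk <= min_len) next
      span <- candidates$start[k]:candidates$end[k]
      if (sum(covered[span]) / lk > max_overlap) next
      covered[span] <- TRUE
      acc[k] <- TRUE
    }
    out <- candidates[acc, c("start", "end", "rank", "id")] |>
      arrange(.data$start)
    out$start <- as.integer(out$start)
    out$end <- as.integer(out$end)
  }
  attr(out, "protein_id") <- protein_id
  attr(out, "n_residues") <- n_residues
  out
}

#' Label contacts by domain membership
#'
#' A contact is `intra` when both residues fall inside the same accepted
#' domain, `inter` when they fall in two different accepted domains, and
#' `unassigned` otherwise. Intra-domain unsatisfied contacts drive the
#' Trigger Factor model, inter-domain ones the DnaK model; unassigned
#' contacts contribute to neither.
#'
#' @param contacts Contact tibble from [extract_contacts()].
#' @param domains Accepted domains from [assign_domains()].
#'
#' @return The contact tibble with `domain_label` filled in.
#' @export
label_contact_domains <- function(contacts, domains) {
  pid_c <- attr(contacts, "protein_id")
  pid_d <- attr(domains, "protein_id")
  if (!is.null(pid_c) && !is.null(pid_d) && !is.na(pid_d) &&
      !identical(pid_c, pid_d)) {
    abort(sprintf("contact map (%s) and domain annotation (%s) disagree",
                  pid_c, pid_d))
  }
  n <- attr(contacts, "n_residues") %||% max(contacts$j, domains$end, 0L)
  dom_of <- integer(n)
  if (nrow(domains) > 0) {
    for (k in seq_len(nrow(domains))) {
      dom_of[domains$start[k]:domains$end[k]] <- k
    }
  }
  if (nrow(contacts) > 0) {
    di <- dom_of[contacts$i]
    dj <- dom_of[contacts$j]
    contacts$domain_label <- dplyr::case_when(
      di > 0 & di == dj ~ "intra",
      di > 0 & dj > 0 ~ "inter",
      TRUE ~ "unassigned")
  }
  finish_contact_map(contacts, pid_c, n)
}
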