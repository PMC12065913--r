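#' Nascent-chain state at a given length
#'
#' At nascent length `L` the `tunnel_len` most C-terminal residues sit in
#' the ribosomal exit tunnel and cannot form contacts; residues further
#' toward the N terminus have emerged.
#'
#' @param L Nascent chain length (1..N).
#' @param N Full protein length.
#' @param tunnel_len Exit tunnel length in residues (default 30).
#'
#' @return A list with `L`, `emerged` (integer vector, possibly empty) and
#'   `tunnel` (integer vector).
#' @export
#' @examples
#' nascent_state(31, 100)$emerged  # residue 1 has just emerged
nascent_state <- function(L, N, tunnel_len = 30) {
  if (L < 1 || L > N) abort(sprintf("L = %d outside 1..%d", L, N))
  e <- max(0L, L - as.integer(tunnel_len))
  list(L = as.integer(L),
       emerged = seq_len(e),
       tunnel = seq.int(e + 1L, L))
}

#' Categorize contacts at a nascent length
#'
#' At nascent length `L`, every native contact `(i, j)` with `i < j` falls
#' into exactly one category: `I` if the N-terminal residue has not emerged
#' (neither partner can form contacts, or is not yet attached); `II` if
#' residue `i` has emerged but `j` is still in the tunnel or untranslated
#' (the emerged residue is "unsatisfied"); `III` if both have emerged
#' (compacted, native-like structure).
#'
#' @param contacts Contact tibble (see [extract_contacts()]).
#' @param L Nascent length.
#' @param tunnel_len Exit tunnel length (default 30).
#'
#' @return The contact tibble with a `category` column (`"I"`, `"II"`,
#'   `"III"`).
#' @export
categorize_contacts <- function(contacts, L, tunnel_len = 30) {
  contacts$category <- contact_category(contacts$i, contacts$j, L, tunnel_len)
  contacts
}

contact_category <- function(i, j, L, tunnel_len) {
  e <- L - tunnel_len  # last emerged residue
  if_else(i > e, "I", if_else(j > e, "II", "III"))
}

#' Delayed-folding eligibility mask
#'
#' Folding of N-terminal regions is delayed until enough compacted
#' structure has accumulated: per residue, the summed strength of its
#' category-III contacts is computed (residues below `res_strength_min`
#' contribute nothing), then the cumulative sum is taken from the C
#' terminus (residue `L`) toward the N terminus. A residue is eligible when
#' the cumulative strength strictly exceeds `cum_threshold`. Unsatisfied
#' (category II) contacts contribute to binding only when their emerged
#' residue is eligible.
#'
#' @param contacts Contact tibble with a `category` column for length `L`
#'   (see [categorize_contacts()]).
#' @param L Nascent length the categories refer to.
#' @param n_residues Protein length.
#' @param params A [model_params()] list.
#' @param exclude_inter If `TRUE`, inter-domain contacts are not counted as
#'   compacted structure (they are held unsatisfied under the DnaK model).
#'
#' @return Logical vector of length `n_residues`.
#' @export
folding_eligibility <- function(contacts, L, n_residues,
                                params = model_params(),
                                exclude_inter = FALSE) {
  mask <- contacts$category == "III"
  if (exclude_inter) mask <- mask & contacts$domain_label != "inter"
  s <- residue_strengths(contacts$i[mask], contacts$j[mask],
                         contacts$strength[mask], n_residues)
  s[s < params$res_strength_min] <- 0
  cum <- rev(cumsum(rev(s[seq_len(L)])))
  elig <- logical(n_residues)
  elig[seq_len(L)] <- if (params$cum_strict) cum > params$cum_threshold else
    cum >= params$cum_threshold
  elig
}

residue_strengths <- function(i, j, strength, n_residues) {
  s <- numeric(n_residues)
  if (length(i) > 0) {
    acc <- tapply(c(strength, strength), c(i, j), sum)
    s[as.integer(names(acc))] <- acc
  }
  s
}

#' Per-length raw binding scores
#'
#' `tf_raw()` sums the strengths of unsatisfied (category II) intra-domain
#' contacts whose emerged residue is folding-eligible: Trigger Factor is
#' modeled to engage unsatisfied residues exposed on partial folds within a
#' domain. `dnak_raw()` does the same for inter-domain contacts, with the
#' key difference that inter-domain contacts never reach category III --
#' native interfaces form only post-translationally, so they stay
#' unsatisfied until termination. `molten_globule_raw()` is an alternative
#' model in which every tunnel-emerged residue of a domain contributes its
#' total native contact strength until the whole domain has been
#' synthesized, at which point all its residues are satisfied at once.
#'
#' @param contacts Domain-labelled contact tibble
#'   (see [label_contact_domains()]).
#' @param domains Accepted domain annotation from [assign_domains()]
#'   (required by `molten_globule_raw`).
#' @param L Nascent length.
#' @param params A [model_params()] list.
#' @param n_residues Protein length; taken from the contact map attribute
#'   when omitted.
#'
#' @return A single non-negative score in atom-count units.
#' @name raw_scores
NULL

#' @rdname raw_scores
#' @export
tf_raw <- function(contacts, L, params = model_params(),
                   n_residues = attr(contacts, "n_residues")) {
  cc <- categorize_contacts(contacts, L, params$tunnel_len)
  elig <- folding_eligibility(cc, L, n_residues, params)
  sel <- cc$category == "II" & cc$domain_label == "intra" & elig[cc$i]
  sum(cc$strength[sel])
}

#' @rdname raw_scores
#' @export
dnak_raw <- function(contacts, L, params = model_params(),
                     n_residues = attr(contacts, "n_residues")) {
  cc <- categorize_contacts(contacts, L, params$tunnel_len)
  elig <- folding_eligibility(cc, L, n_residues, params, exclude_inter = TRUE)
  # inter-domain III -> II: any emerged inter contact is unsatisfied
  sel <- cc$domain_label == "inter" & cc$category != "I" & elig[cc$i]
  sum(cc$strength[sel])
}

#' @rdname raw_scores
#' @export
molten_globule_raw <- function(contacts, domains, L,
                               params = model_params(),
                               n_residues = attr(contacts, "n_residues")) {
  e <- L - params$tunnel_len
  if (e < 1 || nrow(domains) == 0) return(0)
  tot <- residue_strengths(contacts$i, contacts$j, contacts$strength,
                           n_residues)
  score <- 0
  for (k in seq_len(nrow(domains))) {
    if (domains$end[k] <= L) next  # domain complete: satisfied immediately
    r <- domains$start[k]:domains$end[k]
    score <- score + sum(tot[r[r <= e]])
  }
  score
}

#' Fraction of emerged residues in tertiary structure
#'
#' The fraction of tunnel-emerged residues that participate in at least one
#' category-III (compacted) contact at nascent length `L`; 0 when nothing
#' has emerged.
#'
#' @inheritParams raw_scores
#' @return A fraction in `[0, 1]`.
#' @export
structured_fraction <- function(contacts, L, params = model_params(),
                                n_residues = attr(contacts, "n_residues")) {
  e <- L - params$tunnel_len
  if (e < 1) return(0)
  m3 <- contacts$j <= e
  structured <- unique(c(contacts$i[m3], contacts$j[m3]))
  length(structured) / e
}

#' Normalize a raw model profile to enrichment units
#'
#' Affinely maps the raw score range onto `[norm_floor, score]`, where
#' `score` is the gene's SeRP-derived chaperone engagement score, so that
#' model output and measured enrichment share a scale; this accounts for
#' expression-level and background-binding differences. Constant raw
#' profiles map to `norm_floor` everywhere. Presentation-level only:
#' model-data comparisons ([ncc()]) use raw profiles.
#'
#' @param raw Numeric vector of raw per-codon scores.
#' @param engagement_score Positive engagement score (enrichment units).
#' @param norm_floor Lower bound of the output scale. Default 0.25.
#'
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' normalize_profile(c(0, 10, 5), 2.25)
normalize_profile <- function(raw, engagement_score, norm_floor = 0.25) {
  if (length(raw) == 0) abort("empty profile")
  if (engagement_score <= 0) abort("engagement_score must be positive")
  top <- max(engagement_score, norm_floor)
  rng <- max(raw) - min(raw)
  if (rng == 0) return(rep(norm_floor, length(raw)))
  norm_floor + (raw - min(raw)) / rng * (top - norm_floor)
}

#' Per-codon binding profiles for one protein
#'
#' Runs the vectorial-synthesis simulation codon by codon: for every
#' nascent length `L` in `1..N` the contacts are categorized, the
#' delayed-folding mask recomputed, and the TF, DnaK and molten-globule
#' scores accumulated, together with the emerged tertiary-structure
#' fraction.
#'
#' @param contacts Domain-labelled contact tibble.
#' @param domains Accepted domain annotation.
#' @param params A [model_params()] list.
#' @param n_residues Protein length; defaults to the contact-map attribute.
#'
#' @return A tibble with columns `protein_id`, `codon`, `tf_raw`,
#'   `dnak_raw`, `mg_raw`, `structured_fraction`.
#' @export
binding_profile <- function(contacts, domains, params = model_params(),
                            n_residues = attr(contacts, "n_residues")) {
  if (is.null(n_residues)) abort("protein length unknown; pass n_residues")
  N <- n_residues
  ci <- contacts$i; cj <- contacts$j
  cs <- as.numeric(contacts$strength); lab <- contacts$domain_label
  intra <- lab == "intra"; inter <- lab == "inter"
  tot <- residue_strengths(ci, cj, cs, N)
  dom_incomplete_strength <- function(e, L) {
    # molten-globule contribution at length L
    sc <- 0
    for (k in seq_len(nrow(domains))) {
      if (domains$end[k] <= L) next
      r <- domains$start[k]:domains$end[k]
      sc <- sc + sum(tot[r[r <= e]])
    }
    sc
  }
  tf <- dnak <- mg <- sf <- numeric(N)
  for (L in seq_len(N)) {
    e <- L - params$tunnel_len
    if (e < 1) next
    emerged_i <- ci <= e
    is3 <- cj <= e
    is2 <- emerged_i & !is3
    elig_tf <- cum_eligibility(ci, cj, cs, is3, e, L, N, params)
    elig_dk <- cum_eligibility(ci, cj, cs, is3 & !inter, e, L, N, params)
    tf[L] <- sum(cs[is2 & intra & elig_tf[ci]])
    dnak[L] <- sum(cs[emerged_i & inter & elig_dk[ci]])
    if (nrow(domains) > 0) mg[L] <- dom_incomplete_strength(e, L)
    if (any(is3)) {
      sf[L] <- length(unique(c(ci[is3], cj[is3]))) / e
    }
  }
  tibble(protein_id = attr(contacts, "protein_id") %||% NA_character_,
         codon = seq_len(N), tf_raw = tf, dnak_raw = dnak, mg_raw = mg,
         structured_fraction = sf)
}

cum_eligibility <- function(ci, cj, cs, mask3, e, L, N, params) {
  s <- residue_strengths(ci[mask3], cj[mask3], cs[mask3], N)
  s[s < params$res_strength_min] <- 0
  cum <- rev(cumsum(rev(s[seq_len(L)])))
  elig <- logical(N)
  elig[seq_len(L)] <- if (params$cum_strict) cum > params$cum_threshold else
    cum >= params$cum_threshold
  elig
}

#' Predict chaperone binding profiles from a structure
#'
#' End-to-end prediction for one gene: extracts filtered contacts, assigns
#' domains greedily by rank, labels contacts intra/inter-domain, and runs
#' the per-codon binding model. When an engagement score is supplied the
#' raw TF and DnaK profiles are also normalized to enrichment units.
#'
#' @param model A [struct_model()].
#' @param pae A [pae_matrix()].
#' @param candidates Domain candidate table (columns `start`, `end`,
#'   `rank`, `id`).
#' @param cparams,mparams Contact and model parameter lists.
#' @param engagement_score Optional positive engagement score used by
#'   [normalize_profile()].
#'
#' @return A tibble with `protein_id`, `codon`, `tf_raw`, `dnak_raw`,
#'   `mg_raw`, `structured_fraction`, and (when `engagement_score` is
#'   given) `tf_norm`, `dnak_norm`.
#' @export
predict_gene <- function(model, pae, candidates,
                         cparams = contact_params(),
                         mparams = model_params(),
                         engagement_score = NULL) {
  cmap <- extract_contacts(model, pae, cparams)
  ann <- assign_domains(candidates, model$n_residues,
                        protein_id = model$protein_id)
  cmap <- label_contact_domains(cmap, ann)
  prof <- binding_profile(cmap, ann, mparams, model$n_residues)
  if (!is.null(engagement_score)) {
    prof$tf_norm <- normalize_profile(prof$tf_raw, engagement_score,
                                      mparams$norm_floor)
    prof$dnak_norm <- normalize_profile(prof$dnak_raw, engagement_score,
                                        mparams$norm_floor)
  }
  prof
}
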