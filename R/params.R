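#' Contact-extraction parameters
#'
#' Thresholds used when turning a predicted structure into a filtered,
#' weighted residue-residue contact map.
#'
#' @param max_atom_dist Maximum atom-atom distance (Angstrom) for two atoms
#'   to count as contacting. Default 6.
#' @param min_plddt Minimum per-residue predicted confidence (pLDDT, 0-100).
#'   Atoms of residues below this are ignored. Default 70.
#' @param max_pae Maximum predicted aligned error (Angstrom) for a residue
#'   pair; pairs above are ignored. Default 5.
#' @param min_seq_sep Minimum sequence separation `j - i` between contacting
#'   residues; pairs closer than this on the chain are ignored (default 6,
#'   i.e. pairs with `|i - j| <= 5` are dropped, which removes most contacts
#'   internal to a single alpha-helix).
#' @param pae_rule How the (possibly asymmetric) PAE matrix is reduced to a
#'   per-pair value before comparing with `max_pae`: `"max"` (conservative,
#'   default) or `"min"`.
#' @param strength_mode `"atoms"` (default) counts the distinct atoms, from
#'   both residues together, that take part in at least one qualifying atom
#'   pair; `"pairs"` counts qualifying atom pairs.
#'
#' @return A named list of class `contact_params`.
#' @export
#' @examples
#' contact_params(min_plddt = 50)
contact_params <- function(max_atom_dist = 6, min_plddt = 70, max_pae = 5,
                           min_seq_sep = 6, pae_rule = c("max", "min"),
                           strength_mode = c("atoms", "pairs")) {
  pae_rule <- match.arg(pae_rule)
  strength_mode <- match.arg(strength_mode)
  stopifnot(max_atom_dist > 0, min_plddt > 0, max_pae > 0, min_seq_sep > 0)
  structure(list(max_atom_dist = max_atom_dist, min_plddt = min_plddt,
                 max_pae = max_pae, min_seq_sep = min_seq_sep,
                 pae_rule = pae_rule, strength_mode = strength_mode),
            class = "contact_params")
}

#' Nascent-chain binding-model parameters
#'
#' @param tunnel_len Length of the ribosomal exit tunnel in residues; the
#'   `tunnel_len` most C-terminal residues of a nascent chain of length L
#'   cannot form contacts. Default 30.
#' @param res_strength_min Per-residue category-III contact strength
#'   (atom-count units) below which a residue is ignored when accumulating
#'   compacted structure in the delayed-folding rule. Default 20.
#' @param cum_threshold Cumulative category-III strength (atom-count units,
#'   summed from the C- toward the N-terminus) that must be exceeded
#'   (strictly) before unsatisfied residues in a region are allowed to
#'   contribute to binding. Default 750.
#' @param norm_floor Lower bound of the normalized model output, in
#'   enrichment units; matches the background level of SeRP enrichment
#'   plots. Default 0.25.
#' @param cum_strict Logical; if `TRUE` (default) eligibility requires the
#'   cumulative strength to be strictly greater than `cum_threshold`.
#'
#' @return A named list of class `model_params`.
#' @export
model_params <- function(tunnel_len = 30, res_strength_min = 20,
                         cum_threshold = 750, norm_floor = 0.25,
                         cum_strict = TRUE) {
  stopifnot(tunnel_len > 0, res_strength_min > 0, cum_threshold > 0,
            norm_floor > 0)
  structure(list(tunnel_len = tunnel_len, res_strength_min = res_strength_min,
                 cum_threshold = cum_threshold, norm_floor = norm_floor,
                 cum_strict = isTRUE(cum_strict)),
            class = "model_params")
}

#' SeRP enrichment-statistics parameters
#'
#' @param ci_window_profile Sliding-window width (codons) for per-codon
#'   enrichment profiles and onset calling. Default 15.
#' @param ci_window_score Sliding-window width (codons) for single-value
#'   engagement scores. Default 45.
#' @param ci_level Confidence level of the Agresti-Coull interval.
#'   Default 0.95.
#' @param align Window alignment: `"trailing"` (default) places the window
#'   over the codons `c - window + 1 .. c` already translated when the
#'   ribosome sits at codon `c`; `"centered"` centers it on `c`. Both are
#'   truncated at gene ends.
#' @param onset_threshold Enrichment value separating bound from unbound in
#'   onset calling. Default 1.5.
#' @param binding_value_map Named vector mapping the three per-codon
#'   confidence states to numeric values: lower CI above threshold
#'   (`high`), CI straddling it (`low`), upper CI below it (`none`).
#' @param onset_binding_cut Replicate-averaged binding value above which
#'   (strictly) a codon is called bound. Default 0.6.
#' @param min_peak_len Minimum peak length in codons; shorter runs are
#'   discarded. Default 6.
#' @param head_trim,tail_trim Codons excluded at the gene 5' and 3' ends for
#'   engagement scores and DTW clustering (initiation artifacts, downstream
#'   genes). Defaults 30 and 10.
#' @param metagene_bin Bin width (codons) of start/stop-aligned metagene
#'   profiles. Default 6.
#' @param tunnel_shift Shift (amino acids) applied toward the 5' end to
#'   account for the ribosomal exit tunnel. Default 30.
#' @param domain_bins,linker_bins Number of bins a domain / linker is
#'   resampled to in domain-wise metagenes. Defaults 30 and 10.
#' @param max_linker Linkers longer than this (amino acids) are excluded
#'   from domain-wise metagenes. Default 40.
#' @param ratio_cap Upper clamp of enrichment ratios and CI bounds (windows
#'   with zero total counts are otherwise unbounded). Default 100.
#'
#' @return A named list of class `serp_params`.
#' @export
serp_params <- function(ci_window_profile = 15, ci_window_score = 45,
                        ci_level = 0.95, align = c("trailing", "centered"),
                        onset_threshold = 1.5,
                        binding_value_map = c(high = 1, low = 0.2, none = 0),
                        onset_binding_cut = 0.6, min_peak_len = 6,
                        head_trim = 30, tail_trim = 10, metagene_bin = 6,
                        tunnel_shift = 30, domain_bins = 30, linker_bins = 10,
                        max_linker = 40, ratio_cap = 100) {
  align <- match.arg(align)
  stopifnot(ci_window_profile >= 1, ci_window_score >= 1,
            ci_level > 0, ci_level < 1, onset_threshold > 0,
            all(c("high", "low", "none") %in% names(binding_value_map)),
            head_trim >= 0, tail_trim >= 0, min_peak_len >= 1,
            metagene_bin >= 1, domain_bins >= 1, linker_bins >= 1,
            ratio_cap > 0)
  structure(list(ci_window_profile = ci_window_profile,
                 ci_window_score = ci_window_score, ci_level = ci_level,
                 align = align, onset_threshold = onset_threshold,
                 binding_value_map = binding_value_map,
                 onset_binding_cut = onset_binding_cut,
                 min_peak_len = min_peak_len, head_trim = head_trim,
                 tail_trim = tail_trim, metagene_bin = metagene_bin,
                 tunnel_shift = tunnel_shift, domain_bins = domain_bins,
                 linker_bins = linker_bins, max_linker = max_linker,
                 ratio_cap = ratio_cap),
            class = "serp_params")
}
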