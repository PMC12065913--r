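#' Predicted structure model
#'
#' Container for one predicted protein structure: atom coordinates grouped
#' by residue plus a per-residue confidence (pLDDT) track. Residue indices
#' are 1-based and contiguous.
#'
#' @param protein_id Character identifier.
#' @param atoms Data frame with columns `residue` (1-based index), `x`, `y`,
#'   `z` (Angstrom) and optionally `element`.
#' @param plddt Numeric vector of per-residue confidence in `[0, 100]`,
#'   length equal to the number of residues.
#'
#' @return An object of class `struct_model` with fields `protein_id`,
#'   `n_residues`, `atoms` (tibble) and `plddt`.
#' @export
struct_model <- function(protein_id, atoms, plddt) {
  atoms <- as_tibble(atoms)
  if (!all(c("residue", "x", "y", "z") %in% names(atoms))) {
    abort("`atoms` needs columns residue, x, y, z")
  }
  if (!"element" %in% names(atoms)) atoms$element <- "C"
  n <- length(plddt)
  obj <- structure(list(protein_id = as.character(protein_id),
                        n_residues = n,
                        atoms = atoms[c("residue", "element", "x", "y", "z")],
                        plddt = as.numeric(plddt)),
                   class = "struct_model")
  validate_struct_model(obj)
}

validate_struct_model <- function(model) {
  res <- sort(unique(model$atoms$residue))
  if (!identical(as.integer(res), seq_len(model$n_residues))) {
    abort(sprintf("protein %s: residue indices must be 1..%d contiguous and every residue must have >= 1 atom",
                  model$protein_id, model$n_residues))
  }
  if (any(!is.finite(model$plddt)) || any(model$plddt < 0 | model$plddt > 100)) {
    abort(sprintf("protein %s: pLDDT must lie in [0, 100]", model$protein_id))
  }
  if (any(!is.finite(as.matrix(model$atoms[c("x", "y", "z")])))) {
    abort(sprintf("protein %s: non-finite atom coordinates", model$protein_id))
  }
  model
}

#' @export
print.struct_model <- function(x, ...) {
  cat(sprintf("<struct_model> %s: %d residues, %d atoms, mean pLDDT %.1f\n",
              x$protein_id, x$n_residues, nrow(x$atoms), mean(x$plddt)))
  invisible(x)
}

#' Predicted aligned error matrix
#'
#' @param pae Square numeric matrix of predicted aligned error (Angstrom),
#'   one row/column per residue.
#' @param protein_id Character identifier, matched against the structure at
#'   contact extraction.
#'
#' @return A `pae_matrix` object.
#' @export
pae_matrix <- function(pae, protein_id) {
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae)) abort("PAE matrix must be square")
  if (any(!is.finite(pae)) || any(pae < 0)) {
    abort("PAE entries must be finite and non-negative")
  }
  structure(pae, protein_id = as.character(protein_id), class = "pae_matrix")
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat(sprintf("<pae_matrix> %s: %d x %d, mean %.2f A\n",
              attr(x, "protein_id"), nrow(x), ncol(x), mean(x)))
  invisible(x)
}
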