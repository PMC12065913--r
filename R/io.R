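#' Read a predicted structure from an mmCIF file
#'
#' Reads an AlphaFold-DB-dialect mmCIF file (single chain, per-residue
#' confidence stored in the B-factor field) into a [struct_model()].
#'
#' @param path Path to the mmCIF file.
#' @param protein_id Identifier; defaults to the file name without
#'   extension.
#'
#' @return A [struct_model()].
#' @export
read_structure_cif <- function(path, protein_id = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  protein_id <- protein_id %||% sub("\\.cif$", "", basename(path))
  cif <- tryCatch(suppressWarnings(bio3d::read.cif(path)),
                  error = function(e) {
                    abort(sprintf("failed to parse mmCIF %s: %s", path,
                                  conditionMessage(e)))
                  })
  at <- cif$atom
  if (is.null(at) || nrow(at) == 0) {
    abort(sprintf("mmCIF %s contains no atom records", path))
  }
  atoms <- tibble(residue = as.integer(at$resno),
                  element = as.character(at$elesy),
                  x = as.numeric(at$x), y = as.numeric(at$y),
                  z = as.numeric(at$z))
  plddt <- vapply(split(as.numeric(at$b), atoms$residue), function(b) b[1],
                  numeric(1))
  plddt <- plddt[order(as.integer(names(plddt)))]
  struct_model(protein_id, atoms, unname(plddt))
}

#' Write a structure to an mmCIF file
#'
#' Emits a minimal AlphaFold-DB-dialect `atom_site` loop; the per-residue
#' pLDDT goes to the B-factor column. Round-trips through
#' [read_structure_cif()] at 0.001 Angstrom precision.
#'
#' @param model A [struct_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(model, path) {
  at <- model$atoms
  n <- nrow(at)
  lines <- c(
    sprintf("data_%s", model$protein_id),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s C%d . ALA A 1 %d ? %.4f %.4f %.4f 1.00 %.2f %d A 1",
            seq_len(n), at$element, seq_len(n), at$residue,
            at$x, at$y, at$z, model$plddt[at$residue], at$residue),
    "#")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write AlphaFold-DB predicted-aligned-error JSON
#'
#' The AlphaFold-DB scheme is a JSON array holding one object with key
#' `"predicted_aligned_error"` (row-major n x n integer matrix) and
#' `"max_predicted_aligned_error"`.
#'
#' @param path File path.
#' @param protein_id Identifier; defaults to the file name.
#' @return `read_pae_json()` returns a [pae_matrix()];
#'   `write_pae_json()` returns `path` invisibly.
#' @export
read_pae_json <- function(path, protein_id = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  protein_id <- protein_id %||% sub("\\.json$", "", basename(path))
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) {
                    abort(sprintf("failed to parse PAE JSON %s: %s", path,
                                  conditionMessage(e)))
                  })
  if (is.data.frame(obj)) obj <- as.list(obj)
  m <- obj[["predicted_aligned_error"]]
  if (is.null(m)) {
    abort(sprintf("%s: no 'predicted_aligned_error' key", path))
  }
  if (is.list(m) && !is.matrix(m)) m <- do.call(rbind, m)
  if (is.array(m) && length(dim(m)) == 3) m <- m[1, , ]
  pae_matrix(m, protein_id)
}

#' @rdname read_pae_json
#' @param pae A [pae_matrix()].
#' @export
write_pae_json <- function(pae, path) {
  obj <- list(list(predicted_aligned_error = unclass(pae),
                   max_predicted_aligned_error = max(pae)))
  jsonlite::write_json(obj, path, digits = 4, matrix = "rowmajor")
  invisible(path)
}

#' Read / write codon count tables
#'
#' Tab-separated long format with columns `gene_id`, `replicate`,
#' `library`, `codon`, `count`. Library sizes travel in header comment
#' lines of the form `#library_size<TAB>replicate<TAB>library<TAB>size`.
#'
#' @param path File path.
#' @return `read_counts_tsv()` returns the long count tibble with the
#'   `library_sizes` attribute set.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  hdr <- readLines(path, n = 50)
  ls_lines <- grep("^#library_size\t", hdr, value = TRUE)
  counts <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                            progress = FALSE)
  need <- c("gene_id", "replicate", "library", "codon", "count")
  if (!all(need %in% names(counts))) {
    abort(sprintf("%s: need columns %s", path, paste(need, collapse = ", ")))
  }
  if (any(counts$count < 0)) {
    abort(sprintf("%s: negative counts (first at row %d)", path,
                  which(counts$count < 0)[1]))
  }
  counts <- as_tibble(counts)
  lib_sizes <- NULL
  if (length(ls_lines) > 0) {
    parts <- strsplit(ls_lines, "\t", fixed = TRUE)
    lib_sizes <- tibble(replicate = vapply(parts, `[[`, "", 2),
                        library = vapply(parts, `[[`, "", 3),
                        library_size = as.numeric(vapply(parts, `[[`, "", 4)))
    gene_tot <- counts |>
      group_by(.data$gene_id, .data$replicate, .data$library) |>
      summarise(tot = sum(.data$count), .groups = "drop") |>
      left_join(lib_sizes, by = c("replicate", "library"))
    if (any(gene_tot$tot > gene_tot$library_size, na.rm = TRUE)) {
      abort(sprintf("%s: a gene has more counts than its library size", path))
    }
  }
  attr(counts, "library_sizes") <- lib_sizes
  counts
}

#' @rdname read_counts_tsv
#' @param counts Long count tibble; its `library_sizes` attribute (or the
#'   `lib_sizes` argument) is written to the header.
#' @param lib_sizes Optional library-size tibble.
#' @export
write_counts_tsv <- function(counts, path, lib_sizes = NULL) {
  lib_sizes <- lib_sizes %||% attr(counts, "library_sizes")
  hdr <- if (!is.null(lib_sizes)) {
    sprintf("#library_size\t%s\t%s\t%s", lib_sizes$replicate,
            lib_sizes$library,
            format(lib_sizes$library_size, scientific = FALSE, trim = TRUE))
  } else {
    character()
  }
  writeLines(hdr, path)
  readr::write_tsv(counts, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write domain candidate tables
#'
#' Tab-separated with columns `protein_id`, `start`, `end`, `rank`, `id`
#' (1-based inclusive coordinates).
#'
#' @param path File path.
#' @return A tibble of domain candidates.
#' @export
read_domains_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("protein_id", "start", "end", "rank", "id")
  if (!all(need %in% names(d))) {
    abort(sprintf("%s: need columns %s", path, paste(need, collapse = ", ")))
  }
  bad <- which(d$start > d$end | d$start < 1)
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid interval at data row %d", path, bad[1]))
  }
  as_tibble(d)
}

#' @rdname read_domains_tsv
#' @param domains Domain tibble (with `protein_id` column or attribute).
#' @export
write_domains_tsv <- function(domains, path) {
  if (!"protein_id" %in% names(domains)) {
    domains$protein_id <- attr(domains, "protein_id") %||% NA_character_
  }
  readr::write_tsv(domains[c("protein_id", "start", "end", "rank", "id")],
                   path)
  invisible(path)
}

#' Write a contact map or profile table to TSV
#'
#' Plain `readr::write_tsv()` wrappers kept for a stable on-disk contract:
#' contact maps are written as `i`, `j`, `strength`, `domain_label` (plus
#' `protein_id`), profiles as produced by [binding_profile()] /
#' [windowed_enrichment()].
#'
#' @param x A tibble.
#' @param path Output path.
#' @export
write_profile_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Peaks as BED intervals
#'
#' Converts 1-based closed codon peak intervals ([binding_onset()]) to
#' BED-style 0-based half-open rows (`chrom` = gene id, `chromStart` =
#' start - 1, `chromEnd` = end).
#'
#' @param onsets Output of [binding_onset()].
#' @return A tibble with `chrom`, `chromStart`, `chromEnd`, `name`.
#' @export
peaks_to_bed <- function(onsets) {
  onsets |>
    select("gene_id", "peaks") |>
    tidyr::unnest("peaks") |>
    mutate(chrom = .data$gene_id, chromStart = .data$start - 1L,
           chromEnd = .data$end,
           name = sprintf("%s_peak%d", .data$gene_id,
                          row_number())) |>
    select("chrom", "chromStart", "chromEnd", "name")
}

#' Read / write a run configuration
#'
#' YAML with sections `contact`, `model`, `serp` plus optional
#' `gene_exclude` (genes dropped from meta-analyses, e.g. elongation
#' factors with alignment artifacts) and `seed`. Every default equals the
#' corresponding parameter-constructor default; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A list with elements `contact` ([contact_params()]), `model`
#'   ([model_params()]), `serp` ([serp_params()]), `gene_exclude`
#'   (character) and `seed` (integer or `NULL`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  known <- c("contact", "model", "serp", "gene_exclude", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(sprintf("%s: unknown config key(s): %s", path,
                  paste(extra, collapse = ", ")))
  }
  build <- function(ctor, args, section) {
    ok <- names(formals(ctor))
    extra <- setdiff(names(args), ok)
    if (length(extra) > 0) {
      abort(sprintf("%s: unknown key(s) in section '%s': %s", path, section,
                    paste(extra, collapse = ", ")))
    }
    do.call(ctor, args)
  }
  if (!is.null(raw$serp$binding_value_map)) {
    raw$serp$binding_value_map <- unlist(raw$serp$binding_value_map)
  }
  list(contact = build(contact_params, raw$contact %||% list(), "contact"),
       model = build(model_params, raw$model %||% list(), "model"),
       serp = build(serp_params, raw$serp %||% list(), "serp"),
       gene_exclude = as.character(raw$gene_exclude %||% character()),
       seed = raw$seed)
}

#' @rdname read_config
#' @param config A configuration list as returned by [read_config()].
#' @export
write_config <- function(config, path) {
  strip <- function(p) {
    p <- unclass(p)
    p$binding_value_map <- as.list(p$binding_value_map)
    p[!vapply(p, is.null, logical(1))]
  }
  yaml::write_yaml(list(contact = unclass(config$contact),
                        model = unclass(config$model),
                        serp = strip(config$serp),
                        gene_exclude = config$gene_exclude,
                        seed = config$seed), path)
  invisible(path)
}

#' Write a run log
#'
#' Records timestamp, configuration snapshot, seeds, md5 digests of the
#' input files and per-stage record counts, so any profile or score can
#' be traced back to its inputs.
#'
#' @param path Output YAML path.
#' @param config Configuration list (see [read_config()]).
#' @param inputs Character vector of input file paths (digested).
#' @param records Named list/vector of per-stage record counts.
#' @return The log as a list, invisibly.
#' @export
write_run_log <- function(path, config = NULL, inputs = character(),
                          records = list()) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  log <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = config$seed,
              config = if (!is.null(config)) {
                list(contact = unclass(config$contact),
                     model = unclass(config$model),
                     serp = lapply(unclass(config$serp), function(x) {
                       if (is.numeric(x) && !is.null(names(x))) as.list(x)
                       else x
                     }),
                     gene_exclude = config$gene_exclude)
              },
              input_digests = digests,
              record_counts = as.list(records))
  yaml::write_yaml(log, path)
  invisible(log)
}
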