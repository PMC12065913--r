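#' Generate a toy structure with planted domain architecture
#'
#' Builds a synthetic protein whose residues form dense intra-domain
#' contact clusters, with configurable inter-domain interfaces and
#' AlphaFold-style confidence fields, so that contact extraction, domain
#' assignment and the binding models can be exercised against known truth.
#' Each domain is a compact cloud (residue centers uniform in a ball of
#' radius `domain_radius`); linker residues are placed far from everything
#' and get sub-threshold pLDDT. Every adjacent domain pair shares one
#' planted interface contact of strength `interface_strength` (half the
#' atoms contributed by each side), realized by extra atoms at an
#' interface site between the domain clouds; `interface_strength = 0`
#' plants no interface.
#'
#' @param n_domains Number of domains.
#' @param residues_per_domain Residues per domain (scalar or vector of
#'   length `n_domains`).
#' @param linker_len Residues between consecutive domains.
#' @param interface_strength Planted contact strength (atom-count units,
#'   even) of each adjacent-domain interface. Default 40.
#' @param atoms_per_residue Atoms per residue in the domain clouds.
#'   Default 5.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param domain_radius Radius (Angstrom) of a domain cloud. Default 4.5.
#' @param domain_sep Distance (Angstrom) between domain centers; must be
#'   large enough that only planted interfaces cross domains. Default 60.
#' @param plddt_domain,plddt_linker Per-residue confidence assigned inside
#'   domains / on linkers (defaults 90 and 60, i.e. linkers fall below the
#'   standard filter).
#' @param pae_intra,pae_inter,pae_interface Predicted-aligned-error values
#'   (Angstrom) for same-domain pairs, cross-domain pairs, and the planted
#'   interface pairs (defaults 2, 15, 3: cross-domain pairs fail the
#'   standard 5 A filter except at interfaces).
#'
#' @return A list with elements `model` ([struct_model()]), `pae`
#'   ([pae_matrix()]), `candidates` (domain candidate tibble) and `truth`
#'   (list with planted `domains` and `interfaces`).
#' @export
make_structure <- function(n_domains = 2, residues_per_domain = 60,
                           linker_len = 10, interface_strength = 40,
                           atoms_per_residue = 5, seed = 1,
                           domain_radius = 4.5, domain_sep = 60,
                           plddt_domain = 90, plddt_linker = 60,
                           pae_intra = 2, pae_inter = 15,
                           pae_interface = 3) {
  stopifnot(n_domains >= 1, linker_len >= 0, atoms_per_residue >= 1,
            interface_strength >= 0, interface_strength %% 2 == 0)
  rpd <- rep_len(residues_per_domain, n_domains)
  if (domain_sep < 2 * domain_radius + 12) abort("domains would collide")
  with_seed(seed, {
    starts <- cumsum(c(1L, head(rpd, -1L) + linker_len))
    ends <- starts + rpd - 1L
    N <- ends[n_domains]
    plddt <- rep(plddt_linker, N)
    dom_of <- integer(N)
    centers <- cbind(domain_sep * (seq_len(n_domains) - 1), 0, 0)
    atom_rows <- list()
    res_xyz <- matrix(NA_real_, N, 3)
    for (d in seq_len(n_domains)) {
      for (r in starts[d]:ends[d]) {
        res_xyz[r, ] <- centers[d, ] + runif_ball(domain_radius)
        dom_of[r] <- d
        plddt[r] <- plddt_domain
      }
    }
    # linkers: well separated from clouds and from each other
    lk <- which(dom_of == 0L)
    for (t in seq_along(lk)) {
      res_xyz[lk[t], ] <- c(8 * t, 60, 0)
    }
    for (r in seq_len(N)) {
      jit <- matrix(runif(3 * atoms_per_residue, -0.3, 0.3),
                    ncol = 3)
      atom_rows[[r]] <- tibble(residue = r,
                               x = res_xyz[r, 1] + jit[, 1],
                               y = res_xyz[r, 2] + jit[, 2],
                               z = res_xyz[r, 3] + jit[, 3])
    }
    pae <- matrix(pae_inter, N, N)
    for (d in seq_len(n_domains)) {
      span <- starts[d]:ends[d]
      pae[span, span] <- pae_intra
    }
    pae[cbind(seq_len(N), seq_len(N))] <- 0
    interfaces <- tibble(i = integer(), j = integer(),
                         strength = integer())
    if (interface_strength > 0 && n_domains > 1) {
      m <- interface_strength %/% 2L
      for (d in seq_len(n_domains - 1L)) {
        a <- starts[d] + rpd[d] %/% 2L
        b <- starts[d + 1L] + rpd[d + 1L] %/% 2L
        site <- (centers[d, ] + centers[d + 1L, ]) / 2 + c(0, -30 - 12 * d, 0)
        ja <- matrix(runif(3 * m, -0.3, 0.3), ncol = 3)
        jb <- matrix(runif(3 * m, -0.3, 0.3), ncol = 3)
        atom_rows[[length(atom_rows) + 1L]] <-
          tibble(residue = a, x = site[1] - 1 + ja[, 1],
                 y = site[2] + ja[, 2], z = site[3] + ja[, 3])
        atom_rows[[length(atom_rows) + 1L]] <-
          tibble(residue = b, x = site[1] + 1 + jb[, 1],
                 y = site[2] + jb[, 2], z = site[3] + jb[, 3])
        pae[a, b] <- pae[b, a] <- pae_interface
        interfaces <- bind_rows(interfaces,
                                tibble(i = a, j = b,
                                       strength = 2L * m))
      }
    }
    atoms <- bind_rows(atom_rows) |> arrange(.data$residue)
    pid <- sprintf("synth_%dx%d_s%d", n_domains, rpd[1], seed)
    model <- struct_model(pid, atoms, plddt)
    candidates <- tibble(start = starts, end = ends,
                         rank = seq_len(n_domains),
                         id = sprintf("D%d", seq_len(n_domains)))
    list(model = model, pae = pae_matrix(pae, pid),
         candidates = candidates,
         truth = list(domains = tibble(start = starts, end = ends),
                      interfaces = interfaces))
  })
}

runif_ball <- function(r) {
  repeat {
    p <- runif(3, -r, r)
    if (sum(p^2) <= r^2) return(p)
  }
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate two-replicate SeRP codon counts with planted enrichment
#'
#' Per-codon footprint coverage is overdispersed through a gamma dwell
#' factor `lambda(c) ~ Gamma(shape = phi, rate = phi)` shared between the
#' selected and total libraries (and, by default, between replicates):
#' ribosome dwell-time variation affects both libraries of the same sample
#' identically, which is precisely why SeRP works with enrichment ratios.
#' Total counts are Poisson(`mu * lambda`), hence marginally negative
#' binomial with mean `mu` and dispersion `phi`; selected counts are
#' Poisson(`mu * e(c) * s * lambda`) with `s` the selected/total
#' library-size ratio. `shared_dispersion = FALSE` instead draws totals
#' directly from the negative binomial and selected counts from
#' Poisson(`mu * e(c) * s`) with no shared factor.
#'
#' @param enrichment Non-negative truth enrichment profile `e(c)`; its
#'   length is the gene length in codons.
#' @param mu Mean total-translatome coverage per codon. Default 50.
#' @param phi Dispersion (gamma shape; smaller = more overdispersed).
#'   Default 5.
#' @param gene_id Gene identifier. Default `"gene1"`.
#' @param replicates Number of replicates. Default 2.
#' @param lib_selected,lib_total Library sizes (total mapped counts) of
#'   the selected and total libraries; only their ratio enters the
#'   simulation. Defaults 1e7 each.
#' @param seed Integer seed.
#' @param shared_dispersion Share the dwell factor between libraries (and
#'   replicates). Default `TRUE`.
#'
#' @return A long tibble with `gene_id`, `replicate`, `library`, `codon`,
#'   `count`, carrying a `library_sizes` attribute (tibble `replicate`,
#'   `library`, `library_size`).
#' @export
simulate_serp <- function(enrichment, mu = 50, phi = 5, gene_id = "gene1",
                          replicates = 2, lib_selected = 1e7,
                          lib_total = 1e7, seed = 1,
                          shared_dispersion = TRUE) {
  stopifnot(all(is.finite(enrichment)), all(enrichment >= 0),
            mu > 0, phi > 0, replicates >= 1)
  N <- length(enrichment)
  s <- lib_selected / lib_total
  with_seed(seed, {
    lam_shared <- rgamma(N, shape = phi, rate = phi)
    rows <- purrr::map(seq_len(replicates), function(r) {
      lam <- if (shared_dispersion) lam_shared else NULL
      tot <- if (shared_dispersion) {
        rpois(N, mu * lam)
      } else {
        rnbinom(N, mu = mu, size = phi)
      }
      sel_mean <- mu * enrichment * s * (if (shared_dispersion) lam else 1)
      sel <- rpois(N, sel_mean)
      bind_rows(
        tibble(gene_id = gene_id, replicate = sprintf("rep%d", r),
               library = "selected", codon = seq_len(N), count = sel),
        tibble(gene_id = gene_id, replicate = sprintf("rep%d", r),
               library = "total", codon = seq_len(N), count = tot))
    })
    out <- bind_rows(rows)
    attr(out, "library_sizes") <-
      tidyr::expand_grid(replicate = sprintf("rep%d", seq_len(replicates)),
                         library = c("selected", "total")) |>
      mutate(library_size = if_else(.data$library == "selected",
                                    lib_selected, lib_total))
    out
  })
}

#' Self-consistent end-to-end fixture with planted truth
#'
#' Builds a panel of synthetic multi-domain genes, runs the TF binding
#' model on their planted structures, converts each raw TF profile into a
#' truth enrichment profile (`e = 1 + 3 * raw / max(raw)`, i.e. baseline 1
#' and peak 4), and simulates two-replicate SeRP counts from it. Because
#' the truth enrichment *is* the model prediction, the fixture supports
#' closed-loop tests: NCC between model and recovered SeRP profile, and
#' onset recovery against the first codon with `e > 1.5`.
#'
#' @param seed Integer seed controlling the whole panel.
#' @param n_genes Number of genes (default 10).
#' @param mu Mean per-codon coverage (default 50).
#' @param phi Dispersion (default 5).
#' @param interface_strength Planted interface strength (default 40).
#'
#' @return A list with `structures` (named list of [make_structure()]
#'   outputs), `counts` (combined count tibble with `library_sizes`
#'   attribute), `predictions` (tibble from [binding_profile()] for all
#'   genes) and `truth` (tibble `gene_id`, `n_domains`, `n_residues`,
#'   `onset_true`, `score_true`, `enrichment` list-column).
#' @export
end_to_end_fixture <- function(seed = 1, n_genes = 10, mu = 50, phi = 5,
                               interface_strength = 40) {
  cfg <- with_seed(seed, {
    tibble(gene = sprintf("g%02d", seq_len(n_genes)),
           n_domains = rep_len(c(2L, 2L, 3L, 2L, 3L), n_genes),
           rpd = sample(50:70, n_genes, replace = TRUE),
           linker = sample(8:15, n_genes, replace = TRUE),
           sub_seed = sample.int(1e6, n_genes))
  })
  structures <- list()
  preds <- list()
  counts <- list()
  truth <- list()
  for (k in seq_len(nrow(cfg))) {
    st <- make_structure(n_domains = cfg$n_domains[k],
                         residues_per_domain = cfg$rpd[k],
                         linker_len = cfg$linker[k],
                         interface_strength = interface_strength,
                         seed = cfg$sub_seed[k])
    cmap <- extract_contacts(st$model, st$pae)
    ann <- assign_domains(st$candidates, st$model$n_residues,
                          protein_id = st$model$protein_id)
    cmap <- label_contact_domains(cmap, ann)
    prof <- binding_profile(cmap, ann, n_residues = st$model$n_residues)
    prof$protein_id <- cfg$gene[k]
    e <- if (max(prof$tf_raw) > 0) 1 + 3 * prof$tf_raw / max(prof$tf_raw)
    else rep(1, nrow(prof))
    cnt <- simulate_serp(e, mu = mu, phi = phi, gene_id = cfg$gene[k],
                         seed = cfg$sub_seed[k] + 1L)
    structures[[cfg$gene[k]]] <- st
    preds[[k]] <- prof
    counts[[k]] <- cnt
    truth[[k]] <- tibble(gene_id = cfg$gene[k],
                         n_domains = cfg$n_domains[k],
                         n_residues = st$model$n_residues,
                         onset_true = if (any(e > 1.5)) min(which(e > 1.5))
                         else NA_integer_,
                         score_true = max(e),
                         enrichment = list(e))
  }
  all_counts <- bind_rows(counts)
  attr(all_counts, "library_sizes") <- attr(counts[[1]], "library_sizes")
  list(structures = structures, counts = all_counts,
       predictions = bind_rows(preds), truth = bind_rows(truth))
}
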