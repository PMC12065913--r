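# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: plain loops,
# no vectorized shortcuts.

# All-pairs O(A^2) contact oracle: for every residue pair, scan every atom
# pair and apply the filters literally.
oracle_contacts <- function(model, pae, params = contact_params()) {
  at <- as.data.frame(model$atoms)
  n <- model$n_residues
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i < params$min_seq_sep) next
      if (model$plddt[i] < params$min_plddt ||
          model$plddt[j] < params$min_plddt) next
      pv <- if (params$pae_rule == "max") max(pae[i, j], pae[j, i]) else
        min(pae[i, j], pae[j, i])
      if (pv > params$max_pae) next
      ai <- which(at$residue == i)
      aj <- which(at$residue == j)
      involved <- c()
      npairs <- 0L
      for (p in ai) {
        for (q in aj) {
          d <- sqrt((at$x[p] - at$x[q])^2 + (at$y[p] - at$y[q])^2 +
                      (at$z[p] - at$z[q])^2)
          if (d <= params$max_atom_dist) {
            involved <- union(involved, c(p, q))
            npairs <- npairs + 1L
          }
        }
      }
      if (npairs > 0) {
        s <- if (params$strength_mode == "atoms") length(involved) else npairs
        out[[length(out) + 1]] <- data.frame(i = i, j = j, strength = s)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(), j = integer(), strength = integer()))
  }
  do.call(rbind, out)
}

# Random unstructured toy protein (no planted architecture): atoms in a box,
# random confidence and PAE, so boundary cases of every filter are hit.
random_structure <- function(seed, n_res = 15, atoms_per_res = 3,
                             box = 12) {
  set.seed(seed)
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    data.frame(residue = r,
               x = runif(atoms_per_res, 0, box),
               y = runif(atoms_per_res, 0, box),
               z = runif(atoms_per_res, 0, box))
  }))
  plddt <- runif(n_res, 40, 100)
  pae <- matrix(runif(n_res^2, 0, 10), n_res, n_res)
  diag(pae) <- 0
  list(model = struct_model(sprintf("rand%d", seed), atoms, plddt),
       pae = pae_matrix(pae, sprintf("rand%d", seed)))
}

# Memoized brute-force DTW recursion (top-down, independent of the DP).
oracle_dtw <- function(x, y, method = "abs") {
  memo <- new.env()
  cost <- function(a, b) if (method == "abs") abs(a - b) else (a - b)^2
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == 1 && j == 1) {
      cost(x[1], y[1])
    } else if (i == 1) {
      rec(1, j - 1) + cost(x[1], y[j])
    } else if (j == 1) {
      rec(i - 1, 1) + cost(x[i], y[1])
    } else {
      cost(x[i], y[j]) + min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1))
    }
    memo[[key]] <- v
    v
  }
  v <- rec(length(x), length(y))
  if (method == "sqeuclid") sqrt(v) else v
}

# Direct per-contact category rule, evaluated one contact at a time.
oracle_category <- function(i, j, L, tunnel_len = 30) {
  emerged <- function(r) r <= L - tunnel_len
  if (!emerged(i)) "I" else if (!emerged(j)) "II" else "III"
}

# A tiny hand-checkable contact map: two domains [1,40] and [51,90] with
# intra contacts plus one interface contact.
toy_two_domain <- function() {
  contacts <- tibble::tibble(
    protein_id = "toy",
    i = c(5L, 10L, 20L, 55L, 60L, 20L),
    j = c(25L, 30L, 35L, 80L, 85L, 70L),
    strength = c(30L, 40L, 25L, 35L, 30L, 12L),
    domain_label = "unassigned")
  attr(contacts, "protein_id") <- "toy"
  attr(contacts, "n_residues") <- 100L
  domains <- tibble::tibble(start = c(1L, 51L), end = c(40L, 90L),
                            rank = 1:2, id = c("D1", "D2"))
  attr(domains, "protein_id") <- "toy"
  attr(domains, "n_residues") <- 100L
  list(contacts = label_contact_domains(contacts, domains),
       domains = domains)
}

expect_tbl_equal <- function(a, b) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b),
                         ignore_attr = TRUE)
}
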