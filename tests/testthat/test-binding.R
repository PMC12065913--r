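# naive per-L re-implementation of the whole scoring rule, loop-wise
oracle_profile <- function(contacts, domains, N, params = model_params()) {
  res <- data.frame(codon = seq_len(N), tf = 0, dnak = 0, mg = 0)
  for (L in seq_len(N)) {
    e <- L - params$tunnel_len
    cat <- character(nrow(contacts))
    for (k in seq_len(nrow(contacts))) {
      cat[k] <- oracle_category(contacts$i[k], contacts$j[k], L,
                                params$tunnel_len)
    }
    elig_from <- function(mask) {
      s <- numeric(N)
      for (k in which(mask)) {
        s[contacts$i[k]] <- s[contacts$i[k]] + contacts$strength[k]
        s[contacts$j[k]] <- s[contacts$j[k]] + contacts$strength[k]
      }
      s[s < params$res_strength_min] <- 0
      elig <- logical(N)
      run <- 0
      for (r in L:1) {
        run <- run + s[r]
        elig[r] <- run > params$cum_threshold
      }
      elig
    }
    elig_tf <- elig_from(cat == "III")
    elig_dk <- elig_from(cat == "III" & contacts$domain_label != "inter")
    for (k in seq_len(nrow(contacts))) {
      str <- contacts$strength[k]; ik <- contacts$i[k]
      if (cat[k] == "II" && contacts$domain_label[k] == "intra" &&
          elig_tf[ik]) res$tf[L] <- res$tf[L] + str
      if (cat[k] != "I" && contacts$domain_label[k] == "inter" &&
          elig_dk[ik]) res$dnak[L] <- res$dnak[L] + str
    }
    if (e >= 1) {
      tot <- numeric(N)
      for (k in seq_len(nrow(contacts))) {
        tot[contacts$i[k]] <- tot[contacts$i[k]] + contacts$strength[k]
        tot[contacts$j[k]] <- tot[contacts$j[k]] + contacts$strength[k]
      }
      for (d in seq_len(nrow(domains))) {
        if (domains$end[d] > L) {
          for (r in domains$start[d]:domains$end[d]) {
            if (r <= e) res$mg[L] <- res$mg[L] + tot[r]
          }
        }
      }
    }
  }
  res
}

test_that("nascent state splits the chain into emerged and tunnel residues", {
  s <- nascent_state(30, 100)
  expect_length(s$emerged, 0)
  expect_equal(s$tunnel, 1:30)
  expect_equal(nascent_state(31, 100)$emerged, 1L)
  expect_equal(nascent_state(100, 100)$emerged, 1:70)
  s2 <- nascent_state(55, 100)
  expect_equal(sort(c(s2$emerged, s2$tunnel)), 1:55)
  expect_length(intersect(s2$emerged, s2$tunnel), 0)
  expect_error(nascent_state(0, 10), "outside")
  expect_error(nascent_state(11, 10), "outside")
})

test_that("contact categories follow the emergence rule at each length", {
  cm <- tibble::tibble(i = 5L, j = 40L, strength = 10L,
                       domain_label = "intra")
  expect_equal(categorize_contacts(cm, 20)$category, "I")
  expect_equal(categorize_contacts(cm, 45)$category, "II")
  expect_equal(categorize_contacts(cm, 75)$category, "III")
})

test_that("categories match the per-contact oracle and partition the contacts", {
  set.seed(5)
  for (rep in 1:50) {
    N <- sample(40:120, 1)
    n_c <- sample(5:25, 1)
    i <- sample(seq_len(N - 6), n_c, replace = TRUE)
    j <- pmin(N, i + sample(6:30, n_c, replace = TRUE))
    cm <- tibble::tibble(i = i, j = j, strength = 10L,
                         domain_label = "unassigned")
    prev <- rep(1L, n_c)
    for (L in seq_len(N)) {
      got <- categorize_contacts(cm, L)$category
      want <- mapply(oracle_category, i, j, MoreArgs = list(L = L))
      expect_identical(got, unname(want))
      # exactly one category per contact, and monotone I -> II -> III
      idx <- match(got, c("I", "II", "III"))
      expect_false(any(is.na(idx)))
      expect_true(all(idx >= prev))
      prev <- idx
    }
  }
})

test_that("delayed folding gates binding on accumulated compact structure", {
  mp <- model_params(res_strength_min = 20, cum_threshold = 750)
  # single category-III contact of strength 800 at residue k = 40
  cm <- tibble::tibble(i = 34L, j = 40L, strength = 800L,
                       domain_label = "intra")
  cc <- categorize_contacts(cm, 70)
  elig <- folding_eligibility(cc, 70, 100, mp)
  expect_equal(which(elig), 1:40)

  # everything below the per-residue floor is ignored entirely
  weak <- tibble::tibble(i = c(10L, 20L), j = c(30L, 40L),
                         strength = c(19L, 15L), domain_label = "intra")
  ccw <- categorize_contacts(weak, 80)
  expect_false(any(folding_eligibility(ccw, 80, 100, mp)))

  # empty map: nothing eligible
  empty <- tibble::tibble(i = integer(), j = integer(),
                          strength = integer(), domain_label = character())
  cce <- categorize_contacts(empty, 50)
  expect_false(any(folding_eligibility(cce, 50, 100, mp)))
})

test_that("TF/DnaK/molten-globule scores match hand-computed toy values", {
  toy <- toy_two_domain()
  mp <- model_params(res_strength_min = 5, cum_threshold = 50)
  # L = 60: (20,35) is the only intra category-II contact, residue 20
  # eligible (cumulative III strength 70 > 50)
  expect_equal(tf_raw(toy$contacts, 60, mp), 25)
  expect_equal(dnak_raw(toy$contacts, 60, mp), 12)
  # L = 75: the D1 contacts are satisfied, no intra II left
  expect_equal(tf_raw(toy$contacts, 75, mp), 0)
  # interface stays unsatisfied through termination
  expect_equal(dnak_raw(toy$contacts, 75, mp), 12)
  expect_equal(dnak_raw(toy$contacts, 100, mp), 12)
  # nothing scores before anything leaves the tunnel
  for (L in c(10, 30)) {
    expect_equal(tf_raw(toy$contacts, L, mp), 0)
    expect_equal(dnak_raw(toy$contacts, L, mp), 0)
  }
  # structured fraction at L = 60: residues {5,10,25,30} of 30 emerged
  expect_equal(structured_fraction(toy$contacts, 60), 4 / 30)
  expect_equal(structured_fraction(toy$contacts, 31), 0)
})

test_that("molten globule satisfies a domain the moment it is fully attached", {
  cm <- tibble::tibble(protein_id = "mg",
                       i = c(10L, 20L, 30L), j = c(40L, 50L, 60L),
                       strength = c(30L, 20L, 10L),
                       domain_label = "intra")
  attr(cm, "n_residues") <- 100L
  dom <- tibble::tibble(start = 1L, end = 80L, rank = 1L, id = "D1")
  # L = 60: emerged residues 1..30 of the incomplete domain contribute
  # their total strengths: tot[10] = 30, tot[20] = 20, tot[30] = 10
  expect_equal(molten_globule_raw(cm, dom, 60), 60)
  # L = 79: domain still incomplete, emerged 1..49: + tot[40] = 30
  expect_equal(molten_globule_raw(cm, dom, 79), 90)
  # all 80 residues attached: satisfied immediately
  expect_equal(molten_globule_raw(cm, dom, 80), 0)
  expect_equal(molten_globule_raw(cm, dom, 100), 0)
  expect_equal(molten_globule_raw(cm, dom, 20), 0)  # nothing emerged
})

test_that("single-domain proteins never produce DnaK signal", {
  st <- make_structure(n_domains = 1, residues_per_domain = 60, seed = 3)
  prof <- predict_gene(st$model, st$pae, st$candidates)
  expect_true(all(prof$dnak_raw == 0))
  expect_true(any(prof$tf_raw > 0))
})

test_that("profile normalization maps the raw range onto [floor, score]", {
  expect_equal(normalize_profile(c(0, 10, 5), 2.25), c(0.25, 2.25, 1.25))
  expect_equal(normalize_profile(rep(0, 5), 3), rep(0.25, 5))
  raw <- c(1, 8, 3, 8, 2)
  norm <- normalize_profile(raw, 4.2)
  expect_equal(norm[which.max(raw)], 4.2)
  expect_equal(min(norm), 0.25)
  expect_error(normalize_profile(numeric(0), 1), "empty")
  expect_error(normalize_profile(1:3, 0), "positive")
})

test_that("binding_profile equals the naive per-length re-implementation", {
  mp <- model_params(res_strength_min = 5, cum_threshold = 40,
                     tunnel_len = 10)
  set.seed(9)
  for (rep in 1:5) {
    N <- 50
    n_c <- 15
    i <- sample(1:(N - 6), n_c, replace = TRUE)
    j <- pmin(N, i + sample(6:25, n_c, replace = TRUE))
    keep <- !duplicated(paste(i, j))
    dom <- tibble::tibble(start = c(1L, 28L), end = c(25L, 50L),
                          rank = 1:2, id = c("D1", "D2"))
    cm <- tibble::tibble(protein_id = "o", i = i[keep], j = j[keep],
                         strength = sample(5:40, sum(keep), replace = TRUE),
                         domain_label = "unassigned")
    attr(cm, "protein_id") <- "o"; attr(cm, "n_residues") <- N
    cm <- label_contact_domains(cm, dom)
    got <- binding_profile(cm, dom, mp, N)
    want <- oracle_profile(cm, dom, N, mp)
    expect_equal(got$tf_raw, want$tf)
    expect_equal(got$dnak_raw, want$dnak)
    expect_equal(got$mg_raw, want$mg)
  }
})

test_that("scores are bounded by total strength and gate monotonically", {
  toy <- toy_two_domain()
  tot <- sum(toy$contacts$strength)
  mp_loose <- model_params(res_strength_min = 5, cum_threshold = 20)
  mp_tight <- model_params(res_strength_min = 35, cum_threshold = 120)
  for (L in seq(31, 100, by = 7)) {
    lo_tf <- tf_raw(toy$contacts, L, mp_loose)
    hi_tf <- tf_raw(toy$contacts, L, mp_tight)
    expect_lte(lo_tf, tot)
    expect_lte(hi_tf, lo_tf)
    expect_lte(dnak_raw(toy$contacts, L, mp_tight),
               dnak_raw(toy$contacts, L, mp_loose))
  }
})

test_that("predict_gene composes the stages and handles tiny proteins", {
  st <- make_structure(n_domains = 2, residues_per_domain = 50,
                       linker_len = 10, seed = 17)
  prof <- predict_gene(st$model, st$pae, st$candidates)
  # manual composition gives the same profile
  cmap <- extract_contacts(st$model, st$pae)
  ann <- assign_domains(st$candidates, st$model$n_residues)
  cmap <- label_contact_domains(cmap, ann)
  manual <- binding_profile(cmap, ann, n_residues = st$model$n_residues)
  expect_equal(prof$tf_raw, manual$tf_raw)
  expect_equal(prof$dnak_raw, manual$dnak_raw)

  # TF signal rises during domain-1 emergence and vanishes once D1 and its
  # C-terminal context are satisfied; DnaK persists to termination
  N <- st$model$n_residues
  d1_end <- st$candidates$end[1]
  expect_true(any(prof$tf_raw[31:(d1_end + 30)] > 0))
  expect_true(all(prof$tf_raw[1:30] == 0))
  expect_gt(prof$dnak_raw[N], 0)

  # protein entirely inside the tunnel: all-zero profiles
  tiny_atoms <- data.frame(residue = 1:20, x = 3 * (1:20), y = 0, z = 0)
  tiny <- struct_model("tiny", tiny_atoms, rep(90, 20))
  tp <- predict_gene(tiny, pae_matrix(matrix(1, 20, 20), "tiny"),
                     tibble::tibble(start = 1, end = 20, rank = 1, id = "D"))
  expect_true(all(tp$tf_raw == 0) && all(tp$dnak_raw == 0) &&
                all(tp$mg_raw == 0))
})
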