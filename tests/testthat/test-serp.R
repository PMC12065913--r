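make_counts <- function(sel, tot, gene = "g", reps = c("rep1", "rep2"),
                        lib_sel = 1e6, lib_tot = 1e6) {
  n <- length(sel)
  out <- dplyr::bind_rows(lapply(reps, function(r) {
    dplyr::bind_rows(
      tibble::tibble(gene_id = gene, replicate = r, library = "selected",
                     codon = seq_len(n), count = sel),
      tibble::tibble(gene_id = gene, replicate = r, library = "total",
                     codon = seq_len(n), count = tot))
  }))
  attr(out, "library_sizes") <-
    tidyr::expand_grid(replicate = reps,
                       library = c("selected", "total")) |>
    dplyr::mutate(library_size = ifelse(library == "selected", lib_sel,
                                        lib_tot))
  out
}

test_that("identical libraries give unit enrichment everywhere", {
  cnt <- make_counts(rep(10L, 60), rep(10L, 60))
  for (al in c("trailing", "centered")) {
    prof <- windowed_enrichment(cnt, params = serp_params(align = al))
    expect_true(all(abs(prof$ratio - 1) < 1e-12))
    expect_true(all(prof$ci_low <= prof$ratio + 1e-12))
    expect_true(all(prof$ci_high >= prof$ratio - 1e-12))
  }
})

test_that("windows with no selected reads give zero ratio and lower bound", {
  cnt <- make_counts(rep(0L, 40), rep(20L, 40), reps = "rep1")
  prof <- windowed_enrichment(cnt)
  expect_true(all(prof$ratio == 0))
  expect_true(all(prof$ci_low == 0))
  expect_true(all(prof$ci_high > 0))
  # no reads at all -> masked missing
  cnt0 <- make_counts(rep(0L, 40), rep(0L, 40), reps = "rep1")
  prof0 <- windowed_enrichment(cnt0)
  expect_true(all(prof0$missing))
  expect_true(all(is.na(prof0$ratio)))
})

test_that("the interval matches the closed-form Agresti-Coull formula", {
  # single-codon gene: the truncated window is exactly that codon
  cnt <- make_counts(25L, 25L, reps = "rep1")
  prof <- windowed_enrichment(cnt)
  z <- qnorm(0.975)  # 1.959964
  ntil <- 50 + z^2
  ptil <- (25 + z^2 / 2) / ntil
  half <- z * sqrt(ptil * (1 - ptil) / ntil)
  expect_equal(prof$ratio, 1)
  expect_equal(prof$ci_low, (ptil - half) / (1 - (ptil - half)),
               tolerance = 1e-10)
  expect_equal(prof$ci_high, (ptil + half) / (1 - (ptil + half)),
               tolerance = 1e-10)
})

test_that("library-size scaling enters the enrichment ratio", {
  cnt <- make_counts(rep(10L, 30), rep(10L, 30), reps = "rep1",
                     lib_sel = 2e6, lib_tot = 1e6)
  prof <- windowed_enrichment(cnt)
  expect_true(all(abs(prof$ratio - 0.5) < 1e-12))
})

test_that("CI ordering holds across simulated profiles", {
  cnt <- simulate_serp(enrichment = c(rep(1, 100), rep(4, 60), rep(1, 60)),
                       mu = 20, phi = 5, seed = 8)
  prof <- windowed_enrichment(cnt)
  ok <- !prof$missing
  expect_true(all(prof$ci_low[ok] <= prof$ratio[ok] + 1e-12))
  expect_true(all(prof$ratio[ok] <= prof$ci_high[ok] + 1e-12))
})

test_that("replicate averaging is the position-wise mean", {
  cnt <- make_counts(c(5L, 10L, 0L, 8L), c(10L, 10L, 10L, 2L),
                     reps = "rep1")
  p1 <- windowed_enrichment(cnt, window = 1)
  expect_tbl_equal(average_replicates(p1)[c("codon", "ratio")],
                   p1[c("codon", "ratio")])
  # two different replicates, window 1, hand-averaged
  cnt2 <- dplyr::bind_rows(
    dplyr::mutate(cnt, replicate = "rep1"),
    dplyr::mutate(make_counts(c(15L, 10L, 10L, 0L), c(10L, 10L, 10L, 2L),
                              reps = "rep1"), replicate = "rep2"))
  attr(cnt2, "library_sizes") <-
    tidyr::expand_grid(replicate = c("rep1", "rep2"),
                       library = c("selected", "total")) |>
    dplyr::mutate(library_size = 1e6)
  p2 <- windowed_enrichment(cnt2, window = 1)
  avg <- average_replicates(p2)
  r1 <- p2$ratio[p2$replicate == "rep1"]
  r2 <- p2$ratio[p2$replicate == "rep2"]
  expect_equal(avg$ratio, (r1 + r2) / 2)
  expect_equal(avg$n_reps, rep(2L, 4))
})

test_that("engagement score is the trimmed maximum of the averaged lower CI", {
  # all-zero selected counts: score 0
  cnt <- make_counts(rep(0L, 120), rep(30L, 120))
  expect_equal(engagement_score(cnt)$score, 0)

  # planted flat 4x enrichment with deep counts: score near 4
  set.seed(31)
  cnt4 <- simulate_serp(rep(4, 300), mu = 100, phi = 50, seed = 31)
  sc <- engagement_score(cnt4)$score
  expect_gte(sc, 3); expect_lte(sc, 5)

  # the first 30 and last 10 codons are excluded from the maximum: the
  # score equals the trimmed max of the averaged 45-codon lower CI, and a
  # peak whose windows culminate inside the head does not set the score
  sel <- rep(10L, 120); sel[1:25] <- 200L
  cnt_head <- make_counts(sel, rep(10L, 120))
  prof45 <- average_replicates(windowed_enrichment(cnt_head, 45))
  sc_head <- engagement_score(cnt_head)$score
  expect_equal(sc_head, max(prof45$ci_low[31:110]))
  expect_lt(sc_head, max(prof45$ci_low))

  expect_error(engagement_score(make_counts(rep(1L, 40), rep(1L, 40))),
               "too short")
})

test_that("binding onset follows the CI threshold rule", {
  mk_prof <- function(lo, hi, rep_id, gene = "g") {
    tibble::tibble(gene_id = gene, replicate = rep_id,
                   codon = seq_along(lo), ratio = (lo + hi) / 2,
                   ci_low = lo, ci_high = hi, missing = FALSE)
  }
  n <- 200
  lo <- rep(0.5, n); hi <- rep(1.0, n)
  lo[100:140] <- 2; hi[100:140] <- 3
  prof <- dplyr::bind_rows(mk_prof(lo, hi, "rep1"), mk_prof(lo, hi, "rep2"))
  call <- binding_onset(prof)
  expect_equal(call$onset, 100L)
  expect_equal(call$peaks[[1]], tibble::tibble(start = 100L, end = 140L))

  # all below threshold: no peaks
  none <- dplyr::bind_rows(mk_prof(rep(0.2, 50), rep(1.2, 50), "rep1"),
                           mk_prof(rep(0.2, 50), rep(1.2, 50), "rep2"))
  res <- binding_onset(none)
  expect_true(is.na(res$onset))
  expect_equal(res$n_peaks, 0L)

  # a 5-codon run is discarded
  lo5 <- rep(0.5, 60); hi5 <- rep(1.0, 60)
  lo5[20:24] <- 2; hi5[20:24] <- 3
  p5 <- dplyr::bind_rows(mk_prof(lo5, hi5, "rep1"), mk_prof(lo5, hi5, "rep2"))
  expect_true(is.na(binding_onset(p5)$onset))

  # straddling CIs in one replicate (value 0.2) average to 0.6: not bound
  lo_m <- lo; lo_m[100:140] <- 1.2  # CI straddles 1.5 in rep2
  mixed <- dplyr::bind_rows(mk_prof(lo, hi, "rep1"),
                            mk_prof(lo_m, hi, "rep2"))
  expect_true(is.na(binding_onset(mixed)$onset))

  # replicate order does not matter; the call is idempotent
  swapped <- dplyr::bind_rows(mk_prof(lo, hi, "rep2"), mk_prof(lo, hi, "rep1"))
  expect_equal(binding_onset(swapped)$onset, 100L)
})

test_that("occupancy statistics follow the standard error of proportion", {
  one <- occupancy_stats(5, 10, 2)
  expect_equal(one$p, 1)
  expect_equal(one$se, 0)

  two <- occupancy_stats(c(50, 50), c(100, 100), c(1, 1))
  expect_equal(two$p, c(0.5, 0.5))
  expect_equal(two$se, c(0.05, 0.05))

  many <- occupancy_stats(c(58, 65, 47, 3), c(115, 226, 209, 97),
                          c(2.5, 3.1, 4.0, 1.7))
  expect_equal(sum(many$p), 1)
  expect_equal(many$se, sqrt(many$p * (1 - many$p) / many$molecules))
  expect_error(occupancy_stats(1, 0, 1), "positive")
})

test_that("simulated counts recover planted enrichment and are reproducible", {
  e <- rep(1, 500)
  cnt <- simulate_serp(e, mu = 200, phi = 5, seed = 99)
  prof <- average_replicates(windowed_enrichment(cnt))
  ok <- !prof$missing
  inside <- mean(prof$ratio[ok] >= 0.8 & prof$ratio[ok] <= 1.2)
  expect_gte(inside, 0.95)

  expect_true(all(simulate_serp(rep(0, 50), mu = 30, seed = 1,
                                phi = 5)$count[
    simulate_serp(rep(0, 50), mu = 30, seed = 1,
                  phi = 5)$library == "selected"] == 0))

  a <- simulate_serp(rep(2, 80), mu = 40, phi = 3, seed = 123)
  b <- simulate_serp(rep(2, 80), mu = 40, phi = 3, seed = 123)
  expect_identical(a, b)
})

test_that("simulated total coverage matches the requested mean", {
  cnt <- simulate_serp(rep(1, 10000), mu = 50, phi = 5, seed = 4,
                       replicates = 1)
  tot <- cnt$count[cnt$library == "total"]
  expect_lt(abs(mean(tot) - 50) / 50, 0.02)
})
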