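# A small controlled database: one Tbo-IT2-like precursor plus synthetic
# companions, built from generator ground truth.
make_test_db <- function(n_extra = 5, seed = 19) {
  lib <- gen_precursor_library(n_extra, seed = seed)
  models <- models_from_truth(lib$truth)
  tbo <- tbo_it2_mature()
  models[["TBO2"]] <- structure(list(
    aa_sequence = paste0("MLLLLVIFFLLIVAFALA", "EENQEEAR", tbo, "GKR"),
    signal = c(1L, 18L), propeptide = c(19L, 26L),
    mature = c(27L, 65L), amidation_tail = c(66L, 68L),
    amidated = TRUE, mature_seq = tbo
  ), class = "precursor_model")
  models
}

test_that("search database construction is 2-targets-per-precursor with 1:1 decoys", {
  models <- make_test_db()
  db <- build_search_db(models)
  expect_equal(sum(!db$is_decoy), 2L * length(models))
  expect_equal(sum(db$is_decoy), sum(!db$is_decoy))
  # decoys are full reversals
  tgt <- db[!db$is_decoy, ]
  dec <- db[db$is_decoy, ]
  for (k in seq_len(nrow(tgt))) {
    expect_equal(dec$sequence[k],
                 paste(rev(strsplit(tgt$sequence[k], "")[[1]]), collapse = ""))
  }
  # a precursor without propeptide contributes a single target
  one <- list(X = structure(list(
    aa_sequence = "MAAACACACACACACA", signal = c(1L, 4L),
    propeptide = c(NA_integer_, NA_integer_), mature = c(5L, 16L),
    amidation_tail = c(NA_integer_, NA_integer_), amidated = FALSE,
    mature_seq = "CACACACACACA"), class = "precursor_model"))
  db1 <- build_search_db(one)
  expect_equal(nrow(db1), 2L)
})

test_that("a noise-free spectrum of a known peptide is matched completely", {
  models <- make_test_db()
  db <- build_search_db(models)
  index <- build_peptidoform_index(db, enzyme = "trypsin", max_missed = 4)
  pf <- apply_modifications("SSECCGCSVCQCNLFGQNCQCK",
                            fixed = list(mod_carbamidomethyl()))[[1]]
  run <- gen_msms_run(list(pf), seed = 5, ppm_error_sd = 0, frag_noise_peaks = 0)
  psm <- match_spectrum(run$spectra[[1]], index)
  expect_equal(psm$sequence, "SSECCGCSVCQCNLFGQNCQCK")
  expect_equal(psm$n_matched, 42L)  # all 2 x 21 fragment ions
  expect_false(psm$is_decoy)
  expect_equal(c(psm$start, psm$end), c(11L, 32L))

  # removing the true peptide's parent strictly lowers the best score
  models2 <- models[names(models) != "TBO2"]
  index2 <- build_peptidoform_index(build_search_db(models2),
                                    enzyme = "trypsin", max_missed = 4)
  psm2 <- match_spectrum(run$spectra[[1]], index2)
  expect_true(is.null(psm2) || psm2$score < psm$score)

  # precursor 50 ppm off fails the 10 ppm gate
  s <- run$spectra[[1]]
  s$precursor_mz <- s$precursor_mz * (1 + 50e-6)
  expect_null(match_spectrum(s, index))
})

test_that("the score is invariant to peak order and intensity scaling", {
  models <- make_test_db(3)
  index <- build_peptidoform_index(build_search_db(models), enzyme = "trypsin",
                                   max_missed = 2)
  tab <- index$table
  pick <- which(!tab$is_decoy & (tab$end - tab$start) >= 7)[1]
  pf <- index$forms[[tab$form_id[pick]]]
  run <- gen_msms_run(list(pf), seed = 8, frag_noise_peaks = 10)
  s <- run$spectra[[1]]
  base <- match_spectrum(s, index)
  scaled <- spectrum(s$id, s$precursor_mz, s$precursor_charge,
                     s$peaks$mz, s$peaks$intensity * 1000)
  shuffled_idx <- sample(nrow(s$peaks))
  shuffled <- spectrum(s$id, s$precursor_mz, s$precursor_charge,
                       s$peaks$mz[shuffled_idx], s$peaks$intensity[shuffled_idx])
  expect_equal(match_spectrum(scaled, index)$score, base$score, tolerance = 1e-9)
  expect_equal(match_spectrum(shuffled, index)$score, base$score, tolerance = 1e-12)
})

test_that("target-decoy q-values behave at the boundaries", {
  psms <- data.frame(score = c(rep(10, 99), 5),
                     is_decoy = c(rep(FALSE, 99), TRUE))
  res <- target_decoy_fdr(psms, alpha = 0.01)
  expect_equal(nrow(res$accepted), 99L)

  # interleaved equal scores 1:1: q is ~1, nothing passes
  psms2 <- data.frame(score = rep(7, 40), is_decoy = rep(c(TRUE, FALSE), 20))
  res2 <- target_decoy_fdr(psms2, alpha = 0.01)
  expect_equal(nrow(res2$accepted), 0L)
  expect_true(all(res2$all$q_value >= 0.99))

  # all decoys above all targets: empty result is valid
  psms3 <- data.frame(score = c(1, 2, 9, 10), is_decoy = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(nrow(target_decoy_fdr(psms3, alpha = 0.05)$accepted), 0L)

  expect_error(target_decoy_fdr(psms, alpha = 0.6), "alpha")
})

test_that("q-values are monotone non-increasing in score", {
  set.seed(123)
  psms <- data.frame(score = round(rnorm(300, 10, 3), 2),
                     is_decoy = sample(c(TRUE, FALSE), 300, replace = TRUE))
  all_q <- target_decoy_fdr(psms, 0.05)$all
  expect_true(all(diff(all_q$q_value) >= -1e-12))  # sorted by decreasing score
})

test_that("the FDR estimate is conservative on pure-noise spectra", {
  models <- make_test_db(6, seed = 41)
  index <- build_peptidoform_index(build_search_db(models), enzyme = "trypsin",
                                   max_missed = 2)
  tab <- index$table
  pool <- lapply(tab$form_id[!tab$is_decoy & (tab$end - tab$start) >= 6],
                 function(id) index$forms[[id]])
  n <- 400
  noise <- gen_noise_spectra(n, pool, seed = 17, n_peaks = 50)
  psms <- search_spectra(noise, index)
  res <- target_decoy_fdr(psms, alpha = 0.01)
  mc_se <- sqrt(0.01 * 0.99 / n)
  expect_lte(nrow(res$accepted) / n, 0.01 + 2 * mc_se)
})

test_that("sequence coverage merges intervals and counts PSMs per peptide", {
  psms <- data.frame(sequence = c("A", "B", "B"), start = c(10, 14, 14),
                     end = c(32, 39, 39), stringsAsFactors = FALSE)
  cov <- sequence_coverage(psms, 39)
  expect_equal(cov$intervals, data.frame(start = 10L, end = 39L))
  expect_equal(cov$covered, 30L)
  expect_equal(cov$fraction, 30 / 39)
  expect_equal(cov$peptides$psm_count, c(1L, 2L))

  empty <- sequence_coverage(psms[0, ], 39)
  expect_equal(empty$covered, 0L)
  expect_error(sequence_coverage(data.frame(sequence = "A", start = 0, end = 5), 39),
               "outside")
})
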