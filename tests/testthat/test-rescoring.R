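# Independent brute-force evaluation of the target-decoy q-value estimator.
brute_q <- function(score, is_decoy) {
  vapply(score, function(s) {
    thr <- unique(score[score <= s])
    min(vapply(thr, function(t) {
      (sum(is_decoy & score >= t) + 1) / max(1, sum(!is_decoy & score >= t))
    }, numeric(1)))
  }, numeric(1))
}

test_that("q-values match the brute-force estimator on a toy PSM set", {
  score <- c(10, 9, 8, 7, 8.5, 6)
  dec <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  df <- data.frame(spectrum_id = paste0("s", 1:6),
                   peptide = paste0("PEP", 1:6),
                   is_decoy = dec, model_score = score,
                   origin_flag = "non_spliced")
  rep <- assign_qvalues(df, level = "psm")
  expect_equal(rep$q_value, brute_q(score, dec))
  expect_equal(rep$q_value[1], 0.5)  # monotonized downward from lower thresholds

  # all targets above all decoys: top q-value is 1/T
  score2 <- c(10, 9, 8, 7, 3, 2)
  rep2 <- assign_qvalues(transform(df, model_score = score2), level = "psm")
  expect_equal(min(rep2$q_value[!dec]), (0 + 1) / 4)
  expect_error(assign_qvalues(df[!dec, ], level = "psm"), "decoys")

  # q-values are monotone non-increasing in score
  o <- order(rep$model_score)
  expect_true(all(diff(rep$q_value[o]) <= 1e-12))
})

test_that("peptide-level reporting collapses duplicate peptides", {
  df <- data.frame(spectrum_id = paste0("s", 1:5),
                   peptide = c("AAA", "AAA", "BBB", "CCC", "DDD"),
                   is_decoy = c(FALSE, FALSE, FALSE, TRUE, TRUE),
                   model_score = c(9, 8, 7, 5, 4),
                   origin_flag = "non_spliced")
  pep <- assign_qvalues(df, level = "peptide")
  expect_equal(nrow(pep), 4)
  expect_equal(pep$model_score[pep$peptide == "AAA"], 9)
  psm <- assign_qvalues(df, level = "psm")
  expect_lte(sum(pep$q_value <= 0.5 & !pep$is_decoy),
             sum(psm$q_value <= 0.5 & !psm$is_decoy))
})

test_that("origin duplicates keep only the non-spliced record", {
  df <- data.frame(spectrum_id = c("s1", "s1", "s2"),
                   peptide = c("AAA", "AAA", "AAA"),
                   is_decoy = FALSE,
                   origin_flag = c("spliced", "non_spliced", "spliced"))
  out <- resolve_origin_duplicates(df)
  expect_equal(nrow(out), 2)
  expect_equal(out$origin_flag[out$spectrum_id == "s1"], "non_spliced")
  expect_equal(out$origin_flag[out$spectrum_id == "s2"], "spliced")
})

test_that("PTM conflicts follow the 30% rule", {
  base <- data.frame(spectrum_id = "sp1",
                     peptide = c("SPLICEDK", "MODIFIEDNS", "CLEANNS"),
                     is_decoy = FALSE,
                     origin_flag = c("spliced", "non_spliced", "non_spliced"),
                     base_score = c(100, 71, 90),
                     mods = c("", "deamidation", ""))
  # modified non-spliced at 71 >= 0.7 * 100: whole spectrum dropped
  expect_equal(nrow(filter_ptm_conflicts(base)), 0)
  # at 50 only the modified candidate is dropped
  base$base_score[2] <- 50
  out <- filter_ptm_conflicts(base)
  expect_setequal(out$peptide, c("SPLICEDK", "CLEANNS"))
  # no modified candidates: unchanged
  clean <- base; clean$mods <- ""
  expect_equal(nrow(filter_ptm_conflicts(clean)), 3)
})

test_that("training is invariant to affine rescaling of a feature", {
  n <- 200
  feats <- withr::with_seed(5, data.frame(
    spectral_angle = c(stats::runif(n / 2, 0.7, 1), stats::runif(n / 2, 0, 0.5)),
    spearman = stats::runif(n, -1, 1),
    irt_abs_error = stats::rexp(n, 1),
    origin_flag = sample(c("spliced", "non_spliced"), n, replace = TRUE),
    is_decoy = rep(c(FALSE, TRUE), each = n / 2)))
  m1 <- train_semisupervised(feats, seed = 1)
  s1 <- score_psms(m1, feats)
  rescaled <- feats
  rescaled$irt_abs_error <- 10 * rescaled$irt_abs_error + 3
  m2 <- train_semisupervised(rescaled, seed = 1)
  s2 <- score_psms(m2, rescaled)
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("degenerate feature tables return the initial ranking", {
  feats <- data.frame(spectral_angle = 0.5, spearman = 0.1,
                      irt_abs_error = 1, origin_flag = "non_spliced",
                      is_decoy = rep(c(FALSE, TRUE), 10))
  m <- train_semisupervised(feats)
  expect_true(m$degenerate)
  expect_equal(score_psms(m, feats), feats$spectral_angle)
  expect_error(train_semisupervised(feats[!feats$is_decoy, ]),
               "targets and decoys")
})

test_that("PEP estimates respect the mean-bound and separation limits", {
  n <- 200
  df <- data.frame(model_score = c(stats::runif(n, 10, 20), stats::runif(n, 0, 5)),
                   is_decoy = rep(c(FALSE, TRUE), each = n),
                   origin_flag = "non_spliced")
  accepted <- !df$is_decoy
  est <- estimate_pep_and_group_fdr(df, accepted)
  expect_true(all(est$pep >= 0 & est$pep <= 1))
  expect_lt(est$group_fdr[["non_spliced"]], 0.05)  # perfect separation
  expect_gte(est$group_fdr[["non_spliced"]], min(est$pep[accepted]))
  expect_lte(est$group_fdr[["non_spliced"]], max(est$pep[accepted]))

  # targets drawn from the decoy distribution: group FDR near 1
  df2 <- withr::with_seed(11, data.frame(
    model_score = stats::rnorm(2 * n), is_decoy = rep(c(FALSE, TRUE), n),
    origin_flag = "non_spliced"))
  est2 <- estimate_pep_and_group_fdr(df2, !df2$is_decoy)
  expect_gt(est2$group_fdr[["non_spliced"]], 0.8)
  # stratum without accepted members is reported absent
  est3 <- estimate_pep_and_group_fdr(df, rep(FALSE, nrow(df)))
  expect_true(is.na(est3$group_fdr[["non_spliced"]]))
})

test_that("isobaric competitors displace spliced peptides only when scoring higher", {
  sub <- substrate("s", "GADEFKWYHRMNPQVTSCIK")
  # spliced peptide is a permutation of the substring GADEFKW -> isobaric
  spliced_pep <- "GADFEKW"
  obs <- local({
    pr <- mock_predict("GADEFKW", 2)  # spectrum truly from the competitor
    o <- order(pr$mz)
    spectrum("sc1", (peptide_mass("GADEFKW") + 2 * 1.007276466879) / 2,
             2, 30, pr$mz[o], pr$intensity[o])
  })
  spectra <- list(sc1 = obs)
  cal <- structure(list(slope = 1, intercept = 0, n = 10, cv_rmse = 0,
                        used_fallback = FALSE), class = "irt_calibration")
  model <- structure(list(weights = c(intercept = 0, spectral_angle = 1,
                                      spearman = 0, irt_abs_error = 0,
                                      origin = 0),
                          center = rep(0, 4), scale = rep(1, 4),
                          iterations = 5L, train_fdr = 0.01, seed = 1,
                          degenerate = FALSE),
                     class = "rescore_model")
  sp_feats <- compute_features(
    data.frame(spectrum_id = "sc1", peptide = spliced_pep, is_decoy = FALSE,
               origin_flag = "spliced", base_score = 10, precursor_mz = 0,
               charge = 2, retention_time = mock_predict(spliced_pep, 2)$predicted_irt,
               mods = ""),
    spectra, calibration = cal)
  sp_feats$model_score <- score_psms(model, sp_feats)
  out <- isobaric_competitor_filter(sp_feats, sub, model, spectra, cal,
                                    length_window = c(5L, 10L))
  expect_equal(nrow(out$retained), 0)       # competitor explains the spectrum
  expect_true(out$report$removed)
  expect_equal(out$report$competitor, "GADEFKW")

  # no isobaric substring: retained
  sub2 <- substrate("s2", "WWWWWWWWWWWW")
  out2 <- isobaric_competitor_filter(sp_feats, sub2, model, spectra, cal,
                                     length_window = c(5L, 10L))
  expect_equal(nrow(out2$retained), 1)

  # equal competitor score (identical predictions for every peptide): retained
  const_pred <- function(peptide, charge) mock_predict("GADEFKW", 2)
  sp_const <- compute_features(sp_feats[, !(names(sp_feats) %in%
    c("spectral_angle", "spearman", "predicted_irt", "irt_abs_error"))],
    spectra, predictor = const_pred, calibration = cal)
  sp_const$model_score <- score_psms(model, sp_const)
  out3 <- isobaric_competitor_filter(sp_const, sub, model, spectra, cal,
                                     predictor = const_pred,
                                     length_window = c(5L, 10L))
  expect_equal(nrow(out3$retained), 1)
})

test_that("contaminant arbitration drops only strictly better-explained spectra", {
  psms <- data.frame(spectrum_id = c("s1", "s2", "s3"),
                     peptide = c("AAA", "BBB", "CCC"),
                     spectral_angle = c(0.80, 0.90, 0.85))
  cont <- data.frame(spectrum_id = c("s1", "s2"),
                     spectral_angle = c(0.95, 0.90))
  out <- contaminant_arbitration(psms, cont)
  expect_setequal(out$peptide, c("BBB", "CCC"))  # equal angle retained
  expect_equal(contaminant_arbitration(psms, cont[0, , drop = FALSE]), psms)
})
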