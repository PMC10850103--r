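# Origin-aware semi-supervised PSM rescoring with target-decoy q-values,
# posterior error probabilities and per-stratum (group) FDR.
#
# A PSM table is a data.frame with one row per candidate match:
#   spectrum_id, peptide, is_decoy (logical), origin_flag ("spliced" /
#   "non_spliced"), base_score, precursor_mz, charge, retention_time,
#   mods (character; "" when unmodified).

#' Keep only the non-spliced PSM when a peptide maps as both origins
#'
#' If the same (spectrum, peptide) pair is present with both a spliced and a
#' non-spliced origin flag, only the non-spliced record is considered.
#'
#' @param psms PSM data.frame.
#' @return Filtered PSM data.frame.
#' @export
resolve_origin_duplicates <- function(psms) {
  key <- paste(psms$spectrum_id, psms$peptide, psms$is_decoy)
  has_ns <- tapply(psms$origin_flag == "non_spliced", key, any)
  drop <- psms$origin_flag == "spliced" & has_ns[key]
  psms[!drop, , drop = FALSE]
}

predictor_incompatible_mods <- function(mods) {
  grepl("deamid|acetyl", mods, ignore.case = TRUE)
}

#' Remove PTM conflicts before rescoring
#'
#' Peptides carrying asparagine/glutamine deamidation or N-terminal
#' acetylation cannot be predicted and are dropped. If such a modified
#' non-spliced PSM scores within 30% of the best spliced PSM for the same
#' MS2 spectrum (base score at least 0.7 times the best spliced base score),
#' the whole spectrum is ambiguous and all of its PSMs are removed.
#'
#' @param psms PSM data.frame with `base_score` and `mods` columns.
#' @return Filtered PSM data.frame.
#' @export
filter_ptm_conflicts <- function(psms) {
  if (!"mods" %in% names(psms)) psms$mods <- ""
  bad_mod <- predictor_incompatible_mods(psms$mods)
  drop_spectrum <- character(0)
  spliced <- psms$origin_flag == "spliced"
  for (sid in unique(psms$spectrum_id[bad_mod & psms$origin_flag == "non_spliced"])) {
    in_spec <- psms$spectrum_id == sid
    sp_scores <- psms$base_score[in_spec & spliced]
    if (length(sp_scores) == 0L) next
    best_spliced <- max(sp_scores)
    conflicted <- in_spec & bad_mod & psms$origin_flag == "non_spliced" &
      psms$base_score >= 0.7 * best_spliced
    if (any(conflicted)) drop_spectrum <- c(drop_spectrum, sid)
  }
  keep <- !(psms$spectrum_id %in% drop_spectrum) & !bad_mod
  psms[keep, , drop = FALSE]
}

#' Compute rescoring features for a PSM table
#'
#' For every PSM within the identification length window, predicts the MS2
#' spectrum and iRT with `predictor`, matches predicted fragments against
#' the observed spectrum, and records the spectral angle, the Spearman
#' correlation of matched intensities and the predicted iRT. If a
#' calibration is supplied the absolute iRT error (minutes) is added.
#' Undefined Spearman values are imputed with the origin-stratum median.
#' PSMs outside the length window or failing prediction are excluded (with a
#' message) and returned in the `excluded` attribute.
#'
#' @param psms PSM data.frame.
#' @param spectra Named list of [spectrum()] objects keyed by spectrum id.
#' @param predictor Prediction function with the [mock_predict()] contract.
#' @param calibration Optional [fit_irt_calibration()] result.
#' @param tolerance,unit Fragment match tolerance (see [match_peaks()]).
#' @param length_window Identification peptide-length window.
#' @return PSM data.frame with columns `spectral_angle`, `spearman`,
#'   `predicted_irt` (and `irt_abs_error` if calibrated) added.
#' @export
compute_features <- function(psms, spectra, predictor = mock_predict,
                             calibration = NULL, tolerance = 0.02,
                             unit = "Th", length_window = c(7L, 30L)) {
  n <- nrow(psms)
  sa <- sp <- irt <- rep(NA_real_, n)
  scoreable <- rep(TRUE, n)
  cache <- new.env(parent = emptyenv())
  plen <- nchar(psms$peptide)
  for (r in seq_len(n)) {
    if (plen[r] < length_window[1] || plen[r] > length_window[2]) {
      scoreable[r] <- FALSE
      next
    }
    obs <- spectra[[psms$spectrum_id[r]]]
    if (is.null(obs)) { scoreable[r] <- FALSE; next }
    key <- paste0(psms$peptide[r], "/", psms$charge[r])
    pred <- cache[[key]]
    if (is.null(pred)) {
      pred <- tryCatch(predictor(psms$peptide[r], psms$charge[r]),
                       error = function(e) NULL)
      if (is.null(pred)) { scoreable[r] <- FALSE; next }
      cache[[key]] <- pred
    }
    m <- match_peaks(obs, pred, tolerance = tolerance, unit = unit)
    sa[r] <- if (all(m$observed == 0) && all(m$predicted == 0)) 0 else
      spectral_angle(m$observed, m$predicted)
    sp[r] <- spearman_similarity(m$observed, m$predicted)
    irt[r] <- pred$predicted_irt
  }
  if (any(!scoreable)) {
    message(sum(!scoreable),
            " PSM(s) unscoreable (length window or prediction failure); excluded")
  }
  excluded <- psms[!scoreable, , drop = FALSE]
  psms <- psms[scoreable, , drop = FALSE]
  psms$spectral_angle <- sa[scoreable]
  psms$spearman <- sp[scoreable]
  psms$predicted_irt <- irt[scoreable]
  # stratum-median imputation of the undefined-correlation sentinel
  for (g in unique(psms$origin_flag)) {
    idx <- psms$origin_flag == g
    med <- stats::median(psms$spearman[idx], na.rm = TRUE)
    if (is.na(med)) med <- 0
    psms$spearman[idx & is.na(psms$spearman)] <- med
  }
  if (!is.null(calibration)) {
    psms$irt_abs_error <- irt_error(psms$predicted_irt, psms$retention_time,
                                    calibration)
  }
  attr(psms, "excluded") <- excluded
  psms
}

feature_matrix <- function(psms) {
  cbind(spectral_angle = psms$spectral_angle,
        spearman = psms$spearman,
        irt_abs_error = psms$irt_abs_error,
        origin = as.numeric(psms$origin_flag == "spliced"))
}

# Target-decoy q-values: q(s) = min over thresholds t <= s of
# (#decoys >= t + 1) / (#targets >= t), monotone in score.
td_qvalues <- function(score, is_decoy) {
  thr <- sort(unique(score), decreasing = TRUE)
  d_ge <- vapply(thr, function(t) sum(is_decoy & score >= t), numeric(1))
  t_ge <- vapply(thr, function(t) sum(!is_decoy & score >= t), numeric(1))
  raw <- (d_ge + 1) / pmax(t_ge, 1)
  qthr <- rev(cummin(rev(raw)))
  qthr[match(score, thr)]
}

#' Train the origin-aware semi-supervised rescoring model
#'
#' Iterative percolator-style scheme: the score is initialized with the
#' spectral angle; each iteration computes target-decoy q-values, takes the
#' targets at `q <= train_fdr` as positives, fits an L2-regularized linear
#' discriminant of positives versus decoys on standardized features
#' (spectral angle, Spearman correlation, absolute iRT error and the
#' spliced-origin flag), and rescores all PSMs. The origin flag lets the
#' model penalize the spliced stratum automatically when it is enriched for
#' false matches. Fully deterministic.
#'
#' @param psms PSM data.frame with feature columns (see
#'   [compute_features()]) and `is_decoy`.
#' @param train_fdr Training q-value threshold for positives.
#' @param iterations Number of refinement iterations.
#' @param lambda L2 regularization strength.
#' @param seed Recorded for provenance (the scheme uses no randomness).
#' @return List of class `rescore_model`: `weights` (intercept + one per
#'   feature), `center`, `scale`, `iterations`, `train_fdr`, `seed`,
#'   `degenerate`.
#' @export
train_semisupervised <- function(psms, train_fdr = 0.01, iterations = 5L,
                                 lambda = 1.0, seed = 1L) {
  miss <- setdiff(c("spectral_angle", "spearman", "irt_abs_error"), names(psms))
  if (length(miss) > 0L)
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  X <- feature_matrix(psms)
  if (any(!stats::complete.cases(X))) stop("features contain missing values")
  for (g in c(TRUE, FALSE)) {
    if (!any(psms$is_decoy == g))
      stop("training requires both targets and decoys")
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (all(scl == 0)) {
    return(structure(list(weights = c(intercept = 0,
                                      stats::setNames(rep(0, ncol(X)),
                                                      colnames(X))),
                          center = ctr, scale = pmax(scl, 1),
                          iterations = 0L, train_fdr = train_fdr,
                          seed = seed, degenerate = TRUE),
                     class = "rescore_model"))
  }
  scl[scl == 0] <- 1   # constant column -> centered to all-zero, weight inert
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  score <- psms$spectral_angle
  w <- NULL
  for (it in seq_len(iterations)) {
    q <- td_qvalues(score, psms$is_decoy)
    pos <- !psms$is_decoy & q <= train_fdr
    if (!any(pos)) {
      k <- max(50L, ceiling(0.01 * sum(!psms$is_decoy)))
      tgt <- which(!psms$is_decoy)
      pos[tgt[order(-score[tgt])][seq_len(min(k, length(tgt)))]] <- TRUE
      message("no positives at train FDR in iteration ", it,
              "; falling back to top-", k, " targets")
    }
    rows <- pos | psms$is_decoy
    Xd <- cbind(1, Z[rows, , drop = FALSE])
    y <- ifelse(psms$is_decoy[rows], -1, 1)
    P <- diag(c(0, rep(lambda, ncol(Z))))
    w <- solve(crossprod(Xd) + P, crossprod(Xd, y))
    score <- drop(cbind(1, Z) %*% w)
  }
  structure(list(weights = stats::setNames(drop(w),
                                           c("intercept", colnames(X))),
                 center = ctr, scale = scl, iterations = iterations,
                 train_fdr = train_fdr, seed = seed, degenerate = FALSE),
            class = "rescore_model")
}

#' Score PSMs with a trained model
#'
#' @param model A [train_semisupervised()] model.
#' @param psms PSM data.frame with feature columns.
#' @return Numeric model scores (the spectral angle for a degenerate model).
#' @export
score_psms <- function(model, psms) {
  if (model$degenerate) return(psms$spectral_angle)
  X <- feature_matrix(psms)
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  drop(cbind(1, Z) %*% model$weights)
}

#' Target-decoy q-values at PSM or peptide level
#'
#' PSM level uses every record; peptide level collapses to the best-scoring
#' PSM per distinct peptide sequence (targets and decoys alike) before
#' computing q-values. q is the monotonized `(#decoys >= s + 1)/(#targets >= s)`.
#'
#' @param psms PSM data.frame with a `model_score` column.
#' @param level `"psm"` or `"peptide"`.
#' @return Data.frame (possibly peptide-collapsed) with a `q_value` column;
#'   attribute `level` records the report level.
#' @export
assign_qvalues <- function(psms, level = c("psm", "peptide")) {
  level <- match.arg(level)
  if (!any(psms$is_decoy)) stop("q-values undefined without decoys")
  if (level == "peptide") {
    o <- order(-psms$model_score)
    psms <- psms[o, , drop = FALSE]
    psms <- psms[!duplicated(psms$peptide), , drop = FALSE]
  }
  psms$q_value <- td_qvalues(psms$model_score, psms$is_decoy)
  attr(psms, "level") <- level
  psms
}

#' Posterior error probabilities and per-stratum group FDR
#'
#' PEPs are estimated from the local decoy fraction: PSMs are ordered by
#' decreasing model score, the decoy indicator is smoothed by isotonic
#' regression (monotone non-increasing in score), and the fraction p is
#' converted to `PEP = p / (1 - p)` (equal target/decoy null mass), clamped
#' to `[0, 1]`. The group FDR of a stratum is the mean PEP over its accepted
#' target members; a stratum with no accepted member is reported as `NA`.
#'
#' @param psms PSM data.frame with `model_score`, `is_decoy`, `origin_flag`.
#' @param accepted Logical vector marking accepted PSMs (same length).
#' @return List with `pep` (per PSM) and `group_fdr` (named numeric,
#'   one entry per origin stratum).
#' @export
estimate_pep_and_group_fdr <- function(psms, accepted) {
  stopifnot(length(accepted) == nrow(psms))
  ord <- order(-psms$model_score)
  z <- as.numeric(psms$is_decoy[ord])
  fit <- stats::isoreg(seq_along(z), z)
  p <- pmin(pmax(fit$yf, 0), 1 - 1e-9)
  pep_ord <- pmin(p / (1 - p), 1)
  pep <- numeric(length(z))
  pep[ord] <- pep_ord
  strata <- sort(unique(psms$origin_flag))
  gf <- vapply(strata, function(g) {
    m <- accepted & !psms$is_decoy & psms$origin_flag == g
    if (!any(m)) NA_real_ else mean(pep[m])
  }, numeric(1))
  list(pep = pep, group_fdr = gf)
}

substring_masses <- function(substrate, length_window = c(7L, 30L)) {
  aa <- strsplit(substrate$sequence, "")[[1]]
  cum <- c(0, cumsum(residue_masses[aa]))
  L <- length(aa)
  rows <- list()
  for (len in seq(length_window[1], min(length_window[2], L))) {
    i <- seq_len(L - len + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      i = i, j = i + len - 1L,
      peptide = substring(substrate$sequence, i, i + len - 1L),
      mass = cum[i + len] - cum[i] + MASS_WATER)
  }
  do.call(rbind, rows)
}

#' Filter accepted spliced peptides against isobaric non-spliced competitors
#'
#' For each accepted spliced PSM, all substrate substrings whose monoisotopic
#' mass matches the spliced peptide's within the tolerance are rescored with
#' the frozen model weights against the same spectrum. The spliced peptide
#' is removed if a competing non-spliced peptide achieves a strictly higher
#' score (ties retain the original assignment).
#'
#' @param spliced_psms Accepted spliced PSM data.frame with `model_score`.
#' @param substrate A [substrate()] object.
#' @param model Trained [train_semisupervised()] model (frozen weights).
#' @param spectra Named list of observed spectra.
#' @param calibration iRT calibration used for competitor features.
#' @param tolerance_ppm Precursor mass tolerance in ppm.
#' @param predictor Spectrum predictor.
#' @param length_window Competitor length window.
#' @return List with `retained` (filtered data.frame) and `report`
#'   (per-peptide best competitor and both scores).
#' @export
isobaric_competitor_filter <- function(spliced_psms, substrate, model,
                                       spectra, calibration,
                                       tolerance_ppm = 6,
                                       predictor = mock_predict,
                                       length_window = c(7L, 30L)) {
  subs <- substring_masses(substrate, length_window)
  removed <- logical(nrow(spliced_psms))
  rep_rows <- vector("list", nrow(spliced_psms))
  for (r in seq_len(nrow(spliced_psms))) {
    pep <- spliced_psms$peptide[r]
    mass <- peptide_mass(pep)
    hit <- subs[abs(subs$mass - mass) <= mass * tolerance_ppm * 1e-6 &
                  subs$peptide != pep, , drop = FALSE]
    best_score <- -Inf; best_pep <- NA_character_
    if (nrow(hit) > 0L) {
      comp <- spliced_psms[rep(r, nrow(hit)), , drop = FALSE]
      comp$peptide <- hit$peptide
      comp$origin_flag <- "non_spliced"
      comp <- compute_features(comp, spectra, predictor = predictor,
                               calibration = calibration,
                               length_window = length_window)
      if (nrow(comp) > 0L) {
        cs <- score_psms(model, comp)
        best_score <- max(cs)
        best_pep <- comp$peptide[which.max(cs)]
      }
    }
    removed[r] <- is.finite(best_score) &&
      best_score > spliced_psms$model_score[r]
    rep_rows[[r]] <- data.frame(peptide = pep,
                                spectrum_id = spliced_psms$spectrum_id[r],
                                spliced_score = spliced_psms$model_score[r],
                                competitor = best_pep,
                                competitor_score =
                                  ifelse(is.finite(best_score), best_score, NA),
                                removed = removed[r])
  }
  list(retained = spliced_psms[!removed, , drop = FALSE],
       report = do.call(rbind, rep_rows))
}

#' Arbitrate assigned PSMs against contaminant candidates
#'
#' An assigned PSM is dropped if a contaminant candidate for the same
#' spectrum has a strictly higher spectral angle; equal angles retain the
#' assignment.
#'
#' @param psms Assigned PSM data.frame with `spectral_angle`.
#' @param contaminants Data.frame with `spectrum_id` and `spectral_angle` of
#'   contaminant candidates.
#' @return Filtered PSM data.frame.
#' @export
contaminant_arbitration <- function(psms, contaminants) {
  if (nrow(contaminants) == 0L) return(psms)
  best <- tapply(contaminants$spectral_angle, contaminants$spectrum_id, max)
  comp <- best[as.character(psms$spectrum_id)]
  drop <- !is.na(comp) & comp > psms$spectral_angle
  psms[!drop, , drop = FALSE]
}

#' End-to-end rescoring of a candidate PSM table
#'
#' Convenience wrapper running the full identification stage: origin
#' de-duplication, PTM-conflict removal, feature computation, iRT
#' calibration (fitted on high-confidence non-spliced PSMs), model training,
#' scoring and q-value assignment at the requested level.
#'
#' @param psms Candidate PSM data.frame.
#' @param spectra Named list of observed [spectrum()] objects.
#' @param predictor Spectrum predictor (default [mock_predict()]).
#' @param fdr Acceptance q-value threshold.
#' @param level Report level, `"peptide"` (default) or `"psm"`.
#' @param train_fdr,iterations,lambda,seed Passed to
#'   [train_semisupervised()].
#' @param tolerance,unit Fragment-match tolerance.
#' @return List with `report` (records with `model_score`, `q_value` and
#'   `accepted`), `model`, `calibration`, `features` (the scored PSM-level
#'   table) and `group_fdr` (per origin stratum among accepted records).
#' @export
rescore_pipeline <- function(psms, spectra, predictor = mock_predict,
                             fdr = 0.01, level = "peptide",
                             train_fdr = 0.01, iterations = 5L, lambda = 1.0,
                             seed = 1L, tolerance = 0.02, unit = "Th") {
  psms <- resolve_origin_duplicates(psms)
  psms <- filter_ptm_conflicts(psms)
  feats <- compute_features(psms, spectra, predictor = predictor,
                            tolerance = tolerance, unit = unit)
  cal <- fit_irt_calibration(feats)
  feats$irt_abs_error <- irt_error(feats$predicted_irt, feats$retention_time,
                                   cal)
  model <- train_semisupervised(feats, train_fdr = train_fdr,
                                iterations = iterations, lambda = lambda,
                                seed = seed)
  feats$model_score <- score_psms(model, feats)
  report <- assign_qvalues(feats, level = level)
  report$accepted <- !report$is_decoy & report$q_value <= fdr
  pep <- estimate_pep_and_group_fdr(report, report$accepted)
  report$pep <- pep$pep
  list(report = report, model = model, calibration = cal, features = feats,
       group_fdr = pep$group_fdr)
}
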