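# Spectrum model, deterministic mock predictor, peak matching and the
# similarity metrics used as rescoring features.

#' MS2 spectrum
#'
#' @param spectrum_id Identifier string.
#' @param precursor_mz Precursor m/z in Thomson.
#' @param charge Positive integer precursor charge.
#' @param retention_time Observed retention time in minutes.
#' @param mz,intensity Numeric vectors of peak m/z and intensity. Peaks are
#'   sorted by m/z; unsorted input is sorted with a warning, intensities must
#'   be non-negative and at least one peak is required.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(spectrum_id, precursor_mz, charge, retention_time,
                     mz, intensity) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) < 1L) stop("spectrum must contain at least one peak")
  if (any(intensity < 0)) stop("negative peak intensities")
  if (is.unsorted(mz, strictly = TRUE)) {
    warning("peaks not strictly sorted by m/z; sorting")
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    dup <- duplicated(mz)
    mz <- mz[!dup]; intensity <- intensity[!dup]
  }
  structure(list(spectrum_id = spectrum_id,
                 precursor_mz = as.numeric(precursor_mz),
                 charge = as.integer(charge),
                 retention_time = as.numeric(retention_time),
                 mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "spectrum")
}

#' Deterministic mock MS2 spectrum and iRT predictor
#'
#' Stands in for a trained deep-learning predictor behind the same contract:
#' given a peptide and precursor charge it returns singly charged b- and
#' y-fragment m/z from monoisotopic residue masses, intensities normalized to
#' a maximum of 1, and a predicted indexed retention time. Intensities come
#' from a fixed string hash of (peptide, ion), so the same peptide always
#' yields the identical spectrum, with no RNG involvement. The predicted iRT
#' is a fixed linear function of residue hydrophobicity and length.
#'
#' Any function with this signature and return shape can replace it in the
#' pipeline (the predictor is an interface).
#'
#' @param peptide Peptide sequence (length >= 2; the 7-30 identification
#'   window is enforced downstream, at feature computation).
#' @param charge Precursor charge (recorded; fragments are singly charged).
#' @return An object of class `predicted_spectrum` with fields `peptide`,
#'   `charge`, `ion` (e.g. `"b3"`, `"y5"`), `mz`, `intensity` (max 1) and
#'   `predicted_irt`.
#' @examples
#' ps <- mock_predict("ACDEFGHK", 2)
#' max(ps$intensity)  # 1
#' @export
mock_predict <- function(peptide, charge = 2L) {
  aa <- strsplit(peptide, "")[[1]]
  bad <- setdiff(aa, AA_ALPHABET)
  if (length(bad) > 0L)
    stop("unsupported residue(s) for prediction: ",
         paste(unique(bad), collapse = ", "))
  np <- length(aa)
  if (np < 2L) stop("peptide too short to fragment")
  masses <- residue_masses[aa]
  idx <- seq_len(np - 1L)
  b_mz <- cumsum(masses)[idx] + MASS_PROTON
  y_mz <- cumsum(rev(masses))[idx] + MASS_WATER + MASS_PROTON
  ion <- c(paste0("b", idx), paste0("y", idx))
  mz <- c(b_mz, y_mz)
  inten <- hash01(paste0(peptide, "/", ion))
  inten <- inten / max(inten)
  irt <- sum(IRT_COEF[aa]) + 0.85 * np
  structure(list(peptide = peptide, charge = as.integer(charge),
                 ion = ion, mz = as.numeric(mz),
                 intensity = as.numeric(inten),
                 predicted_irt = as.numeric(irt)),
            class = "predicted_spectrum")
}

# Fixed per-residue retention coefficients (Kyte-Doolittle hydropathy),
# giving the mock predictor a plausible, deterministic iRT scale.
IRT_COEF <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Match predicted fragments against an observed spectrum
#'
#' Each predicted fragment is matched to at most one observed peak: the
#' nearest peak within the tolerance. Unmatched fragments contribute zero
#' observed intensity. Output vectors have one entry per predicted fragment.
#'
#' @param observed A [spectrum()] object.
#' @param predicted A [mock_predict()]-shaped predicted spectrum.
#' @param tolerance Match tolerance; Thomson by default.
#' @param unit `"Th"` or `"ppm"`.
#' @return List with numeric vectors `predicted` and `observed` (equal
#'   length) and logical `matched`.
#' @export
match_peaks <- function(observed, predicted, tolerance = 0.02,
                        unit = c("Th", "ppm")) {
  unit <- match.arg(unit)
  pm <- predicted$mz
  om <- observed$mz
  obs <- numeric(length(pm))
  matched <- logical(length(pm))
  for (f in seq_along(pm)) {
    tol <- if (unit == "ppm") pm[f] * tolerance * 1e-6 else tolerance
    d <- abs(om - pm[f])
    w <- which.min(d)
    if (length(w) && d[w] <= tol) {
      obs[f] <- observed$intensity[w]
      matched[f] <- TRUE
    }
  }
  list(predicted = predicted$intensity, observed = obs, matched = matched)
}

#' Normalized spectral contrast angle
#'
#' `SA = 1 - 2 * acos(cos(v1, v2)) / pi` on L2-normalized non-negative
#' intensity vectors: 1 for a perfect match, 0 for orthogonal spectra.
#'
#' @param v1,v2 Non-negative intensity vectors of equal length.
#' @return Score in `[0, 1]`.
#' @examples
#' spectral_angle(c(1, 2, 3), c(2, 4, 6))  # 1
#' @export
spectral_angle <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("intensity vectors differ in length")
  s1 <- sum(v1^2); s2 <- sum(v2^2)
  if (s1 == 0 && s2 == 0) stop("spectral angle undefined for two all-zero vectors")
  if (s1 == 0 || s2 == 0) return(0)
  cosine <- sum(v1 * v2) / sqrt(s1 * s2)
  cosine <- min(1, max(-1, cosine))
  1 - 2 * acos(cosine) / pi
}

#' Spearman rank correlation between intensity vectors
#'
#' Average ranks for ties. Returns `NA` (feature-missing sentinel) when
#' either vector is constant, for which rank correlation is undefined.
#'
#' @param v1,v2 Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_similarity <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors differ in length")
  if (length(v1) < 2L) stop("need at least two entries")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  stats::cor(v1, v2, method = "spearman")
}

#' Calibrate predicted iRT against observed retention time
#'
#' Fits the linear map from predicted iRT to observed retention time on the
#' high-confidence subset: non-spliced PSMs with spectral angle above
#' `sa_threshold`. If fewer than `min_points` qualify, the fit falls back to
#' all non-spliced PSMs (recorded in the result). Ten-fold cross-validation
#' is used for diagnostics only: folds are assigned deterministically from
#' `seed` and the out-of-fold residual RMSE is reported; the returned
#' coefficients come from the fit on all qualifying points.
#'
#' @param psms Data.frame with columns `origin_flag` (`"spliced"` /
#'   `"non_spliced"`), `spectral_angle`, `predicted_irt`, `retention_time`.
#' @param sa_threshold Spectral-angle cut-off for the fitting subset.
#' @param min_points Minimum qualifying PSMs before falling back.
#' @param folds Number of cross-validation folds.
#' @param seed Seed for the deterministic fold assignment.
#' @return List of class `irt_calibration`: `slope`, `intercept`, `n`,
#'   `cv_rmse`, `used_fallback`.
#' @export
fit_irt_calibration <- function(psms, sa_threshold = 0.9, min_points = 20L,
                                folds = 10L, seed = 1L) {
  ns <- psms[psms$origin_flag == "non_spliced", , drop = FALSE]
  fit_set <- ns[!is.na(ns$spectral_angle) & ns$spectral_angle > sa_threshold, ,
                drop = FALSE]
  used_fallback <- FALSE
  if (nrow(fit_set) < min_points) {
    fit_set <- ns
    used_fallback <- TRUE
  }
  if (nrow(fit_set) < 2L) stop("iRT calibration needs at least 2 points")
  fit <- stats::lm(retention_time ~ predicted_irt, data = fit_set)
  cf <- stats::coef(fit)

  cv_rmse <- NA_real_
  n <- nrow(fit_set)
  if (n >= folds) {
    fold <- local({
      rng <- sample_int_det(n, seed)
      rep_len(seq_len(folds), n)[order(rng)]
    })
    res <- numeric(n)
    for (f in seq_len(folds)) {
      te <- fold == f
      m <- stats::lm(retention_time ~ predicted_irt,
                     data = fit_set[!te, , drop = FALSE])
      res[te] <- fit_set$retention_time[te] -
        stats::predict(m, fit_set[te, , drop = FALSE])
    }
    cv_rmse <- sqrt(mean(res^2))
  }
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 n = n, cv_rmse = cv_rmse, used_fallback = used_fallback),
            class = "irt_calibration")
}

# Deterministic pseudo-random permutation keys without touching .Random.seed.
sample_int_det <- function(n, seed) {
  hash01(paste0("fold-", seed, "-", seq_len(n)))
}

#' Absolute iRT prediction error
#'
#' @param predicted_irt Predicted iRT value(s).
#' @param retention_time Observed retention time(s), minutes.
#' @param calibration An [fit_irt_calibration()] result.
#' @return Absolute residual in minutes.
#' @export
irt_error <- function(predicted_irt, retention_time, calibration) {
  abs(retention_time -
        (calibration$slope * predicted_irt + calibration$intercept))
}
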