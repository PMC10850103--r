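# Synthetic-data generator: substrates, simulated digestions with
# controllable sequence preferences and kinetics, mock spectra and candidate
# PSM tables with decoys and contaminants. Every downstream module is
# exercisable end to end from these generators with no external data.
#
# All randomness flows from the single config seed; sub-streams are derived
# with fixed offsets so each artifact is bit-reproducible.

#' Simulate a substrate protein
#'
#' @param length Number of residues (at least the minimum peptide length).
#' @param composition Named residue probability vector (default uniform over
#'   the 20 canonical amino acids).
#' @param seed Integer seed.
#' @return A [substrate()] object.
#' @export
simulate_substrate <- function(length, composition = NULL, seed) {
  if (length < 5L) stop("substrate shorter than the minimum peptide length")
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  stopifnot(all(names(composition) %in% AA_ALPHABET))
  aa <- withr::with_seed(seed, {
    sample(names(composition), length, replace = TRUE, prob = composition)
  })
  substrate(paste0("synthetic_", seed), paste(aa, collapse = ""),
            "simulated substrate")
}

#' Digestion simulation configuration
#'
#' Defaults emulate the statistical structure of in vitro protein digestion
#' by 20S proteasomes: spliced peptides are a minority (~12.5% of unique
#' products, homologous trans-spliced a few percent of those), N-terminal
#' splice-reactants are short, hydrolysis P1 sites favor hydrophobic and
#' acidic residues while splicing P1 sites favor small polar residues, and
#' peptide amounts follow saturating accumulation kinetics measured at 0, 1,
#' 2, 4 and 24 h in 2 biological x 2 technical replicates with
#' multiplicative lognormal noise.
#'
#' @param n_products Target number of unique peptide products.
#' @param spliced_fraction Fraction of products generated by splicing.
#' @param trans_fraction Fraction of spliced products that are trans-spliced.
#' @param hydrolysis_boost,splicing_boost Named propensity multipliers for
#'   P1 residues of each reaction (baseline 1 elsewhere).
#' @param length_window Product length window.
#' @param sr1_geom Geometric parameter for the N-terminal splice-reactant
#'   length (larger = shorter reactants).
#' @param time_grid Digestion time points in hours (must include 0).
#' @param n_bio,n_tech Replicate counts.
#' @param intensity_cv Lognormal coefficient of variation of intensities.
#' @param noise_floor Additive 0 h-style background intensity scale.
#' @param mz_jitter Peak m/z jitter (Th) for observed spectra.
#' @param rt_jitter Retention-time jitter (minutes).
#' @param false_match_rate Fraction of PSMs whose assignment is swapped to a
#'   wrong peptide of the same origin class.
#' @param spliced_false_rate Optional override of the false-match rate for
#'   the spliced stratum.
#' @param seed Mandatory integer seed.
#' @return List of class `digestion_sim_config`.
#' @export
digestion_sim_config <- function(n_products = 300L,
                                 spliced_fraction = 0.125,
                                 trans_fraction = 0.04,
                                 hydrolysis_boost = c(V = 3, D = 3, F = 3,
                                                      Y = 3, H = 3, L = 2,
                                                      E = 2),
                                 splicing_boost = c(G = 3, T = 3, S = 3),
                                 length_window = c(7L, 30L),
                                 sr1_geom = 0.45,
                                 time_grid = c(0, 1, 2, 4, 24),
                                 n_bio = 2L, n_tech = 2L,
                                 intensity_cv = 0.25,
                                 noise_floor = 50,
                                 mz_jitter = 0.004,
                                 rt_jitter = 0.4,
                                 false_match_rate = 0.05,
                                 spliced_false_rate = NULL,
                                 seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(spliced_fraction >= 0, spliced_fraction <= 1,
            trans_fraction >= 0, trans_fraction <= 1,
            0 %in% time_grid)
  prop <- function(boost) {
    p <- stats::setNames(rep(1, 20), AA_ALPHABET)
    p[names(boost)] <- boost
    p
  }
  structure(list(n_products = n_products,
                 spliced_fraction = spliced_fraction,
                 trans_fraction = trans_fraction,
                 hydrolysis_propensity = prop(hydrolysis_boost),
                 splicing_propensity = prop(splicing_boost),
                 length_window = as.integer(length_window),
                 sr1_geom = sr1_geom, time_grid = time_grid,
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 intensity_cv = intensity_cv, noise_floor = noise_floor,
                 mz_jitter = mz_jitter, rt_jitter = rt_jitter,
                 false_match_rate = false_match_rate,
                 spliced_false_rate = spliced_false_rate,
                 seed = as.integer(seed)),
            class = "digestion_sim_config")
}

#' Simulate a proteasomal digestion
#'
#' Draws P1 sites proportionally to the configured residue propensities,
#' assembles non-spliced and (forward-cis, reverse-cis, trans) spliced
#' products under the coordinate rules, maps every unique sequence back to
#' the substrate (multi-mapping), and generates ground-truth abundances
#' following saturating accumulation curves, realized as a kinetics table
#' with multiplicative lognormal noise plus an additive background floor.
#'
#' @param substrate A [substrate()] object.
#' @param config A [digestion_sim_config()].
#' @return List with `products` (one row per sequence-location:
#'   `sequence`, `product_type`, `i`, `j`, `k`, `n`, `n_origins`,
#'   `true_type`), `kinetics` (raw kinetics table) and `truth`
#'   (per-sequence `true_type`, `a0`, `rate` and reference-time abundance).
#' @export
simulate_digestion <- function(substrate, config) {
  L <- substrate$length
  lw <- config$length_window
  if (config$spliced_fraction > 0 && L < lw[1] + 2L)
    stop("substrate too short for spliced products in the length window")
  aa <- strsplit(substrate$sequence, "")[[1]]
  hyd <- config$hydrolysis_propensity[aa]
  spl <- config$splicing_propensity[aa]
  n_sp <- round(config$n_products * config$spliced_fraction)
  n_ns <- config$n_products - n_sp

  gen <- withr::with_seed(config$seed, {
    len_w <- exp(-0.12 * (seq(lw[1], lw[2]) - lw[1]))
    draw_len <- function() sample(seq(lw[1], lw[2]), 1L, prob = len_w)
    seqs <- character(0); types <- character(0)
    guard <- 0L
    while (sum(types == "non_spliced") < n_ns && guard < 50L * n_ns) {
      guard <- guard + 1L
      j <- sample.int(L, 1L, prob = hyd)
      len <- draw_len()
      i <- j - len + 1L
      if (i < 1L) next
      s <- substr(substrate$sequence, i, j)
      if (s %in% seqs) next
      seqs <- c(seqs, s); types <- c(types, "non_spliced")
    }
    guard <- 0L
    while (sum(types != "non_spliced") < n_sp && guard < 200L * max(n_sp, 1L)) {
      guard <- guard + 1L
      j <- sample.int(L, 1L, prob = spl)
      N <- draw_len()
      a <- min(1L + stats::rgeom(1L, config$sr1_geom), N - 1L)
      b <- N - a
      i <- j - a + 1L
      if (i < 1L || b < 1L) next
      type <- if (stats::runif(1) < config$trans_fraction) "trans" else
        if (stats::runif(1) < 0.65) "cis_forward" else "cis_reverse"
      k <- switch(type,
        cis_forward = if (j + 2L <= L - b + 1L)
          sample(seq(j + 2L, L - b + 1L), 1L) else NA_integer_,
        cis_reverse = if (i - b >= 1L)
          sample(seq_len(i - b), 1L) else NA_integer_,
        trans = {
          lo <- max(1L, i - b + 1L); hi <- min(j, L - b + 1L)
          if (lo <= hi) sample(seq(lo, hi), 1L) else NA_integer_
        })
      if (is.na(k)) next
      n <- k + b - 1L
      s <- paste0(substr(substrate$sequence, i, j),
                  substr(substrate$sequence, k, n))
      if (s %in% seqs) next
      # a sequence also present contiguously is a hydrolysis product
      if (grepl(canonical_sequence(s), canonical_sequence(substrate$sequence),
                fixed = TRUE)) next
      seqs <- c(seqs, s); types <- c(types, type)
    }
    n_seq <- length(seqs)
    is_ns <- types == "non_spliced"
    a0 <- stats::rlnorm(n_seq, meanlog = log(1e6) + ifelse(is_ns, 0.4, 0),
                        sdlog = 1)
    rate <- stats::rlnorm(n_seq, meanlog = log(0.5), sdlog = 0.4)
    list(seqs = seqs, types = types, a0 = a0, rate = rate)
  })

  # map every sequence back to the substrate, as the real pipeline would
  prod_rows <- list()
  for (q in seq_along(gen$seqs)) {
    mp <- map_peptide(gen$seqs[q], substrate)
    if (is.null(mp)) next
    loc <- mp$locations
    loc$sequence <- gen$seqs[q]
    loc$n_origins <- mp$n_origins
    loc$true_type <- gen$types[q]
    prod_rows[[length(prod_rows) + 1L]] <- loc
  }
  products <- do.call(rbind, prod_rows)
  products <- products[, c("sequence", "product_type", "i", "j", "k", "n",
                           "n_origins", "true_type")]

  truth <- data.frame(sequence = gen$seqs, true_type = gen$types,
                      a0 = gen$a0, rate = gen$rate)
  truth$abundance_ref <- truth$a0 * (1 - exp(-truth$rate * 4))

  kin <- withr::with_seed(config$seed + 1L, {
    grid <- expand.grid(q = seq_along(gen$seqs), time_h = config$time_grid,
                        bio_rep = seq_len(config$n_bio),
                        tech_rep = seq_len(config$n_tech))
    mu <- truth$a0[grid$q] * (1 - exp(-truth$rate[grid$q] * grid$time_h))
    noise <- exp(stats::rnorm(nrow(grid), 0, config$intensity_cv))
    floor <- stats::runif(nrow(grid), 0, config$noise_floor)
    data.frame(peptide = gen$seqs[grid$q], time_h = grid$time_h,
               bio_rep = grid$bio_rep, tech_rep = grid$tech_rep,
               intensity = mu * noise + floor)
  })
  list(products = products, kinetics = kin, truth = truth)
}

random_spliced_sequence <- function(substrate, len, L_ext = 1L) {
  L <- substrate$length
  for (att in 1:50) {
    a <- sample.int(len - 1L, 1L)
    b <- len - a
    i <- sample.int(L - a + 1L, 1L); j <- i + a - 1L
    k <- sample.int(L - b + 1L, 1L); n <- k + b - 1L
    ok <- (pmax(i, k) <= pmin(j, n)) || k >= j + 2L || i >= n + 1L
    if (!ok) next
    s <- paste0(substr(substrate$sequence, i, j),
                substr(substrate$sequence, k, n))
    if (!grepl(canonical_sequence(s), canonical_sequence(substrate$sequence),
               fixed = TRUE)) return(s)
  }
  NA_character_
}

#' Simulate a candidate PSM table with spectra, decoys and contaminants
#'
#' One MS2 spectrum per product: the observed peak list is the mock
#' prediction with m/z jitter and multiplicative intensity noise; retention
#' times follow a fixed linear iRT map plus jitter. A configured fraction of
#' assignments (optionally different for the spliced stratum) is swapped to
#' a wrong peptide of the same origin class, so the truth table supports
#' exact empirical-FDR computation. Each spectrum also receives one decoy
#' candidate drawn from the reversed substrate (never a substring of the
#' target substrate; collisions redrawn) carrying the same origin flag.
#'
#' @param products Products table from [simulate_digestion()] (or any table
#'   with `sequence` and `product_type`).
#' @param substrate A [substrate()] object.
#' @param config A [digestion_sim_config()].
#' @param n_contaminants Number of spectra that also receive a contaminant
#'   candidate.
#' @return List with `psms` (candidate table incl. decoys), `spectra`
#'   (named list of [spectrum()]), `contaminants` (spectrum_id, peptide) and
#'   `truth` (spectrum_id, true_peptide, assigned correct flag).
#' @export
simulate_psm_table <- function(products, substrate, config,
                               n_contaminants = 0L) {
  uniq <- products[!duplicated(products$sequence), , drop = FALSE]
  cls <- resolved_class(uniq$product_type)
  origin <- ifelse(cls == "non_spliced", "non_spliced", "spliced")
  nq <- nrow(uniq)
  rev_sub <- substrate(paste0(substrate$id, "_rev"),
                       paste(rev(strsplit(substrate$sequence, "")[[1]]),
                             collapse = ""))
  irt_slope <- 0.8; irt_intercept <- 25

  withr::with_seed(config$seed + 2L, {
    spectra <- vector("list", nq)
    sid <- sprintf("scan_%05d", seq_len(nq))
    rt_true <- numeric(nq)
    for (q in seq_len(nq)) {
      pep <- uniq$sequence[q]
      pred <- mock_predict(pep, 2L)
      mz <- pred$mz + stats::rnorm(length(pred$mz), 0, config$mz_jitter)
      inten <- pred$intensity *
        exp(stats::rnorm(length(pred$mz), 0, config$intensity_cv))
      o <- order(mz)
      rt_true[q] <- irt_slope * pred$predicted_irt + irt_intercept +
        stats::rnorm(1, 0, config$rt_jitter)
      spectra[[q]] <- spectrum(sid[q],
                               (peptide_mass(pep) + 2 * MASS_PROTON) / 2,
                               2L, rt_true[q], mz[o], inten[o])
    }
    names(spectra) <- sid

    # swap a fraction of assignments to wrong peptides of the same class
    assigned <- uniq$sequence
    rate <- ifelse(origin == "spliced",
                   if (is.null(config$spliced_false_rate))
                     config$false_match_rate else config$spliced_false_rate,
                   config$false_match_rate)
    is_false <- stats::runif(nq) < rate
    for (q in which(is_false)) {
      len <- nchar(uniq$sequence[q])
      swap <- if (origin[q] == "spliced") {
        random_spliced_sequence(substrate, len)
      } else {
        i <- sample.int(substrate$length - len + 1L, 1L)
        substr(substrate$sequence, i, i + len - 1L)
      }
      if (is.na(swap) || swap == uniq$sequence[q]) {
        is_false[q] <- FALSE
      } else {
        assigned[q] <- swap
      }
    }

    # each spectrum receives one decoy candidate drawn from either database
    # search; the spliced decoy space of a protein is orders of magnitude
    # larger than the non-spliced one, so the decoy origin follows the
    # theoretical search-space ratio (capped so both strata stay populated,
    # as every spectrum's non-spliced search still reports decoys)
    lw <- config$length_window
    theo <- c(ns = 0, sp = 0)
    for (N in seq(lw[1], min(lw[2], substrate$length))) {
      p <- space_params(N, 1L)
      theo["ns"] <- theo["ns"] + count_nonspliced(substrate$length, N)
      theo["sp"] <- theo["sp"] + count_forward_cis(substrate$length, p) +
        count_reverse_cis(substrate$length, p) + count_trans(substrate$length, p)
    }
    p_spliced <- min(0.95, max(0.05, theo["sp"] / sum(theo)))
    decoy_pep <- character(nq)
    decoy_origin <- sample(c("spliced", "non_spliced"), nq, replace = TRUE,
                           prob = c(p_spliced, 1 - p_spliced))
    canon_sub <- canonical_sequence(substrate$sequence)
    for (q in seq_len(nq)) {
      len <- nchar(uniq$sequence[q])
      repeat {
        d <- if (decoy_origin[q] == "spliced") {
          random_spliced_sequence(rev_sub, len)
        } else {
          i <- sample.int(rev_sub$length - len + 1L, 1L)
          substr(rev_sub$sequence, i, i + len - 1L)
        }
        if (!is.na(d) &&
            !grepl(canonical_sequence(d), canon_sub, fixed = TRUE)) break
      }
      decoy_pep[q] <- d
    }

    base_score <- function(correct) {
      ifelse(correct, stats::rnorm(nq, 25, 4), stats::rnorm(nq, 15, 4))
    }
    psms <- rbind(
      data.frame(spectrum_id = sid, peptide = assigned, is_decoy = FALSE,
                 origin_flag = origin,
                 base_score = base_score(!is_false),
                 precursor_mz = vapply(spectra, `[[`, 0, "precursor_mz"),
                 charge = 2L, retention_time = rt_true, mods = ""),
      data.frame(spectrum_id = sid, peptide = decoy_pep, is_decoy = TRUE,
                 origin_flag = decoy_origin,
                 base_score = stats::rnorm(nq, 15, 4),
                 precursor_mz = vapply(spectra, `[[`, 0, "precursor_mz"),
                 charge = 2L, retention_time = rt_true, mods = ""))
    rownames(psms) <- NULL

    contaminants <- NULL
    if (n_contaminants > 0L) {
      pick <- sample.int(nq, min(n_contaminants, nq))
      contaminants <- data.frame(
        spectrum_id = sid[pick],
        peptide = vapply(pick, function(q) {
          len <- nchar(uniq$sequence[q])
          i <- sample.int(rev_sub$length - len + 1L, 1L)
          substr(rev_sub$sequence, i, i + len - 1L)
        }, ""))
    }
    list(psms = psms, spectra = spectra, contaminants = contaminants,
         truth = data.frame(spectrum_id = sid, true_peptide = uniq$sequence,
                            assigned = assigned, correct = !is_false,
                            origin_flag = origin))
  })
}
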