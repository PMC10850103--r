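# Ground-truth benchmark construction and precision-recall evaluation.
#
# A ground-truth dataset couples a constructed (in silico-only) reference
# protein with a truth map from spectrum ids to the embedded peptide
# sequences and their intended product type. Every truth peptide must be
# recoverable from the reference by map_peptide() with its intended type;
# this is checked at build time.

#' Build a constructed reference from high-confidence peptides
#'
#' Filters the input peptides (spectral angle above `sa_threshold`; spliced
#' peptides with an isobaric non-spliced alternative in the original
#' substrate are excluded when `substrate` is given), concatenates the
#' surviving sequences in a seeded random order into an in silico-only
#' reference protein, and records each peptide as a contiguous, non-spliced
#' truth entry.
#'
#' @param peptides Data.frame with columns `spectrum_id`, `sequence`,
#'   `spectral_angle` and optionally `is_spliced`.
#' @param seed Integer seed for the concatenation order.
#' @param sa_threshold Minimum spectral angle.
#' @param substrate Optional [substrate()] for the isobaric exclusion.
#' @param tolerance_ppm Isobaric mass tolerance.
#' @return List of class `ground_truth`: `reference` (a [substrate()]),
#'   `truth` (data.frame `spectrum_id`, `sequence`, `truth_type`, `start`),
#'   `seed`.
#' @export
build_concatenated_reference <- function(peptides, seed, sa_threshold = 0.7,
                                         substrate = NULL,
                                         tolerance_ppm = 6) {
  keep <- peptides$spectral_angle > sa_threshold
  if (!is.null(substrate) && "is_spliced" %in% names(peptides)) {
    subs <- substring_masses(substrate,
                             c(min(nchar(peptides$sequence)),
                               max(nchar(peptides$sequence))))
    iso <- vapply(seq_len(nrow(peptides)), function(r) {
      if (!peptides$is_spliced[r]) return(FALSE)
      m <- peptide_mass(peptides$sequence[r])
      any(abs(subs$mass - m) <= m * tolerance_ppm * 1e-6)
    }, logical(1))
    keep <- keep & !iso
  }
  surv <- peptides[keep, , drop = FALSE]
  if (nrow(surv) == 0L) stop("no peptides survive the high-confidence filter")
  ord <- withr::with_seed(seed, sample.int(nrow(surv)))
  surv <- surv[ord, , drop = FALSE]
  lens <- nchar(surv$sequence)
  start <- cumsum(c(1L, lens[-length(lens)]))
  ref <- substrate(paste0("construct_", seed),
                   paste(surv$sequence, collapse = ""),
                   "in silico-only constructed reference (synthetic)")
  truth <- data.frame(spectrum_id = surv$spectrum_id,
                      sequence = surv$sequence,
                      truth_type = "non_spliced", start = start)
  structure(list(reference = ref, truth = truth, seed = seed),
            class = "ground_truth")
}

#' Embed a peptide into the reference as a spliced product
#'
#' Splits the peptide at a seeded internal position and inserts the two
#' fragments at two distinct, non-adjacent positions of the reference so
#' that [map_peptide()] recovers the peptide only as a forward cis-spliced
#' product (verified after construction; bounded retries).
#'
#' @param peptide Peptide sequence (length >= 2).
#' @param dataset A [build_concatenated_reference()] result.
#' @param spectrum_id Spectrum id of the truth entry.
#' @param seed Integer seed.
#' @param max_attempts Retry bound before giving up.
#' @return Updated `ground_truth` dataset.
#' @export
embed_as_spliced <- function(peptide, dataset, spectrum_id, seed,
                             max_attempts = 100L) {
  len <- nchar(peptide)
  if (len < 2L) stop("peptide too short to split")
  ref0 <- dataset$reference$sequence
  L0 <- nchar(ref0)
  # cut points must not fall inside a contiguous truth peptide, which would
  # destroy its recoverability; cut position c inserts between c and c + 1
  ns <- dataset$truth[dataset$truth$truth_type == "non_spliced" &
                        !is.na(dataset$truth$start), , drop = FALSE]
  blocked <- unlist(lapply(seq_len(nrow(ns)), function(r) {
    s <- ns$start[r]; e <- s + nchar(ns$sequence[r]) - 1L
    if (e > s) seq(s, e - 1L) else integer(0)
  }))
  allowed <- setdiff(seq_len(L0 - 1L), blocked)
  if (length(allowed) < 2L) stop("no admissible insertion points left")
  done <- withr::with_seed(seed, {
    out <- NULL
    for (att in seq_len(max_attempts)) {
      s <- sample.int(len - 1L, 1L)
      f1 <- substr(peptide, 1L, s)
      f2 <- substr(peptide, s + 1L, len)
      cuts <- sort(sample(allowed, 2L))
      if (cuts[2] == cuts[1]) next
      cand <- paste0(substr(ref0, 1L, cuts[1]), f1,
                     substr(ref0, cuts[1] + 1L, cuts[2]), f2,
                     substr(ref0, cuts[2] + 1L, L0))
      mp <- map_peptide(peptide, substrate("cand", cand))
      if (!is.null(mp) && mp$resolved_type %in% c("cis", "cis_multi_mapper") &&
          any(mp$locations$product_type == "cis_forward")) {
        out <- list(cand = cand, cuts = cuts, n1 = nchar(f1),
                    n2 = nchar(f2))
        break
      }
    }
    out
  })
  if (is.null(done))
    stop("could not embed '", peptide, "' as spliced within ",
         max_attempts, " attempts")
  # shift recorded starts of truth peptides downstream of the insertions
  st <- dataset$truth$start
  st[!is.na(st) & st > done$cuts[2]] <-
    st[!is.na(st) & st > done$cuts[2]] + done$n1 + done$n2
  st[!is.na(st) & st > done$cuts[1] & st <= done$cuts[2]] <-
    st[!is.na(st) & st > done$cuts[1] & st <= done$cuts[2]] + done$n1
  dataset$truth$start <- st
  dataset$reference <- substrate(dataset$reference$id, done$cand,
                                 dataset$reference$description)
  dataset$truth <- rbind(dataset$truth,
                         data.frame(spectrum_id = spectrum_id,
                                    sequence = peptide,
                                    truth_type = "spliced",
                                    start = NA_integer_))
  dataset
}

#' Verify truth recoverability of a ground-truth dataset
#'
#' Every truth peptide must map onto the constructed reference with its
#' intended type.
#'
#' @param dataset A `ground_truth` object.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_ground_truth <- function(dataset) {
  for (r in seq_len(nrow(dataset$truth))) {
    mp <- map_peptide(dataset$truth$sequence[r], dataset$reference)
    if (is.null(mp)) stop("truth peptide ", r, " unmappable")
    want <- dataset$truth$truth_type[r]
    got <- mp$resolved_type
    ok <- if (want == "non_spliced") got == "non_spliced" else
      got %in% c("cis", "cis_multi_mapper", "trans")
    if (!ok) stop("truth peptide ", r, " resolves as ", got,
                  " instead of ", want)
  }
  invisible(TRUE)
}

#' Precision-recall evaluation against a ground truth
#'
#' An identification is correct when its sequence matches the truth
#' sequence for that spectrum under I/L equivalence; results for spectra
#' absent from the truth count as incorrect. Curves are computed overall
#' and per truth stratum by sweeping the score threshold; recall is the
#' number of correct identifications over the number of truth spectra of
#' the stratum. An empty result set has recall 0 and precision reported as
#' 1 by convention.
#'
#' @param results Data.frame with `spectrum_id`, `peptide`, `score` and
#'   optionally `q_value`.
#' @param truth A `ground_truth` dataset (or its `truth` data.frame).
#' @param fdr_threshold Operating-point q-value threshold.
#' @return List of class `pr_curve`: `curve` (data.frame `stratum`,
#'   `threshold`, `precision`, `recall`), `operating_point` (per stratum at
#'   the FDR threshold, when `q_value` is present).
#' @export
evaluate_pr <- function(results, truth, fdr_threshold = 0.01) {
  tm <- if (inherits(truth, "ground_truth")) truth$truth else truth
  if (nrow(results) == 0L) {
    return(structure(list(curve = data.frame(stratum = "all", threshold = NA,
                                             precision = 1, recall = 0),
                          operating_point = NULL),
                     class = "pr_curve"))
  }
  tseq <- stats::setNames(canonical_sequence(tm$sequence),
                          as.character(tm$spectrum_id))
  ttype <- stats::setNames(tm$truth_type, as.character(tm$spectrum_id))
  sid <- as.character(results$spectrum_id)
  results$correct <- !is.na(tseq[sid]) &
    canonical_sequence(results$peptide) == tseq[sid]
  results$stratum <- ifelse(is.na(ttype[sid]), "unknown", ttype[sid])

  curve_for <- function(df, n_possible, label) {
    o <- order(-df$score)
    df <- df[o, , drop = FALSE]
    data.frame(stratum = label, threshold = df$score,
               precision = cumsum(df$correct) / seq_len(nrow(df)),
               recall = cumsum(df$correct) / max(n_possible, 1L))
  }
  strata <- unique(tm$truth_type)
  curves <- list(curve_for(results, nrow(tm), "all"))
  for (g in strata) {
    dg <- results[results$stratum == g, , drop = FALSE]
    if (nrow(dg) > 0L)
      curves[[length(curves) + 1L]] <-
        curve_for(dg, sum(tm$truth_type == g), g)
  }
  curve <- do.call(rbind, curves)

  op <- NULL
  if ("q_value" %in% names(results)) {
    acc <- results[results$q_value <= fdr_threshold, , drop = FALSE]
    op <- data.frame(
      stratum = c("all", strata),
      precision = NA_real_, recall = NA_real_)
    for (r in seq_len(nrow(op))) {
      dg <- if (op$stratum[r] == "all") acc else
        acc[acc$stratum == op$stratum[r], , drop = FALSE]
      npos <- if (op$stratum[r] == "all") nrow(tm) else
        sum(tm$truth_type == op$stratum[r])
      op$precision[r] <- if (nrow(dg) == 0L) 1 else mean(dg$correct)
      op$recall[r] <- sum(dg$correct) / max(npos, 1L)
    }
  }
  structure(list(curve = curve, operating_point = op), class = "pr_curve")
}
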