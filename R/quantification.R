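# Label-free MS1 kinetic quantification filtering: substrate-contaminant
# removal, background-noise subtraction, replicate collapsing and the
# reference-time completeness rule.
#
# A kinetics table is a data.frame with columns peptide, time_h, bio_rep,
# tech_rep, intensity (MS1 area >= 0); the time grid includes 0 h.

check_kinetics <- function(table) {
  need <- c("peptide", "time_h", "bio_rep", "tech_rep", "intensity")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L)
    stop("kinetics table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(table$intensity < 0, na.rm = TRUE))
    stop("kinetics table contains negative intensities")
  invisible(table)
}

#' Remove substrate-derived contaminants
#'
#' Peptides present in the purified substrate before proteasomal processing
#' are removed: a spliced peptide is dropped when any control-sample spliced
#' peptide shares its splice-site, i.e. the ordered junction coordinate pair
#' (j, k) of any of its locations (a longer control precursor carries the
#' same junction); a non-spliced peptide found in the controls is dropped
#' only when its maximum 0 h intensity exceeds its maximum intensity at
#' every later time point.
#'
#' @param products Data.frame of identified products, one row per
#'   (peptide, location): columns `sequence`, `product_type`, `i`, `j`,
#'   `k`, `n`.
#' @param control_products Same format, from the 0 h / no-proteasome
#'   control samples.
#' @param kinetics Kinetics table covering the identified peptides (used
#'   for the non-spliced intensity rule).
#' @return Filtered products data.frame.
#' @export
remove_substrate_contaminants <- function(products, control_products,
                                          kinetics) {
  check_kinetics(kinetics)
  is_spliced <- products$product_type != "non_spliced"
  ctrl_spliced <- control_products$product_type != "non_spliced"
  ctrl_sites <- unique(paste(control_products$j[ctrl_spliced],
                             control_products$k[ctrl_spliced]))
  site <- paste(products$j, products$k)
  drop_spliced_seq <- unique(products$sequence[is_spliced &
                                                 site %in% ctrl_sites])

  ctrl_ns_seq <- unique(control_products$sequence[!ctrl_spliced])
  drop_ns_seq <- character(0)
  for (pep in intersect(unique(products$sequence[!is_spliced]), ctrl_ns_seq)) {
    kin <- kinetics[kinetics$peptide == pep, , drop = FALSE]
    if (nrow(kin) == 0L) next
    i0 <- kin$intensity[kin$time_h == 0]
    il <- kin$intensity[kin$time_h > 0]
    if (length(i0) > 0L &&
        (length(il) == 0L || max(i0, na.rm = TRUE) > max(il, na.rm = TRUE))) {
      drop_ns_seq <- c(drop_ns_seq, pep)
    }
  }
  keep <- !(is_spliced & products$sequence %in% drop_spliced_seq) &
    !(!is_spliced & products$sequence %in% drop_ns_seq)
  products[keep, , drop = FALSE]
}

#' Background-noise filtering of a kinetics table
#'
#' The background-noise value of a peptide is the maximum intensity measured
#' at 0 h across all biological and technical replicates (0 when the peptide
#' was never measured at 0 h). The median of these values over peptides with
#' at least one 0 h measurement is the global cut-off. Every measurement is
#' compared against the threshold `max(peptide background, global cut-off)`:
#' smaller values are removed (set missing), all others are reduced by the
#' threshold.
#'
#' The operation consumes raw tables only; a `processed` attribute marks the
#' output and a second application is refused.
#'
#' @param table Raw kinetics data.frame.
#' @return List with `table` (filtered; removed measurements have
#'   `NA` intensity), `background` (per-peptide data.frame with
#'   `background` and `threshold`) and `global_cutoff`.
#' @export
background_noise_filter <- function(table) {
  check_kinetics(table)
  if (isTRUE(attr(table, "processed")))
    stop("table already background-filtered; the filter consumes raw tables only")
  peptides <- unique(table$peptide)
  at0 <- table$time_h == 0
  bg <- vapply(peptides, function(p) {
    v <- table$intensity[at0 & table$peptide == p]
    if (length(v) == 0L) 0 else max(v, na.rm = TRUE)
  }, numeric(1))
  has0 <- vapply(peptides, function(p) any(at0 & table$peptide == p), logical(1))
  if (!any(has0)) {
    message("no 0 h measurements in table; all background values set to 0")
    global <- 0
  } else {
    global <- stats::median(bg[has0])
  }
  thr <- pmax(bg, global)
  t_row <- thr[match(table$peptide, peptides)]
  out <- table
  out$intensity <- ifelse(table$intensity < t_row, NA_real_,
                          table$intensity - t_row)
  attr(out, "processed") <- TRUE
  list(table = out,
       background = data.frame(peptide = peptides, background = unname(bg),
                               threshold = unname(thr)),
       global_cutoff = global)
}

#' Collapse technical replicates
#'
#' Arithmetic mean over the available (non-removed) technical replicates for
#' each (peptide, time point, biological replicate); a cell whose technical
#' replicates were all removed is missing.
#'
#' @param table Background-filtered kinetics data.frame.
#' @return Data.frame with columns `peptide`, `time_h`, `bio_rep`,
#'   `mean_intensity`.
#' @export
collapse_replicates <- function(table) {
  check_kinetics(table)
  agg <- stats::aggregate(intensity ~ peptide + time_h + bio_rep,
                          data = table,
                          FUN = function(v) {
                            v <- v[!is.na(v)]
                            if (length(v) == 0L) NA_real_ else mean(v)
                          },
                          na.action = stats::na.pass)
  names(agg)[names(agg) == "intensity"] <- "mean_intensity"
  agg[order(agg$peptide, agg$time_h, agg$bio_rep), , drop = FALSE]
}

#' Final peptide selection by the reference-time rule
#'
#' Peptides with a missing (or zero) mean intensity at the reference
#' digestion time in every biological replicate are removed from the final
#' quantified set. The rule is evaluated per biological replicate: presence
#' in a single replicate retains the peptide.
#'
#' @param records Output of [collapse_replicates()].
#' @param reference_time Reference digestion time in hours (default 4; 3 for
#'   alpha-Synuclein-style grids).
#' @return Retained records; attribute `dropped` lists removed peptides.
#' @export
finalize_quant <- function(records, reference_time = 4) {
  if (!reference_time %in% unique(records$time_h))
    stop("reference time ", reference_time, " h absent from the time grid")
  at_ref <- records[records$time_h == reference_time, , drop = FALSE]
  present <- tapply(at_ref$mean_intensity, at_ref$peptide,
                    function(v) any(!is.na(v) & v > 0))
  dropped <- names(present)[!present]
  out <- records[!(records$peptide %in% dropped), , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Split a multi-mapper intensity across its origins
#'
#' A peptide explainable by several substrate locations has its intensity
#' divided equally by the number of origins, so that the per-origin values
#' sum exactly to the original.
#'
#' @param intensity Numeric intensity value(s).
#' @param n_origins Positive integer count(s) of substrate origins.
#' @return Per-origin intensity.
#' @export
multi_mapper_adjust <- function(intensity, n_origins) {
  if (any(n_origins < 1)) stop("n_origins must be >= 1")
  intensity / n_origins
}
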