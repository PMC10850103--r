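# Sequence-preference analytics over identified, quantified products.
#
# A products table holds one row per (peptide sequence, substrate location):
# sequence, product_type (non_spliced / cis_forward / cis_reverse / trans),
# i, j, k, n, n_origins, and - where quantitative - intensity, which must
# already be the per-origin value (see multi_mapper_adjust()). For every
# product the P1 residue sits at position j: the C-terminus for non-spliced
# peptides, the C-terminus of the N-terminal splice-reactant for spliced
# peptides.

resolved_class <- function(product_type) {
  ifelse(product_type == "non_spliced", "non_spliced",
         ifelse(product_type == "trans", "trans", "cis"))
}

#' Site-specific cleavage and splicing strengths (SCS-P1 / PSP-P1)
#'
#' For each substrate residue, the summed intensity of all non-spliced
#' peptides with that residue at P1 gives the raw cleavage strength, and the
#' summed intensity of all spliced peptides with that residue at the
#' C-terminus of their first splice-reactant gives the raw splicing
#' strength. Each residue's value is then normalized by the sum over a local
#' window (29 residues by default, truncated at the termini) and expressed
#' as a percentage.
#'
#' @param products Products table with per-origin `intensity` at the
#'   reference time point.
#' @param substrate A [substrate()] object.
#' @param window Odd local window length in residues.
#' @return List with numeric vectors `scs_p1` and `psp_p1` (length L,
#'   percentages in `[0, 100]`).
#' @export
compute_scs_psp <- function(products, substrate, window = 29L) {
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd number of residues")
  L <- substrate$length
  raw <- function(rows) {
    v <- numeric(L)
    for (r in seq_len(nrow(rows))) {
      p <- rows$j[r]
      if (p >= 1L && p <= L) v[p] <- v[p] + rows$intensity[r]
    }
    v
  }
  ns <- products[products$product_type == "non_spliced", , drop = FALSE]
  sp <- products[products$product_type != "non_spliced", , drop = FALSE]
  normalize_window <- function(v) {
    half <- (window - 1L) %/% 2L
    out <- numeric(L)
    for (p in seq_len(L)) {
      w <- sum(v[max(1L, p - half):min(L, p + half)])
      out[p] <- if (w > 0) 100 * v[p] / w else 0
    }
    out
  }
  list(scs_p1 = normalize_window(raw(ns)), psp_p1 = normalize_window(raw(sp)))
}

#' Simulate a qualitative background database
#'
#' Spliced background: the four coordinates (i, j, k, n) are repeatedly
#' sampled uniformly (with replacement) over the substrate length and the
#' tuple is accepted only if it forms a valid spliced peptide (reactant
#' lengths at least `L_ext`, product length inside the identification
#' window, and a forward-cis, reverse-cis or overlapping-trans
#' configuration), until the database holds `factor` times the number of
#' identified spliced sequences. Non-spliced background: all possible
#' non-spliced peptides within the window are enumerated and sampled with
#' replacement. All sampled sequences are re-mapped to the substrate to
#' account for multi-mapping.
#'
#' @param substrate A [substrate()] object.
#' @param identified Identified products table (non-empty).
#' @param factor Background size as a multiple of the identified set.
#' @param seed Integer seed; the sampler is reproducible.
#' @param length_window Identification peptide-length window.
#' @param L_ext Minimal splice-reactant length.
#' @param remap Re-map sampled sequences for multi-mapping (`n_origins`).
#' @return List of class `background_db` with elements `spliced` and
#'   `non_spliced` (products tables), `factor` and `seed`.
#' @export
simulate_background_qualitative <- function(substrate, identified, factor = 50L,
                                            seed, length_window = c(7L, 30L),
                                            L_ext = 1L, remap = TRUE) {
  if (nrow(identified) == 0L) stop("identified set is empty")
  L <- substrate$length
  lw <- as.integer(length_window)
  cls <- resolved_class(identified$product_type)
  n_spliced <- length(unique(identified$sequence[cls != "non_spliced"]))
  n_ns <- length(unique(identified$sequence[cls == "non_spliced"]))
  target_spliced <- factor * n_spliced

  theo <- sum(vapply(seq(max(lw[1], 2 * L_ext), min(lw[2], 2 * L)),
                     function(N) {
                       p <- space_params(N, L_ext)
                       count_forward_cis(L, p) + count_reverse_cis(L, p) +
                         count_trans(L, p)
                     }, numeric(1)))
  if (target_spliced > 0 && theo == 0)
    stop("substrate admits no valid spliced peptide in the length window")

  acc <- withr::with_seed(seed, {
    got <- list(); n_acc <- 0L
    while (n_acc < target_spliced) {
      B <- max(1000L, 4L * (target_spliced - n_acc))
      i <- sample.int(L, B, replace = TRUE)
      j <- sample.int(L, B, replace = TRUE)
      k <- sample.int(L, B, replace = TRUE)
      n <- sample.int(L, B, replace = TRUE)
      a <- j - i + 1L; b <- n - k + 1L
      len <- a + b
      base_ok <- i <= j & k <= n & a >= L_ext & b >= L_ext &
        len >= lw[1] & len <= lw[2]
      overlap <- pmax(i, k) <= pmin(j, n)
      type <- rep(NA_character_, B)
      type[base_ok & overlap] <- "trans"
      type[base_ok & !overlap & k >= j + 2L] <- "cis_forward"
      type[base_ok & !overlap & i >= n + 1L] <- "cis_reverse"
      keep <- which(!is.na(type))
      if (length(keep) > 0L) {
        got[[length(got) + 1L]] <-
          data.frame(i = i[keep], j = j[keep], k = k[keep], n = n[keep],
                     product_type = type[keep])
        n_acc <- n_acc + length(keep)
      }
    }
    if (length(got) == 0L) {
      data.frame(i = integer(0), j = integer(0), k = integer(0),
                 n = integer(0), product_type = character(0))
    } else {
      acc <- do.call(rbind, got)
      acc[seq_len(min(nrow(acc), target_spliced)), , drop = FALSE]
    }
  })
  acc$sequence <- paste0(substring(substrate$sequence, acc$i, acc$j),
                         substring(substrate$sequence, acc$k, acc$n))

  ns_all <- do.call(rbind, lapply(seq(lw[1], min(lw[2], L)), function(N) {
    enumerate_products(substrate, space_params(N, L_ext), "non_spliced")
  }))
  ns_bg <- withr::with_seed(seed + 1L, {
    if (is.null(ns_all) || nrow(ns_all) == 0L || n_ns == 0L) {
      ns_all[0, , drop = FALSE]
    } else {
      ns_all[sample.int(nrow(ns_all), factor * n_ns, replace = TRUE), ,
             drop = FALSE]
    }
  })

  spliced <- data.frame(sequence = acc$sequence, product_type = acc$product_type,
                        i = acc$i, j = acc$j, k = acc$k, n = acc$n,
                        n_origins = 1L)
  if (remap && nrow(spliced) > 0L) {
    uniq <- unique(spliced$sequence)
    no <- vapply(uniq, function(s) {
      mp <- map_peptide(s, substrate, space_params(2, L_ext))
      if (is.null(mp)) 1L else mp$n_origins
    }, integer(1))
    spliced$n_origins <- no[match(spliced$sequence, uniq)]
  }
  if (nrow(ns_bg) > 0L) {
    ns_bg <- data.frame(sequence = ns_bg$sequence, product_type = "non_spliced",
                        i = ns_bg$i, j = ns_bg$j, k = NA_integer_,
                        n = NA_integer_, n_origins = 1L)
    if (remap) {
      uniq <- unique(ns_bg$sequence)
      no <- vapply(uniq, function(s) {
        mp <- map_peptide(s, substrate, space_params(2, L_ext))
        if (is.null(mp)) 1L else mp$n_origins
      }, integer(1))
      ns_bg$n_origins <- no[match(ns_bg$sequence, uniq)]
    }
  } else {
    ns_bg <- spliced[0, , drop = FALSE]
  }
  structure(list(spliced = spliced, non_spliced = ns_bg,
                 factor = factor, seed = seed),
            class = "background_db")
}

#' Assign quantities to a background database
#'
#' Each background sequence receives an intensity drawn uniformly within the
#' range of observed reference-time intensities of detected peptides of the
#' same product class (non-spliced, cis, trans).
#'
#' @param background A [simulate_background_qualitative()] result.
#' @param identified Products table with `intensity` at the reference time.
#' @param seed Integer seed.
#' @return The background database with `intensity` columns added.
#' @export
simulate_background_quantitative <- function(background, identified, seed) {
  cls_id <- resolved_class(identified$product_type)
  draw <- function(df, offset) {
    if (nrow(df) == 0L) return(df)
    cls <- resolved_class(df$product_type)
    df$intensity <- NA_real_
    for (g in unique(cls)) {
      obs <- identified$intensity[cls_id == g]
      if (length(obs) == 0L)
        stop("no observed intensities for product class '", g, "'")
      rng <- range(obs)
      idx <- which(cls == g)
      df$intensity[idx] <- withr::with_seed(seed + offset, {
        stats::runif(length(idx), rng[1], rng[2])
      })
    }
    df
  }
  background$spliced <- draw(background$spliced, 0L)
  background$non_spliced <- draw(background$non_spliced, 1L)
  background
}

LOGO_POSITIONS <- c(paste0("P", 6:1), paste0("P", 1:6, "'"))

#' Position-weight matrix around cleavage/splice sites
#'
#' Builds the 20 x 12 PWM over positions P6..P1 (the six residues ending at
#' the P1 site) and P1'..P6' (the six residues after it: the next substrate
#' residues for non-spliced peptides, the C-terminal splice-reactant onward
#' for spliced peptides). Quantitative weights are log10-transformed
#' intensities (clamped at zero below intensity 10), summed per amino acid
#' and position and normalized so every position column sums to 1; windows
#' truncated at the substrate termini contribute only their existing
#' positions. A position observed in no product gets a uniform column.
#'
#' @param products Products table (with per-origin `intensity` when
#'   `quantitative`).
#' @param substrate A [substrate()] object.
#' @param quantitative Use log10-intensity weights (default) or counts.
#' @return 20 x 12 column-stochastic matrix (rows: amino acids, columns:
#'   `P6..P1, P1'..P6'`).
#' @export
build_pwm <- function(products, substrate, quantitative = TRUE) {
  aa_sub <- strsplit(substrate$sequence, "")[[1]]
  L <- length(aa_sub)
  M <- matrix(0, nrow = 20, ncol = 12,
              dimnames = list(AA_ALPHABET, LOGO_POSITIONS))
  w <- if (quantitative) log10(pmax(products$intensity, 1)) else
    rep(1, nrow(products))
  for (r in seq_len(nrow(products))) {
    p1 <- products$j[r]
    up <- p1 - (5:0)                      # positions P6..P1
    down <- if (products$product_type[r] == "non_spliced") {
      p1 + (1:6)
    } else {
      products$k[r] + (0:5)               # P1'..P6' from the second reactant
    }
    pos <- c(up, down)
    for (c in seq_len(12L)) {
      p <- pos[c]
      if (!is.na(p) && p >= 1L && p <= L) {
        M[aa_sub[p], c] <- M[aa_sub[p], c] + w[r]
      }
    }
  }
  normalize_pwm(M)
}

normalize_pwm <- function(M) {
  cs <- colSums(M)
  for (c in seq_len(ncol(M))) {
    M[, c] <- if (cs[c] > 0) M[, c] / cs[c] else 1 / nrow(M)
  }
  M
}

js_divergence_col <- function(p, q) {
  m <- (p + q) / 2
  term <- function(x) {
    nz <- x > 0
    sum(x[nz] * log2(x[nz] / m[nz]))
  }
  (term(p) + term(q)) / 2
}

#' Jensen-Shannon divergence logo between two PWMs
#'
#' Per position p, the total letter height is the JS divergence (base-2,
#' bits) between the two column distributions; the signed per-letter height
#' is the divergence multiplied by the normalized column difference
#' `r = (P - Q) / sum(|P - Q|)` (zero where the columns are equal). Positive
#' heights mark amino acids over-represented in `P`.
#'
#' @param P,Q Column-stochastic matrices of identical shape.
#' @return List of class `logo_matrix`: `position_height` (`D_p`),
#'   `heights` (signed `D_{a,p}` matrix) and `r` (normalized differences).
#' @export
quantitative_logo <- function(P, Q) {
  if (!all(dim(P) == dim(Q))) stop("PWMs differ in shape")
  np <- ncol(P)
  D <- numeric(np)
  R <- matrix(0, nrow = nrow(P), ncol = np, dimnames = dimnames(P))
  for (c in seq_len(np)) {
    if (isTRUE(all.equal(P[, c], Q[, c], tolerance = 1e-12))) next
    D[c] <- js_divergence_col(P[, c], Q[, c])
    diff <- P[, c] - Q[, c]
    R[, c] <- diff / sum(abs(diff))
  }
  H <- sweep(R, 2, D, "*")
  names(D) <- colnames(P)
  structure(list(position_height = D, heights = H, r = R),
            class = "logo_matrix")
}

#' Quantitative substrate coverage profile
#'
#' For each substrate residue the log10-transformed per-origin intensities
#' of all peptides containing that residue (both splice-reactants for
#' spliced products) are summed. The per-residue quantities are min/max
#' scaled, smoothed with a cubic smoothing spline (smoothing parameter by
#' generalized cross-validation) and min/max scaled a second time.
#'
#' @param products Products table with per-origin `intensity`.
#' @param substrate A [substrate()] object (length >= 4 for the spline).
#' @return Numeric coverage vector of length L in `[0, 1]`.
#' @export
coverage_profile <- function(products, substrate) {
  L <- substrate$length
  if (L < 4L) stop("substrate too short for a smoothed coverage profile")
  cov <- numeric(L)
  w <- log10(pmax(products$intensity, 1))
  for (r in seq_len(nrow(products))) {
    span <- products$i[r]:products$j[r]
    if (!is.na(products$k[r])) span <- c(span, products$k[r]:products$n[r])
    span <- span[span >= 1L & span <= L]
    cov[span] <- cov[span] + w[r]
  }
  minmax <- function(v) {
    rg <- range(v)
    if (rg[1] == rg[2]) return(numeric(length(v)))  # degenerate: all zeros
    (v - rg[1]) / (rg[2] - rg[1])
  }
  sc <- minmax(cov)
  if (all(sc == 0)) return(sc)
  sm <- stats::smooth.spline(seq_len(L), sc)$y
  minmax(sm)
}

#' Hotspot / non-hotspot partition of detected P1 residues
#'
#' The detected P1 residues are split at the median of their coverage
#' values: the half with the highest coverage become hotspot residues
#' (ties at the threshold and the extra residue of an odd count go to the
#' hotspot side). The lowest hotspot coverage is the cut-off; every
#' substrate residue at or above it belongs to the hotspot sequence
#' stretch, the remainder to the non-hotspot stretch.
#'
#' @param coverage Coverage vector from [coverage_profile()].
#' @param p1_positions Integer positions of detected P1 residues (>= 2).
#' @return List of class `hotspot_partition`: `detected`, `hotspot`,
#'   `non_hotspot`, `threshold`, `hot_stretch`, `nonhot_stretch`.
#' @export
hotspot_split <- function(coverage, p1_positions) {
  p1 <- sort(unique(as.integer(p1_positions)))
  if (length(p1) < 2L) stop("need at least two detected P1 residues")
  v <- coverage[p1]
  if (length(unique(v)) == 1L)
    stop("all detected P1 coverages equal; hotspot split is ambiguous")
  n_hot <- ceiling(length(p1) / 2)
  thr <- sort(v, decreasing = TRUE)[n_hot]
  hot <- p1[v >= thr]
  structure(list(detected = p1, hotspot = hot,
                 non_hotspot = setdiff(p1, hot), threshold = thr,
                 hot_stretch = which(coverage >= thr),
                 nonhot_stretch = which(coverage < thr)),
            class = "hotspot_partition")
}

HOTSPOT_POSITIONS <- c(paste0("P", 6:1), paste0("P-", 1:6))

hotspot_window_matrix <- function(positions, substrate, weights = NULL) {
  aa_sub <- strsplit(substrate$sequence, "")[[1]]
  L <- length(aa_sub)
  if (is.null(weights)) weights <- rep(1, length(positions))
  M <- matrix(0, nrow = 20, ncol = 12,
              dimnames = list(AA_ALPHABET, HOTSPOT_POSITIONS))
  for (r in seq_along(positions)) {
    pos <- positions[r] + (-5:6)
    for (c in seq_len(12L)) {
      p <- pos[c]
      if (p >= 1L && p <= L) M[aa_sub[p], c] <- M[aa_sub[p], c] + weights[r]
    }
  }
  M
}

#' Conditional sequence motifs inside and outside hotspots
#'
#' Computes, over the 12-position window P6..P-6 around detected P1
#' residues, the qualitative PWM `P(R)`, the conditional coverage ratio
#' `P(H|R)` (summed coverage of windows contributing amino acid a at
#' position p inside hotspots over all regions), and via Bayes' rule the
#' hotspot and non-hotspot conditional motifs
#' `P(R|H) = P(H|R) P(R) / P(H)` and `P(R|H~)` (column-normalized).
#' Divergence logos are built against randomized backgrounds obtained by
#' permuting the coverage values along the substrate (`n_random`
#' repetitions, seeded), plus the direct hotspot-versus-non-hotspot logo.
#'
#' @param partition A [hotspot_split()] result.
#' @param substrate A [substrate()] object.
#' @param coverage The coverage vector used for the partition.
#' @param n_random Number of randomized backgrounds.
#' @param seed Integer seed for the randomizations.
#' @return List with matrices `p_r`, `p_h_given_r`, `p_r_given_h`,
#'   `p_r_given_nh` and `logos` (elements `hotspot`, `non_hotspot`,
#'   `direct`).
#' @export
hotspot_conditional_pwm <- function(partition, substrate, coverage,
                                    n_random = 100L, seed = 1L) {
  det <- partition$detected
  hot <- partition$hotspot
  if (length(hot) == 0L || length(setdiff(det, hot)) == 0L)
    stop("empty hotspot or non-hotspot class")
  p_h <- length(hot) / length(det)

  p_r <- normalize_pwm(hotspot_window_matrix(det, substrate))
  cov_all <- hotspot_window_matrix(det, substrate, coverage[det])
  cov_hot <- hotspot_window_matrix(hot, substrate, coverage[hot])
  p_h_given_r <- ifelse(cov_all > 0, cov_hot / cov_all, 0)

  p_r_given_h <- normalize_pwm(p_h_given_r * p_r / p_h)
  p_r_given_nh <- normalize_pwm((1 - p_h_given_r) * p_r / (1 - p_h))

  rnd <- withr::with_seed(seed, {
    acc_h <- acc_nh <- matrix(0, 20, 12,
                              dimnames = dimnames(p_r))
    for (b in seq_len(n_random)) {
      cov_b <- sample(coverage)
      vb <- cov_b[det]
      n_hot <- ceiling(length(det) / 2)
      thr_b <- sort(vb, decreasing = TRUE)[n_hot]
      hot_b <- det[vb >= thr_b]
      nh_b <- setdiff(det, hot_b)
      if (length(hot_b) == 0L || length(nh_b) == 0L) next
      all_b <- hotspot_window_matrix(det, substrate, cov_b[det])
      hot_m <- hotspot_window_matrix(hot_b, substrate, cov_b[hot_b])
      phr_b <- ifelse(all_b > 0, hot_m / all_b, 0)
      ph_b <- length(hot_b) / length(det)
      acc_h <- acc_h + normalize_pwm(phr_b * p_r / ph_b)
      acc_nh <- acc_nh + normalize_pwm((1 - phr_b) * p_r / (1 - ph_b))
    }
    list(h = normalize_pwm(acc_h), nh = normalize_pwm(acc_nh))
  })

  list(p_r = p_r, p_h_given_r = p_h_given_r,
       p_r_given_h = p_r_given_h, p_r_given_nh = p_r_given_nh,
       logos = list(hotspot = quantitative_logo(p_r_given_h, rnd$h),
                    non_hotspot = quantitative_logo(p_r_given_nh, rnd$nh),
                    direct = quantitative_logo(p_r_given_h, p_r_given_nh)))
}

#' P1 usage density inside and outside hotspots
#'
#' The number of distinct residues used as P1 by hydrolysis (non-spliced
#' products) and splicing (N-terminal splice-reactants) inside each stretch,
#' divided by the stretch length.
#'
#' @param partition A [hotspot_split()] result.
#' @param products Products table.
#' @return Data.frame with columns `reaction`, `region`, `density`.
#' @export
p1_density <- function(partition, products) {
  if (length(partition$hot_stretch) == 0L ||
      length(partition$nonhot_stretch) == 0L)
    stop("empty hotspot or non-hotspot sequence stretch")
  p1 <- list(
    hydrolysis = unique(products$j[products$product_type == "non_spliced"]),
    splicing = unique(products$j[products$product_type != "non_spliced"]))
  out <- expand.grid(reaction = names(p1), region = c("hotspot", "non_hotspot"),
                     stringsAsFactors = FALSE)
  out$density <- mapply(function(rx, rg) {
    stretch <- if (rg == "hotspot") partition$hot_stretch else
      partition$nonhot_stretch
    length(intersect(p1[[rx]], stretch)) / length(stretch)
  }, out$reaction, out$region)
  out
}

#' Generation efficacy per product type
#'
#' Ratio of the number of detected unique peptide products to the number of
#' all theoretically possible products of the same type, with the
#' theoretical space summed over the identification length window.
#'
#' @param products Identified products table.
#' @param substrate A [substrate()] object.
#' @param length_window Identification peptide-length window.
#' @param L_ext Minimal splice-reactant length.
#' @return Data.frame with columns `type`, `identified`, `theoretical`,
#'   `efficacy`.
#' @export
generation_efficacy <- function(products, substrate,
                                length_window = c(7L, 30L), L_ext = 1L) {
  L <- substrate$length
  Ns <- seq(length_window[1], min(length_window[2], 2L * L))
  theo <- c(non_spliced = 0, cis = 0, trans = 0)
  for (N in Ns) {
    theo["non_spliced"] <- theo["non_spliced"] + count_nonspliced(L, N)
    if (N >= 2 * L_ext && N <= L) {
      p <- space_params(N, L_ext)
      theo["cis"] <- theo["cis"] + count_forward_cis(L, p) +
        count_reverse_cis(L, p)
      theo["trans"] <- theo["trans"] + count_trans(L, p)
    }
  }
  cls <- resolved_class(products$product_type)
  ident <- vapply(names(theo), function(g)
    length(unique(products$sequence[cls == g])), numeric(1))
  if (any(theo == 0))
    stop("zero theoretical count for type(s): ",
         paste(names(theo)[theo == 0], collapse = ", "))
  if (any(ident > theo))
    stop("identified count exceeds theoretical space")
  data.frame(type = names(theo), identified = unname(ident),
             theoretical = unname(theo),
             efficacy = unname(ident / theo))
}

#' Plot a divergence logo as signed letter heights
#'
#' Stacked positive and negative letter heights per position; positive
#' heights mark amino acids over-represented in the first PWM.
#'
#' @param x A [quantitative_logo()] result.
#' @param top Number of letters labeled per position and direction.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.logo_matrix <- function(x, top = 3L, ...) {
  H <- x$heights
  np <- ncol(H)
  ylim <- range(c(colSums(pmax(H, 0)), -colSums(pmax(-H, 0)), 0))
  graphics::plot(NA, xlim = c(0.5, np + 0.5), ylim = ylim,
                 xlab = "position", ylab = "JS divergence (bits)",
                 xaxt = "n", ...)
  graphics::axis(1, at = seq_len(np), labels = colnames(H), las = 2)
  graphics::abline(h = 0, col = "grey60")
  for (c in seq_len(np)) {
    for (sgn in c(1, -1)) {
      v <- sort(H[sgn * H[, c] > 0, c], decreasing = sgn > 0)
      base <- 0
      for (l in seq_len(min(top, length(v)))) {
        graphics::rect(c - 0.4, base, c + 0.4, base + v[l],
                       col = if (sgn > 0) "steelblue" else "firebrick",
                       border = "white")
        graphics::text(c, base + v[l] / 2, names(v)[l], cex = 0.6,
                       col = "white")
        base <- base + v[l]
      }
    }
  }
  invisible(x)
}

#' Plot a substrate coverage profile
#'
#' @param coverage A [coverage_profile()] vector.
#' @param partition Optional [hotspot_split()] result; hotspot stretches are
#'   shaded.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_coverage <- function(coverage, partition = NULL, ...) {
  graphics::plot(seq_along(coverage), coverage, type = "l",
                 xlab = "substrate residue", ylab = "scaled coverage", ...)
  if (!is.null(partition)) {
    r <- rle(seq_along(coverage) %in% partition$hot_stretch)
    ends <- cumsum(r$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    for (b in which(r$values)) {
      graphics::rect(starts[b], graphics::par("usr")[3], ends[b],
                     graphics::par("usr")[4],
                     col = grDevices::adjustcolor("orange", 0.2), border = NA)
    }
    graphics::lines(seq_along(coverage), coverage)
  }
  invisible(coverage)
}
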