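# Coordinate model of the spliced/non-spliced peptide search space.
#
# A peptide product is described by up to four 1-based inclusive residue
# indices on the substrate: the first splice-reactant (i, j) and, for spliced
# products, the second splice-reactant (k, n). The product sequence is the
# concatenation substrate[i..j] + substrate[k..n]. Product classes:
#   non_spliced  - contiguous substring, (k, n) absent
#   cis_forward  - k >= j + 2 (intervening sequence of length >= 1)
#   cis_reverse  - i >= n + 1 (reactants disjoint, first product reactant
#                  downstream of the second; gap may be zero)
#   trans        - reactant intervals overlap (max(i,k) <= min(j,n)), so the
#                  product requires two molecules of the same protein
# Forward-adjacent tuples (k = j + 1) are never spliced products: their
# sequence is identical to a non-spliced peptide.

#' Substrate protein
#'
#' Construct a substrate object: a protein sequence over the canonical
#' 20-letter alphabet with an identifier.
#'
#' @param id Identifier string.
#' @param sequence Amino-acid sequence (uppercase).
#' @param description Optional free-text description.
#' @return An object of class `substrate` with fields `id`, `sequence`,
#'   `description` and `length`.
#' @examples
#' s <- substrate("sub1", "ACDEFGHIK")
#' s$length
#' @export
substrate <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 1L) stop("substrate sequence must be non-empty")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("substrate contains non-canonical residues: ",
         paste(unique(bad), collapse = ", "))
  }
  structure(
    list(id = id, sequence = sequence, description = description,
         length = nchar(sequence)),
    class = "substrate"
  )
}

#' @export
print.substrate <- function(x, ...) {
  cat("<substrate>", x$id, "-", x$length, "residues\n")
  invisible(x)
}

#' Search-space parameters
#'
#' @param N Product length in residues.
#' @param L_ext Minimal splice-reactant length (default 1).
#' @return A list of class `space_params`.
#' @export
space_params <- function(N, L_ext = 1L) {
  N <- as.integer(N); L_ext <- as.integer(L_ext)
  if (is.na(N) || N < 1L) stop("N must be a positive integer")
  if (is.na(L_ext) || L_ext < 1L) stop("L_ext must be a positive integer")
  structure(list(N = N, L_ext = L_ext), class = "space_params")
}

check_LN <- function(L, N) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1)
    stop("L must be a positive integer")
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1)
    stop("N must be a positive integer")
}

check_spliced_params <- function(N, L_ext) {
  if (N < 2L * L_ext)
    stop("spliced products require N >= 2 * L_ext (N = ", N,
         ", L_ext = ", L_ext, ")")
}

#' Count non-spliced peptides
#'
#' Number of distinct coordinate placements of a contiguous peptide of length
#' `N` on a substrate of length `L`: `L - N + 1`, or 0 when the product is
#' longer than the substrate.
#'
#' @param L Substrate length.
#' @param N Product length.
#' @return Non-negative count.
#' @examples
#' count_nonspliced(10, 9)  # 2
#' @export
count_nonspliced <- function(L, N) {
  check_LN(L, N)
  max(0, L - N + 1)
}

#' Count forward cis-spliced peptides
#'
#' Closed form for the number of coordinate tuples (i, j, k, n) of forward
#' cis-spliced products of length `N` from a substrate of length `L`:
#' `(N - 2 L_ext + 1)(L - N)(L - N + 1) / 2`, zero when `L <= N`.
#'
#' @param L Substrate length.
#' @param params A [space_params()] object.
#' @return Non-negative count.
#' @export
count_forward_cis <- function(L, params) {
  check_LN(L, params$N)
  N <- params$N; L_ext <- params$L_ext
  check_spliced_params(N, L_ext)
  if (L <= N) return(0)
  (N - 2 * L_ext + 1) * (L - N) * (L - N + 1) / 2
}

#' Count reverse cis-spliced peptides
#'
#' Closed form `(N - 2 L_ext + 1)(L - N + 1)(L - N + 2) / 2`, zero when
#' `L < N`. Reverse products allow a zero-length gap because the reversed
#' concatenation differs from the contiguous substring.
#'
#' @inheritParams count_forward_cis
#' @return Non-negative count.
#' @export
count_reverse_cis <- function(L, params) {
  check_LN(L, params$N)
  N <- params$N; L_ext <- params$L_ext
  check_spliced_params(N, L_ext)
  if (L < N) return(0)
  (N - 2 * L_ext + 1) * (L - N + 1) * (L - N + 2) / 2
}

#' Count homologous trans-spliced peptides
#'
#' Closed-form polynomial for the number of reactant coordinate pairs whose
#' substrate intervals overlap, so that the product can only arise from two
#' molecules of the same protein.
#'
#' @inheritParams count_forward_cis
#' @return Non-negative count.
#' @export
count_trans <- function(L, params) {
  check_LN(L, params$N)
  N <- params$N; Le <- params$L_ext
  check_spliced_params(N, Le)
  x <- -1 + (2 / 3) * Le^3 + Le^2 * (-1 - N) + (5 / 6) * N + N^2 -
    (5 / 6) * N^3 +
    L * (-1 + Le * (2 - 2 * N) + N^2) +
    Le * (7 / 3 - 3 * N + 2 * N^2)
  max(0, round(x))
}

#' Brute-force counts of the spliced search space
#'
#' Exhaustively loops over all coordinate tuples (i, j, k, n) with reactant
#' lengths summing to `N` and each at least `L_ext`, classifying every tuple
#' by the interval rules. Independent of the closed forms; serves as their
#' oracle.
#'
#' @param L Substrate length.
#' @param params A [space_params()] object.
#' @param cap Refuse substrates longer than this (combinatorial blow-up).
#' @return Named list with counts `non_spliced`, `cis_forward`,
#'   `cis_reverse`, `trans` and `forward_adjacent` (tuples with `k = j + 1`,
#'   which are excluded from every spliced class).
#' @export
brute_force_counts <- function(L, params, cap = 50L) {
  check_LN(L, params$N)
  if (L > cap) stop("L = ", L, " exceeds brute-force cap (", cap, ")")
  N <- params$N; Le <- params$L_ext
  check_spliced_params(N, Le)
  fwd <- rev_ <- trans <- adj <- 0L
  for (a in seq_len(N - 1L)) {          # sr1 length
    b <- N - a                          # sr2 length
    if (a < Le || b < Le) next
    if (a > L || b > L) next
    i <- rep(seq_len(L - a + 1L), each = L - b + 1L)
    k <- rep(seq_len(L - b + 1L), times = L - a + 1L)
    j <- i + a - 1L
    n <- k + b - 1L
    overlap <- pmax(i, k) <= pmin(j, n)
    trans <- trans + sum(overlap)
    fwd <- fwd + sum(!overlap & k >= j + 2L)
    adj <- adj + sum(!overlap & k == j + 1L)
    rev_ <- rev_ + sum(!overlap & i >= n + 1L)
  }
  list(non_spliced = count_nonspliced(L, N), cis_forward = fwd,
       cis_reverse = rev_, trans = trans, forward_adjacent = adj)
}

#' Enumerate peptide products of one class
#'
#' Yields every valid coordinate tuple of the requested product class exactly
#' once, together with the product sequence. Ligation of three or more
#' fragments is not modeled.
#'
#' @param substrate A [substrate()] object.
#' @param params A [space_params()] object.
#' @param product_type One of `"non_spliced"`, `"cis_forward"`,
#'   `"cis_reverse"`, `"trans"`.
#' @return A data.frame with columns `sequence`, `type`, `i`, `j`, `k`, `n`
#'   (the latter two `NA` for non-spliced products).
#' @examples
#' s <- substrate("s", "ACDEF")
#' enumerate_products(s, space_params(2), "cis_forward")
#' @export
enumerate_products <- function(substrate, params, product_type) {
  stopifnot(inherits(substrate, "substrate"), inherits(params, "space_params"))
  type <- match.arg(product_type,
                    c("non_spliced", "cis_forward", "cis_reverse", "trans"))
  L <- substrate$length; N <- params$N; Le <- params$L_ext
  seqc <- substrate$sequence
  empty <- data.frame(sequence = character(0), type = character(0),
                      i = integer(0), j = integer(0),
                      k = integer(0), n = integer(0))

  if (type == "non_spliced") {
    if (N > L) return(empty)
    i <- seq_len(L - N + 1L)
    return(data.frame(sequence = substring(seqc, i, i + N - 1L),
                      type = type, i = i, j = i + N - 1L,
                      k = NA_integer_, n = NA_integer_))
  }

  check_spliced_params(N, Le)
  rows <- list()
  for (a in seq_len(N - 1L)) {
    b <- N - a
    if (a < Le || b < Le || a > L || b > L) next
    i <- rep(seq_len(L - a + 1L), each = L - b + 1L)
    k <- rep(seq_len(L - b + 1L), times = L - a + 1L)
    j <- i + a - 1L
    n <- k + b - 1L
    keep <- switch(type,
      cis_forward = (pmax(i, k) > pmin(j, n)) & k >= j + 2L,
      cis_reverse = (pmax(i, k) > pmin(j, n)) & i >= n + 1L,
      trans       = pmax(i, k) <= pmin(j, n))
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <-
      data.frame(sequence = paste0(substring(seqc, i[keep], j[keep]),
                                   substring(seqc, k[keep], n[keep])),
                 type = type, i = i[keep], j = j[keep],
                 k = k[keep], n = n[keep])
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

canonical_sequence <- function(x, residue_equivalence = c(I = "L")) {
  if (length(residue_equivalence) == 0L) return(x)
  chartr(paste(names(residue_equivalence), collapse = ""),
         paste(residue_equivalence, collapse = ""), x)
}

find_all <- function(pattern, text) {
  m <- gregexpr(pattern, text, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Map a peptide sequence onto a substrate
#'
#' Exact string matching of the complete sequence first; if that fails, the
#' sequence is split into two splice-reactants at every possible position and
#' each reactant is matched independently. All valid coordinate combinations
#' are reported. Leucine and isoleucine are treated as equivalent by default
#' (identical monoisotopic mass). Resolution precedence is
#' non-spliced > cis > trans; a sequence explainable by both forward and
#' reverse cis locations (and not non-spliced) is a cis multi-mapper.
#'
#' @param sequence Peptide sequence.
#' @param substrate A [substrate()] object.
#' @param params A [space_params()] object (only `L_ext` is used).
#' @param residue_equivalence Named character vector of residue equivalences
#'   applied before matching; default `c(I = "L")`.
#' @return `NULL` if the sequence cannot be explained by at most two
#'   fragments; otherwise a list of class `peptide_product` with fields
#'   `sequence`, `resolved_type` (`non_spliced`, `cis`, `trans` or
#'   `cis_multi_mapper`), `locations` (data.frame `product_type,i,j,k,n`) and
#'   `n_origins`.
#' @examples
#' s <- substrate("s", "ACDEFGH")
#' map_peptide("ACEF", s)$resolved_type   # "cis"
#' @export
map_peptide <- function(sequence, substrate, params = space_params(2),
                        residue_equivalence = c(I = "L")) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L, inherits(substrate, "substrate"))
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, AA_ALPHABET)
  if (length(bad) > 0L)
    stop("invalid residue(s) in peptide: ", paste(unique(bad), collapse = ", "))

  pep <- canonical_sequence(sequence, residue_equivalence)
  sub <- canonical_sequence(substrate$sequence, residue_equivalence)
  len <- nchar(pep)
  Le <- params$L_ext

  hits <- find_all(pep, sub)
  if (length(hits) > 0L) {
    loc <- data.frame(product_type = "non_spliced", i = hits,
                      j = hits + len - 1L, k = NA_integer_, n = NA_integer_)
    return(structure(list(sequence = sequence, resolved_type = "non_spliced",
                          locations = loc, n_origins = nrow(loc)),
                     class = "peptide_product"))
  }
  if (len < 2L * Le) return(NULL)

  locs <- list()
  for (s in seq(Le, len - Le)) {
    f1 <- substr(pep, 1L, s)
    f2 <- substr(pep, s + 1L, len)
    p1 <- find_all(f1, sub)
    p2 <- find_all(f2, sub)
    if (length(p1) == 0L || length(p2) == 0L) next
    i <- rep(p1, each = length(p2))
    k <- rep(p2, times = length(p1))
    j <- i + s - 1L
    n <- k + (len - s) - 1L
    overlap <- pmax(i, k) <= pmin(j, n)
    type <- rep(NA_character_, length(i))
    type[overlap] <- "trans"
    type[!overlap & k >= j + 2L] <- "cis_forward"
    type[!overlap & i >= n + 1L] <- "cis_reverse"
    keep <- !is.na(type)   # k = j + 1 would imply an exact match; skipped
    if (any(keep)) {
      locs[[length(locs) + 1L]] <-
        data.frame(product_type = type[keep], i = i[keep], j = j[keep],
                   k = k[keep], n = n[keep])
    }
  }
  if (length(locs) == 0L) return(NULL)
  all_locs <- unique(do.call(rbind, locs))
  rownames(all_locs) <- NULL

  cis <- all_locs[all_locs$product_type %in% c("cis_forward", "cis_reverse"), ]
  if (nrow(cis) > 0L) {
    both <- length(unique(cis$product_type)) == 2L
    resolved <- if (both) "cis_multi_mapper" else "cis"
    loc <- cis
  } else {
    resolved <- "trans"
    loc <- all_locs[all_locs$product_type == "trans", ]
  }
  rownames(loc) <- NULL
  structure(list(sequence = sequence, resolved_type = resolved,
                 locations = loc, n_origins = nrow(loc)),
            class = "peptide_product")
}

#' @export
print.peptide_product <- function(x, ...) {
  cat("<peptide_product>", x$sequence, "-", x$resolved_type,
      "-", x$n_origins, "origin(s)\n")
  invisible(x)
}
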