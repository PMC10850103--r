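test_that("non-spliced counts follow the closed form", {
  expect_equal(count_nonspliced(10, 9), 2)
  expect_equal(count_nonspliced(5, 5), 1)
  expect_equal(count_nonspliced(5, 6), 0)
  expect_error(count_nonspliced(0, 3), "positive")
  expect_error(count_nonspliced(5, -1), "positive")
})

test_that("cis and trans closed forms match hand-enumerated cases", {
  p2 <- space_params(2)
  expect_equal(count_forward_cis(3, p2), 1)
  expect_equal(count_forward_cis(9, space_params(9)), 0)  # L = N
  expect_equal(count_forward_cis(20, space_params(9)), 528)
  expect_equal(count_reverse_cis(3, p2), 3)
  # L = N, L_ext = 1: (L-N+1)(L-N+2)/2 = 1, so N - 1 reverse products
  expect_equal(count_reverse_cis(5, space_params(5)), 4)
  expect_equal(count_trans(2, p2), 2)
  expect_equal(count_trans(3, p2), 3)
  expect_error(count_forward_cis(10, space_params(3, 2)), "L_ext")
})

test_that("closed forms equal the brute-force oracle over a parameter sweep", {
  for (L in c(1:12, 15, 18)) {
    for (N in seq_len(min(L, 10))) {
      for (Le in 1:2) {
        if (N < 2 * Le) next
        p <- space_params(N, Le)
        bf <- brute_force_counts(L, p)
        expect_equal(count_forward_cis(L, p), bf$cis_forward)
        expect_equal(count_reverse_cis(L, p), bf$cis_reverse)
        expect_equal(count_trans(L, p), bf$trans)
        expect_equal(count_nonspliced(L, N), bf$non_spliced)
      }
    }
  }
  expect_error(brute_force_counts(60, space_params(5)), "cap")
})

test_that("enumeration yields each coordinate tuple exactly once", {
  s <- substrate("s", "ACDEF")
  e <- enumerate_products(s, space_params(2), "cis_forward")
  expect_equal(nrow(e), 6)
  expect_setequal(paste(e$i, e$j, e$k, e$n),
                  c("1 1 3 3", "1 1 4 4", "1 1 5 5",
                    "2 2 4 4", "2 2 5 5", "3 3 5 5"))
  expect_equal(e$sequence[e$i == 1 & e$k == 3], "AD")

  s3 <- substrate("s3", "ACD")
  expect_equal(nrow(enumerate_products(s3, space_params(2), "trans")), 3)
  expect_equal(nrow(enumerate_products(s3, space_params(4), "non_spliced")), 0)
  expect_error(enumerate_products(s, space_params(2), "bogus"))

  # cardinalities equal the closed forms, and no duplicated tuples
  for (N in c(2, 3, 5)) {
    p <- space_params(N)
    s8 <- substrate("s8", "ACDEFGHK")
    for (ty in c("cis_forward", "cis_reverse", "trans")) {
      e <- enumerate_products(s8, p, ty)
      cnt <- switch(ty, cis_forward = count_forward_cis(8, p),
                    cis_reverse = count_reverse_cis(8, p),
                    trans = count_trans(8, p))
      expect_equal(nrow(e), cnt)
      expect_false(any(duplicated(e[, c("i", "j", "k", "n")])))
    }
  }
})

test_that("forward-adjacent tuples are never emitted as spliced", {
  s <- substrate("s", "ACDEFGHK")
  e <- enumerate_products(s, space_params(4), "cis_forward")
  expect_true(all(e$k >= e$j + 2))
  # an adjacent concatenation equals a non-spliced peptide
  ns <- enumerate_products(s, space_params(4), "non_spliced")$sequence
  adjacent <- paste0(substr(s$sequence, 1, 2), substr(s$sequence, 3, 4))
  expect_true(adjacent %in% ns)
})

test_that("map_peptide resolves type with non-spliced > cis > trans precedence", {
  s <- substrate("s", "ACDEFGH")
  mp <- map_peptide("ACD", s)
  expect_equal(mp$resolved_type, "non_spliced")
  expect_equal(unlist(mp$locations[1, c("i", "j")], use.names = FALSE), c(1, 3))

  mp <- map_peptide("ACEF", s)
  expect_equal(mp$resolved_type, "cis")
  expect_equal(unlist(mp$locations[1, c("i", "j", "k", "n")],
                      use.names = FALSE), c(1, 2, 4, 5))

  mp <- map_peptide("AA", s)
  expect_equal(mp$resolved_type, "trans")
  expect_equal(unlist(mp$locations[1, c("i", "j", "k", "n")],
                      use.names = FALSE), c(1, 1, 1, 1))

  expect_null(map_peptide("WWWW", s))
  expect_error(map_peptide("AxC", s), "invalid")
})

test_that("mapping treats isoleucine and leucine as equivalent", {
  s <- substrate("s", "AIDEFGH")
  mp <- map_peptide("ALD", s)
  expect_equal(mp$resolved_type, "non_spliced")
  mp2 <- map_peptide("ALD", s, residue_equivalence = character(0))
  expect_null(mp2)
})

test_that("enumerated products map back to their generating location", {
  s <- substrate("s", "ACDEFGHKMW")
  for (ty in c("non_spliced", "cis_forward", "cis_reverse", "trans")) {
    e <- enumerate_products(s, space_params(4), ty)
    pick <- e[seq(1, nrow(e), length.out = min(8, nrow(e))), , drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      mp <- map_peptide(pick$sequence[r], s)
      expect_false(is.null(mp))
      loc <- mp$locations
      if (ty == "non_spliced") {
        expect_equal(mp$resolved_type, "non_spliced")
      } else if (mp$resolved_type != "non_spliced") {
        found <- any(loc$i == pick$i[r] & loc$j == pick$j[r] &
                       loc$k == pick$k[r] & loc$n == pick$n[r])
        expect_true(found || ty == "trans" &&
                      mp$resolved_type %in% c("cis", "cis_multi_mapper"))
      }
    }
  }
})

test_that("substrate and params validate their invariants", {
  expect_error(substrate("x", ""), "non-empty")
  expect_error(substrate("x", "ABZ"), "non-canonical")
  expect_error(space_params(0), "positive")
  expect_error(space_params(5, 0), "positive")
})
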