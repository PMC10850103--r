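rand_pwm <- function(seed, ncol = 12L) {
  withr::with_seed(seed, {
    M <- matrix(stats::runif(20 * ncol), 20, ncol,
                dimnames = list(names(splicescope::residue_masses),
                                paste0("c", seq_len(ncol))))
    sweep(M, 2, colSums(M), "/")
  })
}

test_that("SCS-P1 window normalization yields the stated percentages", {
  sub <- simulate_substrate(60, seed = 2)
  # raw value 1 at every residue: non-spliced product ending at each position
  prods <- data.frame(sequence = paste0("p", 1:60), product_type = "non_spliced",
                      i = pmax(1, (1:60) - 5), j = 1:60, k = NA, n = NA,
                      n_origins = 1, intensity = 1)
  prof <- compute_scs_psp(prods, sub)
  expect_equal(prof$scs_p1[30], 100 / 29, tolerance = 1e-12)
  expect_equal(prof$scs_p1[1], 100 / 15, tolerance = 1e-12)  # truncated window
  expect_true(all(prof$scs_p1 >= 0 & prof$scs_p1 <= 100))
  expect_equal(prof$psp_p1, rep(0, 60))

  single <- prods[30, , drop = FALSE]
  prof2 <- compute_scs_psp(single, sub)
  expect_equal(prof2$scs_p1[30], 100)
  zero <- transform(prods, intensity = 0)
  expect_equal(compute_scs_psp(zero, sub)$scs_p1, rep(0, 60))
  expect_error(compute_scs_psp(prods, sub, window = 28), "odd")
})

test_that("JS-divergence logos satisfy the divergence identities", {
  P <- rand_pwm(1)
  lg0 <- quantitative_logo(P, P)
  expect_equal(unname(lg0$position_height), rep(0, 12))
  expect_equal(max(abs(lg0$heights)), 0)

  # disjoint point masses diverge by exactly 1 bit
  A <- matrix(0, 20, 1, dimnames = list(rownames(P), "c")); A[1, 1] <- 1
  B <- matrix(0, 20, 1, dimnames = list(rownames(P), "c")); B[2, 1] <- 1
  expect_equal(unname(quantitative_logo(A, B)$position_height), 1)

  for (s in 1:25) {
    P <- rand_pwm(s); Q <- rand_pwm(s + 1000)
    lg <- quantitative_logo(P, Q)
    expect_true(all(lg$position_height >= 0 & lg$position_height <= 1))
    expect_equal(lg$position_height,
                 quantitative_logo(Q, P)$position_height)   # symmetry
    expect_equal(unname(colSums(abs(lg$r))), rep(1, 12))    # sum |r| = 1
    expect_equal(lg$heights, sweep(lg$r, 2, lg$position_height, "*"))
  }
  expect_error(quantitative_logo(P, P[, 1:3]), "shape")
})

test_that("quantitative PWMs are column-stochastic over the junction window", {
  sub <- simulate_substrate(120, seed = 4)
  cfg <- digestion_sim_config(n_products = 60, seed = 4)
  dig <- simulate_digestion(sub, cfg)
  prods <- dig$products
  prods$intensity <- multi_mapper_adjust(
    dig$truth$abundance_ref[match(prods$sequence, dig$truth$sequence)],
    prods$n_origins)
  P <- build_pwm(prods, sub)
  expect_equal(dim(P), c(20, 12))
  expect_equal(unname(colSums(P)), rep(1, 12), tolerance = 1e-9)
  expect_true(all(P >= 0))
})

test_that("the background sampler accepts only valid tuples, reproducibly", {
  sub <- simulate_substrate(40, seed = 9)
  ident <- data.frame(sequence = paste0("sp", 1:30),
                      product_type = "cis_forward",
                      i = 1, j = 4, k = 8, n = 11)
  bg <- simulate_background_qualitative(sub, ident, factor = 10, seed = 42,
                                        length_window = c(7, 20))
  expect_equal(nrow(bg$spliced), 10 * 30)
  sp <- bg$spliced
  a <- sp$j - sp$i + 1; b <- sp$n - sp$k + 1
  expect_true(all(sp$i <= sp$j & sp$k <= sp$n))
  expect_true(all(a >= 1 & b >= 1))
  expect_true(all(a + b >= 7 & a + b <= 20))
  overlap <- pmax(sp$i, sp$k) <= pmin(sp$j, sp$n)
  fwd <- !overlap & sp$k >= sp$j + 2
  rev_ <- !overlap & sp$i >= sp$n + 1
  expect_true(all(overlap | fwd | rev_))
  expect_true(all(nchar(sp$sequence) == a + b))

  bg2 <- simulate_background_qualitative(sub, ident, factor = 10, seed = 42,
                                         length_window = c(7, 20))
  expect_identical(bg$spliced, bg2$spliced)
  bg3 <- simulate_background_qualitative(sub, ident, factor = 10, seed = 43,
                                         length_window = c(7, 20))
  expect_false(identical(bg$spliced, bg3$spliced))
})

test_that("quantitative background draws stay within observed ranges", {
  sub <- simulate_substrate(40, seed = 9)
  ident <- data.frame(sequence = c(paste0("sp", 1:10), paste0("tr", 1:4),
                                   paste0("ns", 1:10)),
                      product_type = rep(c("cis_forward", "trans",
                                           "non_spliced"), c(10, 4, 10)),
                      i = 1, j = 4,
                      k = c(rep(8, 10), rep(2, 4), rep(NA, 10)),
                      n = c(rep(11, 10), rep(6, 4), rep(NA, 10)),
                      intensity = c(rep(500, 10), rep(800, 4),
                                    stats::runif(10, 100, 900)))
  bg <- simulate_background_qualitative(sub, ident, factor = 5, seed = 1,
                                        length_window = c(7, 20))
  bg <- bg[c("spliced", "non_spliced", "factor", "seed")]
  class(bg) <- "background_db"
  bgq <- simulate_background_quantitative(bg, ident, seed = 3)
  # degenerate uniform: all observed cis intensities equal 500
  expect_true(all(bgq$spliced$intensity[
    splicescope:::resolved_class(bgq$spliced$product_type) == "cis"] == 500))
  rng <- range(ident$intensity[ident$product_type == "non_spliced"])
  expect_true(all(bgq$non_spliced$intensity >= rng[1] &
                    bgq$non_spliced$intensity <= rng[2]))
  # empirical mean of many draws approaches the midpoint of the range
  ident2 <- ident; ident2$intensity[1:10] <- c(100, rep(300, 8), 500)
  big <- simulate_background_qualitative(sub, ident2, factor = 1000, seed = 5,
                                         length_window = c(7, 20),
                                         remap = FALSE)
  bigq <- simulate_background_quantitative(big, ident2, seed = 7)
  v <- bigq$spliced$intensity[
    splicescope:::resolved_class(bigq$spliced$product_type) == "cis"]
  se <- (500 - 100) / sqrt(12) / sqrt(length(v))
  expect_lt(abs(mean(v) - 300), 3 * se)
})

test_that("coverage profiles are doubly min/max-scaled and spline-smoothed", {
  sub <- simulate_substrate(80, seed = 12)
  prods <- data.frame(sequence = "x", product_type = "non_spliced",
                      i = 38, j = 44, k = NA, n = NA, n_origins = 1,
                      intensity = 1e6)
  more <- withr::with_seed(3, data.frame(
    sequence = paste0("y", 1:15), product_type = "non_spliced",
    i = sample(1:70, 15), j = 0, k = NA, n = NA, n_origins = 1,
    intensity = stats::runif(15, 10, 100)))
  more$j <- pmin(80, more$i + 7)
  cov <- coverage_profile(rbind(prods, more), sub)
  expect_true(all(cov >= 0 & cov <= 1))
  expect_equal(max(cov), 1)
  expect_equal(min(cov), 0)
  expect_lt(abs(which.max(cov) - 41), 5)  # peak at/near the intense span

  const <- data.frame(sequence = "c", product_type = "non_spliced",
                      i = 1, j = 80, k = NA, n = NA, n_origins = 1,
                      intensity = 100)
  expect_equal(coverage_profile(const, sub), rep(0, 80))  # degenerate scaling
  expect_error(coverage_profile(prods, substrate("tiny", "ACD")), "short")
})

test_that("hotspot split halves detected P1 residues at the coverage median", {
  cov <- seq(0.01, 1, length.out = 100)
  part <- hotspot_split(cov, 1:100)
  expect_length(part$hotspot, 50)
  expect_equal(part$threshold, min(cov[part$hotspot]))
  expect_true(all(cov[part$hotspot] >= part$threshold))
  expect_length(intersect(part$hot_stretch, part$nonhot_stretch), 0)

  part_odd <- hotspot_split(cov, 1:101 - 1 + 1)  # 100 detected; use 101 next
  cov101 <- seq(0.01, 1, length.out = 101)
  part_odd <- hotspot_split(cov101, 1:101)
  expect_length(part_odd$hotspot, 51)  # odd count: extra residue to hotspot

  expect_error(hotspot_split(rep(0.5, 10), 1:10), "ambiguous")
  expect_error(hotspot_split(cov, 5), "at least two")
})

test_that("Bayes-rule motifs reduce to P(R) when hotspot membership is uninformative", {
  p_r <- rand_pwm(77)
  phr <- matrix(0.5, 20, 12, dimnames = dimnames(p_r))
  # P(R|H) = P(H|R) P(R) / P(H) with P(H) = 0.5 and P(H|R) = 0.5 everywhere
  expect_equal(splicescope:::normalize_pwm(phr * p_r / 0.5), p_r)
  # coverage concentrated entirely in hotspots: non-hotspot mass vanishes
  phr1 <- matrix(1, 20, 12, dimnames = dimnames(p_r))
  raw_nh <- (1 - phr1) * p_r / 0.5
  expect_equal(max(raw_nh), 0)
})

test_that("hotspot conditional motifs are column-stochastic and seeded", {
  sub <- simulate_substrate(150, seed = 31)
  cfg <- digestion_sim_config(n_products = 120, seed = 31)
  dig <- simulate_digestion(sub, cfg)
  prods <- dig$products
  prods$intensity <- multi_mapper_adjust(
    dig$truth$abundance_ref[match(prods$sequence, dig$truth$sequence)],
    prods$n_origins)
  cov <- coverage_profile(prods, sub)
  p1 <- unique(prods$j[prods$product_type == "non_spliced"])
  part <- hotspot_split(cov, p1)
  hc1 <- hotspot_conditional_pwm(part, sub, cov, n_random = 10, seed = 5)
  hc2 <- hotspot_conditional_pwm(part, sub, cov, n_random = 10, seed = 5)
  expect_identical(hc1, hc2)
  expect_equal(unname(colSums(hc1$p_r)), rep(1, 12), tolerance = 1e-9)
  expect_equal(unname(colSums(hc1$p_r_given_h)), rep(1, 12), tolerance = 1e-9)
  expect_equal(unname(colSums(hc1$p_r_given_nh)), rep(1, 12), tolerance = 1e-9)
  expect_true(all(hc1$p_h_given_r >= 0 & hc1$p_h_given_r <= 1))
})

test_that("P1 densities are distinct-residue counts over stretch lengths", {
  part <- structure(list(detected = 1:10, hotspot = 6:10, non_hotspot = 1:5,
                         threshold = 0.5, hot_stretch = 11:20,
                         nonhot_stretch = 1:10),
                    class = "hotspot_partition")
  prods <- data.frame(sequence = paste0("p", 1:8),
                      product_type = "non_spliced",
                      i = 1, j = c(11:18), k = NA, n = NA)
  d <- p1_density(part, prods)
  expect_equal(d$density[d$reaction == "hydrolysis" & d$region == "hotspot"],
               0.8)
  expect_equal(d$density[d$reaction == "splicing" & d$region == "hotspot"], 0)
  expect_true(all(d$density >= 0 & d$density <= 1))
  empty <- part; empty$nonhot_stretch <- integer(0)
  expect_error(p1_density(empty, prods), "empty")
})

test_that("generation efficacy divides identified by the type-specific space", {
  sub <- substrate("s", "ACDEFGHKMWYVTSRQ")  # L = 16
  lw <- c(7, 10)
  prods <- data.frame(
    sequence = c(substr(sub$sequence, 1, 7), substr(sub$sequence, 2, 9)),
    product_type = "non_spliced", i = c(1, 2), j = c(7, 9), k = NA, n = NA)
  eff <- generation_efficacy(prods, sub, length_window = lw)
  theo_ns <- sum(vapply(7:10, function(N) count_nonspliced(16, N), numeric(1)))
  expect_equal(eff$theoretical[eff$type == "non_spliced"], theo_ns)
  expect_equal(eff$efficacy[eff$type == "non_spliced"], 2 / theo_ns)
  theo_cis <- sum(vapply(7:10, function(N) {
    p <- space_params(N)
    count_forward_cis(16, p) + count_reverse_cis(16, p)
  }, numeric(1)))
  expect_equal(eff$theoretical[eff$type == "cis"], theo_cis)
  expect_true(all(eff$efficacy >= 0 & eff$efficacy <= 1))
})
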