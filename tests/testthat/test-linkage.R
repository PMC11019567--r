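# Pairwise LD: haplotype-level coefficients, overall D', Wn, asymmetric
# ALD, and the permutation significance test.

test_that("haplotype-level D and D' match hand arithmetic on the 2x3 table", {
  co <- ld_coefficients(h_2x3())
  expect_equal(co$d[1, 1], 0.2, tolerance = 1e-12)
  expect_equal(co$dprime[1, 1], 1.0, tolerance = 1e-12)
  expect_equal(co$d[1, 2], -0.05, tolerance = 1e-12)
  expect_equal(abs(co$dprime[1, 2]), 1 / 3, tolerance = 1e-12)
  expect_equal(sum(co$d), 0, tolerance = 1e-10)
})

test_that("complete LD and independence give the boundary values", {
  h_complete <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  co <- ld_coefficients(h_complete)
  expect_equal(co$d[1, 1], 0.25)
  expect_equal(co$dprime[1, 1], 1)
  expect_equal(dprime_overall(co$dprime, co$p, co$q), 1)
  expect_equal(wn_overall(co$d, co$p, co$q), 1)
  expect_equal(unname(ald_pair(h_complete)), c(1, 1))

  p <- c(0.2, 0.3, 0.5); q <- c(0.6, 0.4)
  h_indep <- outer(p, q)
  co2 <- ld_coefficients(h_indep)
  expect_equal(max(abs(co2$d)), 0, tolerance = 1e-14)
  expect_equal(dprime_overall(co2$dprime, p, q), 0)
  expect_equal(wn_overall(co2$d, p, q), 0)
  expect_equal(unname(ald_pair(h_indep)), c(0, 0), tolerance = 1e-7)
})

test_that("overall D' and Wn match hand arithmetic on the 2x3 table", {
  co <- ld_coefficients(h_2x3())
  expect_equal(dprime_overall(co$dprime, co$p, co$q), 0.8, tolerance = 1e-12)
  expect_equal(wn_overall(co$d, co$p, co$q), sqrt(0.7333333333333333),
               tolerance = 1e-12)
})

test_that("ALD reproduces the hand-computed asymmetric 2x3 values", {
  ald <- ald_pair(h_2x3())
  expect_equal(unname(ald["w12"]), sqrt(11 / 15), tolerance = 1e-12)
  expect_equal(unname(ald["w21"]), sqrt(0.26 / 0.66), tolerance = 1e-12)
  expect_equal(round(unname(ald), 4), c(0.8563, 0.6276))
})

test_that("ALD agrees with an independent brute-force evaluation", {
  set.seed(101)
  for (rep in 1:100) {
    h <- random_h(sample(2:5, 1), sample(2:5, 1))
    got <- ald_pair(h)
    want <- ald_brute(h)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("for biallelic pairs W12 and W21 both equal |r|", {
  set.seed(102)
  worst <- 0
  for (rep in 1:300) {
    h <- random_h(2, 2)
    p <- rowSums(h); q <- colSums(h)
    r_abs <- abs(h[1, 1] - p[1] * q[1]) / sqrt(p[1] * p[2] * q[1] * q[2])
    ald <- ald_pair(h)
    worst <- max(worst, abs(ald["w12"] - r_abs), abs(ald["w21"] - r_abs))
    # Wn reduces to |r| as well
    co <- ld_coefficients(h)
    worst <- max(worst, abs(wn_overall(co$d, p, q) - r_abs))
  }
  expect_lt(worst, 1e-10)
})

test_that("all summary measures stay in [0, 1] and D sums to zero", {
  set.seed(103)
  for (rep in 1:50) {
    h <- random_h(sample(2:6, 1), sample(2:6, 1))
    co <- ld_coefficients(h)
    expect_equal(sum(co$d), 0, tolerance = 1e-10)
    dp <- dprime_overall(co$dprime, co$p, co$q)
    wn <- wn_overall(co$d, co$p, co$q)
    ald <- ald_pair(h)
    expect_true(dp >= 0 && dp <= 1 + 1e-12)
    expect_true(wn >= 0 && wn <= 1 + 1e-12)
    expect_true(all(ald >= 0 & ald <= 1 + 1e-12))
  }
})

test_that("ALD asymmetry vanishes on transpose-symmetric square tables", {
  set.seed(104)
  for (rep in 1:20) {
    x <- matrix(stats::rexp(9), 3, 3)
    x <- (x + t(x)) / 2
    h <- x / sum(x)
    ald <- ald_pair(h)
    expect_equal(unname(ald["w12"]), unname(ald["w21"]), tolerance = 1e-12)
  }
})

test_that("a monomorphic focal locus yields an undefined (NA) ALD, not zero", {
  h <- matrix(c(0.6, 0.4), 1, 2)  # locus 1 monomorphic
  ald <- ald_pair(h)
  expect_true(is.na(ald["w12"]))
  expect_equal(unname(ald["w21"]), 0, tolerance = 1e-12)
  expect_true(is.na(wn_overall(h - outer(rowSums(h), colSums(h)),
                               rowSums(h), colSums(h))))
})

test_that("marginal inconsistency is rejected", {
  h <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  expect_error(ld_coefficients(h, p = c(0.6, 0.4)), "inconsistent")
  expect_error(ald_pair(h, q = c(0.7, 0.3)), "inconsistent")
})

test_that("ld_pair computes the full record from a dataset via EM", {
  # phase-known-equivalent data: all homozygotes, perfect association
  rows <- c(lapply(1:6, function(i) c("A", "A", "B", "B")),
            lapply(1:4, function(i) c("a", "a", "b", "b")))
  d <- make_dataset(c("L1", "L2"), rows)
  res <- ld_pair(d, "L1", "L2")
  expect_equal(res$dprime_overall, 1, tolerance = 1e-6)
  expect_equal(res$wn, 1, tolerance = 1e-6)
  expect_equal(res$ald_1_2, 1, tolerance = 1e-6)
  expect_null(res$permutation)   # none requested
})

test_that("permutation p-value hits its minimum under perfect association", {
  set.seed(105)
  hf <- c("A~B" = 0.6, "a~b" = 0.4)   # complete LD
  sim <- sample_population(simulation_spec(c("L1", "L2"), haplotype_freqs = hf,
                                           n_individuals = 100, seed = 55))
  perm <- ld_permutation_test(sim$dataset, "L1", "L2",
                              n_permutations = 99, seed = 4)
  expect_equal(perm$p_value, 1 / 100)
  expect_equal(perm$statistic, "wn")
})

test_that("permutation test is reproducible under a fixed seed", {
  set.seed(106)
  sim <- sample_population(simulation_spec(
    c("L1", "L2"), allele_freqs = list(c(A = 0.5, a = 0.5), c(B = 0.5, b = 0.5)),
    n_individuals = 30, seed = 66))
  p1 <- ld_permutation_test(sim$dataset, "L1", "L2", n_permutations = 50, seed = 8)
  p2 <- ld_permutation_test(sim$dataset, "L1", "L2", n_permutations = 50, seed = 8)
  expect_identical(p1$p_value, p2$p_value)
})
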