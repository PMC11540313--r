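test_that("meiosis counts follow the bracket depth (XOR rule)", {
  # 16-way: sibling slots are 4 meioses from the DHs, opposite halves 1
  expect_equal(meiosis_count(1, 2, 16), 4)
  expect_equal(meiosis_count(1, 9, 16), 1)
  expect_equal(meiosis_count(1, 5, 16), 2)
  expect_equal(meiosis_count(1, 3, 16), 3)
  expect_equal(meiosis_count(1, 2, 2), 1)
  expect_equal(meiosis_count(c(1, 1), c(3, 2), 4), c(1, 2))
  # 8-way exponents: cross-half pairs 1, cross-quarter 2, siblings 3
  expect_equal(meiosis_count(1, 5, 8), 1)
  expect_equal(meiosis_count(1, 3, 8), 2)
  expect_equal(meiosis_count(1, 2, 8), 3)
  expect_error(meiosis_count(2, 2, 4))
  expect_error(meiosis_count(1, 2, 6), "power of 2")
})

test_that("sigma_dh equals the printed 2-way and 4-way closed forms", {
  set.seed(31)
  for (rep in 1:5) {
    p <- sample(3:6, 1)
    map <- rand_map(p, n_chrom = sample(1:2, 1))
    cm <- recombination_matrix(map)
    R <- 1 - 2 * cm
    H <- rand_haplotypes(p, 4)
    D <- function(i, k) pairwise_D(H[, i], H[, k])
    # 2-way: 4 (1-2c) .x. D_AB
    s2 <- sigma_dh(founder_panel(H[, 1:2]), cm)
    expect_equal(s2, 4 * R * D(1, 2), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # 4-way: (1-2c)^2 (D_AB + D_CD) + (1-2c)(D_AC + D_AD + D_BC + D_BD)
    s4 <- sigma_dh(founder_panel(H), cm)
    ref <- R^2 * (D(1, 2) + D(3, 4)) +
      R * (D(1, 3) + D(1, 4) + D(2, 3) + D(2, 4))
    expect_equal(s4, ref, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("two-locus 2-way variances match gamete enumeration", {
  # fully linked coupling pair: DH breeding values {4, 0} equiprobable
  m0 <- genetic_map(c("a", "b"), c("1", "1"), c(0, 0))
  H <- matrix(c(1, 1, 0, 0), 2, 2)
  sig <- sigma_dh(founder_panel(H, m0))
  expect_equal(unname(sig), matrix(1, 2, 2))
  expect_equal(dh_variance(sig, c(1, 1)), 4)
  # unlinked pair: DH BVs {4, 2, 2, 0} equiprobable
  m1 <- genetic_map(c("a", "b"), c("1", "2"), c(0, 0))
  sig1 <- sigma_dh(founder_panel(H, m1))
  expect_equal(unname(sig1), diag(2))
  expect_equal(dh_variance(sig1, c(1, 1)), 2)
  expect_equal(gamete_variance_from_dh(dh_variance(sig1, c(1, 1))), 0.5)
})

test_that("dh_variance/covariance match the enumeration oracle where exact", {
  set.seed(32)
  for (N in c(2, 4)) for (rep in 1:4) {
    p <- sample(2:4, 1)
    map <- rand_map(p, n_chrom = sample(1:2, 1))
    H <- rand_haplotypes(p, N)
    b1 <- rnorm(p); b2 <- rnorm(p)
    sig <- sigma_dh(founder_panel(H, map), recombination_matrix(map))
    orc <- oracle_dh_moments(H, map, b1, b2)
    expect_equal(dh_variance(sig, b1), orc$var1, tolerance = 1e-12)
    expect_equal(dh_covariance(sig, b1, b2), orc$cov, tolerance = 1e-12)
  }
  # N = 8 with every locus unlinked: the decay factors are 0/1 and the
  # predictor is exact there too
  for (rep in 1:3) {
    map <- unlinked_map(3)
    H <- rand_haplotypes(3, 8)
    b <- rnorm(3)
    sig <- sigma_dh(founder_panel(H, map), recombination_matrix(map))
    expect_equal(dh_variance(sig, b), oracle_dh_moments(H, map, b)$var1,
                 tolerance = 1e-12)
  }
})

test_that("sigma is symmetric PSD and vanishes for identical founders", {
  set.seed(33)
  map <- rand_map(6, n_chrom = 2)
  cm <- recombination_matrix(map)
  H <- rand_haplotypes(6, 8)
  sig <- sigma_dh(founder_panel(H), cm)
  expect_true(isSymmetric(sig))
  expect_gte(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values),
             -1e-9)
  Hsame <- matrix(H[, 1], 6, 8)
  expect_equal(sigma_dh(founder_panel(Hsame), cm), matrix(0, 6, 6),
               ignore_attr = TRUE)
})

test_that("covariance and correlation behave like moments", {
  set.seed(34)
  map <- rand_map(5)
  cm <- recombination_matrix(map)
  sig <- sigma_dh(founder_panel(rand_haplotypes(5, 4)), cm)
  b1 <- rnorm(5)
  expect_equal(dh_covariance(sig, b1, b1), dh_variance(sig, b1))
  expect_equal(dh_correlation(sig, b1, b1), 1)
  expect_equal(dh_correlation(sig, b1, -b1), -1)
  expect_equal(dh_variance(sig, rep(0, 5)), 0)
  expect_error(dh_correlation(sig, rep(0, 5), b1), "zero")
  # orthogonal one-locus traits on unlinked loci have zero covariance
  m1 <- genetic_map(c("a", "b"), c("1", "2"), c(0, 0))
  s1 <- sigma_dh(founder_panel(matrix(c(1, 1, 0, 0), 2, 2), m1))
  expect_equal(dh_covariance(s1, c(1, 0), c(0, 1)), 0)
})

test_that("with unlinked loci the predictor reduces to the coancestry form", {
  # exact identity: equal effects beta, all loci unlinked ->
  # dh_variance == expected_dh_variance(N, IBS coancestry, sigmaA2 = p beta^2)
  set.seed(35)
  for (N in c(4, 8, 16)) {
    p <- 12
    map <- unlinked_map(p)
    H <- rand_haplotypes(p, N)
    beta <- rep(0.7, p)
    sig <- sigma_dh(founder_panel(H), recombination_matrix(map))
    expect_equal(dh_variance(sig, beta),
                 expected_dh_variance(N, ibs_coancestry(H),
                                      sigmaA2 = p * 0.7^2),
                 tolerance = 1e-12)
  }
})

test_that("expand_to_panel duplicates lines and splits outbred haplotypes", {
  H <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2)
  pan <- expand_to_panel(H, inbred = TRUE)
  expect_equal(ncol(pan$haplotypes), 4)
  expect_equal(pan$haplotypes[, 1], pan$haplotypes[, 2])
  # an outbred individual's two haplotypes land in sibling slots
  pan2 <- expand_to_panel(H[, 1:2], inbred = FALSE)
  expect_equal(ncol(pan2$haplotypes), 2)
  expect_equal(unname(pan2$haplotypes[, 1]), H[, 1])
  expect_error(founder_panel(matrix(0, 2, 3)), "power of 2")
  expect_error(founder_panel(matrix(2, 2, 2)), "0/1")
})
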