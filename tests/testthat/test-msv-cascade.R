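test_that("msv_from_dh inverts the DH decomposition", {
  expect_equal(msv_from_dh(1.5, 0.5), 0.25)
  expect_equal(msv_from_dh(2, 2), 0)
  expect_equal(msv_from_dh(2, 0), 0.5)  # gen-1 group of identical F1s
  expect_error(msv_from_dh(0.5, 1), "inconsistent")
  expect_error(msv_from_dh(-1, 0))
})

test_that("cascade reproduces the unrelated-founder ladder exactly", {
  # founders with pairwise allele sharing exactly 1/2 on unlinked loci and
  # equal effects scaled to a unit base variance
  hf <- hadamard_founders(16)
  panel <- founder_panel(hf$haplotypes, hf$map)
  casc <- build_cascade(panel, beta = hf$beta)
  per_gen <- function(col)
    as.vector(tapply(casc[[col]], casc$generation, unique))
  expect_equal(per_gen("f1_variance"), c(0, 0.5, 0.75, 0.875))
  expect_equal(per_gen("dh_variance"), c(1, 1.5, 1.75, 1.875))
  expect_equal(per_gen("gametic_msv"), rep(0.25, 4))
  expect_equal(unname(terminal_dh_variance(casc)), 1.875)
  # group labels follow the concatenation convention
  expect_true("ABxCD" %in% casc$group)
  expect_true("ABCDEFGHxIJKLMNOP" %in% casc$group)
})

test_that("cascade identity dh = f1 + 4 msv holds for every group", {
  set.seed(41)
  map <- rand_map(8, n_chrom = 2)
  H <- rand_haplotypes(8, 16)
  beta <- cbind(t1 = rnorm(8), t2 = rnorm(8))
  casc <- build_cascade(founder_panel(H, map), beta = beta)
  expect_equal(casc$dh_variance,
               casc$f1_variance + 4 * casc$gametic_msv, tolerance = 1e-12)
  expect_true(all(casc$gametic_msv >= 0))
  expect_true(all(casc$f1_variance >= 0))
  # generation-1 groups: F1 variance 0 and MSV = 2-way DH variance / 4
  g1 <- casc[casc$generation == 1, ]
  expect_equal(g1$f1_variance, rep(0, nrow(g1)))
  expect_equal(g1$gametic_msv, g1$dh_variance / 4)
  # one row per (group, trait)
  expect_equal(nrow(casc), (8 + 4 + 2 + 1) * 2)
})

test_that("N = 2 cascade collapses to the single 2-way group", {
  m <- genetic_map(c("a", "b"), c("1", "2"), c(0, 0))
  H <- matrix(c(1, 1, 0, 0), 2, 2)
  casc <- build_cascade(founder_panel(H, m), beta = c(1, 1))
  expect_equal(nrow(casc), 1)
  expect_equal(casc$dh_variance, 2)
  expect_equal(casc$gametic_msv, 0.5)
})

test_that("identical founders give an all-zero cascade", {
  map <- unlinked_map(4)
  H <- matrix(1, 4, 8)
  casc <- build_cascade(founder_panel(H, map), beta = rnorm(4))
  expect_equal(casc$dh_variance, rep(0, nrow(casc)))
  expect_equal(casc$f1_variance, rep(0, nrow(casc)))
  expect_equal(casc$gametic_msv, rep(0, nrow(casc)))
})

test_that("F1 variances saturate towards the base variance with panel size", {
  # ladder 1 - 2^(1 - log2 N) for F1s, 2 - 2^(1 - log2 N) for DHs
  for (N in c(2, 4, 8, 16, 32)) {
    hf <- hadamard_founders(N)
    casc <- build_cascade(founder_panel(hf$haplotypes, hf$map),
                          beta = hf$beta)
    top <- casc[casc$generation == log2(N), ]
    expect_equal(top$f1_variance[1], 1 - 2^(1 - log2(N)))
    expect_equal(top$dh_variance[1], 2 - 2^(1 - log2(N)))
  }
})
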