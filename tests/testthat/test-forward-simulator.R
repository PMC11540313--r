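test_that("meiosis of a fully homozygous individual copies the haplotype", {
  set.seed(71)
  map <- rand_map(20, n_chrom = 2)
  h <- sample(0:1, 20, replace = TRUE)
  for (r in 1:5) expect_equal(meiosis(h, h, map), h)
  expect_error(meiosis(h[1:3], h[1:3], map))
})

test_that("simulated recombinant fractions follow the mapping function", {
  set.seed(72)
  n <- 20000
  for (d in c(0.05, 0.2, 0.6)) {
    map <- genetic_map(c("a", "b"), c("1", "1"), c(0, d))
    pat <- matrix(c(1, 1), n, 2, byrow = TRUE)
    mat <- matrix(c(0, 0), n, 2, byrow = TRUE)
    g <- xwaymsv:::sim_gametes(pat, mat, xwaymsv:::gamete_switch_prob(map))
    rec <- mean(g[, 1] != g[, 2])
    cc <- haldane_c(d)
    expect_lt(abs(rec - cc), 3.5 * sqrt(cc * (1 - cc) / n))
  }
  # unlinked loci recombine half the time
  map <- genetic_map(c("a", "b"), c("1", "2"), c(0, 0))
  pat <- matrix(c(1, 1), n, 2, byrow = TRUE)
  mat <- matrix(c(0, 0), n, 2, byrow = TRUE)
  g <- xwaymsv:::sim_gametes(pat, mat, xwaymsv:::gamete_switch_prob(map))
  expect_lt(abs(mean(g[, 1] != g[, 2]) - 0.5), 3.5 * sqrt(0.25 / n))
})

test_that("run_plan builds the configured population shape", {
  set.seed(73)
  hf <- hadamard_founders(16)
  panel <- founder_panel(hf$haplotypes, hf$map)
  pop <- run_plan(panel, hf$beta, n_per_group = 4)
  expect_equal(length(pop$generations), 4)
  expect_equal(lengths(pop$generations), c(8L, 4L, 2L, 1L))
  for (g in seq_len(4))
    for (gr in pop$generations[[g]]) expect_equal(nrow(gr$pat), 4)
  # DH lines are fully homozygous doubled gametes
  expect_identical(pop$dh$pat, pop$dh$mat)
  expect_equal(pop$generations[[2]][[1]]$label, "ABxCD")
  expect_error(run_plan(panel, hf$beta, 1))
  expect_error(run_plan(panel, hf$beta, 10, select_fraction = 0))
})

test_that("individual gametic MSV matches gamete enumeration", {
  m1 <- genetic_map(c("a", "b"), c("1", "2"), c(0, 0))
  cm <- recombination_matrix(m1)
  # heterozygote 1-1/0-0, unlinked: gamete BVs {2,1,1,0}/..., variance 0.5
  expect_equal(individual_gametic_msv(c(1, 1), c(0, 0), cm, c(1, 1)), 0.5)
  expect_equal(individual_gametic_msv(c(1, 1), c(1, 1), cm, c(1, 1)), 0)
  # equals a quarter of the 2-way DH variance of the same pair
  set.seed(74)
  map <- rand_map(6)
  cm2 <- recombination_matrix(map)
  h1 <- sample(0:1, 6, TRUE); h2 <- sample(0:1, 6, TRUE)
  b <- rnorm(6)
  expect_equal(
    individual_gametic_msv(h1, h2, cm2, b),
    dh_variance(sigma_dh(founder_panel(cbind(h1, h2)), cm2), b) / 4)
})

test_that("realized group variances track the analytic ladder", {
  set.seed(75)
  hf <- hadamard_founders(16)
  panel <- founder_panel(hf$haplotypes, hf$map)
  n <- 3000
  pop <- run_plan(panel, hf$beta, n)
  v <- vapply(2:4, function(g)
    mean(vapply(pop$generations[[g]], function(gr) var(gr$bv[, 1]), 0)), 0)
  expect_equal(v, c(0.5, 0.75, 0.875), tolerance = 0.08)
  expect_equal(var(pop$dh$bv[, 1]), 1.875, tolerance = 0.08)
  # mean exact per-individual gametic MSV of the top group ~ 0.25
  cm <- recombination_matrix(hf$map)
  top <- pop$generations[[4]][[1]]
  expect_equal(xwaymsv:::group_gametic_msv(top$pat, top$mat, cm, hf$beta),
               0.25, tolerance = 0.05)
})

test_that("truncation selection raises means and depresses gametic MSV", {
  set.seed(76)
  fo <- generate_founders(16, genome_preset("corn", n_loci = 100))
  beta <- generate_effects(fo, n_traits = 1, target_correlation = 0,
                           variances = 1)
  panel <- founder_panel(fo$haplotypes, fo$map)
  pop <- run_plan(panel, beta, 800, select_fraction = 0.1)
  means <- vapply(seq_len(4), function(g)
    mean(vapply(pop$generations[[g]], function(gr) mean(gr$bv[, 1]), 0)), 0)
  expect_true(all(diff(means) > 0))
  # realized MSV of selected 16-way F1s sits below the no-selection
  # analytic prediction
  cm <- recombination_matrix(fo$map)
  casc <- build_cascade(panel, cm, beta)
  analytic_msv <- casc$gametic_msv[casc$generation == 4]
  top <- pop$generations[[4]][[1]]
  realized_msv <- xwaymsv:::group_gametic_msv(top$pat, top$mat, cm,
                                              as.numeric(beta))
  expect_lt(realized_msv, analytic_msv)
})

test_that("population diagnostics: drift-free founder snapshot and Falconer D", {
  # haplotype pool {1-1, 0-0} in equal parts has D = 0.25
  pool <- rbind(c(1, 1), c(0, 0))
  expect_equal(falconer_d(pool, c("1", "1")), 0.25)
  expect_equal(falconer_d(rbind(c(1, 0), c(0, 1)), c("1", "1")), -0.25)
  expect_true(is.na(falconer_d(pool, c("1", "2"))))

  set.seed(77)
  hf <- hadamard_founders(16)
  panel <- founder_panel(hf$haplotypes, hf$map)
  pop <- run_plan(panel, hf$beta, 50)
  diag <- population_diagnostics(pop, panel)
  # generation 1 pools exactly the founder haplotypes: no frequency change
  expect_equal(diag$af_change_pct[diag$generation == "1"], 0,
               tolerance = 1e-9)
  # DH lines are fully homozygous
  expect_equal(diag$homozygosity_pct[diag$generation == "DH"], 100)
  expect_equal(nrow(diag), 5)
})
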