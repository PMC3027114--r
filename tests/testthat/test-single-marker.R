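test_that("allele-frequency-difference statistic matches hand arithmetic", {
  ## equal case/control rows: no frequency difference
  tb <- genotype_table(c(10, 20, 30), c(10, 20, 30))
  expect_equal(afdt_stat(tb), 0)
  ## stage-1 counts of a type-2-diabetes SNP, computed independently:
  ## theta = 866/1386, varpi = 715/1308, pooled pbar = 1581/2694,
  ## z = (theta - varpi) / sqrt((1/1386 + 1/1308) pbar (1 - pbar))
  tb2 <- genotype_table(c(99, 322, 272), c(121, 351, 182))
  expect_equal(afdt_stat(tb2), 4.1189459378, tolerance = 1e-9)
  ## swapping the rows only changes the sign
  tb2s <- genotype_table(c(121, 351, 182), c(99, 322, 272))
  expect_equal(afdt_stat(tb2s), -afdt_stat(tb2), tolerance = 1e-12)
  ## monomorphic pooled sample is an error, not NaN
  expect_error(suppressWarnings(
    afdt_stat(genotype_table(c(50, 0, 0), c(50, 0, 0)))), "monomorphic")
})

test_that("trend statistic agrees with the brute-force score sum", {
  tb <- genotype_table(c(10, 20, 30), c(30, 20, 10))
  expect_equal(catt_stat(tb, c(0, 1, 2)),
               brute_catt(c(10, 20, 30), c(30, 20, 10), c(0, 1, 2)),
               tolerance = 1e-12)
  set.seed(101)
  for (i in 1:50) {
    tb <- random_table()
    for (x in list(c(0, 0, 1), c(0, 1, 2), c(0, 1, 1))) {
      expect_equal(suppressWarnings(catt_stat(tb, x)),
                   brute_catt(tb$cases, tb$controls, x),
                   tolerance = 1e-10)
    }
  }
})

test_that("trend statistic is affine-invariant and antisymmetric", {
  tb <- genotype_table(c(15, 40, 45), c(35, 40, 25))
  expect_equal(catt_stat(tb, c(0, 1, 2)), catt_stat(tb, c(0, 0.5, 1)),
               tolerance = 1e-12)
  expect_equal(catt_stat(tb, c(0, 1, 2)), catt_stat(tb, c(3, 5, 7)),
               tolerance = 1e-12)
  swapped <- genotype_table(tb$controls, tb$cases)
  expect_equal(catt_stat(swapped, c(0, 1, 2)), -catt_stat(tb, c(0, 1, 2)),
               tolerance = 1e-12)
  expect_equal(mert_stat(swapped), -mert_stat(tb), tolerance = 1e-12)
  expect_equal(max3_stat(swapped), max3_stat(tb), tolerance = 1e-12)
  expect_equal(catt_stat(genotype_table(c(20, 20, 20), c(10, 10, 10))), 0)
  ## all subjects in one genotype: zero variance
  expect_error(suppressWarnings(
    catt_stat(genotype_table(c(0, 50, 0), c(0, 60, 0)))), "degenerate")
})

test_that("null trend correlations have the closed-form moments", {
  R <- genetic_scores("REC"); A <- genetic_scores("ADD"); D <- genetic_scores("DOM")
  ## identical scores: correlation one
  expect_equal(trend_correlation(c(0.2, 0.5, 0.3), A, A), 1)
  ## symmetric HWE frequencies at MAF one half:
  ## cov(R, D) = g0 g2 = 0.0625, var(R) = var(D) = 0.1875, rho = 1/3
  g <- hwe_probs(0.5)
  expect_equal(trend_correlation(g, R, D), 1 / 3, tolerance = 1e-12)
  ## simulation oracle: empirical correlation of the two standardized
  ## statistics over null tables
  set.seed(23)
  mod <- disease_model(0.1, 0.3, 1, 1)
  pop <- genotype_probs(mod)
  ca <- sim_count_matrix(1e5, 1000, pop$case_probs)
  co <- sim_count_matrix(1e5, 1000, pop$control_probs)
  emp <- cor(catt_stat_mat(ca, co, R), catt_stat_mat(ca, co, A))
  thr <- trend_correlation(hwe_probs(0.3), R, A)
  expect_lt(abs(emp - thr), 3 * (1 - thr^2) / sqrt(1e5))
  expect_error(trend_correlation(c(0, 1, 0), R, D), "zero score variance")
})

test_that("omega weights give the exact additive decomposition", {
  ## symmetric frequencies: sigma_R = sigma_D, so omega1 = omega2
  nc <- null_correlations(hwe_probs(0.5))
  expect_equal(unname(nc$omega[1]), unname(nc$omega[2]), tolerance = 1e-12)
  ## formula edge: rho_RA = rho_RD * rho_AD forces omega1 = 0
  w <- omega_weights(0.4, 0.4 * 0.8, 0.8)
  expect_equal(unname(w[1]), 0, tolerance = 1e-14)
  expect_error(omega_weights(1, 0.5, 0.5))
  ## identity T_A = omega1 T_R + omega2 T_D on arbitrary tables, with all
  ## variances estimated from the same pooled genotype frequencies
  set.seed(7)
  for (i in 1:25) {
    tb <- random_table(300, 250)
    g <- (tb$cases + tb$controls) / (sum(tb$cases) + sum(tb$controls))
    w <- null_correlations(g)$omega
    tR <- suppressWarnings(catt_stat(tb, c(0, 0, 1)))
    tA <- suppressWarnings(catt_stat(tb, c(0, 1, 2)))
    tD <- suppressWarnings(catt_stat(tb, c(0, 1, 1)))
    expect_equal(tA, w[1] * tR + w[2] * tD, tolerance = 1e-10,
                 ignore_attr = TRUE)
    ## consequence: MAX3 is determined by (T_R, T_D) alone
    expect_equal(suppressWarnings(max3_stat(tb)),
                 max(abs(tR), abs(w[1] * tR + w[2] * tD), abs(tD)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("MERT and MAX3 behave at the edges and under the null", {
  tb0 <- genotype_table(c(30, 40, 30), c(30, 40, 30))
  expect_equal(mert_stat(tb0), 0)
  expect_equal(max3_stat(tb0), 0)
  tb <- genotype_table(c(20, 50, 130), c(60, 70, 70))
  expect_gte(max3_stat(tb), abs(catt_stat(tb, c(0, 1, 2))))
  expect_gte(max3_stat(tb), abs(catt_stat(tb, c(0, 0, 1))))
  ## null calibration of the MERT variance over many simulated tables
  set.seed(31)
  pop <- genotype_probs(disease_model(0.1, 0.3, 1, 1))
  ca <- sim_count_matrix(1e5, 2000, pop$case_probs)
  co <- sim_count_matrix(1e5, 2000, pop$control_probs)
  v <- var(mert_stat_mat(ca, co))
  expect_lt(abs(v - 1), 3 * sqrt(2 / 1e5))
})
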