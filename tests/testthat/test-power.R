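test_that("analytic power at the null recovers the per-SNP level", {
  mod0 <- disease_model(0.1, 0.3, 1, 1)
  des <- study_design(2000, 2000, 0.5, 1e-4, alpha = 0.05, m = 5e5)
  for (mth in c("ALLEJ", "CATAJ", "MERTJ")) {
    pw <- analytic_power_joint(mth, mod0, des)
    expect_equal(pw$power, 0.05 / 5e5, tolerance = 1e-6)
  }
})

test_that("analytic and empirical power agree for the normal methods", {
  ## two routes to the same estimand: bivariate-normal integration of the
  ## asymptotic law vs direct simulation of the statistics
  des <- study_design(2000, 2000, 0.5, 1e-4)
  mod <- table2_model("additive")
  for (mth in c("ALLEJ", "CATAJ", "MERTJ")) {
    an <- analytic_power_joint(mth, mod, des)$power
    em <- empirical_power_joint(mth, mod, des, n_rep = 1e4, seed = 71)
    expect_lt(abs(an - em$power), 3 * em$se + 0.003)
  }
  ## recessive scenario, where the methods differ most
  desr <- study_design(5000, 5000, 0.5, 1e-4)
  modr <- table2_model("recessive")
  anr <- analytic_power_joint("MERTJ", modr, desr)$power
  emr <- empirical_power_joint("MERTJ", modr, desr, n_rep = 1e4, seed = 73)
  expect_lt(abs(anr - emr$power), 3 * emr$se + 0.003)
})

test_that("power is monotone in the stage-1 gate and stage-1 fraction", {
  mod <- table2_model("dominant")
  for (mth in c("ALLEJ", "CATAJ", "MERTJ")) {
    p_g <- vapply(c(1e-4, 2e-4), function(g)
      analytic_power_joint(mth, mod, study_design(2000, 2000, 0.5, g))$power,
      numeric(1))
    expect_gte(p_g[2], p_g[1])
    p_pi <- vapply(c(0.3, 0.4, 0.5), function(p)
      analytic_power_joint(mth, mod, study_design(2000, 2000, p, 1e-4))$power,
      numeric(1))
    expect_true(all(diff(p_pi) > 0))
  }
})

test_that("MAX3 joint analysis dominates under the recessive model", {
  ## the qualitative robustness ordering: recessive favours MAX3J, the
  ## additive model favours CATAJ
  desr <- study_design(5000, 5000, 0.5, 1e-4)
  modr <- table2_model("recessive")
  max3 <- empirical_power_joint("MAX3J", modr, desr, n_rep = 4000,
                                B1 = 4e5, seed = 79)
  allej <- analytic_power_joint("ALLEJ", modr, desr)$power
  cataj <- analytic_power_joint("CATAJ", modr, desr)$power
  expect_gt(max3$power, allej + 0.1)
  expect_gt(max3$power, cataj + 0.1)
  desa <- study_design(2000, 2000, 0.5, 1e-4)
  moda <- table2_model("additive")
  cat_a <- analytic_power_joint("CATAJ", moda, desa)$power
  mert_a <- analytic_power_joint("MERTJ", moda, desa)$power
  max3_a <- empirical_power_joint("MAX3J", moda, desa, n_rep = 4000,
                                  B1 = 4e5, seed = 83)
  expect_gte(cat_a, mert_a)
  expect_gte(cat_a, max3_a$power - 3 * max3_a$se)
})

test_that("MAX3J empirical power handles edge thresholds", {
  mod <- table2_model("recessive")
  des <- study_design(5000, 5000, 0.5, 1e-4)
  inf_thr <- structure(list(b1 = Inf, bJ = Inf), class = "joint_thresholds")
  pw <- empirical_power_joint("MAX3J", mod, des, n_rep = 500,
                              thresholds = inf_thr, seed = 89)
  expect_equal(pw$power, 0)
})

test_that("power table grids are reproducible and ordered", {
  tb <- power_table(2, rows = "recessive", pis = 0.5,
                    methods = c("ALLEJ", "MERTJ", "MAX3J"),
                    n_rep = 2000, B1 = 2e5, seed = 97)
  tb2 <- power_table(2, rows = "recessive", pis = 0.5,
                     methods = c("ALLEJ", "MERTJ", "MAX3J"),
                     n_rep = 2000, B1 = 2e5, seed = 97)
  expect_identical(tb, tb2)
  ## looser gamma never loses power within a row
  expect_gte(tb$ALLEJ[tb$gamma == 2e-4], tb$ALLEJ[tb$gamma == 1e-4])
  expect_gte(tb$MERTJ[tb$gamma == 2e-4], tb$MERTJ[tb$gamma == 1e-4])
  expect_error(power_table(7), "table_id")
})

test_that("the scaled family-wise error simulation stays near alpha", {
  ## reduced design: the per-SNP level alpha/m with m = 50 SNPs per
  ## genome; 2000 genomes give a quick but informative check (the
  ## full-scale run lives in the acceptance suite)
  des <- study_design(1000, 1000, 0.5, gamma = 0.05, alpha = 0.05, m = 50)
  fw <- empirical_fwer(0.3, des, n_genomes = 2000, B1 = 2e5, seed = 101)
  se <- sqrt(0.05 * 0.95 / 2000)
  for (mth in names(fw$fwer))
    expect_lt(abs(fw$fwer[[mth]] - 0.05), 4 * se)
})
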