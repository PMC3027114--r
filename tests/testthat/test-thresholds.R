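test_that("stage-1 threshold is the two-sided normal quantile", {
  expect_equal(stage1_threshold(1), 0)
  ## frozen values from a bisection inversion of the normal CDF
  expect_equal(stage1_threshold(1e-4), 3.890592, tolerance = 1e-6)
  expect_equal(stage1_threshold(0.05), 1.959964, tolerance = 1e-6)
  expect_error(stage1_threshold(0))
})

test_that("joint threshold solves the bivariate null equation", {
  thr <- joint_threshold_normal(0.5, 1e-4, 0.05, 5e5)
  expect_lt(abs(bvn_rect_exceed(thr$b1, thr$bJ, sqrt(0.5)) - 1e-7), 5e-15)
  ## independence limit: bJ -> qnorm(1 - alpha / (2 m gamma))
  thr0 <- joint_threshold_normal(1e-10, 1e-4, 0.05, 5e5)
  expect_equal(thr0$bJ, 3.290527, tolerance = 1e-4)
  ## perfect-correlation limit: bJ -> qnorm(1 - alpha / (2 m))
  thr1 <- joint_threshold_normal(1 - 1e-10, 1e-4, 0.05, 5e5)
  expect_equal(thr1$bJ, 5.326724, tolerance = 1e-4)
  ## impossible level
  expect_error(joint_threshold_normal(0.5, 1e-8, 0.05, 5e5), "alpha/m")
})

test_that("joint threshold is monotone in gamma and m", {
  ## a looser stage-1 gate admits more null SNPs, so the joint threshold
  ## must rise toward its gamma -> 1 limit qnorm(1 - alpha/(2m));
  ## conversely a severe gate makes selection itself strong evidence and
  ## the joint threshold relaxes
  b <- vapply(c(1e-4, 2e-4, 1e-3, 1e-2),
              function(g) joint_threshold_normal(0.5, g, 0.05, 5e5)$bJ,
              numeric(1))
  expect_true(all(diff(b) > 0))
  expect_lt(b[4], qnorm(1 - 0.05 / (2 * 5e5)))
  bm <- vapply(c(1e4, 1e5, 5e5, 1e6),
               function(m) joint_threshold_normal(0.5, 1e-3, 0.05, m)$bJ,
               numeric(1))
  expect_true(all(diff(bm) > 0))
})

test_that("MAX3 stage-1 threshold solves the hexagon tail equation", {
  corr <- null_correlations(hwe_probs(0.3))
  expect_equal(max3_stage1_threshold(1, corr), 0)
  ## the max dominates any single component
  for (g in c(0.05, 0.01, 1e-3, 1e-4)) {
    v1 <- max3_stage1_threshold(g, corr)
    expect_gte(v1, stage1_threshold(g))
    expect_lt(abs(max3_null_tail(v1, corr) - g), 1e-8)
  }
  ## Monte-Carlo oracle at gamma = 0.01: empirical tail at v1
  set.seed(53)
  v1 <- max3_stage1_threshold(0.01, corr)
  Z <- rbvn(1e6, corr$rho_RD)
  tmax <- pmax(abs(Z[, 1]), abs(Z %*% corr$omega), abs(Z[, 2]))
  expect_lt(abs(mean(tmax > v1) - 0.01), 3 * sqrt(0.01 * 0.99 / 1e6))
})

test_that("conditional stage-1 sampler reproduces the rejection law", {
  corr <- null_correlations(hwe_probs(0.3))
  v1 <- max3_stage1_threshold(0.01, corr)
  set.seed(59)
  cs <- conditional_stage1_sampler(1e4, v1, corr)
  ## every draw satisfies the conditioning event
  tmax <- pmax(abs(cs$draws[, 1]),
               abs(cs$draws %*% corr$omega), abs(cs$draws[, 2]))
  expect_true(all(tmax > v1))
  ## acceptance bookkeeping recovers the selection probability
  p_an <- max3_null_tail(v1, corr)
  se <- p_an / sqrt(cs$n_accepted)
  expect_lt(abs(cs$p_event - p_an), 3 * se)
  ## two-sample agreement with naive rejection, marginal by marginal
  nv <- naive_conditional(1e4, v1, corr$rho_RD, corr$omega)
  expect_gt(suppressWarnings(ks.test(cs$draws[, 1], nv[, 1]))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(cs$draws[, 2], nv[, 2]))$p.value, 0.01)
  nvmax <- pmax(abs(nv[, 1]), abs(nv %*% corr$omega), abs(nv[, 2]))
  expect_gt(suppressWarnings(ks.test(tmax, nvmax))$p.value, 0.01)
  ## conditional exceedance frequency matches naive rejection
  expect_lt(abs(mean(abs(cs$draws[, 1]) > v1) - mean(abs(nv[, 1]) > v1)),
            3 * sqrt(0.5 / 1e4))
})

test_that("MAX3 joint threshold follows the three-step algorithm", {
  corr <- null_correlations(hwe_probs(0.3))
  ## degenerate level rejected
  expect_error(max3_joint_threshold(0.5, 0.05, 0.05, 1, corr1 = corr),
               "alpha")
  ## conditional and naive samplers agree at a desk-scale design
  thr_c <- max3_joint_threshold(0.5, 0.05, 0.05, 10, corr1 = corr,
                                B1 = 2e5, seed = 61)
  thr_n <- max3_joint_threshold(0.5, 0.05, 0.05, 10, corr1 = corr,
                                B = 4e6, sampler = "naive", seed = 62)
  expect_lt(abs(thr_c$bJ - thr_n$bJ), 0.05)
  ## attained fraction is admissible and close to the target
  lvl <- 0.05 / (10 * 0.05)
  expect_lte(thr_c$mc_meta$attained, lvl)
  expect_lt(lvl - thr_c$mc_meta$attained, 10 / sqrt(thr_c$mc_meta$B1))
  ## brute-force oracle: conditional quantile from a direct two-stage
  ## null simulation
  set.seed(63)
  B <- 4e6
  Z1 <- rbvn(B, corr$rho_RD)
  t1max <- pmax(abs(Z1[, 1]), abs(Z1 %*% corr$omega), abs(Z1[, 2]))
  keep <- t1max > thr_c$b1
  Z1 <- Z1[keep, , drop = FALSE]
  Z2 <- rbvn(nrow(Z1), corr$rho_RD)
  pi <- 0.5
  tJmax <- pmax(abs(sqrt(pi) * Z1[, 1] + sqrt(1 - pi) * Z2[, 1]),
                abs(sqrt(pi) * drop(Z1 %*% corr$omega) +
                    sqrt(1 - pi) * drop(Z2 %*% corr$omega)),
                abs(sqrt(pi) * Z1[, 2] + sqrt(1 - pi) * Z2[, 2]))
  expect_lt(abs(mean(tJmax > thr_c$bJ) - lvl), 3 * sqrt(lvl / length(tJmax)))
  ## MAX3 thresholds dominate the single-component thresholds
  thr_norm <- joint_threshold_normal(0.5, 0.05, 0.05, 10)
  expect_gte(thr_c$b1, thr_norm$b1)
  expect_gte(thr_c$bJ, thr_norm$bJ - 0.02)  # bJ is Monte-Carlo
})
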