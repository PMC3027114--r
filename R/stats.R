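#' Genotype score sets for the classical genetic models
#'
#' Per-genotype scores (x0, x1, x2) over (gg, Gg, GG) used by the
#' Cochran-Armitage trend test: recessive (0,0,1), additive (0,1,2),
#' dominant (0,1,1). Note the additive scores are the componentwise sum of
#' the recessive and dominant scores, which underlies the identity
#' `T_A = omega1 T_R + omega2 T_D`.
#'
#' @param model one of "recessive", "additive", "dominant" (or "REC",
#'   "ADD", "DOM").
#' @return numeric score vector of length 3.
#' @export
genetic_scores <- function(model = c("recessive", "additive", "dominant",
                                     "REC", "ADD", "DOM")) {
  model <- match.arg(model)
  switch(model,
         recessive = , REC = c(0, 0, 1),
         additive = , ADD = c(0, 1, 2),
         dominant = , DOM = c(0, 1, 1))
}

.SCORES <- list(REC = c(0, 0, 1), ADD = c(0, 1, 2), DOM = c(0, 1, 1))

## score covariance under rows of a genotype-frequency matrix
.gcov <- function(g, x, y) as.vector(g %*% (x * y)) - as.vector(g %*% x) * as.vector(g %*% y)

check_table <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  if (sum(table$cases) == 0L || sum(table$controls) == 0L)
    stop("genotype table needs at least one case and one control")
  n <- table$cases + table$controls
  N <- sum(n)
  expc <- outer(c(sum(table$cases), sum(table$controls)), n / N)
  if (any(expc < 5))
    warning("some expected cell counts are below 5; asymptotic p-values may be inaccurate")
  invisible(table)
}

## ---- vectorized kernels ------------------------------------------------
## ca, co: n x 3 count matrices. var_est: "pooled" estimates the score
## variance from the combined genotype counts (null-consistent); "arms"
## estimates it from cases and controls separately (consistent under the
## alternative as well). Both agree under the null.

catt_stat_mat <- function(ca, co, x, var_est = c("pooled", "arms")) {
  var_est <- match.arg(var_est)
  R <- rowSums(ca); S <- rowSums(co); N <- R + S
  U <- (S * as.vector(ca %*% x) - R * as.vector(co %*% x)) / N
  if (var_est == "pooled") {
    n <- ca + co
    vg <- as.vector(n %*% (x^2)) / N - (as.vector(n %*% x) / N)^2
    v <- R * S / N * vg
  } else {
    vp <- as.vector(ca %*% (x^2)) / R - (as.vector(ca %*% x) / R)^2
    vq <- as.vector(co %*% (x^2)) / S - (as.vector(co %*% x) / S)^2
    v <- R * S / N * ((S / N) * vp + (R / N) * vq)
  }
  bad <- !(v > 0)
  if (any(bad)) v[bad] <- NA_real_
  U / sqrt(v)
}

afdt_stat_mat <- function(ca, co) {
  R <- rowSums(ca); S <- rowSums(co)
  th <- (2 * ca[, 3] + ca[, 2]) / (2 * R)
  vp <- (2 * co[, 3] + co[, 2]) / (2 * S)
  xi <- R / (R + S)
  pbar <- th * xi + vp * (1 - xi)
  v <- (1 / (2 * R) + 1 / (2 * S)) * pbar * (1 - pbar)
  bad <- !(v > 0)
  if (any(bad)) v[bad] <- NA_real_
  (th - vp) / sqrt(v)
}

## pairwise trend-test null correlation from an n x 3 genotype frequency
## matrix (rows sum to 1)
trend_corr_mat <- function(g, x, y) {
  cxy <- .gcov(g, x, y)
  cxy / sqrt(.gcov(g, x, x) * .gcov(g, y, y))
}

mert_stat_mat <- function(ca, co, var_est = c("pooled", "arms"),
                          rho_source = c("pooled", "cases")) {
  var_est <- match.arg(var_est); rho_source <- match.arg(rho_source)
  tR <- catt_stat_mat(ca, co, .SCORES$REC, var_est)
  tD <- catt_stat_mat(ca, co, .SCORES$DOM, var_est)
  g <- if (rho_source == "pooled") (ca + co) / rowSums(ca + co)
       else ca / rowSums(ca)
  rho <- trend_corr_mat(g, .SCORES$REC, .SCORES$DOM)
  (tR + tD) / sqrt(2 * (1 + rho))
}

max3_stat_mat <- function(ca, co, var_est = c("pooled", "arms")) {
  var_est <- match.arg(var_est)
  tR <- abs(catt_stat_mat(ca, co, .SCORES$REC, var_est))
  tA <- abs(catt_stat_mat(ca, co, .SCORES$ADD, var_est))
  tD <- abs(catt_stat_mat(ca, co, .SCORES$DOM, var_est))
  pmax(tR, tA, tD)
}

## ---- exported per-table statistics ------------------------------------

#' Allele-frequency-difference test statistic
#'
#' Compares the sample risk-allele frequencies of cases and controls,
#' standardized by the pooled-sample variance:
#' `Z = (theta.hat - varpi.hat) /
#'  sqrt((1/(2 r) + 1/(2 s)) * pbar (1 - pbar))`
#' with `pbar = theta.hat xi + varpi.hat (1 - xi)` and `xi = r / (r + s)`
#' computed from the table. Asymptotically standard normal under the null
#' when the population is in Hardy-Weinberg equilibrium.
#'
#' @param table a [genotype_table()].
#' @return the test statistic (scalar).
#' @export
afdt_stat <- function(table) {
  check_table(table)
  z <- afdt_stat_mat(rbind(table$cases), rbind(table$controls))
  if (is.na(z)) stop("degenerate table: pooled sample is monomorphic")
  z
}

#' Cochran-Armitage trend test statistic
#'
#' The score test for trend in proportions across the three genotype
#' columns:
#' `T = sqrt(N) * sum_i x_i (s r_i - r s_i) /
#'  sqrt(r s (N sum_i x_i^2 n_i - (sum_i x_i n_i)^2))`
#' with `n_i = r_i + s_i`, `r`, `s` the case/control totals and `N = r+s`.
#' The default estimates the score variance from the pooled genotype
#' counts; `var_est = "arms"` uses cases and controls separately.
#' The statistic is invariant to affine transformations of the scores and
#' asymptotically standard normal under the null.
#'
#' @param table a [genotype_table()].
#' @param scores score vector of length 3, e.g. [genetic_scores()].
#' @param var_est `"pooled"` (default) or `"arms"`.
#' @return the test statistic (scalar).
#' @export
catt_stat <- function(table, scores = genetic_scores("additive"),
                      var_est = c("pooled", "arms")) {
  check_table(table)
  stopifnot(length(scores) == 3L)
  if (length(unique(scores)) == 1L) stop("scores must not all be equal")
  t <- catt_stat_mat(rbind(table$cases), rbind(table$controls), scores,
                     match.arg(var_est))
  if (is.na(t)) stop("degenerate table: zero score variance")
  t
}

#' Null correlation of two trend statistics
#'
#' Correlation of two Cochran-Armitage trend statistics with score sets
#' `x` and `y` under the null, computed from a genotype distribution `g`:
#' `rho = Cov_g(x, y) / sqrt(Var_g(x) Var_g(y))`. In this standardized
#' form the correlation does not depend on the case fraction.
#'
#' @param g genotype probability triple (sums to 1).
#' @param x,y score vectors of length 3.
#' @return correlation in (-1, 1), or exactly 1 when `x` and `y` are
#'   affinely equivalent.
#' @export
trend_correlation <- function(g, x, y) {
  stopifnot(length(g) == 3L, all(g >= 0),
            isTRUE(all.equal(sum(g), 1, tolerance = 1e-8)))
  g <- rbind(g / sum(g))
  vx <- .gcov(g, x, x); vy <- .gcov(g, y, y)
  if (vx <= 0 || vy <= 0) stop("zero score variance under this distribution")
  trend_corr_mat(g, x, y)
}

#' Null correlations and linear-combination weights for MAX3
#'
#' Computes the pairwise null correlations `rho_RD`, `rho_RA`, `rho_AD`
#' of the recessive/additive/dominant trend statistics under genotype
#' distribution `g`, and the coefficients of the exact identity
#' `T_A = omega1 T_R + omega2 T_D`:
#' `omega1 = (rho_RA - rho_RD rho_AD) / (1 - rho_RD^2)`,
#' `omega2 = (rho_AD - rho_RD rho_RA) / (1 - rho_RD^2)`.
#' Algebraically `omega1 = sigma_R / sigma_A` and
#' `omega2 = sigma_D / sigma_A`, the ratios of the null score-sum
#' standard deviations, because the additive scores are the sum of the
#' recessive and dominant scores.
#'
#' @param g genotype probability triple.
#' @return list with `rho_RD`, `rho_RA`, `rho_AD`, `omega` (length-2
#'   vector).
#' @export
null_correlations <- function(g) {
  rho_RD <- trend_correlation(g, .SCORES$REC, .SCORES$DOM)
  rho_RA <- trend_correlation(g, .SCORES$REC, .SCORES$ADD)
  rho_AD <- trend_correlation(g, .SCORES$ADD, .SCORES$DOM)
  list(rho_RD = rho_RD, rho_RA = rho_RA, rho_AD = rho_AD,
       omega = omega_weights(rho_RD, rho_RA, rho_AD))
}

#' @rdname null_correlations
#' @param rho_RD,rho_RA,rho_AD pairwise null correlations.
#' @export
omega_weights <- function(rho_RD, rho_RA, rho_AD) {
  if (abs(rho_RD) >= 1) stop("|rho_RD| must be < 1")
  c(omega1 = (rho_RA - rho_RD * rho_AD) / (1 - rho_RD^2),
    omega2 = (rho_AD - rho_RD * rho_RA) / (1 - rho_RD^2))
}

#' Maximin efficiency robust test (MERT) statistic
#'
#' The compromise statistic across the extreme genetic models:
#' `T_mert = (T_R + T_D) / sqrt(2 (1 + rho_RD))`, where `T_R`, `T_D` are
#' the recessive and dominant trend statistics and `rho_RD` their null
#' correlation. For observed tables `rho_RD` is estimated by default from
#' the pooled genotype frequencies; `rho_source = "cases"` estimates it
#' from the case arm. Asymptotically standard normal under the null.
#'
#' @inheritParams catt_stat
#' @param rho_source `"pooled"` (default) or `"cases"`.
#' @return the test statistic (scalar).
#' @export
mert_stat <- function(table, var_est = c("pooled", "arms"),
                      rho_source = c("pooled", "cases")) {
  check_table(table)
  t <- mert_stat_mat(rbind(table$cases), rbind(table$controls),
                     match.arg(var_est), match.arg(rho_source))
  if (is.na(t)) stop("degenerate table: zero score variance")
  t
}

#' MAX3 statistic
#'
#' The maximum of the absolute trend statistics under the recessive,
#' additive and dominant score sets:
#' `T_max = max(|T_R|, |T_A|, |T_D|)`. Its null distribution follows from
#' the joint normality of `(T_R, T_D)` and the identity
#' `T_A = omega1 T_R + omega2 T_D`; see [max3_null_tail()].
#'
#' @inheritParams catt_stat
#' @return the test statistic (scalar, non-negative).
#' @export
max3_stat <- function(table, var_est = c("pooled", "arms")) {
  check_table(table)
  t <- max3_stat_mat(rbind(table$cases), rbind(table$controls),
                     match.arg(var_est))
  if (is.na(t)) stop("degenerate table: zero score variance")
  t
}

#' Combine stage statistics into the joint statistic
#'
#' `T_J = sqrt(pi) t1 + sqrt(1 - pi) t2`. Under the null, if `t1` and
#' `t2` are independent standard normal the joint statistic is standard
#' normal with `Corr(t1, T_J) = sqrt(pi)`.
#'
#' @param t1,t2 stage-1 and stage-2 statistics (vectors allowed).
#' @param pi stage-1 subject fraction in (0, 1].
#' @export
joint_stat <- function(t1, t2, pi) {
  if (!(pi > 0 && pi <= 1)) stop("pi must be in (0, 1]")
  sqrt(pi) * t1 + sqrt(1 - pi) * t2
}
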