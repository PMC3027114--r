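## Asymptotic moments of the stage statistics under the alternative.
##
## Each stage statistic is a standardized linear score contrast
## U = (S * sum x r_i - R * sum x s_i) / N between case and control
## genotype distributions. Writing sigma0^2 for the pooled-null variance
## of the score (at the case/control mixture g = xi p + (1 - xi) q) and
## sigma1^2 for its variance under the alternative
## ((1 - xi) Var_p + xi Var_q), two delta-method bookkeepings are
## supported for the H1 law of the statistic:
##
##   "alternative" (default): mean = E(U) / sd1(U), var = Var1(U)/Var0(U).
##     The noncentrality is standardized under H1 (the two-proportion
##     power-formula convention); this is the convention the package's
##     power tables are computed in.
##   "null": mean = E(U) / sd0(U), var = Var1(U)/Var0(U). The plain
##     delta-method law of the pooled-variance statistic.
##
## Both reduce to (0, 1) under the null. The MERT scaling correlation
## rho_RD is evaluated, under the "alternative" convention, at the case
## genotype distribution; under "null" at the mixture.

catt_numerator_moments <- function(p, q, x, n_cases, n_controls, xi) {
  N <- n_cases + n_controls
  gmix <- xi * p + (1 - xi) * q
  p <- rbind(p); q <- rbind(q); gmix <- rbind(gmix)
  E <- sqrt(N * xi * (1 - xi)) *
    (as.vector(p %*% x) - as.vector(q %*% x))
  list(E = E,
       V0 = .gcov(gmix, x, x),
       V1 = (1 - xi) * .gcov(p, x, x) + xi * .gcov(q, x, x))
}

#' Alternative-hypothesis moments of the allele-frequency-difference test
#'
#' Asymptotic mean and variance of the stage statistic with population
#' allele frequencies in place of the estimates:
#' `mu = (theta - varpi) / sqrt((1/(2 r) + 1/(2 s)) pbar (1 - pbar))` and
#' `delta = ((1-xi) theta (1-theta) + xi varpi (1-varpi)) /
#'  (pbar (1 - pbar))`, where `pbar = theta xi + varpi (1 - xi)`.
#'
#' @param pop a [genotype_probs()] result.
#' @param n_cases,n_controls stage arm sizes.
#' @param xi design case fraction `r / (r + s)`.
#' @return list with `mean` and `var`; `(0, 1)` under the null.
#' @export
afdt_moments <- function(pop, n_cases, n_controls, xi) {
  af <- allele_freqs(pop)
  th <- af["theta"]; vp <- af["varpi"]
  if (th <= 0 || th >= 1 || vp <= 0 || vp >= 1)
    stop("degenerate population: allele frequency at 0 or 1")
  pbar <- th * xi + vp * (1 - xi)
  mu <- (th - vp) / sqrt((1 / (2 * n_cases) + 1 / (2 * n_controls)) *
                           pbar * (1 - pbar))
  de <- ((1 - xi) * th * (1 - th) + xi * vp * (1 - vp)) /
    (pbar * (1 - pbar))
  list(mean = unname(mu), var = unname(de))
}

#' Alternative-hypothesis moments of a trend statistic
#'
#' Delta-method mean and variance of the standardized trend statistic for
#' a stage with the given arm sizes, under the case/control genotype
#' distributions of `pop`. See the package vignette for the two
#' standardization conventions.
#'
#' @inheritParams afdt_moments
#' @param scores score vector of length 3.
#' @param standardize `"alternative"` (default) or `"null"`; the
#'   denominator used for the noncentrality.
#' @return list with `mean` and `var`.
#' @export
catt_moments <- function(pop, scores, n_cases, n_controls, xi,
                         standardize = c("alternative", "null")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(pop, "genotype_population"))
  z <- catt_numerator_moments(pop$case_probs, pop$control_probs, scores,
                              n_cases, n_controls, xi)
  if (!(z$V0 > 0) || !(z$V1 > 0))
    stop("degenerate population: zero score variance")
  sd_den <- if (standardize == "alternative") sqrt(z$V1) else sqrt(z$V0)
  list(mean = z$E / sd_den, var = z$V1 / z$V0)
}

#' Alternative-hypothesis moments of the MERT statistic
#'
#' Moments of `(T_R + T_D) / sqrt(2 (1 + rho_RD))` under the alternative,
#' combining the recessive and dominant trend moments with their H1
#' covariance. Under the `"alternative"` convention the scaling
#' correlation `rho_RD` is evaluated at the case genotype distribution;
#' under `"null"` at the case/control mixture.
#'
#' @inheritParams catt_moments
#' @return list with `mean`, `var` and the scaling correlation `rho_RD`.
#' @export
mert_moments <- function(pop, n_cases, n_controls, xi,
                         standardize = c("alternative", "null")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(pop, "genotype_population"))
  p <- pop$case_probs; q <- pop$control_probs
  R <- .SCORES$REC; D <- .SCORES$DOM
  zR <- catt_numerator_moments(p, q, R, n_cases, n_controls, xi)
  zD <- catt_numerator_moments(p, q, D, n_cases, n_controls, xi)
  gmix <- rbind(xi * p + (1 - xi) * q)
  V1c <- (1 - xi) * .gcov(rbind(p), R, D) + xi * .gcov(rbind(q), R, D)
  rho <- if (standardize == "alternative")
    trend_correlation(p, R, D) else trend_corr_mat(gmix, R, D)
  if (standardize == "alternative") {
    mu <- (zR$E / sqrt(zR$V1) + zD$E / sqrt(zD$V1)) / sqrt(2 * (1 + rho))
  } else {
    mu <- (zR$E / sqrt(zR$V0) + zD$E / sqrt(zD$V0)) / sqrt(2 * (1 + rho))
  }
  de <- (zR$V1 / zR$V0 + zD$V1 / zD$V0 + 2 * V1c / sqrt(zR$V0 * zD$V0)) /
    (2 * (1 + rho))
  list(mean = mu, var = de, rho_RD = rho)
}

## Stage moments for one of the normal-based joint methods.
stage_moments <- function(method, pop, n_cases, n_controls, xi,
                          standardize = "alternative") {
  switch(method,
         ALLEJ = afdt_moments(pop, n_cases, n_controls, xi),
         CATAJ = catt_moments(pop, .SCORES$ADD, n_cases, n_controls, xi,
                              standardize),
         MERTJ = mert_moments(pop, n_cases, n_controls, xi, standardize),
         stop("unknown method: ", method))
}
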