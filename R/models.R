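#' Specify a single-SNP disease model
#'
#' Parameterizes the penetrance model of one biallelic SNP with risk allele
#' G: disease prevalence `K`, risk-allele frequency `maf`, and genotype
#' relative risks `lambda1 = f1/f0` (Gg vs gg) and `lambda2 = f2/f0`
#' (GG vs gg), where `f_i` is the penetrance of genotype i. The baseline
#' penetrance is fixed by the prevalence constraint
#' `K = Pr(gg) f0 + Pr(Gg) f1 + Pr(GG) f2` under Hardy-Weinberg genotype
#' proportions, so `f0 = K / (Pr(gg) + lambda1 Pr(Gg) + lambda2 Pr(GG))`.
#'
#' `lambda1 = lambda2 = 1` encodes the null of no association. The three
#' classical genetic models are recessive (`lambda1 = 1 < lambda2`),
#' additive (`2 lambda1 = lambda2 + 1`) and dominant
#' (`lambda1 = lambda2 > 1`).
#'
#' @param K disease prevalence, in (0, 1).
#' @param maf risk-allele frequency, in (0, 1). Values above 0.5 are
#'   accepted with a warning (the formulas remain valid; the risk allele is
#'   then not the minor allele).
#' @param lambda1,lambda2 genotype relative risks, `lambda2 >= lambda1 >= 1`.
#' @param label free-text model label ("recessive", "additive", "dominant",
#'   "custom", ...). If `NULL`, inferred from the relative risks.
#' @return An object of class `"disease_model"`: a list with the inputs plus
#'   the penetrances `f0`, `f1`, `f2`.
#' @examples
#' disease_model(K = 0.1, maf = 0.15, lambda1 = 1, lambda2 = 2)
#' @export
disease_model <- function(K, maf, lambda1, lambda2, label = NULL) {
  stopifnot(is.numeric(K), length(K) == 1L, K > 0, K < 1,
            is.numeric(maf), length(maf) == 1L, maf > 0, maf < 1,
            is.numeric(lambda1), length(lambda1) == 1L,
            is.numeric(lambda2), length(lambda2) == 1L)
  if (lambda1 < 1 || lambda2 < lambda1)
    stop("relative risks must satisfy lambda2 >= lambda1 >= 1")
  if (maf > 0.5)
    warning("maf > 0.5: risk allele G is not the minor allele")
  f0 <- baseline_penetrance(K, maf, lambda1, lambda2)
  if (is.null(label)) {
    label <- if (lambda1 == 1 && lambda2 == 1) "null"
    else if (lambda1 == 1) "recessive"
    else if (lambda1 == lambda2) "dominant"
    else if (isTRUE(all.equal(2 * lambda1, lambda2 + 1))) "additive"
    else "custom"
  }
  structure(list(K = K, maf = maf, lambda1 = lambda1, lambda2 = lambda2,
                 f0 = f0, f1 = lambda1 * f0, f2 = lambda2 * f0,
                 label = label),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("Disease model (%s): K = %g, MAF = %g, lambda = (%g, %g)\n",
              x$label, x$K, x$maf, x$lambda1, x$lambda2))
  cat(sprintf("  penetrances f = (%.6g, %.6g, %.6g)\n", x$f0, x$f1, x$f2))
  invisible(x)
}

#' Hardy-Weinberg genotype proportions
#'
#' Genotype priors (gg, Gg, GG) for risk-allele frequency `maf`:
#' `((1-maf)^2, 2 maf (1-maf), maf^2)`.
#'
#' @param maf risk-allele frequency.
#' @return numeric vector of length 3.
#' @export
hwe_probs <- function(maf) {
  stopifnot(maf >= 0, maf <= 1)
  c(gg = (1 - maf)^2, Gg = 2 * maf * (1 - maf), GG = maf^2)
}

#' Baseline penetrance under the prevalence constraint
#'
#' Solves `K = sum_i Pr(genotype i) f_i` with `f1 = lambda1 f0`,
#' `f2 = lambda2 f0` and HWE genotype priors, giving
#' `f0 = K / (Pr(gg) + lambda1 Pr(Gg) + lambda2 Pr(GG))`.
#'
#' @inheritParams disease_model
#' @return the baseline penetrance `f0`.
#' @export
baseline_penetrance <- function(K, maf, lambda1, lambda2) {
  g <- hwe_probs(maf)
  f0 <- K / sum(g * c(1, lambda1, lambda2))
  if (lambda2 * f0 > 1)
    stop(sprintf("penetrance f2 = lambda2 * f0 = %.4g exceeds 1", lambda2 * f0))
  unname(f0)
}

#' Case and control genotype distributions
#'
#' Conditional genotype probabilities by disease status, from Bayes' rule:
#' `p_i = Pr(genotype i | case) = Pr(genotype i) f_i / K` and
#' `q_i = Pr(genotype i | control) = Pr(genotype i) (1 - f_i) / (1 - K)`.
#' Under the null both triples reduce to the HWE priors; under the
#' alternative the case distribution is tilted toward risk genotypes.
#'
#' @param model a [disease_model()].
#' @return An object of class `"genotype_population"`: a list with
#'   `case_probs` (p0, p1, p2), `control_probs` (q0, q1, q2) and the HWE
#'   priors `prior` -- each a probability triple over (gg, Gg, GG).
#' @export
genotype_probs <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  g <- hwe_probs(model$maf)
  f <- c(model$f0, model$f1, model$f2)
  p <- g * f / model$K
  q <- g * (1 - f) / (1 - model$K)
  structure(list(case_probs = p / sum(p), control_probs = q / sum(q),
                 prior = g),
            class = "genotype_population")
}

#' @export
print.genotype_population <- function(x, ...) {
  m <- rbind(case = x$case_probs, control = x$control_probs)
  colnames(m) <- c("gg", "Gg", "GG")
  print(round(m, 6))
  invisible(x)
}

#' Risk-allele frequencies of a genotype population
#'
#' The case and control risk-allele frequencies
#' `theta = p2 + p1/2` and `varpi = q2 + q1/2`.
#'
#' @param pop a [genotype_probs()] result.
#' @return named vector `c(theta, varpi)`.
#' @export
allele_freqs <- function(pop) {
  stopifnot(inherits(pop, "genotype_population"))
  c(theta = unname(pop$case_probs[3] + pop$case_probs[2] / 2),
    varpi = unname(pop$control_probs[3] + pop$control_probs[2] / 2))
}

#' Specify a two-stage study design
#'
#' @param r,s total numbers of cases and controls across both stages.
#' @param pi fraction of subjects genotyped in stage 1, in (0, 1].
#'   Stage-1 arm sizes are `round(pi * r)` and `round(pi * s)`; stage 2
#'   receives the remainder, so totals are preserved exactly.
#' @param gamma stage-1 selection level: SNPs with stage-1 p-value below
#'   `gamma` advance to stage 2.
#' @param alpha genome-wide type-I error; the per-SNP level is `alpha / m`
#'   (Bonferroni).
#' @param m number of SNPs genotyped in stage 1.
#' @return An object of class `"study_design"` with the inputs, the case
#'   fraction `xi = r / (r + s)`, and the four stage arm sizes
#'   `r1, s1, r2, s2`.
#' @export
study_design <- function(r, s, pi, gamma = 1e-4, alpha = 0.05, m = 5e5) {
  stopifnot(r >= 1, s >= 1, r == round(r), s == round(s),
            pi > 0, pi <= 1, gamma > 0, gamma < 1,
            alpha > 0, alpha < 1, m >= 1)
  r1 <- round(pi * r); s1 <- round(pi * s)
  if (r1 < 1 || s1 < 1) stop("stage-1 arm sizes must be at least 1")
  structure(list(r = r, s = s, pi = pi, gamma = gamma, alpha = alpha, m = m,
                 xi = r / (r + s),
                 r1 = r1, s1 = s1, r2 = r - r1, s2 = s - s1),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Two-stage design: r = %d cases, s = %d controls, pi = %g\n",
              x$r, x$s, x$pi))
  cat(sprintf("  stage 1: %d/%d, stage 2: %d/%d (cases/controls)\n",
              x$r1, x$s1, x$r2, x$s2))
  cat(sprintf("  gamma = %g, alpha = %g, m = %g (per-SNP level %.3g)\n",
              x$gamma, x$alpha, x$m, x$alpha / x$m))
  invisible(x)
}
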