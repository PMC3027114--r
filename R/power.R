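#' Analytic power of a normal-based joint analysis
#'
#' Power of the ALLEJ (allele-frequency-difference), CATAJ (additive
#' trend) or MERTJ joint analysis:
#' `Pr_H1(|T1| > b1, |T_J| > b_J)` under the shifted bivariate normal with
#' mean `(mu1, sqrt(pi) mu1 + sqrt(1-pi) mu2)` and covariance
#' `Gamma diag(delta1, delta2) Gamma'`,
#' `Gamma = rbind(c(1, 0), c(sqrt(pi), sqrt(1-pi)))`, where the stage
#' moments `(mu_k, delta_k)` come from the method's alternative-hypothesis
#' approximation. Thresholds solve the null equation
#' `Pr_H0(|T1| > b1, |T_J| > b_J) = alpha / m`.
#'
#' @param method one of `"ALLEJ"`, `"CATAJ"`, `"MERTJ"`.
#' @param model a [disease_model()].
#' @param design a [study_design()].
#' @param standardize moment convention, see [catt_moments()].
#' @param thresholds optional precomputed [joint_threshold_normal()].
#' @return object of class `"power_result"` with `power`, `se` (0 for the
#'   analytic path), `thresholds`, and the scenario.
#' @examples
#' mod <- disease_model(K = 0.1, maf = 0.15, lambda1 = 1, lambda2 = 2)
#' des <- study_design(r = 5000, s = 5000, pi = 0.5, gamma = 1e-4)
#' analytic_power_joint("MERTJ", mod, des)
#' @export
analytic_power_joint <- function(method = c("ALLEJ", "CATAJ", "MERTJ"),
                                 model, design,
                                 standardize = c("alternative", "null"),
                                 thresholds = NULL) {
  method <- match.arg(method)
  standardize <- match.arg(standardize)
  stopifnot(inherits(model, "disease_model"), inherits(design, "study_design"))
  if (is.null(thresholds))
    thresholds <- joint_threshold_normal(design$pi, design$gamma,
                                         design$alpha, design$m)
  pop <- genotype_probs(model)
  m1 <- stage_moments(method, pop, design$r1, design$s1, design$xi, standardize)
  m2 <- stage_moments(method, pop, design$r2, design$s2, design$xi, standardize)
  pi <- design$pi
  mu <- c(m1$mean, sqrt(pi) * m1$mean + sqrt(1 - pi) * m2$mean)
  V <- matrix(c(m1$var, sqrt(pi) * m1$var,
                sqrt(pi) * m1$var, pi * m1$var + (1 - pi) * m2$var), 2)
  pw <- bvn_rect_exceed_general(thresholds$b1, thresholds$bJ, mu, V)
  structure(list(power = pw, se = 0, method = method,
                 thresholds = thresholds, model = model, design = design,
                 path = "analytic"),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("%s power (%s): %.4f", x$method, x$path, x$power))
  if (x$se > 0) cat(sprintf(" (se %.4f)", x$se))
  cat("\n")
  invisible(x)
}

## simulate the two-stage statistics for one method across n_rep
## replicates; returns a list(t1, tJ). The simulated statistics use the
## same convention the analytic power path models: score variances from
## the arms separately and the MERT scaling correlation from the cases
## ("alternative"), or pooled estimates ("null").
simulate_method_stats <- function(method, pop, design, n_rep,
                                  standardize = "alternative") {
  var_est <- if (standardize == "alternative") "arms" else "pooled"
  rho_source <- if (standardize == "alternative") "cases" else "pooled"
  d <- sim_two_stage_matrices(pop, design, n_rep)
  f <- switch(method,
    ALLEJ = function(ca, co) afdt_stat_mat(ca, co),
    CATAJ = function(ca, co) catt_stat_mat(ca, co, .SCORES$ADD, var_est),
    MERTJ = function(ca, co) mert_stat_mat(ca, co, var_est, rho_source),
    MAX3J = function(ca, co) max3_stat_mat(ca, co, var_est))
  if (method == "MAX3J") {
    T1 <- sapply(.SCORES, function(x) catt_stat_mat(d$ca1, d$co1, x, var_est))
    T2 <- sapply(.SCORES, function(x) catt_stat_mat(d$ca2, d$co2, x, var_est))
    TJ <- joint_stat(T1, T2, design$pi)
    list(t1 = pmax(abs(T1[, 1]), abs(T1[, 2]), abs(T1[, 3])),
         tJ = pmax(abs(TJ[, 1]), abs(TJ[, 2]), abs(TJ[, 3])))
  } else {
    t1 <- f(d$ca1, d$co1)
    t2 <- f(d$ca2, d$co2)
    list(t1 = abs(t1), tJ = abs(joint_stat(t1, t2, design$pi)))
  }
}

#' Empirical power of a joint analysis by simulation
#'
#' Simulates `n_rep` two-stage multinomial data sets under the
#' alternative, computes the method's stage statistics, and reports the
#' fraction of replicates whose stage-1 statistic exceeds the stage-1
#' threshold and whose joint statistic exceeds the joint threshold.
#'
#' For `"MAX3J"` this is the primary power path (thresholds from
#' [max3_stage1_threshold()] and [max3_joint_threshold()], computed with
#' the model's HWE genotype frequencies when not supplied); for the
#' normal-based methods it is the Monte-Carlo cross-check of
#' [analytic_power_joint()].
#'
#' @param method one of `"ALLEJ"`, `"CATAJ"`, `"MERTJ"`, `"MAX3J"`.
#' @inheritParams analytic_power_joint
#' @param n_rep number of replicates (default 10000).
#' @param B1 selected stage-1 draws for the MAX3J threshold Monte Carlo.
#' @param seed optional integer seed.
#' @return a `"power_result"` with the binomial standard error and, for
#'   MAX3J, the Monte-Carlo threshold metadata.
#' @export
empirical_power_joint <- function(method = c("MAX3J", "ALLEJ", "CATAJ", "MERTJ"),
                                  model, design, n_rep = 1e4,
                                  thresholds = NULL, B1 = 1e6, seed = NULL,
                                  standardize = c("alternative", "null")) {
  method <- match.arg(method)
  standardize <- match.arg(standardize)
  stopifnot(inherits(model, "disease_model"), inherits(design, "study_design"))
  if (n_rep < 100) warning("n_rep < 100: power estimate will be very noisy")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(thresholds)) {
    thresholds <- if (method == "MAX3J") {
      corr <- null_correlations(hwe_probs(model$maf))
      max3_joint_threshold(design$pi, design$gamma, design$alpha, design$m,
                           corr1 = corr, B1 = B1)
    } else {
      joint_threshold_normal(design$pi, design$gamma, design$alpha, design$m)
    }
  }
  pop <- genotype_probs(model)
  st <- simulate_method_stats(method, pop, design, n_rep, standardize)
  hit <- st$t1 > thresholds$b1 & st$tJ > thresholds$bJ
  pw <- mean(hit)
  structure(list(power = pw, se = sqrt(pw * (1 - pw) / n_rep),
                 method = method, thresholds = thresholds,
                 model = model, design = design, n_rep = n_rep,
                 path = "empirical"),
            class = "power_result")
}

#' Empirical family-wise error rate of the full two-stage pipeline
#'
#' Simulates `n_genomes` null genomes of `m` independent SNPs each (all at
#' the same allele frequency), runs the full two-stage selection and joint
#' testing for the four methods, and reports the fraction of genomes in
#' which at least one SNP passes both thresholds. With thresholds solved
#' at per-SNP level `alpha / m`, the FWER is controlled at `alpha` by the
#' Bonferroni argument; this simulation validates that control.
#'
#' @param maf allele frequency of the simulated null SNPs.
#' @param design a [study_design()]; `design$m` is the number of SNPs per
#'   genome (kept small here -- the per-SNP level scales as `alpha / m`).
#' @param n_genomes number of simulated genomes.
#' @param B1 selected draws for the MAX3J threshold Monte Carlo.
#' @param seed optional integer seed.
#' @return list with `fwer` (named per-method rates), `per_snp`
#'   (per-SNP rejection probabilities), `se` (binomial standard error of
#'   the FWER estimates) and the thresholds used.
#' @export
empirical_fwer <- function(maf, design, n_genomes = 1e4, B1 = 1e6,
                           seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(seed)) set.seed(seed)
  corr <- null_correlations(hwe_probs(maf))
  thr_n <- joint_threshold_normal(design$pi, design$gamma, design$alpha,
                                  design$m)
  thr_m <- max3_joint_threshold(design$pi, design$gamma, design$alpha,
                                design$m, corr1 = corr, B1 = B1)
  model0 <- disease_model(K = 0.1, maf = maf, lambda1 = 1, lambda2 = 1)
  pop <- genotype_probs(model0)
  n_snp <- design$m * n_genomes
  methods <- c("ALLEJ", "CATAJ", "MERTJ", "MAX3J")
  hits <- matrix(FALSE, n_snp, length(methods),
                 dimnames = list(NULL, methods))
  ## simulate in blocks to bound memory; all methods share the same data
  block <- 1e6
  done <- 0L
  while (done < n_snp) {
    nb <- min(block, n_snp - done)
    idx <- done + seq_len(nb)
    d <- sim_two_stage_matrices(pop, design, nb)
    T1 <- sapply(.SCORES, function(x) catt_stat_mat(d$ca1, d$co1, x, "arms"))
    T2 <- sapply(.SCORES, function(x) catt_stat_mat(d$ca2, d$co2, x, "arms"))
    TJ <- joint_stat(T1, T2, design$pi)
    rho1 <- trend_corr_mat(d$ca1 / rowSums(d$ca1), .SCORES$REC, .SCORES$DOM)
    rho2 <- trend_corr_mat(d$ca2 / rowSums(d$ca2), .SCORES$REC, .SCORES$DOM)
    m1 <- (T1[, 1] + T1[, 3]) / sqrt(2 * (1 + rho1))
    m2 <- (T2[, 1] + T2[, 3]) / sqrt(2 * (1 + rho2))
    a1 <- afdt_stat_mat(d$ca1, d$co1); a2 <- afdt_stat_mat(d$ca2, d$co2)
    hits[idx, "ALLEJ"] <- abs(a1) > thr_n$b1 &
      abs(joint_stat(a1, a2, design$pi)) > thr_n$bJ
    hits[idx, "CATAJ"] <- abs(T1[, 2]) > thr_n$b1 & abs(TJ[, 2]) > thr_n$bJ
    hits[idx, "MERTJ"] <- abs(m1) > thr_n$b1 &
      abs(joint_stat(m1, m2, design$pi)) > thr_n$bJ
    hits[idx, "MAX3J"] <- pmax(abs(T1[, 1]), abs(T1[, 2]), abs(T1[, 3])) > thr_m$b1 &
      pmax(abs(TJ[, 1]), abs(TJ[, 2]), abs(TJ[, 3])) > thr_m$bJ
    done <- done + nb
  }
  genome <- rep(seq_len(n_genomes), each = design$m)
  fwer <- apply(hits, 2, function(h) mean(tapply(h, genome, any)))
  per_snp <- colMeans(hits)
  list(fwer = fwer, per_snp = per_snp,
       se = sqrt(design$alpha * (1 - design$alpha) / n_genomes),
       thresholds = list(normal = thr_n, max3 = thr_m))
}

## scenario grids of the power-comparison study: K = 0.1, alpha = 0.05,
## m = 5e5; MAF per table; three genetic models per table
power_table_spec <- function(table_id) {
  if (!as.character(table_id) %in% c("2", "3", "4", "5"))
    stop("table_id must be 2, 3, 4 or 5")
  maf <- c(`2` = 0.15, `3` = 0.25, `4` = 0.35, `5` = 0.45)[[as.character(table_id)]]
  n_rec <- c(`2` = 5000, `3` = 5000, `4` = 4000, `5` = 2000)[[as.character(table_id)]]
  l2_rec <- if (table_id == 2) 2 else 1.5
  list(maf = maf,
       rows = list(
         recessive = list(lambda1 = 1, lambda2 = l2_rec, n = n_rec),
         additive  = list(lambda1 = 1.4, lambda2 = 1.8, n = 2000),
         dominant  = list(lambda1 = 1.5, lambda2 = 1.5, n = 2000)))
}

#' Reproduce a grid of the power-comparison study
#'
#' Computes the power of the four joint analyses over the scenario grid of
#' one of the study's comparison tables: MAF 0.15/0.25/0.35/0.45 for
#' tables 2/3/4/5, three genetic models (recessive, additive, dominant),
#' `pi` in {0.5, 0.4, 0.3} and `gamma` in {1e-4, 2e-4}, with K = 0.1,
#' alpha = 0.05 and m = 5e5. ALLEJ/CATAJ/MERTJ power is analytic; MAX3J
#' power is empirical with Monte-Carlo thresholds.
#'
#' @param table_id 2, 3, 4 or 5.
#' @param rows subset of `c("recessive", "additive", "dominant")`.
#' @param pis,gammas grid values.
#' @param methods subset of the four method names.
#' @param n_rep replicates for MAX3J power.
#' @param B1 selected draws for MAX3J thresholds.
#' @param seed optional integer seed (applies to the MAX3J Monte Carlo).
#' @return data.frame with one row per scenario and one column per method.
#' @export
power_table <- function(table_id, rows = c("recessive", "additive", "dominant"),
                        pis = c(0.5, 0.4, 0.3), gammas = c(1e-4, 2e-4),
                        methods = c("ALLEJ", "CATAJ", "MERTJ", "MAX3J"),
                        n_rep = 1e4, B1 = 1e6, seed = NULL) {
  grid <- power_table_spec(table_id)
  rows <- match.arg(rows, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (rw in rows) {
    sc <- grid$rows[[rw]]
    model <- disease_model(K = 0.1, maf = grid$maf,
                           lambda1 = sc$lambda1, lambda2 = sc$lambda2,
                           label = rw)
    for (pi in pis) for (gm in gammas) {
      design <- study_design(r = sc$n, s = sc$n, pi = pi, gamma = gm)
      rec <- list(table = table_id, model = rw, maf = grid$maf,
                  lambda1 = sc$lambda1, lambda2 = sc$lambda2,
                  r = sc$n, pi = pi, gamma = gm)
      for (mth in methods) {
        rec[[mth]] <- if (mth == "MAX3J")
          empirical_power_joint("MAX3J", model, design, n_rep = n_rep,
                                B1 = B1)$power
        else analytic_power_joint(mth, model, design)$power
      }
      out[[length(out) + 1L]] <- as.data.frame(rec)
    }
  }
  do.call(rbind, out)
}
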