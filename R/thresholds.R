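#' Stage-1 selection threshold for a normal statistic
#'
#' `b1 = qnorm(1 - gamma / 2)`: a SNP advances to stage 2 when its
#' two-sided stage-1 p-value is below `gamma`, i.e. `|T1| > b1`.
#'
#' @param gamma stage-1 selection level in (0, 1].
#' @export
stage1_threshold <- function(gamma) {
  if (!(gamma > 0 && gamma <= 1)) stop("gamma must be in (0, 1]")
  stats::qnorm(1 - gamma / 2)
}

#' Joint threshold for the normal-based joint analyses
#'
#' Solves `Pr_H0(|Z1| > b1, |Z_J| > b_J) = alpha / m` where
#' `(Z1, Z_J)` is standard bivariate normal with correlation `sqrt(pi)`
#' and `b1 = qnorm(1 - gamma/2)`. The same thresholds apply to the
#' allele-frequency-difference, additive-trend and MERT joint analyses,
#' whose stage statistics are all asymptotically standard normal and
#' combined with the same `sqrt(pi)` weights.
#'
#' @param pi stage-1 subject fraction in (0, 1].
#' @param gamma stage-1 selection level; must exceed `alpha / m`, else the
#'   joint event is impossible at level `gamma`.
#' @param alpha genome-wide type-I error.
#' @param m number of stage-1 SNPs.
#' @return object of class `"joint_thresholds"`: list with `b1`, `bJ`,
#'   the achieved equation `residual`, and the design parameters.
#' @examples
#' joint_threshold_normal(pi = 0.5, gamma = 1e-4, alpha = 0.05, m = 5e5)
#' @export
joint_threshold_normal <- function(pi, gamma, alpha = 0.05, m = 5e5) {
  if (!(pi > 0 && pi <= 1)) stop("pi must be in (0, 1]")
  level <- alpha / m
  if (!(level < gamma))
    stop("alpha/m must be below gamma: the joint rejection is a subset of stage-1 selection")
  b1 <- stage1_threshold(gamma)
  rho <- sqrt(pi)
  f <- function(b) bvn_rect_exceed(b1, b, rho) - level
  lo <- 0.5 * stats::qnorm(1 - level / 2)
  hi <- 10
  while (f(hi) > 0 && hi < 50) hi <- hi + 5
  if (f(lo) < 0) lo <- 0
  if (f(lo) < 0 || f(hi) > 0)
    stop(sprintf("no root in bracket [%g, %g]: f(lo) = %.3g, f(hi) = %.3g",
                 lo, hi, f(lo), f(hi)))
  bJ <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps)$root
  structure(list(b1 = b1, bJ = bJ, residual = f(bJ),
                 pi = pi, gamma = gamma, alpha = alpha, m = m,
                 method = "normal"),
            class = "joint_thresholds")
}

#' @export
print.joint_thresholds <- function(x, ...) {
  cat(sprintf("Joint thresholds (%s): b1 = %.6f, bJ = %.6f\n",
              x$method, x$b1, x$bJ))
  cat(sprintf("  pi = %g, gamma = %g, alpha/m = %.3g, residual = %.2e\n",
              x$pi, x$gamma, x$alpha / x$m, x$residual))
  if (!is.null(x$mc_meta))
    cat(sprintf("  MC: B1 = %d selected draws, attained tail %.4g (target %.4g)\n",
                x$mc_meta$B1, x$mc_meta$attained, x$mc_meta$target))
  invisible(x)
}

#' Null tail probability of MAX3
#'
#' `Pr_H0(max(|T_R|, |T_A|, |T_D|) > v)` where `(T_R, T_D)` is standard
#' bivariate normal with correlation `rho_RD` and
#' `T_A = omega1 T_R + omega2 T_D`. The acceptance region is a hexagon in
#' the `(T_R, T_D)` plane; the probability is computed by integrating the
#' conditional normal band over `T_R`.
#'
#' @param v threshold (non-negative).
#' @param corr a [null_correlations()] result (or any list with `rho_RD`
#'   and `omega`).
#' @return the tail probability.
#' @export
max3_null_tail <- function(v, corr) {
  if (v <= 0) return(1)
  rho <- corr$rho_RD; w <- corr$omega
  if (!(w[2] > 0))
    stop("omega2 must be positive (holds for any genotype distribution with positive variance)")
  tau <- sqrt(1 - rho^2)
  f <- function(x) {
    up <- pmin(v, (v - w[1] * x) / w[2])
    lo <- pmax(-v, (-v - w[1] * x) / w[2])
    r <- stats::pnorm((up - rho * x) / tau) - stats::pnorm((lo - rho * x) / tau)
    r[up <= lo] <- 0
    r * stats::dnorm(x)
  }
  ## the band limits switch between the box and slab constraints at
  ## x = +/- v (1 -+ w2) / w1; integrate each smooth piece separately
  br <- c(-v, v)
  if (abs(w[1]) > 1e-12)
    br <- c(br, v * (1 - w[2]) / w[1], -v * (1 - w[2]) / w[1],
            v * (1 + w[2]) / w[1], -v * (1 + w[2]) / w[1])
  br <- sort(unique(pmin(v, pmax(-v, br))))
  acc <- 0
  for (i in seq_len(length(br) - 1L)) {
    if (br[i + 1L] - br[i] < 1e-14) next
    acc <- acc + stats::integrate(f, br[i], br[i + 1L], rel.tol = 1e-11,
                                  abs.tol = 1e-15, subdivisions = 200L,
                                  stop.on.error = FALSE)$value
  }
  max(0, 1 - acc)
}

#' Stage-1 threshold for MAX3
#'
#' Solves `Pr_H0(max(|T_R|, |T_A|, |T_D|) > v1) = gamma` via
#' [max3_null_tail()]. Always at least `stage1_threshold(gamma)` since the
#' max of the three statistics is stochastically larger than any one of
#' them.
#'
#' @param gamma stage-1 selection level in (0, 1].
#' @inheritParams max3_null_tail
#' @export
max3_stage1_threshold <- function(gamma, corr) {
  if (!(gamma > 0 && gamma <= 1)) stop("gamma must be in (0, 1]")
  if (gamma == 1) return(0)
  f <- function(v) max3_null_tail(v, corr) - gamma
  hi <- stage1_threshold(gamma) + 2
  if (f(hi) > 0) hi <- hi + 4
  if (f(1e-8) < 0 || f(hi) > 0) stop("failed to bracket the MAX3 threshold")
  stats::uniroot(f, c(1e-8, hi), tol = 1e-12)$root
}

#' Exact sampler of the stage-1 pair conditioned on MAX3 selection
#'
#' Draws `(T_R, T_D)` from the standard bivariate normal with correlation
#' `rho_RD`, conditioned on the selection event
#' `max(|T_R|, |T_A|, |T_D|) > v1`. The event is the union of three slabs
#' `|L_i| > v1` for unit-variance linear functionals `L_1 = T_R`,
#' `L_2 = T_A`, `L_3 = T_D`; a slab is chosen uniformly (each has the same
#' marginal probability `2 pnorm(-v1)`), the functional is drawn from the
#' two-sided truncated normal, the orthogonal component from its exact
#' conditional normal, and the draw is accepted with probability 1 over
#' the number of slabs containing it. This reproduces the conditional law
#' exactly; the acceptance bookkeeping also yields an unbiased estimate of
#' the selection probability.
#'
#' @param n number of conditional draws to return.
#' @param v1 selection threshold (positive).
#' @param corr a [null_correlations()] result.
#' @param seed optional integer seed.
#' @return list with `draws` (n x 2 matrix of `(T_R, T_D)`), `p_event`
#'   (estimated selection probability), `n_proposed`, `n_accepted`.
#' @export
conditional_stage1_sampler <- function(n, v1, corr, seed = NULL) {
  stopifnot(n >= 1, v1 > 0)
  if (!is.null(seed)) set.seed(seed)
  rho <- corr$rho_RD; w <- corr$omega
  S <- matrix(c(1, rho, rho, 1), 2)
  A <- rbind(c(1, 0), w / sqrt(drop(t(w) %*% S %*% w)), c(0, 1))
  ## conditional decomposition per slab: Z = (S a) L + b W, W ~ N(0,1),
  ## with b b' = S - (S a)(S a)' (rank 1)
  decomp <- lapply(1:3, function(k) {
    a <- A[k, ]; Sa <- drop(S %*% a)
    C <- S - outer(Sa, Sa)
    b <- if (C[1, 1] > 1e-14) C[, 1] / sqrt(C[1, 1]) else c(0, sqrt(max(C[2, 2], 0)))
    list(Sa = Sa, b = b)
  })
  log_tail <- stats::pnorm(v1, lower.tail = FALSE, log.p = TRUE)
  out <- matrix(NA_real_, 0, 2)
  n_prop <- 0L; n_acc <- 0L
  while (nrow(out) < n) {
    nb <- max(2L * (n - nrow(out)), 1024L)
    slab <- sample.int(3L, nb, replace = TRUE)
    ## two-sided truncated normal: random sign, magnitude beyond v1
    mag <- stats::qnorm(log_tail + log(stats::runif(nb)),
                        lower.tail = FALSE, log.p = TRUE)
    L <- sample(c(-1, 1), nb, replace = TRUE) * mag
    W <- stats::rnorm(nb)
    Z <- matrix(NA_real_, nb, 2)
    for (k in 1:3) {
      id <- slab == k
      if (!any(id)) next
      d <- decomp[[k]]
      Z[id, 1] <- d$Sa[1] * L[id] + d$b[1] * W[id]
      Z[id, 2] <- d$Sa[2] * L[id] + d$b[2] * W[id]
    }
    mult <- (abs(Z[, 1]) > v1) + (abs(Z %*% A[2, ]) > v1) + (abs(Z[, 2]) > v1)
    keep <- mult >= 1L & stats::runif(nb) < 1 / pmax(mult, 1L)
    n_prop <- n_prop + nb; n_acc <- n_acc + sum(keep)
    out <- rbind(out, Z[keep, , drop = FALSE])
  }
  list(draws = out[seq_len(n), , drop = FALSE],
       p_event = 6 * stats::pnorm(-v1) * n_acc / n_prop,
       n_proposed = n_prop, n_accepted = n_acc)
}

## draw n iid pairs from BVN(0, [[1, rho], [rho, 1]])
rbvn <- function(n, rho) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}

#' Monte-Carlo joint threshold for the MAX3 joint analysis
#'
#' Estimates the joint threshold `vJ` by the three-step algorithm:
#' (1) draw stage-1 pairs `(T_R, T_D)` and keep those with stage-1 MAX3
#' above `v1`; (2) draw independent stage-2 pairs for the selected
#' replicates and form the joint MAX3
#' `max(|T_J^R|, |T_J^A|, |T_J^D|)` with `sqrt(pi)` stage weights;
#' (3) take `vJ` as the smallest simulated joint value whose exceedance
#' fraction among selected replicates is at most `alpha / (m gamma)` --
#' the admissible fraction closest to the target (ties resolved toward
#' the smallest value).
#'
#' Stage-1 selection can be simulated naively (`sampler = "naive"`, B
#' total draws) or drawn directly from the conditional law with
#' [conditional_stage1_sampler()] (`sampler = "conditional"`, B1 selected
#' draws), which is exact and removes the 1/gamma rejection cost at
#' genome-wide selection levels.
#'
#' @param pi stage-1 subject fraction.
#' @param gamma stage-1 selection level.
#' @param alpha,m genome-wide error and number of SNPs;
#'   `alpha / (m gamma)` must be below 1.
#' @param corr1,corr2 stage-1 and stage-2 [null_correlations()].
#' @param B1 number of selected stage-1 draws (conditional sampler).
#' @param B total stage-1 draws (naive sampler).
#' @param sampler `"conditional"` (default) or `"naive"`.
#' @param v1 optional precomputed stage-1 threshold.
#' @param seed optional integer seed.
#' @return object of class `"joint_thresholds"` with `b1 = v1`,
#'   `bJ = vJ` and `mc_meta` (B, B1, attained tail fraction, seed).
#' @export
max3_joint_threshold <- function(pi, gamma, alpha = 0.05, m = 5e5,
                                 corr1, corr2 = corr1,
                                 B1 = 1e6, B = NULL,
                                 sampler = c("conditional", "naive"),
                                 v1 = NULL, seed = NULL) {
  sampler <- match.arg(sampler)
  if (!(pi > 0 && pi <= 1)) stop("pi must be in (0, 1]")
  level <- alpha / (m * gamma)
  if (level >= 1)
    stop("alpha/(m*gamma) >= 1: every selected SNP would be declared significant")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(v1)) v1 <- max3_stage1_threshold(gamma, corr1)
  if (sampler == "naive") {
    if (is.null(B)) stop("naive sampler needs B")
    Z <- rbvn(B, corr1$rho_RD)
    tmax <- pmax(abs(Z[, 1]), abs(Z %*% c(corr1$omega)), abs(Z[, 2]))
    Z1 <- Z[tmax > v1, , drop = FALSE]
    B1 <- nrow(Z1)
    if (B1 == 0L)
      stop("no stage-1 draw passed selection; increase B or use the conditional sampler")
  } else {
    cs <- conditional_stage1_sampler(B1, v1, corr1)
    Z1 <- cs$draws
    B <- NA_integer_
  }
  if (B1 * level < 100)
    warning(sprintf("only %.0f expected exceedances at level alpha/(m*gamma); vJ will be noisy",
                    B1 * level))
  Z2 <- rbvn(B1, corr2$rho_RD)
  TJR <- sqrt(pi) * Z1[, 1] + sqrt(1 - pi) * Z2[, 1]
  TJD <- sqrt(pi) * Z1[, 2] + sqrt(1 - pi) * Z2[, 2]
  TJA <- sqrt(pi) * drop(Z1 %*% corr1$omega) +
    sqrt(1 - pi) * drop(Z2 %*% corr2$omega)
  TJmax <- pmax(abs(TJR), abs(TJA), abs(TJD))
  ## step 3 over the simulated values: exceedance fraction is nonincreasing
  ## in the candidate, so the admissible value closest to the target level
  ## is the smallest candidate with fraction <= level
  st <- sort(TJmax)
  n_gt <- B1 - seq_len(B1)           # exceedances if vJ = st[i] (no ties)
  dup <- duplicated(st, fromLast = TRUE)
  ok <- which(!dup & n_gt / B1 <= level)
  if (length(ok) == 0L)
    stop("no admissible vJ among the simulated values; increase B1")
  vJ <- st[ok[1]]
  attained <- mean(TJmax > vJ)
  structure(list(b1 = v1, bJ = vJ, residual = attained - level,
                 pi = pi, gamma = gamma, alpha = alpha, m = m,
                 method = "MAX3J",
                 mc_meta = list(B = B, B1 = B1, attained = attained,
                                target = level, sampler = sampler)),
            class = "joint_thresholds")
}
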