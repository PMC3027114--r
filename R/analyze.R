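#' Read per-SNP two-stage genotype count tables from a TSV file
#'
#' Expects a header and 13 columns: `snp_id`, then stage-1 counts
#' `r0_1 r1_1 r2_1 s0_1 s1_1 s2_1` and stage-2 counts
#' `r0_2 r1_2 r2_2 s0_2 s1_2 s2_2`, all in (gg, Gg, GG) genotype order
#' with G the risk allele (`flip = TRUE` reverses the genotype order of
#' every triple). Counts must be non-negative integers; a SNP whose stage
#' has zero subjects in an arm is skipped with a warning.
#'
#' @param path TSV file path.
#' @param flip reorient tables whose risk allele is the first-listed.
#' @return named list of per-SNP lists with `stage1`, `stage2`
#'   ([genotype_table()]s) and `pi` (stage-1 genotyped fraction,
#'   recomputed from the observed totals).
#' @export
read_counts_tsv <- function(path, flip = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) != 13L)
    stop(sprintf("expected 13 columns (snp_id + 12 counts), found %d", ncol(df)))
  out <- list()
  for (i in seq_len(nrow(df))) {
    cnt <- suppressWarnings(as.numeric(df[i, -1]))
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
      stop(sprintf("row %d (%s): counts must be non-negative integers",
                   i, df[i, 1]))
    s1 <- genotype_table(cnt[1:3], cnt[4:6])
    s2 <- genotype_table(cnt[7:9], cnt[10:12])
    if (flip) { s1 <- flip_table(s1); s2 <- flip_table(s2) }
    n1 <- sum(s1$cases) + sum(s1$controls)
    n2 <- sum(s2$cases) + sum(s2$controls)
    if (n1 == 0L || sum(s1$cases) == 0L || sum(s1$controls) == 0L) {
      warning(sprintf("row %d (%s): empty stage-1 arm, SNP skipped", i, df[i, 1]))
      next
    }
    out[[as.character(df[i, 1])]] <-
      list(stage1 = s1, stage2 = s2, pi = n1 / (n1 + n2))
  }
  out
}

#' Write per-SNP two-stage count tables to TSV
#'
#' Inverse of [read_counts_tsv()].
#'
#' @param snps named list as returned by [read_counts_tsv()], or with
#'   `stage1`/`stage2` tables per element.
#' @param path output file path.
#' @export
write_counts_tsv <- function(snps, path) {
  rows <- lapply(names(snps), function(id) {
    x <- snps[[id]]
    data.frame(snp_id = id,
               t(c(x$stage1$cases, x$stage1$controls,
                   x$stage2$cases, x$stage2$controls)))
  })
  df <- do.call(rbind, rows)
  names(df) <- c("snp_id",
                 "r0_1", "r1_1", "r2_1", "s0_1", "s1_1", "s2_1",
                 "r0_2", "r1_2", "r2_2", "s0_2", "s1_2", "s2_2")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## stage statistics of one table (pooled conventions: the textbook forms
## computed from the observed table); trend components kept separately so
## that the joint MAX3 can be formed componentwise
stage_stats <- function(table) {
  trend <- vapply(.SCORES, function(x) catt_stat(table, x), numeric(1))
  list(ALLEJ = afdt_stat(table),
       CATAJ = trend[["ADD"]],
       MERTJ = mert_stat(table),
       trend = trend)
}

#' Joint analysis of one SNP's two-stage count data
#'
#' Computes, for each requested method, the stage-1 and stage-2
#' statistics, the joint statistic
#' `T_J = sqrt(pi) T1 + sqrt(1 - pi) T2` (for MAX3J formed componentwise:
#' `T_J^max = max(|T_J^R|, |T_J^A|, |T_J^D|)`), the stage-1 p-value, and
#' three joint p-values under explicitly labelled conventions:
#'
#' * `p_marginal`: the unconditional tail of the joint statistic,
#'   `2 (1 - pnorm(|t_J|))` for the normal-based methods and the MAX3
#'   null tail (via [max3_null_tail()], with correlations estimated from
#'   the combined pooled genotype counts) for MAX3J;
#' * `p_selection`: the selection-adjusted tail
#'   `Pr_H0(stage-1 statistic > its selection threshold at gamma,
#'   |T_J| > |t_J^obs|)`, by bivariate-normal integration for the
#'   normal-based methods and by conditional Monte Carlo
#'   ([conditional_stage1_sampler()], stage-specific pooled correlation
#'   estimates) for MAX3J;
#' * `p_obs_pair`: the one-sided tail at the observed pair,
#'   `Pr_H0(T1 > t1^obs, T_J > t_J^obs)` (both exceedances in the
#'   direction of the observed association), again exact for the
#'   normal-based methods and conditional Monte Carlo for MAX3J.
#'
#' `pi` is recomputed from the genotyped totals (missingness makes the
#' design value inexact) and `xi` per stage from that stage's counts; the
#' statistics are the pooled-variance forms.
#'
#' A SNP whose stage-1 p-value is at or above `gamma` would not have been
#' selected into stage 2; its joint p-values are still reported but
#' flagged unselected, and no significance claim is made.
#'
#' @param snp list with `stage1`, `stage2` ([genotype_table()]s) and
#'   optionally `pi` (defaults to the genotyped-total ratio).
#' @param gamma,alpha,m design parameters (per-SNP level `alpha / m`).
#' @param methods subset of `c("ALLEJ", "CATAJ", "MERTJ", "MAX3J")`.
#' @param B1 conditional draws for the MAX3J selection-adjusted p-value.
#' @param seed optional integer seed for the MAX3J Monte Carlo.
#' @return object of class `"joint_result"`: a data.frame with one row per
#'   method and columns `t1`, `t2`, `tJ`, `p_stage1`, `selected`,
#'   `p_marginal`, `p_selection`, `p_obs_pair`, `significant`.
#' @export
analyze_snp <- function(snp, gamma = 1e-4, alpha = 0.05, m = 5e5,
                        methods = c("ALLEJ", "CATAJ", "MERTJ", "MAX3J"),
                        B1 = 1e5, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  s1 <- snp$stage1; s2 <- snp$stage2
  n1 <- sum(s1$cases) + sum(s1$controls)
  n2 <- sum(s2$cases) + sum(s2$controls)
  pi <- if (!is.null(snp$pi)) snp$pi else n1 / (n1 + n2)
  st1 <- stage_stats(s1); st2 <- stage_stats(s2)
  trendJ <- joint_stat(st1$trend, st2$trend, pi)
  t1 <- c(ALLEJ = st1$ALLEJ, CATAJ = st1$CATAJ, MERTJ = st1$MERTJ,
          MAX3J = max(abs(st1$trend)))
  t2 <- c(ALLEJ = st2$ALLEJ, CATAJ = st2$CATAJ, MERTJ = st2$MERTJ,
          MAX3J = max(abs(st2$trend)))
  tJ <- c(joint_stat(t1[1:3], t2[1:3], pi), MAX3J = max(abs(trendJ)))
  g1 <- (s1$cases + s1$controls) / n1
  g2 <- (s2$cases + s2$controls) / n2
  gc <- (s1$cases + s1$controls + s2$cases + s2$controls) / (n1 + n2)
  corr1 <- null_correlations(g1)
  corr2 <- null_correlations(g2)
  corrc <- null_correlations(gc)
  b1 <- stage1_threshold(gamma)
  v1 <- max3_stage1_threshold(gamma, corr1)
  max3_joint_tail <- function(thr1, thrJ) {
    ## Pr(T1max > thr1, TJmax > thrJ) by conditional Monte Carlo
    cs <- conditional_stage1_sampler(B1, thr1, corr1)
    Z2 <- rbvn(B1, corr2$rho_RD)
    TJR <- sqrt(pi) * cs$draws[, 1] + sqrt(1 - pi) * Z2[, 1]
    TJD <- sqrt(pi) * cs$draws[, 2] + sqrt(1 - pi) * Z2[, 2]
    TJA <- sqrt(pi) * drop(cs$draws %*% corr1$omega) +
      sqrt(1 - pi) * drop(Z2 %*% corr2$omega)
    TJmax <- pmax(abs(TJR), abs(TJA), abs(TJD))
    cs$p_event * mean(TJmax > thrJ)
  }
  rows <- lapply(methods, function(mth) {
    if (mth == "MAX3J") {
      p1 <- max3_null_tail(t1[mth], corr1)
      pm <- max3_null_tail(abs(tJ[mth]), corrc)
      ps <- max3_joint_tail(v1, abs(tJ[mth]))
      po <- max3_joint_tail(t1[mth], abs(tJ[mth]))
      sel <- t1[mth] > v1
    } else {
      p1 <- 2 * stats::pnorm(-abs(t1[mth]))
      pm <- 2 * stats::pnorm(-abs(tJ[mth]))
      ps <- bvn_rect_exceed(b1, abs(tJ[mth]), sqrt(pi))
      po <- bvn_upper(abs(t1[mth]), abs(tJ[mth]), sqrt(pi))
      sel <- abs(t1[mth]) > b1
    }
    data.frame(method = mth, t1 = unname(t1[mth]), t2 = unname(t2[mth]),
               tJ = unname(tJ[mth]), p_stage1 = unname(p1),
               selected = unname(sel), p_marginal = unname(pm),
               p_selection = unname(ps), p_obs_pair = unname(po))
  })
  res <- do.call(rbind, rows)
  res$significant <- res$selected & res$p_selection < alpha / m
  attr(res, "pi") <- pi
  attr(res, "design") <- list(gamma = gamma, alpha = alpha, m = m)
  class(res) <- c("joint_result", "data.frame")
  res
}

#' @export
print.joint_result <- function(x, digits = 3, ...) {
  cat(sprintf("Two-stage joint analysis (pi = %.3f, gamma = %g, alpha/m = %.3g)\n",
              attr(x, "pi"), attr(x, "design")$gamma,
              attr(x, "design")$alpha / attr(x, "design")$m))
  y <- as.data.frame(x)
  y$t1 <- round(y$t1, digits); y$t2 <- round(y$t2, digits)
  y$tJ <- round(y$tJ, digits)
  y$p_stage1 <- signif(y$p_stage1, digits)
  y$p_marginal <- signif(y$p_marginal, digits)
  y$p_selection <- signif(y$p_selection, digits)
  y$p_obs_pair <- signif(y$p_obs_pair, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Analyze every SNP in a counts file
#'
#' Runs [analyze_snp()] on each SNP of a [read_counts_tsv()] result and
#' binds the per-method rows into one data.frame.
#'
#' @param snps named list from [read_counts_tsv()].
#' @inheritParams analyze_snp
#' @return data.frame with a leading `snp_id` column.
#' @export
analyze_counts <- function(snps, gamma = 1e-4, alpha = 0.05, m = 5e5,
                           methods = c("ALLEJ", "CATAJ", "MERTJ", "MAX3J"),
                           B1 = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(snps), function(id) {
    res <- analyze_snp(snps[[id]], gamma, alpha, m, methods, B1)
    cbind(snp_id = id, as.data.frame(res), pi = attr(res, "pi"))
  })
  do.call(rbind, out)
}
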