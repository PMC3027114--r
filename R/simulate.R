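#' Simulate a genotype count table for one stage
#'
#' Case and control genotype counts are drawn from independent multinomial
#' distributions over (gg, Gg, GG) with the population's conditional
#' genotype probabilities.
#'
#' @param pop a [genotype_probs()] result.
#' @param n_cases,n_controls arm sizes (non-negative integers).
#' @param seed optional integer seed; when given, the draw is reproducible.
#' @return A `"genotype_table"`: list with integer vectors `cases` and
#'   `controls` of length 3.
#' @export
simulate_table <- function(pop, n_cases, n_controls, seed = NULL) {
  stopifnot(inherits(pop, "genotype_population"),
            n_cases >= 0, n_controls >= 0)
  if (!is.null(seed)) set.seed(seed)
  ca <- if (n_cases > 0) drop(stats::rmultinom(1, n_cases, pop$case_probs)) else c(0L, 0L, 0L)
  co <- if (n_controls > 0) drop(stats::rmultinom(1, n_controls, pop$control_probs)) else c(0L, 0L, 0L)
  genotype_table(ca, co)
}

#' Construct a genotype count table
#'
#' A 2x3 table of genotype counts over (gg, Gg, GG) for one stage, with
#' cases in the first row and controls in the second. The risk allele G is
#' the second-listed allele; tables oriented the other way can be flipped
#' with `flip_table()`.
#'
#' @param cases,controls non-negative integer count vectors of length 3
#'   in (gg, Gg, GG) order.
#' @return object of class `"genotype_table"`.
#' @export
genotype_table <- function(cases, controls) {
  stopifnot(length(cases) == 3L, length(controls) == 3L,
            all(cases >= 0), all(controls >= 0),
            all(cases == round(cases)), all(controls == round(controls)))
  structure(list(cases = as.integer(cases), controls = as.integer(controls)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  m <- rbind(cases = x$cases, controls = x$controls)
  colnames(m) <- c("gg", "Gg", "GG")
  print(m)
  invisible(x)
}

#' Reverse the genotype orientation of a table
#'
#' Reorients a table whose risk allele is the first-listed allele, i.e.
#' maps counts (gg, Gg, GG) to (GG, Gg, gg) in both arms.
#'
#' @param table a [genotype_table()].
#' @export
flip_table <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  genotype_table(rev(table$cases), rev(table$controls))
}

#' Simulate a complete two-stage data set
#'
#' Draws two independent genotype tables from the same case/control
#' population, with stage-1 arm sizes `(round(pi r), round(pi s))` and the
#' remaining subjects in stage 2.
#'
#' @param model a [disease_model()].
#' @param design a [study_design()].
#' @param seed optional integer seed.
#' @return A `"two_stage_data"`: list with `stage1`, `stage2`
#'   (genotype tables) and `design`.
#' @export
simulate_two_stage <- function(model, design, seed = NULL) {
  stopifnot(inherits(model, "disease_model"), inherits(design, "study_design"))
  if (!is.null(seed)) set.seed(seed)
  pop <- genotype_probs(model)
  structure(list(stage1 = simulate_table(pop, design$r1, design$s1),
                 stage2 = simulate_table(pop, design$r2, design$s2),
                 design = design),
            class = "two_stage_data")
}

#' @export
print.two_stage_data <- function(x, ...) {
  cat("Stage 1:\n"); print(x$stage1)
  cat("Stage 2:\n"); print(x$stage2)
  invisible(x)
}

## Vectorized replicate simulation: n independent tables as an n x 3 count
## matrix per arm. Used by the power / FWER / calibration machinery, where
## statistics are evaluated on all replicates at once.
sim_count_matrix <- function(n, size, prob) {
  if (size == 0) return(matrix(0L, n, 3))
  t(stats::rmultinom(n, size, prob))
}

sim_two_stage_matrices <- function(pop, design, n_rep) {
  list(ca1 = sim_count_matrix(n_rep, design$r1, pop$case_probs),
       co1 = sim_count_matrix(n_rep, design$s1, pop$control_probs),
       ca2 = sim_count_matrix(n_rep, design$r2, pop$case_probs),
       co2 = sim_count_matrix(n_rep, design$s2, pop$control_probs))
}
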