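## Independent oracles used across the suite. These deliberately avoid the
## package's internal code paths: the trend-test oracle is the score-sum
## definition written out directly, and the rejection sampler is plain
## accept/reject.

## Cochran-Armitage trend statistic straight from the definition:
## sqrt(N) * sum x_i (s r_i - r s_i) / sqrt(r s (N sum x^2 n - (sum x n)^2))
brute_catt <- function(cases, controls, x) {
  r <- sum(cases); s <- sum(controls); N <- r + s
  n <- cases + controls
  num <- sqrt(N) * sum(x * (s * cases - r * controls))
  den <- sqrt(r * s * (N * sum(x^2 * n) - sum(x * n)^2))
  num / den
}

## naive rejection sampling of (T_R, T_D) | max3 > v under the null
naive_conditional <- function(n, v, rho, omega) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    z1 <- rnorm(5e4); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(5e4)
    keep <- pmax(abs(z1), abs(omega[1] * z1 + omega[2] * z2), abs(z2)) > v
    out <- rbind(out, cbind(z1, z2)[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

## random non-degenerate genotype table
random_table <- function(n_cases = 200, n_controls = 200) {
  repeat {
    p <- as.vector(rmultinom(1, 30, c(1, 1, 1))) + 1
    q <- as.vector(rmultinom(1, 30, c(1, 1, 1))) + 1
    ca <- as.vector(rmultinom(1, n_cases, p / sum(p)))
    co <- as.vector(rmultinom(1, n_controls, q / sum(q)))
    n <- ca + co
    if (sum(n > 0) >= 2 && all(colSums(rbind(ca, co)) >= 0)) {
      ## need variance under all three score sets
      g <- n / sum(n)
      ok <- all(vapply(list(c(0, 0, 1), c(0, 1, 2), c(0, 1, 1)),
                       function(x) sum(x^2 * g) - sum(x * g)^2 > 0,
                       logical(1)))
      if (ok) return(suppressWarnings(genotype_table(ca, co)))
    }
  }
}

table2_model <- function(row = c("recessive", "additive", "dominant")) {
  row <- match.arg(row)
  switch(row,
    recessive = disease_model(0.1, 0.15, 1, 2),
    additive = disease_model(0.1, 0.15, 1.4, 1.8),
    dominant = disease_model(0.1, 0.15, 1.5, 1.5))
}
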