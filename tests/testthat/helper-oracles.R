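# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written from the textbook formulas,
# not via the code paths they validate.

# Pearson chi-squared for an r x c table of counts.
oracle_pearson <- function(tab, corrected = FALSE) {
  tab <- as.matrix(tab)
  total <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / total
  dev <- abs(tab - expected)
  if (corrected) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Goodness of fit against the uniform distribution.
oracle_gof_uniform <- function(x) {
  expected <- rep(sum(x) / length(x), length(x))
  stat <- sum((x - expected)^2 / expected)
  df <- length(x) - 1
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Exact McNemar p-value by direct summation of the Binomial(b+c, 1/2)
# tail, doubled and capped at 1.
oracle_mcnemar_exact <- function(b, cc) {
  n <- b + cc
  if (n == 0) return(1)
  k <- min(b, cc)
  tail <- sum(choose(n, 0:k) * 0.5^n)
  min(1, 2 * tail)
}

# Plain scalar Euler integration of the noise-free two-site system,
# written independently of the package's integrator.
oracle_euler_endpoint <- function(params, drive_p, drive_np,
                                  dt = params$dt,
                                  n_steps = params$n_steps) {
  u_p <- params$h; u_np <- params$h
  for (s in seq_len(n_steps)) {
    sp <- 1 / (1 + exp(-params$beta * u_p))
    snp <- 1 / (1 + exp(-params$beta * u_np))
    new_p <- u_p + (dt / params$tau) *
      (-u_p + params$h - params$c_p * snp + drive_p)
    new_np <- u_np + (dt / params$tau) *
      (-u_np + params$h - params$c_np * sp + drive_np)
    u_p <- new_p; u_np <- new_np
  }
  c(u_p = u_p, u_np = u_np)
}

# Preferred-frame proportions from a cohort, as plain vectors.
cohort_prop <- function(cohort, cond, lab) {
  tr <- cohort$trials
  sel <- tr$selected[tr$condition == cond & tr$label == lab]
  mean(sel == "P")
}
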