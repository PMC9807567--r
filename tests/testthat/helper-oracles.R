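# Independent oracles used to cross-check the package's statistics. These are
# deliberately written as brute-force enumerations or independent model fits,
# never sharing code with the implementations they check.

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (no ties assumed)
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  u_obs <- u_of(a, b)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# exact two-sided Wilcoxon signed-rank p by enumerating all sign assignments
# (no zeros, no tied magnitudes assumed)
enumerate_signed_rank_p <- function(a, b) {
  d <- a - b
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  v_obs <- sum(r[d > 0])
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(1, p)
}

# ICC(A,1) via R's aov() two-way decomposition (independent of the package's
# definitional mean squares)
aov_icc_a1 <- function(x, y) {
  n <- length(x)
  k <- 2
  df <- data.frame(
    value = c(x, y),
    subject = factor(rep(seq_len(n), k)),
    rater = factor(rep(1:2, each = n))
  )
  ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# OLS via the normal equations, solved directly
normal_equations_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# partial correlation via residual regression
residual_partial_r <- function(x, y, z) {
  stats::cor(stats::resid(stats::lm(x ~ z)), stats::resid(stats::lm(y ~ z)))
}

# small noise-free cohort lying exactly on a model's equations
exact_cohort <- function(model, n = 40, seed = 99) {
  cfg <- generator_config(seed = seed, true_model = model,
                          residual_sd = setNames(rep(0, 5), enhv_rois()))
  generate_healthy_cohort(cfg, n = n, seed = seed)
}

# minimal well-formed cohort tibble for IO tests
tiny_cohort <- function() {
  tibble::tibble(
    subject_id = c("s1", "s2", "s3"),
    age = c(25, 40.5, 61),
    sex = c(1L, 0L, 1L),
    icv = c(1.60e6, 1.41e6, 1.52e6),
    whole_brainstem = c(26100.5, 23200.25, 25100),
    medulla = c(4800, 4500.125, 4700),
    pons = c(15000, 13500, 14800.75),
    midbrain = c(5800, 5300, 5600),
    cerebrum = c(1.05e6, 0.95e6, 1.01e6),
    group_label = c("healthy", "healthy", "dai")
  )
}
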