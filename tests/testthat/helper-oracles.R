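# Independent brute-force oracles and shared fixtures for the test suite.

# closed-form OLS slope, written from the sum-of-squares definition
ols_slope_oracle <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# exact permutation p-value for the Mann-Whitney U statistic: enumerate all
# assignments of the pooled values to the first group
mw_oracle_p <- function(x, y, alternative = "greater") {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  p_ge <- mean(u_all >= u_obs - eps)
  p_le <- mean(u_all <= u_obs + eps)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, 2 * min(p_ge, p_le))
  )
}

# measured potential ammonia oxidation rates and abundances, June-November
# 2019, as printed in the study's summary table (rate nmol l-1 d-1,
# abundance 1e4 copies ml-1)
table1 <- data.frame(
  date = as.Date(c("2019-06-18", "2019-07-29", "2019-08-28", "2019-11-05")),
  rate = c(5.67, 4.61, 6.06, 7.72),
  rate_se = c(0.38, 0.39, 0.37, 0.66),
  amoa = c(2.50e4, NA, NA, 3.81e4),
  amoa_sd = c(0.63e4, NA, NA, 1.55e4)
)

# noiseless incubation with a known slope (nmol l-1 d-1)
make_linear_incubation <- function(slope, times_h = c(0, 12, 24, 48),
                                   intercept = 0, replicate = "r1") {
  nox <- intercept + slope * times_h / 24
  tracer_incubation(time_h = times_h, no2_15n = nox / 2, no3_15n = nox / 2,
                    replicate = replicate)
}
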