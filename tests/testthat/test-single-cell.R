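test_that("atom fraction follows the isotope-ratio definition", {
  expect_equal(atom_fraction(37, 9963), 0.0037)
  expect_equal(atom_fraction(0, 100), 0)
  expect_equal(atom_fraction(100, 0), 1)
  expect_error(atom_fraction(0, 0), "positive")
  expect_error(atom_fraction(-1, 10), "non-negative")
})

test_that("growth rate is the linear tracer-uptake form", {
  mu <- growth_rate(N15_NATURAL + 0.0239, x_label = 0.993, t_days = 2)
  expect_equal(round(mu, 4), 0.0121)
  expect_equal(mu, 0.0239 / ((0.993 - N15_NATURAL) * 2))
  # no enrichment, no growth
  expect_equal(growth_rate(N15_NATURAL, 0.993, 2), 0)
  # doubling the incubation time halves the rate
  expect_equal(growth_rate(0.03, 0.993, 4), growth_rate(0.03, 0.993, 2) / 2)
  expect_error(growth_rate(0.01, x_label = 0.002, t_days = 1), "exceed")
  expect_error(growth_rate(0.01, 0.993, 0), "> 0")
})

test_that("cells below natural abundance get zero rate with a warning", {
  expect_warning(mu <- growth_rate(0.001, 0.993, 2), "below natural")
  expect_equal(mu, 0)
})

test_that("growth rate is invariant under affine rescaling of the excess", {
  # scaling both the measured excess and the label excess by k leaves mu fixed
  x_nat <- N15_NATURAL
  for (k in c(0.5, 2, 7)) {
    mu1 <- growth_rate(x_nat + 0.01, x_label = x_nat + 0.9, t_days = 2)
    mu2 <- growth_rate(x_nat + 0.01 * k, x_label = x_nat + 0.9 * k,
                       t_days = 2)
    expect_equal(mu1, mu2)
  }
})

test_that("compound-interest variant agrees at small excess, exceeds beyond", {
  mu_lin <- growth_rate(N15_NATURAL + 0.001, 0.993, 2)
  mu_cmp <- growth_rate(N15_NATURAL + 0.001, 0.993, 2, method = "compound")
  expect_equal(mu_lin, mu_cmp, tolerance = 0.01)
  big_lin <- growth_rate(0.5, 0.993, 2)
  big_cmp <- growth_rate(0.5, 0.993, 2, method = "compound")
  expect_gt(big_cmp, big_lin)
})

test_that("assimilation rate is growth times N quota", {
  expect_equal(assimilation_rate(0.012, 420), 5.04)
  expect_equal(assimilation_rate(0, 420), 0)
  # quota from carbon scales inversely with the C:N ratio
  q1 <- n_quota_from_carbon(46, 4)
  q2 <- n_quota_from_carbon(46, 8)
  expect_equal(q1, 2 * q2)
  expect_equal(n_quota_from_carbon(14, 1), 1000) # 14 fg N = 1 fmol = 1000 amol
})

test_that("rank-sum contrast matches hand-computable exact cases", {
  # complete separation at n1 = n2 = 4: one of choose(8,4) assignments as
  # extreme
  res <- enrichment_contrast(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(res$p.value, 1 / 70)
  expect_equal(unname(res$statistic), 16)
  # identical groups: central U, two-sided p of 1
  same <- enrichment_contrast(rep(1, 4), rep(1, 4),
                              alternative = "two.sided")
  expect_equal(unname(same$statistic), 8) # n1 n2 / 2 under full ties
  expect_equal(same$p.value, 1)
  expect_error(enrichment_contrast(numeric(0), 1), "non-empty")
})

test_that("exact enumeration agrees with the permutation oracle under ties", {
  set.seed(14)
  for (i in 1:40) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    # discrete support forces ties
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    for (alt in c("greater", "two.sided")) {
      expect_equal(enrichment_contrast(x, y, alternative = alt)$p.value,
                   mw_oracle_p(x, y, alternative = alt),
                   info = sprintf("case %d alt %s", i, alt))
    }
  }
})

test_that("exact path agrees with wilcox.test on tie-free samples", {
  set.seed(15)
  for (i in 1:20) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    x <- rnorm(n1)
    y <- rnorm(n2)
    ours <- enrichment_contrast(x, y, alternative = "greater")
    ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)
    expect_equal(ours$p.value, ref$p.value)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("normal approximation agrees with wilcox.test for large groups", {
  set.seed(16)
  x <- rnorm(40, 1)
  y <- rnorm(60)
  ours <- enrichment_contrast(x, y, alternative = "greater")
  ref <- wilcox.test(x, y, alternative = "greater", exact = FALSE,
                     correct = FALSE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("synthetic enrichment mixture is detected at the printed strength", {
  cells <- gen_single_cells(scenario_config(seed = 101))
  tgt <- cells$atom_fraction_15n[cells$population == "target"]
  nt <- cells$atom_fraction_15n[cells$population == "nontarget"]
  expect_length(tgt, 37)
  expect_length(nt, 105)
  expect_lt(enrichment_contrast(tgt, nt)$p.value, 0.005)
  # both groups at natural abundance: nothing to detect
  null_cells <- gen_single_cells(
    scenario_config(seed = 101, excess_mean = 1e-6, excess_sd = 1e-7))
  p0 <- enrichment_contrast(
    null_cells$atom_fraction_15n[null_cells$population == "target"],
    null_cells$atom_fraction_15n[null_cells$population == "nontarget"]
  )$p.value
  expect_gt(p0, 0.05)
})

test_that("geometry summary averages per-cell volumes, not mean dimensions", {
  one <- data.frame(roi_id = "a", population = "target",
                    atom_fraction_15n = 0.01,
                    length_um = 0.54, width_um = 0.39)
  s1 <- summarize_cell_geometry(one)
  expect_equal(round(uv_value(s1$mean_volume_um3), 4), 0.043)
  # two identical cells summarise to the single-cell values
  two <- rbind(one, one)
  s2 <- summarize_cell_geometry(two)
  expect_equal(uv_value(s2$mean_volume_um3), uv_value(s1$mean_volume_um3))
  expect_equal(uv_value(s2$mean_carbon_fg), uv_value(s1$mean_carbon_fg))
  expect_error(summarize_cell_geometry(
    data.frame(length_um = NA_real_, width_um = NA_real_)), "usable")
})

test_that("mean of volumes exceeds volume of mean dimensions (Jensen gap)", {
  cells <- gen_single_cells(scenario_config(seed = 8, n_target = 2000L,
                                            n_nontarget = 1L))
  tgt <- cells[cells$population == "target", ]
  s <- summarize_cell_geometry(tgt)
  v_of_means <- prolate_volume(uv_value(s$mean_width_um),
                               uv_value(s$mean_length_um))
  expect_gt(uv_value(s$mean_volume_um3), v_of_means)
  # at the observed dimension spread the gap lands near the printed 0.048
  expect_gt(uv_value(s$mean_volume_um3), 0.04)
  expect_lt(uv_value(s$mean_volume_um3), 0.06)
})

test_that("rates without dilution correction are conservative lower bounds", {
  # any positive dilution-correction factor can only increase the rates
  mu <- growth_rate(0.03, 0.993, 2)
  for (f in c(1.1, 1.5, 3)) {
    corrected_excess <- (0.03 - N15_NATURAL) * f
    mu_corr <- growth_rate(N15_NATURAL + corrected_excess, 0.993, 2)
    expect_gt(mu_corr, mu)
    expect_gt(assimilation_rate(mu_corr, 420), assimilation_rate(mu, 420))
  }
})
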