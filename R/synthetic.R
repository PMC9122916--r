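#' Scenario configuration for the synthetic-data generators
#'
#' Parameters of the simulated study system. Defaults emulate the observed
#' magnitudes of the hypolimnetic AOA system the pipeline targets: seasonal
#' *amoA* abundances cycling between a winter minimum of 9.8 × 10³ and a
#' summer maximum of 1.2 × 10⁵ copies ml⁻¹ with ~30% qPCR replicate CV,
#' tracer incubations producing ¹⁵NOₓ linearly at 6.0 nmol l⁻¹ d⁻¹ with
#' 0.3 nmol l⁻¹ Gaussian measurement noise, and a single-cell mixture of
#' 37 enriched target cells against 105 near-natural-abundance
#' non-target cells, with target cell dimensions 0.54 ± 0.11 µm (length) by
#' 0.39 ± 0.10 µm (width).
#'
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param winter_min_per_ml,summer_max_per_ml seasonal abundance extremes,
#'   copies ml⁻¹.
#' @param peak_doy day-of-year of the abundance maximum.
#' @param qpcr_cv coefficient of variation of qPCR replicate noise
#'   (lognormal, multiplicative).
#' @param n_qpcr_rep qPCR replicates per date.
#' @param tracer_slope_nmol_l_d true ¹⁵NOₓ production rate.
#' @param tracer_sigma_nmol_l Gaussian noise SD on each concentration.
#' @param tracer_times_h tracer subsampling times, hours.
#' @param n_tracer_rep incubation bottles per experiment.
#' @param n_target,n_nontarget single-cell group sizes.
#' @param excess_mean,excess_sd ¹⁵N atom-fraction excess of target cells
#'   (truncated normal above 0). The default mean 0.0239 corresponds to a
#'   growth rate of 0.012 d⁻¹ over a 2-day incubation at 99.3% labeling.
#' @param background_sd atom-fraction jitter of non-target cells around
#'   natural abundance.
#' @param length_mean_um,length_sd_um,width_mean_um,width_sd_um cell
#'   dimension distribution (truncated normal, > 0.05 µm).
#' @param total_ion_counts total ¹²C¹⁴N⁻ + ¹²C¹⁵N⁻ counts per ROI used to
#'   discretise atom fractions into counts.
#' @param t_days,x_label incubation length and label atom fraction for the
#'   single-cell experiment.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            winter_min_per_ml = 9.8e3,
                            summer_max_per_ml = 1.2e5,
                            peak_doy = 200,
                            qpcr_cv = 0.30,
                            n_qpcr_rep = 3L,
                            tracer_slope_nmol_l_d = 6.0,
                            tracer_sigma_nmol_l = 0.3,
                            tracer_times_h = c(0, 12, 24, 48),
                            n_tracer_rep = 3L,
                            n_target = 37L,
                            n_nontarget = 105L,
                            excess_mean = 0.0239,
                            excess_sd = 0.0119,
                            background_sd = 2e-4,
                            length_mean_um = 0.54,
                            length_sd_um = 0.11,
                            width_mean_um = 0.39,
                            width_sd_um = 0.10,
                            total_ion_counts = 2e5,
                            t_days = 2,
                            x_label = 0.993) {
  cfg <- as.list(environment())
  scales <- c("winter_min_per_ml", "summer_max_per_ml", "qpcr_cv",
              "tracer_slope_nmol_l_d", "n_target", "n_nontarget",
              "excess_mean", "excess_sd", "length_mean_um", "width_mean_um",
              "total_ion_counts", "t_days", "x_label")
  bad <- scales[!vapply(cfg[scales], function(x) all(x > 0), logical(1))]
  if (length(bad)) {
    stop("scenario scales must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$winter_min_per_ml >= cfg$summer_max_per_ml) {
    stop("winter minimum must be below summer maximum", call. = FALSE)
  }
  class(cfg) <- "scenario_config"
  cfg
}

# run code with a local RNG stream without disturbing the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

rtruncnorm_pos <- function(n, mean, sd, lower = 0) {
  out <- stats::rnorm(n, mean, sd)
  while (any(out <= lower)) {
    k <- out <= lower
    out[k] <- stats::rnorm(sum(k), mean, sd)
  }
  out
}

#' Simulate a seasonal qPCR abundance series
#'
#' Abundance follows an annual sinusoid between the configured winter
#' minimum and summer maximum (peak at `peak_doy`), observed with
#' multiplicative lognormal qPCR noise: each date gets `n_qpcr_rep`
#' replicate draws whose mean and SD form the reported determination.
#'
#' @param cfg a [scenario_config].
#' @param dates >= 2 calendar dates (strictly increasing).
#' @return An [abundance_series]; `total_16s_per_ml` is filled in so that
#'   the relative abundance moves between ~8% (winter) and ~39% (summer).
#' @examples
#' gen_abundance_series(scenario_config(seed = 42),
#'                      seq(as.Date("2018-01-01"), by = "month", length = 12))
#' @export
gen_abundance_series <- function(cfg, dates) {
  stopifnot(inherits(cfg, "scenario_config"))
  dates <- as.Date(dates)
  if (length(dates) < 2L) stop("need >= 2 dates", call. = FALSE)
  mid <- (cfg$winter_min_per_ml + cfg$summer_max_per_ml) / 2
  amp <- (cfg$summer_max_per_ml - cfg$winter_min_per_ml) / 2
  doy <- as.numeric(format(dates, "%j"))
  truth <- mid + amp * cos(2 * pi * (doy - cfg$peak_doy) / 365)
  # total 16S held constant at the level putting the summer maximum near 39%
  total_16s <- cfg$summer_max_per_ml / 0.389
  with_seed(cfg$seed, {
    sdlog <- sqrt(log(1 + cfg$qpcr_cv^2))
    reps <- matrix(
      truth * stats::rlnorm(length(truth) * cfg$n_qpcr_rep,
                            meanlog = -sdlog^2 / 2, sdlog = sdlog),
      nrow = length(truth)
    )
    abundance_series(
      date = dates,
      copies_per_ml = rowMeans(reps),
      sd = apply(reps, 1, stats::sd),
      total_16s_per_ml = total_16s
    )
  })
}

#' Simulate a replicated tracer incubation experiment
#'
#' Each bottle's ¹⁵NOₓ grows linearly at the configured true rate, with
#' i.i.d. Gaussian measurement noise added to every concentration and
#' negative values clipped to zero. The label appears in nitrite and
#' nitrate in a fixed 2:1 split (the split is irrelevant downstream, where
#' only the sum is used).
#'
#' @param cfg a [scenario_config].
#' @return A list of `n_tracer_rep` [tracer_incubation] objects.
#' @examples
#' incs <- gen_tracer_incubation(scenario_config(seed = 7))
#' replicate_rate(incs)
#' @export
gen_tracer_incubation <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  t_d <- cfg$tracer_times_h / 24
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_tracer_rep), function(i) {
      nox <- pmax(
        cfg$tracer_slope_nmol_l_d * t_d +
          stats::rnorm(length(t_d), 0, cfg$tracer_sigma_nmol_l),
        0
      )
      tracer_incubation(
        time_h = cfg$tracer_times_h,
        no2_15n = nox * 2 / 3,
        no3_15n = nox / 3,
        replicate = paste0("r", i)
      )
    })
  })
}

#' Simulate a single-cell nanoSIMS measurement table
#'
#' Draws a two-population ¹⁵N enrichment mixture: target cells with a
#' truncated-normal atom-fraction excess above natural abundance, and
#' non-target cells jittered narrowly around natural abundance. Atom
#' fractions are discretised into ¹²C¹⁵N⁻ / ¹²C¹⁴N⁻ counts at the
#' configured total ion counts per ROI; target cells also receive
#' truncated-normal dimensions.
#'
#' @param cfg a [scenario_config].
#' @return A [cell_measurements] table with `n_target + n_nontarget` rows.
#' @examples
#' cells <- gen_single_cells(scenario_config(seed = 3))
#' table(cells$population)
#' @export
gen_single_cells <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(cfg$seed, {
    excess <- rtruncnorm_pos(cfg$n_target, cfg$excess_mean, cfg$excess_sd)
    frac_t <- N15_NATURAL + excess
    frac_nt <- pmax(
      N15_NATURAL + stats::rnorm(cfg$n_nontarget, 0, cfg$background_sd),
      0
    )
    frac <- c(frac_t, frac_nt)
    c15 <- round(frac * cfg$total_ion_counts)
    len <- rtruncnorm_pos(cfg$n_target + cfg$n_nontarget,
                          cfg$length_mean_um, cfg$length_sd_um,
                          lower = 0.05)
    wid <- rtruncnorm_pos(cfg$n_target + cfg$n_nontarget,
                          cfg$width_mean_um, cfg$width_sd_um,
                          lower = 0.05)
    cell_measurements(data.frame(
      roi_id = sprintf("roi%03d", seq_along(frac)),
      population = rep(c("target", "nontarget"),
                       c(cfg$n_target, cfg$n_nontarget)),
      c15n_counts = c15,
      c14n_counts = cfg$total_ion_counts - c15,
      length_um = len,
      width_um = wid
    ))
  })
}
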