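#' qPCR abundance time series
#'
#' A dated series of marker-gene copy numbers (archaeal *amoA*, copies
#' ml⁻¹, here read as cells ml⁻¹ via the single-copy assumption), with the
#' replicate spread of each determination and optionally the total archaeal
#' + bacterial 16S rRNA gene copies for relative-abundance estimates.
#'
#' @param date calendar dates (`Date` or ISO-8601 strings), strictly
#'   increasing.
#' @param copies_per_ml *amoA* copies ml⁻¹, >= 0.
#' @param sd replicate standard deviation of `copies_per_ml` (optional).
#' @param total_16s_per_ml total 16S copies ml⁻¹ (optional).
#' @return A data frame of class `abundance_series`.
#' @examples
#' abundance_series(c("2019-01-01", "2019-07-01"), c(1e4, 1e5))
#' @export
abundance_series <- function(date, copies_per_ml, sd = NA_real_,
                             total_16s_per_ml = NA_real_) {
  date <- as.Date(date)
  if (anyNA(date)) stop("dates must parse as ISO-8601", call. = FALSE)
  if (is.unsorted(as.numeric(date), strictly = TRUE)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  copies_per_ml <- as.numeric(copies_per_ml)
  if (any(!is.finite(copies_per_ml)) || any(copies_per_ml < 0)) {
    stop("abundances must be finite and non-negative", call. = FALSE)
  }
  out <- data.frame(
    date = date,
    copies_per_ml = copies_per_ml,
    sd = rep_len(as.numeric(sd), length(date)),
    total_16s_per_ml = rep_len(as.numeric(total_16s_per_ml), length(date))
  )
  class(out) <- c("abundance_series", "data.frame")
  out
}

#' Lake and conversion constants for ecosystem budgets
#'
#' Bundles the physical and stoichiometric constants used to scale
#' volumetric rates and stocks to the whole-ecosystem level. Defaults
#' describe the hypolimnion of a large, deep, oligotrophic peri-alpine
#' lake (Upper Lake Constance).
#'
#' @param hypolimnion_km3 hypolimnion volume, km³.
#' @param hypolimnion_depth_m vertical extent of the hypolimnion, m.
#' @param surface_km2 lake surface area, km².
#' @param productivity_gc_m2_y annual primary productivity, g C m⁻² y⁻¹.
#' @param c_chla_ratio phytoplankton C : chlorophyll-a mass ratio.
#' @param redfield_c,redfield_n Redfield C:N molar ratio (106:16).
#' @param n_input_g_y annual external dissolved-N input, g N y⁻¹.
#' @param nitrate_pool_input_g_y annual N input to the nitrate pool,
#'   g N y⁻¹.
#' @return A list of class `lake_config`.
#' @examples
#' lake_config()
#' @export
lake_config <- function(hypolimnion_km3 = 38.1,
                        hypolimnion_depth_m = 120,
                        surface_km2 = 473,
                        productivity_gc_m2_y = 220,
                        c_chla_ratio = 31.5,
                        redfield_c = 106,
                        redfield_n = 16,
                        n_input_g_y = 13.7e9,
                        nitrate_pool_input_g_y = 42.8e9) {
  cfg <- list(
    hypolimnion_km3 = hypolimnion_km3,
    hypolimnion_depth_m = hypolimnion_depth_m,
    surface_km2 = surface_km2,
    productivity_gc_m2_y = productivity_gc_m2_y,
    c_chla_ratio = c_chla_ratio,
    redfield_c = redfield_c,
    redfield_n = redfield_n,
    n_input_g_y = n_input_g_y,
    nitrate_pool_input_g_y = nitrate_pool_input_g_y
  )
  bad <- names(cfg)[!vapply(cfg, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("lake constants must be positive scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(cfg) <- "lake_config"
  cfg
}

#' @export
print.lake_config <- function(x, ...) {
  cat("<lake_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %g\n", k, x[[k]]))
  invisible(x)
}

#' Time-weighted mean abundance of a series
#'
#' Trapezoidal time average: adjacent abundances are averaged over each
#' interval, weighted by the interval length in days, and normalised by the
#' series span. Exact for piecewise-linear abundance dynamics.
#'
#' @param series an [abundance_series] spanning >= 2 dates.
#' @return Mean abundance in copies ml⁻¹.
#' @export
time_weighted_abundance <- function(series) {
  stopifnot(inherits(series, "abundance_series"))
  if (nrow(series) < 2L) {
    stop("time integration needs at least 2 dates", call. = FALSE)
  }
  t <- as.numeric(series$date)
  a <- series$copies_per_ml
  dt <- diff(t)
  sum((a[-1] + a[-length(a)]) / 2 * dt) / sum(dt)
}

#' Annual volumetric ammonia oxidation rate of a population
#'
#' Scales a mean cell-specific rate by the population's abundance
#' integrated over its seasonal cycle: the trapezoidal time-weighted mean
#' abundance (copies ml⁻¹) times the cell-specific rate (fmol cell⁻¹ d⁻¹)
#' gives a mean volumetric rate (×10⁻³ nmol l⁻¹ d⁻¹), which
#' [convert_rate_units()] expresses as an annual areal-free flux in
#' mg N m⁻³ y⁻¹. For a constant abundance A the result is the closed form
#' r_cell × A × 365 d (in mass units).
#'
#' @param series an [abundance_series] spanning >= 2 dates.
#' @param r_cell_fmol_d cell-specific rate, fmol cell⁻¹ d⁻¹ ([uv] or
#'   numeric), >= 0.
#' @return Annual volumetric rate in mg N m⁻³ y⁻¹ (a [uv] if `r_cell_fmol_d`
#'   is one).
#' @examples
#' s <- abundance_series(c("2018-01-01", "2019-01-01"), c(4.3e4, 4.3e4))
#' annual_rate(s, 0.21) # ~46 mg N m-3 y-1
#' @export
annual_rate <- function(series, r_cell_fmol_d) {
  if (any(uv_value(r_cell_fmol_d) < 0)) {
    stop("cell-specific rate must be non-negative", call. = FALSE)
  }
  a_bar <- time_weighted_abundance(series)
  rate_nmol_l_d <- as_uv(r_cell_fmol_d) * a_bar * 1e-3
  out <- convert_rate_units(rate_nmol_l_d, to = "mg_n_m3_y")
  if (is_uv(r_cell_fmol_d)) out else uv_value(out)
}

#' Whole-lake annual nitrogen flux
#'
#' Scales a volumetric annual rate over the hypolimnion volume:
#' mg N m⁻³ y⁻¹ × km³ (10⁹ m³) × 10⁻³ g/mg = g N y⁻¹; metric tons are
#' g / 10⁶.
#'
#' @param volumetric_rate_mg_m3_y annual volumetric rate, mg N m⁻³ y⁻¹
#'   ([uv] or numeric), >= 0.
#' @param config a [lake_config].
#' @return A list with `g_n_per_y` and `tons_n_per_y` (each [uv] if the
#'   input is one).
#' @examples
#' lake_total(46.1, lake_config()) # ~1.76e9 g N / ~1760 t
#' @export
lake_total <- function(volumetric_rate_mg_m3_y, config = lake_config()) {
  stopifnot(inherits(config, "lake_config"))
  if (any(uv_value(volumetric_rate_mg_m3_y) < 0)) {
    stop("rate must be non-negative", call. = FALSE)
  }
  g <- as_uv(volumetric_rate_mg_m3_y) * (config$hypolimnion_km3 * 1e9 * 1e-3)
  if (!is_uv(volumetric_rate_mg_m3_y)) g <- uv_value(g)
  list(g_n_per_y = g, tons_n_per_y = g / 1e6)
}

#' Annual phytoplankton nitrogen production
#'
#' Converts annual primary production (g C m⁻² y⁻¹ over the lake surface)
#' to nitrogen through the Redfield C:N ratio. By default the 106:16 ratio
#' is applied directly as a mass ratio (the convention in use for this
#' budget); `mode = "molar"` applies it as a molar ratio with the 12 and 14
#' g mol⁻¹ molar masses, giving ~17% more nitrogen.
#'
#' @param config a [lake_config].
#' @param mode `"mass"` or `"molar"` application of the Redfield ratio.
#' @return Annual phytoplankton N production, g N y⁻¹.
#' @examples
#' phytoplankton_nitrogen(lake_config()) # ~1.57e10 g N
#' @export
phytoplankton_nitrogen <- function(config = lake_config(),
                                   mode = c("mass", "molar")) {
  stopifnot(inherits(config, "lake_config"))
  mode <- match.arg(mode)
  c_total <- config$productivity_gc_m2_y * config$surface_km2 * 1e6
  ratio <- switch(mode,
    mass = config$redfield_n / config$redfield_c,
    molar = config$redfield_n * 14 / (config$redfield_c * 12)
  )
  c_total * ratio
}

#' Nitrogen-budget shares of a population flux
#'
#' Expresses an annual population N flux as a percentage of (i) the annual
#' phytoplankton N production and (ii) the annual N input to the lake's
#' nitrate pool.
#'
#' @param aoa_n_g_y population flux, g N y⁻¹, >= 0.
#' @param config a [lake_config].
#' @param phyto_n_g_y denominator for the biomass share; defaults to
#'   [phytoplankton_nitrogen()] of `config`.
#' @param digits presentation rounding of the percentages; `NULL` for
#'   unrounded.
#' @return A list with `pct_phytoplankton_n` and `pct_nitrate_pool`.
#' @examples
#' budget_fractions(1.76e9) # ~11% and ~4%
#' @export
budget_fractions <- function(aoa_n_g_y, config = lake_config(),
                             phyto_n_g_y = phytoplankton_nitrogen(config),
                             digits = 0) {
  if (any(uv_value(aoa_n_g_y) < 0)) {
    stop("flux must be non-negative", call. = FALSE)
  }
  if (phyto_n_g_y <= 0 || config$nitrate_pool_input_g_y <= 0) {
    stop("budget denominators must be positive", call. = FALSE)
  }
  p1 <- 100 * uv_value(aoa_n_g_y) / phyto_n_g_y
  p2 <- 100 * uv_value(aoa_n_g_y) / config$nitrate_pool_input_g_y
  if (!is.null(digits)) {
    p1 <- round(p1, digits)
    p2 <- round(p2, digits)
  }
  list(pct_phytoplankton_n = p1, pct_nitrate_pool = p2)
}

#' Depth-integrated phytoplankton carbon from a chlorophyll profile
#'
#' Trapezoidal depth integration of a chlorophyll-a profile converted to
#' carbon with a C:Chl-a mass ratio (default 31.5). Optionally compares the
#' water-column AOA carbon stock (volumetric stock × hypolimnion depth
#' extent) to the phytoplankton stock.
#'
#' @param depth_m profile depths, m, strictly increasing, >= 2 points.
#' @param chl_mg_m3 chlorophyll-a at each depth, mg m⁻³, >= 0.
#' @param config a [lake_config].
#' @param aoa_mg_c_m3 optional volumetric AOA carbon, mg C m⁻³, for the
#'   stock comparison.
#' @return A list with `phyto_mg_c_m2` and, when `aoa_mg_c_m3` is given,
#'   `aoa_mg_c_m2` and `aoa_pct_of_phyto`.
#' @examples
#' phytoplankton_carbon(c(0, 10), c(1, 1)) # 315 mg C m-2
#' @export
phytoplankton_carbon <- function(depth_m, chl_mg_m3,
                                 config = lake_config(),
                                 aoa_mg_c_m3 = NULL) {
  stopifnot(inherits(config, "lake_config"))
  depth_m <- as.numeric(depth_m)
  chl_mg_m3 <- as.numeric(chl_mg_m3)
  if (length(depth_m) < 2L || length(chl_mg_m3) != length(depth_m)) {
    stop("profile needs >= 2 matched depth/chlorophyll points",
         call. = FALSE)
  }
  if (is.unsorted(depth_m, strictly = TRUE)) {
    stop("depths must be strictly increasing", call. = FALSE)
  }
  if (any(chl_mg_m3 < 0)) stop("chlorophyll must be >= 0", call. = FALSE)
  dz <- diff(depth_m)
  chl_m2 <- sum((chl_mg_m3[-1] + chl_mg_m3[-length(chl_mg_m3)]) / 2 * dz)
  phyto <- chl_m2 * config$c_chla_ratio
  out <- list(phyto_mg_c_m2 = phyto)
  if (!is.null(aoa_mg_c_m3)) {
    if (phyto <= 0) {
      stop("phytoplankton stock is zero; carbon ratio undefined",
           call. = FALSE)
    }
    aoa_m2 <- uv_value(aoa_mg_c_m3) * config$hypolimnion_depth_m
    out$aoa_mg_c_m2 <- aoa_m2
    out$aoa_pct_of_phyto <- 100 * aoa_m2 / phyto
  }
  out
}

#' Relative abundance of a marker population
#'
#' Percentage of the total picoplankton (16S rRNA gene copies) represented
#' by a marker-gene population, with relative-quadrature uncertainty when
#' either count carries one.
#'
#' @param amoa_per_ml marker copies ml⁻¹ ([uv] or numeric), >= 0.
#' @param total_16s_per_ml total 16S copies ml⁻¹ ([uv] or numeric), > 0.
#' @return Relative abundance in percent ([uv] if either input is one).
#' @examples
#' relative_abundance(8, 100) # 8%
#' @export
relative_abundance <- function(amoa_per_ml, total_16s_per_ml) {
  if (any(uv_value(total_16s_per_ml) <= 0)) {
    stop("total 16S copies must be > 0", call. = FALSE)
  }
  if (any(uv_value(amoa_per_ml) < 0)) {
    stop("marker copies must be >= 0", call. = FALSE)
  }
  out <- as_uv(amoa_per_ml) / as_uv(total_16s_per_ml) * 100
  if (is_uv(amoa_per_ml) || is_uv(total_16s_per_ml)) out else uv_value(out)
}
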