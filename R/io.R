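#' Read and write the pipeline's CSV dialects
#'
#' Plain-CSV readers and writers for the three input tables the pipeline
#' consumes. Column names carry units so files are self-describing:
#'
#' * tracer: `replicate, time_h, no2_15n_nmol_l, no3_15n_nmol_l`
#' * abundance: `date, copies_per_ml, sd` (optional `total_16s_per_ml`)
#' * cells: `roi_id, population, c14n_counts, c15n_counts` (or
#'   `atom_fraction_15n`), optional `length_um, width_um`
#' * chlorophyll: `depth_m, chl_mg_m3`
#'
#' @param path file path.
#' @param added_15n_umol_l,insitu_nh4_umol_l label metadata attached to
#'   each incubation read from a tracer file.
#' @return `read_tracer_csv()`: a named list of [tracer_incubation] (one
#'   per replicate); `read_abundance_csv()`: an [abundance_series];
#'   `read_cells_csv()`: a [cell_measurements]; `read_chl_csv()`: a data
#'   frame with `depth_m`, `chl_mg_m3`.
#' @name pipeline_io
NULL

check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s (line 1)", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' @rdname pipeline_io
#' @export
read_tracer_csv <- function(path, added_15n_umol_l = 10,
                            insitu_nh4_umol_l = 0.07) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("replicate", "time_h", "no2_15n_nmol_l",
                      "no3_15n_nmol_l"), path)
  if (nrow(df) == 0L) stop(path, ": no data rows", call. = FALSE)
  split_df <- split(df, df$replicate)
  out <- lapply(names(split_df), function(r) {
    d <- split_df[[r]]
    d <- d[order(d$time_h), ]
    tracer_incubation(
      time_h = d$time_h,
      no2_15n = d$no2_15n_nmol_l,
      no3_15n = d$no3_15n_nmol_l,
      replicate = r,
      added_15n_umol_l = added_15n_umol_l,
      insitu_nh4_umol_l = insitu_nh4_umol_l
    )
  })
  names(out) <- names(split_df)
  out
}

#' @rdname pipeline_io
#' @param incs named list of [tracer_incubation] to write.
#' @export
write_tracer_csv <- function(incs, path) {
  rows <- do.call(rbind, lapply(incs, function(inc) {
    data.frame(
      replicate = attr(inc, "replicate"),
      time_h = inc$time_d * 24,
      no2_15n_nmol_l = inc$no2_15n,
      no3_15n_nmol_l = inc$no3_15n
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_abundance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("date", "copies_per_ml"), path)
  abundance_series(
    date = df$date,
    copies_per_ml = df$copies_per_ml,
    sd = if ("sd" %in% names(df)) df$sd else NA_real_,
    total_16s_per_ml = if ("total_16s_per_ml" %in% names(df)) {
      df$total_16s_per_ml
    } else {
      NA_real_
    }
  )
}

#' @rdname pipeline_io
#' @param series an [abundance_series] to write.
#' @export
write_abundance_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_cells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cell_measurements(df)
}

#' @rdname pipeline_io
#' @param cells a [cell_measurements] table to write.
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_chl_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("depth_m", "chl_mg_m3"), path)
  df
}

#' Read a pipeline configuration file
#'
#' YAML configuration with incubation metadata at the top level
#' (`added_15n_umol_l`, `insitu_nh4_umol_l`, `t_days`, `x_label`,
#' `n_quota_amol`) and a `lake:` section holding [lake_config()] overrides.
#' Missing keys fall back to the package defaults.
#'
#' @param path path to a YAML file, or `NULL` for all-default settings.
#' @return A list with elements `added_15n_umol_l`, `insitu_nh4_umol_l`,
#'   `t_days`, `x_label`, `n_quota_amol` and `lake` (a [lake_config]).
#' @export
read_pipeline_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(
    added_15n_umol_l = 10,
    insitu_nh4_umol_l = 0.07,
    t_days = 2,
    x_label = 0.993,
    n_quota_amol = 420
  )
  for (k in names(defaults)) {
    if (is.null(raw[[k]])) raw[[k]] <- defaults[[k]]
  }
  lake_args <- raw$lake
  known <- names(formals(lake_config))
  if (!is.null(lake_args)) {
    unknown <- setdiff(names(lake_args), known)
    if (length(unknown)) {
      stop("unknown lake config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  raw$lake <- do.call(lake_config, as.list(lake_args))
  raw
}

check_overwrite <- function(path, force) {
  if (file.exists(path) && !force) {
    stop(path, " exists; use force = TRUE to overwrite", call. = FALSE)
  }
  invisible(path)
}

#' Run the pipeline stages on files
#'
#' File-in/file-out drivers behind the `aoaflux` command-line interface;
#' each is also directly usable from R and returns its result invisibly.
#' Existing outputs are never overwritten unless `force = TRUE`.
#'
#' * `run_simulate()` writes synthetic tracer, abundance and single-cell
#'   CSVs for a [scenario_config()] scenario.
#' * `run_rates()` fits [potential_rate()] per replicate in a tracer CSV
#'   and writes one row per replicate plus a pooled row.
#' * `run_cells()` summarises a single-cell CSV: enrichment contrast,
#'   mean growth and assimilation rates of the target population, and
#'   geometry/carbon summaries.
#' * `run_budget()` combines a rates CSV and an abundance CSV into the
#'   population and ecosystem budget (cell-specific rate, standing stocks,
#'   annual volumetric rate, whole-lake flux, budget shares).
#' * `run_report()` runs rates + budget and writes a human-readable text
#'   report next to the budget CSV.
#'
#' @param out_dir,out output directory or file.
#' @param cfg a [scenario_config] (for `run_simulate`).
#' @param dates dates of the simulated abundance series.
#' @param tracer_csv,abundance_csv,cells_csv,rates_csv input files.
#' @param config a list from [read_pipeline_config()] (or `NULL` for
#'   defaults).
#' @param force overwrite existing outputs?
#' @name pipeline_run
NULL

#' @rdname pipeline_run
#' @export
run_simulate <- function(out_dir, cfg = scenario_config(),
                         dates = seq(as.Date("2018-01-01"),
                                     as.Date("2019-12-01"), by = "month"),
                         force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir,
                     c("tracer.csv", "abundance.csv", "cells.csv"))
  lapply(paths, check_overwrite, force = force)
  write_tracer_csv(gen_tracer_incubation(cfg), paths[1])
  write_abundance_csv(gen_abundance_series(cfg, dates), paths[2])
  write_cells_csv(gen_single_cells(cfg), paths[3])
  message("wrote ", paste(basename(paths), collapse = ", "), " to ", out_dir)
  invisible(paths)
}

#' @rdname pipeline_run
#' @export
run_rates <- function(tracer_csv, out, config = NULL, force = FALSE) {
  config <- if (is.list(config) && !is.null(config$lake)) {
    config
  } else {
    read_pipeline_config(config)
  }
  check_overwrite(out, force)
  incs <- read_tracer_csv(tracer_csv,
                          added_15n_umol_l = config$added_15n_umol_l,
                          insitu_nh4_umol_l = config$insitu_nh4_umol_l)
  fits <- lapply(incs, potential_rate)
  pooled <- replicate_rate(fits)
  per_rep <- data.frame(
    replicate = vapply(fits, `[[`, character(1), "replicate"),
    rate_nmol_per_l_per_d = vapply(fits, `[[`, numeric(1), "slope"),
    se_nmol_per_l_per_d = vapply(fits, `[[`, numeric(1), "se"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    p_one_tailed = vapply(fits, `[[`, numeric(1), "p_value"),
    significant = vapply(fits, `[[`, logical(1), "significant")
  )
  pooled_row <- data.frame(
    replicate = "pooled",
    rate_nmol_per_l_per_d = uv_value(pooled),
    se_nmol_per_l_per_d = uv_sd(pooled),
    r_squared = NA_real_,
    p_one_tailed = NA_real_,
    significant = !attr(pooled, "below_detection")
  )
  res <- rbind(per_rep, pooled_row)
  utils::write.csv(res, out, row.names = FALSE)
  message("rates written to ", out)
  invisible(res)
}

#' @rdname pipeline_run
#' @export
run_cells <- function(cells_csv, out, config = NULL, force = FALSE) {
  config <- if (is.list(config) && !is.null(config$lake)) {
    config
  } else {
    read_pipeline_config(config)
  }
  check_overwrite(out, force)
  cells <- read_cells_csv(cells_csv)
  tgt <- cells[cells$population == "target", ]
  nt <- cells[cells$population == "nontarget", ]
  ct <- enrichment_contrast(tgt$atom_fraction_15n, nt$atom_fraction_15n)
  mu <- growth_rate(tgt$atom_fraction_15n, x_label = config$x_label,
                    t_days = config$t_days)
  assim <- assimilation_rate(mu, config$n_quota_amol)
  geom <- if (all(c("length_um", "width_um") %in% names(tgt))) {
    summarize_cell_geometry(tgt)
  } else {
    NULL
  }
  res <- data.frame(
    quantity = c("n_target", "n_nontarget", "mann_whitney_u",
                 "p_one_tailed_target_greater",
                 "mean_growth_rate_per_d", "sd_growth_rate_per_d",
                 "mean_assimilation_amol_per_cell_per_d",
                 "sd_assimilation_amol_per_cell_per_d",
                 if (!is.null(geom)) c("mean_length_um", "mean_width_um",
                                       "mean_volume_um3", "mean_carbon_fg")),
    value = c(nrow(tgt), nrow(nt), unname(ct$statistic), ct$p.value,
              mean(mu), stats::sd(mu), mean(assim), stats::sd(assim),
              if (!is.null(geom)) c(uv_value(geom$mean_length_um),
                                    uv_value(geom$mean_width_um),
                                    uv_value(geom$mean_volume_um3),
                                    uv_value(geom$mean_carbon_fg)))
  )
  utils::write.csv(res, out, row.names = FALSE)
  message("single-cell summary written to ", out)
  invisible(res)
}

#' @rdname pipeline_run
#' @param m_carbon_fg per-cell carbon used for standing stocks; the default
#'   applies the allometry to the mean target-cell dimensions.
#' @export
run_budget <- function(rates_csv, abundance_csv, out, config = NULL,
                       m_carbon_fg = carbon_content(prolate_volume(0.39, 0.54)),
                       force = FALSE) {
  config <- if (is.list(config) && !is.null(config$lake)) {
    config
  } else {
    read_pipeline_config(config)
  }
  check_overwrite(out, force)
  rates <- utils::read.csv(rates_csv, stringsAsFactors = FALSE)
  check_columns(rates, c("replicate", "rate_nmol_per_l_per_d",
                         "se_nmol_per_l_per_d"), rates_csv)
  pooled <- rates[rates$replicate == "pooled", ]
  r_pot <- if (nrow(pooled) == 1L) {
    uv(pooled$rate_nmol_per_l_per_d, pooled$se_nmol_per_l_per_d)
  } else {
    uv_mean(uv(rates$rate_nmol_per_l_per_d, rates$se_nmol_per_l_per_d),
            method = "sample")
  }
  series <- read_abundance_csv(abundance_csv)
  a_mean <- uv(time_weighted_abundance(series),
               stats::sd(series$copies_per_ml))
  r_cell <- cell_specific_rate(r_pot, a_mean)
  vol_c <- volumetric_carbon(m_carbon_fg, uv_value(a_mean))
  vol_c_range <- volumetric_carbon(
    m_carbon_fg, range(series$copies_per_ml))
  r_annual <- annual_rate(series, r_cell)
  total <- lake_total(r_annual, config$lake)
  shares <- budget_fractions(uv_value(total$g_n_per_y), config$lake)
  res <- data.frame(
    quantity = c(
      "potential_rate_nmol_per_l_per_d",
      "potential_rate_sd",
      "time_weighted_abundance_copies_per_ml",
      "cell_specific_rate_fmol_per_cell_per_d",
      "cell_specific_rate_sd",
      "per_cell_carbon_fg",
      "volumetric_c_mean_mg_per_m3",
      "volumetric_c_min_mg_per_m3",
      "volumetric_c_max_mg_per_m3",
      "annual_rate_mg_n_per_m3_per_y",
      "annual_rate_sd",
      "lake_total_g_n_per_y",
      "lake_total_tons_n_per_y",
      "pct_of_phytoplankton_n",
      "pct_of_nitrate_pool_input"
    ),
    value = c(
      uv_value(r_pot), uv_sd(r_pot),
      uv_value(a_mean),
      uv_value(r_cell), uv_sd(r_cell),
      m_carbon_fg,
      uv_value(vol_c), uv_value(vol_c_range)[1], uv_value(vol_c_range)[2],
      uv_value(r_annual), uv_sd(r_annual),
      uv_value(total$g_n_per_y), uv_value(total$tons_n_per_y),
      shares$pct_phytoplankton_n, shares$pct_nitrate_pool
    )
  )
  utils::write.csv(res, out, row.names = FALSE)
  message("budget written to ", out)
  invisible(res)
}

#' @rdname pipeline_run
#' @export
run_report <- function(tracer_csv, abundance_csv, out_dir, config = NULL,
                       force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rates_out <- file.path(out_dir, "rates.csv")
  budget_out <- file.path(out_dir, "budget.csv")
  report_out <- file.path(out_dir, "report.txt")
  check_overwrite(report_out, force)
  run_rates(tracer_csv, rates_out, config = config, force = force)
  budget <- run_budget(rates_out, abundance_csv, budget_out, config = config,
                       force = force)
  val <- function(q) budget$value[budget$quantity == q]
  lines <- c(
    "AOA nitrification budget",
    "========================",
    sprintf("potential ammonia oxidation rate: %.3g +/- %.2g nmol l-1 d-1",
            val("potential_rate_nmol_per_l_per_d"),
            val("potential_rate_sd")),
    sprintf("cell-specific rate: %.3g +/- %.2g fmol cell-1 d-1",
            val("cell_specific_rate_fmol_per_cell_per_d"),
            val("cell_specific_rate_sd")),
    sprintf("AOA carbon standing stock: %.2g (%.2g-%.2g) mg C m-3",
            val("volumetric_c_mean_mg_per_m3"),
            val("volumetric_c_min_mg_per_m3"),
            val("volumetric_c_max_mg_per_m3")),
    sprintf("annual volumetric oxidation: %.3g mg NH4+-N m-3 y-1",
            val("annual_rate_mg_n_per_m3_per_y")),
    sprintf("whole-lake flux: %.3g g NH4+-N y-1 (%.4g metric tons)",
            val("lake_total_g_n_per_y"), val("lake_total_tons_n_per_y")),
    sprintf("share of phytoplankton N production: %.0f %%",
            val("pct_of_phytoplankton_n")),
    sprintf("share of annual nitrate-pool input: %.0f %%",
            val("pct_of_nitrate_pool_input"))
  )
  writeLines(lines, report_out)
  message("report written to ", report_out)
  invisible(report_out)
}
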