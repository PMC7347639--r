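#' Pipeline run configuration
#'
#' Either supply the three input CSV paths (pollen series, search series,
#' metadata) or a synthetic [panel_spec()] — exactly one of the two. All
#' thresholds default to the study conventions: 60% missingness cap, 4-day
#' gap near the first high day, 200 grains/m3 "high", January--June window,
#' LOWESS bandwidths 0.1/0.8, 5% cumulative onset rule, 0.3-degree matching.
#'
#' @param pollen_csv,search_csv path to daily-series CSVs
#'   ([read_series_csv()] dialect).
#' @param station_meta_csv,region_meta_csv metadata CSV paths
#'   ([read_metadata_csv()] dialect).
#' @param synthetic a [panel_spec()], as an alternative to file inputs.
#' @param thresholds a [quality_thresholds()].
#' @param transform a [transform_config()].
#' @param start_fraction cumulative onset fraction.
#' @param max_delta_deg station-region matching bound, decimal degrees.
#' @param outdir output directory for result CSVs (`NULL` = don't write).
#' @param seed integer seed recorded in the provenance header.
#' @return a `run_config` list.
#' @export
run_config <- function(pollen_csv = NULL, search_csv = NULL,
                       station_meta_csv = NULL, region_meta_csv = NULL,
                       synthetic = NULL, thresholds = quality_thresholds(),
                       transform = transform_config(), start_fraction = 0.05,
                       max_delta_deg = 0.3, outdir = NULL, seed = 1L) {
  file_mode <- !is.null(pollen_csv) || !is.null(search_csv)
  if (file_mode == !is.null(synthetic)) {
    stop("set exactly one of {input CSV paths, synthetic panel spec}",
         call. = FALSE)
  }
  if (file_mode && (is.null(pollen_csv) || is.null(search_csv))) {
    stop("file mode needs both pollen_csv and search_csv", call. = FALSE)
  }
  structure(list(pollen_csv = pollen_csv, search_csv = search_csv,
                 station_meta_csv = station_meta_csv,
                 region_meta_csv = region_meta_csv, synthetic = synthetic,
                 thresholds = thresholds, transform = transform,
                 start_fraction = start_fraction,
                 max_delta_deg = max_delta_deg, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognised top-level keys: `pollen_csv`, `search_csv`, `station_meta_csv`,
#' `region_meta_csv`, `start_fraction`, `max_delta_deg`, `outdir`, `seed`,
#' and nested mappings `thresholds`, `transform`, `synthetic` (with nested
#' `pollen`, `search`, `missingness`, `jitter`) whose fields are passed to
#' the corresponding constructors.
#'
#' @param path YAML file path.
#' @param ... overrides applied after the file (e.g. `seed`, `outdir`).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  args <- list(...)
  take <- function(name, default = NULL) {
    if (name %in% names(args)) args[[name]]
    else if (name %in% names(y)) y[[name]] else default
  }
  build <- function(fn, lst) do.call(fn, lst[names(lst) %in% names(formals(fn))])
  thresholds <- if (is.null(y$thresholds)) quality_thresholds() else
    build(quality_thresholds, y$thresholds)
  transform <- if (is.null(y$transform)) transform_config() else {
    tl <- y$transform
    if (!is.null(tl$window)) tl$window <- unlist(tl$window)
    build(transform_config, tl)
  }
  synthetic <- NULL
  if (!is.null(y$synthetic)) {
    sl <- y$synthetic
    sl$pollen <- if (is.null(sl$pollen)) pollen_model_params() else
      build(pollen_model_params, sl$pollen)
    sl$search <- if (is.null(sl$search)) search_model_params() else
      build(search_model_params, sl$search)
    sl$missingness <- if (is.null(sl$missingness)) missingness_params() else
      build(missingness_params, sl$missingness)
    synthetic <- build(panel_spec, sl)
  }
  run_config(pollen_csv = take("pollen_csv"), search_csv = take("search_csv"),
             station_meta_csv = take("station_meta_csv"),
             region_meta_csv = take("region_meta_csv"),
             synthetic = synthetic, thresholds = thresholds,
             transform = transform,
             start_fraction = take("start_fraction", 0.05),
             max_delta_deg = take("max_delta_deg", 0.3),
             outdir = take("outdir"), seed = take("seed", 1L))
}

#' Run the full proxy-validation pipeline
#'
#' Stages: load (or simulate) the panel; match stations to regions by
#' coordinates; apply station-year inclusion criteria; per-site-year
#' association analysis with quartile stratification by search-data
#' missingness and peak signal-to-noise; season-onset discrepancy analysis
#' across inclusion tiers. Deterministic given config + seed. When `outdir`
#' is set, result tables are written as CSVs carrying the config hash.
#'
#' @param config a [run_config()].
#' @return a `pipeline_summary` list: `counts` (read, matched, unmatched,
#'   included, excluded_* ...), `quality`, `association`,
#'   `quartiles_missing`, `quartiles_snr`, `onset` (discrepancy records and
#'   summary), `manifest` (written files), `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    spec$seed <- config$seed
    panel <- generate_panel(spec)
    stations <- panel$stations
    regions <- panel$regions
  } else {
    st_meta <- if (!is.null(config$station_meta_csv)) {
      read_metadata_csv(config$station_meta_csv)
    }
    rg_meta <- if (!is.null(config$region_meta_csv)) {
      read_metadata_csv(config$region_meta_csv)
    }
    stations <- read_series_csv(config$pollen_csv, "pollen", st_meta)
    regions <- read_series_csv(config$search_csv, "search", rg_meta)
  }
  if (!length(stations) || !length(regions)) {
    stop("no matched site-years: empty input panel", call. = FALSE)
  }
  mt <- match_station_to_region(stations, regions, config$max_delta_deg)
  if (nrow(mt$matches) == 0) {
    stop("no matched site-years: no station within the matching distance",
         call. = FALSE)
  }
  aw <- config$transform$window
  m_stations <- stations[mt$matches$station_idx]
  qt <- quality_table(m_stations, config$thresholds,
                      analysis_window = resolve_window(
                        aw, m_stations[[1]]$series$year))
  keep <- which(qt$included)
  counts <- list(
    read_stations = length(stations), read_regions = length(regions),
    matched = nrow(mt$matches), unmatched = length(mt$unmatched),
    included = length(keep), excluded = sum(!qt$included),
    excluded_no_data = sum(qt$reason_no_data),
    excluded_missingness = sum(qt$reason_missingness),
    excluded_gap_near_high = sum(qt$reason_gap_near_high))
  sub_matches <- list(matches = data.frame(
    station_idx = mt$matches$station_idx[keep],
    region_idx = mt$matches$region_idx[keep]))
  panel_lists <- list(stations = stations, regions = regions)
  assoc <- NULL; qm <- NULL; qs <- NULL; onset <- NULL
  if (length(keep) > 0) {
    assoc <- association_analysis(panel_lists, sub_matches, config$transform)
    qm <- tryCatch(quartile_stratify(assoc, "pct_gt_missing"),
                   error = function(e) NULL)
    qs <- tryCatch(quartile_stratify(assoc, "peak_snr"),
                   error = function(e) NULL)
    onset <- discrepancy_analysis(panel_lists, sub_matches,
                                  fraction = config$start_fraction,
                                  config = config$transform,
                                  thresholds = config$thresholds)
  }
  hash <- config_hash(config)
  manifest <- character()
  if (!is.null(config$outdir)) {
    manifest <- write_outputs(config$outdir, hash, qt, assoc, qm, qs, onset)
  }
  structure(list(counts = counts, quality = qt, association = assoc,
                 quartiles_missing = qm, quartiles_snr = qs, onset = onset,
                 manifest = manifest, config_hash = hash),
            class = "pipeline_summary")
}

# Short deterministic hash of the configuration (provenance stamp on
# outputs); independent of list element order.
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
               collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 251 + 1)) %%
            .Machine$integer.max)
}

write_outputs <- function(outdir, hash, qt, assoc, qm, qs, onset) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- character()
  emit <- function(df, name) {
    if (is.null(df) || !nrow(df)) return()
    path <- file.path(outdir, name)
    con <- file(path, "w")
    writeLines(sprintf("# config_hash: %s", hash), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    manifest <<- c(manifest, path)
  }
  emit(qt, "quality.csv")
  emit(assoc, "association.csv")
  if (!is.null(qm)) emit(qm$summary, "quartiles_missing.csv")
  if (!is.null(qs)) emit(qs$summary, "quartiles_snr.csv")
  if (!is.null(onset)) {
    emit(onset$records, "onset_records.csv")
    emit(onset$summary, "onset_summary.csv")
  }
  manifest
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat(make_report(x))
  invisible(x)
}

#' Render a pipeline summary as a markdown report
#'
#' Tabulates stage counts, median (IQR) rho per quartile of search-data
#' missingness and of peak signal-to-noise, and median (IQR) start-date
#' discrepancy per inclusion tier and data variant.
#'
#' @param summary a `pipeline_summary` from [run_pipeline()].
#' @return a single markdown string.
#' @export
make_report <- function(summary) {
  stopifnot(inherits(summary, "pipeline_summary"))
  cn <- summary$counts
  out <- c("# Pollen/search proxy-validation report", "",
           sprintf("config hash: %s", summary$config_hash), "",
           "## Stage counts", "",
           sprintf("- station-years read: %d (stations), %d (regions)",
                   cn$read_stations, cn$read_regions),
           sprintf("- matched: %d; unmatched: %d", cn$matched, cn$unmatched),
           sprintf(paste0("- included: %d; excluded: %d (no data: %d, ",
                          "missingness: %d, gap near first high: %d)"),
                   cn$included, cn$excluded, cn$excluded_no_data,
                   cn$excluded_missingness, cn$excluded_gap_near_high), "")
  fmt_q <- function(q, label) {
    if (is.null(q)) return(character())
    s <- q$summary
    c(sprintf("## Median rho by quartile of %s", label), "",
      sprintf("cutoffs: %s", paste(signif(q$cutoffs, 3), collapse = ", ")), "",
      "| quartile | n | median rho | IQR |", "|---|---|---|---|",
      sprintf("| Q%d | %d | %.2f | (%.2f, %.2f) |", s$quartile, s$n,
              s$median_rho, s$iqr_lo, s$iqr_hi), "")
  }
  out <- c(out, fmt_q(summary$quartiles_missing, "search-data missingness"),
           fmt_q(summary$quartiles_snr, "peak signal-to-noise"))
  if (!is.null(summary$onset) && nrow(summary$onset$summary)) {
    s <- summary$onset$summary
    out <- c(out, "## Start-date discrepancy (search minus pollen, days)", "",
             "| tier | variant | n | median delta | IQR |",
             "|---|---|---|---|---|",
             sprintf("| %s | %s | %d | %.1f | (%.1f, %.1f) |", s$tier,
                     s$variant, s$n, s$median_delta, s$iqr_lo, s$iqr_hi), "")
  }
  paste(out, collapse = "\n")
}
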