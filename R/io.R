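#' One station-year of pollen observations
#'
#' @param station_id text identifier of the counting station.
#' @param latitude,longitude decimal degrees (|lat| <= 90, |lon| <= 180);
#'   `NA` allowed when metadata are unavailable.
#' @param series a `daily_series` of kind `"pollen"`.
#' @return a `station_year` object.
#' @export
station_year <- function(station_id, latitude, longitude, series) {
  stopifnot(inherits(series, "daily_series"))
  if (series$kind != "pollen") stop("station series must be pollen", call. = FALSE)
  check_coords(latitude, longitude)
  structure(list(station_id = as.character(station_id),
                 latitude = latitude, longitude = longitude,
                 series = series,
                 site_year_id = paste0(station_id, "_", series$year)),
            class = "station_year")
}

#' One region-year of replicate search-volume downloads
#'
#' The day-wise arithmetic mean over replicates (`averaged`) treats reported
#' censored zeros as zeros; a day is missing in the average only when it is
#' missing in every replicate.
#'
#' @param dma_id text identifier of the market region.
#' @param latitude,longitude decimal degrees of the region centroid.
#' @param tv_homes positive count of television households (population/media
#'   size proxy); `NA` allowed.
#' @param replicates list of `daily_series` of kind `"search"`, one per
#'   download replicate.
#' @return a `region_year` object with an `averaged` series.
#' @export
region_year <- function(dma_id, latitude, longitude, tv_homes, replicates) {
  if (!length(replicates)) stop("at least one replicate required", call. = FALSE)
  for (r in replicates) {
    stopifnot(inherits(r, "daily_series"))
    if (r$kind != "search") stop("region replicates must be search series",
                                 call. = FALSE)
  }
  yrs <- vapply(replicates, function(r) r$year, integer(1))
  if (length(unique(yrs)) != 1) stop("replicates span multiple years", call. = FALSE)
  check_coords(latitude, longitude)
  if (!is.na(tv_homes) && tv_homes <= 0) {
    stop("tv_homes must be positive", call. = FALSE)
  }
  structure(list(dma_id = as.character(dma_id),
                 latitude = latitude, longitude = longitude,
                 tv_homes = tv_homes, replicates = replicates,
                 averaged = average_replicates(replicates),
                 site_year_id = paste0(dma_id, "_", yrs[1])),
            class = "region_year")
}

check_coords <- function(latitude, longitude) {
  if (!is.na(latitude) && abs(latitude) > 90) {
    stop("|latitude| must be <= 90", call. = FALSE)
  }
  if (!is.na(longitude) && abs(longitude) > 180) {
    stop("|longitude| must be <= 180", call. = FALSE)
  }
}

#' Day-wise mean of replicate search downloads
#'
#' @param replicates list of `daily_series` (same year, kind `"search"`).
#' @return a `daily_series`: arithmetic mean per day over the replicates in
#'   which that day is observed (reported zeros count as zeros); `NA` where
#'   all replicates are missing.
#' @export
average_replicates <- function(replicates) {
  m <- vapply(replicates, function(r) r$values, numeric(length(replicates[[1]]$values)))
  m <- matrix(m, ncol = length(replicates))
  avg <- rowMeans(m, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  daily_series(avg, replicates[[1]]$year, "search")
}

#' Read daily series from CSV
#'
#' Expected columns: `id`, `date` (ISO-8601 `YYYY-MM-DD`), `value` (empty
#' field = missing day), and for search data an optional `replicate` column.
#' One object is returned per (id, year). Duplicate (id, date, replicate)
#' rows, malformed dates, negative values, and search values above 100 are
#' errors naming the offending row.
#'
#' @param path CSV file path (header mandatory, UTF-8, comma separator).
#' @param kind `"pollen"` or `"search"`.
#' @param metadata optional data frame as returned by [read_metadata_csv()];
#'   matched on `id` to attach coordinates (and `tv_homes` for regions).
#' @return list of [station_year()] (pollen) or [region_year()] (search).
#' @export
read_series_csv <- function(path, kind = c("pollen", "search"), metadata = NULL) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  need <- c("id", "date", "value")
  if (!all(need %in% names(df))) {
    stop(sprintf("CSV must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) | df$date != format(dates, "%Y-%m-%d"))
  if (length(bad)) {
    stop(sprintf("malformed date %s at row %d", df$date[bad[1]], bad[1]),
         call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(df$value))
  empty <- !nzchar(trimws(df$value))
  value[empty] <- NA_real_
  bad <- which(!empty & is.na(value))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' at row %d", df$value[bad[1]], bad[1]),
         call. = FALSE)
  }
  bad <- which(!is.na(value) & value < 0)
  if (length(bad)) stop(sprintf("negative value at row %d", bad[1]), call. = FALSE)
  if (kind == "search") {
    bad <- which(!is.na(value) & value > 100)
    if (length(bad)) {
      stop(sprintf("search value > 100 at row %d", bad[1]), call. = FALSE)
    }
  }
  key <- paste(df$id, df$date, df$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate (id, date, replicate) row at row %d", dup[1]),
         call. = FALSE)
  }
  year <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  groups <- split(seq_len(nrow(df)), list(id = df$id, year = year), drop = TRUE)
  lapply(unname(groups), function(idx) {
    yr <- year[idx[1]]
    id <- df$id[idx[1]]
    meta <- lookup_metadata(metadata, id)
    if (kind == "pollen") {
      v <- rep(NA_real_, days_in_year(yr))
      v[doy[idx]] <- value[idx]
      station_year(id, meta$latitude, meta$longitude,
                   daily_series(v, yr, "pollen"))
    } else {
      reps <- lapply(split(idx, df$replicate[idx]), function(ridx) {
        v <- rep(NA_real_, days_in_year(yr))
        v[doy[ridx]] <- value[ridx]
        daily_series(v, yr, "search")
      })
      region_year(id, meta$latitude, meta$longitude, meta$tv_homes,
                  unname(reps))
    }
  })
}

lookup_metadata <- function(metadata, id) {
  if (is.null(metadata) || !id %in% metadata$id) {
    return(list(latitude = NA_real_, longitude = NA_real_, tv_homes = NA_real_))
  }
  row <- metadata[match(id, metadata$id), , drop = FALSE]
  list(latitude = row$latitude, longitude = row$longitude,
       tv_homes = if ("tv_homes" %in% names(row)) row$tv_homes else NA_real_)
}

#' Read site metadata from CSV
#'
#' Columns: `id`, `latitude`, `longitude`, and optionally `tv_homes`.
#' @param path CSV file path.
#' @return data frame.
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "latitude", "longitude")
  if (!all(need %in% names(df))) {
    stop(sprintf("metadata CSV must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Write station/region site-years to CSV
#'
#' Writes the same dialect [read_series_csv()] reads (missing days become
#' empty value fields). Region-years write one row per replicate per observed
#' day, with a `replicate` column.
#'
#' @param site_years list of `station_year` or `region_year` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(site_years, path) {
  rows <- lapply(site_years, function(sy) {
    if (inherits(sy, "station_year")) {
      s <- sy$series
      data.frame(id = sy$station_id,
                 date = format(doy_to_date(s$year, seq_along(s$values))),
                 value = ifelse(is.na(s$values), "",
                                format(s$values, trim = TRUE, scientific = FALSE, digits = 15)),
                 stringsAsFactors = FALSE)
    } else if (inherits(sy, "region_year")) {
      do.call(rbind, lapply(seq_along(sy$replicates), function(r) {
        s <- sy$replicates[[r]]
        data.frame(id = sy$dma_id,
                   date = format(doy_to_date(s$year, seq_along(s$values))),
                   value = ifelse(is.na(s$values), "",
                                  format(s$values, trim = TRUE, scientific = FALSE, digits = 15)),
                   replicate = r, stringsAsFactors = FALSE)
      }))
    } else {
      stop("site_years must be station_year or region_year objects", call. = FALSE)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Write a synthetic panel as the CSV set the pipeline reads
#'
#' Produces `pollen.csv`, `search.csv`, `stations.csv`, `regions.csv` in
#' `dir`, in the dialects of [read_series_csv()] and [read_metadata_csv()].
#'
#' @param panel a `pollen_panel` from [generate_panel()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_panel_csv <- function(panel, dir) {
  stopifnot(inherits(panel, "pollen_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(pollen = file.path(dir, "pollen.csv"),
             search = file.path(dir, "search.csv"),
             stations = file.path(dir, "stations.csv"),
             regions = file.path(dir, "regions.csv"))
  write_series_csv(panel$stations, paths[["pollen"]])
  write_series_csv(panel$regions, paths[["search"]])
  utils::write.csv(data.frame(
    id = vapply(panel$stations, `[[`, "", "station_id"),
    latitude = vapply(panel$stations, `[[`, 0, "latitude"),
    longitude = vapply(panel$stations, `[[`, 0, "longitude")),
    paths[["stations"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(
    id = vapply(panel$regions, `[[`, "", "dma_id"),
    latitude = vapply(panel$regions, `[[`, 0, "latitude"),
    longitude = vapply(panel$regions, `[[`, 0, "longitude"),
    tv_homes = vapply(panel$regions, `[[`, 0, "tv_homes")),
    paths[["regions"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Match pollen stations to search regions by coordinates
#'
#' A station and a region match when both the latitude and the longitude
#' differ by at most `max_delta_deg` decimal degrees. When several regions
#' qualify for one station, the region minimising the Chebyshev distance
#' `max(|dlat|, |dlon|)` is chosen (ties broken by region order).
#'
#' @param stations list of `station_year` objects.
#' @param regions list of `region_year` objects.
#' @param max_delta_deg per-axis matching bound in decimal degrees.
#' @return list with `matches` (data frame `station_id`, `dma_id`,
#'   `station_idx`, `region_idx`, `chebyshev_deg`) and `unmatched`
#'   (character vector of station site-year ids). Only same-year pairs are
#'   considered.
#' @export
match_station_to_region <- function(stations, regions, max_delta_deg = 0.3) {
  rows <- list()
  unmatched <- character()
  r_lat <- vapply(regions, `[[`, 0, "latitude")
  r_lon <- vapply(regions, `[[`, 0, "longitude")
  r_year <- vapply(regions, function(r) r$replicates[[1]]$year, integer(1))
  for (i in seq_along(stations)) {
    st <- stations[[i]]
    if (is.na(st$latitude) || is.na(st$longitude)) {
      stop(sprintf("station %s lacks coordinates", st$station_id), call. = FALSE)
    }
    dlat <- abs(r_lat - st$latitude)
    dlon <- abs(r_lon - st$longitude)
    ok <- which(dlat <= max_delta_deg & dlon <= max_delta_deg &
                  r_year == st$series$year)
    if (!length(ok)) {
      unmatched <- c(unmatched, st$site_year_id)
      next
    }
    cheb <- pmax(dlat[ok], dlon[ok])
    j <- ok[which.min(cheb)]
    rows[[length(rows) + 1L]] <- data.frame(
      station_id = st$station_id, dma_id = regions[[j]]$dma_id,
      station_idx = i, region_idx = j, chebyshev_deg = min(cheb),
      stringsAsFactors = FALSE)
  }
  matches <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(station_id = character(), dma_id = character(),
               station_idx = integer(), region_idx = integer(),
               chebyshev_deg = numeric(), stringsAsFactors = FALSE)
  }
  list(matches = matches, unmatched = unmatched)
}
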