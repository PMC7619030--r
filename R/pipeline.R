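#' Load and validate a run configuration
#'
#' A run configuration is a named list (or a JSON file holding one) with the
#' paths and options a pipeline command needs. Recognised fields: paths
#' `stations_csv`, `vec_file`, `subword_csv`, `anchors_json`,
#' `map_controls_csv`, `map_stations_csv`, `out_dir`; options `radius_km`
#' (default 6371.0088), `oov_agg` (`"sum"`/`"mean"`), `contrasts`
#' (`"sum"`/`"treatment"`), `map_mode` (`"planar"`/`"lonlat-compat"`),
#' `language` (single code or named per-city list), `seed`, and the
#' synthetic-generator fields of [synth_config()]. Every referenced path
#' must exist at validation time.
#'
#' @param config Named list or path to a JSON file.
#' @return The validated config list with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(radius_km = 6371.0088, oov_agg = "sum", contrasts = "sum",
                   map_mode = "planar", language = "en", seed = 1L,
                   out_dir = ".")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (p in c("stations_csv", "vec_file", "subword_csv", "anchors_json",
              "map_controls_csv", "map_stations_csv")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("configured path does not exist (", p, "): ", config[[p]],
           call. = FALSE)
    }
  }
  stopifnot(config$radius_km > 0,
            config$oov_agg %in% c("sum", "mean"),
            config$contrasts %in% c("sum", "treatment"),
            config$map_mode %in% c("planar", "lonlat-compat"))
  config
}

schema_header <- "# lingmap csv schema 1"

write_output_csv <- function(df, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(schema_header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output CSV (schema-version header tolerated)
#' @param path CSV path written by a pipeline command.
#' @return Data frame.
#' @export
read_output_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", fileEncoding = "UTF-8",
                  stringsAsFactors = FALSE)
}

# serialize a lingmap_fit as tidy CSV + JSON next to `stem`
write_model_outputs <- function(fit, stem) {
  tidy <- merge(fit$fixed,
                fit$terms[, c("term", "statistic", "df", "df2", "stat_type", "p")],
                by = "term", all.x = TRUE, sort = FALSE)
  write_output_csv(tidy, paste0(stem, ".csv"))
  jsonlite::write_json(
    list(kind = fit$kind, fixed = fit$fixed, varcomp = fit$varcomp,
         terms = fit$terms, fit = fit$fit),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}

load_store_and_table <- function(config) {
  store <- read_vec_file(config$vec_file)
  table <- if (!is.null(config$subword_csv)) read_subword_table(config$subword_csv)
  list(store = store, table = table)
}

city_anchor_words <- function(config, cities) {
  lang_of <- function(city) {
    if (is.list(config$language) || length(config$language) > 1L) {
      l <- config$language[[city]]
      if (is.null(l)) stop("no language configured for city '", city, "'",
                           call. = FALSE)
      l
    } else config$language
  }
  setNames(lapply(cities, function(ct) {
    lang <- lang_of(ct)
    if (!is.null(config$anchors_json)) read_anchor_words(config$anchors_json, lang)
    else default_anchor_words(lang)
  }), cities)
}

#' Pipeline: pairwise distances and the distance model
#'
#' Reads stations and embeddings, builds the within-city pairwise table
#' (geographic km and linguistic distance for every unordered station
#' pair), fits the crossed random-intercept model of geographic on
#' linguistic distance — with a linguistic-distance-by-city interaction
#' when several cities are present — and writes the pair table, the model,
#' and the per-city simple slopes under `out_dir`.
#'
#' @param config Run configuration (list or JSON path); needs
#'   `stations_csv`, `vec_file`, optionally `subword_csv`.
#' @return Invisibly, a list with `pairs`, `fit`, `slopes`, and the output
#'   paths.
#' @export
cmd_distances <- function(config) {
  config <- load_run_config(config)
  if (is.null(config$stations_csv) || is.null(config$vec_file)) {
    stop("cmd_distances needs stations_csv and vec_file", call. = FALSE)
  }
  stations <- read_stations_csv(config$stations_csv)
  st <- load_store_and_table(config)
  pairs <- do.call(rbind, lapply(split(stations, stations$city), function(s) {
    build_pair_table(s, st$store, st$table, radius_km = config$radius_km)
  }))
  rownames(pairs) <- NULL
  multi <- length(unique(pairs$city)) > 1L
  fit <- fit_crossed_lmm(pairs$geo_km, pairs$ling_dist,
                         id1 = pairs$station_i, id2 = pairs$station_j,
                         g = if (multi) pairs$city,
                         contrasts = config$contrasts)
  slopes <- simple_slopes(fit)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$out_dir,
                     c(pairs = "pairs.csv", model = "distance_model",
                       slopes = "simple_slopes.csv"))
  write_output_csv(pairs, paths[[1L]])
  write_model_outputs(fit, paths[[2L]])
  write_output_csv(slopes, paths[[3L]])
  message(sprintf("distances: %d pairs, %d cities; model %s; slopes written",
                  nrow(pairs), length(unique(pairs$city)),
                  if (fit$fit$converged) "converged" else "did NOT converge"))
  invisible(list(pairs = pairs, fit = fit, slopes = slopes, paths = paths))
}

#' Pipeline: linguistic coordinates and the coordinate models
#'
#' Builds the per-station coordinate table (geographic and anchor-word
#' linguistic latitude/longitude, with city-level z-scored geographic
#' coordinates) and fits the two interaction linear models — z-scored
#' geographic latitude on linguistic latitude by city, and likewise for
#' longitude.
#'
#' @param config Run configuration; needs `stations_csv`, `vec_file`,
#'   optionally `subword_csv`, `anchors_json`, per-city `language`.
#' @return Invisibly, `coords`, `fit_lat`, `fit_lon`, output paths.
#' @export
cmd_coordinates <- function(config) {
  config <- load_run_config(config)
  if (is.null(config$stations_csv) || is.null(config$vec_file)) {
    stop("cmd_coordinates needs stations_csv and vec_file", call. = FALSE)
  }
  stations <- read_stations_csv(config$stations_csv)
  st <- load_store_and_table(config)
  cities <- unique(stations$city)
  anchors <- lapply(city_anchor_words(config, cities), function(w) {
    cardinal_anchors(st$store, w, st$table)
  })
  coords <- build_coordinate_table(stations, st$store, anchors, st$table)
  fit_lat <- fit_lm_interaction(coords$z_geo_lat, coords$ling_lat, coords$city,
                                contrasts = config$contrasts)
  fit_lon <- fit_lm_interaction(coords$z_geo_lon, coords$ling_lon, coords$city,
                                contrasts = config$contrasts)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$out_dir,
                     c("coordinates.csv", "latitude_model", "longitude_model"))
  write_output_csv(coords, paths[[1L]])
  write_model_outputs(fit_lat, paths[[2L]])
  write_model_outputs(fit_lon, paths[[3L]])
  message(sprintf("coordinates: %d stations, %d cities; residual df %d",
                  nrow(coords), length(cities), fit_lat$fit$df_residual))
  invisible(list(coords = coords, fit_lat = fit_lat, fit_lon = fit_lon,
                 paths = paths))
}

#' Pipeline: schematic-map calibration and comparison
#'
#' Calibrates digitized schematic-map pixels to the geographic frame by
#' least-squares affine fit on control stations, computes map-based
#' distances for every station pair, fits the map-on-geographic distance
#' model, optionally the z-scored distance-by-type model (when embeddings
#' are configured), and reports the Pearson correlations between map and
#' geographic coordinates.
#'
#' @param config Run configuration; needs `stations_csv` and
#'   `map_stations_csv` (`label,x,y` pixels, labels matching station
#'   names). Control points default to all matched stations; pass
#'   `map_controls_csv` to calibrate on a subset. Optional `vec_file`
#'   enables the linguistic-distance-by-type model.
#' @return Invisibly: calibrated coordinates, pair table with `map_dist`,
#'   fits, and the correlation report.
#' @export
cmd_mapcompare <- function(config) {
  config <- load_run_config(config)
  if (is.null(config$stations_csv) || is.null(config$map_stations_csv)) {
    stop("cmd_mapcompare needs stations_csv and map_stations_csv", call. = FALSE)
  }
  stations <- read_stations_csv(config$stations_csv)
  pix <- read_digitized_csv(config$map_stations_csv)
  m <- match(stations$name, pix$label)
  if (anyNA(m)) {
    stop("no digitized map point for station(s): ",
         paste(utils::head(stations$name[is.na(m)], 5L), collapse = ", "),
         call. = FALSE)
  }
  pix <- pix[m, ]
  controls <- if (!is.null(config$map_controls_csv)) {
    read_digitized_csv(config$map_controls_csv)
  } else pix
  cm <- match(controls$label, stations$name)
  if (anyNA(cm)) {
    stop("control point label(s) not in station table: ",
         paste(controls$label[is.na(cm)], collapse = ", "), call. = FALSE)
  }
  transform <- fit_affine(controls[, c("x", "y")],
                          cbind(stations$lon[cm], stations$lat[cm]))
  cal <- apply_affine(transform, pix[, c("x", "y")])
  coords <- data.frame(id = stations$id, city = stations$city,
                       geo_lat = stations$lat, geo_lon = stations$lon,
                       map_x = cal[, 1L], map_y = cal[, 2L],
                       stringsAsFactors = FALSE)
  rowof <- setNames(seq_len(nrow(stations)), stations$id)
  pairs <- all_pairs(stations)
  i <- rowof[pairs$station_i]; j <- rowof[pairs$station_j]
  pairs$geo_km <- haversine_km(stations$lat[i], stations$lon[i],
                               stations$lat[j], stations$lon[j],
                               radius_km = config$radius_km)
  pairs$map_dist <- map_distance(cbind(coords$map_x, coords$map_y)[i, ],
                                 cbind(coords$map_x, coords$map_y)[j, ],
                                 mode = config$map_mode,
                                 radius_km = config$radius_km)
  fit_mapgeo <- fit_crossed_lmm(pairs$map_dist, pairs$geo_km,
                                id1 = pairs$station_i, id2 = pairs$station_j)
  correlations <- list(
    lat = pearson_r(coords$map_y, coords$geo_lat),
    lon = pearson_r(coords$map_x, coords$geo_lon))

  fit_type <- NULL
  if (!is.null(config$vec_file)) {
    st <- load_store_and_table(config)
    pairs$ling_dist <- vapply(seq_len(nrow(pairs)), function(r) {
      linguistic_distance(st$store, stations$name[i[r]], stations$name[j[r]],
                          st$table)
    }, numeric(1L))
    stacked <- data.frame(
      z_dist = zscore_within(c(pairs$geo_km, pairs$map_dist),
                             rep(c("geo", "map"), each = nrow(pairs))),
      ling_dist = rep(pairs$ling_dist, 2L),
      type = rep(c("geo", "map"), each = nrow(pairs)),
      station_i = rep(pairs$station_i, 2L),
      station_j = rep(pairs$station_j, 2L))
    fit_type <- fit_crossed_lmm(stacked$z_dist, stacked$ling_dist,
                                id1 = stacked$station_i, id2 = stacked$station_j,
                                g = stacked$type, contrasts = config$contrasts)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_output_csv(coords, file.path(config$out_dir, "map_coordinates.csv"))
  write_output_csv(pairs, file.path(config$out_dir, "map_pairs.csv"))
  write_model_outputs(fit_mapgeo, file.path(config$out_dir, "map_geo_model"))
  if (!is.null(fit_type)) {
    write_model_outputs(fit_type, file.path(config$out_dir, "distance_type_model"))
  }
  jsonlite::write_json(correlations,
                       file.path(config$out_dir, "map_correlations.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("mapcompare: r(lat) = %.4f, r(lon) = %.4f, map~geo slope %.4f",
                  correlations$lat, correlations$lon,
                  fit_mapgeo$fixed$b[fit_mapgeo$fixed$term == ".x"]))
  invisible(list(coords = coords, pairs = pairs, transform = transform,
                 fit_mapgeo = fit_mapgeo, fit_type = fit_type,
                 correlations = correlations))
}

#' Pipeline: synthetic generation plus recovery report
#'
#' Generates a synthetic city bundle, writes its artifacts in the same
#' formats the real pipeline consumes (station CSV, `.vec` embedding file,
#' anchors JSON, truth JSON), runs the requested recovery experiment, and
#' writes the recovery report.
#'
#' @param config Run configuration; synthetic fields of [synth_config()]
#'   are picked up (`n_stations`, `alpha`, `seed`, ...), plus `experiment`
#'   (`"exp1"` default, or `"exp2"`) and `out_dir`.
#' @return Invisibly, the [simulate_experiment()] result plus paths.
#' @export
cmd_simulate <- function(config) {
  config <- load_run_config(config)
  synth_args <- intersect(names(config), names(formals(synth_config)))
  cfg <- do.call(synth_config, config[synth_args])
  which <- if (is.null(config$experiment)) "exp1" else config$experiment
  sim <- simulate_experiment(cfg, which = which)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stations_csv(sim$city$stations,
                     file.path(config$out_dir, "stations.csv"))
  write_vec_file(sim$city$store, file.path(config$out_dir, "embeddings.vec"))
  jsonlite::write_json(
    setNames(list(sim$city$anchors$words), cfg$language),
    file.path(config$out_dir, "anchors.json"), auto_unbox = TRUE)
  jsonlite::write_json(
    list(lambda = sim$city$truth$lambda, phi = sim$city$truth$phi,
         a_k = sim$city$truth$a_k, contaminated = sim$city$truth$contaminated,
         config = unclass(cfg)),
    file.path(config$out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(sim$recovery,
                       file.path(config$out_dir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("simulate: %s at alpha = %.2f, n = %d; recovery written",
                  which, cfg$alpha, cfg$n_stations))
  invisible(c(sim, list(out_dir = config$out_dir)))
}
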