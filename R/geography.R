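#' Validate a station table
#'
#' A station table is a data frame with columns `id`, `name`, `city`, `lat`,
#' `lon`: one row per underground station, with latitude/longitude in decimal
#' degrees. Stations appearing on multiple lines of a network must be
#' deduplicated to one row each before pairing; `(name, city)` must be unique.
#'
#' @param stations Data frame with columns `id, name, city, lat, lon`.
#' @return The validated data frame (ids coerced to character), invisibly
#'   usable downstream.
#' @export
validate_stations <- function(stations) {
  req <- c("id", "name", "city", "lat", "lon")
  miss <- setdiff(req, names(stations))
  if (length(miss)) {
    stop("station table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stations$id <- as.character(stations$id)
  stations$name <- as.character(stations$name)
  stations$city <- as.character(stations$city)
  if (anyDuplicated(stations$id)) {
    stop("duplicate station id(s): ",
         paste(unique(stations$id[duplicated(stations$id)]), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(stations$name, stations$city, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (name, city) pair(s) in station table", call. = FALSE)
  }
  check_lonlat(stations$lat, stations$lon)
  stations
}

check_lonlat <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90) || any(lat > 90) || any(lon < -180) || any(lon > 180)) {
    stop("coordinates out of range: lat must lie in [-90, 90], lon in [-180, 180]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write station tables as CSV
#'
#' CSV schema: header `id,name,city,lat,lon`, UTF-8, decimal point.
#'
#' @param path CSV path.
#' @param stations Station data frame.
#' @return A validated station data frame (read) or `path` invisibly (write).
#' @export
read_stations_csv <- function(path) {
  validate_stations(utils::read.csv(path, fileEncoding = "UTF-8",
                                    stringsAsFactors = FALSE))
}

#' @rdname read_stations_csv
#' @export
write_stations_csv <- function(stations, path) {
  utils::write.csv(validate_stations(stations)[, c("id", "name", "city", "lat", "lon")],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere. The default radius is the IUGG mean Earth
#' radius, 6371.0088 km; pass `radius_km` to match any other spherical
#' convention. Vectorized over coordinate pairs.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (latitudes in
#'   `[-90, 90]`, longitudes in `[-180, 180]`).
#' @param radius_km Sphere radius in km.
#' @return Non-negative distance(s) in km, at most `pi * radius_km`.
#' @examples
#' haversine_km(0, 0, 0, 180)  # half the circumference
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0088) {
  stopifnot(radius_km > 0)
  check_lonlat(lat1, lon1)
  check_lonlat(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = radius_km)
}

#' Enumerate all unordered station pairs
#'
#' Every unordered pair appears exactly once, with `station_i < station_j`
#' under C-locale lexicographic order of the ids; rows are sorted
#' lexicographically by `(station_i, station_j)`, so regeneration is
#' deterministic. `n` stations yield `n (n - 1) / 2` rows (175 stations give
#' the 15225 pairs of a Berlin-sized network).
#'
#' @param stations Station data frame (validated).
#' @return Data frame with columns `station_i`, `station_j`.
#' @export
all_pairs <- function(stations) {
  stations <- validate_stations(stations)
  if (nrow(stations) < 2L) stop("need at least 2 stations to pair", call. = FALSE)
  ids <- sort(stations$id, method = "radix")
  n <- length(ids)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  data.frame(station_i = ids[i], station_j = ids[j], stringsAsFactors = FALSE)
}

#' Z-score values within groups
#'
#' Standardizes each group block to mean 0 and sample (n-1) standard
#' deviation 1, independently per group — the "city-level z-transform" used
#' for coordinates and for distances standardized within distance type.
#'
#' @param values Numeric vector.
#' @param groups Parallel vector of group labels.
#' @return Numeric vector of within-group z-scores.
#' @export
zscore_within <- function(values, groups) {
  stopifnot(length(values) == length(groups), is.numeric(values))
  groups <- as.character(groups)
  out <- numeric(length(values))
  for (g in unique(groups)) {
    sel <- groups == g
    if (sum(sel) < 2L) {
      stop("group '", g, "' has fewer than 2 members; cannot standardize",
           call. = FALSE)
    }
    s <- stats::sd(values[sel])
    if (!is.finite(s) || s == 0) {
      stop("group '", g, "' is constant; cannot standardize", call. = FALSE)
    }
    out[sel] <- (values[sel] - mean(values[sel])) / s
  }
  out
}
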