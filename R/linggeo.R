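#' Cardinal anchor words and vectors
#'
#' The linguistic coordinate system is spanned by the embedding vectors of
#' the four cardinal-direction words of the city's language. Anchor vectors
#' resolve by exact lookup first and subword composition second, the same
#' policy as station labels.
#'
#' @param store An `embedding_store`.
#' @param words Named list/vector with entries `north`, `south`, `east`,
#'   `west` giving the anchor words.
#' @param table Optional `subword_table` fallback.
#' @param language Language label attached for provenance.
#' @return A `cardinal_anchors` object: `language`, `words`, and `vectors`
#'   (a list of the four resolved vectors).
#' @export
cardinal_anchors <- function(store, words, table = NULL, language = "und") {
  req <- c("north", "south", "east", "west")
  words <- as.list(words)
  miss <- setdiff(req, names(words))
  if (length(miss)) {
    stop("anchor words missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  vectors <- lapply(words[req], function(w) get_label_vector(store, w, table))
  for (d in req) {
    if (sqrt(sum(vectors[[d]]^2)) == 0) {
      stop("anchor '", words[[d]], "' (", d, ") has zero-norm vector", call. = FALSE)
    }
  }
  dims <- lengths(vectors)
  stopifnot(length(unique(dims)) == 1L)
  structure(list(language = language, words = words[req], vectors = vectors),
            class = "cardinal_anchors")
}

#' Default per-language cardinal-direction words
#'
#' Editorial defaults for English, German, Spanish, Italian and French,
#' overridable via an anchors JSON file (`{language: {north: ..., ...}}`).
#' Queries are lowercase by default.
#'
#' @param language One of `"en"`, `"de"`, `"es"`, `"it"`, `"fr"`.
#' @return Named list with `north`, `south`, `east`, `west`.
#' @export
default_anchor_words <- function(language = c("en", "de", "es", "it", "fr")) {
  language <- match.arg(language)
  switch(language,
    en = list(north = "north", south = "south", east = "east",  west = "west"),
    de = list(north = "norden", south = "süden", east = "osten", west = "westen"),
    es = list(north = "norte", south = "sur",   east = "este",  west = "oeste"),
    it = list(north = "nord",  south = "sud",   east = "est",   west = "ovest"),
    fr = list(north = "nord",  south = "sud",   east = "est",   west = "ouest"))
}

#' Read anchor words from JSON
#'
#' @param path JSON file shaped `{language: {north, south, east, west}}`.
#' @param language Which language entry to return; when `NULL` the full
#'   table is returned.
#' @return Named list of anchor words (or list of such lists).
#' @export
read_anchor_words <- function(path, language = NULL) {
  tab <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(language)) return(tab)
  if (is.null(tab[[language]])) {
    stop("no anchor entry for language '", language, "' in ", path, call. = FALSE)
  }
  tab[[language]]
}

#' Linguistic distance between two labels
#'
#' One minus the cosine similarity of the two labels' vectors: 0 for
#' positively collinear vectors, up to 2 for antipodal ones. The lower the
#' value, the closer the two labels in the semantic space.
#'
#' @param store An `embedding_store`.
#' @param a,b Labels (resolved exactly or by subword fallback).
#' @param table Optional `subword_table`.
#' @return Numeric scalar in `[0, 2]`.
#' @export
linguistic_distance <- function(store, a, b, table = NULL) {
  va <- get_label_vector(store, a, table)
  vb <- get_label_vector(store, b, table)
  d <- tryCatch(1 - cosine(va, vb), error = function(e) {
    stop("linguistic distance undefined for pair ('", a, "', '", b, "'): ",
         conditionMessage(e), call. = FALSE)
  })
  d
}

#' Linguistic latitude and longitude of a vector
#'
#' Projects a label vector onto the cardinal axes of the semantic space:
#' latitude is `cos(v, north) - cos(v, south)` (positive = linguistically
#' northern), longitude is `cos(v, east) - cos(v, west)` (positive =
#' linguistically eastern). Both lie in `[-2, 2]`, being differences of two
#' cosines.
#'
#' @param v Non-zero numeric vector.
#' @param anchors A `cardinal_anchors` object.
#' @return Numeric scalar in `[-2, 2]`.
#' @export
linguistic_latitude <- function(v, anchors) {
  stopifnot(inherits(anchors, "cardinal_anchors"))
  cosine(v, anchors$vectors$north) - cosine(v, anchors$vectors$south)
}

#' @rdname linguistic_latitude
#' @export
linguistic_longitude <- function(v, anchors) {
  stopifnot(inherits(anchors, "cardinal_anchors"))
  cosine(v, anchors$vectors$east) - cosine(v, anchors$vectors$west)
}

#' Assemble the pairwise analysis table
#'
#' One row per unordered station pair, carrying the great-circle geographic
#' distance in km and the linguistic distance between the two station
#' labels. Station-label resolution provenance (exact vs subword) is
#' recorded per station in the `"resolution"` attribute. The table is only
#' returned complete: any unresolvable label aborts the build.
#'
#' @param stations Station data frame (`id,name,city,lat,lon`).
#' @param store An `embedding_store` holding station-label vectors.
#' @param table Optional `subword_table` for out-of-vocabulary labels.
#' @param radius_km Sphere radius for [haversine_km()].
#' @return Data frame `station_i, station_j, city, geo_km, ling_dist` with
#'   `n(n-1)/2` rows and attribute `resolution` (named character vector).
#' @export
build_pair_table <- function(stations, store, table = NULL,
                             radius_km = 6371.0088) {
  stations <- validate_stations(stations)
  vecs <- stats::setNames(
    lapply(stations$name, function(nm) get_label_vector(store, nm, table)),
    stations$id)
  resolution <- vapply(vecs, attr, character(1L), "provenance")
  pairs <- all_pairs(stations)
  rowof <- stats::setNames(seq_len(nrow(stations)), stations$id)
  i <- rowof[pairs$station_i]
  j <- rowof[pairs$station_j]
  pairs$city <- ifelse(stations$city[i] == stations$city[j],
                       stations$city[i], NA_character_)
  pairs$geo_km <- haversine_km(stations$lat[i], stations$lon[i],
                               stations$lat[j], stations$lon[j],
                               radius_km = radius_km)
  pairs$ling_dist <- vapply(seq_len(nrow(pairs)), function(r) {
    vi <- vecs[[pairs$station_i[r]]]
    vj <- vecs[[pairs$station_j[r]]]
    tryCatch(1 - cosine(vi, vj), error = function(e) {
      stop("linguistic distance undefined for pair ('", pairs$station_i[r],
           "', '", pairs$station_j[r], "'): ", conditionMessage(e),
           call. = FALSE)
    })
  }, numeric(1L))
  attr(pairs, "resolution") <- resolution
  pairs
}

#' Assemble the per-station coordinate table
#'
#' One row per station with geographic coordinates, linguistic latitude and
#' longitude from the cardinal anchors, and city-level z-transformed
#' geographic coordinates.
#'
#' @param stations Station data frame.
#' @param store An `embedding_store`.
#' @param anchors A `cardinal_anchors` object, or a named list of one per
#'   city (names = city labels) when cities use different languages.
#' @param table Optional `subword_table`.
#' @return Data frame `id, city, geo_lat, geo_lon, ling_lat, ling_lon,
#'   z_geo_lat, z_geo_lon`.
#' @export
build_coordinate_table <- function(stations, store, anchors, table = NULL) {
  stations <- validate_stations(stations)
  per_city <- !inherits(anchors, "cardinal_anchors")
  if (per_city) {
    stopifnot(all(unique(stations$city) %in% names(anchors)))
  }
  ll <- t(vapply(seq_len(nrow(stations)), function(r) {
    v <- get_label_vector(store, stations$name[r], table)
    a <- if (per_city) anchors[[stations$city[r]]] else anchors
    c(linguistic_latitude(v, a), linguistic_longitude(v, a))
  }, numeric(2L)))
  out <- data.frame(id = stations$id, city = stations$city,
                    geo_lat = stations$lat, geo_lon = stations$lon,
                    ling_lat = ll[, 1L], ling_lon = ll[, 2L],
                    stringsAsFactors = FALSE)
  out$z_geo_lat <- zscore_within(out$geo_lat, out$city)
  out$z_geo_lon <- zscore_within(out$geo_lon, out$city)
  out
}
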