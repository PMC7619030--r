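#' Configuration for the synthetic city / embedding generator
#'
#' Bundles the latent-structure parameters under which synthetic embedding
#' spaces are generated: a spatial-signal weight `alpha` mixing planar
#' position into the vectors, a shared base direction of weight
#' `base_weight` (so that cosine distance tracks planar proximity rather
#' than pure direction), station noise `sigma`, anchor noise `tau`, and a
#' polysemy contamination probability under which a station's spatial
#' signal is attenuated to `alpha / 10` (contaminated meanings stay weakly
#' informative). Identical config and seed give bit-identical output; a
#' single root seed feeds named substreams (city, space, anchors) so the
#' components can be varied independently.
#'
#' @param n_stations Number of stations (>= 2). Default 120.
#' @param dim Embedding dimensionality (>= 3). Default 50.
#' @param alpha Spatial-signal weight in `[0, 1]`. Default 0.9.
#' @param base_weight Shared-direction weight `c > 0`. Default 3.
#' @param sigma Station noise sd (>= 0). Default 0.05.
#' @param tau Anchor noise sd (>= 0). Default 0.05.
#' @param polysemy_prob Contamination probability in `[0, 1]`. Default 0.1.
#' @param multiword_frac Fraction of stations given two-word labels with an
#'   internal space. Default 0.2.
#' @param extent Half-width of the coordinate square, degrees. Default 0.15.
#' @param center Latitude/longitude of the city centre. Default a Milan-like
#'   `c(45.4642, 9.19)`.
#' @param city City label. @param language Anchor-word language code.
#' @param name_offset Integer offset into the deterministic name sequence
#'   (used to keep labels disjoint across multi-city datasets).
#' @param seed Root seed (integer).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_stations = 120L, dim = 50L, alpha = 0.9,
                         base_weight = 3, sigma = 0.05, tau = 0.05,
                         polysemy_prob = 0.1, multiword_frac = 0.2,
                         extent = 0.15, center = c(45.4642, 9.19),
                         city = "Synthia", language = "it",
                         name_offset = 0L, seed = 1L) {
  stopifnot(n_stations >= 2L, dim >= 3L, alpha >= 0, alpha <= 1,
            base_weight > 0, sigma >= 0, tau >= 0,
            polysemy_prob >= 0, polysemy_prob <= 1,
            multiword_frac >= 0, multiword_frac <= 1,
            extent >= 0, length(center) == 2L)
  check_lonlat(center[1L], center[2L])
  structure(list(n_stations = as.integer(n_stations), dim = as.integer(dim),
                 alpha = alpha, base_weight = base_weight, sigma = sigma,
                 tau = tau, polysemy_prob = polysemy_prob,
                 multiword_frac = multiword_frac, extent = extent,
                 center = center, city = city, language = language,
                 name_offset = as.integer(name_offset),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# substream seeds derived once from the root seed
synth_substreams <- function(config) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  setNames(sample.int(2147483646L, 3L), c("city", "space", "anchors"))
}

# deterministic pronounceable label for a station index
synth_name <- function(k) {
  syl <- c("ba", "be", "bi", "bo", "bu", "da", "de", "di", "do", "du",
           "ka", "ke", "ki", "ko", "ku", "la", "le", "li", "lo", "lu",
           "ma", "me", "mi", "mo", "mu", "na", "ne", "ni", "no", "nu",
           "ra", "re", "ri", "ro", "ru", "sa", "se", "si", "so", "su",
           "ta", "te", "ti", "to", "tu", "va", "ve", "vi", "vo", "vu")
  n <- length(syl)
  k <- k - 1L
  w <- paste0(syl[(k %/% (n * n)) %% n + 1L], syl[(k %/% n) %% n + 1L],
              syl[k %% n + 1L])
  paste0(toupper(substr(w, 1L, 1L)), substr(w, 2L, nchar(w)))
}

#' Generate a synthetic city
#'
#' Stations are placed uniformly over the square `center +/- extent`;
#' labels are unique, deterministic under the seed, pronounceable, and a
#' configured fraction are two-word labels with an internal space (the
#' multi-word case the subword fallback exists for).
#'
#' @param config A `synth_config`.
#' @return Station data frame `id, name, city, lat, lon`.
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  streams <- synth_substreams(config)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(streams[["city"]])
  n <- config$n_stations
  base_idx <- config$name_offset + seq_len(n)
  names1 <- vapply(base_idx, synth_name, character(1L))
  two_word <- stats::runif(n) < config$multiword_frac
  names2 <- vapply(config$name_offset + 200000L + seq_len(n), synth_name,
                   character(1L))
  name <- ifelse(two_word, paste(names1, names2), names1)
  lat <- config$center[1L] + stats::runif(n, -config$extent, config$extent)
  lon <- config$center[2L] + stats::runif(n, -config$extent, config$extent)
  validate_stations(data.frame(
    id = sprintf("%s_%04d", config$city, seq_len(n)),
    name = name, city = config$city, lat = lat, lon = lon,
    stringsAsFactors = FALSE))
}

#' Generate a synthetic embedding space for a city
#'
#' Draws three mutually orthonormal latent directions in `dim` dimensions —
#' a shared base `u0`, a latitude axis `uN` and a longitude axis `uE` — and
#' builds each station vector as
#' `normalize(c u0 + a_k (lambda_k uN + phi_k uE) + sigma eps_k)`, where
#' `lambda_k, phi_k` are the station coordinates rescaled to `[-1, 1]`,
#' `eps_k` is standard normal per coordinate scaled by `1/sqrt(dim)`, and
#' `a_k` is `alpha`, attenuated to `alpha / 10` with probability
#' `polysemy_prob` (polysemy contamination). Cardinal anchors are noisy
#' antipodal copies of the axes, `normalize(+/- uN + tau zeta)` and
#' `normalize(+/- uE + tau zeta)`. Anchor words of the configured language
#' are inserted into the store so that anchors resolve through the same
#' lookup machinery as station labels.
#'
#' @param stations Station table from [generate_city()].
#' @param config A `synth_config`.
#' @return List with `store` (an `embedding_store`), `anchors` (a
#'   `cardinal_anchors`), and `truth` (latent axes, rescaled coordinates,
#'   per-station signal weights, contamination mask).
#' @export
generate_embedding_space <- function(stations, config) {
  stopifnot(inherits(config, "synth_config"))
  streams <- synth_substreams(config)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  n <- nrow(stations)
  d <- config$dim

  set.seed(streams[["space"]])
  Q <- qr.Q(qr(matrix(stats::rnorm(d * 3L), d, 3L)))
  u0 <- Q[, 1L]; uN <- Q[, 2L]; uE <- Q[, 3L]
  lambda <- if (config$extent > 0) {
    (stations$lat - config$center[1L]) / config$extent
  } else rep(0, n)
  phi <- if (config$extent > 0) {
    (stations$lon - config$center[2L]) / config$extent
  } else rep(0, n)
  contaminated <- stats::runif(n) < config$polysemy_prob
  a_k <- ifelse(contaminated, config$alpha / 10, config$alpha)
  eps <- matrix(stats::rnorm(n * d), n, d) / sqrt(d)
  Vmat <- config$base_weight * matrix(u0, n, d, byrow = TRUE) +
    a_k * (outer(lambda, uN) + outer(phi, uE)) +
    config$sigma * eps
  Vmat <- Vmat / sqrt(rowSums(Vmat^2))
  rownames(Vmat) <- stations$name

  set.seed(streams[["anchors"]])
  noisy_axis <- function(axis) {
    v <- axis + config$tau * stats::rnorm(d) / sqrt(d)
    v / sqrt(sum(v^2))
  }
  anchor_vecs <- list(north = noisy_axis(uN), south = noisy_axis(-uN),
                      east = noisy_axis(uE), west = noisy_axis(-uE))
  words <- default_anchor_words(config$language)
  entries <- c(stats::setNames(lapply(seq_len(n), function(i) Vmat[i, ]),
                               stations$name),
               stats::setNames(anchor_vecs[c("north", "south", "east", "west")],
                               unlist(words[c("north", "south", "east", "west")])))
  store <- embedding_store(entries)
  anchors <- cardinal_anchors(store, words, language = config$language)
  list(store = store, anchors = anchors,
       truth = list(u0 = u0, uN = uN, uE = uE, lambda = lambda, phi = phi,
                    a_k = a_k, contaminated = contaminated, config = config))
}

#' Generate a complete synthetic city bundle
#'
#' @param config A `synth_config`.
#' @return List `stations, store, anchors, truth` (a synthetic city whose
#'   every station label is resolvable in the store).
#' @export
generate_synth_city <- function(config) {
  stations <- generate_city(config)
  space <- generate_embedding_space(stations, config)
  c(list(stations = stations), space)
}

#' Generate several synthetic cities as one dataset
#'
#' @param sizes Named integer vector: city label -> station count.
#' @param seed Root seed; city `i` uses `seed + i - 1` and a disjoint
#'   label range.
#' @param ... Overrides passed to [synth_config()] for every city.
#' @return List with combined `stations` data frame, a merged `store`, and
#'   per-city `anchors` / `truth` lists.
#' @export
generate_synth_cities <- function(sizes, seed = 1L, ...) {
  stopifnot(length(sizes) >= 1L, !is.null(names(sizes)))
  out <- lapply(seq_along(sizes), function(i) {
    cfg <- synth_config(n_stations = sizes[[i]], city = names(sizes)[[i]],
                        name_offset = (i - 1L) * 20000L,
                        seed = seed + i - 1L, ...)
    generate_synth_city(cfg)
  })
  stations <- do.call(rbind, lapply(out, `[[`, "stations"))
  entries <- do.call(c, lapply(out, function(ct) ct$store$entries))
  entries <- entries[!duplicated(names(entries))]  # shared anchor words
  list(stations = validate_stations(stations),
       store = embedding_store(entries),
       anchors = setNames(lapply(out, `[[`, "anchors"), names(sizes)),
       truth = setNames(lapply(out, `[[`, "truth"), names(sizes)))
}

#' Run a full synthetic-recovery experiment
#'
#' `which = "exp1"` generates a city, builds the pairwise table, and fits
#' the crossed random-intercept model of geographic on linguistic distance;
#' `which = "exp2"` builds the coordinate table and regresses city-level
#' z-scored geographic latitude (and longitude) on linguistic latitude
#' (longitude). Deterministic under the config seed.
#'
#' @param config A `synth_config`.
#' @param which `"exp1"` (pairwise distances) or `"exp2"` (coordinates).
#' @return List with `city` (the bundle), the fitted `lingmap_fit`(s), and
#'   `recovery` — a one-row data frame of the headline estimates alongside
#'   the generating truth.
#' @export
simulate_experiment <- function(config, which = c("exp1", "exp2")) {
  which <- match.arg(which)
  city <- generate_synth_city(config)
  if (which == "exp1") {
    pairs <- build_pair_table(city$stations, city$store)
    fit <- fit_crossed_lmm(pairs$geo_km, pairs$ling_dist,
                           id1 = pairs$station_i, id2 = pairs$station_j)
    sl <- fit$fixed[fit$fixed$term == ".x", ]
    recovery <- data.frame(experiment = "exp1", alpha = config$alpha,
                           slope = sl$b, se = sl$se, z = sl$z, beta = sl$beta,
                           boundary = fit$fit$boundary)
    list(city = city, pairs = pairs, fit = fit, recovery = recovery)
  } else {
    coords <- build_coordinate_table(city$stations, city$store, city$anchors)
    fit_lat <- fit_lm_interaction(coords$z_geo_lat, coords$ling_lat, coords$city)
    fit_lon <- fit_lm_interaction(coords$z_geo_lon, coords$ling_lon, coords$city)
    recovery <- data.frame(
      experiment = "exp2", alpha = config$alpha,
      lat_slope = fit_lat$fixed$b[fit_lat$fixed$term == ".x"],
      lat_r2 = fit_lat$fit$r_squared,
      lon_slope = fit_lon$fixed$b[fit_lon$fixed$term == ".x"],
      lon_r2 = fit_lon$fit$r_squared)
    list(city = city, coords = coords, fit_lat = fit_lat, fit_lon = fit_lon,
         recovery = recovery)
  }
}
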