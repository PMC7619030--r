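test_that("generation is deterministic and respects the configuration", {
  cfg <- synth_config(n_stations = 107, seed = 42)
  st1 <- generate_city(cfg)
  st2 <- generate_city(cfg)
  expect_identical(st1, st2)
  expect_equal(nrow(st1), 107L)
  expect_equal(nrow(all_pairs(st1)), 5671L)
  expect_false(anyDuplicated(st1$name) > 0)
  expect_true(any(grepl(" ", st1$name)))   # multi-word labels present
  expect_true(all(abs(st1$lat - 45.4642) <= 0.15))

  city1 <- generate_synth_city(cfg)
  city2 <- generate_synth_city(cfg)
  p1 <- withr::local_tempfile(fileext = ".vec")
  p2 <- withr::local_tempfile(fileext = ".vec")
  write_vec_file(city1$store, p1)
  write_vec_file(city2$store, p2)
  expect_identical(readLines(p1), readLines(p2))

  # a different seed changes the coordinates
  expect_false(isTRUE(all.equal(generate_city(synth_config(seed = 43))$lat,
                                generate_city(synth_config(seed = 44))$lat)))

  # degenerate extent collapses all stations onto the centre
  st0 <- generate_city(synth_config(n_stations = 10, extent = 0, seed = 1))
  expect_equal(nrow(unique(st0[, c("lat", "lon")])), 1L)
})

test_that("noise-free spaces encode position signs and circle monotonicity", {
  # alpha = 1, no noise, no contamination: latitude sign is recovered exactly
  cfg <- synth_config(n_stations = 80, alpha = 1, sigma = 0, tau = 0,
                      polysemy_prob = 0, seed = 9)
  city <- generate_synth_city(cfg)
  lat_hat <- vapply(city$stations$name, function(nm) {
    linguistic_latitude(get_label_vector(city$store, nm), city$anchors)
  }, numeric(1L))
  expect_true(all(sign(lat_hat) == sign(city$truth$lambda)))

  # stations at a common radius: cosine distance increases with chord length
  theta <- seq(0, 2 * pi, length.out = 22)[-22]
  circle <- data.frame(
    id = sprintf("c%02d", seq_along(theta)),
    name = sprintf("C%02d", seq_along(theta)), city = "ring",
    lat = 45.4642 + 0.1 * sin(theta), lon = 9.19 + 0.1 * cos(theta),
    stringsAsFactors = FALSE)
  sp <- generate_embedding_space(circle, synth_config(
    n_stations = 21, alpha = 0.8, sigma = 0, tau = 0, polysemy_prob = 0,
    seed = 9))
  v1 <- get_label_vector(sp$store, "C01")
  # half arc only: beyond pi the chord shortens again and ties appear
  half <- 2:11
  ling <- vapply(sprintf("C%02d", half), function(nm) {
    1 - cosine(v1, get_label_vector(sp$store, nm))
  }, numeric(1L))
  chord <- vapply(half, function(k) {
    sqrt((sin(theta[k]) - sin(theta[1]))^2 + (cos(theta[k]) - cos(theta[1]))^2)
  }, numeric(1L))
  expect_true(all(diff(chord) > 0))
  expect_true(all(diff(ling) > 0))
})

test_that("without spatial signal, linguistic and geographic distance decouple", {
  cors <- vapply(1:200, function(s) {
    city <- generate_synth_city(synth_config(n_stations = 20, alpha = 0,
                                             seed = 1000 + s))
    tab <- build_pair_table(city$stations, city$store)
    pearson_r(tab$ling_dist, tab$geo_km)
  }, numeric(1L))
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("reflecting the city negates the linguistic coordinates exactly", {
  cfg <- synth_config(n_stations = 40, sigma = 0, tau = 0, polysemy_prob = 0,
                      seed = 17)
  st <- generate_city(cfg)
  sp <- generate_embedding_space(st, cfg)
  mirrored <- st
  mirrored$lat <- 2 * cfg$center[1] - st$lat
  mirrored$lon <- 2 * cfg$center[2] - st$lon
  spm <- generate_embedding_space(mirrored, cfg)
  for (nm in st$name[1:10]) {
    expect_equal(
      linguistic_latitude(get_label_vector(spm$store, nm), spm$anchors),
      -linguistic_latitude(get_label_vector(sp$store, nm), sp$anchors),
      tolerance = 1e-12)
    expect_equal(
      linguistic_longitude(get_label_vector(spm$store, nm), spm$anchors),
      -linguistic_longitude(get_label_vector(sp$store, nm), sp$anchors),
      tolerance = 1e-12)
  }
})

test_that("recovered distance signal grows with the spatial-signal weight", {
  # standardized slope: the raw km-per-cosine-unit slope is scale-dependent
  # in alpha by construction (linguistic distances themselves scale with
  # alpha), so recovery strength is compared on the standardized scale.
  # sigma = 1 keeps the sweep away from the recovery ceiling.
  alphas <- c(0, 0.25, 0.5, 0.75, 1)
  nseed <- 50
  betas <- matrix(NA_real_, nseed, length(alphas))
  for (s in seq_len(nseed)) {
    for (k in seq_along(alphas)) {
      sim <- simulate_experiment(
        synth_config(n_stations = 40, alpha = alphas[k], sigma = 1,
                     seed = 5000 + s), "exp1")
      betas[s, k] <- sim$recovery$beta
    }
  }
  mu <- colMeans(betas)
  mcse <- apply(betas, 2, sd) / sqrt(nseed)
  # non-decreasing in alpha, allowing one inversion within Monte-Carlo error
  diffs <- diff(mu)
  bad <- which(diffs < 0)
  expect_lte(length(bad), 1L)
  for (kk in bad) {
    expect_lte(abs(diffs[kk]), sqrt(mcse[kk]^2 + mcse[kk + 1]^2))
  }
})

test_that("polysemy contamination degrades coordinate recovery", {
  r2 <- function(prob, s) {
    sim <- simulate_experiment(
      synth_config(n_stations = 80, polysemy_prob = prob, seed = 7000 + s),
      "exp2")
    sim$recovery$lat_r2
  }
  clean <- vapply(1:50, function(s) r2(0, s), numeric(1L))
  noisy <- vapply(1:50, function(s) r2(0.5, s), numeric(1L))
  expect_lt(mean(noisy), mean(clean))
})
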