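test_that("noise-free placement puts every site exactly on its layer line", {
  g <- build_geometry(list(preset = "two_layer", delta = 60, length = 4000,
                           site_linear_density = 200,
                           membrane_jitter_sigma = 0))
  s <- place_binding_sites(g, 1, 0, seed = 3)
  ya <- layer_polyline(g, 1)[1, "y"]
  yb <- layer_polyline(g, 2)[1, "y"]
  expect_lt(max(abs(s$y[s$species_id == 0] - ya)), 1e-6)
  expect_lt(max(abs(s$y[s$species_id == 1] - yb)), 1e-6)
  # ~800 expected sites per 4 um ribbon at 200 / um
  expect_gt(min(table(s$species_id)), 650)
  expect_lt(max(table(s$species_id)), 950)
})

test_that("labeling efficiency thins the Poisson site process as expected", {
  g <- build_geometry(list(preset = "two_layer", delta = 60, length = 4000,
                           site_linear_density = 200))
  counts <- vapply(1:50, function(sd)
    sum(place_binding_sites(g, 0.5, 0, seed = sd)$species_id == 0),
    numeric(1))
  # mean of 50 runs: Poisson(800) thinned to mean 400; compare within
  # 3 x sd of the mean estimate (var = 400 per run)
  expect_lt(abs(mean(counts) - 400), 3 * sqrt(400 / 50))
})

test_that("linkage error adds the nominal Gaussian spread", {
  g <- build_geometry(list(preset = "two_layer", delta = 60, length = 4000,
                           site_linear_density = 200,
                           membrane_jitter_sigma = 0))
  ya <- layer_polyline(g, 1)[1, "y"]
  res <- unlist(lapply(1:20, function(sd) {
    s <- place_binding_sites(g, 1, 6, seed = sd)
    s$y[s$species_id == 0] - ya
  }))
  expect_lt(abs(sd(res) - 6) / 6, 0.05)
})

test_that("perfect erasure keeps every round pure and blinking is deterministic per seed", {
  g <- build_geometry(list(preset = "two_layer", delta = 60))
  s <- place_binding_sites(g, 1, 0, seed = 4)
  p <- imaging_params(n_rounds = 2, frames_per_round = 2000,
                      eraser_residual = 0)
  ev <- simulate_rounds(s, p, seed = 5)
  expect_true(all(ev$species_id == ev$round))
  expect_identical(ev, simulate_rounds(s, p, seed = 5))
  expect_true(all(ev$start_frame + ev$n_frames <= p$frames_per_round))
  expect_error(simulate_rounds(s, imaging_params(n_rounds = 2,
                                                 eraser_residual = 1)),
               "eraser_residual")
})

test_that("event rate matches the renewal-theory expectation", {
  g <- build_geometry(list(preset = "two_layer", delta = 60, length = 2500,
                           site_linear_density = 200))
  p <- imaging_params(n_rounds = 2, frames_per_round = 3000,
                      mean_dark_frames = 500, mean_bright_frames = 3)
  ratio <- vapply(1:10, function(sd) {
    s <- place_binding_sites(g, 1, 0, seed = sd)
    ev <- simulate_rounds(s, p, seed = sd + 100)
    nrow(ev) / (nrow(s) * 3000 / (500 + 3))
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("imperfect erasure carries earlier species forward at rate ~ eps^(r-s)", {
  g <- build_geometry(list(preset = "golgi7",
                           species = c("GM130", "GRASP65", "VPS13B"),
                           site_linear_density = 250,
                           membrane_jitter_sigma = 0))
  p <- imaging_params(n_rounds = 3, frames_per_round = 3000,
                      eraser_residual = 0.3)
  s <- place_binding_sites(g, 1, 0, seed = 6)
  ev <- simulate_rounds(s, p, seed = 7)
  n_sites <- as.vector(table(s$species_id))
  # per-site event propensity is identical across species, so the active
  # fraction is estimable from event counts
  r2 <- ev[ev$round == 2, ]
  frac1 <- sum(r2$species_id == 1) / n_sites[2]
  frac0 <- sum(r2$species_id == 0) / n_sites[1]
  rate <- sum(r2$species_id == 2) / n_sites[3]
  expect_lt(abs(frac1 / rate - 0.3), 0.08)
  expect_lt(abs(frac0 / rate - 0.09), 0.05)
  expect_gt(frac1, frac0)  # contamination decays with round distance
})

test_that("drift simulation anchors frame zero and follows the requested ramp", {
  d0 <- simulate_drift(3000, 0, c(0, 0), seed = 1)
  expect_true(all(d0$dx == 0) && all(d0$dy == 0))
  d1 <- simulate_drift(3000, 0, c(0.01, 0), seed = 1)
  expect_equal(d1$dx[1], 0)
  expect_equal(d1$dx[3000], 29.99)
  expect_equal(d1$dy[3000], 0)
  finals <- vapply(1:100, function(sd)
    unlist(simulate_drift(3000, 0.05, c(0, 0), seed = sd)[3000, ]),
    numeric(2))
  expect_lt(abs(sd(finals[1, ]) - 0.05 * sqrt(2999)) / (0.05 * sqrt(2999)),
            0.15)
  expect_lt(abs(sd(finals[2, ]) - 0.05 * sqrt(2999)) / (0.05 * sqrt(2999)),
            0.15)
})

test_that("list-mode localizations track site, drift and photon noise", {
  g <- build_geometry(list(preset = "two_layer", delta = 60,
                           site_linear_density = 50))
  s <- place_binding_sites(g, 1, 0, seed = 8)
  p <- imaging_params(n_rounds = 2, frames_per_round = 3000)
  ev <- simulate_rounds(s, p, seed = 9)
  # high-photon limit: localization essentially at site + drift
  ev_hi <- ev
  ev_hi$total_photons <- 1e6
  dr0 <- simulate_drift(6000, 0, c(0, 0), seed = 1)
  tab <- events_to_localizations(ev_hi, s, dr0, p, seed = 10)
  err <- sqrt((tab$x - s$x[tab$site_index])^2 +
              (tab$y - s$y[tab$site_index])^2)
  expect_lt(max(err), 1)
  # injected linear drift appears as the same slope in x(frame)
  dr <- simulate_drift(6000, 0, c(0.02, 0), seed = 2)
  tab2 <- events_to_localizations(ev_hi, s, dr, p, seed = 11)
  one <- tab2[tab2$site_index == tab2$site_index[1], ]
  if (nrow(one) >= 5) {
    slope <- coef(lm(one$x ~ one$frame))[2]
    expect_lt(abs(slope - 0.02) / 0.02, 0.05)
  }
  # sigma_loc formula: sd over many 400-photon events approx 130/sqrt(400)
  ev400 <- ev[rep(1, 10000), ]
  ev400$total_photons <- 400
  tab3 <- events_to_localizations(ev400, s, dr0, p, seed = 12)
  expect_lt(abs(sd(tab3$x) - 6.5) / 6.5, 0.05)
  expect_lt(abs(sd(tab3$y) - 6.5) / 6.5, 0.05)
})

test_that("zero-photon events are dropped with a counted warning and totals conserve", {
  g <- build_geometry(list(preset = "two_layer", delta = 60,
                           site_linear_density = 50))
  s <- place_binding_sites(g, 1, 0, seed = 13)
  p <- imaging_params(n_rounds = 2, frames_per_round = 1000,
                      photons_per_frame = 0.5, mean_bright_frames = 1)
  ev <- simulate_rounds(s, p, seed = 14)
  dr <- simulate_drift(2000, 0, c(0, 0), seed = 1)
  expect_warning(tab <- events_to_localizations(ev, s, dr, p, seed = 15),
                 "zero-photon")
  expect_equal(nrow(tab), sum(ev$total_photons > 0))
  expect_equal(attr(tab, "n_dropped_zero_photon"),
               sum(ev$total_photons == 0))
})

test_that("the generator is bit-reproducible given config and seed", {
  run <- function() {
    g <- build_geometry(list(preset = "golgi7"))
    s <- place_binding_sites(g, 0.8, 6, seed = 21)
    p <- imaging_params(n_rounds = 7, frames_per_round = 1000)
    ev <- simulate_rounds(s, p, seed = 22)
    dr <- simulate_drift(7000, 0.05, c(0.01, 0), seed = 23)
    list(s, ev, dr, events_to_localizations(ev, s, dr, p, seed = 24))
  }
  expect_identical(run(), run())
})
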