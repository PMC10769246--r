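test_that("hand-computable nn distances with self-exclusion and the cutoff semantics", {
  pts <- data.frame(x = c(0, 0, 0), y = c(0, 30, 300))
  d <- cross_distances(pts, pts, proximity_params(500, "nn"), self = TRUE)
  expect_equal(sort(as.numeric(d)), c(30, 30, 270))
  # two points 501 nm apart: cutoff is inclusive <= 500, so empty
  a <- data.frame(x = 0, y = 0); b <- data.frame(x = 501, y = 0)
  expect_length(cross_distances(a, b, proximity_params(500, "nn")), 0)
  b2 <- data.frame(x = 500, y = 0)
  expect_equal(as.numeric(cross_distances(a, b2, proximity_params(500, "nn"))),
               500)
  # empty inputs are flagged
  e <- cross_distances(data.frame(x = numeric(0), y = numeric(0)), b,
                       proximity_params())
  expect_true(attr(e, "empty_input"))
})

test_that("accelerated search equals the exhaustive scan in both modes", {
  for (sd in 1:20) {
    set.seed(sd)
    na <- sample(100:500, 1); nb <- sample(100:500, 1)
    A <- data.frame(x = runif(na, 0, 1500), y = runif(na, 0, 1500))
    B <- data.frame(x = runif(nb, 0, 1500), y = runif(nb, 0, 1500))
    nn_pkg <- cross_distances(A, B, proximity_params(500, "nn"))
    nn_ora <- brute_nn(A, B)
    expect_identical(sort(as.numeric(nn_pkg)),
                     sort(nn_ora[nn_ora <= 500]))
    ap_pkg <- cross_distances(A, B, proximity_params(500, "all_pairs"))
    ap_ora <- brute_pairs_within(A, B, 500)
    expect_identical(sort(as.numeric(ap_pkg)), sort(as.numeric(ap_ora)))
    # self mode on one table
    self_pkg <- cross_distances(A, A, proximity_params(500, "nn"),
                                self = TRUE)
    self_ora <- brute_nn(A, A, self = TRUE)
    expect_identical(sort(as.numeric(self_pkg)),
                     sort(self_ora[self_ora <= 500]))
  }
})

test_that("median_distance follows the even-n convention and flags empty input", {
  expect_equal(median_distance(c(30, 30, 270))$median, 30)
  expect_equal(median_distance(c(10, 20))$median, 15)
  out <- median_distance(numeric(0))
  expect_false(out$defined)
  expect_equal(out$n, 0L)
})

make_two_species_table <- function(n = 300, delta = 60, seed = 1) {
  set.seed(seed)
  mk <- function(sp, y0) data.frame(
    frame = seq_len(n), round = sp,
    x = runif(n, 0, 4000), y = y0 + rnorm(n, 0, 5),
    photons = 676, loc_precision = 5, species = sp)
  as_localization_table(rbind(mk(0L, 0), mk(1L, delta)),
                        frames_per_round = 10000L)
}

test_that("distance_matrix is symmetric in all_pairs mode and flags sparse cells", {
  tab <- make_two_species_table()
  dm <- distance_matrix(tab, proximity_params(500, "all_pairs",
                                              n_boot = 50), seed = 2)
  expect_equal(dm$median[1, 2], dm$median[2, 1])
  expect_equal(dm$n_pairs[1, 2], dm$n_pairs[2, 1])
  # a sparse species triggers the invalid flag, never an omission
  sparse <- as.data.frame(tab)[c(1:300, 301:303), ]
  sparse$species[301:303] <- 1L
  dm2 <- distance_matrix(
    as_localization_table(sparse[c(1:300, 301:303), ],
                          frames_per_round = 10000L),
    proximity_params(500, "nn", min_pairs = 10, n_boot = 0), seed = 3)
  expect_false(dm2$valid[2, 2])
  expect_true(is.na(dm2$median[2, 2]))
})

test_that("nn-median increases monotonically with the true layer separation", {
  meds <- vapply(c(20, 40, 60, 100, 150), function(delta) {
    tab <- make_two_species_table(n = 800, delta = delta, seed = 7)
    A <- as.data.frame(tab)[tab$species == 0, c("x", "y")]
    B <- as.data.frame(tab)[tab$species == 1, c("x", "y")]
    median(cross_distances(A, B, proximity_params(500, "nn")))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("the nn-median at zero separation equals the noise-floor oracle, not zero", {
  # identical layers: the statistic's bias floor is set by localization
  # noise and site density; compare to the generative Monte-Carlo oracle
  sim <- sim_list_mode(
    list(preset = "two_layer", delta = 0, length = 4000,
         site_linear_density = 200, membrane_jitter_sigma = 0),
    list(n_rounds = 2, frames_per_round = 3000, mean_bright_frames = 1,
         mean_dark_frames = 500, photons_per_frame = 676), seed = 71)
  tab <- sim$table
  A <- as.data.frame(tab)[tab$species == 0, c("x", "y")]
  B <- as.data.frame(tab)[tab$species == 1, c("x", "y")]
  med <- median(cross_distances(A, B, proximity_params(500, "nn")))
  oracle <- two_layer_nn_oracle(20000, delta = 0, density_per_nm = 0.2,
                                frames = 3000, m_dark = 500, m_bright = 1,
                                photon_mean = 676, seed = 72, win = 150)
  expect_gt(med, 2)                      # clearly not zero
  expect_lt(abs(med - oracle), 1)
})

test_that("rank_targets sorts ascending, keeps ties stable and lists invalid last", {
  dm <- structure(list(
    labels = c("ref", "a", "b", "c"),
    median = matrix(c(NA, 50, 20, 20,
                      50, NA, 1, 1,
                      20, 1, NA, 1,
                      20, 1, 1, NA), 4, 4, byrow = TRUE,
                    dimnames = rep(list(c("ref", "a", "b", "c")), 2)),
    n_pairs = matrix(100, 4, 4),
    ci_low = matrix(NA_real_, 4, 4), ci_high = matrix(NA_real_, 4, 4),
    valid = matrix(TRUE, 4, 4),
    params = proximity_params()), class = "distance_matrix")
  rk <- rank_targets(dm, "ref")
  expect_equal(rk$species, c("b", "c", "a"))   # tie b/c kept in panel order
  dm$valid[1, 3] <- FALSE
  rk2 <- rank_targets(dm, "ref")
  expect_equal(rk2$species[3], "b")
  expect_false(rk2$valid[3])
})

test_that("bootstrap CIs cover the long-run median at roughly nominal rate", {
  # long-run median of the fixed configuration, from one large independent
  # generative-oracle run
  truth <- two_layer_nn_oracle(40000, delta = 60, density_per_nm = 0.1,
                               frames = 1500, m_dark = 500, m_bright = 1,
                               photon_mean = 676, seed = 80, win = 250)
  hits <- 0L
  n_rep <- 200L
  for (rep in seq_len(n_rep)) {
    sim <- sim_list_mode(
      list(preset = "two_layer", delta = 60, length = 4000,
           site_linear_density = 100, membrane_jitter_sigma = 0),
      list(n_rounds = 2, frames_per_round = 1500, mean_bright_frames = 1,
           mean_dark_frames = 500, photons_per_frame = 676),
      seed = 1000 + rep)
    dm <- distance_matrix(sim$table,
                          proximity_params(500, "nn", n_boot = 200),
                          seed = 2000 + rep)
    if (dm$ci_low[1, 2] <= truth && truth <= dm$ci_high[1, 2])
      hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.90)
  expect_lte(hits / n_rep, 0.98)
})
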