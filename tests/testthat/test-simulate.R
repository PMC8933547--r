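test_that("emitter layouts respect separation, bounds and determinism", {
  e1 <- generate_emitters(1, 10, seed = 3)
  e2 <- generate_emitters(1, 10, seed = 3)
  expect_identical(e1$positions, e2$positions)
  expect_true(all(is.finite(e1$positions)))

  em <- generate_emitters(5, 40, min_separation = 10, seed = 7)
  d <- as.matrix(stats::dist(em$positions))
  expect_true(all(d[upper.tri(d)] >= 10))
  expect_true(all(sqrt(rowSums(em$positions^2)) <= 40))

  ring <- generate_emitters(6, 15, layout = "ring", seed = 1)
  expect_equal(unname(sqrt(rowSums(ring$positions^2))), rep(15, 6),
               tolerance = 1e-12)

  ch <- generate_emitters(7, 40, min_separation = 2,
                          layout = "connected_chain", chain_step = 8,
                          seed = 5)
  gaps <- sqrt(rowSums((ch$positions[-1, ] - ch$positions[-7, ])^2))
  expect_true(all(gaps < 8))
  expect_true(all(gaps >= 2))

  expect_error(generate_emitters(200, 5, min_separation = 3, seed = 1),
               "over-dense")
  expect_error(generate_emitters(3, 10, layout = "connected_chain",
                                 seed = 1),
               "chain_step")
})

test_that("co-located emitters share a fingerprint; shifts are encoded", {
  pr <- fingerprint_pair(c(0, 0), seed = 11)
  expect_equal(pr$w1, pr$w2, tolerance = 1e-8)
  expect_equal(corr_at_lag(pr$w1, pr$w2, 0, 0), 1, tolerance = 1e-8)

  # separation (5, -3) inside a generous ME range: brute-force correlation
  # of the displaced emitter against the reference must peak at (5, -3)
  pr <- fingerprint_pair(c(5, -3), seed = 12, n = 64, me = 30)
  bf <- bruteforce_argmax_lag(pr$w2, pr$w1, window = 8)
  expect_equal(bf$lag, c(5, -3))
  expect_gt(bf$value, 0.7)
  # and the FFT path agrees with the brute-force oracle
  expect_equal(crosscorr_shift(pr$w2, pr$w1)$lag, c(5L, -3L))
})

test_that("fingerprints are fully developed speckle", {
  for (s in 1:4) {
    pr <- fingerprint_pair(c(4, 2), seed = 80 + s)
    for (w in list(pr$w1, pr$w2)) {
      ctr <- stats::sd(w) / mean(w)
      expect_gt(ctr, 0.6)
      expect_lt(ctr, 1.1)
    }
  }
})

test_that("correlation peak translates with the emitter (ME property)", {
  for (s in 1:10) {
    set.seed(s)
    base <- c(sample(-3:3, 1), sample(-3:3, 1))
    delta <- c(sample(1:4, 1), sample(-4:-1, 1))
    cfg <- optical_config(48, 48, 3, 24, seed = 300 + s)
    em <- emitters_at(rbind(c(0, 0), base, base + delta))
    fp <- synthesize_fingerprints(em, cfg)$fingerprints
    w1 <- matrix_frame(fp[, 1], 48, 48)
    l2 <- crosscorr_shift(matrix_frame(fp[, 2], 48, 48), w1)$lag
    l3 <- crosscorr_shift(matrix_frame(fp[, 3], 48, 48), w1)$lag
    expect_equal(l3 - l2, delta)
  }
})

test_that("fingerprint correlation decays monotonically with separation", {
  me <- 10
  seps <- c(0.5, 1, 2, 4) * me
  means <- vapply(seps, function(d) {
    pk <- vapply(1:50, function(s) {
      th <- 2 * pi * s / 50
      pr <- fingerprint_pair(c(d * cos(th), d * sin(th)),
                             seed = 1000 + round(100 * d) + s, me = me)
      cs <- crosscorr_shift(pr$w1, pr$w2)
      cs$peak
    }, numeric(1))
    mean(pk)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_gt(means[1], 0.7)     # well within the ME range
  expect_lt(means[4], 0.2)     # far beyond it
  # calibration point: intensity correlation ~0.5 at d = me_range
  expect_equal(means[2], 0.5, tolerance = 0.1)
})

test_that("illumination weights have speckle statistics", {
  cfg <- optical_config(48, 48, 3, 12, seed = 21)
  h <- synthesize_weights(1, 100, "iid_exponential", cfg)
  # unit-mean exponential: SE of the mean is 1/sqrt(T)
  expect_lt(abs(mean(h) - 1), 3 / sqrt(100))
  expect_true(all(h >= 0))

  em <- emitters_at(rbind(c(0, 0), c(0.3, 0)))   # 0.1 grain apart
  hs <- synthesize_weights(2, 500, "speckle_field", cfg, em)
  expect_true(all(hs >= 0))
  expect_gt(stats::cor(hs[1, ], hs[2, ]), 0.9)
  # far-apart emitters get nearly independent weights
  em2 <- emitters_at(rbind(c(0, 0), c(30, 0)))
  hs2 <- synthesize_weights(2, 500, "speckle_field", cfg, em2)
  expect_lt(abs(stats::cor(hs2[1, ], hs2[2, ])), 0.2)
})

test_that("frames realize the linear mixing model exactly when noiseless", {
  sim <- small_rank3_dataset()
  truth <- sim$truth
  H <- truth$config$frame_height; W <- truth$config$frame_width

  # direct evaluation of the superposition for one frame, as the oracle
  t0 <- 57
  manual <- matrix(0, H, W)
  for (k in 1:3)
    manual <- manual + matrix_frame(truth$fingerprints[, k], H, W) *
      truth$weights[k, t0]
  expect_equal(sim$stack$frames[, , t0], manual, tolerance = 1e-12)

  # matrix form: stack == reshape(W %*% H) everywhere
  I <- flatten_stack(sim$stack)
  expect_equal(I, truth$fingerprints %*% truth$weights, tolerance = 1e-12)

  # single emitter with unit weights reproduces its fingerprint verbatim
  cfg <- optical_config(32, 32, 3, 10, seed = 5)
  em <- emitters_at(c(0, 0))
  tr <- synthesize_fingerprints(em, cfg)
  tr$weights <- matrix(1, 1, 7)
  st <- compose_frames(tr, noiseless = TRUE)
  for (t in 1:7)
    expect_equal(st$frames[, , t], matrix_frame(tr$fingerprints[, 1], 32, 32),
                 tolerance = 1e-12)
})

test_that("noise vanishes in the high-photon limit and clips at zero", {
  sim <- small_rank3_dataset()
  tr <- sim$truth
  tr$config$noise_photons <- 1e6
  tr$config$read_noise_sigma <- 0
  tr$weights <- tr$weights[, 1:20]
  noisy <- compose_frames(tr)
  clean <- compose_frames(tr, noiseless = TRUE)
  rel <- sqrt(mean((noisy$frames / max(noisy$frames) -
                    clean$frames / max(clean$frames))^2)) /
         sqrt(mean((clean$frames / max(clean$frames))^2))
  expect_lt(rel, 0.01)

  tr$config$noise_photons <- 50
  tr$config$read_noise_sigma <- 5
  lownoise <- compose_frames(tr)
  expect_true(all(lownoise$frames >= 0))
})

test_that("many-emitter frames are low contrast", {
  cfg <- optical_config(48, 48, 3, 40, noise_photons = Inf,
                        read_noise_sigma = 0, seed = 9)
  em <- generate_emitters(10, 15, min_separation = 2, seed = 4)
  sim <- simulate_dataset(em, cfg, 50, noiseless = TRUE)
  fp_contrast <- apply(sim$truth$fingerprints, 2,
                       function(w) stats::sd(w) / mean(w))
  frame_contrast <- apply(sim$stack$frames, 3,
                          function(f) stats::sd(f) / mean(f))
  expect_lt(mean(frame_contrast), min(fp_contrast))
})

test_that("config and shape validation catch bad inputs", {
  expect_error(optical_config(frame_height = 4), ">= 8")
  expect_error(optical_config(grain_size = 0.5), "grain_size")
  expect_error(optical_config(me_range = 2, grain_size = 4), "me_range")
  sim <- small_rank3_dataset()
  tr <- sim$truth
  tr$weights <- tr$weights[1:2, ]
  expect_error(compose_frames(tr), "does not match")
})
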