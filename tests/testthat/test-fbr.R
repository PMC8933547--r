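# a fake pairwise_deconvolution carrying only the fields partial_image needs
fake_deconv <- function(o) structure(list(o = o), class = "pairwise_deconvolution")

test_that("self-deconvolution yields a centred delta of high quality", {
  pr <- fingerprint_pair(c(4, 1), seed = 31)
  pd <- pairwise_deconvolve(pr$w1, pr$w1)
  expect_equal(pd$peak_position, c(0L, 0L))
  expect_gt(pd$quality, 50)
  ctr <- c(floor(48 / 2) + 1, floor(48 / 2) + 1)
  expect_equal(unname(which_max_rc(pd$o)), ctr)
  expect_true(all(pd$o >= 0))
})

test_that("deconvolution of an exactly shifted pair recovers the lag", {
  pr <- fingerprint_pair(c(0, 0), seed = 32)
  for (lag in list(c(5, -3), c(-7, 2), c(0, 9))) {
    wi <- pr$w1[((seq_len(48) - 1 - lag[1]) %% 48) + 1,
                ((seq_len(48) - 1 - lag[2]) %% 48) + 1]
    pd <- pairwise_deconvolve(wi, pr$w1)
    expect_equal(pd$peak_position, as.integer(lag))
    # cross-check against the brute-force correlation argmax oracle
    bf <- bruteforce_argmax_lag(wi, pr$w1, window = 10)
    expect_equal(bf$lag, lag)
    cs <- crosscorr_shift(wi, pr$w1)
    expect_equal(cs$lag, as.integer(lag))
    expect_equal(cs$peak, 1, tolerance = 1e-9)
  }
})

test_that("the TV objective trace is monotone non-increasing", {
  pr <- fingerprint_pair(c(5, 2), seed = 33)
  pd <- pairwise_deconvolve(pr$w1, pr$w2, deconv_config(max_iter = 60))
  tr <- pd$objective_trace
  expect_true(all(diff(tr) <= 0))
})

test_that("beyond-ME pairs produce only low-quality noise", {
  q_within <- vapply(1:6, function(s) {
    pr <- fingerprint_pair(c(4, -3), seed = 600 + s, me = 12)
    pairwise_deconvolve(pr$w1, pr$w2)$quality
  }, numeric(1))
  q_beyond <- vapply(1:6, function(s) {
    pr <- fingerprint_pair(c(30, 25), seed = 700 + s, me = 8)
    pairwise_deconvolve(pr$w1, pr$w2)$quality
  }, numeric(1))
  expect_true(all(q_beyond < 0.3 * stats::median(q_within)))
})

test_that("deconvolution and cross-correlation validate their inputs", {
  pr <- fingerprint_pair(c(2, 2), seed = 34)
  expect_error(pairwise_deconvolve(pr$w1, matrix(0, 48, 48)), "all zero")
  expect_error(pairwise_deconvolve(pr$w1, pr$w2[1:24, ]), "shapes differ")
  expect_error(crosscorr_shift(matrix(1, 8, 8), matrix(1, 8, 8)),
               "zero variance")
})

test_that("partial images are plain sums of the deconvolutions", {
  d1 <- matrix(0, 16, 16); d1[9, 9] <- 1
  d2 <- matrix(0, 16, 16); d2[3, 12] <- 2
  deconvs <- vector("list", 4); dim(deconvs) <- c(2, 2)
  deconvs[[1, 1]] <- fake_deconv(d1); deconvs[[2, 1]] <- fake_deconv(d2)
  deconvs[[1, 2]] <- fake_deconv(d2); deconvs[[2, 2]] <- fake_deconv(d1)
  expect_equal(partial_image(1, deconvs), d1 + d2)
  # all-zero contributions leave the single non-zero image unchanged
  deconvs[[2, 1]] <- fake_deconv(matrix(0, 16, 16))
  expect_equal(partial_image(1, deconvs), d1)
  deconvs[2, 1] <- list(NULL)
  expect_error(partial_image(1, deconvs), "missing")
})

test_that("partial image of a simulated patch shows the local layout", {
  cfg <- optical_config(64, 64, 3, 20, seed = 51)
  off <- rbind(c(0, 0), c(6, 5), c(-5, 7))
  em <- emitters_at(off)
  fp <- synthesize_fingerprints(em, cfg)$fingerprints
  deconvs <- deconvolve_all_pairs(fp, c(64, 64))
  Ok <- partial_image(1, deconvs)
  ctr <- c(floor(64 / 2) + 1, floor(64 / 2) + 1)
  # brute-force local-maximum search: the three tallest peaks sit at the
  # relative offsets r_i - r_1
  for (i in 1:3) {
    want <- ctr + round(off[i, ] - off[1, ])
    win <- Ok[want[1] + (-1:1), want[2] + (-1:1)]
    expect_gt(max(win), 0.5 * max(Ok) * 0.1)
    expect_equal(max(win), max(Ok[want[1] + (-2:2), want[2] + (-2:2)]))
  }
})

test_that("shift graph composes collinear shifts and closes cycles", {
  cfg <- optical_config(64, 64, 3, 16, seed = 52)
  pos <- rbind(c(-10, -8), c(0, 0), c(10, 8))
  em <- emitters_at(pos)
  fp <- synthesize_fingerprints(em, cfg)$fingerprints
  deconvs <- deconvolve_all_pairs(fp, c(64, 64))
  g <- build_shift_graph(deconvs)
  # consecutive (within-ME) pairs must be accepted; the long 1-3 pair may
  # legitimately fall below threshold — composition through node 2 covers it
  acc_pairs <- g$edges[g$edges$accepted, c("i", "k")]
  expect_true(all(c("1.2", "2.3") %in% paste(acc_pairs$i, acc_pairs$k,
                                             sep = ".")))
  # antisymmetry of each accepted pair
  expect_true(all(g$edges$antisym[g$edges$accepted] <= g$consistency_tol))
  # node 3 position equals r_31 = r_32 + r_21 within a pixel
  expect_true(all(abs(g$positions[3, ] - (pos[3, ] - pos[1, ])) <= 1))
  # cycle closure across the triangle
  expect_true(all(g$cycle_residuals <= 2 * g$consistency_tol))
})

test_that("disconnected clusters are reported, not silently placed", {
  cfg <- optical_config(64, 64, 3, 8, seed = 53)
  em <- emitters_at(rbind(c(-20, -20), c(-16, -17), c(20, 20), c(17, 16)))
  fp <- synthesize_fingerprints(em, cfg)$fingerprints
  deconvs <- deconvolve_all_pairs(fp, c(64, 64))
  expect_warning(g <- build_shift_graph(deconvs),
                 class = "speckledemix_disconnected")
  expect_setequal(g$placed, c(1L, 2L))
  expect_true(all(is.na(g$positions[3:4, ])))
})

test_that("compose_global stitches partials at their graph offsets", {
  o1 <- matrix(0, 16, 16); o1[9, 9] <- 1
  o2 <- matrix(0, 16, 16); o2[9, 9] <- 2
  graph0 <- structure(list(positions = matrix(0, 2, 2), placed = 1:2),
                      class = "shift_graph")
  gi <- compose_global(list(o1, o2), graph0)
  expect_equal(gi$canvas, o1 + o2)        # all shifts zero: plain sum

  graph1 <- structure(list(positions = rbind(c(0, 0), c(5, -4)),
                           placed = 1:2), class = "shift_graph")
  gi <- compose_global(list(o1, o2), graph1)
  expect_equal(dim(gi$canvas), c(16 + 5, 16 + 4))
  expect_equal(gi$canvas[9, 9 + 4], 1)       # o1 shifted right by +4 cols
  expect_equal(gi$canvas[9 + 5, 9], 2)       # o2 down 5, left 0 relative

  # single partial: re-centred copy
  graphs <- structure(list(positions = matrix(0, 1, 2), placed = 1L),
                      class = "shift_graph")
  gs <- compose_global(list(o1), graphs)
  expect_equal(gs$canvas, o1)
})

test_that("reconstruction is translation-gauge invariant under relabeling", {
  cfg <- optical_config(64, 64, 3, 18, seed = 54)
  pos <- rbind(c(-8, -6), c(0, 0), c(7, 5), c(-2, 9))
  em <- emitters_at(pos)
  fp <- synthesize_fingerprints(em, cfg)$fingerprints
  r1 <- reconstruct(fp, c(64, 64))
  r2 <- reconstruct(fp[, c(3, 1, 2, 4)], c(64, 64))
  peaks_rel <- function(res) {
    pk <- speckledemix:::find_peaks(res$global$canvas, min_distance = 3,
                                    prominence_frac = 0.3)
    rel <- sweep(pk[, 1:2, drop = FALSE], 2,
                 pk[which.max(pk[, 3]), 1:2])
    rel[order(rel[, 1], rel[, 2]), , drop = FALSE]
  }
  p1 <- peaks_rel(r1); p2 <- peaks_rel(r2)
  expect_equal(nrow(p1), nrow(p2))
  expect_true(max(abs(p1 - p2)) <= 1)
})

test_that("single-fingerprint reconstruction degenerates gracefully", {
  cfg <- optical_config(48, 48, 3, 12, seed = 55)
  fp <- synthesize_fingerprints(emitters_at(c(0, 0)), cfg)$fingerprints
  r <- reconstruct(fp, c(48, 48))
  pk <- which_max_rc(r$global$canvas)
  expect_equal(unname(pk), c(25, 25))
})
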