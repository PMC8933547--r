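# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# an emitter_map at explicit positions, bypassing the layout generators
emitters_at <- function(pos, brightness = 1) {
  pos <- matrix(pos, ncol = 2, dimnames = list(NULL, c("row", "col")))
  structure(list(positions = pos,
                 brightness = rep_len(brightness, nrow(pos)),
                 count = nrow(pos)),
            class = "emitter_map")
}

# fingerprint pair at separation vector `sep`, returned as H x W matrices
fingerprint_pair <- function(sep, seed, n = 48, me = 12, grain = 3) {
  cfg <- optical_config(n, n, grain, me, seed = seed)
  em <- emitters_at(rbind(c(0, 0), sep))
  fp <- synthesize_fingerprints(em, cfg)$fingerprints
  list(w1 = matrix_frame(fp[, 1], n, n), w2 = matrix_frame(fp[, 2], n, n),
       cfg = cfg)
}

# column vector (row-major) -> H x W frame, independent of package internals
matrix_frame <- function(v, H, W) t(matrix(v, W, H))

# brute-force zero-mean normalized circular correlation at one integer lag
corr_at_lag <- function(a, b, dr, dc) {
  bs <- b
  nr <- nrow(b); nc <- ncol(b)
  idx_r <- ((seq_len(nr) - 1 - dr) %% nr) + 1
  idx_c <- ((seq_len(nc) - 1 - dc) %% nc) + 1
  bs <- b[idx_r, idx_c]                    # b shifted by (dr, dc)
  stats::cor(as.vector(a), as.vector(bs))
}

# exhaustive correlation argmax over a lag window (independent oracle)
bruteforce_argmax_lag <- function(a, b, window) {
  best <- -Inf; best_lag <- c(NA, NA)
  for (dr in -window:window) for (dc in -window:window) {
    v <- corr_at_lag(a, b, dr, dc)
    if (v > best) { best <- v; best_lag <- c(dr, dc) }
  }
  list(lag = best_lag, value = best)
}

# small noiseless multi-emitter dataset reused across demix tests
small_rank3_dataset <- function() fixture("rank3", {
  cfg <- optical_config(48, 48, 3, 14, noise_photons = Inf,
                        read_noise_sigma = 0, seed = 42)
  em <- emitters_at(rbind(c(-8, -6), c(0, 5), c(7, -2)))
  simulate_dataset(em, cfg, 200, noiseless = TRUE)
})

# the acceptance-scale beyond-ME chain pipeline (criteria 1 and 7 share it)
acceptance_chain_run <- function() fixture("chain_run", {
  cfg <- pipeline_config(
    optical = optical_config(96, 96, 4, 20,
                             noise_photons = 2000, read_noise_sigma = 2),
    emitters = list(n = 11, fov_radius = 40, min_separation = 3,
                    layout = "connected_chain", chain_step = 6.7),
    T_frames = 1000, rank_min = 4, rank_max = 18, rank_step = 2,
    rank_frames = 300, rank_max_iter = 80, restarts = 2,
    nmf_max_iter = 300, seed = 11)
  run_pipeline(cfg)
})
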