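#' Optical configuration for the speckle simulator
#'
#' Bundles the physical parameters of the simulated imaging system: camera
#' frame size, mean speckle grain size, the optical memory-effect (ME) range,
#' and the detector noise model.  The ME range is the emitter separation at
#' which the intensity correlation between two fingerprints has dropped to
#' 0.5; well inside it two fingerprints are near-identical up to a
#' translation, and beyond about three times it they are uncorrelated.
#'
#' @param frame_height,frame_width Camera frame size in pixels (>= 8).
#' @param grain_size Mean speckle grain FWHM in pixels (>= 1).
#' @param me_range Memory-effect range in pixels; must exceed `grain_size`.
#' @param noise_photons Expected photon count at the brightest pixel of the
#'   stack (Poisson scale).  `Inf` disables shot noise.
#' @param read_noise_sigma Gaussian read noise (counts, sd).
#' @param seed Master seed; all simulator randomness derives from it.
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(frame_height = 48, frame_width = 48,
#'                       grain_size = 3, me_range = 12)
#' @export
optical_config <- function(frame_height = 96, frame_width = 96,
                           grain_size = 4, me_range = 20,
                           noise_photons = 2000, read_noise_sigma = 2,
                           seed = 1L) {
  if (frame_height < 8 || frame_width < 8)
    stop("frame dimensions must be >= 8 pixels")
  if (grain_size < 1) stop("grain_size must be >= 1 pixel")
  if (me_range <= grain_size) stop("me_range must exceed grain_size")
  if (read_noise_sigma < 0) stop("read_noise_sigma must be >= 0")
  structure(list(frame_height = as.integer(frame_height),
                 frame_width = as.integer(frame_width),
                 grain_size = grain_size, me_range = me_range,
                 noise_photons = noise_photons,
                 read_noise_sigma = read_noise_sigma,
                 seed = as.integer(seed)),
            class = "optical_config")
}

#' Generate a synthetic emitter layout
#'
#' Places `n` point emitters in the object plane.  Positions are continuous
#' (sub-pixel) `(row, col)` offsets from the field centre.  Three layouts are
#' supported: `random` rejection-samples inside a disk, `ring` spaces the
#' emitters on a circle, and `connected_chain` builds a jittered chain whose
#' consecutive gaps never exceed `chain_step` — the construction that keeps
#' isoplanatic patches connected so stitching can exceed the ME range.
#'
#' @param n Number of emitters (>= 1).
#' @param fov_radius Radius of the placement disk, pixels.
#' @param min_separation Minimum pairwise distance, pixels.
#' @param layout One of `"random"`, `"ring"`, `"connected_chain"`.
#' @param seed Integer seed.
#' @param chain_step Maximum consecutive gap for `connected_chain`; pass a
#'   value below the ME range to guarantee chain connectivity.  For the other
#'   layouts it is ignored.
#' @param brightness Per-emitter brightness; recycled to length `n`.
#' @return An `emitter_map`: list with `positions` (n x 2 matrix of (row,
#'   col)), `brightness`, and `count`.
#' @export
generate_emitters <- function(n, fov_radius, min_separation = 0,
                              layout = c("random", "ring", "connected_chain"),
                              seed = 1L, chain_step = NULL, brightness = 1) {
  layout <- match.arg(layout)
  if (n < 1) stop("n must be >= 1")
  if (fov_radius <= 0) stop("fov_radius must be > 0")
  if (min_separation < 0) stop("min_separation must be >= 0")
  set.seed(child_seed(seed, 101L))

  pos <- switch(layout,
    random = {
      pts <- matrix(numeric(0), 0, 2)
      attempts <- 0L
      max_attempts <- 2000L * n
      while (nrow(pts) < n) {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop("could not place ", n, " emitters with min_separation ",
               min_separation, " in fov_radius ", fov_radius,
               " (over-dense request)")
        r <- fov_radius * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        p <- c(r * sin(th), r * cos(th))
        if (nrow(pts) == 0 ||
            min(sqrt(rowSums(sweep(pts, 2, p)^2))) >= min_separation)
          pts <- rbind(pts, p)
      }
      pts
    },
    ring = {
      th <- 2 * pi * (seq_len(n) - 1) / n + stats::runif(1, 0, 2 * pi)
      pts <- cbind(fov_radius * sin(th), fov_radius * cos(th))
      if (n > 1) {
        d <- stats::dist(pts)
        if (min(d) < min_separation)
          stop("ring of ", n, " emitters at radius ", fov_radius,
               " violates min_separation ", min_separation)
      }
      pts
    },
    connected_chain = {
      if (is.null(chain_step))
        stop("connected_chain layout requires chain_step")
      if (chain_step < min_separation)
        stop("chain_step must be >= min_separation")
      # Walk along a straight spine with perpendicular jitter; gaps are drawn
      # in [max(min_sep, 0.8*chain_step), chain_step) so consecutive emitters
      # always sit well inside one ME range of each other.
      lo <- max(min_separation, 0.8 * chain_step)
      gaps <- stats::runif(n - 1, lo, chain_step)
      s <- c(0, cumsum(gaps))
      s <- s - mean(s)
      jitter <- stats::runif(n, -0.15, 0.15) * chain_step
      th <- stats::runif(1, 0, 2 * pi)
      u <- c(sin(th), cos(th)); v <- c(cos(th), -sin(th))
      pts <- outer(s, u) + outer(jitter, v)
      if (max(sqrt(rowSums(pts^2))) > fov_radius)
        stop("chain of ", n, " emitters does not fit in fov_radius ",
             fov_radius)
      pts
    })
  dimnames(pos) <- list(NULL, c("row", "col"))
  structure(list(positions = pos,
                 brightness = rep_len(brightness, n),
                 count = as.integer(n)),
            class = "emitter_map")
}

# Pairwise intensity-correlation model of the simulator: a stationary
# Gaussian-process phase screen with position correlation
# rho(d) = exp(-d^2 / (2 L^2)) and amplitude sigma gives field correlation
# exp(-sigma^2 (1 - rho)) and intensity correlation its square.  sigma^2 = 2
# fixes the far-field floor at exp(-4) ~ 0.018; L is then solved so the
# intensity correlation is exactly 0.5 at d = me_range.
.decor_sigma2 <- 2
.decor_length <- function(me_range) {
  # 2 * sigma^2 * (1 - exp(-me^2/(2L^2))) = log(2)
  me_range / sqrt(-2 * log(1 - log(2) / (2 * .decor_sigma2)))
}

#' Synthesize memory-effect-correlated speckle fingerprints
#'
#' Generates one fully developed speckle intensity image per emitter.  All
#' emitters share a common random pupil phase screen; each emitter adds (i) a
#' linear phase tilt encoding its position — so nearby emitters produce
#' translated copies of the same speckle (the optical memory effect) — and
#' (ii) a Gaussian-process phase perturbation whose correlation decays with
#' emitter separation, so fingerprints decorrelate beyond the ME range.  The
#' perturbation amplitude is calibrated in closed form so the peak intensity
#' correlation between two fingerprints is 0.5 at separation `me_range` and
#' below 0.04 beyond three ME ranges.
#'
#' @param emitters An `emitter_map`.
#' @param config An `optical_config`.
#' @return A `ground_truth` object with `fingerprints` (pixels x P matrix,
#'   row-major pixel order, each column mean-normalized then scaled by
#'   brightness), `emitter_map`, and `config`; `weights` is `NULL` until
#'   [synthesize_weights()] fills it.
#' @export
synthesize_fingerprints <- function(emitters, config) {
  stopifnot(inherits(emitters, "emitter_map"),
            inherits(config, "optical_config"))
  H <- config$frame_height; W <- config$frame_width
  P <- emitters$count
  set.seed(child_seed(config$seed, 202L))

  # Circular pupil: cutoff 0.5/grain cycles per pixel gives an intensity
  # autocorrelation FWHM of about grain_size pixels.
  fu <- fft_freq(H) / H
  fv <- fft_freq(W) / W
  f2 <- outer(fu^2, fv^2, `+`)
  pupil <- f2 <= (0.5 / config$grain_size)^2
  if (!any(pupil)) stop("grain_size too large for frame: empty pupil")

  phi0 <- matrix(stats::runif(H * W, 0, 2 * pi), H, W)

  # Correlated per-emitter phase perturbations via the eigendecomposition of
  # the P x P position-correlation matrix (exact also for duplicate
  # positions, where the matrix is rank deficient).
  L <- .decor_length(config$me_range)
  D <- as.matrix(stats::dist(emitters$positions))
  C <- exp(-D^2 / (2 * L^2))
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  M <- eg$vectors %*% diag(sqrt(lam), P, P)   # psi_k = sum_j M[k,j] Z_j
  Z <- lapply(seq_len(P), function(j) matrix(stats::rnorm(H * W), H, W))

  ur <- fft_freq(H); vc <- fft_freq(W)
  sig <- sqrt(.decor_sigma2)
  fp <- matrix(0, H * W, P)
  for (k in seq_len(P)) {
    psi <- matrix(0, H, W)
    for (j in seq_len(P)) if (M[k, j] != 0) psi <- psi + M[k, j] * Z[[j]]
    tilt <- outer(ur * (emitters$positions[k, 1] / H),
                  vc * (emitters$positions[k, 2] / W), `+`)
    spec <- pupil * exp(1i * (phi0 + sig * psi - 2 * pi * tilt))
    field <- ifft2(spec)
    w <- Mod(field)^2
    w <- w / mean(w) * emitters$brightness[k]
    fp[, k] <- as.vector(t(w))            # row-major pixel order
  }
  structure(list(fingerprints = fp, weights = NULL,
                 emitter_map = emitters, config = config),
            class = "ground_truth")
}

#' Synthesize per-frame illumination weights
#'
#' Draws the non-negative weight h_k(t) of emitter k in frame t.  Under
#' `iid_exponential` each weight is an independent unit-mean exponential —
#' the intensity statistics of fully developed speckle.  Under
#' `speckle_field` the weights are intensities of a common complex-Gaussian
#' illumination field evaluated at the emitter positions, so emitters closer
#' than the illumination grain receive correlated weights (marginals stay
#' unit-mean exponential).
#'
#' @param P Number of emitters (rows).
#' @param T_frames Number of frames (columns).
#' @param model `"iid_exponential"` or `"speckle_field"`.
#' @param config An `optical_config` (supplies seed and illumination grain).
#' @param emitters Required for `speckle_field`: the `emitter_map` whose
#'   positions are sampled.
#' @return Non-negative `P x T_frames` weight matrix.
#' @export
synthesize_weights <- function(P, T_frames,
                               model = c("iid_exponential", "speckle_field"),
                               config, emitters = NULL) {
  model <- match.arg(model)
  if (P < 1 || T_frames < 1) stop("P and T_frames must be >= 1")
  set.seed(child_seed(config$seed, 303L))
  if (model == "iid_exponential")
    return(matrix(stats::rexp(P * T_frames), P, T_frames))

  if (is.null(emitters)) stop("speckle_field model requires emitters")
  # Complex Gaussian field with spatial correlation exp(-d^2/(2 g^2)) at the
  # emitter positions; intensities are exponential with correlation |C|^2.
  g <- config$grain_size
  D <- as.matrix(stats::dist(emitters$positions[seq_len(P), , drop = FALSE]))
  C <- exp(-D^2 / (2 * g^2))
  eg <- eigen(C, symmetric = TRUE)
  M <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), P, P)
  zr <- matrix(stats::rnorm(P * T_frames), P, T_frames)
  zi <- matrix(stats::rnorm(P * T_frames), P, T_frames)
  a <- (M %*% zr + 1i * M %*% zi) / sqrt(2)
  Mod(a)^2
}

#' Compose noisy camera frames from ground truth
#'
#' Realizes the linear mixing model: the noiseless frame t is
#' `sum_k w_k(r) h_k(t)`, evaluated as the matrix product of fingerprints and
#' weights.  Shot noise is applied by scaling the stack so its brightest
#' pixel has expectation `noise_photons` and drawing Poisson counts, then
#' Gaussian read noise is added and negatives are clipped to zero (sCMOS
#' order of operations; clipping keeps the stack NMF-ready).
#'
#' @param truth A `ground_truth` with both `fingerprints` and `weights`.
#' @param noiseless If `TRUE`, skip all noise regardless of config.
#' @return A `frame_stack`: list with `frames` (H x W x T array) and the
#'   originating config.  Frame t is `frames[, , t]`.
#' @export
compose_frames <- function(truth, noiseless = FALSE) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(truth$weights)) stop("ground truth has no weights")
  fp <- truth$fingerprints; Hm <- truth$weights
  if (ncol(fp) != nrow(Hm))
    stop("fingerprint count ", ncol(fp), " does not match weight rows ",
         nrow(Hm))
  cfg <- truth$config
  H <- cfg$frame_height; W <- cfg$frame_width
  if (nrow(fp) != H * W) stop("fingerprint length does not match frame size")
  I <- fp %*% Hm                      # pixels x T, row-major pixel order
  Tn <- ncol(Hm)
  arr <- unflatten_matrix(I, H, W)
  if (!noiseless) {
    set.seed(child_seed(cfg$seed, 404L))
    if (is.finite(cfg$noise_photons) && cfg$noise_photons > 0) {
      sc <- cfg$noise_photons / max(arr)
      arr <- array(stats::rpois(length(arr), arr * sc), dim(arr))
    }
    if (cfg$read_noise_sigma > 0)
      arr <- arr + stats::rnorm(length(arr), 0, cfg$read_noise_sigma)
    arr[arr < 0] <- 0
  }
  structure(list(frames = arr, config = cfg), class = "frame_stack")
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: fingerprints + weights + frames for a given layout.
#'
#' @param emitters An `emitter_map`.
#' @param config An `optical_config`.
#' @param T_frames Number of frames.
#' @param weight_model Passed to [synthesize_weights()].
#' @param noiseless Skip detector noise.
#' @return List with `truth` (complete `ground_truth`) and `stack`.
#' @export
simulate_dataset <- function(emitters, config, T_frames,
                             weight_model = "iid_exponential",
                             noiseless = FALSE) {
  truth <- synthesize_fingerprints(emitters, config)
  truth$weights <- synthesize_weights(emitters$count, T_frames,
                                      weight_model, config, emitters)
  list(truth = truth, stack = compose_frames(truth, noiseless = noiseless))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", ncol(x$fingerprints), "emitters,",
      nrow(x$fingerprints), "pixels",
      if (!is.null(x$weights)) paste0(", T = ", ncol(x$weights)) else
        "(no weights yet)", "\n")
  invisible(x)
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("frame_stack:", d[3], "frames of", d[1], "x", d[2], "pixels\n")
  invisible(x)
}
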