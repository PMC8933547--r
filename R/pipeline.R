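#' Pipeline configuration
#'
#' One nested configuration object controlling every stage, suitable for
#' round-tripping through JSON (see [read_pipeline_config()]).
#'
#' @param optical An [optical_config()] (simulation stage).
#' @param emitters Either an `emitter_map` or a list of arguments for
#'   [generate_emitters()] (e.g. `list(n = 5, fov_radius = 15,
#'   min_separation = 4, layout = "random")`).
#' @param T_frames Number of frames to simulate.
#' @param weight_model Illumination weight model.
#' @param highpass_sigma,clip_mode Preprocessing stage; `highpass_sigma =
#'   NULL` skips filtering.
#' @param rank `"auto"` for residual-knee estimation or a fixed integer.
#' @param rank_min,rank_max,rank_step,rank_frames,rank_max_iter Rank-scan
#'   controls; `rank_frames` caps the number of frames used during the scan
#'   (the scan is a model-order probe, not the final fit).
#' @param restarts NMF restarts.
#' @param nmf_max_iter,nmf_tol,nmf_method Final NMF controls.
#' @param deconv A [deconv_config()].
#' @param quality_threshold,consistency_tol,accepted_only FBR stage.
#' @param mode `"simulate_and_reconstruct"` or `"reconstruct_only"`.
#' @param input_stack For `reconstruct_only`: path of an RDS frame stack.
#' @param output_dir Optional directory for persisted intermediates.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(optical = optical_config(),
                            emitters = list(n = 5, fov_radius = 15,
                                            min_separation = 4,
                                            layout = "random"),
                            T_frames = 500,
                            weight_model = "iid_exponential",
                            highpass_sigma = 2, clip_mode = "clip_zero",
                            rank = "auto", rank_min = 2, rank_max = 16,
                            rank_step = 1, rank_frames = 300,
                            rank_max_iter = 100, restarts = 3,
                            nmf_max_iter = 500, nmf_tol = 1e-5,
                            nmf_method = "mu",
                            deconv = deconv_config(),
                            quality_threshold = 9, consistency_tol = 2,
                            accepted_only = FALSE,
                            mode = c("simulate_and_reconstruct",
                                     "reconstruct_only"),
                            input_stack = NULL, output_dir = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "reconstruct_only" &&
      (is.null(input_stack) || !file.exists(input_stack)))
    stop("reconstruct_only mode requires an existing input_stack file")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full demix-and-reconstruct pipeline
#'
#' Stages: simulate (or load) the frame stack, high-pass filter, estimate
#' the NMF rank on a frame subset, factorize the full stack, reconstruct by
#' FBR, and — whenever simulator ground truth is available — quantify
#' recovery against it.  Each stage is timed; failures are re-raised tagged
#' with the stage name, and intermediates computed so far are persisted to
#' `output_dir` when one is given.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return List: `global`, `graph`, `factors`, `rank_scan`, `report` (a
#'   `recovery_report` or `NULL`), `truth`, `stack`, `timings` (seconds per
#'   stage).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  state <- new.env(parent = emptyenv())
  persist <- function() {
    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      for (nm in ls(state))
        saveRDS(get(nm, state),
                file.path(config$output_dir, paste0(nm, ".rds")))
    }
  }
  stage <- function(name, expr) {
    if (verbose) message("[", name, "] ...")
    t0 <- proc.time()[3]
    val <- tryCatch(expr, error = function(e) {
      persist()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[name] <<- proc.time()[3] - t0
    val
  }

  cfg <- config$optical
  truth <- NULL
  if (config$mode == "simulate_and_reconstruct") {
    emitters <- stage("emitters", {
      if (inherits(config$emitters, "emitter_map")) config$emitters
      else do.call(generate_emitters,
                   c(config$emitters, list(seed = child_seed(config$seed,
                                                             11L))))
    })
    sim <- stage("simulate", {
      cfg$seed <- child_seed(config$seed, 22L)
      simulate_dataset(emitters, cfg, config$T_frames,
                       weight_model = config$weight_model)
    })
    truth <- sim$truth
    stack <- sim$stack
  } else {
    stack <- stage("load", readRDS(config$input_stack))
  }
  state$stack <- stack

  prep <- stage("preprocess", {
    if (is.null(config$highpass_sigma)) stack
    else highpass_filter(stack, config$highpass_sigma, config$clip_mode)
  })
  I <- flatten_stack(prep)
  d <- dim(prep$frames)

  scan <- NULL
  rank <- config$rank
  if (identical(rank, "auto")) {
    scan <- stage("estimate_rank", {
      Isub <- I[, seq_len(min(config$rank_frames, ncol(I))), drop = FALSE]
      estimate_rank(Isub, config$rank_min,
                    min(config$rank_max, min(dim(Isub))),
                    restarts = max(1, config$restarts - 1),
                    seed = child_seed(config$seed, 33L),
                    step = config$rank_step,
                    max_iter = config$rank_max_iter,
                    method = config$nmf_method)
    })
    rank <- scan$chosen_rank
  }
  state$rank_scan <- scan

  factors <- stage("nmf", {
    best <- NULL
    for (s in seq_len(config$restarts)) {
      f <- nmf_factorize(I, rank, max_iter = config$nmf_max_iter,
                         tol = config$nmf_tol,
                         seed = child_seed(config$seed, 44L + s),
                         method = config$nmf_method)
      if (is.null(best) || f$final_residual < best$final_residual) best <- f
    }
    best
  })
  state$factors <- factors

  fbr <- stage("reconstruct", {
    reconstruct(factors, dims = d[1:2], config = config$deconv,
                quality_threshold = config$quality_threshold,
                consistency_tol = config$consistency_tol,
                accepted_only = config$accepted_only,
                grain_size = max(2, round(cfg$grain_size)))
  })
  state$global <- fbr$global

  report <- NULL
  if (!is.null(truth)) {
    report <- stage("evaluate", {
      evaluate_recovery(fbr$global, truth$emitter_map, cfg$grain_size,
                        me_range = cfg$me_range)
    })
    report$timings <- timings
    state$report <- report
  }
  persist()
  list(global = fbr$global, graph = fbr$graph, factors = factors,
       rank_scan = scan, report = report, truth = truth, stack = stack,
       timings = timings)
}

# Local maxima of an image: pixels that are the strict maximum of their
# (2m+1)^2 neighbourhood and exceed prominence_frac * max, then greedy
# non-maximum suppression at min_distance.
find_peaks <- function(img, min_distance = 2, prominence_frac = 0.2) {
  thr <- prominence_frac * max(img)
  cand <- which(img >= thr & img > 0)
  if (length(cand) == 0)
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("row", "col", "value"))))
  nr <- nrow(img); nc <- ncol(img)
  m <- max(1L, as.integer(ceiling(min_distance / 2)))
  keep <- vapply(cand, function(idx) {
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    rs <- max(1, r - m):min(nr, r + m)
    cs <- max(1, c - m):min(nc, c + m)
    img[r, c] >= max(img[rs, cs])
  }, TRUE)
  cand <- cand[keep]
  pk <- cbind(row = (cand - 1L) %% nr + 1L,
              col = (cand - 1L) %/% nr + 1L,
              value = img[cand])
  pk <- pk[order(-pk[, 3]), , drop = FALSE]
  sel <- logical(nrow(pk))
  for (j in seq_len(nrow(pk))) {
    if (!any(sel)) { sel[j] <- TRUE; next }
    d2 <- (pk[sel, 1] - pk[j, 1])^2 + (pk[sel, 2] - pk[j, 2])^2
    if (min(d2) >= min_distance^2) sel[j] <- TRUE
  }
  pk[sel, , drop = FALSE]
}

#' Quantify recovery of the emitter layout from a global image
#'
#' Extracts local maxima from the reconstruction, finds the integer global
#' translation that best aligns them with the true emitter positions
#' (exhaustive search over a bounded window — the reconstruction is defined
#' only up to translation), greedily matches peaks to truth within
#' `match_radius`, and reports localization statistics and the spatial span
#' of the recovered object.
#'
#' @param global A `global_image` (or bare matrix canvas).
#' @param truth An `emitter_map`.
#' @param grain_size Pixels; sets the default match radius (2 grains, about
#'   the resolution of speckle-correlation imaging) and peak separation.
#' @param me_range If given, the recovered span is also reported in ME
#'   units.
#' @param match_radius Maximum peak-to-truth distance for a match.
#' @param prominence_frac Peak threshold as a fraction of the canvas max.
#' @param search_margin Half-width (pixels) of the translation search window
#'   around the centroid offset.
#' @return A `recovery_report`: `matched`, `fraction`, `mean_error`,
#'   `max_error`, `span_px`, `span_me`, `translation`, `peaks`.
#' @export
evaluate_recovery <- function(global, truth, grain_size,
                              me_range = NULL,
                              match_radius = 2 * grain_size,
                              prominence_frac = 0.2,
                              search_margin = 10) {
  stopifnot(inherits(truth, "emitter_map"))
  canvas <- if (inherits(global, "global_image")) global$canvas else global
  P <- truth$count
  pk <- find_peaks(canvas, min_distance = max(2, grain_size),
                   prominence_frac = prominence_frac)
  if (nrow(pk) == 0)
    return(structure(list(matched = 0L, fraction = 0, mean_error = NA_real_,
                          max_error = NA_real_, span_px = 0,
                          span_me = if (is.null(me_range)) NA_real_ else 0,
                          translation = c(0, 0), peaks = pk),
                     class = "recovery_report"))
  tp <- truth$positions

  match_at <- function(tr) {
    # greedy nearest matching of translated peaks to truth
    pr <- pk[, 1] + tr[1]; pc <- pk[, 2] + tr[2]
    used_p <- logical(nrow(pk)); used_t <- logical(P)
    errs <- numeric(0); pairs <- integer(0)
    d <- outer(tp[, 1], pr, `-`)^2 + outer(tp[, 2], pc, `-`)^2
    repeat {
      d2 <- d
      d2[used_t, ] <- Inf; d2[, used_p] <- Inf
      ij <- arrayInd(which.min(d2), dim(d2))
      if (!is.finite(d2[ij[1], ij[2]]) ||
          d2[ij[1], ij[2]] > match_radius^2) break
      used_t[ij[1]] <- TRUE; used_p[ij[2]] <- TRUE
      errs <- c(errs, sqrt(d2[ij[1], ij[2]]))
      pairs <- c(pairs, ij[2])
    }
    list(n = sum(used_t), errs = errs, matched_peaks = pairs)
  }

  # centre the search window on the centroid offset
  t0 <- round(c(mean(tp[, 1]) - mean(pk[, 1]),
                mean(tp[, 2]) - mean(pk[, 2])))
  best <- NULL; best_tr <- t0
  for (dr in -search_margin:search_margin) {
    for (dc in -search_margin:search_margin) {
      tr <- t0 + c(dr, dc)
      m <- match_at(tr)
      if (is.null(best) || m$n > best$n ||
          (m$n == best$n && sum(m$errs) < sum(best$errs))) {
        best <- m; best_tr <- tr
      }
    }
  }
  mp <- pk[best$matched_peaks, , drop = FALSE]
  span <- if (nrow(mp) > 1) max(stats::dist(mp[, 1:2])) else 0
  structure(list(matched = best$n, fraction = best$n / P,
                 mean_error = if (length(best$errs)) mean(best$errs)
                              else NA_real_,
                 max_error = if (length(best$errs)) max(best$errs)
                             else NA_real_,
                 span_px = span,
                 span_me = if (is.null(me_range)) NA_real_
                           else span / me_range,
                 translation = best_tr, peaks = pk),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "recovery_report: %d matched (%.0f%%), mean error %.2f px, span %.1f px%s\n",
    x$matched, 100 * x$fraction,
    if (is.na(x$mean_error)) NaN else x$mean_error, x$span_px,
    if (is.na(x$span_me)) "" else sprintf(" (%.2f ME)", x$span_me)))
  invisible(x)
}
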