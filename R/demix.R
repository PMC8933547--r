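#' Flatten a frame stack to the pixels-by-frames data matrix
#'
#' Column t of the result is frame t flattened in row-major order: pixel
#' `(i, j)` (0-based) of frame t lands at row `i * W + j + 1`.  The reshape
#' is exactly inverted by [unflatten_matrix()].
#'
#' @param stack A `frame_stack`.
#' @return A non-negative `(H*W) x T` matrix.
#' @export
flatten_stack <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  matrix(aperm(stack$frames, c(2, 1, 3)), d[1] * d[2], d[3])
}

#' Inverse of [flatten_stack()]
#'
#' @param I A `(H*W) x T` matrix in row-major pixel order.
#' @param H,W Frame dimensions.
#' @return An `H x W x T` array.
#' @export
unflatten_matrix <- function(I, H, W) {
  if (nrow(I) != H * W) stop("matrix rows do not match H * W")
  aperm(array(I, c(W, H, ncol(I))), c(2, 1, 3))
}

# One column of I as an H x W frame (row-major convention).
vec_to_frame <- function(v, H, W) t(matrix(v, W, H))

#' Non-negative matrix factorization of the speckle data matrix
#'
#' Solves `min_{W>=0, H>=0} ||I - W H||_F^2` from a random non-negative
#' initialization.  Two monotone solvers are provided: classical
#' multiplicative updates (`"mu"`, the default) and HALS coordinate descent
#' (`"hals"`, faster to high accuracy on exactly low-rank data).  The
#' objective is evaluated every iteration from the Gram matrices already
#' needed by the updates, so the trace costs almost nothing; it is
#' guaranteed non-increasing by both algorithms.
#'
#' On return, columns of `W` are normalized to unit maximum with the scale
#' absorbed into `H`, leaving the product `W H` unchanged.  Columns whose
#' maximum falls below `1e-12 * max(I)` are flagged `dead` and should be
#' excluded downstream.
#'
#' @param I Non-negative data matrix (pixels x frames).
#' @param rank Factorization rank rho, `1 <= rank <= min(dim(I))`.
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative decrease of the Frobenius residual below which the
#'   solver stops and reports convergence (default 1e-5).
#' @param seed Seed for the random initialization.
#' @param method `"mu"` or `"hals"`.
#' @return A `factorization_result`: `W`, `H`, `final_residual` (Frobenius
#'   norm of the misfit), `residual_trace`, `iterations_run`, `converged`,
#'   `dead` (logical per column), `rank`.
#' @export
nmf_factorize <- function(I, rank, max_iter = 500, tol = 1e-5, seed = 1L,
                          method = c("mu", "hals")) {
  method <- match.arg(method)
  if (any(is.na(I))) stop("data matrix contains NaN")
  if (any(I < 0)) stop("data matrix contains negative entries")
  r <- nrow(I); tt <- ncol(I)
  if (rank < 1 || rank > min(r, tt))
    stop("rank must be in [1, ", min(r, tt), "]")
  set.seed(seed)
  W <- matrix(stats::runif(r * rank), r, rank)
  Hm <- matrix(stats::runif(rank * tt), rank, tt)
  sc <- sqrt(mean(I) / max(mean(W %*% Hm), .Machine$double.eps))
  W <- W * sc; Hm <- Hm * sc

  eps <- 1e-12
  normI2 <- sum(I^2)
  trace <- numeric(max_iter)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    if (method == "mu") {
      WtI <- crossprod(W, I)                    # rho x T
      WtW <- crossprod(W)
      Hm <- Hm * WtI / (WtW %*% Hm + eps)
      IHt <- I %*% t(Hm)                        # r x rho
      HHt <- tcrossprod(Hm)
      W <- W * IHt / (W %*% HHt + eps)
    } else {
      WtI <- crossprod(W, I)
      WtW <- crossprod(W)
      for (j in seq_len(rank)) {
        hj <- Hm[j, ] + (WtI[j, ] - WtW[j, ] %*% Hm) / max(WtW[j, j], eps)
        Hm[j, ] <- pmax(hj, 0)
      }
      IHt <- I %*% t(Hm)
      HHt <- tcrossprod(Hm)
      for (j in seq_len(rank)) {
        wj <- W[, j] + (IHt[, j] - W %*% HHt[, j]) / max(HHt[j, j], eps)
        W[, j] <- pmax(wj, 0)
      }
    }
    # ||I - WH||^2 = ||I||^2 - 2 tr(W' I H') + tr(W'W H H')
    WtW <- crossprod(W)
    obj2 <- normI2 - 2 * sum(W * IHt) + sum(WtW * HHt)
    fro <- sqrt(max(obj2, 0))
    trace[it] <- fro
    if (is.finite(prev) && prev > 0 && (prev - fro) / prev < tol) {
      converged <- TRUE
      break
    }
    prev <- fro
  }
  trace <- trace[seq_len(it)]

  cmax <- apply(W, 2, max)
  dead <- cmax < 1e-12 * max(max(I), .Machine$double.eps)
  s <- ifelse(dead, 1, cmax)
  W <- sweep(W, 2, s, `/`)
  Hm <- sweep(Hm, 1, s, `*`)
  structure(list(W = W, H = Hm, final_residual = trace[it],
                 residual_trace = trace, iterations_run = it,
                 converged = converged, dead = dead,
                 rank = as.integer(rank)),
            class = "factorization_result")
}

#' Estimate the factorization rank from the residual-vs-rank curve
#'
#' Runs NMF for every candidate rank (best of `restarts` random starts) and
#' records the root-mean-square residual `||I - WH||_F / sqrt(r t)`.  The
#' residual is monotone non-increasing in rank, so its literal minimum is the
#' largest rank scanned; an operational knee rule is needed.  Two are
#' provided.  `"knee"` (default) is geometric: the chosen rank maximizes the
#' vertical distance between the residual curve and the chord joining its
#' endpoints — robust on noisy data, where extra components keep absorbing a
#' few percent of residual noise per rank.  `"threshold"` picks the last rank
#' whose RMS improvement over its predecessor, measured as a fraction of the
#' data RMS, still exceeds `knee_frac` (normalizing by the data scale rather
#' than the shrinking residual keeps the rule stable both near exact fits
#' and on noise floors).  In both cases a rank whose RMS falls below `1e-9`
#' of the data scale short-circuits the scan: the data are exactly fit.
#'
#' @param I Non-negative data matrix.
#' @param rank_min,rank_max Scan bounds (inclusive).
#' @param restarts Random restarts per rank; best objective kept.
#' @param seed Master seed.
#' @param step Scan stride (default 1).
#' @param criterion `"knee"` (geometric) or `"threshold"`.
#' @param knee_frac Relative-improvement threshold for
#'   `criterion = "threshold"` (default 0.02).
#' @param max_iter,tol,method Passed to [nmf_factorize()].
#' @return A `rank_scan`: `ranks`, `rms_residuals`, `chosen_rank`,
#'   `criterion`, and `fits` (the best fit per rank).
#' @export
estimate_rank <- function(I, rank_min = 1, rank_max = min(dim(I)),
                          restarts = 3, seed = 1L, step = 1,
                          criterion = c("knee", "threshold"),
                          knee_frac = 0.02, max_iter = 200, tol = 1e-5,
                          method = "mu") {
  criterion <- match.arg(criterion)
  if (rank_max < rank_min) stop("rank_max must be >= rank_min")
  if (rank_min < 1 || rank_max > min(dim(I)))
    stop("rank bounds must lie in [1, ", min(dim(I)), "]")
  ranks <- unique(c(seq(rank_min, rank_max, by = step), rank_max))
  nrt <- sqrt(prod(dim(I)))
  scale0 <- sqrt(sum(I^2)) / nrt
  rms <- rep(NA_real_, length(ranks))
  fits <- vector("list", length(ranks))
  for (m in seq_along(ranks)) {
    best <- NULL
    for (s in seq_len(restarts)) {
      f <- nmf_factorize(I, ranks[m], max_iter = max_iter, tol = tol,
                         seed = child_seed(seed, 1000L * m + s),
                         method = method)
      if (is.null(best) || f$final_residual < best$final_residual) best <- f
    }
    fits[[m]] <- best
    rms[m] <- best$final_residual / nrt
    if (rms[m] < 1e-9 * scale0) break    # exact fit: nothing beyond the knee
  }
  keep <- !is.na(rms)
  ranks <- ranks[keep]; rms <- rms[keep]; fits <- fits[keep]

  if (length(ranks) == 1) {
    chosen <- ranks[1]
  } else if (criterion == "threshold") {
    impr <- c(Inf, (rms[-length(rms)] - rms[-1]) /
                     max(scale0, .Machine$double.eps))
    flat <- which(impr < knee_frac)
    chosen <- if (length(flat) == 0) ranks[length(ranks)]
              else ranks[max(flat[1] - 1, 1)]
  } else {
    # vertical distance below the chord joining the curve endpoints
    n <- length(ranks)
    chord <- rms[1] + (rms[n] - rms[1]) *
      (ranks - ranks[1]) / (ranks[n] - ranks[1])
    chosen <- ranks[which.max(chord - rms)]
  }
  # an essentially exact fit anywhere overrides the knee
  exact <- which(rms < 1e-9 * scale0)
  if (length(exact) > 0) chosen <- ranks[exact[1]]
  structure(list(ranks = ranks, rms_residuals = rms,
                 chosen_rank = as.integer(chosen), criterion = criterion,
                 fits = fits),
            class = "rank_scan")
}

#' Match factorized fingerprints to simulator ground truth
#'
#' Test/diagnostic harness: greedily assigns columns of the estimated `W` to
#' true fingerprints in decreasing order of Pearson correlation, one-to-one.
#' Columns never reaching `min_score` stay unmatched (spurious components);
#' true fingerprints left over are missed emitters.
#'
#' @param result A `factorization_result` (or a bare W matrix).
#' @param truth A `ground_truth`.
#' @param min_score Correlation below which a pairing is refused.
#' @return List: `permutation` (index of the matched W column per true
#'   emitter, NA if missed), `scores`, `unmatched_columns`.
#' @export
match_to_truth <- function(result, truth, min_score = 0.5) {
  W <- if (inherits(result, "factorization_result")) result$W else result
  Ft <- truth$fingerprints
  P <- ncol(Ft); K <- ncol(W)
  cm <- suppressWarnings(stats::cor(Ft, W))   # P x K
  cm[!is.finite(cm)] <- -1
  perm <- rep(NA_integer_, P)
  scores <- rep(NA_real_, P)
  avail_p <- rep(TRUE, P); avail_k <- rep(TRUE, K)
  for (step in seq_len(min(P, K))) {
    sub <- cm
    sub[!avail_p, ] <- -Inf; sub[, !avail_k] <- -Inf
    ij <- arrayInd(which.max(sub), dim(sub))
    if (sub[ij[1], ij[2]] < min_score) break
    perm[ij[1]] <- ij[2]
    scores[ij[1]] <- cm[ij[1], ij[2]]
    avail_p[ij[1]] <- FALSE; avail_k[ij[2]] <- FALSE
  }
  list(permutation = perm, scores = scores,
       unmatched_columns = which(avail_k))
}

#' @export
print.factorization_result <- function(x, ...) {
  cat("factorization_result: rank", x$rank, "|", x$iterations_run,
      "iterations | residual", format(x$final_residual, digits = 4),
      if (x$converged) "(converged)" else "(max_iter)", "\n")
  invisible(x)
}

#' @export
print.rank_scan <- function(x, ...) {
  cat("rank_scan:", length(x$ranks), "ranks scanned, chosen rank",
      x$chosen_rank, "\n")
  invisible(x)
}
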