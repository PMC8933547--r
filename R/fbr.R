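#' Configuration of the TV-regularized pairwise deconvolution
#'
#' The pairwise deconvolution solves, per fingerprint pair (i, k),
#' `argmin_o  mu/2 ||w_i - o (*) w_k||_2^2 + ||o||_TV`
#' with circular convolution and the isotropic total-variation norm built
#' from forward finite differences.  `mu` weights data fidelity: it is
#' meaningful because fingerprints are normalized to unit maximum before
#' deconvolution.
#'
#' @param mu Data-fidelity weight (> 0), default 100 on unit-max inputs.
#' @param max_iter ADMM iteration cap.
#' @param solver_tol Relative objective change below which iteration stops.
#' @param beta ADMM penalty on the gradient split.
#' @param boundary Only `"circular"` is implemented (FFT solves).
#' @return A `deconv_config` list.
#' @export
deconv_config <- function(mu = 100, max_iter = 120, solver_tol = 1e-5,
                          beta = 10, boundary = "circular") {
  if (mu <= 0) stop("mu must be > 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (boundary != "circular") stop("only circular boundary is implemented")
  structure(list(mu = mu, max_iter = max_iter, solver_tol = solver_tol,
                 beta = beta, boundary = boundary),
            class = "deconv_config")
}

#' TV-regularized deconvolution of one fingerprint by another
#'
#' Treats `w_k` as the point-spread function and `w_i` as the image.  Within
#' one memory-effect patch the result is a near-uniform image with a single
#' delta-like peak whose offset from the canvas centre equals the emitter
#' displacement `r_i - r_k`; for emitter pairs beyond the ME range the
#' deconvolution yields low-amplitude noise, which is what the quality score
#' detects.
#'
#' Solver: split-variable ADMM with FFT-domain quadratic solves and
#' isotropic shrinkage of the gradient split.  The exact objective is
#' evaluated every iteration and the best-objective iterate is retained, so
#' the reported `objective_trace` (running best) is non-increasing by
#' construction.
#'
#' @param w_i,w_k Same-shape non-negative fingerprint matrices (H x W).
#' @param config A [deconv_config()].
#' @param grain_size Radius (pixels) of the disk excluded around the peak
#'   when estimating the background for the quality score.
#' @return A `pairwise_deconvolution`: `o` (non-negative, canvas centred so
#'   zero lag sits at `(floor(H/2)+1, floor(W/2)+1)`), `peak_position`
#'   (signed integer lag `(row, col)` relative to the canvas centre),
#'   `quality` (peak over median background magnitude), `objective_trace`,
#'   `iterations_run`.
#' @export
pairwise_deconvolve <- function(w_i, w_k, config = deconv_config(),
                                grain_size = 3) {
  if (!all(dim(w_i) == dim(w_k))) stop("fingerprint shapes differ")
  if (max(w_k) <= 0) stop("PSF fingerprint is all zero")
  if (max(w_i) <= 0) stop("image fingerprint is all zero")
  H <- nrow(w_i); W <- ncol(w_i)
  b <- w_i / max(w_i)
  psf <- w_k / max(w_k)

  mu <- config$mu; beta <- config$beta
  Kh <- fft2(psf)
  bh <- fft2(b)
  Dxh <- outer(rep(1, H), exp(2i * pi * fft_freq(W) / W) - 1)
  Dyh <- outer(exp(2i * pi * fft_freq(H) / H) - 1, rep(1, W))
  denom <- mu * Mod(Kh)^2 + beta * (Mod(Dxh)^2 + Mod(Dyh)^2)
  muKb <- mu * Conj(Kh) * bh

  dx <- function(o) cbind(o[, -1, drop = FALSE], o[, 1, drop = FALSE]) - o
  dy <- function(o) rbind(o[-1, , drop = FALSE], o[1, , drop = FALSE]) - o

  o <- matrix(0, H, W)
  ux <- uy <- matrix(0, H, W)
  obj_of <- function(o, oh) {
    res <- b - Re(ifft2(Kh * oh))
    gx <- dx(o); gy <- dy(o)
    mu / 2 * sum(res^2) + sum(sqrt(gx^2 + gy^2))
  }
  best_o <- o
  best_obj <- obj_of(o, fft2(o))
  trace <- numeric(config$max_iter)
  prev_best <- best_obj
  it <- 0L
  for (it in seq_len(config$max_iter)) {
    gx <- dx(o) + ux
    gy <- dy(o) + uy
    mag <- sqrt(gx^2 + gy^2)
    fac <- ifelse(mag > 0, pmax(0, 1 - 1 / (beta * mag)), 0)
    zx <- fac * gx; zy <- fac * gy
    ux <- gx - zx; uy <- gy - zy
    rhs <- muKb + beta * (Conj(Dxh) * fft2(zx - ux) +
                          Conj(Dyh) * fft2(zy - uy))
    oh <- rhs / denom
    o <- Re(ifft2(oh))
    obj <- obj_of(o, oh)
    if (obj < best_obj) { best_obj <- obj; best_o <- o }
    trace[it] <- best_obj
    if (it > 5 && prev_best > 0 &&
        (prev_best - best_obj) / prev_best < config$solver_tol) break
    prev_best <- best_obj
  }
  trace <- trace[seq_len(it)]

  pk <- which_max_rc(best_o)
  peak_val <- best_o[pk[1], pk[2]]
  lag <- c(wrap_lag(pk[1] - 1L, H), wrap_lag(pk[2] - 1L, W))
  # background: |o| outside a grain-sized disk around the peak (toroidal
  # distance, since the uncentred canvas is circular)
  dr <- wrap_lag(outer(seq_len(H) - pk[1], rep(0L, W), `+`), H)
  dc <- wrap_lag(outer(rep(0L, H), seq_len(W) - pk[2], `+`), W)
  bgmask <- (dr^2 + dc^2) > grain_size^2
  bg <- stats::median(abs(best_o[bgmask]))
  quality <- peak_val / max(bg, 1e-9 * max(peak_val, .Machine$double.eps))

  ctr <- c(floor(H / 2), floor(W / 2))
  o_centred <- circ_shift(pmax(best_o, 0), ctr[1], ctr[2])
  structure(list(o = o_centred, peak_position = as.integer(lag),
                 quality = quality, objective_trace = trace,
                 iterations_run = it),
            class = "pairwise_deconvolution")
}

#' Shift estimation by normalized cross-correlation (baseline)
#'
#' The classical alternative to the deconvolution: the lag of the maximum of
#' the zero-mean normalized circular cross-correlation of the two
#' fingerprints, with the peak value as confidence.  Identical inputs give
#' lag (0, 0) and peak 1.
#'
#' @param w_i,w_k Same-shape fingerprint matrices.
#' @return List: `lag` (signed integer `(row, col)`, the displacement of
#'   `w_i` relative to `w_k`), `peak` (normalized correlation at the lag),
#'   `corr_map` (the full centred correlation image).
#' @export
crosscorr_shift <- function(w_i, w_k) {
  if (!all(dim(w_i) == dim(w_k))) stop("fingerprint shapes differ")
  H <- nrow(w_i); W <- ncol(w_i)
  a <- w_i - mean(w_i); bb <- w_k - mean(w_k)
  sa <- sqrt(sum(a^2)); sb <- sqrt(sum(bb^2))
  if (sa == 0 || sb == 0) stop("constant fingerprint: zero variance")
  # correlation theorem: ifft2(F_a conj(F_b))(lag) = sum_r a(r) b(r - lag)
  cc <- Re(ifft2(fft2(a) * Conj(fft2(bb)))) / (sa * sb)
  pk <- which_max_rc(cc)
  lag <- c(wrap_lag(pk[1] - 1L, H), wrap_lag(pk[2] - 1L, W))
  ctr <- c(floor(H / 2), floor(W / 2))
  list(lag = as.integer(lag), peak = cc[pk[1], pk[2]],
       corr_map = circ_shift(cc, ctr[1], ctr[2]))
}

#' All-pairs deconvolution of a fingerprint set
#'
#' Runs [pairwise_deconvolve()] for every ordered pair (i, k), including the
#' self pairs i = k (whose centred delta anchors each partial image).
#'
#' @param fingerprints Pixels x rho matrix of fingerprint columns (row-major
#'   pixel order) or a `factorization_result` (dead columns must be removed
#'   first, see [live_fingerprints()]).
#' @param dims `c(H, W)` frame shape.
#' @param config A [deconv_config()].
#' @param grain_size Passed to [pairwise_deconvolve()].
#' @return rho x rho list-matrix of `pairwise_deconvolution` objects,
#'   `[[i, k]]` holding o_{i,k}.
#' @export
deconvolve_all_pairs <- function(fingerprints, dims,
                                 config = deconv_config(), grain_size = 3) {
  Wm <- if (inherits(fingerprints, "factorization_result"))
          fingerprints$W else fingerprints
  rho <- ncol(Wm)
  imgs <- lapply(seq_len(rho),
                 function(k) vec_to_frame(Wm[, k], dims[1], dims[2]))
  out <- vector("list", rho * rho)
  dim(out) <- c(rho, rho)
  for (i in seq_len(rho))
    for (k in seq_len(rho))
      out[[i, k]] <- pairwise_deconvolve(imgs[[i]], imgs[[k]], config,
                                         grain_size)
  out
}

#' Partial image of the object around one emitter
#'
#' Sums all pairwise deconvolutions that used emitter `k` as the PSF: every
#' emitter i within the ME patch of k contributes a delta at its relative
#' position `r_i - r_k`, so the sum is a local map of the object centred on
#' emitter k.
#'
#' @param k Emitter index.
#' @param deconvs The list-matrix from [deconvolve_all_pairs()].
#' @param include Optional vector of i indices to sum (default all rho;
#'   index k itself is always included).
#' @return Non-negative H x W partial image `O_k`.
#' @export
partial_image <- function(k, deconvs, include = NULL) {
  rho <- nrow(deconvs)
  include <- sort(unique(c(include %||% seq_len(rho), k)))
  if (any(vapply(include, function(i) is.null(deconvs[[i, k]]), TRUE)))
    stop("missing pairwise deconvolution for emitter ", k)
  Reduce(`+`, lapply(include, function(i) deconvs[[i, k]]$o))
}

#' Build the shift graph from pairwise deconvolutions
#'
#' Nodes are emitters; an undirected edge (i, k) is accepted when both
#' directed deconvolutions pass the quality threshold and their peak
#' positions are antisymmetric (`||r_ik + r_ki|| <= consistency_tol`) — a
#' cheap false-edge filter.  Node positions relative to emitter 1 are
#' accumulated along a maximum-quality spanning tree of the component that
#' contains node 1; chains of within-ME edges are what extend the
#' reconstruction beyond a single isoplanatic patch.
#'
#' After placement, accepted edges are checked for cycle consistency: an
#' edge whose shift disagrees with the tree positions by more than
#' `consistency_tol` is rejected and tree and positions are recomputed,
#' until the surviving graph is self-consistent.  This catches false edges
#' that pass the quality and antisymmetry filters — typically produced by
#' imperfectly demixed fingerprints that blend two emitters.  Residuals of
#' the surviving edges are reported in `cycle_residuals`.
#'
#' @param deconvs List-matrix from [deconvolve_all_pairs()].
#' @param quality_threshold Minimum quality for both directions (default 9,
#'   calibrated on simulation so that within-ME and beyond-ME quality
#'   populations fall on opposite sides; see the methods vignette).
#' @param consistency_tol Euclidean antisymmetry tolerance, pixels.
#' @return A `shift_graph`: `edges` data.frame (i, k, dr, dc, quality,
#'   accepted), `positions` (rho x 2, NA for nodes not connected to node 1),
#'   `placed`, `cycle_residuals`, `graph` (the accepted igraph), `tree`.
#'   Emits a warning of class `speckledemix_disconnected` naming nodes that
#'   cannot be placed.
#' @export
build_shift_graph <- function(deconvs, quality_threshold = 9,
                              consistency_tol = 2) {
  rho <- nrow(deconvs)
  rows <- list()
  for (i in seq_len(rho - 1)) {
    for (k in (i + 1):rho) {
      dik <- deconvs[[i, k]]; dki <- deconvs[[k, i]]
      q <- min(dik$quality, dki$quality)
      anti <- sqrt(sum((dik$peak_position + dki$peak_position)^2))
      acc <- q >= quality_threshold && anti <= consistency_tol
      use <- if (dik$quality >= dki$quality) dik$peak_position
             else -dki$peak_position
      rows[[length(rows) + 1]] <-
        data.frame(i = i, k = k, dr = use[1], dc = use[2], quality = q,
                   antisym = anti, accepted = acc)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(), k = integer(), dr = integer(),
               dc = integer(), quality = numeric(), antisym = numeric(),
               accepted = logical())

  # spanning-tree placement for a given accepted-edge subset
  place <- function(acc) {
    positions <- matrix(NA_real_, rho, 2,
                        dimnames = list(NULL, c("row", "col")))
    positions[1, ] <- c(0, 0)
    g <- igraph::make_empty_graph(n = rho, directed = FALSE)
    tree <- NULL
    if (nrow(acc) > 0) {
      g <- igraph::add_edges(g, rbind(acc$i, acc$k))
      igraph::E(g)$quality <- acc$quality
      igraph::E(g)$dr <- acc$dr
      igraph::E(g)$dc <- acc$dc
      tree <- igraph::mst(g, weights = 1 / (1 + igraph::E(g)$quality))
      # BFS from node 1 along the tree, accumulating shifts r_ik = r_i - r_k
      visited <- rep(FALSE, rho); visited[1] <- TRUE
      queue <- 1L
      while (length(queue) > 0) {
        k <- queue[1]; queue <- queue[-1]
        for (eid in igraph::incident(tree, k)) {
          ends <- igraph::ends(tree, eid)
          nb <- if (ends[1] == k) ends[2] else ends[1]
          if (visited[nb]) next
          sh <- c(igraph::E(tree)$dr[eid], igraph::E(tree)$dc[eid])
          # edge stores r_i - r_k for (i = ends[1], k = ends[2])
          positions[nb, ] <- if (nb == ends[1]) positions[k, ] + sh
                             else positions[k, ] - sh
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    resid <- if (nrow(acc) > 0) apply(acc, 1, function(e) {
      pi_ <- positions[e[["i"]], ]; pk_ <- positions[e[["k"]], ]
      if (any(is.na(c(pi_, pk_)))) return(NA_real_)
      sqrt(sum((c(e[["dr"]], e[["dc"]]) - (pi_ - pk_))^2))
    }) else numeric(0)
    list(positions = positions, graph = g, tree = tree, resid = resid)
  }

  # iterative cycle-consistency pruning: drop the worst-closing edge until
  # every surviving accepted edge agrees with the tree positions
  repeat {
    acc <- edges[edges$accepted, , drop = FALSE]
    pl <- place(acc)
    bad <- which(pl$resid > consistency_tol)
    if (length(bad) == 0 || nrow(acc) == 0) break
    worst <- bad[which.max(pl$resid[bad])]
    edges$accepted[which(edges$accepted)[worst]] <- FALSE
  }
  positions <- pl$positions
  cyc <- pl$resid
  g <- pl$graph
  tree <- pl$tree
  placed <- which(!is.na(positions[, 1]))
  if (length(placed) == 0) stop("emitter 1 could not be placed")
  unplaced <- setdiff(seq_len(rho), placed)
  if (length(unplaced) > 0)
    warning(warningCondition(
      paste0("nodes not connected to emitter 1 (cannot be placed): ",
             paste(unplaced, collapse = ", ")),
      class = "speckledemix_disconnected"))
  structure(list(edges = edges, positions = positions, placed = placed,
                 cycle_residuals = cyc, graph = g, tree = tree,
                 quality_threshold = quality_threshold,
                 consistency_tol = consistency_tol),
            class = "shift_graph")
}

#' Stitch partial images into the global reconstruction
#'
#' Places every partial image `O_k` at its shift-graph position relative to
#' emitter 1 on an expanded canvas and sums:
#' `O_global(r) = sum_k O_k(r - r_k1)`.  The result is defined up to a
#' global translation.
#'
#' @param partials List of H x W partial images, indexed by emitter.
#' @param graph A `shift_graph`; only placed nodes are composed.
#' @return A `global_image`: `canvas`, `origin` (1-based canvas coordinate
#'   of the centre of emitter 1's partial), `offsets` (integer placement of
#'   each partial), `placed`.
#' @export
compose_global <- function(partials, graph) {
  placed <- graph$placed
  if (length(placed) == 0) stop("no placeable nodes")
  d <- dim(partials[[placed[1]]])
  Hh <- d[1]; Ww <- d[2]
  off <- round(graph$positions[placed, , drop = FALSE])
  r0 <- min(off[, 1]); c0 <- min(off[, 2])
  canvas <- matrix(0, Hh + max(off[, 1]) - r0, Ww + max(off[, 2]) - c0)
  for (m in seq_along(placed)) {
    k <- placed[m]
    rr <- off[m, 1] - r0; cc <- off[m, 2] - c0
    canvas[rr + seq_len(Hh), cc + seq_len(Ww)] <-
      canvas[rr + seq_len(Hh), cc + seq_len(Ww)] + partials[[k]]
  }
  ctr <- c(floor(Hh / 2) + 1L, floor(Ww / 2) + 1L)
  origin <- c(round(graph$positions[placed[1], 1]) - r0 + ctr[1],
              round(graph$positions[placed[1], 2]) - c0 + ctr[2])
  structure(list(canvas = canvas, origin = origin,
                 offsets = cbind(row = off[, 1] - r0, col = off[, 2] - c0),
                 placed = placed),
            class = "global_image")
}

#' Fingerprint-based reconstruction (FBR)
#'
#' Orchestrates the whole reconstruction from a set of demixed fingerprints:
#' all-pairs TV deconvolution, shift-graph construction, partial images, and
#' global stitching.  Deterministic given its inputs.
#'
#' @param fingerprints Pixels x rho matrix or `factorization_result` (dead
#'   columns are dropped automatically).
#' @param dims `c(H, W)` frame shape.
#' @param config A [deconv_config()].
#' @param quality_threshold,consistency_tol Passed to [build_shift_graph()].
#' @param accepted_only If `TRUE`, each partial image sums only deconvolutions
#'   from accepted neighbours of k (plus k itself) instead of all rho terms.
#'   Default `FALSE`: the literal all-pairs sum.
#' @param grain_size Peak-exclusion radius for quality scores.
#' @return List: `global` (a `global_image`), `graph` (`shift_graph`),
#'   `partials`, `deconvs`.
#' @export
reconstruct <- function(fingerprints, dims, config = deconv_config(),
                        quality_threshold = 9, consistency_tol = 2,
                        accepted_only = FALSE, grain_size = 3) {
  Wm <- live_fingerprints(fingerprints)
  if (ncol(Wm) < 1) stop("no live fingerprints")
  deconvs <- deconvolve_all_pairs(Wm, dims, config, grain_size)
  rho <- ncol(Wm)
  graph <- if (rho > 1) build_shift_graph(deconvs, quality_threshold,
                                          consistency_tol)
           else structure(list(edges = NULL,
                               positions = matrix(0, 1, 2), placed = 1L,
                               cycle_residuals = numeric(0)),
                          class = "shift_graph")
  partials <- vector("list", rho)
  for (k in graph$placed) {
    inc <- if (accepted_only && !is.null(graph$edges)) {
      e <- graph$edges[graph$edges$accepted &
                         (graph$edges$i == k | graph$edges$k == k), ,
                       drop = FALSE]
      unique(c(e$i, e$k, k))
    } else NULL
    partials[[k]] <- partial_image(k, deconvs, include = inc)
  }
  global <- compose_global(partials, graph)
  list(global = global, graph = graph, partials = partials,
       deconvs = deconvs)
}

#' Drop dead fingerprint columns
#'
#' @param fingerprints Matrix or `factorization_result`.
#' @return Matrix of live fingerprint columns.
#' @export
live_fingerprints <- function(fingerprints) {
  if (inherits(fingerprints, "factorization_result"))
    fingerprints$W[, !fingerprints$dead, drop = FALSE]
  else as.matrix(fingerprints)
}

#' @export
print.shift_graph <- function(x, ...) {
  n_acc <- if (is.null(x$edges)) 0 else sum(x$edges$accepted)
  cat("shift_graph:", nrow(x$positions), "nodes,", n_acc,
      "accepted edges,", length(x$placed), "placed\n")
  invisible(x)
}

#' @export
print.global_image <- function(x, ...) {
  cat("global_image:", nrow(x$canvas), "x", ncol(x$canvas),
      "canvas,", length(x$placed), "partials composed\n")
  invisible(x)
}
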