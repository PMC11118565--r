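#' Rolling temporal average of a movie
#'
#' Replaces each frame by the mean of a centred window of frames, the first
#' step of the patch-detection pipeline (it damps frame-to-frame intensity
#' fluctuations before masks are computed). At the movie edges the window is
#' truncated to the available frames, so a stationary series keeps its mean.
#'
#' @param stack a `MovieStack` or a 3D array `[row, col, frame]`.
#' @param window odd window size in frames (default 3).
#' @return same type as `stack`, same shape.
#' @export
rolling_time_average <- function(stack, window = 3L) {
  if (inherits(stack, "MovieStack")) {
    stack$channels <- lapply(stack$channels, rolling_time_average, window = window)
    return(stack)
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be a positive odd integer")
  nt <- dim(stack)[3]
  if (window > nt) stop("window (", window, ") exceeds number of frames (", nt, ")")
  h <- window %/% 2L
  # cumulative sum along time; truncated window at the edges
  cs <- array(0, dim(stack) + c(0, 0, 1))
  for (t in seq_len(nt)) cs[, , t + 1] <- cs[, , t] + stack[, , t]
  out <- array(0, dim(stack))
  for (t in seq_len(nt)) {
    lo <- max(1L, t - h); hi <- min(nt, t + h)
    out[, , t] <- (cs[, , hi + 1] - cs[, , lo]) / (hi - lo + 1)
  }
  out
}

#' Gaussian smoothing of a frame
#'
#' Separable Gaussian convolution with replicated (edge-clamped) boundaries.
#' Used to smooth averaged movies before edge detection; the default
#' `sigma = 1` px is a configuration choice, not a literature constant.
#'
#' @param frame 2D numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return smoothed matrix of the same size.
#' @export
gaussian_blur <- function(frame, sigma = 1) {
  stopifnot(is.matrix(frame), sigma >= 0)
  if (sigma == 0) return(frame)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv_sep_replicate(frame, k)
}

# separable 1D convolution along rows then cols, replicate boundary
conv_sep_replicate <- function(frame, k) {
  r <- (length(k) - 1L) %/% 2L
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
  ri <- pad_idx(nrow(frame)); ci <- pad_idx(ncol(frame))
  x <- frame[ri, , drop = FALSE]
  out <- matrix(0, nrow(frame), ncol(frame))
  for (j in seq_along(k))
    out <- out + k[j] * x[seq_len(nrow(frame)) + (j - 1L), , drop = FALSE]
  x <- out[, ci, drop = FALSE]
  out2 <- matrix(0, nrow(frame), ncol(frame))
  for (j in seq_along(k))
    out2 <- out2 + k[j] * x[, seq_len(ncol(frame)) + (j - 1L), drop = FALSE]
  out2
}

# 2D correlation with a small kernel, replicate boundary
conv2_replicate <- function(frame, kern) {
  kr <- (nrow(kern) - 1L) %/% 2L; kc <- (ncol(kern) - 1L) %/% 2L
  ri <- pmin(pmax(seq_len(nrow(frame) + 2L * kr) - kr, 1L), nrow(frame))
  ci <- pmin(pmax(seq_len(ncol(frame) + 2L * kc) - kc, 1L), ncol(frame))
  x <- frame[ri, ci, drop = FALSE]
  out <- matrix(0, nrow(frame), ncol(frame))
  for (i in seq_len(nrow(kern))) for (j in seq_len(ncol(kern)))
    out <- out + kern[i, j] *
      x[seq_len(nrow(frame)) + (i - 1L), seq_len(ncol(frame)) + (j - 1L), drop = FALSE]
  out
}

#' Sobel gradient magnitude
#'
#' Applies the 3x3 Sobel kernels along rows and columns and returns the
#' per-pixel gradient magnitude, the edge transform used to delineate
#' filaments and LIM-protein assemblies before thresholding.
#'
#' @param frame 2D numeric matrix.
#' @return matrix of gradient magnitudes, same size.
#' @export
sobel_edges <- function(frame) {
  if (!is.matrix(frame)) frame <- as.matrix(frame)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv2_replicate(frame, kx)
  gy <- conv2_replicate(frame, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Automatic intensity thresholding
#'
#' Histogram-based auto-thresholding with the four methods the analysis
#' pipelines rely on: `"otsu"` maximizes between-class variance, `"li"`
#' iteratively minimizes the cross-entropy between image and binarization,
#' `"yen"` maximizes Yen's maximum-correlation criterion, and `"triangle"`
#' maximizes the distance between the histogram and the chord from its peak
#' to its far end. Histograms use 256 bins spanning the frame's min-max
#' range (the 8-bit convention of the reference implementations).
#'
#' @param frame 2D numeric matrix with at least two distinct values.
#' @param method one of `"li"`, `"yen"`, `"otsu"`, `"triangle"`.
#' @param nbins number of histogram bins (default 256).
#' @return list with `threshold` (numeric) and `mask` (logical matrix,
#'   `frame > threshold`).
#' @export
auto_threshold <- function(frame, method = c("li", "yen", "otsu", "triangle"),
                           nbins = 256L) {
  method <- match.arg(method)
  v <- as.numeric(frame)
  rng <- range(v)
  if (!(rng[2] > rng[1]))
    stop("degenerate histogram: frame is constant, cannot threshold")
  thr <- switch(method,
    otsu     = threshold_otsu(v, rng, nbins),
    yen      = threshold_yen(v, rng, nbins),
    triangle = threshold_triangle(v, rng, nbins),
    li       = threshold_li(v))
  list(threshold = thr, mask = matrix(frame > thr, nrow(frame), ncol(frame)))
}

hist_counts <- function(v, rng, nbins) {
  # bin i covers [lo + (i-1)w, lo + iw); top value folded into last bin
  w <- (rng[2] - rng[1]) / nbins
  idx <- pmin(floor((v - rng[1]) / w) + 1L, nbins)
  tabulate(idx, nbins)
}

bin_centers <- function(rng, nbins) {
  w <- (rng[2] - rng[1]) / nbins
  rng[1] + (seq_len(nbins) - 0.5) * w
}

threshold_otsu <- function(v, rng, nbins) {
  h <- hist_counts(v, rng, nbins)
  ctr <- bin_centers(rng, nbins)
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * ctr)
  muT <- mu[nbins]
  # between-class variance at a cut after bin t
  valid <- which(w0 > 0 & w0 < 1)
  bcv <- (muT * w0[valid] - mu[valid])^2 / (w0[valid] * (1 - w0[valid]))
  t <- valid[which.max(bcv)]
  ctr[t]  # mask is "> threshold": bin t itself stays in background
}

threshold_yen <- function(v, rng, nbins) {
  h <- hist_counts(v, rng, nbins)
  ctr <- bin_centers(rng, nbins)
  p <- h / sum(h)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- sum(p^2) - P1sq
  valid <- which(P1 > 0 & P1 < 1 & P1sq > 0 & P2sq > 0)
  crit <- -log(P1sq[valid] * P2sq[valid]) +
    2 * log(P1[valid] * (1 - P1[valid]))
  t <- valid[which.max(crit)]
  ctr[t]
}

threshold_triangle <- function(v, rng, nbins) {
  h <- hist_counts(v, rng, nbins)
  peak <- which.max(h)
  nz <- which(h > 0)
  # chord from the peak to the farther histogram extremity
  far <- if ((peak - nz[1]) >= (nz[length(nz)] - peak)) nz[1] else nz[length(nz)]
  if (far == peak) return(bin_centers(rng, nbins)[peak])
  idx <- if (far > peak) seq(peak, far) else seq(far, peak)
  x <- idx; y <- h[idx]
  # distance from (x, y) to line through (peak, h[peak]) and (far, h[far])
  x1 <- peak; y1 <- h[peak]; x2 <- far; y2 <- h[far]
  d <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1)
  t <- idx[which.max(d)]
  bin_centers(rng, nbins)[t]
}

threshold_li <- function(v) {
  # iterative minimum cross entropy; values shifted to be strictly positive
  shift <- if (min(v) <= 0) 1 - min(v) else 0
  x <- v + shift
  t_new <- mean(x)
  repeat {
    t_old <- t_new
    lo <- x[x <= t_old]; hi <- x[x > t_old]
    if (!length(lo) || !length(hi)) break
    m0 <- mean(lo); m1 <- mean(hi)
    t_new <- (m1 - m0) / (log(m1) - log(m0))
    if (!is.finite(t_new) || abs(t_new - t_old) < 1e-6 * t_old) break
  }
  t_new - shift
}

#' Binary morphology
#'
#' Erosion, dilation and hole filling with a 3x3 square structuring element
#' (the convention all derived measures, in particular the bundle thickness
#' index, assume), applied `iterations` times.
#'
#' @param mask logical or 0/1 matrix.
#' @param op one of `"erode"`, `"dilate"`, `"fill_holes"`.
#' @param iterations non-negative integer (ignored for `fill_holes`).
#' @return logical matrix.
#' @export
morphology <- function(mask, op = c("erode", "dilate", "fill_holes"),
                       iterations = 1L) {
  op <- match.arg(op)
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("iterations must be >= 0")
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (op == "fill_holes") return(EBImage::fillHull(m) != 0)
  if (iterations == 0L) return(m != 0)
  kern <- EBImage::makeBrush(3, "box")
  for (i in seq_len(iterations))
    m <- if (op == "erode") EBImage::erode(m, kern) else EBImage::dilate(m, kern)
  matrix(as.numeric(m) != 0, nrow(mask), ncol(mask))
}

#' Connected-component labeling
#'
#' Labels the connected components of a binary mask under 8- (default) or
#' 4-connectivity. 8-connectivity is the default because thin, diagonal,
#' filament-like objects fragment under 4-connectivity. Labels are assigned
#' in raster order of each component's first pixel, so output is
#' deterministic.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix; 0 = background, components labeled `1..K`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask != 0)
  out <- matrix(0L, nr, nc)
  if (!length(fg)) return(out)
  inmask <- matrix(FALSE, nr, nc); inmask[fg] <- TRUE
  row <- ((fg - 1L) %% nr) + 1L
  col <- ((fg - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))                      # down, right
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (o in offs) {
    r2 <- row + o[1]; c2 <- col + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- inmask[nb]
    if (any(hit)) edges <- c(edges, rbind(fg[ok][hit], nb[hit]))
  }
  # map pixel indices to 1..n node ids; fg is sorted, so node order is raster order
  id <- integer(nr * nc); id[fg] <- seq_along(fg)
  g <- igraph::make_graph(id[edges], n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  relab <- integer(max(comp))
  firsts <- comp[!duplicated(comp)]
  relab[firsts] <- seq_along(firsts)
  out[fg] <- relab[comp]
  out
}

#' Filter labeled objects by area
#'
#' Keeps objects whose pixel area lies in `[min_area, max_area]` (both
#' inclusive) and relabels the survivors contiguously. The default bounds
#' are the LIM-protein bandpass of the patch pipeline (10-150 px).
#'
#' @param labels integer label matrix (0 = background).
#' @param min_area minimum area in pixels.
#' @param max_area maximum area in pixels, or `NULL` for unbounded.
#' @return relabeled integer matrix.
#' @export
size_filter <- function(labels, min_area = 10L, max_area = 150L) {
  if (is.null(max_area)) max_area <- Inf
  if (min_area > max_area) stop("min_area exceeds max_area")
  k <- max(labels)
  if (k == 0L) return(labels)
  areas <- tabulate(labels[labels > 0], k)
  keep <- which(areas >= min_area & areas <= max_area)
  relab <- integer(k)
  relab[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- relab[labels[labels > 0]]
  out
}

#' Morphological rolling-ball background subtraction
#'
#' Estimates the smooth background of a frame as its grayscale opening with
#' a flat disc of the given radius (erosion then dilation), and subtracts
#' it, clamping at zero. Structures smaller than the disc survive; smooth
#' gradients and offsets are removed.
#'
#' @param frame 2D numeric matrix.
#' @param radius disc radius in pixels (default 50).
#' @return background-subtracted matrix, all values >= 0.
#' @export
rolling_ball_background_subtract <- function(frame, radius = 50) {
  stopifnot(is.matrix(frame))
  if (radius <= 0) stop("radius must be > 0")
  if (2 * radius + 1 >= min(dim(frame)))
    stop("radius too large for frame (", paste(dim(frame), collapse = "x"), ")")
  r <- as.integer(radius)
  kern <- EBImage::makeBrush(2L * r + 1L, "disc")
  # replicate-pad so the border is not eroded against an implicit zero frame
  ri <- pmin(pmax(seq_len(nrow(frame) + 2L * r) - r, 1L), nrow(frame))
  ci <- pmin(pmax(seq_len(ncol(frame) + 2L * r) - r, 1L), ncol(frame))
  padded <- frame[ri, ci, drop = FALSE]
  # EBImage works on [0,1]; opening commutes with affine rescaling
  lo <- min(padded); hi <- max(padded)
  if (hi > lo) {
    g <- (padded - lo) / (hi - lo)
    bg <- EBImage::dilate(EBImage::erode(g, kern), kern) * (hi - lo) + lo
  } else bg <- padded
  bg <- bg[r + seq_len(nrow(frame)), r + seq_len(ncol(frame)), drop = FALSE]
  out <- frame - bg
  out[out < 0] <- 0
  out
}

#' Photobleaching correction by histogram matching
#'
#' Maps every frame's intensity distribution onto a reference frame's
#' distribution by quantile (rank) mapping, the standard correction for
#' global multiplicative photobleaching: a planted exponential decay of the
#' whole field is removed exactly up to quantization.
#'
#' @param stack 3D array `[row, col, frame]` or a `MovieStack` (all channels
#'   corrected independently).
#' @param reference_frame index of the reference frame (default 1).
#' @return corrected stack, same type and shape.
#' @export
bleach_correct_histogram_match <- function(stack, reference_frame = 1L) {
  if (inherits(stack, "MovieStack")) {
    stack$channels <- lapply(stack$channels, bleach_correct_histogram_match,
                             reference_frame = reference_frame)
    return(stack)
  }
  nt <- dim(stack)[3]
  if (reference_frame < 1 || reference_frame > nt) stop("invalid reference frame")
  ref <- stack[, , reference_frame]
  if (diff(range(ref)) == 0) stop("constant reference frame: histogram degenerate")
  ref_sorted <- sort(as.numeric(ref))
  out <- stack
  for (t in seq_len(nt)) {
    if (t == reference_frame) next
    v <- as.numeric(stack[, , t])
    mapped <- numeric(length(v))
    mapped[order(v)] <- ref_sorted
    out[, , t] <- matrix(mapped, dim(stack)[1], dim(stack)[2])
  }
  out
}
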