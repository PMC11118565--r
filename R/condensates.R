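## Condensate (droplet) segmentation, enrichment, FRAP traces.

#' Droplet mask and area fraction
#'
#' Thresholds every supplied channel (Otsu), removes objects smaller than
#' `min_size_px`, multiplies the masks together (a droplet must appear in
#' every channel) and labels the result. The area fraction is droplet
#' pixels over field pixels.
#'
#' @param channels named list of 2D matrices (typically 3 channels; a
#'   declared subset for bipartite experiments).
#' @param min_size_px per-channel minimum object size (default 20 px).
#' @param connectivity labeling connectivity.
#' @return list with `labels` (label matrix), `area_fraction`, and
#'   `areas_px` (per-droplet pixel areas).
#' @export
droplet_mask <- function(channels, min_size_px = 20L, connectivity = 8L) {
  stopifnot(is.list(channels), length(channels) >= 1)
  masks <- lapply(names(channels), function(ch) {
    fr <- channels[[ch]]
    if (diff(range(fr)) == 0)
      stop("degenerate channel (constant): ", ch)
    m <- auto_threshold(fr, "otsu")$mask
    size_filter(label_components(m, connectivity), min_size_px, NULL) > 0
  })
  prod_mask <- Reduce(`&`, masks)
  labels <- label_components(prod_mask, connectivity)
  k <- max(labels)
  list(labels = labels,
       area_fraction = sum(prod_mask) / length(prod_mask),
       areas_px = if (k > 0) tabulate(labels[labels > 0], k) else integer(0))
}

#' Per-droplet enrichment
#'
#' Segments droplets from the mask-source channels (Otsu, >= 20 px,
#' intersected) and measures, for each droplet, the mean intensity of the
#' measure channel inside the mask divided by the mean of its local
#' background (dilated ring). Supports measuring a different channel than
#' the mask source (for constructs too dim to segment). Droplets smaller
#' than `min_area_um2` or with enrichment below `floor` are excluded; the
#' area cutoff is configured in um^2 and converted by the pixel size (the
#' printed pixel-unit equivalent of this cutoff is internally
#' inconsistent, so physical units are authoritative).
#'
#' @param channels named list of 2D matrices.
#' @param mask_source_channels channel names used to build the droplet mask.
#' @param measure_channel channel quantified inside each droplet.
#' @param pixel_size um per px.
#' @param min_area_um2 exclusion cutoff (default 0.18 um^2).
#' @param floor minimum reported enrichment (default 1.1).
#' @param min_size_px per-channel mask size filter (default 20 px).
#' @param dilation_iterations background ring control (default 3).
#' @return data.frame: `droplet`, `area_px`, `area_um2`, `enrichment`.
#' @export
droplet_enrichment <- function(channels, mask_source_channels, measure_channel,
                               pixel_size, min_area_um2 = 0.18, floor = 1.1,
                               min_size_px = 20L, dilation_iterations = 3L) {
  dm <- droplet_mask(channels[mask_source_channels], min_size_px)
  labels <- dm$labels
  k <- max(labels)
  img <- channels[[measure_channel]]
  min_area_px <- min_area_um2 / pixel_size^2
  out <- list()
  all_mask <- labels > 0
  for (i in seq_len(k)) {
    m <- labels == i
    area <- sum(m)
    if (area * pixel_size^2 < min_area_um2) next
    ring <- morphology(m, "dilate", dilation_iterations) & !all_mask
    if (!any(ring)) {
      warning("droplet ", i, " skipped: empty background ring")
      next
    }
    enr <- mean(img[m]) / mean(img[ring])
    if (enr < floor) next
    out[[length(out) + 1L]] <- data.frame(
      droplet = i, area_px = area, area_um2 = area * pixel_size^2,
      enrichment = enr)
  }
  if (!length(out))
    return(data.frame(droplet = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), enrichment = numeric(0)))
  do.call(rbind, out)
}

#' FRAP trace extraction and normalization
#'
#' Bleach-corrects the full-field stack by histogram matching to the first
#' frame, averages intensity in each circular ROI per frame, and min-max
#' normalizes every trace to `[0, 1]`. After normalization the recovery
#' plateau of a bleached droplet estimates its mobile fraction.
#'
#' @param stack 3D array `[row, col, frame]` (one channel).
#' @param rois data.frame with `roi`, `center_r`, `center_c`, `radius`.
#' @param bleach_frame frame index of the bleach (recovery starts after).
#' @param bleach_correct logical (default TRUE).
#' @return list with `traces` (long data.frame: roi, frame, raw,
#'   corrected, normalized) and `plateau` (per ROI: mean normalized value
#'   over the final 20% of frames).
#' @export
frap_analyze <- function(stack, rois, bleach_frame, bleach_correct = TRUE) {
  stopifnot(all(c("roi", "center_r", "center_c", "radius") %in% names(rois)))
  nt <- dim(stack)[3]
  if (bleach_frame < 1 || bleach_frame >= nt) stop("invalid bleach frame")
  corrected <- if (bleach_correct)
    bleach_correct_histogram_match(stack, 1L) else stack
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  out <- list()
  plateau <- numeric(nrow(rois))
  tail_frames <- seq(max(bleach_frame + 1L, ceiling(nt * 0.8)), nt)
  for (i in seq_len(nrow(rois))) {
    d2 <- outer((seq_len(nr) - rois$center_r[i])^2,
                (seq_len(nc) - rois$center_c[i])^2, "+")
    m <- d2 <= rois$radius[i]^2
    if (!any(m)) stop("ROI ", rois$roi[i], " outside field or empty")
    raw <- apply(stack, 3, function(fr) mean(fr[m]))
    cor <- apply(corrected, 3, function(fr) mean(fr[m]))
    rng <- range(cor)
    if (diff(rng) == 0) stop("constant trace for ROI ", rois$roi[i],
                             ": cannot normalize")
    norm <- (cor - rng[1]) / diff(rng)
    plateau[i] <- mean(norm[tail_frames])
    out[[i]] <- data.frame(roi = rois$roi[i], frame = seq_len(nt),
                           raw = raw, corrected = cor, normalized = norm)
  }
  list(traces = do.call(rbind, out),
       plateau = data.frame(roi = rois$roi, plateau = plateau))
}

#' Exponential FRAP recovery fit (optional helper)
#'
#' Fits `I(t) = plateau * (1 - exp(-k t))` to the post-bleach normalized
#' trace by nonlinear least squares and reports the plateau (mobile
#' fraction estimate), rate `k` (1/s) and half-time `ln(2)/k`. The
#' normalized traces themselves are the primary output of the analysis;
#' this fit is an extension.
#'
#' @param normalized numeric normalized trace.
#' @param bleach_frame frame of the bleach.
#' @param frame_interval seconds per frame.
#' @return list with `plateau`, `k`, `half_time_s`.
#' @export
frap_fit_exponential <- function(normalized, bleach_frame, frame_interval) {
  post <- normalized[(bleach_frame + 1L):length(normalized)]
  tt <- (seq_along(post) - 1) * frame_interval
  df <- data.frame(y = post, t = tt)
  fit <- stats::nls(y ~ A * (1 - exp(-k * t)), data = df,
                    start = list(A = max(post), k = 1 / max(tt[2], 1)),
                    control = stats::nls.control(warnOnly = TRUE))
  cf <- stats::coef(fit)
  list(plateau = unname(cf["A"]), k = unname(cf["k"]),
       half_time_s = log(2) / unname(cf["k"]))
}
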