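## Bundle thickness, strain-site kymographs and traces, repair frequency,
## SFSS recovery-path categorization and recovery rates.

#' Bundle thickness index
#'
#' For every frame: Otsu-threshold the actin channel, remove objects
#' smaller than `min_object_px`, and count the number of binary erosions
#' (3x3 element) needed to reduce the mask's area to at most the area of
#' the first frame's mask. The first frame's index is 0 by construction;
#' a frame whose mask is already no larger than the first also scores 0.
#'
#' @param actin_stack 3D array `[row, col, frame]`.
#' @param min_object_px size filter (default 50 px).
#' @param max_iterations safety bound on the erosion count.
#' @return integer vector, one index per frame.
#' @export
bundle_thickness_index <- function(actin_stack, min_object_px = 50L,
                                   max_iterations = 64L) {
  nt <- dim(actin_stack)[3]
  if (nt < 2) stop("need at least 2 frames")
  frame_mask <- function(t) {
    fr <- actin_stack[, , t]
    if (diff(range(fr)) == 0) return(matrix(FALSE, nrow(fr), ncol(fr)))
    m <- auto_threshold(fr, "otsu")$mask
    size_filter(label_components(m), min_object_px, NULL) > 0
  }
  ref_area <- sum(frame_mask(1))
  if (ref_area == 0) stop("empty first-frame mask")
  vapply(seq_len(nt), function(t) {
    m <- frame_mask(t)
    k <- 0L
    while (sum(m) > ref_area && k < max_iterations) {
      m <- morphology(m, "erode", 1L)
      k <- k + 1L
    }
    k
  }, integer(1))
}

#' Kymograph along a line
#'
#' Samples the intensity along a straight line at 1 px spacing for every
#' frame, averaging across the line's width (parallel offset lines,
#' bilinear interpolation), and assembles the distance x time matrix.
#'
#' @param stack 3D array `[row, col, frame]` (one channel).
#' @param line numeric c(r0, c0, r1, c1), line endpoints in px.
#' @param width_px averaging width perpendicular to the line (default 3).
#' @return object of class `Kymograph`: list with `intensity`
#'   (distance x time matrix), `line`, `width_px`.
#' @export
make_kymograph <- function(stack, line, width_px = 3L) {
  stopifnot(length(line) == 4)
  p0 <- line[1:2]; p1 <- line[3:4]
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length line")
  n_s <- floor(len) + 1L
  u <- (p1 - p0) / len              # along-line unit vector
  v <- c(-u[2], u[1])               # perpendicular
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, by = 1)
  nt <- dim(stack)[3]
  kymo <- matrix(0, n_s, nt)
  ss <- seq(0, by = 1, length.out = n_s)
  for (t in seq_len(nt)) {
    fr <- stack[, , t]
    acc <- numeric(n_s)
    for (o in offs) {
      rr <- p0[1] + ss * u[1] + o * v[1]
      cc <- p0[2] + ss * u[2] + o * v[2]
      acc <- acc + bilinear_sample(fr, rr, cc)
    }
    kymo[, t] <- acc / length(offs)
  }
  structure(list(intensity = kymo, line = line, width_px = width_px),
            class = "Kymograph")
}

bilinear_sample <- function(fr, rr, cc) {
  nr <- nrow(fr); nc <- ncol(fr)
  rr <- pmin(pmax(rr, 1), nr); cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(rr), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr_r <- rr - r0; fr_c <- cc - c0
  i00 <- fr[cbind(r0, c0)];     i10 <- fr[cbind(r0 + 1, c0)]
  i01 <- fr[cbind(r0, c0 + 1)]; i11 <- fr[cbind(r0 + 1, c0 + 1)]
  i00 * (1 - fr_r) * (1 - fr_c) + i10 * fr_r * (1 - fr_c) +
    i01 * (1 - fr_r) * fr_c + i11 * fr_r * fr_c
}

#' Strain-site intensity traces from kymographs
#'
#' Actin: spatial mean of the kymograph per time point, min-max
#' normalized. Partner (VASP): spatial mean per time point divided by its
#' mean over the pre-ablation frames (fold change, baseline 1).
#'
#' @param actin_kymo `Kymograph` of the actin channel.
#' @param ablation_frame frame at which ablation occurred.
#' @param partner_kymo optional `Kymograph` of the partner channel.
#' @return data.frame with `frame`, `actin_norm` and (if partner given)
#'   `partner_fold`.
#' @export
strain_site_traces <- function(actin_kymo, ablation_frame,
                               partner_kymo = NULL) {
  a <- colMeans(actin_kymo$intensity)
  rng <- range(a)
  if (diff(rng) == 0) stop("flat actin kymograph")
  out <- data.frame(frame = seq_along(a),
                    actin_norm = (a - rng[1]) / diff(rng))
  if (!is.null(partner_kymo)) {
    v <- colMeans(partner_kymo$intensity)
    if (ablation_frame < 1) stop("no pre-ablation frames: fold undefined")
    pre <- mean(v[seq_len(ablation_frame)])
    if (pre == 0) stop("zero pre-ablation partner intensity")
    out$partner_fold <- v / pre
  }
  out
}

#' Repair frequency contingency table and Fisher's exact test
#'
#' Tabulates strain-site outcomes (`repaired` / `not_repaired`) by
#' condition and runs the two-sided Fisher exact test on the 2x2 table.
#'
#' @param records data.frame with `condition` and `outcome` columns.
#' @return list with `table` (condition x outcome) and `p_value`.
#' @export
repair_frequency <- function(records) {
  stopifnot(all(c("condition", "outcome") %in% names(records)))
  tab <- table(records$condition, records$outcome)
  if (nrow(tab) < 2) stop("need at least 2 conditions")
  list(table = tab, p_value = stats::fisher.test(tab)$p.value)
}

#' Segment a strain-site kymograph into ends and center
#'
#' Splits the kymograph's distance axis into the first 10% (left end),
#' middle 80% (center) and last 10% (right end) of the strain-site span,
#' and averages the intensity over each segment per time point.
#'
#' @param kymo a `Kymograph` (distance axis = strain-site span).
#' @param span optional integer range (rows of the kymograph) delimiting
#'   the site; defaults to the full distance axis.
#' @return list of numeric traces: `left`, `center`, `right`.
#' @export
sfss_segments <- function(kymo, span = NULL) {
  m <- kymo$intensity
  if (!is.null(span)) m <- m[span, , drop = FALSE]
  n <- nrow(m)
  if (n < 10) stop("strain-site span < 10 px: segments degenerate")
  n_end <- max(1L, round(0.10 * n))
  left <- seq_len(n_end)
  right <- seq(n - n_end + 1L, n)
  center <- setdiff(seq_len(n), c(left, right))
  list(left = colMeans(m[left, , drop = FALSE]),
       center = colMeans(m[center, , drop = FALSE]),
       right = colMeans(m[right, , drop = FALSE]))
}

#' Segment-wise recovery rates by linear regression
#'
#' Ordinary least-squares slope of each segment trace within the fit
#' window (default 40-320 s, expressed in seconds from movie start).
#'
#' @param segments list of traces from [sfss_segments()].
#' @param frame_interval seconds per frame.
#' @param fit_window c(start_s, end_s) of the fit.
#' @return named numeric vector of slopes (intensity/s).
#' @export
recovery_rates <- function(segments, frame_interval,
                           fit_window = c(40, 320)) {
  tt <- (seq_along(segments[[1]]) - 1) * frame_interval
  sel <- tt >= fit_window[1] & tt <= fit_window[2]
  if (sum(sel) < 3) stop("fewer than 3 points in fit window")
  vapply(segments, function(y)
    unname(stats::coef(stats::lm(y[sel] ~ tt[sel]))[2]), numeric(1))
}

#' Paired end-vs-center comparison of recovery rates
#'
#' For each site: the average of the two end slopes against the center
#' slope; across sites, a paired t test.
#'
#' @param site_rates list of per-site named slope vectors (from
#'   [recovery_rates()]).
#' @return list with `center`, `ends` (per-site values), `t`, `df`,
#'   `p_value`.
#' @export
paired_rate_comparison <- function(site_rates) {
  ctr <- vapply(site_rates, function(r) r[["center"]], numeric(1))
  ends <- vapply(site_rates, function(r) mean(c(r[["left"]], r[["right"]])),
                 numeric(1))
  tt <- stats::t.test(ctr, ends, paired = TRUE)
  list(center = ctr, ends = ends, t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value)
}

#' Advisory recovery-path categorization
#'
#' Compares the recovery onsets of the three segments (first time each
#' smoothed trace exceeds `onset_frac` of its final recovery amplitude).
#' Segments whose onsets fall within `tol_frames` of the earliest are
#' "leading": all three leading is `even`; only the center, `center`;
#' both ends, `both_ends`; the center plus one end, `one_end_center`.
#' Manual annotations always take precedence over this helper; it fills
#' an advisory column for agreement checks, never the authoritative one.
#'
#' @param segments list of traces from [sfss_segments()].
#' @param ablation_frame ablation frame index.
#' @param onset_frac onset threshold as a fraction of final amplitude.
#' @param tol_frames tolerance for "simultaneous" onsets (default 2).
#' @param smooth_window smoothing of traces before onset detection.
#' @return one of `"even"`, `"center"`, `"one_end_center"`, `"both_ends"`,
#'   `"uncategorized"`.
#' @export
categorize_recovery_path <- function(segments, ablation_frame,
                                     onset_frac = 0.2, tol_frames = 2L,
                                     smooth_window = 3L) {
  onset <- vapply(segments, function(y) {
    post <- rolling_mean_trunc(y[(ablation_frame + 1L):length(y)],
                               smooth_window)
    base <- post[1]
    amp <- post[length(post)] - base
    if (amp <= 0) return(NA_real_)
    o <- which(post - base >= onset_frac * amp)
    if (!length(o)) NA_real_ else o[1]
  }, numeric(1))
  if (all(is.na(onset))) return("uncategorized")
  lead <- names(onset)[!is.na(onset) & onset <= min(onset, na.rm = TRUE) +
                         tol_frames]
  lagging <- setdiff(names(segments), lead)
  if (length(lead) == 3) return("even")
  if (identical(lead, "center")) return("center")
  if (setequal(lead, c("left", "right"))) return("both_ends")
  if ("center" %in% lead && length(lead) == 2) return("one_end_center")
  # a single leading end: treat as recovery from one end plus (late) center
  "one_end_center"
}

#' Drift QC flag for strain sites
#'
#' Marks sites whose centroid drifts more than `threshold_px` from its
#' initial position as excluded from intensity-over-time plots (kymograph
#' quality), while keeping them countable for repair-frequency tables.
#'
#' @param centroids data.frame with `frame`, `row`, `col`.
#' @param threshold_px maximum tolerated drift (default 5 px).
#' @return logical: TRUE if the site should be excluded from traces.
#' @export
flag_drift <- function(centroids, threshold_px = 5) {
  d <- sqrt((centroids$row - centroids$row[1])^2 +
            (centroids$col - centroids$col[1])^2)
  max(d) > threshold_px
}
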