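## Partner-protein analyses: VASP / alpha-actinin binding events on
## patches vs bare F-actin, -ATP last-frame colocalization, actin fold
## increase at VASP-enriched patches.

#' Colocalization presets
#'
#' Bundles the per-channel threshold methods, minimum object sizes, search
#' windows and enrichment floors of the three partner-protein analyses:
#'
#' * `vasp`: actin thresholded directly (Otsu, objects >= 4 px); the LIM
#'   mask (edge recipe) times the actin mask defines the patch substrate;
#'   the partner channel (Yen) times the actin mask (>= 4 px) defines
#'   candidate VASP pixels; events below enrichment 1.0 are excluded;
#'   linking window 9 s.
#' * `actinin_atp`: actin by Yen (>= 10 px), LIM channel by triangle,
#'   partner by Yen, both multiplied by the actin mask (>= 4 px); 15 s
#'   search window; enrichment floor 1.3.
#' * `actinin_noatp`: single-frame (last frame) recipe, see
#'   [coloc_noatp_lastframe()]; `actinin_method` switches Li (wild-type
#'   construct) vs Yen (actin-binding-mutant construct).
#'
#' @param name preset name.
#' @param ... field overrides.
#' @return named list of preset parameters.
#' @export
coloc_preset <- function(name = c("vasp", "actinin_atp", "actinin_noatp"), ...) {
  name <- match.arg(name)
  p <- switch(name,
    vasp = list(name = "vasp", actin_method = "otsu", actin_min_px = 4L,
                lim_method = "yen", lim_min_px = 4L,
                partner_method = "yen", partner_min_px = 4L,
                window_s = 9, enrichment_floor = 1.0,
                transient_max_s = 2),
    actinin_atp = list(name = "actinin_atp", actin_method = "yen",
                       actin_min_px = 10L, lim_method = "triangle",
                       lim_min_px = 4L, partner_method = "yen",
                       partner_min_px = 4L, window_s = 15,
                       enrichment_floor = 1.3, transient_max_s = 2),
    actinin_noatp = list(name = "actinin_noatp", actin_method = "li",
                         actin_min_px = 5L, lim_min_px = 3L,
                         partner_min_px = 3L, actinin_method = "li",
                         enrichment_floor = 1.3, erode_iterations = 1L))
  over <- list(...)
  unknown <- setdiff(names(over), c(names(p), "gap_window"))
  if (length(unknown)) stop("unknown preset field(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

# intensity-threshold mask with minimum object size (no Sobel step);
# fluorescent objects are sparse, so a "mask" covering most of the frame
# means the threshold landed below the background (e.g. a darker-than-
# background object inverted the polarity) and no objects are present
intensity_mask <- function(frame, method, min_px, connectivity = 8L,
                           max_mask_fraction = 0.5) {
  if (diff(range(frame)) == 0) return(matrix(FALSE, nrow(frame), ncol(frame)))
  m <- auto_threshold(frame, method)$mask
  if (mean(m) > max_mask_fraction)
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  lab <- size_filter(label_components(m, connectivity), min_px, NULL)
  lab > 0
}

#' Detect partner-protein binding events on patches and bare F-actin
#'
#' Builds the preset's substrate masks per frame, intersects the partner
#' mask with each substrate, links the resulting objects across frames
#' with the preset's gap window, measures per-frame partner enrichment
#' versus the dilated local background, and returns one row per event.
#' The two substrates partition the partner signal (patch substrate and
#' its complement), so no event is double-counted.
#'
#' @param movie `MovieStack` with `actin`, `lim` and `partner` channels.
#' @param preset from [coloc_preset()] (`vasp` or `actinin_atp`).
#' @param params patch parameters controlling the LIM edge recipe and
#'   enrichment ring.
#' @return data.frame of binding events: `substrate`, `t_start_s`,
#'   `lifetime_s`, `category`, `max_enrichment`, `n_frames`.
#' @export
detect_binding_events <- function(movie, preset = coloc_preset("vasp"),
                                  params = patch_params()) {
  if (is.null(preset$partner_method))
    stop("unknown or single-frame preset: ", preset$name)
  for (role in c("actin", "lim", "partner"))
    if (is.null(movie$channels[[role]])) stop("missing channel role: ", role)
  nt <- n_frames(movie)
  gap_window <- if (!is.null(preset$gap_window)) preset$gap_window else
    max(1L, as.integer(round(preset$window_s / movie$frame_interval)))
  actin_avg <- rolling_time_average(movie$channels$actin, params$window)
  lim_avg <- rolling_time_average(movie$channels$lim, params$window)
  part_avg <- rolling_time_average(movie$channels$partner, params$window)
  on_labels <- vector("list", nt); off_labels <- vector("list", nt)
  actin_masks <- vector("list", nt)
  for (t in seq_len(nt)) {
    am <- intensity_mask(actin_avg[, , t], preset$actin_method,
                         preset$actin_min_px, params$connectivity)
    lm_raw <- intensity_mask(lim_avg[, , t], preset$lim_method,
                             preset$lim_min_px, params$connectivity)
    patch_sub <- lm_raw & am           # LIM-actin substrate
    pm <- intensity_mask(part_avg[, , t], preset$partner_method,
                         preset$partner_min_px, params$connectivity) & am
    pm <- size_filter(label_components(pm, params$connectivity),
                      preset$partner_min_px, NULL) > 0
    on_labels[[t]] <- label_components(pm & patch_sub, params$connectivity)
    off_labels[[t]] <- label_components(pm & !patch_sub, params$connectivity)
    actin_masks[[t]] <- am
  }
  link_one <- function(labels, substrate) {
    det <- list(lim_labels = labels, actin_masks = actin_masks,
                lim_smooth = part_avg,
                params = utils::modifyList(params, list(gap_window = gap_window)))
    trajs <- link_trajectories(det, movie)
    if (!length(trajs)) return(NULL)
    do.call(rbind, lapply(trajs, function(tr) {
      rec <- tr$records
      data.frame(substrate = substrate,
                 t_start_s = (min(rec$frame) - 1) * movie$frame_interval,
                 lifetime_s = nrow(rec) * movie$frame_interval,
                 max_enrichment = suppressWarnings(
                   max(rec$enrichment, na.rm = TRUE)),
                 n_frames = nrow(rec), stringsAsFactors = FALSE)
    }))
  }
  ev <- rbind(link_one(on_labels, "on_patch"), link_one(off_labels, "bare_actin"))
  if (is.null(ev)) return(data.frame(substrate = character(0),
                                     t_start_s = numeric(0),
                                     lifetime_s = numeric(0),
                                     category = character(0),
                                     max_enrichment = numeric(0),
                                     n_frames = integer(0)))
  ev <- ev[is.finite(ev$max_enrichment) &
             ev$max_enrichment >= preset$enrichment_floor, , drop = FALSE]
  ev$category <- categorize_event(ev$lifetime_s, preset$transient_max_s)
  rownames(ev) <- NULL
  ev[, c("substrate", "t_start_s", "lifetime_s", "category",
         "max_enrichment", "n_frames")]
}

#' Categorize binding events by lifetime
#'
#' Events lasting at most `transient_max_s` seconds (default 2 s, the
#' closed upper end of the observed 1-2 s transient population) are
#' `transient`; longer events are `stable`.
#'
#' @param lifetime_s numeric lifetimes in seconds.
#' @param transient_max_s cutoff (inclusive).
#' @return character vector.
#' @export
categorize_event <- function(lifetime_s, transient_max_s = 2) {
  ifelse(lifetime_s <= transient_max_s, "transient", "stable")
}

#' Aggregate binding-event statistics
#'
#' Per substrate (and optional extra grouping column): event count, mean
#' lifetime, and the mean of per-event maximum enrichments — the per-trial
#' summaries the binding-event figures report. When trials differ in
#' length, pass `equal_period_s` to count only events starting within the
#' common imaging period. Empty groups yield `NA`, not zero.
#'
#' @param events data.frame from [detect_binding_events()].
#' @param by optional extra grouping column name.
#' @param equal_period_s optional common imaging period in seconds.
#' @return data.frame of group summaries.
#' @export
event_statistics <- function(events, by = NULL, equal_period_s = NULL) {
  if (!is.null(equal_period_s))
    events <- events[events$t_start_s < equal_period_s, , drop = FALSE]
  keys <- c("substrate", by)
  grp <- interaction(events[keys], drop = FALSE)
  lv <- levels(grp)
  out <- do.call(rbind, lapply(lv, function(g) {
    e <- events[grp == g, , drop = FALSE]
    data.frame(group = g,
               n_events = nrow(e),
               mean_lifetime_s = if (nrow(e)) mean(e$lifetime_s) else NA_real_,
               mean_max_enrichment = if (nrow(e)) mean(e$max_enrichment)
                 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Single-frame alpha-actinin colocalization (no myosin forces)
#'
#' The -ATP recipe, applied to the last frame of the movie: actin by Li
#' (objects >= 5 px); LIM and alpha-actinin channels are Sobel-transformed,
#' thresholded (Yen for LIM; Li or Yen for alpha-actinin depending on the
#' construct), hole-filled and eroded once (the edge transform widens
#' masks), multiplied by the actin mask and size-filtered (>= 3 px).
#' Colocalization events are the connected components of the product of
#' the two masks, with alpha-actinin enrichment versus the dilated local
#' background.
#'
#' @param movie `MovieStack` with `actin`, `lim` and `partner`
#'   (alpha-actinin) channels.
#' @param preset from `coloc_preset("actinin_noatp")`; set
#'   `actinin_method = "yen"` for the actin-binding-deficient construct.
#' @param frame frame to analyze; defaults to the movie's last frame (a
#'   shorter movie than expected is used as-is with a warning).
#' @param params patch parameters (connectivity, enrichment ring).
#' @return data.frame: one row per colocalized object with `area_px` and
#'   `enrichment`.
#' @export
coloc_noatp_lastframe <- function(movie, preset = coloc_preset("actinin_noatp"),
                                  frame = NULL, params = patch_params()) {
  nt <- n_frames(movie)
  if (is.null(frame)) frame <- nt
  if (frame > nt) {
    warning("requested frame ", frame, " beyond movie; using final frame ", nt)
    frame <- nt
  }
  actin <- get_frame(movie, "actin", frame)
  lim <- get_frame(movie, "lim", frame)
  actinin <- get_frame(movie, "partner", frame)
  am <- intensity_mask(actin, preset$actin_method, preset$actin_min_px,
                       params$connectivity)
  edge_mask <- function(fr, method, min_px) {
    s <- sobel_edges(gaussian_blur(fr, params$sigma))
    if (diff(range(s)) == 0) return(matrix(FALSE, nrow(fr), ncol(fr)))
    m <- morphology(auto_threshold(s, method)$mask, "fill_holes")
    m <- morphology(m, "erode", preset$erode_iterations)
    size_filter(label_components(m & am, params$connectivity), min_px, NULL) > 0
  }
  zm <- edge_mask(lim, "yen", preset$lim_min_px)
  amk <- edge_mask(actinin, preset$actinin_method, preset$partner_min_px)
  co <- zm & amk
  lab <- label_components(co, params$connectivity)
  k <- max(lab)
  if (k == 0)
    return(data.frame(event = integer(0), area_px = integer(0),
                      enrichment = numeric(0)))
  do.call(rbind, lapply(seq_len(k), function(i) {
    m <- lab == i
    data.frame(event = i, area_px = sum(m),
               enrichment = compute_enrichment(m, actinin,
                                               params$dilation_iterations,
                                               exclude = co & !m))
  }))
}

#' Actin fold increase in fixed boxes
#'
#' For each 20 x 20 px box (centred on a VASP-enriched patch or a control
#' actin region): rolling-ball background subtraction of the actin
#' channel, per-frame integrated density (sum over the box), fold change
#' versus the mean of the first `baseline_frames` frames, a rolling-mean
#' smoothed trace, and the time-averaged fold change.
#'
#' @param movie a `MovieStack` with an `actin` channel.
#' @param boxes data.frame with `center_r`, `center_c` (px) and optional
#'   `group` column (e.g. `"patch"` / `"control"`).
#' @param box_px box side length (default 20).
#' @param baseline_frames frames defining the baseline (default 5).
#' @param smooth_window rolling-mean window for the smoothed trace
#'   (default 10 frames).
#' @param subtract_background logical; rolling-ball subtract each frame
#'   first (default TRUE).
#' @param rolling_ball_radius radius for the subtraction (default 50 px).
#' @return list with `traces` (long data.frame: box, group, frame, fold,
#'   fold_smoothed) and `summary` (per box: time-averaged fold).
#' @export
actin_fold_increase <- function(movie, boxes, box_px = 20L,
                                baseline_frames = 5L, smooth_window = 10L,
                                subtract_background = TRUE,
                                rolling_ball_radius = 50) {
  stopifnot(inherits(movie, "MovieStack"),
            all(c("center_r", "center_c") %in% names(boxes)))
  arr <- movie$channels$actin
  d <- dim(arr)
  half <- box_px %/% 2L
  idx <- lapply(seq_len(nrow(boxes)), function(i) {
    r <- round(boxes$center_r[i]); c <- round(boxes$center_c[i])
    rows <- (r - half + 1L):(r + half); cols <- (c - half + 1L):(c + half)
    if (min(rows) < 1 || min(cols) < 1 || max(rows) > d[1] || max(cols) > d[2])
      stop("box ", i, " extends outside the field")
    list(rows = rows, cols = cols)
  })
  nt <- d[3]
  dens <- matrix(0, nt, nrow(boxes))
  for (t in seq_len(nt)) {
    fr <- arr[, , t]
    if (subtract_background)
      fr <- rolling_ball_background_subtract(fr, rolling_ball_radius)
    for (i in seq_len(nrow(boxes)))
      dens[t, i] <- sum(fr[idx[[i]]$rows, idx[[i]]$cols])
  }
  base <- colMeans(dens[seq_len(baseline_frames), , drop = FALSE])
  if (any(base == 0)) stop("baseline integrated density is zero for box(es): ",
                           paste(which(base == 0), collapse = ", "))
  fold <- sweep(dens, 2, base, "/")
  group <- if ("group" %in% names(boxes)) boxes$group else
    rep(NA_character_, nrow(boxes))
  traces <- do.call(rbind, lapply(seq_len(nrow(boxes)), function(i)
    data.frame(box = i, group = group[i], frame = seq_len(nt),
               fold = fold[, i],
               fold_smoothed = rolling_mean_trunc(fold[, i], smooth_window))))
  summary <- data.frame(box = seq_len(nrow(boxes)), group = group,
                        mean_fold = colMeans(fold))
  list(traces = traces, summary = summary)
}

#' Paired patch-vs-control comparison of time-averaged fold change
#'
#' Pairs each patch box with a control box from the same field (by order)
#' and runs a paired t test on the time-averaged fold changes.
#'
#' @param summary the `summary` element of [actin_fold_increase()], with
#'   groups `"patch"` and `"control"` in matched order.
#' @return list with `patch_mean`, `control_mean`, `t`, `p_value`, `df`.
#' @export
fold_increase_paired_test <- function(summary) {
  a <- summary$mean_fold[summary$group == "patch"]
  b <- summary$mean_fold[summary$group == "control"]
  if (length(a) != length(b) || length(a) < 2)
    stop("need equal numbers (>= 2) of patch and control boxes")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(patch_mean = mean(a), control_mean = mean(b),
       t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Sample control boxes on bare actin
#'
#' Draws `n` box centres from actin-mask-positive pixels at least
#' `exclusion_px` away from any given patch centre, mirroring the "equal
#' numbers of control F-actin regions lacking patches" selection.
#'
#' @param movie `MovieStack` with an `actin` channel.
#' @param patch_boxes data.frame of patch box centres.
#' @param n number of control boxes (default: same as patches).
#' @param box_px box side (margin enforcement).
#' @param exclusion_px minimum distance from any patch centre.
#' @param seed RNG seed for reproducible sampling.
#' @return data.frame with `center_r`, `center_c`, `group = "control"`.
#' @export
sample_control_boxes <- function(movie, patch_boxes, n = nrow(patch_boxes),
                                 box_px = 20L, exclusion_px = 20,
                                 seed = 1L) {
  fr <- movie$channels$actin[, , 1]
  am <- intensity_mask(fr, "otsu", 4L)
  half <- box_px %/% 2L
  cand <- which(am, arr.ind = TRUE)
  ok <- cand[, 1] > half & cand[, 2] > half &
    cand[, 1] <= nrow(fr) - half & cand[, 2] <= ncol(fr) - half
  cand <- cand[ok, , drop = FALSE]
  if (nrow(patch_boxes)) {
    for (i in seq_len(nrow(patch_boxes))) {
      dd <- sqrt((cand[, 1] - patch_boxes$center_r[i])^2 +
                 (cand[, 2] - patch_boxes$center_c[i])^2)
      cand <- cand[dd > exclusion_px, , drop = FALSE]
    }
  }
  if (nrow(cand) < n) stop("not enough patch-free actin area for ", n, " boxes")
  with_seed(seed, {
    pick <- cand[sample(nrow(cand), n), , drop = FALSE]
    data.frame(center_r = pick[, 1], center_c = pick[, 2], group = "control")
  })
}
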