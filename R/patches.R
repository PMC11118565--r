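## Core patch pipeline: detection, gap-tolerant tracking, classification.

#' Region length measures
#'
#' `feret_diameter()` returns the maximum caliper (Feret) distance between
#' pixel centers of a region, the default "maximum length" measure: for an
#' elongated object it equals the geometric end-to-end length.
#' `ellipse_major_axis()` returns the major-axis length of the
#' intensity-free best-fit ellipse (4 sigma convention); note it reads
#' ~15% longer than the geometric length for rectangular objects.
#'
#' @param pts 2-column matrix of (row, col) pixel coordinates.
#' @return length in pixels.
#' @export
feret_diameter <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  n <- nrow(pts)
  if (n == 0) return(NA_real_)
  if (n == 1) return(0)
  if (n > 600) {
    h <- grDevices::chull(pts[, 2], pts[, 1])
    pts <- pts[h, , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' @rdname feret_diameter
#' @export
ellipse_major_axis <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  n <- nrow(pts)
  if (n == 0) return(NA_real_)
  if (n == 1) return(1)
  # second central moments of the pixel footprint (+1/12 per-pixel variance)
  cv <- stats::cov(pts) * (n - 1) / n + diag(2) / 12
  4 * sqrt(max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values))
}

#' Default parameters of the patch-detection pipeline
#'
#' The per-frame mask recipe: rolling temporal average (3 frames), Gaussian
#' blur, Sobel edge transform, auto-threshold (Li for the actin channel,
#' Yen for the LIM channel), hole filling, `post_erode` erosions to undo
#' the size overestimate of the filled edge band, then a 10-150 px area
#' bandpass on LIM objects. Tracking searches +/- `gap_window` frames for
#' overlapping objects, retains those with at least one neighbour, and
#' keeps trajectories that overlap actin for >= 75% of their lifetime and
#' reach a maximum local-background enrichment >= 1.3.
#'
#' @param ... overrides of any default.
#' @return named list of parameters.
#' @export
patch_params <- function(...) {
  p <- list(window = 3L, sigma = 1, actin_method = "li", lim_method = "yen",
            post_erode = 2L,
            min_area = 10L, max_area = 150L, connectivity = 8L,
            gap_window = 3L, dilation_iterations = 3L,
            min_overlap_lifetime_fraction = 0.75, min_max_enrichment = 1.3,
            patch_overlap_threshold = 0.70, outlier_mad_factor = 5,
            length_measure = "feret")
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Detect candidate LIM-protein objects and actin masks per frame
#'
#' Runs the mask recipe of [patch_params()] on the LIM and actin channels
#' and returns per-frame labeled LIM objects plus per-frame actin masks.
#'
#' @param movie a `MovieStack` with `actin` and `lim` channels.
#' @param params list from [patch_params()].
#' @return list with `lim_labels` (list of label matrices), `actin_masks`
#'   (list of logical matrices), `lim_smooth` (rolling-averaged LIM channel
#'   used for intensity measurements) and `params`.
#' @export
detect_candidates <- function(movie, params = patch_params()) {
  stopifnot(inherits(movie, "MovieStack"))
  for (role in c("actin", "lim"))
    if (is.null(movie$channels[[role]]))
      stop("missing channel role: ", role)
  nt <- n_frames(movie)
  actin_avg <- rolling_time_average(movie$channels$actin, params$window)
  lim_avg <- rolling_time_average(movie$channels$lim, params$window)
  channel_mask <- function(fr, method) {
    s <- sobel_edges(gaussian_blur(fr, params$sigma))
    if (diff(range(s)) == 0) return(matrix(FALSE, nrow(fr), ncol(fr)))
    m <- auto_threshold(s, method)$mask
    m <- morphology(m, "fill_holes")
    # the filled edge band overestimates object size; shrink it back
    if (params$post_erode > 0) m <- morphology(m, "erode", params$post_erode)
    m
  }
  actin_masks <- vector("list", nt)
  lim_labels <- vector("list", nt)
  for (t in seq_len(nt)) {
    actin_masks[[t]] <- channel_mask(actin_avg[, , t], params$actin_method)
    lm <- channel_mask(lim_avg[, , t], params$lim_method)
    lab <- label_components(lm, params$connectivity)
    lim_labels[[t]] <- size_filter(lab, params$min_area, params$max_area)
  }
  list(lim_labels = lim_labels, actin_masks = actin_masks,
       lim_smooth = lim_avg, params = params)
}

#' Local-background enrichment of an object
#'
#' Ratio of the object's mean intensity to the mean of its local
#' background, the ring obtained by dilating the object mask
#' (`dilation_iterations` passes of a 3x3 element) and removing the object
#' itself plus any other detected object pixels.
#'
#' @param mask logical object mask.
#' @param frame intensity frame.
#' @param dilation_iterations ring width control (default 3).
#' @param exclude additional logical mask of pixels to keep out of the ring
#'   (e.g. other objects), or `NULL`.
#' @return enrichment ratio (object mean / background mean).
#' @export
compute_enrichment <- function(mask, frame, dilation_iterations = 3L,
                               exclude = NULL) {
  if (!any(mask)) stop("empty object mask")
  ring <- morphology(mask, "dilate", dilation_iterations) & !mask
  if (!is.null(exclude)) ring <- ring & !exclude
  if (!any(ring)) stop("empty background ring: object fills the frame")
  mean(frame[mask]) / mean(frame[ring])
}

# per-frame object measurements (area, centroid, intensity, enrichment,
# actin overlap topology, length)
measure_frame_objects <- function(labels, actin_mask, intensity, params) {
  k <- max(labels)
  if (k == 0)
    return(data.frame(frame = integer(0), label = integer(0), area = integer(0),
                      centroid_r = numeric(0), centroid_c = numeric(0),
                      mean_int = numeric(0), bg_mean = numeric(0),
                      enrichment = numeric(0), overlap_fraction = numeric(0),
                      n_overlap_regions = integer(0), length_px = numeric(0)))
  any_obj <- labels > 0
  out <- vector("list", k)
  for (lb in seq_len(k)) {
    m <- labels == lb
    pts <- which(m, arr.ind = TRUE)
    area <- nrow(pts)
    ring <- morphology(m, "dilate", params$dilation_iterations) & !any_obj
    bg <- if (any(ring)) mean(intensity[ring]) else NA_real_
    ov <- m & actin_mask
    ovn <- sum(ov)
    nreg <- if (ovn == 0) 0L else max(label_components(ov, params$connectivity))
    len <- if (identical(params$length_measure, "ellipse"))
      ellipse_major_axis(pts) else feret_diameter(pts)
    out[[lb]] <- data.frame(
      frame = NA_integer_, label = lb, area = area,
      centroid_r = mean(pts[, 1]), centroid_c = mean(pts[, 2]),
      mean_int = mean(intensity[m]), bg_mean = bg,
      enrichment = if (is.na(bg) || bg <= 0) NA_real_ else mean(intensity[m]) / bg,
      overlap_fraction = ovn / area, n_overlap_regions = nreg,
      length_px = len)
  }
  do.call(rbind, out)
}

#' Assemble gap-tolerant trajectories by depth-first traversal
#'
#' Builds the object-overlap graph: object A in frame t links to object B
#' in a later frame t' if their pixel footprints overlap and the number of
#' missing frames between them (`t' - t - 1`) is at most `gap_window`.
#' Objects with no neighbour in the surrounding frames are discarded as
#' non-persistent; connected components of the graph, found by an
#' iterative depth-first traversal, become trajectories. With the default
#' window of 3, blink gaps of up to 3 frames never split a trajectory and
#' gaps of 4 or more always do.
#'
#' @param detection result of [detect_candidates()].
#' @param movie the source `MovieStack` (for metadata).
#' @return list of `Trajectory` objects; each carries a `records`
#'   data.frame with one row per detected frame.
#' @export
link_trajectories <- function(detection, movie) {
  params <- detection$params
  gap_window <- as.integer(params$gap_window)
  if (gap_window < 1) stop("gap_window must be >= 1")
  labels <- detection$lim_labels
  nt <- length(labels)
  counts <- vapply(labels, max, integer(1))
  if (sum(counts) == 0) return(list())
  # global node ids per (frame, label)
  offs <- cumsum(c(0L, counts))
  node_id <- function(t, lb) offs[t] + lb
  edges <- list()
  for (t1 in seq_len(nt)) {
    if (counts[t1] == 0) next
    t2_max <- min(nt, t1 + gap_window + 1L)
    if (t2_max <= t1) next
    for (t2 in seq(t1 + 1L, t2_max)) {
      if (counts[t2] == 0) next
      l1 <- labels[[t1]]; l2 <- labels[[t2]]
      both <- l1 > 0 & l2 > 0
      if (!any(both)) next
      pr <- unique(cbind(l1[both], l2[both]))
      edges[[length(edges) + 1L]] <-
        cbind(node_id(t1, pr[, 1]), node_id(t2, pr[, 2]))
    }
  }
  n_nodes <- offs[nt + 1L]
  if (!length(edges)) return(list())
  em <- do.call(rbind, edges)
  # adjacency list; only nodes with >= 1 neighbour are persistent
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(em))) {
    a <- em[i, 1]; b <- em[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  persistent <- which(vapply(adj, length, integer(1)) > 0)
  visited <- logical(n_nodes)
  comps <- list()
  for (s in persistent) {
    if (visited[s]) next
    stack <- s; visited[s] <- TRUE; comp <- integer(0)
    while (length(stack)) {            # iterative depth-first traversal
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!visited[w]) { visited[w] <- TRUE; stack <- c(stack, w) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  # measure objects once per frame, then carve trajectories out
  frame_of <- rep(seq_len(nt), counts)
  label_of <- unlist(lapply(counts, seq_len), use.names = FALSE)
  meas <- vector("list", nt)
  need <- unique(frame_of[unlist(comps)])
  for (t in need) {
    m <- measure_frame_objects(labels[[t]], detection$actin_masks[[t]],
                               detection$lim_smooth[, , t], params)
    m$frame <- t
    meas[[t]] <- m
  }
  trajs <- lapply(seq_along(comps), function(ci) {
    nodes <- comps[[ci]]
    rec <- do.call(rbind, lapply(nodes, function(v) {
      mm <- meas[[frame_of[v]]]
      mm[mm$label == label_of[v], , drop = FALSE]
    }))
    rec <- rec[order(rec$frame, -rec$area), , drop = FALSE]
    # if a component holds two objects in one frame (merge), keep the larger
    rec <- rec[!duplicated(rec$frame), , drop = FALSE]
    rec$filled <- FALSE
    structure(list(id = ci, records = rec,
                   first_frame = min(rec$frame), last_frame = max(rec$frame),
                   frame_interval = movie$frame_interval,
                   pixel_size = movie$pixel_size,
                   pixel_sets = lapply(seq_len(nrow(rec)), function(i) {
                     t <- rec$frame[i]
                     which(labels[[t]] == rec$label[i])
                   })),
              class = "Trajectory")
  })
  trajs
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory %s: frames %d-%d (%d recorded, %d filled)\n",
              x$id, x$first_frame, x$last_frame, nrow(x$records),
              sum(x$records$filled)))
  invisible(x)
}

#' Repair gaps and isolated outliers in a trajectory
#'
#' Internal missing frames, and frames whose area or centroid jump exceeds
#' `outlier_mad_factor` times the trajectory's median absolute deviation
#' (floored at 1 px of area / 0.5 px of jump so exact-constant
#' trajectories still expose outliers), are replaced by a copy of the
#' preceding frame's record with the `filled` flag set. A gap at the trajectory start has no preceding frame
#' and is left unfilled.
#'
#' @param traj a `Trajectory`.
#' @param params list from [patch_params()].
#' @return repaired `Trajectory`.
#' @export
repair_trajectory <- function(traj, params = patch_params()) {
  rec <- traj$records
  if (nrow(rec) >= 5) {       # outlier screen needs a meaningful median
    med_a <- stats::median(rec$area)
    mad_a <- max(stats::mad(rec$area, constant = 1), 1)   # floor: 1 px
    jump_r <- c(0, abs(diff(rec$centroid_r)))
    jump_c <- c(0, abs(diff(rec$centroid_c)))
    jmp <- sqrt(jump_r^2 + jump_c^2)
    med_j <- stats::median(jmp)
    mad_j <- max(stats::mad(jmp, constant = 1), 0.5)      # floor: half a px
    bad <- abs(rec$area - med_a) > params$outlier_mad_factor * mad_a |
           jmp > med_j + params$outlier_mad_factor * mad_j
    bad[1] <- FALSE
    for (i in which(bad)) {
      keep_frame <- rec$frame[i]
      rec[i, ] <- rec[i - 1, ]
      rec$frame[i] <- keep_frame
      rec$filled[i] <- TRUE
    }
  }
  full <- seq(min(rec$frame), max(rec$frame))
  missing <- setdiff(full, rec$frame)
  if (length(missing)) {
    add <- do.call(rbind, lapply(missing, function(t) {
      prev <- rec[rec$frame < t, , drop = FALSE]
      r <- prev[nrow(prev), , drop = FALSE]
      r$frame <- t; r$filled <- TRUE
      r
    }))
    rec <- rbind(rec, add)
    rec <- rec[order(rec$frame), , drop = FALSE]
  }
  traj$records <- rec
  traj
}

#' Per-frame topological classification
#'
#' Classifies one object-frame by its actin-overlap topology: two (or
#' more) connected overlap regions make a `bridge`; a single region makes
#' an `actin_bound_patch` when the overlap fraction reaches the 70%
#' threshold and a `tail` otherwise; no overlap is `unbound`.
#'
#' @param n_overlap_regions connected components of (object mask AND actin
#'   mask).
#' @param overlap_fraction fraction of the object's pixels on actin.
#' @param threshold patch/tail overlap threshold (default 0.70, inclusive).
#' @return character vector of classes.
#' @export
classify_patch_frame <- function(n_overlap_regions, overlap_fraction,
                                 threshold = 0.70) {
  ifelse(n_overlap_regions == 0L, "unbound",
    ifelse(n_overlap_regions >= 2L, "bridge",
      ifelse(overlap_fraction >= threshold, "actin_bound_patch", "tail")))
}

#' Filter trajectories by actin overlap and brightness
#'
#' Keeps trajectories overlapping actin in at least
#' `min_overlap_lifetime_fraction` of their recorded frames and reaching a
#' maximum enrichment of at least `min_max_enrichment` (trajectories below
#' that are too dim to track reliably).
#'
#' @param trajs list of `Trajectory`.
#' @param params list from [patch_params()].
#' @return filtered list.
#' @export
filter_trajectories <- function(trajs, params = patch_params()) {
  Filter(function(tr) {
    rec <- tr$records
    frac <- mean(rec$overlap_fraction > 0)
    maxe <- suppressWarnings(max(rec$enrichment, na.rm = TRUE))
    frac >= params$min_overlap_lifetime_fraction &&
      is.finite(maxe) && maxe >= params$min_max_enrichment
  }, trajs)
}

#' Split a trajectory at class transitions
#'
#' Assigns every frame its topological class and cuts the trajectory into
#' maximal runs of constant class; each run becomes its own trajectory
#' with recomputed first/last frames.
#'
#' @param traj a `Trajectory`.
#' @param params list from [patch_params()].
#' @return list of `Trajectory`, each with a single class in `$class`.
#' @export
split_on_class_transition <- function(traj, params = patch_params()) {
  rec <- traj$records
  cls <- classify_patch_frame(rec$n_overlap_regions, rec$overlap_fraction,
                              params$patch_overlap_threshold)
  r <- rle(cls)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  lapply(seq_along(r$values), function(i) {
    seg <- rec[starts[i]:ends[i], , drop = FALSE]
    structure(list(id = paste0(traj$id, ".", i), records = seg,
                   class = r$values[i],
                   first_frame = min(seg$frame), last_frame = max(seg$frame),
                   frame_interval = traj$frame_interval,
                   pixel_size = traj$pixel_size),
              class = "Trajectory")
  })
}

#' Summary table of classified trajectories
#'
#' One row per trajectory: class, lifetime in seconds (recorded frames x
#' frame interval), maximum per-frame object length in um, maximum
#' enrichment, frame counts.
#'
#' @param trajs list of classified `Trajectory` objects.
#' @return data.frame.
#' @export
summarize_trajectories <- function(trajs) {
  if (!length(trajs))
    return(data.frame(traj_id = character(0), class = character(0),
                      lifetime_s = numeric(0), max_length_um = numeric(0),
                      max_enrichment = numeric(0), n_frames = integer(0),
                      filled_frames = integer(0)))
  do.call(rbind, lapply(trajs, function(tr) {
    rec <- tr$records
    data.frame(traj_id = as.character(tr$id),
               class = if (!is.null(tr$class)) tr$class else NA_character_,
               lifetime_s = nrow(rec) * tr$frame_interval,
               max_length_um = max(rec$length_px) * tr$pixel_size,
               max_enrichment = suppressWarnings(max(rec$enrichment, na.rm = TRUE)),
               n_frames = nrow(rec), filled_frames = sum(rec$filled),
               stringsAsFactors = FALSE)
  }))
}

#' Cumulative lifetime distribution and half-life
#'
#' Empirical cumulative relative frequency of lifetimes with the half-life
#' read off at cumulative frequency 0.5 by linear interpolation. An empty
#' input yields an `NA` half-life.
#'
#' @param lifetimes numeric vector of lifetimes (s).
#' @return list with `lifetime`, `cumfreq` and `half_life`.
#' @export
lifetime_cdf <- function(lifetimes) {
  lifetimes <- sort(lifetimes[is.finite(lifetimes)])
  n <- length(lifetimes)
  if (n == 0) return(list(lifetime = numeric(0), cumfreq = numeric(0),
                          half_life = NA_real_))
  cf <- seq_len(n) / n
  hl <- if (n == 1) lifetimes else
    stats::approx(cf, lifetimes, xout = 0.5, ties = "ordered", rule = 2)$y
  list(lifetime = lifetimes, cumfreq = cf, half_life = hl)
}

#' Instantaneous interface velocity
#'
#' Velocity of a tracked boundary point: Euclidean displacement per frame
#' converted to um/s, then smoothed with a rolling mean (default 10
#' frames, truncated at the series edges). Positions may come from a
#' manual-tracking CSV (`frame,row,col`) or from trajectory centroids.
#'
#' @param positions data.frame with columns `frame`, `row`, `col`.
#' @param frame_interval seconds per frame.
#' @param pixel_size um per px.
#' @param smooth_window rolling-mean window in frames (default 10).
#' @return data.frame with `frame`, `velocity_um_s`, `smoothed_um_s`.
#' @export
interface_velocity <- function(positions, frame_interval, pixel_size,
                               smooth_window = 10L) {
  stopifnot(all(c("frame", "row", "col") %in% names(positions)),
            nrow(positions) >= 2)
  if (any(diff(positions$frame) <= 0)) stop("frames must be strictly increasing")
  dd <- sqrt(diff(positions$row)^2 + diff(positions$col)^2)
  dt <- diff(positions$frame) * frame_interval
  v <- dd * pixel_size / dt
  sm <- rolling_mean_trunc(v, smooth_window)
  data.frame(frame = positions$frame[-1], velocity_um_s = v, smoothed_um_s = sm)
}

# centred rolling mean with truncated windows at the edges
rolling_mean_trunc <- function(x, window) {
  n <- length(x)
  h_lo <- (window - 1L) %/% 2L
  h_hi <- window %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h_lo):min(n, i + h_hi)]), numeric(1))
}

#' Translation-only registration by phase correlation
#'
#' Estimates the integer per-frame translation maximizing the circular
#' cross-correlation with a reference frame and shifts every channel
#' accordingly (vacated pixels zero-filled). Featureless frames get zero
#' shift with a warning. Rotation is out of scope.
#'
#' @param movie a `MovieStack` (registration is computed on `register_on`).
#' @param reference_frame index of the reference frame.
#' @param register_on channel used to estimate shifts (default `"actin"`).
#' @return list with `movie` (shifted) and `shifts` (data.frame
#'   `frame, dr, dc`).
#' @export
register_translation <- function(movie, reference_frame = 1L,
                                 register_on = "actin") {
  stopifnot(inherits(movie, "MovieStack"))
  ch <- movie$channels[[register_on]]
  if (is.null(ch)) stop("missing channel: ", register_on)
  nt <- dim(ch)[3]
  ref <- ch[, , reference_frame]
  Fr <- stats::fft(ref)
  shifts <- data.frame(frame = seq_len(nt), dr = 0L, dc = 0L)
  for (t in seq_len(nt)) {
    fr <- ch[, , t]
    if (diff(range(fr)) == 0 || diff(range(ref)) == 0) {
      warning("featureless frame ", t, ": zero shift assumed")
      next
    }
    cross <- Re(stats::fft(Fr * Conj(stats::fft(fr)), inverse = TRUE))
    pk <- which.max(cross)
    dr <- (pk - 1) %% nrow(fr); dc <- (pk - 1) %/% nrow(fr)
    if (dr > nrow(fr) / 2) dr <- dr - nrow(fr)
    if (dc > ncol(fr) / 2) dc <- dc - ncol(fr)
    shifts$dr[t] <- dr; shifts$dc[t] <- dc
  }
  movie$channels <- lapply(movie$channels, function(arr) {
    for (t in seq_len(nt))
      arr[, , t] <- shift_frame(arr[, , t], shifts$dr[t], shifts$dc[t])
    arr
  })
  list(movie = movie, shifts = shifts)
}

shift_frame <- function(frame, dr, dc) {
  out <- matrix(0, nrow(frame), ncol(frame))
  src_r <- seq_len(nrow(frame)) - dr
  src_c <- seq_len(ncol(frame)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(frame)
  ok_c <- src_c >= 1 & src_c <= ncol(frame)
  out[which(ok_r), which(ok_c)] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

#' End-to-end patch analysis
#'
#' Runs the full pipeline on a movie: detection, gap-tolerant linking,
#' gap/outlier repair, overlap/enrichment filtering, per-frame
#' classification with splitting at class transitions, and summary.
#'
#' @param movie a `MovieStack` with `actin` and `lim` channels.
#' @param params list from [patch_params()].
#' @return list with `trajectories` (classified, post-split), `summary`
#'   (data.frame) and `detection`.
#' @export
analyze_patches <- function(movie, params = patch_params()) {
  det <- detect_candidates(movie, params)
  trajs <- link_trajectories(det, movie)
  trajs <- lapply(trajs, repair_trajectory, params = params)
  trajs <- filter_trajectories(trajs, params)
  segs <- do.call(c, lapply(trajs, split_on_class_transition, params = params))
  if (is.null(segs)) segs <- list()
  segs <- Filter(function(tr) tr$class != "unbound", segs)
  list(trajectories = segs, summary = summarize_trajectories(segs),
       detection = det)
}
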