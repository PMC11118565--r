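#' Synthetic acquisition scene
#'
#' Describes a synthetic TIRF/confocal acquisition: field size, optics,
#' noise model and bleaching. The generator renders planted objects into
#' this scene so that every downstream quantification can be checked
#' against exact ground truth. The default pixel size (0.0653 um/px) is
#' derived from the one printed field calibration (1440 x 965 px covering
#' 94 x 62 um); override it for other instruments.
#'
#' Rendering model, per channel and frame: ideal intensity =
#' illumination x (background + sum of object profiles), blurred by a
#' Gaussian PSF, decayed by `bleach_rate^(frame-1)`, scaled to photons,
#' Poisson-sampled if `noise`, plus a constant camera offset.
#'
#' @param field c(rows, cols) in pixels.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds per frame.
#' @param n_frames number of frames (>= 1).
#' @param channels channel roles to render.
#' @param psf_sigma Gaussian PSF sigma in px (0 = off).
#' @param photon_scale photons per intensity unit.
#' @param camera_offset constant added after noise.
#' @param bleach_rate per-frame multiplicative decay in (0, 1]; 1 = none.
#' @param noise logical; Poisson shot noise on/off.
#' @param backgrounds named per-channel uniform background levels.
#' @param illumination optional 2D multiplicative field (default uniform 1).
#' @param seed RNG seed; identical scene + seed gives bit-identical movies.
#' @return object of class `SimScene`.
#' @export
sim_scene <- function(field = c(256L, 256L), pixel_size = 0.0653,
                      frame_interval = 3, n_frames = 30L,
                      channels = c("actin", "lim", "partner"),
                      psf_sigma = 1, photon_scale = 1, camera_offset = 100,
                      bleach_rate = 1, noise = TRUE,
                      backgrounds = c(actin = 10, lim = 20, partner = 10),
                      illumination = NULL, seed = 1L) {
  stopifnot(length(field) == 2, all(field > 0), frame_interval > 0,
            pixel_size > 0, n_frames >= 1)
  if (!(bleach_rate > 0 && bleach_rate <= 1)) stop("bleach_rate must be in (0, 1]")
  if (is.null(illumination)) illumination <- matrix(1, field[1], field[2])
  stopifnot(all(dim(illumination) == field))
  bg <- rep(0, length(channels)); names(bg) <- channels
  bg[names(backgrounds)[names(backgrounds) %in% channels]] <-
    backgrounds[names(backgrounds) %in% channels]
  structure(list(field = as.integer(field), pixel_size = pixel_size,
                 frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 channels = channels, psf_sigma = psf_sigma,
                 photon_scale = photon_scale, camera_offset = camera_offset,
                 bleach_rate = bleach_rate, noise = noise,
                 backgrounds = bg, illumination = illumination,
                 seed = as.integer(seed)),
            class = "SimScene")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## ---- planted objects ------------------------------------------------------

new_planted <- function(id, class, ...) {
  structure(c(list(id = id, class = class), list(...)), class = "PlantedObject")
}

# anti-aliased coverage of a line segment (stadium) or disk over a pixel grid
# geometry: list(type = "polyline", coords = n x 2 (row, col), width)
#        or list(type = "disk", center = c(row, col), radius)
# returns list(rows, cols, coverage matrix) over the geometry's bbox
soft_profile <- function(geom, field) {
  if (geom$type == "disk") {
    ctr <- geom$center; rad <- geom$radius
    r0 <- floor(ctr[1] - rad - 2); r1 <- ceiling(ctr[1] + rad + 2)
    c0 <- floor(ctr[2] - rad - 2); c1 <- ceiling(ctr[2] + rad + 2)
    rows <- max(1, r0):min(field[1], r1); cols <- max(1, c0):min(field[2], c1)
    d <- sqrt(outer((rows - ctr[1])^2, (cols - ctr[2])^2, "+"))
    cov <- if (isTRUE(geom$soft)) pmin(pmax(rad + 0.5 - d, 0), 1)
           else matrix(as.numeric(d < rad), length(rows), length(cols))
  } else {
    xy <- geom$coords; w <- geom$width
    r0 <- floor(min(xy[, 1]) - w - 2); r1 <- ceiling(max(xy[, 1]) + w + 2)
    c0 <- floor(min(xy[, 2]) - w - 2); c1 <- ceiling(max(xy[, 2]) + w + 2)
    rows <- max(1, r0):min(field[1], r1); cols <- max(1, c0):min(field[2], c1)
    pr <- rep(rows, times = length(cols)); pc <- rep(cols, each = length(rows))
    d <- rep(Inf, length(pr))
    for (i in seq_len(nrow(xy) - 1)) {
      a <- xy[i, ]; b <- xy[i + 1, ]
      ab <- b - a; len2 <- sum(ab^2)
      tt <- if (len2 == 0) rep(0, length(pr)) else
        pmin(pmax(((pr - a[1]) * ab[1] + (pc - a[2]) * ab[2]) / len2, 0), 1)
      di <- sqrt((pr - (a[1] + tt * ab[1]))^2 + (pc - (a[2] + tt * ab[2]))^2)
      d <- pmin(d, di)
    }
    cov <- if (isTRUE(geom$soft))
      matrix(pmin(pmax(w / 2 + 0.5 - d, 0), 1), length(rows), length(cols))
    else matrix(as.numeric(d < w / 2), length(rows), length(cols))
  }
  list(rows = rows, cols = cols, coverage = cov)
}

# exact planted binary mask of a geometry (coverage > 0.5, i.e. dist < w/2)
planted_geom_mask <- function(geom, field) {
  p <- soft_profile(geom, field)
  m <- matrix(FALSE, field[1], field[2])
  m[p$rows, p$cols] <- p$coverage > 0.5
  m
}

geom_in_field <- function(geom, field) {
  if (geom$type == "disk") {
    all(geom$center - geom$radius >= 1) &&
      geom$center[1] + geom$radius <= field[1] &&
      geom$center[2] + geom$radius <= field[2]
  } else {
    all(geom$coords[, 1] >= 1 + geom$width / 2) &&
      all(geom$coords[, 2] >= 1 + geom$width / 2) &&
      all(geom$coords[, 1] <= field[1] - geom$width / 2) &&
      all(geom$coords[, 2] <= field[2] - geom$width / 2)
  }
}

segment_geom <- function(center, angle, length_px, width, soft = FALSE) {
  u <- c(sin(angle), cos(angle))
  list(type = "polyline",
       coords = rbind(center - u * length_px / 2, center + u * length_px / 2),
       width = width, soft = soft)
}

# sub-segment of a unit-parameterised segment, from s0 to s1 (may exceed [0,1]
# to extend beyond the parent segment's ends)
sub_segment <- function(center, angle, length_px, width, s0, s1) {
  u <- c(sin(angle), cos(angle))
  a <- center + u * (s0 - 0.5) * length_px
  b <- center + u * (s1 - 0.5) * length_px
  list(type = "polyline", coords = rbind(a, b), width = width)
}

#' Plant a gliding fluorescent filament
#'
#' A filament segment translating along its own axis at a constant gliding
#' velocity, rendered into the actin channel.
#'
#' @param id object id.
#' @param center c(row, col) at the first visible frame.
#' @param angle orientation in radians.
#' @param length_px centerline length in px.
#' @param velocity gliding speed in um/s (along +axis).
#' @param width_px rendered width (default 3 px, diffraction-limited look).
#' @param peak intensity amplitude above background.
#' @param frames visible frame indices (1-based).
#' @return a `PlantedObject`.
#' @export
planted_filament <- function(id, center, angle, length_px, velocity = 0,
                             width_px = 3, peak = 50, frames) {
  new_planted(id, "filament", channel = "actin", center = center, angle = angle,
              length_px = length_px, velocity = velocity, width_px = width_px,
              peak = peak, frames = sort(unique(as.integer(frames))),
              enrichment = NA_real_)
}

#' Plant a classified LIM-protein object (patch, bridge or tail)
#'
#' Renders a LIM-channel segment together with supporting actin-channel
#' fragments whose layout realises the planted topological class:
#' an actin-bound patch lies fully on one actin filament; a bridge's two
#' ends each overlap a distinct actin fragment separated by a central
#' actin-free gap; a tail overlaps a single actin fragment at one end only.
#' The LIM amplitude is chosen so the true enrichment ratio of the object
#' over its uniform local background equals `enrichment`.
#'
#' @param id object id.
#' @param class one of `"actin_patch"`, `"bridge"`, `"tail"`.
#' @param center,angle placement of the LIM segment.
#' @param length_px LIM centerline length in px.
#' @param width_px rendered width.
#' @param frames visible frames for the LIM object (the actin support is
#'   rendered in every frame). Blink gaps are simply missing frames.
#' @param enrichment true enrichment ratio (>= 1) vs local background.
#' @param actin_peak actin fragment amplitude.
#' @param soft_edges anti-alias the object boundary (default TRUE, the
#'   realistic rendering); set FALSE for a hard-edged object whose mean
#'   intensity over its mask equals the planted ratio exactly, the right
#'   construction for validating the enrichment estimator.
#' @return a `PlantedObject`.
#' @export
planted_lim_object <- function(id, class = c("actin_patch", "bridge", "tail"),
                               center, angle, length_px = 24, width_px = 3,
                               frames, enrichment = 2, actin_peak = 50,
                               soft_edges = TRUE) {
  class <- match.arg(class)
  stopifnot(enrichment >= 1, width_px > 0, length_px > 0)
  ext <- 12 / length_px  # actin fragments extend ~12 px beyond the LIM segment
  actin_geoms <- switch(class,
    actin_patch = list(sub_segment(center, angle, length_px, width_px + 2,
                                   -ext, 1 + ext)),
    bridge = list(sub_segment(center, angle, length_px, width_px + 2, -ext, 0.30),
                  sub_segment(center, angle, length_px, width_px + 2, 0.70, 1 + ext)),
    tail = list(sub_segment(center, angle, length_px, width_px + 2, -ext, 0.40)))
  actin_geoms <- lapply(actin_geoms, function(g) { g$soft <- TRUE; g })
  new_planted(id, class, channel = "lim",
              geom = segment_geom(center, angle, length_px, width_px,
                                  soft = soft_edges),
              actin_geoms = actin_geoms,
              frames = sort(unique(as.integer(frames))),
              enrichment = enrichment, actin_peak = actin_peak,
              width_px = width_px, length_px = length_px)
}

#' Plant a partner-protein binding event
#'
#' A partner-channel (e.g. VASP) segment co-located either with a planted
#' LIM patch (`substrate = "on_patch"`) or with bare actin
#' (`substrate = "bare_actin"`), visible during the event's frames, with a
#' planted enrichment ratio over the partner-channel background.
#'
#' @inheritParams planted_lim_object
#' @param substrate `"on_patch"` or `"bare_actin"`.
#' @export
planted_binding_event <- function(id, substrate = c("on_patch", "bare_actin"),
                                  center, angle, length_px = 16, width_px = 3,
                                  frames, enrichment = 2, actin_peak = 50) {
  substrate <- match.arg(substrate)
  obj <- new_planted(id, "binding_event", channel = "partner",
                     substrate = substrate,
                     geom = segment_geom(center, angle, length_px, width_px,
                                         soft = TRUE),
                     actin_geoms = list(sub_segment(center, angle, length_px,
                                                    width_px + 2, -12 / length_px,
                                                    1 + 12 / length_px)),
                     frames = sort(unique(as.integer(frames))),
                     enrichment = enrichment, actin_peak = actin_peak,
                     width_px = width_px, length_px = length_px)
  obj$actin_geoms <- lapply(obj$actin_geoms, function(g) { g$soft <- TRUE; g })
  if (substrate == "on_patch") {
    # co-extensive LIM patch, visible in all frames
    obj$lim_geom <- segment_geom(center, angle, length_px + 4, width_px,
                                 soft = TRUE)
    obj$lim_enrichment <- 2
  }
  obj
}

#' Plant a condensate droplet
#'
#' A disk rendered into the given channels with per-channel enrichment
#' ratios over each channel's uniform background.
#'
#' @param id object id.
#' @param center c(row, col).
#' @param radius_px droplet radius in px.
#' @param enrichment named per-channel enrichment ratios (>= 1).
#' @param frames visible frames.
#' @export
planted_droplet <- function(id, center, radius_px, enrichment, frames) {
  stopifnot(all(enrichment >= 0), radius_px > 0)
  new_planted(id, "droplet", channel = names(enrichment),
              geom = list(type = "disk", center = center, radius = radius_px,
                          soft = TRUE),
              frames = sort(unique(as.integer(frames))),
              enrichment = enrichment)
}

## ---- ground truth ---------------------------------------------------------

gap_lengths <- function(frames) {
  if (length(frames) < 2) return(integer(0))
  d <- diff(frames) - 1L
  d[d > 0]
}

ground_truth_row <- function(obj, scene) {
  frames <- obj$frames
  g <- gap_lengths(frames)
  max_len <- NA_real_
  if (!is.null(obj$geom) && obj$geom$type == "polyline") {
    m <- planted_geom_mask(obj$geom, scene$field)
    max_len <- feret_diameter(which(m, arr.ind = TRUE)) * scene$pixel_size
  } else if (!is.null(obj$geom) && obj$geom$type == "disk") {
    max_len <- 2 * obj$geom$radius * scene$pixel_size
  } else if (obj$class == "filament") {
    max_len <- (obj$length_px + obj$width_px) * scene$pixel_size
  }
  data.frame(id = obj$id, class = obj$class,
             first_frame = min(frames), last_frame = max(frames),
             n_visible = length(frames),
             lifetime_s = length(frames) * scene$frame_interval,
             max_length_um = max_len,
             enrichment = if (length(obj$enrichment) == 1)
               unname(obj$enrichment) else NA_real_,
             max_gap_frames = if (length(g)) max(g) else 0L,
             stringsAsFactors = FALSE)
}

#' Ground-truth table for a set of planted objects
#'
#' One row per planted object: class, first/last visible frame, lifetime in
#' seconds (visible frames x frame interval), maximum length in um (maximum
#' Feret diameter of the planted mask), true enrichment and the longest
#' planned blink gap. This is the oracle downstream recovery tests compare
#' against, and is recomputable exactly from the object list.
#'
#' @param objects list of `PlantedObject`s.
#' @param scene the `SimScene`.
#' @return data.frame.
#' @export
ground_truth <- function(objects, scene) {
  do.call(rbind, lapply(objects, ground_truth_row, scene = scene))
}

## ---- rendering ------------------------------------------------------------

# geometry of an object at a given frame (handles gliding filaments)
object_geom_at <- function(obj, frame) {
  if (obj$class == "filament") {
    # displacement along axis, px
    disp <- obj$.px_per_frame * (frame - min(obj$frames))
    u <- c(sin(obj$angle), cos(obj$angle))
    ctr <- obj$center + u * disp
    # gliding filaments render anti-aliased (sub-pixel motion must not strobe)
    segment_geom(ctr, obj$angle, obj$length_px, obj$width_px, soft = TRUE)
  } else obj$geom
}

render_channels <- function(scene, objects, check_fit = TRUE) {
  field <- scene$field
  ideal <- lapply(scene$channels, function(ch)
    array(rep(scene$backgrounds[[ch]], prod(field) * scene$n_frames),
          c(field, scene$n_frames)))
  names(ideal) <- scene$channels
  add_geom <- function(arr, geom, amp, frames) {
    p <- soft_profile(geom, field)
    for (t in frames) arr[p$rows, p$cols, t] <-
        arr[p$rows, p$cols, t] + amp * p$coverage
    arr
  }
  all_frames <- seq_len(scene$n_frames)
  for (obj in objects) {
    if (length(obj$frames) == 0) stop("object ", obj$id, " has zero frames")
    if (any(obj$frames < 1 | obj$frames > scene$n_frames))
      stop("object ", obj$id, ": visible frames outside movie")
    if (obj$class == "filament") {
      obj$.px_per_frame <- obj$velocity * scene$frame_interval / scene$pixel_size
      for (t in obj$frames) {
        g <- object_geom_at(obj, t)
        if (check_fit && !geom_in_field(g, field))
          stop("object ", obj$id, ": geometry outside field at frame ", t)
        ideal$actin <- add_geom(ideal$actin, g, obj$peak, t)
      }
    } else if (obj$class %in% c("actin_patch", "bridge", "tail", "binding_event")) {
      if (check_fit && !geom_in_field(obj$geom, field))
        stop("object ", obj$id, ": geometry outside field")
      ch <- obj$channel
      amp <- (obj$enrichment - 1) * scene$backgrounds[[ch]]
      ideal[[ch]] <- add_geom(ideal[[ch]], obj$geom, amp, obj$frames)
      for (ag in obj$actin_geoms)
        ideal$actin <- add_geom(ideal$actin, ag, obj$actin_peak, all_frames)
      if (!is.null(obj$lim_geom)) {
        lamp <- (obj$lim_enrichment - 1) * scene$backgrounds[["lim"]]
        ideal$lim <- add_geom(ideal$lim, obj$lim_geom, lamp, all_frames)
      }
    } else if (obj$class == "droplet") {
      if (check_fit && !geom_in_field(obj$geom, field))
        stop("object ", obj$id, ": geometry outside field")
      for (ch in obj$channel) {
        amp <- (obj$enrichment[[ch]] - 1) * scene$backgrounds[[ch]]
        ideal[[ch]] <- add_geom(ideal[[ch]], obj$geom, amp, obj$frames)
      }
    } else stop("cannot render object class: ", obj$class)
  }
  ideal
}

finalize_movie <- function(scene, ideal) {
  with_seed(scene$seed, {
    out <- lapply(names(ideal), function(ch) {
      arr <- ideal[[ch]]
      for (t in seq_len(scene$n_frames)) {
        fr <- arr[, , t] * scene$illumination
        if (scene$psf_sigma > 0) fr <- gaussian_blur(fr, scene$psf_sigma)
        fr <- fr * scene$bleach_rate^(t - 1) * scene$photon_scale
        if (scene$noise) fr <- matrix(stats::rpois(length(fr), fr),
                                      nrow(fr), ncol(fr))
        arr[, , t] <- fr + scene$camera_offset
      }
      arr
    })
    names(out) <- names(ideal)
    movie_stack(out, scene$frame_interval, scene$pixel_size)
  })
}

#' Simulate a gliding-assay movie with planted ground truth
#'
#' Renders planted filaments, LIM-protein objects, binding events and
#' droplets into a multi-channel movie under the scene's optics/noise
#' model, and returns the exact ground-truth table alongside.
#'
#' @param scene a `SimScene`.
#' @param objects list of `PlantedObject`s.
#' @return list with `movie` (a `MovieStack`) and `ground_truth`
#'   (data.frame).
#' @export
simulate_gliding_movie <- function(scene, objects) {
  stopifnot(inherits(scene, "SimScene"))
  if (scene$n_frames < 1) stop("zero frames")
  ideal <- render_channels(scene, objects)
  list(movie = finalize_movie(scene, ideal),
       ground_truth = ground_truth(objects, scene))
}

## ---- strain sites ---------------------------------------------------------

#' Plant a strain site in a contractile bundle
#'
#' Describes an ablation-induced strain site: a bundle along a horizontal
#' line, a gap created at `ablation_frame`, and linear intensity recovery
#' inside the gap following one of four spatial paths, mirroring the four
#' repair-path categories (even, center-first, one end plus center, both
#' ends). Segment recovery rates are in intensity units per second.
#'
#' @param id object id.
#' @param center c(row, col) of the gap center.
#' @param bundle_length_px,bundle_width_px bundle geometry.
#' @param gap_px length of the ablated gap along the bundle.
#' @param ablation_frame frame at which the gap appears.
#' @param path one of `"even"`, `"center"`, `"one_end_center"`, `"both_ends"`.
#' @param rate_center,rate_end recovery rates (intensity/s) of the middle
#'   80% and outer 10% segments.
#' @param delay_s onset delay of the trailing segments for the non-even paths.
#' @param peak bundle amplitude above background.
#' @param lim_flash logical; render a LIM-channel flash spanning the gap.
#' @param partner_fold if > 0, partner channel doubles to this fold over its
#'   pre-ablation level within the gap after ablation.
#' @export
planted_strain_site <- function(id, center, bundle_length_px = 200,
                                bundle_width_px = 7, gap_px = 50,
                                ablation_frame, path = c("even", "center",
                                                         "one_end_center",
                                                         "both_ends"),
                                rate_center = 1, rate_end = 0.5, delay_s = 30,
                                peak = 100, lim_flash = TRUE, partner_fold = 0) {
  path <- match.arg(path)
  new_planted(id, "strain_site", center = center,
              bundle_length_px = bundle_length_px,
              bundle_width_px = bundle_width_px, gap_px = gap_px,
              ablation_frame = as.integer(ablation_frame), path = path,
              rate_center = rate_center, rate_end = rate_end,
              delay_s = delay_s, peak = peak, lim_flash = lim_flash,
              partner_fold = partner_fold,
              frames = NA_integer_, enrichment = NA_real_)
}

#' Simulate a strain-site (ablation) movie
#'
#' Actin channel: a horizontal bundle with a gap appearing at the ablation
#' frame; intensity inside the gap recovers linearly at the planted
#' per-segment rates along the planted spatial path. LIM channel: a flash
#' spanning the gap from the ablation frame. Partner channel: optional
#' fold increase within the gap. Setting both rates to 0 plants a repair
#' failure.
#'
#' @param scene a `SimScene`.
#' @param site a `PlantedObject` of class `strain_site`.
#' @return list with `movie` and `ground_truth`.
#' @export
simulate_strain_site_movie <- function(scene, site) {
  stopifnot(inherits(scene, "SimScene"), site$class == "strain_site")
  if (site$ablation_frame >= scene$n_frames)
    stop("ablation frame (", site$ablation_frame, ") must be < n frames (",
         scene$n_frames, ")")
  field <- scene$field
  ctr <- site$center
  half_b <- site$bundle_length_px / 2
  rows <- max(1, floor(ctr[1] - site$bundle_width_px / 2)):
    min(field[1], ceiling(ctr[1] + site$bundle_width_px / 2))
  cols <- max(1, floor(ctr[2] - half_b)):min(field[2], ceiling(ctr[2] + half_b))
  gap_cols <- cols[abs(cols - ctr[2]) <= site$gap_px / 2]
  if (!length(gap_cols)) stop("gap outside field")
  # segment membership along the gap (first/last 10% = ends, middle 80% = center)
  s <- (gap_cols - min(gap_cols)) / max(1, (length(gap_cols) - 1))
  seg <- ifelse(s < 0.10, "left", ifelse(s > 0.90, "right", "center"))
  dtf <- scene$frame_interval
  onset <- function(segname) {
    t0 <- site$ablation_frame + 1L
    dly <- round(site$delay_s / dtf)
    lead <- switch(site$path,
      even = c(left = 0, center = 0, right = 0),
      center = c(left = dly, center = 0, right = dly),
      one_end_center = c(left = 0, center = 0, right = dly),
      both_ends = c(left = 0, center = dly, right = 0))
    t0 + lead[[segname]]
  }
  rate <- function(segname)
    if (segname == "center") site$rate_center else site$rate_end
  ideal <- lapply(scene$channels, function(ch)
    array(rep(scene$backgrounds[[ch]], prod(field) * scene$n_frames),
          c(field, scene$n_frames)))
  names(ideal) <- scene$channels
  for (t in seq_len(scene$n_frames)) {
    fr <- matrix(0, length(rows), length(cols))
    if (t <= site$ablation_frame) {
      fr[] <- site$peak
    } else {
      fr[, !(cols %in% gap_cols)] <- site$peak
      for (j in which(cols %in% gap_cols)) {
        sg <- seg[match(cols[j], gap_cols)]
        tau <- (t - onset(sg)) * dtf
        fr[, j] <- min(site$peak, max(0, rate(sg) * max(0, tau)))
      }
    }
    ideal$actin[rows, cols, t] <- ideal$actin[rows, cols, t] + fr
    if (site$lim_flash && "lim" %in% scene$channels && t > site$ablation_frame) {
      amp <- 3 * scene$backgrounds[["lim"]] *
        exp(-(t - site$ablation_frame - 1) * dtf / 120)
      ideal$lim[rows, gap_cols, t] <- ideal$lim[rows, gap_cols, t] + amp
    }
    if (site$partner_fold > 0 && "partner" %in% scene$channels &&
        t > site$ablation_frame) {
      ideal$partner[rows, gap_cols, t] <- ideal$partner[rows, gap_cols, t] +
        (site$partner_fold - 1) * scene$backgrounds[["partner"]]
    }
  }
  gt <- data.frame(id = site$id, class = "strain_site", path = site$path,
                   ablation_frame = site$ablation_frame,
                   rate_center = site$rate_center, rate_end = site$rate_end,
                   delay_s = site$delay_s, gap_px = length(gap_cols),
                   repaired = site$rate_center > 0 || site$rate_end > 0,
                   stringsAsFactors = FALSE)
  list(movie = finalize_movie(scene, ideal), ground_truth = gt)
}

## ---- FRAP -----------------------------------------------------------------

#' Simulate a droplet FRAP movie
#'
#' Plants droplets, photobleaches those listed in `bleach_rois` at
#' `bleach_frame`, and lets them recover as
#' `I(t) = I0 * (immobile + mobile * (1 - exp(-k t)))` relative to the
#' bleach depth, all scaled by the scene's global bleach decay. Ground
#' truth stores the planted mobile fraction and rate constant.
#'
#' @param scene a `SimScene` (its channels should include the droplet
#'   channels).
#' @param droplets list of `planted_droplet()` objects.
#' @param bleach_rois integer indices into `droplets` naming which are
#'   photobleached.
#' @param bleach_frame frame after which recovery starts.
#' @param mobile_fraction planted mobile fraction in `[0, 1]`.
#' @param recovery_rate recovery rate constant k in 1/s.
#' @param bleach_depth fraction of intensity removed by the bleach (default 1).
#' @return list with `movie` and `ground_truth`.
#' @export
simulate_frap_movie <- function(scene, droplets, bleach_rois, bleach_frame,
                                mobile_fraction, recovery_rate,
                                bleach_depth = 1) {
  stopifnot(inherits(scene, "SimScene"),
            mobile_fraction >= 0, mobile_fraction <= 1,
            bleach_frame >= 1, bleach_frame < scene$n_frames)
  for (i in bleach_rois)
    if (!geom_in_field(droplets[[i]]$geom, scene$field))
      stop("bleach ROI outside field for droplet ", droplets[[i]]$id)
  ideal <- render_channels(scene, droplets)
  dtf <- scene$frame_interval
  for (i in bleach_rois) {
    d <- droplets[[i]]
    p <- soft_profile(d$geom, scene$field)
    for (ch in d$channel) {
      amp <- (d$enrichment[[ch]] - 1) * scene$backgrounds[[ch]]
      for (t in seq(bleach_frame + 1L, scene$n_frames)) {
        tau <- (t - bleach_frame - 1L) * dtf
        frac <- (1 - bleach_depth) + bleach_depth * mobile_fraction *
          (1 - exp(-recovery_rate * tau))
        # replace the droplet's added intensity by its recovered fraction
        ideal[[ch]][p$rows, p$cols, t] <- ideal[[ch]][p$rows, p$cols, t] -
          amp * p$coverage * (1 - frac)
      }
    }
  }
  gt <- ground_truth(droplets, scene)
  gt$bleached <- seq_along(droplets) %in% bleach_rois
  gt$mobile_fraction <- ifelse(gt$bleached, mobile_fraction, NA_real_)
  gt$recovery_rate <- ifelse(gt$bleached, recovery_rate, NA_real_)
  gt$bleach_frame <- ifelse(gt$bleached, bleach_frame, NA_integer_)
  list(movie = finalize_movie(scene, ideal), ground_truth = gt)
}

## ---- ground-truth detection -----------------------------------------------

#' Detection structures built from planted ground truth
#'
#' Builds the same per-frame structures [detect_candidates()] produces —
#' labeled LIM objects, actin masks, and the intensity stack used for
#' measurements — directly from the planted objects, bypassing image
#' segmentation. This isolates downstream stages (linking, enrichment,
#' filtering, classification) from segmentation error: trajectory linking
#' can be verified against exact planted blink gaps, and the enrichment
#' estimator against exact planted ratios.
#'
#' @param scene the `SimScene`.
#' @param objects list of `PlantedObject`s (LIM-type objects are labeled;
#'   their actin support and filaments populate the actin masks).
#' @param movie optional rendered `MovieStack`; its `lim` channel is used
#'   for intensity measurements (defaults to rendering noiselessly).
#' @param params list from [patch_params()].
#' @return list with `lim_labels`, `actin_masks`, `lim_smooth`, `params` —
#'   accepted by [link_trajectories()].
#' @export
planted_detection <- function(scene, objects, movie = NULL,
                              params = patch_params()) {
  field <- scene$field
  nt <- scene$n_frames
  if (is.null(movie)) movie <- simulate_gliding_movie(scene, objects)$movie
  lim_labels <- vector("list", nt)
  actin_masks <- rep(list(matrix(FALSE, field[1], field[2])), nt)
  for (t in seq_len(nt)) lim_labels[[t]] <- matrix(0L, field[1], field[2])
  for (obj in objects) {
    if (obj$class == "filament") {
      obj$.px_per_frame <- obj$velocity * scene$frame_interval / scene$pixel_size
      for (t in obj$frames) {
        m <- planted_geom_mask(object_geom_at(obj, t), field)
        actin_masks[[t]] <- actin_masks[[t]] | m
      }
    } else if (obj$class %in% c("actin_patch", "bridge", "tail")) {
      m <- planted_geom_mask(obj$geom, field)
      for (t in obj$frames)
        lim_labels[[t]][m] <- max(lim_labels[[t]]) + 1L
      for (ag in obj$actin_geoms) {
        am <- planted_geom_mask(ag, field)
        for (t in seq_len(nt)) actin_masks[[t]] <- actin_masks[[t]] | am
      }
    }
  }
  # relabel contiguously per frame in raster order
  for (t in seq_len(nt)) {
    lab <- lim_labels[[t]]
    ids <- unique(lab[lab > 0])
    relab <- integer(max(c(0L, ids)))
    relab[ids] <- seq_along(ids)
    lab[lab > 0] <- relab[lab[lab > 0]]
    lim_labels[[t]] <- lab
  }
  list(lim_labels = lim_labels, actin_masks = actin_masks,
       lim_smooth = movie$channels$lim, params = params)
}

## ---- layout helper --------------------------------------------------------

#' Lay out a field of classified LIM objects on a grid
#'
#' Places `n_patch + n_bridge + n_tail` planted LIM objects in distinct
#' grid cells of the scene's field (one object per cell, random orientation
#' and jitter), so objects never collide and every planted class is
#' recoverable. Used throughout the test-bench to build classification,
#' gap-tolerance and enrichment studies.
#'
#' @param scene a `SimScene`.
#' @param n_patch,n_bridge,n_tail per-class object counts.
#' @param frames default visible frames for every object.
#' @param enrichment scalar or vector (recycled) of true enrichment ratios.
#' @param length_px LIM segment length.
#' @param gap_spec optional named list: `gap_start` frame and `gap_len`
#'   frames; a blink gap punched into every object's visible set.
#' @param cell_px grid cell size (default 64).
#' @param seed layout RNG seed.
#' @param soft_edges passed to [planted_lim_object()].
#' @return list of `PlantedObject`s.
#' @export
plant_lim_field <- function(scene, n_patch = 0, n_bridge = 0, n_tail = 0,
                            frames = seq_len(scene$n_frames), enrichment = 2,
                            length_px = 24, gap_spec = NULL, cell_px = 64L,
                            seed = scene$seed, soft_edges = TRUE) {
  classes <- rep(c("actin_patch", "bridge", "tail"),
                 c(n_patch, n_bridge, n_tail))
  n <- length(classes)
  ncell_r <- scene$field[1] %/% cell_px
  ncell_c <- scene$field[2] %/% cell_px
  if (n > ncell_r * ncell_c)
    stop("field too small for ", n, " objects at cell size ", cell_px)
  enrichment <- rep(enrichment, length.out = n)
  if (!is.null(gap_spec)) {
    gap_frames <- seq(gap_spec$gap_start, length.out = gap_spec$gap_len)
    frames <- setdiff(frames, gap_frames)
  }
  with_seed(seed, {
    cells <- sample(ncell_r * ncell_c, n)
    lapply(seq_len(n), function(i) {
      cr <- ((cells[i] - 1L) %% ncell_r)
      cc <- ((cells[i] - 1L) %/% ncell_r)
      center <- c(cr * cell_px + cell_px / 2 + stats::runif(1, -4, 4),
                  cc * cell_px + cell_px / 2 + stats::runif(1, -4, 4))
      planted_lim_object(i, classes[i], center = center,
                         angle = stats::runif(1, 0, pi),
                         length_px = length_px, frames = frames,
                         enrichment = enrichment[i], soft_edges = soft_edges)
    })
  })
}
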