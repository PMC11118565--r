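# Patch pipeline: detection, linking, repair, enrichment, classification,
# summaries, velocities, registration.

test_that("noiseless detection finds each planted object once, near its centroid", {
  sc <- test_scene(field = c(192, 192), n_frames = 9, seed = 3)
  objs <- plant_lim_field(sc, 1, 1, 1, cell_px = 64, seed = 9)
  sim <- simulate_gliding_movie(sc, objs)
  det <- detect_candidates(sim$movie)
  for (t in 2:8) {                       # interior frames (full averaging window)
    lab <- det$lim_labels[[t]]
    expect_equal(max(lab), 3)
    for (o in objs) {
      ctr <- colMeans(o$geom$coords)
      hit <- lab[round(ctr[1]), round(ctr[2])]
      expect_gt(hit, 0)
      pts <- which(lab == hit, arr.ind = TRUE)
      expect_lt(sqrt(sum((colMeans(pts) - ctr)^2)), 1)
    }
  }
  # empty movie: no objects anywhere
  sc0 <- test_scene(field = c(64, 64), n_frames = 4, seed = 1)
  sim0 <- simulate_gliding_movie(
    sc0, list(planted_filament(1, c(32, 20), angle = pi / 2, length_px = 20,
                               peak = 40, frames = 1:4)))
  sim0$movie$channels$lim[] <- 20        # flat LIM channel
  det0 <- detect_candidates(sim0$movie)
  expect_true(all(vapply(det0$lim_labels, max, integer(1)) == 0))
  expect_error(detect_candidates(movie_stack(list(
    actin = array(1, c(8, 8, 2))), 1, 0.1)), "lim")
})

test_that("linking window semantics are exact and match the graph oracle", {
  sc <- test_scene(field = c(96, 96), n_frames = 20, seed = 2)
  mk <- function(gap_len) {
    objs <- plant_lim_field(sc, 1, 0, 0, cell_px = 96, seed = 3,
                            gap_spec = list(gap_start = 8, gap_len = gap_len))
    det <- planted_detection(sc, objs)
    link_trajectories(det, simulate_gliding_movie(sc, objs)$movie)
  }
  for (g in 1:3) expect_length(mk(g), 1)
  for (g in 4:5) expect_length(mk(g), 2)

  # single-frame object with no neighbours is not persistent
  objs1 <- plant_lim_field(sc, 1, 0, 0, frames = 3, cell_px = 96, seed = 3)
  det1 <- planted_detection(sc, objs1)
  expect_length(link_trajectories(det1, simulate_gliding_movie(sc, objs1)$movie), 0)

  expect_error(link_trajectories(
    planted_detection(sc, plant_lim_field(sc, 1, 0, 0, cell_px = 96, seed = 3),
                      params = patch_params(gap_window = 0)),
    simulate_gliding_movie(sc, plant_lim_field(sc, 1, 0, 0, cell_px = 96,
                                               seed = 3))), "gap_window")
})

test_that("trajectory partition equals brute-force overlap-graph reachability", {
  set.seed(31)
  for (trial in 1:10) {
    # random objects: static footprints, random visible-frame sets
    sc <- test_scene(field = c(128, 128), n_frames = 12, seed = trial)
    n_obj <- sample(2:4, 1)
    objs <- plant_lim_field(sc, n_obj, 0, 0, cell_px = 64, seed = trial * 7)
    objs <- lapply(objs, function(o) {
      o$frames <- sort(sample(1:12, sample(4:10, 1)))
      o
    })
    det <- planted_detection(sc, objs)
    trajs <- link_trajectories(det, simulate_gliding_movie(sc, objs)$movie)
    # flatten detections to (frame, footprint) nodes for the oracle
    frames <- integer(0); feet <- list(); node_traj <- integer(0)
    for (t in seq_len(12)) {
      lab <- det$lim_labels[[t]]
      for (lb in seq_len(max(0, max(lab)))) {
        frames <- c(frames, t)
        feet[[length(feet) + 1]] <- which(lab == lb)
      }
    }
    want <- link_oracle_components(frames, feet, gap_window = 3)
    # compare partitions: group nodes by which trajectory claimed them
    got <- rep(NA_integer_, length(frames))
    for (ti in seq_along(trajs)) {
      rec <- trajs[[ti]]$records
      for (i in seq_len(nrow(rec))) {
        hit <- which(frames == rec$frame[i] &
                       vapply(feet, function(f)
                         det$lim_labels[[rec$frame[i]]][f[1]] == rec$label[i] &&
                           all(f %in% which(det$lim_labels[[rec$frame[i]]] ==
                                              rec$label[i])),
                         logical(1)))
        got[hit] <- ti
      }
    }
    keep <- !is.na(want)
    expect_identical(is.na(got), is.na(want), info = paste("trial", trial))
    if (any(keep))
      expect_equal(length(unique(paste(got[keep], want[keep]))),
                   length(unique(want[keep])), info = paste("trial", trial))
  }
})

test_that("gap repair copies the preceding record and flags it", {
  sc <- test_scene(field = c(96, 96), n_frames = 12, seed = 2)
  objs <- plant_lim_field(sc, 1, 0, 0, cell_px = 96, seed = 3,
                          gap_spec = list(gap_start = 6, gap_len = 2))
  det <- planted_detection(sc, objs)
  trajs <- link_trajectories(det, simulate_gliding_movie(sc, objs)$movie)
  tr <- repair_trajectory(trajs[[1]])
  rec <- tr$records
  expect_equal(rec$frame, 1:12)
  expect_true(all(rec$filled[rec$frame %in% 6:7]))
  filled <- rec[rec$frame == 6, ]
  prev <- rec[rec$frame == 5, ]
  expect_equal(filled$area, prev$area)
  expect_equal(filled$centroid_r, prev$centroid_r)
  # no gaps: identity
  objs2 <- plant_lim_field(sc, 1, 0, 0, cell_px = 96, seed = 3)
  det2 <- planted_detection(sc, objs2)
  tr2 <- link_trajectories(det2, simulate_gliding_movie(sc, objs2)$movie)[[1]]
  expect_identical(repair_trajectory(tr2)$records, tr2$records)
})

test_that("planted outliers are replaced by the preceding record", {
  # hand-built trajectory: area jumps 10x the median at one frame
  rec <- data.frame(frame = 1:9, label = 1L, area = c(50, 50, 50, 50, 500,
                                                      50, 50, 50, 50),
                    centroid_r = 10, centroid_c = 10, mean_int = 1,
                    bg_mean = 1, enrichment = 1, overlap_fraction = 1,
                    n_overlap_regions = 1L, length_px = 10, filled = FALSE)
  rec$area <- as.numeric(rec$area)
  traj <- structure(list(id = 1, records = rec, first_frame = 1,
                         last_frame = 9, frame_interval = 3, pixel_size = 0.1),
                    class = "Trajectory")
  out <- repair_trajectory(traj)
  expect_equal(out$records$area[5], 50)
  expect_true(out$records$filled[5])
})

test_that("enrichment estimator matches direct means and error contracts", {
  fr <- matrix(100, 30, 30)
  m <- matrix(FALSE, 30, 30); m[14:17, 14:17] <- TRUE
  fr[m] <- 200
  expect_equal(compute_enrichment(m, fr, 3), 2.0)
  expect_equal(compute_enrichment(m, matrix(5, 30, 30), 3), 1.0)
  expect_error(compute_enrichment(matrix(FALSE, 5, 5), fr), "empty object")
  full <- matrix(TRUE, 5, 5)
  expect_error(compute_enrichment(full, matrix(1, 5, 5)), "ring")
})

test_that("overlap/enrichment filters keep and drop per the stated rules", {
  mk_traj <- function(overlap_frames, total, max_enr) {
    rec <- data.frame(frame = seq_len(total), label = 1L, area = 50,
                      centroid_r = 1, centroid_c = 1, mean_int = 1,
                      bg_mean = 1,
                      enrichment = c(rep(1, total - 1), max_enr),
                      overlap_fraction = c(rep(0.5, overlap_frames),
                                           rep(0, total - overlap_frames)),
                      n_overlap_regions = 1L, length_px = 5, filled = FALSE)
    structure(list(id = 1, records = rec, frame_interval = 3,
                   pixel_size = 0.1), class = "Trajectory")
  }
  expect_length(filter_trajectories(list(mk_traj(8, 10, 2.0))), 1)   # 0.8 >= 0.75
  expect_length(filter_trajectories(list(mk_traj(7, 10, 2.0))), 0)   # 0.7 < 0.75
  expect_length(filter_trajectories(list(mk_traj(0, 10, 2.0))), 0)   # never overlaps
  expect_length(filter_trajectories(list(mk_traj(10, 10, 1.29))), 0) # too dim
  expect_length(filter_trajectories(list(mk_traj(10, 10, 1.3))), 1)  # at floor
})

test_that("per-frame classification implements the topology rules", {
  expect_equal(classify_patch_frame(2L, 0.4), "bridge")
  expect_equal(classify_patch_frame(1L, 0.9), "actin_bound_patch")
  expect_equal(classify_patch_frame(1L, 0.70), "actin_bound_patch")  # inclusive
  expect_equal(classify_patch_frame(1L, 0.3), "tail")
  expect_equal(classify_patch_frame(0L, 0), "unbound")
  expect_equal(classify_patch_frame(3L, 0.5), "bridge")   # multi-fragment span
})

test_that("class-transition splitting produces maximal constant runs", {
  mk <- function(classes_n) {
    n <- sum(classes_n)
    rec <- data.frame(frame = seq_len(n), label = 1L, area = 50,
                      centroid_r = 1, centroid_c = 1, mean_int = 1, bg_mean = 1,
                      enrichment = 2,
                      overlap_fraction = rep(c(0.9, 0.4), classes_n),
                      n_overlap_regions = rep(c(1L, 2L), classes_n),
                      length_px = 5, filled = FALSE)
    structure(list(id = 1, records = rec, frame_interval = 3,
                   pixel_size = 0.1), class = "Trajectory")
  }
  segs <- split_on_class_transition(mk(c(5, 4)))
  expect_length(segs, 2)
  expect_equal(vapply(segs, function(s) s$class, character(1)),
               c("actin_bound_patch", "bridge"))
  expect_equal(vapply(segs, function(s) nrow(s$records), integer(1)), c(5L, 4L))
  expect_equal(summarize_trajectories(segs)$lifetime_s, c(15, 12))
  # constant class: identity split
  one <- split_on_class_transition(mk(c(9, 0)))
  expect_length(one, 1)
  # alternating classes: one trajectory per frame
  alt <- mk(c(1, 1)); alt$records <- do.call(rbind, rep(list(alt$records), 3))
  alt$records$frame <- 1:6
  expect_length(split_on_class_transition(alt), 6)
})

test_that("lifetime CDF half-life recovers the median of planted lifetimes", {
  expect_equal(lifetime_cdf(numeric(0))$half_life, NA_real_)
  set.seed(12)
  m <- 30
  lt <- rexp(500, log(2) / m)       # median m
  hl <- lifetime_cdf(lt)$half_life
  expect_lt(abs(hl - m) / m, 0.15)
  # simple arithmetic: 10 frames at 3 s
  rec <- data.frame(frame = 1:10, label = 1L, area = 1, centroid_r = 1,
                    centroid_c = 1, mean_int = 1, bg_mean = 1, enrichment = 2,
                    overlap_fraction = 1, n_overlap_regions = 1L,
                    length_px = 5, filled = FALSE)
  tr <- structure(list(id = 1, records = rec, class = "tail",
                       frame_interval = 3, pixel_size = 0.1),
                  class = "Trajectory")
  expect_equal(summarize_trajectories(list(tr))$lifetime_s, 30)
})

test_that("interface velocity converts displacement to um/s and smooths", {
  pos <- data.frame(frame = 1:10, row = 5, col = 5)
  v <- interface_velocity(pos, 2, 0.1)
  expect_true(all(v$velocity_um_s == 0))
  pos2 <- data.frame(frame = 1:5, row = seq(0, 40, 10), col = 7)
  v2 <- interface_velocity(pos2, 2, 0.1, smooth_window = 10)
  expect_true(all(abs(v2$velocity_um_s - 0.5) < 1e-12))  # 10 px/frame
  expect_true(all(abs(v2$smoothed_um_s - 0.5) < 1e-12))
  expect_error(interface_velocity(data.frame(frame = c(1, 1, 2), row = 0,
                                             col = 0), 2, 0.1), "increasing")
})

test_that("phase correlation recovers planted integer shifts", {
  set.seed(5)
  base <- matrix(runif(64 * 64), 64, 64)
  arr <- array(0, c(64, 64, 3))
  arr[, , 1] <- base
  arr[, , 2] <- base
  sh <- limrepair:::shift_frame(base, 3, -2)
  arr[, , 3] <- sh
  mv <- movie_stack(list(actin = arr), 1, 0.1)
  reg <- register_translation(mv, 1)
  expect_equal(reg$shifts$dr, c(0, 0, -3))
  expect_equal(reg$shifts$dc, c(0, 0, 2))
  # shifting back restores the overlap region
  expect_equal(reg$movie$channels$actin[10:50, 10:50, 3],
               base[10:50, 10:50])
  # featureless frames: zero shift with warning
  arrf <- array(1, c(16, 16, 2))
  mvf <- movie_stack(list(actin = arrf), 1, 0.1)
  w <- capture_warnings(regf <- register_translation(mvf, 1))
  expect_true(any(grepl("featureless", w)))
  expect_true(all(regf$shifts$dr == 0) && all(regf$shifts$dc == 0))
})

test_that("length measures behave as documented on a rectangle", {
  pts <- which(matrix(TRUE, 3, 20), arr.ind = TRUE)   # 3 x 20 rectangle
  expect_equal(feret_diameter(pts), sqrt(19^2 + 2^2))
  expect_gt(ellipse_major_axis(pts), 20)               # 4-sigma convention reads long
  expect_equal(feret_diameter(pts[1, , drop = FALSE]), 0)
})
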