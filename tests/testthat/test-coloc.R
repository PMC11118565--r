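# Partner-protein analyses: binding events, -ATP colocalization, fold increase.

coloc_movie <- function(events, n_frames = 30, seed = 1) {
  sc <- test_scene(field = c(160, 160), n_frames = n_frames, seed = seed,
                   frame_interval = 3)
  simulate_gliding_movie(sc, events)
}

test_that("stable on-patch and bare-actin events are recovered with lifetimes", {
  ev_on <- planted_binding_event(1, "on_patch", center = c(40, 40),
                                 angle = 0.3, frames = 5:24, enrichment = 3)
  ev_off <- planted_binding_event(2, "bare_actin", center = c(110, 110),
                                  angle = 1.2, frames = 8:27, enrichment = 3)
  sim <- coloc_movie(list(ev_on, ev_off))
  ev <- detect_binding_events(sim$movie, coloc_preset("vasp"))
  expect_equal(sort(unique(ev$substrate)), c("bare_actin", "on_patch"))
  on <- ev[ev$substrate == "on_patch", ]
  off <- ev[ev$substrate == "bare_actin", ]
  expect_equal(nrow(on), 1)
  expect_equal(nrow(off), 1)
  # planted 60 s lifetimes, +/- 2 frames of averaging spread
  expect_lt(abs(on$lifetime_s - 60), 2 * 3 + 1e-9)
  expect_lt(abs(off$lifetime_s - 60), 2 * 3 + 1e-9)
  expect_equal(on$category, "stable")
  # substrates partition the signal: no event double-counted
  expect_equal(nrow(ev), 2)
})

test_that("enrichment floors exclude dim events per preset", {
  # planted below-background partner signal is undetectable -> excluded
  dim_ev <- planted_binding_event(1, "on_patch", center = c(40, 40),
                                  angle = 0.3, frames = 5:24, enrichment = 0.9)
  sim <- coloc_movie(list(dim_ev))
  ev <- detect_binding_events(sim$movie, coloc_preset("vasp"))
  expect_equal(nrow(ev), 0)
  # detectable but below the 1.3 alpha-actinin floor -> dropped by the floor
  mid_ev <- planted_binding_event(1, "on_patch", center = c(40, 40),
                                  angle = 0.3, frames = 5:24, enrichment = 1.2)
  sim2 <- coloc_movie(list(mid_ev))
  ev_vasp <- detect_binding_events(sim2$movie, coloc_preset("vasp"))
  ev_act <- detect_binding_events(sim2$movie, coloc_preset("actinin_atp",
                                                           actin_method = "otsu",
                                                           lim_method = "yen"))
  expect_gt(nrow(ev_vasp), 0)     # above the VASP floor of 1.0
  expect_equal(nrow(ev_act), 0)   # below the alpha-actinin floor of 1.3
})

test_that("the 15 s search window links and splits absences as specified", {
  mk <- function(gap_frames) {
    frames <- c(5:10, (11 + gap_frames):28)
    ev <- planted_binding_event(1, "on_patch", center = c(40, 40),
                                angle = 0.3, frames = frames, enrichment = 3)
    sim <- coloc_movie(list(ev), n_frames = 32)
    # window = 1: no temporal averaging, so planted absences are preserved
    detect_binding_events(sim$movie, coloc_preset("actinin_atp",
                                                  actin_method = "otsu",
                                                  lim_method = "yen"),
                          params = patch_params(window = 1))
  }
  ev5 <- mk(5)    # 15 s absence at 3 s/frame: linked
  expect_equal(nrow(ev5[ev5$substrate == "on_patch", ]), 1)
  ev6 <- mk(6)    # 18 s absence: split
  expect_equal(nrow(ev6[ev6$substrate == "on_patch", ]), 2)
})

test_that("lifetime categorization uses a closed 2 s upper bound", {
  expect_equal(categorize_event(c(1, 2, 2.0001, 60), 2),
               c("transient", "transient", "stable", "stable"))
})

test_that("event statistics aggregate means, counts and truncate periods", {
  ev <- data.frame(substrate = c("on_patch", "on_patch", "bare_actin"),
                   t_start_s = c(0, 100, 0), lifetime_s = c(2, 4, 10),
                   category = c("transient", "stable", "stable"),
                   max_enrichment = c(2, 4, 1.5), n_frames = c(2, 4, 10))
  st <- event_statistics(ev)
  on <- st[st$group == "on_patch", ]
  expect_equal(on$mean_lifetime_s, 3)
  expect_equal(on$mean_max_enrichment, 3)
  expect_equal(on$n_events, 2)
  # equal imaging periods: the late event is not counted
  st2 <- event_statistics(ev, equal_period_s = 50)
  expect_equal(st2$n_events[st2$group == "on_patch"], 1)
})

test_that("-ATP last-frame recipe finds on-filament coincident clusters only", {
  sc <- test_scene(field = c(128, 128), n_frames = 5, seed = 6,
                   backgrounds = c(actin = 10, lim = 20, partner = 20))
  fil <- planted_filament(1, c(64, 64), angle = pi / 2, length_px = 100,
                          peak = 60, frames = 1:5)
  on_fil <- planted_droplet(2, c(40, 64), 4,
                            c(lim = 3, partner = 3), frames = 1:5)
  off_fil <- planted_droplet(3, c(20, 100), 4,
                             c(lim = 3, partner = 3), frames = 1:5)
  sim <- simulate_gliding_movie(sc, list(fil, on_fil, off_fil))
  tab <- coloc_noatp_lastframe(sim$movie)
  expect_equal(nrow(tab), 1)
  expect_gt(tab$enrichment, 1.5)
  # empty alpha-actinin channel: zero events
  mv2 <- sim$movie
  mv2$channels$partner[] <- 20
  expect_equal(nrow(coloc_noatp_lastframe(mv2)), 0)
})

test_that("fold increase is exact on time-constant movies and planted growth", {
  nr <- 120; nt <- 30
  base <- matrix(10, nr, nr)
  spot_r <- 55:74; spot_c <- 55:74
  arr <- array(0, c(nr, nr, nt))
  for (t in seq_len(nt)) {
    fr <- base
    fr[spot_r, spot_c] <- fr[spot_r, spot_c] + 40
    arr[, , t] <- fr
  }
  mv <- movie_stack(list(actin = arr), 3, 0.0653)
  boxes <- data.frame(center_r = 64, center_c = 64, group = "patch")
  res <- actin_fold_increase(mv, boxes, rolling_ball_radius = 30)
  expect_equal(res$traces$fold, rep(1, nt))
  expect_equal(res$summary$mean_fold, 1)

  # amplitude doubling linearly over the movie (baseline frames at 1x)
  arr2 <- arr
  ramp <- c(rep(1, 5), seq(1, 2, length.out = nt - 5))
  for (t in seq_len(nt)) {
    fr <- base
    fr[spot_r, spot_c] <- fr[spot_r, spot_c] + 40 * ramp[t]
    arr2[, , t] <- fr
  }
  mv2 <- movie_stack(list(actin = arr2), 3, 0.0653)
  res2 <- actin_fold_increase(mv2, boxes, rolling_ball_radius = 30)
  expect_equal(res2$traces$fold[nt], 2, tolerance = 0.05)

  # empty box after background subtraction: baseline-zero error
  boxes_bad <- data.frame(center_r = 20, center_c = 20)
  expect_error(actin_fold_increase(mv, boxes_bad, rolling_ball_radius = 30),
               "baseline")
  expect_error(actin_fold_increase(mv, data.frame(center_r = 5, center_c = 5)),
               "outside")
})

test_that("paired fold comparison and control-box sampling work together", {
  nr <- 160; nt <- 20
  arr <- array(20, c(nr, nr, nt))
  ramp <- c(rep(1, 5), seq(1, 2, length.out = nt - 5))
  centers <- list(c(30, 30), c(30, 100), c(100, 30))
  for (i in seq_along(centers)) {
    rr <- centers[[i]][1] + (-8:8); cc <- centers[[i]][2] + (-8:8)
    ramp_i <- c(rep(1, 5), seq(1, 1.6 + 0.3 * i, length.out = nt - 5))
    for (t in seq_len(nt))
      arr[rr, cc, t] <- 20 + 40 * ramp_i[t]
  }
  arr[140:155, 60:150, ] <- 70          # bare actin band for controls
  mv <- movie_stack(list(actin = arr), 3, 0.0653)
  patches <- data.frame(center_r = sapply(centers, `[`, 1),
                        center_c = sapply(centers, `[`, 2),
                        group = "patch")
  ctrl <- sample_control_boxes(mv, patches, exclusion_px = 40, seed = 2)
  expect_equal(nrow(ctrl), 3)
  expect_true(all(ctrl$center_r > 130))
  res <- actin_fold_increase(mv, rbind(patches, ctrl),
                             rolling_ball_radius = 30)
  cmp <- fold_increase_paired_test(res$summary)
  expect_gt(cmp$patch_mean, cmp$control_mean)
  expect_lt(cmp$p_value, 0.05)
})
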