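# Bundle thickness, kymographs, strain-site traces, repair statistics,
# SFSS segments, recovery rates and path categorization.

test_that("thickness index equals hand-computed erosion counts", {
  mk_stack <- function(widths, len = 50, nr = 40, nc = 70) {
    arr <- array(10, c(nr, nc, length(widths)))
    for (t in seq_along(widths)) {
      w <- widths[t]
      r0 <- (nr - w) %/% 2
      arr[r0 + seq_len(w), 10 + seq_len(len), t] <- 200
    }
    arr
  }
  # identical frames: index 0 everywhere
  expect_equal(bundle_thickness_index(mk_stack(c(5, 5, 5))), c(0, 0, 0))
  # 5x50 first frame (250 px) vs 9x50 (450): erosions 7x48=336, 5x46=230 -> 2
  expect_equal(bundle_thickness_index(mk_stack(c(5, 9))), c(0, 2))
  # frame smaller than frame 1: index 0
  expect_equal(bundle_thickness_index(mk_stack(c(9, 5))), c(0, 0))
  # monotone widening gives a non-decreasing index
  idx <- bundle_thickness_index(mk_stack(c(3, 5, 7, 9, 11)))
  expect_true(all(diff(idx) >= 0))
  expect_error(bundle_thickness_index(mk_stack(c(5, 5))[, , 1, drop = FALSE]),
               "2 frames")
})

test_that("kymographs sample lines with width averaging and track motion", {
  # static image: every column of the kymograph identical
  fr <- matrix(runif(40 * 40), 40, 40)
  st <- array(rep(fr, 5), c(40, 40, 5))
  ky <- make_kymograph(st, c(20, 5, 20, 35), width_px = 1)
  for (t in 2:5) expect_equal(ky$intensity[, t], ky$intensity[, 1])

  # width 2 averages the two adjacent rows (values 10 and 30 -> 20)
  fr2 <- matrix(0, 20, 20); fr2[10, ] <- 10; fr2[11, ] <- 30
  st2 <- array(fr2, c(20, 20, 1))
  ky2 <- make_kymograph(st2, c(10.5, 3, 10.5, 18), width_px = 2)
  expect_true(all(abs(ky2$intensity - 20) < 1e-9))

  # a band moving at v px/frame makes a ridge of slope v
  v <- 2; nt <- 8
  st3 <- array(0, c(30, 60, nt))
  for (t in seq_len(nt)) st3[15, 10 + v * (t - 1) + 0:2, t] <- 100
  ky3 <- make_kymograph(st3, c(15, 5, 15, 55), width_px = 1)
  ridge <- apply(ky3$intensity, 2, which.max)
  expect_equal(unname(diff(ridge)), rep(v, nt - 1))

  expect_error(make_kymograph(st3, c(5, 5, 5, 5)), "zero-length")
})

test_that("strain-site traces normalize actin and fold the partner channel", {
  nt <- 20
  ky_a <- structure(list(intensity = matrix(rep(seq(20, 100,
                                                    length.out = nt),
                                                each = 30), 30, nt),
                         line = c(1, 1, 1, 30), width_px = 3),
                    class = "Kymograph")
  ky_v <- structure(list(intensity = matrix(5, 30, nt),
                         line = c(1, 1, 1, 30), width_px = 3),
                    class = "Kymograph")
  tr <- strain_site_traces(ky_a, ablation_frame = 5, ky_v)
  expect_equal(tr$actin_norm[1], 0)
  expect_equal(tr$actin_norm[nt], 1)
  expect_true(all(tr$partner_fold == 1))       # constant partner: fold 1

  # planted partner doubling post-ablation
  kv2 <- ky_v
  kv2$intensity[, 11:nt] <- 10
  tr2 <- strain_site_traces(ky_a, ablation_frame = 10, kv2)
  expect_equal(tr2$partner_fold[nt], 2, tolerance = 1e-9)
  expect_error(strain_site_traces(ky_v, 5), "flat")
})

test_that("repair frequency builds the 2x2 table and Fisher p", {
  rec <- data.frame(condition = rep(c("wt", "mut"), each = 2),
                    outcome = c("repaired", "repaired",
                                "not_repaired", "not_repaired"))
  rf <- repair_frequency(rec)
  expect_equal(rf$p_value, 1 / 3, tolerance = 1e-9)
  # identical proportions: p = 1
  rec2 <- data.frame(condition = rep(c("a", "b"), each = 4),
                     outcome = rep(c("repaired", "not_repaired"), 4))
  expect_equal(repair_frequency(rec2)$p_value, 1)
  # row order invariance
  rec3 <- rec; rec3$condition <- factor(rec3$condition,
                                        levels = c("wt", "mut"))
  expect_equal(repair_frequency(rec3)$p_value, rf$p_value)
  expect_error(repair_frequency(data.frame(condition = "a",
                                           outcome = "repaired")), "2 conditions")
})

test_that("Fisher p matches hypergeometric enumeration on random tables", {
  set.seed(17)
  for (i in 1:25) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(stats::fisher.test(tab)$p.value, fisher_enum(tab),
                 tolerance = 1e-9, info = paste(tab, collapse = ","))
  }
})

test_that("SFSS segments follow the 10/80/10 split", {
  m <- matrix(seq_len(100 * 4), 100, 4)
  ky <- structure(list(intensity = m, line = NULL, width_px = 1),
                  class = "Kymograph")
  segs <- sfss_segments(ky)
  expect_equal(segs$left, colMeans(m[1:10, ]))
  expect_equal(segs$center, colMeans(m[11:90, ]))
  expect_equal(segs$right, colMeans(m[91:100, ]))
  # uniform kymograph: identical traces
  ku <- structure(list(intensity = matrix(7, 50, 4)), class = "Kymograph")
  su <- sfss_segments(ku)
  expect_equal(su$left, su$center)
  expect_equal(su$center, su$right)
  expect_error(sfss_segments(structure(list(intensity = matrix(1, 9, 4)),
                                       class = "Kymograph")), "span")
})

test_that("recovery rates are exact on lines; paired t matches closed form", {
  tt <- seq(0, 400, by = 4)
  segs <- list(left = 5 + 0.005 * tt, center = 5 + 0.01 * tt,
               right = 5 + 0.005 * tt)
  r <- recovery_rates(segs, frame_interval = 4)
  expect_equal(unname(r["center"]), 0.01, tolerance = 1e-12)
  expect_equal(unname(r["left"]), 0.005, tolerance = 1e-12)
  # constant trace: slope 0
  expect_equal(unname(recovery_rates(list(x = rep(3, 101)), 4)[1]), 0)
  expect_error(recovery_rates(segs, 4, fit_window = c(40, 44)), "3 points")

  # paired differences (1,2,3): t = mean/(sd/sqrt(n)) = 3.464, df = 2
  sr <- list(c(left = 1, center = 2, right = 1),
             c(left = 1, center = 3, right = 1),
             c(left = 2, center = 5, right = 2))
  pc <- paired_rate_comparison(sr)
  expect_equal(pc$center - pc$ends, c(1, 2, 3))
  expect_equal(pc$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(pc$df, 2)
})

test_that("path categorization reads planted onsets correctly", {
  mk_seg <- function(onsets, rates, nt = 60, abl = 5) {
    tt <- seq_len(nt)
    lapply(stats::setNames(seq_along(onsets), c("left", "center", "right")),
           function(i) pmax(0, pmin(100, rates[i] * (tt - onsets[i]))))
  }
  expect_equal(categorize_recovery_path(mk_seg(c(20, 8, 20), c(1, 2, 1)), 5),
               "center")
  expect_equal(categorize_recovery_path(mk_seg(c(8, 20, 8), c(1, 1, 1)), 5),
               "both_ends")
  expect_equal(categorize_recovery_path(mk_seg(c(8, 8, 8), c(1, 1, 1)), 5),
               "even")
  expect_equal(categorize_recovery_path(mk_seg(c(8, 8, 25), c(1, 1, 1)), 5),
               "one_end_center")
  # no recovery anywhere: uncategorized
  flat <- list(left = rep(1, 60), center = rep(1, 60), right = rep(1, 60))
  expect_equal(categorize_recovery_path(flat, 5), "uncategorized")
})

test_that("drift QC flags sites that wander", {
  still <- data.frame(frame = 1:10, row = 5 + 0.1 * (1:10), col = 3)
  expect_false(flag_drift(still))
  mobile <- data.frame(frame = 1:10, row = 5 + (1:10), col = 3)
  expect_true(flag_drift(mobile))
})

test_that("simulated strain sites round-trip through kymograph analysis", {
  sc <- test_scene(field = c(64, 256), n_frames = 120, seed = 9,
                   frame_interval = 3)
  site <- planted_strain_site(1, center = c(32, 128), ablation_frame = 10,
                              path = "center", rate_center = 0.3,
                              rate_end = 0.15, delay_s = 30, peak = 120,
                              partner_fold = 2)
  sim <- simulate_strain_site_movie(sc, site)
  gap_half <- sim$ground_truth$gap_px / 2
  line <- c(32, 128 - gap_half + 0.5, 32, 128 + gap_half - 0.5)
  ka <- make_kymograph(sim$movie$channels$actin, line, width_px = 3)
  kv <- make_kymograph(sim$movie$channels$partner, line, width_px = 3)
  tr <- strain_site_traces(ka, 10, kv)
  expect_equal(tr$partner_fold[115], 2, tolerance = 0.05)
  segs <- sfss_segments(ka)
  rates <- recovery_rates(segs, 3, fit_window = c(60, 240))
  expect_equal(unname(rates["center"] / mean(rates[c("left", "right")])), 2,
               tolerance = 0.1)
  expect_equal(categorize_recovery_path(segs, 10), "center")
})
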