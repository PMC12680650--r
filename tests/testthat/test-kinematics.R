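straight_track <- function(speed = 50, fps = 25, duration = 1) {
  n <- fps * duration + 1
  sperm_track(x = speed / fps * (seq_len(n) - 1), y = rep(0, n), fps = fps,
              track_id = "straight")
}

test_that("a straight constant-speed track has VCL = VSL = VAP = speed", {
  tr <- straight_track(50)
  expect_equal(vcl(tr), 50, tolerance = 1e-12)
  expect_equal(vsl(tr), 50, tolerance = 1e-12)
  expect_equal(vap(tr), 50, tolerance = 1e-12)
  expect_equal(straightness(tr), 100, tolerance = 1e-12)
})

test_that("a closed loop has VSL 0 and straightness 0 but positive VCL", {
  th <- seq(0, 2 * pi, length.out = 26)
  tr <- sperm_track(10 * cos(th), 10 * sin(th), fps = 25, track_id = "loop")
  expect_equal(vsl(tr), 0, tolerance = 1e-9)
  expect_gt(vcl(tr), 0)
  expect_equal(straightness(tr), 0, tolerance = 1e-9)
})

test_that("zigzag fixture matches the hand-summed arithmetic oracle", {
  # square wave (0,0) (1,1) (2,0) (3,1) (4,0) at 1 fps, 4 s duration
  tr <- sperm_track(0:4, c(0, 1, 0, 1, 0), fps = 1, track_id = "zig")
  expect_equal(vcl(tr), 4 * sqrt(2) / 4, tolerance = 1e-9)
  expect_equal(vsl(tr), 1, tolerance = 1e-9)
  # window-3 smoothed path, worked by hand:
  # ends keep their raw points; interior points average three neighbours:
  # (0,0) (1,1/3) (2,2/3) (3,1/3) (4,0); each of the 4 segments has length
  # sqrt(1 + 1/9), so VAP = 4*sqrt(10)/3 / 4
  expect_equal(vap(tr, window = 3), sqrt(10) / 3, tolerance = 1e-9)
  expect_equal(straightness(tr, window = 3), 100 / (sqrt(10) / 3),
               tolerance = 1e-9)
})

test_that("track constructor and velocity guards reject degenerate input", {
  expect_error(sperm_track(1, 1, fps = 25), ">= 2")
  expect_error(sperm_track(1:3, 1:3, fps = 0), "fps")
  expect_error(vap(straight_track(), window = 4), "odd")
})

test_that("classification applies the standard CASA thresholds", {
  fps <- 25
  # VAP ~35 um/s, straight: progressive
  fast <- straight_track(35)
  expect_equal(classify_track(fast), "progressive")
  # VAP ~8 um/s: immotile
  slow <- straight_track(8)
  expect_equal(classify_track(slow), "immotile")
  # VAP ~20, straightness ~50: motile but not progressive.
  # A triangle-return path: 20 um/s along a path that doubles back halfway.
  n <- 26
  xs <- c(seq(0, 10, length.out = 14), seq(10 - 10 / 12 / 2, 5.42, length.out = 12))
  # simpler: constant-speed path out 0.8 um/frame for 13 frames, then
  # heading rotated ~109 deg so VSL/VAP ~ 0.5
  step <- 0.8
  th2 <- 1.91  # radians
  x <- cumsum(c(0, rep(step, 12), rep(step * cos(th2), 13)))
  y <- cumsum(c(0, rep(0, 12), rep(step * sin(th2), 13)))
  tr <- sperm_track(x, y, fps = fps, track_id = "kink")
  v <- vap(tr)
  s <- straightness(tr)
  expect_gt(v, 10); expect_lt(s, 80)
  expect_equal(classify_track(tr), "motile")
})

test_that("per-track velocity inequalities hold on simulated populations", {
  tracks <- simulate_tracks(n = 120, seed = 301)
  for (tr in tracks) {
    v_c <- vcl(tr); v_s <- vsl(tr); v_a <- vap(tr)
    expect_lte(v_s, v_c + 1e-9)
    expect_lte(v_a, v_c + 1e-9)
    # VSL <= VAP holds up to a small end-effect tolerance
    expect_lte(v_s, v_a * 1.02 + 1e-9)
  }
})

test_that("velocities are nearly frame-rate invariant on a smooth path", {
  path <- function(fps) {
    t <- seq(0, 1, by = 1 / fps)
    sperm_track(30 * t, 5 * sin(2 * pi * t), fps = fps, track_id = fps)
  }
  t25 <- path(25); t50 <- path(50)
  expect_lt(abs(vsl(t50) / vsl(t25) - 1), 0.01)
  expect_lt(abs(vcl(t50) / vcl(t25) - 1), 0.01)
})

test_that("summaries count classes and average velocities over motile
           tracks", {
  tracks <- c(replicate(5, straight_track(50), simplify = FALSE),
              replicate(5, straight_track(2), simplify = FALSE))
  s <- summarize_tracks(tracks)
  expect_equal(s$TM, 50)
  expect_equal(s$PM, 50)
  expect_equal(s$VCL, 50)
  expect_equal(s$VAP, 50)
  expect_equal(s$n_tracks, 10)
  all50 <- replicate(10, straight_track(50), simplify = FALSE)
  s2 <- summarize_tracks(all50)
  expect_equal(c(s2$TM, s2$PM, s2$VCL, s2$VSL, s2$VAP),
               c(100, 100, 50, 50, 50))
  expect_error(summarize_tracks(list()), "empty")
})

test_that("the simulator is seeded, label-faithful and validates mixtures", {
  t1 <- simulate_tracks(n = 30, seed = 7)
  t2 <- simulate_tracks(n = 30, seed = 7)
  expect_identical(t1[[9]]$positions, t2[[9]]$positions)
  expect_error(simulate_tracks(n = 10, mixture = c(immotile = 0.5,
                                                   motile = 0.2,
                                                   progressive = 0.2)),
               "sum to 1")
  # all-immotile population is classified as such
  imm <- simulate_tracks(n = 100,
                         mixture = c(immotile = 1, motile = 0,
                                     progressive = 0), seed = 11)
  cls <- vapply(imm, classify_track, "")
  expect_true(all(cls == "immotile"))
  # noiseless fast swimmers are all progressive with straightness ~100
  prog <- simulate_tracks(n = 50,
                          mixture = c(immotile = 0, motile = 0,
                                      progressive = 1),
                          class_params = list(progressive =
                            list(speed_mean = 40, speed_sd = 0,
                                 turn_sd = 0)),
                          seed = 12)
  expect_true(all(vapply(prog, classify_track, "") == "progressive"))
  expect_true(all(vapply(prog, straightness, 0) > 99.9))
})

test_that("classifier recovers well-separated generative classes at >= 95%", {
  tracks <- simulate_tracks(n = 1000, seed = 2025)
  truth <- attr(tracks, "classes")
  pred <- vapply(tracks, classify_track, "")
  expect_gte(mean(pred == truth), 0.95)
})

test_that("estimated TM tracks the generative motile fraction", {
  tracks <- simulate_tracks(n = 1000,
                            mixture = c(immotile = 0.15, motile = 0.25,
                                        progressive = 0.60),
                            seed = 404)
  s <- summarize_tracks(tracks)
  expect_lt(abs(s$TM - 85), 3)
})
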