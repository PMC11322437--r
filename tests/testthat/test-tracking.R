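test_that("motile truth trajectories step by speed times interval", {
  cfg <- motilityConfig(n_particles = 6, motile_fraction = 0.5,
                        speed_um_per_s = 2, frames = 10,
                        frame_interval_s = 1 / 3, seed = 4,
                        min_separation_px = 25)
  ms <- renderMitoSequence(cfg)
  expect_length(ms$truth@trajectories, 6)
  # the first half are the motile particles
  for (i in 1:3) {
    steps <- sqrt(rowSums(diff(ms$truth@trajectories[[i]])^2)) * 0.16
    expect_equal(steps, rep(2 / 3, 9), tolerance = 1e-9)
  }
})

test_that("stationary truth trajectories jitter at most half a pixel per frame", {
  cfg <- motilityConfig(n_particles = 8, motile_fraction = 0,
                        frames = 15, seed = 6)
  ms <- renderMitoSequence(cfg)
  for (tr in ms$truth@trajectories) {
    steps <- sqrt(rowSums(diff(tr)^2))
    expect_lte(max(steps), 0.5)
  }
})

test_that("a minimal sequence yields one trajectory of length two", {
  cfg <- motilityConfig(n_particles = 1, motile_fraction = 1, frames = 2,
                        seed = 1)
  ms <- renderMitoSequence(cfg)
  expect_length(ms$truth@trajectories, 1)
  expect_identical(nrow(ms$truth@trajectories[[1]]), 2L)
  expect_length(stackFrames(ms$stack), 2)
})

test_that("displacements beyond half the particle spacing are refused", {
  cfg <- motilityConfig(n_particles = 2, motile_fraction = 1,
                        speed_um_per_s = 60, frames = 2,
                        height_px = 80, width_px = 80, seed = 2)
  expect_error(renderMitoSequence(cfg), "ambiguous")
})

test_that("stationary particles track at jitter-level speeds", {
  cfg <- motilityConfig(n_particles = 8, motile_fraction = 0, frames = 20,
                        seed = 9, gaussian_noise_sd = 0, poisson_scale = 0)
  ms <- renderMitoSequence(cfg)
  ts <- trackParticles(ms$stack, max_link_um = 0.8, min_track_frames = 15)
  expect_gte(nrow(ts@tracks), 6)
  jitter_bound <- 0.5 * 0.16 / (1 / 3)   # 0.5 px per frame interval
  expect_true(all(ts@tracks$speed_um_per_s <= jitter_bound))
})

test_that("planted translocation speeds are recovered within 10%", {
  cfg <- motilityConfig(n_particles = 10, motile_fraction = 0.3,
                        speed_um_per_s = 2, frames = 25, seed = 14,
                        min_separation_px = 22)
  ms <- renderMitoSequence(cfg)
  ts <- trackParticles(ms$stack, max_link_um = 1.2, min_track_frames = 15)
  motile <- ts@tracks$speed_um_per_s > 1
  expect_gte(sum(motile), 2)
  expect_lt(abs(mean(ts@tracks$speed_um_per_s[motile]) - 2) / 2, 0.10)
})

test_that("speed recovery holds across the physiological range", {
  # planted speeds spanning slow to fast axonal transport, 3 fps
  errs <- c()
  for (speed in c(0.8, 1.5, 2, 2.7)) {
    for (s in 1:3) {
      cfg <- motilityConfig(n_particles = 8, motile_fraction = 0.25,
                            speed_um_per_s = speed, frames = 20,
                            seed = 100 * speed + s,
                            min_separation_px = 25)
      ms <- renderMitoSequence(cfg)
      ts <- trackParticles(ms$stack, max_link_um = speed / 3 + 0.4,
                          min_track_frames = 12)
      motile <- ts@tracks$speed_um_per_s > speed / 2
      if (sum(motile)) {
        errs <- c(errs, abs(mean(ts@tracks$speed_um_per_s[motile]) - speed) /
                    speed)
      }
    }
  }
  expect_gte(length(errs), 8)
  expect_lte(mean(errs), 0.10)
})

test_that("particles crossing farther apart than the link radius keep identity", {
  # particle A moves right along row 30, particle B down along column 60;
  # their paths cross in space but they are never within the link radius
  # at the same frame
  ps <- 0.16
  mk <- function(posA, posB) {
    img <- matrix(0, 100, 100)
    img <- rvquant:::stampDisk(img, posA[1], posA[2], 3, 7)
    img <- rvquant:::stampDisk(img, posB[1], posB[2], 3, 7)
    1 + img
  }
  frames <- lapply(0:9, function(f) {
    mk(c(30, 20 + 4 * f), c(20 + 4 * (9 - f), 60))
  })
  stack <- new("ImageStack", frames = frames, frame_interval_s = 1 / 3,
               pixel_size_um = ps)
  ts <- trackParticles(stack, max_link_um = 4.5 * ps, min_track_frames = 8)
  expect_identical(nrow(ts@tracks), 2L)
  expect_true(all(ts@tracks$n_frames == 10))
})
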