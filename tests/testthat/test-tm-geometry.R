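first_frame <- function(traj) traj[traj$frame == min(traj$frame), ]
axes_of <- function(fb) {
  list(a = fit_helix_axis(fb[fb$helix == "A", ]),
       b = fit_helix_axis(fb[fb$helix == "B", ]))
}

test_that("the constructed membrane system has the programmed geometry", {
  sys <- build_tm_system(separation = 50, box = c(100, 100, 100))
  ax <- axes_of(first_frame(sys))
  expect_equal(interhelical_distance(ax$a, ax$b), 50)
  expect_equal(abs(ax$a$direction[3]), 1, tolerance = 1e-5)
  expect_equal(abs(ax$b$direction[3]), 1, tolerance = 1e-5)
  expect_equal(crossing_angle(ax$a, ax$b), 0)

  sys0 <- build_tm_system(separation = 0)
  ax0 <- axes_of(first_frame(sys0))
  expect_equal(interhelical_distance(ax0$a, ax0$b), 0)
  expect_error(build_tm_system(separation = 120, box = c(100, 100, 100)),
               class = "helixswitch_geometry_error")
})

test_that("axis fitting is rotation-equivariant and robust to bead noise", {
  fb <- first_frame(build_tm_system())
  a <- fb[fb$helix == "A", ]
  ax0 <- fit_helix_axis(a)
  R <- helixswitch:::rotation_about_axis(c(1, 2, 3), 37)
  a2 <- transform_ensemble(a, R)   # works on any xyz tibble
  ax1 <- fit_helix_axis(a2)
  expect_equal(ax1$direction, as.numeric(R %*% ax0$direction), tolerance = 1e-6)

  errs <- vapply(1:30, function(s) {
    set.seed(s)
    an <- a
    an$x <- an$x + rnorm(nrow(an)); an$y <- an$y + rnorm(nrow(an))
    an$z <- an$z + rnorm(nrow(an))
    axn <- fit_helix_axis(an)
    acos(min(abs(sum(axn$direction * c(0, 0, 1))), 1)) * 180 / pi
  }, numeric(1))
  expect_lt(mean(errs), 3)

  expect_error(fit_helix_axis(a[a$resno < 281, ]),
               class = "helixswitch_insufficient_data")
})

test_that("interhelical distance lives in the membrane plane", {
  fb <- first_frame(build_tm_system())
  ax <- axes_of(fb)
  # displacement purely along the membrane normal is invisible
  b_up <- fb[fb$helix == "B", ]
  b_up$z <- b_up$z + 30
  b_up$x <- b_up$x - 50
  ax_up <- fit_helix_axis(b_up)
  expect_equal(interhelical_distance(ax$a, ax_up), 0, tolerance = 1e-9)
})

test_that("crossing angle is signed, symmetric, and flips under reflection", {
  # explicit construction: tilt each helix by half the target about the
  # closest-approach line (x), second helix as the C2 image of the first
  sim <- simulate_rigid_dimerization(n_frames = 12, encounter_frame = 1,
                                     target_angle = -27, seed = 4)
  fb <- first_frame(sim$trajectory)
  ax <- axes_of(fb)
  expect_equal(crossing_angle(ax$a, ax$b), -27, tolerance = 0.5)
  expect_equal(crossing_angle(ax$b, ax$a), crossing_angle(ax$a, ax$b),
               tolerance = 1e-9)

  mfb <- first_frame(reflect_trajectory(sim$trajectory))
  axm <- axes_of(mfb)
  expect_equal(crossing_angle(axm$a, axm$b), 27, tolerance = 0.5)

  # parallel axes give exactly zero
  ax0 <- axes_of(first_frame(build_tm_system()))
  expect_identical(crossing_angle(ax0$a, ax0$b), 0)
})

test_that("geometric outputs are invariant under in-plane rigid motion", {
  sim <- simulate_rigid_dimerization(n_frames = 12, encounter_frame = 1,
                                     target_angle = -35, seed = 6)
  fb <- first_frame(sim$trajectory)
  ax <- axes_of(fb)
  Rz <- helixswitch:::rotation_about_axis(c(0, 0, 1), 77)
  fb2 <- transform_ensemble(fb, Rz, c(14, -8, 3))
  ax2 <- axes_of(fb2)
  expect_equal(interhelical_distance(ax2$a, ax2$b),
               interhelical_distance(ax$a, ax$b), tolerance = 1e-9)
  expect_equal(crossing_angle(ax2$a, ax2$b), crossing_angle(ax$a, ax$b),
               tolerance = 1e-9)
})

test_that("trajectory tables round trip through the whitespace format", {
  sim <- simulate_rigid_dimerization(n_frames = 5, encounter_frame = 2,
                                     target_angle = -27, seed = 1)
  path <- withr::local_tempfile(fileext = ".dat")
  write_cg_table(sim$trajectory, path)
  back <- read_cg_table(path, dt = 4)
  expect_equal(nrow(back), nrow(sim$trajectory))
  expect_lt(max(abs(back$x - sim$trajectory$x)), 1e-3)
  expect_equal(back$helix, sim$trajectory$helix)
  expect_equal(back$role, sim$trajectory$role)
})
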