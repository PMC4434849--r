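test_that("encounter and dimer intervals follow the programmed schedule", {
  sim <- simulate_rigid_dimerization(n_frames = 150, encounter_frame = 120,
                                     target_angle = -27, seed = 21)
  tl <- detect_encounter_and_dimers(sim$trajectory)
  expect_lte(abs(tl$encounter_frame - 120), 1)
  expect_equal(nrow(tl$intervals), 1L)
  expect_lte(abs(tl$intervals$start - 120), 1)
  expect_equal(tl$intervals$end, 150L)
  expect_true(all(is.na(tl$frames$angle[!tl$frames$in_dimer])))
  expect_true(all(!is.na(tl$frames$angle[tl$frames$in_dimer])))
  # encounter precedes or starts the first interval
  expect_lte(tl$encounter_frame, tl$intervals$start[1])

  g <- glance(tl)
  expect_equal(g$encounter_frame, tl$encounter_frame)
  expect_equal(g$median_angle, -27, tolerance = 0.5)
  expect_equal(nrow(tidy(tl)), 150L)
})

test_that("a purely monomeric trajectory yields no encounter and no intervals", {
  sim <- simulate_rigid_dimerization(n_frames = 60, encounter_frame = NULL,
                                     seed = 3)
  tl <- detect_encounter_and_dimers(sim$trajectory)
  expect_true(is.na(tl$encounter_frame))
  expect_equal(nrow(tl$intervals), 0L)
  expect_true(all(is.na(tl$frames$angle)))
  s <- angle_distribution_summary(tl)
  expect_true(s$empty)
  expect_equal(s$n_modes, 0L)
})

test_that("angle summaries report medians and modes as constructed", {
  s <- angle_distribution_summary(rep(-27, 50))
  expect_equal(s$median, -27)
  expect_equal(s$n_modes, 1L)

  set.seed(10)
  s2 <- angle_distribution_summary(rnorm(1000, -27, 5))
  expect_equal(s2$median, -27, tolerance = 0.6)
  expect_equal(s2$n_modes, 1L)

  set.seed(11)
  bim <- c(rnorm(400, -40, 2.5), rnorm(400, -10, 2.5))
  expect_equal(angle_distribution_summary(bim)$n_modes, 2L)
})

test_that("motif contact profiles are symmetric for the C2-docked dimer", {
  sim <- simulate_rigid_dimerization(n_frames = 15, encounter_frame = 1,
                                     target_angle = -27, seed = 2)
  prof <- motif_contact_profile(sim$trajectory)
  expect_equal(nrow(prof), 15 * 2 * 5)
  or <- classify_orientation(prof)
  expect_equal(unique(or$orientation), "symmetric")
  # infinite tolerance classifies everything symmetric
  or_inf <- classify_orientation(prof, tolerance = Inf)
  expect_equal(unique(or_inf$orientation), "symmetric")
  # missing motif beads raise a structure error
  broken <- sim$trajectory[!(sim$trajectory$resno == 284 &
                               sim$trajectory$role == "sidechain" &
                               sim$trajectory$helix == "B"), ]
  attr(broken, "dt") <- 4
  class(broken) <- class(sim$trajectory)
  expect_error(motif_contact_profile(broken), class = "helixswitch_structure_error")
})

test_that("axial rotation episodes flip the orientation class on cue", {
  sim <- simulate_rigid_dimerization(
    n_frames = 60, encounter_frame = 5, target_angle = -27,
    rotation_schedule = tibble::tibble(start = 25, end = 40, angle = 100),
    seed = 8)
  prof <- motif_contact_profile(sim$trajectory)
  or <- classify_orientation(prof[prof$frame >= 5, ])
  expect_equal(unique(or$orientation[or$frame %in% 10:24]), "symmetric")
  expect_equal(unique(or$orientation[or$frame %in% 25:40]), "asymmetric")
  expect_equal(unique(or$orientation[or$frame %in% 41:60]), "symmetric")
  # the ground-truth sidecar agrees
  truth <- sim$truth[sim$truth$frame >= 5, ]
  expect_equal(or$orientation, truth$orientation[match(or$frame, truth$frame)])
})

test_that("the closest dimer contact localises to the five-valine motif", {
  sim <- simulate_rigid_dimerization(n_frames = 40, encounter_frame = 5,
                                     target_angle = -27, seed = 12)
  tl <- detect_encounter_and_dimers(sim$trajectory)
  res <- residue_run_interface_check(sim$trajectory, tl)
  expect_true(res$defined)
  expect_equal(res$fraction, 1)

  # a construction touching only at the helix termini scores zero
  sys <- build_tm_system(separation = 9)
  fb <- sys[sys$frame == 1, ]
  fb$z[fb$helix == "B"] <- fb$z[fb$helix == "B"] + 30
  traj <- repeat_frames(fb[, c("helix", "resno", "role", "x", "y", "z")], 12)
  tl2 <- detect_encounter_and_dimers(traj)
  expect_gt(nrow(tl2$intervals), 0)
  res2 <- residue_run_interface_check(traj, tl2)
  expect_equal(res2$fraction, 0)

  # no dimer frames -> undefined and flagged
  mono <- simulate_rigid_dimerization(n_frames = 15, encounter_frame = NULL,
                                      seed = 1)
  tl3 <- detect_encounter_and_dimers(mono$trajectory)
  res3 <- residue_run_interface_check(mono$trajectory, tl3)
  expect_false(res3$defined)
  expect_true(is.na(res3$fraction))
})
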