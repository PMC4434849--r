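grid <- seq(190, 270, by = 0.5)

test_that("blank subtraction is pointwise and keeps sample metadata", {
  s <- cd_spectrum(grid, rep(2, length(grid)), conc_mM = 0.05, n_residues = 26,
                   path_cm = 0.1, tfe_percent = 70)
  b <- cd_spectrum(grid, rep(1, length(grid)), tfe_percent = 70)
  d <- subtract_blank(s, b)
  expect_equal(d$signal, rep(1, length(grid)))
  expect_equal(attr(d, "sample")$conc_mM, 0.05)
  expect_equal(subtract_blank(s, s)$signal, rep(0, length(grid)))

  g <- generate_cd_spectrum(0.5, noise_mdeg = 0)
  rec <- subtract_blank(g$sample, g$blank)
  expect_lt(max(abs(rec$signal - g$truth$peptide_mdeg)), 1e-9)

  b2 <- cd_spectrum(grid + 1, rep(1, length(grid)))
  expect_error(subtract_blank(s, b2), class = "helixswitch_grid_error")
  b3 <- cd_spectrum(grid, rep(1, length(grid)), tfe_percent = 0)
  expect_error(subtract_blank(s, b3), class = "helixswitch_metadata_error")
})

test_that("scan averaging is the pointwise mean", {
  s0 <- cd_spectrum(grid, rep(0, length(grid)))
  s2 <- cd_spectrum(grid, rep(2, length(grid)))
  expect_equal(average_scans(list(s0, s2))$signal, rep(1, length(grid)))
  expect_equal(average_scans(list(s2, s2, s2))$signal, s2$signal)
  expect_error(average_scans(list()), class = "helixswitch_input_error")

  # three noisy replicates: averaging shrinks the error ~ 1/sqrt(3)
  sigma <- 0.5
  set.seed(3)
  scans <- lapply(1:3, function(i)
    cd_spectrum(grid, 5 + rnorm(length(grid), 0, sigma)))
  avg <- average_scans(scans)
  expect_lt(max(abs(avg$signal - 5)), 3 * sigma / sqrt(3) * 1.6)
})

test_that("mean residue ellipticity applies the standard normalisation", {
  z <- cd_spectrum(grid, rep(0, length(grid)), conc_mM = 0.05, n_residues = 26,
                   path_cm = 0.1)
  expect_equal(to_mean_residue_ellipticity(z)$signal, rep(0, length(grid)))

  raw3 <- cd_spectrum(c(221, 222, 223), c(0, -6.18, 0), conc_mM = 0.05,
                      n_residues = 26, path_cm = 0.1)
  mre <- to_mean_residue_ellipticity(raw3)
  expect_equal(mre$signal[2], -6.18 / (10 * (0.05 / 1000) * 26 * 0.1))
  expect_equal(mre$signal[2], -4753.846, tolerance = 1e-6)

  # doubling the concentration halves the MRE
  raw_2x <- cd_spectrum(c(221, 222, 223), c(0, -6.18, 0), conc_mM = 0.10,
                        n_residues = 26, path_cm = 0.1)
  expect_equal(to_mean_residue_ellipticity(raw_2x)$signal,
               mre$signal / 2)

  miss <- cd_spectrum(c(221, 222, 223), c(0, -6.18, 0))
  expect_error(to_mean_residue_ellipticity(miss), class = "helixswitch_metadata_error")
})

test_that("fractional helicity is the two-state estimator with clamping", {
  expect_equal(fractional_helicity(-42500)$f_helix, 1)
  expect_equal(fractional_helicity(640)$f_helix, 0)
  expect_equal(fractional_helicity(-11870.6)$f_helix, 0.29, tolerance = 1e-6)

  expect_warning(out <- fractional_helicity(-50000))
  expect_equal(out$f_helix, 1)
  expect_true(out$clamped)
  expect_gt(out$f_helix_raw, 1)

  bad <- helicity_reference()
  bad$theta_helix <- bad$theta_coil
  expect_error(fractional_helicity(-10000, bad),
               class = "helixswitch_degenerate_reference")
  expect_error(helicity_reference(theta_coil = -1, theta_helix = 640),
               class = "helixswitch_degenerate_reference")

  # affine and monotone decreasing in theta_obs
  f <- function(x) fractional_helicity(x)$f_helix_raw
  xs <- seq(-40000, 0, length.out = 9)
  slopes <- diff(vapply(xs, f, numeric(1))) / diff(xs)
  expect_true(all(slopes < 0))
  expect_lt(diff(range(slopes)), 1e-12)
})

test_that("two-state round trip recovers the generator helicity to 1e-9", {
  for (f in c(0, 0.25, 0.29, 0.39, 1)) {
    g <- generate_cd_spectrum(f, noise_mdeg = 0)
    mre <- to_mean_residue_ellipticity(subtract_blank(g$sample, g$blank))
    expect_equal(fractional_helicity(mre)$f_helix, f, tolerance = 1e-9)
  }
})

test_that("MRE conversion commutes with the linear preprocessing steps", {
  g1 <- generate_cd_spectrum(0.3, noise_mdeg = 0.2, seed = 1)
  g2 <- generate_cd_spectrum(0.3, noise_mdeg = 0.2, seed = 2)
  a <- to_mean_residue_ellipticity(average_scans(list(
    subtract_blank(g1$sample, g1$blank), subtract_blank(g2$sample, g2$blank))))
  b <- average_scans(list(
    to_mean_residue_ellipticity(subtract_blank(g1$sample, g1$blank)),
    to_mean_residue_ellipticity(subtract_blank(g2$sample, g2$blank))))
  expect_equal(a$signal, b$signal, tolerance = 1e-12)
})

test_that("minima reporting matches the basis construction", {
  coil <- generate_cd_spectrum(0, noise_mdeg = 0)
  m0 <- to_mean_residue_ellipticity(subtract_blank(coil$sample, coil$blank))
  min0 <- report_minima(m0)
  expect_equal(nrow(min0), 1L)
  expect_equal(min0$wavelength_nm, 198)

  helix <- generate_cd_spectrum(1, noise_mdeg = 0)
  m1 <- to_mean_residue_ellipticity(subtract_blank(helix$sample, helix$blank))
  min1 <- report_minima(m1)
  expect_setequal(min1$wavelength_nm, c(208, 222))
  expect_equal(min1$wavelength_nm[1], 222)  # deepest first
  expect_equal(min1$depth[1], -42500, tolerance = 1e-6)

  mono <- cd_spectrum(grid, seq_along(grid), units = "mre")
  expect_equal(nrow(report_minima(mono)), 0L)
  expect_error(report_minima(m1, window_nm = 0.1), class = "helixswitch_input_error")
})

test_that("CD CSV round trips", {
  g <- generate_cd_spectrum(0.29, noise_mdeg = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cd_csv(g$sample, path)
  back <- read_cd_csv(path, conc_mM = 0.05, n_residues = 26, path_cm = 0.1,
                      tfe_percent = 70)
  expect_equal(back$signal, g$sample$signal, tolerance = 1e-9)
  expect_equal(back$wavelength_nm, g$sample$wavelength_nm)
})
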