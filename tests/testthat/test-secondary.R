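test_that("the ideal builder echoes its dihedral plan", {
  plan <- dplyr::bind_rows(alpha_span(303, 310), three10_span(316, 318))
  m <- build_ideal_peptide(trop2_ic(), plan)
  d <- backbone_dihedrals(m)
  expect_lt(max(abs(d$phi[d$resno %in% 303:310] - (-57))), 0.5)
  expect_lt(max(abs(d$psi[d$resno %in% 303:310] - (-47))), 0.5)
  expect_lt(max(abs(d$phi[d$resno %in% 316:318] - (-49))), 0.5)
  coil <- d$resno %in% c(299:302, 311:315, 319:322)
  expect_lt(max(abs(d$phi[coil] - (-120))), 0.5)
  dd <- abs(d$omega[!is.na(d$omega)] - 180) %% 360
  expect_lt(max(pmin(dd, 360 - dd)), 0.5)
})

test_that("the dihedral-window assigner labels built helices and coil correctly", {
  m <- ic_model(span = alpha_span(305, 314))
  ss <- assign_secondary_structure(m)
  expect_equal(ss$ss[ss$resno %in% 305:314], rep("H", 10))
  expect_equal(unique(ss$ss[!ss$resno %in% 305:314]), "C")

  ext <- build_ideal_peptide(peptide_seq("KELGELRK"))  # all (-120, 120)
  expect_equal(unique(assign_secondary_structure(ext)$ss), "C")

  g3 <- build_ideal_peptide(peptide_seq("AAAAAAAAA"), three10_span(4, 6))
  ss3 <- assign_secondary_structure(g3)
  expect_equal(ss3$ss[4:6], rep("G", 3))
  expect_equal(unique(ss3$ss[-(4:6)]), "C")

  # alpha spans of every length >= 4 label exactly the span
  for (len in 4:8) {
    span <- alpha_span(305, 304 + len)
    ssn <- assign_secondary_structure(ic_model(span = span))
    expect_equal(ssn$resno[ssn$ss == "H"], 305:(304 + len))
  }
  # a 3-residue alpha window run is too short for H
  ss_short <- assign_secondary_structure(ic_model(span = alpha_span(305, 307)))
  expect_false(any(ss_short$ss == "H"))
})

test_that("omega classification windows are honoured", {
  expect_equal(omega_classify(two_residue_omega(180), 1)$conformation, "trans")
  expect_equal(omega_classify(two_residue_omega(-165), 1)$conformation, "trans")
  expect_equal(omega_classify(two_residue_omega(0), 1)$conformation, "cis")
  expect_equal(omega_classify(two_residue_omega(20), 1)$conformation, "cis")
  expect_equal(omega_classify(two_residue_omega(90), 1)$conformation, "twisted")
  expect_equal(omega_classify(two_residue_omega(-100), 1)$conformation, "twisted")
  # every peptide bond of the ideal builder is trans
  om <- omega_classify(ic_model())
  expect_equal(unique(om$conformation), "trans")
  expect_error(omega_classify(two_residue_omega(180), 2),
               class = "helixswitch_structure_error")
})

test_that("Ramachandran classification hits the canonical basins", {
  expect_equal(ramachandran_classify(-60, -45), "most_favored")
  expect_equal(ramachandran_classify(-120, 130), "most_favored")
  expect_equal(ramachandran_classify(60, -60), "disallowed")
  # the glycine map admits the mirrored basin that the general map forbids
  expect_equal(ramachandran_classify(140, 30, residue = "GLY"), "most_favored")
  expect_equal(ramachandran_classify(140, 30), "disallowed")
  expect_error(ramachandran_classify(NaN, 0), class = "helixswitch_input_error")

  # nesting: a 10-degree step away from any favored/additional point can
  # degrade at most to "generous" (the generous band is a 20-degree dilation)
  set.seed(1)
  phis <- runif(300, -179, 179); psis <- runif(300, -179, 179)
  cls <- ramachandran_classify(phis, psis)
  inner <- which(cls %in% c("most_favored", "additional"))
  for (i in inner) {
    for (dphi in c(-10, 0, 10)) for (dpsi in c(-10, 0, 10)) {
      p <- ((phis[i] + dphi + 180) %% 360) - 180
      q <- ((psis[i] + dpsi + 180) %% 360) - 180
      expect_false(ramachandran_classify(p, q) == "disallowed")
    }
  }
})

test_that("Ramachandran percentages sum to 100 over an ensemble", {
  e <- jitter_ensemble(ic_model(), 6, noise_sigma = 0.4, seed = 8)
  s <- ramachandran_summary(e)
  expect_equal(sum(s$percent), 100)
  # 26 residues; the acetyl cap supplies phi for 298, the free C-terminus
  # leaves 323 without psi -> 25 classifiable residues per model
  expect_equal(sum(s$count), 25 * 6)
  s2 <- ramachandran_summary(e, resno_range = c(305, 314))
  expect_equal(sum(s2$percent), 100)
  expect_equal(sum(s2$count), 10 * 6)
})
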