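test_that("NOE restraints are classified by residue separation", {
  one <- function(i, j) tibble::tibble(res_i = i, atom_i = "HA",
                                       res_j = j, atom_j = "HB", upper = 5)
  expect_equal(classify_noe_restraints(restraint_list(one(310, 310)))$intra, 1L)
  cls <- classify_noe_restraints(restraint_list(one(305, 308)))
  expect_equal(cls$medium, 1L)
  # |i-j| = 5 goes to long-range (standard convention)
  expect_equal(classify_noe_restraints(restraint_list(one(305, 310)))$long, 1L)
  expect_equal(classify_noe_restraints(restraint_list(one(305, 306)))$sequential, 1L)
})

test_that("quota generation reproduces the published restraint census", {
  m <- ic_model()
  rl <- generate_restraints(m, cutoff = 6,
                            quotas = c(intra = 89, sequential = 36,
                                       medium = 14, long = 0),
                            slack = 0.5, seed = 7)
  cls <- classify_noe_restraints(rl)
  expect_equal(cls$intra, 89L)
  expect_equal(cls$sequential, 36L)
  expect_equal(cls$medium, 14L)
  expect_equal(cls$long, 0L)
  expect_equal(cls$total, 139L)
  expect_error(generate_restraints(m, cutoff = 6, quotas = c(long = 500)),
               class = "helixswitch_quota_error")
  expect_equal(nrow(generate_restraints(m, cutoff = 0)$distance), 0L)
})

test_that("the class partition is exhaustive and disjoint on random lists", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    d <- tibble::tibble(res_i = sample(1:30, n, replace = TRUE), atom_i = "HA",
                        res_j = sample(1:30, n, replace = TRUE), atom_j = "HN",
                        upper = runif(n, 2, 6))
    cls <- classify_noe_restraints(restraint_list(d))
    expect_identical(cls$intra + cls$sequential + cls$medium + cls$long,
                     cls$total)
    expect_identical(cls$total, n)
  }
})

test_that("violation checks honour tolerance boundaries", {
  # two atoms exactly 5.0 A apart (plus a third residue for a valid roster)
  m <- structure_ensemble(tibble::tibble(
    model = 1L, resno = c(1L, 1L, 1L, 2L, 2L, 2L),
    resname = "ALA", atom = rep(c("N", "CA", "C"), 2),
    element = rep(c("N", "C", "C"), 2),
    x = c(0, 1.5, 2, 0, 1.5, 2), y = c(0, 0, 1.4, 5, 5, 6.4),
    z = 0))
  dist_1 <- sqrt(sum((c(0, 0, 0) - c(0, 5, 0))^2))  # N(1)-N(2) = 5
  rl <- restraint_list(tibble::tibble(res_i = 1L, atom_i = "N", res_j = 2L,
                                      atom_j = "N", upper = 5.0))
  v <- check_violations(m, rl, dist_tol = 0.2)
  expect_equal(v$n_distance_viol, 0L)  # boundary inclusive

  rl2 <- restraint_list(tibble::tibble(res_i = 1L, atom_i = "N", res_j = 2L,
                                       atom_j = "N", upper = dist_1 - 0.3))
  v2 <- check_violations(m, rl2, dist_tol = 0.2)
  expect_equal(v2$n_distance_viol, 1L)
  expect_equal(v2$max_distance_viol, 0.3, tolerance = 1e-9)

  # unresolvable atoms are skipped with a warning and counted
  rl3 <- restraint_list(tibble::tibble(res_i = 1L, atom_i = "HZ9", res_j = 2L,
                                       atom_j = "N", upper = 5))
  expect_warning(v3 <- check_violations(m, rl3))
  expect_equal(v3$n_skipped, 1L)
  expect_equal(v3$n_distance_viol, 0L)
})

test_that("self-generated restraints are satisfied by their source model", {
  m <- ic_model()
  rl <- generate_restraints(m, cutoff = 6, slack = 0.5, torsion_width = 20,
                            seed = 1)
  e <- jitter_ensemble(m, 3, noise_sigma = 0, seed = 1)
  v <- check_violations(e, rl)
  expect_equal(sum(v$n_distance_viol), 0L)
  expect_equal(sum(v$n_torsion_viol), 0L)
  expect_equal(sum(v$n_skipped), 0L)
})

test_that("torsion bounds are compared circularly across the 180 wrap", {
  m <- build_ideal_peptide(peptide_seq("AAA"))
  d <- backbone_dihedrals(m)
  # omega-like range straddling the wrap: [170, -170] contains 180 = psi? use
  # synthetic bounds around the actual coil psi of 120
  rl <- restraint_list(torsion = tibble::tibble(resno = 2L, angle = "PSI",
                                                lower = 115, upper = 125))
  expect_equal(check_violations(m, rl)$n_torsion_viol, 0L)
  rl2 <- restraint_list(torsion = tibble::tibble(resno = 2L, angle = "PSI",
                                                 lower = 170, upper = -170))
  v2 <- check_violations(m, rl2, torsion_tol = 5)
  expect_equal(v2$n_torsion_viol, 1L)   # 120 is far from the wrap window
  # a window that wraps and includes 120: [100, -100]
  rl3 <- restraint_list(torsion = tibble::tibble(resno = 2L, angle = "PSI",
                                                 lower = 100, upper = -100))
  expect_equal(check_violations(m, rl3)$n_torsion_viol, 0L)
})

test_that("chemical shift perturbations follow the combined-shift formula", {
  a <- peak_table(298:300, c(8.10, 8.20, 8.00), c(118, 120, 122))
  same <- chemical_shift_perturbation(a, a)
  expect_equal(same$delta_delta, rep(0, 3))

  b <- peak_table(298:300, c(8.20, 8.23, 8.00), c(118, 120.5, 121))
  csp <- chemical_shift_perturbation(a, b)
  expect_equal(csp$delta_delta[1], 0.1, tolerance = 1e-12)
  expect_equal(csp$delta_delta[2], sqrt(0.03^2 + (0.14 * 0.5)^2),
               tolerance = 1e-9)
  expect_equal(csp$delta_delta[3], 0.14, tolerance = 1e-9)

  # unmatched residues are reported missing, not dropped
  c2 <- peak_table(299:301, c(8.2, 8.0, 8.1), c(120, 122, 119))
  out <- chemical_shift_perturbation(a, c2)
  expect_equal(out$residue, 298:301)
  expect_equal(out$missing, c(TRUE, FALSE, FALSE, TRUE))
})
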