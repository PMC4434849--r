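# Shared fixtures, built in code so every test starts from known ground truth.

ic_model <- function(phospho = FALSE, span = alpha_span(305, 314)) {
  build_ideal_peptide(trop2_ic(phospho = phospho), span)
}

# apply one rigid transform to every model of an ensemble
transform_ensemble <- function(ensemble, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(ensemble[, c("x", "y", "z")]) %*% t(rotation)
  ensemble$x <- xyz[, 1] + translation[1]
  ensemble$y <- xyz[, 2] + translation[2]
  ensemble$z <- xyz[, 3] + translation[3]
  ensemble
}

# minimal two-residue backbone with a chosen omega dihedral
two_residue_omega <- function(omega) {
  n1 <- c(0, 0, 0); ca1 <- c(1.458, 0, 0)
  ca_c <- 1.525
  th <- 111.2 * pi / 180
  c1 <- ca1 + ca_c * (cos(th) * c(-1, 0, 0) + sin(th) * c(0, 1, 0))
  n2 <- helixswitch:::place_atom(n1, ca1, c1, 1.329, 116.2, 150)
  ca2 <- helixswitch:::place_atom(ca1, c1, n2, 1.458, 121.7, omega)
  c2 <- helixswitch:::place_atom(c1, n2, ca2, 1.525, 111.2, -120)
  o1 <- helixswitch:::place_atom(n1, ca1, c1, 1.231, 120.8, -30)
  o2 <- helixswitch:::place_atom(n2, ca2, c2, 1.231, 120.8, -30)
  structure_ensemble(tibble::tibble(
    model = 1L, resno = rep(1:2, each = 4), resname = "ALA",
    atom = rep(c("N", "CA", "C", "O"), 2), element = rep(c("N", "C", "C", "O"), 2),
    x = c(n1[1], ca1[1], c1[1], o1[1], n2[1], ca2[1], c2[1], o2[1]),
    y = c(n1[2], ca1[2], c1[2], o1[2], n2[2], ca2[2], c2[2], o2[2]),
    z = c(n1[3], ca1[3], c1[3], o1[3], n2[3], ca2[3], c2[3], o2[3])
  ))
}

# single frame of a two-helix system as a cg_trajectory with repeated frames
repeat_frames <- function(frame_beads, n, box = c(100, 100, 100)) {
  frames <- lapply(seq_len(n), function(f) dplyr::mutate(frame_beads, frame = as.integer(f)))
  cg_trajectory(dplyr::bind_rows(frames), box = box)
}
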