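# Synthetic-data generators. Every generator is deterministic under a fixed
# seed and carries its ground truth, so each analysis operation can be tested
# against known answers: ideal peptides built from a phi/psi plan, jittered
# ensembles, engineered salt bridges, two-state CD spectra and
# geometry-derived restraint lists.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
         Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

# distance (A) from CA to the single side-chain interaction centre
SC_RADIUS <- c(A = 1.5, R = 4.1, N = 2.5, D = 2.5, C = 2.1, E = 3.1, Q = 3.1,
               G = NA, H = 3.2, I = 2.4, L = 2.6, K = 3.5, M = 3.0, F = 3.4,
               P = 1.9, S = 1.9, T = 1.9, W = 3.9, Y = 3.8, V = 2.0)

# ideal backbone geometry (angstroms / degrees)
BL <- c(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.53)
BA <- c(n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7, ca_c_o = 120.8,
        n_ca_cb = 110.5)

#' Helical and coil phi/psi plan helpers
#'
#' Convenience rows for [build_ideal_peptide()] plans: canonical alpha-helix
#' (-57, -47) and 3-10 helix (-49, -26) dihedrals over an author-numbered
#' span.
#'
#' @param first,last Author residue numbers of the span (inclusive).
#' @return A one-row tibble with `first`, `last`, `phi`, `psi`.
#' @export
alpha_span <- function(first, last) tibble(first = first, last = last,
                                           phi = -57, psi = -47)

#' @rdname alpha_span
#' @export
three10_span <- function(first, last) tibble(first = first, last = last,
                                             phi = -49, psi = -26)

plan_angles <- function(seq, ss_plan, coil = c(-120, 120)) {
  nums <- seq_numbers(seq)
  phi <- rep(coil[1], length(nums))
  psi <- rep(coil[2], length(nums))
  if (!is.null(ss_plan) && nrow(ss_plan) > 0) {
    covered <- integer()
    for (i in seq_len(nrow(ss_plan))) {
      span <- ss_plan$first[i]:ss_plan$last[i]
      if (!all(span %in% nums))
        abort("plan span outside the sequence numbering", class = "helixswitch_plan_error")
      if (any(span %in% covered))
        abort("plan spans overlap", class = "helixswitch_plan_error")
      covered <- c(covered, span)
      idx <- match(span, nums)
      phi[idx] <- ss_plan$phi[i]
      psi[idx] <- ss_plan$psi[i]
    }
  }
  tibble(resno = nums, phi = phi, psi = psi)
}

# unit vector perpendicular to u (any)
perp_unit <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  vec_unit(vec_cross(u, v))
}

# side-chain pseudo-atoms for one residue; sc is the interaction centre
charged_pseudo_atoms <- function(letter, phospho, ca, sc) {
  u <- vec_unit(sc - ca)
  t1 <- perp_unit(u)
  t2 <- vec_cross(u, t1)
  at <- function(name, pos, elem) tibble(atom = name, element = elem,
                                         x = pos[1], y = pos[2], z = pos[3])
  if (letter == "R") {
    bind_rows(at("NE", sc - 0.7 * u, "N"),
              at("NH1", sc + 0.6 * t1, "N"),
              at("NH2", sc - 0.6 * t1, "N"))
  } else if (letter == "K") {
    at("NZ", sc, "N")
  } else if (letter == "E") {
    bind_rows(at("OE1", sc + 0.55 * t1, "O"), at("OE2", sc - 0.55 * t1, "O"))
  } else if (letter == "D") {
    bind_rows(at("OD1", sc + 0.55 * t1, "O"), at("OD2", sc - 0.55 * t1, "O"))
  } else if (letter == "S" && phospho) {
    p <- sc + 1.6 * u
    bind_rows(at("P", p, "P"),
              at("O1P", p + 1.5 * t1, "O"),
              at("O2P", p + 1.5 * t2, "O"),
              at("O3P", p + 1.5 * u, "O"))
  } else {
    NULL
  }
}

#' Build an idealised peptide model from a phi/psi plan
#'
#' Constructs backbone atoms N, CA, C, O with ideal bond geometry from a
#' secondary-structure plan (default coil (-120, 120) outside planned spans),
#' plus one side-chain interaction centre (`SC`) per residue along the
#' CA->CB direction at a residue-specific radius, charged-group pseudo-atoms
#' for Arg/Lys/Asp/Glu/phosphoSer, and ACE/NME capping residues when the
#' sequence is capped. The measured backbone dihedrals of the built model
#' reproduce the plan.
#'
#' @param seq A [peptide_seq()].
#' @param ss_plan A tibble with columns `first`, `last`, `phi`, `psi`
#'   (author-numbered, disjoint spans), e.g. from [alpha_span()]; `NULL`
#'   builds an all-coil chain.
#' @param coil `c(phi, psi)` used outside the planned spans.
#' @return A one-model [structure_ensemble()].
#' @export
#' @examples
#' m <- build_ideal_peptide(trop2_ic(), alpha_span(305, 314))
#' assign_secondary_structure(m)
build_ideal_peptide <- function(seq, ss_plan = NULL, coil = c(-120, 120)) {
  stopifnot(inherits(seq, "peptide_seq"))
  ang <- plan_angles(seq, ss_plan, coil)
  letters <- seq_letters(seq)
  nres <- length(letters)
  N <- CA <- CC <- vector("list", nres)
  # first residue frame
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(BL["n_ca"], 0, 0)
  u <- vec_unit(N[[1]] - CA[[1]])
  d <- cos(deg2rad(BA["n_ca_c"])) * u + sin(deg2rad(BA["n_ca_c"])) * c(0, 1, 0)
  CC[[1]] <- CA[[1]] + BL["ca_c"] * d
  n_next <- NULL
  for (i in seq_len(nres)) {
    if (i < nres || seq$caps["amide_c"]) {
      n_next <- place_atom(N[[i]], CA[[i]], CC[[i]], BL["c_n"], BA["ca_c_n"],
                           ang$psi[i])
    }
    if (i < nres) {
      N[[i + 1]] <- n_next
      CA[[i + 1]] <- place_atom(CA[[i]], CC[[i]], N[[i + 1]], BL["n_ca"],
                                BA["c_n_ca"], 180)
      CC[[i + 1]] <- place_atom(CC[[i]], N[[i + 1]], CA[[i + 1]], BL["ca_c"],
                                BA["n_ca_c"], ang$phi[i + 1])
    }
  }
  rows <- list()
  add <- function(resno, resname, atom, elem, pos) {
    rows[[length(rows) + 1]] <<- tibble(model = 1L, resno = resno,
                                        resname = resname, atom = atom,
                                        element = elem, x = pos[1], y = pos[2],
                                        z = pos[3])
  }
  for (i in seq_len(nres)) {
    r <- ang$resno[i]
    let <- letters[i]
    phos <- r %in% seq$phospho_positions
    rn <- if (let == "S" && phos) "SEP" else unname(AA3[let])
    add(r, rn, "N", "N", N[[i]])
    add(r, rn, "CA", "C", CA[[i]])
    add(r, rn, "C", "C", CC[[i]])
    o <- place_atom(N[[i]], CA[[i]], CC[[i]], BL["c_o"], BA["ca_c_o"],
                    ang$psi[i] + 180)
    add(r, rn, "O", "O", o)
    if (let != "G") {
      cb <- place_atom(CC[[i]], N[[i]], CA[[i]], BL["ca_cb"], BA["n_ca_cb"],
                       122.6)
      add(r, rn, "CB", "C", cb)
      sc <- CA[[i]] + SC_RADIUS[let] * vec_unit(cb - CA[[i]])
      add(r, rn, "SC", "C", sc)
      ch <- charged_pseudo_atoms(let, phos, CA[[i]], sc)
      if (!is.null(ch)) {
        for (j in seq_len(nrow(ch)))
          add(r, rn, ch$atom[j], ch$element[j], c(ch$x[j], ch$y[j], ch$z[j]))
      }
    }
  }
  if (seq$caps["acetyl_n"]) {
    r0 <- seq$start_number - 1L
    ace_c <- place_atom(CC[[1]], CA[[1]], N[[1]], BL["c_n"], BA["c_n_ca"],
                        ang$phi[1])
    ace_o <- place_atom(CA[[1]], N[[1]], ace_c, BL["c_o"], BA["ca_c_o"], 0)
    ace_ch3 <- place_atom(CA[[1]], N[[1]], ace_c, 1.50, BA["ca_c_n"], 180)
    add(r0, "ACE", "C", "C", ace_c)
    add(r0, "ACE", "O", "O", ace_o)
    add(r0, "ACE", "CH3", "C", ace_ch3)
  }
  if (seq$caps["amide_c"]) {
    r1 <- seq$start_number + nres
    nme_ch3 <- place_atom(CA[[nres]], CC[[nres]], n_next, BL["n_ca"],
                          BA["c_n_ca"], 180)
    add(r1, "NME", "N", "N", n_next)
    add(r1, "NME", "CH3", "C", nme_ch3)
  }
  structure_ensemble(list_rbind(rows))
}

#' Jitter a model into a synthetic ensemble
#'
#' Model 1 is the unperturbed input; models 2..n add isotropic Gaussian
#' displacements of standard deviation `noise_sigma` per coordinate.
#'
#' @param model A one-model [structure_ensemble()].
#' @param n_models Number of models (>= 1).
#' @param noise_sigma Displacement standard deviation (angstroms).
#' @param seed Integer seed (determinism contract: fixed seed, identical
#'   ensemble).
#' @return A [structure_ensemble()] with `n_models` models.
#' @export
jitter_ensemble <- function(model, n_models, noise_sigma = 0.5, seed = 1L) {
  stopifnot(inherits(model, "structure_ensemble"), n_models >= 1)
  base <- get_model(model)
  base$model <- 1L
  set.seed(seed)
  out <- map(seq_len(n_models), function(m) {
    d <- base
    d$model <- as.integer(m)
    if (m > 1 && noise_sigma > 0) {
      d$x <- d$x + rnorm(nrow(d), 0, noise_sigma)
      d$y <- d$y + rnorm(nrow(d), 0, noise_sigma)
      d$z <- d$z + rnorm(nrow(d), 0, noise_sigma)
    }
    d
  })
  structure_ensemble(list_rbind(out))
}

#' Engineer a salt bridge into selected models
#'
#' Moves the charged-group pseudo-atoms of the acidic residue so that its
#' closest group atom sits exactly `target_distance` from the closest basic
#' group atom, in the selected models only; all other atoms are untouched.
#'
#' @param ensemble A [structure_ensemble()].
#' @param acidic_resno,basic_resno Author numbers of an acidic (Glu/Asp/pSer)
#'   and a basic (Arg/Lys) residue.
#' @param target_distance Angstroms.
#' @param models Integer model numbers to modify (default all).
#' @return The modified [structure_ensemble()].
#' @export
engineer_salt_bridge <- function(ensemble, acidic_resno, basic_resno,
                                 target_distance, models = NULL) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  models <- models %||% sort(unique(ensemble$model))
  an <- unique(ensemble$resname[ensemble$resno == acidic_resno])
  bn <- unique(ensemble$resname[ensemble$resno == basic_resno])
  if (!any(an %in% names(ACIDIC_GROUP_ATOMS)))
    abort("acidic_resno is not an acidic residue", class = "helixswitch_type_error")
  if (!any(bn %in% names(BASIC_GROUP_ATOMS)))
    abort("basic_resno is not a basic residue", class = "helixswitch_type_error")
  a_atoms <- ACIDIC_GROUP_ATOMS[[intersect(an, names(ACIDIC_GROUP_ATOMS))[1]]]
  b_atoms <- BASIC_GROUP_ATOMS[[intersect(bn, names(BASIC_GROUP_ATOMS))[1]]]
  for (m in models) {
    ai <- which(ensemble$model == m & ensemble$resno == acidic_resno &
                  ensemble$atom %in% a_atoms)
    bi <- which(ensemble$model == m & ensemble$resno == basic_resno &
                  ensemble$atom %in% b_atoms)
    if (length(ai) == 0 || length(bi) == 0)
      abort("charged-group atoms missing", class = "helixswitch_structure_error")
    axyz <- as.matrix(ensemble[ai, c("x", "y", "z")])
    bxyz <- as.matrix(ensemble[bi, c("x", "y", "z")])
    d2 <- outer(rowSums(axyz^2), rowSums(bxyz^2), `+`) - 2 * tcrossprod(axyz, bxyz)
    ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    a0 <- axyz[ij[1], ]; b0 <- bxyz[ij[2], ]
    u <- if (vec_norm(a0 - b0) < 1e-9) c(1, 0, 0) else vec_unit(a0 - b0)
    shift <- (b0 + target_distance * u) - a0
    ensemble$x[ai] <- ensemble$x[ai] + shift[1]
    ensemble$y[ai] <- ensemble$y[ai] + shift[2]
    ensemble$z[ai] <- ensemble$z[ai] + shift[3]
  }
  ensemble
}

# ---- CD spectra -----------------------------------------------------------

cd_gauss <- function(l, centre, width) exp(-((l - centre) / width)^2)

#' Two-state CD basis spectra
#'
#' Gaussian-shaped coil and helix basis spectra in MRE units, calibrated so
#' that the coil basis equals 640 deg cm^2 dmol^-1 at 222 nm with its minimum
#' at 198 nm, and the helix basis equals -42500 at 222 nm with minima at 208
#' and 222 nm. Only these calibration points are contractual; the shapes are
#' convenient idealisations.
#'
#' @param wavelength_nm Wavelength grid (nm).
#' @return A tibble: `wavelength_nm`, `coil`, `helix`.
#' @export
cd_basis <- function(wavelength_nm) {
  l <- wavelength_nm
  coil_main <- -15000 * cd_gauss(l, 198, 9)
  k_coil <- 640 + 15000 * cd_gauss(222, 198, 9)
  coil <- coil_main + k_coil * cd_gauss(l, 222, 25)
  p <- 60000; a <- 39000
  b <- 42500 + p * cd_gauss(222, 192, 5.5) - a * cd_gauss(222, 208, 6)
  helix <- p * cd_gauss(l, 192, 5.5) - a * cd_gauss(l, 208, 6) -
    b * cd_gauss(l, 222, 6)
  tibble(wavelength_nm = l, coil = coil, helix = helix)
}

#' Generate a synthetic raw CD spectrum and its blank
#'
#' The MRE spectrum is the two-state mixture
#' `f_H * helix + (1 - f_H) * coil` of the [cd_basis()] spectra, so its value
#' at 222 nm equals the two-state model exactly and
#' [fractional_helicity()] round-trips `f_H`. The mixture is converted to raw
#' millidegrees with the inverse of the MRE normalisation, a smooth buffer
#' baseline is added, and optional Gaussian noise is applied to both sample
#' and blank.
#'
#' @param f_helix Target fractional helicity in \[0, 1\].
#' @param wavelength_nm Wavelength grid (default 190-270 nm, 0.5 nm step).
#' @param noise_mdeg Gaussian noise sd on the raw signals (default 0).
#' @param conc_mM,n_residues,path_cm,tfe_percent Sample metadata.
#' @param seed Integer seed for the noise.
#' @return A list: `sample` and `blank` (raw [cd_spectrum()] objects) and
#'   `truth` (`f_helix`, `mre_222`, and the noise-free peptide-only mdeg
#'   component `peptide_mdeg`).
#' @export
generate_cd_spectrum <- function(f_helix, wavelength_nm = seq(190, 270, by = 0.5),
                                 noise_mdeg = 0, conc_mM = 0.05,
                                 n_residues = 26L, path_cm = 0.1,
                                 tfe_percent = 70, seed = 1L) {
  stopifnot(f_helix >= 0, f_helix <= 1)
  basis <- cd_basis(wavelength_nm)
  mre <- f_helix * basis$helix + (1 - f_helix) * basis$coil
  denom <- 10 * (conc_mM / 1000) * n_residues * path_cm
  peptide_mdeg <- mre * denom
  baseline <- 0.5 * cd_gauss(wavelength_nm, 195, 20)
  set.seed(seed)
  noise_s <- if (noise_mdeg > 0) rnorm(length(wavelength_nm), 0, noise_mdeg) else 0
  noise_b <- if (noise_mdeg > 0) rnorm(length(wavelength_nm), 0, noise_mdeg) else 0
  mk <- function(sig) cd_spectrum(wavelength_nm, sig, units = "raw_mdeg",
                                  conc_mM = conc_mM, n_residues = n_residues,
                                  path_cm = path_cm, tfe_percent = tfe_percent)
  list(sample = mk(peptide_mdeg + baseline + noise_s),
       blank = mk(baseline + noise_b),
       truth = list(f_helix = f_helix,
                    mre_222 = f_helix * (-42500) + (1 - f_helix) * 640,
                    peptide_mdeg = peptide_mdeg))
}

# ---- restraints -----------------------------------------------------------

#' Generate a geometry-derived restraint list from a model
#'
#' Samples atom pairs within `cutoff` and sets each upper bound to the true
#' distance plus `slack`, so the source model always satisfies its own
#' restraints. In quota mode exactly the requested number of restraints per
#' residue-separation class (intra, sequential, medium, long) is drawn.
#' Optionally emits phi/psi torsion restraints of half-width `torsion_width`
#' around the model dihedrals.
#'
#' @param model A one-model [structure_ensemble()].
#' @param cutoff Heavy-atom distance cutoff (angstroms); 0 gives an empty
#'   list.
#' @param quotas `NULL`, or a numeric vector
#'   `c(intra =, sequential =, medium =, long =)`.
#' @param slack Added to each true distance (>= 0).
#' @param torsion_width Half-width in degrees for torsion restraints, or
#'   `NULL` for none.
#' @param seed Integer seed for the sampling.
#' @return A [restraint_list()].
#' @export
generate_restraints <- function(model, cutoff = 6, quotas = NULL, slack = 0.5,
                                torsion_width = NULL, seed = 1L) {
  stopifnot(inherits(model, "structure_ensemble"), slack >= 0)
  md <- get_model(model)
  md <- md[!md$resname %in% CAP_RESNAMES, ]
  md <- arrange(md, .data$resno, .data$atom)
  xyz <- as.matrix(md[, c("x", "y", "z")])
  n <- nrow(xyz)
  cand <- NULL
  if (cutoff > 0 && n > 1) {
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(xyz)
    idx <- which(upper.tri(d2) & d2 <= cutoff^2 & d2 > 1e-6, arr.ind = TRUE)
    cand <- tibble(
      res_i = md$resno[idx[, 1]], resname_i = md$resname[idx[, 1]],
      atom_i = md$atom[idx[, 1]],
      res_j = md$resno[idx[, 2]], resname_j = md$resname[idx[, 2]],
      atom_j = md$atom[idx[, 2]],
      upper = sqrt(pmax(d2[idx], 0)) + slack,
      sep = abs(md$resno[idx[, 1]] - md$resno[idx[, 2]])
    )
  }
  if (is.null(cand) || nrow(cand) == 0) {
    dist <- NULL
  } else if (is.null(quotas)) {
    dist <- select(cand, -"sep")
  } else {
    need <- c(intra = 0, sequential = 0, medium = 0, long = 0)
    need[names(quotas)] <- quotas
    cls <- list(intra = cand$sep == 0, sequential = cand$sep == 1,
                medium = cand$sep >= 2 & cand$sep <= 4, long = cand$sep >= 5)
    set.seed(seed)
    picked <- list()
    for (k in names(need)) {
      pool <- which(cls[[k]])
      if (length(pool) < need[k])
        abort(sprintf("only %d candidate pairs for class '%s' (need %d)",
                      length(pool), k, need[k]),
              class = "helixswitch_quota_error")
      if (need[k] > 0)
        picked[[k]] <- cand[sample(pool, need[k]), ]
    }
    dist <- if (length(picked)) select(list_rbind(picked), -"sep") else NULL
  }
  torsion <- NULL
  if (!is.null(torsion_width)) {
    dih <- backbone_dihedrals(md)
    rows <- list()
    for (i in seq_len(nrow(dih))) {
      for (ang in c("phi", "psi")) {
        v <- dih[[ang]][i]
        if (is.na(v)) next
        rows[[length(rows) + 1]] <- tibble(
          resno = dih$resno[i], resname = dih$resname[i],
          angle = toupper(ang),
          lower = ((v - torsion_width + 180) %% 360) - 180,
          upper = ((v + torsion_width + 180) %% 360) - 180)
      }
    }
    torsion <- list_rbind(rows)
  }
  restraint_list(distance = dist, torsion = torsion)
}
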