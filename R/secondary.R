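# Backbone dihedrals and the classifications built on them: a
# dihedral-window secondary-structure assigner (alpha / 3-10 / coil), the
# omega cis/trans/twisted call, and a fixed 10-degree-grid Ramachandran
# region map with nested classes (most favored / additional / generous /
# disallowed) and separate maps for glycine and proline.

CAP_RESNAMES <- c("ACE", "NME", "NMA")

#' Backbone dihedral angles of one model
#'
#' Computes phi, psi and omega per residue. Capping groups (ACE/NME) are not
#' reported as residues but do provide the flanking atoms for terminal
#' dihedrals. Angles that cannot be computed (chain ends) are `NA`.
#'
#' @param model A single-model [structure_ensemble()].
#' @return A tibble: `resno`, `resname`, `phi`, `psi`, `omega` (degrees;
#'   `omega` is the dihedral about the peptide bond to the *next* residue).
#' @export
backbone_dihedrals <- function(model) {
  stopifnot(inherits(model, "structure_ensemble"))
  if (n_models(model) != 1) model <- get_model(model)
  res <- model |> distinct(.data$resno, .data$resname) |> arrange(.data$resno)
  aa <- res[!res$resname %in% CAP_RESNAMES, ]
  get <- function(resno, atom) atom_xyz(model, resno, atom)
  rows <- map(seq_len(nrow(aa)), function(i) {
    r <- aa$resno[i]
    n <- get(r, "N"); ca <- get(r, "CA"); cc <- get(r, "C")
    if (is.null(n) || is.null(ca) || is.null(cc))
      abort(sprintf("residue %d is missing a backbone atom", r),
            class = "helixswitch_structure_error")
    c_prev <- get(r - 1L, "C")
    n_next <- get(r + 1L, "N")
    ca_next <- get(r + 1L, "CA")
    next_is_cap <- (r + 1L) %in% res$resno[res$resname %in% CAP_RESNAMES]
    tibble(
      resno = r, resname = aa$resname[i],
      phi = if (is.null(c_prev)) NA_real_ else dihedral_angle(c_prev, n, ca, cc),
      psi = if (is.null(n_next)) NA_real_ else dihedral_angle(n, ca, cc, n_next),
      omega = if (is.null(n_next) || is.null(ca_next) || next_is_cap) NA_real_
              else dihedral_angle(ca, cc, n_next, ca_next)
    )
  })
  list_rbind(rows)
}

in_window <- function(x, centre, half) !is.na(x) & abs(x - centre) <= half

mark_runs <- function(flag, min_run) {
  r <- rle(flag)
  keep <- r$values & r$lengths >= min_run
  rep(keep, r$lengths)
}

#' Assign secondary structure from backbone dihedrals
#'
#' A deterministic dihedral-window assigner: a residue is part of an
#' alpha-helix (`H`) when it lies in a run of >= 4 consecutive residues with
#' (phi, psi) within (-57 +/- 40, -47 +/- 40); a 3-10 helix (`G`) requires a
#' run of >= 3 within (-49 +/- 30, -26 +/- 30) among residues not already
#' `H`. Everything else, including terminal residues lacking a dihedral, is
#' coil (`C`).
#'
#' @param model A single-model [structure_ensemble()].
#' @return A tibble: `resno`, `resname`, `phi`, `psi`, `ss` (one of
#'   `"H"`, `"G"`, `"C"`).
#' @export
assign_secondary_structure <- function(model) {
  d <- backbone_dihedrals(model)
  alpha <- in_window(d$phi, -57, 40) & in_window(d$psi, -47, 40)
  three10 <- in_window(d$phi, -49, 30) & in_window(d$psi, -26, 30)
  h <- mark_runs(alpha, 4L)
  g <- mark_runs(three10 & !h, 3L)
  d$ss <- ifelse(h, "H", ifelse(g, "G", "C"))
  d[, c("resno", "resname", "phi", "psi", "ss")]
}

#' Classify the peptide bond geometry (omega dihedral)
#'
#' The omega dihedral CA(i)-C(i)-N(i+1)-CA(i+1) is classed as `trans` when
#' |omega| >= 150 degrees, `cis` when |omega| <= 30, and `twisted` otherwise.
#'
#' @param model A single-model [structure_ensemble()].
#' @param resno Author number of residue i (bond to residue i+1), or `NULL`
#'   for all bonds.
#' @return A tibble: `resno`, `omega`, `conformation`.
#' @export
omega_classify <- function(model, resno = NULL) {
  d <- backbone_dihedrals(model)
  d <- d[!is.na(d$omega), c("resno", "omega")]
  if (!is.null(resno)) {
    d <- d[d$resno %in% resno, ]
    if (nrow(d) == 0)
      abort("omega undefined for the requested residue (missing atoms?)",
            class = "helixswitch_structure_error")
  }
  d$conformation <- ifelse(abs(d$omega) >= 150, "trans",
                           ifelse(abs(d$omega) <= 30, "cis", "twisted"))
  d
}

# ---- Ramachandran region maps -------------------------------------------

# 36 x 36 character grid (10-degree cells, phi rows, psi columns) painted
# from rectangle lists; generous regions are the additional regions dilated
# by 20 degrees (2 cells, with wraparound), per the usual four-class scheme.
rama_cell <- function(angle) pmin(pmax(floor((angle + 180) / 10) + 1, 1), 36)

paint <- function(mask, rects) {
  for (r in rects) {
    pi_ <- rama_cell(r[1]):rama_cell(r[2] - 1e-9)
    ps <- rama_cell(r[3]):rama_cell(r[4] - 1e-9)
    mask[pi_, ps] <- TRUE
  }
  mask
}

dilate <- function(mask, cells) {
  n <- nrow(mask)
  out <- mask
  for (dx in -cells:cells) for (dy in -cells:cells) {
    out <- out | mask[((seq_len(n) - 1 - dx) %% n) + 1, ((seq_len(n) - 1 - dy) %% n) + 1]
  }
  out
}

build_rama_map <- function(core_rects, additional_rects) {
  empty <- matrix(FALSE, 36, 36)
  core <- paint(empty, core_rects)
  additional <- paint(core, additional_rects)
  generous <- dilate(additional, 2L)
  m <- matrix("disallowed", 36, 36)
  m[generous] <- "generous"
  m[additional] <- "additional"
  m[core] <- "most_favored"
  m
}

# rectangles are c(phi_min, phi_max, psi_min, psi_max)
rama_maps <- local({
  general <- build_rama_map(
    core_rects = list(
      c(-160, -40, -70, -10),    # alpha basin
      c(-170, -60, 90, 180)      # beta basin
    ),
    additional_rects = list(
      c(-180, -20, -90, 30),     # widened alpha
      c(-180, -40, 60, 180),     # widened beta
      c(-180, -40, -180, -150),  # beta wrap (psi near -180)
      c(40, 90, 0, 90)           # left-handed alpha
    )
  )
  gly <- build_rama_map(
    core_rects = list(
      c(-160, -40, -70, -10), c(-170, -60, 90, 180),
      c(40, 160, 10, 70), c(60, 170, -180, -90)   # mirrored basins
    ),
    additional_rects = list(
      c(-180, -20, -90, 40), c(-180, -40, 60, 180),
      c(20, 180, -10, 90), c(40, 180, -180, -80),
      c(-180, -40, -180, -150), c(40, 180, 150, 180)
    )
  )
  pro <- build_rama_map(
    core_rects = list(
      c(-90, -40, -60, -10), c(-90, -40, 110, 180)
    ),
    additional_rects = list(
      c(-110, -30, -80, 10), c(-110, -30, 90, 180),
      c(-110, -30, -180, -170)
    )
  )
  list(general = general, gly = gly, pro = pro)
})

#' Ramachandran region of a (phi, psi) pair
#'
#' Classification against a fixed 10-degree-grid four-class region map in the
#' PROCHECK style; the classes are nested (most favored inside additional
#' inside generous). Glycine and proline use their own maps.
#'
#' @param phi,psi Dihedral angles in degrees, in (-180, 180]. Vectorised.
#' @param residue `"general"`, `"GLY"` or `"PRO"` (3-letter names or
#'   one-letter G/P also accepted); recycled.
#' @return Character vector: `most_favored`, `additional`, `generous` or
#'   `disallowed`.
#' @export
#' @examples
#' ramachandran_classify(-60, -45)   # most_favored (alpha basin)
#' ramachandran_classify(-120, 130)  # most_favored (beta basin)
ramachandran_classify <- function(phi, psi, residue = "general") {
  if (any(!is.finite(phi)) || any(!is.finite(psi)))
    abort("phi/psi must be finite", class = "helixswitch_input_error")
  n <- max(length(phi), length(psi), length(residue))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  residue <- rep_len(toupper(residue), n)
  map_key <- ifelse(residue %in% c("GLY", "G"), "gly",
                    ifelse(residue %in% c("PRO", "P"), "pro", "general"))
  vapply(seq_len(n), function(i) {
    rama_maps[[map_key[i]]][rama_cell(phi[i]), rama_cell(psi[i])]
  }, character(1))
}

#' Ramachandran region percentages over an ensemble
#'
#' Classifies every residue with both phi and psi defined, in every model,
#' and reports the percentage in each region. Percentages sum to 100.
#'
#' @param ensemble A [structure_ensemble()].
#' @param resno_range Optional author residue-number range.
#' @return A tibble: `region`, `count`, `percent`.
#' @export
ramachandran_summary <- function(ensemble, resno_range = NULL) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  regions <- c("most_favored", "additional", "generous", "disallowed")
  all_cls <- unlist(map(sort(unique(ensemble$model)), function(m) {
    d <- backbone_dihedrals(get_model(ensemble, m))
    if (!is.null(resno_range))
      d <- d[d$resno >= resno_range[1] & d$resno <= resno_range[2], ]
    d <- d[!is.na(d$phi) & !is.na(d$psi), ]
    if (nrow(d) == 0) return(character())
    ramachandran_classify(d$phi, d$psi, d$resname)
  }))
  counts <- table(factor(all_cls, levels = regions))
  tibble(region = regions, count = as.integer(counts),
         percent = 100 * as.integer(counts) / max(sum(counts), 1L))
}
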