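# Coarse-grained two-helix systems: the initial membrane construction
# (parallel vertical helices at a set separation) and a kinematic rigid-body
# dimerization surrogate with programmed lateral diffusion, encounter frame,
# crossing angle and axial-rotation episodes. The surrogate computes no
# forces; it exists to give the trajectory analyses exact ground truth.

CG_BB_RADIUS <- 2.3    # backbone bead distance from the helix axis (A)
CG_SC_RADIUS <- 4.7    # side-chain bead distance from the helix axis (A)
CG_RISE <- 1.5         # rise per residue (A)
CG_TWIST <- 100        # twist per residue (deg)

# one ideal coarse-grained helix, axis = z through the origin, z-centred
cg_helix_template <- function(seq) {
  letters <- seq_letters(seq)
  nums <- seq_numbers(seq)
  n <- length(letters)
  z <- CG_RISE * (seq_len(n) - (n + 1) / 2)
  th <- deg2rad(CG_TWIST * (seq_len(n) - 1))
  bb <- tibble(resno = nums, role = "backbone",
               x = CG_BB_RADIUS * cos(th), y = CG_BB_RADIUS * sin(th), z = z)
  has_sc <- letters != "G"
  sc <- tibble(resno = nums[has_sc], role = "sidechain",
               x = CG_SC_RADIUS * cos(th[has_sc]),
               y = CG_SC_RADIUS * sin(th[has_sc]), z = z[has_sc])
  bind_rows(bb, sc)
}

transform_beads <- function(beads, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(beads[, c("x", "y", "z")]) %*% t(rotation)
  beads$x <- xyz[, 1] + translation[1]
  beads$y <- xyz[, 2] + translation[2]
  beads$z <- xyz[, 3] + translation[3]
  beads
}

#' Build the initial two-helix membrane system
#'
#' Two identical ideal coarse-grained helices with axes along the membrane
#' normal (z), centred in the membrane midplane and separated by
#' `separation` along x; the second helix is an exact translated copy of the
#' first, so the fitted-axis interhelical distance equals `separation`
#' exactly.
#'
#' @param separation Interhelical distance (angstroms, default 50).
#' @param box Orthorhombic box dimensions (default 100 x 100 x 100).
#' @param seq Helix sequence (default [trop2_tm()]).
#' @param dt Frame spacing in ns.
#' @return A one-frame [cg_trajectory()].
#' @export
#' @examples
#' sys <- build_tm_system()
#' f <- dplyr::filter(sys, frame == 1)
#' axa <- fit_helix_axis(dplyr::filter(f, helix == "A"))
#' axb <- fit_helix_axis(dplyr::filter(f, helix == "B"))
#' interhelical_distance(axa, axb)  # 50
build_tm_system <- function(separation = 50, box = c(100, 100, 100),
                            seq = trop2_tm(), dt = 1) {
  if (separation >= min(box[1:2]))
    abort("separation must be smaller than the lateral box dimensions",
          class = "helixswitch_geometry_error")
  tpl <- cg_helix_template(seq)
  ca <- c(box[1] / 2 - separation / 2, box[2] / 2, box[3] / 2)
  a <- transform_beads(tpl, translation = ca) |> mutate(helix = "A")
  b <- transform_beads(tpl, translation = ca + c(separation, 0, 0)) |>
    mutate(helix = "B")
  beads <- bind_rows(a, b) |> mutate(frame = 1L)
  cg_trajectory(beads, dt = dt, box = box, normal_axis = "z")
}

# reflective 1-D step
reflect_step <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

#' Reflect a trajectory through the yz-plane
#'
#' Mirrors all bead coordinates (x -> -x), which inverts the handedness of
#' any helix packing.
#'
#' @param traj A [cg_trajectory()].
#' @return The reflected `cg_trajectory`.
#' @export
reflect_trajectory <- function(traj) {
  traj$x <- -traj$x
  traj
}

#' Simulate a rigid-body helix dimerization trajectory
#'
#' A kinematic surrogate for coarse-grained membrane simulations of two
#' transmembrane helices. Before `encounter_frame` the two vertical helices
#' perform independent lateral random walks (reflective box walls, minimum
#' approach enforced so no premature contact occurs). At the encounter the
#' helices dock at `dock_separation` with the interface motif side chains
#' facing each other in a C2-symmetric arrangement, tilted about the line of
#' closest approach so that the signed crossing angle equals `target_angle`
#' exactly. Afterwards the dimer moves as one rigid body (lateral drift and
#' rotation about the membrane normal, both of which leave every reported
#' geometric quantity unchanged). Scheduled axial rotations of helix B about
#' its own axis create asymmetric-orientation episodes.
#'
#' @param n_frames Total frames.
#' @param encounter_frame Frame of the programmed encounter, or `NULL` for a
#'   purely monomeric trajectory.
#' @param target_angle Signed crossing angle of the docked dimer (degrees,
#'   negative = right-handed).
#' @param separation Initial interhelical distance (angstroms).
#' @param box Orthorhombic box dimensions.
#' @param dock_separation Centroid separation of the docked dimer.
#' @param step_sd Lateral random-walk step sd per frame (angstroms).
#' @param min_separation Minimum centroid separation enforced pre-encounter.
#' @param noise_sigma Isotropic Gaussian bead noise (angstroms).
#' @param rotation_schedule `NULL`, or a data frame with columns `start`,
#'   `end`, `angle`: helix B is rotated by `angle` degrees about its own axis
#'   within those frames.
#' @param seq Helix sequence (default [trop2_tm()]).
#' @param motif Interface motif residues (default 282:286).
#' @param dt Frame spacing (ns).
#' @param seed Integer seed; fixed seed gives an identical trajectory.
#' @return A `cg_simulation` list: `trajectory` (a [cg_trajectory()]),
#'   `truth` (per-frame tibble: `frame`, `phase`, `true_angle`,
#'   `orientation`) and `params`.
#' @export
simulate_rigid_dimerization <- function(n_frames = 500, encounter_frame = 120,
                                        target_angle = -27, separation = 50,
                                        box = c(100, 100, 100),
                                        dock_separation = 12, step_sd = 1,
                                        min_separation = 18, noise_sigma = 0,
                                        rotation_schedule = NULL,
                                        seq = trop2_tm(), motif = 282:286,
                                        dt = 4, seed = 1L) {
  if (!is.null(encounter_frame) && encounter_frame >= n_frames)
    abort("encounter_frame must be < n_frames", class = "helixswitch_input_error")
  if (abs(target_angle) > 90)
    abort("target_angle must lie in (-90, 90]", class = "helixswitch_input_error")
  set.seed(seed)
  tpl <- cg_helix_template(seq)
  z_mid <- box[3] / 2
  margin <- 12
  lo <- c(margin, margin); hi <- c(box[1] - margin, box[2] - margin)

  # docked local construction: motif of A faces +x, tilt about x by half the
  # target angle, B is the C2 (180 degrees about z) image of A
  sc <- tpl[tpl$role == "sidechain" & tpl$resno %in% motif, ]
  az <- rad2deg(atan2(mean(sc$y / CG_SC_RADIUS), mean(sc$x / CG_SC_RADIUS)))
  alpha <- target_angle / 2
  ra <- rotation_about_axis(c(1, 0, 0), alpha) %*% rotation_about_axis(c(0, 0, 1), -az)
  a_loc <- transform_beads(tpl, ra, c(-dock_separation / 2, 0, 0))
  b_loc <- transform_beads(a_loc, rotation_about_axis(c(0, 0, 1), 180))
  b_axis_point <- c(dock_separation / 2, 0, 0)
  b_axis_dir <- as.numeric(rotation_about_axis(c(0, 0, 1), 180) %*%
                             (ra %*% c(0, 0, 1)))

  ca <- c(box[1] / 2 - separation / 2, box[2] / 2)
  cb <- ca + c(separation, 0)
  com <- (ca + cb) / 2
  drift_angle <- 0
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  sched_angle <- function(f) {
    if (is.null(rotation_schedule)) return(0)
    hit <- rotation_schedule$start <= f & f <= rotation_schedule$end
    if (any(hit)) sum(rotation_schedule$angle[hit]) else 0
  }
  for (f in seq_len(n_frames)) {
    docked <- !is.null(encounter_frame) && f >= encounter_frame
    if (!docked) {
      if (f > 1) {
        ca <- c(reflect_step(ca[1] + rnorm(1, 0, step_sd), lo[1], hi[1]),
                reflect_step(ca[2] + rnorm(1, 0, step_sd), lo[2], hi[2]))
        cb <- c(reflect_step(cb[1] + rnorm(1, 0, step_sd), lo[1], hi[1]),
                reflect_step(cb[2] + rnorm(1, 0, step_sd), lo[2], hi[2]))
        d <- cb - ca
        if (vec_norm(c(d, 0)) < min_separation) {
          mid <- (ca + cb) / 2
          u <- if (vec_norm(c(d, 0)) < 1e-9) c(1, 0) else d / vec_norm(c(d, 0))
          ca <- mid - u * min_separation / 2
          cb <- mid + u * min_separation / 2
        }
        com <- (ca + cb) / 2
      }
      a <- transform_beads(tpl, translation = c(ca, z_mid)) |> mutate(helix = "A")
      b <- transform_beads(tpl, translation = c(cb, z_mid)) |> mutate(helix = "B")
      orient <- "monomer"
      true_angle <- NA_real_
    } else {
      if (f > encounter_frame) {
        com <- c(reflect_step(com[1] + rnorm(1, 0, step_sd), lo[1], hi[1]),
                 reflect_step(com[2] + rnorm(1, 0, step_sd), lo[2], hi[2]))
        drift_angle <- drift_angle + rnorm(1, 0, 2)
      }
      rot_b <- sched_angle(f)
      b_now <- b_loc
      if (rot_b != 0) {
        r <- rotation_about_axis(b_axis_dir, rot_b)
        b_now <- transform_beads(b_loc, r,
                                 as.numeric(b_axis_point - r %*% b_axis_point))
      }
      g <- rotation_about_axis(c(0, 0, 1), drift_angle)
      shift <- c(com, z_mid)
      a <- transform_beads(a_loc, g, shift) |> mutate(helix = "A")
      b <- transform_beads(b_now, g, shift) |> mutate(helix = "B")
      orient <- if (rot_b != 0) "asymmetric" else "symmetric"
      true_angle <- target_angle
    }
    fb <- bind_rows(a, b) |> mutate(frame = as.integer(f))
    if (noise_sigma > 0) {
      fb$x <- fb$x + rnorm(nrow(fb), 0, noise_sigma)
      fb$y <- fb$y + rnorm(nrow(fb), 0, noise_sigma)
      fb$z <- fb$z + rnorm(nrow(fb), 0, noise_sigma)
    }
    frames[[f]] <- fb
    truth[[f]] <- tibble(frame = as.integer(f),
                         phase = if (docked) "dimer" else "monomer",
                         true_angle = true_angle, orientation = orient)
  }
  out <- list(
    trajectory = cg_trajectory(list_rbind(frames), dt = dt, box = box,
                               normal_axis = "z"),
    truth = list_rbind(truth),
    params = list(n_frames = n_frames, encounter_frame = encounter_frame,
                  target_angle = target_angle, separation = separation,
                  dock_separation = dock_separation, step_sd = step_sd,
                  noise_sigma = noise_sigma, motif = motif, dt = dt,
                  seed = seed)
  )
  class(out) <- "cg_simulation"
  out
}

#' @export
print.cg_simulation <- function(x, ...) {
  cat(sprintf("<cg_simulation> %d frames, encounter at %s, target angle %s deg\n",
              x$params$n_frames,
              ifelse(is.null(x$params$encounter_frame), "none",
                     x$params$encounter_frame),
              ifelse(is.null(x$params$encounter_frame), "-",
                     x$params$target_angle)))
  invisible(x)
}

#' Write a generator ground-truth sidecar as JSON
#'
#' @param sim A `cg_simulation` (or any list with `truth`/`params` elements).
#' @param path Output path (conventionally `*.truth.json`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  payload <- list(params = sim$params, truth = sim$truth)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
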