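# Geometry of two transmembrane helices along a coarse-grained trajectory:
# axis fits, membrane-plane interhelical distance, signed crossing angle
# (negative = right-handed packing), encounter/dimer detection and the
# interface-motif contact profiles.

#' Construct a coarse-grained two-helix trajectory
#'
#' A `cg_trajectory` is a tibble with one row per bead per frame and columns
#' `frame` (0-based or 1-based, any ordered integers), `helix` ("A"/"B"),
#' `resno`, `role` ("backbone"/"sidechain"), `x`, `y`, `z` (angstroms).
#' Attributes hold the frame spacing `dt` (ns), the orthorhombic `box`
#' dimensions and which axis is the membrane normal.
#'
#' @param beads Data frame of beads as above.
#' @param dt Frame spacing in ns.
#' @param box Numeric length-3 box dimensions (angstroms).
#' @param normal_axis Membrane normal: `"x"`, `"y"` or `"z"` (default).
#' @return A `cg_trajectory` tibble.
#' @export
cg_trajectory <- function(beads, dt = 1, box = c(100, 100, 100), normal_axis = "z") {
  req <- c("frame", "helix", "resno", "role", "x", "y", "z")
  if (!all(req %in% names(beads)))
    abort(paste("beads must have columns", paste(req, collapse = ", ")),
          class = "helixswitch_input_error")
  beads <- as_tibble(beads)[req]
  beads$frame <- as.integer(beads$frame)
  if (length(unique(beads$helix)) != 2)
    abort("trajectory must contain exactly two helix ids", class = "helixswitch_input_error")
  rk <- paste(beads$helix, beads$resno, beads$role, sep = "|")
  rosters <- vapply(split(rk, beads$frame),
                    function(k) paste(sort(k), collapse = ";"), character(1))
  if (length(unique(rosters)) != 1)
    abort("bead roster must be identical across frames", class = "helixswitch_input_error")
  attr(beads, "dt") <- dt
  attr(beads, "box") <- box
  attr(beads, "normal_axis") <- match.arg(normal_axis, c("x", "y", "z"))
  class(beads) <- unique(c("cg_trajectory", class(beads)))
  beads
}

normal_index <- function(traj) match(attr(traj, "normal_axis") %||% "z", c("x", "y", "z"))

traj_frames <- function(traj) sort(unique(traj$frame))

frame_beads <- function(traj, f) traj[traj$frame == f, ]

#' Read / write a trajectory as a whitespace table
#'
#' Columns `frame helix resnum role x y z`, one row per bead, `#` comments
#' ignored.
#'
#' @param path File path.
#' @param dt,box,normal_axis See [cg_trajectory()].
#' @return `read_cg_table()` returns a `cg_trajectory`; the writer returns
#'   `path` invisibly.
#' @export
read_cg_table <- function(path, dt = 1, box = c(100, 100, 100), normal_axis = "z") {
  d <- readr::read_table(path, comment = "#", show_col_types = FALSE,
                         col_names = c("frame", "helix", "resno", "role",
                                       "x", "y", "z"))
  cg_trajectory(d, dt = dt, box = box, normal_axis = normal_axis)
}

#' @rdname read_cg_table
#' @param traj A [cg_trajectory()].
#' @export
write_cg_table <- function(traj, path) {
  writeLines(sprintf("%6d %s %4d %-9s %10.4f %10.4f %10.4f",
                     traj$frame, traj$helix, traj$resno, traj$role,
                     traj$x, traj$y, traj$z), path)
  invisible(path)
}

#' Fit a helix axis from backbone beads
#'
#' Sliding-window (4-residue) centroids are computed along the sequence and
#' the principal direction of the centroids is taken by least squares; the
#' windowing suppresses the helical wobble of individual beads. The direction
#' is oriented N-to-C. Set `window = 1` for a plain principal component on
#' the raw beads.
#'
#' @param beads Beads of one helix in one frame (rows of a [cg_trajectory()]).
#' @param window Centroid window in residues (default 4).
#' @return A `helix_axis` list: `centroid`, `direction` (unit, N->C), `span`.
#' @export
fit_helix_axis <- function(beads, window = 4L) {
  bb <- beads[beads$role == "backbone", ]
  bb <- arrange(bb, .data$resno)
  if (nrow(bb) < 7)
    abort("need >= 7 backbone beads to fit an axis", class = "helixswitch_insufficient_data")
  xyz <- as.matrix(bb[, c("x", "y", "z")])
  n <- nrow(xyz)
  w <- min(window, n)
  cent <- t(vapply(seq_len(n - w + 1),
                   function(i) colMeans(xyz[i:(i + w - 1), , drop = FALSE]),
                   numeric(3)))
  pc <- prcomp(cent, center = TRUE, scale. = FALSE)
  dir <- pc$rotation[, 1]
  if (sum(dir * (cent[nrow(cent), ] - cent[1, ])) < 0) dir <- -dir
  structure(list(centroid = colMeans(cent), direction = as.numeric(vec_unit(dir)),
                 span = range(bb$resno)),
            class = "helix_axis")
}

#' Membrane-plane interhelical distance
#'
#' Euclidean distance between the two axis centroids after removing the
#' component along the membrane normal, so vertical drift does not enter.
#'
#' @param axis_a,axis_b [fit_helix_axis()] results from the same frame.
#' @param membrane_normal Unit vector of the membrane normal (default z).
#' @return Distance in angstroms.
#' @export
interhelical_distance <- function(axis_a, axis_b, membrane_normal = c(0, 0, 1)) {
  nrm <- vec_unit(membrane_normal)
  d <- axis_b$centroid - axis_a$centroid
  d <- d - sum(d * nrm) * nrm
  vec_norm(d)
}

#' Signed interhelical crossing angle
#'
#' The magnitude is the angle between the axis directions folded to at most
#' 90 degrees; the sign is the chirality of the dihedral of the two axes
#' about their line of closest approach (the torsion of
#' `a1+u -> a1 -> a2 -> a2+v` where `a1`, `a2` are the closest-approach
#' points). Negative angles correspond to right-handed helix packing.
#' Exactly parallel axes give 0.
#'
#' @param axis_a,axis_b [fit_helix_axis()] results from the same frame.
#' @return Signed angle in degrees, in (-90, 90].
#' @export
crossing_angle <- function(axis_a, axis_b) {
  u <- axis_a$direction
  v <- axis_b$direction
  if (sum(u * v) < 0) v <- -v  # fold to <= 90 degrees
  w <- vec_cross(u, v)
  if (vec_norm(w) < 1e-10) return(0)
  # closest-approach points of the two axis lines
  p <- axis_b$centroid - axis_a$centroid
  uv <- sum(u * v)
  s <- (sum(p * u) - sum(p * v) * uv) / (1 - uv^2)
  t <- (sum(p * u) * uv - sum(p * v)) / (1 - uv^2)
  a1 <- axis_a$centroid + s * u
  a2 <- axis_b$centroid + t * v
  ang <- dihedral_angle(a1 + u, a1, a2, a2 + v)
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

min_interhelix_distance <- function(fb) {
  a <- as.matrix(fb[fb$helix == unique(fb$helix)[1], c("x", "y", "z")])
  b <- as.matrix(fb[fb$helix != unique(fb$helix)[1], c("x", "y", "z")])
  min_cross_dist(a, b)
}

#' Detect the initial encounter and dimer intervals
#'
#' The encounter is the first frame whose minimum inter-helix bead distance
#' is at most `contact_cutoff`. Dimer intervals are maximal runs of frames
#' satisfying the contact condition (single-frame gaps tolerated) that last
#' at least `persistence_frames`. The per-frame signed crossing angle is
#' reported only inside dimer intervals.
#'
#' @param traj A [cg_trajectory()].
#' @param contact_cutoff Angstroms (default 6, the coarse-grained bead scale).
#' @param persistence_frames Minimum dimer length in frames (default 10).
#' @return A `dimer_timeline` list: `frames` (tibble with `frame`,
#'   `distance`, `min_bead_distance`, `in_dimer`, `angle`), `encounter_frame`
#'   (or `NA`), `intervals` (tibble `start`, `end`), plus the parameters.
#' @export
detect_encounter_and_dimers <- function(traj, contact_cutoff = 6,
                                        persistence_frames = 10L) {
  stopifnot(inherits(traj, "cg_trajectory"))
  frames <- traj_frames(traj)
  nrm <- c(0, 0, 0); nrm[normal_index(traj)] <- 1
  helices <- sort(unique(traj$helix))
  per <- map(frames, function(f) {
    fb <- frame_beads(traj, f)
    axa <- fit_helix_axis(fb[fb$helix == helices[1], ])
    axb <- fit_helix_axis(fb[fb$helix == helices[2], ])
    tibble(frame = f,
           distance = interhelical_distance(axa, axb, nrm),
           min_bead_distance = min_interhelix_distance(fb),
           angle_raw = crossing_angle(axa, axb))
  })
  d <- list_rbind(per)
  contact <- d$min_bead_distance <= contact_cutoff
  enc <- if (any(contact)) d$frame[which(contact)[1]] else NA_integer_
  # tolerate single-frame gaps inside a contact stretch
  filled <- contact
  if (length(filled) > 2) {
    gap <- which(!filled[-c(1, length(filled))]) + 1L
    gap <- gap[filled[gap - 1L] & filled[gap + 1L]]
    filled[gap] <- TRUE
  }
  runs <- rle(filled)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= persistence_frames
  intervals <- tibble(start = d$frame[starts[keep]], end = d$frame[ends[keep]])
  in_dimer <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(intervals)))
    in_dimer <- in_dimer | (d$frame >= intervals$start[i] & d$frame <= intervals$end[i])
  out <- list(
    frames = tibble(frame = d$frame, distance = d$distance,
                    min_bead_distance = d$min_bead_distance,
                    in_dimer = in_dimer,
                    angle = ifelse(in_dimer, d$angle_raw, NA_real_)),
    encounter_frame = enc,
    intervals = intervals,
    contact_cutoff = contact_cutoff,
    persistence_frames = persistence_frames,
    dt = attr(traj, "dt")
  )
  class(out) <- "dimer_timeline"
  out
}

#' @export
print.dimer_timeline <- function(x, ...) {
  cat(sprintf("<dimer_timeline> %d frames; encounter at frame %s; %d dimer interval(s)\n",
              nrow(x$frames), ifelse(is.na(x$encounter_frame), "none",
                                     x$encounter_frame), nrow(x$intervals)))
  invisible(x)
}

#' @export
tidy.dimer_timeline <- function(x, ...) x$frames

#' @export
glance.dimer_timeline <- function(x, ...) {
  tibble(n_frames = nrow(x$frames),
         encounter_frame = x$encounter_frame,
         n_intervals = nrow(x$intervals),
         n_dimer_frames = sum(x$frames$in_dimer),
         median_angle = median(x$frames$angle, na.rm = TRUE))
}

#' Plot interhelical distance and dimer intervals over time
#' @param object A `dimer_timeline`.
#' @param ... Unused.
#' @export
autoplot.dimer_timeline <- function(object, ...) {
  d <- object$frames
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$frame, .data$distance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "interhelical distance (Å)") +
    ggplot2::theme_minimal()
  if (nrow(object$intervals) > 0)
    p <- p + ggplot2::geom_rect(
      data = object$intervals,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  if (!is.na(object$encounter_frame))
    p <- p + ggplot2::geom_vline(xintercept = object$encounter_frame,
                                 linetype = 2, colour = "red")
  p
}

#' Interface-motif contact profile
#'
#' For every frame, the distance from each side-chain bead of the motif
#' residues on one helix to the centre (mean side-chain bead position) of the
#' motif on the other helix, in both directions.
#'
#' @param traj A [cg_trajectory()].
#' @param motif Integer author residue numbers of the interface motif
#'   (default 282:286, the five-valine run).
#' @return A tibble: `frame`, `direction` ("A_to_B"/"B_to_A"), `resno`,
#'   `distance`.
#' @export
motif_contact_profile <- function(traj, motif = 282:286) {
  stopifnot(inherits(traj, "cg_trajectory"))
  helices <- sort(unique(traj$helix))
  sc <- traj[traj$role == "sidechain" & traj$resno %in% motif, ]
  have <- sc |> distinct(.data$helix, .data$resno)
  for (h in helices) {
    missing <- setdiff(motif, have$resno[have$helix == h])
    if (length(missing) > 0)
      abort(sprintf("helix %s lacks side-chain beads for motif residue(s) %s",
                    h, paste(missing, collapse = ",")),
            class = "helixswitch_structure_error")
  }
  centres <- sc |>
    group_by(.data$frame, .data$helix) |>
    summarise(cx = mean(.data$x), cy = mean(.data$y), cz = mean(.data$z),
              .groups = "drop")
  other <- setNames(rev(helices), helices)
  sc |>
    left_join(centres |> mutate(helix = other[.data$helix]),
              by = c("frame", "helix")) |>
    mutate(direction = paste0(.data$helix, "_to_", other[.data$helix]),
           distance = sqrt((.data$x - .data$cx)^2 + (.data$y - .data$cy)^2 +
                             (.data$z - .data$cz)^2)) |>
    select("frame", "direction", "resno", "distance") |>
    arrange(.data$frame, .data$direction, .data$resno)
}

#' Classify the dimer orientation of a frame as symmetric or asymmetric
#'
#' A frame is symmetric when the two directions of the motif contact profile
#' mirror each other: `max_k |d(k, A->B) - d(k, B->A)| <= tolerance`.
#'
#' @param profile Output of [motif_contact_profile()] (any subset of frames).
#' @param tolerance Angstroms (default 2).
#' @return A tibble: `frame`, `max_asymmetry`, `orientation`.
#' @export
classify_orientation <- function(profile, tolerance = 2) {
  wide <- profile |>
    pivot_wider(names_from = "direction", values_from = "distance")
  dirs <- setdiff(names(wide), c("frame", "resno"))
  stopifnot(length(dirs) == 2)
  wide |>
    group_by(.data$frame) |>
    summarise(max_asymmetry = max(abs(.data[[dirs[1]]] - .data[[dirs[2]]])),
              .groups = "drop") |>
    mutate(orientation = ifelse(.data$max_asymmetry <= tolerance,
                                "symmetric", "asymmetric"))
}

#' Summary of the crossing-angle distribution over dimer frames
#'
#' Median angle over dimer frames, a histogram at the given bin width, and
#' the number of modes: local maxima of the Gaussian-smoothed (3-bin window)
#' histogram exceeding 10 percent of the global maximum.
#'
#' @param timeline A `dimer_timeline` from [detect_encounter_and_dimers()],
#'   or a numeric vector of angles.
#' @param bin_width Histogram bin width in degrees (default 5).
#' @return An `angle_summary` list: `median`, `n_modes`, `n`, `histogram`
#'   (tibble `mid`, `count`, `smoothed`), `empty` flag.
#' @export
angle_distribution_summary <- function(timeline, bin_width = 5) {
  angles <- if (inherits(timeline, "dimer_timeline"))
    timeline$frames$angle[timeline$frames$in_dimer] else as.numeric(timeline)
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0) {
    out <- list(median = NA_real_, n_modes = 0L, n = 0L,
                histogram = tibble(mid = double(), count = integer(),
                                   smoothed = double()),
                empty = TRUE)
    class(out) <- "angle_summary"
    return(out)
  }
  breaks <- seq(floor(min(angles) / bin_width) * bin_width - bin_width,
                ceiling(max(angles) / bin_width) * bin_width + bin_width,
                by = bin_width)
  counts <- as.integer(table(cut(angles, breaks, right = FALSE)))
  mids <- head(breaks, -1) + bin_width / 2
  # Gaussian smoothing over a 3-bin window (sd = 1 bin)
  k <- dnorm(-1:1)
  k <- k / sum(k)
  padded <- c(0, counts, 0)
  smoothed <- vapply(seq_along(counts),
                     function(i) sum(padded[i:(i + 2)] * k), numeric(1))
  thresh <- 0.1 * max(smoothed)
  sm <- c(-Inf, smoothed, -Inf)
  modes <- sum(vapply(seq_along(smoothed), function(i) {
    sm[i + 1] > thresh && sm[i + 1] >= sm[i] && sm[i + 1] > sm[i + 2]
  }, logical(1)))
  out <- list(median = median(angles), n_modes = as.integer(modes),
              n = length(angles),
              histogram = tibble(mid = mids, count = counts, smoothed = smoothed),
              empty = FALSE)
  class(out) <- "angle_summary"
  out
}

#' @export
print.angle_summary <- function(x, ...) {
  if (x$empty) cat("<angle_summary> no dimer frames\n")
  else cat(sprintf("<angle_summary> median %.1f deg over %d frames; %d mode(s)\n",
                   x$median, x$n, x$n_modes))
  invisible(x)
}

#' @export
glance.angle_summary <- function(x, ...) {
  tibble(median = x$median, n_modes = x$n_modes, n = x$n, empty = x$empty)
}

#' Plot the crossing-angle histogram
#' @param object An `angle_summary`.
#' @param ... Unused.
#' @export
autoplot.angle_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$mid[1:2]) * 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "red") +
    ggplot2::geom_vline(xintercept = object$median, linetype = 2) +
    ggplot2::labs(x = "crossing angle (deg)", y = "frames") +
    ggplot2::theme_minimal()
}

#' Fraction of dimer frames whose closest contact lies in the motif
#'
#' For each dimer frame, the closest inter-helix side-chain bead pair is
#' found; the reported fraction is the share of dimer frames in which both
#' residues of that pair lie inside the motif.
#'
#' @param traj A [cg_trajectory()].
#' @param timeline Matching `dimer_timeline`.
#' @param motif Integer residue numbers (default 282:286).
#' @return A one-row tibble: `fraction`, `n_dimer_frames`, `defined`.
#' @export
residue_run_interface_check <- function(traj, timeline, motif = 282:286) {
  stopifnot(inherits(traj, "cg_trajectory"), inherits(timeline, "dimer_timeline"))
  dimer_frames <- timeline$frames$frame[timeline$frames$in_dimer]
  if (length(dimer_frames) == 0)
    return(tibble(fraction = NA_real_, n_dimer_frames = 0L, defined = FALSE))
  helices <- sort(unique(traj$helix))
  hits <- map_lgl(dimer_frames, function(f) {
    fb <- frame_beads(traj, f)
    sc <- fb[fb$role == "sidechain", ]
    a <- sc[sc$helix == helices[1], ]
    b <- sc[sc$helix == helices[2], ]
    am <- as.matrix(a[, c("x", "y", "z")])
    bm <- as.matrix(b[, c("x", "y", "z")])
    d2 <- outer(rowSums(am^2), rowSums(bm^2), `+`) - 2 * tcrossprod(am, bm)
    ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    a$resno[ij[1]] %in% motif && b$resno[ij[2]] %in% motif
  })
  tibble(fraction = mean(hits), n_dimer_frames = length(hits), defined = TRUE)
}
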