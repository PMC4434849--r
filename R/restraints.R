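# NOE upper-distance-limit restraints and backbone torsion restraints, in the
# CYANA-style plain-text dialects (.upl / .aco), plus the classification by
# residue separation and the ensemble violation check.

#' Construct a restraint list
#'
#' @param distance A data frame with columns `res_i`, `atom_i`, `res_j`,
#'   `atom_j`, `upper` (angstroms); residue-name columns `resname_i`,
#'   `resname_j` are optional and kept if present.
#' @param torsion A data frame with columns `resno`, `angle` ("PHI"/"PSI"),
#'   `lower`, `upper` (degrees in (-180, 180], lower <= upper after
#'   unwrapping).
#' @return A `restraint_list`.
#' @export
restraint_list <- function(distance = NULL, torsion = NULL) {
  if (is.null(distance))
    distance <- tibble(res_i = integer(), atom_i = character(),
                       res_j = integer(), atom_j = character(), upper = double())
  distance <- as_tibble(distance)
  if (nrow(distance) > 0 && any(distance$upper <= 0))
    abort("distance upper bounds must be > 0", class = "helixswitch_input_error")
  if (is.null(torsion))
    torsion <- tibble(resno = integer(), angle = character(),
                      lower = double(), upper = double())
  torsion <- as_tibble(torsion)
  structure(list(distance = distance, torsion = torsion), class = "restraint_list")
}

#' @export
print.restraint_list <- function(x, ...) {
  cat(sprintf("<restraint_list> %d distance, %d torsion restraints\n",
              nrow(x$distance), nrow(x$torsion)))
  invisible(x)
}

#' Read / write CYANA-style restraint files
#'
#' `.upl` columns: `res_i resname_i atom_i res_j resname_j atom_j upper_A`;
#' `.aco` columns: `resno resname angle lower upper`. Whitespace separated,
#' 1-based author numbering, `#` comments ignored.
#'
#' @param path File path.
#' @return `read_upl()` / `read_aco()` return a [restraint_list()] (with only
#'   the respective part populated); writers return `path` invisibly.
#' @export
read_upl <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(restraint_list())
  f <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(f, length, integer(1)) < 7)
  if (length(bad) > 0)
    abort(sprintf(".upl line %d has fewer than 7 fields", bad[1]),
          class = "helixswitch_input_error")
  restraint_list(distance = tibble(
    res_i = as.integer(vapply(f, `[`, "", 1)),
    resname_i = vapply(f, `[`, "", 2),
    atom_i = vapply(f, `[`, "", 3),
    res_j = as.integer(vapply(f, `[`, "", 4)),
    resname_j = vapply(f, `[`, "", 5),
    atom_j = vapply(f, `[`, "", 6),
    upper = as.numeric(vapply(f, `[`, "", 7))
  ))
}

#' @rdname read_upl
#' @export
read_aco <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(restraint_list())
  f <- strsplit(lines, "[[:space:]]+")
  restraint_list(torsion = tibble(
    resno = as.integer(vapply(f, `[`, "", 1)),
    resname = vapply(f, `[`, "", 2),
    angle = toupper(vapply(f, `[`, "", 3)),
    lower = as.numeric(vapply(f, `[`, "", 4)),
    upper = as.numeric(vapply(f, `[`, "", 5))
  ))
}

#' @rdname read_upl
#' @param restraints A [restraint_list()].
#' @export
write_upl <- function(restraints, path) {
  d <- restraints$distance
  rn_i <- if ("resname_i" %in% names(d)) d$resname_i else rep("UNK", nrow(d))
  rn_j <- if ("resname_j" %in% names(d)) d$resname_j else rep("UNK", nrow(d))
  writeLines(sprintf("%4d %-4s %-5s %4d %-4s %-5s %7.2f",
                     d$res_i, rn_i, d$atom_i, d$res_j, rn_j, d$atom_j, d$upper),
             path)
  invisible(path)
}

#' @rdname read_upl
#' @export
write_aco <- function(restraints, path) {
  d <- restraints$torsion
  rn <- if ("resname" %in% names(d)) d$resname else rep("UNK", nrow(d))
  writeLines(sprintf("%4d %-4s %-4s %8.1f %8.1f", d$resno, rn, d$angle,
                     d$lower, d$upper), path)
  invisible(path)
}

#' Classify NOE restraints by residue separation
#'
#' Intra-residue |i-j| = 0, sequential |i-j| = 1, medium-range 2 <= |i-j| <= 4,
#' long-range |i-j| >= 5 (the standard NMR convention). The partition is
#' exhaustive and disjoint; counts sum to the total.
#'
#' @param restraints A [restraint_list()].
#' @return A one-row tibble: `intra`, `sequential`, `medium`, `long`, `total`.
#' @export
classify_noe_restraints <- function(restraints) {
  stopifnot(inherits(restraints, "restraint_list"))
  sep <- abs(restraints$distance$res_i - restraints$distance$res_j)
  tibble(intra = sum(sep == 0), sequential = sum(sep == 1),
         medium = sum(sep >= 2 & sep <= 4), long = sum(sep >= 5),
         total = length(sep))
}

# circular membership test for torsion bounds (degrees)
angle_in_range <- function(x, lower, upper) {
  wrap <- function(a) ((a + 180) %% 360) - 180
  width <- wrap(upper - lower) %% 360
  if (width == 0 && upper != lower) width <- 360
  off <- (x - lower) %% 360
  off <= width + 1e-9
}

#' Check restraint violations over an ensemble
#'
#' A distance restraint is violated in a model when the model distance
#' exceeds `upper + dist_tol` (the boundary itself is not a violation); a
#' torsion restraint when the dihedral falls outside
#' `[lower - torsion_tol, upper + torsion_tol]`, compared circularly.
#' Restraints whose atoms cannot be resolved are skipped with a warning and
#' counted separately.
#'
#' @param ensemble A [structure_ensemble()].
#' @param restraints A [restraint_list()].
#' @param dist_tol Distance tolerance in angstroms (default 0.2).
#' @param torsion_tol Torsion tolerance in degrees (default 5).
#' @return A tibble, one row per model: `model`, `n_distance_viol`,
#'   `max_distance_viol`, `n_torsion_viol`, `max_torsion_viol`, `n_skipped`.
#' @export
check_violations <- function(ensemble, restraints, dist_tol = 0.2, torsion_tol = 5) {
  stopifnot(inherits(ensemble, "structure_ensemble"),
            inherits(restraints, "restraint_list"))
  models <- sort(unique(ensemble$model))
  rows <- map(models, function(m) {
    md <- ensemble[ensemble$model == m, ]
    skipped <- 0L
    dviol <- c()
    d <- restraints$distance
    for (i in seq_len(nrow(d))) {
      a <- atom_xyz(md, d$res_i[i], d$atom_i[i])
      b <- atom_xyz(md, d$res_j[i], d$atom_j[i])
      if (is.null(a) || is.null(b)) { skipped <- skipped + 1L; next }
      excess <- vec_norm(a - b) - (d$upper[i] + dist_tol)
      if (excess > 1e-9) dviol <- c(dviol, excess + dist_tol)  # report vs bound
    }
    tviol <- c()
    t <- restraints$torsion
    if (nrow(t) > 0) {
      dih <- backbone_dihedrals(md)
      for (i in seq_len(nrow(t))) {
        row <- dih[dih$resno == t$resno[i], ]
        val <- if (nrow(row) == 0) NA_real_
               else if (t$angle[i] == "PHI") row$phi else row$psi
        if (is.na(val)) { skipped <- skipped + 1L; next }
        if (!angle_in_range(val, t$lower[i] - torsion_tol, t$upper[i] + torsion_tol)) {
          dev <- min(abs(((val - t$lower[i] + 180) %% 360) - 180),
                     abs(((val - t$upper[i] + 180) %% 360) - 180))
          tviol <- c(tviol, dev)
        }
      }
    }
    tibble(model = m,
           n_distance_viol = length(dviol),
           max_distance_viol = if (length(dviol)) max(dviol) else 0,
           n_torsion_viol = length(tviol),
           max_torsion_viol = if (length(tviol)) max(tviol) else 0,
           n_skipped = skipped)
  })
  out <- list_rbind(rows)
  total_skipped <- sum(out$n_skipped)
  if (total_skipped > 0)
    warn(sprintf("%d restraint(s) with unresolvable atoms were skipped", total_skipped))
  out
}
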