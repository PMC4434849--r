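# Circular dichroism processing: raw millidegree spectra are blank-subtracted
# and scan-averaged, converted to mean residue ellipticity (MRE,
# deg cm^2 dmol^-1), and summarised by the classic two-state helix/coil
# estimator at 222 nm.

#' Construct a CD spectrum
#'
#' A `cd_spectrum` is a tibble with columns `wavelength_nm` and `signal`,
#' plus attributes recording the signal units (`"raw_mdeg"` for raw
#' millidegrees, `"mre"` for mean residue ellipticity in deg cm^2 dmol^-1)
#' and the sample metadata needed for unit conversion.
#'
#' @param wavelength_nm Strictly monotone numeric wavelength grid (nm).
#' @param signal Numeric signal, one value per wavelength.
#' @param units One of `"raw_mdeg"`, `"mre"`.
#' @param conc_mM Peptide concentration in millimolar.
#' @param n_residues Number of peptide residues.
#' @param path_cm Cuvette path length in cm.
#' @param tfe_percent Co-solvent (TFE) volume percent, 0-100.
#' @return A `cd_spectrum` tibble.
#' @export
cd_spectrum <- function(wavelength_nm, signal, units = c("raw_mdeg", "mre"),
                        conc_mM = NA_real_, n_residues = NA_integer_,
                        path_cm = NA_real_, tfe_percent = NA_real_) {
  units <- match.arg(units)
  stopifnot(length(wavelength_nm) == length(signal), length(wavelength_nm) >= 1)
  d <- diff(wavelength_nm)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0)))
    abort("wavelength grid must be strictly monotone", class = "helixswitch_grid_error")
  if (!is.na(conc_mM) && conc_mM <= 0) abort("conc_mM must be > 0", class = "helixswitch_metadata_error")
  if (!is.na(path_cm) && path_cm <= 0) abort("path_cm must be > 0", class = "helixswitch_metadata_error")
  if (!is.na(n_residues) && n_residues < 1) abort("n_residues must be >= 1", class = "helixswitch_metadata_error")
  if (!is.na(tfe_percent) && (tfe_percent < 0 || tfe_percent > 100))
    abort("tfe_percent must be in [0, 100]", class = "helixswitch_metadata_error")
  out <- tibble(wavelength_nm = as.numeric(wavelength_nm), signal = as.numeric(signal))
  attr(out, "units") <- units
  attr(out, "sample") <- list(conc_mM = conc_mM, n_residues = as.integer(n_residues),
                              path_cm = path_cm, tfe_percent = tfe_percent)
  class(out) <- c("cd_spectrum", class(out))
  out
}

cd_units <- function(x) attr(x, "units")
cd_sample <- function(x) attr(x, "sample")

reclass_cd <- function(data, template, units = cd_units(template)) {
  attr(data, "units") <- units
  attr(data, "sample") <- cd_sample(template)
  class(data) <- unique(c("cd_spectrum", class(data)))
  data
}

check_same_grid <- function(a, b) {
  if (length(a$wavelength_nm) != length(b$wavelength_nm) ||
      any(abs(a$wavelength_nm - b$wavelength_nm) > 1e-9))
    abort("wavelength grids differ", class = "helixswitch_grid_error")
}

#' Subtract a blank (baseline) spectrum
#'
#' Pointwise subtraction of a buffer blank recorded on the same grid, same
#' units and at the same TFE percentage. Sample metadata are retained.
#'
#' @param sample,blank Raw (`raw_mdeg`) [cd_spectrum()] objects.
#' @return A blank-subtracted `cd_spectrum` (raw mdeg).
#' @export
subtract_blank <- function(sample, blank) {
  stopifnot(inherits(sample, "cd_spectrum"), inherits(blank, "cd_spectrum"))
  if (cd_units(sample) != "raw_mdeg" || cd_units(blank) != "raw_mdeg")
    abort("blank subtraction operates on raw mdeg spectra", class = "helixswitch_units_error")
  check_same_grid(sample, blank)
  tfe_s <- cd_sample(sample)$tfe_percent
  tfe_b <- cd_sample(blank)$tfe_percent
  if (!is.na(tfe_s) && !is.na(tfe_b) && abs(tfe_s - tfe_b) > 1e-9)
    abort("sample and blank TFE percentages differ", class = "helixswitch_metadata_error")
  out <- sample
  out$signal <- sample$signal - blank$signal
  out
}

#' Average replicate scans
#'
#' Pointwise arithmetic mean of replicate scans sharing grid, units and
#' metadata.
#'
#' @param scans A list of [cd_spectrum()] objects.
#' @return A `cd_spectrum` with the averaged signal.
#' @export
average_scans <- function(scans) {
  if (!is.list(scans) || length(scans) == 0 || !all(map_lgl(scans, inherits, "cd_spectrum")))
    abort("scans must be a non-empty list of cd_spectrum objects", class = "helixswitch_input_error")
  ref <- scans[[1]]
  for (s in scans[-1]) {
    check_same_grid(ref, s)
    if (cd_units(s) != cd_units(ref)) abort("scan units differ", class = "helixswitch_units_error")
  }
  out <- ref
  out$signal <- Reduce(`+`, map(scans, function(s) s$signal)) / length(scans)
  out
}

#' Convert raw millidegrees to mean residue ellipticity
#'
#' Applies the standard normalisation
#' \deqn{[\theta](\lambda) = \theta_{raw}(\lambda) / (10 \cdot c(M) \cdot N \cdot l)}
#' with the concentration metadata stored in millimolar (converted to molar
#' internally), `N` the residue count and `l` the path length in cm, so the
#' result is in deg cm^2 dmol^-1 per residue.
#'
#' @param raw A raw (`raw_mdeg`) [cd_spectrum()] with complete metadata.
#' @return A `cd_spectrum` with `units = "mre"`.
#' @export
to_mean_residue_ellipticity <- function(raw) {
  stopifnot(inherits(raw, "cd_spectrum"))
  if (cd_units(raw) != "raw_mdeg")
    abort("input must be a raw mdeg spectrum", class = "helixswitch_units_error")
  s <- cd_sample(raw)
  if (is.na(s$conc_mM) || is.na(s$n_residues) || is.na(s$path_cm))
    abort("conc_mM, n_residues and path_cm metadata are required",
          class = "helixswitch_metadata_error")
  denom <- 10 * (s$conc_mM / 1000) * s$n_residues * s$path_cm
  out <- raw
  out$signal <- raw$signal / denom
  attr(out, "units") <- "mre"
  out
}

#' Two-state helix/coil reference values
#'
#' Reference mean residue ellipticities at 222 nm for a random coil
#' (640 deg cm^2 dmol^-1) and a fully alpha-helical peptide
#' (-42500 deg cm^2 dmol^-1).
#'
#' @param theta_coil,theta_helix Reference MRE values (deg cm^2 dmol^-1).
#' @param wavelength Reference wavelength (nm), 222 by default.
#' @return A `helicity_reference` list.
#' @export
helicity_reference <- function(theta_coil = 640, theta_helix = -42500,
                               wavelength = 222) {
  if (!(theta_helix < theta_coil))
    abort("theta_helix must be below theta_coil", class = "helixswitch_degenerate_reference")
  structure(list(theta_coil = theta_coil, theta_helix = theta_helix,
                 wavelength = wavelength), class = "helicity_reference")
}

#' Fractional helix content from the 222 nm ellipticity
#'
#' Two-state estimator
#' \deqn{f_H = ([\theta]_{obs} - [\theta]_{coil}) / ([\theta]_{helix} - [\theta]_{coil})}
#' Values outside \[0, 1\] are clamped and flagged rather than erroring,
#' since real baselines can overshoot the reference values.
#'
#' @param theta_obs_222 Observed MRE at 222 nm (deg cm^2 dmol^-1), or a
#'   `cd_spectrum` in MRE units from which the 222 nm point is taken
#'   (nearest grid point).
#' @param ref A [helicity_reference()].
#' @return A one-row tibble: `f_helix` (clamped), `f_helix_raw`, `clamped`,
#'   `theta_obs`.
#' @export
#' @examples
#' fractional_helicity(-42500)$f_helix  # 1
#' fractional_helicity(640)$f_helix     # 0
fractional_helicity <- function(theta_obs_222, ref = helicity_reference()) {
  stopifnot(inherits(ref, "helicity_reference"))
  if (inherits(theta_obs_222, "cd_spectrum")) {
    if (cd_units(theta_obs_222) != "mre")
      abort("spectrum must be in MRE units", class = "helixswitch_units_error")
    i <- which.min(abs(theta_obs_222$wavelength_nm - ref$wavelength))
    theta_obs_222 <- theta_obs_222$signal[i]
  }
  if (abs(ref$theta_helix - ref$theta_coil) < 1e-12)
    abort("degenerate reference: theta_helix equals theta_coil",
          class = "helixswitch_degenerate_reference")
  f_raw <- (theta_obs_222 - ref$theta_coil) / (ref$theta_helix - ref$theta_coil)
  clamped <- f_raw < -1e-9 | f_raw > 1 + 1e-9  # ignore fp noise at the ends
  if (any(clamped)) warn("fractional helicity outside [0, 1]; clamped")
  tibble(f_helix = pmin(pmax(f_raw, 0), 1), f_helix_raw = f_raw,
         clamped = clamped, theta_obs = theta_obs_222)
}

#' Report local minima of an MRE spectrum
#'
#' A grid point is a local minimum when it is the strict minimum of a
#' sliding window of the given width centred on it. Minima are reported at
#' the nearest grid point, deepest first.
#'
#' @param mre A [cd_spectrum()] in MRE units.
#' @param window_nm Window width in nm (default 5; must be at least the grid
#'   step).
#' @return A tibble with columns `wavelength_nm` and `depth` (the signal at
#'   the minimum), sorted by depth (most negative first).
#' @export
report_minima <- function(mre, window_nm = 5) {
  stopifnot(inherits(mre, "cd_spectrum"))
  if (cd_units(mre) != "mre")
    abort("minima are reported on the MRE spectrum", class = "helixswitch_units_error")
  wl <- mre$wavelength_nm
  y <- mre$signal
  if (wl[1] > wl[length(wl)]) { wl <- rev(wl); y <- rev(y) }
  step <- min(diff(wl))
  if (window_nm < step || length(wl) < 3)
    abort("window must span at least one grid step of a >=3 point spectrum",
          class = "helixswitch_input_error")
  half <- window_nm / 2
  is_min <- map_lgl(seq_along(wl), function(i) {
    nb <- which(abs(wl - wl[i]) <= half + 1e-9)
    nb <- setdiff(nb, i)
    length(nb) > 0 && all(y[i] < y[nb]) &&
      i > 1 && i < length(wl)  # interior points only
  })
  tibble(wavelength_nm = wl[is_min], depth = y[is_min]) |>
    arrange(.data$depth)
}

#' Read / write a CD spectrum as CSV
#'
#' Two-column CSV `wavelength_nm,signal` with a header; metadata are supplied
#' via arguments on read and stored as comment-free sidecar-less attributes.
#'
#' @param path File path.
#' @param units,conc_mM,n_residues,path_cm,tfe_percent See [cd_spectrum()].
#' @return `read_cd_csv()` returns a `cd_spectrum`; `write_cd_csv()` returns
#'   `path` invisibly.
#' @export
read_cd_csv <- function(path, units = "raw_mdeg", conc_mM = NA_real_,
                        n_residues = NA_integer_, path_cm = NA_real_,
                        tfe_percent = NA_real_) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("wavelength_nm", "signal") %in% names(d)))
    abort("CSV must have columns wavelength_nm,signal", class = "helixswitch_input_error")
  cd_spectrum(d$wavelength_nm, d$signal, units = units, conc_mM = conc_mM,
              n_residues = n_residues, path_cm = path_cm, tfe_percent = tfe_percent)
}

#' @rdname read_cd_csv
#' @param spectrum A [cd_spectrum()].
#' @export
write_cd_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  readr::write_csv(tibble(wavelength_nm = spectrum$wavelength_nm,
                          signal = spectrum$signal), path)
  invisible(path)
}

#' Plot a CD spectrum
#'
#' @param object A [cd_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cd_spectrum <- function(object, ...) {
  ylab <- if (cd_units(object) == "mre")
    expression("[" * theta * "] (deg" ~ cm^2 ~ dmol^-1 * ")")
  else "ellipticity (mdeg)"
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength_nm, .data$signal)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = ylab) +
    ggplot2::theme_minimal()
}
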