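# Combined 1H/15N amide chemical shift perturbations between two states
# (e.g. phosphorylated vs non-phosphorylated peptide).

#' Construct / read an amide peak table
#'
#' One amide peak per residue: author residue number and 1H / 15N chemical
#' shifts in ppm. The CSV layout is `residue,dH_ppm,dN_ppm` with a header.
#'
#' @param residue Integer author residue numbers (unique).
#' @param dH_ppm,dN_ppm Proton / nitrogen shifts (ppm).
#' @return A `peak_table` tibble.
#' @export
peak_table <- function(residue, dH_ppm, dN_ppm) {
  if (anyDuplicated(residue))
    abort("duplicate residue in peak table", class = "helixswitch_input_error")
  out <- tibble(residue = as.integer(residue), dH_ppm = as.numeric(dH_ppm),
                dN_ppm = as.numeric(dN_ppm))
  class(out) <- unique(c("peak_table", class(out)))
  out
}

#' @rdname peak_table
#' @param path CSV file path.
#' @export
read_peak_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("residue", "dH_ppm", "dN_ppm") %in% names(d)))
    abort("CSV must have columns residue,dH_ppm,dN_ppm", class = "helixswitch_input_error")
  peak_table(d$residue, d$dH_ppm, d$dN_ppm)
}

#' Combined chemical shift perturbation per residue
#'
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}}
#' with the usual nitrogen scaling \eqn{\alpha = 0.14}. Residues present in
#' only one table are reported with `missing = TRUE` and `NA` perturbation.
#'
#' @param reference,perturbed [peak_table()] objects.
#' @param nitrogen_scale Scaling applied to the 15N shift difference.
#' @return A tibble: `residue`, `dd_H`, `dd_N`, `delta_delta`, `missing`.
#' @export
#' @examples
#' a <- peak_table(1:2, c(8.1, 8.2), c(118, 120))
#' b <- peak_table(1:2, c(8.2, 8.2), c(118, 120.5))
#' chemical_shift_perturbation(a, b)
chemical_shift_perturbation <- function(reference, perturbed, nitrogen_scale = 0.14) {
  stopifnot(inherits(reference, "peak_table"), inherits(perturbed, "peak_table"))
  all_res <- sort(union(reference$residue, perturbed$residue))
  d <- tibble(residue = all_res) |>
    left_join(rename(reference, rH = "dH_ppm", rN = "dN_ppm"), by = "residue") |>
    left_join(rename(perturbed, pH = "dH_ppm", pN = "dN_ppm"), by = "residue") |>
    mutate(dd_H = .data$pH - .data$rH,
           dd_N = .data$pN - .data$rN,
           delta_delta = sqrt(.data$dd_H^2 + (nitrogen_scale * .data$dd_N)^2),
           missing = is.na(.data$rH) | is.na(.data$pH)) |>
    select("residue", "dd_H", "dd_N", "delta_delta", "missing")
  class(d) <- unique(c("csp_table", class(d)))
  d
}

#' Plot per-residue chemical shift perturbations
#' @param object Result of [chemical_shift_perturbation()].
#' @param ... Unused.
#' @export
autoplot.csp_table <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !.data$missing),
                  ggplot2::aes(.data$residue, .data$delta_delta)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "residue", y = expression(Delta * delta ~ "(ppm)")) +
    ggplot2::theme_minimal()
}
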