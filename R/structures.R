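# NMR-style multi-model structures are kept as a flat atom table: one row
# per atom per model. All models must share the same atom roster, which makes
# ensemble statistics simple column arithmetic.

#' Construct a structure ensemble
#'
#' @param atoms A data frame with columns `model` (integer), `resno` (author
#'   residue number), `resname` (3-letter residue name, e.g. "GLU", "SEP" for
#'   phosphoserine), `atom` (atom name), `element`, `x`, `y`, `z` (angstroms).
#' @return A `structure_ensemble` tibble.
#' @export
structure_ensemble <- function(atoms) {
  req <- c("model", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    abort(paste("atoms must have columns", paste(req, collapse = ", ")),
          class = "helixswitch_structure_error")
  atoms <- as_tibble(atoms)[req]
  atoms$model <- as.integer(atoms$model)
  atoms$resno <- as.integer(atoms$resno)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    abort("coordinates must be finite", class = "helixswitch_structure_error")
  models <- sort(unique(atoms$model))
  if (length(models) < 1) abort("ensemble needs >= 1 model", class = "helixswitch_structure_error")
  rk <- paste(atoms$resno, atoms$resname, atoms$atom, sep = "|")
  rosters <- vapply(split(rk, atoms$model),
                    function(k) paste(sort(k), collapse = ";"), character(1))
  if (length(unique(rosters)) != 1)
    abort("all models must share an identical atom roster",
          class = "helixswitch_structure_error")
  atoms <- arrange(atoms, .data$model, .data$resno, .data$atom)
  class(atoms) <- unique(c("structure_ensemble", class(atoms)))
  atoms
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d model(s), %d atoms/model, residues %d-%d\n",
              n_models(x), sum(x$model == x$model[1]),
              min(x$resno), max(x$resno)))
  NextMethod()
}

#' Number of models in an ensemble
#' @param ensemble A [structure_ensemble()].
#' @export
n_models <- function(ensemble) length(unique(ensemble$model))

#' Extract one model
#' @param ensemble A [structure_ensemble()].
#' @param model Model number (defaults to the first).
#' @return A single-model `structure_ensemble`.
#' @export
get_model <- function(ensemble, model = NULL) {
  model <- model %||% min(ensemble$model)
  out <- ensemble[ensemble$model == model, ]
  class(out) <- unique(c("structure_ensemble", class(tibble())))
  out
}

# Coordinate matrix (n x 3) of one model under a selection; rows ordered by
# (resno, atom) so matched selections across models align.
coords_matrix <- function(model_atoms, atom_names = NULL, resno_range = NULL) {
  d <- model_atoms
  if (!is.null(atom_names)) d <- d[d$atom %in% atom_names, ]
  if (!is.null(resno_range)) d <- d[d$resno >= resno_range[1] & d$resno <= resno_range[2], ]
  d <- arrange(d, .data$resno, .data$atom)
  as.matrix(d[, c("x", "y", "z")])
}

atom_xyz <- function(model_atoms, resno, atom) {
  i <- which(model_atoms$resno == resno & model_atoms$atom == atom)
  if (length(i) == 0) return(NULL)
  as.numeric(model_atoms[i[1], c("x", "y", "z")])
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Read a multi-model PDB file as a structure ensemble
#'
#' Standard PDB with MODEL/ENDMDL blocks (single-model files give a one-model
#' ensemble). Parsing is delegated to \pkg{bio3d}. Insertion codes are
#' rejected; for alternate locations the first is kept.
#'
#' @param path Path to a PDB file.
#' @return A [structure_ensemble()].
#' @export
read_pdb_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & at$insert != ""))
    abort("insertion codes are not supported", class = "helixswitch_structure_error")
  keep <- is.na(at$alt) | at$alt == "" | at$alt == "A"
  at <- at[keep, ]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  idx <- which(keep)
  per_model <- map(seq_len(nrow(xyz)), function(m) {
    tibble(
      model = m,
      resno = as.integer(at$resno),
      resname = trimws(at$resid),
      atom = trimws(at$elety),
      element = ifelse(is.na(at$elesy) | trimws(at$elesy) == "",
                       substr(trimws(at$elety), 1, 1), trimws(at$elesy)),
      x = xyz[m, 3 * (idx - 1) + 1],
      y = xyz[m, 3 * (idx - 1) + 2],
      z = xyz[m, 3 * (idx - 1) + 3]
    )
  })
  structure_ensemble(list_rbind(per_model))
}

#' Write a structure ensemble as a multi-model PDB file
#'
#' @param ensemble A [structure_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  for (m in sort(unique(ensemble$model))) {
    d <- ensemble[ensemble$model == m, ]
    writeLines(sprintf("MODEL     %4d", m), con)
    name_fmt <- function(a) {
      # columns 13-16: element right-justified into 13-14 for 1-letter elements
      if (nchar(a) >= 4) substr(a, 1, 4) else sprintf(" %-3s", a)
    }
    lines <- vapply(seq_len(nrow(d)), function(i) {
      sprintf("ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
              i, name_fmt(d$atom[i]), substr(d$resname[i], 1, 3), d$resno[i],
              d$x[i], d$y[i], d$z[i], substr(d$element[i], 1, 2))
    }, character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
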