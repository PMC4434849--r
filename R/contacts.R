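# Side-chain contact analyses: ionic contacts between acidic oxygens and
# basic nitrogens (salt bridges, with ensemble frequencies) and hydrophobic
# clusters as connected components of a residue contact graph.

BASIC_GROUP_ATOMS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ")
ACIDIC_GROUP_ATOMS <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"),
                           SEP = c("O1P", "O2P", "O3P"))

# minimum pairwise distance between two coordinate matrices
min_cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

charged_groups <- function(model, table) {
  res <- model |> distinct(.data$resno, .data$resname)
  res <- res[res$resname %in% names(table), ]
  out <- list()
  for (i in seq_len(nrow(res))) {
    want <- table[[res$resname[i]]]
    d <- model[model$resno == res$resno[i] & model$atom %in% want, ]
    if (nrow(d) == 0) {
      warn(sprintf("charged residue %s%d has no side-chain group atoms; skipped",
                   res$resname[i], res$resno[i]))
      next
    }
    out[[length(out) + 1]] <- list(resno = res$resno[i], resname = res$resname[i],
                                   xyz = as.matrix(d[, c("x", "y", "z")]))
  }
  out
}

#' Detect salt bridges across an ensemble
#'
#' A salt bridge between an acidic and a basic residue exists in a model when
#' the minimum distance between any acidic side-chain oxygen (Glu OE1/OE2,
#' Asp OD1/OD2, phosphoserine O1P/O2P/O3P) and any basic side-chain nitrogen
#' (Arg NH1/NH2/NE, Lys NZ) is at most `cutoff`. The report gives, per pair,
#' the fraction of models in which the bridge is present, sorted by
#' decreasing frequency.
#'
#' @param ensemble A [structure_ensemble()].
#' @param cutoff Heavy-atom distance cutoff in angstroms (default 4).
#' @return A `saltbridge_report` tibble: `acidic_resno`, `acidic_resname`,
#'   `basic_resno`, `basic_resname`, `n_present`, `n_models`, `frequency`,
#'   and a list-column `present` of per-model logicals.
#' @export
detect_salt_bridges <- function(ensemble, cutoff = 4) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  models <- sort(unique(ensemble$model))
  per_model <- map(models, function(m) {
    md <- ensemble[ensemble$model == m, ]
    ac <- charged_groups(md, ACIDIC_GROUP_ATOMS)
    ba <- charged_groups(md, BASIC_GROUP_ATOMS)
    if (length(ac) == 0 || length(ba) == 0) return(NULL)
    rows <- list()
    for (a in ac) for (b in ba) {
      rows[[length(rows) + 1]] <- tibble(
        acidic_resno = a$resno, acidic_resname = a$resname,
        basic_resno = b$resno, basic_resname = b$resname,
        model = m, bridged = min_cross_dist(a$xyz, b$xyz) <= cutoff)
    }
    list_rbind(rows)
  })
  long <- list_rbind(per_model)
  if (is.null(long) || nrow(long) == 0) {
    out <- tibble(acidic_resno = integer(), acidic_resname = character(),
                  basic_resno = integer(), basic_resname = character(),
                  n_present = integer(), n_models = integer(),
                  frequency = double(), present = list())
  } else {
    out <- long |>
      group_by(.data$acidic_resno, .data$acidic_resname,
               .data$basic_resno, .data$basic_resname) |>
      summarise(n_present = sum(.data$bridged), n_models = dplyr::n(),
                frequency = mean(.data$bridged),
                present = list(.data$bridged), .groups = "drop") |>
      arrange(desc(.data$frequency), .data$acidic_resno, .data$basic_resno)
  }
  attr(out, "cutoff") <- cutoff
  class(out) <- unique(c("saltbridge_report", class(out)))
  out
}

#' @export
tidy.saltbridge_report <- function(x, ...) {
  x |>
    mutate(pair = paste0(.data$acidic_resname, .data$acidic_resno, "-",
                         .data$basic_resname, .data$basic_resno)) |>
    select("pair", "present") |>
    tidyr::unnest_longer("present", values_to = "bridged", indices_to = "model")
}

#' @export
glance.saltbridge_report <- function(x, ...) {
  tibble(n_pairs = nrow(x),
         n_bridged = sum(x$frequency > 0),
         top_frequency = if (nrow(x)) max(x$frequency) else NA_real_,
         cutoff = attr(x, "cutoff"))
}

#' Plot salt-bridge ensemble frequencies
#' @param object A `saltbridge_report`.
#' @param min_frequency Hide pairs never observed below this frequency.
#' @param ... Unused.
#' @export
autoplot.saltbridge_report <- function(object, min_frequency = 0.05, ...) {
  d <- object |>
    mutate(pair = paste0(.data$acidic_resname, .data$acidic_resno, "-",
                         .data$basic_resname, .data$basic_resno)) |>
    filter(.data$frequency >= min_frequency)
  ggplot2::ggplot(d, ggplot2::aes(stats::reorder(.data$pair, .data$frequency),
                                  .data$frequency)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ensemble frequency") +
    ggplot2::theme_minimal()
}

#' Detect hydrophobic side-chain clusters
#'
#' Builds a residue graph with an edge when the minimum distance between two
#' residues' side-chain heavy atoms is at most `contact_cutoff`, restricted
#' to a configurable residue-type set, and reports connected components of at
#' least `min_size` residues.
#'
#' @param model A single-model [structure_ensemble()].
#' @param contact_cutoff Angstroms (default 5).
#' @param min_size Minimum residues per cluster (default 3).
#' @param residue_types One-letter codes admitted to the graph. The default
#'   adds S to the classic hydrophobic set, since a serine methylene can pack
#'   into a small cluster.
#' @param min_seq_sep Minimum residue-number separation for an edge (default
#'   2: sequence-adjacent side chains are trivially close and are not
#'   evidence of packing).
#' @return A list of integer vectors of author residue numbers.
#' @export
detect_hydrophobic_clusters <- function(model, contact_cutoff = 5, min_size = 3,
                                        residue_types = c("A", "V", "L", "I", "M",
                                                          "F", "W", "Y", "P", "S"),
                                        min_seq_sep = 2) {
  stopifnot(inherits(model, "structure_ensemble"))
  if (n_models(model) != 1) model <- get_model(model)
  three <- c(A = "ALA", V = "VAL", L = "LEU", I = "ILE", M = "MET", F = "PHE",
             W = "TRP", Y = "TYR", P = "PRO", S = "SER", G = "GLY", C = "CYS",
             T = "THR", N = "ASN", Q = "GLN", D = "ASP", E = "GLU", K = "LYS",
             R = "ARG", H = "HIS")
  wanted <- unname(three[residue_types])
  side <- model[!model$atom %in% BACKBONE_ATOMS &
                  model$resname %in% wanted &
                  !model$resname %in% CAP_RESNAMES &
                  model$element != "H", ]
  resnos <- sort(unique(side$resno))
  if (length(resnos) < min_size) return(list())
  xyz_by_res <- map(resnos, function(r) as.matrix(side[side$resno == r, c("x", "y", "z")]))
  n <- length(resnos)
  edges <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(resnos[i] - resnos[j]) < min_seq_sep) next
    if (min_cross_dist(xyz_by_res[[i]], xyz_by_res[[j]]) <= contact_cutoff)
      edges[[length(edges) + 1]] <- c(i, j)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, unlist(edges))
  comp <- igraph::components(g)
  clusters <- split(resnos, comp$membership)
  clusters <- clusters[vapply(clusters, length, integer(1)) >= min_size]
  unname(map(clusters, sort))
}
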