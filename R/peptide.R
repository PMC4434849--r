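AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

BASIC_RESIDUES <- c("R", "K")   # His treated as neutral at pH 7.4
ACIDIC_RESIDUES <- c("D", "E")

#' Construct a peptide sequence with author numbering
#'
#' A `peptide_seq` carries a one-letter residue string, the author number of
#' its first residue (so a construct such as a 26-residue cytosolic tail can
#' be numbered 298-323), an optional set of phosphorylated positions and
#' terminal blocking-group flags. Phosphoserine is represented as a flag on
#' an ordinary S/T/Y, so purely sequence-level operations are
#' phosphorylation-agnostic unless they explicitly use the flags.
#'
#' The residue string may embed `(pX)` markers, e.g.
#' `"TNRRK(pS)GKYKKVEIKELGELRKEPSL"`, which are converted to phospho flags.
#'
#' @param residues One-letter amino-acid string (optionally with `(pX)`
#'   phospho markers).
#' @param start_number Author number of the first residue (default 1).
#' @param phospho_positions Integer vector of author-numbered phosphorylated
#'   positions; merged with any `(pX)` markers. Each must map to S, T or Y.
#' @param acetyl_n,amide_c Logical; N-acetyl / C-amide blocking groups.
#' @return An object of class `peptide_seq`.
#' @export
#' @examples
#' peptide_seq("TNRRK(pS)GKYKKVEIKELGELRKEPSL", start_number = 298)
peptide_seq <- function(residues, start_number = 1L, phospho_positions = integer(),
                        acetyl_n = FALSE, amide_c = FALSE) {
  stopifnot(is.character(residues), length(residues) == 1L)
  marked <- integer()
  # pull out (pX) markers
  while (grepl("\\(p[A-Za-z]\\)", residues)) {
    m <- regexpr("\\(p[A-Za-z]\\)", residues)
    pre <- substr(residues, 1L, m - 1L)
    letter <- toupper(substr(residues, m + 2L, m + 2L))
    marked <- c(marked, nchar(pre) + 1L)
    residues <- paste0(pre, letter, substr(residues, m + 4L, nchar(residues)))
  }
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) < 1L) abort("sequence must contain at least one residue",
                                  class = "helixswitch_invalid_sequence")
  letters <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(letters), AA1)
  if (length(bad) > 0) {
    abort(paste0("unknown residue letter(s): ", paste(bad, collapse = ", ")),
          class = "helixswitch_invalid_sequence")
  }
  start_number <- as.integer(start_number)
  phospho <- sort(unique(c(as.integer(phospho_positions), marked + start_number - 1L)))
  n <- nchar(residues)
  if (length(phospho) > 0) {
    idx <- phospho - start_number + 1L
    if (any(idx < 1L | idx > n)) {
      abort("phospho position outside sequence numbering", class = "helixswitch_range_error")
    }
    if (!all(letters[idx] %in% c("S", "T", "Y"))) {
      abort("phospho positions must map to S, T or Y", class = "helixswitch_invalid_sequence")
    }
  }
  structure(
    list(residues = residues, start_number = start_number,
         phospho_positions = phospho,
         caps = c(acetyl_n = acetyl_n, amide_c = amide_c)),
    class = "peptide_seq"
  )
}

#' @export
print.peptide_seq <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("<peptide_seq> %d residues, numbered %d-%d\n", n,
              x$start_number, x$start_number + n - 1L))
  cat(" ", x$residues, "\n")
  if (length(x$phospho_positions) > 0)
    cat("  phospho at:", paste(x$phospho_positions, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.peptide_seq <- function(x) nchar(x$residues)

seq_letters <- function(seq) strsplit(seq$residues, "")[[1]]

seq_numbers <- function(seq) seq$start_number + seq_len(nchar(seq$residues)) - 1L

#' Per-residue table of a peptide sequence
#'
#' @param x A [peptide_seq()].
#' @param ... Unused.
#' @return A tibble with columns `resno` (author number), `residue`
#'   (one-letter code) and `phospho` (logical).
#' @export
tidy.peptide_seq <- function(x, ...) {
  tibble(
    resno = seq_numbers(x),
    residue = seq_letters(x),
    phospho = seq_numbers(x) %in% x$phospho_positions
  )
}

#' Built-in study sequences
#'
#' The 26-residue Trop2 cytosolic tail (residues 298-323, N-terminally
#' acetylated; optionally phosphorylated at Ser303) and the 23-residue Trop2
#' transmembrane helix (residues 275-297, capped at both ends).
#'
#' @param phospho Logical; flag Ser303 as phosphorylated.
#' @return A [peptide_seq()].
#' @export
trop2_ic <- function(phospho = FALSE) {
  peptide_seq("TNRRKSGKYKKVEIKELGELRKEPSL", start_number = 298L,
              phospho_positions = if (phospho) 303L else integer(),
              acetyl_n = TRUE)
}

#' @rdname trop2_ic
#' @export
trop2_tm <- function() {
  peptide_seq("AGLIAVIVVVVVALVAGMAVLVI", start_number = 275L,
              acetyl_n = TRUE, amide_c = TRUE)
}

#' Census of ionizable residues
#'
#' Counts basic (R, K), acidic (D, E) and other residues. Histidine is
#' counted as "other" (mostly neutral at pH 7.4). Counts ignore phospho
#' flags.
#'
#' @param seq A [peptide_seq()].
#' @return A one-row tibble with columns `basic`, `acidic`, `other`, `length`.
#' @export
#' @examples
#' charge_census(trop2_ic())  # 9 basic, 4 acidic out of 26
charge_census <- function(seq) {
  stopifnot(inherits(seq, "peptide_seq"))
  letters <- seq_letters(seq)
  basic <- sum(letters %in% BASIC_RESIDUES)
  acidic <- sum(letters %in% ACIDIC_RESIDUES)
  tibble(basic = basic, acidic = acidic,
         other = length(letters) - basic - acidic,
         length = length(letters))
}

round_half_up <- function(x) floor(x + 0.5)

#' Percent of the sequence covered by an author-numbered span
#'
#' Used to summarise a secondary-structure span as a fraction of the whole
#' peptide, e.g. a nine-residue helix over a 26-mer is 35%.
#'
#' @param seq A [peptide_seq()].
#' @param first_label,last_label Author numbers of the span ends (inclusive).
#' @return Integer percent, rounded half-up.
#' @export
#' @examples
#' span_fraction(trop2_ic(), 310, 318)  # 35
span_fraction <- function(seq, first_label, last_label) {
  stopifnot(inherits(seq, "peptide_seq"))
  nums <- seq_numbers(seq)
  if (first_label > last_label)
    abort("first_label must be <= last_label", class = "helixswitch_range_error")
  if (!(first_label %in% nums) || !(last_label %in% nums))
    abort("span labels outside the sequence numbering range",
          class = "helixswitch_range_error")
  as.integer(round_half_up(100 * (last_label - first_label + 1) / length(nums)))
}

#' Longest homopolymer run of a residue
#'
#' Finds the longest maximal run of a single residue type; ties are broken
#' towards the N-terminus. Returns a zero-length span if the residue is
#' absent.
#'
#' @param seq A [peptide_seq()].
#' @param residue One-letter residue code.
#' @return A one-row tibble with `first_label`, `last_label`, `run_length`
#'   (labels are `NA` when the run length is 0).
#' @export
#' @examples
#' longest_homopolymer(trop2_tm(), "V")  # Val282-Val286, length 5
longest_homopolymer <- function(seq, residue) {
  stopifnot(inherits(seq, "peptide_seq"))
  residue <- toupper(residue)
  if (!residue %in% AA1)
    abort("invalid residue letter", class = "helixswitch_invalid_sequence")
  letters <- seq_letters(seq)
  r <- rle(letters == residue)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values)
  if (length(hit) == 0) {
    return(tibble(first_label = NA_integer_, last_label = NA_integer_,
                  run_length = 0L))
  }
  best <- hit[which.max(r$lengths[hit])]  # which.max takes the first on ties
  nums <- seq_numbers(seq)
  tibble(first_label = nums[starts[best]], last_label = nums[ends[best]],
         run_length = r$lengths[best])
}

#' Formal net side-chain charge
#'
#' `(#R + #K) - (#D + #E) + phospho_charge * #phospho`, ignoring termini
#' (the study peptides are capped).
#'
#' @param seq A [peptide_seq()].
#' @param phospho_charge Charge per phosphate, -1 or -2 (default -2,
#'   the dominant state at pH 7.4).
#' @return Integer net charge.
#' @export
#' @examples
#' net_charge(trop2_ic())                 # +5
#' net_charge(trop2_ic(phospho = TRUE))   # +3
net_charge <- function(seq, phospho_charge = -2L) {
  stopifnot(inherits(seq, "peptide_seq"), phospho_charge %in% c(-1L, -2L))
  cc <- charge_census(seq)
  as.integer(cc$basic - cc$acidic + phospho_charge * length(seq$phospho_positions))
}
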