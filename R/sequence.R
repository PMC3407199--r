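# One-letter amino-acid alphabet (20 standard residues)
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Load a peptide sequence
#'
#' Reads a peptide sequence either from a FASTA file or from a raw
#' one-letter string. Whitespace and line breaks are ignored and the case
#' is normalized, so the spaced form commonly used in papers
#' (\code{"NLYIQ WLKDG GPSSG RPPPS"}) parses directly.
#'
#' @param source Path to a FASTA file, or a character string of one-letter
#'   amino-acid codes.
#' @param first Index assigned to the first residue (default 1). A nonzero
#'   offset supports fragments numbered within a parent construct.
#' @return A \code{peptide_sequence} object: a character vector of validated
#'   one-letter codes with attributes \code{first} (numbering origin) and
#'   \code{name} (FASTA header, if any).
#' @examples
#' seq <- load_sequence("NLYIQ WLKDG GPSSG RPPPS")
#' length(seq)            # 20
#' residue_type(seq, 6)   # "W"
#' @export
load_sequence <- function(source, first = 1L) {
  stopifnot(is.character(source), length(source) == 1L)
  name <- NULL
  if (file.exists(source)) {
    if (any(grepl("^>", readLines(source, warn = FALSE)))) {
      recs <- seqinr::read.fasta(source, seqtype = "AA", as.string = TRUE,
                                 seqonly = FALSE)
      if (length(recs) > 1L)
        stop("FASTA file contains more than one sequence record")
      name <- sub("^>\\s*", "", attr(recs[[1]], "Annot"))
      source <- as.character(recs[[1]])
    } else {
      source <- paste(readLines(source, warn = FALSE), collapse = "")
    }
  }
  residues <- strsplit(gsub("\\s+", "", source), "")[[1]]
  if (length(residues) == 0L) stop("empty sequence")
  residues <- toupper(residues)
  bad <- which(!(residues %in% AA_ALPHABET))
  if (length(bad) > 0L)
    stop(sprintf("illegal residue code '%s' at position %d",
                 residues[bad[1]], bad[1]))
  structure(residues,
            first = as.integer(first),
            name = name,
            class = "peptide_sequence")
}

#' Residue indices of a peptide sequence
#' @param seq A \code{peptide_sequence}.
#' @return Integer vector of residue numbers (respecting the numbering origin).
#' @export
residue_indices <- function(seq) {
  stopifnot(inherits(seq, "peptide_sequence"))
  attr(seq, "first") + seq_along(seq) - 1L
}

#' Residue type at a given residue number
#' @param seq A \code{peptide_sequence}.
#' @param i Residue number(s) in the sequence's own numbering.
#' @return One-letter code(s).
#' @export
residue_type <- function(seq, i) {
  idx <- i - attr(seq, "first") + 1L
  if (any(idx < 1L | idx > length(seq)))
    stop(sprintf("residue number out of range [%d, %d]",
                 attr(seq, "first"), attr(seq, "first") + length(seq) - 1L))
  unclass(seq)[idx]
}

#' @export
print.peptide_sequence <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf("peptide_sequence: %d residues (numbered %d..%d)%s\n",
              length(x), attr(x, "first"),
              attr(x, "first") + length(x) - 1L,
              if (is.null(nm)) "" else paste0(" [", nm, "]")))
  cat(paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}

#' Per-residue value table
#'
#' The common carrier for per-residue profiles (rates, spectral densities,
#' shifts, ...). A plain data frame with columns \code{residue},
#' \code{value}, \code{sigma} and a logical \code{mask} column that marks
#' usable entries; missing residues are carried with \code{mask = FALSE},
#' never as sentinel numbers.
#'
#' @param residue Integer residue numbers.
#' @param value Numeric values (NA allowed; masked automatically).
#' @param sigma Non-negative uncertainties (NA allowed).
#' @param seq Optional \code{peptide_sequence}; when supplied, residue
#'   numbers are checked against its range.
#' @return A data frame of class \code{residue_table}.
#' @export
residue_table <- function(residue, value, sigma = NA_real_, seq = NULL) {
  residue <- as.integer(residue)
  value <- as.numeric(value)
  sigma <- rep_len(as.numeric(sigma), length(value))
  stopifnot(length(residue) == length(value))
  if (anyDuplicated(residue)) stop("duplicate residue numbers")
  if (any(!is.na(sigma) & sigma < 0)) stop("uncertainties must be >= 0")
  if (!is.null(seq)) {
    rng <- range(residue_indices(seq))
    if (any(residue < rng[1] | residue > rng[2]))
      stop("residue numbers outside the sequence range")
  }
  out <- data.frame(residue = residue, value = value, sigma = sigma,
                    mask = !is.na(value))
  class(out) <- c("residue_table", "data.frame")
  out
}
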