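# NOESY connectivity classification, contact maps and AABUF hydrophobicity
# profiles.

# Proton atom-name taxonomy: HN/H -> backbone amide; HA (incl. glycine
# HA2/HA3) -> alpha; any other proton or proton pseudo-atom -> side chain.
atom_proton_class <- function(atom) {
  a <- toupper(trimws(atom))
  if (a %in% c("HN", "H", "NH")) return("HN")
  if (a %in% c("HA", "HA1", "HA2", "HA3", "QA")) return("HA")
  if (grepl("^[HQ]", a)) return("SC")
  stop(sprintf("unknown atom name '%s' (expected a proton name)", atom))
}

#' Classify an assigned NOE contact
#'
#' Canonicalizes the contact so that res_i <= res_j and assigns exactly one
#' connectivity class from the atom classes and the sequence separation:
#' \code{intra}; backbone \code{dNN(i,i+1)}, \code{dNN(i,i+2)};
#' \code{daN(i,i+1)}, \code{daN(i,i+2)}, \code{daN(i,i+3)} (HA to HN);
#' side-chain-to-HN \code{dscN(i,i+2)}, \code{dscN(i,i+3)}; side-chain to
#' side chain by separation band \code{sc-sc(|d|=1)}, \code{sc-sc(2<=|d|<=4)},
#' \code{sc-sc(|d|>=5)}; anything else falls into \code{other}.
#'
#' @param res_i,atom_i,res_j,atom_j Residue numbers and proton names of the
#'   two contact partners (order irrelevant; canonicalized internally).
#' @return A single class label (character).
#' @export
classify_contact <- function(res_i, atom_i, res_j, atom_j) {
  ci <- atom_proton_class(atom_i)
  cj <- atom_proton_class(atom_j)
  if (res_j < res_i || (res_i == res_j && ci == "HN" && cj != "HN")) {
    tmp <- res_i; res_i <- res_j; res_j <- tmp
    tmp <- ci; ci <- cj; cj <- tmp
  }
  sep <- res_j - res_i
  if (sep == 0L) return("intra")
  pair <- paste(sort(c(ci, cj)), collapse = "-")
  if (ci == "HN" && cj == "HN") {
    if (sep == 1L) return("dNN(i,i+1)")
    if (sep == 2L) return("dNN(i,i+2)")
    return("other")
  }
  if (pair == "HA-HN") {
    if (sep == 1L) return("daN(i,i+1)")
    if (sep == 2L) return("daN(i,i+2)")
    if (sep == 3L) return("daN(i,i+3)")
    return("other")
  }
  if (pair == "HN-SC") {
    if (sep == 2L) return("dscN(i,i+2)")
    if (sep == 3L) return("dscN(i,i+3)")
    return("other")
  }
  if (ci == "SC" && cj == "SC") {
    if (sep == 1L) return("sc-sc(|d|=1)")
    if (sep <= 4L) return("sc-sc(2<=|d|<=4)")
    return("sc-sc(|d|>=5)")
  }
  "other"
}

CONTACT_CLASSES <- c("intra", "dNN(i,i+1)", "dNN(i,i+2)",
                     "daN(i,i+1)", "daN(i,i+2)", "daN(i,i+3)",
                     "dscN(i,i+2)", "dscN(i,i+3)",
                     "sc-sc(|d|=1)", "sc-sc(2<=|d|<=4)", "sc-sc(|d|>=5)",
                     "other")

#' Connectivity map and class counts
#'
#' Classifies every contact, collapses duplicates (same canonical atom
#' pair, e.g. from different mixing times) while recording multiplicity,
#' and tabulates a residue-by-class presence matrix anchored at the
#' lower residue of each contact. All defined classes are reported,
#' including those with zero observed contacts.
#'
#' @param contacts A \code{contact_table} (see
#'   \code{\link{read_contact_table}}).
#' @param seq Optional \code{peptide_sequence} to fix the residue range of
#'   the matrix.
#' @return A \code{connectivity_map} list: \code{contacts} (classified,
#'   deduplicated data frame with \code{class} and \code{multiplicity}),
#'   \code{matrix} (residue x class logical matrix), \code{counts} (named
#'   integer vector over all classes), \code{absent} (classes with zero
#'   count).
#' @export
connectivity_map <- function(contacts, seq = NULL) {
  if (nrow(contacts) > 0) {
    canon <- lapply(seq_len(nrow(contacts)), function(r) {
      ri <- contacts$res_i[r]; ai <- toupper(contacts$atom_i[r])
      rj <- contacts$res_j[r]; aj <- toupper(contacts$atom_j[r])
      if (rj < ri) { tmp <- ri; ri <- rj; rj <- tmp; tmp <- ai; ai <- aj; aj <- tmp }
      data.frame(res_i = ri, atom_i = ai, res_j = rj, atom_j = aj)
    })
    canon <- do.call(rbind, canon)
    key <- paste(canon$res_i, canon$atom_i, canon$res_j, canon$atom_j)
    mult <- as.vector(table(key)[key])
    dedup <- !duplicated(key)
    canon <- canon[dedup, , drop = FALSE]
    canon$multiplicity <- mult[dedup]
    canon$class <- vapply(seq_len(nrow(canon)), function(r)
      classify_contact(canon$res_i[r], canon$atom_i[r],
                       canon$res_j[r], canon$atom_j[r]), character(1))
  } else {
    canon <- data.frame(res_i = integer(), atom_i = character(),
                        res_j = integer(), atom_j = character(),
                        multiplicity = integer(), class = character())
  }
  counts <- stats::setNames(integer(length(CONTACT_CLASSES)), CONTACT_CLASSES)
  tb <- table(canon$class)
  counts[names(tb)] <- as.integer(tb)
  residues <- if (!is.null(seq)) residue_indices(seq) else
    if (nrow(canon) > 0) seq(min(canon$res_i), max(canon$res_j)) else integer()
  mat <- matrix(FALSE, nrow = length(residues), ncol = length(CONTACT_CLASSES),
                dimnames = list(residues, CONTACT_CLASSES))
  for (r in seq_len(nrow(canon)))
    if (canon$res_i[r] %in% residues)
      mat[as.character(canon$res_i[r]), canon$class[r]] <- TRUE
  structure(list(contacts = canon, matrix = mat, counts = counts,
                 absent = names(counts)[counts == 0L]),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat("connectivity_map:", sum(x$counts), "unique contacts\n")
  present <- x$counts[x$counts > 0L]
  for (nm in names(present)) cat(sprintf("  %-18s %d\n", nm, present[nm]))
  if (length(x$absent) > 0)
    cat("  absent classes:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}

#' Side-chain contact table around a focus residue
#'
#' Builds a table of contacts involving one focus residue (e.g. a central
#' tryptophan): rows are the focus residue's atoms, columns the partner
#' residues, and each cell lists the partner atoms (with peak ids when
#' available).
#'
#' @param contacts A \code{contact_table}.
#' @param focus Residue number of the focus residue.
#' @return A \code{sidechain_map} list: \code{focus}, \code{partners}
#'   (sorted partner residue numbers), \code{cells} (data frame
#'   \code{focus_atom}, \code{partner_residue}, \code{partner_atom},
#'   \code{peak_id}), \code{table} (atom x partner character matrix).
#' @export
sidechain_contact_table <- function(contacts, focus) {
  sel <- contacts$res_i == focus | contacts$res_j == focus
  sub <- contacts[sel, , drop = FALSE]
  if (nrow(sub) > 0) {
    focus_atom <- ifelse(sub$res_i == focus, sub$atom_i, sub$atom_j)
    partner_res <- ifelse(sub$res_i == focus, sub$res_j, sub$res_i)
    partner_atom <- ifelse(sub$res_i == focus, sub$atom_j, sub$atom_i)
    keep <- partner_res != focus
    cells <- data.frame(focus_atom = toupper(focus_atom[keep]),
                        partner_residue = partner_res[keep],
                        partner_atom = toupper(partner_atom[keep]),
                        peak_id = if ("peak_id" %in% names(sub))
                          sub$peak_id[keep] else NA_character_)
  } else {
    cells <- data.frame(focus_atom = character(), partner_residue = integer(),
                        partner_atom = character(), peak_id = character())
  }
  partners <- sort(unique(cells$partner_residue))
  atoms <- sort(unique(cells$focus_atom))
  tab <- matrix("", nrow = length(atoms), ncol = length(partners),
                dimnames = list(atoms, as.character(partners)))
  for (r in seq_len(nrow(cells))) {
    lab <- if (!is.na(cells$peak_id[r]))
      sprintf("%s (%s)", cells$partner_atom[r], cells$peak_id[r])
    else cells$partner_atom[r]
    a <- cells$focus_atom[r]; p <- as.character(cells$partner_residue[r])
    tab[a, p] <- if (nzchar(tab[a, p])) paste(tab[a, p], lab, sep = "/") else lab
  }
  structure(list(focus = focus, partners = partners, cells = cells,
                 table = tab),
            class = "sidechain_map")
}

#' AABUF hydrophobicity profile
#'
#' Computes the per-residue average area buried upon folding, applies an
#' edge-truncated sliding-window mean (uniform weighting) and min-max
#' normalizes the result to [0, 1]. The AABUF of a residue is proportional
#' to its hydrophobic contribution to the conformational free energy, so
#' profile maxima highlight candidate hydrophobic-cluster regions.
#'
#' @param seq A \code{peptide_sequence}.
#' @param scale Named numeric vector of per-type AABUF values (one-letter
#'   names); defaults to the buried-surface-area scale shipped in
#'   \code{inst/extdata/aabuf_scale.tsv}.
#' @param window Odd window length <= chain length (default 5).
#' @return An \code{aabuf_profile} data frame: \code{residue}, \code{raw},
#'   \code{windowed}, \code{normalized}. For a constant profile the
#'   normalization is undefined: \code{normalized} is NA and
#'   \code{attr(, "constant")} is TRUE.
#' @export
aabuf_profile <- function(seq, scale = NULL, window = 5L) {
  if (is.null(scale)) scale <- default_aabuf_scale()
  if (window %% 2L != 1L) stop("window must be odd")
  if (window > length(seq)) stop("window longer than the sequence")
  types <- unclass(seq)
  missing_types <- setdiff(unique(types), names(scale))
  if (length(missing_types) > 0L)
    stop(sprintf("scale lacks value(s) for residue type(s): %s",
                 paste(missing_types, collapse = ", ")))
  raw <- unname(scale[types])
  half <- (window - 1L) %/% 2L
  n <- length(raw)
  windowed <- vapply(seq_len(n), function(i)
    mean(raw[max(1L, i - half):min(n, i + half)]), numeric(1))
  rng <- range(windowed)
  constant <- diff(rng) == 0
  normalized <- if (constant) rep(NA_real_, n) else
    (windowed - rng[1]) / diff(rng)
  out <- data.frame(residue = residue_indices(seq), raw = raw,
                    windowed = windowed, normalized = normalized)
  attr(out, "constant") <- constant
  attr(out, "window") <- window
  class(out) <- c("aabuf_profile", "data.frame")
  out
}

#' Buried-surface-area scale shipped with the package
#' @return Named numeric vector (square Angstrom) over the 20 residue
#'   types.
#' @export
default_aabuf_scale <- function() {
  path <- system.file("extdata", "aabuf_scale.tsv", package = "denatr",
                      mustWork = TRUE)
  tab <- read_dialect_tsv(path, required = c("type", "area"))
  stats::setNames(tab$area, tab$type)
}
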