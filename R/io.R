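# TSV dialect used throughout: tab-separated, "#"-prefixed comment lines,
# "." for missing values, units at rest (delays s, rates 1/s, shifts ppm).
# Files may carry delays in ms when the column is named delay_ms; the
# conversion happens at parse time so everything downstream is in seconds.

read_dialect_tsv <- function(path, required = character()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", na.strings = ".",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L)
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")))
  tab
}

write_dialect_tsv <- function(tab, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a peak-height decay table
#'
#' Reads relaxation decay data (peak height versus relaxation delay) in the
#' package TSV dialect. Required columns: \code{residue}, \code{delay_ms}
#' (or \code{delay_s}), \code{height}, \code{replicate_id}. Delays given in
#' ms are converted to seconds; repeated measurements at the same delay are
#' kept as separate rows, distinguished by \code{replicate_id}.
#'
#' @param path Path to a TSV file.
#' @return A \code{decay_table}: data frame with columns \code{residue},
#'   \code{delay} (s), \code{height}, \code{replicate}.
#' @export
read_decay_table <- function(path) {
  tab <- read_dialect_tsv(path)
  dcol <- intersect(c("delay_ms", "delay_s"), names(tab))
  if (length(dcol) == 0L)
    stop(sprintf("missing column(s) in %s: delay_ms (or delay_s)", path))
  for (col in c("residue", "height", "replicate_id"))
    if (!col %in% names(tab))
      stop(sprintf("missing column(s) in %s: %s", path, col))
  if (!is.numeric(tab$height))
    stop("non-numeric height values")
  delay <- tab[[dcol[1]]]
  if (!is.numeric(delay)) stop("non-numeric delay values")
  if (dcol[1] == "delay_ms") delay <- delay / 1000
  out <- data.frame(residue = as.integer(tab$residue),
                    delay = delay,
                    height = tab$height,
                    replicate = as.integer(tab$replicate_id))
  key <- paste(out$residue, signif(out$delay, 12), out$replicate)
  if (anyDuplicated(key))
    stop("duplicate (residue, delay, replicate) triple")
  class(out) <- c("decay_table", "data.frame")
  out
}

#' Write a decay table
#'
#' Inverse of \code{\link{read_decay_table}} up to canonical formatting;
#' delays are written in ms.
#'
#' @param tab A \code{decay_table}.
#' @param path Output path.
#' @export
write_decay_table <- function(tab, path) {
  out <- data.frame(residue = tab$residue,
                    delay_ms = tab$delay * 1000,
                    height = tab$height,
                    replicate_id = tab$replicate)
  write_dialect_tsv(out, path, comment = "decay table: delays in ms")
}

#' Extract one residue's decay series
#' @param tab A \code{decay_table}.
#' @param residue Residue number.
#' @return A \code{decay_table} restricted to that residue.
#' @export
decay_series <- function(tab, residue) {
  out <- tab[tab$residue == residue, , drop = FALSE]
  if (nrow(out) == 0L) stop(sprintf("no decay data for residue %d", residue))
  rownames(out) <- NULL
  out
}

# Normalization map for nucleus labels; anything not listed (after upper-
# casing and prime/superscript cleanup) is skipped with a warning.
NUCLEUS_MAP <- c(CA = "CA", CB = "CB", C = "C", CO = "C", "C'" = "C",
                 HA = "HA", HA2 = "HA", HA3 = "HA", HB = "HB",
                 HN = "HN", H = "HN", N = "N", NH = "N")

normalize_nucleus <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("PRIME$", "'", x)
  unname(NUCLEUS_MAP[x])
}

#' Read a chemical-shift table (TSV or NMR-STAR)
#'
#' TSV input requires columns \code{residue}, \code{nucleus},
#' \code{shift_ppm}. NMR-STAR 3.1 input is scanned for the assigned
#' chemical shift loop (\code{_Atom_chem_shift}) and the sequence code,
#' atom name and shift value columns are extracted. Nucleus labels are
#' normalized to \{CA, CB, C, HA, HB, HN, N\}; rows with unrecognized
#' labels are skipped with a warning.
#'
#' @param path Path to the file.
#' @param format \code{"auto"} (default; NMR-STAR is detected from a
#'   \code{_Atom_chem_shift} token), \code{"tsv"} or \code{"star"}.
#' @return A \code{shift_table}: data frame with columns \code{residue},
#'   \code{nucleus}, \code{shift}.
#' @export
read_shift_table <- function(path, format = c("auto", "tsv", "star")) {
  format <- match.arg(format)
  if (format == "auto") {
    head_lines <- readLines(path, n = 200L, warn = FALSE)
    format <- if (any(grepl("_Atom_chem_shift", head_lines, fixed = TRUE)))
      "star" else "tsv"
  }
  if (format == "tsv") {
    tab <- read_dialect_tsv(path, required = c("residue", "nucleus", "shift_ppm"))
    residue <- as.integer(tab$residue)
    nucleus_raw <- as.character(tab$nucleus)
    shift <- as.numeric(tab$shift_ppm)
  } else {
    star <- parse_star_shift_loop(path)
    residue <- star$residue
    nucleus_raw <- star$nucleus
    shift <- star$shift
  }
  nucleus <- normalize_nucleus(nucleus_raw)
  drop <- is.na(nucleus)
  if (any(drop))
    warning(sprintf("skipping %d row(s) with unrecognized nucleus label(s): %s",
                    sum(drop), paste(unique(nucleus_raw[drop]), collapse = ", ")))
  out <- data.frame(residue = residue[!drop],
                    nucleus = nucleus[!drop],
                    shift = shift[!drop])
  out <- out[order(out$residue, out$nucleus), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("shift_table", "data.frame")
  out
}

# Minimal reader for the NMR-STAR 3.1 assigned-chemical-shift loop. Only the
# _Atom_chem_shift loop is consumed (read-only); no installed R package
# parses NMR-STAR, so the loop grammar (loop_ / tag list / rows / stop_) is
# handled here directly.
parse_star_shift_loop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  loop_starts <- which(lines == "loop_")
  if (length(loop_starts) == 0L) stop("unparseable NMR-STAR file: no loop_")
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i]); i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    seq_col <- match("_Atom_chem_shift.Seq_ID", tags)
    if (is.na(seq_col)) seq_col <- match("_Atom_chem_shift.Comp_index_ID", tags)
    atom_col <- match("_Atom_chem_shift.Atom_ID", tags)
    val_col <- match("_Atom_chem_shift.Val", tags)
    if (is.na(seq_col) || is.na(atom_col) || is.na(val_col))
      stop("assigned chemical shift loop lacks Seq_ID/Atom_ID/Val tags")
    rows <- list()
    while (i <= length(lines) && lines[i] != "stop_") {
      if (nzchar(lines[i]) && !startsWith(lines[i], "#")) {
        fields <- strsplit(lines[i], "\\s+")[[1]]
        if (length(fields) >= length(tags)) rows[[length(rows) + 1L]] <- fields
      }
      i <- i + 1L
    }
    if (length(rows) == 0L) stop("assigned chemical shift loop is empty")
    m <- do.call(rbind, rows)
    return(list(residue = as.integer(m[, seq_col]),
                nucleus = m[, atom_col],
                shift = as.numeric(m[, val_col])))
  }
  stop("unparseable NMR-STAR file: no assigned chemical shift loop")
}

#' Write a chemical-shift table (TSV dialect)
#' @param tab A \code{shift_table}.
#' @param path Output path.
#' @export
write_shift_table <- function(tab, path) {
  out <- data.frame(residue = tab$residue, nucleus = tab$nucleus,
                    shift_ppm = tab$shift)
  write_dialect_tsv(out, path, comment = "chemical shift table (ppm)")
}

#' Read an assigned NOE contact table
#'
#' Required columns: \code{res_i}, \code{atom_i}, \code{res_j},
#' \code{atom_j}; optional \code{peak_id} and \code{mixing_time_ms}.
#'
#' @param path Path to a TSV file.
#' @return A \code{contact_table} data frame.
#' @export
read_contact_table <- function(path) {
  tab <- read_dialect_tsv(path, required = c("res_i", "atom_i", "res_j", "atom_j"))
  out <- data.frame(res_i = as.integer(tab$res_i),
                    atom_i = as.character(tab$atom_i),
                    res_j = as.integer(tab$res_j),
                    atom_j = as.character(tab$atom_j),
                    peak_id = if ("peak_id" %in% names(tab))
                      as.character(tab$peak_id) else NA_character_,
                    mixing_time_ms = if ("mixing_time_ms" %in% names(tab))
                      as.numeric(tab$mixing_time_ms) else NA_real_)
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Read a gradient-intensity diffusion profile
#'
#' Required columns: \code{g} (gradient strength, T/m) and
#' \code{intensity} (relative signal intensity).
#'
#' @param path Path to a TSV file.
#' @return Data frame with columns \code{g}, \code{intensity}.
#' @export
read_gradient_table <- function(path) {
  tab <- read_dialect_tsv(path, required = c("g", "intensity"))
  if (any(tab$g < 0)) stop("gradient strengths must be >= 0")
  data.frame(g = as.numeric(tab$g), intensity = as.numeric(tab$intensity))
}

#' Read per-residue helix propensities (external predictor output)
#'
#' Parses two-column residue/propensity text as produced by helix-propensity
#' predictors (the prediction itself is performed outside this package).
#'
#' @param path Path to a whitespace- or tab-separated two-column file with
#'   columns \code{residue}, \code{propensity} (percent, 0-100).
#' @param seq Optional \code{peptide_sequence}; residues absent from the
#'   file are carried as masked entries.
#' @return A \code{residue_table} of propensities.
#' @export
read_helix_propensity <- function(path, seq = NULL) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           na.strings = ".", stringsAsFactors = FALSE)
  if (!all(c("residue", "propensity") %in% names(tab)))
    stop(sprintf("missing column(s) in %s: residue, propensity", path))
  if (any(!is.na(tab$propensity) &
          (tab$propensity < 0 | tab$propensity > 100)))
    stop("helix propensity outside [0, 100]")
  if (!is.null(seq)) {
    idx <- residue_indices(seq)
    val <- tab$propensity[match(idx, tab$residue)]
    residue_table(idx, val, seq = seq)
  } else {
    residue_table(tab$residue, tab$propensity)
  }
}
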