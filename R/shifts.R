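# Sequence-corrected random-coil referencing, secondary chemical shifts,
# consensus chemical shift index and Karplus phi conversion.

#' Read a random-coil chemical-shift table
#'
#' Base-shift file columns: \code{type} (one-letter code), \code{nucleus},
#' \code{shift_ppm}. Correction-file columns: \code{neighbor_type},
#' \code{offset} (-2, -1, +1 or +2, the neighbour's position relative to
#' the residue being corrected), \code{nucleus}, \code{delta_ppm}.
#' Corrections absent from the file default to zero.
#'
#' The package ships \code{random_coil_consensus.tsv}, an approximate
#' consensus set of 13C random-coil values (see
#' \code{system.file("extdata", package = "denatr")}), and
#' \code{neighbor_corrections_synthetic.tsv}, a small synthetic correction
#' set for testing. For quantitative work on denatured proteins supply a
#' calibrated table measured under matched conditions (e.g. an 8 M urea,
#' low-pH data set).
#'
#' @param base_path Path to the base-shift TSV.
#' @param corrections_path Optional path to a neighbour-correction TSV.
#' @return A \code{coil_table} list with elements \code{base} (data frame),
#'   \code{corrections} (data frame or NULL) and \code{provenance}.
#' @export
read_coil_table <- function(base_path, corrections_path = NULL) {
  base <- read_dialect_tsv(base_path, required = c("type", "nucleus", "shift_ppm"))
  base$nucleus <- normalize_nucleus(base$nucleus)
  base <- base[!is.na(base$nucleus), , drop = FALSE]
  corr <- NULL
  if (!is.null(corrections_path)) {
    corr <- read_dialect_tsv(corrections_path,
                             required = c("neighbor_type", "offset",
                                          "nucleus", "delta_ppm"))
    corr$nucleus <- normalize_nucleus(corr$nucleus)
    corr <- corr[!is.na(corr$nucleus), , drop = FALSE]
    if (any(!corr$offset %in% c(-2L, -1L, 1L, 2L)))
      stop("correction offsets must be in {-2, -1, +1, +2}")
  }
  structure(list(base = base, corrections = corr,
                 provenance = basename(base_path)),
            class = "coil_table")
}

#' Default random-coil table shipped with the package
#' @param with_corrections If TRUE (default), also load the synthetic
#'   neighbour-correction set.
#' @return A \code{coil_table}.
#' @export
default_coil_table <- function(with_corrections = TRUE) {
  base <- system.file("extdata", "random_coil_consensus.tsv",
                      package = "denatr", mustWork = TRUE)
  corr <- if (with_corrections)
    system.file("extdata", "neighbor_corrections_synthetic.tsv",
                package = "denatr", mustWork = TRUE) else NULL
  read_coil_table(base, corr)
}

#' Sequence-corrected random-coil reference shifts
#'
#' For residue i and nucleus X the reference is
#' base(type_i, X) + sum over neighbour offsets o in \{-2, -1, +1, +2\}
#' of correction(type_\{i+o\}, o, X); chain ends use only the neighbours
#' that exist. Input shifts are assumed to be referenced consistently with
#' the table; no re-referencing is applied.
#'
#' @param seq A \code{peptide_sequence}.
#' @param table A \code{\link{read_coil_table}} result.
#' @param nuclei Nuclei to tabulate (default CA, CB, C).
#' @return Data frame with columns \code{residue}, \code{nucleus},
#'   \code{shift} (ppm). Nuclei genuinely absent for a residue type
#'   (glycine CB) are omitted.
#' @export
corrected_random_coil <- function(seq, table = default_coil_table(),
                                  nuclei = c("CA", "CB", "C")) {
  stopifnot(inherits(table, "coil_table"))
  idx <- residue_indices(seq)
  types <- unclass(seq)
  need <- setdiff(unique(types), unique(table$base$type))
  if (length(need) > 0L)
    stop(sprintf("random-coil table lacks base values for residue type(s): %s",
                 paste(need, collapse = ", ")))
  rows <- list()
  for (p in seq_along(idx)) {
    for (nuc in nuclei) {
      hit <- table$base$shift_ppm[table$base$type == types[p] &
                                    table$base$nucleus == nuc]
      if (length(hit) == 0L || is.na(hit[1])) next  # e.g. Gly CB
      ref <- hit[1]
      if (!is.null(table$corrections)) {
        for (o in c(-2L, -1L, 1L, 2L)) {
          q <- p + o
          if (q < 1L || q > length(idx)) next
          ci <- which(table$corrections$neighbor_type == types[q] &
                        table$corrections$offset == o &
                        table$corrections$nucleus == nuc)
          if (length(ci) > 0L)
            ref <- ref + sum(table$corrections$delta_ppm[ci])
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(residue = idx[p], nucleus = nuc,
                                              shift = ref)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Secondary chemical shifts
#'
#' Computes per-(residue, nucleus) secondary shifts
#' delta_obs - delta_ref(sequence-corrected random coil). Residue types in
#' \code{exclude_types} are flagged excluded when
#' \code{exclude_ph_sensitive} is TRUE: Asp and Glu sidechain ionization
#' makes their shifts track pH, so they are uninformative when the sample
#' pH differs from the reference table's.
#'
#' @param observed A \code{shift_table} (columns \code{residue},
#'   \code{nucleus}, \code{shift}).
#' @param reference Output of \code{\link{corrected_random_coil}}.
#' @param seq The \code{peptide_sequence} (used for the exclusion rule).
#' @param exclude_ph_sensitive Apply the residue-type exclusion (default
#'   TRUE).
#' @param exclude_types Residue types to exclude (default Asp, Glu; add
#'   \code{"H"} for histidine near its pKa).
#' @return A \code{secondary_shift} data frame: \code{residue},
#'   \code{nucleus}, \code{dobs}, \code{dref}, \code{ddelta},
#'   \code{excluded}. Unmatched records carry \code{ddelta = NA}.
#' @export
secondary_shifts <- function(observed, reference, seq,
                             exclude_ph_sensitive = TRUE,
                             exclude_types = c("D", "E")) {
  key_o <- paste(observed$residue, observed$nucleus)
  key_r <- paste(reference$residue, reference$nucleus)
  i <- match(key_o, key_r)
  dref <- reference$shift[i]
  out <- data.frame(residue = observed$residue, nucleus = observed$nucleus,
                    dobs = observed$shift, dref = dref,
                    ddelta = observed$shift - dref)
  rng <- range(residue_indices(seq))
  types <- rep(NA_character_, nrow(out))
  in_rng <- out$residue >= rng[1] & out$residue <= rng[2]
  types[in_rng] <- residue_type(seq, out$residue[in_rng])
  out$excluded <- exclude_ph_sensitive & types %in% exclude_types
  class(out) <- c("secondary_shift", "data.frame")
  out
}

#' Consensus chemical shift index
#'
#' Thresholds the secondary shifts per nucleus into an index in
#' \{-1, 0, +1\} (+1 = helix-like deviation): CA and C' score +1 when
#' ddelta exceeds +threshold and -1 below -threshold; the CB sign is
#' inverted (helices shift CB upfield). The per-residue consensus is the
#' majority vote over available nuclei (ties: coil), and helix/strand runs
#' shorter than 3 consecutive residues are reset to coil. Excluded records
#' contribute index 0.
#'
#' The consensus is invariant to a uniform referencing offset applied to
#' both observed and reference shifts, since only differences enter.
#'
#' @param records A \code{\link{secondary_shifts}} data frame.
#' @param thresholds Named list of per-nucleus thresholds in ppm (defaults
#'   CA 0.7, CB 0.5, C 0.5).
#' @param min_run Minimum run length for a non-coil call (default 3).
#' @return A \code{csi_result} list: \code{index} (data frame residue x
#'   nucleus index), \code{consensus} (data frame \code{residue},
#'   \code{call} in \{"helix", "coil", "strand"\}).
#' @export
consensus_csi <- function(records, thresholds = list(CA = 0.7, CB = 0.5, C = 0.5),
                          min_run = 3L) {
  idx_of <- function(nuc, dd) {
    thr <- thresholds[[nuc]]
    if (is.null(thr) || is.na(dd)) return(0L)
    raw <- if (dd > thr) 1L else if (dd < -thr) -1L else 0L
    if (nuc == "CB") -raw else raw
  }
  per <- records[!records$excluded & records$nucleus %in% names(thresholds), ,
                 drop = FALSE]
  per$index <- mapply(idx_of, per$nucleus, per$ddelta)
  residues <- sort(unique(records$residue))
  consensus <- vapply(residues, function(r) {
    v <- per$index[per$residue == r]
    if (length(v) == 0L) return(0L)
    s <- sum(v == 1L) - sum(v == -1L)
    if (s > 0L) 1L else if (s < 0L) -1L else 0L
  }, integer(1))
  # run-length rule: non-coil runs shorter than min_run become coil
  rl <- rle(consensus)
  rl$values[rl$values != 0L & rl$lengths < min_run] <- 0L
  consensus <- inverse.rle(rl)
  call <- c("strand", "coil", "helix")[consensus + 2L]
  structure(list(index = per[, c("residue", "nucleus", "index")],
                 consensus = data.frame(residue = residues, call = call)),
            class = "csi_result")
}

#' Flag residues with deviant secondary shifts
#'
#' A record is deviant when |ddelta| exceeds its nucleus threshold and the
#' record is not excluded. Deviant secondary shifts unassociated with pH
#' effects mark residual (cluster) structure. Flagging is monotone in the
#' threshold: raising it never adds flags.
#'
#' @param records A \code{\link{secondary_shifts}} data frame.
#' @param threshold Either a single ppm value for all nuclei or a named
#'   list per nucleus (default CA/C 0.3 ppm, CB 0.5 ppm). The exact cutoff
#'   is a reporting choice and is attached to the output.
#' @return The input with a logical \code{deviant} column; the thresholds
#'   used are stored in \code{attr(, "threshold")}.
#' @export
flag_deviant <- function(records, threshold = list(CA = 0.3, C = 0.3, CB = 0.5)) {
  if (is.numeric(threshold) && length(threshold) == 1L) {
    if (threshold <= 0) stop("threshold must be > 0")
    thr <- function(nuc) threshold
  } else {
    if (any(unlist(threshold) <= 0)) stop("threshold must be > 0")
    thr <- function(nuc) {
      v <- threshold[[nuc]]
      if (is.null(v)) Inf else v
    }
  }
  tvec <- vapply(records$nucleus, thr, numeric(1))
  records$deviant <- !records$excluded & !is.na(records$ddelta) &
    abs(records$ddelta) > tvec
  attr(records, "threshold") <- threshold
  records
}

#' Backbone phi angles from 3J(HN,HA) couplings
#'
#' Solves the Karplus relation
#' J = A cos^2(phi - 60) + B cos(phi - 60) + C for phi, returning every
#' solution in (-180, 180]. Writing u = cos(phi - 60) gives a quadratic in
#' u; each root with |u| <= 1 yields two angles (+/- acos). A coupling
#' above the curve maximum has no solution (empty result, not an error).
#'
#' Default coefficients are the HNHA calibration A = 6.51, B = -1.76,
#' C = 1.60 Hz.
#'
#' @param j3 Scalar coupling constant(s) in Hz, >= 0.
#' @param A,B,C Karplus coefficients in Hz.
#' @return For a single coupling, a numeric vector of phi solutions in
#'   degrees (possibly empty); for several, a list of such vectors.
#' @export
karplus_phi <- function(j3, A = 6.51, B = -1.76, C = 1.60) {
  stopifnot(all(j3 >= 0))
  solve_one <- function(j) {
    disc <- B^2 - 4 * A * (C - j)
    if (disc < 0) return(numeric())
    roots <- (-B + c(1, -1) * sqrt(disc)) / (2 * A)
    roots <- roots[abs(roots) <= 1]
    if (length(roots) == 0L) return(numeric())
    theta <- c(acos(roots), -acos(roots)) * 180 / pi
    phi <- theta + 60
    phi <- ((phi + 180) %% 360) - 180
    phi[phi == -180] <- 180
    sort(unique(round(phi, 10)))
  }
  if (length(j3) == 1L) solve_one(j3) else lapply(j3, solve_one)
}

#' Evaluate the Karplus curve
#' @param phi Backbone dihedral(s) in degrees.
#' @inheritParams karplus_phi
#' @return Predicted 3J(HN,HA) in Hz.
#' @export
karplus_j <- function(phi, A = 6.51, B = -1.76, C = 1.60) {
  th <- (phi - 60) * pi / 180
  A * cos(th)^2 + B * cos(th) + C
}
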