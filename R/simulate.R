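# Synthetic-data generator. Every generator returns the ground truth
# alongside the data so downstream fits have parameter-recovery oracles,
# and every output is a deterministic function of (config, seed).

TC5B_SEQUENCE <- "NLYIQWLKDGGPSSGRPPPS"

#' Simulation configuration
#'
#' Collects the study conditions emulated by the generators: the peptide
#' sequence, the relaxation delay schedules (ten delays spanning 10-1200 ms
#' for R1 and 15.6-469.4 ms for R2, the latter on a constant-increment
#' echo-train grid), noise levels and the cluster-model truth. Noise
#' defaults: 2% fractional intensity noise on decays, 0.1 1/s additive
#' noise on R2 profiles, 0.02 ppm on chemical shifts.
#'
#' The default cluster truth places one Gaussian cluster in the
#' tryptophan-containing region of the Trp-cage sequence with baseline
#' scaling chosen so the intrinsic R2 sits in the 1.5-2.5 1/s range
#' typical of short urea-denatured chains at 14 T.
#'
#' @param seed Integer seed; every generator call is reproducible given
#'   the config.
#' @param sequence One-letter sequence string (default the 20-residue
#'   Trp-cage mini-protein TC5b).
#' @param r1_delays,r2_delays Delay schedules in seconds.
#' @param intensity_noise Fractional (multiplicative Gaussian) intensity
#'   noise on simulated peak heights.
#' @param r2_noise Additive Gaussian noise (1/s) on simulated R2 profiles.
#' @param shift_noise Additive noise (ppm) on simulated shifts.
#' @param replicate_delays Number of delays carrying a duplicate
#'   measurement (default 2).
#' @param truth List of cluster-model truth parameters: \code{A},
#'   \code{lambda0}, \code{R2c}, \code{xc}, \code{Delta}, \code{variant}.
#' @param mask_prolines If TRUE (default), prolines (no backbone amide
#'   proton) and the N-terminal residue (fast-exchanging alpha-amino
#'   group) are masked in HN-detected observables.
#' @param i0 Reference peak amplitude for decay simulation.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       sequence = TC5B_SEQUENCE,
                       r1_delays = c(10, 50, 100, 200, 350, 500, 650, 800,
                                     1000, 1200) / 1000,
                       r2_delays = c(1, 2, 4, 6, 8, 12, 16, 20, 25, 30) *
                         0.0156466,
                       intensity_noise = 0.02,
                       r2_noise = 0.1,
                       shift_noise = 0.02,
                       replicate_delays = 2L,
                       truth = list(A = 0.1, lambda0 = 2, R2c = 2, xc = 6.5,
                                    Delta = 3, variant = "size_weighted"),
                       mask_prolines = TRUE,
                       i0 = 100) {
  stopifnot(intensity_noise >= 0, r2_noise >= 0, shift_noise >= 0,
            !is.unsorted(r1_delays, strictly = TRUE),
            !is.unsorted(r2_delays, strictly = TRUE))
  structure(list(seed = as.integer(seed), sequence = sequence,
                 r1_delays = r1_delays, r2_delays = r2_delays,
                 intensity_noise = intensity_noise, r2_noise = r2_noise,
                 shift_noise = shift_noise,
                 replicate_delays = as.integer(replicate_delays),
                 truth = truth, mask_prolines = mask_prolines, i0 = i0),
            class = "sim_config")
}

#' Simulate a noisy R2 profile from the cluster model
#'
#' Evaluates the cluster model under the config's truth parameters and
#' adds independent Gaussian noise. Set \code{truth$R2c = 0} for a
#' cluster-free (null) profile.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{truth} (the parameters used), \code{seq},
#'   \code{clean} (noiseless profile) and \code{profile} (data frame
#'   \code{residue}, \code{value}, \code{sigma}, \code{mask}).
#' @export
simulate_r2_profile <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seq <- load_sequence(cfg$sequence)
  tr <- cfg$truth
  w <- residue_weights(seq, tr$variant)
  comp <- if (tr$R2c > 0)
    data.frame(R2c = tr$R2c, xc = tr$xc, Delta = tr$Delta)
  else NULL
  clean <- model_r2(tr$A, tr$lambda0, w, comp,
                    positions = residue_indices(seq),
                    weight_positions = residue_indices(seq))
  set.seed(cfg$seed)
  noisy <- as.vector(clean) + stats::rnorm(length(clean), 0, cfg$r2_noise)
  mask <- rep(TRUE, length(clean))
  # HN-detected observables: prolines have no backbone amide proton and the
  # N-terminal residue carries a fast-exchanging alpha-amino group
  if (cfg$mask_prolines) mask <- unclass(seq) != "P" & seq_along(mask) != 1L
  profile <- data.frame(residue = residue_indices(seq),
                        value = ifelse(mask, noisy, NA_real_),
                        sigma = cfg$r2_noise, mask = mask)
  list(truth = tr, seq = seq, clean = as.vector(clean), profile = profile)
}

#' Simulate exponential decay tables
#'
#' Runs the single-exponential decay model forward for a set of
#' per-residue rates at the configured delay schedule, applies
#' multiplicative Gaussian intensity noise, and duplicates the configured
#' number of delays as replicate measurements (by default two, as in a
#' typical error-estimation scheme).
#'
#' @param rates Data frame with columns \code{residue}, \code{value}
#'   (rate, 1/s); masked/NA entries are skipped.
#' @param cfg A \code{\link{sim_config}}.
#' @param schedule \code{"R1"} or \code{"R2"} (selects the delay grid).
#' @return A \code{decay_table} with attribute \code{truth} (the input
#'   rates).
#' @export
simulate_decays <- function(rates, cfg, schedule = c("R1", "R2")) {
  schedule <- match.arg(schedule)
  delays <- if (schedule == "R1") cfg$r1_delays else cfg$r2_delays
  stopifnot(all(is.na(rates$value) | rates$value > 0))
  rep_idx <- if (cfg$replicate_delays > 0)
    round(seq(2, length(delays) - 1, length.out = cfg$replicate_delays))
  else integer()
  set.seed(cfg$seed)
  rows <- list()
  for (r in seq_len(nrow(rates))) {
    rate <- rates$value[r]
    if (is.na(rate)) next
    d <- c(delays, delays[rep_idx])
    repl <- c(rep(1L, length(delays)), rep(2L, length(rep_idx)))
    h <- cfg$i0 * exp(-rate * d)
    if (cfg$intensity_noise > 0)
      h <- h * (1 + stats::rnorm(length(h), 0, cfg$intensity_noise))
    rows[[length(rows) + 1L]] <- data.frame(residue = rates$residue[r],
                                            delay = d, height = h,
                                            replicate = repl)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("decay_table", "data.frame")
  attr(out, "truth") <- rates
  out
}

#' Simulate relaxation triples from a single-Lorentzian spectral density
#'
#' Evaluates J(omega) = (2/5) tau / (1 + (omega tau)^2) at the three
#' mapping frequencies (0, wN, 0.87 wH) and converts to (R1, R2, NOE)
#' through \code{\link{forward_rates}}; optional fractional Gaussian noise
#' is applied to the rates. Used for closed-form limit tests of the
#' spectral density mapping.
#'
#' @param tau Per-residue correlation times (s), > 0.
#' @param k An \code{\link{interaction_constants}} object.
#' @param noise Fractional noise on R1, R2, NOE (default 0).
#' @param seed Seed used when \code{noise > 0}.
#' @param residues Residue numbers (default \code{seq_along(tau)}).
#' @return A \code{relaxation_record} with attribute \code{truth}
#'   (data frame of tau and the three J values).
#' @export
simulate_rates_from_lorentzian <- function(tau, k, noise = 0, seed = 1L,
                                           residues = seq_along(tau)) {
  stopifnot(all(tau > 0))
  j0 <- j_lorentzian(0, tau)
  jwn <- j_lorentzian(k$omega_n, tau)
  jwh <- j_lorentzian(k$high_freq_factor * k$omega_h, tau)
  fw <- forward_rates(j0, jwn, jwh, k)
  if (noise > 0) {
    set.seed(seed)
    fw$R1 <- fw$R1 * (1 + stats::rnorm(length(tau), 0, noise))
    fw$R2 <- fw$R2 * (1 + stats::rnorm(length(tau), 0, noise))
    fw$noe <- fw$noe * (1 + stats::rnorm(length(tau), 0, noise))
  }
  rec <- data.frame(residue = residues, R1 = fw$R1, sR1 = noise * fw$R1,
                    R2 = fw$R2, sR2 = noise * fw$R2,
                    noe = fw$noe, snoe = abs(noise * fw$noe))
  class(rec) <- c("relaxation_record", "data.frame")
  attr(rec, "truth") <- data.frame(residue = residues, tau = tau,
                                   J0 = j0, JwN = jwn, JwH087 = jwh)
  rec
}

#' Simulate an observed chemical-shift table
#'
#' Builds observed shifts as sequence-corrected random-coil reference
#' values plus a localized Gaussian perturbation bump (amplitude x
#' exp(-(i - centre)^2 / (2 width^2)) on the selected nuclei) plus
#' measurement noise. The bump emulates the secondary-shift signature of
#' residual structure.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param amplitude Bump amplitude in ppm (applied to CA and C; the CB
#'   perturbation has opposite sign, as for helix-like structure).
#' @param centre,width Bump centre and width in residue units.
#' @param coil A \code{coil_table} (default the packaged one).
#' @return List with \code{truth} (data frame of per-record true
#'   perturbations), \code{reference}, \code{observed} (a
#'   \code{shift_table}) and \code{seq}.
#' @export
simulate_shift_table <- function(cfg, amplitude = 0.6, centre = 6,
                                 width = 2.5, coil = default_coil_table()) {
  seq <- load_sequence(cfg$sequence)
  reference <- corrected_random_coil(seq, coil)
  bump <- amplitude * exp(-(reference$residue - centre)^2 / (2 * width^2))
  bump <- ifelse(reference$nucleus == "CB", -bump, bump)
  set.seed(cfg$seed)
  noise <- stats::rnorm(nrow(reference), 0, cfg$shift_noise)
  observed <- data.frame(residue = reference$residue,
                         nucleus = reference$nucleus,
                         shift = reference$shift + bump + noise)
  class(observed) <- c("shift_table", "data.frame")
  list(truth = data.frame(residue = reference$residue,
                          nucleus = reference$nucleus, ddelta = bump),
       reference = reference, observed = observed, seq = seq)
}

#' Simulate a gradient diffusion decay
#'
#' Stejskal-Tanner forward model with multiplicative Gaussian noise.
#'
#' @param D Diffusion coefficient, m^2/s (> 0).
#' @param cfg A \code{\link{sim_config}} (supplies seed and intensity
#'   noise).
#' @param n_points Number of gradient points (default 16).
#' @param g_max Maximum gradient strength, T/m (default 0.5).
#' @param delta,big_delta,gamma Pulse parameters (defaults 2 ms, 100 ms,
#'   1H).
#' @return Data frame with columns \code{g}, \code{intensity}, and
#'   attributes \code{truth} (D), \code{delta}, \code{big_delta},
#'   \code{gamma}.
#' @export
simulate_diffusion <- function(D, cfg, n_points = 16L, g_max = 0.5,
                               delta = 2e-3, big_delta = 0.1,
                               gamma = GAMMA_H) {
  stopifnot(D > 0, n_points >= 4L)
  g <- seq(0.01, g_max, length.out = n_points)
  b <- stejskal_tanner_b(g, delta, big_delta, gamma)
  intensity <- exp(-D * b)
  set.seed(cfg$seed)
  if (cfg$intensity_noise > 0)
    intensity <- intensity * (1 + stats::rnorm(n_points, 0, cfg$intensity_noise))
  out <- data.frame(g = g, intensity = intensity)
  attr(out, "truth") <- D
  attr(out, "delta") <- delta
  attr(out, "big_delta") <- big_delta
  attr(out, "gamma") <- gamma
  out
}

#' Write a complete synthetic fixture directory
#'
#' Generates the default denatured-TC5b preset — a 20-residue chain with a single
#' hydrophobic cluster near the tryptophan, proline HN masking for
#' HN-detected observables — and writes sequence FASTA, R1/R2 decay TSVs,
#' a shift TSV, a gradient TSV and a truth YAML into \code{dir}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the list of file paths written.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seq <- load_sequence(cfg$sequence)
  paths <- list()

  writeLines(c(">synthetic peptide", cfg$sequence),
             paths$fasta <- file.path(dir, "sequence.fasta"))

  prof <- simulate_r2_profile(cfg)
  r2_rates <- data.frame(residue = prof$profile$residue,
                         value = ifelse(prof$profile$mask, prof$clean, NA))
  # R1 truth: flat profile typical of a denatured chain
  r1_rates <- data.frame(residue = r2_rates$residue,
                         value = ifelse(is.na(r2_rates$value), NA, 1.6))
  cfg_r1 <- cfg; cfg_r1$seed <- cfg$seed + 1L
  write_decay_table(simulate_decays(r1_rates, cfg_r1, "R1"),
                    paths$r1 <- file.path(dir, "r1_decays.tsv"))
  cfg_r2 <- cfg; cfg_r2$seed <- cfg$seed + 2L
  # decays are generated from the noisy profile so the fitted profile
  # carries both intensity and profile noise
  r2_noisy <- data.frame(residue = prof$profile$residue,
                         value = ifelse(prof$profile$value > 0,
                                        prof$profile$value, NA))
  write_decay_table(simulate_decays(r2_noisy, cfg_r2, "R2"),
                    paths$r2 <- file.path(dir, "r2_decays.tsv"))

  sh <- simulate_shift_table(cfg)
  write_shift_table(sh$observed, paths$shifts <- file.path(dir, "shifts.tsv"))

  diff_tab <- simulate_diffusion(1.5e-10, cfg)
  write_dialect_tsv(diff_tab, paths$gradients <- file.path(dir, "gradients.tsv"),
                    comment = "gradient diffusion profile: g in T/m")

  yaml::write_yaml(list(seed = cfg$seed, sequence = cfg$sequence,
                        cluster_truth = cfg$truth,
                        r1_truth = 1.6, diffusion_truth = 1.5e-10,
                        noise = list(intensity = cfg$intensity_noise,
                                     r2 = cfg$r2_noise,
                                     shift = cfg$shift_noise)),
                   paths$truth <- file.path(dir, "truth.yaml"))
  invisible(paths)
}
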