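# Reduced spectral density mapping for the backbone 15N-1H spin pair.
#
# The dipolar and CSA interaction strengths are built from CODATA physical
# constants; the mapping itself is the standard single-high-frequency
# reduction in which the spectral density is taken to be flat around the
# proton frequency, so that the three linear combinations entering R1, R2
# and the NOE can be inverted exactly for J(0), J(wN) and J(0.87wH).

# CODATA gyromagnetic ratios (rad s^-1 T^-1); 15N is negative.
GAMMA_H <- 2.6752218744e8
GAMMA_N15 <- -2.7126180e7
HBAR <- 1.054571817e-34
MU0 <- 4 * pi * 1e-7

#' Spectrometer field context
#'
#' Captures the static-field frequencies for the 1H/15N pair. Either
#' frequency may be given alone, in which case the other is derived from
#' the gyromagnetic ratios; when both are given they must agree with
#' |gammaN/gammaH| to within 2%.
#'
#' @param nitrogen_mhz 15N Larmor frequency in MHz (e.g. 60.25).
#' @param proton_mhz 1H Larmor frequency in MHz (e.g. 599.92).
#' @param temperature Sample temperature in K (metadata only).
#' @return A \code{spectrometer_context} list with \code{proton_mhz},
#'   \code{nitrogen_mhz}, \code{omega_h}, \code{omega_n} (rad/s, magnitudes)
#'   and \code{temperature}.
#' @export
spectrometer_context <- function(nitrogen_mhz = NULL, proton_mhz = NULL,
                                 temperature = 298) {
  ratio <- abs(GAMMA_H / GAMMA_N15)
  if (is.null(nitrogen_mhz) && is.null(proton_mhz))
    stop("supply nitrogen_mhz and/or proton_mhz")
  if (is.null(proton_mhz)) proton_mhz <- nitrogen_mhz * ratio
  if (is.null(nitrogen_mhz)) nitrogen_mhz <- proton_mhz / ratio
  stopifnot(proton_mhz > 0, nitrogen_mhz > 0)
  if (abs(proton_mhz / nitrogen_mhz - ratio) / ratio > 0.02)
    stop("proton/nitrogen frequency ratio deviates from |gammaH/gammaN| by > 2%")
  structure(list(proton_mhz = proton_mhz, nitrogen_mhz = nitrogen_mhz,
                 omega_h = 2 * pi * proton_mhz * 1e6,
                 omega_n = 2 * pi * nitrogen_mhz * 1e6,
                 temperature = temperature),
            class = "spectrometer_context")
}

#' Dipolar and CSA interaction constants
#'
#' Builds the interaction strengths entering the 15N relaxation rate
#' expressions: the dipolar constant
#' d = (mu0/4pi) * hbar * gammaH * |gammaN| / rNH^3 and the CSA constant
#' c = omegaN * dsigma / sqrt(3) (dsigma dimensionless, ppm * 1e-6).
#'
#' @param ctx A \code{\link{spectrometer_context}}.
#' @param rnh N-H bond length in Angstrom (default 1.02).
#' @param csa 15N chemical shift anisotropy in ppm (default 172).
#' @return An \code{interaction_constants} list with \code{d}, \code{c}
#'   (rad/s), the angular frequencies and the signed gyromagnetic ratios.
#' @export
interaction_constants <- function(ctx, rnh = 1.02, csa = 172) {
  stopifnot(inherits(ctx, "spectrometer_context"))
  if (rnh <= 0) stop("nonphysical N-H bond length")
  r_m <- rnh * 1e-10
  d <- (MU0 / (4 * pi)) * HBAR * GAMMA_H * abs(GAMMA_N15) / r_m^3
  cc <- ctx$omega_n * csa * 1e-6 / sqrt(3)
  structure(list(d = d, c = cc,
                 omega_h = ctx$omega_h, omega_n = ctx$omega_n,
                 gamma_h = GAMMA_H, gamma_n = GAMMA_N15,
                 rnh = rnh, csa = csa,
                 high_freq_factor = 0.87),
            class = "interaction_constants")
}

#' Relaxation rates from a spectral density triple (forward map)
#'
#' Evaluates the reduced-mapping rate expressions
#' \deqn{R1 = (d^2/4)(3 J(wN) + 7 J(0.87 wH)) + c^2 J(wN)}
#' \deqn{R2 = (d^2/8)(4 J(0) + 3 J(wN) + 13 J(0.87 wH)) + (c^2/6)(4 J(0) + 3 J(wN))}
#' \deqn{NOE = 1 + (gammaH/gammaN)(d^2/4) \, 5 J(0.87 wH) / R1}
#' with the signed gyromagnetic ratio, so a positive high-frequency
#' spectral density lowers the NOE below 1 for 15N. This is the exact
#' algebraic inverse of \code{\link{reduced_jmap}} and serves as its
#' oracle in tests.
#'
#' @param j0,jwn,jwh Spectral densities at 0, wN and 0.87 wH (s/rad).
#' @param k An \code{\link{interaction_constants}} object.
#' @return List with \code{R1}, \code{R2} (1/s) and \code{noe}.
#' @export
forward_rates <- function(j0, jwn, jwh, k) {
  stopifnot(inherits(k, "interaction_constants"))
  d2 <- k$d^2; c2 <- k$c^2
  r1 <- (d2 / 4) * (3 * jwn + 7 * jwh) + c2 * jwn
  r2 <- (d2 / 8) * (4 * j0 + 3 * jwn + 13 * jwh) + (c2 / 6) * (4 * j0 + 3 * jwn)
  if (any(r1 == 0)) stop("R1 = 0: NOE undefined")
  noe <- 1 + (k$gamma_h / k$gamma_n) * (d2 / 4) * 5 * jwh / r1
  list(R1 = r1, R2 = r2, noe = noe)
}

# Deterministic core of the reduction (vectorized over residues)
jmap_core <- function(r1, r2, noe, k) {
  d2 <- k$d^2; c2 <- k$c^2
  sigma_nh <- r1 * (noe - 1) * (k$gamma_n / k$gamma_h)
  jwh <- (4 / 5) * sigma_nh / d2
  jwn <- (r1 - (7 * d2 / 4) * jwh) / (3 * d2 / 4 + c2)
  j0 <- (r2 - (13 * d2 / 8) * jwh - (3 * d2 / 8 + c2 / 2) * jwn) /
    (d2 / 2 + 2 * c2 / 3)
  list(J0 = j0, JwN = jwn, JwH = jwh)
}

#' Reduced spectral density mapping
#'
#' Converts per-residue (R1, R2, NOE) triples into the spectral densities
#' J(0), J(wN) and J(0.87 wH) by inverting the rate expressions of
#' \code{\link{forward_rates}}. Exchange contributions to R2 are assumed
#' absent, so any exchange broadening is absorbed into J(0). Uncertainties
#' are propagated by Monte Carlo: the rate triple is resampled from
#' independent normals with the supplied sigmas and remapped.
#'
#' A noise-perturbed triple can push J(0) negative; such values are
#' reported as-is and flagged in the \code{mask} column rather than
#' clipped.
#'
#' @param rec A \code{relaxation_record} (columns \code{residue},
#'   \code{R1}, \code{sR1}, \code{R2}, \code{sR2}, \code{noe}, \code{snoe}).
#' @param k An \code{\link{interaction_constants}} object.
#' @param n_mc Monte Carlo draws for error propagation (default 1000).
#' @param seed Optional seed for the propagation.
#' @return A \code{spectral_density_record} data frame: \code{residue},
#'   \code{J0}, \code{sJ0}, \code{JwN}, \code{sJwN}, \code{JwH087},
#'   \code{sJwH087} (s/rad), \code{mask}.
#' @export
reduced_jmap <- function(rec, k, n_mc = 1000L, seed = NULL) {
  stopifnot(inherits(k, "interaction_constants"))
  ok <- !is.na(rec$R1) & !is.na(rec$R2) & !is.na(rec$noe) & rec$R1 > 0
  central <- jmap_core(rec$R1, rec$R2, rec$noe, k)
  s <- list(J0 = rep(NA_real_, nrow(rec)), JwN = rep(NA_real_, nrow(rec)),
            JwH = rep(NA_real_, nrow(rec)))
  have_err <- all(c("sR1", "sR2", "snoe") %in% names(rec)) &&
    any(!is.na(rec$sR1) | !is.na(rec$sR2) | !is.na(rec$snoe))
  if (have_err && n_mc > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
      set.seed(seed)
    }
    for (i in which(ok)) {
      r1 <- stats::rnorm(n_mc, rec$R1[i], ifelse(is.na(rec$sR1[i]), 0, rec$sR1[i]))
      r2 <- stats::rnorm(n_mc, rec$R2[i], ifelse(is.na(rec$sR2[i]), 0, rec$sR2[i]))
      nn <- stats::rnorm(n_mc, rec$noe[i], ifelse(is.na(rec$snoe[i]), 0, rec$snoe[i]))
      keep <- r1 > 0
      draws <- jmap_core(r1[keep], r2[keep], nn[keep], k)
      s$J0[i] <- stats::sd(draws$J0); s$JwN[i] <- stats::sd(draws$JwN)
      s$JwH[i] <- stats::sd(draws$JwH)
    }
  }
  out <- data.frame(residue = rec$residue,
                    J0 = ifelse(ok, central$J0, NA_real_), sJ0 = s$J0,
                    JwN = ifelse(ok, central$JwN, NA_real_), sJwN = s$JwN,
                    JwH087 = ifelse(ok, central$JwH, NA_real_), sJwH087 = s$JwH,
                    mask = ok & !is.na(central$J0) & central$J0 >= 0)
  class(out) <- c("spectral_density_record", "data.frame")
  out
}

#' Single-Lorentzian spectral density
#'
#' J(omega) = (2/5) tau / (1 + (omega tau)^2), the spectral density of
#' isotropic tumbling with a single correlation time; used as the
#' closed-form oracle for the mapping in the motional-narrowing limit.
#'
#' @param omega Angular frequency (rad/s).
#' @param tau Correlation time (s).
#' @return Spectral density (s/rad).
#' @export
j_lorentzian <- function(omega, tau) {
  stopifnot(all(tau > 0))
  0.4 * tau / (1 + (omega * tau)^2)
}
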