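# Pulsed-field-gradient diffusion: Stejskal-Tanner fitting and
# hydrodynamic radii.

KB <- 1.380649e-23  # J/K

#' Stejskal-Tanner attenuation exponent
#'
#' b(g) = gamma^2 g^2 delta^2 (Delta - delta/3) * shape, the diffusion
#' weighting of a pulsed-gradient spin-echo with rectangular gradient
#' pulses; \code{shape} is a multiplicative correction for non-rectangular
#' pulse shapes (1 for rectangular, 4/pi^2 for sine-shaped).
#'
#' @param g Gradient strength(s), T/m.
#' @param delta Gradient pulse duration, s.
#' @param big_delta Diffusion delay, s.
#' @param gamma Gyromagnetic ratio of the observed nucleus, rad/s/T
#'   (default 1H).
#' @param shape Gradient-shape correction factor (default 1, rectangular).
#' @return b values in s/m^2.
#' @export
stejskal_tanner_b <- function(g, delta, big_delta, gamma = GAMMA_H, shape = 1) {
  stopifnot(delta > 0, big_delta > delta / 3)
  gamma^2 * g^2 * delta^2 * (big_delta - delta / 3) * shape
}

#' Fit a diffusion coefficient to a gradient decay
#'
#' Least-squares fit of I(g) = I0 exp(-D b(g)) to a gradient-intensity
#' profile. Requires at least 4 gradient points. With all intensities
#' equal the exact solution D = 0 is returned and flagged nonphysical; a
#' noiseless profile that is not monotonically decreasing in g triggers a
#' warning.
#'
#' @param series Data frame with columns \code{g} (T/m) and
#'   \code{intensity}.
#' @param delta,big_delta,gamma,shape Pulse parameters, see
#'   \code{\link{stejskal_tanner_b}}.
#' @param error_method \code{"cov"} (default, linearized) or \code{"mc"}
#'   (residual-resampling Monte Carlo).
#' @param n_mc,seed Monte Carlo settings.
#' @return A \code{diffusion_fit} list: \code{D} (m^2/s), \code{sigma_D},
#'   \code{I0}, \code{converged}, \code{nonphysical}.
#' @export
fit_diffusion <- function(series, delta, big_delta, gamma = GAMMA_H,
                          shape = 1, error_method = c("cov", "mc"),
                          n_mc = 200L, seed = NULL) {
  error_method <- match.arg(error_method)
  g <- series$g; intensity <- series$intensity
  if (length(g) < 4L) stop("need at least 4 gradient points")
  if (any(g < 0)) stop("gradient strengths must be >= 0")
  b <- stejskal_tanner_b(g, delta, big_delta, gamma, shape)
  if (diff(range(intensity)) == 0)
    return(structure(list(D = 0, sigma_D = 0, I0 = intensity[1],
                          converged = TRUE, nonphysical = TRUE),
                     class = "diffusion_fit"))
  ord <- order(g)
  # gross non-monotonicity (an increase above 10% of the intensity range)
  # indicates convection or mis-ordered data rather than noise
  if (any(diff(intensity[ord]) > 0.1 * diff(range(intensity))))
    warning("intensity profile is not monotone decreasing in g")
  fit_once <- function(y) {
    pos <- y > 0
    st <- if (sum(pos) >= 2) {
      cf <- stats::coef(stats::lm(log(y[pos]) ~ b[pos]))
      list(I0 = exp(cf[[1]]), D = max(-cf[[2]], 1e-16))
    } else list(I0 = max(y), D = 1e-10)
    f <- try(minpack.lm::nlsLM(y ~ I0 * exp(-D * b), start = st,
                               lower = c(0, 0)), silent = TRUE)
    if (inherits(f, "try-error")) return(c(NA_real_, NA_real_))
    stats::coef(f)[c("D", "I0")]
  }
  cf <- fit_once(intensity)
  if (any(is.na(cf)))
    return(structure(list(D = NA_real_, sigma_D = NA_real_, I0 = NA_real_,
                          converged = FALSE, nonphysical = FALSE),
                     class = "diffusion_fit"))
  fitted_i <- cf[["I0"]] * exp(-cf[["D"]] * b)
  resid <- intensity - fitted_i
  sigma_D <- NA_real_
  if (error_method == "mc") {
    if (!is.null(seed)) set.seed(seed)
    draws <- vapply(seq_len(n_mc), function(kk)
      fit_once(fitted_i + sample(resid, length(resid), replace = TRUE))[1],
      numeric(1))
    sigma_D <- stats::sd(draws, na.rm = TRUE)
  } else {
    # linearized error from the log-domain regression weighted by I^2
    n <- length(b)
    s2 <- sum(resid^2) / max(n - 2, 1)
    X <- cbind(1, -b) * fitted_i       # Jacobian in (log I0, D)
    cov_m <- try(s2 * solve(crossprod(X)), silent = TRUE)
    if (!inherits(cov_m, "try-error")) sigma_D <- sqrt(cov_m[2, 2])
  }
  structure(list(D = cf[["D"]], sigma_D = sigma_D, I0 = cf[["I0"]],
                 converged = TRUE, nonphysical = cf[["D"]] <= 0),
            class = "diffusion_fit")
}

#' Hydrodynamic radius from a diffusion coefficient
#'
#' Reference mode uses an internal standard of known radius measured in
#' the same sample: R_H = (D_ref / D) * R_H_ref, which cancels the (often
#' unknown) solvent viscosity — the recommended path in denaturant
#' solutions. Stokes-Einstein mode computes R_H = kB T / (6 pi eta D)
#' from an explicit temperature and viscosity.
#'
#' @param D Diffusion coefficient, m^2/s (> 0).
#' @param sigma_D Uncertainty on D (optional).
#' @param reference List with \code{D} (m^2/s) and \code{rh} (Angstrom) of
#'   the internal reference compound.
#' @param solvent List with \code{temperature} (K) and \code{viscosity}
#'   (Pa s).
#' @return A \code{hydro_result} list: \code{D}, \code{sigma_D},
#'   \code{rh} (Angstrom), \code{sigma_rh}, \code{method}.
#' @export
hydrodynamic_radius <- function(D, sigma_D = 0, reference = NULL,
                                solvent = NULL) {
  if (is.null(reference) == is.null(solvent))
    stop("supply exactly one of 'reference' or 'solvent'")
  stopifnot(D > 0)
  if (!is.null(reference)) {
    stopifnot(all(c("D", "rh") %in% names(reference)))
    rh <- reference$D / D * reference$rh
    method <- "reference"
  } else {
    stopifnot(all(c("temperature", "viscosity") %in% names(solvent)))
    rh_m <- KB * solvent$temperature / (6 * pi * solvent$viscosity * D)
    rh <- rh_m * 1e10
    method <- "stokes-einstein"
  }
  sigma_rh <- rh * sigma_D / D
  structure(list(D = D, sigma_D = sigma_D, rh = rh, sigma_rh = sigma_rh,
                 method = method),
            class = "hydro_result")
}
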