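# 15N relaxation: single-exponential decay fitting, replicate-based error
# estimation, steady-state heteronuclear NOE, R2/R1 ratios and cis/trans
# isomer populations.

#' Fit a single-exponential relaxation decay
#'
#' Fits the two-parameter model I(t) = I0 * exp(-R * t) to peak heights by
#' nonlinear least squares. Replicate measurements enter as independent
#' points. The decay model deliberately has no offset term; an offset can
#' be enabled for quality control only, since heteronuclear relaxation
#' decays of well-phased peaks decay to the baseline.
#'
#' @param series A \code{decay_table} restricted to a single residue, or
#'   any data frame with columns \code{delay} (s) and \code{height}.
#' @param sigma Optional per-point intensity uncertainties used as weights
#'   (1/sigma^2). See \code{\link{replicate_error}}.
#' @param error_method How to estimate the rate uncertainty:
#'   \code{"mc"} (default) resamples residuals (parametric when \code{sigma}
#'   is given) and refits; \code{"cov"} uses the linearized covariance
#'   matrix. Small delay schedules (10 points) make linearized errors
#'   unreliable, hence the Monte Carlo default.
#' @param n_mc Number of Monte Carlo draws (default 200).
#' @param seed Optional seed for the Monte Carlo resampling.
#' @param offset If TRUE, adds a constant offset parameter (QC only).
#' @return A \code{rate_estimate} list: \code{rate}, \code{I0},
#'   \code{sigma_rate}, \code{sigma_I0}, \code{residuals}, \code{rss},
#'   \code{converged}, \code{unreliable} (TRUE when sigma_rate/rate > 0.5).
#' @export
fit_exponential <- function(series, sigma = NULL,
                            error_method = c("mc", "cov"),
                            n_mc = 200L, seed = NULL, offset = FALSE) {
  error_method <- match.arg(error_method)
  delays <- series$delay
  heights <- series$height
  stopifnot(length(delays) == length(heights))
  if (any(delays < 0)) stop("delays must be >= 0")
  if (length(unique(delays)) < 3L)
    stop("need at least 3 distinct delays to fit a decay")
  w <- if (is.null(sigma)) rep(1, length(heights)) else {
    stopifnot(length(sigma) == length(heights))
    if (all(sigma == 0)) rep(1, length(heights)) else 1 / pmax(sigma, max(sigma) * 1e-6)^2
  }

  core_fit <- function(h) {
    if (diff(range(h)) == 0) {
      # constant heights: exact solution R = 0, I0 = the constant
      return(list(I0 = h[1], R = 0, fitted = rep(h[1], length(h)),
                  converged = TRUE))
    }
    # log-linear start (guard against non-positive heights)
    pos <- h > 0
    st <- if (sum(pos) >= 2) {
      cf <- stats::coef(stats::lm(log(h[pos]) ~ delays[pos]))
      list(I0 = exp(cf[[1]]), R = max(-cf[[2]], 1e-6))
    } else list(I0 = max(abs(h)), R = 1)
    lower <- if (offset) c(-Inf, 0, -Inf) else c(-Inf, 0)
    fml <- if (offset) h ~ I0 * exp(-R * delays) + B else h ~ I0 * exp(-R * delays)
    start <- if (offset) c(st, list(B = 0)) else st
    fit <- try(minpack.lm::nlsLM(fml, start = start, weights = w,
                                 lower = lower,
                                 control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error"))
      return(list(I0 = NA_real_, R = NA_real_, fitted = rep(NA_real_, length(h)),
                  converged = FALSE))
    cf <- stats::coef(fit)
    list(I0 = cf[["I0"]], R = cf[["R"]], fitted = stats::fitted(fit),
         converged = TRUE, fit = fit)
  }

  base <- core_fit(heights)
  if (!base$converged)
    return(structure(list(rate = NA_real_, I0 = NA_real_,
                          sigma_rate = NA_real_, sigma_I0 = NA_real_,
                          residuals = NULL, rss = NA_real_,
                          converged = FALSE, unreliable = TRUE),
                     class = "rate_estimate"))
  resid <- heights - base$fitted
  rss <- sum(w * resid^2)

  sigma_rate <- sigma_I0 <- NA_real_
  if (error_method == "cov" && !is.null(base$fit)) {
    sm <- try(summary(base$fit), silent = TRUE)
    if (!inherits(sm, "try-error")) {
      sigma_rate <- sm$coefficients["R", "Std. Error"]
      sigma_I0 <- sm$coefficients["I0", "Std. Error"]
    }
  } else if (diff(range(heights)) > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
      set.seed(seed)
    }
    draws <- vapply(seq_len(n_mc), function(k) {
      h_k <- if (is.null(sigma))
        base$fitted + sample(resid, length(resid), replace = TRUE)
      else
        base$fitted + stats::rnorm(length(resid), 0, sigma)
      f <- core_fit(h_k)
      c(f$R, f$I0)
    }, numeric(2))
    sigma_rate <- stats::sd(draws[1, ], na.rm = TRUE)
    sigma_I0 <- stats::sd(draws[2, ], na.rm = TRUE)
  } else {
    sigma_rate <- 0; sigma_I0 <- 0
  }

  structure(list(rate = base$R, I0 = base$I0,
                 sigma_rate = sigma_rate, sigma_I0 = sigma_I0,
                 residuals = resid, rss = rss, converged = TRUE,
                 unreliable = is.finite(sigma_rate) && base$R > 0 &&
                   sigma_rate / base$R > 0.5),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate: R = %.4g +/- %.2g 1/s, I0 = %.4g%s\n",
              x$rate, x$sigma_rate, x$I0,
              if (isTRUE(x$unreliable)) " [unreliable]" else ""))
  invisible(x)
}

#' Replicate-based intensity error
#'
#' Estimates the experimental intensity error from repeated measurements:
#' at every delay with two or more replicates the replicate variance is
#' pooled, expressed as a fractional error relative to the mean height at
#' that delay, and applied to all points of the series as
#' \code{sigma_i = fraction * |height_i|}.
#'
#' @param series A \code{decay_table} for one residue (columns
#'   \code{delay}, \code{height}, \code{replicate}).
#' @return Numeric vector of per-point sigmas (same order as the series),
#'   with attributes \code{fractional} (the pooled fractional error) and
#'   \code{pooled_sd} (the pooled absolute replicate standard deviation).
#' @export
replicate_error <- function(series) {
  key <- signif(series$delay, 12)
  groups <- split(series$height, key)
  reps <- Filter(function(g) length(g) >= 2L, groups)
  if (length(reps) == 0L)
    stop("no replicate pairs found; supply per-point sigma explicitly")
  dfs <- vapply(reps, function(g) length(g) - 1, numeric(1))
  vars <- vapply(reps, stats::var, numeric(1))
  means <- vapply(reps, mean, numeric(1))
  pooled_sd <- sqrt(sum(dfs * vars) / sum(dfs))
  frac_var <- vapply(seq_along(reps),
                     function(k) vars[k] / means[k]^2, numeric(1))
  fraction <- sqrt(sum(dfs * frac_var) / sum(dfs))
  out <- fraction * abs(series$height)
  attr(out, "fractional") <- fraction
  attr(out, "pooled_sd") <- pooled_sd
  out
}

#' Steady-state heteronuclear NOE
#'
#' Computes the 1H-15N heteronuclear NOE per residue as the ratio of peak
#' heights measured with and without proton presaturation,
#' noe = I_sat / I_unsat. This is the standard convention in which a
#' flexible backbone gives values well below 1 (and possibly negative).
#' Uncertainties propagate in quadrature from the supplied intensity
#' errors. Set \code{invert = TRUE} to use the inverse ratio.
#'
#' @param sat Data frame with columns \code{residue}, \code{height}
#'   (presaturated experiment); optional \code{sigma}.
#' @param unsat Same for the reference (no presaturation) experiment.
#' @param invert If TRUE, computes I_unsat / I_sat instead.
#' @return Data frame with columns \code{residue}, \code{noe},
#'   \code{sigma}, \code{mask} (FALSE where the denominator is 0 or a peak
#'   is missing).
#' @export
compute_hetnoe <- function(sat, unsat, invert = FALSE) {
  stopifnot(all(c("residue", "height") %in% names(sat)),
            all(c("residue", "height") %in% names(unsat)))
  residues <- sort(union(sat$residue, unsat$residue))
  is_ <- sat$height[match(residues, sat$residue)]
  iu <- unsat$height[match(residues, unsat$residue)]
  ss <- if ("sigma" %in% names(sat)) sat$sigma[match(residues, sat$residue)] else 0
  su <- if ("sigma" %in% names(unsat)) unsat$sigma[match(residues, unsat$residue)] else 0
  if (invert) { tmp <- is_; is_ <- iu; iu <- tmp; tmp <- ss; ss <- su; su <- tmp }
  mask <- !is.na(is_) & !is.na(iu) & iu != 0
  noe <- ifelse(mask, is_ / iu, NA_real_)
  ss <- rep_len(ss, length(residues)); su <- rep_len(su, length(residues))
  # d(noe) from I_sat and I_unsat errors; safe at I_sat = 0
  sigma <- ifelse(mask, sqrt((ss / iu)^2 + (noe * su / iu)^2), NA_real_)
  data.frame(residue = residues, noe = noe, sigma = sigma, mask = mask)
}

#' Assemble a relaxation record table
#'
#' Joins fitted R1, R2 and heteronuclear NOE results into one per-residue
#' table and adds the R2/R1 ratio with quadrature error propagation. The
#' missing-data mask propagates from the inputs.
#'
#' @param r1,r2 Data frames with columns \code{residue}, \code{value},
#'   \code{sigma} (e.g. from \code{\link{fit_rate_table}}).
#' @param noe Data frame from \code{\link{compute_hetnoe}}.
#' @return A \code{relaxation_record} data frame with columns
#'   \code{residue}, \code{R1}, \code{sR1}, \code{R2}, \code{sR2},
#'   \code{noe}, \code{snoe}, \code{r2_over_r1}, \code{s_r2_over_r1}.
#' @export
relaxation_record <- function(r1, r2, noe = NULL) {
  residues <- sort(Reduce(union, list(r1$residue, r2$residue,
                                      if (is.null(noe)) integer() else noe$residue)))
  pick <- function(tab, col, scol) {
    i <- match(residues, tab$residue)
    list(v = tab[[col]][i], s = tab[[scol]][i])
  }
  a <- pick(r1, "value", "sigma"); b <- pick(r2, "value", "sigma")
  ratio <- ifelse(!is.na(a$v) & !is.na(b$v) & a$v > 0, b$v / a$v, NA_real_)
  sratio <- ratio * sqrt((a$s / a$v)^2 + (b$s / b$v)^2)
  out <- data.frame(residue = residues,
                    R1 = a$v, sR1 = a$s, R2 = b$v, sR2 = b$s,
                    noe = NA_real_, snoe = NA_real_,
                    r2_over_r1 = ratio, s_r2_over_r1 = sratio)
  if (!is.null(noe)) {
    i <- match(residues, noe$residue)
    out$noe <- ifelse(noe$mask[i], noe$noe[i], NA_real_)
    out$snoe <- ifelse(noe$mask[i], noe$sigma[i], NA_real_)
  }
  class(out) <- c("relaxation_record", "data.frame")
  out
}

#' Fit rates for every residue of a decay table
#'
#' Convenience wrapper applying \code{\link{fit_exponential}} (with
#' replicate-based weighting when replicates are present) across residues.
#'
#' @param tab A \code{decay_table}.
#' @param error One of \code{"replicate"} (replicate-derived sigmas +
#'   Monte Carlo rate error), \code{"mc"} (unweighted fit, Monte Carlo
#'   error) or \code{"cov"}.
#' @param seed Optional seed for the Monte Carlo error model.
#' @param n_mc Monte Carlo draws per residue.
#' @return Data frame with columns \code{residue}, \code{value} (rate,
#'   1/s), \code{sigma}, \code{unreliable}.
#' @export
fit_rate_table <- function(tab, error = c("replicate", "mc", "cov"),
                           seed = NULL, n_mc = 200L) {
  error <- match.arg(error)
  residues <- sort(unique(tab$residue))
  rows <- lapply(seq_along(residues), function(k) {
    series <- decay_series(tab, residues[k])
    sig <- if (error == "replicate")
      tryCatch(replicate_error(series), error = function(e) NULL) else NULL
    est <- fit_exponential(series, sigma = sig,
                           error_method = if (error == "cov") "cov" else "mc",
                           n_mc = n_mc,
                           seed = if (is.null(seed)) NULL else seed + k)
    data.frame(residue = residues[k], value = est$rate, sigma = est$sigma_rate,
               unreliable = isTRUE(est$unreliable))
  })
  do.call(rbind, rows)
}

#' Proline cis/trans isomer population from duplicate peak sets
#'
#' In a slowly exchanging denatured state, residues near a proline show a
#' duplicated resonance set; the minor-set population reports the cis
#' isomer fraction. The per-residue fraction is minor / (minor + major);
#' the summary is the mean and standard deviation across residues.
#'
#' @param major Per-residue intensities of the major (trans) peak set:
#'   data frame with columns \code{residue}, \code{height}.
#' @param minor Same for the minor (cis) peak set.
#' @return List with \code{per_residue} (data frame), \code{fraction}
#'   (mean), \code{sigma} (sd across residues; NA with a single residue).
#' @export
isomer_fraction <- function(major, minor) {
  residues <- intersect(major$residue, minor$residue)
  if (length(residues) == 0L) stop("no residue with both peak sets quantified")
  ma <- major$height[match(residues, major$residue)]
  mi <- minor$height[match(residues, minor$residue)]
  tot <- ma + mi
  if (all(tot == 0)) stop("all-zero intensities")
  keep <- tot > 0
  frac <- mi[keep] / tot[keep]
  list(per_residue = data.frame(residue = residues[keep], fraction = frac),
       fraction = mean(frac),
       sigma = if (length(frac) > 1L) stats::sd(frac) else NA_real_)
}
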