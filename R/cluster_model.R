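# Sequence-dependent transverse relaxation cluster model.
#
# The observed R2 profile of a denatured chain is modelled as the sum of an
# intrinsic segmental-motion baseline and localized Gaussian cluster terms:
#
#   R2(i) = A * sum_j w_j * exp(-|i - j| / lambda0)
#         + sum_c R2c * exp(-(i - xc)^2 / (2 Delta^2))
#
# The first term says that the motional restriction a residue feels from
# its neighbours decays exponentially with sequence separation, with
# persistence length lambda0 (residues). The weight w_j is a proxy for the
# intrinsic correlation time of residue j: in the size-weighted variant it
# is 1 for glycine and alanine and 7 for all other residues (small residues
# allow more backbone flexibility); in the uniform variant every residue
# contributes equally (w_j = 1). Each cluster term is a Gaussian bump with
# amplitude R2c (1/s), centre xc (continuous residue coordinate) and
# half-width Delta (residues).

#' Residue weights for the segmental-motion baseline
#'
#' @param seq A \code{peptide_sequence}.
#' @param variant \code{"size_weighted"} (1 for Gly/Ala, 7 otherwise) or
#'   \code{"uniform"} (all 1).
#' @return Numeric weight vector, one entry per residue.
#' @export
residue_weights <- function(seq, variant = c("size_weighted", "uniform")) {
  variant <- match.arg(variant)
  if (variant == "uniform") return(rep(1, length(seq)))
  ifelse(unclass(seq) %in% c("G", "A"), 1, 7)
}

#' Evaluate the cluster model R2 profile
#'
#' @param A Empirical scaling constant (1/s per weight unit), >= 0.
#' @param lambda0 Persistence length in residues, > 0.
#' @param weights Per-residue weight vector (see
#'   \code{\link{residue_weights}}).
#' @param components Data frame of cluster components with columns
#'   \code{R2c}, \code{xc}, \code{Delta} (may have zero rows).
#' @param positions Residue numbers at which to evaluate; defaults to
#'   \code{seq_along(weights)}.
#' @param weight_positions Residue numbers of the weight vector entries
#'   (defaults to \code{seq_along(weights)}); needed when the numbering
#'   origin is not 1.
#' @param width_convention \code{"sigma"} (default): the Gaussian is
#'   \code{exp(-(i-xc)^2 / (2 Delta^2))}; \code{"exp2"}: the alternative
#'   \code{exp(-((i-xc)/Delta)^2)} convention.
#' @return Numeric vector of predicted R2 values at \code{positions},
#'   with attribute \code{baseline} (the first term alone).
#' @export
model_r2 <- function(A, lambda0, weights, components = NULL,
                     positions = NULL, weight_positions = NULL,
                     width_convention = c("sigma", "exp2")) {
  width_convention <- match.arg(width_convention)
  stopifnot(A >= 0, lambda0 > 0)
  if (is.null(weight_positions)) weight_positions <- seq_along(weights)
  if (is.null(positions)) positions <- weight_positions
  base <- A * as.vector(exp(-abs(outer(positions, weight_positions, "-")) /
                              lambda0) %*% weights)
  total <- base
  if (!is.null(components) && nrow(components) > 0) {
    stopifnot(all(components$R2c >= 0), all(components$Delta > 0))
    for (ci in seq_len(nrow(components))) {
      z <- positions - components$xc[ci]
      g <- if (width_convention == "sigma")
        exp(-z^2 / (2 * components$Delta[ci]^2))
      else
        exp(-(z / components$Delta[ci])^2)
      total <- total + components$R2c[ci] * g
    }
  }
  attr(total, "baseline") <- base
  total
}

# residual function used by the optimizer: parameter vector is
# (A, lambda0, R2c_1, xc_1, Delta_1, ..., R2c_K, xc_K, Delta_K)
cluster_par_unpack <- function(p, k) {
  comp <- if (k > 0)
    data.frame(R2c = p[2 + 3 * (seq_len(k) - 1) + 1],
               xc = p[2 + 3 * (seq_len(k) - 1) + 2],
               Delta = p[2 + 3 * (seq_len(k) - 1) + 3])
  else data.frame(R2c = numeric(), xc = numeric(), Delta = numeric())
  list(A = p[1], lambda0 = p[2], components = comp)
}

cluster_nls_fit <- function(obs, wres, model_at, start, lower, upper) {
  resid_fn <- function(p) (obs - model_at(p)) * wres
  fit <- try(minpack.lm::nls.lm(par = start, fn = resid_fn,
                                lower = lower, upper = upper,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200, ptol = 1e-10, ftol = 1e-10)),
             silent = TRUE)
  if (inherits(fit, "try-error") || fit$info %in% c(0, 5)) return(NULL)
  fit
}

#' Fit the cluster model to an R2 profile
#'
#' Weighted nonlinear least squares over the baseline parameters (A,
#' lambda0) and K Gaussian cluster components. Cluster centres are
#' multistarted at the local maxima of the residual left by a cluster-free
#' prefit (ties broken by lowest chi-square). Parameter uncertainties come
#' from a residue-level bootstrap: residues are resampled with replacement
#' and the model refitted.
#'
#' @param profile Data frame with columns \code{residue}, \code{value}
#'   (observed R2, 1/s) and optionally \code{sigma}; masked/NA residues
#'   are dropped.
#' @param seq The \code{peptide_sequence}.
#' @param k Number of cluster components (default 1; 0 fits the baseline
#'   alone).
#' @param variant Weight variant passed to \code{\link{residue_weights}}.
#' @param width_convention Gaussian width convention (see
#'   \code{\link{model_r2}}).
#' @param n_boot Bootstrap replicates for parameter uncertainties
#'   (default 100; 0 disables).
#' @param seed Optional seed (multistart is deterministic; the seed only
#'   affects the bootstrap).
#' @param lambda0_fixed Optionally fix the persistence length instead of
#'   optimizing it.
#' @return A \code{cluster_fit} list: \code{A}, \code{lambda0},
#'   \code{components} (data frame R2c/xc/Delta), \code{variant},
#'   \code{predicted}, \code{baseline}, \code{residuals}, \code{chisq},
#'   \code{aicc}, \code{boot_sigma} (named vector, when bootstrapped),
#'   \code{converged}.
#' @export
fit_cluster_model <- function(profile, seq, k = 1L,
                              variant = c("size_weighted", "uniform"),
                              width_convention = c("sigma", "exp2"),
                              n_boot = 100L, seed = NULL,
                              lambda0_fixed = NULL) {
  variant <- match.arg(variant)
  width_convention <- match.arg(width_convention)
  keep <- !is.na(profile$value)
  if ("mask" %in% names(profile)) keep <- keep & profile$mask
  obs <- profile$value[keep]
  positions_obs <- profile$residue[keep]
  if (length(obs) < 3L * k + 2L)
    stop(sprintf("need at least %d unmasked residues to fit %d cluster(s)",
                 3L * k + 2L, k))
  wres <- if ("sigma" %in% names(profile) &&
              all(is.finite(profile$sigma[keep])) &&
              all(profile$sigma[keep] > 0))
    1 / profile$sigma[keep] else rep(1, length(obs))

  all_pos <- residue_indices(seq)
  weights_all <- residue_weights(seq, variant)
  n <- length(seq)
  # weights at observed positions are irrelevant; the baseline always sums
  # over the full chain
  baseline_at <- function(A, lambda0, positions)
    A * as.vector(exp(-abs(outer(positions, all_pos, "-")) / lambda0) %*%
                    weights_all)
  model_at <- function(p, positions) {
    pp <- cluster_par_unpack(p, k)
    pred <- baseline_at(pp$A, pp$lambda0, positions)
    if (k > 0) for (ci in seq_len(k)) {
      z <- positions - pp$components$xc[ci]
      g <- if (width_convention == "sigma")
        exp(-z^2 / (2 * pp$components$Delta[ci]^2))
      else exp(-(z / pp$components$Delta[ci])^2)
      pred <- pred + pp$components$R2c[ci] * g
    }
    pred
  }

  lam_lo <- if (is.null(lambda0_fixed)) 0.1 else lambda0_fixed
  lam_hi <- if (is.null(lambda0_fixed)) 20 else lambda0_fixed
  fit_once <- function(obs, positions, wres, start_par = NULL) {
    model_here <- function(p) model_at(p, positions)
    if (!is.null(start_par)) {
      # warm start (bootstrap refits): single start from the full-data optimum
      lower <- c(0, lam_lo, rep(c(0, min(all_pos) - 2, 0.5), k))
      upper <- c(Inf, lam_hi, rep(c(Inf, max(all_pos) + 2, n), k))
      return(cluster_nls_fit(obs, wres, model_here, start = start_par,
                             lower = lower[seq_along(start_par)],
                             upper = upper[seq_along(start_par)]))
    }
    # cluster-free prefit for the baseline and the multistart residual
    pre_resid <- function(p) (obs - baseline_at(p[1], min(max(p[2], lam_lo),
                                                          lam_hi), positions)) * wres
    A0 <- max(mean(obs), 1e-3) / max(sum(weights_all) / n, 1)
    pre <- try(minpack.lm::nls.lm(par = c(A0, 2), fn = pre_resid,
                                  lower = c(0, lam_lo), upper = c(Inf, lam_hi)),
               silent = TRUE)
    pre_par <- if (inherits(pre, "try-error")) c(A0, 2) else pre$par
    if (k == 0L) {
      return(cluster_nls_fit(obs, wres, model_here, start = pre_par,
                             lower = c(0, lam_lo), upper = c(Inf, lam_hi)))
    }
    excess <- obs - baseline_at(pre_par[1], pre_par[2], positions)
    # candidate centres: local maxima of the excess (ends included)
    loc <- which(diff(sign(diff(c(-Inf, excess, -Inf)))) < 0)
    cand <- positions[loc[order(excess[loc], decreasing = TRUE)]]
    if (length(cand) == 0L) cand <- positions[which.max(excess)]
    cand <- utils::head(cand, 5L)
    lower <- c(0, lam_lo, rep(c(0, min(all_pos) - 2, 0.5), k))
    upper <- c(Inf, lam_hi, rep(c(Inf, max(all_pos) + 2, n), k))
    best <- NULL
    for (ctr in cand) {
      centres <- ctr + 3 * (seq_len(k) - 1)  # stack extra clusters nearby
      start <- c(pre_par, as.vector(rbind(pmax(max(excess), 0.1),
                                          pmin(centres, max(all_pos)),
                                          rep(2, k))))
      fit <- cluster_nls_fit(obs, wres, model_here, start = start,
                             lower = lower, upper = upper)
      if (!is.null(fit) &&
          (is.null(best) || fit$deviance < best$deviance)) best <- fit
    }
    best
  }

  best <- fit_once(obs, positions_obs, wres)
  if (is.null(best))
    return(structure(list(converged = FALSE, k = k, variant = variant),
                     class = "cluster_fit"))

  pp <- cluster_par_unpack(best$par, k)
  if (k > 0) {
    ord <- order(pp$components$xc)
    pp$components <- pp$components[ord, , drop = FALSE]
    rownames(pp$components) <- NULL
  }
  predicted <- model_at(best$par, all_pos)
  baseline <- baseline_at(pp$A, pp$lambda0, all_pos)
  resids <- obs - model_at(best$par, positions_obs)
  chisq <- sum((resids * wres)^2)
  npar <- 2 + 3 * k
  nobs <- length(obs)
  # small-sample corrected information criterion (Gaussian likelihood)
  aicc <- nobs * log(sum(resids^2) / nobs) + 2 * npar +
    if (nobs - npar - 1 > 0) 2 * npar * (npar + 1) / (nobs - npar - 1) else Inf

  boot_sigma <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
      set.seed(seed)
    }
    draws <- matrix(NA_real_, nrow = n_boot, ncol = npar)
    for (b in seq_len(n_boot)) {
      idx <- sort(sample.int(nobs, nobs, replace = TRUE))
      fb <- tryCatch(fit_once(obs[idx], positions_obs[idx], wres[idx],
                              start_par = best$par),
                     error = function(e) NULL)
      if (!is.null(fb)) draws[b, ] <- fb$par
    }
    boot_sigma <- apply(draws, 2, stats::sd, na.rm = TRUE)
    names(boot_sigma) <- c("A", "lambda0",
                           if (k > 0) as.vector(vapply(seq_len(k), function(ci)
                             paste0(c("R2c", "xc", "Delta"), ci), character(3))))
  }

  structure(list(A = pp$A, lambda0 = pp$lambda0, components = pp$components,
                 variant = variant, width_convention = width_convention,
                 residue = all_pos, predicted = predicted, baseline = baseline,
                 observed_residue = positions_obs, observed = obs,
                 residuals = resids, chisq = chisq, aicc = aicc, k = k,
                 boot_sigma = boot_sigma, converged = TRUE),
            class = "cluster_fit")
}

#' @export
print.cluster_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("cluster_fit: did not converge\n"); return(invisible(x))
  }
  cat(sprintf("cluster_fit (%s, K = %d): A = %.4g 1/s, lambda0 = %.3g residues\n",
              x$variant, x$k, x$A, x$lambda0))
  if (x$k > 0) {
    for (ci in seq_len(nrow(x$components)))
      cat(sprintf("  cluster %d: R2c = %.3g 1/s at residue %.2f, half-width %.2f\n",
                  ci, x$components$R2c[ci], x$components$xc[ci],
                  x$components$Delta[ci]))
  }
  cat(sprintf("  chi-square = %.4g, AICc = %.4g\n", x$chisq, x$aicc))
  invisible(x)
}

#' Compare the size-weighted and uniform baseline variants
#'
#' Fits the cluster model under both residue-weighting schemes and reports
#' the cluster parameters and information criteria side by side.
#'
#' @inheritParams fit_cluster_model
#' @return A \code{variant_comparison} list with the two \code{cluster_fit}
#'   objects (\code{size_weighted}, \code{uniform}) and a \code{summary}
#'   data frame.
#' @export
compare_variants <- function(profile, seq, k = 1L, n_boot = 0L, seed = NULL) {
  fits <- list(
    size_weighted = fit_cluster_model(profile, seq, k = k,
                                      variant = "size_weighted",
                                      n_boot = n_boot, seed = seed),
    uniform = fit_cluster_model(profile, seq, k = k, variant = "uniform",
                                n_boot = n_boot, seed = seed))
  summ <- do.call(rbind, lapply(names(fits), function(v) {
    f <- fits[[v]]
    if (!isTRUE(f$converged))
      return(data.frame(variant = v, A = NA, lambda0 = NA, xc = NA,
                        Delta = NA, R2c = NA, chisq = NA, aicc = NA))
    data.frame(variant = v, A = f$A, lambda0 = f$lambda0,
               xc = if (k > 0) f$components$xc[1] else NA_real_,
               Delta = if (k > 0) f$components$Delta[1] else NA_real_,
               R2c = if (k > 0) f$components$R2c[1] else NA_real_,
               chisq = f$chisq, aicc = f$aicc)
  }))
  structure(list(size_weighted = fits$size_weighted,
                 uniform = fits$uniform, summary = summ),
            class = "variant_comparison")
}

#' Select the number of clusters by information criterion
#'
#' Fits K = 0..k_max and returns the fit minimizing the small-sample
#' corrected information criterion.
#'
#' @inheritParams fit_cluster_model
#' @param k_max Largest number of components to consider (default 2).
#' @return List with \code{best} (a \code{cluster_fit}), \code{k} and
#'   \code{aicc} (vector over K).
#' @export
select_n_clusters <- function(profile, seq, k_max = 2L,
                              variant = "size_weighted", seed = NULL) {
  ks <- 0:k_max
  fits <- lapply(ks, function(kk)
    tryCatch(fit_cluster_model(profile, seq, k = kk, variant = variant,
                               n_boot = 0L, seed = seed),
             error = function(e) NULL))
  aicc <- vapply(fits, function(f)
    if (!is.null(f) && isTRUE(f$converged)) f$aicc else Inf, numeric(1))
  best <- which.min(aicc)
  list(best = fits[[best]], k = ks[best],
       aicc = stats::setNames(aicc, paste0("K", ks)))
}
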