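# Shared fixtures: the 20-residue Trp-cage mini-protein sequence and the
# 60.25 MHz 15N field context used throughout.

tc5b <- load_sequence("NLYIQWLKDGGPSSGRPPPS")

field_ctx <- spectrometer_context(nitrogen_mhz = 60.25, proton_mhz = 599.92)
nh_constants <- interaction_constants(field_ctx, rnh = 1.02, csa = 172)

extdata <- function(name) {
  system.file("extdata", name, package = "denatr", mustWork = TRUE)
}

# brute-force double-loop evaluation of the cluster model, kept deliberately
# independent of model_r2's vectorized implementation
brute_force_model_r2 <- function(A, lambda0, weights, components, positions) {
  n <- length(weights)
  out <- numeric(length(positions))
  for (ii in seq_along(positions)) {
    i <- positions[ii]
    acc <- 0
    for (j in seq_len(n)) {
      acc <- acc + weights[j] * exp(-abs(i - j) / lambda0)
    }
    acc <- A * acc
    if (!is.null(components) && nrow(components) > 0) {
      for (ci in seq_len(nrow(components))) {
        acc <- acc + components$R2c[ci] *
          exp(-(i - components$xc[ci])^2 / (2 * components$Delta[ci]^2))
      }
    }
    out[ii] <- acc
  }
  out
}
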