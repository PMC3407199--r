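coil_base_only <- default_coil_table(with_corrections = FALSE)

test_that("reference shifts equal base values without corrections", {
  ref <- corrected_random_coil(tc5b, coil_base_only)
  # spot check against the packaged table
  tab <- utils::read.table(
    extdata("random_coil_consensus.tsv"), header = TRUE, sep = "\t",
    comment.char = "#", na.strings = ".")
  w_ca <- tab$shift_ppm[tab$type == "W" & tab$nucleus == "CA"]
  expect_equal(ref$shift[ref$residue == 6 & ref$nucleus == "CA"], w_ca)
  # glycine CB rows are absent rather than zero-filled
  expect_false(any(ref$residue %in% c(10, 11, 15) & ref$nucleus == "CB"))
  # single-residue chain: no neighbours, reference = base even with corrections
  one <- load_sequence("W")
  ref1 <- corrected_random_coil(one, default_coil_table())
  expect_equal(ref1$shift[ref1$nucleus == "CA"], w_ca)
})

test_that("neighbour corrections add up as hand-computed sums", {
  base <- withr::local_tempfile(fileext = ".tsv")
  corr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("type\tnucleus\tshift_ppm",
               "G\tCA\t45.0", "W\tCA\t57.0", "S\tCA\t58.0"), base)
  writeLines(c("neighbor_type\toffset\tnucleus\tdelta_ppm",
               "G\t-1\tCA\t0.5", "G\t1\tCA\t-0.3", "W\t2\tCA\t0.1",
               "S\t-2\tCA\t0.2"), corr)
  tab <- read_coil_table(base, corr)
  seq <- load_sequence("GWSGW")
  ref <- corrected_random_coil(seq, tab, nuclei = "CA")
  # hand-computed sums; listed corrections are (G,-1:+0.5), (G,+1:-0.3),
  # (W,+2:+0.1), (S,-2:+0.2)
  expect_equal(ref$shift[ref$residue == 1], 45.0)          # G1: no listed hits
  expect_equal(ref$shift[ref$residue == 2], 57.0 + 0.5)    # W2: G at -1
  expect_equal(ref$shift[ref$residue == 3],
               58.0 - 0.3 + 0.1)                           # S3: G at +1, W at +2
  expect_equal(ref$shift[ref$residue == 4], 45.0)          # G4: no listed hits
  expect_equal(ref$shift[ref$residue == 5],
               57.0 + 0.5 + 0.2)                           # W5: G at -1, S at -2
})

test_that("secondary shifts are differences with exclusion and antisymmetry", {
  ref <- corrected_random_coil(tc5b, coil_base_only)
  obs <- data.frame(residue = ref$residue, nucleus = ref$nucleus,
                    shift = ref$shift)
  ss <- secondary_shifts(obs, ref, tc5b)
  expect_true(all(ss$ddelta == 0))
  # Asp 9 is excluded whenever pH-sensitive exclusion is on, whatever ddelta
  expect_true(all(ss$excluded[ss$residue == 9]))
  expect_false(any(ss$excluded[ss$residue == 6]))
  # a localized +0.5 ppm CA perturbation shows up exactly where injected
  obs2 <- obs
  bump <- obs2$nucleus == "CA" & obs2$residue %in% 4:7
  obs2$shift[bump] <- obs2$shift[bump] + 0.5
  ss2 <- secondary_shifts(obs2, ref, tc5b)
  expect_equal(ss2$ddelta[bump], rep(0.5, sum(bump)))
  expect_true(all(ss2$ddelta[!bump] == 0))
  # antisymmetry under swapping observed and reference
  ss_swap <- secondary_shifts(
    data.frame(residue = ref$residue, nucleus = ref$nucleus, shift = ref$shift),
    data.frame(residue = obs2$residue, nucleus = obs2$nucleus,
               shift = obs2$shift),
    tc5b)
  expect_equal(ss_swap$ddelta, -ss2$ddelta)
})

test_that("consensus CSI: zero deviations give all-coil, helix blocks are called", {
  ref <- corrected_random_coil(tc5b, coil_base_only)
  obs <- data.frame(residue = ref$residue, nucleus = ref$nucleus,
                    shift = ref$shift)
  ss <- secondary_shifts(obs, ref, tc5b, exclude_ph_sensitive = FALSE)
  csi <- consensus_csi(ss)
  expect_true(all(csi$consensus$call == "coil"))
  # synthetic helix block over residues 3-9: CA +0.8, C +0.8, CB -0.8
  obs2 <- obs
  for (nuc in c("CA", "C")) {
    sel <- obs2$nucleus == nuc & obs2$residue %in% 3:9
    obs2$shift[sel] <- obs2$shift[sel] + 0.8
  }
  sel <- obs2$nucleus == "CB" & obs2$residue %in% 3:9
  obs2$shift[sel] <- obs2$shift[sel] - 0.8
  csi2 <- consensus_csi(secondary_shifts(obs2, ref, tc5b,
                                         exclude_ph_sensitive = FALSE))
  expect_true(all(csi2$consensus$call[csi2$consensus$residue %in% 3:9] == "helix"))
  expect_true(all(csi2$consensus$call[!csi2$consensus$residue %in% 3:9] == "coil"))
  # an isolated single-residue exceedance is reset to coil by the run rule
  obs3 <- obs
  for (nuc in c("CA", "C")) {
    sel <- obs3$nucleus == nuc & obs3$residue == 6
    obs3$shift[sel] <- obs3$shift[sel] + 2
  }
  csi3 <- consensus_csi(secondary_shifts(obs3, ref, tc5b,
                                         exclude_ph_sensitive = FALSE))
  expect_true(all(csi3$consensus$call == "coil"))
  # invariance under a uniform referencing offset on both shift sets
  obs4 <- obs2; obs4$shift <- obs4$shift + 0.11
  ref4 <- ref; ref4$shift <- ref4$shift + 0.11
  csi4 <- consensus_csi(secondary_shifts(obs4, ref4, tc5b,
                                         exclude_ph_sensitive = FALSE))
  expect_equal(csi4$consensus, csi2$consensus)
})

test_that("deviant flags honor exclusion, thresholds and monotonicity", {
  ref <- corrected_random_coil(tc5b, coil_base_only)
  obs <- data.frame(residue = ref$residue, nucleus = ref$nucleus,
                    shift = ref$shift)
  # CA exceedances at exactly residues 4, 7, 12, 18
  hit <- obs$nucleus == "CA" & obs$residue %in% c(4, 7, 12, 18)
  obs$shift[hit] <- obs$shift[hit] + 0.45
  ss <- flag_deviant(secondary_shifts(obs, ref, tc5b))
  expect_identical(sort(ss$residue[ss$deviant]), c(4L, 7L, 12L, 18L))
  expect_true(all(ss$nucleus[ss$deviant] == "CA"))
  # a threshold above the largest deviation flags nothing
  expect_false(any(flag_deviant(secondary_shifts(obs, ref, tc5b), 1)$deviant))
  # monotone: raising the threshold never adds flags
  lo <- flag_deviant(secondary_shifts(obs, ref, tc5b), 0.2)$deviant
  hi <- flag_deviant(secondary_shifts(obs, ref, tc5b), 0.4)$deviant
  expect_true(all(which(hi) %in% which(lo)))
  # an excluded residue is never flagged however large its deviation
  obs2 <- obs
  d9 <- obs2$nucleus == "CA" & obs2$residue == 9
  obs2$shift[d9] <- obs2$shift[d9] + 10
  ss2 <- flag_deviant(secondary_shifts(obs2, ref, tc5b))
  expect_false(any(ss2$deviant[ss2$residue == 9]))
  expect_error(flag_deviant(ss, threshold = 0), "> 0")
})

test_that("Karplus inversion finds every angle consistent with the coupling", {
  A <- 6.51; B <- -1.76; C <- 1.60
  # J at phi = 60 is A + B + C
  expect_true(any(abs(karplus_phi(A + B + C) - 60) < 1e-8))
  # couplings above the curve maximum have no solution
  expect_length(karplus_phi(20), 0)
  # every solution satisfies the Karplus relation to well under 0.01 Hz
  set.seed(31)
  for (rep in 1:200) {
    phi <- runif(1, -180, 180)
    j <- karplus_j(phi)
    sols <- karplus_phi(max(j, 0))
    expect_true(min(abs(((sols - phi + 180) %% 360) - 180)) < 0.1)
    expect_true(all(abs(karplus_j(sols) - j) < 0.01))
  }
})
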