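test_that("single contacts classify by atom class and separation", {
  expect_identical(classify_contact(4, "HA", 6, "HN"), "daN(i,i+2)")
  expect_identical(classify_contact(5, "HN", 6, "HN"), "dNN(i,i+1)")
  expect_identical(classify_contact(4, "HA", 4, "HN"), "intra")
  expect_identical(classify_contact(4, "HG2", 6, "HN"), "dscN(i,i+2)")
  expect_identical(classify_contact(4, "HA", 7, "HN"), "daN(i,i+3)")
  expect_identical(classify_contact(6, "HD1", 16, "HG"), "sc-sc(|d|>=5)")
  expect_identical(classify_contact(6, "HB2", 7, "HB"), "sc-sc(|d|=1)")
  expect_identical(classify_contact(4, "HD1", 7, "HB"), "sc-sc(2<=|d|<=4)")
  expect_error(classify_contact(4, "CA", 6, "HN"), "unknown atom")
  # classification is symmetric after canonical ordering
  expect_identical(classify_contact(6, "HN", 4, "HA"),
                   classify_contact(4, "HA", 6, "HN"))
  expect_identical(classify_contact(16, "HG", 6, "HD1"),
                   classify_contact(6, "HD1", 16, "HG"))
})

test_that("the transcribed main-chain contact table reproduces the published counts", {
  contacts <- read_contact_table(extdata("tc5b_main_chain_contacts.tsv"))
  cm <- connectivity_map(contacts, seq = tc5b)
  expect_identical(unname(cm$counts["daN(i,i+3)"]), 2L)
  expect_identical(unname(cm$counts["dNN(i,i+2)"]), 0L)
  expect_true("dNN(i,i+2)" %in% cm$absent)
  expect_identical(unname(cm$counts["dNN(i,i+1)"]), 9L)
  expect_identical(unname(cm$counts["daN(i,i+2)"]), 3L)
  expect_identical(unname(cm$counts["dscN(i,i+2)"]), 6L)
  # the two medium-range daN contacts start at residues 4 and 5
  expect_identical(which(cm$matrix[, "daN(i,i+3)"]), c("4" = 4L, "5" = 5L))
})

test_that("connectivity maps are order-invariant and collapse duplicates", {
  contacts <- read_contact_table(extdata("tc5b_main_chain_contacts.tsv"))
  shuffled <- contacts[rev(seq_len(nrow(contacts))), , drop = FALSE]
  expect_identical(connectivity_map(shuffled, tc5b)$counts,
                   connectivity_map(contacts, tc5b)$counts)
  doubled <- rbind(contacts, contacts)
  cm2 <- connectivity_map(doubled, tc5b)
  expect_identical(cm2$counts, connectivity_map(contacts, tc5b)$counts)
  expect_true(all(cm2$contacts$multiplicity == 2))
  # reversed partner order canonicalizes to the same map
  swapped <- data.frame(res_i = contacts$res_j, atom_i = contacts$atom_j,
                        res_j = contacts$res_i, atom_j = contacts$atom_i,
                        peak_id = contacts$peak_id)
  expect_identical(connectivity_map(swapped, tc5b)$counts,
                   connectivity_map(contacts, tc5b)$counts)
})

test_that("an empty contact list gives an all-zero map", {
  empty <- read_contact_table(extdata("tc5b_main_chain_contacts.tsv"))[0, ]
  cm <- connectivity_map(empty, tc5b)
  expect_true(all(cm$counts == 0L))
  expect_false(any(cm$matrix))
})

test_that("the side-chain table around the central tryptophan matches the transcription", {
  contacts <- read_contact_table(extdata("tc5b_trp6_sidechain_contacts.tsv"))
  sm <- sidechain_contact_table(contacts, focus = 6)
  expect_identical(sm$partners, c(4L, 5L, 7L, 12L, 16L, 18L, 19L))
  # the Pro 12 HD2 partner sits under the Trp zeta protons
  zeta <- sm$cells$focus_atom %in% c("HZ2", "HZ3")
  expect_true(any(sm$cells$partner_residue[zeta] == 12 &
                    sm$cells$partner_atom[zeta] == "HD2"))
  expect_match(sm$table["HZ2", "12"], "HD2")
  # a residue with no contacts yields an empty table
  sm0 <- sidechain_contact_table(contacts, focus = 10)
  expect_length(sm0$partners, 0)
  expect_equal(nrow(sm0$cells), 0)
})

test_that("AABUF profiles are windowed, normalized and idempotent", {
  prof <- aabuf_profile(tc5b, window = 5)
  expect_equal(min(prof$normalized), 0)
  expect_equal(max(prof$normalized), 1)
  # the hydrophobic N-terminal region outscores the polar/proline tail
  expect_gt(mean(prof$windowed[prof$residue %in% 4:8]),
            mean(prof$windowed[prof$residue %in% 13:20]))
  # window 1 on a two-letter sequence gives exactly {0, 1}
  two <- aabuf_profile(load_sequence("WGWGW"), window = 1)
  expect_setequal(two$normalized, c(0, 1))
  # normalization is idempotent: renormalizing normalized values is a no-op
  renorm <- (prof$normalized - min(prof$normalized)) /
    diff(range(prof$normalized))
  expect_equal(renorm, prof$normalized)
  # constant profiles cannot be normalized and are flagged
  flat <- aabuf_profile(load_sequence("AAAAA"), window = 3)
  expect_true(attr(flat, "constant"))
  expect_true(all(is.na(flat$normalized)))
  expect_true(all(flat$raw == flat$raw[1]))
  expect_error(aabuf_profile(tc5b, window = 4), "odd")
  expect_error(aabuf_profile(load_sequence("AG"), window = 5), "longer")
})
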