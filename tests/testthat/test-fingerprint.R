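test_that("packaged profiles carry the literature-named residues and documented sizes", {
  profs <- build_default_profiles()
  gb <- profs$GbpA
  expect_equal(nrow(gb), 18L)
  expect_equal(sum(gb$lobe == "C"), 13L)
  named <- setNames(gb$ref_residue, gb$ref_position)
  expect_identical(named[c("33", "138", "380", "430", "432", "521")],
                   c("33" = "R", "138" = "Y", "380" = "A", "430" = "S",
                     "432" = "D", "521" = "Y"))
  expect_true(all(gb$salt_bridge[gb$ref_position %in% c(33, 432)]))
  dp <- profs$DppA
  expect_equal(nrow(dp), 10L)
  expect_identical(dp$ref_residue[dp$ref_position == 408], "D")
  expect_error(build_default_profiles("/nonexistent/profiles.csv"),
               "not found")
})

test_that("signature profiles enforce their invariants", {
  expect_error(signature_profile("f", c(3, 3), c("A", "A")), "duplicate")
  expect_error(signature_profile("f", c(5, 3), c("A", "A")), "ascending")
  expect_error(signature_profile("f", 3, "A", conserved_set = "GV"),
               "conserved_set")
  p <- signature_profile("f", c(3, 7), c("R", "D"), lobe = c("N", "C"))
  expect_identical(p$conserved_set, c("R", "D"))
})

test_that("contact extraction respects the distance cutoff", {
  atoms <- data.frame(
    type = c("ATOM", "ATOM", "HETATM"),
    resno = c(10L, 20L, 1L),
    resid = c("ARG", "ASP", "LIG"),
    elety = c("CA", "CA", "C1"),
    element = "C",
    x = c(3, 6, 0), y = 0, z = 0)
  m <- structure_model(atoms)
  prof <- extract_contacts(m, "LIG", cutoff = 4)
  expect_equal(prof$ref_position, 10L)
  expect_identical(prof$ref_residue, "R")
  expect_warning(empty <- extract_contacts(m, "LIG", cutoff = 0.1),
                 "no residues")
  expect_equal(nrow(empty), 0L)
  expect_error(extract_contacts(m, "GSS", cutoff = 4), "not found")
})

test_that("contact extraction on a synthetic reference complex reproduces its profile", {
  rc <- simulate_reference_complex(seed = 42)
  truth <- build_default_profiles()$GbpA
  prof <- extract_contacts(rc$model, rc$ligand_id, 4.0, rc$domains)
  expect_equal(prof$ref_position, truth$ref_position)
  expect_identical(prof$ref_residue, truth$ref_residue)
  expect_identical(prof$lobe, truth$lobe)
  expect_equal(sum(prof$lobe == "C"), 13L)
})

test_that("profile positions map through gapped reference rows", {
  prof <- signature_profile("toy", c(2, 4), c("C", "E"))
  aln <- as_alignment(c(ref = "ACDEF", other = "ACDEF"))
  expect_equal(map_profile_to_alignment(prof, aln, "ref"), c(2L, 4L))
  # two gaps before the mapped residues shift the columns by two
  aln2 <- as_alignment(c(ref = "--ACDEF", other = "GGACDEF"))
  expect_equal(map_profile_to_alignment(prof, aln2, "ref"), c(4L, 6L))
  # mismatching reference residue is a hard error naming the position
  bad <- signature_profile("toy", 2, "R")
  expect_error(map_profile_to_alignment(bad, aln, "ref"), "position.*2")
  expect_error(map_profile_to_alignment(prof, aln, "nope"), "not in alignment")
  far <- signature_profile("toy", 99, "A")
  expect_error(map_profile_to_alignment(far, aln, "ref"), "beyond")
})

test_that("mapping is stable under gap-column insertion", {
  sigs <- default_family_signatures()
  ref <- signature_scaffold(sigs$GbpA)
  aln <- as_alignment(c(ref = ref))
  prof <- build_default_profiles()$GbpA
  cols <- map_profile_to_alignment(prof, aln, "ref")
  m <- unclass(aln)
  # splice gap columns at the front, middle and end
  m2 <- cbind(matrix("-", 1, 3), m[, 1:200, drop = FALSE],
              matrix("-", 1, 5), m[, 201:540, drop = FALSE],
              matrix("-", 1, 2))
  rownames(m2) <- "ref"
  cols2 <- map_profile_to_alignment(prof, as_alignment(m2), "ref")
  expect_identical(unname(m[1, cols]), unname(m2[1, cols2]))
})

test_that("strict clade conservation counts drop one per deviant member", {
  sigs <- default_family_signatures()
  prof <- build_default_profiles()$GbpA
  gbpa_seq <- signature_scaffold(sigs$GbpA)
  hbpa_seq <- signature_scaffold(sigs$HbpA2)
  rows <- c(GbpA_1 = gbpa_seq, GbpA_2 = gbpa_seq,
            HbpA2_1 = hbpa_seq, HbpA2_2 = hbpa_seq)
  aln <- as_alignment(rows)
  labels <- c(GbpA_1 = "GbpA", GbpA_2 = "GbpA",
              HbpA2_1 = "HbpA2", HbpA2_2 = "HbpA2")
  sc <- score_clade_conservation(prof, aln, "GbpA_1", labels)
  expect_equal(sc$conserved[sc$clade == "GbpA"], 18L)
  # HbpA2 carries the three C-lobe substitutions (A380P, S430T, D432R)
  scC <- score_clade_conservation(prof, aln, "GbpA_1", labels, lobe = "C")
  expect_equal(scC$total[1], 13L)
  expect_equal(scC$conserved[scC$clade == "HbpA2"], 10L)
  # one deviant member at one position lowers the strict count by exactly 1
  m <- unclass(aln)
  col <- map_profile_to_alignment(prof, aln, "GbpA_1")[6]  # position 138
  m["GbpA_2", col] <- "W"
  sc2 <- score_clade_conservation(prof, as_alignment(m), "GbpA_1", labels)
  expect_equal(sc2$conserved[sc2$clade == "GbpA"], 17L)
  expect_error(score_clade_conservation(prof, aln, "GbpA_1",
                                        c(GbpA_1 = "GbpA", gone = "X")),
               "empty clade")
})

test_that("classification calls families and vetoes salt-bridge-broken sequences", {
  sigs <- default_family_signatures()
  profs <- build_default_profiles()
  gbpa_seq <- signature_scaffold(sigs$GbpA)
  dppa_seq <- signature_scaffold(sigs$DppA, fill = "G")
  broken <- strsplit(gbpa_seq, "")[[1]]
  broken[33] <- "T"; broken[432] <- "R"
  rows <- c(GbpA_ref = gbpa_seq, DppA_ref = dppa_seq,
            broken = paste0(broken, collapse = ""))
  aln <- as_alignment(rows)
  cls <- classify_sequences(aln, profs,
                            ref_ids = c(GbpA = "GbpA_ref", DppA = "DppA_ref"))
  expect_identical(cls$family_call[cls$seq_id == "GbpA_ref"], "GbpA")
  expect_equal(cls$match_GbpA[cls$seq_id == "GbpA_ref"], 1.0)
  expect_identical(cls$family_call[cls$seq_id == "DppA_ref"], "DppA")
  # T33/R432 scaffold: high match but vetoed into unknown with two flags
  expect_identical(cls$family_call[cls$seq_id == "broken"],
                   "HbpA2-like/unknown")
  fl <- attr(cls, "flags")
  fb <- fl[fl$seq_id == "broken" & fl$family == "GbpA", ]
  expect_setequal(fb$ref_position, c(33L, 432L))
  expect_true(all(fb$reason == "salt-bridge disruption"))
})

test_that("an arginine at the DppA salt-bridge position flags dipeptide incompatibility", {
  sigs <- default_family_signatures()
  profs <- build_default_profiles()
  dppa_seq <- signature_scaffold(sigs$DppA, fill = "G")
  bad <- strsplit(dppa_seq, "")[[1]]
  bad[408] <- "R"
  rows <- c(DppA_ref = dppa_seq, GbpA_ref = signature_scaffold(sigs$GbpA),
            mutant = paste0(bad, collapse = ""))
  cls <- classify_sequences(as_alignment(rows), profs,
                            ref_ids = c(GbpA = "GbpA_ref", DppA = "DppA_ref"))
  fl <- attr(cls, "flags")
  hit <- fl[fl$seq_id == "mutant" & fl$family == "DppA", ]
  expect_equal(hit$ref_position, 408L)
  expect_identical(hit$observed, "R")
})

test_that("synthetic three-clade families are classified with perfect label accuracy", {
  fam <- simulate_family_sequences(n_per_clade = 3, divergence = 0.05,
                                   inter_clade_divergence = 0.3, seed = 21)
  aln <- progressive_msa(fam)
  cls <- classify_sequences(aln, build_default_profiles(),
                            ref_ids = c(GbpA = "GbpA_1", DppA = "DppA_1"))
  truth <- attr(fam, "clades")
  expected <- ifelse(truth == "HbpA2", "HbpA2-like/unknown", truth)
  expect_identical(setNames(cls$family_call, cls$seq_id)[names(truth)],
                   setNames(expected, names(truth)))
  # conservation can only fall as deviant members join a clade
  prof <- build_default_profiles()$GbpA
  labels1 <- truth[truth == "GbpA"]
  s1 <- score_clade_conservation(prof, aln, "GbpA_1", labels1)
  labels2 <- c(labels1, setNames("GbpA", names(truth)[truth == "HbpA2"][1]))
  s2 <- score_clade_conservation(prof, aln, "GbpA_1", labels2)
  expect_lte(s2$conserved[s2$clade == "GbpA"],
             s1$conserved[s1$clade == "GbpA"])
})
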