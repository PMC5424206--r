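test_that("reference mapping numbers non-gap columns consecutively", {
  msa <- msa_from_alignment(c(r = "ACD", m = "AYD"))
  rmap <- map_reference(msa, "r")
  expect_equal(rmap$pos_to_col, 1:3)
  msa2 <- msa_from_alignment(c(r = "A-CD", m = "AYCD"))
  rmap2 <- map_reference(msa2, "r")
  expect_equal(rmap2$pos_to_col, c(1L, 3L, 4L))
  expect_error(map_reference(msa, "absent"), "not in alignment")
})

test_that("the reference evaluates as its own fixed point", {
  msa <- ref_msa_fixture()
  fr <- evaluate_features(map_reference(msa, "ref"), sepcyss_rule_set())
  r <- fr[fr$id == "ref", ]
  expect_equal(r$indel_234_235, 0L)
  expect_equal(r$loop_144_147, "present")
  expect_equal(r$persulfide_cys_count, 3L)
  expect_true(r$plp_conserved)
})

test_that("feature worked examples are exact", {
  msa <- ref_msa_fixture()
  fr <- evaluate_features(map_reference(msa, "ref"), sepcyss_rule_set())
  expect_equal(fr$indel_234_235[fr$id == "del8"], -8L)
  expect_equal(fr$loop_144_147[fr$id == "noloop"], "absent")
  expect_equal(fr$persulfide_cys_count[fr$id == "nocys"], 0L)
  expect_equal(fr$persulfide_cys_count[fr$id == "del8"], 3L)
  ## an 8-residue insertion between 234 and 235
  ref <- fx_models()$SepCysS$root
  n <- nchar(ref)
  ins_member <- paste0(substr(ref, 1, 234), "WWWWWWWW", substr(ref, 235, n))
  ref_row <- paste0(substr(ref, 1, 234), strrep("-", 8), substr(ref, 235, n))
  fr2 <- evaluate_features(
    map_reference(msa_from_alignment(c(ref = ref_row, ins = ins_member)), "ref"),
    sepcyss_rule_set())
  expect_equal(fr2$indel_234_235[fr2$id == "ins"], 8L)
})

test_that("residue-444 classification distinguishes Ile from hydrophilic Asp", {
  ref <- fx_models()$SepRS$root
  asp <- ref; substr(asp, 444, 444) <- "D"
  gap <- paste0(substr(ref, 1, 443), "-", substr(ref, 445, nchar(ref)))
  fr <- evaluate_features(
    map_reference(msa_from_alignment(c(ref = ref, asp = asp, del = gap)), "ref"),
    seprs_rule_set())
  expect_equal(fr$res444_class[fr$id == "ref"], "hydrophobic")  # planted Ile
  expect_equal(fr$res444_class[fr$id == "asp"], "hydrophilic")
  expect_equal(fr$res444_class[fr$id == "del"], "deleted")
})

test_that("indel measurement ignores all-gap columns elsewhere in the MSA", {
  msa <- ref_msa_fixture()
  padded <- vapply(msa$aln, function(s)
    paste0(substr(s, 1, 50), "-----", substr(s, 51, nchar(s))), "")
  fr0 <- evaluate_features(map_reference(msa, "ref"), sepcyss_rule_set())
  fr1 <- evaluate_features(
    map_reference(msa_from_alignment(padded), "ref"), sepcyss_rule_set())
  expect_equal(fr1$indel_234_235, fr0$indel_234_235)
})

test_that("rule positions outside the reference are rejected", {
  msa <- msa_from_alignment(c(r = "ACDEF", m = "ACDEF"))
  rules <- list(pos444 = 444L)
  expect_error(evaluate_features(map_reference(msa, "r"), rules),
               "outside reference")
})

test_that("SepRS truncation calls recover planted delta-C variants", {
  models <- fx_models()
  mg <- fx_metagenome()
  prots <- fx_proteins()
  dm <- seprs_domain_model(models$SepRS$root)
  truth <- mg$truth$features
  seprs <- truth[truth$family == "SepRS", ]
  calls <- vapply(seprs$protein_id, function(pid)
    detect_seprs_truncation(prots[[pid]], dm), "")
  expect_equal(unname(calls), seprs$seprs_truncation)
  expect_warning(detect_seprs_truncation(rand_protein(200), dm), "no call")
})

test_that("SepCysE homolog classification separates full, split and fused forms", {
  models <- fx_models()
  ndom <- models$aux$SepCysE_N
  core <- models$SepCysS$root
  set.seed(41)
  full <- paste0(evolve_sequence(ndom, 0.15),
                 evolve_sequence(models$aux$SepCysE_C, 0.15))
  fused <- paste0(evolve_sequence(ndom, 0.15), evolve_sequence(core, 0.15))
  split <- evolve_sequence(ndom, 0.15)
  expect_equal(classify_sepcysE_homolog(full, ndom, core), "full")
  expect_equal(classify_sepcysE_homolog(fused, ndom, core), "fused_N")
  expect_equal(classify_sepcysE_homolog(split, ndom, core,
                                        precedes_sepcyss = TRUE), "split_n")
  expect_equal(classify_sepcysE_homolog(split, ndom, core,
                                        precedes_sepcyss = FALSE), "none")
  expect_equal(classify_sepcysE_homolog(rand_protein(250), ndom, core), "none")
})

test_that("tRNA typing reads the N37 base with no-calls on bad annotation", {
  t_a <- make_trna_fixture("A"); t_g <- make_trna_fixture("G")
  expect_equal(classify_trna(t_a, list(anticodon_start = 34))$n37, "A")
  cl <- classify_trna(t_g, list(anticodon_start = 34))
  expect_equal(cl$n37, "G")
  expect_equal(cl$isotype, "Cys")
  expect_warning(cl2 <- classify_trna(t_a, list(anticodon_start = NA)),
                 "missing")
  expect_false(cl2$ok)
  expect_warning(cl3 <- classify_trna("ACGTGCA", list(anticodon_start = 5)),
                 "end")
  expect_false(cl3$ok)
})
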