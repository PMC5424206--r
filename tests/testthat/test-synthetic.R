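test_that("sequence evolution at distance zero is the identity", {
  s <- rand_protein(100)
  expect_identical(evolve_sequence(s, 0), s)
})

test_that("realized identity matches the 20-state closed form", {
  ## expected identity after distance d: 1/20 + (19/20) exp(-(20/19) d)
  set.seed(5)
  s <- rand_protein(2000)
  for (d in c(0.3, 1.0)) {
    x <- evolve_sequence(s, d)
    obs <- mean(strsplit(s, "")[[1]] == strsplit(x, "")[[1]])
    expected <- 1 / 20 + (19 / 20) * exp(-(20 / 19) * d)
    se <- sqrt(expected * (1 - expected) / 2000)
    expect_lt(abs(obs - expected), 3 * se)
  }
})

test_that("planned indels and feature residues are applied exactly", {
  set.seed(8)
  s <- rand_protein(300)
  del <- evolve_sequence(s, 0.1,
                         indel_plan = list(list(type = "delete", at = 227, len = 8)))
  expect_equal(nchar(del), 292L)
  ins <- evolve_sequence(s, 0.1,
                         indel_plan = list(list(type = "insert", after = 234, len = 8)))
  expect_equal(nchar(ins), 308L)
  asp <- evolve_sequence(s, 0.5,
                         feature_plan = list(list(pos = 44, residue = "D")))
  expect_equal(substr(asp, 44, 44), "D")
  ## feature positions shift through the indel plan
  both <- evolve_sequence(s, 0.2,
                          indel_plan = list(list(type = "insert", after = 10, len = 5)),
                          feature_plan = list(list(pos = 44, residue = "W")))
  expect_equal(substr(both, 49, 49), "W")
  expect_error(evolve_sequence(s, 0.1,
               indel_plan = list(list(type = "delete", at = 299, len = 8))),
               "outside")
})

test_that("family model validates its divergence configuration", {
  expect_error(family_model("F", 100, c(3, 3), d_within = 0.5, d_between = 0.3),
               "within-clade")
  expect_error(family_model("F", 100, c(3, 3), d_within = 0, d_between = 0.3))
})

test_that("the SepRS preset plants 3 major clades plus 2 singleton orphans", {
  fam <- fx_models()$SepRS
  tab <- table(fam$members$clade[fam$members$role == "member"])
  expect_length(tab, 3L)
  expect_true(all(tab >= 3L))
  expect_equal(sum(fam$members$role == "orphan"), 2L)
  cys <- fx_models()$SepCysS
  expect_length(unique(cys$members$clade), 7L)
})

test_that("planted within-clade similarity exceeds between-clade by >= 15 points", {
  v <- fx_two_clades()
  fs <- realize_family(family_model("F", 150, c(4, 4), 0.06, 0.7), 11L)
  cl <- fs$members$clade
  S <- similarity_matrix(v)
  same <- outer(cl, cl, "==") & upper.tri(S)
  diff <- outer(cl, cl, "!=") & upper.tri(S)
  expect_gte(mean(S[same]) - mean(S[diff]), 15)
})

test_that("metagenome generation is byte-identical under a fixed seed", {
  presets <- genome_presets_paper_default()[c(2, 5)]
  m1 <- generate_metagenome(presets, fx_models(), seed = 99)
  m2 <- generate_metagenome(presets, fx_models(), seed = 99)
  expect_identical(m1, m2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_metagenome(m1, d1); write_metagenome(m2, d2)
  for (f in list.files(d1, recursive = TRUE))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("zero depth noise gives every contig exactly its genome depth", {
  mg <- generate_metagenome(genome_presets_paper_default()[c(1, 3)],
                            fx_models(), seed = 3, depth_sigma = 0)
  gt <- mg$truth$contigs
  expected <- c(hadesarchaeote_1 = 10, asgard_BOG_1 = 40)
  expect_equal(mg$depth$mean_depth,
               unname(expected[gt$genome[match(mg$depth$contig_id,
                                               gt$contig_id)]]))
})

test_that("a gene-free contig hits its GC target within the binomial interval", {
  preset <- genome_presets_paper_default()[[5]]
  preset$seprs <- NULL; preset$sepcyss <- NULL; preset$sepcysE_mode <- "none"
  preset$pyl <- "none"; preset$sec <- FALSE
  preset$n_contigs <- 1L
  preset$contig_len_min <- preset$contig_len_mean <- 100000L
  mg <- generate_metagenome(list(preset), fx_models(), seed = 12)
  big <- mg$contigs[nchar(mg$contigs) >= 1e5][1]
  x <- strsplit(big, "")[[1]]
  gc <- mean(x %in% c("G", "C"))
  half <- 2.576 * sqrt(0.52 * 0.48 / nchar(big))
  expect_lt(abs(gc - 0.52), half + 1e-6)
})

test_that("two SepCysS copies yield exactly two truth partners", {
  mg <- fx_metagenome()
  two <- mg$truth$pairings[mg$truth$pairings$genome == "asgard_BOG_1", ]
  expect_length(strsplit(two$partner_ids, ",")[[1]], 2L)
})

test_that("every planted gene has a protein record and appears once in truth", {
  mg <- fx_metagenome()
  tg <- mg$truth$genes
  expect_false(anyDuplicated(tg$gene_id) > 0)
  coding <- tg[!is.na(tg$protein_id), ]
  expect_true(all(coding$protein_id %in% mg$proteins$id))
  expect_true(all(mg$genes$ID %in% tg$gene_id))
  ## every GFF protein-coding gene's protein translates back: lengths agree
  g <- mg$genes[mg$genes$feature_type == "gene", ]
  plen <- nchar(mg$proteins$residues[match(g$protein_id, mg$proteins$id)])
  expect_equal(g$end - g$start + 1L, 3L * plen + 3L)
})

test_that("a contig length cap shorter than a planted locus is an error", {
  preset <- genome_presets_paper_default()[[5]]
  preset$contig_len_max <- 1000L
  expect_error(generate_metagenome(list(preset), fx_models(), seed = 1),
               "too short")
})
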