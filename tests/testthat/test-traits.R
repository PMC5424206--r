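bin_genes_fixture <- function(families, operon = NULL) {
  data.frame(ID = paste0("g", seq_along(families)), family = families,
             protein_id = paste0("p", seq_along(families)),
             start = seq_along(families) * 1000L,
             operon = operon %||% rep(1L, length(families)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Pyl architectures follow the present pylS gene forms", {
  expect_equal(detect_pyl(bin_genes_fixture(c("PylS", "pylT", "pylB")))$architecture,
               "single_pylS")
  expect_equal(detect_pyl(bin_genes_fixture(c("PylSn", "PylSc")))$architecture,
               "split_pylSn_pylSc")
  expect_equal(detect_pyl(bin_genes_fixture(c("PylSc", "mttB")))$architecture,
               "pylSc_only")
  expect_equal(detect_pyl(bin_genes_fixture("marker"))$architecture, "none")
  expect_warning(both <- detect_pyl(bin_genes_fixture(c("PylS", "PylSc"))),
                 "both")
  expect_equal(both$architecture, "single_pylS")
})

test_that("Pyl accessories and the gene-cluster flag are reported", {
  g <- bin_genes_fixture(c("PylS", "pylT", "pylB", "mtmB"), operon = rep(1L, 4))
  d <- detect_pyl(g)
  expect_setequal(d$accessories, c("pylT", "pylB", "mtmB"))
  expect_true(d$cluster)
  ## accessories scattered across operons: no cluster
  g2 <- bin_genes_fixture(c("PylS", "pylT", "pylB"), operon = 1:3)
  expect_false(detect_pyl(g2)$cluster)
})

test_that("Sec trait reports present selenoprotein families and split SPS", {
  g <- bin_genes_fixture(c("SPS", "HdrA", "VhuD", "VhuU"))
  d <- detect_sec(g)
  expect_setequal(d$sec_families, c("SPS", "HdrA", "VhuD", "VhuU"))
  expect_false(d$sps_split)
  expect_length(detect_sec(bin_genes_fixture("marker"))$sec_families, 0L)
  ## split SPS: two fragments jointly covering >= 80%, each < 60%
  ref <- fx_models()$aux$SPS
  L <- nchar(ref)
  frags <- c(p1 = substr(ref, 1, floor(0.53 * L)),
             p2 = substr(ref, floor(0.45 * L), L))
  g2 <- bin_genes_fixture(c("SPS", "SPS"))
  d2 <- detect_sec(g2, proteins = frags, sps_reference = ref)
  expect_true(d2$sps_split)
  ## a single full-length SPS is not split
  g3 <- bin_genes_fixture("SPS")
  d3 <- detect_sec(g3, proteins = c(p1 = ref), sps_reference = ref)
  expect_false(d3$sps_split)
})

test_that("trait profiles on the synthetic metagenome match the planted truth", {
  mg <- fx_metagenome()
  models <- fx_models()
  bins <- bin_contigs(profile_contigs(mg$contigs, mg$depth))
  genes <- call_operons(mg$genes)
  prof <- trait_profiles(genes, bins, proteins = fx_proteins(),
                         refs = list(sepcysE_n = models$aux$SepCysE_N,
                                     sepcyss = models$SepCysS$root,
                                     sps = models$aux$SPS))
  ## map bins to genomes through contig truth
  asn <- bins$assignments
  gt <- mg$truth$contigs
  bin_genome <- vapply(prof$bin, function(b) {
    unique(gt$genome[match(asn$contig_id[asn$bin == b], gt$contig_id)])[1]
  }, "")
  truth <- mg$truth$traits[match(bin_genome, mg$truth$traits$genome), ]
  expect_equal(prof$has_seprs, truth$has_seprs)
  expect_equal(prof$has_sepcyss, truth$has_sepcyss)
  expect_equal(prof$sepcysE_status, truth$sepcysE_status)
  expect_equal(prof$pyl_architecture, truth$pyl_architecture)
  expect_equal(prof$sps_split, truth$sps_split)
  expect_equal(prof$sec_families, truth$sec_families)
})

test_that("co-occurrence tallies equal brute-force recounts and tag uncertainty", {
  prof <- data.frame(
    bin = 1:3, has_seprs = c(TRUE, TRUE, FALSE),
    has_sepcyss = c(TRUE, FALSE, TRUE),
    sepcysE_status = c("full", "none", "full"),
    pyl_architecture = c("single_pylS", "none", "pylSc_only"),
    pyl_accessories = "", pyl_cluster = FALSE,
    sec_families = c("SPS,HdrA,VhuD,VhuU", "", "SPS"),
    n_sec_families = c(4L, 0L, 1L), sps_split = FALSE,
    uncertain = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  tab <- build_cooccurrence(prof)
  s <- tab$summary
  expect_equal(s$n_bins, 3L)
  expect_equal(s$seprs_and_pyl, sum(prof$has_seprs &
                                      prof$pyl_architecture != "none"))
  expect_equal(s$seprs_and_sec, 1L)
  expect_equal(s$sepcysE_full_and_sec, 2L)
  ## permutation invariance
  tab2 <- build_cooccurrence(prof[c(3, 1, 2), ])
  expect_equal(tab2$summary, s)
  expect_error(build_cooccurrence(prof[0, ]), "empty")
})

test_that("uncertain bins are flagged in trait profiles", {
  mg <- fx_metagenome()
  bins <- bin_contigs(profile_contigs(mg$contigs, mg$depth))
  prof <- trait_profiles(call_operons(mg$genes), bins,
                         uncertain_bins = c(2L))
  expect_true(prof$uncertain[prof$bin == 2])
  expect_false(any(prof$uncertain[prof$bin != 2]))
})
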