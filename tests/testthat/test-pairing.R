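mk_genes <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(contig_id = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = r[[4]], ID = r[[5]],
               family = r[[6]], stringsAsFactors = FALSE)))
  df
}

test_that("operon calling follows the max-gap and strand rules", {
  g <- mk_genes(list("c1", 1, 300, "+", "g1", "SepCysS"),
                list("c1", 400, 900, "+", "g2", "SepRS"))
  expect_equal(length(unique(call_operons(g)$operon)), 1L)  # gap 99
  g$start[2] <- 452  # gap 151
  expect_equal(length(unique(call_operons(g)$operon)), 2L)
  g$start[2] <- 400; g$strand[2] <- "-"
  expect_equal(length(unique(call_operons(g)$operon)), 2L)
  ## overlapping same-strand genes: one operon with a warning
  g2 <- mk_genes(list("c1", 1, 300, "+", "g1", "A"),
                 list("c1", 250, 600, "+", "g2", "B"))
  expect_warning(op <- call_operons(g2), "overlap")
  expect_equal(length(unique(op$operon)), 1L)
})

test_that("pairing uses the strongest evidence level and reports all partners there", {
  bins <- data.frame(contig_id = c("c1", "c2", "c3"), bin = 1L)
  ## operon evidence
  g <- call_operons(mk_genes(list("c1", 1, 300, "+", "r1", "SepRS"),
                             list("c1", 350, 700, "+", "s1", "SepCysS")))
  p <- pair_systems(g, bins)
  expect_equal(p$evidence, "operon")
  expect_equal(p$partners, "s1")
  ## bin evidence with two partners on other contigs
  g2 <- call_operons(mk_genes(list("c1", 1, 1400, "+", "r1", "SepRS"),
                              list("c2", 1, 1200, "+", "s1", "SepCysS"),
                              list("c3", 1, 1200, "+", "s2", "SepCysS")))
  p2 <- pair_systems(g2, bins)
  expect_equal(p2$evidence[p2$gene_id == "r1"], "bin")
  expect_equal(p2$partners[p2$gene_id == "r1"], "s1,s2")
  ## same contig beats same bin
  g3 <- call_operons(mk_genes(list("c1", 1, 1400, "+", "r1", "SepRS"),
                              list("c1", 2000, 3200, "+", "s1", "SepCysS"),
                              list("c2", 1, 1200, "+", "s2", "SepCysS")))
  p3 <- pair_systems(g3, bins)
  expect_equal(p3$evidence[p3$gene_id == "r1"], "contig")
  expect_equal(p3$partners[p3$gene_id == "r1"], "s1")
  ## unpaired SepRS, and SepCysS without SepRS in its bin
  bins4 <- data.frame(contig_id = c("c1", "c2"), bin = c(1L, 2L))
  g4 <- call_operons(mk_genes(list("c1", 1, 1400, "+", "r1", "SepRS"),
                              list("c2", 1, 1200, "+", "s1", "SepCysS")))
  p4 <- pair_systems(g4, bins4)
  expect_equal(p4$evidence[p4$gene_id == "r1"], "unpaired")
  expect_equal(p4$partners[p4$gene_id == "r1"], "")
  expect_equal(p4$evidence[p4$gene_id == "s1"], "unpaired")
})

test_that("merging two bins never upgrades the evidence level", {
  split_bins <- data.frame(contig_id = c("c1", "c2"), bin = c(1L, 2L))
  merged_bins <- data.frame(contig_id = c("c1", "c2"), bin = 1L)
  g <- call_operons(mk_genes(list("c1", 1, 1400, "+", "r1", "SepRS"),
                             list("c2", 1, 1200, "+", "s1", "SepCysS")))
  p_split <- pair_systems(g, split_bins)
  p_merged <- pair_systems(g, merged_bins)
  expect_equal(p_split$evidence[p_split$gene_id == "r1"], "unpaired")
  expect_equal(p_merged$evidence[p_merged$gene_id == "r1"], "bin")
})

test_that("pairing on the default synthetic metagenome matches ground truth exactly", {
  mg <- fx_metagenome()
  bins <- bin_contigs(profile_contigs(mg$contigs, mg$depth))
  genes <- call_operons(mg$genes)
  pairs <- pair_systems(genes, bins)
  seprs <- pairs[pairs$family == "SepRS", ]
  truth <- mg$truth$pairings
  expect_equal(nrow(seprs), nrow(truth))   # every SepRS exactly one record
  i <- match(truth$seprs_id, seprs$gene_id)
  expect_false(anyNA(i))
  sort_ids <- function(x) vapply(strsplit(x, ","), function(v)
    paste(sort(v), collapse = ","), "")
  expect_equal(sort_ids(seprs$partners[i]), sort_ids(truth$partner_ids))
  expect_equal(seprs$evidence[i], truth$evidence)
})
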