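test_that("two-sequence MSA equals the optimal global pairwise alignment", {
  sch <- scoring_scheme()
  set.seed(23)
  root <- rand_protein(120)
  for (k in 1:5) {
    a <- evolve_sequence(root, 0.3,
                         indel_plan = list(list(type = "delete",
                                                at = 10 * k, len = 4)))
    b <- evolve_sequence(root, 0.3)
    msa <- build_msa(c(x = a, y = b), sch)
    ## score the induced pairwise alignment and compare with an
    ## independent global aligner
    qa <- strsplit(msa$aln[["x"]], "")[[1]]
    sa <- strsplit(msa$aln[["y"]], "")[[1]]
    sc <- 0; S <- sch$matrix
    in_gap <- 0L
    for (i in seq_along(qa)) {
      if (qa[i] == "-" || sa[i] == "-") {
        sc <- sc - sch$gap_extend - if (in_gap == 0L) sch$gap_open else 0
        in_gap <- 1L
      } else {
        sc <- sc + S[qa[i], sa[i]]; in_gap <- 0L
      }
    }
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = sch$matrix, gapOpening = sch$gap_open,
      gapExtension = sch$gap_extend)
    expect_equal(sc, BiocGenerics::score(ref))
    ## ungapped rows reproduce the inputs
    expect_equal(gsub("-", "", msa$aln[["x"]]), a)
    expect_equal(gsub("-", "", msa$aln[["y"]]), b)
  }
})

test_that("identical sequences align without gaps and width bounds hold", {
  s <- rand_protein(80)
  msa <- build_msa(c(a = s, b = s, c = s))
  expect_false(any(grepl("-", msa$aln)))
  v <- fx_two_clades()
  msa2 <- build_msa(v)
  expect_gte(msa2$width, max(nchar(v)))
  expect_equal(gsub("-", "", msa2$aln), v)
  expect_error(build_msa(c(a = s)), "two")
})

test_that("protein distances follow the 20-state correction with saturation cap", {
  rows <- c(a = strrep("A", 100), b = paste0(strrep("C", 19), strrep("A", 81)))
  D <- protein_distance(msa_from_alignment(rows))
  expect_equal(D["a", "b"], -(19 / 20) * log(1 - (20 / 19) * 0.19),
               tolerance = 1e-10)
  expect_equal(round(D["a", "b"], 4), 0.2120)
  expect_equal(D["a", "a"], 0)
  sat <- c(a = strrep("A", 100), b = strrep("C", 100))
  expect_equal(protein_distance(msa_from_alignment(sat))["a", "b"], 5)
  disjoint <- c(a = paste0(strrep("A", 50), strrep("-", 50)),
                b = paste0(strrep("-", 50), strrep("C", 50)))
  expect_warning(Dd <- protein_distance(msa_from_alignment(disjoint)),
                 "no shared")
  expect_equal(Dd["a", "b"], 5)
})

test_that("neighbor joining recovers additive trees exactly", {
  expect_error(nj_tree(matrix(0, 2, 2)), ">= 3")
  ## 3 taxa: closed-form branch lengths
  D <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  D["a", "b"] <- D["b", "a"] <- 0.7
  D["a", "c"] <- D["c", "a"] <- 0.9
  D["b", "c"] <- D["c", "b"] <- 0.6
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (0.7 + 0.9 - 0.6) / 2)
  expect_equal(bl[["b"]], (0.7 + 0.6 - 0.9) / 2)
  expect_equal(bl[["c"]], (0.9 + 0.6 - 0.7) / 2)
  ## additive distances from random trees are recovered with RF = 0
  set.seed(77)
  for (k in 1:5) {
    true <- ape::rtree(6)
    D6 <- ape::cophenetic.phylo(true)
    rec <- nj_tree(D6)
    expect_equal(ape::dist.topo(ape::unroot(true), rec), 0,
                 ignore_attr = TRUE)
    Drec <- ape::cophenetic.phylo(rec)
    expect_equal(Drec[rownames(D6), colnames(D6)], D6, tolerance = 1e-8)
  }
})

test_that("NJ on ultrametric input matches the UPGMA topology", {
  set.seed(5)
  true <- ape::rcoal(7)
  D <- ape::cophenetic.phylo(true)
  rec <- nj_tree(D)
  up <- phangorn::upgma(as.dist(D))
  expect_equal(ape::dist.topo(ape::unroot(up), rec), 0, ignore_attr = TRUE)
})

test_that("pruning likelihood equals direct state summation (JTT oracle)", {
  ## 2 taxa, 1 column: logL = log(pi_a P_ab(t)) from the matrix exponential
  P <- jtt_P(0.4)
  mod <- jtt_model()
  msa <- msa_from_alignment(c(x = "A", y = "R"))
  tr <- ape::read.tree(text = "(x:0.2,y:0.2);")
  fit <- phangorn::pml(tr, sepmine:::msa_to_phyDat(msa), model = "JTT", k = 1)
  expect_equal(fit$logLik, log(mod$bf[["a"]] * P["a", "r"]), tolerance = 1e-6)

  ## 3 taxa, several columns incl. a gap treated as missing data
  obs <- list(x = c("A", "C", "D", "W"), y = c("A", "C", "E", "W"),
              z = c("A", "R", "D", "-"))
  lens <- c(0.15, 0.25, 0.4)
  msa3 <- msa_from_alignment(vapply(obs, paste, "", collapse = ""))
  tr3 <- ape::read.tree(text = sprintf("(x:%f,y:%f,z:%f);",
                                       lens[1], lens[2], lens[3]))
  fit3 <- phangorn::pml(tr3, sepmine:::msa_to_phyDat(msa3), model = "JTT", k = 1)
  oracle <- oracle_star3_loglik(lapply(obs, tolower), lens)
  expect_equal(fit3$logLik, oracle, tolerance = 1e-6)
})

test_that("ML optimization improves the likelihood and NNI matches enumeration", {
  ## strong 4-taxon signal: clades (a,b) vs (c,d)
  set.seed(19)
  root <- rand_protein(150)
  p1 <- evolve_sequence(root, 0.75); p2 <- evolve_sequence(root, 0.75)
  v <- c(a = evolve_sequence(p1, 0.06), b = evolve_sequence(p1, 0.06),
         c = evolve_sequence(p2, 0.06), d = evolve_sequence(p2, 0.06))
  msa <- build_msa(v)
  start <- nj_tree(protein_distance(msa))
  fit0 <- phangorn::pml(start, sepmine:::msa_to_phyDat(msa), model = "JTT", k = 1)
  fit <- ml_optimize(start, msa)
  expect_gte(fit$logLik, fit0$logLik)
  ## exhaustive enumeration of the 3 unrooted quartet topologies
  topos <- c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));")
  lls <- vapply(topos, function(tx) {
    tr <- ape::unroot(ape::read.tree(text = tx))
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    f <- phangorn::pml(tr, sepmine:::msa_to_phyDat(msa), model = "JTT", k = 1)
    phangorn::optim.pml(f, model = "JTT", optNni = FALSE, optEdge = TRUE,
                        control = phangorn::pml.control(trace = 0))$logLik
  }, 0)
  best <- ape::unroot(ape::read.tree(text = topos[which.max(lls)]))
  expect_equal(ape::dist.topo(best, ape::unroot(fit$tree)), 0,
               ignore_attr = TRUE)
  expect_equal(fit$logLik, max(lls), tolerance = 1e-3)
})

test_that("bootstrap supports are reproducible and saturate on strong splits", {
  v <- fx_two_clades()
  msa <- build_msa(v)
  bs1 <- bootstrap_support(msa, n = 20, seed = 5)
  bs2 <- bootstrap_support(msa, n = 20, seed = 5)
  expect_identical(write_newick(bs1$tree), write_newick(bs2$tree))
  ## the clade-separating split is recovered in every replicate
  expect_true(100 %in% bs1$tree$node.label)
  spl <- ape::prop.part(bs1$tree)
  labs <- bs1$tree$tip.label
  fs_clades <- substr(labs, 3, 3)  # F_I_xx vs F_II_xx naming
  ## find a node whose tip set is exactly one planted clade
  sets <- lapply(spl, function(s) sort(labs[s]))
  clade1 <- sort(labs[startsWith(labs, "F_I_")])
  node_idx <- which(vapply(sets, identical, TRUE, clade1))
  if (length(node_idx) == 1L) {
    expect_equal(bs1$tree$node.label[node_idx], 100L)
  }
  bs_one <- bootstrap_support(msa, n = 1, seed = 2)
  expect_true(all(bs_one$tree$node.label %in% c(0L, 100L)))
})
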