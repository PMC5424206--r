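#' Pairwise evolutionary distances from a protein MSA
#'
#' For each pair: `p` = mismatch fraction over shared non-gap columns;
#' distance = `-(19/20) ln(1 - (20/19) p)` (the 20-state
#' Jukes-Cantor-type correction), capped at 5.0 where the log argument
#' is nonpositive.  A pair with no shared columns gets the cap with a
#' warning.
#'
#' @param msa a `protein_msa`.
#' @param cap saturation cap (default 5).
#' @return symmetric numeric distance matrix.
#' @export
protein_distance <- function(msa, cap = 5) {
  m <- as.matrix(msa)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 rows", call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- !gap[i, ] & !gap[j, ]
      if (!any(shared)) {
        warning(sprintf("no shared columns for %s/%s; distance capped",
                        rownames(m)[i], rownames(m)[j]))
        d <- cap
      } else {
        p <- mean(m[i, shared] != m[j, shared])
        arg <- 1 - (20 / 19) * p
        d <- if (arg <= 0) cap else min(-(19 / 20) * log(arg), cap)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining starting tree
#'
#' Standard neighbor-joining via [ape::nj()]; negative branch lengths
#' are clamped to zero.
#'
#' @param dist symmetric distance matrix (>= 3 taxa).
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dist) {
  if (nrow(as.matrix(dist)) < 3L) stop("need >= 3 taxa", call. = FALSE)
  tr <- ape::nj(as.dist(as.matrix(dist)))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

msa_to_phyDat <- function(msa, complete_deletion = FALSE) {
  m <- as.matrix(msa)
  if (complete_deletion) {
    keep <- colSums(m == "-") == 0L
    if (!any(keep)) stop("no gap-free columns", call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  phangorn::phyDat(m, type = "AA")
}

#' Maximum-likelihood optimization under the JTT model
#'
#' Optimizes branch lengths (and the topology, by
#' nearest-neighbor-interchange moves accepted while the log-likelihood
#' improves) under the Jones-Taylor-Thornton amino-acid model with
#' uniform rates.  Alignment gaps are treated as missing data by
#' default (every state equally likely at the site), the reading of
#' "use all sites"; `complete_deletion = TRUE` instead drops every
#' column containing a gap.
#'
#' @param tree starting tree (e.g. from [nj_tree()]); leaves must match
#'   the MSA ids.
#' @param msa a `protein_msa`.
#' @param optimize_topology perform NNI search (default TRUE).
#' @param complete_deletion drop gapped columns instead of treating
#'   gaps as missing.
#' @return object of class `ml_fit`: list with `tree` (branch-length
#'   optimized [ape::phylo]), `logLik`, and the underlying
#'   `phangorn::pml` fit.
#' @export
ml_optimize <- function(tree, msa, optimize_topology = TRUE,
                        complete_deletion = FALSE) {
  if (msa$width == 0L) stop("zero-length alignment", call. = FALSE)
  if (!setequal(tree$tip.label, msa$ids))
    stop("tree leaves must match MSA ids", call. = FALSE)
  dat <- msa_to_phyDat(msa, complete_deletion)
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  fit <- phangorn::pml(tree, dat, model = "JTT", k = 1)
  fit <- phangorn::optim.pml(
    fit, model = "JTT", optNni = optimize_topology, optEdge = TRUE,
    optBf = FALSE, optQ = FALSE, optInv = FALSE, optGamma = FALSE,
    control = phangorn::pml.control(trace = 0, eps = 1e-6))
  structure(list(tree = fit$tree, logLik = fit$logLik, fit = fit),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("ml_fit: %d taxa, log-likelihood %.4f (JTT, uniform rates)\n",
              length(x$tree$tip.label), x$logLik))
  invisible(x)
}

#' Bootstrap supports for the ML tree
#'
#' Resamples alignment columns with replacement `n` times; each
#' replicate goes through distance + neighbor joining and (optionally)
#' ML branch/topology optimization.  Internal-branch support is the
#' percentage of replicate trees containing the split, attached to the
#' base tree's node labels.
#'
#' @param msa a `protein_msa`.
#' @param n bootstrap replicates (default 100).
#' @param seed integer seed (resampling is reproducible given it).
#' @param optimize_topology run NNI per replicate (default TRUE).
#' @return object of class `ml_fit` whose `tree` carries integer
#'   bootstrap percentages in `node.label`; the replicate trees are in
#'   `$replicates`.
#' @export
bootstrap_support <- function(msa, n = 100, seed = 1L,
                              optimize_topology = TRUE) {
  stopifnot(n >= 1L)
  base <- ml_optimize(nj_tree(protein_distance(msa)), msa,
                      optimize_topology = optimize_topology)
  reps <- with_seed(seed, {
    lapply(seq_len(n), function(b) {
      cols <- sample.int(msa$width, msa$width, replace = TRUE)
      m <- as.matrix(msa)[, cols, drop = FALSE]
      rmsa <- msa_from_alignment(setNames(apply(m, 1, paste, collapse = ""),
                                          rownames(m)))
      fit <- ml_optimize(nj_tree(protein_distance(rmsa)), rmsa,
                         optimize_topology = optimize_topology)
      fit$tree
    })
  })
  class(reps) <- "multiPhylo"
  tr <- base$tree
  counts <- ape::prop.clades(tr, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tr$node.label <- as.integer(round(100 * counts / n))
  out <- base
  out$tree <- tr
  out$replicates <- reps
  out
}
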