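## Independent oracles used by the test suite.  These deliberately avoid
## the code paths they check.

## Brute-force optimal local alignment: enumerate every monotone set of
## aligned residue pairs (any residues may pair), score matched pairs by
## the substitution matrix and unaligned residues inside the span as
## affine gap runs (open + len * extend per maximal run).  The empty
## alignment scores 0.
oracle_local_align <- function(a, b, S, go = 11, ge = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0
  for (k in seq_len(min(na, nb))) {
    ia <- utils::combn(na, k, simplify = FALSE)
    ib <- utils::combn(nb, k, simplify = FALSE)
    for (sa in ia) for (sb in ib) {
      sc <- sum(S[cbind(av[sa], bv[sb])])
      if (k > 1) {
        for (m in seq_len(k - 1)) {
          da <- sa[m + 1] - sa[m] - 1L
          db <- sb[m + 1] - sb[m] - 1L
          if (da > 0) sc <- sc - go - da * ge
          if (db > 0) sc <- sc - go - db * ge
        }
      }
      if (sc > best) best <- sc
    }
  }
  best
}

## JTT rate matrix (from phangorn's published model table), normalized to
## one expected substitution per site, plus its transition matrix by
## numeric matrix exponential
jtt_model <- function() {
  jtt <- get(".JTT", envir = environment(phangorn::pml))
  bf <- jtt$bf
  n <- 20L
  Q <- matrix(0, n, n)
  k <- 1L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    Q[i, j] <- jtt$Q[k] * bf[j]
    Q[j, i] <- jtt$Q[k] * bf[i]
    k <- k + 1L
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(bf * diag(Q)))
  aa <- names(bf)
  dimnames(Q) <- list(aa, aa)
  list(Q = Q, bf = bf, aa = aa)
}

jtt_P <- function(t) {
  mod <- jtt_model()
  e <- eigen(mod$Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  dimnames(P) <- dimnames(mod$Q)
  P
}

## direct-summation likelihood of a 3-taxon star tree (one internal
## node): sum over the internal state of pi_x prod_i P_x,obs(t_i)
oracle_star3_loglik <- function(obs, lens) {
  mod <- jtt_model()
  Ps <- lapply(lens, jtt_P)
  ll <- 0
  for (s in seq_along(obs[[1]])) {
    site <- vapply(obs, `[`, "", s)
    contrib <- mod$bf
    for (i in 1:3) {
      if (site[i] == "-") next
      contrib <- contrib * Ps[[i]][, site[i]]
    }
    ll <- ll + log(sum(contrib))
  }
  ll
}

## adjusted Rand index oracle (mclust)
ari <- function(x, y) mclust::adjustedRandIndex(x, y)
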