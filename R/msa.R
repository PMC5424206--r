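## k-mer distance between unaligned sequences (guide-tree input only)
kmer_distance <- function(v, k = 3L) {
  counts <- lapply(v, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(v)
  D <- matrix(0, n, n, dimnames = list(names(v), names(v)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ci <- counts[[i]]; cj <- counts[[j]]
      shared <- sum(pmin(ci[names(cj)], cj)[!is.na(ci[names(cj)])])
      denom <- min(nchar(v[i]), nchar(v[j])) - k + 1L
      d <- 1 - shared / max(denom, 1L)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

## 20-row residue-frequency profile of an aligned block
profile_of <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(mat)
  P <- matrix(0, 20L, L, dimnames = list(AA20, NULL))
  nr <- nrow(mat)
  for (a in AA20) P[a, ] <- colSums(mat == a) / nr
  P
}

## merge two aligned blocks along a move path from profile_align_path
merge_blocks <- function(rowsA, rowsB, path) {
  a_take <- path != 2L  # consume an A column
  b_take <- path != 1L
  expand <- function(rows, take) {
    vapply(rows, function(s) {
      x <- seq_chars(s)
      out <- rep("-", length(take))
      out[take] <- x
      paste(out, collapse = "")
    }, "", USE.NAMES = TRUE)
  }
  c(expand(rowsA, a_take), expand(rowsB, b_take))
}

#' Progressive multiple protein alignment
#'
#' Classic progressive alignment: k-mer distances, UPGMA guide tree,
#' then profile-profile global alignment with affine gaps along the
#' guide tree.  Deterministic; with two sequences it reduces to the
#' optimal global pairwise alignment under the same scoring.
#'
#' @param seqs named character vector of >= 2 protein sequences (or a
#'   sequence table from [read_fasta()]).
#' @param scheme a [scoring_scheme()].
#' @return object of class `protein_msa`: list with `ids`, `aln`
#'   (named character vector of equal-length aligned rows) and `width`.
#' @export
build_msa <- function(seqs, scheme = scoring_scheme()) {
  v <- as_seq_vec(seqs)
  if (length(v) < 2L) stop("need at least two sequences", call. = FALSE)
  v <- toupper(v)
  S20 <- scheme$matrix[AA20, AA20]
  align_pair <- function(rowsA, rowsB) {
    PA <- profile_of(rowsA); PB <- profile_of(rowsB)
    C <- t(PA) %*% S20 %*% PB
    path <- profile_align_path(C, scheme$gap_open, scheme$gap_extend)
    merge_blocks(rowsA, rowsB, path)
  }
  if (length(v) == 2L) {
    aln <- align_pair(v[1], v[2])
  } else {
    D <- kmer_distance(v)
    hc <- hclust(as.dist(D), method = "average")
    blocks <- lapply(seq_along(v), function(i) v[i])
    merged <- vector("list", nrow(hc$merge))
    for (s in seq_len(nrow(hc$merge))) {
      get_block <- function(x) if (x < 0) blocks[[-x]] else merged[[x]]
      merged[[s]] <- align_pair(get_block(hc$merge[s, 1]),
                                get_block(hc$merge[s, 2]))
    }
    aln <- merged[[length(merged)]]
  }
  aln <- aln[names(v)]
  structure(list(ids = names(v), aln = aln, width = nchar(aln[[1]])),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("protein_msa: %d sequences, %d columns\n",
              length(x$aln), x$width))
  invisible(x)
}

#' @export
as.matrix.protein_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$aln, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Build a `protein_msa` from already-aligned rows
#'
#' @param aln named character vector of equal-length aligned rows.
#' @return a `protein_msa`.
#' @export
msa_from_alignment <- function(aln) {
  aln <- as_seq_vec(aln)
  w <- unique(nchar(aln))
  if (length(w) != 1L) stop("aligned rows must have equal length", call. = FALSE)
  structure(list(ids = names(aln), aln = aln, width = w),
            class = "protein_msa")
}
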