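#' Protein scoring scheme for local alignment
#'
#' Bundle of substitution matrix and affine gap penalties.  A gap of length
#' k costs `gap_open + k * gap_extend` (the convention of
#' [Biostrings::pairwiseAlignment()], which performs the alignments).
#'
#' @param matrix a symmetric integer substitution matrix, or the name of a
#'   matrix shipped with Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend positive gap penalties.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric", call. = FALSE)
  if (gap_open <= 0 || gap_extend <= 0)
    stop("gap penalties must be positive", call. = FALSE)
  core <- intersect(rownames(matrix), AA20)
  if (any(diag(matrix[core, core, drop = FALSE]) <= 0))
    stop("diagonal of the substitution matrix must be positive", call. = FALSE)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman local alignment with affine gaps (exact dynamic
#' programming, no heuristic seeding), as a stand-in for a BLASTp hit.
#' Returns the alignment together with the BLAST-style percent similarity
#' (fraction of columns whose residue pair scores positively, gap columns
#' counted in the denominator) and the query coverage.
#'
#' @param a,b query and subject protein sequences (single strings).
#' @param scheme a [scoring_scheme()].
#' @return an object of class `pairwise_alignment`: list with
#'   `query_aln`, `subject_aln`, `score`, `query_start`, `query_end`,
#'   `subject_start`, `subject_end`, `percent_similarity`,
#'   `query_coverage`.
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  if (!is.character(a) || !is.character(b) || nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty strings", call. = FALSE)
  a <- toupper(a); b <- toupper(b)
  check_alphabet(a, AA_ALPHABET, "query")
  check_alphabet(b, AA_ALPHABET, "subject")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- BiocGenerics::score(pa)
  if (sc <= 0) {
    out <- list(query_id = NA_character_, subject_id = NA_character_,
                query_aln = "", subject_aln = "", score = 0,
                query_start = NA_integer_, query_end = NA_integer_,
                subject_start = NA_integer_, subject_end = NA_integer_,
                percent_similarity = NA_real_, query_coverage = 0,
                scheme = scheme)
    class(out) <- "pairwise_alignment"
    return(out)
  }
  qa <- as.character(Biostrings::alignedPattern(pa))
  sa <- as.character(Biostrings::alignedSubject(pa))
  out <- list(
    query_id = NA_character_, subject_id = NA_character_,
    query_aln = unname(qa), subject_aln = unname(sa), score = sc,
    query_start = BiocGenerics::start(Biostrings::pattern(pa)),
    query_end = BiocGenerics::end(Biostrings::pattern(pa)),
    subject_start = BiocGenerics::start(Biostrings::subject(pa)),
    subject_end = BiocGenerics::end(Biostrings::subject(pa)),
    percent_similarity = NA_real_,
    query_coverage =
      (BiocGenerics::end(Biostrings::pattern(pa)) -
         BiocGenerics::start(Biostrings::pattern(pa)) + 1L) / nchar(a),
    scheme = scheme)
  class(out) <- "pairwise_alignment"
  out$percent_similarity <- percent_similarity(out)
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("local alignment: score %.1f, similarity %.1f%%, query coverage %.2f\n",
              x$score, x$percent_similarity, x$query_coverage))
  cat(" ", x$query_aln, "\n ", x$subject_aln, "\n")
  invisible(x)
}

#' Percent similarity of a local alignment
#'
#' 100 x (columns whose residue pair has positive substitution score) /
#' (all alignment columns, gap columns included in the denominator) --
#' the BLAST "positives" percentage.
#'
#' @param aln a `pairwise_alignment` from [local_align()].
#' @return numeric in \[0, 100\].
#' @export
percent_similarity <- function(aln) {
  if (!inherits(aln, "pairwise_alignment")) stop("need a pairwise_alignment")
  if (nchar(aln$query_aln) == 0L) stop("empty alignment", call. = FALSE)
  qa <- seq_chars(aln$query_aln)
  sa <- seq_chars(aln$subject_aln)
  stopifnot(length(qa) == length(sa))
  resid <- qa != "-" & sa != "-"
  S <- aln$scheme$matrix
  pos <- sum(S[cbind(qa[resid], sa[resid])] > 0)
  100 * pos / length(qa)
}

#' Percent similarity between two sequences
#'
#' Convenience: locally aligns `a` and `b` and returns the percent
#' similarity (0 when no positive-scoring local alignment exists).
#' The pair is canonicalized (lexicographically ordered) before
#' alignment so the statistic is exactly symmetric even when several
#' local alignments tie for the optimal score.
#'
#' @inheritParams local_align
#' @return numeric in \[0, 100\].
#' @export
sequence_similarity <- function(a, b, scheme = scoring_scheme()) {
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  aln <- local_align(a, b, scheme)
  if (nchar(aln$query_aln) == 0L) return(0)
  aln$percent_similarity
}

#' All-pairs percent-similarity matrix
#'
#' @param seqs named character vector of protein sequences (or a sequence
#'   table from [read_fasta()]).
#' @param scheme a [scoring_scheme()].
#' @return symmetric numeric matrix with 100 on the diagonal.
#' @export
similarity_matrix <- function(seqs, scheme = scoring_scheme()) {
  v <- as_seq_vec(seqs)
  n <- length(v)
  m <- matrix(100, n, n, dimnames = list(names(v), names(v)))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    hits <- align_to_query(v[seq.int(i + 1L, n)], v[[i]], scheme)
    m[i, seq.int(i + 1L, n)] <- m[seq.int(i + 1L, n), i] <- hits$similarity
  }
  m
}
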