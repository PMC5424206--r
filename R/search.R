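## align every database sequence to one query in a single vectorized call;
## returns per-subject score, percent similarity and query coverage
align_to_query <- function(db, query, scheme = scoring_scheme()) {
  stopifnot(length(db) >= 1L)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(db), Biostrings::AAString(query), type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- BiocGenerics::score(pa)
  qa <- as.character(Biostrings::alignedPattern(pa))   # database side
  sa <- as.character(Biostrings::alignedSubject(pa))   # query side
  S <- scheme$matrix
  sim <- vapply(seq_along(db), function(i) {
    if (sc[i] <= 0) return(0)
    q <- seq_chars(qa[i]); s <- seq_chars(sa[i])
    resid <- q != "-" & s != "-"
    100 * sum(S[cbind(q[resid], s[resid])] > 0) / length(q)
  }, 0)
  qs <- BiocGenerics::start(Biostrings::subject(pa))
  qe <- BiocGenerics::end(Biostrings::subject(pa))
  cov <- ifelse(sc > 0, (qe - qs + 1L) / nchar(query), 0)
  data.frame(id = names(db), score = sc, similarity = sim,
             query_coverage = cov, stringsAsFactors = FALSE)
}

#' Group sequences by single-linkage similarity
#'
#' Single-linkage clusters at percent similarity >= `link_threshold`;
#' each group's representative is its medoid (maximal mean similarity to
#' the rest of the group, ties broken by lexicographic id).
#'
#' @param seqs named character vector of protein sequences.
#' @param link_threshold linking similarity (percent, default 60).
#' @param scheme a [scoring_scheme()].
#' @param simmat optional precomputed [similarity_matrix()].
#' @return data frame with columns `id`, `group`, `is_representative`.
#' @export
group_by_similarity <- function(seqs, link_threshold = 60,
                                scheme = scoring_scheme(), simmat = NULL) {
  v <- as_seq_vec(seqs)
  n <- length(v)
  if (n == 0L)
    return(data.frame(id = character(), group = integer(),
                      is_representative = logical()))
  if (is.null(simmat)) simmat <- similarity_matrix(v, scheme)
  comp <- single_linkage(simmat >= link_threshold)
  ## stable group numbering: by first (input-order) member
  first <- vapply(split(seq_len(n), comp), min, 0L)
  relabel <- match(as.character(comp), names(sort(first)))
  out <- data.frame(id = names(v), group = relabel,
                    is_representative = FALSE, stringsAsFactors = FALSE)
  for (g in unique(relabel)) {
    idx <- which(relabel == g)
    if (length(idx) == 1L) { out$is_representative[idx] <- TRUE; next }
    msim <- rowMeans(simmat[idx, idx, drop = FALSE]) -
      100 / length(idx)  # exclude self term uniformly
    best <- idx[order(-msim, names(v)[idx])][1]
    out$is_representative[best] <- TRUE
  }
  out
}

## connected components of a symmetric logical adjacency matrix
single_linkage <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      m <- min(comp[c(i, nb)])
      if (any(comp[c(i, nb)] != m)) {
        comp[c(i, nb)] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  as.integer(comp)
}

#' Iterative homolog search with query expansion
#'
#' Round 1 retains every database sequence with percent similarity >=
#' `threshold` and query coverage >= `coverage_min` against any seed
#' query.  Retained sequences are grouped by single-linkage similarity;
#' one medoid representative per group is re-queried, and rounds repeat
#' until no new sequence is retained or `max_rounds` is reached.
#'
#' @param seed_queries named character vector of query proteins.
#' @param database named character vector of database proteins.
#' @param threshold retention percent similarity (default 40).
#' @param coverage_min minimal query coverage (default 0.6); guards
#'   against short domain-only hits chaining into unrelated families.
#' @param max_rounds maximal number of search rounds (default 10).
#' @param link_threshold grouping similarity (default 60).
#' @param scheme a [scoring_scheme()].
#' @return object of class `homolog_set`: data frame with columns `id`,
#'   `similarity` (best similarity to any accepted query), `round`
#'   (discovery round), `group`, `is_representative`.
#' @export
iterative_search <- function(seed_queries, database, threshold = 40,
                             coverage_min = 0.6, max_rounds = 10,
                             link_threshold = 60, scheme = scoring_scheme()) {
  stopifnot(length(seed_queries) >= 1L, threshold > 0, threshold < 100)
  seed_queries <- as_seq_vec(seed_queries)
  if (length(database) == 0L) {
    out <- data.frame(id = character(), similarity = numeric(),
                      round = integer(), group = integer(),
                      is_representative = logical())
    class(out) <- c("homolog_set", class(out))
    return(out)
  }
  database <- as_seq_vec(database)
  retained <- character(0)   # ids in retention order
  best_sim <- numeric(0); found_round <- integer(0)
  queries <- seed_queries
  for (round in seq_len(max_rounds)) {
    new_ids <- character(0)
    for (qi in seq_along(queries)) {
      hits <- align_to_query(database, queries[[qi]], scheme)
      ok <- hits$similarity >= threshold & hits$query_coverage >= coverage_min
      for (i in which(ok)) {
        id <- hits$id[i]
        if (!id %in% retained && !id %in% new_ids) {
          new_ids <- c(new_ids, id)
          best_sim[id] <- hits$similarity[i]
          found_round[id] <- round
        } else {
          best_sim[id] <- max(best_sim[id], hits$similarity[i])
        }
      }
    }
    if (length(new_ids) == 0L) break
    retained <- c(retained, new_ids)
    grp <- group_by_similarity(database[retained], link_threshold, scheme)
    queries <- database[grp$id[grp$is_representative]]
  }
  if (length(retained) == 0L) {
    out <- data.frame(id = character(), similarity = numeric(),
                      round = integer(), group = integer(),
                      is_representative = logical())
  } else {
    grp <- group_by_similarity(database[retained], link_threshold, scheme)
    out <- data.frame(id = retained,
                      similarity = unname(best_sim[retained]),
                      round = unname(found_round[retained]),
                      group = grp$group[match(retained, grp$id)],
                      is_representative =
                        grp$is_representative[match(retained, grp$id)],
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("homolog_set", class(out))
  out
}
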