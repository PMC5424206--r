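#' Partition sequences into major clades and orphans
#'
#' Operational clade delineation: single-linkage clusters at percent
#' similarity >= `similarity_threshold`; clusters of at least
#' `min_clade_size` members are major clades (ordered by decreasing
#' size, then first member), smaller clusters' members are orphans.
#'
#' @param seqs named character vector of protein sequences.
#' @param similarity_threshold linking similarity (percent, default 50).
#' @param min_clade_size minimal major-clade size (default 3).
#' @param scheme a [scoring_scheme()].
#' @param simmat optional precomputed [similarity_matrix()].
#' @return object of class `clade_partition`: list with `clades` (list
#'   of id vectors), `orphans` (ids), and `membership` (data frame
#'   `id`, `clade`; orphans labeled `"orphan"`).
#' @export
partition_clades <- function(seqs, similarity_threshold = 50,
                             min_clade_size = 3, scheme = scoring_scheme(),
                             simmat = NULL) {
  v <- as_seq_vec(seqs)
  if (is.null(simmat)) simmat <- similarity_matrix(v, scheme)
  comp <- single_linkage(simmat >= similarity_threshold)
  groups <- split(names(v), comp)
  sizes <- lengths(groups)
  first <- vapply(split(seq_along(v), comp), min, 0L)
  major <- groups[sizes >= min_clade_size]
  major <- major[order(-sizes[sizes >= min_clade_size],
                       first[sizes >= min_clade_size])]
  orphans <- unlist(groups[sizes < min_clade_size], use.names = FALSE)
  membership <- data.frame(id = names(v), clade = "orphan",
                           stringsAsFactors = FALSE)
  for (i in seq_along(major))
    membership$clade[membership$id %in% major[[i]]] <- as.character(i)
  structure(list(clades = unname(major), orphans = orphans %||% character(0),
                 membership = membership),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("clade_partition: %d major clades (sizes %s), %d orphan(s)\n",
              length(x$clades),
              paste(lengths(x$clades), collapse = ", "),
              length(x$orphans)))
  invisible(x)
}

#' Assign query sequences to labeled reference clades
#'
#' Each query receives the clade label of its most similar reference if
#' that similarity reaches `similarity_threshold`, and `"novel"`
#' otherwise.  Ties are broken by higher similarity, then lexicographic
#' label.
#'
#' @param queries named character vector of query proteins.
#' @param references named character vector of reference proteins.
#' @param ref_labels character vector of clade labels, parallel to
#'   `references`.
#' @param similarity_threshold assignment threshold (percent, default 50).
#' @param scheme a [scoring_scheme()].
#' @return data frame with columns `id`, `label`, `best_similarity`,
#'   `best_reference`.
#' @export
assign_to_reference_clades <- function(queries, references, ref_labels,
                                       similarity_threshold = 50,
                                       scheme = scoring_scheme()) {
  if (length(references) == 0L) stop("empty reference set", call. = FALSE)
  queries <- as_seq_vec(queries)
  references <- as_seq_vec(references)
  stopifnot(length(ref_labels) == length(references))
  rows <- lapply(seq_along(queries), function(i) {
    hits <- align_to_query(references, queries[[i]], scheme)
    ord <- order(-hits$similarity, ref_labels)
    best <- ord[1]
    lab <- if (hits$similarity[best] >= similarity_threshold)
      ref_labels[best] else "novel"
    data.frame(id = names(queries)[i], label = lab,
               best_similarity = hits$similarity[best],
               best_reference = hits$id[best], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
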