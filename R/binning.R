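#' Compute per-contig GC/depth/length profiles
#'
#' GC is the fraction of G+C among unambiguous (ACGT) bases; `N` is
#' excluded from numerator and denominator.
#'
#' @param contigs named character vector of contig sequences (or a
#'   sequence table from [read_fasta()]).
#' @param depth_table data frame with `contig_id`, `mean_depth` (one row
#'   per contig).
#' @return data frame with columns `contig_id`, `length`, `gc`, `depth`.
#' @export
profile_contigs <- function(contigs, depth_table) {
  v <- as_seq_vec(contigs)
  missing <- setdiff(names(v), depth_table$contig_id)
  if (length(missing) > 0L)
    stop(sprintf("no depth row for contig(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  dna <- Biostrings::DNAStringSet(unname(v))
  freq <- Biostrings::alphabetFrequency(dna, baseOnly = TRUE)
  acgt <- freq[, c("A", "C", "G", "T"), drop = FALSE]
  gc <- (acgt[, "G"] + acgt[, "C"]) / rowSums(acgt)
  data.frame(contig_id = names(v), length = nchar(unname(v)), gc = unname(gc),
             depth = depth_table$mean_depth[match(names(v), depth_table$contig_id)],
             stringsAsFactors = FALSE)
}

#' Bin contigs by GC content and read depth
#'
#' Single-linkage clustering with hard gates: two contigs link iff
#' `|delta gc| <= gc_tol` and `|log2(depth ratio)| <= depth_tol_log2`.
#' Depth is compared on the log2 scale because coverage noise is
#' multiplicative.  Contigs shorter than `min_len` are reported
#' unbinned.  Bin ids are dense from 1, ordered by first member in
#' input order, so the result is permutation-invariant up to
#' relabeling.
#'
#' @param profiles data frame from [profile_contigs()].
#' @param gc_tol GC linking tolerance (fraction, default 0.025).
#' @param depth_tol_log2 depth linking tolerance (log2, default 0.5).
#' @param min_len minimal contig length to bin (bp, default 2000).
#' @return object of class `bin_assignment`: list with `assignments`
#'   (data frame `contig_id`, `bin`), `summary` (per-bin n, total bp,
#'   mean gc, mean depth), and `unbinned` (character vector).
#' @export
bin_contigs <- function(profiles, gc_tol = 0.025, depth_tol_log2 = 0.5,
                        min_len = 2000) {
  stopifnot(nrow(profiles) > 0L)
  keep <- profiles$length >= min_len
  unbinned <- profiles$contig_id[!keep]
  pr <- profiles[keep, , drop = FALSE]
  if (nrow(pr) == 0L) {
    out <- list(assignments = data.frame(contig_id = character(),
                                         bin = integer()),
                summary = data.frame(), unbinned = unbinned)
    class(out) <- "bin_assignment"
    return(out)
  }
  depth <- pr$depth
  if (any(depth <= 0)) {
    warning("contig(s) with zero depth assigned pseudo-depth 0.01")
    depth[depth <= 0] <- 0.01
  }
  ld <- log2(depth)
  adj <- abs(outer(pr$gc, pr$gc, "-")) <= gc_tol &
    abs(outer(ld, ld, "-")) <= depth_tol_log2
  comp <- single_linkage(adj)
  first <- vapply(split(seq_len(nrow(pr)), comp), min, 0L)
  bin <- match(as.character(comp), names(sort(first)))
  assignments <- data.frame(contig_id = pr$contig_id, bin = bin,
                            stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    data.frame(bin = b, n_contigs = sum(i), total_bp = sum(pr$length[i]),
               mean_gc = mean(pr$gc[i]), mean_depth = mean(pr$depth[i]))
  }))
  out <- list(assignments = assignments, summary = summary,
              unbinned = unbinned)
  class(out) <- "bin_assignment"
  out
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf("bin_assignment: %d bins over %d contigs (%d unbinned)\n",
              nrow(x$summary), nrow(x$assignments), length(x$unbinned)))
  invisible(x)
}

#' Remove contigs whose marker taxonomy conflicts with the bin majority
#'
#' For each bin the majority taxon is the modal label among its
#' marker-bearing contigs; contigs labeled otherwise are removed
#' (generalizing ad hoc removal of contaminating contigs from a bin).
#' Unlabeled contigs are kept; a tie in the majority vote leaves the bin
#' unchanged with a warning.
#'
#' @param bins a `bin_assignment` from [bin_contigs()] (or its
#'   `assignments` data frame).
#' @param marker_calls data frame with columns `contig_id`, `taxon` for
#'   contigs carrying marker genes.
#' @return list with `assignments` (cleaned data frame) and `removed`
#'   (data frame of removed contigs with their bin and taxon).
#' @export
purge_conflicts <- function(bins, marker_calls) {
  asn <- if (inherits(bins, "bin_assignment")) bins$assignments else bins
  removed <- list()
  for (b in unique(asn$bin)) {
    ids <- asn$contig_id[asn$bin == b]
    lab <- marker_calls$taxon[match(ids, marker_calls$contig_id)]
    lab_known <- lab[!is.na(lab)]
    if (length(lab_known) == 0L) next
    tab <- sort(table(lab_known), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) {
      warning(sprintf("bin %s: tied marker taxonomy, nothing removed", b))
      next
    }
    majority <- names(tab)[1]
    bad <- ids[!is.na(lab) & lab != majority]
    if (length(bad) > 0L)
      removed[[length(removed) + 1L]] <- data.frame(
        contig_id = bad, bin = b,
        taxon = lab[match(bad, ids)], stringsAsFactors = FALSE)
  }
  removed <- if (length(removed) > 0L) do.call(rbind, removed)
    else data.frame(contig_id = character(), bin = integer(),
                    taxon = character())
  list(assignments = asn[!asn$contig_id %in% removed$contig_id, , drop = FALSE],
       removed = removed)
}
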