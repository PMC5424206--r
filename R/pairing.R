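#' Call operons as maximal co-oriented gene runs
#'
#' Genes on the same contig and strand whose successive intergenic gaps
#' are at most `max_gap` nucleotides form one operon; singletons are
#' emitted as one-gene operons.  Overlapping same-strand genes are kept
#' in one operon with a warning.
#'
#' @param genes data frame with columns `contig_id`, `start`, `end`,
#'   `strand` and a gene identifier column `ID` (as from [read_gff3()]
#'   or the generator's feature table).
#' @param max_gap maximal intergenic gap in nt (default 150).
#' @return data frame `genes` with an added integer `operon` column;
#'   operon ids are dense in (contig, start) order.
#' @export
call_operons <- function(genes, max_gap = 150) {
  stopifnot(all(c("contig_id", "start", "end", "strand", "ID") %in% names(genes)))
  ord <- order(genes$contig_id, genes$start, genes$end)
  g <- genes[ord, , drop = FALSE]
  op <- integer(nrow(g))
  cur <- 0L
  ## per contig+strand, sweep by start position
  for (key in unique(paste(g$contig_id, g$strand))) {
    idx <- which(paste(g$contig_id, g$strand) == key)
    prev_end <- NULL
    for (i in idx) {
      if (is.null(prev_end)) {
        cur <- cur + 1L
      } else {
        gap <- g$start[i] - prev_end - 1L
        if (gap < 0L)
          warning(sprintf("overlapping genes on %s kept in one operon",
                          g$contig_id[i]))
        if (gap > max_gap) cur <- cur + 1L
      }
      op[i] <- cur
      prev_end <- max(prev_end %||% 0L, g$end[i])
    }
  }
  g$operon <- op
  g <- g[match(genes$ID, g$ID), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Pair SepRS genes with SepCysS partners by an evidence hierarchy
#'
#' For each SepRS gene, partners are the SepCysS genes found at the
#' strongest available evidence level: same operon, else same contig,
#' else same genome bin.  All partners at that level are reported (so a
#' bin with two SepCysS copies yields two partners).  SepRS with no
#' partner anywhere in its bin is reported unpaired, as is any SepCysS
#' without a SepRS in its bin.
#'
#' @param genes gene table with `ID`, `contig_id`, `family` and an
#'   `operon` column from [call_operons()].
#' @param bins a `bin_assignment` (or its `assignments` data frame)
#'   mapping contigs to bins.
#' @return data frame with one row per SepRS (and per orphan SepCysS):
#'   `gene_id`, `family`, `partners` (comma-separated ids, empty if
#'   none), `evidence` (`operon`, `contig`, `bin` or `unpaired`),
#'   `bin`.
#' @export
pair_systems <- function(genes, bins) {
  asn <- if (inherits(bins, "bin_assignment")) bins$assignments else bins
  stopifnot("operon" %in% names(genes))
  genes$bin <- asn$bin[match(genes$contig_id, asn$contig_id)]
  seprs <- genes[genes$family == "SepRS", , drop = FALSE]
  sepcyss <- genes[genes$family == "SepCysS", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(seprs))) {
    s <- seprs[i, ]
    in_operon <- sepcyss$ID[!is.na(sepcyss$operon) & sepcyss$operon == s$operon]
    in_contig <- sepcyss$ID[sepcyss$contig_id == s$contig_id]
    in_bin <- if (is.na(s$bin)) character(0)
      else sepcyss$ID[!is.na(sepcyss$bin) & sepcyss$bin == s$bin]
    if (length(in_operon) > 0L) {
      partners <- in_operon; ev <- "operon"
    } else if (length(in_contig) > 0L) {
      partners <- in_contig; ev <- "contig"
    } else if (length(in_bin) > 0L) {
      partners <- in_bin; ev <- "bin"
    } else {
      partners <- character(0); ev <- "unpaired"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = s$ID, family = "SepRS",
      partners = paste(sort(partners), collapse = ","),
      evidence = ev, bin = s$bin, stringsAsFactors = FALSE)
  }
  ## SepCysS genes with no SepRS in their bin are reported unpaired too
  for (i in seq_len(nrow(sepcyss))) {
    cs <- sepcyss[i, ]
    has_seprs <- !is.na(cs$bin) && any(!is.na(seprs$bin) & seprs$bin == cs$bin)
    if (!has_seprs)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = cs$ID, family = "SepCysS", partners = "",
        evidence = "unpaired", bin = cs$bin, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(), family = character(),
                      partners = character(), evidence = character(),
                      bin = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
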