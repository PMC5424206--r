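#' Read a FASTA file into a sequence table
#'
#' Parses protein or nucleotide FASTA into a data frame with one row per
#' record.  Wrapped lines are joined, case is normalized to upper, and the
#' residues are validated against the amino-acid (20 + X) or nucleotide
#' (ACGTN) alphabet.  Ambiguity codes beyond X/N are an error, as are
#' duplicate ids and empty sequences.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"auto"` (default), `"protein"` or `"nucleotide"`.
#'   With `"auto"` a record is nucleotide if all residues are in ACGTN.
#' @return data frame with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path, alphabet = c("auto", "protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  res <- toupper(as.character(set))
  if (any(id == "")) stop("FASTA record with empty id", call. = FALSE)
  if (anyDuplicated(id))
    stop(sprintf("duplicate FASTA ids: %s",
                 paste(unique(id[duplicated(id)]), collapse = ", ")), call. = FALSE)
  empty <- nchar(res) == 0L
  if (any(empty))
    stop(sprintf("empty sequence for record '%s'", id[which(empty)[1]]), call. = FALSE)
  for (i in seq_along(res)) {
    ab <- switch(alphabet,
      protein = AA_ALPHABET,
      nucleotide = NT_ALPHABET,
      auto = if (all(seq_chars(res[i]) %in% NT_ALPHABET)) NT_ALPHABET else AA_ALPHABET)
    check_alphabet(res[i], ab, id[i])
  }
  data.frame(id = id, description = desc, residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences, or a data frame with
#'   columns `id`, `residues` (and optionally `description`).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    desc <- if ("description" %in% names(seqs)) seqs$description else rep("", nrow(seqs))
    res <- seqs$residues
  } else {
    v <- as_seq_vec(seqs)
    ids <- names(v); desc <- rep("", length(v)); res <- unname(v)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    hdr <- if (nzchar(desc[i])) paste(ids[i], desc[i]) else ids[i]
    writeLines(paste0(">", hdr), con)
    s <- res[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Thin wrapper over [rtracklayer::import.gff3()] that flattens the result
#' into a feature table with 1-based inclusive coordinates and an attribute
#' list column.  Strands other than `+`/`-` and start > end are errors.
#'
#' @param path path to a GFF3 file with a `##gff-version` header.
#' @return data frame with columns `contig_id`, `source`, `feature_type`,
#'   `start`, `end`, `strand`, and `attributes` (named list column); the
#'   conventional attribute keys `ID`, `family`, `clade_truth`,
#'   `protein_id` are additionally exposed as plain columns when present.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!grepl("^##gff-version", first))
    stop("not a GFF3 file (missing ##gff-version header)", call. = FALSE)
  ## validate strand/coordinates on the raw nine columns first: rtracklayer
  ## silently remaps unknown strands to '*'
  raw <- readLines(path)
  raw <- raw[!grepl("^#", raw) & nzchar(raw)]
  if (length(raw) == 0L) {
    return(data.frame(contig_id = character(), source = character(),
                      feature_type = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  strands <- vapply(parts, `[`, "", 7L)
  if (!all(strands %in% c("+", "-")))
    stop(sprintf("unsupported strand symbol '%s'",
                 setdiff(strands, c("+", "-"))[1]), call. = FALSE)
  st <- as.integer(vapply(parts, `[`, "", 4L))
  en <- as.integer(vapply(parts, `[`, "", 5L))
  if (any(is.na(st)) || any(is.na(en)) || any(st > en) || any(st < 1L))
    stop("invalid feature coordinates (need 1 <= start <= end)", call. = FALSE)
  gr <- rtracklayer::import.gff3(path)
  md <- S4Vectors::mcols(gr)
  keys <- setdiff(colnames(md), c("source", "type", "score", "phase"))
  attrs <- lapply(seq_along(gr), function(i) {
    a <- lapply(keys, function(k) {
      v <- md[[k]][i]
      if (is(v, "List") || is.list(v)) v <- unlist(v)
      if (length(v) == 0L || all(is.na(v))) NULL else as.character(v)
    })
    names(a) <- keys
    a[!vapply(a, is.null, TRUE)]
  })
  out <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    source = as.character(md$source),
    feature_type = as.character(md$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  out$attributes <- attrs
  for (k in c("ID", "family", "clade_truth", "protein_id", "genome")) {
    out[[k]] <- vapply(attrs, function(a) {
      if (is.null(a[[k]])) NA_character_ else a[[k]]
    }, "")
  }
  out
}

#' Write a feature table to GFF3
#'
#' @param features data frame as returned by [read_gff3()] (the
#'   `attributes` list column is serialized as `key=value` pairs).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0L) {
    attr_str <- vapply(seq_len(nrow(features)), function(i) {
      a <- features$attributes[[i]]
      if (is.null(a) || length(a) == 0L) return(".")
      paste(sprintf("%s=%s", names(a), vapply(a, paste, "", collapse = ",")),
            collapse = ";")
    }, "")
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       features$contig_id, features$source,
                       features$feature_type, features$start, features$end,
                       features$strand, attr_str), con)
  }
  invisible(path)
}

#' Read a per-contig depth table
#'
#' Two-column TSV (`contig_id`, `mean_depth`); exactly one row per contig
#' and nonnegative depths are enforced.
#'
#' @param path path to the TSV.
#' @return data frame with columns `contig_id`, `mean_depth`.
#' @export
read_depth_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("contig_id", "mean_depth") %in% names(d)))
    stop("depth table needs columns contig_id, mean_depth", call. = FALSE)
  if (anyDuplicated(d$contig_id))
    stop("duplicate contig_id in depth table", call. = FALSE)
  if (any(d$mean_depth < 0)) stop("negative depth", call. = FALSE)
  d[, c("contig_id", "mean_depth")]
}

#' @rdname read_depth_table
#' @param depth data frame with columns `contig_id`, `mean_depth`.
#' @export
write_depth_table <- function(depth, path) {
  write.table(depth[, c("contig_id", "mean_depth")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a phylogenetic tree to Newick
#'
#' @param tree an [ape::phylo] tree with labeled leaves; integer bootstrap
#'   supports, if present, are carried in `node.label`.
#' @param path optional output path; if `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object", call. = FALSE)
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(tree$tip.label == ""))
    stop("all leaves must be labeled", call. = FALSE)
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @rdname write_newick
#' @param text a Newick string (alternative to `path`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
}
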