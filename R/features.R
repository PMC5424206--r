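#' Map reference residue numbers to MSA columns
#'
#' Numbers the reference row's non-gap columns consecutively from 1 so
#' rules stated in reference coordinates (e.g. "position 444", "loop
#' 144-147") can be evaluated on every member of the alignment.
#'
#' @param msa a `protein_msa` containing the reference.
#' @param reference_id id of the reference row.
#' @return object of class `reference_map`: list with the character
#'   matrix (`chars`), `reference_id` and `pos_to_col` (integer vector;
#'   `pos_to_col[p]` is the MSA column of reference residue `p`).
#' @export
map_reference <- function(msa, reference_id) {
  m <- as.matrix(msa)
  if (!reference_id %in% rownames(m))
    stop(sprintf("reference '%s' not in alignment", reference_id), call. = FALSE)
  ref <- m[reference_id, ]
  pos_to_col <- which(ref != "-")
  structure(list(chars = m, reference_id = reference_id,
                 pos_to_col = unname(pos_to_col)),
            class = "reference_map")
}

#' Default rule set for SepCysS feature calls
#'
#' Reference-anchored positions of the PLP-binding residues, the three
#' persulfide cysteines, the 144-147 loop, and the 234/235 insertion
#' point.  Coordinates follow the archaeal clade-I reference convention
#' used by the synthetic references; supply your own positions to apply
#' the rules to real reference structures.
#'
#' @param flank window half-width (reference residues on each side of
#'   the 234/235 junction) over which the indel length is measured.
#' @return a rule-set list for [evaluate_features()].
#' @export
sepcyss_rule_set <- function(flank = 8L) {
  list(plp_positions = SEPCYSS_PLP,
       persulfide_positions = SEPCYSS_PERSULFIDE,
       loop_span = SEPCYSS_LOOP,
       indel_site = list(left = SEPCYSS_INDEL_LEFT,
                         right = SEPCYSS_INDEL_RIGHT, flank = flank))
}

#' Default rule set for SepRS feature calls
#'
#' The residue-444 class rule (hydrophobic Ile in archaeal-type SepRS,
#' hydrophilic Asp in bacterial-type).
#' @return a rule-set list for [evaluate_features()].
#' @export
seprs_rule_set <- function() {
  list(pos444 = SEPRS_POS444,
       hydrophilic = HYDROPHILIC_SET, hydrophobic = HYDROPHOBIC_SET)
}

#' Evaluate reference-anchored feature rules on every alignment member
#'
#' Applies whichever rules the rule set carries:
#' * `plp_conserved` -- member matches the reference residue at every
#'   PLP-binding position;
#' * `persulfide_cys_count` -- number of the listed positions where the
#'   member has Cys;
#' * `loop_144_147` -- `"absent"` iff all columns spanned by the loop
#'   are gaps in the member;
#' * `indel_234_235` -- member length minus reference length over the
#'   window of `flank` reference residues on each side of the junction
#'   (plus any columns inserted between them): negative = deletion,
#'   positive = insertion, 0 = reference-like;
#' * `res444_class` -- `hydrophobic` / `hydrophilic` / `other` by
#'   residue-set membership; `deleted` when the member has a gap there.
#'
#' @param rmap a [map_reference()] result.
#' @param rule_set e.g. [sepcyss_rule_set()] or [seprs_rule_set()].
#' @return data frame with one row per alignment member (reference
#'   included) and one column per evaluated rule.
#' @export
evaluate_features <- function(rmap, rule_set) {
  m <- rmap$chars
  p2c <- rmap$pos_to_col
  npos <- length(p2c)
  check_pos <- function(p) {
    if (any(p < 1L | p > npos))
      stop("rule position outside reference length", call. = FALSE)
    p
  }
  ids <- rownames(m)
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  ref_row <- m[rmap$reference_id, ]

  if (!is.null(rule_set$plp_positions)) {
    cols <- p2c[check_pos(rule_set$plp_positions)]
    out$plp_conserved <- apply(m[, cols, drop = FALSE], 1,
                               function(x) all(x == ref_row[cols]))
  }
  if (!is.null(rule_set$persulfide_positions)) {
    cols <- p2c[check_pos(rule_set$persulfide_positions)]
    out$persulfide_cys_count <-
      as.integer(rowSums(m[, cols, drop = FALSE] == "C"))
  }
  if (!is.null(rule_set$loop_span)) {
    span <- check_pos(rule_set$loop_span)
    cols <- p2c[span[1]]:p2c[span[2]]
    out$loop_144_147 <- ifelse(
      rowSums(m[, cols, drop = FALSE] != "-") == 0L, "absent", "present")
  }
  if (!is.null(rule_set$indel_site)) {
    is_ <- rule_set$indel_site
    flank <- is_$flank %||% 8L
    wl <- check_pos(max(is_$left - flank + 1L, 1L))
    wr <- check_pos(min(is_$right + flank - 1L, npos))
    cols <- p2c[wl]:p2c[wr]
    ref_len <- sum(ref_row[cols] != "-")
    out$indel_234_235 <-
      as.integer(rowSums(m[, cols, drop = FALSE] != "-") - ref_len)
  }
  if (!is.null(rule_set$pos444)) {
    col <- p2c[check_pos(rule_set$pos444)]
    hphil <- rule_set$hydrophilic %||% HYDROPHILIC_SET
    hphob <- rule_set$hydrophobic %||% HYDROPHOBIC_SET
    res <- m[, col]
    out$res444_class <- ifelse(res == "-", "deleted",
                        ifelse(res %in% hphob, "hydrophobic",
                        ifelse(res %in% hphil, "hydrophilic", "other")))
  }
  rownames(out) <- NULL
  out
}

#' Domain model for SepRS truncation calls
#'
#' @param reference full-length SepRS reference sequence.
#' @param catalytic,cterm 1-based inclusive reference spans of the
#'   catalytic and C-terminal anticodon-binding regions.
#' @return a domain-model list for [detect_seprs_truncation()].
#' @export
seprs_domain_model <- function(reference, catalytic = SEPRS_CATALYTIC,
                               cterm = SEPRS_CTERM) {
  list(reference = reference, catalytic = catalytic, cterm = cterm)
}

#' Detect C-terminally truncated SepRS (SepRS-deltaC)
#'
#' A protein is `delta_C` when its local alignment to the reference
#' covers less than half of the C-terminal anticodon-binding span while
#' covering at least 60% of the catalytic span; `full` when both spans
#' are covered.  Anything matching neither gate is `none` (no-call)
#' with a warning.
#'
#' @param protein protein sequence.
#' @param domain_model a [seprs_domain_model()].
#' @param scheme a [scoring_scheme()].
#' @return `"full"`, `"delta_C"` or `"none"`.
#' @export
detect_seprs_truncation <- function(protein, domain_model,
                                    scheme = scoring_scheme()) {
  aln <- local_align(protein, domain_model$reference, scheme)
  span_cov <- function(span) {
    if (aln$score <= 0) return(0)
    lo <- max(aln$subject_start, span[1])
    hi <- min(aln$subject_end, span[2])
    max(hi - lo + 1L, 0L) / (span[2] - span[1] + 1L)
  }
  cat_cov <- span_cov(domain_model$catalytic)
  ct_cov <- span_cov(domain_model$cterm)
  if (cat_cov >= 0.6 && ct_cov < 0.5) return("delta_C")
  if (cat_cov >= 0.6 && ct_cov >= 0.5) return("full")
  warning("protein matches neither SepRS domain gate; no call")
  "none"
}

#' Classify a SepCysE homolog
#'
#' Distinguishes the full-length scaffold (`full`), the stand-alone
#' N-terminal-domain gene preceding SepCysS (`split_n`, "SepCysSn"),
#' and the N-domain fused to SepCysS (`fused_N`, "SepCysSN"), using
#' span-coverage gates against an N-domain model and a SepCysS core
#' model.
#'
#' @param protein protein sequence.
#' @param n_domain_model SepCysE N-terminal-domain reference sequence.
#' @param sepcyss_model SepCysS core reference sequence.
#' @param precedes_sepcyss TRUE when the gene immediately precedes a
#'   SepCysS gene in the same operon (required for `split_n`).
#' @param min_similarity similarity gate for a domain match (default 40).
#' @param min_coverage model-coverage gate for a domain match (default 0.6).
#' @param fused_window the N-domain match must end within this many
#'   N-terminal residues for `fused_N` (default 120).
#' @param split_max_len maximal length of a split-gene product (default 150).
#' @param scheme a [scoring_scheme()].
#' @return `"full"`, `"split_n"`, `"fused_N"` or `"none"`.
#' @export
classify_sepcysE_homolog <- function(protein, n_domain_model, sepcyss_model,
                                     precedes_sepcyss = FALSE,
                                     min_similarity = 40, min_coverage = 0.6,
                                     fused_window = 120L, split_max_len = 150L,
                                     scheme = scoring_scheme()) {
  n_aln <- local_align(protein, n_domain_model, scheme)
  n_match <- n_aln$score > 0 &&
    n_aln$percent_similarity >= min_similarity &&
    (n_aln$subject_end - n_aln$subject_start + 1L) / nchar(n_domain_model) >=
      min_coverage
  c_aln <- local_align(protein, sepcyss_model, scheme)
  c_match <- c_aln$score > 0 &&
    c_aln$percent_similarity >= min_similarity &&
    (c_aln$subject_end - c_aln$subject_start + 1L) / nchar(sepcyss_model) >= 0.5
  if (n_match && c_match && n_aln$query_end <= fused_window &&
      c_aln$query_start > n_aln$query_start)
    return("fused_N")
  if (n_match && !c_match && nchar(protein) >= 2L * nchar(n_domain_model))
    return("full")
  if (n_match && !c_match && nchar(protein) < split_max_len && precedes_sepcyss)
    return("split_n")
  "none"
}

#' Type a tRNA by anticodon and the N37 base
#'
#' Reads the anticodon from the annotated position and reports the base
#' immediately 3' of it (position 37); the isotype guess is `Cys` iff
#' the anticodon is GCA.  Missing annotation, or an anticodon at the
#' very end of the sequence, yields a no-call.
#'
#' @param trna_seq tRNA gene sequence.
#' @param annotation list or one-row data frame with `anticodon_start`.
#' @return list with `anticodon`, `n37`, `isotype`, `ok` (FALSE for a
#'   no-call).
#' @export
classify_trna <- function(trna_seq, annotation) {
  st <- annotation$anticodon_start
  if (is.null(st) || length(st) != 1L || is.na(st)) {
    warning("missing anticodon annotation; no call")
    return(list(anticodon = NA_character_, n37 = NA_character_,
                isotype = NA_character_, ok = FALSE))
  }
  st <- as.integer(st)
  if (st < 1L || st + 3L > nchar(trna_seq)) {
    warning("anticodon at sequence end; no call")
    return(list(anticodon = NA_character_, n37 = NA_character_,
                isotype = NA_character_, ok = FALSE))
  }
  ac <- toupper(substr(trna_seq, st, st + 2L))
  n37 <- toupper(substr(trna_seq, st + 3L, st + 3L))
  list(anticodon = ac, n37 = n37,
       isotype = if (ac == "GCA") "Cys" else "other", ok = TRUE)
}
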