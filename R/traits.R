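PYL_ACCESSORY_FAMILIES <- c("pylT", "pylB", "pylC", "pylD",
                            "mtmB", "mtbB", "mttB")
SEC_FAMILIES <- c("SPS", "HdrA", "VhuD", "VhuU")

#' Detect the Pyl-encoding architecture of a bin
#'
#' Architecture follows which PylRS gene forms are present: a fused
#' full-length PylS (`single_pylS`), separate PylSn + PylSc
#' (`split_pylSn_pylSc`), PylSc alone (`pylSc_only`), or `none`.
#' Contradictory labels (fused PylS alongside split parts) are reported
#' with a warning.  The cluster flag is set when a PylRS gene shares an
#' operon with at least two accessory genes
#' (pylT/pylB/pylC/pylD/mtxB methyltransferases).
#'
#' @param bin_genes gene table for one bin with columns `family` and
#'   (optionally, for the cluster flag) `operon`.
#' @return list with `architecture`, `accessories` (character vector)
#'   and `cluster` (logical).
#' @export
detect_pyl <- function(bin_genes) {
  fam <- bin_genes$family
  has_fused <- "PylS" %in% fam
  has_n <- "PylSn" %in% fam
  has_c <- "PylSc" %in% fam
  if (has_fused && (has_n || has_c))
    warning("both fused PylS and split pylS parts present")
  arch <- if (has_fused) "single_pylS"
    else if (has_n && has_c) "split_pylSn_pylSc"
    else if (has_c) "pylSc_only"
    else "none"
  acc <- intersect(PYL_ACCESSORY_FAMILIES, fam)
  cluster <- FALSE
  if (arch != "none" && "operon" %in% names(bin_genes)) {
    pyl_ops <- bin_genes$operon[fam %in% c("PylS", "PylSn", "PylSc")]
    for (op in unique(pyl_ops[!is.na(pyl_ops)])) {
      n_acc <- sum(fam %in% PYL_ACCESSORY_FAMILIES &
                     !is.na(bin_genes$operon) & bin_genes$operon == op)
      if (n_acc >= 2L) cluster <- TRUE
    }
  }
  list(architecture = arch, accessories = acc, cluster = cluster)
}

#' Detect the Sec-utilization trait of a bin
#'
#' Reports which of the four selenoprotein families (SPS, HdrA, VhuD,
#' VhuU) have homologs in the bin (detection is homology-level only).
#' `sps_split` is TRUE iff two sub-full-length SPS fragments jointly
#' cover at least 80% of the SPS reference with each fragment covering
#' less than 60%.
#'
#' @param bin_genes gene table for one bin with columns `family` and
#'   `protein_id`.
#' @param proteins named character vector of protein sequences
#'   (needed for the split-SPS call).
#' @param sps_reference full-length SPS reference sequence.
#' @param scheme a [scoring_scheme()].
#' @return list with `sec_families` (character vector) and `sps_split`.
#' @export
detect_sec <- function(bin_genes, proteins = NULL, sps_reference = NULL,
                       scheme = scoring_scheme()) {
  fam <- bin_genes$family
  fams <- intersect(SEC_FAMILIES, fam)
  sps_split <- FALSE
  sps_ids <- bin_genes$protein_id[fam == "SPS"]
  sps_ids <- sps_ids[!is.na(sps_ids)]
  if (length(sps_ids) >= 2L && !is.null(proteins) && !is.null(sps_reference)) {
    refl <- nchar(sps_reference)
    spans <- lapply(sps_ids, function(pid) {
      aln <- local_align(proteins[[pid]], sps_reference, scheme)
      if (aln$score <= 0) return(NULL)
      c(aln$subject_start, aln$subject_end)
    })
    spans <- spans[!vapply(spans, is.null, TRUE)]
    covs <- vapply(spans, function(s) (s[2] - s[1] + 1L) / refl, 0)
    sub_full <- covs < 0.6
    if (sum(sub_full) >= 2L) {
      idx <- which(sub_full)
      for (i in idx) for (j in idx) {
        if (i >= j) next
        covered <- logical(refl)
        covered[spans[[i]][1]:spans[[i]][2]] <- TRUE
        covered[spans[[j]][1]:spans[[j]][2]] <- TRUE
        if (mean(covered) >= 0.8) sps_split <- TRUE
      }
    }
  }
  list(sec_families = fams, sps_split = sps_split)
}

## SepCysE status of a bin: full-length scaffold > fused SepCysSN >
## split SepCysSn > none
detect_sepcysE <- function(bin_genes, proteins, n_domain_model,
                           sepcyss_model, scheme = scoring_scheme()) {
  fam <- bin_genes$family
  cand <- bin_genes[fam %in% c("SepCysE", "SepCysSn", "SepCysS"), , drop = FALSE]
  status <- "none"
  for (i in seq_len(nrow(cand))) {
    pid <- cand$protein_id[i]
    if (is.na(pid) || is.null(proteins[[pid]])) next
    precedes <- FALSE
    if ("operon" %in% names(bin_genes) && !is.na(cand$operon[i])) {
      op <- bin_genes[!is.na(bin_genes$operon) &
                        bin_genes$operon == cand$operon[i], , drop = FALSE]
      precedes <- any(op$family == "SepCysS" & op$start > cand$start[i])
    }
    cls <- classify_sepcysE_homolog(proteins[[pid]], n_domain_model,
                                    sepcyss_model,
                                    precedes_sepcyss = precedes,
                                    scheme = scheme)
    if (cls == "full") return("full")
    if (cls == "fused_N" && status != "full") status <- "fused_N"
    if (cls == "split_n" && status == "none") status <- "split_n"
  }
  status
}

#' Per-bin trait profiles
#'
#' Builds one trait row per bin: SepRS/SepCysS presence, SepCysE status
#' (full / split_n / fused_N / none), Pyl architecture and accessories,
#' and the Sec trait (selenoprotein families, split SPS).
#'
#' @param genes gene table with `ID`, `contig_id`, `family`,
#'   `protein_id`, `start` and an `operon` column from [call_operons()].
#' @param bins a `bin_assignment` (or its `assignments` data frame).
#' @param proteins named character vector of protein sequences (enables
#'   the sequence-level SepCysE and split-SPS calls).
#' @param refs optional list with elements `sepcysE_n`, `sepcyss`,
#'   `sps`: reference sequences for the domain models.
#' @param uncertain_bins bins flagged low-confidence by binning; their
#'   rows carry `uncertain = TRUE`.
#' @param scheme a [scoring_scheme()].
#' @return data frame with one row per bin.
#' @export
trait_profiles <- function(genes, bins, proteins = NULL, refs = NULL,
                           uncertain_bins = integer(),
                           scheme = scoring_scheme()) {
  asn <- if (inherits(bins, "bin_assignment")) bins$assignments else bins
  genes$bin <- asn$bin[match(genes$contig_id, asn$contig_id)]
  rows <- lapply(sort(unique(asn$bin)), function(b) {
    bg <- genes[!is.na(genes$bin) & genes$bin == b, , drop = FALSE]
    pyl <- detect_pyl(bg)
    sec <- detect_sec(bg, proteins, refs$sps, scheme)
    sepcysE <- if (!is.null(proteins) && !is.null(refs$sepcysE_n) &&
                   !is.null(refs$sepcyss))
      detect_sepcysE(bg, proteins, refs$sepcysE_n, refs$sepcyss, scheme)
    else if ("SepCysE" %in% bg$family) "full"
    else if ("SepCysSn" %in% bg$family) "split_n"
    else "none"
    data.frame(
      bin = b,
      has_seprs = "SepRS" %in% bg$family,
      has_sepcyss = "SepCysS" %in% bg$family,
      sepcysE_status = sepcysE,
      pyl_architecture = pyl$architecture,
      pyl_accessories = paste(pyl$accessories, collapse = ","),
      pyl_cluster = pyl$cluster,
      sec_families = paste(sec$sec_families, collapse = ","),
      n_sec_families = length(sec$sec_families),
      sps_split = sec$sps_split,
      uncertain = b %in% uncertain_bins,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-tabulate traits over bins
#'
#' @param profiles data frame from [trait_profiles()] (>= 1 row).
#' @return object of class `cooccurrence_table`: list with `profiles`
#'   and `summary` (named tally data frame: bins with SepRS & Pyl,
#'   SepRS & Sec, full SepCysE & Sec, SepRS & SepCysS).
#' @export
build_cooccurrence <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0L)
    stop("empty profile list", call. = FALSE)
  has_pyl <- profiles$pyl_architecture != "none"
  has_sec <- profiles$n_sec_families > 0L
  summary <- data.frame(
    n_bins = nrow(profiles),
    seprs_and_pyl = sum(profiles$has_seprs & has_pyl),
    seprs_and_sec = sum(profiles$has_seprs & has_sec),
    sepcysE_full_and_sec = sum(profiles$sepcysE_status == "full" & has_sec),
    seprs_and_sepcyss = sum(profiles$has_seprs & profiles$has_sepcyss))
  structure(list(profiles = profiles, summary = summary),
            class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("cooccurrence_table over %d bins: SepRS&Pyl %d, ",
                     "SepRS&Sec %d, SepCysE(full)&Sec %d, SepRS&SepCysS %d\n"),
              s$n_bins, s$seprs_and_pyl, s$seprs_and_sec,
              s$sepcysE_full_and_sec, s$seprs_and_sepcyss))
  invisible(x)
}
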