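## Reference coordinates used by the synthetic families.  The SepCysS
## numbering follows the archaeal clade-I reference convention (loop
## 144-147, insertion point between 234 and 235, PLP and persulfide
## sites); SepRS numbering puts Ile444 inside the C-terminal
## anticodon-binding domain.  Positions are nominal: the synthetic
## references adopt them so the rule engine reads naturally.
SEPRS_LEN <- 460L
SEPRS_CATALYTIC <- c(1L, 380L)
SEPRS_CTERM <- c(381L, 460L)
SEPRS_POS444 <- 444L
SEPCYSS_LEN <- 390L
SEPCYSS_LOOP <- c(144L, 147L)
SEPCYSS_INDEL_LEFT <- 234L
SEPCYSS_INDEL_RIGHT <- 235L
SEPCYSS_PERSULFIDE <- c(65L, 240L, 258L)
SEPCYSS_PLP <- c(98L, 172L, 209L)
SEPCYSE_N_LEN <- 100L

## Divergence defaults.  The only quantitative anchor for family
## divergence is the ~40% similarity retention threshold of the search;
## defaults are calibrated once so that within-clade similarity is ~75-85%
## and cross-clade similarity straddles 40% while staying below the 50%
## clade-partition threshold.
D_WITHIN <- 0.14
D_BETWEEN <- 0.45
D_ORPHAN <- 0.55

seprs_feature_plan <- function(variant = c("archaeal", "bacterial")) {
  variant <- match.arg(variant)
  list(list(pos = SEPRS_POS444,
            residue = if (variant == "archaeal") "I" else "D"))
}

sepcyss_root_features <- function() {
  ## conserved structural anchors flanking the 144-147 loop and the
  ## 234/235 indel junction keep both events unambiguous in alignments
  anchors <- Map(function(p, r) list(pos = p, residue = r),
                 c(140L, 141L, 142L, 143L, 148L, 149L, 150L, 151L,
                   225L, 226L, 243L, 244L),
                 c("W", "P", "G", "F", "E", "K", "Y", "G",
                   "W", "D", "K", "W"))
  c(lapply(SEPCYSS_PERSULFIDE, function(p) list(pos = p, residue = "C")),
    list(list(pos = SEPCYSS_PLP[1], residue = "H"),
         list(pos = SEPCYSS_PLP[2], residue = "N"),
         list(pos = SEPCYSS_PLP[3], residue = "K")),
    anchors)
}

#' Clade-structured family preset: SepRS
#'
#' Three major clades (two archaeal with Ile at position 444, one
#' bacterial with hydrophilic Asp at 444) plus two orphan lineages,
#' mirroring the published classification of SepRS into three clades and
#' a few orphans.
#' @return a [family_model()].
#' @export
preset_seprs_paper <- function() {
  family_model(
    "SepRS", SEPRS_LEN, clade_sizes = c(10L, 9L, 9L),
    d_within = D_WITHIN, d_between = D_BETWEEN,
    clade_labels = c("I", "II", "III"),
    clade_plans = list(
      list(features = seprs_feature_plan("archaeal")),
      list(features = seprs_feature_plan("archaeal")),
      list(features = seprs_feature_plan("bacterial"))),
    orphans = 2L, d_orphan = D_ORPHAN,
    root_features = seprs_feature_plan("archaeal"))
}

#' Clade-structured family preset: SepCysS
#'
#' Seven clades.  Clade I is reference-like at the 234/235 junction;
#' clades II-VII carry the 8-residue insertion there.  PLP-binding
#' residues and the three persulfide cysteines are conserved throughout
#' (exceptional lineages lacking them are planted per-genome by the
#' metagenome generator, not by this preset).
#' @return a [family_model()].
#' @export
preset_sepcyss_paper <- function() {
  ins8 <- list(list(type = "insert", after = SEPCYSS_INDEL_LEFT, len = 8L))
  plans <- c(list(list(features = NULL)),
             rep(list(list(indels = ins8)), 6))
  ## a larger between-clade distance than SepRS: seven clades put many
  ## more lineage pairs under the 50% partition threshold, and no
  ## 40%-retention chaining constraint applies to this family
  family_model(
    "SepCysS", SEPCYSS_LEN, clade_sizes = c(7L, 6L, 6L, 6L, 6L, 5L, 4L),
    d_within = 0.10, d_between = 0.68, sim_band = c(33, 42),
    clade_labels = c("I", "II", "III", "IV", "V", "VI", "VII"),
    clade_plans = plans,
    root_features = sepcyss_root_features())
}

#' Clade-structured family preset: PylRS
#'
#' Three reference-labeled clades (fused single-gene, bacterial split,
#' and PylSc-only lineages) plus two unlabeled novel lineages that fall
#' outside all reference clades.
#' @return a [family_model()].
#' @export
preset_pylrs_paper <- function() {
  family_model(
    "PylS", 310L, clade_sizes = c(5L, 5L, 5L),
    d_within = D_WITHIN, d_between = D_BETWEEN,
    clade_labels = c("Methanosarcinaceae", "Bacteria", "Methanomassiliicoccales"),
    novel_sizes = c(3L, 3L), d_orphan = D_ORPHAN)
}

#' Realize the default family models
#'
#' Realizes the three clade-structured presets (SepRS, SepCysS, PylRS)
#' and the roots of the accessory families (SepCysE domains,
#' selenoprotein families, Pyl cluster genes, marker genes) used by the
#' metagenome generator.
#'
#' @param seed integer seed; the result is deterministic given it.
#' @return named list of class `family_models` with elements `SepRS`,
#'   `SepCysS`, `PylS` ([realize_family()] sets) and `aux`, a named list
#'   of accessory root sequences with their lengths.
#' @export
make_family_models <- function(seed = 1L) {
  fam <- list(SepRS = realize_family(preset_seprs_paper(), seed),
              SepCysS = realize_family(preset_sepcyss_paper(), seed + 1L),
              PylS = realize_family(preset_pylrs_paper(), seed + 2L))
  aux_lens <- c(SepCysE_N = SEPCYSE_N_LEN, SepCysE_C = 200L, PylSn = 120L,
                SPS = 320L, HdrA = 280L, VhuD = 90L, VhuU = 60L,
                pylB = 250L, pylC = 230L, pylD = 210L,
                mtmB = 220L, mtbB = 220L, mttB = 220L, marker = 180L)
  fam$aux <- with_seed(seed + 3L, {
    lapply(aux_lens, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""))
  })
  class(fam) <- "family_models"
  fam
}

## translate a reference-coordinate feature plan into the coordinate
## frame of a clade seed that already carries `indels`
shift_features <- function(features, indels) {
  if (is.null(indels) || length(indels) == 0L || is.null(features)) return(features)
  out <- list()
  for (f in features) {
    off <- 0L; drop <- FALSE
    for (p in indels) {
      if (p$type == "delete") {
        if (f$pos >= p$at && f$pos <= p$at + p$len - 1L) { drop <- TRUE; break }
        if (f$pos > p$at + p$len - 1L) off <- off - p$len
      } else if (f$pos > p$after) off <- off + p$len
    }
    if (!drop) { f$pos <- f$pos + off; out[[length(out) + 1L]] <- f }
  }
  out
}

#' Default genome presets for the synthetic metagenome
#'
#' Eight genomes with staggered GC (0.32-0.67) and read depth
#' (10-1280x), planting the gene-system architectures the pipeline must
#' recover: a compact tRNA-Cys/SepCysSn/SepCysS/SepRS operon, bin-level
#' pairing with two SepCysS copies, a truncated SepRS-deltaC with a
#' persulfide-free SepCysS, bacterial-type features (Asp444, missing
#' 144-147 loop, 8-residue deletion), full/split/fused SepCysE, the
#' three Pyl architectures, the four-selenoprotein Sec trait (once with
#' a split SPS), and an unpaired SepRS.
#'
#' @return list of genome preset lists.
#' @export
genome_presets_paper_default <- function() {
  gp <- function(taxon, gc, depth, seprs = NULL, sepcyss = NULL,
                 sepcysE_mode = "none", pairing_layout = "operon",
                 pyl = "none", pyl_accessories = character(),
                 sec = FALSE, sps_split = FALSE, trna_n37 = "G",
                 extra_trna_n37 = NULL, n_contigs = 12L,
                 contig_len_min = 4000L, contig_len_mean = 9000L,
                 contig_len_max = NULL) {
    list(taxon = taxon, gc = gc, depth = depth, seprs = seprs,
         sepcyss = sepcyss, sepcysE_mode = sepcysE_mode,
         pairing_layout = pairing_layout, pyl = pyl,
         pyl_accessories = pyl_accessories, sec = sec,
         sps_split = sps_split, trna_n37 = trna_n37,
         extra_trna_n37 = extra_trna_n37, n_contigs = n_contigs,
         contig_len_min = contig_len_min,
         contig_len_mean = contig_len_mean,
         contig_len_max = contig_len_max)
  }
  list(
    gp("hadesarchaeote_1", 0.32, 10,
       seprs = list(clade = "II", truncated = FALSE, variant = "archaeal"),
       sepcyss = list(clade = "VII", copies = 1L, variant = "archaeal"),
       sepcysE_mode = "fused_N", pairing_layout = "operon"),
    gp("parcubacterium_CG", 0.37, 20,
       seprs = list(clade = "III", truncated = TRUE, variant = "bacterial"),
       sepcyss = list(clade = "I", copies = 1L, variant = "no_persulfide"),
       pairing_layout = "contig", trna_n37 = "A", extra_trna_n37 = "G"),
    gp("asgard_BOG_1", 0.42, 40,
       seprs = list(clade = "II", truncated = FALSE, variant = "archaeal"),
       sepcyss = list(clade = "II", copies = 2L, variant = "archaeal"),
       sepcysE_mode = "full", pairing_layout = "bin",
       sec = TRUE, sps_split = TRUE),
    gp("bathyarchaeote_BA2", 0.47, 80,
       seprs = list(clade = "II", truncated = FALSE, variant = "archaeal"),
       sepcyss = list(clade = "VII", copies = 1L, variant = "archaeal"),
       sepcysE_mode = "split_n", pairing_layout = "operon",
       pyl = "pylSc_only", pyl_accessories = c("pylT", "mtbB")),
    gp("euryarchaeote_methanogen_1", 0.52, 160,
       seprs = list(clade = "I", truncated = FALSE, variant = "archaeal"),
       sepcyss = list(clade = "I", copies = 1L, variant = "archaeal"),
       sepcysE_mode = "full", pairing_layout = "operon",
       pyl = "single_pylS",
       pyl_accessories = c("pylT", "pylB", "pylC", "pylD", "mtmB"),
       sec = TRUE),
    gp("chloroflexi_dehalo_1", 0.57, 320,
       seprs = list(clade = "III", truncated = FALSE, variant = "bacterial"),
       sepcyss = list(clade = "I", copies = 1L, variant = "bacterial"),
       pairing_layout = "operon", pyl = "split_pylSn_pylSc",
       pyl_accessories = c("pylT", "pylB", "pylC", "pylD", "mttB"),
       trna_n37 = "A"),
    gp("methermicoccus_like", 0.62, 640,
       seprs = list(clade = "I", truncated = FALSE, variant = "archaeal"),
       sepcyss = list(clade = "I", copies = 1L, variant = "archaeal"),
       pairing_layout = "operon", pyl = "pylSc_only",
       pyl_accessories = c("pylT", "mtmB", "mtbB", "mttB")),
    gp("crenarchaeote_pJP", 0.67, 1280,
       seprs = list(clade = "I", truncated = FALSE, variant = "archaeal"),
       sepcyss = NULL, pairing_layout = "unpaired"))
}

#' @export
print.family_models <- function(x, ...) {
  cat("family_models:\n")
  for (nm in c("SepRS", "SepCysS", "PylS"))
    cat(sprintf("  %s: %d sequences\n", nm, nrow(x[[nm]]$members)))
  cat(sprintf("  aux roots: %s\n", paste(names(x$aux), collapse = ", ")))
  invisible(x)
}
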