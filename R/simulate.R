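## --- nucleotide-level helpers -------------------------------------------

## i.i.d. nucleotides at a given GC fraction
random_nt <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

## codon table indexed by amino acid, with per-codon GC counts
.codon_env <- new.env(parent = emptyenv())
codon_table <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  keep <- gc != "*"
  tab <- split(codons[keep], gc[keep])
  ngc <- lapply(tab, function(cs)
    vapply(strsplit(cs, ""), function(x) sum(x %in% c("G", "C")), 0L))
  .codon_env$tab <- list(codons = tab, ngc = ngc)
  .codon_env$tab
}

#' Back-translate a protein with GC-biased codon choice
#'
#' Synonymous codons are drawn with weight proportional to
#' `gc^nGC * (1-gc)^(3-nGC)`; a TAA stop codon is appended.
#'
#' @param prot protein sequence (no `X`).
#' @param gc genome GC target in (0, 1).
#' @return nucleotide coding sequence (string).
#' @export
back_translate <- function(prot, gc) {
  tab <- codon_table()
  aas <- seq_chars(prot)
  if (any(!aas %in% AA20))
    stop("cannot back-translate residues outside the 20-letter alphabet",
         call. = FALSE)
  cs <- vapply(aas, function(a) {
    codons <- tab$codons[[a]]
    w <- gc^tab$ngc[[a]] * (1 - gc)^(3 - tab$ngc[[a]])
    if (length(codons) == 1L) codons else sample(codons, 1L, prob = w)
  }, "")
  paste0(paste(cs, collapse = ""), "TAA")
}

## 75-nt tRNA gene with a fixed anticodon at positions 34-36 and a chosen
## base at position 37
make_trna_seq <- function(gc, anticodon = "GCA", n37 = "G") {
  x <- random_nt(75L, gc)
  x[34:36] <- seq_chars(anticodon)
  x[37] <- n37
  paste(x, collapse = "")
}

## --- per-genome gene realization ----------------------------------------

draw_seprs <- function(entry, models) {
  labels <- models$SepRS$model$clade_labels
  seed <- models$SepRS$clade_seeds[match(entry$clade, labels)]
  indels <- NULL
  if (isTRUE(entry$truncated))
    indels <- list(list(type = "delete", at = SEPRS_CTERM[1],
                        len = SEPRS_CTERM[2] - SEPRS_CTERM[1] + 1L))
  prot <- evolve_sequence(seed, D_WITHIN, indel_plan = indels,
                          feature_plan = seprs_feature_plan(entry$variant))
  list(prot = prot,
       truth = list(
         family = "SepRS", clade = entry$clade,
         res444_class = if (isTRUE(entry$truncated)) "deleted"
                        else if (entry$variant == "archaeal") "hydrophobic"
                        else "hydrophilic",
         seprs_truncation = if (isTRUE(entry$truncated)) "delta_C" else "full"))
}

draw_sepcyss <- function(entry, models) {
  labels <- models$SepCysS$model$clade_labels
  idx <- match(entry$clade, labels)
  seed <- models$SepCysS$clade_seeds[idx]
  clade_indels <- models$SepCysS$model$clade_plans[[idx]]$indels
  feats <- sepcyss_root_features()
  extra <- NULL
  if (entry$variant == "bacterial") {
    if (entry$clade != "I")
      stop("bacterial SepCysS variant is modeled within clade I", call. = FALSE)
    extra <- list(list(type = "delete", at = 227L, len = 8L),
                  list(type = "delete", at = SEPCYSS_LOOP[1],
                       len = SEPCYSS_LOOP[2] - SEPCYSS_LOOP[1] + 1L))
  } else if (entry$variant == "no_persulfide") {
    feats <- c(lapply(SEPCYSS_PERSULFIDE, function(p)
                 list(pos = p, forbid = "C", residue = "S")),
               feats[-seq_along(SEPCYSS_PERSULFIDE)])
    ## also actively replace any Cys that survives at those sites
    feats[seq_along(SEPCYSS_PERSULFIDE)] <-
      lapply(SEPCYSS_PERSULFIDE, function(p) list(pos = p, residue = "S"))
  }
  prot <- evolve_sequence(seed, D_WITHIN, indel_plan = extra,
                          feature_plan = shift_features(feats, clade_indels))
  list(prot = prot,
       truth = list(
         family = "SepCysS", clade = entry$clade,
         indel_234_235 = if (entry$clade == "I") {
           if (entry$variant == "bacterial") -8L else 0L
         } else 8L,
         loop_144_147 = if (entry$variant == "bacterial") "absent" else "present",
         persulfide_cys_count = if (entry$variant == "no_persulfide") 0L else 3L,
         plp_conserved = TRUE))
}

## --- the generator -------------------------------------------------------

#' Generate a synthetic metagenome with planted gene systems
#'
#' Emits contigs, a per-contig depth table, gene annotations, protein and
#' tRNA records, and machine-readable ground truth for every planted
#' gene, pairing, feature and trait.  Intergenic composition is
#' compensated per contig so contig GC matches the genome's target in
#' expectation despite the constrained GC of back-translated genes.
#' Per-contig depth is the genome depth times lognormal noise.
#' Deterministic and byte-stable under a fixed seed.
#'
#' @param presets list of genome presets
#'   (default [genome_presets_paper_default()]).
#' @param models family models from [make_family_models()].
#' @param seed integer seed.
#' @param depth_sigma sdlog of the lognormal depth noise (default 0.1;
#'   0 gives every contig exactly its genome's depth).
#' @param intergene_gap intergenic gap (nt) between operon members.
#' @return object of class `synthetic_metagenome`: list with `contigs`
#'   (named nucleotide vector), `depth`, `genes` (feature table),
#'   `proteins`, `trnas`, `trna_annot`, and `truth` (list of data
#'   frames: `contigs`, `genes`, `pairings`, `features`, `traits`,
#'   `trnas`, `markers`).
#' @export
generate_metagenome <- function(presets = genome_presets_paper_default(),
                                models = make_family_models(1L),
                                seed = 1L, depth_sigma = 0.1,
                                intergene_gap = 25L) {
  stopifnot(length(presets) >= 1L)
  for (p in presets) {
    if (p$gc <= 0 || p$gc >= 1) stop("gc_target must be in (0,1)", call. = FALSE)
    if (p$depth <= 0) stop("depth_target must be positive", call. = FALSE)
  }
  with_seed(seed, {
    contigs <- character(0)
    depth_rows <- list(); gene_rows <- list(); prot_rows <- list()
    trna_rows <- list(); trna_annot <- list()
    t_contig <- list(); t_gene <- list(); t_pair <- list(); t_feat <- list()
    t_trait <- list(); t_trna <- list(); t_marker <- list()

    for (preset in presets) {
      gname <- preset$taxon
      gcnt <- 0L; pcnt <- 0L
      new_gene_id <- function() { gcnt <<- gcnt + 1L; sprintf("%s_g%02d", gname, gcnt) }
      new_prot_id <- function() { pcnt <<- pcnt + 1L; sprintf("%s_p%02d", gname, pcnt) }

      ## a gene element: protein-coding or tRNA
      gene_el <- function(family, clade = NA_character_, prot = NULL,
                          nt = NULL, type = "gene", truth_feat = NULL,
                          sepcysE_class = NA_character_, role = NA_character_) {
        gid <- new_gene_id()
        pid <- if (type == "gene") new_prot_id() else NA_character_
        if (type == "gene" && is.null(nt)) nt <- back_translate(prot, preset$gc)
        list(id = gid, protein_id = pid, family = family, clade = clade,
             prot = prot, nt = nt, type = type, truth_feat = truth_feat,
             sepcysE_class = sepcysE_class, role = role)
      }

      loci <- list()
      add_locus <- function(genes, colocate = NA_integer_) {
        loci[[length(loci) + 1L]] <<- list(genes = genes, colocate = colocate)
      }

      seprs_el <- NULL; sepcyss_els <- list()
      if (!is.null(preset$seprs)) {
        d <- draw_seprs(preset$seprs, models)
        seprs_el <- gene_el("SepRS", preset$seprs$clade, d$prot,
                            truth_feat = d$truth, role = "seprs")
      }
      fused <- identical(preset$sepcysE_mode, "fused_N")
      if (!is.null(preset$sepcyss)) {
        for (k in seq_len(preset$sepcyss$copies)) {
          d <- draw_sepcyss(preset$sepcyss, models)
          prot <- d$prot
          cls <- NA_character_
          if (fused && k == 1L) {
            prot <- paste0(evolve_sequence(models$aux$SepCysE_N, 0.15), prot)
            cls <- "fused_N"
          }
          sepcyss_els[[k]] <- gene_el("SepCysS", preset$sepcyss$clade, prot,
                                      truth_feat = d$truth,
                                      sepcysE_class = cls, role = "sepcyss")
        }
      }

      ## main SepRS/SepCysS locus layout
      trna_main <- NULL
      mk_trna <- function(n37, family = "tRNA-Cys", anticodon = "GCA") {
        nt <- make_trna_seq(preset$gc, anticodon, n37)
        el <- gene_el(family, prot = NULL, nt = nt, type = "tRNA")
        t_trna[[length(t_trna) + 1L]] <<- data.frame(
          trna_id = el$id, genome = gname, family = family,
          anticodon = anticodon, n37 = n37, stringsAsFactors = FALSE)
        trna_annot[[length(trna_annot) + 1L]] <<- data.frame(
          trna_id = el$id, anticodon_start = 34L, anticodon = anticodon,
          stringsAsFactors = FALSE)
        el
      }

      layout <- preset$pairing_layout
      expected_evidence <- NA_character_
      if (!is.null(seprs_el)) {
        if (layout == "operon") {
          ops <- list()
          if (identical(preset$sepcysE_mode, "split_n")) {
            trna_main <- mk_trna(preset$trna_n37)
            sn <- gene_el("SepCysSn", prot = evolve_sequence(models$aux$SepCysE_N, 0.15),
                          sepcysE_class = "split_n", role = "sepcysE_n")
            ops <- c(ops, list(trna_main, sn))
          }
          ops <- c(ops, sepcyss_els, list(seprs_el))
          add_locus(ops)
          expected_evidence <- "operon"
        } else if (layout == "contig") {
          add_locus(list(seprs_el), colocate = 1L)
          add_locus(sepcyss_els, colocate = 1L)
          expected_evidence <- "contig"
        } else if (layout == "bin") {
          add_locus(list(seprs_el))
          for (el in sepcyss_els) add_locus(list(el))
          expected_evidence <- "bin"
        } else {  # unpaired
          add_locus(list(seprs_el))
          expected_evidence <- "unpaired"
        }
        t_pair[[length(t_pair) + 1L]] <- data.frame(
          genome = gname, seprs_id = seprs_el$id,
          partner_ids = paste(vapply(sepcyss_els, `[[`, "", "id"),
                              collapse = ","),
          evidence = expected_evidence, stringsAsFactors = FALSE)
      } else if (length(sepcyss_els) > 0L) {
        for (el in sepcyss_els) add_locus(list(el))
      }

      ## stand-alone tRNA-Cys when not already in the main operon
      if (is.null(trna_main)) add_locus(list(mk_trna(preset$trna_n37)))
      if (!is.null(preset$extra_trna_n37))
        add_locus(list(mk_trna(preset$extra_trna_n37)))

      ## SepCysE gene (full-length scaffold protein)
      if (identical(preset$sepcysE_mode, "full")) {
        prot <- paste0(evolve_sequence(models$aux$SepCysE_N, 0.15),
                       evolve_sequence(models$aux$SepCysE_C, 0.15))
        add_locus(list(gene_el("SepCysE", prot = prot,
                               sepcysE_class = "full", role = "sepcysE")))
      }

      ## Pyl cluster
      pylrs_labels <- models$PylS$model$clade_labels
      pyl_seed <- function(lab) models$PylS$clade_seeds[match(lab, pylrs_labels)]
      acc_el <- function(f) {
        if (f == "pylT") mk_trna("A", family = "pylT", anticodon = "CTA")
        else gene_el(f, prot = evolve_sequence(models$aux[[f]], 0.2))
      }
      if (preset$pyl != "none") {
        cluster <- list()
        if (preset$pyl == "single_pylS") {
          prot <- paste0(evolve_sequence(models$aux$PylSn, 0.15),
                         evolve_sequence(pyl_seed("Methanosarcinaceae"), D_WITHIN))
          cluster <- list(gene_el("PylS", prot = prot))
        } else if (preset$pyl == "split_pylSn_pylSc") {
          cluster <- list(
            gene_el("PylSn", prot = evolve_sequence(models$aux$PylSn, 0.15)),
            gene_el("PylSc", prot = evolve_sequence(pyl_seed("Bacteria"), D_WITHIN)))
        } else {  # pylSc_only
          sd <- if (preset$taxon == "bathyarchaeote_BA2")
            evolve_sequence(models$PylS$root, D_ORPHAN)  # novel lineage
          else pyl_seed("Methanomassiliicoccales")
          cluster <- list(gene_el("PylSc", prot = evolve_sequence(sd, D_WITHIN)))
        }
        for (f in preset$pyl_accessories) cluster <- c(cluster, list(acc_el(f)))
        add_locus(cluster)
      }

      ## Sec trait: homologs of the four selenoprotein families
      if (isTRUE(preset$sec)) {
        sps <- evolve_sequence(models$aux$SPS, 0.2)
        if (isTRUE(preset$sps_split)) {
          L <- nchar(sps)
          f1 <- substr(sps, 1L, floor(0.53 * L))
          f2 <- substr(sps, floor(0.45 * L), L)
          add_locus(list(gene_el("SPS", prot = f1), gene_el("SPS", prot = f2),
                         gene_el("HdrA", prot = evolve_sequence(models$aux$HdrA, 0.2))))
        } else {
          add_locus(list(gene_el("SPS", prot = sps),
                         gene_el("HdrA", prot = evolve_sequence(models$aux$HdrA, 0.2))))
        }
        add_locus(list(gene_el("VhuD", prot = evolve_sequence(models$aux$VhuD, 0.2)),
                       gene_el("VhuU", prot = evolve_sequence(models$aux$VhuU, 0.2))))
      }

      ## marker genes on two contigs (taxonomy channel for decontamination)
      for (k in 1:2)
        add_locus(list(gene_el("marker",
                               prot = evolve_sequence(models$aux$marker, 0.1))))

      ## --- assemble contigs ------------------------------------------
      draw_len <- function() {
        round(preset$contig_len_min +
                stats::rexp(1, 1 / (preset$contig_len_mean - preset$contig_len_min)))
      }
      locus_nt <- function(locus) {
        parts <- character(0)
        for (i in seq_along(locus$genes)) {
          if (i > 1L) parts <- c(parts,
                                 paste(random_nt(intergene_gap, preset$gc), collapse = ""))
          parts <- c(parts, locus$genes[[i]]$nt)
        }
        paste(parts, collapse = "")
      }

      ## group loci that must share a contig
      colo <- vapply(loci, function(l)
        if (is.na(l$colocate)) NA_integer_ else l$colocate, 0L)
      groups <- list()
      for (i in seq_along(loci)) {
        if (is.na(colo[i])) groups[[length(groups) + 1L]] <- i
      }
      for (g in unique(colo[!is.na(colo)]))
        groups[[length(groups) + 1L]] <- which(!is.na(colo) & colo == g)

      cidx <- 0L
      place <- function(nts) {
        ## nts: character vector of locus sequences to put on one contig
        cidx <<- cidx + 1L
        cid <- sprintf("%s_c%02d", gname, cidx)
        total <- sum(nchar(nts))
        need <- round(3.3 * total) + 600L * length(nts)
        if (!is.null(preset$contig_len_max) && need > preset$contig_len_max)
          stop(sprintf("contig too short for planted locus on %s (need %d, max %d)",
                       cid, need, preset$contig_len_max), call. = FALSE)
        clen <- max(need, draw_len())
        ## spread loci across the contig with wide margins
        slots <- length(nts)
        span <- floor((clen - 400L) / slots)
        offs <- integer(slots); gap_fill <- character(0)
        seqv <- character(0); cursor <- 0L
        gc_count <- 0L
        for (s in seq_len(slots)) {
          lo <- 200L + (s - 1L) * span
          hi <- lo + span - nchar(nts[s]) - 200L
          off <- if (hi > lo) sample(lo:hi, 1L) else lo
          offs[s] <- off
          cursor <- cursor  # placeholder
        }
        ## build sequence with compensated intergenic GC
        gene_gc <- sum(vapply(strsplit(nts, ""), function(x)
          sum(x %in% c("G", "C")), 0L))
        inter_len <- clen - sum(nchar(nts))
        p <- (preset$gc * clen - gene_gc) / inter_len
        p <- min(max(p, 0.02), 0.98)
        chars <- random_nt(clen, p)
        starts <- integer(slots)
        for (s in seq_len(slots)) {
          g <- seq_chars(nts[s])
          chars[(offs[s] + 1L):(offs[s] + length(g))] <- g
          starts[s] <- offs[s] + 1L
        }
        list(id = cid, seq = paste(chars, collapse = ""), starts = starts,
             len = clen)
      }

      for (grp in groups) {
        nts <- vapply(loci[grp], locus_nt, "")
        pl <- place(nts)
        contigs[pl$id] <- pl$seq
        t_contig[[length(t_contig) + 1L]] <- data.frame(
          contig_id = pl$id, genome = gname, stringsAsFactors = FALSE)
        depth_rows[[length(depth_rows) + 1L]] <- data.frame(
          contig_id = pl$id,
          mean_depth = preset$depth *
            if (depth_sigma > 0) exp(rnorm(1, 0, depth_sigma)) else 1,
          stringsAsFactors = FALSE)
        for (s in seq_along(grp)) {
          locus <- loci[[grp[s]]]
          pos <- pl$starts[s]
          for (i in seq_along(locus$genes)) {
            el <- locus$genes[[i]]
            glen <- nchar(el$nt)
            gstart <- pos; gend <- pos + glen - 1L
            pos <- gend + 1L + intergene_gap
            attrs <- list(ID = el$id, family = el$family, genome = gname)
            if (!is.na(el$clade)) attrs$clade_truth <- el$clade
            if (!is.na(el$protein_id)) attrs$protein_id <- el$protein_id
            gene_rows[[length(gene_rows) + 1L]] <- data.frame(
              contig_id = pl$id, source = "sepmine_sim",
              feature_type = el$type, start = gstart, end = gend,
              strand = "+", ID = el$id, family = el$family,
              clade_truth = ifelse(is.na(el$clade), NA, el$clade),
              protein_id = el$protein_id, genome = gname,
              stringsAsFactors = FALSE)
            gene_rows[[length(gene_rows)]]$attributes <- list(attrs)
            if (el$type == "gene") {
              prot_rows[[length(prot_rows) + 1L]] <- data.frame(
                id = el$protein_id, description = sprintf("%s %s", el$family, gname),
                residues = el$prot, stringsAsFactors = FALSE)
            } else {
              trna_rows[[length(trna_rows) + 1L]] <- data.frame(
                id = el$id, description = sprintf("%s %s", el$family, gname),
                residues = el$nt, stringsAsFactors = FALSE)
            }
            t_gene[[length(t_gene) + 1L]] <- data.frame(
              gene_id = el$id, protein_id = el$protein_id,
              family = el$family,
              clade = ifelse(is.na(el$clade), NA, el$clade),
              genome = gname, contig_id = pl$id,
              sepcysE_class = el$sepcysE_class, stringsAsFactors = FALSE)
            if (!is.null(el$truth_feat)) {
              tf <- el$truth_feat
              t_feat[[length(t_feat) + 1L]] <- data.frame(
                protein_id = el$protein_id, family = tf$family,
                clade = tf$clade,
                res444_class = tf$res444_class %||% NA_character_,
                seprs_truncation = tf$seprs_truncation %||% NA_character_,
                indel_234_235 = tf$indel_234_235 %||% NA_integer_,
                loop_144_147 = tf$loop_144_147 %||% NA_character_,
                persulfide_cys_count = tf$persulfide_cys_count %||% NA_integer_,
                plp_conserved = tf$plp_conserved %||% NA,
                stringsAsFactors = FALSE)
            }
            if (el$family == "marker") {
              t_marker[[length(t_marker) + 1L]] <- data.frame(
                contig_id = pl$id, taxon = gname, stringsAsFactors = FALSE)
            }
          }
        }
      }

      ## extra gene-free contigs + one sub-threshold short contig
      n_extra <- max(preset$n_contigs - cidx, 0L) + 1L
      for (k in seq_len(n_extra)) {
        cidx <- cidx + 1L
        cid <- sprintf("%s_c%02d", gname, cidx)
        clen <- if (k == n_extra) 1200L else draw_len()
        contigs[cid] <- paste(random_nt(clen, preset$gc), collapse = "")
        t_contig[[length(t_contig) + 1L]] <- data.frame(
          contig_id = cid, genome = gname, stringsAsFactors = FALSE)
        depth_rows[[length(depth_rows) + 1L]] <- data.frame(
          contig_id = cid,
          mean_depth = preset$depth *
            if (depth_sigma > 0) exp(rnorm(1, 0, depth_sigma)) else 1,
          stringsAsFactors = FALSE)
      }

      ## per-genome trait truth
      t_trait[[length(t_trait) + 1L]] <- data.frame(
        genome = gname,
        has_seprs = !is.null(preset$seprs),
        has_sepcyss = !is.null(preset$sepcyss),
        sepcysE_status = preset$sepcysE_mode,
        pyl_architecture = preset$pyl,
        pyl_accessories = paste(preset$pyl_accessories, collapse = ","),
        sec_families = if (isTRUE(preset$sec)) "SPS,HdrA,VhuD,VhuU" else "",
        sps_split = isTRUE(preset$sps_split),
        stringsAsFactors = FALSE)
    }

    genes <- do.call(rbind, gene_rows)
    out <- list(
      contigs = contigs,
      depth = do.call(rbind, depth_rows),
      genes = genes,
      proteins = do.call(rbind, prot_rows),
      trnas = do.call(rbind, trna_rows),
      trna_annot = do.call(rbind, trna_annot),
      truth = list(contigs = do.call(rbind, t_contig),
                   genes = do.call(rbind, t_gene),
                   pairings = do.call(rbind, t_pair),
                   features = do.call(rbind, t_feat),
                   traits = do.call(rbind, t_trait),
                   trnas = do.call(rbind, t_trna),
                   markers = do.call(rbind, t_marker)),
      seed = seed)
    class(out) <- "synthetic_metagenome"
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_metagenome <- function(x, ...) {
  cat(sprintf("synthetic_metagenome: %d genomes, %d contigs (%.2f Mb), %d genes, %d tRNAs\n",
              length(unique(x$truth$contigs$genome)), length(x$contigs),
              sum(nchar(x$contigs)) / 1e6, nrow(x$proteins),
              nrow(x$trnas)))
  invisible(x)
}

#' Write a synthetic metagenome to a directory
#'
#' Emits `contigs.fna`, `depth.tsv`, `genes.gff3`, `proteins.faa`,
#' `trnas.fna`, `trnas.tsv` and `truth/*.tsv`.
#'
#' @param mg a [generate_metagenome()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metagenome <- function(mg, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(mg$contigs, file.path(dir, "contigs.fna"))
  write_depth_table(mg$depth, file.path(dir, "depth.tsv"))
  write_gff3(mg$genes, file.path(dir, "genes.gff3"))
  write_fasta(mg$proteins, file.path(dir, "proteins.faa"))
  write_fasta(mg$trnas, file.path(dir, "trnas.fna"))
  write.table(mg$trna_annot, file.path(dir, "trnas.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(mg$truth))
    write.table(mg$truth[[nm]], file.path(dir, "truth", paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
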