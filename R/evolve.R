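#' Evolve a protein sequence by uniform substitution plus planned indels
#'
#' Sites accumulate Poisson-distributed substitution events under a
#' 20-state uniform (Jukes-Cantor-like) replacement process in which each
#' event draws the new residue uniformly from all 20 amino acids.  With
#' `d` expected substitutions per site the event rate is `(20/19) d`, so
#' the expected fractional identity between start and end sequence is
#' `1/20 + (19/20) exp(-(20/19) d)`.  Planned indels are applied after
#' substitution at reference coordinates, and feature-plan residues are
#' re-imposed last so diagnostic sites are never mutated away unless the
#' plan marks them absent.
#'
#' @param seed_seq starting protein sequence (string over the 20-residue
#'   alphabet).
#' @param distance expected substitutions per site (>= 0).
#' @param indel_plan list of entries `list(type = "delete", at, len)`
#'   (remove reference positions `at .. at+len-1`) or
#'   `list(type = "insert", after, len)` (insert `len` random residues
#'   after reference position `after`).
#' @param feature_plan list of entries `list(pos, residue)` fixing the
#'   residue at a reference position, or `list(pos, forbid, residue)`
#'   replacing a forbidden residue (e.g. ensure a site is *not* Cys).
#'   Positions deleted by the indel plan are skipped.
#' @return evolved protein sequence (string).  Uses the current RNG
#'   stream; seed at the caller.
#' @export
evolve_sequence <- function(seed_seq, distance, indel_plan = NULL,
                            feature_plan = NULL) {
  if (distance < 0) stop("distance must be >= 0", call. = FALSE)
  x <- seq_chars(toupper(seed_seq))
  L <- length(x)
  ## composition of k >= 1 uniform replacement events is uniform, so only
  ## whether any event hit a site matters
  nev <- rpois(L, (20 / 19) * distance)
  hit <- which(nev > 0L)
  if (length(hit) > 0L) x[hit] <- sample(AA20, length(hit), replace = TRUE)

  ## map from reference position to current position offset under indels
  offset_at <- function(pos, applied) {
    off <- 0L
    for (p in applied) {
      if (p$type == "delete") {
        if (pos >= p$at && pos <= p$at + p$len - 1L) return(NA_integer_)
        if (pos > p$at + p$len - 1L) off <- off - p$len
      } else if (pos > p$after) off <- off + p$len
    }
    off
  }
  if (!is.null(indel_plan) && length(indel_plan) > 0L) {
    ## apply in descending coordinate order so earlier reference
    ## coordinates stay valid during application
    key <- vapply(indel_plan, function(p)
      if (p$type == "delete") p$at else p$after, 0)
    for (p in indel_plan[order(-key)]) {
      if (p$type == "delete") {
        if (p$at < 1L || p$at + p$len - 1L > L)
          stop("indel region outside sequence", call. = FALSE)
        x <- x[-seq.int(p$at, p$at + p$len - 1L)]
      } else if (p$type == "insert") {
        if (p$after < 0L || p$after > L)
          stop("indel region outside sequence", call. = FALSE)
        ins <- sample(AA20, p$len, replace = TRUE)
        x <- append(x, ins, after = p$after)
      } else stop("unknown indel type", call. = FALSE)
    }
  }
  if (!is.null(feature_plan)) {
    for (f in feature_plan) {
      off <- offset_at(f$pos, indel_plan)
      if (is.na(off)) next  # site deleted by plan
      i <- f$pos + off
      if (i < 1L || i > length(x)) next
      if (!is.null(f$forbid)) {
        if (x[i] == f$forbid) x[i] <- f$residue
      } else x[i] <- f$residue
    }
  }
  paste(x, collapse = "")
}

#' Construct a protein family model
#'
#' A family model plants a star-like clade structure: one family root
#' sequence, per-clade seeds evolved at `d_between` from the root, and
#' clade members evolved at `d_within` from their clade seed.  Orphan and
#' novel lineages are singleton/small lineages evolved directly from the
#' root.  Per-clade indel and feature plans let diagnostic sites (e.g.
#' residue 444 class, the 234/235 indel, persulfide cysteines) be planted
#' deterministically.
#'
#' @param name family name (e.g. `"SepRS"`).
#' @param length reference sequence length (residues).
#' @param clade_sizes integer vector of member counts per clade.
#' @param d_within expected substitutions/site from clade seed to member.
#' @param d_between expected substitutions/site from family root to clade
#'   seed; must exceed `d_within`.
#' @param clade_labels optional character labels (default `"I"`, `"II"`, ...).
#' @param clade_plans optional list (per clade) of
#'   `list(indels = ..., features = ...)` plans as in [evolve_sequence()].
#' @param orphans number of singleton orphan lineages.
#' @param novel_sizes integer vector of member counts for unlabeled novel
#'   lineages (used by the PylRS preset).
#' @param d_orphan root-to-orphan/novel-lineage distance (default
#'   `d_between`).
#' @param root_features feature plan applied to the family root (and so
#'   inherited by every lineage whose plan does not override it).
#' @param sim_band accepted percent-similarity range between lineage
#'   seeds (default `c(36, 45)`); realized draws are kept inside it so
#'   cross-lineage similarity stays in the band the thresholds assume.
#' @return object of class `family_model`.
#' @export
family_model <- function(name, length, clade_sizes, d_within, d_between,
                         clade_labels = NULL, clade_plans = NULL,
                         orphans = 0L, novel_sizes = integer(),
                         d_orphan = d_between, root_features = NULL,
                         sim_band = c(36, 45)) {
  if (any(clade_sizes < 1L)) stop("clade sizes must be >= 1", call. = FALSE)
  if (d_within <= 0 || d_within >= 3 || d_between <= 0 || d_between >= 3)
    stop("distances must lie in (0, 3)", call. = FALSE)
  if (d_within >= d_between)
    stop("within-clade distance must be smaller than between-clade distance",
         call. = FALSE)
  if (is.null(clade_labels))
    clade_labels <- as.character(utils::as.roman(seq_along(clade_sizes)))
  stopifnot(length(clade_labels) == length(clade_sizes))
  if (is.null(clade_plans)) clade_plans <- rep(list(NULL), length(clade_sizes))
  structure(list(name = name, length = as.integer(length),
                 clade_sizes = as.integer(clade_sizes),
                 d_within = d_within, d_between = d_between,
                 clade_labels = clade_labels, clade_plans = clade_plans,
                 orphans = as.integer(orphans),
                 novel_sizes = as.integer(novel_sizes),
                 d_orphan = d_orphan, root_features = root_features,
                 sim_band = sim_band),
            class = "family_model")
}

## expected fractional identity after total distance d under the uniform
## 20-state process
expected_identity <- function(d) 1 / 20 + (19 / 20) * exp(-(20 / 19) * d)

#' Realize the sequences of a family model
#'
#' Draws the family root, clade seeds, members, orphans and novel-lineage
#' members.  Lineage seeds are drawn banded (deterministically, from the
#' same stream): candidates are redrawn until the realized divergence
#' from every previous lineage seed is within ~3% of its expectation and
#' the pairwise percent similarity falls inside the model's `sim_band`,
#' so cross-lineage similarity reliably occupies the band the search and
#' partition thresholds assume.
#'
#' @param model a [family_model()].
#' @param seed integer seed (the realization is deterministic given it).
#' @return object of class `family_set`: list with `members` (data frame
#'   `id`, `family`, `clade`, `role`, `residues`), `root`, `clade_seeds`,
#'   and the model.  Roles are `"member"`, `"orphan"` or `"novel"`;
#'   novel lineages get clade labels `novel_1`, `novel_2`, ...
#' @export
realize_family <- function(model, seed) {
  with_seed(seed, {
    root <- paste(sample(AA20, model$length, replace = TRUE), collapse = "")
    if (!is.null(model$root_features))
      root <- evolve_sequence(root, 0, feature_plan = model$root_features)
    nclade <- length(model$clade_sizes)
    ## draw lineage seeds whose realized pairwise divergence stays close
    ## to its expectation: evolutionary wander in the seed draws would
    ## otherwise blur the similarity bands the presets are built around
    exp_diff <- 1 - expected_identity(2 * model$d_between)
    hamming <- function(x, y) {
      nmin <- min(nchar(x), nchar(y))
      mean(seq_chars(substr(x, 1, nmin)) != seq_chars(substr(y, 1, nmin)))
    }
    ## hamming band first (cheap), then the local-alignment similarity
    ## band itself: trimmed local alignments have a fat upper tail that
    ## raw site divergence does not bound
    draw_banded <- function(distance, others, expected, tries = 200L,
                            sim_band = model$sim_band, sim_checks = 40L) {
      best <- NULL; best_dev <- Inf; checks <- 0L
      for (k in seq_len(tries)) {
        s <- evolve_sequence(root, distance,
                             feature_plan = model$root_features)
        dev <- if (length(others) == 0L) 0 else
          max(abs(vapply(others, hamming, 0, y = s) / expected - 1))
        if (dev < best_dev) { best <- s; best_dev <- dev }
        if (dev <= 0.03) {
          if (length(others) == 0L) return(s)
          if (checks >= sim_checks) return(best)
          checks <- checks + 1L
          sims <- vapply(others, sequence_similarity, 0, b = s)
          if (all(sims >= sim_band[1] & sims <= sim_band[2])) return(s)
        }
      }
      best
    }
    seeds <- character(nclade)
    for (i in seq_len(nclade)) {
      s <- draw_banded(model$d_between, seeds[seq_len(i - 1L)], exp_diff)
      ## clade-specific indels/features are applied on top of the
      ## banded draw (they barely change pairwise divergence)
      s <- evolve_sequence(s, 0,
                           indel_plan = model$clade_plans[[i]]$indels,
                           feature_plan = c(model$root_features,
                                            model$clade_plans[[i]]$features))
      seeds[i] <- s
    }
    rows <- list()
    for (i in seq_len(nclade)) {
      for (k in seq_len(model$clade_sizes[i])) {
        s <- evolve_sequence(seeds[i], model$d_within,
                             feature_plan = c(model$root_features,
                                              model$clade_plans[[i]]$features))
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_%s_%02d", model$name, model$clade_labels[i], k),
          family = model$name, clade = model$clade_labels[i],
          role = "member", residues = s, stringsAsFactors = FALSE)
      }
    }
    exp_diff_o <- 1 - expected_identity(model$d_orphan + model$d_between)
    if (model$orphans > 0L) {
      for (k in seq_len(model$orphans)) {
        s <- draw_banded(model$d_orphan, seeds, exp_diff_o)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_orphan_%02d", model$name, k),
          family = model$name, clade = sprintf("orphan_%d", k),
          role = "orphan", residues = s, stringsAsFactors = FALSE)
      }
    }
    if (length(model$novel_sizes) > 0L) {
      for (i in seq_along(model$novel_sizes)) {
        lin_seed <- draw_banded(model$d_orphan, seeds, exp_diff_o)
        for (k in seq_len(model$novel_sizes[i])) {
          s <- evolve_sequence(lin_seed, model$d_within,
                               feature_plan = model$root_features)
          rows[[length(rows) + 1L]] <- data.frame(
            id = sprintf("%s_novel%d_%02d", model$name, i, k),
            family = model$name, clade = sprintf("novel_%d", i),
            role = "novel", residues = s, stringsAsFactors = FALSE)
        }
      }
    }
    members <- do.call(rbind, rows)
    structure(list(members = members, root = root, clade_seeds = seeds,
                   model = model), class = "family_set")
  })
}

#' @export
print.family_set <- function(x, ...) {
  cat(sprintf("family_set '%s': %d sequences (%d clades, %d orphans, %d novel lineages)\n",
              x$model$name, nrow(x$members), length(x$model$clade_sizes),
              x$model$orphans, length(x$model$novel_sizes)))
  invisible(x)
}
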