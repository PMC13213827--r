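# End-to-end driver: from parsed structures plus a tabular bioactivity
# extract to candidate targets, cascade winners, activity link rows and the
# assembled table variants.

#' Apply SEQADV entries to a chain sequence
#'
#' Replaces each SEQADV-documented position of the ATOM-derived chain
#' sequence with the database reference residue, yielding the sequence the
#' reference database records (the modeled structure does not contain these
#' residues, which is why matches built from it are discarded later).
#'
#' @param s A `structure_record`.
#' @param chain_id Chain identifier.
#' @return The adjusted one-letter sequence, or `NA` when no applicable
#'   SEQADV entry exists.
#' @export
seqadv_adjusted_sequence <- function(s, chain_id) {
  sa <- s$seqadv_entries
  sa <- sa[sa$chain == chain_id & nzchar(sa$reference_residue), , drop = FALSE]
  chain <- s$chains[[chain_id]]
  if (is.null(chain) || nrow(sa) == 0L) return(NA_character_)
  seq <- strsplit(chain$seq_atom, "")[[1]]
  changed <- FALSE
  for (i in seq_len(nrow(sa))) {
    idx <- match(sa$position[i], chain$residues$resno)
    if (is.na(idx)) next
    ref1 <- .aa_one(sa$reference_residue[i])
    if (!is.na(ref1) && ref1 != seq[idx]) {
      seq[idx] <- ref1
      changed <- TRUE
    }
  }
  if (!changed) return(NA_character_)
  paste(seq, collapse = "")
}

#' Link bioactivity records to structures
#'
#' For every structure-ligand pair (binding mode) or structure (target mode),
#' aligns the relevant chain sequences against each candidate target's
#' effective assay sequences (assay variant when present and usable,
#' component otherwise), keeps matches at or above the 80 percent identity
#' floor, retains the single best alignment per candidate, grades the
#' molecule correspondence between the structure ligand and the target's
#' activity molecules, counts binding-site mutations, and runs the selection
#' cascade.
#'
#' In binding mode only chains contributing residues to the ligand's binding
#' site are aligned; SEQADV-adjusted chain sequences are additionally aligned
#' and flagged so the cascade can discard them.
#'
#' @param structures List of `structure_record` objects.
#' @param activities Data frame with columns `assay_id`, `target_accession`,
#'   `target_type`, `component_sequence`, `variant_sequence` (may be `NA`),
#'   `canonical_smiles`, `standard_type`, `standard_value`, `standard_units`,
#'   `pchembl_value`, `doc_date`, `data_validity_comment`.
#' @param het_smiles Named character vector mapping HET codes to SMILES (the
#'   component-dictionary route for structure-side molecules).
#' @param mode `"binding"` or `"target"`.
#' @param cutoff Binding-site cutoff in angstroms.
#' @param min_score Minimum raw Smith-Waterman score for a match to count as
#'   a candidate link. The internal aligner reports the single best local
#'   alignment for every sequence pair, so a significance floor stands in
#'   for the statistical reporting threshold of a database search tool;
#'   without it, short chance alignments between unrelated sequences (which
#'   can reach 100 percent identity over a handful of residues) would enter
#'   the candidate set.
#' @param ref_formulas Optional reference formulas for [extract_ligands()].
#' @return List with `ligand_rows`, `activity_rows`, `candidates` (list per
#'   unit), `cascade` (list of `run_cascade()` results per unit), `winners`
#'   (a [cascade_winner_table()]), `sites` (binding sites per pair, binding
#'   mode only).
#' @export
link_bioactivities <- function(structures, activities, het_smiles,
                               mode = c("binding", "target"),
                               cutoff = 3.25, min_score = 70,
                               ref_formulas = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(activities))

  act_forms <- mol_forms(unique(activities$canonical_smiles))
  act_form_of <- function(smi) act_forms[match(smi, act_forms$input), ]
  lig_forms <- if (length(het_smiles) > 0L) {
    mol_forms(unname(het_smiles), id = names(het_smiles))
  } else {
    NULL
  }

  targets <- unique(activities[, c("target_accession", "target_type",
                                   "component_sequence")])
  if (anyDuplicated(targets$target_accession)) {
    stop("inconsistent target_type/component_sequence for one accession",
         call. = FALSE)
  }

  ligand_rows <- do.call(rbind, lapply(structures, extract_ligands,
                                       ref_formulas = ref_formulas))
  rownames(ligand_rows) <- NULL

  units <- list()   # one element per structure (target) or pair (binding)
  if (mode == "binding") {
    for (s in structures) {
      ligs <- ligand_rows[ligand_rows$structure_id == s$structure_id, ,
                          drop = FALSE]
      for (i in seq_len(nrow(ligs))) {
        units[[length(units) + 1L]] <- list(s = s, lig = ligs[i, ])
      }
    }
  } else {
    units <- lapply(structures, function(s) list(s = s, lig = NULL))
  }

  candidates <- list()
  cascade <- list()
  sites <- list()
  keys <- list()
  activity_rows <- list()

  for (u in units) {
    s <- u$s
    site <- NULL
    chains <- names(s$chains)
    if (mode == "binding") {
      site <- find_binding_site(s, u$lig$het_code, u$lig$chain_id,
                                u$lig$residue_number, cutoff = cutoff)
      chains <- names(site$sequence_positions)
    }

    per_target <- lapply(seq_len(nrow(targets)), function(ti) {
      tg <- targets[ti, ]
      acts_t <- activities[activities$target_accession == tg$target_accession, ,
                           drop = FALSE]
      eff <- unique(vapply(seq_len(nrow(acts_t)), function(ai) {
        resolve_assay_sequence(acts_t$variant_sequence[ai],
                               tg$component_sequence)$sequence
      }, character(1)))

      alns <- list()
      for (ch in chains) {
        qseqs <- list(list(seq = s$chains[[ch]]$seq_atom, seqadv = FALSE))
        adj <- seqadv_adjusted_sequence(s, ch)
        if (!is.na(adj)) {
          qseqs[[2]] <- list(seq = adj, seqadv = TRUE)
        }
        for (q in qseqs) {
          for (hseq in eff) {
            a <- align_sequences(q$seq, hseq,
                                 query_id = paste0(s$structure_id, "_", ch),
                                 hit_id = tg$target_accession,
                                 from_seqadv = q$seqadv)
            a$query_chain <- ch
            if (!a$sub_threshold && a$score >= min_score) {
              alns[[length(alns) + 1L]] <- a
            }
          }
        }
      }
      if (length(alns) == 0L) return(NULL)
      best <- select_best_alignment(alns)

      mol_level <- NA_integer_
      row_levels <- rep(NA_integer_, nrow(acts_t))
      if (mode == "binding" && !is.null(lig_forms)) {
        lf <- lig_forms[match(u$lig$het_code, lig_forms$id), ]
        if (!is.na(lf$id[1])) {
          row_levels <- vapply(acts_t$canonical_smiles, function(smi) {
            match_level(lf, act_form_of(smi))
          }, integer(1))
          mol_level <- max(row_levels)
        }
      }

      n_mut <- NA_integer_
      if (mode == "binding") {
        n_mut <- count_site_mutations(best, site, best$query_chain)
      }
      n_dp <- NA_integer_
      if (mode == "binding") {
        n_dp <- nrow(unique(acts_t[, c("assay_id", "standard_type",
                                       "standard_value", "standard_units")]))
      }
      list(target = tg, best = best, score = score_match(best),
           mol_level = mol_level, row_levels = row_levels,
           n_mut = n_mut, n_dp = n_dp, acts = acts_t)
    })
    per_target <- Filter(Negate(is.null), per_target)

    cand <- if (length(per_target) == 0L) {
      target_candidates(character(), character(), numeric())
    } else {
      target_candidates(
        target_accession = vapply(per_target, function(p) p$target$target_accession, character(1)),
        target_type = vapply(per_target, function(p) p$target$target_type, character(1)),
        cov_id = vapply(per_target, function(p) p$score$cov_id, numeric(1)),
        molecule_level = vapply(per_target, function(p) p$mol_level, integer(1)),
        n_site_mutations = vapply(per_target, function(p) p$n_mut, integer(1)),
        n_unique_datapoints = vapply(per_target, function(p) p$n_dp, integer(1)),
        from_seqadv = vapply(per_target, function(p) p$best$from_seqadv, logical(1))
      )
    }
    res <- run_cascade(cand, mode = mode)

    key <- data.frame(
      structure_id = s$structure_id,
      het_code = if (mode == "binding") u$lig$het_code else NA_character_,
      chain_id = if (mode == "binding") u$lig$chain_id else NA_character_,
      stringsAsFactors = FALSE
    )
    keys[[length(keys) + 1L]] <- key
    candidates[[length(candidates) + 1L]] <- cand
    cascade[[length(cascade) + 1L]] <- res
    if (mode == "binding") {
      sites[[paste(s$structure_id, u$lig$het_code, u$lig$chain_id,
                   sep = ":")]] <- site
    }

    for (p in per_target) {
      acts_t <- p$acts
      variant_origin <- vapply(seq_len(nrow(acts_t)), function(ai) {
        resolve_assay_sequence(acts_t$variant_sequence[ai],
                               p$target$component_sequence)$origin
      }, character(1))
      block <- data.frame(
        structure_id = key$structure_id,
        het_code = key$het_code,
        chain_id = key$chain_id,
        assay_id = acts_t$assay_id,
        target_accession = p$target$target_accession,
        target_type = p$target$target_type,
        canonical_smiles = acts_t$canonical_smiles,
        standard_type = acts_t$standard_type,
        standard_value = acts_t$standard_value,
        standard_units = acts_t$standard_units,
        pchembl_value = acts_t$pchembl_value,
        doc_date = acts_t$doc_date,
        data_validity_comment = acts_t$data_validity_comment,
        variant_origin = variant_origin,
        identity = p$best$identity,
        coverage = p$best$coverage_query,
        cov_id = p$score$cov_id,
        d_query = p$score$d_query,
        d_hit = p$score$d_hit,
        quality = p$score$quality,
        molecule_level = p$row_levels,
        n_site_mutations = p$n_mut,
        from_seqadv = p$best$from_seqadv,
        match_chain = p$best$query_chain,
        stringsAsFactors = FALSE
      )
      activity_rows[[length(activity_rows) + 1L]] <- block
    }
  }

  keys_df <- do.call(rbind, c(keys, list(make.row.names = FALSE)))
  activity_df <- if (length(activity_rows) > 0L) {
    do.call(rbind, c(activity_rows, list(make.row.names = FALSE)))
  } else {
    NULL
  }
  list(
    ligand_rows = ligand_rows,
    activity_rows = activity_df,
    candidates = candidates,
    cascade = cascade,
    winners = cascade_winner_table(cascade, keys_df, mode = mode),
    sites = sites
  )
}

#' Extract per-structure header quality rows
#'
#' @param structures List of `structure_record` objects.
#' @param density_scores Optional named numeric vector (structure_id ->
#'   density-support score; -1 encodes "not computable").
#' @return Data frame suitable as `structure_rows` for [merge_outputs()].
#' @export
structure_quality_rows <- function(structures, density_scores = NULL) {
  out <- do.call(rbind, lapply(structures, function(s) {
    data.frame(
      structure_id = s$structure_id,
      resolution = s$resolution,
      r_factor = s$r_factor,
      r_free = s$r_free,
      experimental_method = s$experimental_method,
      deposition_date = s$deposition_date,
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(density_scores)) {
    out$density_score <- unname(density_scores[out$structure_id])
  }
  rownames(out) <- NULL
  out
}

#' Run the full linking pipeline
#'
#' Executes ligand extraction, binding- and target-mode linking, the merges,
#' and all four table variants.
#'
#' @inheritParams link_bioactivities
#' @param density_scores Optional named numeric vector passed to
#'   [structure_quality_rows()].
#' @return List with `binding`, `target` (the two [link_bioactivities()]
#'   results), `structure_rows`, and `tables`: `FULL`, `FILTERED`, `TARGET`,
#'   `TARGET_FILTERED`.
#' @export
run_pipeline <- function(structures, activities, het_smiles, cutoff = 3.25,
                         min_score = 70, ref_formulas = NULL,
                         density_scores = NULL) {
  binding <- link_bioactivities(structures, activities, het_smiles,
                                mode = "binding", cutoff = cutoff,
                                min_score = min_score,
                                ref_formulas = ref_formulas)
  target <- link_bioactivities(structures, activities, het_smiles,
                               mode = "target", cutoff = cutoff,
                               min_score = min_score,
                               ref_formulas = ref_formulas)
  structure_rows <- structure_quality_rows(structures, density_scores)

  full <- merge_outputs(binding$ligand_rows, structure_rows,
                        binding$activity_rows)
  target_full <- merge_outputs(binding$ligand_rows, structure_rows,
                               target$activity_rows)
  list(
    binding = binding,
    target = target,
    structure_rows = structure_rows,
    tables = list(
      FULL = full,
      FILTERED = build_variant(full, "FILTERED", binding$winners),
      TARGET = build_variant(target_full, "TARGET"),
      TARGET_FILTERED = build_variant(target_full, "TARGET_FILTERED",
                                      target$winners)
    )
  )
}
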