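# Assembly of the linked table: full outer join of the ligand inventory,
# structure quality fields, and activity links, with merge indicators; the
# four variants; the growth timeline; and quality-filter queries.

.join_key <- c("structure_id", "het_code", "chain_id")

# Activity-block columns a variant may blank out.
.activity_cols <- c(
  "assay_id", "target_accession", "target_type", "standard_type",
  "standard_value", "standard_units", "pchembl_value", "doc_date",
  "data_validity_comment", "canonical_smiles", "variant_origin",
  "identity", "coverage", "cov_id", "d_query", "d_hit", "quality",
  "molecule_level", "n_site_mutations", "from_seqadv", "match_chain"
)
.ligand_specific_activity_cols <- c("molecule_level", "n_site_mutations")

#' Full outer join of the three per-tool outputs
#'
#' Ligand rows are keyed by (structure_id, het_code, chain_id), structure
#' rows by structure_id, activity rows by the ligand key plus target and
#' assay. Every input row is represented in the output; two merge indicators
#' record which sources contributed: `merge_ligand_structure` (`both`,
#' `ligand_only`, `structure_only`, or `neither` for activity-only rows) and
#' `merge_activity` (`present`/`absent`).
#'
#' @param ligand_rows Ligand inventory data frame (see [extract_ligands()]).
#' @param structure_rows Data frame with `structure_id`, `resolution`,
#'   `r_factor`, `r_free`, `experimental_method`, `deposition_date`, and
#'   optionally `density_score` (the externally supplied density-support
#'   column; -1 encodes "not computable").
#' @param activity_rows Optional activity-link data frame (see
#'   [link_bioactivities()]).
#' @return A `linked_table` data frame.
#' @export
merge_outputs <- function(ligand_rows, structure_rows, activity_rows = NULL) {
  .check_unique_keys(ligand_rows, .join_key, "ligand")
  .check_unique_keys(structure_rows, "structure_id", "structure")

  lig <- ligand_rows
  lig$.in_ligand <- TRUE
  if (is.null(activity_rows) || nrow(activity_rows) == 0L) {
    m1 <- lig
    m1$.in_activity <- FALSE
  } else {
    act <- activity_rows
    act$.in_activity <- TRUE
    m1 <- merge(lig, act, by = .join_key, all = TRUE)
  }
  str <- structure_rows
  str$.in_structure <- TRUE
  m2 <- merge(m1, str, by = "structure_id", all = TRUE)

  in_l <- !is.na(m2$.in_ligand) & m2$.in_ligand
  in_s <- !is.na(m2$.in_structure) & m2$.in_structure
  in_a <- !is.na(m2$.in_activity) & m2$.in_activity
  m2$merge_ligand_structure <- ifelse(in_l & in_s, "both",
                               ifelse(in_l, "ligand_only",
                               ifelse(in_s, "structure_only", "neither")))
  m2$merge_activity <- ifelse(in_a, "present", "absent")
  m2$.in_ligand <- m2$.in_structure <- m2$.in_activity <- NULL
  class(m2) <- c("linked_table", "data.frame")
  m2
}

.check_unique_keys <- function(df, key, source) {
  key <- intersect(key, names(df))
  if (length(key) == 0L || nrow(df) == 0L) return(invisible(TRUE))
  k <- do.call(paste, c(df[key], sep = "\r"))
  dup <- unique(k[duplicated(k)])
  for (d in dup) {
    rows <- df[k == d, , drop = FALSE]
    if (nrow(unique(rows)) > 1L) {
      stop("duplicate conflicting ", source, " rows for key ",
           gsub("\r", ":", d), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build one of the four table variants
#'
#' `FULL` is the merged binding-mode table unchanged. `TARGET` is the merged
#' target-mode table with the ligand-specific activity columns dropped.
#' `FILTERED` / `TARGET_FILTERED` additionally keep activity blocks only for
#' cascade winners: non-winner activity rows are removed, and a key that
#' thereby loses all its activity rows keeps one representative row with an
#' absent activity block (SEQADV-only matches disappear this way too, since
#' SEQADV-built candidates can never win).
#'
#' @param rows A `linked_table`.
#' @param variant `"FULL"`, `"TARGET"`, `"FILTERED"`, or `"TARGET_FILTERED"`.
#' @param cascade_results For the filtered variants: data frame of winners
#'   with key columns (`structure_id`, and for binding mode `het_code`,
#'   `chain_id`) plus `winner`, carrying a `mode` attribute (see
#'   [cascade_winner_table()]).
#' @return A `linked_table` restricted to the variant.
#' @export
build_variant <- function(rows, variant = c("FULL", "TARGET", "FILTERED",
                                            "TARGET_FILTERED"),
                          cascade_results = NULL) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(rows))
  if (variant == "FULL") return(rows)
  if (variant == "TARGET") return(.drop_ligand_activity_cols(rows))

  if (is.null(cascade_results)) {
    stop("cascade_results is required for variant ", variant, call. = FALSE)
  }
  mode <- attr(cascade_results, "mode")
  want <- if (variant == "FILTERED") "binding" else "target"
  if (!is.null(mode) && !identical(mode, want)) {
    stop("variant ", variant, " requires cascade results in ", want,
         " mode, got ", mode, call. = FALSE)
  }
  key <- if (want == "binding") .join_key else "structure_id"

  act <- rows$merge_activity == "present"
  rk <- do.call(paste, c(rows[key], sep = "\r"))
  wk <- do.call(paste, c(cascade_results[key], sep = "\r"))
  winner_of <- cascade_results$winner[match(rk, wk)]
  keep_act <- act & !is.na(winner_of) &
    !is.na(rows$target_accession) & rows$target_accession == winner_of

  out <- rows[!act | keep_act, , drop = FALSE]

  # keys that lost every activity row but carry ligand/structure data keep a
  # single representative with the activity block blanked
  lost <- setdiff(unique(rk[act & !keep_act]), unique(rk[!act | keep_act]))
  if (length(lost) > 0L) {
    cand <- rows[act & !keep_act & rk %in% lost &
                   rows$merge_ligand_structure != "neither", , drop = FALSE]
    ck <- do.call(paste, c(cand[key], sep = "\r"))
    reps <- cand[!duplicated(ck), , drop = FALSE]
    if (nrow(reps) > 0L) {
      blank_cols <- setdiff(intersect(.activity_cols, names(reps)), key)
      for (cl in blank_cols) {
        reps[[cl]] <- reps[[cl]][rep(NA_integer_, nrow(reps))]
      }
      reps$merge_activity <- "absent"
      out <- rbind(out, reps)
    }
  }
  rownames(out) <- NULL
  if (variant == "TARGET_FILTERED") out <- .drop_ligand_activity_cols(out)
  class(out) <- c("linked_table", "data.frame")
  out
}

.drop_ligand_activity_cols <- function(rows) {
  drop <- intersect(.ligand_specific_activity_cols, names(rows))
  rows[drop] <- NULL
  rows
}

#' Tabulate cascade winners for variant building
#'
#' @param results List of `run_cascade()` results.
#' @param keys Data frame of the per-result keys (`structure_id` and, in
#'   binding mode, `het_code`, `chain_id`), one row per result.
#' @param mode `"binding"` or `"target"`.
#' @return Data frame `keys` + `winner` + `decided_at`, with a `mode`
#'   attribute.
#' @export
cascade_winner_table <- function(results, keys, mode = c("binding", "target")) {
  mode <- match.arg(mode)
  stopifnot(nrow(keys) == length(results))
  out <- keys
  out$winner <- vapply(results, `[[`, character(1), "winner")
  out$decided_at <- vapply(results, function(r) {
    d <- r$audit$decided_at
    if (is.na(d)) NA_character_ else d
  }, character(1))
  attr(out, "mode") <- mode
  out
}

#' Growth timeline of linked complexes
#'
#' Each unique complex (structure, het code) with at least one activity link
#' is dated by the later of the structure deposition date and the bioactivity
#' document date; the timeline gives per-year new-complex counts and the
#' running cumulative total. Complexes missing both dates are excluded with
#' a warning.
#'
#' @param rows A `linked_table` (or any data frame with `structure_id`,
#'   `het_code`, `merge_activity`, `deposition_date`, `doc_date`).
#' @return Data frame with `year`, `new_complexes`, `cumulative`.
#' @export
growth_timeline <- function(rows) {
  act <- rows[rows$merge_activity == "present", , drop = FALSE]
  if (nrow(act) == 0L) {
    return(data.frame(year = integer(), new_complexes = integer(),
                      cumulative = integer()))
  }
  dep <- as.Date(act$deposition_date)
  doc <- as.Date(act$doc_date)
  eff <- as.Date(ifelse(is.na(dep), doc,
                 ifelse(is.na(doc), dep, pmax(dep, doc))),
                 origin = "1970-01-01")
  complex <- paste(act$structure_id, act$het_code, sep = "\r")
  dropped <- unique(complex[is.na(eff)])
  dropped <- setdiff(dropped, complex[!is.na(eff)])
  if (length(dropped) > 0L) {
    warning(length(dropped), " complex(es) excluded from timeline: ",
            "missing both deposition and document date")
  }
  ok <- !is.na(eff)
  if (!any(ok)) {
    return(data.frame(year = integer(), new_complexes = integer(),
                      cumulative = integer()))
  }
  first <- tapply(eff[ok], complex[ok], min)
  years <- as.integer(format(as.Date(first, origin = "1970-01-01"), "%Y"))
  tab <- table(years)
  data.frame(
    year = as.integer(names(tab)),
    new_complexes = as.integer(tab),
    cumulative = cumsum(as.integer(tab))
  )
}

.quality_rank <- c(NONE = 0L, BRONZE = 1L, SILVER = 2L, GOLD = 3L)

#' Filter a linked table down to a high-quality subset
#'
#' Applies the conjunction of the requested criteria. A row lacking a field
#' some active criterion needs (for example no density score under a density
#' criterion) is removed by that criterion. Supported criteria:
#' `skip_reasons_allowed` (character vector; rows with any other skip reason,
#' or without a ligand block, are removed), `density_min` / `density_max`
#' (bounds on `density_score`), `resolution_max` (inclusive upper bound),
#' `remove_duplicates` (collapse identical (molecule, target, activity type,
#' value, units) tuples to one row), `remove_flagged_validity` (drop rows
#' with a non-empty data-validity comment), `molecule_level_min`,
#' `identity_min`, `site_mutation_max`, `quality_min` (`"BRONZE"`,
#' `"SILVER"`, or `"GOLD"`).
#'
#' @param rows A `linked_table`.
#' @param criteria Named list of criteria.
#' @return The filtered `linked_table`.
#' @export
apply_quality_filters <- function(rows, criteria = list()) {
  stopifnot(is.data.frame(rows), is.list(criteria))
  known <- c("skip_reasons_allowed", "density_min", "density_max",
             "resolution_max", "remove_duplicates", "remove_flagged_validity",
             "molecule_level_min", "identity_min", "site_mutation_max",
             "quality_min")
  unknown <- setdiff(names(criteria), known)
  if (length(unknown) > 0L) {
    stop("unknown quality criterion: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  col <- function(name) {
    if (name %in% names(rows)) rows[[name]] else rep(NA, nrow(rows))
  }
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(criteria$skip_reasons_allowed)) {
    sr <- col("skip_reasons")
    ok <- !is.na(sr) & vapply(strsplit(ifelse(is.na(sr), "", sr), ";"),
      function(r) all(r[nzchar(r)] %in% criteria$skip_reasons_allowed),
      logical(1))
    keep <- keep & ok
  }
  if (!is.null(criteria$density_min)) {
    v <- col("density_score")
    keep <- keep & !is.na(v) & v >= criteria$density_min
  }
  if (!is.null(criteria$density_max)) {
    v <- col("density_score")
    keep <- keep & !is.na(v) & v <= criteria$density_max
  }
  if (!is.null(criteria$resolution_max)) {
    v <- col("resolution")
    keep <- keep & !is.na(v) & v <= criteria$resolution_max
  }
  if (isTRUE(criteria$remove_flagged_validity)) {
    v <- col("data_validity_comment")
    keep <- keep & (is.na(v) | !nzchar(v))
  }
  if (!is.null(criteria$molecule_level_min)) {
    v <- col("molecule_level")
    keep <- keep & !is.na(v) & v >= criteria$molecule_level_min
  }
  if (!is.null(criteria$identity_min)) {
    v <- col("identity")
    keep <- keep & !is.na(v) & v >= criteria$identity_min
  }
  if (!is.null(criteria$site_mutation_max)) {
    v <- col("n_site_mutations")
    keep <- keep & !is.na(v) & v <= criteria$site_mutation_max
  }
  if (!is.null(criteria$quality_min)) {
    v <- .quality_rank[as.character(col("quality"))]
    keep <- keep & !is.na(v) & v >= .quality_rank[[criteria$quality_min]]
  }
  out <- rows[keep, , drop = FALSE]
  if (isTRUE(criteria$remove_duplicates)) {
    tup <- paste(out$canonical_smiles %||% "", out$target_accession %||% "",
                 out$standard_type %||% "", out$standard_value %||% "",
                 out$standard_units %||% "", sep = "\r")
    has_act <- !is.na(out$merge_activity) & out$merge_activity == "present"
    out <- out[!has_act | !duplicated(paste(has_act, tup)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
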